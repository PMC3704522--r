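#' Segment mitochondria from a single-channel image
#'
#' Thresholds the channel (Otsu by default), labels 8-connected foreground
#' components, discards components smaller than \code{minAreaPx}, and
#' measures each object's length and width as the side lengths of its
#' minimum-area enclosing rectangle. The rectangle is fitted to the pixel
#' centers and widened by the 1-px pixel extent per dimension, so an
#' axis-aligned a x b pixel block measures exactly a x b pixels while
#' rotated rods are not inflated by their rasterization staircase. The 2-D
#' size is length times width, the measurement convention used for
#' electron-micrograph morphometry.
#'
#' @param image numeric matrix, one channel.
#' @param pixelSize pixel size, um/px.
#' @param thresholdMethod \code{"otsu"} or \code{"fixed"}.
#' @param threshold fixed threshold value (required when
#'   \code{thresholdMethod = "fixed"}).
#' @param minAreaPx minimum component area in pixels.
#' @return A data.frame with columns \code{id}, \code{length_um},
#'   \code{width_um}, \code{size2d_um2}, \code{area_px}, \code{center_row},
#'   \code{center_col}; zero rows for an empty foreground. The integer label
#'   matrix is attached as \code{attr(, "labels")} for downstream geometry.
#' @examples
#' img <- matrix(0, 40, 40); img[10:29, 10:14] <- 1
#' segmentMito(img, pixelSize = 0.1, thresholdMethod = "fixed",
#'             threshold = 0.5)
#' @export
segmentMito <- function(image, pixelSize, thresholdMethod = c("otsu", "fixed"),
                        threshold = NULL, minAreaPx = 4L) {
  stopifnot(is.matrix(image))
  checkPositive(pixelSize, "pixelSize")
  thresholdMethod <- match.arg(thresholdMethod)
  thr <- if (thresholdMethod == "fixed") {
    if (is.null(threshold))
      stop("a fixed 'threshold' value is required", call. = FALSE)
    threshold
  } else {
    rng <- range(image)
    if (rng[1L] == rng[2L]) rng[2L]        # flat image -> empty foreground
    else EBImage::otsu(EBImage::Image(image), range = rng)
  }
  mask <- image > thr
  labels <- labelComponents8(mask)
  emptyDf <- data.frame(id = integer(0), length_um = numeric(0),
                        width_um = numeric(0), size2d_um2 = numeric(0),
                        area_px = integer(0), center_row = numeric(0),
                        center_col = numeric(0))
  nLab <- max(labels)
  if (nLab == 0L) {
    attr(emptyDf, "labels") <- labels
    attr(emptyDf, "pixelSize") <- pixelSize
    return(emptyDf)
  }
  keepId <- 0L
  rows <- list()
  relabel <- matrix(0L, nrow(labels), ncol(labels))
  for (k in seq_len(nLab)) {
    px <- which(labels == k, arr.ind = TRUE)
    if (nrow(px) < minAreaPx) next
    keepId <- keepId + 1L
    relabel[px] <- keepId
    # min-area rectangle over pixel centers, plus the 1-px pixel extent:
    # exact for axis-aligned blocks and, unlike rectangles over pixel
    # corners, not inflated by the staircase of rotated rods
    rect <- minAreaRect(px) + 1
    rows[[keepId]] <- data.frame(
      id = keepId,
      length_um = rect[1L] * pixelSize,
      width_um = rect[2L] * pixelSize,
      size2d_um2 = rect[1L] * rect[2L] * pixelSize^2,
      area_px = nrow(px),
      center_row = mean(px[, 1L]),
      center_col = mean(px[, 2L]))
  }
  out <- if (keepId > 0L) do.call(rbind, rows) else emptyDf
  rownames(out) <- NULL
  attr(out, "labels") <- relabel
  attr(out, "pixelSize") <- pixelSize
  out
}

# 8-connected component labeling by iterative minimum-label propagation.
# Adequate for the compact objects this package segments; converges in
# O(object diameter) passes.
labelComponents8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- which(mask)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  repeat {
    new <- lab
    for (s in shifts) {
      shifted <- matrix(0L, nr, nc)
      rs <- max(1, 1 + s[1L]):min(nr, nr + s[1L])
      cs <- max(1, 1 + s[2L]):min(nc, nc + s[2L])
      shifted[rs, cs] <- lab[rs - s[1L], cs - s[2L]]
      upd <- mask & shifted > 0L & (new == 0L | shifted < new)
      new[upd] <- shifted[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- sort(unique(lab[lab > 0L]))
  out <- matrix(0L, nr, nc)
  out[lab > 0L] <- match(lab[lab > 0L], ids)
  out
}

# Minimum-area enclosing rectangle via rotating the convex hull edges;
# returns c(length, width), length >= width.
minAreaRect <- function(pts) {
  hull <- pts[grDevices::chull(pts[, 1L], pts[, 2L]), , drop = FALSE]
  nh <- nrow(hull)
  if (nh == 1L) return(c(0, 0))
  if (nh == 2L) {
    d <- sqrt(sum((hull[2L, ] - hull[1L, ])^2))
    return(c(d, 0))
  }
  best <- c(Inf, Inf); bestArea <- Inf
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len
    v <- c(-u[2L], u[1L])
    pu <- hull %*% u
    pv <- hull %*% v
    side <- c(max(pu) - min(pu), max(pv) - min(pv))
    area <- side[1L] * side[2L]
    if (area < bestArea) {
      bestArea <- area
      best <- sort(side, decreasing = TRUE)
    }
  }
  best
}

#' Mean 2-D size with standard error
#'
#' @param objects a mitochondrion table carrying \code{size2d_um2} (from
#'   \code{\link{segmentMito}}, \code{\link{simulateEMObjects}} or
#'   \code{\link{readObjectTable}}).
#' @return list with \code{meanSize2d} (um^2), \code{se} (sample SD /
#'   sqrt(n); 0 with \code{singleObject = TRUE} when n = 1) and \code{n}.
#' @examples
#' sizeStats(simulateEMObjects(500, 0.8, 1.0, 0.6, 0.8, seed = 1))
#' @export
sizeStats <- function(objects) {
  if (!is.data.frame(objects) || nrow(objects) < 1L)
    stop("value error: 'objects' must contain at least one mitochondrion",
         call. = FALSE)
  s <- objects$size2d_um2
  if (is.null(s)) s <- objects$length_um * objects$width_um
  n <- length(s)
  list(meanSize2d = mean(s),
       se = if (n > 1L) stats::sd(s) / sqrt(n) else 0,
       n = n, singleObject = n == 1L)
}

#' Classify a cell's mitochondrial network as fused
#'
#' A cell is scored as fused when either the largest object holds at least
#' \code{largestFractionMin} of the total mitochondrial 2-D area, or the
#' longest object reaches \code{lengthMinUm}. Ties for the largest object are
#' broken by the lowest id.
#'
#' @param objects a per-cell mitochondrion table with \code{size2d_um2} and
#'   \code{length_um}.
#' @param largestFractionMin area-fraction threshold.
#' @param lengthMinUm length threshold, um.
#' @return list with \code{fused} (logical), \code{largestFraction},
#'   \code{largestId}, \code{maxLengthUm}.
#' @export
classifyFused <- function(objects, largestFractionMin = 0.5,
                          lengthMinUm = 5.0) {
  if (!is.data.frame(objects) || nrow(objects) < 1L)
    stop("classification error: the cell has no mitochondria", call. = FALSE)
  s <- objects$size2d_um2
  if (is.null(s)) s <- objects$length_um * objects$width_um
  frac <- max(s) / sum(s)
  largestId <- objects$id[which.max(s)]   # earliest (lowest id) on ties
  maxLen <- max(objects$length_um)
  list(fused = frac >= largestFractionMin || maxLen >= lengthMinUm,
       largestFraction = frac, largestId = largestId,
       maxLengthUm = maxLen)
}

#' SR:mitochondrial contact-site frequency
#'
#' A mitochondrion is a contact when its SR distance is at most
#' \code{dMaxNm}; the frequency is the ratio of contacts to mitochondria
#' scored.
#'
#' @param objects a mitochondrion table with \code{sr_distance_nm} on every
#'   row (from \code{\link{imageContactDistance}},
#'   \code{\link{simulateEMObjects}} or a measurement table).
#' @param dMaxNm contact distance criterion, nm (default 30, a typical
#'   SR/ER-mitochondria gap; the criterion is deliberately configurable).
#' @return A \code{\linkS4class{ContactSummary}}.
#' @examples
#' em <- simulateEMObjects(50, 0.8, 1, 0.6, 0.8, contactFraction = 0.94,
#'                         seed = 1)
#' contactSites(em)
#' @export
contactSites <- function(objects, dMaxNm = 30) {
  checkPositive(dMaxNm, "dMaxNm")
  d <- objects$sr_distance_nm
  if (is.null(d))
    stop("input error: objects carry no 'sr_distance_nm' column",
         call. = FALSE)
  bad <- which(is.na(d))
  if (length(bad))
    stop(sprintf("input error: missing sr_distance_nm for object id %s",
                 paste(objects$id[bad], collapse = ", ")), call. = FALSE)
  nC <- sum(d <= dMaxNm)
  new("ContactSummary", nMito = nrow(objects), nContacts = as.integer(nC),
      frequency = nC / nrow(objects), dMaxNm = dMaxNm)
}

#' Boundary-to-SR distances for segmented objects
#'
#' For each segmented mitochondrion, the minimum Euclidean distance from its
#' boundary pixels to the SR foreground, computed on the distance transform
#' of the SR mask and reported in nanometres. An object overlapping the SR
#' mask has distance 0; with an empty SR mask all distances are infinite.
#'
#' @param objects output of \code{\link{segmentMito}} (its \code{labels}
#'   attribute is used), or pass \code{labels} explicitly.
#' @param srMask logical/binary matrix of SR foreground, same shape.
#' @param pixelSize pixel size, um/px.
#' @param labels optional integer label matrix overriding the attribute.
#' @return \code{objects} with an \code{sr_distance_nm} column added.
#' @export
imageContactDistance <- function(objects, srMask, pixelSize = NULL,
                                 labels = NULL) {
  if (is.null(labels)) labels <- attr(objects, "labels")
  if (is.null(labels))
    stop("no label matrix: pass segmentMito output or 'labels'",
         call. = FALSE)
  if (is.null(pixelSize)) pixelSize <- attr(objects, "pixelSize")
  checkPositive(pixelSize, "pixelSize")
  stopifnot(all(dim(srMask) == dim(labels)))
  srMask <- srMask > 0
  if (!any(srMask)) {
    objects$sr_distance_nm <- rep(Inf, nrow(objects))
    attr(objects, "emptySRMask") <- TRUE
    return(objects)
  }
  # distance of every pixel to the nearest SR pixel
  d <- as.matrix(EBImage::distmap(EBImage::Image(1 - srMask)))
  objects$sr_distance_nm <- vapply(objects$id, function(k) {
    bd <- boundaryPixels(labels == k)
    min(d[bd]) * pixelSize * 1000
  }, numeric(1))
  objects
}

# Logical matrix marking foreground pixels with a 4-neighbour outside the
# object (or on the image edge).
boundaryPixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  inner <- mask
  inner[2:(nr - 1), 2:(nc - 1)] <-
    mask[2:(nr - 1), 2:(nc - 1)] &
    mask[1:(nr - 2), 2:(nc - 1)] & mask[3:nr, 2:(nc - 1)] &
    mask[2:(nr - 1), 1:(nc - 2)] & mask[2:(nr - 1), 3:nc]
  edge <- mask
  edge[2:(nr - 1), 2:(nc - 1)] <- FALSE
  mask & (!inner | edge)
}
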