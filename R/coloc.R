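#' Extract a dual-channel line-scan profile
#'
#' Samples both channels along the segment from \code{p0} to \code{p1} at
#' unit-pixel spacing by bilinear interpolation, averaging across
#' \code{widthPx} integer perpendicular offsets, and reports positions in
#' micrometres. This is the computational counterpart of the line scans drawn
#' alongside dual-label confocal panels (mitochondrial vs SR/ER marker).
#'
#' @param image rows x cols x 2 numeric array (or list of two matrices).
#' @param p0,p1 numeric(2) segment endpoints as (row, col) pixel coordinates
#'   (1-based); must differ and lie inside the image together with the
#'   perpendicular averaging offsets.
#' @param widthPx odd perpendicular averaging width in pixels.
#' @param pixelSize pixel size, um/px.
#' @return A \code{\linkS4class{LineScanProfile}}.
#' @examples
#' img <- array(1, dim = c(32, 32, 2))
#' lineScan(img, c(5, 5), c(5, 28), pixelSize = 0.1)
#' @export
lineScan <- function(image, p0, p1, widthPx = 1L, pixelSize = 0.1) {
  if (is.list(image)) image <- array(c(image[[1L]], image[[2L]]),
                                     dim = c(dim(image[[1L]]), 2L))
  stopifnot(length(dim(image)) == 3L, dim(image)[3L] >= 2L)
  checkPositive(pixelSize, "pixelSize")
  widthPx <- as.integer(widthPx)
  if (widthPx < 1L || widthPx %% 2L == 0L)
    stop("parameter 'widthPx' must be odd and >= 1", call. = FALSE)
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  if (len == 0)
    stop("geometry error: p0 and p1 must differ", call. = FALSE)
  nr <- dim(image)[1L]; nc <- dim(image)[2L]
  inside <- function(p) all(p >= 1) && p[1L] <= nr && p[2L] <= nc
  if (!inside(p0) || !inside(p1))
    stop("geometry error: endpoints must lie inside the image",
         call. = FALSE)
  u <- d / len
  v <- c(-u[2L], u[1L])                    # unit perpendicular
  steps <- seq(0, floor(len))              # unit-pixel spacing
  offs <- seq(-(widthPx %/% 2L), widthPx %/% 2L)
  acc1 <- acc2 <- numeric(length(steps))
  for (o in offs) {
    rr <- p0[1L] + steps * u[1L] + o * v[1L]
    cc <- p0[2L] + steps * u[2L] + o * v[2L]
    if (any(rr < 1 | rr > nr | cc < 1 | cc > nc))
      stop("geometry error: averaging width extends outside the image",
           call. = FALSE)
    acc1 <- acc1 + bilinearAt(image[, , 1L], rr, cc)
    acc2 <- acc2 + bilinearAt(image[, , 2L], rr, cc)
  }
  new("LineScanProfile",
      positions = steps * pixelSize,
      ch1 = acc1 / length(offs), ch2 = acc2 / length(offs),
      endpoints = rbind(p0, p1), widthPx = widthPx)
}

#' Pearson correlation of a line-scan profile
#'
#' The single quantitative colocalization readout adopted here: the Pearson
#' correlation of the two channel profiles. It is invariant under affine
#' rescaling of either channel and symmetric in the channels. When either
#' channel has zero variance the correlation is undefined and \code{NA} is
#' returned with a warning.
#'
#' @param profile a \code{\linkS4class{LineScanProfile}}.
#' @return numeric r in [-1, 1], or \code{NA} when undefined.
#' @examples
#' img <- array(0, dim = c(32, 32, 2))
#' img[, , 1] <- matrix(runif(1024), 32)
#' img[, , 2] <- 2 * img[, , 1] + 5
#' profileCorrelation(lineScan(img, c(16, 2), c(16, 30)))
#' @export
profileCorrelation <- function(profile) {
  stopifnot(is(profile, "LineScanProfile"))
  x <- profile@ch1; y <- profile@ch2
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("undefined correlation: a channel has zero variance along the scan")
    return(NA_real_)
  }
  stats::cor(x, y)
}
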