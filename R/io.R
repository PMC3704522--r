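# File formats: comma-separated UTF-8 CSV with a mandatory header row and
# '.' decimal; times in seconds, lengths in um, distances in nm, intensities
# in fau, with units embedded in column names. Multichannel images travel as
# TIFF (one directory per channel) with a JSON sidecar carrying pixel size;
# an explicit pixelSize argument always wins over the sidecar.

sidecarPath <- function(path) paste0(path, ".json")

#' Write / read a fluorescence trace as CSV
#'
#' The CSV has columns \code{time_s}, \code{fluorescence_fau}; the stimulus
#' time and any generator ground truth travel in a JSON sidecar
#' (\code{<path>.json}). An explicit \code{tApp} argument on read overrides
#' the sidecar.
#'
#' @param trace a \code{\linkS4class{FluorescenceTrace}}.
#' @param path CSV file path.
#' @return \code{writeTraceCsv} returns \code{path} invisibly;
#'   \code{readTraceCsv} returns a \code{FluorescenceTrace}.
#' @export
writeTraceCsv <- function(trace, path) {
  df <- data.frame(time_s = sampleTimes(trace),
                   fluorescence_fau = intensities(trace))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(t_app_s = stimulusTime(trace),
               ground_truth = groundTruth(trace))
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeTraceCsv
#' @param tApp stimulus time (s); overrides the sidecar when given.
#' @export
readTraceCsv <- function(path, tApp = NULL) {
  df <- readCsvChecked(path, c("time_s", "fluorescence_fau"))
  truth <- list()
  if (is.null(tApp)) {
    sp <- sidecarPath(path)
    if (!file.exists(sp))
      stop(sprintf("parse error: %s has no sidecar and no tApp was given",
                   path), call. = FALSE)
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
    tApp <- meta$t_app_s
    if (length(meta$ground_truth)) truth <- as.list(meta$ground_truth)
  }
  FluorescenceTrace(df$time_s, df$fluorescence_fau, tApp,
                    groundTruth = truth)
}

readCsvChecked <- function(path, requiredCols) {
  if (!file.exists(path))
    stop(sprintf("parse error: file '%s' does not exist", path),
         call. = FALSE)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop(sprintf("parse error in '%s': %s", path,
                                conditionMessage(e)), call. = FALSE))
  missing <- setdiff(requiredCols, names(df))
  if (length(missing))
    stop(sprintf("schema error: '%s' lacks column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df
}

#' Write / read a metrics table as CSV
#'
#' Values round-trip to within 1e-9 relative (15 significant digits).
#'
#' @param metrics a data.frame (e.g. from \code{\link{analyzeTraceBatch}}).
#' @param path CSV file path.
#' @export
writeMetricsCsv <- function(metrics, path) {
  out <- metrics
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) format(x, digits = 15,
                                                  trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeMetricsCsv
#' @export
readMetricsCsv <- function(path) {
  readCsvChecked(path, character(0))
}

#' Read / write an EM-style mitochondrion object table
#'
#' Columns: \code{id}, \code{length_um}, \code{width_um}, optional
#' \code{sr_distance_nm} and \code{contact_truth}; \code{size2d_um2} is
#' recomputed as length x width on read.
#'
#' @param path CSV file path.
#' @return A validated object table data.frame.
#' @export
readObjectTable <- function(path) {
  df <- readCsvChecked(path, c("id", "length_um", "width_um"))
  bad <- which(!(df$length_um >= df$width_um & df$width_um > 0))
  if (length(bad))
    stop(sprintf(
      "schema error: '%s' rows %s violate length_um >= width_um > 0", path,
      paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  df$size2d_um2 <- df$length_um * df$width_um
  df
}

#' @rdname readObjectTable
#' @param objects an object table data.frame.
#' @export
writeObjectTable <- function(objects, path) {
  writeMetricsCsv(objects, path)
}

#' Write / read a multichannel image as TIFF
#'
#' Channels are stored as separate TIFF directories (32-bit float);
#' intensities must lie in [0, 1]. Pixel size (um/px) travels in a JSON
#' sidecar; an explicit \code{pixelSize} on read wins over the sidecar.
#'
#' @param image rows x cols x channels numeric array.
#' @param path TIFF file path.
#' @param pixelSize pixel size, um/px.
#' @return \code{readImageTiff} returns a list with \code{image} (array) and
#'   \code{pixelSize}.
#' @export
writeImageTiff <- function(image, path, pixelSize) {
  checkPositive(pixelSize, "pixelSize")
  stopifnot(length(dim(image)) == 3L)
  if (min(image) < 0 || max(image) > 1)
    stop("image intensities must lie in [0, 1] for TIFF storage",
         call. = FALSE)
  planes <- lapply(seq_len(dim(image)[3L]), function(k) image[, , k])
  tiff::writeTIFF(planes, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(pixel_size_um = pixelSize), sidecarPath(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeImageTiff
#' @export
readImageTiff <- function(path, pixelSize = NULL) {
  if (!file.exists(path))
    stop(sprintf("parse error: file '%s' does not exist", path),
         call. = FALSE)
  planes <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  img <- array(unlist(planes), dim = c(dim(planes[[1L]]), length(planes)))
  if (is.null(pixelSize)) {
    sp <- sidecarPath(path)
    if (file.exists(sp))
      pixelSize <- jsonlite::read_json(sp)$pixel_size_um
  }
  list(image = img, pixelSize = pixelSize)
}

#' Pipeline configuration
#'
#' Builds, writes and reads the nested pipeline configuration. The file
#' format is YAML; round-trips are lossless at 15 significant digits.
#'
#' @param kinetics a \code{\link{kineticsConfig}}.
#' @param dMaxNm,largestFractionMin,lengthMinUm,minAreaPx,thresholdMethod
#'   morphometry thresholds (see \code{\link{contactSites}},
#'   \code{\link{classifyFused}}, \code{\link{segmentMito}}).
#' @param pixelSize pixel size, um/px.
#' @param seed integer RNG seed for simulation stages.
#' @param outdir output directory.
#' @return A validated list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(kinetics = kineticsConfig(), dMaxNm = 30,
                           largestFractionMin = 0.5, lengthMinUm = 5.0,
                           minAreaPx = 4L, thresholdMethod = "otsu",
                           pixelSize = 0.1, seed = 1L,
                           outdir = tempdir()) {
  checkPositive(dMaxNm, "dMaxNm")
  checkPositive(largestFractionMin, "largestFractionMin")
  checkPositive(lengthMinUm, "lengthMinUm")
  checkPositive(minAreaPx, "minAreaPx")
  checkPositive(pixelSize, "pixelSize")
  structure(list(
    kinetics = unclass(kinetics),
    morphometry = list(dMaxNm = dMaxNm,
                       largestFractionMin = largestFractionMin,
                       lengthMinUm = lengthMinUm,
                       minAreaPx = as.integer(minAreaPx),
                       thresholdMethod = thresholdMethod),
    pixelSize = pixelSize, seed = as.integer(seed), outdir = outdir),
    class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param config a \code{PipelineConfig}.
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipelineConfig(
    kinetics = do.call(kineticsConfig, raw$kinetics),
    dMaxNm = raw$morphometry$dMaxNm,
    largestFractionMin = raw$morphometry$largestFractionMin,
    lengthMinUm = raw$morphometry$lengthMinUm,
    minAreaPx = raw$morphometry$minAreaPx,
    thresholdMethod = raw$morphometry$thresholdMethod,
    pixelSize = raw$pixelSize, seed = raw$seed, outdir = raw$outdir)
  cfg
}

#' Demo pipeline specification
#'
#' A bundled end-to-end demonstration: two simulated trace groups (a
#' control-like condition and a "forced fusion" condition with larger, later,
#' steeper transients) and two simulated EM groups (small mitochondria with
#' rare SR contacts vs large mitochondria with frequent contacts). Group
#' parameters echo the magnitudes reported for control vs fission-inhibited
#' myotubes.
#'
#' @param nTraces traces per group.
#' @param nObjects mitochondria per EM group.
#' @return A list understood by \code{\link{runPipeline}}'s \code{manifest}.
#' @export
demoPipelineSpec <- function(nTraces = 10L, nObjects = 50L) {
  list(
    traceGroups = list(
      control = list(n = nTraces, baselineF0 = 500, tApp = 30, latency = 8,
                     riseSlope = 70, riseDuration = 8,
                     decayTau = 80 / log(2), noiseSd = 12),
      fused = list(n = nTraces, baselineF0 = 500, tApp = 30, latency = 14,
                   riseSlope = 245, riseDuration = 9,
                   decayTau = 114 / log(2), noiseSd = 45)),
    emGroups = list(
      control = list(n = nObjects, lengthLow = 0.2, lengthHigh = 0.4,
                     widthLow = 0.15, widthHigh = 0.25,
                     contactFraction = 0.04),
      efs5 = list(n = nObjects, lengthLow = 0.8, lengthHigh = 1.0,
                  widthLow = 0.6, widthHigh = 0.8,
                  contactFraction = 0.94)))
}

#' Run the end-to-end pipeline
#'
#' Simulates (or loads) traces and EM object tables per the manifest,
#' analyzes every trace, summarizes groups with the matching statistics
#' (t-test / ANOVA for numeric metrics, Fisher's exact for contact), and
#' writes a metrics CSV plus a JSON report to \code{config$outdir}. Log
#' lines record the config hash and seed. Identical config + seed give
#' byte-identical metrics CSVs.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param manifest either a simulation spec (see
#'   \code{\link{demoPipelineSpec}}) or a data.frame with columns
#'   \code{trace_id}, \code{file}, \code{t_app}, \code{group} referring to
#'   trace CSVs.
#' @return The report, invisibly: \code{metrics} (data.frame),
#'   \code{summaries}, \code{contacts}, \code{tests}, and output paths.
#' @examples
#' \donttest{
#' rep <- runPipeline(pipelineConfig(outdir = tempdir()),
#'                    demoPipelineSpec(nTraces = 10))
#' rep$tests$amplitude_fau
#' }
#' @export
runPipeline <- function(config, manifest = demoPipelineSpec()) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  cfgFile <- tempfile(fileext = ".yaml")
  writePipelineConfig(config, cfgFile)
  message(sprintf("[pipeline] config hash %s, seed %d",
                  unname(tools::md5sum(cfgFile)), config$seed))
  kcfg <- do.call(kineticsConfig, config$kinetics)

  if (is.data.frame(manifest)) {
    need <- c("trace_id", "file", "t_app", "group")
    missing <- setdiff(need, names(manifest))
    if (length(missing))
      stop(sprintf("schema error: manifest lacks column(s) %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    gone <- !file.exists(manifest$file)
    if (any(gone))
      stop(sprintf("schema error: missing trace file(s) %s",
                   paste(manifest$file[gone], collapse = ", ")),
           call. = FALSE)
    traces <- lapply(seq_len(nrow(manifest)), function(i)
      readTraceCsv(manifest$file[i], tApp = manifest$t_app[i]))
    ids <- manifest$trace_id
    groups <- manifest$group
    emTables <- list()
  } else {
    seedBase <- config$seed
    traces <- list(); ids <- character(0); groups <- character(0)
    k <- 0L
    for (g in names(manifest$traceGroups)) {
      sp <- manifest$traceGroups[[g]]
      for (i in seq_len(sp$n)) {
        k <- k + 1L
        args <- sp[setdiff(names(sp), "n")]
        args$seed <- seedBase + k
        traces[[k]] <- do.call(simulateTrace, args)
        ids <- c(ids, sprintf("%s_%02d", g, i))
        groups <- c(groups, g)
      }
    }
    emTables <- lapply(seq_along(manifest$emGroups), function(j) {
      sp <- manifest$emGroups[[j]]
      sp$seed <- seedBase + 10000L + j
      do.call(simulateEMObjects, sp)
    })
    names(emTables) <- names(manifest$emGroups)
  }
  message(sprintf("[pipeline] analyzing %d traces in %d group(s)",
                  length(traces), length(unique(groups))))
  metrics <- analyzeTraceBatch(traces, kcfg, ids = ids, groups = groups)
  metricsPath <- file.path(config$outdir, "transient_metrics.csv")
  writeMetricsCsv(metrics, metricsPath)

  summaries <- list(); tests <- list()
  for (m in c("amplitude_fau", "max_rate_fau_per_s", "response_time_s",
              "time_to_peak_s", "t50_s")) {
    cens <- if (m == "t50_s") metrics$t50_censored else NULL
    sg <- summarizeGroups(metrics[[m]], metrics$group, censored = cens,
                          metricName = m)
    summaries[[m]] <- sg$groups
    if (length(sg$tests)) tests[[m]] <- sg$tests[[1L]]
  }

  contacts <- list()
  if (length(emTables)) {
    contacts <- lapply(emTables, contactSites,
                       dMaxNm = config$morphometry$dMaxNm)
    for (g in names(emTables)) {
      st <- sizeStats(emTables[[g]])
      summaries[[paste0("size2d_", g)]] <-
        data.frame(label = g, n = st$n, mean = st$meanSize2d, se = st$se,
                   n_censored_excluded = 0L)
    }
    if (length(emTables) >= 2L) {
      cs <- contacts[[1L]]; cs2 <- contacts[[2L]]
      tab <- matrix(c(cs@nContacts, cs@nMito - cs@nContacts,
                      cs2@nContacts, cs2@nMito - cs2@nContacts), 2L)
      tests[["contact_frequency"]] <- fisherExact(tab)
    }
  }

  report <- list(
    seed = config$seed,
    metrics_csv = metricsPath,
    n_traces = length(traces),
    group_summaries = lapply(summaries, function(d)
      lapply(seq_len(nrow(d)), function(i)
        as.list(d[i, c("label", "n", "mean", "se",
                       "n_censored_excluded")]))),
    contact_frequencies = lapply(contacts, function(cs)
      list(n_mito = cs@nMito, n_contacts = cs@nContacts,
           frequency = cs@frequency)),
    tests = lapply(tests, function(t)
      list(test = t@testName, statistic = t@statistic,
           df = t@df, p = t@pValue)))
  reportPath <- file.path(config$outdir, "report.json")
  jsonlite::write_json(report, reportPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  message(sprintf("[pipeline] report written to %s", reportPath))
  invisible(c(list(metrics = metrics, summaries = summaries,
                   contacts = contacts, tests = tests),
              report_json = reportPath))
}
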