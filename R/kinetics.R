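#' Kinetics analysis configuration
#'
#' Bundles the tunable parameters of the transient analysis. Defaults are the
#' package's standing choices: a 20 s pre-stimulus baseline window, onset at
#' the first run of 3 consecutive samples exceeding baseline + max(3 x
#' baseline SD, 1 fau), and a 9-sample centered moving average before
#' differentiation. The smoothing window is short against the >= 8 s rises
#' analyzed here, so the maximal slope of the linear rise is measured without
#' attenuation while the central-difference derivative noise stays
#' compatible with the package's recovery targets at realistic trace noise.
#'
#' @param baselineWindow seconds of pre-stimulus trace used for the baseline.
#' @param onsetK onset threshold in multiples of the baseline SD.
#' @param onsetMinSamples consecutive supra-threshold samples required.
#' @param onsetAbsFloor absolute threshold floor, fau (guards noiseless
#'   traces whose baseline SD is 0).
#' @param smoothWindow odd sample count for moving-average smoothing.
#' @return A validated list of class \code{KineticsConfig}.
#' @examples
#' kineticsConfig(smoothWindow = 7)
#' @export
kineticsConfig <- function(baselineWindow = 20, onsetK = 3,
                           onsetMinSamples = 3, onsetAbsFloor = 1,
                           smoothWindow = 9) {
  checkPositive(baselineWindow, "baselineWindow")
  checkPositive(onsetK, "onsetK")
  checkPositive(onsetAbsFloor, "onsetAbsFloor")
  if (onsetMinSamples < 1)
    stop("parameter 'onsetMinSamples' must be >= 1", call. = FALSE)
  smoothWindow <- as.integer(smoothWindow)
  if (smoothWindow < 1L || smoothWindow %% 2L == 0L)
    stop("parameter 'smoothWindow' must be odd and >= 1", call. = FALSE)
  structure(list(baselineWindow = baselineWindow, onsetK = onsetK,
                 onsetMinSamples = as.integer(onsetMinSamples),
                 onsetAbsFloor = onsetAbsFloor,
                 smoothWindow = smoothWindow),
            class = "KineticsConfig")
}

#' Estimate the pre-stimulus baseline
#'
#' Mean and sample SD of the fluorescence over the window
#' \code{[tApp - baselineWindow, tApp)}.
#'
#' @param trace a \code{\linkS4class{FluorescenceTrace}}.
#' @param config a \code{\link{kineticsConfig}}.
#' @return list with \code{baselineF0} and \code{baselineSd} (fau); the SD of
#'   a single-sample window is 0.
#' @export
estimateBaseline <- function(trace, config = kineticsConfig()) {
  tt <- sampleTimes(trace)
  idx <- which(tt >= stimulusTime(trace) - config$baselineWindow &
               tt < stimulusTime(trace))
  if (length(idx) < 5L)
    stop("trace error: fewer than 5 pre-stimulus samples in the baseline window",
         call. = FALSE)
  f <- intensities(trace)[idx]
  list(baselineF0 = mean(f),
       baselineSd = if (length(f) > 1L) stats::sd(f) else 0)
}

#' Detect the response onset ("caffeine response time")
#'
#' Scans the trace from the stimulus time for the first run of
#' \code{onsetMinSamples} consecutive samples exceeding
#' \code{baselineF0 + max(onsetK * baselineSd, onsetAbsFloor)}. The reported
#' onset is the sub-sample linear interpolation of the threshold crossing
#' between the last sub-threshold sample and the first sample of the run,
#' which removes the up-to-one-sample grid bias of reporting the run's first
#' sample time.
#'
#' @param trace a \code{\linkS4class{FluorescenceTrace}}.
#' @param baseline output of \code{\link{estimateBaseline}} on the same trace.
#' @param config a \code{\link{kineticsConfig}}.
#' @return list with \code{responded} (logical), \code{responseTime}
#'   (s after stimulus; NA if no response), \code{onsetTime} (absolute s),
#'   and \code{threshold} (fau).
#' @export
detectOnset <- function(trace, baseline, config = kineticsConfig()) {
  tt <- sampleTimes(trace)
  ff <- intensities(trace)
  thr <- baseline$baselineF0 +
    max(config$onsetK * baseline$baselineSd, config$onsetAbsFloor)
  cand <- which(tt >= stimulusTime(trace))
  above <- ff[cand] > thr
  runStart <- firstRun(above, config$onsetMinSamples)
  if (is.na(runStart))
    return(list(responded = FALSE, responseTime = NA_real_,
                onsetTime = NA_real_, threshold = thr))
  i <- cand[runStart]
  tStar <- tt[i]
  if (i > 1L && ff[i - 1L] <= thr && ff[i] > ff[i - 1L])
    tStar <- tt[i - 1L] + (thr - ff[i - 1L]) / (ff[i] - ff[i - 1L]) *
      (tt[i] - tt[i - 1L])
  rt <- max(tStar - stimulusTime(trace), 0)
  list(responded = TRUE, responseTime = rt,
       onsetTime = stimulusTime(trace) + rt, threshold = thr)
}

# Index of the first element of the first run of >= k TRUEs; NA if none.
firstRun <- function(x, k) {
  if (!length(x)) return(NA_integer_)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= k)
  if (!length(hit)) return(NA_integer_)
  ends[hit[1L]] - r$lengths[hit[1L]] + 1L
}

#' Amplitude and time to peak
#'
#' Amplitude is the maximum post-onset fluorescence minus the baseline; time
#' to peak is measured from the detected onset to the (earliest) maximum.
#'
#' @param trace a \code{\linkS4class{FluorescenceTrace}}.
#' @param baseline output of \code{\link{estimateBaseline}}.
#' @param onset output of \code{\link{detectOnset}}; must have responded.
#' @return list with \code{amplitude} (fau), \code{timeToPeak} (s) and
#'   \code{tPeakAbs} (absolute s; earliest sample at the maximum).
#' @export
peakMetrics <- function(trace, baseline, onset) {
  if (!isTRUE(onset$responded))
    stop("peakMetrics requires a detected onset", call. = FALSE)
  tt <- sampleTimes(trace)
  ff <- intensities(trace)
  idx <- which(tt >= onset$onsetTime)
  iPeak <- idx[which.max(ff[idx])]   # which.max takes the earliest tie
  list(amplitude = ff[iPeak] - baseline$baselineF0,
       timeToPeak = tt[iPeak] - onset$onsetTime,
       tPeakAbs = tt[iPeak])
}

#' Maximal rise rate (dF/dT)
#'
#' Smooths the fluorescence with a centered moving average of
#' \code{smoothWindow} samples, takes central finite differences, and returns
#' the maximum over the onset-to-peak window (clipped to the available
#' samples). With fewer than 3 samples between onset and peak the rate over
#' the available pair is returned with a low-confidence flag.
#'
#' @param trace a \code{\linkS4class{FluorescenceTrace}}.
#' @param config a \code{\link{kineticsConfig}}.
#' @param onsetTime,peakTime absolute times (s) bounding the search window;
#'   defaults span the whole trace.
#' @return list with \code{maxRate} (fau/s) and \code{lowConfidence}
#'   (logical).
#' @export
maxRate <- function(trace, config = kineticsConfig(), onsetTime = NULL,
                    peakTime = NULL) {
  tt <- sampleTimes(trace)
  s <- movingAverage(intensities(trace), config$smoothWindow)
  n <- length(tt)
  lo <- if (is.null(onsetTime)) 1L else
    max(1L, findInterval(onsetTime, tt))
  hi <- if (is.null(peakTime)) n else
    min(n, max(1L, findInterval(peakTime + 1e-9, tt)))
  iRange <- max(lo, 2L):min(hi, n - 1L)
  low <- FALSE
  if (hi - lo < 2L) {           # fewer than 3 samples between onset and peak
    low <- TRUE
    iRange <- max(lo, 2L):min(max(lo + 1L, 2L), n - 1L)
  }
  rates <- (s[iRange + 1L] - s[iRange - 1L]) / (tt[iRange + 1L] - tt[iRange - 1L])
  list(maxRate = max(rates), lowConfidence = low)
}

#' Clearance times t25, t50, t90
#'
#' Times from the peak until 25, 50 and 90 percent of the measured rise
#' (amplitude above the pre-stimulus baseline) has cleared, i.e. the first
#' time after the peak at which the smoothed fluorescence falls to
#' \code{baselineF0 + (1 - q) * amplitude}, with linear interpolation between
#' the bracketing samples. If the record ends before a level is reached the
#' value is censored: the flag is set and the value reports the record's
#' remaining duration after the peak (the recovery was not observed to
#' completion).
#'
#' @param trace a \code{\linkS4class{FluorescenceTrace}}.
#' @param baseline output of \code{\link{estimateBaseline}}.
#' @param peak output of \code{\link{peakMetrics}}; \code{amplitude} must be
#'   positive.
#' @param config a \code{\link{kineticsConfig}} (the smoothing window is
#'   shared with \code{\link{maxRate}}).
#' @return list with \code{t25}, \code{t50}, \code{t90} (s) and logical
#'   \code{t25Censored}, \code{t50Censored}, \code{t90Censored}.
#' @export
clearanceTimes <- function(trace, baseline, peak,
                           config = kineticsConfig()) {
  if (!is.finite(peak$amplitude) || peak$amplitude <= 0)
    stop("metric error: clearance requires a positive amplitude",
         call. = FALSE)
  tt <- sampleTimes(trace)
  s <- movingAverage(intensities(trace), config$smoothWindow)
  iPeak <- which.min(abs(tt - peak$tPeakAbs))
  out <- list()
  for (q in c(0.25, 0.5, 0.9)) {
    lvl <- baseline$baselineF0 + (1 - q) * peak$amplitude
    nm <- paste0("t", q * 100)
    idx <- if (iPeak < length(tt)) (iPeak + 1L):length(tt) else integer(0)
    hit <- idx[which(s[idx] <= lvl)[1L]]
    if (length(hit) == 1L && !is.na(hit)) {
      i0 <- hit - 1L
      tq <- if (s[i0] > lvl)
        tt[i0] + (s[i0] - lvl) / (s[i0] - s[hit]) * (tt[hit] - tt[i0])
      else tt[hit]
      out[[nm]] <- tq - peak$tPeakAbs
      out[[paste0(nm, "Censored")]] <- FALSE
    } else {
      out[[nm]] <- tt[length(tt)] - peak$tPeakAbs
      out[[paste0(nm, "Censored")]] <- TRUE
    }
  }
  out
}

#' Full transient analysis of one trace
#'
#' Runs baseline estimation, onset detection, peak metrics, maximal dF/dT and
#' clearance times in order, and returns the per-trace metric row. A trace
#' with no detectable response yields a row with \code{responded = FALSE} and
#' NA response fields rather than an error.
#'
#' @param trace a \code{\linkS4class{FluorescenceTrace}}.
#' @param config a \code{\link{kineticsConfig}}.
#' @return A one-row data.frame with columns \code{baseline_f0},
#'   \code{baseline_sd}, \code{responded}, \code{response_time_s},
#'   \code{time_to_peak_s}, \code{t_peak_abs_s}, \code{amplitude_fau},
#'   \code{max_rate_fau_per_s}, \code{max_rate_low_confidence},
#'   \code{t25_s}, \code{t50_s}, \code{t90_s} and the three
#'   \code{t*_censored} flags.
#' @examples
#' m <- analyzeTransient(simulateTrace(noiseSd = 0))
#' m$amplitude_fau
#' @export
analyzeTransient <- function(trace, config = kineticsConfig()) {
  baseline <- estimateBaseline(trace, config)
  onset <- detectOnset(trace, baseline, config)
  empty <- data.frame(
    baseline_f0 = baseline$baselineF0, baseline_sd = baseline$baselineSd,
    responded = FALSE, response_time_s = NA_real_,
    time_to_peak_s = NA_real_, t_peak_abs_s = NA_real_,
    amplitude_fau = NA_real_, max_rate_fau_per_s = NA_real_,
    max_rate_low_confidence = NA, t25_s = NA_real_, t50_s = NA_real_,
    t90_s = NA_real_, t25_censored = NA, t50_censored = NA,
    t90_censored = NA)
  if (!onset$responded) return(empty)
  peak <- peakMetrics(trace, baseline, onset)
  if (!is.finite(peak$amplitude) || peak$amplitude <= 0) return(empty)
  rate <- maxRate(trace, config, onsetTime = onset$onsetTime,
                  peakTime = peak$tPeakAbs)
  cl <- clearanceTimes(trace, baseline, peak, config)
  data.frame(
    baseline_f0 = baseline$baselineF0, baseline_sd = baseline$baselineSd,
    responded = TRUE, response_time_s = onset$responseTime,
    time_to_peak_s = peak$timeToPeak, t_peak_abs_s = peak$tPeakAbs,
    amplitude_fau = peak$amplitude, max_rate_fau_per_s = rate$maxRate,
    max_rate_low_confidence = rate$lowConfidence,
    t25_s = cl$t25, t50_s = cl$t50, t90_s = cl$t90,
    t25_censored = cl$t25Censored, t50_censored = cl$t50Censored,
    t90_censored = cl$t90Censored)
}

#' Analyze a batch of traces
#'
#' @param traces a list of \code{\linkS4class{FluorescenceTrace}} objects.
#' @param config a \code{\link{kineticsConfig}}.
#' @param ids optional trace identifiers (defaults to list names or indices).
#' @param groups optional group labels, recycled checkably to the batch size.
#' @return A data.frame with one metric row per trace, in input order, with
#'   leading \code{trace_id} (and \code{group} if given) columns.
#' @export
analyzeTraceBatch <- function(traces, config = kineticsConfig(), ids = NULL,
                              groups = NULL) {
  stopifnot(is.list(traces), length(traces) >= 1L)
  if (is.null(ids))
    ids <- if (!is.null(names(traces))) names(traces)
           else as.character(seq_along(traces))
  rows <- lapply(traces, analyzeTransient, config = config)
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(trace_id = ids, stringsAsFactors = FALSE), out)
  if (!is.null(groups)) {
    if (length(groups) != length(traces))
      stop("'groups' must match the number of traces", call. = FALSE)
    out <- cbind(out[, 1L, drop = FALSE],
                 data.frame(group = as.character(groups)),
                 out[, -1L, drop = FALSE])
  }
  rownames(out) <- NULL
  out
}
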