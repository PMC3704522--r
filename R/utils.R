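# Internal helpers shared across modules.

# Run expr under a fixed RNG seed without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("parameter 'seed' must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

checkPositive <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) || value <= 0)
    stop(sprintf("parameter '%s' must be a single strictly positive number",
                 name), call. = FALSE)
  invisible(value)
}

checkNonNegative <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) || value < 0)
    stop(sprintf("parameter '%s' must be a single non-negative number", name),
         call. = FALSE)
  invisible(value)
}

checkProportion <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value > 1)
    stop(sprintf("parameter '%s' must lie in [0, 1]", name), call. = FALSE)
  invisible(value)
}

checkRange <- function(low, high, nameLow, nameHigh) {
  checkPositive(low, nameLow)
  checkPositive(high, nameHigh)
  if (low >= high)
    stop(sprintf("parameter '%s' must be < '%s'", nameLow, nameHigh),
         call. = FALSE)
  invisible(NULL)
}

# Centered moving average with shrinking (partial) windows at the edges, so
# the output has the input's length and no NA padding.
movingAverage <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1L) return(x)
  half <- window %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Bilinear interpolation of matrix m at fractional (row, col) positions
# (1-based). Positions must lie within [1, nrow] x [1, ncol].
bilinearAt <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  if (any(r < 1 - 1e-9 | r > nr + 1e-9 | c < 1 - 1e-9 | c > nc + 1e-9))
    stop("sampling position outside the image", call. = FALSE)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}
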