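#' Unpaired two-sample t-test (pooled variance)
#'
#' Two-tailed Student's t-test with pooled variance, the comparison used for
#' two-group contrasts (e.g. control vs DRP1K38E amplitudes). Welch's
#' unequal-variance form is available behind a flag.
#'
#' @param groupA,groupB numeric vectors, each with at least 2 values.
#' @param welch use Welch's t instead of the pooled form.
#' @return A \code{\linkS4class{TestResult}} with \code{df = nA + nB - 2} for
#'   the pooled form.
#' @examples
#' ttestUnpaired(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
#' @export
ttestUnpaired <- function(groupA, groupB, welch = FALSE) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  if (!welch && stats::var(c(groupA - mean(groupA),
                             groupB - mean(groupB))) == 0)
    stop("degenerate data: pooled variance is zero", call. = FALSE)
  ht <- stats::t.test(groupA, groupB, var.equal = !welch)
  TestResult(if (welch) "Welch t" else "Student t (pooled)",
             unname(ht$statistic), unname(ht$parameter), ht$p.value)
}

#' One-way analysis of variance
#'
#' @param groups a list of numeric vectors (>= 2 groups, each n >= 2).
#' @return A \code{\linkS4class{TestResult}} with F, df = (k - 1, N - k).
#' @examples
#' anovaOneway(list(c(1, 2), c(3, 4), c(5, 6)))
#' @export
anovaOneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2L))
    stop("each group needs at least 2 values", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  if (stats::var(values) == 0)
    stop("degenerate data: all values identical", call. = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  ow <- stats::oneway.test(values ~ g, var.equal = TRUE)
  TestResult("one-way ANOVA", unname(ow$statistic),
             unname(ow$parameter), ow$p.value)
}

#' Two-sided Fisher's exact test on a 2 x 2 table
#'
#' Exact two-sided p-value by the probability-mass rule: the sum, over all
#' tables with the observed margins, of hypergeometric probabilities no
#' larger than the observed table's (ties at relative tolerance 1e-7). This
#' is the test used for contact-frequency comparisons (contact yes/no by
#' group, one mitochondrion per observation).
#'
#' @param table 2 x 2 matrix of non-negative counts.
#' @return A \code{\linkS4class{TestResult}}; the statistic slot carries the
#'   conditional odds-ratio estimate, \code{df} is empty.
#' @examples
#' fisherExact(matrix(c(2, 47, 48, 3), 2))   # 4% vs 94% contact, n = 50
#' @export
fisherExact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("input error: a 2 x 2 table is required", call. = FALSE)
  if (any(is.na(table)) || any(table < 0))
    stop("input error: counts must be non-negative", call. = FALSE)
  if (sum(table) < 1)
    stop("input error: the table must contain at least one count",
         call. = FALSE)
  ht <- stats::fisher.test(round(table))
  TestResult("Fisher exact (two-sided)",
             unname(ht$estimate), numeric(0), ht$p.value)
}

#' Group summaries and the matching comparison test
#'
#' Computes mean +/- SE per group and dispatches the study's comparison
#' rules: numeric metrics get a pooled t-test for 2 groups or a one-way ANOVA
#' for 3 or more; boolean metrics (fused, contact) get pairwise two-sided
#' Fisher's exact tests on the per-observation 2 x 2 tables. Censored values
#' are excluded from numeric summaries, with the exclusion count reported per
#' group. No multiple-testing correction is applied; p-values are raw.
#'
#' @param values numeric or logical metric values, one per observation.
#' @param groups group labels, same length.
#' @param censored optional logical vector; censored observations are
#'   excluded (numeric metrics only).
#' @param metricName label used in the output.
#' @return list with \code{metric}, \code{groups} (data.frame: label, n,
#'   mean, se, n_censored_excluded) and \code{tests} (named list of
#'   \code{\linkS4class{TestResult}}).
#' @examples
#' summarizeGroups(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
#' @export
summarizeGroups <- function(values, groups, censored = NULL,
                            metricName = "metric") {
  stopifnot(length(values) == length(groups))
  if (is.null(censored)) censored <- rep(FALSE, length(values))
  stopifnot(length(censored) == length(values))
  censored[is.na(censored)] <- FALSE
  groups <- as.character(groups)
  labs <- unique(groups)
  isBool <- is.logical(values)

  keep <- !censored & !is.na(values)
  summ <- do.call(rbind, lapply(labs, function(l) {
    v <- values[groups == l & keep]
    data.frame(label = l, n = length(v), mean = mean(as.numeric(v)),
               se = if (length(v) > 1L)
                 stats::sd(as.numeric(v)) / sqrt(length(v)) else 0,
               n_censored_excluded = sum(censored[groups == l]))
  }))

  tests <- list()
  if (isBool) {
    if (length(labs) >= 2L) {
      pairs <- utils::combn(labs, 2L, simplify = FALSE)
      for (p in pairs) {
        a <- values[groups == p[1L] & keep]
        b <- values[groups == p[2L] & keep]
        tab <- matrix(c(sum(a), sum(!a), sum(b), sum(!b)), 2L)
        tests[[paste(p, collapse = " vs ")]] <- fisherExact(tab)
      }
    }
  } else if (length(labs) == 2L) {
    tests[[paste(labs, collapse = " vs ")]] <-
      ttestUnpaired(values[groups == labs[1L] & keep],
                    values[groups == labs[2L] & keep])
  } else if (length(labs) >= 3L) {
    tests[["omnibus"]] <-
      anovaOneway(lapply(labs, function(l) values[groups == l & keep]))
  }
  list(metric = metricName, groups = summ, tests = tests)
}
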