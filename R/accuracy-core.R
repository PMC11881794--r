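# Point estimation, Wilson-score intervals and the intersection-union test
# for the co-primary sensitivity/specificity endpoints of a single-test
# diagnostic accuracy study.

#' Construct a 2x2 diagnostic agreement table
#'
#' The atom of every analysis in the package: counts of index-test results
#' cross-classified against the reference standard.
#'
#' @param tp,fp,tn,fn Non-negative integer counts of true positives, false
#'   positives, true negatives and false negatives.
#'
#' @return An object of class `counts_2x2`, a list with elements `tp`, `fp`,
#'   `tn`, `fn` plus the derived margins `cases` (`tp + fn`) and `controls`
#'   (`tn + fp`).
#' @examples
#' counts_2x2(tp = 90, fp = 20, tn = 80, fn = 10)
#' @export
counts_2x2 <- function(tp, fp, tn, fn) {
  x <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (length(x) != 4L || anyNA(x)) {
    stop("tp, fp, tn, fn must each be a single non-missing number", call. = FALSE)
  }
  if (any(x < 0) || any(x != trunc(x))) {
    stop("all counts must be non-negative integers", call. = FALSE)
  }
  structure(
    list(tp = as.integer(tp), fp = as.integer(fp),
         tn = as.integer(tn), fn = as.integer(fn),
         cases = as.integer(tp + fn), controls = as.integer(tn + fp)),
    class = "counts_2x2"
  )
}

#' @export
print.counts_2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2,
              dimnames = list(`index test` = c("positive", "negative"),
                              `reference`  = c("condition", "no condition")))
  cat("2x2 diagnostic agreement table\n")
  print(m)
  cat(sprintf("cases: %d, controls: %d\n", x$cases, x$controls))
  invisible(x)
}

#' Maximum-likelihood estimates of sensitivity and specificity
#'
#' @param counts A [counts_2x2()] object.
#' @return A list with elements `se_hat` (`tp / (tp + fn)`) and `sp_hat`
#'   (`tn / (tn + fp)`).
#' @examples
#' estimate_accuracy(counts_2x2(90, 20, 80, 10))
#' @export
estimate_accuracy <- function(counts) {
  stopifnot(inherits(counts, "counts_2x2"))
  if (counts$cases == 0L) {
    stop("sensitivity is undefined: the table contains no cases (tp + fn = 0)",
         call. = FALSE)
  }
  if (counts$controls == 0L) {
    stop("specificity is undefined: the table contains no controls (tn + fp = 0)",
         call. = FALSE)
  }
  list(se_hat = counts$tp / counts$cases,
       sp_hat = counts$tn / counts$controls)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Closed-form two-sided Wilson score interval, without continuity
#' correction. Vectorized over `x` and `n`.
#'
#' @param x Number of successes, `0 <= x <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param level Two-sided confidence level in (0, 1); default 0.95.
#'
#' @return A data frame with columns `lower`, `upper` and `level`.
#' @examples
#' wilson_ci(90, 100)            # approx (0.826, 0.945)
#' wilson_ci(0, 10)$lower        # collapses to 0 at zero successes
#' @export
wilson_ci <- function(x, n, level = 0.95) {
  if (any(n < 1)) stop("interval undefined for n = 0", call. = FALSE)
  stopifnot(all(x >= 0), all(x <= n), level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- n + z^2
  centre <- (x + z^2 / 2) / denom
  half <- (z / denom) * sqrt(x * (n - x) / n + z^2 / 4)
  data.frame(lower = pmax(0, centre - half),
             upper = pmin(1, centre + half),
             level = level)
}

#' Intersection-union test for co-primary sensitivity and specificity
#'
#' Confirms a single index test against predefined minimum values
#' `(se0, sp0)`. Each endpoint is tested by comparing the lower limit of its
#' two-sided Wilson interval with the minimum value; the global null
#' hypothesis `se <= se0 OR sp <= sp0` is rejected only if both endpoint
#' nulls are rejected. The comparison is strict: a lower limit exactly equal
#' to the minimum value does not reject.
#'
#' @param counts A [counts_2x2()] object with at least one case and one
#'   control.
#' @param se0,sp0 Minimum acceptable sensitivity and specificity, in (0, 1).
#' @param level Two-sided confidence level of the per-endpoint intervals;
#'   0.95 gives one-sided 2.5% endpoint tests and a nominal global level of
#'   `0.025^2` (see [nominal_global_level()]).
#'
#' @return A list of class `iu_test` with the point estimates, both Wilson
#'   intervals, and logical flags `reject_se`, `reject_sp`, `reject_global`.
#' @examples
#' iu_test(counts_2x2(tp = 95, fp = 8, tn = 92, fn = 5), se0 = 0.8, sp0 = 0.8)
#' @export
iu_test <- function(counts, se0, sp0, level = 0.95) {
  stopifnot(se0 > 0, se0 < 1, sp0 > 0, sp0 < 1)
  est <- estimate_accuracy(counts)
  ci_se <- wilson_ci(counts$tp, counts$cases, level)
  ci_sp <- wilson_ci(counts$tn, counts$controls, level)
  reject_se <- ci_se$lower > se0
  reject_sp <- ci_sp$lower > sp0
  structure(
    list(se_hat = est$se_hat, sp_hat = est$sp_hat,
         ci_se = ci_se, ci_sp = ci_sp, se0 = se0, sp0 = sp0, level = level,
         reject_se = reject_se, reject_sp = reject_sp,
         reject_global = reject_se && reject_sp),
    class = "iu_test"
  )
}

#' @export
print.iu_test <- function(x, ...) {
  cat("Intersection-union test for co-primary sensitivity/specificity\n")
  cat(sprintf("  sensitivity: %.4f, %2.0f%% CI [%.4f, %.4f] vs se0 = %.3f -> %s\n",
              x$se_hat, 100 * x$level, x$ci_se$lower, x$ci_se$upper, x$se0,
              if (x$reject_se) "reject" else "fail to reject"))
  cat(sprintf("  specificity: %.4f, %2.0f%% CI [%.4f, %.4f] vs sp0 = %.3f -> %s\n",
              x$sp_hat, 100 * x$level, x$ci_sp$lower, x$ci_sp$upper, x$sp0,
              if (x$reject_sp) "reject" else "fail to reject"))
  cat(sprintf("  global null hypothesis: %s\n",
              if (x$reject_global) "rejected" else "not rejected"))
  invisible(x)
}

#' Nominal level of the global intersection-union test
#'
#' When the sensitivity and specificity tests are stochastically independent
#' and each is performed one-sided at level `alpha`, the global
#' intersection-union test has nominal level `alpha^2` (0.025 per endpoint
#' gives 0.000625).
#'
#' @param alpha_one_sided One-sided per-endpoint significance level in
#'   \[0, 1).
#' @return `alpha_one_sided^2`.
#' @export
nominal_global_level <- function(alpha_one_sided) {
  stopifnot(alpha_one_sided >= 0, alpha_one_sided < 1)
  alpha_one_sided^2
}

#' Standard error of a binomial proportion
#'
#' `sqrt(p (1 - p) / n)`; used in the back-of-envelope sample-size
#' illustration where 100 cases estimate a sensitivity of 0.9 with a
#' standard error of 0.03.
#'
#' @param p_true True proportion in \[0, 1\].
#' @param n Number of trials, `n >= 1`.
#' @return The standard error.
#' @export
se_of_proportion <- function(p_true, n) {
  stopifnot(all(n >= 1), all(p_true >= 0), all(p_true <= 1))
  sqrt(p_true * (1 - p_true) / n)
}
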