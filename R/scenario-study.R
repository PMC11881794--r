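# Factorial scenario grid and Monte Carlo operating characteristics:
# stopping probability, conditional relative bias, conditional and
# unconditional coverage, power over a grid of minimum-value hypotheses,
# and type I error.

#' Hypothetical minimum values used for the power grid
#'
#' All 25 combinations of these five values for (se0, sp0) are evaluated
#' when computing power; type I error is the entry where the hypothetical
#' values equal the true values.
#' @export
hypothesis_values <- function() c(0.55, 0.65, 0.75, 0.85, 0.95)

#' Build the full factorial scenario grid
#'
#' The simulation study crosses seven design choices: final sample size N
#' in \{333, 500, 1000\} (chosen so the final analysis holds about 100 or
#' 50 cases), stopping time s in \{0.1, 0.2, 0.3\}, prevalence in
#' \{0.1, 0.2, 0.3\}, true sensitivity and specificity each in
#' \{0.65, 0.75, 0.85, 0.95\}, the distance `delta` between the futility
#' boundaries and the true values in \{-0.3, -0.25, ..., 0.1\} (the same
#' distance for both endpoints, so `f_se = se_true + delta` and
#' `f_sp = sp_true + delta`), and the added-case sensitivity increase
#' `delta_add` in \{0, 0.1\}. The cross-product holds 7776 scenarios.
#'
#' Rows are in deterministic order: the columns appear in the order above
#' and earlier columns vary fastest.
#'
#' @return A data frame with one scenario per row and columns `final_n`,
#'   `s`, `prevalence`, `se_true`, `sp_true`, `delta`, `delta_add`,
#'   `f_se`, `f_sp`.
#' @export
build_grid <- function() {
  g <- expand.grid(
    final_n = c(333L, 500L, 1000L),
    s = c(0.1, 0.2, 0.3),
    prevalence = c(0.1, 0.2, 0.3),
    se_true = c(0.65, 0.75, 0.85, 0.95),
    sp_true = c(0.65, 0.75, 0.85, 0.95),
    delta = seq(-0.3, 0.1, by = 0.05),
    delta_add = c(0, 0.1),
    KEEP.OUT.ATTRS = FALSE
  )
  g$f_se <- g$se_true + g$delta
  g$f_sp <- g$sp_true + g$delta
  g
}

scenario_design <- function(scn, f_se = scn$f_se, f_sp = scn$f_sp) {
  seamless_design(final_n = scn$final_n, stopping_time = scn$s,
                  prevalence = scn$prevalence, f_se = f_se, f_sp = f_sp,
                  se0 = 0.9, sp0 = 0.9, margin_mode = "fixed")
}

#' Relative frequency of stopping for futility
#'
#' @param outcomes A data frame of simulated trials from [run_trials()].
#' @return Proportion of runs stopped at the interim analysis.
#' @export
stopping_probability <- function(outcomes) mean(outcomes$stopped)

#' Conditional relative bias of the final estimates
#'
#' Mean difference between the final estimate and the true value over the
#' runs that were not stopped, divided by one minus the true value and
#' multiplied by 100. Scaling by `1 - true` reflects that the same absolute
#' bias is more harmful the closer the true value is to 1.
#'
#' @param outcomes A data frame from [run_trials()].
#' @param truth The [trial_truth()] the runs were simulated under.
#' @return A list with percentage biases `se` and `sp`; both `NA` if every
#'   run stopped.
#' @export
conditional_relative_bias <- function(outcomes, truth) {
  kept <- outcomes[!outcomes$stopped, , drop = FALSE]
  if (nrow(kept) == 0L) return(list(se = NA_real_, sp = NA_real_))
  rel <- function(est, true) {
    if (true >= 1) return(NA_real_)
    100 * mean(est - true) / (1 - true)
  }
  list(se = rel(kept$se_hat, truth$se_true),
       sp = rel(kept$sp_hat, truth$sp_true))
}

#' Coverage probability of the final confidence intervals
#'
#' Conditional coverage divides the number of covering intervals by the
#' number of non-stopped runs. Unconditional coverage divides by all runs,
#' with each stopped run counted as covering by convention, so the identity
#' `uncond = stop_freq + (1 - stop_freq) * cond` holds exactly.
#'
#' @inheritParams conditional_relative_bias
#' @param conditional Logical; if `TRUE` (default) condition on reaching the
#'   final analysis.
#' @return A list with coverage proportions `se` and `sp`.
#' @export
coverage <- function(outcomes, truth, conditional = TRUE) {
  cov_se <- outcomes$ci_se_lower <= truth$se_true &
    truth$se_true <= outcomes$ci_se_upper
  cov_sp <- outcomes$ci_sp_lower <= truth$sp_true &
    truth$sp_true <= outcomes$ci_sp_upper
  if (conditional) {
    n_final <- sum(!outcomes$stopped)
    if (n_final == 0L) return(list(se = NA_real_, sp = NA_real_))
    list(se = sum(cov_se[!outcomes$stopped]) / n_final,
         sp = sum(cov_sp[!outcomes$stopped]) / n_final)
  } else {
    n <- nrow(outcomes)
    list(se = (sum(cov_se[!outcomes$stopped]) + sum(outcomes$stopped)) / n,
         sp = (sum(cov_sp[!outcomes$stopped]) + sum(outcomes$stopped)) / n)
  }
}

#' Power over a grid of minimum-value hypotheses
#'
#' For each hypothetical pair (se0, sp0), the proportion of all runs in
#' which the global intersection-union null was rejected in the final
#' analysis; stopped runs count as not rejecting.
#'
#' @param outcomes A data frame from [run_trials()].
#' @param values Hypothetical minimum values; all pairwise combinations are
#'   evaluated (default [hypothesis_values()], 25 pairs).
#' @return A data frame with columns `se0`, `sp0`, `power`.
#' @export
power_grid <- function(outcomes, values = hypothesis_values()) {
  pairs <- expand.grid(se0 = values, sp0 = values, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(outcomes)
  keep <- !outcomes$stopped
  lo_se <- outcomes$ci_se_lower[keep]
  lo_sp <- outcomes$ci_sp_lower[keep]
  pairs$power <- vapply(seq_len(nrow(pairs)), function(i) {
    sum(lo_se > pairs$se0[i] & lo_sp > pairs$sp0[i]) / n
  }, numeric(1))
  pairs
}

#' Empirical type I error of the global test
#'
#' The power-grid entry at the hypothetical pair equal to the true values;
#' only defined when both true values lie on the hypothesis grid.
#'
#' @inheritParams conditional_relative_bias
#' @param values Hypothetical minimum values (default [hypothesis_values()]).
#' @return The empirical rejection rate under the null, or `NA` if the true
#'   values are off-grid.
#' @export
type1_error <- function(outcomes, truth, values = hypothesis_values()) {
  on_grid <- function(v) any(abs(v - values) < 1e-9)
  if (!on_grid(truth$se_true) || !on_grid(truth$sp_true)) return(NA_real_)
  n <- nrow(outcomes)
  keep <- !outcomes$stopped
  sum(outcomes$ci_se_lower[keep] > truth$se_true &
        outcomes$ci_sp_lower[keep] > truth$sp_true) / n
}

#' Operating characteristics of one scenario
#'
#' Simulates `reps` independent seamless trials under the scenario's design
#' and truth and computes every performance measure: stopping frequency,
#' conditional relative bias, conditional and unconditional coverage, the
#' 25-pair power grid and the type I error.
#'
#' @param scn A one-row data frame (or list) with fields `final_n`, `s`,
#'   `prevalence`, `se_true`, `sp_true`, `delta`, `delta_add` (as produced
#'   by [build_grid()]); `f_se`/`f_sp` are derived if absent.
#' @param reps Number of simulated trials.
#' @param seed Seed for this scenario's random stream.
#' @param power Compute the 25-pair power grid and type I error (default
#'   `TRUE`; skipping it speeds up sweeps that only need stopping/bias/
#'   coverage measures).
#' @return A one-row data frame: the scenario fields, `reps`, `seed`,
#'   `stop_freq`, `n_final`, `cond_rel_bias_se/sp`, `cond_cov_se/sp`,
#'   `uncond_cov_se/sp`, and with `power = TRUE` the `type1` column plus one
#'   `power_se<..>_sp<..>` column per hypothesis pair.
#' @export
run_scenario <- function(scn, reps, seed = NULL, power = TRUE) {
  scn <- as.list(scn)
  if (is.null(scn$f_se)) scn$f_se <- scn$se_true + scn$delta
  if (is.null(scn$f_sp)) scn$f_sp <- scn$sp_true + scn$delta
  spec <- scenario_design(scn)
  truth <- trial_truth(scn$se_true, scn$sp_true, scn$delta_add)
  if (!is.null(seed)) set.seed(seed)
  outcomes <- run_trials(spec, truth, reps)

  bias <- conditional_relative_bias(outcomes, truth)
  ccov <- coverage(outcomes, truth, conditional = TRUE)
  ucov <- coverage(outcomes, truth, conditional = FALSE)
  res <- data.frame(
    final_n = scn$final_n, s = scn$s, prevalence = scn$prevalence,
    se_true = scn$se_true, sp_true = scn$sp_true,
    delta = scn$delta, delta_add = scn$delta_add,
    f_se = scn$f_se, f_sp = scn$f_sp,
    reps = reps, seed = if (is.null(seed)) NA_integer_ else seed,
    stop_freq = stopping_probability(outcomes),
    n_final = sum(!outcomes$stopped),
    cond_rel_bias_se = bias$se, cond_rel_bias_sp = bias$sp,
    cond_cov_se = ccov$se, cond_cov_sp = ccov$sp,
    uncond_cov_se = ucov$se, uncond_cov_sp = ucov$sp
  )
  if (power) {
    res$type1 <- type1_error(outcomes, truth)
    pw <- power_grid(outcomes)
    pcols <- as.list(pw$power)
    names(pcols) <- sprintf("power_se%.2f_sp%.2f", pw$se0, pw$sp0)
    res <- cbind(res, as.data.frame(pcols, check.names = FALSE))
  }
  res
}

#' Run a sweep over many scenarios
#'
#' Each scenario receives its own pre-assigned seed drawn once from the
#' master seed, so results do not depend on the order in which scenarios
#' are run and re-running with the same master seed reproduces every
#' summary exactly.
#'
#' @param scenarios A data frame of scenarios ([build_grid()] or a filtered
#'   subset).
#' @param reps Simulated trials per scenario.
#' @param seed Master seed.
#' @param power Forwarded to [run_scenario()].
#' @param progress Print a progress line every `progress` scenarios
#'   (0 disables, the default).
#' @return A data frame with one [run_scenario()] row per scenario.
#' @export
run_grid <- function(scenarios, reps, seed = 1L, power = FALSE, progress = 0L) {
  n <- nrow(scenarios)
  stopifnot(n >= 1)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- run_scenario(scenarios[i, , drop = FALSE], reps,
                              seed = seeds[i], power = power)
    if (progress > 0L && i %% progress == 0L) {
      message(sprintf("scenario %d / %d", i, n))
    }
  }
  do.call(rbind, rows)
}

#' Power of the population-based cohort comparator
#'
#' The same trial engine with futility stopping disabled (boundaries at
#' -Inf), i.e. a plain population-based cohort study with the same final
#' sample size. Run under the same seed as the seamless scenario, every
#' underlying count is shared, so the comparison isolates the effect of the
#' stopping rule: seamless power can never exceed the comparator's.
#'
#' @inheritParams run_scenario
#' @return A `power_grid()` data frame with columns `se0`, `sp0`, `power`.
#' @export
cohort_only_power <- function(scn, reps, seed = NULL) {
  scn <- as.list(scn)
  spec <- scenario_design(scn, f_se = -Inf, f_sp = -Inf)
  truth <- trial_truth(scn$se_true, scn$sp_true,
                       if (is.null(scn$delta_add)) 0 else scn$delta_add)
  if (!is.null(seed)) set.seed(seed)
  power_grid(run_trials(spec, truth, reps))
}

#' Grouped percentile summaries across designs
#'
#' Applies the reporting filter used for conditional measures — designs
#' whose number of completed final analyses falls below `min_final_runs`
#' (interpreted at 40000 replicates and scaled proportionally to the actual
#' replicate count) are omitted — then computes percentiles of a measure
#' within groups. For the relative-bias and coverage summaries the
#' sensitivity and specificity values of each design are pooled.
#'
#' @param results A data frame of [run_scenario()] rows.
#' @param group_by Column name(s) of `results` to group by (e.g. `"s"` or
#'   `"delta"`); `NULL` summarizes everything together.
#' @param measure One of `"cond_rel_bias"`, `"cond_cov"`, `"uncond_cov"`
#'   (pooled over the two endpoints) or `"stop_freq"`.
#' @param probs Percentile levels (default 0.9). Quantiles use linear
#'   interpolation between order statistics (type 7).
#' @param min_final_runs Minimum completed final analyses per design at
#'   40000 replicates: 40 for bias summaries, 200 for conditional coverage.
#' @return A data frame with the grouping columns, `prob`, `value` and
#'   `n_designs` (designs surviving the filter).
#' @export
summarize_across_designs <- function(results, group_by = NULL,
                                     measure = c("cond_rel_bias", "cond_cov",
                                                 "uncond_cov", "stop_freq"),
                                     probs = 0.9, min_final_runs = 40) {
  measure <- match.arg(measure)
  stopifnot(nrow(results) > 0)
  cols <- switch(measure,
                 cond_rel_bias = c("cond_rel_bias_se", "cond_rel_bias_sp"),
                 cond_cov = c("cond_cov_se", "cond_cov_sp"),
                 uncond_cov = c("uncond_cov_se", "uncond_cov_sp"),
                 stop_freq = "stop_freq")
  if (measure %in% c("cond_rel_bias", "cond_cov")) {
    need <- ceiling(min_final_runs * results$reps / 40000)
    results <- results[results$n_final >= need, , drop = FALSE]
  }
  key <- if (is.null(group_by)) rep("all", nrow(results)) else {
    interaction(results[group_by], drop = TRUE, lex.order = TRUE)
  }
  groups <- split(results, key)
  out <- lapply(names(groups), function(g) {
    grp <- groups[[g]]
    pooled <- unlist(grp[cols], use.names = FALSE)
    pooled <- pooled[!is.na(pooled)]
    q <- if (length(pooled)) stats::quantile(pooled, probs, type = 7, names = FALSE)
         else rep(NA_real_, length(probs))
    cbind(
      if (is.null(group_by)) data.frame(group = rep(g, length(probs)))
      else grp[rep(1L, length(probs)), group_by, drop = FALSE],
      data.frame(prob = probs, value = q, n_designs = nrow(grp),
                 row.names = NULL)
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
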