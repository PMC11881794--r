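# Single-trial engine: stage-I recruitment with case enrichment, interim
# futility decision, stage-II continuation with reuse of the stage-I
# population subjects, removal of the added cases, and the final analysis.

#' True accuracy parameters of a simulated trial
#'
#' @param se_true,sp_true True sensitivity and specificity of the index
#'   test in the target population, in \[0, 1\].
#' @param delta_add Additive shift of the sensitivity among the externally
#'   added cases (enriched cases may be easier to detect). The added-case
#'   sensitivity is `min(se_true + delta_add, 1)`.
#' @return An object of class `trial_truth`.
#' @export
trial_truth <- function(se_true, sp_true, delta_add = 0) {
  stopifnot(se_true >= 0, se_true <= 1, sp_true >= 0, sp_true <= 1)
  structure(list(se_true = se_true, sp_true = sp_true,
                 delta_add = delta_add,
                 se_added = min(max(se_true + delta_add, 0), 1)),
            class = "trial_truth")
}

#' Interim futility decision
#'
#' The study proceeds to stage II only if both interim point estimates are
#' strictly above their futility boundaries; an estimate exactly equal to
#' its boundary stops the study. Vectorized.
#'
#' @param se_hat,sp_hat Interim point estimates of sensitivity and
#'   specificity.
#' @param f_se,f_sp Futility boundaries.
#' @return Logical: `TRUE` if the trial stops for futility. Undefined
#'   estimates (`NaN`, possible only when a margin of the interim analysis
#'   population is empty) stop the trial.
#' @examples
#' interim_decision(0.73, 0.81, f_se = 0.80, f_sp = 0.75)  # TRUE: stop
#' interim_decision(0.89, 0.76, f_se = 0.80, f_sp = 0.75)  # FALSE: continue
#' @export
interim_decision <- function(se_hat, sp_hat, f_se, f_sp) {
  keep <- se_hat > f_se & sp_hat > f_sp
  keep[is.na(keep)] <- FALSE
  !keep
}

#' Simulate the stage-I (interim) data of a seamless trial
#'
#' Draws index-test results for the stage-I population stream and the added
#' cases. With `margin_mode = "fixed"` the case/control margins are the
#' deterministic planned composition from [interim_composition()]; with
#' `"binomial"` the number of population cases is drawn binomially from the
#' prevalence and the added-case requirement is recomputed from the
#' realized split. Positives among population cases are
#' `Binomial(., se_true)`, among added cases
#' `Binomial(., min(se_true + delta_add, 1))`, and negatives among controls
#' `Binomial(., sp_true)`.
#'
#' @param spec A [seamless_design()].
#' @param truth A [trial_truth()].
#' @param reps Number of independent stage-I replicates to draw.
#' @return A data frame with one row per replicate and columns `pop_cases`,
#'   `added_cases`, `controls`, `tp_pop`, `tp_add`, `tn`, `interim_se`,
#'   `interim_sp`.
#' @export
simulate_stage1 <- function(spec, truth, reps = 1L) {
  stopifnot(inherits(spec, "seamless_design"), inherits(truth, "trial_truth"),
            reps >= 1)
  n1 <- round_half_up(spec$stopping_time * spec$final_n)
  if (spec$margin_mode == "fixed") {
    comp <- interim_composition(spec$prevalence, spec$final_n, spec$stopping_time)
    pop_cases <- rep.int(comp$pop_cases, reps)
    controls <- rep.int(comp$controls, reps)
    added <- rep.int(comp$added_cases, reps)
  } else {
    pop_cases <- stats::rbinom(reps, n1, spec$prevalence)
    controls <- n1 - pop_cases
    added <- pmax(controls - pop_cases, 0L)
  }
  tp_pop <- stats::rbinom(reps, pop_cases, truth$se_true)
  tp_add <- stats::rbinom(reps, added, truth$se_added)
  tn <- stats::rbinom(reps, controls, truth$sp_true)
  pool <- pop_cases + added
  data.frame(pop_cases = pop_cases, added_cases = added, controls = controls,
             tp_pop = tp_pop, tp_add = tp_add, tn = tn,
             interim_se = (tp_pop + tp_add) / pool,
             interim_sp = tn / controls)
}

#' Simulate many seamless trials at once
#'
#' Vectorized engine behind [run_trial()] and the scenario sweep. Stage-I
#' randomness is drawn before stage-II randomness in a fixed order, so two
#' calls under the same seed but different futility boundaries share every
#' underlying count; paired comparisons (seamless vs cohort-only) exploit
#' this. Stage II adds the remaining population subjects; the stage-I
#' population case/control results are carried into the final counts
#' unchanged and the added-case results are discarded.
#'
#' @inheritParams simulate_stage1
#' @return A data frame with one row per replicate: the stage-I columns of
#'   [simulate_stage1()], the stop flag `stopped`, and for continued runs
#'   the final margins (`cases`, `controls_final`), final counts (`tp`,
#'   `fn`, `tn_final`, `fp`), estimates (`se_hat`, `sp_hat`) and Wilson
#'   limits (`ci_se_lower`, `ci_se_upper`, `ci_sp_lower`, `ci_sp_upper`);
#'   final columns are `NA` for stopped runs.
#' @export
run_trials <- function(spec, truth, reps = 1L) {
  s1 <- simulate_stage1(spec, truth, reps)
  n1 <- round_half_up(spec$stopping_time * spec$final_n)
  n2 <- spec$final_n - n1

  if (spec$margin_mode == "fixed") {
    cases_final <- rep.int(round_half_up(spec$prevalence * spec$final_n), reps)
    cases2 <- cases_final - s1$pop_cases
    if (any(cases2 < 0)) {
      warning("stage-II case target below the realized stage-I case count; ",
              "truncating at 0", call. = FALSE)
      cases2 <- pmax(cases2, 0L)
    }
    controls2 <- spec$final_n - cases_final - s1$controls
  } else {
    cases2 <- stats::rbinom(reps, n2, spec$prevalence)
    controls2 <- n2 - cases2
    cases_final <- s1$pop_cases + cases2
  }
  controls_final <- s1$controls + controls2

  # stage-II outcomes are drawn for every replicate (stopped ones included)
  # so that the draw sequence is identical across boundary choices
  tp2 <- stats::rbinom(reps, cases2, truth$se_true)
  tn2 <- stats::rbinom(reps, controls2, truth$sp_true)

  stopped <- interim_decision(s1$interim_se, s1$interim_sp, spec$f_se, spec$f_sp)

  tp <- s1$tp_pop + tp2
  tn_final <- s1$tn + tn2
  se_hat <- tp / cases_final
  sp_hat <- tn_final / controls_final
  ci_se <- wilson_ci(tp, cases_final, spec$ci_level)
  ci_sp <- wilson_ci(tn_final, controls_final, spec$ci_level)

  out <- data.frame(
    s1, stopped = stopped,
    cases = cases_final, controls_final = controls_final,
    tp = tp, fn = cases_final - tp,
    tn_final = tn_final, fp = controls_final - tn_final,
    se_hat = se_hat, sp_hat = sp_hat,
    ci_se_lower = ci_se$lower, ci_se_upper = ci_se$upper,
    ci_sp_lower = ci_sp$lower, ci_sp_upper = ci_sp$upper
  )
  final_cols <- c("cases", "controls_final", "tp", "fn", "tn_final", "fp",
                  "se_hat", "sp_hat", "ci_se_lower", "ci_se_upper",
                  "ci_sp_lower", "ci_sp_upper")
  out[out$stopped, final_cols] <- NA
  out
}

#' Simulate and analyze a single seamless trial
#'
#' @inheritParams simulate_stage1
#' @return An object of class `trial_outcome`: the interim estimates and
#'   stop flag; if continued, the final [counts_2x2()] (added cases
#'   removed, stage-I population subjects reused) and the confirmatory
#'   [iu_test()] against the design's minimum values.
#' @export
run_trial <- function(spec, truth) {
  row <- run_trials(spec, truth, reps = 1L)
  out <- list(stopped = row$stopped,
              interim_se_hat = row$interim_se, interim_sp_hat = row$interim_sp,
              spec = spec)
  if (!row$stopped) {
    counts <- counts_2x2(tp = row$tp, fp = row$fp, tn = row$tn_final, fn = row$fn)
    out$final_counts <- counts
    out$final_test <- iu_test(counts, spec$se0, spec$sp0, spec$ci_level)
  }
  structure(out, class = "trial_outcome")
}

#' @export
print.trial_outcome <- function(x, ...) {
  cat(sprintf("Interim: se = %.4f, sp = %.4f vs boundaries (%s, %s) -> %s\n",
              x$interim_se_hat, x$interim_sp_hat,
              format(x$spec$f_se), format(x$spec$f_sp),
              if (x$stopped) "stop for futility" else "continue"))
  if (!x$stopped) print(x$final_test)
  invisible(x)
}

#' Exact probability of stopping for futility at the interim analysis
#'
#' Enumeration oracle for fixed case/control margins: the interim
#' true-positive count is the convolution of independent binomials over the
#' population and added cases, the true-negative count a single binomial
#' over the controls, and every outcome is passed through
#' [interim_decision()]. Used to verify the Monte Carlo engine.
#'
#' @inheritParams simulate_stage1
#' @param max_pool Largest case pool or control margin enumerated.
#' @return The exact stopping probability.
#' @export
exact_stopping_probability <- function(spec, truth, max_pool = 10000L) {
  stopifnot(inherits(spec, "seamless_design"), inherits(truth, "trial_truth"))
  if (spec$margin_mode != "fixed") {
    stop("the enumeration oracle requires margin_mode = \"fixed\"", call. = FALSE)
  }
  comp <- interim_composition(spec$prevalence, spec$final_n, spec$stopping_time)
  pool <- comp$pop_cases + comp$added_cases
  if (pool > max_pool || comp$controls > max_pool) {
    stop("interim margins exceed the enumeration cap (", max_pool, ")",
         call. = FALSE)
  }
  # pmf of TP = TP_pop + TP_added (independent binomials, convolved)
  d_pop <- stats::dbinom(0:comp$pop_cases, comp$pop_cases, truth$se_true)
  d_add <- stats::dbinom(0:comp$added_cases, comp$added_cases, truth$se_added)
  pmf_tp <- rep(0, pool + 1L)
  for (k in 0:comp$pop_cases) {
    idx <- k + 0:comp$added_cases + 1L
    pmf_tp[idx] <- pmf_tp[idx] + d_pop[k + 1L] * d_add
  }
  # strict "above" comparisons, on the same estimate scale the engine uses
  p_se_above <- sum(pmf_tp[(0:pool) / pool > spec$f_se])
  k_tn <- 0:comp$controls
  p_sp_above <- sum(stats::dbinom(k_tn, comp$controls, truth$sp_true)[
    k_tn / comp$controls > spec$f_sp])
  1 - p_se_above * p_sp_above
}

#' Analyze observed interim data of a real seamless trial
#'
#' @param counts A [counts_2x2()] of the interim analysis population
#'   (population cases plus added cases vs controls).
#' @param spec The trial's [seamless_design()].
#' @param observed_pop_cases,observed_pop_controls Optional realized
#'   case/control split of the stage-I population stream; when given, the
#'   realized added-case requirement [observed_added_cases()] is reported.
#' @return A list of class `interim_report` with the point estimates, the
#'   boundaries, the stop/continue verdict and (if computable) the realized
#'   added-case requirement.
#' @examples
#' des <- seamless_design(500, 0.2, 0.2, f_se = 0.80, f_sp = 0.75,
#'                        se0 = 0.90, sp0 = 0.85)
#' analyze_interim(counts_2x2(tp = 80, fp = 22, tn = 68, fn = 10), des,
#'                 observed_pop_cases = 10, observed_pop_controls = 90)
#' @export
analyze_interim <- function(counts, spec,
                            observed_pop_cases = NULL,
                            observed_pop_controls = NULL) {
  stopifnot(inherits(spec, "seamless_design"))
  est <- estimate_accuracy(counts)
  stopped <- interim_decision(est$se_hat, est$sp_hat, spec$f_se, spec$f_sp)
  rep <- list(se_hat = est$se_hat, sp_hat = est$sp_hat,
              f_se = spec$f_se, f_sp = spec$f_sp,
              stopped = stopped,
              verdict = if (stopped) "stop" else "continue")
  if (!is.null(observed_pop_cases) && !is.null(observed_pop_controls)) {
    rep$added_cases_required <-
      observed_added_cases(observed_pop_cases, observed_pop_controls)
  }
  structure(rep, class = "interim_report")
}

#' @export
print.interim_report <- function(x, ...) {
  cat("Interim analysis\n")
  cat(sprintf("  se = %.4f vs f_se = %s; sp = %.4f vs f_sp = %s\n",
              x$se_hat, format(x$f_se), x$sp_hat, format(x$f_sp)))
  if (!is.null(x$added_cases_required)) {
    cat(sprintf("  realized added-case requirement: %d\n", x$added_cases_required))
  }
  cat(sprintf("  verdict: %s%s\n", x$verdict,
              if (x$stopped) " for futility" else " to stage II"))
  invisible(x)
}

#' Confirmatory final analysis of a seamless trial
#'
#' Applies the Wilson-interval intersection-union test to the final
#' population-based counts (added cases already removed).
#'
#' @param counts The final-analysis [counts_2x2()].
#' @param spec The trial's [seamless_design()].
#' @return The [iu_test()] result.
#' @export
analyze_final <- function(counts, spec) {
  stopifnot(inherits(spec, "seamless_design"))
  iu_test(counts, spec$se0, spec$sp0, spec$ci_level)
}
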