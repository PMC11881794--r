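# Design specification and interim analysis-population composition
# arithmetic for the seamless diagnostic accuracy design.

round_half_up <- function(x) floor(x + 0.5)

#' Specify a seamless diagnostic accuracy design
#'
#' Bundles every planning parameter of the two-stage design: the intended
#' final-analysis sample size, the stopping time (the fraction of that
#' sample size recruited before the interim analysis), the expected
#' prevalence of the target condition, futility boundaries for the interim
#' point estimates, the minimum acceptable sensitivity and specificity for
#' the confirmatory final analysis, and the confidence level.
#'
#' @param final_n Intended sample size N of the population-based final
#'   analysis.
#' @param stopping_time Fraction s in (0, 1) of `final_n` recruited before
#'   the interim analysis; values between 0.1 and 0.3 are typical.
#' @param prevalence Expected prevalence p of the target condition, in
#'   (0, 1); the design as implemented enriches cases, which presumes
#'   p < 0.5.
#' @param f_se,f_sp Futility boundaries for the interim sensitivity and
#'   specificity point estimates. The study continues only if both interim
#'   estimates are strictly above their boundary. Boundaries are normally
#'   chosen in \[0, 1), slightly below the minimum acceptable values;
#'   values outside that range are accepted (a boundary of `-Inf` disables
#'   stopping, a boundary >= 1 forces it) so that comparator designs and
#'   full scenario grids can be expressed.
#' @param se0,sp0 Minimum acceptable sensitivity and specificity tested in
#'   the final analysis, in (0, 1).
#' @param ci_level Two-sided confidence level of the Wilson intervals
#'   (default 0.95).
#' @param margin_mode `"fixed"` (default) treats the case/control margins at
#'   both analyses as deterministic, per [interim_composition()];
#'   `"binomial"` draws the number of population cases binomially from the
#'   prevalence at each stage and recomputes the added-case requirement from
#'   the realized stage-I counts.
#'
#' @return An object of class `seamless_design`.
#' @examples
#' seamless_design(final_n = 500, stopping_time = 0.2, prevalence = 0.2,
#'                 f_se = 0.80, f_sp = 0.75, se0 = 0.90, sp0 = 0.85)
#' @export
seamless_design <- function(final_n, stopping_time, prevalence,
                            f_se, f_sp, se0 = 0.9, sp0 = 0.9,
                            ci_level = 0.95,
                            margin_mode = c("fixed", "binomial")) {
  margin_mode <- match.arg(margin_mode)
  if (!is.numeric(final_n) || length(final_n) != 1L || final_n < 2 ||
      final_n != trunc(final_n)) {
    stop("final_n must be a single integer >= 2", call. = FALSE)
  }
  if (!is.numeric(stopping_time) || stopping_time <= 0 || stopping_time >= 1) {
    stop("stopping_time must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie strictly between 0 and 1", call. = FALSE)
  }
  stopifnot(is.numeric(f_se), is.numeric(f_sp),
            se0 > 0, se0 < 1, sp0 > 0, sp0 < 1,
            ci_level > 0, ci_level < 1)
  structure(
    list(final_n = as.integer(final_n), stopping_time = stopping_time,
         prevalence = prevalence, f_se = f_se, f_sp = f_sp,
         se0 = se0, sp0 = sp0, ci_level = ci_level,
         margin_mode = margin_mode),
    class = "seamless_design"
  )
}

#' @export
print.seamless_design <- function(x, ...) {
  cat("Seamless diagnostic accuracy design\n")
  cat(sprintf("  final analysis N = %d, stopping time s = %.2f, prevalence p = %.2f\n",
              x$final_n, x$stopping_time, x$prevalence))
  cat(sprintf("  futility boundaries: f_se = %s, f_sp = %s (continue only if both estimates strictly above)\n",
              format(x$f_se), format(x$f_sp)))
  cat(sprintf("  minimum values: se0 = %.3f, sp0 = %.3f at %2.0f%% two-sided Wilson CIs\n",
              x$se0, x$sp0, 100 * x$ci_level))
  cat(sprintf("  margin mode: %s\n", x$margin_mode))
  comp <- interim_composition(x$prevalence, x$final_n, x$stopping_time)
  cat(sprintf("  planned interim composition: %d population cases + %d added cases vs %d controls (stage-I n = %d)\n",
              comp$pop_cases, comp$added_cases, comp$controls, comp$n1))
  invisible(x)
}

new_interim_composition <- function(n1, pop_cases, added_cases, controls) {
  structure(
    list(n1 = as.integer(n1), pop_cases = as.integer(pop_cases),
         added_cases = as.integer(added_cases), controls = as.integer(controls)),
    class = "interim_composition"
  )
}

#' @export
print.interim_composition <- function(x, ...) {
  cat(sprintf("Interim analysis population (stage-I n = %d):\n", x$n1))
  cat(sprintf("  cases:    %d from population sampling + %d added = %d\n",
              x$pop_cases, x$added_cases, x$pop_cases + x$added_cases))
  cat(sprintf("  controls: %d\n", x$controls))
  invisible(x)
}

#' Composition of the interim analysis population
#'
#' At stopping time s, `n1 = round(s * N)` population participants have been
#' recruited, of whom `round(p * n1)` are expected to be cases. Enough
#' external cases are then added to balance cases and controls 1:1 in the
#' interim analysis. Rounding is half-up, applied first to `n1` and then to
#' the expected case count; controls and added cases follow by subtraction,
#' which keeps the balance `pop_cases + added_cases = controls` exact.
#'
#' @param prevalence Expected prevalence p, with p < 0.5 (cases are
#'   enriched; a prevalence above 0.5 would require adding controls
#'   instead, which this function does not do).
#' @param final_n Intended final-analysis sample size N.
#' @param s Stopping time as a fraction in (0, 1).
#'
#' @return An `interim_composition` object with fields `n1`, `pop_cases`,
#'   `added_cases`, `controls`.
#' @examples
#' interim_composition(0.2, 500, 0.2)   # 20 population cases + 60 added vs 80
#' @export
interim_composition <- function(prevalence, final_n, s) {
  stopifnot(prevalence > 0, s > 0, s < 1, final_n >= 1)
  if (prevalence >= 0.5) {
    stop("case enrichment requires prevalence < 0.5; ",
         "a design with prevalence >= 0.5 must add controls instead",
         call. = FALSE)
  }
  n1 <- round_half_up(s * final_n)
  pop_cases <- round_half_up(prevalence * n1)
  controls <- n1 - pop_cases
  added <- controls - pop_cases
  new_interim_composition(n1, pop_cases, added, controls)
}

#' Interim composition for a fixed interim analysis population
#'
#' Alternative parameterization in which the total interim analysis
#' population (population participants plus added cases) is fixed, split
#' 1:1 between cases and controls. The population stream is recruited until
#' it yields `interim_total / 2` controls; the added-case requirement is the
#' control target minus the expected population cases in that stream,
#' rounded half-up. With prevalence 0.1 and a 100-participant interim
#' population this gives 44 added cases.
#'
#' @param prevalence Expected prevalence p < 0.5.
#' @param interim_total Total interim analysis population (cases +
#'   controls); an even number >= 2.
#'
#' @return An `interim_composition` object.
#' @examples
#' composition_for_target_interim_total(0.1, 100)  # 44 added cases
#' @export
composition_for_target_interim_total <- function(prevalence, interim_total) {
  stopifnot(prevalence > 0, interim_total >= 2,
            interim_total == trunc(interim_total))
  if (prevalence > 0.5) {
    stop("case enrichment requires prevalence <= 0.5", call. = FALSE)
  }
  if (interim_total %% 2 != 0) {
    stop("interim_total must be even for a 1:1 case:control split", call. = FALSE)
  }
  controls <- interim_total / 2
  # expected added cases = controls - p * (controls / (1 - p)); rounding this
  # quantity (rather than the stage-I size first) keeps cases = controls exact
  added <- round_half_up(controls * (1 - 2 * prevalence) / (1 - prevalence))
  pop_cases <- controls - added
  new_interim_composition(pop_cases + controls, pop_cases, added, controls)
}

#' Realized added-case requirement at the interim analysis
#'
#' Recomputed from the case/control split actually observed in the stage-I
#' recruitment rather than from the planned prevalence: the number of
#' external cases needed to balance the interim analysis is simply
#' `observed_controls - observed_cases`.
#'
#' @param observed_cases,observed_controls Non-negative integer counts from
#'   the stage-I population stream, with at least as many controls as cases.
#' @return The number of cases to add.
#' @examples
#' observed_added_cases(10, 90)  # 80
#' @export
observed_added_cases <- function(observed_cases, observed_controls) {
  stopifnot(observed_cases >= 0, observed_controls >= 0,
            observed_cases == trunc(observed_cases),
            observed_controls == trunc(observed_controls))
  if (observed_controls < observed_cases) {
    stop("observed cases exceed controls: balancing would require adding ",
         "controls, not cases", call. = FALSE)
  }
  as.integer(observed_controls - observed_cases)
}

#' Check a seamless design for questionable planning choices
#'
#' Returns (and by default signals) warnings for choices that are legal but
#' at odds with the usual planning guidance: futility boundaries at or above
#' the minimum acceptable values, a stopping time outside the typical
#' \[0.1, 0.3\] range, or a planned added-case requirement exceeding a
#' declared enrichment pool.
#'
#' @param spec A [seamless_design()].
#' @param enrichment_pool Optional size of the available external case pool.
#' @param warn Emit each message as an R warning (default `TRUE`).
#' @return Invisibly, a character vector of warning messages (empty if the
#'   design raises none).
#' @export
validate_design <- function(spec, enrichment_pool = NULL, warn = TRUE) {
  stopifnot(inherits(spec, "seamless_design"))
  msgs <- character(0)
  if (spec$f_se >= spec$se0) {
    msgs <- c(msgs, sprintf(
      "futility boundary f_se = %s is not below the minimum sensitivity se0 = %s; boundaries are normally chosen slightly below the minimally acceptable values",
      format(spec$f_se), format(spec$se0)))
  }
  if (spec$f_sp >= spec$sp0) {
    msgs <- c(msgs, sprintf(
      "futility boundary f_sp = %s is not below the minimum specificity sp0 = %s; boundaries are normally chosen slightly below the minimally acceptable values",
      format(spec$f_sp), format(spec$sp0)))
  }
  if (spec$stopping_time < 0.1 || spec$stopping_time > 0.3) {
    msgs <- c(msgs, sprintf(
      "stopping time s = %s lies outside the typical range [0.1, 0.3]",
      format(spec$stopping_time)))
  }
  if (!is.null(enrichment_pool) && spec$prevalence < 0.5) {
    comp <- interim_composition(spec$prevalence, spec$final_n, spec$stopping_time)
    if (comp$added_cases > enrichment_pool) {
      msgs <- c(msgs, sprintf(
        "planned added-case requirement (%d) exceeds the declared enrichment pool (%d); the interim analysis would proceed unbalanced",
        comp$added_cases, as.integer(enrichment_pool)))
    }
  }
  if (warn) for (m in msgs) warning(m, call. = FALSE)
  invisible(msgs)
}
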