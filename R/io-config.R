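# Configuration files, results serialization and reproducible fixtures.

#' Load a run configuration
#'
#' Reads a YAML (or JSON) configuration describing a design, optionally a
#' simulation truth, and run settings, applying defaults
#' (`ci_level = 0.95`, `margin_mode = "fixed"`, `delta_add = 0`,
#' `reps = 2000`, `seed = 1`). The design block is validated through
#' [seamless_design()], so schema violations name the offending field.
#'
#' @param path Path to the configuration file.
#' @return A list of class `run_config` with elements `design`
#'   (a `seamless_design`), `truth` (a `trial_truth` or `NULL`), `reps`,
#'   `seed`, `out` and `min_final_runs`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$design)) stop("config must contain a 'design' block", call. = FALSE)
  d <- raw$design
  required <- c("final_n", "stopping_time", "prevalence", "f_se", "f_sp")
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop("design block is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  design <- seamless_design(
    final_n = d$final_n, stopping_time = d$stopping_time,
    prevalence = d$prevalence, f_se = d$f_se, f_sp = d$f_sp,
    se0 = d$se0 %||% 0.9, sp0 = d$sp0 %||% 0.9,
    ci_level = d$ci_level %||% 0.95,
    margin_mode = d$margin_mode %||% "fixed"
  )
  truth <- NULL
  if (!is.null(raw$truth)) {
    t <- raw$truth
    if (is.null(t$se_true) || is.null(t$sp_true)) {
      stop("truth block requires fields se_true and sp_true", call. = FALSE)
    }
    truth <- trial_truth(t$se_true, t$sp_true, t$delta_add %||% 0)
  }
  structure(
    list(design = design, truth = truth,
         reps = as.integer(raw$reps %||% 2000L),
         seed = as.integer(raw$seed %||% 1L),
         out = raw$out %||% NULL,
         min_final_runs = raw$min_final_runs %||% 40),
    class = "run_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a run configuration
#'
#' Inverse of [load_config()]; `load_config(save_config(cfg, path))`
#' reproduces `cfg`.
#'
#' @param config A `run_config` list.
#' @param path Destination YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  d <- config$design
  out <- list(design = list(
    final_n = d$final_n, stopping_time = d$stopping_time,
    prevalence = d$prevalence, f_se = d$f_se, f_sp = d$f_sp,
    se0 = d$se0, sp0 = d$sp0, ci_level = d$ci_level,
    margin_mode = d$margin_mode
  ))
  if (!is.null(config$truth)) {
    out$truth <- list(se_true = config$truth$se_true,
                      sp_true = config$truth$sp_true,
                      delta_add = config$truth$delta_add)
  }
  out$reps <- config$reps
  out$seed <- config$seed
  if (!is.null(config$out)) out$out <- config$out
  out$min_final_runs <- config$min_final_runs
  yaml::write_yaml(out, path)
  invisible(path)
}

results_fingerprint <- function(df) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  utils::write.csv(df, tmp, row.names = FALSE)
  unname(tools::md5sum(tmp))
}

#' Write scenario results with a metadata sidecar
#'
#' Writes one CSV row per scenario (RFC 4180, header row, missing
#' conditional measures as empty cells) and a JSON sidecar
#' (`<path>.meta.json`) recording the seed, replicate count, package
#' version, tie rule, margin mode and a content fingerprint of the table.
#'
#' @param summaries A nonempty data frame of [run_scenario()] rows.
#' @param path Destination CSV path.
#' @param seed,reps Run metadata; taken from the table's columns when
#'   omitted.
#' @return `path`, invisibly.
#' @export
write_results <- function(summaries, path, seed = NULL, reps = NULL) {
  if (!is.data.frame(summaries) || nrow(summaries) == 0L) {
    stop("summaries must be a nonempty data frame", call. = FALSE)
  }
  utils::write.csv(summaries, path, row.names = FALSE, na = "")
  meta <- list(
    seed = seed %||% (if ("seed" %in% names(summaries)) summaries$seed[1] else NA),
    reps = reps %||% (if ("reps" %in% names(summaries)) summaries$reps[1] else NA),
    n_scenarios = nrow(summaries),
    version = as.character(utils::packageVersion("seamlessDx")),
    tie_rule = "continue only if both interim estimates strictly above the boundaries",
    bias_pooling = "percentile summaries pool sensitivity and specificity values",
    margin_mode = "fixed",
    fingerprint = results_fingerprint(summaries)
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a scenario results CSV
#'
#' @param path CSV written by [write_results()].
#' @return A data frame; empty cells become `NA`.
#' @export
read_results <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Deterministic fixture trial sets
#'
#' Small, fully reproducible datasets used by the test suite and the
#' examples. Both presets are synthetic reconstructions.
#'
#' * `"sec2_6_study"`: a design with minimum values se0 = 0.90,
#'   sp0 = 0.85, futility boundaries f_se = 0.80, f_sp = 0.75, prevalence
#'   0.2, N = 500, stopping time 0.2 (planned added-case requirement 60),
#'   together with two hypothetical courses: one stopped at the interim
#'   (interim estimates about 0.73 / 0.81) and one continued after a
#'   realized stage-I prevalence of 10% (80 added cases; interim about
#'   0.89 / 0.76; final estimates exactly 0.82 / 0.77). The interim counts
#'   are the integer tables closest to the illustrative two-decimal
#'   estimates.
#' * `"figure1"`: the fixed-interim-total variant with prevalence 0.1 and a
#'   100-participant interim population (44 added cases), plus a small set
#'   of simulated trials under that design.
#'
#' @param preset_name `"sec2_6_study"` or `"figure1"`.
#' @param seed Seed for the simulated component; the same seed always
#'   yields identical output.
#' @return A list describing the preset (design, compositions, counts,
#'   simulated trials where applicable).
#' @export
make_fixture_trials <- function(preset_name = c("sec2_6_study", "figure1"),
                                seed = 1L) {
  preset_name <- match.arg(preset_name)
  if (preset_name == "sec2_6_study") {
    design <- seamless_design(final_n = 500, stopping_time = 0.2,
                              prevalence = 0.2, f_se = 0.80, f_sp = 0.75,
                              se0 = 0.90, sp0 = 0.85)
    planned <- interim_composition(0.2, 500, 0.2)
    study1 <- list(
      # realized prevalence as planned: 20 + 60 added cases vs 80 controls
      pop_cases = 20L, pop_controls = 80L,
      interim_counts = counts_2x2(tp = 58, fp = 15, tn = 65, fn = 22)
    )
    study2 <- list(
      # realized stage-I prevalence 10%: 10 + 80 added cases vs 90 controls
      pop_cases = 10L, pop_controls = 90L,
      interim_counts = counts_2x2(tp = 80, fp = 22, tn = 68, fn = 10),
      final_counts = counts_2x2(tp = 82, fp = 92, tn = 308, fn = 18)
    )
    set.seed(seed)
    truth <- trial_truth(se_true = 0.85, sp_true = 0.80)
    trials <- run_trials(design, truth, reps = 25L)
    list(preset = preset_name, design = design, planned = planned,
         study1 = study1, study2 = study2, truth = truth, trials = trials)
  } else {
    design <- seamless_design(final_n = 500, stopping_time = 0.2,
                              prevalence = 0.1, f_se = 0.80, f_sp = 0.75,
                              se0 = 0.90, sp0 = 0.85)
    comp <- composition_for_target_interim_total(0.1, 100)
    set.seed(seed)
    truth <- trial_truth(se_true = 0.90, sp_true = 0.85)
    trials <- run_trials(design, truth, reps = 25L)
    list(preset = preset_name, design = design, interim = comp,
         truth = truth, trials = trials)
  }
}
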