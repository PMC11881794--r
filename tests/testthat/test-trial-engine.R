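# Single-trial engine: interim decision, stage simulation, data reuse,
# enumeration oracle, and analysis of observed counts.

test_that("interim decision continues only if both estimates strictly above", {
  expect_true(interim_decision(0.73, 0.81, f_se = 0.80, f_sp = 0.75))
  expect_false(interim_decision(0.89, 0.76, f_se = 0.80, f_sp = 0.75))
  # equality fails the strict 'above' requirement
  expect_true(interim_decision(0.80, 0.90, f_se = 0.80, f_sp = 0.75))
  # undefined estimates stop conservatively
  expect_true(interim_decision(NaN, 0.9, 0.5, 0.5))
})

test_that("stage-I margins follow the planned composition under fixed mode", {
  spec <- demo_design()
  s1 <- simulate_stage1(spec, trial_truth(0.85, 0.85), reps = 5)
  expect_true(all(s1$pop_cases == 20))
  expect_true(all(s1$added_cases == 60))
  expect_true(all(s1$controls == 80))
})

test_that("degenerate truth gives perfect interim estimates and clamping works", {
  spec <- demo_design()
  s1 <- simulate_stage1(spec, trial_truth(1, 1), reps = 10)
  expect_true(all(s1$interim_se == 1))
  expect_true(all(s1$interim_sp == 1))

  # added-case sensitivity clamps at 1: every added case tests positive
  tru <- trial_truth(0.95, 0.85, delta_add = 0.1)
  expect_equal(tru$se_added, 1)
  s1 <- simulate_stage1(spec, tru, reps = 50)
  expect_true(all(s1$tp_add == s1$added_cases))
})

test_that("binomial margins rebalance from the realized stage-I split", {
  spec <- demo_design(margin_mode = "binomial")
  set.seed(5)
  s1 <- simulate_stage1(spec, trial_truth(0.85, 0.85), reps = 500)
  n1 <- s1$pop_cases + s1$controls
  expect_true(all(n1 == 100))
  expect_true(var(s1$pop_cases) > 0)
  expect_true(all(s1$added_cases == pmax(s1$controls - s1$pop_cases, 0)))
})

test_that("final analysis reuses stage-I population data and drops added cases", {
  spec <- demo_design(f_se = -Inf, f_sp = -Inf)
  set.seed(9)
  out <- run_trials(spec, trial_truth(0.85, 0.80), reps = 200)
  expect_true(all(!out$stopped))
  # final margins: round(p N) cases, remainder controls; no added cases
  expect_true(all(out$cases == 100))
  expect_true(all(out$controls_final == 400))
  # stage-I population results carried over unchanged
  expect_true(all(out$tp >= out$tp_pop))
  expect_true(all(out$tp - out$tp_pop <= out$cases - out$pop_cases))
  expect_true(all(out$tn_final >= out$tn))
  expect_true(all(out$tp + out$fn == out$cases))
  expect_true(all(out$tn_final + out$fp == out$controls_final))
})

test_that("without stopping, estimates are unbiased and coverage matches enumeration", {
  spec <- demo_design(f_se = -Inf, f_sp = -Inf)
  tru <- trial_truth(0.85, 0.80)
  reps <- 20000
  set.seed(21)
  out <- run_trials(spec, tru, reps = reps)
  bias <- conditional_relative_bias(out, tru)
  expect_lt(abs(bias$se), 1)
  expect_lt(abs(bias$sp), 1)
  # coverage of the final intervals equals the exact enumerated Wilson
  # coverage at the final margins (100 cases, 400 controls) within MC error
  cov <- coverage(out, tru, conditional = TRUE)
  exp_se <- exact_wilson_coverage(100, tru$se_true)
  exp_sp <- exact_wilson_coverage(400, tru$sp_true)
  expect_lt(abs(cov$se - exp_se), 3 * sqrt(exp_se * (1 - exp_se) / reps))
  expect_lt(abs(cov$sp - exp_sp), 3 * sqrt(exp_sp * (1 - exp_sp) / reps))
})

test_that("stopped runs carry no final results", {
  spec <- demo_design(f_se = 1.01, f_sp = 1.01)  # estimates can never exceed 1
  set.seed(3)
  out <- run_trials(spec, trial_truth(0.9, 0.9), reps = 20)
  expect_true(all(out$stopped))
  expect_true(all(is.na(out$se_hat)))
  expect_true(all(is.na(out$ci_sp_lower)))
  single <- run_trial(spec, trial_truth(0.9, 0.9))
  expect_true(single$stopped)
  expect_null(single$final_counts)
})

test_that("enumeration oracle: degenerate boundaries", {
  spec_never <- demo_design(f_se = -Inf, f_sp = -Inf)
  spec_always <- demo_design(f_se = 1.01, f_sp = 1.01)
  tru <- trial_truth(0.85, 0.85)
  expect_equal(exact_stopping_probability(spec_never, tru), 0)
  expect_equal(exact_stopping_probability(spec_always, tru), 1)
  # boundaries at zero: stopping requires a zero estimate, which has
  # vanishing probability at these margins
  expect_equal(exact_stopping_probability(demo_design(0, 0), tru), 0,
               tolerance = 1e-12)
  expect_error(
    exact_stopping_probability(demo_design(margin_mode = "binomial"), tru),
    "fixed")
  expect_error(exact_stopping_probability(demo_design(), tru, max_pool = 10),
               "enumeration cap")
})

test_that("Monte Carlo stopping frequency matches the enumeration oracle", {
  reps <- 10000
  cases <- list(
    list(spec = demo_design(0.85, 0.85), tru = trial_truth(0.85, 0.85)),
    list(spec = demo_design(0.80, 0.75), tru = trial_truth(0.85, 0.80)),
    list(spec = demo_design(0.80, 0.75), tru = trial_truth(0.90, 0.80, 0.1))
  )
  set.seed(31)
  for (cs in cases) {
    p_exact <- exact_stopping_probability(cs$spec, cs$tru)
    freq <- mean(run_trials(cs$spec, cs$tru, reps)$stopped)
    band <- mc_stop_band(p_exact, reps)
    expect_gte(freq, band[1])
    expect_lte(freq, band[2])
  }
})

test_that("continuing selects upward: conditional estimates exceed unconditional", {
  spec <- demo_design(0.85, 0.85)
  tru <- trial_truth(0.85, 0.85)
  set.seed(13)
  out <- run_trials(spec, tru, reps = 20000)
  kept <- out[!out$stopped, ]
  expect_gt(mean(kept$se_hat), tru$se_true)
  expect_gt(mean(kept$sp_hat), tru$sp_true)
})

test_that("observed interim analyses reproduce the two hypothetical studies", {
  fix <- make_fixture_trials("sec2_6_study")
  expect_equal(fix$planned$added_cases, 60L)

  rep1 <- analyze_interim(fix$study1$interim_counts, fix$design,
                          observed_pop_cases = fix$study1$pop_cases,
                          observed_pop_controls = fix$study1$pop_controls)
  expect_equal(rep1$verdict, "stop")   # sensitivity below its boundary
  expect_lt(rep1$se_hat, fix$design$f_se)
  expect_gt(rep1$sp_hat, fix$design$f_sp)
  expect_equal(rep1$added_cases_required, 60L)

  rep2 <- analyze_interim(fix$study2$interim_counts, fix$design,
                          observed_pop_cases = fix$study2$pop_cases,
                          observed_pop_controls = fix$study2$pop_controls)
  expect_equal(rep2$verdict, "continue")
  expect_equal(rep2$added_cases_required, 80L)

  # balanced perfect counts always continue
  perfect <- analyze_interim(counts_2x2(80, 0, 80, 0), fix$design)
  expect_equal(perfect$verdict, "continue")
})

test_that("final confirmatory analysis applies the intersection-union rule", {
  fix <- make_fixture_trials("sec2_6_study")
  res <- analyze_final(fix$study2$final_counts, fix$design)
  expect_equal(res$se_hat, 0.82)
  expect_equal(res$sp_hat, 0.77)
  expect_false(res$reject_global)  # estimates below the minimum values

  strong <- analyze_final(
    counts_2x2(tp = 1000, fp = 0, tn = 1000, fn = 0),
    seamless_design(2000, 0.2, 0.2, 0.4, 0.4, se0 = 0.5, sp0 = 0.5))
  expect_true(strong$reject_global)

  near_one <- analyze_final(
    counts_2x2(tp = 1000, fp = 0, tn = 1000, fn = 0),
    seamless_design(2000, 0.2, 0.2, 0.4, 0.4, se0 = 0.999, sp0 = 0.999))
  expect_false(near_one$reject_global)
})
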