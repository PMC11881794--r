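# Scenario grid and operating-characteristic measures.

test_that("the factorial grid has the documented shape and order", {
  g <- build_grid()
  expect_equal(nrow(g), 7776)
  expect_equal(nrow(g[abs(g$delta) < 1e-9 & abs(g$s - 0.1) < 1e-9, ]), 288)
  expect_equal(nrow(unique(g)), 7776)
  expect_identical(g, build_grid())  # deterministic ordering
  expect_equal(g$f_se, g$se_true + g$delta)
  expect_equal(g$f_sp, g$sp_true + g$delta)
})

test_that("per-scenario measures are internally consistent", {
  scn <- list(final_n = 500L, s = 0.2, prevalence = 0.2,
              se_true = 0.85, sp_true = 0.85, delta = 0, delta_add = 0)
  res <- run_scenario(scn, reps = 4000, seed = 17, power = TRUE)
  expect_equal(res$n_final, round((1 - res$stop_freq) * 4000))
  # unconditional coverage identity, exact by construction
  expect_equal(res$uncond_cov_se,
               res$stop_freq + (1 - res$stop_freq) * res$cond_cov_se)
  expect_equal(res$uncond_cov_sp,
               res$stop_freq + (1 - res$stop_freq) * res$cond_cov_sp)
  # type I error is the power entry at the true values
  expect_equal(res$type1, res$power_se0.85_sp0.85)
  # reproducibility under the same seed
  res2 <- run_scenario(scn, reps = 4000, seed = 17, power = TRUE)
  expect_identical(res, res2)
})

test_that("stopped runs count as non-covering-exempt and non-rejecting", {
  scn <- list(final_n = 500L, s = 0.2, prevalence = 0.2,
              se_true = 0.85, sp_true = 0.85, delta = 0.2, delta_add = 0)
  # boundaries 0.05 above 1 are unreachable: every run stops
  scn$f_se <- 1.05; scn$f_sp <- 1.05
  res <- run_scenario(scn, reps = 500, seed = 2, power = TRUE)
  expect_equal(res$stop_freq, 1)
  expect_equal(res$uncond_cov_se, 1)  # stopped runs count as covering
  expect_true(is.na(res$cond_cov_se))
  pw <- res[grep("^power_", names(res))]
  expect_true(all(unlist(pw) == 0))   # stopped runs never reject
  expect_equal(res$type1, 0)
})

test_that("power decreases in the hypothesized minimum values", {
  spec <- demo_design(f_se = -Inf, f_sp = -Inf)
  set.seed(4)
  out <- run_trials(spec, trial_truth(0.9, 0.9), reps = 3000)
  pw <- power_grid(out)
  for (sp0 in hypothesis_values()) {
    col <- pw$power[pw$sp0 == sp0][order(pw$se0[pw$sp0 == sp0])]
    expect_true(all(diff(col) <= 0))
  }
})

test_that("type I error is only defined on the hypothesis grid", {
  spec <- demo_design(f_se = -Inf, f_sp = -Inf)
  set.seed(6)
  out <- run_trials(spec, trial_truth(0.85, 0.85), reps = 500)
  expect_false(is.na(type1_error(out, trial_truth(0.85, 0.85))))
  expect_true(is.na(type1_error(out, trial_truth(0.66, 0.85))))
})

test_that("seamless power never exceeds cohort-only power under shared seeds", {
  scn <- list(final_n = 500L, s = 0.2, prevalence = 0.2,
              se_true = 0.85, sp_true = 0.85, delta = 0, delta_add = 0)
  seam <- run_scenario(scn, reps = 3000, seed = 23, power = TRUE)
  coh <- cohort_only_power(scn, reps = 3000, seed = 23)
  seam_pw <- unlist(seam[sprintf("power_se%.2f_sp%.2f", coh$se0, coh$sp0)])
  expect_true(all(coh$power - seam_pw >= 0))
  expect_gt(sum(coh$power), sum(seam_pw))  # stopping removes some rejections
})

test_that("disabled boundaries make the seamless and cohort designs identical", {
  scn <- list(final_n = 500L, s = 0.2, prevalence = 0.2,
              se_true = 0.85, sp_true = 0.85, delta = NA, delta_add = 0,
              f_se = -Inf, f_sp = -Inf)
  seam <- run_scenario(scn, reps = 1000, seed = 8, power = TRUE)
  coh <- cohort_only_power(scn, reps = 1000, seed = 8)
  expect_equal(unname(unlist(seam[sprintf("power_se%.2f_sp%.2f",
                                          coh$se0, coh$sp0)])),
               coh$power)
  expect_equal(seam$stop_freq, 0)
})

test_that("stopping frequency is monotone in the boundary distance", {
  base <- list(final_n = 500L, s = 0.2, prevalence = 0.2,
               se_true = 0.85, sp_true = 0.85, delta_add = 0)
  p_stop <- vapply(seq(-0.3, 0.1, by = 0.05), function(d) {
    spec <- seamless_design(500, 0.2, 0.2, f_se = 0.85 + d, f_sp = 0.85 + d,
                            se0 = 0.9, sp0 = 0.9)
    exact_stopping_probability(spec, trial_truth(0.85, 0.85))
  }, numeric(1))
  expect_true(all(diff(p_stop) >= 0))
})

test_that("grouped summaries pool endpoints and apply the reporting filter", {
  one <- run_scenario(list(final_n = 500L, s = 0.1, prevalence = 0.2,
                           se_true = 0.85, sp_true = 0.85, delta = 0,
                           delta_add = 0), reps = 2000, seed = 5)
  summ <- summarize_across_designs(one, NULL, "cond_rel_bias", 0.5, 40)
  expect_equal(summ$value,
               median(c(one$cond_rel_bias_se, one$cond_rel_bias_sp)))
  expect_equal(summ$n_designs, 1L)

  # a design with (almost) certain stopping is filtered out of conditional
  # summaries: min_final_runs scales with the replicate count
  sure_stop <- one
  sure_stop$n_final <- 1L
  both <- rbind(one, sure_stop)
  summ2 <- summarize_across_designs(both, NULL, "cond_rel_bias", 0.9, 40)
  expect_equal(summ2$n_designs, 1L)

  # stop_freq summaries are not filtered
  summ3 <- summarize_across_designs(both, NULL, "stop_freq", 0.9, 40)
  expect_equal(summ3$n_designs, 2L)
})

test_that("sweeps are reproducible and order-independent via per-scenario seeds", {
  g <- build_grid()
  sub <- g[abs(g$delta) < 1e-9 & g$delta_add == 0 & g$final_n == 500 &
             abs(g$prevalence - 0.2) < 1e-9 & abs(g$s - 0.2) < 1e-9, ]
  r1 <- run_grid(sub, reps = 500, seed = 99)
  r2 <- run_grid(sub, reps = 500, seed = 99)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 16)  # 4 x 4 accuracy combinations
})
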