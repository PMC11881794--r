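# Shared fixtures: the published planning table for the interim analysis
# population and convenience constructors.

# prevalence, final N, stopping time -> population cases, added cases, controls
table1_compositions <- function() {
  read.table(header = TRUE, text = "
    prevalence final_n s   pop_cases added controls
    0.1        1000    0.1 10        80    90
    0.1        1000    0.2 20        160   180
    0.1        1000    0.3 30        240   270
    0.1        500     0.1 5         40    45
    0.1        500     0.2 10        80    90
    0.1        500     0.3 15        120   135
    0.2        500     0.1 10        30    40
    0.2        500     0.2 20        60    80
    0.2        500     0.3 30        90    120
    0.2        250     0.1 5         15    20
    0.2        250     0.2 10        30    40
    0.2        250     0.3 15        45    60
    0.3        333     0.1 10        13    23
    0.3        333     0.2 20        27    47
    0.3        333     0.3 30        40    70
    0.3        167     0.1 5         7     12
    0.3        167     0.2 10        13    23
    0.3        167     0.3 15        20    35
  ")
}

demo_design <- function(f_se = 0.80, f_sp = 0.75, margin_mode = "fixed") {
  seamless_design(final_n = 500, stopping_time = 0.2, prevalence = 0.2,
                  f_se = f_se, f_sp = f_sp, se0 = 0.90, sp0 = 0.85,
                  margin_mode = margin_mode)
}

# an exact Monte-Carlo band: the central ~99.7% (3-sigma analogue) range of
# the binomial count of stopped runs under the oracle probability;
# computed on the complement scale when p is near 1, where qbinom is
# numerically unreliable
mc_stop_band <- function(p_exact, reps) {
  if (p_exact > 0.5) {
    (reps - stats::qbinom(c(0.99865, 0.00135), reps, 1 - p_exact)) / reps
  } else {
    stats::qbinom(c(0.00135, 0.99865), reps, p_exact) / reps
  }
}

# exact coverage of the two-sided Wilson interval at sample size n and true
# proportion p, by enumeration over all possible counts
exact_wilson_coverage <- function(n, p, level = 0.95) {
  ci <- wilson_ci(0:n, n, level)
  sum(stats::dbinom(0:n, n, p)[ci$lower <= p & p <= ci$upper])
}
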