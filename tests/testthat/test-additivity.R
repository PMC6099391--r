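test_that("two-group ANOVA equals the squared pooled t-test", {
  set.seed(101)
  for (k in 1:50) {
    s <- rnorm(sample(3:8, 1), mean = runif(1, 0.1, 0.4), sd = 0.02)
    n <- rnorm(sample(3:8, 1), mean = 0.1, sd = 0.012)
    got <- anova_s_vs_n(s, n)
    tt <- t.test(s, n, var.equal = TRUE)
    expect_equal(got$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(got$p_value, tt$p.value, tolerance = 1e-12)
  }
})

test_that("ANOVA handles degenerate inputs by convention", {
  x <- c(0.1, 0.1, 0.1)
  expect_equal(anova_s_vs_n(x, x)$p_value, 1)
  expect_equal(anova_s_vs_n(x, c(0.2, 0.2))$p_value, 0)
  expect_error(anova_s_vs_n(0.1, c(0.1, 0.2)), "at least 2")
  # identical lists with internal variance: difference is exactly zero
  y <- c(0.1, 0.12, 0.11)
  expect_equal(anova_s_vs_n(y, y)$p_value, 1)
})

test_that("the Welch option changes only the denominator model", {
  set.seed(7)
  s <- rnorm(5, 0.2, 0.05)
  n <- rnorm(5, 0.1, 0.005)
  pooled <- anova_s_vs_n(s, n)
  welch <- anova_s_vs_n(s, n, welch = TRUE)
  expect_equal(welch$p_value,
               t.test(s, n, var.equal = FALSE)$p.value, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(pooled$p_value, welch$p_value)))
})

test_that("the additivity decision rule applies threshold then test", {
  set.seed(13)
  n_reps <- rnorm(5, 0.10, 0.01)
  # high mean S: confirmed directly, whatever the p-value
  d1 <- decide_additivity(rnorm(5, 0.21, 0.02), n_reps)
  expect_equal(d1$verdict, "confirmed_direct")
  # below threshold with a significant test
  s2 <- c(0.148, 0.149, 0.147, 0.1485, 0.1475)
  d2 <- decide_additivity(s2, n_reps)
  expect_true(d2$p_value < 0.01)
  expect_equal(d2$verdict, "confirmed_by_test")
  # S at the noise level: not confirmed
  d3 <- decide_additivity(rnorm(5, 0.108, 0.012), rnorm(5, 0.105, 0.012))
  expect_true(d3$p_value >= 0.01)
  expect_equal(d3$verdict, "not_confirmed")
})

test_that("raising every S replicate never revokes a confirmation", {
  set.seed(19)
  for (k in 1:20) {
    s <- rnorm(5, runif(1, 0.1, 0.2), 0.015)
    n <- rnorm(5, 0.1, 0.011)
    v0 <- decide_additivity(s, n)$verdict
    if (v0 == "not_confirmed") next
    for (shift in c(0.01, 0.05, 0.2)) {
      expect_true(decide_additivity(s + shift, n)$verdict !=
                    "not_confirmed")
    }
  }
})

test_that("candidate sites require confirmation on both strands", {
  params <- sim_params(seed = 37)
  seq <- as.character(test_ref)
  het <- data.frame(pos = 122, minor = "T", fraction = 0.3)
  fwd <- render_trace(seq, het, params, seed = 41)
  rev <- render_trace(seq, het, params, strand = "reverse", seed = 43)
  expect_equal(detect_candidate_sites(fwd, rev), 122L)
  # pure traces yield nothing
  pf <- render_trace(seq, NULL, params, seed = 47)
  pr <- render_trace(seq, NULL, params, strand = "reverse", seed = 53)
  expect_equal(detect_candidate_sites(pf, pr), integer(0))
  # a forward-only double peak is rejected
  expect_equal(detect_candidate_sites(fwd, pr), integer(0))
  expect_error(detect_candidate_sites(fwd, as_sanger_trace(pr[1:10, ])),
               "contiguous|length")
})

test_that("calibration table flags follow alpha monotonically", {
  params <- sim_params(seed = 61)
  tab <- calibration_table(params = params)
  expect_equal(tab$fraction_pct, c(10, 15, 20, 30, 40, 50))
  expect_identical(tab$significant,
                   tab$p_value < 0.01 & tab$s_mean > tab$n_mean)
  expect_true(all(diff(tab$s_mean) > 0))
  strict <- calibration_table(params = params, alpha = 1e-9)
  loose <- calibration_table(params = params, alpha = 0.9999)
  expect_true(all(strict$significant <= tab$significant))
  expect_true(all(tab$significant <= loose$significant))
  # a zero mixture is never confirmed: its S mean sits at or below the
  # noise mean, so the directional rule refuses the flag
  z <- calibration_table(fractions = 0, params = sim_params(seed = 67))
  expect_false(z$significant)
  reps0 <- simulate_sn_replicates(0, 5, sim_params(seed = 67))
  expect_equal(decide_additivity(reps0$s, reps0$n_val)$verdict,
               "not_confirmed")
})

test_that("hybrid ratio summarizes replicates on the percent scale", {
  expect_equal(unname(hybrid_ratio(c(0.334, 0.335, 0.333))),
               c(33.40, 0.10))
  expect_equal(unname(hybrid_ratio(c(0.2, 0.2, 0.2))[2]), 0)
  expect_error(hybrid_ratio(0.3), "at least 2")
  # measurement recovery from rendered traces at a true fraction
  params <- sim_params(seed = 71)
  seq <- as.character(test_ref)
  s_reps <- vapply(1:3, function(k) {
    tr <- render_trace(seq, data.frame(pos = 122, minor = "T",
                                       fraction = 0.35), params,
                       seed = 700 + k)
    s_value(extract_peaks(tr, 122L, c(117L, 127L)))
  }, numeric(1))
  expect_equal(unname(hybrid_ratio(s_reps)[1]), 35, tolerance = 0.1)
})

test_that("per-type aggregation reproduces the packaged panel means", {
  panel <- build_specimen_panel()
  agg <- aggregate_ratios_by_type(panel)
  pick <- function(ty, site) agg$mean_ratio[agg$its_type == ty &
                                              agg$site == site]
  # independent recomputation for one multi-specimen cell
  p4 <- panel$ratio122_mean[panel$its_type == "P4"]
  expect_equal(pick("P4", 122), round(mean(p4), 2))
  expect_equal(agg$n[agg$its_type == "P1" & agg$site == 122], 33L)
  # cells with no measured specimen are absent (CT46 has no ratios)
  expect_false(any(agg$its_type == "T1"))
  expect_false(any(agg$its_type == "P2" & agg$site == 122))
})
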