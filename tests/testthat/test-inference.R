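make_flow_fixture <- function(n = 1000, n_outliers = 10, ref_mean = 200) {
  # scatter spread with a few planted fluorescence outliers that sit at the
  # scatter centre so only the fluorescence filter can remove them
  set.seed(31)
  fs <- data.frame(
    fl = rlnorm(n, log(ref_mean), 0.2),
    fsc = rnorm(n, 5e4, 5e3),
    ssc = rnorm(n, 5e4, 5e3)
  )
  idx <- seq_len(n_outliers)
  fs$fl[idx] <- ref_mean * 6 * (1.5 + runif(n_outliers))
  fs$fsc[idx] <- mean(fs$fsc[-idx])
  fs$ssc[idx] <- mean(fs$ssc[-idx])
  fs
}

test_that("the scatter gate and fluorescence outlier filter remove exactly
           what they should", {
  # all events at the scatter mean: scatter gate removes nothing
  fs0 <- data.frame(fl = rlnorm(50, 5, 0.1), fsc = rep(1, 50),
                    ssc = rep(1, 50))
  g0 <- gate_events(fs0, reference_mean = 1e6)
  expect_identical(nrow(g0), 50L)
  expect_identical(attr(g0, "n_scatter_removed"), 0L)

  # planted >6-fold outliers at the scatter centre are removed in step 2
  fs <- make_flow_fixture(n = 1000, n_outliers = 10, ref_mean = 200)
  g <- gate_events(fs, scatter_sd = 3, outlier_fold = 6,
                   reference_mean = 200)
  expect_identical(attr(g, "n_outlier_removed"), 10L)

  # a single extreme scatter event is caught by a tight gate
  fs2 <- fs0
  fs2$fsc[1] <- 100
  g2 <- gate_events(fs2, scatter_sd = 0.5, reference_mean = 1e6)
  expect_false(1 %in% as.integer(rownames(g2)))

  # gating with a fixed reference is idempotent
  fs3 <- gen_flow_sample(n_events = 2000, arrest_fraction = 0.1, seed = 8)
  g3a <- gate_events(fs3, reference_mean = 200)
  g3b <- gate_events(g3a, reference_mean = 200)
  expect_identical(nrow(g3a), nrow(g3b))
  expect_identical(g3a$fl, g3b$fl)

  expect_error(gate_events(fs0, scatter_sd = 1e-9, outlier_fold = 1e-9,
                           reference_mean = 1),
               class = "satarrest_empty_gate")
})

test_that("distribution moments match known shapes", {
  set.seed(11)
  z <- rnorm(1e5)
  mz <- distribution_moments(z + 10)
  expect_lt(abs(mz$skewness), 0.05)
  expect_lt(abs(mz$excess_kurtosis), 0.05)
  ml <- distribution_moments(rlnorm(1e5, 0, 0.5))
  expect_gt(ml$skewness, 0.5)
  mc <- distribution_moments(rep(3, 10))
  expect_identical(mc$cv, 0)
  expect_error(distribution_moments(c(-1, 1, -1, 1)), "zero")
  expect_error(distribution_moments(c(1, 2, 3)), "at least 4")
})

test_that("growth-rate fits recover exponential, noisy and saturating
           curves", {
  tt <- seq(0, 8, by = 0.1)
  exact <- data.frame(time = tt, od = 0.01 * exp(0.6 * tt))
  f1 <- fit_growth_rate(exact, blank = 0)
  expect_equal(f1$rate, 0.6, tolerance = 1e-10)
  expect_equal(f1$r_squared, 1)

  set.seed(21)
  noisy <- data.frame(time = tt,
                      od = 0.01 * exp(0.6 * tt) *
                        exp(rnorm(length(tt), 0, 0.01)))
  expect_equal(fit_growth_rate(noisy, blank = 0)$rate, 0.6,
               tolerance = 0.02 / 0.6)

  oc <- gen_od_curves(noise_cv = 0, seed = 2)
  f3 <- fit_growth_rate(oc[oc$replicate == 1, ])
  expect_equal(f3$rate, 0.6, tolerance = 0.05)
  # the selected window excludes the plateau
  curve1 <- oc[oc$replicate == 1, ]
  expect_lt(max(curve1$od[f3$window]), 0.5 * max(curve1$od))

  flat <- data.frame(time = tt, od = rep(0.005, length(tt)))
  expect_error(fit_growth_rate(flat, blank = 0.004), "window")
})

test_that("the heterogeneous fluorescence model nests the uniform model
           and recovers planted parameters", {
  cal <- fluorescence_model(a = 50, b = 120)
  g <- seq(0.15, 0.7, length.out = 10)
  m0 <- cal
  m0$s <- 0
  m0$p_arr <- 900
  expect_equal(predict_mean_fluorescence(g, m0, "heterogeneous"),
               predict_mean_fluorescence(g, m0, "uniform"))
  # total arrest dominance: mean fluorescence approaches p_arr
  m1 <- cal
  m1$s <- 1e6
  m1$p_arr <- 900
  expect_equal(predict_mean_fluorescence(0.3, m1, "heterogeneous"), 900,
               tolerance = 1e-3)

  fp <- gen_fluorescence_pairs(seed = 5)  # p_arr = 1500, s = 0.12, 2% noise
  fit <- fit_arrest_parameters(fp, cal)
  expect_equal(fit$p_arr, 1500, tolerance = 0.1)
  expect_equal(fit$s, 0.12, tolerance = 0.1)
  expect_true(fit$identifiable)
  expect_lte(fit$ss, fit$ss_uniform)
  expect_gt(fit$cor_heterogeneous, fit$cor_uniform)

  # uniform-generated data: best switching rate collapses to zero
  fpu <- gen_fluorescence_pairs(mode = "uniform", noise_cv = 0, seed = 6)
  fitu <- fit_arrest_parameters(fpu, cal)
  expect_lt(fitu$s, 0.01)
})

test_that("polynomial model comparison uses the full Gaussian AIC and
           behaves consistently under both truths", {
  x <- seq(0, 10, length.out = 30)
  yq <- 1 + 0.5 * x - 0.08 * x^2
  cmp <- compare_polynomial_models(x, yq)
  expect_identical(cmp$preferred, "quadratic")
  expect_lt(sum(residuals(cmp$fit_quadratic)^2), 1e-20)
  # convention check against the reference implementation in stats
  set.seed(2)
  yn <- yq + rnorm(30, 0, 0.3)
  cmp2 <- compare_polynomial_models(x, yn)
  expect_equal(cmp2$aic_linear, AIC(cmp2$fit_linear))
  expect_equal(cmp2$aic_quadratic, AIC(cmp2$fit_quadratic))
  # pure line: the parsimony penalty favours the linear model on average
  set.seed(3)
  pref_lin <- vapply(1:50, function(i) {
    y <- 2 + 0.3 * x + rnorm(30, 0, 0.3)
    compare_polynomial_models(x, y)$preferred == "linear"
  }, logical(1))
  expect_gt(mean(pref_lin), 0.6)
})

test_that("biphasic kill fits recover planted parameters and flag
           degenerate single-phase curves", {
  kc <- gen_kill_curve(seed = 4, replicates = 3)
  fit <- fit_biphasic_kill(kc)
  expect_false(fit$non_biphasic)
  expect_equal(fit$fast_rate, 1.0, tolerance = 0.25)
  expect_equal(fit$slow_rate, 0.05, tolerance = 0.25)
  expect_equal(fit$persister_fraction, 1e-3, tolerance = 0.25)
  expect_gt(fit$breakpoint, 0)

  # single-exponential decay is flagged as non-biphasic
  tt <- c(0, 1, 2, 3, 4, 6, 8)
  single <- data.frame(time = tt, cfu = 1e8 * exp(-0.8 * tt))
  fs <- fit_biphasic_kill(single, detection_limit = 1)
  expect_true(fs$non_biphasic || fs$fast_rate < 1.5 * fs$slow_rate)

  # larger persister fractions raise the slow-phase plateau monotonically
  fhat <- vapply(c(1e-4, 1e-3, 1e-2), function(f_true) {
    fit_biphasic_kill(gen_kill_curve(f = f_true, seed = 12,
                                     replicates = 3))$persister_fraction
  }, numeric(1))
  expect_true(all(diff(fhat) > 0))
})

test_that("survival ratios are computed per matched replicate with
           censoring handled by detection-limit substitution", {
  same <- survival_ratio_stats(c(50, 70, 90), c(50, 70, 90))
  expect_identical(same$ratios, c(0, 0, 0))
  sr <- survival_ratio_stats(c(10, 100), c(1000, 1000))
  expect_identical(sr$ratios, c(-2, -1))
  expect_identical(sr$mean, -1.5)
  tri <- survival_ratio_stats(c(10, 20, 40), c(1000, 1000, 1000))
  expect_equal(tri$sem, sd(tri$ratios) / sqrt(3))
  cen <- survival_ratio_stats(c(0, 100), c(1000, 1000),
                              detection_limit = 10)
  expect_identical(cen$ratios[1], -2)
  expect_identical(cen$censored, c(TRUE, FALSE))
  expect_error(survival_ratio_stats(c(1, 2), c(1, 2, 3)), "unmatched")
})
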