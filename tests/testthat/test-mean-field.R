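test_that("benefit factor matches its closed forms and stays in [0,1]", {
  expect_equal(benefit_factor(0, 400), 0)
  expect_equal(benefit_factor(400, 400), 1)
  expect_equal(benefit_factor(800, 400), 1)
  expect_equal(benefit_factor(400, 400, "michaelis_menten"), 0.5)
  flux <- seq(0, 50, length.out = 200)
  for (form in c("piecewise_linear", "michaelis_menten")) {
    f <- benefit_factor(flux, 7, form)
    expect_true(all(f >= 0 & f <= 1))
    expect_true(all(diff(f) >= 0))
  }
  expect_error(benefit_factor(-1, 400), "nonnegative")
  expect_error(benefit_factor(1, 0), "delta")
})

test_that("toxicity factor is a decreasing Hill function with f(0) = 1", {
  expect_equal(toxicity_factor(0, 1), 1)
  expect_equal(toxicity_factor(5, 5), 0.5)
  expect_equal(toxicity_factor(5, 5, hill = 3), 0.5)
  expect_equal(toxicity_factor(10, 1, hill = 1), 1 / 11)
  x <- seq(0, 100, length.out = 300)
  for (h in c(1, 2, 4)) {
    f <- toxicity_factor(x, 10, h)
    expect_true(all(f >= 0 & f <= 1))
    expect_true(all(diff(f) < 0))
  }
  expect_error(toxicity_factor(-1, 1), "nonnegative")
})

test_that("pathway RHS is production-only at the origin and zero at a solved
           steady state", {
  pb <- pathway_params(v_plus = 0.3, delta = 0.5,
                       toxicity_variant = "byproduct",
                       byproduct_yield = 0.7)
  d0 <- pathway_rhs(list(m = 0, t = 0), pb)
  expect_equal(unname(d0[["m"]]), 0.3)
  expect_equal(unname(d0[["t"]]), 0.7 * 0.3)

  p <- pathway_params(v_plus = 0.6, delta = 0.5)
  ss <- solve_steady_state(p)
  expect_false(is.null(ss))
  resid <- pathway_rhs(list(m = ss$m), p)[["m"]]
  expect_lt(abs(resid), 1e-8 * max(p$v_plus, p$vmax_b))
})

test_that("without toxicity the trajectory converges to a finite steady
           state", {
  p <- pathway_params(v_plus = 0.9, delta = 0.5, toxicity_variant = "none")
  ss <- integrate_to_steady_state(p)
  expect_false(is.null(ss))
  expect_true(is.finite(ss$m) && ss$m > 0)
  expect_equal(ss$m, solve_steady_state(p)$m, tolerance = 1e-3)
})

test_that("steady-state solver handles the analytic corner cases", {
  p0 <- pathway_params(v_plus = 0, delta = 0.5,
                       toxicity_variant = "none")
  expect_equal(solve_steady_state(p0)$m, 0)
  # production beyond consumption + maximal dilution capacity: no root
  p_hi <- pathway_params(v_plus = 5, delta = 0.5, theta = 100,
                         vmax_b = 1, g_max = 6e-4)
  expect_null(solve_steady_state(p_hi))
})

test_that("root-finding classification agrees with the integration oracle
           on randomized parameter sets", {
  set.seed(7)
  for (i in 1:30) {
    q <- pathway_params(v_plus = runif(1, 0, 2), delta = runif(1, 0.05, 2),
                        theta = 10^runif(1, 0, 3),
                        vmax_b = runif(1, 0.2, 2),
                        km_b = 10^runif(1, -1, 1))
    expect_identical(is.null(solve_steady_state(q)),
                     is.null(integrate_to_steady_state(q)),
                     label = paste("draw", i))
  }
})

test_that("regime classification recovers starvation, satiation and
           surfeit along a production scan", {
  expect_identical(classify_regime(pathway_params(v_plus = 1e-4,
                                                  delta = 0.5)), "I")
  expect_identical(classify_regime(pathway_params(v_plus = 0.8,
                                                  delta = 0.5)), "II")
  expect_identical(classify_regime(pathway_params(v_plus = 1.3,
                                                  delta = 0.5)), "III")
})

test_that("toxicity-free and non-saturating consumption variants never lose
           their steady state", {
  vs <- seq(0.05, 2, length.out = 12)
  for (v in vs) {
    pn <- pathway_params(v_plus = v, delta = 0.5,
                         toxicity_variant = "none")
    expect_false(classify_regime(pn) == "III")
    # linear consumption: km -> Inf at fixed vmax/km slope
    plin <- pathway_params(v_plus = v, delta = 0.5, theta = 100,
                           vmax_b = 1e8, km_b = 1e8)
    expect_false(classify_regime(plin) == "III")
  }
})

test_that("phase diagram contains all three regimes, ordered along the
           production axis, with no satiation beyond the convergence
           demand", {
  pd <- phase_diagram(seq(0.02, 1.4, length.out = 20),
                      seq(0.05, 1.3, length.out = 20))
  expect_setequal(unique(as.vector(pd$regime)), c("I", "II", "III"))
  # per demand column: I block, then II, then III as V+ increases
  for (j in seq_along(pd$delta_grid)) {
    col <- pd$regime[, j]
    expect_true(!is.unsorted(match(col, c("I", "II", "III"))),
                label = paste("column", j))
  }
  # regime III has zero growth; others positive
  expect_true(all(pd$norm_growth[pd$regime == "III"] == 0))
  expect_true(all(pd$norm_growth[pd$regime != "III"] > 0))
  # demand above the convergence point (> vmax_b): no satiation regime
  high <- pd$regime[, pd$delta_grid > 1.05]
  expect_false(any(high == "II"))
  # interior growth maximum along V+ at high demand
  jhi <- max(which(pd$delta_grid <= 1))
  prof <- pd$norm_growth[, jhi]
  expect_true(which.max(prof) > 1 &&
                which.max(prof) < length(prof))
  expect_error(phase_diagram(numeric(0), 1), "non-empty")
})

test_that("byproduct toxicity loses its steady state at a production flux
           no larger than substrate toxicity", {
  scan <- seq(0.05, 6, by = 0.05)
  ps <- pathway_params(delta = 0.5, theta = 5000)
  pb <- pathway_params(delta = 0.5, theta = 5000,
                       toxicity_variant = "byproduct")
  thr_s <- regime3_threshold(ps, scan)
  thr_b <- regime3_threshold(pb, scan)
  expect_true(is.finite(thr_b) && is.finite(thr_s))
  expect_lte(thr_b, thr_s)
})

test_that("rescaled parameters follow their definitions and the existence
           boundary is monotone in (R, Theta)", {
  rp <- rescale_parameters(pathway_params(v_plus = 1, vmax_b = 2,
                                          theta = 5, km_b = 10))
  expect_equal(rp$r_ratio, 0.5)
  expect_equal(rp$theta_scaled, 0.5)
  # existence over an (R, Theta) grid at fixed delta and km
  r_grid <- seq(0.1, 1.6, length.out = 8)
  th_grid <- 10^seq(0, 3, length.out = 8)
  exists_mat <- outer(r_grid, th_grid, Vectorize(function(r, th) {
    p <- pathway_params(v_plus = r * 1, vmax_b = 1, theta = th * 1,
                        km_b = 1, delta = 0.5)
    !is.null(solve_steady_state(p))
  }))
  # increasing R can only destroy existence; increasing Theta only helps
  expect_true(all(apply(exists_mat, 2, function(col) all(diff(col) <= 0))))
  expect_true(all(apply(exists_mat, 1, function(row) all(diff(row) >= 0))))
  # R -> 0: steady state always exists
  expect_false(is.null(solve_steady_state(
    pathway_params(v_plus = 1e-9, delta = 0.5))))
})

test_that("runaway metabolite buildup is irreversible once past the largest
           root", {
  p <- pathway_params(v_plus = 1.3, delta = 0.5)  # surfeit regime
  expect_null(solve_steady_state(p))
  times <- seq(0, 2e5, length.out = 400)
  sol <- deSolve::ode(c(m = 0), times, satarrest:::rhs_desolve, p,
                      rtol = 1e-8, atol = 1e-10)
  m <- sol[, "m"]
  expect_true(all(diff(m) > -1e-8))
})

test_that("first-passage times behave as the volume-scan model predicts", {
  base <- pathway_params(delta = 500, vmax_b = 1, theta = 100,
                         g_max = 6e-4, km_b = 100)
  p0 <- base; p0$v_plus <- 0
  expect_null(first_passage_time(p0))
  # in the runaway region, passage time decreases with production
  tms <- vapply(c(1.5, 2, 3), function(v) {
    p <- base; p$v_plus <- v
    first_passage_time(p, volume = 1)
  }, numeric(1))
  expect_true(all(diff(tms) < 0))
  # a 10% larger cell reaches the threshold later, for every Km
  for (km in c(10, 100, 1000)) {
    p <- base; p$km_b <- km; p$v_plus <- 2
    d <- first_passage_time(p, volume = 1.1) -
      first_passage_time(p, volume = 1)
    expect_gte(d, 0)
  }
})
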