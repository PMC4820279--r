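test_that("reaction system encodes 13 reaction types over 22 channels with
           a toggle pair per gene", {
  sp <- build_reaction_system()
  expect_s3_class(sp, "reaction_system_spec")
  expect_identical(sp$n_reactions, 13L)
  ch <- sp$reaction_channels
  expect_identical(nrow(ch), 22L)
  expect_identical(sort(unique(ch$reaction)), 1:13)
  # gene toggling: two on/off channel pairs
  expect_identical(sum(ch$reaction == 5), 4L)
  expect_error(build_reaction_system(k_im = -1), "nonnegative")
})

test_that("growth feedback vanishes without product and toxin-free states
           are uninhibited", {
  sp <- build_reaction_system()
  st0 <- cell_state()  # I = 0, P = 0
  expect_identical(satarrest:::feedback_factor(st0, sp), 0)
  st1 <- cell_state(P = 400)  # demand met, no toxin
  expect_identical(satarrest:::feedback_factor(st1, sp), 1)
  stt <- cell_state(P = 400, I = 1e4)  # intermediate at threshold
  expect_equal(satarrest:::feedback_factor(stt, sp), 0.5)
})

test_that("a system with all rate constants zero stays frozen with zero
           growth", {
  sp <- build_reaction_system(k_im = 0, k_tA = 0, k_tB = 0, k_mdeg = 0,
                              k_tsn = 0, k_g = 0, k_gon = 0, k_goff = 0,
                              k_minus1 = 0, k_cat1 = 0, k_2 = 0,
                              k_minus2 = 0, k_cat2 = 0, k_u = 0)
  init <- cell_state(mA = 2, A = 5, B = 7, I = 3, P = 11)
  tr <- simulate_trajectory(sp, init = init, t_end = 100, seed = 5)
  expect_identical(tr$final, init[names(tr$final)])
  expect_identical(tr$growth_avg, 0)
  expect_identical(tr$n_events, 0)
})

test_that("identical seeds reproduce trajectories and ensembles exactly", {
  sp <- build_reaction_system(k_im = 0.5)
  init <- mean_field_init_state(sp)
  a <- simulate_trajectory(sp, init, t_end = 500, seed = 42)
  b <- simulate_trajectory(sp, init, t_end = 500, seed = 42)
  expect_identical(a$final, b$final)
  expect_identical(a$growth_avg, b$growth_avg)
  expect_identical(a$samples, b$samples)
  d <- simulate_trajectory(sp, init, t_end = 500, seed = 43)
  expect_false(identical(a$final, d$final) &&
                 identical(a$n_events, d$n_events))
  e1 <- run_ensemble(sp, n_traj = 5, t_end = 300, seed_base = 9,
                     init = init)
  e2 <- run_ensemble(sp, n_traj = 5, t_end = 300, seed_base = 9,
                     init = init)
  expect_identical(e1$trajectories, e2$trajectories)
  expect_identical(e1$correlations, e2$correlations)
})

test_that("gene copies are conserved and growth never exceeds its
           ceiling", {
  sp <- build_reaction_system(k_im = 1)
  e <- run_ensemble(sp, n_traj = 10, t_end = 1000, seed_base = 3,
                    keep_samples = TRUE)
  fin <- e$trajectories
  final_mat <- t(vapply(seq_len(10), function(i) {
    simulate_trajectory(sp, mean_field_init_state(sp), t_end = 400,
                        seed = i, keep_samples = FALSE)$final
  }, numeric(12)))
  expect_true(all(final_mat[, "gA"] + final_mat[, "gA_on"] == 1))
  expect_true(all(final_mat[, "gB"] + final_mat[, "gB_on"] == 1))
  expect_true(all(fin$growth_avg >= 0 & fin$growth_avg <= sp$k_g))
  # 2-D histogram counts account for every sample of every trajectory
  expect_identical(sum(e$hist2d$counts),
                   as.integer(e$n_traj * (1000 / 10 + 1)))
})

test_that("mean-field initial conditions solve the rate equations and the
           runaway fallback engages only when needed", {
  sp <- build_reaction_system(k_im = 1e-5)
  init <- mean_field_init_state(sp)
  expect_false(attr(init, "fallback"))
  expect_lt(attr(init, "residual"), 1e-3)
  expect_lte(init[["I"]], 1)   # starvation: intermediate and product empty
  expect_lte(init[["P"]], 1)
  # enzymes at transcription/dilution balance are present
  expect_gt(init[["A"]], 10)
  # unrounded state satisfies the rate equations to the stated tolerance
  mf <- attr(init, "mean_field")
  res <- satarrest:::ode_residual(sp, mf)
  expect_lt(max(abs(res)), 1e-3)
  # production capacity above consumption capacity: runaway, fallback path
  sp_run <- build_reaction_system(k_im = 1, k_tA = 0.3)
  init_run <- mean_field_init_state(sp_run)
  expect_true(attr(init_run, "fallback"))
})

test_that("in the high-copy limit ensemble averages match the deterministic
           rate equations within three standard errors", {
  sp <- build_reaction_system(k_im = 0.1, theta = 1e12, omega = 100,
                              gene_copies = 100L)
  init <- mean_field_init_state(sp)
  t_end <- 1500
  e <- run_ensemble(sp, n_traj = 24, t_end = t_end, seed_base = 17,
                    init = init, keep_samples = FALSE)
  times <- seq(0, t_end, by = 10)
  y0 <- stats::setNames(as.numeric(init), names(init))
  ode <- reaction_ode(sp, y0, times)
  ode_avg <- colMeans(ode[, -1])
  traj <- e$trajectories
  for (spc in c("mA", "mB", "A", "B", "AS", "BI", "P")) {
    v <- traj[[spc]]
    se <- stats::sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - ode_avg[[spc]]), 3 * se + 1e-9,
              label = paste("species", spc))
  }
})

test_that("arrest is toxic, not starvation: empty at low import, total when
           production capacity outstrips consumption", {
  sp_lo <- build_reaction_system(k_im = 1e-5)
  e_lo <- run_ensemble(sp_lo, n_traj = 20, t_end = 2000, seed_base = 5,
                       keep_samples = FALSE)
  expect_lt(arrest_fraction(e_lo), 0.05)
  # producing enzyme overexpressed: import capacity deterministically
  # exceeds consumption capacity, every trajectory crosses the threshold
  sp_hi <- build_reaction_system(k_im = 1, k_tA = 0.3)
  e_hi <- run_ensemble(sp_hi, n_traj = 20, t_end = 2000, seed_base = 5,
                       keep_samples = FALSE)
  expect_gt(arrest_fraction(e_hi), 0.95)
  # arrest responds monotonically to the import rate at fixed seeds
  fracs <- vapply(c(1e-3, 0.3, 10), function(k) {
    sp <- build_reaction_system(k_im = k)
    arrest_fraction(run_ensemble(sp, n_traj = 20, t_end = 2000,
                                 seed_base = 5, keep_samples = FALSE))
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("at the capacity threshold the intermediate marginal splits into
           a low fast-growing mode and a high arrested mode", {
  sp <- build_reaction_system(k_im = 1, k_tA = 0.2)
  e <- run_ensemble(sp, n_traj = 30, t_end = 8000, seed_base = 13)
  i_final <- e$trajectories$I_final
  low <- mean(i_final < 100)
  high <- mean(i_final > 1e4)
  expect_gt(low, 0.1)
  expect_gt(high, 0.1)
  # the two modes are separated by a depleted middle
  expect_lt(mean(i_final >= 100 & i_final <= 1e4), min(low, high))
  # low-mode trajectories grow, high-mode trajectories are arrested
  expect_gt(mean(e$trajectories$growth_avg[i_final < 100]),
            2 * mean(e$trajectories$growth_avg[i_final > 1e4]))
})

test_that("the intermediate marginal at low import is supported on small
           integers with discreteness gaps", {
  sp <- build_reaction_system(k_im = 0.01)
  e <- run_ensemble(sp, n_traj = 10, t_end = 1000, seed_base = 21,
                    keep_samples = TRUE)
  # counts sampled on the grid are small integers
  expect_true(max(e$trajectories$I_final) <= 5)
  expect_true(all(e$trajectories$I_final >= 0))
})
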