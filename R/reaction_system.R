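#' Build the growth-feedback reaction system
#'
#' Encodes the 13-reaction network coupling expression of two enzymes to a
#' saturable metabolic pathway with growth-rate feedback: transcription of
#' each enzyme from a toggling gene (growth-coupled), mRNA decay,
#' translation, growth-coupled enzyme dilution, substrate import through
#' enzyme A (`A + S <-> A.S -> A + I`, substrate subsumed into the
#' composite constant `k_im`), consumption of the intermediate by enzyme B
#' (`B + I <-> B.I -> B + P`), growth-coupled dilution of the complexes and
#' the intermediate, and first-order demand turnover of the product.  The
#' toxicity factor `f_tox` acts on the intermediate I (the only species
#' that can build up) and the benefit factor `f_gr` on the product P
#' relative to the demand `delta`; their product multiplies every
#' growth-coupled propensity (transcription and all dilution channels).
#'
#' Default constants are the stochastic-simulation values:
#' `k_tE = 0.05`, `k_mdeg = 0.0033`, `k_tsn = 0.05`, `k_g = 6e-4`,
#' `k_gon = 4.5e-4`, `k_goff = 2.8e-3`, `k_minus1 = 2`, `k_cat1 = 1`,
#' `k_2 = 2`, `k_minus2 = 2`, `k_cat2 = 1`, `k_u = 2` (all s^-1; `k_2` in
#' volume per count per second), `delta = 400`, and `theta = 1e4` (low
#' toxicity) or `1` (high toxicity); the import constant `k_im` is the
#' control parameter, varied over `[1e-5, 10]`.
#'
#' @param k_im composite import constant (s^-1), absorbing the fixed
#'   substrate level.
#' @param theta toxicity threshold on the intermediate (counts per volume).
#' @param delta demand on the product (counts per volume).
#' @param k_tA,k_tB transcription constants of enzymes A and B (s^-1).
#' @param k_mdeg,k_tsn,k_g,k_gon,k_goff,k_minus1,k_cat1,k_2,k_minus2,k_cat2,k_u
#'   remaining rate constants, as above.
#' @param omega cell volume (sets the bimolecular propensity
#'   `k_2 * B * I / omega` and the count scale of `theta` and `delta`).
#' @param gene_copies gene copies per enzyme.
#' @param benefit_form form of the growth benefit factor.
#' @param hill_tox Hill exponent of the toxicity factor.
#' @param fgr_floor optional floor on `f_gr` (default 0: with no product
#'   the cell does not grow, so growth-coupled channels stall).
#' @return object of class `reaction_system_spec`.
#' @export
build_reaction_system <- function(k_im = 0.1,
                                  theta = 1e4,
                                  delta = 400,
                                  k_tA = 0.05, k_tB = 0.05,
                                  k_mdeg = 0.0033, k_tsn = 0.05,
                                  k_g = 6e-4,
                                  k_gon = 4.5e-4, k_goff = 2.8e-3,
                                  k_minus1 = 2, k_cat1 = 1,
                                  k_2 = 2, k_minus2 = 2, k_cat2 = 1,
                                  k_u = 2,
                                  omega = 1, gene_copies = 1L,
                                  benefit_form = c("piecewise_linear",
                                                   "michaelis_menten"),
                                  hill_tox = 1,
                                  fgr_floor = 0) {
  benefit_form <- match.arg(benefit_form)
  vals <- c(k_im = k_im, theta = theta, delta = delta, k_tA = k_tA,
            k_tB = k_tB, k_mdeg = k_mdeg, k_tsn = k_tsn, k_g = k_g,
            k_gon = k_gon, k_goff = k_goff, k_minus1 = k_minus1,
            k_cat1 = k_cat1, k_2 = k_2, k_minus2 = k_minus2,
            k_cat2 = k_cat2, k_u = k_u, omega = omega,
            hill_tox = hill_tox, fgr_floor = fgr_floor)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all rate constants must be finite and nonnegative")
  }
  stopifnot(omega > 0, gene_copies >= 1)
  spec <- c(as.list(vals),
            list(gene_copies = as.integer(gene_copies),
                 benefit_form = benefit_form))
  # 13 reaction types; gene toggling contributes one forward/backward pair
  # per gene
  spec$n_reactions <- 13L
  spec$reaction_channels <- reaction_channel_table()
  class(spec) <- "reaction_system_spec"
  spec
}

reaction_channel_table <- function() {
  data.frame(
    channel = 1:22,
    reaction = c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L, 5L, 5L,
                 6L, 6L, 7L, 8L, 8L, 9L, 10L, 11L, 12L, 13L),
    description = c(
      "transcription mA", "transcription mB",
      "mRNA decay mA", "mRNA decay mB",
      "translation A", "translation B",
      "dilution A", "dilution B",
      "gene A on", "gene A off", "gene B on", "gene B off",
      "A + S -> A.S", "A.S -> A + S", "A.S -> A + I",
      "B + I -> B.I", "B.I -> B + I", "B.I -> B + P",
      "dilution A.S", "dilution B.I", "dilution I", "demand P -> 0"
    ),
    stringsAsFactors = FALSE
  )
}

#' @export
print.reaction_system_spec <- function(x, ...) {
  cat("Growth-feedback reaction system:",
      x$n_reactions, "reaction types,",
      nrow(x$reaction_channels), "channels\n")
  cat(sprintf("  k_im = %g, theta = %g, delta = %g, k_tA = %g, k_tB = %g\n",
              x$k_im, x$theta, x$delta, x$k_tA, x$k_tB))
  cat(sprintf("  benefit: %s, Hill(tox) = %g, omega = %g, %d gene copies\n",
              x$benefit_form, x$hill_tox, x$omega, x$gene_copies))
  invisible(x)
}

species_names <- function() {
  c("mA", "mB", "A", "B", "AS", "BI", "I", "P",
    "gA", "gA_on", "gB", "gB_on")
}

#' Construct an integer cell state
#'
#' @param ... named counts overriding zeros; names among `mA, mB, A, B, AS,
#'   BI, I, P, gA, gA_on, gB, gB_on` (genes default to one inactive copy).
#' @param gene_copies gene copies per enzyme.
#' @return named numeric vector of nonnegative integer counts.
#' @export
cell_state <- function(..., gene_copies = 1L) {
  st <- stats::setNames(numeric(12L), species_names())
  st["gA"] <- gene_copies
  st["gB"] <- gene_copies
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), species_names())
    if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
    st[names(ov)] <- ov
  }
  if (any(st < 0) || any(st != round(st))) {
    stop("counts must be nonnegative integers")
  }
  st
}

# growth-feedback factor of a (possibly continuous) state
feedback_factor <- function(state, spec) {
  ftox <- 1 / (1 + (state[["I"]] / (spec$omega * spec$theta))^spec$hill_tox)
  r <- state[["P"]] / (spec$omega * spec$delta)
  fgr <- if (spec$benefit_form == "michaelis_menten") r / (1 + r)
         else min(r, 1)
  ftox * max(fgr, spec$fgr_floor)
}

# deterministic rate equations of the same network (deSolve form);
# clamp: "none", "ftox" (f_tox = 1) or "all" (f = 1)
reaction_rates_ode <- function(t, y, parms) {
  spec <- parms$spec
  clamp <- parms$clamp
  f <- switch(clamp,
    all = 1,
    ftox = {
      r <- y[["P"]] / (spec$omega * spec$delta)
      fgr <- if (spec$benefit_form == "michaelis_menten") r / (1 + r)
             else min(r, 1)
      max(fgr, spec$fgr_floor)
    },
    none = feedback_factor(y, spec)
  )
  with(as.list(c(y, spec[c("k_tA", "k_tB", "k_mdeg", "k_tsn", "k_g",
                           "k_gon", "k_goff", "k_im", "k_minus1", "k_cat1",
                           "k_2", "k_minus2", "k_cat2", "k_u", "omega")])), {
    bind <- (k_2 / omega) * B * I
    list(c(
      mA = k_tA * f * gA_on - k_mdeg * mA,
      mB = k_tB * f * gB_on - k_mdeg * mB,
      A = k_tsn * mA - k_g * f * A - k_im * A + (k_minus1 + k_cat1) * AS,
      B = k_tsn * mB - k_g * f * B - bind + (k_minus2 + k_cat2) * BI,
      AS = k_im * A - (k_minus1 + k_cat1) * AS - k_g * f * AS,
      BI = bind - (k_minus2 + k_cat2) * BI - k_g * f * BI,
      I = k_cat1 * AS - bind + k_minus2 * BI - k_g * f * I,
      P = k_cat2 * BI - k_u * P,
      gA = k_goff * gA_on - k_gon * gA,
      gA_on = k_gon * gA - k_goff * gA_on,
      gB = k_goff * gB_on - k_gon * gB,
      gB_on = k_gon * gB - k_goff * gB_on
    ))
  })
}

#' Integrate the deterministic rate equations of the reaction system
#'
#' Mean-field companion of the stochastic simulator: identical network and
#' feedback factors, continuous species.  Used for initial conditions and
#' as the high-copy-limit oracle of the exact simulation.
#'
#' @param spec a [build_reaction_system()] spec.
#' @param init named state vector (see [cell_state()]).
#' @param times output times (s).
#' @param clamp feedback clamp: `"none"` (full model), `"ftox"` (toxicity
#'   factor clamped to 1) or `"all"` (both factors clamped to 1).
#' @return deSolve matrix of the trajectory.
#' @export
reaction_ode <- function(spec, init, times, clamp = "none") {
  deSolve::ode(init, times, reaction_rates_ode,
               list(spec = spec, clamp = clamp),
               method = "lsoda", rtol = 1e-8, atol = 1e-10)
}

# residual of the deterministic rate equations
ode_residual <- function(spec, y, clamp = "none") {
  unlist(reaction_rates_ode(0, y, list(spec = spec, clamp = clamp)))
}

#' Mean-field initial state of the reaction system
#'
#' Solves the deterministic rate equations of the network for their steady
#' state and rounds species to integer counts, mirroring acclimatized
#' cultures.  The nontrivial branch is reached by first solving the
#' feedback-clamped (f = 1) linear system and then relaxing the full model
#' from there.  If the full model has no steady state (runaway intermediate
#' buildup), the steady state of the network with `f_tox` clamped to 1 is
#' used instead; this fallback is reported in the `fallback` attribute.
#'
#' Gene copies are rounded like every other species, so with a single gene
#' copy and an active fraction below one half the genes start inactive.
#'
#' @param spec a [build_reaction_system()] spec.
#' @return integer [cell_state()] with attributes `mean_field` (the
#'   unrounded state), `residual` (max absolute rate residual) and
#'   `fallback` (logical).
#' @export
mean_field_init_state <- function(spec) {
  ss <- mean_field_steady_state(spec, clamp = "none")
  fallback <- is.null(ss)
  if (fallback) {
    ss <- mean_field_steady_state(spec, clamp = "ftox")
    if (is.null(ss)) {
      stop("deterministic rate equations did not converge even with ",
           "f_tox clamped")
    }
  }
  st <- round(ss$state)
  # keep gene-copy conservation exact after rounding
  st["gA_on"] <- min(st["gA_on"], spec$gene_copies)
  st["gA"] <- spec$gene_copies - st["gA_on"]
  st["gB_on"] <- min(st["gB_on"], spec$gene_copies)
  st["gB"] <- spec$gene_copies - st["gB_on"]
  st[st < 0] <- 0
  structure(st, mean_field = ss$state, residual = ss$residual,
            fallback = fallback)
}

# steady state of the deterministic network, or NULL on runaway
mean_field_steady_state <- function(spec, clamp = "none") {
  y0 <- cell_state(gene_copies = spec$gene_copies)
  # stage 1: fully clamped (f = 1) system to land on the nontrivial branch
  t1 <- seq(0, 20 / spec$k_mdeg + 40 / spec$k_g, length.out = 200L)
  s1 <- reaction_ode(spec, y0, t1, clamp = "all")
  y1 <- s1[nrow(s1), -1]
  if (clamp == "all") {
    return(list(state = y1, residual = max(abs(ode_residual(spec, y1,
                                                            "all")))))
  }
  # stage 2: relax the requested model from the clamped steady state
  horizon <- 40 / spec$k_g
  y <- y1
  for (attempt in 1:3) {
    t2 <- seq(0, horizon, length.out = 200L)
    s2 <- reaction_ode(spec, y, t2, clamp = clamp)
    y <- s2[nrow(s2), -1]
    res <- ode_residual(spec, y, clamp)
    prop_scale <- max(abs(y) * max(spec$k_u, spec$k_cat1, spec$k_minus1),
                      spec$k_tA, 1e-6)
    if (max(abs(res)) < 1e-6 * prop_scale) {
      return(list(state = y, residual = max(abs(res))))
    }
    # runaway diagnosis: intermediate climbing without bound
    iI <- s2[, "I"]
    if (clamp != "ftox" && y[["I"]] > 10 * spec$omega * spec$theta &&
        res[["I"]] > 0 && !is.unsorted(iI[(length(iI) %/% 2):length(iI)])) {
      return(NULL)
    }
    horizon <- horizon * 10
  }
  if (clamp != "ftox" && res[["I"]] > 0) return(NULL)
  stop("deterministic steady-state solve did not converge (residual ",
       format(max(abs(res))), ")")
}

#' Simulate one exact trajectory of the reaction system
#'
#' Gillespie direct-method simulation with growth-feedback propensities
#' re-evaluated at every event.  Species and the instantaneous growth rate
#' `k_g * f_tox * f_gr` are recorded on a fixed sampling grid; reported
#' time averages are exact time-weighted averages over the trajectory.
#'
#' @param spec a [build_reaction_system()] spec.
#' @param init integer state (default [mean_field_init_state()]).
#' @param t_end trajectory length (s); 8000 s by default.
#' @param seed integer seed of the trajectory's dedicated RNG stream.
#' @param sample_dt sampling grid spacing (s).
#' @param arrest_epsilon arrest criterion: the trajectory is flagged
#'   arrested when the instantaneous growth rate at `t_end` is below
#'   `arrest_epsilon * k_g` and the intermediate has crossed the toxicity
#'   threshold `theta * omega` (toxic arrest, as opposed to starvation).
#' @param keep_samples record the sampled growth/intermediate series.
#' @return list of class `trajectory_summary`: seed, time-averaged counts
#'   (`avg`), final counts (`final`), time-averaged and final growth rate,
#'   arrest flag, event count, and (optionally) the sampled series.
#' @export
simulate_trajectory <- function(spec, init = mean_field_init_state(spec),
                                t_end = 8000, seed = 1L,
                                sample_dt = 10, arrest_epsilon = 0.01,
                                keep_samples = TRUE) {
  stopifnot(t_end > 0, sample_dt > 0)
  init <- init[species_names()]
  raw <- .ssa_run(spec, as.numeric(init), t_end, sample_dt,
                  as.numeric(seed), arrest_epsilon, keep_samples)
  out <- list(
    seed = seed,
    avg = stats::setNames(raw$avg[1, ], species_names()),
    final = stats::setNames(raw$final[1, ], species_names()),
    growth_avg = raw$growth_avg[1],
    growth_final = raw$growth_final[1],
    arrest = raw$arrest[1] == 1L,
    n_events = raw$n_events[1],
    t_end = t_end, sample_dt = sample_dt
  )
  if (keep_samples) {
    out$samples <- data.frame(
      time = seq(0, by = sample_dt, length.out = raw$n_samples),
      growth = raw$samp_growth[1, ],
      I = raw$samp_I[1, ]
    )
  }
  class(out) <- "trajectory_summary"
  out
}

#' @export
print.trajectory_summary <- function(x, ...) {
  cat(sprintf(
    "SSA trajectory (seed %s): %g events over %g s\n",
    format(x$seed), x$n_events, x$t_end))
  cat(sprintf("  time-averaged growth rate %.3g /s; arrested: %s\n",
              x$growth_avg, x$arrest))
  invisible(x)
}

#' Run a seeded ensemble of stochastic trajectories
#'
#' Simulates `n_traj` independent trajectories from the mean-field initial
#' state with per-trajectory RNG streams derived from `seed_base + index`,
#' and summarizes the ensemble: mean and standard error of the
#' time-averaged growth rate (the population growth proxy), Pearson
#' correlations of each species' per-trajectory time average with growth,
#' a 2-D histogram of sampled growth rate versus intermediate counts, and
#' the arrested fraction.
#'
#' @inheritParams simulate_trajectory
#' @param n_traj number of trajectories (>= 2).
#' @param seed_base base seed; trajectory `i` uses stream `seed_base + i`.
#' @param init integer initial state shared by all trajectories.
#' @param hist_breaks number of bins per axis of the growth-vs-intermediate
#'   histogram (log-spaced on the intermediate axis).
#' @param keep_samples keep per-sample series for the 2-D histogram.
#' @return object of class `ensemble_summary`.
#' @export
run_ensemble <- function(spec, n_traj = 200, t_end = 8000,
                         seed_base = 1L,
                         init = mean_field_init_state(spec),
                         sample_dt = 10, arrest_epsilon = 0.01,
                         hist_breaks = 40, keep_samples = TRUE) {
  stopifnot(n_traj >= 2, t_end > 0)
  init <- init[species_names()]
  seeds <- seed_base + seq_len(n_traj)
  raw <- .ssa_run(spec, as.numeric(init), t_end, sample_dt,
                  as.numeric(seeds), arrest_epsilon, keep_samples)
  gr <- raw$growth_avg
  corr <- vapply(seq_along(species_names()), function(i) {
    v <- raw$avg[, i]
    if (stats::sd(v) == 0 || stats::sd(gr) == 0) return(NA_real_)
    stats::cor(v, gr)
  }, numeric(1))
  names(corr) <- species_names()
  hist2d <- NULL
  if (keep_samples) {
    gs <- as.vector(raw$samp_growth)
    is <- as.vector(raw$samp_I)
    gx <- seq(0, max(gs, spec$k_g * 1e-3), length.out = hist_breaks + 1L)
    # log-spaced intermediate-count bins with unit bins at 0 and 1 so the
    # small-integer support of the starved mode stays visible
    iy <- sort(unique(c(-0.5, 0.5,
                        exp(seq(log(1.5), log(max(is, 10) + 1),
                                length.out = hist_breaks - 1L)))))
    cg <- cut(gs, breaks = gx, include.lowest = TRUE)
    ci <- cut(is, breaks = iy, include.lowest = TRUE)
    hist2d <- list(growth_breaks = gx, i_breaks = iy,
                   counts = table(growth = cg, intermediate = ci))
  }
  traj <- data.frame(seed = seeds, growth_avg = gr,
                     growth_final = raw$growth_final,
                     I_final = raw$final[, "I"],
                     arrest = raw$arrest == 1L,
                     n_events = raw$n_events)
  traj <- cbind(traj, as.data.frame(raw$avg))
  structure(
    list(
      n_traj = n_traj, t_end = t_end, seed_base = seed_base,
      spec = spec,
      mean_growth = mean(gr),
      se_growth = stats::sd(gr) / sqrt(n_traj),
      correlations = corr,
      arrest_fraction = mean(raw$arrest == 1L),
      hist2d = hist2d,
      trajectories = traj,
      species_avg = colMeans(raw$avg),
      species_final = colMeans(raw$final),
      init = init,
      rng = list(kind = "xoshiro256+ per-trajectory streams",
                 seeds = range(seeds))
    ),
    class = "ensemble_summary"
  )
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("SSA ensemble: %d trajectories x %g s (k_im = %g)\n",
              x$n_traj, x$t_end, x$spec$k_im))
  cat(sprintf("  mean growth rate %.4g +/- %.2g /s; arrested fraction %.3f\n",
              x$mean_growth, x$se_growth, x$arrest_fraction))
  invisible(x)
}

#' Fraction of arrested trajectories in an ensemble
#'
#' A trajectory counts as toxically growth-arrested when its instantaneous
#' growth rate at the end of the run is below `arrest_epsilon * k_g` AND
#' the intermediate metabolite has crossed the toxicity threshold
#' (`I > theta * omega`); the second condition distinguishes runaway
#' metabolite buildup from simple starvation, where growth is also near
#' zero but the intermediate stays low.  The fraction increases with the
#' metabolite production rate and approaches 1 once production capacity
#' deterministically exceeds consumption capacity.
#'
#' @param ensemble an [run_ensemble()] result.
#' @param arrest_epsilon optional stricter/looser criterion re-applied to
#'   the stored final growth rates and intermediate counts.
#' @return fraction in \[0, 1\].
#' @export
arrest_fraction <- function(ensemble, arrest_epsilon = NULL) {
  stopifnot(inherits(ensemble, "ensemble_summary"))
  if (is.null(arrest_epsilon)) return(ensemble$arrest_fraction)
  sp <- ensemble$spec
  mean(ensemble$trajectories$growth_final < arrest_epsilon * sp$k_g &
         ensemble$trajectories$I_final > sp$theta * sp$omega)
}

#' Sweep the ensemble over a ladder of rate constants
#'
#' Runs [run_ensemble()] at each value of one control constant (typically
#' the import constant `k_im` or the transcription constant `k_tA`) and
#' tabulates mean growth, its standard error, the arrested fraction, and
#' the species-growth correlations.
#'
#' @param values ladder of values for `param`.
#' @param param name of the spec constant to vary.
#' @param spec template [build_reaction_system()] spec.
#' @param ... passed to [run_ensemble()].
#' @return data frame, one row per ladder value, with an `ensembles`
#'   attribute holding the full summaries.
#' @export
ensemble_sweep <- function(values, param = "k_im",
                           spec = build_reaction_system(), ...) {
  stopifnot(param %in% names(spec))
  ens <- lapply(values, function(v) {
    sp <- spec
    sp[[param]] <- v
    run_ensemble(sp, ...)
  })
  out <- data.frame(
    value = values,
    mean_growth = vapply(ens, `[[`, numeric(1), "mean_growth"),
    se_growth = vapply(ens, `[[`, numeric(1), "se_growth"),
    arrest_fraction = vapply(ens, `[[`, numeric(1), "arrest_fraction"),
    corr_A = vapply(ens, function(e) e$correlations[["A"]], numeric(1)),
    corr_B = vapply(ens, function(e) e$correlations[["B"]], numeric(1)),
    corr_I = vapply(ens, function(e) e$correlations[["I"]], numeric(1))
  )
  names(out)[1] <- param
  attr(out, "ensembles") <- ens
  out
}
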