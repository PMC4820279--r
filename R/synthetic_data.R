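# Seeded generators producing measurement-like tables with the statistical
# structure the inference stages assume, each carrying its ground truth in
# the "truth" attribute.  All randomness flows through R's RNG under a
# locally scoped seed, so a generator call never disturbs the caller's RNG
# state.

with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a two-subpopulation flow-cytometry sample
#'
#' Per-event fluorescence is drawn from a mixture: with probability
#' `arrest_fraction` an event comes from the high-fluorescence arrested
#' subpopulation (lognormal with log-mean `mu_arr`), otherwise from the
#' growing subpopulation (lognormal `mu`); forward and side scatter are
#' independent Gaussians.  Emulates a constitutive growth-rate reporter:
#' arrested cells accumulate reporter and sit in the right tail, so a
#' growing arrested fraction raises the CV, skewness and excess kurtosis
#' of the fluorescence distribution.
#'
#' @param n_events events to draw.
#' @param arrest_fraction mixture weight of the arrested subpopulation.
#' @param mu,sigma log-mean and log-SD of growing-cell fluorescence (AU).
#' @param mu_arr,sigma_arr log-mean and log-SD of arrested-cell
#'   fluorescence.
#' @param scatter_mean,scatter_sd Gaussian scatter parameters (both
#'   channels).
#' @param seed integer seed; the same seed reproduces the same events.
#' @return data frame with columns `fl`, `fsc`, `ssc` and logical
#'   `arrested`; attribute `truth` records the configuration.
#' @export
gen_flow_sample <- function(n_events = 10000, arrest_fraction = 0,
                            mu = log(200), sigma = 0.35,
                            mu_arr = log(1200), sigma_arr = 0.35,
                            scatter_mean = 5e4, scatter_sd = 5e3,
                            seed = 1L) {
  stopifnot(n_events > 0, arrest_fraction >= 0, arrest_fraction <= 1,
            sigma > 0, sigma_arr > 0, scatter_sd > 0)
  with_local_seed(seed, {
    arrested <- stats::runif(n_events) < arrest_fraction
    fl <- ifelse(arrested,
                 stats::rlnorm(n_events, mu_arr, sigma_arr),
                 stats::rlnorm(n_events, mu, sigma))
    out <- data.frame(
      fl = fl,
      fsc = stats::rnorm(n_events, scatter_mean, scatter_sd),
      ssc = stats::rnorm(n_events, scatter_mean, scatter_sd),
      arrested = arrested
    )
    attr(out, "truth") <- list(
      seed = seed, n_events = n_events, arrest_fraction = arrest_fraction,
      mu = mu, sigma = sigma, mu_arr = mu_arr, sigma_arr = sigma_arr,
      scatter_mean = scatter_mean, scatter_sd = scatter_sd
    )
    out
  })
}

#' Generate replicate OD growth curves
#'
#' Logistic growth `N(t) = K / (1 + (K/N0 - 1) exp(-r t))` plus a blank
#' offset, with multiplicative lognormal noise per reading.  The
#' early-exponential rate `r` is the stored ground truth recovered by
#' [fit_growth_rate()].
#'
#' @param rate true exponential growth rate (h^-1).
#' @param n0 inoculum OD.
#' @param capacity carrying capacity (OD).
#' @param blank blank (background) OD added to every reading.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param times reading times (h).
#' @param replicates number of replicate curves (distinct sub-seeds).
#' @param seed integer seed.
#' @return data frame with columns `time`, `od`, `blank`, `replicate`;
#'   attribute `truth`.
#' @export
gen_od_curves <- function(rate = 0.6, n0 = 0.001, capacity = 0.8,
                          blank = 0.002, noise_cv = 0.01,
                          times = seq(0, 24, by = 1 / 30),
                          replicates = 3, seed = 1L) {
  stopifnot(rate >= 0, n0 > 0, capacity >= n0, noise_cv >= 0,
            replicates >= 1)
  with_local_seed(seed, {
    curves <- lapply(seq_len(replicates), function(r) {
      det <- if (rate == 0) {
        rep(n0, length(times))
      } else {
        capacity / (1 + (capacity / n0 - 1) * exp(-rate * times))
      }
      noise <- if (noise_cv > 0) {
        sd_log <- sqrt(log(1 + noise_cv^2))
        stats::rlnorm(length(times), -sd_log^2 / 2, sd_log)
      } else {
        1
      }
      data.frame(time = times, od = det * noise + blank, blank = blank,
                 replicate = r)
    })
    out <- do.call(rbind, curves)
    attr(out, "truth") <- list(seed = seed, rate = rate, n0 = n0,
                               capacity = capacity, blank = blank,
                               noise_cv = noise_cv,
                               replicates = replicates)
    out
  })
}

#' Generate a biphasic antibiotic kill curve
#'
#' Biexponential decay
#' `N(t) = N0 ((1 - f) exp(-k1 t) + f exp(-k2 t))` sampled with
#' multiplicative lognormal noise; readings below the detection limit are
#' censored (flagged, value set to the limit).  Emulates CFU survival
#' curves in which the fast phase kills normal cells and the slow phase
#' reflects persisters.
#'
#' @param n0 initial CFU/ml.
#' @param k1,k2 fast and slow killing rates (h^-1), `k1 > k2 >= 0`.
#' @param f persister fraction in \[0, 1\].
#' @param noise_cv multiplicative noise CV.
#' @param detection_limit censoring threshold (CFU/ml).
#' @param times sampling times (h).
#' @param replicates replicate curves.
#' @param seed integer seed.
#' @return data frame with columns `time`, `cfu`, `censored`, `replicate`;
#'   attributes `truth` and `detection_limit`.
#' @export
gen_kill_curve <- function(n0 = 5e8, k1 = 1.0, k2 = 0.05, f = 1e-3,
                           noise_cv = 0.05, detection_limit = 100,
                           times = c(0, 1, 2, 3, 4, 6, 8, 12, 16, 20, 24),
                           replicates = 1, seed = 1L) {
  stopifnot(k1 > k2, k2 >= 0, f >= 0, f <= 1, n0 > 0, noise_cv >= 0)
  with_local_seed(seed, {
    rows <- lapply(seq_len(replicates), function(r) {
      det <- n0 * ((1 - f) * exp(-k1 * times) + f * exp(-k2 * times))
      noise <- if (noise_cv > 0) {
        sd_log <- sqrt(log(1 + noise_cv^2))
        stats::rlnorm(length(times), -sd_log^2 / 2, sd_log)
      } else {
        1
      }
      cfu <- det * noise
      cens <- cfu < detection_limit
      cfu[cens] <- detection_limit
      data.frame(time = times, cfu = cfu, censored = cens, replicate = r)
    })
    out <- do.call(rbind, rows)
    attr(out, "truth") <- list(seed = seed, n0 = n0, k1 = k1, k2 = k2,
                               f = f, noise_cv = noise_cv,
                               detection_limit = detection_limit)
    attr(out, "detection_limit") <- detection_limit
    out
  })
}

#' Generate a replicate dose-response table with quadratic mean structure
#'
#' Replicate growth rates `y = a + b x + c x^2 + e`, `e ~ N(0, noise_sd)`,
#' at the configured doses.  With `c < 0` the response has an interior
#' maximum at `-b / (2 c)`, emulating growth-rate dose responses that peak
#' at intermediate substrate concentrations.
#'
#' @param doses dose levels (e.g. lactose mg/ml).
#' @param a,b,c quadratic coefficients of the true mean structure.
#' @param noise_sd replicate noise SD (same units as the response).
#' @param replicates replicates per dose.
#' @param seed integer seed.
#' @return data frame with columns `dose`, `rate`, `replicate`; attribute
#'   `truth` including the true argmax where defined.
#' @export
gen_dose_response <- function(doses = c(0.1, 0.5, 1, 1.5, 2.5, 5, 10,
                                        20, 30, 40, 50),
                              a = 0.45, b = 0.012, c = -0.00024,
                              noise_sd = 0.02, replicates = 3,
                              seed = 1L) {
  stopifnot(length(doses) >= 3, noise_sd >= 0, replicates >= 1)
  with_local_seed(seed, {
    grid <- expand.grid(dose = doses, replicate = seq_len(replicates),
                        KEEP.OUT.ATTRS = FALSE)
    mu <- a + b * grid$dose + c * grid$dose^2
    grid$rate <- mu + stats::rnorm(nrow(grid), 0, noise_sd)
    out <- grid[, c("dose", "rate", "replicate")]
    attr(out, "truth") <- list(
      seed = seed, a = a, b = b, c = c, noise_sd = noise_sd,
      replicates = replicates,
      argmax = if (c < 0) -b / (2 * c) else NA_real_
    )
    out
  })
}

#' Generate matched rate-fluorescence condition pairs
#'
#' Condition-level data for the heterogeneous-growth fluorescence fit:
#' population growth rates over a dose range and the mean fluorescence
#' predicted by [predict_mean_fluorescence()] under the chosen mode, with
#' multiplicative observation noise.
#'
#' @param growth_rates population growth rates per condition (h^-1).
#' @param model a [fluorescence_model()] carrying calibration constants
#'   and, for the heterogeneous mode, the true `p_arr` and `s`.
#' @param mode `"uniform"` or `"heterogeneous"` ground truth.
#' @param noise_cv multiplicative noise CV on the mean fluorescence.
#' @param seed integer seed.
#' @return data frame with columns `growth_rate`, `fluorescence`;
#'   attribute `truth`.
#' @export
gen_fluorescence_pairs <- function(growth_rates = seq(0.15, 0.7,
                                                      length.out = 10),
                                   model = fluorescence_model(
                                     a = 50, b = 120, p_arr = 1500,
                                     s = 0.12),
                                   mode = c("heterogeneous", "uniform"),
                                   noise_cv = 0.02, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(all(growth_rates > 0), noise_cv >= 0)
  with_local_seed(seed, {
    f <- predict_mean_fluorescence(growth_rates, model, mode)
    if (noise_cv > 0) {
      sd_log <- sqrt(log(1 + noise_cv^2))
      f <- f * stats::rlnorm(length(f), -sd_log^2 / 2, sd_log)
    }
    out <- data.frame(growth_rate = growth_rates, fluorescence = f)
    attr(out, "truth") <- list(seed = seed, mode = mode,
                               p_arr = model$p_arr, s = model$s,
                               a = model$a, b = model$b,
                               noise_cv = noise_cv)
    out
  })
}
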