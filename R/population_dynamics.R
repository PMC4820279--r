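#' Parameters of the metastable two-compartment population model
#'
#' A growing subpopulation divides at rate `g` (per hour) and switches
#' irreversibly into a non-growing, arrested state at rate `s`.  The
#' switching rate is driven by noise in the ratio of mean pathway fluxes
#' `x = V+/V-`: cells whose fluctuating flux ratio exceeds 1 (consumption
#' saturated) cross into runaway metabolite buildup, so
#' `s = s_max * CDF((x - 1) / sigma_x)` with a standard normal CDF.
#'
#' @param g growth rate of the growing subpopulation (h^-1).
#' @param s_max maximal switching rate (h^-1).
#' @param sigma_x width of the flux-ratio noise distribution.
#' @param x ratio of mean fluxes V+/V-.
#' @param delta demand, used by [metastable_surface()] to set the effective
#'   growth rate through the benefit factor.
#' @return object of class `switching_model_params`.
#' @export
switching_model_params <- function(g = 1, s_max = 1.5, sigma_x = 0.1,
                                   x = 0.5, delta = 0.5) {
  stopifnot(g >= 0, s_max >= 0, sigma_x > 0, x >= 0, delta > 0)
  structure(list(g = g, s_max = s_max, sigma_x = sigma_x, x = x,
                 delta = delta),
            class = "switching_model_params")
}

#' Noise-driven switching rate into growth arrest
#'
#' `s = s_max * Phi((x - 1) / sigma_x)`: the fraction of cells whose
#' fluctuating flux ratio exceeds the saturation point `x = 1` sets the
#' per-hour rate of irreversible switching into the arrested state.
#'
#' @param params a [switching_model_params()] object.
#' @return switching rate (h^-1), nondecreasing in `x`.
#' @export
switching_rate <- function(params) {
  params$s_max * stats::pnorm((params$x - 1) / params$sigma_x)
}

#' Asymptotic growth of a metastable population
#'
#' Two-compartment linear dynamics `Ng' = (g - s) Ng`, `Na' = s Ng` with
#' irreversible switching: the population growth rate is `lambda = g - s`
#' and, for `g > s`, the long-time arrested fraction is `s / g`
#' (`Na/Ng -> s/(g - s)`).  When `g <= s` the population cannot outgrow the
#' losses and `lambda <= 0` is reported (not an error), with arrested
#' fraction 1.
#'
#' @param params a [switching_model_params()] object; the switching rate is
#'   [switching_rate()] of `params` unless `s` is supplied.
#' @param s optional explicit switching rate (h^-1), overriding the
#'   noise-driven form.
#' @return list with `lambda` (h^-1) and `arrested_fraction`.
#' @export
metastable_growth_rate <- function(params, s = NULL) {
  if (is.null(s)) s <- switching_rate(params)
  g <- params$g
  lambda <- g - s
  frac <- if (g > s) s / g else 1
  list(lambda = lambda, arrested_fraction = frac)
}

#' Numerically integrated metastable population dynamics
#'
#' Integrates the two-compartment model over a finite horizon and extracts
#' the realized log-slope of the growing compartment and the arrested
#' fraction at the horizon.  Serves as an independent check on the closed
#' forms of [metastable_growth_rate()].
#'
#' @inheritParams metastable_growth_rate
#' @param horizon integration time (h).
#' @return list with `lambda` (log-slope of Ng over the final half of the
#'   horizon) and `arrested_fraction` at the horizon.
#' @export
integrate_metastable <- function(params, s = NULL, horizon = 200) {
  if (is.null(s)) s <- switching_rate(params)
  g <- params$g
  rhs <- function(t, y, p) {
    list(c(ng = (g - s) * y[["ng"]], na = s * y[["ng"]]))
  }
  times <- seq(0, horizon, length.out = 201L)
  # work on a log-safe scale: Ng is exactly exponential, Na accumulates
  sol <- deSolve::ode(c(ng = 1, na = 0), times, rhs, NULL,
                      rtol = 1e-10, atol = 1e-12)
  half <- times >= horizon / 2
  lam <- stats::coef(stats::lm(log(sol[half, "ng"]) ~ times[half]))[[2]]
  tot <- sol[nrow(sol), "ng"] + sol[nrow(sol), "na"]
  list(lambda = lam, arrested_fraction = sol[nrow(sol), "na"] / tot)
}

#' Fitness surface of the metastable model over demand and flux ratio
#'
#' Reconstructs the population growth-rate surface over demand `delta` and
#' flux ratio `x = V+/V-`: the growing subpopulation's rate is
#' `g = g_max * f_gr(V-, delta)` with `V- = min(V+, vmax)` (consumption
#' saturates at the maximal enzyme activity), and the switching rate is the
#' noise-driven [switching_rate()].  Growth rates are reported normalized
#' by `g_max`; negative values mark populations that shrink.
#'
#' @param delta_grid,x_grid axis vectors (demand in units of `vmax`; flux
#'   ratio dimensionless).
#' @param g_max maximal division rate (h^-1).
#' @param s_max,sigma_x switching-model constants.
#' @param vmax maximal consumption flux (sets the scale of `V+ = x * vmax`).
#' @return data frame with columns `delta`, `x`, `lambda_normalized`,
#'   `arrested_fraction`.
#' @export
metastable_surface <- function(delta_grid, x_grid, g_max = 1, s_max = 1.5,
                               sigma_x = 0.1, vmax = 1) {
  stopifnot(length(delta_grid) > 0, length(x_grid) > 0,
            all(delta_grid > 0), all(x_grid >= 0))
  grid <- expand.grid(delta = delta_grid, x = x_grid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- mapply(function(d, x) {
    v_minus <- min(x * vmax, vmax)
    g <- g_max * benefit_factor(v_minus, d)
    p <- switching_model_params(g = g, s_max = s_max, sigma_x = sigma_x,
                                x = x, delta = d)
    out <- metastable_growth_rate(p)
    c(out$lambda / g_max, out$arrested_fraction)
  }, grid$delta, grid$x)
  grid$lambda_normalized <- res[1, ]
  grid$arrested_fraction <- res[2, ]
  grid
}

#' Timescale parameters of the four-state growth framework
#'
#' Characteristic switching timescales between four states of bacterial
#' growth: balanced exponential growth (rate `g`), a transient shifted
#' state with changing growth rate (`g_hat`), viable growth arrest, and
#' death.  Cells leave balanced growth on timescale `tau1`, return on
#' `tau_m1`, fall from the shifted state into arrest on `tau2`, resume
#' growth on `tau_m2`, and die from arrest on `tau3`.
#'
#' @param tau1,tau_m1,tau2,tau_m2,tau3 positive timescales (h).
#' @param g balanced growth rate (h^-1).
#' @param g_hat growth rate in the shifted state (h^-1); free in sign of
#'   its deviation from `g`.
#' @return object of class `timescale_params`.
#' @export
timescale_params <- function(tau1 = 10, tau_m1 = 10, tau2 = 10,
                             tau_m2 = 10, tau3 = 10, g = 1, g_hat = 0.5) {
  stopifnot(tau1 > 0, tau_m1 > 0, tau2 > 0, tau_m2 > 0, tau3 > 0,
            g >= 0)
  structure(list(tau1 = tau1, tau_m1 = tau_m1, tau2 = tau2,
                 tau_m2 = tau_m2, tau3 = tau3, g = g, g_hat = g_hat),
            class = "timescale_params")
}

#' Population growth rate of the four-state timescale framework
#'
#' Linear dynamics on states (balanced, shifted, arrested, dead) with
#' per-state growth (g, g_hat, 0, 0) and transition rates `1/tau1`
#' (balanced to shifted), `1/tau_m1` (shifted to balanced), `1/tau2`
#' (shifted to arrested), `1/tau_m2` (arrested to balanced) and `1/tau3`
#' (arrested to dead; absorbing).  The asymptotic population growth rate is
#' the leading eigenvalue of the growth + transition matrix restricted to
#' the live states; occupancy is the corresponding eigenvector normalized
#' over the live states.
#'
#' Known limits: `tau1 -> Inf` (or `tau_m1 -> 0`) recovers classical
#' balanced growth `lambda = g`; `tau2 -> 0` with `tau_m2, tau3 -> Inf`
#' recovers the metastable two-compartment model with `s = 1/tau1`.
#'
#' @param params a [timescale_params()] object.
#' @return list with `lambda` (h^-1) and `occupancy` (named fractions over
#'   balanced/shifted/arrested, summing to 1).
#' @export
framework_growth_rate <- function(params) {
  with(params, {
    A <- matrix(c(
      g - 1 / tau1,  1 / tau_m1,                 1 / tau_m2,
      1 / tau1,      g_hat - 1 / tau_m1 - 1 / tau2, 0,
      0,             1 / tau2,                   -1 / tau_m2 - 1 / tau3
    ), nrow = 3, byrow = TRUE,
    dimnames = list(c("balanced", "shifted", "arrested"), NULL))
    e <- eigen(A)
    i <- which.max(Re(e$values))
    lambda <- Re(e$values[i])
    v <- abs(Re(e$vectors[, i]))
    list(lambda = lambda,
         occupancy = stats::setNames(v / sum(v), rownames(A)))
  })
}

#' Long-horizon integration of the four-state framework
#'
#' Integrates the linear four-state system (including the absorbing dead
#' state) and extracts the realized log-slope of the total live
#' population; cross-checks the eigenvalue route of
#' [framework_growth_rate()].
#'
#' @inheritParams framework_growth_rate
#' @param horizon integration time (h).
#' @return realized asymptotic growth rate (h^-1).
#' @export
integrate_framework <- function(params, horizon = 400) {
  with(params, {
    rhs <- function(t, y, p) {
      nb <- y[[1]]; ns <- y[[2]]; na <- y[[3]]
      list(c(
        g * nb - nb / tau1 + ns / tau_m1 + na / tau_m2,
        g_hat * ns + nb / tau1 - ns / tau_m1 - ns / tau2,
        ns / tau2 - na / tau_m2 - na / tau3,
        na / tau3
      ))
    }
    times <- seq(0, horizon, length.out = 401L)
    sol <- deSolve::ode(c(1, 0, 0, 0), times, rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
    live <- rowSums(sol[, 2:4])
    half <- times >= horizon / 2
    stats::coef(stats::lm(log(live[half]) ~ times[half]))[[2]]
  })
}
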