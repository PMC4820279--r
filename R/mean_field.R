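#' Parameters of the deterministic two-enzyme pathway model
#'
#' Bundles the constants of the cost/benefit pathway model in which an
#' upstream enzyme A produces an intracellular metabolite M at flux `v_plus`
#' and a downstream Michaelis-Menten enzyme B consumes it at flux
#' `V-(M) = vmax_b * M / (km_b + M)`.  Growth is stimulated by the
#' consumption flux relative to a demand `delta` (benefit factor `f_gr`) and
#' inhibited by a toxic species relative to a threshold `theta` (toxicity
#' factor `f_tox`).  The toxic species is either the metabolite itself
#' (`toxicity_variant = "substrate"`), a byproduct produced in proportion to
#' the production flux (`"byproduct"`, e.g. symported protons from a
#' permease), or absent (`"none"`).
#'
#' All quantities are in molecules per unit cell volume and per second;
#' the cell volume is taken as the unit of volume.
#'
#' @param v_plus metabolite production flux (molecules vol^-1 s^-1).
#' @param delta demand: consumption flux at which the growth benefit
#'   saturates (same units as a flux).
#' @param theta toxicity threshold (molecules vol^-1); half-inhibition point
#'   of `f_tox`.
#' @param vmax_b maximal consumption rate of enzyme B.
#' @param km_b Michaelis constant of enzyme B (molecules vol^-1).
#' @param g_max maximum growth rate (s^-1).
#' @param toxicity_variant one of `"substrate"`, `"byproduct"`, `"none"`.
#' @param benefit_form one of `"piecewise_linear"` (`min(flux/delta, 1)`,
#'   sharp starvation/satiation border) or `"michaelis_menten"`
#'   (saturating, blurred border).
#' @param byproduct_yield toxin molecules produced per imported metabolite
#'   (byproduct variant only).
#' @param hill_tox Hill exponent of the toxicity function.
#' @return An object of class `pathway_params`.
#' @examples
#' p <- pathway_params(v_plus = 0.5, delta = 0.5)
#' solve_steady_state(p)
#' @export
pathway_params <- function(v_plus = 0.5,
                           delta = 0.5,
                           theta = 100,
                           vmax_b = 1,
                           km_b = 1,
                           g_max = 6e-4,
                           toxicity_variant = c("substrate", "byproduct", "none"),
                           benefit_form = c("piecewise_linear", "michaelis_menten"),
                           byproduct_yield = 1,
                           hill_tox = 1) {
  toxicity_variant <- match.arg(toxicity_variant)
  benefit_form <- match.arg(benefit_form)
  stopifnot(
    is.numeric(v_plus), length(v_plus) == 1L, v_plus >= 0,
    is.numeric(delta), length(delta) == 1L, delta > 0,
    is.numeric(vmax_b), vmax_b >= 0,
    is.numeric(km_b), km_b > 0,
    is.numeric(g_max), g_max >= 0,
    is.numeric(byproduct_yield), byproduct_yield >= 0,
    is.numeric(hill_tox), hill_tox > 0
  )
  if (toxicity_variant != "none" && !(is.numeric(theta) && theta > 0)) {
    stop("`theta` must be > 0 unless toxicity_variant = \"none\"")
  }
  structure(
    list(
      v_plus = v_plus, delta = delta, theta = theta,
      vmax_b = vmax_b, km_b = km_b, g_max = g_max,
      toxicity_variant = toxicity_variant,
      benefit_form = benefit_form,
      byproduct_yield = byproduct_yield,
      hill_tox = hill_tox
    ),
    class = "pathway_params"
  )
}

#' @export
print.pathway_params <- function(x, ...) {
  cat("Two-enzyme pathway model parameters\n")
  cat(sprintf("  V+ = %g, delta = %g, theta = %g\n", x$v_plus, x$delta, x$theta))
  cat(sprintf("  Vmax[B] = %g, Km[B] = %g, g_max = %g /s\n",
              x$vmax_b, x$km_b, x$g_max))
  cat(sprintf("  toxicity: %s (yield %g, Hill %g); benefit: %s\n",
              x$toxicity_variant, x$byproduct_yield, x$hill_tox,
              x$benefit_form))
  invisible(x)
}

#' Growth benefit factor
#'
#' Fraction of the maximal growth rate supported by a given pathway
#' consumption flux, relative to the demand `delta`.
#'
#' @param consumption_flux nonnegative consumption flux (vectorised).
#' @param delta demand (> 0).
#' @param form `"piecewise_linear"` gives `min(flux/delta, 1)`;
#'   `"michaelis_menten"` gives `(flux/delta) / (1 + flux/delta)`.
#' @return benefit factor in \[0, 1\], nondecreasing in the flux.
#' @export
benefit_factor <- function(consumption_flux, delta,
                           form = c("piecewise_linear", "michaelis_menten")) {
  form <- match.arg(form)
  if (any(consumption_flux < 0) || any(is.na(consumption_flux))) {
    stop("`consumption_flux` must be nonnegative")
  }
  if (!is.numeric(delta) || any(delta <= 0)) stop("`delta` must be > 0")
  r <- consumption_flux / delta
  switch(form,
    piecewise_linear = pmin(r, 1),
    michaelis_menten = r / (1 + r)
  )
}

#' Toxicity factor
#'
#' Hill-type growth inhibition by a toxic species: `1 / (1 + (x/theta)^h)`.
#' Equals 1 with no toxin and 1/2 at the threshold.
#'
#' @param toxic_level nonnegative toxin level (vectorised).
#' @param theta threshold (> 0).
#' @param hill Hill exponent (> 0).
#' @return toxicity factor in \[0, 1\], strictly decreasing in `toxic_level`.
#' @export
toxicity_factor <- function(toxic_level, theta, hill = 1) {
  if (any(toxic_level < 0) || any(is.na(toxic_level))) {
    stop("`toxic_level` must be nonnegative")
  }
  if (!is.numeric(theta) || any(theta <= 0)) stop("`theta` must be > 0")
  if (!is.numeric(hill) || any(hill <= 0)) stop("`hill` must be > 0")
  1 / (1 + (toxic_level / theta)^hill)
}

# Michaelis-Menten consumption flux of enzyme B.
consumption_flux <- function(m, params) {
  params$vmax_b * m / (params$km_b + m)
}

# Instantaneous growth rate at metabolite m (and toxin t for the byproduct
# variant): g = g_max * f_gr(V-(m)) * f_tox(toxic species).
growth_rate_at <- function(m, t, params) {
  vm <- consumption_flux(m, params)
  fgr <- benefit_factor(vm, params$delta, params$benefit_form)
  ftox <- switch(params$toxicity_variant,
    substrate = toxicity_factor(m, params$theta, params$hill_tox),
    byproduct = toxicity_factor(t, params$theta, params$hill_tox),
    none = 1
  )
  params$g_max * fgr * ftox
}

#' Right-hand side of the deterministic pathway model
#'
#' Time derivatives of the metabolite `m` (and, for the byproduct toxicity
#' variant, the toxin `t`):
#' `dM/dt = V+ - V-(M) - g * M`, with `V-(M) = vmax_b M / (km_b + M)` and
#' `g = g_max * f_gr(V-(M)) * f_tox`.  In the byproduct variant
#' `dT/dt = yield * V+ - g * T` and `f_tox` acts on T; in the substrate
#' variant `f_tox` acts on M; with `toxicity_variant = "none"` `f_tox = 1`.
#'
#' @param state list or named numeric with elements `m` and (byproduct
#'   variant) `t`.
#' @param params a [pathway_params()] object.
#' @return named numeric vector of derivatives (`m`, and `t` when present),
#'   with attribute `growth_rate` giving the instantaneous growth rate.
#' @export
pathway_rhs <- function(state, params) {
  m <- state[["m"]]
  tt <- if (params$toxicity_variant == "byproduct") state[["t"]] else 0
  stopifnot(m >= 0, tt >= 0)
  g <- growth_rate_at(m, tt, params)
  dm <- params$v_plus - consumption_flux(m, params) - g * m
  out <- c(m = dm)
  if (params$toxicity_variant == "byproduct") {
    out <- c(out, t = params$byproduct_yield * params$v_plus - g * tt)
  }
  attr(out, "growth_rate") <- g
  out
}

# deSolve-compatible wrapper.
rhs_desolve <- function(t, y, parms) {
  st <- as.list(y)
  names(st) <- names(y)
  list(as.numeric(pathway_rhs(st, parms)))
}

#' Solve for the low-metabolite steady state of the pathway model
#'
#' Finds the smallest nonnegative stable root of the model right-hand side
#' reachable from `M = 0` ("acclimatized" initial conditions), or reports
#' that none exists below `m_max` (runaway metabolite buildup; the
#' non-growing surfeit regime).  For the byproduct variant the toxin
#' equation is solved self-consistently with the metabolite equation.
#'
#' @param params a [pathway_params()] object.
#' @param m_max metabolite bound above which the search declares runaway.
#' @return A list with elements `m`, `t` (toxin; 0 for other variants) and
#'   `growth_rate`, or `NULL` when no admissible steady state exists.
#' @details The root search brackets sign changes of `dM/dt` on a log-spaced
#'   grid in `[0, m_max]` and polishes them with [stats::uniroot()]
#'   (residual tolerance `1e-9 * max(v_plus, vmax_b)`); stability is the
#'   local slope test `d(dM/dt)/dM < 0`.  For the byproduct variant the
#'   effective toxicity at metabolite `m` solves the scalar self-consistency
#'   relation `g * T = yield * V+` for the quasi-stationary toxin.
#' @export
solve_steady_state <- function(params, m_max = 1e6 * max(params$theta, 1)) {
  f <- steady_residual_fun(params)
  tol <- 1e-9 * max(params$v_plus, params$vmax_b, 1e-12)
  if (params$v_plus == 0) {
    return(steady_state_at(0, params))
  }
  # log-spaced bracket grid from below km_b up to m_max
  lo <- min(params$km_b, params$theta, 1) * 1e-6
  grid <- c(0, exp(seq(log(lo), log(m_max), length.out = 400L)))
  fv <- vapply(grid, f, numeric(1))
  roots <- c()
  for (i in seq_len(length(grid) - 1L)) {
    if (is.na(fv[i]) || is.na(fv[i + 1L])) next
    if (fv[i] == 0) roots <- c(roots, grid[i])
    if (fv[i] > 0 && fv[i + 1L] < 0) {
      # dM/dt falls through zero: stable root in this bracket
      r <- stats::uniroot(f, c(grid[i], grid[i + 1L]), tol = tol)$root
      roots <- c(roots, r)
    }
  }
  if (length(roots) == 0L) return(NULL)
  m_star <- min(roots)
  if (abs(f(m_star)) > max(tol, 1e-6 * max(abs(params$v_plus), 1))) {
    stop("steady-state residual did not converge: |dM/dt| = ",
         format(abs(f(m_star))), " at M = ", format(m_star))
  }
  # stability: slope of dM/dt at the root must be negative
  h <- max(m_star, 1) * 1e-6
  slope <- (f(m_star + h) - f(max(m_star - h, 0))) / (h + min(m_star, h))
  if (!is.finite(slope) || slope >= 0) return(NULL)
  steady_state_at(m_star, params)
}

# dM/dt as a function of m alone, with the byproduct toxin eliminated by
# quasi-steady-state self-consistency (g*T = yield*V+ gives
# f_tox = 1 - c with c = yield*V+ / (g_max * f_gr * theta) for Hill 1;
# for general Hill exponents the scalar relation is solved numerically).
steady_residual_fun <- function(params) {
  force(params)
  function(m) {
    vm <- consumption_flux(m, params)
    fgr <- benefit_factor(vm, params$delta, params$benefit_form)
    ftox <- switch(params$toxicity_variant,
      substrate = toxicity_factor(m, params$theta, params$hill_tox),
      none = 1,
      byproduct = byproduct_ftox(fgr, params)
    )
    if (is.na(ftox)) return(NA_real_)  # no self-consistent toxin level
    g <- params$g_max * fgr * ftox
    params$v_plus - vm - g * m
  }
}

# Self-consistent f_tox for the byproduct variant at fixed f_gr:
# T = yield*V+ / g with g = g_max * f_gr * f_tox(T).  Returns NA when no
# positive solution exists (toxin runaway).
byproduct_ftox <- function(fgr, params) {
  if (params$v_plus == 0) return(1)
  if (fgr <= 0) return(NA_real_)
  cc <- params$byproduct_yield * params$v_plus /
    (params$g_max * fgr * params$theta)
  if (params$hill_tox == 1) {
    u <- 1 - cc
    return(if (u > 0) u else NA_real_)
  }
  # general Hill: solve u = 1/(1 + (cc/u)^h) for u in (0, 1]
  h <- params$hill_tox
  fn <- function(u) u * (1 + (cc / u)^h) - 1
  # fn(1) >= 0 iff a fixed point may exist below 1; search for sign change
  us <- exp(seq(log(1e-12), 0, length.out = 200L))
  vals <- vapply(us, fn, numeric(1))
  idx <- which(vals[-length(vals)] * vals[-1] < 0)
  if (length(idx) == 0L) {
    return(if (abs(fn(1)) < 1e-12) 1 else NA_real_)
  }
  # largest root = stable quasi-steady toxin branch
  i <- max(idx)
  stats::uniroot(fn, c(us[i], us[i + 1L]), tol = 1e-12)$root
}

steady_state_at <- function(m, params) {
  m <- unname(m)
  tt <- 0
  if (params$toxicity_variant == "byproduct" && params$v_plus > 0) {
    vm <- consumption_flux(m, params)
    fgr <- benefit_factor(vm, params$delta, params$benefit_form)
    ftox <- byproduct_ftox(fgr, params)
    g <- params$g_max * fgr * ftox
    tt <- if (g > 0) params$byproduct_yield * params$v_plus / g else Inf
  }
  list(m = m, t = tt, growth_rate = growth_rate_at(m, tt, params))
}

#' Brute-force steady-state existence oracle
#'
#' Integrates the model from `M = 0` (and `T = 0`) for a long horizon and
#' classifies the trajectory as convergent (returns the endpoint state) or
#' runaway (returns `NULL`): runaway is declared when M (or the toxin)
#' exceeds `m_max` with a positive derivative sustained over the final 10%
#' of the horizon.  Used as an independent check on [solve_steady_state()].
#'
#' @inheritParams solve_steady_state
#' @param t_long integration horizon (s); default `1e5 / g_max`.
#' @return list like [solve_steady_state()], or `NULL` on runaway.
#' @export
integrate_to_steady_state <- function(params,
                                      m_max = 1e6 * max(params$theta, 1),
                                      t_long = 1e5 / max(params$g_max, 1e-12)) {
  y0 <- c(m = 0)
  if (params$toxicity_variant == "byproduct") y0 <- c(y0, t = 0)
  horizon <- t_long
  for (attempt in 1:2) {
    times <- seq(0, horizon, length.out = 400L)
    sol <- deSolve::ode(y0, times, rhs_desolve, params,
                        method = "lsoda", rtol = 1e-8, atol = 1e-10)
    m_end <- sol[nrow(sol), "m"]
    tox_end <- if (params$toxicity_variant == "byproduct") {
      sol[nrow(sol), "t"]
    } else {
      m_end
    }
    last <- stats::setNames(as.list(as.numeric(sol[nrow(sol), -1])),
                            colnames(sol)[-1])
    d_end <- pathway_rhs(last, params)
    dm_end <- d_end[["m"]]
    dtox_end <- if (params$toxicity_variant == "byproduct") d_end[["t"]]
                else dm_end
    # runaway: past the bound and still climbing, sustained over the tail
    tail_idx <- times >= 0.9 * horizon
    tox_tail <- if (params$toxicity_variant == "byproduct") {
      sol[tail_idx, "t"]
    } else {
      sol[tail_idx, "m"]
    }
    if (max(m_end, tox_end) > m_max &&
        max(dm_end, dtox_end) > 0 &&
        !is.unsorted(tox_tail)) {
      return(NULL)
    }
    scale <- max(abs(params$v_plus), abs(params$vmax_b), 1e-12)
    if (max(abs(dm_end), abs(dtox_end)) < 1e-6 * scale) {
      return(steady_state_at(m_end, params))
    }
    horizon <- horizon * 10  # not converged, not runaway: integrate longer
  }
  if (max(dm_end, dtox_end) > 0) return(NULL)
  steady_state_at(m_end, params)
}

#' Classify the growth regime of a parameter set
#'
#' Regime I (starvation): a steady state exists but the benefit factor is
#' below `starvation_cutoff`.  Regime II (satiation): a steady state exists
#' with benefit at or above the cutoff.  Regime III (surfeit): no steady
#' state exists and the metabolite (or toxin) builds up without bound,
#' stalling growth.
#'
#' With the piecewise-linear benefit the I/II border is sharp and the test
#' is `f_gr < 1`; with the Michaelis-Menten benefit the border is blurred
#' and the default cutoff 0.9 is used.
#'
#' @inheritParams solve_steady_state
#' @param starvation_cutoff benefit-factor cutoff separating regimes I/II.
#' @return one of `"I"`, `"II"`, `"III"`.
#' @export
classify_regime <- function(params, starvation_cutoff = 0.9,
                            m_max = 1e6 * max(params$theta, 1)) {
  stopifnot(starvation_cutoff > 0, starvation_cutoff <= 1)
  ss <- solve_steady_state(params, m_max = m_max)
  if (is.null(ss)) return("III")
  fgr <- benefit_factor(consumption_flux(ss$m, params), params$delta,
                        params$benefit_form)
  cutoff <- if (params$benefit_form == "piecewise_linear") {
    1 - 1e-9
  } else {
    starvation_cutoff
  }
  if (fgr < cutoff) "I" else "II"
}

#' Regime phase diagram over production flux and demand
#'
#' Classifies every grid point of (`v_plus`, `delta`) and records the
#' normalized growth rate `g(M*)/g_max` (0 in regime III).
#'
#' @param v_plus_grid,delta_grid positive, monotone increasing axis vectors.
#' @param params template [pathway_params()]; `v_plus` and `delta` are
#'   overridden point-wise.
#' @param starvation_cutoff passed to [classify_regime()].
#' @return object of class `regime_phase_map`: list with the axis vectors,
#'   a character matrix `regime` and numeric matrix `norm_growth`
#'   (rows index `v_plus`, columns `delta`), also available as a tidy
#'   data frame via [as.data.frame()].
#' @export
phase_diagram <- function(v_plus_grid, delta_grid, params = pathway_params(),
                          starvation_cutoff = 0.9) {
  if (length(v_plus_grid) == 0L || length(delta_grid) == 0L) {
    stop("phase diagram grid must be non-empty")
  }
  stopifnot(all(v_plus_grid >= 0), all(delta_grid > 0),
            !is.unsorted(v_plus_grid), !is.unsorted(delta_grid))
  nr <- length(v_plus_grid); nc <- length(delta_grid)
  regime <- matrix(NA_character_, nr, nc)
  ng <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      p <- params
      p$v_plus <- v_plus_grid[i]
      p$delta <- delta_grid[j]
      ss <- solve_steady_state(p)
      if (is.null(ss)) {
        regime[i, j] <- "III"
        ng[i, j] <- 0
      } else {
        fgr <- benefit_factor(consumption_flux(ss$m, p), p$delta,
                              p$benefit_form)
        cutoff <- if (p$benefit_form == "piecewise_linear") 1 - 1e-9
                  else starvation_cutoff
        regime[i, j] <- if (fgr < cutoff) "I" else "II"
        ng[i, j] <- ss$growth_rate / p$g_max
      }
    }
  }
  structure(
    list(v_plus_grid = v_plus_grid, delta_grid = delta_grid,
         regime = regime, norm_growth = ng),
    class = "regime_phase_map"
  )
}

#' @export
as.data.frame.regime_phase_map <- function(x, ...) {
  data.frame(
    v_plus = rep(x$v_plus_grid, times = length(x$delta_grid)),
    delta = rep(x$delta_grid, each = length(x$v_plus_grid)),
    regime = as.vector(x$regime),
    norm_growth = as.vector(x$norm_growth),
    stringsAsFactors = FALSE
  )
}

#' @export
print.regime_phase_map <- function(x, ...) {
  tab <- table(factor(x$regime, levels = c("I", "II", "III")))
  cat(sprintf("Regime phase map: %d x %d grid (V+ x delta)\n",
              length(x$v_plus_grid), length(x$delta_grid)))
  cat(sprintf("  regime I: %d, II: %d, III: %d points\n",
              tab[["I"]], tab[["II"]], tab[["III"]]))
  invisible(x)
}

#' Lowest production flux at which the steady state is lost
#'
#' Scans `v_plus` upward at fixed demand and returns the smallest value
#' classified as regime III, or `Inf` if the steady state survives the whole
#' scan.  Used to compare toxicity variants: the byproduct variant loses its
#' steady state at a production flux no larger than the substrate variant's
#' at matched parameters.
#'
#' @param params template [pathway_params()].
#' @param v_plus_grid increasing scan of production fluxes.
#' @return smallest `v_plus` in the scan with no steady state, or `Inf`.
#' @export
regime3_threshold <- function(params, v_plus_grid) {
  for (v in v_plus_grid) {
    p <- params
    p$v_plus <- v
    if (is.null(solve_steady_state(p))) return(v)
  }
  Inf
}

#' Rescaled model parameters
#'
#' Dimensionless parameters governing steady-state existence:
#' `R = v_plus / vmax_b` (ratio of maximal enzyme activities) and
#' `Theta = theta / km_b` (toxicity threshold in units of the Michaelis
#' constant).  Increasing `R` or decreasing `Theta` can eliminate the
#' steady state.
#'
#' @param params a [pathway_params()] object.
#' @return list with `r_ratio` and `theta_scaled`.
#' @export
rescale_parameters <- function(params) {
  list(
    r_ratio = params$v_plus / params$vmax_b,
    theta_scaled = params$theta / params$km_b
  )
}

#' First-passage time of the metabolite to a threshold
#'
#' Integrates the pathway model from a low initial metabolite level until M
#' first reaches `m_threshold`, in a cell of relative volume `volume`.  The
#' production flux is specified in molecules per second per reference
#' volume, so in a larger cell the concentration production rate is
#' `v_plus / volume`; enzyme kinetics act on concentrations and are volume
#' invariant.  Returns `NULL` when a steady state below the threshold is
#' reached first (the threshold is never crossed).
#'
#' @param params a [pathway_params()] object.
#' @param volume relative cell volume (> 0).
#' @param m_threshold threshold concentration (molecules per cell volume).
#' @param from initial metabolite level, `0 <= from < m_threshold`.
#' @param t_max integration horizon (s).
#' @return passage time in seconds, or `NULL` if the threshold is not
#'   reached.
#' @export
first_passage_time <- function(params, volume = 1, m_threshold = 1000,
                               from = 0, t_max = 1e7) {
  stopifnot(volume > 0, m_threshold > from, from >= 0)
  p <- params
  p$v_plus <- params$v_plus / volume
  y0 <- c(m = from)
  if (p$toxicity_variant == "byproduct") y0 <- c(y0, t = 0)
  root_fn <- function(t, y, parms) y[["m"]] - m_threshold
  times <- c(0, t_max)
  sol <- deSolve::lsodar(y0, times, rhs_desolve, p,
                         rootfunc = root_fn, rtol = 1e-8, atol = 1e-10)
  troot <- attr(sol, "troot")
  if (is.null(troot) || length(troot) == 0L) return(NULL)
  troot[1]
}
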