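---
title: "Models and methods: enzyme saturation, growth arrest and persistence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: enzyme saturation, growth arrest and persistence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satarrest)
```

# The scientific problem

A generic metabolic conversion step — an upstream enzyme A producing an
intracellular metabolite M at flux $V^+$, a downstream Michaelis–Menten
enzyme B consuming it at flux $V^-(M) = V_{max}\,M/(K_m+M)$ — couples to
cellular growth in two opposing ways.  Consumption flux relative to a
demand $\delta$ feeds growth (benefit factor $f_{gr}$), while buildup of
the metabolite, or of a byproduct of its import such as symported
protons, inhibits it (toxicity factor $f_{tox}$).  Because $V^-$
saturates at $V_{max}$, production can outrun every removal process; the
package quantifies the consequences of that saturation threshold at
three scales: single deterministic cells, stochastic single-cell
trajectories, and exponentially growing populations.

# Deterministic regimes (`pathway_params`, `phase_diagram`)

The metabolite obeys
$$\dot M = V^+ - V^-(M) - g(M)\,M, \qquad
  g = g_{max}\, f_{gr}(V^-)\, f_{tox},$$
with first-order dilution of M by growth.  The functional forms are

* $f_{gr}(v) = \min(v/\delta, 1)$ (default), or the saturating
  alternative $\frac{v/\delta}{1+v/\delta}$ which blurs the
  starvation/satiation border while preserving the sharp loss of steady
  state;
* $f_{tox}(x) = \frac{1}{1+(x/\theta)^h}$ with Hill exponent $h = 1$ by
  default, acting on M (substrate variant), on a byproduct T with
  $\dot T = y\,V^+ - g\,T$ (byproduct variant), or absent.

These forms are the package's own minimal choices: they are the
simplest bounded, monotone factors with the stated half-saturation
behaviour, and both are configuration-switchable.

Three regimes emerge.  **Regime I (starvation)**: a steady state exists
but $f_{gr} < 1$.  **Regime II (satiation)**: a steady state exists with
demand met.  **Regime III (surfeit)**: no steady state — M (or T) grows
without bound and growth stalls; the crossing is irreversible because
the dilution term that would stabilise the state vanishes with the
growth rate itself.

Numerical choices: steady states are the smallest nonnegative root of
the right-hand side reachable from $M = 0$ (acclimatized initial
conditions), located by bracketing sign changes on a 400-point
log-spaced grid up to $M_{max} = 10^6\,\theta$ and polished by
`uniroot` to a residual below $10^{-9}\max(V^+, V_{max})$; stability is
the local slope test.  The independent oracle
(`integrate_to_steady_state`) integrates the ODE for
$10^5/g_{max}$ seconds and declares runaway only when the toxic species
exceeds $M_{max}$ with a sustained positive derivative; an unconverged,
still-rising trajectory triggers one ten-fold horizon extension before
being classified.  For the byproduct variant the quasi-stationary toxin
level solves $g\,T = y\,V^+$ self-consistently; with $h = 1$ this gives
$f_{tox} = 1 - y V^+/(g_{max} f_{gr} \theta)$, so the steady state is
lost once $y V^+ > g_{max} f_{gr} \theta$ — always at a production flux
no larger than the substrate variant's threshold
$\approx V_{max} + g_{max}\theta$.  At the default
$g_{max} = 6\times10^{-4}\,\mathrm{s^{-1}}$ a byproduct phase diagram
with all three regimes therefore needs a larger $\theta$ (the
comparison tests use $\theta = 5000$).

Default grid: $V^+ \in [0.02, 1.4]$, $\delta \in [0.05, 1.3]$ in units
of $V_{max} = 1$, $\theta = 100$, $K_m = 1$ (all molecules per unit
cell volume).  On this grid the convergence demand sits at
$\delta \approx V_{max}$: above it no production level yields
regime II, and the growth maximum of a high-demand column approaches
the point where the three regimes meet.  With the sharp benefit form
that maximum sits at the starvation/satiation border of the column
(inside regime II the toxicity factor only falls with $V^+$); the
blurred benefit form moves it into the interior.  Normalization of the
growth-rate surface is per diagram ($g/g_{max}$).

`first_passage_time` supports the cell-volume analysis: production is
specified in molecules per second per reference volume, so a 10% larger
cell sees a 10% smaller concentration production rate and reaches a
fixed per-volume metabolite threshold later — a window for compensatory
regulation that the tests scan across $K_m$ at the printed conditions
($\delta = 500$, $V_{max} = 1$, $\theta = 100$,
$g_{max} = 6\times10^{-4}$, threshold 1000 molecules per volume).

# Exact stochastic simulation (`build_reaction_system`, `run_ensemble`)

The single-cell model couples bursty gene expression to the same
pathway: 13 reaction types over 22 channels — transcription of each
enzyme's mRNA from a toggling gene, mRNA decay, translation, reversible
substrate capture by A ($k_{im}$ absorbs the constant substrate),
catalysis to the intermediate I, reversible binding of I by B,
catalysis to the product P, first-order demand turnover of P, and
growth-coupled dilution of both enzymes, both complexes and I.  Every
growth-coupled propensity (transcription and all dilutions) carries the
factor $f_{tox}(I/\Omega\theta)\cdot f_{gr}(P/\Omega\delta)$, evaluated
fresh after every event, so the cell's own growth state feeds back on
its molecular turnover.  The instantaneous growth rate is
$k_g f_{tox} f_{gr}$ with $k_g$ the maximum attainable rate.

Rate constants default to $k_{tE} = 0.05$, $k_{mdeg} = 0.0033$,
$k_{tsn} = 0.05$, $k_g = 6\times10^{-4}$, $k_{gon} = 4.5\times10^{-4}$,
$k_{goff} = 2.8\times10^{-3}$, $k_{-1} = k_2 = k_{-2} = k_u = 2$,
$k_{cat1} = k_{cat2} = 1$ (s$^{-1}$; $k_2$ per volume per count),
$\delta = 400$ and $\theta = 10^4$ (low toxicity) or $1$ (high
toxicity), with the import constant $k_{im}$ spanning
$[10^{-5}, 10]$.  Genes activate with probability
$k_{gon}/(k_{gon}+k_{goff}) \approx 0.14$, i.e. expression is bursty.

The simulator is an exact Gillespie direct method in C++ with a
per-trajectory xoshiro256+ stream seeded by `seed_base + index`;
identical seeds give bit-identical trajectories, and R's RNG is never
consumed.  Trajectories start from the deterministic (mean-field)
steady state of the same network, rounded to integers; the nontrivial
branch is reached by first solving the feedback-clamped system.  When
the deterministic network itself has no steady state (production
capacity above consumption capacity) the initial state falls back to
the $f_{tox}$-clamped steady state, and the fallback is flagged.

**Arrest criterion.**  A trajectory is scored as growth-arrested when
its instantaneous growth rate at the end of the run is below 1% of
$k_g$ *and* the intermediate has crossed the toxicity threshold
($I > \Omega\theta$).  The second condition separates toxic arrest —
runaway metabolite buildup, the phenomenon of interest — from
starvation, where growth is also near zero but the intermediate stays
at a handful of molecules.  Without it, deeply starved cells
($k_{im} = 10^{-5}$, product count $\approx 0$) would be misclassified
as arrested.

**The production scan.**  Mean growth across an ensemble is non-monotone
in the metabolite production rate.  The scan that exhibits the full
pattern — growth peak, correlation sign flips, and near-total arrest at
the top — varies the transcription rate of the producing enzyme
($k_{tA} \in [10^{-3}, 0.3]$ over 7 log-spaced points at $k_{im} = 1$,
$k_{tB} = 0.05$ fixed).  The reason is structural: with equal enzyme
expression the import flux $k_{cat1}\cdot A{\cdot}S$ is bounded by the
consumption capacity $k_{cat2}\,B_{tot}$ at *any* import rate (the
bound complex cannot exceed total A, which matches total B), so
deterministic runaway is impossible and arrest stays noise-driven and
partial.  Overexpressing A breaks the capacity balance at
$k_{tA}/k_{tB} \gtrsim 4$ at these settings; past that point every
trajectory crosses the threshold and arrests.  An import-rate ladder at
matched expression is still informative (arrest rises monotonically
with $k_{im}$) and is reported alongside, but its top-end arrest
saturates near one half rather than one.

Ensembles of 200 trajectories × 8000 s are used for the scan (the full
ensemble summaries also carry species–growth correlations computed on
per-trajectory time averages, and a growth-versus-intermediate
2-D histogram on a 10 s sampling grid).  The high-copy validity check
scales counts by 100 ($\Omega = 100$, 100 gene copies, toxicity
disabled) and requires ensemble means within three standard errors of
the deterministic rate equations.

# Metastable populations (`metastable_growth_rate`, `framework_growth_rate`)

At the population scale, a growing majority dividing at rate $g$ feeds
an irreversibly arrested subpopulation at rate $s$:
$\dot N_g = (g-s)N_g$, $\dot N_a = sN_g$.  The population rate is
$\lambda = g - s$ and the long-time arrested fraction $s/g$ (for
$g > s$); the population grows exactly when division outpaces
switching.  The switching rate is driven by noise in the flux ratio
$x = V^+/V^-$: $s = s_{max}\,\Phi((x-1)/\sigma_x)$ with a standard
normal CDF.  The CDF family and the saturation at $s_{max}$ are package
choices (the underlying distribution is not constrained beyond its
role as a CDF of $x$); $\sigma_x = 0.1$ and $s_{max} = 1.5\,g_{max}$
by default so that fitness turns negative beyond saturation.  The
fitness surface over $(\delta, x)$ reconstructs the growing-cell rate
as $g = g_{max} f_{gr}(\min(x,1)V_{max}, \delta)$; its optimum sits
slightly below $x = 1$, the saturation point.

The four-state framework generalises this: balanced growth ($g$), a
shifted state with changing rate ($\hat g$, a free parameter), viable
arrest, and death, connected by timescales $\tau_1, \tau_{-1}, \tau_2,
\tau_{-2}, \tau_3$.  The population rate is the leading eigenvalue of
the $3\times3$ live-state growth+transition matrix (the dead state is
absorbing and contributes nothing).  Limits recovered exactly:
$\tau_1 \to \infty$ gives balanced growth $\lambda = g$; fast
shift-to-arrest with negligible escape and death reduces to the
two-compartment model with $s = 1/\tau_1$.  The eigenvalue route is
cross-checked against long-horizon ODE integration to $10^{-6}$
relative.

# Inference stages (`phenotype_inference`)

* **Gating** mirrors standard flow-cytometry practice: events within
  0.5 SD of the mean forward and side scatter (linear coordinates),
  then removal of events above 6× a fixed reference mean fluorescence.
  The scatter statistics are computed once and carried on the gated
  result, so the gate is strictly idempotent.
* **Moments** are population (biased) central moments; CV, skewness and
  excess kurtosis serve as heterogeneity readouts.  A small arrested
  admixture raises all three; past roughly a quarter arrested the
  mixture turns visibly bimodal and kurtosis declines again while CV
  keeps rising.
* **Growth rates** come from OLS on $\log(\mathrm{OD}-\mathrm{blank})$
  over an automatically selected early-exponential window: points above
  2× blank, local log-slopes smoothed over a tenth of the series, the
  longest run within 20% of the maximum slope, and the fit restricted
  to the earliest quarter of that run.  The trimming matters: fitting
  the whole admissible run biases the rate low on saturating curves by
  several percent.
* **Fluorescence models** compare balanced growth against heterogeneous
  growth for a constitutive reporter whose concentration falls with
  growth rate, calibrated as $F_{cal}(g) = a + b/g$ (an exponential
  alternative is available; the inverse form is the package's choice
  for the canonical dilution-dominated reporter).  Uniform model:
  $F = F_{cal}(g_{pop})$.  Heterogeneous model: growing cells divide at
  $g_{pop} + s$ so the *net* rate stays $g_{pop}$, the arrested
  fraction is $\phi = s/(g_{pop}+s)$ (a reconstruction from the
  two-compartment bookkeeping), and
  $F = (1-\phi)F_{cal}(g_{pop}+s) + \phi\,p_{arr}$.  Fitting is a
  41×41 grid search over $(p_{arr}, s)$ with Nelder–Mead refinement;
  the heterogeneous model nests the uniform one at $s = 0$, so its
  optimal sum of squares can never be worse.
* **Model selection** uses the full Gaussian-likelihood AIC,
  $n\log(2\pi\,\mathrm{RSS}/n) + n + 2(k+1)$, identical to
  `stats::AIC` on `lm` fits (the error variance counts as a
  parameter), so values are comparable across software using the same
  convention.
* **Kill curves** are fit as
  $N(t) = N_0[(1-f)e^{-k_1t} + f e^{-k_2t}]$ by least squares on
  $\log_{10}$ CFU with bounds $k_1 > k_2 \ge 0$, $f \in [0,1]$;
  censored points are substituted by the detection limit and flagged.
  Structurally single-phase data leave the Jacobian rank-deficient and
  fall back to a flagged single-exponential fit.  The breakpoint
  $\ln[(1-f)/f]/(k_1-k_2)$ marks where the two phases contribute
  equally.
* **Survival ratios** are $\log_{10}(x_i/y_i)$ per matched
  treated/untreated replicate pair, with mean and SEM over pairs and
  detection-limit substitution for treated zeros.

# Synthetic data (`synthetic_data`)

Each generator produces exactly the structure its inference stage
assumes, with the ground truth attached: lognormal two-component
fluorescence mixtures with Gaussian scatter; logistic OD curves with
multiplicative noise (defaults: rate 0.6 h⁻¹, inoculum $10^{-3}$ OD,
capacity 0.8, blank 0.002, 1% noise, 2-minute readings over 24 h, three
replicates); biexponential kill curves (defaults $N_0 = 5\times10^8$
CFU/ml, $k_1 = 1$ h⁻¹, $k_2 = 0.05$ h⁻¹, $f = 10^{-3}$, 5% noise,
detection limit 100 CFU/ml); and quadratic dose–response tables
(defaults $a = 0.45$, $b = 0.012$, $c = -2.4\times10^{-4}$ h⁻¹ over
doses 0.1–50 mg/ml, replicate SD 0.02, interior optimum at 25 mg/ml).
Lognormal fluorescence, Gaussian scatter and multiplicative OD noise
are standard stand-ins; no per-event instrument model is claimed.  What
passing recovery tests show is that the estimators are consistent under
these assumed noise families at realistic sizes — not that real flow
or plate-reader data satisfy those families, and not anything about
spillover, doublets, or instrument drift.

# Problem sizes and reproducibility

The shipped checks use: 50×50 deterministic phase grids (25×25 for the
variant scans); 100 randomized parameter draws for the oracle
equivalence; 200 trajectories × 8000 s per point of the 7-point
production scan and a 5-point import ladder at 100 trajectories; a
24-trajectory high-copy ensemble over 1500 s; and 100–200 seeded
replicates per recovery or model-selection statistic.  These sizes were
chosen so a full desk run completes comfortably on one core while
keeping Monte Carlo error well inside every asserted margin.  All
randomness is seeded: generators through a locally scoped R seed that
never leaks into the caller's RNG state, the simulator through
per-trajectory counter-seeded streams.

# Known limitations

* The deterministic variants treat enzyme levels as constant;
  regulation, efflux, and detoxification are outside the model, which
  is exactly what makes the arrest irreversible.
* Trajectories contain no cell division, so ensemble arrest fractions
  depend on the trajectory length by construction; 8000 s is the
  reference horizon.
* The exact algebraic forms of the growth-benefit, toxicity and
  threshold relations are minimal reconstructions (stated above), and
  so are the switching-rate CDF family, the shifted-state growth rate,
  the reporter calibration form and the arrested-fraction bookkeeping.
* FCS binary parsing is out of scope; event tables enter as plain CSV.
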