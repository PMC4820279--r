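# satarrest

Models of cellular growth arrest and antibiotic persistence driven by
enzyme saturation in a metabolic pathway.

## Who this is for

Systems and quantitative microbiologists studying how a saturable
metabolic step — an upstream enzyme producing an intracellular
metabolite, a downstream Michaelis–Menten enzyme consuming it — shapes
single-cell and population growth. The package covers the full chain
from deterministic theory to data analysis: regime phase diagrams,
exact stochastic simulation of the gene-expression/metabolism network
with growth feedback, metastable population dynamics, and inference
tools for flow-cytometry fluorescence mixtures, growth curves,
antibiotic kill curves and dose–response model selection, plus
ground-truth synthetic data generators for all of them.

## The model at its core

The metabolite M obeys

    dM/dt = V+ − V−(M) − g·M,     V−(M) = Vmax·M/(Km + M),
    g = g_max · f_gr(V−/δ) · f_tox(x/θ),

where the benefit factor `f_gr = min(V−/δ, 1)` rewards consumption flux
up to a demand δ and the toxicity factor `f_tox = 1/(1 + (x/θ)^h)`
penalises buildup of the metabolite itself or of an import byproduct.
Because V− saturates, three regimes exist: **I, starvation** (steady
state, demand unmet), **II, satiation** (steady state, demand met), and
**III, surfeit** — no steady state, irreversible metabolite runaway,
growth arrest. A stochastic version of the same pathway (13 reaction
types with growth-coupled transcription and dilution propensities,
simulated exactly with a Gillespie direct method in C++) shows how
noise drives a fraction of cells over the threshold while the rest
grow fast, and a two-compartment population model (growing cells
switch irreversibly to arrest at rate s) gives the population growth
rate λ = g − s with arrested fraction s/g. Arrested cells tolerate
bactericidal antibiotics, so kill curves turn biphasic; the package
fits `N(t) = N0[(1−f)e^(−k1·t) + f·e^(−k2·t)]` to recover the persister
fraction f.

## Worked example

```r
library(satarrest)

# 1. Where does growth arrest live in parameter space?
pd <- phase_diagram(seq(0.02, 1.4, length.out = 50),
                    seq(0.05, 1.3, length.out = 50))
pd
#> Regime phase map: 50 x 50 grid (V+ x delta)
#>   regime I: 1145, II: 705, III: 650 points

# 2. Stochastic single cells at the edge of regime III
sp <- build_reaction_system(k_im = 1, k_tA = 0.1159, theta = 1e4)
ens <- run_ensemble(sp, n_traj = 60, t_end = 8000, seed_base = 3)
ens
#> SSA ensemble: 60 trajectories x 8000 s (k_im = 1)
#>   mean growth rate 7.101e-05 +/- 1.2e-06 /s; arrested fraction 0.017

# 3. What population growth rate does that switching imply?
metastable_growth_rate(switching_model_params(g = 1), s = 0.25)
#> $lambda            [1] 0.75
#> $arrested_fraction [1] 0.25

# 4. Recover a persister fraction from a (synthetic) kill curve
kc <- gen_kill_curve(seed = 4, replicates = 3)   # truth: k1=1, k2=0.05, f=1e-3
fit <- fit_biphasic_kill(kc)
round(c(fit$fast_rate, fit$slow_rate, fit$persister_fraction), 5)
#> [1] 0.99820 0.04713 0.00095
```

The phase map counts say most of the default grid starves (I), a band
meets demand (II), and the top of the production axis has lost its
steady state (III). The ensemble near the arrest threshold grows at
`7.1e-5 /s` — about 12% of the ceiling `k_g = 6e-4` — with under 2% of
trajectories arrested; raising the producing enzyme's transcription
rate pushes that fraction to one and collapses mean growth. The kill
fit recovers the planted fast/slow rates and persister fraction to a
few percent.

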