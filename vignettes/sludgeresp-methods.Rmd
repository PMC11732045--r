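---
title: "Methods: batch respirometry kinetics and community diversity with sludgeresp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: batch respirometry kinetics and community diversity with sludgeresp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sludgeresp)
```

## The model and its assumptions

`sludgeresp` encodes a six-process ASM-type model for simultaneous
growth and storage in a batch of activated sludge fed a pulse of fully
biodegradable substrate. Everything is expressed in COD units, which
makes oxygen the bookkeeping mirror of organic matter: each process row
of the stoichiometric matrix sums to zero once consumed oxygen is
counted as COD with content −1 (`cod_continuity()`).

The processes and their assumptions:

* **Growth on readily biodegradable COD** (Monod in `S_S`): the dominant
  oxygen sink at the OUR peak.
* **Two hydrolysis steps** converting the readily (`S_H1`) and slowly
  (`S_H2`) hydrolysable fractions into `S_S`, with surface-saturation
  (Contois) kinetics in the ratio `S_H/X_H`: hydrolysis is limited by
  biomass surface, not by bulk substrate. Hydrolysis consumes no oxygen
  itself — its oxygen cost appears when the released `S_S` is grown on.
* **PHA storage** of excess `S_S` (Monod, half-saturation `K_STO` well
  below `K_S`: storage wins at low residual substrate) and **growth on
  stored PHA**, first-order in `X_STO`. Under the antibiotic, storage is
  knocked out completely (`k_STO = 0` in the acute/chronic/intermittent
  parameter sets), which is one of the two clearest kinetic signatures of
  exposure.
* **Endogenous decay**, first-order in `X_H`, splitting the decayed
  biomass into an inert particulate fraction `f_EX`, a soluble microbial
  product fraction `f_ES`, and oxidized COD `1 − f_ES − f_EX`.

**Dissolved oxygen is not a dynamic state.** The respirometer holds DO
above 3 mg O₂/L while the oxygen half-saturation is 0.01 mg O₂/L, so the
oxygen switch `S_O/(K_OH + S_O)` is ≥ 0.997 throughout. The package
treats the switch as exactly 1 and integrates cumulative consumed oxygen
`O_cum` instead; OUR(t) = (dO_cum/dt)/24. A finite DO can still be
supplied (`S_O` argument of `process_rates()`/`simulate_batch()`) for
sensitivity analysis; it scales all rates by the same switch. Removing
the DO state eliminates an unobserved stiff variable at negligible cost.

**Units.** Rates are per day (the natural unit of the constants); the
public interface uses hours, and OUR is reported per hour.

## Parameters that matter

| symbol | meaning | unit | control value |
|---|---|---|---|
| μ_H | max growth rate on `S_S` | 1/day | 5.2 |
| K_S | growth half-saturation | mg COD/L | 24 (rises to 80 under chronic exposure) |
| b_H | endogenous decay rate | 1/day | 0.1 (0.27 chronic: the second exposure signature) |
| k_h1, K_X | hydrolysis of `S_H1` | 1/day, g COD/g COD | 5.2, 0.15 |
| k_h2, K_XX | hydrolysis of `S_H2` | 1/day, g COD/g COD | 0.56, 0.05 |
| k_STO, K_STO | PHA storage | 1/day, mg COD/L | 1.2, 0.5 (0 with antibiotic) |
| μ_STO | growth on PHA | 1/day | 0.8 |
| Y_H, Y_STO | growth/storage yields | g COD/g COD | 0.6, 0.8 |
| f_ES, f_EX | decay product fractions | – | 0.05, 0.15 |
| Y_SP | soluble-product yield on utilized COD | g COD/g COD | 0.06 (mass balance only) |

The bundled sets `run_params(1|2|4|5)` / `run_init(...)` are the
calibrated control, acute, chronic and intermittent runs. Initial
substrate fields are the *bioavailable* amounts: the antibiotic-bound
("blocked") COD is already excluded, and `bound_cod` is carried
alongside so the dosed total is reconstructable.

## Numerical choices

* **Integrator:** adaptive Dormand–Prince RK5(4) in compiled code, mixed
  error norm with `rtol = atol = 1e-8` by default. The depletion of
  `S_S` (time constant of minutes against a one-day test) is the fast
  scale; the embedded error estimate resolves it without a stiff solver.
  Halving tolerances moves the OUR peak and the area under the curve by
  far less than 0.1% (asserted in the tests).
* **Nonnegativity:** rates are evaluated on states clipped at zero, and
  accepted steps are floored at zero, so stiff depletion cannot
  propagate a transient undershoot. Conservation of total COD + `O_cum`
  holds to ~1e−15 relative in practice.
* **Output grid:** 2000 points over 24 h by default; the OUR peak is
  read off the grid without interpolation refinement (the peak is broad
  at this resolution; grid error ≪ 1%).
* **Peak ties** break to the earliest time (`which.max`).

## Mass-balance conventions

Utilized COD is back-calculated from oxygen as `O₂/(1 − Y_H)`; the
soluble microbial product as `Y_SP ×` utilized; bound COD as dose −
utilized. Three conventions are deliberate:

* **Rounding is half-away-from-zero at integer mg/L**, because
  275/0.4 = 687.5 must print as 688 to match the published table.
  Bound COD is rounded from the *unrounded* utilized value, so
  720 − 687.5 = 32.5 prints as 33 (consistent with the published 688/33
  pair, which a rounded-first computation cannot reproduce).
* **Control runs are taken at full utilization** (utilized := dose,
  bound := 0). In the control the storage pathway and decay recycle
  oxygen in a way the simple growth-only back-calculation does not
  capture (211 mg O₂/L ≠ 0.4 × 600); the antibiotic runs have storage
  suppressed, where the back-calculation is valid.
* The published "remaining soluble COD" column is treated as an input
  passthrough, not computed: its construction is not derivable from the
  other columns.

`removal_efficiency()` in the assembled table uses the soluble microbial
product as the residual, the convention under which the control run
yields 94%.

## Calibration

The objective is weighted least squares over up to three streams (OUR,
soluble COD = `S_S + S_H1 + S_H2 + S_P`, PHA = `X_STO`), the model
evaluated at the observation times:

loss = Σ_streams w_s Σ_i ((sim_i − obs_i) / scale_i)²,
scale_i = max(|obs_i|, 0.1 · mean|obs|).

**Why per-point relative scaling:** respirometer error is dominantly
multiplicative (≈1% of signal) with an additive floor near the
endogenous baseline. Scaling residuals by the observation (floored at
10% of the stream mean so near-zero observations cannot dominate) is the
heteroscedasticity-consistent choice, and it is what makes `K_S`
identifiable: under constant intra-stream scaling the loss is dominated
by the high-OUR plateau, where `K_S` has almost no leverage, and
least-squares optima sit 10–20% away from the generating value even with
a perfect optimizer. The same scaling makes streams of different
magnitude (OUR ~10², PHA ~10¹) directly comparable; the per-stream
weights `w_s` remain available on top.

**Optimizer:** bounded L-BFGS-B with `parscale` set to the start point,
so finite-difference steps are ~0.1% of each parameter. This is
deliberate: an adaptive integrator's output carries tolerance-level
noise, and optimizers probing at `sqrt(eps)`-sized steps (`nlminb`) read
pure noise as gradient and stall with false convergence. Multistart
draws starting points log-uniformly within the bounds from the stated
seed (default 20 starts), each start is polished locally, the incumbent
gets one extra polish pass, and the whole procedure is deterministic
given the seed. Collapsed (zero-width) bounds pin a parameter without
optimizing it. Failed simulations return a finite penalty (1e12) with a
warning so the search continues.

**Default free set and bounds** mirror what varied across the
experimental runs (μ_H, K_S, b_H, k_h1, K_X, k_STO, μ_STO, X_H1,
bound_cod), with yields and decay fractions held fixed; bounds of
×/÷10 around the control values are a practical default. Freeing
`bound_cod` rescales the three substrate fractions proportionally so the
dosed total stays fixed. Approximate standard errors come from a
forward-difference Jacobian of the scaled residuals at the optimum; they
are curvature-based approximations, not posterior intervals.

## Diversity conventions

* **Chao1** uses the bias-corrected form
  `S_obs + F1(F1−1)/(2(F2+1))` by default: it is defined at `F2 = 0` and
  it reproduces the published species-level estimate (647.7 from
  S_obs = 288, F1 = 168) with an integer doubleton count (F2 = 38 — a
  derived fixture; the true doubleton counts were not published). The
  classical form is available behind a flag.
* **ACE** follows Chao & Lee with the conventional rare/abundant cutoff
  of 10 reads (the mothur default, matching the upstream tool of the
  source study); the CV term is floored at 0, and an all-singleton rare
  class is an error pointing the user to Chao1.
* **Shannon uses natural log** — required for the published evenness
  cells (H/ln S) to reproduce.
* **Coverage:** the published table's "Good's coverage" matches
  `1 − F1/S_obs` in all six columns, not Good's `1 − F1/N`. Both are
  implemented; `variant = "paper"` (the default) reproduces such tables,
  `variant = "good"` is the textbook estimator. This is a deliberate
  deviation from the standard definition, made visible in the function
  documentation rather than silently corrected. One published evenness
  cell (0.63 at the species level for the day-30 sample) is not
  reproducible from its own printed inputs (3.6/ln 289 = 0.6353 → 0.64);
  the tests assert it only at the precision the printed inputs allow.
* **Rarefaction** is the hypergeometric expectation computed in log
  space; the Monte-Carlo route (resampling without replacement, seeded)
  exists as a cross-check and is tested to agree within 3 SE.

## What the synthetic generators emulate — and what they do not

`gen_our_profile()` corrupts a simulated OUR curve with multiplicative
plus additive Gaussian noise (defaults 1% and 0.5 mg O₂/L·h), mimicking
a respirometer's roughly constant relative error at high signal and its
absolute floor near the baseline. It does not emulate probe drift,
aeration-control transients, or autocorrelated error — so a green
recovery test establishes statistical identifiability under iid noise,
not robustness to instrument artifacts.

`gen_otu_table()` draws relative abundances from a log-series (default),
rank-geometric or symmetric-Dirichlet law and multinomial reads, then
calibrates the free law parameter (species pool, or Dirichlet
concentration) by bisection — at most 50 iterations, each candidate
evaluated under the same derived seed — until realized richness is
within ±5% of the target. The log-series default reflects the rare-heavy
shape of real amplicon data at this scale (~3000 reads, ~300 OTUs).
One caveat measured during development: a log-series community
calibrated to the real sample's richness yields ~50 singletons, well
short of the 168 observed in the real data — real communities are even
more singleton-heavy than the log-series. Singleton-sensitive estimators
(Chao1, ACE, coverage) are therefore exercised at milder rare-tail
regimes than the real study; their formula-level correctness is
established against an independent implementation (vegan) instead.

## Known limitations

* Simulating the control run from the published parameter set gives a
  PHA transient peaking near 167 mg COD/L, although the source study
  measured a maximum PHA storage of ~32 mg COD/L. The printed model
  structure and constants do not reproduce the measured PHA amplitude;
  the package implements the model as printed and does not re-tune it.
  The OUR profile — the quantity the model was calibrated to — is
  reproduced (peaks within 5% of the measured 160 and 106 mg O₂/L·h).
* The published total oxygen of the control run (211 mg/L) is not the
  raw 24-h area under the simulated curve (~375 mg/L including decay and
  storage turnover); the accounting convention behind the printed number
  (baseline handling, integration window) is not stated. Areas are
  therefore validated through the mass-balance module, where the
  convention is explicit, not through the simulator.
* After substrate depletion the OUR approaches the endogenous line only
  asymptotically (the stored-PHA pool drains with a ~1.2-day time
  constant in the control), so "ends at the endogenous level" holds to
  ~10–15% at 24–48 h, not exactly.
* No nitrification (inhibited in the experiments), no antibiotic
  degradation kinetics (the compound was not utilized), no adsorption,
  and no sequencing-error model for the OTU generator.
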