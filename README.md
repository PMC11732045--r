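# sludgeresp

Kinetic and microbial analysis of activated sludge batch respirometry
under antibiotic stress.

## The problem

Antibiotics reaching wastewater treatment plants change how the activated
sludge community degrades organic matter. The standard way to quantify
that change is a batch respirometric test: a fill/draw pulse of a fully
biodegradable substrate (a peptone–meat extract mixture, fractionated in
COD units) is dosed to a biomass suspension and the oxygen uptake rate
(OUR, mg O₂/L·h) is recorded continuously until the system returns to the
endogenous decay line. Fitting an ASM-type process model to the OUR curve
turns the profile into kinetic constants; comparing runs with and without
the antibiotic (acute, chronic, intermittent exposure) quantifies the
inhibition. In parallel, 16S amplicon OTU tables describe how the
community itself shifts.

`sludgeresp` implements this whole analysis chain for the
sulfamethoxazole (SMX) exposure experiment it was built around, with a
synthetic-data generator so every stage is testable offline:

* **model core** — the six-process simultaneous growth-and-storage model,
* **respirometry** — stiff-capable batch simulation of OUR/COD/PHA
  profiles (compiled adaptive Dormand–Prince RK5(4)),
* **mass balance** — oxygen/COD utilization accounting with antibiotic
  substrate-binding ("blocked" COD),
* **calibration** — seeded, bounded, multistart weighted least squares
  replacing manual curve fitting,
* **diversity** — Chao1, ACE, Shannon, evenness, coverage, rarefaction
  and shared-OTU (Venn) counts for OTU tables,
* **synthetic data** — noisy OUR profiles from known kinetics and OTU
  tables with controlled richness,
* **cli/io** — JSON/YAML configs, CSV/mothur-shared I/O, and a
  subcommand CLI.

## The model

Six processes over components expressed in COD units
(S_S readily biodegradable, S_H1/S_H2 readily/slowly hydrolysable
substrate, X_H active biomass, X_STO stored PHA, X_P/S_P inert
particulate/soluble decay products), with rates

| process | rate (per day) |
|---|---|
| growth on S_S | μ_H · S_S/(K_S+S_S) · X_H |
| hydrolysis of S_H1 | k_h1 · (S_H1/X_H)/(K_X+S_H1/X_H) · X_H |
| hydrolysis of S_H2 | k_h2 · (S_H2/X_H)/(K_XX+S_H2/X_H) · X_H |
| PHA storage | k_STO · S_S/(K_STO+S_S) · X_H |
| growth on PHA | μ_STO · X_STO |
| endogenous decay | b_H · X_H |

with yields Y_H (growth), Y_STO (storage) and decay fractions f_ES/f_EX.
Every process row conserves COD once consumed oxygen is counted as
negative COD (`cod_continuity()`), so total COD + cumulative O₂ is an
invariant of every trajectory — the package's main correctness oracle.
Dissolved oxygen is held far above its half-saturation in the aerated
respirometer, so the oxygen switch is saturated by default and the model
tracks cumulative consumed oxygen `O_cum`; OUR(t) = (dO_cum/dt)/24.

## Worked example

Simulate the control run from the bundled calibrated parameter set and
read off the OUR summaries:

```r
library(sludgeresp)
traj <- simulate_batch(run_init(1), run_params(1))
our_peak(traj)
#>   t_peak  our_max
#>   0.0000 166.8163
round(endogenous_baseline(1450, run_params(1)), 2)
#> [1] 4.83
```

The peak of 166.8 mg O₂/L·h sits within 5% of the measured control peak
(160 mg/L·h); the endogenous baseline 4.83 mg O₂/L·h is the respiration
of 1450 mg/L active biomass with no external substrate. The acute run
(`run_params(2)`: storage suppressed, K_S raised, b_H doubled) peaks at
110.2 against the measured 106.

The oxygen/COD mass balance for the four runs, from dosed COD and the
oxygen consumed in each test (Y_H = 0.6, Y_SP = 0.06):

```r
runs <- data.frame(run = c(1, 2, 4, 5), smx_mg_L = c(0, 50, 50, 50),
                   initial_cod = c(600, 600, 720, 720),
                   oxygen_consumed = c(211, 206, 278, 275))
build_balance_table(runs)
#>   run smx_mg_L initial_cod oxygen_consumed cod_utilized bound_cod
#> 1   1        0         600             211          600         0
#> 2   2       50         600             206          515        85
#> 3   4       50         720             278          695        25
#> 4   5       50         720             275          688        33
#>   soluble_product removal_efficiency
#> 1              36                 94
#> 2              31                 95
#> 3              42                 94
#> 4              41                 94
```

`bound_cod` is the substrate the antibiotic blocked from utilization:
85 mg COD/L (14% of the dose) under acute exposure, shrinking to 25 and
33 mg COD/L in the chronic and intermittent runs.

A synthetic species-level community with the richness of the real
control sample, and its diversity statistics:

```r
g <- gen_otu_table(community_spec(S_obs = 288, N = 2977, seed = 7))
round(alpha_summary(g$abundances), 3)
#>   n_otus n_singletons n_doubletons   chao1     ace shannon evenness
#> 1    279           48           42 305.233 309.696   4.933    0.876
#>   coverage_paper coverage_good
#> 1         82.796        98.388
```

## CLI

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "sludgeresp.R", package = "sludgeresp"))')
Rscript "$CLI" simulate --params params.json --init init.json --duration 24 --out traj.csv
Rscript "$CLI" fit --data our.csv --config fit.json --seed 42 --out fit_out.json
Rscript "$CLI" massbalance --runs runs.csv --out balance.csv
Rscript "$CLI" diversity --otu sample.shared --out alpha.csv
Rscript "$CLI" synth our --params params.json --init init.json --seed 42 --out synth.csv
Rscript "$CLI" synth otu --sobs 288 --reads 2977 --seed 7 --out synth.shared
```

Exit codes: 0 success, 1 validation error, 2 numerical failure.
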