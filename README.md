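# growthtoggle

Stochastic and deterministic simulation of a genetic toggle switch whose
balance is set by the bacterial growth rate.

## The science

In fast-growing *E. coli*, chromosome replication takes longer than the
division cycle, so replication rounds overlap and genes near the replication
origin are present in more copies, on average, than genes near the terminus.
The average copy-number ratio between an origin-proximal and a
terminus-proximal locus is `2^(C/T)`, where `C` is the replication time
(~40 min) and `T` the doubling time: a four-fold dosage bias at `T = 20` min
that fades to ~1.26-fold at `T = 120` min.

A mutual-repression toggle switch built from two identical genes placed at
*different* chromosomal positions therefore has its symmetry broken by
growth rate alone. Fast growth hands the origin-proximal gene a dosage
advantage and the switch settles with that gene ON; slow growth removes the
advantage (and, past the balance point, reverses it). The switch becomes a
growth-rate sensor with memory: bistable over a band of doubling times, with
stochastic switching between states whose mean first-passage times (MFPTs)
range from hours to weeks.

This package implements:

- **Copy-number analytics** (`cell_cycle_params()`, `mean_copies()`,
  `dosage_ratio()`, `balanced_locus()`, `best_balanced_design()`): exact
  Cooper–Helmstetter copy numbers for arbitrary loci, genome-average gene
  dose, and design of dosage-balanced gene placements.
- **Deterministic model** (`relax_to_steady_state()`, `hysteresis_scan()`):
  an ODE approximation over cycle-averaged copy numbers and volume, with a
  quasi-static continuation scan that maps the bistable region in `T`.
- **Stochastic model** (`simulation_config()`, `simulate_lineage()`,
  `run_ensemble()`): an exact Gillespie-type simulator of a single cell
  lineage with exponential volume growth, deterministically scheduled gene
  replication, repressor–operator binding, dimerization, and binomial
  partitioning at division (one copy of each replicated pair is kept;
  repressors bound to the copy that leaves go with it).
- **Analysis** (`switching_time()`, `mfpt_fit()`, `equilibrium_ratio()`,
  `state_lifetimes()`, `shift_response()`, `sensitivity_scan()`): MFPT
  estimation from exponential tails of transition-time samples, equilibrium
  expression ratios from occupancy-weighted committed-state averages, and
  response to growth-rate shifts.
- **CLI + config I/O** (`gt_main()`, `load_config()`): YAML/JSON configs and
  a command-line front end with CSV/JSON outputs and run manifests.

## Quick start

Gene dosage across growth rates:

```r
library(growthtoggle)

cc <- cell_cycle_params(T = 20)          # C = 40, D = 20 min by default
mean_copies(locus_spec(L = 0), cc)       # origin locus:   8 copies
mean_copies(locus_spec(L = 1), cc)       # terminus locus: 2 copies
dosage_ratio(0, 1, cell_cycle_params(40))  # 2
best_balanced_design(cell_cycle_params(40))
# ratio 1/2 -> place the second gene at L2 = 1 (the terminus)
```

Deterministic steady states and bistability:

```r
rc0 <- rate_constants(r_g_scale = 0)     # repression off
st <- relax_to_steady_state(deterministic_state(), rc0, cell_cycle_params(20))
state_protein_ratio(st)                  # 2.0  (pure dosage)
state_protein_ratio(relax_to_steady_state(deterministic_state(), rc0,
                                          cell_cycle_params(120)))
                                         # 0.643 (terminus gene is doubled)

hysteresis_scan(rate_constants(r_g_scale = 3.5e-3))
# bistable over a band of doubling times; the band narrows at
# r_g_scale = 2e-3 and vanishes at 5e-4
```

Stochastic lineages and switching:

```r
cfg <- simulation_config(cell_cycle_params(40),
                         rate_constants(r_g_scale = 2e-3),
                         t_end_hours = 50, seed = 1)
run <- simulate_lineage(cfg, detect = TRUE)
head(run$trajectory)

fit <- switching_time(cell_cycle_params(40),
                      rate_constants(r_g_scale = 2e-3), seed = 1)
fit$mfpt_h        # ~25 h mean first-passage time between states
```

Equilibrium expression ratio (occupancy-weighted over both committed
states):

```r
eq <- equilibrium_ratio(cell_cycle_params(30),
                        rate_constants(r_g_scale = 3.5e-3), seed = 1)
eq$R_protein      # >> 1: the origin-proximal gene dominates at fast growth
eq$occupancy      # fraction of time spent in each committed state
```

## Command line

A ready-to-run script ships with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "growthtoggle.R", package = "growthtoggle"))')
Rscript "$CLI" dosage --grid 20,120,1 --out out/dosage
Rscript "$CLI" design --T 40 --out out/design
Rscript "$CLI" ode-scan --rg 0.0035 --out out/scan
Rscript "$CLI" simulate --T 40 --rg 0.002 --seed 1 --out out/run
Rscript "$CLI" mfpt --T 40 --rg 0.002 --seed 1 --out out/mfpt
```

Each subcommand writes CSV/JSON results plus a `*_manifest.json` recording
the resolved configuration and seeds. Exit codes: 0 success, 2
configuration error, 3 numerical failure.

Configs are YAML or JSON; flags override file values:

```yaml
T: 40
rg: 0.0035        # repression strength label (r_g scale, 1/molecule/s)
seed: 7
loci:
  ori: {L: 0, copies: 1}
  ter: {L: 1, copies: 2}
```

## Package layout

- `R/cell_cycle.R` — replication-geometry analytics
- `R/model_params.R` — rate constants and volume/dosage scaling
- `R/deterministic.R` — ODE model and hysteresis scan
- `R/stochastic.R`, `src/ssa.cpp` — exact stochastic lineage simulator
- `R/analysis.R` — switching, equilibrium, response and sensitivity
  estimators
- `R/config_io.R`, `R/cli.R`, `inst/cli/growthtoggle.R` — configs, outputs
  and the command-line front end
- `vignettes/methods.Rmd` — model definition, conventions and estimator
  methodology
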