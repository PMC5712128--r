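---
title: "Model definition and estimator methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model definition and estimator methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette defines the model implemented by `growthtoggle`, pins down
every convention that affects numbers, and documents how the statistical
estimators work and why they are built the way they are. Chunks are not
evaluated at build time; all are runnable as shown.

## 1. Cell-cycle geometry

A cell divides every `T` minutes. Chromosome replication takes `C` minutes
(origin to terminus) and is followed by a `D`-minute gap before division;
defaults are `C = 40`, `D = 20`. A locus at relative origin–terminus
distance `L` (0 = origin, 1 = terminus) is replicated
`x = C(1 - L) + D` minutes before the division it serves. With overlapping
rounds the copy number of a locus inserted in `n` copies per chromosome is
a square wave over the cycle:

- base count `n * 2^floor(x / T)` from birth,
- doubling once at cell age `T - (x mod T)`,
- constant over the whole cycle when `x` is a multiple of `T`.

The cycle-average is `mean_copies()`, and the average over a locus'
position gives the genome-average gene dose `S(T)`
(`genome_average_copies()`), used to normalise transcription so that total
mRNA output per cell is growth-rate independent. The origin:terminus
average-dosage ratio is `2^(C/T)` (`dosage_ratio()`), and
`balanced_locus()` inverts it: given an insertion-count ratio `R` between
two genes, the second gene balances the first when placed
`L2 = -(T/C) log2(R)` downstream. `best_balanced_design()` scans a fixed
menu of small-integer insertion ratios and returns the admissible design
(`L2 <= 1`) with the largest locus separation.

Cell volume grows exponentially, `V(t) = V0 * 2^(t/T)`, with birth volume
`V0(T) = (1/6) (40/T)^2 + 1/3` (in units where the reference volume at
`T = 40` gives `V0 = 0.5`), so bimolecular rates are diluted as the cell
grows.

## 2. The toggle switch

Two identical repressor genes, `ori` (at `L = 0`, one insertion) and `ter`
(at `L = 1`, two insertions), each produce mRNA, monomer and homodimer; the
dimer of each gene represses all copies of the *other* gene by binding its
operator. Reaction channels per gene `i` (with `o` the other gene):

| channel | propensity | notes |
|---|---|---|
| operator activation | `k_g * (copies_i - active_i)` | bound repressor falls off |
| operator repression | `(r_g/V) * d_o * active_i` | consumes one free dimer of `o` |
| transcription | `(k_m/S(T)) * active_i` | per active copy |
| mRNA decay | `r_m * m_i` | |
| translation | `k_p(T) * m_i` | `k_p = 2 V0 (40/T) k_p_scale` |
| dimerization | `(k_d/V) * p_i * (p_i - 1)` | see note below |
| dissociation | `r_d * d_i` | |

There is no protein degradation; proteins are diluted only by division.
Default rate scales: `k_g = 2e-3`, `k_m_scale = 5e-3`,
`k_p_scale = 1e-2`, `k_d_scale = 1e-3`, `r_d = 0.1`, `r_m = 3e-3` (all per
second), and the repression scale `r_g_scale` is the control parameter
(`5e-4`, `2e-3` or `3.5e-3`).

**Dimerization convention.** The stochastic propensity is the literal
mass-action form `k_d * p * (p - 1)` (not divided by 2). The deterministic
model uses the matched mean-field form `d[D]/dt = (k_d/2) P^2 / V ...` so
that both describe the same process. This convention is pinned by the
switching-time behaviour of the full model; halving `k_d` roughly halves
the simulated mean first-passage times and is inconsistent with the rest
of the parametrization.

**Replication and division.** Gene copies double at their scheduled age
(each new copy is born unbound/active). At division each replicated pair
keeps exactly one copy — which one is uniform — and a repressor bound to
the copy that leaves is lost with it. When a locus' copy number is
constant over the cycle (x a multiple of `T`), division resets all its
copies to the active state and the displaced bound dimers are released
into the free pool of the sibling species before partitioning. All free
molecules (mRNA, monomer, dimer) are split `Binomial(1/2)`. The simulator
(`src/ssa.cpp`) is an exact next-reaction implementation between scheduled
events and keeps an audit of every channel firing; the identity

```
delta(bound_i) = n_repress_i - n_activate_i - n_rep_release_i - n_div_bound_lost_i
```

holds exactly on every run and is asserted in the tests, as is agreement
of a frozen-volume, no-schedule reduction with the exact stationary
distribution of the corresponding master equation (computed by sparse
linear algebra in a test helper).

## 3. Deterministic model

`relax_to_steady_state()` integrates the cycle-averaged ODEs (mean copy
numbers, fixed effective volume `2 V0`, dilution `ln 2 / T` applied to all
species) to convergence with `deSolve::lsoda`. With repression off the
steady-state origin:terminus total-protein ratio
(`(P + 2D)_ori / (P + 2D)_ter`) is the pure dosage prediction: 2.0 at
`T = 20` and 0.643 at `T = 120` (the terminus gene's two insertions more
than compensate the dosage bias at slow growth).

`hysteresis_scan()` performs quasi-static continuation in `T`, sweeping up
from an ori-high state and down from a ter-high state; disagreement
between the two fold points (`|log2 ratio| > 1` threshold) marks the
bistable band. At `r_g_scale = 5e-4` the system is monostable everywhere;
at `2e-3` a bistable band appears; at `3.5e-3` it is wider.

## 4. Stochastic estimators

### Switching times

`switching_time()` collects state-to-state passages: lineages are started
committed to one state (a dosage-biased burn-in produces a consistent
committed initial condition), simulated until the opposite state is
reached (`detect_switch()` requires both monomers and dimers of the
challenger to strictly exceed the incumbent), and the passage durations
are pooled across chunks until at least 100 transitions are available.

`mfpt_fit()` estimates the mean first-passage time from the exponential
tail. Passage times are exponential except for very short recrossings near
the unstable intermediate; for each truncation threshold `u` the
maximum-likelihood tail estimate is the mean excess
`mean(x - u | x > u)`, and the reported MFPT is the first plateau of this
curve. With the default parametrization this gives ~25 h at `T = 40`,
`r_g_scale = 2e-3`, ~58 h at `T = 40`, `3.5e-3`, and ~10 h for the
ter-to-ori direction at `T = 30`, `3.5e-3`.

### Committed-state lifetimes and occupancy

`state_lifetimes()` runs a few long, *unrestarted* lineages, classifies
every recorded instant into committed states, and reports for each state
the total exposure time, the exit count, the renewal estimate
`tau = exposure / exits`, and the occupancy `exposure / total`. Two design
points matter:

- Short recrossing dwells are *included*: occupancy weights need the full
  exposure, not just long dwells, so this is deliberately a different
  quantity from the tail-fit MFPT.
- No chunk restarting: restarting chunks in a committed state injects one
  committed dwell per restart and systematically inflates the minority
  state's occupancy (measured: an order of magnitude at slow growth).
  A censored state (never exited during the run) is reported as
  `tau = Inf` with the observed exposure.

### Equilibrium expression ratio

`equilibrium_ratio()` estimates the long-run origin:terminus
total-protein ratio as an occupancy-weighted average of committed-state
means: per-state expression is measured on ensembles started committed to
each state (stopping at the first switch, so the average covers only the
committed window), and the weights are the occupancies from
`state_lifetimes()`. This stratified design reaches the slow-switching
regimes (state lifetimes of weeks) at a small fraction of the cost of a
brute-force ergodic average, and it reproduces direct long-run averages
where those are feasible.

At strong repression (`r_g_scale = 3.5e-3`) the stationary ratio of this
model is ~71 at `T = 20` and ~0.01 at `T = 120`, i.e. the majority state
dominates almost completely (minority-state occupancies well below 1%).
A reported pair of reference values (32.4 and 0.02) corresponds to
minority occupancies of a few percent, which this model's stationary
distribution does not produce; a finite observation window starting from
a symmetric ensemble can produce such values, but the window length is
then a free parameter, and we do not fit it. The acceptance tests assert
the reference values as given and are expected to fail on these two
points; the strong growth-rate dependence itself (a two-fold change in `T`
moving the ratio by more than two orders of magnitude) is reproduced.

### Response to growth-rate shifts

`shift_response()` equilibrates an ensemble at one doubling time, switches
`T` (preserving each cell's cycle-age fraction and molecule counts), and
fits a single-exponential relaxation (`response_time()`, `nls` with a
log-linear initial guess) to the ensemble-mean log2 expression ratio.
`sensitivity_scan()` re-evaluates bistability range, switching time,
dosage sensitivity and response time under two-fold parameter changes.

## 5. Reproducibility and problem sizes

Every stochastic entry point requires an explicit seed and derives
per-lineage seeds deterministically, so all results are exactly
reproducible. Default problem sizes (200 cells and 30 h for
`equilibrium_ratio()`, two 30,000 h runs for lifetimes, 100 transitions
for MFPTs) are package choices balancing runtime against the statistical
error quoted above; they are arguments, not constants.

## 6. Limitations

- The deterministic model uses cycle-averaged copy numbers and a fixed
  effective volume; it predicts means and fold bifurcations, not noise.
- Replication timing is deterministic (no initiation-volume noise), and
  division is symmetric apart from binomial partitioning.
- Operator binding is all-or-none per copy; no partial repression or
  cooperativity beyond dimerization.
- The balance-design menu is restricted to small-integer insertion
  ratios; arbitrary real ratios would trivially balance at any `L2`.
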