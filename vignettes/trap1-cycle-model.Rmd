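---
title: "Modeling the sequential, asymmetric ATPase cycle of TRAP1"
author: "trapcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the sequential, asymmetric ATPase cycle of TRAP1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapcycle)
```

# The model

TRAP1 is a homodimeric, ATP-driven chaperone. ATP binding stabilizes an
N-terminally dimerized **closed** state that is conformationally
*asymmetric*: one protomer arm is buckled, the other straight. The package
encodes the cycle as a continuous-time Markov chain on dimer states
`(conformation, nucleotide on protomer 1, nucleotide on protomer 2,
buckled protomer)`:

1. **Closure.** The open ATP/ATP dimer closes at `k_close`. ATP binding is
   folded into this step: all assays modeled here run at saturating
   nucleotide (500 µM ATP is well above the closure half-max), so binding
   is never rate-limiting and a separate binding step would be
   unidentifiable. Buckling is assigned by a fair coin — closure into the
   strained state traps either protomer with equal probability, which is
   what the roughly equal 22 Å / 41 Å conformer populations of the
   wild-type closed state report.
2. **First hydrolysis.** Only the buckled protomer is hydrolysis-competent
   in solution (`k_hyd_buckled`); the straight protomer's rate
   `k_hyd_straight` defaults to 0 and is exercised only in crystal mode,
   where the in-lattice timecourse shows it is much slower but nonzero.
3. **Asymmetry flip.** Phosphate release drives an exchange of buckled and
   straight roles while the dimer stays closed (`k_flip`, first order,
   with `Inf` = instantaneous as an option). The flip places the remaining
   ATP on the buckled arm, licensing the second hydrolysis. The kinetics of
   this step have not been measured; the default simply makes it fast
   relative to hydrolysis.
4. **Second hydrolysis and reopening.** The ADP/ADP dimer reopens at
   `k_open_dd`; all other closed states reopen only through a small leak
   `k_open_leak` (default 0 — the hemi-hydrolyzed dimer's reopening is very
   slow but not strictly zero).

## Buckling exchange in the ATP/ATP closed state

The rate set includes `k_swap`, a symmetric buckled/straight exchange
confined to the pre-hydrolysis ATP/ATP closed state. It is required by the
single-turnover phenotype of the hemi-dead (+/E115A-like) heterodimer: that
construct hydrolyzes **exactly half** of its bound ATP, which means every
dimer — including the half that initially closed with the dead protomer
buckled — eventually presents its competent protomer in the buckled
position. A frozen one-shot coin would stall a quarter of the ATP
unhydrolyzed (asymptote 0.25, not 0.5). Symmetric exchange preserves the
50:50 conformer partition of the ATP/ATP state exactly, and because it is
confined to the pre-hydrolysis state it cannot violate sequentiality: after
the first hydrolysis, asymmetry changes only through the Pi-driven flip.
Any `k_swap > 0` gives the same asymptote; the default only sets how fast
the trapped half re-equilibrates.

## Protomer variants

* `variant_hemi_dead()` — one protomer binds but cannot hydrolyze ATP
  (active-site E115A-like). Its hydrolysis edges are removed; with no leak,
  the post-flip hemi-hydrolyzed closed state becomes the single absorbing
  state, reproducing closed-state accumulation under turnover and the 0.5
  single-turnover asymptote.
* `variant_sensor_broken()` — one protomer has lost the γ-phosphate-sensing
  middle-domain arginine (R402A-like) and is pinned to the straight,
  ADP-mimicking conformation; its partner is buckled in every closed state.
  This idealizes the observed near-deterministic partitioning of the
  hemi-hydrolyzed mimic; the real mutant's residual flexibility and its
  mildly elevated steady-state ATPase are not modeled.
* `variant_dead_dead()` — both sites dead; a negative control.

## Engines

`simulate_ssa()` is an exact Gillespie simulation of independent dimers
(vectorized over dimers; per-run integer seed, bit-reproducible).
`simulate_master()` solves the master equation `dP/dt = P Q` on the same
graph with `deSolve::lsoda` (`rtol 1e-10`, `atol 1e-12`; probability
conservation is checked to 1e-9), plus an integrated hydrolysis-flux
counter for cumulative Pi. Having two engines on one graph gives a
cross-validation: SSA occupancies must match the master equation within
Monte-Carlo error, which the test suite asserts at 10⁴ dimers for all
variants.

Operating modes change the boundary behavior, not the chemistry:
multiple-turnover resets any reopened dimer to the ATP/ATP open state
(nucleotide exchange at saturating ATP is treated as instantaneous);
single-turnover forbids pool rebinding — ADP is released on reopening and
any remaining ATP re-equilibrates between the two sites at the next
closure, which is what produces the slow second phase of the hemi-dead
construct when a reopening leak is allowed; crystal mode freezes closure,
buckling exchange, flip and reopening (the lattice fixes both the closed
state and the conformation — consistent with the absence of conformational
changes in the aging crystals), leaving only the two hydrolysis rates.

## Rate defaults

Rates carry explicit time units; two regimes provide defaults:

| rate | `"mg"` (per min) | `"mg_free"` (per hr) | origin |
|---|---|---|---|
| `k_close` | 0.16 | 6.95 | measured closure rates |
| `k_hyd_buckled` | 1.5 | 0.5808 | Mg-free value measured; Mg value chosen so closure is rate-limiting |
| `k_hyd_straight` | 0 | 0 | unresolved in solution; crystal mode sets it |
| `k_flip` | 10 | 10 | unmeasured; fast relative to hydrolysis |
| `k_swap` | 2 | 10 | unmeasured; fast relative to hydrolysis |
| `k_open_dd` | 2 | 2 | fast reopening after completion |
| `k_open_leak` | 0 | 0 | hemi-hydrolyzed reopening is very slow |

Only `k_close` (both regimes) and the Mg-free `k_hyd_buckled` are measured
quantities. The remaining `"mg"` defaults are model choices fixed once: the
wild-type steady-state turnover (0.19 min⁻¹) is close to the closure rate
(0.16 min⁻¹), so everything downstream of closure must be faster; the exact
values only set how low the wild-type closed-state steady state sits. None
of the package's quantitative claims (asymptotes, partitions, orderings)
depend on them.

# Assay models

**Exponential fits** use `offset + A(1 − e^{−kt})` for buildup and
`offset + A e^{−kt}` for decay, each optionally with a linear drift term;
the measured traces are fit in both directions but the functional form is
fixed here explicitly. Starting values are derived from the data (offset
and amplitude from the range, `k` from the half-rise time) and the
optimizer is Levenberg–Marquardt (`minpack.lm::nlsLM`, `k ≥ 0` bounded).
A non-converged fit is returned flagged, with a warning, rather than
hidden. Flat traces short-circuit to `amplitude = 0` — there is no rate to
estimate.

**Initial rates** implement "slope within the linear regime" as a concrete
rule: the longest prefix of the trace whose linear fit keeps
`R² ≥ 0.995` (at least 5 points), falling back to the first 5 points with a
warning. The threshold is a package choice; tighter thresholds shorten the
window and track the t = 0 derivative more closely, at the price of noise
sensitivity.

**The phosphate-sensor calibration** fits only standards strictly below
the 20000 RFU detector-linearity cap and reports exclusions; applying it
inverts the line and NAs out capped trace points.

**The mixing model** uses the binomial-weight convention
`V = V_wt f² + V_mut (1−f)² + V_het · 2f(1−f)`. The convention question
arises because the heterodimer term can be written with or without the
binomial factor 2; only the factor-2 form makes "independent sites"
(`V_het = (V_wt + V_mut)/2`) collapse the quadratic to the straight line
between the homodimer anchors, which is how the independence expectation is
always drawn. The literal form remains available behind
`include_factor_two = FALSE` (it only rescales `V_het`). Dimer exchange is
assumed complete (the mixing protocol pre-incubates for 1.5 hr) and the fit
is unweighted — replicate SDs are carried but not used, since the source
protocol does not state a weighting.

**DEER decomposition** starts from P(r) — dipolar-signal processing is out
of scope — and fits a two-Gaussian mixture by bounded least squares on the
grid. Gaussians are a parsimony choice, not a physical claim about peak
shapes. Initialization takes the two highest local maxima at least 5 Å
apart; for unimodal inputs a moment-based split-peak fallback is used and
the result is flagged degenerate when the centers land within 2 Å.
Component order (`µ1 ≤ µ2`) is enforced after fitting, which resolves the
mixture's label-swap symmetry deterministically. Conformer assignment maps
each component to the nearer of the 22 Å (buckled) / 41 Å (straight)
references; both are overridable because the ~8 Å maleimide linker offsets
absolute distances.

**Water-pocket analysis** identifies waters by oxygen only and uses a
strict `< 5 Å` cutoff (configurable to `≤`); the site atom set (in
practice the β/γ-phosphate phosphorus atoms plus bonded oxygens) is
supplied through the atom-role table rather than hard-coded. Counting is
invariant under rigid motion, so alignment (in-package Kabsch with the
proper-rotation sign correction, cross-checked against `bio3d::fit.xyz` in
the tests) matters only for positional density maps. Dwell bookkeeping
defaults to gap tolerance 0 — a single excursion ends a dwell — with a
configurable tolerance, and each in-cutoff frame contributes one frame
interval; non-uniform frame spacing falls back to timestamps with a
warning. The cell-list neighbor search is exact (asserted equal to brute
force), not approximate.

# Synthetic data

The generators produce every input the analyses consume, under the study
conditions: FRET channels are affine maps of the model's closed fraction;
phosphate release uses the initial-rate regime
`d[Pi]/dt = k_spont·atp0 + 2 k_cat_site [dimer]` (only a small fraction of
the 500 µM pool turns over within the assay window) rendered through the
standard curve with the linearity cap; mixing tables come from the binomial
model with triplicate Gaussian noise; P(r) is a noisy renormalized
mixture; and trajectories place telegraph-process waters around two pocket
sites, the buckled site drier (stationary occupancy
`k_on/(k_on + k_off)`, default 1/11 vs 1/2) with shorter dwells (mean
`1/k_off`, 2 ns vs 10 ns), sampled every 3 ns.

What the generators deliberately do **not** emulate: detector artifacts,
photobleaching or drift; correlated or heteroscedastic noise; incomplete
dimer exchange; real MD solvation structure (periodic boxes, hydrogen
bonding, the Mg²⁺-coordination shell). Passing round-trip tests therefore
demonstrates that the estimators are correct and calibrated under their own
assumptions — not that those assumptions hold for any particular
instrument's data.

# Problem sizes and numerics

The test suite and acceptance script use sizes chosen to make Monte-Carlo
assertions sharp while keeping runs interactive: 10⁴ dimers for
stochastic/deterministic cross-checks and the 50:50 partition (binomial SE
0.005), 100-seed recovery studies for the kinetic and mixture fits,
150–200-frame trajectories with 60–200 waters. Statistical assertions are
stated against their exact sampling distributions — e.g. a 3-SE recovery
claim whose SE comes from 10 residual degrees of freedom is t-distributed
and is asserted as a coverage rate over seeded tables, not as a hard
per-table bound.

# Known limitations

* The cycle model is phenomenological: no spatial detail, no client or
  cochaperone coupling, no temperature dependence of the closure barrier.
* The γ-sensor variant is idealized as a hard conformational pin; the real
  mutant retains some flexibility and slightly elevated activity.
* The flip and swap rates are unmeasured; only their being fast relative
  to hydrolysis matters for the reproduced observables.
* The mapping between per-dimer cycle flux and the measured steady-state
  rate is exposed through both rate bases (`convert_rate_basis()`), since
  the published comparison of closure (0.16 min⁻¹) with turnover
  (0.19 min⁻¹) does not state its basis.
* Crystal-mode rates are user-set illustrations; in-lattice rates are not
  asserted to equal solution rates.
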