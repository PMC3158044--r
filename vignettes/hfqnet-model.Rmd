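---
title: "The hfqnet kinetic model: assumptions, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hfqnet kinetic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hfqnet)
```

## The model and its assumptions

`hfqnet` simulates duplex formation between `n` sRNA species and `m`
target-mRNA species that compete for a shared pool of Hfq hexamers, as a
deterministic mass-action ODE system. The assumptions that define the
model's scope:

* **One RNA of each class per hexamer.** Hfq carries at most one sRNA and
  one mRNA (separate binding sites). Shared-site competition, Hfq
  dodecamers and inter-hexamer RNA exchange are outside the model;
  `count_complex_types(shared_sites = TRUE)` only reports the shared-site
  combinatorics of complex *types*, not their dynamics.
* **Lumped annealing.** Strand exchange and duplex release are a single
  first-order step `HS_iT_j -> D_ij + H` with rate `k5(i,j)`. Hfq is
  recycled at this step. A pair is cognate when `k5 > 0`.
* **No duplex rebinding.** In vivo most duplexes are degraded quickly, so
  `D_ij` is only removed by degradation.
* **Uniform turnover.** Production is constant per species; degradation/
  dilution is one global first-order rate `beta` (default 1 time⁻¹, which
  also defines the RNA lifetime `1/beta`). `beta_overrides` exists solely
  for sensitivity checks such as faster free-sRNA turnover.
* **Unitless magnitudes.** Concentrations and time are model units; the
  preset regimes span rate constants from 1e-5 to 1e8, which is why a
  stiff solver is a hard requirement rather than an option.

The state layout is fixed (`H`, `S`, `T`, `HS`, `HT`, `HST` row-major,
`D` row-major) so that serialized states are reproducible.

## Composite parameters

Nine composite parameters (`?compute_y_metrics`) summarise a pair's
elementary constants; they are the coordinates in which the preset
regimes are defined. The defaults used by the scenario library:

| parameter | meaning | default | rationale |
|---|---|---|---|
| `y2` | association magnitude (conc⁻¹·time⁻¹) | `10^2.5` | centre of the explored `10^0.5–10^4.5` range |
| `y5`/`y9` | dissociation magnitude (time⁻¹) | `1` (slow) / `1e4` (fast) | brackets the degradation rate `beta = 1` |
| `k5` | annealing + release (time⁻¹) | `1e3` | centre of the explored `1–1e6` range |
| `y7` | cognate selection | `0.1` when enabled | one decade of preferential cognate affinity |
| `y8` | non-cognate exclusion | `10` when enabled | one decade of non-cognate destabilisation |

Two inversions are under-determined and resolved by convention:

* `dissociation_from_y(y5, y6)` splits two constraints over four
  constants symmetrically (`kneg1 = kneg2`, `kneg3 = kneg4`), treating
  sRNA and mRNA alike; regimes that pin all four equal are expressed as
  `y6 = 1`.
* Cognate selection (`y7`) and non-cognate exclusion (`y8`) can each act
  through association or dissociation constants. **Selection defaults to
  the association route** (diagonal `k3`,`k4` scaled by `y7^-2`): in the
  network regimes the cognate ternary complex empties through `k5`, which
  is orders of magnitude above its dissociation constants, so scaling
  those constants down is dynamically inert — only faster cognate
  association changes the steady state. **Exclusion defaults to the
  dissociation route** (off-diagonal `kneg3`,`kneg4` scaled by `y8^2`),
  i.e. non-cognate RNAs destabilise one another, which matches the
  mechanism the unpartnered-pool design attributes to exclusion. Both
  routes are selectable per mechanism (`y7_route`, `y8_route`). Note that
  the association route deliberately changes the focal pair's `y2`/`y4`:
  preferential cognate association *is* pair-restricted positive
  cooperativity.

## Steady-state numerics

The reference solver integrates from the all-zero state (a cell before
induction) with `deSolve::lsoda` and the analytic Jacobian. The horizon
is 100 RNA lifetimes; convergence requires the solution at 90% and 100%
of the horizon to agree per species within `1e-10` absolute *or* `1e-8`
relative (the relative guard matters when concentrations reach `1e7`,
where a 1e-10 absolute criterion would sit below double-precision
resolution of the integrator's own error). Failing that, the horizon is
doubled up to six times and the failure is reported explicitly
(`converged = FALSE`), never silently. The all-zero start is justified
empirically: this reaction class showed a single steady state in all
regimes we probed (cold-started root finding and rescaled starts agree
with integration), and multistability is not searched for.

Sweeps (`hfq_sweep`) solve each grid point by damped Newton iteration
warm-started from the previous point's solution, validated against the
mass-action residual (`<= 1e-8 * max(state)`) and non-negativity, with
automatic fallback to full integration. This continuation strategy is
5–50x faster than integrating every point and is bitwise-checked against
the integrator in the test suite. `steady_state_oracle` is an
*independent* cross-check — Levenberg–Marquardt root finding
(`minpack.lm`) from multiple starts — kept separate from the solution
path it validates.

## Output metrics and conventions

* `percent_duplex` divides by the focal mRNA's total pool
  (`T + HT + ΣHST + ΣD`), which equals `alpha_T / beta` at steady state;
  the identity is verified rather than assumed.
* `relative_hfq` is total Hfq over the focal pair's total mRNA, the
  natural x-axis for titrations (1 means Hfq matches the focal mRNA).
* **Bounds and robustness.** The lower/upper bounds are the outermost
  crossings of the 10% duplex threshold, interpolated linearly in
  `log10(relative Hfq)` between the bracketing grid points (the source
  figures do not state a read-off rule; log-linear interpolation resolves
  bounds well below the 0.1-decade grid spacing). Curves that never reach
  the threshold report `robustness = 0` with `defined = FALSE`. Crossings
  at a grid edge warn, because the true bound then lies outside the sweep.
* **Percent Hfq sequestered** is defined as bound Hfq outside cognate
  ternary complexes (singly-bound plus non-cognate ternary): Hfq that is
  occupied but cannot currently produce a duplex. This axis has no
  published formula; the chosen convention reproduces the described
  qualitative behaviour and is stated here as a convention.

## Scenario design choices

Where a design's exact constants are not published, the scenario presets
choose values from the printed value sets that are consistent with the
design's stated outcome, and everything is overridable:

* **Isolation vs network (`fig6`).** `y2 = 10^0.5`, `y9 = 1`, `k5 = 1`
  (slow binding and annealing). Under these constants a lone pair exceeds
  10% conversion while five identical pairs never reach it — the
  competition collapse this design demonstrates. With the faster defaults
  (`y2 = 10^2.5`, `k5 = 1e3`) a five-pair network still converts ~40% and
  no collapse occurs, so those cannot be this design's conditions.
* **Stability mixes (`fig9`).** Each RNA carries its class's dissociation
  rate (`1` stable, `1e4` unstable); ternary dissociation of an RNA
  follows that RNA's class. Stable pairs come first in the network.
* **Overproduction (`fig12`).** sRNA-1 production is scanned log-spaced
  over 1–100x the common rate (the published axis is graphical only).
* **Unpartnered pool (`fig13`).** The 100 unpartnered mRNAs are
  represented as one aggregate species with 100x production — identical
  mass-action dynamics at identical constants, at a fraction of the cost.
  The exclusion variant solves `kneg_base = y9 * y8^(-2/3)`,
  `kneg_starred = y9 * y8^(4/3)` so that `y8 = 10` and `y9 = 10` hold
  simultaneously. The affinity tilt scales `(k1, k4, k4*)` and
  `(k2, k3, k3*)` reciprocally, holding their geometric mean fixed.
* **Branch-bias imbalance (`fig11`).** Production ratio 5:1 to 1:5 at
  constant combined production, `y3` in `{1e-8, 1, 1e8}` with
  `y1 = y4 = 1` and no dissociation (the regime family in which branch
  bias was introduced).

## Known limitations

* The free-sRNA degradation sensitivity check (`s1`) shows a regime
  dependence worth knowing about: the upper bound and the curve shape are
  essentially unchanged by 10x free-sRNA turnover, but the *lower* bound
  shifts right by up to a decade. Near the lower bound Hfq is scarce and
  the capture flux `k1*[H]` is comparable to degradation, so a produced
  sRNA is likelier to die free; the shift only vanishes when binding is
  fast enough (`y2` well above `1e5`) that capture outruns degradation.
  The test suite computes and reports the per-regime shift.
* Continuation sweeps assume the steady state varies continuously along
  the Hfq grid; the residual/non-negativity validation plus integration
  fallback guards this but a genuinely multistable variant of the model
  would need the integrator everywhere.
* The model is deterministic; copy-number noise, explicit RNase/ribosome
  species, spatial effects and Hfq binding to DNA or proteins are out of
  scope.

## Problem sizes

The shipped tests and the acceptance script use single-pair titrations at
10 grid points per decade over `alpha_H = 1e-5..1e7`, network regimes at
`n` up to 20 (881 ODE states) at 5 points per decade, and 50+20 randomly
generated small networks for the conservation and oracle cross-checks;
the full suite solves a few thousand steady states.
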