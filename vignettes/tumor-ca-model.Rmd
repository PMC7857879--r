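---
title: "A multiscale cellular-automaton model of avascular tumor growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiscale cellular-automaton model of avascular tumor growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 4)
library(tumorca)
```

## The model

`tumorca` simulates avascular solid-tumor growth as a stochastic cellular
automaton on a two-dimensional square lattice, coupled to five continuous
concentration fields. Each lattice site holds one of four cell states:

| code | state | behavior |
|------|-------|----------|
| 0 | normal tissue / empty space | consumes oxygen and glucose at a reduced rate (empty sites are inert); can be displaced by a tumor daughter cell |
| 1 | proliferating tumor cell (PC) | consumes nutrients, produces acid, attempts mitosis |
| 2 | quiescent tumor cell (QC) | nearly metabolically inactive; can recover or die |
| 3 | necrotic cell (NeC) | absorbing state; keeps acidifying its surroundings |

The five fields are oxygen and glucose (mMol), hydrogen ions (mol/L scale, so
`pH = -log10(h)`), and dimensionless growth and inhibitory factors. The
growth/inhibitory factors are transported and consumed/produced but
deliberately gate no transition rule: the model isolates the effect of
oxygen and acidity on growth, and carries the two signalling fields only as
observables.

### Metabolite transport

Diffusion uses a block-cellular-automata (BCA) scheme: the lattice is tiled
by 3x3 blocks and each field value relaxes toward its block mean,

```
u[t+1] = alpha * A[t] + (1 - alpha) * u[t] - f,
```

where `A` is the block-average lattice, `alpha` in (0,1) is a per-field
mixing weight, and `f` is the local consumption (positive) or production
(negative). The partition origin shifts down one row and right one column
each iteration, cycling through three distinct partitions so mass crosses
block boundaries; boundaries are periodic. Block averaging conserves mass
exactly, so total mass changes only through `f` and through medium
replenishment.

The mixing weights are derived from the physical diffusion coefficients as
`alpha_i = alpha_max * (D_i / max(D))^alpha_gamma`, which preserves the
monotone relation "faster-diffusing species mix more" while letting
`alpha_gamma` compress the spread between species whose tabulated
coefficients differ by orders of magnitude (the signalling factors would
otherwise effectively never move). `alpha_gamma` is one of the calibrated
scale constants discussed below.

### Cell responses and transitions

Cell fate is driven by local thresholds, checked most-lethal first:

* necrosis when oxygen < `O2_thre/2` (0.01 mMol), glucose < `gl_thre/2`
  (0.03 mMol), or pH < 6.0;
* quiescence when oxygen < `O2_thre` (0.02 mMol), glucose < `gl_thre`
  (0.06 mMol), or pH < 6.4;
* otherwise proliferation is permitted. Below `O2_thre` a cell additionally
  switches to anaerobic glycolysis: glucose uptake and acid output are
  multiplied up and oxygen uptake damped.

A proliferating cell that is permitted to divide does so with probability

```
p1 = p0 * (1 - r/Rmax)                 (mutant phenotype)
p2 = phi0 * (n0/8) * (1 - r/Rmax)      (nonmutant phenotype)
```

with `p0 = 0.7`, `phi0 = 0.6`, `r` the distance from the seed, `Rmax = 37.5`
the maximum tumor extent, and `n0` the number of state-0 Moore neighbors.
The neighbor count is normalized by the neighborhood size 8 so that `p2` is
a probability; the literal product `phi0 * n0` can exceed 1 and would also
make nonmutant cells divide faster than mutants, contradicting the model's
own phenotype-selection behavior (raising `Nmm` shrinks the tumor). One
daughter keeps the parent site, the other replaces a uniformly chosen
state-0 neighbor. A mutant parent's daughter is nonmutant with probability
`Nmm`; nonmutant parents breed true. A cell that cannot divide (blocked or
failed draw) stalls; after `stall_limit` consecutive failures it falls
quiescent.

Tumor geometry follows the multicellular-layer relation

```
Wp = b * Rt^(2/3),    Rn = Rt - (a + Wp),    a = 0.42, b = 0.11,
```

with `Rt` the mean distance from the seed to the boundary tumor cells.
Quiescent cells recover to proliferating when they sit within `Wp` of the
tumor radius **or** when all three metabolic factors are above the
quiescence thresholds; otherwise, quiescent cells deeper than `Rn` turn
necrotic. Access to sufficient nutrients deliberately overrides position
here: because `a + Wp` is only ~1.6 lattice units, the alternative order
(geometric death first) kills every quiescent cell deeper than ~1.6 sites
within one step regardless of its microenvironment, which collapses the
living rim to a sliver and makes the observed growth/necrotic fractions
unreachable. With recovery checked first, necrosis claims exactly the
nutrient-starved interior, which is the biological reading.

Necrotic cells are absorbing. Normal cells under lethal conditions undergo
apoptosis and leave empty space (a config toggle routes them to the necrotic
count instead), so the necrotic core counts only tumor-derived cells.

### Iteration order

Each iteration executes: (1) BCA diffusion with metabolic sinks, (2) medium
replenishment, (3) necrosis from the updated fields, (4) one geometry
computation, (5) quiescent-cell updates against that geometry, (6)
proliferating-cell updates in a freshly shuffled random order (immediate
quiescence where triggered, otherwise a mitosis attempt). The shuffle
avoids directional growth bias; a single seeded RNG stream makes runs
bit-reproducible.

The medium is perfused: at every normal/empty site, oxygen and glucose are
floored at 95% of their fresh-medium backgrounds (0.8 mMol, 5.5 mMol) and
hydrogen ions are washed out to at most the pH-7.4 background divided by
0.95. A boundary-only perfusion mode exists for experiments with an explicit
nutrient boundary. Whether acid removal should extend into the tumor is
ambiguous in avascular settings; this implementation removes acid in the
medium only.

## Parameters that matter, and the calibrated scale constants

The biological constants (thresholds, diffusion coefficients, uptake rates,
division constants, backgrounds) are tabulated laboratory values and are
the defaults of `tumor_params()`. Five scale constants have no laboratory
value because they convert between per-cell laboratory units and
per-site-per-iteration lattice units; they were calibrated once against the
reference experiment's endpoint behavior and then frozen:

* `rate_scale = 1.55e14` converts Mol/cell/s uptake rates to mMol per site
  per iteration (one proliferating cell then consumes ~4.5% of the oxygen
  background per iteration).
* `h_scale = 3e-6` additionally damps the H+ increment: tissue is strongly
  pH-buffered, so free-proton accumulation is a tiny fraction of the acid
  load. Without it no single conversion factor can serve both the nutrient
  fields (which must change by order 1 mMol) and the proton field (which
  must stay within ~1e-7 mol/L to keep pH in the physiological 6.8-7.4
  window).
* `gf_scale = 1e-3` plays the same role for the dimensionless signalling
  fields, whose tabulated rates are in different units (cm^3/h).
* `alpha_max = 0.9`, `alpha_gamma = 0.05` fix the mixing weights
  (oxygen 0.83, glucose 0.90, H+ 0.81, factors 0.48).
* `stall_limit = 3` failed mitosis attempts before quiescence, and
  `quiescent_factor = 0.2` (quiescent metabolism relative to proliferating),
  `k_gl_anaerobic = 5`, `k_H_anaerobic = 2`, `k_o2_anaerobic = 0.1`
  (anaerobic-glycolysis multipliers).

Two calibration trade-offs are worth recording. First, oxygen consumption
and oxygen mixing jointly set both when the core first turns hypoxic (hence
when necrosis begins) and how thick the oxygenated rim is (hence the final
growth fraction); strong consumption buys early necrosis at the cost of a
thin rim. The shipped defaults favor the rim thickness, the saturation
level, the fraction endpoints and the critical point; first necrosis then
falls near iteration 46 rather than in the low twenties, at a tumor radius
of ~20 lattice units. Both cannot be had simultaneously under this rule
set: reaching a radius of 15+ lattice units by iteration ~25 would need the
rim to advance nearly one site per iteration, while the division
probabilities cap the front speed at roughly half that. Second, `dt_days =
0.1` is the nominal duration of one iteration; it tensions with reading an
iteration as one full cell cycle (~1 day), and the model makes no claim of
biological consistency here — it only scales the time axis of plots.

## The default experiment

```{r run, eval = FALSE}
p <- tumor_params()          # 101 x 101 lattice, Nmm = 0.2, 200 iterations
sim <- run_simulation(p, seed = 1)
summary(sim)
plot(sim, "counts")
plot(sim, "fractions")
```

A single mutant proliferating cell is seeded at the lattice center on
uniform background fields. The population grows near-exponentially, the
core turns hypoxic and then necrotic, and the proliferating count saturates
(Gompertz-like) while the necrotic core expands. `summary()` reports the
endpoint fractions, the proliferating-cell plateau (mean over the last 20
iterations), the critical point (first iteration with at least as many
necrotic as proliferating cells), the first necrotic iteration and the
radius at which it occurred, and the lattice pH floor.

Replicate experiments (`run_replicates()`) and the phenotype sweep
(`sweep_nmm()`) rerun the same protocol over seeds and over the `Nmm` grid
0, 0.1, ..., 1; the sweep also returns pH-layer occupancies (boundaries
7.2, 7.0, 6.8) and oxygen-difference layers against the matching `Nmm = 0`
run with the same seed.

## What the generator does and does not emulate

All inputs are synthetic: the initial condition is the uniform-background,
single-seed configuration described above (an optional multiplicative
jitter honors a randomized-background reading of the initialization, and is
off by default). The simulation reproduces the qualitative structure of
avascular spheroid growth — layered proliferative rim / quiescent shell /
necrotic core, hypoxia-correlated acidity, center-to-edge gradients,
saturating growth. It does not model vasculature, immune response, therapy,
migration or metastasis, mechanical pressure, or 3-D geometry, and lattice
units map to physical lengths only through an arbitrary scale. Passing
tests therefore validate the automaton's internal rules and reproducibility,
not quantitative agreement with any particular in-vivo system.

## Numerical choices and degenerate inputs

* Lattice side `ncell = 101` with the seed at the center: `Rmax = 37.5`
  fits with margin. Sizes not divisible by 3 are tiled with wrapped partial
  blocks, which keeps the partition exact and mass conserved.
* Consumption is truncated to the locally available concentration and the
  update clamps at zero, so fields are non-negative by construction.
* `pH = -log10(h)` guards against `h = 0` with a floor of 1e-300 before
  taking logs (relevant only for artificially zeroed fields).
* A tumor that fills the lattice has no boundary cells; the radius then
  falls back to the mean distance over all tumor cells (reachable only in
  deliberately undersized test lattices).
* A single-cell tumor has radius 0, `Rn` clamps at 0, and the critical
  point is `NA` when the counts never cross.
* The division probability is clamped to [0, 1] and is exactly 0 at and
  beyond `Rmax`; a daughter placed diagonally from a parent just inside
  `Rmax` can sit at most `Rmax + sqrt(2)` from the seed.
* Test and example runs use reduced problem sizes (lattice 33-61, 20-60
  iterations); the replicate analyses in the acceptance checks use the full
  101 x 101 x 200-iteration protocol with 20 seeds.

## Known limitations

* The spatial scale of one site and the cell count it represents are not
  pinned to physical units; radii are reported in lattice units.
* The rules coupling cell metabolism to the automaton (the modulation of
  uptake by cell type, the anaerobic multipliers) use round literature-free
  defaults exposed in the configuration, since no tabulated values exist
  for them on the lattice scale.
* Growth and inhibitory factors are observables only.
* The first-necrosis timing and the radius at first necrosis cannot be made
  simultaneously consistent with the layered-fraction endpoints under this
  rule set (see the calibration discussion above); the shipped defaults
  document which side of that trade-off they take.
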