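---
title: "Quantifying perisomatic varicosity density: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying perisomatic varicosity density: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Enteric neurons receive synaptic input from varicose axons — beaded release
sites strung along fibres that weave between cell bodies in a ganglion. In
confocal reconstructions of immunolabelled wholemounts, each nerve cell body
can be rendered as a closed triangulated surface and each varicosity as a
point. The scientific question is whether particular axon populations (e.g.
sympathetic noradrenergic fibres marked by tyrosine hydroxylase, TH, or
enteric enkephalin-positive fibres, ENK) innervate particular ChAT/NOS-defined
neuron classes preferentially.

`perishell` answers this with a *shell density*: the number of marker-positive
points lying within ±1 µm of a cell's surface, divided by the volume of that
±1 µm shell, in varicosities per 1,000 µm³. Counting into the shell rather
than onto the surface tolerates reconstruction error and varicosities lodged
in surface clefts; dividing by shell volume makes the statistic independent of
cell size, which matters because the neuron classes differ severalfold in
volume.

## Geometry

**Signed distance.** Distances from points to a cell are minimum Euclidean
distances to any surface triangle, computed by an exact closest-point
decomposition per triangle with bounding-box pruning. The sign convention is
negative inside the cell (an arbitrary but fixed choice); the inside test is
ray-crossing parity with a deterministic sequence of retry directions for
numerically marginal rays. Points within 10⁻⁴ µm of the surface are treated
as *on* it: the parity test is ill-posed when the ray origin lies on a
triangle, and at that scale the sign carries no information.

**Shell membership** is |d| ≤ t with t = 1 µm by default, boundary inclusive
(a measure-zero choice fixed for determinism). For a watertight surface this
equals "unsigned distance to the surface ≤ t", which is how the compiled code
evaluates it.

**Shell volume** is estimated by voxel-centre counting: a grid of pitch
0.25 µm (configurable; required ≤ t/2) covers the mesh bounding box padded by
t, and a voxel counts if its centre lies within t of the surface. The
estimate converges to the exact shell volume as the pitch shrinks, though not
strictly monotonically — the error oscillates inside a shrinking envelope as
voxel centres move relative to the surface, and the property tests check that
envelope rather than per-halving monotonicity. At the default pitch the
radius-5 µm sphere fixture is within 0.5% of the closed form
4π/3[(r+t)³−(r−t)³]. The grid is anchored to the mesh's own bounding box, so
shell volumes are exactly translation invariant; under rotation they vary at
the few-tenths-of-a-percent level, which is the price of an axis-aligned
grid. Shells are *not* clipped to the imaged bounding box by default (the
`clip_to_bbox` option exists for sensitivity analysis); border cells are
instead excluded outright.

**Attribution.** Every spot is attributed to at most one cell — the cell
whose surface is nearest — and only if that distance is within t, so no spot
is ever double-counted. Exact ties go to the lexicographically smallest
`cell_id`, a deterministic rule that in practice only fires for duplicated
geometry. Spots whose nearest cell is excluded are *dropped*, not reassigned:
reassignment would hand the runner-up cell a spot that was not genuinely
closest to it.

**Meshes.** Input surfaces must be watertight. Construction runs one repair
pass: degenerate faces are dropped, winding is made consistent by flood fill,
inward-facing surfaces are flipped outward (enclosed volume must be
positive), and small boundary loops (≤ 12 edges) are filled by a centroid
fan. Larger openings — a hemisphere, a clipped cell — are treated as
irreparable and the cell is excluded, mirroring how imperfect reconstructions
are handled upstream. No smoothing is applied.

## Typing, exclusions and baskets

Cells are classed as ChAT+/NOS−, ChAT−/NOS+, ChAT+/NOS+ or ChAT−/NOS−.
Manual boolean calls take precedence; otherwise a channel mean intensity
above threshold calls the channel positive. Cells are excluded when manually
flagged (e.g. merged surfaces), when their mesh failed repair, or when their
bounding box comes within `border_margin` (default 0.5 µm) of the imaged
volume's face — a proxy for "cut off at the image edge".

A *basket* is a dense arrangement of varicosities encircling one cell body.
The package formalises the visual call with two thresholds on the spots
attributed to a cell: shell count ≥ 15 and angular coverage ≥ 1/3, where
coverage is the occupied fraction of 64 Fibonacci-sphere directional bins
seen from the cell centroid. The defaults were chosen so that an encircling
ring passes and a single-octant cluster (coverage ≤ 1/8) fails; both
thresholds are configurable and echoed in the output. One known limitation:
coverage saturates for any cell with many spots spread over the whole shell,
so on densely and uniformly innervated cells the criterion degenerates to a
count threshold — manual basket calls, when present in the label table,
therefore override automatic ones. Basket–cell-type association is tested
with the plain Pearson χ² (no continuity correction) on the (basket,
no-basket) × type table over included cells.

## The density model

Shell counts are overdispersed, so the model is a negative-binomial mixed
regression with log link and log shell volume as offset:

$$\log \mu_i = \beta_{c(i)} + a_{s(i)} + e_{s(i),c(i)} + b_{g(i)} + f_{g(i),c(i)} + \log V_i$$

with Count ~ NB(µ, φ) in the mean/shape parameterisation
(Var = µ + µ²/φ). Indices: c(i) the cell-type × marker combination (cell-mean
coding: one coefficient per combination, no global intercept, so
exp(β) × 1000 *is* a density per 1,000 µm³), s(i) the subject, g(i) the
ganglion nested in subject. The shape gets its own log-linear submodel over
the same six combinations, because TH and ENK counts need not share an
overdispersion level. Only the three well-populated cell types enter the
model; ChAT−/NOS− cells stay in basket and morphometry outputs but are too
few to model.

**Random effects.** Subjects and ganglia carry a shared intercept (a, b) plus
independent per-combination deviations (e, f) — a compound-symmetry
structure. This pools the level shift that all six combinations share (a
brighter or denser specimen raises every count) while still letting each
combination drift, which is what a correlated random-coefficient vector buys
at a fraction of its parameter cost; with seven subjects a free 6×6
correlation matrix would be essentially prior-driven anyway. Priors:
normal(0, 1) on mean and shape coefficients, half-normal(0, 1) on all
random-effect scales — weakly informative on the log scale in the same spirit
as the coefficient prior.

**Sampling and identifiability.** The posterior is sampled by MCMC (JAGS),
default 4 chains × 1,000 retained draws after 1,000 warmup. The flat
parameterisation has a ridge between the coefficients and the random-effect
means (only their sum is data-identified), so the population coefficients
are monitored in swept form, β*ₖ = βₖ + mean(a) + mean(b) + mean(e·ₖ) +
mean(f·ₖ); densities and ratios are computed from β* draws, which mix well.
Gelman–Rubin Rhat is reported for every monitored parameter and a warning
(not an abort) fires above 1.05; variance-component Rhats are the usual
laggards at small draw counts. The sampler is Gibbs/slice, so there is no
divergence diagnostic to report; the divergence field is `NA` by
construction.

**Estimands.** Per type × marker, the mean density is the posterior of
exp(β*) × 1000. Preferential innervation is read from density ratios
exp(β*ₐ − β*ᵦ), summarised as posterior median, equal-tailed 95% credible
interval (the package default interval type), and Pr(ratio > 1); the
`significant` flag marks intervals excluding 1. Three contrasts are reported
per marker: ChAT+/NOS− vs ChAT−/NOS+, ChAT+/NOS− vs ChAT+/NOS+, and
ChAT−/NOS+ vs ChAT+/NOS+.

**Morphometrics.** Surface area and volume are compared across the four
types with one-way ANOVA plus Tukey HSD. The unit of analysis defaults to
per-ganglion type means, since cells within a ganglion are not independent;
`unit_of_analysis = "cell"` is available and the choice is always recorded in
the output. Published degrees of freedom for this comparison are internally
inconsistent across measures, so no attempt is made to match any particular
df — the unit is stated instead.

## The synthetic generator

`generate_ganglia()` builds complete scenes with known ground truth so every
stage can be validated without imaging data. Defaults encode the target study
design: 7 subjects × 2 ganglia × ~35 cells (Poisson), type proportions
38/42/12/8%, per-type mean volumes 4,566/3,177/6,078/2,156 µm³, and true
shell densities per 1,000 µm³ of TH 7.43/5.59/6.02 and ENK 19.52/12.99/13.22
for the three modelled types (ChAT−/NOS− cells get background values of
5 and 12 — they never enter the density model, these just exercise the
exclusion path).

Choices the design left open, fixed once here:

* **Cell shape:** randomly oriented ellipsoids, axis ratios ~(1, 0.75, 0.6)
  jittered ±10%, icosphere subdivision 3 (facets of order 1 µm at cell
  size) — closed-form bookkeeping beats anatomical realism for truth
  tracking. Cells are placed on a jittered grid, which guarantees
  non-overlap; real ganglia pack tighter.
* **Within-type volume spread:** lognormal with CV 0.30, a typical
  cell-size spread.
* **Overdispersion:** NB shape φ = 3 per marker — visible overdispersion
  (variance ≈ µ + µ²/3) without drowning the type signal.
* **Random effects:** subject SD 0.2, ganglion SD 0.1 on the log scale —
  between-specimen staining variation large enough that ignoring the nesting
  would visibly miscalibrate intervals, small enough that recovery at 7
  subjects is feasible.
* **Baskets:** per-cell probability 0.10 (ENK) and 0.02 (TH) on ChAT+/NOS−
  cells only, with expected counts multiplied by 3. The generator writes its
  true basket flags into the label tables as manual calls. Because counts are
  multiplied for basket cells, the *marginal* mean density of a type exceeds
  the base density parameter by the factor 1 + p(mult − 1); calibration and
  recovery tests therefore run with basket probability 0 so that the truth is
  exactly the density parameter.
* **Background:** a homogeneous Poisson process at 10⁻⁴ spots/µm³ per marker,
  rejection-sampled to lie outside every shell.

Shell spots are placed by rejection sampling *using the same signed-distance
code the pipeline uses*, and an independent pure-R distance oracle re-checks
their placement in the tests — self-consistency alone would prove nothing.
What the generator does *not* emulate: irregular soma shapes, fibre
structure (spots are independent points, not beads along axons),
staining-intensity variation within a scene, z-axis anisotropy of the point
spread, and merged or clipped surfaces (the exclusion paths are exercised by
constructed fixtures instead). Passing tests on synthetic data therefore
validate the *algorithms*, not the biology of any particular tissue.

## Problem sizes and numerical settings used by the test-suite

The packaged tests validate geometry against brute-force oracles on scenes of
up to 20 cells and 2,000 spots; statistical calibration and recovery run five
replicate datasets each at the full design size (7 × 2 × ~35 cells, ~900
model rows) with a scaled-down sampler of 2 chains × 500 retained draws after
500 warmup, which keeps each fit around 15 s while leaving enough effective
draws for median and interval checks. The Monte-Carlo shell-volume oracle
uses 10⁶ uniform samples. The acceptance script runs one full synthetic
pipeline at the same design size and sampler scale.

## Known limitations

* Shell volumes from the voxel estimator carry O(pitch) discretisation noise;
  at the default pitch this is ≲0.5% and immaterial next to count noise.
* The coverage-based basket criterion cannot distinguish a genuine basket
  from dense uniform innervation (see above).
* The compound-symmetry random-effect structure assumes equal pooling across
  combinations; a full correlated-vector structure could in principle borrow
  strength asymmetrically, at the cost of a 6×6 correlation prior dominating
  with few subjects.
* Anisotropic distance metrics (z-resolution) and partial-volume corrections
  are out of scope; distances are Euclidean in calibrated µm.
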