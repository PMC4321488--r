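---
title: "Methods: pre-merging diagnostics for serial diffraction data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pre-merging diagnostics for serial diffraction data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialdx)
```

serialdx diagnoses three pathologies of serial crystallography datasets
before merging: multiple crystal forms hiding in the per-frame unit cells,
systematic bias in the laboratory-frame crystal orientations, and
mis-indexed frames whose integrated intensities do not belong to the lattice
they claim. This vignette is the package's own account of the models and
procedures involved, the tunable parameters and why their defaults are what
they are, the numerical choices, and the limits of what the validation
suite demonstrates.

## The frames table

All diagnostics consume a tibble with one row per still image: the unit
cell (`a`–`gamma`, Å and degrees), an optional `orientation` list-column of
3×3 matrices whose rows are the reciprocal basis vectors a\*, b\*, c\* in
laboratory coordinates (Å⁻¹), and an optional `reflections` list-column of
(h, k, l, I_partial, σ_I) tables. Frames arrive through the native JSON
format (`det-frames-v1`, schema in `?read_frames_json`), a documented subset
of the CrystFEL stream format (lengths ×10 nm→Å, reciprocal rows ×0.1
nm⁻¹→Å⁻¹), or plain CSV cell tables.

## Lattice distance

### Why G6

Two indexing solutions can describe the same lattice with different
parameter tuples, and a Euclidean distance on raw (a, b, c, α, β, γ) mixes
ångströms with degrees. Both problems are addressed by working in G6 space:
every cell is first Niggli-reduced (canonical basis, a ≤ b ≤ c with the
standard angle-sign conventions) and embedded as

g = (a², b², c², 2bc·cos α, 2ac·cos β, 2ab·cos γ),

all components in Å². Distances, merge heights and the clustering threshold
are then all in one unit. The "Euclidean" metric option also reduces first:
comparing raw tuples would make the metric depend on the arbitrary basis the
indexing program happened to emit. (The alternative — raw-tuple Euclidean —
is noted for users who want to reproduce other tools' behaviour, but is not
implemented.)

### Niggli reduction

The reduction iterates the Krivy–Gruber decision steps with
epsilon-stabilized comparisons (tolerance relative to the mean squared edge,
default `tol = 1e-5`), operating directly on the metric tensor and
accumulating the integer change of basis, so the invariant
MᵀG₀M = G_reduced holds by construction. The iteration cap is 100; cells
that fail to settle within it are degenerate in a way worth surfacing, so
the cap raises an error naming the frame rather than returning something
silently wrong. Reduction is idempotent, and round-trips through random
unimodular re-basings reproduce the reduced cell to better than 1e-6
relative (exercised at scale in the test suite).

### The symmetry-aware metric

Even after reduction, near-degenerate cells can legitimately land on
different representatives (permutation/sign conventions at ties, Niggli-cone
boundary crossings). The full Andrews–Bernstein NCDist algorithm embeds the
cone in a manifold to handle this exhaustively; serialdx deliberately does
not reproduce it. Instead, `ncdist()` minimizes the reduced-G6 Euclidean
distance over a fixed transform set: all 48 signed axis permutations
composed with the identity and the 12 unit shears (the boundary transforms
of the reduction steps), deduplicated by their action on G6. Minimizing over
both operand directions makes the result exactly symmetric, and the identity
transform guarantees `ncdist ≤ g6_distance_euclidean` always.

The design trade-off: the finite set cannot chain multiple boundary
crossings, so for *distant* cell pairs the value can exceed the true
shortest path. For the regimes that matter here — same-lattice pairs (where
the tests demand agreement with a brute-force enumeration of all integer
transforms with entries in {−1, 0, 1} and determinant ±1, to 1e-6 Å²) and
small perturbations — the approximation is exact in practice, and for
distant pairs only the ordering of "large" matters to single linkage.

A numerical note: the clustering path computes orbit distances through an
inner-product expansion for speed; squared G6 norms are ~10¹⁰ Å⁴ for these
cells, so cancellation limits that path to ~10⁻³ Å² absolute accuracy near
zero. Entries below 1 Å² are therefore recomputed with exact differences,
restoring machine-precision zeros for identical cells without a measurable
speed cost.

## Clustering

Single linkage is the right linkage for this problem: crystal forms are
separated by gaps orders of magnitude larger than within-form scatter, and
single linkage finds connected components across such gaps without assuming
cluster shape. Merge heights are non-decreasing, which makes the threshold
cut well-defined. The cut keeps merges *strictly below* the threshold (a
merge exactly at it does not join). Clusters are labelled in order of
decreasing size with ties broken by the smallest member index; single-member
clusters are flagged as singletons and reported separately from the
non-singleton count, since a lone frame is not evidence of a crystal form.
Per-cluster summaries give component-wise medians of the reduced parameters
(robust to stragglers; the median cell is the re-indexing target) and
unscaled median absolute deviations as spreads.

The dendrogram is exported as Newick with branch lengths encoding merge
heights (leaf-to-root path length = root height), so standard tree software
recovers the full merge structure; the test suite round-trips random trees
through an independent Newick parser.

## Orientation diagnostics

The laboratory frame is fixed as: beam = +z, up = +y, right when looking
along the beam = +x (right-handed). Latitude/longitude of a unit vector v
are asin(v_y) and atan2(v_x, v_z), so (0, 0) is along the beam, North/South
are up/down, East/West are right/left. Users with a different beamline
convention need only remap axes at ingest. Real axes come from the
reciprocal rows by duality (a = (b\*×c\*)/V\*, etc.) and are normalized;
each axis is emitted as both antipodes because crystallographic axes carry
no sign. Whether to plot one hemisphere or both was an open choice; both are
plotted so that density structure at the equatorial seam is not visually
split.

The density estimate is a von Mises–Fisher kernel,
f(u) = (1/N) Σ c(κ) exp(κ u·vᵢ) with c(κ) = κ/(4π sinh κ), evaluated on a
regular 2° lat/long grid. κ = 50 gives a kernel FWHM of ≈20°, wide enough to
smooth a few hundred frames and narrow enough to show a goniometer-style
preferred axis. The estimator choice (kernel rather than binned counts) was
open; a kernel avoids the lat/long cell-area distortion that plain binning
inherits. Normalization is verified by equal-area quadrature
(Σ f·cos(lat)·Δ² = 1 ± 1%).

Visual bias assessment is subjective, so the package adds a quantitative
test: the Bingham statistic S = (15N/2)(tr T² − 1/3) on the orientation
tensor T = (1/N) Σ vᵢvᵢᵀ, which is sign-invariant (correct for axial data)
and asymptotically χ²₅ under uniformity. N is the number of axis
observations (one per frame per axis, not double-counting antipodes), with
N ≥ 10 required for the asymptotics to be meaningful. Null calibration and
power against a κ = 5 von Mises–Fisher concentration are measured by
simulation in the test suite; uniform null rotations are generated from
normalized 4-component Gaussian quaternions (exactly Haar).

## Pseudo-Wilson intensity statistics

For each frame, ordinary least squares of y = ln I_partial on
x = (sin θ/λ)² = 1/(4d²) gives intercept c = ln G and gradient m = −2B. The
logarithm base was left open by convention; natural log is used (the Wilson
convention) and documented, since B is only base-invariant if the slope is
rescaled. Both G and ln G are reported. s² is computed as hᵀG⁻¹h/4 from the
frame's *reported* cell — deliberately, because the mismatch between
reported cell and true lattice is exactly what makes mis-indexed frames
visible.

Choices worth stating:

* Non-positive partial intensities (legitimate in profile-fitted data) are
  dropped and counted, not offset-shifted — a shift would bias the slope.
* No multiplicity/epsilon normalization and no partiality correction: the
  statistic is *pseudo*-Wilson on purpose; partiality enters as
  heteroscedastic multiplicative noise that OLS absorbs without bias in the
  slope.
* Frames with fewer than 10 positive reflections (or zero variance in s²)
  get a refused-fit marker and are excluded from aggregates rather than
  erroring the whole run.
* The per-frame standard errors are the OLS standard errors of slope and
  intercept; both are histogrammed, since "standard errors on the fits" is
  ambiguous between them.

The outlier filter flags a frame when the robust z score of its gradient
*or* intercept exceeds 3.5: |x − median|/(1.4826·MAD) > 3.5, i.e. ≈3.5σ
two-sided for Gaussian inliers (expected false-positive rate ≈ 0.09%, and
the MAD keeps the scale estimate honest under ≤10% contamination). When the
MAD collapses to zero with non-identical values, the filter falls back to
exact-match comparison and says so. Coverage of the OLS intervals for B
(B̂ ± 1.96·se_slope/2) is verified by simulation.

## The synthetic generator

`generate_frames()` is first-class, tested code: it defines the study
conditions under which every statistical claim in the test suite is made.
The flagship `two_form_config()` emulates a goniometer-based XFEL dataset
with two orthorhombic crystal forms:

* population medians (69, 169, 288) Å and (69, 146, 170) Å, all angles 90°,
  weights 249/318 and 69/318, 318 frames — the scale and composition of a
  realistic two-form serial experiment;
* cell jitter applied to the reduced parameters directly, σ = 0.5 Å on
  edges and 0.1° on angles (how indexing scatter presents in practice);
* orientations either Haar-uniform or with the crystal c axis von
  Mises–Fisher-concentrated (κ = 5) around the lab "up" axis with a random
  spin — a loop-mounted goniometer bias;
* Wilson-model intensities I = G·exp(−2Bs²)·p·ε with per-frame
  B ~ N(15, 2²) Å² and ln G ~ N(ln 100, 0.3²), 200 reflections per frame,
  s² near-uniform on [0.001, 0.08] Å⁻² (≈1.8 Å resolution limit for these
  cells), partiality p ~ U(0.3, 1), lognormal noise σ = 0.3;
* a 10% mis-indexed fraction.

Reflections carry genuine integer hkl: a target s² is drawn uniformly, a
random direction chosen, and the nearest lattice point taken — for
macromolecular cells the reciprocal lattice is dense enough that s² stays
near-uniform.

Mis-indexing is modelled as what a wrong-lattice indexing solution does: the
reported cell is drawn from a *different* population, and the
index-to-intensity pairing is scrambled, because wrongly indexed spots carry
Miller indices unrelated to their intensities. An earlier design that only
swapped the cell (keeping the hkl pairing) was found during generator
development to produce regression *attenuation* rather than aberration —
both s² forms are positive quadratic forms of the same indices, so the
fitted slope merely shrinks and often stays inside the inlier range, which
is not the phenomenology the filter exists for. The truth table records
both the reported-cell population (what clustering can observe) and the
generating population, plus the mis-indexed flag and true (B, G).

Everything is bit-reproducible under the config seed, and the global RNG
state is left untouched.

### What the generator does not emulate

Spot shapes, detector noise, absorption, correlated cell-parameter jitter,
resolution-dependent partiality, twinning, and the error structure of any
real indexing program. Consequently, passing tests demonstrate that the
*estimators and filters are correct under their stated models* — unbiased B
recovery under lognormal noise, exact form recovery at realistic separation,
calibrated uniformity testing — not that real data will be as clean. On real
data the clustering threshold in particular may need adjustment when forms
are closer than the demo's, and the filter's recall depends on mis-indexing
actually producing aberrant fits.

## Problem sizes in the validation suite

The suite validates at sizes chosen to make the statistics meaningful while
keeping a full run in a couple of minutes: 100 reduction round-trips and 200
same-lattice pairs for the lattice algebra, 1000 random instances (n ≤ 20)
against a naive O(n³) single-linkage oracle, the full 318-frame demo for
form recovery, 500 frames for bias/coverage of B̂, 1000 null and 500
powered simulations for the Bingham test, and 100 replicates of 100 frames
for the mis-indexing filter. `scripts/acceptance.R` recomputes the same
quantities end to end from a single seed.

## Known limitations

* The finite-transform metric is an approximation; pairs separated by many
  Niggli-cone boundary crossings can be over-estimated relative to true
  NCDist (harmless for thresholded single linkage, wrong if you need exact
  geodesics).
* The Bingham test is asymptotic; at N much below ~30 per axis its size is
  approximate, hence the N ≥ 10 floor.
* The CrystFEL reader covers cells, reciprocal axes, and reflection lists
  only; geometry/panel records are ignored.
* No automatic threshold selection: the 5000 Å² default matches the
  two-form separation scale but is a parameter, not an inference.
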