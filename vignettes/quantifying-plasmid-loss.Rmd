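---
title: "Quantifying spatial plasmid loss: models, parameters and validation"
author: "plasmidQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial plasmid loss: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

A dual-label reporter makes plasmid status of a bacterium visible in two
fluorescence channels: cells express plasmid-encoded mCherry while the
plasmid is present, and a chromosomal GFP (repressed by a plasmid-encoded
LacI^q^) once it is lost. Red therefore marks plasmid-carrying and green
plasmid-free cells. plasmidQuant quantifies that readout in three
experimental systems — flow-cell biofilms imaged as confocal z-stacks,
microcolonies grown inside alginate beads, and planktonic cultures
measured by flow cytometry — and adds a synthetic-data generator so every
analysis stage can be validated against known ground truth.

This vignette documents the models and procedures, the tunable parameters
with their defaults and units, the numerical conventions, the design
choices made where the problem left them genuinely open, and what the
validation suite does and does not establish.

# Image primitives

**Median smoothing.** `medianSmooth3D()` replaces each voxel by the median
of its 3×3×3 neighborhood. Borders are handled by edge replication
(indices clamped to the array), so every neighborhood holds exactly 27
values; the alternative (shrinking the window at borders) dims object
boundaries at the first and last optical sections, which would bias
per-layer counts exactly where flow-cell biofilms are measured. The filter
is idempotent on constant regions, never produces values outside the
input range, and removes isolated bright voxels (shot noise).

**Auto-thresholding.** `autoThreshold()` implements three classic
histogram criteria: Otsu (maximize between-class variance), Yen (maximize
the entropic maximum-correlation criterion) and Tsai's moment-preserving
threshold (the cut whose background mass best matches the fraction that
preserves the first three gray-level moments). Conventions, chosen once
and applied everywhere:

* histograms use 256 uniform bins over the observed intensity range;
* the returned threshold is the upper edge of the last background bin, and
  foreground is **strictly greater** than the threshold — so the histogram
  classes and the voxel classification agree exactly, and an
  all-background image stays clean;
* ties between optimal cuts break toward the lowest candidate, making
  results deterministic;
* a constant image raises a "degenerate histogram" error rather than
  returning an arbitrary cut.

Per-experiment defaults mirror common practice for these data: flow-cell
stacks are thresholded without smoothing, Yen for the green channel and
Moments for the red; bead stacks are median-smoothed and Otsu-thresholded
in both channels. Which flow-cell channel gets which algorithm is not
dictated by anything fundamental; the assignment is a configurable
assumption (`methodGreen`, `methodRed` in the run configuration).

**Connected components.** `labelComponents()` groups foreground voxels
under 26-connectivity by default — face, edge and corner ("diagonal")
neighbors all connect, the 3D analogue of grouping adjacent pixels
including diagonals. 18- and 6-connectivity are available for sensitivity
analysis. Voxel anisotropy deliberately does **not** alter adjacency:
components are defined on the voxel grid, and physical units enter only
in volumes and distances. Labels are assigned in raster-scan order of each
component's first-encountered voxel, so labeling is reproducible.

# Flow-cell analysis

`layerProfile()` counts green and red foreground voxels per optical
section; voxels, not cells, are the unit throughout. `recenterZ()` shifts
layer positions by the biomass-weighted mean
$\bar z = \sum_z z\,B(z) / \sum_z B(z)$, so corrected position 0 marks the
biomass center and stacks of different thickness align. One subtlety: the
weighted mean does not in general coincide with the single most
biomass-rich layer, although for near-symmetric biomass profiles the two
agree. The operation implemented is the weighted-mean subtraction; the
modal layer's corrected position is attached as the `modalZCorrected`
attribute so a user can flag profiles where the two notions diverge.

`averageReplicates()` aligns images of one biological replicate by binning
corrected positions to unit-layer bins centered on integers (corrected
shifts are generally non-integer) and averages counts per bin across the
images covering it.

Two related statistics are exposed, matching how such data are reported:
the per-layer **proportion** `p(z) = n_free / (n_free + n_carrier)` (the
natural y-axis for depth profiles) and the per-stratum **ratio**
`Σ n_free / Σ n_carrier` (the stratification statistic). Aggregating
counts before forming the stratum ratio is equivalent to biomass-weighting
the per-layer ratios; an unweighted mean of per-layer ratios is available
behind the `perLayerMean` flag.

`weightedLoess()` fits a locally weighted polynomial regression (tricube
kernel, degree 2) of the loss proportion on position, with layer biomass
as prior weights, via `stats::loess`. The span defaults to 0.75 and is a
configuration key; nothing in the data dictates a span, so it is treated
as a reporting choice, pinned in the validation suite. Fitted values are
reported raw and clipped to [0, 1] (a proportion's range); points with
zero weight are dropped before fitting, which a test confirms is
equivalent to their having no influence.

`splitTopBottom()` assigns layers with corrected z below 0 to the bottom
stratum and at or above 0 to the top (the tie case is not dictated by the
definition "above or below 0"; assigning the boundary layer to the top is
the package's documented convention). Because the split is at the
weighted mean, each stratum holds half the biomass up to the boundary
layer's own biomass **when the biomass profile is not strongly skewed**
(splitting at the mean rather than the median is what the operational
definition prescribes; for heavily skewed profiles the two differ, and the
reported per-stratum biomasses make the property checkable on any data).
`compareStrata()` feeds the per-image stratum ratios into a fixed-effects
two-way ANOVA (stratum × plasmid variant, no interaction by default,
matching a main-effects report; the interaction is available behind a
flag).

# Bead analysis

The bead center is the coordinate-wise **median** position of all
foreground voxels (union of both channels), converted to µm — robust to
stray voxels in a way the mean is not, which a test demonstrates
explicitly. Aggregates are 26-connected components per channel; each gets

* a volume = voxel count × voxel volume, exactly (no interpolation);
* a centroid = unweighted mean voxel position in µm (the inputs are
  thresholded, so intensity weighting has nothing to add);
* a Euclidean distance from centroid to bead center in µm.

Voxel centers sit at `(index − 1) × voxelSize`; all µm quantities share
this convention. Distances are 3D Euclidean in image space; the half-bead
geometry of a cut bead is not modeled (a documented simplification), and a
voxel-unit distance flag exists because with anisotropic voxels µm and
voxel-grid distances differ.

`filterAggregates()` discards aggregates **strictly below** 50 µm³ (an
aggregate of exactly 50 µm³ survives — the strict reading of "smaller
than") and aggregates outside the bead. "Visibly outside" is inherently a
manual judgement; the automated rule excludes distances beyond 1.1 × the
bead radius, with the radius either supplied or estimated per bead as the
99th percentile of volume-passing aggregate distances (robust to
stragglers). Both the factor and the estimator are configuration keys, and
every removal is logged with its reason.

`normalizeDistances()` divides each retained aggregate's distance by the
maximum **retained** distance of its bead, so the farthest aggregate maps
to exactly 1. The pipeline order is fixed as filter → normalize — the
maximum over retained versus all aggregates differs, and a test asserts
the order. A bead with one retained aggregate gets 1.0 and a warning.

Two models summarize the biology: `sizeDistanceRegression()`, an OLS of
log₁₀(volume) on normalized distance with a 95% confidence band (growth
increases toward the bead surface where substrate arrives), and
`sizeByStatusLMM()`, a random-intercept model
`log10(volume) ~ status + (1 | bead)` fitted by REML through `lme4`,
testing whether plasmid-free aggregates outgrow plasmid-carrying ones
within beads. The reported p-value uses a normal approximation on
estimate/SE and is labelled as such — Satterthwaite or Kenward–Roger
degrees of freedom are deliberately out of scope; with one bead the
model falls back to OLS with a warning.

# Flow-cytometry analysis

Event tables are plain CSV (columns `green`, `red`, `strain`, `plasmid`,
`day`, `bioRep`, `techRep`); binary FCS parsing is out of scope — the CSV
convention is the interface contract.

**Gating is the module's largest assumption.** No operational gating
recipe exists for this reporter beyond "use controls", so `buildGates()`
derives gates from pure-population controls: one cut per channel at the
midpoint between the two controls' mean log₁₀ intensities, with the
controls' mean ± 3 sd boxes recorded as construction parameters. Events
are classified by quadrant — carrier (red above its cut, green below),
free (green above, red below), debris (below both), unclassified (above
both). Misclassification therefore means a cell event landing in the
*opposite* cell gate, which requires both channels to cross their cuts at
once; single-channel excursions fall into debris/unclassified and are
excluded from fractions rather than silently miscounted. Controls whose
means are closer than 2 sd in either channel are rejected as
non-separable. Gating is invariant to a joint monotone rescaling of both
channels and gates, which a test verifies.

`lossFraction()` reports `n_free / (n_free + n_carrier)` with a Wilson
95% score interval. `aggregateTrajectory()` averages technical replicates
within each biological replicate, keeps biological replicates separate,
and summarizes per day as mean ± SEM. `compareTrends()` fits
`fraction ~ day × strain` on replicate-level fractions (day numeric); the
interaction coefficient is the trend difference and its t test the
comparison. Fractions are analyzed untransformed by default — the natural
reading for raw proportions well inside (0, 1) — with a logit flag for
sensitivity. `welchT()` is the unequal-variance t test with Satterthwaite
degrees of freedom, and `relativeFitness()` uses the classical
Malthusian-parameter ratio
$w = \ln(N^{free}_{final}/N^{free}_{initial}) /
\ln(N^{carrier}_{final}/N^{carrier}_{initial})$, with the raw counts
always echoed so alternative conventions can be recomputed; swapping
competitors maps $w \mapsto 1/w$ exactly.

# The synthetic-data generators

The experiments these workflows target measure loss; they do not define a
generative model. Every distributional form here is therefore a package
invention,
chosen to match the statistical structure the analyses assume, and the
generators' role is to provide *recoverable ground truth*, not to imitate
optics.

**Flow-cell stacks** (`flowcellTruth()`): per layer z, exactly
`round(B(z))` foreground voxels at random lateral positions, each green
with probability `p_loss(z)` and red otherwise; foreground intensity
N(150, 10²), Gaussian background N(10, 3²) added everywhere, clipped at 0
and rounded to integers like a detector export. Defaults: 40 layers of
128 × 128 voxels at (dz, dy, dx) = (0.5, 0.2, 0.2) µm — plausible for a
63×/1.4 oil objective — 2000 biomass voxels per layer, and a step profile
of 5% (bottom half) to 30% (top half) plasmid-free, emulating elevated
segregational loss among actively growing top layers. Before noise, the
stored true counts equal the rendered foreground exactly.

**Bead stacks** (`beadTruth()`): non-overlapping voxelized spheres inside
a spherical bead; sphericity makes the volume ground truth analytic, and
discrete microcolonies from single founder cells are well approximated by
compact blobs. Each aggregate draws a plasmid status (free with
probability 0.2), a uniform normalized radial distance d, and a volume
from log₁₀(volume µm³) = intercept(status) + 0.8·d + N(0, 0.15²), with
intercepts 2.8 (carrier) and 3.1 (free). The sizes (10^2.8^–10^4^ µm³,
sphere radii ≳ 5 µm) were chosen so rendered spheres span several voxels
in every axis at the default (2, 1, 1) µm voxels of a low-magnification
objective, keeping voxelization and smoothing erosion well inside the
discretization bound of one voxel volume per surface voxel; microcolonies
grown for days are indeed tens of µm across. The default bead radius of
150 µm keeps a full bead (≈15M voxels) tractable in memory and time while
preserving realistic geometry (real beads are larger still). Placement is
rejection-sampled with a two-voxel gap so 26-connected labeling cannot
merge neighbors; an over-packed request fails with a clear error rather
than silently overlapping.

**FACS events** (`facsTruth()`): a three-component mixture — carrier,
free, debris — with log₁₀-normal intensities in both channels; defaults
put carrier and free 8 log-sd apart (a clean dual-reporter experiment)
with 5% dim debris. The true class of every event is stored.

**Loss trajectories** (`trajectoryTruth()`): per generation, with free
fraction f, segregational loss probability λ per division and selective
advantage s of plasmid-free cells,
$$f' = \frac{f(1+s) + (1-f)\lambda}{f(1+s) + (1-f)},$$
applied `generationsPerDay` times per day, then a binomial sample of
`samplingN` cells emulates the daily measurement. No quantitative loss
rates are available to pin λ and s, so the defaults (λ = 0.001,
s = 0.05, 10 generations/day) are labelled illustrative; the workflow
defaults give the dispersal-deficient strain a lower effective λ than the
wild type so the trend comparison has a recoverable signal.

What the generators deliberately **omit**: the optical point-spread
function and z-attenuation, conjugative plasmid transfer (the biology of
interest is segregational loss without selection), non-spherical aggregate
shapes, bead-surface geometry, and spectral spillover between channels.
Passing the validation suite therefore shows the *quantification
machinery* is correct under the stated statistical structure — it does not
certify segmentation performance on real optics.

# Numerical choices and degenerate inputs

* Histograms: 256 bins; threshold = upper edge of the last background
  bin; foreground strictly greater; ties to the lowest cut; constant
  images error.
* Median filter borders: edge replication.
* Labeling: raster-scan label order; connectivity 26/18/6.
* Voxel centers at `(index − 1) × voxelSize` µm, shared by centroids,
  distances and the sphere renderer.
* Zero-biomass layers: proportions undefined and flagged, never imputed;
  zero-carrier strata or beads: infinite ratios flagged, never dropped
  silently.
* Stage seeds derive from the base seed as
  `(seed × 1000 + offset) mod (2³¹ − 1)`, in double precision, so every
  derived seed is a valid 32-bit integer and a run is reproducible from
  one number; rerunning a workflow with the same configuration and seed
  is byte-identical, and every report file carries the configuration
  hash.
* The REML fixed-effect p-values/CIs use the normal approximation; the
  validation suite checks their coverage in a 12-groups × 8 layout, the
  regime that approximation targets — in very small designs (a handful of
  groups) it is expected to undercover slightly, which is why the
  package labels the approximation rather than hiding it.

# Validation strategy

The suite follows a dual-route principle: each primitive is checked
against an independent oracle (a BFS flood fill for labeling, a sort-based
neighborhood gather for the median, exhaustive criterion scans for the
thresholds, normal equations for OLS, closed-form balanced-design
estimators and a criterion-grid check for REML, an external library's
Otsu and the estimated-marginal-trends route as cross-checks), and each
workflow is checked for parameter recovery against generator ground truth
(stratum plateaus within ±0.03; LOESS curves of measured proportions
within ±0.05 of the same smoother applied to the true counts — the raw
step itself is not the reference, because any local smoother rounds a
discontinuity by far more than the sampling error, so the informative
comparison is measured-versus-truth through the identical smoother;
aggregate recall, volumes within the discretization bound, model
coefficients within 2 SE; gating misclassification and fraction
recovery). The statistical kernel is calibrated by simulation: type-I
error of the Welch, stratum-ANOVA and trend-interaction tests at nominal
α = 0.05, and REML CI coverage.

Problem sizes in the suite (40 × 128 × 128 flow-cell stacks, one
150-aggregate bead at radius 150 µm plus six 40-aggregate beads at
100 µm, 10⁴-event FACS samples, 1000–2000 null simulations, 200 coverage
replicates) were chosen so the whole suite runs in a few minutes on one
CPU while keeping Monte-Carlo error small relative to every tolerance
tested.

# Known limitations

* Voxels are the counting unit; absolute cell numbers are out of reach by
  design, so all statistics are ratios and proportions.
* The gating strategy is reconstructed from controls, not from any
  particular instrument session; real samples with drifting
  autofluorescence would need the control-derived cuts re-examined.
* The "outside the bead" exclusion automates a manual judgement with a
  radius heuristic; pathological beads (far off-center illumination,
  merged beads) should be inspected.
* The mean-split half-biomass property degrades for strongly skewed
  biomass profiles (see above); the reported stratum biomasses expose
  this on any dataset.
* LOESS span, like any smoothing bandwidth, trades bias for variance;
  conclusions about sharp features near the biofilm surface should not
  rest on the smoothed curve alone — the per-layer proportions are always
  reported alongside.
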