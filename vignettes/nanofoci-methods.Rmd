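---
title: "Models and methods behind nanofoci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanofoci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`nanofoci` evaluates two-color single-molecule localization microscopy
(SMLM) of DNA-damage foci.  This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic
generator does and does not establish.  It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The data model

SMLM reduces an acquisition (typically 2000 frames of 100 ms) to an
"orte matrix" per color channel: one row per fluorophore blink with
signal amplitude, lateral x/y coordinates in nm and a localization
error.  Coordinates are absolute nm in the image frame, origin at the
top-left corner, y increasing downward; all thresholds in the analysis
(200, 95, 50, 20 nm) are metric, so conversion from pixels happens
exactly once at ingest.  Two raster masks restrict the analysis: a
nucleus mask (from DAPI counterstain) and a damage-focus mask (from the
first-channel overview).  Pixel membership is half-open —
`(floor(x/p), floor(y/p))` — so boundary events belong to exactly one
pixel and masking is deterministic.

## Synthetic scenes: the stated world

Real acquisitions of irradiated blood cells are not publicly deposited,
so the package ships a ground-truth generator whose defaults encode the
experimental regime:

| parameter | default | rationale |
|---|---|---|
| nucleus radius | 3090 nm | disc of ~30 um^2, typical PBMC nucleus |
| foci per nucleus | 2 | one or two isolated breaks at ~100 mGy |
| focus spread (sigma) | 50 nm | nanocluster scale; cluster radius 200 nm |
| events per focus | 300 per channel | saturating nanocluster labelling |
| background density | 50 events/um^2 | unspecific labelling + free protein |
| co-localization fraction | 0.5 | plantable, 0..1 |
| planting displacement sigma | 10 nm | below all thresholds |
| localization error | 17 nm (ch 1), 15 nm (ch 2) | Cy3 / Cy5 precision |

Focus centres are uniform in the nucleus disc with a 3-sigma boundary
margin and pairwise separation >= 4 sigma (so ground-truth clusters
stay resolvable); focus events are isotropic Gaussians truncated to the
nucleus mask; background counts are Poisson.  A `coloc_fraction` subset
of channel-2 focus events (deterministically rounded per focus, which
keeps the planted count noise-free for parameter-recovery tests) is
placed at a uniformly chosen channel-1 event plus an isotropic 10 nm
displacement.  The focus-mask radius is calibrated so the default mask
covers ~6% of the nucleus (the observed macro-focus fraction); a fixed
multiple of the 50 nm nanocluster sigma cannot reach that coverage, so
the radius is an independent parameter rather than `3 * sigma`.

Blink photophysics is a geometric count per emitter (memoryless
off-switching; Poisson offered), with lognormal amplitudes — the source
study does not report dye photophysics, so these are exposed defaults,
not claims.  The renderer draws each blink as a pixel-integrated
Gaussian PSF plus uniform background, Poisson-sampled; there is no
EMCCD gain-register excess noise, drift or chromatic aberration.

**What a green test establishes.**  The generator produces stationary,
isotropic Gaussian clusters with known labels.  Real foci are
heterogeneous in size and density, sit in structured chromatin, and are
measured with drift and detector excess noise.  Green tests therefore
establish correctness of the *algorithms* against known ground truth
and analytic identities — not biological claims.

One deliberate consequence of the stated world: inside a default focus
(300 events, sigma 50 nm) the mean nearest-neighbour spacing is ~6 nm,
so chance co-localization saturates at every threshold >= 20 nm.
Irradiated-vs-control comparisons therefore use a foci-free control
cohort (unirradiated cells show no damage foci; their fraction is
background chance only), which is where the generator's co-localization
fraction becomes statistically visible.

## Localization

Candidates are 8-neighbourhood local maxima above
`median + threshold_factor * 1.4826 * MAD` per frame; the factor
defaults to 3.  The robust (median/MAD) baseline was chosen because the
original in-house software does not document its statistic and spot
pixels would otherwise inflate a plain standard deviation.  Candidates
closer than the fit window are merged to the brighter one.

Fitting is least squares of an isotropic Gaussian with constant offset
on an odd window (default 7 px): an unweighted fit initializes one
refinement with Poisson-variance weights `1/max(mu, 0.25)`.  The
reweighting matters: unweighted least squares on shot-noise-limited
spots loses ~25-40% precision against the information bound, which
would break the calibration property below.  Rejections (window at the
frame edge, non-convergence, centre escaping the window) are counted
per reason, never silently dropped.

The recorded per-event error is the Thompson-style estimate
`sigma_loc^2 = (s^2 + a^2/12)/N + 8 pi s^4 b^2 / (a^2 N^2)` (PSF width
`s`, pixel `a`, photons `N`, background variance `b^2 = offset`).  The
test suite verifies at 5000 photons that this estimate matches
Monte-Carlo truth within 25%, and that a photon budget placed in the
15-17 nm regime reproduces that regime within 25% — a calibration
property, not a constant of the software.

## DBSCAN morphometrics

Defaults `R = 200` nm, `N_min = 30`, with the point itself counted in
its own neighbourhood (the usual convention; the source evaluation does
not say).  Clusters are discovered by scanning seeds in ascending row
index and fully expanding each cluster before the next, so border
points reachable from several clusters deterministically join the
first-discovered one; the suite proves label-exact equivalence with a
brute-force O(n^2) implementation on hundreds of random instances.
Hull areas use the shoelace formula; clusters with fewer than three
non-collinear members get area 0 and a *missing* density (never an
infinity).  Per-cluster densities are averaged unweighted across
clusters, matching a "mean tag density within clusters" reading.

## Distance statistics

The pairwise-distance histogram bins all unordered pairs with
`d <= max_distance` into half-open 10 nm bins (a distance exactly equal
to the maximum joins the last bin — a measure-zero convention) and
normalizes by the pair count.  No Ripley edge correction and no K/L
transformation are applied: the deliverable is the raw relative
abundance curve; an uncorrected `K(r)` is a secondary output.  Defaults
(bin 10 nm, range 1000 nm, smoothing window 3 bins, prominence 5% of
the global maximum) are exposed because the source analysis states
none.  Pooling across nuclei weights by pair count by default
(per-nucleus weighting is available) — the per-figure normalization in
the source is not documented, so both modes exist behind one switch.
Peaks are local maxima of the moving-average-smoothed curve filtered by
topographic prominence; FWHM is interpolated on the smoothed curve and
reported missing when the half level is never crossed inside the range.

## Co-localization

Point-based, not pixel-based: an event of channel A co-localizes when
its nearest channel-B neighbour is within the threshold.  Both
directions are computed because the labels play asymmetric roles.
Cluster-hull unions are rasterized at 5 nm for overlap percentages and
cross-channel densities — exact polygon clipping of degenerate hulls is
brittle, and the raster error is bounded and tested (<1% on analytic
cases).  Whether co-localized counts should be restricted to
first-channel clusters is ambiguous in the source; both the
nucleus-wide count and the in-cluster restriction are reported.

## Topology

Alpha is a radius: a disc grows around every point, and the filtration
tracks components (dim 0) and holes (dim 1).  The implementation
triangulates with Bowyer-Watson (points numerically on a circumcircle
count as inside, which keeps cavities valid for cocircular inputs such
as regular polygons; exact duplicates are deterministically perturbed
by ~1e-9 of the extent), assigns filtration values — vertices 0, edges
half their length if Gabriel else the smallest incident triangle,
triangles their circumradius — and reduces the boundary matrix over Z2
(union-find for dim 0, triangle-column reduction for dim 1).  In
general position this equals Cech persistence of growing discs, which
the suite verifies against a from-first-principles Cech oracle
(all-pairs/all-triples minimum enclosing balls) to 1e-9 nm.  Bars
shorter than 1e-9 of their death value are treated as zero-persistence
(cocircular ties).  Barcodes are truncated at `alpha_max` (default
500 nm — beyond cluster scale, below nucleus scale); the everlasting
component is reported at `alpha_max` and flagged essential.

Barcode similarity: bars of one dimension are matched greedily in
descending interval-Jaccard order (each bar used once), and
`S = sum(matched Jaccards) / max(#bars_1, #bars_2)`.  The cited
similarity method does not pin down the overlap computation; this
greedy interval matching is the package's normative definition (a
discretized-binarization alternative would slot behind the same
operation contract).  Two empty barcodes give S = 1 (identical
emptiness), exactly one empty gives 0; S is symmetric and bounded in
[0, 1] by construction.  First-generation heatmaps are the pairwise S
matrices of one label; second-generation cells are the mean
off-diagonal of the same-label block and the mean of the full
rectangular cross-label block.  Per-focus, per-cluster and per-nucleus
granularities are supported; the pipeline defaults to the focus-mask
region (`topology$region = "foci"`), subsampled to 400 points for
tractability of the cubic-ish reduction.

## Group statistics

Per-nucleus summaries are skewed, so the default test is a two-sided
rank-sum: exact full enumeration of group assignments when both groups
have <= 10 values, the normal approximation with continuity correction
otherwise (the suite checks both branches agree within 0.01 at n = 10).
Stars follow the strict map `* p<0.05, ** p<0.01, **** p<0.001` — the
three-star level is deliberately absent, matching the annotation scheme
being reproduced — and boundary p-values map to the weaker category.

## Pipeline and reproducibility

`run_config()` validates every block before any computation; exactly
one input mode (synthetic, orte files, frame stacks) is allowed.  A
single master seed is fanned out via deterministic integer mixing
(`derive_seed(seed, stage, index)`, no RNG state involved), so toggling
one stage never shifts another stage's stream; identical config + seed
gives bit-identical reports and emitted files (asserted in the
acceptance suite).  A nucleus failing one stage is excluded from that
stage's aggregate with a logged reason, not from other stages.  Every
emitted CSV carries the config hash; re-emission backs existing files
up with `.bak`.  Selection of intact nuclei with foci in both channels
is an input metadata flag (`include = FALSE` skips an entry), not image
analysis.

## Known limitations

* The Bowyer-Watson triangulation uses floating-point predicates with a
  1e-9 relative in-circle tolerance; adversarially near-degenerate
  inputs beyond cocircular/collinear configurations are not handled
  exactly.
* The localization module is a documented stand-in for unpublished
  in-house software; it is validated by parameter recovery, not by
  comparison with that software.
* Hull-union areas are raster approximations (5 nm); overlap
  percentages inherit that error bound.
* Cohort-level statistical properties (e.g. component similarity
  exceeding hole similarity) are tested on scaled-down cohorts sized to
  the test-time budget; the generator parameters themselves are never
  scaled.
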