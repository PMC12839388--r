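# nanofoci

Nanoscale evaluation of two-color single-molecule localization
microscopy (SMLM) data of radiation-induced DNA-damage foci, in R.

Low-dose beta-irradiation (e.g. Lu-177 radionuclide therapy) induces
only one or two isolated DNA double-strand breaks per blood-cell
nucleus.  SMLM resolves the repair machinery around such breaks as
pointillist coordinate maps: per channel, a table of localized blink
events ("orte matrix") with amplitude, lateral x/y position in nm and a
localization error.  `nanofoci` implements the full evaluation chain
used for such data:

* **Localization** — spot detection on raw frame stacks (local maxima
  above `median + 3 * 1.4826 MAD`) and least-squares fitting of an
  isotropic 2D Gaussian with offset, with a Thompson-style per-event
  precision estimate `sqrt((s^2 + a^2/12)/N + 8 pi s^4 b^2 /(a^2 N^2))`.
* **Masking** — the two masking methods: a nucleus (DAPI) mask and a
  damage-focus mask, applied to orte tables with half-open pixel
  membership.
* **DBSCAN morphometrics** — clustering with radius `R = 200` nm and
  `N_min = 30` signals, convex hulls, hull areas (shoelace formula,
  um^2) and tag densities, summarized per label and mask.
* **Ripley distance statistics** — relative frequencies of all pairwise
  point-to-point distances; cluster structure appears as low-distance
  peaks, spatial randomness as a near-linear rise.  Peak positions,
  prominences, FWHM and spacings are annotated; a raw Ripley
  `K(r) = A / (n(n-1)) * #{d_ij <= r}` is available.
* **Co-localization** — a channel-A event co-localizes when its nearest
  channel-B neighbour lies within a threshold (95 / 50 / 20 nm);
  cluster-overlap percentages and cross-channel densities in cluster
  hulls complete the picture.
* **Topology** — alpha-filtration persistent homology (alpha = a
  growing disc radius in nm): components (dim 0) and holes (dim 1) as
  barcodes, compared by greedy interval-Jaccard matching
  `S = sum(matched |I1 ∩ I2| / |I1 ∪ I2|) / max(#bars1, #bars2)`,
  summarized in 1st-generation (sample x sample) and 2nd-generation
  (label x label mean) heatmaps.
* **Group statistics** — two-sided rank-sum comparisons (exact
  enumeration for small samples) with the strict star map `* p<0.05`,
  `** p<0.01`, `**** p<0.001`.
* **Synthetic scenes** — a ground-truth generator (disc nucleus of
  ~30 um^2, 1-2 Gaussian damage foci, Thomas-type clustered channels
  with a plantable co-localization fraction, uniform background,
  17 / 15 nm localization errors) plus a frame renderer, so every stage
  is testable without microscope data.

Everything is pure R (plus `jsonlite`); Delaunay triangulation,
persistence reduction, DBSCAN, nearest neighbours and a minimal
baseline-TIFF codec are implemented in the package and validated
against independent brute-force oracles in the test suite.

## Worked example

```r
library(nanofoci)
params <- scene_params(seed = 7)        # defaults: 2 foci, 30 um^2 nucleus
scene  <- generate_scene(params)
orte1  <- sample_localizations(scene, channel = 1)   # e.g. gH2AX / Cy3
orte2  <- sample_localizations(scene, channel = 2)   # e.g. H3K9me3 / Cy5

summarize_nucleus(list(gH2AX = orte1, H3K9me3 = orte2),
                  scene$nucleus_mask, scene$foci_mask)
#>     label    mask n_events n_clusters mean_cluster_area_um2
#> 1   gH2AX nucleus     2143          2             0.3523272
#> 2   gH2AX    foci      694          2             0.3523272
#> 3 H3K9me3 nucleus     2160          2             0.2953115
#> 4 H3K9me3    foci      680          2             0.2953115

o1 <- apply_mask(orte1, scene$nucleus_mask)
o2 <- apply_mask(orte2, scene$nucleus_mask)
colocalize_points(o2, o1, coloc_params(95))
#> co-localization @ 95 nm: A->B 82.8% (1788/2160), B->A 82.5% (1767/2143)
colocalize_points(o2, o1, coloc_params(20))
#> co-localization @ 20 nm: A->B 31.5% (680/2160), B->A 32.1% (687/2143)

of <- apply_mask(orte1, scene$foci_mask)
b  <- alpha_persistence(cbind(of$x_nm, of$y_nm)[1:150, ],
                        alpha_max_nm = 500)
b
#> barcode: 150 points, alpha_max 500 nm, 150 components, 117 holes
jaccard_barcodes(b, b, dimension = 0)   # identity -> 1
```

The two clusters found are the two simulated damage foci; each recovers
its ~300 planted events plus absorbed background.  The co-localized
fraction drops from 82.8% at 95 nm to 31.5% at 20 nm: at 95 nm chance
co-localization inside the dense foci saturates, while 20 nm isolates
the planted channel-2 events (`coloc_fraction = 0.5` of the focus
events, recovered as 680/2160 with background dilution).

End-to-end runs (synthetic cohorts or orte/mask files) go through
`run_config()` / `run_pipeline()` / `emit_report()`, or the CLI front
end in `inst/cli/nanofoci` (`nanofoci run --config run.json --out dir`).

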