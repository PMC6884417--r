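# blastoquant

Quantitative analysis of monozygotic twin mouse embryos produced by
bisecting 2-cell embryos, and of mRNA spatial patterning in oocytes and
2-cell blastomeres.

Bisected 2-cell embryos yield twin blastocysts whose epiblast (EPI,
NANOG-positive) compartments are often strongly unequal — a median twofold
higher/lower imbalance — while the trophectoderm (CDX2) stays balanced. The
package implements the statistics used to establish and dissect that
asymmetry, for developmental biologists working with confocal FISH stacks,
lineage count tables and blastomere-pair expression matrices:

* **Eccentricity of FISH signal.** On a 10-slice equatorial
  maximum-intensity projection, for an ROI with intensities *I(x, y)*:

  *E* = ‖ **m̄** − **c̄** ‖, where **c̄** is the unweighted pixel centroid
  and **m̄** = Σ *I*·(x, y) / Σ *I* is the intensity-weighted centre of
  mass — the hypotenuse of the right triangle with legs Δx and Δy. Uniform
  signal ⇒ *E* = 0; spatial patterning displaces the centre of mass.
  Group comparisons use the two-sided Wilcoxon rank-sum test.
* **Twin lineage-count statistics.** Per-pair, per-germ-layer
  C^high/C^low ratios; EPI sufficiency (≥ 4 NANOG cells, normalized to
  blastocysts, optional ≥ 50-cell filter); singleton/complete pair
  accounting; Fisher exact allocation test; bisection survival summaries.
* **Twin-pair recovery by clustering.** Hierarchical clustering of count
  vectors or transcriptomes with a dendrogram-sibling recovery criterion,
  plus per-gene interblastomere expression ratios ranked by coefficient of
  variation.
* **Synthetic generators** for all three data types (Airyscan-like
  two-channel z-stacks with configurable spot density families and ground
  truth; twin count tables with a calibrated EPI imbalance; blastomere-pair
  expression matrices), making the whole pipeline testable end to end with
  no specimen data.

## Worked example

Simulate six 2-cell embryos carrying a strong transcript gradient
(g = 0.8) and six with a uniform probe, run the measurement pipeline
(projection → orientation → shared normalization → per-blastomere ROIs →
eccentricity), and compare the groups:

```r
library(blastoquant)

params <- image_sim_params(image_shape = c(176, 176), n_slices = 12,
                           geometry = "two_cell", blastomere_radii_px = 36,
                           n_spots = 400, distribution = "gradient",
                           gradient_strength = 0.8, seed = 42)

specimens <- lapply(1:6, function(s) {
  p <- params; p$seed <- s
  x <- generate_embryo_stack(p)
  list(stack = x$stack, truth = x$truth, id = paste0("embryo", s))
})
uniform <- lapply(7:12, function(s) {
  p <- params; p$distribution <- "uniform"; p$gradient_strength <- 0; p$seed <- s
  x <- generate_embryo_stack(p)
  list(stack = x$stack, truth = x$truth, id = paste0("ctrl", s))
})

res <- batch_eccentricity(c(specimens, uniform), level = "blastomere",
                          roi_mode = "ground_truth")
head(res[, c("specimen", "roi_label", "E_px", "E_norm")], 4)
#>   specimen roi_label E_px E_norm
#> 1  embryo1         a 2.39 0.0666
#> 2  embryo1         b 2.49 0.0694
#> 3  embryo2         a 2.49 0.0693
#> 4  embryo2         b 1.79 0.0497

compare_groups(res$E_px[1:12], res$E_px[13:24],
               labels = c("patterned", "uniform"))
#> <group_comparison> patterned (n=12, median 2.15) vs uniform (n=12, median 0.2182)
#>   Wilcoxon rank sum exact test: W = 144, p = 7.396e-07
```

The patterned probe shows a clearly elevated eccentricity in every
blastomere; the uniform probe sits near zero (its residual E is spot-count
sampling noise).

Twin lineage counts from the calibrated generator reproduce the imbalance
structure — EPI and PE ratios near 2, trophectoderm near 1 — and twin pairs
are essentially unrecoverable by clustering their germ-layer counts:

```r
tab <- generate_twin_counts(count_sim_params(n_pairs = 36, seed = 1))
ratios <- pair_ratios(tab)
sapply(split(ratios$ratio, ratios$layer), median, na.rm = TRUE)
#>     cdx2    nanog    sox17
#> 1.111111 2.000000 2.000000

epi_sufficiency(tab, threshold = 4)
#>       group  n n_sufficient proportion
#> 1 KSOM twin 72           47  0.6527778

tw <- tab[tab$member != "intact", ]
feats <- t(as.matrix(tw[, c("cdx2", "sox17", "nanog", "total")]))
cluster_pair_recovery(feats, tw$pair_id)
#> <pair recovery> 0 / 36 pairs recovered (0.0%)
```

A methods vignette
(`vignettes/twin-blastomere-quantification.Rmd`) documents the model,
the generator families, the calibration of the imbalance parameter, the
numerical conventions and the known limitations.

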