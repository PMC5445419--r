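# fishpol

Quantification of mRNA spatial distribution and anterior–posterior
polarity from single-molecule FISH images of migrating cells.

## What it does

In a confocal maximum-intensity projection, FISH-labelled transcripts
appear as diffraction-limited spots over a low background. Chemotaxing
cells present two obstacles to quantifying where those transcripts sit:
the cell boundary cannot be segmented precisely, and spots overlap
wherever the message is abundant. `fishpol` implements a
region-of-interest workflow built around a calibrated **mRNA unit** — the
fluorescence signature of the smallest recurring spot:

1. **Unit calibration.** Peaks are detected (8-neighbour local maxima
   above a MAD-based threshold), fit to isotropic Gaussian PSFs
   `b + A·exp(−((r−r₀)² + (c−c₀)²)/2σ²)`, and the fit-parameter
   distributions are thresholded from above until unimodal. The surviving
   means define the unit, with integrated intensity `I_u = 2πA_u σ_u²`.
2. **Two count estimators per ROI.** The *linear estimate* is the ROI's
   integrated intensity divided by `I_u`. The *simulated estimate*
   rebuilds the image one unit PSF at a time — each placement starts at
   the residual maximum, is stochastically jittered, refined to the
   locally SSD-minimising position, and accepted while the sum of squared
   differences keeps decreasing — repeated over seeds to give a count mean
   and spread that stay accurate when spots overlap.
3. **Polarity geometry.** Cells are bisected into anterior and posterior
   halves by the line through the nucleus centroid perpendicular to the
   direction of the aggregation centre; elongation is scored by the
   eccentricity `ε = √(1 − b²/a²)` of the moment-equivalent ellipse
   (0 = round, 1 = fully elongated).
4. **Statistics.** Median-centred box summaries (50% box / 99% bars from
   order statistics), Welch or paired t tests of posterior vs anterior
   counts overall and by stream position, and Pearson correlation of the
   mRNA and protein posterior fractions.

A synthetic-scene generator renders FISH-like images with exact ground
truth (spot positions, half labels, protein posterior fraction), so the
entire pipeline is testable without microscopy data.

## Worked example

```r
library(fishpol)

# a synthetic cell: 30 spots, 70% posterior, well separated
p <- scene_params(image_shape = c(160L, 160L), cell_axes = c(55, 30),
                  n_spots = 30L, enrichment = 0.7,
                  min_spot_separation = 8, seed = 7)
out <- render_scene(p)
out$scene
#> <fish_scene> 160 x 160 px, 30 spots (9 anterior / 21 posterior), f = 0.70

unit <- calibrate_unit(out$mrna, out$scene$cell_mask)
unit
#> <unit_model> A = 99.89, sigma = 1.481 px, I = 1377 (2*pi*A*sigma^2)
#>   support: 30 candidates, trim fraction 0.000

img  <- subtract_background(out$mrna, out$scene$cell_mask)
rois <- scene_roi_pair(out$scene)
est  <- simulated_estimate(img, rois, unit, n_reps = 10, master_seed = 1)
as.data.frame(est)
#>      roi_id linear_count sim_count_mean sim_count_sd n_reps
#> 1  anterior     9.435338              9            0     10
#> 2 posterior    21.356741             21            0     10
```

The calibrated unit intensity is within 3% of the generator's
`2π·100·1.5²`, and both estimators recover the true 9 anterior / 21
posterior split. At cohort level:

```r
cohort  <- make_stream_cohort(30L, c("beginning", "middle", "end"),
                              list(beginning = 0.5, middle = 0.6, end = 0.7),
                              scene_params(image_shape = c(64L, 64L),
                                           cell_axes = c(20, 10), n_spots = 40L,
                                           unit_sigma = 1.2, background = 5,
                                           seed = 42L),
                              protein_tracks_mrna = TRUE)
records <- cohort_records(cohort, master_seed = 42L)
compare_anterior_posterior(records, "linear")
#> <group_comparison> Welch two-sample t test, linear estimator
#>   medians: anterior 16.79, posterior 22.82 (n = 30, 30)
#>   t = 4.362, p = 5.5474e-05

sapply(compare_by_stream_position(records, "linear"),
       function(x) x$mean_mrna_posterior_fraction)
#> beginning    middle       end
#>     0.505     0.556     0.682

mrna_protein_correlation(records)$per_position$r
#> [1] 0.9722304
```

The estimated posterior fractions recover the generated gradient
(0.5 / 0.6 / 0.7 by stream position), the posterior excess is highly
significant, and the group-mean mRNA–protein correlation is near 1 when
the protein tracks the mRNA enrichment.

`run_pipeline()` chains simulate → calibrate → bisect → estimate → stats
from one seeded YAML configuration and writes TIFF/GeoJSON/CSV/JSON
artifacts plus a manifest; `inst/cli/fishpol.R` exposes the same stages as
shell subcommands (`simulate`, `calibrate`, `bisect`, `estimate`,
`stats`, `run`).

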