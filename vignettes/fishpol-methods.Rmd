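---
title: "Counting mRNA units and scoring cell polarity: the methods behind fishpol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting mRNA units and scoring cell polarity: the methods behind fishpol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishpol)
```

## The problem

Single-molecule FISH labels a chosen mRNA species with fluorescent probes,
so that transcripts appear in a confocal maximum-intensity projection as
diffraction-limited spots over a low background. In polarized, chemotaxing
cells the question is spatial: how much of the message sits in the rear
(posterior) half of the cell versus the front (anterior) half, how does
that asymmetry depend on where the cell sits in a migratory stream, and
does the asymmetry of the mRNA track the asymmetry of the protein it
encodes?

Two obstacles shape the method. First, fixed chemotaxing cells have no
sharp boundary in phase contrast, so precise automatic segmentation is not
available; the analysis therefore works with generous regions of interest
(ROIs) and is designed to be insensitive to the exact outline. Second,
spots overlap wherever the transcript is abundant, so naive spot counting
undercounts. `fishpol` addresses both with a *unit-denominated* pipeline:
it calibrates the fluorescence signature of the smallest recurring spot
(the "mRNA unit", plausibly a small cluster of transcripts rather than a
single molecule), then expresses every regional measurement in that
denomination. No attempt is made to convert units to molecule counts.

## The image model

An image is modelled as

$$ I(r, c) = B + \sum_{k=1}^{N} A\, \exp\!\left(-\frac{(r - r_k)^2 + (c - c_k)^2}{2\sigma^2}\right) + \varepsilon(r, c), $$

a constant background plus $N$ isotropic Gaussian point-spread functions
of common amplitude $A$ and width $\sigma$, with optional Poisson shot
noise and Gaussian read noise $\varepsilon$. One unit has integrated
intensity $I_u = 2\pi A \sigma^2$. All geometry uses 1-based `(row, col)`
coordinates with the centre of pixel $(i, j)$ at $(i, j)$; Gaussians are
evaluated at pixel centres, and the synthetic generator and the estimators
share that convention, so pixel-integration effects cancel in all
self-consistency checks.

## Unit calibration

`calibrate_unit()` chains four steps.

1. **Background subtraction** (`subtract_background()`): the median of the
   pixels outside the cell mask (or of the whole image) is subtracted and
   the result clipped at zero. The median is insensitive to the bright
   minority of spot pixels.
2. **Peak finding** (`detect_peaks()`): 8-neighbourhood local maxima above
   `k_sigma` (default 5) times a robust noise scale. The scale is the
   median absolute deviation rather than the standard deviation so that
   bright spots do not inflate their own detection threshold. Peaks closer
   than `min_separation_px` (default 3 px) are reduced to the brighter
   member.
3. **PSF fitting** (`fit_psf()`): each candidate window (11 x 11 px by
   default) is fit by Levenberg-Marquardt least squares to a Gaussian with
   free local background. Non-convergent fits, non-positive amplitudes and
   widths wider than the window are marked not accepted.
4. **Unit derivation** (`derive_unit()`): fits with width outside
   `size_bounds` (default 0.8-3.0 px) are discarded; then the amplitude
   and width distributions are thresholded from above — at each iteration
   the top `trim_step` (default 2%) of whichever distribution is currently
   the more bimodal is removed — until both distributions are unimodal.
   The means of the survivors define the unit $(A_u, \sigma_u)$ and
   $I_u = 2\pi A_u \sigma_u^2$.

Trimming *both* parameters matters in crowded images: unresolved spot
pairs fit as single wide Gaussians, creating a second mode in the width
distribution that amplitude trimming alone cannot remove; we observed
amplitude-only trimming exhausting its candidates on dense synthetic
cohorts for exactly this reason.

Unimodality is judged by Sarle's bimodality coefficient with the
finite-sample correction; values at or above 0.555 (the value attained by
the uniform distribution) are treated as evidence of more than one mode.
Distributions whose spread is below 1% of their mean are treated as
unimodal outright, because third and fourth moments estimated from such
samples are numerical noise. Calibration errors loudly
(`"insufficient isolated spots"`) rather than returning a unit it cannot
support with at least `min_support` (default 10) candidates.

## Two estimators of regional unit content

The **linear estimate** (`linear_estimate()`) of an ROI is its integrated
background-subtracted intensity divided by $I_u$. It is exact in
expectation regardless of overlap, but it is blind to *where* intensity
decomposes into spots and inherits any error in the ROI boundary.

The **simulated estimate** (`simulated_estimate()`) rebuilds the image one
unit at a time (`reconstruct()`): at each step a candidate position is
drawn at the maximum of the current residual, perturbed by a seeded
uniform jitter (default 1 px per coordinate), then refined to the locally
SSD-minimising subpixel position; the unit PSF is subtracted there if the
sum of squared differences over the mask decreases by more than
`stop_tol` (default $10^{-4}$) times the initial SSD, and the first
rejected placement ends the loop. The residual is allowed to go negative,
so over-placement penalises itself. Repeating the reconstruction
(`n_reps`, default 10) with derived seeds gives a count mean and spread
per ROI, and `average_image()` renders the placements into a spatial map
of the estimated units.

Three choices deserve comment.

* *Jitter plus refinement.* The jitter supplies the run-to-run variation
  that makes repetitions informative where spots overlap (different
  starting points fall into different local minima of the placement
  objective). The refinement step matters quantitatively: subtracting a
  unit 1 px off-centre leaves a dipole residue of roughly 7% of the
  unit's energy, and without refinement those residues accumulate into a
  systematic undercount of about 5% on 40-spot scenes. At `jitter_px = 0`
  the whole procedure is deterministic, which the test suite exploits.
* *Fixed amplitude.* Units are placed with the calibrated $A_u$,
  $\sigma_u$; there is no per-spot amplitude fit. This is what makes the
  output a *count* in the unit denomination.
* *Stopping rule.* "Until the SSD is minimised" is operationalised as the
  first placement that fails to improve SSD by `stop_tol` relative to the
  start; a safety cap (three times the linear estimate plus 20) guards
  against pathological inputs and is reported via the `converged` flag.

For anterior/posterior pairs, both estimators split the *whole image* by
the bisecting line rather than clipping at the drawn cell outline: spot
tails extend beyond any outline, and the method is meant to be insensitive
to the outline's accuracy. Per-ROI placement counts use the same
half-plane rule (ties to the anterior), so the linear and simulated
counts always refer to the same partition.

## Cell geometry

`bisect_cell()` cuts the cell polygon with the line through the nucleus
centroid perpendicular to the nucleus-to-aggregation-centre direction; the
half toward the aggregate is the anterior. Areas use the shoelace
formula; the two half-areas sum to the cell area to machine precision.
When a data set carries manually drawn anterior/posterior polygons,
`cell_roi_pair()` uses them verbatim and only falls back to the
programmatic cut when they are absent.

Cell elongation is summarised by the eccentricity of the
equivalent-inertia ellipse: `fit_cell_axes()` computes the second-order
area moments of the outline polygon (for an ellipse the covariance
eigenvalues are $a^2/4$ and $b^2/4$), and
$\varepsilon = \sqrt{1 - b^2/a^2}$ — 0 for a circle (unpolarized), 1 in
the fully elongated limit. Moments were chosen over extremal chord
lengths because they are differentiable in the vertices and insensitive
to single-vertex noise; on smooth outlines the two definitions agree.

`posterior_intensity_fraction()` reports the share of within-cell
intensity in the posterior half; it is the protein-channel analogue of
the mRNA posterior count share, and by construction the mRNA fraction
computed from pixel intensities equals the fraction computed from linear
counts. A zero-intensity cell returns 0.5 with a warning.

## Statistics

The box summaries (`summarize_box()`) follow a median-centred convention:
the box is a 50% and the bars a 99% distribution-free confidence interval
for the *median*, built from order statistics of the binomial
distribution (the widest symmetric pair of order statistics whose exact
coverage still reaches the level); points outside the bars are flagged as
outliers. Conventional quartiles are reported alongside, clearly
labelled, since this convention is narrower than a Tukey box plot.

`compare_anterior_posterior()` applies a two-sample t test of posterior
versus anterior counts across cells — Welch by default, with a paired
variant (arguably more faithful to the per-cell design) behind a flag.
`compare_by_stream_position()` repeats the comparison within
beginning/middle/end groups; no multiple-testing correction is applied by
default because the three positions address one ordered hypothesis, and a
Bonferroni flag is available. `mrna_protein_correlation()` returns the
Pearson correlation of the mRNA and protein posterior fractions both
across cells and across position-group means; the group-mean variant with
three positions correlates three points and is reported with its `n` so
the reader can weigh it accordingly.

## The synthetic-scene generator

`render_scene()` draws spots inside an elliptical cell (posterior side
with probability `enrichment`, uniformly within the chosen half, the
halves being defined by the same nucleus-centred line the analysis uses),
renders them as unit Gaussians over a constant background, and adds
optional Poisson and read noise. The protein channel is piecewise
constant within the cell, with its posterior share set exactly to
`protein_posterior_fraction`. Spots are resampled if they fall within 3
PSF widths of the image border (keeping photometric invariants exact) or
closer than `min_spot_separation` to another spot. Defaults — amplitude
100, width 1.5 px, background 10, 40-50 spots in a cell of semi-axes a
few tens of pixels — are free parameters chosen to look like a
well-exposed confocal FISH projection; the real images' noise statistics
and dynamic range are not on record, so no claim of matching them is
made.

`make_stream_cohort()` builds one scene per cell with the enrichment set
by stream position and per-cell seeds derived from a master seed. Cohort
cells draw their spot count from a Poisson distribution with mean
`n_spots`: with a fixed count the anterior and posterior counts would sum
to a constant and be perfectly anticorrelated — an artifact no real
cohort exhibits, and one that would make the unpaired t test
anti-conservative by construction. Poisson cell-to-cell variability is
the standard model for transcript counts and makes the two half-counts
independent by thinning.

What the generator does *not* emulate: real cell-shape irregularity
(cells are ellipses), optical aberrations and anisotropic PSFs, camera
gain and offset structure, autofluorescence gradients, z-projection
artifacts, and segmentation error in the manual outlines. Tests passing
on these scenes therefore validate the estimators and statistics under
the stated image model, not robustness to every property of real data.

## Numerical choices and degenerate inputs

* Background estimates use medians; noise scales use the MAD.
* PSF fits start from the candidate pixel with $\sigma_0 = 1.5$ px and
  box constraints keeping the centre inside the window and
  $\sigma \in [0.2, 2w]$.
* Pixel-in-polygon tests use pixel centres with boundary points counted
  inside; in a bisection, pixels exactly on the cut line go to the
  anterior half, so every pixel belongs to exactly one half.
* Flat or empty inputs return empty results where that is meaningful (no
  peaks on a flat image; zero placements on a zero image) and error where
  it is not (empty ROI, mask covering the whole image, degenerate
  polygon).
* Seeds: every stochastic function takes an explicit seed; cohorts and
  repetition loops derive per-item seeds from a master seed via a seeded
  draw without replacement, so results are independent of evaluation
  order.

## Problem sizes in the test suite

The suite exercises full scenes of 64-192 px on a side with 10-50 spots:
sparse photometric oracles on scenes with spots at least 6 PSF widths
apart; dense-regime bias on 20 scenes with nearest neighbours around 2
PSF widths; enrichment recovery on 100 replicate 30-cell cohorts at
posterior fractions 0.5/0.6/0.7 and test calibration on 500 replicate
null cohorts; correlation contrast on 100 replicate cohorts with the
protein either tracking the mRNA enrichment or fixed at 0.5. These sizes
were chosen so the whole suite runs in a few minutes while leaving the
Monte Carlo margins comfortably wider than the assertion tolerances.

## Known limitations

* The unit calibrated from crowded images is biased (up to ~25% in
  $I_u$ on our densest synthetic cohorts) because truly isolated spots
  are scarce; the bias is a scale factor that cancels in posterior
  fractions and anterior/posterior comparisons, but absolute unit counts
  from such images should be treated with caution.
* The reconstruction assumes a single spot species; a mixture of unit
  sizes would be absorbed into count variance.
* The bisection is a straight line through the nucleus; strongly bent
  cells would need the manual-ROI path.
* Group-mean correlations over three stream positions rest on three
  points; the per-cell correlation is the statistically serious variant.
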