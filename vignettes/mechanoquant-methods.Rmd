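---
title: "Methods: quantifying substrate-stiffness effects on cell mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying substrate-stiffness effects on cell mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechanoquant)
```

`mechanoquant` implements the quantitative chain used to study how the
stiffness of the extracellular environment shapes epithelial cancer cell
behaviour: measuring tissue and hydrogel stiffness by AFM microindentation,
measuring the forces cells exert on hydrogels by traction force microscopy
(TFM), and quantifying the downstream phenotypes — migration, durotaxis,
spheroid disaggregation, adhesion morphology, colocalization, and YAP1
nuclear translocation. Because raw microscopy data of this kind are rarely
deposited, the package pairs every estimator with a synthetic-data generator
that emits the matching ground truth, so the whole chain is validated by
parameter recovery rather than by comparison to inaccessible recordings.

## AFM microindentation and the Hertz model

A spherical probe of radius $R$ pressed a depth $\delta$ into an elastic
half-space with Young's modulus $E$ and Poisson ratio $\nu$ experiences the
Hertz (paraboloidal-approximation) force

$$F = \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2},$$

valid for $\delta \ll R$. Units are Pa, µm and nN throughout
(`hertz_force()`). Defaults mirror a common soft-tissue configuration: a
5 µm borosilicate sphere ($R = 2.5$ µm) on a 0.06 N/m cantilever, $\nu = 0.5$
(tissues and fully swollen polyacrylamide behave as incompressible; the
tissue value is an assumption, stated, not measured).

Fitting proceeds in two steps:

1. **Contact point.** A two-segment model (flat baseline, then Hertz) is fit
   to the *whole* curve with the changepoint free
   (`detect_contact_point()`), initialized at the first sustained crossing
   of baseline + 3 noise SD. The baseline segment is what anchors the
   changepoint; this matters below.
2. **Modulus.** Samples whose force lies outside 15–80% of the curve's
   maximum force are discarded (the curve's extremes are where baseline
   drift and substrate effects live), and $E$ — which enters linearly — is
   solved in closed form on the remaining samples with the contact point
   held fixed (`fit_hertz()`).

Two choices deserve comment. The 15–80% exclusion is interpreted on the
*force* axis; the indentation-axis reading is also defensible, but the
force-axis convention is robust to differences in piezo range and is
configurable (`window =`). And the contact point is deliberately *not*
re-refined on the windowed samples: the window excludes the baseline, so the
changepoint would be unconstrained there, and Monte-Carlo experiments show
that joint re-refinement induces a systematic low bias of about 2% in $E$ at
2% force noise, while the fixed-contact scheme is unbiased to about 0.1%.

Force maps (`build_force_map()`) assemble 8×8 grids of fits over
20×20 µm regions (2.5 µm spacing); failed fits propagate as flagged `NA`
cells, never as zeros. `render_heatmap()` reproduces the two display modes
for such maps — each map scaled to its own extrema (`local`) or a whole set
sharing one scale (`global`) — and `summarize_moduli()` provides the
box-plot order statistics. The tissue generator (`gen_force_map_grid()`)
emulates the empirical structure of soft peritoneum: a 4.33 kPa background
with sparse ~10× stiffness hotspots hitting roughly 1 map in 15.

## Traction force microscopy

### Forward model

On a semi-infinite incompressible elastic substrate, tangential surface
traction $\mathbf T$ and surface displacement $\mathbf u$ are linked per
wavevector $\mathbf k = (k_x, k_y)$ by the Boussinesq Green tensor

$$\hat{\mathbf u}(\mathbf k) = G(\mathbf k)\, \hat{\mathbf T}(\mathbf k),
\qquad
G = \frac{2(1+\nu)}{E k^3}
\begin{pmatrix}(1-\nu)k^2 + \nu k_y^2 & -\nu k_x k_y\\
-\nu k_x k_y & (1-\nu)k^2 + \nu k_x^2\end{pmatrix}.$$

`forward_displacement()` evaluates this spectrally with zero-padding to
suppress periodic wrap-around (factor 2 by default; the dipole far field
decays slowly, so oracle-grade comparisons use `pad = 6`). An independent
real-space implementation (`forward_displacement_pointsum()`, the
Cerruti point-force solution summed over loaded cells) exists purely as a
cross-check so that the inverse solver is never tested against its own code
path; the two agree to ~0.1% median where the point-force idealization is
valid. The ~65 µm gel is treated as semi-infinite, as is conventional for
these displacement magnitudes.

### PIV

Displacements between the zero-force reference (cells lysed) and the loaded
bead image are estimated by three-pass normalized cross-correlation block
matching (`piv_multipass()`): first pass interrogation/search/spacing =
128/256/64 px, each subsequent pass halving all three, search windows offset
by the previous pass's prediction. Correlations below 0.8 invalidate a
vector, which is then replaced by the median of its valid neighbours —
standard robust PIV practice. Peaks are refined by a three-point Gaussian
fit, except when the peak correlation is exactly 1 (a perfect lattice match,
where refinement could only add noise) — this makes the zero-motion field
identically zero. Measured accuracy on bead fixtures: ≈0.05 px RMS for
uniform subpixel translations, ≈0.1 px RMS on smoothly varying dipole
fields. Rigid drift between frames is removed beforehand by whole-frame
correlation (`register_translation()`), whose shifts can be applied to the
companion phase-contrast channel (`apply_shifts()`).

### Inversion and regularization

`fttc()` inverts the forward model per wavevector with Tikhonov damping:

$$\hat{\mathbf T}_\lambda = (G^\top G + \alpha I)^{-1} G^\top \hat{\mathbf u},
\qquad \alpha = \lambda\, s_{\max}^2,$$

where $s_{\max}$ is the largest singular value of $G$ over the sampled
wavevectors. This makes $\lambda$ dimensionless and portable across grid
sizes and stiffnesses — unlike the absolute regularization factors of
plugin implementations, whose internal scaling is tool-specific.
To map such absolute factors onto this convention the package ships a
calibration: on displacement-matched dipole fixtures (~5 px peak
displacement, 1% camera noise) the traction-RMSE-optimal weight is
$\lambda \approx 2\times10^{-3}$, and — because the problem is linear in
$E$ — the *same* dimensionless optimum holds at 3, 25 and 125 kPa. That
value is the pipeline default; with it, the full
simulate → register → PIV → FTTC chain recovers a contractile-dipole
traction field with spatial correlation ≈0.95–0.96 against ground truth.

Displacement fields are edge-tapered (cosine, 10%) and zero-padded to twice
their size before inversion; the mean (k = 0) component, which the
half-space problem cannot determine, is zeroed.

`l_curve_sweep()` computes the residual-norm/solution-norm table across a
λ sweep and returns the point of maximum curvature of the log-log curve
(`l_curve_corner()` is the generic corner finder). A known limitation,
found during validation and worth stating plainly: on the *discrete* FTTC
problem the system matrix is square and well-conditioned, the residual
vanishes as $\lambda \to 0$, and the L-curve has no sharp corner — the
curvature maximum sits well above the RMSE-optimal weight. The corner
finder is validated instead on a classical ill-posed Tikhonov problem
(severely smoothing kernel), where it matches a brute-force dense-grid
curvature search to one grid step. For FTTC itself, the fixture-calibrated
default above is the recommended route; the sweep table is still returned
for inspection, with monotone branches guaranteed.

Cell contours (`mask_traction()`, polygons or masks) clear tractions
outside the cell, and `traction_metrics()` reports the figures of merit:
maximum and mean traction magnitude, cell area, and total cell strength =
area × mean traction (an exact identity in the implementation, reported in
Pa·µm²).

## Migration and durotaxis

Tracks are (t, x, y) series per cell, either supplied or produced by
`detect_nuclei()` (threshold + connected components + centroids; a stand-in
for commercial trackers, adequate for well-separated stained nuclei) and
`link_tracks()` (greedy nearest-neighbour with ascending-distance
tie-breaking and one-frame gap closing). `migration_metrics()` computes the
maximum displacement from the origin, path length, and mean speed; a cell is
*migrating* when its maximum displacement strictly exceeds 50 µm
(`percent_migrating()`). The threshold is strict by specification — exactly
50 µm is non-migrating — and an alternative classifier based on leaving a
circle of twice the cell diameter is available (`cell_diameter =`), since
both definitions appear in practice. Tracks spanning less than 80% of the
movie are excluded from the percentage by default (attrition policy;
configurable).

Durotactic responses are quantified as the turn angle
$\theta = \arccos(\hat{\mathbf d}_{\text{before}} \cdot
\hat{\mathbf d}_{\text{after}}) \in [0°, 180°]$ between the direction of
travel (or morphological long axis) just before the stimulus and 75 minutes
after (`turn_angle()`; `track_direction()` extracts smoothed tangents from
tracks, 3-frame window, and each result records which source was used).
`color_coded_projection()` renders the standard time-coded
maximum-projection overview of a movie.

The track generator is a persistent random walk: per frame the heading
turns by a wrapped-normal angle with SD $(1-p)\pi$, $p \in [0,1]$ the
persistence. Defaults — 15 min frames, 57 frames (14 h), migrating cells at
0.35 µm/min with $p = 0.8$ — were chosen once so that migrating cells show
a mean maximum displacement near 125 µm (the scale reported for stiff
substrates) while exceeding the 50 µm threshold with probability >0.99, as
the recovery tests require; non-migrators jitter with 1 µm SD. The
durotaxis generator draws stretched-cell turn magnitudes from a folded
normal centred at 75° (SD 20°) versus controls at 0° (SD 15°), with 20
cells per arm — larger than the handful typical of micropipette
experiments, so that replicate-level detection-rate statistics are stable.

## Spheroid disaggregation

`segment_spheroid()` outlines the aggregate footprint. The default pipeline
is Gaussian smoothing → Otsu threshold on the absolute deviation from the
background level (median of the image border) → morphological closing →
hole filling → size filtering. A texture route (Otsu on a local
standard-deviation map) is provided for phase-contrast images whose
aggregate matches the background in mean intensity; it is not the default
because the texture filter's support dilates the boundary by its kernel
radius, which breaks the ≤2% disk-area accuracy the package holds itself to
for radii ≥50 px. Manual polygon outlines are accepted verbatim. At the
initial timepoint the largest component is the spheroid; at the late
timepoint `mode = "union"` counts all fragments above the size filter
(disaggregation *is* dispersal), with a convex-hull option.

`disaggregation_fold()` is the assay statistic: footprint area at ~20 h
divided by the area at ~2 h, with a relative-area mode normalizing each
spheroid to its own initial size. Generator scenarios reproduce the
reported ~6.6-fold (25 kPa) and ~8.5-fold (125 kPa) spreads; recovery is
well within 5%.

## Fluorescence quantifications

* `cell_area()`: Otsu threshold of the F-actin (phalloidin) channel, hole
  fill, largest component; flags when a second sizeable cell is present.
* `segment_adhesions()`: constant background subtraction (median within the
  cell mask), threshold, connected components ≥0.25 µm² (configurable —
  the floor suppresses single-pixel noise at 0.1075 µm pixels); per-ROI
  area, centroid, mean intensity and aspect ratio from the coordinate
  covariance eigenvalues (exactly the best-fit-ellipse axis ratio for solid
  ellipses). ROIs can be transferred to other raw channels;
  `adhesion_intensity_ratio()` reports per-adhesion mean-intensity ratios
  (e.g. pFAK : vinculin), excluding ROIs with non-positive denominators.
* `manders()`: classical split coefficients —
  $M_1 = \sum_i a_i [b_i > t_b] / \sum_i a_i$ and symmetrically $M_2$ —
  with thresholds defaulting to 0 and a Costes-style automatic mode
  (`auto = TRUE`, common-quantile walk-down until below-threshold pixels
  decorrelate), since published analyses rarely state which was used.
  Pearson's r over the joint above-threshold mask is also reported.
* `linescan()` / `pearson_linescan()`: bilinear sampling along a segment
  averaged across a perpendicular width, and the Pearson correlation of two
  profiles.
* `nuc_cyto_ratio()`: mean signal in the nuclear mask over the mean in the
  cytoplasm, where the cytoplasm is the cell mask minus the nucleus dilated
  by 2 px (nuclear-envelope bleed margin; configurable).

## Synthetic data: what it does and does not show

Every generator takes a `sim_config(seed, noise_sd)`; identical configs give
bit-identical output, all randomness flows through a private RNG stream
(callers' `.Random.seed` is untouched), and `noise_sd = 0` yields the exact
analytic skeleton. Noise levels are deliberately explicit: the source
experiments publish no noise magnitudes for raw curves or images, so the
defaults used in tests (2% force noise for AFM, 1–2% camera noise for
images) are stated assumptions, chosen once as representative of
well-configured instruments.

The generators emulate the *geometry and statistics* the estimators depend
on — Hertzian curves with a contact point, Gaussian diffraction-limited
beads displaced by the true forward model, persistent random walks with a
known migrating fraction, irregular-boundary spheroids with exact mask
areas, spot patterns with exact overlap fractions, uniform-compartment
cells with exact N:C ratios. They do not emulate optical point-spread
functions beyond Gaussian spots, uneven illumination, focal drift,
cell-shape variation, out-of-plane (2.5D/3D) displacements, or
segmentation-confounding debris. Passing recovery tests therefore
demonstrates correctness of the estimators under their stated models, not
robustness to every pathology of real microscopy; parameters that absorb
such pathologies (thresholds, minimum sizes, correlation cutoffs) are
exposed and recorded in outputs.

## Numerical choices and problem sizes

Tests and the acceptance script run on one CPU in a few minutes; problem
sizes were chosen as the smallest that exercise the stated configurations:
TFM fixtures at 512×512 px (the smallest size admitting the 256 px
first-pass search window with a meaningful grid), 200 curves per modulus,
200 tracks, 50 replicate assays. Degenerate inputs fail loudly by policy:
flat force curves, empty masks, zero-length direction vectors, zero-area
contours and blank segmentations raise errors rather than returning
defaults; PIV vectors failing the correlation threshold and adhesions with
zero denominator are flagged and interpolated/excluded, and both policies
are tested.
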