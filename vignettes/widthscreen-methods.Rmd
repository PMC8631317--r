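---
title: "Measuring bacterial cell width at screening scale: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring bacterial cell width at screening scale: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(widthscreen)
library(dplyr)
```

## The problem

Rod-shaped bacteria such as *Bacillus subtilis* keep their diameter nearly
constant — wild-type populations in exponential growth vary by under 2%
between replicate cultures, with a cell-to-cell standard deviation of only
0.07–0.09 µm. That tight control makes width a sensitive phenotype: a
genome-scale knockout collection can be screened for width mutants if one
can (i) measure single-cell width reproducibly from membrane-stained
fluorescence images, (ii) compare thousands of strains imaged on different
96-well plates without a wild-type reference well, and (iii) verify
candidate hits with statistics that respect the replicate structure of the
experiments. `widthscreen` implements that full pipeline, together with a
synthetic-data generator that renders membrane-stained cells with known
ground truth so every stage can be validated end to end.

## Synthetic microscopy with known truth

A simulated cell is a spherocylinder: a cylinder of diameter $w$ and
pole-to-pole length $\ell \ge w$ capped by hemispheres. The fluorescent
signal of a membrane stain lives on the cell surface, so the renderer
draws a uniform-intensity band of configurable thickness (default 1 pixel
before blurring) centred on the projected outline, evaluates it on a
4-fold supersampled grid (anti-aliasing the thin band), convolves with an
isotropic Gaussian point-spread function, and adds background, shot noise
(Gaussian with variance `signal / photon_scale`) and Gaussian read noise
before quantising to the camera's bit depth. Tapered cells interpolate
their diameter linearly between two pole diameters — the simplest shape
that reproduces division-site mutants whose single cells span 0.7–1.4 µm.
Minicells are rendered as near-spheres, chains as collinear cells touching
pole to pole, and fixation artifacts as bright membrane puncta.

Two optics dialects bracket the acquisition regimes of a real screen:

| dialect | pixel size | PSF sigma | emulates |
|---|---|---|---|
| `"hcs"` | 115 nm | 0.18 µm | automated high-content microscope (lower NA) |
| `"epi"` | 65 nm | 0.12 µm | research epifluorescence scope, 100× objective |

The 115 nm pixel matches the high-content instruments such screens use;
the epifluorescence pixel size is a convention (the 100× setup's exact
camera geometry is not standardised), chosen so the dialect is roughly
twice as finely sampled, which is what matters for the comparisons the
package makes. Rendering is bit-exactly reproducible: every stochastic
element (noise, focus placement, well sampling) draws its stream from a
root seed plus a string path (`plate`, `well`, `field`), so plates can be
generated piecewise in any order.

What the generator deliberately does *not* emulate: 3-D structure and
defocus, photobleaching, uneven illumination, staining heterogeneity
beyond per-cell intensity, and condition shifts (fixation, magnesium)
other than a scalar width multiplier. Passing tests on synthetic images
therefore demonstrates that the *measurement definitions* are implemented
correctly and are unbiased under the modelled optics — not that any real
microscope is free of systematic error. The package mirrors the practical
consequence: high-content images report slightly larger absolute widths
than epifluorescence images, so all comparisons are made within one
dialect, never across dialects.

## Width along the medial axis

The measurement definition is the field's standard one: *cell width is the
mean cross-sectional diameter along the medial axis*, and cell length is
the axis arc length plus one width (restoring the two hemispherical caps
of ~$w/2$ that a skeleton does not reach).

Segmentation is deliberately plain — Gaussian smoothing, Otsu threshold,
morphological closing, hole filling (the stained shell becomes a filled
body), connected components, minimum-area filter — because detection only
needs to be reliable, not unbiased. The measurement then works at
sub-pixel precision on top of the mask:

1. **Medial axis.** Zhang–Suen thinning gives the topological skeleton,
   pruned to its longest path (weighted by Euclidean step length) between
   endpoints. Thinning has two end artifacts, handled explicitly: residual
   tails that run into a pole (endpoint pixels are topologically
   protected) are cut where the distance transform still climbs at the
   cap's characteristic ~1 px/px rate; and conversely, ends that stop
   short are extended by tracing the distance-transform ridge outward
   (re-centring laterally each step, so curved cells are followed along
   their own centreline) until the cap's distance drop terminates the
   trace. The final endpoint is placed by a boundary-inset rule — walk a
   straight ray to the mask's sub-pixel 0.5-level pole boundary, step back
   by the local mask radius — which is exact for a uniformly dilated
   capsule and puts the axis end half a width inside the pole regardless
   of how far the blurred mask over-segments.
2. **Width profile.** At each axis point the diameter is measured along
   the perpendicular. The mask gives a first estimate (sub-pixel 0.5-level
   crossings of the bilinearly interpolated component). When the source
   image is available — the default — each boundary is refined to the
   membrane intensity ridge by a local quadratic peak fit. This choice is
   load-bearing: the outer threshold crossing of a blurred thin shell is
   displaced outward by a quantity of order the PSF width, which differs
   between optics dialects, whereas the ridge peak of a symmetric band is
   blur-invariant. It is also the same definition as the manual
   cross-check used with membrane stains (the peak-to-peak distance of an
   intensity line profile, exposed as `profile_maxima_width()`).
3. **Cap exclusion.** Axis points within $0.5 \times$ the median profile
   diameter of either axis end lie on the hemispherical poles, where the
   cross-section narrows geometrically; including them would bias the
   width mean downward, so they are excluded. A cell whose entire profile
   falls inside the cap zones is a sphere for all practical purposes: it
   is flagged `minicell`, its width falls back to the maximum profile
   diameter, and it never contributes to length statistics.

On noise-free synthetic rods this stack recovers width to within a
quarter pixel in both dialects, varies by less than half a pixel across
orientations, and recovers length to within one pixel on the
epifluorescence dialect (the heavily pixelated high-content poles carry
slightly more length uncertainty, up to ~1.4 px; widths are unaffected).
A +15% width difference between two populations reads identically
(±2 percentage points) through either dialect, which is the property that
lets a low-resolution screen rank strains correctly even when its absolute
calibration is off.

Exclusion rules are applied in a fixed order with recorded reasons:
border-touching; area outside a configurable range; solidity < 0.7
(aggregates of touching cells — note that only clumped or angled contacts
are caught this way; two parallel touching rods merge into a nearly convex
slab and must be avoided upstream by plating density); and
`length < 1.5 × width` (minicells — flagged, kept for width by default,
always excluded from length). `filter_cells()` never drops rows, so
kept + excluded always reconstructs the input.

```{r measure-example}
sc <- render_scene(
  scene_spec(c(120, 120),
    place_cells(sample_well(4, seed = 8), c(120, 120), 0.115, seed = 8),
    seed = 8
  ),
  optics_dialect("hcs")
)
measure_cells(sc) |>
  filter_cells() |>
  select(cell_id, width_um, length_um, sv_um_1, kept)
```

## Spherocylinder surface and volume

Shape descriptors use the spherocylinder closed forms
$S = \pi w \ell$ and $V = \pi w^2 (3\ell - w)/12$, so
$S/V = 12\ell / (w(3\ell - w))$, degenerating to the sphere
($S/V = 6/w$) at $\ell = w$. The geometric model is an idealisation — real
cells taper and bend — but it is applied uniformly to all strains, so
*relative* S/V differences are meaningful. The closed forms are verified
against numerical integration of the capsule's solid of revolution to
$10^{-6}$ relative accuracy.

## Plate normalisation and hit calling

A screen has no wild-type well on its plates, so each strain is scored
against the **average cell width per plate (AWP)**: the arithmetic mean
width of *all* measured cells of its plate (equivalently, the
cell-count-weighted mean of well means; typically 17–19 × 10³ cells).
Each strain's deviation is

$$\Delta\text{width}\,(\%) = \frac{\bar w_\text{strain} - \text{AWP}}{\text{AWP}} \times 100.$$

The AWP is robust by construction: with equal per-well counts,
$k$ contaminated wells with a common effect $e$ shift it by exactly
$(k/96)\,e$ — ten wells at +13% (about the largest effect such a screen
produces) move the reference by only ~1.35%. `awp_sensitivity()` is that
closed form, and the test suite checks it against brute-force plate
recomputation to $10^{-12}$ relative.

Wells with fewer than 30 measurable cells are flagged for re-acquisition
and excluded from both the AWP and hit calling, mirroring how a live
screen would repeat the acquisition rather than score it.

Hit calling keeps the `tail_fraction` (default 0.5%) most extreme strains
per tail. The percentile rule is realised as **fixed tail counts**
$k = \mathrm{round}(0.005\,N)$: interpolated-percentile conventions
disagree about whether 38, 39 or 40 of 3,983 strains fall outside the
0.5th/99.5th percentiles, while tail counts give exactly 40 — the size a
1%-most-affected selection should have at that library size. Ties break
by ascending strain id so the call is deterministic.

```{r screen-example}
planted <- tibble::tibble(strain_id = c("S0010", "S0123"), delta_pct = c(14, -11))
cells <- simulate_screen(
  n_strains = 192, cells_per_well = 60,
  planted = planted, seed = 42
)
scr <- screen_strains(cells, tail_fraction = 0.005)
scr
tidy(scr) |> filter(selected)
```

## Verification statistics

Stage-2 verification compares candidates to a wild-type reference over at
least three independent replicate experiments. The experimental unit is
the replicate, not the cell, so the **nested t-test** reduces each
replicate to its mean and runs a two-sample pooled-variance t-test on the
replicate means ($df = R_a + R_b - 2$). For balanced designs this equals
the nested test of common statistics packages; it is implemented in closed
form so the degenerate zero-variance case is defined ($t = 0$, $p = 1$
when the means coincide). The unbalanced mixed-model variant is out of
scope. One-way ANOVA (replicate comparability) and the Mann–Whitney test
(generation times, where cell-level normality is unavailable) come from
base R's `oneway.test` and `wilcox.test`; the Mann–Whitney exact path is
cross-checked against full enumeration in the tests. Significance stars
follow the usual printed convention, with boundary p-values assigned to
the *less* significant bin since the convention leaves boundaries
ambiguous.

A candidate is **confirmed** when its pooled width differs from the wild
type by at least 8% (the stringent cutoff a backcrossed verification
stage uses), the nested t-test gives $p < 0.05$, and the per-replicate
deltas share one sign — "reproducibly wider or thinner" made operational.
One escape hatch mirrors a real phenotype class: a strain whose *mean*
width is nearly normal but whose individual cells are strongly uneven
(diameter CV above 0.12 along single cells) is rescued when more than 10%
of its cells carry the `uneven_width` flag. Both thresholds are
configurable; 10% sits well below the ~19% affected-cell fraction of the
motivating division-site mutant while staying far above the false-flag
rate on straight cells. No multiple-testing correction is applied across
candidates, matching stage-2 practice where each candidate is re-measured
independently; a corrected variant is a one-liner with `p.adjust` on the
returned p-values.

## Generation time from OD600 curves

Growth curves are summarised by the maximal exponential rate:
$GT = \ln 2 / \mu_{\max}$. The estimator slides a `window_points = 5`
regression window over log-OD, restricted to the mid-exponential band
(OD within `[0.02, 0.5 × max]`), weights each window regression by OD²
(the delta-method variance of log OD under additive reader noise), and
keeps windows with $r^2 \ge 0.98$.

Two rate definitions are offered. The naive `"max_slope"` (steepest
qualifying window) carries two opposing biases we quantified on simulated
logistic curves: an order-statistic bias (the maximum over many noisy
window slopes overestimates $\mu$, worst for slow growers where relative
noise is largest) and a saturation bias (per-capita growth declines
continuously with density, so even the steepest *observable* window
underestimates the low-density rate). The default `"extrapolated"` method
removes both: for logistic growth the per-capita rate is exactly linear
in density, so regressing qualifying window slopes on their window mean
OD and taking the zero-density intercept recovers $\mu$ unbiasedly, and
because it pools all windows the noise bias largely cancels. The method
falls back to `max_slope` when fewer than five windows qualify or the
slope–density relation is not decreasing; on an exact exponential both
methods coincide (GT = 20.000 min on a 20-min doubling curve, to
$10^{-6}$). Under realistic conditions — 10-min sampling, OD noise
SD 0.002, carrying capacity 1.5 — the median |GT error| over
GT ∈ [15, 60] min is about 1.4%, versus ~4.5% for `max_slope`.

Curves that never double report `no_growth`; curves with no linear window
report `poor_fit`; OD is floored at $10^{-4}$ before the log-transform so
noisy blanked readings cannot produce `-Inf`.

```{r growth-example}
gm <- growth_model(od0 = 0.01, gt_true = 25, lag = 60, noise_sd = 0.002, seed = 3)
fit <- estimate_gt(simulate_growth_curve(gm, seq(0, 600, 10)))
fit
```

The growth-law diagnostic `growth_length_correlation()` regresses
per-strain mean length on GT and reports $r^2$ — used to ask whether a
mutant class's length changes simply mirror its growth-rate changes.

## Numerical choices and problem sizes

* Coordinates: pixel centres at integer positions, 0-based, x = column;
  all public outputs in µm (4 decimals in CSV exports).
* Sub-pixel sampling steps: 0.2 px along width perpendiculars, 0.125 px
  for boundary-crossing rays; peak refinement windows are 1.5 px.
* Tie-breaks are lexicographic by strain id everywhere a rank or
  selection could otherwise depend on input order.
* The validation suite exercises, among others: a full measurement-level
  screen of 3,983 strains × 200 cells on 48 plates with 40 planted
  effects of |Δwidth| ≥ 9% (≥ 38/40 must be recovered, and 0/1,000 null
  candidates may pass the 8% verification cutoff); a width-recovery grid
  over w ∈ [0.7, 1.5] µm in both dialects; and 200 simulated growth
  curves spanning GT ∈ [15, 60] min. Image-level simulation is exercised
  on small fields (a few cells per field) — the per-image statistics are
  identical at larger cell counts, only slower.

## Known limitations

* Filament-forming chains are measured per segmented component, not
  traced as biological chains; heavily clumped fields are excluded as
  aggregates rather than split.
* The solidity rule cannot separate two parallel touching rods (their
  union is nearly convex); such contacts must stay rare in the input.
* Absolute widths are dialect-dependent by design; no cross-dialect
  calibration is attempted.
* The logistic generator and the rate extrapolation share the assumption
  that per-capita growth declines roughly linearly with density over the
  fitted band; strongly diauxic curves would need the `max_slope` method
  and a narrower OD band.
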