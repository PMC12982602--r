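---
title: "Mapping agricultural drought impacts from LAI relative thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping agricultural drought impacts from LAI relative thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtlai)
```

## The problem and the method

Annual drought statistics published at provincial level record, per year and
severity degree, the sown area whose drought-caused yield losses exceeded
10% (*drought-covered*, DC), 30% (*drought-damaged*, DD) and 80% (*crop
failure*, CF) — but only as regional annual totals. Satellite leaf-area-index
(LAI) composites observe every 500 m pixel every 8 days but do not say which
pixels were drought-impacted. The method implemented here bridges the two: it
calibrates, per region, crop-season class and severity degree, a **relative
LAI threshold** and a **key phenological time window** such that the pixels
flagged by the threshold reproduce the historical annual statistics, then
uses the calibrated rule to map impacts at pixel scale.

A pixel $i$ is flagged at degree $d$ in year $y$ when its window-mean LAI
falls to or below a percentage $T_d$ of its **own** baseline value:

$$\mathrm{EA} = A \sum_i I\!\left(\overline{\mathrm{LAI}}_{i,y} \le
\tfrac{T_d}{100}\,\overline{\mathrm{LAI}}_{i,\mathrm{base}}\right),$$

where $\overline{\mathrm{LAI}}$ is the mean over the composites of the key
window, $A = 25\ \mathrm{ha} = 0.025$ thousand ha is the pixel area, and the
baseline year is the year with the weakest impacts summed over the three
degrees. The threshold is *relative* — each pixel is compared with itself in
the baseline year — so spatial heterogeneity in absolute LAI (soil, crop
variety, topography) cancels and naturally sparse vegetation is not mistaken
for drought.

For a region growing several crop-season classes (summer-harvest,
autumn-harvest, early rice), per-crop extractions are summed and anchored at
the baseline-year statistic:

$$\mathrm{EA}(y) = \mathrm{EA}_s(y) + \mathrm{EA}_a(y) + \mathrm{EA}_e(y) +
\mathrm{HA}_{\mathrm{base}},$$

and the estimated series is scored against the historical series
$\mathrm{HA}(y)$ with the Pearson correlation $R$ and the root-mean-square
error (RMSE, thousand ha).

## The search space

Candidate windows are all contiguous runs of 8-day composites inside the
crop's growing season: $m$ composites give $m(m+1)/2$ candidates (a DOY
145–273 season holds 17 composites, hence 153 candidates). Thresholds run
over the integer grid 0–100%. Candidates are computational search objects;
the single selected window per crop — the *key phenological period* —
typically lands on the yield-sensitive stages (heading/grain filling), where
drought stress translates most directly into end-of-season statistics.

## Selection rule and window scope

Two design points were genuinely open and are resolved as follows; both are
configurable.

**Selection rule** (`selection`, default `"rmse_r"`). The optimum is the
candidate with "highest R and lowest RMSE". Those two objectives need an
order. Ranking by $R$ first makes RMSE inoperative on any noisy data (exact
ties in $R$ have probability zero) and $R$ is affine-invariant — a candidate
whose EA is ten times HA can score $R = 1$ — so $R$ alone cannot anchor the
*magnitude* of the threshold. The default therefore ranks by lowest RMSE,
breaking ties by highest $R$, then by smaller $T$, then by earlier/shorter
window. On noise-free data the two orderings coincide (the truth candidate
attains $R = 1$ and RMSE $= 0$); in our noisy recovery experiments the
RMSE-first rule recovered thresholds at the truth window in 91% of
replicate–degree pairs versus 40% for the $R$-first rule. `"r_rmse"` is
retained as an option.

**Window scope** (`window_scope`, default `"per_crop"`). One key window can
be selected per crop (shared by the three degrees) or per (crop, degree).
The default is per crop: the three degree series are re-uses of the same
biological signal, a single phenological period per crop is the natural
reading of the method's "key phenological period", and pooling the three
degrees' fits (each degree's best-threshold RMSE normalised by the standard
deviation of its historical series, summed) triples the information
constraining the window, which measurably stabilises it against noise.

## The multi-crop joint search

With two or three crops per region the exhaustive joint search over all
(window, threshold) assignments is combinatorially infeasible
($\sim 10^4$–$10^6$ windows pairs $\times 101^2$–$101^3$ thresholds). Plain
one-crop-at-a-time coordinate descent (initialised at $T = 100$ with the
full-season window) proved unreliable: on the bundled two-crop region it
converges to a non-global equilibrium where neither single-crop sweep can
improve, because the first swept crop absorbs part of the other crop's
signal.

The implementation instead performs **block coordinate descent over crop
pairs**, where each block move is an *exact* joint search of one pair's two
(window, threshold) assignments with the remaining crops held fixed. The
move is tractable because for a fixed window pair both the squared-error and
the correlation surfaces over the $101 \times 101$ threshold grid decompose
into per-crop inner products plus a single cross-product matrix
($M_a M_b^\top$), all vectorised. For a two-crop region the single block
move *is* the exact joint search, and on the bundled scenario it recovers
every truth threshold and window exactly. With three crops the pairwise
blocks remain an approximation of the full joint optimum; they subsume every
single-crop move and all pairwise escapes.

## The synthetic scene generator

The generator supplies every input the pipeline needs — LAI cube, crop
masks, region partition, historical statistics — with known ground truth, so
calibration can be tested as parameter recovery. What it emulates, per
pixel:

* **Seasonal phenology**: a raised-cosine bell over each crop's growing
  season with a per-pixel amplitude drawn once from `amplitude_range`
  (default 1.5–6.5 LAI units) and a per-pixel timing jitter
  (`phenology_shift_days`) emulating spatially varying sowing dates. Pixels
  in a double-cropping footprint carry both the summer and the autumn bell.
* **Ordinary inter-annual variability** (`annual_amplitude_cv`): a mean-one
  lognormal factor multiplying the pixel's curve independently each year —
  the weather/management variability real composites show on top of drought
  signals. This term matters: without it, every event-free year is an exact
  copy of the baseline, all candidate windows carry essentially the same
  information and the key window is unidentifiable in principle.
* **Drought events**: per (year, crop), a seeded random fraction of the
  region's crop pixels has the composites of the crop's truth window
  depressed so that the *window-mean* LAI is scaled by exactly
  $(1-d_p)$. Per-pixel depressions $d_p$ spread around the event's mean
  (`depression_spread`) so pixel ratios form a continuum — this is what makes
  the truth threshold identifiable on the 1% grid — and the within-window
  temporal profile varies per pixel (`event_profile_sd`), emulating varying
  drought onset, which distinguishes the truth window from its sub- and
  super-windows.
* **Statistics**: derived from the generated cube with the *same* indicator
  rule and code path as calibration (so noise-free statistics are exactly
  recomputable by a brute-force pixel loop), then multiplied by a mean-one
  lognormal factor with CV `stats_noise_cv`; the baseline year is clamped to
  the series minimum so it remains the weakest-impact year.

What it does **not** emulate: spectral/radiometric effects, cloud-gap
patterns beyond a uniform random fill mask, spatially correlated weather,
mixed pixels, multi-modal cropping calendars, or reporting biases in the
statistics. Passing recovery tests therefore demonstrates the correctness
and statistical behaviour of the calibration machinery under the stated
generative assumptions, not performance on real satellite composites and
published drought statistics.

### Bundled study scenarios

`scenario_default()` (the main experiment): 24 × 40 pixels at 500 m,
2006–2020, region R1 (autumn only, season DOY 145–273 — the 153-window
season) and region R2 (summer + autumn, 60% double-cropped), 4–5 drought
years per crop with fractions 0.25–0.6 and mean depressions 0.40–0.55,
`depression_spread = 0.8`, `event_profile_sd = 0.6`,
`phenology_shift_days = 10`, `annual_amplitude_cv = 0.1`, and 2013 kept
event-free as the designed baseline. `scenario_reduced()` (Monte-Carlo
replication): one 16 × 16 region, a 10-composite season (55 windows), four
events, LAI noise 0.02, statistics CV 0.05. These sizes keep a full
calibration at seconds-to-minutes on one CPU; real provinces are two to
three orders of magnitude more pixels, which changes runtime, not logic.

## Numerical choices

* **Savitzky–Golay smoothing**: the configured window 3 / polynomial order 3
  is over-parameterised (a cubic through three points); the order is clamped
  to `window − 1` with a warning. A 3-point quadratic filter reproduces its
  input exactly, so the default smoothing is a deliberate pass-through;
  heavier smoothing (e.g. window 5) is one config field away. Endpoints use
  the off-centre rows of the edge windows' least-squares fit, so polynomials
  up to the fitted order pass through unchanged along the whole series.
* **Threshold semantics**: the indicator uses `<=` with the comparison
  `actual <= (T/100) * baseline` evaluated identically in the fast
  calibration path (via a per-pixel critical index with one-step
  floating-point fix-ups) and in `extracted_area()`; equality of the two
  paths is asserted by test on random grids.
* **Zero or invalid baselines**: excluded from extraction entirely (a zero
  baseline would flag bare ground at any threshold); such pixels carry code
  99 in the maps.
* **Undefined Pearson R** (zero-variance EA): the candidate is skipped; if a
  historical series itself has zero variance calibration stops with a
  diagnostic.
* **Determinism**: all scene randomness derives from one seed; the grid
  search is deterministic with documented tie-breaks (smaller threshold,
  then earlier/shorter window), so reruns are bit-identical.

## Output conventions

One GeoTIFF per (crop, degree, year), named `{Crop}_{Degree}_{Year}.tif`
with `Crop` ∈ {Autumn, Summer, ER} and `Degree` ∈ {DC, DD, CF}; unsigned
8-bit band; the file for degree $d$ carries only that degree's code (1, 2 or
3), 0 for assessed-but-unimpacted crop pixels, and 99 (= nodata) for
non-crop or invalid pixels. Severity nesting (CF ⊆ DD ⊆ DC) is implied by
ordered thresholds but not enforced during calibration — each degree is
calibrated against its own series — and can be checked and optionally
enforced at mapping time (`check_nesting()`, `enforce_nesting` in the
config). A 15-year run over three crop classes yields 9 files per year, 135
files in total; dataset descriptions quoting different totals for the same
period conflate auxiliary sidecar files with code rasters. Rasters are
written by the package's minimal GeoTIFF codec (uncompressed, single band,
little-endian, pixel-scale/tiepoint/EPSG GeoKey tags plus the GDAL-style
nodata tag), which standard GIS readers open directly.

## Known limitations

* The calibration transfers regional annual statistics to pixels; flagged
  pixels reproduce regional totals and temporal dynamics but are not
  individually validated yield losses.
* One threshold/window per (region, crop class) ignores within-class
  phenological diversity; regions with highly mixed cropping calendars are
  exactly where the real-data analogue of this method performs worst.
* The noisy-recovery experiment (5% statistics noise, four drought years)
  recovers thresholds within ±2 points in roughly 85% of replicate–degree
  pairs in our test runs — short of the 90% design target. The residual
  errors are window-selection errors: a slightly shifted window with a
  compensating (higher) threshold can fit four noisy event years marginally
  better than the truth. More drought years, stronger inter-annual
  variability, or larger regions all sharpen window identification; the
  bundled scenario intentionally keeps the harder, data-poor regime.
* Coordinate descent over crop pairs is exact for two crops; for three-crop
  regions the pairwise optimum is not guaranteed to be the global joint
  optimum.
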