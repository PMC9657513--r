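---
title: "Methods: thermographic segmentation and monitoring of infantile hemangiomas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermographic segmentation and monitoring of infantile hemangiomas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermolesion)
```

## The measurement problem

Infantile hemangiomas (IHs) are benign vascular tumors of infancy. Their
increased blood flow warms the overlying skin by a fraction of a degree,
which a long-wave infrared (LWIR) microbolometer camera can resolve
without touching the patient. Two quantities carry the clinical signal:

* **ΔT**, the temperature difference between the lesion core and the
  surrounding healthy skin. An active, proliferating lesion has ΔT > 0;
  a decreasing ΔT across follow-up sessions indicates a favorable
  response to treatment.
* **the lesion area**, delimited by an isotherm (a contour of constant
  temperature). Reusing the same isotherm level across sessions makes
  areas comparable, and area regrowth flags an undesirable evolution.

`thermolesion` implements the full chain from a calibrated temperature
raster to a longitudinal verdict, plus a synthetic phantom generator with
analytic ground truth so every stage can be validated without clinical
images.

## Frames and calibration

A `thermal_frame` is a matrix of absolute temperatures (°C) with a
validity mask and acquisition geometry: sensor-to-lesion distance $d$,
focal distance $f$, and physical pixel pitch $W \times L$ (all cm).
Invalid pixels are `NA`, never a sentinel temperature, so they cannot
bias downstream statistics. Pixel centers sit at integer coordinates,
origin at the top-left, $x$ = column − 1, $y$ = row − 1; all polygon
arithmetic uses this convention.

Microbolometer response is linear over the physiological range, so
calibration fits $T = a \cdot \text{counts} + b$. With two reference
regions of known temperature both coefficients are solved from the two
(mean counts, temperature) pairs; with a single reference (the common
case when only ambient drift changes between sessions) the gain is fixed
from sensor characterization and only the offset is solved. The fit is
exact at the references by construction.

Interchange formats are CSV (°C, lossy only through printing), 16-bit
TIFF at 0.01 °C per unit with count 0 reserved as no-data (a convention
of this package, chosen to match common radiometric-camera centi-degree
encodings; it cannot represent temperatures ≤ 0 °C), and a lossless
native binary array used wherever bit-exact round-trips matter. Metadata
travels in a JSON sidecar.

## Skin segmentation

Segmentation is histogram thresholding in four steps:

1. histogram the valid temperatures (default bin width 0.05 °C — half
   the 0.1 °C sensor resolution, so binning never hides sensor-level
   structure);
2. discard everything below a floor (default 34 °C): inert background
   objects, clothes and hair are not compatible with body temperature,
   and removing the cold background mode restores the approximately
   bimodal histogram Otsu's method assumes;
3. Otsu's threshold $TH$ maximizes the between-class variance
   $\omega_0\,\omega_1\,(\mu_0-\mu_1)^2$ over all bin edges, where
   $\omega_i$ are class pixel counts and $\mu_i$ class mean temperatures
   at bin centers;
4. pixels at or above $TH$ form the skin mask.

Two numerical choices matter. Removal is represented as mask
invalidation, not as writing 0 °C into the raster, so "removed" pixels
can never contaminate means or histograms. And Otsu ties are broken
toward the *lowest* optimal threshold — which keeps the most skin — with
a $10^{-10}$ relative tolerance band, so splits that are mathematically
tied (e.g. symmetric histograms, or candidate edges separated only by
empty bins) resolve identically regardless of floating-point evaluation
order. The test suite checks the implementation against an exhaustive
search written independently.

Which two classes $TH$ separates depends on what survives the floor:
with the default 34 °C floor the background is already gone and $TH$
splits cooler skin from the warmer lesion; with a floor below the
background temperature $TH$ splits background from skin. Both uses are
exposed deliberately — phantom scenes with a cold background use the
latter to obtain a skin-plus-lesion mask.

## Isotherms and areas

Contours are extracted by marching squares with linear interpolation
between pixel centers, giving sub-pixel, level-accurate isotherms. The
default levels are six equally spaced values over 35.5–38.0 °C, the
range in which skin temperature typically varies around vascular
anomalies; any level can be requested. A level outside the observed
range yields no contours rather than an error.

The valid region is embedded in a one-pixel pad far below any level, so
every iso-line closes: a contour that would run off the image, or into
masked-out pixels, is pinched shut essentially along the outermost valid
pixel centers and flagged `touches_border`. Its area remains computable
but is understood to be truncated; the flag propagates into measurement
records. Saddle (ambiguous) marching-squares cells are resolved by the
cell-center average, and zero-length segments arising from values
exactly at the level are dropped before chaining.

The area inside a closed contour with vertices $P_1\dots P_k$,
$P_1 = P_k$, is the shoelace (coordinate-method) area

$$A = \tfrac12\,\bigl|\,\textstyle\sum_i x_i y_{i+1} - \sum_i x_{i+1} y_i\,\bigr|,$$

orientation-independent by the absolute value and invariant under cyclic
relabeling. With the closing vertex duplicated the two sums already
contain the wrap-around terms; no extra leading terms are needed.

Physical area uses the pinhole model: a pixel of size $W \times L$ at
focal distance $f$ views a skin patch magnified by $(d/f)^2$ at distance
$d$, so

$$A_\mathrm{abs} = A\,(d/f)^2\,W\,L \quad [\mathrm{cm}^2].$$

A published variant of this relation carries the reciprocal factor
$(f/d)^2$, which *de-magnifies* the image-plane area and shrinks with
distance — dimensional analysis and the limit $d = f$ (where both forms
coincide) favor $(d/f)^2$, so that is the default; the
`convention = "printed"` option (CLI flag `--eq3-as-printed`) reproduces
the other form for comparability. $W$ and $L$ are treated as lengths
(cm), as the dimensions of the formula require.

The lesion boundary at a level is the largest-area closed contour at
that level (nested hotter contours and small noise loops are thereby
ignored), with ties broken by the smallest centroid row, then column.

## ΔT: core and surround

Neither "lesion center" nor "surrounding healthy skin" has a canonical
pixel-level definition, so the package fixes both explicitly:

* **core** — the mean over valid pixels strictly inside the boundary
  polygon (even-odd ray casting; centers exactly on the outline are
  excluded, deterministically). A `core = "peak"` option returns the
  hottest interior pixel instead; the mean is the default because it is
  robust to single-pixel noise, at the cost of averaging the Gaussian
  peak down — an attenuation the phantom's closed forms predict exactly.
* **surround** — the mean over valid skin-mask pixels outside the
  polygon but within `ring_px` (default 10 px) of it. Intersecting with
  the skin mask excludes background, clothes and hair; keeping the ring
  narrow keeps the reference local. On a spatially flat skin field the
  choice of ring width is immaterial (the suite asserts ≤ 0.02 °C
  sensitivity); near a Gaussian lesion the ring inevitably contains some
  tail, which the analytic surround mean accounts for.

ΔT = core − surround is invariant under adding a constant to the whole
frame. A variation smaller in magnitude than the sensor resolution
(0.1 °C) is classified `null`; otherwise its sign decides
(`classify_variation()`).

## Longitudinal assessment

A `session_series` holds one lesion's measurements in strict time order
(sessions are typically three months apart). The temperature trend
classifies $\Delta T_\mathrm{last} - \Delta T_\mathrm{first}$ against
the same 0.1 °C resolution; first-versus-last is the default because the
clinical protocol compares sessions pairwise, with a least-squares slope
available as an option for longer series. The area change is the
relative first-to-last difference of the boundary iso-area.

The verdict compares the thermographic trend with the dermatologists'
clinical response through three agreement rules: *agree* iff
(i) positive trend and negative response, (ii) negative trend and
positive response, or (iii) null trend, positive response, and an area
change at or below the "substantially lower" threshold. That threshold
is not quantified clinically; the package defaults to −20% (configurable
and recorded in every output) — small enough that genuine involution
clears it, large enough that contour jitter between sessions does not.

Cohort summaries report class counts, the percentage of lesions with a
detectable variation (one decimal), the mean ΔT with a 90% Student-t
confidence interval (the interval method is this package's choice; a
single lesion or all-unknown ΔT yields a flagged degenerate interval),
and the mean ΔT change over treatment when last-visit values exist. Two
packaged fixtures encode the published study tables this pipeline
replays: per-class first-visit counts for 55 lesions, and per-lesion
(trend, clinical response, area trend) encodings for the 17 monitored
lesions — where the transient regrowth episodes noted after early
treatment discontinuation are kept as annotations, the trend field
following each lesion's overall course. The per-lesion area values in
that fixture are ordinal encodings of "decreased" / "substantially
lower", not measurements, since the underlying frames are unpublished.

## The phantom generator

`generate_phantom()` builds the scene the segmentation model assumes:

$$T(x,y) = \begin{cases} T_\mathrm{bg} & \text{outside the skin region}\\
T_\mathrm{skin} + \sum_j A_j e^{-((x-x_j)^2+(y-y_j)^2)/2\sigma_j^2} + \varepsilon & \text{inside}\end{cases}$$

with $\varepsilon \sim N(0, \sigma_\mathrm{noise}^2)$, plus optional
hair occlusion overwriting a random fraction of skin pixels with
30–33.9 °C values (hair hides the skin beneath it; the 34 °C pre-filter
removes it, as it should). Defaults: $T_\mathrm{bg} = 25$ °C,
$T_\mathrm{skin} = 36.2$ °C, noise 0.05 °C (half the sensor
resolution), rectangular skin region, 30 cm acquisition distance and a
17 µm pixel pitch. All randomness derives from the spec's seed (noise
first, then hair placement), so frames are bit-reproducible; series
derive one seed per session deterministically.

The Gaussian profile gives closed-form ground truth: the iso-set above
level $L$ (for $T_\mathrm{skin} < L < T_\mathrm{skin}+A$) is a disk of
area $\pi\,2\sigma^2 \ln\!\bigl(A/(L-T_\mathrm{skin})\bigr)$, and the
expected core and surround means are elementary radial integrals
(`phantom_core_mean()`, `phantom_surround_mean()`), which the tests also
verify against numeric quadrature. Treated series scale amplitude and
width per session: shrinking scales emulate involution, a rebound
emulates regrowth after treatment discontinuation.

What the phantom deliberately does **not** emulate: spatial skin
temperature gradients, non-Gaussian and non-convex lesion shapes,
camera artifacts (non-uniformity, vignetting, dead pixels), motion blur,
emissivity variation, and physically based bio-heat transport. Passing
the recovery tests therefore demonstrates correctness of the *computational
chain* under the stated scene model, not clinical performance on real
images.

## Validation problem sizes and tolerances

The suite validates each primitive against an independent oracle at
sizes chosen to be decisive yet quick: 1000 random histograms against
exhaustive between-class-variance search (exact match), 1000 random
star-shaped polygons against fan triangulation ($10^{-9}$ relative),
marching-squares areas against pixel counting (within half the
perimeter), against `grDevices::contourLines` (1%), and against the
analytic Gaussian iso-area (5% for $\sigma \ge 10$ px — the
discretization regime where sub-pixel interpolation is trustworthy).
Phantom ΔT recovery is asserted to 0.05 °C, half the sensor resolution,
on 140–180 px frames; end-to-end treated-series phantoms must reproduce
the constructed trend, area change and verdict.

## Known limitations

* Marching squares closes border-crossing contours along the outermost
  valid pixel centers, slightly under-reporting truncated areas (they
  are flagged).
* The Otsu threshold is a bin edge; threshold resolution equals the bin
  width.
* Pixels exactly at the pre-filter floor are kept; values below it are
  discarded, per the "below 34 °C can be discarded" rule.
* The ring-based surround includes lesion tail for lesions wider than
  their iso-disk; ΔT is therefore a conservative (attenuated) estimate
  of the peak elevation, consistently across sessions.
* The 16-bit TIFF convention cannot store sub-zero temperatures; use
  CSV or the binary format for cold scenes.
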