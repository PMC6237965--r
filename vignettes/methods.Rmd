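---
title: "Methods: snow, freeze-thaw and proxy-year analysis of shallow soil temperature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: snow, freeze-thaw and proxy-year analysis of shallow soil temperature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In boreal and tundra ecosystems, winter soil temperature at shallow depth
(T~S~, 1--2 cm) is decoupled from air temperature (T~A~) by snow.  A warmer
winter can therefore produce *colder* soil: snowfall arrives later and the
pack is thinner, so insulation is lost exactly when the air is coldest
("cold soil in a warm world").  `coldsoil` implements the full analysis
chain used to test this hypothesis with hourly logger networks and fused
satellite imagery, plus a seeded synthetic-data generator so that every
stage can be validated against known ground truth.

The chain is: **simulate** (optional) → **sensors** (daily summaries, snow
flags, snow seasons, freeze--thaw events, seasonal statistics) → **proxy
years** (anomaly-based selection of a baseline and a warm stand-in year) →
**fusion** (daily fine-resolution reflectance via STARFM-style prediction)
→ **snow mapping** (NDSI/NDVI classification) → **comparison** (mixed-model
year x site contrasts, sensor-satellite agreement).

# Sensor pipeline

Hourly series are reduced to daily mean/min/max; the daily range
\[ \Delta T_S = T_{S,\max} - T_{S,\min} \]
is the snow statistic.  A day *d* is flagged snow iff \(\Delta T_S \le 1\)
°C on each of the 2 calendar days ending at *d* (the "48-hour" rule, read
as two calendar days of quiet range rather than a rolling hourly window)
and the daily maximum on *d* is strictly below 2 °C.  Whether the max
check also applies to day *d-1* is ambiguous in the source method; it is
applied to day *d* only, and the window length is configurable.  Unknown
days (fewer than `min_hours` = 18 hourly values) are never snow and reset
the window — conservative under data loss.

A plot is snow-covered on a day iff at least 50% of its sensors with known
flags say so (`quorum = 0.5`, chosen to mirror the satellite algorithm's
50%-cover validity rule).  The snow season is the longest contiguous run
of plot-snow days inside the Oct 1 -- May 31 search window; its length is
the snow-cover duration SCD~ST~.  The season-extraction rule is not
defined by the source method, so the longest-run convention is used for
both sensor and satellite series, making the two durations comparable.

A freeze--thaw event (FTE) is a day with daily mean T~S~ ≤ −5 °C — the
level at which soil microbial activity is strongly inhibited — with at
most one event per day.  Note this is a freeze-*state* day count, not a
freeze→thaw transition count; the name follows field convention.

Seasonal statistics aggregate daily → monthly → season (winter = DJF,
spring = MAM, summer = JJA, fall = SON), with December assigned to the
study year it opens (Dec 2015 belongs to the Dec 2015--Nov 2016 year).
"Average minimum" is the mean of daily minima, per the method's phrasing.

# Proxy years

Monthly anomalies are departures from the 1961--1990 calendar-month
climatology.  Candidate study years (Dec--Nov) are compared with the
reference (hemispheric) anomaly distribution over the same span using
Yuen's 20%-trimmed Welch test — the source names only "one-way ANOVA with
robust estimation", so this standard robust location comparison is a
documented choice, not a claimed match.  The baseline year is the
lowest-anomaly candidate not significantly different from the reference
(two-sided, α = 0.05).  The warm year is the highest-anomaly candidate
significantly *above* the reference; because that candidate is the maximum
of k candidates, the test is one-sided at α/k (Bonferroni), which keeps
the family-wise false-declaration rate at α — an unadjusted test on a
selected maximum would run at 2--4 times nominal α.  Roles with no
qualifying candidate are reported as NA with a note, never silently
filled.  The hemispheric trend curve is an OLS polynomial (degree 2 by
default; the source says only "polynomial" and shows a smooth accelerating
curve) with pointwise standard errors.

# Fusion (STARFM-style)

Scenes are 4-band (green, red, NIR, SWIR2) scaled reflectance
(value = reflectance × 10⁴, signed 16-bit, nodata −9999) with a boolean
QA mask.  Preparation masks QA-bad pixels and clamps to the valid range;
coarse scenes are resampled to the fine grid by nearest neighbour.
Because no GDAL binding is available in the target environment, file I/O
uses a flat-binary dialect (row-major int16 planes + JSON sidecar), which
matches the paper-style preprocessing convention of signed-16-bit binary
images.

For a coarse-only date t~p~, each band of the synthetic fine scene is
predicted from 1--2 same-day coarse/fine pairs (t~k~).  Candidates within
a moving window (half width 15) must be valid in all three scenes of a
pair and spectrally similar to the central pixel
(|L − L~c~| ≤ 2σ~band~/m, m = 4).  Candidate weights are
1/(S·T·D) with S = |L−M|, T = |M(t~k~)−M(t~p~)|, D = 1 + d/A (A = 15),
S and T floored at 1 scaled unit; the prediction is the weighted mean of
M(t~p~) + L(t~k~) − M(t~k~).  Two numerical rules matter:

* **Zero-difference shortcut.**  If the central pixel's unfloored T (or S)
  is exactly zero, the first-order relation is exact there and the central
  value is used directly.  This makes the temporal-identity case
  (M(t~p~) = M(t~k~) ⇒ prediction = L(t~k~)) exact, which the floored
  weighting alone does not guarantee.
* **Fallback.**  With no qualifying candidate, the central-pixel relation
  of the best pair (smallest floored S·T) is used; a pixel invalid in
  every input stays nodata.  A pixel whose central M(t~p~) is missing can
  still be predicted from candidates (each carries its own M(t~p~)).

Predictions are rounded half-away-from-zero to int16.  The main path is
C++ for speed; tests compare it bitwise against an independent plain-R
exhaustive-loop oracle on small grids.

**Known limitation.**  The weighted neighbourhood is a smoother: it
shrinks each pixel toward the mean of its spectrally similar set, so
fine-scale *within-class* texture is partially smoothed away, most
strongly in bands with large between-class contrast (red, SWIR2 in the
synthetic world).  On the synthetic recovery benchmark (noise SD 50
scaled units), green/NIR meet the RMSE ≤ 100 bound while red/SWIR2 come
out at ~105--125 with Spearman ρ ≥ 0.96 everywhere — within the range
published for this algorithm family, but above the bound; the
corresponding acceptance test is left failing rather than weakened.  The
original algorithm's better-than-central-pixel candidate filter was
evaluated and rejected: it worsens both metrics here because its central
fallback carries unaveraged noise.

# Snow mapping

NDSI = (green − SWIR2)/(green + SWIR2); NDVI = (NIR − red)/(NIR + red).
Pixels with green reflectance ≤ 0.1 are masked before NDSI to prevent
overestimation over dark surfaces.  A pixel is snow iff NDSI exceeds the
period threshold (0.35 for Oct 2013--May 2014, 0.30 for Oct 2015--May
2016; patchier snow in the warmer year lowers the optimal threshold), or,
to catch snow under conifer canopy, 0.1 < NDSI < 0.3 with
0.08 ≤ NDVI ≤ 0.12.  Values in (0.30, 0.35] in period 1 are no-snow by
the literal rule; a config override exists.  Plot decisions use pixels
whose centers fall in a 15-m buffer around the plot center (1--4 pixels at
30 m; the source is silent on membership, center-in-buffer is documented
here), with the same ≥ 50% quorum and longest-run season rule as the
sensor side, yielding SCD~S~.

# Comparison

Plots are classified open / partially forested / forested by k-means
(k = 3) on LAI, labels by ascending center.  Seasonal responses are
modelled as `value ~ year * site` with nested random intercepts
(`~1 | plot/sensor`) by REML via `nlme`; per-site warm-minus-baseline
contrasts use Wald t tests on the model's inner-stratum denominator df (a
Satterthwaite-style package is not available in the target environment;
with balanced year-within-sensor designs the inner-stratum df is the
appropriate stratum).  Residuals failing a Shapiro test at α = 0.01
trigger a log transform when the response is positive.  Two degenerate
designs are handled explicitly: a single plot falls back to a sensor-only
random intercept (flagged), and identical years (zero within-sensor
year-difference variance, where REML is singular) return the common
difference exactly with a degenerate flag.  Sensor-vs-satellite agreement
is a 2 × 2 confusion matrix over jointly known plot-days; overall accuracy
is the trace over the total, with unknown days excluded and counted.  FTE
percent change is (warm − baseline)/baseline × 100 on plot-level counts.

# The synthetic world

The generator states one emulated field campaign; its defaults are fixed
and the tests interrogate that world.  What it emulates:

* **Air temperature**: seasonal sinusoid (mean −1.1 °C, amplitude 14 °C —
  the study region's climate normals), diurnal sinusoid (amplitude 4 °C),
  daily AR(1) regional weather (φ = 0.8, innovation SD 1.5 °C) shared by
  all plots of a year, a constant per-plot offset (SD 0.3 °C), and hourly
  sensor noise.  The warm year adds +8 °C in DJF (the reported winter
  contrasts are 6.6--9.5 °C), tapering to 0 in summer.
* **Snowpack**: snowfall on sub-zero days with probability 0.15 and
  Gamma(4, scale 1.25) amounts (≈ 0.75 cm/day, peak ≈ 100 cm baseline /
  ≈ 35 cm warm — the reported station peaks are ~100 vs ~40 cm);
  degree-day melt (1.5 cm per positive °C-day); packs below a 1.5 cm trace
  threshold are flushed (sub-trace cover is not snow cover).  The warm
  year shifts the snowfall schedule 20 days later (snow started ~18--23
  days earlier in the baseline year) and scales amounts by 0.4.
* **Soil temperature**: snow-free, T~S~ tracks an exponentially smoothed
  daily-mean T~A~ (gain 0.9, 2-day memory) plus a damped diurnal wave
  (gain 0.6).  Under snow the mean term couples to min(smoothed T~A~, 0)
  — a melting pack cannot conduct above-zero heat downward — with
  coupling exp(−depth/10 cm), and the diurnal wave is damped with an
  0.8 cm e-folding (thin snow kills the diurnal signal first).  Below
  15 cm of pack, coupling is multiplied by (1 + 1.5·LAI), capped at 1:
  the tree-well effect, by which stems channel cold air through a thin
  pack, strongest under canopy.  Sensor noise defaults to the loggers'
  calibration RMSE, 0.11 °C; field variance beyond that is unknown, so
  noise levels are explicit knobs rather than claims.
* **RH**: bounded hourly AR(1) around 70%, +7% on melt days (the reported
  melt-season elevation is 5.5--9.2%).
* **Scenes**: a static open/forest mosaic with per-pixel texture
  (SD 0.02 reflectance), snow signature overriding land where the truth
  mask is snow, spatially uniform seasonal drift, daily coarse scenes as
  exact block means (ratio 10, so grids nest exactly; the real 500/30
  ratio does not), fine scenes every 16 days with rectangular cloud-QA
  patches, and int16 storage.
* **Anomalies**: climatology + linear-plus-quadratic trend + monthly
  noise (reference SD 0.3 °C, local 1.0 °C); the designated warm study
  year receives a local spike with annual mean 2.5 °C weighted
  1 + 0.5·cos(month) so it peaks in winter.  The weighting is softer than
  a full cosine because the spike's own seasonality is within-year
  variance to the robust test; at full amplitude, detection of a genuinely
  injected warm year becomes structurally marginal at n = 12 months.

Two consequences are built in deliberately, so noise-free recovery tests
are theorems of the stated world rather than luck: any surviving pack
(≥ 1.5 cm) quiets the diurnal range below the 1 °C detection bound and
pins the daily maximum below 2 °C, hence with zero sensor noise the
detected season start lags truth by exactly the 1-day window warm-up and
the duration errs by at most 2 days.  What a green test therefore does
*not* establish: robustness to melt-water percolation, litter insulation,
soil-moisture phase buffering, sensor drift, patchy within-plot snow, or
real QA-bit semantics — none of which the generator emulates.

# Numerical conventions

Gregorian calendar with leap days; study years run Dec 1 -- Nov 30 and are
labelled by their December year.  All random streams derive from one
master seed through a string-keyed hash, so outputs are bit-reproducible
and independent of call order.  Int16 rounding is half-away-from-zero.
Ties in longest-run extraction resolve to the earliest run.  Config files
for the CLI are JSON (no YAML parser in the target environment).

# Limitations

The generator is mechanistic, not an energy-balance model (no SNOWPACK);
the fusion module does not model orbital geometry, BRDF or reprojection
beyond nested-grid nearest neighbour; the paper's field numbers (e.g. the
0.43--1.22 °C winter contrasts, 72.8% agreement) derive from unreleased
sensor data and full-size archives and are not reproduction targets —
only procedure fidelity and synthetic-truth recovery are claimed.  The
published p-values cannot be matched without the field data.
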