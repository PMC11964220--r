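---
title: "From leaf colour to a nitrogen dose: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From leaf colour to a nitrogen dose: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maizeNrec)
```

## The problem

Blanket fertilizer-nitrogen schedules for maize routinely over- or
under-shoot the crop's actual mid-season demand, wasting money and
leaking reactive nitrogen into water and air. Sensor-based in-season
management instead reads the crop's greenness — a proxy for leaf N —
part-way through the season and prescribes only the N the crop is
predicted to convert into extra grain. maizeNrec implements a complete
version of this workflow in which the greenness sensor is an ordinary
RGB photograph, scored by the dark green colour index (DGCI), together
with the evaluation metrics used to judge such a system: nitrogen-use
efficiency, greenhouse-gas intensity, and eco-efficiency.

## The prescription model

**Colour index.** Each pixel's normalized RGB is converted to
hue/saturation/brightness (`rgb_to_hsb()`): brightness is the channel
maximum, chroma the max-min spread, saturation chroma over brightness,
and hue comes from the piecewise branch of the maximal channel, taken
modulo 360 into [0, 360). The index is

$$\mathrm{DGCI} = \frac{(H/60 - 1) + (1 - S) + (1 - B)}{3},$$

so pure green (H = 120, S = B = 1) scores 1/3 and a fully saturated
yellow (H = 60) scores 0. Greener, darker, more saturated leaves —
higher leaf N — score higher. Three deliberate choices:

* **No clamping.** For hue in [0, 360) the formula's range is
  [-1/3, 4/3]. We evaluate it exactly; an optional hue band (e.g.
  `hue_band = c(60, 180)`, the green-yellow band the index was designed
  for) restricts *aggregation* instead, which guards against stray sky
  or soil pixels without altering the formula.
* **Achromatic pixels are excluded, not defaulted.** At zero chroma hue
  is undefined; assigning any default hue would bias the image mean, so
  such pixels are dropped and counted in `excluded_count`.
* **Negative hue branches wrap.** When green falls slightly below blue
  at maximal red the branch value is negative; we wrap modulo 360, the
  standard colorimetric convention.

**Segmentation** (`segment_leaf()`) is plain green-dominance
thresholding (G strictly above both R and blue) with configurable
brightness bounds. The field protocol behind any particular phone app —
which leaf, how many photos, what lighting — is unknown, so the package
exposes the knobs and makes no claim of replicating one.

**Thermal time and INSEY.** Daily growing degree days are
`max(0, (Tmax + Tmin)/2 - Tbase)` with a maize base temperature of
10 °C (configurable; the convention, since no other value is stated
with the method). The in-season estimated yield is

$$\mathrm{INSEY} = \frac{\mathrm{DGCI}}{\#\{\text{days with GDD} > 0\}}$$

over the window from sowing (exclusive) to sensing (inclusive). The
phrase "number of GDD > 0" is ambiguous between a day count and
cumulative degree-days; we default to the day count — the established
INSEY convention in the sensor-based N literature — and offer
`denominator = "gdd"` as a switch.

**Dose equation.** With a calibration `yield = a * INSEY^b` fitted per
sensing stage (`fit_power_function()`, ordinary least squares on the
log-log scale), the chain is

$$YP_0 = a\,\mathrm{INSEY}^b,\qquad RI = \frac{\mathrm{DGCI}_{enrich}}{\mathrm{DGCI}_{test}},\qquad YP_N = YP_0 \times RI,$$
$$\text{N dose} = \frac{10 \times 1.43 \times (YP_N - YP_0)}{0.5}\ \text{kg/ha},$$

where 1.43 is the mean maize grain N concentration (%) and 0.5 the
achievable efficiency factor for South Asia; the factor 10 converts
t/ha x %N to kg/ha. The grouping follows dimensional analysis — with
the defaults the dose is 28.6 kg/ha per t/ha of predicted response,
which lands in the 30-60 kg/ha range of doses actually applied in
validation trials of such systems. Further choices:

* **RI is uncapped by default** (no cap is stated with the method); a
  configurable ceiling is available as a guardrail.
* **RI < 1 floors the dose at zero** with a warning rather than
  erroring: a test plot out-greening the enriched strip is plausible
  field noise.
* **`a` and `b` are never hard-coded.** The published account does not
  report the fitted constants at either sensing stage, so the package
  ships the calibration routine and a synthetic demo model, not
  invented "official" constants.
* **NDVI mode** (`index_kind = "ndvi"`) substitutes optical-sensor NDVI
  readings for DGCI and changes nothing else, mirroring how such
  systems are compared against the GreenSeeker-style workflow.
* Doses are reported to 0.1 kg/ha; each sensing event is treated as an
  independent prescription.

## Evaluation metrics

`compute_metrics()` consumes one table keyed by treatment with an
explicitly designated zero-N control, because two of the indices are
two-plot contrasts: physiological efficiency needs the control's yield
and uptake, and the virtual N factor takes the control's total uptake
as the soil N supply. Units: yields are stored in t/ha and converted to
kg/ha internally where an index demands it; conversion lives in one
place. Indices undefined for a row — partial N balance or VNF on the
unfertilized control, intensity ratios at zero yield — are reported as
`NA`, never as zero.

Energy accounting (`energy_input()`) is a coefficient-weighted
inventory sum with the standard double partition: direct (labour, fuel,
electricity) vs indirect (seeds, fertilizers, machinery, chemicals),
and renewable (seeds, labour) vs non-renewable. Published accounts cite
coefficient compilations but print no values, so coefficients are a
user-supplied table; the shipped demo table is labelled as such and is
for examples only. Likewise the N2O estimator
(`estimate_n2o_tier1()`) is an explicitly labelled Tier-1-style
stand-in (EF x applied N x 44/28 x GWP); process-based farm emission
models are out of scope and their output enters as plain input columns.

## What the synthetic generators emulate

The generators are pure functions of their arguments, seed included.

**Leaf images** (`make_leaf_image()`): an elliptical leaf on a
non-green background. Colours are sampled in HSB space, where DGCI is
*linear* in (H, S, B), so zero-mean jitter leaves the expected
mask-mean at the target; the mean hue solves the DGCI equation at fixed
S and B (S = B = 1 when noiseless, 0.85 under noise, keeping truncation
at the [0, 1] bounds negligible for the default jitter sd of 0.05).
They emulate controllable greenness and additive sensor noise — not
camera optics, illumination gradients, white balance, specular
highlights or leaf venation, so passing image tests says nothing about
a specific phone's colour pipeline.

**Weather** (`make_weather()`): a monsoon ("kharif") preset whose days
all clear the 10 °C base — so the positive-GDD day count equals the
series length, the typical situation for a July-sown maize crop — and a
winter preset with sub-base days for exercising the day-count logic.

**Calibration trials** (`make_trial()`): INSEY spread uniformly over
(0.004, 0.02) — DGCI 0.3-0.7 sensed 35-45 days after sowing — with
yields on a power law times lognormal noise. Defaults a = 300, b = 0.9,
n = 35 plots, log-sd 0.1 give 3-8 t/ha yields, the scale of a
multi-rate N trial. At these settings ordinary least squares on logs
recovers b with median absolute error about 0.025 over repeated
simulation, comfortably identifying the curvature that matters for the
dose.

**Validation table** (`make_validation_table()`): works *backwards*
from target index values to raw plot quantities — total uptake from
partial N balance, grain yield from internal utilization efficiency,
biological and cob yields from harvest index and shelling percent,
grain N concentration from the virtual N factor, emissions from GHG
intensity, energy and GHG totals from the eco-efficiency targets. The
metrics pipeline is then the generator's exact inverse at zero noise,
which makes every index testable to 1e-6 without access to field data.

The default six-treatment target set mirrors a validation design:
unfertilized control, 50 or 75 kg/ha basal N with two image-guided
("App") or optical-sensor ("GS") splits, and the blanket recommended
dose ("RDF", 150 kg/ha). Published field-scale index values are used
where available (e.g. PNB 1.19 and VNF 0.45 for N50PK+App, harvest
index 35.13%, GHGI 59.3 and 66.9 kg CO2-eq/t for the GS treatments,
eco-efficiencies 0.116 US $/MJ and 0.85 US $/kg CO2-eq). The remaining
entries are fixed plausible values at the same scale, chosen once:
soil N supply 60 kg/ha (the control's uptake), grain price 185 US $/t,
internal utilization efficiencies 40-45 kg grain per kg N, and costs
placing the cheapest fertilized treatment 4 US $/ha under RDF. One
reconciliation was necessary: a sub-unity RDF partial N balance is
jointly infeasible with RDF's low virtual N factor (0.38) and a 60
kg/ha soil supply — it would force grain N uptake above total uptake —
so RDF's PNB defaults to 1.18, reading the reported "not close to 1"
deviation as being on the high side. Raw grain/stover N concentrations
are *derived* quantities here and can drift from typical field values
when users supply extreme targets; the generator validates only
physical consistency (HI < shelling < 100%, grain N uptake within
total uptake) and rejects impossible target sets.

## Numerical choices and degenerate inputs

* Power-law fitting requires ≥ 3 strictly positive pairs and errors on
  all-equal INSEY (singular design) rather than returning an arbitrary
  slope.
* Hue branch ties (two channels sharing the maximum) give identical
  hue under every branch, so the R-then-G-then-B priority is
  arbitrary but inconsequential.
* The weather window check lists the missing dates instead of silently
  shortening the GDD count.
* Typed CSV readers report the first bad cell by row and column;
  missing numeric cells propagate as `NA` through the metrics table.
* Config files reject unknown keys by name; omitted keys take the
  published defaults (1.43% grain N, 0.5 efficiency, 14.5% moisture).

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations use 120 x 120-pixel
images, 35-day weather series, 35-plot trials (200 replicate fits) and
100 random sensing sessions — sizes at which every stochastic check is
stable across seeds while the whole suite runs in seconds.

## A worked season

```{r example}
weather <- make_weather(35, "kharif", seed = 1)
ctx <- thermal_context(weather, sowing = as.Date(weather$date[1]) - 1,
                       sensing = weather$date[35])
trial <- make_trial(a_true = 300, b_true = 0.9, noise_sd_log = 0, seed = 2)
model <- fit_power_function(trial$insey, trial$grain_yield_t_ha,
                            stage_das = 35)
recommend(sensing_session(0.45, 0.55, ctx, stage_das = 35), model)
```

## Known limitations

* No colour-checker calibration or illumination normalization: DGCI
  from uncontrolled photographs inherits the camera's colour pipeline.
* The calibration constants shipped in examples are synthetic; real
  deployment requires a local multi-rate trial per sensing stage.
* Emission inputs are taken at face value; the Tier-1 stand-in is a
  scale device, not an emission model.
* The metrics module evaluates treatment means; replicate-level
  inference (ANOVA, LSD letters) is deliberately left to standard
  statistics tools.
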