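---
title: "Sum-intensity viability for encapsulated spheroids: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sum-intensity viability for encapsulated spheroids: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The assay

Alginate-encapsulated liver cell spheroids (AELS) are ~500 µm hydrogel beads
containing 3-D cell aggregates, the functional unit of a fluidised-bed
bioartificial liver. Assessing their viability non-destructively is done *in
situ* with two dyes imaged in two fluorescence channels:

* **FDA** (fluorescein diacetate) is converted to fluorescent fluorescein by
  esterases of *viable* cells only — the green channel reports live cells;
* **PI** (propidium iodide) stains nuclei of membrane-compromised cells —
  the red channel reports dead cells.

Each channel is quantified by its **sum intensity**: the sum of 8-bit grey
levels (0–255) over all pixels selected by a low/high threshold window, with
the high threshold fixed at 255. Because sum intensity is linear in the
number of stained cells, viability is

$$\%\,\text{viability} = \frac{S_{\mathrm{FDA}}}{S_{\mathrm{FDA}} + S_{\mathrm{PI}}} \times 100 .$$

The formula is only meaningful under a **matched calibration**: an equal
number of live and dead cells must produce the same sum intensity in their
respective channels. Calibration therefore has three parts, mirroring the
validated protocol:

1. **Exposure selection** (`select_exposure()`): among the instrument's
   available exposures (100–400 ms for FDA; 600–2000 ms for PI), choose the
   one maximising the signal-to-noise ratio, defined as the sum intensity of
   pixels representing cells over the sum intensity of pixels without cells.
   Exposures whose saturated-pixel fraction exceeds a limit are excluded —
   a clipped image no longer reports sum intensity linearly. Ties go to the
   shorter exposure (less photodamage, less clipping risk); in the noiseless
   unclipped limit numerator and denominator both scale linearly with
   exposure, so all candidates tie and the shortest wins.
2. **Low-threshold fitting** (`fit_low_threshold()`): per field, the lowest
   grey level that separates background from cells, operationalised as the
   smallest integer strictly above the robust background ceiling
   (histogram mode + *k*·MAD, *k* = 3) that still captures every cell
   region. The reported threshold is the mean over fields (recommended: 10
   images of 40–60 beads, including high-density samples), rounded half-up
   — the rounding is a documented convention, since the protocol does not
   state one. Fields without detectable cells are excluded with a warning,
   never averaged in.
3. **Signal-equivalence matching** (`match_pi_setup()`): with the FDA side
   fixed, the PI exposure and PI low threshold are chosen so the mean PI
   sum intensity per cell on fully killed controls equals the mean FDA sum
   intensity per cell on fully live controls, within 5% by default (the
   protocol demands "no significant difference" without a numeric bound).
   An over-long exposure can always be thresholded down to match, but only
   by selecting very few pixels; the implementation therefore prefers,
   among candidates reaching the tolerance, the one requiring the least
   threshold elevation above its fitted background level, then the shorter
   exposure. This reproduces the documented rejection of the 2 s PI
   exposure.

Killed controls are produced by a timed 50% (w/v) Me₂SO insult
(`apply_lethal_insult()`), modelled as exponential survival
`exp(-rate · minutes)` with a default rate of 0.35/min so that the
15-minute preset leaves under 1% of cells alive — the protocol states the
insult is controllable and lethal but not its kinetics, so the rate is a
package choice, exposed as an argument.

## Aggregation and per-bead quantification

`quantify()` pools sum intensities across fields **before** applying the
formula (the primary estimate), which weights fields by signal and is
robust to sparse fields; per-field percentages are reported alongside, and
both are returned because the protocol does not state which convention its
batch figures use. Pixels selected by both channels' windows contribute to
both sums — the protocol has no exclusivity rule. A field with no signal in
either channel yields a flagged undefined result rather than an arbitrary
0 or 100. Fewer than 5 fields or fewer than ~100 beads trigger warnings
(the protocol's minima); warnings never alter results.

Per-bead viability uses `segment_beads()`: beads are detected from the
union of above-threshold signal in both channels with a disc matched
filter (coverage of a disc of half the expected bead radius), followed by
non-maximum suppression, nearest-centre pixel assignment, and refinement
of each centre as the approximate minimal enclosing circle
(Bădoiu–Clarkson iteration) of the bead's pixels — the bead circle
circumscribes its spheroids, so the enclosing circle is a far better
centre estimate than the centroid when spheroids sit asymmetrically.
Touching beads keep separate filter peaks and are returned as separate
regions. Centre accuracy is information-limited: a small bead holding only
two or three spheroids simply does not trace its own outline.

## The synthetic-data generator

No micrographs are deposited, so the package ships a generator
(`generate_bead_field()`) whose defaults encode the study conditions:

| Parameter | Default | Why |
|---|---|---|
| bead diameter | 525.8 ± 95 µm (truncated normal) | measured encapsulation distribution |
| pixel size | 4 µm/px | a 525 µm bead spans ~130 px, the ×4-objective scale |
| cell density | 22 × 10⁶ cells/mL beads | the high-density calibration condition |
| exposures | FDA 150 ms, PI 1000 ms | the validated instrument's choices |
| per-cell response | 2.4 (FDA), 0.36 (PI) grey·px/ms | equal integrated signal at the chosen exposures |
| background | ~10 grey at reference exposures (rate/ms) | scales with exposure, as fluorescent background does |
| camera offset | 0 (configurable) | an exposure-independent offset makes SNR exposure-dependent |
| read noise | 1.5 grey (sd) | typical 8-bit camera read noise |
| cell footprint | Gaussian, σ = 15 µm | ~one cell diameter |
| Me₂SO kill rate | 0.35/min | 15 min ⇒ <1% viable |

Cells are placed in **spheroid-like clusters** (~100 cells, σ = 25 µm)
distributed through the whole bead volume, not uniformly at random over
the bead circle. This is a deliberate design choice: the assay's objects
are spheroids, and uniform placement at low density produces isolated dim
blobs whose tails fall below any background-separating threshold — a
rendering artefact that would make quantification density-dependent in a
way the real assay is not. Clustered rendering keeps local brightness
approximately density-independent, matching the observed insensitivity of
the readout to cell density (except at the very lowest densities, where
the real data also departs). Uniform placement remains available via
`placement = "uniform"`.

Live cells contribute only to the FDA channel and dead cells only to the
PI channel; optional crosstalk coefficients inject a known fraction of one
channel's imaged cell signal into the other for `check_overspill()`
validation. An optional `fda_density_response` hook can attenuate the FDA
per-cell response at low densities (the mechanism behind the reported
low-density FDA deficit is unexplained, so the default assumes none).

Pixels are quantised to 8-bit integers and clipped at 255. Quantisation
breaks exact linearity at the 10⁻⁶ level, so the generator exposes
`integer_pixels = FALSE` as a diagnostic mode in which the pre-clipping
signal is exactly proportional to cell count and exposure; the shipped
property tests use it for the exact-linearity checks and integer images
for everything else. Generation is a pure function of `(params, seed)`;
geometry and noise use separate derived RNG streams, so geometry is
unchanged when only the noise level changes.

**What the generator does not emulate:** optical point-spread physics,
photobleaching, illumination inhomogeneity (flat-field error), autofocus
error, and bead deformation. Passing the recovery suites therefore shows
the *quantification chain* is correct and well-calibrated under the
assay's own model of signal formation; it does not certify performance on
micrographs with structured backgrounds or uneven illumination, which
would need flat-field correction upstream.

## Bioprocess metrics

The bioreactor-side quantities are deliberately thin, unit-explicit
functions:

* `check_nutrient_bounds()` — glucose must stay strictly above 15 mM and
  lactate strictly below 10 mM; a sample exactly on a bound violates it
  (the bounds are worded strictly).
* `oxygen_consumption_per_cell()` — mass balance
  `ΔDO/100 · sat · flow / cells` in fmol/cell/s. The conversion from
  percent saturation to concentration is not stated in the source process
  description, so the saturation concentration is an explicit argument
  (default 200 µM, air-saturated medium at 37 °C). The published
  0.153 fmol/cell/s also includes direct chamber oxygenation that is not
  quantified anywhere, so that figure is documented context, not a number
  this function can recompute.
* `functional_value_bilirubin()`, `secretion_rate()` — ordinary
  least-squares slope of concentration over a window (default from 1 h
  onward, excluding the initial dilution artefact when plasma mixes with
  hydrogel fluid), scaled by volume and normalised per 10¹¹ cells/day or
  per 10⁶ cells/h.
* `protein_auc_mg()` — trapezoidal integral of compartment mass
  (concentration × volume) over time. The units are mg·h; the source
  figure legends label this quantity "total mg produced", and that
  convention is kept in the reporting while the documentation states the
  true units.
* `do_setpoint_recipe()` — the DO setpoint escalates (21% → 35%) when the
  post-chamber reading falls below a trigger, never de-escalates within a
  run, and is absorbing at the top setpoint. The trigger level is nowhere
  stated for the original process, so it is a required configuration value
  with no default.
* `media_regime()` — the default schedule follows the day-4 regime
  (days 4, 7, 9, 11 at 50/55/70/80%); the source states day 7 as a
  "50/60%" range, encoded as its midpoint. The earlier day-5 variant is
  provided as a named alternative because the two descriptions of the
  schedule disagree.
* `media_biomass_ratio()`, `production_efficiency()`,
  `viability_drop_summary()` — direct arithmetic with rounded and
  unrounded values both returned.

## Numerical conventions and problem sizes

* Integer apportionment (cells to beads, live cells to beads, survivors
  under insult) uses largest-remainder rounding, so field totals are exact
  and ties resolve deterministically.
* Reported integers round half away from zero.
* SNR ties in exposure selection are declared at a relative tolerance of
  10⁻⁶.
* The test suite runs on reduced problem sizes chosen to keep the full
  suite around a minute: fields of 512×512 px with 4 beads for the
  recovery grid (5 viabilities × 3 densities × 10 seeds), 1500×1500 px
  fields of 50 beads at 8 µm/px for segmentation recovery, and 10 + 10
  control fields for the killed/live contract. These sizes are the
  package's own choices for routine verification; all scale up through
  `gen_params()`.

## Known limitations

* The viability estimate inherits a small bias toward 50% at intermediate
  viabilities (≲2 points under default conditions) because selected pixels
  carry their share of background in both channels; the effect shrinks as
  the low threshold rises relative to background.
* Segmentation centre error is bounded below by spheroid coverage, not by
  the algorithm (see above); beads under ~350 µm at low density are
  localised to ~15–20% of their radius.
* The assay is single-plane by design; no z-stack reconstruction or
  attenuation correction is attempted, and none of the trypan-blue/MTT
  comparison assays are modelled.
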