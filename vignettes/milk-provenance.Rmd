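---
title: "Seasonal isotope calibration and the two-step milk provenance check"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal isotope calibration and the two-step milk provenance check}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomilk)
```

## The problem

Milk sold under a Protected Designation of Origin (PDO) label — here,
milk for Parmigiano-Reggiano cheese — must come from a defined region.
The water fraction of milk carries the oxygen and hydrogen isotope
signature of the water the cows drank, modified by a metabolic,
evaporation-like enrichment that tracks air temperature. Because farm
(drinking) water in a region is isotopically near-constant through the
year while the enrichment follows the seasons, paired measurements of
milk water and farm water support a quantitative compatibility test: is
this milk, declared to have been milked on a given date, consistent with
the region's waters and with the region's seasonal enrichment pattern?

`isomilk` implements that test and everything needed to calibrate it:
the milk/farm-water fractionation factor, seasonal quartic calibrations
with prediction bands, water-line and deuterium-excess diagnostics, a
variance partition of the fractionation factor by time and shed, and a
synthetic dairy-herd generator used to validate the statistical
behaviour of the whole pipeline.

## Quantities and model

All delta values are per mil vs VSMOW. The fractionation factor between
milk water (M) and farm water (W) sampled at the same shed and time is

$$\alpha_t = \frac{\delta_{M,t}/10^3 + 1}{\delta_{W,t}/10^3 + 1},$$

computed by `compute_alpha()`. It is dimensionless and close to 1;
differences between fractionation factors are reported multiplied by
1000, i.e. in per mil. Milk water is normally heavier than farm water
($\alpha > 1$), and the enrichment grows with temperature.

Both the milk-water $\delta^{18}\mathrm{O}_M$ and $\alpha$ follow a
smooth annual course when plotted against the day number $t$ (ordinal
day of a non-leap year; `day_number()`). A LOESS smoother
(`loess_smooth()`, span 0.2, locally linear, tricube weights) describes
that course model-freely, and a quartic

$$y(t) = A t^4 + B t^3 + C t^2 + D t + E$$

reproduces the smoother closely while giving a closed formula
(`fit_quartic()`, `predict()`). The residual standard error uses the
residual degrees of freedom, $s_{yx} = \sqrt{SSE/(n-5)}$ for the quartic
and $\sqrt{SSE/(n-2)}$ for straight lines — the conventional "standard
error of the regression". Under approximately normal residuals the band
$\hat y \pm 1.645\, s_{yx}$ covers about 90% of the population around
the curve.

Three calibrations for the Parmigiano-Reggiano region ship with the
package (`milk_calibration()`): the seasonal quartic of the milk-water
$\delta^{18}\mathrm{O}_M$ (n = 84, $s_{yx}$ = 0.92 ‰, fitted without the
two summer-grazing herds), and two seasonal quartics of $\alpha$ — one
from all nine surveyed herds (n = 108, $s_{yx}$ = 0.50 ‰) and one from
the indoor herds only (n = 84, $s_{yx}$ = 0.41 ‰). Users can refit all
of them on their own data and exchange them as versioned text files
(`write_calibration()` / `read_calibration()`).

For a sample from a herd that did not contribute to the calibration, the
prediction uncertainty of the calibrated $\alpha$ is approximated as

$$u_{\hat\alpha} = \sqrt{s_{yx}^2 + s_{yx}^2/n}$$

(`alpha_prediction_uncertainty()`). This mildly underestimates the true
prediction uncertainty because it ignores the leverage of the evaluation
day. The bundled calibrations therefore carry the slightly more
conservative published constants (0.51 ‰ and 0.42 ‰) and use them for
threshold computations; `recompute = TRUE` applies the formula, and
calibrations you refit yourself use the formula by default. The
difference matters only in the second decimal of the step-2 threshold.

## The two-step decision rule

`verify()` runs two conditions; **both must pass** for the sample to be
called compatible with the region.

**Step 1 — seasonal band of the milk delta.** With measured
$\delta^{18}\mathrm{O}_{M}$ and declared day $t$:

$$\left|\delta_{M,\text{meas}} - \delta_{M,\text{calc}}(t)\right| \le 1.645\, s_{yx}.$$

With the bundled calibration the threshold is $1.645 \times 0.92 =
1.51$ ‰. The coverage factor (significance level 0.10) is an argument.

**Step 2 — fractionation-factor compatibility with the water.** The
measured $\alpha_m$ from the sample's milk and farm water is compared
with the calibration value $\hat\alpha(t)$:

$$10^3\left|\alpha_m - \hat\alpha(t)\right| \le
u = \sqrt{u^2_{\delta_M} + u^2_{\delta_W} + u^2_{\hat\alpha}},$$

which with the default measurement uncertainties (0.15 ‰ milk, 0.08 ‰
farm water; `default_uncertainties()`) and the indoor calibration gives
$u = 0.45$ ‰ (`combined_uncertainty()`). A difference exactly equal to a
threshold passes in both steps (the conditions are `<=`).

When the farm water was not sampled, a regional groundwater value may be
supplied (`groundwater_d18O`); with neither, step 2 is skipped and the
overall verdict is *undetermined*, never a pass. Step 2 defaults to the
indoor-herd calibration because the published validation table was
computed for animals living indoors; `milk_calibration("alpha_all")`
(with its 0.51 ‰-based threshold) suits herds grazing outdoors.

Step 1's threshold is a 90% coverage band, so about 10% of genuinely
regional samples fail it by construction — the check trades a known
false-rejection rate for sensitivity. Step 2's threshold is a propagated
*measurement* uncertainty, not a population band: when herd-to-herd
scatter of $\alpha$ around the seasonal curve exceeds the measurement
uncertainty (as it does in realistic simulations), step 2 rejects more
than 10% of authentic single samples. The published validation samples
all pass it comfortably; users screening many samples should read step-2
failures near the threshold as "re-sample and re-measure", not as proof
of fraud.

### Day numbers and dates

Day numbers use the non-leap calendar (1 January = 1, 29 February
rejected) so a calendar date maps to the same $t$ every year. Published
sample tables sometimes print a day number that disagrees with the
printed date; `read_samples()` therefore treats an explicit `t` column
as authoritative and only falls back to the date when `t` is missing.
The bundled validation table contains both kinds of rows: two samples
whose printed day numbers (150, 30) disagree with their dates but
reproduce the published computed columns, and one (Viarolo) whose
published day number does not, while its date-derived day (358) does —
that row ships without an explicit `t`.

## The synthetic herd generator

`herd_config()` / `simulate_herd_year()` generate a year of monthly
records for a set of sheds with the structure the analysis assumes:

* **Farm water.** Per-shed means spread over the regional range
  (−11.3 to −7.9 ‰ in $\delta^{18}\mathrm{O}$ by default), with
  $\delta^2\mathrm{H}$ means on a local water line (slope 8.33,
  intercept 16.3 ‰, shed-level scatter 1.6 ‰) and small month-to-month
  variation (0.08 ‰ O, 1.0 ‰ H) — drinking waters are near-constant.
* **Temperature.** A deterministic annual sinusoid (default mean
  13.5 °C, amplitude 11.5 °C, peak day 205 — a Po-plain-like climate)
  plus day-to-day Gaussian noise (sd 2 °C); the biologically relevant
  covariate is the mean over the 14 days preceding sampling, the
  equilibration time of a cow's body water.
* **Fractionation.** $\alpha = A_i + B_i \bar T$ per shed, with slopes
  $B_i$ drawn from the range observed across real herds
  (5.7–9.0 × 10⁻⁵ per °C indoors; outdoor sheds get their slope
  inflated by a factor 1.7 during May–October, reproducing the
  summer-grazing enrichment of roughly +1 ‰ above the common trend).
  Alternatively a stored quartic calibration can drive $\alpha(t)$
  directly.
* **Milk values.** $\delta^{18}\mathrm{O}_M$ is built by inverting
  $\alpha$ against the shed's water (`milk_delta_from_alpha()`) plus
  0.15 ‰ measurement noise. $\delta^2\mathrm{H}_M$ is generated from
  the shed's water $\delta^2\mathrm{H}$ along an evaporation-like slope
  (default 6.30, the observed milk-line slope), minus an explicit
  temperature-driven deuterium-excess depression (default 0.35 ‰/°C
  about the annual mean), plus 1.5 ‰ measurement noise. An alternative
  construction — drawing milk $\delta^2\mathrm{H}$ from the pooled
  milk line with its full 3.2 ‰ scatter — was rejected: treating that
  scatter as independent per-observation noise destroys the strong
  temperature dependence of $d_{ex,W} - d_{ex,M}$ that real herd data
  show (correlations near 0.8), because most of the pooled scatter is
  actually structured between sheds. The chosen construction preserves
  both the dual-isotope geometry and the deuterium-excess behaviour.

Identical configuration and seed give byte-identical output.
`simulate_fraud_scenarios()` layers labelled perturbations on top:
`foreign_water` (+3 ‰ water shift at unchanged milk), `foreign_milk`
(+1.5 ‰ offset of the measured $\alpha$), and `season_mislabel`
(production shifted 180 days from the declared date).

**What the generator does not emulate.** Month-to-month autocorrelation
of $\alpha$ beyond what temperature induces; feed and forage water as a
distinct isotope source; shed-specific husbandry changes during the
year; real (non-sinusoidal) weather. Passing tests on synthetic herds
therefore demonstrate the statistical correctness of the machinery under
the stated model, not the field validity of the calibration — that rests
on the published survey behind the bundled calibrations.

## Numerical and design notes

* Quartics are fitted by `lm()` on raw powers of `t` and evaluated in
  Horner form; tests cross-check the fits against explicitly solved
  normal equations (on a rescaled day variable — raw powers of day 365
  make the unscaled normal equations numerically singular, which is why
  the package relies on `lm()`'s QR decomposition).
* `predict()` accepts `t = 0` so the constant term can be inspected
  directly; verification itself always uses day numbers in 1..365.
* Quartic fits require at least 6 points and 5 distinct day numbers;
  water lines at least 3 points with non-degenerate spread.
* Unicode minus signs in input files are normalised to ASCII on read;
  dates are serialised `DD/MM/YYYY`; missing values are empty fields.
* If you refit the alpha calibration on new data, the step-2 threshold
  is recomputed from your fit's $s_{yx}$ and $n$ by default rather than
  frozen at 0.45 ‰; pass `threshold2` to `verify()` to pin it.
* Simulation-based tests use one herd-year (9 sheds × 12 months,
  n = 108) for structural checks and pooled experiments of about
  650 records (four independent training years, two test years each)
  for the power estimates; these sizes keep every Monte-Carlo rate well
  inside its binomial tolerance.

## Worked check

```{r}
verify(list(shed_id = "Torrile", d18O_M = -8.16, d18O_W = -8.78, t = 20))
```

And the full bundled validation set:

```{r}
samples <- read_samples(system.file("extdata", "validation_sheds.csv",
                                    package = "isomilk"))
report <- verify_samples(samples)
report[, c("shed_id", "t", "delta1_permil", "delta2_permil", "overall")]
```

Three of the four samples declared by farmers to be regional (L2, L3,
L4) fail step 2: their milk is seasonally plausible (step 1 passes) but
incompatible with the declared water source — exactly the fraud pattern
the second step exists to catch.

## Limitations

The bundled calibrations describe one region observed for one year;
year-to-year climate variation will move the seasonal curves, and the
package deliberately exposes refitting rather than claiming
transferability. Only oxygen-isotope calibrations are bundled — the
machinery is generic in the response, but no published hydrogen
coefficients exist to ship. The check is a binary compatibility test
against one region, not a classifier over candidate origins.
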