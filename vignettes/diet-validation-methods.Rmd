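---
title: "Methods: validating dietary assessment tools against doubly labelled water"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating dietary assessment tools against doubly labelled water}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietval)
```

## The problem

Self-reported dietary intake is systematically biased: people forget,
misjudge portions, and under-report. Before a new assessment tool (for
instance an image-based food-logging app) can be used in research, its
energy-intake estimates must be validated against an objective reference.
The doubly labelled water (DLW) technique provides that reference: under
approximate energy balance over an observation week, total daily energy
intake (TDEI) should equal total daily energy expenditure (TDEE), and
TDEE can be measured objectively from the differential elimination of two
stable isotopes. `dietval` implements that validation pipeline end to
end, together with a synthetic-cohort generator that makes every stage
testable by parameter recovery.

## The DLW two-point model

A participant drinks water labelled with ²H and ¹⁸O. Deuterium leaves the
body only as water; ¹⁸O leaves as both water and CO₂. The difference
between the two elimination rates therefore measures CO₂ production, and
hence energy expenditure.

With the two-point protocol, enrichments are measured at a post-dose
plateau (two samples a few hours after dosing, averaged) and at the end
of the metabolic period (again two samples). Background-corrected
enrichments give, per tracer,

* elimination constant: $k = \ln(\Delta E_\text{initial} /
  \Delta E_\text{final}) / \Delta t$ (per day), with $\Delta t$ computed
  from the actual sample times, not assumed to be exactly 7 days;
* dilution space (plateau method): $N = d \,(E_\text{dose} -
  E_\text{tap}) / (E_\text{plateau} - E_\text{pre})$ for dose $d$ in mol.

Total body water averages the two exchange-corrected spaces,
$\mathrm{TBW} = (N_d/1.041 + N_O/1.007)/2$; fat-free mass assumes the
hydration factor 0.732, $\mathrm{FFM} = \mathrm{TBW}/0.732$, and
$\mathrm{FM} = \text{weight} - \mathrm{FFM}$. CO₂ production uses the
Speakman two-point equation
$r\mathrm{CO}_2 = 0.4554\, N (1.007\,k_O - 1.043\,k_d) \times 22.26$
L/day, and the Weir equation converts it to energy:
$\mathrm{TDEE} = r\mathrm{CO}_2 (1.106 + 3.94/\mathrm{RQ})$ kcal/day.

Two design choices here were genuinely open:

* **N for the Speakman equation.** The protocol estimates total body
  water "using the dilution spaces of both isotopes" without fixing the
  combination. We use the arithmetic mean of $N_O$ and $N_d$ in mol,
  configurable through `dlw_config()`.
* **Respiratory quotient.** RQ is not measured by DLW; we default to
  0.85, a typical food quotient for a mixed Western diet, and record the
  RQ used in every result. TDEE is strictly decreasing in RQ, so
  sensitivity is easy to probe by re-running with another value.

Quality control uses two ratios with configured physiological bands: the
dilution space ratio $N_d/N_O$ (default acceptance 1.000–1.070 — the
conventional upper bound; a wider 1.700 bound seen in parts of the
literature is available via `dlw_config(dsr_high = 1.7)`) and the
elimination rate ratio $k_O/k_d$ (acceptance 1.100–1.700). Violations
raise named flags rather than dropping participants.

## Intake aggregation

Each eating occasion is recorded as a *before* image, closed by an
*after* image (leftovers) or an *ate everything* image. Consumed energy
is the before total minus the after total; negative values (after
exceeding before) are physically impossible recording errors, floored at
zero with a warning. Days with no recorded occasion count as zero intake
and are **included** in the within-subject CV by default: omission is a
reporting behaviour, exactly what a validity analysis should see. A
configuration switch (`include_empty_days = FALSE`) supports the other
convention, since field practice varies.

Within-subject variation is $CV_i = 100\,\mathrm{SD}/\text{mean}$ using
the sample (n−1) SD — day counts per participant are small — and the
cohort value pools them as a root mean square,
$CV_w = \sqrt{\sum_i CV_i^2 / n}$.

## Goldberg cut-offs

The misreporting classification compares each participant's TDEI:BMR
ratio with a confidence band around the cohort physical activity level
(PAL):

$$\text{limits} = \mathrm{PAL} \cdot \exp\!\left(\pm 2\,
\frac{S}{100\sqrt{n}}\right),\qquad
S = \sqrt{CV_{w\mathrm{TDEI}}^2/d + CV_{wB}^2 + CV_{tP}^2}.$$

Defaults follow the standard coefficients for free-living normal-weight
women: $CV_{wB} = 4.1\%$, $CV_{tP} = 16.5\%$, $CV_{w\mathrm{TDEI}} =
26\%$, with the study-specific pooled CV substituted automatically when
app series are available. Decisions worth making explicit:

* **d = 6 assessment days, not 7.** With a 7-day recording week one might
  expect $d = 7$; $d = 6$ is the default here because it is the value
  under which the published S factors this package reproduces
  (20.04% from the literature coefficients and ≈26.99% from the
  study-specific ones) are internally consistent, while $d = 7$
  reproduces neither. It is configurable and recorded in every report.
* **Boundary ratios are plausible.** Under- and over-reporting are
  defined by strict inequalities, so a ratio exactly on a limit
  classifies as plausible.
* **Cohort PAL is the mean of individual TDEE:BMR ratios**, not the
  ratio of cohort means; the two differ (Jensen), and the mean-of-ratios
  convention is what makes the published confidence limits coherent.
  `goldberg_config(pal = <value>)` fixes it externally instead.
* **BMR equation.** Mifflin-St Jeor is the default; Harris-Benedict is
  provided (`bmr_harris_benedict()`) because published cohort BMR means
  in this literature are sometimes closer to it, and cross-checking the
  two is cheap.

The classification is used for characterising the cohort, never for
excluding participants. The band is geometrically symmetric
($\text{lower} \times \text{upper} = \mathrm{PAL}^2$), which the test
suite asserts to 1e-12 — this symmetry is also what lets an upper limit
be recovered from a published lower limit.

## Agreement statistics

* **Bland–Altman.** Differences are test minus reference, bias is their
  mean, limits of agreement are $\text{bias} \pm 1.96\,\mathrm{SD}$.
  Confidence intervals use the t quantile with $n-1$ degrees of freedom
  (not 1.96) with $SE(\text{bias}) = SD/\sqrt{n}$ and the classical
  $SE(\mathrm{LoA}) = SD\sqrt{3/n}$; with 30 participants the t-based
  interval is visibly wider and matches published agreement tables in
  this literature, which is why it is the default. Level-dependent bias
  is left to visual inspection of the plot data (returned as
  `differences`/`means`) and deliberately not modelled.
* **Paired tests.** Shapiro–Wilk at 0.05 gates between the paired t-test
  and the Wilcoxon signed-rank test; p-values are Bonferroni-multiplied
  by 3 (the three planned comparisons: app–DLW, recall–DLW, app–recall)
  and capped at 1. Zero-variance differences return a degenerate record
  rather than a meaningless p.
* **Correlations** report both r and r², explicitly labelled — published
  reports in this area sometimes print signed "R²" values, which can
  only be r; carrying both removes the ambiguity.
* **ICC.** Day-to-day diet stability is the between-participant share of
  daily-intake variance. Variance components come from a REML
  random-intercept fit (`lme4`); the F statistic, p-value and confidence
  interval come from the one-way ANOVA representation with the exact F
  method, using the average group size for unbalanced data. On balanced
  data the REML and ANOVA estimators agree, which the tests exploit as
  an independent cross-check.
* **Over/under-estimation.** The mean percentage difference is the mean
  of individual percentage differences $100(a_i-b_i)/b_i$ — *not* the
  percentage difference of the means; the two differ materially in
  skewed cohorts, and the suite verifies the definition against a
  brute-force loop. Exact zero differences get their own count instead
  of an arbitrary tie-break.

## The nine-step benchmark

`run_benchmark()` renders the whole validation as nine standard steps:
(1) Bland–Altman per tool, (2) intake–expenditure correlation,
(3) absolute and percentage differences with gated paired tests,
(4) over/under-estimation, (5) Goldberg classification, (6) intake vs
body composition (FM, FFM), (7) energy-store change vs measurement
differences, (8) expenditure vs measurement differences, (9) ICC of
daily intake. Step 7 prefers measured FM/FFM changes through the
energy-density coefficients (9.5 kcal/g FM, 1.1 kcal/g FFM); when
composition changes are unavailable it falls back to raw body-weight
change and records the fallback. Missing inputs mark individual steps
skipped with a reason; the run never dies half-way. The orchestrator
stores unrounded module outputs — rounding to one decimal happens only in
the markdown renderer.

## The synthetic cohort

`simulation_config()` encodes the study conditions the pipeline is meant
for: 30 normal-weight adult women (age 28.5 ± 6.7 y, height
1.63 ± 0.07 m, weight 57.8 ± 6.1 kg, BMI constrained to 18.5–24.9
kg/m²), true TDEE 2235.2 ± 456.5 kcal/day, seven recording days with
within-subject intake CV 42.55%, participant-level reporting biases of
−329.6 ± 599.1 kcal/day (app) and −543.0 ± 642.6 kcal/day (recall).
Weight is drawn at its marginal distribution and height conditionally on
weight, so every draw respects the BMI bounds without distorting the
weight mean. Body-fat fraction is drawn at 0.27 ± 0.04 (truncated
0.15–0.40), a realistic range for normal-weight adult women, giving
FM/FFM and TBW = 0.732 · FFM.

Key generator mechanics:

* **Isotope inversion.** Dilution spaces follow from true TBW; doses
  follow the protocol rule (1.8 g of 10 atom% H₂¹⁸O and 0.12 g of 99.9
  atom% ²H₂O per kg body water); the elimination-rate ratio is drawn
  uniformly in 1.20–1.35 (inside the physiological 1.193–1.366 band) and
  the rates are then solved so the Speakman–Weir chain reproduces the
  true TDEE exactly. With zero enrichment noise the engine therefore
  recovers truth to floating-point accuracy — the round-trip test.
  Multiplicative noise on individual samples is available
  (`enrichment_noise`) and leaves recovered TDEE unbiased to within 1%
  at 2% noise.
* **Intake.** Daily true intake is lognormal around the participant
  mean — intake is positive and right-skewed — parameterised so its
  natural-scale CV equals the configured value exactly. Reported intake
  adds the participant-level tool bias (between-subject) and optional
  day-level noise (within-subject), floored at zero. App days are split
  into 3–9 eating occasions (7.5 ± 1.9), each a before image closed by
  an after (30%, leftover fraction 5–30%) or ate-everything image;
  macronutrients follow a fixed 50/35/15 carbohydrate/fat/protein energy
  split. The recall reports one extra simulated day with 4.6 ± 1.3
  occasions.
* **Energy balance.** By default the participant-level
  intake−expenditure gap (SD 150 kcal/day) drives the week's weight
  change through the energy-store coefficients, with 75% of the mass
  change attributed to fat mass (short-term imbalance in weight-stable
  adults is predominantly fat). This makes
  `delta_energy_stores()` exactly invertible on the generated truth and
  gives benchmark step 7 a non-degenerate signal. `energy_balance =
  FALSE` decouples them.
* **Seeding.** One global seed drives named substreams per module
  (cohort, isotopes, intake per tool), so regenerating any single block
  is reproducible independently of the others.

What the generator does **not** emulate: food-item identity and real
macronutrient composition (energy is the validated stream; nutrients are
proportional), intra-day temporal structure beyond occasion counts,
digit-preference and day-of-week effects in self-report, isotope
background drift, or correlated measurement error between tools. Passing
parameter-recovery tests therefore demonstrates the estimators are
correct under the stated statistical structure — not that any particular
real tool is valid.

## Numerical choices and problem sizes

Interchange CSVs are comma-separated UTF-8 with `.` decimals and
ISO-8601 timestamps; numeric output uses the shortest decimal string
that round-trips the double, so write-then-read is bit-exact. JSON
reports serialize non-finite numbers as `null` with a warning and are
byte-deterministic for identical inputs.

The test suite sizes its simulations for tight Monte-Carlo behaviour at
interactive runtimes: 10,000 draws for distribution means, 500
replicates for bias-recovery coverage (a 95% interval must cover in at
least 90% of them), 200 replicates for ICC recovery (±0.1 around the
generating 0.25), 30–50 replicates for noise-bias checks. Exact
arithmetic identities (band symmetry, unit coherence, MPD brute force)
are asserted at 1e-9–1e-12.

## Known limitations

* The DLW engine consumes plateau-averaged enrichments; raw
  per-sample spectrometry processing (memory correction, calibration
  against reference waters) is upstream of this package.
* The ICC confidence interval uses the average-group-size approximation
  under unbalance; for severely unbalanced designs a parametric
  bootstrap on the REML fit would be preferable.
* The Goldberg S factor treats the within-subject CV as known; its
  sampling error at n = 30 is not propagated into the band.
* Energy is the validated quantity; macronutrient agreement tables are
  produced but inherit the proportionality assumption in simulation.
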