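---
title: "Mtp methods: conventions, generative model, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mtp methods: conventions, generative model, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtplacenta)
```

## The index

Serum PlGF (pro-angiogenic, secreted by the syncytiotrophoblast) falls
and sFlt-1 (anti-angiogenic decoy receptor) rises as the placenta ages,
and prematurely so in hypertensive disorders of pregnancy. The Mtp
index expresses a single dosage of either marker as a multiple of the
value expected in an uncomplicated pregnancy at term:

$$\mathrm{Mtp}_{c} = \frac{x}{x_{c}},$$

where $x$ is the measured concentration (pg/mL) and $x_c$ a fixed
reference centile of the term distribution. Because dysfunction pushes
PlGF into its lower tail and sFlt-1 into its upper tail, the reference
centiles are the 2.5th/5th/10th for PlGF (48.9, 54.4, 68.6 pg/mL) and
the 90th/95th/97.5th for sFlt-1 (7901, 9184, 11471 pg/mL). An Mtp near
1 means the dosage sits at the edge of the normal term distribution;
Mtp sFlt-1 90th c ≥ 2 means twice the term 90th centile.

The reference table is a package constant (`default_reference()`) but
can be overridden from a YAML/JSON file (`read_reference()`), because
different immunoassay platforms yield systematically different
concentrations; any replacement must supply exactly the six centiles
above, strictly positive and strictly increasing per marker — the
category definitions below only make sense for these six.

## Rounding and raw values

Displayed values use **half-away-from-zero** decimal rounding: one
decimal for Mtp, two for the sFlt-1/PlGF ratio, zero for table
percentages. This is the only convention consistent with the clinical
reporting style the package mirrors (24.48/54.4 = 0.45 is displayed as
0.5, which rules out round-half-even). `round_display()` implements it
as `trunc(|x|·10^p + 0.5)·sign(x)/10^p`; we verified the seven
worked-example quotients land on the intended side in double precision
without any epsilon correction.

Every decision — risk classification, category membership — uses the
**raw, unrounded** quotients. Applying thresholds to rounded values
would create avoidable boundary artifacts (e.g. a raw ratio of 37.996
displaying as 38.00 yet being below the cutoff); with measured
concentrations, exact ties on the decision thresholds have measure
zero, so no tolerance is applied.

## Risk classes

The sFlt-1/PlGF ratio partitions into four classes at fixed gestational
age; the upper cutoffs switch at 34+0 weeks (238 completed days):

| class     | before 34+0 weeks | at/after 34+0 weeks |
|-----------|-------------------|---------------------|
| low       | ratio < 38        | ratio < 38          |
| medium    | 38 ≤ ratio ≤ 85   | 38 ≤ ratio ≤ 110    |
| high      | 85 < ratio ≤ 655  | 110 < ratio ≤ 201   |
| very high | ratio > 655       | ratio > 201         |

Boundary inclusion follows the strict inequalities of the published
cutoffs: "low" is strictly below 38, "high" and "very high" are
strictly above their cutoffs, so the boundary values 38/85/110 fall in
medium and 655/201 in high. Gestational age is held in completed days
(weeks·7 + days), and "before the 34th week" is `ga_days < 238`,
"before the 37th week" `ga_days < 259`.

## Mtp categories

`category_registry()` holds 19 named predicates over the six Mtp
values: thresholds from {0.5, 1, 2, 3} combined with ≤/</≥/> per
centile, plus three two-clause categories pairing the markers at
matched centiles (PlGF 10th with sFlt-1 90th, 5th with 95th, 2.5th
with 97.5th). The comparator sets are deliberately asymmetric between
the markers (there is a "PlGF 10th c < 1" but no "sFlt-1 90th c < 1",
and a "sFlt-1 90th c > 1" but no PlGF "> 1" category); the registry
reproduces the published list verbatim rather than symmetrising it.
Categories are *not* a partition: a dosage may satisfy several or
none. Note that at Mtp exactly 1 the 5th/95th and 2.5th/97.5th
combined categories are satisfied (both their clauses are non-strict)
while the 10th/90th combined category is not — a direct consequence of
the printed comparators.

## Summary tables

The unit of analysis is the **dosage**, not the patient: all available
dosages from admission to delivery are pooled, so women measured
repeatedly contribute several rows. Tables are produced for three
nested gestational-age strata (all dosages, < 37 weeks, < 34 weeks)
with, per group, the count, its percentage of the stratum total
(half-away-from-zero to integers), and the median and IQR of days to
delivery.

Quantiles use linear interpolation between order statistics
(`stats::quantile` type 7, the common default; the even-length median
is the mean of the two central order statistics). The original
reports do not state their quantile convention, so the `quantile_type`
argument lets a user swap in any of R's nine conventions; the test
suite pins type 7 against an independently coded order-statistic
oracle.

## Synthetic cohort generator

Patient-level data behind the motivating analysis are not publicly
deposited, so the package ships a generative model
(`generator_config()`, `generate_cohort()`) that reproduces the
*structure* the analysis assumes, for testing and demonstration:

- **Cohort shape.** 182 women; per-woman dosage count
  1 + Geometric(p) with mean 240/182 ≈ 1.32, giving ≈ 240 dosages in
  expectation. No per-patient dosage-count distribution is published;
  a geometric tail is the simplest choice with the right mean and is
  configurable.
- **Gestational age.** A three-window uniform mixture over
  [22+0, 33+6], [34+0, 36+6], [37+0, 42+0] weeks with weights
  0.34/0.30/0.36, matching the reported fractions of dosages before 34
  and before 37 weeks (34% and 64%).
- **Biomarkers.** A single latent severity $s_i \sim U(0,1)$ per woman
  drives both markers:
  $\log \mathrm{PlGF} = \log 250 - 2.53\,s - 0.004\,(ga - 238) + \varepsilon_1$,
  $\log \mathrm{sFlt\text{-}1} = \log 3000 + 1.67\,s + 0.004\,(ga - 238) + \varepsilon_2$,
  with $(\varepsilon_1, \varepsilon_2)$ bivariate normal (sds 0.35 and
  0.30, correlation −0.4). The slopes were chosen so that severity
  sweeps the ratio from ≈ 12 (clearly low) to ≈ 800 (beyond the
  very-high cutoffs), and so that class-wise Mtp medians reproduce the
  direction observed clinically: in generated cohorts the low class
  has median Mtp PlGF 2.5th c ≈ 3.8 and Mtp sFlt-1 90th c ≈ 0.45,
  the very-high class ≈ 0.56 and ≈ 1.7 respectively. One latent cause
  for both the angiogenic imbalance and earlier delivery is the
  simplest mechanism producing the observed association; no causal
  claim is intended.
- **Time to delivery.**
  $T = \mathrm{round}\!\left(\min\!\left(e^{a - b \log(\mathrm{ratio}) + \epsilon},\; 294 - ga\right)\right)$
  with $a = 3.25$, $b = 0.35$, $\epsilon \sim N(0, 0.6^2)$. The decay
  in the ratio makes median time to delivery fall from ≈ 9–10 days in
  the low class to ≈ 2–3 days in the very-high class. Times are capped
  so no synthetic delivery occurs after 42+0 weeks (294 days) —
  obstetrically implausible and never observed — and converted to
  integer days half-away-from-zero.

Numerical choices worth noting: with `keep_latent = TRUE` the
generator also returns the pre-truncation continuous time
`ttd_latent`. Integer rounding and the 42-week cap make the recorded
day counts only approximately log-linear in the ratio, so the
closed-form check that the decay exponent $b$ is exactly recoverable
by OLS (`recover_exponent()`) regresses on the latent time; with
`ttd_sigma = 0` the recovery is exact to machine precision. A fixed
seed yields a bit-identical cohort, and the caller's RNG stream is
restored on exit.

**What the generator does not emulate**, and hence what passing tests
do not show about real data: longitudinal biomarker kinetics within a
woman (the physiological PlGF rise to 29–32 weeks and subsequent fall
is collapsed into one linear gestational-age term, and a woman's
repeated dosages share a constant severity rather than a trajectory);
clinical delivery decisions (real delivery timing is determined by
management protocol, while the generator ties it directly to the
ratio); assay noise structure, detection limits, and the exact
class-occupancy percentages of any particular cohort. Structural
properties (partition/additivity of the tables, category nesting,
trend direction) transfer to real data; the specific medians and
percentages in generated tables do not.

## Degenerate inputs and edge behaviour

Empty cohorts are refused with an `"empty cohort"` error before any
output is written; empty groups within a non-empty stratum are
reported with `n = 0` and `NA` summaries. Non-positive concentrations
and ratios, gestational ages below 140 days (20 weeks), and negative
times to delivery are rejected at the IO boundary with the offending
row cited. Concentrations outside the assays' quantitation ranges are
not rejected — positivity is the only hard constraint, since range
filtering is a platform property, not a property of the index.

## Problem sizes in the test suite

The suite exercises the classifier on a 100,000-point ratio grid at
both gestational-age regimes, category nesting on 10,000 random
profiles, the quantile oracle on 1,000 random small samples, the trend
on an amplified cohort of ≈ 2,400 dosages (ten times the default
patient count), and cohort composition over 20 seeds — sizes chosen so
each property is tested well past its decision boundaries while the
whole suite runs in under a minute.

## Limitations

The reference centiles ship as constants from one assay platform
(electrochemiluminescence); users of other platforms must supply their
own. The package is purely descriptive by design — no survival
modelling, confidence intervals, or hypothesis tests — matching the
descriptive character of the analysis it implements. Whether
thresholds should be applied to rounded rather than raw values is
unstated in the source material; we chose raw (see above), which can
differ from a rounded-value reading only exactly at category
boundaries.
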