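---
title: "Predicting the post-filter IVC diameter by circle fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the post-filter IVC diameter by circle fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivcfit)
```

## The model and its assumptions

The inferior vena cava is predominantly oval in cross-section, so the
diameter measured from one projection angle is an accident of geometry:
the widest projection gives `D_max`, the narrowest `D_min`, and neither
is what the vessel will measure once an IVC filter has pushed it toward a
circular shape. `ivcfit` models the pre-placement cross-section as an
ellipse with semi-axes `a = D_max/2` and `b = D_min/2`, approximates its
perimeter with Ramanujan's first formula,

$$C \approx \pi\left[3(a+b) - \sqrt{(3a+b)(a+3b)}\right],$$

and predicts the post-placement diameter as the equivalent circular
diameter $D_{eq} = C/\pi$. The working assumptions are:

1. **Elliptical cross-section.** Irregular ("type V") lumens are not
   modelled; for them the two-axis summary loses information.
2. **Perimeter conservation.** Remodeling changes shape, not
   circumference, to first order. The residual ovality observed after
   placement is small and is represented in the simulator by the
   `anisotropy` parameter rather than in the predictor.
3. **Calibrated millimetre inputs.** No magnification or calibration
   correction is applied; measurements are assumed to already be in true
   millimetres. All columns carry an `_mm` suffix to keep units honest.

The closed form used in code,
$D_{eq} = 1.5(D_{max}+D_{min}) - \sqrt{(1.5D_{max}+0.5D_{min})(0.5D_{max}+1.5D_{min})}$,
is algebraically identical to the composition above (the test suite holds
them together to 1e-12 relative over $10^4$ random diameter pairs). It is
symmetric in its arguments, homogeneous of degree one, strictly
increasing in each diameter, and pinned between `d_min` and `d_max`.
Ramanujan's approximation is exact for circles and has relative error
below 0.5% even in the degenerate flat-ellipse limit (below 1e-4 for
aspect ratios of 0.3 or more), which is far inside measurement error for
vessels whose aspect ratios rarely drop below 0.4.

```{r}
predict_equivalent_diameter(15.52, 8.88)
```

## Numerical choices

- Diameters are double-precision millimetres throughout; rounding to
  two decimals happens only in printing.
- A circular input (`d_max == d_min`) is special-cased to return its own
  diameter exactly: the radical path agrees only to within a unit in the
  last place, and the circle identity is a contract, not an
  approximation.
- `d_max >= d_min` is enforced at construction. Files produced by
  single-angle workflows are sometimes column-swapped, so an explicit
  `auto_sort = TRUE` tolerates and logs swapped rows instead of failing.
- Degenerate zero-width vessels (`b = 0`) are rejected; the flat limit is
  exercised only when testing the approximation bound.

## Agreement statistics

Agreement between a prediction and a measurement is summarized with
Lin's concordance correlation coefficient,
$\rho_c = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)$, computed
with n-denominator (maximum-likelihood) moments — Lin's original
estimator. The convention matters for small-sample worked examples (the
four-point example in the tests gives 0.714286 under this convention)
and is held fixed. Confidence intervals use Lin's (1989) asymptotic
variance of the Fisher-z transformed coefficient, which involves the
standardized location shift $u = (\bar x - \bar y)/\sqrt{s_x s_y}$, and
are back-transformed so they stay inside $(-1, 1)$. Simulation places
the interval's coverage at the nominal 95% within sampling error
(the test suite checks 92–98% over 1000 replicates at true CCC 0.9,
n = 50) and its endpoints within 0.03 of a percentile bootstrap.

CCC values are classified with the conventional taxonomy — poor
(CCC ≤ 0.40), fair to good (0.40 < CCC ≤ 0.75), excellent (CCC > 0.75) —
with boundary values assigned to the lower class.

Two predictors of the same measured quantity are compared with
`compare_dependent_ccc()`: the principal inference is a percentile
bootstrap (default 2000 subject resamples, seed required) of the
difference of the two CCCs, with a two-sided p-value from the
sign-crossing fraction with an add-one correction. The construction of
the interval printed in comparable published comparisons is not
documented there, so no attempt is made to reproduce it numerically; a
Steiger-style Fisher-z test, which accounts for the shared variable
through the candidate–candidate correlation, is exposed alongside and
labelled approximate. Mean contrasts use Student's t tests — paired for
within-subject stages, pooled-variance two-sample for independent
groups. A constant non-zero paired difference yields an exact mean
contrast but an undefined t statistic; it is reported as such (t = NA
with a note) rather than failing, while identical vectors are an error.
Two-sided p-values and a 0.05 threshold are used throughout.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates cohorts with the published first and
second moments. Latent pre-placement diameters come from a correlated
bivariate normal, rejected until `d_max > d_min > 1` mm; the true
equivalent diameter is computed deterministically; post-placement
diameters are `d_eq (1 ± anisotropy)` plus Normal(0, `remodel_sd`) noise
(the larger noisy draw carries the "maximum" label, as it would in a
measurement); and each diameter is split into a superior/inferior edge
pair `(D + δ, D − δ)` so edge averaging recovers it exactly.

Built-in profiles fix the study conditions: `"swine"` (n = 24, maximum
diameter 15.52 ± 2.82 mm, minimum 8.88 ± 2.01 mm) and `"patient"`
(n = 62, 22.07 ± 3.99 mm and 15.95 ± 3.99 mm). Three parameters are not
published anywhere and are modeling choices, set once:

- `rho = 0.5` — the pre-placement max/min correlation. No source cohort
  reports it; 0.5 encodes that wide vessels tend to be wide in both
  axes without making the two measurements redundant. It is exposed
  because the strength of the predictor-ordering result depends on it.
- `anisotropy = 0.02` and `remodel_sd = 0.5` mm — residual post-placement
  ovality and remodeling noise, chosen so simulated CCCs between the
  predicted and post-placement diameters fall in the published 0.93–0.99
  range. These are tuning values, not estimates.
- `edge_sd = 0.2` mm — spread between the superior and inferior edge
  readings; it cancels in the average by construction.

What passing simulation tests show is that the pipeline recovers the
structure this generator puts in — the ordering "equivalent diameter
beats either single-angle diameter", excellent-class CCCs, calibrated
intervals. What they cannot show is anything the generator does not
contain: irregular lumen shapes, respiratory diameter dynamics,
reader-to-reader measurement bias, filter-model-specific mechanics, or
any misfit of the bivariate-normal family itself (the sources publish
only means and SDs, so the family is a transparency-motivated choice).
Conclusions about real vessels rest on the published validation, not on
these simulations.

## Pipeline and reproducibility

`read_measurement_table()` accepts two CSV schemas (raw edge pairs or
already-averaged diameters), detected from the header and never mixed;
rows with missing values are dropped with a counted warning.
`run_analysis()` computes the seven-pair agreement matrix (each
pre-placement predictor and the equivalent diameter against each
post-placement diameter, plus the post-max/post-min circularity check),
the five dependent-CCC comparisons, paired t tests, and group summaries
when a `group` column is present. Degenerate statistics — a CCC of
exactly 1 has no finite-width interval — are carried as structured
entries with a `note`, never dropped. Reports render to canonical JSON
(full precision, schema-tagged, byte-identical for a fixed seed unless a
timestamp is requested), CSV, or text.

Problem sizes in the test suite were chosen to make the statistical
checks decisive at interactive speed: $10^4$ pairs for the algebraic
identity, 1000 replicates for interval coverage, 500 simulated cohorts
of n = 24 for the ordering property, 2000 bootstrap resamples where a
bootstrap is compared against the asymptotic interval.

## Known limitations

- The elliptical model understates the perimeter of irregular lumens.
- The asymptotic CCC interval is first-order; at n well below ~15 it can
  undercover, and the bootstrap comparison is preferable.
- The Steiger-style z test treats CCCs as correlations on the Fisher-z
  scale; it is a labelled approximation, reported alongside the
  bootstrap, never instead of it.
- The simulator's defaults reproduce published summary moments, not
  per-subject data; parameter-recovery results are statements about the
  generator.
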