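# ivcfit

Circle-fitting prediction of the inferior vena cava (IVC) diameter after
vena cava filter (IVCF) placement, with the concordance-based validation
machinery and a synthetic cohort simulator.

## The problem

The IVC is usually oval in cross-section, so the diameter seen from a
single projection angle depends on the angle: the maximum diameter
overstates, and the minimum understates, how wide the vessel will be once
a filter is deployed. After placement the vessel remodels toward a
near-circular shape. Filter sizing based on one pre-placement angle can
therefore misrepresent filter–vessel compatibility.

## The model

Treat the pre-placement cross-section as an ellipse with semi-axes
`a = D_max / 2`, `b = D_min / 2`. Its circumference is approximated with
Ramanujan's formula

    C ≈ π [ 3(a + b) − √((3a + b)(a + 3b)) ]

and, because remodeling approximately conserves the perimeter while
circularizing the lumen, the predicted post-placement diameter is the
equivalent circular diameter `D_eq = C / π`, which simplifies to

    D_eq = 1.5 (D_max + D_min) − √((1.5 D_max + 0.5 D_min)(0.5 D_max + 1.5 D_min))

Note on the formula: some printed renderings of this model drop the
radical, leaving a dimensionally inconsistent expression (mm minus mm²);
this package implements the closed form above, which is Ramanujan's first
approximation, exact for circles, and reproduces the published
cohort-mean predictions to within 0.2 mm.

Predictions are validated with Lin's concordance correlation coefficient
(CCC) with 95% confidence intervals (Lin 1989 asymptotic variance on the
Fisher-z scale), classified as poor (CCC ≤ 0.40), fair to good
(0.40 < CCC ≤ 0.75), or excellent (CCC > 0.75), and competing predictors
are compared with a percentile bootstrap of the difference of dependent
CCCs (plus an approximate Steiger-style Fisher-z test).

## Worked example

```r
library(ivcfit)
predict_equivalent_diameter(c(15.52, 22.07), c(8.88, 15.95))
#> Circle-fitting equivalent-diameter prediction (mm)
#>  d_max d_min     a    b circumference  d_eq
#>  15.52  8.88  7.76 4.44         39.04 12.43
#>  22.07 15.95 11.04 7.97         60.11 19.13
```

A vessel measuring 15.52 mm at its widest and 8.88 mm at its narrowest
projection has an estimated perimeter of 39.04 mm, so after
circularization its diameter is predicted to be 12.43 mm — between the
two single-angle readings and close to the published post-placement means
(12.55 and 12.59 mm).

The full pipeline on a synthetic cohort:

```r
tab <- simulate_cohort(cohort_profile("swine", seed = 7))
run_analysis(tab, seed = 3)
#> Agreement (Lin's CCC, 95% CI; poor <=0.40 < fair to good <=0.75 < excellent):
#>   dmax       vs post_dmax  CCC = 0.612 (0.496-0.706)  fair to good
#>   dmin       vs post_dmax  CCC = 0.243 (0.140-0.340)  poor
#>   deq        vs post_dmax  CCC = 0.974 (0.944-0.988)  excellent
#>   ...
```

The predicted diameter agrees excellently with the simulated
post-placement diameters while either single-angle measurement alone does
not — the qualitative pattern reported for both the angiographic (swine)
and CT (patient) cohorts.

The same operations are available from a shell:

```sh
Rscript inst/scripts/ivcfit.R predict --dmax 22.07 --dmin 15.95
#> D_eq = 19.13 mm (circumference 60.11 mm)
Rscript inst/scripts/ivcfit.R simulate --profile swine --seed 11 --out cohort.csv
Rscript inst/scripts/ivcfit.R analyze --in cohort.csv --seed 11 --out report.json
Rscript inst/scripts/ivcfit.R report --in report.json --format text
```

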