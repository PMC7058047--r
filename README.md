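# jsmapr

Three-dimensional **joint space mapping** for the hip in R: measure joint
space width (JSW) from CT-like volumes by constrained deconvolution, register
every hip to a canonical acetabular surface, model 3D shape variation by PCA,
test regional JSW differences with surface statistical parametric mapping
(SPM) under random-field-theory correction, estimate shape–outcome odds
ratios with generalised estimating equations (GEE), and evaluate prediction
of future total hip replacement (THR) by leave-one-out cross-validated ROC.

Who it is for: researchers in musculoskeletal imaging and osteoarthritis
epidemiology who want a fully scripted, testable version of the 3D
joint-space analysis chain — and, because clinical CT of this kind is rarely
shareable, a synthetic phantom and cohort generator that exercises every
stage with known ground truth.

## The measurement model

The joint space is laminar and often narrower than the CT point spread
function (PSF). At each vertex of the femoral joint-space patch a density
profile is sampled along the surface normal and fitted with a
Gaussian-blurred four-interface step model

    y(x) = y_bg1 + (y_c − y_bg1) Φ((x−e1)/σ) + (y_gap − y_c) Φ((x−e2)/σ)
                 + (y_c − y_gap) Φ((x−e3)/σ) + (y_bg2 − y_c) Φ((x−e4)/σ)

with the cortical plateau `y_c` fixed per patch (the deconvolution
constraint) and JSW = `e3 − e2`. Downstream, the vertex-wise surface model is
`JSW ~ 1 + THR + SM1 + … + SM7` with F tests and peak-level random field
correction; shape-mode odds ratios are per adjusted SD with hips weighted
`1/(1+R)` for the within-individual side correlation `R`.

## Worked example

Simulate a cohort on a reduced canonical surface, map the group difference,
and fit the association model:

```r
library(jsmapr)

can <- canonical_surface(n_theta = 12, n_phi = 12)   # 145-vertex template
sim <- simulate_cohort(cohort_spec(), can, seed = 1)

# surface SPM of JSW on future THR, confounded on shape modes SM1-SM7
res <- spm_jsw(sim$maps, sim$cohort, sim$coefficients, can)
res
#> <spm_result> n=267, df=(1,258), FWHM 16.4 mm, 42/145 ROI vertices (alpha 0.05)
#>   mean difference in ROI: -1.12 to 0.37 mm
```

The significant region sits over the superior joint space, where the
generator planted case narrowing of up to 1 mm in the individual-averaged
maps: the fitted THR coefficient (case-minus-control difference) reaches
−1.12 mm inside the ROI.

```r
g <- gee_odds_ratios(sim$cohort, sim$coefficients, n_modes = 7)
tidy(g)[3:4, ]
#> # A tibble: 2 × 6
#>   term     or  lo95  hi95   p_value significant
#>   <chr> <dbl> <dbl> <dbl>     <dbl> <lgl>
#> 1 SM1    1.35 0.964  1.89 0.0802    FALSE
#> 2 SM2    1.66 1.29   2.13 0.0000938 TRUE
```

The second shape mode, planted with an odds ratio of 1.75 per adjusted SD,
is recovered at 1.66 (1.29–2.13) in this draw and survives the
Bonferroni-corrected threshold of 0.05/18 < 0.003. `autoplot()` methods draw the scree plot,
forest plot, ROC curve and the SPM difference map; `tidy()`/`glance()`
return tibbles throughout.

A thin command-line surface over the same functions ships in
`inst/cli/jsmpipe.R` (subcommands `simulate`, `map`, `register`, `ssm`,
`gee`, `spm`, `predict`).

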