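# apf2 — ensemble prediction of pharmacogenomic variant effects

Most variant effect predictors are trained to flag disease-*pathogenic*
variants and lean heavily on evolutionary conservation. Pharmacogenomic
variants — missense changes that reduce the function of drug-metabolizing
enzymes and transporters without causing disease — are often poorly
conserved and sometimes common, so those tools misjudge them. This package
implements the APF2 approach for this problem, for anyone benchmarking
predictors on labeled pharmacogenomic variants or scoring variants of
unknown significance in pharmacogenes:

1. **Benchmarking.** For each predictor with conventional decision rule
   (direction, operator, cutoff), calls on a labeled variant set are
   tallied into TP/TN/FP/FN and summarized as sensitivity, specificity,
   accuracy, PPV, NPV, FPR, FNR, Youden's J = SEN + SPE − 1, and the
   trapezoidal ROC AUC. Variants a tool cannot score are first-class
   missingness: reported as a count and percent, never imputed.
2. **Threshold re-parametrization.** Each component predictor's cutoff is
   refit by maximizing J over all candidate cutoffs (midpoints between
   consecutive distinct scores), with k-fold cross-validation reporting the
   informedness gain ΔJ on training and held-out folds.
3. **The ensemble score.** Each re-parametrized component casts a binary
   functionality vote (1 = functional, 0 = deleterious); the APF2 score is
   the weighted mean of available votes (weights ∝ cross-validated
   validation-fold J, renormalized over scored components), lying in
   [0, 1]. Scores ≤ 0.367 are classified deleterious, > 0.367 neutral; a
   variant with fewer than 3 scored components gets NO_CALL.
4. **Quantitative effects.** Ensemble scores are mapped to in-vitro enzyme
   activity (% of wild type) by binned ordinary least squares.
5. **Population burden.** Allele frequencies aggregate under
   Hardy-Weinberg equilibrium into expected deleterious variants per
   individual (Σ 2p), carrier frequencies (1 − Π(1−p)²), the rare-variant
   share of the burden (MAF < 1%), and per-1000 "individuals at risk"
   estimates from drug–gene actionability rules.

A synthetic-data module generates labeled score tables and population
frequency tables with known ground truth (closed-form Gaussian AUC and
optimal-threshold oracles), so the whole pipeline is testable without
external annotation downloads.

## Worked example

```r
library(apf2)

# simulated variant set emulating a 530-variant fitting set
sim <- simulate_labeled_scores(sim_config(seed = 7))
fit <- apf2(sim$scores, sim$labels, seed = 7)
summary(fit)
#> Ensemble model summary (n = 530 variants, 5-fold CV, seed 7)
#>         algorithm conventional_threshold optimized_threshold J_conventional
#>     AlphaMissense                  0.564               0.472          0.425
#>           PROVEAN                 -2.282              -2.478          0.407
#>  MutationAssessor                  1.900               2.292          0.377
#>        PolyPhen-2                  0.446               0.531          0.402
#>             VEST4                  0.500               0.500          0.366
#>  J_optimized delta_J mean_val_J mean_val_delta_J weight
#>        0.537   0.112      0.470            0.051  0.240
#>        0.430   0.023      0.397           -0.011  0.203
#>        0.398   0.020      0.347           -0.029  0.177
#>        0.440   0.038      0.433            0.032  0.222
#>        0.366   0.000      0.308           -0.059  0.157
#> deleterious cutoff on ensemble score: <= 0.367
```

Each row is one component: its conventional cutoff, the cutoff refit by
maximizing Youden's J on these variants, the informedness before/after,
the cross-validated mean validation-fold J, and the resulting ensemble
weight. Scoring variants:

```r
head(predict(fit, sim$scores), 3)
#>        variant apf2_score        call n_components_used ...
#> 1 CYP2C9:p.V1A  0.0000000 deleterious                 3
#> 2 CYP2D6:p.V2A  0.7295019     neutral                 3
#> 3 CYP3A5:p.V3A  0.4436015     neutral                 5
```

The first variant's three available components all vote deleterious, so
its score is 0 and the call is deleterious (score ≤ 0.367). To score
variants with the shipped published parametrization instead of refitting,
use `apf2_default_model()`.

Population aggregation:

```r
carrier_frequency(0.1)
#> [1] 0.19
ft <- simulate_frequency_table(sim_config(seed = 7))
expected_burden(ft, population = "AFR")
#> <burden_report> AFR / all: 61.2 variants per individual
#>   (carrier freq 1, rare fraction 0.0126) over 400 variants
```

A command-line front end over the same functions is in
`inst/scripts/apf2.R` (subcommands `benchmark`, `optimize`, `score`,
`burden`, `simulate`).

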