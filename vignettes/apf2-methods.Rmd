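---
title: "Methods: ensemble pharmacogenomic variant effect prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble pharmacogenomic variant effect prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apf2)
```

## The problem and the model

Pharmacogenomic missense variants reduce the function of drug-metabolizing
enzymes and transporters (CYPs, UGTs, SLCO/ABC transporters) without being
disease-pathogenic in the clinical-genetics sense. General-purpose variant
effect predictors, mostly trained on pathogenic/benign labels and driven by
evolutionary conservation, systematically misjudge them: pharmacogenomic
sites are often weakly conserved, and some functionally deleterious alleles
are common in the population. The approach implemented here addresses this
with three moves:

1. **Re-parametrize, don't retrain.** Each component predictor keeps its
   published score and deleteriousness direction but gets a new cutoff
   fitted on labeled pharmacogenomic variants, by maximizing Youden's J
   (informedness, J = sensitivity + specificity − 1). J weighs both error
   types equally and is prevalence-free, which suits a fitting set whose
   class balance is a curation artifact.
2. **Aggregate binary votes.** Components were individually thresholded in
   this workflow, so the ensemble aggregates their binary calls rather
   than rescaled continuous scores: each scored component votes 1
   (functional) or 0 (deleterious), and the ensemble score is the weighted
   mean of available votes. It lives in [0, 1], is 1 exactly at a
   unanimous functional vote and 0 at a unanimous deleterious vote, is
   monotone in every vote, and correlates positively with measured enzyme
   activity. Classification uses a fixed cutoff: score ≤ 0.367 is
   deleterious, > 0.367 neutral.
3. **Aggregate frequencies, not genotypes.** Population-scale resources
   publish allele frequencies, not individual genotypes, so per-individual
   quantities are derived under Hardy-Weinberg equilibrium with
   independence across sites and genes.

## Labels and evidence tiers

Labels are binary (deleterious / neutral) with three evidence tiers:
clinical guideline annotations (decreased- or loss-of-function alleles are
deleterious), in-vitro characterization (deleterious iff measured intrinsic
clearance is below 50% of wild type — the boundary value 50 is neutral),
and curated database annotations for independent testing. The loader
derives labels from activity where no explicit label is given and rejects
rows whose explicit label contradicts a measured activity. The reference
fitting set combines the first two tiers (145 + 385 = 530 variants); the
independent test tier has 146.

## Benchmarking and missingness

Every predictor is evaluated with its published decision rule, including
the printed operator's strictness: SIFT ≤ 0.05 calls the boundary value
deleterious, CADD > 15 calls it neutral. The registry ships all 29
published rules (28 distinct tools; VEST appears in its version-3 and
version-4 scorings, and the alias `"VEST"` resolves to VEST4, the version
the optimized ensemble uses).

Metrics are computed on each predictor's scored variants only; variants a
tool cannot score are reported as a separate missingness count and percent.
No imputation is done — a tool that scores half the variants is shown as
such rather than silently evaluated on a different denominator. Ratios with
empty denominators are undefined (`NA`, serialized as JSON `null`), never
coerced to zero, to avoid inflating metrics on degenerate inputs. AUC is
the trapezoidal area under the ROC curve with tied scores collapsed to one
operating point, which equals the Mann-Whitney concordance probability with
ties counted one half; tie handling is a convention choice and is asserted
against an exhaustive pairwise-concordance oracle in the tests.

## Threshold optimization

Candidate cutoffs are the midpoints between consecutive distinct sorted
scores, plus one candidate below the minimum and one above the maximum
(offset by half the adjacent gap). Midpoints — rather than observed score
values — make strict and non-strict comparison operators classify every
candidate partition identically, so operator strictness cannot flip an
optimization result. The scan is vectorized via cumulative class counts
(O(n log n)); the tests assert exact agreement with a brute-force
per-candidate oracle.

Ties on J are broken in favor of higher specificity, then the smallest
candidate. The specificity preference reflects the clinical cost asymmetry
for this application — a false deleterious call can wrongly withhold or
re-dose a drug — and the final rule makes results deterministic.

Cross-validation is 5-fold, label-stratified (stratification stabilizes J
estimates on 20% folds), with the partition a pure function of a logged
integer seed (default 1). Items are dealt to folds class by class in one
continuous cycle, so both the overall fold sizes and each class's fold
counts differ by at most one (530 variants split exactly 106/106/106/106/106).
The reported final threshold is refit on the full set — a single shipped
threshold per component is the interface — while the CV folds exist to
report honest train/validation ΔJ distributions and the validation-fold J
used for weighting. On fitting data the optimized J can never be below the
conventional-threshold J (the conventional partition is among the
candidates); on held-out folds ΔJ can legitimately be negative.

## Ensemble weighting and scoring

The published method aggregates "weighted" component predictions without
stating the weights — the one genuinely open design point. This package
weights each component proportionally to its cross-validated mean
validation-fold J, normalized to sum to one: J is the very objective the
thresholds maximize, and validation-fold J avoids rewarding components
whose threshold overfits. The scheme is pluggable (`"cv_J"`, `"uniform"`,
or user-supplied positive weights) and recorded in the model object.
Components with non-positive informedness are dropped with a warning; a
model needs at least two informative components (a deliberate
single-component model is allowed and gets weight 1).

Missing component scores renormalize the remaining weights to sum to one.
A call requires at least `min_components = 3` of 5 scored components —
tolerant of partial missingness (one reference tool is unusable for a third
of variants) but not of majority missingness, mirroring the exclusion of a
tool that missed half the benchmark. The shipped reference model
(`apf2_default_model()`) carries the published optimized thresholds and the
published combined-set J values as weights; the 0.367 cutoff is a stored
constant of that model, presumed to originate as the J-optimal cutoff on
fitting-set ensemble scores, and `apf2(..., cutoff = "refit")` recomputes
it that way on refits.

## Score-to-activity map

The quantitative map from ensemble score to enzyme activity (% wild type)
bins variants into 7 equal-width score bins over [0, 1] and fits ordinary
least squares of bin-mean activity on bin midpoints, reporting slope,
intercept, R² and the two-sided p of the slope. Binning first smooths
variant-level assay noise; 7 bins is consistent with the granularity of the
published score-activity regression and is a recorded knob of the fitted
map. The regression is unweighted by bin occupancy (occupancy is reported
per bin). At least 3 non-empty bins are required; a constant response is
returned as slope 0, R² 0, p 1 rather than an undefined fit. Predictions
are clamped to [0, max observed activity].

## Population aggregation

"Deleterious variants per individual" is the expected variant-allele count
Σ<sub>v</sub> 2p<sub>v</sub> under Hardy-Weinberg equilibrium — the only
per-individual quantity derivable from allele frequencies alone — and the
carrier probability 1 − Π<sub>v</sub>(1 − p<sub>v</sub>)² is emitted
alongside it, since published aggregate analyses do not state which of the
two they use. Rare means allele frequency strictly below 1%; exactly 1% is
common. The rare/common split is applied to the table's frequencies as
given (population resources export minor/alternate allele frequencies).

Actionability rules are user-auditable configuration, not a hard-coded
guideline engine: each rule names a drug, one or more genes, and a trigger
— `any_variant_allele` (1 − (1−q)², dominant-acting) or
`two_variant_alleles` (q², recessive loss of function) — where
q = 1 − Π(1 − p<sub>v</sub>) is the gene's aggregate deleterious allele
frequency; multi-gene rules combine as 1 − Π(1 − f<sub>g</sub>). Results
are reported per 1000 individuals. Diplotype-level phenotype logic
(star-alleles, PM/IM/NM categories) is out of scope. Independence across
sites and genes ignores linkage — a stated limitation matching the
aggregate treatment this mirrors.

## The synthetic-data generator

`simulate_labeled_scores()` draws class-conditional Gaussian scores per
predictor with completely-at-random missingness; `simulate_frequency_table()`
draws a configured mixture of common (uniform on [0.01, 0.5]) and rare
(log-uniform on [10⁻⁵, 0.01)) allele frequencies per gene and population.
Defaults are fixed once as the study conditions the generators emulate:

* class sizes 285 deleterious / 245 neutral — the 530-variant combined
  fitting set at the class balance implied by its published
  accuracy/sensitivity/specificity;
* per-component separations chosen so each simulated tool's analytic
  Gaussian AUC Φ(Δμ/(σ√2)) equals the corresponding published benchmark
  AUC (0.80, 0.76, 0.75, 0.76, 0.74) at its published missingness (33%,
  4%, 22%, 25%, 1%), on a plausible version of each tool's score scale and
  direction;
* eight population labels with 70% rare variants per gene.

Gaussian class-conditionals buy closed-form oracles: the analytic AUC
above, and the analytic J-optimal threshold (equal class sizes) at the
class-density intersection — the midpoint of the means for equal scales,
otherwise the root of the log-density quadratic between the means
(`analytic_optimal_threshold()`, verified in the tests against a dense
closed-form grid search of J). A location-scale t option stresses
tie-breaking under heavy tails.

What the generator does **not** emulate: correlation between predictors
(real tools share training data and conservation features, so real
ensembles gain less from aggregation than independent-noise simulations
suggest), informative missingness (tools fail on particular protein
regions, not at random), per-gene score heterogeneity, and realistic
mutation spectra. Passing tests on simulated data therefore demonstrate
correctness of the estimators and aggregation arithmetic, not real-data
performance.

## Numerical choices and problem sizes

* Threshold-recovery checks run at 10⁴ variants per class against the
  analytic optimum in a well-separated equal-variance configuration (class
  means 0.2/0.8, σ = 0.1). The empirical argmax-J threshold converges at a
  cube-root rate, so at published-benchmark-level class overlap (AUC
  ≈ 0.8) its sampling error at this n is on the order of 0.1σ — recovery
  to 0.05 is a property of the well-separated regime, which is what the
  check certifies.
* Oracle-equivalence suites use 200 random instances of up to 500 variants
  (threshold scan) and 50 instances up to 200 variants (pairwise
  concordance AUC); null calibration uses 5000 permuted-label variants.
* Floating-point ties in the J scan are resolved with a 10⁻¹² slack before
  the specificity/smallest-candidate tie-break.
* Empty-denominator metrics are `NA`; single-class inputs to ROC or
  threshold fitting are errors, not silent degenerate output.
* All randomness (simulation, fold assignment) flows through explicit
  integer seeds; generators restore the caller's RNG state.

## Known limitations

Only single missense variants with reduced-function effects are modeled:
no gain of function, no substrate-specific effects, no combinatorial
haplotypes, no splicing/regulatory variants. Multi-transcript variants
must be pre-collapsed to one score per variant upstream. The ensemble's
published parametrization is reproduced from its printed thresholds and
informedness values; its exact training weights were never published.
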