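# mvslearn

Multi-view subspace-learning biomarkers for predicting conversion from mild
cognitive impairment (MCI) to Alzheimer's disease (AD).

## The problem

Whether an MCI patient will progress to AD (pMCI) or remain stable (sMCI)
is hard to read off high-dimensional structural MRI features: regional
cortical thickness and cortical volume differences between the two MCI
subgroups are subtle. AD and normal-control (NC) subjects, however, show
the same anatomical contrast in amplified form — pMCI resembles AD, sMCI
resembles NC. `mvslearn` exploits that: it learns a projection of the two
morphological feature views into a shared class-label subspace from AD/NC
*auxiliary* subjects, then maps held-out MCI subjects through those
projections and fuses the two views into a low-dimensional biomarker for
pMCI-vs-sMCI classification. Intended users are neuroimaging researchers
evaluating conversion biomarkers, and methods researchers who need a fully
synthetic, reproducible test bed for auxiliary-data subspace learning.

## The model

Given aligned views `X_CT, X_CV ∈ R^{d×n}` (d regional features, n
auxiliary subjects) and a one-hot label matrix `Y ∈ R^{n×c}`, two
projections `U, V ∈ R^{d×c}` minimize

```
Q(U,V) = λ(‖Y − X_CTᵀU‖²_F + ‖Y − X_CVᵀV‖²_F)          label regression
       + (1−λ)‖X_CTᵀU − X_CVᵀV‖²_F                      cross-view consistency
       + α(tr(UᵀX_CT L_CT X_CTᵀU) + tr(VᵀX_CV L_CV X_CVᵀV))   graph smoothness
       + β(‖U‖²_F + ‖V‖²_F)                              ridge
```

where `L_CT, L_CV` are graph Laplacians of per-view kNN heat-kernel
affinity graphs (`w_ij = exp(−‖x_i−x_j‖²/2σ²)`). Both blocks have exact
closed-form minimizers, so `U` and `V` are fitted by alternating
ridge-type updates from zero initialization; the objective is
monotonically nonincreasing. Target (MCI) subjects `Z_CT, Z_CV` are then
projected (`Fea_CT = Z_CTᵀU`, `Fea_CV = Z_CVᵀV`) and fused by the
self-weighted convex combination

```
Fea = η |Fea_CT|⊙|Fea_CT| + (1−η) |Fea_CV|⊙|Fea_CV|
```

giving an `m×c` nonnegative biomarker matrix. The evaluation harness
reproduces the full protocol: stratified 10-fold cross-validation repeated
20 times, three classifier families (linear SVM, RBF SVM, decision tree),
an ACC/SEN/SPE/AUC panel, paired t-tests across repeats, hyperparameter
grid search, a self-learning protocol variant (projections relearned from
target training folds only), and an auxiliary-set-size sweep. A synthetic
two-view four-group cohort generator makes everything testable without any
external data.

## Worked example

```r
library(mvslearn)

spec <- cohortSpec(nPerGroup = c(AD = 142, NC = 165, pMCI = 126, sMCI = 95),
                   d = 78, delta = 1.5, seed = 42)
cohort <- generateCohort(spec)
g <- groupLabels(cohort)
aux    <- cohort[, g %in% c("AD", "NC")]
target <- cohort[, g %in% c("pMCI", "sMCI")]

model <- learnProjections(aux, hyperParams())
model
#> ProjectionModel: d = 78 features -> c = 2 label dimensions (AD vs NC)
#>   43 iterations, converged: TRUE, final objective 22.9542
#>   lambda = 0.1, alpha = 0.1, beta = 10, k = (11, 3), eta = 0.03

biom <- extractBiomarkers(model, target)
head(round(biom, 4), 3)
#>              AD     NC
#> pMCI_001 0.3304 0.1248
#> pMCI_002 0.3166 0.1935
#> pMCI_003 0.3094 0.2170

result <- runProtocol(aux, target, hyperParams(),
                      cvConfig(nRepeats = 20, baseSeed = 7), "auxiliary")
result
#> ProtocolResult (protocol = auxiliary, positive class = pMCI)
#>   20 repeats of 10-fold CV, classifier = svm-linear
#>   mean ACC = 0.8247  SEN = 0.8817  SPE = 0.7489  AUC = 0.9228
```

The biomarker columns are coordinates along the AD-like and NC-like label
axes: pMCI subjects load higher on the AD axis (e.g. 0.33 vs 0.12 for the
first subject), which is exactly the structure the classifier exploits.
The panel means say that on this synthetic cohort (moderate effect size,
`delta = 1.5`) the fused biomarkers separate pMCI from sMCI with 82%
pooled accuracy and AUC 0.92 over 20 repeated 10-fold CV rounds.

A thin command-line front end over the same functions is installed at
`inst/scripts/mvslearn-cli.R` with subcommands `simulate`, `fit`,
`transform`, `evaluate` and `report`.

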