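# invasig

Derivation and survival validation of tumor-invasion gene signatures.

## The problem

Migratory tumor cells collected from live primary breast tumors can be
expression-profiled against the average primary-tumor cell population to
yield an *invasion signature*: the genes whose regulation marks the
subpopulation that actually migrates and invades. Whether such a
signature carries prognostic information is then a statistical question
asked of independent patient cohorts: does the signature separate
patients by metastasis- or recurrence-free survival, beyond chance and
beyond established clinical factors?

`invasig` implements that full computational arc for R users
(Bioconductor-style S4 API over `SummarizedExperiment`):

* **Preprocessing** — global LOWESS MA-normalization of two-channel
  intensities, probe filtering, and max-variance probe-to-gene
  collapsing (`lowessNormalize`, `filterAndCollapse`).
* **Derivation** — two-class SAM, d = (x̄₁ − x̄₂)/(s + s₀), with
  permutation-based FDR estimation and extraction of the top-k genes by
  fold change (`samStatistics`, `samPermutationFdr`, `callSignificant`,
  `extractSignature`).
* **Validation** — the Minn-style leave-one-out cross-validated Cox risk
  index RIⱼ = Σ β̂ᵍ xᵍⱼ with top-20th-percentile stratification,
  Kaplan–Meier / (weighted) log-rank / hazard-ratio evaluation, and
  multivariate Cox adjustment (`loocvAssign`, `evaluateStratification`,
  `multivariateAdjustment`; primitives in `kmEstimate`,
  `weightedLogrank`, `coxFit`, `coxUnivariateBatch`).
* **Specificity** — the empirical null of 1,000 random signatures of
  matched size (`nullDistribution`, `empiricalSpecificity`).
* **Subtype correlation** — the Creighton-style per-patient R value
  against the signature's ±1 pattern after centroid-mean centering
  (`centroidCenter`, `rValue`, `rvalueBySubtype`).
* **Synthetic data** — generators with known planted structure so every
  stage is testable against ground truth (`simulateTwoClassExpression`,
  `simulateSurvivalCohort`).
* **Pipelines** — file-based, seed-stamped, byte-reproducible end-to-end
  runs (`runDerive`, `runValidate`).

## A worked example

Derive a signature from synthetic two-class arrays (4 biologic repeats
per class, 50 planted genes of effect 2.0 log2 units among 1000):

```r
library(invasig)
se  <- simulateTwoClassExpression(n_genes = 1000, n_per_class = 4,
    n_de = 50, effect_size = 2, noise_sd = 0.5, seed = 1)
sam <- samPermutationFdr(se, seed = 1)     # enumerates all 70 arrangements
sam <- callSignificant(sam, target_fdr = 0.10)
sam
#> SamResult: 1000 genes, s0 = 0.7375
#>   delta table: 60 thresholds, 70 permutations (full enumeration)
#>   called: 55 genes at delta = 0.2489 (target FDR 0.1 )
```

55 genes pass the 10% FDR (all 50 planted genes plus 5 false calls);
`extractSignature(sam, k = 80)` returns them ranked by fold change.

Validate a 20-gene signature in a synthetic cohort of 300 patients whose
planted risk score carries an aggregate log hazard ratio of 1:

```r
genes  <- sprintf("g%05d", 1:20)
truth  <- cohortSimTruth(risk_genes = genes,
    per_gene_log_hr = rep(c(1, -1), 10) / sqrt(20))
cohort <- simulateSurvivalCohort(n_patients = 300, n_genes = 100,
    truth, seed = 2)
sig    <- GeneSignature(genes, fold_change = rep(c(4, 0.25), 10))

assign <- loocvAssign(cohort, matchSignatureToCohort(sig, cohort))
evaluateStratification(assign, cohort, gehan = TRUE)
#> Stratification: 58 high / 242 low risk
#> log-rank: chi2 = 109.9, p = 1.035e-25
#> Gehan-Breslow-Wilcoxon: p = 1.05e-22
#> hazard ratio (high vs low): 5.46 (95% CI 3.84-7.76), p = 2.79e-21
```

The cross-validated risk index puts 58 patients in the high-risk tail,
whose hazard of recurrence is ~5.5-fold that of the low-risk group. The
random-signature control shows the association is specific to the
planted genes, not an artifact of the method:

```r
nd  <- nullDistribution(cohort, size = 20, M = 200, seed = 2,
    method = "fast")
# observed p computed by the same fast route, then ranked in the null
empiricalSpecificity(obs_p, nd)
#> $rank          1
#> $tail_fraction 0.00498      # (r+1)/(M+1), best of 200 nulls
#> $best5_cutoff  3.37e-13
#> $beats_cutoff  TRUE
```

Per-patient R values quantify how much each tumor's expression looks
like the signature pattern, grouped by intrinsic subtype:

```r
rv <- rvalueBySubtype(cohort, sig, assign$group)
head(rv, 3)
#>   patient_id          r          p subtype n_genes_used
#> 1      p0001  0.4103375 0.07233132   basal           20
#> 2      p0002 -0.2983558 0.20135018  normal           20
#> 3      p0003  0.2449529 0.29792580    lumA           20
attr(rv, "r_crit")   # the P < 0.05 line for 20 genes
#> [1] 0.4437634
```

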