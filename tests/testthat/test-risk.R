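test_that("the risk index is the coefficient-weighted sum of expression", {
    expect_equal(riskIndex(c(g1 = 2.5), c(g1 = 1)), 2.5)
    expect_equal(riskIndex(c(g1 = 2, g2 = 1), c(g1 = 0.5, g2 = -1)), 0)
    # brute-force summation oracle
    set.seed(12)
    b <- rnorm(50)
    x <- rnorm(50)
    names(b) <- names(x) <- paste0("g", 1:50)
    acc <- 0
    for (g in names(x)) acc <- acc + b[[g]] * x[[g]]
    expect_equal(riskIndex(x, b), acc, tolerance = 1e-12)
    # name alignment is honored, misalignment is an error
    expect_equal(riskIndex(x, b[sample(names(b))]), acc, tolerance = 1e-12)
    expect_error(riskIndex(c(g1 = 1), c(g2 = 1)), "misaligned")
    expect_error(riskIndex(c(1, 2), 1), "misaligned")
})

test_that("leave-one-out assignment equals the naive-loop oracle", {
    pc <- plantedCohort(n = 25, seed = 13)
    co <- pc$cohort[, 1:25]
    sig <- pc$signature[1:3]
    a <- suppressMessages(loocvAssign(co, sig))
    b <- naiveLoocv(co, sig)
    expect_identical(as.character(a$group), b$group)
    expect_equal(a$risk_index, b$risk_index, tolerance = 1e-6)
    expect_equal(a$training_cutoff, b$training_cutoff, tolerance = 1e-6)
    # one assignment per patient, deterministic
    expect_equal(nrow(a), 25)
    expect_identical(a, suppressMessages(loocvAssign(co, sig)))
    # the documented strict top-20th-percentile rule
    expect_identical(as.character(a$group),
        ifelse(a$risk_index > a$training_cutoff, "high", "low"))
})

test_that("each fold is blind to its held-out patient", {
    pc <- plantedCohort(n = 30, seed = 14)
    co <- pc$cohort
    sig <- pc$signature[1:4]
    a <- suppressMessages(loocvAssign(co, sig))
    # perturb patient 7's expression: fold 7 trains without patient 7, so
    # its training cutoff cannot move; other folds retrain and do move
    co2 <- co
    SummarizedExperiment::assay(co2)[geneIds(sig), 7] <-
        SummarizedExperiment::assay(co2)[geneIds(sig), 7] + 5
    a2 <- suppressMessages(loocvAssign(co2, sig))
    expect_equal(a2$training_cutoff[7], a$training_cutoff[7],
        tolerance = 1e-12)
    expect_false(all(a2$training_cutoff[-7] == a$training_cutoff[-7]))
})

test_that("assignments are invariant to a global expression rescaling", {
    pc <- plantedCohort(n = 40, seed = 15)
    co <- pc$cohort
    sig <- pc$signature
    a <- suppressMessages(loocvAssign(co, sig))
    co2 <- co
    SummarizedExperiment::assay(co2) <-
        SummarizedExperiment::assay(co2) * 3
    a2 <- suppressMessages(loocvAssign(co2, sig))
    # beta rescales by 1/c, so risk indices, cutoffs and groups are fixed
    expect_identical(a2$group, a$group)
    expect_equal(a2$risk_index, a$risk_index, tolerance = 1e-6)
})

test_that("stratification evaluation is honest under the null and powered when planted", {
    # null: hazard ratio near 1 on average
    hrs <- vapply(1:15, function(i) {
        co <- nullCohort(n = 80, n_genes = 30, seed = 3000 + i)
        set.seed(i)
        sig <- sampleRandomSignature(rownames(co), 10)
        a <- suppressMessages(loocvAssign(co, sig))
        log(evaluateStratification(a, co)$hazard_ratio$hr)
    }, numeric(1))
    expect_lt(abs(mean(hrs)), 0.45)
    # planted signal: significant HR > 1 in >= 80% of replicates
    signif <- vapply(1:12, function(i) {
        pc <- plantedCohort(n = 300, seed = 100 + i)
        a <- suppressMessages(loocvAssign(pc$cohort, pc$signature))
        s <- evaluateStratification(a, pc$cohort)
        s$hazard_ratio$ci95[1] > 1
    }, logical(1))
    expect_gte(mean(signif), 0.8)
})

test_that("stratification reports are complete and guard degenerate groups", {
    pc <- plantedCohort(n = 60, seed = 16)
    a <- suppressMessages(loocvAssign(pc$cohort, pc$signature))
    s <- evaluateStratification(a, pc$cohort, gehan = TRUE)
    expect_s3_class(s$km_high, "KMCurve")
    expect_s3_class(s$logrank, "LogRankResult")
    expect_equal(s$n_high + s$n_low, 60)
    expect_false(is.null(s$gbw))
    expect_true(s$hazard_ratio$ci95[1] < s$hazard_ratio$hr &
        s$hazard_ratio$hr < s$hazard_ratio$ci95[2])
    a_bad <- a
    a_bad$group[] <- "low"
    expect_error(evaluateStratification(a_bad, pc$cohort), "degenerate")
    expect_error(evaluateStratification(a[-1, ], pc$cohort), "cover")
})

test_that("multivariate adjustment leaves an unconfounded HR and shrinks a confounded one", {
    genes <- sprintf("g%05d", 1:10)
    sig <- GeneSignature(genes, fold_change = rep(2, 10))
    # covariates independent of the risk score: adjustment is a no-op
    truth0 <- cohortSimTruth(risk_genes = genes, per_gene_log_hr = 0.35,
        covariate_mix = 0)
    co0 <- simulateSurvivalCohort(250, 60, truth0, seed = 41)
    a0 <- suppressMessages(loocvAssign(co0, sig))
    un0 <- evaluateStratification(a0, co0)$hazard_ratio$hr
    ad0 <- multivariateAdjustment(co0, a0)
    expect_equal(log(unname(ad0$hazard_ratios["high_risk"])), log(un0),
        tolerance = 0.15)
    # covariates driven by the same risk score: adjustment attenuates
    trut1 <- cohortSimTruth(risk_genes = genes, per_gene_log_hr = 0.35,
        covariate_mix = 0.9)
    co1 <- simulateSurvivalCohort(250, 60, trut1, seed = 31)
    a1 <- suppressMessages(loocvAssign(co1, sig))
    un1 <- evaluateStratification(a1, co1)$hazard_ratio$hr
    ad1 <- multivariateAdjustment(co1, a1)
    expect_lt(unname(ad1$hazard_ratios["high_risk"]), un1)
    # external score covariate and input validation
    ext <- stats::setNames(rnorm(250), colnames(co1))
    ad2 <- multivariateAdjustment(co1, a1, covariates = c("grade", "node"),
        external_score = ext)
    expect_true("external_score" %in% names(ad2$coefficients))
    expect_error(multivariateAdjustment(co1, a1, covariates = "bogus"),
        "among")
})

test_that("subtype exclusion reruns cleanly on the patient subset", {
    pc <- plantedCohort(n = 80, seed = 17)
    co <- pc$cohort
    keep <- subtypes(co) != "basal"
    sub <- co[, keep]
    a1 <- suppressMessages(loocvAssign(sub, pc$signature))
    a2 <- suppressMessages(loocvAssign(sub, pc$signature))
    expect_identical(a1, a2)
    expect_equal(nrow(a1), sum(keep))
    expect_s4_class(sub, "SurvivalCohort")
})
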