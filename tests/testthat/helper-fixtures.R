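# Fixtures shared across test files; everything is generated in code.

# planted-signature cohort: 20 risk genes whose aggregate score (sd 1 under
# iid N(0,1) expression) carries log HR 1
plantedCohort <- function(n = 300, seed = 1) {
    genes <- sprintf("g%05d", 1:20)
    truth <- cohortSimTruth(risk_genes = genes,
        per_gene_log_hr = 1 / sqrt(20))
    list(cohort = simulateSurvivalCohort(n, 100, truth, seed = seed),
        signature = GeneSignature(genes, fold_change = rep(2, 20)))
}

nullCohort <- function(n = 100, n_genes = 200, seed = 1) {
    simulateSurvivalCohort(n, n_genes, cohortSimTruth(), seed = seed)
}

# independent leave-one-out oracle: naive loop, one survival::coxph call
# per gene per fold
naiveLoocv <- function(cohort, signature, percentile = 0.8) {
    X <- t(SummarizedExperiment::assay(cohort)[geneIds(signature), ,
        drop = FALSE])
    tm <- survTime(cohort)
    ev <- survEvent(cohort)
    n <- nrow(X)
    out <- data.frame(patient_id = colnames(cohort),
        risk_index = NA_real_, group = NA_character_,
        training_cutoff = NA_real_, stringsAsFactors = FALSE)
    for (j in seq_len(n)) {
        beta <- vapply(seq_len(ncol(X)), function(g) {
            f <- tryCatch(survival::coxph(
                survival::Surv(tm[-j], ev[-j]) ~ X[-j, g]),
                warning = function(w) NULL, error = function(e) NULL)
            if (is.null(f) || !is.finite(coef(f)) || abs(coef(f)) > 10) 0
            else unname(coef(f))
        }, numeric(1))
        ri_tr <- X[-j, , drop = FALSE] %*% beta
        out$training_cutoff[j] <- quantile(ri_tr, percentile, names = FALSE)
        out$risk_index[j] <- sum(X[j, ] * beta)
        out$group[j] <- if (out$risk_index[j] > out$training_cutoff[j])
            "high" else "low"
    }
    out
}
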