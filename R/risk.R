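NULL

#' Linear Cox risk index
#'
#' The per-patient risk index is the linear combination of expression
#' values weighted by univariate Cox coefficients: RI = sum(beta_g * x_g).
#'
#' @param expression_vector per-gene expression values, named by gene.
#' @param coefficients per-gene coefficients, named by gene; the gene sets
#'   must match exactly (order-insensitive when both are named).
#' @return The scalar risk index.
#' @examples
#' riskIndex(c(g1 = 2, g2 = 1), c(g1 = 0.5, g2 = -1))  # 0
#' @export
riskIndex <- function(expression_vector, coefficients) {
    if (length(expression_vector) != length(coefficients))
        stop("expression and coefficient gene sets are misaligned")
    if (!is.null(names(expression_vector)) && !is.null(names(coefficients))) {
        if (!setequal(names(expression_vector), names(coefficients)))
            stop("expression and coefficient gene sets are misaligned")
        coefficients <- coefficients[names(expression_vector)]
    }
    sum(expression_vector * coefficients)
}

#' Leave-one-out cross-validated risk classification
#'
#' The Minn-style training-testing construction: for each patient, every
#' signature gene is fit in a univariate Cox model on the remaining n - 1
#' patients; the held-out patient's risk index is the linear combination
#' of its expression weighted by those coefficients, and it is assigned to
#' the high-risk group when its index exceeds the 80th percentile (by
#' default) of the training patients' risk indices, computed with the same
#' coefficients. Repeating over all patients yields one assignment each,
#' none of which used its own data for training.
#'
#' Univariate fits that do not converge in a fold contribute a zero
#' coefficient for that fold (the gene is effectively excluded there).
#'
#' @param cohort a \linkS4class{SurvivalCohort}.
#' @param signature a \linkS4class{GeneSignature}, already matched to the
#'   cohort (see [matchSignatureToCohort()]).
#' @param percentile training quantile defining the high-risk tail
#'   (default 0.80: "top 20th percentile"); assignment is strictly above
#'   the cutoff.
#' @param ties "efron" or "breslow" tie handling for the univariate fits.
#' @param standardize per-fold z-scoring of each gene on the training
#'   patients (off by default; sensitivity analysis only).
#' @return A data.frame with one row per patient: `patient_id`,
#'   `risk_index`, `group` ("high"/"low"), `training_cutoff`, `fold_id`.
#' @export
loocvAssign <- function(cohort, signature, percentile = 0.80,
                        ties = "efron", standardize = FALSE) {
    if (percentile <= 0 || percentile >= 1)
        stop("percentile must be in (0, 1)")
    genes <- geneIds(signature)
    if (!all(genes %in% rownames(cohort)))
        stop("signature not matched to cohort; run matchSignatureToCohort")
    X <- t(assay(cohort)[genes, , drop = FALSE])
    time <- survTime(cohort)
    event <- survEvent(cohort)
    n <- nrow(X)
    # warm start from the full-data coefficients
    warm <- coxUnivariateBatch(X, time, event, ties = ties)$beta
    warm[!is.finite(warm)] <- 0
    ri <- numeric(n)
    grp <- character(n)
    cutoffs <- numeric(n)
    n_nonconv <- 0L
    for (j in seq_len(n)) {
        Xtr <- X[-j, , drop = FALSE]
        Xte <- X[j, ]
        if (standardize) {
            mu <- colMeans(Xtr)
            sdv <- apply(Xtr, 2, stats::sd)
            sdv[sdv == 0] <- 1
            Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
            Xte <- (Xte - mu) / sdv
        }
        fit <- coxUnivariateBatch(Xtr, time[-j], event[-j], init = warm,
            ties = ties)
        beta <- ifelse(fit$converged, fit$beta, 0)
        n_nonconv <- n_nonconv + sum(!fit$converged)
        ri_tr <- drop(Xtr %*% beta)
        cutoffs[j] <- stats::quantile(ri_tr, percentile, names = FALSE,
            type = 7)
        ri[j] <- sum(Xte * beta)
        grp[j] <- if (ri[j] > cutoffs[j]) "high" else "low"
    }
    if (n_nonconv > 0)
        message(n_nonconv, " non-convergent univariate fits set to beta = 0",
            " across folds")
    data.frame(patient_id = colnames(cohort), risk_index = ri,
        group = factor(grp, levels = c("low", "high")),
        training_cutoff = cutoffs, fold_id = seq_len(n),
        stringsAsFactors = FALSE)
}

#' Evaluate a high/low risk stratification
#'
#' Kaplan-Meier curves per group, the log-rank comparison, and the hazard
#' ratio of high vs low risk from a Cox fit on the group indicator with a
#' Wald 95% confidence interval. Optionally also the
#' Gehan-Breslow-Wilcoxon p-value, which emphasizes early separation of
#' the curves.
#'
#' @param assignments data.frame from [loocvAssign()] covering the cohort.
#' @param cohort the \linkS4class{SurvivalCohort} the assignments refer to.
#' @param gehan also compute the Gehan-Breslow-Wilcoxon test.
#' @return A list of class `StratificationReport`: `km_high`, `km_low`
#'   (KMCurve), `logrank` (LogRankResult), optionally `gbw`,
#'   `hazard_ratio` (list hr/ci95/p from Cox on the indicator), `cox_fit`,
#'   `n_high`, `n_low`.
#' @export
evaluateStratification <- function(assignments, cohort, gehan = FALSE) {
    idx <- match(colnames(cohort), assignments$patient_id)
    if (anyNA(idx)) stop("assignments do not cover the cohort")
    grp <- assignments$group[idx]
    if (any(table(grp) == 0))
        stop("degenerate stratification: a group is empty")
    time <- survTime(cohort)
    event <- survEvent(cohort)
    lr <- weightedLogrank(grp, time, event, "logrank")
    ind <- as.integer(grp == "high")
    cf <- coxFit(data.frame(high_risk = ind), time, event)
    res <- list(
        km_high = kmEstimate(time[grp == "high"], event[grp == "high"]),
        km_low = kmEstimate(time[grp == "low"], event[grp == "low"]),
        logrank = lr,
        gbw = if (gehan) weightedLogrank(grp, time, event,
            "gehan-breslow-wilcoxon") else NULL,
        hazard_ratio = list(hr = unname(cf$hazard_ratios["high_risk"]),
            ci95 = unname(cf$ci95["high_risk", ]),
            p = unname(cf$wald_p["high_risk"])),
        cox_fit = cf,
        n_high = sum(grp == "high"), n_low = sum(grp == "low"))
    class(res) <- "StratificationReport"
    res
}

#' @export
print.StratificationReport <- function(x, ...) {
    cat(sprintf("Stratification: %d high / %d low risk\n", x$n_high, x$n_low))
    cat(sprintf("log-rank: chi2 = %.4g, p = %.4g\n", x$logrank$chi2,
        x$logrank$p))
    if (!is.null(x$gbw))
        cat(sprintf("Gehan-Breslow-Wilcoxon: p = %.4g\n", x$gbw$p))
    cat(sprintf("hazard ratio (high vs low): %.3g (95%% CI %.3g-%.3g), p = %.3g\n",
        x$hazard_ratio$hr, x$hazard_ratio$ci95[1], x$hazard_ratio$ci95[2],
        x$hazard_ratio$p))
    invisible(x)
}

#' Multivariate Cox adjustment of the risk classification
#'
#' Fits a multivariate Cox model with the high/low indicator alongside the
#' requested clinical covariates (grade coded ordinal-linear, node and ER
#' binary, size continuous in cm, external per-patient scores continuous),
#' to ask whether the signature remains an independent predictor.
#'
#' @param cohort a \linkS4class{SurvivalCohort} carrying the requested
#'   clinical columns.
#' @param assignments data.frame from [loocvAssign()].
#' @param covariates character vector among
#'   `c("grade", "node", "size", "er")`.
#' @param external_score optional named numeric vector (per patient) of an
#'   external signature score, entered as covariate `external_score`.
#' @return A `CoxFit` (see [coxFit()]); constant covariates are dropped
#'   with a warning.
#' @export
multivariateAdjustment <- function(cohort, assignments,
                                   covariates = c("grade", "node", "size",
                                       "er"),
                                   external_score = NULL) {
    idx <- match(colnames(cohort), assignments$patient_id)
    if (anyNA(idx)) stop("assignments do not cover the cohort")
    allowed <- c("grade", "node", "size", "er")
    if (!all(covariates %in% allowed))
        stop("covariates must be among: ", paste(allowed, collapse = ", "))
    df <- data.frame(high_risk = as.integer(assignments$group[idx] == "high"))
    cd <- colData(cohort)
    for (cv in covariates) {
        if (!cv %in% colnames(cd))
            stop("cohort lacks clinical column: ", cv)
        df[[cv]] <- as.numeric(cd[[cv]])
    }
    if (!is.null(external_score)) {
        if (!is.null(names(external_score)))
            external_score <- external_score[colnames(cohort)]
        df$external_score <- as.numeric(external_score)
    }
    coxFit(df, survTime(cohort), survEvent(cohort))
}
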