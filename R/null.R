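NULL

#' Draw a random gene signature
#'
#' Samples `size` genes uniformly without replacement from the given
#' universe, using the current RNG state. Directions are nominally +1:
#' the risk-index pipeline estimates effect signs from the cohort via Cox
#' coefficients, so the stored direction is irrelevant to outcome testing.
#'
#' @param universe character vector of candidate gene ids.
#' @param size signature size (<= length(universe)).
#' @return A \linkS4class{GeneSignature}.
#' @examples
#' set.seed(1)
#' sampleRandomSignature(paste0("g", 1:100), 5)
#' @export
sampleRandomSignature <- function(universe, size) {
    if (size > length(universe))
        stop("size exceeds the gene universe")
    GeneSignature(sample(universe, size),
        fold_change = rep(2, size))
}

# single-split approximation: univariate coefficients fit once on the full
# cohort, risk index for everyone, cutoff on the full risk-index vector.
# Faster than LOOCV but optimistically biased (documented); for null
# calibration use method = "loocv".
.fastStratifyP <- function(cohort, signature, percentile, ties = "efron") {
    X <- t(assay(cohort)[geneIds(signature), , drop = FALSE])
    time <- survTime(cohort)
    event <- survEvent(cohort)
    fit <- coxUnivariateBatch(X, time, event, ties = ties)
    beta <- ifelse(fit$converged, fit$beta, 0)
    ri <- drop(X %*% beta)
    cutoff <- stats::quantile(ri, percentile, names = FALSE, type = 7)
    grp <- ifelse(ri > cutoff, "high", "low")
    if (length(unique(grp)) < 2) return(1)
    weightedLogrank(grp, time, event, "logrank")$p
}

#' Random-signature null distribution of outcome association
#'
#' Empirical specificity control: draws `M` random signatures of the
#' observed signature's size from the cohort's measured gene universe and
#' records, for each, the log-rank p-value of the high/low stratification
#' produced by the same risk-index method as the observed signature
#' (conventionally M = 1000 signatures of the matched size).
#'
#' `method = "loocv"` runs the full leave-one-out pipeline per signature;
#' `method = "fast"` fits the univariate coefficients once on the full
#' cohort and stratifies at the same percentile - an optimistically biased
#' approximation (its null p-values are anti-conservative) that is orders
#' of magnitude faster and suitable for ranking an observed signature
#' against nulls computed by the same fast route.
#'
#' @param cohort a \linkS4class{SurvivalCohort}.
#' @param size genes per random signature.
#' @param M number of random signatures (default 1000).
#' @param percentile high-risk cutoff quantile (default 0.80).
#' @param seed integer RNG seed for the whole M-signature run.
#' @param method "loocv" or "fast".
#' @param exclude gene ids excluded from the sampling universe (e.g. the
#'   observed signature's genes); default none.
#' @return A \linkS4class{NullDistribution}.
#' @export
nullDistribution <- function(cohort, size, M = 1000, percentile = 0.80,
                             seed = 1, method = c("loocv", "fast"),
                             exclude = NULL) {
    method <- match.arg(method)
    universe <- setdiff(rownames(cohort), exclude)
    if (size > length(universe)) stop("size exceeds the gene universe")
    set.seed(seed)
    p <- vapply(seq_len(M), function(m) {
        sig <- sampleRandomSignature(universe, size)
        if (method == "fast")
            .fastStratifyP(cohort, sig, percentile)
        else {
            a <- suppressMessages(loocvAssign(cohort, sig,
                percentile = percentile))
            if (length(unique(a$group)) < 2) 1
            else weightedLogrank(a$group, survTime(cohort),
                survEvent(cohort), "logrank")$p
        }
    }, numeric(1))
    new("NullDistribution", p_values = p, signature_size = as.integer(size),
        M = as.integer(M), universe_size = length(universe),
        method = method, seed = as.integer(seed))
}

#' Empirical specificity of an observed signature p-value
#'
#' Places the observed stratification p-value within the random-signature
#' null: its rank, the empirical tail fraction with the add-one
#' (r + 1)/(M + 1) convention (so it is never exactly zero), the best-5%
#' null cutoff (5th percentile of the null p-values), and whether the
#' observed p-value beats that cutoff.
#'
#' @param observed_p the observed signature's log-rank p-value.
#' @param null a \linkS4class{NullDistribution}.
#' @return A list: `rank`, `tail_fraction`, `best5_cutoff`,
#'   `beats_cutoff`.
#' @export
empiricalSpecificity <- function(observed_p, null) {
    p <- pValues(null)
    if (!length(p)) stop("empty null distribution")
    list(
        rank = sum(p < observed_p) + 1L,
        tail_fraction = (sum(p <= observed_p) + 1) / (length(p) + 1),
        best5_cutoff = stats::quantile(p, 0.05, names = FALSE, type = 7),
        beats_cutoff = observed_p <
            stats::quantile(p, 0.05, names = FALSE, type = 7)
    )
}
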