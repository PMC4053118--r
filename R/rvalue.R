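#' @importFrom stats cor pt qt
NULL

#' Centroid-mean centering of an expression matrix
#'
#' Per gene, subtracts the mean of the two comparison-group means (the
#' centroid mean) from every sample, so that after centering the two group
#' means are negatives of each other.
#'
#' @param x gene x sample matrix or `SummarizedExperiment`.
#' @param group_labels two-level factor over samples.
#' @return A matrix of the same shape, centered per gene.
#' @examples
#' m <- rbind(g1 = c(1, 3, 3, 5))
#' centroidCenter(m, factor(c("a", "a", "b", "b")))  # centroid mean 3
#' @export
centroidCenter <- function(x, group_labels) {
    m <- if (is.matrix(x)) x else assay(x)
    g <- droplevels(as.factor(group_labels))
    if (nlevels(g) != 2 || any(table(g) == 0))
        stop("two non-empty comparison groups are required")
    m1 <- rowMeans(m[, g == levels(g)[1], drop = FALSE])
    m2 <- rowMeans(m[, g == levels(g)[2], drop = FALSE])
    m - (m1 + m2) / 2
}

#' Signature-correlation R value for one patient
#'
#' The Creighton-style R value: the Pearson correlation between the
#' signature's +1/-1 direction pattern and the patient's (centered)
#' expression over the signature genes. Patients whose tumors have high
#' expression of the up-regulated genes and low expression of the
#' down-regulated genes score high. Significance uses the t transform
#' with n_genes - 2 degrees of freedom.
#'
#' @param patient_vector per-gene expression values named by gene,
#'   restricted to (or a superset of) the signature genes; at least 3
#'   signature genes must be present.
#' @param signature a \linkS4class{GeneSignature}.
#' @return A list: `r`, `p`, `n_genes_used`, `defined` (FALSE when the
#'   patient vector has zero variance over the signature genes, in which
#'   case `r` is `NA`).
#' @examples
#' sig <- GeneSignature(c("a", "b", "c", "d"), fold_change = c(2, 2, .5, .5))
#' rValue(c(a = 1, b = 1, c = -1, d = -1), sig)$r  # exactly 1
#' @export
rValue <- function(patient_vector, signature) {
    genes <- geneIds(signature)
    if (!is.null(names(patient_vector)))
        patient_vector <- patient_vector[genes]
    if (length(patient_vector) != length(genes) || anyNA(patient_vector))
        stop("patient vector does not cover the signature genes")
    if (length(genes) < 3) stop("at least 3 signature genes are required")
    pattern <- directions(signature)
    if (stats::sd(patient_vector) == 0 || stats::sd(pattern) == 0)
        return(list(r = NA_real_, p = NA_real_,
            n_genes_used = length(genes), defined = FALSE))
    r <- cor(pattern, patient_vector)
    df <- length(genes) - 2
    tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    list(r = r, p = 2 * pt(-abs(tval), df), n_genes_used = length(genes),
        defined = TRUE)
}

#' R values per patient, grouped by intrinsic subtype
#'
#' Centers the cohort's expression (restricted to the signature genes) on
#' the centroid mean of the two comparison groups, computes the R value
#' for every patient, and reports them with subtype labels. The default
#' comparison groups are the high/low risk groups of the cross-validated
#' classifier. The attribute `r_crit` is the |r| threshold for two-sided
#' P < 0.05 at n_genes - 2 degrees of freedom (the "dotted line").
#'
#' @param cohort a \linkS4class{SurvivalCohort} with subtype labels
#'   (patients with missing subtype are grouped as "unknown").
#' @param signature a \linkS4class{GeneSignature} (matched to the cohort
#'   automatically).
#' @param comparison_groups two-level factor over patients for the
#'   centroid centering, e.g. `assignments$group` from [loocvAssign()].
#' @return A data.frame: `patient_id`, `r`, `p`, `subtype`,
#'   `n_genes_used`, with attribute `r_crit`.
#' @export
rvalueBySubtype <- function(cohort, signature, comparison_groups) {
    sig <- suppressMessages(matchSignatureToCohort(signature, cohort))
    m <- assay(cohort)[geneIds(sig), , drop = FALSE]
    centered <- centroidCenter(m, comparison_groups)
    res <- lapply(seq_len(ncol(centered)), function(j) {
        v <- centered[, j]
        names(v) <- rownames(centered)
        rValue(v, sig)
    })
    st <- subtypes(cohort)
    st[is.na(st)] <- "unknown"
    df <- length(sig) - 2
    r_crit <- qt(0.975, df) / sqrt(df + qt(0.975, df)^2)
    out <- data.frame(
        patient_id = colnames(cohort),
        r = vapply(res, `[[`, numeric(1), "r"),
        p = vapply(res, `[[`, numeric(1), "p"),
        subtype = st,
        n_genes_used = length(sig),
        stringsAsFactors = FALSE)
    attr(out, "r_crit") <- r_crit
    out
}
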