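#' @importFrom stats lowess approx var mad
NULL

#' Global LOWESS normalization of two-channel intensities
#'
#' Per array, forms M = log2(R/G) and A = (1/2) log2(R*G) and subtracts a
#' locally weighted linear fit of M on A from M, removing global
#' intensity-dependent dye bias. Probes with a non-positive intensity in
#' either channel on any array are dropped (with a message), not errored.
#'
#' @param red_intensity,green_intensity positive probe x array matrices of
#'   channel intensities, identical dimensions.
#' @param smoother_span LOWESS span as a fraction of the data (default
#'   0.3); the smoother is local linear with 3 robustness iterations.
#' @return A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment]
#'   with assay `log2ratio` holding the normalized M values.
#' @examples
#' G <- matrix(2^rnorm(200, 10), 100, 2,
#'     dimnames = list(paste0("pr", 1:100), c("a1", "a2")))
#' R <- G * 2          # constant dye gain
#' se <- lowessNormalize(R, G)
#' max(abs(SummarizedExperiment::assay(se)))  # ~0: gain absorbed
#' @export
lowessNormalize <- function(red_intensity, green_intensity,
                            smoother_span = 0.3) {
    R <- as.matrix(red_intensity)
    G <- as.matrix(green_intensity)
    if (!all(dim(R) == dim(G)))
        stop("red and green intensity matrices must have the same shape")
    bad <- rowSums(!is.finite(R) | R <= 0 | !is.finite(G) | G <= 0) > 0
    if (any(bad)) {
        message(sum(bad), " probes with non-positive intensities filtered")
        R <- R[!bad, , drop = FALSE]
        G <- G[!bad, , drop = FALSE]
    }
    if (nrow(R) == 0) stop("no probes left after intensity filtering")
    M <- log2(R / G)
    A <- 0.5 * log2(R * G)
    for (j in seq_len(ncol(M))) {
        fit <- lowess(A[, j], M[, j], f = smoother_span, iter = 3)
        M[, j] <- M[, j] - approx(fit$x, fit$y, xout = A[, j], rule = 2,
            ties = mean)$y
    }
    SummarizedExperiment(assays = list(log2ratio = M))
}

#' Filter probes and collapse to one row per gene
#'
#' Drops probes without a gene mapping, filters probes with more than
#' `max_missing` missing values, imputes remaining missing entries with the
#' probe median, and for genes measured by several probes retains the probe
#' with the greatest across-sample variation. Variance ties are broken by
#' the lexicographically smallest probe id.
#'
#' @param x a `SummarizedExperiment` (or matrix) whose rownames are probe
#'   ids.
#' @param probe_to_gene data.frame with columns `probe_id` and `gene_id`
#'   (extra columns ignored), or a named character vector
#'   (names = probe ids).
#' @param measure "var" (sample variance, default) or "mad" as the
#'   variation measure.
#' @param max_missing maximum tolerated fraction of missing values per
#'   probe (default 0.2).
#' @return A `SummarizedExperiment` keyed by gene ids, with the retained
#'   probe id per gene in `rowData(x)$probe_id`. Any `colData` of the
#'   input is preserved.
#' @examples
#' m <- matrix(rnorm(12), 3, 4, dimnames = list(c("p1", "p2", "p3"), NULL))
#' map <- data.frame(probe_id = c("p1", "p2", "p3"),
#'     gene_id = c("IL8", "IL8", "SMAD2"))
#' filterAndCollapse(m, map)
#' @export
filterAndCollapse <- function(x, probe_to_gene, measure = c("var", "mad"),
                              max_missing = 0.2) {
    measure <- match.arg(measure)
    if (is.matrix(x)) x <- SummarizedExperiment(assays = list(log2ratio = x))
    m <- assay(x)
    if (is.null(rownames(m))) stop("probe ids (rownames) are required")
    if (is.data.frame(probe_to_gene)) {
        if (!all(c("probe_id", "gene_id") %in% colnames(probe_to_gene)))
            stop("probe_to_gene needs columns 'probe_id' and 'gene_id'")
        map <- stats::setNames(as.character(probe_to_gene$gene_id),
            as.character(probe_to_gene$probe_id))
    } else {
        map <- probe_to_gene
    }
    map <- map[!is.na(map) & nzchar(map)]
    if (length(map) == 0) stop("empty probe-to-gene mapping")
    keep <- rownames(m) %in% names(map)
    if (any(!keep))
        message(sum(!keep), " unmapped probes dropped")
    m <- m[keep, , drop = FALSE]
    if (nrow(m) == 0) stop("no probes map to a gene")
    # missing-value filter, then probe-median imputation
    miss <- rowMeans(is.na(m))
    if (any(miss > max_missing)) {
        message(sum(miss > max_missing), " probes with > ",
            round(100 * max_missing), "% missing values filtered")
        m <- m[miss <= max_missing, , drop = FALSE]
    }
    if (anyNA(m)) {
        med <- apply(m, 1, stats::median, na.rm = TRUE)
        idx <- which(is.na(m), arr.ind = TRUE)
        m[idx] <- med[idx[, 1]]
    }
    gene <- map[rownames(m)]
    score <- if (measure == "var") apply(m, 1, var) else apply(m, 1, mad)
    # per gene: greatest variation wins, ties to smallest probe id
    ord <- order(gene, -score, rownames(m))
    pick <- ord[!duplicated(gene[ord])]
    pick <- pick[order(match(gene[pick], unique(gene)))]
    out <- m[pick, , drop = FALSE]
    probe_ids <- rownames(out)
    rownames(out) <- gene[pick]
    se <- SummarizedExperiment(assays = list(log2ratio = out),
        colData = colData(x))
    rowData(se)$probe_id <- probe_ids
    se
}

#' Restrict a signature to the genes measured in a cohort
#'
#' Published cohort arrays rarely carry every signature gene: an 80-gene
#' signature typically loses a handful of genes per platform. This
#' returns the sub-signature measured in the cohort, with a message for
#' the dropped count, and errors when the overlap is empty (the signature
#' cannot be evaluated at all).
#'
#' @param signature a \linkS4class{GeneSignature}.
#' @param cohort a \linkS4class{SurvivalCohort} (or any object with gene
#'   rownames).
#' @return The matched \linkS4class{GeneSignature}.
#' @examples
#' sig <- GeneSignature(c("g1", "g2", "g3"), fold_change = c(4, 2, 0.5))
#' expr <- matrix(rnorm(20), 2, 10, dimnames = list(c("g1", "g3"), NULL))
#' co <- SurvivalCohort(expr, time = 1:10, event = rep(1, 10))
#' length(matchSignatureToCohort(sig, co))  # 2
#' @export
matchSignatureToCohort <- function(signature, cohort) {
    genes <- rownames(cohort)
    present <- geneIds(signature) %in% genes
    if (!any(present))
        stop("no signature gene is measured in the cohort")
    if (any(!present))
        message(sum(!present), " of ", length(signature),
            " signature genes absent from the cohort; ",
            sum(present), " retained")
    signature[present]
}

#' @importFrom SummarizedExperiment rowData<-
NULL
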