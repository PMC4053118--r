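#' @include AllGenerics.R
#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   colData<- rowData rowData<-
NULL

# ---------------------------------------------------------------------------
# GeneSignature
# ---------------------------------------------------------------------------

#' GeneSignature: a directed gene list with fold changes
#'
#' A gene signature is an ordered set of genes, each with a regulation
#' direction (+1 = up in the class of interest, -1 = down) and a
#' linear-scale fold change. The invasion signature derived by
#' [extractSignature()] and the random signatures drawn by
#' [sampleRandomSignature()] are both of this class.
#'
#' @slot gene_id unique gene identifiers.
#' @slot direction +1/-1 per gene; +1 exactly when `fold_change >= 1`.
#' @slot fold_change positive linear-scale fold change (2^ mean log2
#'   difference between the two classes).
#' @slot rank integer rank, 1 = largest absolute log2 fold.
#'
#' @seealso [extractSignature()], [matchSignatureToCohort()],
#'   [readSignatureTsv()]
#' @export
setClass("GeneSignature",
    slots = c(
        gene_id = "character",
        direction = "numeric",
        fold_change = "numeric",
        rank = "integer"
    )
)

setValidity("GeneSignature", function(object) {
    n <- length(object@gene_id)
    msg <- character()
    if (length(object@direction) != n || length(object@fold_change) != n ||
        length(object@rank) != n)
        msg <- c(msg, "slot lengths differ")
    if (anyDuplicated(object@gene_id))
        msg <- c(msg, "gene_id values must be unique")
    if (n > 0 && !all(object@direction %in% c(-1, 1)))
        msg <- c(msg, "direction must be +1 or -1")
    if (n > 0 && !all(object@fold_change > 0))
        msg <- c(msg, "fold_change must be positive")
    if (n > 0 &&
        !all(object@direction == ifelse(object@fold_change >= 1, 1, -1)))
        msg <- c(msg, "direction must be +1 iff fold_change >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneSignature
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param direction +1/-1 per gene; defaults to the sign implied by
#'   `fold_change`.
#' @param fold_change positive linear-scale fold changes.
#' @param rank integer ranks; defaults to the order given.
#' @return A \linkS4class{GeneSignature}.
#' @examples
#' GeneSignature(c("IL8", "SMAD2"), fold_change = c(4, 0.5))
#' @export
GeneSignature <- function(gene_id, direction = NULL, fold_change, rank = NULL) {
    gene_id <- as.character(gene_id)
    fold_change <- as.numeric(fold_change)
    if (is.null(direction)) direction <- ifelse(fold_change >= 1, 1, -1)
    if (is.null(rank)) rank <- seq_along(gene_id)
    new("GeneSignature", gene_id = gene_id, direction = as.numeric(direction),
        fold_change = fold_change, rank = as.integer(rank))
}

#' @rdname geneIds
#' @export
setMethod("geneIds", "GeneSignature", function(x) x@gene_id)

#' @rdname directions
#' @export
setMethod("directions", "GeneSignature", function(x)
    stats::setNames(x@direction, x@gene_id))

#' @rdname foldChanges
#' @export
setMethod("foldChanges", "GeneSignature", function(x)
    stats::setNames(x@fold_change, x@gene_id))

#' @describeIn GeneSignature number of genes in the signature.
#' @param x a `GeneSignature`.
#' @export
setMethod("length", "GeneSignature", function(x) length(x@gene_id))

#' @describeIn GeneSignature subset by index, logical, or gene identifier.
#' @param i subscript.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "GeneSignature", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@gene_id)
    new("GeneSignature", gene_id = x@gene_id[i], direction = x@direction[i],
        fold_change = x@fold_change[i], rank = x@rank[i])
})

#' @describeIn GeneSignature coerce to a data.frame with columns
#'   gene_id, direction, fold_change, rank.
#' @export
setMethod("as.data.frame", "GeneSignature", function(x, ...) {
    data.frame(gene_id = x@gene_id, direction = x@direction,
        fold_change = x@fold_change, rank = x@rank,
        stringsAsFactors = FALSE)
})

setMethod("show", "GeneSignature", function(object) {
    n <- length(object)
    cat("GeneSignature with", n, "genes (",
        sum(object@direction > 0), "up /", sum(object@direction < 0),
        "down )\n")
    if (n) {
        head_n <- min(5L, n)
        df <- as.data.frame(object)[seq_len(head_n), ]
        print(df, row.names = FALSE)
        if (n > head_n) cat("...", n - head_n, "more\n")
    }
})

# ---------------------------------------------------------------------------
# SurvivalCohort
# ---------------------------------------------------------------------------

#' SurvivalCohort: expression plus clinical follow-up
#'
#' A \linkS4class{SummarizedExperiment} whose columns are patients. The
#' `colData` carries the clinical table: `time` (months), `event`
#' (0/1; 1 = metastasis or recurrence), and optionally `grade` (1/2/3),
#' `node` (0/1), `size` (cm), `er` (0/1) and `subtype`
#' (basal / luminal A / luminal B / HER2 / normal-like).
#'
#' @seealso [SurvivalCohort()], [simulateSurvivalCohort()], [readCohort()]
#' @export
setClass("SurvivalCohort", contains = "SummarizedExperiment")

setValidity("SurvivalCohort", function(object) {
    cd <- colData(object)
    msg <- character()
    if (!all(c("time", "event") %in% colnames(cd)))
        return("colData must contain 'time' and 'event'")
    if (!is.numeric(cd$time) || any(!is.finite(cd$time)) || any(cd$time <= 0))
        msg <- c(msg, "time must be finite and > 0")
    if (!all(cd$event %in% c(0, 1)))
        msg <- c(msg, "event must be 0 or 1")
    if (length(SummarizedExperiment::assays(object)) < 1)
        msg <- c(msg, "an expression assay is required")
    if (length(msg)) msg else TRUE
})

#' Construct a SurvivalCohort
#'
#' @param expression gene x patient numeric matrix (rownames = gene ids,
#'   colnames = patient ids).
#' @param time follow-up in months, > 0.
#' @param event 0/1 event indicator (1 = metastasis/recurrence).
#' @param grade,node,size,er,subtype optional clinical covariates (ordinal
#'   1-3, 0/1, cm, 0/1, character).
#' @return A \linkS4class{SurvivalCohort}.
#' @examples
#' expr <- matrix(rnorm(20), 4, 5,
#'     dimnames = list(paste0("g", 1:4), paste0("p", 1:5)))
#' SurvivalCohort(expr, time = c(12, 30, 45, 60, 80),
#'     event = c(1, 0, 1, 0, 0))
#' @export
SurvivalCohort <- function(expression, time, event, grade = NULL, node = NULL,
                           size = NULL, er = NULL, subtype = NULL) {
    expression <- as.matrix(expression)
    if (is.null(colnames(expression)))
        colnames(expression) <- paste0("p", seq_len(ncol(expression)))
    cd <- DataFrame(time = as.numeric(time), event = as.integer(event),
        row.names = colnames(expression))
    for (nm in c("grade", "node", "size", "er", "subtype")) {
        v <- get(nm)
        if (!is.null(v)) cd[[nm]] <- v
    }
    se <- SummarizedExperiment(assays = list(exprs = expression), colData = cd)
    new("SurvivalCohort", se)
}

#' @rdname survTime
#' @export
setMethod("survTime", "SurvivalCohort", function(x) colData(x)$time)

#' @rdname survTime
#' @export
setMethod("survEvent", "SurvivalCohort", function(x) colData(x)$event)

#' @rdname survTime
#' @export
setMethod("subtypes", "SurvivalCohort", function(x) {
    st <- colData(x)$subtype
    if (is.null(st)) rep(NA_character_, ncol(x)) else as.character(st)
})

setMethod("show", "SurvivalCohort", function(object) {
    callNextMethod()
    ev <- survEvent(object)
    cat("events:", sum(ev), "of", length(ev),
        "| median follow-up:", round(stats::median(survTime(object)), 1),
        "months\n")
})

# ---------------------------------------------------------------------------
# SamResult
# ---------------------------------------------------------------------------

#' SamResult: per-gene SAM statistics and the permutation FDR table
#'
#' Holds the two-class SAM statistic d = (mean1 - mean2) / (s + s0) per
#' gene, the pooled standard errors s, the exchangeability constant s0,
#' linear fold changes, and - after [samPermutationFdr()] - the delta table
#' of (delta, genes called, median permutation false calls, estimated FDR).
#' [callSignificant()] fills `called` and `chosen_delta`.
#'
#' @slot gene_id gene identifiers.
#' @slot d per-gene SAM statistic.
#' @slot s per-gene pooled standard error.
#' @slot fold_change linear-scale fold change 2^(mean1 - mean2).
#' @slot s0 exchangeability constant added to every s.
#' @slot delta_table data.frame with columns delta, n_called,
#'   median_false, fdr (running-minimum monotonized).
#' @slot expected_order permutation means of the order statistics of d.
#' @slot called logical significance flags at `chosen_delta`.
#' @slot chosen_delta the smallest tabulated delta meeting `target_fdr`.
#' @slot target_fdr the FDR level used by [callSignificant()].
#' @slot n_permutations number of label permutations used.
#' @slot enumerated TRUE when all distinct label arrangements were used.
#' @slot seed RNG seed of the permutation draw.
#' @export
setClass("SamResult",
    slots = c(
        gene_id = "character",
        d = "numeric",
        s = "numeric",
        fold_change = "numeric",
        s0 = "numeric",
        delta_table = "data.frame",
        expected_order = "numeric",
        called = "logical",
        chosen_delta = "numeric",
        target_fdr = "numeric",
        n_permutations = "integer",
        enumerated = "logical",
        seed = "integer"
    ),
    prototype = list(
        delta_table = data.frame(),
        expected_order = numeric(0),
        called = logical(0),
        chosen_delta = NA_real_,
        target_fdr = NA_real_,
        n_permutations = 0L,
        enumerated = FALSE,
        seed = NA_integer_
    )
)

setValidity("SamResult", function(object) {
    n <- length(object@gene_id)
    msg <- character()
    if (length(object@d) != n || length(object@s) != n ||
        length(object@fold_change) != n)
        msg <- c(msg, "per-gene slot lengths differ")
    if (length(object@s0) == 1 && (is.na(object@s0) || object@s0 < 0))
        msg <- c(msg, "s0 must be >= 0")
    dt <- object@delta_table
    if (nrow(dt)) {
        if (!all(c("delta", "n_called", "median_false", "fdr") %in%
                colnames(dt)))
            msg <- c(msg, "delta_table columns incomplete")
        else {
            if (is.unsorted(rev(dt$fdr)) && any(diff(dt$fdr) > 1e-12))
                msg <- c(msg, "fdr must be non-increasing in delta")
            if (any(diff(dt$n_called) > 0))
                msg <- c(msg, "n_called must be non-increasing in delta")
        }
    }
    if (length(msg)) msg else TRUE
})

#' @rdname geneIds
#' @export
setMethod("geneIds", "SamResult", function(x) x@gene_id)

setMethod("show", "SamResult", function(object) {
    cat("SamResult:", length(object@gene_id), "genes, s0 =",
        signif(object@s0, 4), "\n")
    if (nrow(object@delta_table))
        cat("  delta table:", nrow(object@delta_table), "thresholds,",
            object@n_permutations, "permutations",
            if (object@enumerated) "(full enumeration)" else "", "\n")
    if (!is.na(object@chosen_delta))
        cat("  called:", sum(object@called), "genes at delta =",
            signif(object@chosen_delta, 4), "(target FDR",
            object@target_fdr, ")\n")
})

# ---------------------------------------------------------------------------
# NullDistribution
# ---------------------------------------------------------------------------

#' NullDistribution: random-signature outcome-association p-values
#'
#' The empirical null of [nullDistribution()]: for each of M random
#' signatures of the observed signature's size, the log-rank p-value of the
#' high/low stratification obtained by the same risk-index method.
#'
#' @slot p_values numeric vector of length M, each in [0, 1].
#' @slot signature_size genes per random signature.
#' @slot M number of random signatures.
#' @slot universe_size number of genes sampled from.
#' @slot method "loocv" (full pipeline) or "fast" (single full-data fit,
#'   a documented approximation).
#' @slot seed RNG seed.
#' @export
setClass("NullDistribution",
    slots = c(
        p_values = "numeric",
        signature_size = "integer",
        M = "integer",
        universe_size = "integer",
        method = "character",
        seed = "integer"
    )
)

setValidity("NullDistribution", function(object) {
    msg <- character()
    if (length(object@p_values) != object@M)
        msg <- c(msg, "length(p_values) must equal M")
    if (any(object@p_values < 0 | object@p_values > 1, na.rm = TRUE))
        msg <- c(msg, "p-values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' @rdname pValues
#' @export
setMethod("pValues", "NullDistribution", function(x) x@p_values)

#' @describeIn NullDistribution number of random signatures.
#' @param x a `NullDistribution`.
#' @export
setMethod("length", "NullDistribution", function(x) x@M)

setMethod("show", "NullDistribution", function(object) {
    cat("NullDistribution:", object@M, "random signatures of size",
        object@signature_size, "from a universe of", object@universe_size,
        "genes [", object@method, "mode ]\n")
    cat("  p < 0.05 fraction:",
        signif(mean(object@p_values < 0.05), 3),
        "| best-5% cutoff:",
        signif(stats::quantile(object@p_values, 0.05, names = FALSE), 3),
        "\n")
})
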