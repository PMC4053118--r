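#' @importFrom utils read.delim write.table
NULL

# all writers go through write-then-rename so a failure never leaves a
# truncated file behind.
.atomicWrite <- function(writer, path) {
    tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
    on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
    writer(tmp)
    if (!file.rename(tmp, path))
        stop("could not move temporary file onto ", path)
    invisible(path)
}

.writeTsv <- function(df, path, row_label = NULL) {
    .atomicWrite(function(tmp) {
        if (!is.null(row_label)) {
            df <- cbind(stats::setNames(data.frame(rownames(df),
                stringsAsFactors = FALSE), row_label), df)
        }
        write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    }, path)
}

#' Read and write genes-as-rows expression TSV
#'
#' The expression format is a tab-separated table whose first column holds
#' gene (or probe) ids and whose header row holds sample ids.
#'
#' @param path file path.
#' @return `readExpressionTsv`: a numeric matrix with gene rownames and
#'   sample colnames.
#' @export
readExpressionTsv <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(df[[1]])
    m
}

#' @rdname readExpressionTsv
#' @param x gene x sample numeric matrix.
#' @export
writeExpressionTsv <- function(x, path) {
    .writeTsv(as.data.frame(x, check.names = FALSE), path,
        row_label = "gene_id")
}

#' Read and write the clinical table
#'
#' Columns: `patient_id`, `time_months`, `event`, and optionally `grade`,
#' `node`, `size_cm`, `er`, `subtype`.
#'
#' @param path file path.
#' @return `readClinicalTsv`: a data.frame keyed by `patient_id`.
#' @export
readClinicalTsv <- function(path) {
    read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname readClinicalTsv
#' @param cohort a \linkS4class{SurvivalCohort}.
#' @export
writeClinicalTsv <- function(cohort, path) {
    cd <- as.data.frame(colData(cohort))
    df <- data.frame(patient_id = colnames(cohort),
        time_months = cd$time, event = cd$event,
        stringsAsFactors = FALSE)
    for (nm in c("grade", "node", "er", "subtype"))
        if (nm %in% colnames(cd)) df[[nm]] <- cd[[nm]]
    if ("size" %in% colnames(cd)) df$size_cm <- cd$size
    .writeTsv(df, path)
}

#' Assemble a SurvivalCohort from expression and clinical files
#'
#' @param expr_path genes-as-rows expression TSV (columns = patients).
#' @param clinical_path clinical TSV (see [readClinicalTsv()]); patients
#'   are matched to expression columns by `patient_id`.
#' @return A \linkS4class{SurvivalCohort}.
#' @export
readCohort <- function(expr_path, clinical_path) {
    expr <- readExpressionTsv(expr_path)
    cl <- readClinicalTsv(clinical_path)
    idx <- match(colnames(expr), cl$patient_id)
    if (anyNA(idx))
        stop("clinical table is missing patients: ",
            paste(utils::head(colnames(expr)[is.na(idx)]), collapse = ", "))
    cl <- cl[idx, ]
    SurvivalCohort(expr, time = cl$time_months, event = cl$event,
        grade = cl$grade, node = cl$node, size = cl$size_cm, er = cl$er,
        subtype = cl$subtype)
}

#' Read and write a gene-signature TSV
#'
#' Columns: `gene_id`, `direction` (+1/-1), `fold_change`, `rank`.
#'
#' @param path file path.
#' @return `readSignatureTsv`: a \linkS4class{GeneSignature}.
#' @export
readSignatureTsv <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    GeneSignature(df$gene_id, direction = df$direction,
        fold_change = df$fold_change, rank = df$rank)
}

#' @rdname readSignatureTsv
#' @param signature a \linkS4class{GeneSignature}.
#' @export
writeSignatureTsv <- function(signature, path) {
    .writeTsv(as.data.frame(signature), path)
}
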