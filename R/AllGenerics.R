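NULL

#' Gene identifiers of a signature or result
#'
#' @param x a \linkS4class{GeneSignature} or \linkS4class{SamResult}.
#' @return Character vector of gene identifiers.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Signature directions
#'
#' Per-gene regulation direction, +1 for genes up in the class of interest
#' (linear fold change above 1), -1 for genes down.
#'
#' @param x a \linkS4class{GeneSignature}.
#' @return Numeric vector of +1/-1.
#' @export
setGeneric("directions", function(x) standardGeneric("directions"))

#' Linear-scale fold changes
#'
#' @param x a \linkS4class{GeneSignature}.
#' @return Positive numeric vector (2^ mean log2 difference).
#' @export
setGeneric("foldChanges", function(x) standardGeneric("foldChanges"))

#' Follow-up time and event indicator of a survival cohort
#'
#' @param x a \linkS4class{SurvivalCohort}.
#' @return `survTime`: numeric vector of follow-up times (months);
#'   `survEvent`: 0/1 integer vector (1 = metastasis/recurrence observed);
#'   `subtypes`: per-patient intrinsic-subtype labels (character, `NA` when
#'   not recorded).
#' @export
setGeneric("survTime", function(x) standardGeneric("survTime"))

#' @rdname survTime
#' @export
setGeneric("survEvent", function(x) standardGeneric("survEvent"))

#' @rdname survTime
#' @export
setGeneric("subtypes", function(x) standardGeneric("subtypes"))

#' Null-distribution p-values
#'
#' @param x a \linkS4class{NullDistribution}.
#' @return Numeric vector of log-rank p-values, one per random signature.
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))
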