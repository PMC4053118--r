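#' @importFrom jsonlite write_json toJSON
#' @importFrom tools md5sum
NULL

#' Pipeline run configuration
#'
#' Bundles file paths, the analysis parameters (all defaulting to the
#' study's printed choices: FDR 10%, top 80 genes by fold, top 20th
#' percentile risk cutoff, 1000 random signatures), and the seed. Every
#' artifact written by [runDerive()]/[runValidate()] embeds the seed and a
#' hash of this configuration, so runs with equal hashes are
#' byte-identical.
#'
#' @param expr path to a genes-as-rows expression TSV (derivation: sample
#'   columns; validation: patient columns).
#' @param labels optional path to a two-column TSV (sample_id, class) with
#'   the derivation class labels; the first class listed is the class of
#'   interest.
#' @param clinical path to the clinical TSV (validation).
#' @param signature path to a signature TSV (validation input /
#'   derivation output name).
#' @param probe_map optional path to a probe-to-gene two-column TSV; when
#'   given, [filterAndCollapse()] runs before SAM.
#' @param out_dir output directory (created if missing).
#' @param fdr_target SAM target FDR (default 0.10).
#' @param top_k signature size by fold change (default 80).
#' @param percentile risk-index cutoff quantile (default 0.80).
#' @param M random signatures for the null (default 1000; 0 skips it).
#' @param null_method "loocv" or "fast" (see [nullDistribution()]).
#' @param n_permutations SAM permutations (default 300).
#' @param covariates clinical covariates for the multivariate model
#'   (empty vector = unadjusted analysis only).
#' @param exclude_subtype optional subtype label dropped from the cohort
#'   before validation (e.g. "basal").
#' @param seed integer seed recorded in every output artifact.
#' @return A list of class `RunConfig`.
#' @export
runConfig <- function(expr = NULL, labels = NULL, clinical = NULL,
                      signature = NULL, probe_map = NULL, out_dir = NULL,
                      fdr_target = 0.10, top_k = 80, percentile = 0.80,
                      M = 1000, null_method = "loocv",
                      n_permutations = 300,
                      covariates = character(0),
                      exclude_subtype = NULL, seed = 1) {
    stopifnot(fdr_target > 0, fdr_target <= 1, top_k > 0,
        percentile > 0, percentile < 1, M >= 0, n_permutations >= 25)
    cfg <- list(expr = expr, labels = labels, clinical = clinical,
        signature = signature, probe_map = probe_map, out_dir = out_dir,
        fdr_target = fdr_target, top_k = top_k, percentile = percentile,
        M = M, null_method = null_method, n_permutations = n_permutations,
        covariates = covariates, exclude_subtype = exclude_subtype,
        seed = as.integer(seed))
    class(cfg) <- "RunConfig"
    cfg
}

.configHash <- function(config) {
    cfg <- unclass(config)
    cfg$out_dir <- NULL  # analysis parameters only, not the output location
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(toJSON(cfg, auto_unbox = TRUE, null = "null", digits = NA),
        tmp)
    unname(md5sum(tmp))
}

.writeJson <- function(x, path) {
    .atomicWrite(function(tmp) write_json(x, tmp, auto_unbox = TRUE,
        digits = NA, pretty = TRUE, null = "null"), path)
}

#' Derive the invasion signature from a two-class matrix
#'
#' End-to-end derivation: (optional) probe collapsing, SAM statistics,
#' permutation FDR, significance calls at the target FDR, and extraction
#' of the top-`top_k`-by-fold signature. All intermediate tables are
#' persisted in `out_dir` (`signature.tsv`, `sam_delta_table.tsv`,
#' `sam_genes.tsv`, `derive_log.json`); files are written atomically, and
#' re-running the same configuration reproduces them byte for byte.
#'
#' @param config a [runConfig()]; `expr` (and labels, via a file or a
#'   `class` column in the expression input's colData) are required.
#' @param x optional in-memory `SummarizedExperiment` used instead of
#'   `config$expr`.
#' @return Invisibly, a list with the `GeneSignature`, the `SamResult`,
#'   and the paths written.
#' @export
runDerive <- function(config, x = NULL) {
    stopifnot(inherits(config, "RunConfig"))
    if (is.null(config$out_dir)) stop("config$out_dir is required")
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (is.null(x)) {
        if (is.null(config$expr)) stop("config$expr is required")
        m <- readExpressionTsv(config$expr)
        x <- SummarizedExperiment(assays = list(log2ratio = m))
        if (!is.null(config$labels)) {
            lab <- read.delim(config$labels, stringsAsFactors = FALSE)
            idx <- match(colnames(m), lab[[1]])
            if (anyNA(idx)) stop("labels file is missing samples")
            colData(x)$class <- factor(lab[[2]][idx],
                levels = unique(lab[[2]]))
        }
    }
    if (!is.null(config$probe_map)) {
        map <- read.delim(config$probe_map, stringsAsFactors = FALSE)
        colnames(map)[1:2] <- c("probe_id", "gene_id")
        x <- filterAndCollapse(x, map)
    }
    res <- samPermutationFdr(x, n_permutations = config$n_permutations,
        seed = config$seed)
    res <- callSignificant(res, target_fdr = config$fdr_target)
    if (!any(res@called))
        warning("target FDR ", config$fdr_target,
            " unreachable: empty signature written")
    sig <- extractSignature(res, k = config$top_k)
    paths <- file.path(config$out_dir,
        c("signature.tsv", "sam_delta_table.tsv", "sam_genes.tsv",
            "derive_log.json"))
    writeSignatureTsv(sig, paths[1])
    .writeTsv(res@delta_table, paths[2])
    .writeTsv(data.frame(gene_id = res@gene_id, d = res@d, s = res@s,
        fold_change = res@fold_change, called = res@called), paths[3])
    .writeJson(list(
        stage = "derive", seed = config$seed,
        config_hash = .configHash(config),
        parameters = list(fdr_target = config$fdr_target,
            top_k = config$top_k, n_permutations = res@n_permutations,
            enumerated = res@enumerated, s0 = res@s0,
            chosen_delta = res@chosen_delta),
        counts = list(n_genes = length(res@gene_id),
            n_called = sum(res@called), signature_size = length(sig))),
        paths[4])
    invisible(list(signature = sig, sam = res, paths = paths))
}

#' Validate a signature in a survival cohort
#'
#' End-to-end validation: signature-to-cohort matching, leave-one-out
#' risk classification, Kaplan-Meier / log-rank / hazard-ratio evaluation,
#' optional multivariate adjustment, the random-signature null, and the
#' per-patient R values grouped by subtype. Artifacts written to
#' `out_dir`: `assignments.tsv`, `km_curves.tsv`, `null_pvalues.tsv`,
#' `rvalues.tsv`, `validate_report.json`.
#'
#' @param config a [runConfig()]; `expr` + `clinical` + `signature` paths
#'   are required unless in-memory objects are given.
#' @param cohort optional in-memory \linkS4class{SurvivalCohort}.
#' @param signature optional in-memory \linkS4class{GeneSignature}.
#' @return Invisibly, a list with `assignments`, `stratification`,
#'   `multivariate` (or NULL), `null` (or NULL), `rvalues`, `paths`.
#' @export
runValidate <- function(config, cohort = NULL, signature = NULL) {
    stopifnot(inherits(config, "RunConfig"))
    if (is.null(config$out_dir)) stop("config$out_dir is required")
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (is.null(cohort))
        cohort <- readCohort(config$expr, config$clinical)
    if (is.null(signature))
        signature <- readSignatureTsv(config$signature)
    if (!is.null(config$exclude_subtype)) {
        keep <- !(subtypes(cohort) %in% config$exclude_subtype)
        message("excluding subtype ",
            paste(config$exclude_subtype, collapse = ","), ": ",
            sum(!keep), " patients dropped")
        cohort <- cohort[, keep]
    }
    sig <- matchSignatureToCohort(signature, cohort)
    assignments <- loocvAssign(cohort, sig, percentile = config$percentile)
    strat <- evaluateStratification(assignments, cohort, gehan = TRUE)
    multi <- if (length(config$covariates))
        multivariateAdjustment(cohort, assignments,
            covariates = config$covariates) else NULL
    nd <- if (config$M > 0)
        nullDistribution(cohort, size = length(sig), M = config$M,
            percentile = config$percentile, seed = config$seed,
            method = config$null_method) else NULL
    rv <- rvalueBySubtype(cohort, sig, assignments$group)
    paths <- file.path(config$out_dir,
        c("assignments.tsv", "km_curves.tsv", "null_pvalues.tsv",
            "rvalues.tsv", "validate_report.json"))
    .writeTsv(assignments, paths[1])
    km <- rbind(
        data.frame(group = "high", time = strat$km_high$event_times,
            survival = strat$km_high$survival,
            n_at_risk = strat$km_high$n_at_risk,
            n_events = strat$km_high$n_events),
        data.frame(group = "low", time = strat$km_low$event_times,
            survival = strat$km_low$survival,
            n_at_risk = strat$km_low$n_at_risk,
            n_events = strat$km_low$n_events))
    .writeTsv(km, paths[2])
    if (!is.null(nd))
        .writeTsv(data.frame(signature = seq_len(length(nd)),
            p = pValues(nd)), paths[3])
    .writeTsv(rv, paths[4])
    spec <- if (!is.null(nd))
        empiricalSpecificity(strat$logrank$p, nd) else NULL
    .writeJson(list(
        stage = "validate", seed = config$seed,
        config_hash = .configHash(config),
        signature_size = length(sig),
        n_high = strat$n_high, n_low = strat$n_low,
        logrank_p = strat$logrank$p,
        gbw_p = strat$gbw$p,
        hazard_ratio = strat$hazard_ratio,
        multivariate = if (!is.null(multi)) list(
            coefficients = as.list(multi$coefficients),
            hazard_ratios = as.list(multi$hazard_ratios),
            wald_p = as.list(multi$wald_p),
            converged = multi$converged) else NULL,
        null = if (!is.null(nd)) list(M = nd@M, method = nd@method,
            frac_p_lt_05 = mean(pValues(nd) < 0.05),
            best5_cutoff = spec$best5_cutoff,
            observed_tail_fraction = spec$tail_fraction,
            beats_best5 = spec$beats_cutoff) else NULL,
        rvalue_crit = attr(rv, "r_crit")), paths[5])
    invisible(list(assignments = assignments, stratification = strat,
        multivariate = multi, null = nd, rvalues = rv, paths = paths))
}
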