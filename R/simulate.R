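#' @importFrom stats rnorm rexp rbinom runif median quantile plogis qlogis
#'   rlnorm
NULL

#' Simulate a two-class log-ratio expression matrix with planted effects
#'
#' Generates the substrate of the signature-derivation stage: a gene x
#' sample matrix of log2 ratios with two sample classes ("migratory" vs
#' "average", mirroring migratory tumor cells against the average primary
#' tumor population), in which a known subset of genes carries a mean
#' log2 shift of random sign and all genes carry Gaussian noise.
#'
#' The ground truth (which genes are differential, their signed effects,
#' the noise level and the seed) is stored in `metadata(x)$truth` as a
#' `TwoClassSimTruth` list with fields `de_flags`, `de_log2_effects`,
#' `noise_sd` and `seed`; effects are exactly 0 where `de_flags` is 0.
#'
#' @param n_genes number of genes.
#' @param n_per_class samples per class (>= 2); small designs of about 4
#'   biologic repeats per class are typical for this assay.
#' @param n_de number of genes with a planted shift (<= n_genes).
#' @param effect_size absolute mean log2 shift of planted genes; the sign
#'   is random per gene.
#' @param noise_sd residual standard deviation in log2 units (> 0).
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @return A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment]
#'   with assay `log2ratio`, `colData(x)$class` a factor with levels
#'   `c("migratory", "average")`, and truth in `metadata(x)$truth`.
#' @examples
#' se <- simulateTwoClassExpression(200, 4, n_de = 10, effect_size = 2,
#'     noise_sd = 0.5, seed = 1)
#' table(S4Vectors::metadata(se)$truth$de_flags)
#' @export
simulateTwoClassExpression <- function(n_genes, n_per_class, n_de,
                                       effect_size = 2, noise_sd = 0.5,
                                       seed = 1) {
    if (n_genes < 1 || n_per_class < 2 || n_de < 0)
        stop("n_genes >= 1, n_per_class >= 2 and n_de >= 0 are required")
    if (n_de > n_genes) stop("n_de must not exceed n_genes")
    if (noise_sd <= 0) stop("noise_sd must be positive")
    set.seed(seed)
    n <- 2L * n_per_class
    genes <- sprintf("g%05d", seq_len(n_genes))
    cls <- factor(rep(c("migratory", "average"), each = n_per_class),
        levels = c("migratory", "average"))
    de_idx <- if (n_de > 0) sample.int(n_genes, n_de) else integer(0)
    effects <- numeric(n_genes)
    if (n_de > 0)
        effects[de_idx] <- effect_size * sample(c(-1, 1), n_de, replace = TRUE)
    x <- matrix(rnorm(n_genes * n, sd = noise_sd), n_genes, n)
    # shift the migratory class by the planted effect
    x[, cls == "migratory"] <- x[, cls == "migratory"] + effects
    dimnames(x) <- list(genes,
        paste0(ifelse(cls == "migratory", "inv", "avg"),
            rep(seq_len(n_per_class), 2)))
    truth <- list(
        de_flags = as.integer(seq_len(n_genes) %in% de_idx),
        de_log2_effects = effects,
        noise_sd = noise_sd,
        seed = as.integer(seed)
    )
    se <- SummarizedExperiment(assays = list(log2ratio = x),
        colData = DataFrame(class = cls, row.names = colnames(x)))
    metadata(se)$truth <- truth
    se
}

#' Parameters of a simulated survival cohort
#'
#' Bundles the planted structure of [simulateSurvivalCohort()]: which genes
#' carry hazard signal and how strongly, the exponential baseline hazard,
#' independent exponential censoring, administrative cutoff, and intrinsic
#' subtype proportions.
#'
#' @param risk_genes character vector of gene ids carrying hazard signal
#'   (may be empty for a global null).
#' @param per_gene_log_hr log hazard ratio per unit expression for each
#'   risk gene (recycled to `length(risk_genes)`).
#' @param baseline_hazard constant event rate per month (> 0).
#' @param censor_rate rate of independent exponential censoring per month
#'   (>= 0; 0 disables random censoring).
#' @param admin_cutoff administrative censoring time in months (may be
#'   `Inf`).
#' @param subtype_props named proportions over subtype labels; must sum
#'   to 1.
#' @param covariate_mix mixing weight in [0, 1] tying clinical covariates
#'   to the true risk score (0 = independent covariates).
#' @return A list of class `CohortSimTruth`.
#' @examples
#' cohortSimTruth(risk_genes = c("g00001", "g00002"), per_gene_log_hr = 0.5)
#' @export
cohortSimTruth <- function(risk_genes = character(0),
                           per_gene_log_hr = numeric(0),
                           baseline_hazard = 0.01,
                           censor_rate = 0.005,
                           admin_cutoff = 120,
                           subtype_props = c(basal = 0.15, lumA = 0.35,
                               lumB = 0.20, her2 = 0.15, normal = 0.15),
                           covariate_mix = 0) {
    if (baseline_hazard <= 0) stop("baseline_hazard must be > 0")
    if (censor_rate < 0) stop("censor_rate must be >= 0")
    if (abs(sum(subtype_props) - 1) > 1e-8)
        stop("subtype_props must sum to 1")
    if (length(risk_genes))
        per_gene_log_hr <- rep_len(as.numeric(per_gene_log_hr),
            length(risk_genes))
    structure(list(
        risk_genes = as.character(risk_genes),
        per_gene_log_hr = per_gene_log_hr,
        baseline_hazard = baseline_hazard,
        censor_rate = censor_rate,
        admin_cutoff = admin_cutoff,
        subtype_props = subtype_props,
        covariate_mix = covariate_mix
    ), class = "CohortSimTruth")
}

#' Simulate a proportional-hazards survival cohort
#'
#' Emulates a breast-cancer validation cohort (expression plus clinical
#' table): per-gene standard-normal expression, exponential event times
#' with patient hazard `baseline_hazard * exp(sum(log_hr_g * x_gj))` over
#' the planted risk genes, independent exponential censoring and an
#' administrative cutoff, intrinsic subtype labels, and clinical covariates
#' with documented marginals (grade uniform on 1-3, node Bernoulli(0.4),
#' size log-normal with 2 cm median, ER Bernoulli(0.7)). A positive
#' `covariate_mix` in the truth ties grade/node/size (positively) and ER
#' (negatively) to the true risk score.
#'
#' @param n_patients number of patients; fewer than 10 triggers a warning.
#' @param n_genes size of the simulated gene universe.
#' @param truth a [cohortSimTruth()]; its `risk_genes` must be a subset of
#'   the simulated universe `g00001 ... g<n_genes>`.
#' @param seed integer RNG seed.
#' @return A \linkS4class{SurvivalCohort}; the truth (with the seed added)
#'   is in `metadata(x)$truth`.
#' @examples
#' truth <- cohortSimTruth(risk_genes = "g00001", per_gene_log_hr = 0.7)
#' co <- simulateSurvivalCohort(100, 50, truth, seed = 1)
#' summary(survTime(co))
#' @export
simulateSurvivalCohort <- function(n_patients, n_genes,
                                   truth = cohortSimTruth(), seed = 1) {
    if (n_patients < 1 || n_genes < 1)
        stop("n_patients and n_genes must be positive")
    if (n_patients < 10)
        warning("n_patients < 10: survival estimates will be unstable")
    genes <- sprintf("g%05d", seq_len(n_genes))
    if (!all(truth$risk_genes %in% genes))
        stop("risk_genes must be a subset of the simulated gene universe")
    set.seed(seed)
    x <- matrix(rnorm(n_genes * n_patients), n_genes, n_patients,
        dimnames = list(genes, sprintf("p%04d", seq_len(n_patients))))
    lp <- if (length(truth$risk_genes)) {
        drop(crossprod(x[truth$risk_genes, , drop = FALSE],
            truth$per_gene_log_hr))
    } else numeric(n_patients)
    rate <- truth$baseline_hazard * exp(lp)
    t_event <- rexp(n_patients, rate)
    t_censor <- if (truth$censor_rate > 0)
        rexp(n_patients, truth$censor_rate) else rep(Inf, n_patients)
    time <- pmin(t_event, t_censor, truth$admin_cutoff)
    event <- as.integer(t_event <= pmin(t_censor, truth$admin_cutoff))
    # guard: strictly positive observed times
    time <- pmax(time, .Machine$double.eps)
    w <- truth$covariate_mix
    z <- (lp - mean(lp)) / max(stats::sd(lp), .Machine$double.eps)
    grade <- findInterval(plogis(qlogis(runif(n_patients)) + 2 * w * z),
        c(1 / 3, 2 / 3)) + 1L
    node <- rbinom(n_patients, 1, plogis(qlogis(0.4) + 2 * w * z))
    size <- rlnorm(n_patients, meanlog = log(2) + 0.3 * w * z, sdlog = 0.4)
    er <- rbinom(n_patients, 1, plogis(qlogis(0.7) - 2 * w * z))
    subtype <- sample(names(truth$subtype_props), n_patients, replace = TRUE,
        prob = truth$subtype_props)
    co <- SurvivalCohort(x, time = time, event = event, grade = grade,
        node = node, size = size, er = er, subtype = subtype)
    truth$seed <- as.integer(seed)
    metadata(co)$truth <- truth
    co
}
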