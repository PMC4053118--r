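#' @importFrom stats sd quantile median mad
#' @importFrom utils combn
NULL

# unpaired two-class SAM ingredients for one label assignment.
# x: gene x sample matrix; idx1/idx2: column indices of the two classes.
.samCore <- function(x, idx1, idx2) {
    n1 <- length(idx1); n2 <- length(idx2)
    x1 <- x[, idx1, drop = FALSE]; x2 <- x[, idx2, drop = FALSE]
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
    s <- sqrt(ss * (1 / n1 + 1 / n2) / (n1 + n2 - 2))
    list(diff = m1 - m2, s = s)
}

# Tusher-style s0: grid over percentiles of s, minimizing the coefficient
# of variation of window-wise MADs of d across s-quantile windows.
.chooseS0 <- function(diff, s) {
    alphas <- seq(0, 1, by = 0.05)
    cand <- unique(quantile(s, alphas, names = FALSE))
    nw <- max(5L, min(25L, floor(length(s) / 20)))
    br <- unique(quantile(s, seq(0, 1, length.out = nw + 1), names = FALSE))
    if (length(br) < 3) return(median(s))
    win <- cut(s, br, include.lowest = TRUE)
    cv <- vapply(cand, function(s0) {
        d <- diff / (s + s0)
        mads <- tapply(d, win, mad)
        mads <- mads[is.finite(mads) & mads > 0]
        if (length(mads) < 3) return(NA_real_)
        sd(mads) / mean(mads)
    }, numeric(1))
    if (all(is.na(cv))) return(median(s))
    cand[which.min(cv)]
}

.getLabels <- function(x, labels) {
    if (is.null(labels)) labels <- colData(x)$class
    if (is.null(labels)) stop("no class labels supplied or found in colData")
    labels <- droplevels(as.factor(labels))
    if (nlevels(labels) != 2) stop("exactly two classes are required")
    if (any(table(labels) < 2)) stop("each class needs at least 2 samples")
    labels
}

#' Per-gene SAM statistics
#'
#' Computes the unpaired two-class SAM statistic
#' d = (mean1 - mean2) / (s + s0), where s is the pooled standard error of
#' the mean difference and s0 a small exchangeability constant that
#' stabilizes d for low-variance genes. Class 1 is the first factor level
#' of `labels` (the class of interest, e.g. "migratory"); on log2 input
#' the fold change is 2^(mean1 - mean2).
#'
#' @param x a `SummarizedExperiment` with a log2 expression assay, or a
#'   gene x sample matrix.
#' @param labels two-class factor over samples; defaults to
#'   `colData(x)$class`.
#' @param s0 "auto" (percentile-grid rule minimizing the coefficient of
#'   variation of d's spread across s-quantile windows), "median"
#'   (median of s), or a non-negative number.
#' @return A \linkS4class{SamResult} with `d`, `s`, `fold_change` and `s0`
#'   filled (no permutation table yet).
#' @examples
#' m <- rbind(g1 = c(1, 2, 3, 3, 4, 5))
#' r <- samStatistics(m, factor(rep(c("a", "b"), each = 3),
#'     levels = c("a", "b")), s0 = 0)
#' r@d  # -2 / 0.8165
#' @export
samStatistics <- function(x, labels = NULL, s0 = "auto") {
    if (is.matrix(x)) x <- SummarizedExperiment(assays = list(log2ratio = x))
    labels <- .getLabels(x, labels)
    m <- assay(x)
    if (is.null(rownames(m))) rownames(m) <- sprintf("g%05d", seq_len(nrow(m)))
    core <- .samCore(m, which(labels == levels(labels)[1]),
        which(labels == levels(labels)[2]))
    s0v <- if (identical(s0, "auto")) .chooseS0(core$diff, core$s)
        else if (identical(s0, "median")) median(core$s)
        else as.numeric(s0)
    if (is.na(s0v) || s0v < 0) stop("s0 must be non-negative")
    new("SamResult", gene_id = rownames(m), d = core$diff / (core$s + s0v),
        s = core$s, fold_change = 2^core$diff, s0 = s0v)
}

# threshold rule: from the origin of the expected order statistics, the
# first order position whose observed-minus-expected excess passes delta
# fixes the cut; everything beyond is called.
.samCuts <- function(d_sorted, dbar, delta) {
    diffv <- d_sorted - dbar
    i0 <- which.min(abs(dbar))
    idx <- seq_along(diffv)
    up <- idx[idx >= i0 & diffv > delta]
    lo <- idx[idx <= i0 & diffv < -delta]
    c(cutup = if (length(up)) min(d_sorted[up]) else Inf,
      cutlow = if (length(lo)) max(d_sorted[lo]) else -Inf)
}

#' SAM permutation-based FDR table
#'
#' Permutes the class labels, recomputes the order statistics of d for
#' each permutation, and forms the expected order statistics as their
#' permutation means. For each threshold delta a gene is called when its
#' observed order statistic exceeds the expected one by more than delta
#' beyond the cut points; the estimated FDR at delta is the median
#' permutation false-call count divided by the observed call count, capped
#' at 1 (`fdr_raw`) and monotonized by a running minimum over increasing
#' delta (`fdr`, the column used for threshold selection). When the
#' number of distinct label arrangements is at most `n_permutations`, all
#' arrangements are enumerated instead (message emitted).
#'
#' s0 is held fixed at its value on the observed labeling.
#'
#' @inheritParams samStatistics
#' @param n_permutations number of label permutations (>= 25; default 300).
#' @param seed integer RNG seed for the permutation draw.
#' @param n_delta number of delta thresholds tabulated.
#' @param fp_summary "median" (conservative SAM default) or "q90" for the
#'   false-call summary across permutations.
#' @return A \linkS4class{SamResult} with the `delta_table` filled.
#' @seealso [callSignificant()], [extractSignature()]
#' @export
samPermutationFdr <- function(x, labels = NULL, n_permutations = 300,
                              seed = 1, s0 = "auto", n_delta = 60,
                              fp_summary = c("median", "q90")) {
    fp_summary <- match.arg(fp_summary)
    if (n_permutations < 25) stop("at least 25 permutations are required")
    if (is.matrix(x)) x <- SummarizedExperiment(assays = list(log2ratio = x))
    labels <- .getLabels(x, labels)
    obs <- samStatistics(x, labels, s0 = s0)
    m <- assay(x)
    n <- ncol(m)
    idx1_obs <- which(labels == levels(labels)[1])
    n1 <- length(idx1_obs)
    total <- choose(n, n1)
    enumerated <- total <= n_permutations
    if (enumerated) {
        arrangements <- combn(n, n1)
        message("enumerating all ", ncol(arrangements),
            " distinct label arrangements")
    } else {
        set.seed(seed)
        arrangements <- replicate(n_permutations,
            sort(sample.int(n, n1)))
    }
    B <- ncol(arrangements)
    G <- nrow(m)
    perm_sorted <- matrix(0, B, G)
    for (b in seq_len(B)) {
        i1 <- arrangements[, b]
        core <- .samCore(m, i1, setdiff(seq_len(n), i1))
        perm_sorted[b, ] <- sort(core$diff / (core$s + obs@s0))
    }
    dbar <- colMeans(perm_sorted)
    d_sorted <- sort(obs@d)
    max_exc <- max(abs(d_sorted - dbar))
    deltas <- seq(0, max_exc, length.out = n_delta)
    tab <- t(vapply(deltas, function(delta) {
        cuts <- .samCuts(d_sorted, dbar, delta)
        ncall <- sum(obs@d >= cuts["cutup"] | obs@d <= cuts["cutlow"])
        fp <- rowSums(perm_sorted >= cuts["cutup"]) +
            rowSums(perm_sorted <= cuts["cutlow"])
        fp_hat <- if (fp_summary == "median") median(fp)
            else quantile(fp, 0.9, names = FALSE)
        c(ncall, fp_hat)
    }, numeric(2)))
    fdr_raw <- ifelse(tab[, 1] > 0, pmin(tab[, 2] / tab[, 1], 1), 0)
    dt <- data.frame(delta = deltas, n_called = as.integer(tab[, 1]),
        median_false = tab[, 2], fdr_raw = fdr_raw, fdr = cummin(fdr_raw))
    initialize(obs, delta_table = dt, expected_order = dbar,
        n_permutations = as.integer(B), enumerated = enumerated,
        seed = as.integer(seed))
}

#' Call significant genes at a target FDR
#'
#' Picks the smallest tabulated delta whose estimated FDR is at or below
#' `target_fdr` and flags the genes called there. When no delta achieves
#' the target with at least one call, the call set is empty and a warning
#' is raised (not an error).
#'
#' @param result a \linkS4class{SamResult} from [samPermutationFdr()].
#' @param target_fdr target false discovery rate (default 0.10).
#' @return The `SamResult` with `called`, `chosen_delta` and `target_fdr`
#'   set.
#' @export
callSignificant <- function(result, target_fdr = 0.10) {
    dt <- result@delta_table
    if (!nrow(dt)) stop("delta_table missing: run samPermutationFdr first")
    ok <- which(dt$fdr <= target_fdr)
    if (!length(ok) || dt$n_called[min(ok)] == 0) {
        warning("no delta achieves FDR <= ", target_fdr,
            " with a non-empty call set")
        return(initialize(result,
            called = rep(FALSE, length(result@gene_id)),
            chosen_delta = if (length(ok)) dt$delta[min(ok)] else NA_real_,
            target_fdr = target_fdr))
    }
    chosen <- dt$delta[min(ok)]
    cuts <- .samCuts(sort(result@d), result@expected_order, chosen)
    called <- result@d >= cuts["cutup"] | result@d <= cuts["cutlow"]
    initialize(result, called = called, chosen_delta = chosen,
        target_fdr = target_fdr)
}

#' Extract the top-fold signature from a SAM call set
#'
#' Among the called genes, ranks by absolute log2 fold change (descending)
#' and takes the top `k` (default 80): on whole-tissue validation arrays
#' the largest fold changes are the ones most likely to surface above
#' stromal background, so a prognostic subset is cut by fold rather than
#' by d. Ties in |log2 fold| at the boundary are all
#' included (with a message). When fewer than `k` genes are called, the
#' whole call set is returned.
#'
#' @param result a \linkS4class{SamResult} with `called` flags set.
#' @param k signature size (default 80).
#' @return A \linkS4class{GeneSignature}; direction is the sign of the
#'   log2 fold.
#' @export
extractSignature <- function(result, k = 80) {
    if (!length(result@called)) stop("run callSignificant first")
    idx <- which(result@called)
    if (!length(idx)) return(GeneSignature(character(0),
        fold_change = numeric(0)))
    lfc <- log2(result@fold_change[idx])
    ord <- idx[order(-abs(lfc), result@gene_id[idx])]
    if (length(ord) <= k) {
        if (length(ord) < k)
            message("only ", length(ord), " genes called; returning all")
        take <- ord
    } else {
        thr <- abs(log2(result@fold_change[ord[k]]))
        take <- ord[abs(log2(result@fold_change[ord])) >= thr - 1e-12]
        if (length(take) > k)
            message("fold-change tie at rank ", k, ": signature expanded to ",
                length(take), " genes")
    }
    lfc_t <- log2(result@fold_change[take])
    GeneSignature(result@gene_id[take],
        direction = ifelse(lfc_t >= 0, 1, -1),
        fold_change = result@fold_change[take],
        rank = seq_along(take))
}
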