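#' @importFrom stats pchisq setNames pnorm coef
#' @importFrom survival coxph Surv
NULL

#' Kaplan-Meier product-limit estimate
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators; times that are censored only affect
#'   the number at risk.
#' @return A list of class `KMCurve`: `event_times` (sorted distinct event
#'   times), `survival` (product-limit estimates), `n_at_risk`, `n_events`.
#'   With no events all fields are empty (survival is 1 throughout).
#' @examples
#' kmEstimate(c(1, 2, 3), c(1, 0, 1))$survival  # 2/3, 0
#' @export
kmEstimate <- function(time, event) {
    if (length(time) == 0) stop("empty input")
    stopifnot(length(time) == length(event), all(time > 0),
        all(event %in% c(0, 1)))
    ut <- sort(unique(time[event == 1]))
    n_at_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
    n_events <- vapply(ut, function(t) sum(time == t & event == 1),
        numeric(1))
    structure(list(event_times = ut,
        survival = cumprod(1 - n_events / n_at_risk),
        n_at_risk = n_at_risk, n_events = n_events), class = "KMCurve")
}

#' @export
print.KMCurve <- function(x, ...) {
    cat("KMCurve:", length(x$event_times), "event times\n")
    if (length(x$event_times))
        print(data.frame(time = x$event_times, n_at_risk = x$n_at_risk,
            n_events = x$n_events, survival = round(x$survival, 4)),
            row.names = FALSE)
    invisible(x)
}

#' Weighted log-rank test
#'
#' Accumulates observed-minus-expected events per group over the risk sets
#' at each distinct event time, with weight 1 (standard log-rank) or the
#' total number at risk (Gehan-Breslow-Wilcoxon, sensitive to early
#' separation of the curves). The chi-square statistic uses the
#' hypergeometric covariance of the event counts, with df = groups - 1.
#'
#' @param group group labels (>= 2 non-empty groups).
#' @param time,event follow-up times and 0/1 event indicators.
#' @param weight_scheme "logrank" or "gehan-breslow-wilcoxon".
#' @return A list of class `LogRankResult`: `chi2`, `df`, `p`,
#'   `weight_scheme`, and the per-group observed/expected table `oe`.
#' @examples
#' weightedLogrank(rep(c("A", "B"), each = 2), c(1, 2, 3, 4),
#'     rep(1, 4))$chi2  # 49/17
#' @export
weightedLogrank <- function(group, time, event,
                            weight_scheme = c("logrank",
                                "gehan-breslow-wilcoxon")) {
    weight_scheme <- match.arg(weight_scheme)
    group <- droplevels(as.factor(group))
    K <- nlevels(group)
    if (K < 2) stop("at least two groups are required")
    if (any(table(group) == 0)) stop("a group has zero members")
    stopifnot(length(time) == length(group), length(event) == length(group))
    ut <- sort(unique(time[event == 1]))
    U <- numeric(K)
    V <- matrix(0, K, K)
    O <- numeric(K); E <- numeric(K)
    for (t in ut) {
        at_risk <- time >= t
        n <- sum(at_risk)
        ng <- tabulate(group[at_risk], nbins = K)
        dg <- tabulate(group[time == t & event == 1], nbins = K)
        d <- sum(dg)
        if (n <= 0 || d == 0) next
        e <- d * ng / n
        w <- if (weight_scheme == "logrank") 1 else n
        U <- U + w * (dg - e)
        O <- O + dg; E <- E + e
        if (n > 1) {
            mult <- d * (n - d) / (n - 1)
            Vt <- mult * (diag(ng / n, K) - tcrossprod(ng / n))
            V <- V + w^2 * Vt
        }
    }
    # quadratic form on the first K-1 groups (covariance is singular)
    U1 <- U[-K]; V1 <- V[-K, -K, drop = FALSE]
    chi2 <- tryCatch(drop(t(U1) %*% solve(V1, U1)),
        error = function(e) drop(t(U1) %*% MASS::ginv(V1) %*% U1))
    chi2 <- max(chi2, 0)
    structure(list(chi2 = chi2, df = K - 1L,
        p = pchisq(chi2, K - 1, lower.tail = FALSE),
        weight_scheme = weight_scheme,
        oe = data.frame(group = levels(group), observed = O, expected = E)),
        class = "LogRankResult")
}

#' @export
print.LogRankResult <- function(x, ...) {
    cat(sprintf("%s test: chi2 = %.4g on %d df, p = %.4g\n",
        x$weight_scheme, x$chi2, x$df, x$p))
    print(x$oe, row.names = FALSE)
    invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Multivariate (or univariate) Cox partial-likelihood fit via
#' `survival::coxph`, with the Efron tie correction by default, Wald
#' standard errors, and 95% confidence intervals exp(beta +/- 1.96 se).
#' Constant covariates are an error for a univariate fit and are dropped
#' with a warning otherwise. A coefficient beyond +/- 10 (monotone
#' likelihood / perfect separation) is capped there and the fit flagged
#' not converged.
#'
#' @param covariates patient x p matrix or data.frame of covariates.
#' @param time,event follow-up times and 0/1 event indicators.
#' @param ties_method "efron" (default) or "breslow".
#' @return A list of class `CoxFit`: `coefficients`, `standard_errors`,
#'   `hazard_ratios`, `ci95` (2-column matrix), `wald_p`,
#'   `log_partial_likelihood` (at the estimate), `loglik0` (at 0),
#'   `converged`, `ties_method`, `n`, `n_events`.
#' @examples
#' x <- rnorm(60); t <- rexp(60, exp(0.8 * x)); e <- rep(1, 60)
#' coxFit(data.frame(x = x), t, e)$hazard_ratios
#' @export
coxFit <- function(covariates, time, event,
                   ties_method = c("efron", "breslow")) {
    ties_method <- match.arg(ties_method)
    df <- as.data.frame(covariates)
    if (ncol(df) < 1) stop("at least one covariate is required")
    if (is.null(colnames(df)) || any(!nzchar(colnames(df))))
        colnames(df) <- paste0("x", seq_len(ncol(df)))
    const <- vapply(df, function(v) length(unique(v[!is.na(v)])) < 2,
        logical(1))
    if (any(const)) {
        if (ncol(df) == 1)
            stop("constant covariate in a univariate fit")
        warning("dropping constant covariates: ",
            paste(colnames(df)[const], collapse = ", "))
        df <- df[, !const, drop = FALSE]
        if (ncol(df) == 0) stop("all covariates constant")
    }
    fit <- coxph(Surv(time, event) ~ ., data = df, ties = ties_method)
    beta <- coef(fit)
    se <- sqrt(diag(fit$var))
    capped <- !is.finite(beta) | abs(beta) > 10
    beta[capped] <- sign(beta[capped]) * 10
    converged <- !any(capped) && fit$iter < 20 && all(is.finite(se))
    ci <- cbind(lower = exp(beta - 1.96 * se), upper = exp(beta + 1.96 * se))
    rownames(ci) <- names(beta)
    structure(list(
        coefficients = beta,
        standard_errors = setNames(se, names(beta)),
        hazard_ratios = exp(beta),
        ci95 = ci,
        wald_p = setNames(2 * stats::pnorm(-abs(beta / se)), names(beta)),
        log_partial_likelihood = fit$loglik[2],
        loglik0 = fit$loglik[1],
        converged = converged,
        ties_method = ties_method,
        n = fit$n, n_events = fit$nevent), class = "CoxFit")
}

#' @export
print.CoxFit <- function(x, ...) {
    cat(sprintf("Cox fit (%s ties), n = %d, events = %d%s\n", x$ties_method,
        x$n, x$n_events,
        if (!x$converged) " [NOT CONVERGED: estimates unusable]" else ""))
    print(data.frame(
        coef = round(x$coefficients, 4),
        HR = round(x$hazard_ratios, 3),
        lower95 = round(x$ci95[, "lower"], 3),
        upper95 = round(x$ci95[, "upper"], 3),
        p = signif(x$wald_p, 3)))
    invisible(x)
}
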