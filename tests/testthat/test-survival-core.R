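test_that("Kaplan-Meier matches hand-computed product limits", {
    expect_equal(kmEstimate(c(1, 2, 3), c(1, 1, 1))$survival,
        c(2 / 3, 1 / 3, 0))
    # censoring at t=2 removes one from the risk set only
    k <- kmEstimate(c(1, 2, 3), c(1, 0, 1))
    expect_equal(k$event_times, c(1, 3))
    expect_equal(k$survival, c(2 / 3, 0))
    # all censored: survival stays 1, no event times
    expect_length(kmEstimate(c(1, 2, 3), c(0, 0, 0))$event_times, 0)
    expect_error(kmEstimate(numeric(0), numeric(0)), "empty")
})

test_that("Kaplan-Meier equals survival::survfit on tied, censored data", {
    set.seed(7)
    tm <- sample(1:20, 100, replace = TRUE)
    ev <- rbinom(100, 1, 0.6)
    k <- kmEstimate(tm, ev)
    sf <- survival::survfit(survival::Surv(tm, ev) ~ 1)
    at <- sf$n.event > 0
    expect_equal(k$event_times, sf$time[at])
    expect_equal(k$survival, sf$surv[at])
    expect_equal(k$n_at_risk, sf$n.risk[at])
    # no censoring: 1 - empirical CDF at every event time
    tm2 <- rexp(50) + 0.1
    k2 <- kmEstimate(tm2, rep(1, 50))
    expect_equal(k2$survival,
        vapply(k2$event_times, function(t) mean(tm2 > t), numeric(1)))
})

test_that("log-rank accumulates the hand-computed O-E over risk sets", {
    lr <- weightedLogrank(rep(c("A", "B"), each = 2), c(1, 2, 3, 4),
        rep(1, 4))
    # O-E = 7/6, Var = 17/36 -> chi2 = 49/17
    expect_equal(lr$chi2, 49 / 17, tolerance = 1e-12)
    expect_equal(lr$df, 1L)
    # identical groups: no signal
    lr0 <- weightedLogrank(rep(c("A", "B"), times = 3),
        rep(c(1, 2, 3), each = 2), rep(1, 6))
    expect_equal(lr0$chi2, 0, tolerance = 1e-12)
    expect_equal(lr0$p, 1)
    expect_error(weightedLogrank(factor(c("A", "A"), levels = c("A", "B")),
        c(1, 2), c(1, 1)), "zero members|two groups")
    expect_error(weightedLogrank(rep("A", 4), 1:4, rep(1, 4)), "two groups")
})

test_that("log-rank agrees with survival::survdiff and is label-invariant", {
    set.seed(8)
    g <- sample(c("x", "y", "z"), 120, replace = TRUE)
    tm <- rexp(120, 0.1) + 0.01
    ev <- rbinom(120, 1, 0.7)
    lr <- weightedLogrank(g, tm, ev)
    sd <- survival::survdiff(survival::Surv(tm, ev) ~ g)
    expect_equal(lr$chi2, sd$chisq, tolerance = 1e-8)
    expect_equal(lr$df, 2L)
    # permuting group labels leaves the statistic unchanged
    g2 <- factor(g, levels = c("z", "x", "y"))
    expect_equal(weightedLogrank(g2, tm, ev)$chi2, lr$chi2,
        tolerance = 1e-10)
})

test_that("Gehan-Breslow-Wilcoxon outperforms log-rank on early separation", {
    # group A fails fast early, then the curves come back together
    tA <- c(1, 2, 3, 4, 5, 30, 32, 34, 36, 38, 40, 42)
    tB <- c(10, 12, 14, 16, 18, 29, 31, 33, 35, 37, 39, 41)
    g <- rep(c("A", "B"), each = 12)
    tm <- c(tA, tB)
    ev <- rep(1, 24)
    p_lr <- weightedLogrank(g, tm, ev, "logrank")$p
    p_gbw <- weightedLogrank(g, tm, ev, "gehan-breslow-wilcoxon")$p
    expect_lt(p_gbw, p_lr)
})

test_that("the Cox MLE equals the grid-search maximizer on the 4-subject fixture", {
    x <- c(1, 0, 1, 0)
    tm <- c(1, 2, 3, 4)
    ev <- rep(1, 4)
    # independent oracle: grid search of the exact partial likelihood
    pl <- function(b) (exp(b) / (2 * exp(b) + 2)) * (1 / (exp(b) + 2)) *
        (exp(b) / (exp(b) + 1))
    grid <- seq(-5, 5, by = 1e-4)
    b_star <- grid[which.max(pl(grid))]
    fit <- coxFit(data.frame(x = x), tm, ev)
    expect_equal(unname(fit$coefficients), b_star, tolerance = 1e-3)
    batch <- coxUnivariateBatch(matrix(x, ncol = 1), tm, ev)
    expect_equal(batch$beta, b_star, tolerance = 1e-3)
    # likelihood at the estimate is no worse than at zero
    expect_gte(fit$log_partial_likelihood, fit$loglik0)
    expect_gte(batch$loglik, batch$loglik0)
})

test_that("the score test at beta 0 for a binary covariate is the log-rank chi2", {
    set.seed(9)
    tm <- rexp(60) + 0.01  # continuous: no ties
    ev <- rbinom(60, 1, 0.8)
    x <- rbinom(60, 1, 0.4)
    sc <- survival::coxph(survival::Surv(tm, ev) ~ x)$score
    expect_equal(weightedLogrank(x, tm, ev)$chi2, unname(sc),
        tolerance = 1e-8)
})

test_that("the batch univariate fitter agrees with coxph for both tie methods", {
    set.seed(10)
    n <- 80
    x <- matrix(rnorm(n * 6), n, 6)
    tm <- round(rexp(n, exp(0.5 * x[, 1])) * 10) + 1  # heavy ties
    ev <- rbinom(n, 1, 0.7)
    for (ties in c("efron", "breslow")) {
        fit <- coxUnivariateBatch(x, tm, ev, ties = ties)
        ref <- vapply(1:6, function(j) {
            f <- survival::coxph(survival::Surv(tm, ev) ~ x[, j],
                ties = ties)
            c(unname(coef(f)), sqrt(f$var[1, 1]), f$loglik[2])
        }, numeric(3))
        expect_equal(fit$beta, ref[1, ], tolerance = 1e-7)
        expect_equal(fit$se, ref[2, ], tolerance = 1e-7)
        expect_equal(fit$loglik, ref[3, ], tolerance = 1e-7)
        expect_true(all(fit$converged))
    }
    # warm start changes nothing but the path
    warm <- coxUnivariateBatch(x, tm, ev, init = rep(0.4, 6))
    expect_equal(warm$beta, coxUnivariateBatch(x, tm, ev)$beta,
        tolerance = 1e-7)
})

test_that("null coverage: beta-hat within 2 SE of zero in >= 93% of fits", {
    hits <- vapply(1:100, function(i) {
        set.seed(2000 + i)
        x <- rnorm(500)
        tm <- rexp(500, 0.01)
        ev <- rbinom(500, 1, 0.7)
        f <- coxFit(data.frame(x = x), tm, ev)
        abs(f$coefficients) < 2 * f$standard_errors
    }, logical(1))
    expect_gte(mean(hits), 0.93)
})

test_that("degenerate Cox inputs are flagged rather than trusted", {
    # monotone likelihood: the covariate perfectly orders the events
    x <- c(rep(1, 5), rep(0, 5))
    tm <- c(1:5, 11:15)
    ev <- rep(1, 10)
    fit <- suppressWarnings(coxFit(data.frame(x = x), tm, ev))
    expect_false(fit$converged)
    expect_equal(abs(unname(fit$coefficients)), 10)
    expect_error(coxFit(data.frame(x = rep(1, 10)), tm, ev), "constant")
    expect_warning(coxFit(data.frame(x = rnorm(10), z = rep(2, 10)),
        tm, ev), "constant")
    # batch fitter: zero-variance gene -> not converged, usable beta 0
    b <- coxUnivariateBatch(cbind(rnorm(10), rep(1, 10)), tm, ev)
    expect_false(b$converged[2])
})
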