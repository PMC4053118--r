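test_that("the SAM statistic matches its hand-computed definition", {
    labels <- factor(rep(c("a", "b"), each = 3), levels = c("a", "b"))
    r <- samStatistics(rbind(g1 = c(1, 2, 3, 3, 4, 5)), labels, s0 = 0)
    # pooled standard error sqrt((2+2)*(1/3+1/3)/4) = sqrt(2/3)
    expect_equal(unname(r@d), -2 / sqrt(2 / 3), tolerance = 1e-12)
    expect_equal(unname(r@s), sqrt(2 / 3), tolerance = 1e-12)
    # equal class means -> d = 0; mean log2 diff of 1 -> fold change 2
    r2 <- samStatistics(rbind(g1 = c(1, 2, 3, 1, 2, 3),
        g2 = c(2, 3, 4, 1, 2, 3)), labels, s0 = 0.1)
    expect_equal(unname(r2@d[1]), 0)
    expect_equal(unname(r2@fold_change), c(1, 2))
    expect_error(samStatistics(rbind(g1 = c(1, 2, 3)),
        factor(c("a", "a", "b"))), "at least 2")
    expect_error(samStatistics(rbind(g1 = c(1, 2, 3, 4)),
        factor(rep("a", 4))), "two classes")
})

test_that("d is antisymmetric under class-label swap and s0 is sane", {
    se <- simulateTwoClassExpression(150, 4, 15, seed = 11)
    lab <- SummarizedExperiment::colData(se)$class
    swapped <- factor(ifelse(lab == "migratory", "average", "migratory"),
        levels = c("migratory", "average"))
    r1 <- samStatistics(se)
    r2 <- samStatistics(se, labels = swapped, s0 = r1@s0)
    expect_equal(r1@d, -r2@d)
    expect_gte(r1@s0, 0)
    # shifting one class of a gene moves d monotonically
    m <- SummarizedExperiment::assay(se)
    m["g00001", lab == "migratory"] <- m["g00001", lab == "migratory"] + 1
    r3 <- samStatistics(m, lab, s0 = r1@s0)
    expect_gt(r3@d["g00001"], r1@d["g00001"])
})

test_that("the permutation FDR table is reproducible, monotone and sane", {
    se <- simulateTwoClassExpression(200, 4, 20, seed = 21)
    expect_message(r <- samPermutationFdr(se, seed = 21), "enumerating")
    expect_true(r@enumerated)
    expect_equal(r@n_permutations, choose(8L, 4L))
    r2 <- suppressMessages(samPermutationFdr(se, seed = 99))
    expect_identical(r@delta_table, r2@delta_table)  # enumeration: seed-free
    dt <- r@delta_table
    expect_true(all(diff(dt$fdr) <= 1e-12))
    expect_true(all(diff(dt$n_called) <= 0))
    expect_true(all(dt$fdr >= 0 & dt$fdr <= 1))
    expect_error(samPermutationFdr(se, n_permutations = 10), "25")
})

test_that("under the global null the delta-0 call set is large with FDR near 1", {
    # at delta = 0 every gene with any observed-minus-expected excess is
    # called; genes in a sign run near the origin can escape, so the call
    # fraction sits below 1 even here
    stats_ <- vapply(31:35, function(s) {
        se <- simulateTwoClassExpression(200, 4, 0, effect_size = 0,
            seed = s)
        r <- suppressMessages(samPermutationFdr(se, seed = s))
        c(r@delta_table$n_called[1] / 200, r@delta_table$fdr_raw[1])
    }, numeric(2))
    expect_gt(mean(stats_[1, ]), 0.6)
    expect_true(all(stats_[2, ] > 0.8))
    # target FDR 1.0 calls everything with any excess
    se <- simulateTwoClassExpression(200, 4, 0, effect_size = 0, seed = 31)
    r <- suppressMessages(samPermutationFdr(se, seed = 31))
    r2 <- callSignificant(r, target_fdr = 1.0)
    expect_equal(sum(r2@called), r@delta_table$n_called[1])
})

test_that("estimated FDR tracks the realized false-discovery proportion", {
    # fully null matrices: every call is false, so the realized FDP is 1
    # wherever calls occur; assessed at thresholds calling >= 25% of genes,
    # where the median false-call count has meaningful resolution
    est <- vapply(1:20, function(i) {
        se <- simulateTwoClassExpression(200, 4, 0, effect_size = 0,
            noise_sd = 0.5, seed = 400 + i)
        r <- suppressMessages(samPermutationFdr(se, seed = 400 + i,
            n_permutations = 100))
        dt <- r@delta_table
        ok <- dt$n_called >= 50
        if (!any(ok)) return(NA_real_)
        mean(dt$fdr_raw[ok])
    }, numeric(1))
    expect_equal(mean(est, na.rm = TRUE), 1, tolerance = 0.1)
})

test_that("significance calling at the target FDR recovers planted genes", {
    se <- simulateTwoClassExpression(500, 4, 25, effect_size = 2,
        noise_sd = 0.5, seed = 41)
    r <- suppressMessages(samPermutationFdr(se, seed = 41))
    r <- callSignificant(r, target_fdr = 0.10)
    truth <- S4Vectors::metadata(se)$truth
    expect_gte(mean(r@called[truth$de_flags == 1]), 0.8)
    expect_equal(sum(r@called),
        r@delta_table$n_called[r@delta_table$delta == r@chosen_delta])
    # unreachable target -> empty set with a warning, not an error
    fake <- r
    fake@delta_table$fdr <- rep(0.5, nrow(fake@delta_table))
    fake@delta_table$fdr_raw <- fake@delta_table$fdr
    expect_warning(out <- callSignificant(fake, target_fdr = 0.01),
        "no delta")
    expect_equal(sum(out@called), 0)
})

test_that("signature extraction ranks by fold, handles short call sets and ties", {
    r <- new("SamResult", gene_id = paste0("g", 1:6),
        d = c(5, 4, 3, -4, -3, 1), s = rep(1, 6),
        fold_change = 2^c(3, 2, 1, -2, -1, 0.1), s0 = 0.1,
        called = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
        chosen_delta = 1, target_fdr = 0.1)
    # called |log2 fold| = 3, 2, 2, 1, 1 (genes g1, g2, g4, g3, g5)
    expect_equal(geneIds(extractSignature(r, k = 3)), c("g1", "g2", "g4"))
    # |fold| tie at rank 2 (g2 and g4) expands the signature
    expect_message(extractSignature(r, k = 2), "tie")
    expect_equal(geneIds(suppressMessages(extractSignature(r, k = 2))),
        c("g1", "g2", "g4"))
    expect_equal(unname(directions(suppressMessages(
        extractSignature(r, k = 3)))), c(1, 1, -1))
    # k beyond the call set returns every called gene
    expect_message(all5 <- extractSignature(r, k = 10), "returning all")
    expect_length(all5, 5)
    expect_error(extractSignature(new("SamResult", gene_id = "g",
        d = 1, s = 1, fold_change = 2, s0 = 0)), "callSignificant")
})

test_that("null matrices never yield mass calls at FDR 0.10", {
    # an extreme observed order statistic occasionally beats the median
    # permutation false count (which is then 0), producing a spurious call
    # set of a handful of genes; a sane s0 must keep these sets tiny and
    # most replicates empty
    ncalls <- vapply(1:100, function(i) {
        se <- simulateTwoClassExpression(200, 4, 0, effect_size = 0,
            seed = 600 + i)
        r <- suppressMessages(samPermutationFdr(se, seed = 600 + i))
        r <- suppressWarnings(callSignificant(r, 0.10))
        sum(r@called)
    }, integer(1))
    expect_lte(mean(ncalls > 5), 0.05)
    expect_gte(mean(ncalls == 0), 0.4)
})
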