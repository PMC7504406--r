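test_that("residual degrees of freedom follow the unbalanced fit", {
    pop <- fourPops(3)
    x <- matrix(rnorm(3 * 12), nrow = 3)
    x[2, pop == "dendritic"] <- NA              # one group fully missing
    x[3, ] <- NA                                # all missing
    fit <- fitGroupMeans(makeLogMatrix(x, pop))
    expect_equal(fit$df[[1]], 8)                # 12 - 4
    expect_equal(fit$df[[2]], 6)                # 9 - 3
    expect_equal(fit$df[[3]], 0)
    expect_true(rownames(fit$means)[3] %in% fit$noResidualDf)
    expect_true(is.na(fit$s2[3]))               # flagged, not an error
})

test_that("group means and within-group sums of squares are exact", {
    # group (1, 1, 3): mean 5/3, SS = 2*(2/3)^2 + (4/3)^2 = 8/3
    pop <- fourPops(3)
    x <- matrix(0, nrow = 1, ncol = 12)
    x[1, pop == "progenitor"] <- c(1, 1, 3)
    x[1, pop == "erythrocyte"] <- c(2, 2, 2)
    x[1, pop == "dendritic"] <- c(4, 5, 6)
    x[1, pop == "neutrophil"] <- c(0, 0, 0)
    fit <- fitGroupMeans(makeLogMatrix(x, pop))
    expect_equal(unname(fit$means[1, ]), c(5 / 3, 2, 5, 0))
    expect_equal(unname(fit$s2[1]), (8 / 3 + 0 + 2 + 0) / 8)
})

test_that("identical variances with equal df give d0 = Inf", {
    h <- estimateHyperparams(rep(0.3, 50), rep(8, 50))
    expect_identical(h$d0, Inf)
    expect_equal(h$s0sq, 0.3, tolerance = 1e-9)
})

test_that("heterogeneous variances give finite d0 and interpolating shrinkage", {
    set.seed(10)
    d <- rep(8, 200)
    s2 <- 0.25 * d / rchisq(200, df = 4) * rchisq(200, df = 8) / 8
    h <- estimateHyperparams(s2, d)
    expect_true(is.finite(h$d0) && h$d0 > 0)
    post <- (h$d0 * h$s0sq + d * s2) / (h$d0 + d)
    expect_true(all(post >= pmin(s2, h$s0sq) - 1e-12))
    expect_true(all(post <= pmax(s2, h$s0sq) + 1e-12))
})

test_that("too few usable variances is an actionable error", {
    expect_error(estimateHyperparams(0.5, 8), "d0 = 0")
})

test_that("with d0 = 0 the moderated t equals the lm() pooled t", {
    set.seed(21)
    pop <- fourPops(3)
    x <- matrix(rnorm(50 * 12), nrow = 50)
    la <- makeLogMatrix(x, pop)
    fit <- fitGroupMeans(la)
    elig <- eligibilityFilter(la)$eligible
    ct <- moderatedStatistics(fit, elig, hyper = NULL)  # d0 = 0
    oracle <- oracleLmContrasts(x, pop)
    ct <- ct[order(ct$metabolite_id, ct$contrast), ]
    orc <- oracle[order(rep(seq_len(50), each = 3), oracle$contrast), ]
    expect_equal(ct$logFC, orc$logFC, tolerance = 1e-10)
    expect_equal(ct$moderated_t, orc$t, tolerance = 1e-10)
    expect_equal(ct$p_raw, orc$p, tolerance = 1e-10)
})

test_that("d0 = Inf gives the full-shrinkage normal-tail limit", {
    pop <- fourPops(3)
    x <- matrix(rnorm(4 * 12, sd = 0.5), nrow = 4)
    la <- makeLogMatrix(x, pop)
    fit <- fitGroupMeans(la)
    elig <- eligibilityFilter(la)$eligible
    hyper <- structure(list(d0 = Inf, s0sq = 0.25),
                       class = "ShrinkageHyperparams")
    ct <- moderatedStatistics(fit, elig, hyper)
    expected_t <- ct$logFC / (0.5 * sqrt(1 / 3 + 1 / 3))
    expect_equal(ct$moderated_t, expected_t, tolerance = 1e-12)
    expect_equal(ct$p_raw, 2 * pnorm(-abs(expected_t)), tolerance = 1e-12)
    expect_true(all(is.infinite(ct$df_total)))
})

test_that("closed-form single-metabolite moderated t matches hand computation", {
    # means progenitor 5, lineage 7; posterior variance 0.5; n = 3/3; df 8:
    # t = 2 / sqrt(0.5 * 2/3) = 3.4641016, two-sided p from t(8) = 0.008516263
    pop <- fourPops(3)
    x <- matrix(5, nrow = 1, ncol = 12)
    x[1, pop == "erythrocyte"] <- 7
    la <- makeLogMatrix(x, pop)
    fit <- fitGroupMeans(la)
    fit$s2[] <- 0.5                              # pin the posterior variance
    hyper <- structure(list(d0 = 0, s0sq = NA_real_),
                       class = "ShrinkageHyperparams")
    ct <- moderatedStatistics(fit, eligibilityFilter(la)$eligible, hyper)
    e <- ct[ct$contrast == "E", ]
    expect_equal(e$logFC, 2)
    expect_equal(e$moderated_t, 3.4641016151, tolerance = 1e-9)
    expect_equal(e$p_raw, 0.008516263371, tolerance = 1e-8)
})

test_that("moderated results agree with the limma reference implementation", {
    skip_if_not_installed("limma")
    set.seed(77)
    pop <- fourPops(3)
    # heterogeneous true variances so the finite-d0 branch is exercised
    sigma <- sqrt(0.25 * 4 / rchisq(200, df = 4))
    x <- matrix(rnorm(200 * 12, mean = 5, sd = rep(sigma, 12)), nrow = 200)
    x[1:30, pop == "erythrocyte"] <- x[1:30, pop == "erythrocyte"] + 2
    la <- makeLogMatrix(x, pop)
    res <- contrastStatistics(la)
    design <- stats::model.matrix(~ 0 + factor(pop, levels = c(
        "progenitor", "erythrocyte", "dendritic", "neutrophil")))
    colnames(design) <- c("P", "E", "DC", "N")
    cm <- limma::makeContrasts(E - P, DC - P, N - P, levels = design)
    fit <- limma::eBayes(limma::contrasts.fit(limma::lmFit(x, design), cm))
    expect_equal(res$hyper$d0, fit$df.prior, tolerance = 1e-5)
    expect_equal(res$hyper$s0sq, fit$s2.prior, tolerance = 1e-6)
    for (j in 1:3) {
        lin <- c("E", "DC", "N")[j]
        mine <- res$contrasts[res$contrasts$contrast == lin, ]
        i <- match(mine$metabolite_id, rownames(la))
        expect_equal(mine$logFC, unname(fit$coefficients[i, j]),
                     tolerance = 1e-9)
        expect_equal(mine$moderated_t, unname(fit$t[i, j]), tolerance = 1e-6)
        expect_equal(mine$p_raw, unname(fit$p.value[i, j]), tolerance = 1e-6)
    }
})

test_that("BH adjustment matches the step-up definition and its examples", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.03), 0.03)
    expect_identical(bhAdjust(numeric()), numeric())
    set.seed(13)
    for (i in 1:20) {
        p <- runif(sample(1:12, 1))
        adj <- bhAdjust(p)
        expect_equal(adj, bruteBH(p), tolerance = 1e-12)
        expect_true(all(adj >= p & adj <= 1))
    }
})

test_that("FDR families: per-contrast is the default, global is available", {
    set.seed(5)
    pop <- fourPops(3)
    x <- matrix(rnorm(30 * 12), nrow = 30)
    la <- makeLogMatrix(x, pop)
    perC <- contrastStatistics(la, fdrFamily = "per_contrast")$contrasts
    glob <- contrastStatistics(la, fdrFamily = "global")$contrasts
    for (lin in c("E", "DC", "N")) {
        sub <- perC[perC$contrast == lin & perC$eligible, ]
        expect_equal(sub$p_fdr, bhAdjust(sub$p_raw))
    }
    ok <- glob$eligible
    expect_equal(glob$p_fdr[ok], bhAdjust(glob$p_raw[ok]))
    expect_true(all(perC$p_fdr[ok] >= perC$p_raw[ok]))
})

test_that("ineligible entries carry no statistics", {
    pop <- fourPops(3)
    x <- matrix(rnorm(2 * 12), nrow = 2)
    x[2, pop == "neutrophil"] <- NA
    la <- makeLogMatrix(x, pop)
    ct <- contrastStatistics(la)$contrasts
    bad <- ct[ct$metabolite_id == rownames(la)[2] & ct$contrast == "N", ]
    expect_false(bad$eligible)
    expect_true(all(is.na(bad[, c("logFC", "moderated_t", "p_raw", "p_fdr")])))
})
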