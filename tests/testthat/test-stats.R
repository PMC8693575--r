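test_that("method-of-moments NB fit matches the closed form", {
    ## mean 10, variance 20 exactly -> p = 0.5, r = 10
    x <- c(5, 15, 5, 15, 10, 10)
    expect_equal(mean(x), 10); expect_equal(var(x), 20)
    fit <- fitNegbinMoments(x)
    expect_equal(fit$status, "ok")
    expect_equal(fit$p, 0.5)
    expect_equal(fit$r, 10)
})

test_that("NB parameters are recovered from simulated draws", {
    set.seed(1234)
    x <- rnbinom(10000, size = 5, prob = 0.3)
    fit <- fitNegbinMoments(x)
    expect_equal(fit$status, "ok")
    expect_lt(abs(fit$r - 5) / 5, 0.10)
})

test_that("degenerate sample vectors are flagged, not fatal", {
    expect_equal(fitNegbinMoments(rep(7, 50))$status, "underdispersed")
    expect_equal(fitNegbinMoments(rep(0, 50))$status, "untestable")
    expect_error(fitNegbinMoments(5), "at least 2")
    expect_error(fitNegbinMoments(c(-1, 2)), "non-negative")
})

test_that("NB p-values follow the inclusive upper-tail convention", {
    fit <- list(status = "ok", r = 1, p = 0.5)
    expect_equal(negbinPvalue(fit, 0), 1)
    ## NB(r=1, p=0.5) is geometric: P(X >= 3) = (1-p)^3 = 0.125
    expect_equal(negbinPvalue(fit, 3), 0.125)
    ps <- vapply(0:20, function(s) negbinPvalue(fit, s), numeric(1))
    expect_true(all(diff(ps) <= 0))
    ## underdispersed fallback uses the Poisson tail
    fit2 <- fitNegbinMoments(c(4, 4, 4, 4, 5, 3))
    expect_equal(fit2$status, "underdispersed")
    expect_equal(negbinPvalue(fit2, 6),
                 ppois(5, fit2$lambda, lower.tail = FALSE))
})

test_that("empirical p-values use the add-one rule", {
    expect_equal(empiricalPvalue(1:199, 500), 1 / 200)
    x <- c(3, 9, 7)
    expect_equal(empiricalPvalue(x, min(x)), 1)
    expect_equal(empiricalPvalue(0:99, 50), 51 / 101)
})

test_that("fold change is log2 with a pseudo-count only at zero", {
    expect_equal(foldChange(20, 20), 0)
    expect_equal(foldChange(2000, 2), log2(1000))
    fc0 <- foldChange(0, 100)
    expect_true(is.finite(fc0) && fc0 < -6)
    expect_equal(fc0, log2(1 / 101))
})

test_that("Cramer's V separates self-fit from misfit and flags constants", {
    set.seed(55)
    x <- rnbinom(1000, size = 8, prob = 0.4)
    fit <- fitNegbinMoments(x)
    self <- cramersVFit(x, fit)
    expect_equal(self$verdict, "good")
    expect_lt(self$cramersV, 0.1)

    u <- sample(0:floor(4 * mean(x)), 1000, replace = TRUE)
    mis <- cramersVFit(u, fit)
    expect_gt(mis$cramersV, 2 * self$cramersV)

    expect_equal(cramersVFit(rep(3, 100),
                             list(status = "underdispersed"))$verdict,
                 "untestable")
    expect_equal(cramersVFit(rep(c(0, 1), 50),
                             fit)$verdict, "untestable")
})

test_that("Beta moment fit recovers shape parameters and edge cases", {
    set.seed(66)
    scale <- 1e6
    x <- rbeta(20000, 2, 50) * scale
    bf <- fitBetaPvalue(x, sObs = 0.1 * scale, scale = scale)
    expect_equal(bf$status, "ok")
    expect_lt(abs(bf$a - 2) / 2, 0.15)
    expect_equal(fitBetaPvalue(x, 0, scale)$p, 1)
    expect_equal(fitBetaPvalue(rep(100, 50), 5, scale)$status, "degenerate")
    expect_error(fitBetaPvalue(c(10, 20), 5, scale = 15), "scale")
})

test_that("summarizeCombination populates a consistent record", {
    set.seed(77)
    s <- rnbinom(200, size = 5, prob = 0.1)
    n <- rnbinom(200, size = 5, prob = 0.5)
    st <- summarizeCombination(s, n, Sobs = 120, Nobs = 12, scale = 1e6)
    expect_true(all(c(st$p_nb_S, st$p_empirical_S, st$p_nb_N) >= 0))
    expect_true(all(c(st$p_nb_S, st$p_empirical_S, st$p_nb_N) <= 1))
    expect_equal(st$S_exp_mean, mean(s))
    expect_equal(st$log2_fold_change, log2(120 / mean(s)))

    ## a no-op null (samples identical to the observation)
    st0 <- summarizeCombination(rep(50, 30), rep(5, 30), 50, 5, scale = 1e4)
    expect_equal(st0$log2_fold_change, 0)
    expect_equal(st0$p_empirical_S, 1)
    expect_equal(st0$p_nb_S_flag, "underdispersed")
})

test_that("NB and empirical p-values agree under a well-fitted null", {
    set.seed(88)
    s <- rnbinom(500, size = 10, prob = 0.05)
    fit <- fitNegbinMoments(s)
    expect_equal(cramersVFit(s, fit)$verdict, "good")
    sObs <- quantile(s, 0.8)
    expect_lt(abs(negbinPvalue(fit, sObs) - empiricalPvalue(s, sObs)), 0.05)
})

test_that("superbatch merging pools samples and disables fit assessment", {
    set.seed(31)
    g <- genomeInfo(c(chr1 = 3e4))
    sets <- randomInstance(3, g, n = 15L)
    r1 <- runMonteCarlo(sets, g, config = shuffleConfig(nShuffles = 20L,
                                                        seed = 1L))
    r2 <- runMonteCarlo(sets, g, config = shuffleConfig(nShuffles = 15L,
                                                        seed = 2L))
    m <- mergeRuns(r1, r2)
    expect_equal(m@nShuffles, 35L)
    expect_false(m@fitAssessed)
    expect_setequal(m@codes, union(r1@codes, r2@codes))
    ## pooled moments equal moments of the pooled raw samples
    for (code in intersect(r1@codes, r2@codes)) {
        pooled <- c(shuffledS(r1)[r1@codes == code, ],
                    shuffledS(r2)[r2@codes == code, ])
        expect_equal(mean(shuffledS(m)[m@codes == code, ]), mean(pooled))
        expect_equal(var(shuffledS(m)[m@codes == code, ]), var(pooled))
    }
    ## a combination absent from one run is zero-padded there
    only2 <- setdiff(r2@codes, r1@codes)
    if (length(only2)) {
        row <- shuffledS(m)[m@codes == only2[1], ]
        expect_true(all(row[seq_len(20L)] == 0))
    }
    ## self-merge doubles the sample count and keeps the mean
    mm <- mergeRuns(r1, r1)
    expect_equal(mm@nShuffles, 40L)
    expect_equal(rowMeans(shuffledS(mm))[match(r1@codes, mm@codes)],
                 rowMeans(shuffledS(r1)), ignore_attr = TRUE)
    ## merged summaries flag the fit as not assessed
    expect_true(all(summarizeEnrichment(m)$fit_verdict == "not assessed"))
    ## mismatched set lists refuse to merge
    other <- runMonteCarlo(randomInstance(2, g, n = 10L), g,
                           config = shuffleConfig(nShuffles = 5L, seed = 3L))
    expect_error(mergeRuns(r1, other), "different set lists")
})
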