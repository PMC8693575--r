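test_that("shuffling conserves region-length and gap-length multisets", {
    set.seed(3)
    g <- genomeInfo(c(chr1 = 5e4, chr2 = 2e4))
    for (rep in 1:10) {
        rs <- randomRegionSet("R", g, n = 25L)
        before <- lengthGapMultisets(rs, g)
        sh <- shuffleRegions(rs, g)
        after <- lengthGapMultisets(sh, g)
        for (ch in names(before)) {
            ## fused abutting regions would shorten the vectors; multiset
            ## conservation still holds at the bp level, and when no fusion
            ## happened (the generic case) the multisets match exactly
            if (length(after[[ch]]$lengths) == length(before[[ch]]$lengths)) {
                expect_equal(after[[ch]]$lengths, before[[ch]]$lengths)
                expect_equal(after[[ch]]$gaps, before[[ch]]$gaps)
            } else {
                expect_equal(sum(after[[ch]]$lengths),
                             sum(before[[ch]]$lengths))
            }
        }
        ## output fits chromosome bounds, sorted and merged
        expect_true(isMerged(sh))
        gr <- regions(sh)
        lens <- GenomeInfoDb::seqlengths(g)
        expect_true(all(GenomicRanges::end(gr) <=
                        lens[as.character(GenomeInfoDb::seqnames(gr))]))
        expect_true(all(GenomicRanges::start(gr) >= 1))
    }
})

test_that("a single region admits exactly the two flanking-gap layouts", {
    g <- genomeInfo(c(chr1 = 1000))
    rs <- regionSet("R", "chr1", 300, 400)   # gaps: 300 and 600
    starts <- integer(0)
    set.seed(8)
    for (i in 1:200)
        starts <- c(starts,
                    GenomicRanges::start(regions(shuffleRegions(rs, g))) - 1)
    expect_setequal(unique(starts), c(300, 600))
    expect_true(all(GenomicRanges::width(regions(shuffleRegions(rs, g))) == 100))
})

test_that("Monte Carlo runs are deterministic and batch-invariant", {
    set.seed(15)
    g <- genomeInfo(c(chr1 = 1e5))
    sets <- randomInstance(3, g, n = 40L, maxLen = 300L)
    cfg <- function(bs) shuffleConfig(nShuffles = 30L, seed = 7L,
                                      batchSize = bs)
    r1 <- runMonteCarlo(sets, g, config = cfg(5L))
    r2 <- runMonteCarlo(sets, g, config = cfg(30L))
    r3 <- runMonteCarlo(sets, g, config = cfg(1L))
    expect_identical(shuffledS(r1), shuffledS(r2))
    expect_identical(shuffledS(r1), shuffledS(r3))
    expect_identical(shuffledN(r1), shuffledN(r3))
    expect_equal(ncol(shuffledS(r1)), 30L)
    ## same seed reproduces; different seed does not (generically)
    r4 <- runMonteCarlo(sets, g, config = cfg(5L))
    expect_identical(shuffledS(r1), shuffledS(r4))
    r5 <- runMonteCarlo(sets, g, config = shuffleConfig(nShuffles = 30L,
                                                        seed = 8L))
    expect_false(identical(shuffledS(r1), shuffledS(r5)))
})

test_that("locking all sets reproduces the observed counts in every shuffle", {
    g <- toyGenome()
    sets <- list(toyA(), toyB())
    expect_warning(
        mc <- runMonteCarlo(sets, g,
                            config = shuffleConfig(nShuffles = 20L, seed = 1L,
                                                   lockedSets = c("A", "B"))),
        "locked")
    expect_true(all(shuffledS(mc) == mc@Sobs))
    res <- summarizeEnrichment(mc)
    expect_equal(res$log2_fold_change, 0)
    expect_equal(res$p_empirical_S, 1)
    expect_error(runMonteCarlo(sets, g,
        config = shuffleConfig(lockedSets = "Z")), "lockedSets")
})

test_that("a locked reference keeps its observed positions in shuffles", {
    set.seed(19)
    g <- genomeInfo(c(chr1 = 5e4))
    a <- randomRegionSet("A", g, n = 20L)
    b <- randomRegionSet("B", g, n = 20L)
    mcLock <- runMonteCarlo(list(a, b), g,
        config = shuffleConfig(nShuffles = 10L, seed = 2L, lockedSets = "B"))
    ## with B locked and A shuffled, shuffle S values still vary
    expect_gt(length(unique(as.vector(shuffledS(mcLock)))), 1L)
})

test_that("mean shuffled overlap matches the independent-placement expectation", {
    ## two sets covering fractions f1 and f2 of a 1 Mb chromosome:
    ## E[S(A+B)] ~= f1 * f2 * G under the null
    g <- genomeInfo(c(chr1 = 1e6))
    sim <- generateRegionSets(genome = g, nQuery = 500L, queryLength = 100L,
                              references = data.frame(
                                  name = "B", overlapFraction = 0,
                                  jitter = 0, n = 500L, length = 100L),
                              seed = 23L)
    mc <- runMonteCarlo(sim$sets, g,
                        config = shuffleConfig(nShuffles = 200L, seed = 5L))
    i <- which(mc@codes == 3L)
    s <- shuffledS(mc)[i, ]
    expected <- (500 * 100 / 1e6)^2 * 1e6    # 2500 bp
    se <- sd(s) / sqrt(length(s))
    expect_lt(abs(mean(s) - expected), 3 * se + 0.02 * expected)
})

test_that("shuffle samples are tracked for combinations unseen in truth", {
    set.seed(29)
    g <- genomeInfo(c(chr1 = 2e4))
    sets <- randomInstance(3, g, n = 15L)
    mc <- runMonteCarlo(sets, g, config = shuffleConfig(nShuffles = 50L,
                                                        seed = 3L))
    expect_true(all(dim(shuffledS(mc)) == c(length(mc@codes), 50L)))
    expect_true(all(shuffledS(mc) >= 0))
    ## every truth combination is tracked
    truthCodes <- countTable(countCombinations(
        sweepIntersections(sets, g), "transitive"))$code
    expect_true(all(truthCodes %in% mc@codes))
})
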