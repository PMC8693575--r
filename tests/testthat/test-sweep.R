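test_that("the worked toy pair yields a single 20 bp A+B window", {
    X <- sweepIntersections(list(toyA(), toyB()), toyGenome())
    expect_equal(nrow(overlapFlags(X)), 1L)
    w <- windows(X)
    expect_equal(as.character(GenomeInfoDb::seqnames(w)), "chr1")
    expect_equal(GenomicRanges::start(w) - 1, 500)
    expect_equal(GenomicRanges::end(w), 520)
    expect_equal(GenomicRanges::width(w), 20)
    expect_equal(unname(overlapFlags(X)[1, ]), c(TRUE, TRUE))
})

test_that("disjoint sets and invalid inputs are handled", {
    a <- regionSet("A", "chr1", 0, 100)
    b <- regionSet("B", "chr1", 200, 300)
    X <- sweepIntersections(list(a, b))
    expect_equal(nrow(overlapFlags(X)), 0L)

    expect_error(sweepIntersections(list(a)), "k >= 2")
    unm <- regionSet("U", c("chr1", "chr1"), c(0, 50), c(100, 150),
                     merge = FALSE)
    expect_error(sweepIntersections(list(unm, b)), "unmerged")
    a2 <- regionSet("A", "chr1", 10, 20)
    expect_error(sweepIntersections(list(a, a2)), "duplicate")
})

test_that("abutting intervals from different sets do not overlap", {
    ## half-open semantics: [500,520) and [520,530) share no base pair
    a <- regionSet("A", "chr1", 500, 520)
    b <- regionSet("B", "chr1", 520, 530)
    X <- sweepIntersections(list(a, b))
    expect_equal(nrow(overlapFlags(X)), 0L)
})

test_that("sweep equals the per-base-pair brute-force scan", {
    set.seed(42)
    g <- genomeInfo(c(chr1 = 6000, chr2 = 4000))
    for (rep in 1:20) {
        k <- sample(2:6, 1)
        sets <- randomInstance(k, g, n = sample(5:40, 1))
        X <- sweepIntersections(sets, g)
        bf <- bruteForceCounts(sets, g)
        w <- windows(X)
        expect_equal(as.character(GenomeInfoDb::seqnames(w)), bf$windows$chrom)
        expect_equal(GenomicRanges::start(w) - 1, bf$windows$start0)
        expect_equal(as.numeric(GenomicRanges::end(w)), bf$windows$end0)
        codes <- as.integer(overlapFlags(X) %*% 2^(seq_len(k) - 1))
        expect_equal(codes, bf$windows$code)
    }
})

test_that("sweep agrees with an IRanges disjoin-based computation", {
    ## independent route: disjoin all regions, flag by overlapsAny per set
    set.seed(77)
    g <- genomeInfo(c(chr1 = 1e5))
    sets <- randomInstance(4, g, n = 50L, maxLen = 500L)
    X <- sweepIntersections(sets, g)
    all <- do.call(c, lapply(sets, regions))
    dj <- GenomicRanges::disjoin(all)
    fl <- vapply(sets, function(s)
        IRanges::overlapsAny(dj, regions(s)), logical(length(dj)))
    keep <- rowSums(fl) >= 2
    dj <- dj[keep]; fl <- fl[keep, , drop = FALSE]
    ## merge adjacent disjoint pieces with identical flags (maximality)
    key <- apply(fl, 1, paste, collapse = "")
    brk <- c(TRUE, key[-1] != key[-length(key)] |
                   GenomicRanges::start(dj)[-1] !=
                   GenomicRanges::end(dj)[-length(dj)] + 1)
    grp <- cumsum(brk)
    expSt <- tapply(GenomicRanges::start(dj), grp, min)
    expEn <- tapply(GenomicRanges::end(dj), grp, max)
    w <- windows(X)
    expect_equal(unname(GenomicRanges::start(w)), unname(as.numeric(expSt)))
    expect_equal(unname(as.numeric(GenomicRanges::end(w))),
                 unname(as.numeric(expEn)))
})

test_that("counting is invariant under permutation of input set order", {
    set.seed(99)
    g <- genomeInfo(c(chr1 = 2e4))
    sets <- randomInstance(5, g, n = 25L)
    ref <- countTable(countCombinations(sweepIntersections(sets, g), "exact"))
    refKey <- ref[order(ref$combination), c("S", "N")]
    for (rep in 1:5) {
        perm <- sample(5)
        tab <- countTable(countCombinations(
            sweepIntersections(sets[perm], g), "exact"))
        ## labels render sets in the permuted input order; compare by the
        ## membership (sorted within the label) instead
        canon <- vapply(strsplit(gsub("\\[|\\]|\\.\\.\\.", "",
                                      tab$combination), " \\+ "),
                        function(x) paste(sort(trimws(x)), collapse = "+"),
                        character(1))
        refCanon <- vapply(strsplit(gsub("\\[|\\]|\\.\\.\\.", "",
                                         ref$combination), " \\+ "),
                           function(x) paste(sort(trimws(x)), collapse = "+"),
                           character(1))
        expect_equal(sort(canon), sort(refCanon))
        expect_equal(tab$S[order(canon)], ref$S[order(refCanon)])
        expect_equal(tab$N[order(canon)], ref$N[order(refCanon)])
    }
})

test_that("the intersection matrix exports to TSV with 0/1 flag columns", {
    X <- sweepIntersections(list(toyA(), toyB(), toyC()), toyGenome())
    tf <- withr::local_tempfile(fileext = ".tsv")
    writeIntersectionTsv(X, tf)
    df <- read.delim(tf)
    expect_equal(names(df), c("chrom", "start", "end", "A", "B", "C"))
    expect_equal(df$start, c(500, 510))
    expect_equal(df$end, c(510, 520))
    expect_equal(df$A, c(1L, 1L))
    expect_equal(df$C, c(0L, 1L))
    ## flag columns alone are a valid miner input
    M <- as.matrix(df[, c("A", "B", "C")])
    expect_true(all(M %in% c(0, 1)))
    expect_silent(smotherMatrix(M))
})
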