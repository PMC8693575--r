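test_that("BED reading parses coordinates, ignores extras and sorts", {
    tf <- withr::local_tempfile(fileext = ".bed")
    writeLines(c("chr1\t100\t200\tfeat1\t0\t+", "chr1\t500\t550"), tf)
    rs <- readRegions(tf, "A")
    expect_s4_class(rs, "RegionSet")
    expect_equal(length(rs), 2L)
    expect_equal(totalWidth(rs), 150)

    ## shuffled lines on disk come back sorted by (chrom, start)
    set.seed(5)
    chrom <- sample(c("chr1", "chr2", "chr3"), 1000, replace = TRUE)
    start <- sample.int(100000, 1000)
    lines <- sprintf("%s\t%d\t%d", chrom, start, start + 50L)
    writeLines(sample(lines), tf)
    rs <- readRegions(tf, "R", merge = FALSE)
    gr <- regions(rs)
    o <- order(as.character(GenomeInfoDb::seqnames(gr)),
               GenomicRanges::start(gr))
    expect_equal(o, seq_along(gr))
    expect_equal(sort(GenomicRanges::start(gr) - 1), sort(start))
})

test_that("BED reading handles empty input and rejects malformed lines", {
    tf <- withr::local_tempfile(fileext = ".bed")
    writeLines(character(0), tf)
    expect_equal(length(readRegions(tf, "E")), 0L)

    writeLines(c("chr1\t100\t200", "chr1\tx\t300"), tf)
    expect_error(readRegions(tf, "A"), "line 2")
    writeLines(c("chr1\t100"), tf)
    expect_error(readRegions(tf, "A"), "line 1")
    writeLines(c("chr1\t200\t200"), tf)
    expect_error(readRegions(tf, "A"), "start")
    expect_error(readRegions(tempfile(), "A"), "not found")
})

test_that("BED write/read round-trips sorted merged sets byte-identically", {
    set.seed(11)
    g <- genomeInfo(c(chr1 = 5e4, chr2 = 3e4))
    rs <- randomRegionSet("R", g, n = 200L)
    f1 <- withr::local_tempfile(fileext = ".bed")
    f2 <- withr::local_tempfile(fileext = ".bed")
    writeRegions(rs, f1)
    writeRegions(readRegions(f1, "R"), f2)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("chromosome-sizes parsing validates its input", {
    tf <- withr::local_tempfile()
    writeLines(c("chr1 1000000", "chr2 500000"), tf)
    g <- readChromSizes(tf)
    expect_equal(length(GenomeInfoDb::seqlengths(g)), 2L)
    expect_equal(unname(GenomeInfoDb::seqlengths(g)[["chr1"]]), 1000000L)

    writeLines(character(0), tf)
    expect_error(readChromSizes(tf), "no chromosomes")
    writeLines(c("chr1 1000", "chr1 2000"), tf)
    expect_error(readChromSizes(tf), "duplicate")
    writeLines(c("chr1 abc"), tf)
    expect_error(readChromSizes(tf), "non-integer")
})

test_that("region validation enforces genome bounds and coordinates", {
    g <- toyGenome()
    expect_error(regionSet("A", "chr9", 0, 10, genome = g), "chr9")
    expect_error(regionSet("A", "chr1", 900, 1100, genome = g), "exceed")
    expect_error(regionSet("A", "chr1", -5, 10), ">= 0")
    expect_error(regionSet("A", "chr1", 10, 10), "end")
})

test_that("merging fuses overlapping and abutting regions, conserving bp", {
    rs <- regionSet("A", c("chr1", "chr1"), c(100, 150), c(200, 250),
                    merge = FALSE)
    m <- mergeRegions(rs)
    expect_equal(length(m), 1L)
    expect_equal(totalWidth(m), 150)

    rs <- regionSet("A", c("chr1", "chr1"), c(100, 200), c(200, 300),
                    merge = FALSE)
    m <- mergeRegions(rs)
    expect_equal(length(m), 1L)
    expect_equal(totalWidth(m), 200)

    ## covered bp of the merge equals a per-base-pair coverage count
    set.seed(21)
    g <- genomeInfo(c(chr1 = 5000, chr2 = 5000))
    chrom <- sample(c("chr1", "chr2"), 500, replace = TRUE)
    start <- sample.int(4800, 500, replace = TRUE) - 1
    len <- sample.int(150, 500, replace = TRUE)
    end <- pmin(start + len, 5000)
    rs <- regionSet("R", chrom, start, end, merge = FALSE)
    m <- mergeRegions(rs)
    covered <- 0L
    for (ch in c("chr1", "chr2")) {
        v <- logical(5000)
        sel <- chrom == ch
        for (i in which(sel)) v[(start[i] + 1):end[i]] <- TRUE
        covered <- covered + sum(v)
    }
    expect_equal(totalWidth(m), covered)
    expect_true(isMerged(m))
})

test_that("sub-genome restriction remaps, discards and inverts correctly", {
    g <- genomeInfo(c(chr1 = 1000))
    rs <- regionSet("A", "chr1", 100, 300)
    incl <- regionSet("incl", c("chr1", "chr1"), c(0, 250), c(150, 400))
    sub <- subgenomeRestrict(list(rs), incl, g)
    expect_equal(genomeSize(sub$genome), 300)     # 150 + 150 bp of blocks
    frag <- regions(sub$sets[[1]])
    ## retained parts: [100,150) (50 bp) and [250,300) (50 bp); the middle
    ## [150,250) is discarded. In pseudo-chromosome coordinates the two
    ## fragments land at [100,150) and [150,200): they abut across the
    ## block seam and are fused, preserving the 50 + 50 retained bp
    expect_equal(sum(GenomicRanges::width(frag)), 100)
    expect_equal(GenomicRanges::start(frag) - 1, 100)
    expect_equal(as.numeric(GenomicRanges::end(frag)), 200)

    ## inverse mapping returns the intersected fragments in source coords
    back <- mapFromSubgenome(sub$sets[[1]], sub$map, g)
    b <- regions(back)
    expect_equal(GenomicRanges::start(b) - 1, c(100, 250))
    expect_equal(GenomicRanges::end(b), c(150, 300))

    ## region entirely outside the inclusion blocks disappears
    out <- regionSet("B", "chr1", 160, 240)
    sub2 <- subgenomeRestrict(list(out), incl, g)
    expect_equal(length(sub2$sets[[1]]), 0L)

    ## whole-genome inclusion is an identity remap (offset 0)
    whole <- regionSet("w", "chr1", 0, 1000)
    sub3 <- subgenomeRestrict(list(rs), whole, g)
    expect_equal(GenomicRanges::start(regions(sub3$sets[[1]])),
                 GenomicRanges::start(regions(rs)))
    expect_equal(genomeSize(sub3$genome), 1000)

    expect_error(subgenomeRestrict(list(rs),
                                   regionSet("e", character(0), numeric(0),
                                             numeric(0)), g),
                 "empty")
    expect_error(subgenomeRestrict(list(rs),
                                   regionSet("e", "chr1", 900, 1200), g),
                 "exceed")
})

test_that("random sub-genome restrictions invert exactly", {
    set.seed(31)
    g <- genomeInfo(c(chr1 = 2e4, chr2 = 1e4))
    for (rep in 1:10) {
        rs <- randomRegionSet("R", g, n = 40L)
        incl <- randomRegionSet("incl", g, n = 10L, maxLen = 2000L)
        sub <- subgenomeRestrict(list(rs), incl, g)
        back <- mergeRegions(mapFromSubgenome(sub$sets[[1]], sub$map, g))
        expected <- GenomicRanges::reduce(
            GenomicRanges::intersect(regions(rs), regions(incl)),
            min.gapwidth = 1L)
        expect_equal(GenomicRanges::start(regions(back)),
                     GenomicRanges::start(expected))
        expect_equal(GenomicRanges::end(regions(back)),
                     GenomicRanges::end(expected))
    }
})
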