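## Shared fixtures: the worked toy sets, random region-set instances and
## small utilities. All fixtures are built in code; nothing is read from
## disk except through temp files created by the tests themselves.

toyGenome <- function() genomeInfo(c(chr1 = 1000, chr2 = 1000))

## A = {chr1:[100,200), chr1:[500,550)}, B = {chr1:[480,520), chr2:[100,210)}
toyA <- function() regionSet("A", c("chr1", "chr1"), c(100, 500), c(200, 550))
toyB <- function() regionSet("B", c("chr1", "chr2"), c(480, 100), c(520, 210))
toyC <- function() regionSet("C", "chr1", 510, 520)

## random merged region set on a given genome (uses the caller's RNG state)
randomRegionSet <- function(name, genome, n = 30L, maxLen = 200L) {
    lens <- GenomeInfoDb::seqlengths(genome)
    chrom <- sample(names(lens), n, replace = TRUE)
    len <- sample.int(maxLen, n, replace = TRUE)
    start <- floor(runif(n) * (as.numeric(lens[chrom]) - len))
    regionSet(name, chrom, start, start + len, genome = genome)
}

randomInstance <- function(k, genome, n = 30L, maxLen = 200L) {
    lapply(seq_len(k), function(i)
        randomRegionSet(paste0("S", i), genome, n = n, maxLen = maxLen))
}

## per-chromosome sorted region-length and gap-length multisets of a set,
## computed directly from the GRanges (independent of the shuffler's
## internal bookkeeping)
lengthGapMultisets <- function(rs, genome) {
    gr <- regions(rs)
    lens <- GenomeInfoDb::seqlengths(genome)
    out <- list()
    for (ch in unique(as.character(GenomeInfoDb::seqnames(gr)))) {
        sel <- as.character(GenomeInfoDb::seqnames(gr)) == ch
        s0 <- GenomicRanges::start(gr)[sel] - 1
        e0 <- GenomicRanges::end(gr)[sel]
        m <- length(s0)
        out[[ch]] <- list(
            lengths = sort(e0 - s0),
            gaps = sort(c(s0[1], s0[-1] - e0[-m], lens[[ch]] - e0[m])))
    }
    out
}

plantedMembers <- c("A,B", "A,B,C,D", "E,F")
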