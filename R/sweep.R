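## Sweep-line computation of the intersection matrix.
##
## Critical points (region starts/ends) from all sets are sorted once per
## chromosome; a cumulative bit-coded open count then yields, in a single
## linear pass, every maximal window on which a constant subset of sets is
## open. Total work is O(N log N) in the total number of regions, dominated
## by the sort. At an identical coordinate, close events are processed
## before open events, so half-open abutting intervals from different sets
## do not overlap.

## internal per-chromosome sweep on 0-based half-open coordinates.
## pos: event positions; delta: +bit for an open, -bit for a close.
## Returns a list(start0, end0, code) of maximal windows with >= 2 open sets.
.sweepChrom <- function(pos, delta) {
    o <- order(pos, delta)          # ties: closes (negative) first
    pos <- pos[o]; cum <- cumsum(delta[o])
    keep <- !duplicated(pos, fromLast = TRUE)   # state after all events at pos
    pu <- pos[keep]; cu <- cum[keep]
    n <- length(pu)
    chg <- c(TRUE, cu[-1L] != cu[-n])           # run starts (maximality)
    rs <- pu[chg]; rv <- cu[chg]
    m <- length(rs)
    re <- c(rs[-1L], pu[n])                      # run m has value 0, dropped below
    sel <- .popcount(rv) >= 2L
    list(start0 = rs[sel], end0 = re[sel], code = rv[sel])
}

.popcount <- function(code) {
    out <- integer(length(code))
    code <- as.integer(code)
    while (any(code > 0L)) {
        out <- out + (code %% 2L)
        code <- code %/% 2L
    }
    out
}

.codesToFlags <- function(codes, k) {
    m <- vapply(seq_len(k),
                function(i) bitwAnd(as.integer(codes), bitwShiftL(1L, i - 1L)) > 0L,
                logical(length(codes)))
    if (is.null(dim(m))) m <- matrix(m, nrow = length(codes))
    m
}

.flagsToCode <- function(flags) {
    if (is.null(dim(flags))) flags <- matrix(flags, nrow = 1L)
    as.integer(flags %*% bitwShiftL(1L, seq_len(ncol(flags)) - 1L))
}

## internal: per-chromosome interval lists for a list of RegionSets,
## 0-based half-open. Returns list(chrom -> list(start0, end0, set)).
.setsToChromTable <- function(sets) {
    per <- lapply(seq_along(sets), function(i) {
        gr <- sets[[i]]@regions
        data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start0 = GenomicRanges::start(gr) - 1,
                   end0 = as.numeric(GenomicRanges::end(gr)),
                   set = i)
    })
    tab <- do.call(rbind, per)
    split(tab, tab$chrom)
}

## internal sweep over a chrom table (as produced by .setsToChromTable or the
## Monte Carlo fast path). Returns data.frame(chrom, start0, end0, code).
.sweepTable <- function(byChrom) {
    res <- lapply(names(byChrom), function(ch) {
        tb <- byChrom[[ch]]
        bit <- bitwShiftL(1L, tb$set - 1L)
        sw <- .sweepChrom(c(tb$start0, tb$end0), c(bit, -bit))
        if (!length(sw$code)) return(NULL)
        data.frame(chrom = ch, start0 = sw$start0, end0 = sw$end0,
                   code = sw$code)
    })
    res <- res[!vapply(res, is.null, logical(1))]
    if (!length(res))
        return(data.frame(chrom = character(0), start0 = numeric(0),
                          end0 = numeric(0), code = integer(0)))
    out <- do.call(rbind, res)
    out[order(out$chrom, out$start0), , drop = FALSE]
}

#' Compute the intersection matrix of k region sets
#'
#' Runs the sweep-line algorithm over \code{k >= 2} merged region sets and
#' returns every maximal genomic window on which at least two sets are
#' simultaneously open, with one boolean open flag per set.
#'
#' @param sets list of merged \code{\linkS4class{RegionSet}} objects
#'   (\code{k >= 2}); an unmerged set is an error, since its open state
#'   could exceed one.
#' @param genome optional \code{Seqinfo}; when supplied, all regions are
#'   validated against it.
#' @return an \code{\linkS4class{IntersectionMatrix}}.
#' @examples
#' a <- regionSet("A", c("chr1", "chr1"), c(100, 500), c(200, 550))
#' b <- regionSet("B", c("chr1", "chr2"), c(480, 100), c(520, 210))
#' sweepIntersections(list(a, b))   # one window: chr1:[500,520), A+B
#' @export
sweepIntersections <- function(sets, genome = NULL) {
    if (!is.list(sets) || length(sets) < 2L)
        stop("need a list of k >= 2 RegionSets")
    ok <- vapply(sets, function(s) methods::is(s, "RegionSet"), logical(1))
    if (!all(ok)) stop("all elements of 'sets' must be RegionSet objects")
    if (length(sets) > 30L)
        stop("at most 30 sets are supported")
    nm <- vapply(sets, regionName, character(1))
    if (anyDuplicated(nm)) stop("duplicate set names: ",
                                paste(nm[duplicated(nm)], collapse = ", "))
    unmerged <- !vapply(sets, isMerged, logical(1))
    if (any(unmerged))
        stop("unmerged set(s): ", paste(nm[unmerged], collapse = ", "),
             "; call mergeRegions() first")
    if (!is.null(genome))
        for (s in sets) .checkAgainstGenome(s@regions, genome, s@name)
    tab <- .sweepTable(.setsToChromTable(sets))
    .newIntersectionMatrix(tab, nm, genome)
}

.newIntersectionMatrix <- function(tab, setNames, genome = NULL) {
    k <- length(setNames)
    if (nrow(tab)) {
        gr <- GenomicRanges::GRanges(tab$chrom,
                                     IRanges::IRanges(tab$start0 + 1, tab$end0))
        flags <- .codesToFlags(tab$code, k)
        if (is.null(dim(flags))) flags <- matrix(flags, nrow = 1L)
    } else {
        gr <- GenomicRanges::GRanges()
        flags <- matrix(logical(0), nrow = 0L, ncol = k)
    }
    if (!is.null(genome)) {
        GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(genome)
        GenomeInfoDb::seqinfo(gr) <- genome
    }
    colnames(flags) <- setNames
    methods::new("IntersectionMatrix", windows = gr, flags = flags,
                 setNames = setNames)
}

#' Export / import an intersection matrix as TSV
#'
#' Writes one row per overlap window: \code{chrom}, \code{start}, \code{end}
#' (0-based half-open) and one 0/1 column per set. This is the programmatic
#' surface for external itemset mining: the flag columns alone form the
#' binary overlap matrix accepted by \code{\link{mineItemsets}}.
#'
#' @param X an \code{\linkS4class{IntersectionMatrix}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeIntersectionTsv <- function(X, path) {
    stopifnot(methods::is(X, "IntersectionMatrix"))
    gr <- X@windows
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1,
                     end = GenomicRanges::end(gr))
    df <- cbind(df, as.data.frame(X@flags + 0L))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
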