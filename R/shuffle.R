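## Monte Carlo null model. Each non-locked set is shuffled per chromosome by
## independently permuting its multiset of region lengths and its multiset of
## inter-region gap lengths (including the two flanking gaps to the
## chromosome ends), then laying the permuted series end to start. Region
## positions are therefore NOT uniformly redrawn: the inter-region distance
## distribution of the input is preserved, which is the null model's defining
## property. Regions that abut after shuffling (a zero-length gap drawn
## between them) are fused before counting, consistent with merged-set
## semantics.

#' Shuffle configuration for the Monte Carlo null
#'
#' @param nShuffles number of shuffles (default 200; one to two hundred
#'   shuffles are enough for a stable method-of-moments Negative Binomial
#'   fit).
#' @param seed integer master seed. One independent substream is derived per
#'   (shuffle, set) pair, so results are identical for any batch size and
#'   set processing order.
#' @param lockedSets character vector of set names whose regions are kept
#'   fixed (not shuffled).
#' @param batchSize shuffles per processing batch (memory bookkeeping only;
#'   results are independent of it).
#' @return a list with class \code{"ShuffleConfig"}.
#' @export
shuffleConfig <- function(nShuffles = 200L, seed = 1L,
                          lockedSets = character(0), batchSize = 50L) {
    nShuffles <- as.integer(nShuffles); batchSize <- as.integer(batchSize)
    seed <- as.integer(seed)
    if (is.na(nShuffles) || nShuffles < 1L) stop("nShuffles must be >= 1")
    if (is.na(batchSize) || batchSize < 1L) stop("batchSize must be >= 1")
    if (is.na(seed)) stop("seed must be an integer")
    structure(list(nShuffles = nShuffles, seed = seed,
                   lockedSets = as.character(lockedSets),
                   batchSize = batchSize),
              class = "ShuffleConfig")
}

## run fn with a temporary RNG state seeded at `seed`
.withSeed <- function(seed, fn) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    fn()
}

## internal per-chromosome layout: permute widths and gaps, lay end to
## start, fuse abutting regions. Returns list(start0, end0).
.shuffleChromLayout <- function(w, g) {
    m <- length(w)
    wp <- if (m > 1L) w[sample.int(m)] else w
    gp <- g[sample.int(m + 1L)]
    start0 <- cumsum(gp[seq_len(m)]) + c(0, cumsum(wp[-m]))
    end0 <- start0 + wp
    if (m > 1L) {
        grp <- cumsum(c(TRUE, start0[-1L] > end0[-m]))
        start0 <- start0[!duplicated(grp)]
        end0 <- tapply(end0, grp, max)
    }
    list(start0 = as.numeric(start0), end0 = as.numeric(end0))
}

## decompose one set into per-chromosome widths and gap series.
.chromSeries <- function(rs, genome) {
    gr <- rs@regions
    chroms <- as.character(GenomeInfoDb::seqnames(gr))
    lens <- GenomeInfoDb::seqlengths(genome)
    out <- list()
    for (ch in unique(chroms)) {
        sel <- chroms == ch
        s0 <- GenomicRanges::start(gr)[sel] - 1
        e0 <- as.numeric(GenomicRanges::end(gr)[sel])
        L <- as.numeric(lens[[ch]])
        w <- e0 - s0
        if (any(w > L))
            stop("set '", rs@name, "': region longer than chromosome ", ch)
        m <- length(s0)
        g <- c(s0[1L], s0[-1L] - e0[-m], L - e0[m])
        out[[ch]] <- list(w = w, g = g)
    }
    out
}

#' Shuffle one region set under the null model
#'
#' Per chromosome, permutes the multiset of region lengths and the multiset
#' of inter-region gap lengths independently of each other (two separate
#' series) and lays them out end to start. Both multisets are exactly
#' conserved; shuffled regions always fit within chromosome bounds. Uses
#' the caller's RNG state (seed externally for reproducibility).
#'
#' @param rs a merged \code{\linkS4class{RegionSet}}.
#' @param genome \code{Seqinfo} governing the chromosome lengths.
#' @return a sorted, merged \code{RegionSet} with the same name.
#' @export
shuffleRegions <- function(rs, genome) {
    stopifnot(methods::is(rs, "RegionSet"), methods::is(genome, "Seqinfo"))
    if (!rs@merged) stop("shuffleRegions requires a merged RegionSet")
    if (!length(rs@regions)) return(rs)
    .checkAgainstGenome(rs@regions, genome, rs@name)
    ser <- .chromSeries(rs, genome)
    parts <- lapply(names(ser), function(ch) {
        lay <- .shuffleChromLayout(ser[[ch]]$w, ser[[ch]]$g)
        GenomicRanges::GRanges(ch, IRanges::IRanges(lay$start0 + 1, lay$end0),
                               seqinfo = genome)
    })
    gr <- GenomicRanges::sort(do.call(c, parts))
    methods::new("RegionSet", name = rs@name, regions = gr, merged = TRUE)
}

#' Run the Monte Carlo shuffling null model
#'
#' Shuffles every non-locked set \code{nShuffles} times (independent
#' substream per shuffle and per set), recomputes the sweep-line
#' intersections and the per-combination S / N counts for each shuffle, and
#' collects them together with the observed counts. Combinations tracked
#' are the union of those observed in the true data and in any shuffle
#' (plus any explicitly requested ones); a combination absent from a
#' shuffle contributes 0 to that shuffle's sample.
#'
#' @param sets list of merged \code{\linkS4class{RegionSet}}s (k >= 2).
#' @param genome \code{Seqinfo}; shuffling happens within its chromosome
#'   bounds (pass the sub-genome when a restriction is active, see
#'   \code{\link{subgenomeRestrict}}).
#' @param queryIndex optional query-set index; only combinations containing
#'   the query are tracked.
#' @param config a \code{\link{shuffleConfig}}.
#' @param mode counting mode, \code{"transitive"} (default) or
#'   \code{"exact"}.
#' @param combinations optional explicit combination selection (see
#'   \code{\link{countCombinations}}), e.g. from \code{\link{mineItemsets}}.
#' @return a \code{\linkS4class{MonteCarloResult}}.
#' @seealso \code{\link{summarizeEnrichment}} to fit the Negative Binomial
#'   model and compute p-values.
#' @export
runMonteCarlo <- function(sets, genome, queryIndex = NULL,
                          config = shuffleConfig(),
                          mode = c("transitive", "exact"),
                          combinations = NULL) {
    mode <- match.arg(mode)
    if (!inherits(config, "ShuffleConfig")) stop("config must be a shuffleConfig()")
    if (!is.list(sets) || length(sets) < 2L) stop("need k >= 2 region sets")
    stopifnot(methods::is(genome, "Seqinfo"))
    k <- length(sets)
    nm <- vapply(sets, regionName, character(1))
    unknown <- setdiff(config$lockedSets, nm)
    if (length(unknown))
        stop("lockedSets name(s) not among the sets: ",
             paste(unknown, collapse = ", "))
    locked <- nm %in% config$lockedSets
    if (all(locked))
        warning("all sets are locked: the null model is degenerate ",
                "(every shuffle reproduces the observed data)")
    if (!is.null(queryIndex)) {
        queryIndex <- as.integer(queryIndex)
        if (queryIndex < 1L || queryIndex > k) stop("queryIndex out of range")
    }
    for (s in sets) {
        if (!methods::is(s, "RegionSet")) stop("sets must be RegionSet objects")
        if (!s@merged) stop("set '", s@name, "' is not merged")
        .checkAgainstGenome(s@regions, genome, s@name)
    }

    ## observed intersections
    truth <- .sweepTable(.setsToChromTable(sets))
    truthAdj <- .tableAdjacency(truth)

    ## per-set per-chromosome length/gap series for the fast shuffle path
    series <- lapply(sets, .chromSeries, genome = genome)
    lockedTab <- lapply(sets, function(s) {
        gr <- s@regions
        split(data.frame(start0 = GenomicRanges::start(gr) - 1,
                         end0 = as.numeric(GenomicRanges::end(gr))),
              as.character(GenomeInfoDb::seqnames(gr)))
    })

    nsh <- config$nShuffles
    seedMat <- .withSeed(config$seed, function()
        matrix(sample.int(.Machine$integer.max - 1L, nsh * k, replace = TRUE),
               nrow = nsh, ncol = k))

    shuffleRows <- vector("list", nsh)
    batches <- split(seq_len(nsh), ceiling(seq_len(nsh) / config$batchSize))
    for (batch in batches) {
        for (i in batch) {
            ev <- list()   # chrom -> list(pos, delta)
            for (j in seq_len(k)) {
                bit <- bitwShiftL(1L, j - 1L)
                if (locked[j]) {
                    for (ch in names(lockedTab[[j]])) {
                        tb <- lockedTab[[j]][[ch]]
                        ev[[ch]]$pos <- c(ev[[ch]]$pos, tb$start0, tb$end0)
                        ev[[ch]]$delta <- c(ev[[ch]]$delta,
                                            rep(bit, nrow(tb)),
                                            rep(-bit, nrow(tb)))
                    }
                } else {
                    ser <- series[[j]]
                    lays <- .withSeed(seedMat[i, j], function()
                        lapply(ser, function(sc)
                            .shuffleChromLayout(sc$w, sc$g)))
                    for (ch in names(lays)) {
                        lay <- lays[[ch]]
                        nreg <- length(lay$start0)
                        ev[[ch]]$pos <- c(ev[[ch]]$pos, lay$start0, lay$end0)
                        ev[[ch]]$delta <- c(ev[[ch]]$delta,
                                            rep(bit, nreg), rep(-bit, nreg))
                    }
                }
            }
            rows <- lapply(names(ev), function(ch) {
                sw <- .sweepChrom(ev[[ch]]$pos, ev[[ch]]$delta)
                if (!length(sw$code)) return(NULL)
                list(chrom = ch, start0 = sw$start0, end0 = sw$end0,
                     code = sw$code)
            })
            rows <- rows[!vapply(rows, is.null, logical(1))]
            shuffleRows[[i]] <- .flattenShuffle(rows)
        }
    }

    trackedExtra <- .resolveCombinations(combinations, nm)
    seen <- unlist(lapply(shuffleRows, function(x) unique(x$code)))
    tracked <- sort(unique(c(truth$code, seen, trackedExtra)))
    if (!is.null(queryIndex)) {
        qbit <- bitwShiftL(1L, queryIndex - 1L)
        tracked <- tracked[bitwAnd(tracked, qbit) > 0L]
    }

    Smat <- matrix(0, nrow = length(tracked), ncol = nsh)
    Nmat <- matrix(0, nrow = length(tracked), ncol = nsh)
    for (i in seq_len(nsh)) {
        sr <- shuffleRows[[i]]
        if (!length(sr$code)) next
        cc <- .countCodes(sr$code, sr$width, sr$adj, tracked, mode)
        Smat[, i] <- cc$S
        Nmat[, i] <- cc$N
    }
    obs <- .countCodes(truth$code, truth$end0 - truth$start0, truthAdj,
                       tracked, mode)
    methods::new("MonteCarloResult",
                 setNames = nm, mode = mode, codes = tracked,
                 Sobs = obs$S, Nobs = obs$N, S = Smat, N = Nmat,
                 nShuffles = nsh, seed = config$seed,
                 queryIndex = if (is.null(queryIndex)) NA_integer_ else queryIndex,
                 genomeSize = genomeSize(genome), fitAssessed = TRUE)
}

## adjacency vector for a sweep table in genomic order
.tableAdjacency <- function(tab) {
    m <- nrow(tab)
    if (m < 2L) return(logical(0))
    tab$chrom[-1L] == tab$chrom[-m] & tab$start0[-1L] == tab$end0[-m]
}

## flatten a list of per-chromosome window lists into parallel vectors with
## a cross-window adjacency vector (FALSE across chromosome boundaries).
.flattenShuffle <- function(rows) {
    if (!length(rows))
        return(list(code = integer(0), width = numeric(0), adj = logical(0)))
    code <- unlist(lapply(rows, `[[`, "code"), use.names = FALSE)
    width <- unlist(lapply(rows, function(r) r$end0 - r$start0),
                    use.names = FALSE)
    adj <- unlist(lapply(rows, function(r) {
        n <- length(r$code)
        if (n < 2L) return(logical(max(n - 1L, 0L)))
        r$start0[-1L] == r$end0[-n]
    }), use.names = FALSE)
    ## insert FALSE between chromosome chunks
    sizes <- vapply(rows, function(r) length(r$code), integer(1))
    if (length(sizes) > 1L) {
        adjFull <- logical(sum(sizes) - 1L)
        pos <- 1L; src <- 1L
        for (b in seq_along(sizes)) {
            n <- sizes[b]
            if (n > 1L) {
                adjFull[pos:(pos + n - 2L)] <- adj[src:(src + n - 2L)]
                src <- src + n - 1L
            }
            pos <- pos + n
        }
        adj <- adjFull
    }
    list(code = code, width = width, adj = adj)
}
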