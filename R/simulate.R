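## Synthetic data with known ground truth: artificial BED region sets with
## controlled association structure, planted-itemset binary matrices with
## uniform flip noise, and a per-base-pair brute-force counting oracle.

## uniform placement of n non-overlapping regions of length len on [0, L):
## order statistics of n uniforms on [0, L - n*len], shifted — the standard
## construction for a uniform draw over non-overlapping configurations.
.placeUniform <- function(n, len, L) {
    if (n == 0L) return(numeric(0))
    slack <- L - n * len
    if (slack < 0) stop("infeasible density: ", n, " x ", len,
                        " bp does not fit in ", L, " bp")
    u <- sort(stats::runif(n, 0, slack))
    u + (seq_len(n) - 1) * len
}

## allocate n regions to chromosomes proportionally to length, then place
## uniformly per chromosome. Returns data.frame(chrom, start0, end0).
.placeOnGenome <- function(n, len, genome) {
    lens <- GenomeInfoDb::seqlengths(genome)
    alloc <- as.vector(stats::rmultinom(1, n, prob = as.numeric(lens)))
    parts <- lapply(seq_along(lens), function(i) {
        if (alloc[i] == 0L) return(NULL)
        s0 <- .placeUniform(alloc[i], len, as.numeric(lens[i]))
        data.frame(chrom = names(lens)[i], start0 = floor(s0),
                   end0 = floor(s0) + len)
    })
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (!length(parts))
        return(data.frame(chrom = character(0), start0 = numeric(0),
                          end0 = numeric(0)))
    do.call(rbind, parts)
}

#' Generate artificial region sets with controlled association
#'
#' Builds a query set placed uniformly at random (non-overlapping regions)
#' and one reference set per row of \code{references}. A reference with
#' \code{overlapFraction = f} copies a fraction f of the query's regions
#' (each copy shifted by an independent uniform jitter in \code{[-jitter,
#' +jitter]} bp) and fills the remainder independently; a reference with
#' \code{f = 0} is a fully independent negative control.
#'
#' @param genome \code{Seqinfo}; default a single 10 Mb chromosome.
#' @param nQuery number of query regions (default 1000).
#' @param queryLength query region length in bp (default 100).
#' @param references data.frame with columns \code{name},
#'   \code{overlapFraction} (in [0,1]), \code{jitter} (bp), \code{n},
#'   \code{length}; default three independent 1000 x 100 bp references.
#' @param seed integer seed; the generator is a pure function of it.
#' @return list with \code{sets} (query first, then references, as merged
#'   \code{\linkS4class{RegionSet}}s) and \code{truth} (the design table).
#' @export
generateRegionSets <- function(genome = genomeInfo(c(chr1 = 1e7)),
                               nQuery = 1000L, queryLength = 100L,
                               references = data.frame(
                                   name = c("B", "C", "D"),
                                   overlapFraction = 0,
                                   jitter = 0,
                                   n = 1000L, length = 100L),
                               seed = 1L) {
    stopifnot(methods::is(genome, "Seqinfo"))
    if (any(references$overlapFraction < 0 | references$overlapFraction > 1))
        stop("overlapFraction must be in [0, 1]")
    totalLen <- genomeSize(genome)
    dens <- max(nQuery * queryLength,
                references$n * references$length) / totalLen
    if (dens > 0.5)
        stop("infeasible density: sets would cover more than half the genome")
    .withSeed(as.integer(seed), function() {
        qtab <- .placeOnGenome(nQuery, queryLength, genome)
        query <- regionSet("query", qtab$chrom, qtab$start0, qtab$end0,
                           genome = genome)
        refs <- lapply(seq_len(nrow(references)), function(i) {
            rf <- references[i, ]
            nCopy <- round(rf$overlapFraction * nrow(qtab))
            nCopy <- min(nCopy, rf$n)
            copy <- NULL
            if (nCopy > 0L) {
                pick <- qtab[sample.int(nrow(qtab), nCopy), , drop = FALSE]
                shift <- if (rf$jitter > 0)
                    round(stats::runif(nCopy, -rf$jitter, rf$jitter))
                    else 0
                s0 <- pmax(0, pick$start0 + shift)
                lens <- GenomeInfoDb::seqlengths(genome)[pick$chrom]
                s0 <- pmin(s0, as.numeric(lens) - (pick$end0 - pick$start0))
                copy <- data.frame(chrom = pick$chrom, start0 = s0,
                                   end0 = s0 + (pick$end0 - pick$start0))
            }
            fill <- .placeOnGenome(rf$n - nCopy, rf$length, genome)
            tab <- rbind(copy, fill)
            regionSet(rf$name, tab$chrom, tab$start0, tab$end0,
                      genome = genome)
        })
        truth <- data.frame(name = c("query", references$name),
                            overlapFraction = c(NA, references$overlapFraction),
                            jitter = c(NA, references$jitter),
                            n = c(nQuery, references$n),
                            length = c(queryLength, references$length),
                            negativeControl = c(NA,
                                references$overlapFraction == 0))
        list(sets = c(list(query), refs), truth = truth)
    })
}

#' Generate a planted-complex binary overlap matrix
#'
#' Each row is drawn from one planted complex (per the abundance weights)
#' as that complex's membership indicator over the k items; every cell is
#' then flipped independently with probability \code{noiseRate} (uniform
#' bit-flip noise). The default fixture mirrors the standard mining test
#' bed: complexes AB, ABCD and EF over k = 6 items in comparable
#' abundances, with two of the complexes overlapping (AB is a subset of
#' ABCD).
#'
#' @param k number of items (sets).
#' @param itemNames item labels, default \code{LETTERS[1:k]}.
#' @param complexes list of character vectors (item names) or integer
#'   vectors (item indices); every complex needs at least one item.
#' @param abundances positive weights, one per complex (normalized to
#'   sum 1).
#' @param m number of rows.
#' @param noiseRate per-cell flip probability in [0, 1).
#' @param seed integer seed; the generator is a pure function of it.
#' @return list with \code{X} (the m x k binary matrix), \code{assignments}
#'   (the generating complex of each row) and \code{truth} (data.frame of
#'   complex memberships, codes and abundances).
#' @export
generateOverlapMatrix <- function(k = 6L, itemNames = LETTERS[seq_len(k)],
                                  complexes = list(c("A", "B"),
                                                   c("A", "B", "C", "D"),
                                                   c("E", "F")),
                                  abundances = c(1, 1, 1) / 3,
                                  m = 1000L, noiseRate = 0, seed = 1L) {
    k <- as.integer(k)
    if (length(itemNames) != k) stop("itemNames must have length k")
    if (length(abundances) != length(complexes))
        stop("one abundance per complex required")
    if (any(abundances <= 0)) stop("abundances must be positive")
    if (noiseRate < 0 || noiseRate >= 1) stop("noiseRate must be in [0, 1)")
    flagList <- lapply(complexes, function(cx) {
        if (is.character(cx)) {
            bad <- setdiff(cx, itemNames)
            if (length(bad)) stop("unknown item(s): ",
                                  paste(bad, collapse = ", "))
            itemNames %in% cx
        } else {
            if (max(cx) > k) stop("complex item index exceeds k")
            seq_len(k) %in% cx
        }
    })
    if (any(!vapply(flagList, any, logical(1))))
        stop("every complex needs at least one item")
    abundances <- abundances / sum(abundances)
    .withSeed(as.integer(seed), function() {
        z <- sample.int(length(complexes), m, replace = TRUE,
                        prob = abundances)
        X <- do.call(rbind, flagList)[z, , drop = FALSE] + 0
        if (noiseRate > 0) {
            flips <- matrix(stats::runif(m * k) < noiseRate, m, k)
            X <- (X + flips) %% 2
        }
        colnames(X) <- itemNames
        truth <- data.frame(
            members = vapply(flagList, function(f)
                paste(itemNames[f], collapse = ","), character(1)),
            code = vapply(flagList, .flagsToCode, integer(1)),
            abundance = abundances)
        list(X = X, assignments = z, truth = truth)
    })
}

#' Per-base-pair brute-force overlap counting oracle
#'
#' Independent reference implementation for testing the sweep line: scans
#' every base pair of a small genome (at most 1 Mb in total), records the
#' open-flag vector at each position and tallies exact S and N per
#' combination with \code{base::rle}. Shares no code with
#' \code{\link{sweepIntersections}}.
#'
#' @param sets list of merged \code{\linkS4class{RegionSet}}s.
#' @param genome \code{Seqinfo}; total length must not exceed 1e6 bp.
#' @return list with \code{counts} (data.frame code, S, N — exact
#'   counting) and \code{windows} (data.frame chrom, start0, end0, code of
#'   every maximal >= 2-set window).
#' @export
bruteForceCounts <- function(sets, genome) {
    stopifnot(methods::is(genome, "Seqinfo"))
    if (genomeSize(genome) > 1e6)
        stop("genome too large for the brute-force oracle (> 1e6 bp)")
    k <- length(sets)
    lens <- GenomeInfoDb::seqlengths(genome)
    winList <- list()
    for (ch in names(lens)) {
        v <- integer(lens[[ch]])
        for (i in seq_len(k)) {
            gr <- sets[[i]]@regions
            sel <- as.character(GenomeInfoDb::seqnames(gr)) == ch
            if (!any(sel)) next
            bit <- bitwShiftL(1L, i - 1L)
            s <- GenomicRanges::start(gr)[sel]; e <- GenomicRanges::end(gr)[sel]
            for (j in seq_along(s))
                v[s[j]:e[j]] <- v[s[j]:e[j]] + bit
        }
        r <- rle(v)
        end1 <- cumsum(r$lengths)
        start1 <- end1 - r$lengths + 1L
        keep <- .popcount(r$values) >= 2L
        if (any(keep))
            winList[[ch]] <- data.frame(chrom = ch,
                                        start0 = as.numeric(start1[keep] - 1L),
                                        end0 = as.numeric(end1[keep]),
                                        code = as.integer(r$values[keep]))
    }
    if (!length(winList)) {
        win <- data.frame(chrom = character(0), start0 = numeric(0),
                          end0 = numeric(0), code = integer(0))
        return(list(counts = data.frame(code = integer(0), S = numeric(0),
                                        N = numeric(0)),
                    windows = win))
    }
    win <- do.call(rbind, winList)
    rownames(win) <- NULL
    Sagg <- tapply(win$end0 - win$start0, win$code, sum)
    Nagg <- tapply(win$code, win$code, length)
    counts <- data.frame(code = as.integer(names(Sagg)),
                         S = as.numeric(Sagg), N = as.numeric(Nagg))
    counts <- counts[order(counts$code), , drop = FALSE]
    rownames(counts) <- NULL
    list(counts = counts, windows = win)
}
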