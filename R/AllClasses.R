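#' @import methods
#' @importFrom GenomicRanges GRanges granges
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb Seqinfo seqnames seqlengths seqlevels
#' @importFrom S4Vectors mcols mcols<-
NULL

#' RegionSet: a named set of genomic regions
#'
#' A \code{RegionSet} holds one named collection of genomic intervals (the
#' "A", "B", ... sets of a multiple-overlap analysis) as a \code{GRanges},
#' sorted by (chromosome, start). When \code{merged} is \code{TRUE},
#' overlapping or abutting regions within the set have been fused, so the
#' set is a disjoint union of maximal intervals. All overlap and shuffling
#' operations in this package require merged sets.
#'
#' Coordinates at the package boundary (BED files, the \code{\link{regionSet}}
#' constructor) are 0-based half-open; internally a 1-based closed
#' \code{GRanges} is stored, so a BED interval \code{[100, 200)} becomes
#' \code{GRanges} 101-200 with width 100.
#'
#' @slot name single character label of the set.
#' @slot regions \code{GRanges} with the intervals, sorted.
#' @slot merged logical flag: have within-set overlaps been fused?
#'
#' @seealso \code{\link{regionSet}}, \code{\link{readRegions}},
#'   \code{\link{mergeRegions}}
#' @export
setClass("RegionSet",
    slots = c(name = "character", regions = "GRanges", merged = "logical"))

setValidity("RegionSet", function(object) {
    msg <- character(0)
    if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
        msg <- c(msg, "'name' must be a single non-empty string")
    if (length(object@merged) != 1L || is.na(object@merged))
        msg <- c(msg, "'merged' must be TRUE or FALSE")
    gr <- object@regions
    if (length(gr)) {
        if (is.unsorted(GenomicRanges::order(gr)))
            msg <- c(msg, "regions must be sorted by (chrom, start)")
        if (isTRUE(object@merged)) {
            red <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
            if (length(red) != length(gr))
                msg <- c(msg, "merged=TRUE but regions overlap or abut")
        }
    }
    if (length(msg)) msg else TRUE
})

#' IntersectionMatrix: maximal multi-set overlap windows
#'
#' Output of the sweep-line algorithm (\code{\link{sweepIntersections}}):
#' one row per maximal genomic window on which at least two region sets are
#' simultaneously open, together with a logical flag per set. Rows are
#' maximal: two adjacent rows on a chromosome either differ in their flags
#' or are separated by a gap.
#'
#' @slot windows \code{GRanges} of the overlap windows, sorted,
#'   non-overlapping; \code{width(windows)} are the window lengths in bp.
#' @slot flags logical matrix, one row per window, one column per set;
#'   every row has at least two \code{TRUE} entries.
#' @slot setNames character vector of the k set labels, in input order.
#'
#' @seealso \code{\link{sweepIntersections}}, \code{\link{countCombinations}}
#' @export
setClass("IntersectionMatrix",
    slots = c(windows = "GRanges", flags = "matrix", setNames = "character"))

setValidity("IntersectionMatrix", function(object) {
    msg <- character(0)
    fl <- object@flags
    if (!is.logical(fl))
        msg <- c(msg, "'flags' must be a logical matrix")
    if (nrow(fl) != length(object@windows))
        msg <- c(msg, "nrow(flags) must equal length(windows)")
    if (ncol(fl) != length(object@setNames))
        msg <- c(msg, "ncol(flags) must equal length(setNames)")
    if (nrow(fl) && any(rowSums(fl) < 2L))
        msg <- c(msg, "every intersection row must have >= 2 open sets")
    if (length(object@windows) > 1L) {
        if (is.unsorted(GenomicRanges::order(object@windows)))
            msg <- c(msg, "windows must be sorted")
        if (!GenomicRanges::isDisjoint(object@windows))
            msg <- c(msg, "windows must not overlap")
    }
    if (length(msg)) msg else TRUE
})

#' CombinationCounts: S and N per overlap combination
#'
#' Per-combination overlap statistics as computed by
#' \code{\link{countCombinations}}: for every combination gamma, \code{S} is
#' the total number of base pairs on which gamma is observed and \code{N}
#' the number of contiguous windows carrying it. The counting mode is either
#' \code{"exact"} (a window is credited only to the precise open-flag
#' combination) or \code{"transitive"} (windows of any child combination are
#' credited to the parent as well, and contiguous windows are merged
#' a posteriori before counting N).
#'
#' @slot table data.frame with columns \code{combination} (canonical label),
#'   \code{code} (integer bitmask over the sets), \code{order}, \code{S},
#'   \code{N}.
#' @slot setNames character vector of set labels (bit i of \code{code} is
#'   set i).
#' @slot mode \code{"exact"} or \code{"transitive"}.
#' @export
setClass("CombinationCounts",
    slots = c(table = "data.frame", setNames = "character", mode = "character"))

setValidity("CombinationCounts", function(object) {
    msg <- character(0)
    if (!object@mode %in% c("exact", "transitive"))
        msg <- c(msg, "mode must be 'exact' or 'transitive'")
    need <- c("combination", "code", "order", "S", "N")
    if (!all(need %in% names(object@table)))
        msg <- c(msg, paste("table must have columns:",
                            paste(need, collapse = ", ")))
    else {
        tb <- object@table
        if (any(tb$S < 0) || any(tb$N < 0))
            msg <- c(msg, "S and N must be non-negative")
        if (any(tb$S > 0 & tb$N < 1))
            msg <- c(msg, "S > 0 requires N >= 1")
    }
    if (length(msg)) msg else TRUE
})

#' MonteCarloResult: null-model shuffle samples per combination
#'
#' Result of \code{\link{runMonteCarlo}}: for every tracked combination
#' (union of combinations observed in the true data and in any shuffle),
#' the observed S and N and one S / N value per shuffle (0 when the
#' combination was absent from that shuffle). Feed to
#' \code{\link{summarizeEnrichment}} for Negative Binomial fitting and
#' p-values.
#'
#' @slot setNames character, the k set labels.
#' @slot mode counting mode used, \code{"exact"} or \code{"transitive"}.
#' @slot codes integer bitmasks of the tracked combinations.
#' @slot Sobs,Nobs observed values in the true (unshuffled) data, parallel
#'   to \code{codes}.
#' @slot S,N numeric matrices, one row per tracked combination, one column
#'   per shuffle.
#' @slot nShuffles number of shuffles actually run.
#' @slot seed master seed of the run.
#' @slot queryIndex index of the query set, or \code{NA_integer_} when all
#'   combinations are reported.
#' @slot genomeSize total bp of the (sub-)genome analysed; the scale for
#'   Beta fitting.
#' @slot fitAssessed \code{FALSE} after \code{\link{mergeRuns}}: goodness
#'   of fit is not assessed on merged superbatches.
#' @export
setClass("MonteCarloResult",
    slots = c(setNames = "character", mode = "character", codes = "integer",
              Sobs = "numeric", Nobs = "numeric",
              S = "matrix", N = "matrix",
              nShuffles = "integer", seed = "integer",
              queryIndex = "integer", genomeSize = "numeric",
              fitAssessed = "logical"))

setValidity("MonteCarloResult", function(object) {
    msg <- character(0)
    nc <- length(object@codes)
    if (length(object@Sobs) != nc || length(object@Nobs) != nc)
        msg <- c(msg, "Sobs/Nobs must be parallel to codes")
    if (nrow(object@S) != nc || nrow(object@N) != nc)
        msg <- c(msg, "S/N matrices must have one row per combination")
    if (ncol(object@S) != object@nShuffles ||
        ncol(object@N) != object@nShuffles)
        msg <- c(msg, "S/N matrices must have one column per shuffle")
    if (any(object@S < 0) || any(object@N < 0))
        msg <- c(msg, "shuffle samples must be non-negative")
    if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "RegionSet", function(object) {
    cat("RegionSet \"", object@name, "\": ", length(object@regions),
        " regions, ", sum(GenomicRanges::width(object@regions)),
        " bp covered", if (object@merged) " (merged)" else " (unmerged)",
        "\n", sep = "")
})

setMethod("show", "IntersectionMatrix", function(object) {
    cat("IntersectionMatrix: ", nrow(object@flags), " overlap windows over ",
        length(object@setNames), " sets (",
        paste(object@setNames, collapse = ", "), "), ",
        sum(GenomicRanges::width(object@windows)), " bp\n", sep = "")
})

setMethod("show", "CombinationCounts", function(object) {
    cat("CombinationCounts (", object@mode, " counting): ",
        nrow(object@table), " combinations over sets ",
        paste(object@setNames, collapse = ", "), "\n", sep = "")
    if (nrow(object@table))
        print(utils::head(object@table[, c("combination", "order", "S", "N")],
                          10L), row.names = FALSE)
})

setMethod("show", "MonteCarloResult", function(object) {
    cat("MonteCarloResult: ", length(object@codes),
        " tracked combinations, ", object@nShuffles, " shuffles (",
        object@mode, " counting, seed ", object@seed, ")\n", sep = "")
    if (!object@fitAssessed)
        cat("  merged superbatch: goodness of fit not assessed\n")
})

## ---- accessors ----------------------------------------------------------

#' @describeIn RegionSet label of the set
#' @param x,object a \code{RegionSet}
#' @export
setGeneric("regionName", function(x) standardGeneric("regionName"))

#' @rdname RegionSet
#' @export
setMethod("regionName", "RegionSet", function(x) x@name)

#' @describeIn RegionSet the underlying \code{GRanges}
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname RegionSet
#' @export
setMethod("regions", "RegionSet", function(x) x@regions)

#' @describeIn RegionSet whether within-set overlaps have been fused
#' @export
setGeneric("isMerged", function(x) standardGeneric("isMerged"))

#' @rdname RegionSet
#' @export
setMethod("isMerged", "RegionSet", function(x) x@merged)

#' @rdname RegionSet
#' @export
setMethod("length", "RegionSet", function(x) length(x@regions))

#' Total covered base pairs of a RegionSet
#'
#' @param x a \code{RegionSet}
#' @return total bp covered by the (merged) regions.
#' @export
totalWidth <- function(x) {
    stopifnot(is(x, "RegionSet"))
    sum(GenomicRanges::width(x@regions))
}

#' @describeIn IntersectionMatrix overlap windows as \code{GRanges}
#' @export
setGeneric("windows", function(x) standardGeneric("windows"))

#' @rdname IntersectionMatrix
#' @param x an \code{IntersectionMatrix}
#' @export
setMethod("windows", "IntersectionMatrix", function(x) x@windows)

#' @describeIn IntersectionMatrix logical open-flag matrix
#' @export
setGeneric("overlapFlags", function(x) standardGeneric("overlapFlags"))

#' @rdname IntersectionMatrix
#' @export
setMethod("overlapFlags", "IntersectionMatrix", function(x) x@flags)

#' Set labels of an overlap object
#'
#' @param x an \code{IntersectionMatrix}, \code{CombinationCounts} or
#'   \code{MonteCarloResult}
#' @return character vector of the k region-set labels, in input order.
#' @export
setGeneric("setLabels", function(x) standardGeneric("setLabels"))

#' @rdname setLabels
#' @export
setMethod("setLabels", "IntersectionMatrix", function(x) x@setNames)

#' @rdname setLabels
#' @export
setMethod("setLabels", "CombinationCounts", function(x) x@setNames)

#' @rdname setLabels
#' @export
setMethod("setLabels", "MonteCarloResult", function(x) x@setNames)

#' @describeIn CombinationCounts the per-combination count table
#' @param x a \code{CombinationCounts}
#' @export
setGeneric("countTable", function(x) standardGeneric("countTable"))

#' @rdname CombinationCounts
#' @export
setMethod("countTable", "CombinationCounts", function(x) x@table)

#' @describeIn MonteCarloResult counting mode of the run
#' @param x a \code{MonteCarloResult} (or \code{CombinationCounts})
#' @export
setGeneric("countingMode", function(x) standardGeneric("countingMode"))

#' @rdname MonteCarloResult
#' @export
setMethod("countingMode", "MonteCarloResult", function(x) x@mode)

#' @rdname CombinationCounts
#' @export
setMethod("countingMode", "CombinationCounts", function(x) x@mode)

#' @describeIn MonteCarloResult matrix of shuffled S values
#' @export
setGeneric("shuffledS", function(x) standardGeneric("shuffledS"))

#' @rdname MonteCarloResult
#' @export
setMethod("shuffledS", "MonteCarloResult", function(x) x@S)

#' @describeIn MonteCarloResult matrix of shuffled N values
#' @export
setGeneric("shuffledN", function(x) standardGeneric("shuffledN"))

#' @rdname MonteCarloResult
#' @export
setMethod("shuffledN", "MonteCarloResult", function(x) x@N)
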