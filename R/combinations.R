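## Combinations of region sets, their parent/child partial order, and
## exact vs transitive counting of the S (bp) and N (window) measures.

#' Combination: a subset of the k region-set identities
#'
#' A combination gamma names the region sets that are simultaneously open
#' on some genomic window. Its \emph{order} is the number of participating
#' sets. Combinations over the same k sets carry a partial order: gamma1 is
#' a \emph{parent} of gamma2 when its sets are a strict subset of gamma2's
#' (e.g. \{A + B\} is a parent of \{A + B + C\}, but not of \{B + C\}).
#'
#' @slot setNames the k set labels, in input order.
#' @slot flags logical vector of length k: does set i participate?
#' @seealso \code{\link{combination}}, \code{\link{relateCombinations}}
#' @export
setClass("Combination",
    slots = c(setNames = "character", flags = "logical"))

setValidity("Combination", function(object) {
    msg <- character(0)
    if (length(object@flags) != length(object@setNames))
        msg <- c(msg, "flags must be parallel to setNames")
    if (any(is.na(object@flags)))
        msg <- c(msg, "flags must not contain NA")
    if (sum(object@flags) < 1L)
        msg <- c(msg, "a combination involves at least one set")
    if (length(msg)) msg else TRUE
})

#' Construct a Combination
#'
#' @param setNames character vector of the k set labels.
#' @param members character vector of participating set names (subset of
#'   \code{setNames}), or a logical vector of length k.
#' @return a \code{\linkS4class{Combination}}.
#' @examples
#' combination(c("A", "B", "C"), c("A", "B"))
#' @export
combination <- function(setNames, members) {
    if (is.logical(members)) {
        flags <- members
    } else {
        bad <- setdiff(members, setNames)
        if (length(bad))
            stop("unknown set name(s): ", paste(bad, collapse = ", "))
        flags <- setNames %in% members
    }
    methods::new("Combination", setNames = setNames, flags = flags)
}

setMethod("show", "Combination", function(object) {
    cat("Combination ",
        combinationLabel(object@flags, object@setNames),
        " (order ", sum(object@flags), ")\n", sep = "")
})

#' Canonical label of a combination
#'
#' Renders a combination as \code{"[A + B + C]"} with set names in input
#' order. Under transitive counting a trailing \code{" + ..."} marks that
#' the label stands for the combination and all its children.
#'
#' @param flags logical vector (or a \code{\linkS4class{Combination}}).
#' @param setNames the k set labels (ignored when \code{flags} is a
#'   \code{Combination}).
#' @param transitive append the \code{" + ..."} child marker.
#' @return a single character label.
#' @export
combinationLabel <- function(flags, setNames = NULL, transitive = FALSE) {
    if (methods::is(flags, "Combination")) {
        setNames <- flags@setNames
        flags <- flags@flags
    }
    stopifnot(length(flags) == length(setNames))
    paste0("[", paste(setNames[flags], collapse = " + "),
           if (transitive) " + ..." else "", "]")
}

#' Partial-order relation between two combinations
#'
#' @param a,b \code{\linkS4class{Combination}} objects (or logical flag
#'   vectors) over the same k sets.
#' @return one of \code{"parent"} (a's sets are a strict subset of b's),
#'   \code{"child"}, \code{"equal"} or \code{"unrelated"}.
#' @examples
#' sn <- c("A", "B", "C")
#' relateCombinations(combination(sn, c("A", "B")),
#'                    combination(sn, c("A", "B", "C")))  # "parent"
#' @export
relateCombinations <- function(a, b) {
    fa <- if (methods::is(a, "Combination")) a@flags else a
    fb <- if (methods::is(b, "Combination")) b@flags else b
    if (methods::is(a, "Combination") && methods::is(b, "Combination") &&
        !identical(a@setNames, b@setNames))
        stop("combinations are defined over different set lists")
    if (length(fa) != length(fb))
        stop("combinations are defined over different numbers of sets")
    if (all(fa == fb)) return("equal")
    if (all(fb[fa])) return("parent")   # a subset of b: a is the parent
    if (all(fa[fb])) return("child")
    "unrelated"
}

## internal: parse the user-facing 'combinations' argument into codes.
.resolveCombinations <- function(combinations, setNames) {
    k <- length(setNames)
    if (is.null(combinations)) return(NULL)
    if (is.numeric(combinations)) return(as.integer(combinations))
    if (methods::is(combinations, "Combination"))
        combinations <- list(combinations)
    if (is.list(combinations)) {
        codes <- vapply(combinations, function(cmb) {
            if (methods::is(cmb, "Combination")) {
                if (!identical(cmb@setNames, setNames))
                    stop("combination defined over different set list")
                .flagsToCode(cmb@flags)
            } else if (is.character(cmb)) {
                .flagsToCode(setNames %in% cmb)
            } else if (is.logical(cmb)) {
                .flagsToCode(cmb)
            } else stop("cannot interpret combination specification")
        }, integer(1))
        return(codes)
    }
    stop("cannot interpret 'combinations'")
}

#' Count S and N per combination from an intersection matrix
#'
#' Computes, for every reported combination gamma, the total overlapping
#' base pairs \code{S(gamma)} and the number of contiguous windows
#' \code{N(gamma)}.
#'
#' Under \emph{exact} counting, a window is credited only to the precise
#' combination of sets open on it. Under \emph{transitive} counting (the
#' default), windows of every child combination (superset of gamma's sets)
#' are credited to gamma as well, and windows that become contiguous are
#' merged a posteriori before counting N.
#'
#' @param X an \code{\linkS4class{IntersectionMatrix}}.
#' @param mode \code{"transitive"} (default) or \code{"exact"}.
#' @param queryIndex optional index of the query set; when given, only
#'   combinations containing the query are reported.
#' @param combinations optional explicit selection: an integer vector of
#'   bitmask codes, a list of character vectors of set names, a list of
#'   \code{\linkS4class{Combination}}s, or a logical matrix (one row per
#'   combination). Default: all combinations observed (as exact flag
#'   patterns) in \code{X}.
#' @return a \code{\linkS4class{CombinationCounts}}.
#' @examples
#' a <- regionSet("A", c("chr1", "chr1"), c(100, 500), c(200, 550))
#' b <- regionSet("B", c("chr1", "chr2"), c(480, 100), c(520, 210))
#' countTable(countCombinations(sweepIntersections(list(a, b))))
#' @export
countCombinations <- function(X, mode = c("transitive", "exact"),
                              queryIndex = NULL, combinations = NULL) {
    stopifnot(methods::is(X, "IntersectionMatrix"))
    mode <- match.arg(mode)
    k <- length(X@setNames)
    if (!is.null(queryIndex)) {
        queryIndex <- as.integer(queryIndex)
        if (length(queryIndex) != 1L || is.na(queryIndex) ||
            queryIndex < 1L || queryIndex > k)
            stop("queryIndex out of range (1..", k, ")")
    }
    if (is.logical(combinations) && is.matrix(combinations))
        combinations <- lapply(seq_len(nrow(combinations)),
                               function(i) combinations[i, ])
    codes <- .flagsToCode(X@flags)
    gammas <- .resolveCombinations(combinations, X@setNames)
    if (is.null(gammas)) gammas <- sort(unique(codes))
    if (!is.null(queryIndex)) {
        qbit <- bitwShiftL(1L, queryIndex - 1L)
        gammas <- gammas[bitwAnd(gammas, qbit) > 0L]
    }
    tab <- .countCodes(codes, GenomicRanges::width(X@windows),
                       .rowAdjacency(X), gammas, mode)
    tab$combination <- vapply(tab$code, function(g)
        combinationLabel(.codesToFlags(g, k)[1L, ], X@setNames,
                         transitive = (mode == "transitive")), character(1))
    tab$order <- .popcount(tab$code)
    tab <- tab[, c("combination", "code", "order", "S", "N")]
    rownames(tab) <- NULL
    methods::new("CombinationCounts", table = tab, setNames = X@setNames,
                 mode = mode)
}

## adjacency of consecutive intersection rows: TRUE when row i+1 directly
## abuts row i on the same chromosome.
.rowAdjacency <- function(X) {
    gr <- X@windows
    m <- length(gr)
    if (m < 2L) return(logical(0))
    same <- as.character(GenomeInfoDb::seqnames(gr))[-1L] ==
            as.character(GenomeInfoDb::seqnames(gr))[-m]
    same & (GenomicRanges::start(gr)[-1L] == GenomicRanges::end(gr)[-m] + 1L)
}

## core counting on integer codes; shared by the GRanges path and the
## Monte Carlo fast path.
.countCodes <- function(codes, widths, adj, gammas, mode) {
    m <- length(codes)
    S <- numeric(length(gammas)); N <- numeric(length(gammas))
    for (j in seq_along(gammas)) {
        g <- gammas[j]
        mask <- if (mode == "exact") codes == g
                else bitwAnd(codes, g) == g
        if (!any(mask)) next
        S[j] <- sum(widths[mask])
        if (m == 1L) { N[j] <- 1; next }
        prevMasked <- c(FALSE, mask[-m])
        prevAdj <- c(FALSE, adj)
        N[j] <- sum(mask & !(prevMasked & prevAdj))
    }
    data.frame(code = gammas, S = S, N = N)
}
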