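## Itemset mining on the binary overlap matrix via sparse dictionary
## learning. Two steps:
##   1. Library creation: repeated penalised factorizations of the
##      smothered matrix psi(X) under an increasing L1 penalty schedule
##      produce candidate atoms of various lengths.
##   2. Greedy selection: starting from an empty dictionary, the candidate
##      whose addition best rebuilds X under an L1 criterion is appended,
##      up to q itemsets.
## The factorization model is
##      min_(U,V) 1/2 ||X - UV||_2^2 + alpha ||U||_1,  ||V_i||_2 = 1,
## solved by alternating a coordinate-descent lasso coder (U) with
## MOD-style dictionary updates (V). Codes and atoms are constrained
## non-negative: itemset memberships and usages have no meaningful sign.

## ---- sparse coding ------------------------------------------------------

## Coordinate-descent non-negative lasso, all rows of X at once.
## V: nAtoms x k with rows of positive L2 norm. Returns U: m x nAtoms.
.sparseCode <- function(X, V, alpha, maxIter = 200L, tol = 1e-7) {
    A <- nrow(V)
    G <- V %*% t(V)                     # atom Gram matrix
    B <- X %*% t(V)
    U <- matrix(0, nrow(X), A)
    for (iter in seq_len(maxIter)) {
        delta <- 0
        for (j in seq_len(A)) {
            gjj <- G[j, j]
            if (gjj <= 1e-12) next
            resid <- B[, j] - U %*% G[, j] + U[, j] * gjj
            new <- pmax(0, resid - alpha) / gjj
            delta <- max(delta, max(abs(new - U[, j]), 0))
            U[, j] <- new
        }
        if (delta < tol) break
    }
    U
}

## Alternating dictionary learning with unit-norm non-negative atoms.
## Atoms are initialized at the most frequent distinct row patterns of X
## (an informed, stable starting point for itemset data); remaining slots,
## and the symmetry-breaking jitter, draw from the caller's RNG state.
.dictLearn <- function(X, nAtoms, alpha, maxIter = 40L, tol = 1e-5,
                       init = NULL) {
    m <- nrow(X); k <- ncol(X)
    if (is.null(init)) {
        key <- apply(X, 1L, paste, collapse = "\r")
        counts <- sort(table(key), decreasing = TRUE)
        pat <- do.call(rbind, lapply(strsplit(names(counts), "\r"),
                                     as.numeric))
        pat <- pat[rowSums(pat) > 0, , drop = FALSE]
        init <- pat[seq_len(min(nAtoms, nrow(pat))), , drop = FALSE]
        if (nrow(init) < nAtoms)
            init <- rbind(init,
                          matrix(stats::runif(k * (nAtoms - nrow(init))),
                                 ncol = k))
    }
    V <- init + matrix(stats::runif(nAtoms * k, 0, 0.01), nAtoms, k)
    V <- .normalizeAtoms(V)
    objPrev <- Inf
    U <- matrix(0, m, nAtoms)
    for (iter in seq_len(maxIter)) {
        U <- .sparseCode(X, V, alpha)
        if (all(U == 0)) break
        R <- X - U %*% V
        for (j in seq_len(nAtoms)) {
            nj <- sum(U[, j]^2)
            if (nj <= 1e-12) next
            vj <- V[j, ] + as.numeric(crossprod(U[, j], R)) / nj
            vj <- pmax(0, vj)
            nrm <- sqrt(sum(vj^2))
            if (nrm > 1e-12) {
                R <- R + U[, j, drop = FALSE] %*% (V[j, , drop = FALSE] -
                                                   matrix(vj / nrm, 1))
                V[j, ] <- vj / nrm
            }
        }
        obj <- 0.5 * sum((X - U %*% V)^2) + alpha * sum(U)
        if (is.finite(objPrev) && abs(objPrev - obj) < tol * max(1, objPrev))
            break
        objPrev <- obj
    }
    list(U = U, V = V)
}

.normalizeAtoms <- function(V) {
    nrm <- sqrt(rowSums(V^2))
    nrm[nrm == 0] <- 1
    V / nrm
}

## ---- smothering ---------------------------------------------------------

#' Smother a binary overlap matrix
#'
#' Pre-processing before library creation: the abundance of each distinct
#' row pattern is quadratically reduced, a pattern occurring \code{c} times
#' being retained \code{ceiling(sqrt(c))} times. Rare combinations thereby
#' gain relative weight and are not drowned out by the most frequent ones,
#' while no pattern is ever dropped. Row order is canonicalized (by
#' decreasing original count, then pattern).
#'
#' @param X binary matrix (m rows, k item columns), or an
#'   \code{\linkS4class{IntersectionMatrix}} whose flags are used.
#' @return list with \code{rows} (the smothered matrix) and \code{mapping}
#'   (data.frame: pattern, original count, retained count).
#' @examples
#' X <- matrix(rep(c(1, 1, 0), 100), ncol = 3, byrow = TRUE)
#' nrow(smotherMatrix(X)$rows)   # ceiling(sqrt(100)) = 10
#' @export
smotherMatrix <- function(X) {
    X <- .asOverlapMatrix(X)
    if (!nrow(X)) stop("empty overlap matrix")
    key <- apply(X, 1L, paste, collapse = "")
    counts <- table(key)
    ord <- order(-as.numeric(counts), names(counts))
    counts <- counts[ord]
    retained <- ceiling(sqrt(as.numeric(counts)))
    pat <- do.call(rbind, strsplit(names(counts), ""))
    pat <- matrix(as.numeric(pat), nrow = nrow(pat))
    colnames(pat) <- colnames(X)
    rows <- pat[rep(seq_along(retained), retained), , drop = FALSE]
    list(rows = rows,
         mapping = data.frame(pattern = names(counts),
                              count = as.numeric(counts),
                              retained = retained,
                              row.names = NULL))
}

.asOverlapMatrix <- function(X) {
    if (methods::is(X, "IntersectionMatrix")) {
        M <- X@flags + 0
        colnames(M) <- X@setNames
        return(M)
    }
    X <- as.matrix(X)
    if (!all(X %in% c(0, 1))) stop("overlap matrix must be binary (0/1)")
    if (is.null(colnames(X)))
        colnames(X) <- paste0("set", seq_len(ncol(X)))
    storage.mode(X) <- "numeric"
    X
}

## ---- library creation ---------------------------------------------------

#' Miner configuration
#'
#' @param q queried number of final itemsets (>= 1).
#' @param atomsPerFactorization atoms learned per factorization in the
#'   library step; default \code{min(k, q + 2)}: enough capacity for q
#'   complexes plus slack (resolved at run time when \code{NULL}).
#' @param binarizationThreshold fraction of an atom's maximum weight above
#'   which an item belongs to the binarized membership (in (0,1)).
#' @param selectionAlpha L1 penalty used by the greedy selection coder;
#'   default \code{0.5/k} (resolved at run time when \code{NULL}).
#' @param maxLibraryIterations safety cap on the penalty schedule.
#' @return a list with class \code{"ItemsetConfig"}.
#' @export
itemsetConfig <- function(q = 5L, atomsPerFactorization = NULL,
                          binarizationThreshold = 0.3,
                          selectionAlpha = NULL,
                          maxLibraryIterations = 25L) {
    q <- as.integer(q)
    if (is.na(q) || q < 1L) stop("q must be >= 1")
    if (binarizationThreshold <= 0 || binarizationThreshold >= 1)
        stop("binarizationThreshold must be in (0, 1)")
    structure(list(q = q, atomsPerFactorization = atomsPerFactorization,
                   binarizationThreshold = binarizationThreshold,
                   selectionAlpha = selectionAlpha,
                   maxLibraryIterations = as.integer(maxLibraryIterations)),
              class = "ItemsetConfig")
}

#' Build the candidate-atom library
#'
#' Step 1 of the miner: repeated dictionary-learning factorizations of the
#' smothered matrix under an increasing sparsity schedule. The L1 penalty
#' starts at \code{1/k} and is raised by \code{i/k} at iteration i, so
#' later factorizations admit fewer, longer atoms. After each
#' factorization, every atom with positive total usage (the column sum of
#' its coefficients in the rebuilt code) is binarized and added to the
#' library, deduplicated by membership. The schedule stops once the total
#' usage of all atoms is zero.
#'
#' @param psiX a smothered matrix as returned by \code{\link{smotherMatrix}}
#'   (or any binary/numeric matrix).
#' @param config an \code{\link{itemsetConfig}}.
#' @return data.frame library: one row per candidate with \code{members}
#'   (comma-joined item names), \code{code} (bitmask), \code{size} and
#'   \code{alpha} (penalty at which the atom was first learned).
#' @export
buildLibrary <- function(psiX, config = itemsetConfig()) {
    if (is.list(psiX) && !is.null(psiX$rows)) psiX <- psiX$rows
    psiX <- as.matrix(psiX)
    if (!nrow(psiX)) stop("empty matrix")
    k <- ncol(psiX)
    itemNames <- colnames(psiX)
    if (is.null(itemNames)) itemNames <- paste0("set", seq_len(k))
    nAtoms <- config$atomsPerFactorization
    if (is.null(nAtoms)) nAtoms <- min(k, config$q + 2L)
    lib <- list()
    alpha <- 0
    for (i in seq_len(config$maxLibraryIterations)) {
        alpha <- alpha + i / k
        fit <- tryCatch(.dictLearn(psiX, nAtoms, alpha),
                        error = function(e) NULL)
        if (is.null(fit)) {                # non-convergent: one retry
            fit <- tryCatch(.dictLearn(psiX, nAtoms, alpha),
                            error = function(e) NULL)
            if (is.null(fit)) {
                warning("factorization failed at alpha = ", signif(alpha, 3),
                        "; skipping")
                next
            }
        }
        usage <- colSums(fit$U)
        if (all(usage <= 1e-9)) break
        for (j in which(usage > 1e-9)) {
            w <- fit$V[j, ]
            if (max(w) <= 0) next
            memb <- w >= config$binarizationThreshold * max(w)
            if (!any(memb)) next
            code <- .flagsToCode(memb)
            if (!is.null(lib[[as.character(code)]])) next
            lib[[as.character(code)]] <-
                data.frame(members = paste(itemNames[memb], collapse = ","),
                           code = code, size = sum(memb), alpha = alpha)
        }
    }
    if (!length(lib))
        return(data.frame(members = character(0), code = integer(0),
                          size = integer(0), alpha = numeric(0)))
    out <- do.call(rbind, lib)
    rownames(out) <- NULL
    out[order(out$size, out$members), , drop = FALSE]
}

## ---- greedy selection ---------------------------------------------------

#' Greedy selection of the final itemsets
#'
#' Step 2 of the miner: starting from an empty dictionary, at each step
#' every remaining library candidate is tentatively appended, the raw
#' matrix X is sparse-coded against the enlarged dictionary, and the
#' candidate minimizing \code{d1 = ||X - X~||_1 + alpha * sum(U)} is kept.
#' Ties break toward the smaller membership, then lexicographically
#' (parsimony bias). Selection order is the output rank. Atoms are coded as
#' unit-L2-norm indicator vectors, which also fixes each atom's squared
#' weight sum to one so that usages of broad and narrow atoms are
#' comparable when ranking.
#'
#' @param X binary overlap matrix (or \code{IntersectionMatrix}).
#' @param library data.frame from \code{\link{buildLibrary}}.
#' @param config an \code{\link{itemsetConfig}}; \code{config$q} itemsets
#'   are selected (fewer if the library is exhausted).
#' @return data.frame with \code{rank}, \code{members}, \code{code},
#'   \code{size} and \code{objective} (d1 after the atom was added);
#'   empty (with a warning) when the library is empty.
#' @export
greedySelect <- function(X, library, config = itemsetConfig()) {
    X <- .asOverlapMatrix(X)
    k <- ncol(X)
    if (!nrow(library)) {
        warning("empty candidate library; no itemsets selected")
        return(data.frame(rank = integer(0), members = character(0),
                          code = integer(0), size = integer(0),
                          objective = numeric(0)))
    }
    alpha <- config$selectionAlpha
    if (is.null(alpha)) alpha <- 0.5 / k
    cand <- library[order(library$size, library$members), , drop = FALSE]
    atoms <- .codesToFlags(cand$code, k) + 0
    atoms <- .normalizeAtoms(atoms)
    chosen <- integer(0)
    Vt <- matrix(numeric(0), nrow = 0L, ncol = k)
    out <- list()
    q <- min(config$q, nrow(cand))
    for (t in seq_len(q)) {
        best <- NULL; bestD1 <- Inf
        for (ci in seq_len(nrow(cand))) {
            if (ci %in% chosen) next
            S <- rbind(Vt, atoms[ci, ])
            U <- .sparseCode(X, S, alpha)
            d1 <- sum(abs(X - U %*% S)) + alpha * sum(U)
            if (d1 < bestD1 - 1e-9) { bestD1 <- d1; best <- ci }
        }
        if (is.null(best)) break
        chosen <- c(chosen, best)
        Vt <- rbind(Vt, atoms[best, ])
        out[[t]] <- data.frame(rank = t, members = cand$members[best],
                               code = cand$code[best],
                               size = cand$size[best], objective = bestD1)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Mine itemsets from a binary overlap matrix
#'
#' Full miner: smother the matrix, build the candidate library over the
#' sparsity schedule, then greedily select \code{q} final itemsets.
#' Deterministic for a fixed \code{seed}.
#'
#' @param X binary overlap matrix (rows = overlap events, columns = sets),
#'   an \code{\linkS4class{IntersectionMatrix}}, or a path readable by
#'   \code{\link{readMatrixTsv}}.
#' @param q number of itemsets to return.
#' @param seed integer seed for the factorization initializations.
#' @param config optional \code{\link{itemsetConfig}} (its \code{q} is
#'   overridden by the \code{q} argument).
#' @return data.frame of ranked itemsets (see \code{\link{greedySelect}}).
#' @examples
#' sim <- generateOverlapMatrix(m = 200, seed = 7)
#' mineItemsets(sim$X, q = 3, seed = 7)$members
#' @export
mineItemsets <- function(X, q = 5L, seed = 1L, config = NULL) {
    if (is.character(X) && length(X) == 1L) X <- readMatrixTsv(X)
    X <- .asOverlapMatrix(X)
    if (!nrow(X)) stop("empty overlap matrix")
    if (is.null(config)) config <- itemsetConfig(q = q)
    else config$q <- as.integer(q)
    .withSeed(as.integer(seed), function() {
        psi <- smotherMatrix(X)
        lib <- buildLibrary(psi, config)
        greedySelect(X, lib, config)
    })
}

## ---- standalone matrix I/O ---------------------------------------------

#' Read / write a binary overlap matrix as TSV
#'
#' Standalone-miner interchange format: a header line with the set names
#' followed by one 0/1 row per overlap event. \code{writeMatrixTsv} is the
#' inverse of \code{readMatrixTsv}.
#'
#' @param path TSV path.
#' @return \code{readMatrixTsv}: a numeric binary matrix with column names.
#' @export
readMatrixTsv <- function(path) {
    if (!file.exists(path)) stop("matrix file not found: ", path)
    df <- utils::read.delim(path, check.names = FALSE)
    M <- as.matrix(df)
    storage.mode(M) <- "numeric"
    if (any(is.na(M)) || !all(M %in% c(0, 1)))
        stop("matrix file must contain only 0/1 values")
    M
}

#' @rdname readMatrixTsv
#' @param X binary matrix to write.
#' @export
writeMatrixTsv <- function(X, path) {
    X <- .asOverlapMatrix(X)
    utils::write.table(X, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write ranked itemsets as TSV
#'
#' @param itemsets data.frame from \code{\link{mineItemsets}} /
#'   \code{\link{greedySelect}}.
#' @param path output TSV path.
#' @export
writeItemsetsTsv <- function(itemsets, path) {
    utils::write.table(itemsets[, c("rank", "members", "size", "objective")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
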