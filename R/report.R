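## Results assembly and export: the per-combination statistics table,
## lossless TSV round-trip, and the parent/child combination graph in DOT.

#' Summarize a Monte Carlo run into the per-combination results table
#'
#' Fits the null model to every tracked combination and assembles the full
#' statistics table: observed and expected S, log2 fold change, Negative
#' Binomial / empirical / Beta p-values, the Cramer's V fit diagnostic, and
#' the N-based statistics. Rows are sorted by descending observed S (the
#' default emphasis is on frequent combinations, not on the smallest
#' p-values).
#'
#' @param mc a \code{\linkS4class{MonteCarloResult}}.
#' @param cramersVThreshold verdict threshold for the fit diagnostic.
#' @param bhColumn add a Benjamini-Hochberg adjusted column for
#'   \code{p_nb_S} (off by default; no multiple-testing correction is
#'   applied otherwise).
#' @return data.frame, one row per combination.
#' @export
summarizeEnrichment <- function(mc, cramersVThreshold = 0.25,
                                bhColumn = FALSE) {
    stopifnot(methods::is(mc, "MonteCarloResult"))
    k <- length(mc@setNames)
    rows <- lapply(seq_along(mc@codes), function(i) {
        st <- summarizeCombination(mc@S[i, ], mc@N[i, ],
                                   mc@Sobs[i], mc@Nobs[i],
                                   scale = mc@genomeSize,
                                   cramersVThreshold = cramersVThreshold,
                                   fitAssessed = mc@fitAssessed)
        flags <- .codesToFlags(mc@codes[i], k)[1L, ]
        cbind(data.frame(
                  combination = combinationLabel(flags, mc@setNames,
                      transitive = (mc@mode == "transitive")),
                  code = mc@codes[i],
                  order = sum(flags)),
              st)
    })
    out <- do.call(rbind, rows)
    out$counting_mode <- mc@mode
    out$n_shuffles <- mc@nShuffles
    out$seed <- mc@seed
    out <- out[order(-out$S_obs, out$code), , drop = FALSE]
    if (bhColumn)
        out$padj_bh_S <- stats::p.adjust(out$p_nb_S, method = "BH")
    rownames(out) <- NULL
    out
}

#' Write / read the results table as TSV
#'
#' Tab-separated with a header row and a fixed column order; numeric
#' columns are written with full (17 significant digit) precision so that
#' \code{readResultsTsv(writeResultsTsv(x))} round-trips losslessly.
#'
#' @param table results data.frame from \code{\link{summarizeEnrichment}}.
#' @param path output TSV path.
#' @return \code{path} invisibly (\code{writeResultsTsv}); the table
#'   (\code{readResultsTsv}).
#' @export
writeResultsTsv <- function(table, path) {
    fmt <- table
    for (cn in names(fmt)) {
        if (is.numeric(fmt[[cn]]) && !is.integer(fmt[[cn]])) {
            x <- fmt[[cn]]
            fmt[[cn]] <- ifelse(is.na(x), "NA", sprintf("%.17g", x))
        }
    }
    utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeResultsTsv
#' @export
readResultsTsv <- function(path) {
    if (!file.exists(path)) stop("results file not found: ", path)
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

## parse a combination label "[A + B + ...]" back into member names
.parseLabel <- function(label) {
    inner <- sub("^\\[", "", sub("\\]$", "", label))
    parts <- strsplit(inner, " \\+ ")[[1L]]
    setdiff(parts, "...")
}

#' Build the parent/child combination graph
#'
#' Nodes are the reported combinations, annotated with S, the log2 fold
#' change and the Negative Binomial p-value; a directed edge joins a parent
#' to a child when the child has exactly one additional set (so the graph
#' is the Hasse diagram of the reported part of the combination lattice,
#' and is acyclic by construction).
#'
#' @param table results data.frame from \code{\link{summarizeEnrichment}}
#'   (possibly filtered / read back from TSV).
#' @return list with \code{nodes} (data.frame: id, label, members, order,
#'   S_obs, log2_fold_change, p_nb_S) and \code{edges} (data.frame: from,
#'   to — node ids).
#' @export
buildCombinationDag <- function(table) {
    if (!nrow(table)) stop("empty results table")
    members <- lapply(table$combination, .parseLabel)
    ord <- lengths(members)
    nodes <- data.frame(id = seq_len(nrow(table)),
                        label = table$combination,
                        members = vapply(members, paste, character(1),
                                         collapse = ","),
                        order = ord,
                        S_obs = table$S_obs,
                        log2_fold_change = table$log2_fold_change,
                        p_nb_S = table$p_nb_S,
                        stringsAsFactors = FALSE)
    from <- integer(0); to <- integer(0)
    for (i in seq_along(members)) {
        for (j in seq_along(members)) {
            if (ord[j] == ord[i] + 1L && all(members[[i]] %in% members[[j]])) {
                from <- c(from, i); to <- c(to, j)
            }
        }
    }
    list(nodes = nodes, edges = data.frame(from = from, to = to))
}

#' Render a combination graph as DOT
#'
#' Writes the graph from \code{\link{buildCombinationDag}} in Graphviz DOT
#' format. Each node shows the combination, its observed S, the log2 fold
#' change and the p-value; the fill colour encodes the fold change (blue =
#' depleted, white = neutral, red = enriched). Image rendering is left to
#' external tooling (\code{dot -Tpng ...}).
#'
#' @param dag list from \code{\link{buildCombinationDag}}.
#' @param path output .dot path.
#' @return \code{path}, invisibly.
#' @importFrom grDevices colorRampPalette
#' @export
writeDot <- function(dag, path) {
    nodes <- dag$nodes
    fc <- nodes$log2_fold_change
    fc[!is.finite(fc)] <- 0
    ramp <- grDevices::colorRampPalette(c("#4575B4", "#FFFFFF", "#D73027"))(101)
    lim <- max(abs(fc), 1e-9)
    colIdx <- round(50 + 50 * pmax(-1, pmin(1, fc / lim)))
    lines <- c("digraph combinations {",
               "  node [shape=box, style=filled, fontname=\"Helvetica\"];")
    for (i in seq_len(nrow(nodes))) {
        lab <- sprintf("%s\\nS = %s\\nlog2 FC = %.3g; p = %.3g",
                       nodes$label[i], format(nodes$S_obs[i], big.mark = ","),
                       nodes$log2_fold_change[i], nodes$p_nb_S[i])
        lines <- c(lines, sprintf("  n%d [label=\"%s\", fillcolor=\"%s\"];",
                                  nodes$id[i], lab, ramp[colIdx[i] + 1L]))
    }
    if (nrow(dag$edges))
        lines <- c(lines, sprintf("  n%d -> n%d;",
                                  dag$edges$from, dag$edges$to))
    lines <- c(lines, "}")
    writeLines(lines, path)
    invisible(path)
}
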