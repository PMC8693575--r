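## Genome plumbing: chromosome sizes, BED region sets, sub-genome remapping.
## External coordinates are BED-standard 0-based half-open; internally we
## store 1-based closed GRanges (so width() is exactly end - start in BED
## coordinates).

#' Build a RegionSet from BED-style coordinates
#'
#' Convenience constructor taking parallel vectors of 0-based half-open
#' coordinates, as printed in a BED file. Regions are sorted and, by
#' default, merged (overlapping or abutting regions within the set are
#' fused).
#'
#' @param name label of the set.
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open (\code{end > start}).
#' @param genome optional \code{Seqinfo} (see \code{\link{readChromSizes}});
#'   when given, every chromosome must exist in it and no region may exceed
#'   its chromosome length.
#' @param merge fuse overlapping/abutting regions (default \code{TRUE}).
#' @return a \code{\linkS4class{RegionSet}}.
#' @examples
#' a <- regionSet("A", c("chr1", "chr1"), c(100, 500), c(200, 550))
#' totalWidth(a)  # 150
#' @export
regionSet <- function(name, chrom, start, end, genome = NULL, merge = TRUE) {
    if (length(chrom) != length(start) || length(start) != length(end))
        stop("chrom, start and end must have equal length")
    start <- as.numeric(start); end <- as.numeric(end)
    if (any(is.na(start)) || any(is.na(end)) || any(is.na(chrom)))
        stop("missing values in region coordinates")
    if (any(start < 0))
        stop("start coordinates must be >= 0")
    if (any(end <= start))
        stop("invalid region(s): end must be greater than start")
    gr <- GenomicRanges::GRanges(as.character(chrom),
                                 IRanges::IRanges(start = start + 1, end = end))
    GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
    if (!is.null(genome))
        gr <- .checkAgainstGenome(gr, genome, what = name)
    gr <- GenomicRanges::sort(gr)
    rs <- methods::new("RegionSet", name = as.character(name),
                       regions = gr, merged = FALSE)
    if (merge) rs <- mergeRegions(rs)
    rs
}

.checkAgainstGenome <- function(gr, genome, what = "regions") {
    stopifnot(methods::is(genome, "Seqinfo"))
    chroms <- as.character(GenomeInfoDb::seqnames(gr))
    known <- GenomeInfoDb::seqlevels(genome)
    bad <- setdiff(unique(chroms), known)
    if (length(bad))
        stop("set '", what, "': chromosome(s) not in genome: ",
             paste(bad, collapse = ", "))
    lens <- GenomeInfoDb::seqlengths(genome)[chroms]
    over <- GenomicRanges::end(gr) > lens
    if (any(over))
        stop("set '", what, "': ", sum(over),
             " region(s) exceed their chromosome length (first at ",
             chroms[which(over)[1L]], ":", GenomicRanges::start(gr[which(over)[1L]]) - 1L,
             "); regions beyond chromosome bounds are an error, not clipped")
    GenomeInfoDb::seqlevels(gr) <- known
    GenomeInfoDb::seqinfo(gr) <- genome
    gr
}

#' Read a BED file into a RegionSet
#'
#' Reads the first three columns of a BED file (tab- or space-separated;
#' 0-based half-open coordinates). Strand and any further columns are
#' ignored: regions are treated purely as position intervals. Lines that do
#' not parse raise an error naming the line number; \code{end <= start} is a
#' validation error.
#'
#' @param path path to the BED file.
#' @param name label for the set; defaults to the file base name without
#'   extension.
#' @inheritParams regionSet
#' @return a \code{\linkS4class{RegionSet}} (sorted; merged unless
#'   \code{merge = FALSE}).
#' @seealso \code{\link{writeRegions}} for the inverse.
#' @export
readRegions <- function(path, name = NULL,
                        genome = NULL, merge = TRUE) {
    if (!file.exists(path))
        stop("BED file not found: ", path)
    if (is.null(name))
        name <- sub("\\.[^.]*$", "", basename(path))
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines))
        return(regionSet(name, character(0), numeric(0), numeric(0),
                         genome = genome, merge = merge))
    fields <- strsplit(lines, "[\t ]+")
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("BED parse error at line ", which(nf < 3L)[1L], " of ", path,
             ": fewer than 3 columns")
    chrom <- vapply(fields, `[`, character(1), 1L)
    start <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad))
        stop("BED parse error at line ", bad[1L], " of ", path,
             ": non-numeric coordinate")
    bad <- which(end <= start | start < 0)
    if (length(bad))
        stop("invalid region at line ", bad[1L], " of ", path,
             ": need 0 <= start < end (got ", chrom[bad[1L]], ":",
             start[bad[1L]], "-", end[bad[1L]], ")")
    regionSet(name, chrom, start, end, genome = genome, merge = merge)
}

#' Write a RegionSet as a 3-column BED file
#'
#' Emits tab-separated \code{chrom start end} in 0-based half-open
#' coordinates. For a sorted, merged set, \code{readRegions} followed by
#' \code{writeRegions} round-trips the first three BED columns exactly.
#'
#' @param rs a \code{\linkS4class{RegionSet}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeRegions <- function(rs, path) {
    stopifnot(methods::is(rs, "RegionSet"))
    gr <- rs@regions
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                     start = format(GenomicRanges::start(gr) - 1, scientific = FALSE, trim = TRUE),
                     end = format(GenomicRanges::end(gr), scientific = FALSE, trim = TRUE))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a chromosome-sizes table
#'
#' Parses a UCSC chromInfo-style two-column text file (chromosome name,
#' length in bp, whitespace-separated) into a \code{Seqinfo}, the genome
#' container used throughout the package.
#'
#' @param path path to the chromosome-sizes file.
#' @return a \code{Seqinfo} with one entry per chromosome.
#' @examples
#' tf <- tempfile()
#' writeLines(c("chr1\t1000000", "chr2\t500000"), tf)
#' readChromSizes(tf)
#' @export
readChromSizes <- function(path) {
    if (!file.exists(path))
        stop("chromosome-sizes file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines))
        stop("no chromosomes in ", path)
    fields <- strsplit(trimws(lines), "[\t ]+")
    nf <- lengths(fields)
    if (any(nf < 2L))
        stop("chromosome-sizes parse error at line ", which(nf < 2L)[1L],
             " of ", path, ": need two columns")
    chrom <- vapply(fields, `[`, character(1), 1L)
    len <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
    if (any(is.na(len)))
        stop("non-integer chromosome length at line ", which(is.na(len))[1L],
             " of ", path)
    genomeInfo(stats::setNames(len, chrom))
}

#' Build a genome (Seqinfo) from a named vector of chromosome lengths
#'
#' @param chromLengths named numeric vector, chromosome name to length in bp.
#' @return a \code{Seqinfo}.
#' @examples
#' genomeInfo(c(chr1 = 1e6, chr2 = 5e5))
#' @export
genomeInfo <- function(chromLengths) {
    if (!length(chromLengths) || is.null(names(chromLengths)))
        stop("no chromosomes: need a named vector of lengths")
    if (anyDuplicated(names(chromLengths)))
        stop("duplicate chromosome name(s): ",
             paste(unique(names(chromLengths)[duplicated(names(chromLengths))]),
                   collapse = ", "))
    if (any(is.na(chromLengths)) || any(chromLengths <= 0) ||
        any(chromLengths != round(chromLengths)))
        stop("chromosome lengths must be positive integers")
    GenomeInfoDb::Seqinfo(seqnames = names(chromLengths),
                          seqlengths = as.integer(chromLengths))
}

#' Total length of a genome in bp
#'
#' @param genome a \code{Seqinfo}.
#' @return sum of chromosome lengths.
#' @export
genomeSize <- function(genome) {
    stopifnot(methods::is(genome, "Seqinfo"))
    sum(as.numeric(GenomeInfoDb::seqlengths(genome)))
}

#' Fuse overlapping or abutting regions within a set
#'
#' Within-set merging: overlapping and abutting regions are fused into
#' maximal intervals, so that each set becomes a disjoint union of
#' intervals and per-set open state is a simple boolean during the sweep.
#' Total covered bp is preserved.
#'
#' @param rs a \code{\linkS4class{RegionSet}}.
#' @return the merged \code{RegionSet} (with \code{isMerged(rs)} TRUE).
#' @export
mergeRegions <- function(rs) {
    stopifnot(methods::is(rs, "RegionSet"))
    red <- GenomicRanges::reduce(GenomicRanges::sort(rs@regions),
                                 min.gapwidth = 1L)
    methods::new("RegionSet", name = rs@name, regions = red, merged = TRUE)
}

## ---- sub-genome restriction --------------------------------------------

#' Restrict an analysis to a sub-genome
#'
#' Concatenates the (merged) inclusion regions into pseudo-chromosomes, one
#' per source chromosome, and remaps every input region onto them. Region
#' parts falling outside the inclusion regions are discarded. Shuffling and
#' counting then take place entirely inside the sub-genome, which encodes
#' the null-hypothesis assumption that features can only occur there.
#'
#' @param sets list of \code{\linkS4class{RegionSet}}.
#' @param incl a \code{RegionSet} of inclusion regions (merged internally);
#'   must be non-empty.
#' @param genome \code{Seqinfo} of the source genome.
#' @return a list with elements \code{sets} (remapped RegionSets),
#'   \code{map} (the block table, see Details) and \code{genome} (the
#'   sub-genome \code{Seqinfo}).
#'
#' @details The \code{map} is a data.frame with one row per inclusion block:
#' source chromosome, source start/end (0-based half-open), target
#' pseudo-chromosome (named \code{<chrom>_sub}) and target offset. Blocks
#' tile each pseudo-chromosome without gaps, so the remapping is invertible
#' for retained region parts via \code{\link{mapFromSubgenome}}. Fragments
#' of one region that land on adjoining blocks abut across the seam and are
#' fused (merged-set semantics in sub-genome space); the inverse mapping
#' splits them back at block boundaries, so no retained base pair is lost.
#' @export
subgenomeRestrict <- function(sets, incl, genome) {
    stopifnot(is.list(sets), methods::is(incl, "RegionSet"),
              methods::is(genome, "Seqinfo"))
    incl <- mergeRegions(incl)
    blocks <- incl@regions
    if (!length(blocks))
        stop("inclusion set is empty")
    blocks <- .checkAgainstGenome(blocks, genome, what = incl@name)
    src_chrom <- as.character(GenomeInfoDb::seqnames(blocks))
    src_start0 <- GenomicRanges::start(blocks) - 1L
    src_end0 <- GenomicRanges::end(blocks)
    w <- GenomicRanges::width(blocks)
    tgt_chrom <- paste0(src_chrom, "_sub")
    ## per-pseudo-chromosome running offset
    tgt_offset <- unlist(lapply(split(w, factor(src_chrom, unique(src_chrom))),
                                function(x) cumsum(c(0, x[-length(x)]))),
                         use.names = FALSE)
    ## restore original block order after split
    ord <- order(match(src_chrom, unique(src_chrom)), src_start0)
    map <- data.frame(src_chrom = src_chrom, src_start = src_start0,
                      src_end = src_end0, tgt_chrom = tgt_chrom,
                      tgt_offset = NA_real_)[ord, , drop = FALSE]
    map$tgt_offset <- tgt_offset
    sub_len <- tapply(map$src_end - map$src_start, map$tgt_chrom, sum)
    subGenome <- genomeInfo(stats::setNames(as.numeric(sub_len), names(sub_len)))
    restricted <- lapply(sets, function(rs) {
        stopifnot(methods::is(rs, "RegionSet"))
        .remapToSub(rs, map, subGenome)
    })
    list(sets = restricted, map = map, genome = subGenome)
}

.remapToSub <- function(rs, map, subGenome) {
    gr <- rs@regions
    if (!length(gr))
        return(methods::new("RegionSet", name = rs@name,
                            regions = GenomicRanges::GRanges(seqinfo = subGenome),
                            merged = TRUE))
    blocks <- GenomicRanges::GRanges(map$src_chrom,
                                     IRanges::IRanges(map$src_start + 1,
                                                      map$src_end))
    hits <- GenomicRanges::findOverlaps(gr, blocks)
    if (!length(hits)) {
        return(methods::new("RegionSet", name = rs@name,
                            regions = GenomicRanges::GRanges(seqinfo = subGenome),
                            merged = TRUE))
    }
    qi <- S4Vectors::queryHits(hits); bi <- S4Vectors::subjectHits(hits)
    s <- pmax(GenomicRanges::start(gr)[qi], map$src_start[bi] + 1)
    e <- pmin(GenomicRanges::end(gr)[qi], map$src_end[bi])
    new_s <- s - (map$src_start[bi] + 1) + map$tgt_offset[bi] + 1
    new_e <- new_s + (e - s)
    out <- GenomicRanges::GRanges(map$tgt_chrom[bi],
                                  IRanges::IRanges(new_s, new_e),
                                  seqinfo = subGenome)
    out <- GenomicRanges::reduce(GenomicRanges::sort(out), min.gapwidth = 1L)
    methods::new("RegionSet", name = rs@name, regions = out, merged = TRUE)
}

#' Map sub-genome regions back to source coordinates
#'
#' Inverse of the remapping performed by \code{\link{subgenomeRestrict}}:
#' every region (fragment) in pseudo-chromosome coordinates is translated
#' back to its source chromosome and position.
#'
#' @param rs a \code{\linkS4class{RegionSet}} in sub-genome coordinates.
#' @param map the block table returned by \code{subgenomeRestrict}.
#' @param genome the source \code{Seqinfo}.
#' @return a \code{RegionSet} in source coordinates.
#' @export
mapFromSubgenome <- function(rs, map, genome) {
    stopifnot(methods::is(rs, "RegionSet"))
    gr <- rs@regions
    if (!length(gr))
        return(methods::new("RegionSet", name = rs@name,
                            regions = GenomicRanges::GRanges(seqinfo = genome),
                            merged = rs@merged))
    tgt_blocks <- GenomicRanges::GRanges(
        map$tgt_chrom,
        IRanges::IRanges(map$tgt_offset + 1,
                         map$tgt_offset + (map$src_end - map$src_start)))
    hits <- GenomicRanges::findOverlaps(gr, tgt_blocks)
    qi <- S4Vectors::queryHits(hits); bi <- S4Vectors::subjectHits(hits)
    s <- pmax(GenomicRanges::start(gr)[qi], GenomicRanges::start(tgt_blocks)[bi])
    e <- pmin(GenomicRanges::end(gr)[qi], GenomicRanges::end(tgt_blocks)[bi])
    src_s <- s - map$tgt_offset[bi] + map$src_start[bi]
    out <- GenomicRanges::GRanges(map$src_chrom[bi],
                                  IRanges::IRanges(src_s, src_s + (e - s)),
                                  seqinfo = genome)
    out <- GenomicRanges::sort(out)
    methods::new("RegionSet", name = rs@name, regions = out, merged = FALSE)
}
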