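#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<-
#' @importFrom GenomeInfoDb seqnames seqlengths seqlevels
NULL

#' Read a BED3/BED4/BED6 file into a GRanges
#'
#' Coordinates on disk are 0-based half-open (BED native); in memory they are
#' held as 1-based closed GRanges, the standard Bioconductor convention. The
#' two conventions are interconverted losslessly on read/write.
#'
#' @param path Path to a BED3/BED4/BED6 file (tab-separated).
#' @param genome Named numeric vector of chromosome lengths (see
#'   [read_genome()]); intervals exceeding chromosome bounds are rejected.
#' @param strict If `FALSE` (default), records on chromosomes absent from
#'   `genome` are skipped with a warning; if `TRUE` they are an error.
#' @return A sorted [GenomicRanges::GRanges] with metadata columns `name` and
#'   `score` (NA where absent) and strand (`*` where `.` on disk).
#' @export
read_bed <- function(path, genome, strict = FALSE) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) return(empty_gr(genome))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 0L)
  if (any(nf < 3L))
    stop("BED parse error at line ", lineno[which(nf < 3L)[1]],
         ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("BED parse error at line ", lineno[bad[1]],
         ": non-numeric coordinate")
  bad <- which(start < 0 | start >= end)
  if (length(bad))
    stop("BED parse error at line ", lineno[bad[1]],
         ": requires 0 <= start < end (start=", start[bad[1]],
         ", end=", end[bad[1]], ")")
  name <- ifelse(nf >= 4L, vapply(fields, function(f) if (length(f) >= 4) f[4] else ".", ""), NA_character_)
  name[name == "."] <- NA_character_
  score_chr <- ifelse(nf >= 5L, vapply(fields, function(f) if (length(f) >= 5) f[5] else ".", ""), ".")
  score <- suppressWarnings(as.numeric(score_chr))
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) if (length(f) >= 6) f[6] else ".", ""), ".")
  strand[!strand %in% c("+", "-")] <- "*"

  unknown <- !(chrom %in% names(genome))
  if (any(unknown)) {
    if (strict)
      stop("BED parse error at line ", lineno[which(unknown)[1]],
           ": unknown chromosome '", chrom[which(unknown)[1]], "'")
    warning("skipped ", sum(unknown), " record(s) on chromosome(s) absent ",
            "from the genome: ",
            paste(unique(chrom[unknown]), collapse = ", "))
    keep2 <- !unknown
    chrom <- chrom[keep2]; start <- start[keep2]; end <- end[keep2]
    name <- name[keep2]; score <- score[keep2]; strand <- strand[keep2]
    lineno <- lineno[keep2]
    if (!length(chrom)) return(empty_gr(genome))
  }
  over <- end > genome[chrom]
  if (any(over))
    stop("BED parse error at line ", lineno[which(over)[1]],
         ": interval exceeds length of ", chrom[which(over)[1]])
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = names(genome)),
    ranges = IRanges::IRanges(start = start + 1, end = end),
    strand = strand,
    name = name, score = score,
    seqinfo = genome_seqinfo(genome))
  sort_gr(gr)
}

#' Write a GRanges as BED6
#'
#' Inverse of [read_bed()]: emits 0-based half-open coordinates. Missing
#' names become `.`; missing scores become `0` so the file stays canonical
#' BED6; `*` strand becomes `.`.
#'
#' @param gr A GRanges with optional `name`/`score` metadata columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(gr, path) {
  name <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else rep(NA_character_, length(gr))
  score <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else rep(NA_real_, length(gr))
  name[is.na(name)] <- "."
  score_chr <- vapply(score, function(s)
    if (is.na(s)) "0" else format(s, scientific = FALSE, trim = TRUE), "")
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  out <- paste(as.character(seqnames(gr)),
               format_bp(GenomicRanges::start(gr) - 1),
               format_bp(GenomicRanges::end(gr)),
               name, score_chr, strand, sep = "\t")
  writeLines(out, path)
  invisible(path)
}

empty_gr <- function(genome) {
  gr <- GenomicRanges::GRanges(seqinfo = genome_seqinfo(genome))
  mcols(gr)$name <- character(0)
  mcols(gr)$score <- numeric(0)
  gr
}

# reproducible sort: genome (seqlevels) order, then start, then end
sort_gr <- function(gr) {
  gr[order(as.integer(seqnames(gr)), GenomicRanges::start(gr),
           GenomicRanges::end(gr))]
}

#' All overlapping pairs between two interval sets
#'
#' @param a,b GRanges on the same genome.
#' @param min_overlap_bp Minimum overlap in bp for a pair to be reported.
#' @return data.frame with columns `query` (index into `a`), `subject`
#'   (index into `b`) and `overlap_bp`.
#' @export
overlap_pairs <- function(a, b, min_overlap_bp = 1L) {
  stopifnot(min_overlap_bp >= 1L)
  hits <- GenomicRanges::findOverlaps(a, b, minoverlap = min_overlap_bp)
  ov <- IRanges::pintersect(GenomicRanges::ranges(a)[queryHits(hits)],
                            GenomicRanges::ranges(b)[subjectHits(hits)])
  data.frame(query = queryHits(hits), subject = subjectHits(hits),
             overlap_bp = IRanges::width(ov))
}

#' Condition-unique peaks by overlap subtraction
#'
#' Returns the control peaks having no case peak overlapping them by at least
#' `min_overlap_bp` — whole-peak retention, no truncation. With
#' control = control ATAC peaks and case = knockout ATAC peaks this is the
#' reduced-chromatin-accessibility (RCA) call; the symmetric call gives
#' case-unique peaks.
#'
#' @param control,case GRanges peak sets on the same genome build.
#' @param min_overlap_bp Minimum overlap that counts as shared.
#' @return GRanges subset of `control`.
#' @export
subtract_condition <- function(control, case, min_overlap_bp = 1L) {
  n <- GenomicRanges::countOverlaps(control, case, minoverlap = min_overlap_bp)
  control[n == 0L]
}

#' Nearest subject and edge-to-edge distance per query
#'
#' Distance is the edge-to-edge gap in bp, 0 when the intervals overlap or
#' touch; defined only within the same chromosome. Queries without a
#' same-chromosome subject get `NA` in both columns (no-neighbor flag).
#'
#' @param query,subject GRanges on the same genome.
#' @return data.frame with one row per query: `subject` (index or NA) and
#'   `distance` (bp or NA).
#' @export
nearest_distance <- function(query, subject) {
  out <- data.frame(subject = rep(NA_integer_, length(query)),
                    distance = rep(NA_real_, length(query)))
  if (!length(query) || !length(subject)) return(out)
  hits <- GenomicRanges::distanceToNearest(query, subject)
  out$subject[queryHits(hits)] <- subjectHits(hits)
  out$distance[queryHits(hits)] <- mcols(hits)$distance
  out
}

#' Sites within a window of any region
#'
#' With `window_bp = 0` a site must genuinely overlap (>= 1 bp inside) a
#' region — the "embedded" call used for HH-site identification (H-sites
#' inside knockout-unique H3K9me3 domains). With `window_bp > 0` a site is
#' kept when its edge-to-edge distance to some region is at most the window
#' (touching intervals, distance 0, are kept).
#'
#' @param sites,regions GRanges on the same genome.
#' @param window_bp Non-negative window in bp.
#' @return GRanges subset of `sites`.
#' @export
window_intersect <- function(sites, regions, window_bp = 0L) {
  stopifnot(window_bp >= 0)
  if (window_bp == 0) {
    IRanges::subsetByOverlaps(sites, regions)
  } else {
    IRanges::subsetByOverlaps(sites, regions, maxgap = window_bp)
  }
}

#' Filter peaks by score
#'
#' Retains peaks whose score (conventionally -log10 p) is strictly greater
#' than `min_score`; the printed peak filtering uses -log10(p) > 2.
#'
#' @param peaks GRanges with a `score` metadata column.
#' @param min_score Threshold; strict inequality.
#' @return GRanges subset of `peaks`.
#' @export
filter_by_score <- function(peaks, min_score) {
  score <- mcols(peaks)$score
  if (is.null(score))
    stop("filter_by_score: peaks carry no score column")
  if (anyNA(score)) {
    i <- which(is.na(score))[1]
    stop("filter_by_score: missing score for interval ",
         as.character(seqnames(peaks))[i], ":",
         GenomicRanges::start(peaks)[i] - 1, "-", GenomicRanges::end(peaks)[i])
  }
  peaks[score > min_score]
}

#' Count flanking peaks around sites
#'
#' A flanking event is a (site, peak) pair whose edge-to-edge distance is at
#' most `window_bp` (overlap included). A peak within the window of k sites
#' contributes k events — events are occasions, not unique peaks.
#'
#' @param sites,peaks GRanges on the same genome.
#' @param window_bp Window in bp (default 10 kb).
#' @return List with `n_flanked_sites` (sites with >= 1 peak in window) and
#'   `n_flanking_peaks` (total events).
#' @export
count_flanking <- function(sites, peaks, window_bp = 10000L) {
  stopifnot(window_bp > 0)
  hits <- GenomicRanges::findOverlaps(sites, peaks, maxgap = window_bp)
  list(n_flanked_sites = length(unique(queryHits(hits))),
       n_flanking_peaks = length(hits))
}

#' Midpoints of intervals
#'
#' @param gr A GRanges.
#' @return Integer vector of interval midpoints (1-based).
#' @keywords internal
gr_mid <- function(gr) {
  floor((GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2)
}
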