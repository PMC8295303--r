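#' Anchored feature-density matrix
#'
#' The matrix behind the anchor-centered heat-maps: one row per anchor, one
#' column per offset bin spanning `+/- halfwidth_bp` around the anchor
#' midpoint. Every feature whose midpoint falls within the halfwidth of an
#' anchor midpoint increments the bin holding its signed offset
#' (feature - anchor); features outside all windows are ignored. Rows follow
#' the display chromosome order (chr1..9, chrX, chr10..19 for a mouse-like
#' genome; genome order otherwise), then start coordinate.
#'
#' @param anchors,features GRanges on the same genome.
#' @param halfwidth_bp Window half-width in bp (e.g. 5000 or 10000).
#' @param binsize_bp Bin size in bp; must divide `halfwidth_bp`.
#' @param genome Named numeric vector of chromosome lengths (row ordering).
#' @return Integer matrix `length(anchors) x (2*halfwidth/binsize)`; row
#'   names are `chrom:start-end` of each anchor (BED coordinates), column
#'   names the offset-bin midpoints in bp.
#' @export
anchored_matrix <- function(anchors, features, halfwidth_bp, binsize_bp,
                            genome) {
  stopifnot(halfwidth_bp > 0, binsize_bp > 0,
            halfwidth_bp %% binsize_bp == 0)
  ord <- display_order_idx(anchors, genome)
  anchors <- anchors[ord]
  nbin <- as.integer(2 * halfwidth_bp / binsize_bp)
  mat <- matrix(0L, nrow = length(anchors), ncol = nbin)
  rownames(mat) <- paste0(as.character(seqnames(anchors)), ":",
                          GenomicRanges::start(anchors) - 1, "-",
                          GenomicRanges::end(anchors))
  colnames(mat) <- format_bp(seq(-halfwidth_bp + binsize_bp / 2,
                                 halfwidth_bp - binsize_bp / 2,
                                 by = binsize_bp))
  if (!length(anchors) || !length(features)) return(mat)
  amid <- gr_mid(anchors)
  fmid <- gr_mid(features)
  awin <- GenomicRanges::GRanges(seqnames(anchors),
                                 IRanges::IRanges(start = amid - halfwidth_bp,
                                                  end = amid + halfwidth_bp))
  fpt <- GenomicRanges::GRanges(seqnames(features),
                                IRanges::IRanges(start = fmid, width = 1))
  GenomeInfoDb::seqlevels(fpt) <- GenomeInfoDb::seqlevels(awin)
  hits <- GenomicRanges::findOverlaps(fpt, awin, ignore.strand = TRUE)
  if (!length(hits)) return(mat)
  off <- fmid[queryHits(hits)] - amid[subjectHits(hits)]
  bin <- pmin(floor((off + halfwidth_bp) / binsize_bp) + 1L, nbin)
  idx <- cbind(subjectHits(hits), bin)
  for (k in seq_len(nrow(idx)))
    mat[idx[k, 1], idx[k, 2]] <- mat[idx[k, 1], idx[k, 2]] + 1L
  mat
}

display_order_idx <- function(gr, genome) {
  lev <- chrom_display_order(genome)
  order(match(as.character(seqnames(gr)), lev), GenomicRanges::start(gr))
}

#' Nearest-feature distance bracket histogram
#'
#' Bins the nearest-subject distance of every query into the brackets
#' `[0, b1], (b1, b2], ..., (bk, Inf)`; an overlapping pair (distance 0)
#' falls in the first bracket, which is closed on the left. Queries without
#' a same-chromosome subject are reported separately, so bracket counts plus
#' the no-neighbor count always equal the number of queries.
#'
#' @param query,subject GRanges on the same genome.
#' @param brackets_kbp Strictly increasing bracket boundaries in kbp
#'   (default `c(1, 5, 50, 500, 1000)`, reconstructed from the distance
#'   brackets used across the published distance figures).
#' @return List of class `bracket_histogram`: `counts` data.frame
#'   (bracket label, count) and `n_no_neighbor`.
#' @export
bracket_histogram <- function(query, subject,
                              brackets_kbp = c(1, 5, 50, 500, 1000)) {
  stopifnot(length(brackets_kbp) >= 1, all(diff(brackets_kbp) > 0),
            all(brackets_kbp > 0))
  nd <- nearest_distance(query, subject)
  d <- nd$distance[!is.na(nd$distance)]
  breaks <- c(0, brackets_kbp * 1000, Inf)
  labs <- c(paste0("<=", format_bp(brackets_kbp[1]), "kb"),
            if (length(brackets_kbp) > 1)
              paste0(format_bp(brackets_kbp[-length(brackets_kbp)]), "-",
                     format_bp(brackets_kbp[-1]), "kb"),
            paste0(">", format_bp(brackets_kbp[length(brackets_kbp)]), "kb"))
  bins <- cut(d, breaks = breaks, labels = labs, include.lowest = TRUE,
              right = TRUE)
  counts <- as.integer(table(bins))
  structure(list(counts = data.frame(bracket = labs, count = counts),
                 n_no_neighbor = sum(is.na(nd$distance))),
            class = "bracket_histogram")
}

#' @export
print.bracket_histogram <- function(x, ...) {
  print(x$counts)
  cat("no same-chromosome neighbor:", x$n_no_neighbor, "\n")
  invisible(x)
}

#' Write an anchored matrix as TSV
#' @param mat Matrix from [anchored_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(anchor = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
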