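#' Read significant Hi-C contact pairs from BEDPE
#'
#' Columns: chrom1, start1, end1, chrom2, start2, end2, name, score
#' (coordinates 0-based half-open; name/score optional). Anchors of
#' intra-chromosomal pairs are put in canonical orientation (anchor1
#' midpoint < anchor2 midpoint) and duplicate contacts (identical anchor
#' coordinates after orientation) are dropped. Separation is the distance
#' between anchor midpoints.
#'
#' @param path BEDPE path.
#' @param genome Named numeric vector of chromosome lengths.
#' @param strict Escalate unknown chromosomes to an error (default skip with
#'   warning).
#' @return data.frame of class `contact_pairs` with columns chrom1, start1,
#'   end1, chrom2, start2, end2, name, score, intra, separation.
#' @export
read_bedpe <- function(path, genome, strict = FALSE) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines))
    return(contact_pairs(data.frame(chrom1 = character(0), start1 = numeric(0),
                                    end1 = numeric(0), chrom2 = character(0),
                                    start2 = numeric(0), end2 = numeric(0),
                                    name = character(0), score = numeric(0))))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 0L)
  if (any(nf < 6L))
    stop("BEDPE parse error at line ", lineno[which(nf < 6L)[1]],
         ": fewer than 6 fields")
  g <- function(i) vapply(fields, `[[`, "", i)
  gn <- function(i) suppressWarnings(as.numeric(g(i)))
  df <- data.frame(chrom1 = g(1), start1 = gn(2), end1 = gn(3),
                   chrom2 = g(4), start2 = gn(5), end2 = gn(6),
                   name = ifelse(nf >= 7, vapply(fields, function(f)
                     if (length(f) >= 7) f[7] else ".", ""), "."),
                   score = suppressWarnings(as.numeric(
                     ifelse(nf >= 8, vapply(fields, function(f)
                       if (length(f) >= 8) f[8] else "NA", ""), "NA"))))
  bad <- which(is.na(df$start1) | is.na(df$end1) | is.na(df$start2) |
               is.na(df$end2) | df$start1 < 0 | df$start2 < 0 |
               df$start1 >= df$end1 | df$start2 >= df$end2)
  if (length(bad))
    stop("BEDPE parse error at line ", lineno[bad[1]],
         ": invalid anchor coordinates")
  unknown <- !(df$chrom1 %in% names(genome)) | !(df$chrom2 %in% names(genome))
  if (any(unknown)) {
    if (strict)
      stop("BEDPE parse error at line ", lineno[which(unknown)[1]],
           ": unknown chromosome")
    warning("skipped ", sum(unknown),
            " contact(s) on chromosomes absent from the genome")
    df <- df[!unknown, , drop = FALSE]
  }
  contact_pairs(df)
}

#' Construct a contact-pair table
#'
#' Canonicalizes orientation, computes midpoint separation, deduplicates by
#' coordinate identity and flags intra-chromosomal pairs.
#'
#' @param df data.frame with chrom1, start1, end1, chrom2, start2, end2 and
#'   optional name, score (0-based half-open anchors).
#' @return data.frame of class `contact_pairs`.
#' @export
contact_pairs <- function(df) {
  if (is.null(df$name)) df$name <- rep(".", nrow(df))
  if (is.null(df$score)) df$score <- rep(NA_real_, nrow(df))
  mid1 <- floor((df$start1 + df$end1) / 2)
  mid2 <- floor((df$start2 + df$end2) / 2)
  flip <- df$chrom1 == df$chrom2 & mid1 > mid2
  if (any(flip)) {
    tmp <- df[flip, c("start1", "end1")]
    df[flip, c("start1", "end1")] <- df[flip, c("start2", "end2")]
    df[flip, c("start2", "end2")] <- tmp
    m <- mid1[flip]; mid1[flip] <- mid2[flip]; mid2[flip] <- m
  }
  df$intra <- df$chrom1 == df$chrom2
  df$separation <- ifelse(df$intra, mid2 - mid1, NA_real_)
  key <- paste(df$chrom1, df$start1, df$end1,
               df$chrom2, df$start2, df$end2, sep = "|")
  df <- df[!duplicated(key), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("contact_pairs", "data.frame")
  df
}

#' Filter contacts by anchor separation
#'
#' Retains intra-chromosomal pairs separated by at least `min_sep` and at
#' most `max_sep` (both bounds inclusive); inter-chromosomal pairs are
#' always dropped. Idempotent.
#'
#' @param pairs A `contact_pairs` table.
#' @param min_sep Minimum midpoint separation in bp (default 1 kb).
#' @param max_sep Maximum midpoint separation in bp (default 10 Mb).
#' @return Filtered `contact_pairs` table.
#' @export
filter_contacts <- function(pairs, min_sep = 1000, max_sep = 1e7) {
  stopifnot(min_sep >= 0, max_sep >= min_sep)
  keep <- pairs$intra & pairs$separation >= min_sep &
    pairs$separation <= max_sep
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

anchor_gr <- function(pairs, side, genome) {
  ch <- if (side == 1) pairs$chrom1 else pairs$chrom2
  s <- if (side == 1) pairs$start1 else pairs$start2
  e <- if (side == 1) pairs$end1 else pairs$end2
  GenomicRanges::GRanges(seqnames = factor(ch, levels = names(genome)),
                         ranges = IRanges::IRanges(start = s + 1, end = e),
                         seqinfo = genome_seqinfo(genome))
}

#' Find promoter-anchored contacts (areas-1)
#'
#' An anchor lying within `window` bp (edge-to-edge against the anchor
#' interval, bound inclusive) of a promoter RCA becomes an area-1; its
#' partner anchor is the area-2. Both anchors of a pair are eligible by
#' default, so a contact matching p-RCAs at both anchors yields two hits;
#' `both_anchors = FALSE` restricts matching to anchor 1. When an anchor is
#' within the window of several p-RCAs the nearest one is reported.
#'
#' @param pairs Filtered `contact_pairs` table (see [filter_contacts()]).
#' @param p_rcas GRanges of promoter RCAs (optionally named via `name`).
#' @param genome Named numeric vector of chromosome lengths.
#' @param window Matching window in bp (default 1000, inclusive).
#' @param both_anchors Consider both anchors as candidate areas-1.
#' @return data.frame of class `area1_hits`: contact (row index into
#'   `pairs`), side (1/2), p_rca (index), p_rca_id, distance, separation,
#'   and the area-2 anchor coordinates (chrom, start2, end2, 0-based
#'   half-open).
#' @export
find_area1 <- function(pairs, p_rcas, genome, window = 1000,
                       both_anchors = TRUE) {
  sides <- if (both_anchors) 1:2 else 1L
  res <- lapply(sides, function(side) {
    agr <- anchor_gr(pairs, side, genome)
    nd <- nearest_distance(agr, p_rcas)
    hit <- which(!is.na(nd$distance) & nd$distance <= window)
    if (!length(hit)) return(NULL)
    other <- if (side == 1) 2L else 1L
    data.frame(contact = hit, side = side,
               p_rca = nd$subject[hit],
               p_rca_id = prca_ids(p_rcas)[nd$subject[hit]],
               distance = nd$distance[hit],
               separation = pairs$separation[hit],
               chrom = if (other == 1) pairs$chrom1[hit] else pairs$chrom2[hit],
               area2_start = if (other == 1) pairs$start1[hit] else pairs$start2[hit],
               area2_end = if (other == 1) pairs$end1[hit] else pairs$end2[hit])
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(contact = integer(0), side = integer(0),
                      p_rca = integer(0), p_rca_id = character(0),
                      distance = numeric(0), separation = numeric(0),
                      chrom = character(0), area2_start = numeric(0),
                      area2_end = numeric(0))
  out <- out[order(out$contact, out$side), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("area1_hits", "data.frame")
  out
}

prca_ids <- function(p_rcas) {
  nm <- mcols(p_rcas)$name
  if (is.null(nm)) nm <- rep(NA_character_, length(p_rcas))
  ifelse(is.na(nm), paste0("p_rca_", seq_along(p_rcas)), nm)
}

area2_gr <- function(hits, genome) {
  GenomicRanges::GRanges(
    seqnames = factor(hits$chrom, levels = names(genome)),
    ranges = IRanges::IRanges(start = hits$area2_start + 1,
                              end = hits$area2_end),
    seqinfo = genome_seqinfo(genome))
}

#' Profile the distal anchors (areas-2)
#'
#' For every area-2: nearest i-RCA and H-site distances, and counts of
#' i-RCAs / H-sites lying strictly closer than `window` bp (the published
#' wording is "< 50 Kbp", so the count bound is exclusive while the nearest
#' distance is reported as-is). Areas-2 on a chromosome without any i-RCA
#' (or H-site) get NA distances and zero counts.
#'
#' @param hits An `area1_hits` table (see [find_area1()]).
#' @param i_rcas GRanges of intergenic RCAs.
#' @param h_sites GRanges of hypermethylation sites.
#' @param genome Named numeric vector of chromosome lengths.
#' @param window Neighborhood radius in bp (default 50000, exclusive).
#' @return data.frame of class `area2_profile`: per hit, nearest_irca_bp,
#'   n_irca_within, nearest_hsite_bp, n_hsite_within, plus the hit columns.
#' @export
area2_profile <- function(hits, i_rcas, h_sites, genome, window = 50000) {
  stopifnot(nrow(hits) > 0)
  a2 <- area2_gr(hits, genome)
  prof <- function(set) {
    nd <- nearest_distance(a2, set)
    nwin <- GenomicRanges::countOverlaps(a2, set, maxgap = window - 1L)
    list(nearest = nd$distance, n = nwin)
  }
  pi <- prof(i_rcas)
  ph <- prof(h_sites)
  out <- cbind(hits,
               data.frame(nearest_irca_bp = pi$nearest,
                          n_irca_within = pi$n,
                          nearest_hsite_bp = ph$nearest,
                          n_hsite_within = ph$n))
  class(out) <- c("area2_profile", "data.frame")
  out
}

#' Summarize the contact-mining stage
#'
#' Separation statistics over area-1 hits, and (when a pairing result is
#' supplied) the per-gene report: number of distinct interacting areas-2 per
#' downregulated gene and whether at least one of its areas-2 has an i-RCA
#' inside the neighborhood window — the three-criteria gene list (gene with
#' a promoter RCA near a contact anchor; its distal anchors; i-RCA support).
#'
#' @param hits An `area1_hits` table.
#' @param profiles An `area2_profile` table aligned with `hits`.
#' @param pairing Optional `pairing_result` linking p-RCAs to gene ids.
#' @return List with `separation` (mean/min/max bp, n), and `per_gene`
#'   data.frame (gene_id, n_contacts, n_area2_with_irca, has_irca_support)
#'   when `pairing` is given.
#' @export
contact_summary <- function(hits, profiles, pairing = NULL) {
  sep <- list(n = nrow(hits),
              mean_bp = if (nrow(hits)) mean(hits$separation) else NA_real_,
              min_bp = if (nrow(hits)) min(hits$separation) else NA_real_,
              max_bp = if (nrow(hits)) max(hits$separation) else NA_real_)
  per_gene <- NULL
  if (!is.null(pairing)) {
    stopifnot(inherits(pairing, "pairing_result"))
    map <- unique(pairing$pairs[c("p_rca", "gene_id")])
    joined <- merge(cbind(profiles, hit = seq_len(nrow(profiles))),
                    map, by = "p_rca")
    if (nrow(joined)) {
      sp <- split(joined, joined$gene_id)
      per_gene <- do.call(rbind, lapply(names(sp), function(g) {
        x <- sp[[g]]
        data.frame(gene_id = g,
                   n_contacts = length(unique(x$contact)),
                   n_area2_with_irca = sum(x$n_irca_within > 0),
                   has_irca_support = any(x$n_irca_within > 0))
      }))
      per_gene <- per_gene[order(per_gene$gene_id), , drop = FALSE]
      rownames(per_gene) <- NULL
    } else {
      per_gene <- data.frame(gene_id = character(0), n_contacts = integer(0),
                             n_area2_with_irca = integer(0),
                             has_irca_support = logical(0))
    }
  }
  list(separation = sep, per_gene = per_gene)
}
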