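# Brute-force O(n*m) reference implementations used as oracles against the
# interval-tree-backed operations, plus random-instance builders.

tiny_genome <- function(n_chroms = 3, len = 1e6) {
  stats::setNames(rep(len, n_chroms), paste0("chr", seq_len(n_chroms)))
}

rand_gr <- function(n, genome, max_width = 500, score = FALSE) {
  chrom <- sample(names(genome), n, replace = TRUE)
  start <- floor(runif(n, 1, genome[chrom] - max_width - 1))
  width <- sample.int(max_width, n, replace = TRUE)
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = names(genome)),
    ranges = IRanges::IRanges(start = start, width = width),
    seqinfo = chromRCA::genome_seqinfo(genome))
  S4Vectors::mcols(gr)$name <- sprintf("f%04d", seq_len(n))
  S4Vectors::mcols(gr)$score <- if (score) round(runif(n, 0, 10), 3)
                                else rep(NA_real_, n)
  gr
}

gr_fields <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             s = GenomicRanges::start(gr), e = GenomicRanges::end(gr))
}

# overlap width of 1-based closed intervals; <= 0 means disjoint
bf_ov_width <- function(s1, e1, s2, e2) pmin(e1, e2) - pmax(s1, s2) + 1

# edge-to-edge gap in bp, 0 when overlapping or adjacent-touching
bf_gap <- function(s1, e1, s2, e2) pmax(0, pmax(s1, s2) - pmin(e1, e2) - 1)

bf_overlap_pairs <- function(a, b, min_overlap = 1) {
  fa <- gr_fields(a); fb <- gr_fields(b)
  out <- list()
  for (i in seq_len(nrow(fa))) for (j in seq_len(nrow(fb))) {
    if (fa$chrom[i] != fb$chrom[j]) next
    w <- bf_ov_width(fa$s[i], fa$e[i], fb$s[j], fb$e[j])
    if (w >= min_overlap)
      out[[length(out) + 1]] <- c(i, j, w)
  }
  if (!length(out))
    return(data.frame(query = integer(0), subject = integer(0),
                      overlap_bp = integer(0)))
  m <- do.call(rbind, out)
  data.frame(query = m[, 1], subject = m[, 2], overlap_bp = m[, 3])
}

bf_subtract_idx <- function(control, case, min_overlap = 1) {
  pr <- bf_overlap_pairs(control, case, min_overlap)
  setdiff(seq_along(control), unique(pr$query))
}

bf_nearest <- function(query, subject) {
  fq <- gr_fields(query); fs <- gr_fields(subject)
  t(vapply(seq_len(nrow(fq)), function(i) {
    same <- which(fs$chrom == fq$chrom[i])
    if (!length(same)) return(c(NA_real_, NA_real_))
    d <- bf_gap(fq$s[i], fq$e[i], fs$s[same], fs$e[same])
    k <- which.min(d)
    c(same[k], d[k])
  }, c(0, 0)))
}

bf_window_idx <- function(sites, regions, window) {
  fs <- gr_fields(sites); fr <- gr_fields(regions)
  keep <- logical(nrow(fs))
  for (i in seq_len(nrow(fs))) {
    same <- which(fr$chrom == fs$chrom[i])
    if (!length(same)) next
    if (window == 0) {
      keep[i] <- any(bf_ov_width(fs$s[i], fs$e[i],
                                 fr$s[same], fr$e[same]) >= 1)
    } else {
      keep[i] <- any(bf_gap(fs$s[i], fs$e[i],
                            fr$s[same], fr$e[same]) <= window)
    }
  }
  which(keep)
}

bf_flank <- function(sites, peaks, window) {
  pr <- list(n_sites = 0L, n_events = 0L)
  fs <- gr_fields(sites); fp <- gr_fields(peaks)
  events <- 0L; flanked <- logical(nrow(fs))
  for (i in seq_len(nrow(fs))) for (j in seq_len(nrow(fp))) {
    if (fs$chrom[i] != fp$chrom[j]) next
    if (bf_gap(fs$s[i], fs$e[i], fp$s[j], fp$e[j]) <= window) {
      events <- events + 1L
      flanked[i] <- TRUE
    }
  }
  list(n_flanked_sites = sum(flanked), n_flanking_peaks = events)
}

bf_tad_table <- function(tads, setA, setB) {
  hasA <- lengths(lapply(seq_along(tads), function(i)
    which(bf_overlap_pairs(tads[i], setA)$query == 1))) > 0
  hasB <- lengths(lapply(seq_along(tads), function(i)
    which(bf_overlap_pairs(tads[i], setB)$query == 1))) > 0
  c(both = sum(hasA & hasB), A = sum(hasA & !hasB),
    B = sum(!hasA & hasB), none = sum(!hasA & !hasB))
}

bf_chi2_oe <- function(a, b, cc, d) {
  obs <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
  exp <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  sum((obs - exp)^2 / exp)
}

bf_anchored_total <- function(anchors, features, halfwidth) {
  fa <- gr_fields(anchors); ff <- gr_fields(features)
  am <- floor((fa$s + fa$e) / 2); fm <- floor((ff$s + ff$e) / 2)
  tot <- 0L
  for (i in seq_len(nrow(fa))) for (j in seq_len(nrow(ff))) {
    if (fa$chrom[i] == ff$chrom[j] && abs(fm[j] - am[i]) <= halfwidth)
      tot <- tot + 1L
  }
  tot
}

# all permutations of 1..n (n small), as a matrix with one row per perm
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# exact two-sided permutation p for Spearman, distinct values assumed
bf_spearman_exact <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  s_obs <- sum((rx - ry)^2)
  pm <- all_perms(n)
  s_all <- rowSums((pm - matrix(ry[order(rx)], nrow(pm), n, byrow = TRUE))^2)
  p <- 2 * min(mean(s_all <= s_obs), mean(s_all >= s_obs))
  min(p, 1)
}
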