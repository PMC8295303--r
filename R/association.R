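#' Per-chromosome feature density
#'
#' @param features GRanges.
#' @param genome Named numeric vector of chromosome lengths.
#' @return Named numeric vector: features per Mbp, one entry per genome
#'   chromosome (0 where a chromosome has no features).
#' @export
chromosome_density <- function(features, genome) {
  counts <- table(factor(as.character(seqnames(features)),
                         levels = names(genome)))
  as.numeric(counts) / (genome / 1e6)
}

#' Spearman correlation between two density vectors
#'
#' Nonparametric Spearman rank correlation with average ranks for ties. The
#' two-tailed p-value uses the exact null distribution of the rank statistic
#' for n <= 12 without ties and the t-approximation otherwise (no
#' multiple-comparison adjustment, matching the source analysis).
#'
#' @param a,b Named numeric vectors over the same chromosomes.
#' @return List with `r` (rho) and `p` (two-tailed).
#' @export
density_correlation <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!identical(names(a), names(b)))
      stop("density_correlation: chromosome sets differ")
  }
  n <- length(a)
  if (n < 4) stop("density_correlation: need >= 4 chromosomes")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("density_correlation: zero-variance vector")
  ties <- anyDuplicated(a) > 0 || anyDuplicated(b) > 0
  use_exact <- n <= 12 && !ties
  ct <- suppressWarnings(
    stats::cor.test(a, b, method = "spearman", exact = use_exact,
                    alternative = "two.sided"))
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Pair promoter RCAs with downregulated-gene regions
#'
#' Reports all (p-RCA, gene) pairs whose edge-to-edge distance is at most
#' `max_dist_bp` (closed bound: exactly 5,000 bp qualifies, 5,001 does not).
#' A p-RCA may pair with several genes and vice versa; unique counts of both
#' are reported alongside the pair list.
#'
#' @param p_rcas GRanges of promoter-annotated RCAs.
#' @param n_rna GRanges of reduced-expression regions with gene ids in the
#'   `name` metadata column (see [n_rna_regions()]).
#' @param max_dist_bp Maximum pairing distance in bp (default 5000).
#' @return List of class `pairing_result`: `pairs` data.frame (p_rca index,
#'   p_rca_id, gene_id, distance), `n_pairs`, `n_genes`, `n_prcas`.
#' @export
pair_prca_with_downregulated <- function(p_rcas, n_rna, max_dist_bp = 5000L) {
  stopifnot(max_dist_bp >= 0)
  if (is.null(mcols(n_rna)$name) || anyNA(mcols(n_rna)$name))
    stop("pair_prca_with_downregulated: n_rna intervals must be named by gene id")
  hits <- GenomicRanges::findOverlaps(p_rcas, n_rna, maxgap = max_dist_bp,
                                      ignore.strand = TRUE)
  d <- GenomicRanges::distance(p_rcas[queryHits(hits)],
                               n_rna[subjectHits(hits)], ignore.strand = TRUE)
  prca_id <- if (!is.null(mcols(p_rcas)$name))
    mcols(p_rcas)$name[queryHits(hits)] else as.character(queryHits(hits))
  pairs <- data.frame(p_rca = queryHits(hits), p_rca_id = prca_id,
                      gene_id = mcols(n_rna)$name[subjectHits(hits)],
                      distance = as.numeric(d))
  structure(list(pairs = pairs,
                 n_pairs = nrow(pairs),
                 n_genes = length(unique(pairs$gene_id)),
                 n_prcas = length(unique(pairs$p_rca))),
            class = "pairing_result")
}

#' TAD-level co-occurrence contingency table
#'
#' Classifies every TAD by whether it overlaps at least one member of
#' `setA` and/or `setB`. Membership is any-overlap (>= 1 bp) by default; a
#' feature spanning two adjacent TADs counts for both. `type = "within"`
#' restricts membership to features fully contained in the TAD
#' (bedops-style containment).
#'
#' @param tads GRanges of TADs (may be non-overlapping or nested).
#' @param setA,setB GRanges feature sets (e.g. p-RCAs and i-RCAs).
#' @param type "any" (default) or "within".
#' @return List of class `cooccurrence_table`: n_both, n_A_only, n_B_only,
#'   n_neither, N.
#' @export
tad_cooccurrence <- function(tads, setA, setB, type = c("any", "within")) {
  type <- match.arg(type)
  member <- function(set) {
    if (type == "any")
      GenomicRanges::countOverlaps(tads, set, ignore.strand = TRUE) > 0
    else
      tad_contains_any(tads, set)
  }
  hasA <- member(setA)
  hasB <- member(setB)
  cooccurrence_table(n_both = sum(hasA & hasB),
                     n_A_only = sum(hasA & !hasB),
                     n_B_only = sum(!hasA & hasB),
                     n_neither = sum(!hasA & !hasB))
}

tad_contains_any <- function(tads, set) {
  hits <- GenomicRanges::findOverlaps(set, tads, type = "within",
                                      ignore.strand = TRUE)
  seq_along(tads) %in% subjectHits(hits)
}

#' Construct a 2x2 co-occurrence table
#' @param n_both,n_A_only,n_B_only,n_neither Non-negative cell counts.
#' @return List of class `cooccurrence_table`.
#' @export
cooccurrence_table <- function(n_both, n_A_only, n_B_only, n_neither) {
  cells <- c(n_both, n_A_only, n_B_only, n_neither)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  structure(list(n_both = n_both, n_A_only = n_A_only, n_B_only = n_B_only,
                 n_neither = n_neither, N = sum(cells)),
            class = "cooccurrence_table")
}

#' Pearson chi-squared test on a 2x2 co-occurrence table
#'
#' Uncorrected Pearson statistic
#' `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with
#' a = both, b = A-only, c = B-only, d = neither; no Yates continuity
#' correction. P-value from the chi-squared distribution with 1 df; odds
#' ratio ad/bc (`Inf`, flagged with a warning, when bc = 0).
#'
#' @param table A `cooccurrence_table`.
#' @return List with `chi2`, `p`, `odds_ratio`.
#' @export
chi_square_2x2 <- function(table) {
  stopifnot(inherits(table, "cooccurrence_table"))
  a <- table$n_both; b <- table$n_A_only
  cc <- table$n_B_only; d <- table$n_neither
  N <- table$N
  if (N == 0) stop("chi_square_2x2: empty table")
  m <- c(a + b, cc + d, a + cc, b + d)
  if (any(m == 0))
    stop("chi_square_2x2: degenerate margin (a zero row or column total)")
  chi2 <- N * (a * d - b * cc)^2 / prod(m)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  if (b * cc == 0) {
    warning("chi_square_2x2: zero off-diagonal product; odds ratio is Inf")
    or <- Inf
  } else {
    or <- (a * d) / (b * cc)
  }
  list(chi2 = chi2, p = p, odds_ratio = or)
}
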