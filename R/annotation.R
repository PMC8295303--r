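#' Annotation configuration
#'
#' Two promoter windows coexist in the analysis: ATAC/RCA genomic annotation
#' uses a core-promoter window of 200 bp around the TSS, while
#' methylation-site promoter calls use 1 kb. Both are carried here and each
#' pipeline stage names which one it uses.
#'
#' @param promoter_window_bp Core promoter window (bp, default 200).
#' @param promoter_window_alt_bp Wide promoter window (bp, default 1000).
#' @return List of class `annotation_config`.
#' @export
annotation_config <- function(promoter_window_bp = 200L,
                              promoter_window_alt_bp = 1000L) {
  stopifnot(promoter_window_bp > 0, promoter_window_alt_bp > 0)
  structure(list(promoter_window_bp = as.integer(promoter_window_bp),
                 promoter_window_alt_bp = as.integer(promoter_window_alt_bp)),
            class = "annotation_config")
}

#' Build a gene-model set
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `strand` (+/-),
#'   `start`, `end` (0-based half-open gene body) and `exons` (semicolon
#'   separated `start-end` blocks, 0-based half-open, within the gene body).
#' @param genome Named numeric vector of chromosome lengths.
#' @return Object of class `gene_models`: list with `genes` (GRanges named by
#'   gene_id), `tss` (width-1 GRanges at each TSS) and `exons` (GRangesList).
#' @export
gene_models <- function(df, genome) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end", "exons")
                %in% names(df)))
  if (anyDuplicated(df$gene_id))
    stop("gene_models: duplicated gene_id")
  if (!all(df$strand %in% c("+", "-")))
    stop("gene_models: strand must be '+' or '-'")
  si <- genome_seqinfo(genome)
  genes <- GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = names(genome)),
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = df$strand, seqinfo = si)
  names(genes) <- df$gene_id
  # TSS: gene start on +, gene end on - (half-open end - 1 on disk scale)
  tss_pos <- ifelse(df$strand == "+", df$start + 1, df$end)
  tss <- GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = names(genome)),
    ranges = IRanges::IRanges(start = tss_pos, width = 1),
    strand = df$strand, seqinfo = si)
  names(tss) <- df$gene_id
  exon_list <- lapply(seq_len(nrow(df)), function(i) {
    blocks <- strsplit(df$exons[i], ";", fixed = TRUE)[[1]]
    se <- do.call(rbind, strsplit(blocks, "-", fixed = TRUE))
    s <- as.numeric(se[, 1]); e <- as.numeric(se[, 2])
    if (any(s < df$start[i]) || any(e > df$end[i]))
      stop("gene_models: exon outside gene body for ", df$gene_id[i])
    GenomicRanges::GRanges(
      seqnames = factor(rep(df$chrom[i], length(s)), levels = names(genome)),
      ranges = IRanges::IRanges(start = s + 1, end = e),
      strand = df$strand[i], seqinfo = si)
  })
  names(exon_list) <- df$gene_id
  structure(list(genes = genes, tss = tss,
                 exons = GenomicRanges::GRangesList(exon_list)),
            class = "gene_models")
}

#' Read gene models from a simplified TSV
#'
#' Expected header: gene_id, chrom, strand, start, end, exons (see
#' [gene_models()] for the column contract).
#'
#' @param path TSV path.
#' @param genome Named numeric vector of chromosome lengths.
#' @return A `gene_models` object.
#' @export
read_gene_models <- function(path, genome) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "character",
                                         "numeric", "numeric", "character"))
  gene_models(df, genome)
}

#' Annotate intervals by genomic context
#'
#' Each interval receives exactly one label from promoter / exon / intron /
#' intergenic, with precedence promoter > exon > intron > intergenic. An
#' interval is a promoter when it lies within `window_bp` of any TSS
#' (strand-aware TSS position; the window itself is symmetric around it),
#' an exon when it overlaps any exon, an intron when it overlaps a gene body
#' without touching an exon, and intergenic otherwise.
#'
#' @param intervals GRanges to annotate.
#' @param genes A `gene_models` object.
#' @param window_bp Promoter window in bp; pass
#'   `cfg$promoter_window_bp` (200, ATAC/RCA annotation) or
#'   `cfg$promoter_window_alt_bp` (1000, methylation-site promoter calls).
#' @return Factor of length `length(intervals)` with levels
#'   promoter, exon, intron, intergenic.
#' @export
annotate_regions <- function(intervals, genes, window_bp = 200L) {
  stopifnot(inherits(genes, "gene_models"), length(genes$genes) > 0,
            window_bp > 0)
  is_prom <- IRanges::overlapsAny(intervals, genes$tss, maxgap = window_bp)
  all_exons <- unlist(genes$exons, use.names = FALSE)
  is_exon <- IRanges::overlapsAny(intervals, all_exons)
  is_body <- IRanges::overlapsAny(intervals, genes$genes)
  lab <- ifelse(is_prom, "promoter",
         ifelse(is_exon, "exon",
         ifelse(is_body, "intron", "intergenic")))
  factor(lab, levels = c("promoter", "exon", "intron", "intergenic"))
}

#' Read a differential-expression table
#'
#' Expected header: gene_id, fold_change, p_value. Fold changes are signed
#' ratios, negative meaning lower in the knockout; tables stating ratios in
#' (0,1) are converted to the signed convention (`fc -> -1/fc`) on load.
#'
#' @param path TSV path.
#' @return data.frame with gene_id, fold_change, p_value.
#' @export
read_de_table <- function(path) {
  de <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric", "numeric"))
  stopifnot(all(c("gene_id", "fold_change", "p_value") %in% names(de)))
  if (any(de$fold_change == 0)) stop("read_de_table: fold_change must be nonzero")
  if (any(de$p_value <= 0 | de$p_value > 1))
    stop("read_de_table: p_value must lie in (0, 1]")
  ratio <- de$fold_change > 0 & de$fold_change < 1
  de$fold_change[ratio] <- -1 / de$fold_change[ratio]
  de
}

#' Select downregulated genes
#'
#' Strict thresholds on both axes: |fold change| > `min_fold` and
#' p < `max_p`, direction down (negative fold change).
#'
#' @param de data.frame as returned by [read_de_table()].
#' @param min_fold Fold-change threshold (default 1.2, strict).
#' @param max_p P-value threshold (default 0.05, strict).
#' @return Character vector of gene ids.
#' @export
select_downregulated <- function(de, min_fold = 1.2, max_p = 0.05) {
  stopifnot(min_fold > 0, max_p > 0)
  de$gene_id[abs(de$fold_change) > min_fold & de$p_value < max_p &
             de$fold_change < 0]
}

#' Reduced-expression regions for downregulated genes
#'
#' Operationalizes a "negative RNA-seq site" as the downregulated gene's
#' annotated gene body (no sub-gene coverage-dip coordinates are defined by
#' the upstream expression analysis; the gene body is the documented proxy).
#'
#' @param down_genes Character vector of downregulated gene ids.
#' @param genes A `gene_models` object; every id must resolve.
#' @return GRanges, one interval per gene spanning its body, with `name` set
#'   to the gene id.
#' @export
n_rna_regions <- function(down_genes, genes) {
  stopifnot(inherits(genes, "gene_models"))
  missing <- setdiff(down_genes, names(genes$genes))
  if (length(missing))
    stop("n_rna_regions: unknown gene id(s): ",
         paste(missing, collapse = ", "))
  gr <- genes$genes[down_genes]
  mcols(gr)$name <- down_genes
  mcols(gr)$score <- rep(NA_real_, length(gr))
  names(gr) <- NULL
  sort_gr(gr)
}
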