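#' Read a per-region signal table
#'
#' Expected header: region_id, chrom, start, end, length, count_atac,
#' count_k4me1, count_k4me3 (coordinates 0-based half-open; counts are raw
#' reads summarized over each RCA region).
#'
#' @param path TSV path.
#' @return data.frame validated for the signal-table contract.
#' @export
read_signal_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "character", "numeric",
                                          "numeric", "numeric", "numeric",
                                          "numeric", "numeric"))
  validate_signal_table(tab)
}

validate_signal_table <- function(tab) {
  need <- c("region_id", "chrom", "start", "end", "length",
            "count_atac", "count_k4me1", "count_k4me3")
  stopifnot(all(need %in% names(tab)))
  if (anyDuplicated(tab$region_id))
    stop("signal table: duplicated region_id")
  if (any(tab$length <= 0)) stop("signal table: length_bp must be > 0")
  counts <- tab[c("count_atac", "count_k4me1", "count_k4me3")]
  if (any(unlist(counts) < 0)) stop("signal table: counts must be >= 0")
  tab
}

#' TPM over a region set
#'
#' Transcripts-per-kilobase-million computed over the region set itself:
#' `TPM_i = (c_i / L_i_kb) / sum_j(c_j / L_j_kb) * 1e6`, so the per-track
#' values sum to 1e6. The normalization basis is the RCA region set, not
#' genome-wide bins; substitute a genome-wide table if that is wanted.
#'
#' @param table Signal table (see [read_signal_table()]).
#' @param track One of "atac", "k4me1", "k4me3".
#' @return Named numeric vector of TPM values (names = region_id).
#' @export
compute_tpm <- function(table, track = c("atac", "k4me1", "k4me3")) {
  track <- match.arg(track)
  counts <- table[[paste0("count_", track)]]
  rate <- counts / (table$length / 1000)
  total <- sum(rate)
  if (total == 0)
    stop("compute_tpm: all counts are zero for track '", track,
         "'; normalization undefined")
  stats::setNames(rate / total * 1e6, table$region_id)
}

#' Classify RCA regions into five chromatin states
#'
#' Regions with a TPM > 4 for either H3K4me3 or H3K4me1 are segregated by
#' the H3K4me3/H3K4me1 ratio: > 1.5 promoter, < 0.67 enhancer, intermediate
#' weak promoter. Regions failing the TPM gate are insulator when the ATAC
#' signal strictly exceeds H3K4me1, weak insulator otherwise. All
#' inequalities are strict, so the boundary cases TPM = 4, ratio = 1.5,
#' ratio = 0.67 and ATAC = H3K4me1 fall to the gate-fail / weak branches.
#' A zero H3K4me1 denominator inside the gate is treated as an infinite
#' ratio (promoter) and flagged with a warning.
#'
#' @param tpm_k4me3,tpm_k4me1,atac_signal Aligned per-region numeric vectors;
#'   `atac_signal` is expected on the same TPM scale as the histone tracks.
#' @param tpm_gate TPM threshold for the active branch (default 4).
#' @param promoter_ratio,enhancer_ratio Ratio cut points (defaults 1.5, 0.67).
#' @return Factor with levels promoter, weak_promoter, enhancer, insulator,
#'   weak_insulator; one label per region.
#' @export
classify_rca <- function(tpm_k4me3, tpm_k4me1, atac_signal,
                         tpm_gate = 4, promoter_ratio = 1.5,
                         enhancer_ratio = 0.67) {
  n <- length(tpm_k4me3)
  stopifnot(length(tpm_k4me1) == n, length(atac_signal) == n)
  active <- pmax(tpm_k4me3, tpm_k4me1) > tpm_gate
  ratio <- tpm_k4me3 / tpm_k4me1
  zero_den <- active & tpm_k4me1 == 0
  if (any(zero_den)) {
    ratio[zero_den] <- Inf
    warning("classify_rca: ", sum(zero_den),
            " region(s) with zero H3K4me1 inside the TPM gate; ",
            "ratio treated as +Inf (promoter)")
  }
  lab <- character(n)
  lab[active & ratio > promoter_ratio] <- "promoter"
  lab[active & ratio < enhancer_ratio] <- "enhancer"
  lab[active & lab == ""] <- "weak_promoter"
  lab[!active & atac_signal > tpm_k4me1] <- "insulator"
  lab[!active & lab == ""] <- "weak_insulator"
  factor(lab, levels = c("promoter", "weak_promoter", "enhancer",
                         "insulator", "weak_insulator"))
}

#' Classify insulator RCAs by CTCF/cohesin occupancy
#'
#' CAC when the region overlaps at least one Rad21 (cohesin) peak and at
#' least one CTCF peak; CNC when Rad21 only; neither otherwise (including
#' CTCF-only).
#'
#' @param insulators GRanges of insulator-class RCA regions.
#' @param ctcf,rad21 GRanges peak sets on the same genome.
#' @return Factor with levels CAC, CNC, neither; one label per region.
#' @export
classify_insulator_cohesin <- function(insulators, ctcf, rad21) {
  has_ctcf <- IRanges::overlapsAny(insulators, ctcf)
  has_rad21 <- IRanges::overlapsAny(insulators, rad21)
  lab <- ifelse(has_rad21 & has_ctcf, "CAC",
         ifelse(has_rad21, "CNC", "neither"))
  factor(lab, levels = c("CAC", "CNC", "neither"))
}

#' Class summary table
#' @param classes Factor of class labels.
#' @return data.frame with class, count and fraction.
#' @export
class_summary <- function(classes) {
  tab <- table(classes)
  data.frame(class = names(tab), count = as.integer(tab),
             fraction = as.numeric(tab) / length(classes))
}
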