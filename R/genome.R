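#' Read a genome file
#'
#' A genome is an ordered map from chromosome name to length in bp, stored as
#' a two-column tab-separated file (chrom, length). Chromosome order in the
#' file defines the canonical sort order for all outputs.
#'
#' @param path Path to a two-column TSV (chrom, length).
#' @return Named numeric vector of chromosome lengths, in file order.
#' @export
read_genome <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) < 2L)
  if (length(bad))
    stop("genome file ", path, ": line ", bad[1], " has fewer than 2 fields")
  nm <- vapply(fields, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (anyNA(len) || any(len <= 0))
    stop("genome file ", path, ": lengths must be positive numbers")
  if (anyDuplicated(nm))
    stop("genome file ", path, ": duplicated chromosome name '",
         nm[duplicated(nm)][1], "'")
  stats::setNames(len, nm)
}

#' Write a genome file
#' @param genome Named numeric vector of chromosome lengths.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genome <- function(genome, path) {
  writeLines(paste(names(genome), format_bp(genome), sep = "\t"), path)
  invisible(path)
}

#' Seqinfo for a genome
#' @param genome Named numeric vector of chromosome lengths.
#' @return A [GenomeInfoDb::Seqinfo] object.
#' @export
genome_seqinfo <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = names(genome),
                        seqlengths = as.integer(genome))
}

#' Chromosome display order
#'
#' Heat-map rows follow the idiosyncratic order chr1..chr9, chrX,
#' chr10..chr19 when the genome looks mouse-like (contains exactly those
#' autosome names plus chrX); otherwise genome-file order is kept.
#'
#' @param genome Named numeric vector of chromosome lengths.
#' @return Character vector of chromosome names in display order.
#' @export
chrom_display_order <- function(genome) {
  nm <- names(genome)
  mouse <- c(paste0("chr", 1:19), "chrX")
  if (all(mouse %in% nm) && all(nm %in% c(mouse, "chrY", "chrM"))) {
    ord <- c(paste0("chr", 1:9), "chrX", paste0("chr", 10:19))
    c(ord, setdiff(nm, ord))
  } else {
    nm
  }
}

# integer-style formatting for coordinates (never scientific notation)
format_bp <- function(x) {
  format(x, scientific = FALSE, trim = TRUE)
}
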