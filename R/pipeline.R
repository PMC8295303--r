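#' Default pipeline configuration
#'
#' All thresholds used anywhere in the pipeline live here with their
#' published defaults, so no stage hard-codes a constant: peak score filter
#' (-log10 p > 2), promoter windows (200 bp for RCA annotation, 1 kb for
#' methylation-site calls), DE thresholds (>1.2-fold, p < 0.05), pairing
#' distance (5 kb), TPM gate (4) and ratio cuts (1.5 / 0.67), contact
#' separation bounds (1 kb - 10 Mb), area-1 match window (1 kb), area-2
#' neighborhood (50 kb), flanking window (10 kb) and distance brackets.
#'
#' @param inputs Named list/character of input paths with names genome,
#'   tads, atac_control, atac_ko, k9_control, k9_ko, hsites, demethylated,
#'   t3tr, utr, ctcf, rad21, genes, de, signal, contacts (as written by
#'   [simulate_chromatin()]).
#' @param ... Threshold overrides (see Details in the function body).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs, ...) {
  cfg <- list(
    inputs = as.list(inputs),
    min_peak_score = 2,          # -log10 p, strict >
    promoter_window_bp = 200,    # RCA/ATAC annotation window
    promoter_window_alt_bp = 1000,  # methylation-site promoter window
    min_fold = 1.2,              # DE fold-change, strict >
    max_p = 0.05,                # DE p-value, strict <
    pair_max_dist_bp = 5000,     # p-RCA:n-RNA-seq pairing, inclusive
    tpm_gate = 4,                # strict >
    promoter_ratio = 1.5,        # strict >
    enhancer_ratio = 0.67,       # strict <
    contact_min_sep = 1000,      # inclusive
    contact_max_sep = 1e7,       # inclusive
    area1_window = 1000,         # inclusive ("within 1 Kbp")
    area2_window = 50000,        # exclusive ("< 50 Kbp")
    flank_window_bp = 10000,
    brackets_kbp = c(1, 5, 50, 500, 1000),
    both_anchors = TRUE,
    strict = FALSE)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("pipeline_config: unknown option(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_pipeline_config(structure(cfg, class = "pipeline_config"))
}

validate_pipeline_config <- function(cfg) {
  num <- c("min_peak_score", "promoter_window_bp", "promoter_window_alt_bp",
           "min_fold", "max_p", "pair_max_dist_bp", "tpm_gate",
           "promoter_ratio", "enhancer_ratio", "contact_min_sep",
           "contact_max_sep", "area1_window", "area2_window",
           "flank_window_bp")
  for (nm in num)
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] < 0)
      stop("pipeline_config: ", nm, " must be a non-negative number")
  if (cfg$contact_max_sep < cfg$contact_min_sep)
    stop("pipeline_config: contact_max_sep < contact_min_sep")
  if (any(diff(cfg$brackets_kbp) <= 0))
    stop("pipeline_config: brackets_kbp must be strictly increasing")
  need <- c("genome", "tads", "atac_control", "atac_ko", "k9_control",
            "k9_ko", "hsites", "demethylated", "t3tr", "utr", "ctcf",
            "rad21", "genes", "de", "signal", "contacts")
  missing <- setdiff(need, names(cfg$inputs))
  if (length(missing))
    stop("pipeline_config: missing input path(s): ",
         paste(missing, collapse = ", "))
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Expects a top-level `inputs` mapping plus optional threshold overrides
#' (same keys as [pipeline_config()]). Relative input paths are resolved
#' against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return List of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$inputs)) stop("pipeline config: no 'inputs' section")
  base <- dirname(normalizePath(path))
  y$inputs <- lapply(y$inputs, function(p)
    if (startsWith(p, "/")) p else file.path(base, p))
  do.call(pipeline_config, c(list(inputs = y$inputs),
                             y[setdiff(names(y), "inputs")]))
}

#' Run the full pipeline
#'
#' Executes every stage in order on the configured inputs and writes a
#' deterministic report bundle to `out_dir`: the RCA BED and annotation
#' summary, chromatin-state classification with insulator sub-typing, the
#' HH-site and demethylation cross-checks, TR flanking counts, the
#' p-RCA:gene pairing table, chromosome-density correlations, the TAD
#' contingency table with its chi-squared test, the area-1/area-2 tables
#' with the per-gene contact report, and a machine-readable `summary.yaml`.
#' A `log.txt` records every threshold used and the md5 checksum of every
#' input, so a bundle is traceable to its exact inputs.
#'
#' @param cfg A `pipeline_config` (or path to a YAML config).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(cfg, out_dir) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  for (nm in names(cfg$inputs))
    if (!file.exists(cfg$inputs[[nm]]))
      stop("run_pipeline: input '", nm, "' not found at ", cfg$inputs[[nm]])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  op <- function(f) file.path(out_dir, f)
  logf <- op("log.txt")
  log_lines <- c("chromRCA pipeline run",
                 "thresholds:",
                 paste0("  ", setdiff(names(cfg), "inputs"), " = ",
                        vapply(cfg[setdiff(names(cfg), "inputs")],
                               function(x) paste(format(x, scientific = FALSE),
                                                 collapse = ","), "")),
                 "input checksums (md5):",
                 paste0("  ", names(cfg$inputs), " = ",
                        vapply(unlist(cfg$inputs), function(f)
                          unname(tools::md5sum(f)), "")))
  writeLines(log_lines, logf)

  genome <- read_genome(cfg$inputs$genome)
  tads <- read_bed(cfg$inputs$tads, genome, strict = cfg$strict)
  atac_ctrl <- read_bed(cfg$inputs$atac_control, genome, strict = cfg$strict)
  atac_ko <- read_bed(cfg$inputs$atac_ko, genome, strict = cfg$strict)
  genes <- read_gene_models(cfg$inputs$genes, genome)
  de <- read_de_table(cfg$inputs$de)
  hsites <- read_bed(cfg$inputs$hsites, genome, strict = cfg$strict)

  ## RCA detection and genomic annotation
  rca <- subtract_condition(atac_ctrl, atac_ko)
  rca_anno <- annotate_regions(rca, genes, window_bp = cfg$promoter_window_bp)
  p_rca <- rca[rca_anno == "promoter"]
  i_rca <- rca[rca_anno == "intergenic"]
  write_bed(rca, op("rca.bed"))
  anno_tab <- as.data.frame(table(rca_anno))
  names(anno_tab) <- c("category", "count")
  write_tsv(anno_tab, op("rca_annotation.tsv"))

  ## chromatin-state classification + insulator sub-typing
  signal <- read_signal_table(cfg$inputs$signal)
  classes <- classify_rca(compute_tpm(signal, "k4me3"),
                          compute_tpm(signal, "k4me1"),
                          compute_tpm(signal, "atac"),
                          tpm_gate = cfg$tpm_gate,
                          promoter_ratio = cfg$promoter_ratio,
                          enhancer_ratio = cfg$enhancer_ratio)
  write_tsv(data.frame(region_id = signal$region_id, class = classes),
            op("rca_classes.tsv"))
  write_tsv(class_summary(classes), op("class_summary.tsv"))
  ins_gr <- signal_regions(signal[classes == "insulator", ], genome)
  ctcf <- read_bed(cfg$inputs$ctcf, genome, strict = cfg$strict)
  rad21 <- read_bed(cfg$inputs$rad21, genome, strict = cfg$strict)
  ins_type <- classify_insulator_cohesin(ins_gr, ctcf, rad21)
  write_tsv(data.frame(region_id = signal$region_id[classes == "insulator"],
                       type = ins_type), op("insulator_types.tsv"))

  ## HH-sites, demethylation cross-check, TR flanking
  k9_ctrl <- filter_by_score(read_bed(cfg$inputs$k9_control, genome,
                                      strict = cfg$strict),
                             cfg$min_peak_score)
  k9_ko <- filter_by_score(read_bed(cfg$inputs$k9_ko, genome,
                                    strict = cfg$strict),
                           cfg$min_peak_score)
  k9_ko_unique <- subtract_condition(k9_ko, k9_ctrl)
  hh <- window_intersect(hsites, k9_ko_unique, window_bp = 0L)
  write_bed(hh, op("hh_sites.bed"))
  demeth <- read_bed(cfg$inputs$demethylated, genome, strict = cfg$strict)
  n_demeth_overlap <- length(window_intersect(hsites, demeth, window_bp = 0L))
  t3tr <- read_bed(cfg$inputs$t3tr, genome, strict = cfg$strict)
  utr <- read_bed(cfg$inputs$utr, genome, strict = cfg$strict)
  fl_t3 <- count_flanking(hh, t3tr, window_bp = cfg$flank_window_bp)
  fl_u <- count_flanking(hh, utr, window_bp = cfg$flank_window_bp)
  write_tsv(data.frame(
    peak_set = c("t3tr", "utr"),
    n_flanked_hh_sites = c(fl_t3$n_flanked_sites, fl_u$n_flanked_sites),
    n_flanking_events = c(fl_t3$n_flanking_peaks, fl_u$n_flanking_peaks)),
    op("flanking.tsv"))

  ## p-RCA : downregulated-gene pairing
  down <- select_downregulated(de, min_fold = cfg$min_fold, max_p = cfg$max_p)
  n_rna <- n_rna_regions(down, genes)
  pairing <- pair_prca_with_downregulated(p_rca, n_rna,
                                          max_dist_bp = cfg$pair_max_dist_bp)
  write_tsv(pairing$pairs[c("p_rca_id", "gene_id", "distance")],
            op("pairing.tsv"))

  ## chromosome densities and correlations
  dens <- list(hsite = chromosome_density(hsites, genome),
               rca = chromosome_density(rca, genome),
               p_rca = chromosome_density(p_rca, genome),
               i_rca = chromosome_density(i_rca, genome))
  cors <- list()
  for (pair in list(c("hsite", "rca"), c("hsite", "p_rca"),
                    c("hsite", "i_rca"), c("p_rca", "i_rca"))) {
    key <- paste(pair, collapse = "_vs_")
    cors[[key]] <- tryCatch(
      density_correlation(dens[[pair[1]]], dens[[pair[2]]]),
      error = function(e) list(r = NA_real_, p = NA_real_))
  }
  write_tsv(data.frame(pair = names(cors),
                       spearman_r = vapply(cors, `[[`, 0, "r"),
                       p_value = vapply(cors, `[[`, 0, "p")),
            op("density_correlation.tsv"))

  ## distance brackets: p-RCA -> nearest H-site, i-RCA -> nearest H-site
  bh_p <- bracket_histogram(p_rca, hsites, brackets_kbp = cfg$brackets_kbp)
  bh_i <- bracket_histogram(i_rca, hsites, brackets_kbp = cfg$brackets_kbp)
  write_tsv(rbind(cbind(query = "p_rca", bh_p$counts),
                  cbind(query = "i_rca", bh_i$counts)),
            op("distance_brackets.tsv"))

  ## TAD co-occurrence
  tab <- tad_cooccurrence(tads, p_rca, i_rca)
  chi <- chi_square_2x2(tab)
  write_tsv(data.frame(n_both = tab$n_both, n_prca_only = tab$n_A_only,
                       n_irca_only = tab$n_B_only, n_neither = tab$n_neither,
                       N = tab$N, chi2 = chi$chi2, p = chi$p,
                       odds_ratio = chi$odds_ratio),
            op("tad_table.tsv"))

  ## Hi-C mining
  contacts <- read_bedpe(cfg$inputs$contacts, genome, strict = cfg$strict)
  filtered <- filter_contacts(contacts, min_sep = cfg$contact_min_sep,
                              max_sep = cfg$contact_max_sep)
  hits <- find_area1(filtered, p_rca, genome, window = cfg$area1_window,
                     both_anchors = cfg$both_anchors)
  summary_list <- list()
  if (nrow(hits)) {
    prof <- area2_profile(hits, i_rca, hsites, genome,
                          window = cfg$area2_window)
    csum <- contact_summary(hits, prof, pairing)
    write_tsv(hits, op("area1.tsv"))
    write_tsv(prof, op("area2_profile.tsv"))
    if (!is.null(csum$per_gene)) write_tsv(csum$per_gene, op("gene_report.tsv"))
  } else {
    prof <- NULL
    csum <- list(separation = list(n = 0, mean_bp = NA, min_bp = NA,
                                   max_bp = NA), per_gene = NULL)
  }

  summary <- list(
    n_rca = length(rca),
    rca_annotation = stats::setNames(as.list(as.integer(anno_tab$count)),
                                     as.character(anno_tab$category)),
    n_p_rca = length(p_rca), n_i_rca = length(i_rca),
    class_counts = stats::setNames(as.list(as.integer(table(classes))),
                                   levels(classes)),
    insulator_types = stats::setNames(as.list(as.integer(table(ins_type))),
                                      levels(ins_type)),
    n_hh_sites = length(hh),
    n_hsites_demethylated = n_demeth_overlap,
    flanking = list(t3tr_events = fl_t3$n_flanking_peaks,
                    t3tr_sites = fl_t3$n_flanked_sites,
                    utr_events = fl_u$n_flanking_peaks),
    n_down_genes = length(down),
    pairing = list(n_pairs = pairing$n_pairs, n_genes = pairing$n_genes,
                   n_prcas = pairing$n_prcas),
    density_correlations = lapply(cors, function(x)
      list(r = x$r, p = x$p)),
    tad = list(n_tads = tab$N, n_both = tab$n_both,
               n_prca = tab$n_both + tab$n_A_only,
               n_irca = tab$n_both + tab$n_B_only,
               chi2 = chi$chi2, p = chi$p, odds_ratio = chi$odds_ratio),
    contacts = list(n_total = nrow(contacts), n_filtered = nrow(filtered),
                    n_area1_hits = nrow(hits),
                    n_matched_prcas = length(unique(hits$p_rca)),
                    mean_separation_bp = csum$separation$mean_bp,
                    min_separation_bp = csum$separation$min_bp,
                    max_separation_bp = csum$separation$max_bp,
                    n_genes_with_irca_support =
                      if (!is.null(csum$per_gene))
                        sum(csum$per_gene$has_irca_support) else 0L))
  yaml::write_yaml(summary, op("summary.yaml"))
  invisible(summary)
}

signal_regions <- function(signal, genome) {
  gr <- GenomicRanges::GRanges(
    seqnames = factor(signal$chrom, levels = names(genome)),
    ranges = IRanges::IRanges(start = signal$start + 1, end = signal$end),
    seqinfo = genome_seqinfo(genome))
  mcols(gr)$name <- signal$region_id
  gr
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x)
    ifelse(is.na(x), "NA", format(x, scientific = FALSE, trim = TRUE,
                                  digits = 10)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
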