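#' Simulation configuration
#'
#' Defines the study conditions the generator plants: a mouse-like genome
#' partitioned into TADs, promoter/intergenic RCAs whose TAD co-occurrence
#' follows a prescribed odds ratio, downregulated genes paired to promoter
#' RCAs within 5 kb, hypermethylation sites spatially clustered around
#' intergenic RCAs, insulator RCAs carrying CTCF/cohesin peaks, and
#' significant Hi-C contacts whose promoter-side anchors sit within 1 kb of
#' paired promoter RCAs while the distal anchors sit near intergenic RCAs.
#' Every planted association is recorded in a ground-truth manifest.
#'
#' @param seed Integer seed; the same seed reproduces all outputs
#'   byte-identically.
#' @param n_chroms Number of chromosomes (20 gives the mouse-like set
#'   chr1..chr19 + chrX, which also triggers the display chromosome order).
#' @param chrom_length Chromosome length in bp.
#' @param mean_tad_size Mean TAD size in bp (TADs partition each chromosome,
#'   sizes uniform in 0.6-1.4 x mean).
#' @param p_tad_prca,p_tad_irca Marginal probabilities that a TAD is flagged
#'   to carry promoter / intergenic RCAs.
#' @param cooccurrence_odds_ratio Odds ratio of the 2x2 TAD flag joint
#'   distribution.
#' @param n_pair_genes,n_pair_prcas Planted p-RCA:gene pairs: `n_pair_genes`
#'   downregulated genes carrying `n_pair_prcas` promoter RCAs in total
#'   (the surplus genes carry two each).
#' @param n_prcas,n_ircas Total promoter / intergenic RCA counts (planted
#'   pairs included in `n_prcas`).
#' @param n_insulators,n_cac,n_cnc Insulator-class RCA regions and how many
#'   carry CTCF+Rad21 (CAC) or Rad21 only (CNC).
#' @param n_weak_insulators Additional RCA regions planted as weak insulator.
#' @param n_hsites,n_hh_sites Hypermethylation sites and the subset embedded
#'   in knockout-unique H3K9me3 domains.
#' @param hsite_clustering_sd Gaussian scatter (bp) of H-sites around their
#'   parent intergenic RCA.
#' @param frac_hsite_noise Fraction of H-sites placed uniformly instead.
#' @param n_demeth,n_demeth_overlap Normally-demethylated control sites and
#'   how many coincide with H-sites.
#' @param n_t3tr_events,n_utr_events Planted T3-bound / unoccupied thyroid
#'   receptor peaks within 10 kb of HH-sites (occasions, not unique peaks).
#' @param n_genes Total genes; `frac_downregulated` of them are planted
#'   downregulated (paired genes included).
#' @param frac_downregulated Fraction of genes downregulated.
#' @param n_up_genes Genes planted significantly upregulated.
#' @param n_contacts Total Hi-C contact pairs (planted promoter-anchored
#'   ones included).
#' @param contact_sep_meanlog,contact_sep_sdlog Lognormal anchor-separation
#'   parameters; the defaults target a mean separation of ~324 kb.
#' @param n_shared_atac,n_ko_only_atac,n_shared_k9,n_bg_ctcf,n_bg_rad21,n_bg_utr
#'   Background peak counts.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 20L,
                       chrom_length = 6e7,
                       mean_tad_size = 1e6,
                       p_tad_prca = 0.20,
                       p_tad_irca = 0.30,
                       cooccurrence_odds_ratio = 9.6,
                       n_pair_genes = 146L,
                       n_pair_prcas = 154L,
                       n_prcas = 400L,
                       n_ircas = 600L,
                       n_insulators = 34L,
                       n_cac = 30L,
                       n_cnc = 4L,
                       n_weak_insulators = 16L,
                       n_hsites = 400L,
                       n_hh_sites = 40L,
                       hsite_clustering_sd = 27500,
                       frac_hsite_noise = 0.15,
                       n_demeth = 300L,
                       n_demeth_overlap = 25L,
                       n_t3tr_events = 69L,
                       n_utr_events = 7L,
                       n_genes = 500L,
                       frac_downregulated = 0.32,
                       n_up_genes = 40L,
                       n_contacts = 500L,
                       contact_sep_meanlog = log(324000) - 0.8^2 / 2,
                       contact_sep_sdlog = 0.8,
                       n_shared_atac = 1500L,
                       n_ko_only_atac = 200L,
                       n_shared_k9 = 200L,
                       n_bg_ctcf = 150L,
                       n_bg_rad21 = 150L,
                       n_bg_utr = 100L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_pair_prcas >= cfg$n_pair_genes,
            cfg$n_prcas >= cfg$n_pair_prcas,
            cfg$n_contacts >= cfg$n_pair_prcas,
            cfg$n_cac + cfg$n_cnc <= cfg$n_insulators,
            cfg$n_hh_sites <= cfg$n_hsites,
            cfg$n_demeth_overlap <= min(cfg$n_demeth, cfg$n_hsites),
            cfg$n_utr_events <= cfg$n_hh_sites,
            cfg$n_t3tr_events >= cfg$n_hh_sites,
            cfg$cooccurrence_odds_ratio > 0,
            cfg$p_tad_prca > 0, cfg$p_tad_prca < 1,
            cfg$p_tad_irca > 0, cfg$p_tad_irca < 1,
            round(cfg$n_genes * cfg$frac_downregulated) >= cfg$n_pair_genes)
  structure(cfg, class = "sim_config")
}

#' Joint 2x2 cell probability from margins and odds ratio
#'
#' Solves for P(A and B) given P(A), P(B) and the odds ratio of the 2x2
#' joint distribution (Plackett construction; closed-form quadratic root).
#'
#' @param pA,pB Marginal probabilities.
#' @param or Odds ratio (> 0).
#' @return Probability of the (A and B) cell.
#' @export
cooccurrence_joint <- function(pA, pB, or) {
  stopifnot(pA > 0, pA < 1, pB > 0, pB < 1, or > 0)
  if (abs(or - 1) < 1e-12) return(pA * pB)
  a <- or - 1
  b <- -((or - 1) * (pA + pB) + 1)
  cc <- or * pA * pB
  p11 <- (-b - sqrt(b^2 - 4 * a * cc)) / (2 * a)
  max(min(p11, pA, pB), max(0, pA + pB - 1))
}

# --- interval registry: rejection-sampled non-overlapping placement -------

reg_new <- function(chroms) {
  reg <- new.env(parent = emptyenv())
  for (ch in chroms) assign(ch, list(s = numeric(0), e = numeric(0)), envir = reg)
  reg
}

reg_add <- function(reg, chrom, s, e) {
  x <- get(chrom, envir = reg)
  assign(chrom, list(s = c(x$s, s), e = c(x$e, e)), envir = reg)
  invisible(NULL)
}

# TRUE when [s,e) with `margin` bp of padding hits nothing in the registry
reg_clear <- function(reg, chrom, s, e, margin = 0) {
  x <- get(chrom, envir = reg)
  if (!length(x$s)) return(TRUE)
  !any(s - margin < x$e & e + margin > x$s)
}

clear_all <- function(avoid, chrom, s, e) {
  for (av in avoid)
    if (!reg_clear(av$reg, chrom, s, e, av$margin)) return(FALSE)
  TRUE
}

# sample a start for a width-`w` interval in [lo, hi) clear of `avoid`
place_in <- function(chrom, lo, hi, w, avoid, max_try = 200L) {
  if (hi - lo < w) return(NA_real_)
  for (i in seq_len(max_try)) {
    s <- floor(stats::runif(1, lo, hi - w))
    if (clear_all(avoid, chrom, s, s + w)) return(s)
  }
  NA_real_
}

feat_df <- function(chrom = character(0), start = numeric(0),
                    end = numeric(0), name = NA_character_,
                    score = NA_real_, strand = ".") {
  if (length(chrom))
    data.frame(chrom = chrom, start = start, end = end, name = name,
               score = score, strand = strand)
  else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               name = character(0), score = numeric(0), strand = character(0))
}

write_bed_df <- function(df, path, genome, columns = 6L) {
  df <- df[order(match(df$chrom, names(genome)), df$start, df$end), ,
           drop = FALSE]
  name <- ifelse(is.na(df$name), ".", df$name)
  score <- ifelse(is.na(df$score), "0",
                  format(round(df$score, 4), scientific = FALSE, trim = TRUE))
  lines <- switch(as.character(columns),
    "3" = paste(df$chrom, format_bp(df$start), format_bp(df$end), sep = "\t"),
    paste(df$chrom, format_bp(df$start), format_bp(df$end), name, score,
          df$strand, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

pack_error <- function(what) {
  stop("simulate_chromatin: could not place ", what,
       " without violating spacing constraints; increase chrom_length / ",
       "n_chroms or reduce feature counts", call. = FALSE)
}

#' Generate a complete synthetic input bundle
#'
#' Writes every file the pipeline reads — genome table, TAD BED, ATAC peak
#' BEDs for control and knockout, H3K9me3 peak BEDs for both conditions,
#' H-site / demethylated-site / TR / CTCF / Rad21 BEDs, gene-model TSV,
#' differential-expression TSV, per-region signal TSV and a contact BEDPE —
#' plus a YAML ground-truth manifest of everything planted. Placement is
#' rejection-sampled against spacing constraints chosen so that each planted
#' association is recoverable exactly (no accidental pairings within the
#' windows the pipeline uses).
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with `paths` (named file paths), `manifest`
#'   (the ground-truth list) and `genome`.
#' @export
simulate_chromatin <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed, kind = "Mersenne-Twister")

  chroms <- if (cfg$n_chroms == 20L) c(paste0("chr", 1:19), "chrX")
            else paste0("chr", seq_len(cfg$n_chroms))
  genome <- stats::setNames(rep(cfg$chrom_length, length(chroms)), chroms)

  ## --- TAD partition ----------------------------------------------------
  tad <- list()
  for (ch in chroms) {
    pos <- 0; s <- numeric(0); e <- numeric(0)
    while (pos < genome[ch]) {
      w <- round(stats::runif(1, 0.6, 1.4) * cfg$mean_tad_size)
      end <- min(pos + w, genome[ch])
      s <- c(s, pos); e <- c(e, end); pos <- end
    }
    tad[[ch]] <- feat_df(ch, s, e, name = paste0(ch, "_tad", seq_along(s)))
  }
  tads <- do.call(rbind, tad); rownames(tads) <- NULL
  n_tads <- nrow(tads)

  ## --- TAD flags from the 2x2 joint -------------------------------------
  p11 <- cooccurrence_joint(cfg$p_tad_prca, cfg$p_tad_irca,
                            cfg$cooccurrence_odds_ratio)
  probs <- c(both = p11, A = cfg$p_tad_prca - p11, B = cfg$p_tad_irca - p11,
             none = 1 - cfg$p_tad_prca - cfg$p_tad_irca + p11)
  u <- stats::runif(n_tads)
  cls <- cut(u, breaks = cumsum(c(0, probs)), labels = names(probs),
             include.lowest = TRUE)
  tads$has_prca <- cls %in% c("both", "A")
  tads$has_irca <- cls %in% c("both", "B")

  ## registries -----------------------------------------------------------
  r <- list(block = reg_new(chroms), gene = reg_new(chroms),
            prca = reg_new(chroms), irca = reg_new(chroms),
            ins = reg_new(chroms), anchor = reg_new(chroms),
            a2zone = reg_new(chroms), hsite = reg_new(chroms),
            k9u = reg_new(chroms), k9s = reg_new(chroms),
            shared = reg_new(chroms), tr = reg_new(chroms))

  ## --- planted pairing modules ------------------------------------------
  # truncated TADs at chromosome ends can be too small to host anything
  roomy <- (tads$end - tads$start) >= 150000
  both_idx <- which(cls == "both" & roomy)
  if (2L * length(both_idx) < cfg$n_pair_genes)
    pack_error("pairing modules (too few TADs flagged for both RCA types)")
  slots <- rep(both_idx[sample.int(length(both_idx))],
               2L)[seq_len(cfg$n_pair_genes)]
  n_double <- cfg$n_pair_prcas - cfg$n_pair_genes
  double_gene <- seq_len(cfg$n_pair_genes) %in%
    sample(cfg$n_pair_genes, n_double)

  genes <- list(); prcas <- list(); anchors1 <- list()
  block_w <- 45000
  for (m in seq_len(cfg$n_pair_genes)) {
    td <- tads[slots[m], ]
    bs <- place_in(td$chrom, td$start + 5000, td$end - 5000, block_w,
                   list(list(reg = r$block, margin = 12000)))
    if (is.na(bs)) pack_error(paste0("pairing module ", m))
    reg_add(r$block, td$chrom, bs, bs + block_w)
    glen <- round(stats::runif(1, 5000, 15000))
    gstart <- bs + 20000; gend <- gstart + glen
    strand <- "+"                       # TSS = gstart; layout is built for +
    genes[[length(genes) + 1]] <-
      data.frame(gene_id = sprintf("gene%04d", m), chrom = td$chrom,
                 strand = strand, start = gstart, end = gend,
                 role = "pair_down", stringsAsFactors = FALSE)
    reg_add(r$gene, td$chrom, gstart, gend)
    # promoter RCA just upstream of the TSS (within the 200 bp window)
    gap <- round(stats::runif(1, 1, 150))
    p1s <- gstart - gap - 500
    pid1 <- sprintf("prca%04d", length(prcas) + 1L)
    prcas[[length(prcas) + 1]] <-
      data.frame(chrom = td$chrom, start = p1s, end = p1s + 500, name = pid1,
                 gene_id = sprintf("gene%04d", m), planted_pair = TRUE)
    reg_add(r$prca, td$chrom, p1s, p1s + 500)
    a1c <- p1s + 250 + round(stats::runif(1, -800, 800))
    anchors1[[length(anchors1) + 1]] <-
      data.frame(chrom = td$chrom, start = a1c - 500, end = a1c + 500,
                 prca = pid1, gene_id = sprintf("gene%04d", m))
    reg_add(r$anchor, td$chrom, a1c - 500, a1c + 500)
    if (double_gene[m]) {               # second promoter RCA across the TSS
      gap2 <- round(stats::runif(1, 1, 150))
      p2s <- gstart + gap2
      pid2 <- sprintf("prca%04d", length(prcas) + 1L)
      prcas[[length(prcas) + 1]] <-
        data.frame(chrom = td$chrom, start = p2s, end = p2s + 500,
                   name = pid2, gene_id = sprintf("gene%04d", m),
                   planted_pair = TRUE)
      reg_add(r$prca, td$chrom, p2s, p2s + 500)
      a2c <- p2s + 250 + round(stats::runif(1, -800, 800))
      anchors1[[length(anchors1) + 1]] <-
        data.frame(chrom = td$chrom, start = a2c - 500, end = a2c + 500,
                   prca = pid2, gene_id = sprintf("gene%04d", m))
      reg_add(r$anchor, td$chrom, a2c - 500, a2c + 500)
    }
  }
  anchors1 <- do.call(rbind, anchors1)
  stopifnot(nrow(anchors1) == cfg$n_pair_prcas)

  ## --- planted contacts: anchor-2 and its intergenic RCA ----------------
  contacts <- list(); ircas <- list()
  for (k in seq_len(nrow(anchors1))) {
    a1 <- anchors1[k, ]
    mid1 <- floor((a1$start + a1$end) / 2)
    placed <- FALSE
    for (try in 1:200) {
      sep <- round(stats::rlnorm(1, cfg$contact_sep_meanlog,
                                 cfg$contact_sep_sdlog))
      if (sep < 1000 || sep > 2.4e6) next
      room_right <- genome[a1$chrom] - mid1 > sep + 30000
      room_left <- mid1 > sep + 30000
      if (!room_right && !room_left) next
      dir <- if (room_right && room_left) sample(c(-1, 1), 1)
             else if (room_right) 1 else -1
      mid2 <- mid1 + dir * sep
      a2s <- mid2 - 500; a2e <- mid2 + 500
      ok <- clear_all(list(list(reg = r$prca, margin = 2500),
                           list(reg = r$block, margin = 2500),
                           list(reg = r$irca, margin = 60000),
                           list(reg = r$anchor, margin = 1500)),
                      a1$chrom, a2s, a2e)
      if (!ok) next
      # intergenic RCA within < 50 kb of the distal anchor
      ioff <- sample(c(-1, 1), 1) * round(stats::runif(1, 2000, 20000))
      is0 <- mid2 + ioff - 250
      ok2 <- is0 > 0 && is0 + 500 < genome[a1$chrom] &&
        clear_all(list(list(reg = r$prca, margin = 1000),
                       list(reg = r$block, margin = 1000),
                       list(reg = r$irca, margin = 1000),
                       list(reg = r$gene, margin = 2500),
                       list(reg = r$a2zone, margin = 0),
                       list(reg = r$anchor, margin = 1500)),
                  a1$chrom, is0, is0 + 500)
      if (!ok2) next
      iid <- sprintf("irca%04d", length(ircas) + 1L)
      ircas[[length(ircas) + 1]] <-
        data.frame(chrom = a1$chrom, start = is0, end = is0 + 500,
                   name = iid, planted_contact = TRUE)
      reg_add(r$irca, a1$chrom, is0, is0 + 500)
      reg_add(r$anchor, a1$chrom, a2s, a2e)
      reg_add(r$a2zone, a1$chrom, mid2 - 60000, mid2 + 60000)
      contacts[[length(contacts) + 1]] <-
        data.frame(chrom1 = a1$chrom, start1 = a1$start, end1 = a1$end,
                   chrom2 = a1$chrom, start2 = a2s, end2 = a2e,
                   name = sprintf("contact%04d", length(contacts) + 1L),
                   score = round(stats::runif(1, 10, 100), 2),
                   planted = TRUE, prca = a1$prca, gene_id = a1$gene_id,
                   irca = iid)
      placed <- TRUE
      break
    }
    if (!placed) pack_error(paste0("planted contact for ", a1$prca))
  }

  ## --- standalone promoter RCAs with host genes -------------------------
  a_tads <- which(tads$has_prca & roomy)
  n_standalone_p <- cfg$n_prcas - cfg$n_pair_prcas
  gi <- cfg$n_pair_genes
  host_tads <- rep(a_tads, length.out = n_standalone_p)
  for (k in seq_len(n_standalone_p)) {
    td <- tads[host_tads[k], ]
    gi <- gi + 1L
    glen <- round(stats::runif(1, 5000, 15000))
    gs <- place_in(td$chrom, td$start + 2000, td$end - 2000, glen + 700,
                   list(list(reg = r$block, margin = 12000),
                        list(reg = r$gene, margin = 2500),
                        list(reg = r$irca, margin = 2500),
                        list(reg = r$ins, margin = 2500),
                        list(reg = r$anchor, margin = 3000),
                        list(reg = r$prca, margin = 2500)))
    if (is.na(gs)) pack_error("standalone promoter RCA")
    gstart <- gs + 700; gend <- gstart + glen
    genes[[length(genes) + 1]] <-
      data.frame(gene_id = sprintf("gene%04d", gi), chrom = td$chrom,
                 strand = "+", start = gstart, end = gend,
                 role = "prca_host", stringsAsFactors = FALSE)
    reg_add(r$gene, td$chrom, gstart, gend)
    gap <- round(stats::runif(1, 1, 150))
    ps <- gstart - gap - 500
    prcas[[length(prcas) + 1]] <-
      data.frame(chrom = td$chrom, start = ps, end = ps + 500,
                 name = sprintf("prca%04d", length(prcas) + 1L),
                 gene_id = sprintf("gene%04d", gi), planted_pair = FALSE)
    reg_add(r$prca, td$chrom, ps, ps + 500)
  }
  prcas <- do.call(rbind, prcas); rownames(prcas) <- NULL

  ## --- standalone intergenic RCAs ---------------------------------------
  b_tads <- which(tads$has_irca & roomy)
  n_standalone_i <- cfg$n_ircas - length(ircas)
  if (n_standalone_i < 0)
    stop("sim_config: n_ircas smaller than the planted contact count")
  itads <- rep(b_tads, length.out = n_standalone_i)
  for (k in seq_len(n_standalone_i)) {
    td <- tads[itads[k], ]
    s <- place_in(td$chrom, td$start + 2000, td$end - 2000, 500,
                  list(list(reg = r$a2zone, margin = 0),
                       list(reg = r$gene, margin = 2500),
                       list(reg = r$block, margin = 2500),
                       list(reg = r$prca, margin = 1000),
                       list(reg = r$irca, margin = 1000),
                       list(reg = r$ins, margin = 1000),
                       list(reg = r$anchor, margin = 2500)))
    if (is.na(s)) pack_error("standalone intergenic RCA")
    ircas[[length(ircas) + 1]] <-
      data.frame(chrom = td$chrom, start = s, end = s + 500,
                 name = sprintf("irca%04d", length(ircas) + 1L),
                 planted_contact = FALSE)
    reg_add(r$irca, td$chrom, s, s + 500)
  }
  ircas <- do.call(rbind, ircas); rownames(ircas) <- NULL

  ## --- insulator-class RCAs and CTCF/Rad21 ------------------------------
  n_ins_all <- cfg$n_insulators + cfg$n_weak_insulators
  ins <- list()
  ins_chroms <- rep(chroms, length.out = n_ins_all)
  for (k in seq_len(n_ins_all)) {
    ch <- ins_chroms[k]
    s <- place_in(ch, 10000, genome[ch] - 10000, 500,
                  list(list(reg = r$a2zone, margin = 0),
                       list(reg = r$gene, margin = 2500),
                       list(reg = r$block, margin = 2500),
                       list(reg = r$prca, margin = 1000),
                       list(reg = r$irca, margin = 1000),
                       list(reg = r$ins, margin = 1000),
                       list(reg = r$anchor, margin = 1000)))
    if (is.na(s)) pack_error("insulator RCA")
    ins[[k]] <- data.frame(chrom = ch, start = s, end = s + 500,
                           name = sprintf("ins%03d", k))
    reg_add(r$ins, ch, s, s + 500)
  }
  ins <- do.call(rbind, ins)
  ins$cohesin_type <- c(rep("CAC", cfg$n_cac), rep("CNC", cfg$n_cnc),
                        rep("neither", n_ins_all - cfg$n_cac - cfg$n_cnc))
  ins$class <- c(rep("insulator", cfg$n_insulators),
                 rep("weak_insulator", cfg$n_weak_insulators))
  # CTCF on CAC; Rad21 on CAC + CNC; centered so overlap is guaranteed
  ctcf <- feat_df(); rad21 <- feat_df()
  typed <- ins[ins$class == "insulator", ]
  cac <- typed[typed$cohesin_type == "CAC", ]
  withr21 <- typed[typed$cohesin_type %in% c("CAC", "CNC"), ]
  mkpeak <- function(x, label)
    feat_df(x$chrom, floor((x$start + x$end) / 2) - 200,
            floor((x$start + x$end) / 2) + 200,
            name = paste0(label, seq_len(nrow(x))),
            score = round(stats::runif(nrow(x), 2.5, 30), 3))
  if (nrow(cac)) ctcf <- mkpeak(cac, "ctcf_p")
  if (nrow(withr21)) rad21 <- mkpeak(withr21, "rad21_p")
  for (bg in list(list(n = cfg$n_bg_ctcf, lab = "ctcf_bg"),
                  list(n = cfg$n_bg_rad21, lab = "rad21_bg"))) {
    rows <- list()
    for (k in seq_len(bg$n)) {
      ch <- sample(chroms, 1)
      s <- place_in(ch, 1000, genome[ch] - 1000, 400,
                    list(list(reg = r$ins, margin = 1000)))
      if (is.na(s)) pack_error("background CTCF/Rad21 peak")
      rows[[k]] <- feat_df(ch, s, s + 400, name = paste0(bg$lab, k),
                           score = round(stats::runif(1, 2.5, 30), 3))
    }
    if (bg$lab == "ctcf_bg") ctcf <- rbind(ctcf, do.call(rbind, rows))
    else rad21 <- rbind(rad21, do.call(rbind, rows))
  }

  ## --- hypermethylation sites -------------------------------------------
  hs <- list()
  irca_mid <- floor((ircas$start + ircas$end) / 2)
  for (k in seq_len(cfg$n_hsites)) {
    placed <- FALSE
    for (try in 1:300) {
      if (stats::runif(1) < cfg$frac_hsite_noise) {
        ch <- sample(chroms, 1)
        pos <- floor(stats::runif(1, 1000, genome[ch] - 1000))
      } else {
        j <- sample(nrow(ircas), 1)
        ch <- ircas$chrom[j]
        pos <- irca_mid[j] + round(stats::rnorm(1, 0, cfg$hsite_clustering_sd))
        if (pos < 1000 || pos > genome[ch] - 1000) next
      }
      if (!reg_clear(r$hsite, ch, pos, pos + 2, 2500)) next
      hs[[k]] <- feat_df(ch, pos, pos + 2, name = sprintf("hsite%04d", k))
      reg_add(r$hsite, ch, pos, pos + 2)
      placed <- TRUE
      break
    }
    if (!placed) pack_error("hypermethylation site")
  }
  hsites <- do.call(rbind, hs)

  # HH candidates: isolated by > 22 kb from every other H-site so a TR peak
  # within 10 kb of one site can never flank a second one
  iso <- vapply(seq_len(nrow(hsites)), function(i) {
    same <- hsites$chrom == hsites$chrom[i]
    d <- abs(hsites$start[same] - hsites$start[i])
    sum(d > 0 & d <= 22000) == 0
  }, logical(1))
  if (sum(iso) < cfg$n_hh_sites) pack_error("isolated HH-site candidates")
  hh_idx <- sort(sample(which(iso), cfg$n_hh_sites))
  hsites$is_hh <- seq_len(nrow(hsites)) %in% hh_idx

  # knockout-unique H3K9me3 domains covering each HH-site
  k9_unique <- feat_df(hsites$chrom[hh_idx], hsites$start[hh_idx] - 400,
                       hsites$start[hh_idx] + 400,
                       name = sprintf("k9u%03d", seq_along(hh_idx)),
                       score = round(stats::runif(length(hh_idx), 2.5, 30), 3))
  for (k in seq_len(nrow(k9_unique)))
    reg_add(r$k9u, k9_unique$chrom[k], k9_unique$start[k], k9_unique$end[k])

  # shared H3K9me3 domains present in both conditions, clear of H-sites
  k9_shared <- list()
  for (k in seq_len(cfg$n_shared_k9)) {
    ch <- sample(chroms, 1)
    s <- place_in(ch, 1000, genome[ch] - 1000, 800,
                  list(list(reg = r$hsite, margin = 600),
                       list(reg = r$k9u, margin = 500),
                       list(reg = r$k9s, margin = 500)))
    if (is.na(s)) pack_error("shared H3K9me3 domain")
    k9_shared[[k]] <- feat_df(ch, s, s + 800, name = paste0("k9s", k),
                              score = round(stats::runif(1, 0.5, 30), 3))
    reg_add(r$k9s, ch, s, s + 800)
  }
  k9_shared <- do.call(rbind, k9_shared)
  jit <- round(stats::runif(nrow(k9_shared), -150, 150))
  k9_control <- rbind(k9_shared)
  k9_ko <- rbind(k9_unique,
                 transform(k9_shared, start = start + jit, end = end + jit))

  ## --- demethylated control sites ---------------------------------------
  dm_hit <- sort(sample(nrow(hsites), cfg$n_demeth_overlap))
  demeth <- feat_df(hsites$chrom[dm_hit], hsites$start[dm_hit],
                    hsites$end[dm_hit],
                    name = sprintf("dm_ov%03d", seq_along(dm_hit)))
  for (k in seq_len(cfg$n_demeth - cfg$n_demeth_overlap)) {
    ch <- sample(chroms, 1)
    s <- place_in(ch, 1000, genome[ch] - 1000, 2,
                  list(list(reg = r$hsite, margin = 500)))
    if (is.na(s)) pack_error("demethylated site")
    demeth <- rbind(demeth, feat_df(ch, s, s + 2, name = paste0("dm_bg", k)))
  }

  ## --- thyroid-receptor peaks around HH-sites ---------------------------
  hh <- hsites[hh_idx, ]
  extra <- cfg$n_t3tr_events - cfg$n_hh_sites
  ev_per_site <- rep(1L, cfg$n_hh_sites) +
    tabulate(sample(cfg$n_hh_sites, extra, replace = TRUE),
             nbins = cfg$n_hh_sites)
  t3tr <- list()
  for (i in seq_len(cfg$n_hh_sites)) {
    for (j in seq_len(ev_per_site[i])) {
      off <- sample(c(-1, 1), 1) * round(stats::runif(1, 1000, 8300))
      s <- hh$start[i] + off - 150
      if (!reg_clear(r$tr, hh$chrom[i], s, s + 300, 100)) {
        off <- sample(c(-1, 1), 1) * round(stats::runif(1, 1000, 8300))
        s <- hh$start[i] + off - 150
      }
      t3tr[[length(t3tr) + 1]] <-
        feat_df(hh$chrom[i], s, s + 300,
                name = sprintf("t3tr%03d", length(t3tr) + 1L),
                score = round(stats::runif(1, 2.5, 30), 3))
      reg_add(r$tr, hh$chrom[i], s, s + 300)
    }
  }
  t3tr <- do.call(rbind, t3tr)
  utr <- list()
  for (i in seq_len(cfg$n_utr_events)) {
    off <- sample(c(-1, 1), 1) * round(stats::runif(1, 1000, 8300))
    s <- hh$start[i] + off - 150
    utr[[i]] <- feat_df(hh$chrom[i], s, s + 300,
                        name = sprintf("utr%03d", i),
                        score = round(stats::runif(1, 2.5, 30), 3))
  }
  for (k in seq_len(cfg$n_bg_utr)) {
    ch <- sample(chroms, 1)
    s <- place_in(ch, 1000, genome[ch] - 1000, 300,
                  list(list(reg = r$hsite, margin = 12000)))
    if (is.na(s)) pack_error("background uTR peak")
    utr[[length(utr) + 1]] <-
      feat_df(ch, s, s + 300, name = paste0("utr_bg", k),
              score = round(stats::runif(1, 2.5, 30), 3))
  }
  utr <- do.call(rbind, utr)

  ## --- remaining genes and the DE table ---------------------------------
  n_down <- round(cfg$n_genes * cfg$frac_downregulated)
  n_free_down <- n_down - cfg$n_pair_genes
  n_free_other <- cfg$n_genes - length(genes) - n_free_down
  if (n_free_other < cfg$n_up_genes)
    stop("sim_config: n_genes too small for the planted gene roles")
  free_roles <- c(rep("free_down", n_free_down),
                  rep("up", cfg$n_up_genes),
                  rep("null", n_free_other - cfg$n_up_genes))
  for (role in free_roles) {
    gi <- gi + 1L
    glen <- round(stats::runif(1, 5000, 15000))
    avoid <- list(list(reg = r$gene, margin = 2500),
                  list(reg = r$irca, margin = 2500),
                  list(reg = r$ins, margin = 2500),
                  list(reg = r$block, margin = if (role == "free_down") 12000 else 2500))
    if (role == "free_down")
      avoid <- c(avoid, list(list(reg = r$prca, margin = 12000)))
    placed <- FALSE
    for (try in 1:100) {
      ch <- sample(chroms, 1)
      s <- place_in(ch, 5000, genome[ch] - 5000, glen, avoid, max_try = 50L)
      if (!is.na(s)) {
        genes[[length(genes) + 1]] <-
          data.frame(gene_id = sprintf("gene%04d", gi), chrom = ch,
                     strand = sample(c("+", "-"), 1), start = s,
                     end = s + glen, role = role, stringsAsFactors = FALSE)
        reg_add(r$gene, ch, s, s + glen)
        placed <- TRUE
        break
      }
    }
    if (!placed) pack_error("gene body")
  }
  genes <- do.call(rbind, genes); rownames(genes) <- NULL
  # exon blocks: 2-4 exons, first/last pinned to the gene ends
  genes$exons <- vapply(seq_len(nrow(genes)), function(i) {
    glen <- genes$end[i] - genes$start[i]
    k <- sample(2:4, 1)
    grid <- seq(100, glen - 100, by = 50)
    cuts <- sort(sample(grid, 2 * (k - 1)))
    bounds <- c(0, cuts, glen) + genes$start[i]
    paste(vapply(seq_len(k), function(j)
      paste0(format_bp(bounds[2 * j - 1]), "-", format_bp(bounds[2 * j])), ""),
      collapse = ";")
  }, "")

  down_ids <- genes$gene_id[genes$role %in% c("pair_down", "free_down")]
  up_ids <- genes$gene_id[genes$role == "up"]
  de <- data.frame(gene_id = genes$gene_id)
  fc <- numeric(nrow(de)); pv <- numeric(nrow(de))
  for (i in seq_len(nrow(de))) {
    role <- genes$role[i]
    if (role %in% c("pair_down", "free_down")) {
      fc[i] <- -stats::runif(1, 1.3, 5); pv[i] <- stats::runif(1, 1e-6, 0.045)
    } else if (role == "up") {
      fc[i] <- stats::runif(1, 1.3, 4); pv[i] <- stats::runif(1, 1e-6, 0.045)
    } else if (stats::runif(1) < 0.5) {  # null: small fold change
      fc[i] <- sample(c(-1, 1), 1) * stats::runif(1, 1.01, 1.19)
      pv[i] <- stats::runif(1, 0.001, 0.99)
    } else {                             # null: large fold, non-significant
      fc[i] <- sample(c(-1, 1), 1) * stats::runif(1, 1.3, 3)
      pv[i] <- stats::runif(1, 0.06, 0.99)
    }
  }
  de$fold_change <- round(fc, 4); de$p_value <- signif(pv, 4)

  ## --- ATAC peak sets ----------------------------------------------------
  rca_all <- rbind(
    data.frame(chrom = prcas$chrom, start = prcas$start, end = prcas$end,
               name = prcas$name),
    data.frame(chrom = ircas$chrom, start = ircas$start, end = ircas$end,
               name = ircas$name),
    data.frame(chrom = ins$chrom, start = ins$start, end = ins$end,
               name = ins$name))
  shared_atac <- list()
  for (k in seq_len(cfg$n_shared_atac)) {
    ch <- sample(chroms, 1)
    w <- round(stats::runif(1, 300, 800))
    s <- place_in(ch, 1000, genome[ch] - 1000, w,
                  list(list(reg = r$prca, margin = 1000),
                       list(reg = r$irca, margin = 1000),
                       list(reg = r$ins, margin = 1000),
                       list(reg = r$shared, margin = 400)))
    if (is.na(s)) pack_error("shared ATAC peak")
    shared_atac[[k]] <- feat_df(ch, s, s + w, name = paste0("shared", k),
                                score = round(stats::runif(1, 2.5, 30), 3))
    reg_add(r$shared, ch, s, s + w)
  }
  shared_atac <- do.call(rbind, shared_atac)
  atac_control <- rbind(
    feat_df(rca_all$chrom, rca_all$start, rca_all$end, name = rca_all$name,
            score = round(stats::runif(nrow(rca_all), 2.5, 30), 3)),
    shared_atac)
  jit2 <- round(stats::runif(nrow(shared_atac), -150, 150))
  atac_ko <- transform(shared_atac, start = start + jit2, end = end + jit2)
  for (k in seq_len(cfg$n_ko_only_atac)) {
    ch <- sample(chroms, 1)
    w <- round(stats::runif(1, 300, 800))
    s <- place_in(ch, 1000, genome[ch] - 1000, w,
                  list(list(reg = r$prca, margin = 1000),
                       list(reg = r$irca, margin = 1000),
                       list(reg = r$ins, margin = 1000),
                       list(reg = r$shared, margin = 500)))
    if (is.na(s)) pack_error("knockout-only ATAC peak")
    atac_ko <- rbind(atac_ko, feat_df(ch, s, s + w, name = paste0("ko", k),
                                      score = round(stats::runif(1, 2.5, 30), 3)))
  }

  ## --- per-region signal table -------------------------------------------
  n_p <- nrow(prcas); n_i <- nrow(ircas)
  n_weak_prom <- min(20L, n_p)
  rca_class <- c(rep("promoter", n_p - n_weak_prom),
                 rep("weak_promoter", n_weak_prom),
                 rep("enhancer", n_i), ins$class)
  cnt <- function(cls) {
    switch(cls,
      promoter = c(atac = stats::rpois(1, 200) + 20,
                   k4me1 = stats::rpois(1, 100) + 20,
                   k4me3 = stats::rpois(1, 400) + 80),
      weak_promoter = c(atac = stats::rpois(1, 200) + 20,
                        k4me1 = 150 + sample(-5:5, 1),
                        k4me3 = 150 + sample(-5:5, 1)),
      enhancer = c(atac = stats::rpois(1, 200) + 20,
                   k4me1 = stats::rpois(1, 400) + 80,
                   k4me3 = stats::rpois(1, 100) + 20),
      insulator = c(atac = stats::rpois(1, 50) + 10, k4me1 = 0, k4me3 = 0),
      weak_insulator = c(atac = 0, k4me1 = 0, k4me3 = 0))
  }
  counts <- t(vapply(rca_class, cnt, c(atac = 0, k4me1 = 0, k4me3 = 0)))
  signal <- data.frame(region_id = rca_all$name, chrom = rca_all$chrom,
                       start = rca_all$start, end = rca_all$end,
                       length = rca_all$end - rca_all$start,
                       count_atac = counts[, "atac"],
                       count_k4me1 = counts[, "k4me1"],
                       count_k4me3 = counts[, "k4me3"])
  # planted classes must reproduce through the classifier; fail loudly if
  # the count templates ever drift out of their guaranteed margins
  got <- classify_rca(compute_tpm(signal, "k4me3"),
                      compute_tpm(signal, "k4me1"),
                      compute_tpm(signal, "atac"))
  stopifnot(identical(as.character(got), rca_class))

  ## --- noise contacts -----------------------------------------------------
  contacts <- do.call(rbind, contacts)
  n_noise <- cfg$n_contacts - nrow(contacts)
  n_inter <- min(10L, n_noise); n_short <- min(5L, n_noise - n_inter)
  noise <- list()
  noise_anchor <- function() {
    for (try in 1:200) {
      ch <- sample(chroms, 1)
      s <- floor(stats::runif(1, 1000, genome[ch] - 2000))
      if (clear_all(list(list(reg = r$prca, margin = 2500),
                         list(reg = r$block, margin = 2500)),
                    ch, s, s + 1000))
        return(list(chrom = ch, start = s, end = s + 1000))
    }
    pack_error("noise contact anchor")
  }
  for (k in seq_len(n_noise)) {
    a1 <- noise_anchor()
    kind <- if (k <= n_inter) "inter" else if (k <= n_inter + n_short)
      "short" else "intra"
    if (kind == "inter") {
      a2 <- noise_anchor()
      while (a2$chrom == a1$chrom) a2 <- noise_anchor()
    } else {
      sep <- if (kind == "short") round(stats::runif(1, 100, 900))
             else {
               s0 <- 0
               while (s0 < 1000 || s0 > 2.4e6)
                 s0 <- round(stats::rlnorm(1, cfg$contact_sep_meanlog,
                                           cfg$contact_sep_sdlog))
               s0
             }
      mid1 <- a1$start + 500
      dir <- if (mid1 + sep + 2000 < genome[a1$chrom]) 1 else -1
      placed <- FALSE
      for (try in 1:200) {
        mid2 <- mid1 + dir * sep
        if (mid2 > 1500 && mid2 < genome[a1$chrom] - 1500 &&
            clear_all(list(list(reg = r$prca, margin = 2500),
                           list(reg = r$block, margin = 2500)),
                      a1$chrom, mid2 - 500, mid2 + 500)) {
          placed <- TRUE
          break
        }
        a1 <- noise_anchor(); mid1 <- a1$start + 500
        dir <- if (mid1 + sep + 2000 < genome[a1$chrom]) 1 else -1
      }
      if (!placed) pack_error("noise contact")
      a2 <- list(chrom = a1$chrom, start = mid2 - 500, end = mid2 + 500)
    }
    noise[[k]] <- data.frame(chrom1 = a1$chrom, start1 = a1$start,
                             end1 = a1$end, chrom2 = a2$chrom,
                             start2 = a2$start, end2 = a2$end,
                             name = sprintf("noise%04d", k),
                             score = round(stats::runif(1, 10, 100), 2),
                             planted = FALSE, prca = NA_character_,
                             gene_id = NA_character_, irca = NA_character_)
  }
  contacts <- rbind(contacts, do.call(rbind, noise))
  rownames(contacts) <- NULL

  ## --- write the bundle ---------------------------------------------------
  p <- function(f) file.path(out_dir, f)
  paths <- c(genome = p("genome.tsv"), tads = p("tads.bed"),
             atac_control = p("atac_control.bed"), atac_ko = p("atac_ko.bed"),
             k9_control = p("k9_control.bed"), k9_ko = p("k9_ko.bed"),
             hsites = p("hsites.bed"), demethylated = p("demethylated.bed"),
             t3tr = p("t3tr.bed"), utr = p("utr.bed"),
             ctcf = p("ctcf.bed"), rad21 = p("rad21.bed"),
             genes = p("genes.tsv"), de = p("de.tsv"),
             signal = p("signal.tsv"), contacts = p("contacts.bedpe"),
             manifest = p("manifest.yaml"))
  write_genome(genome, paths["genome"])
  write_bed_df(feat_df(tads$chrom, tads$start, tads$end, name = tads$name),
               paths["tads"], genome, columns = 3L)
  write_bed_df(atac_control, paths["atac_control"], genome)
  write_bed_df(atac_ko, paths["atac_ko"], genome)
  write_bed_df(k9_control, paths["k9_control"], genome)
  write_bed_df(k9_ko, paths["k9_ko"], genome)
  write_bed_df(feat_df(hsites$chrom, hsites$start, hsites$end,
                       name = hsites$name), paths["hsites"], genome)
  write_bed_df(demeth, paths["demethylated"], genome)
  write_bed_df(t3tr, paths["t3tr"], genome)
  write_bed_df(utr, paths["utr"], genome)
  write_bed_df(ctcf, paths["ctcf"], genome)
  write_bed_df(rad21, paths["rad21"], genome)
  gene_out <- genes[order(genes$gene_id),
                    c("gene_id", "chrom", "strand", "start", "end", "exons")]
  utils::write.table(
    transform(gene_out, start = format_bp(start), end = format_bp(end)),
    paths["genes"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(de[order(de$gene_id), ], paths["de"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    transform(signal, start = format_bp(start), end = format_bp(end)),
    paths["signal"], sep = "\t", quote = FALSE, row.names = FALSE)
  bedpe <- contacts[c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                      "name", "score")]
  writeLines(do.call(paste, c(lapply(bedpe, function(x)
    if (is.numeric(x)) format_bp(x) else x), sep = "\t")),
    paths["contacts"])

  planted <- contacts[contacts$planted, ]
  manifest <- list(
    config = lapply(unclass(cfg), function(x) unname(x)),
    n_tads = n_tads,
    tad_flags = list(n_prca_flagged = sum(tads$has_prca),
                     n_irca_flagged = sum(tads$has_irca),
                     n_both_flagged = sum(tads$has_prca & tads$has_irca)),
    pairs = list(n_pairs = cfg$n_pair_prcas, n_genes = cfg$n_pair_genes,
                 prca_ids = prcas$name[prcas$planted_pair],
                 gene_ids = unique(prcas$gene_id[prcas$planted_pair])),
    down_gene_ids = down_ids, up_gene_ids = up_ids,
    hh_site_ids = hsites$name[hsites$is_hh],
    demethylated_overlap_ids = hsites$name[dm_hit],
    rca_classes = stats::setNames(as.list(rca_class), rca_all$name),
    insulator_types = stats::setNames(as.list(ins$cohesin_type), ins$name),
    contact_triples = lapply(seq_len(nrow(planted)), function(i)
      list(contact = planted$name[i], prca = planted$prca[i],
           gene = planted$gene_id[i], irca = planted$irca[i])),
    mean_planted_separation_bp =
      mean(abs(floor((planted$start2 + planted$end2) / 2) -
               floor((planted$start1 + planted$end1) / 2))),
    t3tr_flank_events = cfg$n_t3tr_events,
    utr_flank_events = cfg$n_utr_events)
  yaml::write_yaml(manifest, paths["manifest"])
  invisible(list(paths = paths, manifest = manifest, genome = genome))
}

#' Null calibration of the TAD co-occurrence test
#'
#' Draws per-TAD (has-A, has-B) indicators from the independent 2x2 joint
#' (odds ratio 1 is required), builds the contingency table those flags
#' induce — the generator guarantees a flagged TAD contains at least one
#' feature and an unflagged one none, so the table is identical to what
#' interval scanning would produce — and applies [chi_square_2x2()].
#'
#' @param cfg A [sim_config()] with `cooccurrence_odds_ratio = 1`.
#' @param n_reps Number of replicates.
#' @param alpha Nominal test level (default 0.05).
#' @return List: `replicates` data.frame (chi2, p), `rejection_rate`
#'   (NA when `n_reps < 2`), `se` (binomial standard error).
#' @export
null_resample <- function(cfg, n_reps, alpha = 0.05) {
  stopifnot(inherits(cfg, "sim_config"))
  if (abs(cfg$cooccurrence_odds_ratio - 1) > 1e-12)
    stop("null_resample: cooccurrence_odds_ratio must be 1")
  set.seed(cfg$seed, kind = "Mersenne-Twister")
  n_tads <- round(cfg$n_chroms * cfg$chrom_length / cfg$mean_tad_size)
  p11 <- cfg$p_tad_prca * cfg$p_tad_irca
  probs <- c(p11, cfg$p_tad_prca - p11, cfg$p_tad_irca - p11,
             1 - cfg$p_tad_prca - cfg$p_tad_irca + p11)
  draws <- stats::rmultinom(n_reps, n_tads, probs)
  res <- apply(draws, 2, function(cells) {
    out <- tryCatch(
      chi_square_2x2(cooccurrence_table(cells[1], cells[2],
                                        cells[3], cells[4])),
      error = function(e) list(chi2 = NA_real_, p = NA_real_))
    c(chi2 = out$chi2, p = out$p)
  })
  reps <- data.frame(chi2 = res["chi2", ], p = res["p", ])
  rate <- if (n_reps >= 2) mean(reps$p < alpha, na.rm = TRUE) else NA_real_
  list(replicates = reps, rejection_rate = rate,
       se = if (n_reps >= 2) sqrt(alpha * (1 - alpha) / n_reps) else NA_real_)
}
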