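test_that("identical seeds reproduce the bundle byte-for-byte", {
  d1 <- file.path(tempdir(), "sim-det-1")
  d2 <- file.path(tempdir(), "sim-det-2")
  r1 <- simulate_chromatin(sim_config(seed = 7), d1)
  r2 <- simulate_chromatin(sim_config(seed = 7), d2)
  sums1 <- tools::md5sum(unname(r1$paths))
  sums2 <- tools::md5sum(unname(r2$paths))
  expect_equal(unname(sums1), unname(sums2))
  # a different seed changes the data
  r3 <- simulate_chromatin(sim_config(seed = 8),
                           file.path(tempdir(), "sim-det-3"))
  expect_false(all(unname(tools::md5sum(unname(r3$paths))) == unname(sums1)))
})

test_that("every generated file parses through the pipeline's own readers", {
  sim <- sim_fixture()
  genome <- read_genome(sim$paths[["genome"]])
  for (nm in c("tads", "atac_control", "atac_ko", "k9_control", "k9_ko",
               "hsites", "demethylated", "t3tr", "utr", "ctcf", "rad21"))
    expect_s4_class(read_bed(sim$paths[[nm]], genome, strict = TRUE),
                    "GRanges")
  expect_s3_class(read_gene_models(sim$paths[["genes"]], genome),
                  "gene_models")
  expect_true(nrow(read_de_table(sim$paths[["de"]])) ==
                sim$manifest$config$n_genes)
  expect_true(nrow(read_signal_table(sim$paths[["signal"]])) > 0)
  expect_s3_class(read_bedpe(sim$paths[["contacts"]], genome, strict = TRUE),
                  "contact_pairs")
})

test_that("planted embedded HH-sites are recovered exactly", {
  sim <- sim_fixture()
  genome <- read_genome(sim$paths[["genome"]])
  hs <- read_bed(sim$paths[["hsites"]], genome)
  k9_ko <- filter_by_score(read_bed(sim$paths[["k9_ko"]], genome), 2)
  k9_ctrl <- filter_by_score(read_bed(sim$paths[["k9_control"]], genome), 2)
  unique_ko <- subtract_condition(k9_ko, k9_ctrl)
  hh <- window_intersect(hs, unique_ko, window_bp = 0)
  expect_setequal(S4Vectors::mcols(hh)$name, sim$manifest$hh_site_ids)
})

test_that("planted demethylation overlap and TR flanking counts hold", {
  sim <- sim_fixture()
  genome <- read_genome(sim$paths[["genome"]])
  hs <- read_bed(sim$paths[["hsites"]], genome)
  demeth <- read_bed(sim$paths[["demethylated"]], genome)
  ov <- window_intersect(hs, demeth, window_bp = 0)
  expect_setequal(S4Vectors::mcols(ov)$name,
                  sim$manifest$demethylated_overlap_ids)
  hh <- hs[S4Vectors::mcols(hs)$name %in% sim$manifest$hh_site_ids]
  t3 <- read_bed(sim$paths[["t3tr"]], genome)
  u <- read_bed(sim$paths[["utr"]], genome)
  expect_equal(count_flanking(hh, t3, 10000)$n_flanking_peaks,
               sim$manifest$t3tr_flank_events)
  expect_equal(count_flanking(hh, u, 10000)$n_flanking_peaks,
               sim$manifest$utr_flank_events)
})

test_that("an overfilled genome raises a packing error with a sizing hint", {
  cfg <- sim_config(seed = 3, n_chroms = 2L, chrom_length = 2e6,
                    mean_tad_size = 5e5)
  expect_error(simulate_chromatin(cfg, file.path(tempdir(), "sim-tiny")),
               "increase chrom_length")
})

test_that("null_resample structure and odds-ratio guard", {
  cfg1 <- sim_config(seed = 4, cooccurrence_odds_ratio = 1)
  one <- null_resample(cfg1, n_reps = 1)
  expect_equal(nrow(one$replicates), 1)
  expect_true(is.na(one$rejection_rate))
  expect_error(null_resample(sim_config(seed = 4), 10), "must be 1")
})

test_that("independent flags land within the binomial band, planted OR above it", {
  # with odds ratio 1 the both-flag count matches independence expectation
  cfg <- sim_config(seed = 9, cooccurrence_odds_ratio = 1,
                    p_tad_prca = 0.4, p_tad_irca = 0.4)
  sim <- simulate_chromatin(cfg, file.path(tempdir(), "sim-null-flags"))
  n <- sim$manifest$n_tads
  p0 <- 0.16
  expect_lt(abs(sim$manifest$tad_flags$n_both_flagged - n * p0),
            4 * sqrt(n * p0 * (1 - p0)))
  # the default planted odds ratio pushes the count far above independence
  def <- sim_fixture()
  p_ind <- def$manifest$config$p_tad_prca * def$manifest$config$p_tad_irca
  n2 <- def$manifest$n_tads
  expect_gt(def$manifest$tad_flags$n_both_flagged,
            n2 * p_ind + 4 * sqrt(n2 * p_ind * (1 - p_ind)))
})
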