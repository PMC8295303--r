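test_that("chromosome_density is features per Mbp over all chromosomes", {
  g <- c(chr1 = 1e7, chr2 = 2e7)
  f <- read_bed(withr::local_tempfile(lines = c(
    paste0("chr1\t", (0:9) * 1000, "\t", (0:9) * 1000 + 100))), g)
  d <- chromosome_density(f, g)
  expect_equal(unname(d), c(1.0, 0))
  expect_equal(unname(chromosome_density(f[0], g)), c(0, 0))
})

test_that("density_correlation is a rank correlation with exact small-n p", {
  a <- c(chr1 = 1, chr2 = 3, chr3 = 2, chr4 = 7, chr5 = 5)
  # monotone transform preserves r = 1
  expect_equal(density_correlation(a, exp(a))$r, 1)
  expect_equal(density_correlation(a, -a)$r, -1)
  expect_error(density_correlation(a, a * 0 + 2), "zero-variance")
  expect_error(density_correlation(a[1:3], a[1:3] * 2), ">= 4")

  set.seed(51)
  for (rep in 1:5) {
    x <- stats::setNames(sample(100, 8), paste0("chr", 1:8))
    y <- stats::setNames(sample(100, 8), paste0("chr", 1:8))
    dc <- density_correlation(x, y)
    expect_equal(dc$p, bf_spearman_exact(x, y), tolerance = 1e-12)
  }
})

test_that("p-RCA pairing respects the closed 5 kb bound", {
  g <- tiny_genome(1, 1e6)
  genes <- gene_models(data.frame(
    gene_id = c("g1", "g2"), chrom = "chr1", strand = "+",
    start = c(100000, 400000), end = c(110000, 410000),
    exons = c("100000-110000", "400000-410000")), g)
  n_rna <- n_rna_regions(c("g1", "g2"), genes)
  # 2 kb from g1; 5,001 bp from g2 (excluded)
  prcas <- read_bed(withr::local_tempfile(lines = c(
    "chr1\t97500\t98000\tp1", "chr1\t394499\t394999\tp2")), g)
  pr <- pair_prca_with_downregulated(prcas, n_rna, 5000)
  expect_equal(pr$n_pairs, 1)
  expect_equal(pr$pairs$gene_id, "g1")
  expect_equal(pr$pairs$distance, 2000)
  # exactly 5,000 bp qualifies
  edge <- read_bed(withr::local_tempfile(lines = "chr1\t394500\t395000\tp3"), g)
  expect_equal(pair_prca_with_downregulated(edge, n_rna, 5000)$n_pairs, 1)
})

test_that("tad_cooccurrence classifies TADs by any-overlap membership", {
  g <- tiny_genome(1, 1e6)
  tads <- read_bed(withr::local_tempfile(lines = c(
    "chr1\t0\t100000", "chr1\t100000\t200000",
    "chr1\t200000\t300000", "chr1\t300000\t400000")), g)
  setA <- read_bed(withr::local_tempfile(lines = c(
    "chr1\t10000\t10500", "chr1\t110000\t110500")), g)
  setB <- read_bed(withr::local_tempfile(lines = c(
    "chr1\t20000\t20500", "chr1\t210000\t210500")), g)
  tab <- tad_cooccurrence(tads, setA, setB)
  expect_equal(c(tab$n_both, tab$n_A_only, tab$n_B_only, tab$n_neither),
               c(1, 1, 1, 1))
  empty <- tad_cooccurrence(tads, setA, setB[0])
  expect_equal(empty$n_both, 0)
  expect_equal(empty$n_B_only, 0)
  expect_equal(tab$N, length(tads))
})

test_that("tad_cooccurrence matches a per-TAD oracle scan", {
  set.seed(61)
  g <- tiny_genome(2, 1e6)
  tads <- read_bed(withr::local_tempfile(lines = unlist(lapply(1:2, function(c)
    paste0("chr", c, "\t", seq(0, 9.5e5, 5e4), "\t",
           seq(5e4, 1e6, 5e4))))), g)
  for (rep in 1:3) {
    A <- rand_gr(60, g, max_width = 2000); B <- rand_gr(40, g, max_width = 2000)
    tab <- tad_cooccurrence(tads, A, B)
    want <- bf_tad_table(tads, A, B)
    expect_equal(c(tab$n_both, tab$n_A_only, tab$n_B_only, tab$n_neither),
                 unname(want))
  }
})

test_that("chi_square_2x2 equals the Sigma (O-E)^2/E form and handles edges", {
  # independence gives exactly zero
  ind <- cooccurrence_table(10, 10, 10, 10)
  expect_equal(chi_square_2x2(ind)$chi2, 0)
  set.seed(71)
  for (rep in 1:20) {
    cells <- rmultinom(1, 500, c(0.1, 0.2, 0.3, 0.4))[, 1]
    tab <- cooccurrence_table(cells[1], cells[2], cells[3], cells[4])
    res <- chi_square_2x2(tab)
    expect_equal(res$chi2, bf_chi2_oe(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
    expect_gte(res$chi2, 0)
    # cross-check against the standard implementation, uncorrected
    expect_equal(res$chi2, unname(suppressWarnings(stats::chisq.test(
      matrix(cells, 2, byrow = TRUE), correct = FALSE))$statistic))
  }
  expect_error(chi_square_2x2(cooccurrence_table(0, 0, 5, 5)), "degenerate")
  expect_warning(res <- chi_square_2x2(cooccurrence_table(5, 0, 5, 5)), "Inf")
  expect_equal(res$odds_ratio, Inf)
})

test_that("the null chi-squared rejects at its nominal level", {
  cfg <- sim_config(seed = 5, cooccurrence_odds_ratio = 1,
                    p_tad_prca = 0.3, p_tad_irca = 0.3)
  nr <- null_resample(cfg, n_reps = 500)
  expect_lt(abs(nr$rejection_rate - 0.05), 4 * sqrt(0.05 * 0.95 / 500))
})

test_that("the planted odds ratio shifts the TAD table as prescribed", {
  # OR > 1 concentrates both-flags well above the independence expectation
  cfg <- sim_config(seed = 6)
  set.seed(6)
  p11 <- cooccurrence_joint(cfg$p_tad_prca, cfg$p_tad_irca,
                            cfg$cooccurrence_odds_ratio)
  expect_gt(p11, cfg$p_tad_prca * cfg$p_tad_irca)
  # the quadratic root reproduces the requested odds ratio
  or <- p11 * (1 - cfg$p_tad_prca - cfg$p_tad_irca + p11) /
    ((cfg$p_tad_prca - p11) * (cfg$p_tad_irca - p11))
  expect_equal(or, cfg$cooccurrence_odds_ratio, tolerance = 1e-9)
  expect_equal(cooccurrence_joint(0.2, 0.3, 1), 0.06)
})
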