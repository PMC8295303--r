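`%||%` <- function(a, b) if (is.null(a)) b else a

mk_signal <- function(counts_k4me3, counts_k4me1 = NULL, counts_atac = NULL,
                      length_bp = 1000) {
  n <- length(counts_k4me3)
  data.frame(region_id = sprintf("r%03d", seq_len(n)),
             chrom = "chr1", start = seq_len(n) * 10000,
             end = seq_len(n) * 10000 + length_bp,
             length = rep(length_bp, n),
             count_atac = counts_atac %||% rep(1, n),
             count_k4me1 = counts_k4me1 %||% rep(1, n),
             count_k4me3 = counts_k4me3)
}

test_that("compute_tpm matches the closed form and conserves 1e6", {
  # two regions, equal count and length -> half a million each
  tab <- mk_signal(c(10, 10))
  expect_equal(unname(compute_tpm(tab, "k4me3")), c(5e5, 5e5))
  # single region takes the whole million
  expect_equal(unname(compute_tpm(mk_signal(7), "k4me3")), 1e6)
  # normalization undefined on an all-zero track
  expect_error(compute_tpm(mk_signal(c(0, 0)), "k4me3"), "all counts are zero")

  set.seed(11)
  for (rep in 1:5) {
    n <- 50
    tab <- data.frame(region_id = sprintf("r%03d", 1:n), chrom = "chr1",
                      start = 1:n * 1000, end = 1:n * 1000 + 500,
                      length = sample(200:2000, n, replace = TRUE),
                      count_atac = rpois(n, 50),
                      count_k4me1 = rpois(n, 50),
                      count_k4me3 = rpois(n, 50) + 1)
    tpm <- compute_tpm(tab, "k4me3")
    expect_equal(sum(tpm), 1e6, tolerance = 1e-6)
    rate <- tab$count_k4me3 / (tab$length / 1000)
    expect_equal(unname(tpm), rate / sum(rate) * 1e6)
  }
})

test_that("classify_rca applies the published rules", {
  # ratio 3 with gate passed -> promoter
  expect_equal(as.character(classify_rca(6, 2, 1)), "promoter")
  # ratio 1/3 with gate passed -> enhancer
  expect_equal(as.character(classify_rca(2, 6, 1)), "enhancer")
  # gate failed, ATAC > H3K4me1 -> insulator
  expect_equal(as.character(classify_rca(2, 1, 3)), "insulator")
  # gate failed, ATAC <= H3K4me1 -> weak insulator
  expect_equal(as.character(classify_rca(2, 3, 1)), "weak_insulator")
})

test_that("classification boundaries follow the literal inequalities", {
  # TPM exactly 4 on both tracks: gate fails (strict >)
  expect_equal(as.character(classify_rca(4, 4, 10)), "insulator")
  expect_equal(as.character(classify_rca(4, 4, 2)), "weak_insulator")
  # ratio exactly 1.5 and 0.67: intermediate branch
  expect_equal(as.character(classify_rca(7.5, 5, 1)), "weak_promoter")
  expect_equal(as.character(classify_rca(0.67 * 8, 8, 1)), "weak_promoter")
  # ATAC exactly equal to H3K4me1 under the gate: weak insulator
  expect_equal(as.character(classify_rca(1, 2, 2)), "weak_insulator")
  # zero H3K4me1 inside the gate: infinite ratio, logged promoter
  expect_warning(lab <- classify_rca(5, 0, 1), "zero H3K4me1")
  expect_equal(as.character(lab), "promoter")
})

test_that("classification is total and order-invariant", {
  set.seed(21)
  n <- 400
  t3 <- runif(n, 0, 12); t1 <- runif(n, 0, 12); at <- runif(n, 0, 12)
  lab <- classify_rca(t3, t1, at)
  expect_false(anyNA(lab))
  expect_equal(sum(table(lab)), n)
  perm <- sample(n)
  expect_equal(as.character(classify_rca(t3[perm], t1[perm], at[perm])),
               as.character(lab)[perm])
})

test_that("CAC/CNC typing follows cohesin/CTCF overlap rules", {
  g <- tiny_genome(1)
  ins <- read_bed(withr::local_tempfile(lines = c(
    "chr1\t1000\t1500", "chr1\t5000\t5500", "chr1\t9000\t9500")), g)
  ctcf <- read_bed(withr::local_tempfile(lines = "chr1\t1200\t1300"), g)
  rad21 <- read_bed(withr::local_tempfile(
    lines = c("chr1\t1100\t1250", "chr1\t5100\t5200")), g)
  expect_equal(as.character(classify_insulator_cohesin(ins, ctcf, rad21)),
               c("CAC", "CNC", "neither"))
})

test_that("planted chromatin classes and cohesin types are recovered", {
  sim <- sim_fixture()
  sig <- read_signal_table(sim$paths[["signal"]])
  lab <- classify_rca(compute_tpm(sig, "k4me3"), compute_tpm(sig, "k4me1"),
                      compute_tpm(sig, "atac"))
  want <- unlist(sim$manifest$rca_classes[sig$region_id])
  expect_equal(as.character(lab), unname(want))
})
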