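test_that("read_bed parses BED3/BED6 with half-open coordinates", {
  g <- c(chr1 = 1000)
  f <- withr::local_tempfile(lines = "chr1\t100\t200")
  gr <- read_bed(f, g)
  expect_length(gr, 1)
  expect_equal(GenomicRanges::start(gr), 101)  # 1-based in memory
  expect_equal(GenomicRanges::end(gr), 200)

  f6 <- withr::local_tempfile(lines = "chr1\t100\t200\tpeak1\t3.2\t+")
  gr6 <- read_bed(f6, g)
  expect_equal(S4Vectors::mcols(gr6)$score, 3.2)
  expect_equal(S4Vectors::mcols(gr6)$name, "peak1")
  expect_equal(as.character(GenomicRanges::strand(gr6)), "+")
})

test_that("read_bed rejects malformed records with line numbers", {
  g <- c(chr1 = 1000)
  f <- withr::local_tempfile(lines = c("chr1\t100\t200", "chr1\t200\t100"))
  expect_error(read_bed(f, g), "line 2.*start < end|line 2")
  f2 <- withr::local_tempfile(lines = "chr1\t100\t2000")
  expect_error(read_bed(f2, g), "exceeds length")
  f3 <- withr::local_tempfile(lines = c("chr1\t1\t5", "chr9\t1\t5"))
  expect_warning(gr <- read_bed(f3, g), "skipped 1")
  expect_length(gr, 1)
  expect_error(read_bed(f3, g, strict = TRUE), "unknown chromosome")
})

test_that("write_bed round-trips canonical BED6 byte-identically", {
  g <- c(chr1 = 10000, chr2 = 10000)
  lines <- c("chr1\t100\t200\ta\t1.5\t+",
             "chr1\t500\t900\tb\t2\t-",
             "chr2\t0\t50\tc\t0\t.")
  f <- withr::local_tempfile(lines = lines)
  out <- withr::local_tempfile()
  write_bed(read_bed(f, g), out)
  expect_identical(readLines(out), lines)
})

test_that("half-open semantics: touching intervals never overlap", {
  g <- tiny_genome(1)
  a <- read_bed(withr::local_tempfile(lines = "chr1\t100\t200"), g)
  b <- read_bed(withr::local_tempfile(lines = "chr1\t200\t300"), g)
  expect_equal(nrow(overlap_pairs(a, b)), 0)
  # but they are at edge distance 0
  expect_equal(nearest_distance(a, b)$distance, 0)
})

test_that("overlap_pairs matches worked examples", {
  g <- tiny_genome(1)
  a <- read_bed(withr::local_tempfile(lines = "chr1\t100\t200"), g)
  b <- read_bed(withr::local_tempfile(lines = "chr1\t150\t250"), g)
  pr <- overlap_pairs(a, b)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$overlap_bp, 50)
})

test_that("subtract_condition keeps whole control peaks lacking case overlap", {
  g <- tiny_genome(1)
  ctrl <- read_bed(withr::local_tempfile(
    lines = c("chr1\t0\t100\tp1", "chr1\t500\t600\tp2")), g)
  case <- read_bed(withr::local_tempfile(lines = "chr1\t50\t80"), g)
  out <- subtract_condition(ctrl, case)
  expect_length(out, 1)
  expect_equal(S4Vectors::mcols(out)$name, "p2")
  # identity when the case set is empty
  expect_length(subtract_condition(ctrl, case[0]), 2)
})

test_that("nearest_distance computes gaps and flags no-neighbor queries", {
  g <- tiny_genome(2)
  q <- read_bed(withr::local_tempfile(
    lines = c("chr1\t100\t200", "chr2\t100\t200")), g)
  s <- read_bed(withr::local_tempfile(lines = "chr1\t300\t400"), g)
  nd <- nearest_distance(q, s)
  expect_equal(nd$distance, c(100, NA))
  expect_equal(nd$subject, c(1, NA))
})

test_that("window_intersect: window 0 means embedded, window > 0 widens", {
  g <- tiny_genome(1)
  region <- read_bed(withr::local_tempfile(lines = "chr1\t100\t200"), g)
  inside <- read_bed(withr::local_tempfile(lines = "chr1\t150\t152"), g)
  left10 <- read_bed(withr::local_tempfile(lines = "chr1\t88\t90"), g)
  expect_length(window_intersect(inside, region, 0), 1)
  expect_length(window_intersect(left10, region, 0), 0)
  expect_length(window_intersect(left10, region, 50), 1)
})

test_that("filter_by_score is strictly greater-than and demands scores", {
  g <- tiny_genome(1)
  f <- withr::local_tempfile(lines = c("chr1\t0\t10\ta\t1.9\t.",
                                       "chr1\t20\t30\tb\t2\t.",
                                       "chr1\t40\t50\tc\t2.1\t."))
  peaks <- read_bed(f, g)
  kept <- filter_by_score(peaks, 2)
  expect_equal(S4Vectors::mcols(kept)$name, "c")
  expect_length(filter_by_score(peaks, 0), 3)
  noscore <- read_bed(withr::local_tempfile(lines = "chr1\t0\t10"), g)
  expect_error(filter_by_score(noscore, 2), "missing score")
})

test_that("count_flanking counts occasions, not unique peaks", {
  g <- tiny_genome(1)
  site <- read_bed(withr::local_tempfile(lines = "chr1\t50000\t50002"), g)
  peaks <- read_bed(withr::local_tempfile(
    lines = c("chr1\t53000\t53300", "chr1\t58000\t58300")), g)
  expect_equal(count_flanking(site, peaks, 10000),
               list(n_flanked_sites = 1L, n_flanking_peaks = 2L))
  far <- read_bed(withr::local_tempfile(lines = "chr1\t90000\t90300"), g)
  expect_equal(count_flanking(site, far, 10000),
               list(n_flanked_sites = 0L, n_flanking_peaks = 0L))
  # one peak near two sites contributes two events
  sites2 <- read_bed(withr::local_tempfile(
    lines = c("chr1\t50000\t50002", "chr1\t56000\t56002")), g)
  one <- read_bed(withr::local_tempfile(lines = "chr1\t53000\t53300"), g)
  expect_equal(count_flanking(sites2, one, 10000)$n_flanking_peaks, 2L)
})

test_that("interval operations agree with brute-force oracles", {
  set.seed(7)
  g <- tiny_genome(3, 2e5)
  for (rep in 1:10) {
    a <- rand_gr(120, g); b <- rand_gr(150, g)
    pr <- overlap_pairs(a, b)
    bf <- bf_overlap_pairs(a, b)
    o1 <- pr[order(pr$query, pr$subject), ]
    o2 <- bf[order(bf$query, bf$subject), ]
    expect_equal(unname(as.matrix(o1)), unname(as.matrix(o2)))

    keep <- subtract_condition(a, b)
    expect_equal(gr_fields(keep), gr_fields(a[bf_subtract_idx(a, b)]))

    nd <- nearest_distance(a, b)
    expect_equal(nd$distance, bf_nearest(a, b)[, 2])

    w <- sample(c(0, 100, 5000), 1)
    expect_equal(gr_fields(window_intersect(a, b, w)),
                 gr_fields(a[sort(bf_window_idx(a, b, w))]))

    expect_equal(count_flanking(a, b, 2000), bf_flank(a, b, 2000))
  }
})
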