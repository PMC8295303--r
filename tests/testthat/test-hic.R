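mk_contacts <- function(lines, genome = tiny_genome(2, 2e7)) {
  read_bedpe(withr::local_tempfile(lines = lines), genome)
}

test_that("read_bedpe canonicalizes orientation and deduplicates", {
  cp <- mk_contacts(c(
    "chr1\t100000\t101000\tchr1\t500000\t501000\tc1\t10",
    "chr1\t500000\t501000\tchr1\t100000\t101000\tc1dup\t10",
    "chr1\t900000\t901000\tchr1\t200000\t201000\tc2\t5",
    "chr1\t100\t1100\tchr2\t100\t1100\tinter\t3"))
  expect_equal(nrow(cp), 3)   # duplicate collapsed after orientation
  expect_true(all(cp$start1[cp$intra] <= cp$start2[cp$intra]))
  expect_equal(cp$separation[cp$name == "c2"], 700000)
  expect_true(is.na(cp$separation[cp$name == "inter"]))
})

test_that("filter_contacts applies inclusive separation bounds", {
  g <- tiny_genome(1, 5e7)
  cp <- mk_contacts(c(
    "chr1\t1000\t1200\tchr1\t1500\t1700\tshort\t1",       # sep 500: dropped
    "chr1\t1000\t2000\tchr1\t2000\t3000\tmin\t1",          # sep 1000: kept
    "chr1\t1000\t2000\tchr1\t10001000\t10002000\tmax\t1",  # sep 1e7: kept
    "chr1\t1000\t2000\tchr1\t12001000\t12002000\tfar\t1"), # sep 1.2e7: dropped
    genome = g)
  f <- filter_contacts(cp)
  expect_setequal(f$name, c("min", "max"))
  # idempotent
  expect_identical(filter_contacts(f), f)
})

test_that("find_area1 matches anchors within the window, both sides", {
  g <- tiny_genome(1, 5e7)
  prcas <- read_bed(withr::local_tempfile(lines = c(
    "chr1\t99000\t99500\tpA", "chr1\t800000\t800500\tpB")), g)
  cp <- mk_contacts(c(
    # anchor1 800 bp from pA -> hit; anchor2 far from everything
    "chr1\t100300\t101300\tchr1\t700000\t701000\tc1\t1",
    # anchor1 1,200 bp away -> no hit
    "chr1\t100700\t101700\tchr1\t2000000\t2001000\tc2\t1",
    # both anchors within window -> two hits
    "chr1\t99600\t100600\tchr1\t799000\t799900\tc3\t1"), genome = g)
  f <- filter_contacts(cp)
  hits <- find_area1(f, prcas, g, window = 1000)
  expect_equal(nrow(hits), 3)
  expect_equal(sum(hits$contact == which(f$name == "c3")), 2)
  expect_false(which(f$name == "c2") %in% hits$contact)
  one_side <- find_area1(f, prcas, g, window = 1000, both_anchors = FALSE)
  expect_true(all(one_side$side == 1))
})

test_that("area2_profile counts neighbors strictly inside the window", {
  g <- tiny_genome(2, 5e7)
  prcas <- read_bed(withr::local_tempfile(lines = "chr1\t99000\t99500\tpA"), g)
  cp <- mk_contacts("chr1\t99200\t100200\tchr1\t1000000\t1001000\tc1\t1",
                    genome = g)
  hits <- find_area1(filter_contacts(cp), prcas, g)
  # i-RCAs at 10, 20 and 60 kb from the area-2 interval edges
  ircas <- read_bed(withr::local_tempfile(lines = c(
    "chr1\t1011000\t1011500", "chr1\t1021000\t1021500",
    "chr1\t1061000\t1061500")), g)
  hsites <- read_bed(withr::local_tempfile(lines = "chr2\t5000\t5002"), g)
  prof <- area2_profile(hits, ircas, hsites, g, window = 50000)
  expect_equal(prof$n_irca_within, 2)
  expect_equal(prof$nearest_irca_bp, 10000)
  # H-sites only on the other chromosome: no-neighbor flag, zero count
  expect_true(is.na(prof$nearest_hsite_bp))
  expect_equal(prof$n_hsite_within, 0)
})

test_that("area2_profile matches an all-pairs oracle", {
  set.seed(81)
  g <- tiny_genome(2, 5e6)
  for (rep in 1:3) {
    prcas <- rand_gr(20, g)
    anchors <- rand_gr(60, g, max_width = 1000)
    df <- gr_fields(anchors)
    cp <- contact_pairs(data.frame(
      chrom1 = df$chrom[1:30], start1 = df$s[1:30] - 1, end1 = df$e[1:30],
      chrom2 = df$chrom[31:60], start2 = df$s[31:60] - 1, end2 = df$e[31:60]))
    f <- filter_contacts(cp, min_sep = 1, max_sep = 1e9)
    hits <- find_area1(f, prcas, g, window = 2000)
    if (!nrow(hits)) next
    ircas <- rand_gr(40, g)
    hsites <- rand_gr(30, g)
    prof <- area2_profile(hits, ircas, hsites, g, window = 50000)
    a2 <- GenomicRanges::GRanges(
      seqnames = factor(hits$chrom, levels = names(g)),
      IRanges::IRanges(start = hits$area2_start + 1, end = hits$area2_end),
      seqinfo = genome_seqinfo(g))
    nd <- bf_nearest(a2, ircas)
    expect_equal(prof$nearest_irca_bp, nd[, 2])
    fi <- gr_fields(ircas); fa <- gr_fields(a2)
    want <- vapply(seq_along(a2), function(i) {
      same <- fi$chrom == fa$chrom[i]
      sum(bf_gap(fa$s[i], fa$e[i], fi$s[same], fi$e[same]) < 50000)
    }, 0L)
    expect_equal(prof$n_irca_within, want)
    # profile sanity: nearest distance never exceeds a counted neighbor's
    expect_true(all(is.na(prof$nearest_irca_bp) |
                    prof$n_irca_within == 0 |
                    prof$nearest_irca_bp < 50000))
  }
})

test_that("contact_summary reports separation stats and per-gene support", {
  g <- tiny_genome(1, 5e7)
  genes <- gene_models(data.frame(
    gene_id = "g1", chrom = "chr1", strand = "+",
    start = 99500, end = 109500, exons = "99500-109500"), g)
  prcas <- read_bed(withr::local_tempfile(lines = "chr1\t99000\t99400\tpA"), g)
  cp <- mk_contacts(c(
    "chr1\t99200\t100200\tchr1\t199200\t200200\tc1\t1",
    "chr1\t99200\t100200\tchr1\t399200\t400200\tc2\t1"), genome = g)
  f <- filter_contacts(cp)
  hits <- find_area1(f, prcas, g)
  expect_equal(mean(hits$separation), 200000)
  ircas <- read_bed(withr::local_tempfile(lines = "chr1\t210000\t210500"), g)
  prof <- area2_profile(hits, ircas,
                        read_bed(withr::local_tempfile(
                          lines = "chr1\t1000\t1002"), g), g)
  pairing <- pair_prca_with_downregulated(prcas, n_rna_regions("g1", genes))
  cs <- contact_summary(hits, prof, pairing)
  expect_equal(cs$separation$mean_bp, 200000)
  expect_equal(cs$per_gene$gene_id, "g1")
  expect_equal(cs$per_gene$n_contacts, 2)
  expect_equal(cs$per_gene$n_area2_with_irca, 1)
  expect_true(cs$per_gene$has_irca_support)
})
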