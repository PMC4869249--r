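test_that("BED parsing honors strand and enforces uniform length", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t121\tx\t0\t-",
               "chr1\t200\t221\ty\t0\t+"), path)
  rs <- read_bed(path)
  expect_equal(rs$L, 21L)
  expect_equal(rs$regions$start, c(100L, 200L))
  expect_equal(rs$regions$strand, c("-", "+"))

  # BED3 defaults to the plus strand
  writeLines("chr1\t10\t31", path)
  expect_equal(read_bed(path)$regions$strand, "+")

  writeLines(c("chr1\t0\t21", "chr1\t30\t50"), path)
  expect_error(read_bed(path), "differ in length")
  writeLines(character(0), path)
  expect_error(read_bed(path), "empty")
})

test_that("feature windows place anchors at the documented offsets", {
  codon <- region_set(data.frame(chrom = "chr1", start = 100L, end = 103L,
                                 strand = "+"))
  w <- make_feature_windows(codon, up = 9L, down = 9L)
  expect_equal(w$L, 21L)
  expect_equal(w$regions$start, 91L)
  # the codon occupies 0-based offsets 9-11 of the window
  expect_equal(100L - w$regions$start, 9L)
  expect_equal(102L - w$regions$start, 11L)

  heptamer <- region_set(data.frame(chrom = "chr1", start = 500L,
                                    end = 507L, strand = "+"))
  w <- make_feature_windows(heptamer, up = 21L, down = 21L)
  expect_equal(w$L, 49L)
  expect_equal(500L - w$regions$start, 21L)  # motif at offsets 21-27
  expect_equal(506L - w$regions$start, 27L)

  expect_equal(make_feature_windows(codon, 0L, 0L)$regions,
               codon$regions)
})

test_that("window flanks are applied in transcript orientation", {
  # minus-strand anchor: upstream (5') is the higher-coordinate side
  anchor <- region_set(data.frame(chrom = "chr1", start = 100L, end = 103L,
                                  strand = "-"))
  w <- make_feature_windows(anchor, up = 9L, down = 2L)
  expect_equal(w$regions$start, 98L)   # 2 nt downstream (lower coords)
  expect_equal(w$regions$end, 112L)    # 9 nt upstream (higher coords)
})

test_that("windows crossing chromosome bounds are dropped with a warning", {
  anchors <- region_set(data.frame(
    chrom = "chr1", start = c(3L, 50L), end = c(6L, 53L), strand = "+"))
  expect_warning(w <- make_feature_windows(anchors, up = 9L, down = 9L),
                 "dropped")
  expect_equal(nrow(w$regions), 1L)
  safe <- region_set(data.frame(
    chrom = "chr1", start = c(20L, 50L), end = c(23L, 53L), strand = "+"))
  expect_warning(
    w2 <- make_feature_windows(safe, 9L, 9L, chrom_lengths = c(chr1 = 60L)),
    "dropped")
  expect_equal(w2$regions$start, 11L)  # only the in-bounds window survives
  expect_error(
    suppressWarnings(
      make_feature_windows(anchors[["regions"]][1, ], 9L, 9L)),
    "no windows remain")
})

test_that("oriented extraction reverses minus-strand score vectors", {
  st <- store_with_track(c(10, 20, 30), chrom = "chr1", strand = "+")
  add_scores(st, score_track("chr1", "-", "pars", c(10, 20, 30)))
  plus <- genomic_interval("chr1", 0, 3, "+")
  minus <- genomic_interval("chr1", 0, 3, "-")
  expect_equal(extract_oriented_profile(st, plus, "pars"), c(10, 20, 30))
  expect_equal(extract_oriented_profile(st, minus, "pars"), c(30, 20, 10))
  # a region with no scores is all-missing, not an error
  empty <- genomic_interval("chr1", 100, 103, "+")
  expect_equal(extract_oriented_profile(st, empty, "pars"),
               rep(NA_real_, 3))
})

test_that("meta-profile means exclude missing values and count contributors", {
  st <- score_store()
  add_scores(st, score_track("chr1", "+", "dms",
                             c(1, 2, 3,           # region A: [0,3)
                               NA, NA, NA, NA,
                               3, 2, 1,           # region B: [7,10)
                               NA, NA,
                               5, NA, NA)))       # region C: [12,15)
  rs <- region_set(data.frame(
    chrom = "chr1", start = c(0L, 7L, 12L), end = c(3L, 10L, 15L),
    strand = "+"))
  prof <- aggregate_mean(st, rs, "dms")
  expect_equal(prof$mean_score, c(3, 2, 2))
  expect_equal(prof$n_contrib, c(3L, 2L, 2L))

  # two full regions only: the worked average
  rs2 <- region_set(rs$regions[1:2, ])
  prof2 <- aggregate_mean(st, rs2, "dms")
  expect_equal(prof2$mean_score, c(2, 2, 2))
  expect_equal(prof2$n_contrib, c(2L, 2L, 2L))

  # all regions missing at an offset -> missing mean, n = 0
  rs3 <- region_set(data.frame(chrom = "chr1", start = 3L, end = 6L,
                               strand = "+"))
  prof3 <- aggregate_mean(st, rs3, "dms")
  expect_true(all(is.na(prof3$mean_score)))
  expect_equal(prof3$n_contrib, rep(0L, 3))
})

test_that("aggregation is unweighted, bounded, and consistent", {
  st <- store_with_track(c(1, NA, 3, 4, NA), method = "pars")
  regs <- data.frame(chrom = "chr1", start = c(0L, 2L), end = c(2L, 4L),
                     strand = "+")
  rs <- region_set(regs)
  prof <- aggregate_mean(st, rs, "pars")
  # duplicating every region leaves the mean unchanged, doubles n_contrib
  prof2 <- aggregate_mean(st, region_set(rbind(regs, regs)), "pars")
  expect_equal(prof2$mean_score, prof$mean_score)
  expect_equal(prof2$n_contrib, 2L * prof$n_contrib)
  expect_true(all(prof2$n_contrib <= 4L))
  # a single region's profile equals its oriented extraction
  one <- region_set(regs[1, ])
  expect_equal(aggregate_mean(st, one, "pars")$mean_score,
               extract_oriented_profile(
                 st, genomic_interval("chr1", 0, 2, "+"), "pars"))
  # mean missing exactly where nothing contributes
  expect_equal(is.na(prof$mean_score), prof$n_contrib == 0L)
})

test_that("minus-strand aggregation matches the mirrored plus-strand setup", {
  # same score sequence written forward on + and mirrored on -, so the
  # oriented profiles must agree
  vals <- c(0.5, -1, 2, 7, 0)
  st <- score_store()
  add_scores(st, score_track("chr1", "+", "dsss", vals))
  add_scores(st, score_track("chr1", "-", "dsss", rev(vals)))
  plus <- region_set(data.frame(chrom = "chr1", start = 0L, end = 5L,
                                strand = "+"))
  minus <- region_set(data.frame(chrom = "chr1", start = 0L, end = 5L,
                                 strand = "-"))
  expect_equal(aggregate_mean(st, minus, "dsss")$mean_score,
               aggregate_mean(st, plus, "dsss")$mean_score)
})

test_that("IUPAC motif scanning finds exact matches on both strands", {
  hits <- motif_scan(c(seq1 = "GAAAAAAAG"), "AAAAAAA")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 1L)
  expect_equal(hits$end, 8L)
  expect_equal(hits$strand, "+")
  # a reverse-complement match is a minus-strand hit over the matched span
  hits <- motif_scan(c(seq1 = "GGTTTTTTTGG"), "AAAAAAA")
  expect_equal(hits$strand, "-")
  expect_equal(c(hits$start, hits$end), c(2L, 9L))
  # degenerate codes and RNA alphabet
  hits <- motif_scan(c(seq1 = "CCATGCC"), "NNAUGNN")
  expect_true(any(hits$strand == "+" & hits$start == 0L))
  # no room for the motif
  expect_equal(nrow(motif_scan(c(s = "AAA"), "AAAAAAA")), 0L)
  expect_error(motif_scan(c(s = "ACGT"), "AXG"), "invalid IUPAC")
})

test_that("motif scanning reads FASTA and feeds window construction", {
  toy <- make_toy_annotation(4, seed = 9)
  fa <- withr::local_tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(toy$sequences, fa)
  hits <- motif_scan(fa, "ATG")
  # every planted plus-strand codon is recovered
  planted <- toy$anchors$regions
  plus_anchors <- planted[planted$strand == "+", ]
  found <- merge(plus_anchors, hits,
                 by = c("chrom", "start", "end", "strand"))
  expect_equal(nrow(found), nrow(plus_anchors))
  # and the hits can be turned into profile windows directly
  w <- make_feature_windows(region_set(plus_anchors), up = 9L, down = 9L)
  expect_equal(w$L, 21L)
})
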