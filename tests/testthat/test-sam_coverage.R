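test_that("alignment filter applies the inclusive thresholds", {
  rec <- alignment_records(
    read_id = c("lowmm", "himm", "boundary", "multi"),
    chrom = "chr1", start = c(0L, 10L, 20L, 30L),
    end = c(36L, 46L, 56L, 66L), strand = "+",
    mismatches = c(0L, 3L, 2L, 0L),
    edit_distance = c(0L, 3L, 2L, 0L),
    n_hits = c(1L, 1L, 5L, 6L))
  kept <- filter_alignments(rec)
  # 3 mismatches and 6 mapping locations are out; the exact-boundary read
  # (mm = 2, edit = 2, hits = 5) is in
  expect_identical(kept$read_id, c("lowmm", "boundary"))
  # order is preserved and filtering is idempotent
  expect_identical(filter_alignments(kept), kept)
})

test_that("filter is idempotent and respects each threshold independently", {
  set.seed(42)
  for (rep in 1:5) {
    rec <- random_records(50)
    kept <- filter_alignments(rec)
    expect_identical(filter_alignments(kept), kept)
    expect_true(all(kept$mismatches <= 2L))
    expect_true(all(kept$n_hits <= 5L))
    manual <- rec[rec$mismatches <= 2L & rec$edit_distance <= 2L &
                    rec$n_hits <= 5L, ]
    expect_equal(kept$read_id, manual$read_id)
  }
})

test_that("missing tags follow the configured policy", {
  rec <- alignment_records("r1", "chr1", 0L, 36L, "+")
  rec$n_hits <- NA_integer_
  expect_error(filter_alignments(rec), "missing a required tag")
  expect_equal(nrow(filter_alignments(rec, policy = "lenient")), 1L)
})

test_that("5'-end coverage counts the biological 5' terminus", {
  plus <- alignment_records("p", "chr1", 100L, 150L, "+")
  cov <- five_prime_end_coverage(plus, 200L)
  expect_equal(which(cov[["+"]]$counts > 0) - 1L, 100L)
  expect_equal(sum(cov[["+"]]$counts), 1L)
  expect_equal(sum(cov[["-"]]$counts), 0L)

  # a minus-strand read runs 3'->5' left to right: its 5' end is the
  # rightmost genomic base
  minus <- alignment_records("m", "chr1", 100L, 150L, "-")
  cov <- five_prime_end_coverage(minus, 200L)
  expect_equal(which(cov[["-"]]$counts > 0) - 1L, 149L)

  empty <- plus[0, ]
  cov <- five_prime_end_coverage(empty, 50L, chrom = "chr1")
  expect_equal(sum(cov[["+"]]$counts) + sum(cov[["-"]]$counts), 0L)
  expect_equal(length(cov[["+"]]), 50L)
})

test_that("full-read coverage increments every aligned base", {
  one <- alignment_records("a", "chr1", 10L, 13L, "+")
  cov <- full_read_coverage(one, 20L)
  expect_equal(cov[["+"]]$counts, c(rep(0L, 10), 1L, 1L, 1L, rep(0L, 7)))

  two <- alignment_records(c("a", "b"), "chr1", c(10L, 12L), c(13L, 15L), "+")
  cov <- full_read_coverage(two, 20L)
  expect_equal(cov[["+"]]$counts[13L], 2L)  # position 12, covered twice
  expect_equal(sum(cov[["+"]]$counts), 6L)
})

test_that("spliced alignments cover only their aligned blocks", {
  rec <- alignment_records("spliced", "chr1", 10L, 30L, "+",
                           cigar = "5M10N5M")
  cov <- full_read_coverage(rec, 40L)
  covered <- which(cov[["+"]]$counts > 0) - 1L
  expect_equal(covered, c(10:14, 25:29))  # intron 15..24 untouched
  # 5' end of a spliced minus-strand read is the terminal aligned base
  rec_m <- alignment_records("sm", "chr1", 10L, 30L, "-", cigar = "5M10N5M")
  cov5 <- five_prime_end_coverage(rec_m, 40L)
  expect_equal(which(cov5[["-"]]$counts > 0) - 1L, 29L)
})

test_that("coverage conserves read and base counts and matches a naive oracle", {
  set.seed(7)
  for (rep in 1:5) {
    rec <- filter_alignments(random_records(80))
    cov5 <- five_prime_end_coverage(rec, 300L, chrom = "chrT")
    covf <- full_read_coverage(rec, 300L, chrom = "chrT")
    # conservation: one 5'-end count per read; one full-read count per base
    expect_equal(sum(cov5[["+"]]$counts) + sum(cov5[["-"]]$counts), nrow(rec))
    expect_equal(sum(covf[["+"]]$counts) + sum(covf[["-"]]$counts),
                 sum(rec$end - rec$start))
    # naive per-read loop oracle
    o5 <- oracle_coverage(rec, 300L, "five_prime_end")
    of <- oracle_coverage(rec, 300L, "full_read")
    expect_identical(cov5[["+"]]$counts, o5[["+"]])
    expect_identical(cov5[["-"]]$counts, o5[["-"]])
    expect_identical(covf[["+"]]$counts, of[["+"]])
    expect_identical(covf[["-"]]$counts, of[["-"]])
  }
})

test_that("out-of-bounds reads are named, off-chromosome reads skipped", {
  rec <- alignment_records("runaway", "chr1", 95L, 120L, "+")
  expect_error(five_prime_end_coverage(rec, 100L), "runaway")
  mixed <- alignment_records(c("keep", "drop"), c("chr1", "chr2"),
                             c(0L, 0L), c(10L, 10L), "+")
  expect_warning(cov <- five_prime_end_coverage(mixed, 50L, chrom = "chr1"),
                 "skipped")
  expect_equal(sum(cov[["+"]]$counts), 1L)
  expect_error(five_prime_end_coverage(mixed, 50L), "multiple chromosomes")
})

test_that("SAM files round-trip through the standard parser with tags intact", {
  sam <- simulate_alignments(12, read_length = 30L, chrom_length = 500L,
                             mismatches = rep(0:3, 3), n_hits = rep(1:4, 3),
                             seed = 11)
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(sam, path)
  rec <- read_alignments(path)
  expect_equal(nrow(rec), 12L)
  expect_equal(rec$mismatches, rep(0:3, 3))
  expect_equal(rec$n_hits, rep(1:4, 3))
  expect_true(all(rec$end - rec$start == 30L))
  expect_setequal(unique(rec$strand), c("+", "-"))
  # filtering then coverage works straight off the parsed records
  cov <- five_prime_end_coverage(filter_alignments(rec), 500L)
  expect_equal(sum(cov[["+"]]$counts) + sum(cov[["-"]]$counts),
               sum(rep(0:3, 3) <= 2L & rep(1:4, 3) <= 5L))
})

test_that("coverage track TSV format round-trips", {
  tr <- coverage_track("chrX", "-", c(0L, 5L, 0L, 2L), "full_read")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_track_tsv(tr, path)
  back <- read_track_tsv(path)
  expect_identical(back$counts, tr$counts)
  expect_identical(back$chrom, "chrX")
  expect_identical(back$strand, "-")
  expect_identical(back$mode, "full_read")
})
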