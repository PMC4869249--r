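#' Construct a coverage track
#'
#' A coverage track holds non-negative per-position counts for one reference
#' sequence and one strand, indexed from 0, tagged with its counting mode:
#' `"five_prime_end"` (one count at the biological 5' terminus of each read,
#' marking an RT stop or nuclease cleavage site) or `"full_read"` (one count
#' at every aligned base).
#'
#' @param chrom reference sequence name.
#' @param strand `"+"` or `"-"`.
#' @param counts integer vector of per-position counts; `counts[i]` is the
#'   count at 0-based position `i - 1`.
#' @param mode `"five_prime_end"` or `"full_read"`.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(chrom, strand, counts,
                           mode = c("five_prime_end", "full_read")) {
  mode <- match.arg(mode)
  stopifnot(strand %in% c("+", "-"))
  counts <- as.integer(counts)
  if (anyNA(counts) || any(counts < 0L))
    stop("coverage counts must be non-negative integers")
  structure(
    list(chrom = as.character(chrom), strand = strand,
         counts = counts, mode = mode),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track %s(%s) mode=%s length=%d total=%s\n",
              x$chrom, x$strand, x$mode, length(x$counts),
              format(sum(as.numeric(x$counts)))))
  invisible(x)
}

#' @export
length.coverage_track <- function(x) length(x$counts)

# Accept a coverage_track or a bare count vector wherever a scorer needs
# counts; keeps the scoring functions usable on toy vectors.
as_counts <- function(x) {
  if (inherits(x, "coverage_track")) x$counts else as.numeric(x)
}

one_chrom <- function(records, chrom) {
  if (is.null(chrom)) {
    chrom <- unique(records$chrom)
    if (length(chrom) > 1L)
      stop("records span multiple chromosomes (",
           paste(head(chrom, 3L), collapse = ", "),
           "); pass `chrom` to select one")
    if (length(chrom) == 0L) chrom <- NA_character_
  } else {
    drop <- records$chrom != chrom
    if (any(drop)) {
      warning(sum(drop), " read(s) on other chromosomes skipped")
      records <- records[!drop, , drop = FALSE]
    }
  }
  list(records = records, chrom = chrom)
}

check_bounds <- function(records, chrom_length) {
  bad <- records$start < 0L | records$end > chrom_length
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("read '", records$read_id[i], "' [", records$start[i], ",",
         records$end[i], ") out of bounds for chromosome of length ",
         chrom_length)
  }
}

#' Count the 5'-most nucleotide of each read, per strand
#'
#' PARS, DMS-seq and icSHAPE all read out single-nucleotide events (a
#' nuclease cut or an RT stop) as the 5' end of a sequencing read, so their
#' coverage counts only the 5'-most aligned base of each read. For a
#' plus-strand read that is its leftmost genomic base; for a minus-strand
#' read it is the rightmost, because the read runs 3'-to-5' in genomic
#' coordinates.
#'
#' @param records an [alignment_records()] table, all on one chromosome
#'   (reads on other chromosomes are skipped with a warning when `chrom` is
#'   given explicitly).
#' @param chrom_length length of the reference sequence.
#' @param chrom reference name; defaults to the single chromosome present.
#' @return A list with elements `"+"` and `"-"`, each a [coverage_track()]
#'   with `mode = "five_prime_end"`.
#' @examples
#' rec <- alignment_records(c("a", "b"), "chr1", c(100L, 100L),
#'                          c(150L, 150L), c("+", "-"))
#' cov <- five_prime_end_coverage(rec, 200L)
#' which(cov[["+"]]$counts > 0) - 1  # 100
#' which(cov[["-"]]$counts > 0) - 1  # 149
#' @export
five_prime_end_coverage <- function(records, chrom_length, chrom = NULL) {
  sel <- one_chrom(records, chrom)
  records <- sel$records
  check_bounds(records, chrom_length)
  out <- lapply(c("+", "-"), function(s) {
    r <- records[records$strand == s, , drop = FALSE]
    pos5 <- if (s == "+") r$start else r$end - 1L
    coverage_track(sel$chrom, s,
                   tabulate(pos5 + 1L, nbins = chrom_length),
                   mode = "five_prime_end")
  })
  names(out) <- c("+", "-")
  out
}

#' Count every aligned base of each read, per strand
#'
#' ds/ssRNA-seq signal is the protected fragment itself, so its coverage
#' counts all aligned bases of each read. When CIGAR strings are present,
#' only aligned blocks contribute: spliced (`N`) gaps are excluded.
#'
#' @inheritParams five_prime_end_coverage
#' @return A list with elements `"+"` and `"-"`, each a [coverage_track()]
#'   with `mode = "full_read"`.
#' @examples
#' rec <- alignment_records("a", "chr1", 10L, 13L, "+")
#' full_read_coverage(rec, 20L)[["+"]]$counts[11:13]  # 1 1 1
#' @export
full_read_coverage <- function(records, chrom_length, chrom = NULL) {
  sel <- one_chrom(records, chrom)
  records <- sel$records
  check_bounds(records, chrom_length)
  out <- lapply(c("+", "-"), function(s) {
    r <- records[records$strand == s, , drop = FALSE]
    ir <- aligned_blocks(r)
    cov <- IRanges::coverage(ir, width = chrom_length)
    coverage_track(sel$chrom, s, as.integer(cov), mode = "full_read")
  })
  names(out) <- c("+", "-")
  out
}

# 1-based IRanges of the aligned blocks of each record; uses CIGAR when
# available so intron gaps are not covered.
aligned_blocks <- function(records) {
  if (nrow(records) == 0L) return(IRanges::IRanges())
  has_cigar <- !is.null(records$cigar) && !anyNA(records$cigar)
  if (has_cigar) {
    rl <- GenomicAlignments::extractAlignmentRangesOnReference(
      records$cigar, pos = records$start + 1L)
    unlist(rl, use.names = FALSE)
  } else {
    IRanges::IRanges(start = records$start + 1L, end = records$end)
  }
}

#' Write a coverage or score track as bedGraph
#'
#' Adjacent equal values are run-length collapsed; zero-count (or missing)
#' positions are omitted, following bedGraph convention.
#'
#' @param track a [coverage_track()] or [score_track()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  vals <- if (inherits(track, "score_track")) track$scores else track$counts
  keep <- !is.na(vals) & vals != 0
  if (!any(keep)) {
    rle_v <- S4Vectors::Rle(numeric(0))
    gr <- GenomicRanges::GRanges()
  } else {
    v <- vals
    v[is.na(v)] <- 0
    rle_v <- S4Vectors::Rle(v)
    starts <- cumsum(c(0L, S4Vectors::runLength(rle_v)))
    run_val <- S4Vectors::runValue(rle_v)
    nz <- run_val != 0
    gr <- GenomicRanges::GRanges(
      seqnames = track$chrom,
      ranges = IRanges::IRanges(
        start = starts[which(nz)] + 1L,
        width = S4Vectors::runLength(rle_v)[nz]),
      score = run_val[nz])
  }
  label <- sprintf("%s_%s_%s", track$chrom, track$strand,
                   if (inherits(track, "score_track")) track$method else track$mode)
  rtracklayer::export(gr, path, format = "bedGraph",
                      trackLine = methods::new("GraphTrackLine",
                                               name = label, type = "bedGraph"))
  invisible(path)
}

#' Write / read a coverage track in the package's TSV track format
#'
#' A plain-text sparse format: comment headers naming chromosome, strand,
#' counting mode and track length, then `pos0<TAB>count` rows for the
#' non-zero positions.
#'
#' @param track a [coverage_track()].
#' @param path file path.
#' @return `write_track_tsv()` returns `path` invisibly;
#'   `read_track_tsv()` returns the reconstructed [coverage_track()].
#' @export
write_track_tsv <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# structscore coverage_track v1",
    sprintf("# chrom=%s strand=%s mode=%s length=%d",
            track$chrom, track$strand, track$mode, length(track$counts))
  ), con)
  nz <- which(track$counts != 0L)
  if (length(nz))
    writeLines(sprintf("%d\t%d", nz - 1L, track$counts[nz]), con)
  invisible(path)
}

#' @rdname write_track_tsv
#' @export
read_track_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# chrom=", lines, value = TRUE)
  if (length(hdr) != 1L) stop("not a structscore track file: ", path)
  m <- regmatches(hdr, regexec(
    "chrom=(\\S+) strand=([+-]) mode=(\\S+) length=(\\d+)", hdr))[[1L]]
  if (length(m) != 5L) stop("malformed track header in ", path)
  counts <- integer(as.integer(m[5L]))
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    pos <- as.integer(vapply(parts, `[`, "", 1L))
    val <- as.integer(vapply(parts, `[`, "", 2L))
    counts[pos + 1L] <- val
  }
  coverage_track(m[2L], m[3L], counts, mode = m[4L])
}
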