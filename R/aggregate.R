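#' Construct a set of equal-length regions
#'
#' Meta-profiles average scores position-by-position across regions, which
#' only makes sense when every region has the same length; the constructor
#' enforces that.
#'
#' @param regions a `data.frame` with columns `chrom`, `start`, `end`,
#'   `strand` (0-based half-open), or a list of [genomic_interval()]s.
#' @param label optional label for the set.
#' @return An object of class `region_set`.
#' @export
region_set <- function(regions, label = "") {
  if (is.list(regions) && !is.data.frame(regions) &&
      all(vapply(regions, inherits, TRUE, "genomic_interval"))) {
    regions <- data.frame(
      chrom = vapply(regions, `[[`, "", "chrom"),
      start = vapply(regions, `[[`, 1L, "start"),
      end = vapply(regions, `[[`, 1L, "end"),
      strand = vapply(regions, `[[`, "", "strand"),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(regions),
            all(c("chrom", "start", "end", "strand") %in% names(regions)))
  if (nrow(regions) == 0L) stop("region set is empty")
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  if (any(regions$start >= regions$end))
    stop("regions must satisfy start < end")
  if (!all(regions$strand %in% c("+", "-")))
    stop("region strand must be '+' or '-'")
  len <- regions$end - regions$start
  if (length(unique(len)) != 1L) {
    off <- which(len != len[1L])
    stop("regions differ in length (expected ", len[1L], " nt): rows ",
         paste(head(off, 10L), collapse = ", "))
  }
  rownames(regions) <- NULL
  structure(list(regions = regions, L = len[1L], label = label),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set '%s': %d region(s) of %d nt\n",
              x$label, nrow(x$regions), x$L))
  invisible(x)
}

#' Read a BED file of equal-length regions
#'
#' Accepts BED3 (strand defaults to `"+"`) or BED6 (column 6 strand
#' honored). BED is already 0-based half-open, so coordinates pass through
#' unchanged. Regions of differing lengths are an error listing the
#' offending lines, since profiles require a uniform length.
#'
#' @param path BED3/BED6 file.
#' @param label label for the resulting set (default: file name).
#' @return A [region_set()].
#' @export
read_bed <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0L) stop("empty BED file: ", path)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  regions <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strand,
    stringsAsFactors = FALSE)
  len <- regions$end - regions$start
  if (length(unique(len)) != 1L) {
    off <- which(len != len[1L])
    stop("BED regions in ", path, " differ in length (expected ", len[1L],
         " nt): line(s) ", paste(head(off, 10L), collapse = ", "))
  }
  region_set(regions, label = label)
}

#' Build fixed flanking windows around anchor features
#'
#' Expands each anchor (e.g. a 3-nt codon or a 7-nt motif match) by `up`
#' nucleotides upstream and `down` downstream *in transcript orientation*:
#' for a minus-strand anchor, upstream means higher genomic coordinates.
#' With a 3-nt anchor and `up = down = 9`, the feature occupies 0-based
#' offsets 9-11 of the resulting 21-nt windows; a 7-nt anchor with 21-nt
#' flanks occupies offsets 21-27 of a 49-nt window.
#'
#' @param anchors a [region_set()] or `data.frame` of equal-length anchor
#'   intervals.
#' @param up,down flank lengths in nt (>= 0).
#' @param chrom_lengths optional named vector of chromosome lengths;
#'   windows running past a known boundary (or below position 0) are
#'   dropped with a warning.
#' @return A [region_set()] of windows of length `up + anchor_length +
#'   down`.
#' @export
make_feature_windows <- function(anchors, up, down, chrom_lengths = NULL) {
  stopifnot(up >= 0L, down >= 0L)
  if (inherits(anchors, "region_set")) anchors <- anchors$regions
  anchors <- region_set(anchors)$regions  # validates uniform length
  plus <- anchors$strand == "+"
  start <- ifelse(plus, anchors$start - up, anchors$start - down)
  end <- ifelse(plus, anchors$end + down, anchors$end + up)
  keep <- start >= 0L
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[anchors$chrom]
    keep <- keep & (is.na(lim) | end <= lim)
  }
  if (any(!keep))
    warning(sum(!keep), " window(s) dropped: extend past chromosome bounds")
  if (!any(keep)) stop("no windows remain inside chromosome bounds")
  region_set(data.frame(chrom = anchors$chrom[keep],
                        start = as.integer(start[keep]),
                        end = as.integer(end[keep]),
                        strand = anchors$strand[keep],
                        stringsAsFactors = FALSE))
}

#' Extract one region's scores in transcript orientation
#'
#' Pulls the per-position scores of one method over an interval and lists
#' them 5' to 3' along the transcript: minus-strand intervals have their
#' genomic-order vector reversed, so offset 0 is always the transcript-5'
#' end of the region.
#'
#' @param store a [score_store()].
#' @param interval a [genomic_interval()] with strand `"+"` or `"-"`.
#' @param method one method tag.
#' @return Numeric vector of length `end - start`; `NA` where unscored.
#' @export
extract_oriented_profile <- function(store, interval, method) {
  if (is.character(interval)) interval <- parse_region(interval)
  if (!interval$strand %in% c("+", "-"))
    stop("oriented extraction needs a stranded interval ('+' or '-')")
  res <- suppressWarnings(query_interval(store, interval, methods = method))
  v <- res[[method]][[interval$strand]]
  if (interval$strand == "-") rev(v) else v
}

#' Average scores across a region collection into a meta-profile
#'
#' The meta-profile's value at offset `k` is the arithmetic mean of the
#' oriented (5'-to-3') scores at offset `k` over all regions that have a
#' score there; missing positions are excluded from both numerator and
#' denominator, and the number of contributing regions is reported
#' alongside so downstream users can weight or filter. Regions are
#' unweighted: a deeply covered region counts once, like any other.
#'
#' @param store a [score_store()].
#' @param regionset a [region_set()].
#' @param method one method tag.
#' @return An object of class `aggregate_profile` with fields `method`,
#'   `L`, `mean_score` (length-`L` numeric, `NA` where no region
#'   contributes) and `n_contrib` (length-`L` integer).
#' @export
aggregate_mean <- function(store, regionset, method) {
  stopifnot(inherits(regionset, "region_set"))
  method <- match.arg(method, score_methods())
  regs <- regionset$regions
  mat <- matrix(NA_real_, nrow = nrow(regs), ncol = regionset$L)
  for (i in seq_len(nrow(regs))) {
    iv <- genomic_interval(regs$chrom[i], regs$start[i], regs$end[i],
                           regs$strand[i])
    mat[i, ] <- extract_oriented_profile(store, iv, method)
  }
  n <- colSums(!is.na(mat))
  mean_score <- ifelse(n > 0L, colMeans(mat, na.rm = TRUE), NA_real_)
  structure(list(method = method, L = regionset$L,
                 mean_score = mean_score, n_contrib = as.integer(n)),
            class = "aggregate_profile")
}

#' @export
print.aggregate_profile <- function(x, ...) {
  cat(sprintf("aggregate_profile method=%s L=%d (max n_contrib=%d)\n",
              x$method, x$L, max(x$n_contrib)))
  invisible(x)
}

#' Write meta-profiles as TSV
#'
#' One row per offset and method: `offset  method  mean  n`, with `NA` for
#' offsets no region contributed to.
#'
#' @param profiles an `aggregate_profile` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profiles, path) {
  if (inherits(profiles, "aggregate_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(offset = seq_len(p$L) - 1L, method = p$method,
               mean = p$mean_score, n = p$n_contrib,
               stringsAsFactors = FALSE)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# structscore aggregate_profile v1", con)
  writeLines("offset\tmethod\tmean\tn", con)
  writeLines(sprintf("%d\t%s\t%s\t%d", rows$offset, rows$method,
                     ifelse(is.na(rows$mean), "NA",
                            format(rows$mean, digits = 15, trim = TRUE,
                                   scientific = FALSE)),
                     rows$n), con)
  invisible(path)
}

#' Scan sequences for IUPAC motif matches on both strands
#'
#' Exact IUPAC-degenerate matching (no mismatches, no PWM scoring). `U` is
#' treated as `T`. Plus-strand hits are matches of the motif itself;
#' minus-strand hits are matches of its reverse complement, reported as
#' minus-strand intervals over the matched span in forward coordinates.
#'
#' @param sequences a named `DNAStringSet`, a named character vector of
#'   sequences, or the path to a FASTA file.
#' @param motif IUPAC motif string (e.g. `"NNAAUNN"`).
#' @return A `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `strand`; zero rows when nothing matches.
#' @examples
#' motif_scan(c(seq1 = "GAAAAAAAG"), "AAAAAAA")  # one + hit at [1,8)
#' @export
motif_scan <- function(sequences, motif) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    sequences <- Biostrings::readDNAStringSet(sequences)
  } else if (is.character(sequences)) {
    sequences <- Biostrings::DNAStringSet(gsub("U", "T", toupper(sequences)))
  }
  stopifnot(methods::is(sequences, "DNAStringSet"))
  if (is.null(names(sequences)))
    stop("sequences must be named (FASTA headers provide names)")
  motif <- toupper(gsub("U", "T", motif))
  if (nchar(motif) < 1L) stop("motif must have length >= 1")
  ok <- strsplit(motif, "")[[1L]] %in% names(Biostrings::IUPAC_CODE_MAP)
  if (!all(ok))
    stop("invalid IUPAC character(s) in motif: ",
         paste(unique(strsplit(motif, "")[[1L]][!ok]), collapse = ", "))
  pat <- Biostrings::DNAString(motif)
  scan_one_strand <- function(pattern, strand) {
    hits <- Biostrings::vmatchPattern(pattern, sequences, fixed = FALSE)
    do.call(rbind, lapply(seq_along(hits), function(i) {
      h <- hits[[i]]
      if (length(h) == 0L) return(NULL)
      data.frame(chrom = names(sequences)[i],
                 start = IRanges::start(h) - 1L,
                 end = IRanges::end(h),
                 strand = strand, stringsAsFactors = FALSE)
    }))
  }
  fwd <- scan_one_strand(pat, "+")
  rvs <- scan_one_strand(Biostrings::reverseComplement(pat), "-")
  out <- rbind(fwd, rvs)
  if (is.null(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
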