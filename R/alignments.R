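#' Construct a table of alignment records
#'
#' An alignment record table is the package's in-memory form of aligned reads:
#' one row per alignment with the fields the post-alignment filters and the
#' coverage counters need. Coordinates are 0-based half-open.
#'
#' @param read_id character, read names.
#' @param chrom character, reference sequence names.
#' @param start integer, 0-based leftmost aligned position.
#' @param end integer, 0-based exclusive rightmost aligned position.
#' @param strand character, `"+"` or `"-"`.
#' @param mismatches integer, mismatch count per read (SAM `XM`-style).
#' @param edit_distance integer, edit distance per read (SAM `NM`-style).
#' @param n_hits integer, number of reported mapping locations (SAM
#'   `NH`-style).
#' @param cigar optional character CIGAR strings; when present, full-read
#'   coverage counts only the aligned (`M`/`=`/`X`/`D`) blocks so spliced
#'   alignments do not cover their introns.
#'
#' @return A `data.frame` of class `alignment_records`.
#' @examples
#' alignment_records("r1", "chr1", 100L, 150L, "+", 0L, 0L, 1L)
#' @export
alignment_records <- function(read_id, chrom, start, end, strand,
                              mismatches = 0L, edit_distance = mismatches,
                              n_hits = 1L, cigar = NULL) {
  n <- length(start)
  rec <- data.frame(
    read_id = rep_len(as.character(read_id), n),
    chrom = rep_len(as.character(chrom), n),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), n),
    mismatches = rep_len(as.integer(mismatches), n),
    edit_distance = rep_len(as.integer(edit_distance), n),
    n_hits = rep_len(as.integer(n_hits), n),
    stringsAsFactors = FALSE
  )
  rec$cigar <- if (is.null(cigar)) NA_character_ else rep_len(as.character(cigar), n)
  validate_alignment_records(rec)
  class(rec) <- c("alignment_records", "data.frame")
  rec
}

validate_alignment_records <- function(rec) {
  if (nrow(rec) == 0L) return(invisible(rec))
  if (any(rec$start >= rec$end))
    stop("alignment records must satisfy start < end")
  if (!all(rec$strand %in% c("+", "-")))
    stop("alignment strand must be '+' or '-'")
  bad <- !is.na(rec$mismatches) & rec$mismatches < 0L
  if (any(bad)) stop("mismatch counts must be >= 0")
  bad <- !is.na(rec$n_hits) & rec$n_hits < 1L
  if (any(bad)) stop("n_hits must be >= 1")
  invisible(rec)
}

#' Read aligned reads from a SAM or BAM file
#'
#' Parses alignments with their mismatch (`XM`), edit-distance (`NM`) and
#' hit-count (`NH`) tags into an [alignment_records()] table. SAM text files
#' are converted on the fly. Unmapped reads are never returned.
#'
#' Aligners differ in which tags they emit. Under the default `"strict"`
#' policy a record missing a required tag is an error; under `"lenient"`, a
#' missing `NH` is taken as 1 (unique), a missing `XM` falls back to `NM`,
#' and a missing `NM` falls back to `XM` (0 if both absent), so a file
#' carrying only one of the two distance tags can still be filtered on both
#' thresholds.
#'
#' @param path path to a SAM (`.sam`) or BAM (`.bam`) file.
#' @param policy `"strict"` or `"lenient"` handling of absent tags.
#' @return An [alignment_records()] table, one row per mapped alignment.
#' @seealso [filter_alignments()]
#' @export
read_alignments <- function(path, policy = c("strict", "lenient")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  ga <- GenomicAlignments::readGAlignments(
    bam,
    param = Rsamtools::ScanBamParam(
      tag = c("NM", "XM", "NH"),
      what = "qname"
    ),
    use.names = FALSE
  )
  tags <- S4Vectors::mcols(ga)
  nm <- as.integer(tags$NM)
  xm <- as.integer(tags$XM)
  nh <- as.integer(tags$NH)
  if (policy == "strict") {
    if (length(ga) && (anyNA(nm) || anyNA(xm) || anyNA(nh)))
      stop("alignments missing NM/XM/NH tags; use policy = \"lenient\" ",
           "to impute them")
  } else {
    xm <- ifelse(is.na(xm), ifelse(is.na(nm), 0L, nm), xm)
    nm <- ifelse(is.na(nm), xm, nm)
    nh <- ifelse(is.na(nh), 1L, nh)
  }
  rec <- data.frame(
    read_id = as.character(tags$qname),
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    start = GenomicAlignments::start(ga) - 1L,
    end = GenomicAlignments::end(ga),
    strand = as.character(GenomicAlignments::strand(ga)),
    mismatches = xm,
    edit_distance = nm,
    n_hits = nh,
    cigar = as.character(GenomicAlignments::cigar(ga)),
    stringsAsFactors = FALSE
  )
  class(rec) <- c("alignment_records", "data.frame")
  rec
}

#' Filter alignments on mismatches, edit distance and mapping multiplicity
#'
#' Retains alignments with at most `max_mismatch` mismatches, edit distance
#' at most `max_edit`, and at most `max_hits` reported mapping locations
#' (all thresholds inclusive). Input order is preserved, and multi-mapped
#' reads that pass contribute one count per retained alignment.
#'
#' @param records an [alignment_records()] table.
#' @param max_mismatch maximum mismatches per read (default 2).
#' @param max_edit maximum edit distance (default 2).
#' @param max_hits maximum number of mapping locations (default 5).
#' @param policy `"strict"` (default): a record with an `NA` in any filtered
#'   field is an error; `"lenient"`: `NA` mismatches/edit distance count as
#'   0 and `NA` hit counts as 1.
#' @return The retained subset, same class, original order.
#' @examples
#' rec <- alignment_records(letters[1:3], "chr1", c(0L, 10L, 20L),
#'                          c(36L, 46L, 56L), "+",
#'                          mismatches = c(0L, 3L, 2L), n_hits = c(1L, 1L, 6L))
#' nrow(filter_alignments(rec))  # only the first read survives
#' @export
filter_alignments <- function(records, max_mismatch = 2L, max_edit = 2L,
                              max_hits = 5L, policy = c("strict", "lenient")) {
  policy <- match.arg(policy)
  stopifnot(max_mismatch >= 0L, max_edit >= 0L, max_hits >= 0L)
  mm <- records$mismatches
  ed <- records$edit_distance
  nh <- records$n_hits
  if (anyNA(mm) || anyNA(ed) || anyNA(nh)) {
    if (policy == "strict") {
      bad <- which(is.na(mm) | is.na(ed) | is.na(nh))
      stop("record(s) missing a required tag (rows ",
           paste(head(bad, 5L), collapse = ", "),
           "); use policy = \"lenient\" to impute")
    }
    mm[is.na(mm)] <- 0L
    ed[is.na(ed)] <- 0L
    nh[is.na(nh)] <- 1L
  }
  keep <- mm <= max_mismatch & ed <= max_edit & nh <= max_hits
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
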