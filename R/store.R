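#' Genomic intervals in 0-based half-open coordinates
#'
#' @param chrom reference sequence name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; `start < end`.
#' @param strand `"+"`, `"-"`, or `"."` (query both strands).
#' @return An object of class `genomic_interval`.
#' @examples
#' genomic_interval("chr19", 9982727, 9982762, "+")
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end) || start >= end)
    stop("interval must satisfy start < end")
  if (!strand %in% c("+", "-", "."))
    stop("strand must be '+', '-' or '.'")
  structure(list(chrom = as.character(chrom), start = start,
                 end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%d-%d(%s) [0-based half-open, width %d]\n",
              x$chrom, x$start, x$end, x$strand, x$end - x$start))
  invisible(x)
}

#' Parse a genome-browser region string
#'
#' User-facing region strings `chr:start-end` follow the 1-based inclusive
#' genome-browser convention and are converted to the package's internal
#' 0-based half-open coordinates here, at the interface edge.
#'
#' @param region string like `"chr19:9982728-9982762"`, optionally with a
#'   trailing `:+`, `:-` or `:.` strand.
#' @param strand strand when not carried by the string.
#' @return A [genomic_interval()].
#' @examples
#' parse_region("chr19:9982728-9982762")  # 35 positions
#' @export
parse_region <- function(region, strand = ".") {
  m <- regmatches(region, regexec(
    "^(\\S+?):([0-9,]+)-([0-9,]+)(?::([+.-]))?$", region))[[1L]]
  if (length(m) < 4L || !nzchar(m[2L]))
    stop("cannot parse region string: ", region,
         " (expected chr:start-end, 1-based inclusive)")
  s1 <- as.integer(gsub(",", "", m[3L], fixed = TRUE))
  e1 <- as.integer(gsub(",", "", m[4L], fixed = TRUE))
  if (length(m) >= 5L && nzchar(m[5L])) strand <- m[5L]
  genomic_interval(m[2L], s1 - 1L, e1, strand)
}

#' Create an empty score store
#'
#' The score store is the package's stand-in for a database server: an
#' in-memory, key-indexed table of `(chrom, pos0, strand, method, score)`
#' records plus a manifest describing each loaded dataset. Lookups by
#' interval are binary searches on the sorted key, so queries cost
#' O(log n + hits).
#'
#' @return An object of class `score_store`.
#' @seealso [load_scores()], [add_scores()], [query_interval()],
#'   [export_scores()]
#' @export
score_store <- function() {
  env <- new.env(parent = emptyenv())
  env$dt <- data.table::data.table(
    chrom = character(), pos0 = integer(), strand = character(),
    method = character(), score = numeric())
  data.table::setkeyv(env$dt, c("method", "chrom", "strand", "pos0"))
  env$manifest <- data.frame(method = character(), species = character(),
                             condition = character(), source = character(),
                             stringsAsFactors = FALSE)
  class(env) <- "score_store"
  env
}

#' @export
print.score_store <- function(x, ...) {
  cat(sprintf("score_store: %d records, %d dataset(s)\n",
              nrow(x$dt), nrow(x$manifest)))
  if (nrow(x$manifest)) print(x$manifest)
  invisible(x)
}

register_dataset <- function(store, method, species, condition, source) {
  key <- paste(method, species, condition)
  if (key %in% paste(store$manifest$method, store$manifest$species,
                     store$manifest$condition))
    stop("dataset already loaded: method=", method, " species=", species,
         " condition=", condition)
  store$manifest <- rbind(store$manifest, data.frame(
    method = method, species = species, condition = condition,
    source = source, stringsAsFactors = FALSE))
}

insert_records <- function(store, recs, source) {
  dup <- duplicated(recs[, c("chrom", "pos0", "strand")])
  if (any(dup)) {
    i <- which(dup)[1L]
    stop("duplicate position in ", source, ": line ", recs$line[i], " (",
         recs$chrom[i], ":", recs$pos0[i], recs$strand[i], ")")
  }
  add <- data.table::data.table(
    chrom = recs$chrom, pos0 = recs$pos0, strand = recs$strand,
    method = recs$method, score = recs$score)
  store$dt <- data.table::rbindlist(list(store$dt, add))
  data.table::setkeyv(store$dt, c("method", "chrom", "strand", "pos0"))
  invisible(store)
}

#' Load a score TSV or bedGraph file into a store
#'
#' Accepts the package's five-column score TSV (see [write_score_tsv()]) or
#' a bedGraph file. bedGraph carries no strand or method, so both must then
#' be supplied. Each loaded file is one dataset; duplicate positions within
#' a dataset are an error naming the offending line.
#'
#' @param store a [score_store()].
#' @param path score TSV or bedGraph file.
#' @param method method tag; required for bedGraph, validated against the
#'   file's method column for TSV (`NULL` = accept the file's tags).
#' @param species,condition manifest annotations (e.g. `"human"`,
#'   `"in_vitro"`).
#' @param strand strand for bedGraph input.
#' @return The store, invisibly.
#' @export
load_scores <- function(store, path, method = NULL, species = NA_character_,
                        condition = NA_character_, strand = "+") {
  stopifnot(inherits(store, "score_store"))
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE)) {
    if (is.null(method)) stop("bedGraph input requires an explicit method")
    method <- match.arg(method, score_methods())
    gr <- rtracklayer::import(path, format = "bedGraph")
    recs <- data.frame(
      chrom = rep(as.character(GenomicRanges::seqnames(gr)),
                  GenomicRanges::width(gr)),
      pos0 = unlist(lapply(seq_along(gr), function(i) {
        seq(GenomicRanges::start(gr)[i] - 1L, GenomicRanges::end(gr)[i] - 1L)
      }), use.names = FALSE),
      strand = strand,
      method = method,
      score = rep(gr$score, GenomicRanges::width(gr)),
      line = NA_integer_,
      stringsAsFactors = FALSE)
    if (length(recs$pos0) == 0L) recs$pos0 <- integer(0)
  } else {
    lines <- readLines(path)
    body_idx <- which(!startsWith(lines, "#") & nzchar(lines))
    parts <- strsplit(lines[body_idx], "\t", fixed = TRUE)
    nfield <- lengths(parts)
    if (any(nfield != 5L)) {
      bad <- body_idx[which(nfield != 5L)[1L]]
      stop("malformed score line ", bad, " in ", path,
           ": expected 5 tab-separated fields")
    }
    mat <- matrix(unlist(parts), ncol = 5L, byrow = TRUE)
    pos0 <- suppressWarnings(as.integer(mat[, 2L]))
    sc <- suppressWarnings(as.numeric(mat[, 5L]))
    bad <- which(is.na(pos0) | is.na(sc) | !mat[, 3L] %in% c("+", "-"))
    if (length(bad))
      stop("malformed score line ", body_idx[bad[1L]], " in ", path)
    recs <- data.frame(chrom = mat[, 1L], pos0 = pos0, strand = mat[, 3L],
                       method = mat[, 4L], score = sc, line = body_idx,
                       stringsAsFactors = FALSE)
    if (!is.null(method)) {
      method <- match.arg(method, score_methods())
      if (nrow(recs) && !all(recs$method == method))
        stop("file contains method tags other than '", method, "'")
    }
    ftags <- unique(recs$method)
    if (length(setdiff(ftags, score_methods())))
      stop("unknown method tag(s): ",
           paste(setdiff(ftags, score_methods()), collapse = ", "))
    if (is.null(method)) method <- paste(sort(ftags), collapse = "+")
  }
  register_dataset(store, method, species, condition, path)
  insert_records(store, recs, path)
  invisible(store)
}

#' Add an in-memory score track to a store
#'
#' Tracks carrying the same method/species/condition triple (e.g. the two
#' strands of one experiment) accumulate into a single in-memory dataset;
#' colliding positions within that dataset are an error.
#'
#' @param store a [score_store()].
#' @param track a [score_track()]; only its non-`NA` positions are stored.
#' @param species,condition manifest annotations.
#' @return The store, invisibly.
#' @export
add_scores <- function(store, track, species = NA_character_,
                       condition = NA_character_) {
  stopifnot(inherits(store, "score_store"), inherits(track, "score_track"))
  keep <- which(!is.na(track$scores))
  recs <- data.frame(
    chrom = track$chrom, pos0 = keep - 1L, strand = track$strand,
    method = track$method, score = track$scores[keep],
    line = NA_integer_, stringsAsFactors = FALSE)
  m <- store$manifest
  open <- which(m$method == track$method &
                  (m$species %in% species) & (m$condition %in% condition) &
                  m$source == "<memory>")
  if (length(open) == 0L) {
    register_dataset(store, track$method, species, condition, "<memory>")
  } else {
    clash <- store$dt[list(track$method, track$chrom, track$strand),
                      nomatch = NULL]
    if (nrow(clash) && any((recs$pos0) %in% clash$pos0))
      stop("duplicate position in <memory>: ", track$chrom, ":",
           recs$pos0[recs$pos0 %in% clash$pos0][1L], track$strand)
  }
  insert_records(store, recs, "<memory>")
  invisible(store)
}

#' Query a store by genomic interval
#'
#' Returns, for each requested method and strand, the dense score vector
#' over the half-open interval `[start, end)`: element `k` holds the score
#' at position `start + k - 1`, `NA` where the store has none. Querying a
#' chromosome the store has never seen is not an error — many regions of
#' real transcriptomes simply have no scores — but it raises a warning.
#'
#' @param store a [score_store()].
#' @param interval a [genomic_interval()] (or region string parseable by
#'   [parse_region()]). Strand `"."` queries both strands.
#' @param methods method tags to query; default all methods in the store.
#' @return A list of class `interval_scores`: one element per method, each a
#'   list keyed by strand of numeric score vectors of length
#'   `end - start`. Minus-strand vectors are in genomic (left-to-right)
#'   order; use [extract_oriented_profile()] for transcript orientation.
#' @export
query_interval <- function(store, interval, methods = NULL) {
  stopifnot(inherits(store, "score_store"))
  if (is.character(interval)) interval <- parse_region(interval)
  stopifnot(inherits(interval, "genomic_interval"))
  if (is.null(methods)) {
    methods <- unique(store$dt$method)
    if (length(methods) == 0L) methods <- character(0)
  } else {
    methods <- vapply(methods, match.arg, "", choices = score_methods())
  }
  strands <- if (interval$strand == ".") c("+", "-") else interval$strand
  width <- interval$end - interval$start
  known <- interval$chrom %in% unique(store$dt$chrom)
  if (!known)
    warning("chromosome '", interval$chrom, "' has no scores in the store")
  out <- lapply(methods, function(m) {
    per_strand <- lapply(strands, function(s) {
      v <- rep(NA_real_, width)
      hit <- store$dt[
        list(m, interval$chrom, s),
        nomatch = NULL][pos0 >= interval$start & pos0 < interval$end]
      if (nrow(hit)) v[hit$pos0 - interval$start + 1L] <- hit$score
      v
    })
    names(per_strand) <- strands
    per_strand
  })
  names(out) <- methods
  structure(out, interval = interval, class = "interval_scores")
}

#' Export a store's records as score TSV
#'
#' Writes every record (optionally restricted to some methods) in canonical
#' order — method, chromosome, strand, position — in the same format
#' [write_score_tsv()] produces, so a load/export cycle reproduces a
#' canonically ordered input file byte for byte.
#'
#' @param store a [score_store()].
#' @param path output file.
#' @param methods optional subset of method tags.
#' @return `path`, invisibly.
#' @export
export_scores <- function(store, path, methods = NULL) {
  stopifnot(inherits(store, "score_store"))
  dt <- store$dt
  if (!is.null(methods)) dt <- dt[dt$method %in% methods]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# structscore score_tsv v1",
               "# columns: chrom pos0 strand method score"), con)
  if (nrow(dt))
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s",
                       dt$chrom, dt$pos0, dt$strand, dt$method,
                       format(dt$score, digits = 15, trim = TRUE,
                              scientific = FALSE)), con)
  invisible(path)
}
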