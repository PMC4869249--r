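#' Construct a score track
#'
#' Per-position real-valued structure scores for one method on one strand of
#' one reference sequence. Positions the method cannot score are `NA`
#' (explicit missing), never 0: a zero is a real score.
#'
#' @param chrom reference sequence name.
#' @param strand `"+"` or `"-"`.
#' @param method one of `"pars"`, `"dms"`, `"icshape_invitro"`,
#'   `"icshape_invivo"`, `"dsss"`.
#' @param scores numeric vector, `NA` where unscored; `scores[i]` belongs to
#'   0-based position `i - 1`.
#' @return An object of class `score_track`.
#' @export
score_track <- function(chrom, strand, method, scores) {
  method <- match.arg(method, score_methods())
  stopifnot(strand %in% c("+", "-"))
  structure(
    list(chrom = as.character(chrom), strand = strand,
         method = method, scores = as.numeric(scores)),
    class = "score_track"
  )
}

#' Method tags understood by the score store and display layer
#' @return Character vector of the recognized method tags.
#' @export
score_methods <- function() {
  c("pars", "dms", "icshape_invitro", "icshape_invivo", "dsss")
}

#' @export
print.score_track <- function(x, ...) {
  cat(sprintf("score_track %s(%s) method=%s length=%d scored=%d\n",
              x$chrom, x$strand, x$method, length(x$scores),
              sum(!is.na(x$scores))))
  invisible(x)
}

#' @export
length.score_track <- function(x) length(x$scores)

track_meta <- function(x, default_chrom = "track", default_strand = "+") {
  if (inherits(x, "coverage_track")) list(chrom = x$chrom, strand = x$strand)
  else list(chrom = default_chrom, strand = default_strand)
}

check_aligned <- function(a, b, what) {
  if (length(as_counts(a)) != length(as_counts(b)))
    stop(what, " tracks must cover the same positions (lengths ",
         length(as_counts(a)), " vs ", length(as_counts(b)), ")")
}

#' DMS-seq reactivity
#'
#' DMS labels unpaired A/C nucleotides and stalls reverse transcriptase, so
#' 5' read ends pile up one base downstream of reactive positions. Because
#' RT also stalls for reasons unrelated to DMS, the native-structure signal
#' is expressed relative to a denatured control in which every base is
#' accessible:
#'
#' \deqn{R_i = \frac{D_i / D_{max}}{C_i / C_{max}}}
#'
#' where \eqn{D_i}, \eqn{C_i} are the 5'-end counts at position \eqn{i} in
#' the treated and denatured libraries and \eqn{D_{max}}, \eqn{C_{max}}
#' their maxima over the normalization scope. High reactivity indicates an
#' unpaired nucleotide.
#'
#' @param D treated (native) 5'-end [coverage_track()] or count vector.
#' @param C denatured-control 5'-end [coverage_track()] or count vector.
#' @param scope `"per-region"` (default): maxima taken over the supplied
#'   tracks themselves; `"global"`: maxima supplied via `D_max`/`C_max`,
#'   e.g. library-wide maxima, which lets rRNA-scale outliers dominate.
#' @param D_max,C_max explicit maxima for `scope = "global"`.
#' @return A [score_track()] with `method = "dms"`; positions with
#'   \eqn{C_i = 0} are `NA` (the ratio is undefined there).
#' @examples
#' dms_reactivity(c(10, 0, 5), c(5, 5, 5))$scores  # 1.0 0.0 0.5
#' @export
dms_reactivity <- function(D, C, scope = c("per-region", "global"),
                           D_max = NULL, C_max = NULL) {
  scope <- match.arg(scope)
  check_aligned(D, C, "DMS")
  meta <- track_meta(D)
  d <- as_counts(D)
  cc <- as_counts(C)
  if (scope == "per-region") {
    D_max <- max(d)
    C_max <- max(cc)
  } else if (is.null(D_max) || is.null(C_max)) {
    stop("scope = \"global\" requires explicit D_max and C_max")
  }
  if (D_max <= 0 || C_max <= 0)
    stop("unscoreable scope: D_max and C_max must both be positive")
  r <- (d / D_max) / (cc / C_max)
  r[cc == 0] <- NA_real_
  score_track(meta$chrom, meta$strand, "dms", r)
}

#' icSHAPE reactivity
#'
#' icSHAPE acylates the 2'-hydroxyl of unpaired nucleotides with a
#' biotin-tagged reagent; RT stops at modified bases give 5' read ends. The
#' treated 5'-end counts are background-subtracted against a DMSO (solvent
#' only) control and scaled by the control's base density:
#'
#' \deqn{R_i = (D_i - C_i) / B_i}
#'
#' where \eqn{B_i} is the sequencing depth (full-read coverage) of base
#' \eqn{i} in the DMSO library. High reactivity indicates an unpaired
#' nucleotide. Negative values (control exceeding treatment) are retained by
#' default so that display inversion loses no information.
#'
#' @param D treated 5'-end [coverage_track()] or count vector.
#' @param C DMSO-control 5'-end [coverage_track()] or count vector.
#' @param B DMSO-library base density: full-read [coverage_track()] or
#'   vector; positions with \eqn{B_i = 0} are unscoreable (`NA`).
#' @param condition `"in_vitro"` or `"in_vivo"`, selecting the method tag.
#' @param floor_at_zero clip negative reactivities to 0 (off by default).
#' @return A [score_track()] with method `"icshape_invitro"` or
#'   `"icshape_invivo"`.
#' @examples
#' icshape_reactivity(10, 4, 2)$scores  # 3
#' @export
icshape_reactivity <- function(D, C, B,
                               condition = c("in_vitro", "in_vivo"),
                               floor_at_zero = FALSE) {
  condition <- match.arg(condition)
  check_aligned(D, C, "icSHAPE")
  check_aligned(D, B, "icSHAPE")
  meta <- track_meta(D)
  d <- as_counts(D)
  cc <- as_counts(C)
  b <- as_counts(B)
  if (any(b < 0)) stop("base density must be non-negative")
  r <- (d - cc) / b
  r[b == 0] <- NA_real_
  if (floor_at_zero) r <- pmax(r, 0)
  method <- if (condition == "in_vitro") "icshape_invitro" else "icshape_invivo"
  score_track(meta$chrom, meta$strand, method, r)
}

#' PARS structure score
#'
#' PARS cleaves each RNA once with either RNase V1 (double-strand specific)
#' or RNase S1 (single-strand specific); each sequencing read's 5' end marks
#' one cleavage site. The score at position \eqn{i} is the generalized log
#' ratio of V1 over S1 5'-end counts summed over the surrounding window
#' (5 nt at the default halfwidth of 2), with a pseudocount per position so
#' that positions cut in only one library remain scoreable:
#'
#' \deqn{S_i = \log_2\frac{\sum_{j \in W_i} V1_j + |W_i| c}
#'                        {\sum_{j \in W_i} S1_j + |W_i| c}}
#'
#' where \eqn{W_i} is the in-bounds part of \eqn{[i-2, i+2]} and \eqn{c} the
#' per-position pseudocount (default 1). Any common per-position divisor of
#' the two windowed sums cancels in the ratio. Windows at the track ends are
#' truncated to their in-bounds positions rather than dropped. Positions
#' whose window has no coverage in either library are `NA`. Positive scores
#' indicate pairing (V1 cleavage), negative unpaired (S1 cleavage).
#'
#' @param V1 dsRNase (V1) 5'-end [coverage_track()] or count vector.
#' @param S1 ssRNase (S1) 5'-end [coverage_track()] or count vector.
#' @param window_halfwidth window half-width in nt (default 2, i.e. a 5-nt
#'   window).
#' @param pseudocount per-position pseudocount \eqn{c > 0} (default 1).
#' @return A [score_track()] with `method = "pars"`.
#' @examples
#' v1 <- c(3, 3, 3, 3, 3); s1 <- c(1, 1, 1, 1, 1)
#' pars_score(v1, s1)$scores[3]  # log2(20/10) = 1
#' @export
pars_score <- function(V1, S1, window_halfwidth = 2L, pseudocount = 1) {
  stopifnot(window_halfwidth >= 0L, pseudocount > 0)
  check_aligned(V1, S1, "PARS")
  meta <- track_meta(V1)
  v <- as_counts(V1)
  s <- as_counts(S1)
  n <- length(v)
  h <- as.integer(window_halfwidth)
  # windowed sums with truncation at the ends, via cumulative sums
  cv <- cumsum(c(0, v))
  cs <- cumsum(c(0, s))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  wsize <- hi - lo + 1L
  wv <- cv[hi + 1L] - cv[lo]
  ws <- cs[hi + 1L] - cs[lo]
  sc <- log2((wv + wsize * pseudocount) / (ws + wsize * pseudocount))
  sc[wv == 0 & ws == 0] <- NA_real_
  score_track(meta$chrom, meta$strand, "pars", sc)
}

#' ds/ssRNA-seq structure score
#'
#' ds/ssRNA-seq digests one aliquot to completion with a single-strand
#' specific nuclease (RNaseONE; double-stranded regions survive) and the
#' other with the double-strand specific RNase V1 (single-stranded regions
#' survive), then sequences the protected fragments. Every aligned base of a
#' read is signal, so the inputs are full-read coverage tracks, compared
#' per position as a generalized log ratio:
#'
#' \deqn{S_i = \log_2\frac{ONE_i + 1}{V1_i + 1}}
#'
#' The pseudocount makes the score finite everywhere, so no position is
#' missing. Positive scores indicate pairing.
#'
#' @param ONE RNaseONE-treated full-read [coverage_track()] or count vector
#'   (double-strand-protected signal).
#' @param V1 RNase V1-treated full-read [coverage_track()] or count vector
#'   (single-strand-protected signal).
#' @param pseudocount additive pseudocount (default 1).
#' @return A [score_track()] with `method = "dsss"`.
#' @examples
#' dsss_score(7, 3)$scores   # log2(8/4) = 1
#' dsss_score(0, 15)$scores  # log2(1/16) = -4
#' @export
dsss_score <- function(ONE, V1, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  check_aligned(ONE, V1, "ds/ss")
  meta <- track_meta(ONE)
  a <- as_counts(ONE)
  b <- as_counts(V1)
  score_track(meta$chrom, meta$strand, "dsss",
              log2((a + pseudocount) / (b + pseudocount)))
}

#' Export a score track as score TSV
#'
#' Writes the package's five-column score format,
#' `chrom  pos0  strand  method  score`, one row per scored (non-`NA`)
#' position, with `#`-prefixed metadata headers. This is the interchange
#' format consumed by [load_scores()].
#'
#' @param track a [score_track()].
#' @param path output file; opened in append mode when `append = TRUE` so
#'   several tracks can share one file.
#' @param append append to an existing score TSV without repeating headers.
#' @return `path`, invisibly.
#' @export
write_score_tsv <- function(track, path, append = FALSE) {
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  if (!append) {
    writeLines(c("# structscore score_tsv v1",
                 "# columns: chrom pos0 strand method score"), con)
  }
  keep <- which(!is.na(track$scores))
  if (length(keep))
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s",
                       track$chrom, keep - 1L, track$strand, track$method,
                       format(track$scores[keep], digits = 15,
                              trim = TRUE, scientific = FALSE)), con)
  invisible(path)
}
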