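# Independent brute-force re-evaluations of each scoring formula and of
# coverage counting, kept deliberately naive (per-position loops) so they
# share no code with the package's vectorized implementations.

oracle_pars <- function(v1, s1, h = 2L, c = 1) {
  n <- length(v1)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    w <- max(1L, i - h):min(n, i + h)
    wv <- sum(v1[w])
    ws <- sum(s1[w])
    if (wv == 0 && ws == 0) next
    out[i] <- log2((wv + length(w) * c) / (ws + length(w) * c))
  }
  out
}

oracle_dms <- function(d, cc) {
  dmax <- max(d)
  cmax <- max(cc)
  out <- rep(NA_real_, length(d))
  for (i in seq_along(d)) {
    if (cc[i] == 0) next
    out[i] <- (d[i] / dmax) / (cc[i] / cmax)
  }
  out
}

oracle_icshape <- function(d, cc, b) {
  out <- rep(NA_real_, length(d))
  for (i in seq_along(d)) {
    if (b[i] == 0) next
    out[i] <- (d[i] - cc[i]) / b[i]
  }
  out
}

oracle_dsss <- function(one, v1) {
  out <- numeric(length(one))
  for (i in seq_along(one)) out[i] <- log2((one[i] + 1) / (v1[i] + 1))
  out
}

# naive per-read coverage counting
oracle_coverage <- function(records, chrom_length, mode) {
  counts <- list(`+` = integer(chrom_length), `-` = integer(chrom_length))
  for (i in seq_len(nrow(records))) {
    s <- records$strand[i]
    if (mode == "five_prime_end") {
      p <- if (s == "+") records$start[i] else records$end[i] - 1L
      counts[[s]][p + 1L] <- counts[[s]][p + 1L] + 1L
    } else {
      for (p in records$start[i]:(records$end[i] - 1L))
        counts[[s]][p + 1L] <- counts[[s]][p + 1L] + 1L
    }
  }
  counts
}

# random alignment records on one chromosome, no cigar
random_records <- function(n, chrom_length = 300L, read_length = 20L) {
  start <- sample.int(chrom_length - read_length, n, replace = TRUE) - 1L
  alignment_records(
    read_id = sprintf("r%03d", seq_len(n)), chrom = "chrT",
    start = start, end = start + read_length,
    strand = sample(c("+", "-"), n, replace = TRUE),
    mismatches = sample(0:4, n, replace = TRUE),
    n_hits = sample(1:7, n, replace = TRUE))
}

# a store preloaded with one plus-strand track of known scores
store_with_track <- function(scores, chrom = "chr1", strand = "+",
                             method = "pars") {
  st <- score_store()
  add_scores(st, score_track(chrom, strand, method, scores))
  st
}
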