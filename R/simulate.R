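# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Construct a base-pairing mask
#'
#' A structure mask records, per position, whether the nucleotide is base
#' paired. It is the ground truth the simulators encode and the scorers are
#' expected to recover.
#'
#' @param paired logical vector, `TRUE` = paired.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(paired) {
  paired <- as.logical(paired)
  if (length(paired) < 1L || anyNA(paired))
    stop("mask must be a logical vector of length >= 1 with no NA")
  structure(list(length = length(paired), paired = paired),
            class = "structure_mask")
}

#' A hairpin (stem-loop) mask
#'
#' The canonical test structure, shaped like an iron-response-element
#' stem-loop: a paired stem on both arms around an unpaired loop. The
#' default 15 + 5 + 15 layout gives a 35-nt hairpin.
#'
#' @param stem stem arm length in nt.
#' @param loop loop length in nt.
#' @return A [structure_mask()].
#' @export
hairpin_mask <- function(stem = 15L, loop = 5L) {
  stopifnot(stem >= 1L, loop >= 1L)
  structure_mask(c(rep(TRUE, stem), rep(FALSE, loop), rep(TRUE, stem)))
}

#' Simulate probing coverage tracks from a known structure
#'
#' Encodes the defining contract of each assay family: the probing signal
#' depends on base-pairing status. Counts are Poisson around a rate of
#' `depth` at baseline positions and `depth * unpaired_factor` at preferred
#' positions (unpaired for reactivity reagents, paired for the
#' double-strand nuclease). Control libraries are flat at `depth`. The
#' icSHAPE base-density track is flat at `10 * depth` full-read counts,
#' mimicking a well-covered transcript in the solvent-only control.
#'
#' * `dms_like`: treated (`D`) and denatured-control (`C`) 5'-end tracks;
#'   `D` elevated at unpaired positions.
#' * `icshape_like`: treated (`D`), DMSO-control (`C`) 5'-end tracks and
#'   DMSO base density (`B`, full-read); `D` elevated at unpaired.
#' * `pars_like`: `V1` 5'-end track elevated at paired, `S1` elevated at
#'   unpaired.
#' * `dsss_like`: `ONE` full-read track elevated over paired runs, `V1`
#'   over unpaired runs.
#'
#' @param mask a [structure_mask()].
#' @param assay one of `"dms_like"`, `"icshape_like"`, `"pars_like"`,
#'   `"dsss_like"`.
#' @param depth expected counts per baseline position (> 0).
#' @param unpaired_factor signal ratio of preferred over baseline positions
#'   (> 1; default 5).
#' @param seed RNG seed; the same seed always yields identical tracks.
#' @param chrom,strand coordinates to stamp on the tracks.
#' @return A named list of [coverage_track()]s matching the argument names
#'   of the corresponding scorer.
#' @export
simulate_probe_counts <- function(mask,
                                  assay = c("dms_like", "icshape_like",
                                            "pars_like", "dsss_like"),
                                  depth = 200, unpaired_factor = 5,
                                  seed = 1L, chrom = "sim", strand = "+") {
  assay <- match.arg(assay)
  stopifnot(inherits(mask, "structure_mask"), depth > 0, unpaired_factor > 1)
  up <- !mask$paired
  n <- mask$length
  rate_pref <- depth * unpaired_factor
  tr <- function(counts, mode) coverage_track(chrom, strand, counts, mode)
  with_seed(seed, {
    switch(assay,
      dms_like = list(
        D = tr(rpois(n, ifelse(up, rate_pref, depth)), "five_prime_end"),
        C = tr(rpois(n, depth), "five_prime_end")),
      icshape_like = list(
        D = tr(rpois(n, ifelse(up, rate_pref, depth)), "five_prime_end"),
        C = tr(rpois(n, depth), "five_prime_end"),
        B = tr(rpois(n, 10 * depth), "full_read")),
      pars_like = list(
        V1 = tr(rpois(n, ifelse(up, depth, rate_pref)), "five_prime_end"),
        S1 = tr(rpois(n, ifelse(up, rate_pref, depth)), "five_prime_end")),
      dsss_like = list(
        ONE = tr(rpois(n, ifelse(up, depth, rate_pref)), "full_read"),
        V1 = tr(rpois(n, ifelse(up, rate_pref, depth)), "full_read"))
    )
  })
}

#' Score simulated tracks with the matching scorer
#'
#' Convenience bridge from [simulate_probe_counts()] output to the
#' corresponding scoring function.
#'
#' @param tracks the list returned by [simulate_probe_counts()].
#' @param assay the assay the tracks were simulated for.
#' @return A [score_track()].
#' @export
score_simulated <- function(tracks, assay = c("dms_like", "icshape_like",
                                              "pars_like", "dsss_like")) {
  assay <- match.arg(assay)
  switch(assay,
    dms_like = dms_reactivity(tracks$D, tracks$C),
    icshape_like = icshape_reactivity(tracks$D, tracks$C, tracks$B),
    pars_like = pars_score(tracks$V1, tracks$S1),
    dsss_like = dsss_score(tracks$ONE, tracks$V1))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a SAM file with controlled filter-relevant tags
#'
#' Emits syntactically valid single-end SAM text whose `XM` (mismatches),
#' `NM` (edit distance) and `NH` (mapping locations) tags and strands are
#' under the caller's control, for exercising [read_alignments()] and
#' [filter_alignments()] without real data. Values are recycled across
#' reads.
#'
#' @param n_reads number of reads (0 gives a valid header-only file).
#' @param read_length read length in nt.
#' @param chrom_length reference length; read starts are drawn uniformly.
#' @param chrom reference name.
#' @param mismatches,edit_distance,n_hits integer vectors, recycled.
#' @param strands character vector of `"+"`/`"-"`, recycled; default
#'   alternating.
#' @param seed RNG seed.
#' @return Character vector of SAM lines; write with [write_sam()].
#' @export
simulate_alignments <- function(n_reads, read_length = 36L,
                                chrom_length = 1000L, chrom = "chrSim",
                                mismatches = 0L,
                                edit_distance = mismatches,
                                n_hits = 1L, strands = c("+", "-"),
                                seed = 1L) {
  stopifnot(n_reads >= 0L, read_length >= 1L,
            chrom_length >= read_length)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_length))
  if (n_reads == 0L) return(header)
  mm <- rep_len(as.integer(mismatches), n_reads)
  ed <- rep_len(as.integer(edit_distance), n_reads)
  nh <- rep_len(as.integer(n_hits), n_reads)
  st <- rep_len(strands, n_reads)
  with_seed(seed, {
    pos1 <- sample.int(chrom_length - read_length + 1L, n_reads,
                       replace = TRUE)
    seqs <- vapply(seq_len(n_reads), function(i) random_dna(read_length), "")
    body <- sprintf(
      "read%03d\t%d\t%s\t%d\t50\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d\tXM:i:%d\tNH:i:%d",
      seq_len(n_reads), ifelse(st == "+", 0L, 16L), chrom, pos1,
      read_length, seqs, strrep("I", read_length), ed, mm, nh)
    c(header, body)
  })
}

#' Write SAM lines to a file
#'
#' @param lines character vector from [simulate_alignments()].
#' @param path output path (should end in `.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(lines, path) {
  writeLines(lines, path)
  invisible(path)
}

#' Generate a toy genome with start-codon anchors
#'
#' Builds one random chromosome carrying `n_genes` genes on alternating
#' strands, plants a start codon at each gene's anchor (written `ATG` on
#' the plus strand and `CAT` in genomic orientation for minus-strand
#' genes), and returns the sequence together with the 3-nt codon anchor
#' regions — the standard input shape for codon meta-profiles.
#'
#' @param n_genes number of genes (>= 1); strands alternate `+`, `-`, ...
#' @param seed RNG seed.
#' @param gene_spacing genomic distance between consecutive anchors (nt);
#'   must leave room for flanking windows.
#' @return A list with `sequences` (a named `DNAStringSet` of length 1) and
#'   `anchors` (a [region_set()] of 3-nt codon intervals).
#' @export
make_toy_annotation <- function(n_genes, seed = 1L, gene_spacing = 60L) {
  stopifnot(n_genes >= 1L, gene_spacing >= 30L)
  chrom_length <- (n_genes + 1L) * gene_spacing
  with_seed(seed, {
    seq <- strsplit(random_dna(chrom_length), "")[[1L]]
    starts <- gene_spacing * seq_len(n_genes)  # 0-based anchor starts
    strands <- rep_len(c("+", "-"), n_genes)
    for (i in seq_len(n_genes)) {
      codon <- if (strands[i] == "+") c("A", "T", "G") else c("C", "A", "T")
      seq[(starts[i] + 1L):(starts[i] + 3L)] <- codon
    }
    sequences <- Biostrings::DNAStringSet(paste(seq, collapse = ""))
    names(sequences) <- "toy_chr"
    anchors <- region_set(data.frame(
      chrom = "toy_chr", start = starts, end = starts + 3L,
      strand = strands, stringsAsFactors = FALSE), label = "start_codons")
    list(sequences = sequences, anchors = anchors)
  })
}

#' Write a region set as BED6
#'
#' @param regions a [region_set()] or compatible `data.frame`.
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  if (inherits(regions, "region_set")) regions <- regions$regions
  writeLines(sprintf("%s\t%d\t%d\tregion%d\t0\t%s",
                     regions$chrom, regions$start, regions$end,
                     seq_len(nrow(regions)), regions$strand), path)
  invisible(path)
}
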