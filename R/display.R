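#' Scale and re-center a score segment
#'
#' The four assays produce scores on incomparable scales (log ratios,
#' normalized ratios, background-scaled differences), so for side-by-side
#' display each method's segment is z-transformed over its own non-missing
#' values: `(s - mean) / sd`, with the population (divide-by-n) standard
#' deviation. A constant segment maps to all zeros rather than dividing by
#' zero. Missing values stay missing. This is a display transform only; the
#' untransformed scores are always exported alongside (see
#' [render_profiles()]).
#'
#' @param x numeric vector with `NA` for missing positions.
#' @return Numeric vector of the same length.
#' @examples
#' standardize(c(1, 2, 3))     # -1.2247  0  1.2247
#' standardize(c(1, NA, 3))    # -1  NA  1
#' @export
standardize <- function(x) {
  x <- as.numeric(x)
  obs <- !is.na(x)
  if (!any(obs)) return(x)
  mu <- mean(x[obs])
  sigma <- sqrt(mean((x[obs] - mu)^2))
  out <- x
  out[obs] <- if (sigma == 0) 0 else (x[obs] - mu) / sigma
  out
}

#' Orient a score segment so that higher always means more paired
#'
#' PARS and ds/ssRNA-seq scores already measure degree of structure
#' (positive = paired). DMS-seq and icSHAPE measure nucleotide
#' *reactivity*, which is highest at unpaired bases, so those segments are
#' negated for display. After this transform the polarity contract "higher
#' = more evidence of pairing" holds for every method.
#'
#' @param x numeric vector with `NA` for missing positions.
#' @param method one of the tags in [score_methods()].
#' @return Numeric vector of the same length.
#' @examples
#' orient_polarity(c(0.5, -0.5), "icshape_invivo")  # -0.5  0.5
#' orient_polarity(c(1, -1), "pars")                #  1 -1
#' @export
orient_polarity <- function(x, method) {
  method <- match.arg(method, score_methods())
  if (method %in% c("dms", "icshape_invitro", "icshape_invivo")) -x
  else as.numeric(x)
}

#' Build a display track from raw scores
#'
#' Applies [orient_polarity()] then [standardize()], keeping the raw scores
#' attached for lossless export.
#'
#' @param scores numeric vector of raw scores (`NA` = missing).
#' @param method method tag.
#' @return An object of class `display_track` with fields `method`,
#'   `values` (harmonized) and `raw`.
#' @export
display_track <- function(scores, method) {
  method <- match.arg(method, score_methods())
  raw <- as.numeric(scores)
  structure(list(method = method,
                 values = standardize(orient_polarity(raw, method)),
                 raw = raw),
            class = "display_track")
}

#' Render harmonized profiles to SVG with a raw-score side file
#'
#' Draws one line per method over a shared x-axis (0-based offset) and
#' writes the *untransformed* scores to a TSV alongside, so nothing shown
#' is irrecoverable from the download. Tracks with no scored position at
#' all are omitted from the plot and flagged in the legend. Output is a
#' vector (SVG) image: deterministic for fixed input and diffable.
#'
#' @param tracks a [display_track()] or list of them, all the same length.
#' @param svg_path output SVG file.
#' @param tsv_path output TSV of raw scores (`offset  method  score`);
#'   `NULL` to skip.
#' @param main plot title.
#' @param annotations optional named list `list(label = c(from, to))` of
#'   0-based offset spans to shade (e.g. the codon inside a window).
#' @return Invisibly, a list with the paths written.
#' @export
render_profiles <- function(tracks, svg_path, tsv_path = NULL, main = "",
                            annotations = NULL) {
  if (inherits(tracks, "display_track")) tracks <- list(tracks)
  stopifnot(length(tracks) >= 1L,
            all(vapply(tracks, inherits, TRUE, "display_track")))
  L <- unique(vapply(tracks, function(t) length(t$values), 1L))
  if (length(L) != 1L)
    stop("all display tracks must have the same length; got ",
         paste(L, collapse = ", "))
  methods_all <- vapply(tracks, `[[`, "", "method")
  empty <- vapply(tracks, function(t) all(is.na(t$values)), TRUE)

  grDevices::svg(svg_path, width = 8, height = 4.5)
  on.exit(grDevices::dev.off(), add = TRUE)
  x <- seq_len(L) - 1L
  ylim <- range(unlist(lapply(tracks[!empty], `[[`, "values")),
                na.rm = TRUE, finite = TRUE)
  if (!any(!empty)) ylim <- c(-1, 1)
  graphics::plot(NA, xlim = c(0, L - 1L), ylim = ylim,
                 xlab = "offset (nt, 5' to 3')",
                 ylab = "harmonized score (higher = more paired)",
                 main = main, xaxt = "n")
  graphics::axis(1, at = pretty(x[x == round(x)]))
  if (!is.null(annotations)) {
    for (lab in names(annotations)) {
      span <- annotations[[lab]]
      graphics::rect(span[1L], ylim[1L], span[2L], ylim[2L],
                     col = grDevices::adjustcolor("grey", 0.3), border = NA)
      graphics::mtext(lab, at = mean(span), side = 3, cex = 0.7)
    }
  }
  palette <- c(pars = "#1b9e77", dms = "#d95f02", icshape_invitro = "#7570b3",
               icshape_invivo = "#e7298a", dsss = "#66a61e")
  for (i in which(!empty)) {
    graphics::lines(x, tracks[[i]]$values, col = palette[[methods_all[i]]],
                    lwd = 2)
  }
  legend_lab <- ifelse(empty, paste0(methods_all, " (no scores)"),
                       methods_all)
  graphics::legend("topright", legend = legend_lab,
                   col = palette[methods_all],
                   lwd = ifelse(empty, NA, 2), cex = 0.8, bty = "n")

  if (!is.null(tsv_path)) {
    rows <- do.call(rbind, lapply(tracks, function(t) {
      data.frame(offset = x, method = t$method, score = t$raw,
                 stringsAsFactors = FALSE)
    }))
    con <- file(tsv_path, "w")
    writeLines("offset\tmethod\tscore", con)
    writeLines(sprintf("%d\t%s\t%s", rows$offset, rows$method,
                       ifelse(is.na(rows$score), "NA",
                              format(rows$score, digits = 15, trim = TRUE,
                                     scientific = FALSE))), con)
    close(con)
  }
  invisible(list(svg = svg_path, tsv = tsv_path))
}

#' Read back a raw-score TSV written by [render_profiles()]
#'
#' @param path the TSV side file.
#' @return A `data.frame` with columns `offset`, `method`, `score`.
#' @export
read_raw_scores <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    na.strings = "NA", stringsAsFactors = FALSE)
}
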