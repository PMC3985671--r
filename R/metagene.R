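# Class-wise antisense metagene profiles: per-10-bp-bin median expression
# across the genes of a class, aligned to the TSS or the TTS, smoothed
# with a 150-bp moving average stepped every 10 bp.

# Centered moving average with shrinking windows at the edges; missing
# bins are skipped (the window mean renormalises over available bins) and
# a window with no data stays missing.
moving_average <- function(x, width_bins) {
  n <- length(x)
  half <- (width_bins - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- x[max(1L, i - half):min(n, i + half)]
    out[i] <- if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }
  out
}

#' Antisense metagene profile of a gene class
#'
#' For every bin (width `bin` bp, transcript orientation) of the span
#' around the anchor, takes the mean replicate signal on the antisense
#' strand per gene (sense strand if `orientation = "sense"`), then the
#' median across the genes of the class, and finally smooths the median
#' curve with a centered moving average (`smooth_window` bp wide, stepped
#' one bin at a time).
#'
#' @param tracks List of [signal_track()]s; all tracks with `condition ==
#'   condition` are averaged (typically the exosome-mutant replicates).
#' @param genes [gene_records()] rows of one class (non-empty).
#' @param condition Strain whose tracks are profiled.
#' @param anchor `"TSS"` or `"TTS"`.
#' @param span Offsets (bp, transcript orientation) covered by the
#'   profile.
#' @param bin Bin width in bp.
#' @param smooth_window Moving-average window in bp.
#' @param orientation `"antisense"` (default) or `"sense"`.
#' @return A list of class `metagene_profile` with `positions` (bin start
#'   offsets), `raw_median` and `smoothed`.
#' @export
antisense_metagene <- function(tracks, genes, condition = "rrp6",
                               anchor = c("TSS", "TTS"),
                               span = c(-500L, 1500L), bin = 10L,
                               smooth_window = 150L,
                               orientation = c("antisense", "sense")) {
  anchor <- match.arg(anchor)
  orientation <- match.arg(orientation)
  if (!nrow(genes)) stop("empty gene class")
  window <- genomic_window(anchor, span[1L], span[2L], orientation)
  cache <- new.env(parent = emptyenv())
  m <- condition_bin_matrix(tracks, condition, genes, window, bin, cache)
  raw <- apply(m, 2L, function(v) {
    if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)
  })
  offs <- window_bin_offsets(window, bin)
  width_bins <- max(1L, round(smooth_window / bin))
  structure(list(anchor = anchor, condition = condition,
                 positions = offs[-length(offs)],
                 raw_median = unname(raw),
                 smoothed = moving_average(unname(raw), width_bins),
                 n_genes = nrow(genes), bin = bin,
                 smooth_window = smooth_window),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("<metagene_profile: %d genes, %s-anchored, %d bins of %d bp>\n",
              x$n_genes, x$anchor, length(x$positions), x$bin))
  invisible(x)
}

#' Write a metagene profile as TSV (and optionally offset-anchored bedGraph)
#'
#' @param profile A `metagene_profile`.
#' @param path Output TSV path.
#' @param bedgraph Optional bedGraph path using offset coordinates on a
#'   pseudo-chromosome named after the anchor.
#' @export
write_metagene <- function(profile, path, bedgraph = NULL) {
  df <- data.frame(offset = profile$positions,
                   raw_median = profile$raw_median,
                   smoothed = profile$smoothed)
  write_table(df, path)
  if (!is.null(bedgraph)) {
    keep <- !is.na(profile$smoothed)
    writeLines(sprintf("%s\t%d\t%d\t%.6f", profile$anchor,
                       profile$positions[keep] - min(profile$positions),
                       profile$positions[keep] - min(profile$positions) +
                         profile$bin,
                       profile$smoothed[keep]), bedgraph)
  }
  invisible(path)
}
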