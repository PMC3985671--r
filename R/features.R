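# Binned differential-expression features: the per-gene input to the
# clustering.  Each (contrast, orientation) block is a genes x bins matrix
# of log2 ratios; blocks are concatenated into one feature matrix.

# Genomic bin edges (ascending) for a window tiled left-to-right in
# transcript orientation.  The final bin is truncated when the window
# length is not a multiple of `bin` (e.g. -100..+750 at 20 bp -> 43 bins,
# the last one 10 bp).
window_bin_offsets <- function(window, bin) {
  offs <- seq(window$offset_start, window$offset_end, by = bin)
  if (offs[length(offs)] < window$offset_end) {
    offs <- c(offs, window$offset_end)
  }
  offs
}

# Per-gene per-bin mean signal for one track.  Returns genes x bins matrix.
# Bins are ordered 5'->3' in transcript orientation.
track_bin_matrix <- function(track, genes, window, bin) {
  offs <- window_bin_offsets(window, bin)
  nb <- length(offs) - 1L
  out <- matrix(NA_real_, nrow(genes), nb,
                dimnames = list(genes$gene_id, NULL))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    anchor <- if (window$anchor == "TSS") g$tss else g$tts
    if (g$strand == "+") {
      edges <- anchor + offs
      strand <- if (window$target_strand == "sense") "+" else "-"
      out[i, ] <- region_bin_means(track, g$chrom, strand, edges)
    } else {
      edges <- anchor - rev(offs)  # ascending genomic coordinates
      strand <- if (window$target_strand == "sense") "-" else "+"
      out[i, ] <- rev(region_bin_means(track, g$chrom, strand, edges))
    }
  }
  out
}

# Mean across replicate tracks of one condition (NA-aware: a bin is
# missing only when it is missing in every replicate).
condition_bin_matrix <- function(tracks, condition, genes, window, bin,
                                 cache = NULL) {
  ckey <- paste(condition, window$anchor, window$offset_start,
                window$offset_end, window$target_strand, bin, sep = "|")
  if (!is.null(cache) && !is.null(cache[[ckey]])) return(cache[[ckey]])
  sel <- Filter(function(t) t$condition == condition, tracks)
  if (!length(sel)) stop("no tracks for condition ", condition)
  mats <- lapply(sel, track_bin_matrix, genes = genes, window = window,
                 bin = bin)
  tot <- Reduce(`+`, lapply(mats, function(m) ifelse(is.na(m), 0, m)))
  cnt <- Reduce(`+`, lapply(mats, function(m) !is.na(m)))
  res <- tot / cnt
  res[cnt == 0L] <- NA_real_
  if (!is.null(cache)) cache[[ckey]] <- res
  res
}

#' Binned differential expression for one contrast and orientation
#'
#' For each gene and each bin of the window, the differential expression
#' is the mean-over-replicates log2 signal of the numerator condition
#' minus that of the denominator condition (replicates are averaged before
#' differencing).  A bin is missing when it is missing in either
#' condition.
#'
#' @param tracks List of [signal_track()]s covering both conditions.
#' @param genes A [gene_records()] data frame.
#' @param contr A [contrast()].
#' @param window A [genomic_window()]; its `target_strand` defines the
#'   orientation of the block.
#' @param bin Bin width in bp.
#' @param cache Optional environment memoising per-condition bin matrices
#'   across calls (used when building all blocks of a feature matrix).
#' @return A list of class `binned_de` with the contrast, orientation,
#'   `bin_offsets` (transcript-coordinate bin edges) and a genes x bins
#'   `values` matrix of log2 ratios.
#' @export
bin_differential_expression <- function(tracks, genes, contr, window, bin,
                                        cache = NULL) {
  stopifnot(inherits(contr, "contrast"), inherits(window, "genomic_window"))
  num <- condition_bin_matrix(tracks, contr$numerator, genes, window, bin, cache)
  den <- condition_bin_matrix(tracks, contr$denominator, genes, window, bin, cache)
  structure(list(contrast = contr,
                 orientation = window$target_strand,
                 window = window,
                 bin_offsets = window_bin_offsets(window, bin),
                 values = num - den),
            class = "binned_de")
}

#' Assemble the clustering feature matrix
#'
#' Concatenates binned differential-expression blocks per gene.  Genes
#' missing more than `max_missing_fraction` of their entries are dropped;
#' remaining missing entries are imputed with 0 (no change).  Columns are
#' ordered block by block in the order given, bins 5' to 3'.
#'
#' @param blocks List of `binned_de` objects covering the same genes.
#' @param max_missing_fraction Missingness gate per gene.
#' @return A list of class `feature_matrix` with elements `x` (numeric
#'   matrix, genes in rows), `features` (data frame with `contrast`,
#'   `orientation`, `bin`), `imputed` (logical matrix marking imputed
#'   cells) and `dropped` (gene ids removed by the gate).
#' @export
build_feature_matrix <- function(blocks, max_missing_fraction = 0.2) {
  stopifnot(length(blocks) >= 1)
  ids <- rownames(blocks[[1L]]$values)
  for (b in blocks) {
    if (!identical(rownames(b$values), ids)) {
      common <- Reduce(intersect, lapply(blocks, function(b) rownames(b$values)))
      if (!length(common)) stop("blocks share no genes")
      blocks <- lapply(blocks, function(b) {
        b$values <- b$values[common, , drop = FALSE]; b
      })
      ids <- common
      break
    }
  }
  x <- do.call(cbind, lapply(blocks, `[[`, "values"))
  info <- do.call(rbind, lapply(blocks, function(b) {
    nb <- ncol(b$values)
    data.frame(contrast = b$contrast$label, orientation = b$orientation,
               bin = seq_len(nb), stringsAsFactors = FALSE)
  }))
  colnames(x) <- sprintf("%s|%s|bin%02d", info$contrast, info$orientation,
                         info$bin)
  miss <- is.na(x)
  frac <- rowMeans(miss)
  drop <- frac > max_missing_fraction
  if (any(drop)) {
    message(sum(drop), " gene(s) dropped for > ",
            round(100 * max_missing_fraction), "% missing feature bins")
  }
  x <- x[!drop, , drop = FALSE]
  miss <- miss[!drop, , drop = FALSE]
  x[miss] <- 0
  structure(list(x = x, features = info, imputed = miss,
                 dropped = ids[drop]),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d genes x %d features (%d blocks), %d dropped>\n",
              nrow(x$x), ncol(x$x),
              length(unique(paste(x$features$contrast, x$features$orientation))),
              length(x$dropped)))
  invisible(x)
}

#' Write a feature matrix (or one block) as TSV
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(gene_id = rownames(fm$x), fm$x, check.names = FALSE)
  write_table(df, path)
}

#' RNA half-life from a decay series
#'
#' Fits ordinary least squares to `ln(level)` versus time for
#' control-normalised abundances and reports the first-order rate constant
#' `k = -slope` and the half-life `t1/2 = coefficient / k` (coefficient
#' 0.693).  A non-positive `k` (no decay) yields an infinite half-life.
#'
#' @param timepoints Minutes, strictly increasing, starting at 0.
#' @param levels Normalised abundances (unitless ratios to a stable
#'   control RNA); must be positive.
#' @param gene_id Optional identifier carried through.
#' @param coefficient Numerator of the half-life formula.
#' @return A list of class `decay_fit` with `gene_id`, `timepoints`,
#'   `levels`, `k` (per minute) and `t_half` (minutes).
#' @examples
#' # levels halving every 10 minutes
#' fit <- half_life(c(0, 10, 20, 30), 2^-(0:3 / 1))
#' fit$t_half
#' @export
half_life <- function(timepoints, levels, gene_id = NA_character_,
                      coefficient = 0.693) {
  stopifnot(length(timepoints) == length(levels), length(timepoints) >= 3)
  if (is.unsorted(timepoints, strictly = TRUE)) {
    stop("timepoints must be strictly increasing")
  }
  if (any(levels <= 0)) stop("levels must be positive (log undefined)")
  fit <- stats::lm(log(levels) ~ timepoints)
  k <- -unname(stats::coef(fit)[2L])
  if (k < 1e-12) k <- 0  # constant series leaves a ~1e-19 numerical slope
  t_half <- if (k <= 0) Inf else coefficient / k
  structure(list(gene_id = gene_id, timepoints = timepoints,
                 levels = levels, k = max(k, 0), t_half = t_half),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit%s: k = %.4g /min, t1/2 = %.4g min>\n",
              if (is.na(x$gene_id)) "" else paste0(" ", x$gene_id),
              x$k, x$t_half))
  invisible(x)
}

#' Half-lives for a table of decay series
#'
#' @param series Data frame with columns `gene_id`, `minutes`, `level`
#'   (the 3-column decay TSV layout).
#' @param coefficient Numerator of the half-life formula.
#' @return Data frame with one row per gene: `gene_id`, `k`, `t_half`.
#' @export
half_life_table <- function(series, coefficient = 0.693) {
  stopifnot(all(c("gene_id", "minutes", "level") %in% names(series)))
  do.call(rbind, lapply(split(series, series$gene_id), function(s) {
    s <- s[order(s$minutes), ]
    f <- half_life(s$minutes, s$level, s$gene_id[1L], coefficient)
    data.frame(gene_id = f$gene_id, k = f$k, t_half = f$t_half,
               stringsAsFactors = FALSE)
  }))
}
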