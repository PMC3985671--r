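#' Anchored genomic window
#'
#' A window is defined relative to a transcript anchor (TSS or TTS) with
#' offsets in transcript orientation: positive offsets point downstream,
#' i.e. in the direction of sense transcription, negative offsets upstream.
#' `target_strand` selects whether signal/sequence is taken from the gene's
#' own strand (`"sense"`) or the opposite strand (`"antisense"`).
#'
#' @param anchor `"TSS"` or `"TTS"`.
#' @param offset_start,offset_end Signed offsets in bp; `offset_start` must
#'   be strictly less than `offset_end`.
#' @param target_strand `"sense"` or `"antisense"`.
#' @return An object of class `genomic_window`.
#' @examples
#' genomic_window("TTS", -400, 0, "antisense")
#' @export
genomic_window <- function(anchor = c("TSS", "TTS"),
                           offset_start, offset_end,
                           target_strand = c("sense", "antisense")) {
  anchor <- match.arg(anchor)
  target_strand <- match.arg(target_strand)
  offset_start <- as.integer(offset_start)
  offset_end <- as.integer(offset_end)
  if (!is.finite(offset_start) || !is.finite(offset_end) ||
      offset_start >= offset_end) {
    stop("offset_start must be < offset_end")
  }
  structure(list(anchor = anchor, offset_start = offset_start,
                 offset_end = offset_end, target_strand = target_strand),
            class = "genomic_window")
}

#' @export
print.genomic_window <- function(x, ...) {
  cat(sprintf("<window %s %+d..%+d bp, %s strand>\n",
              x$anchor, x$offset_start, x$offset_end, x$target_strand))
  invisible(x)
}

#' Analysis configuration
#'
#' Bundles every fixed parameter of the classification pipeline.  Defaults
#' are the study's published values: sense differential expression is taken
#' from TSS -100..+750 bp, antisense from TTS -100..+750 bp on the opposite
#' strand, both in 20-bp bins; the base clustering uses 15 medoids; the
#' robustness procedure runs 120 clusterings (10..15 clusters, 20 each) on
#' 80% subsamples and keeps genes whose mean co-clustering frequency with
#' their cluster mates is at least 60%; CUTs are segments at least 2-fold up
#' in the exosome mutant; ncRNAs must be at least 200 bp; Nrd1/Nab3 motifs
#' are counted in TTS -400..0 on the antisense strand; half-lives use
#' t1/2 = 0.693/k.
#'
#' @param conditions Character vector of strain labels; the first must be
#'   the wild type and the second the exosome (rrp6) deletion, in the order
#'   WT, rrp6, set1rrp6, hda2rrp6, rpd3rrp6 by default.
#' @param sense_window,antisense_window [genomic_window()]s over which the
#'   sense/antisense differential-expression features are binned.
#' @param de_bin Feature bin width in bp.
#' @param profile_bin Metagene bin width in bp.
#' @param smooth_window,smooth_step Metagene moving-average window and step
#'   in bp.
#' @param k_main Number of medoids of the base clustering.
#' @param k_range Integer range of cluster numbers for the robustness runs.
#' @param runs_per_k Number of subsampled runs for each k.
#' @param subsample_fraction Fraction of genes drawn (without replacement)
#'   in each robustness run.
#' @param core_cutoff Minimum mean co-clustering frequency for a gene to
#'   enter the core set of its cluster.
#' @param fold_threshold Linear fold change defining CUTs and the
#'   silenced/overexpressed split.
#' @param min_ncrna_len Minimum ncRNA segment length in bp.
#' @param motif_window [genomic_window()] scanned for Nrd1/Nab3 motifs and
#'   summed for PAR-CLiP binding.
#' @param halflife_coefficient Numerator of the half-life formula.
#' @param class_epsilon Dead zone (log2 units) around zero for the class
#'   rules applied to cluster median summaries.
#' @param seg_min_level,seg_max_gap Segmentation threshold (log2 units) and
#'   maximum probe gap (bp) when extracting expressed segments.
#' @param max_missing_fraction Genes missing more than this fraction of
#'   feature bins are dropped before clustering.
#' @param seed Master seed for the subsampled robustness runs.
#' @return A list of class `asrna_config`.
#' @export
asrna_config <- function(conditions = c("WT", "rrp6", "set1rrp6",
                                        "hda2rrp6", "rpd3rrp6"),
                         sense_window = genomic_window("TSS", -100, 750, "sense"),
                         antisense_window = genomic_window("TTS", -100, 750, "antisense"),
                         de_bin = 20L,
                         profile_bin = 10L,
                         smooth_window = 150L,
                         smooth_step = 10L,
                         k_main = 15L,
                         k_range = 10:15,
                         runs_per_k = 20L,
                         subsample_fraction = 0.8,
                         core_cutoff = 0.60,
                         fold_threshold = 2.0,
                         min_ncrna_len = 200L,
                         motif_window = genomic_window("TTS", -400, 0, "antisense"),
                         halflife_coefficient = 0.693,
                         class_epsilon = 0.2,
                         seg_min_level = 6.0,
                         seg_max_gap = 50L,
                         max_missing_fraction = 0.2,
                         seed = 1L) {
  stopifnot(length(conditions) >= 2, !anyDuplicated(conditions))
  stopifnot(de_bin > 0, profile_bin > 0, smooth_window > 0, smooth_step > 0,
            k_main >= 1, all(k_range >= 1), runs_per_k >= 1,
            subsample_fraction > 0, subsample_fraction < 1,
            core_cutoff > 0, core_cutoff <= 1,
            fold_threshold > 1, min_ncrna_len > 0,
            class_epsilon >= 0,
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  # study design: exosome mutant vs WT first, then each double mutant vs it
  contrasts <- lapply(conditions[-1], function(cnd) {
    contrast(cnd, if (cnd == conditions[2L]) conditions[1L] else conditions[2L])
  })
  structure(list(conditions = conditions,
                 contrasts = contrasts,
                 sense_window = sense_window,
                 antisense_window = antisense_window,
                 de_bin = as.integer(de_bin),
                 profile_bin = as.integer(profile_bin),
                 smooth_window = as.integer(smooth_window),
                 smooth_step = as.integer(smooth_step),
                 k_main = as.integer(k_main),
                 k_range = as.integer(k_range),
                 runs_per_k = as.integer(runs_per_k),
                 subsample_fraction = subsample_fraction,
                 core_cutoff = core_cutoff,
                 fold_threshold = fold_threshold,
                 min_ncrna_len = as.integer(min_ncrna_len),
                 motif_window = motif_window,
                 halflife_coefficient = halflife_coefficient,
                 class_epsilon = class_epsilon,
                 seg_min_level = seg_min_level,
                 seg_max_gap = as.integer(seg_max_gap),
                 max_missing_fraction = max_missing_fraction,
                 seed = as.integer(seed)),
            class = "asrna_config")
}

#' Expression contrast between two strains
#'
#' @param numerator,denominator Condition (strain) labels; must differ.
#' @return A list of class `contrast` with a `label` of the form
#'   `"<numerator>_vs_<denominator>"`.
#' @export
contrast <- function(numerator, denominator) {
  stopifnot(is.character(numerator), is.character(denominator),
            length(numerator) == 1L, length(denominator) == 1L)
  if (numerator == denominator) stop("numerator and denominator must differ")
  structure(list(numerator = numerator, denominator = denominator,
                 label = paste0(numerator, "_vs_", denominator)),
            class = "contrast")
}

#' @export
print.contrast <- function(x, ...) {
  cat(sprintf("<contrast %s vs %s>\n", x$numerator, x$denominator))
  invisible(x)
}

#' @export
print.asrna_config <- function(x, ...) {
  cat("Antisense classification configuration\n")
  cat("  conditions:      ", paste(x$conditions, collapse = ", "), "\n")
  cat("  contrasts:       ", paste(vapply(x$contrasts, `[[`, "", "label"),
                                   collapse = ", "), "\n")
  cat(sprintf("  sense window:     %s %+d..%+d\n", x$sense_window$anchor,
              x$sense_window$offset_start, x$sense_window$offset_end))
  cat(sprintf("  antisense window: %s %+d..%+d (opposite strand)\n",
              x$antisense_window$anchor, x$antisense_window$offset_start,
              x$antisense_window$offset_end))
  cat(sprintf("  DE bin %d bp | k = %d | robustness %d runs (k %d..%d, %.0f%% subsample) | core >= %.0f%%\n",
              x$de_bin, x$k_main, length(x$k_range) * x$runs_per_k,
              min(x$k_range), max(x$k_range), 100 * x$subsample_fraction,
              100 * x$core_cutoff))
  invisible(x)
}
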