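# Nrd1/Nab3 termination-motif scanning and PAR-CLiP binding aggregation
# in the antisense-transcript 5' region (the last 400 bp of each gene,
# read on the antisense strand).

#' Count Nrd1/Nab3 motifs per gene
#'
#' Resolves the motif window for every gene, extracts the genomic
#' sequence, reverse-complements it when the resolved strand is `-`, and
#' scans 5' to 3' for the Nab3 consensus `TCTT` and the Nrd1 consensus
#' `GTA[AG]`.  Overlapping occurrences are counted; ambiguous bases never
#' match.  Windows reaching past a chromosome end are clipped and the
#' covered fraction recorded.
#'
#' @param sequences A [Biostrings::DNAStringSet] (genome), names matching
#'   `genes$chrom`.
#' @param genes A [gene_records()] data frame.
#' @param window A [genomic_window()]; default TTS -400..0 on the
#'   antisense strand.
#' @return Data frame with `gene_id`, `nab3_count`, `nrd1_count`,
#'   `coverage` (fraction of the window on-chromosome).
#' @export
count_motifs <- function(sequences, genes,
                         window = genomic_window("TTS", -400, 0, "antisense")) {
  stopifnot(methods::is(sequences, "DNAStringSet"))
  lens <- stats::setNames(Biostrings::width(sequences), names(sequences))
  if (!all(genes$chrom %in% names(lens))) {
    stop("genome does not cover chromosome(s): ",
         paste(setdiff(unique(genes$chrom), names(lens)), collapse = ", "))
  }
  span <- window$offset_end - window$offset_start
  res <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    w <- resolve_window(g, window, chrom_len = lens[[g$chrom]])
    if (w$end <= w$start) {
      return(data.frame(gene_id = g$gene_id, nab3_count = 0L,
                        nrd1_count = 0L, coverage = 0))
    }
    seq <- Biostrings::subseq(sequences[[w$chrom]], w$start + 1L, w$end)
    if (w$strand == "-") seq <- Biostrings::reverseComplement(seq)
    data.frame(gene_id = g$gene_id,
               nab3_count = Biostrings::countPattern("TCTT", seq),
               nrd1_count = Biostrings::countPattern("GTAA", seq) +
                 Biostrings::countPattern("GTAG", seq),
               coverage = (w$end - w$start) / span)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Aggregate PAR-CLiP binding in the antisense 5' region
#'
#' Sums the (linear, nonnegative) cross-link signal in the resolved window
#' on the antisense strand and normalises it by the linear-scale WT
#' expression of the same region, `2^mean(log2 WT signal)`.  Genes whose
#' WT expression is missing get a missing normalised score and are
#' reported.
#'
#' @param binding_track A [signal_track()] of nonnegative counts.
#' @param genes A [gene_records()] data frame.
#' @param wt_tracks List of WT [signal_track()]s (replicates averaged).
#' @param window A [genomic_window()]; default TTS -400..0 antisense.
#' @param wt_condition Condition label of the WT tracks.
#' @return Data frame with `gene_id`, `raw_sum`, `wt_expression` (linear)
#'   and `normalized`.
#' @export
aggregate_binding <- function(binding_track, genes, wt_tracks,
                              window = genomic_window("TTS", -400, 0, "antisense"),
                              wt_condition = "WT") {
  wt <- Filter(function(t) t$condition == wt_condition, wt_tracks)
  if (!length(wt)) stop("no WT tracks")
  res <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    w <- resolve_window(g, window)
    raw <- region_sum(binding_track, w$chrom, w$start, w$end, w$strand)
    if (is.na(raw)) raw <- 0
    log2wt <- mean(vapply(wt, region_signal, 0, chrom = w$chrom,
                          start = w$start, end = w$end, strand = w$strand),
                   na.rm = TRUE)
    wt_lin <- if (is.finite(log2wt)) 2^log2wt else NA_real_
    data.frame(gene_id = g$gene_id, raw_sum = raw, wt_expression = wt_lin,
               normalized = if (!is.na(wt_lin) && wt_lin > 0) raw / wt_lin
                            else NA_real_)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (anyNA(out$normalized)) {
    message(sum(is.na(out$normalized)),
            " gene(s) without WT expression in the binding window: excluded")
  }
  out
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Exact two-sided Mann-Whitney/Wilcoxon rank-sum p-value when the smaller
#' group has at most 8 values and there are no ties; otherwise the normal
#' approximation with tie and continuity correction.  Two identical
#' multisets give p = 1.
#'
#' @param values_a,values_b Numeric vectors (each non-empty).
#' @return List with `statistic` (Mann-Whitney U of the first group) and
#'   `p_value`.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
compare_groups <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  stopifnot(length(values_a) >= 1, length(values_b) >= 1)
  ties <- anyDuplicated(c(values_a, values_b)) > 0L
  if (length(unique(c(values_a, values_b))) == 1L) {
    # all values tied across both groups
    u <- length(values_a) * length(values_b) / 2
    return(list(statistic = u, p_value = 1.0))
  }
  exact <- min(length(values_a), length(values_b)) <= 8L && !ties
  ht <- stats::wilcox.test(values_a, values_b, exact = exact,
                           correct = TRUE)
  list(statistic = unname(ht$statistic), p_value = min(1, ht$p.value))
}
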