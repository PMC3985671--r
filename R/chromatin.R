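# H3K4me3 window scoring, quartile-stratified Set1-effect splits,
# promoter-feature enrichment, and ncRNA/CUT/SUT annotation.

#' Mean chromatin signal in an anchored window
#'
#' Chromatin marks are strandless: the window is resolved through the
#' gene's orientation (so "0..-300 of the TTS" lies inside the gene's 3'
#' end on either strand) but the track is read strand-agnostically from
#' its single stored strand (conventionally `"*"`).
#'
#' @param track A strandless [signal_track()] (e.g. an H3K4me3/H3
#'   log-ratio).
#' @param genes A [gene_records()] data frame.
#' @param window A [genomic_window()] (use `target_strand = "sense"`).
#' @return Named numeric vector of per-gene window means (`NA` when the
#'   window holds no probes).
#' @export
window_score <- function(track, genes, window) {
  strands <- unique(sub("^.*\\|", "", ls(track$data)))
  if (length(strands) != 1L) {
    stop("chromatin track must be stored on a single strand")
  }
  out <- vapply(seq_len(nrow(genes)), function(i) {
    w <- resolve_window(genes[i, ], window)
    region_signal(track, w$chrom, w$start, w$end, strands)
  }, 0)
  stats::setNames(out, genes$gene_id)
}

#' Promoter-feature enrichment per class
#'
#' For each class, builds the 2x2 table of (in class vs all other genes) x
#' (has feature vs not) and computes the two-sided Fisher exact p-value
#' (the sum of all tables with point probability at most the observed
#' one) and the sample odds ratio `(ad)/(bc)`.  A zero margin gives a
#' missing odds ratio and p = 1.
#'
#' @param assignment A `class_assignment` (or named factor/character of
#'   classes per gene).
#' @param feature Named logical vector per gene (e.g. has a TATA box, has
#'   a closed promoter).
#' @param feature_name Label carried into the result.
#' @param alpha Significance threshold for the star flag.
#' @return Data frame with one row per class: counts `a`..`d`,
#'   `odds_ratio`, `p_two_sided`, `starred`.
#' @export
promoter_enrichment <- function(assignment, feature,
                                feature_name = "feature", alpha = 0.05) {
  cls <- if (inherits(assignment, "class_assignment")) assignment$class
         else assignment
  ids <- intersect(names(cls), names(feature))
  if (!length(ids)) stop("no shared genes between assignment and feature")
  cls <- as.character(cls[ids])
  feat <- as.logical(feature[ids])
  res <- lapply(setdiff(unique(cls), NA), function(cl) {
    a <- sum(cls == cl & feat)      # in class, feature
    b <- sum(cls == cl & !feat)     # in class, no feature
    c_ <- sum(cls != cl & feat)     # out of class, feature
    d <- sum(cls != cl & !feat)
    tab <- matrix(c(a, b, c_, d), 2L, byrow = TRUE)
    zero_margin <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)
    p <- if (zero_margin) 1.0 else stats::fisher.test(tab)$p.value
    or <- if (b * c_ == 0) NA_real_ else (a * d) / (b * c_)
    data.frame(class = cl, feature = feature_name, a = a, b = b,
               c = c_, d = d, odds_ratio = or, p_two_sided = p,
               starred = p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$class), , drop = FALSE]
}

#' Read a promoter annotation table
#'
#' A TSV keyed by `gene_id` with logical `tata`, a promoter occupancy
#' category `occ` (open/closed/other) and an optional semicolon-separated
#' `tf_sites` column.
#'
#' @param path TSV path.
#' @return Data frame with at least `gene_id`, `tata`, `occ`.
#' @export
read_promoter_annotation <- function(path) {
  df <- read_table(path)
  stopifnot(all(c("gene_id", "tata", "occ") %in% names(df)))
  df$tata <- as.logical(df$tata)
  df
}

#' Quartile-stratified Set1-effect split
#'
#' Orders transcripts by expression level in the exosome mutant (ties
#' broken by stable id order), cuts them into four quartiles, and splits
#' each quartile into silenced (log2 differential expression at or below
#' `-log2(fold_threshold)` in the Set1 double mutant vs the exosome
#' mutant), overexpressed (at or above `+log2(fold_threshold)`) and not
#' affected.
#'
#' @param expr_rrp6 Named numeric vector of expression levels.
#' @param de_set1 Named numeric vector of log2 ratios on the same ids.
#' @param fold_threshold Linear fold-change threshold (default 2).
#' @return A list with `table` (quartile x group counts) and `groups`
#'   (data frame with `gene_id`, `quartile`, `group`).
#' @export
set1_effect_split <- function(expr_rrp6, de_set1, fold_threshold = 2.0) {
  ids <- intersect(names(expr_rrp6), names(de_set1))
  n <- length(ids)
  if (n < 4L) stop("need at least 4 transcripts")
  e <- expr_rrp6[ids]
  o <- ids[order(e, ids)]
  cuts <- floor(n * (1:3) / 4)
  quart <- findInterval(seq_len(n), c(cuts + 1L)) + 1L  # 1..4 by rank
  quart <- stats::setNames(quart[match(ids, o)], ids)
  thr <- log2(fold_threshold)
  de <- de_set1[ids]
  group <- ifelse(de <= -thr, "silenced",
                  ifelse(de >= thr, "overexpressed", "not_affected"))
  groups <- data.frame(gene_id = ids, quartile = unname(quart),
                       group = unname(group), stringsAsFactors = FALSE)
  tab <- table(quartile = groups$quartile,
               group = factor(groups$group,
                              c("silenced", "not_affected", "overexpressed")))
  list(table = tab, groups = groups)
}

#' Annotate ncRNA segments and redefine CUTs/SUTs
#'
#' Expressed segments overlapping (same strand, at least 1 bp) any
#' transcript of the known catalog are dropped; survivors shorter than
#' `min_len` bp are dropped; the remainder are scored with their mean WT
#' and exosome-mutant levels and categorised: CUT when the log2 mutant/WT
#' ratio is at least `log2(fold_threshold)`, otherwise SUT when detectable
#' in WT (mean WT level at or above `min_level`), otherwise ncRNA-other.
#'
#' @param segments Data frame with `chrom`, `start`, `end`, `strand` (from
#'   [segment_track()]).
#' @param known_catalog Data frame of annotated transcript intervals with
#'   the same columns.
#' @param wt_tracks,rrp6_tracks Lists of [signal_track()]s; replicates
#'   averaged per segment.
#' @param fold_threshold Linear fold change defining CUTs.
#' @param min_len Minimum ncRNA length in bp.
#' @param min_level WT detectability threshold (log2 units).
#' @return Data frame of class `ncrna_annotation` with coordinates,
#'   `mean_wt_level`, `mean_rrp6_level`, `log2_ratio`, `category`.
#' @export
annotate_ncrnas <- function(segments, known_catalog, wt_tracks, rrp6_tracks,
                            fold_threshold = 2.0, min_len = 200L,
                            min_level = 6.0) {
  if (!nrow(segments)) {
    return(structure(data.frame(), class = c("ncrna_annotation", "data.frame")))
  }
  drop <- logical(nrow(segments))
  if (nrow(known_catalog)) {
    for (key in unique(paste0(segments$chrom, "|", segments$strand))) {
      si <- which(paste0(segments$chrom, "|", segments$strand) == key)
      ki <- which(paste0(known_catalog$chrom, "|", known_catalog$strand) == key)
      if (!length(ki)) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(segments$start[si] + 1L, segments$end[si]),
        IRanges::IRanges(known_catalog$start[ki] + 1L, known_catalog$end[ki]),
        minoverlap = 1L)
      drop[si[unique(S4Vectors::queryHits(ov))]] <- TRUE
    }
  }
  seg <- segments[!drop & (segments$end - segments$start) >= min_len, ,
                  drop = FALSE]
  if (!nrow(seg)) {
    return(structure(data.frame(), class = c("ncrna_annotation", "data.frame")))
  }
  lvl <- function(tracks, s) {
    mean(vapply(tracks, region_signal, 0, chrom = s$chrom, start = s$start,
                end = s$end, strand = s$strand), na.rm = TRUE)
  }
  seg$id <- sprintf("ncRNA_%04d", seq_len(nrow(seg)))
  seg$mean_wt_level <- vapply(seq_len(nrow(seg)), function(i)
    lvl(wt_tracks, seg[i, ]), 0)
  seg$mean_rrp6_level <- vapply(seq_len(nrow(seg)), function(i)
    lvl(rrp6_tracks, seg[i, ]), 0)
  seg$log2_ratio <- seg$mean_rrp6_level - seg$mean_wt_level
  thr <- log2(fold_threshold)
  seg$category <- ifelse(seg$log2_ratio >= thr, "CUT",
                         ifelse(seg$mean_wt_level >= min_level, "SUT",
                                "ncRNA-other"))
  rownames(seg) <- NULL
  structure(seg[, c("id", "chrom", "start", "end", "strand",
                    "mean_wt_level", "mean_rrp6_level", "log2_ratio",
                    "category")],
            class = c("ncrna_annotation", "data.frame"))
}
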