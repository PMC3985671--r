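# Grouping of PAM clusters into silencing classes.  Cluster median
# profiles are summarised per (contrast, orientation); a small fixed rule
# set formalising the published class descriptions maps each cluster to
# Class I-IV or unclassified; gene labels are restricted to the
# robustness-filtered core sets.

#' Median profiles of the clusters
#'
#' For every cluster and every (contrast, orientation) block: the per-bin
#' median across member genes (`median_curve`) and a scalar summary
#' defined as the median over cluster genes of the gene's mean over its
#' non-imputed bins.
#'
#' @param features A `feature_matrix`.
#' @param clustering A `pam_fit` on the same genes.
#' @param clusters Optional subset of cluster indices (defaults to the
#'   non-empty clusters of the base solution).  Requesting an empty
#'   cluster is an error.
#' @return A list of class `cluster_profiles`; one element per cluster
#'   with `cluster`, `n`, `summary` (contrasts x orientations matrix) and
#'   `median_curve` (list of per-bin median vectors per block).
#' @export
cluster_profiles <- function(features, clustering, clusters = NULL) {
  x <- features$x
  imp <- features$imputed
  info <- features$features
  labels <- clustering$labels[rownames(x)]
  if (anyNA(labels)) stop("clustering does not cover all feature genes")
  if (is.null(clusters)) clusters <- sort(unique(unname(labels)))
  blocks <- unique(info[, c("contrast", "orientation")])
  contrasts <- unique(info$contrast)
  orientations <- unique(info$orientation)
  out <- lapply(clusters, function(cl) {
    mem <- names(labels)[labels == cl]
    if (!length(mem)) stop("cluster ", cl, " is empty")
    summary <- matrix(NA_real_, length(contrasts), length(orientations),
                      dimnames = list(contrasts, orientations))
    curves <- list()
    for (b in seq_len(nrow(blocks))) {
      cols <- which(info$contrast == blocks$contrast[b] &
                    info$orientation == blocks$orientation[b])
      sub <- x[mem, cols, drop = FALSE]
      subimp <- imp[mem, cols, drop = FALSE]
      curves[[paste0(blocks$contrast[b], "|", blocks$orientation[b])]] <-
        apply(sub, 2L, stats::median)
      vals <- sub
      vals[subimp] <- NA_real_
      gene_means <- rowMeans(vals, na.rm = TRUE)
      gene_means[!is.finite(gene_means)] <- NA_real_
      summary[blocks$contrast[b], blocks$orientation[b]] <-
        stats::median(gene_means, na.rm = TRUE)
    }
    list(cluster = cl, n = length(mem), summary = summary,
         median_curve = curves)
  })
  names(out) <- as.character(clusters)
  structure(out, class = "cluster_profiles",
            contrasts = contrasts, orientations = orientations)
}

#' Group clusters into silencing classes
#'
#' Applies, in order, the class rules to each cluster's summary matrix.
#' With `AS_rrp6`/`S_rrp6` the antisense/sense summaries of the exosome
#' mutant vs WT contrast and `S_set1`, `S_hda2`, `S_rpd3` the sense
#' summaries of the three double-mutant contrasts (contrast order as in
#' the configuration):
#'
#' * Class IV: all three double-mutant sense summaries above `epsilon`
#'   while the antisense response to the exosome mutant stays at or below
#'   `epsilon` (HDAC/HMT-repressed genes without a strong Rrp6-sensitive
#'   antisense);
#' * Class I: antisense up and sense down in the exosome mutant, sense
#'   de-repressed (above `epsilon`) in all three double mutants;
#' * Class II: antisense up and sense down in the exosome mutant, all
#'   three double-mutant sense summaries within the dead zone;
#' * Class III: antisense up in the exosome mutant with no sense effect;
#' * otherwise unclassified.  Clusters whose antisense is elevated only in
#'   a double-mutant contrast but not in the exosome mutant vs WT fall
#'   through to unclassified by construction.
#'
#' The dead zone `epsilon` (log2 units) replaces a strict sign test, which
#' would classify every cluster under noise.
#'
#' @param profiles A `cluster_profiles` list.
#' @param epsilon Dead-zone half-width in log2 units.
#' @return A list of class `class_assignment_rules` with `cluster_to_class`
#'   (named character vector) and `rule_trace` (data frame recording the
#'   summaries and the rule that fired for each cluster).
#' @export
assign_classes <- function(profiles, epsilon = 0.2) {
  stopifnot(inherits(profiles, "cluster_profiles"), epsilon >= 0)
  contrasts <- attr(profiles, "contrasts")
  if (length(contrasts) < 4L) stop("class rules need the four study contrasts")
  trace <- lapply(profiles, function(p) {
    s <- p$summary
    if (any(is.na(s[contrasts[1:4], c("sense", "antisense")]))) {
      stop("cluster ", p$cluster, ": missing summary value")
    }
    as_rrp6 <- s[contrasts[1L], "antisense"]
    s_rrp6 <- s[contrasts[1L], "sense"]
    s_dbl <- s[contrasts[2:4], "sense"]
    cls <- if (all(s_dbl > epsilon) && as_rrp6 <= epsilon) {
      "IV"
    } else if (as_rrp6 > epsilon && s_rrp6 < -epsilon && all(s_dbl > epsilon)) {
      "I"
    } else if (as_rrp6 > epsilon && s_rrp6 < -epsilon &&
               max(abs(s_dbl)) <= epsilon) {
      "II"
    } else if (as_rrp6 > epsilon && abs(s_rrp6) <= epsilon) {
      "III"
    } else {
      "unclassified"
    }
    data.frame(cluster = p$cluster, n = p$n, AS_rrp6 = as_rrp6,
               S_rrp6 = s_rrp6, S_dbl1 = s_dbl[1L], S_dbl2 = s_dbl[2L],
               S_dbl3 = s_dbl[3L], class = cls, stringsAsFactors = FALSE)
  })
  trace <- do.call(rbind, trace)
  rownames(trace) <- NULL
  structure(list(cluster_to_class = stats::setNames(trace$class,
                                                    trace$cluster),
                 rule_trace = trace, epsilon = epsilon),
            class = "class_assignment_rules")
}

#' Label genes by their cluster's class
#'
#' Core genes inherit the class of their base cluster; non-core genes are
#' unclassified.
#'
#' @param rules A `class_assignment_rules` (see [assign_classes()]).
#' @param clustering The base `pam_fit`.
#' @param core_flags Named logical vector from [select_core_genes()].
#' @return A list of class `class_assignment` with `class` (named factor
#'   over I, II, III, IV, unclassified), `counts`, `cluster_to_class` and
#'   `core`.
#' @export
label_genes <- function(rules, clustering, core_flags) {
  ids <- names(clustering$labels)
  stopifnot(all(ids %in% names(core_flags)))
  c2c <- rules$cluster_to_class
  cls <- c2c[as.character(clustering$labels[ids])]
  cls[is.na(cls)] <- "unclassified"
  cls[!core_flags[ids]] <- "unclassified"
  cls <- factor(unname(cls), levels = c("I", "II", "III", "IV", "unclassified"))
  names(cls) <- ids
  structure(list(class = cls, counts = table(cls),
                 cluster_to_class = c2c, core = core_flags[ids]),
            class = "class_assignment")
}

#' @export
print.class_assignment <- function(x, ...) {
  cat("Gene class assignment\n")
  print(x$counts)
  invisible(x)
}

class_levels <- c("I", "II", "III", "IV", "unclassified")
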