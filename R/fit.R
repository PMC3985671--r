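#' Classify genes by the behaviour of their Rrp6-sensitive antisense RNAs
#'
#' The central fitting function.  Starting from strand-specific log2
#' tiling tracks for the five strains (WT, the exosome mutant and the
#' three double mutants, in replicate) and an ORF annotation, it
#'
#' 1. excludes convergent overlapping gene pairs,
#' 2. computes binned differential expression for the four study
#'    contrasts, sense (TSS-anchored window) and antisense (TTS-anchored
#'    window on the opposite strand),
#' 3. concatenates the bins into a per-gene feature matrix,
#' 4. clusters genes by deterministic PAM with `k_main` medoids,
#' 5. measures cluster robustness by subsampled consensus clustering and
#'    selects the core genes of each cluster,
#' 6. summarises cluster median profiles, applies the class rules, and
#' 7. labels core genes with their cluster's class (everything else is
#'    unclassified).
#'
#' @param tracks List of [signal_track()]s (all strains, all replicates).
#' @param genes A [gene_records()] annotation.
#' @param config An [asrna_config()].
#' @return An object of class `asrna_fit`; see Details.  Key components:
#'   `assignment` (a `class_assignment`), `clustering` (`pam_fit`),
#'   `consensus`, `core`, `profiles`, `rules`, `features`, `excluded`
#'   (convergent genes) and `config`.
#' @seealso [generate_dataset()] for a synthetic study to run this on,
#'   [truth_compare()] for evaluating recovery of planted classes.
#' @export
asrna_classify <- function(tracks, genes, config = asrna_config()) {
  stopifnot(inherits(genes, "gene_records"), inherits(config, "asrna_config"))
  have <- unique(vapply(tracks, `[[`, "", "condition"))
  missing_cond <- setdiff(config$conditions, have)
  if (length(missing_cond)) {
    stop("no tracks for condition(s): ", paste(missing_cond, collapse = ", "))
  }
  filt <- exclude_convergent_overlapping(genes)
  cache <- new.env(parent = emptyenv())
  blocks <- list()
  for (ct in config$contrasts) {
    for (w in list(config$sense_window, config$antisense_window)) {
      blocks[[length(blocks) + 1L]] <-
        bin_differential_expression(tracks, filt$kept, ct, w,
                                    config$de_bin, cache = cache)
    }
  }
  fm <- build_feature_matrix(blocks, config$max_missing_fraction)
  dmat <- euclidean_distance_matrix(fm$x)
  base <- pam_cluster(fm, config$k_main, dist_matrix = dmat)
  cons <- consensus_robustness(fm, config$k_range, config$runs_per_k,
                               config$subsample_fraction, config$seed,
                               dist_matrix = dmat)
  core <- select_core_genes(cons, base, config$core_cutoff)
  prof <- cluster_profiles(fm, base)
  rules <- assign_classes(prof, config$class_epsilon)
  assignment <- label_genes(rules, base, core)
  structure(list(assignment = assignment,
                 clustering = base,
                 consensus = cons,
                 core = core,
                 profiles = prof,
                 rules = rules,
                 features = fm,
                 genes = filt$kept,
                 excluded = filt$excluded,
                 config = config,
                 call = match.call()),
            class = "asrna_fit")
}

#' @export
print.asrna_fit <- function(x, ...) {
  cat("Antisense-RNA gene classification\n")
  cat(sprintf("  %d genes clustered (k = %d), %d convergent genes excluded\n",
              nrow(x$features$x), x$clustering$k, nrow(x$excluded)))
  cat(sprintf("  %d/%d core genes (cutoff %.0f%%, %d consensus runs)\n",
              sum(x$core), length(x$core), 100 * x$config$core_cutoff,
              x$consensus$runs))
  cat("  class counts:\n")
  print(x$assignment$counts)
  invisible(x)
}

#' @export
summary.asrna_fit <- function(object, ...) {
  structure(list(counts = object$assignment$counts,
                 rule_trace = object$rules$rule_trace,
                 n_excluded = nrow(object$excluded),
                 n_core = sum(object$core),
                 n_genes = length(object$core),
                 config = object$config),
            class = "summary.asrna_fit")
}

#' @export
print.summary.asrna_fit <- function(x, ...) {
  cat("Antisense-RNA gene classification -- summary\n\n")
  cat("Class counts (core genes carry class labels):\n")
  print(x$counts)
  cat(sprintf("\n%d of %d genes are core; %d convergent genes were excluded.\n",
              x$n_core, x$n_genes, x$n_excluded))
  cat("\nCluster rule trace (median summaries, log2):\n")
  print(x$rule_trace, digits = 3)
  invisible(x)
}

#' @export
as.data.frame.asrna_fit <- function(x, ...) {
  ids <- names(x$assignment$class)
  data.frame(gene_id = ids,
             cluster = unname(x$clustering$labels[ids]),
             core = unname(x$core[ids]),
             score = unname(attr(x$core, "score")[ids]),
             class = unname(as.character(x$assignment$class)),
             stringsAsFactors = FALSE)
}

#' Plot cluster median antisense/sense responses
#'
#' One panel per (contrast, orientation) block showing the per-bin median
#' differential-expression curves of the clusters, coloured by assigned
#' class.
#'
#' @param x An `asrna_fit`.
#' @param blocks Which blocks to draw (indices into the block list).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.asrna_fit <- function(x, blocks = NULL, ...) {
  curves <- x$profiles[[1L]]$median_curve
  block_names <- names(curves)
  if (is.null(blocks)) blocks <- seq_along(block_names)
  cls_col <- c(I = "firebrick", II = "steelblue", III = "goldenrod",
               IV = "forestgreen", unclassified = "grey60")
  c2c <- x$rules$cluster_to_class
  old <- graphics::par(mfrow = c(ceiling(length(blocks) / 2), 2),
                       mar = c(3, 3, 2, 1), mgp = c(1.8, 0.5, 0))
  on.exit(graphics::par(old))
  for (b in blocks) {
    bn <- block_names[b]
    mat <- vapply(x$profiles, function(p) p$median_curve[[bn]],
                  numeric(length(curves[[bn]])))
    cols <- cls_col[c2c[names(x$profiles)]]
    graphics::matplot(mat, type = "l", lty = 1, col = cols,
                      xlab = "bin (5' to 3')", ylab = "median log2 ratio",
                      main = bn, ...)
    graphics::abline(h = 0, col = "grey80")
  }
  invisible(x)
}
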