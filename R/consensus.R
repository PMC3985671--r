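# Subsampled consensus clustering: the robustness procedure behind the
# core-gene selection.  120 additional clusterings (10..15 clusters, 20
# runs each) on random 80% subsamples; for every gene pair we count how
# often both were sampled and how often they landed in the same cluster.

#' Consensus robustness of the clustering
#'
#' For each k in `k_range` runs `runs_per_k` PAM clusterings on uniform
#' random subsamples (without replacement) of
#' `floor(subsample_fraction * n)` genes, and accumulates, for every gene
#' pair, how often both were sampled (`co_sampled`) and how often they
#' were assigned to the same cluster (`co_clustered`).  Run r draws its
#' subsample from a stream seeded deterministically from (`seed`, r), so
#' results replay exactly for a fixed master seed.
#'
#' @param features A `feature_matrix` or numeric matrix (genes in rows).
#' @param k_range Integer vector of cluster numbers.
#' @param runs_per_k Runs per value of k.
#' @param subsample_fraction Fraction of genes drawn per run.
#' @param seed Master seed.
#' @param dist_matrix Optional precomputed distance matrix (computed once
#'   here and subset per run otherwise).
#' @param keep_runs Store each run's subsample and cluster assignment in
#'   `run_assignments` (for auditing the pair counters).
#' @return A list of class `consensus_result` with `runs`, `gene_ids`,
#'   symmetric integer matrices `co_sampled` and `co_clustered`, and
#'   `run_info` (k and seed per run).  Pair frequencies are
#'   `co_clustered / co_sampled`, defined where `co_sampled > 0`.
#' @export
consensus_robustness <- function(features, k_range = 10:15, runs_per_k = 20L,
                                 subsample_fraction = 0.8, seed = 1L,
                                 dist_matrix = NULL, keep_runs = FALSE) {
  x <- if (inherits(features, "feature_matrix")) features$x else features
  ids <- rownames(x)
  n <- nrow(x)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  m <- floor(subsample_fraction * n)
  if (m < max(k_range)) stop("subsample smaller than max(k_range)")
  if (is.null(dist_matrix)) dist_matrix <- euclidean_distance_matrix(x)
  ks <- rep(as.integer(k_range), each = runs_per_k)
  runs <- length(ks)
  run_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, runs))
  co_sampled <- matrix(0L, n, n, dimnames = list(ids, ids))
  co_clustered <- matrix(0L, n, n, dimnames = list(ids, ids))
  run_assignments <- if (keep_runs) vector("list", runs) else NULL
  for (r in seq_len(runs)) {
    idx <- sort(withr::with_seed(run_seeds[r], sample.int(n, m)))
    fit <- .pam_dist_cpp(dist_matrix[idx, idx, drop = FALSE], ks[r])
    co_sampled[idx, idx] <- co_sampled[idx, idx] + 1L
    for (cl in seq_len(ks[r])) {
      mem <- idx[fit$labels == cl]
      if (length(mem)) {
        co_clustered[mem, mem] <- co_clustered[mem, mem] + 1L
      }
    }
    if (keep_runs) {
      run_assignments[[r]] <- list(idx = idx, labels = fit$labels)
    }
  }
  structure(list(runs = runs, gene_ids = ids, co_sampled = co_sampled,
                 co_clustered = co_clustered,
                 run_info = data.frame(run = seq_len(runs), k = ks,
                                       seed = run_seeds),
                 run_assignments = run_assignments),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result: %d genes, %d runs (k %s)>\n",
              length(x$gene_ids), x$runs,
              paste(range(x$run_info$k), collapse = "..")))
  invisible(x)
}

#' Pair co-clustering frequency
#'
#' @param consensus A `consensus_result`.
#' @return Symmetric matrix `co_clustered / co_sampled` with `NA` where a
#'   pair was never co-sampled.
#' @export
pair_frequency <- function(consensus) {
  f <- consensus$co_clustered / consensus$co_sampled
  f[consensus$co_sampled == 0L] <- NA_real_
  f
}

#' Select core genes of each cluster
#'
#' A gene's robustness score is the mean, over the other members of its
#' base cluster with which it was co-sampled at least once, of the pair
#' co-clustering frequency.  Core genes are those with score at or above
#' the cutoff.  Singleton clusters are core by convention; a gene never
#' co-sampled with any cluster mate is non-core (both are messaged).
#'
#' @param consensus A `consensus_result`.
#' @param base A `pam_fit` on the same genes (the base clustering whose
#'   clusters define the mates).
#' @param cutoff Minimum mean co-clustering frequency.
#' @return Named logical vector of core flags, with the per-gene scores in
#'   attribute `"score"`.
#' @export
select_core_genes <- function(consensus, base, cutoff = 0.60) {
  ids <- consensus$gene_ids
  stopifnot(setequal(ids, names(base$labels)))
  labels <- base$labels[ids]
  freq <- pair_frequency(consensus)
  score <- stats::setNames(rep(NA_real_, length(ids)), ids)
  core <- stats::setNames(logical(length(ids)), ids)
  for (cl in sort(unique(labels))) {
    mem <- ids[labels == cl]
    if (length(mem) == 1L) {
      message("singleton cluster ", cl, ": gene ", mem, " core by convention")
      core[mem] <- TRUE
      score[mem] <- 1
      next
    }
    f <- freq[mem, mem, drop = FALSE]
    diag(f) <- NA_real_
    s <- rowMeans(f, na.rm = TRUE)
    nocomate <- !is.finite(s)
    if (any(nocomate)) {
      message(sum(nocomate), " gene(s) in cluster ", cl,
              " never co-sampled with a cluster mate: non-core")
      s[nocomate] <- NA_real_
    }
    score[mem] <- s
    core[mem] <- !is.na(s) & s >= cutoff
  }
  attr(core, "score") <- score
  core
}
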