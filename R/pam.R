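# Deterministic partitioning around medoids (BUILD + steepest-descent
# SWAP) on Euclidean distances between feature rows.  The numerical core
# lives in src/pam.cpp; this file provides the user-facing wrapper and the
# distance helper shared with the consensus procedure.

# Squared-Euclidean via the Gram-matrix identity, symmetrised and clamped
# at zero before the square root.  Much faster than stats::dist for the
# ~2000 x 344 matrices this pipeline clusters, and deterministic.
euclidean_distance_matrix <- function(x) {
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(x)
  d2 <- (d2 + t(d2)) / 2
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  diag(d) <- 0
  d
}

#' PAM clustering of a feature matrix
#'
#' Classic partitioning around medoids with a deterministic BUILD phase
#' (greedy cost-minimising medoid addition, ties to the smallest index)
#' followed by exact steepest-descent SWAP (the best strictly
#' cost-decreasing medoid/non-medoid exchange is applied until none
#' exists).  Distances are Euclidean on the feature rows.  The result is a
#' deterministic function of the input; `seed` is accepted for interface
#' symmetry with the stochastic consensus procedure but unused.
#'
#' @param features A `feature_matrix` (see [build_feature_matrix()]) or a
#'   plain numeric matrix with genes in rows.
#' @param k Number of medoids.
#' @param seed Ignored (the algorithm is deterministic).
#' @param dist_matrix Optional precomputed symmetric distance matrix
#'   matching the rows of `features`.
#' @return A list of class `pam_fit`: `k`, `labels` (named cluster index
#'   per gene, clusters numbered by medoid build order), `medoid_ids`,
#'   `total_cost` (sum of distances to assigned medoids) and `cost_trace`
#'   (total cost after BUILD and after each accepted swap; non-increasing).
#' @export
pam_cluster <- function(features, k, seed = NULL, dist_matrix = NULL) {
  x <- if (inherits(features, "feature_matrix")) features$x else features
  stopifnot(is.matrix(x) || is.null(x))
  ids <- rownames(x)
  n <- if (is.null(dist_matrix)) nrow(x) else nrow(dist_matrix)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (k > n) stop("k (", k, ") exceeds number of genes (", n, ")")
  d <- if (is.null(dist_matrix)) euclidean_distance_matrix(x) else dist_matrix
  res <- .pam_dist_cpp(d, as.integer(k))
  labels <- res$labels
  names(labels) <- ids
  structure(list(k = as.integer(k), labels = labels,
                 medoid_ids = ids[res$medoids],
                 medoid_idx = res$medoids,
                 total_cost = res$cost,
                 cost_trace = res$cost_trace),
            class = "pam_fit")
}

#' @export
print.pam_fit <- function(x, ...) {
  cat(sprintf("<pam_fit: k = %d, n = %d, total cost %.4g (%d swap(s))>\n",
              x$k, length(x$labels), x$total_cost,
              length(x$cost_trace) - 1L))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Write a clustering as two-column TSV
#'
#' @param fit A `pam_fit`.
#' @param path Output path.
#' @export
write_clustering <- function(fit, path) {
  write_table(data.frame(gene_id = names(fit$labels),
                         cluster = unname(fit$labels)), path)
}
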