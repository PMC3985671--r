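two_blob_features <- function(n_per = 10, sep = 30) {
  x <- rbind(matrix(rnorm(n_per * 4, 0, 0.3), n_per, 4),
             matrix(rnorm(n_per * 4, sep, 0.3), n_per, 4))
  rownames(x) <- sprintf("g%02d", seq_len(2 * n_per))
  x
}

test_that("perfectly separated blobs always co-cluster within blob", {
  withr::local_seed(20)
  x <- two_blob_features()
  cons <- consensus_robustness(x, k_range = 2, runs_per_k = 15,
                               subsample_fraction = 0.8, seed = 1)
  f <- pair_frequency(cons)
  blob <- rep(1:2, each = 10)
  for (i in 1:19) for (j in (i + 1):20) {
    if (blob[i] == blob[j] && cons$co_sampled[i, j] > 0) {
      expect_equal(f[i, j], 1.0)
    }
  }
})

test_that("co-sampling counters match their binomial expectation and symmetry", {
  withr::local_seed(21)
  x <- matrix(rnorm(10 * 4), 10, 4, dimnames = list(letters[1:10], NULL))
  # 6 k values x 20 runs = 120 runs on subsamples of floor(0.8 * 10) = 8
  # (k must stay below the subsample size, so 2..7 rather than 10..15)
  cons <- consensus_robustness(x, k_range = 2:7, runs_per_k = 20,
                               subsample_fraction = 0.8, seed = 3)
  expect_equal(cons$runs, 120L)
  expect_identical(cons$co_sampled, t(cons$co_sampled))
  expect_identical(cons$co_clustered, t(cons$co_clustered))
  expect_true(all(cons$co_clustered <= cons$co_sampled))
  expect_true(all(cons$co_sampled <= cons$runs))
  # subsample size floor(0.8 * 10) = 8: E[co_sampled] = 120 * (8/10) * (7/9)
  p <- (8 / 10) * (7 / 9)
  expectation <- 120 * p
  sigma <- sqrt(120 * p * (1 - p))
  off <- cons$co_sampled[upper.tri(cons$co_sampled)]
  expect_lt(abs(mean(off) - expectation), 3 * sigma)
  expect_true(all(abs(off - expectation) < 5 * sigma))
})

test_that("pair counters equal a brute-force recount of the stored runs", {
  withr::local_seed(22)
  x <- matrix(rnorm(25 * 3), 25, 3, dimnames = list(sprintf("g%02d", 1:25), NULL))
  cons <- consensus_robustness(x, k_range = 3:4, runs_per_k = 6,
                               subsample_fraction = 0.8, seed = 5,
                               keep_runs = TRUE)
  n <- 25
  cs <- matrix(0L, n, n)
  cc <- matrix(0L, n, n)
  for (run in cons$run_assignments) {
    for (a in seq_along(run$idx)) for (b in seq_along(run$idx)) {
      i <- run$idx[a]; j <- run$idx[b]
      cs[i, j] <- cs[i, j] + 1L
      if (run$labels[a] == run$labels[b]) cc[i, j] <- cc[i, j] + 1L
    }
  }
  expect_equal(unname(cons$co_sampled), cs)
  expect_equal(unname(cons$co_clustered), cc)
})

test_that("a fixed master seed replays exactly", {
  withr::local_seed(23)
  x <- matrix(rnorm(12 * 3), 12, 3, dimnames = list(letters[1:12], NULL))
  c1 <- consensus_robustness(x, k_range = 2, runs_per_k = 1,
                             subsample_fraction = 0.8, seed = 99)
  c2 <- consensus_robustness(x, k_range = 2, runs_per_k = 1,
                             subsample_fraction = 0.8, seed = 99)
  expect_identical(c1$co_sampled, c2$co_sampled)
  expect_identical(c1$co_clustered, c2$co_clustered)
  c3 <- consensus_robustness(x, k_range = 2, runs_per_k = 1,
                             subsample_fraction = 0.8, seed = 100)
  expect_false(identical(c1$co_sampled, c3$co_sampled))
})

fabricate_consensus <- function(ids, co_sampled, co_clustered, runs = 10L) {
  dimnames(co_sampled) <- list(ids, ids)
  dimnames(co_clustered) <- list(ids, ids)
  structure(list(runs = runs, gene_ids = ids, co_sampled = co_sampled,
                 co_clustered = co_clustered),
            class = "consensus_result")
}

fabricate_base <- function(labels) {
  structure(list(k = max(labels), labels = labels,
                 medoid_ids = names(labels)[!duplicated(labels)]),
            class = "pam_fit")
}

test_that("core selection applies the inclusive 60% boundary", {
  ids <- c("a", "b", "c")
  base <- fabricate_base(stats::setNames(c(1L, 1L, 1L), ids))
  cs <- matrix(100L, 3, 3)
  # gene a: mean frequency with b and c = 0.59 -> non-core
  cc <- matrix(100L, 3, 3)
  cc[1, 2] <- cc[2, 1] <- 59L
  cc[1, 3] <- cc[3, 1] <- 59L
  core <- select_core_genes(fabricate_consensus(ids, cs, cc), base, 0.60)
  expect_false(core[["a"]])
  expect_true(core[["b"]])  # mean(1.0, 0.59) = 0.795
  # exactly at the boundary: >= keeps the gene
  cc[1, 2] <- cc[2, 1] <- 60L
  cc[1, 3] <- cc[3, 1] <- 60L
  core2 <- select_core_genes(fabricate_consensus(ids, cs, cc), base, 0.60)
  expect_true(core2[["a"]])
  # all frequencies 1 -> core
  core3 <- select_core_genes(fabricate_consensus(ids, cs, matrix(100L, 3, 3)),
                             base, 0.60)
  expect_true(all(core3))
})

test_that("core scores equal a brute-force pair average and are monotone in cutoff", {
  withr::local_seed(24)
  x <- rbind(matrix(rnorm(60 * 3, 0, 1.5), 60, 3),
             matrix(rnorm(60 * 3, 4, 1.5), 60, 3))
  rownames(x) <- sprintf("g%03d", 1:120)
  base <- pam_cluster(x, 2)
  cons <- consensus_robustness(x, k_range = 2:3, runs_per_k = 10,
                               subsample_fraction = 0.8, seed = 7)
  core <- select_core_genes(cons, base, 0.60)
  score <- attr(core, "score")
  freq <- pair_frequency(cons)
  for (g in sample(rownames(x), 50)) {
    mates <- setdiff(names(base$labels)[base$labels == base$labels[g]], g)
    vals <- freq[g, mates]
    vals <- vals[cons$co_sampled[g, mates] > 0]
    expect_equal(score[[g]], mean(vals))
  }
  # raising the cutoff never adds core genes; selection is idempotent
  core_hi <- select_core_genes(cons, base, 0.80)
  expect_true(all(names(which(core_hi)) %in% names(which(core))))
  expect_identical(select_core_genes(cons, base, 0.60), core)
})

test_that("singleton clusters are core by convention", {
  ids <- c("a", "b", "c")
  base <- fabricate_base(stats::setNames(c(1L, 2L, 2L), ids))
  cs <- matrix(10L, 3, 3); cc <- matrix(10L, 3, 3)
  expect_message(
    core <- select_core_genes(fabricate_consensus(ids, cs, cc), base, 0.6),
    "singleton")
  expect_true(core[["a"]])
})
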