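make_pair_tracks <- function(genes, shift = 0, len = 6000L, noise = NULL) {
  # denominator: flat 5.0 everywhere; numerator: 5.0 + shift
  pos <- seq(0, len - 1, by = 10)
  base <- if (is.null(noise)) rep(5, length(pos)) else 5 + noise
  list(make_dense_track2(pos, base + shift, "num", 1L),
       make_dense_track2(pos, base, "den", 1L))
}

make_dense_track2 <- function(pos, val, condition, replicate) {
  signal_track(paste0(condition, replicate), condition, replicate,
               chrom = rep("chrI", 2 * length(pos)),
               strand = rep(c("+", "-"), each = length(pos)),
               pos = rep(pos, 2), value = rep(val, 2))
}

test_that("identity and uniformly shifted contrasts give flat DE", {
  g <- one_gene("+", 1000L, 3000L)
  w <- genomic_window("TSS", -100, 750, "sense")
  tr <- make_pair_tracks(g, shift = 0)
  de0 <- bin_differential_expression(tr, g, contrast("num", "den"), w, 20L)
  expect_true(all(de0$values == 0))
  tr1 <- make_pair_tracks(g, shift = 1)
  de1 <- bin_differential_expression(tr1, g, contrast("num", "den"), w, 20L)
  expect_true(all(abs(de1$values - 1) < 1e-12))
})

test_that("the -100..+750 window at 20 bp yields 43 bins, last 10 bp", {
  w <- genomic_window("TSS", -100, 750, "sense")
  offs <- asRNAclass:::window_bin_offsets(w, 20L)
  expect_length(offs, 44L)
  expect_equal(offs[43:44], c(740L, 750L))
  expect_equal(diff(offs)[42:43], c(20L, 10L))
})

test_that("swapping the contrast negates every DE value", {
  withr::local_seed(5)
  g <- gene_records(c("a", "b"), "chrI", c(1000L, 3500L), c(2800L, 5200L),
                    c("+", "-"))
  pos <- seq(0, 5999, by = 10)
  tracks <- list(make_dense_track2(pos, rnorm(600, 6), "num", 1L),
                 make_dense_track2(pos, rnorm(600, 6), "den", 1L))
  w <- genomic_window("TTS", -100, 750, "antisense")
  de_ab <- bin_differential_expression(tracks, g, contrast("num", "den"), w, 20L)
  de_ba <- bin_differential_expression(tracks, g, contrast("den", "num"), w, 20L)
  expect_equal(de_ab$values, -de_ba$values)
})

test_that("DE is invariant to replicate order and gene-strand orientation flip", {
  withr::local_seed(6)
  pos <- seq(0, 5999, by = 10)
  r1 <- rnorm(600, 6); r2 <- rnorm(600, 6); den <- rnorm(600, 5)
  tracks <- list(make_dense_track2(pos, r1, "num", 1L),
                 make_dense_track2(pos, r2, "num", 2L),
                 make_dense_track2(pos, den, "den", 1L))
  tracks_perm <- tracks[c(2, 1, 3)]
  g <- one_gene("+", 1000L, 3000L)
  w <- genomic_window("TSS", -100, 750, "sense")
  expect_equal(
    bin_differential_expression(tracks, g, contrast("num", "den"), w, 20L)$values,
    bin_differential_expression(tracks_perm, g, contrast("num", "den"), w, 20L)$values)
})

test_that("sense block equals the mirrored antisense block of the flipped gene", {
  # orientation-consistency: a + gene's sense window, and the antisense
  # window (mirrored offsets) of the same interval annotated on the -
  # strand with the anchor kept in place, read the same probes; the bins
  # come out in reverse transcript order.
  withr::local_seed(9)
  pos <- seq(0, 5999, by = 10)
  tracks <- list(make_dense_track2(pos, rnorm(600, 6), "num", 1L),
                 make_dense_track2(pos, rnorm(600, 5), "den", 1L))
  g <- data.frame(gene_id = "g", chrom = "chrI", strand = "+",
                  start = 1000L, end = 3000L, tss = 1000L, tts = 3000L,
                  stringsAsFactors = FALSE)
  g_flip <- transform(g, strand = "-")  # anchor coordinate unchanged
  w_sense <- genomic_window("TSS", -100, 700, "sense")
  w_mirror <- genomic_window("TSS", -700, 100, "antisense")
  de_s <- bin_differential_expression(tracks, g, contrast("num", "den"),
                                      w_sense, 20L)$values
  de_m <- bin_differential_expression(tracks, g_flip, contrast("num", "den"),
                                      w_mirror, 20L)$values
  expect_equal(unname(de_s[1, ]), rev(unname(de_m[1, ])))
})

test_that("missing conditions raise an error naming the condition", {
  g <- one_gene()
  tr <- make_pair_tracks(g)
  expect_error(
    bin_differential_expression(tr, g, contrast("num", "ghost"),
                                genomic_window("TSS", -100, 750, "sense"), 20L),
    "ghost")
})

test_that("feature matrix concatenation, gating and imputation follow the rules", {
  withr::local_seed(8)
  ids <- sprintf("g%d", 1:10)
  mk_block <- function(ct, orient, nb = 43L) {
    v <- matrix(rnorm(10 * nb), 10, dimnames = list(ids, NULL))
    structure(list(contrast = contrast(ct, "WT"), orientation = orient,
                   bin_offsets = seq_len(nb + 1L), values = v),
              class = "binned_de")
  }
  blocks <- list()
  for (ct in c("c1", "c2", "c3", "c4")) {
    for (o in c("sense", "antisense")) blocks[[length(blocks) + 1L]] <- mk_block(ct, o)
  }
  # gene 1: 30% missing -> dropped; gene 2: one missing bin -> imputed 0
  blocks[[1]]$values["g1", 1:13] <- NA
  blocks[[2]]$values["g1", 1:43] <- NA
  blocks[[3]]$values["g1", 1:43] <- NA
  blocks[[4]]$values["g1", 1:5] <- NA
  blocks[[1]]$values["g2", 7] <- NA
  fm <- suppressMessages(build_feature_matrix(blocks, 0.2))
  expect_equal(ncol(fm$x), 4 * 2 * 43)
  expect_equal(fm$dropped, "g1")
  expect_false("g1" %in% rownames(fm$x))
  expect_equal(fm$x["g2", 7], 0)
  expect_true(fm$imputed["g2", 7])
  expect_false(anyNA(fm$x))
  # column order: contrast blocks in order, sense then antisense
  expect_equal(fm$features$contrast[c(1, 44, 87)],
               c("c1_vs_WT", "c1_vs_WT", "c2_vs_WT"))
  expect_equal(fm$features$orientation[c(1, 44)], c("sense", "antisense"))
})

test_that("half-life follows t1/2 = 0.693/k and recovers noiseless decay", {
  # k given directly through a series built with k = 1 per minute
  t <- 0:5
  f1 <- half_life(t, exp(-1 * t))
  expect_equal(f1$k, 1.0, tolerance = 1e-12)
  expect_equal(f1$t_half, 0.693, tolerance = 1e-12)
  # exact halving every 10 minutes: k = ln2/10, relative error < 1e-9
  t2 <- seq(0, 60, by = 10)
  f2 <- half_life(t2, 2^(-t2 / 10))
  expect_equal(f2$k, log(2) / 10, tolerance = 1e-9)
  expect_equal(f2$t_half, 0.693 / (log(2) / 10), tolerance = 1e-9)
  # cross-check against an independent closed-form slope computation
  y <- log(2^(-t2 / 10))
  slope <- sum((t2 - mean(t2)) * (y - mean(y))) / sum((t2 - mean(t2))^2)
  expect_equal(f2$k, -slope, tolerance = 1e-12)
  # constant levels: no decay
  f3 <- half_life(t2, rep(0.8, length(t2)))
  expect_equal(f3$k, 0)
  expect_equal(f3$t_half, Inf)
  expect_error(half_life(t2, c(1, 2, 3, 0, 1, 1, 1)), "positive")
  expect_error(half_life(0:1, c(1, 0.5)))
})

test_that("half_life_table fits each gene of a decay TSV independently", {
  t <- c(0, 5, 10, 20, 30)
  series <- rbind(
    data.frame(gene_id = "fast", minutes = t, level = 2^(-t / 5)),
    data.frame(gene_id = "slow", minutes = t, level = 2^(-t / 30)))
  ht <- half_life_table(series)
  expect_equal(ht[ht$gene_id == "fast", "t_half"], 0.693 / (log(2) / 5),
               tolerance = 1e-9)
  expect_equal(ht[ht$gene_id == "slow", "t_half"], 0.693 / (log(2) / 30),
               tolerance = 1e-9)
})
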