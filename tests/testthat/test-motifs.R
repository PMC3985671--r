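test_that("literal motif examples count overlaps", {
  fx <- genome_with_window("TCTTCTT")
  mc <- count_motifs(fx$genome, fx$genes, fx$window)
  expect_equal(mc$nab3_count, 2L)
  expect_equal(mc$nrd1_count, 0L)
  fx2 <- genome_with_window("GTAAGTAG")
  mc2 <- count_motifs(fx2$genome, fx2$genes, fx2$window)
  expect_equal(mc2$nrd1_count, 2L)
  fx3 <- genome_with_window(strrep("C", 60))
  mc3 <- count_motifs(fx3$genome, fx3$genes, fx3$window)
  expect_equal(mc3$nab3_count + mc3$nrd1_count, 0L)
})

test_that("motif counts equal a naive sliding-window oracle on random sequences", {
  withr::local_seed(40)
  n <- 1000L
  seq_len_each <- 400L
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), seq_len_each, TRUE), collapse = "")
  }, "")
  # genes tile one chromosome; each gene's motif window is its own body,
  # half read on the antisense (-) strand, half as - strand genes read on +
  strand <- rep(c("+", "-"), length.out = n)
  starts <- 200L + (seq_len(n) - 1L) * (seq_len_each + 100L)
  plus_piece <- vapply(seq_len(n), function(i) {
    if (strand[i] == "+") {
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seqs[i])))
    } else {
      seqs[i]
    }
  }, "")
  chrom_seq <- paste0(strrep("A", 200L),
    paste(vapply(seq_len(n), function(i)
      paste0(plus_piece[i], strrep("A", 100L)), ""), collapse = ""))
  genome <- Biostrings::DNAStringSet(chrom_seq)
  names(genome) <- "chrI"
  genes <- gene_records(sprintf("g%04d", seq_len(n)), "chrI",
                        ifelse(strand == "+", starts - 50L, starts),
                        ifelse(strand == "+", starts + seq_len_each,
                               starts + seq_len_each + 50L),
                        strand)
  mc <- count_motifs(genome, genes,
                     genomic_window("TTS", -seq_len_each, 0L, "antisense"))
  ord <- match(mc$gene_id, sprintf("g%04d", seq_len(n)))
  for (i in seq_len(n)) {
    j <- which(ord == i)
    expect_identical(mc$nab3_count[j], naive_motif_count(seqs[i], "TCTT"))
    expect_identical(mc$nrd1_count[j],
                     naive_motif_count(seqs[i], c("GTAA", "GTAG")))
  }
})

test_that("strand handling: + gene antisense window equals revcomp forward scan", {
  withr::local_seed(41)
  plus_seq <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(plus_seq)
  names(genome) <- "chrI"
  g <- gene_records("g1", "chrI", 50L, 500L, "+")
  mc <- count_motifs(genome, g, genomic_window("TTS", -400L, 0L, "antisense"))
  window_plus <- substr(plus_seq, 101, 500)   # [100, 500) 0-based
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(window_plus)))
  expect_identical(mc$nab3_count, naive_motif_count(rc, "TCTT"))
  expect_identical(mc$nrd1_count, naive_motif_count(rc, c("GTAA", "GTAG")))
})

test_that("windows past the chromosome end are clipped with coverage recorded", {
  genome <- Biostrings::DNAStringSet(strrep("T", 300))
  names(genome) <- "chrI"
  g <- gene_records("g1", "chrI", 0L, 250L, "+")  # window [-150, 250) clipped
  mc <- count_motifs(genome, g, genomic_window("TTS", -400L, 0L, "antisense"))
  expect_equal(mc$coverage, 250 / 400)
  expect_equal(mc$nab3_count, 0L)
})

dense_wt_track <- function(len, val) {
  pos <- 0:(len - 1)
  signal_track("WT_1", "WT", 1L, chrom = rep("chrI", 2 * len),
               strand = rep(c("+", "-"), each = len), pos = rep(pos, 2),
               value = rep(val, 2 * len))
}

test_that("binding aggregation sums the window and normalises by linear WT level", {
  g <- one_gene("+", 1000L, 3000L)
  # binding on the antisense strand of the last 400 bp
  bpos <- seq(2600, 2992, by = 8)
  binding <- make_track(bpos, rep(0, length(bpos)), strand = "-",
                        condition = "parclip")
  wt <- dense_wt_track(4000, 1.0)
  bs <- aggregate_binding(binding, g, list(wt))
  expect_equal(bs$raw_sum, 0)
  expect_equal(bs$normalized, 0)
  binding2 <- make_track(bpos, rep(0.2, length(bpos)), strand = "-",
                         condition = "parclip")
  bs2 <- aggregate_binding(binding2, g, list(wt))
  expect_equal(bs2$raw_sum, 10)
  expect_equal(bs2$wt_expression, 2.0)
  expect_equal(bs2$normalized, 5.0)
})

test_that("binding scores match brute-force recomputation on random data", {
  withr::local_seed(42)
  n <- 50L
  starts <- seq(1000L, by = 3000L, length.out = n)
  genes <- gene_records(sprintf("g%02d", 1:n), "chrI", starts,
                        starts + sample(800:2000, n, TRUE),
                        sample(c("+", "-"), n, TRUE))
  len <- max(genes$end) + 1000L
  pos <- seq(0, len - 1, by = 8)
  bind_vals_p <- rpois(length(pos), 0.5)
  bind_vals_m <- rpois(length(pos), 0.5)
  binding <- signal_track("b", "parclip", 1L,
                          chrom = rep("chrI", 2 * length(pos)),
                          strand = rep(c("+", "-"), each = length(pos)),
                          pos = rep(pos, 2), value = c(bind_vals_p, bind_vals_m))
  wt_vals_p <- rnorm(length(pos), 6); wt_vals_m <- rnorm(length(pos), 6)
  wt <- signal_track("WT_1", "WT", 1L,
                     chrom = rep("chrI", 2 * length(pos)),
                     strand = rep(c("+", "-"), each = length(pos)),
                     pos = rep(pos, 2), value = c(wt_vals_p, wt_vals_m))
  w <- genomic_window("TTS", -400L, 0L, "antisense")
  bs <- aggregate_binding(binding, genes, list(wt), w)
  for (i in seq_len(n)) {
    g <- genes[i, ]
    rw <- resolve_window(g, w)
    sel <- pos >= rw$start & pos < rw$end
    bv <- if (rw$strand == "+") bind_vals_p else bind_vals_m
    wv <- if (rw$strand == "+") wt_vals_p else wt_vals_m
    expected_raw <- sum(bv[sel])
    expected_norm <- expected_raw / 2^mean(wv[sel])
    j <- which(bs$gene_id == g$gene_id)
    expect_equal(bs$raw_sum[j], expected_raw)
    expect_equal(bs$normalized[j], expected_norm)
  }
})

test_that("rank-sum comparison follows the exact/approximate policy", {
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)
  # identical multisets
  expect_equal(compare_groups(c(1, 2, 2, 5), c(2, 1, 5, 2))$p_value, 1.0)
  # symmetry
  withr::local_seed(43)
  a <- rnorm(12); b <- rnorm(15, 0.5)
  expect_equal(compare_groups(a, b)$p_value, compare_groups(b, a)$p_value)
  # all values tied
  expect_equal(compare_groups(rep(3, 5), rep(3, 9))$p_value, 1.0)
})

test_that("exact rank-sum p equals full permutation enumeration for n = m = 3", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  vals <- c(a, b)
  combs <- utils::combn(6, 3)
  u_obs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  us <- apply(combs, 2, function(idx) {
    aa <- vals[idx]; bb <- vals[-idx]
    sum(outer(aa, bb, ">"))
  })
  # two-sided exact p: permutations at least as extreme in either tail
  p_perm <- mean(abs(us - 4.5) >= abs(u_obs - 4.5))
  expect_equal(compare_groups(a, b)$p_value, p_perm)
})

test_that("normal approximation tracks a Monte-Carlo permutation oracle", {
  withr::local_seed(44)
  a <- rnorm(30); b <- rnorm(30, 0.4)
  p_apx <- compare_groups(a, b)$p_value
  vals <- c(a, b)
  r <- rank(vals)
  w_obs <- sum(r[1:30]) - 30 * 31 / 2
  n_perm <- 1e5
  stats_perm <- replicate(n_perm, {
    idx <- sample.int(60, 30)
    sum(r[idx]) - 30 * 31 / 2
  })
  p_perm <- mean(abs(stats_perm - 450) >= abs(w_obs - 450))
  expect_lt(abs(p_apx - p_perm), 0.02)
})
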