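strandless_track <- function(pos, val, chrom = "chrI") {
  signal_track("k4", "h3k4me3", 1L, chrom = rep(chrom, length(pos)),
               strand = rep("*", length(pos)), pos = pos, value = val)
}

test_that("window_score reads chromatin windows through gene orientation", {
  # constant track
  tr <- strandless_track(0:3999, rep(1.25, 4000))
  g <- one_gene("+", 1000L, 3000L)
  w <- genomic_window("TSS", -100L, 300L, "sense")
  expect_equal(unname(window_score(tr, g, w)), 1.25)
  # per-bp values 1..300 over a 300-bp window -> mean 150.5
  tr2 <- strandless_track(900:1199, 1:300)
  g2 <- one_gene("+", 900L, 2000L)
  w2 <- genomic_window("TSS", 0L, 300L, "sense")
  expect_equal(unname(window_score(tr2, g2, w2)), 150.5)
  # 0..-300 of the TTS for a - strand gene maps to genomic [tts, tts+300)
  gm <- one_gene("-", 1000L, 3000L)  # tts = 1000
  w3 <- genomic_window("TTS", -300L, 0L, "sense")
  rw <- resolve_window(gm[1, ], w3)
  expect_equal(rw$start, 1000L)
  expect_equal(rw$end, 1300L)
  tr3 <- strandless_track(0:3999, ifelse(0:3999 >= 1000 & 0:3999 < 1300, 2, 0))
  expect_equal(unname(window_score(tr3, gm, w3)), 2)
})

hypergeom_two_sided <- function(a, b, c_, d) {
  # full enumeration over all tables with the observed margins: sum the
  # point probabilities at most that of the observed table
  m1 <- a + b; m2 <- c_ + d; k <- a + c_
  lo <- max(0, k - m2); hi <- min(k, m1)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(m1, x) + lchoose(m2, k - x) - lchoose(m1 + m2, k))
  }, 0)
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("enrichment odds ratios and Fisher p follow the 2x2 definition", {
  cls <- stats::setNames(rep(c("I", "unclassified"), c(15, 120)),
                         sprintf("g%03d", 1:135))
  feat <- stats::setNames(rep(FALSE, 135), names(cls))
  feat[1:10] <- TRUE               # 10 of 15 in class I
  feat[16:35] <- TRUE              # 20 of 120 outside
  res <- promoter_enrichment(cls, feat, "tata")
  row <- res[res$class == "I", ]
  expect_equal(row$a, 10); expect_equal(row$b, 5)
  expect_equal(row$c, 20); expect_equal(row$d, 100)
  expect_equal(row$odds_ratio, 10.0)
  expect_equal(row$p_two_sided, hypergeom_two_sided(10, 5, 20, 100),
               tolerance = 1e-9)
  expect_true(row$starred == (row$p_two_sided < 0.05))
})

test_that("Fisher p equals hypergeometric enumeration for random small tables", {
  withr::local_seed(50)
  for (i in 1:200) {
    a <- sample(0:20, 1); b <- sample(0:20, 1)
    c_ <- sample(0:20, 1); d <- sample(0:20, 1)
    if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0) next
    p_fisher <- stats::fisher.test(matrix(c(a, b, c_, d), 2,
                                          byrow = TRUE))$p.value
    expect_equal(p_fisher, hypergeom_two_sided(a, b, c_, d),
                 tolerance = 1e-7)
  }
})

test_that("identical proportions give odds ratio 1 and p 1; zero margins p 1", {
  cls <- stats::setNames(rep(c("I", "unclassified"), c(20, 40)),
                         sprintf("g%03d", 1:60))
  feat <- stats::setNames(rep(c(TRUE, FALSE, TRUE, FALSE),
                              c(10, 10, 20, 20)), names(cls))
  res <- promoter_enrichment(cls, feat, "open")
  row <- res[res$class == "I", ]
  expect_equal(row$odds_ratio, 1.0)
  expect_equal(row$p_two_sided, 1.0)
  feat0 <- stats::setNames(rep(FALSE, 60), names(cls))
  res0 <- promoter_enrichment(cls, feat0, "none")
  expect_true(all(res0$p_two_sided == 1.0))
  expect_true(all(is.na(res0$odds_ratio)))
})

test_that("set1 split applies the 2-fold thresholds and partitions the universe", {
  ids <- sprintf("t%d", 1:8)
  expr <- stats::setNames(1:8, ids)
  de <- stats::setNames(c(-2, -1.5, 0, 0, 0, 0, 1.2, 3), ids)
  sp <- set1_effect_split(expr, de, 2.0)
  expect_equal(sum(sp$groups$group == "silenced"), 2L)
  expect_equal(sum(sp$groups$group == "overexpressed"), 2L)
  expect_equal(sum(sp$groups$group == "not_affected"), 4L)
  expect_equal(sum(sp$table), 8)
  # quartiles partition: 2 per quartile for n = 8
  expect_equal(as.vector(table(sp$groups$quartile)), rep(2L, 4))
  # all zero -> all not affected
  sp0 <- set1_effect_split(expr, stats::setNames(rep(0, 8), ids))
  expect_true(all(sp0$groups$group == "not_affected"))
  expect_error(set1_effect_split(expr[1:3], de[1:3]), "at least 4")
})

make_level_tracks <- function(segments_levels, len = 6000L, cond, reps = 1L) {
  # segments_levels: list of (start, end, strand, level); background 4
  lapply(seq_len(reps), function(r) {
    pos <- seq(0, len - 1, by = 8)
    vp <- rep(4, length(pos)); vm <- rep(4, length(pos))
    for (s in segments_levels) {
      sel <- pos >= s[[1]] & pos < s[[2]]
      if (s[[3]] == "+") vp[sel] <- s[[4]] else vm[sel] <- s[[4]]
    }
    signal_track(paste0(cond, r), cond, r,
                 chrom = rep("chrI", 2 * length(pos)),
                 strand = rep(c("+", "-"), each = length(pos)),
                 pos = rep(pos, 2), value = c(vp, vm))
  })
}

test_that("ncRNA annotation drops known overlaps and short segments, labels CUT/SUT", {
  segs <- data.frame(chrom = "chrI",
                     start = c(100L, 1000L, 2000L, 3000L, 4000L),
                     end = c(400L, 1150L, 2500L, 3500L, 4500L),
                     strand = c("+", "+", "+", "+", "-"))
  catalog <- data.frame(chrom = "chrI", start = 50L, end = 450L,
                        strand = "+")
  wt <- make_level_tracks(list(list(3000, 3500, "+", 7.0)), cond = "WT")
  rrp6 <- make_level_tracks(list(list(2000, 2500, "+", 6.5),
                                 list(3000, 3500, "+", 7.0),
                                 list(4000, 4500, "-", 6.5)),
                            cond = "rrp6")
  nc <- annotate_ncrnas(segs, catalog, wt, rrp6, fold_threshold = 2.0,
                        min_len = 200L, min_level = 6.0)
  # segment 1 overlaps the catalog (same strand) -> dropped
  expect_false(any(nc$start == 100))
  # segment 2 is 150 bp -> dropped
  expect_false(any(nc$start == 1000))
  # segment 3: log2 ratio 2.5 -> CUT
  expect_equal(nc$category[nc$start == 2000], "CUT")
  # segment 4: ratio 0 but detectable in WT -> SUT
  expect_equal(nc$category[nc$start == 3000], "SUT")
  # segment 5 (- strand): exosome-specific -> CUT
  expect_equal(nc$category[nc$start == 4000], "CUT")
})

test_that("opposite-strand catalog overlap does not drop a segment", {
  segs <- data.frame(chrom = "chrI", start = 100L, end = 400L, strand = "-")
  catalog <- data.frame(chrom = "chrI", start = 50L, end = 450L,
                        strand = "+")
  wt <- make_level_tracks(list(), cond = "WT")
  rrp6 <- make_level_tracks(list(list(100, 400, "-", 6.5)), cond = "rrp6")
  nc <- annotate_ncrnas(segs, catalog, wt, rrp6)
  expect_equal(nrow(nc), 1L)
  expect_equal(nc$category, "CUT")
})

test_that("raising length or fold thresholds never adds ncRNAs or CUTs", {
  withr::local_seed(51)
  segs <- data.frame(chrom = "chrI",
                     start = seq(0L, 5700L, by = 600L),
                     end = seq(0L, 5700L, by = 600L) +
                       sample(c(150L, 250L, 400L), 10, TRUE),
                     strand = sample(c("+", "-"), 10, TRUE))
  lv <- lapply(seq_len(10), function(i)
    list(segs$start[i], segs$end[i], segs$strand[i], runif(1, 5, 8)))
  wt <- make_level_tracks(lv[1:5], cond = "WT")
  rrp6 <- make_level_tracks(lv, cond = "rrp6")
  catalog <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), strand = character(0))
  n_cut <- function(fold, min_len) {
    nc <- annotate_ncrnas(segs, catalog, wt, rrp6, fold, min_len, 6.0)
    if (!nrow(nc)) 0L else sum(nc$category == "CUT")
  }
  expect_true(n_cut(2, 100) >= n_cut(2, 300))
  expect_true(n_cut(1.5, 200) >= n_cut(4, 200))
})
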