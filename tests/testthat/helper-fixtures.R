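# Shared fixture builders for the test suite.  Everything is generated in
# code; no binary fixtures.

# A track from parallel vectors, defaulting to one chromosome/strand.
make_track <- function(pos, val, chrom = "chrI", strand = "+",
                       condition = "x", replicate = 1L,
                       sample_id = paste0(condition, "_rep", replicate)) {
  n <- length(pos)
  signal_track(sample_id, condition, replicate,
               chrom = rep(chrom, length.out = n),
               strand = rep(strand, length.out = n), pos = pos,
               value = rep(val, length.out = n))
}

# Dense per-bp track over [0, len) with constant or supplied values on
# both strands of one chromosome.
make_dense_track <- function(len, value, chrom = "chrI", condition = "x",
                             replicate = 1L, strands = c("+", "-")) {
  pos <- 0:(len - 1)
  v <- rep(value, length.out = len)
  signal_track(paste0(condition, "_rep", replicate), condition, replicate,
               chrom = rep(chrom, len * length(strands)),
               strand = rep(strands, each = len),
               pos = rep(pos, length(strands)),
               value = rep(v, length(strands)))
}

one_gene <- function(strand = "+", start = 1000L, end = 3000L,
                     chrom = "chrI", id = "g1") {
  gene_records(id, chrom, start, end, strand)
}

# Per-base enumeration oracle for resolve_window: the set of genomic
# 0-based positions covered by transcript offsets [off_start, off_end).
enumerate_window_positions <- function(gene, window) {
  anchor <- if (window$anchor == "TSS") gene$tss else gene$tts
  offs <- window$offset_start:(window$offset_end - 1L)
  if (gene$strand == "+") anchor + offs else anchor - 1L - offs
}

# A genome with a single + strand gene whose motif window (TTS -w..0 on
# the antisense strand) reads exactly `seq_in_window` 5'->3'.
genome_with_window <- function(seq_in_window, flank = 250L) {
  wlen <- nchar(seq_in_window)
  plus <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq_in_window)))
  genome <- Biostrings::DNAStringSet(paste0(strrep("A", flank), plus,
                                            strrep("A", flank)))
  names(genome) <- "chrI"
  genes <- gene_records("g1", "chrI", flank - 200L, flank + wlen, "+")
  list(genome = genome, genes = genes,
       window = genomic_window("TTS", -wlen, 0L, "antisense"))
}

# Naive overlapping motif scan (sliding window, independent of the
# Biostrings-based analysis path).
naive_motif_count <- function(seq, patterns) {
  chars <- strsplit(seq, "")[[1L]]
  n <- length(chars)
  total <- 0L
  for (pat in patterns) {
    p <- strsplit(pat, "")[[1L]]
    w <- length(p)
    if (n < w) next
    for (i in seq_len(n - w + 1L)) {
      if (all(chars[i:(i + w - 1L)] == p)) total <- total + 1L
    }
  }
  total
}

# Fabricated cluster_profiles object from a list of 4 x 2 summary
# matrices (contrast x orientation).
fake_profiles <- function(summaries,
                          contrasts = c("rrp6_vs_WT", "set1rrp6_vs_rrp6",
                                        "hda2rrp6_vs_rrp6",
                                        "rpd3rrp6_vs_rrp6")) {
  out <- lapply(seq_along(summaries), function(i) {
    s <- summaries[[i]]
    dimnames(s) <- list(contrasts, c("sense", "antisense"))
    list(cluster = i, n = 10L, summary = s, median_curve = list())
  })
  names(out) <- as.character(seq_along(summaries))
  structure(out, class = "cluster_profiles", contrasts = contrasts,
            orientations = c("sense", "antisense"))
}

# Summary matrix shorthand: values per contrast for sense/antisense.
summ <- function(sense = c(0, 0, 0, 0), antisense = c(0, 0, 0, 0)) {
  cbind(sense = sense, antisense = antisense)
}

# Small synthetic study used by several test files (cheap: ~3 s).
small_synth_config <- function(...) {
  synthetic_config(n_class = c(I = 8L, II = 10L, III = 30L, IV = 10L,
                               none = 100L),
                   n_convergent_pairs = 5L,
                   n_ncrna = c(CUT = 6L, SUT = 4L, short = 3L), ...)
}

small_analysis_config <- function(...) {
  asrna_config(k_main = 8L, k_range = 6:8, runs_per_k = 5L, seed = 11L, ...)
}
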