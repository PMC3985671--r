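# Fully synthetic study with planted class structure: annotation, genome
# sequence with planted Nrd1/Nab3 motif densities, stranded expression
# tracks for the five strains in triplicate, PAR-CLiP and H3K4me3
# companion tracks, promoter tables and a ground-truth table.  Everything
# the pipeline consumes, generated from one seed.

#' Synthetic study configuration
#'
#' Defaults define the simulated study: ~1970 genes across four planted
#' classes plus an unaffected majority, 50 convergent decoy pairs, tiling
#' probes every 8 bp, triplicates, and log2-additive class effects shaped
#' like the published class profiles.  Class effect geometry: each
#' Rrp6-sensitive antisense unit spans the antisense feature window
#' downstream of the TTS plus a class-dependent fraction of the gene body
#' (Class I reaching beyond the TSS, Class III short); Class IV carries a
#' weak, largely Rrp6-insensitive antisense confined near the TTS.
#'
#' @param n_class Named integer vector of genes per planted class.
#' @param n_convergent_pairs Convergent overlapping decoy pairs (class
#'   `none`, excluded by the convergent filter).
#' @param gene_len_range Uniform gene length range in bp.
#' @param intergenic_gap Gap between placed genes in bp.
#' @param n_chrom Number of gene-bearing chromosomes.
#' @param probe_step Tiling probe spacing in bp.
#' @param replicates Replicates per strain.
#' @param noise_sd Per-probe Gaussian noise, log2 units.
#' @param replicate_sd Per-replicate Gaussian offset, log2 units.
#' @param baseline_mean,baseline_sd Per-gene sense baseline (log2).
#' @param background_level Background probe level (log2).
#' @param sense_effects,antisense_effects 5 x 5 class-by-strain matrices
#'   of log2 offsets (antisense offsets are relative to background over
#'   the antisense unit).
#' @param as_into_gene Fraction of gene length the antisense unit extends
#'   from the TTS toward (Class I: beyond) the TSS.
#' @param as_beyond_tts Extension of the antisense unit past the TTS, bp.
#' @param motif_rates Named list `nab3`/`nrd1` of expected planted motifs
#'   per window by class.
#' @param binding_per_motif Poisson rate per probe per motif for the
#'   PAR-CLiP track.
#' @param tata_prob,closed_prob Probability of a TATA box / closed
#'   promoter for Class I vs all other genes.
#' @param n_ncrna Named counts of planted intergenic ncRNAs (`CUT`,
#'   `SUT`, `short` decoys below the length cutoff).
#' @param ncrna_len_range,ncrna_short_len_range Length ranges in bp.
#' @param ncrna_gain Log2 elevation of expressed ncRNAs above background.
#' @param seed Default seed used by [generate_dataset()].
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_class = c(I = 30L, II = 70L, III = 400L,
                                         IV = 70L, none = 1400L),
                             n_convergent_pairs = 50L,
                             gene_len_range = c(800L, 3000L),
                             intergenic_gap = 1000L,
                             n_chrom = 4L,
                             probe_step = 8L,
                             replicates = 3L,
                             noise_sd = 0.3,
                             replicate_sd = 0.05,
                             baseline_mean = 8, baseline_sd = 1,
                             background_level = 4,
                             sense_effects = NULL,
                             antisense_effects = NULL,
                             as_into_gene = c(I = 1.1, II = 0.9, III = 0.35,
                                              IV = 0.25, none = 0),
                             as_beyond_tts = c(I = 760, II = 760, III = 760,
                                               IV = 100, none = 0),
                             motif_rates = list(nab3 = c(I = 2, II = 2, III = 6,
                                                         IV = 2, none = 2),
                                                nrd1 = c(I = 2, II = 2, III = 5,
                                                         IV = 2, none = 2)),
                             binding_per_motif = 0.3,
                             tata_prob = c(I = 0.7, other = 0.25),
                             closed_prob = c(I = 0.7, other = 0.25),
                             n_ncrna = c(CUT = 40L, SUT = 20L, short = 10L),
                             ncrna_len_range = c(250L, 700L),
                             ncrna_short_len_range = c(100L, 180L),
                             ncrna_gain = 2.5,
                             seed = 1L) {
  strains <- c("WT", "rrp6", "set1rrp6", "hda2rrp6", "rpd3rrp6")
  classes <- c("I", "II", "III", "IV", "none")
  if (is.null(sense_effects)) {
    sense_effects <- rbind(
      I    = c(0, -1.5, -0.5, -0.5, -0.5),
      II   = c(0, -1.5, -1.5, -1.5, -1.5),
      III  = c(0,  0,    0,    0,    0),
      IV   = c(0,  0,    1.0,  1.0,  1.0),
      none = c(0,  0,    0,    0,    0))
    colnames(sense_effects) <- strains
  }
  if (is.null(antisense_effects)) {
    antisense_effects <- rbind(
      I    = c(0,   2.0, 1.7, 2.0, 2.0),
      II   = c(0,   2.0, 0.8, 2.0, 2.0),
      III  = c(0,   2.0, 0.8, 2.0, 2.0),
      IV   = c(1.0, 1.3, 1.3, 1.3, 1.3),
      none = c(0,   0,   0,   0,   0))
    colnames(antisense_effects) <- strains
  }
  stopifnot(identical(rownames(sense_effects), classes),
            identical(rownames(antisense_effects), classes),
            all(n_class > 0), n_convergent_pairs >= 0,
            noise_sd >= 0, replicates >= 1)
  structure(list(n_class = n_class, n_convergent_pairs = n_convergent_pairs,
                 gene_len_range = gene_len_range,
                 intergenic_gap = intergenic_gap, n_chrom = n_chrom,
                 probe_step = probe_step, replicates = replicates,
                 noise_sd = noise_sd, replicate_sd = replicate_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 background_level = background_level,
                 strains = strains, classes = classes,
                 sense_effects = sense_effects,
                 antisense_effects = antisense_effects,
                 as_into_gene = as_into_gene, as_beyond_tts = as_beyond_tts,
                 motif_rates = motif_rates,
                 binding_per_motif = binding_per_motif,
                 tata_prob = tata_prob, closed_prob = closed_prob,
                 n_ncrna = n_ncrna, ncrna_len_range = ncrna_len_range,
                 ncrna_short_len_range = ncrna_short_len_range,
                 ncrna_gain = ncrna_gain, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Probe index range covering [s, e) on a step grid starting at 0.
probe_range <- function(s, e, step) {
  i1 <- ceiling(max(s, 0) / step) + 1L
  i2 <- floor((e - 1) / step) + 1L
  if (i2 < i1) integer(0) else i1:i2
}

# Overlapping motif occurrences in a character scalar (base-R scan, used
# for ground-truth bookkeeping; the analysis path uses Biostrings).
scan_motifs_chr <- function(seq) {
  cnt <- function(pat) {
    m <- gregexpr(paste0("(?=", pat, ")"), seq, perl = TRUE)[[1L]]
    if (m[1L] == -1L) 0L else length(m)
  }
  c(nab3 = cnt("TCTT"), nrd1 = cnt("GTA[AG]"))
}

#' Generate a synthetic antisense-regulation study
#'
#' Produces annotation, genome, stranded log2 expression tracks for all
#' strains and replicates, PAR-CLiP and H3K4me3 companion tracks, a
#' promoter table and ground truth, with planted class structure (see
#' [synthetic_config()]).  With `dir` set, the bundle is also written to
#' disk (BED6, FASTA, bedGraph pairs, TSV, and a manifest with md5
#' digests); a fixed seed gives a byte-identical bundle.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param dir Optional output directory; refused if it already contains a
#'   manifest, unless `overwrite = TRUE`.
#' @param overwrite Allow writing into an existing bundle directory.
#' @return A list of class `asrna_dataset`: `genes` ([gene_records()]),
#'   `tracks` (list of [signal_track()]s), `parclip`, `h3k4me3`, `genome`
#'   (`DNAStringSet`), `promoters`, `truth` (list with `genes` and
#'   `ncrnas`), `config`, `seed`, and `dir`/`manifest` when written.
#' @export
generate_dataset <- function(config = synthetic_config(),
                             seed = config$seed, dir = NULL,
                             overwrite = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(as.integer(seed), {
    ds <- generate_dataset_impl(config)
  })
  ds$seed <- as.integer(seed)
  if (!is.null(dir)) {
    ds <- write_dataset(ds, dir, overwrite = overwrite)
  }
  ds
}

generate_dataset_impl <- function(cfg) {
  strains <- cfg$strains
  step <- cfg$probe_step

  ## ---- gene layout ----
  classes <- sample(rep(names(cfg$n_class), cfg$n_class))
  n_reg <- length(classes)
  placement <- as.list(seq_len(n_reg))
  if (cfg$n_convergent_pairs > 0) {
    pair_slots <- sort(sample(n_reg, cfg$n_convergent_pairs))
    for (i in seq_along(pair_slots)) {
      placement <- append(placement, list(paste0("pair", i)),
                          after = pair_slots[i] + i - 1L)
    }
  }
  chrom_of <- rep(paste0("chr", seq_len(cfg$n_chrom)),
                  length.out = length(placement))
  chrom_of <- sort(chrom_of)  # contiguous blocks per chromosome
  cursor <- stats::setNames(rep(1200, cfg$n_chrom),
                            paste0("chr", seq_len(cfg$n_chrom)))
  rows <- list()
  gi <- 0L
  rlen <- function() round(stats::runif(1, cfg$gene_len_range[1L],
                                        cfg$gene_len_range[2L]))
  for (j in seq_along(placement)) {
    chr <- chrom_of[j]
    if (is.numeric(placement[[j]])) {
      gi <- gi + 1L
      len <- rlen()
      start <- cursor[[chr]]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sprintf("SYN%04d", gi), chrom = chr, start = start,
        end = start + len, strand = sample(c("+", "-"), 1L),
        class = classes[placement[[j]]], convergent = FALSE,
        stringsAsFactors = FALSE)
      cursor[[chr]] <- start + len + cfg$intergenic_gap
    } else {
      lenA <- rlen(); lenB <- rlen()
      ov <- round(stats::runif(1, 100, 300))
      start <- cursor[[chr]]
      gi <- gi + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sprintf("SYN%04d", gi), chrom = chr, start = start,
        end = start + lenA, strand = "+", class = "none",
        convergent = TRUE, stringsAsFactors = FALSE)
      gi <- gi + 1L
      startB <- start + lenA - ov
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sprintf("SYN%04d", gi), chrom = chr, start = startB,
        end = startB + lenB, strand = "-", class = "none",
        convergent = TRUE, stringsAsFactors = FALSE)
      cursor[[chr]] <- max(start + lenA, startB + lenB) + cfg$intergenic_gap
    }
  }
  gt <- do.call(rbind, rows)

  ## ---- planted intergenic ncRNAs on a dedicated chromosome ----
  nc_rows <- list()
  nc_cursor <- 1200
  nc_kinds <- sample(rep(names(cfg$n_ncrna), cfg$n_ncrna))
  for (i in seq_along(nc_kinds)) {
    kind <- nc_kinds[i]
    len <- if (kind == "short") {
      round(stats::runif(1, cfg$ncrna_short_len_range[1L],
                         cfg$ncrna_short_len_range[2L]))
    } else {
      round(stats::runif(1, cfg$ncrna_len_range[1L], cfg$ncrna_len_range[2L]))
    }
    nc_rows[[i]] <- data.frame(
      id = sprintf("ncTRUE%03d", i), chrom = "chrNC", start = nc_cursor,
      end = nc_cursor + len, strand = sample(c("+", "-"), 1L),
      category = kind, stringsAsFactors = FALSE)
    nc_cursor <- nc_cursor + len + 400
  }
  nc_truth <- if (length(nc_rows)) do.call(rbind, nc_rows) else
    data.frame(id = character(0), chrom = character(0), start = integer(0),
               end = integer(0), strand = character(0),
               category = character(0))

  chrom_lens <- c(cursor + 800, chrNC = nc_cursor + 800)
  chroms <- names(chrom_lens)

  ## ---- antisense unit geometry (sense coordinates) ----
  len <- gt$end - gt$start
  into <- cfg$as_into_gene[gt$class] * len
  beyond <- cfg$as_beyond_tts[gt$class]
  as_start <- ifelse(gt$strand == "+", gt$end - into, gt$start - beyond)
  as_end <- ifelse(gt$strand == "+", gt$end + beyond, gt$start + into)
  has_as <- gt$class != "none"
  gt$as_start <- as.integer(pmax(0, ifelse(has_as, round(as_start), NA)))
  gt$as_end <- as.integer(ifelse(has_as, round(as_end), NA))

  ## ---- genome sequence with planted motifs ----
  genome_chars <- lapply(chrom_lens, function(L) {
    sample(c("A", "C", "G", "T"), L, replace = TRUE)
  })
  motif_window <- genomic_window("TTS", -400, 0, "antisense")
  revcomp_chr <- function(s) chartr("ACGT", "TGCA",
                                    paste(rev(strsplit(s, "")[[1L]]),
                                          collapse = ""))
  for (i in seq_len(nrow(gt))) {
    g <- list(chrom = gt$chrom[i], strand = gt$strand[i],
              tss = ifelse(gt$strand[i] == "+", gt$start[i], gt$end[i]),
              tts = ifelse(gt$strand[i] == "+", gt$end[i], gt$start[i]))
    w <- resolve_window(g, motif_window,
                        chrom_len = chrom_lens[[gt$chrom[i]]])
    wlen <- w$end - w$start
    if (wlen < 10L) next
    for (motif in c("nab3", "nrd1")) {
      lambda <- cfg$motif_rates[[motif]][[gt$class[i]]]
      k <- stats::rpois(1L, lambda)
      if (k == 0L) next
      pat <- if (motif == "nab3") "TCTT" else
        paste0("GTA", sample(c("A", "G"), 1L))
      for (q in seq_len(k)) {
        # offset within the window, on the antisense transcript 5'->3'
        off <- sample.int(wlen - 4L, 1L)
        if (w$strand == "-") {
          # motif read on the minus strand: write its reverse complement
          # into the plus-strand reference, right-anchored
          gpos <- w$end - off - 4L
          genome_chars[[w$chrom]][(gpos + 1L):(gpos + 4L)] <-
            strsplit(revcomp_chr(pat), "")[[1L]]
        } else {
          gpos <- w$start + off
          genome_chars[[w$chrom]][(gpos + 1L):(gpos + 4L)] <-
            strsplit(pat, "")[[1L]]
        }
      }
    }
  }
  genome <- Biostrings::DNAStringSet(vapply(genome_chars, paste,
                                            "", collapse = ""))
  names(genome) <- chroms

  ## ---- ground-truth motif bookkeeping (final sequence, base-R scan) ----
  gt$nab3_count <- 0L
  gt$nrd1_count <- 0L
  for (i in seq_len(nrow(gt))) {
    g <- list(chrom = gt$chrom[i], strand = gt$strand[i],
              tss = ifelse(gt$strand[i] == "+", gt$start[i], gt$end[i]),
              tts = ifelse(gt$strand[i] == "+", gt$end[i], gt$start[i]))
    w <- resolve_window(g, motif_window,
                        chrom_len = chrom_lens[[gt$chrom[i]]])
    if (w$end <= w$start) next
    s <- paste(genome_chars[[w$chrom]][(w$start + 1L):w$end], collapse = "")
    if (w$strand == "-") s <- revcomp_chr(s)
    cnt <- scan_motifs_chr(s)
    gt$nab3_count[i] <- cnt[["nab3"]]
    gt$nrd1_count[i] <- cnt[["nrd1"]]
  }

  ## ---- expression level profiles per (chrom, strand, strain) ----
  gt$baseline <- stats::rnorm(nrow(gt), cfg$baseline_mean, cfg$baseline_sd)
  pos_of <- lapply(chrom_lens, function(L) seq(0, L - 1, by = step))
  level <- list()  # level[[strain]][[chrom|strand]]
  for (st in strains) level[[st]] <- list()
  for (chr in chroms) {
    np <- length(pos_of[[chr]])
    for (sd_ in c("+", "-")) {
      base <- rep(cfg$background_level, np)
      off <- matrix(0, np, length(strains),
                    dimnames = list(NULL, strains))
      gidx <- which(gt$chrom == chr)
      for (i in gidx) {
        # sense body on the gene's own strand
        if (gt$strand[i] == sd_) {
          pr <- probe_range(gt$start[i], gt$end[i], step)
          base[pr] <- gt$baseline[i]
          off[pr, ] <- off[pr, ] +
            rep(cfg$sense_effects[gt$class[i], ], each = length(pr))
        } else if (!is.na(gt$as_start[i])) {
          # antisense unit on the opposite strand
          pr <- probe_range(gt$as_start[i],
                            min(gt$as_end[i], chrom_lens[[chr]]), step)
          if (length(pr)) {
            off[pr, ] <- off[pr, ] +
              rep(cfg$antisense_effects[gt$class[i], ], each = length(pr))
          }
        }
      }
      if (chr == "chrNC" && nrow(nc_truth)) {
        for (i in which(nc_truth$strand == sd_)) {
          pr <- probe_range(nc_truth$start[i], nc_truth$end[i], step)
          if (!length(pr)) next
          if (nc_truth$category[i] == "SUT") {
            off[pr, ] <- off[pr, ] + cfg$ncrna_gain
          } else {  # CUT and short decoys: exosome-sensitive
            off[pr, strains != "WT"] <- off[pr, strains != "WT"] +
              cfg$ncrna_gain
          }
        }
      }
      for (st in strains) {
        level[[st]][[paste0(chr, "|", sd_)]] <- base + off[, st]
      }
    }
  }

  ## ---- expression tracks: strain x replicate with noise ----
  tracks <- list()
  for (st in strains) {
    for (rep_ in seq_len(cfg$replicates)) {
      rep_off <- stats::rnorm(1L, 0, cfg$replicate_sd)
      chrom_v <- character(0); strand_v <- character(0)
      pos_v <- numeric(0); val_v <- numeric(0)
      for (chr in chroms) {
        for (sd_ in c("+", "-")) {
          lv <- level[[st]][[paste0(chr, "|", sd_)]]
          np <- length(lv)
          chrom_v <- c(chrom_v, rep(chr, np))
          strand_v <- c(strand_v, rep(sd_, np))
          pos_v <- c(pos_v, pos_of[[chr]])
          val_v <- c(val_v, lv + rep_off + stats::rnorm(np, 0, cfg$noise_sd))
        }
      }
      id <- sprintf("%s_rep%d", st, rep_)
      tracks[[id]] <- signal_track(id, st, rep_, chrom_v, strand_v,
                                   pos_v, val_v)
    }
  }

  ## ---- PAR-CLiP binding track (antisense strand of each motif window) ----
  pc_chrom <- character(0); pc_strand <- character(0)
  pc_pos <- numeric(0); pc_val <- numeric(0)
  for (i in seq_len(nrow(gt))) {
    g <- list(chrom = gt$chrom[i], strand = gt$strand[i],
              tss = ifelse(gt$strand[i] == "+", gt$start[i], gt$end[i]),
              tts = ifelse(gt$strand[i] == "+", gt$end[i], gt$start[i]))
    w <- resolve_window(g, motif_window,
                        chrom_len = chrom_lens[[gt$chrom[i]]])
    pr <- probe_range(w$start, w$end, step)
    if (!length(pr)) next
    pos <- pos_of[[gt$chrom[i]]][pr]
    lam <- cfg$binding_per_motif * (gt$nab3_count[i] + gt$nrd1_count[i])
    pc_chrom <- c(pc_chrom, rep(gt$chrom[i], length(pos)))
    pc_strand <- c(pc_strand, rep(w$strand, length(pos)))
    pc_pos <- c(pc_pos, pos)
    pc_val <- c(pc_val, stats::rpois(length(pos), lam))
  }
  o <- order(pc_chrom, pc_strand, pc_pos)
  dup <- duplicated(paste0(pc_chrom, "|", pc_strand, "|", pc_pos)[o])
  o <- o[!dup]  # overlapping neighbour windows: keep first
  parclip <- signal_track("parclip", "parclip", 1L, pc_chrom[o],
                          pc_strand[o], pc_pos[o], pc_val[o])

  ## ---- H3K4me3/H3 track (strandless) ----
  k4_chrom <- character(0); k4_pos <- numeric(0); k4_val <- numeric(0)
  for (chr in chroms) {
    np <- length(pos_of[[chr]])
    v <- rep(0.2, np)
    for (i in which(gt$chrom == chr)) {
      tss <- ifelse(gt$strand[i] == "+", gt$start[i], gt$end[i])
      tts <- ifelse(gt$strand[i] == "+", gt$end[i], gt$start[i])
      prom <- if (gt$strand[i] == "+") c(tss - 100, tss + 300)
              else c(tss - 300, tss + 100)
      pr <- probe_range(prom[1L], prom[2L], step)
      v[pr] <- v[pr] + 0.8 + 0.15 * (gt$baseline[i] - cfg$baseline_mean)
      if (gt$class[i] %in% c("I", "II", "III")) {
        tpr <- if (gt$strand[i] == "+") probe_range(tts - 300, tts, step)
               else probe_range(tts, tts + 300, step)
        v[tpr] <- v[tpr] + 0.8
      }
    }
    k4_chrom <- c(k4_chrom, rep(chr, np))
    k4_pos <- c(k4_pos, pos_of[[chr]])
    k4_val <- c(k4_val, v + stats::rnorm(np, 0, 0.1))
  }
  h3k4me3 <- signal_track("h3k4me3", "h3k4me3", 1L, k4_chrom,
                          rep("*", length(k4_pos)), k4_pos, k4_val)

  ## ---- promoter annotation ----
  is_I <- gt$class == "I"
  tata <- stats::runif(nrow(gt)) <
    ifelse(is_I, cfg$tata_prob[["I"]], cfg$tata_prob[["other"]])
  closed <- stats::runif(nrow(gt)) <
    ifelse(is_I, cfg$closed_prob[["I"]], cfg$closed_prob[["other"]])
  tf_pool <- c("MIG1", "UME6", "IME1", "ADR1", "MSN2", "MSN4", "SPT15",
               "STP1", "RAP1", "ABF1")
  tf_sites <- vapply(seq_len(nrow(gt)), function(i) {
    paste(sample(tf_pool, stats::rpois(1L, 1.2)), collapse = ";")
  }, "")
  promoters <- data.frame(gene_id = gt$gene_id, tata = tata,
                          occ = ifelse(closed, "closed", "open"),
                          tf_sites = tf_sites, stringsAsFactors = FALSE)

  genes <- gene_records(gt$gene_id, gt$chrom, gt$start, gt$end, gt$strand)
  truth_genes <- gt[, c("gene_id", "class", "convergent", "as_start",
                        "as_end", "nab3_count", "nrd1_count", "baseline")]
  structure(list(genes = genes, tracks = tracks, parclip = parclip,
                 h3k4me3 = h3k4me3, genome = genome, promoters = promoters,
                 truth = list(genes = truth_genes, ncrnas = nc_truth),
                 chrom_lens = chrom_lens, config = cfg),
            class = "asrna_dataset")
}

#' @export
print.asrna_dataset <- function(x, ...) {
  cat(sprintf("<asrna_dataset: %d genes on %d chromosomes, %d expression tracks, seed %s>\n",
              nrow(x$genes), length(x$chrom_lens), length(x$tracks),
              if (is.null(x$seed)) "?" else x$seed))
  print(table(planted = x$truth$genes$class))
  invisible(x)
}

#' Write a synthetic bundle to disk
#'
#' @param ds An `asrna_dataset`.
#' @param dir Output directory.
#' @param overwrite Allow writing over an existing bundle.
#' @return The dataset with `dir` and `manifest` filled in.
#' @export
write_dataset <- function(ds, dir, overwrite = FALSE) {
  manifest_path <- file.path(dir, "MANIFEST")
  if (file.exists(manifest_path) && !overwrite) {
    stop("bundle already exists in ", dir, " (use overwrite = TRUE)")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  step <- ds$config$probe_step
  files <- character(0)
  bed <- file.path(dir, "genes.bed")
  write_annotation(ds$genes, bed); files <- c(files, bed)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(ds$genome, fa); files <- c(files, fa)
  for (id in names(ds$tracks)) {
    files <- c(files, write_track(ds$tracks[[id]],
                                  file.path(dir, paste0("expr_", id)), step))
  }
  files <- c(files, write_track(ds$parclip, file.path(dir, "parclip"), step))
  files <- c(files, write_track(ds$h3k4me3,
                                file.path(dir, "h3k4me3.bedgraph"), step))
  prom <- file.path(dir, "promoters.tsv")
  write_table(ds$promoters, prom); files <- c(files, prom)
  tg <- file.path(dir, "truth_genes.tsv")
  write_table(ds$truth$genes, tg); files <- c(files, tg)
  tn <- file.path(dir, "truth_ncrnas.tsv")
  write_table(ds$truth$ncrnas, tn); files <- c(files, tn)
  md5 <- tools::md5sum(files)
  lines <- c(paste0("seed\t", ds$seed),
             paste0("file\t", basename(names(md5)), "\t", unname(md5)))
  writeLines(lines, manifest_path)
  ds$dir <- dir
  ds$manifest <- manifest_path
  ds
}

#' Compare a class assignment with the planted truth
#'
#' @param assignment A `class_assignment`, `asrna_fit`, or named
#'   factor/character of classes per gene.
#' @param truth The `truth$genes` data frame of an `asrna_dataset` (or any
#'   data frame with `gene_id` and `class`, planted class `none` mapping
#'   to unclassified).
#' @param core Optional named logical; when given, recall is additionally
#'   reported over core genes only (`core_recall`).
#' @return A list with `confusion` (planted x assigned), `recall`,
#'   `precision` per class, and `core_recall` when `core` is given.
#' @export
truth_compare <- function(assignment, truth, core = NULL) {
  if (inherits(assignment, "asrna_fit")) {
    if (is.null(core)) core <- assignment$core
    assignment <- assignment$assignment
  }
  cls <- if (inherits(assignment, "class_assignment")) assignment$class
         else assignment
  ids <- intersect(names(cls), truth$gene_id)
  planted <- truth$class[match(ids, truth$gene_id)]
  planted[planted == "none"] <- "unclassified"
  lv <- c("I", "II", "III", "IV", "unclassified")
  planted <- factor(planted, lv)
  assigned <- factor(as.character(cls[ids]), lv)
  confusion <- table(planted = planted, assigned = assigned)
  recall <- diag(confusion) / rowSums(confusion)
  precision <- diag(confusion) / colSums(confusion)
  out <- list(confusion = confusion, recall = recall, precision = precision)
  if (!is.null(core)) {
    keep <- ids[core[ids]]
    ctab <- table(planted = planted[match(keep, ids)],
                  assigned = assigned[match(keep, ids)])
    out$core_confusion <- ctab
    out$core_recall <- diag(ctab) / rowSums(ctab)
  }
  out
}
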