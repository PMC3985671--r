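# File-based orchestration of the analysis stages: one run directory, one
# YAML config, deterministic outputs plus a manifest of md5 digests.

#' Load a pipeline configuration
#'
#' YAML with up to three top-level keys: `seed`, `synthetic` (arguments of
#' [synthetic_config()]) and `analysis` (arguments of [asrna_config()]).
#' Command-line style overrides (`"section.key=value"`) are applied on
#' top and round-trip into the config snapshot of the run manifest.
#'
#' @param path YAML file path (`NULL` for all defaults).
#' @param overrides Character vector of `section.key=value` strings.
#' @return List with `seed`, `synthetic`, `analysis` and `raw` (the
#'   merged key-value tree).
#' @export
load_pipeline_config <- function(path = NULL, overrides = character()) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("override must be key=value: ", ov)
    keys <- strsplit(kv[1L], ".", fixed = TRUE)[[1L]]
    val <- utils::type.convert(kv[2L], as.is = TRUE)
    if (length(keys) == 1L) raw[[keys]] <- val
    else raw[[keys[1L]]][[keys[2L]]] <- val
  }
  seed <- if (!is.null(raw$seed)) as.integer(raw$seed) else 1L
  syn_args <- raw$synthetic %||% list()
  if (!is.null(syn_args$n_class)) syn_args$n_class <- unlist(syn_args$n_class)
  if (!is.null(syn_args$n_ncrna)) syn_args$n_ncrna <- unlist(syn_args$n_ncrna)
  ana_args <- raw$analysis %||% list()
  if (!is.null(ana_args$k_range) && length(ana_args$k_range) == 2L) {
    ana_args$k_range <- ana_args$k_range[1L]:ana_args$k_range[2L]
  }
  syn_args$seed <- seed
  ana_args$seed <- seed
  list(seed = seed,
       synthetic = do.call(synthetic_config, syn_args),
       analysis = do.call(asrna_config, ana_args),
       raw = raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a synthetic bundle from disk
#'
#' Reads back everything [generate_dataset()] wrote: annotation, genome,
#' stranded expression tracks (conditions and replicates parsed from the
#' `expr_<strain>_rep<k>` file names), PAR-CLiP, H3K4me3, promoter table
#' and truth tables.
#'
#' @param dir Bundle directory.
#' @param probe_step Probe spacing used when the bundle was written.
#' @return An `asrna_dataset`-shaped list.
#' @export
load_dataset <- function(dir, probe_step = 8L) {
  stopifnot(dir.exists(dir))
  genes <- read_annotation(file.path(dir, "genes.bed"), "BED")
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  prefixes <- unique(sub("\\.(plus|minus)\\.bedgraph$", "",
                         list.files(dir, "^expr_.*\\.bedgraph$")))
  tracks <- list()
  for (p in prefixes) {
    meta <- regmatches(p, regexec("^expr_(.+)_rep(\\d+)$", p))[[1L]]
    tracks[[sub("^expr_", "", p)]] <-
      read_stranded_track(file.path(dir, p), probe_step,
                          sample_id = sub("^expr_", "", p),
                          condition = meta[2L],
                          replicate = as.integer(meta[3L]))
  }
  parclip <- read_stranded_track(file.path(dir, "parclip"), probe_step,
                                 sample_id = "parclip",
                                 condition = "parclip")
  h3k4me3 <- read_track(file.path(dir, "h3k4me3.bedgraph"), "bedGraph",
                        strand = "*", probe_step = probe_step,
                        sample_id = "h3k4me3")
  list(genes = genes, tracks = tracks, parclip = parclip,
       h3k4me3 = h3k4me3, genome = genome,
       promoters = read_table(file.path(dir, "promoters.tsv")),
       truth = list(genes = read_table(file.path(dir, "truth_genes.tsv")),
                    ncrnas = read_table(file.path(dir, "truth_ncrnas.tsv"))),
       dir = dir)
}

#' Read a feature matrix written by the pipeline
#'
#' @param path TSV written by the `features` stage (pre-imputation values,
#'   empty cells for missing bins).
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(path) {
  df <- read_table(path)
  x <- as.matrix(df[, -1L, drop = FALSE])
  rownames(x) <- df[[1L]]
  lab <- do.call(rbind, strsplit(colnames(x), "|", fixed = TRUE))
  info <- data.frame(contrast = lab[, 1L], orientation = lab[, 2L],
                     bin = as.integer(sub("^bin", "", lab[, 3L])),
                     stringsAsFactors = FALSE)
  miss <- is.na(x)
  x[miss] <- 0
  structure(list(x = x, features = info, imputed = miss,
                 dropped = character(0)),
            class = "feature_matrix")
}

manifest_add <- function(outdir, stage, paths) {
  mf <- file.path(outdir, "RUN_MANIFEST.tsv")
  old <- if (file.exists(mf)) read_table(mf) else
    data.frame(stage = character(0), artifact = character(0),
               md5 = character(0))
  md5 <- tools::md5sum(paths)
  new <- data.frame(stage = stage, artifact = basename(paths),
                    md5 = unname(md5), stringsAsFactors = FALSE)
  old <- old[!(old$artifact %in% new$artifact), , drop = FALSE]
  write_table(rbind(old, new), mf)
}

manifest_check <- function(outdir, paths) {
  mf <- file.path(outdir, "RUN_MANIFEST.tsv")
  if (!file.exists(mf)) return(invisible())
  man <- read_table(mf)
  for (p in paths) {
    i <- match(basename(p), man$artifact)
    if (!is.na(i) && file.exists(p) &&
        !identical(unname(tools::md5sum(p)), man$md5[i])) {
      warning("stale upstream digest for ", basename(p))
    }
  }
  invisible()
}

need_file <- function(path, stage, wanted_by) {
  if (!file.exists(path)) {
    stop("stage '", wanted_by, "' needs ", basename(path),
         "; run stage '", stage, "' first")
  }
  path
}

pipeline_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the analysis pipeline
#'
#' Executes the stages on a run directory.  `simulate` writes the
#' synthetic bundle under `<outdir>/data`; the analysis stages read their
#' declared inputs from the run directory and write their outputs there,
#' updating a manifest of md5 digests.  `all` chains
#' simulate, features, cluster, classify, profile, motifs, chromatin,
#' ncrna, evaluate.
#'
#' @param stages Character vector of stage names, or `"all"`.
#' @param outdir Run directory.
#' @param config A list from [load_pipeline_config()] (or `NULL` for
#'   defaults).
#' @return Invisibly, the run directory.
#' @export
run_pipeline <- function(stages = "all", outdir, config = NULL) {
  if (is.null(config)) config <- load_pipeline_config(NULL)
  all_stages <- c("simulate", "features", "cluster", "classify", "profile",
                  "motifs", "chromatin", "ncrna", "evaluate")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(list(seed = config$seed, config = config$raw),
                   file.path(outdir, "config_snapshot.yaml"))
  data_dir <- file.path(outdir, "data")
  ana <- config$analysis

  ds <- NULL
  get_ds <- function() {
    if (is.null(ds)) {
      need_file(file.path(data_dir, "genes.bed"), "simulate", "this stage")
      ds <<- load_dataset(data_dir, config$synthetic$probe_step)
    }
    ds
  }

  for (stage in stages) {
    pipeline_log(stage, "start")
    switch(stage,
      simulate = {
        d <- generate_dataset(config$synthetic, config$seed, dir = data_dir,
                              overwrite = TRUE)
        ds <- d
        manifest_add(outdir, "simulate",
                     list.files(data_dir, full.names = TRUE))
      },
      features = {
        d <- get_ds()
        filt <- exclude_convergent_overlapping(d$genes)
        cache <- new.env(parent = emptyenv())
        blocks <- list()
        for (ct in ana$contrasts) {
          for (w in list(ana$sense_window, ana$antisense_window)) {
            blocks[[length(blocks) + 1L]] <-
              bin_differential_expression(d$tracks, filt$kept, ct, w,
                                          ana$de_bin, cache = cache)
          }
        }
        fm <- build_feature_matrix(blocks, ana$max_missing_fraction)
        out <- fm$x
        out[fm$imputed] <- NA_real_
        write_table(data.frame(gene_id = rownames(out), out,
                               check.names = FALSE),
                    file.path(outdir, "features.tsv"))
        write_table(data.frame(gene_id = filt$excluded$gene_id),
                    file.path(outdir, "excluded_convergent.tsv"))
        manifest_add(outdir, "features",
                     file.path(outdir, c("features.tsv",
                                         "excluded_convergent.tsv")))
      },
      cluster = {
        fm <- read_feature_matrix(
          need_file(file.path(outdir, "features.tsv"), "features", stage))
        dmat <- euclidean_distance_matrix(fm$x)
        base <- pam_cluster(fm, ana$k_main, dist_matrix = dmat)
        cons <- consensus_robustness(fm, ana$k_range, ana$runs_per_k,
                                     ana$subsample_fraction, ana$seed,
                                     dist_matrix = dmat)
        core <- select_core_genes(cons, base, ana$core_cutoff)
        write_clustering(base, file.path(outdir, "clusters.tsv"))
        write_table(data.frame(gene_id = names(core), core = unname(core),
                               score = unname(attr(core, "score"))),
                    file.path(outdir, "core_genes.tsv"))
        manifest_add(outdir, "cluster",
                     file.path(outdir, c("clusters.tsv", "core_genes.tsv")))
      },
      classify = {
        fm <- read_feature_matrix(
          need_file(file.path(outdir, "features.tsv"), "features", stage))
        cl <- read_table(
          need_file(file.path(outdir, "clusters.tsv"), "cluster", stage))
        manifest_check(outdir, file.path(outdir, c("features.tsv",
                                                   "clusters.tsv")))
        co <- read_table(
          need_file(file.path(outdir, "core_genes.tsv"), "cluster", stage))
        base <- structure(list(k = max(cl$cluster),
                               labels = stats::setNames(cl$cluster,
                                                        cl$gene_id)),
                          class = "pam_fit")
        core <- stats::setNames(co$core, co$gene_id)
        prof <- cluster_profiles(fm, base)
        rules <- assign_classes(prof, ana$class_epsilon)
        assignment <- label_genes(rules, base, core)
        write_table(data.frame(gene_id = names(assignment$class),
                               class = as.character(assignment$class)),
                    file.path(outdir, "classes.tsv"))
        write_table(rules$rule_trace, file.path(outdir, "rule_trace.tsv"))
        manifest_add(outdir, "classify",
                     file.path(outdir, c("classes.tsv", "rule_trace.tsv")))
      },
      profile = {
        d <- get_ds()
        cls <- read_table(
          need_file(file.path(outdir, "classes.tsv"), "classify", stage))
        paths <- character(0)
        for (cl in intersect(c("I", "II", "III", "IV"), unique(cls$class))) {
          genes_cl <- d$genes[d$genes$gene_id %in%
                                cls$gene_id[cls$class == cl], ]
          if (!nrow(genes_cl)) next
          for (anchor in c("TSS", "TTS")) {
            mp <- antisense_metagene(d$tracks, genes_cl,
                                     condition = ana$conditions[2L],
                                     anchor = anchor,
                                     bin = ana$profile_bin,
                                     smooth_window = ana$smooth_window)
            p <- file.path(outdir, sprintf("metagene_class%s_%s.tsv",
                                           cl, anchor))
            write_metagene(mp, p)
            paths <- c(paths, p)
          }
        }
        manifest_add(outdir, "profile", paths)
      },
      motifs = {
        d <- get_ds()
        mc <- count_motifs(d$genome, d$genes, ana$motif_window)
        bs <- aggregate_binding(d$parclip, d$genes,
                                Filter(function(t)
                                  t$condition == ana$conditions[1L],
                                  d$tracks),
                                ana$motif_window, ana$conditions[1L])
        write_table(mc, file.path(outdir, "motif_counts.tsv"))
        write_table(bs, file.path(outdir, "binding_scores.tsv"))
        manifest_add(outdir, "motifs",
                     file.path(outdir, c("motif_counts.tsv",
                                         "binding_scores.tsv")))
      },
      chromatin = {
        d <- get_ds()
        cls <- read_table(
          need_file(file.path(outdir, "classes.tsv"), "classify", stage))
        prom_w <- genomic_window("TSS", -100, 300, "sense")
        tts_w <- genomic_window("TTS", -300, 0, "sense")
        k4 <- data.frame(gene_id = d$genes$gene_id,
                         promoter = unname(window_score(d$h3k4me3, d$genes,
                                                        prom_w)),
                         tts = unname(window_score(d$h3k4me3, d$genes,
                                                   tts_w)))
        write_table(k4, file.path(outdir, "h3k4me3_scores.tsv"))
        assignment <- stats::setNames(cls$class, cls$gene_id)
        prom <- d$promoters
        enr <- rbind(
          promoter_enrichment(assignment,
                              stats::setNames(prom$tata, prom$gene_id),
                              "tata"),
          promoter_enrichment(assignment,
                              stats::setNames(prom$occ == "closed",
                                              prom$gene_id),
                              "closed"))
        write_table(enr, file.path(outdir, "promoter_enrichment.tsv"))
        manifest_add(outdir, "chromatin",
                     file.path(outdir, c("h3k4me3_scores.tsv",
                                         "promoter_enrichment.tsv")))
      },
      ncrna = {
        d <- get_ds()
        rrp6_tracks <- Filter(function(t)
          t$condition == ana$conditions[2L], d$tracks)
        wt_tracks <- Filter(function(t)
          t$condition == ana$conditions[1L], d$tracks)
        mean_rrp6 <- average_tracks(rrp6_tracks)
        segs <- segment_track(mean_rrp6, ana$seg_min_level,
                              ana$seg_max_gap, ana$min_ncrna_len,
                              config$synthetic$probe_step)
        nc <- annotate_ncrnas(segs, d$genes, wt_tracks, rrp6_tracks,
                              ana$fold_threshold, ana$min_ncrna_len,
                              ana$seg_min_level)
        write_table(as.data.frame(nc), file.path(outdir, "ncrnas.tsv"))
        manifest_add(outdir, "ncrna", file.path(outdir, "ncrnas.tsv"))
      },
      evaluate = {
        d <- get_ds()
        cls <- read_table(
          need_file(file.path(outdir, "classes.tsv"), "classify", stage))
        co_path <- file.path(outdir, "core_genes.tsv")
        core <- if (file.exists(co_path)) {
          co <- read_table(co_path)
          stats::setNames(co$core, co$gene_id)
        } else NULL
        tc <- truth_compare(stats::setNames(factor(cls$class,
                                                   class_levels),
                                            cls$gene_id),
                            d$truth$genes, core = core)
        ev <- data.frame(class = names(tc$recall),
                         recall = unname(tc$recall),
                         precision = unname(tc$precision),
                         core_recall = if (is.null(tc$core_recall))
                           NA_real_ else unname(tc$core_recall))
        write_table(ev, file.path(outdir, "evaluation.tsv"))
        manifest_add(outdir, "evaluate", file.path(outdir, "evaluation.tsv"))
        pipeline_log(stage, paste0("core recall: ",
          paste(sprintf("%s=%.2f", ev$class, ev$core_recall),
                collapse = " ")))
      })
    pipeline_log(stage, "done")
  }
  invisible(outdir)
}

#' Average replicate tracks into one track
#'
#' Probe-wise mean of tracks sharing a probe grid (per chromosome/strand
#' key, positions must agree).
#'
#' @param tracks List of [signal_track()]s.
#' @return A [signal_track()] with condition of the first track.
#' @export
average_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  keys <- ls(tracks[[1L]]$data)
  chrom <- character(0); strand <- character(0)
  pos <- numeric(0); val <- numeric(0)
  for (k in keys) {
    ds <- lapply(tracks, function(t) get(k, envir = t$data))
    p <- ds[[1L]]$pos
    for (d in ds) stopifnot(identical(d$pos, p))
    v <- rowMeans(do.call(cbind, lapply(ds, `[[`, "val")))
    chrom <- c(chrom, rep(sub("\\|.*$", "", k), length(p)))
    strand <- c(strand, rep(sub("^.*\\|", "", k), length(p)))
    pos <- c(pos, p)
    val <- c(val, v)
  }
  signal_track(paste0("mean_", tracks[[1L]]$condition),
               tracks[[1L]]$condition, 1L, chrom, strand, pos, val)
}
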