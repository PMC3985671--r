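#' Strand-resolved signal track
#'
#' Holds per-position log2 intensities (or linear counts, for binding
#' data) for one sample, keyed by (chromosome, strand).  Positions are
#' 0-based probe start coordinates and must be strictly increasing within
#' each key; unsorted input is sorted with a warning.  Strand `"*"` is
#' allowed for strandless (chromatin) tracks.
#'
#' @param sample_id Sample identifier.
#' @param condition Strain label.
#' @param replicate Replicate number.
#' @param chrom,strand,pos,value Parallel vectors describing the probes.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(sample_id, condition = sample_id, replicate = 1L,
                         chrom, strand, pos, value) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  if (length(strand) == 1L) strand <- rep(strand, length(pos))
  stopifnot(length(chrom) == length(pos), length(strand) == length(pos),
            length(value) == length(pos))
  if (any(!is.finite(value))) stop("intensities must be finite")
  key <- paste0(chrom, "|", strand)
  data <- new.env(parent = emptyenv())
  warned <- FALSE
  for (k in unique(key)) {
    i <- which(key == k)
    p <- as.numeric(pos[i]); v <- as.numeric(value[i])
    if (is.unsorted(p, strictly = TRUE)) {
      if (anyDuplicated(p)) stop("duplicate probe position in ", k)
      if (!warned) { warning("unsorted probe positions; sorting"); warned <- TRUE }
      o <- order(p); p <- p[o]; v <- v[o]
    }
    assign(k, list(pos = p, val = v, cum = cumsum(v)), envir = data)
  }
  structure(list(sample_id = sample_id, condition = condition,
                 replicate = as.integer(replicate), data = data),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  keys <- ls(x$data)
  n <- sum(vapply(keys, function(k) length(get(k, envir = x$data)$pos), 0))
  cat(sprintf("<signal_track %s (%s, rep %d): %d probes on %d chrom/strand keys>\n",
              x$sample_id, x$condition, x$replicate, n, length(keys)))
  invisible(x)
}

track_key <- function(track, chrom, strand) {
  k <- paste0(chrom, "|", strand)
  if (!exists(k, envir = track$data, inherits = FALSE)) return(NULL)
  get(k, envir = track$data, inherits = FALSE)
}

.signal_log <- new.env(parent = emptyenv())

log_unknown_key_once <- function(chrom, strand) {
  k <- paste0(chrom, "|", strand)
  if (is.null(.signal_log[[k]])) {
    .signal_log[[k]] <- TRUE
    message("no signal stored for ", chrom, " strand ", strand)
  }
}

#' Mean signal in a genomic interval
#'
#' Arithmetic mean of probe values with position in `[start, end)` on the
#' given strand.  Returns `NA` when no probe falls in the interval or the
#' (chromosome, strand) key is unknown (the latter is logged once per key).
#'
#' @param track A [signal_track()].
#' @param chrom,start,end,strand Query interval (0-based half-open).
#' @return Mean log2 intensity, or `NA_real_`.
#' @export
region_signal <- function(track, chrom, start, end, strand) {
  if (start >= end) {
    if (start > end) stop("start must be < end")
    return(NA_real_)
  }
  d <- track_key(track, chrom, strand)
  if (is.null(d)) {
    log_unknown_key_once(chrom, strand)
    return(NA_real_)
  }
  lo <- findInterval(start - 0.5, d$pos)
  hi <- findInterval(end - 0.5, d$pos)
  if (hi <= lo) return(NA_real_)
  tot <- if (lo == 0) d$cum[hi] else d$cum[hi] - d$cum[lo]
  tot / (hi - lo)
}

# Per-bin means for a run of consecutive bins given by `edges` (ascending
# genomic coordinates, length nbins+1).  Returns a numeric vector with NA
# for empty bins.  Workhorse behind feature binning and metagenes.
region_bin_means <- function(track, chrom, strand, edges) {
  nb <- length(edges) - 1L
  d <- track_key(track, chrom, strand)
  if (is.null(d)) {
    log_unknown_key_once(chrom, strand)
    return(rep(NA_real_, nb))
  }
  idx <- findInterval(edges - 0.5, d$pos)
  cnt <- diff(idx)
  cum0 <- c(0, d$cum)
  tot <- cum0[idx[-1L] + 1L] - cum0[idx[-length(idx)] + 1L]
  out <- tot / cnt
  out[cnt == 0L] <- NA_real_
  out
}

# Sum of track values in [start, end) (used for PAR-CLiP binding).
region_sum <- function(track, chrom, start, end, strand) {
  d <- track_key(track, chrom, strand)
  if (is.null(d)) {
    log_unknown_key_once(chrom, strand)
    return(NA_real_)
  }
  lo <- findInterval(start - 0.5, d$pos)
  hi <- findInterval(end - 0.5, d$pos)
  if (hi <= lo) return(0)
  if (lo == 0) d$cum[hi] else d$cum[hi] - d$cum[lo]
}

#' Read a signal track
#'
#' Reads bedGraph or wiggle (fixedStep/variableStep, honouring `span`)
#' files.  Each covered interval is expanded to probes spaced `probe_step`
#' bp apart starting at the interval start, so a bedGraph line
#' `chrI 100 120 1.5` at `probe_step = 20` yields one probe at position
#' 100.  Strand is taken from the `strand` argument; stranded data are
#' conventionally stored as file pairs `*.plus.bedgraph` /
#' `*.minus.bedgraph` (see [read_stranded_track()]).
#'
#' @param path File path.
#' @param format `"bedGraph"` or `"wig"`; guessed from the extension by
#'   default.
#' @param strand Strand to store the values under.
#' @param probe_step Probe spacing used to expand covered intervals.
#' @param sample_id,condition,replicate Track metadata.
#' @return A [signal_track()].
#' @export
read_track <- function(path, format = c("auto", "bedGraph", "wig"),
                       strand = "*", probe_step = 1L,
                       sample_id = basename(path), condition = sample_id,
                       replicate = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(wig|wiggle)$", path, ignore.case = TRUE))
      "wig" else "bedGraph"
  }
  gr <- rtracklayer::import(path, format = if (format == "wig") "wig" else "bedGraph")
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  s <- BiocGenerics::start(gr) - 1L  # to 0-based
  e <- BiocGenerics::end(gr)
  v <- as.numeric(gr$score)
  if (any(!is.finite(v))) stop("non-numeric signal value in ", path)
  reps <- pmax(1L, ceiling((e - s) / probe_step))
  pos <- unlist(lapply(seq_along(s), function(i) {
    seq(s[i], e[i] - 1L, by = probe_step)
  }))
  val <- rep(v, reps)
  signal_track(sample_id, condition, replicate,
               chrom = rep(chrom, reps), strand = strand, pos = pos, val)
}

#' Read a stranded track from a plus/minus bedGraph file pair
#'
#' @param prefix Path prefix; `<prefix>.plus.bedgraph` and
#'   `<prefix>.minus.bedgraph` must exist.
#' @inheritParams read_track
#' @return A [signal_track()] with `+` and `-` keys.
#' @export
read_stranded_track <- function(prefix, probe_step = 1L,
                                sample_id = basename(prefix),
                                condition = sample_id, replicate = 1L) {
  tp <- read_track(paste0(prefix, ".plus.bedgraph"), "bedGraph", "+",
                   probe_step, sample_id, condition, replicate)
  tm <- read_track(paste0(prefix, ".minus.bedgraph"), "bedGraph", "-",
                   probe_step, sample_id, condition, replicate)
  for (k in ls(tm$data)) assign(k, get(k, envir = tm$data), envir = tp$data)
  tp
}

#' Write a signal track as bedGraph
#'
#' One line per probe (interval `[pos, pos + probe_step)`), values printed
#' with enough digits for a 6-decimal round trip.  Stranded tracks are
#' written as a `*.plus.bedgraph` / `*.minus.bedgraph` pair; strandless
#' tracks as a single file.
#'
#' @param track A [signal_track()].
#' @param prefix Output path prefix (or full path for strandless tracks).
#' @param probe_step Probe footprint in bp.
#' @return Invisibly, the paths written.
#' @export
write_track <- function(track, prefix, probe_step = 1L) {
  keys <- ls(track$data)
  strands <- unique(sub("^.*\\|", "", keys))
  paths <- character(0)
  for (st in strands) {
    suffix <- switch(st, "+" = ".plus.bedgraph", "-" = ".minus.bedgraph",
                     ".bedgraph")
    path <- if (st == "*" && grepl("\\.bedgraph$", prefix)) prefix
            else paste0(prefix, suffix)
    kk <- keys[endsWith(keys, paste0("|", st))]
    dt <- data.table::rbindlist(lapply(kk, function(k) {
      d <- get(k, envir = track$data)
      data.table::data.table(chrom = sub("\\|.*$", "", k),
                             start = as.integer(d$pos),
                             end = as.integer(d$pos + probe_step),
                             value = sprintf("%.6f", d$val))
    }))
    data.table::setorder(dt, chrom, start)
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read/write plain TSV tables
#'
#' Thin wrappers with a header row, used for all matrices and annotation
#' tables the pipeline exchanges.
#'
#' @param path File path.
#' @param x Data frame to write.
#' @return `read_table()` returns a `data.frame`.
#' @export
read_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_table
#' @export
write_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Segment a track into expressed regions
#'
#' Plumbing segmenter: maximal runs of probes at or above `min_level` on
#' one strand, merging runs whose gap is below `max_gap`, and discarding
#' segments shorter than `min_len` bp.  Segment ends extend `probe_step`
#' bp past the last probe start.
#'
#' @param track A [signal_track()] (typically the exosome-mutant mean).
#' @param min_level Expression threshold (log2 units).
#' @param max_gap Maximum probe gap (bp) merged into one segment.
#' @param min_len Minimum segment length in bp.
#' @param probe_step Probe footprint in bp.
#' @return A `data.frame` with `chrom`, `start`, `end`, `strand`.
#' @export
segment_track <- function(track, min_level, max_gap = 50L, min_len = 200L,
                          probe_step = 1L) {
  out <- list()
  for (k in sort(ls(track$data))) {
    d <- get(k, envir = track$data)
    chrom <- sub("\\|.*$", "", k)
    strand <- sub("^.*\\|", "", k)
    hi <- which(d$val >= min_level)
    if (!length(hi)) next
    p <- d$pos[hi]
    brk <- which(diff(p) >= max_gap)
    starts <- p[c(1L, brk + 1L)]
    ends <- p[c(brk, length(p))] + probe_step
    keep <- (ends - starts) >= min_len
    if (any(keep)) {
      out[[k]] <- data.frame(chrom = chrom, start = starts[keep],
                             end = ends[keep], strand = strand,
                             stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$strand, res$start), , drop = FALSE]
}
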