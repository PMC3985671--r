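#' Gene records
#'
#' The annotation container: one row per ORF with 0-based half-open
#' coordinates and transcript anchors.  For a `+` gene the TSS is the
#' interval start and the TTS the interval end; for a `-` gene the anchors
#' are swapped (the anchors are boundary coordinates under the half-open
#' convention).
#'
#' @param gene_id,chrom Character vectors.
#' @param start,end Integer 0-based half-open coordinates, `start < end`.
#' @param strand `"+"` or `"-"`.
#' @return A `data.frame` of class `gene_records` with columns `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `tss`, `tts`, ordered by
#'   (chrom, start).
#' @export
gene_records <- function(gene_id, chrom, start, end, strand) {
  start <- as.integer(start); end <- as.integer(end)
  gene_id <- as.character(gene_id); chrom <- as.character(chrom)
  strand <- as.character(strand)
  if (any(is.na(start)) || any(is.na(end))) stop("non-integer coordinates")
  if (any(start >= end)) {
    bad <- gene_id[start >= end][1L]
    stop("start must be < end (gene ", bad, ")")
  }
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id: ", gene_id[duplicated(gene_id)][1L])
  }
  tss <- ifelse(strand == "+", start, end)
  tts <- ifelse(strand == "+", end, start)
  df <- data.frame(gene_id = gene_id, chrom = chrom, start = start,
                   end = end, strand = strand, tss = as.integer(tss),
                   tts = as.integer(tts), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$gene_id), , drop = FALSE]
  rownames(df) <- df$gene_id
  class(df) <- c("gene_records", "data.frame")
  df
}

#' Read a gene annotation
#'
#' Reads BED6/BED12 or GFF3 into [gene_records()].  BED coordinates are
#' taken as-is (already 0-based half-open); GFF3 coordinates are shifted
#' from 1-based closed to 0-based half-open on read.  For GFF3, features of
#' type `gene` are used and the identifier is taken from the `ID` (or
#' `Name`) attribute.
#'
#' @param path File path.
#' @param format `"BED"` or `"GFF3"`; guessed from the extension when
#'   missing.
#' @return A [gene_records()] data frame.
#' @export
read_annotation <- function(path, format = c("auto", "BED", "GFF3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "GFF3" else "BED"
  }
  if (format == "BED") {
    lines <- readLines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 6L)) {
      stop("malformed BED line ", which(keep)[which(nf < 6L)[1L]],
           ": fewer than 6 fields")
    }
    m <- do.call(rbind, lapply(fields, `[`, 1:6))
    start <- suppressWarnings(as.integer(m[, 2L]))
    end <- suppressWarnings(as.integer(m[, 3L]))
    if (any(is.na(start) | is.na(end))) {
      stop("malformed BED line ", which(keep)[which(is.na(start) | is.na(end))[1L]],
           ": non-numeric coordinates")
    }
    gene_records(m[, 4L], m[, 1L], start, end, m[, 6L])
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    if ("type" %in% names(S4Vectors::mcols(gr))) {
      sel <- as.character(gr$type) == "gene"
      if (any(sel)) gr <- gr[sel]
    }
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
    if (anyNA(ids)) stop("GFF3 gene feature without ID/Name attribute")
    gene_records(ids, as.character(GenomeInfoDb::seqnames(gr)),
                 BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr),
                 as.character(BiocGenerics::strand(gr)))
  }
}

#' Write gene records as BED6
#'
#' @param genes A [gene_records()] data frame.
#' @param path Output path.
#' @export
write_annotation <- function(genes, path) {
  stopifnot(inherits(genes, "gene_records"))
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", genes$chrom, genes$start,
                   genes$end, genes$gene_id, genes$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Resolve an anchored window to genomic coordinates
#'
#' Offsets are applied in transcript orientation (downstream is the
#' direction of sense transcription), so the same window definition lands
#' on opposite genomic sides of the anchor for `+` and `-` genes.
#' `target_strand = "sense"` returns the gene's own strand; `"antisense"`
#' the opposite strand.
#'
#' @param gene One row of a [gene_records()] data frame (or a list with
#'   `chrom`, `strand`, `tss`, `tts`).
#' @param window A [genomic_window()].
#' @param chrom_len Optional chromosome length for clipping.
#' @return A list with `chrom`, `start`, `end` (0-based half-open, clipped
#'   to the chromosome when `chrom_len` is given) and `strand`.  A window
#'   entirely off-chromosome yields `start == end`.
#' @examples
#' g <- gene_records("g1", "chrI", 999, 2000, "+")
#' resolve_window(g[1, ], genomic_window("TSS", -100, 750, "sense"))
#' @export
resolve_window <- function(gene, window, chrom_len = NULL) {
  stopifnot(inherits(window, "genomic_window"))
  anchor <- if (window$anchor == "TSS") gene$tss else gene$tts
  if (gene$strand == "+") {
    gstart <- anchor + window$offset_start
    gend <- anchor + window$offset_end
    out_strand <- if (window$target_strand == "sense") "+" else "-"
  } else {
    gstart <- anchor - window$offset_end
    gend <- anchor - window$offset_start
    out_strand <- if (window$target_strand == "sense") "-" else "+"
  }
  if (!is.null(chrom_len)) {
    gstart <- max(gstart, 0L)
    gend <- min(gend, chrom_len)
  } else {
    gstart <- max(gstart, 0L)
  }
  if (gend < gstart) gend <- gstart
  list(chrom = gene$chrom, start = as.integer(gstart), end = as.integer(gend),
       strand = out_strand)
}

#' Exclude convergent overlapping gene pairs
#'
#' A gene is excluded when it overlaps (shared interval > 0 bp) a gene on
#' the opposite strand whose transcription is oriented toward it, i.e. the
#' two 3' ends face each other inside or beyond the shared region.  Both
#' members of such a pair are removed.  Tandem (same-strand) overlaps are
#' kept.
#'
#' @param genes A [gene_records()] data frame.
#' @return A list with elements `kept` and `excluded`, both
#'   [gene_records()]-shaped.
#' @export
exclude_convergent_overlapping <- function(genes) {
  stopifnot(inherits(genes, "gene_records"))
  plus <- genes[genes$strand == "+", , drop = FALSE]
  minus <- genes[genes$strand == "-", , drop = FALSE]
  bad <- character(0)
  if (nrow(plus) && nrow(minus)) {
    for (chr in intersect(unique(plus$chrom), unique(minus$chrom))) {
      p <- plus[plus$chrom == chr, , drop = FALSE]
      m <- minus[minus$chrom == chr, , drop = FALSE]
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(p$start + 1L, p$end),
        IRanges::IRanges(m$start + 1L, m$end),
        minoverlap = 1L)
      if (length(ov)) {
        pi <- S4Vectors::queryHits(ov)
        mi <- S4Vectors::subjectHits(ov)
        # convergent: the + gene's 3' end (its end) is at or beyond the
        # - gene's 3' end (its start), so the 3' ends face each other
        conv <- p$tts[pi] >= m$tts[mi]
        bad <- c(bad, p$gene_id[pi[conv]], m$gene_id[mi[conv]])
      }
    }
  }
  bad <- unique(bad)
  list(kept = genes[!genes$gene_id %in% bad, , drop = FALSE],
       excluded = genes[genes$gene_id %in% bad, , drop = FALSE])
}
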