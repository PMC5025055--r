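#' Read and write package tables
#'
#' Plain TSV readers/writers for the exchange tables: gene annotation,
#' counts with sample metadata, motif hits and simulation truth. All
#' writers emit deterministic, locale-independent TSV (no quoting, "."
#' decimal, fixed column order) so reruns are byte-identical.
#'
#' @name tsv-io
NULL

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_plain <- function(path, colClasses = NA) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = colClasses)
}

#' @rdname tsv-io
#' @param ann a [gene_annotation()] table.
#' @param path file path.
#' @export
write_annotation <- function(ann, path) {
  write_tsv_plain(as.data.frame(ann)[, c("gene_id", "chrom", "start",
                                         "end", "strand", "tss")], path)
}

#' @rdname tsv-io
#' @export
read_annotation <- function(path) gene_annotation(read_tsv_plain(path))

#' @rdname tsv-io
#' @param cm a [count_matrix()].
#' @param prefix path prefix; writes `<prefix>_counts.tsv` and
#'   `<prefix>_samples.tsv`.
#' @export
write_counts <- function(cm, prefix) {
  cdf <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_plain(cdf, paste0(prefix, "_counts.tsv"))
  sdf <- cm$samples
  sdf$lib_size <- cm$lib_size
  write_tsv_plain(sdf, paste0(prefix, "_samples.tsv"))
  invisible(prefix)
}

#' @rdname tsv-io
#' @export
read_counts <- function(prefix) {
  cdf <- read_tsv_plain(paste0(prefix, "_counts.tsv"))
  sdf <- read_tsv_plain(paste0(prefix, "_samples.tsv"))
  counts <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(counts) <- cdf$gene_id
  count_matrix(counts, group = sdf$group, pair = sdf$pair,
               condition = sdf$condition, lib_size = sdf$lib_size)
}

#' bedGraph track I/O
#'
#' Tracks are exchanged as bedGraph (4-column, 0-based half-open).
#' Reading snaps intervals onto the track's bin grid; browser `track`
#' lines are tolerated and skipped.
#'
#' @param track a [signal_track()].
#' @param path file path.
#' @export
write_bedgraph <- function(track, path) {
  gr <- track_granges(track)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

track_granges <- function(track) {
  ctg <- rep(names(track$bins),
             vapply(track$bins, length, integer(1)))
  idx <- unlist(lapply(track$bins, seq_along), use.names = FALSE)
  GenomicRanges::GRanges(
    seqnames = factor(ctg, levels = names(track$bins)),
    ranges = IRanges::IRanges(
      start = idx * track$bin_size - track$bin_size + 1L,
      width = track$bin_size
    ),
    score = unlist(track$bins, use.names = FALSE)
  )
}

#' @rdname write_bedgraph
#' @param bin_size bin width the values are snapped onto; intervals in the
#'   file must align to this grid.
#' @param sample_id,mark labels attached to the returned track.
#' @export
read_bedgraph <- function(path, bin_size, sample_id = NA_character_,
                          mark = NA_character_) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  bins <- lapply(split(gr, GenomicRanges::seqnames(gr)), function(g) {
    if (length(g) == 0) return(NULL)
    st <- GenomicRanges::start(g)
    en <- GenomicRanges::end(g)
    if (any((st - 1L) %% bin_size != 0L) || any(en %% bin_size != 0L)) {
      stop("bedGraph intervals in ", path,
           " do not align to a ", bin_size, " bp grid")
    }
    v <- numeric(max(en) %/% bin_size)
    first <- (st - 1L) %/% bin_size + 1L
    nbins <- en %/% bin_size - first + 1L
    v[sequence(nbins, from = first)] <- rep(g$score, nbins)
    v
  })
  bins <- Filter(Negate(is.null), bins)
  signal_track(bins, bin_size, sample_id = sample_id, mark = mark)
}

#' narrowPeak I/O
#'
#' narrowPeak is BED6+4 (chrom, start, end, name, score, strand,
#' signalValue, pValue, qValue, peak) with 0-based half-open intervals and
#' the summit given as `peak`, the 0-based offset from `start`. Internally
#' peaks are a data.frame with 1-based closed coordinates and an absolute
#' 1-based `summit` position.
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end`, `summit`,
#'   `score` (and optionally `name`).
#' @param path file path.
#' @export
write_narrowpeak <- function(peaks, path) {
  name <- if (is.null(peaks$name)) {
    sprintf("peak_%d", seq_len(nrow(peaks)))
  } else {
    peaks$name
  }
  df <- data.frame(
    chrom = peaks$chrom,
    start = peaks$start - 1L,            # to 0-based half-open
    end = peaks$end,
    name = name,
    score = round(peaks$score),
    strand = ".",
    signalValue = peaks$score,
    pValue = -1,
    qValue = -1,
    peak = peaks$summit - peaks$start,   # 0-based offset from start
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_narrowpeak
#' @export
read_narrowpeak <- function(path) {
  gr <- rtracklayer::import(
    path, format = "BED",
    extraCols = c(signalValue = "numeric", pValue = "numeric",
                  qValue = "numeric", peak = "integer")
  )
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),    # rtracklayer converts to 1-based
    end = GenomicRanges::end(gr),
    name = if (is.null(gr$name)) NA_character_ else gr$name,
    summit = GenomicRanges::start(gr) + gr$peak,
    score = gr$signalValue,
    stringsAsFactors = FALSE
  )
}

#' @rdname tsv-io
#' @param hits motif hit table (`motif_id`, `family_id`, `chrom`, `start`,
#'   `end`, `strand`, `score`).
#' @export
write_motif_hits <- function(hits, path) write_tsv_plain(hits, path)

#' @rdname tsv-io
#' @export
read_motif_hits <- function(path) {
  # ids like "F" or "T" must not be parsed as logicals
  hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  cc <- c(motif_id = "character", family_id = "character",
          chrom = "character", strand = "character")
  hits <- read_tsv_plain(path, colClasses = cc[names(cc) %in% hdr])
  need <- c("motif_id", "family_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop("motif table missing: ", paste(miss, collapse = ", "))
  hits
}
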