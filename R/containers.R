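#' Gene annotation table
#'
#' Validates and classes a per-gene annotation: one row per gene with its
#' contig, 1-based closed span, strand and transcription start site (TSS).
#' The TSS is the start coordinate for plus-strand genes and the end
#' coordinate for minus-strand genes.
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`"+"` or `"-"`); a `tss` column is recomputed if absent.
#' @return A `gene_annotation` data.frame (adds `tss` if missing).
#' @export
gene_annotation <- function(df) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("annotation is missing columns: ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) stop("duplicated gene_id in annotation")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(df$start > df$end)) stop("annotation has start > end")
  if (is.null(df$tss)) {
    df$tss <- ifelse(df$strand == "+", df$start, df$end)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("Gene annotation: ", nrow(x), " genes on ",
      length(unique(x$chrom)), " contig(s)\n", sep = "")
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Convert a gene annotation to GRanges
#'
#' @param ann a [gene_annotation()] table.
#' @return A `GRanges` with `gene_id` and `tss` metadata columns.
#' @export
annotation_granges <- function(ann) {
  GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start, end = ann$end),
    strand = ann$strand,
    gene_id = ann$gene_id,
    tss = ann$tss
  )
}

#' Count matrix with sample metadata
#'
#' Bundles an integer genes x samples count matrix with the per-sample
#' group labels (and, for paired designs, pair labels) and library sizes.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param group character/factor of length `ncol(counts)`: group per sample.
#' @param pair optional pair label per sample; in a paired design every
#'   pair must contain exactly two samples (control, treated).
#' @param condition optional per-sample condition within a pair
#'   (e.g. `"control"` / `"treated"`); required when `pair` is given.
#' @param lib_size per-sample library size; defaults to column sums.
#' @return A `count_matrix` object (list with `counts`, `samples`,
#'   `lib_size`).
#' @export
count_matrix <- function(counts, group, pair = NULL, condition = NULL,
                         lib_size = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts needs rownames (gene ids)")
  if (is.null(colnames(counts))) stop("counts needs colnames (sample ids)")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  group <- as.character(group)
  if (length(group) != ncol(counts)) stop("one group label per sample")
  if (!is.null(pair)) {
    pair <- as.character(pair)
    if (length(pair) != ncol(counts)) stop("one pair label per sample")
    if (is.null(condition)) stop("paired design needs per-sample condition")
    condition <- as.character(condition)
    tab <- table(pair)
    if (any(tab != 2)) {
      stop("every pair must have exactly 2 samples: ",
           paste(names(tab)[tab != 2], collapse = ", "))
    }
  }
  if (is.null(lib_size)) lib_size <- colSums(counts)
  samples <- data.frame(
    sample_id = colnames(counts), group = group,
    stringsAsFactors = FALSE
  )
  if (!is.null(pair)) {
    samples$pair <- pair
    samples$condition <- condition
  }
  structure(
    list(counts = counts, samples = samples, lib_size = lib_size),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("Count matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("Groups:", paste(sprintf("%s (n=%d)", names(table(x$samples$group)),
                               table(x$samples$group)), collapse = ", "), "\n")
  if (!is.null(x$samples$pair)) {
    cat("Paired design:", length(unique(x$samples$pair)), "pairs\n")
  }
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Binned genome signal track
#'
#' One sample's signal over the genome, stored as one numeric vector of
#' fixed-width bin values per contig. Bin `i` of a contig covers 1-based
#' positions `[(i-1)*bin_size + 1, i*bin_size]`.
#'
#' @param bins named list: contig -> numeric vector of bin values.
#' @param bin_size bin width in bp.
#' @param sample_id sample identifier.
#' @param mark assay label (e.g. `"E2F1"`, `"H3K27ac"`, `"input"`).
#' @return A `signal_track` object.
#' @export
signal_track <- function(bins, bin_size, sample_id = NA_character_,
                         mark = NA_character_) {
  if (!is.list(bins) || is.null(names(bins))) {
    stop("bins must be a named list of per-contig numeric vectors")
  }
  if (any(!vapply(bins, function(v) all(is.finite(v)), logical(1)))) {
    stop("track values must be finite")
  }
  structure(
    list(bins = bins, bin_size = as.integer(bin_size),
         sample_id = sample_id, mark = mark),
    class = "signal_track"
  )
}

#' @export
print.signal_track <- function(x, ...) {
  nb <- sum(vapply(x$bins, length, integer(1)))
  cat("Signal track [", x$mark, "/", x$sample_id, "]: ",
      length(x$bins), " contig(s), ", nb, " bins of ", x$bin_size,
      " bp\n", sep = "")
  invisible(x)
}

# shared helper: total bin count of a track
n_bins <- function(track) sum(vapply(track$bins, length, integer(1)))

# flatten a track's bins into one vector (contig order as stored)
track_values <- function(track) unlist(track$bins, use.names = FALSE)
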