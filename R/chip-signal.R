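#' Signal extraction scaling (SES) factor
#'
#' Background-based ChIP/input scale factor. Bins are sorted by
#' increasing ChIP value; the split point k* maximizes the absolute gap
#' between the cumulative ChIP fraction and the cumulative input
#' fraction (the background/enrichment separation point). The factor is
#' the input mass over the ChIP mass in bins 1..k*, i.e. the
#' multiplier that equalizes background coverage. When several k tie for
#' the maximal gap (e.g. identical tracks) the largest k is used, which
#' includes the full background.
#'
#' @param chip,input [signal_track()]s on the same binning.
#' @return positive scale factor to multiply the ChIP track with.
#' @export
ses_scale_factor <- function(chip, input) {
  if (chip$bin_size != input$bin_size ||
      !identical(lapply(chip$bins, length), lapply(input$bins, length))) {
    stop("chip and input tracks must share the same binning")
  }
  cv <- track_values(chip)
  iv <- track_values(input)
  if (sum(cv > 0 | iv > 0) < 10) stop("need >= 10 non-empty bins")
  tot_c <- sum(cv); tot_i <- sum(iv)
  if (tot_i <= 0) stop("input track ", input$sample_id, " has zero mass")
  if (tot_c <= 0) stop("chip track ", chip$sample_id, " has zero mass")
  o <- order(cv)          # stable; ties keep genomic order
  cum_c <- cumsum(cv[o]) / tot_c
  cum_i <- cumsum(iv[o]) / tot_i
  gap <- abs(cum_c - cum_i)
  k <- max(which(gap >= max(gap) - 1e-12))
  mass_c <- sum(cv[o][1:k])
  mass_i <- sum(iv[o][1:k])
  if (mass_c <= 0) {
    stop("chip track ", chip$sample_id, " has zero background mass")
  }
  mass_i / mass_c
}

#' Input-normalize a ChIP track
#'
#' Per-bin ChIP/input normalization after SES scaling:
#' `log2((chip * factor + pseudocount) / (input + pseudocount))` in
#' `"log2ratio"` mode (default), or the linear ratio in `"ratio"` mode.
#'
#' @param chip,input [signal_track()]s on the same binning.
#' @param factor positive ChIP scale factor, e.g. from
#'   [ses_scale_factor()].
#' @param mode `"log2ratio"` or `"ratio"`.
#' @param pseudocount added to both numerator and denominator.
#' @return a normalized [signal_track()] (keeps the ChIP track's labels).
#' @export
normalize_track <- function(chip, input, factor = ses_scale_factor(chip, input),
                            mode = c("log2ratio", "ratio"), pseudocount = 1) {
  mode <- match.arg(mode)
  if (factor <= 0) stop("scale factor must be positive")
  bins <- lapply(names(chip$bins), function(ctg) {
    r <- (chip$bins[[ctg]] * factor + pseudocount) /
      (input$bins[[ctg]] + pseudocount)
    if (mode == "log2ratio") log2(r) else r
  })
  names(bins) <- names(chip$bins)
  signal_track(bins, chip$bin_size, sample_id = chip$sample_id,
               mark = chip$mark)
}

# bin indices covering 1-based closed interval [lo, hi] on a contig
bin_window <- function(lo, hi, bin_size, nbin) {
  b1 <- max(1L, (as.integer(lo) - 1L) %/% bin_size + 1L)
  b2 <- min(nbin, (as.integer(hi) - 1L) %/% bin_size + 1L)
  if (b1 > b2) integer(0) else b1:b2
}

#' Promoter score: track maximum around the TSS
#'
#' Per gene, the maximum bin value over all bins intersecting the
#' inclusive window `[tss - half_window, tss + half_window]`, clipped at
#' contig edges. Genes on contigs absent from the track get `NA`.
#'
#' @param track a (normalized) [signal_track()].
#' @param ann a [gene_annotation()].
#' @param half_window half-width of the TSS window in bp (default 2000).
#' @return named numeric vector of scores, one per gene.
#' @export
tss_score <- function(track, ann, half_window = 2000) {
  out <- rep(NA_real_, nrow(ann))
  names(out) <- ann$gene_id
  unknown <- !(ann$chrom %in% names(track$bins))
  if (any(unknown)) {
    message(sum(unknown), " gene(s) on contigs absent from track ",
            track$sample_id, "; scored NA")
  }
  for (ctg in unique(ann$chrom[!unknown])) {
    v <- track$bins[[ctg]]
    idx <- which(ann$chrom == ctg)
    for (i in idx) {
      w <- bin_window(ann$tss[i] - half_window, ann$tss[i] + half_window,
                      track$bin_size, length(v))
      if (length(w)) out[i] <- max(v[w])
    }
  }
  out
}

# max track value over a 1-based closed region; NA if contig unknown
region_max <- function(track, chrom, lo, hi) {
  v <- track$bins[[chrom]]
  if (is.null(v)) return(NA_real_)
  w <- bin_window(lo, hi, track$bin_size, length(v))
  if (!length(w)) NA_real_ else max(v[w])
}

#' Promoter score table for one mark
#'
#' Collects per-sample TSS scores into a genes x samples matrix, takes
#' arithmetic group means, and assigns a binding tier from the overall
#' mean. Use [group_scale_scores()] afterwards to remove global bias
#' between groups before interpreting group means.
#'
#' @param tracks list of normalized [signal_track()]s, one per sample
#'   (same mark).
#' @param ann a [gene_annotation()].
#' @param group group label per track.
#' @param half_window TSS window half-width in bp.
#' @param tier_thresholds length-2 numeric: low/moderate and
#'   moderate/high boundaries on the overall mean score.
#' @return list of class `promoter_score_table`: `scores` (matrix),
#'   `group`, `mark`, `group_means` (matrix genes x groups),
#'   `overall_mean`, `tier`, `tier_thresholds`, `scale_factor`.
#' @export
promoter_score_table <- function(tracks, ann, group, half_window = 2000,
                                 tier_thresholds = c(2, 4)) {
  if (length(tracks) != length(group)) stop("one group label per track")
  scores <- vapply(tracks, tss_score, numeric(nrow(ann)),
                   ann = ann, half_window = half_window)
  colnames(scores) <- vapply(tracks, function(t) t$sample_id, character(1))
  rownames(scores) <- ann$gene_id
  tbl <- structure(
    list(scores = scores, group = as.character(group),
         mark = tracks[[1]]$mark, tier_thresholds = tier_thresholds,
         scale_factor = NA_real_),
    class = "promoter_score_table"
  )
  refresh_score_summary(tbl)
}

refresh_score_summary <- function(tbl) {
  groups <- unique(tbl$group)
  gm <- vapply(groups, function(g) {
    rowMeans(tbl$scores[, tbl$group == g, drop = FALSE])
  }, numeric(nrow(tbl$scores)))
  colnames(gm) <- groups
  tbl$group_means <- gm
  tbl$overall_mean <- rowMeans(tbl$scores)
  tbl$tier <- assign_tier(tbl$overall_mean, tbl$tier_thresholds)
  tbl
}

#' @export
print.promoter_score_table <- function(x, ...) {
  cat("Promoter score table [", x$mark, "]: ", nrow(x$scores), " genes x ",
      ncol(x$scores), " samples\n", sep = "")
  cat("Tiers:", paste(sprintf("%s=%d", names(table(x$tier)),
                              table(x$tier)), collapse = ", "), "\n")
  if (!is.na(x$scale_factor)) {
    cat("Group scale factor:", format(x$scale_factor), "\n")
  }
  invisible(x)
}

#' Remove global bias between score groups
#'
#' Estimates a single multiplicative factor between the two groups'
#' promoter scores and applies it to the target group. The factor is the
#' exponentiated median, over genes with positive means in both groups,
#' of `log(mean_ref) - log(mean_target)` -- a robust estimate of the
#' global ratio, so after scaling the median per-gene log-ratio is zero.
#'
#' @param tbl a [promoter_score_table()].
#' @param reference_group,target_group group labels; the target group's
#'   scores are multiplied by the factor.
#' @return the rescaled table, with the factor in `$scale_factor`; group
#'   means, overall means and tiers are recomputed.
#' @export
group_scale_scores <- function(tbl, reference_group, target_group) {
  gm <- tbl$group_means
  if (!all(c(reference_group, target_group) %in% colnames(gm))) {
    stop("unknown group label")
  }
  mref <- gm[, reference_group]
  mtar <- gm[, target_group]
  ok <- mref > 0 & mtar > 0
  if (!any(ok)) stop("no genes with positive means in both groups")
  f <- exp(stats::median(log(mref[ok]) - log(mtar[ok])))
  sel <- tbl$group == target_group
  tbl$scores[, sel] <- tbl$scores[, sel] * f
  tbl$scale_factor <- f
  refresh_score_summary(tbl)
}

#' Binding tier from the mean promoter score
#'
#' Partition of the overall mean score into `low` (score < 2),
#' `moderate` (2 <= score <= 4) and `high` (score > 4) binding, with
#' configurable boundaries.
#'
#' @param score numeric vector of mean promoter scores.
#' @param thresholds length-2 boundaries `c(low_upper, moderate_upper)`.
#' @return character vector of tiers.
#' @export
assign_tier <- function(score, thresholds = c(2, 4)) {
  ifelse(score < thresholds[1], "low",
         ifelse(score <= thresholds[2], "moderate", "high"))
}

#' Consensus peak set across samples
#'
#' Merges peak calls from several samples by single-linkage on >= 1 bp
#' overlap, discards merged regions supported by fewer than
#' `min_support` distinct samples, scores the survivors by the maximum
#' normalized intensity within the region, and returns the top `top_n`
#' regions sorted by decreasing intensity (ties broken by genomic
#' coordinate).
#'
#' @param peaksets either a single data.frame with a `sample_id` column
#'   or a named list of per-sample peak data.frames (`chrom`, `start`,
#'   `end`, `summit`, `score`).
#' @param min_support minimum number of distinct supporting samples.
#' @param top_n maximum number of regions returned.
#' @param intensity optional normalized [signal_track()] used to score
#'   regions; when `NULL`, the maximum member peak score is used.
#' @return data.frame: `chrom`, `start`, `end`, `n_support`,
#'   `intensity`, sorted by decreasing intensity.
#' @export
consensus_peaks <- function(peaksets, min_support = 2, top_n = 500,
                            intensity = NULL) {
  if (is.data.frame(peaksets)) {
    if (is.null(peaksets$sample_id)) stop("need a sample_id column")
    all_peaks <- peaksets
  } else {
    if (length(peaksets) < min_support) {
      stop("fewer peak sets than min_support")
    }
    ids <- names(peaksets)
    if (is.null(ids)) ids <- paste0("sample", seq_along(peaksets))
    all_peaks <- do.call(rbind, lapply(seq_along(peaksets), function(i) {
      p <- peaksets[[i]]
      p$sample_id <- ids[i]
      p
    }))
  }
  if (nrow(all_peaks) == 0) {
    warning("no peaks supplied")
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_support = integer(),
                      intensity = numeric()))
  }
  gr <- GenomicRanges::GRanges(
    all_peaks$chrom, IRanges::IRanges(all_peaks$start, all_peaks$end)
  )
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(merged, gr)
  support <- vapply(split(S4Vectors::subjectHits(hits),
                          S4Vectors::queryHits(hits)),
                    function(i) length(unique(all_peaks$sample_id[i])),
                    integer(1))
  n_support <- integer(length(merged))
  n_support[as.integer(names(support))] <- support
  keep <- n_support >= min_support
  if (!any(keep)) {
    warning("no merged region reaches min_support = ", min_support)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_support = integer(),
                      intensity = numeric()))
  }
  merged <- merged[keep]
  n_support <- n_support[keep]
  res <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged),
    end = GenomicRanges::end(merged),
    n_support = n_support,
    stringsAsFactors = FALSE
  )
  if (is.null(intensity)) {
    hits2 <- GenomicRanges::findOverlaps(merged, gr)
    res$intensity <- vapply(split(S4Vectors::subjectHits(hits2),
                                  S4Vectors::queryHits(hits2)),
                            function(i) max(all_peaks$score[i]),
                            numeric(1))
  } else {
    res$intensity <- mapply(region_max, res$chrom, res$start, res$end,
                            MoreArgs = list(track = intensity))
  }
  o <- order(-res$intensity, res$chrom, res$start)
  res <- res[o, , drop = FALSE]
  rownames(res) <- NULL
  utils::head(res, top_n)
}

#' Annotate peaks relative to genes
#'
#' Classifies each peak by its summit (midpoint when no summit): a
#' `promoter` peak lies within +/- `promoter_half_window` of some TSS, a
#' `gene_body` peak within some gene span, anything else is
#' `intergenic`. Also reports the signed distance from the summit to the
#' nearest TSS, oriented in the transcription direction (negative =
#' upstream of the TSS).
#'
#' @param peaks data.frame with `chrom`, `start`, `end` and optionally
#'   `summit`.
#' @param ann a [gene_annotation()].
#' @param promoter_half_window promoter half-width in bp (default 2000).
#' @return the peak table with `category`, `nearest_gene` and
#'   `tss_distance` columns added.
#' @export
annotate_peaks <- function(peaks, ann, promoter_half_window = 2000) {
  if (nrow(ann) == 0) stop("annotation is empty")
  summit <- if (is.null(peaks$summit)) {
    (peaks$start + peaks$end) %/% 2
  } else {
    ifelse(is.na(peaks$summit), (peaks$start + peaks$end) %/% 2,
           peaks$summit)
  }
  sgr <- GenomicRanges::GRanges(peaks$chrom,
                                IRanges::IRanges(summit, summit))
  tss_gr <- GenomicRanges::GRanges(
    ann$chrom,
    IRanges::IRanges(pmax(1L, ann$tss - promoter_half_window),
                     ann$tss + promoter_half_window)
  )
  body_gr <- annotation_granges(ann)
  in_prom <- IRanges::overlapsAny(sgr, tss_gr)
  in_body <- IRanges::overlapsAny(sgr, body_gr, ignore.strand = TRUE)
  category <- ifelse(in_prom, "promoter",
                     ifelse(in_body, "gene_body", "intergenic"))
  tss_pt <- GenomicRanges::GRanges(ann$chrom,
                                   IRanges::IRanges(ann$tss, ann$tss))
  near <- GenomicRanges::nearest(sgr, tss_pt, select = "arbitrary")
  tss_distance <- rep(NA_real_, nrow(peaks))
  nearest_gene <- rep(NA_character_, nrow(peaks))
  ok <- !is.na(near)
  if (any(ok)) {
    g <- near[ok]
    raw <- summit[ok] - ann$tss[g]
    tss_distance[ok] <- ifelse(ann$strand[g] == "+", raw, -raw)
    nearest_gene[ok] <- ann$gene_id[g]
  }
  peaks$category <- category
  peaks$nearest_gene <- nearest_gene
  peaks$tss_distance <- tss_distance
  peaks
}
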