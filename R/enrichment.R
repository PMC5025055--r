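#' Genes with a motif hit in their promoter
#'
#' @param hits motif hit table (`motif_id`, `family_id`, `chrom`,
#'   `start`, `end`).
#' @param ann a [gene_annotation()].
#' @param half_window promoter half-width around the TSS in bp.
#' @return data.frame of (`motif_id`, `family_id`, `gene_id`) pairs, one
#'   row per motif x promoter overlap.
#' @export
promoter_motif_hits <- function(hits, ann, half_window = 2000) {
  if (nrow(hits) == 0) {
    return(data.frame(motif_id = character(), family_id = character(),
                      gene_id = character()))
  }
  mgr <- GenomicRanges::GRanges(hits$chrom,
                                IRanges::IRanges(hits$start, hits$end))
  pgr <- GenomicRanges::GRanges(
    ann$chrom,
    IRanges::IRanges(pmax(1L, ann$tss - half_window),
                     ann$tss + half_window)
  )
  ov <- GenomicRanges::findOverlaps(mgr, pgr)
  data.frame(
    motif_id = hits$motif_id[S4Vectors::queryHits(ov)],
    family_id = hits$family_id[S4Vectors::queryHits(ov)],
    gene_id = ann$gene_id[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE
  )
}

#' Motif family enrichment between two promoter sets
#'
#' Per motif, a two-sided Fisher test on \[positive-set genes with a hit
#' within `half_window` of the TSS, positive without; negative with,
#' negative without\]. Motif p-values are then collapsed per family with
#' the dual correction `corrected_p = min(best_p * n_motifs, median_p)`
#' (capped at 1) and BH-adjusted across families. Families are ranked by
#' FDR, then corrected p.
#'
#' @param hits motif hit table (`motif_id`, `family_id`, `chrom`,
#'   `start`, `end`).
#' @param set_pos,set_neg disjoint gene sets to contrast.
#' @param ann a [gene_annotation()].
#' @param half_window promoter half-width in bp (default 2000).
#' @return data.frame: `family_id`, `n_motifs`, `best_p`, `median_p`,
#'   `corrected_p`, `fdr`, `direction` (`"pos"`/`"neg"`, the set the
#'   best motif is enriched in).
#' @export
motif_family_enrichment <- function(hits, set_pos, set_neg, ann,
                                    half_window = 2000) {
  if (length(intersect(set_pos, set_neg))) {
    stop("positive and negative gene sets must be disjoint")
  }
  prom <- promoter_motif_hits(hits, ann, half_window)
  motifs <- unique(hits[, c("motif_id", "family_id")])
  if (anyDuplicated(motifs$motif_id)) {
    stop("a motif_id maps to more than one family_id")
  }
  n_pos <- length(set_pos); n_neg <- length(set_neg)
  per_motif <- lapply(seq_len(nrow(motifs)), function(i) {
    g <- unique(prom$gene_id[prom$motif_id == motifs$motif_id[i]])
    a <- sum(set_pos %in% g); b <- n_pos - a
    cc <- sum(set_neg %in% g); d <- n_neg - cc
    data.frame(
      motif_id = motifs$motif_id[i], family_id = motifs$family_id[i],
      p = fisher_exact_2x2(c(a, b, cc, d))$p,
      direction = if (a / max(n_pos, 1) >= cc / max(n_neg, 1)) "pos" else "neg",
      stringsAsFactors = FALSE
    )
  })
  per_motif <- do.call(rbind, per_motif)
  fams <- split(per_motif, per_motif$family_id)
  res <- do.call(rbind, lapply(fams, function(f) {
    best <- which.min(f$p)
    data.frame(
      family_id = f$family_id[1], n_motifs = nrow(f),
      best_p = f$p[best], median_p = stats::median(f$p),
      corrected_p = min(min(f$p[best] * nrow(f), stats::median(f$p)), 1),
      direction = f$direction[best],
      stringsAsFactors = FALSE
    )
  }))
  res$fdr <- bh_adjust(res$corrected_p)
  res <- res[order(res$fdr, res$corrected_p, res$family_id), ]
  rownames(res) <- NULL
  res
}

#' Association between promoter binding and DEG direction
#'
#' Two-sided Fisher test on \[upregulated and bound, upregulated not
#' bound; downregulated and bound, downregulated not bound\], where
#' "bound" means a binding site within the promoter window of the TSS.
#'
#' @param bound gene set with promoter binding.
#' @param deg_up,deg_down up/downregulated gene sets.
#' @return list: `p`, `odds_ratio`, `prop_up_bound`, `prop_down_bound`,
#'   `table` (the 2x2).
#' @export
binding_vs_deg_association <- function(bound, deg_up, deg_down) {
  if (length(deg_up) == 0 || length(deg_down) == 0) {
    stop("both DEG sets must be non-empty")
  }
  a <- sum(deg_up %in% bound); b <- length(deg_up) - a
  cc <- sum(deg_down %in% bound); d <- length(deg_down) - cc
  ft <- fisher_exact_2x2(c(a, b, cc, d))
  list(
    p = ft$p, odds_ratio = ft$odds_ratio,
    prop_up_bound = a / length(deg_up),
    prop_down_bound = cc / length(deg_down),
    table = matrix(c(a, b, cc, d), 2, 2, byrow = TRUE,
                   dimnames = list(c("up", "down"),
                                   c("bound", "unbound")))
  )
}

#' Cross-tabulation of expression categories by binding tier
#'
#' Stacks the binding-tier composition (low / moderate / high) of every
#' combination of basal expression category (`"S>A"`, `"S<A"`, `"S=A"`,
#' `"UN"`) and knockdown response (`"down"`, `"up"`, `"none"`), and runs
#' a headline Fisher test comparing the proportion of moderate-or-high
#' genes between two chosen basal categories (optionally restricted to a
#' knockdown response).
#'
#' @param basal_category per-gene basal category.
#' @param kd_response per-gene knockdown response.
#' @param tier per-gene binding tier (`low`/`moderate`/`high`).
#' @param compare_basal length-2: the two basal categories contrasted in
#'   the headline test (default `c("S>A", "S<A")`).
#' @param compare_kd optional knockdown response both contrasted cells
#'   are restricted to (e.g. `"down"`).
#' @return list of class `category_crosstab`: `counts` (tier x
#'   category matrix), `proportions` (columns sum to 1), `fisher`
#'   (headline test: `p`, `table`, `comparison`).
#' @export
category_crosstab <- function(basal_category, kd_response, tier,
                              compare_basal = c("S>A", "S<A"),
                              compare_kd = NULL) {
  basal_levels <- c("S>A", "S<A", "S=A", "UN")
  kd_levels <- c("down", "up", "none")
  tier_levels <- c("low", "moderate", "high")
  check <- function(x, levels, what) {
    bad <- setdiff(unique(x), levels)
    if (length(bad)) stop("unknown ", what, " label: ",
                          paste(bad, collapse = ", "))
    factor(x, levels = levels)
  }
  b <- check(basal_category, basal_levels, "basal category")
  k <- check(kd_response, kd_levels, "knockdown response")
  tr <- check(tier, tier_levels, "tier")
  col <- interaction(b, k, sep = " / ", lex.order = TRUE)
  counts <- table(tier = tr, category = col)
  csum <- colSums(counts)
  props <- sweep(counts, 2, ifelse(csum == 0, 1, csum), "/")
  sel <- function(cat_b) {
    idx <- b == cat_b
    if (!is.null(compare_kd)) idx <- idx & k == compare_kd
    c(modhigh = sum(idx & tr %in% c("moderate", "high"), na.rm = TRUE),
      low = sum(idx & tr == "low", na.rm = TRUE))
  }
  s1 <- sel(compare_basal[1]); s2 <- sel(compare_basal[2])
  tab <- matrix(c(s1, s2), 2, 2, byrow = TRUE,
                dimnames = list(compare_basal, c("mod_high", "low")))
  structure(list(
    counts = counts, proportions = props,
    fisher = list(p = fisher_exact_2x2(c(s1, s2))$p, table = tab,
                  comparison = list(basal = compare_basal,
                                    kd = compare_kd))
  ), class = "category_crosstab")
}

#' @export
print.category_crosstab <- function(x, ...) {
  cat("Expression category x binding tier cross-tab\n")
  print(x$counts)
  cat(sprintf("Headline Fisher (%s vs %s%s): p = %.3g\n",
              x$fisher$comparison$basal[1], x$fisher$comparison$basal[2],
              if (is.null(x$fisher$comparison$kd)) "" else
                paste0(", kd=", x$fisher$comparison$kd),
              x$fisher$p))
  invisible(x)
}
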