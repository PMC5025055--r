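#' Counts per million
#'
#' @param cm a [count_matrix()].
#' @return numeric matrix of CPM values (count / library size * 1e6).
#' @export
cpm <- function(cm) {
  if (any(cm$lib_size <= 0)) {
    stop("zero or negative library size for sample(s): ",
         paste(cm$samples$sample_id[cm$lib_size <= 0], collapse = ", "))
  }
  sweep(cm$counts, 2, cm$lib_size, "/") * 1e6
}

#' Expression filter on counts per million
#'
#' Retains genes with CPM strictly greater than `min_cpm` in at least
#' `min_samples` samples (the "expressed" universe used downstream).
#' Library sizes are kept at their pre-filter values so CPM is unchanged
#' by filtering.
#'
#' @param cm a [count_matrix()].
#' @param min_cpm CPM threshold (default 1).
#' @param min_samples minimum number of samples above threshold (default 3).
#' @return the filtered [count_matrix()].
#' @export
cpm_filter <- function(cm, min_cpm = 1, min_samples = 3) {
  keep <- rowSums(cpm(cm) > min_cpm) >= min_samples
  out <- cm
  out$counts <- cm$counts[keep, , drop = FALSE]
  out
}

# per-gene log2(CPM + pseudocount)
log2_cpm <- function(cm, pseudocount = 0.5) log2(cpm(cm) + pseudocount)

row_var <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

# median-of-ratios size factors (composition-robust): per sample, the
# median ratio of its counts to the per-gene geometric-mean reference,
# rescaled to geometric mean 1
size_factors_median_ratio <- function(counts) {
  lg <- log(counts)
  ok <- rowSums(!is.finite(lg)) == 0
  if (sum(ok) < 10) return(colSums(counts) / exp(mean(log(colSums(counts)))))
  ref <- rowMeans(lg[ok, , drop = FALSE])
  sf <- apply(exp(lg[ok, , drop = FALSE] - ref), 2, stats::median)
  sf / exp(mean(log(sf)))
}

# common negative-binomial dispersion by conditional maximum likelihood
# on library-size-equalized counts: conditioned on each gene's group
# total the within-group counts are Dirichlet-multinomial with
# concentration 1/phi, which frees the likelihood from the gene means.
# One dispersion is shared across genes (no per-gene shrinkage).
estimate_common_dispersion <- function(y, group) {
  groups <- unique(group)
  neg_cll <- function(log_phi) {
    s <- 1 / exp(log_phi)
    ll <- 0
    for (g in groups) {
      x <- y[, group == g, drop = FALSE]
      n <- ncol(x)
      if (n < 2) next
      t <- rowSums(x)
      ll <- ll + sum(lgamma(n * s) - lgamma(t + n * s) +
                       rowSums(lgamma(x + s)) - n * lgamma(s))
    }
    -ll
  }
  opt <- stats::optimize(neg_cll, interval = log(c(1e-6, 5)))
  exp(opt$minimum)
}

# exact conditional two-group NB test (common dispersion): conditional
# on the gene's total count the group-A sum follows a negative
# hypergeometric law that does not depend on the gene mean; two-sided p
# sums all splits no more probable than the observed one
nb_exact_p <- function(a, b, n1, n2, phi) {
  t <- a + b
  if (t == 0) return(1)
  s1 <- n1 / max(phi, 1e-8)
  s2 <- n2 / max(phi, 1e-8)
  x <- 0:t
  lp <- lgamma(x + s1) - lgamma(x + 1) +
    lgamma(t - x + s2) - lgamma(t - x + 1)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  min(sum(pr[pr <= pr[a + 1] * (1 + 1e-7)]), 1)
}

#' Differential expression tests
#'
#' Per-gene differential expression for the two study designs. For
#' `design = "two_group"` two methods are available: `"nb_exact"`
#' (default), an exact conditional negative-binomial test with a single
#' dispersion shared across genes (estimated by conditional maximum
#' likelihood on median-of-ratios-equalized counts; no per-gene
#' shrinkage), and `"lcpm"`, Welch's t-test on log2(CPM + pseudocount).
#' For `design = "paired"`, `"nb_exact"` runs a conditional
#' beta-binomial score test (per pair, the treated count given the pair
#' total is beta-binomial with concentration 1/dispersion under the
#' null; the pooled centred statistic is normal-approximated) and
#' `"lcpm"` a one-sample t-test on per-pair treated-minus-control
#' log2-CPM differences. In all cases the reported log2 fold change is the
#' difference of mean log2(CPM + pseudocount); a gene passes when
#' |log2fc| >= log2(`fc_cutoff`) (inclusive) and the chosen criterion
#' (raw p or BH FDR) is below `alpha`. Degenerate (constant) genes get
#' p = 1.
#'
#' @param cm a [count_matrix()]; for `"paired"` it must carry `pair` and
#'   `condition` (`"control"`/`"treated"`) sample metadata.
#' @param design `"two_group"` or `"paired"`.
#' @param group_a,group_b group labels for the two-group contrast
#'   (log2fc is A over B); default: first two labels in order of
#'   appearance.
#' @param fc_cutoff linear fold-change cutoff (default 1.3).
#' @param alpha significance level (default 0.05).
#' @param criterion `"p"` for raw p-values or `"fdr"` for BH adjustment.
#' @param method `"nb_exact"` or `"lcpm"` (two-group only).
#' @param pseudocount added to CPM before log2 (default 0.5).
#' @return data.frame of class `de_result`: `gene_id`, `log2fc`, `p`,
#'   `fdr`, `passes`, `direction` (`up`/`down`/`none`).
#' @export
de_test <- function(cm, design = c("two_group", "paired"),
                    group_a = NULL, group_b = NULL,
                    fc_cutoff = 1.3, alpha = 0.05,
                    criterion = c("p", "fdr"),
                    method = c("nb_exact", "lcpm"), pseudocount = 0.5) {
  design <- match.arg(design)
  criterion <- match.arg(criterion)
  method <- match.arg(method)
  lc <- log2_cpm(cm, pseudocount)
  if (design == "two_group") {
    groups <- cm$samples$group
    labs <- unique(groups)
    if (is.null(group_a)) group_a <- labs[1]
    if (is.null(group_b)) group_b <- setdiff(labs, group_a)[1]
    sel1 <- groups == group_a
    sel2 <- groups == group_b
    x <- lc[, sel1, drop = FALSE]
    y <- lc[, sel2, drop = FALSE]
    n1 <- ncol(x); n2 <- ncol(y)
    if (n1 < 2 || n2 < 2) stop("need >= 2 samples per group")
    lfc <- rowMeans(x) - rowMeans(y)
    if (method == "nb_exact") {
      sub <- cm$counts[, sel1 | sel2, drop = FALSE]
      grp <- groups[sel1 | sel2]
      sf <- size_factors_median_ratio(sub)
      yy <- round(sweep(sub, 2, sf, "/"))
      phi <- estimate_common_dispersion(yy, grp)
      a <- rowSums(yy[, grp == group_a, drop = FALSE])
      b <- rowSums(yy[, grp == group_b, drop = FALSE])
      p <- vapply(seq_along(a), function(i) {
        nb_exact_p(a[i], b[i], n1, n2, phi)
      }, numeric(1))
    } else {
      m1 <- rowMeans(x); m2 <- rowMeans(y)
      v1 <- row_var(x); v2 <- row_var(y)
      se2 <- v1 / n1 + v2 / n2
      tt <- lfc / sqrt(se2)
      df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
      p <- 2 * stats::pt(-abs(tt), df)
      p[!is.finite(p)] <- 1   # zero-variance (constant) genes
    }
  } else {
    s <- cm$samples
    if (is.null(s$pair)) stop("paired design needs pair metadata")
    pairs <- unique(s$pair)
    if (length(pairs) < 2) stop("need >= 2 pairs")
    trt <- vapply(pairs, function(pp) {
      which(s$pair == pp & s$condition == "treated")
    }, integer(1))
    ctl <- vapply(pairs, function(pp) {
      which(s$pair == pp & s$condition == "control")
    }, integer(1))
    d <- lc[, trt, drop = FALSE] - lc[, ctl, drop = FALSE]
    n <- ncol(d)
    lfc <- rowMeans(d)
    if (method == "nb_exact") {
      sf <- size_factors_median_ratio(cm$counts)
      yy <- round(sweep(cm$counts, 2, sf, "/"))
      phi <- estimate_common_dispersion(yy, s$pair)
      sconc <- 1 / max(phi, 1e-8)
      yt <- yy[, trt, drop = FALSE]
      yc <- yy[, ctl, drop = FALSE]
      tot <- yt + yc
      # per pair, treated | pair total is beta-binomial(total, s, s)
      # under the null; sum the centred counts and normal-approximate
      vv <- tot * (tot + 2 * sconc) / (4 * (2 * sconc + 1))
      z <- rowSums(yt - tot / 2) / sqrt(rowSums(vv))
      p <- 2 * stats::pnorm(-abs(z))
      p[!is.finite(p)] <- 1
    } else {
      v <- row_var(d)
      tt <- lfc / sqrt(v / n)
      p <- 2 * stats::pt(-abs(tt), n - 1)
      p[!is.finite(p)] <- 1
    }
  }
  fdr <- bh_adjust(p)
  crit <- if (criterion == "p") p else fdr
  passes <- abs(lfc) >= log2(fc_cutoff) & crit < alpha
  direction <- ifelse(!passes, "none", ifelse(lfc > 0, "up", "down"))
  res <- data.frame(
    gene_id = rownames(lc), log2fc = lfc, p = p, fdr = fdr,
    passes = passes, direction = direction,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(res) <- c("de_result", "data.frame")
  res
}

round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Two-set Venn summary
#'
#' Exact set algebra for a two-set comparison (e.g. genes repressed by a
#' knockdown in each of two groups): totals, overlap, exclusives and the
#' exclusive percentages (rounded half-up to one decimal).
#'
#' @param set_a,set_b character vectors of gene identifiers.
#' @return list of class `venn_summary` with `n_total_a`, `n_total_b`,
#'   `n_common`, `n_exclusive_a`, `n_exclusive_b`, `pct_exclusive_a`,
#'   `pct_exclusive_b` (percentage is `NA` when the total is empty).
#' @export
venn_summarize <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  n_common <- length(intersect(set_a, set_b))
  n_a <- length(set_a); n_b <- length(set_b)
  ex_a <- n_a - n_common; ex_b <- n_b - n_common
  structure(list(
    n_total_a = n_a, n_total_b = n_b, n_common = n_common,
    n_exclusive_a = ex_a, n_exclusive_b = ex_b,
    pct_exclusive_a = if (n_a > 0) round_half_up(100 * ex_a / n_a) else NA_real_,
    pct_exclusive_b = if (n_b > 0) round_half_up(100 * ex_b / n_b) else NA_real_
  ), class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat("Venn summary\n")
  cat(sprintf("  A: %d total, %d exclusive (%s%%)\n", x$n_total_a,
              x$n_exclusive_a, format(x$pct_exclusive_a, nsmall = 1)))
  cat(sprintf("  B: %d total, %d exclusive (%s%%)\n", x$n_total_b,
              x$n_exclusive_b, format(x$pct_exclusive_b, nsmall = 1)))
  cat(sprintf("  common: %d\n", x$n_common))
  invisible(x)
}

#' Quadrant triangulation of basal versus knockdown fold changes
#'
#' Joins a basal and a knockdown differential-expression table and
#' classifies each gene into a fold-change quadrant. A gene is assigned
#' (quadrant `"up-up"`, `"up-down"`, `"down-up"` or `"down-down"`; basal
#' axis first, knockdown axis second) only when both |log2fc| >= `tau`
#' (inclusive) and both `passes` flags are set; otherwise it is
#' `"unassigned"`. Genes missing from either table are unassigned with
#' `NA` for the missing axis.
#'
#' @param basal,kd `de_result` tables (see [de_test()]).
#' @param tau log2 fold-change cutoff for both axes (default log2(1.3)).
#' @return data.frame of class `quadrant_table`: `gene_id`,
#'   `basal_log2fc`, `kd_log2fc`, `basal_sig`, `kd_sig`, `quadrant`.
#' @export
quadrant_classify <- function(basal, kd, tau = log2(1.3)) {
  genes <- union(basal$gene_id, kd$gene_id)
  bi <- match(genes, basal$gene_id)
  ki <- match(genes, kd$gene_id)
  b_lfc <- basal$log2fc[bi]
  k_lfc <- kd$log2fc[ki]
  b_sig <- basal$passes[bi]; b_sig[is.na(b_sig)] <- FALSE
  k_sig <- kd$passes[ki]; k_sig[is.na(k_sig)] <- FALSE
  assigned <- b_sig & k_sig &
    !is.na(b_lfc) & !is.na(k_lfc) &
    abs(b_lfc) >= tau & abs(k_lfc) >= tau
  quadrant <- rep("unassigned", length(genes))
  quadrant[assigned] <- paste0(
    ifelse(b_lfc[assigned] > 0, "up", "down"), "-",
    ifelse(k_lfc[assigned] > 0, "up", "down")
  )
  res <- data.frame(
    gene_id = genes, basal_log2fc = b_lfc, kd_log2fc = k_lfc,
    basal_sig = b_sig, kd_sig = k_sig, quadrant = quadrant,
    stringsAsFactors = FALSE
  )
  class(res) <- c("quadrant_table", "data.frame")
  res
}

#' Per-quadrant Fisher enrichment
#'
#' For each of the four fold-change quadrants, tests whether assigned
#' genes (both axes significant) concentrate in that quadrant relative
#' to the sign pattern of the remaining (unassigned) genes. The 2x2 is
#' \[assigned in quadrant, assigned elsewhere; unassigned whose signed
#' fold changes fall in the quadrant's sign sector, other unassigned\].
#'
#' @param qt a `quadrant_table` from [quadrant_classify()].
#' @return data.frame: `quadrant`, `n_assigned`, `n_unassigned_sector`,
#'   `p` (two-sided Fisher; empty margins give p = 1).
#' @export
quadrant_enrichment <- function(qt) {
  if (!any(qt$quadrant != "unassigned")) stop("no assigned genes")
  quads <- c("up-up", "up-down", "down-up", "down-down")
  signs <- list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  assigned <- qt$quadrant != "unassigned"
  n_assigned <- sum(assigned)
  un <- qt[!assigned & !is.na(qt$basal_log2fc) & !is.na(qt$kd_log2fc), ]
  out <- lapply(seq_along(quads), function(i) {
    a <- sum(qt$quadrant == quads[i])
    b <- n_assigned - a
    in_sector <- sign(un$basal_log2fc) == signs[[i]][1] &
      sign(un$kd_log2fc) == signs[[i]][2]
    cc <- sum(in_sector)
    d <- nrow(un) - cc
    data.frame(quadrant = quads[i], n_assigned = a,
               n_unassigned_sector = cc,
               p = fisher_exact_2x2(c(a, b, cc, d))$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Intersect a gene list with a reference set
#'
#' Exact intersection preserving the input order (used e.g. to pull the
#' mitochondrially annotated genes out of a DEG list).
#'
#' @param genes character vector (order preserved in the result).
#' @param reference character vector.
#' @return the elements of `genes` present in `reference`.
#' @export
intersect_gene_list <- function(genes, reference) {
  genes[genes %in% reference]
}
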