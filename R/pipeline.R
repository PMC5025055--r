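#' Pipeline run configuration
#'
#' Bundles every tunable of an end-to-end run. Either `sim` (a
#' [sim_config()], inputs are simulated) or `paths` (a named list of
#' input files) must be given. Defaults mirror the analysis thresholds:
#' fold change 1.3, alpha 0.05 (raw p for the basal contrast, BH FDR for
#' the paired knockdown), +/- 2 kb promoter windows, binding tiers at
#' 2 and 4, consensus support 2, top 500 ranked peaks.
#'
#' @param sim optional [sim_config()].
#' @param paths optional named list: `annotation`, `basal_prefix`,
#'   `kd_prefix`, `motifs`, `peaks` (named character vector of
#'   narrowPeak files per sample), `chip` and `input` (named vectors of
#'   bedGraph files per sample, per mark for `chip` as
#'   `"<sample>.<mark>"`), `bin_size`.
#' @param group_a,group_b group labels (A is the upregulated-direction
#'   reference, default `"SGA"` vs `"AGA"`).
#' @param fc_cutoff,alpha,basal_criterion,kd_criterion differential
#'   expression thresholds, see [de_test()].
#' @param min_cpm,min_samples expression filter, see [cpm_filter()].
#' @param half_window promoter half-width in bp.
#' @param tier_thresholds binding tier boundaries, see [assign_tier()].
#' @param track_mode `"log2ratio"` or `"ratio"`, see [normalize_track()].
#' @param min_support,top_n consensus peak parameters.
#' @param seed run seed (only consumed when simulating).
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = NULL, paths = NULL,
                       group_a = "SGA", group_b = "AGA",
                       fc_cutoff = 1.3, alpha = 0.05,
                       basal_criterion = "p", kd_criterion = "fdr",
                       min_cpm = 1, min_samples = 3,
                       half_window = 2000, tier_thresholds = c(2, 4),
                       track_mode = "log2ratio",
                       min_support = 2, top_n = 500, seed = 1) {
  if (is.null(sim) && is.null(paths)) {
    stop("either sim or paths must be supplied")
  }
  if (fc_cutoff <= 1 || alpha <= 0 || half_window <= 0 ||
      min_support < 1 || top_n < 1) {
    stop("thresholds must be positive (and fc_cutoff > 1)")
  }
  if (identical(group_a, group_b)) stop("groups must be distinct")
  structure(list(
    sim = sim, paths = paths, group_a = group_a, group_b = group_b,
    fc_cutoff = fc_cutoff, alpha = alpha,
    basal_criterion = basal_criterion, kd_criterion = kd_criterion,
    min_cpm = min_cpm, min_samples = min_samples,
    half_window = half_window, tier_thresholds = tier_thresholds,
    track_mode = track_mode, min_support = min_support, top_n = top_n,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param cfg a [run_config()].
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  x <- unclass(cfg)
  if (!is.null(x$sim)) {
    x$sim <- unclass(x$sim)
    # yaml drops names of atomic vectors; keep the tier map as a map
    x$sim$peak_amp_by_tier <- as.list(x$sim$peak_amp_by_tier)
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(x$sim)) {
    s <- x$sim
    s$peak_amp_by_tier <- unlist(s$peak_amp_by_tier)
    sim <- do.call(sim_config, s)
  }
  do.call(run_config, c(list(sim = sim),
                        x[setdiff(names(x), c("sim"))]))
}

load_pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$sim)) {
    ann <- simulate_annotation(cfg$sim)
    cnt <- simulate_counts(cfg$sim, ann)
    tp <- simulate_tracks_and_peaks(cfg$sim, ann, cnt$truth)
    return(list(ann = ann, basal = cnt$basal, kd = cnt$kd,
                truth = cnt$truth, tracks = tp$tracks,
                peaks = tp$peaks, motifs = tp$motifs))
  }
  p <- cfg$paths
  ann <- read_annotation(p$annotation)
  tracks <- list()
  for (nm in names(p$chip)) {
    sm <- strsplit(nm, ".", fixed = TRUE)[[1]]
    tracks[[nm]] <- read_bedgraph(p$chip[[nm]], p$bin_size,
                                  sample_id = sm[1], mark = sm[2])
  }
  for (s in names(p$input)) {
    tracks[[paste0(s, ".input")]] <- read_bedgraph(p$input[[s]],
                                                   p$bin_size,
                                                   sample_id = s,
                                                   mark = "input")
  }
  peaks <- lapply(p$peaks, read_narrowpeak)
  truth_path <- p$truth
  list(
    ann = ann,
    basal = read_counts(p$basal_prefix),
    kd = read_counts(p$kd_prefix),
    truth = if (is.null(truth_path)) NULL else read_tsv_plain(truth_path),
    tracks = tracks,
    peaks = peaks,
    motifs = read_motif_hits(p$motifs)
  )
}

subset_count_matrix <- function(cm, genes) {
  cm$counts <- cm$counts[rownames(cm$counts) %in% genes, , drop = FALSE]
  cm
}

subset_samples <- function(cm, keep) {
  cm$counts <- cm$counts[, keep, drop = FALSE]
  cm$samples <- cm$samples[keep, , drop = FALSE]
  cm$lib_size <- cm$lib_size[keep]
  cm
}

#' Run the full triangulation pipeline
#'
#' Orchestrates filter -> differential expression (basal two-group and
#' paired knockdown per group) -> SES normalization and promoter
#' scoring -> group scaling and binding tiers -> consensus peaks ->
#' quadrant triangulation -> Venn summaries -> binding/expression
#' association -> motif-family enrichment -> expression x tier
#' cross-tab -> histone intensity comparisons, and collects every table
#' into a results bundle. With an output directory the bundle tables,
#' the run log (config echo plus every derived scale factor) and the
#' text report are written as deterministic TSV/text, so identical
#' config and seed reproduce identical bytes.
#'
#' @param cfg a [run_config()].
#' @param outdir optional output directory.
#' @param write_tracks also write normalized bedGraph tracks (large).
#' @return list of class `tritarget_run`; see Details for components.
#' @export
run_pipeline <- function(cfg, outdir = NULL, write_tracks = FALSE) {
  inputs <- load_pipeline_inputs(cfg)
  ann <- inputs$ann
  log_lines <- c("# tritarget run log", "", "## configuration",
                 utils::capture.output(utils::str(unclass(cfg))))

  ## expression -----------------------------------------------------------
  basal_f <- cpm_filter(inputs$basal, cfg$min_cpm, cfg$min_samples)
  universe <- rownames(basal_f$counts)
  de_basal <- de_test(basal_f, "two_group",
                      group_a = cfg$group_a, group_b = cfg$group_b,
                      fc_cutoff = cfg$fc_cutoff, alpha = cfg$alpha,
                      criterion = cfg$basal_criterion)
  kd_f <- subset_count_matrix(cpm_filter(inputs$kd, cfg$min_cpm,
                                         cfg$min_samples), universe)
  kd_a_cm <- subset_samples(kd_f, kd_f$samples$group == cfg$group_a)
  kd_b_cm <- subset_samples(kd_f, kd_f$samples$group == cfg$group_b)
  # primary knockdown contrast pools all pairs (both groups); the
  # per-group contrasts feed the Venn comparison
  de_kd <- de_test(kd_f, "paired", fc_cutoff = cfg$fc_cutoff,
                   alpha = cfg$alpha, criterion = cfg$kd_criterion)
  de_kd_a <- de_test(kd_a_cm, "paired", fc_cutoff = cfg$fc_cutoff,
                     alpha = cfg$alpha, criterion = cfg$kd_criterion)
  de_kd_b <- de_test(kd_b_cm, "paired", fc_cutoff = cfg$fc_cutoff,
                     alpha = cfg$alpha, criterion = cfg$kd_criterion)

  venn_down <- venn_summarize(
    de_kd_a$gene_id[de_kd_a$direction == "down"],
    de_kd_b$gene_id[de_kd_b$direction == "down"]
  )
  venn_up <- venn_summarize(
    de_kd_a$gene_id[de_kd_a$direction == "up"],
    de_kd_b$gene_id[de_kd_b$direction == "up"]
  )
  quad <- quadrant_classify(de_basal, de_kd, tau = log2(cfg$fc_cutoff))
  quad_enr <- tryCatch(quadrant_enrichment(quad), error = function(e) NULL)

  ## chip signal ----------------------------------------------------------
  marks <- setdiff(unique(vapply(inputs$tracks, function(t) t$mark,
                                 character(1))), "input")
  samples <- unique(vapply(inputs$tracks, function(t) t$sample_id,
                           character(1)))
  sample_group <- ifelse(grepl("^S", samples), cfg$group_a, cfg$group_b)
  norm_tracks <- list()
  ses <- list()
  for (mk in marks) {
    for (s in samples) {
      chip <- inputs$tracks[[paste0(s, ".", mk)]]
      inp <- inputs$tracks[[paste0(s, ".input")]]
      f <- ses_scale_factor(chip, inp)
      ses[[paste0(s, ".", mk)]] <- f
      norm_tracks[[paste0(s, ".", mk)]] <-
        normalize_track(chip, inp, f, mode = cfg$track_mode)
    }
  }
  log_lines <- c(log_lines, "", "## SES scale factors",
                 sprintf("%s: %.6f", names(ses), unlist(ses)))
  score_tables <- list()
  for (mk in marks) {
    tbl <- promoter_score_table(norm_tracks[paste0(samples, ".", mk)],
                                ann, sample_group,
                                half_window = cfg$half_window,
                                tier_thresholds = cfg$tier_thresholds)
    tbl <- group_scale_scores(tbl, cfg$group_a, cfg$group_b)
    score_tables[[mk]] <- tbl
    log_lines <- c(log_lines,
                   sprintf("group scale factor [%s]: %.6f", mk,
                           tbl$scale_factor))
  }

  ## consensus peaks and binding -----------------------------------------
  mean_e2f1 <- local({
    tr <- norm_tracks[paste0(samples, ".E2F1")]
    bins <- lapply(names(tr[[1]]$bins), function(ctg) {
      Reduce(`+`, lapply(tr, function(t) t$bins[[ctg]])) / length(tr)
    })
    names(bins) <- names(tr[[1]]$bins)
    signal_track(bins, tr[[1]]$bin_size, "group_mean", "E2F1")
  })
  consensus_all <- consensus_peaks(inputs$peaks,
                                   min_support = cfg$min_support,
                                   top_n = .Machine$integer.max,
                                   intensity = mean_e2f1)
  consensus_top <- utils::head(consensus_all, cfg$top_n)
  consensus_ann <- annotate_peaks(consensus_all, ann, cfg$half_window)
  prom_peaks <- consensus_ann[consensus_ann$category == "promoter", ]
  bound <- unique(prom_peaks$nearest_gene[
    abs(prom_peaks$tss_distance) <= cfg$half_window])

  up_basal <- de_basal$gene_id[de_basal$direction == "up"]
  down_basal <- de_basal$gene_id[de_basal$direction == "down"]
  assoc <- binding_vs_deg_association(bound, up_basal, down_basal)

  ## motif enrichment -----------------------------------------------------
  motif_enr <- motif_family_enrichment(inputs$motifs, up_basal,
                                       down_basal, ann,
                                       half_window = cfg$half_window)

  ## crosstab -------------------------------------------------------------
  e2f1_tier <- score_tables[["E2F1"]]$tier
  names(e2f1_tier) <- rownames(score_tables[["E2F1"]]$scores)
  basal_cat <- rep("UN", nrow(ann))
  names(basal_cat) <- ann$gene_id
  basal_cat[de_basal$gene_id] <- "S=A"
  basal_cat[up_basal] <- "S>A"
  basal_cat[down_basal] <- "S<A"
  kd_resp <- rep("none", nrow(ann))
  names(kd_resp) <- ann$gene_id
  kd_resp[de_kd$gene_id[de_kd$direction == "down"]] <- "down"
  kd_resp[de_kd$gene_id[de_kd$direction == "up"]] <- "up"
  crosstab <- category_crosstab(basal_cat, kd_resp,
                                e2f1_tier[ann$gene_id])

  ## histone group comparisons -------------------------------------------
  intensity_tests <- list()
  for (mk in marks) {
    gm <- score_tables[[mk]]$group_means
    for (set_name in c("up", "down")) {
      genes <- intersect(if (set_name == "up") up_basal else down_basal,
                         rownames(gm))
      if (length(genes) < 2) next
      a <- gm[genes, cfg$group_a]
      b <- gm[genes, cfg$group_b]
      ties <- sum(a == b)
      intensity_tests[[paste(mk, set_name, sep = ".")]] <- data.frame(
        mark = mk, deg_set = set_name, n_genes = length(genes),
        wilcoxon_p = wilcoxon_group_compare(a, b, paired = TRUE),
        n_above = sum(a > b), n_below = sum(a < b), n_ties = ties,
        binomial_p = if (sum(a != b) >= 1) {
          binomial_sign_test(sum(a > b), sum(a < b))
        } else 1,
        stringsAsFactors = FALSE
      )
    }
  }
  intensity_tests <- do.call(rbind, c(intensity_tests,
                                      list(make.row.names = FALSE)))

  ## integration record ---------------------------------------------------
  prom_motif <- promoter_motif_hits(inputs$motifs, ann, cfg$half_window)
  integration <- data.frame(gene_id = universe, stringsAsFactors = FALSE)
  bi <- match(universe, de_basal$gene_id)
  integration$basal_log2fc <- de_basal$log2fc[bi]
  integration$basal_p <- de_basal$p[bi]
  integration$basal_fdr <- de_basal$fdr[bi]
  integration$basal_direction <- de_basal$direction[bi]
  ki <- match(universe, de_kd$gene_id)
  integration$kd_log2fc <- de_kd$log2fc[ki]
  integration$kd_p <- de_kd$p[ki]
  integration$kd_fdr <- de_kd$fdr[ki]
  integration$kd_direction <- de_kd$direction[ki]
  for (mk in marks) {
    integration[[paste0("score_", mk)]] <-
      score_tables[[mk]]$overall_mean[match(universe,
                                            rownames(score_tables[[mk]]$scores))]
    integration[[paste0("tier_", mk)]] <-
      score_tables[[mk]]$tier[match(universe,
                                    rownames(score_tables[[mk]]$scores))]
  }
  integration$quadrant <- quad$quadrant[match(universe, quad$gene_id)]
  integration$has_motif <- universe %in%
    prom_motif$gene_id[prom_motif$family_id == "E2F"]
  integration$bound <- universe %in% bound
  if (!is.null(inputs$truth)) {
    ti <- match(universe, inputs$truth$gene_id)
    for (cn in setdiff(names(inputs$truth), "gene_id")) {
      integration[[paste0("truth_", cn)]] <- inputs$truth[[cn]][ti]
    }
  }

  mito <- if (is.null(inputs$truth)) character(0) else
    inputs$truth$gene_id[inputs$truth$is_mito]
  deg_all <- c(up_basal, down_basal)

  bundle <- structure(list(
    config = cfg,
    annotation = ann,
    de_basal = de_basal, de_kd = de_kd, de_kd_a = de_kd_a,
    de_kd_b = de_kd_b,
    venn_down = venn_down, venn_up = venn_up,
    quadrants = quad, quadrant_enrichment = quad_enr,
    score_tables = score_tables, ses_factors = unlist(ses),
    consensus_peaks = consensus_top, consensus_all = consensus_ann,
    bound_genes = bound, binding_association = assoc,
    motif_enrichment = motif_enr, crosstab = crosstab,
    intensity_tests = intensity_tests,
    mito_degs = intersect_gene_list(deg_all, mito),
    integration = integration,
    truth = inputs$truth,
    log = log_lines
  ), class = "tritarget_run")

  if (!is.null(outdir)) {
    write_bundle(bundle, outdir)
    if (write_tracks) {
      for (nm in names(norm_tracks)) {
        write_bedgraph(norm_tracks[[nm]],
                       file.path(outdir, paste0(nm, ".norm.bedGraph")))
      }
    }
  }
  bundle
}

write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    write_tsv_plain(as.data.frame(df), file.path(outdir, name))
  }
  wt(bundle$de_basal, "de_basal.tsv")
  wt(bundle$de_kd, "de_kd.tsv")
  wt(bundle$de_kd_a, "de_kd_groupA.tsv")
  wt(bundle$de_kd_b, "de_kd_groupB.tsv")
  wt(bundle$quadrants, "quadrants.tsv")
  if (!is.null(bundle$quadrant_enrichment)) {
    wt(bundle$quadrant_enrichment, "quadrant_enrichment.tsv")
  }
  wt(bundle$consensus_peaks, "consensus_peaks_top.tsv")
  wt(bundle$consensus_all, "consensus_peaks_annotated.tsv")
  wt(bundle$motif_enrichment, "motif_family_enrichment.tsv")
  wt(bundle$intensity_tests, "intensity_tests.tsv")
  wt(bundle$integration, "integration.tsv")
  for (mk in names(bundle$score_tables)) {
    st <- bundle$score_tables[[mk]]
    df <- data.frame(gene_id = rownames(st$scores), st$scores,
                     st$group_means, overall_mean = st$overall_mean,
                     tier = st$tier, check.names = FALSE,
                     stringsAsFactors = FALSE)
    wt(df, paste0("scores_", mk, ".tsv"))
  }
  writeLines(bundle$log, file.path(outdir, "run_log.txt"))
  writeLines(report(bundle), file.path(outdir, "report.txt"))
  invisible(outdir)
}

#' @export
print.tritarget_run <- function(x, ...) {
  cat("tritarget pipeline run\n")
  cat("  expressed genes:", nrow(x$integration), "\n")
  cat("  basal DEGs:", sum(x$de_basal$passes), "\n")
  cat("  knockdown-responsive:", sum(x$de_kd$passes), "\n")
  cat("  bound promoters:", length(x$bound_genes), "\n")
  cat("  binding/DEG association p:",
      format(x$binding_association$p, digits = 3), "\n")
  invisible(x)
}

#' @export
summary.tritarget_run <- function(object, ...) {
  cat(report(object), sep = "\n")
  invisible(object)
}

fmt_pct <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.1f%%", x))
}

#' Human-readable run report
#'
#' Renders the summary shapes of a pipeline run from its bundle tables
#' only: Venn counts and exclusive percentages, quadrant counts with
#' Fisher p-values, the binding-tier proportion table, the binding /
#' expression association and the top motif families. Missing bundle
#' components are reported as explicit gaps.
#'
#' @param bundle a `tritarget_run` from [run_pipeline()].
#' @param top_families number of motif families to list.
#' @return character vector of report lines.
#' @export
report <- function(bundle, top_families = 5) {
  out <- c("==== tritarget report ====", "")
  venn_block <- function(v, label) {
    if (is.null(v)) return(paste0("[", label, ": missing]"))
    c(sprintf("%s:", label),
      sprintf("  group A: %d total, %d exclusive (%s), %d common",
              v$n_total_a, v$n_exclusive_a, fmt_pct(v$pct_exclusive_a),
              v$n_common),
      sprintf("  group B: %d total, %d exclusive (%s)",
              v$n_total_b, v$n_exclusive_b, fmt_pct(v$pct_exclusive_b)))
  }
  out <- c(out, venn_block(bundle$venn_down,
                           "Knockdown-repressed genes (Venn)"),
           venn_block(bundle$venn_up,
                      "Knockdown-elevated genes (Venn)"), "")
  if (!is.null(bundle$quadrant_enrichment)) {
    qe <- bundle$quadrant_enrichment
    out <- c(out, "Quadrant triangulation (basal x knockdown):",
             sprintf("  %-10s n=%4d (sector n=%4d)  Fisher p = %.3g",
                     qe$quadrant, qe$n_assigned, qe$n_unassigned_sector,
                     qe$p), "")
  } else out <- c(out, "[quadrants: missing]", "")
  if (!is.null(bundle$crosstab)) {
    pr <- bundle$crosstab$proportions
    out <- c(out, "Binding tier proportions by category:",
             utils::capture.output(print(round(unclass(pr), 3))),
             sprintf("  headline Fisher p = %.3g", bundle$crosstab$fisher$p),
             "")
  } else out <- c(out, "[crosstab: missing]", "")
  if (!is.null(bundle$binding_association)) {
    ba <- bundle$binding_association
    out <- c(out, sprintf(
      "Binding vs DEG direction: %s of up, %s of down bound; p = %.3g",
      fmt_pct(100 * ba$prop_up_bound), fmt_pct(100 * ba$prop_down_bound),
      ba$p), "")
  } else out <- c(out, "[binding association: missing]", "")
  me <- bundle$motif_enrichment
  if (is.null(me) || nrow(me) == 0) {
    out <- c(out, "Motif families: no families tested", "")
  } else {
    top <- utils::head(me, top_families)
    out <- c(out, "Top motif families:",
             sprintf("  %-8s n=%2d corrected_p = %.3g fdr = %.3g (%s)",
                     top$family_id, top$n_motifs, top$corrected_p,
                     top$fdr, top$direction), "")
  }
  if (!is.null(bundle$mito_degs)) {
    out <- c(out, sprintf("Mitochondrially annotated DEGs: %d (%s)",
                          length(bundle$mito_degs),
                          paste(utils::head(bundle$mito_degs, 10),
                                collapse = ", ")))
  }
  out
}
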