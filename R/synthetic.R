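#' Simulation configuration
#'
#' Parameters of the synthetic study: a two-group (3 vs 3) basal design
#' with planted differentially expressed genes, a paired knockdown
#' design with a planted direct-target subset, promoter-centred ChIP
#' signal with tiered amplitudes, and motif hits planted at target
#' promoters. Defaults emulate the study conditions: 3 lines per group,
#' negative-binomial counts with dispersion 0.05 around a log-normal
#' mean of 200, 10% DEGs at 4-fold, half of the group-A-up DEGs planted
#' as direct targets.
#'
#' @param n_genes number of genes.
#' @param n_per_group cell lines per group (default 3).
#' @param genome_size total genome length in bp (default 10 kb per gene).
#' @param bin_size track bin width in bp; must divide `genome_size`.
#' @param lib_size_mean optional target expected library size; when
#'   `NULL` (default) gene means are left at their log-normal draw
#'   (median 200).
#' @param nb_dispersion negative-binomial dispersion (default 0.05).
#' @param frac_deg fraction of genes planted as DEGs (default 0.1),
#'   split evenly between up and down in group A.
#' @param deg_fold linear fold change of planted DEGs (default 4).
#' @param frac_e2f1_target fraction of group-A-up DEGs planted as direct
#'   E2F1 targets (default 0.5).
#' @param bg_target_rate fraction of the remaining genes planted as
#'   background-bound targets (default 0: targets sit among the
#'   group-A-up DEGs only).
#' @param kd_fold fold by which targets drop in the knockdown member of
#'   each pair (default 3).
#' @param peak_amp_by_tier named amplitudes (signal per bin at the
#'   summit) for the planted tiers.
#' @param background_rate expected background signal per bin.
#' @param hist_boost multiplier on the histone-mark amplitude in group A
#'   for genes that are both group-A-up DEGs and targets (default 2).
#' @param bg_motif_rate chance a non-target gene still carries a planted
#'   motif hit (default 0.1).
#' @param frac_mito fraction of genes flagged as mitochondrially
#'   annotated (default 0.05).
#' @param seed master seed; one RNG stream per output family is derived
#'   from it so regenerating one artifact does not shift the others.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_per_group = 3,
                       genome_size = n_genes * 10000, bin_size = 50,
                       lib_size_mean = NULL, nb_dispersion = 0.05,
                       frac_deg = 0.1, deg_fold = 4,
                       frac_e2f1_target = 0.5, bg_target_rate = 0,
                       kd_fold = 3,
                       peak_amp_by_tier = c(low = 0, moderate = 350,
                                            high = 1550),
                       background_rate = 50, hist_boost = 2,
                       bg_motif_rate = 0.1, frac_mito = 0.05, seed = 1) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_per_group = as.integer(n_per_group),
    genome_size = as.numeric(genome_size), bin_size = as.integer(bin_size),
    lib_size_mean = lib_size_mean, nb_dispersion = nb_dispersion,
    frac_deg = frac_deg, deg_fold = deg_fold,
    frac_e2f1_target = frac_e2f1_target, bg_target_rate = bg_target_rate,
    kd_fold = kd_fold, peak_amp_by_tier = peak_amp_by_tier,
    background_rate = background_rate, hist_boost = hist_boost,
    bg_motif_rate = bg_motif_rate, frac_mito = frac_mito,
    seed = as.integer(seed)
  )
  fr <- c(cfg$frac_deg, cfg$frac_e2f1_target, cfg$bg_target_rate,
          cfg$bg_motif_rate, cfg$frac_mito)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$deg_fold <= 1 || cfg$kd_fold < 1) {
    stop("deg_fold must exceed 1 and kd_fold be at least 1")
  }
  if (cfg$genome_size %% cfg$bin_size != 0) {
    stop("bin_size must divide genome_size")
  }
  if (!all(c("low", "moderate", "high") %in% names(cfg$peak_amp_by_tier))) {
    stop("peak_amp_by_tier needs low/moderate/high entries")
  }
  class(cfg) <- "sim_config"
  cfg
}

# derived per-artifact RNG stream seeds (kept below 2^31)
stream_seed <- function(seed, id) {
  (as.numeric(seed) * 48271 + id * 9973) %% 2147483647 + 1
}

sim_sample_ids <- function(cfg) {
  list(a = sprintf("S%02d", seq_len(cfg$n_per_group)),
       b = sprintf("A%02d", seq_len(cfg$n_per_group)))
}

#' Simulate a gene annotation
#'
#' Places `n_genes` non-overlapping genes on two contigs, each gene in
#' its own fixed-width slot with a 2.5 kb margin on both sides (so that
#' +/- 2 kb promoter windows and planted signal bumps never reach a
#' neighbouring gene). Strands are random; the TSS is the start of a
#' plus-strand gene and the end of a minus-strand gene.
#'
#' @param cfg a [sim_config()].
#' @return a [gene_annotation()].
#' @export
simulate_annotation <- function(cfg) {
  margin <- 2500L
  slot <- as.integer(cfg$genome_size %/% cfg$n_genes)
  slot <- slot - slot %% cfg$bin_size
  max_len <- slot - 2L * margin
  if (max_len < 1000L) {
    stop("genome too small: need >= ", (2L * margin + 1000L),
         " bp per gene, have ", slot)
  }
  set.seed(stream_seed(cfg$seed, 1))
  n1 <- ceiling(cfg$n_genes / 2)
  chrom <- rep(c("chr1", "chr2"), c(n1, cfg$n_genes - n1))
  slot_i <- c(seq_len(n1), seq_len(cfg$n_genes - n1)) - 1L
  len <- sample(1000:min(3000L, max_len), cfg$n_genes, replace = TRUE)
  start <- slot_i * slot + margin + 1L
  gene_annotation(data.frame(
    gene_id = sprintf("g%05d", seq_len(cfg$n_genes)),
    chrom = chrom,
    start = start,
    end = start + len - 1L,
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
    stringsAsFactors = FALSE
  ))
}

# contig lengths implied by the annotation layout (full slots, binned)
sim_contig_lengths <- function(cfg) {
  slot <- as.integer(cfg$genome_size %/% cfg$n_genes)
  slot <- slot - slot %% cfg$bin_size
  n1 <- ceiling(cfg$n_genes / 2)
  c(chr1 = n1 * slot, chr2 = (cfg$n_genes - n1) * slot)
}

#' Simulate basal and knockdown count matrices with planted truth
#'
#' Basal design: `n_per_group` vs `n_per_group` negative-binomial
#' samples; planted DEGs are scaled by `deg_fold` (up) or `1/deg_fold`
#' (down) in group A (SGA). Knockdown design: every cell line
#' contributes a paired control/treated sample; planted E2F1 targets are
#' scaled by `1/kd_fold` in the treated member of each pair. The truth
#' table records every planted flag.
#'
#' @param cfg a [sim_config()].
#' @param ann the matching [gene_annotation()].
#' @return list: `basal` ([count_matrix()]), `kd` (paired
#'   [count_matrix()]), `truth` (data.frame: `gene_id`,
#'   `is_deg_up_groupA`, `is_deg_down_groupA`, `is_e2f1_target`,
#'   `planted_tier`, `has_motif`, `is_mito`).
#' @export
simulate_counts <- function(cfg, ann) {
  n <- cfg$n_genes
  stopifnot(nrow(ann) == n)
  set.seed(stream_seed(cfg$seed, 2))
  mu <- stats::rlnorm(n, log(200), 1)
  if (!is.null(cfg$lib_size_mean)) {
    mu <- mu * cfg$lib_size_mean / sum(mu)
  }
  n_deg <- round(cfg$frac_deg * n)
  deg <- sample(n, n_deg)
  up <- deg[seq_len(ceiling(n_deg / 2))]
  down <- setdiff(deg, up)
  is_up <- seq_len(n) %in% up
  is_down <- seq_len(n) %in% down
  # direct targets: a fraction of the group-A-up DEGs, plus a background
  # rate among all remaining genes
  n_tgt_up <- round(cfg$frac_e2f1_target * length(up))
  tgt <- sample(up, n_tgt_up)
  rest <- setdiff(seq_len(n), tgt)
  tgt <- c(tgt, sample(rest, round(cfg$bg_target_rate * length(rest))))
  is_tgt <- seq_len(n) %in% tgt
  planted_tier <- rep("low", n)
  planted_tier[is_tgt] <- sample(c("moderate", "high"), sum(is_tgt),
                                 replace = TRUE)
  has_motif <- is_tgt | stats::runif(n) < cfg$bg_motif_rate
  is_mito <- stats::runif(n) < cfg$frac_mito
  truth <- data.frame(
    gene_id = ann$gene_id,
    is_deg_up_groupA = is_up, is_deg_down_groupA = is_down,
    is_e2f1_target = is_tgt, planted_tier = planted_tier,
    has_motif = has_motif, is_mito = is_mito,
    stringsAsFactors = FALSE
  )

  ids <- sim_sample_ids(cfg)
  fold_a <- ifelse(is_up, cfg$deg_fold, ifelse(is_down, 1 / cfg$deg_fold, 1))
  size <- 1 / cfg$nb_dispersion
  draw <- function(mu_vec) stats::rnbinom(n, mu = mu_vec, size = size)
  basal <- cbind(
    vapply(ids$a, function(s) draw(mu * fold_a), numeric(n)),
    vapply(ids$b, function(s) draw(mu), numeric(n))
  )
  rownames(basal) <- ann$gene_id
  basal_cm <- count_matrix(basal,
                           group = rep(c("SGA", "AGA"),
                                       each = cfg$n_per_group))

  lines <- c(ids$a, ids$b)
  line_group <- rep(c("SGA", "AGA"), each = cfg$n_per_group)
  mu_line <- lapply(line_group, function(g) if (g == "SGA") mu * fold_a else mu)
  kd_fold_vec <- ifelse(is_tgt, 1 / cfg$kd_fold, 1)
  kd_cols <- lapply(seq_along(lines), function(i) {
    cbind(draw(mu_line[[i]]), draw(mu_line[[i]] * kd_fold_vec))
  })
  kd <- do.call(cbind, kd_cols)
  rownames(kd) <- ann$gene_id
  colnames(kd) <- as.vector(rbind(paste0(lines, "_ctrl"),
                                  paste0(lines, "_kd")))
  kd_cm <- count_matrix(
    kd,
    group = rep(line_group, each = 2),
    pair = rep(lines, each = 2),
    condition = rep(c("control", "treated"), length(lines))
  )
  list(basal = basal_cm, kd = kd_cm, truth = truth)
}

# triangular bump profile: bin indices and weights around a TSS
bump_profile <- function(tss, bin_size, nbin, half_width = 500) {
  w <- bin_window(tss - half_width, tss + half_width, bin_size, nbin)
  if (!length(w)) return(NULL)
  centre <- (w - 0.5) * bin_size
  list(bins = w, weight = pmax(0, 1 - abs(centre - tss) / half_width))
}

#' Simulate signal tracks, peak calls and motif hits
#'
#' Per cell line: an input track of Poisson background noise and, for
#' each simulated mark (`E2F1`, `H3K27ac`), a ChIP track of background
#' plus triangular bumps (+/- 500 bp) centred at planted-target TSSs
#' with amplitude `peak_amp_by_tier[planted_tier]`. The histone mark
#' carries a bump at every gene; its amplitude is multiplied by
#' `hist_boost` in group-A samples at genes that are both group-A-up
#' DEGs and targets. E2F1 peak calls are emitted at planted bumps (with
#' small per-sample jitter and a 10% per-sample dropout) plus
#' sample-specific noise peaks; motif hits are planted within +/- 2 kb
#' of the TSS of `has_motif` genes (an E2F-family motif) alongside
#' background motif families placed uniformly.
#'
#' @param cfg a [sim_config()].
#' @param ann the matching [gene_annotation()].
#' @param truth the truth table from [simulate_counts()].
#' @return list: `tracks` (list of [signal_track()], marks `E2F1`,
#'   `H3K27ac`, `input` per line), `peaks` (named list of per-line E2F1
#'   peak data.frames), `motifs` (motif hit table).
#' @export
simulate_tracks_and_peaks <- function(cfg, ann, truth) {
  set.seed(stream_seed(cfg$seed, 3))
  clen <- sim_contig_lengths(cfg)
  nbin <- as.integer(clen) %/% cfg$bin_size
  names(nbin) <- names(clen)
  ids <- sim_sample_ids(cfg)
  lines <- c(ids$a, ids$b)
  line_group <- rep(c("SGA", "AGA"), each = cfg$n_per_group)

  amp_e2f1 <- unname(cfg$peak_amp_by_tier[truth$planted_tier])
  amp_hist <- rep(unname(cfg$peak_amp_by_tier["moderate"]), cfg$n_genes)
  boost <- truth$is_deg_up_groupA & truth$is_e2f1_target

  profiles <- lapply(seq_len(cfg$n_genes), function(i) {
    bump_profile(ann$tss[i], cfg$bin_size, nbin[[ann$chrom[i]]])
  })

  rate_track <- function(amp) {
    lapply(names(nbin), function(ctg) {
      r <- rep(cfg$background_rate, nbin[[ctg]])
      idx <- which(ann$chrom == ctg & amp > 0)
      for (i in idx) {
        pr <- profiles[[i]]
        if (!is.null(pr)) r[pr$bins] <- r[pr$bins] + amp[i] * pr$weight
      }
      names(r) <- NULL
      r
    })
  }
  base_rate <- lapply(names(nbin), function(ctg) {
    rep(cfg$background_rate, nbin[[ctg]])
  })
  rate_e2f1 <- rate_track(amp_e2f1)
  rate_hist_plain <- rate_track(amp_hist)
  rate_hist_boost <- rate_track(amp_hist * ifelse(boost, cfg$hist_boost, 1))
  names(base_rate) <- names(rate_e2f1) <- names(nbin)
  names(rate_hist_plain) <- names(rate_hist_boost) <- names(nbin)

  pois_track <- function(rate, sample_id, mark) {
    bins <- lapply(rate, function(r) as.numeric(stats::rpois(length(r), r)))
    names(bins) <- names(rate)
    signal_track(bins, cfg$bin_size, sample_id = sample_id, mark = mark)
  }
  tracks <- list()
  for (i in seq_along(lines)) {
    s <- lines[i]
    hist_rate <- if (line_group[i] == "SGA") rate_hist_boost else rate_hist_plain
    tracks[[paste0(s, ".input")]] <- pois_track(base_rate, s, "input")
    tracks[[paste0(s, ".E2F1")]] <- pois_track(rate_e2f1, s, "E2F1")
    tracks[[paste0(s, ".H3K27ac")]] <- pois_track(hist_rate, s, "H3K27ac")
  }

  # E2F1 peak calls: planted bumps with jitter and dropout, plus noise
  peak_genes <- which(truth$planted_tier != "low")
  peaks <- lapply(seq_along(lines), function(i) {
    keep <- peak_genes[stats::runif(length(peak_genes)) > 0.1]
    jit <- sample(-100:100, length(keep), replace = TRUE)
    df <- data.frame(
      chrom = ann$chrom[keep],
      start = pmax(1L, ann$tss[keep] - 500L + jit),
      end = ann$tss[keep] + 500L + jit,
      summit = ann$tss[keep] + jit %/% 2L,
      score = amp_e2f1[keep],
      stringsAsFactors = FALSE
    )
    n_noise <- max(1L, round(0.05 * cfg$n_genes))
    ctg <- sample(names(nbin), n_noise, replace = TRUE)
    pos <- floor(stats::runif(n_noise) * (clen[ctg] - 1000)) + 500L
    noise <- data.frame(
      chrom = ctg, start = as.integer(pos - 150L),
      end = as.integer(pos + 150L), summit = as.integer(pos),
      score = cfg$background_rate,
      stringsAsFactors = FALSE
    )
    out <- rbind(df, noise)
    out[order(out$chrom, out$start), , drop = FALSE]
  })
  names(peaks) <- lines

  set.seed(stream_seed(cfg$seed, 4))
  e2f_motifs <- paste0("E2F-", 1:4)
  motif_rows <- list()
  with_motif <- which(truth$has_motif)
  # family members share similar consensus sequences, so a true site
  # matches most of them: each motif hits a motif-bearing promoter
  # independently with probability 0.7
  for (m in e2f_motifs) {
    g <- with_motif[stats::runif(length(with_motif)) < 0.7]
    if (!length(g)) next
    off <- sample(-1900:1900, length(g), replace = TRUE)
    motif_rows[[m]] <- data.frame(
      motif_id = m, family_id = "E2F",
      chrom = ann$chrom[g],
      start = pmax(1L, ann$tss[g] + off),
      stringsAsFactors = FALSE
    )
  }
  bg_fams <- list(SP = paste0("SP-", 1:3), NFY = paste0("NFY-", 1:2),
                  CTCF = "CTCF-1", AP1 = paste0("AP1-", 1:4))
  for (fam in names(bg_fams)) {
    for (m in bg_fams[[fam]]) {
      g <- which(stats::runif(cfg$n_genes) < cfg$bg_motif_rate)
      if (!length(g)) next
      off <- sample(-1900:1900, length(g), replace = TRUE)
      motif_rows[[m]] <- data.frame(
        motif_id = m, family_id = fam, chrom = ann$chrom[g],
        start = pmax(1L, ann$tss[g] + off),
        stringsAsFactors = FALSE
      )
    }
  }
  motifs <- do.call(rbind, motif_rows)
  motifs$end <- motifs$start + 9L
  motifs$strand <- sample(c("+", "-"), nrow(motifs), replace = TRUE)
  motifs$score <- round(stats::runif(nrow(motifs), 5, 15), 3)
  motifs <- motifs[order(motifs$chrom, motifs$start, motifs$motif_id), ]
  rownames(motifs) <- NULL

  list(tracks = tracks, peaks = peaks, motifs = motifs)
}

#' Write a full synthetic dataset to disk
#'
#' Emits the annotation, basal/knockdown counts, truth table, bedGraph
#' tracks, narrowPeak files and motif table for a configuration.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory (created if needed).
#' @param write_tracks also write the (large) bedGraph tracks.
#' @return invisibly, the list of generated objects.
#' @export
simulate_dataset <- function(cfg, outdir, write_tracks = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ann <- simulate_annotation(cfg)
  cnt <- simulate_counts(cfg, ann)
  tp <- simulate_tracks_and_peaks(cfg, ann, cnt$truth)
  write_annotation(ann, file.path(outdir, "annotation.tsv"))
  write_counts(cnt$basal, file.path(outdir, "basal"))
  write_counts(cnt$kd, file.path(outdir, "knockdown"))
  write_tsv_plain(cnt$truth, file.path(outdir, "truth.tsv"))
  write_motif_hits(tp$motifs, file.path(outdir, "motifs.tsv"))
  for (s in names(tp$peaks)) {
    write_narrowpeak(tp$peaks[[s]],
                     file.path(outdir, paste0(s, ".E2F1.narrowPeak")))
  }
  if (write_tracks) {
    for (nm in names(tp$tracks)) {
      write_bedgraph(tp$tracks[[nm]],
                     file.path(outdir, paste0(nm, ".bedGraph")))
    }
  }
  invisible(list(ann = ann, basal = cnt$basal, kd = cnt$kd,
                 truth = cnt$truth, tracks = tp$tracks,
                 peaks = tp$peaks, motifs = tp$motifs))
}
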