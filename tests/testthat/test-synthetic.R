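test_that("simulated annotation: disjoint genes, both strands, TSS convention", {
  cfg <- sim_config(n_genes = 10, genome_size = 1e6, seed = 3)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann), 10)
  for (ctg in unique(ann$chrom)) {
    a <- ann[ann$chrom == ctg, ]
    a <- a[order(a$start), ]
    if (nrow(a) > 1) expect_true(all(a$start[-1] > a$end[-nrow(a)]))
  }
  expect_setequal(unique(ann$strand), c("+", "-"))
  expect_equal(ann$tss[ann$strand == "+"], ann$start[ann$strand == "+"])
  expect_equal(ann$tss[ann$strand == "-"], ann$end[ann$strand == "-"])
})

test_that("a minus-strand gene's TSS is its rightmost base", {
  ann <- gene_annotation(data.frame(
    gene_id = "g", chrom = "chr1", start = 1001, end = 3000,
    strand = "-"))
  # 1-based closed [1001, 3000] is [1000, 3000) in 0-based half-open
  # terms; the TSS base is 0-based 2999 = 1-based 3000
  expect_equal(ann$tss, 3000)
})

test_that("generation is deterministic and streams are independent", {
  cfg <- sim_config(n_genes = 40, seed = 12)
  a1 <- simulate_annotation(cfg); a2 <- simulate_annotation(cfg)
  expect_identical(a1, a2)
  c1 <- simulate_counts(cfg, a1); c2 <- simulate_counts(cfg, a1)
  expect_identical(c1, c2)
  t1 <- simulate_tracks_and_peaks(cfg, a1, c1$truth)
  t2 <- simulate_tracks_and_peaks(cfg, a1, c1$truth)
  expect_identical(t1, t2)
  # regenerating counts (a later stream) does not depend on whether
  # annotation was regenerated in between
  set.seed(999)   # pollute the global RNG state
  c3 <- simulate_counts(cfg, a1)
  expect_identical(c1, c3)
})

test_that("genome too small raises a sizing error", {
  expect_error(simulate_annotation(sim_config(n_genes = 100,
                                              genome_size = 100000)),
               "genome too small")
})

test_that("truth flags are mutually consistent and conserve planted counts", {
  cfg <- sim_config(n_genes = 300, seed = 8)
  ann <- simulate_annotation(cfg)
  tr <- simulate_counts(cfg, ann)$truth
  expect_false(any(tr$is_deg_up_groupA & tr$is_deg_down_groupA))
  expect_true(all(tr$is_e2f1_target[tr$planted_tier == "high"]))
  expect_equal(sum(tr$is_deg_up_groupA | tr$is_deg_down_groupA),
               round(cfg$frac_deg * cfg$n_genes))
  expect_true(all(tr$has_motif[tr$is_e2f1_target]))
})

test_that("frac_deg = 0 and kd_fold -> 1 give exchangeable null designs", {
  cfg <- sim_config(n_genes = 400, frac_deg = 0, kd_fold = 1,
                    seed = 5)
  ann <- simulate_annotation(cfg)
  cnt <- simulate_counts(cfg, ann)
  expect_equal(sum(cnt$truth$is_deg_up_groupA), 0)
  # group means statistically indistinguishable: t on log-ratios
  m_a <- rowMeans(cnt$basal$counts[, 1:3])
  m_b <- rowMeans(cnt$basal$counts[, 4:6])
  expect_gt(stats::t.test(log1p(m_a), log1p(m_b), paired = TRUE)$p.value,
            0.01)
})

test_that("planted 4-fold DEGs show the expected empirical mean ratio", {
  cfg <- sim_config(n_genes = 5000, frac_deg = 0.2, deg_fold = 4,
                    nb_dispersion = 1e-4, seed = 13)
  ann <- simulate_annotation(cfg)
  cnt <- simulate_counts(cfg, ann)
  tr <- cnt$truth
  up <- tr$is_deg_up_groupA
  ratio <- rowMeans(cnt$basal$counts[up, 1:3]) /
    rowMeans(cnt$basal$counts[up, 4:6])
  # each gene mean ratio ~ 4 with near-zero dispersion; pooled mean of
  # ratios within 3 standard errors of 4
  se <- stats::sd(ratio) / sqrt(sum(up))
  expect_lt(abs(mean(ratio) - 4), 3 * se)
})

test_that("low-tier genes carry no bump; planted bumps dominate TSS scores", {
  cfg <- sim_config(n_genes = 150, seed = 21)
  ann <- simulate_annotation(cfg)
  cnt <- simulate_counts(cfg, ann)
  tp <- simulate_tracks_and_peaks(cfg, ann, cnt$truth)
  chip <- tp$tracks[["S01.E2F1"]]
  inp <- tp$tracks[["S01.input"]]
  nt <- normalize_track(chip, inp)
  sc <- tss_score(nt, ann)
  tr <- cnt$truth
  if (sum(tr$planted_tier != "low") > 0 && sum(tr$planted_tier == "low") > 0) {
    expect_gt(mean(sc[tr$planted_tier != "low"]),
              mean(sc[tr$planted_tier == "low"]))
  }
  # raw chip rate at a low gene's TSS is plain background
  low_gene <- which(tr$planted_tier == "low")[1]
  w <- tritarget:::bin_window(ann$tss[low_gene] - 250,
                              ann$tss[low_gene] + 250, cfg$bin_size,
                              length(chip$bins[[ann$chrom[low_gene]]]))
  expect_lt(mean(chip$bins[[ann$chrom[low_gene]]][w]),
            3 * cfg$background_rate)
})

test_that("planted targets separate from non-targets across seeds", {
  hits <- 0
  for (s in 1:20) {
    cfg <- sim_config(n_genes = 100, seed = s)
    ann <- simulate_annotation(cfg)
    cnt <- simulate_counts(cfg, ann)
    tp <- simulate_tracks_and_peaks(cfg, ann, cnt$truth)
    nt <- normalize_track(tp$tracks[["A01.E2F1"]],
                          tp$tracks[["A01.input"]])
    sc <- tss_score(nt, ann)
    tr <- cnt$truth
    if (!any(tr$is_e2f1_target) ||
        mean(sc[tr$is_e2f1_target]) > mean(sc[!tr$is_e2f1_target])) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / 20, 0.95)
})

test_that("peaks round-trip through narrowPeak identically", {
  cfg <- sim_config(n_genes = 60, seed = 17)
  ann <- simulate_annotation(cfg)
  cnt <- simulate_counts(cfg, ann)
  tp <- simulate_tracks_and_peaks(cfg, ann, cnt$truth)
  d <- withr::local_tempdir()
  p <- tp$peaks[[1]]
  write_narrowpeak(p, file.path(d, "p.narrowPeak"))
  p2 <- read_narrowpeak(file.path(d, "p.narrowPeak"))
  rownames(p) <- NULL
  expect_equal(p2[, c("chrom", "start", "end", "summit")],
               p[, c("chrom", "start", "end", "summit")])
})

test_that("simulate_dataset writes a complete, reproducible file set", {
  cfg <- sim_config(n_genes = 30, seed = 2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1, write_tracks = FALSE)
  simulate_dataset(cfg, d2, write_tracks = FALSE)
  files <- list.files(d1)
  expect_true(all(c("annotation.tsv", "basal_counts.tsv",
                    "knockdown_counts.tsv", "truth.tsv", "motifs.tsv")
                  %in% files))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
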