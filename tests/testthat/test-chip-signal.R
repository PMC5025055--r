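test_that("SES factor: identical tracks give 1, uniform 2x ratio gives 0.5", {
  v <- c(rep(1, 50), rep(5, 30), rep(20, 20))
  expect_equal(ses_scale_factor(toy_track(v), toy_track(v)), 1)
  expect_equal(ses_scale_factor(toy_track(2 * v), toy_track(v)), 0.5)
})

test_that("SES factor equals the exhaustive split-point scan on random spiked tracks", {
  set.seed(42)
  for (i in 1:50) {
    input <- rpois(100, 20) + 1
    chip <- rpois(100, 20) + 1
    chip[sample(100, sample(1:5, 1))] <- rpois(1, 500) + 100  # spikes
    got <- ses_scale_factor(toy_track(chip), toy_track(input))
    expect_equal(got, oracle_ses_factor(chip, input), tolerance = 1e-12)
  }
})

test_that("SES factor rejects degenerate tracks", {
  expect_error(ses_scale_factor(toy_track(rep(0, 100)),
                                toy_track(rep(1, 100))), "zero mass")
  expect_error(ses_scale_factor(toy_track(rep(1, 100)),
                                toy_track(rep(0, 100))), "zero mass")
  expect_error(ses_scale_factor(toy_track(c(1, 1)), toy_track(c(1, 1))),
               "10 non-empty")
})

test_that("normalize_track computes log2 and linear input ratios", {
  chip <- toy_track(rep(16, 100))
  inp <- toy_track(rep(1, 100))
  same <- normalize_track(chip, chip, factor = 1, pseudocount = 1e-9)
  expect_equal(unique(same$bins$chr1), 0)
  lg <- normalize_track(chip, inp, factor = 1, pseudocount = 1e-9)
  expect_equal(unique(lg$bins$chr1), 4, tolerance = 1e-6)
  lin <- normalize_track(chip, inp, factor = 1, mode = "ratio",
                         pseudocount = 1e-9)
  expect_equal(unique(lin$bins$chr1), 16, tolerance = 1e-6)
})

test_that("tss_score takes the window maximum, inclusive at +/- half_window", {
  ann <- gene_annotation(data.frame(
    gene_id = "g1", chrom = "chr1", start = 5000, end = 6000,
    strand = "+"))
  flat <- toy_track(rep(3, 1000), bin_size = 10)
  expect_equal(unname(tss_score(flat, ann, 2000)), 3)

  spike_in <- rep(1, 1000); spike_in[520] <- 50     # 5,191-5,200: inside
  expect_equal(unname(tss_score(toy_track(spike_in, 10), ann, 2000)), 50)
  spike_out <- rep(1, 1000); spike_out[750] <- 50   # 7,491-7,500: outside
  expect_equal(unname(tss_score(toy_track(spike_out, 10), ann, 2000)), 1)
  # bin containing position tss + 2000 = 7000 is included
  spike_edge <- rep(1, 1000); spike_edge[700] <- 50 # 6,991-7,000
  expect_equal(unname(tss_score(toy_track(spike_edge, 10), ann, 2000)), 50)
})

test_that("tss_score is invariant to values outside the window and clips at edges", {
  ann <- gene_annotation(data.frame(
    gene_id = c("g1", "g2"), chrom = c("chr1", "chrX"),
    start = c(100, 100), end = c(300, 300), strand = "-"))
  v1 <- rep(1, 500); v2 <- v1
  v2[480:500] <- 99   # beyond tss 300 + 2000
  t1 <- toy_track(v1, 10); t2 <- toy_track(v2, 10)
  suppressMessages({
    s1 <- tss_score(t1, ann); s2 <- tss_score(t2, ann)
  })
  expect_equal(s1[["g1"]], s2[["g1"]])
  expect_true(is.na(s1[["g2"]]))    # unknown contig
})

test_that("group scaling: factor 1 for identical groups, 0.5 for doubled target", {
  ann <- gene_annotation(data.frame(
    gene_id = sprintf("g%02d", 1:5), chrom = "chr1",
    start = seq(1000, 41000, by = 10000),
    end = seq(3000, 43000, by = 10000), strand = "+"))
  set.seed(5)
  base <- matrix(rlnorm(5 * 6, 1, 0.2), nrow = 5,
                 dimnames = list(ann$gene_id, sprintf("s%d", 1:6)))
  tbl <- structure(list(scores = base, group = rep(c("A", "B"), each = 3),
                        mark = "E2F1", tier_thresholds = c(2, 4),
                        scale_factor = NA_real_),
                   class = "promoter_score_table")
  tbl <- tritarget:::refresh_score_summary(tbl)
  same <- tbl; same$scores[, 4:6] <- same$scores[, 1:3]
  same <- tritarget:::refresh_score_summary(same)
  expect_equal(group_scale_scores(same, "A", "B")$scale_factor, 1)
  dbl <- tbl; dbl$scores[, 4:6] <- dbl$scores[, 1:3] * 2
  dbl <- tritarget:::refresh_score_summary(dbl)
  expect_equal(group_scale_scores(dbl, "A", "B")$scale_factor, 0.5)
})

test_that("group scaling zeroes the median log-ratio and inverts on label swap", {
  ann_ids <- sprintf("g%02d", 1:21)   # odd count: median is a datum
  set.seed(6)
  scores <- matrix(rlnorm(21 * 6, 1, 0.5), nrow = 21,
                   dimnames = list(ann_ids, sprintf("s%d", 1:6)))
  tbl <- structure(list(scores = scores, group = rep(c("A", "B"), each = 3),
                        mark = "E2F1", tier_thresholds = c(2, 4),
                        scale_factor = NA_real_),
                   class = "promoter_score_table")
  tbl <- tritarget:::refresh_score_summary(tbl)
  scaled <- group_scale_scores(tbl, "A", "B")
  lr <- log(scaled$group_means[, "A"]) - log(scaled$group_means[, "B"])
  expect_equal(stats::median(lr), 0, tolerance = 1e-9)
  # involution on the log scale: the two directed factors are inverse
  f_ab <- group_scale_scores(tbl, "A", "B")$scale_factor
  f_ba <- group_scale_scores(tbl, "B", "A")$scale_factor
  expect_equal(f_ab * f_ba, 1, tolerance = 1e-9)
  # once balanced, rescaling in either direction is a no-op
  expect_equal(group_scale_scores(scaled, "B", "A")$scale_factor, 1,
               tolerance = 1e-9)
  expect_equal(group_scale_scores(scaled, "A", "B")$scale_factor, 1,
               tolerance = 1e-9)
})

test_that("tier assignment matches the printed partition at the boundaries", {
  expect_equal(assign_tier(c(1.99, 2.0, 4.0, 4.01)),
               c("low", "moderate", "moderate", "high"))
})

test_that("consensus peaks: support filtering, ranking and order invariance", {
  p1 <- data.frame(chrom = "chr1", start = c(100, 900), end = c(200, 950),
                   summit = c(150, 925), score = c(5, 2))
  p2 <- data.frame(chrom = "chr1", start = 150, end = 250, summit = 200,
                   score = 7)
  p3 <- data.frame(chrom = "chr1", start = c(120, 400), end = c(220, 500),
                   summit = c(170, 450), score = c(6, 9))
  intensity <- toy_track(c(rep(1, 10), rep(8, 15), rep(1, 15),
                           rep(3, 10), rep(1, 50)), bin_size = 10)
  got <- suppressWarnings(
    consensus_peaks(list(a = p1, b = p2, c = p3), min_support = 2,
                    top_n = 500, intensity = intensity)
  )
  # region 100-250 supported by 3 samples; 900-950 and 400-500 by 1
  expect_equal(nrow(got), 1)
  expect_equal(got$n_support, 3)
  expect_equal(got$intensity, 8)

  # identical peak in 2 samples is kept; singleton is dropped
  q <- data.frame(chrom = "chr1", start = 100, end = 200, summit = 150,
                  score = 5)
  got2 <- consensus_peaks(list(a = q, b = q), min_support = 2,
                          top_n = 500, intensity = intensity)
  expect_equal(nrow(got2), 1)

  # top_n truncation keeps the highest-intensity regions
  r <- lapply(1:2, function(i) data.frame(
    chrom = "chr1", start = c(100, 400, 700), end = c(200, 500, 800),
    summit = c(150, 450, 750), score = 1))
  got3 <- consensus_peaks(r, min_support = 2, top_n = 2,
                          intensity = intensity)
  expect_equal(nrow(got3), 2)
  expect_equal(got3$start, c(100, 400))  # intensities 8 and 3 beat 1

  # input order invariance
  got4 <- suppressWarnings(
    consensus_peaks(list(c = p3, a = p1, b = p2), min_support = 2,
                    top_n = 500, intensity = intensity))
  expect_equal(got4[, c("chrom", "start", "end", "n_support")],
               got[, c("chrom", "start", "end", "n_support")])
})

test_that("peak annotation classifies promoter, gene body and intergenic summits", {
  ann <- gene_annotation(data.frame(
    gene_id = c("plus", "minus"), chrom = "chr1",
    start = c(10000, 50000), end = c(30000, 70000),
    strand = c("+", "-")))
  peaks <- data.frame(
    chrom = "chr1",
    start = c(10000, 20000, 90000, 69500),
    end = c(10400, 20400, 90400, 70900),
    summit = c(10100, 20200, 90200, 70200)
  )
  got <- annotate_peaks(peaks, ann)
  expect_equal(got$category,
               c("promoter", "gene_body", "intergenic", "promoter"))
  # signed distance is oriented by transcription direction
  expect_equal(got$tss_distance[1], 100)       # + gene, downstream of TSS
  expect_equal(got$nearest_gene[4], "minus")
  expect_equal(got$tss_distance[4], -200)      # minus gene TSS 70000, summit
                                               # 70200 genomically => upstream
})
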