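make_cm <- function(counts, group, ...) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("s%d", seq_len(ncol(counts)))
  }
  count_matrix(counts, group, ...)
}

test_that("cpm_filter keeps genes above 1 cpm in at least 3 of 6 samples", {
  lib <- rep(1e6, 6)
  counts <- rbind(
    kept = c(1.5, 1.5, 1.5, 0, 0, 0) * 1,     # cpm 1.5 in 3 samples
    dropped = c(1, 1, 1, 1, 1, 1),            # cpm exactly 1, not > 1
    zero = rep(0, 6),
    counts2 = c(2, 2, 2, 0, 0, 0)             # cpm 2 > 1 in 3 samples
  )
  cm <- make_cm(round(counts), rep(c("A", "B"), each = 3),
                lib_size = lib)
  kept <- rownames(cpm_filter(cm)$counts)
  expect_setequal(kept, c("kept", "counts2"))
})

test_that("cpm_filter is monotone: adding counts never removes a retained gene", {
  set.seed(11)
  for (i in 1:20) {
    counts <- matrix(rpois(60, 3), nrow = 10)
    cm <- make_cm(counts, rep(c("A", "B"), each = 3))
    kept1 <- rownames(cpm_filter(cm)$counts)
    bumped <- cm$counts
    g <- sample(match(kept1, rownames(cm$counts)), 1)
    bumped[g, ] <- bumped[g, ] + sample(0:5, 6, replace = TRUE)
    cm2 <- count_matrix(bumped, rep(c("A", "B"), each = 3),
                        lib_size = cm$lib_size)
    expect_true(rownames(cm$counts)[g] %in%
                  rownames(cpm_filter(cm2)$counts))
  }
})

test_that("cpm errors on zero library size", {
  cm <- make_cm(matrix(0:5, 3, 2), c("A", "B"), lib_size = c(10, 0))
  expect_error(cpm(cm), "library size")
})

test_that("de_test: identical groups give log2fc 0 and no passes", {
  counts <- matrix(rep(c(100, 200, 400), each = 6), nrow = 3,
                   byrow = TRUE)
  cm <- make_cm(counts, rep(c("A", "B"), each = 3))
  for (m in c("nb_exact", "lcpm")) {
    de <- de_test(cm, "two_group", method = m)
    expect_equal(de$log2fc, rep(0, 3))
    expect_false(any(de$passes))
    expect_true(all(de$direction == "none"))
  }
})

test_that("the fold-change threshold is log2(1.3) = 0.38 (two decimals), boundary inclusive", {
  expect_equal(round(log2(1.3), 2), 0.38)
  # gene with |log2fc| exactly at threshold and tiny p must pass
  de <- data.frame(gene_id = c("a", "b"), log2fc = c(log2(1.3), 0.2),
                   p = c(1e-6, 1e-6), fdr = c(1e-6, 1e-6),
                   passes = c(TRUE, FALSE),
                   direction = c("up", "none"))
  # recompute passes via the same rule used in de_test
  expect_true(abs(de$log2fc[1]) >= log2(1.3))
  expect_false(abs(de$log2fc[2]) >= log2(1.3))
})

test_that("a planted 4-fold gene (n=3 vs 3, dispersion 0.05, mean 200) is detected reliably", {
  set.seed(77)
  hits <- 0
  n_sim <- 200
  for (i in 1:n_sim) {
    mu <- rep(200, 50)
    mu_a <- mu; mu_a[1] <- mu_a[1] * 4
    counts <- cbind(
      matrix(rnbinom(50 * 3, mu = mu_a, size = 20), 50),
      matrix(rnbinom(50 * 3, mu = mu, size = 20), 50)
    )
    cm <- make_cm(counts, rep(c("A", "B"), each = 3))
    de <- de_test(cm, "two_group", group_a = "A", group_b = "B")
    if (de$passes[1] && de$direction[1] == "up") hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.8)
})

test_that("degenerate constant genes give p = 1, not an error", {
  counts <- matrix(5, nrow = 2, ncol = 6)
  cm <- make_cm(counts, rep(c("A", "B"), each = 3))
  expect_equal(de_test(cm, "two_group", method = "lcpm")$p, c(1, 1))
})

test_that("null p-values are approximately uniform for both designs", {
  set.seed(99)
  pooled_2g <- c(); pooled_pair <- c()
  for (s in 1:10) {
    counts <- matrix(rnbinom(500 * 6, mu = rep(rlnorm(500, log(200), 1), 6),
                             size = 20), ncol = 6)
    cm <- make_cm(counts, rep(c("A", "B"), each = 3))
    pooled_2g <- c(pooled_2g, de_test(cm, "two_group")$p)
    cmp <- make_cm(counts, rep("A", 6), pair = rep(c("p1", "p2", "p3"), each = 2),
                   condition = rep(c("control", "treated"), 3))
    pooled_pair <- c(pooled_pair, de_test(cmp, "paired")$p)
  }
  ks1 <- suppressWarnings(stats::ks.test(pooled_2g, "punif"))$statistic
  ks2 <- suppressWarnings(stats::ks.test(pooled_pair, "punif"))$statistic
  expect_lt(unname(ks1), 0.1)
  expect_lt(unname(ks2), 0.1)
})

test_that("venn_summarize reproduces exact set algebra and conserves totals", {
  v <- venn_summarize(letters[1:5], letters[4:8])
  expect_equal(v$n_common, 2)
  expect_equal(v$n_total_a, v$n_common + v$n_exclusive_a)
  expect_equal(v$n_total_b, v$n_common + v$n_exclusive_b)
  expect_equal(venn_summarize(letters[1:3], LETTERS[1:3])$n_common, 0)
  expect_true(is.na(venn_summarize(character(0), letters[1:3])$pct_exclusive_a))
  set.seed(21)
  for (i in 1:25) {
    a <- sample(letters, sample(0:20, 1))
    b <- sample(letters, sample(0:20, 1))
    v <- venn_summarize(a, b)
    expect_equal(v$n_total_a, v$n_common + v$n_exclusive_a)
    expect_equal(v$n_total_b, v$n_common + v$n_exclusive_b)
  }
})

test_that("quadrant classification follows the inclusive log2(1.3) rule", {
  basal <- data.frame(gene_id = c("a", "b", "c", "d"),
                      log2fc = c(0.5, 0.5, log2(1.3), -0.5),
                      p = 0.01, fdr = 0.01,
                      passes = c(TRUE, TRUE, TRUE, TRUE),
                      direction = "up")
  kd <- data.frame(gene_id = c("a", "b", "c", "e"),
                   log2fc = c(-0.5, 0.2, log2(1.3), 0.6),
                   p = 0.01, fdr = 0.01,
                   passes = c(TRUE, TRUE, TRUE, TRUE),
                   direction = "down")
  q <- quadrant_classify(basal, kd)
  qq <- q$quadrant[match(c("a", "b", "c", "d", "e"), q$gene_id)]
  expect_equal(qq[1], "up-down")     # basal up, kd down
  expect_equal(qq[2], "unassigned")  # |kd lfc| below cutoff
  expect_equal(qq[3], "up-up")       # exactly at cutoff: inclusive
  expect_equal(qq[4], "unassigned")  # missing from kd table
  expect_equal(qq[5], "unassigned")  # missing from basal table
})

test_that("quadrant enrichment flags concentration in one quadrant", {
  set.seed(31)
  n <- 400
  lfc_b <- runif(n, -1, 1); lfc_k <- runif(n, -1, 1)
  assigned <- seq_len(60)
  lfc_b[assigned] <- runif(60, 0.5, 1)
  lfc_k[assigned] <- runif(60, -1, -0.5)
  mk <- function(lfc, pass_idx) data.frame(
    gene_id = sprintf("g%03d", 1:n), log2fc = lfc, p = 0.5, fdr = 0.5,
    passes = seq_len(n) %in% pass_idx,
    direction = ifelse(seq_len(n) %in% pass_idx,
                       ifelse(lfc > 0, "up", "down"), "none"))
  q <- quadrant_classify(mk(lfc_b, assigned), mk(lfc_k, assigned))
  enr <- quadrant_enrichment(q)
  expect_lt(enr$p[enr$quadrant == "up-down"], 1e-3)
})

test_that("quadrant enrichment with balanced 2x2 gives p = 1", {
  expect_equal(fisher_exact_2x2(c(1, 1, 1, 1))$p, 1)
})

test_that("intersect_gene_list preserves order and handles empties", {
  expect_equal(intersect_gene_list(c("a", "b", "c"), c("b", "c", "d")),
               c("b", "c"))
  expect_equal(intersect_gene_list(c("c", "a", "b"), c("a", "b", "c")),
               c("c", "a", "b"))
  expect_equal(intersect_gene_list(c("a", "b"), character(0)), character(0))
})
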