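# Brute-force enumeration oracles, independent of the package's
# implementations (direct probability sums / exhaustive enumeration).

# Fisher 2x2: enumerate every table with the observed margins and sum
# the probabilities of those no more probable than the observed table.
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }, numeric(1))
  obs <- probs[match(a, support)]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Binomial two-tailed, minimum-likelihood: direct sum over outcomes.
oracle_binom_two_sided <- function(k, n, p0 = 0.5) {
  probs <- vapply(0:n, function(x) {
    exp(lchoose(n, x) + x * log(p0) + (n - x) * log(1 - p0))
  }, numeric(1))
  min(sum(probs[probs <= probs[k + 1] * (1 + 1e-7)]), 1)
}

# Signed-rank: enumerate all 2^n sign assignments of the ranked
# absolute differences (valid for tie-free data).
oracle_signrank_two_sided <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  mu <- n * (n + 1) / 4
  p_low <- mean(v_all <= v_obs)
  p_high <- mean(v_all >= v_obs)
  if (v_obs > mu) min(2 * p_high, 1) else min(2 * p_low, 1)
}

# Rank-sum: enumerate all choose(nx+ny, nx) group assignments.
oracle_ranksum_two_sided <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  w_all <- apply(combs, 2, function(i) sum(r[i])) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (w_obs > mu) min(2 * mean(w_all >= w_obs), 1) else
    min(2 * mean(w_all <= w_obs), 1)
}

# BH step-up from the definition: find the largest k with
# p_(k) <= k/m * q by scanning all thresholds; adjusted value for each
# p is the smallest q at which it would be rejected.
oracle_bh_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[o[i]] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  adj
}

# SES split point by exhaustive scan over every k (largest k among
# those attaining the maximal gap).
oracle_ses_factor <- function(chip, input) {
  o <- order(chip)
  cv <- chip[o]; iv <- input[o]
  gaps <- vapply(seq_along(cv), function(k) {
    abs(sum(cv[1:k]) / sum(cv) - sum(iv[1:k]) / sum(iv))
  }, numeric(1))
  k <- max(which(gaps >= max(gaps) - 1e-12))
  sum(iv[1:k]) / sum(cv[1:k])
}

# small helper: signal track on one contig
toy_track <- function(values, bin_size = 10, sample_id = "s1",
                      mark = "E2F1") {
  signal_track(list(chr1 = values), bin_size, sample_id, mark)
}
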