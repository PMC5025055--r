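#' Fisher's exact test for a 2x2 table
#'
#' Exact conditional test on a 2x2 contingency table with fixed margins.
#' The two-sided p-value follows the minimum-likelihood convention: the
#' sum of hypergeometric probabilities of all tables (with the observed
#' margins) no more probable than the observed one. The reported odds
#' ratio is the sample odds ratio `ad/bc` (may be 0 or Inf).
#'
#' @param tab 2x2 integer matrix `rbind(c(a, b), c(c, d))`, or a length-4
#'   vector `c(a, b, c, d)` read row-wise.
#' @param sided `"two"` (default), `"greater"` or `"less"`; one-sided
#'   alternatives refer to the odds ratio of the first row.
#' @return list with `p` and `odds_ratio`.
#' @export
fisher_exact_2x2 <- function(tab, sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  if (is.matrix(tab)) tab <- c(t(tab))
  if (length(tab) != 4) stop("need a 2x2 table")
  if (any(!is.finite(tab)) || any(tab < 0)) stop("counts must be non-negative")
  if (any(tab != round(tab))) stop("counts must be integers")
  a <- tab[1]; b <- tab[2]; cc <- tab[3]; d <- tab[4]
  m <- a + b          # row 1 total
  n <- cc + d         # row 2 total
  k <- a + cc         # column 1 total
  or <- (a * d) / (b * cc)
  if (m == 0 || n == 0 || k == 0 || b + d == 0) {
    return(list(p = 1, odds_ratio = or))
  }
  lo <- max(0, k - n)
  hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  p <- switch(sided,
    two = sum(dens[dens <= obs * (1 + 1e-7)]),
    greater = sum(dens[support >= a]),
    less = sum(dens[support <= a])
  )
  list(p = min(p, 1), odds_ratio = or)
}

#' Two-tailed exact binomial sign test
#'
#' Tests whether the number of "above" outcomes among `n_above + n_below`
#' Bernoulli trials is compatible with success probability `p0`. The
#' two-sided p-value is the minimum-likelihood sum: all outcome counts
#' whose binomial probability does not exceed that of the observed count.
#' Ties are expected to be dropped by the caller before the test.
#'
#' @param n_above,n_below non-negative integer counts.
#' @param p0 null success probability (default 0.5).
#' @return two-sided p-value.
#' @export
binomial_sign_test <- function(n_above, n_below, p0 = 0.5) {
  if (n_above < 0 || n_below < 0) stop("counts must be non-negative")
  n <- n_above + n_below
  if (n < 1) stop("need at least one non-tied observation")
  dens <- stats::dbinom(0:n, n, p0)
  obs <- dens[n_above + 1]
  min(sum(dens[dens <= obs * (1 + 1e-7)]), 1)
}

#' Wilcoxon comparison of two score vectors
#'
#' Paired mode runs the signed-rank test on per-element differences
#' (exact zeros are dropped first); unpaired mode runs the rank-sum test.
#' The exact null distribution is used for small samples without ties
#' (n <= `exact_limit`); otherwise a normal approximation with tie
#' correction is used.
#'
#' @param x,y numeric score vectors (equal length when `paired`).
#' @param paired logical; paired signed-rank (default) or rank-sum.
#' @param exact_limit largest sample size for the exact distribution.
#' @return two-sided p-value.
#' @export
wilcoxon_group_compare <- function(x, y, paired = TRUE, exact_limit = 25) {
  if (paired) {
    if (length(x) != length(y)) stop("paired vectors must have equal length")
    d <- x - y
    d <- d[d != 0]
    n <- length(d)
    if (n == 0) return(1)
    r <- rank(abs(d))
    v <- sum(r[d > 0])
    ties <- any(duplicated(abs(d)))
    if (!ties && n <= exact_limit) {
      p <- if (v > n * (n + 1) / 4) {
        stats::psignrank(v - 1, n, lower.tail = FALSE)
      } else {
        stats::psignrank(v, n)
      }
      return(min(2 * p, 1))
    }
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    if (sigma2 <= 0) return(1)
    z <- (v - mu) / sqrt(sigma2)
    return(min(2 * stats::pnorm(-abs(z)), 1))
  }
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && nx <= exact_limit && ny <= exact_limit) {
    p <- if (w > nx * ny / 2) {
      stats::pwilcox(w - 1, nx, ny, lower.tail = FALSE)
    } else {
      stats::pwilcox(w, nx, ny)
    }
    return(min(2 * p, 1))
  }
  mu <- nx * ny / 2
  tie_tab <- table(r)
  sigma2 <- nx * ny / 12 *
    (nx + ny + 1 - sum(tie_tab^3 - tie_tab) / ((nx + ny) * (nx + ny - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - mu) / sqrt(sigma2)
  min(2 * stats::pnorm(-abs(z)), 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment: adjusted p for the i-th
#' smallest p-value is `min over j >= i of p_(j) * m / j`, clipped at 1,
#' returned in the original order. NAs are preserved and excluded from m.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(out)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / seq(m, 1) * pv[o]))[ro]
  out[ok] <- adj
  out
}
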