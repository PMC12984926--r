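#' Two-sided Fisher's exact test for a 2x2 contingency table
#'
#' Computes the exact two-sided p-value for the 2x2 table
#' \preformatted{    | col1 | col2
#' row1 |  a   |  b
#' row2 |  c   |  d }
#' as the sum, over every table sharing the observed margins, of the
#' hypergeometric point probabilities
#' \deqn{P_i = \frac{(a+b)!\,(c+d)!\,(a+c)!\,(b+d)!}{n!\;a_i!\,b_i!\,c_i!\,d_i!}}
#' that do not exceed the observed table's point probability — the standard
#' "at least as extreme by point probability" two-sided rule. Factorials are
#' handled in log space and the comparison uses a relative tolerance of 1e-12
#' so equal-probability tables on the opposite tail are never lost to
#' floating-point round-off.
#'
#' In the co-regulation screen the cells are: `a` = conditions where neither
#' site was called, `b` = exactly one called, `c` = discordant calls (one up,
#' one down), `d` = concordant calls (both up or both down).
#'
#' @param a,b,c,d Non-negative integer cell counts (vectorized; recycled to a
#'   common length).
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' fisher_exact_2x2(1, 1, 1, 1)   # 1
#' fisher_exact_2x2(10, 2, 1, 7)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  n_in <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n_in); b <- rep_len(as.numeric(b), n_in)
  c <- rep_len(as.numeric(c), n_in); d <- rep_len(as.numeric(d), n_in)
  if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != floor(c(a, b, c, d)))) {
    abort("Cell counts must be non-negative integers.")
  }
  vapply(seq_len(n_in), function(i) {
    fet_one(a[i], b[i], c[i], d[i])
  }, numeric(1))
}

fet_one <- function(a, b, c, d) {
  n <- a + b + c + d
  if (n == 0) abort("empty table: all four cells are zero")
  r1 <- a + b
  c1 <- a + c
  # support of the top-left cell given fixed margins
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  x <- lo:hi
  lp <- lfact(r1) + lfact(n - r1) + lfact(c1) + lfact(n - c1) - lfact(n) -
    (lfact(x) + lfact(r1 - x) + lfact(c1 - x) + lfact(n - r1 - c1 + x))
  lp_obs <- lp[x == a]
  take <- lp <= lp_obs + log1p(1e-12)
  if (all(take)) return(1)  # every admissible table is at least as extreme
  min(sum(exp(lp[take])), 1)
}

lfact <- function(x) lgamma(x + 1)

#' Upper-tail hypergeometric probability of an overlap
#'
#' `P(X >= k)` for `X` hypergeometric with `K` successes in a universe of
#' `N`, drawing `n`. This is the over-representation p-value used by
#' [hypergeometric_ora()].
#'
#' @param k Observed overlap.
#' @param K Gene-set size (within the universe).
#' @param n Query size.
#' @param N Universe size.
#' @return `P(X >= k)`, exactly 1 when `k = 0`.
#' @export
hyper_upper_tail <- function(k, K, n, N) {
  stopifnot(N >= 1, K <= N, n <= N, k <= min(K, n))
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
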