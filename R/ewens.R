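# Ewens sampling distribution of the number of haplotypes, and the
# haplotype-distribution neutrality tests built on it.

# log(exp(x) + exp(y)) without overflow; -Inf-safe
.lse2 <- function(x, y) {
  m <- pmax(x, y)
  out <- m + log1p(exp(pmin(x, y) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# log unsigned Stirling numbers of the first kind |s(n, k)|, k = 1..n,
# via the recurrence |s(n,k)| = (n-1)|s(n-1,k)| + |s(n-1,k-1)| carried in
# log space so that large n cannot overflow.
.log_stirling1 <- function(n) {
  row <- 0 # log|s(1,1)|
  if (n == 1L) return(row)
  for (m in 2:n) {
    prev <- c(row, -Inf)           # |s(m-1, k)|, k = 1..m
    shift <- c(-Inf, row)          # |s(m-1, k-1)|
    row <- .lse2(log(m - 1) + prev, shift)
  }
  row
}

#' Ewens sampling distribution of the number of distinct haplotypes
#'
#' P(K = k | n, theta) = |s(n, k)| theta^k / (theta (theta+1) ...
#' (theta+n-1)), with |s| the unsigned Stirling numbers of the first
#' kind.  Evaluated in log space, so it is stable for large n.
#'
#' @param n sample size, >= 1.
#' @param theta scaled mutation rate, >= 0.  `theta = 0` gives a point
#'   mass at K = 1.
#' @return probability vector over K = 1..n (sums to 1 up to rounding).
#' @examples
#' ewens_k_pmf(2, 1)          # (0.5, 0.5)
#' @export
ewens_k_pmf <- function(n, theta) {
  n <- .check_count(n, "n", min = 1L)
  if (length(theta) != 1L || !is.finite(theta) || theta < 0)
    .stop_domain("'theta' must be a single number >= 0")
  if (theta == 0) return(c(1, rep(0, n - 1L)))
  ls <- .log_stirling1(n)
  k <- seq_len(n)
  logdenom <- lgamma(theta + n) - lgamma(theta)
  exp(ls + k * log(theta) - logdenom)
}

#' Haplotype-distribution neutrality tests
#'
#' From the observed haplotype multiplicities and a scaled mutation rate
#' theta (conventionally the observed mean pairwise differences k):
#' \describe{
#'   \item{strobeck_s}{P(K <= K_obs | theta, n) under the Ewens sampling
#'     distribution.}
#'   \item{fu_w}{the upper-tail probability S' = P(K >= K_obs | theta, n);
#'     this package exposes the tail probability itself under this name
#'     (see the methods vignette for the reading of the ambiguous
#'     historical label).}
#'   \item{fu_fs}{Fs = ln(S' / (1 - S')).  When S' rounds to 0 or 1 the
#'     logit overflows and -Inf/+Inf is returned as the overflow
#'     sentinel.}
#'   \item{watterson_w}{the haplotype homozygosity sum(x_i^2), the
#'     statistic of the Ewens-Watterson homozygosity test.}
#' }
#'
#' @param counts haplotype multiplicities (or a [haplotype_counts()]
#'   object).
#' @param theta scaled mutation rate; defaults to `k` when omitted, and
#'   must end up > 0 — it is never silently estimated from the counts.
#' @param k observed mean pairwise differences, used as theta when
#'   `theta` is missing.
#' @return list with `strobeck_s`, `fu_w`, `fu_fs`, `watterson_w`.
#' @examples
#' haplotype_tests(c(1, 1), theta = 1)   # n = 2, K = 2: Fs = 0
#' @export
haplotype_tests <- function(counts, theta = NULL, k = NULL) {
  h <- if (inherits(counts, "haplotype_counts")) counts else haplotype_counts(counts)
  if (h$n < 2L) .stop_domain("haplotype tests need n >= 2")
  if (is.null(theta)) theta <- k
  if (is.null(theta) || length(theta) != 1L || !is.finite(theta) || theta <= 0)
    stop("haplotype tests need theta > 0 (supply 'theta' or 'k')", call. = FALSE)
  pmf <- ewens_k_pmf(h$n, theta)
  # tails spanning the whole support are 1 by construction, independent of
  # floating-point rounding in the pmf
  lower <- if (h$K == h$n) 1 else sum(pmf[seq_len(h$K)])
  upper <- if (h$K == 1L) 1 else sum(pmf[h$K:h$n])
  fs <- if (upper <= 0) -Inf else if (upper >= 1) Inf else log(upper / (1 - upper))
  x <- h$counts / h$n
  list(strobeck_s = lower, fu_w = upper, fu_fs = fs, watterson_w = sum(x^2))
}
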