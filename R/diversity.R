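# Genetic diversity statistics: H, Hd, k, pi, PIC.

#' Expected heterozygosity (gene diversity)
#'
#' H = 1 - sum(p_i^2) from allele relative frequencies.  With
#' `unbiased = TRUE` the plug-in value is multiplied by n/(n-1) (Nei's
#' sample-size correction), which requires the sample size in allele
#' copies.
#'
#' @param freqs numeric vector of allele frequencies (validated and
#'   renormalized via [check_freqs()]).
#' @param n sample size in allele copies; required when `unbiased = TRUE`.
#' @param unbiased apply the n/(n-1) correction? Default `FALSE`: the
#'   natural estimator when only frequencies, not sample sizes, are known.
#' @return heterozygosity in \[0, 1\] (the unbiased version can slightly
#'   exceed the plug-in bound).
#' @examples
#' expected_heterozygosity(c(0.5, 0.5))
#' expected_heterozygosity(c(0.5, 0.5), n = 10, unbiased = TRUE)
#' @export
expected_heterozygosity <- function(freqs, n = NULL, unbiased = FALSE) {
  p <- check_freqs(freqs)
  h <- 1 - sum(p^2)
  if (unbiased) {
    if (is.null(n))
      stop("unbiased heterozygosity requires the sample size 'n'", call. = FALSE)
    n <- .check_count(n, "n", min = 2L)
    h <- h * n / (n - 1)
  }
  h
}

#' Haplotype (gene) diversity Hd
#'
#' Hd = n/(n-1) * (1 - sum(x_i^2)) with x_i the relative frequency of the
#' i-th distinct haplotype: the sample-corrected probability that two
#' sequences drawn without replacement carry different haplotypes.
#'
#' @param counts positive integer multiplicities of the distinct
#'   haplotypes (or a [haplotype_counts()] object).
#' @return Hd in \[0, 1\].
#' @examples
#' haplotype_diversity(c(3, 1))   # 0.5
#' @export
haplotype_diversity <- function(counts) {
  h <- if (inherits(counts, "haplotype_counts")) counts else haplotype_counts(counts)
  if (h$n < 2L) .stop_domain("haplotype diversity needs n >= 2")
  x <- h$counts / h$n
  h$n / (h$n - 1) * (1 - sum(x^2))
}

#' Mean number of pairwise nucleotide differences k
#'
#' Two equivalent input routes: an unfolded or folded site frequency
#' spectrum (k = sum_i i (n - i) S_i * 2 / (n (n - 1)); the folded classes
#' contribute identically because i (n - i) is symmetric), or a symmetric
#' matrix of per-pair difference counts, averaged over the n(n-1)/2
#' unordered pairs.
#'
#' @param x an [sfs()] object (or numeric SFS counts with `n` supplied),
#'   or a symmetric pairwise-difference matrix with zero diagonal.
#' @param n sample size; only needed when `x` is a bare SFS count vector.
#' @return mean pairwise differences per sequence pair.
#' @examples
#' mean_pairwise_differences(sfs(c(2, 1, 0), n = 4))   # 5/3
#' @export
mean_pairwise_differences <- function(x, n = NULL) {
  if (inherits(x, "sfs")) {
    i <- if (x$folded) seq_len(x$n %/% 2L) else seq_len(x$n - 1L)
    return(sum(i * (x$n - i) * x$counts) * 2 / (x$n * (x$n - 1)))
  }
  if (is.matrix(x)) {
    if (nrow(x) != ncol(x) || nrow(x) < 2L)
      .stop_domain("pairwise difference matrix must be square, n >= 2")
    if (any(abs(x - t(x)) > 1e-9) || any(diag(x) != 0) || any(x < 0))
      .stop_domain("pairwise difference matrix must be symmetric, non-negative, zero-diagonal")
    return(mean(x[upper.tri(x)]))
  }
  if (is.null(n))
    .stop_domain("supply 'n' when passing a bare SFS count vector")
  mean_pairwise_differences(sfs(x, n = n))
}

#' Nucleotide diversity pi
#'
#' pi = k / L: mean pairwise differences per site.
#'
#' @param k mean pairwise nucleotide differences (differences per pair).
#' @param L sequence length in sites, >= 1.
#' @return per-site diversity in \[0, 1\].
#' @export
nucleotide_diversity <- function(k, L) {
  if (length(k) != 1L || !is.finite(k) || k < 0)
    .stop_domain("'k' must be a single non-negative number")
  if (length(L) != 1L || !is.finite(L) || L < 1)
    .stop_domain("'L' must be a sequence length >= 1")
  pi <- k / L
  if (pi > 1) .stop_domain("k/L exceeds 1; inconsistent k and L")
  pi
}

#' Polymorphism information content (PIC)
#'
#' PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2 (Botstein's marker
#' informativeness index).  The pair sum is evaluated as
#' ((sum p^2)^2 - sum p^4) to stay O(length(p)).
#'
#' @inheritParams expected_heterozygosity
#' @return PIC in \[0, 1).
#' @examples
#' pic(c(0.5, 0.5))          # 0.375
#' pic(rep(1, 3) / 3)        # 48/81
#' @export
pic <- function(freqs) {
  p <- check_freqs(freqs)
  s2 <- sum(p^2)
  1 - s2 - (s2^2 - sum(p^4))
}
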