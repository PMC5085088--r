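# Population differentiation: Nei's gene-diversity decomposition,
# Wright's F statistics, Hedrick's G'ST, Jost's D, allele-size R_ST and
# the Weir-Cockerham variance-component estimators.

.as_pop_freqs <- function(table, n = NULL) {
  if (inherits(table, "pop_freqs")) table else pop_freqs(table, n = n)
}

# weighted/unweighted per-pop weights
.pop_weights <- function(tab, weighted) {
  if (!weighted) return(rep(1 / tab$r, tab$r))
  if (is.null(tab$n))
    stop("sample-size weighting requires per-population sample sizes",
         call. = FALSE)
  tab$n / sum(tab$n)
}

#' Nei's gene-diversity decomposition (JS, JT, HS, HT, DST, GST)
#'
#' J_S is the mean within-subpopulation gene identity sum(p_ij^2), J_T
#' the identity of the pooled (mean) frequency vector; H_S = 1 - J_S,
#' H_T = 1 - J_T, D_ST = H_T - H_S and G_ST = D_ST / H_T.  Subpopulation
#' means are unweighted by default; `weighted = TRUE` uses sample-size
#' weights n_i / sum(n_i).  With `unbiased = TRUE` (requires n in allele
#' copies) each within-pop heterozygosity gets the n_i/(n_i - 1)
#' correction before averaging.
#'
#' @param table a [pop_freqs()] object or a pops x alleles frequency
#'   matrix.
#' @param n optional per-subpopulation sample sizes (allele copies).
#' @param weighted use sample-size weights for the subpopulation means?
#' @param unbiased apply the within-population sample-size correction?
#' @return list with `J_S, J_T, H_S, H_T, D_ST, G_ST` (G_ST is NA when
#'   H_T = 0, i.e. all pops fixed for the same allele).
#' @examples
#' nei_decomposition(rbind(c(0.7, 0.3), c(0.3, 0.7)))$G_ST   # 0.16
#' @export
nei_decomposition <- function(table, n = NULL, weighted = FALSE,
                              unbiased = FALSE) {
  tab <- .as_pop_freqs(table, n = n)
  w <- .pop_weights(tab, weighted)
  hs_i <- 1 - rowSums(tab$freqs^2)
  if (unbiased) {
    if (is.null(tab$n))
      stop("unbiased within-population diversity requires sample sizes",
           call. = FALSE)
    hs_i <- hs_i * tab$n / (tab$n - 1)
  }
  H_S <- sum(w * hs_i)
  pbar <- colSums(w * tab$freqs)
  J_T <- sum(pbar^2)
  H_T <- 1 - J_T
  D_ST <- H_T - H_S
  list(J_S = 1 - H_S, J_T = J_T, H_S = H_S, H_T = H_T, D_ST = D_ST,
       G_ST = if (H_T > 0) D_ST / H_T else NA_real_)
}

#' Wright's FST (equal and sample-size weighted) and FIS
#'
#' F_ST = (H_T - H_S)/H_T with equal subpopulation weights; the weighted
#' variant recomputes H_S and the pooled frequencies with weights
#' n_i/sum(n_i).  F_IS is computed per subpopulation as
#' 1 - H_obs,i / H_exp,i and averaged with the same weighting.
#'
#' @inheritParams nei_decomposition
#' @param obs_het optional per-subpopulation observed heterozygosity (one
#'   value per pop), required for F_IS.
#' @param weighted weighting used for the reported `F_IS` average.
#' @return list with `F_ST`, `F_ST_weighted` (NA without sample sizes)
#'   and `F_IS` (NA without `obs_het`).
#' @export
wright_f <- function(table, n = NULL, obs_het = NULL, weighted = FALSE) {
  tab <- .as_pop_freqs(table, n = n)
  f_from <- function(wtd) {
    d <- nei_decomposition(tab, weighted = wtd)
    if (is.na(d$G_ST)) NA_real_ else d$G_ST
  }
  out <- list(F_ST = f_from(FALSE),
              F_ST_weighted = if (is.null(tab$n)) NA_real_ else f_from(TRUE))
  if (is.null(obs_het)) {
    out$F_IS <- NA_real_
    return(out)
  }
  if (length(obs_het) != tab$r || anyNA(obs_het) ||
      any(obs_het < 0) || any(obs_het > 1))
    stop("'obs_het' must give one value in [0, 1] per subpopulation",
         call. = FALSE)
  hs_i <- 1 - rowSums(tab$freqs^2)
  w <- .pop_weights(tab, weighted)
  ok <- hs_i > 0
  if (!any(ok)) {
    out$F_IS <- NA_real_
  } else {
    fis_i <- 1 - obs_het[ok] / hs_i[ok]
    out$F_IS <- sum(w[ok] * fis_i) / sum(w[ok])
  }
  out
}

#' Hedrick's standardized G'ST
#'
#' G'_ST = G_ST (r - 1 + H_S) / ((r - 1)(1 - H_S)) rescales G_ST by its
#' maximum attainable value given the within-population diversity H_S.
#'
#' @param gst Nei's G_ST.
#' @param H_S mean within-subpopulation expected heterozygosity, in
#'   \[0, 1).
#' @param r number of subpopulations, >= 2.
#' @return G'_ST, or NA when H_S = 1.
#' @examples
#' hedrick_gst_prime(0.16, 0.42, 2)
#' @export
hedrick_gst_prime <- function(gst, H_S, r) {
  r <- .check_count(r, "r", min = 2L)
  if (!is.finite(H_S) || H_S < 0 || H_S > 1)
    .stop_domain("'H_S' must lie in [0, 1]")
  if (H_S >= 1) return(NA_real_)
  gst * (r - 1 + H_S) / ((r - 1) * (1 - H_S))
}

#' Jost's differentiation D
#'
#' D = (r/(r-1)) (H_T - H_S)/(1 - H_S): the fraction of allelic
#' diversity found between subpopulations, on the effective-number-of-
#' alleles scale (plug-in version).
#'
#' @param H_T total expected heterozygosity.
#' @param H_S mean within-subpopulation expected heterozygosity.
#' @param r number of subpopulations, >= 2.
#' @return D in \[0, 1\], or NA when H_S = 1.
#' @examples
#' jost_d(0.5, 0.42, 2)
#' @export
jost_d <- function(H_T, H_S, r) {
  r <- .check_count(r, "r", min = 2L)
  if (!is.finite(H_T) || !is.finite(H_S) || H_S < 0 || H_T < 0)
    .stop_domain("'H_T' and 'H_S' must be non-negative")
  if (H_S >= 1) return(NA_real_)
  r / (r - 1) * (H_T - H_S) / (1 - H_S)
}

#' Allele-size differentiation R_ST for stepwise-mutating loci
#'
#' R_ST = (Sbar - S_W)/Sbar, where S_W is the unweighted mean of the
#' within-subpopulation allele-size sample variances (denominator n - 1;
#' a single-observation subpopulation contributes 0) and Sbar the sample
#' variance of the pooled allele sizes.
#'
#' @param table an [allele_sizes()] object or a list of per-population
#'   allele-size vectors.
#' @return R_ST, or NA when the pooled variance is 0.
#' @examples
#' slatkin_rst(list(c(10, 12), c(14, 16)))   # 0.7
#' @export
slatkin_rst <- function(table) {
  tab <- if (inherits(table, "allele_sizes")) table else allele_sizes(table)
  all_sizes <- unlist(tab$sizes)
  if (length(all_sizes) < 2L)
    .stop_domain("R_ST needs at least 2 allele observations in total")
  v_within <- vapply(tab$sizes,
                     function(x) if (length(x) < 2L) 0 else stats::var(x),
                     numeric(1))
  S_W <- mean(v_within)
  S_bar <- stats::var(all_sizes)
  if (S_bar == 0) return(NA_real_)
  (S_bar - S_W) / S_bar
}

# ---- Weir & Cockerham variance components --------------------------------

# Per-allele components a (among pops), b (among individuals within
# pops), c (within individuals) for one locus of a genotype table.
.wc_components <- function(df) {
  pops <- sort(unique(df$pop))
  alleles <- sort(unique(c(df$allele1, df$allele2)))
  r <- length(pops)
  ni <- vapply(pops, function(p) sum(df$count[df$pop == p]), numeric(1))
  if (any(ni < 1)) .stop_domain("every subpopulation needs >= 1 individual")
  # p[i, u]: allele frequency; h[i, u]: freq of individuals heterozygous
  # for allele u
  p <- h <- matrix(0, r, length(alleles), dimnames = list(pops, alleles))
  for (rw in seq_len(nrow(df))) {
    i <- df$pop[rw]; a1 <- df$allele1[rw]; a2 <- df$allele2[rw]
    cnt <- df$count[rw]
    p[i, a1] <- p[i, a1] + cnt
    p[i, a2] <- p[i, a2] + cnt
    if (a1 != a2) {
      h[i, a1] <- h[i, a1] + cnt
      h[i, a2] <- h[i, a2] + cnt
    }
  }
  p <- p / (2 * ni)
  h <- h / ni
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  per_allele <- lapply(seq_along(alleles), function(u) {
    pbar <- sum(ni * p[, u]) / (r * nbar)
    s2 <- sum(ni * (p[, u] - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * h[, u]) / (r * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    c(a = a, b = b, c = cc, pbar = pbar)
  })
  do.call(rbind, per_allele)
}

#' Weir-Cockerham estimators of theta (FST) and f (FIS)
#'
#' Computes the per-allele variance components a (among populations),
#' b (among individuals within populations) and c (within individuals)
#' from diploid genotype counts, then combines them over alleles (and
#' loci) in three ways: `W` sums components before taking the ratios
#' theta = a/(a+b+c) and f = 1 - c/(b+c); `U` averages the per-allele
#' ratios unweighted; `RH` averages per-allele ratios with
#' Robertson-Hill-style weights pbar_u (1 - pbar_u) (this package's
#' documented reconstruction of that weighting).  Estimates may be
#' negative; `truncate = TRUE` clamps them to \[0, 1\].
#'
#' @param table a [genotype_tab()] object or a data.frame with columns
#'   `pop, allele1, allele2, count` (and optionally `locus`).
#' @param truncate clamp the estimates into \[0, 1\]?
#' @return list with `theta_W, theta_U, theta_RH, f_W, f_U, f_RH`; all NA
#'   when every locus is monomorphic across populations.
#' @examples
#' gt <- data.frame(pop = rep(c("A", "B"), each = 3),
#'                  allele1 = c("1", "1", "2", "1", "1", "2"),
#'                  allele2 = c("1", "2", "2", "1", "2", "2"),
#'                  count   = c(4, 2, 0, 1, 2, 3))
#' weir_cockerham(gt)$theta_W
#' @export
weir_cockerham <- function(table, truncate = FALSE) {
  df <- if (inherits(table, "genotype_tab")) table else genotype_tab(table)
  comp <- do.call(rbind, lapply(split(df, df$locus),
                                function(d) .wc_components(d)))
  denom <- comp[, "a"] + comp[, "b"] + comp[, "c"]
  poly <- denom > 0
  if (!any(poly))
    return(list(theta_W = NA_real_, theta_U = NA_real_, theta_RH = NA_real_,
                f_W = NA_real_, f_U = NA_real_, f_RH = NA_real_))
  comp <- comp[poly, , drop = FALSE]
  a <- comp[, "a"]; b <- comp[, "b"]; cc <- comp[, "c"]
  w_rh <- comp[, "pbar"] * (1 - comp[, "pbar"])
  theta_u <- a / (a + b + cc)
  f_u <- ifelse(b + cc > 0, 1 - cc / (b + cc), NA_real_)
  wmean <- function(x, w) {
    ok <- !is.na(x)
    if (!any(ok) || sum(w[ok]) == 0) NA_real_ else sum(x[ok] * w[ok]) / sum(w[ok])
  }
  out <- list(
    theta_W = sum(a) / sum(a + b + cc),
    theta_U = mean(theta_u),
    theta_RH = wmean(theta_u, w_rh),
    f_W = if (sum(b + cc) > 0) 1 - sum(cc) / sum(b + cc) else NA_real_,
    f_U = if (all(is.na(f_u))) NA_real_ else mean(f_u, na.rm = TRUE),
    f_RH = wmean(f_u, w_rh))
  if (truncate)
    out <- lapply(out, function(x) if (is.na(x)) x else min(1, max(0, x)))
  out
}
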