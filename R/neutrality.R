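# SFS- and mutation-class-based neutrality tests.
#
# Statistics that are undefined on the given input (S = 0, eta = 0, n too
# small) return NA_real_ rather than throwing, so that batch runs keep
# going; the CLI renders these as "NA".

#' Watterson's estimator of theta
#'
#' theta_W = S / a1(n), with a1 the (n-1)-th harmonic number.
#'
#' @param S number of segregating sites.
#' @param n sample size (sequences).
#' @return theta per locus.
#' @examples
#' watterson_theta(10, 5)   # 4.8
#' @export
watterson_theta <- function(S, n) {
  S <- .check_count(S, "S")
  n <- .check_count(n, "n", min = 2L)
  S / harmonic_constants(n)$a1
}

#' Tajima's D
#'
#' D = (k - S/a1) / sqrt(e1 S + e2 S (S - 1)): the standardized contrast
#' between the mean-pairwise-difference and segregating-sites estimators
#' of theta.  Undefined (NA) when S = 0.
#'
#' @param n sample size (sequences), >= 2.
#' @param S number of segregating sites.
#' @param k mean pairwise nucleotide differences.
#' @return D, or NA when S = 0.
#' @examples
#' tajima_d(n = 4, S = 3, k = 2)
#' @export
tajima_d <- function(n, S, k) {
  n <- .check_count(n, "n", min = 2L)
  S <- .check_count(S, "S")
  if (!is.finite(k) || k < 0) .stop_domain("'k' must be non-negative")
  if (S == 0L) return(NA_real_)
  h <- harmonic_constants(n)
  (k - S / h$a1) / sqrt(h$e1 * S + h$e2 * S * (S - 1))
}

#' Fu and Li's D, F, D* and F* tests
#'
#' Numerators contrast the total number of mutations eta with the
#' external/singleton mutation classes: D = (eta - a_n eta_e) / sd,
#' F = (k - eta_e) / sd, D* = (n/(n-1) eta - a_n eta_s) / sd,
#' F* = (k - (n-1)/n eta_s) / sd, each standardized by
#' sqrt(u eta + v eta^2) with the published u/v coefficients
#' (as corrected by Simonsen, Churchill and Aquadro).  D and F need
#' outgroup-polarized external singletons `eta_e`; D* and F* need the
#' unpolarized singleton count `eta_s` and n >= 3.
#'
#' @param n sample size (sequences).
#' @param eta total number of mutations.
#' @param k mean pairwise differences (needed for F and F*).
#' @param eta_s number of singleton mutations.
#' @param eta_e number of external (outgroup-polarized derived singleton)
#'   mutations.
#' @param tests character subset of `c("D", "F", "D_star", "F_star")`;
#'   default computes every test whose inputs were supplied.  Explicitly
#'   requesting a test whose inputs are missing is an error.
#' @return named list of the requested statistics; NA where eta = 0.
#' @examples
#' fu_li_tests(n = 5, eta = 4, k = 1.8, eta_s = 1, eta_e = 1)
#' @export
fu_li_tests <- function(n, eta, k = NULL, eta_s = NULL, eta_e = NULL,
                        tests = NULL) {
  n <- .check_count(n, "n", min = 2L)
  eta <- .check_count(eta, "eta")
  all_tests <- c("D", "F", "D_star", "F_star")
  have <- c(D = !is.null(eta_e),
            F = !is.null(eta_e) && !is.null(k),
            D_star = !is.null(eta_s) && n >= 3L,
            F_star = !is.null(eta_s) && !is.null(k) && n >= 3L)
  if (is.null(tests)) {
    tests <- all_tests[have]
  } else {
    tests <- match.arg(tests, all_tests, several.ok = TRUE)
    if (!all(have[tests]))
      stop("missing inputs for requested Fu-Li test(s): ",
           paste(tests[!have[tests]], collapse = ", "), call. = FALSE)
  }
  if (length(tests) == 0L)
    stop("no Fu-Li test computable from the supplied inputs", call. = FALSE)
  uv <- .fu_li_uv(n)
  val <- function(num, u, v) {
    if (eta == 0L) return(NA_real_)
    if (num == 0) return(0)  # a vanishing numerator is exactly 0
    s2 <- u * eta + v * eta^2
    if (!is.finite(s2) || s2 <= 0) return(NA_real_)
    num / sqrt(s2)
  }
  out <- list()
  if ("D" %in% tests) out$D <- val(eta - uv$a * eta_e, uv$uD, uv$vD)
  if ("F" %in% tests) out$F <- val(k - eta_e, uv$uF, uv$vF)
  if ("D_star" %in% tests)
    out$D_star <- val(n / (n - 1) * eta - uv$a * eta_s, uv$uDs, uv$vDs)
  if ("F_star" %in% tests)
    out$F_star <- val(k - (n - 1) / n * eta_s, uv$uFs, uv$vFs)
  out
}

#' Fay-Wu and Zeng statistics from an unfolded SFS
#'
#' Computes the frequency-weighted theta estimators
#' theta_pi = sum 2 i (n-i) S_i / (n(n-1)),
#' theta_H = sum 2 i^2 S_i / (n(n-1)),
#' theta_L = sum i S_i / (n-1), theta_W = S/a1, the unnormalized
#' Fay-Wu H = theta_pi - theta_H (= 2 (theta_pi - theta_L)), the
#' normalized H_n = (theta_pi - theta_L)/sqrt(Var) and Zeng's
#' E = (theta_L - theta_W)/sqrt(Var), with the published variance
#' expressions.  theta is plugged in as theta_W and theta^2 as the
#' unbiased S(S-1)/(a1^2 + a2).
#'
#' Requires derived-allele polarization: folded spectra are rejected.
#'
#' @param x an unfolded [sfs()] object, or numeric counts with `n` given.
#' @param n sample size, when `x` is a bare count vector.
#' @return list with `theta_pi`, `theta_h`, `theta_l`, `theta_w`, `H`,
#'   `Hn`, `E`.  H is 0 and Hn/E are NA when S = 0.
#' @examples
#' fay_wu_zeng(sfs(c(2, 1, 0), n = 4))$H   # 2/3
#' @export
fay_wu_zeng <- function(x, n = NULL) {
  if (!inherits(x, "sfs")) x <- sfs(x, n = n)
  if (x$folded)
    stop("Fay-Wu/Zeng statistics need an unfolded (outgroup-polarized) SFS",
         call. = FALSE)
  n <- x$n
  i <- seq_len(n - 1L)
  S <- sum(x$counts)
  theta_pi <- sum(2 * i * (n - i) * x$counts) / (n * (n - 1))
  theta_h  <- sum(2 * i^2 * x$counts) / (n * (n - 1))
  theta_l  <- sum(i * x$counts) / (n - 1)
  h <- harmonic_constants(n)
  theta_w <- S / h$a1
  out <- list(theta_pi = theta_pi, theta_h = theta_h, theta_l = theta_l,
              theta_w = theta_w, H = theta_pi - theta_h,
              Hn = NA_real_, E = NA_real_)
  if (S == 0L) return(out)
  bn1 <- h$a2 + 1 / n^2                      # sum_{i<=n} 1/i^2
  theta2 <- S * (S - 1) / (h$a1^2 + h$a2)    # unbiased estimate of theta^2
  var_hl <- (n - 2) / (6 * (n - 1)) * theta_w +
    (18 * n^2 * (3 * n + 2) * bn1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
    (9 * n * (n - 1)^2) * theta2
  var_e <- (n / (2 * (n - 1)) - 1 / h$a1) * theta_w +
    (h$a2 / h$a1^2 + 2 * (n / (n - 1))^2 * h$a2 -
       2 * (n * h$a2 - n + 1) / ((n - 1) * h$a1) -
       (3 * n + 1) / (n - 1)) * theta2
  out$Hn <- (theta_pi - theta_l) / sqrt(var_hl)
  out$E  <- (theta_l - theta_w) / sqrt(var_e)
  out
}
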