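# Shared harmonic-sum constants of the SFS-based neutrality tests.

#' Harmonic constants for sample size n
#'
#' Returns the harmonic sums a1 = sum_{i<n} 1/i, a2 = sum_{i<n} 1/i^2 and
#' the derived Tajima normalization constants b1, b2, c1, c2, e1, e2,
#' together with the Fu-Li auxiliaries a_n (= a1), b_n (= a2),
#' c_n = 2 (n a_n - 2(n-1)) / ((n-1)(n-2)) and
#' d_n = c_n + (n-2)/(n-1)^2 + 2/(n-1) (3/2 - (2 a_{n+1} - 3)/(n-2) - 1/n)
#' (d_n is NA at n = 2, where the starred tests are not defined).
#'
#' @param n sample size (number of sequences), >= 2.
#' @return named list with `a1, a2, b1, b2, c1, c2, e1, e2, a_n, b_n,
#'   c_n, d_n, a_n1` (a_{n+1} = a_n + 1/n).
#' @examples
#' harmonic_constants(4)$a1   # 11/6
#' @export
harmonic_constants <- function(n) {
  n <- .check_count(n, "n", min = 2L)
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  an1 <- a1 + 1 / n
  cn <- if (n == 2L) 1 else 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- if (n == 2L) NA_real_ else
    cn + (n - 2) / (n - 1)^2 + 2 / (n - 1) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2),
       a_n = a1, b_n = a2, c_n = cn, d_n = dn, a_n1 = an1)
}

# u/v variance coefficients for the four Fu-Li tests (with the standard
# corrections to the originally printed formulas).
.fu_li_uv <- function(n) {
  h <- harmonic_constants(n)
  a <- h$a_n; b <- h$b_n; cn <- h$c_n; dn <- h$d_n; an1 <- h$a_n1
  vD <- 1 + a^2 / (b + a^2) * (cn - (n + 1) / (n - 1))
  uD <- a - 1 - vD
  vF <- (cn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) - 2 / (n - 1)) / (a^2 + b)
  uF <- (1 + (n + 1) / (3 * (n - 1)) -
           4 * (n + 2) / ((n + 1) * (n - 1)) * (an1 - 2 * n / (n + 1))) / a - vF
  if (is.na(dn)) {
    vDs <- uDs <- vFs <- uFs <- NA_real_
  } else {
    vDs <- ((n / (n - 1))^2 * b + a^2 * dn -
              2 * n * a * (a + 1) / (n - 1)^2) / (a^2 + b)
    uDs <- n / (n - 1) * (a - n / (n - 1)) - vDs
    vFs <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
              2 / (n - 1) * (4 * b - 6 + 8 / n)) / (a^2 + b)
    uFs <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
              2 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / a - vFs
  }
  list(a = a, b = b,
       uD = uD, vD = vD, uF = uF, vF = vF,
       uDs = uDs, vDs = vDs, uFs = uFs, vFs = vFs)
}
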