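# Singleton-profile statistics of the Ramos-Onsins family.

#' Ramos-Onsins singleton statistics (R2 family, Ch, Che, ku)
#'
#' Let U_i be the number of singleton mutations carried by sequence i and
#' k the mean pairwise differences; under neutrality each sequence is
#' expected to carry about k/2 singletons.  The statistics summarize the
#' centered profile d_i = U_i - k/2:
#' \describe{
#'   \item{R2}{sqrt(mean(d_i^2)) / S}
#'   \item{R3}{cbrt(mean(|d_i|^3)) / S}
#'   \item{R4}{mean(d_i^4)^(1/4) / S}
#'   \item{Ch}{mean(d_i^2) / (k/2), a chi-square-style dispersion of the
#'     singleton profile (NA when k = 0)}
#'   \item{ku}{mean(d_i^4) / mean(d_i^2)^2, the kurtosis ratio of the
#'     profile (NA when the second moment vanishes)}
#' }
#' The E-variants (R2E, R3E, R4E, Che) substitute the outgroup-polarized
#' external singletons U_i^e for U_i.  Ch, Che and ku are this package's
#' documented reading of the historically under-specified labels; see the
#' methods vignette.
#'
#' All statistics are NA when S = 0.
#'
#' @param profile a [singleton_profile()] object, or the numeric vector
#'   U of per-sequence singleton counts.
#' @param k mean pairwise nucleotide differences.
#' @param S number of segregating sites.
#' @param U_ext optional per-sequence external singleton counts (ignored
#'   when `profile` is a [singleton_profile()] that already carries them).
#' @return named list with `R2, R3, R4, Ch, ku` and, when external
#'   singletons are available, `R2E, R3E, R4E, Che`.
#' @examples
#' r_family(c(1, 0, 0, 0), k = 0.5, S = 1)$R2
#' @export
r_family <- function(profile, k, S, U_ext = NULL) {
  if (!inherits(profile, "singleton_profile"))
    profile <- singleton_profile(profile, U_ext = U_ext)
  S <- .check_count(S, "S")
  if (length(k) != 1L || !is.finite(k) || k < 0)
    .stop_domain("'k' must be a single non-negative number")
  moments <- function(U) {
    d <- U - k / 2
    m2 <- mean(d^2); m3 <- mean(abs(d)^3); m4 <- mean(d^4)
    list(R = c(sqrt(m2), m3^(1 / 3), m4^(1 / 4)) / S,
         Ch = if (k > 0) m2 / (k / 2) else NA_real_,
         ku = if (m2 > 0) m4 / m2^2 else NA_real_)
  }
  if (S == 0L) {
    out <- list(R2 = NA_real_, R3 = NA_real_, R4 = NA_real_,
                Ch = NA_real_, ku = NA_real_)
    if (!is.null(profile$U_ext))
      out <- c(out, list(R2E = NA_real_, R3E = NA_real_, R4E = NA_real_,
                         Che = NA_real_))
    return(out)
  }
  m <- moments(profile$U)
  out <- list(R2 = m$R[1], R3 = m$R[2], R4 = m$R[3], Ch = m$Ch, ku = m$ku)
  if (!is.null(profile$U_ext)) {
    me <- moments(profile$U_ext)
    out <- c(out, list(R2E = me$R[1], R3E = me$R[2], R4E = me$R[3],
                       Che = me$Ch))
  }
  out
}
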