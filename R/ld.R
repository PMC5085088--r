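# Linkage-disequilibrium summaries over a phased haplotype matrix.

# r^2 between two binary site columns: D^2 / (pA qA pB qB) with
# D = p11 - pA pB, estimated from phased haplotype counts.
.r2_pair <- function(a, b) {
  pA <- mean(a); pB <- mean(b)
  D <- mean(a * b) - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' Kelly's ZnS and ZA linkage-disequilibrium statistics
#'
#' ZnS is the mean squared correlation r^2 over all S(S-1)/2 pairs of
#' polymorphic sites; ZA averages r^2 over the S-1 physically adjacent
#' pairs only (adjacency taken from the column positions).  r^2 uses the
#' phased-haplotype definition D^2/(pA qA pB qB).
#'
#' @param x a [hap_matrix()] object, or a binary 0/1 matrix with
#'   haplotypes in rows.
#' @param positions optional site coordinates when `x` is a bare matrix.
#' @return list with `ZnS` and `ZA`, both in \[0, 1\]; NA when fewer than
#'   2 polymorphic sites are present.
#' @examples
#' m <- cbind(c(0, 0, 1, 1), c(0, 0, 1, 1), c(0, 1, 0, 1))
#' kelly_z(m)
#' @export
kelly_z <- function(x, positions = NULL) {
  if (!inherits(x, "hap_matrix")) x <- hap_matrix(x, positions = positions)
  m <- x$matrix
  S <- ncol(m)
  if (S < 2L) return(list(ZnS = NA_real_, ZA = NA_real_))
  ord <- order(x$positions)
  m <- m[, ord, drop = FALSE]
  r2 <- matrix(0, S, S)
  for (i in seq_len(S - 1L))
    for (j in (i + 1L):S)
      r2[i, j] <- .r2_pair(m[, i], m[, j])
  zns <- sum(r2) / (S * (S - 1) / 2)
  za <- mean(r2[cbind(seq_len(S - 1L), 2:S)])
  list(ZnS = zns, ZA = za)
}
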