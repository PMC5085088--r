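#' @keywords internal
"_PACKAGE"

# Shared input validators and lightweight S3 containers.
#
# Every statistic works on descriptive summary metadata, never on raw
# sequence alignments, so the containers are thin wrappers around numeric
# vectors/matrices with the invariants the formulas rely on enforced at
# construction time.

.stop_domain <- function(...) stop(..., call. = FALSE)

.check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    .stop_domain(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}

#' Validate (and renormalize) an allele-frequency vector
#'
#' Frequencies must lie in \[0, 1\] and sum to 1 within `tol`; sums inside
#' the tolerance are silently renormalized, larger deviations are an error
#' (they usually mean a truncated input file).
#'
#' @param freqs numeric vector of relative allele frequencies.
#' @param tol allowed deviation of `sum(freqs)` from 1.
#' @return the renormalized frequency vector.
#' @export
check_freqs <- function(freqs, tol = 1e-6) {
  freqs <- as.numeric(freqs)
  if (length(freqs) < 1L || anyNA(freqs))
    .stop_domain("frequencies must be a non-empty numeric vector without NA")
  if (any(freqs < 0) || any(freqs > 1))
    .stop_domain("every allele frequency must lie in [0, 1]")
  s <- sum(freqs)
  if (abs(s - 1) > tol)
    .stop_domain(sprintf("frequencies sum to %.6g, not 1 (tolerance %g)", s, tol))
  freqs / s
}

#' Site frequency spectrum container
#'
#' An unfolded spectrum holds counts of sites whose derived allele occurs
#' in i = 1..n-1 sampled sequences; a folded spectrum holds minor-allele
#' classes i = 1..floor(n/2).  Folded spectra disable outgroup-polarized
#' statistics downstream.
#'
#' @param counts non-negative integer vector of per-class site counts.
#' @param n sample size (number of sequences), >= 2.
#' @param folded logical; is `counts` a minor-allele (folded) spectrum?
#' @return an object of class `"sfs"`.
#' @export
sfs <- function(counts, n, folded = FALSE) {
  n <- .check_count(n, "n", min = 2L)
  counts <- as.numeric(counts)
  len <- if (folded) n %/% 2L else n - 1L
  if (length(counts) != len)
    .stop_domain(sprintf("SFS for n = %d must have %d classes, got %d",
                         n, len, length(counts)))
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    .stop_domain("SFS entries must be non-negative integers")
  structure(list(counts = counts, n = n, folded = folded), class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("%s site frequency spectrum: n = %d, S = %d\n",
              if (x$folded) "folded" else "unfolded", x$n, sum(x$counts)))
  invisible(x)
}

#' Haplotype multiplicity container
#'
#' @param counts positive integer multiplicities of the distinct haplotypes.
#' @return an object of class `"haplotype_counts"` with fields `counts`,
#'   `n` (total sample size) and `K` (number of distinct haplotypes).
#' @export
haplotype_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 1L || anyNA(counts) ||
      any(counts < 1) || any(counts != round(counts)))
    .stop_domain("haplotype counts must be positive integers")
  structure(list(counts = as.integer(counts), n = as.integer(sum(counts)),
                 K = length(counts)),
            class = "haplotype_counts")
}

#' Mismatch (pairwise difference) distribution container
#'
#' Accepts either relative frequencies (summing to 1 within 1e-6) or raw
#' class counts, which are normalized on ingest.  Class i holds the
#' probability that a random sequence pair differs at exactly i sites,
#' i = 0..d.
#'
#' @param x numeric vector of frequencies or counts over classes `0..d`.
#' @return object of class `"mismatch_dist"` with normalized `probs`.
#' @export
mismatch_dist <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 1L || anyNA(x) || any(x < 0))
    .stop_domain("mismatch distribution must be non-empty and non-negative")
  s <- sum(x)
  if (s <= 0) .stop_domain("mismatch distribution sums to zero")
  if (abs(s - 1) > 1e-6 && any(x != round(x)))
    .stop_domain("mismatch input is neither a frequency vector (sum 1) nor integer counts")
  structure(list(probs = x / s), class = "mismatch_dist")
}

#' Binary haplotype-by-site matrix container
#'
#' Rows are phased haplotypes, columns are polymorphic sites coded 0
#' (ancestral/major) / 1 (derived/minor).  Every column must be
#' polymorphic in the sample.
#'
#' @param m binary 0/1 matrix, haplotypes in rows.
#' @param positions optional numeric site coordinates (one per column),
#'   used to define physical adjacency for `kelly_z()`'s ZA.
#' @return object of class `"hap_matrix"`.
#' @export
hap_matrix <- function(m, positions = NULL) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  if (nrow(m) < 2L) .stop_domain("haplotype matrix needs at least 2 rows")
  if (anyNA(m) || !all(m %in% c(0L, 1L)))
    .stop_domain("haplotype matrix entries must be 0/1")
  if (ncol(m) > 0L) {
    cs <- colSums(m)
    if (any(cs == 0L | cs == nrow(m)))
      .stop_domain("every haplotype-matrix column must be polymorphic")
  }
  if (is.null(positions)) positions <- seq_len(ncol(m))
  if (length(positions) != ncol(m))
    .stop_domain("'positions' must have one coordinate per column")
  structure(list(matrix = m, positions = as.numeric(positions)),
            class = "hap_matrix")
}

#' Per-sequence singleton profile
#'
#' `U[i]` is the number of singleton mutations carried by sequence i;
#' `U_ext` optionally holds the outgroup-polarized external (derived)
#' singletons per sequence, enabling the E-variants of the Ramos-Onsins
#' statistics.
#'
#' @param U non-negative integer vector, one entry per sequence.
#' @param U_ext optional vector of external singletons, same length.
#' @return object of class `"singleton_profile"`.
#' @export
singleton_profile <- function(U, U_ext = NULL) {
  U <- as.numeric(U)
  if (length(U) < 2L || anyNA(U) || any(U < 0) || any(U != round(U)))
    .stop_domain("'U' must be non-negative integers, one per sequence (n >= 2)")
  if (!is.null(U_ext)) {
    U_ext <- as.numeric(U_ext)
    if (length(U_ext) != length(U) || anyNA(U_ext) ||
        any(U_ext < 0) || any(U_ext != round(U_ext)))
      .stop_domain("'U_ext' must match 'U' in length and be non-negative integers")
  }
  structure(list(U = U, U_ext = U_ext, n = length(U)),
            class = "singleton_profile")
}

#' Per-subpopulation allele frequency table
#'
#' @param freqs matrix of relative allele frequencies, one row per
#'   subpopulation, columns over a shared allele set; each row must sum to
#'   1 within 1e-6 (renormalized).
#' @param n optional vector of per-subpopulation sample sizes in allele
#'   copies.
#' @return object of class `"pop_freqs"`.
#' @export
pop_freqs <- function(freqs, n = NULL) {
  freqs <- as.matrix(freqs)
  if (nrow(freqs) < 2L)
    .stop_domain("at least 2 subpopulations are required")
  fixed <- t(apply(freqs, 1L, check_freqs))
  freqs[] <- if (ncol(freqs) == 1L) t(fixed) else fixed
  if (!is.null(n)) {
    if (length(n) != nrow(freqs) || anyNA(n) || any(n < 2) || any(n != round(n)))
      .stop_domain("'n' must give an integer sample size >= 2 per subpopulation")
    n <- as.integer(n)
  }
  structure(list(freqs = freqs, n = n, r = nrow(freqs)), class = "pop_freqs")
}

#' Per-subpopulation diploid genotype count table
#'
#' Long format: one row per (pop, allele1, allele2) unordered genotype with
#' its count of individuals.  An optional `locus` column allows multi-locus
#' tables for the Weir-Cockerham estimators.
#'
#' @param df data.frame with columns `pop`, `allele1`, `allele2`, `count`
#'   and optionally `locus`.
#' @return object of class `"genotype_tab"` (a validated data.frame).
#' @export
genotype_tab <- function(df) {
  df <- as.data.frame(df)
  need <- c("pop", "allele1", "allele2", "count")
  if (!all(need %in% names(df)))
    .stop_domain("genotype table needs columns pop, allele1, allele2, count")
  if (!("locus" %in% names(df))) df$locus <- "locus1"
  if (anyNA(df$count) || any(df$count < 0) || any(df$count != round(df$count)))
    .stop_domain("genotype counts must be non-negative integers")
  df$count <- as.integer(df$count)
  for (col in c("pop", "locus", "allele1", "allele2"))
    df[[col]] <- as.character(df[[col]])
  if (length(unique(df$pop)) < 2L)
    .stop_domain("at least 2 subpopulations are required")
  class(df) <- c("genotype_tab", "data.frame")
  df
}

#' Per-subpopulation microsatellite allele-size table
#'
#' @param sizes list of numeric vectors, one multiset of allele sizes
#'   (repeat units, positive integers) per subpopulation.
#' @return object of class `"allele_sizes"`.
#' @export
allele_sizes <- function(sizes) {
  if (!is.list(sizes) || length(sizes) < 2L)
    .stop_domain("at least 2 subpopulations of allele sizes are required")
  sizes <- lapply(sizes, as.numeric)
  ok <- vapply(sizes, function(x)
    length(x) >= 1L && !anyNA(x) && all(x > 0) && all(x == round(x)),
    logical(1))
  if (!all(ok))
    .stop_domain("allele sizes must be non-empty vectors of positive integers")
  structure(list(sizes = sizes, r = length(sizes)), class = "allele_sizes")
}
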