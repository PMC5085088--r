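# Synthetic-input generators: a minimal neutral Kingman coalescent
# (infinite sites, no recombination) and a Dirichlet-multinomial
# population-frequency sampler.  These back the property-based test
# surface and let users calibrate null distributions; they are test
# infrastructure, not a statistical contribution.

.coalescent_one <- function(n, theta) {
  # active lineages carry their leaf sets and birth times; a branch is
  # recorded (length + leaf set) when it coalesces.  The root lineage is
  # never recorded, so every mutation is polymorphic in the sample.
  sets <- lapply(seq_len(n), identity)
  start <- numeric(n)
  t <- 0
  br_len <- numeric(2L * (n - 1L))
  br_size <- integer(2L * (n - 1L))
  br_sets <- vector("list", 2L * (n - 1L))
  bi <- 0L
  j <- n
  while (j > 1L) {
    t <- t + stats::rexp(1L, j * (j - 1) / 2)
    pair <- sample.int(j, 2L)
    for (p in pair) {
      bi <- bi + 1L
      br_len[bi] <- t - start[p]
      br_size[bi] <- length(sets[[p]])
      br_sets[[bi]] <- sets[[p]]
    }
    merged <- c(sets[[pair[1L]]], sets[[pair[2L]]])
    keep <- setdiff(seq_len(j), pair)
    sets <- c(sets[keep], list(merged))
    start <- c(start[keep], t)
    j <- j - 1L
  }
  mut <- stats::rpois(bi, theta / 2 * br_len)
  S <- sum(mut)
  counts <- tabulate(rep.int(br_size, mut), nbins = n - 1L)
  m <- matrix(0L, n, S)
  col <- 0L
  for (b in seq_len(bi)) {
    if (mut[b] == 0L) next
    for (s in seq_len(mut[b])) {
      col <- col + 1L
      m[br_sets[[b]], col] <- 1L
    }
  }
  spec <- sfs(counts, n = n)
  hap_counts <- if (S == 0L) n else
    as.integer(table(apply(m, 1L, paste, collapse = "")))
  structure(list(n = n, theta = theta,
                 sfs = spec,
                 matrix = hap_matrix(m),
                 haplotypes = haplotype_counts(hap_counts),
                 k = mean_pairwise_differences(spec)),
            class = "coal_replicate")
}

#' Simulate neutral coalescent replicates
#'
#' Standard Kingman coalescent for a panmictic constant-size population:
#' while j lineages remain, the next coalescence is exponential with rate
#' j(j-1)/2, a uniformly chosen pair merges, and mutations fall on each
#' branch as Poisson(theta/2 * length) under the infinite-sites model
#' (so eta = S in every replicate).  Each replicate carries a mutually
#' consistent unfolded SFS, haplotype matrix, haplotype multiplicities
#' and realized mean pairwise differences k.
#'
#' @param n sample size (sequences), >= 2.
#' @param theta scaled mutation rate 4 N mu, >= 0.
#' @param reps number of independent replicates.
#' @param seed optional integer seed; replicates are bit-reproducible
#'   under a fixed seed.
#' @return list of `reps` objects of class `"coal_replicate"`, each with
#'   fields `n, theta, sfs, matrix, haplotypes, k`.
#' @examples
#' reps <- simulate_coalescent(n = 6, theta = 2, reps = 3, seed = 1)
#' reps[[1]]$k
#' @export
simulate_coalescent <- function(n, theta, reps = 1L, seed = NULL) {
  n <- .check_count(n, "n", min = 2L)
  reps <- .check_count(reps, "reps", min = 1L)
  if (!is.finite(theta) || theta < 0) .stop_domain("'theta' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(reps), function(i) .coalescent_one(n, theta))
}

#' Simulate a Dirichlet-multinomial population frequency table
#'
#' Draws a shared ancestral allele-frequency vector from a symmetric
#' Dirichlet(1), then per-population frequency vectors from a Dirichlet
#' centered on the ancestral vector with total concentration
#' `concentration` (large values keep populations close to the ancestral
#' frequencies, small values push them toward fixation), and finally
#' multinomial samples of `n_i` allele copies per population.
#'
#' @param r number of populations, >= 2.
#' @param alleles number of alleles at the locus, >= 2.
#' @param concentration Dirichlet concentration parameter, > 0.
#' @param n_i per-population sample sizes in allele copies (recycled to
#'   length `r`).
#' @param seed optional integer seed.
#' @return a [pop_freqs()] table of observed (sampled) frequencies.
#' @export
simulate_population_freqs <- function(r, alleles, concentration,
                                      n_i = 100L, seed = NULL) {
  r <- .check_count(r, "r", min = 2L)
  alleles <- .check_count(alleles, "alleles", min = 2L)
  if (!is.finite(concentration) || concentration <= 0)
    .stop_domain("'concentration' must be > 0")
  n_i <- rep_len(as.integer(n_i), r)
  if (any(n_i < 2)) .stop_domain("'n_i' must be >= 2 allele copies")
  if (!is.null(seed)) set.seed(seed)
  rdirichlet <- function(alpha) {
    g <- stats::rgamma(length(alpha), shape = alpha)
    if (sum(g) == 0) g[which.max(alpha)] <- 1
    g / sum(g)
  }
  anc <- rdirichlet(rep(1, alleles))
  freqs <- t(vapply(seq_len(r), function(i) {
    p <- rdirichlet(concentration * anc)
    cnt <- stats::rmultinom(1L, n_i[i], p)[, 1L]
    cnt / n_i[i]
  }, numeric(alleles)))
  pop_freqs(freqs, n = n_i)
}

#' Mismatch distribution realized by a haplotype matrix
#'
#' Tabulates the pairwise Hamming distances between all unordered rows of
#' a binary haplotype matrix into a [mismatch_dist()] over classes
#' 0..max(distance).
#'
#' @param x a [hap_matrix()] object or binary 0/1 matrix.
#' @return a [mismatch_dist()] object.
#' @export
mismatch_from_matrix <- function(x) {
  if (!inherits(x, "hap_matrix")) x <- hap_matrix(x)
  m <- x$matrix
  n <- nrow(m)
  d <- unlist(lapply(seq_len(n - 1L), function(i)
    colSums(abs(t(m[(i + 1L):n, , drop = FALSE]) - m[i, ]))))
  mismatch_dist(tabulate(d + 1L, nbins = max(d) + 1L))
}
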