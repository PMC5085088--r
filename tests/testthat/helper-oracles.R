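# Independent brute-force oracles used against the closed-form routes.

# mean pairwise Hamming distance over all unordered row pairs
oracle_k_matrix <- function(m) {
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      tot <- tot + sum(m[i, ] != m[j, ])
  tot / (n * (n - 1) / 2)
}

# r^2 from the 2x2 haplotype table of two binary columns
oracle_r2_pair <- function(a, b) {
  p11 <- mean(a == 1 & b == 1)
  pA <- mean(a); pB <- mean(b)
  (p11 - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
}

oracle_zns <- function(m) {
  S <- ncol(m)
  vals <- c()
  for (i in seq_len(S - 1))
    for (j in (i + 1):S)
      vals <- c(vals, oracle_r2_pair(m[, i], m[, j]))
  mean(vals)
}

# random binary haplotype matrix with every column polymorphic
random_hap_matrix <- function(n, S) {
  m <- vapply(seq_len(S), function(s) {
    i <- sample.int(n - 1, 1)
    col <- integer(n)
    col[sample.int(n, i)] <- 1L
    col
  }, integer(n))
  matrix(m, nrow = n)
}

sfs_from_matrix <- function(m) tabulate(colSums(m), nbins = nrow(m) - 1)

# |s(n, k)| by expanding the rising factorial x(x+1)...(x+n-1):
# a route independent of the package's log-space recurrence
oracle_stirling1 <- function(n) {
  p <- 1
  for (m in 0:(n - 1)) p <- c(0, p) + m * c(p, 0)
  p[-1]  # coefficient of x^k, k = 1..n
}

# frequency table fixture: the two-population 0.7/0.3 contrast
two_pop_table <- function() rbind(c(0.7, 0.3), c(0.3, 0.7))

# genotype-count fixture with frozen Weir-Cockerham values
wc_fixture <- function() {
  data.frame(pop = rep(c("A", "B"), each = 3),
             allele1 = c("1", "1", "2", "1", "1", "2"),
             allele2 = c("1", "2", "2", "1", "2", "2"),
             count = c(4, 2, 0, 1, 2, 3))
}
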