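---
title: "Methods and design choices in popgenstats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in popgenstats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgenstats)
```

`popgenstats` implements the calculation step of 45 basic statistics of
molecular population genetics on *summary metadata*. This vignette
documents the models behind the three statistic classes, the numerical
conventions, and the places where the historical literature leaves room
and this package had to fix a reading.

## Input model

Every function consumes descriptive summaries: allele/haplotype
frequency vectors, the scalar per-locus summaries (n, S, k, L, η, η_s,
η_e), unfolded or folded site frequency spectra, per-sequence singleton
profiles, mismatch distributions, binary haplotype-by-site matrices and
per-population frequency/genotype/allele-size tables. Frequencies are
validated on ingest: vectors summing to 1 within 1e-6 are silently
renormalized (this absorbs rounding in hand-typed inputs), anything
further off is rejected as a likely truncated file. Integer count
vectors are accepted wherever a frequency vector is, and normalized.

Undefined statistics — Tajima's D at S = 0, Fu–Li tests at η = 0,
G_ST when every population is fixed for the same allele — return
`NA_real_` rather than throwing, so batch runs keep going; the CLI
renders these as `NA` with exit status 0.

## Genetic diversity

H, Hd, π, k and PIC follow the textbook plug-in definitions. The
package exposes both the plug-in and the n/(n−1)-corrected H behind an
explicit `unbiased` flag and defaults to the plug-in form, because the
natural inputs are bare frequency vectors whose sample size may be
unknown; Hd always applies the correction, as its standard definition
does. `mean_pairwise_differences()` accepts either an SFS or a
pairwise-difference matrix; the two routes are algebraically equivalent
and are tested against each other by brute-force pair counting on random
haplotype matrices (the identity π·L = k holds exactly by
construction). Folded spectra give the same k as their unfolded source
because i(n−i) is invariant under i → n−i.

## Neutrality tests

**Constants.** All tests share the harmonic sums a₁ = Σ 1/i and
a₂ = Σ 1/i² (`harmonic_constants()`). IEEE double precision carries
these with relative error around 1e-15, which is far below the 1e-6
agreement the worked examples are certified to; expected values in the
test-suite were frozen from a separate exact-rational-arithmetic script
written before the implementation.

**Tajima's D, Fu and Li's tests.** D uses the standard e₁/e₂
normalization. The Fu–Li family uses the corrected u/v variance
coefficients (the Simonsen–Churchill–Aquadro forms, which are what the
widely used programs compute; the originally printed versions contain
typos). D is (η − a_n η_e)/sd on the total mutation count η, not S,
so recurrent-mutation inputs with η > S are handled as stated. The
starred tests need n ≥ 3 (their d_n auxiliary divides by n − 2). A
vanishing numerator returns exactly 0, including at n = 2 where the
variance term itself degenerates to 0.

**Fay–Wu/Zeng.** θ_π, θ_H and θ_L come straight from the unfolded SFS;
H = θ_π − θ_H = 2(θ_π − θ_L) is returned unnormalized, and H_n
normalizes (θ_π − θ_L) by its variance, as the normalized statistic is
usually tabulated. The variance expressions need a value for θ and θ²:
the package plugs in θ_W = S/a₁ and the unbiased
θ²-estimate S(S−1)/(a₁² + a₂). Folded spectra are rejected for this
family — polarization is essential.

**Ewens-sampling haplotype tests.** The distribution of the number of
distinct haplotypes K given θ is computed from unsigned Stirling numbers
of the first kind via the integer recurrence, carried in log space so
that any practical n is safe. Strobeck's S is the lower tail
P(K ≤ K_obs); Fs is the logit of the upper tail S′ = P(K ≥ K_obs).
Tails that span the whole support are set to 1 exactly rather than
summed, so the complementarity invariant holds to floating-point
accuracy and the degenerate logits surface as the ±Inf overflow
sentinel. θ is always an explicit argument (conventionally the observed
k); it is never estimated internally. Two historical labels needed a
reading: "Fu's W" is exposed as the upper-tail probability S′ itself
(the quantity whose logit is Fs), and "Watterson's W" as the
homozygosity statistic Σx_i² of the Ewens–Watterson test (the statistic,
not its tail probability).

**Ramos-Onsins singleton family.** With U_i the singletons carried by
sequence i and expectation k/2 per sequence, R₂ = √(mean((U_i − k/2)²))/S
and R₃/R₄ use the matching third/fourth root-moments; the E-variants
substitute outgroup-polarized external singletons. The labels Ch, Che
and ku are under-specified in the secondary literature; this package
defines them on the same centered profile — Ch = mean((U_i − k/2)²)/(k/2)
(a chi-square-style dispersion, NA at k = 0), Che its external-singleton
version, and ku = m₄/m₂² (the kurtosis ratio, NA when m₂ = 0) — and
documents that reading here rather than leaving the names dangling.

**Raggedness.** rg sums squared differences of successive mismatch
class frequencies with a single zero class padded *after* the last
observed class and no leading boundary term:
rg = Σ_{i=1}^{d+1} (x_i − x_{i−1})², x_{d+1} = 0. The literature is
inconsistent about the boundary; this convention makes the uniform
5-class distribution give 0.04 and a point mass give 1.

**Kelly's Z.** r² is the phased-haplotype D²/(p_A q_A p_B q_B)
(equivalently the squared Pearson correlation of the two binary
columns); ZnS averages over all pairs, ZA over physically adjacent
pairs after sorting columns by their coordinates. Unphased/composite LD
is out of scope.

## Population structure

Nei's decomposition uses **unweighted** population means by default
(equal weight per population), with sample-size weighting behind a
flag: the statistics are defined on frequency vectors, and unequal
weighting is a choice the user should make explicitly. All estimators
are plug-in; Nei's within-population n/(n−1) correction is available
behind `unbiased` when sample sizes are supplied. Jost's D is the
plug-in version, not the Chao estimator. G′_ST and Jost's D accept
either a population table or precomputed (G_ST, H_S, H_T, r), matching
calculator-style use.

R_ST is the allele-size variance ratio (S̄ − S_W)/S̄ with **sample**
variances (denominator n − 1), S_W the unweighted mean within-population
variance and S̄ the pooled-sample variance; a single-observation
population contributes 0 within-variance. Two consequences are worth
stating: two populations fixed at different sizes give exactly 1, and
*identical* populations give a small negative value of order −(r−1)/(r(n−1))
rather than exactly 0, because the pooled n−1 variance of duplicated
samples is slightly below the within variance. The tests assert that
exact behaviour instead of hiding it.

The Weir–Cockerham estimators compute the per-allele components a, b, c
from n̄, n_c, p̄, s² and h̄ exactly as defined for diploid genotype
counts, then combine them three ways: **W** sums components over alleles
and loci before the ratios θ = a/(a+b+c) and f = 1 − c/(b+c); **U**
averages per-allele ratios unweighted; **RH** averages per-allele ratios
with weights p̄_u(1 − p̄_u), this package's reconstruction of the
Robertson–Hill-style weighting (the exact historical weighting is not
pinned down; for biallelic loci all three coincide, which the tests
exploit). Negative estimates are reported as computed — they are part
of the estimator's sampling distribution — with truncation to [0, 1]
behind a flag.

## The synthetic-data generators

`simulate_coalescent()` is a standard Kingman coalescent for a
panmictic, constant-size, non-recombining locus: exponential
coalescence times with rate j(j−1)/2, Poisson mutations at rate θ/2 per
branch per unit time, infinite-sites labeling (so η = S in every
replicate). Each replicate carries a mutually consistent SFS, haplotype
matrix, haplotype multiplicities and realized k, which gives the tests
an internal consistency oracle for free. `simulate_population_freqs()`
draws an ancestral frequency vector from Dirichlet(1), per-population
vectors from a Dirichlet centered on it with a chosen concentration,
and multinomial samples — large concentrations emulate panmixia, small
ones near-fixation.

What the generators deliberately do **not** emulate: recombination,
migration, demography, selection, recurrent mutation, sequencing error
and ascertainment bias. Green calibration tests therefore certify the
arithmetic and the neutral-equilibrium behaviour of the estimators, not
their performance on demographically complex real data.

## Problem sizes and tolerances

The calibration suite uses n = 20, θ = 5 with 2000 replicates under a
fixed seed — enough that the Monte-Carlo standard errors of mean θ_W and
mean k are about 1 % of θ, comfortably inside the 5 % bands asserted,
and that mean Tajima's D and mean unnormalized Fay–Wu H (both 0 in
expectation, with the well-known slight negative bias of D at finite
sample size) resolve within ±0.2 and ±0.15. Brute-force oracle
equivalence (k from SFS vs. pair counting; ZnS vs. 2×2-table r²) runs
over 200 random matrices with n ≤ 12, S ≤ 20. Worked examples are
checked to 1e-6 against pre-computed exact-rational values; the Ewens
pmf must hold unit mass within 1e-9 up to n = 50.

## Known limitations

* No significance testing: the package computes statistics, not
  p-values (coalescent p-values for Fs/R₂ and permutation tests for
  differentiation are explicitly out of scope).
* No recombination-aware variance corrections for the SFS tests.
* The Ch/Che/ku and Robertson–Hill readings above are this package's
  documented conventions; compare with care against tools that chose
  differently.
* Exact arithmetic is not used internally; IEEE doubles bound the error
  well below every stated tolerance, but bit-identical agreement with
  rational-arithmetic references is not guaranteed.
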