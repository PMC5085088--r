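# popgenstats

`popgenstats` computes 45 classical statistics of molecular population
genetics directly from *descriptive summary metadata* — allele and
haplotype frequencies, segregating-site and mutation-class counts, site
frequency spectra (SFS), mismatch distributions, per-population genotype
counts and microsatellite allele sizes — rather than from raw sequence
alignments or genotype files. It is aimed at two audiences: teachers and
researchers who want a calculator-style tool for individual statistics
(each statistic is one independent function and one CLI subcommand), and
bioinformaticians who want the bare calculation step as a library they
can embed in a larger pipeline. Summaries are expected to be prepared
upstream with the usual alignment/genotyping tools.

## The statistic catalogue

Three classes, 45 statistics (`statistic_catalogue()` lists them all):

* **Genetic diversity** — heterozygosity *H* = 1 − Σp<sub>i</sub>²
  (optionally Nei's n/(n−1) correction), haplotype diversity *Hd*,
  nucleotide diversity π = k/L, mean pairwise differences
  *k* = Σ 2i(n−i)S<sub>i</sub>/(n(n−1)), and the polymorphism
  information content PIC = 1 − Σp<sub>i</sub>² − Σ<sub>i&lt;j</sub>
  2p<sub>i</sub>²p<sub>j</sub>².
* **Neutrality tests** — Tajima's *D* = (k − S/a₁)/√(e₁S + e₂S(S−1));
  Fu and Li's *D*, *F*, *D\**, *F\** from the mutation classes η, η_s,
  η_e; the Ewens-sampling haplotype tests (Strobeck's *S*, Fu's *W* and
  *F*<sub>s</sub>, the Ewens–Watterson homozygosity Σx<sub>i</sub>²);
  Fay and Wu's *H* = θ<sub>π</sub> − θ<sub>H</sub>, its normalized form
  *H*<sub>n</sub> and Zeng's *E*; the Ramos-Onsins singleton family
  (*R₂*, *R₃*, *R₄*, their outgroup E-variants, *Ch*, *Che*, *ku*); the
  mismatch raggedness *rg*; and Kelly's LD statistics *Z*<sub>nS</sub>
  (mean r² over all site pairs) and *Z*<sub>A</sub> (adjacent pairs).
* **Population structure** — Wright's F<sub>ST</sub> (equal and
  sample-size weighted) and F<sub>IS</sub>; Nei's decomposition J_S,
  J_T, H_S, H_T, D_ST, G_ST; Hedrick's standardized G′_ST; Jost's D;
  the allele-size R_ST for stepwise-mutating microsatellites; and the
  Weir–Cockerham variance-component estimators θ and f under the W
  (ratio of summed components), U (unweighted mean of per-allele
  ratios) and RH (Robertson–Hill weighted) combinations.

A small neutral Kingman coalescent (infinite sites) and a
Dirichlet-multinomial frequency sampler (`simulate_coalescent()`,
`simulate_population_freqs()`) generate synthetic inputs with known
expectations for calibration and testing.

## Worked example

```r
library(popgenstats)

tajima_d(n = 4, S = 3, k = 2)
#> [1] 2.01187

fay_wu_zeng(sfs(c(2, 1, 0), n = 4))$H     # theta_pi - theta_H
#> [1] 0.6666667

d <- nei_decomposition(rbind(c(0.7, 0.3), c(0.3, 0.7)))
d$G_ST
#> [1] 0.16
hedrick_gst_prime(d$G_ST, d$H_S, r = 2)
#> [1] 0.3917241
jost_d(d$H_T, d$H_S, r = 2)
#> [1] 0.2758621
```

The Tajima value says the two-estimator contrast (k above S/a₁) sits
about two standard deviations from the neutral expectation of 0; the
positive Fay–Wu H reflects an excess of low-frequency derived sites in
that toy spectrum; and the two-population table shows 16 % of its gene
diversity between populations (G_ST), which standardizes to 0.39 when
rescaled by its maximum (G′_ST) and to a true allelic differentiation of
0.28 (Jost's D).

Same calculations from a shell:

```sh
./exec/popgenstats tajima-d --n 4 --s 3 --k 2
./exec/popgenstats list                  # all 45 ids in their 3 classes
./exec/popgenstats pic --freqs 0.5,0.5 --json
./exec/popgenstats nei-gst --input popfreq.tsv
```

Scalar inputs come from flags, structured inputs from small TSV files
(`--input FILE --schema {freq,sfs,mismatch,hapmatrix,popfreq,genotype,allelesize}`);
undefined statistics (e.g. Tajima's D at S = 0) print `NA` and exit 0.

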