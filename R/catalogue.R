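# The closed catalogue of the 45 statistics, in three classes.

.CLASS_LABELS <- c(genetic_diversity = "Genetic diversity",
                   neutrality_test = "Neutrality test",
                   population_structure = "Population structure")

#' Catalogue of the 45 implemented statistics
#'
#' One row per statistic: its CLI identifier (`id`), its class
#' (`genetic_diversity`, `neutrality_test` or `population_structure`) and
#' a human-readable label.  Every identifier is a CLI subcommand.
#'
#' @return data.frame with columns `id`, `class`, `label` (45 rows).
#' @examples
#' table(statistic_catalogue()$class)
#' @export
statistic_catalogue <- function() {
  row <- function(id, class, label) data.frame(id = id, class = class,
                                               label = label)
  div <- rbind(
    row("heterozygosity", "genetic_diversity", "Heterozygosity H"),
    row("haplotype-diversity", "genetic_diversity", "Haplotype diversity Hd"),
    row("nucleotide-diversity", "genetic_diversity", "Nucleotide diversity pi"),
    row("avg-nucleotide-differences", "genetic_diversity",
        "Average nucleotide differences k"),
    row("pic", "genetic_diversity", "Polymorphism information content PIC"))
  neu <- rbind(
    row("tajima-d", "neutrality_test", "Tajima's D"),
    row("fu-li-d", "neutrality_test", "Fu and Li's D"),
    row("fu-li-f", "neutrality_test", "Fu and Li's F"),
    row("fu-li-d-star", "neutrality_test", "Fu and Li's D*"),
    row("fu-li-f-star", "neutrality_test", "Fu and Li's F*"),
    row("strobeck-s", "neutrality_test", "Strobeck's S"),
    row("fu-w", "neutrality_test", "Fu's W"),
    row("fu-fs", "neutrality_test", "Fu's Fs"),
    row("watterson-w", "neutrality_test", "Watterson's W (homozygosity)"),
    row("fay-wu-h", "neutrality_test", "Fay and Wu's H"),
    row("fay-wu-hn", "neutrality_test", "Fay and Wu's normalized Hn"),
    row("zeng-e", "neutrality_test", "Zeng's E"),
    row("ramos-r2", "neutrality_test", "Ramos-Onsins R2"),
    row("ramos-r3", "neutrality_test", "Ramos-Onsins R3"),
    row("ramos-r4", "neutrality_test", "Ramos-Onsins R4"),
    row("ramos-r2e", "neutrality_test", "Ramos-Onsins R2E"),
    row("ramos-r3e", "neutrality_test", "Ramos-Onsins R3E"),
    row("ramos-r4e", "neutrality_test", "Ramos-Onsins R4E"),
    row("ramos-ch", "neutrality_test", "Ramos-Onsins Ch"),
    row("ramos-che", "neutrality_test", "Ramos-Onsins Che"),
    row("ramos-ku", "neutrality_test", "Ramos-Onsins ku"),
    row("raggedness", "neutrality_test", "Raggedness index rg"),
    row("kelly-zns", "neutrality_test", "Kelly's ZnS"),
    row("kelly-za", "neutrality_test", "Kelly's ZA"))
  str <- rbind(
    row("wright-fst", "population_structure", "Wright's FST"),
    row("wright-fst-weighted", "population_structure",
        "Wright's FST (sample-size weighted)"),
    row("wright-fis", "population_structure", "Wright's FIS"),
    row("nei-gst", "population_structure", "Nei's GST"),
    row("nei-dst", "population_structure", "Nei's DST"),
    row("nei-jt", "population_structure", "Nei's JT"),
    row("nei-js", "population_structure", "Nei's JS"),
    row("rst", "population_structure", "Allele-size RST"),
    row("hedrick-gst-prime", "population_structure", "Hedrick's G'ST"),
    row("jost-d", "population_structure", "Jost's D"),
    row("wc-theta-w", "population_structure", "Weir-Cockerham theta (W)"),
    row("wc-theta-u", "population_structure", "Weir-Cockerham theta (U)"),
    row("wc-theta-rh", "population_structure", "Weir-Cockerham theta (RH)"),
    row("wc-f-w", "population_structure", "Weir-Cockerham f (W)"),
    row("wc-f-u", "population_structure", "Weir-Cockerham f (U)"),
    row("wc-f-rh", "population_structure", "Weir-Cockerham f (RH)"))
  out <- rbind(div, neu, str)
  rownames(out) <- NULL
  out
}
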