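#' Published microsatellite panel summary for Edith's checkerspot
#'
#' Per-locus summary statistics for the 10-locus microsatellite panel
#' developed from 454 transcriptome contigs of the butterfly *Euphydryas
#' editha* (Edith's checkerspot), genotyped in four multiplex PCR mixes on
#' 835 individuals from 72 populations. Columns mirror [locus_summaries()]
#' output: allele count, observed (`H_o`) and expected (`H_e`)
#' heterozygosity, percent missing calls, plus the repeat motif, product
#' size range and PCR mix (`group`). These printed values drive the
#' package's worked QC examples: the heterozygote-deficit/missingness rank
#' correlation ([deficit_vs_missingness()]) and the missingness-by-mix
#' ANOVA ([missingness_anova()]).
#'
#' @return A 10-row data frame with columns `locus`, `group` (PCR mix),
#'   `motif`, `size_range`, `allele_count`, `H_o`, `H_e`,
#'   `percent_missing`.
#' @examples
#' panel <- editha_panel()
#' deficit_vs_missingness(panel)
#' missingness_anova(panel)
#' @export
editha_panel <- function() {
  data.frame(
    locus = c("euphy2", "euphy3", "euphy21", "euphy69", "euphy14",
              "euphy61", "euphy35", "euphy50", "euphy37", "euphy47"),
    group = c("1", "1", "1", "1", "2", "2", "3", "3", "4", "4"),
    motif = c("CAG", "ATC", "CAA", "GTT", "TACA", "AC", "TG", "CA,A",
              "C,CA", "AT"),
    size_range = c("144-191", "121-171", "220-239", "72-103", "99-170",
                   "186-246", "267-335", "135-176", "130-182", "172-335"),
    allele_count = c(20L, 18L, 9L, 13L, 32L, 42L, 56L, 28L, 21L, 34L),
    H_o = c(0.42, 0.52, 0.18, 0.17, 0.15, 0.44, 0.33, 0.22, 0.41, 0.44),
    H_e = c(0.72, 0.83, 0.24, 0.39, 0.68, 0.87, 0.96, 0.85, 0.80, 0.87),
    percent_missing = c(0.60, 0.84, 1.32, 3.59, 14.0, 12.9, 13.1, 22.5,
                        2.28, 5.99),
    stringsAsFactors = FALSE)
}
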