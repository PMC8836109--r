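## Packaged worked-example fixtures.

#' Packaged six-variant family prioritization fixture
#'
#' The six exonic candidate variants of the worked example (genes ADAMTS10,
#' C2orf42, GNA13, PTK7, RSBN1L, TNIP1) with their published
#' classifications, allele frequencies, CADD and conservation scores, panel
#' calls realizing the published favorable percentages, and family
#' genotypes implied by the published carrier sets. Call quality and
#' coverage were not published per variant; the fixture carries values
#' that pass the QC stage by construction.
#'
#' @param ped Pedigree whose member identifiers head the genotype columns
#'   (default [crcFamilyPedigree()]).
#' @return A [VariantTable][VariantTable-class] with six rows.
#' @examples
#' tab <- table1Variants()
#' variantIds(tab)
#' @export
table1Variants <- function(ped = crcFamilyPedigree()) {
  readAnnotatedTable(
    system.file("extdata", "table1_variants.tsv",
                package = "VariantFunnel"),
    ped)
}
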