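## Funnel orchestration: fixed stage order, per-stage survivor accounting,
## ranked candidate report.

#' Ordered funnel stage identifiers
#'
#' The fixed stage order of the prioritization funnel: call QC, allele
#' frequency, pedigree segregation, coding region, non-synonymous
#' classification, CADD, conservation, intolerance, deleteriousness.
#' Filters are pure per-variant predicates, so the order affects only the
#' per-stage survivor counts, never the final set.
#'
#' @return Character vector of stage names.
#' @export
stageSequence <- function() .STAGES

#' Run the variant prioritization funnel
#'
#' Applies the nine funnel stages in [stageSequence()] order: the
#' survivors of each stage are exactly the inputs of the next. Returns the
#' per-stage report, the final candidates ranked by descending CADD (ties
#' broken by chromosome and position), and the full per-stage audit
#' decisions.
#'
#' @param x A [VariantTable][VariantTable-class].
#' @param ped A [Pedigree][Pedigree-class] with roles assigned.
#' @param config A [FilterConfig][FilterConfig-class].
#' @param policy A [SegregationPolicy][SegregationPolicy-class].
#' @return A list with elements `report` (a
#'   [FunnelReport][FunnelReport-class]), `candidates` (the final
#'   [VariantTable][VariantTable-class], ranked), and `decisions` (named
#'   list of [TierDecision][TierDecision-class] objects, evaluated on each
#'   stage's input).
#' @examples
#' res <- runFunnel(table1Variants(), crcFamilyPedigree())
#' stageCounts(res$report)
#' @export
runFunnel <- function(x, ped, config = filterConfig(),
                      policy = segregationPolicy()) {
  stopifnot(is(x, "VariantTable"), is(ped, "Pedigree"))
  stages <- data.frame(stage = "input", count = nVariants(x),
                       stringsAsFactors = FALSE)
  survivors <- list(input = variantIds(x))
  decisions <- list()
  alive <- x
  for (stage in .STAGES) {
    dec <- switch(stage,
      qc = qcFilter(alive, config),
      frequency = frequencyFilter(alive, config),
      segregation = .segregationDecision(alive, ped, policy),
      coding = codingFilter(alive),
      nonsynonymous = nonsynonymousFilter(alive),
      cadd = caddFilter(alive, config),
      conservation = conservationFilter(alive, config),
      intolerance = intoleranceFilter(alive, config),
      deleteriousness = deleteriousnessFilter(alive, config)
    )
    decisions[[stage]] <- dec
    alive <- alive[which(passed(dec))]
    stages <- rbind(stages, data.frame(stage = stage,
                                       count = nVariants(alive)))
    survivors[[stage]] <- variantIds(alive)
  }
  ord <- .rankCandidates(alive)
  alive <- alive[ord]
  survivors[["deleteriousness"]] <- variantIds(alive)
  report <- new("FunnelReport", stages = stages, survivors = survivors,
                config = config)
  list(report = report, candidates = alive, decisions = decisions)
}

.segregationDecision <- function(x, ped, policy) {
  g <- genotypeMatrix(x)
  carries <- if (nVariants(x) == 0L) character(0) else
    apply(g, 1L, function(row)
      paste(colnames(g)[row %in% policy@carrier_genotypes],
            collapse = ","))
  new("TierDecision", stage = "segregation",
      passed = segregates(x, ped, policy),
      detail = data.frame(carriers = as.character(carries),
                          stringsAsFactors = FALSE))
}

## CADD descending, then chromosome (natural order), then position.
.rankCandidates <- function(x) {
  v <- variantData(x)
  if (nrow(v) == 0L) return(integer(0))
  chrnum <- suppressWarnings(as.numeric(
    c(X = 23, Y = 24, MT = 25, M = 25)[toupper(v$chrom)]))
  chrnum[is.na(chrnum)] <- suppressWarnings(as.numeric(
    v$chrom[is.na(chrnum)]))
  chrnum[is.na(chrnum)] <- 26
  order(-ifelse(is.na(v$cadd_phred), -Inf, v$cadd_phred), chrnum, v$pos)
}

#' Ranked candidate report
#'
#' One row per final candidate, mirroring the structure of a published
#' prioritization table: gene, variant identifier, classification, the
#' carrier set observed in the family, allele frequencies, CADD, the three
#' conservation scores, and the favorable percentages of the
#' deleteriousness and intolerance panels (with their numerators and
#' denominators). Passthrough annotation columns (e.g. externally supplied
#' driver predictions) are appended uninterpreted. Rows are ranked by
#' descending CADD, ties broken by chromosome and position.
#'
#' @param candidates The final [VariantTable][VariantTable-class] from
#'   [runFunnel()].
#' @param config The [FilterConfig][FilterConfig-class] used (its
#'   favorability thresholds feed the percentage columns).
#' @param policy The [SegregationPolicy][SegregationPolicy-class] defining
#'   which genotypes count as carrying.
#' @return A `data.frame`, one row per candidate.
#' @examples
#' res <- runFunnel(table1Variants(), crcFamilyPedigree())
#' candidateReport(res$candidates)[, c("gene", "cadd_phred")]
#' @export
candidateReport <- function(candidates, config = filterConfig(),
                            policy = segregationPolicy()) {
  stopifnot(is(candidates, "VariantTable"))
  candidates <- candidates[.rankCandidates(candidates)]
  v <- variantData(candidates)
  g <- genotypeMatrix(candidates)
  carriers <- if (nrow(v) == 0L) character(0) else
    apply(g, 1L, function(row)
      paste(colnames(g)[row %in% policy@carrier_genotypes],
            collapse = ", "))
  del <- decisionDetail(deleteriousnessFilter(candidates, config))
  intol <- decisionDetail(intoleranceFilter(candidates, config))
  out <- data.frame(
    gene = v$gene,
    variant = variantIds(candidates),
    exonic_classification = v$exonic_classification,
    pedigree_segregation = as.character(carriers),
    maf_exac_nontcga = v$maf_exac_nontcga,
    maf_gnomad_nfe = v$maf_gnomad_nfe,
    cadd_phred = v$cadd_phred,
    gerp = v$gerp,
    phylop = v$phylop,
    phastcons = v$phastcons,
    deleteriousness_pct = round(100 * del$fraction, 2),
    deleteriousness_panel = sprintf("%d/%d", del$numerator,
                                    del$denominator),
    intolerance_pct = round(100 * intol$fraction, 2),
    intolerance_panel = sprintf("%d/%d", intol$numerator,
                                intol$denominator),
    stringsAsFactors = FALSE
  )
  if (ncol(candidates@passthrough))
    out <- cbind(out, candidates@passthrough)
  out
}

#' Write a candidate report as TSV
#'
#' @param report The `data.frame` from [candidateReport()].
#' @param path Output path.
#' @export
writeCandidateReport <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}
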