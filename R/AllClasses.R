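#' @import methods
NULL

## Canonical vocabularies shared across the package ---------------------------

.SEXES <- c("male", "female", "unknown")
.PHENOTYPES <- c("crc_case", "polyp", "unaffected")
.ROLES <- c("obligate_carrier", "optional_carrier", "uninformative")
.GENOTYPES <- c("hom_ref", "het", "hom_alt", "missing")

.EXONIC_CLASSES <- c(
  "nonsynonymous_snv", "synonymous_snv", "frameshift_deletion",
  "frameshift_insertion", "nonframeshift", "stopgain", "stoploss",
  "unknown", "noncoding"
)
.REGION_CLASSES <- c("exonic", "splicing", "intronic", "intergenic",
                     "utr", "other")

## The 12-member dbNSFP-style deleteriousness panel (10 individual predictors
## plus 2 meta-predictors; the reliability index of the meta-predictors is the
## 12th panel member).
.PREDICTORS <- c(
  "SIFT", "Polyphen2_HumDiv", "Polyphen2_HumVar", "LRT", "MutationTaster",
  "MutationAssessor", "FATHMM", "MetaSVM", "MetaLR", "VEST3", "PROVEAN",
  "ReliabilityIndex"
)

## Names of the five gene-intolerance panel members.
.INTOLERANCE_PANEL <- c("intolerance_inhouse", "intolerance_esp",
                        "intolerance_exac", "z_score", "pli")

.STAGES <- c("qc", "frequency", "segregation", "coding", "nonsynonymous",
             "cadd", "conservation", "intolerance", "deleteriousness")

## Pedigree --------------------------------------------------------------------

#' Pedigree of a sequenced family
#'
#' Holds one row per family member: identifier, parent identifiers (`NA` for
#' founders or unsequenced parents), sex, phenotype (`crc_case`, `polyp`,
#' `unaffected`), age at diagnosis or recruitment, and the carrier-expectation
#' role used by the segregation filter (`obligate_carrier`,
#' `optional_carrier`, `uninformative`).
#'
#' @slot members A `data.frame` with columns `member_id`, `father_id`,
#'   `mother_id`, `sex`, `phenotype`, `age_at_event`, `role`.
#'
#' @seealso [readPedigree()], [assignRoles()], [crcFamilyPedigree()]
#' @export
setClass("Pedigree", representation(members = "data.frame"))

setValidity("Pedigree", function(object) {
  m <- object@members
  need <- c("member_id", "father_id", "mother_id", "sex", "phenotype",
            "age_at_event", "role")
  if (!all(need %in% names(m)))
    return(paste("missing member columns:",
                 paste(setdiff(need, names(m)), collapse = ", ")))
  if (anyDuplicated(m$member_id))
    return(paste("duplicate member id:",
                 m$member_id[duplicated(m$member_id)][1L]))
  for (col in c("father_id", "mother_id")) {
    ref <- m[[col]]
    bad <- !is.na(ref) & !(ref %in% m$member_id)
    if (any(bad))
      return(sprintf("unresolved %s '%s' for member '%s'",
                     sub("_id", "", col), ref[bad][1L],
                     m$member_id[bad][1L]))
  }
  if (!all(m$sex %in% .SEXES)) return("invalid sex value")
  if (!all(m$phenotype %in% .PHENOTYPES)) return("invalid phenotype value")
  if (!all(m$role %in% .ROLES)) return("invalid role value")
  TRUE
})

## VariantTable ----------------------------------------------------------------

#' Annotated variant table
#'
#' One row per variant with position and alleles, functional classification,
#' call quality, population and local allele frequencies, the per-variant and
#' per-gene score panels consumed by the tier filters, and one genotype call
#' per sequenced family member. Extra input columns that the pipeline does not
#' interpret are preserved in `passthrough`.
#'
#' @slot variants A typed `data.frame`; see [annotationManifest()] for the
#'   canonical column set.
#' @slot genotypes A character matrix (variants x members) with values
#'   `hom_ref`, `het`, `hom_alt`, `missing`.
#' @slot passthrough A `data.frame` of uninterpreted input columns.
#' @slot manifest Character vector of source column names, in input order.
#' @slot source Path the table was read from (`NA` if built in memory).
#'
#' @seealso [readAnnotatedTable()], [writeAnnotatedTable()], [runFunnel()]
#' @export
setClass("VariantTable", representation(
  variants = "data.frame",
  genotypes = "matrix",
  passthrough = "data.frame",
  manifest = "character",
  source = "character"
))

setValidity("VariantTable", function(object) {
  v <- object@variants
  g <- object@genotypes
  if (nrow(v) != nrow(g))
    return("variants and genotypes disagree on row count")
  if (nrow(v) == 0L) return(TRUE)
  if (any(v$pos < 1L)) return("pos must be >= 1")
  if (any(v$ref == v$alt)) return("ref and alt alleles must differ")
  for (col in c("maf_1kg", "maf_exac_nontcga", "maf_gnomad_nfe",
                "local_cohort_freq", "phastcons")) {
    x <- v[[col]]
    if (any(!is.na(x) & (x < 0 | x > 1)))
      return(sprintf("%s must lie in [0, 1]", col))
  }
  if (any(!is.na(v$cadd_phred) & v$cadd_phred < 0))
    return("cadd_phred must be >= 0")
  if (!all(g %in% .GENOTYPES))
    return("invalid genotype state")
  TRUE
})

## FilterConfig ----------------------------------------------------------------

#' Funnel threshold configuration
#'
#' All thresholds and policies of the prioritization funnel. Boundary
#' inclusivity mirrors how each rule is stated: call quality and coverage are
#' strict (`> 20`, `> 5`), CADD, GERP and PhyloP are inclusive, PhastCons is
#' strict, the two panel fractions are inclusive.
#'
#' @slot qual_min Variant call quality, strict lower bound (default 20).
#' @slot depth_min Read coverage, strict lower bound (default 5).
#' @slot maf_max Population minor allele frequency cap, inclusive
#'   (default 0.001, i.e. 0.1%).
#' @slot local_freq_max Local cohort frequency cap, strict (default 0.05).
#' @slot cadd_min PHRED-scaled CADD minimum, inclusive (default 10).
#' @slot gerp_min GERP++ minimum, inclusive (default 2.0).
#' @slot phastcons_min PhastCons minimum, strict (default 0.3).
#' @slot phylop_min PhyloP minimum, inclusive (default 3.0).
#' @slot conservation_required How many of the 3 conservation scores must be
#'   satisfied (default 2).
#' @slot intolerance_fraction Minimum favorable fraction of the intolerance
#'   panel, inclusive (default 0.60).
#' @slot deleteriousness_fraction Minimum favorable fraction of the
#'   deleteriousness panel, inclusive (default 0.60).
#' @slot vest3_min VEST3 favorability threshold, inclusive (default 0.5).
#' @slot reliability_index_min Reliability-index favorability threshold,
#'   inclusive (default 5).
#' @slot missing_frequency_policy `treat_as_rare` (missing frequencies pass)
#'   or `drop`.
#' @slot missing_score_policy `exclude_from_denominator` (panel fractions over
#'   non-missing members) or `count_unfavorable` (fixed denominator).
#'
#' @seealso [filterConfig()], [readFilterConfig()], [writeFilterConfig()]
#' @export
setClass("FilterConfig", representation(
  qual_min = "numeric",
  depth_min = "numeric",
  maf_max = "numeric",
  local_freq_max = "numeric",
  cadd_min = "numeric",
  gerp_min = "numeric",
  phastcons_min = "numeric",
  phylop_min = "numeric",
  conservation_required = "integer",
  intolerance_fraction = "numeric",
  deleteriousness_fraction = "numeric",
  vest3_min = "numeric",
  reliability_index_min = "numeric",
  missing_frequency_policy = "character",
  missing_score_policy = "character"
))

setValidity("FilterConfig", function(object) {
  for (fr in c("intolerance_fraction", "deleteriousness_fraction")) {
    x <- slot(object, fr)
    if (x < 0 || x > 1) return(sprintf("%s must lie in [0, 1]", fr))
  }
  if (!(object@conservation_required %in% 0:3))
    return("conservation_required must be in 0..3")
  if (!(object@missing_frequency_policy %in% c("treat_as_rare", "drop")))
    return("missing_frequency_policy must be 'treat_as_rare' or 'drop'")
  if (!(object@missing_score_policy %in%
        c("exclude_from_denominator", "count_unfavorable")))
    return(paste("missing_score_policy must be 'exclude_from_denominator'",
                 "or 'count_unfavorable'"))
  TRUE
})

## FavorabilityMap -------------------------------------------------------------

#' Favorability rules for the deleteriousness predictor panel
#'
#' Maps each of the 12 panel predictors to the set of categorical calls, or
#' the numeric threshold, that counts as favorable (i.e. supporting a
#' deleterious interpretation).
#'
#' @slot rules Named list, one entry per predictor. Categorical entries are
#'   `list(type = "categorical", favorable = <character>)`; numeric entries
#'   are `list(type = "numeric", threshold = <number>)` with an inclusive
#'   `>=` test.
#'
#' @seealso [defaultFavorabilityMap()], [favorability()]
#' @export
setClass("FavorabilityMap", representation(rules = "list"))

setValidity("FavorabilityMap", function(object) {
  if (!all(names(object@rules) %in% .PREDICTORS))
    return("rules contain an unknown predictor name")
  for (rule in object@rules) {
    if (!rule$type %in% c("categorical", "numeric"))
      return("rule type must be 'categorical' or 'numeric'")
  }
  TRUE
})

## SegregationPolicy -----------------------------------------------------------

#' Pedigree segregation policy
#'
#' How phenotypes map to carrier-expectation roles, which genotype states
#' count as carrying, and how a missing genotype on an obligate carrier is
#' handled.
#'
#' @slot role_of_phenotype Named character: phenotype -> role.
#' @slot carrier_genotypes Genotype states counted as carrying
#'   (default `het` and `hom_alt`).
#' @slot missing_genotype_policy `fail_if_obligate_missing` (default) or
#'   `permissive`.
#'
#' @seealso [segregationPolicy()], [segregates()]
#' @export
setClass("SegregationPolicy", representation(
  role_of_phenotype = "character",
  carrier_genotypes = "character",
  missing_genotype_policy = "character"
))

setValidity("SegregationPolicy", function(object) {
  if (!all(.PHENOTYPES %in% names(object@role_of_phenotype)))
    return("every phenotype must be assigned a role")
  if (!all(object@role_of_phenotype %in% .ROLES))
    return("invalid role in role_of_phenotype")
  if (!all(object@carrier_genotypes %in% .GENOTYPES))
    return("invalid genotype state in carrier_genotypes")
  if (!(object@missing_genotype_policy %in%
        c("fail_if_obligate_missing", "permissive")))
    return("invalid missing_genotype_policy")
  TRUE
})

## TierDecision ----------------------------------------------------------------

#' Outcome of one filter stage
#'
#' A vectorized audit record for one tier filter applied to a variant table:
#' the stage name, a pass/fail flag per variant, and the evaluated quantities
#' (scores tested, favorable and available panel counts) behind each flag.
#'
#' @slot stage Stage identifier.
#' @slot passed Named logical vector, one element per variant.
#' @slot detail `data.frame` of evaluated quantities, rows aligned with
#'   `passed`; fraction-based stages record numerator and denominator.
#'
#' @export
setClass("TierDecision", representation(
  stage = "character",
  passed = "logical",
  detail = "data.frame"
))

setValidity("TierDecision", function(object) {
  if (nrow(object@detail) != length(object@passed))
    return("detail rows must align with passed")
  TRUE
})

## FunnelReport ----------------------------------------------------------------

#' Per-stage funnel survivor report
#'
#' Ordered stage counts, the variant identifiers surviving each stage
#' boundary, and a snapshot of the configuration used.
#'
#' @slot stages `data.frame` with columns `stage` and `count`; the first row
#'   is the input count, counts are non-increasing.
#' @slot survivors Named list of character vectors: variant identifiers
#'   alive after each stage.
#' @slot config The [FilterConfig][FilterConfig-class] the run used.
#'
#' @seealso [runFunnel()], [writeFunnelReport()]
#' @export
setClass("FunnelReport", representation(
  stages = "data.frame",
  survivors = "list",
  config = "FilterConfig"
))

setValidity("FunnelReport", function(object) {
  s <- object@stages
  if (!all(c("stage", "count") %in% names(s)))
    return("stages must have 'stage' and 'count' columns")
  if (is.unsorted(rev(s$count)))
    return("stage counts must be non-increasing")
  last <- s$stage[nrow(s)]
  if (!is.null(object@survivors[[last]]) &&
      length(object@survivors[[last]]) != s$count[nrow(s)])
    return("final survivor list length must equal final count")
  TRUE
})

## CarrierCounts ---------------------------------------------------------------

#' Carrier counts from a case-control genotyping screen
#'
#' @slot case_carriers,case_total Carriers and genotyped total among cases.
#' @slot control_carriers,control_total Same for controls.
#' @slot case_missing,control_missing Calls excluded because the genotype
#'   was missing.
#'
#' @seealso [tallyGenotyping()], [carrierExactTest()]
#' @export
setClass("CarrierCounts", representation(
  case_carriers = "integer",
  case_total = "integer",
  control_carriers = "integer",
  control_total = "integer",
  case_missing = "integer",
  control_missing = "integer"
))

setValidity("CarrierCounts", function(object) {
  if (object@case_carriers < 0L || object@case_carriers > object@case_total)
    return("case carriers must lie in [0, case_total]")
  if (object@control_carriers < 0L ||
      object@control_carriers > object@control_total)
    return("control carriers must lie in [0, control_total]")
  TRUE
})

## Simulation ------------------------------------------------------------------

#' Parameters of the synthetic family-variant generator
#'
#' @slot seed Integer seed; a fixed seed yields byte-identical output.
#' @slot n_background Number of background (non-planted) variants.
#' @slot pedigree Pedigree template the genotypes are dropped through.
#' @slot freq_range Two numbers: founder alternate-allele frequencies are
#'   drawn log-uniformly from this range.
#' @slot score_regimes Named list with elements `benign` and `deleterious`,
#'   each a list of distribution parameters for the annotation scores.
#' @slot fraction_deleterious_background Probability a background variant
#'   draws its scores from the deleterious-like regime.
#' @slot planted List of planted-variant specifications
#'   (see [plantedVariant()]).
#'
#' @seealso [simulationParams()], [generateDataset()]
#' @export
setClass("SimulationParams", representation(
  seed = "integer",
  n_background = "integer",
  pedigree = "Pedigree",
  freq_range = "numeric",
  score_regimes = "list",
  fraction_deleterious_background = "numeric",
  planted = "list"
))

setValidity("SimulationParams", function(object) {
  if (object@n_background < 0L) return("n_background must be >= 0")
  f <- object@fraction_deleterious_background
  if (f < 0 || f > 1)
    return("fraction_deleterious_background must lie in [0, 1]")
  if (length(object@freq_range) != 2L || any(object@freq_range <= 0) ||
      any(object@freq_range > 1))
    return("freq_range must be two frequencies in (0, 1]")
  if (!all(c("benign", "deleterious") %in% names(object@score_regimes)))
    return("score_regimes must name 'benign' and 'deleterious'")
  TRUE
})

#' Ground truth of a synthetic dataset
#'
#' @slot planted_ids Identifiers of the planted variants, present in the
#'   emitted table.
#' @slot params The [SimulationParams][SimulationParams-class] echo.
#'
#' @export
setClass("SyntheticTruth", representation(
  planted_ids = "character",
  params = "SimulationParams"
))
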