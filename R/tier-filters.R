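## Per-variant tier filters. Each filter is a pure predicate over the
## annotation columns; the public functions return a vectorized
## TierDecision whose detail table records every evaluated quantity.

.decision <- function(stage, pass, detail, ids) {
  new("TierDecision", stage = stage,
      passed = stats::setNames(pass, ids),
      detail = detail)
}

#' Tier filters of the prioritization funnel
#'
#' Each filter evaluates one funnel stage over all rows of a variant
#' table and returns a [TierDecision][TierDecision-class]:
#'
#' * `qcFilter()`: call quality strictly above `qual_min` and coverage
#'   strictly above `depth_min`.
#' * `frequencyFilter()`: every present population MAF at most `maf_max`
#'   and the local cohort frequency strictly below `local_freq_max`;
#'   missing frequency fields pass under `treat_as_rare` (a variant absent
#'   from reference populations is at least as rare as the cap) or fail
#'   under `drop`.
#' * `codingFilter()`: region class `exonic` or `splicing`.
#' * `nonsynonymousFilter()`: classification among non-synonymous SNV,
#'   frameshift insertion/deletion, stopgain, stoploss, or unknown
#'   (synonymous and non-frameshift changes are excluded as less likely
#'   deleterious).
#' * `caddFilter()`: PHRED-scaled CADD present and at least `cadd_min`.
#' * `conservationFilter()`: at least `conservation_required` of
#'   \{GERP++ >= `gerp_min`, PhastCons > `phastcons_min`,
#'   PhyloP >= `phylop_min`\}; a missing score counts as unsatisfied (the
#'   rule has a fixed 3-score denominator).
#' * `intoleranceFilter()`: favorable fraction of the 5-member gene
#'   intolerance panel (three frequency-based intolerance scores tested
#'   `< 0`, missense Z tested `> 0`, pLI tested `>= 0.9`) at least
#'   `intolerance_fraction`. Under the default missing-score policy the
#'   fraction is over non-missing members; an empty panel fails.
#' * `deleteriousnessFilter()`: favorable fraction of the 12-member
#'   predictor panel (via [favorability()]) at least
#'   `deleteriousness_fraction`; an empty panel fails.
#'
#' @param x A [VariantTable][VariantTable-class].
#' @param config A [FilterConfig][FilterConfig-class].
#' @param map A [FavorabilityMap][FavorabilityMap-class]; by default built
#'   from the config's `vest3_min` and `reliability_index_min`.
#' @return A [TierDecision][TierDecision-class] covering all rows of `x`.
#' @examples
#' tab <- table1Variants()
#' passed(caddFilter(tab))
#' decisionDetail(conservationFilter(tab))
#' @name tierFilters
NULL

#' @rdname tierFilters
#' @export
qcFilter <- function(x, config = filterConfig()) {
  v <- variantData(x)
  qual_ok <- !is.na(v$qual) & v$qual > config@qual_min
  depth_ok <- !is.na(v$depth) & v$depth > config@depth_min
  .decision("qc", qual_ok & depth_ok,
            data.frame(qual = v$qual, depth = v$depth,
                       qual_ok = qual_ok, depth_ok = depth_ok),
            variantIds(x))
}

#' @rdname tierFilters
#' @export
frequencyFilter <- function(x, config = filterConfig()) {
  v <- variantData(x)
  rare_ok <- function(f, cap, strict = FALSE) {
    present <- !is.na(f)
    ok <- rep(config@missing_frequency_policy == "treat_as_rare", length(f))
    ok[present] <- if (strict) f[present] < cap else f[present] <= cap
    ok
  }
  ok <- rare_ok(v$maf_1kg, config@maf_max) &
    rare_ok(v$maf_exac_nontcga, config@maf_max) &
    rare_ok(v$maf_gnomad_nfe, config@maf_max) &
    rare_ok(v$local_cohort_freq, config@local_freq_max, strict = TRUE)
  .decision("frequency", ok,
            data.frame(maf_1kg = v$maf_1kg,
                       maf_exac_nontcga = v$maf_exac_nontcga,
                       maf_gnomad_nfe = v$maf_gnomad_nfe,
                       local_cohort_freq = v$local_cohort_freq),
            variantIds(x))
}

#' @rdname tierFilters
#' @export
codingFilter <- function(x) {
  v <- variantData(x)
  ok <- v$region_class %in% c("exonic", "splicing")
  .decision("coding", ok, data.frame(region_class = v$region_class),
            variantIds(x))
}

.NONSYN_KEEP <- c("nonsynonymous_snv", "frameshift_deletion",
                  "frameshift_insertion", "stopgain", "stoploss", "unknown")

#' @rdname tierFilters
#' @export
nonsynonymousFilter <- function(x) {
  v <- variantData(x)
  ok <- v$exonic_classification %in% .NONSYN_KEEP
  .decision("nonsynonymous", ok,
            data.frame(exonic_classification = v$exonic_classification),
            variantIds(x))
}

#' @rdname tierFilters
#' @export
caddFilter <- function(x, config = filterConfig()) {
  v <- variantData(x)
  ok <- !is.na(v$cadd_phred) & v$cadd_phred >= config@cadd_min
  .decision("cadd", ok, data.frame(cadd_phred = v$cadd_phred),
            variantIds(x))
}

#' @rdname tierFilters
#' @export
conservationFilter <- function(x, config = filterConfig()) {
  v <- variantData(x)
  gerp_ok <- !is.na(v$gerp) & v$gerp >= config@gerp_min
  phastcons_ok <- !is.na(v$phastcons) & v$phastcons > config@phastcons_min
  phylop_ok <- !is.na(v$phylop) & v$phylop >= config@phylop_min
  satisfied <- gerp_ok + phastcons_ok + phylop_ok
  .decision("conservation", satisfied >= config@conservation_required,
            data.frame(gerp_ok = gerp_ok, phastcons_ok = phastcons_ok,
                       phylop_ok = phylop_ok,
                       numerator = satisfied,
                       denominator = rep(3L, length(satisfied))),
            variantIds(x))
}

#' @rdname tierFilters
#' @param type_specific When `TRUE`, the missense Z-score is scored only
#'   for missense variants and pLI only for loss-of-function variants
#'   (frameshift, stopgain, stoploss); the default pools every available
#'   panel member for every variant.
#' @export
intoleranceFilter <- function(x, config = filterConfig(),
                              type_specific = FALSE) {
  v <- variantData(x)
  ## the panel's tests follow the stated rules: intolerance scores are
  ## favorable strictly below 0, Z strictly above 0, pLI at or above 0.9
  tests <- list(
    intolerance_inhouse = v$intolerance_inhouse < 0,
    intolerance_esp = v$intolerance_esp < 0,
    intolerance_exac = v$intolerance_exac < 0,
    z_score = v$z_score > 0,
    pli = v$pli >= 0.9
  )
  if (type_specific) {
    lof <- v$exonic_classification %in%
      c("frameshift_deletion", "frameshift_insertion", "stopgain",
        "stoploss")
    missense <- v$exonic_classification == "nonsynonymous_snv"
    tests$z_score[lof] <- NA
    tests$pli[missense] <- NA
  }
  fav <- Reduce(`+`, lapply(tests, function(t) !is.na(t) & t))
  avail <- Reduce(`+`, lapply(tests, function(t) !is.na(t)))
  denom <- if (config@missing_score_policy == "count_unfavorable")
    rep(length(tests), length(fav)) else avail
  frac <- ifelse(denom > 0, fav / denom, 0)
  ok <- denom > 0 & frac >= config@intolerance_fraction
  .decision("intolerance", ok,
            data.frame(numerator = fav, denominator = denom,
                       available = avail, fraction = frac),
            variantIds(x))
}

#' @rdname tierFilters
#' @export
deleteriousnessFilter <- function(x, config = filterConfig(),
                                  map = defaultFavorabilityMap(
                                    config@vest3_min,
                                    config@reliability_index_min)) {
  v <- variantData(x)
  n <- nrow(v)
  fav <- integer(n)
  avail <- integer(n)
  for (p in .PREDICTORS) {
    cls <- .favorabilityVec(v[[p]], p, map)
    fav <- fav + (cls == "favorable")
    avail <- avail + (cls != "missing")
  }
  denom <- if (config@missing_score_policy == "count_unfavorable")
    rep(length(.PREDICTORS), n) else avail
  frac <- ifelse(denom > 0, fav / denom, 0)
  ok <- denom > 0 & frac >= config@deleteriousness_fraction
  .decision("deleteriousness", ok,
            data.frame(numerator = fav, denominator = denom,
                       available = avail, fraction = frac),
            variantIds(x))
}
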