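## Constructors, accessors and the favorability mapping.

#' Construct a funnel threshold configuration
#'
#' Returns a [FilterConfig][FilterConfig-class] populated with the default
#' funnel thresholds; any field can be overridden by name.
#'
#' @param qual_min,depth_min Call-quality and coverage strict lower bounds.
#' @param maf_max Population MAF cap (inclusive).
#' @param local_freq_max Local cohort frequency cap (strict).
#' @param cadd_min PHRED-scaled CADD minimum (inclusive).
#' @param gerp_min,phastcons_min,phylop_min Conservation thresholds
#'   (GERP and PhyloP inclusive, PhastCons strict).
#' @param conservation_required Conservation scores required out of 3.
#' @param intolerance_fraction,deleteriousness_fraction Minimum favorable
#'   panel fractions (inclusive).
#' @param vest3_min,reliability_index_min Favorability thresholds for the two
#'   numeric panel members (inclusive).
#' @param missing_frequency_policy `"treat_as_rare"` or `"drop"`.
#' @param missing_score_policy `"exclude_from_denominator"` or
#'   `"count_unfavorable"`.
#'
#' @return A `FilterConfig`.
#' @examples
#' cfg <- filterConfig(cadd_min = 15)
#' cfg
#' @export
filterConfig <- function(qual_min = 20, depth_min = 5, maf_max = 0.001,
                         local_freq_max = 0.05, cadd_min = 10,
                         gerp_min = 2.0, phastcons_min = 0.3,
                         phylop_min = 3.0, conservation_required = 2L,
                         intolerance_fraction = 0.60,
                         deleteriousness_fraction = 0.60,
                         vest3_min = 0.5, reliability_index_min = 5,
                         missing_frequency_policy = "treat_as_rare",
                         missing_score_policy = "exclude_from_denominator") {
  new("FilterConfig",
      qual_min = as.numeric(qual_min),
      depth_min = as.numeric(depth_min),
      maf_max = as.numeric(maf_max),
      local_freq_max = as.numeric(local_freq_max),
      cadd_min = as.numeric(cadd_min),
      gerp_min = as.numeric(gerp_min),
      phastcons_min = as.numeric(phastcons_min),
      phylop_min = as.numeric(phylop_min),
      conservation_required = as.integer(conservation_required),
      intolerance_fraction = as.numeric(intolerance_fraction),
      deleteriousness_fraction = as.numeric(deleteriousness_fraction),
      vest3_min = as.numeric(vest3_min),
      reliability_index_min = as.numeric(reliability_index_min),
      missing_frequency_policy = missing_frequency_policy,
      missing_score_policy = missing_score_policy)
}

.configFields <- function() {
  setdiff(slotNames("FilterConfig"), character(0))
}

#' Read and write a funnel configuration file
#'
#' The configuration is a flat YAML file mirroring the
#' [FilterConfig][FilterConfig-class] field names; fields absent from the
#' file keep their defaults. An optional `segregation:` section configures
#' the [SegregationPolicy][SegregationPolicy-class] (keys
#' `carrier_genotypes` and `missing_genotype_policy`). Round-tripping a
#' config through `writeFilterConfig()` and `readFilterConfig()` is
#' lossless.
#'
#' @param path Path of the YAML file.
#' @param config,policy Objects to serialize.
#'
#' @return `readFilterConfig()` returns a list with elements `config`
#'   (a `FilterConfig`) and `policy` (a `SegregationPolicy`).
#' @export
readFilterConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  seg <- raw$segregation
  raw$segregation <- NULL
  unknown <- setdiff(names(raw), .configFields())
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  config <- do.call(filterConfig, raw)
  polArgs <- list()
  if (!is.null(seg)) {
    known <- c("carrier_genotypes", "missing_genotype_policy")
    bad <- setdiff(names(seg), known)
    if (length(bad))
      stop("unknown segregation keys: ", paste(bad, collapse = ", "))
    polArgs <- seg
  }
  list(config = config, policy = do.call(segregationPolicy, polArgs))
}

#' @rdname readFilterConfig
#' @export
writeFilterConfig <- function(config, path, policy = segregationPolicy()) {
  stopifnot(is(config, "FilterConfig"), is(policy, "SegregationPolicy"))
  vals <- lapply(.configFields(), function(f) slot(config, f))
  names(vals) <- .configFields()
  vals$segregation <- list(
    carrier_genotypes = policy@carrier_genotypes,
    missing_genotype_policy = policy@missing_genotype_policy
  )
  yaml::write_yaml(vals, path)
  invisible(path)
}

## Favorability ----------------------------------------------------------------

#' Default favorability rules for the deleteriousness panel
#'
#' The categorical calls counted as favorable for each predictor: SIFT `D`;
#' PolyPhen-2 HumDiv and HumVar `D` and `P`; LRT `D`; MutationTaster `D` and
#' `A`; MutationAssessor `H` and `M`; FATHMM, MetaSVM, MetaLR and PROVEAN
#' `D`; VEST3 at least `vest3_min`; reliability index at least
#' `reliability_index_min`.
#'
#' @param vest3_min Inclusive VEST3 threshold (default 0.5).
#' @param reliability_index_min Inclusive reliability-index threshold
#'   (default 5).
#' @return A [FavorabilityMap][FavorabilityMap-class].
#' @examples
#' favorability("D", "SIFT")
#' favorability(0.5, "VEST3")
#' @export
defaultFavorabilityMap <- function(vest3_min = 0.5,
                                   reliability_index_min = 5) {
  cat_rule <- function(...) list(type = "categorical", favorable = c(...))
  num_rule <- function(th) list(type = "numeric", threshold = th)
  new("FavorabilityMap", rules = list(
    SIFT = cat_rule("D"),
    Polyphen2_HumDiv = cat_rule("D", "P"),
    Polyphen2_HumVar = cat_rule("D", "P"),
    LRT = cat_rule("D"),
    MutationTaster = cat_rule("D", "A"),
    MutationAssessor = cat_rule("H", "M"),
    FATHMM = cat_rule("D"),
    MetaSVM = cat_rule("D"),
    MetaLR = cat_rule("D"),
    VEST3 = num_rule(vest3_min),
    PROVEAN = cat_rule("D"),
    ReliabilityIndex = num_rule(reliability_index_min)
  ))
}

## Vectorized favorability core; `calls` may be character or numeric.
.favorabilityVec <- function(calls, predictor, map) {
  rule <- map@rules[[predictor]]
  if (is.null(rule))
    stop("unknown predictor: '", predictor, "'")
  out <- rep("missing", length(calls))
  if (rule$type == "numeric") {
    x <- suppressWarnings(as.numeric(calls))
    ok <- !is.na(x)
    out[ok] <- ifelse(x[ok] >= rule$threshold, "favorable", "unfavorable")
  } else {
    ok <- !is.na(calls) & calls != "" & calls != "."
    out[ok] <- ifelse(as.character(calls[ok]) %in% rule$favorable,
                      "favorable", "unfavorable")
  }
  out
}

#' Classify a predictor call as favorable, unfavorable or missing
#'
#' Applies the favorability rule of one deleteriousness-panel predictor to a
#' call. Categorical calls not in the predictor's favorable set are
#' unfavorable (including unrecognized codes); a missing call (`NA`, `"."`,
#' empty) maps to `"missing"`.
#'
#' @param call Categorical code or numeric value.
#' @param predictor One of the 12 panel predictor names.
#' @param map A [FavorabilityMap][FavorabilityMap-class].
#' @return `"favorable"`, `"unfavorable"` or `"missing"` (vectorized over
#'   `call`).
#' @examples
#' favorability("D", "SIFT")       # favorable
#' favorability("T", "FATHMM")     # unfavorable
#' favorability(NA, "LRT")         # missing
#' @export
favorability <- function(call, predictor, map = defaultFavorabilityMap()) {
  if (!predictor %in% .PREDICTORS)
    stop("unknown predictor: '", predictor, "'")
  .favorabilityVec(call, predictor, map)
}

## Accessors -------------------------------------------------------------------

#' Accessors for pedigrees and variant tables
#'
#' @param x A [Pedigree][Pedigree-class] or
#'   [VariantTable][VariantTable-class].
#' @return `memberIds()` the member identifiers; `roles()` the named role
#'   vector; `nVariants()` the variant count; `variantIds()` the
#'   `chrom_pos_ref_alt` identifiers; `variantData()` the typed annotation
#'   `data.frame`; `genotypeMatrix()` the variants x members genotype matrix.
#' @name accessors
NULL

#' @rdname accessors
#' @export
memberIds <- function(x) {
  stopifnot(is(x, "Pedigree"))
  x@members$member_id
}

#' @rdname accessors
#' @export
roles <- function(x) {
  stopifnot(is(x, "Pedigree"))
  stats::setNames(x@members$role, x@members$member_id)
}

#' @rdname accessors
#' @export
nVariants <- function(x) {
  stopifnot(is(x, "VariantTable"))
  nrow(x@variants)
}

#' @rdname accessors
#' @export
variantIds <- function(x) {
  stopifnot(is(x, "VariantTable"))
  v <- x@variants
  if (nrow(v) == 0L) return(character(0))
  paste(v$chrom, v$pos, v$ref, v$alt, sep = "_")
}

#' @rdname accessors
#' @export
variantData <- function(x) {
  stopifnot(is(x, "VariantTable"))
  x@variants
}

#' @rdname accessors
#' @export
genotypeMatrix <- function(x) {
  stopifnot(is(x, "VariantTable"))
  x@genotypes
}

#' Subset a variant table by row
#'
#' @param x A [VariantTable][VariantTable-class].
#' @param i Row indices (numeric, logical, or variant identifiers).
#' @param j,drop Ignored (rows only).
#' @param ... Ignored.
#' @export
setMethod("[", "VariantTable", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, variantIds(x))
  new("VariantTable",
      variants = x@variants[i, , drop = FALSE],
      genotypes = x@genotypes[i, , drop = FALSE],
      passthrough = x@passthrough[i, , drop = FALSE],
      manifest = x@manifest,
      source = x@source)
})

#' Extract the pass/fail vector of a tier decision
#'
#' @param x A [TierDecision][TierDecision-class].
#' @return Named logical vector, one element per variant.
#' @export
passed <- function(x) {
  stopifnot(is(x, "TierDecision"))
  x@passed
}

#' @rdname passed
#' @param x A [TierDecision][TierDecision-class].
#' @export
decisionDetail <- function(x) {
  stopifnot(is(x, "TierDecision"))
  x@detail
}

#' Stage counts of a funnel report
#'
#' @param x A [FunnelReport][FunnelReport-class].
#' @return `data.frame` with columns `stage` and `count`.
#' @export
stageCounts <- function(x) {
  stopifnot(is(x, "FunnelReport"))
  x@stages
}

#' @rdname stageCounts
#' @param stage Stage name; defaults to the final stage.
#' @export
survivingIds <- function(x, stage = NULL) {
  stopifnot(is(x, "FunnelReport"))
  if (is.null(stage)) stage <- x@stages$stage[nrow(x@stages)]
  x@survivors[[stage]]
}

## Show methods ----------------------------------------------------------------

setMethod("show", "Pedigree", function(object) {
  m <- object@members
  cat(sprintf("Pedigree with %d member(s)\n", nrow(m)))
  if (nrow(m)) {
    tab <- table(factor(m$phenotype, levels = .PHENOTYPES))
    cat(sprintf("  phenotypes: %s\n",
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
    print(m, row.names = FALSE)
  }
  invisible(NULL)
})

setMethod("show", "VariantTable", function(object) {
  cat(sprintf("VariantTable: %d variant(s), %d genotyped member(s)\n",
              nrow(object@variants), ncol(object@genotypes)))
  if (nrow(object@variants)) {
    ids <- variantIds(object)
    cat("  ", paste(utils::head(ids, 5), collapse = ", "),
        if (length(ids) > 5) ", ..." else "", "\n", sep = "")
  }
  invisible(NULL)
})

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig\n")
  for (f in .configFields())
    cat(sprintf("  %s: %s\n", f, as.character(slot(object, f))))
  invisible(NULL)
})

setMethod("show", "TierDecision", function(object) {
  cat(sprintf("TierDecision [%s]: %d/%d passed\n", object@stage,
              sum(object@passed), length(object@passed)))
  invisible(NULL)
})

setMethod("show", "FunnelReport", function(object) {
  cat("FunnelReport\n")
  print(object@stages, row.names = FALSE)
  invisible(NULL)
})

setMethod("show", "CarrierCounts", function(object) {
  cat(sprintf("CarrierCounts: cases %d/%d, controls %d/%d",
              object@case_carriers, object@case_total,
              object@control_carriers, object@control_total))
  if (object@case_missing + object@control_missing > 0L)
    cat(sprintf(" (missing: %d case, %d control)",
                object@case_missing, object@control_missing))
  cat("\n")
  invisible(NULL)
})
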