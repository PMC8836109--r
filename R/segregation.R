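## Role-based pedigree segregation: obligate carriers (cancer cases) must
## carry the variant; polyp patients and not-yet-at-risk members are
## unconstrained.

#' Construct a segregation policy
#'
#' @param role_of_phenotype Named character mapping each phenotype to a
#'   role. Default: cancer cases are obligate carriers, polyp patients are
#'   optional carriers (they may express a preliminary disease stage), and
#'   unaffected members are uninformative.
#' @param carrier_genotypes Genotype states counted as carrying. The
#'   default `c("het", "hom_alt")` encodes "carries at least one alternate
#'   allele"; pass `"het"` alone for a strict heterozygous-dominant mode.
#' @param missing_genotype_policy `"fail_if_obligate_missing"` (an obligate
#'   carrier without a genotype call fails the variant, the default) or
#'   `"permissive"` (such members are skipped).
#' @return A [SegregationPolicy][SegregationPolicy-class].
#' @export
segregationPolicy <- function(
    role_of_phenotype = c(crc_case = "obligate_carrier",
                          polyp = "optional_carrier",
                          unaffected = "uninformative"),
    carrier_genotypes = c("het", "hom_alt"),
    missing_genotype_policy = "fail_if_obligate_missing") {
  new("SegregationPolicy",
      role_of_phenotype = role_of_phenotype,
      carrier_genotypes = carrier_genotypes,
      missing_genotype_policy = missing_genotype_policy)
}

#' Assign carrier-expectation roles from phenotypes
#'
#' Sets each member's role from its phenotype via the policy; explicit
#' per-member overrides win and are stored, keeping deviations auditable.
#'
#' @param ped A [Pedigree][Pedigree-class].
#' @param policy A [SegregationPolicy][SegregationPolicy-class].
#' @param overrides Optional named character vector `member_id -> role`.
#' @return The pedigree with roles set.
#' @examples
#' ped <- crcFamilyPedigree()
#' roles(assignRoles(ped))
#' roles(assignRoles(ped, overrides = c("III-2" = "obligate_carrier")))
#' @export
assignRoles <- function(ped, policy = segregationPolicy(),
                        overrides = NULL) {
  stopifnot(is(ped, "Pedigree"), is(policy, "SegregationPolicy"))
  m <- ped@members
  m$role <- unname(policy@role_of_phenotype[m$phenotype])
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), m$member_id)
    if (length(unknown))
      stop("override for unknown member: ",
           paste(unknown, collapse = ", "))
    m$role[match(names(overrides), m$member_id)] <- unname(overrides)
  }
  out <- new("Pedigree", members = m)
  validObject(out)
  out
}

#' Does a variant segregate with disease in the family?
#'
#' A variant segregates when every obligate carrier (by role) has a
#' carrying genotype. Optional carriers and uninformative members impose
#' no constraint in either direction: the model is a set-membership
#' requirement, not an inheritance-likelihood computation.
#'
#' An obligate carrier with no genotype (missing call, or no genotype
#' column at all) fails the variant under the default policy, or is
#' skipped under `"permissive"`.
#'
#' @param x A [VariantTable][VariantTable-class]; the check is vectorized
#'   over its rows.
#' @param ped A [Pedigree][Pedigree-class] with roles assigned.
#' @param policy A [SegregationPolicy][SegregationPolicy-class].
#' @return Logical vector, one element per variant, named by variant id.
#' @export
segregates <- function(x, ped, policy = segregationPolicy()) {
  stopifnot(is(x, "VariantTable"), is(ped, "Pedigree"))
  r <- roles(ped)
  obligate <- names(r)[r == "obligate_carrier"]
  n <- nVariants(x)
  out <- rep(TRUE, n)
  g <- x@genotypes
  for (member in obligate) {
    if (member %in% colnames(g)) {
      gm <- g[, member]
      carries <- gm %in% policy@carrier_genotypes
      if (policy@missing_genotype_policy == "permissive")
        carries <- carries | gm == "missing"
      out <- out & carries
    } else if (policy@missing_genotype_policy != "permissive") {
      out[] <- FALSE
    }
  }
  stats::setNames(out, variantIds(x))
}
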