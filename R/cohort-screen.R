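## Validation-cohort carrier screen: tally genotyping calls and test the
## 2x2 carrier table exactly.

#' Tally carriers from case-control genotyping calls
#'
#' Counts carriers (heterozygous or homozygous alternate) per group from a
#' table of genotyping calls. Missing calls are excluded from the group
#' totals and reported separately.
#'
#' @param calls A `data.frame` with columns `group` (`"case"` or
#'   `"control"`) and `genotype` (genotype state names or VCF-style tokens
#'   `0/0`, `0/1`, `1/1`, `./.`).
#' @return A [CarrierCounts][CarrierCounts-class].
#' @examples
#' calls <- data.frame(group = c("case", "case", "control"),
#'                     genotype = c("0/1", "0/0", "0/0"))
#' tallyGenotyping(calls)
#' @export
tallyGenotyping <- function(calls) {
  stopifnot(all(c("group", "genotype") %in% names(calls)))
  grp <- as.character(calls$group)
  bad <- setdiff(unique(grp), c("case", "control"))
  if (length(bad))
    stop("unknown group label: ", paste(bad, collapse = ", "))
  gt <- .parseGenotypes(as.character(calls$genotype), "screen",
                        seq_along(grp))
  carrier <- gt %in% c("het", "hom_alt")
  genotyped <- gt != "missing"
  cnt <- function(grp_is, what) as.integer(sum(grp == grp_is & what))
  new("CarrierCounts",
      case_carriers = cnt("case", carrier & genotyped),
      case_total = cnt("case", genotyped),
      control_carriers = cnt("control", carrier & genotyped),
      control_total = cnt("control", genotyped),
      case_missing = cnt("case", !genotyped),
      control_missing = cnt("control", !genotyped))
}

#' Shortcut constructor for carrier counts
#'
#' @param case_carriers,case_total,control_carriers,control_total Counts.
#' @return A [CarrierCounts][CarrierCounts-class].
#' @export
carrierCounts <- function(case_carriers, case_total, control_carriers,
                          control_total) {
  new("CarrierCounts",
      case_carriers = as.integer(case_carriers),
      case_total = as.integer(case_total),
      control_carriers = as.integer(control_carriers),
      control_total = as.integer(control_total),
      case_missing = 0L, control_missing = 0L)
}

#' Exact test of a carrier 2x2 table
#'
#' Two-sided exact test of carrier status against group for a
#' case-control carrier table, computed by the standard convention:
#' conditional on both margins, the p-value sums the hypergeometric point
#' probabilities of all tables at most as probable as the observed one.
#' The odds ratio is reported as the sample cross-product ratio; when a
#' zero cell drives it to infinity (or leaves it undefined) it is flagged
#' `unbounded` and reported as `NA` rather than a number.
#'
#' @param counts A [CarrierCounts][CarrierCounts-class]; both group totals
#'   must be positive.
#' @return A list with elements `odds_ratio`, `unbounded`, `p_value`, and
#'   the 2x2 `table`.
#' @examples
#' carrierExactTest(carrierCounts(1, 1704, 0, 1674))
#' @export
carrierExactTest <- function(counts) {
  stopifnot(is(counts, "CarrierCounts"))
  if (counts@case_total <= 0L || counts@control_total <= 0L)
    stop("both group totals must be positive")
  a <- counts@case_carriers
  b <- counts@control_carriers
  cc <- counts@case_total - a
  d <- counts@control_total - b
  tab <- matrix(c(a, cc, b, d), nrow = 2,
                dimnames = list(c("carrier", "non_carrier"),
                                c("case", "control")))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  unbounded <- (b == 0L || cc == 0L)
  or <- if (unbounded) NA_real_
        else (a * d) / (b * cc)  # a zero numerator is a genuine OR of 0
  list(odds_ratio = or, unbounded = unbounded,
       p_value = min(p, 1), table = tab)
}
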