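## Shared fixture builders and independent oracles.

## Touch the sequence machinery once so per-test timings measure the
## operations, not deferred namespace loading.
invisible(Biostrings::width(Biostrings::AAStringSet("ACDEF")))

## Minimal canonical-header data.frame for fixture tables; extra columns
## (scores, genotypes) are supplied by the caller.
base_rows <- function(n = 1L) {
  data.frame(Chrom = "1", Pos = seq_len(n), Ref = "A", Alt = "G",
             Gene = "G1", ExonicClassification = "nonsynonymous SNV",
             RegionClass = "exonic", Qual = 60, Depth = 30,
             check.names = FALSE, stringsAsFactors = FALSE)
}

## Write a raw data.frame as TSV and load it as a VariantTable.
load_table <- function(df, ped = crcFamilyPedigree()) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  readAnnotatedTable(path, ped)
}

## Brute-force segregation oracle: every obligate member must have a
## carrying genotype.
seg_oracle <- function(genotypes, obligate,
                       carrier_states = c("het", "hom_alt")) {
  all(vapply(obligate, function(m) {
    g <- genotypes[[m]]
    !is.null(g) && g %in% carrier_states
  }, logical(1)))
}

## Brute-force panel fraction oracle over favorable/unfavorable/missing
## statuses.
frac_oracle <- function(status, fraction, panel_size,
                        policy = "exclude_from_denominator") {
  fav <- sum(status == "favorable")
  avail <- sum(status != "missing")
  denom <- if (policy == "count_unfavorable") panel_size else avail
  denom > 0 && fav / denom >= fraction
}

## Exhaustive hypergeometric enumeration oracle for the two-sided exact
## test on a 2x2 carrier table: conditional on both margins, sum the
## point probabilities of all tables at most as probable as the observed
## one (with the standard relative tolerance for floating-point ties).
hyper_oracle <- function(a, n1, b, n2) {
  m <- a + b
  k <- max(0L, m - n2):min(m, n1)
  probs <- stats::dhyper(k, n1, n2, m)
  obs <- stats::dhyper(a, n1, n2, m)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

table1_path <- function() {
  system.file("extdata", "table1_variants.tsv", package = "VariantFunnel")
}

alignment_path <- function() {
  system.file("extdata", "ptk7_ig4_synthetic_alignment.fasta",
              package = "VariantFunnel")
}
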