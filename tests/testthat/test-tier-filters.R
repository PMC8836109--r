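make_scored <- function(...) {
  df <- base_rows(1)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  load_table(df)
}

test_that("QC bounds are strict on both quality and coverage", {
  df <- base_rows(3)
  df$Qual <- c(21, 20, 100)
  df$Depth <- c(6, 100, 5)
  expect_identical(unname(passed(qcFilter(load_table(df)))),
                   c(TRUE, FALSE, FALSE))
})

test_that("frequency filter caps present MAFs and honours the missing policy", {
  ok <- make_scored(MAF_ExAC_nonTCGA = 2.21e-4, MAF_gnomAD_NFE = 3.33e-4)
  expect_true(passed(frequencyFilter(ok)))
  allmiss <- make_scored()
  expect_true(passed(frequencyFilter(allmiss)))   # treat_as_rare default
  expect_false(passed(frequencyFilter(
    allmiss, filterConfig(missing_frequency_policy = "drop"))))
  common <- make_scored(MAF_1KG = 0.5)
  expect_false(passed(frequencyFilter(common)))
  ## population cap is inclusive, local cap strict
  expect_true(passed(frequencyFilter(make_scored(MAF_1KG = 0.001))))
  expect_false(passed(frequencyFilter(make_scored(LocalCohortFreq = 0.05))))
  expect_true(passed(frequencyFilter(make_scored(LocalCohortFreq = 0.049))))
})

test_that("coding and non-synonymous stages keep the right classes", {
  df <- base_rows(3)
  df$RegionClass <- c("exonic", "intergenic", "UTR3")
  expect_identical(unname(passed(codingFilter(load_table(df)))),
                   c(TRUE, FALSE, FALSE))
  df <- base_rows(4)
  df$ExonicClassification <- c("nonsynonymous SNV", "synonymous SNV",
                               "unknown", "frameshift deletion")
  expect_identical(unname(passed(nonsynonymousFilter(load_table(df)))),
                   c(TRUE, FALSE, TRUE, TRUE))
})

test_that("CADD threshold is inclusive and fails closed on missing", {
  df <- base_rows(4)
  df$CADD_PHRED <- c("25.3", "10.0", "9.99", ".")
  expect_identical(unname(passed(caddFilter(load_table(df)))),
                   c(TRUE, TRUE, FALSE, FALSE))
})

test_that("conservation uses a fixed 2-of-3 rule with missing unsatisfied", {
  df <- base_rows(4)
  df$GERP <- c("4.14", "2.33", "0", ".")
  df$PhyloP <- c("4.217", "1.849", "0", "4")
  df$PhastCons <- c("1", "1", "0", ".")
  dec <- conservationFilter(load_table(df))
  expect_identical(unname(passed(dec)), c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(decisionDetail(dec)$numerator, c(3L, 2L, 0L, 1L))
  expect_identical(decisionDetail(dec)$denominator, rep(3L, 4))
})

test_that("intolerance fraction is inclusive at the 60% boundary", {
  five <- make_scored(Intolerance_InHouse = -1.2, Intolerance_ESP = -0.8,
                      Intolerance_ExAC = -0.5, ZScore = 1.5, pLI = 0.97)
  d5 <- intoleranceFilter(five)
  expect_true(passed(d5))
  expect_identical(decisionDetail(d5)$fraction, 1)
  three <- make_scored(Intolerance_InHouse = -0.4, Intolerance_ESP = 0.2,
                       Intolerance_ExAC = -0.2, ZScore = 0.8, pLI = 0.02)
  d3 <- intoleranceFilter(three)
  expect_true(passed(d3))                       # exactly 3/5 = 60%
  expect_identical(decisionDetail(d3)$numerator, 3L)
  two <- make_scored(Intolerance_InHouse = -0.4, Intolerance_ESP = 0.2,
                     Intolerance_ExAC = 0.2, ZScore = 0.8, pLI = 0.02)
  expect_false(passed(intoleranceFilter(two)))  # 2/5 = 40%
  ## boundary values: intolerance and Z are strict, pLI inclusive
  bnd <- make_scored(Intolerance_InHouse = 0, Intolerance_ESP = 0,
                     Intolerance_ExAC = 0, ZScore = 0, pLI = 0.9)
  expect_identical(decisionDetail(intoleranceFilter(bnd))$numerator, 1L)
  ## an empty panel fails closed
  expect_false(passed(intoleranceFilter(make_scored())))
})

test_that("type-specific intolerance restricts Z and pLI by variant class", {
  ## missense variant: pLI leaves the panel, so a favorable pLI no longer
  ## rescues a 3-of-5 pattern (it becomes 2-of-4)
  ms <- make_scored(Intolerance_InHouse = -0.4, Intolerance_ESP = 0.2,
                    Intolerance_ExAC = 0.2, ZScore = 0.8, pLI = 0.95)
  expect_true(passed(intoleranceFilter(ms)))          # pooled: 3/5
  dec <- intoleranceFilter(ms, type_specific = TRUE)
  expect_identical(decisionDetail(dec)$available, 4L) # pLI excluded
  expect_false(passed(dec))                           # 2/4 = 50%
  ## loss-of-function variant: Z leaves the panel instead
  df <- base_rows(1)
  df$ExonicClassification <- "stopgain"
  df$ZScore <- 5; df$pLI <- 0.99
  lof <- load_table(df)
  dlof <- intoleranceFilter(lof, type_specific = TRUE)
  expect_identical(decisionDetail(dlof)$available, 1L)
  expect_true(passed(dlof))                           # pLI alone, 1/1
})

test_that("deleteriousness fraction counts favorability over the panel", {
  tab <- table1Variants()
  dec <- deleteriousnessFilter(tab)
  v <- variantData(tab)
  det <- decisionDetail(dec)
  expect_true(all(passed(dec)))
  expect_identical(det$numerator[v$gene == "RSBN1L"], 12L)
  expect_identical(det$denominator[v$gene == "C2orf42"], 6L)
  expect_identical(det$numerator[v$gene == "C2orf42"], 5L)
  expect_equal(det$fraction[v$gene == "PTK7"], 8 / 12)
  ## 6 of 12 favorable fails (50% < 60%)
  half <- make_scored(SIFT = "D", Polyphen2_HumDiv = "D",
                      Polyphen2_HumVar = "D", LRT = "D",
                      MutationTaster = "D", MutationAssessor = "H",
                      FATHMM = "T", MetaSVM = "T", MetaLR = "T",
                      VEST3 = 0.1, PROVEAN = "N", ReliabilityIndex = 1)
  expect_false(passed(deleteriousnessFilter(half)))
  expect_false(passed(deleteriousnessFilter(make_scored())))
  ## under count_unfavorable the C2orf42-style sparse panel fails
  sparse <- make_scored(SIFT = "D", LRT = "D", MutationTaster = "D",
                        VEST3 = 0.8, ReliabilityIndex = 6, FATHMM = "T")
  expect_true(passed(deleteriousnessFilter(sparse)))
  expect_false(passed(deleteriousnessFilter(
    sparse, filterConfig(missing_score_policy = "count_unfavorable"))))
})

test_that("tightening any threshold never admits new variants", {
  sim <- generateDataset(simulationParams(seed = 5, n_background = 400,
                                          fraction_deleterious_background = 0.5))
  tab <- sim$table
  base <- filterConfig()
  tighter <- list(
    list(qcFilter, filterConfig(qual_min = 40, depth_min = 10)),
    list(frequencyFilter, filterConfig(maf_max = 1e-4,
                                       local_freq_max = 0.01)),
    list(caddFilter, filterConfig(cadd_min = 20)),
    list(conservationFilter, filterConfig(conservation_required = 3L,
                                          gerp_min = 4, phylop_min = 4,
                                          phastcons_min = 0.9)),
    list(intoleranceFilter, filterConfig(intolerance_fraction = 0.9)),
    list(deleteriousnessFilter,
         filterConfig(deleteriousness_fraction = 0.9, vest3_min = 0.9,
                      reliability_index_min = 9))
  )
  for (tc in tighter) {
    loose <- passed(tc[[1]](tab, base))
    tight <- passed(tc[[1]](tab, tc[[2]]))
    expect_true(all(loose | !tight))
  }
})
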