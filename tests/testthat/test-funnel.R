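test_that("the packaged six-variant fixture survives the whole funnel", {
  res <- runFunnel(table1Variants(), crcFamilyPedigree())
  s <- stageCounts(res$report)
  expect_identical(s$stage, c("input", stageSequence()))
  expect_true(all(s$count == 6L))
  expect_identical(nVariants(res$candidates), 6L)
})

test_that("an empty table yields an all-zero funnel", {
  sim <- generateDataset(simulationParams(seed = 1, n_background = 0))
  res <- runFunnel(sim$table, sim$pedigree)
  expect_true(all(stageCounts(res$report)$count == 0L))
  expect_identical(nVariants(res$candidates), 0L)
  expect_identical(nrow(candidateReport(res$candidates)), 0L)
})

test_that("weakening one row's conservation removes exactly that row", {
  ped <- crcFamilyPedigree()
  tab <- table1Variants(ped)
  i <- which(variantData(tab)$gene == "PTK7")
  tab@variants$phylop[i] <- NA_real_
  tab@variants$gerp[i] <- 1.0
  res <- runFunnel(tab, ped)
  s <- stageCounts(res$report)
  ## PTK7 now satisfies only PhastCons: eliminated at the conservation
  ## stage (1 of 3), leaving five finalists
  expect_identical(s$count[s$stage == "cadd"], 6L)
  expect_identical(s$count[s$stage == "conservation"], 5L)
  expect_identical(nVariants(res$candidates), 5L)
  expect_false("6_43100257_G_A" %in% variantIds(res$candidates))
})

test_that("stage survivors chain and counts never increase", {
  sim <- generateDataset(simulationParams(
    seed = 9, n_background = 3000, fraction_deleterious_background = 0.3))
  res <- runFunnel(sim$table, sim$pedigree)
  s <- stageCounts(res$report)
  expect_true(all(diff(s$count) <= 0))
  surv <- res$report@survivors
  stages <- names(surv)
  for (k in seq_along(stages)[-1])
    expect_true(all(surv[[stages[k]]] %in% surv[[stages[k - 1]]]))
  ## survivors of stage k are exactly the inputs scored at stage k+1
  for (st in stageSequence())
    expect_identical(sort(names(passed(res$decisions[[st]]))),
                     sort(surv[[stages[match(st, stages) - 1]]]))
})

test_that("input row order never changes the final set", {
  sim <- generateDataset(simulationParams(
    seed = 21, n_background = 500, fraction_deleterious_background = 0.5,
    planted = list(plantedVariant("6", 43100257, "G", "A", "PTK7",
                                  carriers = c("I-2", "II-1", "II-2",
                                               "II-4")))))
  res1 <- runFunnel(sim$table, sim$pedigree)
  set.seed(77)
  perm <- sample(nVariants(sim$table))
  res2 <- runFunnel(sim$table[perm], sim$pedigree)
  expect_setequal(variantIds(res2$candidates), variantIds(res1$candidates))
  expect_identical(stageCounts(res2$report)$count,
                   stageCounts(res1$report)$count)
  ## ranking makes the candidate order itself permutation-invariant
  expect_identical(variantIds(res2$candidates), variantIds(res1$candidates))
})

test_that("candidate report ranks by CADD with positional tie-break", {
  res <- runFunnel(table1Variants(), crcFamilyPedigree())
  rep1 <- candidateReport(res$candidates)
  expect_identical(rep1$gene[1], "RSBN1L")
  expect_identical(rep1$cadd_phred[1], 35)
  expect_identical(rep1$cadd_phred, sort(rep1$cadd_phred,
                                         decreasing = TRUE))
  expect_identical(rep1$pedigree_segregation[rep1$gene == "ADAMTS10"],
                   "I-2, II-1, II-2, II-4, II-6")
  ## tie on CADD: ordered by chromosome then position
  ped <- crcFamilyPedigree()
  df <- base_rows(3)
  df$Chrom <- c("10", "2", "2"); df$Pos <- c(5, 9, 3)
  df$CADD_PHRED <- 20
  tied <- candidateReport(load_table(df, ped))
  expect_identical(tied$variant,
                   c("2_3_A_G", "2_9_A_G", "10_5_A_G"))
})

test_that("reruns on identical input are byte-identical on disk", {
  sim <- generateDataset(simulationParams(seed = 33, n_background = 800))
  f1 <- tempfile(); f2 <- tempfile()
  r1 <- runFunnel(sim$table, sim$pedigree)
  r2 <- runFunnel(sim$table, sim$pedigree)
  writeFunnelReport(r1$report, f1)
  writeFunnelReport(r2$report, f2)
  expect_identical(readLines(f1), readLines(f2))
  writeCandidateReport(candidateReport(r1$candidates), f1)
  writeCandidateReport(candidateReport(r2$candidates), f2)
  expect_identical(readLines(f1), readLines(f2))
})
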