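test_that("gene dropping honours degenerate founder frequencies", {
  ped <- crcFamilyPedigree()
  expect_true(all(geneDrop(ped, 0, seed = 1) == "hom_ref"))
  expect_true(all(geneDrop(ped, 1, seed = 1) == "hom_alt"))
})

test_that("trio carrier rate matches the closed-form Mendelian expectation", {
  trio <- pedigree(member_id = c("dad", "mum", "kid"),
                   father_id = c(NA, NA, "dad"),
                   mother_id = c(NA, NA, "mum"))
  f <- 0.5
  n <- 10000
  set.seed(2024)
  kid <- replicate(n, geneDrop(trio, f)[["kid"]])
  ## each transmitted allele is alt with marginal probability f, so the
  ## child carries with probability 1 - (1 - f)^2
  p_exp <- 1 - (1 - f)^2
  p_obs <- mean(kid %in% c("het", "hom_alt"))
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("a cyclic pedigree is rejected", {
  loop <- new("Pedigree", members = data.frame(
    member_id = c("a", "b"), father_id = c("b", "a"),
    mother_id = c(NA, NA), sex = "unknown",
    phenotype = "unaffected", age_at_event = NA_integer_,
    role = "uninformative"))
  expect_error(geneDrop(loop, 0.5, seed = 1), "cyclic")
})

test_that("generation is deterministic at a fixed seed", {
  p <- simulationParams(seed = 12, n_background = 300,
                        planted = list(plantedVariant(
                          "1", 100, "A", "T", "GX",
                          carriers = c("I-2", "II-1", "II-4"))))
  s1 <- generateDataset(p)
  s2 <- generateDataset(p)
  expect_identical(variantData(s1$table), variantData(s2$table))
  expect_identical(genotypeMatrix(s1$table), genotypeMatrix(s2$table))
  f1 <- tempfile(); f2 <- tempfile()
  writeAnnotatedTable(s1$table, f1)
  writeAnnotatedTable(s2$table, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted specifications are validated and recovered", {
  expect_error(generateDataset(simulationParams(
    seed = 1, n_background = 0,
    planted = list(plantedVariant("1", 1, "A", "T", "G",
                                  carriers = "NOBODY")))),
    "not in pedigree")
  ## with no background, the funnel's final list is exactly the plant
  sim <- generateDataset(simulationParams(
    seed = 4, n_background = 0,
    planted = list(plantedVariant(
      "6", 43100257, "G", "A", "PTK7",
      maf_exac_nontcga = 0, maf_gnomad_nfe = 0,
      cadd_phred = 25.3, gerp = 4.14, phylop = 4.217, phastcons = 1,
      carriers = c("I-2", "II-1", "II-2", "II-4")))))
  expect_identical(sim$truth@planted_ids, "6_43100257_G_A")
  res <- runFunnel(sim$table, sim$pedigree)
  expect_identical(variantIds(res$candidates), "6_43100257_G_A")
})

test_that("emitted scores respect the variant-record invariants", {
  sim <- generateDataset(simulationParams(seed = 8, n_background = 2000,
                                          fraction_deleterious_background = 0.4))
  v <- variantData(sim$table)
  expect_true(all(v$pos >= 1))
  expect_true(all(v$ref != v$alt))
  for (f in c("maf_1kg", "maf_exac_nontcga", "maf_gnomad_nfe",
              "local_cohort_freq", "phastcons")) {
    x <- v[[f]]
    expect_true(all(is.na(x) | (x >= 0 & x <= 1)), label = f)
  }
  expect_true(all(is.na(v$cadd_phred) | v$cadd_phred >= 0))
  expect_true(all(genotypeMatrix(sim$table) %in%
                  c("hom_ref", "het", "hom_alt", "missing")))
  ## deleteriousness calls only exist where dbNSFP would have them
  nsyn <- v$exonic_classification == "nonsynonymous_snv"
  expect_true(all(is.na(v$SIFT[!nsyn])))
})

test_that("a benign-only background yields an essentially empty final list", {
  sim <- generateDataset(simulationParams(
    seed = 15, n_background = 5000,
    fraction_deleterious_background = 0))
  res <- runFunnel(sim$table, sim$pedigree)
  ## under the benign regime the per-stage pass probabilities multiply to
  ## far below 1/5000, before even requiring segregation
  expect_lte(nVariants(res$candidates), 1L)
})

test_that("background survival is monotone in the thresholds", {
  sim <- generateDataset(simulationParams(
    seed = 18, n_background = 1500,
    fraction_deleterious_background = 0.5))
  ## release the segregation constraint so later stages see background
  ped <- assignRoles(sim$pedigree, overrides = stats::setNames(
    rep("uninformative", 6), memberIds(sim$pedigree)))
  base <- runFunnel(sim$table, ped)$candidates
  expect_gt(nVariants(base), 0L)
  for (cfg in list(filterConfig(cadd_min = 20),
                   filterConfig(intolerance_fraction = 0.8),
                   filterConfig(deleteriousness_fraction = 0.8),
                   filterConfig(conservation_required = 3L))) {
    tight <- runFunnel(sim$table, ped, cfg)$candidates
    expect_true(all(variantIds(tight) %in% variantIds(base)))
  }
})
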