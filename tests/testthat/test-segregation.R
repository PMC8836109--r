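test_that("roles derive from phenotype with auditable overrides", {
  ped <- crcFamilyPedigree()
  r <- roles(assignRoles(ped))
  expect_identical(unname(r[c("I-2", "II-1", "II-4")]),
                   rep("obligate_carrier", 3))
  expect_identical(unname(r[c("II-2", "II-6")]),
                   rep("optional_carrier", 2))
  expect_identical(unname(r["III-2"]), "uninformative")
  r2 <- roles(assignRoles(ped,
                          overrides = c("III-2" = "obligate_carrier")))
  expect_identical(unname(r2["III-2"]), "obligate_carrier")
  expect_error(assignRoles(ped, overrides = c(NOBODY = "uninformative")),
               "unknown member")
  allun <- pedigree(c("a", "b"), phenotype = "unaffected")
  expect_true(all(roles(allun) == "uninformative"))
})

test_that("published carrier sets all segregate; an obligate non-carrier fails", {
  ped <- crcFamilyPedigree()
  tab <- table1Variants(ped)
  ## every Table-1 carrier set contains all three cancer cases
  expect_true(all(segregates(tab, ped)))
  ## flipping one obligate carrier to reference breaks segregation
  tab2 <- tab
  tab2@genotypes[variantData(tab)$gene == "PTK7", "II-1"] <- "hom_ref"
  s <- segregates(tab2, ped)
  expect_false(s[["6_43100257_G_A"]])
  expect_identical(sum(s), 5L)
})

test_that("optional and uninformative members impose no constraint", {
  ped <- crcFamilyPedigree()
  tab <- table1Variants(ped)
  ## monotonicity: adding carrier genotypes to non-obligate members never
  ## flips a segregating variant to non-segregating
  for (m in c("II-2", "II-6", "III-2")) {
    tab2 <- tab
    tab2@genotypes[, m] <- "het"
    expect_true(all(segregates(tab2, ped)))
    tab2@genotypes[, m] <- "hom_ref"
    expect_true(all(segregates(tab2, ped)))
  }
})

test_that("missing obligate genotypes follow the configured policy", {
  ped <- crcFamilyPedigree()
  tab <- table1Variants(ped)
  tab@genotypes[1L, "I-2"] <- "missing"
  expect_false(segregates(tab, ped)[1L])
  expect_true(segregates(tab, ped, segregationPolicy(
    missing_genotype_policy = "permissive"))[1L])
  ## a het-only dominant mode rejects homozygous carriers
  tab@genotypes[2L, "II-4"] <- "hom_alt"
  strict <- segregationPolicy(carrier_genotypes = "het")
  expect_false(segregates(tab, ped, strict)[2L])
  expect_true(segregates(tab, ped)[2L])
})

test_that("segregation equals brute force on random genotype assignments", {
  ped <- crcFamilyPedigree()
  members <- memberIds(ped)
  set.seed(101)
  for (rep in 1:25) {
    assign <- sample(c("hom_ref", "het", "hom_alt", "missing"),
                     length(members), replace = TRUE)
    names(assign) <- members
    tab <- table1Variants(ped)[1L]
    tab@genotypes[1L, members] <- assign
    expect_identical(
      unname(segregates(tab, ped)),
      seg_oracle(as.list(assign), c("I-2", "II-1", "II-4")))
  }
})
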