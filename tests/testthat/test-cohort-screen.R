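test_that("carrier tally counts het and hom-alt calls per group", {
  calls <- data.frame(
    group = c(rep("case", 5), rep("control", 4)),
    genotype = c("0/1", "0/0", "1/1", "0/0", "./.",
                 "0/0", "0/0", "0/1", "./."))
  counts <- tallyGenotyping(calls)
  expect_identical(counts@case_carriers, 2L)
  expect_identical(counts@case_total, 4L)    # missing call excluded
  expect_identical(counts@control_carriers, 1L)
  expect_identical(counts@control_total, 3L)
  expect_identical(counts@case_missing, 1L)
  expect_identical(counts@control_missing, 1L)
  expect_error(tallyGenotyping(data.frame(group = "patient",
                                          genotype = "0/1")),
               "unknown group")
  empty <- tallyGenotyping(data.frame(group = character(0),
                                      genotype = character(0)))
  expect_identical(empty@case_total + empty@control_total, 0L)
})

test_that("the published screen tallies to one carrier case, zero controls", {
  calls <- data.frame(
    group = c(rep("case", 1704), rep("control", 1674)),
    genotype = c("0/1", rep("0/0", 1703), rep("0/0", 1674)))
  counts <- tallyGenotyping(calls)
  expect_identical(counts@case_carriers, 1L)
  expect_identical(counts@case_total, 1704L)
  expect_identical(counts@control_carriers, 0L)
  expect_identical(counts@control_total, 1674L)
  res <- carrierExactTest(counts)
  expect_true(res$unbounded)
  expect_equal(res$p_value,
               hyper_oracle(1, 1704, 0, 1674), tolerance = 1e-12)
})

test_that("exact test matches enumeration and is label-symmetric", {
  expect_equal(carrierExactTest(carrierCounts(0, 100, 0, 100))$p_value, 1)
  expect_lt(carrierExactTest(carrierCounts(50, 100, 0, 100))$p_value,
            1e-10)
  set.seed(404)
  for (i in 1:40) {
    n1 <- sample(1:50, 1); n2 <- sample(1:50, 1)
    a <- sample(0:n1, 1); b <- sample(0:n2, 1)
    p <- carrierExactTest(carrierCounts(a, n1, b, n2))$p_value
    expect_equal(p, hyper_oracle(a, n1, b, n2), tolerance = 1e-12)
    p_swapped <- carrierExactTest(carrierCounts(b, n2, a, n1))$p_value
    expect_equal(p, p_swapped, tolerance = 1e-12)
  }
})

test_that("odds ratio is numeric when bounded, flagged otherwise", {
  res <- carrierExactTest(carrierCounts(10, 100, 5, 100))
  expect_false(res$unbounded)
  expect_equal(res$odds_ratio, (10 * 95) / (5 * 90))
  expect_true(carrierExactTest(carrierCounts(1, 10, 0, 10))$unbounded)
  expect_equal(carrierExactTest(carrierCounts(0, 10, 3, 10))$odds_ratio, 0)
  expect_error(carrierExactTest(carrierCounts(0, 0, 1, 10)), "positive")
})
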