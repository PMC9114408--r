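test_that("theta draws are reproducible and match the stated distribution", {
  spec <- cohortSpec(nPersons = 1e5, thetaDistribution = "standard-normal",
                     seed = 42)
  th <- drawThetas(spec)
  expect_lt(abs(mean(th)), 0.02)
  expect_identical(th, drawThetas(spec))

  spec2 <- cohortSpec(seed = 42)
  expect_identical(drawThetas(spec2), drawThetas(spec2))
  expect_false(identical(drawThetas(cohortSpec(seed = 1)),
                         drawThetas(cohortSpec(seed = 2))))
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohortSpec(mixtureWeights = c(0.5, 0.4)), "sum to 1")
  expect_error(cohortSpec(aRange = c(3, 1)), "ordered")
})

test_that("generated banks respect the parameter ranges and monotonicity", {
  spec <- cohortSpec(nItems = 28L, seed = 7)
  gb <- generateBank(spec)
  expect_equal(nItems(gb$bank), 28L)
  a <- discrimination(gb$bank)
  expect_true(all(a >= 1.5 & a <= 3.4))
  b <- thresholds(gb$bank)
  b1 <- vapply(b, `[`, numeric(1), 1)
  bl <- vapply(b, function(x) x[length(x)], numeric(1))
  expect_true(all(b1 >= 0 & b1 <= 1.6))
  expect_true(all(bl >= 2.5 & bl <= 4.4))
  # threshold monotonicity over many draws
  for (s in 1:25) {
    gb2 <- generateBank(cohortSpec(nItems = 40L, seed = s))
    expect_true(all(vapply(thresholds(gb2$bank),
                           function(x) !is.unsorted(x, strictly = TRUE),
                           logical(1))))
  }
})

test_that("default severity mixture with the default bank is study-like", {
  spec <- cohortSpec()           # 393 persons, 62 items, skewed mixture
  cohort <- makeStudyCohort(spec)
  m <- responseCodes(cohort$responses)
  expect_equal(dim(m), c(393L, 62L))
  expect_equal(dim(responseCodes(cohort$legacyResponses)), c(393L, 9L))
  # mean item score in the low-severity band
  expect_gt(mean(m), 1.3)
  expect_lt(mean(m), 1.7)
  # rare top categories: some items never receive category 5
  top5 <- vapply(seq_len(ncol(m)), function(j) sum(m[, j] == 5L), integer(1))
  expect_gt(sum(top5 == 0L), 0L)
  # truth registry empty by default
  expect_equal(nrow(cohort$truth$violations), 0L)
  # both forms load on the same trait
  tot62 <- rowSums(m)
  tot9 <- rowSums(responseCodes(cohort$legacyResponses))
  expect_gt(cor(tot62, tot9), 0.4)
})

test_that("simulated category frequencies match the model probabilities", {
  bank <- makeTestBank(1, seed = 3)
  theta0 <- 0.4
  n <- 1e5
  rm <- simulateResponses(bank[1], rep(theta0, n), seed = 11)
  freq <- tabulate(responseCodes(rm)[, 1], nbins = 5) / n
  p <- categoryProbs(bank@a[1], bank@thresholds[[1]], theta0)[1, ]
  mcse <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(freq - p) <= 3 * mcse + 1e-12))

  # logistic tail: theta = -10 answers category 1 essentially always
  rm2 <- simulateResponses(bank[1], rep(-10, 1000), seed = 12)
  expect_true(all(responseCodes(rm2) == 1L))
})

test_that("violation injection is recorded, targeted and otherwise inert", {
  dat <- makeTestData(J = 8, n = 200)
  clean <- injectViolations(dat$bank, dat$responses, dat$thetas,
                            kinds = character(0), seed = 5)
  expect_identical(responseCodes(clean$responses),
                   responseCodes(dat$responses))
  expect_equal(nrow(clean$truth$violations), 0L)

  expect_error(injectViolations(dat$bank, dat$responses, dat$thetas,
                                kinds = "typo", seed = 5), "unknown violation")

  v <- injectViolations(dat$bank, dat$responses, dat$thetas,
                        kinds = c("dif", "low_discrimination"),
                        items = list(dif = "I02",
                                     low_discrimination = "I06"),
                        seed = 5)
  expect_setequal(v$truth$violations$item, c("I02", "I06"))
  expect_s3_class(v$groups, "factor")
  expect_equal(unname(discrimination(v$bank)["I06"]), 0.2)
  # untouched columns are bitwise identical
  same <- setdiff(itemIds(dat$responses), c("I02", "I06"))
  expect_identical(responseCodes(v$responses)[, same],
                   responseCodes(dat$responses)[, same])
})
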