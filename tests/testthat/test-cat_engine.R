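test_that("UW-FI selection equals brute-force information ranking", {
  set.seed(41)
  for (r in 1:50) {
    bank <- makeTestBank(10, seed = 400 + r)
    th <- runif(1, -3, 3)
    adm <- sample(itemIds(bank), sample(0:7, 1))
    pick <- selectNextItem(bank, adm, th, "UW-FI")
    pool <- sort(setdiff(itemIds(bank), adm))
    info <- vapply(pool, function(id) {
      j <- match(id, itemIds(bank))
      itemInformation(bank@a[j], bank@thresholds[[j]], th)
    }, numeric(1))
    expect_identical(pick, pool[which.max(info)])
    expect_false(pick %in% adm)
  }
})

test_that("FP-KL approaches UW-FI as delta shrinks", {
  set.seed(43)
  agree <- 0
  n <- 200
  for (r in 1:n) {
    bank <- makeTestBank(8, seed = 600 + r)
    th <- runif(1, -3, 3)
    adm <- sample(itemIds(bank), sample(0:5, 1))
    agree <- agree +
      (selectNextItem(bank, adm, th, "UW-FI") ==
         selectNextItem(bank, adm, th, "FP-KL", klDelta = 0.01))
  }
  expect_gte(agree / n, 0.95)
})

test_that("sessions honor min-items, max-items and no-repeat contracts", {
  bank <- makeTestBank(12, seed = 44)
  # an unreachable SEM rule still administers minItems
  s1 <- runCatSession(bank, 0.3, config = catConfig(semThreshold = 10,
                                                    seed = 1))
  expect_length(s1@administered, 3L)
  expect_equal(s1@reason, "SEM met")
  # fixed-length mode
  s2 <- runCatSession(bank, 0.3, config = catConfig(semThreshold = NA,
                                                    maxItems = 4, seed = 1))
  expect_length(s2@administered, 4L)
  expect_equal(s2@reason, "max items")
  # property loop: no repeats, trajectory lengths, min items
  set.seed(45)
  for (r in 1:20) {
    cfg <- catConfig(estimator = sample(c("MLE", "BME", "EAP"), 1),
                     selector = sample(c("UW-FI", "FP-KL"), 1),
                     semThreshold = sample(c(0.32, 0.5), 1),
                     seed = 700 + r)
    s <- runCatSession(bank, rnorm(1), config = cfg)
    expect_false(anyDuplicated(s@administered) > 0)
    expect_gte(length(s@administered), 3L)
    expect_length(s@thetaTrajectory, length(s@administered))
    expect_length(s@semTrajectory, length(s@administered))
  }
  # first item is the information argmax at the zero start
  info0 <- vapply(seq_len(12), function(j)
    itemInformation(bank@a[j], bank@thresholds[[j]], 0), numeric(1))
  expect_equal(s1@administered[1], itemIds(bank)[which.max(info0)])
})

test_that("replay mode follows the recorded responses", {
  bank <- makeTestBank(9, seed = 46)
  rec <- drawPattern(bank, 0.7, seed = 47)
  s <- runCatSession(bank, recorded = rec,
                     config = catConfig(semThreshold = 0.5, seed = 3))
  expect_identical(s@responses, unname(rec[s@administered]))
  expect_error(runCatSession(bank, recorded = rec[1:3],
                             config = catConfig(seed = 3)),
               "all items")
})

test_that("SEM falls monotonically as items accumulate at a fixed trait", {
  bank <- makeTestBank(15, seed = 48)
  # information additivity: SEM of a growing item set at fixed theta
  ids <- itemIds(bank)
  for (th in c(-1, 0.5, 2)) {
    sems <- vapply(seq_along(ids), function(k)
      1 / sqrt(testInformation(bank, th, items = ids[1:k]) + 1), numeric(1))
    expect_true(all(diff(sems) < 1e-12))
  }
})

test_that("cohort simulation is reproducible and threshold-ordered", {
  bank <- makeTestBank(15, seed = 49)
  set.seed(50)
  th <- rnorm(60)
  cfgA <- catConfig(estimator = "BME", semThreshold = 0.5, seed = 77)
  c1 <- simulateCat(bank, th, cfgA)
  c2 <- simulateCat(bank, th, cfgA)
  expect_identical(c1@summary, c2@summary)

  cfgB <- catConfig(estimator = "BME", semThreshold = 0.32, seed = 77)
  c3 <- simulateCat(bank, th, cfgB)
  expect_gte(c3@meanItems, c1@meanItems)
})

test_that("Fisher-z intervals match the analytic transform", {
  ci <- fisherZCI(0.916, 393)
  expect_equal(ci$lower, tanh(atanh(0.916) - 1.96 / sqrt(390)),
               tolerance = 1e-12)
  set.seed(51)
  x <- rnorm(100); y <- x + rnorm(100)
  p <- pccFisherCI(x, y)
  expect_equal(p$r, cor(x, y))
  expect_true(p$lower < p$r && p$r < p$upper)
  expect_warning(ciD <- fisherZCI(1, 50), "degenerate")
  expect_equal(ciD$lower, 1)
  expect_error(pccFisherCI(rep(1, 10), rnorm(10)), "variance")
  expect_error(pccFisherCI(1:3, 1:3), "n >= 4")
})
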