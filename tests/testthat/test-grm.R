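test_that("category probabilities match closed forms and sum to one", {
  # published-style item: at theta = b1 the cumulative P(X >= 2) is exactly 1/2
  p <- categoryProbs(3.32, c(0.93, 1.84, 2.32, 3.33), 0.93)
  expect_equal(1 - p[1, 1], 0.5, tolerance = 1e-12)
  # logistic closed form for a middle category
  p2 <- categoryProbs(2, c(-1, 0, 1, 2), 0)
  expect_equal(p2[1, 2], plogis(2) - plogis(0), tolerance = 1e-12)
  # tails
  expect_equal(categoryProbs(2, c(-1, 0, 1, 2), -40)[1, 1], 1)
  # probabilities valid and cumulative curves monotone for random items
  set.seed(2)
  for (r in 1:20) {
    a <- runif(1, 0.5, 4)
    b <- sort(rnorm(4, 0, 2))
    if (is.unsorted(b, strictly = TRUE)) next
    th <- seq(-6, 6, length.out = 41)
    p <- categoryProbs(a, b, th)
    expect_true(all(p >= 0))
    expect_equal(rowSums(p), rep(1, 41), tolerance = 1e-12)
    cum <- t(apply(p[, 5:1], 1, cumsum))[, 5:1]  # P(X >= k)
    for (k in 2:5) expect_true(all(diff(cum[, k]) >= -1e-12))
  }
})

test_that("analytic item information matches numerical differentiation", {
  set.seed(14)
  th <- seq(-5, 5, length.out = 21)
  h <- 1e-5
  for (r in 1:100) {
    a <- runif(1, 0.8, 3.5)
    b <- sort(runif(4, -3, 3.5))
    I <- itemInformation(a, b, th)
    num <- vapply(th, function(t) {
      pk <- function(t) categoryProbs(a, b, t)[1, ]
      d <- (pk(t + h) - pk(t - h)) / (2 * h)
      sum(d^2 / pk(t))
    }, numeric(1))
    expect_lt(max(abs(I - num)), 1e-4)
  }
  # symmetry for symmetric thresholds, decay in the tails
  Isym <- itemInformation(2, c(-1.5, -0.5, 0.5, 1.5), c(-2, 2))
  expect_equal(Isym[1], Isym[2], tolerance = 1e-10)
  expect_lt(itemInformation(2, c(-1, 0, 1, 2), 30), 1e-8)
  # additivity of test information
  bank <- makeTestBank(5, seed = 6)
  th0 <- c(-1, 0, 1)
  expect_equal(testInformation(bank, th0),
               Reduce(`+`, lapply(1:5, function(j)
                 itemInformation(bank@a[j], bank@thresholds[[j]], th0))))
})

test_that("category maximality scan finds never-modal categories", {
  expect_equal(categoryMaximality(3, c(0, 1, 2, 3)), integer(0))
  expect_equal(categoryMaximality(2, c(0, 0.1, 0.2, 3)), c(2L, 3L))
  expect_equal(categoryMaximality(1.7, 0.4), integer(0))  # 2 categories
})

test_that("EM calibration recovers generating parameters and is monotone", {
  dat <- makeTestData(J = 10, n = 1000, seedBank = 5, seedTheta = 6,
                      seedResp = 7)
  fit <- fitGRM(dat$responses)
  expect_true(fit@converged)
  # marginal log-likelihood never decreases across cycles
  expect_true(all(diff(fit@logLikHistory) > -1e-8 * abs(fit@logLik)))
  est <- calibratedBank(fit)
  expect_lt(sqrt(mean((est@a - dat$bank@a)^2)), 0.25)
  bt <- unlist(thresholds(dat$bank)); be <- unlist(thresholds(est))
  expect_lt(sqrt(mean((be - bt)^2)), 0.30)
})

test_that("items with unobserved categories are rejected before fitting", {
  dat <- makeTestData(J = 4, n = 60)
  X <- responseCodes(dat$responses)
  X[X[, 2] == 5L, 2] <- 4L
  expect_error(fitGRM(responseMatrix(X, nCategories = 5)),
               "I02.*category 5 unobserved")
})

test_that("EAP and MAP agree with a dense-grid brute-force oracle", {
  bank <- makeTestBank(12, seed = 8)
  set.seed(9)
  for (r in 1:25) {
    items <- sample(itemIds(bank), sample(3:10, 1))
    x <- drawPattern(bank[items], rnorm(1), seed = 100 + r)
    eap <- scoreTheta(x, bank, "EAP")
    map <- scoreTheta(x, bank, "BME")
    expect_lt(abs(eap$theta - bruteForceScore(x, bank, "EAP")), 1e-3)
    expect_lt(abs(map$theta - bruteForceScore(x, bank, "MAP")), 1e-3)
  }
})

test_that("scoring honors the estimator contracts", {
  bank <- makeTestBank(8, seed = 10)
  # zero answered items: Bayesian estimators return the prior
  none <- responseMatrix(
    matrix(NA_integer_, 1, 8, dimnames = list("p1", itemIds(bank))),
    nCategories = 5)
  for (m in c("BME", "EAP")) {
    s <- scoreTheta(none, bank, m)
    expect_equal(s$theta, 0)
    expect_equal(s$sem, 1)
  }
  # shrinkage: |BME| <= |MLE| for informative patterns off the boundary
  set.seed(11)
  for (r in 1:10) {
    x <- drawPattern(bank, runif(1, -1, 2), seed = 200 + r)
    mle <- scoreTheta(x, bank, "MLE")
    bme <- scoreTheta(x, bank, "BME")
    if (!mle$boundary) expect_lte(abs(bme$theta), abs(mle$theta) + 1e-8)
    # SEM contracts: MLE 1/sqrt(I), BME 1/sqrt(I+1)
    I_mle <- testInformation(bank, mle$theta)
    I_bme <- testInformation(bank, bme$theta)
    expect_equal(mle$sem, 1 / sqrt(I_mle), tolerance = 1e-8)
    expect_equal(bme$sem, 1 / sqrt(I_bme + 1), tolerance = 1e-8)
  }
  # all-lowest pattern drives the MLE to the support edge with a flag
  low <- setNames(rep(1L, 8), itemIds(bank))
  s <- scoreTheta(low, bank, "MLE")
  expect_true(s$boundary)
  expect_equal(s$theta, -6)
  # long informative patterns: the prior washes out
  big <- makeTestBank(60, seed = 12)
  x <- drawPattern(big, 0.8, seed = 13)
  ests <- vapply(c("MLE", "BME", "EAP"),
                 function(m) scoreTheta(x, big, m)$theta, numeric(1))
  expect_lt(diff(range(ests)), 0.05)
})

test_that("S-X2 is well-formed and powered against a non-graded item", {
  dat <- makeTestData(J = 8, n = 1000, seedBank = 21, seedTheta = 22,
                      seedResp = 23)
  fit <- fitGRM(dat$responses, llTol = 1e-5)
  sx <- sx2ItemFit(dat$responses, calibratedBank(fit))
  ok <- !is.na(sx$statistic)
  expect_true(all(sx$statistic[ok] >= 0))
  expect_true(all(sx$df[ok] >= 1))
  expect_true(all(sx$p[ok] >= 0 & sx$p[ok] <= 1))

  # plant one item whose data ignore the trait in the middle range
  X <- responseCodes(dat$responses)
  set.seed(24)
  mid <- abs(dat$thetas) < 1
  X[mid, 3] <- sample(1:5, sum(mid), replace = TRUE)
  bad <- responseMatrix(X, nCategories = 5)
  fit2 <- fitGRM(bad, llTol = 1e-5)
  sx2 <- sx2ItemFit(bad, calibratedBank(fit2))
  expect_true(sx2$flagged[3])
})

test_that("DIF likelihood-ratio tests behave under null and alternative", {
  dat <- makeTestData(J = 6, n = 600, seedBank = 31, seedTheta = 32,
                      seedResp = 33)
  g <- factor(rep(c("ref", "foc"), length.out = 600),
              levels = c("ref", "foc"))
  dd <- difTest(dat$responses, g, tol = 1e-3, llTol = 1e-5)
  expect_true(all(dd$LR >= 0))
  expect_true(all(dd$df == 5))
  expect_true(all(!dd$flagged))          # true null at alpha = 0.01

  # planted threshold shift must be caught
  v <- injectViolations(dat$bank, dat$responses, dat$thetas,
                        kinds = "dif", items = list(dif = "I04"),
                        seed = 34, difShift = 0.8)
  dv <- difTest(v$responses, v$groups, tol = 1e-3, llTol = 1e-5)
  expect_true(dv$flagged[dv$item == "I04"])

  expect_error(difTest(dat$responses, factor(rep("x", 600))), "2 levels")
  expect_error(difTest(dat$responses[1:40, ],
                       factor(rep(c("a", "b"), 20))), ">= 30")
})
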