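makeJoint <- function(nAnchor = 12, nLegacy = 5, n = 400, seed = 60) {
  anchors <- makeTestBank(nAnchor, seed = seed)
  set.seed(seed + 1)
  legacy <- itemBank(
    sprintf("L%d", seq_len(nLegacy)),
    a = runif(nLegacy, 1.2, 2.4),
    thresholds = lapply(seq_len(nLegacy), function(j)
      runif(1, -1.5, 0) + cumsum(c(0, runif(2, 0.8, 1.2)))),
    offset = 1L)
  set.seed(seed + 2)
  th <- rnorm(n)
  ra <- simulateResponses(anchors, th, seed = seed + 3)
  rl <- simulateResponses(legacy, th, seed = seed + 4)
  joint <- responseMatrix(cbind(responseCodes(ra), responseCodes(rl)),
                          nCategories = c(rep(5, nAnchor), rep(4, nLegacy)),
                          offset = c(rep(0L, nAnchor), rep(1L, nLegacy)))
  list(anchors = anchors, legacy = legacy, thetas = th, joint = joint,
       anchorResponses = ra, legacyResponses = rl)
}

test_that("fixed calibration leaves anchors untouched and recovers legacy items", {
  d <- makeJoint()
  fc <- fixedCalibrate(d$joint, d$anchors, itemIds(d$legacy))
  expect_identical(thresholds(fc@anchorBank), thresholds(d$anchors))
  expect_identical(discrimination(fc@anchorBank), discrimination(d$anchors))
  lb <- fc@legacyBank
  expect_lt(sqrt(mean((lb@a - d$legacy@a)^2)), 0.3)
  expect_lt(sqrt(mean((unlist(thresholds(lb)) -
                         unlist(thresholds(d$legacy)))^2)), 0.3)
})

test_that("fixed calibration is idempotent against the joint fit", {
  # anchors fixed at the joint MML solution: the legacy optimum must be the
  # joint solution itself (scale coherence)
  d <- makeJoint(nAnchor = 8, nLegacy = 3, n = 500, seed = 70)
  full <- fitGRM(d$joint, tol = 1e-5)
  fb <- calibratedBank(full)
  fc <- fixedCalibrate(d$joint, fb[itemIds(d$anchors)],
                       itemIds(d$legacy), tol = 1e-5)
  jointLegacy <- fb[itemIds(d$legacy)]
  expect_lt(max(abs(fc@legacyBank@a - jointLegacy@a)), 1e-3)
  expect_lt(max(abs(unlist(thresholds(fc@legacyBank)) -
                      unlist(thresholds(jointLegacy)))), 1e-3)
})

test_that("trait-independent legacy items calibrate to near-zero slopes", {
  d <- makeJoint(nAnchor = 10, nLegacy = 3, n = 1000, seed = 80)
  X <- responseCodes(d$joint)
  set.seed(81)
  for (id in itemIds(d$legacy)) {
    X[, id] <- sample(1:4, nrow(X), replace = TRUE)
  }
  noisy <- responseMatrix(X, nCategories = d$joint@nCategories,
                          offset = d$joint@offset)
  fc <- fixedCalibrate(noisy, d$anchors, itemIds(d$legacy))
  expect_true(all(fc@legacyBank@a < 0.3))
})

test_that("fixed-form SEM curves obey the BME information identity", {
  d <- makeJoint()
  crv <- fixedFormSemCurve(d$legacyResponses, d$legacy, itemIds(d$legacy))
  sc <- scoreTheta(d$legacyResponses, d$legacy, "BME")
  ident <- 1 / sqrt(testInformation(d$legacy, sc$theta) + 1)
  expect_equal(crv@points$sem, ident, tolerance = 1e-6)
  expect_true(all(crv@smoothed$sem > 0))
  expect_error(fixedFormSemCurve(d$legacyResponses, d$legacy, character(0)),
               "empty")
})

test_that("fixed-length CATs use exactly the requested items and stack by length", {
  d <- makeJoint(nAnchor = 14, n = 150, seed = 90)
  grid <- seq(-2, 2, length.out = 40)
  f4 <- fixedLengthCatSem(d$anchors, d$thetas[1:150], 4,
                          config = catConfig(seed = 5), commonGrid = grid)
  f8 <- fixedLengthCatSem(d$anchors, d$thetas[1:150], 8,
                          config = catConfig(seed = 5), commonGrid = grid)
  expect_true(all(f4$cohort@summary$nItems == 4))
  expect_true(all(f8$cohort@summary$nItems == 8))
  # more items, no worse precision (within smoothing error)
  expect_true(all(f8$curve@smoothed$sem <=
                    f4$curve@smoothed$sem + 0.02))
})

test_that("lowess smoothing is exact on flats and lines and matches a hand-rolled oracle", {
  x <- seq(-3, 3, length.out = 60)
  expect_equal(lowessSmooth(x, rep(2, 60), grid = x), rep(2, 60),
               tolerance = 1e-9)
  expect_equal(lowessSmooth(x, 1.5 * x - 1, grid = x), 1.5 * x - 1,
               tolerance = 1e-6)
  expect_error(lowessSmooth(x, x, span = 1.5), "span")
  expect_error(lowessSmooth(1:5, 1:5), ">= 10")

  # independent oracle: direct tricube-weighted local linear regression
  set.seed(91)
  xs <- sort(runif(80, -2, 2))
  ys <- sin(xs) + rnorm(80, 0, 0.1)
  span <- 2 / 3
  k <- floor(span * length(xs))
  oracle <- vapply(xs, function(x0) {
    d <- abs(xs - x0)
    h <- sort(d)[k]
    w <- (1 - pmin(d / h, 1)^3)^3
    fit <- lm.wfit(cbind(1, xs - x0), ys, w)
    fit$coefficients[1]
  }, numeric(1))
  got <- lowessSmooth(xs, ys, span = span, grid = xs)
  expect_lt(max(abs(got - oracle)), 1e-3)
})

test_that("precision dominance compares curves node by node", {
  g <- seq(-2, 2, length.out = 20)
  mk <- function(sem, label) new("SemCurve",
                                 points = data.frame(theta = g, sem = sem),
                                 smoothed = data.frame(theta = g, sem = sem),
                                 label = label)
  a <- mk(rep(0.3, 20), "a"); b <- mk(rep(0.5, 20), "b")
  expect_true(precisionDominance(a, b)$dominates)
  same <- precisionDominance(a, a)
  expect_false(same$dominates)
  expect_true(all(same$margin == 0))
  # crossing curves are flagged with the crossing node
  cr <- mk(c(rep(0.2, 10), rep(0.6, 10)), "cross")
  res <- precisionDominance(cr, mk(rep(0.4, 20), "flat"))
  expect_false(res$dominates)
  expect_length(res$crossings, 1L)
  gg <- new("SemCurve", points = data.frame(theta = 1:21, sem = 1:21),
            smoothed = data.frame(theta = seq(0, 2, length.out = 21),
                                  sem = rep(1, 21)), label = "other")
  expect_error(precisionDominance(a, gg), "same grid")
})
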