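test_that("Cronbach's alpha matches hand computation and its invariances", {
  # two perfectly correlated items: variances 1 + 1, total variance 4
  m <- matrix(c(1, 2, 2, 3, 3, 4), ncol = 2, byrow = TRUE,
              dimnames = list(paste0("p", 1:3), c("A", "B")))
  expect_equal(cronbachAlpha(m), 1.0)
  # k copies of one item
  m2 <- matrix(rep(c(1, 3, 2, 5), 4), ncol = 4,
               dimnames = list(paste0("p", 1:4), paste0("I", 1:4)))
  expect_equal(cronbachAlpha(m2), 1.0)
  # order invariance and shift invariance
  dat <- makeTestData(J = 6, n = 80)
  X <- responseCodes(dat$responses)
  a0 <- cronbachAlpha(X)
  expect_equal(cronbachAlpha(X[, sample(ncol(X))]), a0)
  expect_equal(cronbachAlpha(X + 7), a0)
  # independent items: alpha near zero
  set.seed(31)
  Xind <- matrix(sample(1:5, 5 * 5000, replace = TRUE), ncol = 5,
                 dimnames = list(NULL, paste0("I", 1:5)))
  expect_lt(abs(cronbachAlpha(Xind)), 0.05)
  expect_error(cronbachAlpha(matrix(1, 4, 3)), "variance")
})

test_that("item-remainder correlations flag weak items with a strict rule", {
  dat <- makeTestData(J = 8, n = 3000)
  X <- responseCodes(dat$responses)
  # replace one item by pure noise: near-zero remainder correlation
  set.seed(8)
  X[, 4] <- sample(1:5, nrow(X), replace = TRUE)
  rm <- responseMatrix(X, nCategories = 5)
  irc <- itemRemainderCorrelations(rm)
  expect_true(irc$flagged[4])
  expect_lt(abs(irc$r[4]), 0.1)
  expect_true(all(!irc$flagged[-4]))
  # the rule is strictly "< threshold": boundary value retained
  ircB <- itemRemainderCorrelations(rm, minR = irc$r[4])
  expect_false(ircB$flagged[4])
})

test_that("unanswered categories are detected per item", {
  m <- matrix(c(1, 2, 3, 1, 2, 3, NA, NA, NA, NA, NA, NA), ncol = 2,
              dimnames = list(paste0("p", 1:6), c("A", "B")))
  rm <- responseMatrix(m, nCategories = 5)
  ua <- unansweredCategories(rm)
  expect_equal(ua$unused$A, c(4L, 5L))
  expect_equal(ua$unused$B, 1:5)
  dat <- makeTestData(J = 4, n = 2000)
  expect_true(all(lengths(unansweredCategories(dat$responses)$unused) == 0))
})

test_that("PCA criteria reproduce closed-form eigenvalue cases", {
  cfg <- screeningConfig()
  # identity correlation, p = 10: all eigenvalues 1
  I10 <- diag(10)
  r1 <- pcaUnidimensionality(I10, cfg)
  expect_equal(r1$proportions[1], 0.1, tolerance = 1e-8)
  expect_false(r1$pass)
  # the exclusion loop strictly decreases the set and stops at the floor
  expect_length(r1$excluded, 7L)
  # compound symmetry rho = 0.64, p = 10: eigenvalues 1 + 9*rho and 1 - rho
  CS <- matrix(0.64, 10, 10); diag(CS) <- 1
  r2 <- pcaUnidimensionality(CS, cfg)
  expect_equal(r2$proportions[1], 6.76 / 10, tolerance = 1e-8)
  expect_equal(r2$proportions[1] / r2$proportions[2], 6.76 / 0.36,
               tolerance = 1e-6)
  expect_true(r2$pass)
  expect_equal(sum(r2$proportions), 1, tolerance = 1e-8)
})

test_that("PCA exclusion loop drops the weakest-loading item and stops", {
  # one factor plus two pure-noise items; iterative exclusion removes noise
  dat <- makeTestData(J = 8, n = 1200)
  X <- responseCodes(dat$responses)
  set.seed(19)
  X[, 7] <- sample(1:5, nrow(X), replace = TRUE)
  X[, 8] <- sample(1:5, nrow(X), replace = TRUE)
  rm <- responseMatrix(X, nCategories = 5)
  res <- pcaUnidimensionality(rm, screeningConfig())
  expect_true(res$pass)
  expect_true(all(res$excluded %in% c("I07", "I08")))
})

test_that("one-factor residuals are small for clean data and catch planted dependence", {
  dat <- makeTestData(J = 10, n = 2000)
  rc <- residualCorrelations(dat$responses)
  off <- rc$residuals[upper.tri(rc$residuals)]
  expect_lt(max(abs(off)), 0.05)
  expect_equal(nrow(rc$flaggedPairs), 0L)

  v <- injectViolations(dat$bank, dat$responses, dat$thetas,
                        kinds = "local_dependence",
                        items = list(local_dependence = "I03"), seed = 21)
  rc2 <- residualCorrelations(v$responses)
  expect_gt(nrow(rc2$flaggedPairs), 0L)
  expect_true(any(rc2$flaggedPairs$item1 == "I03" &
                    rc2$flaggedPairs$item2 == "I04"))
})

test_that("Loevinger H is 1 for Guttman data, ~0 for independence, symmetric", {
  # perfect Guttman-ordered polytomous data: comonotone items
  base <- c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5)
  m <- cbind(A = base, B = pmin(base + 1, 5), C = rep(1:5, each = 2))
  rownames(m) <- paste0("p", 1:10)
  mk <- mokkenScalability(responseMatrix(m, nCategories = 5))
  expect_true(all(abs(mk$Hi$H - 1) < 1e-12))
  expect_equal(mk$Hij, t(mk$Hij))

  set.seed(77)
  ind <- matrix(sample(1:5, 4 * 8000, replace = TRUE), ncol = 4,
                dimnames = list(NULL, paste0("I", 1:4)))
  mkI <- mokkenScalability(responseMatrix(ind, nCategories = 5))
  expect_lt(max(abs(mkI$Hi$H)), 0.05)

  # monotone graded-model data scales well
  dat <- makeTestData(J = 8, n = 400)
  mkG <- mokkenScalability(dat$responses)
  expect_true(all(mkG$Hi$H > 0.3))
})

test_that("the screening funnel chains counts and attributes exclusions", {
  dat <- makeTestData(J = 12, n = 600)
  v <- injectViolations(dat$bank, dat$responses, dat$thetas,
                        kinds = c("nonmonotone", "local_dependence"),
                        items = list(nonmonotone = "I09",
                                     local_dependence = "I02"),
                        seed = 13)
  scr <- runScreening(v$responses)
  at <- auditTable(scr$audit)
  expect_true(all(at$entering - at$excluded == at$surviving))
  expect_equal(at$entering[-1], at$surviving[-nrow(at)])
  excl <- auditExclusions(scr$audit)
  # the unimodal item must fall at a pre-model stage (weak/negative
  # item-remainder correlation or poor scalability), not survive
  expect_false("I09" %in% scr$surviving)
  # one member of the dependent pair is excluded at the residual stage
  resStage <- excl$item[excl$stage == "residual_correlations"]
  expect_true(any(c("I02", "I03") %in% resStage))

  # clean data: assumption-level stages exclude nothing
  scrClean <- runScreening(dat$responses)
  atc <- auditTable(scrClean$audit)
  expect_true(all(atc$excluded[atc$stage %in%
    c("pca_unidimensionality", "residual_correlations",
      "scalability")] == 0))
})

test_that("screening errors once the bank is exhausted", {
  set.seed(5)
  noise <- matrix(sample(1:5, 4 * 200, replace = TRUE), ncol = 4,
                  dimnames = list(NULL, paste0("I", 1:4)))
  expect_error(runScreening(responseMatrix(noise, nCategories = 5)),
               "bank exhausted")
})
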