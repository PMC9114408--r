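# Fixtures built in code.  Test banks use well-separated thresholds so all
# categories carry mass at moderate n; study-like cohorts come from the
# package's own generator.

# J items, K categories, spread thresholds; reproducible
makeTestBank <- function(J, seed = 1, K = 5, aRange = c(1.5, 2.8),
                         b1Range = c(-2.2, -1), gapRange = c(0.6, 1.1)) {
  set.seed(seed)
  a <- runif(J, aRange[1], aRange[2])
  b <- lapply(seq_len(J), function(j) {
    runif(1, b1Range[1], b1Range[2]) +
      cumsum(c(0, runif(K - 2, gapRange[1], gapRange[2])))
  })
  itemBank(sprintf("I%02d", seq_len(J)), a = a, thresholds = b)
}

# standard-normal cohort answering a test bank
makeTestData <- function(J = 10, n = 500, seedBank = 1, seedTheta = 2,
                         seedResp = 3, ...) {
  bank <- makeTestBank(J, seed = seedBank, ...)
  set.seed(seedTheta)
  thetas <- rnorm(n)
  resp <- simulateResponses(bank, thetas, seed = seedResp)
  list(bank = bank, thetas = thetas, responses = resp)
}

# single response pattern drawn from the model at theta
drawPattern <- function(bank, theta, seed) {
  set.seed(seed)
  x <- vapply(seq_len(nItems(bank)), function(j) {
    p <- categoryProbs(bank@a[j], bank@thresholds[[j]], theta)[1, ]
    sample.int(length(p), 1, prob = p)
  }, integer(1))
  names(x) <- itemIds(bank)
  x
}

# brute-force EAP/MAP oracle on a dense grid (independent of the package's
# scoring path: plain sums and a parabolic refinement of the grid argmax)
bruteForceScore <- function(x, bank, method, nNodes = 2001) {
  fine <- seq(-6, 6, length.out = nNodes)
  w <- dnorm(fine); w <- w / sum(w)
  ll <- rep(0, nNodes)
  for (id in names(x)) {
    j <- match(id, itemIds(bank))
    ll <- ll + log(categoryProbs(bank@a[j], bank@thresholds[[j]],
                                 fine)[, x[[id]]])
  }
  if (method == "EAP") {
    post <- exp(ll - max(ll)) * w
    post <- post / sum(post)
    sum(post * fine)
  } else {
    lp <- ll - fine^2 / 2
    i0 <- which.max(lp)
    if (i0 == 1 || i0 == nNodes) return(fine[i0])
    y <- lp[(i0 - 1):(i0 + 1)]
    h <- fine[2] - fine[1]
    fine[i0] + h * (y[1] - y[3]) / (2 * (y[1] - 2 * y[2] + y[3]))
  }
}
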