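## Likelihood-ratio tests of differential item functioning (DIF) between two
## groups.  Baseline model: all item parameters equal across groups, focal
## group latent mean and variance free (reference fixed at N(0,1), the usual
## identification).  The augmented model for the studied item additionally
## frees that item's discrimination and thresholds in the focal group; all
## other items act as anchors (no purification).  LR = 2 * (logL1 - logL0),
## df = number of freed parameters.

## Two-group EM.  split = index of the item with group-specific parameters
## (0 = none).  Warm starts via `start` (transform-space list) and
## `startSplit` (focal-group params of the split item).
.grmFitCore2 <- function(Xr, Xf, K, nodes, wts0, tol = 1e-4,
                         maxCycles = 200L, llTol = 1e-6, start,
                         split = 0L, startSplit = NULL, mu0 = 0, sd0 = 1) {
  J <- ncol(Xr)
  pars <- start
  parsF <- startSplit                                # focal params of split
  mu <- mu0; sdv <- sd0
  logw_r <- log(wts0)
  logPr <- vector("list", J)
  logPf <- vector("list", J)
  mkLogP <- function(par) {
    ab <- .par2ab(par)
    t(log(pmax(categoryProbs(ab$a, ab$b, nodes), .PFLOOR)))
  }
  for (j in seq_len(J)) logPr[[j]] <- logPf[[j]] <- mkLogP(pars[[j]])
  if (split > 0L && !is.null(parsF)) logPf[[split]] <- mkLogP(parsF)
  ll_prev <- -Inf
  converged <- FALSE
  cycle <- 0L
  ll <- NA_real_
  while (cycle < maxCycles) {
    cycle <- cycle + 1L
    wf <- dnorm(nodes, mu, sdv); wf <- wf / sum(wf)
    er <- .estep(Xr, logPr, logw_r)
    ef <- .estep(Xf, logPf, log(wf))
    ll <- er$logLik + ef$logLik
    delta <- 0
    for (j in seq_len(J)) {
      rr <- .expectedCounts(Xr[, j], K[j], er$post)
      rf <- .expectedCounts(Xf[, j], K[j], ef$post)
      if (j == split) {
        newR <- .mstepItem(rr, nodes, pars[[j]])
        pf0 <- if (is.null(parsF)) pars[[j]] else parsF
        newF <- .mstepItem(rf, nodes, pf0)
        delta <- max(delta, abs(unlist(.par2ab(newR)) -
                                  unlist(.par2ab(pars[[j]]))),
                     abs(unlist(.par2ab(newF)) - unlist(.par2ab(pf0))))
        pars[[j]] <- newR; parsF <- newF
        logPr[[j]] <- mkLogP(newR); logPf[[j]] <- mkLogP(newF)
      } else {
        new <- .mstepItem(rr + rf, nodes, pars[[j]])
        delta <- max(delta, abs(unlist(.par2ab(new)) -
                                  unlist(.par2ab(pars[[j]]))))
        pars[[j]] <- new
        logPr[[j]] <- logPf[[j]] <- mkLogP(new)
      }
    }
    m1 <- mean(ef$post %*% nodes)
    m2 <- mean(ef$post %*% nodes^2)
    muNew <- m1; sdNew <- sqrt(max(m2 - m1^2, 1e-4))
    delta <- max(delta, abs(muNew - mu), abs(sdNew - sdv))
    mu <- muNew; sdv <- sdNew
    if (delta < tol || (ll - ll_prev < llTol && cycle > 1L)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  ## final log-likelihood at the updated parameters
  wf <- dnorm(nodes, mu, sdv); wf <- wf / sum(wf)
  er <- .estep(Xr, logPr, logw_r)
  ef <- .estep(Xf, logPf, log(wf))
  list(pars = pars, parsF = parsF, mu = mu, sd = sdv,
       logLik = er$logLik + ef$logLik, cycles = cycle,
       converged = converged)
}

#' Likelihood-ratio DIF tests
#'
#' One-at-a-time likelihood-ratio tests of differential item functioning
#' between two groups (e.g. age >= 65 versus < 65, or male versus female).
#' See the package vignette for the model details.
#'
#' @param responses a [ResponseMatrix-class].
#' @param groups factor (or coercible) of length \code{nPersons(responses)}
#'   with exactly two levels; the first level is the reference group.
#' @param alpha flag threshold (default 0.01).
#' @param items item ids to test (default: all).
#' @param grid quadrature from [quadratureGrid()].
#' @param tol,llTol,maxCycles EM controls; convergence on parameter change
#'   or on the per-cycle log-likelihood gain, whichever comes first
#'   (likelihood-ratio statistics need likelihood precision, not parameter
#'   precision).
#' @return data.frame with columns item, LR, df, p, flagged.  Items whose
#'   categories are unobserved in either group are skipped (NA) with a
#'   warning.
#' @export
difTest <- function(responses, groups, alpha = 0.01, items = NULL,
                    grid = quadratureGrid(), tol = 1e-4, llTol = 1e-6,
                    maxCycles = 200L) {
  X <- responseCodes(responses)
  K <- responses@nCategories
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) .stopf("groups must have exactly 2 levels")
  if (length(groups) != nrow(X)) .stopf("one group label per person")
  if (any(table(groups) < 30L)) {
    .stopf("each group needs >= 30 persons for a stable two-group fit")
  }
  Xr <- X[groups == levels(groups)[1L], , drop = FALSE]
  Xf <- X[groups == levels(groups)[2L], , drop = FALSE]
  .checkObservedCategories(X, K, colnames(X))        # pooled identification
  if (is.null(items)) items <- colnames(X)
  nodes <- grid$nodes; wts <- grid$weights
  start <- lapply(seq_len(ncol(X)), function(j) .itemStart(X[, j], K[j]))
  base <- .grmFitCore2(Xr, Xf, K, nodes, wts, tol = tol, llTol = llTol,
                       maxCycles = maxCycles, start = start)
  res <- data.frame(item = items, LR = NA_real_, df = NA_real_,
                    p = NA_real_, flagged = NA, stringsAsFactors = FALSE)
  for (ii in seq_along(items)) {
    j <- match(items[ii], colnames(X))
    if (is.na(j)) .stopf("unknown item '%s'", items[ii])
    cntR <- tabulate(Xr[!is.na(Xr[, j]), j], nbins = K[j])
    cntF <- tabulate(Xf[!is.na(Xf[, j]), j], nbins = K[j])
    if (any(cntR == 0L) || any(cntF == 0L)) {
      .warnf("DIF: item '%s' skipped (category unobserved in one group)",
             items[ii])
      next
    }
    aug <- .grmFitCore2(Xr, Xf, K, nodes, wts, tol = tol, llTol = llTol,
                        maxCycles = maxCycles, start = base$pars,
                        split = j, startSplit = base$pars[[j]],
                        mu0 = base$mu, sd0 = base$sd)
    lr <- max(0, 2 * (aug$logLik - base$logLik))
    df <- K[j]                                      # a + (K-1) thresholds
    res$LR[ii] <- lr
    res$df[ii] <- df
    res$p[ii] <- pchisq(lr, df, lower.tail = FALSE)
    res$flagged[ii] <- res$p[ii] < alpha
  }
  res
}
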