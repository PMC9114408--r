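## Marginal maximum likelihood estimation of the graded response model.
##
## The latent density is fixed at N(0,1) (standard identification for a
## single group) and discretized on a quadrature grid.  The E-step computes
## per-person posterior weights over the nodes; the M-step maximizes each
## item's expected complete-data log-likelihood by quasi-Newton ascent with
## analytic gradients, in an unconstrained parameterization
## (log a, b1, log successive threshold gaps) that enforces a > 0 and
## strictly increasing thresholds by construction.

## par <-> (a, b) transform -------------------------------------------------

.par2ab <- function(par) {
  a <- exp(par[1L])
  b <- par[2L] + cumsum(c(0, exp(par[-(1:2)])))
  list(a = a, b = b)
}

.ab2par <- function(a, b) {
  d <- diff(b)
  c(log(a), b[1L], if (length(d)) log(pmax(d, 1e-8)))
}

## One M-step: maximize the item's expected complete-data log-likelihood
## (r: K x Q expected counts) by quasi-Newton ascent with an analytic
## gradient.  The logistic pieces are cached between the objective and
## gradient calls nlminb makes at the same parameter value.
.mstepItem <- function(r, nodes, par0) {
  K <- nrow(r)
  rq <- t(r)                                        # Q x K
  Q <- length(nodes)
  k1 <- seq_len(K - 1L)
  cache <- new.env(parent = emptyenv())
  compute <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(invisible())
    a <- exp(par[1L])
    b <- par[2L] + cumsum(c(0, exp(par[-(1:2)])))
    C <- plogis(a * (nodes - rep(b, each = Q)))
    dim(C) <- c(Q, K - 1L)
    p <- cbind(1, C) - cbind(C, 0)
    p[p < .PFLOOR] <- .PFLOOR
    cache$par <- par; cache$a <- a; cache$b <- b
    cache$C <- C; cache$p <- p
    invisible()
  }
  obj <- function(par) {
    compute(par)
    -sum(rq * log(cache$p))
  }
  gr <- function(par) {
    compute(par)
    a <- cache$a; b <- cache$b; C <- cache$C
    ratio <- rq / cache$p
    ## dL/dC_m = -r_m/p_m + r_{m+1}/p_{m+1} per node, m = 1..K-1
    dLdC <- ratio[, k1 + 1L, drop = FALSE] - ratio[, k1, drop = FALSE]
    V <- C * (1 - C)
    dLda <- sum(dLdC * (nodes - rep(b, each = Q)) * V)
    dLdb <- -a * colSums(dLdC * V)
    g <- numeric(length(par))
    g[1L] <- a * dLda
    g[2L] <- sum(dLdb)
    if (K > 2L) {
      csum <- rev(cumsum(rev(dLdb)))                # sum_{m >= t} dL/db_m
      g[2L + seq_len(K - 2L)] <- exp(par[2L + seq_len(K - 2L)]) * csum[-1L]
    }
    -g
  }
  fit <- nlminb(par0, obj, gradient = gr,
                lower = c(-4.6, -30, rep(-12, K - 2L)),
                upper = c(3, 30, rep(4, K - 2L)),
                control = list(iter.max = 100L))
  fit$par
}

## Starting values from marginal category proportions (a = 1).
.itemStart <- function(x, K) {
  counts <- tabulate(x[!is.na(x)], nbins = K) + 0.5   # mild smoothing
  q <- rev(cumsum(rev(counts)))[-1L] / sum(counts)    # P(X >= k+1)
  .ab2par(1, -qlogis(q))
}

## E-step quantities.  X: n x J integer matrix (NA allowed); logP: list of
## K x Q log-probability matrices.  Returns posterior (n x Q, rows sum 1)
## and the marginal log-likelihood.
.estep <- function(X, logP, logw) {
  n <- nrow(X); Q <- length(logw)
  L <- matrix(logw, n, Q, byrow = TRUE)
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ok <- !is.na(x)
    L[ok, ] <- L[ok, ] + logP[[j]][x[ok], , drop = FALSE]
  }
  mx <- apply(L, 1L, max)
  W <- exp(L - mx)
  rs <- rowSums(W)
  list(post = W / rs, logLik = sum(log(rs) + mx))
}

## Expected counts for one item: K x Q.
.expectedCounts <- function(x, K, post) {
  r <- matrix(0, K, ncol(post))
  for (k in seq_len(K)) {
    idx <- which(!is.na(x) & x == k)
    if (length(idx)) r[k, ] <- colSums(post[idx, , drop = FALSE])
  }
  r
}

## Core EM loop shared by fitGRM() and fixedCalibrate().  `update` marks the
## items whose parameters move; the rest stay fixed (anchors).
.grmFitCore <- function(X, K, nodes, wts, tol = 1e-4, maxCycles = 500L,
                        llTol = NULL, start, update = NULL) {
  J <- ncol(X)
  if (is.null(update)) update <- rep(TRUE, J)
  pars <- start                                     # list of transform-space
  logw <- log(wts)
  logP <- vector("list", J)
  refresh <- function(j) {
    ab <- .par2ab(pars[[j]])
    t(log(pmax(categoryProbs(ab$a, ab$b, nodes), .PFLOOR)))
  }
  for (j in seq_len(J)) logP[[j]] <- refresh(j)
  hist <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  cycle <- 0L
  while (cycle < maxCycles) {
    cycle <- cycle + 1L
    es <- .estep(X, logP, logw)
    hist <- c(hist, es$logLik)
    delta <- 0
    for (j in which(update)) {
      r <- .expectedCounts(X[, j], K[j], es$post)
      newpar <- .mstepItem(r, nodes, pars[[j]])
      old <- .par2ab(pars[[j]]); new <- .par2ab(newpar)
      delta <- max(delta, abs(new$a - old$a), max(abs(new$b - old$b)))
      pars[[j]] <- newpar
      logP[[j]] <- refresh(j)
    }
    if (delta < tol ||
        (!is.null(llTol) && es$logLik - ll_prev < llTol && cycle > 1L)) {
      converged <- TRUE
      break
    }
    ll_prev <- es$logLik
  }
  es <- .estep(X, logP, logw)                       # log-lik at final params
  hist <- c(hist, es$logLik)
  list(pars = pars, logLik = es$logLik, history = hist, cycles = cycle,
       converged = converged, post = es$post)
}

.checkObservedCategories <- function(X, K, ids) {
  for (j in seq_len(ncol(X))) {
    cnt <- tabulate(X[!is.na(X[, j]), j], nbins = K[j])
    if (any(cnt == 0L)) {
      .stopf("item '%s': category %d unobserved; exclude it before fitting",
             ids[j], which(cnt == 0L)[1L])
    }
  }
}

#' Fit a graded response model by marginal maximum likelihood (EM)
#'
#' The latent trait is fixed at N(0,1); item parameters are estimated by an
#' EM algorithm whose M-step maximizes each item's expected complete-data
#' log-likelihood.  Missing responses are marginalized out of the
#' likelihood.  Items with unobserved categories are rejected (their
#' parameters are not identifiable) and must be screened out first.
#'
#' @param responses a [ResponseMatrix-class].
#' @param grid quadrature from [quadratureGrid()].
#' @param tol convergence tolerance on the maximum absolute change of any
#'   item parameter between cycles (default 1e-4).
#' @param maxCycles EM cycle cap (default 500); hitting it flags
#'   non-convergence without raising.
#' @param llTol optional additional stop rule on the marginal log-likelihood
#'   gain per cycle; useful when only likelihood values are needed (e.g.
#'   inside likelihood-ratio tests).
#' @param start optional [ItemBank-class] of starting values.
#' @return A [GRMFit-class].
#' @examples
#' spec <- cohortSpec(nPersons = 200, nItems = 5, seed = 7)
#' gb <- generateBank(spec)
#' th <- drawThetas(spec)
#' rm <- simulateResponses(gb$bank, th, seed = 8)
#' fit <- fitGRM(rm, maxCycles = 50)
#' @export
fitGRM <- function(responses, grid = quadratureGrid(), tol = 1e-4,
                   maxCycles = 500L, llTol = NULL, start = NULL) {
  X <- responseCodes(responses)
  K <- responses@nCategories
  if (nrow(X) < 2L || ncol(X) < 1L) .stopf("need >= 2 persons and >= 1 item")
  .checkObservedCategories(X, K, colnames(X))
  startPars <- if (is.null(start)) {
    lapply(seq_len(ncol(X)), function(j) .itemStart(X[, j], K[j]))
  } else {
    idx <- match(colnames(X), itemIds(start))
    if (anyNA(idx)) .stopf("start bank is missing some items")
    lapply(idx, function(j) .ab2par(start@a[j], start@thresholds[[j]]))
  }
  core <- .grmFitCore(X, K, grid$nodes, grid$weights, tol = tol,
                      maxCycles = maxCycles, llTol = llTol,
                      start = startPars)
  ab <- lapply(core$pars, .par2ab)
  bank <- itemBank(colnames(X),
                   a = vapply(ab, `[[`, numeric(1), "a"),
                   thresholds = lapply(ab, `[[`, "b"),
                   offset = responses@offset)
  new("GRMFit", bank = bank, logLik = core$logLik,
      logLikHistory = core$history, cycles = core$cycles,
      converged = core$converged)
}

setMethod("show", "GRMFit", function(object) {
  cat(sprintf("GRMFit: %d item(s), logLik %.3f, %d EM cycle(s), %s\n",
              nItems(object@bank), object@logLik, object@cycles,
              if (object@converged) "converged" else "NOT converged"))
  invisible(object)
})

#' @describeIn fitGRM extract the calibrated bank from a fit
#' @param fit a [GRMFit-class].
#' @export
calibratedBank <- function(fit) {
  stopifnot(is(fit, "GRMFit"))
  fit@bank
}
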