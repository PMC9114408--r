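## Adaptive-testing simulation: estimator x selector x termination grid.

#' Configuration of a CAT session
#'
#' @param estimator "MLE", "BME" or "EAP".
#' @param selector "UW-FI" (unweighted Fisher information at the current
#'   estimate) or "FP-KL" (symmetrized pointwise Kullback-Leibler divergence
#'   between the item's category distributions at the current estimate
#'   +/- \code{klDelta}).
#' @param semThreshold stop once the SEM falls to this value or below
#'   (after \code{minItems}); \code{NA} disables the rule (fixed-length
#'   mode).  Typical values: 0.32 (reliability about 0.90) and 0.50
#'   (about 0.75).
#' @param minItems minimum number of items administered (default 3).
#' @param maxItems maximum (default NA = the bank size).
#' @param startTheta initial trait estimate used to select the first item
#'   (default 0).
#' @param klDelta FP-KL offset (default 0.1).
#' @param seed master seed for response generation (per-simulee substreams
#'   are derived from it, so cohort results are order-independent).
#' @return validated list of class "CatConfig".
#' @export
catConfig <- function(estimator = c("BME", "MLE", "EAP"),
                      selector = c("UW-FI", "FP-KL"),
                      semThreshold = 0.5, minItems = 3L, maxItems = NA,
                      startTheta = 0, klDelta = 0.1, seed = 1L) {
  estimator <- match.arg(estimator)
  selector <- match.arg(selector)
  if (!is.na(semThreshold) && semThreshold <= 0) {
    .stopf("semThreshold must be positive (or NA for fixed-length mode)")
  }
  stopifnot(.is_count(minItems), minItems >= 1)
  if (!is.na(maxItems) && maxItems < minItems) {
    .stopf("minItems must not exceed maxItems")
  }
  stopifnot(is.finite(startTheta), klDelta > 0)
  structure(list(estimator = estimator, selector = selector,
                 semThreshold = semThreshold,
                 minItems = as.integer(minItems), maxItems = maxItems,
                 startTheta = startTheta, klDelta = klDelta,
                 seed = as.integer(seed)),
            class = "CatConfig")
}

#' Select the next item
#'
#' UW-FI picks the unadministered item with maximal Fisher information at
#' the current trait estimate; FP-KL picks the one with maximal symmetrized
#' Kullback-Leibler divergence between its category distributions at
#' \code{thetaEst - klDelta} and \code{thetaEst + klDelta} (for small delta
#' the two criteria coincide, since the symmetrized KL is approximately
#' \eqn{4\delta^2 I(\theta)}).  Ties break to the lowest item id.
#'
#' @param bank an [ItemBank-class].
#' @param administered character vector of already-used item ids.
#' @param thetaEst current trait estimate.
#' @param selector "UW-FI" or "FP-KL".
#' @param klDelta FP-KL offset.
#' @return the selected item id.
#' @export
selectNextItem <- function(bank, administered, thetaEst,
                           selector = c("UW-FI", "FP-KL"), klDelta = 0.1) {
  selector <- match.arg(selector)
  pool <- setdiff(itemIds(bank), administered)
  if (!length(pool)) .stopf("no unadministered items left")
  pool <- sort(pool)                                 # tie-break: lowest id
  crit <- vapply(pool, function(id) {
    j <- match(id, bank@id)
    if (selector == "UW-FI") {
      itemInformation(bank@a[j], bank@thresholds[[j]], thetaEst)
    } else {
      pp <- pmax(categoryProbs(bank@a[j], bank@thresholds[[j]],
                               thetaEst + klDelta)[1L, ], .PFLOOR)
      pm <- pmax(categoryProbs(bank@a[j], bank@thresholds[[j]],
                               thetaEst - klDelta)[1L, ], .PFLOOR)
      sum((pp - pm) * log(pp / pm))
    }
  }, numeric(1))
  pool[which.max(crit)]
}

.scoreOne <- function(x, bank, estimator, grid) {
  s <- scoreTheta(x, bank, method = estimator, grid = grid)
  list(theta = s$theta[1L], sem = s$sem[1L], boundary = s$boundary[1L])
}

#' Run one adaptive-testing session
#'
#' Loop: select the next item, obtain a response (drawn from the graded
#' model at \code{thetaTrue}, or replayed from \code{recorded}), re-estimate
#' the trait and its SEM, and stop once at least \code{minItems} items are
#' administered and the SEM rule is met, or the item budget is exhausted.
#' The first item is selected at \code{startTheta}.
#'
#' When the MLE is undefined or at the support boundary (all responses in an
#' extreme category), item selection continues at the clamped estimate.
#'
#' @param bank an [ItemBank-class].
#' @param thetaTrue the simulee's generating severity (model-generated
#'   mode); ignored when \code{recorded} is given.
#' @param recorded named integer vector of 1-based recorded responses
#'   covering every bank item (replay mode).
#' @param config a [catConfig()].
#' @param grid quadrature from [quadratureGrid()].
#' @param seed optional seed override for this session.
#' @return a [CatResult-class].
#' @export
runCatSession <- function(bank, thetaTrue = NULL, recorded = NULL,
                          config = catConfig(), grid = quadratureGrid(),
                          seed = NULL) {
  stopifnot(inherits(config, "CatConfig"))
  replay <- !is.null(recorded)
  if (replay) {
    miss <- setdiff(itemIds(bank), names(recorded))
    if (length(miss)) .stopf("replay mode needs responses for all items")
  } else {
    if (is.null(thetaTrue)) .stopf("need thetaTrue or recorded responses")
    set.seed(if (is.null(seed)) config$seed else seed)
  }
  maxItems <- if (is.na(config$maxItems)) nItems(bank) else
    min(config$maxItems, nItems(bank))
  administered <- character(0)
  resp <- integer(0)
  thetaTraj <- semTraj <- numeric(0)
  thetaEst <- config$startTheta
  boundary <- FALSE
  reason <- "max items"
  repeat {
    id <- selectNextItem(bank, administered, thetaEst, config$selector,
                         config$klDelta)
    j <- match(id, bank@id)
    x <- if (replay) as.integer(recorded[[id]]) else {
      p <- categoryProbs(bank@a[j], bank@thresholds[[j]], thetaTrue)[1L, ]
      sample.int(length(p), 1L, prob = p)
    }
    administered <- c(administered, id)
    resp <- c(resp, x)
    est <- .scoreOne(setNames(resp, administered), bank, config$estimator,
                     grid)
    if (!is.na(est$theta)) thetaEst <- est$theta
    if (isTRUE(est$boundary)) {
      thetaEst <- min(max(thetaEst, grid$nodes[1L]),
                      grid$nodes[length(grid$nodes)])
    }
    thetaTraj <- c(thetaTraj, est$theta)
    semTraj <- c(semTraj, est$sem)
    boundary <- isTRUE(est$boundary)
    n <- length(administered)
    if (!is.na(config$semThreshold) && n >= config$minItems &&
        is.finite(est$sem) && est$sem <= config$semThreshold) {
      reason <- "SEM met"
      break
    }
    if (n >= maxItems) break
  }
  new("CatResult", administered = administered, responses = resp,
      thetaTrajectory = thetaTraj, semTrajectory = semTraj,
      finalTheta = thetaTraj[length(thetaTraj)],
      finalSem = semTraj[length(semTraj)],
      estimator = config$estimator, boundary = boundary, reason = reason)
}

setMethod("show", "CatResult", function(object) {
  cat(sprintf(
    "CatResult: %d item(s), final theta %.3f (SEM %.3f, %s), stopped: %s\n",
    length(object@administered), object@finalTheta, object@finalSem,
    object@estimator, object@reason))
  invisible(object)
})

#' Simulate a cohort of adaptive-testing sessions
#'
#' Runs [runCatSession()] for every simulee with independent per-simulee
#' random substreams derived from the config seed, then aggregates the mean
#' number of administered items and Pearson correlations (with Fisher-z 95%
#' intervals) of the final estimates against the generating severities and,
#' optionally, a legacy total score.
#'
#' @param bank an [ItemBank-class].
#' @param thetaTrue numeric vector of generating severities.
#' @param config a [catConfig()].
#' @param legacyTotals optional numeric vector (NA allowed) of legacy
#'   short-form total scores for concurrent validity.
#' @param grid quadrature from [quadratureGrid()].
#' @return a [CatCohort-class].
#' @export
simulateCat <- function(bank, thetaTrue, config = catConfig(),
                        legacyTotals = NULL, grid = quadratureGrid()) {
  n <- length(thetaTrue)
  set.seed(config$seed)
  seeds <- sample.int(2147483646L, n)
  sessions <- vector("list", n)
  for (i in seq_len(n)) {
    sessions[[i]] <- runCatSession(bank, thetaTrue[i], config = config,
                                   grid = grid, seed = seeds[i])
  }
  smry <- data.frame(
    person = sprintf("P%03d", seq_len(n)),
    thetaTrue = thetaTrue,
    thetaEst = vapply(sessions, slot, numeric(1), "finalTheta"),
    sem = vapply(sessions, slot, numeric(1), "finalSem"),
    nItems = vapply(sessions, function(s) length(s@administered),
                    integer(1)),
    reason = vapply(sessions, slot, character(1), "reason"),
    stringsAsFactors = FALSE)
  ok <- is.finite(smry$thetaEst)
  pccTrue <- tryCatch(
    unlist(pccFisherCI(smry$thetaEst[ok], thetaTrue[ok]), use.names = FALSE),
    error = function(e) rep(NA_real_, 3L))
  pccLegacy <- rep(NA_real_, 3L)
  if (!is.null(legacyTotals)) {
    ok2 <- ok & is.finite(legacyTotals)
    pccLegacy <- tryCatch(
      unlist(pccFisherCI(smry$thetaEst[ok2], legacyTotals[ok2]),
             use.names = FALSE),
      error = function(e) rep(NA_real_, 3L))
  }
  new("CatCohort", sessions = sessions, summary = smry,
      meanItems = mean(smry$nItems),
      pccTrue = pccTrue, pccLegacy = pccLegacy,
      config = unclass(config))
}

setMethod("show", "CatCohort", function(object) {
  cat(sprintf(
    "CatCohort: %d simulee(s), %s + %s, mean items %.2f, PCC %.3f (%.3f-%.3f)\n",
    nrow(object@summary), object@config$estimator, object@config$selector,
    object@meanItems, object@pccTrue[1L], object@pccTrue[2L],
    object@pccTrue[3L]))
  invisible(object)
})

#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param x,y numeric vectors (n >= 4, finite, non-constant).
#' @return list with r, lower, upper (95% interval
#'   \eqn{\tanh(\mathrm{atanh}(r) \pm 1.96/\sqrt{n-3})}).
#' @examples
#' fisherZCI(0.916, 393)  # reproduces a printed interval to ~3 decimals
#' @export
pccFisherCI <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4L) .stopf("need n >= 4 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) .stopf("values must be finite")
  if (var(x) == 0 || var(y) == 0) .stopf("zero variance")
  r <- cor(x, y)
  c(list(r = r), fisherZCI(r, length(x))[c("lower", "upper")])
}

#' @rdname pccFisherCI
#' @param r a correlation in (-1, 1); |r| = 1 yields a degenerate interval
#'   with a warning.
#' @param n sample size (> 3).
#' @export
fisherZCI <- function(r, n) {
  stopifnot(n > 3)
  if (abs(r) >= 1) {
    .warnf("|r| = 1: Fisher-z interval is degenerate")
    return(list(r = r, lower = r, upper = r))
  }
  z <- atanh(r)
  hw <- 1.96 / sqrt(n - 3)
  list(r = r, lower = tanh(z - hw), upper = tanh(z + hw))
}
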