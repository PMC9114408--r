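## Fixed-parameter calibration of a legacy short form onto the bank's theta
## scale, and SEM-versus-theta precision comparison curves.

#' Fixed-parameter calibration
#'
#' Places legacy items on the anchor bank's latent scale: an EM run in which
#' the E-step posterior uses *all* items (anchors at their fixed parameters,
#' legacy items at their current values) under a N(0,1) latent density, and
#' the M-step updates the legacy items only.  Anchor parameters are returned
#' bit-identical.  Legacy items with unobserved categories are dropped with
#' a warning.
#'
#' @param responses joint [ResponseMatrix-class] containing both anchor and
#'   legacy columns.
#' @param anchorBank calibrated [ItemBank-class] of anchors.
#' @param legacyIds character ids of the legacy items within
#'   \code{responses}.
#' @param grid quadrature from [quadratureGrid()].
#' @param tol,maxCycles EM controls (as in [fitGRM()]).
#' @return a [FixedCalib-class].
#' @export
fixedCalibrate <- function(responses, anchorBank, legacyIds,
                           grid = quadratureGrid(), tol = 1e-4,
                           maxCycles = 500L) {
  X <- responseCodes(responses)
  K <- responses@nCategories
  anchorIds <- intersect(itemIds(anchorBank), colnames(X))
  if (!length(anchorIds)) .stopf("no anchor items found in the responses")
  miss <- setdiff(legacyIds, colnames(X))
  if (length(miss)) .stopf("legacy item(s) not in responses: %s",
                           paste(miss, collapse = ", "))
  ## drop legacy items with unobserved categories
  dropped <- character(0)
  for (id in legacyIds) {
    j <- match(id, colnames(X))
    cnt <- tabulate(X[!is.na(X[, j]), j], nbins = K[j])
    if (any(cnt == 0L)) {
      .warnf("fixed calibration: dropping legacy item '%s' (unobserved category)",
             id)
      dropped <- c(dropped, id)
    }
  }
  legacyIds <- setdiff(legacyIds, dropped)
  if (!length(legacyIds)) .stopf("no calibrable legacy items left")
  cols <- c(anchorIds, legacyIds)
  idxX <- match(cols, colnames(X))
  Xs <- X[, idxX, drop = FALSE]
  Ks <- K[idxX]
  update <- c(rep(FALSE, length(anchorIds)), rep(TRUE, length(legacyIds)))
  start <- vector("list", length(cols))
  for (i in seq_along(anchorIds)) {
    jb <- match(anchorIds[i], itemIds(anchorBank))
    start[[i]] <- .ab2par(anchorBank@a[jb], anchorBank@thresholds[[jb]])
  }
  for (i in seq_along(legacyIds)) {
    jj <- length(anchorIds) + i
    start[[jj]] <- .itemStart(Xs[, jj], Ks[jj])
  }
  core <- .grmFitCore(Xs, Ks, grid$nodes, grid$weights, tol = tol,
                      maxCycles = maxCycles, start = start, update = update)
  legPars <- lapply(core$pars[update], .par2ab)
  legacyBank <- itemBank(
    legacyIds,
    a = vapply(legPars, `[[`, numeric(1), "a"),
    thresholds = lapply(legPars, `[[`, "b"),
    offset = responses@offset[match(legacyIds, colnames(X))])
  new("FixedCalib", legacyBank = legacyBank, anchorBank = anchorBank,
      logLik = core$logLik, cycles = core$cycles,
      converged = core$converged, dropped = dropped)
}

setMethod("show", "FixedCalib", function(object) {
  cat(sprintf(
    "FixedCalib: %d legacy item(s) on a %d-anchor scale, %s (%d cycles)\n",
    nItems(object@legacyBank), nItems(object@anchorBank),
    if (object@converged) "converged" else "NOT converged", object@cycles))
  invisible(object)
})

#' Build a SemCurve
#'
#' @param points data.frame with columns theta, sem.
#' @param label curve label.
#' @param grid common theta grid for the smoothed curve; defaults to 50
#'   nodes over the observed theta range.
#' @param span lowess span (default 2/3).
#' @return a [SemCurve-class].
#' @export
semCurve <- function(points, label, grid = NULL, span = 2 / 3) {
  stopifnot(all(c("theta", "sem") %in% names(points)))
  pts <- points[is.finite(points$theta) & is.finite(points$sem), ,
                drop = FALSE]
  if (is.null(grid)) grid <- seq(min(pts$theta), max(pts$theta),
                                 length.out = 50L)
  sm <- lowessSmooth(pts$theta, pts$sem, span = span, grid = grid)
  new("SemCurve", points = pts[, c("theta", "sem")],
      smoothed = data.frame(theta = grid, sem = sm), label = label)
}

setMethod("show", "SemCurve", function(object) {
  cat(sprintf("SemCurve '%s': %d point(s), smoothed SEM range [%.3f, %.3f]\n",
              object@label, nrow(object@points),
              min(object@smoothed$sem), max(object@smoothed$sem)))
  invisible(object)
})

#' SEM curve of a fixed item set
#'
#' Scores every person with exactly the given item set and records the
#' (theta estimate, SEM) pairs; the Bayesian modal estimator is the default,
#' for which SEM(theta) obeys the analytic identity
#' \eqn{1/\sqrt{I(\theta) + 1}}.
#'
#' @param responses a [ResponseMatrix-class] containing the items.
#' @param bank an [ItemBank-class] with parameters for the item set.
#' @param items character ids of the fixed form (non-empty).
#' @param method estimator (default "BME").
#' @param grid quadrature; @param label curve label; @param commonGrid
#'   optional theta grid for smoothing; @param span lowess span.
#' @return a [SemCurve-class].
#' @export
fixedFormSemCurve <- function(responses, bank, items, method = "BME",
                              grid = quadratureGrid(), label = "fixed form",
                              commonGrid = NULL, span = 2 / 3) {
  if (!length(items)) .stopf("empty item set")
  sc <- scoreTheta(responses[, items], bank, method = method, grid = grid)
  semCurve(data.frame(theta = sc$theta, sem = sc$sem), label = label,
           grid = commonGrid, span = span)
}

#' SEM curve of a fixed-length CAT
#'
#' Runs adaptive sessions terminated after exactly \code{length} items (no
#' SEM rule) and collects the final (theta, SEM) pairs.
#'
#' @param bank an [ItemBank-class].
#' @param thetaTrue generating severities.
#' @param length items per session (e.g. 4 or 8).
#' @param config a [catConfig()]; its estimator/selector/seed are used, the
#'   termination settings are overridden.
#' @param grid quadrature; @param label curve label; @param commonGrid
#'   optional smoothing grid; @param span lowess span.
#' @return list: \code{curve} ([SemCurve-class]), \code{cohort}
#'   ([CatCohort-class]).
#' @export
fixedLengthCatSem <- function(bank, thetaTrue, length = 4L,
                              config = catConfig(), grid = quadratureGrid(),
                              label = sprintf("%d-item CAT", length),
                              commonGrid = NULL, span = 2 / 3) {
  if (length > nItems(bank)) .stopf("length exceeds the bank size")
  cfg <- catConfig(estimator = config$estimator, selector = config$selector,
                   semThreshold = NA, minItems = min(config$minItems, length),
                   maxItems = length, startTheta = config$startTheta,
                   klDelta = config$klDelta, seed = config$seed)
  cohort <- simulateCat(bank, thetaTrue, cfg, grid = grid)
  s <- cohort@summary
  list(curve = semCurve(data.frame(theta = s$thetaEst, sem = s$sem),
                        label = label, grid = commonGrid, span = span),
       cohort = cohort)
}

#' Local-linear (lowess) smoothing onto a grid
#'
#' Locally weighted linear regression with tricube weights (no robustness
#' iterations by default), evaluated on a common grid by interpolation.
#'
#' @param x,y data points (>= 10).
#' @param span fraction of points per local fit, in (0, 1] (default 2/3).
#' @param grid evaluation grid (default: the sorted x).
#' @param iter robustness iterations passed to [stats::lowess()] (default 0,
#'   a plain local-linear fit).
#' @return numeric vector of smoothed values on \code{grid}.
#' @export
lowessSmooth <- function(x, y, span = 2 / 3, grid = NULL, iter = 0L) {
  if (length(x) < 10L) .stopf("need >= 10 points")
  if (span <= 0 || span > 1) .stopf("span must be in (0, 1]")
  if (is.null(grid)) grid <- sort(x)
  lw <- lowess(x, y, f = span, iter = iter, delta = 0)
  approx(lw$x, lw$y, xout = grid, rule = 2, ties = mean)$y
}

#' Pointwise precision dominance of one SEM curve over another
#'
#' @param curveA,curveB [SemCurve-class] objects smoothed on the same grid.
#' @return list: \code{dominates} (TRUE iff A < B at every node),
#'   \code{margin} (B - A per node), \code{crossings} (nodes where the sign
#'   of the margin changes).
#' @export
precisionDominance <- function(curveA, curveB) {
  ga <- curveA@smoothed$theta; gb <- curveB@smoothed$theta
  if (length(ga) != length(gb) || any(abs(ga - gb) > 1e-9)) {
    .stopf("curves must be smoothed on the same grid")
  }
  margin <- curveB@smoothed$sem - curveA@smoothed$sem
  sgn <- sign(margin)
  nz <- which(sgn != 0)
  cross <- ga[nz[which(diff(sgn[nz]) != 0) + 1L]]
  list(dominates = all(margin > 0), margin = margin, crossings = cross)
}
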