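## S4 class definitions.  Validity methods enforce the structural invariants
## that every downstream computation relies on, so user-constructed objects
## fail fast rather than deep inside an EM cycle.

#' ItemBank: a set of ordinal items with graded-response-model parameters
#'
#' An \code{ItemBank} holds one discrimination parameter and an ordered
#' vector of category thresholds per item, together with item metadata.
#' Thresholds are on the latent-trait (theta) scale in the logistic metric
#' with scaling constant D = 1, so parameters are directly comparable to
#' those reported by standard IRT software.
#'
#' @slot id character, unique machine keys for the items.
#' @slot text character, free-text item stems (placeholders allowed).
#' @slot nCategories integer, number of response categories per item (>= 2).
#' @slot offset integer per item: value added to raw input codes to reach the
#'   1-based internal coding (0 for items already coded 1..K, 1 for legacy
#'   0-based scales such as the PHQ-9's 0-3 coding).
#' @slot a numeric, discrimination parameters (> 0).
#' @slot thresholds list of numeric vectors, each of length
#'   \code{nCategories - 1}, strictly increasing.
#'
#' @seealso [itemBank()], [readItemBank()], [categoryProbs()]
#' @export
setClass("ItemBank",
  representation(
    id = "character",
    text = "character",
    nCategories = "integer",
    offset = "integer",
    a = "numeric",
    thresholds = "list"
  )
)

setValidity("ItemBank", function(object) {
  n <- length(object@id)
  msgs <- character()
  if (anyDuplicated(object@id)) msgs <- c(msgs, "item ids must be unique")
  if (any(!nzchar(object@id))) msgs <- c(msgs, "item ids must be non-empty")
  for (s in c("text", "nCategories", "offset", "a", "thresholds")) {
    if (length(slot(object, s)) != n) {
      msgs <- c(msgs, sprintf("slot '%s' must have one entry per item", s))
    }
  }
  if (length(msgs)) return(msgs)
  if (any(object@nCategories < 2L)) {
    msgs <- c(msgs, "every item needs at least 2 categories")
  }
  bad_a <- which(!is.finite(object@a) | object@a <= 0)
  if (length(bad_a)) {
    msgs <- c(msgs, sprintf("item '%s': discrimination must be finite and > 0",
                            object@id[bad_a[1L]]))
  }
  for (j in seq_len(n)) {
    b <- object@thresholds[[j]]
    if (length(b) != object@nCategories[j] - 1L) {
      msgs <- c(msgs, sprintf("item '%s': expected %d thresholds, got %d",
                              object@id[j], object@nCategories[j] - 1L,
                              length(b)))
    } else if (anyNA(b) || any(!is.finite(b))) {
      msgs <- c(msgs, sprintf("item '%s': thresholds must be finite",
                              object@id[j]))
    } else if (is.unsorted(b, strictly = TRUE)) {
      msgs <- c(msgs, sprintf("item '%s': thresholds not increasing",
                              object@id[j]))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' ResponseMatrix: persons x items ordinal responses
#'
#' Stores integer category codes, 1-based internally (a raw 0-based legacy
#' coding is shifted on import and shifted back on export).  Missing
#' responses are \code{NA} and are dropped pairwise in classical statistics
#' and marginalized in likelihood-based computations.
#'
#' @slot data integer matrix, rows = persons, columns = items, values in
#'   \code{1..nCategories[j]} or \code{NA}; dimnames carry person and item
#'   ids.
#' @slot nCategories integer, categories per item (column).
#' @slot offset integer per item, raw-code offset as in [ItemBank-class].
#'
#' @seealso [responseMatrix()], [readResponses()]
#' @export
setClass("ResponseMatrix",
  representation(
    data = "matrix",
    nCategories = "integer",
    offset = "integer"
  )
)

setValidity("ResponseMatrix", function(object) {
  d <- object@data
  msgs <- character()
  if (!is.numeric(d)) return("response data must be numeric")
  if (is.null(rownames(d)) || is.null(colnames(d))) {
    return("response data needs person row names and item column names")
  }
  if (anyDuplicated(rownames(d))) msgs <- c(msgs, "person ids must be unique")
  if (anyDuplicated(colnames(d))) msgs <- c(msgs, "item ids must be unique")
  if (length(object@nCategories) != ncol(d) ||
      length(object@offset) != ncol(d)) {
    return(c(msgs, "nCategories and offset must have one entry per item"))
  }
  for (j in seq_len(ncol(d))) {
    v <- d[, j]
    v <- v[!is.na(v)]
    if (length(v) && (any(v < 1) || any(v > object@nCategories[j]) ||
                      any(v != round(v)))) {
      msgs <- c(msgs, sprintf(
        "item '%s': categories must be integers in 1..%d",
        colnames(d)[j], object@nCategories[j]))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' GRMFit: result of a marginal maximum likelihood GRM calibration
#'
#' @slot bank the calibrated [ItemBank-class].
#' @slot logLik numeric, final marginal log-likelihood.
#' @slot logLikHistory numeric, marginal log-likelihood per EM cycle
#'   (non-decreasing up to numerical tolerance).
#' @slot cycles integer, EM cycles used.
#' @slot converged logical.
#'
#' @seealso [fitGRM()]
#' @export
setClass("GRMFit",
  representation(
    bank = "ItemBank",
    logLik = "numeric",
    logLikHistory = "numeric",
    cycles = "integer",
    converged = "logical"
  )
)

#' ScreeningAudit: item-selection funnel bookkeeping
#'
#' One row per screening stage, with entering/excluded/surviving counts that
#' chain (entering - excluded = surviving, and each stage's survivors enter
#' the next stage), plus the per-stage excluded item ids with reasons.
#'
#' @slot stages data.frame with columns stage, entering, excluded, surviving.
#' @slot exclusions named list (by stage) of data.frames with columns
#'   item, reason.
#'
#' @seealso [runScreening()]
#' @export
setClass("ScreeningAudit",
  representation(stages = "data.frame", exclusions = "list")
)

setValidity("ScreeningAudit", function(object) {
  st <- object@stages
  need <- c("stage", "entering", "excluded", "surviving")
  if (!all(need %in% names(st))) {
    return("stages must have columns stage, entering, excluded, surviving")
  }
  if (nrow(st)) {
    if (any(st$entering - st$excluded != st$surviving)) {
      return("entering - excluded must equal surviving at every stage")
    }
    if (nrow(st) > 1L &&
        any(st$entering[-1L] != st$surviving[-nrow(st)])) {
      return("stages must chain: survivors of one stage enter the next")
    }
  }
  TRUE
})

#' CatResult: one simulated (or replayed) adaptive-testing session
#'
#' @slot administered character, item ids in administration order.
#' @slot responses integer, 1-based category codes in the same order.
#' @slot thetaTrajectory numeric, trait estimate after each item.
#' @slot semTrajectory numeric, standard error of measurement after each item.
#' @slot finalTheta,finalSem numeric, the terminal estimate.
#' @slot estimator character, MLE, BME or EAP.
#' @slot boundary logical, whether the final estimate hit the support edge.
#' @slot reason character, "SEM met" or "max items".
#'
#' @seealso [runCatSession()]
#' @export
setClass("CatResult",
  representation(
    administered = "character",
    responses = "integer",
    thetaTrajectory = "numeric",
    semTrajectory = "numeric",
    finalTheta = "numeric",
    finalSem = "numeric",
    estimator = "character",
    boundary = "logical",
    reason = "character"
  )
)

setValidity("CatResult", function(object) {
  if (anyDuplicated(object@administered)) return("no item administered twice")
  n <- length(object@administered)
  if (length(object@responses) != n ||
      length(object@thetaTrajectory) != n ||
      length(object@semTrajectory) != n) {
    return("trajectory length must equal the number of items administered")
  }
  TRUE
})

#' CatCohort: cohort-level roll-up of adaptive-testing simulations
#'
#' @slot sessions list of [CatResult-class].
#' @slot summary data.frame, one row per simulee: person, thetaTrue (NA when
#'   replaying recorded responses), thetaEst, sem, nItems, reason.
#' @slot meanItems numeric, mean number of administered items.
#' @slot pccTrue numeric length 3 (r, lower, upper) against the generating
#'   trait, or NA when unavailable.
#' @slot pccLegacy numeric length 3 against a legacy total score, or NA.
#' @slot config list, the [catConfig()] used.
#'
#' @seealso [simulateCat()]
#' @export
setClass("CatCohort",
  representation(
    sessions = "list",
    summary = "data.frame",
    meanItems = "numeric",
    pccTrue = "numeric",
    pccLegacy = "numeric",
    config = "list"
  )
)

#' SemCurve: standard error of measurement versus trait estimate
#'
#' Raw per-person (theta, sem) points together with a local-linear (tricube
#' weighted) smooth evaluated on a common theta grid, so curves from
#' different scoring rules can be compared node by node.
#'
#' @slot points data.frame with columns theta, sem.
#' @slot smoothed data.frame with columns theta, sem (on the common grid).
#' @slot label character, curve label for reports.
#'
#' @seealso [fixedFormSemCurve()], [fixedLengthCatSem()], [lowessSmooth()]
#' @export
setClass("SemCurve",
  representation(points = "data.frame", smoothed = "data.frame",
                 label = "character")
)

#' FixedCalib: fixed-parameter calibration of a legacy form
#'
#' @slot legacyBank [ItemBank-class] with the newly calibrated legacy items
#'   (on the anchor scale).
#' @slot anchorBank the anchor [ItemBank-class], returned untouched.
#' @slot logLik numeric, final joint marginal log-likelihood.
#' @slot cycles integer; @slot converged logical.
#' @slot dropped character, legacy items dropped for unobserved categories.
#'
#' @seealso [fixedCalibrate()]
#' @export
setClass("FixedCalib",
  representation(
    legacyBank = "ItemBank",
    anchorBank = "ItemBank",
    logLik = "numeric",
    cycles = "integer",
    converged = "logical",
    dropped = "character"
  )
)
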