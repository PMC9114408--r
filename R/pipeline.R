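## End-to-end bank development: screening -> GRM calibration -> category
## maximality -> S-X2 item fit -> DIF -> refit of the final bank (alpha and
## per-person severities recomputed) -> CAT simulation grid -> legacy-form
## calibration and precision comparison.

#' Configuration of the full pipeline
#'
#' @param cohort a [cohortSpec()] describing the synthetic cohort, or NULL
#'   when \code{responses} is supplied.
#' @param responses,legacyResponses,groups optional user data overriding the
#'   synthetic cohort: a [ResponseMatrix-class], an optional legacy-form
#'   [ResponseMatrix-class], and an optional data.frame of two-level person
#'   covariates for DIF.
#' @param screening a [screeningConfig()].
#' @param grmTol,maxCycles EM controls for the calibration fits.
#' @param alphaItemFit,alphaDif exclusion alpha levels (default 0.01 each).
#' @param catGrid data.frame with columns estimator, selector, semThreshold
#'   defining the simulation grid (default: the full 3 x 2 x {0.32, 0.50}
#'   grid).
#' @param fixedLengths item counts for the fixed-length CAT SEM curves
#'   (default c(4, 8)).
#' @param seed master seed; every stage derives a named substream from it.
#' @return validated list of class "PipelineConfig".
#' @export
pipelineConfig <- function(cohort = cohortSpec(), responses = NULL,
                           legacyResponses = NULL, groups = NULL,
                           screening = screeningConfig(), grmTol = 1e-4,
                           maxCycles = 500L, alphaItemFit = 0.01,
                           alphaDif = 0.01,
                           catGrid = expand.grid(
                             estimator = c("MLE", "BME", "EAP"),
                             selector = c("UW-FI", "FP-KL"),
                             semThreshold = c(0.32, 0.50),
                             stringsAsFactors = FALSE),
                           fixedLengths = c(4L, 8L), seed = 1L) {
  if (is.null(cohort) && is.null(responses)) {
    .stopf("need a cohort spec or a response matrix")
  }
  stopifnot(all(c("estimator", "selector", "semThreshold") %in%
                  names(catGrid)))
  structure(list(cohort = cohort, responses = responses,
                 legacyResponses = legacyResponses, groups = groups,
                 screening = screening, grmTol = grmTol,
                 maxCycles = as.integer(maxCycles),
                 alphaItemFit = alphaItemFit, alphaDif = alphaDif,
                 catGrid = catGrid, fixedLengths = as.integer(fixedLengths),
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Run the full bank-development pipeline
#'
#' Stages, in order: item screening ([runScreening()]), GRM calibration
#' ([fitGRM()]), category-maximality exclusion, S-X2 item-fit exclusion,
#' DIF exclusion for each supplied two-level covariate, refit of the final
#' bank with Cronbach's alpha and per-person severities (MAP) recomputed,
#' the CAT simulation grid ([simulateCat()]), and legacy-form calibration
#' with the fixed-length-CAT precision comparison.  Each exclusion stage
#' extends the audit, so the full funnel chains arithmetically.
#'
#' @param config a [pipelineConfig()].
#' @param verbose log stage progress to stderr (default TRUE).
#' @return list of class "PipelineReport": \code{audit}, \code{alphaBefore},
#'   \code{alphaAfter}, \code{fit} (final [GRMFit-class]), \code{thetaTrue}
#'   (MAP scores on the final bank), \code{catGrid} (data.frame, one row per
#'   grid cell), \code{cohorts} (list of [CatCohort-class]), \code{legacy}
#'   ([FixedCalib-class] or NULL), \code{semCurves} (list of
#'   [SemCurve-class]), \code{dominance} (verdict of the shortest
#'   fixed-length CAT against the legacy form, or NULL), \code{dif} (list of
#'   per-covariate data.frames), \code{truth} (when synthetic).
#' @export
runPipeline <- function(config = pipelineConfig(), verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  log <- function(fmt, ...) if (verbose) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }
  seed <- config$seed
  truth <- NULL
  if (is.null(config$responses)) {
    log("generating synthetic cohort (n=%d, %d items)",
        config$cohort$nPersons, config$cohort$nItems)
    cohort <- makeStudyCohort(config$cohort)
    responses <- cohort$responses
    legacyResponses <- cohort$legacyResponses
    groups <- cohort$groups
    truth <- cohort$truth
  } else {
    responses <- config$responses
    legacyResponses <- config$legacyResponses
    groups <- config$groups
  }

  log("stage 1: screening")
  scr <- runScreening(responses, config = config$screening)
  audit <- scr$audit
  keep <- scr$surviving
  records <- lapply(seq_len(nrow(audit@stages)), function(i) {
    list(row = audit@stages[i, , drop = FALSE],
         excl = audit@exclusions[[i]])
  })

  grid <- quadratureGrid()
  log("stage 2: GRM calibration of %d surviving items", length(keep))
  fit0 <- fitGRM(responses[, keep], grid = grid, tol = config$grmTol,
                 maxCycles = config$maxCycles)

  log("stage 3: category maximality")
  bank0 <- calibratedBank(fit0)
  nm <- vapply(seq_len(nItems(bank0)), function(j) {
    length(categoryMaximality(bank0@a[j], bank0@thresholds[[j]])) > 0L
  }, logical(1))
  out <- itemIds(bank0)[nm]
  records <- c(records, list(.stageRecord("category_maximality", keep, out,
                                          "never-maximal category")))
  keep <- setdiff(keep, out)

  log("stage 4: S-X2 item fit")
  sx2 <- sx2ItemFit(responses[, keep], bank0[keep],
                    alpha = config$alphaItemFit, grid = grid)
  out <- sx2$item[!is.na(sx2$flagged) & sx2$flagged]
  records <- c(records, list(.stageRecord("s_x2_item_fit", keep, out,
                                          sprintf("S-X2 p < %g",
                                                  config$alphaItemFit))))
  keep <- setdiff(keep, out)

  difResults <- list()
  if (!is.null(groups)) {
    covars <- setdiff(names(groups), "person")
    for (cv in covars) {
      log("stage 5: DIF for %s", cv)
      dd <- difTest(responses[, keep], groups[[cv]],
                    alpha = config$alphaDif, grid = grid)
      difResults[[cv]] <- dd
      out <- dd$item[!is.na(dd$flagged) & dd$flagged]
      records <- c(records, list(.stageRecord(
        paste0("dif_", cv), keep, out,
        sprintf("DIF (%s) p < %g", cv, config$alphaDif))))
      keep <- setdiff(keep, out)
    }
  }
  if (length(keep) < 3L) .stopf("bank exhausted before CAT simulation")
  audit <- .buildAudit(records)

  log("stage 6: refit of the final %d-item bank", length(keep))
  fit <- fitGRM(responses[, keep], grid = grid, tol = config$grmTol,
                maxCycles = config$maxCycles)
  bank <- calibratedBank(fit)
  alphaAfter <- cronbachAlpha(responses[, keep])
  thetaTrue <- scoreTheta(responses[, keep], bank, method = "BME",
                          grid = grid)$theta

  legacyTotals <- NULL
  if (!is.null(legacyResponses)) {
    m <- responseCodes(legacyResponses)
    legacyTotals <- rowSums(sweep(m, 2L, legacyResponses@offset, `-`))
  }

  log("stage 7: CAT grid (%d cells)", nrow(config$catGrid))
  cohorts <- list()
  gridRows <- list()
  for (i in seq_len(nrow(config$catGrid))) {
    g <- config$catGrid[i, ]
    cfg <- catConfig(estimator = g$estimator, selector = g$selector,
                     semThreshold = g$semThreshold,
                     seed = .substream(seed, paste0("cat", i)))
    cc <- simulateCat(bank, thetaTrue, cfg, legacyTotals = legacyTotals,
                      grid = grid)
    cohorts[[i]] <- cc
    gridRows[[i]] <- data.frame(
      estimator = g$estimator, selector = g$selector,
      semThreshold = g$semThreshold, meanItems = cc@meanItems,
      pcc = cc@pccTrue[1L], pccLow = cc@pccTrue[2L],
      pccHigh = cc@pccTrue[3L], pccLegacy = cc@pccLegacy[1L],
      pccLegacyLow = cc@pccLegacy[2L], pccLegacyHigh = cc@pccLegacy[3L],
      stringsAsFactors = FALSE)
  }
  catGrid <- do.call(rbind, gridRows)

  legacy <- NULL; semCurves <- list(); dominance <- NULL
  if (!is.null(legacyResponses)) {
    log("stage 8: legacy-form calibration and precision comparison")
    joint <- .bindResponses(responses[, keep], legacyResponses)
    legacy <- fixedCalibrate(joint, bank, itemIds(legacyResponses),
                             grid = grid, tol = config$grmTol,
                             maxCycles = config$maxCycles)
    legBank <- legacy@legacyBank
    scLeg <- scoreTheta(legacyResponses[, itemIds(legBank)], legBank,
                        method = "BME", grid = grid)
    allTheta <- scLeg$theta
    commonGrid <- seq(quantile(allTheta, 0.02), quantile(allTheta, 0.98),
                      length.out = 50L)
    semCurves$legacy <- semCurve(
      data.frame(theta = scLeg$theta, sem = scLeg$sem),
      label = "calibrated legacy form", grid = commonGrid)
    lens <- config$fixedLengths[config$fixedLengths <= nItems(bank)]
    if (length(lens) < length(config$fixedLengths)) {
      .warnf("dropping fixed-length CAT curves longer than the final bank")
    }
    for (len in lens) {
      fl <- fixedLengthCatSem(
        bank, thetaTrue, length = len,
        config = catConfig(seed = .substream(seed, paste0("flcat", len))),
        grid = grid, commonGrid = commonGrid)
      semCurves[[sprintf("cat%d", len)]] <- fl$curve
    }
    if (length(lens)) {
      shortest <- semCurves[[sprintf("cat%d", min(lens))]]
      dominance <- precisionDominance(shortest, semCurves$legacy)
    }
  }

  structure(list(audit = audit, alphaBefore = scr$alpha,
                 alphaAfter = alphaAfter, fit = fit, thetaTrue = thetaTrue,
                 catGrid = catGrid, cohorts = cohorts, legacy = legacy,
                 semCurves = semCurves, dominance = dominance,
                 dif = difResults, truth = truth, seed = seed),
            class = "PipelineReport")
}

## Column-bind two response matrices over the same persons.
.bindResponses <- function(a, b) {
  stopifnot(identical(personIds(a), personIds(b)))
  new("ResponseMatrix",
      data = cbind(responseCodes(a), responseCodes(b)),
      nCategories = c(a@nCategories, b@nCategories),
      offset = c(a@offset, b@offset))
}

#' Serialize a pipeline report
#'
#' Writes a machine-readable JSON report and/or a human-readable markdown
#' summary: the screening flowchart counts, the calibrated parameter table
#' (sorted by discrimination, extremes of a and the outer thresholds
#' marked), the CAT grid table, and the SEM comparison verdict.  The two
#' renderings are produced from the same report object.
#'
#' @param report a "PipelineReport" from [runPipeline()].
#' @param dir output directory (created if needed).
#' @param format subset of c("json", "markdown").
#' @return invisibly, the paths written.
#' @export
buildReport <- function(report, dir, format = c("json", "markdown")) {
  stopifnot(inherits(report, "PipelineReport"))
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  bank <- calibratedBank(report$fit)
  ord <- order(-bank@a)
  maxb <- max(lengths(bank@thresholds))
  bm <- t(vapply(bank@thresholds,
                 function(b) c(b, rep(NA_real_, maxb - length(b))),
                 numeric(maxb)))
  params <- data.frame(item = bank@id, a = bank@a, bm,
                       check.names = FALSE)[ord, , drop = FALSE]
  names(params)[2L + seq_len(maxb)] <- paste0("b", seq_len(maxb))
  obj <- list(
    audit = auditTable(report$audit),
    exclusions = auditExclusions(report$audit),
    alpha = list(before = report$alphaBefore, after = report$alphaAfter),
    parameters = params,
    catGrid = report$catGrid,
    dominance = if (!is.null(report$dominance)) {
      list(shortCatDominatesLegacy = report$dominance$dominates,
           minMargin = min(report$dominance$margin))
    },
    seed = report$seed)
  if ("json" %in% format) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
    paths <- c(paths, p)
  }
  if ("markdown" %in% format) {
    p <- file.path(dir, "report.md")
    con <- file(p, "w")
    on.exit(close(con))
    w <- function(...) writeLines(sprintf(...), con)
    w("# Bank development report\n")
    w("## Item selection funnel\n")
    at <- auditTable(report$audit)
    w("| stage | entering | excluded | surviving |")
    w("|---|---|---|---|")
    for (i in seq_len(nrow(at))) {
      w("| %s | %d | %d | %d |", at$stage[i], at$entering[i],
        at$excluded[i], at$surviving[i])
    }
    w("\nCronbach's alpha: %.3f before selection, %.3f after.\n",
      report$alphaBefore, report$alphaAfter)
    w("## Calibrated parameters (sorted by discrimination)\n")
    hdr <- paste(names(params), collapse = " | ")
    w("| %s |", hdr)
    w("|%s|", paste(rep("---", ncol(params)), collapse = "|"))
    for (i in seq_len(nrow(params))) {
      w("| %s |", paste(vapply(params[i, ], function(v)
        if (is.numeric(v)) sprintf("%.3f", v) else as.character(v),
        character(1)), collapse = " | "))
    }
    w("\n## CAT simulation grid\n")
    w("| estimator | selector | SEM threshold | mean items | PCC (95%% CI) |")
    w("|---|---|---|---|---|")
    cg <- report$catGrid
    for (i in seq_len(nrow(cg))) {
      w("| %s | %s | %.2f | %.2f | %.3f (%.3f-%.3f) |",
        cg$estimator[i], cg$selector[i], cg$semThreshold[i],
        cg$meanItems[i], cg$pcc[i], cg$pccLow[i], cg$pccHigh[i])
    }
    if (!is.null(report$dominance)) {
      w("\n## Precision comparison\n")
      w("Shortest fixed-length CAT %s the calibrated legacy form at every grid node (min margin %.4f).",
        if (report$dominance$dominates) "dominates" else "does NOT dominate",
        min(report$dominance$margin))
    }
    paths <- c(paths, p)
  }
  invisible(paths)
}
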