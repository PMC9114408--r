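## Classical item screening and checks of the IRT assumptions, applied as a
## fixed funnel: unanswered categories -> item-remainder correlation ->
## PCA unidimensionality -> one-factor residual correlations (local
## independence) -> Loevinger scalability (monotonicity).  Correlations are
## computed on raw category codes treated as numeric, the convention of the
## classical stage of bank development.

#' Screening thresholds
#'
#' @param minItemRemainder exclusion rule: item-remainder correlation
#'   strictly below this (default 0.3) excludes the item.
#' @param minFirstFactorProportion unidimensionality: proportion of variance
#'   of the first principal component must be >= this (default 0.20).
#' @param minFirstToSecondRatio ratio of first to second eigenvalue must be
#'   >= this (default 4.0).
#' @param maxResidualCorrelation local independence: pairs with one-factor
#'   residual correlation above this (default 0.2) are flagged.
#' @param minScalability monotonicity: items with Loevinger H strictly below
#'   this (default 0.3) are excluded.
#' @return validated list of class "ScreeningConfig".
#' @export
screeningConfig <- function(minItemRemainder = 0.3,
                            minFirstFactorProportion = 0.20,
                            minFirstToSecondRatio = 4.0,
                            maxResidualCorrelation = 0.2,
                            minScalability = 0.3) {
  vals <- c(minItemRemainder, minFirstFactorProportion,
            minFirstToSecondRatio, maxResidualCorrelation, minScalability)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    .stopf("all screening thresholds must be positive")
  }
  structure(list(minItemRemainder = minItemRemainder,
                 minFirstFactorProportion = minFirstFactorProportion,
                 minFirstToSecondRatio = minFirstToSecondRatio,
                 maxResidualCorrelation = maxResidualCorrelation,
                 minScalability = minScalability),
            class = "ScreeningConfig")
}

.ccMatrix <- function(responses) {
  X <- responseCodes(responses)
  X[complete.cases(X), , drop = FALSE]
}

#' Cronbach's alpha
#'
#' \eqn{\alpha = k/(k-1)\,(1 - \sum_i s_i^2 / s_T^2)} on complete-case rows,
#' with unbiased (n-1) sample variances.  Invariant to item order and to
#' adding a constant to every response.
#'
#' @param responses a [ResponseMatrix-class] (or plain numeric matrix) with
#'   at least 2 items and 2 complete rows.
#' @return scalar in (-Inf, 1].
#' @export
cronbachAlpha <- function(responses) {
  X <- if (is(responses, "ResponseMatrix")) .ccMatrix(responses) else
    responses[complete.cases(responses), , drop = FALSE]
  k <- ncol(X)
  if (k < 2L || nrow(X) < 2L) .stopf("need >= 2 items and >= 2 complete rows")
  tot <- var(rowSums(X))
  if (tot <= 0) .stopf("total-score variance is zero")
  k / (k - 1) * (1 - sum(apply(X, 2L, var)) / tot)
}

#' Item-remainder correlations
#'
#' Pearson correlation of each item with the sum of the remaining items, on
#' complete-case rows.  Items with correlation strictly below the threshold
#' (or undefined because the item is constant) are flagged; the boundary
#' value itself is retained (the rule is strict "< threshold").
#'
#' @param responses a [ResponseMatrix-class] with >= 3 items.
#' @param minR exclusion threshold (default 0.3).
#' @return data.frame with columns item, r, flagged.
#' @export
itemRemainderCorrelations <- function(responses, minR = 0.3) {
  X <- .ccMatrix(responses)
  if (ncol(X) < 3L) .stopf("need >= 3 items")
  tot <- rowSums(X)
  r <- vapply(seq_len(ncol(X)), function(j) {
    if (var(X[, j]) == 0) return(NA_real_)
    cor(X[, j], tot - X[, j])
  }, numeric(1))
  data.frame(item = colnames(X), r = r,
             flagged = is.na(r) | r < minR, stringsAsFactors = FALSE)
}

#' Unused response categories per item
#'
#' Categories with zero observed count; any non-empty set flags the item for
#' exclusion (its parameters would not be estimable).
#'
#' @param responses a [ResponseMatrix-class].
#' @param bank optional [ItemBank-class] supplying category counts (else the
#'   matrix's own).
#' @return list: \code{unused} (named list of integer vectors),
#'   \code{flagged} (data.frame item/flagged).
#' @export
unansweredCategories <- function(responses, bank = NULL) {
  X <- responseCodes(responses)
  K <- if (is.null(bank)) responses@nCategories else
    bank@nCategories[match(colnames(X), itemIds(bank))]
  unused <- lapply(seq_len(ncol(X)), function(j) {
    cnt <- tabulate(X[!is.na(X[, j]), j], nbins = K[j])
    which(cnt == 0L)
  })
  names(unused) <- colnames(X)
  list(unused = unused,
       flagged = data.frame(item = colnames(X),
                            flagged = lengths(unused) > 0L,
                            stringsAsFactors = FALSE))
}

.corMatrix <- function(responses) {
  X <- responseCodes(responses)
  R <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))
  ev <- try(eigen(R, symmetric = TRUE, only.values = TRUE)$values,
            silent = TRUE)
  if (anyNA(R) || inherits(ev, "try-error") || any(ev < -1e-8)) {
    ## pairwise deletion produced an indefinite (or incomplete) matrix;
    ## fall back to complete cases
    R <- cor(.ccMatrix(responses))
  }
  R
}

#' PCA unidimensionality check with iterative exclusion
#'
#' Eigendecomposition of the Pearson correlation matrix.  The item set
#' passes when the first component explains at least
#' \code{minFirstFactorProportion} of the variance and the first-to-second
#' eigenvalue ratio is at least \code{minFirstToSecondRatio}.  While the
#' criteria fail, the item with the smallest absolute first-component
#' loading is dropped and the decomposition recomputed, stopping at a floor
#' of 3 items.
#'
#' @param responses a [ResponseMatrix-class] with >= 3 items, or a
#'   pre-computed item correlation matrix.
#' @param config a [screeningConfig()].
#' @return list: \code{proportions} and \code{loadings} for the entering
#'   item set (what the unidimensionality verdict is reported on),
#'   \code{finalProportions} and \code{finalLoadings} for the surviving set,
#'   \code{pass}, and \code{excluded} (ids in exclusion order).
#' @export
pcaUnidimensionality <- function(responses, config = screeningConfig()) {
  asMatrix <- is.matrix(responses)
  if (asMatrix) {
    if (nrow(responses) != ncol(responses) ||
        any(abs(diag(responses) - 1) > 1e-8)) {
      .stopf("matrix input must be a correlation matrix")
    }
    if (is.null(colnames(responses))) {
      dimnames(responses) <- list(paste0("I", seq_len(ncol(responses))),
                                  paste0("I", seq_len(ncol(responses))))
    }
  }
  ids <- if (asMatrix) colnames(responses) else itemIds(responses)
  if (length(ids) < 3L) .stopf("need >= 3 items")
  excluded <- character(0)
  keep <- ids
  prop0 <- NULL; load0 <- NULL
  repeat {
    R <- if (asMatrix) responses[keep, keep] else .corMatrix(responses[, keep])
    eig <- eigen(R, symmetric = TRUE)
    prop <- eig$values / sum(eig$values)
    load <- eig$vectors[, 1L] * sqrt(max(eig$values[1L], 0))
    names(load) <- keep
    if (is.null(prop0)) { prop0 <- prop; load0 <- load }
    pass <- prop[1L] >= config$minFirstFactorProportion &&
      prop[1L] / max(prop[2L], 1e-12) >= config$minFirstToSecondRatio
    if (pass || length(keep) <= 3L) {
      return(list(proportions = prop0, loadings = load0,
                  finalProportions = prop, finalLoadings = load,
                  pass = pass, excluded = excluded))
    }
    drop <- keep[which.min(abs(load))]
    excluded <- c(excluded, drop)
    keep <- setdiff(keep, drop)
  }
}

## One-factor ML loadings from a correlation matrix.  factanal() is the
## workhorse; if it fails (e.g. 3 items, zero df) fall back to iterated
## principal-axis extraction.  Loadings are clamped below 1 so residuals
## stay defined in Heywood cases.
.oneFactorLoadings <- function(R, nObs) {
  fa <- try(suppressWarnings(factanal(covmat = R, factors = 1L,
                                      n.obs = nObs)),
            silent = TRUE)
  if (!inherits(fa, "try-error")) {
    lam <- as.numeric(fa$loadings)
  } else {
    lam <- sqrt(pmax(eigen(R, symmetric = TRUE)$values[1L] / nrow(R), 0)) *
      eigen(R, symmetric = TRUE)$vectors[, 1L]
    for (i in 1:50) {
      comm <- pmin(lam^2, 0.998)
      Rh <- R; diag(Rh) <- comm
      e <- eigen(Rh, symmetric = TRUE)
      new <- e$vectors[, 1L] * sqrt(max(e$values[1L], 0))
      if (max(abs(new - lam)) < 1e-6) { lam <- new; break }
      lam <- new
    }
  }
  if (any(abs(lam) >= 1)) {
    .warnf("Heywood case: clamping loading(s) to 0.999")
    lam <- pmin(pmax(lam, -0.999), 0.999)
  }
  if (sum(lam) < 0) lam <- -lam                      # sign convention
  lam
}

#' Residual correlations after a one-factor fit
#'
#' Fits a one-factor model to the Pearson correlation matrix by maximum
#' likelihood (categories treated as numeric) and returns the residual
#' matrix \eqn{R - \Lambda\Lambda'} (diagonal zeroed).  Pairs whose residual
#' exceeds \code{maxR} violate local independence; bank development excludes
#' the member of each flagged pair with the lower first-factor PCA loading.
#'
#' @param responses a [ResponseMatrix-class] with >= 3 items.
#' @param maxR flag threshold (default 0.2).
#' @return list: \code{residuals} (matrix), \code{loadings},
#'   \code{flaggedPairs} (data.frame item1/item2/residual, decreasing).
#' @export
residualCorrelations <- function(responses, maxR = 0.2) {
  ids <- itemIds(responses)
  if (length(ids) < 3L) .stopf("need >= 3 items")
  R <- .corMatrix(responses)
  lam <- .oneFactorLoadings(R, nPersons(responses))
  res <- R - tcrossprod(lam)
  diag(res) <- 0
  dimnames(res) <- list(ids, ids)
  ut <- which(upper.tri(res) & res > maxR, arr.ind = TRUE)
  fp <- data.frame(item1 = ids[ut[, 1L]], item2 = ids[ut[, 2L]],
                   residual = res[ut], stringsAsFactors = FALSE)
  fp <- fp[order(-fp$residual), , drop = FALSE]
  list(residuals = res, loadings = setNames(lam, ids), flaggedPairs = fp)
}

## Maximum covariance attainable between two ordinal items given both
## marginal distributions: the covariance of the comonotone coupling,
## computed by merging the two cumulative distributions.
.comonotoneCov <- function(p1, p2, v1 = seq_along(p1), v2 = seq_along(p2)) {
  c1 <- cumsum(p1); c2 <- cumsum(p2)
  cuts <- sort(unique(c(0, c1, c2)))
  cuts <- cuts[cuts <= 1 + 1e-12]
  exy <- 0
  for (t in seq_len(length(cuts) - 1L)) {
    mass <- cuts[t + 1L] - cuts[t]
    if (mass <= 0) next
    mid <- (cuts[t] + cuts[t + 1L]) / 2
    x <- v1[which(c1 >= mid - 1e-12)[1L]]
    y <- v2[which(c2 >= mid - 1e-12)[1L]]
    exy <- exy + mass * x * y
  }
  exy - sum(p1 * v1) * sum(p2 * v2)
}

#' Loevinger scalability coefficients (Mokken H)
#'
#' Polytomous covariance-ratio definition: \eqn{H_{ij} =
#' \mathrm{cov}(X_i, X_j) / \mathrm{cov}_{\max}(X_i, X_j)}, where the
#' denominator is the maximum covariance attainable given both marginal
#' category distributions (the comonotone coupling).  Item coefficients
#' pool numerators and denominators over partners: \eqn{H_i = \sum_{j\ne i}
#' \mathrm{cov}_{ij} / \sum_{j\ne i} \mathrm{cov}_{\max,ij}}.  Computed on
#' complete-case rows.  Pairs with zero maximal covariance (a constant
#' margin) are skipped with a warning.
#'
#' @param responses a [ResponseMatrix-class] with >= 2 items.
#' @param minH exclusion threshold on \eqn{H_i} (default 0.3).
#' @return list: \code{Hij} (symmetric matrix), \code{Hi} (data.frame
#'   item/H/flagged).
#' @export
mokkenScalability <- function(responses, minH = 0.3) {
  X <- .ccMatrix(responses)
  J <- ncol(X)
  if (J < 2L) .stopf("need >= 2 items")
  K <- responses@nCategories
  covs <- cov(X) * (nrow(X) - 1) / nrow(X)           # population covariances
  cmax <- matrix(NA_real_, J, J, dimnames = dimnames(covs))
  marg <- lapply(seq_len(J), function(j)
    tabulate(X[, j], nbins = K[j]) / nrow(X))
  for (i in seq_len(J - 1L)) {
    for (j in (i + 1L):J) {
      cm <- .comonotoneCov(marg[[i]], marg[[j]])
      if (cm <= 1e-12) {
        .warnf("scalability: pair (%s, %s) skipped (zero maximal covariance)",
               colnames(X)[i], colnames(X)[j])
        next
      }
      cmax[i, j] <- cmax[j, i] <- cm
    }
  }
  Hij <- covs / cmax
  diag(Hij) <- NA_real_
  Hi <- vapply(seq_len(J), function(i) {
    ok <- !is.na(cmax[i, ])
    if (!any(ok)) return(NA_real_)
    sum(covs[i, ok]) / sum(cmax[i, ok])
  }, numeric(1))
  list(Hij = Hij,
       Hi = data.frame(item = colnames(X), H = Hi,
                       flagged = is.na(Hi) | Hi < minH,
                       stringsAsFactors = FALSE))
}

.stageRecord <- function(stage, entering, excludedIds, reason) {
  list(row = data.frame(stage = stage, entering = length(entering),
                        excluded = length(excludedIds),
                        surviving = length(entering) - length(excludedIds),
                        stringsAsFactors = FALSE),
       excl = data.frame(item = excludedIds,
                         reason = rep_len(reason, length(excludedIds)),
                         stringsAsFactors = FALSE))
}

.buildAudit <- function(records) {
  new("ScreeningAudit",
      stages = do.call(rbind, lapply(records, `[[`, "row")),
      exclusions = setNames(lapply(records, `[[`, "excl"),
                            vapply(records, function(r) r$row$stage,
                                   character(1))))
}

#' @rdname screeningAudit-accessors
#' @param x a [ScreeningAudit-class].
#' @export
setMethod("auditTable", "ScreeningAudit", function(x) x@stages)
#' @rdname screeningAudit-accessors
#' @export
setMethod("auditExclusions", "ScreeningAudit",
          function(x) do.call(rbind, unname(Map(function(nm, df) {
            if (nrow(df)) cbind(stage = nm, df) else NULL
          }, names(x@exclusions), x@exclusions))))

setMethod("show", "ScreeningAudit", function(object) {
  cat("ScreeningAudit\n")
  print(object@stages, row.names = FALSE)
  invisible(object)
})

#' Run the full item-screening funnel
#'
#' Stages in order: unanswered categories, item-remainder correlation, PCA
#' unidimensionality (iterative), residual correlations (single pass over
#' flagged pairs, dropping the lower-PCA-loading member), Loevinger
#' scalability.  Counts chain: entering - excluded = surviving at every
#' stage.
#'
#' @param responses a [ResponseMatrix-class].
#' @param bank optional [ItemBank-class] (category counts for the unanswered
#'   check).
#' @param config a [screeningConfig()].
#' @return list: \code{surviving} (character ids), \code{audit}
#'   ([ScreeningAudit-class]), \code{alpha} (Cronbach's alpha of the full
#'   entering set).  Errors with "bank exhausted" if fewer than 3 items
#'   survive.
#' @export
runScreening <- function(responses, bank = NULL,
                         config = screeningConfig()) {
  keep <- itemIds(responses)
  records <- list()
  alpha0 <- cronbachAlpha(responses)

  ua <- unansweredCategories(responses, bank)
  out <- ua$flagged$item[ua$flagged$flagged]
  records[[1L]] <- .stageRecord("unanswered_categories", keep, out,
                                "unanswered category")
  keep <- setdiff(keep, out)
  if (length(keep) < 3L) .stopf("bank exhausted during screening")

  ir <- itemRemainderCorrelations(responses[, keep], config$minItemRemainder)
  out <- ir$item[ir$flagged]
  records[[2L]] <- .stageRecord("item_remainder", keep, out,
                                sprintf("item-remainder r < %g",
                                        config$minItemRemainder))
  keep <- setdiff(keep, out)
  if (length(keep) < 3L) .stopf("bank exhausted during screening")

  pca <- pcaUnidimensionality(responses[, keep], config)
  records[[3L]] <- .stageRecord("pca_unidimensionality", keep, pca$excluded,
                                "low first-factor contribution")
  keep <- setdiff(keep, pca$excluded)
  if (length(keep) < 3L) .stopf("bank exhausted during screening")

  rc <- residualCorrelations(responses[, keep],
                             config$maxResidualCorrelation)
  pcaLoad <- abs(pca$loadings[keep])
  out <- character(0)
  if (nrow(rc$flaggedPairs)) {
    for (r in seq_len(nrow(rc$flaggedPairs))) {
      i1 <- rc$flaggedPairs$item1[r]; i2 <- rc$flaggedPairs$item2[r]
      if (i1 %in% out || i2 %in% out) next           # pair already resolved
      out <- c(out, if (pcaLoad[i1] <= pcaLoad[i2]) i1 else i2)
    }
  }
  records[[4L]] <- .stageRecord("residual_correlations", keep, out,
                                sprintf("residual correlation > %g",
                                        config$maxResidualCorrelation))
  keep <- setdiff(keep, out)
  if (length(keep) < 3L) .stopf("bank exhausted during screening")

  mk <- mokkenScalability(responses[, keep], config$minScalability)
  out <- mk$Hi$item[mk$Hi$flagged]
  records[[5L]] <- .stageRecord("scalability", keep, out,
                                sprintf("scalability H < %g",
                                        config$minScalability))
  keep <- setdiff(keep, out)
  if (length(keep) < 3L) .stopf("bank exhausted during screening")

  list(surviving = keep, audit = .buildAudit(records), alpha = alpha0)
}
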