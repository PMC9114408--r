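## S-X2 item fit: observed versus model-expected category frequencies within
## summed-score groups, the Orlando-Thissen statistic generalized to
## polytomous items.  The summed-score distribution of the remaining items
## is obtained by recursive convolution of category probabilities over the
## quadrature nodes.

## Convolve summed-score distributions item by item.  probs: list of K x Q
## matrices; returns (S+1) x Q matrix of P(score = s | theta_q), s = 0..S.
.scoreDistribution <- function(probs, Q) {
  f <- matrix(1, 1L, Q)
  for (P in probs) {
    K <- nrow(P)
    Sold <- nrow(f)
    fn <- matrix(0, Sold + K - 1L, Q)
    for (k in seq_len(K)) {
      rows <- (k - 1L) + seq_len(Sold)
      fn[rows, ] <- fn[rows, ] + f * matrix(P[k, ], Sold, Q, byrow = TRUE)
    }
    f <- fn
  }
  f
}

## Cell collapsing.  Within each score group, adjacent category cells with
## expected count < minE are merged; a group whose cells all merge into one
## carries no degrees of freedom, and such degenerate groups at the extremes
## are collapsed inward into their neighbor (the extreme summed scores are
## nearly deterministic, the Orlando-Thissen convention).  Returns the final
## observed/expected cell vectors and the per-group cell counts.
.mergeRowCells <- function(o, e, minE) {
  while (length(e) > 1L && any(e < minE)) {
    k <- which(e < minE)[1L]
    into <- if (k == 1L) 2L else k - 1L
    e[into] <- e[into] + e[k]; o[into] <- o[into] + o[k]
    e <- e[-k]; o <- o[-k]
  }
  list(o = o, e = e)
}

.collapseCells <- function(O, E, minE = 1) {
  degenerate <- function(e) {
    length(.mergeRowCells(numeric(length(e)), e, minE)$e) < 2L
  }
  while (nrow(E) > 1L && degenerate(E[1L, ])) {
    O[2L, ] <- O[2L, ] + O[1L, ]; E[2L, ] <- E[2L, ] + E[1L, ]
    O <- O[-1L, , drop = FALSE]; E <- E[-1L, , drop = FALSE]
  }
  while (nrow(E) > 1L && degenerate(E[nrow(E), ])) {
    m <- nrow(E)
    O[m - 1L, ] <- O[m - 1L, ] + O[m, ]; E[m - 1L, ] <- E[m - 1L, ] + E[m, ]
    O <- O[-m, , drop = FALSE]; E <- E[-m, , drop = FALSE]
  }
  obs <- exps <- list()
  for (g in seq_len(nrow(E))) {
    m <- .mergeRowCells(O[g, ], E[g, ], minE)
    obs[[g]] <- m$o; exps[[g]] <- m$e
  }
  list(O = unlist(obs), E = unlist(exps),
       cellsPerGroup = lengths(exps), nGroups = nrow(E))
}

#' S-X2 item fit statistics
#'
#' For each item, compares observed category frequencies within summed-score
#' groups to their model-expected values under the calibrated graded
#' response model.  Expected frequencies condition on the total score via
#' the recursive summed-score convolution of the remaining items.  Adjacent
#' score groups (and, within a group, adjacent category cells) with expected
#' count below 1 are collapsed from the extremes inward; the degrees of
#' freedom are the independent cells after collapsing (cells minus one per
#' score group) minus the number of item parameters.
#'
#' Persons with any missing response are dropped (the summed score is
#' undefined for them).  Items with fewer than two usable score groups, or
#' non-positive degrees of freedom after collapsing, are skipped with a
#' warning.
#'
#' @param responses a [ResponseMatrix-class].
#' @param bank the calibrated [ItemBank-class] (same items).
#' @param alpha flag threshold on the p-value (default 0.01).
#' @param grid quadrature from [quadratureGrid()].
#' @return data.frame with columns item, statistic, df, p, flagged.
#' @export
sx2ItemFit <- function(responses, bank, alpha = 0.01,
                       grid = quadratureGrid()) {
  X <- responseCodes(responses)
  idx <- match(colnames(X), itemIds(bank))
  if (anyNA(idx)) .stopf("bank is missing response item(s)")
  bank <- bank[idx]
  cc <- complete.cases(X)
  if (!all(cc)) {
    .warnf("S-X2: dropping %d person(s) with missing responses", sum(!cc))
    X <- X[cc, , drop = FALSE]
  }
  J <- ncol(X)
  K <- bank@nCategories
  nodes <- grid$nodes; wts <- grid$weights; Q <- length(nodes)
  probs <- .bankProbs(bank, nodes)
  total <- as.integer(rowSums(X - 1L))
  res <- data.frame(item = colnames(X), statistic = NA_real_, df = NA_real_,
                    p = NA_real_, flagged = NA, stringsAsFactors = FALSE)
  for (j in seq_len(J)) {
    frest <- .scoreDistribution(probs[-j], Q)       # (Srest+1) x Q
    Srest <- nrow(frest) - 1L
    Smax <- Srest + K[j] - 1L
    ## N[s+1, k] = sum_q w_q p_jk(q) frest(s - (k-1) | q)
    N <- matrix(0, Smax + 1L, K[j])
    for (k in seq_len(K[j])) {
      N[(k - 1L) + seq_len(Srest + 1L), k] <-
        frest %*% (wts * probs[[j]][k, ])
    }
    D <- rowSums(N)
    ns <- tabulate(total + 1L, nbins = Smax + 1L)
    keep <- which(ns > 0L & D > 0)
    if (length(keep) < 2L) {
      .warnf("S-X2: item '%s' skipped (fewer than 2 usable score groups)",
             colnames(X)[j])
      next
    }
    E <- N[keep, , drop = FALSE] / D[keep] * ns[keep]
    O <- matrix(0, length(keep), K[j])
    for (r in seq_along(keep)) {
      s <- keep[r] - 1L
      O[r, ] <- tabulate(X[total == s, j], nbins = K[j])
    }
    cl <- .collapseCells(O, E)
    df <- length(cl$E) - cl$nGroups - (K[j])        # K-1 thresholds + a
    if (cl$nGroups < 2L || df < 1) {
      .warnf("S-X2: item '%s' skipped (df < 1 after collapsing)",
             colnames(X)[j])
      next
    }
    stat <- sum((cl$O - cl$E)^2 / cl$E)
    res$statistic[j] <- stat
    res$df[j] <- df
    res$p[j] <- pchisq(stat, df, lower.tail = FALSE)
    res$flagged[j] <- res$p[j] < alpha
  }
  res
}
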