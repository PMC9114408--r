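#' Quadrature grid over the latent trait
#'
#' Equally spaced nodes with standard-normal weights renormalized to sum to
#' one; used for marginal likelihoods, EAP scoring and posterior moments.
#'
#' @param n number of nodes (default 61).
#' @param range support (default \code{c(-6, 6)}; also the clamping range for
#'   modal estimators).
#' @return list with components \code{nodes} and \code{weights}.
#' @export
quadratureGrid <- function(n = 61L, range = c(-6, 6)) {
  stopifnot(n >= 3L, length(range) == 2L, range[1L] < range[2L])
  nodes <- seq(range[1L], range[2L], length.out = n)
  w <- dnorm(nodes)
  list(nodes = nodes, weights = w / sum(w))
}

#' Graded response model category probabilities
#'
#' Cumulative ("operating") curves are \eqn{P^*_k(\theta) =
#' \mathrm{logistic}(a(\theta - b_{k-1}))} for categories \eqn{k = 2..K}
#' (with \eqn{P^*_1 = 1} and \eqn{P^*_{K+1} = 0}); the probability of
#' category \eqn{k} is \eqn{P^*_k - P^*_{k+1}}.  Logistic metric, D = 1.
#'
#' @param a discrimination (> 0).
#' @param b strictly increasing thresholds, length K - 1.
#' @param theta numeric vector of trait values.
#' @return matrix \code{length(theta) x K}; rows sum to 1.
#' @examples
#' categoryProbs(3.32, c(0.93, 1.84, 2.32, 3.33), theta = 0.93)
#' @export
categoryProbs <- function(a, b, theta) {
  C <- plogis(a * outer(theta, b, "-"))           # n x (K-1), decreasing in k
  p <- cbind(1, C) - cbind(C, 0)
  p[p < 0] <- 0                                    # guard fp round-off
  dimnames(p) <- NULL
  p
}

## Per-item probability matrices (K x Q) over quadrature nodes, as a list.
.bankProbs <- function(bank, nodes) {
  lapply(seq_len(nItems(bank)), function(j) {
    t(categoryProbs(bank@a[j], bank@thresholds[[j]], nodes))
  })
}

#' Fisher information of one item
#'
#' \eqn{I(\theta) = \sum_k (\partial P_k / \partial \theta)^2 / P_k}, with
#' \eqn{\partial P_k/\partial\theta = a[P^*_k(1-P^*_k) -
#' P^*_{k+1}(1-P^*_{k+1})]}.
#'
#' @inheritParams categoryProbs
#' @return numeric vector, one non-negative value per theta.
#' @export
itemInformation <- function(a, b, theta) {
  C <- plogis(a * outer(theta, b, "-"))
  V <- C * (1 - C)                                 # P*(1-P*) for inner bounds
  dP <- a * (cbind(0, V) - cbind(V, 0))            # d p_k / d theta
  p <- cbind(1, C) - cbind(C, 0)
  rowSums(dP^2 / pmax(p, .PFLOOR))
}

#' Test information of a bank
#'
#' Pointwise sum of [itemInformation()] over (a subset of) the bank's items.
#'
#' @param bank an [ItemBank-class].
#' @param theta numeric vector.
#' @param items optional item ids or indices.
#' @return numeric vector, one value per theta.
#' @export
testInformation <- function(bank, theta, items = NULL) {
  if (!is.null(items)) bank <- bank[items]
  info <- numeric(length(theta))
  for (j in seq_len(nItems(bank))) {
    info <- info + itemInformation(bank@a[j], bank@thresholds[[j]], theta)
  }
  info
}

#' Categories that are never the most probable response
#'
#' Scans a fine theta grid for categories that are not the modal response at
#' any node; items with such categories have degenerate category response
#' curves and are excluded during bank development.  Ties go to the lowest
#' category index.
#'
#' @inheritParams categoryProbs
#' @param grid theta scan grid (default 0.01 spacing on [-6, 6]).
#' @return integer vector of never-maximal category indices (possibly empty).
#' @export
categoryMaximality <- function(a, b, grid = seq(-6, 6, by = 0.01)) {
  p <- categoryProbs(a, b, grid)
  maximal <- unique(max.col(p, ties.method = "first"))
  setdiff(seq_len(ncol(p)), maximal)
}
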