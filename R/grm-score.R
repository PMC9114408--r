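#' Score latent traits from item responses
#'
#' Three estimators of the latent trait for each person:
#' \describe{
#'   \item{MLE}{maximum likelihood on the support (default [-6, 6]); when
#'     the likelihood is monotone (e.g. every response in an extreme
#'     category) the estimate is clamped to the support edge and flagged.
#'     SEM = \eqn{1/\sqrt{I(\hat\theta)}}.}
#'   \item{BME}{Bayesian modal (MAP) under a N(0,1) prior.
#'     SEM = \eqn{1/\sqrt{I(\hat\theta) + 1}}, the prior contributing one
#'     unit of precision.}
#'   \item{EAP}{posterior mean by quadrature; SEM = posterior standard
#'     deviation.}
#' }
#' With zero answered items the Bayesian estimators return the prior:
#' theta 0, SEM 1 (MLE is undefined and returns NA with infinite SEM).
#'
#' @param responses a [ResponseMatrix-class], or a named integer vector of
#'   1-based codes for a single person (names = item ids).
#' @param bank an [ItemBank-class] covering the answered items.
#' @param method "EAP", "BME" (alias "MAP") or "MLE".
#' @param grid quadrature from [quadratureGrid()]; its range is also the
#'   MLE/BME search support.
#' @return data.frame with columns person, theta, sem, method, boundary.
#' @examples
#' b <- itemBank(c("I1", "I2"), a = c(2, 2),
#'               thresholds = list(c(-1, 0, 1, 2), c(0, 1, 2, 3)))
#' scoreTheta(c(I1 = 3L, I2 = 2L), b, method = "EAP")
#' @export
scoreTheta <- function(responses, bank, method = c("EAP", "BME", "MAP", "MLE"),
                       grid = quadratureGrid()) {
  method <- match.arg(method)
  if (method == "MAP") method <- "BME"
  if (!is(responses, "ResponseMatrix")) {
    x <- responses
    if (is.null(names(x))) .stopf("single-person responses need item names")
    m <- matrix(as.integer(x), nrow = 1L,
                dimnames = list("p1", names(x)))
    responses <- new("ResponseMatrix", data = m,
                     nCategories = bank@nCategories[match(names(x), bank@id)],
                     offset = rep(0L, length(x)))
  }
  X <- responseCodes(responses)
  idx <- match(colnames(X), itemIds(bank))
  if (anyNA(idx)) .stopf("bank is missing item(s): %s",
                         paste(colnames(X)[is.na(idx)], collapse = ", "))
  sub <- bank[idx]
  n <- nrow(X)
  out <- data.frame(person = rownames(X), theta = NA_real_, sem = NA_real_,
                    method = method, boundary = FALSE,
                    stringsAsFactors = FALSE)
  nodes <- grid$nodes
  support <- range(nodes)

  if (method == "EAP") {
    logP <- lapply(seq_len(nItems(sub)), function(j) {
      t(log(pmax(categoryProbs(sub@a[j], sub@thresholds[[j]], nodes),
                 .PFLOOR)))
    })
    es <- .estep(X, logP, log(grid$weights))
    m1 <- as.numeric(es$post %*% nodes)
    m2 <- as.numeric(es$post %*% nodes^2)
    out$theta <- m1
    out$sem <- sqrt(pmax(m2 - m1^2, 0))
    none <- rowSums(!is.na(X)) == 0L
    out$theta[none] <- 0
    out$sem[none] <- 1
    return(out)
  }

  for (i in seq_len(n)) {
    x <- X[i, ]
    ans <- which(!is.na(x))
    if (!length(ans)) {
      if (method == "BME") { out$theta[i] <- 0; out$sem[i] <- 1 }
      else { out$theta[i] <- NA_real_; out$sem[i] <- Inf }
      next
    }
    ll <- function(theta) {
      v <- 0
      for (j in ans) {
        v <- v + log(pmax(
          categoryProbs(sub@a[j], sub@thresholds[[j]], theta)[, x[j]],
          .PFLOOR))
      }
      if (method == "BME") v - theta^2 / 2 else v
    }
    opt <- optimize(ll, interval = support, maximum = TRUE, tol = 1e-6)
    cand <- c(opt$maximum, support)
    vals <- c(opt$objective, ll(support[1L]), ll(support[2L]))
    best <- which.max(vals)
    th <- cand[best]
    out$theta[i] <- th
    out$boundary[i] <- best > 1L
    info <- testInformation(sub, th, items = ans)
    out$sem[i] <- if (method == "BME") 1 / sqrt(info + 1) else
      1 / sqrt(max(info, .PFLOOR))
  }
  out
}
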