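## Synthetic cohorts with known ground truth.
##
## The generator emulates the study conditions this package was built
## around: roughly 393 respondents answering 62 five-category items about
## depressive symptoms, with low average severity (mean item score around
## 1.4 of 5), item discriminations in about [1.5, 3.4], first thresholds in
## about [0.0, 1.6] and last thresholds in about [2.5, 4.4] -- a regime in
## which the top categories of harder items are rarely (sometimes never)
## endorsed.  Randomness uses R's default Mersenne-Twister stream; every
## operation takes or derives an explicit seed, so output is fully
## reproducible across platforms.

#' Specification of a synthetic cohort
#'
#' @param nPersons number of respondents (default 393).
#' @param nItems number of five-category bank items (default 62).
#' @param thetaDistribution "skewed-mixture" (default) or "standard-normal".
#'   The default severity distribution is the two-component normal mixture
#'   0.75 N(-0.6, 0.8^2) + 0.25 N(0.8, 1^2), which paired with the default
#'   bank yields a mean item score near 1.4/5 and rare top-category
#'   endorsement.
#' @param mixtureWeights,mixtureMeans,mixtureSds mixture components (weights
#'   must sum to 1).
#' @param aRange discrimination range (default c(1.5, 3.4)).
#' @param b1Range first-threshold range (default c(0.0, 1.6)).
#' @param bLastRange last-threshold range (default c(2.5, 4.4)).
#' @param nCategories response categories per bank item (default 5).
#' @param seed master seed (default 20220517).
#' @return validated list of class "CohortSpec".
#' @export
cohortSpec <- function(nPersons = 393L, nItems = 62L,
                       thetaDistribution = c("skewed-mixture",
                                             "standard-normal"),
                       mixtureWeights = c(0.75, 0.25),
                       mixtureMeans = c(-0.6, 0.8),
                       mixtureSds = c(0.8, 1),
                       aRange = c(1.5, 3.4),
                       b1Range = c(0.0, 1.6),
                       bLastRange = c(2.5, 4.4),
                       nCategories = 5L,
                       seed = 20220517L) {
  thetaDistribution <- match.arg(thetaDistribution)
  stopifnot(.is_count(nPersons), .is_count(nItems), nItems >= 1,
            nCategories >= 2)
  if (thetaDistribution == "skewed-mixture") {
    if (length(mixtureWeights) != length(mixtureMeans) ||
        length(mixtureWeights) != length(mixtureSds)) {
      .stopf("mixture weights, means and sds must have equal length")
    }
    if (abs(sum(mixtureWeights) - 1) > 1e-8 || any(mixtureWeights < 0)) {
      .stopf("mixture weights must be non-negative and sum to 1")
    }
    if (any(mixtureSds <= 0)) .stopf("mixture sds must be positive")
  }
  for (rng in list(aRange, b1Range, bLastRange)) {
    if (length(rng) != 2L || rng[1L] > rng[2L]) {
      .stopf("ranges must be ordered pairs")
    }
  }
  if (b1Range[2L] >= bLastRange[1L]) {
    .stopf("b1Range must lie entirely below bLastRange")
  }
  structure(list(
    nPersons = as.integer(nPersons), nItems = as.integer(nItems),
    thetaDistribution = thetaDistribution,
    mixtureWeights = mixtureWeights, mixtureMeans = mixtureMeans,
    mixtureSds = mixtureSds, aRange = aRange, b1Range = b1Range,
    bLastRange = bLastRange, nCategories = as.integer(nCategories),
    seed = as.integer(seed)), class = "CohortSpec")
}

#' Draw latent severities for a cohort
#'
#' @param spec a [cohortSpec()].
#' @param seed optional override of the cohort spec's theta substream seed.
#' @return numeric vector of length \code{nPersons}.
#' @export
drawThetas <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(if (is.null(seed)) .substream(spec$seed, "thetas") else seed)
  n <- spec$nPersons
  if (spec$thetaDistribution == "standard-normal") return(rnorm(n))
  cmp <- sample.int(length(spec$mixtureWeights), n, replace = TRUE,
                    prob = spec$mixtureWeights)
  rnorm(n, spec$mixtureMeans[cmp], spec$mixtureSds[cmp])
}

#' Generate a study-like item bank with known parameters
#'
#' Discriminations are uniform on \code{aRange}; the first and last
#' thresholds are uniform on \code{b1Range} and \code{bLastRange}, and the
#' interior thresholds are sorted uniform draws strictly between them.
#'
#' @param spec a [cohortSpec()].
#' @param seed optional override of the bank substream seed.
#' @return list with components \code{bank} ([ItemBank-class]) and
#'   \code{truth} (list: \code{params} copy of the generating bank,
#'   \code{violations} empty registry).
#' @export
generateBank <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(if (is.null(seed)) .substream(spec$seed, "bank") else seed)
  J <- spec$nItems; K <- spec$nCategories
  a <- runif(J, spec$aRange[1L], spec$aRange[2L])
  b <- lapply(seq_len(J), function(j) {
    b1 <- runif(1, spec$b1Range[1L], spec$b1Range[2L])
    if (K == 2L) return(b1)
    bK <- runif(1, spec$bLastRange[1L], spec$bLastRange[2L])
    if (K == 3L) return(c(b1, bK))
    ## interior thresholds: sorted uniform draws, re-drawn a few times to
    ## keep gaps above a minimum so that fully degenerate category curves
    ## (every interior category never modal) stay the exception rather
    ## than the rule, as in real symptom banks
    gap <- min(0.35, (bK - b1) / (K - 1L) * 0.9)
    for (try in 1:40) {
      inner <- sort(runif(K - 3L, b1, bK))
      if (all(diff(c(b1, inner, bK)) >= gap)) break
    }
    if (any(diff(c(b1, inner, bK)) < gap)) {
      inner <- b1 + seq_len(K - 3L) * (bK - b1) / (K - 2L)
    }
    c(b1, inner, bK)
  })
  ids <- sprintf("I%02d", seq_len(J))
  bank <- itemBank(ids, a = a, thresholds = b,
                   text = sprintf("Synthetic depressive-symptom item %d",
                                  seq_len(J)))
  list(bank = bank,
       truth = list(params = bank, violations = .emptyViolations()))
}

.emptyViolations <- function() {
  data.frame(item = character(), kind = character(), detail = character(),
             stringsAsFactors = FALSE)
}

#' Simulate graded responses at given severities
#'
#' Each response is drawn from the item's graded-response category
#' distribution at the person's theta.
#'
#' @param bank an [ItemBank-class].
#' @param thetas numeric vector of latent severities.
#' @param seed integer seed.
#' @return a [ResponseMatrix-class] (\code{length(thetas)} x
#'   \code{nItems(bank)}).
#' @export
simulateResponses <- function(bank, thetas, seed) {
  validObject(bank)
  set.seed(seed)
  n <- length(thetas); J <- nItems(bank)
  m <- matrix(NA_integer_, n, J,
              dimnames = list(sprintf("P%03d", seq_len(n)), itemIds(bank)))
  for (j in seq_len(J)) {
    p <- categoryProbs(bank@a[j], bank@thresholds[[j]], thetas)
    cp <- p %*% upper.tri(diag(ncol(p)), diag = TRUE)  # row cumsums
    u <- runif(n)
    m[, j] <- 1L + as.integer(rowSums(u > cp[, -ncol(cp), drop = FALSE]))
  }
  new("ResponseMatrix", data = m, nCategories = bank@nCategories,
      offset = bank@offset)
}

#' Inject known assumption violations into a synthetic cohort
#'
#' Violations are opt-in and recorded in the returned truth registry, never
#' silent.  Kinds:
#' \describe{
#'   \item{local_dependence}{one item pair is regenerated with a shared
#'     binary nuisance factor: both items respond to
#'     \eqn{\theta + \gamma(u - 1/2)}, \eqn{u \sim} Bernoulli(1/2) shared
#'     within person (default \eqn{\gamma = 2}), inducing residual
#'     correlation after a one-factor fit.}
#'   \item{dif}{one item's thresholds are shifted by +0.5 for a randomly
#'     labeled focal half of the cohort, whose responses to that item are
#'     regenerated; group labels are returned.}
#'   \item{nonmonotone}{one item's responses are regenerated from a
#'     non-monotone response function (the graded model evaluated at
#'     \eqn{0.5 - |\theta|}, a unimodal severity profile).}
#'   \item{low_discrimination}{one item is regenerated with a = 0.2.}
#' }
#'
#' @param bank generating [ItemBank-class].
#' @param responses the clean [ResponseMatrix-class] from the same bank and
#'   thetas.
#' @param thetas the generating severities.
#' @param kinds character subset of the four kinds above (empty = no-op).
#' @param items optional named character vector/list mapping kinds to target
#'   item ids (for \code{local_dependence}, the first item of the pair; its
#'   partner is the next item in the bank).  Defaults are spread over the
#'   bank.
#' @param seed integer seed.
#' @param gamma nuisance-factor strength for local dependence (default 2).
#' @param difShift threshold shift for the focal group (default 0.5).
#' @return list: \code{responses} (modified), \code{bank} (modified where a
#'   violation changes parameters), \code{truth} (violation registry),
#'   \code{groups} (factor, only when "dif" requested).
#' @export
injectViolations <- function(bank, responses, thetas, kinds, items = NULL,
                             seed = 1L, gamma = 2, difShift = 0.5) {
  kinds <- unique(as.character(kinds))
  known <- c("local_dependence", "dif", "nonmonotone", "low_discrimination")
  bad <- setdiff(kinds, known)
  if (length(bad)) .stopf("unknown violation kind(s): %s",
                          paste(bad, collapse = ", "))
  X <- responseCodes(responses)
  ids <- colnames(X)
  J <- length(ids)
  if (length(kinds) && J < length(kinds) + 1L) {
    .stopf("bank too small to host the requested violations")
  }
  set.seed(seed)
  ## default targets: spread across the bank, no overlaps
  pick <- setNames(ids[round(seq(1L, J - 1L, length.out = max(1L, length(known))))
                       ][seq_along(known)], known)
  if (!is.null(items)) pick[names(items)] <- unlist(items)
  reg <- .emptyViolations()
  groups <- NULL
  newBank <- bank
  drawItem <- function(a, b, th) {
    p <- categoryProbs(a, b, th)
    cp <- p %*% upper.tri(diag(ncol(p)), diag = TRUE)
    u <- runif(length(th))
    1L + as.integer(rowSums(u > cp[, -ncol(cp), drop = FALSE]))
  }
  for (kind in kinds) {
    it <- pick[[kind]]
    j <- match(it, ids)
    if (is.na(j)) .stopf("violation target '%s' not in the bank", it)
    jb <- match(it, itemIds(bank))
    a <- bank@a[jb]; b <- bank@thresholds[[jb]]
    if (kind == "local_dependence") {
      j2 <- if (j < J) j + 1L else j - 1L
      jb2 <- match(ids[j2], itemIds(bank))
      u <- rbinom(nrow(X), 1L, 0.5)
      shifted <- thetas + gamma * (u - 0.5)
      X[, j] <- drawItem(a, b, shifted)
      X[, j2] <- drawItem(bank@a[jb2], bank@thresholds[[jb2]], shifted)
      reg <- rbind(reg, data.frame(
        item = c(it, ids[j2]), kind = kind,
        detail = sprintf("shared binary nuisance, gamma=%g", gamma)))
    } else if (kind == "dif") {
      groups <- factor(ifelse(runif(nrow(X)) < 0.5, "focal", "reference"),
                       levels = c("reference", "focal"))
      foc <- groups == "focal"
      X[foc, j] <- drawItem(a, b + difShift, thetas[foc])
      reg <- rbind(reg, data.frame(
        item = it, kind = kind,
        detail = sprintf("focal thresholds shifted by +%g", difShift)))
    } else if (kind == "nonmonotone") {
      X[, j] <- drawItem(a, b, 0.5 - abs(thetas))
      reg <- rbind(reg, data.frame(
        item = it, kind = kind, detail = "unimodal response function"))
    } else {                                         # low_discrimination
      newBank@a[jb] <- 0.2
      X[, j] <- drawItem(0.2, b, thetas)
      reg <- rbind(reg, data.frame(
        item = it, kind = kind, detail = "regenerated with a = 0.2"))
    }
  }
  out <- new("ResponseMatrix", data = X, nCategories = responses@nCategories,
             offset = responses@offset)
  list(responses = out, bank = newBank,
       truth = list(params = newBank, violations = reg), groups = groups)
}

#' Generate a complete study-like dataset
#'
#' Draws severities, a 62-item five-category bank, joint responses, and a
#' co-administered 9-item legacy short form (four categories, 0-3 raw
#' coding) loading on the same latent trait, plus age/sex-like group labels
#' that are independent of severity (so a DIF analysis on them is a true
#' null).  The default seed is fixed so the default dataset is stable.
#'
#' @param spec a [cohortSpec()].
#' @return list: \code{responses}, \code{bank}, \code{truth} (thetas, both
#'   generating banks, empty violation registry), \code{legacyResponses},
#'   \code{legacyBank}, \code{groups} (data.frame person/ageGroup/sex).
#' @export
makeStudyCohort <- function(spec = cohortSpec()) {
  stopifnot(inherits(spec, "CohortSpec"))
  thetas <- drawThetas(spec)
  gb <- generateBank(spec)
  responses <- simulateResponses(gb$bank, thetas,
                                 seed = .substream(spec$seed, "responses"))
  ## legacy 9-item short form: 4 categories, moderately discriminating
  set.seed(.substream(spec$seed, "legacy-bank"))
  aL <- runif(9L, 1.3, 2.8)
  bL <- lapply(seq_len(9L), function(j) {
    b1 <- runif(1, 0.3, 1.5); b3 <- runif(1, 1.8, 3.2)
    c(b1, runif(1, b1, b3), b3)
  })
  legacyBank <- itemBank(sprintf("L%d", 1:9), a = aL, thresholds = bL,
                         text = sprintf("Synthetic legacy item %d", 1:9),
                         offset = 1L)
  legacyResponses <- simulateResponses(
    legacyBank, thetas, seed = .substream(spec$seed, "legacy-resp"))
  set.seed(.substream(spec$seed, "groups"))
  n <- spec$nPersons
  groups <- data.frame(
    person = personIds(responses),
    ageGroup = factor(ifelse(runif(n) < 0.5, "under65", "over65"),
                      levels = c("under65", "over65")),
    sex = factor(ifelse(runif(n) < 0.67, "male", "female"),
                 levels = c("male", "female")),
    stringsAsFactors = FALSE)
  list(responses = responses, bank = gb$bank,
       truth = list(thetas = thetas, params = gb$bank,
                    legacyParams = legacyBank,
                    violations = .emptyViolations()),
       legacyResponses = legacyResponses, legacyBank = legacyBank,
       groups = groups)
}
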