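## Internal helpers shared across modules.

#' @importFrom stats plogis dnorm qlogis pchisq cor cov var complete.cases
#'   optimize nlminb runif rnorm rbinom approx lowess factanal setNames
#'   quantile
#' @importFrom methods new validObject is slot
#' @importFrom utils read.csv write.csv head
NULL

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Probabilities are floored before taking logs; 1e-300 keeps log() finite
## without perturbing any quantity at double precision.
.PFLOOR <- 1e-300

## Derive a reproducible substream seed from a master seed and a stage label.
## Must stay below 2^31 - 1 (R integers are 32-bit).
.substream <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

.is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == round(x) && x >= 0
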