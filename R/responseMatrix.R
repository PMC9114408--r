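#' Construct a response matrix
#'
#' @param data numeric matrix of category codes, 1-based, persons in rows and
#'   items in columns (dimnames required; missing responses as NA).
#' @param nCategories integer, categories per item; a scalar is recycled.
#'   Defaults to the maximum observed code per column (at least 2), which is
#'   only safe when every category was endorsed.
#' @param offset integer raw-code offset per item (see [ItemBank-class]);
#'   recycled.
#'
#' @return A [ResponseMatrix-class].
#' @export
responseMatrix <- function(data, nCategories = NULL, offset = 0L) {
  data <- as.matrix(data)
  storage.mode(data) <- "integer"
  if (is.null(rownames(data))) rownames(data) <- paste0("P", seq_len(nrow(data)))
  if (is.null(colnames(data))) colnames(data) <- paste0("I", seq_len(ncol(data)))
  if (is.null(nCategories)) {
    nCategories <- pmax(apply(data, 2L, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) max(v) else 2L
    }), 2L)
  }
  new("ResponseMatrix", data = data,
      nCategories = as.integer(rep_len(nCategories, ncol(data))),
      offset = as.integer(rep_len(offset, ncol(data))))
}

#' Accessors for ResponseMatrix objects
#'
#' @param x a [ResponseMatrix-class].
#' @return Person/item ids, counts, or the internal 1-based integer matrix.
#' @name responseMatrix-accessors
NULL

#' @rdname responseMatrix-accessors
#' @export
setMethod("nPersons", "ResponseMatrix", function(x) nrow(x@data))
#' @rdname responseMatrix-accessors
#' @export
setMethod("personIds", "ResponseMatrix", function(x) rownames(x@data))
#' @rdname responseMatrix-accessors
#' @export
setMethod("itemIds", "ResponseMatrix", function(x) colnames(x@data))
#' @rdname responseMatrix-accessors
#' @export
setMethod("nItems", "ResponseMatrix", function(x) ncol(x@data))
#' @rdname responseMatrix-accessors
#' @export
setMethod("nCategories", "ResponseMatrix",
          function(x) setNames(x@nCategories, colnames(x@data)))
#' @rdname responseMatrix-accessors
#' @export
setMethod("codeOffset", "ResponseMatrix",
          function(x) setNames(x@offset, colnames(x@data)))
#' @rdname responseMatrix-accessors
#' @export
setMethod("responseCodes", "ResponseMatrix", function(x) x@data)

#' @describeIn ResponseMatrix subset persons (i) and/or items (j)
#' @param x,i,j the matrix and person/item indices (numeric, logical or ids).
#' @aliases [,ResponseMatrix-method
#' @export
setMethod("[", "ResponseMatrix", function(x, i, j) {
  if (missing(i)) i <- seq_len(nrow(x@data))
  if (missing(j)) j <- seq_len(ncol(x@data))
  if (is.character(j)) j <- match(j, colnames(x@data))
  if (anyNA(j)) .stopf("unknown item id in subset")
  new("ResponseMatrix", data = x@data[i, j, drop = FALSE],
      nCategories = x@nCategories[j], offset = x@offset[j])
})

setMethod("show", "ResponseMatrix", function(object) {
  cat(sprintf("ResponseMatrix: %d person(s) x %d item(s)\n",
              nrow(object@data), ncol(object@data)))
  nmiss <- sum(is.na(object@data))
  cat(sprintf("  categories per item: %s; missing cells: %d (%.1f%%)\n",
              paste(sort(unique(object@nCategories)), collapse = ", "),
              nmiss, 100 * nmiss / max(1L, length(object@data))))
  invisible(object)
})
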