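#' Construct an item bank
#'
#' @param id character vector of unique item ids.
#' @param a numeric vector of discriminations (> 0).
#' @param thresholds list of strictly increasing numeric threshold vectors
#'   (one per item), or a single numeric vector recycled structure-wise for
#'   a one-item bank.
#' @param text optional item stems; defaults to the ids.
#' @param offset integer raw-code offset per item (0 for 1-based input
#'   coding, 1 for 0-based legacy coding); recycled.
#'
#' @return An [ItemBank-class].
#' @examples
#' b <- itemBank("I1", a = 3.32, thresholds = list(c(0.93, 1.84, 2.32, 3.33)))
#' discrimination(b)
#' @export
itemBank <- function(id, a, thresholds, text = id, offset = 0L) {
  if (is.numeric(thresholds)) thresholds <- list(thresholds)
  nc <- as.integer(lengths(thresholds) + 1L)
  new("ItemBank",
      id = as.character(id), text = as.character(text),
      nCategories = nc,
      offset = as.integer(rep_len(offset, length(id))),
      a = as.numeric(a),
      thresholds = lapply(thresholds, as.numeric))
}

#' Accessors for ItemBank objects
#'
#' @param x an [ItemBank-class] (or, where it applies, a
#'   [ResponseMatrix-class]).
#' @return The corresponding component: ids, stems, discriminations,
#'   threshold list, category counts, code offsets, or item count.
#' @name itemBank-accessors
NULL

#' @rdname itemBank-accessors
#' @export
setMethod("itemIds", "ItemBank", function(x) x@id)
#' @rdname itemBank-accessors
#' @export
setMethod("itemText", "ItemBank", function(x) setNames(x@text, x@id))
#' @rdname itemBank-accessors
#' @export
setMethod("discrimination", "ItemBank", function(x) setNames(x@a, x@id))
#' @rdname itemBank-accessors
#' @export
setMethod("thresholds", "ItemBank", function(x) setNames(x@thresholds, x@id))
#' @rdname itemBank-accessors
#' @export
setMethod("nCategories", "ItemBank", function(x) setNames(x@nCategories, x@id))
#' @rdname itemBank-accessors
#' @export
setMethod("codeOffset", "ItemBank", function(x) setNames(x@offset, x@id))
#' @rdname itemBank-accessors
#' @export
setMethod("nItems", "ItemBank", function(x) length(x@id))

#' @describeIn ItemBank subset a bank by index, id or logical mask
#' @param x,i bank and index.
#' @aliases [,ItemBank-method
#' @export
setMethod("[", "ItemBank", function(x, i) {
  if (is.character(i)) {
    miss <- setdiff(i, x@id)
    if (length(miss)) .stopf("unknown item id(s): %s",
                             paste(miss, collapse = ", "))
    i <- match(i, x@id)
  }
  new("ItemBank", id = x@id[i], text = x@text[i],
      nCategories = x@nCategories[i], offset = x@offset[i],
      a = x@a[i], thresholds = x@thresholds[i])
})

setMethod("show", "ItemBank", function(object) {
  cat(sprintf("ItemBank with %d item(s)\n", length(object@id)))
  if (length(object@id)) {
    cat(sprintf("  categories: %s\n",
                paste(sort(unique(object@nCategories)), collapse = ", ")))
    cat(sprintf("  discrimination range: [%.3f, %.3f]\n",
                min(object@a), max(object@a)))
    b1 <- vapply(object@thresholds, `[`, numeric(1), 1L)
    bl <- vapply(object@thresholds, function(b) b[length(b)], numeric(1))
    cat(sprintf("  first/last threshold ranges: [%.3f, %.3f] / [%.3f, %.3f]\n",
                min(b1), max(b1), min(bl), max(bl)))
  }
  invisible(object)
})
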