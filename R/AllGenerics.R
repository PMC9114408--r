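## Generics for the accessor surface.  Slot access from user code is
## discouraged; these are the supported entry points.

#' @rdname itemBank-accessors
#' @export
setGeneric("itemIds", function(x) standardGeneric("itemIds"))

#' @rdname itemBank-accessors
#' @export
setGeneric("itemText", function(x) standardGeneric("itemText"))

#' @rdname itemBank-accessors
#' @export
setGeneric("discrimination", function(x) standardGeneric("discrimination"))

#' @rdname itemBank-accessors
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname itemBank-accessors
#' @export
setGeneric("nCategories", function(x) standardGeneric("nCategories"))

#' @rdname itemBank-accessors
#' @export
setGeneric("codeOffset", function(x) standardGeneric("codeOffset"))

#' @rdname itemBank-accessors
#' @export
setGeneric("nItems", function(x) standardGeneric("nItems"))

#' @rdname responseMatrix-accessors
#' @export
setGeneric("nPersons", function(x) standardGeneric("nPersons"))

#' @rdname responseMatrix-accessors
#' @export
setGeneric("personIds", function(x) standardGeneric("personIds"))

#' @rdname responseMatrix-accessors
#' @export
setGeneric("responseCodes", function(x) standardGeneric("responseCodes"))

#' @rdname screeningAudit-accessors
#' @export
setGeneric("auditTable", function(x) standardGeneric("auditTable"))

#' @rdname screeningAudit-accessors
#' @export
setGeneric("auditExclusions", function(x) standardGeneric("auditExclusions"))
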