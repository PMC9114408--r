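## File formats
##
## Bank CSV:   header id,text,a,b1,...,bK-1 (trailing b columns blank for
##             items with fewer categories), optional column 'offset'.
## Bank JSON:  array of {id, text, a, b: [...], offset}.
## Responses:  wide CSV, first column person_id, one column per item; cells
##             hold raw category codes (offset applied on read).

#' Read an item bank from CSV or JSON
#'
#' @param path file path.
#' @param format "auto" (by extension), "csv" or "json".
#' @param offset default raw-code offset for files without an offset column.
#' @return An [ItemBank-class]; malformed rows raise an error naming the item
#'   and the violated invariant (e.g. "thresholds not increasing").
#' @examples
#' path <- system.file("extdata", "example_bank.csv", package = "catgrm")
#' bank <- readItemBank(path)
#' discrimination(bank)
#' @export
readItemBank <- function(path, format = c("auto", "csv", "json"),
                         offset = 0L) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("no such file: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (!length(recs)) .stopf("no items in %s", path)
    df <- data.frame(
      id = vapply(recs, function(r) as.character(r$id), character(1)),
      text = vapply(recs, function(r) as.character(r$text %||% r$id),
                    character(1)),
      a = vapply(recs, function(r) as.numeric(r$a), numeric(1)),
      offset = vapply(recs, function(r) as.integer(r$offset %||% offset),
                      integer(1))
    )
    bl <- lapply(recs, function(r) as.numeric(unlist(r$b)))
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    bcols <- grep("^b[0-9]+$", names(df), value = TRUE)
    need <- c("id", "a")
    if (!all(need %in% names(df)) || !length(bcols)) {
      .stopf("bank CSV needs columns id, text, a, b1..bK-1 (got: %s)",
             paste(names(df), collapse = ", "))
    }
    if (!nrow(df)) .stopf("no items in %s", path)
    bcols <- bcols[order(as.integer(sub("^b", "", bcols)))]
    bl <- lapply(seq_len(nrow(df)), function(i) {
      b <- as.numeric(df[i, bcols])
      b[!is.na(b)]
    })
    if (is.null(df$text)) df$text <- df$id
    if (is.null(df$offset)) df$offset <- offset
  }
  for (i in seq_along(bl)) {
    if (!length(bl[[i]])) .stopf("item '%s': no thresholds", df$id[i])
    if (is.na(df$a[i]) || df$a[i] <= 0) {
      .stopf("item '%s': discrimination must be > 0", df$id[i])
    }
    if (is.unsorted(bl[[i]], strictly = TRUE)) {
      .stopf("item '%s': thresholds not increasing", df$id[i])
    }
  }
  itemBank(df$id, a = df$a, thresholds = bl, text = df$text,
           offset = df$offset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an item bank to CSV or JSON
#'
#' Round-trips with [readItemBank()] at full double precision.
#'
#' @param bank an [ItemBank-class].
#' @param path output path.
#' @param format "auto", "csv" or "json".
#' @export
writeItemBank <- function(bank, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    recs <- lapply(seq_len(nItems(bank)), function(j) {
      list(id = bank@id[j], text = bank@text[j], a = bank@a[j],
           b = bank@thresholds[[j]], offset = bank@offset[j])
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  } else {
    maxb <- max(lengths(bank@thresholds))
    bm <- t(vapply(bank@thresholds,
                   function(b) c(b, rep(NA_real_, maxb - length(b))),
                   numeric(maxb)))
    df <- data.frame(id = bank@id, text = bank@text, a = bank@a,
                     bm, offset = bank@offset, check.names = FALSE)
    names(df)[3L + seq_len(maxb)] <- paste0("b", seq_len(maxb))
    write.csv(format(df, digits = 17, trim = TRUE), path, row.names = FALSE,
              quote = TRUE, na = "")
  }
  invisible(path)
}

#' Read a wide response CSV
#'
#' @param path CSV with first column \code{person_id} and one column per
#'   item; blank cells are treated as missing.
#' @param nCategories categories per item (scalar recycled); default 5.
#' @param offset raw-code offset (scalar recycled): responses are stored as
#'   raw + offset, so a 0-3 legacy scale read with \code{offset = 1} becomes
#'   1-4 internally.
#' @return A [ResponseMatrix-class]; out-of-range cells raise an error with
#'   person/item coordinates.
#' @export
readResponses <- function(path, nCategories = 5L, offset = 0L) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) .stopf("response CSV needs person_id plus item columns")
  pid <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- pid
  nc <- as.integer(rep_len(nCategories, ncol(m)))
  off <- as.integer(rep_len(offset, ncol(m)))
  m <- sweep(m, 2L, off, `+`)
  for (j in seq_len(ncol(m))) {
    bad <- which(!is.na(m[, j]) & (m[, j] < 1L | m[, j] > nc[j]))
    if (length(bad)) {
      .stopf("person '%s', item '%s': category %d outside 1..%d",
             pid[bad[1L]], colnames(m)[j], m[bad[1L], j], nc[j])
    }
  }
  new("ResponseMatrix", data = m, nCategories = nc, offset = off)
}

#' Write responses back to the wide CSV format
#'
#' The per-item offset is subtracted so legacy 0-based scales are exported
#' in their original coding.
#'
#' @param responses a [ResponseMatrix-class].
#' @param path output path.
#' @export
writeResponses <- function(responses, path) {
  m <- sweep(responses@data, 2L, responses@offset, `-`)
  df <- data.frame(person_id = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Cross-validate a bank against a response matrix
#'
#' Report-only: never raises.
#'
#' @param bank an [ItemBank-class].
#' @param responses a [ResponseMatrix-class].
#' @return data.frame with columns type, item, detail; zero rows when the
#'   pair is consistent.  Types: \code{missing_from_bank},
#'   \code{missing_from_responses}, \code{category_mismatch},
#'   \code{all_missing}.
#' @export
validateData <- function(bank, responses) {
  out <- list()
  add <- function(type, item, detail) {
    out[[length(out) + 1L]] <<- data.frame(type = type, item = item,
                                           detail = detail)
  }
  rid <- itemIds(responses)
  bid <- itemIds(bank)
  for (it in setdiff(rid, bid)) add("missing_from_bank", it,
                                    "response item not in bank")
  for (it in setdiff(bid, rid)) add("missing_from_responses", it,
                                    "bank item has no response column")
  common <- intersect(rid, bid)
  ncr <- nCategories(responses)[common]
  ncb <- nCategories(bank)[common]
  for (it in common[ncr != ncb]) {
    add("category_mismatch", it,
        sprintf("bank has %d categories, responses %d", ncb[it], ncr[it]))
  }
  d <- responseCodes(responses)
  for (it in rid[colSums(!is.na(d)) == 0L]) {
    add("all_missing", it, "no observed responses")
  }
  if (length(out)) do.call(rbind, out) else {
    data.frame(type = character(), item = character(), detail = character())
  }
}
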