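# Internal helpers: structured conditions, value matching, TSV I/O.

#' Signal a structured hipnet error
#'
#' All user-facing validation failures raise conditions of class
#' `hipnet_error` with a sub-class naming the failure kind, so callers can
#' dispatch on the condition rather than parse messages.
#'
#' @param message error message.
#' @param class sub-class suffix, e.g. `"missing_column"` becomes
#'   `hipnet_error_missing_column`.
#' @param data optional named list attached to the condition.
#' @noRd
stop_hipnet <- function(message, class, data = list()) {
  cond <- structure(
    class = c(paste0("hipnet_error_", class), "hipnet_error", "error", "condition"),
    c(list(message = message, call = sys.call(-1)), data)
  )
  stop(cond)
}

#' Canonicalize a metadata value for matching: trim whitespace, case-fold.
#' @noRd
canon_value <- function(x) {
  tolower(trimws(as.character(x)))
}

#' Is a raw table cell missing? Empty string or "NA" (any case) counts.
#' @noRd
is_missing_token <- function(x) {
  is.na(x) | trimws(x) == "" | toupper(trimws(x)) == "NA"
}

#' Read a tab-separated table with a header row (UTF-8), keeping strings.
#' Transparently handles gzip via R's connection machinery.
#' @noRd
read_tsv_strict <- function(path, sep = "\t", comment.char = "") {
  if (!file.exists(path)) {
    stop_hipnet(sprintf("input file not found: %s", path), "unreadable_file")
  }
  utils::read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = comment.char,
                    colClasses = "character", fileEncoding = "UTF-8")
}

#' Write a data frame as headerful TSV without quoting or row names.
#' @noRd
write_tsv_strict <- function(x, path) {
  ok <- tryCatch({
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_hipnet(sprintf("failed to write %s: %s", path, conditionMessage(ok)),
                "io")
  }
  invisible(path)
}

#' Flatten an annotations entry (named list of character/numeric vectors)
#' into the `label=v1,v2` serialization used in exports.
#' @noRd
flatten_annotations <- function(ann) {
  if (is.null(ann) || length(ann) == 0) return("")
  paste(vapply(names(ann), function(lab) {
    paste0(lab, "=", paste(ann[[lab]], collapse = ","))
  }, character(1)), collapse = ";")
}

#' Inverse of flatten_annotations(). Numeric-looking scalars are restored
#' as numeric values.
#' @noRd
unflatten_annotations <- function(s) {
  if (is.na(s) || !nzchar(s)) return(list())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) next
    vals <- strsplit(paste(kv[-1], collapse = "="), ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(vals))
    out[[kv[1]]] <- if (length(vals) == 1 && !is.na(num)) num else vals
  }
  out
}
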