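# Reading and writing assessment records (wide CSV and JSON-lines).
#
# The on-disk contracts: CSV is wide, one column per item code, header row,
# empty cell = missing, item columns in sorted order; JSON-lines is one
# record object per line with "responses" and "covariates" maps.  Both
# round-trip bit-exactly through read_assessments()/write_assessments().

record_col_order <- function(records, registry) {
  cols <- split_record_cols(records, registry)
  c(cols$id, sort(cols$covariate), sort(c(cols$item, cols$unknown)))
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jsonl", "ndjson", "json")) "jsonl" else "csv"
}

#' Write assessment records
#'
#' Writes records to wide CSV (one column per item code, sorted, empty
#' cell = missing) or JSON-lines (one record object per line).  Records
#' are validated against the registry first and the write is refused,
#' with the violation report attached to the error, if any response is
#' invalid.  Output is deterministic: re-reading yields an identical
#' collection.
#'
#' @param records Tibble of assessment records (see [validate_assessments()]).
#' @param path Output file path.
#' @param format `"csv"` or `"jsonl"`; default guessed from the extension.
#' @param registry An `mh_registry`.
#' @param validate Set `FALSE` to skip validation.
#' @return `path`, invisibly.
#' @export
write_assessments <- function(records, path, format = guess_format(path),
                              registry = mh_registry(), validate = TRUE) {
  format <- match.arg(format, c("csv", "jsonl"))
  records <- tibble::as_tibble(records)
  if (validate && nrow(records)) {
    viol <- validate_assessments(records, registry)
    if (nrow(viol)) {
      stop("refusing to write invalid records: ", nrow(viol),
           " violation(s), first: ", viol$message[1], call. = FALSE)
    }
  }
  ord <- record_col_order(records, registry)
  records <- records[, ord, drop = FALSE]
  if (format == "csv") {
    readr::write_csv(records, path, na = "")
  } else {
    cols <- split_record_cols(records, registry)
    item_cols <- sort(c(cols$item, cols$unknown))
    cov_cols <- sort(cols$covariate)
    lines <- vapply(seq_len(nrow(records)), function(i) {
      row <- records[i, ]
      resp <- lapply(row[item_cols], function(v) v[[1]])
      resp <- resp[!vapply(resp, is.na, TRUE)]
      covs <- lapply(row[cov_cols], function(v) v[[1]])
      covs <- covs[!vapply(covs, is.na, TRUE)]
      obj <- list(
        person_id = row$person_id, instrument = row$instrument,
        reason = row$reason, date = format(row$date, "%Y-%m-%d"),
        responses = resp, covariates = covs
      )
      as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null"))
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Read assessment records
#'
#' Reads records written by [write_assessments()] (or conforming files)
#' from wide CSV or JSON-lines.  Item codes are never renamed or
#' reordered relative to the registry's namespace; empty CSV cells and
#' absent JSON keys become missing responses.  Malformed lines raise an
#' error naming the line (and, for non-integer responses, the item).
#'
#' @inheritParams write_assessments
#' @return A tibble of assessment records.
#' @export
read_assessments <- function(path, format = guess_format(path),
                             registry = mh_registry()) {
  format <- match.arg(format, c("csv", "jsonl"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
    item_cols <- intersect(hdr, registry$items$item_code)
    types <- readr::cols(.default = readr::col_guess())
    types$cols <- stats::setNames(
      rep(list(readr::col_integer()), length(item_cols)), item_cols)
    types$cols[["person_id"]] <- readr::col_character()
    types$cols[["instrument"]] <- readr::col_character()
    if ("reason" %in% hdr) types$cols[["reason"]] <- readr::col_character()
    if ("date" %in% hdr) types$cols[["date"]] <- readr::col_date("%Y-%m-%d")
    out <- readr::read_csv(path, col_types = types, na = "",
                           show_col_types = FALSE, progress = FALSE)
    probs <- readr::problems(out)
    if (nrow(probs)) {
      stop(sprintf("malformed CSV: line %d (%s)", probs$row[1] + 1L,
                   probs$expected[1]), call. = FALSE)
    }
    return(out[, record_col_order(out, registry), drop = FALSE])
  }

  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
      error = function(e) {
        stop(sprintf("malformed JSON on line %d: %s", i, conditionMessage(e)),
             call. = FALSE)
      }
    )
    resp <- obj$responses
    if (length(resp)) {
      for (nm in names(resp)) {
        v <- resp[[nm]]
        if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != round(v)) {
          stop(sprintf("parse error on line %d: item '%s' has a non-integer response",
                       i, nm), call. = FALSE)
        }
      }
      resp <- lapply(resp, as.integer)
    }
    row <- c(
      list(person_id = as.character(obj$person_id),
           instrument = as.character(obj$instrument),
           reason = as.character(obj$reason),
           date = as.Date(obj$date)),
      as.list(obj$covariates), resp
    )
    recs[[i]] <- tibble::as_tibble(row)
  }
  out <- dplyr::bind_rows(recs)
  if (!nrow(out)) {
    out <- tibble::tibble(person_id = character(), instrument = character(),
                          reason = character(), date = as.Date(character()))
  }
  out[, record_col_order(out, registry), drop = FALSE]
}
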