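# Instrument registries: construction, invariant checks, record validation.

the <- new.env(parent = emptyenv())

instrument_codes <- function() c("MH", "CMH", "ESP", "BMHS", "FS", "AS")

membership_col <- function(instrument) {
  paste0("in_", tolower(instrument))
}

#' Build an instrument registry
#'
#' Constructs a validated registry of item definitions and instrument
#' membership from a configuration document.  The registry is the contract
#' every other operation relies on: record validation, scale applicability
#' and CAP applicability are all resolved against it.
#'
#' Construction fails loudly if the configuration violates a structural
#' invariant: duplicated item codes, non-positive coding ranges, subset
#' violations (every ESP item must be present in both MH and CMH, and every
#' BMHS item in the ESP), or — when the configuration declares expected
#' cardinalities — instrument item counts or overlaps that contradict the
#' declaration.  The default configuration declares the published counts
#' (MH 396, CMH 405, ESP 141, BMHS 46, with 330 items shared by MH and CMH).
#'
#' @param config A registry configuration: a list with an `items` data
#'   frame (see [default_registry_config()]), or a path to a YAML/JSON file
#'   holding the same structure.  Defaults to the shipped configuration.
#' @return An object of class `mh_registry`: a list with `items` (tibble),
#'   `instruments` (tibble) and `expected` (list or NULL).
#' @export
#' @examples
#' reg <- build_registry()
#' sum(reg$items$in_mh)
build_registry <- function(config = default_registry_config()) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_registry_config(config)
  }
  stopifnot(is.list(config), !is.null(config$items))
  items <- tibble::as_tibble(config$items)

  required <- c("item_code", "domain", "min_code", "max_code")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols)) {
    stop("registry config lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"label" %in% names(items)) items$label <- items$item_code
  if (!"lookback" %in% names(items)) items$lookback <- "3-day"
  for (ins in instrument_codes()) {
    col <- membership_col(ins)
    if (!col %in% names(items)) items[[col]] <- FALSE
  }
  items$min_code <- as.integer(items$min_code)
  items$max_code <- as.integer(items$max_code)

  dup <- items$item_code[duplicated(items$item_code)]
  if (length(dup)) {
    stop("registry error: duplicate item code(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad <- items$min_code < 0L | items$max_code <= items$min_code
  if (any(bad)) {
    stop("registry error: invalid coding range for item(s): ",
         paste(items$item_code[bad], collapse = ", "), call. = FALSE)
  }
  memb <- as.matrix(items[, membership_col(instrument_codes())])
  orphan <- rowSums(memb) == 0
  if (any(orphan)) {
    stop("registry error: item(s) belong to no instrument: ",
         paste(items$item_code[orphan], collapse = ", "), call. = FALSE)
  }
  viol_esp <- items$in_esp & !(items$in_mh & items$in_cmh)
  if (any(viol_esp)) {
    stop("registry error: ESP item(s) not shared by MH and CMH: ",
         paste(items$item_code[viol_esp], collapse = ", "), call. = FALSE)
  }
  viol_bmhs <- items$in_bmhs & !items$in_esp
  if (any(viol_bmhs)) {
    stop("registry error: BMHS item(s) not in the ESP: ",
         paste(items$item_code[viol_bmhs], collapse = ", "), call. = FALSE)
  }

  expected <- config$expected
  if (!is.null(expected)) {
    got <- c(
      MH = sum(items$in_mh), CMH = sum(items$in_cmh),
      ESP = sum(items$in_esp), BMHS = sum(items$in_bmhs),
      mh_cmh_shared = sum(items$in_mh & items$in_cmh),
      mh_only = sum(items$in_mh & !items$in_cmh),
      cmh_only = sum(items$in_cmh & !items$in_mh)
    )
    for (nm in intersect(names(got), names(expected))) {
      if (got[[nm]] != expected[[nm]]) {
        stop(sprintf(
          "registry error: %s has %d items, configuration declares %d",
          nm, got[[nm]], expected[[nm]]), call. = FALSE)
      }
    }
  }

  instruments <- config$instruments
  if (is.null(instruments)) {
    instruments <- tibble::tibble(
      code = instrument_codes(),
      default_lookback = c("3-day", "3-day", "24-hour", "24-hour", "3-day", "3-day")
    )
  }
  structure(
    list(items = items, instruments = tibble::as_tibble(instruments),
         expected = expected),
    class = "mh_registry"
  )
}

read_registry_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML registry configs requires the 'yaml' package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg$items <- tibble::as_tibble(cfg$items)
  cfg
}

#' @export
print.mh_registry <- function(x, ...) {
  cat("<mh_registry> ", nrow(x$items), " items\n", sep = "")
  counts <- vapply(instrument_codes(), function(i) sum(x$items[[membership_col(i)]]), 0L)
  cat(paste(sprintf("%s: %d", names(counts), counts), collapse = ", "), "\n")
  invisible(x)
}

#' Default registry (cached)
#'
#' Returns the registry built from [default_registry_config()], building
#' it once per session.
#' @return An `mh_registry` object.
#' @export
mh_registry <- function() {
  if (is.null(the$default_registry)) {
    the$default_registry <- build_registry(default_registry_config())
  }
  the$default_registry
}

#' Items of one instrument
#'
#' @param registry An `mh_registry`.
#' @param instrument Instrument code: one of MH, CMH, ESP, BMHS, FS, AS.
#' @return A tibble of the instrument's item definitions.
#' @export
registry_items <- function(registry = mh_registry(), instrument = NULL) {
  stopifnot(inherits(registry, "mh_registry"))
  if (is.null(instrument)) return(registry$items)
  instrument <- match_instrument(instrument)
  registry$items[registry$items[[membership_col(instrument)]], , drop = FALSE]
}

match_instrument <- function(instrument) {
  instrument <- toupper(instrument)
  if (!instrument %in% instrument_codes()) {
    stop("unknown instrument: ", instrument, call. = FALSE)
  }
  instrument
}

record_id_cols <- function() c("person_id", "instrument", "reason", "date")

assessment_reasons <- function() c("admission", "review", "discharge", "crisis", "screen")

# Covariate columns the record format reserves (everything else that is
# not an id or a registry item code is treated as an unknown item).
known_covariate_pattern <- function() {
  "^(homeless|setting|age|sex|period|year|episode|dx_)"
}

# Split a record tibble's columns into id / item / covariate / unknown sets.
split_record_cols <- function(records, registry) {
  nms <- names(records)
  ids <- intersect(record_id_cols(), nms)
  item_cols <- intersect(nms, registry$items$item_code)
  rest <- setdiff(nms, c(ids, item_cols))
  cov_cols <- rest[grepl(known_covariate_pattern(), rest)]
  list(id = ids, item = item_cols, covariate = cov_cols,
       unknown = setdiff(rest, cov_cols))
}

#' Validate assessment records against a registry
#'
#' Checks each record's responses against the registry of its instrument:
#' every responded item must exist in that instrument's item set and its
#' value must lie inside the item's coding range.  Missing responses
#' (`NA` / absent columns) are legitimate and never flagged — missingness
#' is absence, not an in-band code.
#'
#' @param records A tibble of assessment records: identifier columns
#'   (`person_id`, `instrument`, `reason`, `date`), item columns named by
#'   item code, and any covariate columns.
#' @param registry An `mh_registry`.
#' @return A tibble of violations (possibly empty) with columns `row`,
#'   `person_id`, `instrument`, `item`, `rule`, `message`.  An unknown
#'   instrument code raises an error rather than a validation row.
#' @export
#' @examples
#' reg <- build_registry()
#' rec <- tibble::tibble(person_id = "p1", instrument = "MH",
#'                       reason = "admission", date = as.Date("2020-01-01"),
#'                       hallucinations = 2L)
#' validate_assessments(rec, reg)
validate_assessments <- function(records, registry = mh_registry()) {
  stopifnot(is.data.frame(records), inherits(registry, "mh_registry"))
  records <- tibble::as_tibble(records)
  if (!"instrument" %in% names(records)) {
    stop("records lack an 'instrument' column", call. = FALSE)
  }
  unknown <- setdiff(unique(records$instrument), instrument_codes())
  if (length(unknown)) {
    stop("unknown instrument: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cols <- split_record_cols(records, registry)
  items <- registry$items
  out <- list()
  # Columns that are neither ids, registry items, nor reserved covariates
  # are unknown item codes; any response in them is a violation.
  for (col in cols$unknown) {
    bad <- which(!is.na(records[[col]]))
    if (!length(bad)) next
    out[[length(out) + 1L]] <- tibble::tibble(
      row = bad,
      person_id = as.character(records$person_id[bad]),
      instrument = as.character(records$instrument[bad]),
      item = col, rule = "unknown_item",
      message = sprintf("item '%s' is not a registry item", col)
    )
  }
  for (ins in unique(records$instrument)) {
    rows <- which(records$instrument == ins)
    in_ins <- items$item_code[items[[membership_col(ins)]]]
    for (col in cols$item) {
      vals <- records[[col]][rows]
      present <- !is.na(vals)
      if (!any(present)) next
      if (!col %in% in_ins) {
        bad <- rows[present]
        out[[length(out) + 1L]] <- tibble::tibble(
          row = bad,
          person_id = as.character(records$person_id[bad]),
          instrument = ins, item = col, rule = "unknown_item",
          message = sprintf("item '%s' is not in the %s registry", col, ins)
        )
        next
      }
      def <- items[items$item_code == col, ]
      oob <- present & (vals < def$min_code | vals > def$max_code |
                          vals != round(vals))
      if (any(oob)) {
        bad <- rows[oob]
        out[[length(out) + 1L]] <- tibble::tibble(
          row = bad,
          person_id = as.character(records$person_id[bad]),
          instrument = ins, item = col, rule = "out_of_range",
          message = sprintf("item '%s' value outside [%d, %d]",
                            col, def$min_code, def$max_code)
        )
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(
      row = integer(), person_id = character(), instrument = character(),
      item = character(), rule = character(), message = character()
    ))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$row, .data$item)
}
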