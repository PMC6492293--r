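#' @title Statement corpora: reading, validation, windowing, stratification
#' @name statement_store
#' @description A corpus holds coded statements: one row per instance of an
#'   actor (a person speaking for an organization) agreeing or disagreeing
#'   with a concept (a recurring argument in the debate) in a dated media
#'   article. These are the four coded variables of a discourse-network
#'   coding frame plus provenance (article, source, date).
NULL

DN_FIELDS <- c("statement_id", "article_id", "source", "date",
               "person", "organization", "actor_type", "concept", "stance")

# Fields the reader can auto-assign when missing from the input.
DN_OPTIONAL_FIELDS <- "statement_id"

dn_squish <- function(x) {
  x <- gsub("[[:space:]]+", " ", as.character(x))
  trimws(x)
}

normalize_stance <- function(x) {
  raw <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(raw))
  out[raw %in% c("1", "true", "agree")] <- "agree"
  out[raw %in% c("0", "false", "disagree")] <- "disagree"
  out
}

#' Construct a statement corpus from a data frame
#'
#' Validates the eight coded/provenance fields, normalizes stance values to
#' `"agree"`/`"disagree"`, parses ISO-8601 dates, collapses internal
#' whitespace in actor and concept labels, and auto-assigns sequential
#' `statement_id`s when absent. Extra columns are preserved (and ignored by
#' all analysis functions).
#'
#' @param df data frame with columns `article_id`, `source`, `date`,
#'   `person`, `organization`, `actor_type`, `concept`, `stance` and
#'   optionally `statement_id`. `stance` may be coded `{1,0}`,
#'   `{true,false}` or `{agree,disagree}` (any case).
#' @param window optional length-2 `Date` vector, the half-open interval
#'   `[start, end)` this corpus was sliced to.
#' @return A `dn_corpus` object: list with `statements` (data frame, row
#'   order preserved), `concept_inventory` (sorted unique concepts) and
#'   `window`.
#' @export
as_corpus <- function(df, window = NULL) {
  if (!is.data.frame(df)) dn_abort("dn_schema_error", "input must be a data frame")
  missing_cols <- setdiff(setdiff(DN_FIELDS, DN_OPTIONAL_FIELDS), names(df))
  if (length(missing_cols) > 0) {
    dn_abort("dn_schema_error",
             sprintf("missing required column(s): %s",
                     paste(missing_cols, collapse = ", ")),
             columns = missing_cols)
  }
  if (nrow(df) == 0) dn_abort("dn_empty_error", "corpus has no statements")
  df <- as.data.frame(df, stringsAsFactors = FALSE)

  if (!"statement_id" %in% names(df)) {
    df$statement_id <- sprintf("s%04d", seq_len(nrow(df)))
  }
  st <- normalize_stance(df$stance)
  if (anyNA(st)) {
    bad <- which(is.na(st))[1]
    dn_abort("dn_row_error",
             sprintf("row %d: unparseable stance value '%s'", bad, df$stance[bad]),
             row = bad)
  }
  df$stance <- st

  dt <- suppressWarnings(as.Date(as.character(df$date), format = "%Y-%m-%d"))
  if (anyNA(dt)) {
    bad <- which(is.na(dt))[1]
    dn_abort("dn_row_error",
             sprintf("row %d: unparseable date '%s' (expected YYYY-MM-DD)",
                     bad, df$date[bad]),
             row = bad)
  }
  df$date <- dt

  for (col in c("person", "organization", "concept", "source",
                "actor_type", "article_id", "statement_id")) {
    df[[col]] <- dn_squish(df[[col]])
  }
  for (col in c("person", "organization", "concept")) {
    if (any(df[[col]] == "")) {
      bad <- which(df[[col]] == "")[1]
      dn_abort("dn_row_error",
               sprintf("row %d: empty %s after whitespace normalization", bad, col),
               row = bad)
    }
  }
  if (!is.null(window)) {
    window <- as.Date(window)
    if (length(window) != 2 || anyNA(window) || window[1] >= window[2]) {
      dn_abort("dn_interval_error", "window must be two dates with start < end")
    }
    if (any(df$date < window[1] | df$date >= window[2])) {
      dn_abort("dn_interval_error", "statement dates fall outside the declared window")
    }
  }
  # canonical column order: the eight fields first, extras after
  extras <- setdiff(names(df), DN_FIELDS)
  df <- df[, c(DN_FIELDS, extras), drop = FALSE]
  rownames(df) <- NULL
  structure(list(statements = df,
                 concept_inventory = dn_sort(unique(df$concept)),
                 window = window),
            class = "dn_corpus")
}

#' Read a statement table from CSV or JSON
#'
#' @param path file path. CSV: RFC-4180, UTF-8, header row. JSON: array of
#'   objects, one per statement.
#' @param format `"csv"` or `"json"`; guessed from the file extension when
#'   omitted.
#' @return A [as_corpus()] `dn_corpus`.
#' @export
read_statements <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) dn_abort("dn_schema_error", sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  df <- if (format == "csv") {
    if (file.size(path) == 0) dn_abort("dn_empty_error", "empty input file")
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    encoding = "UTF-8")
  } else {
    x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(x) == 0) dn_abort("dn_empty_error", "empty input file")
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0) dn_abort("dn_empty_error", "input contains no statements")
  as_corpus(df)
}

#' Write a corpus back to CSV or JSON
#'
#' Round-trips through [read_statements()] field-by-field, including any
#' extra columns present on input.
#'
#' @param corpus a `dn_corpus`.
#' @param path output file path.
#' @param format `"csv"` or `"json"`; guessed from the extension when omitted.
#' @return `path`, invisibly.
#' @export
write_statements <- function(corpus, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(corpus, "dn_corpus"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  df <- corpus$statements
  df$date <- format(df$date, "%Y-%m-%d")
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Restrict a corpus to a half-open date window
#'
#' Keeps statements with `start <= date < end`. Half-open intervals make
#' consecutive time slices (e.g. the three half-year phases of a debate) a
#' partition of the corpus: no statement is lost or double-counted.
#'
#' @param corpus a `dn_corpus`.
#' @param start,end `Date` (or ISO-8601 strings); `start < end`.
#' @return A `dn_corpus` with the window recorded; possibly zero statements
#'   (represented with an empty statement table, not an error).
#' @export
slice_window <- function(corpus, start, end) {
  stopifnot(inherits(corpus, "dn_corpus"))
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end) || start >= end) {
    dn_abort("dn_interval_error", "window start must precede window end")
  }
  keep <- corpus$statements$date >= start & corpus$statements$date < end
  df <- corpus$statements[keep, , drop = FALSE]
  rownames(df) <- NULL
  structure(list(statements = df,
                 concept_inventory = dn_sort(unique(df$concept)),
                 window = c(start, end)),
            class = "dn_corpus")
}

#' Split a corpus by publication source
#'
#' One sub-corpus per distinct `source`, so separate networks can be built
#' per newspaper. The parts are disjoint and their union is the corpus.
#'
#' @param corpus a `dn_corpus`.
#' @return Named list of `dn_corpus`, names sorted.
#' @export
stratify_by_source <- function(corpus) {
  stopifnot(inherits(corpus, "dn_corpus"))
  sources <- dn_sort(unique(corpus$statements$source))
  out <- lapply(sources, function(s) {
    df <- corpus$statements[corpus$statements$source == s, , drop = FALSE]
    rownames(df) <- NULL
    structure(list(statements = df,
                   concept_inventory = dn_sort(unique(df$concept)),
                   window = corpus$window),
              class = "dn_corpus")
  })
  names(out) <- sources
  out
}

#' Actor keys of a corpus at a given aggregation level
#' @param corpus a `dn_corpus`.
#' @param level `"organization"` (default) or `"person"`.
#' @return character vector of per-statement actor keys (same length as the
#'   statement table).
#' @keywords internal
actor_keys <- function(corpus, level = c("organization", "person")) {
  level <- match.arg(level)
  corpus$statements[[level]]
}

#' Per-actor statement counts
#'
#' Statement frequency per actor at the chosen aggregation level; used for
#' node sizing and as the activity term of average-activity normalization.
#'
#' @inheritParams actor_keys
#' @return Named integer vector (actor -> count), actors sorted; counts sum
#'   to the corpus size.
#' @export
actor_statement_counts <- function(corpus, level = c("organization", "person")) {
  stopifnot(inherits(corpus, "dn_corpus"))
  keys <- actor_keys(corpus, level)
  if (length(keys) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- table(keys)
  out <- stats::setNames(as.integer(tab), names(tab))
  out[dn_sort(names(out))]
}

#' @export
print.dn_corpus <- function(x, ...) {
  n <- nrow(x$statements)
  cat(sprintf("<dn_corpus> %d statements, %d organizations, %d persons, %d concepts\n",
              n,
              length(unique(x$statements$organization)),
              length(unique(x$statements$person)),
              length(x$concept_inventory)))
  if (n > 0) {
    cat(sprintf("  dates %s .. %s", min(x$statements$date), max(x$statements$date)))
  }
  if (!is.null(x$window)) {
    cat(sprintf("  window [%s, %s)", x$window[1], x$window[2]))
  }
  cat("\n")
  invisible(x)
}
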