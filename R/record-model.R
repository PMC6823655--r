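# Multi-source client record model: bundle I/O, validation, linkage into
# virtual patient records (VPRs), and analysis-window filtering.

BUNDLE_SCHEMA_VERSION <- "1.0"

BUNDLE_TABLES <- c(
  "encounters", "honos", "problems", "vitals",
  "ed_visits", "admissions", "flags", "phq9"
)

#' Recognised administrative flag kinds
#'
#' Closed enumeration of the presence-style indicators used by the domain
#' scorers: Persons With Disabilities forms, social-history (SHX) problem
#' codes, InterRAI-MDS assessments, mobility (transfer/bed) assessments,
#' violence alerts and Extended Leave status.
#' @export
FLAG_KINDS <- c(
  "PWD_FORM", "SHX_CODE", "INTERRAI_MDS",
  "MOBILITY_ASSESSMENT", "VIOLENCE_ALERT", "EXTENDED_LEAVE"
)

HONOS_ITEM_COLS <- paste0("item", 1:12)

# Column name -> storage type for every bundle table. The order here is the
# canonical column order used by all writers.
bundle_columns <- function() {
  list(
    encounters = c(
      client_id = "character", source_system = "character", date = "date",
      program = "character", booked = "logical", attended = "logical"
    ),
    honos = c(
      c(client_id = "character", date = "date"),
      setNames(rep("integer", 12), HONOS_ITEM_COLS)
    ),
    problems = c(
      client_id = "character", code = "character", label = "character",
      is_sumh = "logical", is_complex_care = "logical",
      is_neurodegenerative = "logical"
    ),
    vitals = c(
      client_id = "character", date = "date", systolic_bp = "double",
      diastolic_bp = "double", bmi = "double"
    ),
    ed_visits = c(client_id = "character", date = "date", ctas_level = "integer"),
    admissions = c(
      client_id = "character", admit_date = "date", discharge_date = "date"
    ),
    flags = c(client_id = "character", flag_kind = "character", date = "date"),
    phq9 = c(client_id = "character", date = "date", total = "integer")
  )
}

coerce_column <- function(x, type) {
  switch(type,
    character = as.character(x),
    date      = as.Date(x),
    logical   = if (is.character(x)) as.logical(toupper(x)) else as.logical(x),
    integer   = {
      y <- suppressWarnings(as.integer(x))
      y
    },
    double    = suppressWarnings(as.numeric(x)),
    stop("unknown column type: ", type)
  )
}

empty_bundle_table <- function(table) {
  spec <- bundle_columns()[[table]]
  cols <- lapply(spec, function(type) coerce_column(character(0), type))
  tibble::as_tibble(cols)
}

coerce_bundle_table <- function(df, table) {
  spec <- bundle_columns()[[table]]
  if (is.null(df) || (is.list(df) && length(df) == 0) ||
      (is.data.frame(df) && nrow(df) == 0 && ncol(df) == 0)) {
    return(empty_bundle_table(table))
  }
  df <- tibble::as_tibble(df)
  missing <- setdiff(names(spec), names(df))
  for (col in missing) df[[col]] <- rep(NA, nrow(df))
  out <- df[names(spec)]
  for (col in names(spec)) out[[col]] <- coerce_column(out[[col]], spec[[col]])
  out
}

#' Construct a multi-source record bundle
#'
#' A record bundle is the on-disk and in-memory unit of exchange: one table
#' per source record type (`encounters`, `honos`, `problems`, `vitals`,
#' `ed_visits`, `admissions`, `flags`, `phq9`), each a tibble keyed by an
#' opaque `client_id`. Missing tables become empty tibbles with the canonical
#' columns; supplied tables are coerced to the canonical column types (dates
#' parsed as ISO-8601).
#'
#' @param encounters,honos,problems,vitals,ed_visits,admissions,flags,phq9
#'   Data frames (or `NULL`) for each source table.
#' @param validate If `TRUE` (default), run [validate_bundle()] and raise an
#'   error naming table, row and field on any invariant violation.
#' @return An object of class `record_bundle`: a named list of tibbles.
#' @seealso [read_bundle()], [write_bundle()], [link_records()]
#' @export
record_bundle <- function(encounters = NULL, honos = NULL, problems = NULL,
                          vitals = NULL, ed_visits = NULL, admissions = NULL,
                          flags = NULL, phq9 = NULL, validate = TRUE) {
  supplied <- list(
    encounters = encounters, honos = honos, problems = problems,
    vitals = vitals, ed_visits = ed_visits, admissions = admissions,
    flags = flags, phq9 = phq9
  )
  bundle <- lapply(BUNDLE_TABLES, function(tb) coerce_bundle_table(supplied[[tb]], tb))
  names(bundle) <- BUNDLE_TABLES
  bundle <- structure(bundle,
    class = c("record_bundle", "list"),
    schema_version = BUNDLE_SCHEMA_VERSION
  )
  if (validate) assert_valid_bundle(bundle)
  bundle
}

#' @export
print.record_bundle <- function(x, ...) {
  counts <- vapply(x, nrow, integer(1))
  cat("<record_bundle> schema", attr(x, "schema_version") %||% "?",
      "-", length(bundle_client_ids(x)), "clients\n")
  for (tb in names(counts)) cat(sprintf("  %-11s %d rows\n", tb, counts[[tb]]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

bundle_client_ids <- function(bundle) {
  ids <- unlist(lapply(bundle, function(df) df$client_id), use.names = FALSE)
  sort(unique(ids[!is.na(ids)]))
}

#' Validate a record bundle against its schema invariants
#'
#' Checks every row of every table: required identifiers and dates present,
#' HoNOS items in 0--4, CTAS levels in 1--5, PHQ-9 totals in 0--27, positive
#' vitals, discharge on or after admission, and flag kinds drawn from
#' [FLAG_KINDS].
#'
#' @param bundle A `record_bundle`.
#' @return A tibble of row-level diagnostics with columns `table`, `row`,
#'   `field`, `message`; zero rows when the bundle is valid.
#' @export
validate_bundle <- function(bundle) {
  issues <- list()
  add <- function(table, rows, field, message) {
    if (length(rows) == 0) return()
    issues[[length(issues) + 1]] <<- tibble::tibble(
      table = table, row = as.integer(rows), field = field, message = message
    )
  }
  need <- function(table, field, bad, message) {
    add(table, which(bad), field, message)
  }

  enc <- bundle$encounters
  need("encounters", "client_id", is.na(enc$client_id) | enc$client_id == "",
       "client_id must be non-empty")
  need("encounters", "date", is.na(enc$date), "date must be a valid ISO-8601 date")
  need("encounters", "booked", is.na(enc$booked), "booked must be TRUE/FALSE")
  need("encounters", "attended", is.na(enc$attended), "attended must be TRUE/FALSE")

  hon <- bundle$honos
  need("honos", "client_id", is.na(hon$client_id) | hon$client_id == "",
       "client_id must be non-empty")
  need("honos", "date", is.na(hon$date), "date must be a valid ISO-8601 date")
  for (col in HONOS_ITEM_COLS) {
    vals <- hon[[col]]
    need("honos", col, is.na(vals) | vals < 0L | vals > 4L,
         "HoNOS item scores must be integers in 0..4")
  }

  prb <- bundle$problems
  need("problems", "client_id", is.na(prb$client_id) | prb$client_id == "",
       "client_id must be non-empty")
  need("problems", "code", is.na(prb$code) | prb$code == "",
       "diagnosis code must be non-empty")

  vit <- bundle$vitals
  need("vitals", "client_id", is.na(vit$client_id) | vit$client_id == "",
       "client_id must be non-empty")
  need("vitals", "date", is.na(vit$date), "date must be a valid ISO-8601 date")
  for (col in c("systolic_bp", "diastolic_bp", "bmi")) {
    vals <- vit[[col]]
    need("vitals", col, !is.na(vals) & vals <= 0,
         "present measurements must be positive")
  }

  ed <- bundle$ed_visits
  need("ed_visits", "client_id", is.na(ed$client_id) | ed$client_id == "",
       "client_id must be non-empty")
  need("ed_visits", "date", is.na(ed$date), "date must be a valid ISO-8601 date")
  need("ed_visits", "ctas_level",
       is.na(ed$ctas_level) | ed$ctas_level < 1L | ed$ctas_level > 5L,
       "CTAS level must be an integer in 1..5")

  adm <- bundle$admissions
  need("admissions", "client_id", is.na(adm$client_id) | adm$client_id == "",
       "client_id must be non-empty")
  need("admissions", "admit_date", is.na(adm$admit_date),
       "admit_date must be a valid ISO-8601 date")
  need("admissions", "discharge_date",
       !is.na(adm$discharge_date) & adm$discharge_date < adm$admit_date,
       "discharge_date must be on or after admit_date")

  flg <- bundle$flags
  need("flags", "client_id", is.na(flg$client_id) | flg$client_id == "",
       "client_id must be non-empty")
  need("flags", "flag_kind", is.na(flg$flag_kind) | !(flg$flag_kind %in% FLAG_KINDS),
       paste0("flag_kind must be one of: ", paste(FLAG_KINDS, collapse = ", ")))

  phq <- bundle$phq9
  need("phq9", "client_id", is.na(phq$client_id) | phq$client_id == "",
       "client_id must be non-empty")
  need("phq9", "date", is.na(phq$date), "date must be a valid ISO-8601 date")
  need("phq9", "total", is.na(phq$total) | phq$total < 0L | phq$total > 27L,
       "PHQ-9 total must be an integer in 0..27")

  if (length(issues) == 0) {
    return(tibble::tibble(
      table = character(0), row = integer(0),
      field = character(0), message = character(0)
    ))
  }
  do.call(rbind, issues)
}

assert_valid_bundle <- function(bundle) {
  issues <- validate_bundle(bundle)
  if (nrow(issues) > 0) {
    shown <- head(issues, 5)
    lines <- sprintf(
      "  %s row %d field '%s': %s",
      shown$table, shown$row, shown$field, shown$message
    )
    stop(
      "invalid record bundle (", nrow(issues), " problem",
      if (nrow(issues) > 1) "s" else "", "):\n",
      paste(lines, collapse = "\n"),
      if (nrow(issues) > nrow(shown)) "\n  ..." else "",
      call. = FALSE
    )
  }
  invisible(bundle)
}

date_to_chr <- function(x) ifelse(is.na(x), NA_character_, format(x, "%Y-%m-%d"))

bundle_table_for_export <- function(df, table) {
  spec <- bundle_columns()[[table]]
  for (col in names(spec)) {
    if (spec[[col]] == "date") df[[col]] <- date_to_chr(df[[col]])
  }
  df
}

#' Write a record bundle to disk
#'
#' @param bundle A validated `record_bundle`.
#' @param path Output path: a `.json` file for `format = "json"`, a directory
#'   (created if needed) holding one `<table>.csv` per table for
#'   `format = "csv"`.
#' @param format `"json"` (single bundle file) or `"csv"` (per-table files).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path, format = c("json", "csv")) {
  format <- match.arg(format)
  assert_valid_bundle(bundle)
  exportable <- lapply(BUNDLE_TABLES, function(tb) {
    bundle_table_for_export(as.data.frame(bundle[[tb]]), tb)
  })
  names(exportable) <- BUNDLE_TABLES
  if (format == "json") {
    payload <- c(list(schema_version = attr(bundle, "schema_version") %||%
                        BUNDLE_SCHEMA_VERSION), exportable)
    jsonlite::write_json(payload, path,
      dataframe = "rows", na = "null", auto_unbox = TRUE, digits = NA
    )
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (tb in BUNDLE_TABLES) {
      write.csv(exportable[[tb]], file.path(path, paste0(tb, ".csv")),
                row.names = FALSE, na = "")
    }
  }
  invisible(path)
}

#' Read a record bundle from disk
#'
#' Accepts either the single-file JSON bundle format or a directory of
#' per-table CSV files (UTF-8, header row, one file per table; absent files
#' are treated as empty tables). All rows are validated on load; malformed
#' rows raise an error with row-level diagnostics naming table, row and field.
#'
#' @param path A `.json` bundle file or a CSV directory.
#' @param format `"auto"` (default; inferred from `path`), `"json"` or `"csv"`.
#' @return A validated `record_bundle`.
#' @export
read_bundle <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "csv" else "json"
  }
  if (format == "json") {
    if (!file.exists(path)) stop("bundle file not found: ", path, call. = FALSE)
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    tables <- lapply(BUNDLE_TABLES, function(tb) raw[[tb]])
  } else {
    if (!dir.exists(path)) stop("bundle directory not found: ", path, call. = FALSE)
    tables <- lapply(BUNDLE_TABLES, function(tb) {
      f <- file.path(path, paste0(tb, ".csv"))
      if (!file.exists(f)) return(NULL)
      read.csv(f, colClasses = "character", na.strings = "")
    })
  }
  names(tables) <- BUNDLE_TABLES
  bundle <- do.call(record_bundle, c(tables, list(validate = FALSE)))
  assert_valid_bundle(bundle)
  bundle
}

#' Link source records into virtual patient records
#'
#' Groups every record in the bundle by exact `client_id` into one virtual
#' patient record (VPR) per distinct client: the unified cross-source view
#' the domain scorers consume. Every input record lands in exactly one VPR;
#' a client present in any source table gets a VPR.
#'
#' @param bundle A `record_bundle`.
#' @return A named list of `vpr` objects, one per client, ordered by id.
#' @export
link_records <- function(bundle) {
  ids <- bundle_client_ids(bundle)
  out <- lapply(ids, function(id) {
    tables <- lapply(bundle, function(df) df[!is.na(df$client_id) & df$client_id == id, , drop = FALSE])
    new_vpr(id, tables)
  })
  names(out) <- ids
  out
}

new_vpr <- function(client_id, tables) {
  structure(
    c(list(client_id = client_id), tables[BUNDLE_TABLES]),
    class = c("vpr", "list")
  )
}

#' Build a single-client virtual patient record directly
#'
#' Convenience constructor used in tests and worked examples: builds the same
#' object [link_records()] produces, filling in `client_id` on every supplied
#' table row.
#'
#' @inheritParams record_bundle
#' @param client_id The client identifier (opaque string).
#' @return A `vpr` object.
#' @export
vpr <- function(client_id = "client", encounters = NULL, honos = NULL,
                problems = NULL, vitals = NULL, ed_visits = NULL,
                admissions = NULL, flags = NULL, phq9 = NULL) {
  supplied <- list(
    encounters = encounters, honos = honos, problems = problems,
    vitals = vitals, ed_visits = ed_visits, admissions = admissions,
    flags = flags, phq9 = phq9
  )
  tables <- lapply(BUNDLE_TABLES, function(tb) {
    df <- coerce_bundle_table(supplied[[tb]], tb)
    if (nrow(df) > 0) df$client_id <- client_id
    df
  })
  names(tables) <- BUNDLE_TABLES
  new_vpr(client_id, tables)
}

#' @export
print.vpr <- function(x, ...) {
  counts <- vapply(BUNDLE_TABLES, function(tb) nrow(x[[tb]]), integer(1))
  cat("<vpr>", x$client_id, "-",
      paste(sprintf("%s:%d", BUNDLE_TABLES, counts), collapse = " "), "\n")
  invisible(x)
}

# -- analysis window ----------------------------------------------------------

# Calendar-month arithmetic with day-of-month clipping (e.g. Mar 31 minus one
# month is Feb 28/29).
add_months <- function(date, n) {
  date <- as.Date(date)
  lt <- as.POSIXlt(date)
  total <- lt$year * 12L + lt$mon + as.integer(n)
  year <- total %/% 12L
  mon <- total %% 12L
  day <- lt$mday
  last_day <- function(y, m) {
    first_next <- as.Date(sprintf(
      "%04d-%02d-01",
      ifelse(m == 11L, y + 1901L, y + 1900L),
      ifelse(m == 11L, 1L, m + 2L)
    ))
    as.integer(format(first_next - 1L, "%d"))
  }
  day <- pmin(day, last_day(year, mon))
  as.Date(sprintf("%04d-%02d-%02d", year + 1900L, mon + 1L, day))
}

#' Define a lookback analysis window
#'
#' The window covers `(as_of_date - lookback_months, as_of_date]`: half-open
#' at the start and inclusive of the as-of date, with the lookback computed
#' in calendar months (not a fixed day count). The 18-month default is the
#' lookback over which utilization-type records (encounters, HoNOS, PHQ-9,
#' ED visits, admissions) contribute to scoring.
#'
#' @param as_of_date The reference ("as of") date.
#' @param lookback_months Positive integer number of calendar months.
#' @return An `analysis_window` with fields `as_of_date`, `lookback_months`
#'   and the computed `start`.
#' @export
analysis_window <- function(as_of_date, lookback_months = 18L) {
  as_of_date <- as.Date(as_of_date)
  if (is.na(as_of_date)) stop("as_of_date must be a valid date", call. = FALSE)
  lookback_months <- as.integer(lookback_months)
  if (is.na(lookback_months) || lookback_months <= 0L) {
    stop("lookback_months must be a positive integer", call. = FALSE)
  }
  structure(
    list(
      as_of_date = as_of_date,
      lookback_months = lookback_months,
      start = add_months(as_of_date, -lookback_months)
    ),
    class = "analysis_window"
  )
}

#' @export
print.analysis_window <- function(x, ...) {
  cat(sprintf(
    "<analysis_window> (%s, %s] (%d months)\n",
    format(x$start), format(x$as_of_date), x$lookback_months
  ))
  invisible(x)
}

in_window <- function(dates, window) {
  !is.na(dates) & dates > window$start & dates <= window$as_of_date
}

#' Restrict a virtual patient record to an analysis window
#'
#' Utilization records (encounters, HoNOS assessments, PHQ-9 results, ED
#' visits) dated outside the window are dropped. Admissions are kept when the
#' stay intersects the window (an open admission runs to the as-of date).
#' The problem list and administrative flags are current-state information
#' and pass through unfiltered. Idempotent.
#'
#' @param x A `vpr`.
#' @param window An [analysis_window()].
#' @return The windowed `vpr`.
#' @export
window_filter <- function(x, window) {
  stopifnot(inherits(x, "vpr"), inherits(window, "analysis_window"))
  key <- paste(window$start, window$as_of_date)
  if (identical(attr(x, "window_key"), key)) return(x)
  x$encounters <- x$encounters[in_window(x$encounters$date, window), , drop = FALSE]
  x$honos <- x$honos[in_window(x$honos$date, window), , drop = FALSE]
  x$phq9 <- x$phq9[in_window(x$phq9$date, window), , drop = FALSE]
  x$ed_visits <- x$ed_visits[in_window(x$ed_visits$date, window), , drop = FALSE]
  adm <- x$admissions
  if (nrow(adm) > 0) {
    stay_end <- adm$discharge_date
    stay_end[is.na(stay_end)] <- window$as_of_date
    keep <- adm$admit_date <= window$as_of_date & stay_end > window$start
    x$admissions <- adm[keep, , drop = FALSE]
  }
  attr(x, "window_key") <- key
  x
}

#' Latest HoNOS assessment in a window
#'
#' Returns the assessment with the maximum date (after window filtering when
#' a window is supplied). Date ties are broken toward the assessment with the
#' highest item sum -- the complexity-preserving choice -- then by row order.
#'
#' @param x A `vpr`.
#' @param window Optional [analysis_window()].
#' @return A one-row tibble, or `NULL` when no assessment is in scope.
#' @export
latest_honos <- function(x, window = NULL) {
  hon <- x$honos
  if (!is.null(window)) hon <- hon[in_window(hon$date, window), , drop = FALSE]
  if (nrow(hon) == 0) return(NULL)
  sums <- rowSums(as.matrix(hon[HONOS_ITEM_COLS]))
  ord <- order(hon$date, sums, decreasing = TRUE)
  hon[ord[1], , drop = FALSE]
}

# Latest PHQ-9 result; ties broken toward the highest total.
latest_phq9 <- function(x, window = NULL) {
  phq <- x$phq9
  if (!is.null(window)) phq <- phq[in_window(phq$date, window), , drop = FALSE]
  if (nrow(phq) == 0) return(NULL)
  ord <- order(phq$date, phq$total, decreasing = TRUE)
  phq[ord[1], , drop = FALSE]
}
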