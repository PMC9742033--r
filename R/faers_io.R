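# Reading, validating and deduplicating FAERS-style quarterly ASCII tables.
#
# The supported dialect is the modern (post-2012, PRIMARYID-era) public FAERS
# quarterly extract: one table per file, dollar-sign delimited, header row of
# column names, UTF-8 with undecodable bytes replaced.  Legacy ISR-era column
# aliases are deliberately not supported.

faers_table_kinds <- c("demo", "drug", "reac", "outc", "ther", "indi")

#' Column schema of the supported FAERS dialect
#'
#' @param schema_version schema identifier; only `"faers2012"` (the
#'   PRIMARYID-era layout) is supported.
#' @return named list mapping table kind (`demo`, `drug`, `reac`, `outc`,
#'   `ther`, `indi`) to its mandatory lower-case column names.
#' @export
faers_schema <- function(schema_version = "faers2012") {
  if (!identical(schema_version, "faers2012")) {
    stop("unsupported schema_version: ", schema_version,
         " (only 'faers2012' is implemented)", call. = FALSE)
  }
  list(
    demo = c("primaryid", "caseid", "caseversion", "fda_dt", "event_dt",
             "age", "age_cod", "sex", "occp_cod", "reporter_country"),
    drug = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
    reac = c("primaryid", "pt"),
    outc = c("primaryid", "outc_cod"),
    ther = c("primaryid", "dsg_drug_seq", "start_dt"),
    indi = c("primaryid", "indi_drug_seq", "indi_pt")
  )
}

empty_faers_table <- function(kind, schema_version = "faers2012") {
  cols <- faers_schema(schema_version)[[kind]]
  dt <- data.table::setDT(stats::setNames(
    rep(list(character(0)), length(cols)), cols))
  type_faers_table(dt, kind)
}

# character -> typed columns, per table kind; blanks become NA
type_faers_table <- function(dt, kind) {
  blank_to_na <- function(x) {
    x <- trimws(x)
    x[!nzchar(x)] <- NA_character_
    x
  }
  for (j in names(dt)) data.table::set(dt, j = j, value = blank_to_na(dt[[j]]))
  upper <- function(j) if (j %in% names(dt))
    data.table::set(dt, j = j, value = toupper(dt[[j]]))
  int_col <- function(j) if (j %in% names(dt))
    data.table::set(dt, j = j, value = suppressWarnings(as.integer(dt[[j]])))
  num_col <- function(j) if (j %in% names(dt))
    data.table::set(dt, j = j, value = suppressWarnings(as.numeric(dt[[j]])))
  switch(kind,
    demo = {
      int_col("caseversion"); num_col("age")
      upper("age_cod"); upper("sex"); upper("occp_cod")
      upper("reporter_country")
    },
    drug = { int_col("drug_seq"); upper("role_cod") },
    ther = { int_col("dsg_drug_seq") },
    indi = { int_col("indi_drug_seq") },
    NULL)
  dt[]
}

# Read one $-delimited table.  Rows whose field count disagrees with the
# header are rejected and counted, never silently dropped.
read_faers_table <- function(path, kind, schema_version = "faers2012") {
  required <- faers_schema(schema_version)[[kind]]
  raw <- readLines(path, warn = FALSE)
  raw <- iconv(raw, from = "UTF-8", to = "UTF-8", sub = "�")
  raw <- raw[!is.na(raw)]
  if (length(raw) == 0 || !nzchar(trimws(raw[1]))) {
    return(list(data = empty_faers_table(kind, schema_version),
                n_rows = 0L, n_rejected = 0L))
  }
  header <- tolower(trimws(strsplit(raw[1], "$", fixed = TRUE)[[1]]))
  missing <- setdiff(required, header)
  if (length(missing)) {
    stop(sprintf("%s [%s]: missing mandatory column(s): %s",
                 basename(path), toupper(kind),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  body <- raw[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) {
    return(list(data = empty_faers_table(kind, schema_version),
                n_rows = 0L, n_rejected = 0L))
  }
  # sentinel keeps trailing empty fields countable
  parts <- strsplit(paste0(body, "$\x01"), "$", fixed = TRUE)
  ok <- lengths(parts) == length(header) + 1L
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    warning(sprintf("%s [%s]: rejected %d malformed row(s) (wrong field count)",
                    basename(path), toupper(kind), n_rejected), call. = FALSE)
  }
  good <- parts[ok]
  if (length(good) == 0) {
    dt <- empty_faers_table(kind, schema_version)
  } else {
    cols <- data.table::transpose(lapply(good, function(p) p[seq_along(header)]))
    dt <- data.table::setDT(stats::setNames(cols, header))
    dt <- dt[, intersect(c(required, setdiff(header, required)), names(dt)),
             with = FALSE]
    dt <- type_faers_table(dt, kind)
  }
  list(data = dt, n_rows = length(body), n_rejected = n_rejected)
}

locate_quarter_files <- function(dir) {
  files <- list.files(dir, pattern = "\\.(txt|TXT)$", full.names = TRUE)
  found <- list()
  for (kind in faers_table_kinds) {
    hit <- files[grepl(paste0("^", kind), tolower(basename(files)))]
    if (length(hit)) found[[kind]] <- hit[1]
  }
  found
}

#' Parse a FAERS-style quarter
#'
#' Reads the dollar-delimited ASCII tables of one quarterly extract and
#' returns typed tables plus a machine-readable parse report with row and
#' reject counts per table.  Malformed rows (wrong field count) are rejected
#' and counted; a missing mandatory column is an error naming the column; an
#' empty file yields an empty table.
#'
#' @param path either a directory containing files named `DEMO*.txt`,
#'   `DRUG*.txt`, `REAC*.txt`, `OUTC*.txt`, `THER*.txt`, `INDI*.txt`
#'   (case-insensitive), or a named character vector/list of file paths with
#'   names among `demo`, `drug`, `reac`, `outc`, `ther`, `indi`.
#' @param schema_version see [faers_schema()].
#' @return an object of class `faers_quarter`: a list with `tables` (one
#'   `data.table` per kind) and `parse_report` (rows read / rejected per
#'   table).
#' @seealso [assemble_reports()], [write_quarter()]
#' @export
parse_quarter <- function(path, schema_version = "faers2012") {
  if (is.character(path) && length(path) == 1 && dir.exists(path)) {
    paths <- locate_quarter_files(path)
  } else {
    paths <- as.list(path)
    bad <- setdiff(names(paths), faers_table_kinds)
    if (is.null(names(paths)) || length(bad)) {
      stop("path must be a directory or a named vector with names among: ",
           paste(faers_table_kinds, collapse = ", "), call. = FALSE)
    }
  }
  if (!"demo" %in% names(paths)) {
    stop("no DEMO table found: the demographic table is mandatory",
         call. = FALSE)
  }
  tables <- list()
  report <- list()
  for (kind in faers_table_kinds) {
    if (kind %in% names(paths)) {
      if (!file.exists(paths[[kind]])) {
        stop("file does not exist: ", paths[[kind]], call. = FALSE)
      }
      parsed <- read_faers_table(paths[[kind]], kind, schema_version)
    } else {
      parsed <- list(data = empty_faers_table(kind, schema_version),
                     n_rows = 0L, n_rejected = 0L)
    }
    tables[[kind]] <- parsed$data
    report[[kind]] <- list(rows = parsed$n_rows, rejected = parsed$n_rejected,
                           kept = nrow(parsed$data))
  }
  structure(list(tables = tables, parse_report = report,
                 schema_version = schema_version),
            class = "faers_quarter")
}

#' @export
print.faers_quarter <- function(x, ...) {
  cat("<faers_quarter> schema", x$schema_version, "\n")
  for (kind in names(x$tables)) {
    r <- x$parse_report[[kind]]
    cat(sprintf("  %-5s %6d rows (%d rejected)\n",
                toupper(kind), r$kept, r$rejected))
  }
  invisible(x)
}

#' Write a FAERS-style quarter to disk
#'
#' Inverse of [parse_quarter()] on valid input: writes each table as a
#' dollar-delimited text file with a header row (`DEMO.txt`, `DRUG.txt`, ...).
#' Dates are written back as `YYYYMMDD`/`YYYYMM`/`YYYY` strings; `NA` fields
#' become empty strings.
#'
#' @param x a `faers_quarter` object or a named list of data.tables.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_quarter <- function(x, dir) {
  tables <- if (inherits(x, "faers_quarter")) x$tables else x
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- character(0)
  for (kind in intersect(faers_table_kinds, names(tables))) {
    dt <- tables[[kind]]
    path <- file.path(dir, paste0(toupper(kind), ".txt"))
    cols <- lapply(dt, function(col) {
      col <- as.character(col)
      col[is.na(col)] <- ""
      col
    })
    lines <- c(paste(names(dt), collapse = "$"),
               if (nrow(dt)) do.call(paste, c(cols, sep = "$")))
    writeLines(lines, path, useBytes = TRUE)
    out[kind] <- path
  }
  invisible(out)
}

#' Parse a possibly partial FAERS date string
#'
#' FAERS dates are digit strings: `YYYYMMDD` (day precision), `YYYYMM`
#' (month precision) or `YYYY` (year precision).  Partial dates are anchored
#' at the first day of their period but flagged, so downstream consumers can
#' refuse to use them where day precision is required (no imputation is ever
#' performed).  Anything unparseable maps to precision `"absent"`; the
#' function never raises on arbitrary input.
#'
#' @param x character (or numeric) vector of raw date fields.
#' @param warn warn when non-empty input is not a digit string.
#' @return a `data.table` with columns `date` (`IDate`, `NA` when absent) and
#'   `precision` (one of `"day"`, `"month"`, `"year"`, `"absent"`).
#' @examples
#' parse_partial_date(c("20200315", "202003", "2020", "", "0000"))
#' @export
parse_partial_date <- function(x, warn = TRUE) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- trimws(x)
  n <- length(x)
  date <- rep(data.table::as.IDate(NA), n)
  precision <- rep("absent", n)

  digits <- grepl("^\\d+$", x)
  bad <- nzchar(x) & !digits
  if (warn && any(bad)) {
    warning(sprintf("parse_partial_date: %d non-digit date value(s) treated as absent",
                    sum(bad)), call. = FALSE)
  }

  year_ok <- function(y) !is.na(y) & y >= 1900 & y <= 2100

  i8 <- which(digits & nchar(x) == 8)
  if (length(i8)) {
    d <- suppressWarnings(data.table::as.IDate(x[i8], format = "%Y%m%d"))
    valid <- !is.na(d) & year_ok(as.integer(substr(x[i8], 1, 4)))
    date[i8[valid]] <- d[valid]
    precision[i8[valid]] <- "day"
  }
  i6 <- which(digits & nchar(x) == 6)
  if (length(i6)) {
    y <- as.integer(substr(x[i6], 1, 4))
    m <- as.integer(substr(x[i6], 5, 6))
    valid <- year_ok(y) & m >= 1 & m <= 12
    date[i6[valid]] <- data.table::as.IDate(
      sprintf("%04d-%02d-01", y[valid], m[valid]))
    precision[i6[valid]] <- "month"
  }
  i4 <- which(digits & nchar(x) == 4)
  if (length(i4)) {
    y <- as.integer(x[i4])
    valid <- year_ok(y)
    date[i4[valid]] <- data.table::as.IDate(sprintf("%04d-01-01", y[valid]))
    precision[i4[valid]] <- "year"
  }
  data.table::data.table(date = date, precision = precision)
}

#' Assemble case reports from parsed tables
#'
#' Joins parsed date/precision columns onto the demographic table and bundles
#' the child tables (drugs, reactions, outcomes, therapy dates, indications)
#' into a report collection keyed by `primaryid`.  Duplicate `primaryid` rows
#' within the DEMO table violate the quarter invariant; the first occurrence
#' is kept with a warning.
#'
#' @param quarter a `faers_quarter` from [parse_quarter()] (or a compatible
#'   named list of tables).
#' @return an object of class `faers_reports`: list of data.tables `demo`
#'   (with `fda_date`, `fda_precision`, `event_date`, `event_precision`,
#'   `quarter` added), `drug`, `reac`, `outc`, `ther`, `indi`.
#' @export
assemble_reports <- function(quarter) {
  tables <- if (inherits(quarter, "faers_quarter")) quarter$tables else quarter
  demo <- type_faers_table(
    data.table::copy(data.table::as.data.table(tables$demo)), "demo")
  if (anyDuplicated(demo$primaryid)) {
    warning(sprintf("assemble_reports: %d duplicate primaryid row(s) dropped",
                    sum(duplicated(demo$primaryid))), call. = FALSE)
    demo <- demo[!duplicated(primaryid)]
  }
  fda <- parse_partial_date(demo$fda_dt, warn = FALSE)
  evt <- parse_partial_date(demo$event_dt, warn = FALSE)
  demo[, `:=`(fda_date = fda$date, fda_precision = fda$precision,
              event_date = evt$date, event_precision = evt$precision)]
  demo[, quarter := quarter_label(fda_date)]
  if (any(is.na(demo$caseversion))) {
    demo[is.na(caseversion), caseversion := 1L]
  }
  keep_children <- function(kind) {
    dt <- data.table::copy(data.table::as.data.table(
      tables[[kind]] %||% empty_faers_table(kind)))
    dt <- type_faers_table(dt, kind)
    dt[primaryid %in% demo$primaryid]
  }
  out <- list(demo = demo,
              drug = keep_children("drug"),
              reac = keep_children("reac"),
              outc = keep_children("outc"),
              ther = keep_children("ther"),
              indi = keep_children("indi"))
  structure(out, class = "faers_reports")
}

#' @export
print.faers_reports <- function(x, ...) {
  cat("<faers_reports>", nrow(x$demo), "reports;",
      nrow(x$drug), "drug rows;", nrow(x$reac), "reaction rows\n")
  invisible(x)
}

#' Deduplicate case reports
#'
#' FAERS cases are resubmitted as new versions; following FDA guidance only
#' the latest version of each case is analysed.  Exactly one report per
#' `caseid` survives: the one with the highest `caseversion`; ties are broken
#' by the most recent FDA receipt date, then by the lexicographically largest
#' `primaryid`.  The operation is idempotent and the output size equals the
#' number of distinct case identifiers.
#'
#' @param reports a `faers_reports` object from [assemble_reports()].
#' @return a deduplicated `faers_reports`; attribute `n_removed` carries the
#'   number of dropped report versions.
#' @export
deduplicate <- function(reports) {
  stopifnot(inherits(reports, "faers_reports"))
  demo <- reports$demo
  if (nrow(demo) == 0) return(reports)
  fda_num <- as.integer(demo$fda_date)
  fda_num[is.na(fda_num)] <- -.Machine$integer.max
  ord <- order(demo$caseid, -demo$caseversion, -fda_num,
               -xtfrm(demo$primaryid))
  keep_ids <- demo$primaryid[ord][!duplicated(demo$caseid[ord])]
  out <- lapply(reports, function(dt) dt[primaryid %in% keep_ids])
  out$demo <- out$demo[order(primaryid)]
  structure(out, class = "faers_reports",
            n_removed = nrow(demo) - length(keep_ids))
}
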