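#' @importFrom rlang .data
#' @importFrom stats median quantile rnorm rpois rexp runif sd setNames
#' @importFrom utils head tail
NULL

# Canonical vocabularies for the two interchange streams.
event_kinds <- c("motion", "usage_started", "usage_ended")
event_locations <- c("living_room", "bedroom", "bathroom", "kitchen",
                     "bed", "chair", "other")
vital_kinds <- c("systolic_mmHg", "diastolic_mmHg", "pulse_bpm",
                 "spo2_percent", "weight_kg")

#' Parse and format ISO-8601 local timestamps
#'
#' Timestamps are carried as local naive civil datetimes at 1 s resolution.
#' They are stored as POSIXct in the "UTC" zone purely as a zone-free
#' container: no offset arithmetic is ever applied, so daylight-savings
#' transitions in the source data pass through untouched.
#'
#' @param x character vector of `YYYY-MM-DDTHH:MM:SS` strings, or POSIXct.
#' @return `parse_ts()`: POSIXct; `format_ts()`: character.
#' @export
parse_ts <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

#' @rdname parse_ts
#' @export
format_ts <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' Civil day of a timestamp
#'
#' Day boundaries sit at local civil midnight; every event or reading maps
#' to exactly one civil day.
#'
#' @param ts POSIXct vector.
#' @return Date vector.
#' @export
civil_day <- function(ts) as.Date(ts, tz = "UTC")

#' Seconds since local midnight
#' @param ts POSIXct vector.
#' @return numeric seconds in `[0, 86400)`.
#' @export
time_of_day_s <- function(ts) {
  as.numeric(ts) - as.numeric(as.POSIXct(paste0(civil_day(ts), "T00:00:00"),
                                         format = "%Y-%m-%dT%H:%M:%S",
                                         tz = "UTC"))
}

# "HH:MM" or "HH:MM:SS" -> seconds since midnight; "24:00" allowed.
parse_clock <- function(x) {
  if (is.numeric(x)) return(x)
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.numeric(p)
    p[1] * 3600 + ifelse(length(p) >= 2, p[2] * 60, 0) +
      ifelse(length(p) >= 3, p[3], 0)
  }, numeric(1))
}

new_ingest_report <- function(n_read, n_kept, n_duplicates, rejects) {
  list(n_read = n_read, n_kept = n_kept, n_duplicates = n_duplicates,
       rejects = rejects)
}

#' Read a sensor event stream
#'
#' Reads the `events.csv` interchange format
#' (`sensor_id,location,kind,timestamp`): one row per timestamped emission
#' from a named home sensor — a PIR motion pulse or a pressure-sensor
#' `usage_started` / `usage_ended` state change. Rows are validated,
#' exact-duplicate rows (sensor retransmissions) are dropped and counted,
#' and events are returned sorted by `(sensor_id, timestamp)`. Row-level
#' problems are reported with their file line numbers in the ingest report
#' attached as attribute `"ingest_report"`; an unreadable file is fatal.
#'
#' @param path path to a delimited text file with a header row.
#' @param schema named character vector mapping the canonical column names
#'   (`sensor_id`, `location`, `kind`, `timestamp`) to the file's column
#'   names, for files whose headers differ from the default.
#' @return tibble with columns `sensor_id`, `location`, `kind`,
#'   `timestamp` (POSIXct), plus attribute `ingest_report`.
#' @export
read_events <- function(path, schema = NULL) {
  raw <- read_interchange(path, c("sensor_id", "location", "kind", "timestamp"),
                          schema)
  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  ts <- parse_ts(raw$timestamp)
  bad_kind <- !(raw$kind %in% event_kinds)
  bad_loc <- !(raw$location %in% event_locations)
  bad_ts <- is.na(ts)
  reject <- bad_kind | bad_loc | bad_ts
  rejects <- tibble::tibble(
    line = line[reject],
    reason = dplyr::case_when(
      bad_kind[reject] ~ "unknown kind",
      bad_loc[reject] ~ "unknown location",
      TRUE ~ "unparseable timestamp"
    )
  )
  ev <- tibble::tibble(
    sensor_id = raw$sensor_id[!reject],
    location = raw$location[!reject],
    kind = raw$kind[!reject],
    timestamp = ts[!reject]
  )
  n_before <- nrow(ev)
  ev <- dplyr::distinct(ev)
  n_dup <- n_before - nrow(ev)
  ev <- dplyr::arrange(ev, .data$sensor_id, .data$timestamp)
  if (nrow(rejects) > 0)
    message(sprintf("read_events: skipped %d malformed row(s) in %s (lines %s)",
                    nrow(rejects), path,
                    paste(utils::head(rejects$line, 10), collapse = ",")))
  attr(ev, "ingest_report") <- new_ingest_report(nrow(raw), nrow(ev), n_dup,
                                                 rejects)
  ev
}

#' Read a vital-sign reading stream
#'
#' Reads the `vitals.csv` interchange format (`kind,timestamp,value`):
#' timestamped clinical measurements. Values must be finite and positive;
#' oxygen saturation must lie in `[0, 100]` percent. Out-of-range or
#' non-numeric values are rejected with row-level diagnostics, duplicates
#' dropped, and readings returned sorted by `(kind, timestamp)`. An empty
#' file yields an empty collection with a warning.
#'
#' @inheritParams read_events
#' @return tibble with columns `kind`, `timestamp` (POSIXct), `value`,
#'   plus attribute `ingest_report`.
#' @export
read_vitals <- function(path, schema = NULL) {
  raw <- read_interchange(path, c("kind", "timestamp", "value"), schema)
  line <- seq_len(nrow(raw)) + 1L
  ts <- parse_ts(raw$timestamp)
  val <- suppressWarnings(as.numeric(raw$value))
  bad_kind <- !(raw$kind %in% vital_kinds)
  bad_ts <- is.na(ts)
  bad_val <- is.na(val) | !is.finite(val) | val <= 0 |
    (raw$kind == "spo2_percent" & !is.na(val) & val > 100)
  reject <- bad_kind | bad_ts | bad_val
  rejects <- tibble::tibble(
    line = line[reject],
    reason = dplyr::case_when(
      bad_kind[reject] ~ "unknown kind",
      bad_ts[reject] ~ "unparseable timestamp",
      TRUE ~ "value out of range"
    )
  )
  vt <- tibble::tibble(kind = raw$kind[!reject], timestamp = ts[!reject],
                       value = val[!reject])
  n_before <- nrow(vt)
  vt <- dplyr::distinct(vt)
  n_dup <- n_before - nrow(vt)
  vt <- dplyr::arrange(vt, .data$kind, .data$timestamp)
  if (nrow(raw) == 0) warning("read_vitals: empty file ", path)
  if (nrow(rejects) > 0)
    message(sprintf("read_vitals: rejected %d row(s) in %s (lines %s)",
                    nrow(rejects), path,
                    paste(utils::head(rejects$line, 10), collapse = ",")))
  attr(vt, "ingest_report") <- new_ingest_report(nrow(raw), nrow(vt), n_dup,
                                                 rejects)
  vt
}

read_interchange <- function(path, cols, schema) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()))
  if (!is.null(schema)) {
    # schema maps canonical name -> file column name
    for (canon in names(schema)) {
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  missing <- setdiff(cols, names(raw))
  if (length(missing) > 0)
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  raw[cols]
}

#' Write a tabular result as delimited text
#'
#' Writes any homogeneous tabular record set as comma-separated UTF-8 text
#' with a header row. POSIXct columns are serialized as ISO-8601 local
#' timestamps at 1 s resolution, so [read_events()] / [read_vitals()]
#' round-trip their own writes losslessly and a read-then-rewrite is
#' byte-identical.
#'
#' @param records data frame.
#' @param path output path; parent directory must be writable.
#' @return invisibly, `path`.
#' @export
write_table <- function(records, path) {
  out <- as.data.frame(records)
  for (nm in names(out)) {
    if (inherits(out[[nm]], "POSIXct")) out[[nm]] <- format_ts(out[[nm]])
  }
  tryCatch(readr::write_csv(out, path, na = ""),
           error = function(e) stop("cannot write ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}
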