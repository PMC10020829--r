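#' Column mapping for event-log tables
#'
#' Describes how source CSV columns map onto the canonical fields of the three
#' event-log tables (observations, identifications, projects), together with
#' the date formats and the field delimiter. Canonical field names are fixed;
#' only the source column names vary between exports.
#'
#' Required canonical fields are `observation_id`, `observer_id`,
#' `observed_date` (observations); `identification_id`, `observation_id`,
#' `identifier_id` (identifications); and `project_id`, `title`, `start`,
#' `end` (projects). Optional fields (`taxon`, coordinates, `quality`,
#' `identified_date`, `description`, `place_label`) are carried through when
#' mapped and omitted otherwise; any extra mapped column is passed through
#' untouched.
#'
#' @param observations,identifications,projects Named character vectors
#'   mapping canonical field names to source column names. Defaults map each
#'   canonical name to itself.
#' @param date_format Format string for calendar dates (default ISO-8601).
#' @param datetime_format Format string for project start/end timestamps;
#'   timestamps are naive (assumed local to the event). A date-only value is
#'   accepted and read as midnight.
#' @param delimiter Field delimiter, default comma.
#'
#' @return A `col_map` object (a list) accepted by the `read_*` functions.
#' @seealso [read_col_map()] to load a mapping from a YAML file.
#' @export
col_map <- function(observations = NULL, identifications = NULL,
                    projects = NULL, date_format = "%Y-%m-%d",
                    datetime_format = "%Y-%m-%dT%H:%M:%S",
                    delimiter = ",") {
  default_obs <- c(observation_id = "observation_id",
                   observer_id = "observer_id",
                   observed_date = "observed_date",
                   project_id = "project_id",
                   taxon = "taxon",
                   latitude = "latitude",
                   longitude = "longitude")
  default_ids <- c(identification_id = "identification_id",
                   observation_id = "observation_id",
                   identifier_id = "identifier_id",
                   identified_date = "identified_date")
  default_prj <- c(project_id = "project_id",
                   title = "title",
                   description = "description",
                   start = "start",
                   end = "end",
                   place_label = "place_label")
  merge_map <- function(default, user) {
    if (is.null(user)) return(default)
    user <- unlist(user)
    out <- default
    out[names(user)] <- user
    out
  }
  structure(
    list(
      observations = merge_map(default_obs, observations),
      identifications = merge_map(default_ids, identifications),
      projects = merge_map(default_prj, projects),
      date_format = date_format,
      datetime_format = datetime_format,
      delimiter = delimiter
    ),
    class = "col_map"
  )
}

#' Read a column mapping from a YAML configuration file
#'
#' The YAML file may contain sections `observations:`, `identifications:` and
#' `projects:` (each a mapping of canonical field name to source column name)
#' plus optional top-level keys `date_format`, `datetime_format` and
#' `delimiter`.
#'
#' @param path Path to the YAML file.
#' @return A [col_map()] object.
#' @export
read_col_map <- function(path) {
  if (!file.exists(path)) {
    abort_bioblitzr(sprintf("column-map file not found: %s", path),
                    class = "bioblitzr_config_error")
  }
  cfg <- yaml::read_yaml(path)
  col_map(
    observations = cfg$observations,
    identifications = cfg$identifications,
    projects = cfg$projects,
    date_format = cfg$date_format %||% "%Y-%m-%d",
    datetime_format = cfg$datetime_format %||% "%Y-%m-%dT%H:%M:%S",
    delimiter = cfg$delimiter %||% ","
  )
}

# Read a delimited file as all-character tibble; NULL on a zero-row file.
read_raw_table <- function(path, colmap) {
  if (!file.exists(path)) {
    abort_bioblitzr(sprintf("input file not found: %s", path),
                    class = "bioblitzr_config_error")
  }
  if (file.size(path) == 0) return(NULL)
  readr::read_delim(path, delim = colmap$delimiter,
                    col_types = readr::cols(.default = readr::col_character()),
                    na = c("", "NA"), progress = FALSE,
                    show_col_types = FALSE)
}

check_mapped_columns <- function(raw, mapping, required, what) {
  present <- mapping[mapping %in% names(raw)]
  missing_req <- setdiff(required, names(present))
  if (length(missing_req) > 0) {
    missing_src <- mapping[missing_req]
    abort_bioblitzr(
      sprintf("%s: required column(s) not found in header: %s",
              what,
              paste(sprintf("%s (mapped from '%s')", missing_req, missing_src),
                    collapse = ", ")),
      class = "bioblitzr_config_error"
    )
  }
  present
}

# Select + rename mapped columns to canonical names, preserving row order.
canonicalize <- function(raw, present) {
  out <- raw[, unname(present), drop = FALSE]
  names(out) <- names(present)
  out$.row_index <- seq_len(nrow(out))
  out
}

new_rejections <- function() {
  tibble::tibble(row_index = integer(), reason = character())
}

finish_table <- function(out, rejections, canonical_order) {
  keep <- intersect(canonical_order, names(out))
  extra <- setdiff(names(out), c(canonical_order, ".row_index"))
  out <- out[, c(keep, extra), drop = FALSE]
  attr(out, "rejections") <- rejections
  out
}

#' Row-level rejection report of an ingested table
#'
#' Every input row is either present in the returned table or listed exactly
#' once here with the (first) reason it failed validation.
#'
#' @param x A table returned by [read_observations()],
#'   [read_identifications()] or [read_projects()].
#' @return A tibble with columns `row_index` (1-based data row in the source
#'   file, header excluded) and `reason`.
#' @export
rejections <- function(x) {
  attr(x, "rejections") %||% new_rejections()
}

#' Write a rejection report to CSV
#'
#' @param x A table carrying a rejection report (see [rejections()]).
#' @param path Output CSV path.
#' @return Invisibly, the report tibble.
#' @export
write_rejections <- function(x, path) {
  rej <- rejections(x)
  readr::write_csv(rej, path)
  invisible(rej)
}

# Reject rows by a logical mask; returns list(kept, rejections-rows).
reject_rows <- function(out, bad, reason) {
  bad[is.na(bad)] <- FALSE
  rej <- tibble::tibble(row_index = out$.row_index[bad],
                        reason = rep(reason, sum(bad)))
  list(kept = out[!bad, , drop = FALSE], rej = rej)
}

#' Read and validate an observation event log
#'
#' Reads a delimited text file of biodiversity observation records (one row
#' per observation: who recorded what, where and on which calendar day),
#' renames source columns to canonical names via the column map, and
#' validates each row. Rows failing validation are dropped from the result
#' and reported, with their source row number, in the rejection report
#' attached to the returned table (see [rejections()]). Validation checks:
#' parseable `observed_date`; `latitude` in [-90, 90] and `longitude` in
#' [-180, 180] when present; unique `observation_id` (first occurrence kept,
#' later duplicates rejected). Row order is preserved.
#'
#' @param path Path to the CSV file (header row required).
#' @param colmap A [col_map()]; defaults to canonical column names.
#' @return A tibble of validated observation records with canonical columns
#'   (`observation_id`, `observer_id`, `observed_date` as `Date`, plus any
#'   mapped optional columns), carrying a rejection report as an attribute.
#'   An empty file yields an empty table with a warning, not an error.
#' @export
read_observations <- function(path, colmap = col_map()) {
  raw <- read_raw_table(path, colmap)
  mapping <- colmap$observations
  required <- c("observation_id", "observer_id", "observed_date")
  if (is.null(raw) || nrow(raw) == 0) {
    if (is.null(raw)) {
      warning("empty observations file: ", path, call. = FALSE)
    } else {
      check_mapped_columns(raw, mapping, required, "observations")
      warning("observations file has a header but no rows: ", path,
              call. = FALSE)
    }
    out <- tibble::tibble(observation_id = character(),
                          observer_id = character(),
                          observed_date = as.Date(character()))
    attr(out, "rejections") <- new_rejections()
    return(out)
  }
  present <- check_mapped_columns(raw, mapping, required, "observations")
  out <- canonicalize(raw, present)
  rej <- new_rejections()

  parsed <- as.Date(out$observed_date, format = colmap$date_format)
  bad <- is.na(parsed)
  out$observed_date <- parsed
  r <- reject_rows(out, bad, "unparseable observed_date")
  out <- r$kept; rej <- dplyr::bind_rows(rej, r$rej)

  for (coord in c("latitude", "longitude")) {
    if (coord %in% names(out)) {
      val <- suppressWarnings(as.numeric(out[[coord]]))
      lim <- if (coord == "latitude") 90 else 180
      bad <- !is.na(out[[coord]]) & (is.na(val) | abs(val) > lim)
      out[[coord]] <- val
      r <- reject_rows(out, bad, paste0("invalid ", coord))
      out <- r$kept; rej <- dplyr::bind_rows(rej, r$rej)
    }
  }

  bad <- duplicated(out$observation_id)
  r <- reject_rows(out, bad, "duplicate observation_id")
  out <- r$kept; rej <- dplyr::bind_rows(rej, r$rej)

  out$.row_index <- NULL
  finish_table(out, dplyr::arrange(rej, row_index), names(mapping))
}

#' Read and validate an identification event log
#'
#' Reads identification records (who assigned or confirmed a taxonomic
#' identification on which observation). Validation mirrors
#' [read_observations()]: parseable `identified_date` when mapped and
#' non-missing, unique `identification_id` (first kept). When an observation
#' table is supplied, identifications whose `observation_id` does not resolve
#' against it are rejected into the report (cross-validation).
#'
#' @param path Path to the CSV file.
#' @param colmap A [col_map()].
#' @param observations Optional validated observation table; enables
#'   cross-validation of `observation_id`.
#' @return A tibble of identification records with a rejection report
#'   attribute (see [rejections()]).
#' @export
read_identifications <- function(path, colmap = col_map(),
                                 observations = NULL) {
  raw <- read_raw_table(path, colmap)
  mapping <- colmap$identifications
  required <- c("identification_id", "observation_id", "identifier_id")
  if (is.null(raw) || nrow(raw) == 0) {
    if (is.null(raw)) {
      warning("empty identifications file: ", path, call. = FALSE)
    } else {
      check_mapped_columns(raw, mapping, required, "identifications")
      warning("identifications file has a header but no rows: ", path,
              call. = FALSE)
    }
    out <- tibble::tibble(identification_id = character(),
                          observation_id = character(),
                          identifier_id = character())
    attr(out, "rejections") <- new_rejections()
    return(out)
  }
  present <- check_mapped_columns(raw, mapping, required, "identifications")
  out <- canonicalize(raw, present)
  rej <- new_rejections()

  if ("identified_date" %in% names(out)) {
    parsed <- as.Date(out$identified_date, format = colmap$date_format)
    bad <- !is.na(out$identified_date) & is.na(parsed)
    out$identified_date <- parsed
    r <- reject_rows(out, bad, "unparseable identified_date")
    out <- r$kept; rej <- dplyr::bind_rows(rej, r$rej)
  }

  bad <- duplicated(out$identification_id)
  r <- reject_rows(out, bad, "duplicate identification_id")
  out <- r$kept; rej <- dplyr::bind_rows(rej, r$rej)

  if (!is.null(observations)) {
    bad <- !(out$observation_id %in% observations$observation_id)
    r <- reject_rows(out, bad, "unknown observation_id")
    out <- r$kept; rej <- dplyr::bind_rows(rej, r$rej)
  }

  out$.row_index <- NULL
  finish_table(out, dplyr::arrange(rej, row_index), names(mapping))
}

#' Read and validate a project/event metadata table
#'
#' Reads candidate bioblitz events (id, title, start and end timestamps).
#' Start/end are parsed as naive timestamps assumed local to the event; a
#' date-only value is accepted as midnight. Rows with unparseable timestamps
#' or with `end` before `start` are rejected into the report. The returned
#' table gains a `duration_hours` column.
#'
#' @param path Path to the CSV file.
#' @param colmap A [col_map()].
#' @return A tibble of project events with a rejection report attribute.
#' @export
read_projects <- function(path, colmap = col_map()) {
  raw <- read_raw_table(path, colmap)
  mapping <- colmap$projects
  required <- c("project_id", "title", "start", "end")
  if (is.null(raw) || nrow(raw) == 0) {
    if (is.null(raw)) {
      warning("empty projects file: ", path, call. = FALSE)
    } else {
      check_mapped_columns(raw, mapping, required, "projects")
      warning("projects file has a header but no rows: ", path, call. = FALSE)
    }
    out <- tibble::tibble(project_id = character(), title = character(),
                          start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"),
                          duration_hours = numeric())
    attr(out, "rejections") <- new_rejections()
    return(out)
  }
  present <- check_mapped_columns(raw, mapping, required, "projects")
  out <- canonicalize(raw, present)
  rej <- new_rejections()

  parse_ts <- function(x) {
    p <- as.POSIXct(x, format = colmap$datetime_format, tz = "UTC")
    fallback <- is.na(p) & !is.na(x)
    if (any(fallback)) {
      p[fallback] <- as.POSIXct(as.Date(x[fallback],
                                        format = colmap$date_format),
                                tz = "UTC")
    }
    p
  }
  out$start <- parse_ts(out$start)
  out$end <- parse_ts(out$end)
  bad <- is.na(out$start) | is.na(out$end)
  r <- reject_rows(out, bad, "unparseable start/end timestamp")
  out <- r$kept; rej <- dplyr::bind_rows(rej, r$rej)

  bad <- out$end < out$start
  r <- reject_rows(out, bad, "end before start")
  out <- r$kept; rej <- dplyr::bind_rows(rej, r$rej)

  bad <- duplicated(out$project_id)
  r <- reject_rows(out, bad, "duplicate project_id")
  out <- r$kept; rej <- dplyr::bind_rows(rej, r$rej)

  out$duration_hours <- as.numeric(difftime(out$end, out$start,
                                            units = "hours"))
  out$.row_index <- NULL
  finish_table(out, dplyr::arrange(rej, row_index),
               c(names(mapping), "duration_hours"))
}

#' Write event-log tables to CSV in canonical form
#'
#' Writers matching the three readers. Canonical column names and ISO-8601
#' dates/timestamps are used, so a written table read back with the default
#' [col_map()] reproduces the in-memory table field for field.
#'
#' @param x The table to write.
#' @param path Output CSV path.
#' @return Invisibly, `x`.
#' @name eventlog-writers
NULL

#' @rdname eventlog-writers
#' @export
write_observations <- function(x, path) {
  out <- dplyr::mutate(x, observed_date = format(.data$observed_date,
                                                 "%Y-%m-%d"))
  readr::write_csv(out, path, na = "")
  invisible(x)
}

#' @rdname eventlog-writers
#' @export
write_identifications <- function(x, path) {
  out <- x
  if ("identified_date" %in% names(out)) {
    out$identified_date <- format(out$identified_date, "%Y-%m-%d")
  }
  readr::write_csv(out, path, na = "")
  invisible(x)
}

#' @rdname eventlog-writers
#' @export
write_projects <- function(x, path) {
  out <- dplyr::mutate(x,
                       start = format(.data$start, "%Y-%m-%dT%H:%M:%S"),
                       end = format(.data$end, "%Y-%m-%dT%H:%M:%S"))
  out$duration_hours <- NULL
  readr::write_csv(out, path, na = "")
  invisible(x)
}
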