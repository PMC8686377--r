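# Timeline tracks and the first-diagnosis-date registry.
#
# cBioPortal's timeline coordinate is the integer number of calendar days
# since the patient's first diagnosis, not a date. The registry stores one
# first-diagnosis date per patient (as an ISO-8601 date in a sidecar file
# that is not uploaded); every calendar date handed to the timeline API is
# converted to a day offset against it. Day arithmetic is plain proleptic
# Gregorian calendar-day differences — no time zones, no times of day.

BUILTIN_TRACKS <- list(
  treatment = list(mode = "span",
                   extra_columns = c("TREATMENT_TYPE", "SUBTYPE", "AGENT")),
  surgery = list(mode = "point", extra_columns = "SUBTYPE"),
  status = list(mode = "point", extra_columns = "STATUS")
)

TIMELINE_BASE_COLUMNS <- c("PATIENT_ID", "START_DATE", "STOP_DATE", "EVENT_TYPE")

new_timeline_track <- function(name, mode, extra_columns = character(0)) {
  events <- empty_character_df(c(TIMELINE_BASE_COLUMNS, extra_columns))
  events$START_DATE <- integer(0)
  events$STOP_DATE <- integer(0)
  structure(list(name = name, mode = mode,
                 extra_columns = as.character(extra_columns), events = events),
            class = "cbp_timeline_track")
}

parse_iso_date <- function(date, what = "date") {
  if (inherits(date, "Date")) {
    if (is.na(date)) cbp_format_error(sprintf("%s is NA", what))
    return(date)
  }
  date <- as.character(date)
  if (length(date) != 1L || !grepl("^\\d{4}-\\d{2}-\\d{2}$", date)) {
    cbp_format_error(sprintf(
      "%s must be an ISO-8601 calendar date (YYYY-MM-DD), got '%s'",
      what, paste(date, collapse = ",")))
  }
  d <- as.Date(date, format = "%Y-%m-%d")
  if (is.na(d) || format(d, "%Y-%m-%d") != date) {
    cbp_format_error(sprintf("'%s' is not a valid calendar date", date))
  }
  d
}

#' Register a patient's first-diagnosis date
#'
#' Timeline events are stored as day offsets from the patient's first
#' diagnosis, so a diagnosis date must be registered once per patient
#' before any timeline event can be added. If the date is changed later,
#' every stored day offset for that patient is recomputed: moving the
#' diagnosis k days earlier increases every offset by k, because the
#' underlying event dates are unchanged.
#'
#' @param study A \code{cbp_study}.
#' @param patient_id A patient present in the study's patient table.
#' @param date ISO-8601 date string or a \code{Date}.
#' @return The updated study.
#' @export
set_first_diagnosis_date <- function(study, patient_id, date) {
  stopifnot(inherits(study, "cbp_study"))
  if (!patient_id %in% study$patients$records$PATIENT_ID) {
    cbp_not_found_error(sprintf(
      "patient '%s' is not in the study; add the patient first", patient_id))
  }
  d <- parse_iso_date(date, "diagnosis date")
  reg <- study$diagnosis_dates
  existing <- which(reg$PATIENT_ID == patient_id)
  if (length(existing)) {
    old <- as.Date(reg$DATE[[existing]])
    shift <- as.integer(old - d)  # earlier new date -> positive shift
    if (shift != 0L) {
      for (track_name in names(study$timelines)) {
        tr <- study$timelines[[track_name]]
        hit <- tr$events$PATIENT_ID == patient_id
        if (any(hit)) {
          tr$events$START_DATE[hit] <- tr$events$START_DATE[hit] + shift
          tr$events$STOP_DATE[hit] <- tr$events$STOP_DATE[hit] + shift
          study$timelines[[track_name]] <- tr
          study <- mark_dirty(study, paste0("timeline:", track_name))
        }
      }
    }
    reg$DATE[[existing]] <- format(d, "%Y-%m-%d")
  } else {
    reg <- rbind(reg, data.frame(PATIENT_ID = patient_id,
                                 DATE = format(d, "%Y-%m-%d"),
                                 stringsAsFactors = FALSE))
  }
  rownames(reg) <- NULL
  study$diagnosis_dates <- reg
  mark_dirty(study, "diagnosis_dates")
}

#' Convert a calendar date to a day offset
#'
#' Returns the calendar-day difference between an event date and the
#' patient's registered first-diagnosis date (event minus diagnosis).
#' Pre-diagnosis events yield negative offsets, which are allowed but
#' flagged with a warning.
#'
#' @param registry The study's diagnosis-date registry (a data frame with
#'   columns \code{PATIENT_ID}, \code{DATE}), or a \code{cbp_study}.
#' @param patient_id A patient with a registered diagnosis date.
#' @param date The event's calendar date.
#' @return Integer number of days.
#' @export
#' @examples
#' \dontrun{
#' date_to_days(study, "P1", "2020-03-01")
#' }
date_to_days <- function(registry, patient_id, date) {
  if (inherits(registry, "cbp_study")) registry <- registry$diagnosis_dates
  hit <- which(registry$PATIENT_ID == patient_id)
  if (!length(hit)) {
    cbp_precondition_error(sprintf(
      "patient '%s' has no registered first-diagnosis date; call set_first_diagnosis_date() first",
      patient_id))
  }
  diagnosis <- as.Date(registry$DATE[[hit[[1L]]]])
  d <- parse_iso_date(date, "event date")
  days <- as.integer(d - diagnosis)
  if (days < 0L) {
    cbp_warn(sprintf(
      "event date %s precedes the first diagnosis of patient '%s' (offset %d)",
      format(d), patient_id, days), "cbp_negative_offset_warning")
  }
  days
}

#' Create a timeline track
#'
#' The built-in tracks \code{treatment} (span), \code{surgery} (point) and
#' \code{status} (point) exist in every study with fixed modes and extra
#' columns; creating one of them with a different mode is a validation
#' error, with the matching mode it is a no-op. Custom tracks carry either
#' span events (start and stop) or point events (start only).
#'
#' @inheritParams set_first_diagnosis_date
#' @param name Track name; a filesystem-safe token, used in the data file
#'   name \code{data_timeline_<name>.txt}.
#' @param mode \code{"span"} or \code{"point"}.
#' @param extra_columns Further event columns beyond PATIENT_ID,
#'   START_DATE, STOP_DATE, EVENT_TYPE.
#' @return The updated study.
#' @export
create_track <- function(study, name, mode = c("span", "point"),
                         extra_columns = character(0)) {
  stopifnot(inherits(study, "cbp_study"))
  mode <- match.arg(mode)
  if (!grepl("^[A-Za-z0-9_-]+$", name)) {
    cbp_validation_error(sprintf(
      "track name '%s' must be a filesystem-safe token ([A-Za-z0-9_-]+)", name))
  }
  if (name %in% names(BUILTIN_TRACKS)) {
    if (!identical(mode, BUILTIN_TRACKS[[name]]$mode)) {
      cbp_validation_error(sprintf(
        "'%s' is a built-in %s track; its mode cannot be overridden",
        name, BUILTIN_TRACKS[[name]]$mode))
    }
    return(study)  # built-ins always exist
  }
  if (name %in% names(study$timelines)) {
    cbp_conflict_error(sprintf("timeline track '%s' already exists", name))
  }
  assert_cells(extra_columns, "extra column name")
  study$timelines[[name]] <- new_timeline_track(name, mode, extra_columns)
  mark_dirty(study, paste0("timeline:", name))
}

#' Add a timeline event
#'
#' Appends one event to a track. The patient must exist and have a
#' registered first-diagnosis date (the mandated workflow order). Start and
#' stop may be calendar dates (converted via [date_to_days()]) or integer
#' day offsets. Point tracks take no stop; span tracks require
#' stop >= start when a stop is given.
#'
#' @inheritParams set_first_diagnosis_date
#' @param track Track name (built-in or previously created).
#' @param start Event start: ISO date, \code{Date}, or integer days.
#' @param stop Optional event stop, same forms as \code{start}.
#' @param event_type Free-text event type (e.g. the agent of a treatment).
#' @param extras Named values for the track's extra columns.
#' @return The updated study.
#' @export
add_event <- function(study, track, patient_id, start, stop = NULL,
                      event_type = "", extras = list()) {
  stopifnot(inherits(study, "cbp_study"))
  if (!track %in% names(study$timelines)) {
    cbp_not_found_error(sprintf(
      "no timeline track '%s'; create it with create_track() first", track))
  }
  if (!patient_id %in% study$patients$records$PATIENT_ID) {
    cbp_precondition_error(sprintf(
      "patient '%s' is not in the study; add the patient before adding timeline events",
      patient_id))
  }
  if (!patient_id %in% study$diagnosis_dates$PATIENT_ID) {
    cbp_precondition_error(sprintf(
      "patient '%s' has no first-diagnosis date; set it with set_first_diagnosis_date() before adding timeline events",
      patient_id))
  }
  tr <- study$timelines[[track]]
  to_days <- function(x, what) {
    if (is.numeric(x)) {
      v <- as.integer(x)
      if (is.na(v) || v != x) {
        cbp_validation_error(sprintf("%s must be an integer day offset or a date", what))
      }
      v
    } else if (is.character(x) && length(x) == 1L && grepl("^-?[0-9]+$", x)) {
      as.integer(x)
    } else {
      date_to_days(study$diagnosis_dates, patient_id, x)
    }
  }
  start_days <- to_days(start, "start")
  stop_days <- NA_integer_
  if (!is.null(stop) && !(length(stop) == 1L && is.na(stop))) {
    if (tr$mode == "point") {
      cbp_validation_error(sprintf(
        "track '%s' holds point events; a stop cannot be supplied", track))
    }
    stop_days <- to_days(stop, "stop")
    if (stop_days < start_days) {
      cbp_validation_error(sprintf(
        "stop (%d) must not precede start (%d) on span track '%s'",
        stop_days, start_days, track))
    }
  }
  extras <- as.list(extras)
  unknown <- setdiff(names(extras), tr$extra_columns)
  if (length(unknown)) {
    cbp_validation_error(sprintf(
      "track '%s' has no column(s): %s", track, paste(unknown, collapse = ", ")))
  }
  assert_cells(c(event_type, unlist(extras)), "event value")
  row <- stats::setNames(as.list(rep("", length(tr$extra_columns))),
                         tr$extra_columns)
  row[names(extras)] <- lapply(extras, as.character)
  new_row <- data.frame(PATIENT_ID = patient_id, START_DATE = start_days,
                        STOP_DATE = stop_days, EVENT_TYPE = as.character(event_type),
                        stringsAsFactors = FALSE)
  for (col in tr$extra_columns) new_row[[col]] <- row[[col]]
  tr$events <- rbind(tr$events, new_row)
  rownames(tr$events) <- NULL
  study$timelines[[track]] <- tr
  mark_dirty(study, paste0("timeline:", track))
}

# ---- file dialect -----------------------------------------------------------

timeline_lines <- function(track) {
  ev <- track$events
  ev$START_DATE <- as.character(ev$START_DATE)
  ev$STOP_DATE <- ifelse(is.na(track$events$STOP_DATE), "",
                         as.character(track$events$STOP_DATE))
  format_tsv_table(ev)
}

parse_timeline_file <- function(path, name) {
  tab <- read_tsv_table(path, comment = FALSE)
  missing <- setdiff(TIMELINE_BASE_COLUMNS, names(tab))
  if (length(missing)) {
    cbp_parse_error(sprintf("timeline file '%s' lacks column(s): %s",
                            basename(path), paste(missing, collapse = ", ")),
                    file = path)
  }
  start <- suppressWarnings(as.integer(tab$START_DATE))
  if (any(is.na(start) & nzchar(tab$START_DATE)) || any(!nzchar(tab$START_DATE))) {
    cbp_parse_error(sprintf(
      "timeline file '%s': START_DATE must be integer day offsets", basename(path)),
      file = path)
  }
  stop_raw <- tab$STOP_DATE
  stop <- suppressWarnings(as.integer(stop_raw))
  if (any(is.na(stop) & nzchar(stop_raw))) {
    cbp_parse_error(sprintf(
      "timeline file '%s': STOP_DATE must be integer day offsets or empty",
      basename(path)), file = path)
  }
  extra <- setdiff(names(tab), TIMELINE_BASE_COLUMNS)
  if (name %in% names(BUILTIN_TRACKS)) {
    mode <- BUILTIN_TRACKS[[name]]$mode
  } else if (nrow(tab) == 0L) {
    # the file dialect records no mode; an event-less custom track defaults
    # to span (the permissive choice: point events remain addable)
    mode <- "span"
  } else {
    mode <- if (any(nzchar(stop_raw))) "span" else "point"
  }
  track <- new_timeline_track(name, mode, extra)
  ev <- tab
  ev$START_DATE <- start
  ev$STOP_DATE <- stop
  attr(ev, "row_lines") <- NULL
  track$events <- ev[, c(TIMELINE_BASE_COLUMNS, extra), drop = FALSE]
  track
}

diagnosis_lines <- function(registry) {
  format_tsv_table(registry)
}

parse_diagnosis_file <- function(path) {
  tab <- read_tsv_table(path, comment = FALSE)
  missing <- setdiff(c("PATIENT_ID", "DATE"), names(tab))
  if (length(missing)) {
    cbp_parse_error(sprintf("diagnosis-date file '%s' lacks column(s): %s",
                            basename(path), paste(missing, collapse = ", ")),
                    file = path)
  }
  for (d in tab$DATE) parse_iso_date(d, sprintf("date in '%s'", basename(path)))
  attr(tab, "row_lines") <- NULL
  tab[, c("PATIENT_ID", "DATE"), drop = FALSE]
}

meta_timeline_keys <- function(study_id, track_name) {
  c(cancer_study_identifier = study_id,
    genetic_alteration_type = "CLINICAL",
    datatype = "TIMELINE",
    data_filename = sprintf("data_timeline_%s.txt", track_name))
}
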