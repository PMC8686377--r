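timeline_study <- function() {
  root <- new_root()
  s <- create_study(root, study_meta("tl_study", "mixed", "TL", "Timeline fixture"))
  s <- add_patient(s, c(PATIENT_ID = "P1"))
  s <- add_patient(s, c(PATIENT_ID = "P2"))
  s
}

test_that("diagnosis dates are registered per patient with validation", {
  s <- timeline_study()
  s <- set_first_diagnosis_date(s, "P1", "2020-01-01")
  expect_identical(s$diagnosis_dates$DATE, "2020-01-01")
  expect_error(set_first_diagnosis_date(s, "PX", "2020-01-01"),
               class = "cbp_not_found_error")
  expect_error(set_first_diagnosis_date(s, "P1", "01.02.2020"),
               class = "cbp_format_error")
  expect_error(set_first_diagnosis_date(s, "P1", "2020-02-30"),
               class = "cbp_format_error")
})

test_that("date_to_days matches calendar arithmetic including leap years", {
  s <- timeline_study()
  s <- set_first_diagnosis_date(s, "P1", "2020-01-01")
  expect_identical(date_to_days(s, "P1", "2020-01-01"), 0L)
  expect_identical(date_to_days(s, "P1", "2020-03-01"), 60L)  # 2020 is a leap year
  expect_warning(d <- date_to_days(s, "P1", "2019-12-31"),
                 class = "cbp_negative_offset_warning")
  expect_identical(d, -1L)
  expect_error(date_to_days(s, "P2", "2020-01-01"),
               class = "cbp_precondition_error")
})

test_that("day offsets agree with an independent day-count oracle", {
  set.seed(11)
  n <- 400
  from <- random_iso_dates(n)
  to <- random_iso_dates(n)
  s <- timeline_study()
  got <- integer(n)
  for (i in seq_len(n)) {
    s <- set_first_diagnosis_date(s, "P1", from[[i]])
    got[[i]] <- suppressWarnings(date_to_days(s, "P1", to[[i]]))
  }
  expect_identical(got, as.integer(oracle_day_diff(from, to)))
})

test_that("tracks enforce built-in modes and uniqueness", {
  s <- timeline_study()
  s <- create_track(s, "imaging", "point", "MODALITY")
  expect_identical(s$timelines$imaging$mode, "point")
  expect_identical(nrow(s$timelines$imaging$events), 0L)
  expect_error(create_track(s, "imaging", "point"), class = "cbp_conflict_error")
  expect_error(create_track(s, "treatment", "point"),
               class = "cbp_validation_error")
  expect_error(create_track(s, "bad name!", "point"),
               class = "cbp_validation_error")
  # matching mode on a built-in is a no-op
  s2 <- create_track(s, "surgery", "point")
  expect_identical(s2$timelines, s$timelines)
})

test_that("events convert dates, enforce modes and the workflow order", {
  s <- timeline_study()
  s <- set_first_diagnosis_date(s, "P1", "2020-01-01")
  s <- add_event(s, "treatment", "P1", start = "2020-02-01",
                 stop = "2020-03-01", event_type = "Medical Therapy",
                 extras = list(AGENT = "Cisplatin"))
  ev <- s$timelines$treatment$events
  expect_identical(ev$START_DATE, 31L)
  expect_identical(ev$STOP_DATE, 60L)

  expect_error(add_event(s, "status", "P1", start = "2020-02-01",
                         stop = "2020-03-01"),
               class = "cbp_validation_error")  # point events take no stop
  expect_error(add_event(s, "treatment", "P1", start = "2020-03-01",
                         stop = "2020-02-01"),
               class = "cbp_validation_error")  # stop before start
  expect_error(add_event(s, "treatment", "P2", start = "2020-02-01"),
               class = "cbp_precondition_error")  # no diagnosis date yet
  expect_error(add_event(s, "treatment", "P9", start = "2020-02-01"),
               class = "cbp_precondition_error")  # patient does not exist
  expect_error(add_event(s, "nope", "P1", start = "2020-02-01"),
               class = "cbp_not_found_error")
  expect_error(add_event(s, "treatment", "P1", start = 5L,
                         extras = list(NOT_A_COL = "x")),
               class = "cbp_validation_error")

  # integer day offsets are accepted directly
  s <- add_event(s, "status", "P1", start = 90L, event_type = "STATUS",
                 extras = list(STATUS = "Stable Disease"))
  expect_identical(s$timelines$status$events$START_DATE, 90L)
})

test_that("re-setting a diagnosis date shifts stored offsets by the day delta", {
  s <- timeline_study()
  s <- set_first_diagnosis_date(s, "P1", "2020-01-11")
  s <- set_first_diagnosis_date(s, "P2", "2020-01-11")
  s <- add_event(s, "treatment", "P1", start = "2020-02-01", stop = "2020-03-01")
  s <- add_event(s, "status", "P1", start = "2020-04-01")
  s <- add_event(s, "status", "P2", start = "2020-04-01")
  before_p2 <- s$timelines$status$events$START_DATE[[2L]]

  # move the diagnosis 10 days earlier: every P1 offset grows by 10
  s <- set_first_diagnosis_date(s, "P1", "2020-01-01")
  expect_identical(s$timelines$treatment$events$START_DATE, 21L + 10L)
  expect_identical(s$timelines$treatment$events$STOP_DATE, 50L + 10L)
  expect_identical(s$timelines$status$events$START_DATE[[1L]], 81L + 10L)
  # other patients are untouched
  expect_identical(s$timelines$status$events$START_DATE[[2L]], before_p2)
})

test_that("tracks round trip through files with extra columns and modes", {
  root <- new_root()
  s <- create_study(root, study_meta("tl_rt", "mixed", "TL", "Round trip"))
  s <- add_patient(s, c(PATIENT_ID = "P1"))
  s <- set_first_diagnosis_date(s, "P1", "2020-01-01")
  s <- create_track(s, "imaging", "point", "MODALITY")
  s <- add_event(s, "imaging", "P1", start = "2020-02-10", event_type = "IMAGING",
                 extras = list(MODALITY = "MRI"))
  s <- add_event(s, "treatment", "P1", start = 3L, stop = 40L,
                 event_type = "Medical Therapy",
                 extras = list(TREATMENT_TYPE = "Medical Therapy",
                               AGENT = "Trametinib"))
  s <- save_study(s, components = "all")
  loaded <- load_study(root, "tl_rt")
  expect_identical(loaded$timelines$imaging$events, s$timelines$imaging$events)
  expect_identical(loaded$timelines$imaging$mode, "point")
  expect_identical(loaded$timelines$imaging$extra_columns, "MODALITY")
  expect_identical(loaded$timelines$treatment$events, s$timelines$treatment$events)
  # point events are written with an empty STOP_DATE cell
  lines <- readLines(file.path(root, "tl_rt", "data_timeline_imaging.txt"))
  expect_match(lines[[2L]], "^P1\t40\t\tIMAGING\tMRI$")
})
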