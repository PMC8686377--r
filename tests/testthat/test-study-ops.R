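test_that("samples require their patient to exist first", {
  root <- new_root()
  s <- create_study(root, study_meta("order_study", "mixed", "O", "Ordering"))
  err <- tryCatch(add_sample(s, c(PATIENT_ID = "P1", SAMPLE_ID = "S1")),
                  error = function(e) e)
  expect_s3_class(err, "cbp_precondition_error")
  expect_match(conditionMessage(err), "add the patient")
  s <- add_patient(s, c(PATIENT_ID = "P1"))
  s <- add_sample(s, c(PATIENT_ID = "P1", SAMPLE_ID = "S1"))
  expect_identical(nrow(s$samples$records), 1L)
})

test_that("deleting a patient cascades to every dependent component", {
  root <- new_root()
  s <- make_linked_study(root)
  s <- delete_patient(s, "P1")
  expect_identical(s$patients$records$PATIENT_ID, "P2")
  expect_identical(nrow(s$samples$records), 0L)
  expect_identical(nrow(s$mutations), 0L)
  expect_identical(nrow(s$diagnosis_dates), 0L)
  expect_identical(sum(vapply(s$timelines, function(t) nrow(t$events), 0L)), 0L)
  expect_identical(nrow(s$resources$patient), 0L)
  # the emptied components persist through a save
  s <- save_study(s)
  reloaded <- load_study(root, "linked_study")
  expect_identical(nrow(reloaded$samples$records), 0L)
  expect_identical(nrow(reloaded$mutations), 0L)
})

test_that("import_patient transfers the patient's full data cascade", {
  root <- new_root()
  src <- make_linked_study(root)
  dst <- create_study(root, study_meta("dst_study", "mixed", "D", "Destination"))
  dst <- add_patient(dst, c(PATIENT_ID = "Q1"))

  dst <- import_patient(src, dst, "P1")
  expect_setequal(dst$patients$records$PATIENT_ID, c("Q1", "P1"))
  expect_identical(nrow(dst$samples$records), 2L)
  expect_identical(nrow(dst$mutations), 5L)
  expect_identical(sum(vapply(dst$timelines, function(t) nrow(t$events), 0L)), 3L)
  expect_identical(dst$diagnosis_dates$PATIENT_ID, "P1")
  expect_identical(nrow(dst$resources$patient), 1L)
  expect_identical(dst$resources$definitions$RESOURCE_ID, "REPORT")

  # src-only columns are created in dst with src metadata; existing dst
  # patients get empty values
  expect_true(all(c("AGE", "ECOG") %in% dst$patients$attributes$column_id))
  expect_identical(
    dst$patients$attributes$short_name[dst$patients$attributes$column_id == "ECOG"],
    "ECOG Status")
  q1 <- dst$patients$records[dst$patients$records$PATIENT_ID == "Q1", ]
  expect_identical(q1$ECOG, "")
  p1 <- dst$patients$records[dst$patients$records$PATIENT_ID == "P1", ]
  expect_identical(p1$AGE, "61")
})

test_that("a second identical import is refused and leaves dst unchanged", {
  root <- new_root()
  src <- make_linked_study(root)
  dst <- create_study(root, study_meta("dst2", "mixed", "D", "Destination"))
  dst <- import_patient(src, dst, "P1")
  snapshot <- study_state(dst)
  expect_error(import_patient(src, dst, "P1"), class = "cbp_conflict_error")
  expect_identical(study_state(dst), snapshot)
  expect_error(import_patient(src, dst, "P_NONE"), class = "cbp_not_found_error")
})

test_that("imported studies remain valid on disk", {
  root <- new_root()
  src <- make_linked_study(root)
  save_study(src, components = "all")
  dst <- create_study(root, study_meta("dst3", "mixed", "D", "Destination"))
  dst <- import_patient(src, dst, "P1")
  save_study(dst)
  expect_identical(validate_study(file.path(root, "dst3"))$status, "PASS")
})
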