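test_that("records honour mandatory IDs, uniqueness and datatypes", {
  tbl <- clinical_table("patient")
  tbl <- add_record(tbl, c(PATIENT_ID = "P1"))
  expect_identical(nrow(tbl$records), 1L)
  expect_true(all(tbl$records[1L, setdiff(names(tbl$records), "PATIENT_ID")] == ""))

  expect_error(add_record(tbl, c(PATIENT_ID = "P1")), class = "cbp_conflict_error")
  expect_error(add_record(tbl, c(SEX = "F")), class = "cbp_validation_error")

  tbl <- add_column(tbl, "AGE")
  expect_error(add_record(tbl, c(PATIENT_ID = "P2", AGE = "abc")),
               class = "cbp_datatype_error")
  tbl <- add_record(tbl, c(PATIENT_ID = "P2", AGE = "42"))
  expect_identical(tbl$records$AGE[[2L]], "42")

  stbl <- clinical_table("sample")
  expect_error(add_record(stbl, c(PATIENT_ID = "P1")),
               class = "cbp_validation_error")  # SAMPLE_ID missing
})

test_that("edit and delete operate on single records and protect IDs", {
  tbl <- clinical_table("patient")
  tbl <- add_column(tbl, "SEX")
  tbl <- add_column(tbl, "AGE")
  tbl <- add_record(tbl, c(PATIENT_ID = "P1", SEX = "M", AGE = "50"))
  tbl <- edit_record(tbl, "P1", c(SEX = "F"))
  expect_identical(tbl$records$SEX[[1L]], "F")
  expect_identical(tbl$records$AGE[[1L]], "50")
  expect_error(edit_record(tbl, "P1", c(PATIENT_ID = "P9")),
               class = "cbp_validation_error")
  expect_error(edit_record(tbl, "PX", c(SEX = "F")), class = "cbp_not_found_error")
  expect_error(delete_record(tbl, "PX"), class = "cbp_not_found_error")
  tbl <- delete_record(tbl, "P1")
  expect_identical(nrow(tbl$records), 0L)
})

test_that("columns can be added from definitions or the predefined catalog", {
  tbl <- clinical_table("patient")
  tbl <- add_column(tbl, attribute_def("SMOKER", "Smoker", "Smoking status",
                                       "BOOLEAN"))
  expect_true("SMOKER" %in% tbl$attributes$column_id)
  expect_false(tbl$attributes$predefined[tbl$attributes$column_id == "SMOKER"])

  tbl <- add_column(tbl, "OS_STATUS")
  at <- tbl$attributes[tbl$attributes$column_id == "OS_STATUS", ]
  expect_identical(at$short_name, "Overall Survival Status")
  expect_identical(at$datatype, "STRING")
  expect_true(at$predefined)

  expect_error(add_column(tbl, "PATIENT_ID"), class = "cbp_conflict_error")
  err <- tryCatch(add_column(tbl, "NOT_PREDEFINED"), error = function(e) e)
  expect_s3_class(err, "cbp_not_found_error")
  expect_match(conditionMessage(err), "OS_STATUS")  # lists available names

  expect_error(delete_column(tbl, "PATIENT_ID"), class = "cbp_validation_error")
  expect_error(delete_column(tbl, "ABSENT"), class = "cbp_not_found_error")
  tbl <- delete_column(tbl, "SMOKER")
  expect_false("SMOKER" %in% names(tbl$records))
})

test_that("the editable model carries three metadata rows ahead of records", {
  tbl <- clinical_table("patient")
  tbl <- add_column(tbl, "AGE")
  tbl <- add_record(tbl, c(PATIENT_ID = "P1", AGE = "61"))
  view <- clinical_editable_view(tbl)
  expect_identical(attr(view, "n_metadata_rows"), 3L)
  expect_identical(nrow(view), 3L + 1L)
  expect_identical(view$AGE[1:3], c("Diagnosis Age",
                                    "Age at which the condition or disease was first diagnosed, in years",
                                    "NUMBER"))
  expect_identical(view$PATIENT_ID[[4L]], "P1")
})

test_that("table-file-table round trip preserves attributes and values", {
  root <- new_root()
  s <- make_linked_study(root)
  s <- save_study(s, components = "all")
  loaded <- load_study(root, "linked_study")
  expect_identical(loaded$patients$attributes, s$patients$attributes)
  expect_identical(loaded$patients$records, s$patients$records)
  expect_identical(loaded$samples$attributes, s$samples$attributes)
  expect_identical(loaded$samples$records, s$samples$records)
})

test_that("invariants hold under random operation sequences", {
  set.seed(7)
  tbl <- clinical_table("patient")
  tbl <- add_column(tbl, "AGE")
  pool_cols <- c("C1", "C2", "C3", "C4")
  for (i in 1:120) {
    op <- sample(c("add", "edit", "delete", "add_col", "del_col"), 1L)
    res <- tryCatch(switch(op,
      add = add_record(tbl, list(PATIENT_ID = sprintf("P%d", sample(1:30, 1L)),
                                 AGE = as.character(sample(20:90, 1L)))),
      edit = edit_record(tbl, sprintf("P%d", sample(1:30, 1L)),
                         list(AGE = as.character(sample(20:90, 1L)))),
      delete = delete_record(tbl, sprintf("P%d", sample(1:30, 1L))),
      add_col = add_column(tbl, attribute_def(sample(pool_cols, 1L), "Short",
                                              "Long", "NUMBER")),
      del_col = delete_column(tbl, sample(pool_cols, 1L))
    ), cbp_error = function(e) e)
    if (!inherits(res, "error")) tbl <- res
    # invariants after every step
    expect_false(anyDuplicated(tbl$records$PATIENT_ID) > 0L)
    expect_identical(names(tbl$records), tbl$attributes$column_id)
    expect_true("PATIENT_ID" %in% tbl$attributes$column_id)
    for (j in seq_len(nrow(tbl$attributes))) {
      vals <- tbl$records[[tbl$attributes$column_id[[j]]]]
      expect_true(all(vapply(vals, function(v) {
        cbpstudio:::value_conforms(v, tbl$attributes$datatype[[j]])
      }, logical(1))))
    }
  }
})
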