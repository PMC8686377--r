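test_that("studies are discovered, created and listed", {
  root <- new_root()
  expect_identical(list_studies(root), character(0))

  create_study(root, study_meta("testpatient", "mixed", "Test", "Test study"))
  create_study(root, study_meta("mtb_2021", "mixed", "MTB", "MTB study"))
  expect_identical(list_studies(root), c("mtb_2021", "testpatient"))

  # a folder without meta_study is skipped with a warning, not an error
  dir.create(file.path(root, "not_a_study"))
  expect_warning(ids <- list_studies(root), class = "cbp_skipped_folder_warning")
  expect_identical(ids, c("mtb_2021", "testpatient"))

  expect_error(list_studies(file.path(root, "missing")), class = "cbp_io_error")
})

test_that("create_study writes the meta-study file and rejects bad input", {
  root <- new_root()
  meta <- study_meta("mtb_mainz", "mixed", "MTB", "MTB study")
  study <- create_study(root, meta)
  lines <- readLines(file.path(root, "mtb_mainz", "meta_study.txt"))
  expect_identical(lines, c("type_of_cancer: mixed",
                            "cancer_study_identifier: mtb_mainz",
                            "name: MTB",
                            "description: MTB study"))
  expect_identical(nrow(study$patients$records), 0L)
  expect_identical(nrow(study$mutations), 0L)

  expect_error(study_meta("a b/c", "mixed", "x", "y"),
               class = "cbp_validation_error")
  expect_error(study_meta("ok_id", "mixed", "", "y"),
               class = "cbp_validation_error")
  expect_error(study_meta("ok_id", "not_a_code", "x", "y"),
               class = "cbp_validation_error")
  expect_error(create_study(root, meta), class = "cbp_conflict_error")
  expect_true("mtb_mainz" %in% list_studies(root))
})

test_that("load_study parses all present components and is atomic", {
  root <- new_root()
  s <- make_linked_study(root)
  s <- save_study(s, components = "all")
  loaded <- load_study(root, "linked_study")
  expect_identical(nrow(loaded$patients$records), 2L)
  expect_identical(nrow(loaded$samples$records), 2L)
  expect_identical(nrow(loaded$mutations), 5L)
  expect_identical(nrow(loaded$diagnosis_dates), 1L)
  expect_identical(nrow(loaded$timelines$treatment$events), 2L)
  expect_identical(length(loaded$dirty), 0L)

  # study with only meta_study -> all-empty components
  create_study(root, study_meta("bare", "brca", "Bare", "Only meta"))
  bare <- load_study(root, "bare")
  expect_identical(nrow(bare$patients$records), 0L)
  expect_identical(nrow(bare$mutations), 0L)
  expect_identical(nrow(bare$resources$definitions), 0L)

  # clinical record row with more cells than header columns -> parse error
  # citing the row
  clin <- file.path(root, "linked_study", "data_clinical_patient.txt")
  lines <- readLines(clin)
  lines[[6L]] <- paste0(lines[[6L]], "\textra_cell")
  writeLines(lines, clin)
  err <- tryCatch(load_study(root, "linked_study"), error = function(e) e)
  expect_s3_class(err, "cbp_parse_error")
  expect_match(conditionMessage(err), "row 1")

  expect_error(load_study(root, "does_not_exist"), class = "cbp_not_found_error")
})

test_that("save_study writes exactly the dirty components", {
  root <- new_root()
  s <- make_linked_study(root)
  s <- save_study(s, components = "all")

  # no dirty components -> nothing written
  s2 <- load_study(root, "linked_study")
  s2 <- save_study(s2)
  expect_identical(attr(s2, "written"), character(0))

  # modify one patient -> exactly the patient data+meta pair
  s2 <- load_study(root, "linked_study")
  s2$patients <- edit_record(s2$patients, "P1", list(AGE = "62"))
  s2 <- mark_dirty(s2, "patients")
  s2 <- save_study(s2)
  expect_setequal(basename(attr(s2, "written")),
                  c("data_clinical_patient.txt", "meta_clinical_patient.txt"))
})

test_that("load-save round trip is byte-identical and state-identical", {
  root <- new_root()
  s <- make_linked_study(root)
  s <- save_study(s, components = "all")
  dir <- file.path(root, "linked_study")
  before <- read_study_bytes(dir)
  first <- load_study(root, "linked_study")
  save_study(first, components = "all")
  expect_identical(read_study_bytes(dir), before)
  second <- load_study(root, "linked_study")
  expect_identical(study_state(first), study_state(second))
})

test_that("a save failing its referential check writes nothing", {
  root <- new_root()
  s <- make_linked_study(root)
  s <- save_study(s, components = "all")
  dir <- file.path(root, "linked_study")
  before <- read_study_bytes(dir)
  # force an orphan sample directly into the table
  s$samples$records$PATIENT_ID[[1L]] <- "P_GHOST"
  s <- mark_dirty(s, "samples")
  expect_error(save_study(s, components = "all"), class = "cbp_referential_error")
  expect_identical(read_study_bytes(dir), before)
})

test_that("update_meta changes metadata but never the identifier", {
  root <- new_root()
  s <- create_study(root, study_meta("meta_study1", "mixed", "Name", "Desc"))
  s <- update_meta(s, study_meta("meta_study1", "brca", "Name", "New description"))
  s <- save_study(s)
  reloaded <- load_study(root, "meta_study1")
  expect_identical(reloaded$meta$description, "New description")
  expect_identical(reloaded$meta$type_of_cancer, "brca")
  expect_error(
    update_meta(s, study_meta("renamed", "mixed", "Name", "Desc")),
    class = "cbp_unsupported_error")
})
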