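make_maf_df <- function(n, barcode = "P1-S1", gene = "TP53") {
  data.frame(
    Hugo_Symbol = rep(gene, n),
    Tumor_Sample_Barcode = rep(barcode, n),
    Variant_Classification = rep("Missense_Mutation", n),
    HGVSp_Short = sprintf("p.R%dH", seq_len(n)),
    stringsAsFactors = FALSE)
}

study_with_samples <- function() {
  root <- new_root()
  s <- create_study(root, study_meta("maf_study", "mixed", "MAF", "MAF fixture"))
  s <- add_patient(s, c(PATIENT_ID = "P1"))
  s <- add_sample(s, c(PATIENT_ID = "P1", SAMPLE_ID = "P1-S1"))
  s <- add_sample(s, c(PATIENT_ID = "P1", SAMPLE_ID = "P1-S2"))
  s
}

test_that("MAF import concatenates rows and unions columns", {
  s <- study_with_samples()
  s <- import_maf(s, make_maf_df(5))
  expect_identical(nrow(s$mutations), 5L)

  extra <- make_maf_df(3, barcode = "P1-S2")
  extra$Variant_Type <- rep("SNP", 3)
  s <- import_maf(s, extra)
  expect_identical(nrow(s$mutations), 8L)
  expect_true("Variant_Type" %in% names(s$mutations))
  expect_identical(s$mutations$Variant_Type[1:5], rep("", 5L))
  expect_true("mutations" %in% s$dirty)
})

test_that("MAF import requires the four mandatory columns", {
  s <- study_with_samples()
  bad <- make_maf_df(2)
  bad$HGVSp_Short <- NULL
  err <- tryCatch(import_maf(s, bad), error = function(e) e)
  expect_s3_class(err, "cbp_format_error")
  expect_match(conditionMessage(err), "HGVSp_Short")
  expect_identical(err$missing_columns, "HGVSp_Short")
})

test_that("unknown barcodes import with a referential warning", {
  s <- study_with_samples()
  expect_warning(s <- import_maf(s, make_maf_df(2, barcode = "S_UNKNOWN")),
                 class = "cbp_referential_warning")
  expect_identical(nrow(s$mutations), 2L)
})

test_that("MAF files round trip through disk, tolerating comment lines", {
  s <- study_with_samples()
  s <- import_maf(s, make_maf_df(5))
  s <- save_study(s, components = "all")
  root <- s$root

  loaded <- load_study(root, "maf_study")
  expect_identical(loaded$mutations, s$mutations)

  # a MAF file with leading '#' comments reads identically
  path <- tempfile(fileext = ".maf")
  writeLines(c("#version 2.4",
               readLines(file.path(root, "maf_study",
                                   "data_mutations_extended.txt"))), path)
  s2 <- study_with_samples()
  s2 <- import_maf(s2, path)
  expect_identical(s2$mutations, s$mutations)
})

test_that("concatenation matches importing the pre-concatenated file", {
  a <- make_maf_df(3)
  b <- make_maf_df(4, barcode = "P1-S2", gene = "KRAS")
  s1 <- study_with_samples()
  s1 <- import_maf(import_maf(s1, a), b)
  s2 <- study_with_samples()
  s2 <- import_maf(s2, rbind(a, b))
  expect_identical(s1$mutations, s2$mutations)
})

test_that("empty mutation tables write a header-only file, meta and case list", {
  root <- new_root()
  s <- create_study(root, study_meta("empty_maf", "mixed", "E", "Empty MAF"))
  write_maf(s)
  dir <- file.path(root, "empty_maf")
  data_lines <- readLines(file.path(dir, "data_mutations_extended.txt"))
  expect_identical(data_lines, paste(c("Hugo_Symbol", "Tumor_Sample_Barcode",
                                       "Variant_Classification", "HGVSp_Short"),
                                     collapse = "\t"))
  expect_true(file.exists(file.path(dir, "meta_mutations_extended.txt")))
  cl <- readLines(file.path(dir, "case_lists", "cases_sequenced.txt"))
  expect_identical(cl[[length(cl)]], "case_list_ids: ")
})

test_that("the case list holds each barcode exactly once", {
  s <- study_with_samples()
  s <- import_maf(s, rbind(make_maf_df(3), make_maf_df(2, barcode = "P1-S2")))
  s <- save_study(s, components = "all")
  cl <- readLines(file.path(s$root, "maf_study", "case_lists",
                            "cases_sequenced.txt"))
  ids_line <- grep("^case_list_ids:", cl, value = TRUE)
  ids <- strsplit(sub("^case_list_ids: ", "", ids_line), "\t")[[1L]]
  expect_identical(sort(ids), c("P1-S1", "P1-S2"))
})

test_that("mutations_for_sample filters and partitions the table", {
  s <- study_with_samples()
  s <- import_maf(s, rbind(make_maf_df(3), make_maf_df(5, barcode = "P1-S2")))
  sub <- mutations_for_sample(s, "P1-S1")
  expect_identical(nrow(sub), 3L)
  expect_identical(names(sub), names(s$mutations))

  none <- mutations_for_sample(s, "S_NOPE")
  expect_identical(nrow(none), 0L)
  expect_identical(names(none), names(s$mutations))

  # union over all samples reassembles the whole table
  parts <- lapply(unique(s$mutations$Tumor_Sample_Barcode),
                  function(x) mutations_for_sample(s, x))
  reassembled <- do.call(rbind, parts)
  rownames(reassembled) <- NULL
  expect_identical(reassembled, s$mutations)
})
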