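# Deterministic example-study generation (the bundled test-study analog) and
# seeded-defect variants for validator tests. Studies are built exclusively
# through the package's own API and save paths, so a generated study always
# passes validation by construction.

GENERATOR_GENES <- c("TP53", "KRAS", "BRAF", "EGFR", "PIK3CA", "PTEN", "ALK",
                     "NRAS", "IDH1", "MYC")
GENERATOR_CLASSIFICATIONS <- c("Missense_Mutation", "Nonsense_Mutation",
                               "Frame_Shift_Del", "Silent")
GENERATOR_AGENTS <- c("Cisplatin", "Pembrolizumab", "Trametinib", "Olaparib")
AA_CODES <- c("A", "R", "N", "D", "C", "G", "H", "L", "K", "S", "T", "V")

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a complete example study
#'
#' Writes a synthetic but structurally complete study — the analog of a
#' bundled test study — under the given root: a patient table with
#' predefined AGE/SEX/OS_STATUS attributes plus a custom ECOG column,
#' samples per patient, MAF rows drawn from a fixed gene pool with
#' plausible variant classifications, first-diagnosis dates, treatment
#' (span) and status (point) timeline events, and a PATIENT resource. All
#' randomness derives from the seed; the same seed yields byte-identical
#' output.
#'
#' @param root Study root directory.
#' @param seed Integer seed driving all generated values.
#' @param n_patients Number of patients.
#' @param n_samples_per_patient Samples per patient.
#' @param n_mutations_per_sample MAF rows per sample.
#' @param n_timeline_events Timeline events per patient, alternating
#'   between the treatment and status tracks.
#' @param identifier Study identifier; defaults to \code{"example_study"}.
#' @return The study identifier, invisibly.
#' @export
#' @examples
#' root <- tempfile()
#' generate_example_study(root, seed = 42)
#' list_studies(root)
generate_example_study <- function(root, seed = 42L, n_patients = 2L,
                                   n_samples_per_patient = 2L,
                                   n_mutations_per_sample = 3L,
                                   n_timeline_events = 2L,
                                   identifier = "example_study") {
  counts <- c(n_patients, n_samples_per_patient, n_mutations_per_sample,
              n_timeline_events)
  if (any(is.na(counts)) || any(counts < 0)) {
    cbp_validation_error("all generator counts must be >= 0")
  }
  with_seed(seed, {
    meta <- study_meta(identifier, "mixed", "Example MTB study",
                       "Synthetic example study for testing and demonstration",
                       short_name = "Example")
    study <- create_study(root, meta)
    if (n_patients > 0L) {
      study$patients <- add_column(study$patients, "AGE")
      study$patients <- add_column(study$patients, "SEX")
      study$patients <- add_column(study$patients, "OS_STATUS")
      study$patients <- add_column(study$patients, attribute_def(
        "ECOG", "ECOG Status", "ECOG performance status at diagnosis", "NUMBER"))
      study <- mark_dirty(study, "patients")
      study$samples <- add_column(study$samples, "CANCER_TYPE")
      study$samples <- add_column(study$samples, "SAMPLE_CLASS")
      study <- mark_dirty(study, "samples")
      study <- define_resource(study, "REPORT", "MTB Report", "PATIENT",
                               description = "Molecular tumor board report")
    }
    cancer_types <- c("Breast Cancer", "Colorectal Cancer",
                      "Non-Small Cell Lung Cancer", "Melanoma")
    for (i in seq_len(n_patients)) {
      pid <- sprintf("P%d", i)
      study <- add_patient(study, list(
        PATIENT_ID = pid,
        AGE = as.character(sample(30:80, 1L)),
        SEX = sample(c("Male", "Female"), 1L),
        OS_STATUS = sample(c("0:LIVING", "1:DECEASED"), 1L),
        ECOG = as.character(sample(0:3, 1L))))
      diagnosis <- as.Date("2019-01-01") + sample(0:364, 1L)
      study <- set_first_diagnosis_date(study, pid, diagnosis)
      study <- add_resource_entry(
        study, "REPORT",
        sprintf("https://example.org/mtb/reports/%s.pdf", pid),
        patient_id = pid)
      for (j in seq_len(n_samples_per_patient)) {
        sid <- sprintf("%s-S%d", pid, j)
        study <- add_sample(study, list(
          PATIENT_ID = pid, SAMPLE_ID = sid,
          CANCER_TYPE = sample(cancer_types, 1L),
          SAMPLE_CLASS = "Tumor"))
        if (n_mutations_per_sample > 0L) {
          maf <- data.frame(
            Hugo_Symbol = sample(GENERATOR_GENES, n_mutations_per_sample,
                                 replace = TRUE),
            Tumor_Sample_Barcode = rep(sid, n_mutations_per_sample),
            Variant_Classification = sample(GENERATOR_CLASSIFICATIONS,
                                            n_mutations_per_sample,
                                            replace = TRUE),
            HGVSp_Short = sprintf("p.%s%d%s",
                                  sample(AA_CODES, n_mutations_per_sample,
                                         replace = TRUE),
                                  sample(10:900, n_mutations_per_sample,
                                         replace = TRUE),
                                  sample(AA_CODES, n_mutations_per_sample,
                                         replace = TRUE)),
            stringsAsFactors = FALSE)
          study <- suppressWarnings(import_maf(study, maf))
        }
      }
      for (k in seq_len(n_timeline_events)) {
        if (k %% 2L == 1L) {
          start <- diagnosis + sample(5:50, 1L)
          study <- add_event(study, "treatment", pid,
                            start = start, stop = start + sample(10:60, 1L),
                            event_type = "Medical Therapy",
                            extras = list(TREATMENT_TYPE = "Medical Therapy",
                                          AGENT = sample(GENERATOR_AGENTS, 1L)))
        } else {
          study <- add_event(study, "status", pid,
                            start = diagnosis + sample(60:200, 1L),
                            event_type = "STATUS",
                            extras = list(STATUS = sample(
                              c("Complete Response", "Partial Response",
                                "Stable Disease", "Progressive Disease"), 1L)))
        }
      }
    }
    save_study(study, components = "all")
  })
  invisible(identifier)
}

# minimal file edits, one per validator rule
DEFECT_EDITS <- list(
  `struct.meta_pairing` = function(dir) {
    unlink(file.path(dir, "meta_clinical_patient.txt"))
  },
  `struct.meta_study_fields` = function(dir) {
    p <- file.path(dir, STUDY_META_FILE)
    lines <- readLines(p, warn = FALSE)
    writeLines(lines[!startsWith(lines, "description:")], p)
  },
  `clin.header_shape` = function(dir) {
    p <- file.path(dir, "data_clinical_patient.txt")
    lines <- readLines(p, warn = FALSE)
    lines[[4L]] <- sub("\t[^\t]*$", "", lines[[4L]])  # drop one priority cell
    writeLines(lines, p)
  },
  `clin.datatype` = function(dir) {
    p <- file.path(dir, "data_clinical_patient.txt")
    lines <- readLines(p, warn = FALSE)
    ids <- strsplit(lines[[5L]], "\t", fixed = TRUE)[[1L]]
    j <- match("AGE", ids)
    row <- strsplit(lines[[6L]], "\t", fixed = TRUE)[[1L]]
    row[[j]] <- "not_a_number"
    lines[[6L]] <- paste(row, collapse = "\t")
    writeLines(lines, p)
  },
  `clin.unique_ids` = function(dir) {
    p <- file.path(dir, "data_clinical_patient.txt")
    lines <- readLines(p, warn = FALSE)
    writeLines(c(lines, lines[[6L]]), p)
  },
  `ref.sample_patient` = function(dir) {
    p <- file.path(dir, "data_clinical_sample.txt")
    lines <- readLines(p, warn = FALSE)
    row <- strsplit(lines[[6L]], "\t", fixed = TRUE)[[1L]]
    row[[1L]] <- "P_GHOST"
    lines[[6L]] <- paste(row, collapse = "\t")
    writeLines(lines, p)
  },
  `maf.required_cols` = function(dir) {
    p <- file.path(dir, MUTATION_FILE)
    lines <- readLines(p, warn = FALSE)
    cells <- tsv_cells(lines)
    j <- match("HGVSp_Short", cells[[1L]])
    writeLines(vapply(cells, function(r) paste(r[-j], collapse = "\t"), ""), p)
  },
  `ref.maf_sample` = function(dir) {
    p <- file.path(dir, MUTATION_FILE)
    lines <- readLines(p, warn = FALSE)
    hdr <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    j <- match("Tumor_Sample_Barcode", hdr)
    row <- strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]]
    row[[j]] <- "S_GHOST"
    lines[[2L]] <- paste(row, collapse = "\t")
    writeLines(lines, p)
  },
  `maf.duplicates` = function(dir) {
    p <- file.path(dir, MUTATION_FILE)
    lines <- readLines(p, warn = FALSE)
    writeLines(c(lines, lines[[2L]]), p)
  },
  `tl.patient_exists` = function(dir) {
    p <- file.path(dir, "data_timeline_treatment.txt")
    lines <- readLines(p, warn = FALSE)
    row <- strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]]
    row[[1L]] <- "P_GHOST"
    lines[[2L]] <- paste(row, collapse = "\t")
    writeLines(lines, p)
  },
  `tl.int_days` = function(dir) {
    p <- file.path(dir, "data_timeline_treatment.txt")
    lines <- readLines(p, warn = FALSE)
    row <- strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]]
    row[[2L]] <- "2020-01-01"
    lines[[2L]] <- paste(row, collapse = "\t")
    writeLines(lines, p)
  },
  `tl.stop_ge_start` = function(dir) {
    p <- file.path(dir, "data_timeline_treatment.txt")
    lines <- readLines(p, warn = FALSE)
    row <- strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]]
    row[[3L]] <- as.character(as.integer(row[[2L]]) - 10L)
    lines[[2L]] <- paste(row, collapse = "\t")
    writeLines(lines, p)
  },
  `tl.negative_start` = function(dir) {
    p <- file.path(dir, "data_timeline_status.txt")
    lines <- readLines(p, warn = FALSE)
    row <- strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]]
    row[[2L]] <- "-5"
    lines[[2L]] <- paste(row, collapse = "\t")
    writeLines(lines, p)
  },
  `res.definition_exists` = function(dir) {
    p <- file.path(dir, "data_resource_patient.txt")
    lines <- readLines(p, warn = FALSE)
    hdr <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    j <- match("RESOURCE_ID", hdr)
    row <- strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]]
    row[[j]] <- "UNDEFINED_RES"
    lines[[2L]] <- paste(row, collapse = "\t")
    writeLines(lines, p)
  },
  `res.target_exists` = function(dir) {
    p <- file.path(dir, "data_resource_patient.txt")
    lines <- readLines(p, warn = FALSE)
    row <- strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]]
    row[[1L]] <- "P_GHOST"
    lines[[2L]] <- paste(row, collapse = "\t")
    writeLines(lines, p)
  },
  `onco.known_code` = function(dir) {
    p <- file.path(dir, STUDY_META_FILE)
    lines <- readLines(p, warn = FALSE)
    lines <- sub("^type_of_cancer:.*$", "type_of_cancer: zzz_not_a_code", lines)
    writeLines(lines, p)
  }
)

#' Seed a single validation defect into a copy of a study
#'
#' Copies the study directory and applies the minimal file edit that
#' triggers exactly the given validator rule — e.g. for
#' \code{ref.sample_patient} one sample row's PATIENT_ID is replaced by a
#' ghost ID. Used to test validator completeness rule by rule.
#'
#' @param study_path Path to a clean study directory (typically output of
#'   [generate_example_study()]).
#' @param rule_id One of the validator rule IDs (see [validate_study()]).
#' @return The path of the mutated copy.
#' @export
seed_defect <- function(study_path, rule_id) {
  if (!rule_id %in% VALIDATOR_RULES) {
    cbp_not_found_error(sprintf("unknown rule_id '%s'; known rules: %s",
                                rule_id, paste(VALIDATOR_RULES, collapse = ", ")))
  }
  if (!dir.exists(study_path)) {
    cbp_io_error(sprintf("study directory '%s' does not exist", study_path))
  }
  dest <- file.path(dirname(study_path),
                    paste0(basename(study_path), ".defect.",
                           gsub("[^A-Za-z0-9_]", "_", rule_id)))
  unlink(dest, recursive = TRUE)
  dir.create(dest, recursive = TRUE)
  for (f in list.files(study_path, recursive = TRUE)) {
    target_dir <- dirname(file.path(dest, f))
    if (!dir.exists(target_dir)) dir.create(target_dir, recursive = TRUE)
    file.copy(file.path(study_path, f), file.path(dest, f))
  }
  DEFECT_EDITS[[rule_id]](dest)
  dest
}
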