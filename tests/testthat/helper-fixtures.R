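# Shared fixtures, built in code at test time.

new_root <- function() {
  root <- tempfile("studies_")
  dir.create(root)
  root
}

# A small study with fully linked components for one patient:
# P1 with 2 samples, 5 MAF rows, 3 timeline events (2 treatment + 1 status),
# 1 diagnosis date and 1 patient resource entry; P2 is minimal.
make_linked_study <- function(root, id = "linked_study") {
  s <- create_study(root, study_meta(id, "mixed", "Linked", "Linked fixture"))
  s$patients <- add_column(s$patients, "AGE")
  s$patients <- add_column(s$patients, attribute_def(
    "ECOG", "ECOG Status", "ECOG performance status", "NUMBER"))
  s <- mark_dirty(s, "patients")
  s <- add_patient(s, list(PATIENT_ID = "P1", AGE = "61", ECOG = "1"))
  s <- add_patient(s, list(PATIENT_ID = "P2", AGE = "48"))
  s <- add_sample(s, list(PATIENT_ID = "P1", SAMPLE_ID = "P1-S1"))
  s <- add_sample(s, list(PATIENT_ID = "P1", SAMPLE_ID = "P1-S2"))
  maf <- data.frame(
    Hugo_Symbol = c("TP53", "KRAS", "BRAF", "EGFR", "PTEN"),
    Tumor_Sample_Barcode = c("P1-S1", "P1-S1", "P1-S1", "P1-S2", "P1-S2"),
    Variant_Classification = c("Missense_Mutation", "Nonsense_Mutation",
                               "Missense_Mutation", "Silent", "Frame_Shift_Del"),
    HGVSp_Short = c("p.R175H", "p.G12D", "p.V600E", "p.L858R", "p.T321fs"),
    stringsAsFactors = FALSE)
  s <- import_maf(s, maf)
  s <- set_first_diagnosis_date(s, "P1", "2020-01-01")
  s <- add_event(s, "treatment", "P1", start = "2020-02-01", stop = "2020-03-01",
                 event_type = "Medical Therapy", extras = list(AGENT = "Cisplatin"))
  s <- add_event(s, "treatment", "P1", start = "2020-04-01", stop = "2020-05-01",
                 event_type = "Medical Therapy", extras = list(AGENT = "Olaparib"))
  s <- add_event(s, "status", "P1", start = "2020-06-01", event_type = "STATUS",
                 extras = list(STATUS = "Partial Response"))
  s <- define_resource(s, "REPORT", "MTB Report", "PATIENT",
                       description = "Report of the MTB session")
  s <- add_resource_entry(s, "REPORT", "https://example.org/reports/P1.pdf",
                          patient_id = "P1")
  s
}

# Hinnant's days-from-civil algorithm: an independent proleptic-Gregorian
# day count used as the oracle for calendar-day arithmetic.
days_from_civil <- function(y, m, d) {
  y <- ifelse(m <= 2, y - 1, y)
  era <- floor(y / 400)
  yoe <- y - era * 400
  mp <- ifelse(m > 2, m - 3, m + 9)
  doy <- floor((153 * mp + 2) / 5) + d - 1
  doe <- yoe * 365 + floor(yoe / 4) - floor(yoe / 100) + doy
  era * 146097 + doe - 719468
}

iso_split <- function(dates) {
  parts <- do.call(rbind, strsplit(dates, "-", fixed = TRUE))
  list(y = as.numeric(parts[, 1]), m = as.numeric(parts[, 2]),
       d = as.numeric(parts[, 3]))
}

oracle_day_diff <- function(from, to) {
  a <- iso_split(from)
  b <- iso_split(to)
  days_from_civil(b$y, b$m, b$d) - days_from_civil(a$y, a$m, a$d)
}

# random valid ISO dates in [1900, 2100], drawn uniformly over days
random_iso_dates <- function(n) {
  format(as.Date("1900-01-01") + sample.int(73108, n, replace = TRUE) - 1L,
         "%Y-%m-%d")
}

# study equality ignoring bookkeeping fields
study_state <- function(s) {
  s$dirty <- NULL
  s$root <- NULL
  attr(s, "written") <- NULL
  unclass(s)
}

read_study_bytes <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE))
  stats::setNames(lapply(files, function(f) {
    readBin(file.path(dir, f), "raw", file.size(file.path(dir, f)))
  }), files)
}
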