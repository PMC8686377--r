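# Native upload-readiness validation.
#
# Validates the on-disk files of one study directory (not the in-memory
# object) against the rule set covering every data type this package
# writes. Each rule has a stable rule_id so findings are testable units.
# The report decides upload readiness: any ERROR means FAIL.

VALIDATOR_RULES <- c(
  "struct.meta_pairing", "struct.meta_study_fields", "clin.header_shape",
  "clin.datatype", "clin.unique_ids", "ref.sample_patient",
  "maf.required_cols", "ref.maf_sample", "maf.duplicates",
  "tl.patient_exists", "tl.int_days", "tl.stop_ge_start", "tl.negative_start",
  "res.definition_exists", "res.target_exists", "onco.known_code"
)

finding <- function(severity, file, line, message, rule_id) {
  data.frame(severity = severity, file = file,
             line = if (is.null(line)) NA_integer_ else as.integer(line),
             message = message, rule_id = rule_id, stringsAsFactors = FALSE)
}

no_findings <- function() {
  empty_character_df(c("severity", "file", "line", "message", "rule_id"))
}

# lenient table reader for validation: never errors, returns NULL on failure
read_table_or_null <- function(path, comment = TRUE) {
  tryCatch(read_tsv_table(path, comment = comment), error = function(e) NULL)
}

#' Validate a study directory
#'
#' Runs the full rule set against the files of one study directory and
#' returns an ordered report of errors and warnings. The checks mirror what
#' cBioPortal's importer enforces for the data types this package writes:
#' data/meta file pairing, required meta-study keys, clinical header shape
#' and datatypes, ID uniqueness, sample-to-patient and
#' mutation-barcode-to-sample references, MAF required columns and duplicate
#' rows, timeline integer day offsets and span ordering, resource
#' referential integrity, and cancer-type code resolution.
#'
#' @param study_path Path to one study folder (containing
#'   \code{meta_study.txt}).
#' @param vocabulary OncoTree vocabulary for the cancer-type check;
#'   defaults to the bundled snapshot.
#' @return An object of class \code{cbp_validation_report}: study_id,
#'   findings (severity, file, line, message, rule_id, ordered by file then
#'   line), and status \code{PASS}, \code{PASS_WITH_WARNINGS} or
#'   \code{FAIL}.
#' @export
validate_study <- function(study_path, vocabulary = NULL) {
  if (!dir.exists(study_path)) {
    cbp_io_error(sprintf("study directory '%s' does not exist or is unreadable",
                         study_path))
  }
  f <- list()
  add <- function(...) f[[length(f) + 1L]] <<- finding(...)

  files <- list.files(study_path)
  meta_study_path <- file.path(study_path, STUDY_META_FILE)
  study_id <- basename(study_path)

  # --- structural rules ------------------------------------------------------
  meta_keys <- NULL
  if (!file.exists(meta_study_path)) {
    add("ERROR", STUDY_META_FILE, NULL, "meta_study.txt is missing",
        "struct.meta_study_fields")
  } else {
    meta_keys <- tryCatch(read_meta_file(meta_study_path), error = function(e) NULL)
    if (is.null(meta_keys)) {
      add("ERROR", STUDY_META_FILE, NULL, "meta_study.txt cannot be parsed",
          "struct.meta_study_fields")
    } else {
      required <- c("type_of_cancer", "cancer_study_identifier", "name",
                    "description")
      missing <- setdiff(required, names(meta_keys))
      if (length(missing)) {
        add("ERROR", STUDY_META_FILE, NULL,
            sprintf("meta_study.txt lacks required key(s): %s",
                    paste(missing, collapse = ", ")),
            "struct.meta_study_fields")
      }
      if ("cancer_study_identifier" %in% names(meta_keys)) {
        study_id <- meta_keys[["cancer_study_identifier"]]
      }
      toc <- unname(meta_keys["type_of_cancer"])
      if (!is.na(toc) && !is_known_cancer_type(toc, vocabulary)) {
        add("WARNING", STUDY_META_FILE, NULL,
            sprintf("type_of_cancer '%s' is neither 'mixed' nor a known OncoTree code",
                    toc), "onco.known_code")
      }
    }
  }

  data_files <- grep("^data_.*\\.txt$", files, value = TRUE)
  meta_files <- setdiff(grep("^meta_.*\\.txt$", files, value = TRUE),
                        STUDY_META_FILE)
  for (df in data_files) {
    if (!meta_name_for(df) %in% meta_files) {
      add("ERROR", df, NULL,
          sprintf("data file '%s' has no paired meta file '%s'",
                  df, meta_name_for(df)), "struct.meta_pairing")
    }
  }
  for (mf in meta_files) {
    paired <- sub("^meta_", "data_", mf)
    if (!paired %in% data_files) {
      add("ERROR", mf, NULL,
          sprintf("meta file '%s' has no paired data file '%s'", mf, paired),
          "struct.meta_pairing")
    }
  }

  # --- clinical tables -------------------------------------------------------
  # referential rules are suppressed against a table that itself failed to
  # parse, so one header defect does not cascade into spurious findings
  patient_ids <- character(0)
  sample_ids <- character(0)
  patients_ok <- TRUE
  samples_ok <- TRUE
  for (comp in names(CLINICAL_FILES)) {
    fname <- CLINICAL_FILES[[comp]]
    path <- file.path(study_path, fname)
    if (!file.exists(path)) next
    kind <- if (comp == "patients") "patient" else "sample"
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) < 5L || !all(startsWith(lines[1:4], "#"))) {
      add("ERROR", fname, NULL,
          "clinical file must start with four '#' metadata rows and a column-ID row",
          "clin.header_shape")
      if (kind == "patient") patients_ok <- FALSE else samples_ok <- FALSE
      next
    }
    hdr <- tsv_cells(sub("^#", "", lines[1:4]))
    ids <- tsv_cells(lines[[5L]])[[1L]]
    ncol <- length(ids)
    shape_ok <- TRUE
    if (any(lengths(hdr) != ncol)) {
      add("ERROR", fname, NULL,
          sprintf("metadata rows have %s cells but the column-ID row has %d",
                  paste(unique(lengths(hdr)), collapse = "/"), ncol),
          "clin.header_shape")
      shape_ok <- FALSE
    }
    rows <- tsv_cells(lines[-(1:5)])
    long <- which(lengths(rows) > ncol)
    for (r in long) {
      add("ERROR", fname, r + 5L,
          sprintf("record row has %d cells but the header has %d columns",
                  lengths(rows)[[r]], ncol), "clin.header_shape")
    }
    if (!shape_ok || length(long)) {
      if (kind == "patient") patients_ok <- FALSE else samples_ok <- FALSE
      next
    }
    datatypes <- hdr[[3L]]
    get_col <- function(col) {
      j <- match(col, ids)
      if (is.na(j)) return(NULL)
      vapply(rows, function(r) if (length(r) >= j) r[[j]] else "", "")
    }
    for (j in seq_len(ncol)) {
      vals <- vapply(rows, function(r) if (length(r) >= j) r[[j]] else "", "")
      vals[vals == "NA"] <- ""
      bad <- which(!vapply(vals, value_conforms, logical(1),
                           datatype = datatypes[[j]]))
      for (b in bad) {
        add("ERROR", fname, b + 5L,
            sprintf("value '%s' in column %s does not conform to datatype %s",
                    vals[[b]], ids[[j]], datatypes[[j]]), "clin.datatype")
      }
    }
    id_col <- if (kind == "patient") "PATIENT_ID" else "SAMPLE_ID"
    idv <- get_col(id_col)
    if (!is.null(idv)) {
      dup <- unique(idv[duplicated(idv)])
      for (d in dup) {
        add("ERROR", fname, NULL,
            sprintf("%s '%s' occurs more than once", id_col, d),
            "clin.unique_ids")
      }
      if (kind == "patient") patient_ids <- idv else sample_ids <- idv
    }
    if (kind == "sample") {
      pv <- get_col("PATIENT_ID")
      if (!is.null(pv) && patients_ok) {
        unknown <- which(!pv %in% patient_ids)
        for (u in unknown) {
          add("ERROR", fname, u + 5L,
              sprintf("sample row references unknown PATIENT_ID '%s'", pv[[u]]),
              "ref.sample_patient")
        }
      }
    }
  }

  # --- mutations -------------------------------------------------------------
  maf_path <- file.path(study_path, MUTATION_FILE)
  if (file.exists(maf_path)) {
    maf <- read_table_or_null(maf_path)
    if (!is.null(maf)) {
      missing <- setdiff(MAF_REQUIRED_COLUMNS, names(maf))
      if (length(missing)) {
        add("ERROR", MUTATION_FILE, NULL,
            sprintf("MAF is missing required column(s): %s",
                    paste(missing, collapse = ", ")), "maf.required_cols")
      }
      if ("Tumor_Sample_Barcode" %in% names(maf) && nrow(maf) && samples_ok) {
        row_lines <- attr(maf, "row_lines")
        unknown <- which(!maf$Tumor_Sample_Barcode %in% sample_ids)
        for (u in unknown) {
          add("ERROR", MUTATION_FILE, row_lines[[u]],
              sprintf("Tumor_Sample_Barcode '%s' is not among the study's samples",
                      maf$Tumor_Sample_Barcode[[u]]), "ref.maf_sample")
        }
      }
      if (nrow(maf)) {
        key <- do.call(paste, c(unname(as.list(maf)), sep = "\t"))
        dup <- which(duplicated(key))
        row_lines <- attr(maf, "row_lines")
        for (d in dup) {
          add("WARNING", MUTATION_FILE, row_lines[[d]],
              "exact duplicate mutation row", "maf.duplicates")
        }
      }
    }
  }

  # --- timelines -------------------------------------------------------------
  tl_files <- sort(grep("^data_timeline_.+\\.txt$", files, value = TRUE),
                   method = "radix")
  for (fname in tl_files) {
    tab <- read_table_or_null(file.path(study_path, fname), comment = FALSE)
    if (is.null(tab) || !all(c("PATIENT_ID", "START_DATE") %in% names(tab))) next
    row_lines <- attr(tab, "row_lines")
    for (i in seq_len(nrow(tab))) {
      pid <- tab$PATIENT_ID[[i]]
      if (patients_ok && !pid %in% patient_ids) {
        add("ERROR", fname, row_lines[[i]],
            sprintf("timeline event references unknown PATIENT_ID '%s'", pid),
            "tl.patient_exists")
      }
      start <- suppressWarnings(as.integer(tab$START_DATE[[i]]))
      stop_raw <- if ("STOP_DATE" %in% names(tab)) tab$STOP_DATE[[i]] else ""
      stop <- suppressWarnings(as.integer(stop_raw))
      if (is.na(start) ||
          as.character(start) != sub("^\\+", "", tab$START_DATE[[i]])) {
        add("ERROR", fname, row_lines[[i]],
            sprintf("START_DATE '%s' is not an integer day offset",
                    tab$START_DATE[[i]]), "tl.int_days")
        next
      }
      if (nzchar(stop_raw) && is.na(stop)) {
        add("ERROR", fname, row_lines[[i]],
            sprintf("STOP_DATE '%s' is not an integer day offset", stop_raw),
            "tl.int_days")
        next
      }
      if (!is.na(stop) && nzchar(stop_raw) && stop < start) {
        add("ERROR", fname, row_lines[[i]],
            sprintf("STOP_DATE (%d) precedes START_DATE (%d)", stop, start),
            "tl.stop_ge_start")
      }
      if (start < 0L) {
        add("WARNING", fname, row_lines[[i]],
            sprintf("event starts %d day(s) before the first diagnosis", -start),
            "tl.negative_start")
      }
    }
  }

  # --- resources -------------------------------------------------------------
  def_path <- file.path(study_path, RESOURCE_FILES[["definitions"]])
  defs <- if (file.exists(def_path)) read_table_or_null(def_path, comment = FALSE)
  for (part in c("study", "patient", "sample")) {
    fname <- RESOURCE_FILES[[part]]
    path <- file.path(study_path, fname)
    if (!file.exists(path)) next
    tab <- read_table_or_null(path, comment = FALSE)
    if (is.null(tab) || !"RESOURCE_ID" %in% names(tab)) next
    row_lines <- attr(tab, "row_lines")
    for (i in seq_len(nrow(tab))) {
      rid <- tab$RESOURCE_ID[[i]]
      dhit <- if (!is.null(defs)) which(defs$RESOURCE_ID == rid) else integer(0)
      if (!length(dhit)) {
        add("ERROR", fname, row_lines[[i]],
            sprintf("resource entry references undefined RESOURCE_ID '%s'", rid),
            "res.definition_exists")
      } else if (!identical(defs$RESOURCE_TYPE[[dhit[[1L]]]], toupper(part))) {
        add("ERROR", fname, row_lines[[i]],
            sprintf("resource '%s' is of type %s but appears in the %s resource file",
                    rid, defs$RESOURCE_TYPE[[dhit[[1L]]]], part),
            "res.definition_exists")
      }
      if (part %in% c("patient", "sample") && "PATIENT_ID" %in% names(tab) &&
          patients_ok && !tab$PATIENT_ID[[i]] %in% patient_ids) {
        add("ERROR", fname, row_lines[[i]],
            sprintf("resource entry references unknown PATIENT_ID '%s'",
                    tab$PATIENT_ID[[i]]), "res.target_exists")
      }
      if (part == "sample" && "SAMPLE_ID" %in% names(tab) &&
          samples_ok && !tab$SAMPLE_ID[[i]] %in% sample_ids) {
        add("ERROR", fname, row_lines[[i]],
            sprintf("resource entry references unknown SAMPLE_ID '%s'",
                    tab$SAMPLE_ID[[i]]), "res.target_exists")
      }
    }
  }

  findings <- if (length(f)) do.call(rbind, f) else {
    data.frame(severity = character(0), file = character(0),
               line = integer(0), message = character(0),
               rule_id = character(0), stringsAsFactors = FALSE)
  }
  ord <- order(findings$file, ifelse(is.na(findings$line), 0L, findings$line),
               findings$rule_id, method = "radix")
  findings <- findings[ord, , drop = FALSE]
  rownames(findings) <- NULL
  status <- if (any(findings$severity == "ERROR")) "FAIL"
            else if (any(findings$severity == "WARNING")) "PASS_WITH_WARNINGS"
            else "PASS"
  structure(list(study_id = study_id, findings = findings, status = status),
            class = "cbp_validation_report")
}

#' Render a validation report
#'
#' The text format is stable and line-oriented — one finding per line as
#' \code{SEVERITY<TAB>file:line<TAB>rule_id<TAB>message} with the status
#' summary last — suitable for logs and diffing. The HTML format wraps the
#' same content for download/viewing.
#'
#' @param report A \code{cbp_validation_report} from [validate_study()].
#' @param format \code{"text"} or \code{"html"}.
#' @return A character vector of lines.
#' @export
render_report <- function(report, format = c("text", "html")) {
  stopifnot(inherits(report, "cbp_validation_report"))
  if (!is.character(format) || !all(format %in% c("text", "html"))) {
    cbp_validation_error("format must be 'text' or 'html'")
  }
  format <- match.arg(format)
  fd <- report$findings
  loc <- ifelse(is.na(fd$line), fd$file, paste0(fd$file, ":", fd$line))
  body <- if (nrow(fd)) {
    paste(fd$severity, loc, fd$rule_id, fd$message, sep = "\t")
  } else character(0)
  if (format == "text") {
    return(c(sprintf("Validation report for study '%s'", report$study_id),
             body,
             sprintf("%d error(s), %d warning(s)",
                     sum(fd$severity == "ERROR"), sum(fd$severity == "WARNING")),
             report$status))
  }
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  rows <- if (nrow(fd)) {
    sprintf("<tr class=\"%s\"><td>%s</td><td>%s</td><td>%s</td><td>%s</td></tr>",
            tolower(fd$severity), esc(fd$severity), esc(loc), esc(fd$rule_id),
            esc(fd$message))
  } else character(0)
  c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\">",
    sprintf("<title>Validation report: %s</title></head><body>",
            esc(report$study_id)),
    sprintf("<h1>Validation report for study '%s'</h1>", esc(report$study_id)),
    "<table border=\"1\"><tr><th>Severity</th><th>Location</th><th>Rule</th><th>Message</th></tr>",
    rows, "</table>",
    sprintf("<p>%d error(s), %d warning(s)</p>",
            sum(fd$severity == "ERROR"), sum(fd$severity == "WARNING")),
    sprintf("<p><strong>%s</strong></p>", esc(report$status)),
    "</body></html>")
}

#' @export
print.cbp_validation_report <- function(x, ...) {
  cat(render_report(x, "text"), sep = "\n")
  invisible(x)
}
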