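# Clinical patient/sample attribute tables.
#
# The editable model carries three metadata rows per attribute — short name,
# long name, datatype — ahead of the record rows; that is the representation
# a documentalist edits. The written file uses the cBioPortal clinical
# dialect: four `#`-prefixed header lines (display names, descriptions,
# datatypes, priorities) followed by the column-ID line, with priority
# defaulted to 1 for every attribute.

CLINICAL_DATATYPES <- c("STRING", "NUMBER", "BOOLEAN")

#' Define a clinical attribute
#'
#' A clinical attribute is one column of a patient or sample table, carrying
#' display metadata used by cBioPortal: a short (display) name, a long name
#' (description), and a datatype.
#'
#' @param column_id Uppercase column identifier matching
#'   \code{[A-Z][A-Z0-9_]*}, e.g. \code{"SMOKER"}.
#' @param short_name Display name shown in cBioPortal.
#' @param long_name Longer description of the attribute.
#' @param datatype One of \code{"STRING"}, \code{"NUMBER"}, \code{"BOOLEAN"}.
#' @param priority Display priority written to file; defaults to 1.
#' @return An object of class \code{cbp_attribute_def}.
#' @export
#' @examples
#' attribute_def("SMOKER", "Smoker", "Smoking status", "BOOLEAN")
attribute_def <- function(column_id, short_name, long_name,
                          datatype = c("STRING", "NUMBER", "BOOLEAN"),
                          priority = 1L) {
  datatype <- match.arg(datatype)
  if (!is.character(column_id) || length(column_id) != 1L ||
      !grepl("^[A-Z][A-Z0-9_]*$", column_id)) {
    cbp_validation_error(sprintf(
      "column_id must be an uppercase token matching [A-Z][A-Z0-9_]*, got '%s'",
      paste(column_id, collapse = ",")))
  }
  assert_cells(c(short_name, long_name), "attribute metadata")
  if (!nzchar(short_name) || !nzchar(long_name)) {
    cbp_validation_error("short_name and long_name must be non-empty")
  }
  priority <- as.integer(priority)
  if (is.na(priority) || priority < 1L) {
    cbp_validation_error("priority must be a positive integer")
  }
  structure(
    list(column_id = column_id, short_name = short_name,
         long_name = long_name, datatype = datatype, priority = priority),
    class = "cbp_attribute_def"
  )
}

#' Predefined clinical attribute catalog
#'
#' cBioPortal reserves a set of attribute IDs (survival status, age, sex,
#' cancer type, ...) whose display metadata is fixed by convention; adding
#' one of these needs only its column ID. The catalog is a plain
#' tab-separated file so sites can extend it.
#'
#' @param kind \code{"patient"} or \code{"sample"}.
#' @param path Optional path to a site-specific catalog file with columns
#'   KIND, COLUMN_ID, SHORT_NAME, LONG_NAME, DATATYPE.
#' @return A data frame of the predefined attributes for that table kind.
#' @export
predefined_attributes <- function(kind = c("patient", "sample"), path = NULL) {
  kind <- match.arg(kind)
  if (is.null(path)) {
    path <- system.file("extdata", "predefined_attributes.tsv",
                        package = "cbpstudio", mustWork = TRUE)
  }
  cat <- read_tsv_table(path, comment = FALSE)
  out <- cat[cat$KIND == kind, c("COLUMN_ID", "SHORT_NAME", "LONG_NAME", "DATATYPE")]
  rownames(out) <- NULL
  out
}

id_columns <- function(kind) {
  if (kind == "patient") "PATIENT_ID" else c("PATIENT_ID", "SAMPLE_ID")
}

mandatory_attribute <- function(column_id) {
  meta <- switch(
    column_id,
    PATIENT_ID = list("Patient Identifier", "Unique identifier of the patient"),
    SAMPLE_ID = list("Sample Identifier", "Unique identifier of the sample")
  )
  new_attribute_row(column_id, meta[[1L]], meta[[2L]], "STRING", 1L, TRUE)
}

new_attribute_row <- function(column_id, short_name, long_name, datatype,
                              priority, predefined) {
  data.frame(column_id = column_id, short_name = short_name,
             long_name = long_name, datatype = datatype,
             priority = as.integer(priority), predefined = predefined,
             stringsAsFactors = FALSE)
}

#' Create an empty clinical table
#'
#' Patient tables start with the mandatory \code{PATIENT_ID} attribute;
#' sample tables with \code{PATIENT_ID} and \code{SAMPLE_ID}. Every record
#' value is stored as a string; \code{NUMBER} and \code{BOOLEAN} attributes
#' are type-checked on entry.
#'
#' @param kind \code{"patient"} or \code{"sample"}.
#' @return An object of class \code{cbp_clinical_table}.
#' @export
clinical_table <- function(kind = c("patient", "sample")) {
  kind <- match.arg(kind)
  attrs <- do.call(rbind, lapply(id_columns(kind), mandatory_attribute))
  structure(
    list(kind = kind, attributes = attrs,
         records = empty_character_df(attrs$column_id)),
    class = "cbp_clinical_table"
  )
}

table_id_column <- function(table) {
  if (table$kind == "patient") "PATIENT_ID" else "SAMPLE_ID"
}

value_conforms <- function(value, datatype) {
  if (is.na(value) || !nzchar(value)) return(TRUE)
  switch(datatype,
    STRING = TRUE,
    NUMBER = !is.na(suppressWarnings(as.numeric(value))),
    BOOLEAN = tolower(value) %in% c("true", "false")
  )
}

check_datatypes <- function(table, values) {
  for (col in names(values)) {
    dt <- table$attributes$datatype[table$attributes$column_id == col]
    if (!value_conforms(values[[col]], dt)) {
      cbp_datatype_error(sprintf(
        "value '%s' for attribute %s does not conform to datatype %s",
        values[[col]], col, dt))
    }
  }
}

#' Add a record to a clinical table
#'
#' Appends one patient or sample row. \code{PATIENT_ID} is the only
#' mandatory field for patients; samples additionally require
#' \code{SAMPLE_ID}. Unspecified attributes are stored empty. Values are
#' checked against each attribute's datatype. Whether a sample's
#' \code{PATIENT_ID} refers to an existing patient is checked by the owning
#' study (see [add_sample()]).
#'
#' @param table A \code{cbp_clinical_table}.
#' @param values Named character list/vector of attribute values.
#' @return The updated table.
#' @export
#' @examples
#' tbl <- clinical_table("patient")
#' tbl <- add_record(tbl, c(PATIENT_ID = "P1"))
add_record <- function(table, values) {
  stopifnot(inherits(table, "cbp_clinical_table"))
  values <- as.list(values)
  unknown <- setdiff(names(values), table$attributes$column_id)
  if (length(unknown)) {
    cbp_validation_error(sprintf("unknown attribute(s): %s",
                                 paste(unknown, collapse = ", ")))
  }
  for (id_col in id_columns(table$kind)) {
    v <- values[[id_col]]
    if (is.null(v) || !nzchar(trimws(as.character(v)))) {
      cbp_validation_error(sprintf(
        "%s is mandatory when adding a %s record", id_col, table$kind))
    }
  }
  assert_cells(values, "record value")
  id_col <- table_id_column(table)
  id <- as.character(values[[id_col]])
  if (id %in% table$records[[id_col]]) {
    cbp_conflict_error(sprintf("%s '%s' already exists", id_col, id))
  }
  check_datatypes(table, values)
  row <- stats::setNames(as.list(rep("", nrow(table$attributes))),
                         table$attributes$column_id)
  row[names(values)] <- lapply(values, as.character)
  table$records <- rbind(table$records,
                         as.data.frame(row, check.names = FALSE,
                                       stringsAsFactors = FALSE))
  rownames(table$records) <- NULL
  table
}

find_record <- function(table, id) {
  idx <- which(table$records[[table_id_column(table)]] == id)
  if (!length(idx)) {
    cbp_not_found_error(sprintf("no %s record with %s '%s'",
                                table$kind, table_id_column(table), id))
  }
  idx[[1L]]
}

#' Edit a record in place
#'
#' Merges the supplied values into the record with the given ID; all other
#' fields are untouched. The identifying columns are immutable.
#'
#' @inheritParams add_record
#' @param id The record's \code{PATIENT_ID} (patient table) or
#'   \code{SAMPLE_ID} (sample table).
#' @return The updated table.
#' @export
edit_record <- function(table, id, values) {
  stopifnot(inherits(table, "cbp_clinical_table"))
  idx <- find_record(table, id)
  values <- as.list(values)
  unknown <- setdiff(names(values), table$attributes$column_id)
  if (length(unknown)) {
    cbp_validation_error(sprintf("unknown attribute(s): %s",
                                 paste(unknown, collapse = ", ")))
  }
  for (id_col in id_columns(table$kind)) {
    if (id_col %in% names(values) &&
        !identical(as.character(values[[id_col]]),
                   table$records[[id_col]][[idx]])) {
      cbp_validation_error(sprintf("%s cannot be changed", id_col))
    }
  }
  assert_cells(values, "record value")
  check_datatypes(table, values)
  for (col in names(values)) {
    table$records[[col]][[idx]] <- as.character(values[[col]])
  }
  table
}

#' Delete a record
#'
#' Removes the record with the given ID from the table. Deleting a patient
#' from a study should go through [delete_patient()], which also removes the
#' patient's samples, mutations, timeline events and resources.
#'
#' @inheritParams edit_record
#' @return The updated table.
#' @export
delete_record <- function(table, id) {
  stopifnot(inherits(table, "cbp_clinical_table"))
  idx <- find_record(table, id)
  table$records <- table$records[-idx, , drop = FALSE]
  rownames(table$records) <- NULL
  table
}

#' Add a column (attribute) to a clinical table
#'
#' Either a user-defined attribute built with [attribute_def()], or a
#' predefined one named by its column ID, whose short/long name and datatype
#' come from the built-in catalog (see [predefined_attributes()]).
#' All existing records gain an empty value for the new column.
#'
#' @inheritParams add_record
#' @param def A \code{cbp_attribute_def}, or a single string naming a
#'   predefined attribute (e.g. \code{"OS_STATUS"}).
#' @return The updated table.
#' @export
#' @examples
#' tbl <- clinical_table("patient")
#' tbl <- add_column(tbl, "OS_STATUS")
#' tbl <- add_column(tbl, attribute_def("SMOKER", "Smoker", "Smoking status", "BOOLEAN"))
add_column <- function(table, def) {
  stopifnot(inherits(table, "cbp_clinical_table"))
  predefined <- FALSE
  if (is.character(def) && length(def) == 1L) {
    if (def %in% table$attributes$column_id) {
      cbp_conflict_error(sprintf("column %s already exists", def))
    }
    catalog <- predefined_attributes(table$kind)
    hit <- catalog$COLUMN_ID == def
    if (!any(hit)) {
      cbp_not_found_error(sprintf(
        "'%s' is not a predefined %s attribute; available: %s",
        def, table$kind, paste(catalog$COLUMN_ID, collapse = ", ")))
    }
    row <- catalog[hit, ][1L, ]
    def <- attribute_def(row$COLUMN_ID, row$SHORT_NAME, row$LONG_NAME, row$DATATYPE)
    predefined <- TRUE
  }
  if (!inherits(def, "cbp_attribute_def")) {
    cbp_validation_error("def must be an attribute_def or a predefined column name")
  }
  if (def$column_id %in% table$attributes$column_id) {
    cbp_conflict_error(sprintf("column %s already exists", def$column_id))
  }
  table$attributes <- rbind(
    table$attributes,
    new_attribute_row(def$column_id, def$short_name, def$long_name,
                      def$datatype, def$priority, predefined)
  )
  table$records[[def$column_id]] <- rep("", nrow(table$records))
  table
}

#' Delete a column from a clinical table
#'
#' The mandatory identifier columns (\code{PATIENT_ID}, \code{SAMPLE_ID})
#' cannot be deleted.
#'
#' @inheritParams add_record
#' @param column_id The attribute to remove.
#' @return The updated table.
#' @export
delete_column <- function(table, column_id) {
  stopifnot(inherits(table, "cbp_clinical_table"))
  if (column_id %in% id_columns(table$kind)) {
    cbp_validation_error(sprintf("%s is mandatory and cannot be deleted", column_id))
  }
  if (!column_id %in% table$attributes$column_id) {
    cbp_not_found_error(sprintf("no column %s in the %s table", column_id, table$kind))
  }
  table$attributes <- table$attributes[table$attributes$column_id != column_id, ,
                                       drop = FALSE]
  rownames(table$attributes) <- NULL
  table$records[[column_id]] <- NULL
  table
}

#' Editable view of a clinical table
#'
#' Returns the table as a documentalist edits it: three metadata rows
#' (short name, long name, datatype) ahead of one row per record, one
#' column per attribute. This mirrors the on-screen model; the on-disk file
#' adds a fourth (priority) header row.
#'
#' @inheritParams add_record
#' @return A character data frame; rows 1–3 are metadata, the rest records.
#'   The number of metadata rows is also available as
#'   \code{attr(, "n_metadata_rows")}.
#' @export
clinical_editable_view <- function(table) {
  stopifnot(inherits(table, "cbp_clinical_table"))
  at <- table$attributes
  meta <- rbind(at$short_name, at$long_name, at$datatype)
  out <- as.data.frame(meta, check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- at$column_id
  out <- rbind(out, table$records)
  rownames(out) <- c("short_name", "long_name", "datatype",
                     if (nrow(table$records)) as.character(seq_len(nrow(table$records))))
  attr(out, "n_metadata_rows") <- 3L
  out
}

# ---- file dialect -----------------------------------------------------------

format_clinical_lines <- function(table) {
  at <- table$attributes
  assert_cells(unlist(at[c("short_name", "long_name")]), "attribute metadata")
  c(paste0("#", tsv_line(at$short_name)),
    paste0("#", tsv_line(at$long_name)),
    paste0("#", tsv_line(at$datatype)),
    paste0("#", tsv_line(at$priority)),
    format_tsv_table(table$records[, at$column_id, drop = FALSE]))
}

parse_clinical_file <- function(path, kind) {
  lines <- read_study_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 5L || !all(startsWith(lines[1:4], "#"))) {
    cbp_parse_error(sprintf(
      "clinical file '%s' must start with four '#' metadata rows followed by the column-ID row",
      basename(path)), file = path)
  }
  hdr <- tsv_cells(sub("^#", "", lines[1:4]))
  ids <- tsv_cells(lines[[5L]])[[1L]]
  ncol <- length(ids)
  if (any(lengths(hdr) != ncol)) {
    cbp_parse_error(sprintf(
      "clinical file '%s': metadata rows have %s cells but there are %d columns",
      basename(path), paste(unique(lengths(hdr)), collapse = "/"), ncol),
      file = path)
  }
  priorities <- suppressWarnings(as.integer(hdr[[4L]]))
  priorities[is.na(priorities)] <- 1L
  catalog <- predefined_attributes(kind)
  attrs <- do.call(rbind, lapply(seq_len(ncol), function(j) {
    new_attribute_row(ids[[j]], hdr[[1L]][[j]], hdr[[2L]][[j]], hdr[[3L]][[j]],
                      priorities[[j]],
                      ids[[j]] %in% c(catalog$COLUMN_ID, id_columns(kind)))
  }))
  missing_ids <- setdiff(id_columns(kind), ids)
  if (length(missing_ids)) {
    cbp_parse_error(sprintf("clinical file '%s' lacks mandatory column(s): %s",
                            basename(path), paste(missing_ids, collapse = ", ")),
                    file = path)
  }
  rows <- tsv_cells(lines[-(1:5)])
  if (length(rows)) {
    lens <- lengths(rows)
    if (any(lens > ncol)) {
      bad <- which(lens > ncol)[[1L]]
      cbp_parse_error(sprintf(
        "clinical file '%s': record row %d has %d cells but the header has %d columns",
        basename(path), bad, lens[[bad]], ncol),
        file = path, line = bad + 5L)
    }
    rows <- lapply(rows, function(r) {
      r <- c(r, rep("", ncol - length(r)))
      r[r == "NA"] <- ""
      r
    })
  }
  records <- as.data.frame(
    stats::setNames(lapply(seq_len(ncol), function(j) vapply(rows, `[[`, "", j)), ids),
    check.names = FALSE, stringsAsFactors = FALSE)
  structure(list(kind = kind, attributes = attrs, records = records),
            class = "cbp_clinical_table")
}

#' @export
print.cbp_clinical_table <- function(x, ...) {
  cat(sprintf("<cbp_clinical_table: %s> %d attribute(s), %d record(s)\n",
              x$kind, nrow(x$attributes), nrow(x$records)))
  cat("attributes:", paste(x$attributes$column_id, collapse = ", "), "\n")
  invisible(x)
}
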