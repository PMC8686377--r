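# Study-level clinical operations. These wrap the table-level operations and
# enforce the mandated workflow order: a study exists before patients are
# added, a patient exists before their samples, a diagnosis date before
# timeline events (see add_event).

#' Add a patient to a study
#'
#' @param study A \code{cbp_study}.
#' @param values Named attribute values; \code{PATIENT_ID} is the only
#'   mandatory one.
#' @return The updated study.
#' @export
add_patient <- function(study, values) {
  stopifnot(inherits(study, "cbp_study"))
  study$patients <- add_record(study$patients, values)
  mark_dirty(study, "patients")
}

#' Add a sample to a study
#'
#' \code{PATIENT_ID} and \code{SAMPLE_ID} are mandatory, and the patient
#' must already exist in the study — samples are linked to patients by
#' \code{PATIENT_ID}, so the patient is created first.
#'
#' @inheritParams add_patient
#' @return The updated study.
#' @export
add_sample <- function(study, values) {
  stopifnot(inherits(study, "cbp_study"))
  values <- as.list(values)
  pid <- as.character(values[["PATIENT_ID"]] %||% "")
  if (nzchar(pid) && !pid %in% study$patients$records$PATIENT_ID) {
    cbp_precondition_error(sprintf(
      "patient '%s' is not in the study; add the patient before adding samples",
      pid))
  }
  study$samples <- add_record(study$samples, values)
  mark_dirty(study, "samples")
}

#' Delete a patient and everything that depends on them
#'
#' Removes the patient record, all their sample records, all mutation rows
#' whose \code{Tumor_Sample_Barcode} belongs to those samples, the
#' registered diagnosis date, all timeline events, and all patient/sample
#' resource entries. Dependents are removed rather than orphaned — the
#' validator would reject orphans anyway.
#'
#' @inheritParams add_patient
#' @param patient_id The patient to delete.
#' @return The updated study.
#' @export
delete_patient <- function(study, patient_id) {
  stopifnot(inherits(study, "cbp_study"))
  study$patients <- delete_record(study$patients, patient_id)
  study <- mark_dirty(study, "patients")

  srec <- study$samples$records
  sample_ids <- srec$SAMPLE_ID[srec$PATIENT_ID == patient_id]
  if (length(sample_ids)) {
    study$samples$records <- srec[srec$PATIENT_ID != patient_id, , drop = FALSE]
    rownames(study$samples$records) <- NULL
    study <- mark_dirty(study, "samples")
  }
  if (nrow(study$mutations) &&
      any(study$mutations$Tumor_Sample_Barcode %in% sample_ids)) {
    study$mutations <- study$mutations[
      !study$mutations$Tumor_Sample_Barcode %in% sample_ids, , drop = FALSE]
    rownames(study$mutations) <- NULL
    study <- mark_dirty(study, "mutations")
  }
  if (patient_id %in% study$diagnosis_dates$PATIENT_ID) {
    study$diagnosis_dates <- study$diagnosis_dates[
      study$diagnosis_dates$PATIENT_ID != patient_id, , drop = FALSE]
    rownames(study$diagnosis_dates) <- NULL
    study <- mark_dirty(study, "diagnosis_dates")
  }
  for (nm in names(study$timelines)) {
    tr <- study$timelines[[nm]]
    if (any(tr$events$PATIENT_ID == patient_id)) {
      tr$events <- tr$events[tr$events$PATIENT_ID != patient_id, , drop = FALSE]
      rownames(tr$events) <- NULL
      study$timelines[[nm]] <- tr
      study <- mark_dirty(study, paste0("timeline:", nm))
    }
  }
  for (part in c("patient", "sample")) {
    tab <- study$resources[[part]]
    if (nrow(tab) && any(tab$PATIENT_ID == patient_id)) {
      study$resources[[part]] <- tab[tab$PATIENT_ID != patient_id, , drop = FALSE]
      rownames(study$resources[[part]]) <- NULL
      study <- mark_dirty(study, "resources")
    }
  }
  study
}

# union of attribute columns: create src-only attributes in dst (with src
# metadata); existing dst records gain empty values
union_attributes <- function(dst_table, src_table) {
  for (i in seq_len(nrow(src_table$attributes))) {
    at <- src_table$attributes[i, ]
    if (!at$column_id %in% dst_table$attributes$column_id) {
      dst_table <- add_column(dst_table, attribute_def(
        at$column_id, at$short_name, at$long_name, at$datatype, at$priority))
    }
  }
  dst_table
}

#' Import a patient from another study
#'
#' Copies the patient record, all their samples, all mutation rows of those
#' samples, the first-diagnosis date, all timeline events and all resource
#' entries of the patient from a source study into the destination study.
#' Attribute columns and timeline tracks present in the source but absent
#' in the destination are created (with the source metadata); resource
#' definitions are copied as needed. A patient already present in the
#' destination is refused, leaving the destination unchanged.
#'
#' @param src_study Source \code{cbp_study}.
#' @param dst_study Destination \code{cbp_study}.
#' @param patient_id The patient to import.
#' @return The updated destination study.
#' @export
import_patient <- function(src_study, dst_study, patient_id) {
  stopifnot(inherits(src_study, "cbp_study"), inherits(dst_study, "cbp_study"))
  if (!patient_id %in% src_study$patients$records$PATIENT_ID) {
    cbp_not_found_error(sprintf("patient '%s' is not in the source study",
                                patient_id))
  }
  if (patient_id %in% dst_study$patients$records$PATIENT_ID) {
    cbp_conflict_error(sprintf(
      "patient '%s' already exists in the destination study", patient_id))
  }
  dst <- dst_study

  # patient record, with column union
  dst$patients <- union_attributes(dst$patients, src_study$patients)
  prec <- src_study$patients$records
  prow <- as.list(prec[prec$PATIENT_ID == patient_id, , drop = FALSE])
  prow <- prow[vapply(prow, nzchar, logical(1))]
  dst$patients <- add_record(dst$patients, prow)
  dst <- mark_dirty(dst, "patients")

  # samples
  dst$samples <- union_attributes(dst$samples, src_study$samples)
  srec <- src_study$samples$records
  sample_rows <- srec[srec$PATIENT_ID == patient_id, , drop = FALSE]
  for (i in seq_len(nrow(sample_rows))) {
    row <- as.list(sample_rows[i, , drop = FALSE])
    row <- row[vapply(row, nzchar, logical(1))]
    dst$samples <- add_record(dst$samples, row)
  }
  if (nrow(sample_rows)) dst <- mark_dirty(dst, "samples")
  sample_ids <- sample_rows$SAMPLE_ID

  # mutations of those samples
  maf <- src_study$mutations[
    src_study$mutations$Tumor_Sample_Barcode %in% sample_ids, , drop = FALSE]
  if (nrow(maf)) {
    dst$mutations <- bind_union(dst$mutations, maf)
    dst <- mark_dirty(dst, "mutations")
  }

  # diagnosis date
  reg <- src_study$diagnosis_dates
  if (patient_id %in% reg$PATIENT_ID) {
    dst <- set_first_diagnosis_date(dst, patient_id,
                                    reg$DATE[reg$PATIENT_ID == patient_id][[1L]])
  }

  # timeline events; create missing tracks / extra columns with src schema
  for (nm in names(src_study$timelines)) {
    src_tr <- src_study$timelines[[nm]]
    ev <- src_tr$events[src_tr$events$PATIENT_ID == patient_id, , drop = FALSE]
    if (!nrow(ev)) next
    if (!nm %in% names(dst$timelines)) {
      dst <- create_track(dst, nm, src_tr$mode, src_tr$extra_columns)
    }
    dst_tr <- dst$timelines[[nm]]
    new_extra <- setdiff(src_tr$extra_columns, dst_tr$extra_columns)
    if (length(new_extra)) {
      dst_tr$extra_columns <- c(dst_tr$extra_columns, new_extra)
      for (col in new_extra) dst_tr$events[[col]] <- rep("", nrow(dst_tr$events))
    }
    for (col in setdiff(names(dst_tr$events), names(ev))) {
      ev[[col]] <- rep("", nrow(ev))
    }
    dst_tr$events <- rbind(dst_tr$events,
                           ev[, names(dst_tr$events), drop = FALSE])
    rownames(dst_tr$events) <- NULL
    dst$timelines[[nm]] <- dst_tr
    dst <- mark_dirty(dst, paste0("timeline:", nm))
  }

  # resources of the patient and their samples
  src_defs <- src_study$resources$definitions
  copy_entries <- function(dst, part, rows) {
    if (!nrow(rows)) return(dst)
    for (rid in unique(rows$RESOURCE_ID)) {
      if (!rid %in% dst$resources$definitions$RESOURCE_ID) {
        d <- src_defs[src_defs$RESOURCE_ID == rid, , drop = FALSE]
        if (nrow(d)) {
          dst <- define_resource(dst, resource_definition(
            d$RESOURCE_ID, d$DISPLAY_NAME, d$RESOURCE_TYPE, d$DESCRIPTION,
            identical(d$OPEN_BY_DEFAULT, "true")))
        }
      }
    }
    dst$resources[[part]] <- rbind(dst$resources[[part]], rows)
    rownames(dst$resources[[part]]) <- NULL
    mark_dirty(dst, "resources")
  }
  pres <- src_study$resources$patient
  dst <- copy_entries(dst, "patient",
                      pres[pres$PATIENT_ID == patient_id, , drop = FALSE])
  sres <- src_study$resources$sample
  dst <- copy_entries(dst, "sample",
                      sres[sres$PATIENT_ID == patient_id, , drop = FALSE])
  dst
}
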