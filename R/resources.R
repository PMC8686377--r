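# Resources: hyperlinks to external documents (reports, images, web pages)
# attached to the whole study, to a patient, or to a sample, shown as tabs
# in cBioPortal. A resource definition declares the ID, display metadata and
# scope; entries then attach URLs to concrete targets. URLs are only checked
# for non-emptiness — clinical intranet links are not reachable from here.

RESOURCE_TYPES <- c("STUDY", "PATIENT", "SAMPLE")

new_resource_set <- function() {
  list(
    definitions = empty_character_df(c("RESOURCE_ID", "DISPLAY_NAME",
                                       "RESOURCE_TYPE", "DESCRIPTION",
                                       "OPEN_BY_DEFAULT")),
    study = empty_character_df(c("RESOURCE_ID", "URL")),
    patient = empty_character_df(c("PATIENT_ID", "RESOURCE_ID", "URL")),
    sample = empty_character_df(c("PATIENT_ID", "SAMPLE_ID", "RESOURCE_ID", "URL"))
  )
}

#' Declare a resource definition
#'
#' @param resource_id Token identifying the resource (e.g. \code{"REPORT"}).
#' @param display_name Name shown as the tab label in cBioPortal.
#' @param resource_type Scope: \code{"STUDY"}, \code{"PATIENT"} or
#'   \code{"SAMPLE"}; fixed after creation.
#' @param description Free-text description.
#' @param open_by_default Whether cBioPortal opens the resource tab
#'   automatically; defaults to \code{FALSE}.
#' @return An object of class \code{cbp_resource_definition}.
#' @export
resource_definition <- function(resource_id, display_name, resource_type,
                                description = "", open_by_default = FALSE) {
  if (!is.character(resource_type) || length(resource_type) != 1L ||
      !resource_type %in% RESOURCE_TYPES) {
    cbp_validation_error(sprintf(
      "resource_type must be one of %s", paste(RESOURCE_TYPES, collapse = ", ")))
  }
  if (!grepl("^[A-Za-z0-9_-]+$", resource_id)) {
    cbp_validation_error("resource_id must be a token matching [A-Za-z0-9_-]+")
  }
  assert_cells(c(display_name, description), "resource metadata")
  structure(list(resource_id = resource_id, display_name = display_name,
                 resource_type = resource_type, description = description,
                 open_by_default = isTRUE(open_by_default)),
            class = "cbp_resource_definition")
}

#' Register a resource definition in a study
#'
#' @param study A \code{cbp_study}.
#' @param definition A [resource_definition()], or its arguments can be
#'   passed directly via \code{...}.
#' @param ... Passed to [resource_definition()] when \code{definition} is a
#'   string (the resource_id).
#' @return The updated study.
#' @export
#' @examples
#' \dontrun{
#' study <- define_resource(study, "REPORT", "MTB Report", "PATIENT")
#' }
define_resource <- function(study, definition, ...) {
  stopifnot(inherits(study, "cbp_study"))
  if (!inherits(definition, "cbp_resource_definition")) {
    definition <- resource_definition(definition, ...)
  }
  defs <- study$resources$definitions
  if (definition$resource_id %in% defs$RESOURCE_ID) {
    cbp_conflict_error(sprintf("resource '%s' is already defined",
                               definition$resource_id))
  }
  study$resources$definitions <- rbind(defs, data.frame(
    RESOURCE_ID = definition$resource_id,
    DISPLAY_NAME = definition$display_name,
    RESOURCE_TYPE = definition$resource_type,
    DESCRIPTION = definition$description,
    OPEN_BY_DEFAULT = if (definition$open_by_default) "true" else "false",
    stringsAsFactors = FALSE))
  rownames(study$resources$definitions) <- NULL
  mark_dirty(study, "resources")
}

#' Attach a resource entry
#'
#' Attaches a URL to the target appropriate for the definition's type:
#' the whole study (no IDs), a patient (\code{patient_id}), or a sample
#' (\code{patient_id} and \code{sample_id}). Targets must exist in the
#' study's clinical tables.
#'
#' @inheritParams define_resource
#' @param resource_id A previously defined resource.
#' @param url Non-empty link to the document.
#' @param patient_id Required for PATIENT- and SAMPLE-type resources.
#' @param sample_id Required for SAMPLE-type resources.
#' @return The updated study.
#' @export
add_resource_entry <- function(study, resource_id, url,
                               patient_id = NULL, sample_id = NULL) {
  stopifnot(inherits(study, "cbp_study"))
  defs <- study$resources$definitions
  hit <- which(defs$RESOURCE_ID == resource_id)
  if (!length(hit)) {
    cbp_not_found_error(sprintf(
      "resource '%s' is not defined; call define_resource() first", resource_id))
  }
  if (!is.character(url) || length(url) != 1L || !nzchar(url)) {
    cbp_validation_error("url must be a non-empty string")
  }
  assert_cells(url, "url")
  type <- defs$RESOURCE_TYPE[[hit]]
  if (type %in% c("PATIENT", "SAMPLE")) {
    if (is.null(patient_id)) {
      cbp_validation_error(sprintf(
        "a %s-type resource entry requires patient_id", type))
    }
    if (!patient_id %in% study$patients$records$PATIENT_ID) {
      cbp_referential_error(sprintf("patient '%s' is not in the study", patient_id))
    }
  }
  if (type == "SAMPLE") {
    if (is.null(sample_id)) {
      cbp_validation_error("a SAMPLE-type resource entry requires sample_id")
    }
    srec <- study$samples$records
    if (!any(srec$SAMPLE_ID == sample_id & srec$PATIENT_ID == patient_id)) {
      cbp_referential_error(sprintf(
        "sample '%s' of patient '%s' is not in the study", sample_id, patient_id))
    }
  }
  study$resources[[tolower(type)]] <- rbind(
    study$resources[[tolower(type)]],
    switch(type,
      STUDY = data.frame(RESOURCE_ID = resource_id, URL = url,
                         stringsAsFactors = FALSE),
      PATIENT = data.frame(PATIENT_ID = patient_id, RESOURCE_ID = resource_id,
                           URL = url, stringsAsFactors = FALSE),
      SAMPLE = data.frame(PATIENT_ID = patient_id, SAMPLE_ID = sample_id,
                          RESOURCE_ID = resource_id, URL = url,
                          stringsAsFactors = FALSE)))
  rownames(study$resources[[tolower(type)]]) <- NULL
  mark_dirty(study, "resources")
}

#' List resource entries for a target
#'
#' Entries for the given scope and target, joined with their definitions so
#' the display name and description are included.
#'
#' @inheritParams define_resource
#' @param scope \code{"study"}, \code{"patient"} or \code{"sample"}.
#' @param id Patient or sample ID (ignored for study scope).
#' @return A data frame of entries; empty when nothing matches.
#' @export
resources_for <- function(study, scope = c("study", "patient", "sample"),
                          id = NULL) {
  stopifnot(inherits(study, "cbp_study"))
  scope <- match.arg(scope)
  entries <- study$resources[[scope]]
  if (scope == "patient" && !is.null(id)) {
    entries <- entries[entries$PATIENT_ID == id, , drop = FALSE]
  } else if (scope == "sample" && !is.null(id)) {
    entries <- entries[entries$SAMPLE_ID == id, , drop = FALSE]
  }
  defs <- study$resources$definitions
  j <- match(entries$RESOURCE_ID, defs$RESOURCE_ID)
  entries$DISPLAY_NAME <- defs$DISPLAY_NAME[j]
  entries$DESCRIPTION <- defs$DESCRIPTION[j]
  rownames(entries) <- NULL
  entries
}

# ---- file dialect -----------------------------------------------------------

RESOURCE_FILES <- c(
  definitions = "data_resource_definition.txt",
  study = "data_resource_study.txt",
  patient = "data_resource_patient.txt",
  sample = "data_resource_sample.txt"
)

meta_resource_keys <- function(study_id, component) {
  c(cancer_study_identifier = study_id,
    resource_type = if (component == "definitions") "RESOURCE_DEFINITION" else "RESOURCES",
    data_filename = RESOURCE_FILES[[component]])
}

parse_resource_file <- function(path, component) {
  tab <- read_tsv_table(path, comment = FALSE)
  want <- names(new_resource_set()[[component]])
  missing <- setdiff(want, names(tab))
  if (length(missing)) {
    cbp_parse_error(sprintf("resource file '%s' lacks column(s): %s",
                            basename(path), paste(missing, collapse = ", ")),
                    file = path)
  }
  attr(tab, "row_lines") <- NULL
  tab[, want, drop = FALSE]
}
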