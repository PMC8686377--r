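# Study store: discovery, creation, loading and saving of whole studies.
#
# The study root directory is the interface between this package and a
# cBioPortal instance: each immediate subdirectory holding a meta_study.txt
# is one study. Data files carry canonical names; each data file is paired
# 1:1 with a meta_<same suffix>.txt file. All writes are atomic
# (temp file + rename) because several users may read a shared study folder
# concurrently.

STUDY_META_FILE <- "meta_study.txt"

CLINICAL_FILES <- c(
  patients = "data_clinical_patient.txt",
  samples = "data_clinical_sample.txt"
)
MUTATION_FILE <- "data_mutations_extended.txt"
DIAGNOSIS_FILE <- "dates_first_diagnosis.txt"
CASE_LIST_FILE <- file.path("case_lists", "cases_sequenced.txt")

meta_name_for <- function(data_file) {
  sub("^data_", "meta_", data_file)
}

#' Describe the metadata of a cancer study
#'
#' The fields of cBioPortal's meta-study file: the study identifier (also
#' the folder name), the cancer type as an OncoTree code or the literal
#' \code{"mixed"} for multi-entity cohorts, a name and description, and
#' optionally a short name and the global-case-list flag.
#'
#' @param cancer_study_identifier Filesystem-safe token
#'   (\code{[A-Za-z0-9_-]+}) naming the study and its folder.
#' @param type_of_cancer OncoTree code or \code{"mixed"}.
#' @param name Study name (non-empty).
#' @param description Study description (non-empty).
#' @param short_name Optional short display name.
#' @param add_global_case_list Optional logical; asks cBioPortal to create
#'   an "All cases" list.
#' @param vocabulary OncoTree vocabulary used to check
#'   \code{type_of_cancer}; defaults to the bundled snapshot.
#' @return An object of class \code{cbp_study_meta}.
#' @export
#' @examples
#' study_meta("mtb_mainz", "mixed", "MTB", "MTB study")
study_meta <- function(cancer_study_identifier, type_of_cancer, name,
                       description, short_name = NULL,
                       add_global_case_list = NULL, vocabulary = NULL) {
  if (!is.character(cancer_study_identifier) ||
      length(cancer_study_identifier) != 1L ||
      !grepl("^[A-Za-z0-9_-]+$", cancer_study_identifier)) {
    cbp_validation_error(sprintf(
      "cancer_study_identifier must be a non-empty filesystem-safe token ([A-Za-z0-9_-]+), got '%s'",
      paste(cancer_study_identifier, collapse = ",")))
  }
  if (!nzchar(trimws(name)) || !nzchar(trimws(description))) {
    cbp_validation_error("study name and description must be non-empty")
  }
  if (!is_known_cancer_type(type_of_cancer, vocabulary)) {
    cbp_validation_error(sprintf(
      "type_of_cancer '%s' is neither 'mixed' nor a known cancer-type code",
      type_of_cancer))
  }
  assert_cells(c(name, description, short_name), "study metadata")
  structure(
    list(cancer_study_identifier = cancer_study_identifier,
         type_of_cancer = type_of_cancer, name = name,
         description = description, short_name = short_name,
         add_global_case_list = if (is.null(add_global_case_list)) NULL
                                else isTRUE(add_global_case_list)),
    class = "cbp_study_meta")
}

study_meta_keys <- function(meta) {
  keys <- c(type_of_cancer = meta$type_of_cancer,
            cancer_study_identifier = meta$cancer_study_identifier,
            name = meta$name,
            description = meta$description)
  if (!is.null(meta$short_name)) keys[["short_name"]] <- meta$short_name
  if (!is.null(meta$add_global_case_list)) {
    keys[["add_global_case_list"]] <- if (meta$add_global_case_list) "true" else "false"
  }
  keys
}

parse_study_meta <- function(path) {
  keys <- read_meta_file(path)
  required <- c("type_of_cancer", "cancer_study_identifier", "name", "description")
  missing <- setdiff(required, names(keys))
  if (length(missing)) {
    cbp_parse_error(sprintf("meta study file '%s' lacks key(s): %s",
                            basename(path), paste(missing, collapse = ", ")),
                    file = path)
  }
  meta <- list(cancer_study_identifier = keys[["cancer_study_identifier"]],
               type_of_cancer = keys[["type_of_cancer"]],
               name = keys[["name"]], description = keys[["description"]],
               short_name = if ("short_name" %in% names(keys)) keys[["short_name"]],
               add_global_case_list = if ("add_global_case_list" %in% names(keys))
                 identical(tolower(keys[["add_global_case_list"]]), "true"))
  # existing on-disk studies may carry codes beyond the bundled snapshot;
  # the validator reports unknown codes as a warning instead
  class(meta) <- "cbp_study_meta"
  meta
}

new_study <- function(root, meta) {
  timelines <- stats::setNames(
    lapply(names(BUILTIN_TRACKS), function(nm) {
      new_timeline_track(nm, BUILTIN_TRACKS[[nm]]$mode,
                         BUILTIN_TRACKS[[nm]]$extra_columns)
    }),
    names(BUILTIN_TRACKS))
  structure(
    list(root = root, meta = meta,
         patients = clinical_table("patient"),
         samples = clinical_table("sample"),
         mutations = new_mutation_table(),
         diagnosis_dates = empty_character_df(c("PATIENT_ID", "DATE")),
         timelines = timelines,
         resources = new_resource_set(),
         dirty = character(0)),
    class = "cbp_study")
}

mark_dirty <- function(study, component) {
  study$dirty <- union(study$dirty, component)
  study
}

study_dir <- function(study) {
  file.path(study$root, study$meta$cancer_study_identifier)
}

#' List the studies under a root directory
#'
#' Immediate subdirectories of the root that contain a parseable
#' \code{meta_study.txt} are studies; subdirectories without one are skipped
#' with a warning.
#'
#' @param root The study root directory.
#' @return Sorted character vector of study identifiers (folder names).
#' @export
list_studies <- function(root) {
  if (!dir.exists(root)) {
    cbp_io_error(sprintf("study root '%s' does not exist", root))
  }
  dirs <- list.dirs(root, recursive = FALSE, full.names = FALSE)
  ok <- vapply(dirs, function(d) {
    meta_path <- file.path(root, d, STUDY_META_FILE)
    if (!file.exists(meta_path)) {
      cbp_warn(sprintf("skipping '%s': no %s", d, STUDY_META_FILE),
               "cbp_skipped_folder_warning")
      return(FALSE)
    }
    tryCatch({ parse_study_meta(meta_path); TRUE },
             cbp_error = function(e) {
               cbp_warn(sprintf("skipping '%s': %s", d, conditionMessage(e)),
                        "cbp_skipped_folder_warning")
               FALSE
             })
  }, logical(1))
  sort(dirs[ok], method = "radix")
}

#' Create a new study
#'
#' Creates the study subfolder (named after the identifier) under the root
#' and writes its meta-study file. The returned study has empty component
#' tables, ready for the mandated workflow: patients first, then samples,
#' then optional mutation/timeline/resource data.
#'
#' @param root The study root directory (created if absent).
#' @param meta A [study_meta()].
#' @return A \code{cbp_study}.
#' @export
create_study <- function(root, meta) {
  stopifnot(inherits(meta, "cbp_study_meta"))
  id <- meta$cancer_study_identifier
  dir <- file.path(root, id)
  if (dir.exists(dir)) {
    cbp_conflict_error(sprintf("a study folder named '%s' already exists under '%s'",
                               id, root))
  }
  if (!dir.create(dir, recursive = TRUE, showWarnings = FALSE)) {
    cbp_io_error(sprintf("cannot create study folder '%s'", dir))
  }
  write_meta_file(file.path(dir, STUDY_META_FILE), study_meta_keys(meta))
  new_study(root, meta)
}

#' Load a study from disk
#'
#' Parses every canonical data file present in the study folder; absent
#' optional components load as empty collections (the workflow adds
#' components incrementally). Loading is atomic: a malformed file raises a
#' parse error and no partial study is returned.
#'
#' @param root The study root directory.
#' @param identifier The study identifier (subfolder name).
#' @return A \code{cbp_study} with an empty dirty set.
#' @export
load_study <- function(root, identifier) {
  dir <- file.path(root, identifier)
  meta_path <- file.path(dir, STUDY_META_FILE)
  if (!dir.exists(dir) || !file.exists(meta_path)) {
    cbp_not_found_error(sprintf("no study '%s' under '%s'", identifier, root))
  }
  meta <- parse_study_meta(meta_path)
  study <- new_study(root, meta)

  for (comp in names(CLINICAL_FILES)) {
    path <- file.path(dir, CLINICAL_FILES[[comp]])
    if (file.exists(path)) {
      study[[comp]] <- parse_clinical_file(
        path, if (comp == "patients") "patient" else "sample")
    }
  }
  maf_path <- file.path(dir, MUTATION_FILE)
  if (file.exists(maf_path)) {
    maf <- read_maf_file(maf_path)
    check_maf_columns(names(maf))
    attr(maf, "row_lines") <- NULL
    study$mutations <- maf
  }
  diag_path <- file.path(dir, DIAGNOSIS_FILE)
  if (file.exists(diag_path)) {
    study$diagnosis_dates <- parse_diagnosis_file(diag_path)
  }
  tl_files <- list.files(dir, pattern = "^data_timeline_.+\\.txt$")
  for (f in sort(tl_files, method = "radix")) {
    name <- sub("^data_timeline_(.+)\\.txt$", "\\1", f)
    study$timelines[[name]] <- parse_timeline_file(file.path(dir, f), name)
  }
  for (comp in names(RESOURCE_FILES)) {
    path <- file.path(dir, RESOURCE_FILES[[comp]])
    if (file.exists(path)) {
      study$resources[[comp]] <- parse_resource_file(path, comp)
    }
  }
  study
}

all_components <- function(study) {
  c("meta", "patients", "samples", "mutations", "diagnosis_dates",
    paste0("timeline:", names(study$timelines)), "resources")
}

component_present <- function(study, comp) {
  if (comp == "meta") return(TRUE)
  if (comp == "mutations") return(nrow(study$mutations) > 0L)
  if (comp == "diagnosis_dates") return(nrow(study$diagnosis_dates) > 0L)
  if (comp == "resources") return(nrow(study$resources$definitions) > 0L ||
                                  any(vapply(study$resources[-1L], nrow, 0L) > 0L))
  if (startsWith(comp, "timeline:")) {
    tr <- study$timelines[[sub("^timeline:", "", comp)]]
    return(!is.null(tr) && nrow(tr$events) > 0L)
  }
  nrow(study[[comp]]$records) > 0L
}

# All files (relative path -> lines) one component writes.
component_files <- function(study, comp) {
  id <- study$meta$cancer_study_identifier
  if (comp == "meta") {
    return(list(meta_study.txt = study_meta_keys_lines(study$meta)))
  }
  if (comp %in% c("patients", "samples")) {
    data_file <- CLINICAL_FILES[[comp]]
    keys <- c(cancer_study_identifier = id,
              genetic_alteration_type = "CLINICAL",
              datatype = if (comp == "patients") "PATIENT_ATTRIBUTES"
                         else "SAMPLE_ATTRIBUTES",
              data_filename = data_file)
    out <- list(format_clinical_lines(study[[comp]]),
                paste0(names(keys), ": ", keys))
    names(out) <- c(data_file, meta_name_for(data_file))
    return(out)
  }
  if (comp == "mutations") {
    keys <- meta_mutations_keys(id)
    out <- list(maf_lines(study),
                paste0(names(keys), ": ", keys),
                case_list_lines(id, study$mutations$Tumor_Sample_Barcode))
    names(out) <- c(MUTATION_FILE, meta_name_for(MUTATION_FILE), CASE_LIST_FILE)
    return(out)
  }
  if (comp == "diagnosis_dates") {
    out <- list(diagnosis_lines(study$diagnosis_dates))
    names(out) <- DIAGNOSIS_FILE
    return(out)
  }
  if (startsWith(comp, "timeline:")) {
    name <- sub("^timeline:", "", comp)
    tr <- study$timelines[[name]]
    data_file <- sprintf("data_timeline_%s.txt", name)
    keys <- meta_timeline_keys(id, name)
    out <- list(timeline_lines(tr), paste0(names(keys), ": ", keys))
    names(out) <- c(data_file, meta_name_for(data_file))
    return(out)
  }
  if (comp == "resources") {
    # all four files are (re)written so removed entries do not go stale
    out <- list()
    for (part in names(RESOURCE_FILES)) {
      tab <- study$resources[[part]]
      data_file <- RESOURCE_FILES[[part]]
      keys <- meta_resource_keys(id, part)
      out[[data_file]] <- format_tsv_table(tab)
      out[[meta_name_for(data_file)]] <- paste0(names(keys), ": ", keys)
    }
    return(out)
  }
  cbp_validation_error(sprintf("unknown component '%s'", comp))
}

study_meta_keys_lines <- function(meta) {
  keys <- study_meta_keys(meta)
  paste0(names(keys), ": ", keys)
}

#' Save a study to its folder
#'
#' Writes the data file and its paired meta file for each selected
#' component. By default only components modified since load (the dirty
#' set) are written; \code{components = "all"} writes every non-empty
#' component. Referential integrity (every sample's PATIENT_ID exists) is
#' checked before anything is written, and each file is written atomically,
#' so a failed save leaves all previously existing files untouched.
#'
#' @param study A \code{cbp_study} created or loaded from a root.
#' @param components Character vector of component names
#'   (\code{"meta"}, \code{"patients"}, \code{"samples"},
#'   \code{"mutations"}, \code{"diagnosis_dates"},
#'   \code{"timeline:<track>"}, \code{"resources"}), \code{"all"}, or
#'   \code{NULL} for the dirty set.
#' @return The updated study, with the written file paths in
#'   \code{attr(, "written")} and the dirty flags of the saved components
#'   cleared.
#' @export
save_study <- function(study, components = NULL) {
  stopifnot(inherits(study, "cbp_study"))
  explicit <- !is.null(components)
  if (identical(components, "all")) {
    components <- all_components(study)
    explicit <- FALSE
  }
  if (is.null(components)) components <- study$dirty
  unknown <- setdiff(components, all_components(study))
  if (length(unknown)) {
    cbp_validation_error(sprintf("unknown component(s): %s",
                                 paste(unknown, collapse = ", ")))
  }
  # dirty components are written even when empty (deletions must persist,
  # and the empty-MAF placeholder is deliberate); otherwise empty
  # components are skipped
  selected <- components[vapply(components, function(comp) {
    component_present(study, comp) || comp %in% study$dirty ||
      (explicit && comp == "mutations")
  }, logical(1))]

  # referential check before any write: nothing is written on failure
  if (any(c("samples", "patients") %in% sub(":.*", "", selected)) ||
      length(selected)) {
    orphan <- setdiff(study$samples$records$PATIENT_ID,
                      study$patients$records$PATIENT_ID)
    if (length(orphan)) {
      cbp_referential_error(sprintf(
        "sample records reference unknown PATIENT_ID(s): %s; nothing was written",
        paste(unique(orphan), collapse = ", ")))
    }
  }

  dir <- study_dir(study)
  if (!dir.exists(dir)) {
    cbp_io_error(sprintf("study folder '%s' does not exist", dir))
  }
  written <- character(0)
  for (comp in selected) {
    files <- component_files(study, comp)
    for (rel in names(files)) {
      path <- file.path(dir, rel)
      write_lines_atomic(files[[rel]], path)
      written <- c(written, path)
    }
  }
  study$dirty <- setdiff(study$dirty, selected)
  attr(study, "written") <- written
  study
}

#' Update a study's metadata
#'
#' Replaces the study metadata; the identifier itself cannot change
#' (renaming a study folder is not supported).
#'
#' @inheritParams save_study
#' @param new_meta A [study_meta()] with the same
#'   \code{cancer_study_identifier}.
#' @return The updated study with the meta component marked dirty.
#' @export
update_meta <- function(study, new_meta) {
  stopifnot(inherits(study, "cbp_study"), inherits(new_meta, "cbp_study_meta"))
  if (!identical(new_meta$cancer_study_identifier,
                 study$meta$cancer_study_identifier)) {
    cbp_unsupported_error(
      "changing the cancer_study_identifier (renaming a study) is not supported")
  }
  study$meta <- new_meta
  mark_dirty(study, "meta")
}

#' Reader/writer registry of supported cBioPortal data types
#'
#' The six cBioPortal data types the package both reads and writes:
#' Cancer Study, Patient, Sample, Mutation, Timeline and Resource.
#'
#' @return A data frame with columns \code{data_type}, \code{reader} and
#'   \code{writer} naming the internal parse/format routine for each type.
#' @export
cbp_format_registry <- function() {
  data.frame(
    data_type = c("Cancer Study", "Patient", "Sample", "Mutation",
                  "Timeline", "Resource"),
    reader = c("parse_study_meta", "parse_clinical_file", "parse_clinical_file",
               "read_maf_file", "parse_timeline_file", "parse_resource_file"),
    writer = c("study_meta_keys_lines", "format_clinical_lines",
               "format_clinical_lines", "maf_lines", "timeline_lines",
               "format_tsv_table"),
    stringsAsFactors = FALSE)
}

#' @export
print.cbp_study <- function(x, ...) {
  n_events <- sum(vapply(x$timelines, function(t) nrow(t$events), 0L))
  cat(sprintf("<cbp_study> %s (%s)\n", x$meta$cancer_study_identifier,
              x$meta$type_of_cancer))
  cat(sprintf("  patients: %d  samples: %d  mutations: %d\n",
              nrow(x$patients$records), nrow(x$samples$records),
              nrow(x$mutations)))
  cat(sprintf("  timeline events: %d (%d tracks)  diagnosis dates: %d\n",
              n_events, length(x$timelines), nrow(x$diagnosis_dates)))
  cat(sprintf("  resources: %d definition(s)  dirty: %s\n",
              nrow(x$resources$definitions),
              if (length(x$dirty)) paste(x$dirty, collapse = ", ") else "<none>"))
  invisible(x)
}
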