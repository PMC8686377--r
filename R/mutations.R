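# MAF mutation data.
#
# cBioPortal requires at least Hugo_Symbol, Tumor_Sample_Barcode,
# Variant_Classification and HGVSp_Short; any further columns are carried
# through untouched, in order of first appearance. Uploaded files are
# concatenated onto the existing table (no deduplication, no re-sorting);
# the validator flags exact duplicate rows as a warning.

MAF_REQUIRED_COLUMNS <- c("Hugo_Symbol", "Tumor_Sample_Barcode",
                          "Variant_Classification", "HGVSp_Short")

new_mutation_table <- function() {
  empty_character_df(MAF_REQUIRED_COLUMNS)
}

read_maf_file <- function(path) {
  tab <- read_tsv_table(path, comment = TRUE)
  attr(tab, "row_lines") <- NULL
  tab
}

check_maf_columns <- function(columns) {
  missing <- setdiff(MAF_REQUIRED_COLUMNS, columns)
  if (length(missing)) {
    cbp_format_error(
      sprintf("MAF is missing required column(s): %s",
              paste(missing, collapse = ", ")),
      missing_columns = missing)
  }
}

# rbind with column union; missing cells become "".
bind_union <- function(a, b) {
  all_cols <- union(names(a), names(b))
  fill <- function(df) {
    for (col in setdiff(all_cols, names(df))) df[[col]] <- rep("", nrow(df))
    df[, all_cols, drop = FALSE]
  }
  out <- rbind(fill(a), fill(b))
  rownames(out) <- NULL
  out
}

#' Import a MAF file into a study
#'
#' Reads a tab-separated Mutation Annotation Format file (header row
#' mandatory, \code{#}-prefixed comment lines tolerated) and concatenates
#' its rows onto the study's existing mutation data. The column set becomes
#' the union of old and new columns, missing cells stored empty. Rows whose
#' \code{Tumor_Sample_Barcode} is not among the study's samples are imported
#' with a referential warning; the validator reports them too.
#'
#' @param study A \code{cbp_study}.
#' @param maf_source Path to a MAF file, or a data frame with the same
#'   columns.
#' @return The updated study, with the mutation component marked dirty.
#' @export
import_maf <- function(study, maf_source) {
  stopifnot(inherits(study, "cbp_study"))
  maf <- if (is.character(maf_source)) read_maf_file(maf_source) else {
    df <- as.data.frame(maf_source, check.names = FALSE, stringsAsFactors = FALSE)
    df[] <- lapply(df, as.character)
    df
  }
  check_maf_columns(names(maf))
  assert_cells(unlist(maf, use.names = FALSE), "MAF cell")
  unknown <- setdiff(unique(maf$Tumor_Sample_Barcode),
                     study$samples$records$SAMPLE_ID)
  if (length(unknown)) {
    cbp_warn(sprintf(
      "MAF references Tumor_Sample_Barcode(s) not among the study's samples: %s",
      paste(unknown, collapse = ", ")), "cbp_referential_warning")
  }
  study$mutations <- bind_union(study$mutations, maf)
  mark_dirty(study, "mutations")
}

#' Mutations for one sample
#'
#' Subset of the study's mutation table whose
#' \code{Tumor_Sample_Barcode} equals the given sample ID, original row
#' order preserved. An unknown sample yields an empty table with the same
#' columns.
#'
#' @inheritParams import_maf
#' @param sample_id A sample barcode.
#' @return A data frame subset of the mutation table.
#' @export
mutations_for_sample <- function(study, sample_id) {
  stopifnot(inherits(study, "cbp_study"))
  out <- study$mutations[study$mutations$Tumor_Sample_Barcode == sample_id, ,
                         drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the study's MAF data file
#'
#' Writes \code{data_mutations_extended.txt}, its meta file, and the
#' \code{case_lists/cases_sequenced.txt} case list enumerating every
#' distinct \code{Tumor_Sample_Barcode}. An empty mutation table is written
#' as a header-only file with the four required columns (plus an empty case
#' list), so a study without mutation data still imports cleanly into
#' cBioPortal.
#'
#' @inheritParams import_maf
#' @return The path of the written data file (invisibly, with the meta and
#'   case-list paths as names in the full return of [save_study()]).
#' @export
write_maf <- function(study) {
  stopifnot(inherits(study, "cbp_study"))
  written <- save_study(study, components = "mutations")
  invisible(written[[1L]])
}

maf_lines <- function(study) {
  format_tsv_table(study$mutations)
}

meta_mutations_keys <- function(study_id) {
  c(cancer_study_identifier = study_id,
    genetic_alteration_type = "MUTATION_EXTENDED",
    datatype = "MAF",
    stable_id = "mutations",
    show_profile_in_analysis_tab = "true",
    profile_name = "Mutations",
    profile_description = "Somatic mutation data",
    data_filename = "data_mutations_extended.txt")
}

case_list_lines <- function(study_id, barcodes) {
  barcodes <- unique(barcodes)
  c(paste0("cancer_study_identifier: ", study_id),
    paste0("stable_id: ", study_id, "_sequenced"),
    "case_list_name: Sequenced samples",
    "case_list_description: All samples with mutation data",
    "case_list_category: all_cases_with_mutation_data",
    paste0("case_list_ids: ", paste(barcodes, collapse = "\t")))
}
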