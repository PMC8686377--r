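#' Load an OncoTree cancer-type vocabulary
#'
#' OncoTree is MSK's open ontology of short lowercase cancer-type codes
#' (e.g. \code{brca} for invasive breast carcinoma). A study's
#' \code{type_of_cancer} must be one of these codes, or the literal
#' \code{"mixed"} for multi-entity cohorts such as Molecular Tumor Board
#' studies. The package bundles a snapshot of common codes; a full OncoTree
#' export in the same four-column tab-separated format (CODE, NAME,
#' MAIN_TYPE, PARENT_CODE) can be supplied instead.
#'
#' The vocabulary is checked on load: codes must be unique, every
#' \code{PARENT_CODE} must itself be a code, and every ancestor chain must
#' terminate at a root (no cycles).
#'
#' @param path Path to a vocabulary file; \code{NULL} loads the bundled
#'   snapshot.
#' @return A data frame of class \code{oncotree} with columns \code{code},
#'   \code{name}, \code{main_type}, \code{parent_code} (\code{NA} for roots).
#' @export
#' @examples
#' voc <- oncotree_load()
#' oncotree_resolve(voc, "brca")$name
oncotree_load <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "oncotree_snapshot.tsv",
                        package = "cbpstudio", mustWork = TRUE)
  }
  tab <- read_tsv_table(path, comment = FALSE)
  required <- c("CODE", "NAME", "MAIN_TYPE", "PARENT_CODE")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    cbp_format_error(
      sprintf("vocabulary file '%s' lacks required columns: %s",
              basename(path), paste(missing, collapse = ", ")),
      missing_columns = missing
    )
  }
  voc <- data.frame(
    code = tab$CODE,
    name = tab$NAME,
    main_type = tab$MAIN_TYPE,
    parent_code = ifelse(nzchar(tab$PARENT_CODE), tab$PARENT_CODE, NA_character_),
    stringsAsFactors = FALSE
  )
  dup <- voc$code[duplicated(voc$code)]
  if (length(dup)) {
    cbp_validation_error(sprintf("duplicate OncoTree codes: %s",
                                 paste(unique(dup), collapse = ", ")))
  }
  unknown_parent <- setdiff(voc$parent_code[!is.na(voc$parent_code)], voc$code)
  if (length(unknown_parent)) {
    cbp_validation_error(sprintf("parent codes missing from vocabulary: %s",
                                 paste(unknown_parent, collapse = ", ")))
  }
  # ancestor chains must reach a root within n steps, else there is a cycle
  parent_of <- stats::setNames(voc$parent_code, voc$code)
  n <- nrow(voc)
  for (code in voc$code) {
    cur <- code
    steps <- 0L
    while (!is.na(parent_of[[cur]])) {
      cur <- parent_of[[cur]]
      steps <- steps + 1L
      if (steps > n) {
        cbp_validation_error(sprintf(
          "vocabulary contains a cycle involving code '%s'", code))
      }
    }
  }
  class(voc) <- c("oncotree", "data.frame")
  voc
}

#' Search the cancer-type vocabulary
#'
#' Case-insensitive substring search over code, name and main type, as used
#' to pick a study's cancer type. Exact code matches rank first, then
#' entries whose name matches, then the remaining matches; ties are broken
#' alphabetically by code. An empty query returns the full vocabulary.
#'
#' @param vocabulary An \code{oncotree} vocabulary from [oncotree_load()].
#' @param query Search text.
#' @return The matching rows, best match first.
#' @export
oncotree_search <- function(vocabulary, query = "") {
  stopifnot(inherits(vocabulary, "oncotree"))
  q <- tolower(trimws(query))
  voc <- vocabulary
  if (!nzchar(q)) {
    out <- voc[order(voc$code, method = "radix"), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  code_l <- tolower(voc$code)
  name_l <- tolower(voc$name)
  main_l <- tolower(voc$main_type)
  hit <- grepl(q, code_l, fixed = TRUE) |
    grepl(q, name_l, fixed = TRUE) |
    grepl(q, main_l, fixed = TRUE)
  rank <- ifelse(code_l == q, 1L, ifelse(grepl(q, name_l, fixed = TRUE), 2L, 3L))
  out <- voc[hit, , drop = FALSE]
  out <- out[order(rank[hit], out$code, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve a cancer-type code
#'
#' Returns the vocabulary entry for an exact code. The literal
#' \code{"mixed"} — the conventional type for multi-entity cohorts — is
#' always resolvable and returns a sentinel entry that is not part of the
#' tree. Unknown codes raise a not-found error listing the nearest matches.
#'
#' @inheritParams oncotree_search
#' @param code A lowercase OncoTree code or \code{"mixed"}.
#' @return A one-row data frame (code, name, main_type, parent_code).
#' @export
oncotree_resolve <- function(vocabulary, code) {
  stopifnot(inherits(vocabulary, "oncotree"))
  if (identical(tolower(code), "mixed")) {
    return(data.frame(code = "mixed", name = "Mixed Cancer Types",
                      main_type = "Mixed", parent_code = NA_character_,
                      stringsAsFactors = FALSE))
  }
  hit <- vocabulary$code == code
  if (!any(hit)) {
    near <- oncotree_search(vocabulary, code)
    hint <- if (nrow(near)) {
      sprintf("; nearest matches: %s", paste(utils::head(near$code, 5), collapse = ", "))
    } else ""
    cbp_not_found_error(sprintf("unknown cancer-type code '%s'%s", code, hint))
  }
  out <- vocabulary[hit, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

is_known_cancer_type <- function(code, vocabulary = NULL) {
  if (identical(tolower(code), "mixed")) return(TRUE)
  voc <- vocabulary %||% oncotree_load()
  code %in% voc$code
}
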