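# Low-level file I/O shared by all writers and readers.
#
# Study files are UTF-8, Unix line endings, tab-separated, unquoted. Cells may
# not contain tabs or newlines; that is enforced at input time so the writers
# never need quoting rules and round trips are byte-exact.

assert_cells <- function(values, what = "value") {
  values <- as.character(unlist(values, use.names = FALSE))
  bad <- grepl("[\t\n\r]", values)
  if (any(bad)) {
    cbp_validation_error(sprintf(
      "%s may not contain tab or newline characters: %s",
      what, paste(sQuote(values[bad]), collapse = ", ")
    ))
  }
  invisible(values)
}

# Atomic write: temp file in the target directory, then rename. Readers of a
# shared study folder never observe a half-written file.
write_lines_atomic <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) {
      cbp_io_error(sprintf("cannot create directory '%s'", dir))
    }
  }
  tmp <- tempfile(pattern = ".cbp_write_", tmpdir = dir)
  con <- tryCatch(file(tmp, open = "wb"), error = function(e) {
    cbp_io_error(sprintf("cannot write to '%s': %s", path, conditionMessage(e)))
  })
  ok <- tryCatch({
    writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE, finally = close(con))
  if (!ok || !file.rename(tmp, path)) {
    unlink(tmp)
    cbp_io_error(sprintf("failed to write '%s'", path))
  }
  invisible(path)
}

tsv_line <- function(cells) paste(cells, collapse = "\t")

# Split raw lines into cells; returns a list of character vectors.
tsv_cells <- function(lines) strsplit(lines, "\t", fixed = TRUE)

read_study_lines <- function(path) {
  if (!file.exists(path)) {
    cbp_io_error(sprintf("file '%s' does not exist", path))
  }
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

# key: value meta files (meta_study, meta_clinical_*, meta_mutations, ...).
# One key per line, fixed key order on output for deterministic files.
read_meta_file <- function(path) {
  lines <- read_study_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- character(0)
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    pos <- regexpr(":", line, fixed = TRUE)
    if (pos < 0L) {
      cbp_parse_error(
        sprintf("malformed meta file '%s': line %d has no 'key: value' separator",
                basename(path), i),
        file = path, line = i
      )
    }
    key <- trimws(substr(line, 1L, pos - 1L))
    value <- trimws(substr(line, pos + 1L, nchar(line)))
    if (!nzchar(key)) {
      cbp_parse_error(
        sprintf("malformed meta file '%s': empty key on line %d", basename(path), i),
        file = path, line = i
      )
    }
    out[[key]] <- value
  }
  out
}

write_meta_file <- function(path, keys) {
  # keys: named character vector, already in output order
  assert_cells(keys, "meta value")
  write_lines_atomic(paste0(names(keys), ": ", keys), path)
}

# Generic tab-separated table with one header line (MAF, resources, timeline,
# diagnosis-date sidecar). Lenient on read: `#` comment lines skipped, short
# rows padded with "", "NA" mapped to "". Over-long rows are a parse error.
read_tsv_table <- function(path, comment = TRUE) {
  lines <- read_study_lines(path)
  keep <- nzchar(lines)
  if (comment) keep <- keep & !startsWith(lines, "#")
  idx <- which(keep)
  if (length(idx) == 0L) {
    cbp_parse_error(sprintf("file '%s' has no header row", basename(path)),
                    file = path)
  }
  cells <- tsv_cells(lines[idx])
  header <- cells[[1L]]
  ncol <- length(header)
  rows <- cells[-1L]
  row_lines <- idx[-1L]
  if (length(rows)) {
    lens <- lengths(rows)
    if (any(lens > ncol)) {
      bad <- which(lens > ncol)[[1L]]
      cbp_parse_error(
        sprintf("file '%s': row at line %d has %d cells but the header has %d columns",
                basename(path), row_lines[[bad]], lens[[bad]], ncol),
        file = path, line = row_lines[[bad]]
      )
    }
    rows <- lapply(rows, function(r) {
      r <- c(r, rep("", ncol - length(r)))
      r[r == "NA"] <- ""
      r
    })
  }
  df <- as.data.frame(
    stats::setNames(
      lapply(seq_len(ncol), function(j) vapply(rows, `[[`, "", j)),
      header
    ),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  attr(df, "row_lines") <- row_lines
  df
}

# Deterministic writer for one-header-line tables. All columns character;
# missing values written as empty cells.
format_tsv_table <- function(df) {
  df[] <- lapply(df, function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  })
  assert_cells(unlist(df, use.names = FALSE), "cell")
  assert_cells(names(df), "column name")
  lines <- tsv_line(names(df))
  if (nrow(df) > 0L) {
    body <- do.call(paste, c(unname(as.list(df)), sep = "\t"))
    lines <- c(lines, body)
  }
  lines
}

empty_character_df <- function(columns) {
  as.data.frame(
    stats::setNames(rep(list(character(0)), length(columns)), columns),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
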