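# Reading and writing the delimited tables the pipeline consumes and
# produces. All verbatim content is carried byte-for-byte: columns are read
# as character, whitespace is never trimmed at ingest, and empty cells are
# the empty string (normalization is an explicit, flagged step downstream).

# Canonical Darwin Core taxon vocabulary (matching is case-insensitive).
DWC_NAME_FIELDS <- c(
  "scientificName", "genus", "subgenus", "specificEpithet",
  "infraspecificEpithet", "scientificNameAuthorship"
)

DWC_OCCURRENCE_FIELDS <- c(
  DWC_NAME_FIELDS,
  "basisOfRecord", "country", "continent", "year", "class", "institutionCode"
)

# Frozen column order of the assessment table (documented in the README and
# pinned by a golden-file test).
ASSESSMENT_COLUMNS <- c(
  "id", DWC_NAME_FIELDS,
  "constructedscientificname", "scientificnameplus",
  "dwcsn_rank", "sn_rank", "con_rank",
  "hasMisspelling", "hasFormatError", "hasConceptualError", "isSynonym",
  "hasIssue", "hasError",
  "con_authcap", "con_autherr", "sn_inf_missing", "con_sgerror", "con_rnk",
  "extra_whitespace", "epithet_capitalized", "genus_uncapitalized",
  "abbreviation_present", "qualifier_present", "only_infraspecific",
  "edit_distance_used",
  "validCanonical", "validSource", "sourceURL", "sourceDate",
  "comments", "checked"
)

ASSESSMENT_LOGICAL_COLUMNS <- c(
  "hasMisspelling", "hasFormatError", "hasConceptualError",
  "hasIssue", "hasError",
  "con_authcap", "con_autherr", "sn_inf_missing", "con_sgerror", "con_rnk",
  "extra_whitespace", "epithet_capitalized", "genus_uncapitalized",
  "abbreviation_present", "qualifier_present", "only_infraspecific"
)

delim_for <- function(path, dialect = c("auto", "tab", "comma")) {
  dialect <- match.arg(dialect)
  switch(dialect,
    tab = "\t",
    comma = ",",
    auto = if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  )
}

assert_utf8 <- function(path) {
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  txt <- rawToChar(raw)
  if (!all(validUTF8(txt))) {
    tv_abort(
      sprintf("file '%s' contains bytes that are not valid UTF-8", path),
      class = "taxonvet_encoding_error"
    )
  }
  invisible(TRUE)
}

read_verbatim_delim <- function(path, dialect = "auto") {
  if (!file.exists(path)) {
    tv_abort(sprintf("file not found: '%s'", path), "taxonvet_io_error")
  }
  assert_utf8(path)
  tbl <- suppressWarnings(readr::read_delim(
    path,
    delim = delim_for(path, dialect),
    col_types = readr::cols(.default = readr::col_character()),
    trim_ws = FALSE,
    na = character(),
    quote = "\"",
    progress = FALSE,
    show_col_types = FALSE
  ))
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    tv_abort(
      sprintf(
        "malformed rows in '%s': row(s) %s (%s)", path,
        paste(unique(probs$row), collapse = ", "),
        paste(unique(probs$expected), collapse = "; ")
      ),
      class = "taxonvet_parse_error"
    )
  }
  # A header-less file shows up as data in the header slot: no canonical
  # term can then be recognized, which the schema mappers treat as fatal.
  tbl
}

# Map header names onto a canonical vocabulary, case-insensitively.
# Returns the table with canonical names; unmapped columns are kept as-is.
map_headers <- function(tbl, vocabulary, path) {
  hits <- match(tolower(names(tbl)), tolower(vocabulary))
  if (all(is.na(hits))) {
    tv_abort(
      sprintf(
        "no recognizable Darwin Core header in '%s' (is the header row missing?)",
        path
      ),
      class = "taxonvet_parse_error"
    )
  }
  names(tbl)[!is.na(hits)] <- vocabulary[hits[!is.na(hits)]]
  dupes <- names(tbl)[duplicated(names(tbl))]
  if (length(dupes) > 0) {
    tv_abort(
      sprintf("duplicated columns after header mapping: %s",
              paste(unique(dupes), collapse = ", ")),
      class = "taxonvet_parse_error"
    )
  }
  for (f in setdiff(vocabulary, names(tbl))) tbl[[f]] <- ""
  tbl
}

check_unique_ids <- function(ids, what, path) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    tv_abort(
      sprintf("duplicate %s id(s) in '%s': %s", what, path,
              paste(head(dup, 10), collapse = ", ")),
      class = "taxonvet_parse_error"
    )
  }
}

#' Read a table of Darwin Core name combinations
#'
#' Reads a tab- or comma-delimited table whose header carries (a subset of)
#' the Darwin Core taxon terms `scientificName`, `genus`, `subgenus`,
#' `specificEpithet`, `infraspecificEpithet`, `scientificNameAuthorship`,
#' plus an `id` column. Header matching is case-insensitive; unmapped
#' columns are passed through untouched. Cell content is preserved
#' byte-for-byte (no trimming, no NA conversion); absent canonical columns
#' are filled with the empty string. Files must be valid UTF-8.
#'
#' @param path file path; `.csv` selects comma, anything else tab, unless
#'   `dialect` overrides.
#' @param dialect one of `"auto"`, `"tab"`, `"comma"`.
#' @return a tibble with one row per name combination, columns `id`, the six
#'   verbatim fields, then any pass-through extras. Row order is preserved.
#' @export
read_name_table <- function(path, dialect = "auto") {
  tbl <- read_verbatim_delim(path, dialect)
  tbl <- map_headers(tbl, c("id", DWC_NAME_FIELDS), path)
  if (!all(is_filled(tbl$id))) {
    tbl$id <- ifelse(is_filled(tbl$id), tbl$id,
                     sprintf("name-%06d", seq_len(nrow(tbl))))
  }
  check_unique_ids(tbl$id, "name", path)
  dplyr::relocate(tbl, dplyr::all_of(c("id", DWC_NAME_FIELDS)))
}

#' Read a table of occurrence records
#'
#' As [read_name_table()], for the occurrence schema: the six taxon fields
#' plus `basisOfRecord`, `country`, `continent`, `year`, `class` and
#' `institutionCode`, keyed by `occurrenceID` (an `id` header is accepted as
#' an alias). Extra columns (e.g. `datasetName`) pass through.
#'
#' @inheritParams read_name_table
#' @return a tibble of occurrence records, row order preserved.
#' @export
read_occurrence_table <- function(path, dialect = "auto") {
  tbl <- read_verbatim_delim(path, dialect)
  tbl <- map_headers(tbl, c("occurrenceID", "id", DWC_OCCURRENCE_FIELDS), path)
  if (!is_filled(tbl$occurrenceID[1]) && any(is_filled(tbl$id))) {
    tbl$occurrenceID <- tbl$id
    tbl$id <- NULL
  } else if ("id" %in% names(tbl) && all(!is_filled(tbl$id))) {
    tbl$id <- NULL
  }
  if (nrow(tbl) > 0 && !all(is_filled(tbl$occurrenceID))) {
    tbl$occurrenceID <- ifelse(is_filled(tbl$occurrenceID), tbl$occurrenceID,
                               sprintf("occ-%07d", seq_len(nrow(tbl))))
  }
  check_unique_ids(tbl$occurrenceID, "occurrence", path)
  dplyr::relocate(tbl, dplyr::all_of(c("occurrenceID", DWC_OCCURRENCE_FIELDS)))
}

#' Write an assessment table
#'
#' Writes assessment records with a fixed, documented column order (see
#' `taxonvet:::ASSESSMENT_COLUMNS`). Logical flags are serialized as
#' TRUE/FALSE, everything else verbatim; fields containing the delimiter
#' are quoted so that [read_assessment_table()] round-trips exactly.
#'
#' @param records assessment tibble as produced by [assess_table()].
#' @param path output path; `.csv` writes comma-separated, else tab.
#' @return `path`, invisibly.
#' @export
write_assessment_table <- function(records, path) {
  missing_cols <- setdiff(ASSESSMENT_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    tv_abort(
      sprintf("assessment records lack column(s): %s",
              paste(missing_cols, collapse = ", ")),
      class = "taxonvet_io_error"
    )
  }
  out <- records[, ASSESSMENT_COLUMNS]
  # quote = "all" because free-text fields (comments) may embed the
  # delimiter, which bare TSV quoting does not protect against
  readr::write_delim(out, path, delim = delim_for(path, "auto"),
                     quote = "all", escape = "double", na = "")
  invisible(path)
}

#' Read an assessment table written by [write_assessment_table()]
#'
#' @inheritParams read_name_table
#' @return assessment tibble with flag columns restored to logical,
#'   `isSynonym` as its yes/no/indeterminate code and `edit_distance_used`
#'   numeric.
#' @export
read_assessment_table <- function(path, dialect = "auto") {
  tbl <- read_verbatim_delim(path, dialect)
  missing_cols <- setdiff(ASSESSMENT_COLUMNS, names(tbl))
  if (length(missing_cols) > 0) {
    tv_abort(
      sprintf("'%s' is not an assessment table (missing: %s)", path,
              paste(missing_cols, collapse = ", ")),
      class = "taxonvet_parse_error"
    )
  }
  for (col in ASSESSMENT_LOGICAL_COLUMNS) tbl[[col]] <- tbl[[col]] == "TRUE"
  tbl$edit_distance_used <- suppressWarnings(as.numeric(tbl$edit_distance_used))
  tbl[, ASSESSMENT_COLUMNS]
}
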