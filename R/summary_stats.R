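# Prevalence summary (Table-1 style), issue-overlap counts, and the
# person-hours effort projection.

SUMMARY_CATEGORIES <- c("Total", "Valid name found", "Valid name not found",
                        "Has error", "Has issue", "Misspelling",
                        "Format error", "Conceptual error", "Synonym",
                        "Indeterminate")

ISSUE_CLASSES <- c("misspelling", "format", "conceptual", "synonym")

summary_row_masks <- function(assessments) {
  list(
    "Total" = rep(TRUE, nrow(assessments)),
    "Valid name found" = nzchar(assessments$validCanonical),
    "Valid name not found" = !nzchar(assessments$validCanonical),
    "Has error" = assessments$hasError,
    "Has issue" = assessments$hasIssue,
    "Misspelling" = assessments$hasMisspelling,
    "Format error" = assessments$hasFormatError,
    "Conceptual error" = assessments$hasConceptualError,
    "Synonym" = assessments$isSynonym == "yes",
    "Indeterminate" = assessments$isSynonym == "indeterminate"
  )
}

validate_summary_table <- function(tbl) {
  g <- function(cat) tbl$names_n[tbl$category == cat]
  stopifnot(
    g("Valid name found") + g("Valid name not found") == g("Total"),
    g("Has error") <= g("Has issue"),
    g("Has issue") <= g("Total"),
    all(tbl$names_n[tbl$category %in% c("Misspelling", "Format error",
                                        "Conceptual error", "Synonym")] <=
          g("Has issue")),
    all(tbl$names_pct == pct1(tbl$names_n, g("Total")))
  )
  invisible(tbl)
}

#' Build a prevalence summary table from explicit counts
#'
#' Constructor used when the per-category counts are already known (for
#' example when re-deriving printed percentages from a published table).
#' Percentages are recomputed from the paired counts with half-up rounding
#' at one decimal; name-combination percentages are of the assessed total,
#' occurrence percentages of the total matching occurrences.
#'
#' @param names_n named integer vector over the summary categories
#'   (`Total`, `Valid name found`, ..., `Indeterminate`).
#' @param occurrences_n optional named integer vector, same categories.
#' @param institutions_n,datasets_n optional named integer vectors of
#'   distinct-institution / distinct-data-set counts.
#' @return summary tibble with count and percentage columns.
#' @export
summary_table_from_counts <- function(names_n, occurrences_n = NULL,
                                      institutions_n = NULL,
                                      datasets_n = NULL) {
  cats <- SUMMARY_CATEGORIES
  grab <- function(x) {
    if (is.null(x)) return(rep(NA_integer_, length(cats)))
    out <- x[cats]
    as.integer(out)
  }
  nn <- grab(names_n)
  on <- grab(occurrences_n)
  tbl <- tibble::tibble(
    category = cats,
    names_n = nn,
    names_pct = pct1(nn, nn[1]),
    occurrences_n = on,
    occurrences_pct = if (all(is.na(on))) NA_real_ else pct1(on, on[1]),
    institutions_n = grab(institutions_n),
    datasets_n = grab(datasets_n)
  )
  validate_summary_table(tbl)
}

#' Summarize issue prevalence across an assessed name set
#'
#' Produces the per-category count/percentage table over name
#' combinations, with matching-occurrence counts and distinct
#' institution/data-set counts taken from the linked occurrence set when
#' supplied. Ids in `exclusions` (e.g. combinations with competing equally
#' valid resolutions) are dropped from every row except the first three,
#' mirroring how dual-resolution records are reported only in the
#' resolution rows.
#'
#' @param assessments assessment tibble from [assess_table()].
#' @param matched optional matched occurrence set from
#'   [link_occurrences()] (`$matched`), used for occurrence, institution
#'   and data-set counts.
#' @param exclusions character ids to drop from the issue rows.
#' @return summary tibble (see [summary_table_from_counts()]).
#' @export
summarize_issues <- function(assessments, matched = NULL,
                             exclusions = character()) {
  if (nrow(assessments) == 0) {
    tv_abort("cannot summarize an empty assessment set",
             class = "taxonvet_summary_error")
  }
  keep_all <- assessments
  keep_issue <- assessments[!(assessments$id %in% exclusions), ]
  first3 <- c("Total", "Valid name found", "Valid name not found")

  masks_all <- summary_row_masks(keep_all)
  masks_issue <- summary_row_masks(keep_issue)

  count_occ <- function(ids) {
    if (is.null(matched)) return(c(n = NA_integer_, inst = NA_integer_,
                                   ds = NA_integer_))
    m <- matched[matched$id %in% ids, ]
    c(n = nrow(m),
      inst = length(unique(m$institutionCode[is_filled(m$institutionCode)])),
      ds = if ("datasetName" %in% names(m)) {
        length(unique(m$datasetName[is_filled(m$datasetName)]))
      } else NA_integer_)
  }

  rows <- lapply(SUMMARY_CATEGORIES, function(cat) {
    src <- if (cat %in% first3) keep_all else keep_issue
    mask <- (if (cat %in% first3) masks_all else masks_issue)[[cat]]
    occ <- count_occ(src$id[mask])
    tibble::tibble(category = cat, names_n = sum(mask),
                   occurrences_n = occ[["n"]],
                   institutions_n = occ[["inst"]],
                   datasets_n = occ[["ds"]])
  })
  tbl <- dplyr::bind_rows(rows)
  tbl$names_pct <- pct1(tbl$names_n, tbl$names_n[1])
  tbl$occurrences_pct <- if (all(is.na(tbl$occurrences_n))) NA_real_ else
    pct1(tbl$occurrences_n, tbl$occurrences_n[1])
  tbl <- tbl[, c("category", "names_n", "names_pct", "occurrences_n",
                 "occurrences_pct", "institutions_n", "datasets_n")]
  validate_summary_table(tbl)
}

#' Count issue-type overlaps
#'
#' Partitions the issue-bearing name combinations into the 15 non-empty
#' subsets of {misspelling, format, conceptual, synonym} (synonym
#' membership means confirmed synonymy). Subset counts sum to the
#' has-issue count.
#'
#' @param assessments assessment tibble.
#' @return tibble with `subset` (classes joined by "+") and `n`, covering
#'   all 15 subsets (zeros included).
#' @export
issue_overlap <- function(assessments) {
  flags <- cbind(
    misspelling = assessments$hasMisspelling,
    format = assessments$hasFormatError,
    conceptual = assessments$hasConceptualError,
    synonym = assessments$isSynonym == "yes"
  )
  subsets <- lapply(seq_len(15), function(bits) {
    ISSUE_CLASSES[bitwAnd(bits, c(1L, 2L, 4L, 8L)) > 0]
  })
  labels <- vapply(subsets, paste, character(1), collapse = "+")
  n <- vapply(subsets, function(s) {
    members <- ISSUE_CLASSES %in% s
    sum(apply(flags, 1L, function(r) all(r == members)))
  }, integer(1))
  tibble::tibble(subset = labels, n = n)
}

#' Project the person-hours needed to vet a corpus of names
#'
#' Linear extrapolation of a measured vetting rate: `n_names *
#' hours_per_batch / batch_size`, rounded half-up to whole hours. With the
#' measured rate of 4 hours of concerted work per 100 records, a corpus of
#' 522,163 name combinations projects to 20,887 person-hours.
#'
#' @param n_names number of name combinations to vet.
#' @param hours_per_batch measured hours per vetting batch (default 4).
#' @param batch_size records per batch (default 100); must be positive.
#' @return integer person-hours.
#' @export
#' @examples
#' project_effort(522163, 4, 100)  # 20887
project_effort <- function(n_names, hours_per_batch = 4, batch_size = 100) {
  if (length(batch_size) != 1 || is.na(batch_size) || batch_size <= 0) {
    tv_abort("batch_size must be a positive number",
             class = "taxonvet_summary_error")
  }
  as.integer(round_half_up(n_names * hours_per_batch / batch_size))
}
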