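# A local, pluggable taxonomic authority: exact lookup, fuzzy lookup by
# Damerau-Levenshtein distance, and one-hop synonym chasing. This is the
# programmatic stand-in for the curated online checklists a human vetter
# would consult; it is single-voice by construction (no multi-source
# arbitration).

AUTHORITY_COLUMNS <- c("canonical", "rank", "status", "acceptedCanonical",
                       "source", "sourceURL", "sourceDate")

#' Damerau-Levenshtein edit distance
#'
#' Unit-cost character insertions, deletions, substitutions and adjacent
#' transpositions (optimal-string-alignment variant: a transposed pair is
#' not edited again). Case-sensitive; callers that want case-insensitive
#' behaviour normalize first (capitalization issues are charged to the
#' format detector, not the distance).
#'
#' @param a,b character vectors (recycled against each other).
#' @return integer vector of distances.
#' @export
#' @examples
#' edit_distance("caeruleus", "caerulesu")  # 1 (adjacent transposition)
edit_distance <- function(a, b) {
  dl_distance_cpp(as.character(a), as.character(b))
}

#' Load a taxonomic authority from a delimited file
#'
#' The file carries the columns `canonical`, `rank`, `status`
#' (accepted|synonym), `acceptedCanonical`, `source`, `sourceURL`,
#' `sourceDate`. At load the resolution-closure invariants are verified:
#' every accepted entry points to itself, every synonym points to an
#' accepted entry present in the table (chains resolve in one hop), and no
#' canonical appears twice with conflicting status.
#'
#' @param path delimited file (tab by default, comma for `.csv`).
#' @return a `taxon_authority` object.
#' @export
load_authority <- function(path) {
  tbl <- read_verbatim_delim(path)
  missing_cols <- setdiff(AUTHORITY_COLUMNS, names(tbl))
  if (length(missing_cols) > 0) {
    tv_abort(
      sprintf("'%s' is not an authority table (missing: %s)", path,
              paste(missing_cols, collapse = ", ")),
      class = "taxonvet_parse_error"
    )
  }
  new_authority(tbl[, AUTHORITY_COLUMNS])
}

#' Construct a taxon authority from a tibble of entries
#'
#' @param entries tibble with the authority columns (see [load_authority()]).
#' @return a `taxon_authority`: the validated entry table plus lookup index.
#' @export
new_authority <- function(entries) {
  entries <- tibble::as_tibble(entries)
  entries$status <- tolower(entries$status)
  bad_status <- setdiff(unique(entries$status), c("accepted", "synonym"))
  if (length(bad_status) > 0) {
    tv_abort(sprintf("unknown status value(s): %s",
                     paste(bad_status, collapse = ", ")),
             class = "taxonvet_authority_error")
  }
  dup <- entries$canonical[duplicated(entries$canonical)]
  if (length(dup) > 0) {
    conflicting <- vapply(unique(dup), function(cn) {
      length(unique(entries$status[entries$canonical == cn])) > 1
    }, logical(1))
    if (any(conflicting)) {
      tv_abort(
        sprintf("duplicate canonical with conflicting status: %s",
                paste(unique(dup)[conflicting], collapse = ", ")),
        class = "taxonvet_authority_error"
      )
    }
    entries <- entries[!duplicated(entries$canonical), ]
  }
  accepted <- entries$canonical[entries$status == "accepted"]
  self_ok <- entries$status != "accepted" |
    entries$acceptedCanonical == entries$canonical
  if (!all(self_ok)) {
    tv_abort(
      sprintf("accepted entries must point to themselves: %s",
              paste(entries$canonical[!self_ok], collapse = ", ")),
      class = "taxonvet_authority_error"
    )
  }
  syn <- entries[entries$status == "synonym", ]
  orphan <- setdiff(syn$acceptedCanonical, accepted)
  if (length(orphan) > 0) {
    tv_abort(
      sprintf("synonym(s) point to absent accepted name(s): %s",
              paste(orphan, collapse = ", ")),
      class = "taxonvet_authority_error"
    )
  }
  idx <- seq_len(nrow(entries))
  names(idx) <- entries$canonical
  structure(
    list(entries = entries, index = idx,
         genera = sort(unique(vapply(
           strsplit(entries$canonical, " ", fixed = TRUE), `[[`, "", 1L)))),
    class = "taxon_authority"
  )
}

#' @export
print.taxon_authority <- function(x, ...) {
  n_acc <- sum(x$entries$status == "accepted")
  cat(sprintf(
    "<taxon_authority> %d entries (%d accepted, %d synonyms), %d genera\n",
    nrow(x$entries), n_acc, nrow(x$entries) - n_acc, length(x$genera)))
  invisible(x)
}

#' @export
length.taxon_authority <- function(x) nrow(x$entries)

#' Exact lookup of a canonical name
#'
#' Case-sensitive exact match against the authority's canonical names.
#'
#' @param authority a `taxon_authority`.
#' @param name canonical name string.
#' @return a one-row entry tibble, or `NULL` when absent.
#' @export
lookup_exact <- function(authority, name) {
  i <- authority$index[name]
  if (is.na(i)) return(NULL)
  authority$entries[i, ]
}

#' Fuzzy lookup by Damerau-Levenshtein distance
#'
#' Returns every authority entry within `max_dist` of `name`, ordered by
#' (distance, accepted before synonym, lexicographic canonical) so that
#' ties break deterministically. Callers short-circuit on exact matches
#' upstream; a distance-0 hit is returned here like any other candidate.
#'
#' @param authority a `taxon_authority`.
#' @param name query string (already normalized by the caller).
#' @param max_dist maximum edit distance to admit.
#' @return tibble of candidates with a `distance` column (possibly empty).
#' @export
lookup_fuzzy <- function(authority, name, max_dist) {
  cand <- authority$entries
  # cheap length pre-filter: |len(a) - len(b)| bounds the distance
  keep <- abs(nchar(cand$canonical) - nchar(name)) <= max_dist
  cand <- cand[keep, ]
  if (nrow(cand) == 0) {
    return(tibble::add_column(cand, distance = integer()))
  }
  d <- edit_distance(cand$canonical, name)
  cand <- tibble::add_column(cand, distance = d)[d <= max_dist, ]
  cand[order(cand$distance, cand$status != "accepted", cand$canonical), ]
}

#' Resolve an entry to its accepted canonical name
#'
#' One-hop resolution through `acceptedCanonical`; idempotent (resolving an
#' accepted entry returns it unchanged).
#'
#' @param authority a `taxon_authority`.
#' @param entry a one-row entry tibble.
#' @return the accepted entry the input resolves to.
#' @export
resolve_accepted <- function(authority, entry) {
  if (entry$status == "accepted") return(entry)
  lookup_exact(authority, entry$acceptedCanonical)
}

#' Write an authority to a delimited file
#'
#' @param authority a `taxon_authority`.
#' @param path output path (tab-delimited unless `.csv`).
#' @return `path`, invisibly.
#' @export
write_authority <- function(authority, path) {
  if (delim_for(path, "auto") == ",") {
    readr::write_csv(authority$entries, path, na = "")
  } else {
    readr::write_tsv(authority$entries, path, na = "")
  }
  invisible(path)
}
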