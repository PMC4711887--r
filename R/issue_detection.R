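# Detection and classification of the four issue types per name
# combination, and resolution against the authority. The four classes are:
#   misspelling   - character-level corruption (ins/del/sub/transposition)
#   format error  - capitalization, whitespace, abbreviation problems
#   conceptual    - misuse of Darwin Core field semantics
#   synonymy      - out-of-date but otherwise correct names (not an error)

#' Assessment configuration
#'
#' Thresholds and token lists used by the detectors and the resolver.
#'
#' @param max_dist_genus,max_dist_binomial,max_dist_trinomial maximum
#'   Damerau-Levenshtein distance admitted for fuzzy resolution of
#'   uninomial, binomial and trinomial queries. The defaults (1, 2, 3)
#'   bound false positives at realistic misspelling rates while catching
#'   common slips, including 1-2 edit gender-ending variants.
#' @param qualifier_tokens identification-qualifier tokens flagged as
#'   Darwin Core conceptual errors when found inside name fields. The core
#'   three ("sp.", "cf.", "?") are standard; the rest are conservative
#'   extensions and can be switched off by passing a shorter list.
#' @param expand_abbreviated_genus try expanding a leading single-letter
#'   abbreviated genus ("P. major") against the authority's genus list
#'   before matching.
#' @return a list of class `assessment_config`.
#' @export
assessment_config <- function(max_dist_genus = 1,
                              max_dist_binomial = 2,
                              max_dist_trinomial = 3,
                              qualifier_tokens = c("sp.", "spp.", "ssp.",
                                                   "cf.", "aff.", "nr.",
                                                   "?", "sp"),
                              expand_abbreviated_genus = TRUE) {
  structure(
    list(
      max_dist_genus = max_dist_genus,
      max_dist_binomial = max_dist_binomial,
      max_dist_trinomial = max_dist_trinomial,
      qualifier_tokens = qualifier_tokens,
      expand_abbreviated_genus = expand_abbreviated_genus
    ),
    class = "assessment_config"
  )
}

max_dist_for <- function(n_tokens, config) {
  if (n_tokens <= 1) config$max_dist_genus
  else if (n_tokens == 2) config$max_dist_binomial
  else config$max_dist_trinomial
}

is_qualifier_token <- function(tok, config) {
  tolower(tok) %in% tolower(config$qualifier_tokens) |
    grepl("\\?", tok)
}

drop_qualifiers <- function(name, config) {
  toks <- strsplit(squish(name), " ", fixed = TRUE)[[1]]
  toks <- toks[!is_qualifier_token(toks, config)]
  paste(toks, collapse = " ")
}

contains_qualifier <- function(x, config) {
  vapply(blank_na(x), function(s) {
    toks <- strsplit(squish(s), " ", fixed = TRUE)[[1]]
    any(is_qualifier_token(toks, config))
  }, logical(1), USE.NAMES = FALSE)
}

cap_first <- function(x) {
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
}

#' Normalize a name string for authority matching
#'
#' Collapses whitespace, removes identification-qualifier tokens, strips
#' subgenus and authorship tokens (see [infer_rank()] for the token
#' classifier) and case-normalizes the remainder: genus capitalized,
#' epithets lowercased. Capitalization problems are thereby charged to the
#' format detector, never to the edit distance. The verbatim input is
#' never mutated.
#'
#' @param name character vector of name strings.
#' @param config an [assessment_config()].
#' @return character vector of canonical-form matching keys ("" when
#'   nothing survives stripping, e.g. authorship-only content).
#' @export
normalize_name <- function(name, config = assessment_config()) {
  vapply(blank_na(name), function(s) {
    s <- drop_qualifiers(s, config)
    parts <- classify_tokens(s)
    toks <- parts$name
    if (length(toks) == 0) return("")
    toks[1] <- cap_first(toks[1])
    if (length(toks) > 1) toks[-1] <- tolower(toks[-1])
    paste(toks, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

# ---------------------------------------------------------------------------
# Format issues

auth_particles <- c("de", "van", "von", "der", "den", "la", "le", "du",
                    "dos", "da", "y", "et", "ex", "in")

authorship_miscapitalized <- function(auth) {
  vapply(blank_na(auth), function(s) {
    toks <- strsplit(squish(gsub("[(),]", " ", s)), " ", fixed = TRUE)[[1]]
    toks <- toks[grepl("^[A-Za-z]", toks)]
    toks <- toks[!(tolower(toks) %in% auth_particles)]
    any(grepl("^[a-z]", toks))
  }, logical(1), USE.NAMES = FALSE)
}

has_messy_whitespace <- function(x) {
  grepl("^[ \t]|[ \t]$|[ \t]{2,}", blank_na(x))
}

#' Detect format issues in a name combination
#'
#' Flags whitespace problems (leading/trailing/doubled), an uncapitalized
#' genus, capitalized epithets, authorship capitalization violations
#' (`con_authcap`) and abbreviations (single-letter genus with period,
#' "var."-style rank abbreviations embedded in name strings). Operates on
#' the verbatim fields plus both convenience strings; never mutates them.
#'
#' @param tbl name table with convenience fields
#'   (see [add_convenience_fields()]).
#' @param config an [assessment_config()].
#' @return tibble of logical flag columns `extra_whitespace`,
#'   `genus_uncapitalized`, `epithet_capitalized`, `con_authcap`,
#'   `abbreviation_present`, plus the rollup `hasFormatError`.
#' @export
detect_format_issues <- function(tbl, config = assessment_config()) {
  n <- nrow(tbl)
  ws <- rep(FALSE, n)
  for (f in DWC_NAME_FIELDS) ws <- ws | has_messy_whitespace(tbl[[f]])

  sn_first <- vapply(blank_na(tbl$scientificName), function(s) {
    t <- strsplit(squish(s), " ", fixed = TRUE)[[1]]
    if (length(t) == 0) "" else t[1]
  }, character(1), USE.NAMES = FALSE)
  genus_unc <- grepl("^[a-z]", trimws(blank_na(tbl$genus))) |
    grepl("^[a-z]", sn_first) & !grepl("^[a-z][a-z]*\\.$", sn_first)

  field_cap <- grepl("^[A-Z]", trimws(blank_na(tbl$specificEpithet))) |
    grepl("^[A-Z]", trimws(blank_na(tbl$infraspecificEpithet)))
  sn_cap <- vapply(blank_na(tbl$scientificName), function(s) {
    toks <- classify_tokens(s)$name
    length(toks) > 1 && any(grepl("^[A-Z]", toks[-1]))
  }, logical(1), USE.NAMES = FALSE)
  epi_cap <- field_cap | sn_cap

  authcap <- authorship_miscapitalized(tbl$scientificNameAuthorship)
  # authorship may be embedded in scientificName, or displaced into an
  # epithet field (and hence into the constructed name): check both
  embedded_auth <- function(x) {
    vapply(blank_na(x), function(s) {
      paste(classify_tokens(s)$authorship, collapse = " ")
    }, character(1), USE.NAMES = FALSE)
  }
  authcap <- authcap | authorship_miscapitalized(embedded_auth(tbl$scientificName))
  if ("constructedscientificname" %in% names(tbl)) {
    authcap <- authcap |
      authorship_miscapitalized(embedded_auth(tbl$constructedscientificname))
  }

  abbrev_tok <- function(x) {
    grepl("(^|[ \t])[A-Za-z]\\.([ \t]|$)", blank_na(x)) |
      grepl("(^|[ \t])(var|subvar|f)\\.([ \t]|$)", blank_na(x))
  }
  abbrev <- abbrev_tok(tbl$genus) | abbrev_tok(tbl$scientificName)

  out <- tibble::tibble(
    extra_whitespace = ws,
    genus_uncapitalized = genus_unc,
    epithet_capitalized = epi_cap,
    con_authcap = authcap,
    abbreviation_present = abbrev
  )
  out$hasFormatError <- Reduce(`|`, out)
  out
}

# ---------------------------------------------------------------------------
# Darwin Core conceptual issues

epithet_autherr <- function(x) {
  x <- blank_na(x)
  has_authorish <- grepl("[,()]|[0-9]", x)
  multi_cap <- vapply(x, function(s) {
    toks <- strsplit(squish(s), " ", fixed = TRUE)[[1]]
    length(toks) > 1 && any(grepl("^[A-Z]", toks[-1])) ||
      length(toks) >= 1 && grepl("^[A-Z]", toks[1]) && length(toks) > 1
  }, logical(1), USE.NAMES = FALSE)
  has_authorish | multi_cap
}

implied_atomic_tokens <- function(tbl) {
  is_filled(tbl$genus) + is_filled(tbl$subgenus) +
    is_filled(tbl$specificEpithet) + is_filled(tbl$infraspecificEpithet)
}

#' Detect Darwin Core conceptual issues
#'
#' Flags misuse of the standard's field semantics: identification
#' qualifiers ("sp.", "cf.", "?", ...) inside any taxon name field
#' (`qualifier_present`); author-name content inside an epithet field
#' (`con_autherr`); a binomial-only `scientificName` when an infraspecific
#' epithet is also given (`sn_inf_missing`); usage where only the
#' infraspecific epithet is populated among the atomic fields
#' (`only_infraspecific`); malformed subgenus content (`con_sgerror`); and
#' a token-count inconsistency between the constructed name and the
#' populated atomic fields (`con_rnk`). The last three implement fields
#' whose published definitions are abbreviated; the interpretations used
#' here are documented as provisional in the package vignette.
#'
#' @inheritParams detect_format_issues
#' @return tibble of logical flags plus the rollup `hasConceptualError`.
#' @export
detect_conceptual_issues <- function(tbl, config = assessment_config()) {
  n <- nrow(tbl)
  qual <- rep(FALSE, n)
  for (f in DWC_NAME_FIELDS) qual <- qual | contains_qualifier(tbl[[f]], config)

  autherr <- epithet_autherr(tbl$specificEpithet) |
    epithet_autherr(tbl$infraspecificEpithet)

  inf <- squish(blank_na(tbl$infraspecificEpithet))
  sn_inf_missing <- is_filled(tbl$scientificName) & is_filled(inf) &
    !purrr::map2_lgl(blank_na(tbl$scientificName), inf, token_seq_present)

  only_inf <- is_filled(tbl$infraspecificEpithet) &
    !is_filled(tbl$genus) & !is_filled(tbl$subgenus) &
    !is_filled(tbl$specificEpithet)

  sg <- trimws(blank_na(tbl$subgenus))
  sgerror <- nzchar(sg) &
    !grepl("^[A-Z][a-z-]+$", sg) & !grepl("^\\([A-Z][a-z-]+\\)$", sg)

  con_tokens <- vapply(tbl$constructedscientificname, function(s) {
    s <- drop_qualifiers(s, config)
    length(classify_tokens(s)$name)
  }, integer(1), USE.NAMES = FALSE)
  con_rnk <- nzchar(tbl$constructedscientificname) &
    con_tokens != implied_atomic_tokens(tbl)

  out <- tibble::tibble(
    qualifier_present = qual,
    con_autherr = autherr,
    sn_inf_missing = sn_inf_missing,
    only_infraspecific = only_inf,
    con_sgerror = sgerror,
    con_rnk = con_rnk
  )
  out$hasConceptualError <- Reduce(`|`, out)
  out
}

# ---------------------------------------------------------------------------
# Resolution

# Resolve a single normalized candidate string against the authority.
# Returns NULL when the candidate is empty/unresolvable, else a list with
# the matched entry, the accepted entry it chases to, the edit distance
# used, a corrections count (distance + 1 per abbreviation expansion) and
# an ambiguity note.
resolve_candidate <- function(norm, authority, config) {
  if (!nzchar(norm)) return(NULL)
  toks <- strsplit(norm, " ", fixed = TRUE)[[1]]

  queries <- tibble::tibble(q = norm, penalty = 0L)
  if (config$expand_abbreviated_genus && grepl("^[A-Za-z]\\.$", toks[1])) {
    initial <- toupper(substr(toks[1], 1, 1))
    genera <- authority$genera[toupper(substr(authority$genera, 1, 1)) == initial]
    if (length(genera) > 0) {
      queries <- tibble::tibble(
        q = vapply(genera, function(g) paste(c(g, toks[-1]), collapse = " "),
                   character(1), USE.NAMES = FALSE),
        penalty = 1L
      )
    }
  }

  for (i in seq_len(nrow(queries))) {
    hit <- lookup_exact(authority, queries$q[i])
    if (!is.null(hit)) {
      return(list(matched = hit,
                  accepted = resolve_accepted(authority, hit),
                  distance = 0L, corrections = queries$penalty[i],
                  ambiguous = FALSE))
    }
  }

  md <- max_dist_for(length(toks), config)
  best <- NULL
  for (i in seq_len(nrow(queries))) {
    cand <- lookup_fuzzy(authority, queries$q[i], md)
    if (nrow(cand) == 0) next
    top <- cand[1, ]
    amb <- sum(cand$distance == top$distance) > 1
    score <- top$distance + queries$penalty[i]
    if (is.null(best) || score < best$corrections) {
      best <- list(matched = top[, AUTHORITY_COLUMNS],
                   accepted = resolve_accepted(authority,
                                               top[, AUTHORITY_COLUMNS]),
                   distance = as.integer(top$distance),
                   corrections = as.integer(score),
                   ambiguous = amb)
    }
  }
  best
}

#' Resolve the two convenience name strings against an authority
#'
#' Each candidate is normalized (whitespace, case, qualifier and
#' authorship stripping, optional abbreviated-genus expansion) and then
#' matched: an exact accepted hit is valid as-is; an exact synonym hit
#' yields `isSynonym = "yes"` and the accepted name; a fuzzy hit within the
#' rank-dependent distance threshold charges `hasMisspelling` and then
#' applies the same synonym logic to the matched entry, so misspelled
#' junior synonyms set both flags. If neither candidate reaches the
#' authority, `isSynonym` is `"indeterminate"` and `validCanonical` empty.
#' When the candidates disagree, the one reaching an accepted name with
#' fewer total corrections wins, with ties going to the candidate built
#' from the atomic fields; the disagreement is logged in `comments`.
#'
#' @param constructed,scientificnameplus the two convenience strings.
#' @param authority a `taxon_authority`.
#' @param config an [assessment_config()].
#' @return list with `validCanonical`, `validSource`, `sourceURL`,
#'   `sourceDate`, `isSynonym` ("yes"/"no"/"indeterminate"),
#'   `hasMisspelling`, `edit_distance_used`, `comments`.
#' @export
resolve_name <- function(constructed, scientificnameplus, authority,
                         config = assessment_config()) {
  norm_con <- normalize_name(constructed, config)
  norm_sn <- normalize_name(scientificnameplus, config)
  res_con <- resolve_candidate(norm_con, authority, config)
  res_sn <- if (identical(norm_sn, norm_con)) res_con
            else resolve_candidate(norm_sn, authority, config)

  comments <- character()
  if (!is.null(res_con) && !is.null(res_sn) &&
      res_con$accepted$canonical != res_sn$accepted$canonical) {
    comments <- c(comments, sprintf(
      "candidates disagree: constructed -> %s (%d corrections), scientificnameplus -> %s (%d corrections)",
      res_con$accepted$canonical, res_con$corrections,
      res_sn$accepted$canonical, res_sn$corrections))
  }

  # precedence: resolved beats unresolved; then fewer corrections; then the
  # candidate derived from atomic fields (constructed)
  chosen <- if (is.null(res_con)) res_sn
            else if (is.null(res_sn)) res_con
            else if (res_sn$corrections < res_con$corrections) res_sn
            else res_con

  if (is.null(chosen)) {
    return(list(validCanonical = "", validSource = "", sourceURL = "",
                sourceDate = "", isSynonym = "indeterminate",
                hasMisspelling = FALSE, edit_distance_used = NA_real_,
                comments = paste(comments, collapse = "; ")))
  }
  if (chosen$ambiguous) {
    comments <- c(comments, "ambiguous fuzzy tie; deterministic tie-break applied")
  }
  if (chosen$distance > 0 && chosen$matched$status == "synonym") {
    comments <- c(comments, "misspelled junior synonym (two-stage resolution)")
  }
  list(
    validCanonical = chosen$accepted$canonical,
    validSource = chosen$accepted$source,
    sourceURL = chosen$accepted$sourceURL,
    sourceDate = chosen$accepted$sourceDate,
    isSynonym = if (chosen$matched$status == "synonym") "yes" else "no",
    hasMisspelling = chosen$distance > 0,
    edit_distance_used = as.numeric(chosen$distance),
    comments = paste(comments, collapse = "; ")
  )
}

#' Assess a table of name combinations
#'
#' Composes name assembly, the format and conceptual detectors, and
#' authority resolution into one assessment record per name combination.
#' Rollups follow the issue taxonomy: `hasError` is misspelling OR format
#' OR conceptual (synonymy excluded, as it is not strictly an error);
#' `hasIssue` additionally includes confirmed synonymy.
#'
#' @param names_tbl verbatim name table (see [read_name_table()]).
#' @param authority a `taxon_authority`.
#' @param config an [assessment_config()].
#' @param checked vetting-tier label carried as data
#'   (bronze/silver/gold); default "bronze".
#' @return assessment tibble with the documented column order.
#' @export
assess_table <- function(names_tbl, authority,
                         config = assessment_config(),
                         checked = "bronze") {
  tbl <- add_convenience_fields(tibble::as_tibble(names_tbl))
  fmt <- detect_format_issues(tbl, config)
  con <- detect_conceptual_issues(tbl, config)

  res <- purrr::map(seq_len(nrow(tbl)), function(i) {
    resolve_name(tbl$constructedscientificname[i], tbl$scientificnameplus[i],
                 authority, config)
  })
  res_tbl <- dplyr::bind_rows(purrr::map(res, tibble::as_tibble))
  if (nrow(tbl) == 0) {
    res_tbl <- tibble::tibble(
      validCanonical = character(), validSource = character(),
      sourceURL = character(), sourceDate = character(),
      isSynonym = character(), hasMisspelling = logical(),
      edit_distance_used = numeric(), comments = character())
  }

  out <- dplyr::bind_cols(
    tbl[, c("id", DWC_NAME_FIELDS, "constructedscientificname",
            "scientificnameplus", "dwcsn_rank", "sn_rank", "con_rank")],
    tibble::tibble(
      hasMisspelling = res_tbl$hasMisspelling,
      hasFormatError = fmt$hasFormatError,
      hasConceptualError = con$hasConceptualError,
      isSynonym = res_tbl$isSynonym
    ),
    fmt[, c("con_authcap", "extra_whitespace", "epithet_capitalized",
            "genus_uncapitalized", "abbreviation_present")],
    con[, c("con_autherr", "sn_inf_missing", "con_sgerror", "con_rnk",
            "qualifier_present", "only_infraspecific")],
    res_tbl[, c("edit_distance_used", "validCanonical", "validSource",
                "sourceURL", "sourceDate", "comments")]
  )
  out$hasError <- out$hasMisspelling | out$hasFormatError | out$hasConceptualError
  out$hasIssue <- out$hasError | out$isSynonym == "yes"
  out$checked <- if (nrow(out) > 0) checked else character()
  out[, ASSESSMENT_COLUMNS]
}
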