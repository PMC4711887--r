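# Construction of the two convenience name strings and taxon-rank
# assignment. The convenience strings give resolvers two complementary
# views of a record: one rebuilt from the atomic fields
# (constructedscientificname) and one anchored on the composite
# scientificName field (scientificnameplus).

RANK_LEVELS <- c("none", "higher", "genus", "subgenus", "species",
                 "infraspecific", "indeterminate")

#' Build the constructed scientific name
#'
#' Space-separated concatenation of the verbatim `genus`, `subgenus`,
#' `specificEpithet`, `infraspecificEpithet` and `scientificNameAuthorship`
#' fields, skipping empty fields. When the only populated field among the
#' five is `infraspecificEpithet` the result is blank: that pattern signals
#' a provider convention in which the full name lives in `scientificName`
#' and is handled through [build_scientificname_plus()] instead.
#'
#' The subgenus is concatenated verbatim, without adding parentheses; a
#' malformed subgenus is flagged downstream (`con_sgerror`), never altered
#' here. The output never carries leading/trailing or doubled spaces, even
#' when the verbatim fields do.
#'
#' @param record one-row list/tibble with the six verbatim fields (vectors
#'   are accepted; all arguments are recycled together).
#' @return character vector of constructed names.
#' @export
#' @examples
#' build_constructed_name(list(genus = "Parus", subgenus = "",
#'   specificEpithet = "major", infraspecificEpithet = "",
#'   scientificNameAuthorship = "Linnaeus, 1758"))
build_constructed_name <- function(record) {
  parts <- lapply(
    c("genus", "subgenus", "specificEpithet", "infraspecificEpithet",
      "scientificNameAuthorship"),
    function(f) blank_na(record[[f]])
  )
  mat <- do.call(cbind, lapply(parts, function(p) p))
  out <- apply(mat, 1L, function(row) {
    keep <- is_filled(row)
    if (!any(keep)) return("")
    # only-infraspecific condition: the 4th input alone is populated
    if (identical(which(keep), 4L)) return("")
    squish(paste(row[keep], collapse = " "))
  })
  as.character(out)
}

#' Build scientificnameplus
#'
#' If both `scientificName` and `infraspecificEpithet` are populated and
#' the scientificName does not already contain the infraspecific epithet,
#' the two are concatenated with a space; otherwise `scientificName` is
#' returned unchanged. "Contains" is a case-sensitive whole-token test on
#' the space-split scientificName (a substring test would wrongly suppress
#' epithets that prefix other tokens).
#'
#' @inheritParams build_constructed_name
#' @return character vector, never shorter than `scientificName`.
#' @export
build_scientificname_plus <- function(record) {
  sn <- blank_na(record[["scientificName"]])
  inf <- blank_na(record[["infraspecificEpithet"]])
  inf_trim <- squish(inf)
  needs <- is_filled(sn) & is_filled(inf) &
    !purrr::map2_lgl(sn, inf_trim, token_seq_present)
  ifelse(needs, paste(sn, inf_trim), sn)
}

# Case-sensitive whole-token membership: every token of `needle` appears
# as a contiguous run in the space-split `haystack`. Reduces to plain
# token membership for the common one-word epithet.
token_seq_present <- function(haystack, needle) {
  h <- strsplit(squish(haystack), " ", fixed = TRUE)[[1]]
  n <- strsplit(squish(needle), " ", fixed = TRUE)[[1]]
  if (length(n) == 0) return(TRUE)
  if (length(n) > length(h)) return(FALSE)
  for (start in seq_len(length(h) - length(n) + 1)) {
    if (all(h[start + seq_along(n) - 1] == n)) return(TRUE)
  }
  FALSE
}

year_token <- function(tok) grepl("^\\(?[0-9]{4}\\)?[.,]?$", tok)
subgenus_token <- function(tok) grepl("^\\([A-Z][A-Za-z-]+\\)$", tok)
capitalized_token <- function(tok) grepl("^[A-Z]", tok)
lower_epithet_token <- function(tok) grepl("^[a-z][a-z-]*$", tok)

# Classify the tokens of a name string into name tokens, a subgenus token,
# and authorship-like tokens. A token is authorship-like if it is a 4-digit
# year, starts with "(", contains ",", or is a capitalized token appearing
# after at least two lowercase epithet tokens; a conservative, auditable
# heuristic whose misfires surface as rank = indeterminate downstream,
# never as silent corruption. Everything from the first authorship-like
# token onward is treated as authorship.
classify_tokens <- function(name) {
  toks <- strsplit(squish(name), " ", fixed = TRUE)[[1]]
  n <- length(toks)
  if (n == 0 || !nzchar(toks[1])) {
    return(list(name = character(), subgenus = character(),
                authorship = character()))
  }
  subg <- character()
  if (n >= 2 && subgenus_token(toks[2])) {
    subg <- toks[2]
    toks <- toks[-2]
    n <- n - 1
  }
  lower_seen <- cumsum(lower_epithet_token(toks))
  auth_like <- year_token(toks) |
    startsWith(toks, "(") |
    grepl(",", toks, fixed = TRUE) |
    (capitalized_token(toks) & dplyr::lag(lower_seen, default = 0) >= 2 &
       seq_along(toks) > 1)
  first_auth <- if (any(auth_like)) which(auth_like)[1] else n + 1
  list(
    name = toks[seq_len(first_auth - 1)],
    subgenus = subg,
    authorship = if (first_auth <= n) toks[first_auth:n] else character()
  )
}

infer_rank_one <- function(name) {
  parts <- classify_tokens(name)
  toks <- parts$name
  k <- length(toks)
  if (k == 0) {
    return(if (length(parts$subgenus) > 0) "subgenus" else "none")
  }
  if (!capitalized_token(toks[1]) && !lower_epithet_token(toks[1])) {
    return("indeterminate")
  }
  epithets <- toks[-1]
  if (k > 1 && !all(lower_epithet_token(epithets))) return("indeterminate")
  if (k == 1) {
    if (length(parts$subgenus) > 0) return("subgenus")
    return("genus")
  }
  if (k == 2) return("species")
  if (k == 3) return("infraspecific")
  if (k >= 4) return("indeterminate")
  "indeterminate"
}

#' Infer the terminal taxon rank of a name string
#'
#' Counts the non-authorship tokens of a name: 0 tokens is `none`, one
#' capitalized token `genus`, two `species`, three `infraspecific`; a
#' parenthesized capitalized second token is recognized as a subgenus.
#' Authorship tokens (years, parenthesized spans, tokens with commas,
#' capitalized surnames following two lowercase epithets) are excluded
#' before counting. Unclassifiable mixtures return `indeterminate`.
#'
#' @param name character vector of name strings.
#' @return character vector over
#'   `c("none","higher","genus","subgenus","species","infraspecific","indeterminate")`.
#' @export
#' @examples
#' infer_rank("Parus major Linnaeus, 1758")  # "species"
infer_rank <- function(name) {
  vapply(blank_na(name), infer_rank_one, character(1), USE.NAMES = FALSE)
}

#' Attach convenience fields to a name table
#'
#' Adds `constructedscientificname`, `scientificnameplus` and the three
#' rank determinations (`dwcsn_rank`, `sn_rank`, `con_rank`) to a verbatim
#' name table from [read_name_table()].
#'
#' @param names_tbl tibble with the six verbatim fields.
#' @return the input with the five convenience columns appended.
#' @export
add_convenience_fields <- function(names_tbl) {
  names_tbl$constructedscientificname <- build_constructed_name(names_tbl)
  names_tbl$scientificnameplus <- build_scientificname_plus(names_tbl)
  names_tbl$dwcsn_rank <- infer_rank(names_tbl$scientificName)
  names_tbl$sn_rank <- infer_rank(names_tbl$scientificnameplus)
  names_tbl$con_rank <- infer_rank(names_tbl$constructedscientificname)
  names_tbl
}
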