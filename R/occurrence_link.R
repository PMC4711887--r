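# Linking name combinations to occurrence records via the six-field
# verbatim key, and standardizing the modelling covariates.

KEY_SEP <- "\x1F"  # ASCII unit separator: non-printing, unreachable in real data

REGIONS <- c("Africa", "Asia", "Australasia", "Europe", "North America",
             "Oceania", "South America")
CLADES <- c("Amphibia", "Aves", "Mammalia", "Reptilia", "Fishes")
FISH_CLASSES <- c("Actinopterygii", "Cephalaspidomorphi", "Conodonta",
                  "Elasmobranchii", "Holocephali", "Myxini", "Placodermi",
                  "Sarcopterygii")
BASIS_VOCABULARY <- c("PreservedSpecimen", "FossilSpecimen",
                      "HumanObservation", "MachineObservation",
                      "LivingSpecimen", "MaterialSample", "Occurrence",
                      "MaterialCitation")
BASIS_RETAINED <- c("PreservedSpecimen", "FossilSpecimen")

#' Build the six-field taxon name key
#'
#' Deterministic concatenation of the six verbatim taxon fields with a
#' non-printing unit-separator delimiter, so equal field tuples give equal
#' keys and nothing else does. The join is case-sensitive on verbatim
#' bytes.
#'
#' @param record tibble/list with the six verbatim fields (vectorized).
#' @return character vector of keys.
#' @export
make_name_key <- function(record) {
  fields <- lapply(DWC_NAME_FIELDS, function(f) blank_na(record[[f]]))
  if (any(vapply(fields, function(x) any(grepl(KEY_SEP, x, fixed = TRUE)),
                 logical(1)))) {
    tv_abort("a verbatim field contains the reserved key separator (unit separator, 0x1F)",
             class = "taxonvet_key_error")
  }
  do.call(paste, c(fields, sep = KEY_SEP))
}

#' Link assessed names to occurrence records
#'
#' Inner join between the six-field taxon name keys of the two tables.
#' Unmatched occurrences and unmatched names are reported separately, and
#' a per-name matching-occurrence count (zero included) is attached.
#' Duplicate identical occurrences are each counted; no deduplication
#' happens at the join.
#'
#' @param names_tbl name or assessment table carrying `id` and the six
#'   verbatim fields.
#' @param occurrences occurrence table from [read_occurrence_table()].
#' @return list with `matched` (occurrence rows plus the matching name
#'   `id`), `name_counts` (`id`, `n_occurrences`), `unmatched_names` and
#'   `unmatched_occurrences` (ids).
#' @export
link_occurrences <- function(names_tbl, occurrences) {
  nk <- tibble::tibble(id = names_tbl$id, .key = make_name_key(names_tbl))
  ok <- tibble::add_column(tibble::as_tibble(occurrences),
                           .key = make_name_key(occurrences))
  matched <- dplyr::inner_join(ok, nk, by = ".key",
                               relationship = "many-to-many")
  counts <- dplyr::left_join(
    tibble::tibble(id = names_tbl$id),
    dplyr::count(matched, .data$id, name = "n_occurrences"),
    by = "id"
  )
  counts$n_occurrences[is.na(counts$n_occurrences)] <- 0L
  list(
    matched = dplyr::select(matched, -".key"),
    name_counts = counts,
    unmatched_names = counts$id[counts$n_occurrences == 0],
    unmatched_occurrences = ok$occurrenceID[!(ok$.key %in% nk$.key)]
  )
}

#' Default country/continent to region mapping
#'
#' The editable mapping table shipped with the package, assigning
#' countries to the seven analysis regions. Continent values matching a
#' region name directly are also accepted by
#' [standardize_covariates()]. Marine localities without a country are not
#' covered and fall out as region exclusions.
#'
#' @return tibble with columns `country`, `region`.
#' @export
default_region_map <- function() {
  path <- system.file("extdata", "country_region_map.tsv",
                      package = "taxonvet", mustWork = TRUE)
  readr::read_tsv(path, col_types = "cc", progress = FALSE)
}

normalize_basis <- function(x) {
  key <- gsub("[^a-z]", "", tolower(blank_na(x)))
  BASIS_VOCABULARY[match(key, gsub("[^a-z]", "", tolower(BASIS_VOCABULARY)))]
}

#' Standardize occurrence covariates for modelling
#'
#' Maps `basisOfRecord` to the Darwin Core controlled vocabulary and
#' retains only FossilSpecimen and PreservedSpecimen records; derives the
#' analysis region from country (via the bundled mapping) or continent,
#' excluding Antarctica; parses 4-digit collection years inside the
#' plausibility bounds; maps `class` to the five clades (all fish classes
#' grouped as "Fishes"); and attaches the institutional digital record
#' count. Records failing any step are excluded, never coerced, and each
#' exclusion carries exactly one primary machine-readable reason, applied
#' in the order basisOfRecord, region, year, clade.
#'
#' @param occurrences occurrence table.
#' @param institution_counts optional named vector or two-column table
#'   (`institutionCode`, `n_records`) of digitally accessible record
#'   counts per institution; by default counted from `occurrences` itself.
#' @param region_map country-to-region table; defaults to the bundled one.
#' @param year_min,year_max plausible collection-year bounds.
#' @return list with `covariates` (tibble: `occurrenceID`,
#'   `basisOfRecord`, `region`, `clade`, `year`, `institutionCode`,
#'   `institutionRecords`) and `exclusions` (tibble: `occurrenceID`,
#'   `reason`).
#' @export
standardize_covariates <- function(occurrences, institution_counts = NULL,
                                   region_map = default_region_map(),
                                   year_min = 1700,
                                   year_max = as.integer(format(Sys.Date(), "%Y"))) {
  occ <- tibble::as_tibble(occurrences)
  n <- nrow(occ)

  basis <- normalize_basis(occ$basisOfRecord)
  basis_ok <- !is.na(basis) & basis %in% BASIS_RETAINED

  country <- squish(blank_na(occ$country))
  continent <- squish(blank_na(occ$continent))
  region <- region_map$region[match(tolower(country),
                                    tolower(region_map$country))]
  cont_hit <- match(tolower(continent), tolower(c(REGIONS, "Antarctica")))
  region <- ifelse(is.na(region),
                   c(REGIONS, "Antarctica")[cont_hit], region)
  region_ok <- !is.na(region) & region %in% REGIONS

  year_txt <- trimws(blank_na(occ$year))
  year <- suppressWarnings(as.integer(ifelse(grepl("^[0-9]{4}$", year_txt),
                                             year_txt, NA)))
  year_ok <- !is.na(year) & year >= year_min & year <= year_max

  cls <- squish(blank_na(occ$class))
  clade <- ifelse(tolower(cls) %in% tolower(setdiff(CLADES, "Fishes")),
                  cap_first(cls),
                  ifelse(tolower(cls) %in% tolower(FISH_CLASSES),
                         "Fishes", NA))
  clade_ok <- !is.na(clade)

  reason <- rep(NA_character_, n)
  reason[!basis_ok] <- "basisOfRecord"
  reason[is.na(reason) & !region_ok] <- "region"
  reason[is.na(reason) & !year_ok] <- "year"
  reason[is.na(reason) & !clade_ok] <- "clade"
  keep <- is.na(reason)

  if (is.null(institution_counts)) {
    tab <- table(occ$institutionCode)
    institution_counts <- setNames(as.integer(tab), names(tab))
  } else if (is.data.frame(institution_counts)) {
    institution_counts <- setNames(institution_counts$n_records,
                                   institution_counts$institutionCode)
  }
  inst <- blank_na(occ$institutionCode)
  missing_inst <- setdiff(unique(inst[keep]), names(institution_counts))
  if (length(missing_inst) > 0) {
    tv_abort(
      sprintf("no institution record count for: %s",
              paste(missing_inst, collapse = ", ")),
      class = "taxonvet_covariate_error"
    )
  }

  list(
    covariates = tibble::tibble(
      occurrenceID = occ$occurrenceID[keep],
      basisOfRecord = basis[keep],
      region = region[keep],
      clade = clade[keep],
      year = year[keep],
      institutionCode = inst[keep],
      institutionRecords = as.integer(institution_counts[inst[keep]])
    ),
    exclusions = tibble::tibble(
      occurrenceID = occ$occurrenceID[!keep],
      reason = reason[!keep]
    )
  )
}
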