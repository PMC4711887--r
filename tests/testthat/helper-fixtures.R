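# In-code fixtures shared across test files.

# A small hand-built authority: two accepted tits, one junior synonym
# (the pre-2005 placement of the blue tit in Parus), a wagtail with an
# infraspecific form.
tiny_authority <- function() {
  new_authority(tibble::tibble(
    canonical = c("Parus major", "Cyanistes caeruleus", "Parus caeruleus",
                  "Motacilla alba", "Motacilla alba yarrellii"),
    rank = c("species", "species", "species", "species", "infraspecific"),
    status = c("accepted", "accepted", "synonym", "accepted", "accepted"),
    acceptedCanonical = c("Parus major", "Cyanistes caeruleus",
                          "Cyanistes caeruleus", "Motacilla alba",
                          "Motacilla alba yarrellii"),
    source = "Test Checklist",
    sourceURL = "https://example.org/test",
    sourceDate = "2015-01-01"
  ))
}

# One verbatim name record with defaults, as a one-row tibble.
name_row <- function(id = "n1", scientificName = "", genus = "",
                     subgenus = "", specificEpithet = "",
                     infraspecificEpithet = "",
                     scientificNameAuthorship = "") {
  tibble::tibble(id = id, scientificName = scientificName, genus = genus,
                 subgenus = subgenus, specificEpithet = specificEpithet,
                 infraspecificEpithet = infraspecificEpithet,
                 scientificNameAuthorship = scientificNameAuthorship)
}

# Minimal assessment tibble carrying only the columns the summary
# functions consume.
flag_assessments <- function(misspelling = logical(), format = logical(),
                             conceptual = logical(),
                             synonym = character(),
                             valid = NULL) {
  n <- max(length(misspelling), length(format), length(conceptual),
           length(synonym))
  misspelling <- rep_len(misspelling, n)
  format <- rep_len(format, n)
  conceptual <- rep_len(conceptual, n)
  synonym <- rep_len(synonym, n)
  if (is.null(valid)) valid <- rep("Somename validus", n)
  has_error <- misspelling | format | conceptual
  tibble::tibble(
    id = sprintf("r%03d", seq_len(n)),
    hasMisspelling = misspelling,
    hasFormatError = format,
    hasConceptualError = conceptual,
    isSynonym = synonym,
    hasError = has_error,
    hasIssue = has_error | synonym == "yes",
    validCanonical = valid
  )
}

# A small cached bundle (generated once per test run) for cross-module
# tests that do not need the full study-scale corpus.
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(generator_config(seed = 101, n_names = 250))
    }
    cache
  }
})

random_covariates <- function(n) {
  tibble::tibble(
    basisOfRecord = sample(c("PreservedSpecimen", "FossilSpecimen"), n,
                           replace = TRUE, prob = c(0.8, 0.2)),
    region = sample(c("North America", "Europe", "South America", "Asia",
                      "Africa", "Australasia", "Oceania"), n, replace = TRUE,
                    prob = c(0.5, 0.15, 0.1, 0.1, 0.05, 0.05, 0.05)),
    clade = sample(c("Aves", "Fishes", "Mammalia", "Amphibia", "Reptilia"),
                   n, replace = TRUE, prob = c(0.35, 0.3, 0.15, 0.1, 0.1)),
    year = sample(1850:2015, n, replace = TRUE),
    institutionRecords = pmax(1L, as.integer(round(exp(rnorm(n, 8, 1.5)))))
  )
}
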