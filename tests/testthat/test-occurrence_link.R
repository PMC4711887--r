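# Name keys, the six-field join, covariate standardization.

test_that("name keys are injective on the six verbatim fields", {
  r1 <- name_row(genus = "Parus", specificEpithet = "major")
  r2 <- name_row(genus = "Parus", specificEpithet = "major")
  expect_identical(make_name_key(r1), make_name_key(r2))

  r3 <- name_row(genus = "Parus", specificEpithet = "major",
                 scientificNameAuthorship = "Linnaeus, 1758")
  expect_false(make_name_key(r1) == make_name_key(r3))

  empty_key <- make_name_key(name_row())
  expect_identical(empty_key, strrep("\x1F", 5))

  bad <- name_row(genus = paste0("Pa", "\x1F", "rus"))
  expect_error(make_name_key(bad), class = "taxonvet_key_error")
})

test_that("linking matches the nested-loop join oracle", {
  set.seed(77)
  b <- small_bundle()
  nm <- b$names[sample(nrow(b$names), 40), ]
  occ <- b$occurrences[sample(nrow(b$occurrences), 120), ]
  lk <- link_occurrences(nm, occ)
  oracle <- join_oracle(nm, occ)
  got <- paste(lk$matched$occurrenceID, lk$matched$id)
  want <- paste(oracle$occ, oracle$id)
  expect_setequal(got, want)
  expect_equal(sum(lk$name_counts$n_occurrences), nrow(lk$matched))
  expect_setequal(lk$unmatched_occurrences,
                  setdiff(occ$occurrenceID, oracle$occ))
})

test_that("empty occurrence sets and duplicate occurrences behave per contract", {
  nm <- dplyr::bind_rows(name_row("x1", genus = "Parus",
                                  specificEpithet = "major"),
                         name_row("x2", genus = "Parus",
                                  specificEpithet = "ater"))
  occ0 <- tibble::tibble(occurrenceID = character(),
                         scientificName = character(), genus = character(),
                         subgenus = character(), specificEpithet = character(),
                         infraspecificEpithet = character(),
                         scientificNameAuthorship = character())
  lk <- link_occurrences(nm, occ0)
  expect_identical(lk$name_counts$n_occurrences, c(0L, 0L))

  occ2 <- dplyr::bind_cols(
    tibble::tibble(occurrenceID = c("o1", "o2")),
    dplyr::bind_rows(name_row(genus = "Parus", specificEpithet = "major"),
                     name_row(genus = "Parus",
                              specificEpithet = "major"))[, -1]
  )
  lk <- link_occurrences(nm, occ2)  # identical occurrences each counted
  expect_identical(
    lk$name_counts$n_occurrences[lk$name_counts$id == "x1"], 2L)
})

test_that("covariate standardization filters and maps per the documented rules", {
  occ <- tibble::tibble(
    occurrenceID = sprintf("o%d", 1:7),
    basisOfRecord = c("HumanObservation", "preserved_specimen",
                      "PRESERVED_SPECIMEN", "FossilSpecimen",
                      "PreservedSpecimen", "PreservedSpecimen",
                      "PreservedSpecimen"),
    country = c("Spain", "Spain", "", "United States", "Brazil", "Spain",
                "Spain"),
    continent = c("", "", "Antarctica", "", "", "", ""),
    year = c("1950", "1950", "1950", "1950", "19xx", "1950", "2150"),
    class = c("Aves", "Elasmobranchii", "Aves", "Mammalia", "Aves",
              "Notaclass", "Aves"),
    institutionCode = "MVZ"
  )
  std <- standardize_covariates(occ)
  expect_identical(std$covariates$occurrenceID, c("o2", "o4"))
  expect_identical(std$covariates$clade, c("Fishes", "Mammalia"))
  expect_identical(std$covariates$region, c("Europe", "North America"))
  # one primary reason each, in documented precedence order
  expect_identical(
    std$exclusions$reason[match(c("o1", "o3", "o5", "o6", "o7"),
                                std$exclusions$occurrenceID)],
    c("basisOfRecord", "region", "year", "clade", "year"))
  expect_equal(nrow(std$covariates) + nrow(std$exclusions), nrow(occ))

  # institution counts default to the supplied table's own tallies
  expect_identical(unique(std$covariates$institutionRecords), 7L)
  # an explicit mapping must cover every institution
  expect_error(
    standardize_covariates(occ, institution_counts = c(OTHER = 10L)),
    class = "taxonvet_covariate_error")
})
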