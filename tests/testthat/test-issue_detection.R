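# Detectors, resolution and the composed assessment.

prep <- function(row) add_convenience_fields(row)

test_that("format detector flags whitespace, case and authorship problems", {
  f <- detect_format_issues(prep(name_row(scientificName = "Parus  major")))
  expect_true(f$extra_whitespace)
  expect_true(f$hasFormatError)

  f <- detect_format_issues(prep(name_row(scientificName = "parus Major")))
  expect_true(f$genus_uncapitalized)
  expect_true(f$epithet_capitalized)

  f <- detect_format_issues(prep(name_row(
    genus = "Parus", specificEpithet = "major",
    scientificNameAuthorship = "linnaeus, 1758")))
  expect_true(f$con_authcap)

  f <- detect_format_issues(prep(name_row(scientificName = "P. major")))
  expect_true(f$abbreviation_present)

  clean <- detect_format_issues(prep(name_row(
    scientificName = "Parus major", genus = "Parus",
    specificEpithet = "major", scientificNameAuthorship = "Linnaeus, 1758")))
  expect_false(clean$hasFormatError)
})

test_that("conceptual detector flags qualifiers, displaced authorship and field misuse", {
  d <- detect_conceptual_issues(prep(name_row(scientificName = "Parus sp.")))
  expect_true(d$qualifier_present)

  d <- detect_conceptual_issues(prep(name_row(
    genus = "Parus", specificEpithet = "major Linnaeus")))
  expect_true(d$con_autherr)

  d <- detect_conceptual_issues(prep(name_row(
    scientificName = "Motacilla alba", infraspecificEpithet = "yarrellii")))
  expect_true(d$sn_inf_missing)
  expect_true(d$hasConceptualError)

  d <- detect_conceptual_issues(prep(name_row(infraspecificEpithet = "alba")))
  expect_true(d$only_infraspecific)

  d <- detect_conceptual_issues(prep(name_row(
    genus = "Parus", subgenus = "parus!!", specificEpithet = "major")))
  expect_true(d$con_sgerror)

  clean <- detect_conceptual_issues(prep(name_row(
    scientificName = "Motacilla alba yarrellii", genus = "Motacilla",
    specificEpithet = "alba", infraspecificEpithet = "yarrellii")))
  expect_false(clean$hasConceptualError)
})

test_that("resolution handles exact, synonym, fuzzy and unresolvable names", {
  auth <- tiny_authority()

  r <- resolve_name("Cyanistes caeruleus", "Cyanistes caeruleus", auth)
  expect_identical(r$validCanonical, "Cyanistes caeruleus")
  expect_identical(r$isSynonym, "no")
  expect_false(r$hasMisspelling)

  r <- resolve_name("Parus caeruleus", "", auth)
  expect_identical(r$isSynonym, "yes")
  expect_identical(r$validCanonical, "Cyanistes caeruleus")

  # misspelled junior synonym: both flags, two-stage resolution
  r <- resolve_name("Parus caerulues", "", auth)
  expect_true(r$hasMisspelling)
  expect_identical(r$isSynonym, "yes")
  expect_identical(r$validCanonical, "Cyanistes caeruleus")

  r <- resolve_name("Zzzzz qqqqq", "Zzzzz qqqqq", auth)
  expect_identical(r$validCanonical, "")
  expect_identical(r$isSynonym, "indeterminate")
})

test_that("authorship and qualifiers are stripped before matching", {
  auth <- tiny_authority()
  r <- resolve_name("Parus major Linnaeus, 1758", "", auth)
  expect_identical(r$validCanonical, "Parus major")
  expect_false(r$hasMisspelling)

  r <- resolve_name("Parus cf. major", "", auth)
  expect_identical(r$validCanonical, "Parus major")

  # capitalization is charged to the format detector, not the distance
  r <- resolve_name("parus Major", "", auth)
  expect_identical(r$validCanonical, "Parus major")
  expect_false(r$hasMisspelling)
})

test_that("abbreviated genus expansion resolves against the authority", {
  auth <- tiny_authority()
  r <- resolve_name("M. alba", "", auth)
  expect_identical(r$validCanonical, "Motacilla alba")
})

test_that("assessment composes detectors and sets consistent rollups", {
  auth <- tiny_authority()
  tbl <- dplyr::bind_rows(
    name_row("c1", genus = "Parus", specificEpithet = "major",
             scientificNameAuthorship = "Linnaeus, 1758"),
    name_row("c2", scientificName = "Parus  caeruleus"),  # whitespace + synonym
    name_row("c3", scientificName = "Wqzkv pphtx")        # gibberish
  )
  a <- assess_table(tbl, auth)
  expect_false(a$hasIssue[1])
  expect_identical(a$validCanonical[1], "Parus major")

  expect_true(a$hasFormatError[2])
  expect_identical(a$isSynonym[2], "yes")
  expect_true(a$hasIssue[2] && a$hasError[2])

  expect_identical(a$validCanonical[3], "")
  expect_identical(a$isSynonym[3], "indeterminate")
})

test_that("rollup invariants hold across the synthetic corpus", {
  b <- small_bundle()
  a <- assess_table(b$names, b$authority)
  expect_identical(a$hasIssue,
                   a$hasMisspelling | a$hasFormatError | a$hasConceptualError |
                     a$isSynonym == "yes")
  expect_identical(a$hasError,
                   a$hasMisspelling | a$hasFormatError | a$hasConceptualError)
  expect_true(all(a$hasIssue[a$hasError]))
  # synonymy alone is an issue but not an error
  syn_only <- a$isSynonym == "yes" & !a$hasError
  expect_true(all(a$hasIssue[syn_only]))
  # resolution failed on both candidates <=> no valid canonical
  expect_identical(!nzchar(a$validCanonical), a$isSynonym == "indeterminate")
})

test_that("assessing an already-normalized resolved output yields no flags", {
  b <- small_bundle()
  a <- assess_table(head(b$names, 60), b$authority)
  resolved <- a[nzchar(a$validCanonical), ]
  toks <- strsplit(resolved$validCanonical, " ", fixed = TRUE)
  rebuilt <- tibble::tibble(
    id = resolved$id,
    scientificName = resolved$validCanonical,
    genus = vapply(toks, `[`, "", 1),
    subgenus = "",
    specificEpithet = vapply(toks, function(t) {
      if (length(t) >= 2) t[2] else ""
    }, ""),
    infraspecificEpithet = vapply(toks, function(t) {
      if (length(t) >= 3) t[3] else ""
    }, ""),
    scientificNameAuthorship = ""
  )
  a2 <- assess_table(rebuilt, b$authority)
  expect_false(any(a2$hasIssue))
  expect_identical(a2$validCanonical, resolved$validCanonical)
})
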