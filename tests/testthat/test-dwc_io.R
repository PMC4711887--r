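# IO: verbatim round trips, header mapping, structured errors.

test_that("name tables round-trip verbatim, including messy whitespace", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "id\tscientificName\tgenus\tsubgenus\tspecificEpithet\tinfraspecificEpithet\tscientificNameAuthorship",
    "a1\t Parus  major \tParus\t\tmajor\t\tLinnaeus, 1758",
    "a2\tparus major\t parus \t\tmajor\t\t"
  ), path)
  tbl <- read_name_table(path)
  expect_equal(nrow(tbl), 2)
  expect_identical(tbl$scientificName[1], " Parus  major ")  # byte-for-byte
  expect_identical(tbl$genus[2], " parus ")
  expect_identical(tbl$id, c("a1", "a2"))
})

test_that("headers map case-insensitively and extras pass through", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,ScientificName,GENUS,notes",
               "x1,Parus major,Parus,keep me"), path)
  tbl <- read_name_table(path)
  expect_identical(tbl$scientificName, "Parus major")
  expect_identical(tbl$genus, "Parus")
  expect_identical(tbl$notes, "keep me")
  expect_identical(tbl$subgenus, "")  # absent column filled empty
})

test_that("unrecognizable or missing headers and duplicate ids error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("w,x,y", "1,2,3"), path)
  expect_error(read_name_table(path), class = "taxonvet_parse_error")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,scientificName", "a,Parus major", "a,Parus palustris"),
             path2)
  expect_error(read_name_table(path2), regexp = "duplicate.*a",
               class = "taxonvet_parse_error")
})

test_that("occurrence tables read, tolerate empty data, reject ragged rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("occurrenceID", "scientificName", "genus", "subgenus",
                 "specificEpithet", "infraspecificEpithet",
                 "scientificNameAuthorship", "basisOfRecord", "country",
                 "continent", "year", "class", "institutionCode"),
               collapse = "\t")
  rows <- vapply(1:3, function(i) {
    paste(c(sprintf("o%d", i), "Parus major", "Parus", "", "major", "", "",
            "PreservedSpecimen", "Spain", "", "1950", "Aves", "MVZ"),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  occ <- read_occurrence_table(path)
  expect_equal(nrow(occ), 3)
  expect_identical(occ$occurrenceID, c("o1", "o2", "o3"))

  writeLines(hdr, path)
  expect_equal(nrow(read_occurrence_table(path)), 0)

  writeLines(c(hdr, "o1\tonly-two-cells"), path)
  expect_error(read_occurrence_table(path), regexp = "row",
               class = "taxonvet_parse_error")
})

test_that("files that are not valid UTF-8 are a hard error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  con <- file(path, "wb")
  writeBin(c(charToRaw("id\tscientificName\n1\tParus ma"), as.raw(0xE9),
             charToRaw("or\n")), con)
  close(con)
  expect_error(read_name_table(path), class = "taxonvet_encoding_error")
})

test_that("assessment tables round-trip exactly, embedded delimiters included", {
  b <- small_bundle()
  a <- assess_table(head(b$names, 12), b$authority)
  a$comments[1] <- "tab\there; quote \" and, comma"
  path <- withr::local_tempfile(fileext = ".tsv")
  write_assessment_table(a, path)
  back <- read_assessment_table(path)
  expect_equal(as.data.frame(back), as.data.frame(a))

  # empty collection -> header-only file
  write_assessment_table(a[0, ], path)
  expect_equal(length(readLines(path)), 1)
  expect_equal(nrow(read_assessment_table(path)), 0)
})

test_that("assessment column order is frozen", {
  b <- small_bundle()
  a <- assess_table(head(b$names, 1), b$authority)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_assessment_table(a, path)
  golden <- paste(sprintf('"%s"',
    c("id", "scientificName", "genus", "subgenus", "specificEpithet",
      "infraspecificEpithet", "scientificNameAuthorship",
      "constructedscientificname", "scientificnameplus",
      "dwcsn_rank", "sn_rank", "con_rank",
      "hasMisspelling", "hasFormatError", "hasConceptualError", "isSynonym",
      "hasIssue", "hasError",
      "con_authcap", "con_autherr", "sn_inf_missing", "con_sgerror",
      "con_rnk", "extra_whitespace", "epithet_capitalized",
      "genus_uncapitalized", "abbreviation_present", "qualifier_present",
      "only_infraspecific", "edit_distance_used",
      "validCanonical", "validSource", "sourceURL", "sourceDate",
      "comments", "checked")),
    collapse = "\t")
  expect_identical(readLines(path)[1], golden)
})
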