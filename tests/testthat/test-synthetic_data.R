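# Generator: determinism, configured rates, truth-consistency.

test_that("authority shape follows the configuration", {
  set.seed(1)
  cfg <- generator_config(seed = 1, n_genera = 10, species_per_genus = 5,
                          subspecies_rate = 0, synonym_rate = 0)
  gen <- generate_authority(cfg)
  expect_equal(sum(gen$authority$entries$status == "accepted"), 50)
  expect_equal(sum(gen$authority$entries$status == "synonym"), 0)

  set.seed(2)
  cfg2 <- generator_config(seed = 2, synonym_rate = 0.5)
  gen2 <- generate_authority(cfg2)
  ent <- gen2$authority$entries
  expect_gt(sum(ent$status == "synonym"), 0)
  # closure by construction: every synonym target is an accepted entry
  expect_true(all(ent$acceptedCanonical[ent$status == "synonym"] %in%
                    ent$canonical[ent$status == "accepted"]))
  # and the table survives a write/load cycle with its invariant checks
  path <- withr::local_tempfile(fileext = ".tsv")
  write_authority(gen2$authority, path)
  expect_s3_class(load_authority(path), "taxon_authority")
})

test_that("generated names are mutually well-separated", {
  b <- small_bundle()
  canon <- b$authority$entries$canonical
  sep <- b$config$min_separation
  for (i in seq_along(canon)) {
    d <- edit_distance(canon[-i], canon[i])
    expect_true(all(d >= sep), label = sprintf("separation around %s", canon[i]))
  }
})

test_that("the bundle is a deterministic function of the seed", {
  b1 <- generate_dataset(generator_config(seed = 33, n_names = 40))
  b2 <- generate_dataset(generator_config(seed = 33, n_names = 40))
  expect_identical(b1$names, b2$names)
  expect_identical(b1$occurrences, b2$occurrences)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$authority$entries, b2$authority$entries)

  b3 <- generate_dataset(generator_config(seed = 34, n_names = 40))
  expect_false(identical(b1$names, b3$names))
})

test_that("corrupting with no issues reconstructs the clean name verbatim", {
  b <- small_bundle()
  clean <- b$truth[!b$truth$has_misspelling & !b$truth$has_format &
                     !b$truth$has_conceptual & !b$truth$has_synonym, ]
  recs <- b$names[match(clean$id, b$names$id), ]
  rebuilt <- ifelse(nzchar(recs$genus),
                    build_constructed_name(recs),
                    build_scientificname_plus(recs))
  rebuilt <- normalize_name(rebuilt)
  expect_identical(rebuilt, clean$clean_canonical)
})

test_that("injected misspellings sit at the labelled edit distance from the source", {
  b <- small_bundle()
  mis <- b$truth[b$truth$has_misspelling, ]
  recs <- b$names[match(mis$id, b$names$id), ]
  source_name <- ifelse(is.na(mis$synonym_used), mis$clean_canonical,
                        mis$synonym_used)
  corrupted <- normalize_name(ifelse(
    nzchar(recs$scientificName),
    build_scientificname_plus(recs),
    build_constructed_name(recs)))
  # abbreviation-format names shorten the genus; skip those for the
  # distance identity (their edits are epithet-only by construction)
  plain <- is.na(mis$format_subtype) | mis$format_subtype != "abbreviation"
  d <- edit_distance(corrupted[plain], source_name[plain])
  expect_identical(as.integer(d), as.integer(mis$edit_distance[plain]))
  expect_true(all(mis$edit_distance >= 1))
  expect_true(all(mis$edit_distance <=
                    ifelse(grepl(" .* ", source_name), 3, 2)))
})

test_that("synonym injection errors when no junior synonym exists", {
  b <- small_bundle()
  no_syn <- b$truth$clean_canonical[!b$truth$id %in%
    b$truth$id[b$truth$has_synonym]][1]
  pool_row <- tibble::tibble(canonical = "Nullius nomen", rank = "species",
                             authorship = "Smith, 1900", clade = "Aves",
                             has_synonym = FALSE)
  expect_error(
    corrupt_name(pool_row, "synonym", b$config, b$authority, seed = 1),
    class = "taxonvet_generator_error")
  expect_error(
    corrupt_name(pool_row, "unknowable", b$config, b$authority, seed = 1),
    class = "taxonvet_generator_error")
})

test_that("simulated outcomes follow the requested logit model", {
  set.seed(55)
  mf <- prepare_model_frame(random_covariates(10000))
  flat <- setNames(rep(0, length(default_true_coefficients())),
                   names(default_true_coefficients()))
  y <- simulate_issue_outcomes(mf, flat, seed = 9)
  expect_lt(abs(mean(y) - 0.5), 3 * sqrt(0.25 / 10000))

  flat["(Intercept)"] <- qlogis(0.25)
  y2 <- simulate_issue_outcomes(mf, flat, seed = 9)
  expect_lt(abs(mean(y2) - 0.25), 2.58 * sqrt(0.25 * 0.75 / 10000))

  expect_identical(simulate_issue_outcomes(mf, flat, seed = 10),
                   simulate_issue_outcomes(mf, flat, seed = 10))

  expect_error(simulate_issue_outcomes(mf, c(whatever = 1)),
               class = "taxonvet_generator_error")
})

test_that("an empty bundle is valid and write/read round-trips through the IO layer", {
  b0 <- generate_dataset(generator_config(seed = 3, n_names = 0))
  expect_equal(nrow(b0$names), 0)

  b <- generate_dataset(generator_config(seed = 4, n_names = 30))
  dir <- withr::local_tempdir()
  write_dataset(b, dir)
  names_back <- read_name_table(file.path(dir, "names.tsv"))
  expect_identical(as.data.frame(names_back[, names(b$names)]),
                   as.data.frame(b$names))
  occ_back <- read_occurrence_table(file.path(dir, "occurrences.tsv"))
  expect_equal(nrow(occ_back), nrow(b$occurrences))
  expect_s3_class(load_authority(file.path(dir, "authority.tsv")),
                  "taxon_authority")
})
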