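# Authority loading, closure invariants, edit distance, lookups.

test_that("authorities load from file and verify closure at load", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_authority(tiny_authority(), path)
  auth <- load_authority(path)
  expect_s3_class(auth, "taxon_authority")
  expect_equal(length(auth), 5)

  bad <- tiny_authority()$entries
  bad$acceptedCanonical[bad$canonical == "Parus caeruleus"] <- "Ghost species"
  readr::write_tsv(bad, path)
  expect_error(load_authority(path), regexp = "Ghost species",
               class = "taxonvet_authority_error")

  dup <- rbind(tiny_authority()$entries,
               tibble::tibble(canonical = "Parus major", rank = "species",
                              status = "synonym",
                              acceptedCanonical = "Cyanistes caeruleus",
                              source = "x", sourceURL = "x", sourceDate = "x"))
  readr::write_tsv(dup, path)
  expect_error(load_authority(path), regexp = "conflicting",
               class = "taxonvet_authority_error")
})

test_that("edit distance matches the DP oracle on the spec examples", {
  expect_identical(edit_distance("major", "major"), 0L)
  expect_identical(edit_distance("major", "mojor"), dl_oracle("major", "mojor"))
  expect_identical(edit_distance("major", "mojor"), 1L)
  expect_identical(edit_distance("caeruleus", "caerulesu"), 1L)  # transposition
  expect_identical(edit_distance("", "abc"), 3L)
  expect_identical(edit_distance("Major", "major"), 1L)  # case-sensitive
})

test_that("edit distance agrees with the oracle and behaves as a metric", {
  set.seed(421)
  for (i in 1:400) {
    a <- random_string(); b <- random_string(); c <- random_string()
    dab <- edit_distance(a, b)
    expect_identical(dab, dl_oracle(a, b))
    expect_identical(dab, edit_distance(b, a))            # symmetry
    expect_identical(dab == 0L, a == b)                   # identity
    expect_lte(dab, edit_distance(a, c) + edit_distance(c, b))  # triangle
  }
})

test_that("exact lookup is case-sensitive and total", {
  auth <- tiny_authority()
  expect_identical(lookup_exact(auth, "Parus major")$status, "accepted")
  expect_null(lookup_exact(auth, "Parus Major"))
  expect_null(lookup_exact(auth, "Nullius nomen"))
})

test_that("fuzzy lookup matches a brute-force scan with deterministic ties", {
  auth <- tiny_authority()
  hit <- lookup_fuzzy(auth, "Parus mojor", 1)
  expect_equal(nrow(hit), 1)
  expect_identical(hit$canonical, "Parus major")
  expect_identical(hit$distance, 1L)

  expect_equal(nrow(lookup_fuzzy(auth, "Xxxx yyyy", 1)), 0)

  # brute-force oracle on a wider radius
  query <- "Parus caeruleos"
  d <- vapply(auth$entries$canonical, dl_oracle, integer(1), b = query)
  want <- sort(names(d)[d <= 3])
  got <- lookup_fuzzy(auth, query, 3)
  expect_setequal(got$canonical, want)
  expect_true(!is.unsorted(got$distance))

  # equal-distance tie: accepted sorts before synonym, then lexicographic
  tie <- new_authority(tibble::tibble(
    canonical = c("Abcdef one", "Abcdeg one", "Abcdeh one"),
    rank = "species",
    status = c("synonym", "accepted", "accepted"),
    acceptedCanonical = c("Abcdeg one", "Abcdeg one", "Abcdeh one"),
    source = "t", sourceURL = "t", sourceDate = "t"))
  got <- lookup_fuzzy(tie, "Abcdex one", 1)
  expect_identical(got$canonical, c("Abcdeg one", "Abcdeh one", "Abcdef one"))
})

test_that("fuzzy at distance zero equals exact match; resolution is idempotent", {
  auth <- tiny_authority()
  got <- lookup_fuzzy(auth, "Parus major", 0)
  expect_identical(got$canonical, "Parus major")

  syn <- lookup_exact(auth, "Parus caeruleus")
  acc <- resolve_accepted(auth, syn)
  expect_identical(acc$canonical, "Cyanistes caeruleus")
  expect_identical(resolve_accepted(auth, acc), acc)
})
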