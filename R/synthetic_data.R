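# Seeded synthetic-data generator: an authority bank of pronounceable
# latinized names, name combinations corrupted by the four issue classes
# at configured rates with full truth labels, and occurrence tables with
# modelling covariates. Everything is a deterministic function of the
# seed.
#
# Identifiability by construction: generated genus names (active and
# retired pools together) have pairwise Damerau-Levenshtein distance of at
# least `min_separation` and distinct initial letters, and epithets are
# globally separated the same way. Any corruption of up to
# `min_separation - 1 - max edit` characters therefore has a unique
# nearest authority entry - the truth - so detector recall measures the
# resolver rather than authority-collision luck.

#' Generator configuration
#'
#' Defaults mirror the study conditions the package is validated against:
#' 1,000 name combinations with per-class issue rates of 12.9%
#' (misspelling), 8.9% (format), 13.7% (conceptual) and 27% (synonymy),
#' and a mean of about 27 matching occurrences per name. Issue classes
#' combine independently, exercising all 15 overlap cells.
#'
#' @param seed integer seed; fully determines the output bundle.
#' @param n_genera,species_per_genus,subspecies_rate,synonym_rate authority
#'   shape: active genera, species per genus, fraction of species that get
#'   an infraspecific form, fraction of species with a junior synonym.
#' @param rates named per-class issue probabilities
#'   (misspelling/format/conceptual/synonym).
#' @param edit_mix probabilities of the four edit operations used for
#'   misspellings (insertion, deletion, substitution, transposition).
#' @param k_edit_probs probabilities of applying 1 or 2 edits.
#' @param n_names number of name combinations to generate.
#' @param occ_mu,occ_size negative-binomial mean/size of the
#'   occurrences-per-name distribution.
#' @param n_institutions number of contributing institutions.
#' @param gender_swap_rate fraction of synonyms built as gender-ending
#'   swaps instead of genus transfers. Off by default: gender variants sit
#'   within fuzzy distance of their accepted form, so misspelling and
#'   synonymy labels would no longer be unambiguous.
#' @param unresolvable_rate fraction of names replaced by names absent
#'   from the authority (emulating authority incompleteness); such names
#'   carry no injected issues. Off by default.
#' @param mess_rate rate of unusable covariate values (junk year, unknown
#'   country, non-specimen basisOfRecord) in the occurrence table.
#' @param coefficients true logit coefficients used by
#'   [simulate_issue_outcomes()]; see [default_true_coefficients()].
#' @param min_separation minimum pairwise edit distance enforced between
#'   generated words (see module notes).
#' @return a `generator_config` list.
#' @export
generator_config <- function(seed = 1,
                             n_genera = 10,
                             species_per_genus = 8,
                             subspecies_rate = 0.15,
                             synonym_rate = 0.6,
                             rates = c(misspelling = 0.129, format = 0.089,
                                       conceptual = 0.137, synonym = 0.27),
                             edit_mix = c(insertion = 0.25, deletion = 0.25,
                                          substitution = 0.25,
                                          transposition = 0.25),
                             k_edit_probs = c(`1` = 0.75, `2` = 0.25),
                             n_names = 1000,
                             occ_mu = 26,
                             occ_size = 0.6,
                             n_institutions = 40,
                             gender_swap_rate = 0,
                             unresolvable_rate = 0,
                             mess_rate = 0.03,
                             coefficients = default_true_coefficients(),
                             min_separation = 5) {
  stopifnot(all(rates >= 0 & rates <= 1),
            all(ISSUE_CLASSES %in% names(rates)),
            n_genera >= 1, species_per_genus >= 1,
            synonym_rate >= 0, synonym_rate <= 1,
            n_names >= 0)
  if (2 * n_genera > 20) {
    tv_abort("at most 10 active genera: active + retired genus pools need distinct initials",
             class = "taxonvet_generator_error")
  }
  structure(as.list(environment()), class = "generator_config")
}

# --- latinate word morphology ----------------------------------------------

LATIN_ONSETS <- c("b", "c", "d", "f", "g", "h", "j", "k", "l", "m", "n",
                  "p", "qu", "r", "s", "t", "v", "w", "x", "z", "br", "cr",
                  "dr", "gr", "pl", "pr", "st", "tr", "ch", "th", "ph",
                  "sc", "sp")
LATIN_VOWELS <- c("a", "e", "i", "o", "u", "ae", "ia", "io")
GENUS_ENDINGS <- c("us", "a", "is", "ops", "ura", "odon", "ornis", "ella")
EPITHET_ENDINGS <- c("us", "a", "um", "is", "ensis", "atus", "icus", "ides")

make_latin_word <- function(kind = c("genus", "epithet"), n_syllables = 3,
                            first_onset = NULL) {
  kind <- match.arg(kind)
  onsets <- sample(LATIN_ONSETS, n_syllables, replace = TRUE)
  if (!is.null(first_onset)) onsets[1] <- first_onset
  core <- paste(paste0(onsets, sample(LATIN_VOWELS, n_syllables,
                                      replace = TRUE)), collapse = "")
  ending <- sample(if (kind == "genus") GENUS_ENDINGS else EPITHET_ENDINGS, 1)
  w <- paste0(core, ending)
  if (kind == "genus") cap_first(w) else tolower(w)
}

# Draw n words pairwise separated by >= min_dist from each other and from
# `existing`. With distinct_initials, each word gets a distinct initial
# letter, assigned up front from the onset alphabet.
distinct_words <- function(n, kind, min_dist, existing = character(),
                           distinct_initials = FALSE) {
  first_onsets <- rep(list(NULL), n)
  if (distinct_initials) {
    by_initial <- split(LATIN_ONSETS, substr(LATIN_ONSETS, 1, 1))
    if (n > length(by_initial)) {
      tv_abort(sprintf(
        "cannot give %d genus names distinct initials (alphabet has %d)",
        n, length(by_initial)), class = "taxonvet_generator_error")
    }
    chosen <- sample(names(by_initial), n)
    first_onsets <- lapply(chosen, function(i) {
      o <- by_initial[[i]]
      if (length(o) == 1) o else sample(o, 1)
    })
  }
  words <- character(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    syll <- 3
    for (attempt in 1:2000) {
      if (attempt %% 500 == 0) syll <- syll + 1
      w <- make_latin_word(kind, syll, first_onset = first_onsets[[i]])
      pool <- c(existing, words)
      if (length(pool) > 0 && any(edit_distance(pool, w) < min_dist)) next
      words <- c(words, w)
      placed <- TRUE
      break
    }
    if (!placed) {
      tv_abort("could not generate enough well-separated words; relax the shape parameters",
               class = "taxonvet_generator_error")
    }
  }
  words
}

AUTHOR_SURNAMES <- c("Linnaeus", "Gmelin", "Boddaert", "Temminck",
                     "Vieillot", "Cuvier", "Wagler", "Lesson", "Lichtenstein",
                     "Swainson", "Lafresnaye", "Sclater", "Salvin", "Ridgway")

sample_authorship <- function() {
  a <- sprintf("%s, %d", sample(AUTHOR_SURNAMES, 1), sample(1758:1950, 1))
  if (runif(1) < 0.5) paste0("(", a, ")") else a
}

# --- authority generation --------------------------------------------------

#' Generate a synthetic taxonomic authority
#'
#' Builds an authority of pronounceable latinized binomials and trinomials
#' plus junior synonyms pointing at accepted names (genus transfers by
#' default, gender-ending swaps optionally), satisfying the resolution
#' closure invariant by construction. Also returns the clean name pool
#' used by [generate_dataset()]: each accepted name with its authorship,
#' clade and synonym availability.
#'
#' @param config a [generator_config()]. Called inside an existing RNG
#'   stream by [generate_dataset()]; call `set.seed()` first for
#'   standalone reproducibility.
#' @return list with `authority` (a `taxon_authority`) and `pool` (tibble:
#'   `canonical`, `rank`, `authorship`, `clade`, `has_synonym`).
#' @export
generate_authority <- function(config) {
  n_act <- config$n_genera
  sep <- config$min_separation
  genera <- distinct_words(2 * n_act, "genus", sep, distinct_initials = TRUE)
  active <- genera[seq_len(n_act)]
  retired <- genera[n_act + seq_len(n_act)]
  clades <- sample(CLADES, n_act, replace = TRUE,
                   prob = c(0.08, 0.36, 0.12, 0.11, 0.33))

  n_epi <- ceiling(config$species_per_genus * (1 + config$subspecies_rate) + 2)
  all_epithets <- distinct_words(n_act * n_epi, "epithet", sep)
  epi_by_genus <- split(all_epithets, rep(seq_len(n_act), each = n_epi))

  rows <- list()
  pool <- list()
  retired_i <- 0
  for (g in seq_len(n_act)) {
    epis <- epi_by_genus[[g]]
    sp_epis <- epis[seq_len(config$species_per_genus)]
    extra <- setdiff(epis, sp_epis)
    for (e in sp_epis) {
      canonical <- paste(active[g], e)
      auth <- sample_authorship()
      has_syn <- runif(1) < config$synonym_rate
      rows[[length(rows) + 1]] <- tibble::tibble(
        canonical = canonical, rank = "species", status = "accepted",
        acceptedCanonical = canonical)
      pool[[length(pool) + 1]] <- tibble::tibble(
        canonical = canonical, rank = "species", authorship = auth,
        clade = clades[g], has_synonym = has_syn)
      if (has_syn) {
        syn <- if (runif(1) < config$gender_swap_rate) {
          paste(active[g], gender_swap(e))
        } else {
          retired_i <- retired_i + 1
          paste(retired[(retired_i - 1) %% length(retired) + 1], e)
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          canonical = syn, rank = "species", status = "synonym",
          acceptedCanonical = !!canonical)
      }
      if (runif(1) < config$subspecies_rate && length(extra) > 0) {
        inf <- extra[1]
        extra <- extra[-1]
        tri <- paste(canonical, inf)
        rows[[length(rows) + 1]] <- tibble::tibble(
          canonical = tri, rank = "infraspecific", status = "accepted",
          acceptedCanonical = tri)
        pool[[length(pool) + 1]] <- tibble::tibble(
          canonical = tri, rank = "infraspecific",
          authorship = sample_authorship(), clade = clades[g],
          has_synonym = FALSE)
      }
    }
  }
  entries <- dplyr::bind_rows(rows)
  entries$source <- "Synthetic Reference Checklist v1.0 (synthetic authority)"
  entries$sourceURL <- paste0("https://example.org/synthetic-checklist/",
                              gsub(" ", "-", entries$canonical))
  entries$sourceDate <- "2015-04-18"
  list(authority = new_authority(entries), pool = dplyr::bind_rows(pool))
}

gender_swap <- function(epithet) {
  if (grepl("us$", epithet)) sub("us$", "a", epithet)
  else if (grepl("a$", epithet)) sub("a$", "us", epithet)
  else if (grepl("um$", epithet)) sub("um$", "us", epithet)
  else paste0(epithet, "a")
}

# --- name corruption -------------------------------------------------------

apply_one_edit <- function(tok, op) {
  n <- nchar(tok)
  chars <- strsplit(tok, "")[[1]]
  alphabet <- letters
  # positions 1 (the capitalized initial) is never touched so that case
  # normalization stays orthogonal to the edit distance
  switch(op,
    insertion = {
      pos <- sample(2:(n + 1), 1)
      paste(c(chars[seq_len(pos - 1)], sample(alphabet, 1),
              if (pos <= n) chars[pos:n]), collapse = "")
    },
    deletion = {
      if (n < 3) return(tok)
      pos <- sample(2:n, 1)
      paste(chars[-pos], collapse = "")
    },
    substitution = {
      pos <- sample(2:n, 1)
      chars[pos] <- sample(setdiff(alphabet, tolower(chars[pos])), 1)
      paste(chars, collapse = "")
    },
    transposition = {
      if (n < 3) return(tok)
      pos <- sample(2:(n - 1), 1)
      if (chars[pos] == chars[pos + 1]) return(tok)
      chars[c(pos, pos + 1)] <- chars[c(pos + 1, pos)]
      paste(chars, collapse = "")
    }
  )
}

misspell_tokens <- function(toks, k, edit_mix, eligible = seq_along(toks),
                            max_dist = length(toks)) {
  clean <- paste(toks, collapse = " ")
  for (attempt in 1:20) {
    out <- toks
    ops <- character(0)
    for (j in seq_len(k)) {
      ti <- if (length(eligible) == 1) eligible else sample(eligible, 1)
      op <- sample(names(edit_mix), 1, prob = edit_mix)
      out[ti] <- apply_one_edit(out[ti], op)
      ops <- c(ops, sprintf("%s@token%d", op, ti))
    }
    d <- edit_distance(paste(out, collapse = " "), clean)
    if (d >= 1 && d <= max_dist) {
      return(list(tokens = out, ops = ops, distance = d))
    }
  }
  tv_abort("could not realize the requested misspelling", "taxonvet_generator_error")
}

#' Corrupt a clean name with the requested issue classes
#'
#' Applies the requested classes to one clean accepted name: synonymy
#' replaces the name with a junior synonym from the authority;
#' misspelling applies 1-2 random edit operations (insertion, deletion,
#' substitution, transposition), never touching a token's initial
#' character; conceptual errors inject an identification qualifier,
#' displace authorship into an epithet field, split a trinomial into a
#' binomial-only scientificName, or use the only-infraspecific pattern;
#' format errors add whitespace, break capitalization, or abbreviate the
#' genus. Fields are then populated in a sampled provider style
#' (atomic-only, scientificName-only, or both), adjusted where a class
#' requires specific fields to exist.
#'
#' @param clean one-row of the clean pool (see [generate_authority()]):
#'   `canonical`, `rank`, `authorship`.
#' @param issues character subset of
#'   `c("misspelling","format","conceptual","synonym")`.
#' @param config a [generator_config()].
#' @param authority the generated `taxon_authority` (needed for synonym
#'   swaps; an error is raised if synonymy is requested but no junior
#'   synonym exists for the name).
#' @param seed optional seed for standalone reproducibility.
#' @return list with `record` (one-row tibble of the six verbatim fields)
#'   and `truth` (clean canonical, classes, subtypes, edit operations,
#'   realized edit distance, provider style).
#' @export
corrupt_name <- function(clean, issues, config, authority, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bad <- setdiff(issues, ISSUE_CLASSES)
  if (length(bad) > 0) {
    tv_abort(sprintf("unknown issue class(es): %s", paste(bad, collapse = ", ")),
             class = "taxonvet_generator_error")
  }
  canonical <- clean$canonical
  authorship <- clean$authorship
  base <- canonical
  synonym_used <- NA_character_

  if ("synonym" %in% issues) {
    ent <- authority$entries
    syns <- ent$canonical[ent$status == "synonym" &
                            ent$acceptedCanonical == canonical]
    if (length(syns) == 0) {
      tv_abort(sprintf("no junior synonym available for '%s'", canonical),
               class = "taxonvet_generator_error")
    }
    base <- if (length(syns) == 1) syns else sample(syns, 1)
    synonym_used <- base
  }

  toks <- strsplit(base, " ", fixed = TRUE)[[1]]
  rank <- if (length(toks) >= 3) "infraspecific" else "species"

  conceptual_subtype <- NA_character_
  if ("conceptual" %in% issues) {
    opts <- if (rank == "infraspecific") {
      c("qualifier", "autherr", "binomial_only", "only_infraspecific")
    } else c("qualifier", "autherr")
    conceptual_subtype <- sample(opts, 1)
  }
  format_subtype <- NA_character_
  if ("format" %in% issues) {
    opts <- c("whitespace", "genus_case", "epithet_case", "authcap",
              "abbreviation")
    format_subtype <- sample(opts, 1)
  }

  edit_ops <- character(0)
  edit_dist <- 0L
  if ("misspelling" %in% issues) {
    k <- as.integer(sample(names(config$k_edit_probs), 1,
                           prob = config$k_edit_probs))
    cap <- min(k, if (rank == "infraspecific") 3L else 2L)
    eligible <- seq_along(toks)
    if (identical(format_subtype, "abbreviation")) eligible <- eligible[-1]
    ms <- misspell_tokens(toks, cap, config$edit_mix, eligible,
                          max_dist = if (rank == "infraspecific") 3L else 2L)
    toks <- ms$tokens
    edit_ops <- ms$ops
    edit_dist <- ms$distance
  }

  # authorship mis-capitalization transforms the authorship string itself,
  # so the corruption survives wherever the authorship ends up (field,
  # scientificName, or displaced into an epithet by the autherr subtype)
  if (identical(format_subtype, "authcap")) {
    authorship <- sub("^(\\(?)([A-Z])", "\\1\\L\\2", authorship, perl = TRUE)
  }

  style <- sample(c("atomic", "sn", "both"), 1, prob = c(0.3, 0.3, 0.4))
  if (identical(conceptual_subtype, "autherr") && style == "sn") style <- "both"
  if (identical(conceptual_subtype, "binomial_only")) style <- "both"
  if (identical(conceptual_subtype, "only_infraspecific")) style <- "sn"

  genus <- toks[1]
  specific <- if (length(toks) >= 2) toks[2] else ""
  infra <- if (length(toks) >= 3) toks[3] else ""
  sn <- if (style %in% c("sn", "both")) paste(toks, collapse = " ") else ""
  sn_has_auth <- nzchar(sn) && runif(1) < 0.3
  if (sn_has_auth) sn <- paste(sn, authorship)
  auth_field <- if (runif(1) < 0.7) authorship else ""
  if (identical(format_subtype, "authcap") ||
      identical(conceptual_subtype, "autherr")) auth_field <- authorship
  if (style == "sn" && !identical(conceptual_subtype, "only_infraspecific")) {
    genus <- ""; specific <- ""; infra <- ""
  }

  if (!is.na(conceptual_subtype)) {
    switch(conceptual_subtype,
      qualifier = {
        q <- sample(c("sp.", "cf.", "aff.", "?"), 1)
        if (nzchar(sn)) {
          sn_toks <- strsplit(sn, " ", fixed = TRUE)[[1]]
          pos <- sample(2:(length(sn_toks) + 1), 1)
          sn <- paste(append(sn_toks, q, after = pos - 1), collapse = " ")
        } else {
          specific <- paste(q, specific)
        }
      },
      autherr = {
        if (rank == "infraspecific" && nzchar(infra)) {
          infra <- paste(infra, auth_field)
        } else {
          specific <- paste(specific, auth_field)
        }
        if (runif(1) < 0.5) auth_field <- ""
      },
      binomial_only = {
        sn <- paste(toks[1:2], collapse = " ")
      },
      only_infraspecific = {
        genus <- ""; specific <- ""; infra <- toks[3]
        sn <- paste(toks, collapse = " ")
      }
    )
  }

  if (!is.na(format_subtype)) {
    switch(format_subtype,
      whitespace = {
        done <- FALSE
        if (nzchar(sn) && grepl(" ", sn)) {
          sn <- sub(" ", "  ", sn); done <- TRUE
        }
        if (!done && nzchar(genus)) { genus <- paste0(" ", genus); done <- TRUE }
        if (!done && nzchar(infra)) infra <- paste0(infra, " ")
        if (!done && nzchar(specific)) specific <- paste0(specific, " ")
      },
      genus_case = {
        lower1 <- function(x) paste0(tolower(substr(x, 1, 1)),
                                     substr(x, 2, nchar(x)))
        if (nzchar(genus)) genus <- lower1(genus)
        if (nzchar(sn)) sn <- lower1(sn)
      },
      epithet_case = {
        target <- if (nzchar(specific)) "specific"
                  else if (nzchar(infra)) "infra" else "sn"
        if (target == "specific") specific <- cap_first(specific)
        if (target == "infra") infra <- cap_first(infra)
        if (nzchar(sn)) {
          sn_toks <- strsplit(sn, " ", fixed = TRUE)[[1]]
          if (length(sn_toks) >= 2) {
            sn_toks[2] <- cap_first(sn_toks[2])
            sn <- paste(sn_toks, collapse = " ")
          }
        }
      },
      authcap = {
        # already applied to the authorship string itself above
      },
      abbreviation = {
        ab <- paste0(substr(toks[1], 1, 1), ".")
        if (nzchar(genus)) genus <- ab
        if (nzchar(sn)) {
          sn_toks <- strsplit(sn, " ", fixed = TRUE)[[1]]
          sn_toks[1] <- ab
          sn <- paste(sn_toks, collapse = " ")
        }
      }
    )
  }

  record <- tibble::tibble(
    scientificName = sn,
    genus = genus,
    subgenus = "",
    specificEpithet = specific,
    infraspecificEpithet = infra,
    scientificNameAuthorship = auth_field
  )
  truth <- tibble::tibble(
    clean_canonical = canonical,
    synonym_used = synonym_used,
    has_misspelling = "misspelling" %in% issues,
    has_format = "format" %in% issues,
    has_conceptual = "conceptual" %in% issues,
    has_synonym = "synonym" %in% issues,
    conceptual_subtype = conceptual_subtype,
    format_subtype = format_subtype,
    edit_ops = paste(edit_ops, collapse = ";"),
    edit_distance = edit_dist,
    provider_style = style
  )
  list(record = record, truth = truth)
}

# --- outcome simulation ----------------------------------------------------

#' Default true logit coefficients for issue probability
#'
#' A coefficient vector on the [prepare_model_frame()] design encoding the
#' qualitative driver structure the models are meant to recover: fossils
#' and South American records more issue-prone, Amphibia highest and
#' Fishes lowest among clades, fewer issues for recent years and for
#' institutions with large digitized volumes. The intercept puts the
#' reference-class issue probability near 0.25.
#'
#' @return named numeric vector of logit-scale coefficients.
#' @export
default_true_coefficients <- function() {
  c("(Intercept)" = qlogis(0.25),
    "basisOfRecordFossilSpecimen" = 0.6,
    "regionAfrica" = 0.30, "regionAsia" = 0.25,
    "regionAustralasia" = 0.20, "regionEurope" = 0.10,
    "regionOceania" = 0.20, "regionSouth America" = 0.45,
    "cladeAmphibia" = 0.80, "cladeFishes" = -0.50,
    "cladeMammalia" = 0.10, "cladeReptilia" = 0.30,
    "year_s" = -0.30, "log_institutionRecords_s" = -0.30)
}

#' Simulate binary issue outcomes from a known logit model
#'
#' Independent Bernoulli draws with probability
#' `plogis(model.matrix %*% coefficients)` over the standardized
#' covariate design, enabling coefficient-recovery testing of the driver
#' models.
#'
#' @param covariates modelling frame from [prepare_model_frame()] (or a
#'   covariate table, which is passed through it).
#' @param coefficients named coefficient vector conformable with the
#'   design; an error is raised on a name mismatch.
#' @param seed optional seed.
#' @return integer 0/1 vector of outcomes.
#' @export
simulate_issue_outcomes <- function(covariates,
                                    coefficients = default_true_coefficients(),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mf <- if ("year_s" %in% names(covariates)) covariates
        else prepare_model_frame(covariates)
  X <- model.matrix(~ basisOfRecord + region + clade + year_s +
                      log_institutionRecords_s, data = as.data.frame(mf))
  missing_terms <- setdiff(colnames(X), names(coefficients))
  if (length(missing_terms) > 0) {
    tv_abort(sprintf("coefficients not conformable; missing: %s",
                     paste(missing_terms, collapse = ", ")),
             class = "taxonvet_generator_error")
  }
  eta <- as.numeric(X %*% coefficients[colnames(X)])
  rbinom(length(eta), 1, plogis(eta))
}

# --- end-to-end bundle -----------------------------------------------------

COUNTRY_POOL <- c(
  "United States" = 0.58, "Canada" = 0.05, "Mexico" = 0.05, "Brazil" = 0.05,
  "Argentina" = 0.03, "Peru" = 0.02, "United Kingdom" = 0.03,
  "Germany" = 0.02, "France" = 0.02, "China" = 0.03, "India" = 0.02,
  "Indonesia" = 0.01, "Australia" = 0.04, "New Zealand" = 0.01,
  "South Africa" = 0.02, "Kenya" = 0.01, "Fiji" = 0.005,
  "Antarctica" = 0.005
)

#' Generate a full synthetic bundle: names, occurrences, authority, truth
#'
#' End-to-end generator. Issue classes are drawn independently per name at
#' the configured rates (synonymy-flagged names are drawn from the pool of
#' accepted names that have junior synonyms, so realized class frequencies
#' are exact Bernoulli draws at the configured rates); each name is then
#' corrupted accordingly and linked to a negative-binomially sized set of
#' occurrence records carrying covariates (institution, country/region,
#' year, class, basisOfRecord) with a small configurable rate of unusable
#' values. The whole bundle is a deterministic function of `config$seed`.
#'
#' @param config a [generator_config()].
#' @return list with `names` (verbatim name table), `occurrences`,
#'   `authority`, `truth` (per-name labels), `institution_counts` and
#'   `config`.
#' @export
generate_dataset <- function(config = generator_config()) {
  set.seed(config$seed)
  gen <- generate_authority(config)
  pool <- gen$pool
  authority <- gen$authority

  n <- config$n_names
  if (n == 0) {
    empty_names <- tibble::tibble(id = character())
    for (f in DWC_NAME_FIELDS) empty_names[[f]] <- character()
    return(list(names = empty_names,
                occurrences = tibble::tibble(occurrenceID = character()),
                authority = authority,
                truth = tibble::tibble(id = character()),
                institution_counts = tibble::tibble(
                  institutionCode = character(), n_records = integer()),
                config = config))
  }

  unresolvable <- runif(n) < config$unresolvable_rate
  issue_mat <- cbind(
    misspelling = runif(n) < config$rates[["misspelling"]],
    format = runif(n) < config$rates[["format"]],
    conceptual = runif(n) < config$rates[["conceptual"]],
    synonym = runif(n) < config$rates[["synonym"]]
  )
  issue_mat[unresolvable, ] <- FALSE

  with_syn <- pool[pool$has_synonym, ]
  rows <- vector("list", n)
  truths <- vector("list", n)
  seen_keys <- new.env(parent = emptyenv())
  off_authority_name <- function() {
    for (attempt in 1:200) {
      cand <- paste(make_latin_word("genus"), make_latin_word("epithet"))
      if (all(edit_distance(authority$entries$canonical, cand) >=
                config$min_separation)) return(cand)
    }
    tv_abort("could not generate an off-authority name",
             class = "taxonvet_generator_error")
  }
  for (i in seq_len(n)) {
    if (unresolvable[i]) {
      cl <- tibble::tibble(canonical = off_authority_name(), rank = "species",
                           authorship = sample_authorship(),
                           clade = sample(CLADES, 1), has_synonym = FALSE)
      out <- corrupt_name(cl, character(0), config, authority)
      out$truth$clean_canonical <- NA_character_
      rows[[i]] <- out$record
      truths[[i]] <- out$truth
      truths[[i]]$clade <- cl$clade
      next
    }
    issues <- ISSUE_CLASSES[issue_mat[i, ]]
    src <- if ("synonym" %in% issues) with_syn else pool
    # name combinations are distinct six-field tuples: redraw on collision
    for (attempt in 1:100) {
      clean <- src[sample.int(nrow(src), 1), ]
      out <- corrupt_name(clean, issues, config, authority)
      key <- make_name_key(out$record)
      if (!exists(key, envir = seen_keys, inherits = FALSE)) break
    }
    assign(key, TRUE, envir = seen_keys)
    rows[[i]] <- out$record
    truths[[i]] <- out$truth
    truths[[i]]$clade <- clean$clade
  }
  ids <- sprintf("name-%06d", seq_len(n))
  names_tbl <- dplyr::bind_cols(tibble::tibble(id = ids),
                                dplyr::bind_rows(rows))
  truth_tbl <- dplyr::bind_cols(tibble::tibble(id = ids),
                                dplyr::bind_rows(truths))
  truth_tbl$unresolvable <- unresolvable

  # occurrences
  inst_codes <- sprintf("INST-%02d", seq_len(config$n_institutions))
  inst_w <- exp(stats::rnorm(config$n_institutions, 0, 1.2))
  occ_counts <- rnbinom(n, size = config$occ_size, mu = config$occ_mu)
  total <- sum(occ_counts)
  name_idx <- rep(seq_len(n), occ_counts)

  mess <- function(m) runif(m) < config$mess_rate
  m <- total
  country <- sample(names(COUNTRY_POOL), m, replace = TRUE,
                    prob = COUNTRY_POOL)
  continent <- rep("", m)
  junk_country <- mess(m)
  country[junk_country] <- ""
  continent[junk_country] <- sample(c("North America", "Europe", "Unknown", ""),
                                    sum(junk_country), replace = TRUE)
  yr <- sample(1850:2015, m, replace = TRUE,
               prob = (1850:2015 - 1700) / sum(1850:2015 - 1700))
  year <- as.character(yr)
  junk_year <- mess(m)
  year[junk_year] <- sample(c("", "19xx", "1923-05", "c. 1900"),
                            sum(junk_year), replace = TRUE)
  basis <- sample(c("PreservedSpecimen", "preserved_specimen",
                    "PRESERVED_SPECIMEN", "FossilSpecimen",
                    "fossil_specimen"), m, replace = TRUE,
                  prob = c(0.55, 0.2, 0.1, 0.1, 0.05))
  junk_basis <- mess(m)
  basis[junk_basis] <- sample(c("HumanObservation", "Observation", ""),
                              sum(junk_basis), replace = TRUE)
  clade_of <- truth_tbl$clade[name_idx]
  cls <- ifelse(clade_of == "Fishes",
                sample(FISH_CLASSES, m, replace = TRUE), clade_of)
  inst <- sample(inst_codes, m, replace = TRUE, prob = inst_w)

  occ <- dplyr::bind_cols(
    tibble::tibble(occurrenceID = sprintf("occ-%07d", seq_len(m))),
    names_tbl[name_idx, DWC_NAME_FIELDS],
    tibble::tibble(
      basisOfRecord = basis, country = country, continent = continent,
      year = year, class = cls, institutionCode = inst,
      datasetName = paste0(inst, "-main")
    )
  )
  inst_tab <- table(factor(inst, levels = inst_codes))
  list(
    names = names_tbl,
    occurrences = occ,
    authority = authority,
    truth = truth_tbl,
    institution_counts = tibble::tibble(
      institutionCode = inst_codes,
      n_records = as.integer(inst_tab)
    ),
    config = config
  )
}

#' Write a generated bundle to a directory
#'
#' Serializes the bundle through the package's own IO layer: `names.tsv`,
#' `occurrences.tsv`, `authority.tsv` and `truth.tsv`.
#'
#' @param bundle output of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(bundle$names, file.path(dir, "names.tsv"), na = "")
  readr::write_tsv(bundle$occurrences, file.path(dir, "occurrences.tsv"),
                   na = "")
  write_authority(bundle$authority, file.path(dir, "authority.tsv"))
  readr::write_tsv(bundle$truth, file.path(dir, "truth.tsv"), na = "")
  invisible(dir)
}
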