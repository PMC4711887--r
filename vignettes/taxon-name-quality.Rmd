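---
title: "Assessing and resolving taxon names in Darwin Core occurrence data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing and resolving taxon names in Darwin Core occurrence data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxonvet)
```

`taxonvet` audits the taxonomic content of digitized biocollections
records. This vignette documents the models and procedures it implements,
the parameters that matter and why their defaults are what they are, what
the synthetic-data generator does and does not emulate, and the numerical
and design choices made where more than one defensible option existed.

## The issue taxonomy

A *name combination* is a distinct tuple of the six verbatim Darwin Core
taxon fields. Each combination is assessed for four issue classes:

* **Misspelling** — character-level corruption of an otherwise correct
  name: insertions, deletions, substitutions, and adjacent
  transpositions.
* **Format error** — violations of name-string form that leave the
  intended name intact: mis-capitalized genus or epithets, incorrectly
  capitalized authorship, stray or doubled whitespace, abbreviations.
* **Darwin Core conceptual error** — misuse of the standard's field
  semantics: identification qualifiers ("sp.", "cf.", "?") inside name
  fields rather than `identificationQualifier`; author names inside an
  epithet field; a binomial-only `scientificName` when an infraspecific
  epithet is also populated; records populating only the infraspecific
  epithet among the atomic fields.
* **Synonymy** — a junior synonym: not an error, since the name was once
  correct, but an issue for any analysis that aggregates by taxon.

The per-record rollups are `hasError = misspelling ∨ format ∨ conceptual`
and `hasIssue = hasError ∨ (isSynonym = yes)`; synonymy alone makes a
combination issue-bearing but not error-bearing. When a name cannot be
found at all, its synonymy is recorded as `indeterminate` rather than
forced into yes/no, and such records are excluded from synonymy
modelling.

## Name assembly

Two candidate strings are built per record, because providers split names
across fields in incompatible ways:

* `constructedscientificname`: the space-separated concatenation of
  `genus`, `subgenus`, `specificEpithet`, `infraspecificEpithet` and
  `scientificNameAuthorship`, skipping empty fields. If the infraspecific
  epithet is the *only* populated field among the five, the constructed
  name is left blank — that pattern signals a provider convention where
  the full name lives in `scientificName`, and a fragment like "alba"
  would otherwise masquerade as a uninomial.
* `scientificnameplus`: `scientificName`, with the infraspecific epithet
  appended when both are populated and the epithet is not already
  present. "Already present" is a case-sensitive whole-token test
  (extended to contiguous token runs when the epithet field itself holds
  several tokens); a substring test would wrongly suppress epithets that
  prefix longer tokens. This operation is idempotent.

The subgenus is concatenated verbatim — no parentheses are added; a
malformed subgenus raises a flag downstream instead of being silently
repaired. Ranks (`dwcsn_rank`, `sn_rank`, `con_rank`) are inferred by
counting non-authorship tokens (one capitalized token → genus, two →
species, three → infraspecific), where a token is authorship-like if it
is a four-digit year, starts with "(", contains a comma, or is a
capitalized token following at least two lowercase epithet tokens. The
heuristic is deliberately conservative: anything it cannot classify
surfaces as `indeterminate`, never as a silent guess. Single-surname
authorship without a comma or year directly after one epithet (e.g.
"Parus major Linnaeus") is therefore classified indeterminate rather than
mis-stripped — a known, documented limitation.

## The authority and fuzzy matching

The authority is a local table — canonical name, rank, status,
accepted-name pointer, source fields — standing in for the online
checklists a human vetter would consult. Three invariants are enforced at
load: accepted entries point to themselves, every synonym's target exists
as an accepted entry (so chains resolve in one hop), and no canonical
appears with conflicting status. The table is single-voice by
construction; arbitrating among disagreeing live sources is out of scope.

Fuzzy matching uses the Damerau–Levenshtein distance in its
optimal-string-alignment form (unit-cost edits, adjacent transpositions
counted once, a transposed pair not edited again), implemented in C++ and
cross-checked in the tests against an independent full-matrix dynamic
program in R. The distance operates on the whole canonical string rather
than per token, matching the character-level definition of a
misspelling. Distances are computed on a case-normalized copy (genus
capitalized, epithets lowercased) so capitalization problems are charged
to the format detector, not to the edit distance.

Distance caps default to 1 edit for uninomial queries, 2 for binomials,
and 3 for trinomials. The rationale for these numbers is pragmatic: they
bound false positives at realistic misspelling rates while admitting
the common slip classes, including one- and two-edit latinized
gender-ending variants. Candidate ties sort deterministically (distance,
accepted before synonym, lexicographic); an ambiguous tie is additionally
noted in `comments` so a caller may choose to treat the record as
indeterminate.

## Resolution policy

Each candidate string is normalized (whitespace squashed, qualifier
tokens removed, subgenus and authorship stripped, case fixed), then: an
exact accepted hit is valid as-is; an exact synonym hit sets
`isSynonym = "yes"` and returns the accepted name; a fuzzy hit within the
cap charges `hasMisspelling` and then applies the same synonym logic to
the matched entry — misspelled junior synonyms set both flags. A leading
single-letter abbreviated genus ("P. major") is expanded against the
authority's genus list before matching, at the cost of one correction.
When the two candidates resolve to different accepted names, the one
reaching an accepted name with fewer total corrections (edit distance
plus expansions) wins; ties go to the candidate built from atomic fields,
which sit closer to the source of truth; every disagreement is logged in
`comments`. Authorship-only content in the constructed name is not
treated as invalid unless the authorship itself is malformed.

Three granular flags named in the reference field schema but not defined
precisely in its published text are implemented provisionally:
`sn_inf_missing` (the `scientificName` lacks the populated infraspecific
epithet), `con_sgerror` (subgenus content that is not a single
capitalized word, parenthesized or not), and `con_rnk` (the constructed
name's token count disagrees with the count implied by the populated
atomic fields). The first-pass regular expressions of the original
workflow are likewise unpublished; the detectors here are their
documented, versioned counterparts.

## Linking and covariates

Assessments join back to occurrences on a key concatenating the six
verbatim fields with a non-printing unit separator — equal field tuples,
and nothing else, produce equal keys; the join is byte-exact and
case-sensitive, and is verified against a nested-loop oracle in the
tests. Covariates then standardize as follows: `basisOfRecord` maps
case- and underscore-insensitively onto the Darwin Core controlled
vocabulary and only FossilSpecimen and PreservedSpecimen records are
retained; region derives from country (bundled editable mapping) or a
continent fallback into Africa, Asia, Australasia, Europe, North America,
Oceania and South America, with Antarctica excluded; years must be bare
4-digit values inside configurable plausibility bounds (1700–present);
class maps onto Amphibia, Aves, Mammalia, Reptilia, or "Fishes", the
latter pooling Actinopterygii, Cephalaspidomorphi, Conodonta,
Elasmobranchii, Holocephali, Myxini, Placodermi and Sarcopterygii.
Anything unresolvable is excluded, never coerced, and every exclusion
carries exactly one primary reason applied in the fixed order
basisOfRecord → region → year → clade. The institutional record count
defaults to tallies of the supplied occurrence table and can be
overridden with an external census for fidelity. The bundled region map
covers countries and continents only; marine localities without a
country fall out as region exclusions.

## Summaries and the effort projection

`summarize_issues()` reproduces the standard prevalence layout: counts
and percentages per category over name combinations and over matching
occurrences, plus distinct institutions and data sets from the matched
set. Percentages are stored at one decimal with half-up rounding and
always recompute exactly from the paired counts; name-combination
percentages use the assessed total as denominator even for rows from
which excluded dual-resolution records are dropped. `issue_overlap()`
partitions the issue-bearing records into the 15 non-empty subsets of the
four classes; its marginals equal the per-class summary counts by
construction and by test. `project_effort()` is the linear person-hours
extrapolation of a measured vetting rate (default 4 hours per 100
records), rounded half-up to whole hours.

## Driver models

Issue prevalence at the occurrence level is modelled with binomial-logit
GLMs on five covariates: basisOfRecord, region, clade, year (centered and
scaled), and the institution's digitized record count (log10, then
centered and scaled; counts span orders of magnitude, and a log scale is
the conventional choice for volume effects — the reference workflow does
not state a transform, so this is a package decision). Reference levels
are the bulk categories — PreservedSpecimen, North America, Aves — and
are configurable; the original analysis does not state its contrasts.

`select_model_aic()` fits *every* subset of the candidate two-way
interactions — all `2^C(k,2)` models, 1,024 for the full five-covariate
set — and ranks them by AIC with ΔAIC. Members are fitted through a
shared precomputed model matrix and reduced to scalar statistics, since
retaining a thousand full model objects at study scale is prohibitively
heavy; only the winning specification is refitted in full. Members that
fail (separation, non-convergence, detected by the convergence flag and
a |coefficient| > 15 guard on the logit scale) are flagged and ranked
last, never silently dropped; enumeration beyond 2^10 requires raising an
explicit cap. Per-issue models are main-effects only — interaction
structure in the overall model complicates comparing issue classes — and
a response that cannot be fitted is carried as its error condition.
McFadden's R² is `1 − ll/ll₀` and Nagelkerke's is Cox–Snell rescaled by
its maximum, both computed from log-likelihoods on identical observation
sets (enforced). `effect_profile()` evaluates the inverse-logit of the
linear predictor over a grid with co-predictors at reference/zero, with
delta-method bands on the link scale; out-of-range grid points are
annotated, not refused.

The reference study's fitted coefficients, its AIC values (17,342 vs
21,510) and its pseudo-R² (0.257 / 0.378) depend on an occurrence-level
matrix that was never published; they are not reproduction targets.
What the package validates instead is the machinery: exact pseudo-R²
arithmetic on a hand-computed fixture, per-coefficient 2-standard-error
coverage across 50 Monte-Carlo replicates at n = 20,000 on a fixed
design (fixing the design across replicates makes the generating
coefficients exactly the truth, removing standardization jitter from the
comparison), and recovery of a strong injected interaction (|β| = 1.5)
by the exhaustive AIC search in at least 90% of replicates.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
not real taxonomy or a real provider network.

* **Names.** Pronounceable latinized words from syllable templates over a
  fixed alphabet; genera and epithets are drawn so that any two generated
  words are at least `min_separation = 5` edits apart (and genus initials
  are unique across the active and retired pools). This is an
  identifiability choice: every corruption of up to 2–3 edits then has a
  unique nearest authority entry — the truth — so detector-recall
  measurements test the resolver rather than authority-collision luck.
  Real checklists contain near-neighbour names; recall on real data will
  be correspondingly lower, and the tests make no claim about it.
* **Authority.** Each species gets a junior synonym with probability
  `synonym_rate` (default 0.6), built by genus transfer into a retired
  genus pool. Gender-ending swaps are available (`gender_swap_rate`) but
  off by default: a gender variant sits within fuzzy distance of its
  accepted form, so misspelling and synonymy labels would cease to be
  unambiguous — a blur the reference workflow itself reports. Closure
  invariants hold by construction.
* **Issue injection.** Classes combine independently per name at the
  reference prevalence rates (misspelling 0.129, format 0.089,
  conceptual 0.137, synonymy 0.27 — name-combination rates, since
  injection operates on names). The synonymy flag is drawn first and the
  clean name then sampled from the synonym-having pool when it is set, so
  realized frequencies are exact Bernoulli draws at the configured rates.
  Misspellings apply 1–2 edit operations from a configurable mix, never
  touching a token's first character (keeping case normalization
  orthogonal to the distance) and restricted to epithet tokens when the
  genus is simultaneously abbreviated by a format corruption (otherwise
  the abbreviation would erase the edit and the truth label would be
  wrong). Conceptual subtypes are sampled compatibly with the name's rank
  (binomial-only and only-infraspecific require trinomials). Fields are
  populated in a sampled provider style — atomic-only,
  scientificName-only, or both — adjusted where a subtype requires
  specific fields to exist. An `unresolvable_rate` knob (default 0)
  emulates authority incompleteness with off-authority names; such names
  carry no injected issues, since issue labels are undefined for names
  the authority cannot adjudicate.
* **Occurrences.** Per-name occurrence counts are negative-binomial
  (mean 26, size 0.6 — heavy-tailed, matching the skew of real
  aggregator holdings around a mean of ~27 records per name), with
  institution volumes log-normal across 40 institutions, a US-dominated
  country mix, recency-weighted years 1850–2015, and a 3% rate of
  unusable covariate values (junk years, unknown countries,
  non-specimen basisOfRecord) to exercise the exclusion paths.
* **Outcomes.** `simulate_issue_outcomes()` draws Bernoulli outcomes from
  a known logit model over the standardized design; the default
  coefficient vector encodes the qualitative driver structure the models
  should recover (fossils and South American records more issue-prone,
  Amphibia highest and Fishes lowest, fewer issues in recent years and at
  high-volume institutions, reference-class probability ≈ 0.25). By
  default the name-level injection draws are *not* coupled to covariates
  — the bundle's prevalence follows the configured rates exactly, and
  driver-recovery testing uses the simulated outcomes, where truth is
  known. Consequently the analysis scripts' fitted effects on the default
  bundle are correctly near zero, and the exhaustive AIC search correctly
  prefers the no-interaction model there.

Everything is a deterministic function of the seed; two runs with the
same configuration are identical object-for-object and byte-for-byte
through the IO layer.

## Problem sizes used in validation

The test suite and the acceptance script run the detector-fidelity checks
on a 1,000-name bundle at the default rates; the edit-distance oracle
comparison on 10,000 random string pairs up to 12 characters; the join
oracle on instances up to 10³ × 10³; coefficient recovery on 50
replicates of n = 20,000; and interaction recovery with a 3-covariate
pool (2³ = 8 candidate models per replicate, 50 replicates at
n = 20,000), with the full 1,024-model enumeration exercised at smaller n
and in the analysis scripts. These sizes were chosen as the smallest at
which the binomial tolerances quoted in the tests are meaningful.

## Known limitations

* Authorship parsing covers the common "Surname, year" and
  "(Surname, year)" forms; basionym authorship, "ex" authors and sensu
  qualifiers are out of scope, and uncommon forms degrade to
  rank-indeterminate rather than to wrong answers.
* The authority is single-voice; conflicting contemporary treatments and
  multi-source arbitration are not modelled.
* Fuzzy matching is whole-string; per-token matching (genus and epithet
  separately) would catch more compound corruptions and is a deliberate
  non-goal here.
* The region map is country/continent-based; marine localities without a
  country are excluded rather than resolved against ocean polygons.
* Synthetic recall figures are upper bounds for real data, by the
  separation argument above.
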