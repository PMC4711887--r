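# taxonvet

Quality assessment and resolution of the scientific names attached to
digitized biocollections records.

## The problem

Occurrence records mobilized through aggregators carry their taxon names in
six verbatim Darwin Core fields (`scientificName`, `genus`, `subgenus`,
`specificEpithet`, `infraspecificEpithet`, `scientificNameAuthorship`).
Those names were often captured once at accessioning and never revisited:
they arrive misspelled, inconsistently formatted, mapped onto the wrong
Darwin Core fields, or taxonomically out of date. Before such records can
support biodiversity analyses, each distinct *name combination* (a tuple of
the six verbatim fields) has to be audited and, where possible, resolved to
a currently valid canonical name.

`taxonvet` implements that audit as a reusable pipeline over four issue
classes:

| class | meaning | error? |
|---|---|---|
| misspelling | character-level corruption (insertions, deletions, substitutions, adjacent transpositions) | yes |
| format error | mis-capitalization, stray whitespace, abbreviations | yes |
| Darwin Core conceptual error | field-semantics misuse: identification qualifiers ("sp.", "cf.", "?") inside name fields, authorship inside an epithet field, a binomial-only `scientificName` beside a populated infraspecific epithet | yes |
| synonymy | a superseded (junior) name — an issue, but not strictly an error | no |

For each name combination the pipeline builds two candidate strings — a
`constructedscientificname` concatenated from the atomic fields and a
`scientificnameplus` anchored on the composite `scientificName` — and
resolves them against a local, pluggable taxonomic authority: exact match
first, then Damerau–Levenshtein fuzzy match within rank-dependent caps
(2 edits for binomials, 3 for trinomials), with one-hop synonym chasing.
A misspelled junior synonym therefore sets *both* flags. Per-record
rollups obey

    hasError = misspelling ∨ format ∨ conceptual
    hasIssue = hasError ∨ (isSynonym = yes)

Assessments link back to occurrence records by an inner join on the
six-field verbatim key, covariates (basisOfRecord, region, clade, year,
institutional digitized-record volume) are standardized, and issue drivers
are modelled with logistic GLMs — per-issue main-effects models plus
exhaustive AIC ranking over all 2^10 = 1,024 subsets of the two-way
interactions, with McFadden and Nagelkerke pseudo-R².

A seeded synthetic-data generator produces authority banks, issue-injected
name combinations with full truth labels, and occurrence tables, so every
stage is testable against known ground truth.

## Worked example

```r
library(taxonvet)

bundle <- generate_dataset(generator_config(seed = 1, n_names = 300))
assessed <- assess_table(bundle$names, bundle$authority)
linked <- link_occurrences(assessed, bundle$occurrences)
summarize_issues(assessed, linked$matched)
```

```
             category names_n names_pct occurrences_n occurrences_pct
                Total     300     100.0          9344           100.0
     Valid name found     300     100.0          9344           100.0
 Valid name not found       0       0.0             0             0.0
            Has error      90      30.0          2550            27.3
            Has issue     146      48.7          4401            47.1
          Misspelling      33      11.0           960            10.3
         Format error      22       7.3           834             8.9
     Conceptual error      47      15.7          1150            12.3
              Synonym      79      26.3          2579            27.6
        Indeterminate       0       0.0             0             0.0
```

Every generated name resolved to a valid canonical (rows 2–3); about half
carry at least one issue, synonymy being the most common class — the
counts are Bernoulli realizations of the injection rates configured in
`generator_config()`, and the percentages are recomputed from the paired
counts at one decimal. Single calls are just as direct. Resolving a
misspelled junior synonym against a small authority in which *Parus
caeruleus* points to *Cyanistes caeruleus*:

```r
resolve_name("Parus caerulues", "", authority)
#> $validCanonical      "Cyanistes caeruleus"
#> $isSynonym           "yes"
#> $hasMisspelling      TRUE
#> $edit_distance_used  1
#> $comments            "misspelled junior synonym (two-stage resolution)"

project_effort(522163, 4, 100)
#> [1] 20887
```

The last line is the package's effort projection: hand-vetting 522,163
name combinations at the measured rate of 4 hours per 100 records costs
20,887 person-hours — the arithmetic that motivates automating the audit.

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end, writing
tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # seeded bundle: names, occurrences, authority, truth
Rscript analysis/02_assess.R          # assessments + detector recall vs truth
Rscript analysis/03_link_summarize.R  # join, covariates, prevalence + overlap tables
Rscript analysis/04_models.R          # per-issue GLMs + 1,024-model AIC selection
```

Equivalently, `run_pipeline(run_config(...))` executes the same stages on
any input tables and writes a provenance manifest (input hashes, config,
package version); reruns are byte-identical.

## Package layout

- `R/` — IO (`read_name_table`, `read_occurrence_table`,
  `write_assessment_table`), name assembly (`build_constructed_name`,
  `build_scientificname_plus`, `infer_rank`), authority
  (`load_authority`, `edit_distance`, `lookup_fuzzy`), detection and
  resolution (`detect_format_issues`, `detect_conceptual_issues`,
  `resolve_name`, `assess_table`), linking
  (`make_name_key`, `link_occurrences`, `standardize_covariates`),
  summaries (`summarize_issues`, `issue_overlap`, `project_effort`),
  models (`fit_issue_model`, `select_model_aic`, `pseudo_r2`,
  `effect_profile`), and the generator (`generator_config`,
  `generate_dataset`, `corrupt_name`, `simulate_issue_outcomes`).
- `src/` — the Damerau–Levenshtein distance kernel (Rcpp).
- `inst/extdata/country_region_map.tsv` — editable country→region table.
- `vignettes/taxon-name-quality.Rmd` — methods: models, assumptions,
  parameter choices, generator design, limitations.

The assessment table's column order is fixed and documented in
`taxonvet:::ASSESSMENT_COLUMNS` (id, the six verbatim fields, the two
constructed strings and three ranks, the four class flags and two
rollups, granular flags, then resolution output and the vetting tier);
a golden-file test pins it.
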