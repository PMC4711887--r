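# End-to-end orchestration: assemble -> assess -> link -> summarize ->
# model, with a provenance manifest. Each stage consumes and produces the
# documented file formats, so stages remain independently scriptable.

#' Pipeline run configuration
#'
#' @param names_path,occurrences_path,authority_path input tables (see
#'   [read_name_table()], [read_occurrence_table()], [load_authority()]).
#' @param out_dir output directory, created if needed.
#' @param region_map_path optional override of the bundled country-region
#'   mapping.
#' @param assessment an [assessment_config()].
#' @param exclusions name ids excluded from the issue summary rows (e.g.
#'   dual-resolution records).
#' @param fit_models fit the per-issue main-effects models on the linked
#'   covariates (skipped when too few usable occurrences remain).
#' @param select_interactions also run exhaustive AIC selection over
#'   two-way interactions for the has-issue model (the 1,024-model
#'   enumeration; heavier).
#' @param seed integer seed recorded in the manifest and set before any
#'   stochastic step.
#' @return a `run_config` list.
#' @export
run_config <- function(names_path, occurrences_path, authority_path,
                       out_dir,
                       region_map_path = NULL,
                       assessment = assessment_config(),
                       exclusions = character(),
                       fit_models = TRUE,
                       select_interactions = FALSE,
                       seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

validate_run_config <- function(config) {
  paths <- c(names = config$names_path, occurrences = config$occurrences_path,
             authority = config$authority_path)
  if (!is.null(config$region_map_path)) {
    paths <- c(paths, region_map = config$region_map_path)
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    tv_abort(
      sprintf("input path(s) do not exist: %s",
              paste(sprintf("%s (%s)", missing, names(missing)),
                    collapse = ", ")),
      class = "taxonvet_validation_error"
    )
  }
  invisible(config)
}

#' Run the full assessment pipeline
#'
#' Executes assemble, assess, link, summarize and (optionally) model in
#' order, writing each stage's outputs to `out_dir` and finishing with a
#' provenance manifest (input hashes, config snapshot, package version,
#' per-stage row counts). Validation failures abort before any stage
#' runs; a stage failure propagates with the stage name, leaving prior
#' outputs intact. Reruns with identical config and inputs are
#' byte-identical.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with the in-memory stage outputs:
#'   `assessments`, `link`, `covariates`, `summary`, `overlap`, `models`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      tv_abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               class = "taxonvet_stage_error", parent = e)
    })
  }

  names_tbl <- stage("read", read_name_table(config$names_path))
  occurrences <- stage("read", read_occurrence_table(config$occurrences_path))
  authority <- stage("read", load_authority(config$authority_path))
  region_map <- if (is.null(config$region_map_path)) default_region_map()
                else readr::read_tsv(config$region_map_path, col_types = "cc",
                                     progress = FALSE)

  assessments <- stage("assess",
                       assess_table(names_tbl, authority, config$assessment))
  out <- function(f) file.path(config$out_dir, f)
  write_assessment_table(assessments, out("assessments.tsv"))

  link <- stage("link", link_occurrences(assessments, occurrences))
  std <- stage("link", standardize_covariates(link$matched,
                                              region_map = region_map))
  readr::write_tsv(link$name_counts, out("name_counts.tsv"))
  readr::write_tsv(std$exclusions, out("covariate_exclusions.tsv"))
  readr::write_tsv(std$covariates, out("covariates.tsv"))

  summary_tbl <- stage("summarize",
                       summarize_issues(assessments, link$matched,
                                        config$exclusions))
  overlap <- stage("summarize", issue_overlap(
    assessments[!(assessments$id %in% config$exclusions), ]))
  readr::write_tsv(summary_tbl, out("summary.tsv"), na = "")
  readr::write_tsv(overlap, out("issue_overlap.tsv"))

  models <- NULL
  if (isTRUE(config$fit_models) && nrow(std$covariates) >= 200) {
    models <- stage("model", {
      mf <- prepare_model_frame(std$covariates)
      flags <- assessments[match(
        link$matched$id[match(std$covariates$occurrenceID,
                              link$matched$occurrenceID)],
        assessments$id), ]
      mf$hasIssue <- flags$hasIssue
      mf$isSynonym <- flags$isSynonym
      mf$hasMisspelling <- flags$hasMisspelling
      mf$hasConceptualError <- flags$hasConceptualError
      mf$hasFormatError <- flags$hasFormatError
      fits <- fit_per_issue_models(mf)
      ok <- !vapply(fits, inherits, logical(1), "error")
      coefs <- dplyr::bind_rows(lapply(names(fits)[ok], function(r) {
        tibble::add_column(fits[[r]]$coefficients, response = r, .before = 1)
      }))
      readr::write_tsv(coefs, out("model_coefficients.tsv"))
      fit_stats <- dplyr::bind_rows(lapply(names(fits), function(r) {
        f <- fits[[r]]
        if (inherits(f, "error")) {
          tibble::tibble(response = r, n = NA_integer_, logLik = NA_real_,
                         AIC = NA_real_, mcfadden = NA_real_,
                         nagelkerke = NA_real_,
                         status = conditionMessage(f))
        } else {
          tibble::tibble(response = r, n = f$n, logLik = f$logLik,
                         AIC = f$aic, mcfadden = f$mcfadden,
                         nagelkerke = f$nagelkerke, status = "ok")
        }
      }))
      readr::write_tsv(fit_stats, out("model_fit_stats.tsv"), na = "")
      selection <- NULL
      if (isTRUE(config$select_interactions)) {
        selection <- select_model_aic(mf, "hasIssue")
        readr::write_tsv(selection$ranking, out("model_selection.tsv"))
      }
      list(fits = fits, selection = selection)
    })
  }

  manifest <- list(
    tool = "taxonvet",
    version = as.character(utils::packageVersion("taxonvet")),
    seed = config$seed,
    inputs = lapply(
      list(names = config$names_path, occurrences = config$occurrences_path,
           authority = config$authority_path),
      function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    stages = list(
      assess = list(n_names = nrow(assessments)),
      link = list(n_matched = nrow(link$matched),
                  n_unmatched_names = length(link$unmatched_names),
                  n_unmatched_occurrences = length(link$unmatched_occurrences)),
      covariates = list(n_usable = nrow(std$covariates),
                        n_excluded = nrow(std$exclusions)),
      model = list(fitted = !is.null(models))
    ),
    outputs = setdiff(list.files(config$out_dir), "manifest.json")
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(assessments = assessments, link = link,
                 covariates = std, summary = summary_tbl, overlap = overlap,
                 models = models, manifest = manifest))
}
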