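# Logistic GLMs for issue prevalence: main effects of the five
# occurrence-level covariates, exhaustive AIC selection over two-way
# interaction subsets, likelihood-based pseudo-R-squared, and effect
# profiles on the probability scale.

MODEL_RESPONSES <- c("hasIssue", "isSynonym", "hasMisspelling",
                     "hasConceptualError", "hasFormatError")
MODEL_COVARIATES <- c("basisOfRecord", "region", "clade", "year_s",
                      "log_institutionRecords_s")

#' Prepare standardized covariates for modelling
#'
#' Turns a covariate table from [standardize_covariates()] into a
#' modelling frame: factors with documented reference levels
#' (PreservedSpecimen, North America, Aves — the bulk categories), year
#' centered and scaled, and the institutional record count
#' log10-transformed then centered and scaled. Rows with an indeterminate
#' response are dropped by the caller before fitting.
#'
#' @param covariates tibble with `basisOfRecord`, `region`, `clade`,
#'   `year`, `institutionRecords`.
#' @return tibble with factor columns and standardized `year_s`,
#'   `log_institutionRecords_s`; scaling attributes are attached as
#'   `scaling`.
#' @export
prepare_model_frame <- function(covariates) {
  cv <- tibble::as_tibble(covariates)
  out <- tibble::tibble(
    basisOfRecord = stats::relevel(
      factor(cv$basisOfRecord, levels = BASIS_RETAINED), "PreservedSpecimen"),
    region = stats::relevel(
      factor(cv$region, levels = REGIONS), "North America"),
    clade = stats::relevel(factor(cv$clade, levels = CLADES), "Aves")
  )
  yr <- as.numeric(cv$year)
  lg <- log10(pmax(as.numeric(cv$institutionRecords), 1))
  scl <- list(year_center = mean(yr), year_scale = stats::sd(yr),
              log_rec_center = mean(lg), log_rec_scale = stats::sd(lg))
  if (!isTRUE(scl$year_scale > 0)) scl$year_scale <- 1
  if (!isTRUE(scl$log_rec_scale > 0)) scl$log_rec_scale <- 1
  out$year_s <- (yr - scl$year_center) / scl$year_scale
  out$log_institutionRecords_s <- (lg - scl$log_rec_center) / scl$log_rec_scale
  attr(out, "scaling") <- scl
  out
}

model_formula <- function(response, covariates, interactions = character()) {
  terms <- c(covariates, interactions)
  if (length(terms) == 0) terms <- "1"
  as.formula(paste(response, "~", paste(terms, collapse = " + ")))
}

#' Fit a logistic issue model
#'
#' Maximum-likelihood logit fit of a binary issue response on the
#' standardized covariates plus an optional set of two-way interactions.
#' Non-convergence or (quasi-)separation is a structured error naming the
#' offending terms, never a silent result.
#'
#' @param data modelling frame (see [prepare_model_frame()]) with the
#'   response column attached; the response must be 0/1 or logical and
#'   non-constant. Rows with `NA` response (e.g. indeterminate synonymy)
#'   are dropped.
#' @param response response column name.
#' @param covariates main-effect terms (default: all five).
#' @param interactions character vector of `a:b` interaction terms; each
#'   side must appear in `covariates`.
#' @return an `issue_fit`: coefficient table (estimate, std.error),
#'   log-likelihood, AIC, McFadden and Nagelkerke R-squared, n used, and
#'   the fitted `glm` object.
#' @export
fit_issue_model <- function(data, response,
                            covariates = intersect(MODEL_COVARIATES,
                                                   names(data)),
                            interactions = character()) {
  for (ia in interactions) {
    parts <- strsplit(ia, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% covariates)) {
      tv_abort(sprintf("interaction '%s' lacks its main effects", ia),
               class = "taxonvet_model_error")
    }
  }
  df <- as.data.frame(data)
  y <- df[[response]]
  if (is.character(y)) y <- c(yes = 1, no = 0)[y]
  if (is.logical(y)) y <- as.numeric(y)
  df[[response]] <- y
  df <- df[!is.na(y), , drop = FALSE]
  if (nrow(df) == 0 || length(unique(df[[response]])) < 2) {
    tv_abort(sprintf("response '%s' is constant or empty", response),
             class = "taxonvet_model_error")
  }
  fml <- model_formula(response, covariates, interactions)
  fit <- suppressWarnings(glm(fml, family = binomial(), data = df))
  bad <- !fit$converged |
    any(abs(coef(fit)[!is.na(coef(fit))]) > 15)
  if (bad) {
    big <- names(coef(fit))[!is.na(coef(fit)) & abs(coef(fit)) > 15]
    tv_abort(
      sprintf("model for '%s' failed to converge cleanly (suspect terms: %s)",
              response,
              if (length(big)) paste(big, collapse = ", ") else "unknown"),
      class = "taxonvet_model_error"
    )
  }
  null_fit <- glm(model_formula(response, character()), family = binomial(),
                  data = df)
  ll <- as.numeric(logLik(fit))
  ll0 <- as.numeric(logLik(null_fit))
  k <- attr(logLik(fit), "df")
  se <- sqrt(diag(vcov(fit)))
  r2 <- pseudo_r2_from_loglik(ll, ll0, nrow(df))
  structure(
    list(
      response = response,
      covariates = covariates,
      interactions = interactions,
      coefficients = tibble::tibble(
        term = names(coef(fit)),
        estimate = as.numeric(coef(fit)),
        std.error = as.numeric(se[names(coef(fit))])
      ),
      logLik = ll,
      logLik_null = ll0,
      n_params = k,
      aic = -2 * ll + 2 * k,
      mcfadden = r2[["mcfadden"]],
      nagelkerke = r2[["nagelkerke"]],
      n = nrow(df),
      glm = fit
    ),
    class = "issue_fit"
  )
}

#' @export
print.issue_fit <- function(x, ...) {
  cat(sprintf("<issue_fit> %s ~ %s\n", x$response,
              paste(c(x$covariates, x$interactions), collapse = " + ")))
  cat(sprintf("  n = %d, logLik = %.2f, AIC = %.1f, McFadden = %.3f, Nagelkerke = %.3f\n",
              x$n, x$logLik, x$aic, x$mcfadden, x$nagelkerke))
  invisible(x)
}

pseudo_r2_from_loglik <- function(ll, ll0, n) {
  mcf <- 1 - ll / ll0
  cox_snell <- 1 - exp((2 / n) * (ll0 - ll))
  nag <- cox_snell / (1 - exp((2 / n) * ll0))
  c(mcfadden = mcf, nagelkerke = nag)
}

#' Likelihood-based pseudo-R-squared
#'
#' McFadden: `1 - logLik(model)/logLik(null)`. Nagelkerke: Cox-Snell
#' `1 - exp((2/n)(ll0 - ll))` rescaled by its maximum
#' `1 - exp((2/n) ll0)`. The null model must be fitted on the identical
#' observation set.
#'
#' @param model an `issue_fit` (or a fitted `glm`).
#' @param null optional null (intercept-only) fit on the same data; for an
#'   `issue_fit` the stored null log-likelihood is used.
#' @return named vector `c(mcfadden, nagelkerke)`, both in `[0, 1]`.
#' @export
pseudo_r2 <- function(model, null = NULL) {
  if (inherits(model, "issue_fit")) {
    ll <- model$logLik; ll0 <- model$logLik_null; n <- model$n
    if (!is.null(null)) {
      n0 <- if (inherits(null, "issue_fit")) null$n else stats::nobs(null)
      if (n0 != n) {
        tv_abort("model and null were fitted on different observation sets",
                 class = "taxonvet_model_error")
      }
      ll0 <- if (inherits(null, "issue_fit")) null$logLik
             else as.numeric(logLik(null))
    }
  } else {
    if (is.null(null)) {
      tv_abort("a null fit is required for a raw glm",
               class = "taxonvet_model_error")
    }
    if (stats::nobs(model) != stats::nobs(null)) {
      tv_abort("model and null were fitted on different observation sets",
               class = "taxonvet_model_error")
    }
    ll <- as.numeric(logLik(model)); ll0 <- as.numeric(logLik(null))
    n <- stats::nobs(model)
  }
  pseudo_r2_from_loglik(ll, ll0, n)
}

#' Exhaustive AIC selection over two-way interaction subsets
#'
#' Enumerates every subset of the candidate pairwise interactions of the
#' supplied covariates (all `2^C(k,2)` subsets for `k` covariates; 1,024
#' models for the full five-covariate set), fits each, and returns the
#' models ranked AIC-ascending with delta-AIC. A member fit that fails is
#' flagged and ranked last; the run continues.
#'
#' @inheritParams fit_issue_model
#' @param interaction_pool candidate interactions; defaults to all
#'   unordered covariate pairs.
#' @param max_models guard on the enumeration size (default `2^10`).
#' @return list with `ranking` (tibble: interactions, n_interactions,
#'   n_params, logLik, AIC, dAIC, mcfadden, nagelkerke, converged) and
#'   `best` (the top `issue_fit`).
#' @export
select_model_aic <- function(data, response,
                             covariates = intersect(MODEL_COVARIATES,
                                                    names(data)),
                             interaction_pool = NULL,
                             max_models = 1024) {
  if (is.null(interaction_pool)) {
    interaction_pool <- if (length(covariates) >= 2) {
      apply(combn(covariates, 2), 2, paste, collapse = ":")
    } else character()
  }
  k <- length(interaction_pool)
  if (2^k > max_models) {
    tv_abort(sprintf(
      "2^%d candidate models exceed max_models = %d; reduce the pool or raise the cap",
      k, max_models), class = "taxonvet_model_error")
  }
  subsets <- lapply(seq_len(2^k) - 1L, function(bits) {
    interaction_pool[bitwAnd(bits, bitwShiftL(1L, seq_len(k) - 1L)) > 0]
  })

  # members are fitted on a shared precomputed model matrix through
  # glm.fit, keeping only scalar statistics: storing 2^k full glm objects
  # at study scale would be prohibitively heavy
  df <- as.data.frame(data)
  y <- df[[response]]
  if (is.character(y)) y <- c(yes = 1, no = 0)[y]
  if (is.logical(y)) y <- as.numeric(y)
  keep <- !is.na(y)
  df <- df[keep, , drop = FALSE]
  y <- y[keep]
  full_fml <- model_formula(".dummy", c(covariates, interaction_pool))
  X_full <- model.matrix(stats::delete.response(stats::terms(full_fml)),
                         data = df)
  assign_ix <- attr(X_full, "assign")
  term_labels <- attr(stats::terms(full_fml), "term.labels")
  cols_for <- function(ia) {
    which(assign_ix %in% c(0L, match(c(covariates, ia), term_labels)))
  }
  n <- length(y)
  p0 <- mean(y)
  if (n == 0 || p0 == 0 || p0 == 1) {
    tv_abort(sprintf("response '%s' is constant or empty", response),
             class = "taxonvet_model_error")
  }
  ll0 <- n * (p0 * log(p0) + (1 - p0) * log(1 - p0))
  member <- function(ia) {
    tryCatch({
      X <- X_full[, cols_for(ia), drop = FALSE]
      fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
      if (!fit$converged || any(abs(fit$coefficients) > 15, na.rm = TRUE)) {
        stop("did not converge cleanly")
      }
      ll <- -fit$deviance / 2
      kfit <- fit$rank
      r2 <- pseudo_r2_from_loglik(ll, ll0, n)
      c(n_params = kfit, logLik = ll, AIC = -2 * ll + 2 * kfit,
        mcfadden = r2[["mcfadden"]], nagelkerke = r2[["nagelkerke"]])
    }, error = function(e) {
      c(n_params = NA_real_, logLik = NA_real_, AIC = Inf,
        mcfadden = NA_real_, nagelkerke = NA_real_)
    })
  }
  stats_mat <- vapply(subsets, member, numeric(5))
  ranking <- tibble::tibble(
    interactions = vapply(subsets, function(s) {
      if (length(s) == 0) "(none)" else paste(s, collapse = " + ")
    }, character(1)),
    n_interactions = lengths(subsets),
    n_params = as.integer(stats_mat["n_params", ]),
    logLik = stats_mat["logLik", ],
    AIC = stats_mat["AIC", ],
    mcfadden = stats_mat["mcfadden", ],
    nagelkerke = stats_mat["nagelkerke", ],
    converged = is.finite(stats_mat["AIC", ])
  )
  ord <- order(ranking$AIC)
  ranking <- ranking[ord, ]
  ranking$dAIC <- ranking$AIC - min(ranking$AIC[ranking$converged])
  best_ia <- subsets[ord][[1]]
  list(ranking = ranking,
       best = fit_issue_model(data, response, covariates, best_ia))
}

#' Predicted-probability profile of one predictor
#'
#' Inverse-logit of the linear predictor over a grid of the focal
#' predictor, with the remaining covariates held at their reference level
#' (factors) or zero (standardized numerics) unless overridden through
#' `at`. Confidence bands are delta-method (normal on the link scale,
#' back-transformed). Grid points outside the observed range are annotated
#' with a warning flag, not rejected.
#'
#' @param model an `issue_fit`.
#' @param focal focal predictor name.
#' @param grid values of the focal predictor; defaults to the factor
#'   levels or an 25-point span of the observed range.
#' @param at named list of fixed values for other covariates.
#' @param level confidence level for the bands (default 0.95).
#' @return tibble: focal value, `prob`, `lower`, `upper`,
#'   `outside_observed_range`.
#' @export
effect_profile <- function(model, focal, grid = NULL, at = list(),
                           level = 0.95) {
  fit <- model$glm
  mf <- fit$model
  if (!(focal %in% names(mf))) {
    tv_abort(sprintf("'%s' is not a model predictor", focal),
             class = "taxonvet_model_error")
  }
  obs <- mf[[focal]]
  if (is.null(grid)) {
    grid <- if (is.factor(obs)) levels(obs)
            else seq(min(obs), max(obs), length.out = 25)
  }
  newdata <- as.data.frame(lapply(
    mf[setdiff(names(mf), c(focal, model$response))],
    function(col) {
      if (is.factor(col)) factor(levels(col)[1], levels = levels(col))
      else 0
    }))
  if (nrow(newdata) == 0) newdata <- data.frame(row.names = 1)
  newdata <- newdata[rep(1, length(grid)), , drop = FALSE]
  newdata[[focal]] <- if (is.factor(obs)) factor(grid, levels = levels(obs))
                      else grid
  for (nm in names(at)) {
    newdata[[nm]] <- if (is.factor(mf[[nm]]))
      factor(at[[nm]], levels = levels(mf[[nm]])) else at[[nm]]
  }
  pr <- predict(fit, newdata = newdata, type = "link", se.fit = TRUE)
  pr$fit <- unname(pr$fit)
  pr$se.fit <- unname(pr$se.fit)
  z <- stats::qnorm(1 - (1 - level) / 2)
  outside <- if (is.factor(obs)) !(grid %in% unique(as.character(obs)))
             else grid < min(obs) | grid > max(obs)
  tibble::tibble(
    !!focal := grid,
    prob = plogis(pr$fit),
    lower = plogis(pr$fit - z * pr$se.fit),
    upper = plogis(pr$fit + z * pr$se.fit),
    outside_observed_range = outside
  )
}

#' Fit per-issue main-effects models
#'
#' One main-effects-only logistic model per issue response (the
#' interaction structure of the overall has-issue model complicates
#' comparative conclusions, so per-issue models stay additive).
#' Indeterminate synonymy rows enter the synonymy model as `NA` and are
#' dropped by the fitter.
#'
#' @param data modelling frame with all response columns attached.
#' @param responses responses to fit (default all five).
#' @return named list of `issue_fit` objects; a response whose fit fails
#'   (separation, constant response) is carried as the error condition
#'   itself, so failures are reported rather than silently dropped.
#' @export
fit_per_issue_models <- function(data, responses = MODEL_RESPONSES) {
  out <- lapply(responses, function(r) {
    tryCatch(fit_issue_model(data, r), taxonvet_model_error = function(e) e)
  })
  names(out) <- responses
  out
}
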