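# Logistic driver models: closed-form checks, AIC identity, pseudo-R2
# arithmetic, exhaustive interaction enumeration.

test_that("intercept-only fit recovers logit of the response mean", {
  set.seed(11)
  d <- tibble::tibble(y = rbinom(500, 1, 0.3))
  f <- fit_issue_model(d, "y", covariates = character())
  expect_equal(unname(f$coefficients$estimate[1]), qlogis(mean(d$y)),
               tolerance = 1e-6)
  expect_equal(unname(pseudo_r2(f)), c(0, 0))
})

test_that("a constant response is a structured precondition error", {
  d <- tibble::tibble(y = rep(1, 50))
  expect_error(fit_issue_model(d, "y", covariates = character()),
               class = "taxonvet_model_error")
})

test_that("AIC identity holds and is recomputed independently", {
  set.seed(12)
  mf <- random_covariates(2000)
  mf <- prepare_model_frame(mf)
  mf$y <- simulate_issue_outcomes(mf)
  f <- fit_issue_model(mf, "y")
  expect_equal(f$aic, -2 * f$logLik + 2 * f$n_params)
  expect_equal(f$aic, as.numeric(AIC(f$glm)))
  expect_true(f$mcfadden >= 0 && f$mcfadden <= 1)
  expect_true(f$nagelkerke >= 0 && f$nagelkerke <= 1)
})

test_that("pseudo-R2 formulas match direct log-likelihood arithmetic on a 20-row fixture", {
  # 20 observations, binary predictor: x=0 has 2/10 successes, x=1 has 7/10
  d <- tibble::tibble(
    x = factor(rep(c("a", "b"), each = 10)),
    y = c(rep(c(1, 0), c(2, 8)), rep(c(1, 0), c(7, 3)))
  )
  f <- fit_issue_model(d, "y", covariates = "x")
  # hand-computed group MLE log-likelihoods
  ll_model <- 2 * log(0.2) + 8 * log(0.8) + 7 * log(0.7) + 3 * log(0.3)
  ll_null <- 9 * log(0.45) + 11 * log(0.55)
  expect_equal(f$logLik, ll_model, tolerance = 1e-6)
  expect_equal(f$logLik_null, ll_null, tolerance = 1e-6)
  r2 <- pseudo_r2(f)
  expect_equal(unname(r2["mcfadden"]), 1 - ll_model / ll_null,
               tolerance = 1e-6)
  cs <- 1 - exp((2 / 20) * (ll_null - ll_model))
  expect_equal(unname(r2["nagelkerke"]), cs / (1 - exp((2 / 20) * ll_null)),
               tolerance = 1e-6)
})

test_that("pseudo-R2 rejects mismatched observation sets and rewards strong signal", {
  set.seed(13)
  x <- rnorm(4000)
  d <- tibble::tibble(x = x, y = rbinom(4000, 1, plogis(4 * x)))
  f <- fit_issue_model(d, "y", covariates = "x")
  r2 <- pseudo_r2(f)
  expect_gt(r2[["mcfadden"]], 0.5)
  expect_gt(r2[["nagelkerke"]], 0.5)

  g1 <- glm(y ~ x, binomial(), data = d)
  g0 <- glm(y ~ 1, binomial(), data = d[1:100, ])
  expect_error(pseudo_r2(g1, g0), class = "taxonvet_model_error")
})

test_that("interaction enumeration covers every subset of candidate pairs", {
  set.seed(14)
  mf <- prepare_model_frame(random_covariates(600))
  mf$y <- simulate_issue_outcomes(mf)
  sel <- select_model_aic(mf, "y",
                          covariates = c("clade", "year_s",
                                         "log_institutionRecords_s"))
  expect_equal(nrow(sel$ranking), 2^choose(3, 2))
  expect_true(!is.unsorted(sel$ranking$AIC))
  expect_equal(sel$ranking$dAIC[1], 0)

  # the full five-covariate pool enumerates 2^10 models
  sel_full <- select_model_aic(mf, "y")
  expect_equal(nrow(sel_full$ranking), 1024)
  expect_equal(sort(unique(sel_full$ranking$n_interactions)), 0:10)
})

test_that("adding an interaction never decreases the log-likelihood", {
  set.seed(15)
  mf <- prepare_model_frame(random_covariates(3000))
  mf$y <- simulate_issue_outcomes(mf)
  base <- fit_issue_model(mf, "y")
  for (ia in c("basisOfRecord:year_s", "clade:year_s",
               "region:log_institutionRecords_s")) {
    bigger <- fit_issue_model(mf, "y", interactions = ia)
    expect_gte(bigger$logLik, base$logLik - 1e-8)
  }
})

test_that("coefficient bias shrinks as the sample grows", {
  true_b <- default_true_coefficients()
  bias_at <- function(n, seeds) {
    mean(vapply(seeds, function(s) {
      set.seed(s)
      mf <- prepare_model_frame(random_covariates(n))
      mf$y <- simulate_issue_outcomes(mf)
      f <- fit_issue_model(mf, "y")
      est <- setNames(f$coefficients$estimate, f$coefficients$term)
      mean(abs(est[names(true_b)] - true_b))
    }, numeric(1)))
  }
  expect_lt(bias_at(20000, 1:4), bias_at(2000, 1:4))
})

test_that("effect profiles equal direct inverse-logit arithmetic", {
  set.seed(16)
  d <- tibble::tibble(x = rnorm(2000))
  d$y <- rbinom(2000, 1, plogis(0.2 + 1 * d$x))
  f <- fit_issue_model(d, "y", covariates = "x")
  prof <- effect_profile(f, "x", grid = c(-1, 0, 1, 99))
  b <- setNames(f$coefficients$estimate, f$coefficients$term)
  expect_equal(prof$prob, plogis(b["(Intercept)"] + b["x"] * c(-1, 0, 1, 99)),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_true(all(diff(prof$prob) > 0))  # monotone in a positive slope
  expect_identical(prof$outside_observed_range, c(FALSE, FALSE, FALSE, TRUE))
  expect_true(all(prof$lower <= prof$prob & prof$prob <= prof$upper))

  # factor profile at reference levels matches coefficient arithmetic
  mf <- prepare_model_frame(random_covariates(3000))
  mf$y <- simulate_issue_outcomes(mf)
  fm <- fit_issue_model(mf, "y")
  bm <- setNames(fm$coefficients$estimate, fm$coefficients$term)
  pr <- effect_profile(fm, "clade")
  expect_equal(pr$prob[pr$clade == "Aves"],
               unname(plogis(bm["(Intercept)"])), tolerance = 1e-10)
  expect_equal(pr$prob[pr$clade == "Fishes"],
               unname(plogis(bm["(Intercept)"] + bm["cladeFishes"])),
               tolerance = 1e-10)
})
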