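fake_records <- function(n = 31, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    participant_id = sprintf("P%02d", 1:n),
    cadence = rnorm(n, 95, 15),
    si_step_time = abs(rnorm(n, 0.15, 0.08)),
    cv_step_time = abs(rnorm(n, 0.1, 0.04)),
    avg_step_width = rnorm(n, 0.6, 0.15),
    cv_step_width = abs(rnorm(n, 0.15, 0.05)),
    avg_emos = rnorm(n, 0.25, 0.08),
    min_emos = rnorm(n, 0.15, 0.08),
    poma_gait = sample(4:12, n, replace = TRUE),
    poma_balance = sample(2:14, n, replace = TRUE),
    n_falls = rpois(n, 1.5),
    exposure_days = runif(n, 20, 70)
  )
}

test_that("a noiseless linear outcome is recovered exactly", {
  rec <- fake_records()
  rec$poma_gait <- 2 * rec$cadence + 1
  fit <- suppressWarnings(univariate_linear(rec, "cadence", "poma_gait"))
  td <- suppressWarnings(tidy(fit))
  expect_equal(td$estimate[td$term == "cadence"], 2, tolerance = 1e-9)
  expect_equal(suppressWarnings(glance(fit))$r2, 1, tolerance = 1e-9)
})

test_that("a constant outcome yields slope 0 and R2 reported as 0", {
  rec <- fake_records()
  rec$poma_gait <- 7
  fit <- suppressWarnings(univariate_linear(rec, "cadence", "poma_gait"))
  td <- suppressWarnings(tidy(fit))
  expect_equal(td$estimate[td$term == "cadence"], 0, tolerance = 1e-12)
  expect_equal(suppressWarnings(glance(fit))$r2, 0)
})

test_that("a zero-variance feature raises a degenerate-design error", {
  rec <- fake_records()
  rec$cadence <- 95
  expect_error(univariate_linear(rec, "cadence", "poma_gait"),
               class = "gaitvision_degenerate")
  expect_error(univariate_poisson(rec, "cadence"),
               class = "gaitvision_degenerate")
})

test_that("the OLS slope CI covers the truth at its nominal rate", {
  n <- 31
  cover <- vapply(1:1000, function(s) {
    set.seed(s)
    x <- rnorm(n)
    y <- 2 * x + rnorm(n, 0, 1.5)
    rec <- tibble::tibble(participant_id = as.character(1:n),
                          cadence = x, poma_gait = y)
    td <- tidy(univariate_linear(rec, "cadence", "poma_gait"))
    sl <- td[td$term == "cadence", ]
    crit <- stats::qt(0.975, n - 2)
    (2 >= sl$estimate - crit * sl$std.error) &&
      (2 <= sl$estimate + crit * sl$std.error)
  }, logical(1))
  expect_gte(mean(cover), 0.93)
})

test_that("the intercept-only Poisson rate is total falls over total exposure", {
  rec <- tibble::tibble(
    participant_id = c("a", "b", "c"),
    n_falls = c(2, 0, 4),
    exposure_days = c(10, 20, 10)
  )
  fit <- univariate_poisson(rec, NULL)
  expect_equal(unname(coef(fit$fit)[1]), log(6 / 40), tolerance = 1e-8)
})

test_that("scaling exposures shifts only the Poisson intercept by -log c", {
  rec <- fake_records(seed = 4)
  f1 <- univariate_poisson(rec, "cadence")
  rec2 <- dplyr::mutate(rec, exposure_days = exposure_days * 2)
  f2 <- univariate_poisson(rec2, "cadence")
  c1 <- coef(f1$fit)
  c2 <- coef(f2$fit)
  expect_equal(unname(c2["(Intercept)"] - c1["(Intercept)"]), -log(2),
               tolerance = 1e-6)
  expect_equal(unname(c2["cadence"]), unname(c1["cadence"]),
               tolerance = 1e-8)
})

test_that("the Poisson coefficient estimator is unbiased at the simulated effect size", {
  est <- vapply(1:60, function(s) {
    sim <- simulate_cohort(cohort_sim_params(
      seed = s,
      beta = c(cadence = 0.03, si_step_time = 0, cv_step_time = 0,
               avg_step_width = 0, cv_step_width = 0, avg_emos = 0,
               min_emos = 0)
    ))
    td <- tidy(univariate_poisson(sim$records, "cadence"))
    td$estimate[td$term == "cadence"]
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.03), 0.01)
})

test_that("pseudo-R2 is 1 for a saturated fit and 0 for the null model", {
  rec <- fake_records(n = 8, seed = 2)
  sat <- glm(n_falls ~ factor(participant_id) + offset(log(exposure_days)),
             family = poisson(), data = rec)
  expect_equal(pseudo_r2(sat)$r2, 1, tolerance = 1e-9)
  null_fit <- univariate_poisson(rec, NULL)
  expect_equal(pseudo_r2(null_fit)$r2, 0, tolerance = 1e-12)
})

test_that("pseudo-R2 matches deviances computed directly from the likelihood", {
  rec <- tibble::tibble(
    participant_id = letters[1:5],
    cadence = c(80, 90, 100, 110, 120),
    n_falls = c(0, 1, 1, 3, 5),
    exposure_days = c(30, 45, 40, 50, 35)
  )
  fit <- univariate_poisson(rec, "cadence")
  got <- pseudo_r2(fit)

  # direct deviance oracle: D = 2 * sum(y log(y/mu) - (y - mu))
  dev_of <- function(mu) {
    term <- ifelse(rec$n_falls > 0, rec$n_falls * log(rec$n_falls / mu), 0)
    2 * sum(term - (rec$n_falls - mu))
  }
  mu_fit <- fitted(fit$fit)
  mu_null <- rec$exposure_days * sum(rec$n_falls) / sum(rec$exposure_days)
  r2_oracle <- 1 - dev_of(mu_fit) / dev_of(mu_null)
  expect_equal(got$r2, r2_oracle, tolerance = 1e-8)
  n <- 5
  k <- 1
  expect_equal(got$adjusted_r2, 1 - (1 - r2_oracle) * (n - 1) / (n - k - 1),
               tolerance = 1e-8)
})

test_that("multivariate selection keeps significant features and prunes collinear pairs", {
  # one clearly significant feature -> model equals the univariate fit
  set.seed(11)
  sim <- simulate_cohort(cohort_sim_params(
    seed = 11,
    beta = c(cadence = 0.04, si_step_time = 0, cv_step_time = 0,
             avg_step_width = 0, cv_step_width = 0, avg_emos = 0,
             min_emos = 0),
    corr = diag(7) |>
      `dimnames<-`(list(gait_feature_names(), gait_feature_names()))
  ))
  multi <- build_multivariate(sim$records)
  if (identical(multi$predictors, "cadence")) {
    uni <- univariate_poisson(sim$records, "cadence")
    expect_equal(coef(multi$fit), coef(uni$fit), tolerance = 1e-9)
  }

  # hand-built: two collinear significant features, stronger one kept
  rec <- fake_records(seed = 21)
  set.seed(99)
  rec$avg_emos <- rnorm(31, 0.25, 0.08)
  rec$min_emos <- rec$avg_emos - 0.1 + rnorm(31, 0, 0.01) # r ~ 0.99
  rec$n_falls <- rpois(31, rec$exposure_days *
                         exp(log(0.03) - 6 * (rec$avg_emos - 0.25)))
  univ <- purrr::map(
    rlang::set_names(gait_feature_names()),
    ~ univariate_poisson(rec, .x)
  )
  multi2 <- build_multivariate(rec, univariate = univ)
  expect_true(all(c("avg_emos", "min_emos") %in%
                    multi2$selection$significant))
  expect_true(xor("avg_emos" %in% multi2$predictors,
                  "min_emos" %in% multi2$predictors))
  emos_kept <- intersect(multi2$predictors, c("avg_emos", "min_emos"))
  emos_dropped <- setdiff(c("avg_emos", "min_emos"), emos_kept)
  r2s <- multi2$selection$univariate_r2
  expect_true(emos_dropped %in% multi2$selection$dropped_collinear)
  expect_gte(r2s[[emos_kept]], r2s[[emos_dropped]])
})

test_that("no significant features yields an intercept-only report, not an error", {
  sim <- simulate_cohort(cohort_sim_params(
    seed = 40,
    beta = c(cadence = 0, si_step_time = 0, cv_step_time = 0,
             avg_step_width = 0, cv_step_width = 0, avg_emos = 0,
             min_emos = 0)
  ))
  multi <- build_multivariate(sim$records, alpha = 1e-6)
  expect_identical(multi$predictors, character())
  expect_match(multi$note, "intercept-only")
})
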