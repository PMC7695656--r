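test_that("with no between-person heterogeneity the fit collapses to a GLM", {
  sim <- model_test_cohort(500, seed = 61,
                           coefs = c(time = log(0.74),
                                     score_traditional = log(0.6)),
                           ri_sd = 0)
  tbl <- sim$cohort
  fit <- fit_logistic_mixed(tbl, fast_spec("score_traditional", seed = 3))
  s <- fit$summary
  # the intercept-SD posterior concentrates near zero (relative to its
  # half-normal prior scale of 2)
  expect_lt(s$estimate[s$term == "sd_random_intercept"], 0.4)
  expect_lt(s$ci_lower[s$term == "sd_random_intercept"], 0.05)
  # fixed effect matches an ordinary logistic fit within Monte-Carlo error
  g <- glm(steatosis ~ scale(score_traditional), binomial(), data = tbl)
  se <- summary(g)$coefficients[2, 2] / sd(tbl$score_traditional)
  bhat <- coef(g)[2] / sd(tbl$score_traditional)
  post <- log(s$estimate[s$term == "score_traditional"])
  expect_lt(abs(post - bhat), 2 * se)
})

test_that("fits are reproducible from the seed", {
  tbl <- model_test_cohort(150, seed = 62)$cohort
  sp <- fast_spec("score_veg_fish", seed = 7)
  f1 <- fit_logistic_mixed(tbl, sp)
  f2 <- fit_logistic_mixed(tbl, sp)
  expect_equal(f1$summary, f2$summary, tolerance = 1e-12)
  f3 <- fit_logistic_mixed(tbl, fast_spec("score_veg_fish", seed = 8))
  expect_false(isTRUE(all.equal(f1$summary$estimate, f3$summary$estimate)))
})

test_that("back-transformed coefficients are invariant to covariate rescaling", {
  tbl <- model_test_cohort(200, seed = 63)$cohort
  sp <- model_spec("nafld", exposures = "score_veg_fish",
                   covariates = c("age", "energy"), n_chains = 1,
                   n_adapt = 150, n_burn = 150, n_iter = 300, seed = 4)
  f1 <- fit_logistic_mixed(tbl, sp)
  tbl2 <- tbl
  tbl2$energy <- tbl2$energy / 100       # per-100-kcal units
  f2 <- fit_logistic_mixed(tbl2, sp)
  b1 <- log(f1$summary$estimate[f1$summary$term == "energy"])
  b2 <- log(f2$summary$estimate[f2$summary$term == "energy"])
  # identical standardized problem and seed: exact equality after rescale
  expect_equal(b2 / 100, b1, tolerance = 1e-10)
  others <- c("(Intercept)", "age", "score_veg_fish")
  expect_equal(f1$summary$estimate[f1$summary$term %in% others],
               f2$summary$estimate[f2$summary$term %in% others],
               tolerance = 1e-10)
})

test_that("extraction without missing data returns identical copies", {
  tbl <- model_test_cohort(100, seed = 64)$cohort
  fit <- fit_logistic_mixed(tbl, fast_spec("score_traditional", seed = 2))
  imps <- extract_imputations(fit, m = 5)
  expect_length(imps, 5)
  for (d in imps) expect_identical(d, fit$data)
  expect_error(extract_imputations(fit, m = 1e6), "exceeds")
})

test_that("imputation draws fill every hole and vary across extractions", {
  sim <- generate_cohort(sim_config(n_participants = 250, seed = 65,
                                    exclusion_rates = c(no_ultrasound = 0),
                                    dropout_rate = 0))
  tbl <- sim$cohort
  expect_gt(sum(is.na(tbl$education)), 2)
  fit <- fit_logistic_mixed(tbl, fast_spec("score_traditional",
                                           covariates = "model1", seed = 5))
  imps <- extract_imputations(fit, m = 10)
  expect_true(all(vapply(imps, function(d)
    !anyNA(d[c("education", "physical_activity")]), TRUE)))
  # observed cells are untouched; imputed cells vary across draws
  obs <- !is.na(tbl$education)
  tbl_sorted <- fit$data
  for (d in imps)
    expect_identical(d$education[!is.na(tbl_sorted$education)],
                     tbl_sorted$education[!is.na(tbl_sorted$education)])
  filled <- vapply(imps, function(d)
    d$education[is.na(tbl_sorted$education)][1], numeric(1))
  expect_gt(length(unique(filled)), 1)
  # extraction is deterministic for a given fit
  expect_identical(extract_imputations(fit, m = 10), imps)
})

test_that("pooling identical fits reproduces the single-fit summary", {
  tbl <- model_test_cohort(100, seed = 66)$cohort
  fit <- fit_logistic_mixed(tbl, fast_spec("score_veg_fish", seed = 6))
  pooled <- pool_fits(list(fit, fit, fit))
  cols <- c("estimate", "ci_lower", "ci_upper")
  expect_equal(pooled$summary[cols], fit$summary[cols], tolerance = 1e-12)
  # tail probabilities agree up to the 1/draws floor
  expect_equal(pooled$summary$tail_prob, fit$summary$tail_prob,
               tolerance = 2e-3)
})

test_that("pooled intervals span chains with disjoint support", {
  tbl <- model_test_cohort(100, seed = 66)$cohort
  fit <- fit_logistic_mixed(tbl, fast_spec("score_veg_fish", seed = 6))
  shifted <- fit
  shifted$samples <- coda::as.mcmc.list(lapply(fit$samples, function(ch)
    coda::mcmc(as.matrix(ch) + 10, start = start(ch))))
  pooled <- pool_fits(list(fit, shifted))
  i <- which(pooled$summary$term == "score_veg_fish")
  lo <- log(pooled$summary$ci_lower[i]); hi <- log(pooled$summary$ci_upper[i])
  orig <- log(fit$summary$estimate[i])
  expect_lt(lo, orig + 0.5)
  expect_gt(hi, orig + 9)
})

test_that("pooling refuses structurally different fits", {
  tbl <- model_test_cohort(80, seed = 67)$cohort
  f1 <- fit_logistic_mixed(tbl, fast_spec("score_veg_fish", seed = 1))
  f2 <- fit_logistic_mixed(tbl, fast_spec("score_traditional", seed = 1))
  expect_error(pool_fits(list(f1, f2)), "different model structure")
})

test_that("interaction screening: null verdict and exact refit on complete data", {
  tbl <- model_test_cohort(250, seed = 68,
                           coefs = c(time = log(0.74)))$cohort
  sp <- model_spec("nafld", exposures = "score_traditional",
                   covariates = c("age", "time"),
                   interactions = "diet_time", n_chains = 2,
                   n_adapt = 200, n_burn = 200, n_iter = 400, seed = 11)
  scr <- screen_interactions(tbl, sp)
  expect_equal(scr$verdicts$term, "score_traditional:time")
  expect_false(scr$verdicts$relevant)
  # with no missing data the refit equals a direct no-interaction fit
  sp0 <- sp; sp0$interactions <- character()
  direct <- fit_logistic_mixed(tbl, sp0)
  expect_equal(scr$fit$summary, direct$summary, tolerance = 1e-12)
})

test_that("the BMI mixed model recovers a diet-dependent time slope", {
  sim <- generate_cohort(sim_config(
    n_participants = 500, seed = 69,
    bmi_time_coefficients = c(score_traditional = -1.2),
    missingness_rates = c(education = 0), dropout_rate = 0,
    exclusion_rates = c(no_ultrasound = 0)))
  sp <- model_spec("bmi", exposures = "score_traditional",
                   covariates = c("age", "time"),
                   interactions = "diet_time", n_chains = 2,
                   n_adapt = 300, n_burn = 300, n_iter = 600, seed = 12)
  fit <- fit_bmi_lmm(sim$cohort, sp)
  s <- fit$summary
  i <- s$term == "score_traditional:time"
  expect_lt(s$estimate[i], 0)                 # sign recovered
  expect_lt(s$ci_upper[i], 0)                 # clearly non-null
})

test_that("the univariable screen recovers a per-SD odds ratio", {
  set.seed(70)
  n <- 5000
  X <- generate_foodgroups(n, reference_loadings(), mode = "positive",
                           seed = 71)
  nut <- derive_nutrients(X)
  base <- data.frame(X, nut, check.names = FALSE)
  adj <- energy_residual(base$fg_fruit, base$energy)
  z <- (adj - mean(adj)) / sd(adj)
  base$steatosis <- rbinom(n, 1, plogis(-0.6 + log(1.6) * z))
  scr <- univariable_foodgroup_screen(base)
  expect_equal(scr$or_per_sd[scr$group == "fruit"], 1.6, tolerance = 0.1)
  # an outcome-independent group sits near the null
  expect_equal(scr$or_per_sd[scr$group == "coffee"], 1, tolerance = 0.12)
  # changing a group's unit leaves the per-SD estimate untouched
  base2 <- base
  base2$fg_tea <- base2$fg_tea * 2
  scr2 <- univariable_foodgroup_screen(base2, groups = "tea")
  expect_equal(scr2$or_per_sd,
               scr$or_per_sd[scr$group == "tea"], tolerance = 1e-10)
  # constant groups are flagged, not fitted
  base3 <- base
  base3$fg_soy <- 0
  scr3 <- univariable_foodgroup_screen(base3, groups = "soy")
  expect_true(scr3$skipped)
  expect_true(is.na(scr3$or_per_sd))
})

test_that("specification guards reject invalid requests", {
  expect_error(model_spec("nafld", "mds", covariates = "model1",
                          interactions = "diet_bmi"), "model2")
  tbl <- model_test_cohort(50, seed = 72)$cohort
  tbl$steatosis[3] <- NA
  expect_error(fit_logistic_mixed(tbl, fast_spec("score_veg_fish")),
               "outcome")
  tbl2 <- model_test_cohort(50, seed = 72)$cohort
  tbl2$score_veg_fish[5] <- NA
  expect_error(fit_logistic_mixed(tbl2, fast_spec("score_veg_fish")),
               "exposures")
})
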