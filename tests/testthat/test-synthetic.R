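test_that("cohort generation is deterministic given the seed", {
  cfg <- sim_config(n_participants = 80, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth$outcome_coefficients, b$truth$outcome_coefficients)
  c <- generate_cohort(sim_config(n_participants = 80, seed = 12))
  expect_false(identical(a$cohort$steatosis, c$cohort$steatosis))
})

test_that("a degenerate config yields complete two-visit data", {
  cfg <- sim_config(n_participants = 60, seed = 2,
                    missingness_rates = c(education = 0),
                    dropout_rate = 0,
                    exclusion_rates = c(te_failure = 0))
  tbl <- generate_cohort(cfg)$cohort
  expect_equal(sum(is.na(tbl[c("education", "physical_activity",
                               "smoking")])), 0)
  expect_true(all(table(tbl$id) == 2))
  expect_true(all(tbl$lsm > 0))
})

test_that("realized baseline prevalence matches the configured marginal", {
  sim <- generate_cohort(sim_config(n_participants = 1000, seed = 5))
  base <- sim$cohort[sim$cohort$visit == 1, ]
  expect_lt(abs(mean(base$steatosis) - 0.356), 0.05)
  # the solved intercept reproduces the configured marginal exactly
  tr <- sim$truth
  p <- plogis(tr$outcome_coefficients[["(Intercept)"]] +
                tr$random_intercepts[base$id])
  expect_equal(mean(p), 0.356, tolerance = 1e-6)
})

test_that("positive-mode intakes are non-negative and median-calibrated", {
  X <- generate_foodgroups(4000, reference_loadings(), mode = "positive",
                           seed = 3)
  expect_true(all(X >= 0))
  med <- apply(X, 2, median)
  ref <- reference_intakes()
  # softplus calibration: median within 10% of the reference for the
  # larger groups (small groups are relatively noisier)
  big <- ref >= 20
  expect_true(all(abs(med[big] / ref[big] - 1) < 0.10))
})

test_that("linear-mode sample correlation converges to the factor model", {
  L <- reference_loadings()
  X <- generate_foodgroups(50000, L, mode = "linear", seed = 7)
  R <- cor(X)
  target <- tcrossprod(L) + diag(pmax(1 - rowSums(L^2), 1e-6))
  expect_lt(max(abs(R - target)), 0.02)
})

test_that("a single shared factor gives the closed-form correlation", {
  L <- matrix(0, 28, 1, dimnames = list(food_groups(), "f1"))
  L[1:2, 1] <- 0.8
  X <- generate_foodgroups(50000, L, mode = "linear", seed = 9)
  expect_equal(cor(X[, 1], X[, 2]), 0.64, tolerance = 0.02)
  # null loadings: off-diagonal correlations vanish
  X0 <- generate_foodgroups(50000, L * 0, mode = "linear", seed = 9)
  R0 <- cor(X0)
  expect_lt(max(abs(R0[upper.tri(R0)])), 0.03)
})

test_that("over-factored loading matrices are refused", {
  L <- matrix(0.1, 28, 28)
  expect_error(generate_foodgroups(10, L, seed = 1), "over-factored")
  expect_error(sim_config(loadings = L), "over-factored")
})

test_that("missingness injection hits the requested marginal rate", {
  sim <- generate_cohort(sim_config(n_participants = 963, seed = 21,
                                    missingness_rates = c(smoking = 0),
                                    dropout_rate = 0,
                                    exclusion_rates = c(te_failure = 0)))
  tbl <- inject_missingness(sim$cohort, c(smoking = 0.057), seed = 4)
  base <- tbl[tbl$visit == 1, ]
  n_miss <- sum(is.na(base$smoking))
  # expected 55 of 963; allow 3 binomial SDs
  expect_lt(abs(n_miss - 0.057 * 963), 3 * sqrt(963 * 0.057 * 0.943))
  # missingness is participant-constant across visits
  fu <- tbl[tbl$visit == 2, ]
  expect_identical(is.na(base$smoking)[match(fu$id, base$id)],
                   is.na(fu$smoking))
})

test_that("rate zero leaves the table unchanged; exposures are protected", {
  sim <- generate_cohort(sim_config(n_participants = 50, seed = 3,
                                    missingness_rates = c(smoking = 0)))
  out <- inject_missingness(sim$cohort, c(education = 0), seed = 1)
  expect_identical(out, sim$cohort)
  expect_error(inject_missingness(sim$cohort, c(steatosis = 0.1)),
               "only covariates")
  expect_error(inject_missingness(sim$cohort, c(fg_fruit = 0.1)),
               "only covariates")
  expect_error(inject_missingness(sim$cohort, c(nonexistent = 0.1)),
               "unknown column")
})

test_that("MAR missingness on age changes rates across age terciles", {
  sim <- generate_cohort(sim_config(n_participants = 2000, seed = 31,
                                    missingness_rates = c(education = 0),
                                    dropout_rate = 0))
  tbl <- inject_missingness(sim$cohort, c(education = 0.3), seed = 2,
                            predictor = "age", slope = 1.5)
  base <- tbl[tbl$visit == 1, ]
  terc <- cut(base$age, quantile(base$age, c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE)
  rates <- tapply(is.na(base$education), terc, mean)
  expect_true(rates[[1]] < rates[[2]] && rates[[2]] < rates[[3]])
  mech <- attr(tbl, "missingness")
  expect_equal(mech$education$mechanism, "MAR")
})

test_that("ground truth records the generating parameters", {
  cfg <- sim_config(n_participants = 40, seed = 8,
                    outcome_coefficients = c(time = log(0.74),
                                             score_veg_fish = log(0.6)))
  tr <- generate_cohort(cfg)$truth
  expect_identical(tr$loadings, cfg$loadings)
  expect_equal(tr$outcome_coefficients[["score_veg_fish"]], log(0.6))
  expect_equal(tr$random_intercept_sd, cfg$random_intercept_sd)
  expect_length(tr$random_intercepts, 40)
})

test_that("cohort round-trips through the CSV/JSON/YAML writers", {
  dir <- withr::local_tempdir()
  sim <- generate_cohort(sim_config(n_participants = 25, seed = 13))
  paths <- write_cohort(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[["cohort"]])
  expect_equal(nrow(back), nrow(sim$cohort))
  tr <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(tr$random_intercept_sd, 5.5)
})
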