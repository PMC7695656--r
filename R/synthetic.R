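#' Configuration for the synthetic cohort generator
#'
#' Builds the full parameter set for [generate_cohort()]. Defaults emulate
#' an elderly population-based cohort with two FFQ/liver-imaging visits
#' about 4.4 years apart: 35.6% baseline steatosis, follow-up odds of
#' steatosis decaying by a factor 0.74 per year, 23.5% loss to follow-up,
#' and small missing-at-random fractions in the interview covariates
#' (education 2.7%, physical activity 7.1%, smoking 5.7%).
#'
#' @param n_participants Number of participants (>= 1).
#' @param n_visits Number of visits (1 or 2).
#' @param followup_years Mean time between visits, years.
#' @param loadings 28 x k factor-loading matrix generating the food-group
#'   correlation structure; rows must be named by [food_groups()].
#' @param intake_mode `"positive"` (softplus-transformed g/day intakes,
#'   calibrated to [reference_intakes()]) or `"linear"` (untransformed
#'   latent scale, X = Lambda F + e, used for factor-recovery checks).
#' @param median_intakes Per-group median intakes calibrating the positive
#'   transform.
#' @param composition Food-group to nutrient matrix
#'   ([nutrient_composition()]).
#' @param nutrient_noise_sd Lognormal noise SD on nutrient totals.
#' @param outcome_coefficients Named log-odds effects on steatosis. Names
#'   may refer to any generated column, e.g. `time`, `score_veg_fish`,
#'   `bmi`, `female`, or a food-group column such as `fg_red_meat`.
#' @param baseline_prevalence Target marginal steatosis prevalence at
#'   baseline; the model intercept is solved so the marginal probability
#'   over the generated covariates and random intercepts equals it.
#' @param random_intercept_sd SD of the participant random intercept on
#'   the log-odds scale. The default (5.5) is calibrated so that, with
#'   the 0.74/year time odds, the model reproduces the observed
#'   persistence of steatosis over 4.4 years (about 5% incidence and 30%
#'   regression); parameter-recovery simulations typically override it
#'   with a smaller value.
#' @param bmi_time_coefficients Optional named vector: per-year BMI slope
#'   modifiers per unit of the named columns (diet-by-time effects on BMI).
#' @param visit_innovation Share (0-1) of visit-specific variance in the
#'   latent factor scores; 0 keeps a participant's dietary pattern fixed
#'   over time.
#' @param missingness_rates Named per-covariate missingness proportions.
#' @param mar_slope Log-odds slope of missingness on standardized baseline
#'   age (0 gives MCAR; the default makes older participants more likely
#'   to have missing interview data, a MAR mechanism).
#' @param dropout_rate Proportion of participants with no follow-up visit
#'   (completely at random).
#' @param exclusion_rates Named rates of eligibility-flag conditions
#'   (`no_ultrasound`, `ffq_missing`, `hepatitis`, `steatogenic_drugs`,
#'   `intracardiac_device`, `te_failure`). Set to zeros for a cohort with
#'   no exclusions.
#' @param seed Integer seed; every generator call is reproducible from it.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_participants = 1000,
                       n_visits = 2,
                       followup_years = 4.4,
                       loadings = reference_loadings(),
                       intake_mode = c("positive", "linear"),
                       median_intakes = reference_intakes(),
                       composition = nutrient_composition(),
                       nutrient_noise_sd = 0.05,
                       outcome_coefficients = c(time = log(0.74)),
                       baseline_prevalence = 0.356,
                       random_intercept_sd = 5.5,
                       bmi_time_coefficients = NULL,
                       visit_innovation = 0.15,
                       missingness_rates = c(education = 0.027,
                                             physical_activity = 0.071,
                                             smoking = 0.057),
                       mar_slope = 0.5,
                       dropout_rate = 0.235,
                       exclusion_rates = c(no_ultrasound = 0.10,
                                           ffq_missing = 0.12,
                                           hepatitis = 0.005,
                                           steatogenic_drugs = 0.04,
                                           intracardiac_device = 0.01,
                                           te_failure = 0.02),
                       seed = 1L) {
  intake_mode <- match.arg(intake_mode)
  if (!is.numeric(n_participants) || n_participants < 1)
    stop("invalid 'n_participants': must be >= 1")
  if (!n_visits %in% 1:2) stop("invalid 'n_visits': must be 1 or 2")
  if (!is.matrix(loadings) || nrow(loadings) != 28L)
    stop("invalid 'loadings': must be a matrix with 28 rows")
  if (ncol(loadings) >= 28L)
    stop("invalid 'loadings': k >= 28 factors is over-factored")
  if (is.null(rownames(loadings))) rownames(loadings) <- food_groups()
  if (!setequal(rownames(loadings), food_groups()))
    stop("invalid 'loadings': row names must be the canonical food groups")
  if (any(rowSums(loadings^2) >= 1))
    stop("invalid 'loadings': communalities must be < 1")
  if (any(missingness_rates < 0 | missingness_rates > 1))
    stop("invalid 'missingness_rates': must be in [0, 1]")
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("invalid 'dropout_rate': must be in [0, 1]")
  if (baseline_prevalence <= 0 || baseline_prevalence >= 1)
    stop("invalid 'baseline_prevalence': must be in (0, 1)")
  if (random_intercept_sd < 0) stop("invalid 'random_intercept_sd'")
  if (visit_innovation < 0 || visit_innovation > 1)
    stop("invalid 'visit_innovation': must be in [0, 1]")
  structure(list(n_participants = as.integer(n_participants),
                 n_visits = as.integer(n_visits),
                 followup_years = followup_years,
                 loadings = loadings[food_groups(), , drop = FALSE],
                 intake_mode = intake_mode,
                 median_intakes = median_intakes,
                 composition = composition,
                 nutrient_noise_sd = nutrient_noise_sd,
                 outcome_coefficients = outcome_coefficients,
                 baseline_prevalence = baseline_prevalence,
                 random_intercept_sd = random_intercept_sd,
                 bmi_time_coefficients = bmi_time_coefficients,
                 visit_innovation = visit_innovation,
                 missingness_rates = missingness_rates,
                 mar_slope = mar_slope,
                 dropout_rate = dropout_rate,
                 exclusion_rates = exclusion_rates,
                 seed = as.integer(seed)),
            class = "sim_config")
}

softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)

#' Simulate food-group intakes from a factor model
#'
#' Draws n observations from X = Lambda F + e with independent standard
#' normal factors and uniquenesses 1 - communality, so that in linear mode
#' the population correlation matrix is Lambda Lambda' + Psi. In positive
#' mode each column is passed through a softplus transform scaled so the
#' median intake matches `median_intakes` (this distorts the correlation
#' structure slightly; factor-recovery checks should use linear mode).
#'
#' @param n Number of observations.
#' @param loadings 28 x k loading matrix (k < 28), rows named by food group.
#' @param mode `"linear"` or `"positive"`.
#' @param seed Integer seed.
#' @param median_intakes Positive-mode calibration medians.
#' @return n x 28 matrix, columns named `fg_<group>`. Attribute `"factors"`
#'   holds the n x k latent factor scores.
#' @export
generate_foodgroups <- function(n, loadings, mode = c("linear", "positive"),
                                seed = 1L,
                                median_intakes = reference_intakes()) {
  mode <- match.arg(mode)
  if (nrow(loadings) != 28L) stop("'loadings' must have 28 rows")
  if (ncol(loadings) >= 28L) stop("k >= 28 factors is over-factored")
  rs <- local_seed(seed)
  on.exit(restore_seed(rs))
  X <- draw_foodgroups(n, loadings, mode, median_intakes)
  X$intakes
}

# core draw, shared with generate_cohort(); assumes RNG already seeded
draw_foodgroups <- function(n, loadings, mode, median_intakes,
                            factors = NULL) {
  k <- ncol(loadings)
  psi <- pmax(1 - rowSums(loadings^2), 1e-6)
  if (is.null(factors)) factors <- matrix(rnorm(n * k), n, k)
  Z <- factors %*% t(loadings) +
    matrix(rnorm(n * 28L), n, 28L) %*% diag(sqrt(psi), 28L)
  colnames(Z) <- rownames(loadings)
  if (mode == "positive") {
    scl <- median_intakes[rownames(loadings)] / log(2)
    Z <- sweep(softplus(Z), 2L, scl, `*`)
  }
  colnames(Z) <- paste0("fg_", rownames(loadings))
  list(intakes = Z, factors = factors)
}

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic participant-visit cohort
#'
#' Produces one row per participant-visit with food-group intakes (from
#' the configured factor structure), derived nutrient totals, covariates,
#' latent pattern adherence scores (`score_<pattern>`, the standardized
#' true factor scores), a steatosis outcome from a random-intercept
#' logistic model, liver stiffness readouts, eligibility flags,
#' missingness in interview covariates, and dropout. The returned
#' `sim_truth` records every parameter actually used, including the solved
#' outcome intercept and the per-participant random intercepts, for
#' parameter-recovery tests.
#'
#' @param config A [sim_config()].
#' @return List with elements `cohort` (data frame) and `truth`
#'   (class `sim_truth`).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config")
  rs <- local_seed(config$seed)
  on.exit(restore_seed(rs))
  n <- config$n_participants
  k <- ncol(config$loadings)
  pat <- colnames(config$loadings)
  if (is.null(pat)) pat <- paste0("f", seq_len(k))

  ## participant-level covariates
  female <- rbinom(n, 1L, 0.56)
  age <- pmin(pmax(rnorm(n, 72, 4.8), 55), 95)
  education <- sample(1:3, n, replace = TRUE, prob = c(0.482, 0.317, 0.201))
  smoking_ever <- rbinom(n, 1L, 1 - 0.377)
  physical_activity <- exp(rnorm(n, log(44.7), 0.95))
  bmi0 <- pmin(pmax(rnorm(n, 26.9, 3.8), 16), 50)
  diabetes <- rbinom(n, 1L, 0.152)
  hypertension <- rbinom(n, 1L, 0.828)
  alcohol <- exp(rnorm(n, log(0.49), 1.35))      # units/day
  b_i <- rnorm(n, 0, config$random_intercept_sd) # random intercepts

  ## latent dietary factors: stable participant component + visit noise
  Fpart <- matrix(rnorm(n * k), n, k)
  w <- config$visit_innovation
  nv <- config$n_visits
  times <- if (nv == 2)
    c(rep(0, n), pmax(rnorm(n, config$followup_years, 0.06), 0.1)) else rep(0, n)

  rows <- vector("list", nv)
  factor_scores <- vector("list", nv)
  for (v in seq_len(nv)) {
    Fv <- sqrt(1 - w) * Fpart + sqrt(w) * matrix(rnorm(n * k), n, k)
    fg <- draw_foodgroups(n, config$loadings, config$intake_mode,
                          config$median_intakes, factors = Fv)
    nut <- derive_nutrients(fg$intakes, config$composition,
                            noise_sd = config$nutrient_noise_sd)
    colnames(Fv) <- paste0("score_", pat)
    factor_scores[[v]] <- Fv
    bmi <- if (v == 1) bmi0 else {
      drift <- rnorm(n, -0.2, 0.8)
      if (!is.null(config$bmi_time_coefficients)) {
        for (nm in names(config$bmi_time_coefficients))
          drift <- drift + config$bmi_time_coefficients[[nm]] *
            lookup_column(nm, Fv, fg$intakes, NULL)
      }
      bmi0 + drift * times[n * (v - 1) + seq_len(n)] / config$followup_years
    }
    rows[[v]] <- data.frame(
      id = seq_len(n), visit = v,
      time = times[n * (v - 1) + seq_len(n)],
      female = female, age = age, education = education,
      smoking = smoking_ever, physical_activity = physical_activity,
      bmi = bmi, diabetes = diabetes, hypertension = hypertension,
      alcohol = alcohol, Fv, fg$intakes, nut, check.names = FALSE)
  }
  tbl <- do.call(rbind, rows)

  ## outcome model: solve intercept for the configured marginal prevalence
  lp0 <- rep(b_i, nv)
  for (nm in names(config$outcome_coefficients)) {
    if (!nm %in% names(tbl))
      stop("outcome coefficient refers to unknown column: ", nm)
    lp0 <- lp0 + config$outcome_coefficients[[nm]] * tbl[[nm]]
  }
  base_rows <- tbl$visit == 1
  a0 <- uniroot(function(a) mean(plogis(a + lp0[base_rows])) -
                  config$baseline_prevalence, c(-20, 20), tol = 1e-10)$root
  tbl$steatosis <- rbinom(nrow(tbl), 1L, plogis(a0 + lp0))

  ## transient elastography: lognormal LSM with a higher median and a
  ## heavier upper tail under steatosis (so that, after the reliability
  ## exclusions preferentially remove high-stiffness readings, about 9%
  ## of eligible steatosis cases exceed the 8 kPa fibrosis proxy)
  tbl$lsm <- exp(rnorm(nrow(tbl), log(4.7) + tbl$steatosis * log(5.5 / 4.7),
                       ifelse(tbl$steatosis == 1, 0.36, 0.28)))
  tbl$lsm_iqr <- tbl$lsm * rbeta(nrow(tbl), 2, 8) * 1.5
  tbl$te_attempts <- pmax(1L, rpois(nrow(tbl), 3))

  ## eligibility flags (participant-level where appropriate)
  er <- config$exclusion_rates
  flag <- function(nm) rbinom(n, 1L, if (nm %in% names(er)) er[[nm]] else 0)
  tbl$no_ultrasound <- rep(flag("no_ultrasound"), nv)
  tbl$hepatitis <- rep(flag("hepatitis"), nv)
  tbl$steatogenic_drugs <- rep(flag("steatogenic_drugs"), nv)
  tbl$intracardiac_device <- rep(flag("intracardiac_device"), nv)
  tbl$ffq_missing <- rbinom(nrow(tbl), 1L,
                            if ("ffq_missing" %in% names(er)) er[["ffq_missing"]] else 0)
  te_fail <- rbinom(nrow(tbl), 1L,
                    if ("te_failure" %in% names(er)) er[["te_failure"]] else 0) == 1L
  tbl$lsm[te_fail] <- NA_real_
  tbl$lsm_iqr[te_fail] <- NA_real_
  tbl$te_attempts[te_fail] <- 10L

  ## dropout (completely at random), then MAR missingness
  if (nv == 2 && config$dropout_rate > 0) {
    drop_id <- which(runif(n) < config$dropout_rate)
    tbl <- tbl[!(tbl$id %in% drop_id & tbl$visit == 2), ]
  }
  if (any(config$missingness_rates > 0))
    tbl <- inject_missingness(tbl, config$missingness_rates,
                              seed = config$seed + 1L,
                              predictor = "age", slope = config$mar_slope)
  rownames(tbl) <- NULL

  truth <- structure(list(
    loadings = config$loadings,
    uniquenesses = pmax(1 - rowSums(config$loadings^2), 1e-6),
    outcome_coefficients = c("(Intercept)" = a0, config$outcome_coefficients),
    random_intercept_sd = config$random_intercept_sd,
    random_intercepts = b_i,
    factor_scores = factor_scores,
    baseline_prevalence = config$baseline_prevalence,
    config = config), class = "sim_truth")
  list(cohort = tbl, truth = truth)
}

lookup_column <- function(nm, scores, intakes, tbl) {
  if (!is.null(scores) && nm %in% colnames(scores)) return(scores[, nm])
  if (!is.null(intakes) && nm %in% colnames(intakes)) return(intakes[, nm])
  if (!is.null(tbl) && nm %in% names(tbl)) return(tbl[[nm]])
  stop("unknown column: ", nm)
}

#' Inject missing-at-random values into covariate columns
#'
#' Sets covariate values to `NA` at the participant level (interview
#' covariates are baseline measurements carried across visits). The
#' missingness probability follows a logistic model on a fully observed
#' predictor (default standardized baseline age), with the intercept
#' solved so the marginal probability equals the requested rate: with
#' `slope = 0` this is MCAR, otherwise MAR. Outcome (`steatosis`, `lsm`)
#' and exposure (`score_*`, `fg_*`) columns may not be made missing.
#' The realized mechanism is recorded in the `"missingness"` attribute.
#'
#' @param tbl Participant-visit data frame with `id` and `visit` columns.
#' @param rates Named vector of marginal missingness proportions.
#' @param seed Integer seed.
#' @param predictor Fully observed numeric column driving MAR missingness.
#' @param slope Log-odds slope on the standardized predictor (may be a
#'   named vector per covariate).
#' @return The table with `NA`s injected.
#' @export
inject_missingness <- function(tbl, rates, seed = 1L, predictor = "age",
                               slope = 0) {
  forbidden <- c("steatosis", "lsm", grep("^(score_|fg_)", names(tbl), value = TRUE))
  bad <- intersect(names(rates), forbidden)
  if (length(bad))
    stop("only covariates may be made missing, not: ", paste(bad, collapse = ", "))
  miss_cols <- names(rates)[rates > 0]
  if (!length(miss_cols)) return(tbl)
  if (!all(miss_cols %in% names(tbl)))
    stop("missingness rate refers to unknown column(s): ",
         paste(setdiff(miss_cols, names(tbl)), collapse = ", "))
  rs <- local_seed(seed)
  on.exit(restore_seed(rs))
  base <- tbl[tbl$visit == min(tbl$visit), c("id", predictor)]
  z <- as.numeric(scale(base[[predictor]]))
  mech <- list()
  for (cv in miss_cols) {
    r <- rates[[cv]]
    sl <- if (length(slope) > 1) slope[[cv]] else slope
    a <- uniroot(function(a) mean(plogis(a + sl * z)) - r, c(-30, 30))$root
    hit <- base$id[runif(nrow(base)) < plogis(a + sl * z)]
    tbl[[cv]][tbl$id %in% hit] <- NA
    mech[[cv]] <- list(rate = r, predictor = predictor, slope = sl,
                       intercept = a, mechanism = if (sl == 0) "MCAR" else "MAR")
  }
  attr(tbl, "missingness") <- mech
  tbl
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Synthetic cohort ground truth\n")
  cat("  factors:", ncol(x$loadings), " groups:", nrow(x$loadings), "\n")
  cat("  outcome coefficients:\n")
  print(round(x$outcome_coefficients, 4))
  cat("  random intercept SD:", x$random_intercept_sd, "\n")
  invisible(x)
}

#' Write a simulated cohort and its ground truth to disk
#'
#' The cohort is written as CSV (one row per participant-visit), the
#' ground-truth parameters as JSON, and the generating configuration as
#' YAML.
#'
#' @param sim Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cohort = file.path(dir, "cohort.csv"),
             truth = file.path(dir, "sim_truth.json"),
             config = file.path(dir, "sim_config.yaml"))
  utils::write.csv(sim$cohort, paths["cohort"], row.names = FALSE)
  tr <- sim$truth
  jsonlite::write_json(list(
    loadings = as.data.frame(tr$loadings),
    uniquenesses = tr$uniquenesses,
    outcome_coefficients = as.list(tr$outcome_coefficients),
    random_intercept_sd = tr$random_intercept_sd,
    baseline_prevalence = tr$baseline_prevalence),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  cfg <- tr$config
  yaml::write_yaml(list(n_participants = cfg$n_participants,
                        n_visits = cfg$n_visits,
                        followup_years = cfg$followup_years,
                        intake_mode = cfg$intake_mode,
                        baseline_prevalence = cfg$baseline_prevalence,
                        random_intercept_sd = cfg$random_intercept_sd,
                        dropout_rate = cfg$dropout_rate,
                        seed = cfg$seed), paths["config"])
  invisible(paths)
}
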