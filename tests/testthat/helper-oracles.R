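# Independent brute-force scorers, written as plain indicator arithmetic
# against the published component definitions -- deliberately separate
# from the production scoring path.

bf_mds <- function(q, med) {
  s <- 0
  for (cn in c("vegetables", "legumes", "fruit", "nuts", "whole_grains",
               "fish", "mufa_sfa_ratio"))
    s <- s + (q[[cn]] >= med[[cn]])
  s + (q[["red_meat"]] < med[["red_meat"]])
}

bf_ddg <- function(fg, nut) {
  r <- function(num, den) if (den == 0) 0 else num / den
  (fg[["vegetables"]] + fg[["tomatoes"]] >= 200) +
    (fg[["fruit"]] >= 200) +
    (fg[["whole_grains"]] >= 90) +
    (fg[["legumes"]] * 7 >= 135) +
    (fg[["nuts"]] >= 15) +
    (fg[["fish"]] * 7 >= 100) +
    (fg[["low_fat_dairy"]] + fg[["high_fat_dairy"]] >= 350) +
    (fg[["tea"]] >= 150) +
    (r(fg[["whole_grains"]], fg[["whole_grains"]] + fg[["refined_grains"]]) >= 0.5) +
    (r(nut[["mufa"]] + nut[["pufa"]], nut[["fat_total"]]) >= 0.5) +
    ((fg[["red_meat"]] + fg[["processed_meat"]]) * 7 < 300) +
    (fg[["sugary_drinks"]] <= 150) +
    (nut[["alcohol_g"]] <= 10) +
    (nut[["sodium"]] * 2.54 <= 6)
}

bf_who <- function(fg, nut) {
  (fg[["vegetables"]] + fg[["tomatoes"]] + fg[["fruit"]] >= 400) +
    (nut[["added_sugar"]] < 10) +
    (nut[["fat_total"]] * 9 / nut[["energy"]] * 100 < 30) +
    (nut[["sfa"]] * 9 / nut[["energy"]] * 100 < 10) +
    (nut[["trans_fat"]] * 9 / nut[["energy"]] * 100 < 1) +
    (nut[["sodium"]] * 2.54 < 5)
}

# random diets as one-row data frames matching the package column layout
random_diet_table <- function(n, seed) {
  set.seed(seed)
  fg <- matrix(rexp(n * 28, rate = 1 / 60), n, 28,
               dimnames = list(NULL, paste0("fg_", food_groups())))
  nut <- data.frame(
    energy = runif(n, 800, 3500),
    added_sugar = rexp(n, 1 / 15),
    fat_total = rexp(n, 1 / 70),
    sfa = rexp(n, 1 / 25),
    mufa = rexp(n, 1 / 25),
    pufa = rexp(n, 1 / 15),
    trans_fat = rexp(n, 1 / 1.5),
    sodium = rexp(n, 1 / 2.4),
    alcohol_g = rexp(n, 1 / 8))
  cbind(as.data.frame(fg), nut,
        female = rep(c(1, 0), length.out = n))
}

score_test_cohort <- random_diet_table

# toy eligibility roster: one row engineered to trip each exclusion rule
# once (in flowchart order), plus clean rows covering the phenotypes
toy_roster <- function() {
  base <- data.frame(
    id = 1:12, visit = 1, energy = 1932, steatosis = 1L, lsm = 5,
    lsm_iqr = 0.5, te_attempts = 3L, alcohol = 0.1, female = 1L,
    no_ultrasound = 0L, ffq_missing = 0L, hepatitis = 0L,
    steatogenic_drugs = 0L, intracardiac_device = 0L)
  base$no_ultrasound[1] <- 1L
  base$energy[2] <- 400
  base$lsm[3] <- 7.5; base$lsm_iqr[3] <- 2.7          # ratio 0.36 at >= 7.1
  base$lsm[4] <- NA; base$lsm_iqr[4] <- NA; base$te_attempts[4] <- 10L
  base$hepatitis[5] <- 1L
  base$alcohol[6] <- 2.0                               # female threshold
  base$steatogenic_drugs[7] <- 1L
  base$intracardiac_device[8] <- 1L
  base$steatosis[9] <- 0L; base$lsm[9] <- 9
  base$lsm[10] <- 4.9                                  # NAFLD
  base$lsm[11] <- 8.2                                  # NASF
  base$steatosis[12] <- 0L; base$lsm[12] <- 5          # no_NAFLD
  base
}

# small complete cohort for model tests (no exclusions, no missingness)
model_test_cohort <- function(n, seed, coefs = c(time = log(0.74)),
                              ri_sd = 0.5) {
  generate_cohort(sim_config(
    n_participants = n, seed = seed, outcome_coefficients = coefs,
    random_intercept_sd = ri_sd,
    missingness_rates = c(education = 0), dropout_rate = 0,
    exclusion_rates = c(no_ultrasound = 0)))
}

fast_spec <- function(exposures, covariates = "none", seed = 1, ...) {
  model_spec("nafld", exposures = exposures, covariates = covariates,
             n_chains = 2, n_adapt = 200, n_burn = 200, n_iter = 400,
             seed = seed, ...)
}
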