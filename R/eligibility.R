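#' FFQ reliability from reported energy intake
#'
#' An FFQ is considered reliable when reported caloric consumption lies
#' between 500 and 7500 kcal/day (inclusive); a missing energy value means
#' the FFQ is missing and counts as unreliable.
#'
#' @param energy Numeric vector of kcal/day (may contain `NA`).
#' @param lower,upper Bounds in kcal/day.
#' @return Logical vector.
#' @export
#' @examples
#' kcal_reliable(c(1932, 499.9, 7500, NA))
kcal_reliable <- function(energy, lower = 500, upper = 7500) {
  if (any(energy < 0, na.rm = TRUE))
    stop("energy intake cannot be negative")
  !is.na(energy) & energy >= lower & energy <= upper
}

#' Transient elastography reliability
#'
#' A liver stiffness measurement (LSM) is unreliable when IQR/median
#' exceeds 0.30 in measurements with a median of 7.1 kPa or above, or when
#' no LSM was obtained after at least ten attempts (TE failure). An absent
#' LSM with fewer than ten attempts is not evidence of unreliability and
#' returns `TRUE`.
#'
#' @param lsm_median Median LSM in kPa (`NA` if no measurement).
#' @param iqr IQR of the LSM in kPa.
#' @param n_attempts Number of measurement attempts.
#' @param ratio_cutoff IQR/median threshold (default 0.30).
#' @param lsm_floor Median above which the ratio rule applies (default 7.1).
#' @param max_attempts Attempts defining TE failure when no LSM (default 10).
#' @return Logical vector: `TRUE` if reliable.
#' @export
#' @examples
#' te_reliable(7.5, 2.7, 3)  # ratio 0.36 at median >= 7.1: unreliable
#' te_reliable(6.0, 3.0, 3)  # ratio rule only applies at median >= 7.1
te_reliable <- function(lsm_median, iqr = 0, n_attempts = 1,
                        ratio_cutoff = 0.30, lsm_floor = 7.1,
                        max_attempts = 10) {
  if (any(lsm_median <= 0, na.rm = TRUE))
    stop("lsm_median must be positive when present")
  failure <- is.na(lsm_median) & n_attempts >= max_attempts
  unreliable <- !is.na(lsm_median) &
    (iqr / lsm_median > ratio_cutoff) & (lsm_median >= lsm_floor)
  !(failure | unreliable)
}

#' Alcohol misuse by sex-specific thresholds
#'
#' Misuse is >= 2 units of alcohol per day in women and >= 3 units in men.
#' One unit is taken as 10 g ethanol where conversion is needed.
#'
#' @param units_per_day Non-negative numeric vector.
#' @param sex Character vector, `"female"` or `"male"` (or a 0/1 vector
#'   where 1 = female).
#' @return Logical vector.
#' @export
alcohol_misuse <- function(units_per_day, sex) {
  if (any(units_per_day < 0, na.rm = TRUE))
    stop("units_per_day cannot be negative")
  if (is.numeric(sex)) sex <- ifelse(sex == 1, "female", "male")
  if (!all(sex %in% c("female", "male")))
    stop("unknown sex code: ", paste(unique(setdiff(sex, c("female", "male"))),
                                     collapse = ", "))
  thr <- ifelse(sex == "female", 2, 3)
  !is.na(units_per_day) & units_per_day >= thr
}

#' Liver phenotype classification
#'
#' Classifies every (steatosis, LSM) pair into exactly one phenotype using
#' the 8 kPa liver-stiffness cut-off as a fibrosis proxy:
#' * steatosis with LSM >= 8 kPa: `NASF` (non-alcoholic steatofibrosis);
#' * steatosis with LSM < 8 kPa or missing LSM: `NAFLD` (a missing LSM
#'   leaves the fibrosis proxy unknown; such rows are flagged via the
#'   `"lsm_missing"` attribute and retained as NAFLD);
#' * no steatosis with LSM >= 8 kPa: `excluded_high_LSM_without_steatosis`;
#' * no steatosis otherwise: `no_NAFLD`.
#'
#' @param steatosis Logical/0-1 vector (ultrasound diagnosis; must be known).
#' @param lsm LSM in kPa, `NA` if absent.
#' @param cutoff Fibrosis-proxy cut-off in kPa (default 8).
#' @return Factor with levels `no_NAFLD`, `NAFLD`, `NASF`,
#'   `excluded_high_LSM_without_steatosis`.
#' @export
#' @examples
#' classify_liver(c(TRUE, FALSE, TRUE), c(8.2, 9.0, 4.9))
classify_liver <- function(steatosis, lsm, cutoff = 8) {
  if (any(is.na(steatosis))) stop("steatosis status must be known")
  steatosis <- as.logical(steatosis)
  high <- !is.na(lsm) & lsm >= cutoff
  out <- ifelse(steatosis,
                ifelse(high, "NASF", "NAFLD"),
                ifelse(high, "excluded_high_LSM_without_steatosis", "no_NAFLD"))
  out <- factor(out, levels = c("no_NAFLD", "NAFLD", "NASF",
                                "excluded_high_LSM_without_steatosis"))
  attr(out, "lsm_missing") <- which(steatosis & is.na(lsm))
  out
}

exclusion_rules <- function() {
  c("missing_ultrasound", "ffq_missing_or_unreliable", "te_unreliable",
    "te_failure", "viral_hepatitis", "alcohol_misuse", "steatogenic_drugs",
    "intracardiac_device", "high_lsm_no_steatosis")
}

#' Apply the cohort inclusion and exclusion rules
#'
#' Filters a participant-visit table by the baseline eligibility rules, in
#' flowchart order: missing ultrasound; missing or unreliable FFQ (energy
#' outside 500-7500 kcal/day); unreliable transient elastography
#' (IQR/median > 0.30 at median >= 7.1 kPa); TE failure (no LSM after at
#' least ten attempts); viral hepatitis; alcohol misuse (>= 2 units/day in
#' women, >= 3 in men); steatogenic drug use; intra-cardiac device; and
#' LSM >= 8 kPa without steatosis. A participant is attributed to the
#' first failing rule and removed at all visits. Follow-up rows whose own
#' FFQ is missing or unreliable are additionally dropped (counted
#' separately in `tally$followup_ffq_dropped`). The operation is
#' idempotent.
#'
#' @param tbl Participant-visit data frame. Required columns: `id`,
#'   `visit`, `energy`, `steatosis`, `lsm`, `lsm_iqr`, `te_attempts`,
#'   `alcohol`, `female`. Optional flag columns (assumed 0 when absent):
#'   `no_ultrasound`, `ffq_missing`, `hepatitis`, `steatogenic_drugs`,
#'   `intracardiac_device`.
#' @param thresholds Optional named list overriding rule thresholds
#'   (`kcal_lower`, `kcal_upper`, `te_ratio`, `te_floor`, `te_attempts`,
#'   `lsm_cutoff`), e.g. read from a YAML config.
#' @return List with `cohort` (the filtered table, with a `phenotype`
#'   column added) and `tally` (class `exclusion_tally`: per-rule counts
#'   of excluded participants, first-rule attribution).
#' @export
apply_exclusions <- function(tbl, thresholds = list()) {
  req <- c("id", "visit", "energy", "steatosis", "lsm", "lsm_iqr",
           "te_attempts", "alcohol", "female")
  miss <- setdiff(req, names(tbl))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  th <- utils::modifyList(list(kcal_lower = 500, kcal_upper = 7500,
                               te_ratio = 0.30, te_floor = 7.1,
                               te_attempts = 10, lsm_cutoff = 8), thresholds)
  opt <- function(nm) if (nm %in% names(tbl)) tbl[[nm]] else rep(0L, nrow(tbl))

  base <- tbl[tbl$visit == min(tbl$visit), ]
  optb <- function(nm) if (nm %in% names(base)) base[[nm]] else rep(0L, nrow(base))
  fails <- cbind(
    missing_ultrasound = optb("no_ultrasound") == 1 | is.na(base$steatosis),
    ffq_missing_or_unreliable = optb("ffq_missing") == 1 |
      !kcal_reliable(base$energy, th$kcal_lower, th$kcal_upper),
    te_unreliable = !is.na(base$lsm) &
      !te_reliable(base$lsm, base$lsm_iqr, base$te_attempts,
                   th$te_ratio, th$te_floor, th$te_attempts),
    te_failure = is.na(base$lsm) & base$te_attempts >= th$te_attempts,
    viral_hepatitis = optb("hepatitis") == 1,
    alcohol_misuse = alcohol_misuse(base$alcohol, base$female),
    steatogenic_drugs = optb("steatogenic_drugs") == 1,
    intracardiac_device = optb("intracardiac_device") == 1,
    high_lsm_no_steatosis = !is.na(base$steatosis) & base$steatosis == 0 &
      !is.na(base$lsm) & base$lsm >= th$lsm_cutoff)
  first_fail <- apply(fails, 1L, function(z) if (any(z)) which(z)[1] else 0L)
  counts <- vapply(seq_along(exclusion_rules()),
                   function(i) sum(first_fail == i), integer(1))
  names(counts) <- exclusion_rules()
  excluded_ids <- base$id[first_fail > 0L]
  out <- tbl[!(tbl$id %in% excluded_ids), , drop = FALSE]

  # follow-up rows with their own missing/unreliable FFQ are dropped
  fu_bad <- out$visit > min(tbl$visit) &
    (opt("ffq_missing")[!(tbl$id %in% excluded_ids)] == 1 |
       !kcal_reliable(out$energy, th$kcal_lower, th$kcal_upper))
  n_fu <- sum(fu_bad)
  out <- out[!fu_bad, , drop = FALSE]
  out$phenotype <- classify_liver(out$steatosis, out$lsm, th$lsm_cutoff)
  rownames(out) <- NULL

  tally <- structure(list(counts = counts,
                          n_input = length(unique(tbl$id)),
                          n_excluded = length(excluded_ids),
                          n_retained = length(unique(out$id)),
                          followup_ffq_dropped = n_fu),
                     class = "exclusion_tally")
  list(cohort = out, tally = tally)
}

#' @export
print.exclusion_tally <- function(x, ...) {
  cat("Exclusion tally (first-rule attribution)\n")
  cat(sprintf("  participants in: %d, excluded: %d, retained: %d (%.1f%%)\n",
              x$n_input, x$n_excluded, x$n_retained,
              100 * x$n_retained / x$n_input))
  for (r in names(x$counts))
    if (x$counts[[r]] > 0) cat(sprintf("  %-28s %d\n", r, x$counts[[r]]))
  if (x$followup_ffq_dropped > 0)
    cat("  follow-up visits dropped for missing/unreliable FFQ:",
        x$followup_ffq_dropped, "\n")
  invisible(x)
}

#' Write an exclusion tally as JSON
#'
#' @param tally An `exclusion_tally`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_tally <- function(tally, path) {
  jsonlite::write_json(list(counts = as.list(tally$counts),
                            n_input = tally$n_input,
                            n_excluded = tally$n_excluded,
                            n_retained = tally$n_retained,
                            followup_ffq_dropped = tally$followup_ffq_dropped),
                       path, auto_unbox = TRUE)
  invisible(path)
}
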