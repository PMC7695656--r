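#' Default thresholds for the a priori diet scores
#'
#' Central, overridable configuration for the Dutch Dietary Guidelines
#' (DDG) and WHO score thresholds, the sodium-to-salt conversion factor,
#' and the energy densities used for energy-percentage components.
#' Alternative guideline editions can be loaded from YAML with
#' [read_thresholds()].
#'
#' @return Nested list of thresholds.
#' @export
diet_thresholds <- function() {
  list(
    ddg = list(vegetables = 200, fruit = 200, whole_grains = 90,
               legumes_week = 135, nuts = 15, fish_week = 100, dairy = 350,
               tea = 150, whole_grain_ratio = 0.5, unsat_fat_ratio = 0.5,
               meat_week_cap = 300, sugary_drinks_cap = 150,
               alcohol_cap = 10, salt_cap = 6),
    who = list(veg_fruit = 400, sugar = 10, fat_en_pct = 30,
               sfa_en_pct = 10, trans_en_pct = 1, salt = 5),
    sodium_to_salt = 2.54,
    kcal_per_g_fat = 9)
}

#' Read score thresholds from a YAML file
#'
#' Values present in the file override the defaults of
#' [diet_thresholds()]; everything else keeps its default.
#'
#' @param path YAML file path.
#' @return Nested threshold list.
#' @export
read_thresholds <- function(path) {
  utils::modifyList(diet_thresholds(), yaml::read_yaml(path))
}

# component quantities entering the adapted Mediterranean Diet Score
mds_components <- function() {
  c("vegetables", "legumes", "fruit", "nuts", "whole_grains", "fish",
    "mufa_sfa_ratio", "red_meat")
}

# extract the 8 MDS quantities from a row (food groups + nutrients).
# vegetables include tomatoes; red meat includes processed meat;
# MUFA:SFA with SFA = 0 is +Inf when MUFA > 0 and 0 when both are 0.
mds_quantities <- function(row) {
  fg <- function(nm) row[[paste0("fg_", nm)]]
  ratio <- if (!is.na(row[["sfa"]]) && row[["sfa"]] == 0) {
    if (is.na(row[["mufa"]]) || row[["mufa"]] == 0) 0 else Inf
  } else row[["mufa"]] / row[["sfa"]]
  c(vegetables = fg("vegetables") + fg("tomatoes"),
    legumes = fg("legumes"),
    fruit = fg("fruit"),
    nuts = fg("nuts"),
    whole_grains = fg("whole_grains"),
    fish = fg("fish"),
    mufa_sfa_ratio = ratio,
    red_meat = fg("red_meat") + fg("processed_meat"))
}

#' Sex-specific median cut-offs for the adapted Mediterranean Diet Score
#'
#' Computes, from the baseline visit of the analysis sample, the per-sex
#' median of each of the 8 MDS component quantities: the 7 beneficial
#' components (vegetables incl. tomatoes, legumes, fruits, nuts, whole
#' grains, fish, MUFA-to-SFA ratio) and red meat (incl. processed meat).
#'
#' @param baseline Data frame of baseline-visit rows with `fg_*` food
#'   group columns, `mufa`, `sfa`, and a 0/1 `female` column.
#' @return Object of class `mds_cutoffs`: list with a `female` and `male`
#'   named vector of medians.
#' @export
mds_medians <- function(baseline) {
  if ("visit" %in% names(baseline))
    baseline <- baseline[baseline$visit == min(baseline$visit), ]
  out <- list()
  for (s in c("female", "male")) {
    sub <- baseline[baseline$female == (s == "female"), , drop = FALSE]
    if (nrow(sub) < 2L)
      stop("need at least 2 participants in the ", s, " stratum")
    q <- t(vapply(seq_len(nrow(sub)),
                  function(i) mds_quantities(sub[i, ]), numeric(8)))
    out[[s]] <- apply(q, 2L, median, na.rm = TRUE)
    names(out[[s]]) <- mds_components()
  }
  structure(out, class = "mds_cutoffs")
}

score_result <- function(index, components, range) {
  total <- if (anyNA(components)) NA_integer_ else as.integer(sum(components))
  structure(list(index = index, components = components, total = total,
                 complete = !anyNA(components), range = range),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("%s score: %s (range 0-%d)%s\n", x$index,
              ifelse(is.na(x$total), "incomplete", x$total), x$range[2],
              if (!x$complete) paste0(" [missing: ",
                paste(names(x$components)[is.na(x$components)], collapse = ", "),
                "]") else ""))
  invisible(x)
}

#' Adapted Mediterranean Diet Score (0-8)
#'
#' Scores one participant-visit against sex-specific median cut-offs. The
#' 7 beneficial components score 1 when the quantity is at or above the
#' sex median; red meat scores 1 when strictly below its median. The
#' alcohol component of the original 9-component score is excluded
#' (alcohol is handled as a model covariate instead), giving a 0-8 range.
#' A missing component quantity flags the total as incomplete (`NA`)
#' rather than silently scoring 0.
#'
#' @param row One participant-visit row (data frame or named list) with
#'   `fg_*` columns and `mufa`, `sfa`.
#' @param sex `"female"` or `"male"` (or 0/1 with 1 = female).
#' @param cutoffs An [mds_medians()] result.
#' @return A `score_result`.
#' @export
score_mds <- function(row, sex, cutoffs) {
  if (is.numeric(sex)) sex <- ifelse(sex == 1, "female", "male")
  if (!sex %in% names(cutoffs)) stop("no cut-offs for sex: ", sex)
  med <- cutoffs[[sex]]
  q <- mds_quantities(row)
  comp <- integer(8)
  names(comp) <- mds_components()
  for (cn in mds_components()) {
    comp[cn] <- if (is.na(q[cn])) NA_integer_
    else if (cn == "red_meat") as.integer(q[cn] < med[cn])
    else as.integer(q[cn] >= med[cn])
  }
  score_result("MDS", comp, c(0L, 8L))
}

#' Dutch Dietary Guidelines score (0-14)
#'
#' Fourteen 0/1 components: (1) vegetables >= 200 g/day (incl. tomatoes),
#' (2) fruit >= 200 g/day, (3) whole grains >= 90 g/day, (4) legumes
#' >= 135 g/week, (5) unsalted nuts >= 15 g/day, (6) fish >= 100 g/week,
#' (7) dairy >= 350 g/day, (8) tea >= 150 mL/day, (9) whole grains at
#' least half of total grains, (10) unsaturated fats and oils at least
#' half of total fats (MUFA+PUFA over total fat), (11) red and processed
#' meat < 300 g/week, (12) sugar-containing beverages <= 150 mL/day,
#' (13) alcohol <= 10 g/day, (14) salt <= 6 g/day (sodium x 2.54).
#' Weekly thresholds are compared against daily intake x 7. Ratio
#' components with a zero denominator score 0 (undefined adherence is not
#' rewarded).
#'
#' @inheritParams score_mds
#' @param thresholds Threshold configuration ([diet_thresholds()]).
#' @return A `score_result` with 14 components.
#' @export
score_ddg <- function(row, thresholds = diet_thresholds()) {
  th <- thresholds$ddg
  fg <- function(nm) row[[paste0("fg_", nm)]]
  ratio0 <- function(num, den) if (is.na(num) || is.na(den)) NA_real_
    else if (den == 0) 0 else num / den
  ind <- function(x) if (is.na(x)) NA_integer_ else as.integer(x)
  grains_tot <- fg("whole_grains") + fg("refined_grains")
  comp <- c(
    vegetables = ind(fg("vegetables") + fg("tomatoes") >= th$vegetables),
    fruit = ind(fg("fruit") >= th$fruit),
    whole_grains = ind(fg("whole_grains") >= th$whole_grains),
    legumes = ind(fg("legumes") * 7 >= th$legumes_week),
    nuts = ind(fg("nuts") >= th$nuts),
    fish = ind(fg("fish") * 7 >= th$fish_week),
    dairy = ind(fg("low_fat_dairy") + fg("high_fat_dairy") >= th$dairy),
    tea = ind(fg("tea") >= th$tea),
    whole_grain_ratio = ind(ratio0(fg("whole_grains"), grains_tot) >=
                              th$whole_grain_ratio),
    unsat_fat_ratio = ind(ratio0(row[["mufa"]] + row[["pufa"]],
                                 row[["fat_total"]]) >= th$unsat_fat_ratio),
    meat_cap = ind((fg("red_meat") + fg("processed_meat")) * 7 <
                     th$meat_week_cap),
    sugary_drinks_cap = ind(fg("sugary_drinks") <= th$sugary_drinks_cap),
    alcohol_cap = ind(row[["alcohol_g"]] <= th$alcohol_cap),
    salt_cap = ind(row[["sodium"]] * thresholds$sodium_to_salt <= th$salt_cap))
  score_result("DDG", comp, c(0L, 14L))
}

#' WHO recommendation score (0-6)
#'
#' Six 0/1 components: (1) vegetables and fruit >= 400 g/day, (2) sugar
#' intake (added sugar, including sugar-sweetened beverages) < 10 g/day,
#' (3) energy percentage from fat < 30, (4) energy percentage from
#' saturated fat < 10, (5) energy percentage from trans fat < 1, and
#' (6) salt < 5 g/day. Energy percentages are grams x 9 kcal/g divided by
#' total energy, x 100. Total energy must be positive.
#'
#' @inheritParams score_ddg
#' @return A `score_result` with 6 components.
#' @export
score_who <- function(row, thresholds = diet_thresholds()) {
  th <- thresholds$who
  if (is.na(row[["energy"]]) || row[["energy"]] <= 0)
    stop("energy must be positive for energy-percentage components")
  fg <- function(nm) row[[paste0("fg_", nm)]]
  ind <- function(x) if (is.na(x)) NA_integer_ else as.integer(x)
  en_pct <- function(g) g * thresholds$kcal_per_g_fat / row[["energy"]] * 100
  comp <- c(
    veg_fruit = ind(fg("vegetables") + fg("tomatoes") + fg("fruit") >=
                      th$veg_fruit),
    sugar = ind(row[["added_sugar"]] < th$sugar),
    fat_energy = ind(en_pct(row[["fat_total"]]) < th$fat_en_pct),
    sfa_energy = ind(en_pct(row[["sfa"]]) < th$sfa_en_pct),
    trans_energy = ind(en_pct(row[["trans_fat"]]) < th$trans_en_pct),
    salt = ind(row[["sodium"]] * thresholds$sodium_to_salt < th$salt))
  score_result("WHO", comp, c(0L, 6L))
}

#' Score a cohort table with all three a priori indices
#'
#' Computes the adapted MDS, DDG and WHO totals for every participant-
#' visit row and appends them as columns `mds`, `ddg`, `who`. MDS
#' cut-offs are computed on the baseline visit of the supplied table
#' unless given.
#'
#' @param tbl Participant-visit data frame with food-group and nutrient
#'   columns and a `female` column.
#' @param cutoffs Optional precomputed [mds_medians()] result.
#' @param thresholds Threshold configuration.
#' @return `tbl` with `mds`, `ddg`, `who` integer columns appended
#'   (`NA` where a component quantity is missing); the cut-offs used are
#'   attached as attribute `"mds_cutoffs"`.
#' @export
score_cohort <- function(tbl, cutoffs = NULL, thresholds = diet_thresholds()) {
  if (is.null(cutoffs)) cutoffs <- mds_medians(tbl)
  n <- nrow(tbl)
  mds <- ddg <- who <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    row <- tbl[i, ]
    mds[i] <- score_mds(row, row$female, cutoffs)$total
    ddg[i] <- score_ddg(row, thresholds)$total
    who[i] <- score_who(row, thresholds)$total
  }
  tbl$mds <- mds; tbl$ddg <- ddg; tbl$who <- who
  attr(tbl, "mds_cutoffs") <- cutoffs
  tbl
}
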