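# build a minimal scoring row from plain vectors
make_row <- function(fg = list(), nut = list()) {
  row <- as.list(setNames(rep(0, 28), paste0("fg_", food_groups())))
  defaults <- list(energy = 2000, added_sugar = 0, fat_total = 0, sfa = 0,
                   mufa = 0, pufa = 0, trans_fat = 0, sodium = 0,
                   alcohol_g = 0)
  row <- utils::modifyList(row, defaults)
  for (nm in names(fg)) row[[paste0("fg_", nm)]] <- fg[[nm]]
  for (nm in names(nut)) row[[nm]] <- nut[[nm]]
  as.data.frame(row)
}

test_that("sex-specific medians match hand-sorted values", {
  rows <- do.call(rbind, lapply(c(1, 2, 3), function(v)
    make_row(fg = list(vegetables = 100 * v, legumes = 10 * v,
                       fruit = 200 * v, nuts = v, whole_grains = 50 * v,
                       fish = 15 * v, red_meat = 30 * v),
             nut = list(mufa = 20 * v, sfa = 10))))
  rows$female <- 1
  rows <- rbind(rows, transform(rows, female = 0))
  cut <- mds_medians(rows)
  expect_equal(cut$female[["vegetables"]], 200)   # median of 100,200,300
  expect_equal(cut$female[["fruit"]], 400)
  expect_equal(cut$female[["mufa_sfa_ratio"]], 4)
  expect_equal(cut$male, cut$female)
  # duplicating every row leaves medians unchanged
  cut2 <- mds_medians(rbind(rows, rows))
  expect_equal(cut2, cut)
  expect_error(mds_medians(rows[rows$female == 1, ]), "male")
})

test_that("MDS extremes and the at-median boundary follow the convention", {
  med <- structure(list(
    female = setNames(c(200, 10, 200, 2, 80, 20, 1.5, 40),
                      nafldiet:::mds_components())), class = "mds_cutoffs")
  med$male <- med$female
  high <- make_row(fg = list(vegetables = 500, legumes = 50, fruit = 500,
                             nuts = 10, whole_grains = 200, fish = 60,
                             red_meat = 0),
                   nut = list(mufa = 30, sfa = 10))
  expect_equal(score_mds(high, "female", med)$total, 8L)
  low <- make_row(fg = list(red_meat = 100), nut = list(sfa = 10))
  expect_equal(score_mds(low, "male", med)$total, 0L)
  # exactly at the median: beneficial score 1 (>=), red meat scores 0 (<)
  at <- make_row(fg = list(vegetables = 200, legumes = 10, fruit = 200,
                           nuts = 2, whole_grains = 80, fish = 20,
                           red_meat = 40),
                 nut = list(mufa = 15, sfa = 10))
  r <- score_mds(at, "female", med)
  expect_equal(r$total, 7L)
  expect_equal(unname(r$components[["red_meat"]]), 0L)
})

test_that("missing component data flags the total incomplete, not zero", {
  med <- mds_medians(score_test_cohort(20, 1))
  row <- score_test_cohort(1, 2)
  row$fg_fish <- NA
  r <- score_mds(row, "female", med)
  expect_true(is.na(r$total))
  expect_false(r$complete)
  expect_true(is.na(r$components[["fish"]]))
  expect_false(anyNA(r$components[setdiff(names(r$components), "fish")]))
})

test_that("DDG component indicators match the printed thresholds", {
  r <- score_ddg(make_row(fg = list(vegetables = 250)))
  expect_equal(unname(r$components[["vegetables"]]), 1L)
  # median-intake legumes (9 g/day = 63 g/week) fail the 135 g/week rule
  r <- score_ddg(make_row(fg = list(legumes = 9)))
  expect_equal(unname(r$components[["legumes"]]), 0L)
  r <- score_ddg(make_row(fg = list(legumes = 135 / 7)))
  expect_equal(unname(r$components[["legumes"]]), 1L)
  # all-zero diet: only the four caps are met; ratios score 0 on 0/0
  r0 <- score_ddg(make_row())
  expect_equal(r0$total, 4L)
  expect_equal(unname(r0$components[c("meat_cap", "sugary_drinks_cap",
                                      "alcohol_cap", "salt_cap")]),
               rep(1L, 4))
  expect_equal(unname(r0$components[c("whole_grain_ratio",
                                      "unsat_fat_ratio")]), c(0L, 0L))
})

test_that("WHO components use energy percentages and printed cut-offs", {
  r <- score_who(make_row(fg = list(vegetables = 211, fruit = 301)))
  expect_equal(unname(r$components[["veg_fruit"]]), 1L)
  r <- score_who(make_row(nut = list(fat_total = 80, energy = 2000)))
  expect_equal(unname(r$components[["fat_energy"]]), 0L)  # 36 en%
  r <- score_who(make_row(nut = list(fat_total = 66, energy = 2000)))
  expect_equal(unname(r$components[["fat_energy"]]), 1L)  # 29.7 en%
  # zero-intake diet at 1 kcal: everything except produce passes
  r0 <- score_who(make_row(nut = list(energy = 1)))
  expect_equal(r0$total, 5L)
  expect_equal(unname(r0$components[["veg_fruit"]]), 0L)
  expect_error(score_who(make_row(nut = list(energy = 0))), "positive")
})

test_that("scorers are monotone in the healthy direction", {
  med <- mds_medians(score_test_cohort(30, 5))
  rows <- score_test_cohort(40, 6)
  for (i in seq_len(20)) {
    r <- rows[i, ]
    base_ddg <- score_ddg(r)$total
    base_who <- score_who(r)$total
    base_mds <- score_mds(r, "female", med)$total
    up <- r
    up$fg_vegetables <- up$fg_vegetables + 150   # beneficial everywhere
    expect_gte(score_ddg(up)$total, base_ddg)
    expect_gte(score_who(up)$total, base_who)    # higher veg+fruit only helps
    expect_gte(score_mds(up, "female", med)$total, base_mds)
    worse <- r
    worse$sodium <- worse$sodium + 5             # capped quantity
    expect_lte(score_ddg(worse)$total, base_ddg)
    expect_lte(score_who(worse)$total, base_who)
  }
})

test_that("totals ignore rescaling of irrelevant quantities", {
  r <- score_test_cohort(1, 9)
  a <- score_ddg(r)$total
  r2 <- r
  r2$fg_coffee <- r2$fg_coffee * 10   # coffee enters no DDG component
  expect_equal(score_ddg(r2)$total, a)
  w <- score_who(r)$total
  r3 <- r
  r3$fg_potatoes <- r3$fg_potatoes * 3
  expect_equal(score_who(r3)$total, w)
})

test_that("score_cohort appends totals consistent with the row scorers", {
  tbl <- score_test_cohort(25, 12)
  tbl$id <- seq_len(25); tbl$visit <- 1
  out <- score_cohort(tbl)
  expect_true(all(c("mds", "ddg", "who") %in% names(out)))
  cut <- attr(out, "mds_cutoffs")
  i <- 7
  expect_equal(out$mds[i], score_mds(tbl[i, ], tbl$female[i], cut)$total)
  expect_equal(out$ddg[i], score_ddg(tbl[i, ])$total)
  expect_equal(out$who[i], score_who(tbl[i, ])$total)
  expect_true(all(out$mds <= 8 & out$ddg <= 14 & out$who <= 6, na.rm = TRUE))
})
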