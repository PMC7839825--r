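test_that("a constant 50 g/day of a 2 ug/100 g food gives 1 ug/day", {
  tab <- toy_table(list(food = c(2.0, 0)))
  d <- toy_diary(events = data.frame(day = 1:7, meal_slot = "dinner",
                                     food_ref = "food", amount_g = 50))
  res <- person_intake(d, list(), tab)
  expect_equal(res$vitd3, 1.0)
  expect_equal(res$ohd3, 0)
  expect_equal(res$activity, 1.0)
})

test_that("zero amounts give zero intake and an undefined share", {
  tab <- toy_table(list(food = c(2.0, 0)))
  d <- toy_diary(events = data.frame(day = 1, meal_slot = "lunch",
                                     food_ref = "food", amount_g = 0))
  res <- person_intake(d, list(), tab)
  expect_equal(res$vitd3, 0)
  expect_true(is.na(res$share_ohd3))
})

test_that("intake through recipes equals event-by-event recursive expansion", {
  set.seed(21)
  world <- random_recipe_world()
  tab <- world$table
  refs <- c(tab$food_id[1], world$top, "R2")
  d <- toy_diary(events = data.frame(
    day = sample(1:7, 9, replace = TRUE),
    meal_slot = sample(c("breakfast", "lunch", "dinner", "snack"), 9,
                       replace = TRUE),
    food_ref = sample(refs, 9, replace = TRUE),
    amount_g = runif(9, 10, 300)))
  res <- person_intake(d, world$recipes, tab)

  expected <- c(vitd3 = 0, vitd2 = 0, ohd3 = 0, ohd2 = 0)
  for (i in seq_len(nrow(d))) {
    expected <- expected + d$amount_g[i] / 100 *
      content_oracle(d$food_ref[i], world$recipes, tab)
  }
  expected <- expected / 7
  expect_equal(c(res$vitd3, res$vitd2, res$ohd3, res$ohd2),
               unname(expected), tolerance = 1e-9)
})

test_that("intake is linear in amounts and shares are scale-invariant", {
  set.seed(31)
  tab <- toy_table(list(a = c(1.2, 0.3), b = c(0.1, 0.8)))
  d <- toy_diary(events = data.frame(
    day = sample(1:7, 12, replace = TRUE), meal_slot = "snack",
    food_ref = sample(c("a", "b"), 12, replace = TRUE),
    amount_g = runif(12, 5, 200)))
  base <- person_intake(d, list(), tab)
  for (cc in c(0.5, 2, 10)) {
    scaled <- d
    scaled$amount_g <- scaled$amount_g * cc
    res <- person_intake(scaled, list(), tab)
    expect_equal(res$vitd3, cc * base$vitd3, tolerance = 1e-12)
    expect_equal(res$ohd3, cc * base$ohd3, tolerance = 1e-12)
    expect_equal(res$share_ohd3, base$share_ohd3, tolerance = 1e-9)
  }
  # the share is defined on unconverted micrograms: f only moves activity
  alt <- person_intake(d, list(), tab, activity_config(factor_f = 1.7))
  expect_equal(alt$share_ohd3, base$share_ohd3)
  expect_gt(alt$activity, base$activity)
})

test_that("unresolvable food references are reported", {
  tab <- toy_table(list(a = c(1, 0)))
  d <- toy_diary(events = data.frame(day = 1, meal_slot = "lunch",
                                     food_ref = "mystery", amount_g = 10))
  expect_error(person_intake(d, list(), tab), "mystery")
})

test_that("diary validation catches out-of-design records", {
  tab <- toy_table(list(a = c(1, 0)))
  bad_day <- toy_diary(events = data.frame(day = 8, meal_slot = "lunch",
                                           food_ref = "a", amount_g = 10))
  expect_error(person_intake(bad_day, list(), tab), "1\\.\\.7")
  bad_slot <- toy_diary(events = data.frame(day = 1, meal_slot = "brunch",
                                            food_ref = "a", amount_g = 10))
  expect_error(person_intake(bad_slot, list(), tab), "meal_slot")
  too_old <- toy_diary(age = 90, events = data.frame(
    day = 1, meal_slot = "lunch", food_ref = "a", amount_g = 10))
  expect_error(person_intake(too_old, list(), tab), "4\\.\\.75")
})

test_that("population summaries split children and adults correctly", {
  tab <- toy_table(list(a = c(2, 1)))
  mk <- function(pid, age) toy_diary(pid, age, data.frame(
    day = 1:7, meal_slot = "dinner", food_ref = "a", amount_g = 100))
  d <- dplyr::bind_rows(mk("kid", 10), mk("teen", 17), mk("adult", 18))
  res <- compute_intake(d, list(), tab)
  expect_equal(res$age_group, c("children", "children", "adults"))

  summ <- population_summary(res)
  expect_equal(summ$n, c(2, 1))
  expect_equal(summ$vitd3_mean, c(2, 2))
  expect_equal(summ$ohd3_mean, c(1, 1))
  expect_equal(summ$activity_mean, c(3, 3))
  expect_equal(summ$share_ohd3_pooled, c(100 / 3, 100 / 3))
  # identical persons have zero spread
  expect_equal(summ$vitd3_sd[1], 0)

  only_adult <- res[res$age_group == "adults", ]
  expect_warning(s1 <- population_summary(only_adult), "children.*empty")
  expect_equal(s1$age_group, "adults")
})

test_that("scenario comparison obeys identity and scaling laws", {
  tab <- toy_table(list(a = c(1.2, 0.3), b = c(0.4, 0.6)))
  d <- dplyr::bind_rows(
    toy_diary("p1", 9, data.frame(day = 1:3, meal_slot = "lunch",
                                  food_ref = "a", amount_g = 80)),
    toy_diary("p2", 40, data.frame(day = c(2, 5), meal_slot = "dinner",
                                   food_ref = "b", amount_g = 120)))

  ident <- compare_scenarios(d, list(), tab,
                             list(scenario_override("same", list())))
  base_rows <- ident[ident$scenario == "toy", -1]
  same_rows <- ident[ident$scenario == "same", -1]
  expect_equal(as.data.frame(same_rows), as.data.frame(base_rows))

  doubled_tab <- toy_table(list(a = c(2.4, 0.6), b = c(0.8, 1.2)),
                           scenario = "doubled")
  cmp <- dplyr::bind_rows(
    cbind(scenario = "base", population_summary(compute_intake(d, list(), tab))),
    cbind(scenario = "x2",
          population_summary(compute_intake(d, list(), doubled_tab))))
  b <- cmp[cmp$scenario == "base", ]
  x2 <- cmp[cmp$scenario == "x2", ]
  expect_equal(x2$vitd3_mean, 2 * b$vitd3_mean, tolerance = 1e-12)
  expect_equal(x2$ohd3_mean, 2 * b$ohd3_mean, tolerance = 1e-12)
  expect_equal(x2$activity_mean, 2 * b$activity_mean, tolerance = 1e-12)
  expect_equal(x2$share_ohd3_pooled, b$share_ohd3_pooled, tolerance = 1e-9)
})

test_that("a toy two-person two-scenario run matches hand computation", {
  tab <- toy_table(list(a = c(1, 0.5), b = c(2, 0.25)))
  d <- dplyr::bind_rows(
    toy_diary("p1", 10, data.frame(day = 1, meal_slot = "lunch",
                                   food_ref = "a", amount_g = 700)),
    toy_diary("p2", 30, data.frame(day = 1, meal_slot = "lunch",
                                   food_ref = "b", amount_g = 350)))
  ov <- scenario_override("alt", list(a = toy_profile(vitd3 = 2, ohd3 = 1)))
  out <- compare_scenarios(d, list(), tab, list(ov))
  # p1 base: 700/100 * (1, 0.5) / 7 = (1, 0.5); alt: (2, 1)
  # p2 both: 350/100 * (2, 0.25) / 7 = (1, 0.125)
  get <- function(sc, grp, col) out[[col]][out$scenario == sc & out$age_group == grp]
  expect_equal(get("toy", "children", "vitd3_mean"), 1)
  expect_equal(get("toy", "children", "ohd3_mean"), 0.5)
  expect_equal(get("alt", "children", "vitd3_mean"), 2)
  expect_equal(get("alt", "children", "ohd3_mean"), 1)
  expect_equal(get("alt", "adults", "vitd3_mean"), 1)
  expect_equal(get("alt", "adults", "ohd3_mean"), 0.125)
  expect_equal(get("toy", "children", "share_ohd3_pooled"), 100 * 0.5 / 1.5)
})
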