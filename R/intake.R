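MEAL_SLOTS <- c("breakfast", "lunch", "dinner", "snack")

#' Validate a diary table
#'
#' Diaries are tibbles of 7-day, meal-slotted consumption events with
#' columns `person_id`, `age` (years, 4-75), `day` (1-7), `meal_slot`
#' (breakfast/lunch/dinner/snack), `food_ref` (food or recipe id) and
#' `amount_g` (grams, `>= 0`).
#'
#' @param diaries A data frame of consumption events.
#' @return The validated diaries as a tibble (invisibly usable in a pipe).
#' @export
validate_diaries <- function(diaries) {
  diaries <- tibble::as_tibble(diaries)
  needed <- c("person_id", "age", "day", "meal_slot", "food_ref", "amount_g")
  missing <- setdiff(needed, names(diaries))
  if (length(missing) > 0L) {
    stop("diaries missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(diaries) > 0L) {
    if (any(diaries$day < 1 | diaries$day > 7)) {
      stop("diary `day` must be in 1..7", call. = FALSE)
    }
    if (any(!diaries$meal_slot %in% MEAL_SLOTS)) {
      stop("diary `meal_slot` must be one of ",
           paste(MEAL_SLOTS, collapse = ", "), call. = FALSE)
    }
    if (any(diaries$amount_g < 0)) {
      stop("diary `amount_g` must be >= 0", call. = FALSE)
    }
    if (any(diaries$age < 4 | diaries$age > 75)) {
      stop("diary `age` must be within the survey range 4..75", call. = FALSE)
    }
    age_per_person <- tapply(diaries$age, diaries$person_id,
                             function(a) length(unique(a)))
    if (any(age_per_person > 1L)) {
      stop("each person must have a single age across events", call. = FALSE)
    }
  }
  diaries
}

#' Age group of the survey design
#'
#' @param age Age in years.
#' @return `"children"` for ages 4-17, `"adults"` for 18-75.
#' @export
age_group <- function(age) {
  if (any(age < 4 | age > 75)) stop("age outside the survey range 4..75",
                                    call. = FALSE)
  ifelse(age <= 17, "children", "adults")
}

#' Per-person daily vitamin D vitamer intake
#'
#' For each person, every consumption event is decomposed to raw
#' ingredients with [flatten_recipe()], the event's grams are multiplied
#' by each ingredient's content per 100 g, and the 7-day total is divided
#' by exactly 7 (the fixed recording window), giving mean daily intake in
#' \eqn{\mu}g/day per vitamer, plus the vitamin D activity and the
#' 25-hydroxyvitamin D3 share of the person's vitD3 + 25(OH)D3 intake.
#'
#' @param diaries Diary tibble (see [validate_diaries()]); may hold many
#'   persons.
#' @param recipes Named list of [recipe()] objects (may be empty).
#' @param table A [composition_table()].
#' @param cfg An [activity_config()].
#' @return A tibble with one row per person: `person_id`, `age`,
#'   `age_group`, `vitd3`, `vitd2`, `ohd3`, `ohd2` (\eqn{\mu}g/day),
#'   `activity` (\eqn{\mu}g/day) and `share_ohd3` (%, `NA` when the person
#'   consumed no D3 vitamers).
#' @export
compute_intake <- function(diaries, recipes = list(), table,
                           cfg = activity_config()) {
  diaries <- validate_diaries(diaries)
  stopifnot(inherits(table, "composition_table"),
            inherits(cfg, "activity_config"))

  # content per 100 g of each distinct reference, after recipe flattening
  refs <- unique(diaries$food_ref)
  content_of <- new.env(parent = emptyenv())
  for (ref in refs) {
    flat <- flatten_recipe(ref, recipes, table)
    contents <- vapply(flat$food_id,
                       function(id) profile_content(table_profile(table, id)),
                       numeric(length(VITAMERS)))
    assign(ref, as.numeric(contents %*% flat$fraction), envir = content_of)
  }

  persons <- unique(diaries$person_id)
  rows <- lapply(persons, function(pid) {
    ev <- diaries[diaries$person_id == pid, ]
    intake <- stats::setNames(numeric(length(VITAMERS)), VITAMERS)
    for (i in seq_len(nrow(ev))) {
      intake <- intake + ev$amount_g[i] / 100 * get(ev$food_ref[i],
                                                    envir = content_of)
    }
    intake <- intake / 7
    total_d3 <- intake[["vitd3"]] + intake[["ohd3"]]
    tibble::tibble(
      person_id = pid,
      age = ev$age[1],
      age_group = age_group(ev$age[1]),
      vitd3 = intake[["vitd3"]], vitd2 = intake[["vitd2"]],
      ohd3 = intake[["ohd3"]], ohd2 = intake[["ohd2"]],
      activity = activity(intake, cfg),
      share_ohd3 = if (total_d3 > 0) 100 * intake[["ohd3"]] / total_d3 else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' @rdname compute_intake
#' @details `person_intake()` is the single-person form: it requires the
#'   diary to contain exactly one person and returns the one-row result.
#' @export
person_intake <- function(diaries, recipes = list(), table,
                          cfg = activity_config()) {
  diaries <- validate_diaries(diaries)
  if (length(unique(diaries$person_id)) > 1L) {
    stop("`person_intake()` expects events of a single person", call. = FALSE)
  }
  compute_intake(diaries, recipes, table, cfg)
}

#' Population summary of intake results by age group
#'
#' Summarises per-person intakes into the survey's two age groups:
#' children (4-17 years) and adults (18-75 years). The headline
#' 25-hydroxyvitamin D3 share is pooled (ratio of group mean intakes,
#' i.e. the share of the group's total consumption); the mean of the
#' per-person shares is reported alongside.
#'
#' @param results Tibble of per-person results from [compute_intake()].
#' @return A tibble with one row per non-empty age group: `age_group`,
#'   `n`, mean and SD of `vitd3`, `ohd3` and `activity` (\eqn{\mu}g/day),
#'   `share_ohd3_pooled` and `share_ohd3_mean` (%). Empty groups are
#'   omitted with a warning.
#' @export
population_summary <- function(results) {
  if (!is.data.frame(results) || nrow(results) == 0L) {
    stop("`results` must be a non-empty intake result table", call. = FALSE)
  }
  groups <- c("children", "adults")
  rows <- lapply(groups, function(g) {
    r <- results[results$age_group == g, ]
    if (nrow(r) == 0L) {
      warning("age group '", g, "' is empty and was omitted", call. = FALSE)
      return(NULL)
    }
    denom <- mean(r$vitd3) + mean(r$ohd3)
    tibble::tibble(
      age_group = g, n = nrow(r),
      vitd3_mean = mean(r$vitd3), vitd3_sd = stats::sd(r$vitd3),
      ohd3_mean = mean(r$ohd3), ohd3_sd = stats::sd(r$ohd3),
      activity_mean = mean(r$activity), activity_sd = stats::sd(r$activity),
      share_ohd3_pooled = if (denom > 0) 100 * mean(r$ohd3) / denom else NA_real_,
      share_ohd3_mean = mean(r$share_ohd3, na.rm = TRUE)
    )
  })
  dplyr::bind_rows(rows)
}

#' Compare composition scenarios on a fixed diary population
#'
#' Runs the intake pipeline once per scenario on identical diaries and
#' stacks the per-age-group summaries. The base table is included as its
#' own scenario; each [scenario_override()] contributes one further
#' scenario.
#'
#' @param diaries Diary tibble (see [validate_diaries()]).
#' @param recipes Named list of [recipe()] objects.
#' @param base A [composition_table()] (reported under its own
#'   `scenario_id`).
#' @param overrides List of [scenario_override()] objects (possibly empty).
#' @param cfg An [activity_config()].
#' @return A tibble: [population_summary()] rows with a leading
#'   `scenario` column, plus attribute `factor_f` recording the activity
#'   conversion used.
#' @export
compare_scenarios <- function(diaries, recipes = list(), base,
                              overrides = list(), cfg = activity_config()) {
  stopifnot(inherits(base, "composition_table"))
  tables <- c(stats::setNames(list(base), scenario_id(base)),
              stats::setNames(lapply(overrides, function(ov) {
                apply_scenario(base, ov)
              }), vapply(overrides, function(ov) ov$scenario_id, character(1))))
  rows <- lapply(names(tables), function(sc) {
    res <- compute_intake(diaries, recipes, tables[[sc]], cfg)
    summ <- population_summary(res)
    dplyr::bind_cols(tibble::tibble(scenario = rep(sc, nrow(summ))), summ)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "factor_f") <- cfg$factor_f
  out
}
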