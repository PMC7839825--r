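FIXTURE_IDS <- c("eggs", "dairy", "chicken", "veal_beef", "pork",
                 "scenario1_ingredients", "scenario2_overrides",
                 "scenario3_overrides", "recipes_example", "diaries_example")

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "vitDintake")
  if (!nzchar(path)) stop("fixture not found: ", file, call. = FALSE)
  path
}

#' Load a packaged reference table
#'
#' The package ships the published composition summaries it was built
#' around, as plain text: per-group summary tables for eggs, dairy,
#' chicken, veal/beef and pork (means, SDs and sample sizes, with
#' censoring tokens exactly as printed), a representative scenario-1
#' ingredient composition table, and example scenario-2/3 override files.
#' The ingredient table is a synthetic stand-in for the full survey
#' ingredient list, which is not public: measured foods carry the
#' published means, and the fish and pork-liver rows carry illustrative
#' stand-in values (marked in their names).
#'
#' @param table_id One of `"eggs"`, `"dairy"`, `"chicken"`, `"veal_beef"`,
#'   `"pork"` (summary tables), `"scenario1_ingredients"` (a
#'   [composition_table()]), `"scenario2_overrides"`,
#'   `"scenario3_overrides"` (each a [scenario_override()]),
#'   `"recipes_example"` (named list of [recipe()]s) or
#'   `"diaries_example"` (a diary tibble).
#' @return See `table_id`. Summary tables are tibbles in which vitamer
#'   `*_mean` columns are list-columns of [vitamer_quantity()] (or `NULL`
#'   where the source prints no estimate) and `n`, `fat_*` and `*_sd`
#'   columns are numeric.
#' @examples
#' pork <- load_fixture_table("pork")
#' base <- load_fixture_table("scenario1_ingredients")
#' @export
load_fixture_table <- function(table_id) {
  table_id <- match.arg(table_id, FIXTURE_IDS)
  switch(table_id,
    eggs = read_summary_fixture("eggs_summary.csv"),
    dairy = read_summary_fixture("dairy_summary.csv"),
    chicken = read_summary_fixture("chicken_summary.csv"),
    veal_beef = read_summary_fixture("veal_beef_summary.csv"),
    pork = read_summary_fixture("pork_summary.csv"),
    scenario1_ingredients = read_composition(
      fixture_path("scenario1_ingredients.csv"), scenario_id = "scenario_1"),
    scenario2_overrides = read_overrides(
      fixture_path("scenario2_overrides.csv"), scenario_id = "scenario_2"),
    scenario3_overrides = read_overrides(
      fixture_path("scenario3_overrides.csv"), scenario_id = "scenario_3"),
    recipes_example = read_recipes(fixture_path("recipes_example.json")),
    diaries_example = read_diaries(fixture_path("diaries_example.csv"))
  )
}

read_summary_fixture <- function(file) {
  raw <- read_delimited(fixture_path(file))
  out <- raw
  for (col in names(raw)) {
    if (col %in% c("n")) {
      out[[col]] <- as.integer(raw[[col]])
    } else if (grepl("_sd$", col) || grepl("^fat", col) || col == "fat_pct") {
      out[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
    } else if (grepl("_mean$", col)) {
      out[[col]] <- lapply(raw[[col]], function(cell) {
        if (is.na(cell) || !nzchar(trimws(cell))) NULL
        else parse_quantity_token(cell)
      })
    }
  }
  out
}

summary_mean_value <- function(tbl, row, col) {
  q <- tbl[[col]][[row]]
  if (is.null(q)) stop("no estimate in fixture cell", call. = FALSE)
  censor_substitute(q)
}

#' Per-hen-type group summaries from the egg reference table
#'
#' @param vitamer `"vitd3"` or `"ohd3"`.
#' @return A [group_summary()] tibble of the four hen types (the pooled
#'   all-types row is excluded), ready for [anova_from_summaries()].
#' @export
egg_group_summaries <- function(vitamer = c("vitd3", "ohd3")) {
  vitamer <- match.arg(vitamer)
  eggs <- load_fixture_table("eggs")
  eggs <- eggs[eggs$source != "all_types", ]
  dplyr::bind_rows(lapply(seq_len(nrow(eggs)), function(i) {
    group_summary(eggs$source[i], eggs$n[i],
                  summary_mean_value(eggs, i, paste0(vitamer, "_mean")),
                  eggs[[paste0(vitamer, "_sd")]][i])
  }))
}

#' Sample-size-weighted all-types egg mean
#'
#' The pooled egg mean is the n-weighted average of the four hen-type
#' means.
#'
#' @param vitamer `"vitd3"` or `"ohd3"`.
#' @return The pooled mean, \eqn{\mu}g/100 g.
#' @export
egg_alltypes_mean <- function(vitamer = c("vitd3", "ohd3")) {
  g <- egg_group_summaries(vitamer)
  sum(g$n * g$mean) / sum(g$n)
}

#' Fat and vitamer means of the dairy foods on the fat regression line
#'
#' The dairy foods whose vitamer content follows the zero-intercept fat
#' relationship: milk (1.5%, 3.5%, 3.5% organic), yoghurt, cream and
#' spreadable butter. Cheese does not follow the line and is excluded, as
#' is skimmed milk (all vitamers censored).
#'
#' @return A tibble with numeric columns `fat_pct`, `vitd3`, `ohd3`
#'   (censored means substituted at half LOQ).
#' @export
dairy_fat_points <- function() {
  dairy <- load_fixture_table("dairy")
  keep <- c("milk_1.5", "milk_3.5", "milk_organic_3.5", "yoghurt", "cream",
            "butter_spreadable")
  dairy <- dairy[match(keep, dairy$sample_type), ]
  tibble::tibble(
    fat_pct = dairy$fat_pct,
    vitd3 = vapply(seq_len(nrow(dairy)), function(i)
      summary_mean_value(dairy, i, "vitd3_mean"), numeric(1)),
    ohd3 = vapply(seq_len(nrow(dairy)), function(i)
      summary_mean_value(dairy, i, "ohd3_mean"), numeric(1))
  )
}

#' Equal-weight all-cut averages for veal or beef
#'
#' Averages the printed per-cut means with equal weight per cut. Veal
#' averages the four veal cuts; beef averages its seven cuts plus minced
#' beef (eight rows). Calf liver belongs to neither. Censored cut means
#' enter at half their LOQ.
#'
#' @param species `"veal"` or `"beef"`.
#' @return Named numeric `(fat_pct, vitd3, ohd3)`.
#' @export
cut_average <- function(species = c("veal", "beef")) {
  species <- match.arg(species)
  vb <- load_fixture_table("veal_beef")
  vb <- vb[vb$species == species, ]
  c(fat_pct = mean(vb$fat_mean),
    vitd3 = mean(vapply(seq_len(nrow(vb)), function(i)
      summary_mean_value(vb, i, "vitd3_mean"), numeric(1))),
    ohd3 = mean(vapply(seq_len(nrow(vb)), function(i)
      summary_mean_value(vb, i, "ohd3_mean"), numeric(1))))
}

pork_profile <- function(cut, collection) {
  pork <- load_fixture_table("pork")
  i <- which(pork$cut == cut & pork$collection == collection)
  if (length(i) != 1L) stop("unknown pork cut/collection", call. = FALSE)
  vitamer_profile(vitd3 = pork$vitd3_mean[[i]], vitd2 = pork$vitd2_mean[[i]],
                  ohd3 = pork$ohd3_mean[[i]], ohd2 = pork$ohd2_mean[[i]],
                  fat_pct = pork$fat_mean[i])
}

chicken_part_profile <- function(origin, cut) {
  ck <- load_fixture_table("chicken")
  i <- which(ck$origin == origin & ck$cut == cut)
  if (length(i) != 1L) stop("unknown chicken origin/cut", call. = FALSE)
  vitamer_profile(vitd3 = ck$vitd3_mean[[i]],
                  vitd2 = ck$vitd2_mean[[i]] %||% 0,
                  ohd3 = ck$ohd3_mean[[i]],
                  ohd2 = ck$ohd2_mean[[i]] %||% 0,
                  fat_pct = ck$fat_mean[i])
}

DERIVE_PRESETS <- c("minced_pork_summer", "minced_pork_spring",
                    "thigh_with_skin_dk", "thigh_with_skin_fr")

#' Derive the package's reference composite foods
#'
#' Recomputes the composite foods that the reference tables derive from
#' analysed parts:
#' \describe{
#'   \item{`minced_pork_summer` / `minced_pork_spring`}{10%-fat minced
#'     pork as a 92% lean meat / 8% subcutaneous fat mixture of the
#'     seasonal shoulder means.}
#'   \item{`thigh_with_skin_dk` / `thigh_with_skin_fr`}{chicken thigh with
#'     skin, mass-aggregated from thigh meat and thigh skin (Danish
#'     chickens: 133 g meat + 21 g skin; French: 129 g + 22 g; bone is
#'     inedible and excluded).}
#' }
#'
#' @param preset One of `r paste0('"', DERIVE_PRESETS, '"', collapse = ", ")`.
#' @return A [vitamer_profile()] (full precision; apply [round_half_up()]
#'   for display at table precision).
#' @examples
#' round_half_up(profile_content(derive_preset("minced_pork_summer")))
#' @export
derive_preset <- function(preset) {
  preset <- match.arg(preset, DERIVE_PRESETS)
  switch(preset,
    minced_pork_summer = mixture_profile(
      list(pork_profile("lean_meat", "summer"),
           pork_profile("sc_fat", "summer")),
      c(0.92, 0.08)),
    minced_pork_spring = mixture_profile(
      list(pork_profile("lean_meat", "spring"),
           pork_profile("sc_fat", "spring")),
      c(0.92, 0.08)),
    thigh_with_skin_dk = aggregate_parts(list(
      list(part_id = "thigh_meat", mass = 133,
           profile = chicken_part_profile("denmark", "thigh_meat")),
      list(part_id = "thigh_skin", mass = 21,
           profile = chicken_part_profile("denmark", "thigh_skin")))),
    thigh_with_skin_fr = aggregate_parts(list(
      list(part_id = "thigh_meat", mass = 129,
           profile = chicken_part_profile("france", "thigh_meat")),
      list(part_id = "thigh_skin", mass = 22,
           profile = chicken_part_profile("france", "thigh_skin"))))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
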