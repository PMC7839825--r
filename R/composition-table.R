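FOOD_GROUPS <- c("eggs", "dairy", "chicken", "veal", "beef", "pork",
                 "fish", "other")
PROVENANCES <- c("measured", "derived", "scenario_override")

#' Create a food record
#'
#' One row of a composition table: a food with its group, optional fat
#' content and four-vitamer profile.
#'
#' @param food_id Unique identifier string.
#' @param name Human-readable name.
#' @param group One of `r paste0('"', FOOD_GROUPS, '"', collapse = ", ")`.
#' @param profile A [vitamer_profile()].
#' @param fat_pct Optional fat content, percent by mass (falls back to the
#'   profile's fat when absent).
#' @param provenance One of `"measured"`, `"derived"`,
#'   `"scenario_override"`.
#' @return A one-row tibble in composition-table layout (list-column
#'   `profile`).
#' @export
food_record <- function(food_id, name, group, profile, fat_pct = NULL,
                        provenance = "measured") {
  stopifnot(is.character(food_id), length(food_id) == 1L, nzchar(food_id))
  if (length(group) != 1L || !group %in% FOOD_GROUPS) {
    stop("unknown food group '", group, "' (code BAD_GROUP); expected one of ",
         paste(FOOD_GROUPS, collapse = ", "), call. = FALSE)
  }
  provenance <- match.arg(provenance, PROVENANCES)
  stopifnot(is_vitamer_profile(profile))
  if (is.null(fat_pct)) fat_pct <- profile_fat(profile)
  if (!is.null(fat_pct) && (fat_pct < 0 || fat_pct > 100)) {
    stop("`fat_pct` must be in [0, 100]", call. = FALSE)
  }
  tibble::tibble(food_id = food_id,
                 name = as.character(name),
                 group = group,
                 fat_pct = if (is.null(fat_pct)) NA_real_ else as.numeric(fat_pct),
                 provenance = provenance,
                 profile = list(profile))
}

#' Assemble a composition table
#'
#' A composition table maps food ids to food records for one scenario. It
#' is a tibble with columns `food_id`, `name`, `group`, `fat_pct`,
#' `provenance` and a list-column `profile` of [vitamer_profile()] objects,
#' carrying the scenario id as an attribute.
#'
#' @param records A tibble of rows built with [food_record()] (rows are
#'   concatenated with `dplyr::bind_rows()` when given as a list).
#' @param scenario_id Identifier for the composition scenario.
#' @return An object of classes `composition_table` and `tbl_df`.
#' @export
composition_table <- function(records, scenario_id = "scenario_1") {
  if (is.list(records) && !is.data.frame(records)) {
    records <- dplyr::bind_rows(records)
  }
  needed <- c("food_id", "name", "group", "fat_pct", "provenance", "profile")
  if (!all(needed %in% names(records))) {
    stop("records must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  dup <- records$food_id[duplicated(records$food_id)]
  if (length(dup) > 0L) {
    stop("duplicate food_id in composition table: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(records$group), FOOD_GROUPS)
  if (length(bad) > 0L) {
    stop("unknown food group(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(tibble::as_tibble(records), scenario_id = scenario_id,
            class = c("composition_table", class(tibble::tibble())))
}

#' @rdname composition_table
#' @param table A `composition_table`.
#' @export
scenario_id <- function(table) attr(table, "scenario_id", exact = TRUE)

#' Look up a food's profile in a composition table
#'
#' @param table A [composition_table()].
#' @param food_id Food identifier.
#' @return The food's [vitamer_profile()].
#' @export
table_profile <- function(table, food_id) {
  i <- match(food_id, table$food_id)
  if (is.na(i)) {
    stop("food_id not in composition table: ", food_id, call. = FALSE)
  }
  table$profile[[i]]
}

#' Create a scenario override
#'
#' A scenario override maps food ids to replacement vitamer profiles,
#' representing alternative composition assumptions (e.g. animal feeding
#' with extra vitamin D3, UVB exposure, or 25-hydroxyvitamin D3 feeding).
#'
#' @param scenario_id Identifier of the resulting scenario.
#' @param overrides Named list mapping food ids to [vitamer_profile()]
#'   objects. May be empty (identity scenario).
#' @return An object of class `scenario_override`.
#' @export
scenario_override <- function(scenario_id, overrides = list()) {
  stopifnot(is.list(overrides))
  if (length(overrides) > 0L) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      stop("`overrides` must be a named list keyed by food_id", call. = FALSE)
    }
    ok <- vapply(overrides, is_vitamer_profile, logical(1))
    if (!all(ok)) stop("all overrides must be vitamer_profile objects", call. = FALSE)
  }
  structure(list(scenario_id = scenario_id, overrides = overrides),
            class = "scenario_override")
}

#' Apply a scenario override to a composition table
#'
#' Returns a new table in which the overridden foods carry the replacement
#' profiles (provenance `"scenario_override"`); every other record and the
#' input table itself are left untouched.
#'
#' @param base A [composition_table()].
#' @param override A [scenario_override()].
#' @return A new `composition_table` with the override's scenario id.
#' @export
apply_scenario <- function(base, override) {
  stopifnot(inherits(base, "composition_table"),
            inherits(override, "scenario_override"))
  unknown <- setdiff(names(override$overrides), base$food_id)
  if (length(unknown) > 0L) {
    stop("override refers to food_id(s) absent from the base table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(base)
  for (id in names(override$overrides)) {
    i <- match(id, out$food_id)
    out$profile[[i]] <- override$overrides[[id]]
    out$provenance[i] <- "scenario_override"
    fat <- profile_fat(override$overrides[[id]])
    if (!is.null(fat)) out$fat_pct[i] <- fat
  }
  composition_table(out, scenario_id = override$scenario_id)
}
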