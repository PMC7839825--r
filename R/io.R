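#' Parse and format censoring tokens
#'
#' Composition files write left-censored cells as `"<"` followed by the
#' LOQ, e.g. `"<0.01"`, matching the notation of printed composition
#' tables; measured cells are plain decimal numbers (decimal point,
#' UTF-8).
#'
#' @param token A character scalar, e.g. `"0.88"` or `"<0.01"`.
#' @return `parse_quantity_token()`: a [vitamer_quantity()];
#'   `format_quantity_token()`: a character scalar.
#' @export
parse_quantity_token <- function(token) {
  token <- trimws(token)
  if (is.na(token) || !nzchar(token)) {
    stop("empty vitamer cell (code EMPTY_CELL)", call. = FALSE)
  }
  if (startsWith(token, "<")) {
    loq <- suppressWarnings(as.numeric(substring(token, 2)))
    if (is.na(loq) || loq <= 0) {
      stop("malformed censoring token '", token,
           "' (code BAD_CENSOR): expected \"<\" followed by a positive LOQ",
           call. = FALSE)
    }
    return(vitamer_quantity(loq = loq))
  }
  value <- suppressWarnings(as.numeric(token))
  if (is.na(value)) {
    stop("malformed numeric cell '", token, "' (code BAD_NUMBER)",
         call. = FALSE)
  }
  vitamer_quantity(value = value)
}

#' @rdname parse_quantity_token
#' @param q A [vitamer_quantity()].
#' @export
format_quantity_token <- function(q) {
  stopifnot(is_vitamer_quantity(q))
  if (is_censored(q)) paste0("<", format(q$loq, scientific = FALSE))
  else format(q$value, scientific = FALSE)
}

COMPOSITION_COLUMNS <- c("food_id", "name", "group", "fat_pct",
                         "vitd3", "vitd2", "ohd3", "ohd2", "provenance")

#' Read and write composition tables
#'
#' Composition files are delimited text (comma or tab, auto-detected on
#' read) with header columns `food_id`, `name`, `group`, `fat_pct`,
#' `vitd3`, `vitd2`, `ohd3`, `ohd2`, `provenance`. Vitamer cells hold
#' either a decimal content in \eqn{\mu}g/100 g or a censoring token such
#' as `"<0.01"`; `fat_pct` may be empty. Reading stops with a combined
#' message when any record is invalid (duplicate ids: code `DUP_ID`;
#' unknown group: `BAD_GROUP`; malformed cells: `BAD_NUMBER` /
#' `BAD_CENSOR`); a header-only file yields an empty table with a warning.
#' `write_composition()` round-trips censoring state exactly.
#'
#' @param path File path.
#' @param scenario_id Scenario id to attach; defaults to the file name
#'   without extension.
#' @return `read_composition()`: a [composition_table()].
#' @export
read_composition <- function(path, scenario_id = NULL) {
  if (is.null(scenario_id)) {
    scenario_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- read_delimited(path)
  missing <- setdiff(COMPOSITION_COLUMNS, names(raw))
  if (length(missing) > 0L) {
    stop("composition file ", path, " missing column(s): ",
         paste(missing, collapse = ", "), " (code BAD_HEADER)", call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    warning("composition file ", path, " has a header but no records",
            call. = FALSE)
    empty <- tibble::tibble(food_id = character(), name = character(),
                            group = character(), fat_pct = numeric(),
                            provenance = character(), profile = list())
    return(composition_table(empty, scenario_id = scenario_id))
  }
  errors <- character(0)
  rows <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    row <- raw[i, ]
    rec <- tryCatch({
      fat <- if (is.na(row$fat_pct) || !nzchar(trimws(row$fat_pct))) NULL
             else as.numeric(row$fat_pct)
      prof <- vitamer_profile(vitd3 = parse_quantity_token(row$vitd3),
                              vitd2 = parse_quantity_token(row$vitd2),
                              ohd3 = parse_quantity_token(row$ohd3),
                              ohd2 = parse_quantity_token(row$ohd2),
                              fat_pct = fat)
      food_record(row$food_id, row$name, row$group, prof, fat_pct = fat,
                  provenance = row$provenance)
    }, error = function(e) conditionMessage(e))
    if (is.character(rec)) {
      errors <- c(errors, paste0("line ", i + 1L, " (", row$food_id, "): ", rec))
    } else {
      rows[[i]] <- rec
    }
  }
  dup <- raw$food_id[duplicated(raw$food_id)]
  if (length(dup) > 0L) {
    errors <- c(errors, paste0("duplicate food_id (code DUP_ID): ",
                               paste(unique(dup), collapse = ", ")))
  }
  if (length(errors) > 0L) {
    stop("invalid composition file ", path, ":\n  ",
         paste(errors, collapse = "\n  "), call. = FALSE)
  }
  composition_table(dplyr::bind_rows(rows), scenario_id = scenario_id)
}

#' @rdname read_composition
#' @param table A [composition_table()].
#' @export
write_composition <- function(table, path) {
  stopifnot(inherits(table, "composition_table"))
  out <- tibble::tibble(
    food_id = table$food_id,
    name = table$name,
    group = table$group,
    fat_pct = ifelse(is.na(table$fat_pct), "",
                     format(table$fat_pct, scientific = FALSE, trim = TRUE)),
    vitd3 = vapply(table$profile, function(p) format_quantity_token(p$vitd3),
                   character(1)),
    vitd2 = vapply(table$profile, function(p) format_quantity_token(p$vitd2),
                   character(1)),
    ohd3 = vapply(table$profile, function(p) format_quantity_token(p$ohd3),
                  character(1)),
    ohd2 = vapply(table$profile, function(p) format_quantity_token(p$ohd2),
                  character(1)),
    provenance = table$provenance
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read and write scenario override files
#'
#' Override files are delimited text with columns `food_id`, `vitd3`,
#' `vitd2`, `ohd3`, `ohd2`; vitamer cells accept censoring tokens. An
#' optional `fat_pct` column is honoured.
#'
#' @param path File path.
#' @param scenario_id Scenario id; defaults to the file name without
#'   extension.
#' @return `read_overrides()`: a [scenario_override()].
#' @export
read_overrides <- function(path, scenario_id = NULL) {
  if (is.null(scenario_id)) {
    scenario_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- read_delimited(path)
  needed <- c("food_id", "vitd3", "vitd2", "ohd3", "ohd2")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0L) {
    stop("override file ", path, " missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  overrides <- stats::setNames(lapply(seq_len(nrow(raw)), function(i) {
    row <- raw[i, ]
    fat <- if (!"fat_pct" %in% names(raw) || is.na(row$fat_pct) ||
               !nzchar(trimws(row$fat_pct))) NULL else as.numeric(row$fat_pct)
    vitamer_profile(vitd3 = parse_quantity_token(row$vitd3),
                    vitd2 = parse_quantity_token(row$vitd2),
                    ohd3 = parse_quantity_token(row$ohd3),
                    ohd2 = parse_quantity_token(row$ohd2),
                    fat_pct = fat)
  }), raw$food_id)
  scenario_override(scenario_id, overrides)
}

#' Read and write diary files
#'
#' Diary files are delimited text with columns `person_id`, `age`, `day`,
#' `meal_slot`, `food_ref`, `amount_g` (see [validate_diaries()]).
#'
#' @param path File path.
#' @return `read_diaries()`: a validated diary tibble.
#' @export
read_diaries <- function(path) {
  raw <- read_delimited(path)
  needed <- c("person_id", "age", "day", "meal_slot", "food_ref", "amount_g")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0L) {
    stop("diary file ", path, " missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_diaries(tibble::tibble(
    person_id = raw$person_id,
    age = as.numeric(raw$age),
    day = as.integer(raw$day),
    meal_slot = raw$meal_slot,
    food_ref = raw$food_ref,
    amount_g = as.numeric(raw$amount_g)
  ))
}

#' @rdname read_diaries
#' @param diaries A diary tibble.
#' @export
write_diaries <- function(diaries, path) {
  readr::write_csv(validate_diaries(diaries), path)
  invisible(path)
}

#' Read and write recipe files
#'
#' Recipes are stored as JSON: an array of objects with `recipe_id` and
#' `variants`, each variant an object with `weight` (market share) and
#' `components`, an array of `{ref, proportion}` pairs.
#'
#' @param path File path.
#' @return `read_recipes()`: a named list of [recipe()] objects keyed by
#'   recipe id.
#' @export
read_recipes <- function(path) {
  parsed <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  recipes <- lapply(parsed, function(r) {
    recipe(r$recipe_id, lapply(r$variants, function(v) {
      list(weight = v$weight,
           components = dplyr::bind_rows(lapply(v$components, function(cmp) {
             tibble::tibble(ref = cmp$ref, proportion = cmp$proportion)
           })))
    }))
  })
  stats::setNames(recipes, vapply(recipes, function(r) r$recipe_id,
                                  character(1)))
}

#' @rdname read_recipes
#' @param recipes Named list of [recipe()] objects.
#' @export
write_recipes <- function(recipes, path) {
  payload <- lapply(recipes, function(r) {
    list(recipe_id = r$recipe_id,
         variants = lapply(r$variants, function(v) {
           list(weight = v$weight,
                components = lapply(seq_len(nrow(v$components)), function(i) {
                  list(ref = v$components$ref[i],
                       proportion = v$components$proportion[i])
                }))
         }))
  })
  jsonlite::write_json(unname(payload), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# comma/tab auto-detected delimited reader; every cell as character so
# censoring tokens survive
read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    na = character())
}
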