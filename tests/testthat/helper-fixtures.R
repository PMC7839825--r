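# In-code builders for small test worlds: a toy composition table, toy
# recipes, random profiles and random acyclic recipe graphs.

toy_profile <- function(vitd3 = 0, vitd2 = 0, ohd3 = 0, ohd2 = 0, fat = NULL) {
  vitamer_profile(vitd3 = vitd3, vitd2 = vitd2, ohd3 = ohd3, ohd2 = ohd2,
                  fat_pct = fat)
}

toy_table <- function(contents, scenario = "toy") {
  # contents: named list food_id -> c(vitd3, ohd3) or vitamer_profile
  rows <- lapply(names(contents), function(id) {
    x <- contents[[id]]
    prof <- if (is_vitamer_profile(x)) x else
      toy_profile(vitd3 = x[[1]], ohd3 = x[[2]])
    food_record(id, id, "other", prof)
  })
  composition_table(rows, scenario_id = scenario)
}

random_profile <- function() {
  toy_profile(vitd3 = runif(1, 0, 8), vitd2 = runif(1, 0, 0.2),
              ohd3 = runif(1, 0, 1), ohd2 = runif(1, 0, 0.2))
}

random_fractions <- function(k) {
  w <- runif(k)
  w / sum(w)
}

# random acyclic recipe graph over leaf foods A..F, depth <= 4, fan-out <= 4
random_recipe_world <- function(depth = 4, fanout = 4) {
  leaves <- LETTERS[1:6]
  table <- toy_table(stats::setNames(
    lapply(leaves, function(i) c(runif(1, 0, 5), runif(1, 0, 1))), leaves))
  recipes <- list()
  available <- leaves
  for (d in seq_len(depth)) {
    id <- paste0("R", d)
    n_var <- sample(1:2, 1)
    weights <- random_fractions(n_var)
    variants <- lapply(seq_len(n_var), function(v) {
      k <- sample(2:fanout, 1)
      refs <- sample(available, k)
      list(weight = weights[v],
           components = data.frame(ref = refs,
                                   proportion = random_fractions(k)))
    })
    recipes[[id]] <- recipe(id, variants)
    available <- c(available, id)
  }
  list(table = table, recipes = recipes, top = paste0("R", depth))
}

# independent route to per-100 g content: direct recursive evaluation,
# never building fraction lists
content_oracle <- function(ref, recipes, table) {
  if (ref %in% table$food_id) {
    return(profile_content(table_profile(table, ref)))
  }
  rec <- recipes[[ref]]
  out <- stats::setNames(numeric(4), c("vitd3", "vitd2", "ohd3", "ohd2"))
  for (v in rec$variants) {
    for (i in seq_len(nrow(v$components))) {
      out <- out + v$weight * v$components$proportion[i] *
        content_oracle(v$components$ref[i], recipes, table)
    }
  }
  out
}

toy_diary <- function(person_id = "p1", age = 30, events) {
  # events: data.frame(day, meal_slot, food_ref, amount_g)
  tibble::tibble(person_id = person_id, age = age,
                 day = events$day, meal_slot = events$meal_slot,
                 food_ref = events$food_ref, amount_g = events$amount_g)
}
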