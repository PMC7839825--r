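#' Define a recipe with market-share variants
#'
#' A recipe is a composite dish broken down into components. It may exist
#' in several marketplace variants (e.g. a dish made with butter vs.
#' margarine); each variant carries a market-share weight and a component
#' list of mass proportions. Components may reference raw ingredients
#' (food ids of a composition table) or other recipes; the reference graph
#' must be acyclic.
#'
#' @param recipe_id Identifier string.
#' @param variants List of variants, each a list with `weight` (market
#'   share, `>= 0`; weights sum to 1 across variants) and `components`, a
#'   data frame or tibble with columns `ref` (food or recipe id) and
#'   `proportion` (mass fractions, `>= 0`, summing to 1).
#' @return An object of class `recipe`.
#' @examples
#' recipe("minced_pork_10pct", list(list(
#'   weight = 1,
#'   components = data.frame(ref = c("pork_lean", "pork_fat"),
#'                           proportion = c(0.92, 0.08)))))
#' @export
recipe <- function(recipe_id, variants) {
  stopifnot(is.character(recipe_id), length(recipe_id) == 1L, nzchar(recipe_id))
  if (!is.list(variants) || length(variants) == 0L) {
    stop("`variants` must be a non-empty list", call. = FALSE)
  }
  weights <- vapply(variants, function(v) as.numeric(v$weight), numeric(1))
  if (any(weights < 0)) stop("variant weights must be >= 0", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("variant weights must sum to 1 in recipe '", recipe_id, "'",
         call. = FALSE)
  }
  variants <- lapply(variants, function(v) {
    comp <- tibble::as_tibble(v$components)
    if (!all(c("ref", "proportion") %in% names(comp)) || nrow(comp) == 0L) {
      stop("each variant needs components with `ref` and `proportion`",
           call. = FALSE)
    }
    if (any(comp$proportion < 0)) {
      stop("component proportions must be >= 0 in recipe '", recipe_id, "'",
           call. = FALSE)
    }
    if (abs(sum(comp$proportion) - 1) > 1e-9) {
      stop("component proportions must sum to 1 in recipe '", recipe_id, "'",
           call. = FALSE)
    }
    list(weight = as.numeric(v$weight), components = comp)
  })
  structure(list(recipe_id = recipe_id, variants = variants), class = "recipe")
}

#' Flatten a recipe to effective ingredient fractions
#'
#' Resolves a food or recipe reference to the raw ingredients of a
#' composition table. Nested recipes are expanded recursively; each leaf's
#' effective fraction is the sum over all paths of the product of variant
#' weights and component proportions along the path. Fractions sum to 1.
#'
#' @param ref A food id (returned as-is with fraction 1) or recipe id.
#' @param recipes Named list of [recipe()] objects, keyed by recipe id.
#' @param table A [composition_table()] resolving the leaf food ids.
#' @return A tibble with columns `food_id` and `fraction`, ordered
#'   lexicographically by `food_id`.
#' @export
flatten_recipe <- function(ref, recipes, table) {
  stopifnot(inherits(table, "composition_table"))
  if (length(recipes) > 0L && is.null(names(recipes))) {
    names(recipes) <- vapply(recipes, function(r) r$recipe_id, character(1))
  }
  fr <- flatten_ref(ref, recipes, table, active = character(0))
  agg <- tapply(fr$fraction, fr$food_id, sum)
  out <- tibble::tibble(food_id = names(agg), fraction = as.numeric(agg))
  out[order(out$food_id), ]
}

flatten_ref <- function(ref, recipes, table, active) {
  if (ref %in% table$food_id) {
    return(tibble::tibble(food_id = ref, fraction = 1))
  }
  if (!ref %in% names(recipes)) {
    stop("unresolved reference '", ref,
         "': not a food in the composition table nor a known recipe",
         call. = FALSE)
  }
  if (ref %in% active) {
    stop("recipe cycle detected: ",
         paste(c(active[seq(match(ref, active), length(active))], ref),
               collapse = " -> "),
         call. = FALSE)
  }
  rec <- recipes[[ref]]
  parts <- list()
  for (v in rec$variants) {
    if (v$weight == 0) next
    for (i in seq_len(nrow(v$components))) {
      prop <- v$components$proportion[i]
      if (prop == 0) next
      sub <- flatten_ref(v$components$ref[i], recipes, table,
                         active = c(active, ref))
      sub$fraction <- sub$fraction * v$weight * prop
      parts[[length(parts) + 1L]] <- sub
    }
  }
  dplyr::bind_rows(parts)
}
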