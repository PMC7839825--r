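#' Specify a synthetic 7-day diary population
#'
#' Describes a population of meal-slotted 7-day food diaries emulating a
#' national dietary survey: persons are children (4-17 years) or adults
#' (18-75 years), and on each of the 7 days each of the 4 meal slots
#' (breakfast, lunch, dinner, snack) independently includes each candidate
#' food with a per-food probability; consumed amounts are lognormal
#' (positive, right-skewed, as real portion sizes are).
#'
#' @param n_persons Number of persons.
#' @param p_child Proportion of children, in `[0, 1]`. Default 0.25,
#'   roughly the child share of a general population sample; ages are
#'   integer-uniform within each group.
#' @param food_probs Named numeric vector: per-meal-slot consumption
#'   probability of each candidate food, values in `[0, 1]`, names being
#'   food or recipe ids.
#' @param meanlog,sdlog Lognormal amount parameters on the log-gram scale;
#'   defaults `log(50)` and `0.6` give a median portion of 50 g.
#'   `sdlog` must be `> 0`.
#' @param seed Base integer seed; the same (model, seed) reproduces the
#'   population exactly.
#' @return An object of class `diary_model`.
#' @export
diary_model <- function(n_persons, p_child = 0.25, food_probs,
                        meanlog = log(50), sdlog = 0.6, seed = 1L) {
  if (n_persons < 1) stop("`n_persons` must be >= 1", call. = FALSE)
  if (p_child < 0 || p_child > 1) stop("`p_child` must be in [0, 1]", call. = FALSE)
  if (length(food_probs) == 0L || is.null(names(food_probs)) ||
      any(!nzchar(names(food_probs)))) {
    stop("`food_probs` must be a named numeric vector", call. = FALSE)
  }
  if (any(food_probs < 0 | food_probs > 1)) {
    stop("food probabilities must be in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(sdlog) || sdlog <= 0) stop("`sdlog` must be > 0", call. = FALSE)
  structure(list(n_persons = as.integer(n_persons), p_child = p_child,
                 food_probs = food_probs, meanlog = meanlog, sdlog = sdlog,
                 seed = as.integer(seed)),
            class = "diary_model")
}

# deterministic per-person stream: a fixed mix of the base seed and the
# person index, kept below 2^31 so populations extend without reshuffling
person_seed <- function(base_seed, index) {
  (as.double(base_seed) * 48271 + as.double(index) * 104729) %% 2147483647
}

#' Generate synthetic diaries with closed-form ground truth
#'
#' Draws the population described by a [diary_model()] and attaches the
#' analytic expectation of each person's daily intake: for every food,
#' expected daily intake per vitamer is
#' `4 slots x p_food x E[amount] x content / 100`, with
#' `E[amount] = exp(meanlog + sdlog^2 / 2)`. The empirical population mean
#' from [compute_intake()] converges to this ground truth, which is the
#' basis for validating the intake engine.
#'
#' @param model A [diary_model()].
#' @param table A [composition_table()] resolving every food in
#'   `food_probs` (recipe ids are allowed when `recipes` is given).
#' @param recipes Optional named list of [recipe()] objects, flattened for
#'   the ground-truth expectation exactly as the intake engine flattens
#'   them.
#' @return A list with `diaries` (a diary tibble, possibly with zero rows
#'   for all-zero probabilities) and `ground_truth`, a named numeric
#'   vector of expected daily intake per vitamer (\eqn{\mu}g/day,
#'   identical for every person).
#' @export
generate_diaries <- function(model, table, recipes = list()) {
  stopifnot(inherits(model, "diary_model"),
            inherits(table, "composition_table"))
  foods <- names(model$food_probs)

  # expected content per 100 g of each reference (recipes flattened)
  contents <- vapply(foods, function(ref) {
    flat <- flatten_recipe(ref, recipes, table)
    cc <- vapply(flat$food_id,
                 function(id) profile_content(table_profile(table, id)),
                 numeric(length(VITAMERS)))
    as.numeric(cc %*% flat$fraction)
  }, numeric(length(VITAMERS)))
  rownames(contents) <- VITAMERS

  e_amount <- exp(model$meanlog + model$sdlog^2 / 2)
  ground_truth <- as.numeric(
    contents %*% (4 * model$food_probs * e_amount / 100))
  names(ground_truth) <- VITAMERS

  rows <- vector("list", model$n_persons)
  for (i in seq_len(model$n_persons)) {
    set.seed(person_seed(model$seed, i))
    is_child <- stats::runif(1) < model$p_child
    age <- if (is_child) sample(4:17, 1) else sample(18:75, 1)
    pid <- sprintf("p%05d", i)
    slots <- expand.grid(day = 1:7, meal_slot = MEAL_SLOTS,
                         food_ref = foods, stringsAsFactors = FALSE)
    eat <- stats::runif(nrow(slots)) < model$food_probs[slots$food_ref]
    if (!any(eat)) next
    picked <- slots[eat, ]
    rows[[i]] <- tibble::tibble(
      person_id = pid, age = age,
      day = as.integer(picked$day), meal_slot = picked$meal_slot,
      food_ref = picked$food_ref,
      amount_g = stats::rlnorm(nrow(picked), model$meanlog, model$sdlog))
  }
  diaries <- dplyr::bind_rows(rows)
  if (nrow(diaries) == 0L) {
    diaries <- tibble::tibble(person_id = character(), age = numeric(),
                              day = integer(), meal_slot = character(),
                              food_ref = character(), amount_g = numeric())
  }
  list(diaries = diaries, ground_truth = ground_truth)
}

#' Generate left-censored measurement samples
#'
#' Draws `n` measurements from a normal distribution truncated at zero
#' (contents cannot be negative) and reports draws below the limit of
#' quantification as censored quantities — the measurement process behind
#' censoring-aware summaries. The default relative spread of analytical
#' replicates is about 10% (method precision), so `true_sd` is typically
#' around `0.1 * true_mean`.
#'
#' @param true_mean,true_sd Parameters of the underlying normal
#'   (\eqn{\mu}g/100 g); `true_sd > 0`.
#' @param loq Limit of quantification, `> 0`.
#' @param n Number of samples, `>= 1`.
#' @param seed Integer seed.
#' @return A list of `n` [vitamer_quantity()] objects.
#' @export
generate_censored_samples <- function(true_mean, true_sd = 0.1 * true_mean,
                                      loq, n, seed = 1L) {
  if (!is.numeric(loq) || loq <= 0) stop("`loq` must be > 0", call. = FALSE)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (!is.numeric(true_sd) || true_sd <= 0) stop("`true_sd` must be > 0",
                                                 call. = FALSE)
  set.seed(seed)
  draws <- numeric(0)
  while (length(draws) < n) {
    x <- stats::rnorm(2L * (n - length(draws)), true_mean, true_sd)
    draws <- c(draws, x[x >= 0])
  }
  draws <- draws[seq_len(n)]
  lapply(draws, function(x) {
    if (x < loq) vitamer_quantity(loq = loq) else vitamer_quantity(value = x)
  })
}
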