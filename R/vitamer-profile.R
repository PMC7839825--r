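VITAMERS <- c("vitd3", "vitd2", "ohd3", "ohd2")

#' Create a four-vitamer composition profile
#'
#' A `vitamer_profile` holds the content of the four vitamin D vitamers of
#' one food: vitamin D3, vitamin D2, 25-hydroxyvitamin D3 and
#' 25-hydroxyvitamin D2, each in \eqn{\mu}g per 100 g edible portion. Slots
#' may be left-censored: pass a [vitamer_quantity()] built with `loq =` for
#' values below the analytical limit of quantification. Bare numbers are
#' treated as measured values.
#'
#' @param vitd3,vitd2,ohd3,ohd2 A [vitamer_quantity()] or a single numeric
#'   (interpreted as a measured value). Unmeasured vitamers should be given
#'   as `vitamer_quantity(loq = <method LOQ>)`.
#' @param fat_pct Optional fat content, percent by mass, in `[0, 100]`.
#' @return An object of class `vitamer_profile`.
#' @examples
#' # free-range pork lean meat, summer
#' vitamer_profile(vitd3 = 0.88, ohd3 = 0.38,
#'                 vitd2 = vitamer_quantity(loq = 0.01),
#'                 ohd2 = vitamer_quantity(loq = 0.01), fat_pct = 4.2)
#' @export
vitamer_profile <- function(vitd3 = 0, vitd2 = 0, ohd3 = 0, ohd2 = 0,
                            fat_pct = NULL) {
  p <- list(vitd3 = as_vitamer_quantity(vitd3),
            vitd2 = as_vitamer_quantity(vitd2),
            ohd3 = as_vitamer_quantity(ohd3),
            ohd2 = as_vitamer_quantity(ohd2))
  if (!is.null(fat_pct)) {
    if (!is.numeric(fat_pct) || length(fat_pct) != 1L || is.na(fat_pct) ||
        fat_pct < 0 || fat_pct > 100) {
      stop("`fat_pct` must be a single number in [0, 100]", call. = FALSE)
    }
    fat_pct <- as.numeric(fat_pct)
  }
  structure(p, fat_pct = fat_pct, class = "vitamer_profile")
}

#' @rdname vitamer_profile
#' @param x Object to test.
#' @export
is_vitamer_profile <- function(x) inherits(x, "vitamer_profile")

#' @rdname vitamer_profile
#' @param profile A `vitamer_profile`.
#' @export
profile_fat <- function(profile) attr(profile, "fat_pct", exact = TRUE)

#' @export
print.vitamer_profile <- function(x, ...) {
  cat("<vitamer_profile> µg/100 g:",
      paste(VITAMERS, vapply(unclass(x)[VITAMERS], format, character(1)),
            sep = "=", collapse = " "), "\n")
  fat <- profile_fat(x)
  if (!is.null(fat)) cat("  fat: ", fat, "%\n", sep = "")
  invisible(x)
}

#' Numeric vitamer contents of a profile after censor substitution
#'
#' @param profile A [vitamer_profile()].
#' @return Named numeric vector `(vitd3, vitd2, ohd3, ohd2)`,
#'   \eqn{\mu}g/100 g, with censored slots substituted at half their LOQ.
#' @export
profile_content <- function(profile) {
  stopifnot(is_vitamer_profile(profile))
  vapply(unclass(profile)[VITAMERS], censor_substitute, numeric(1))
}

#' Mass-fraction mixture of vitamer profiles
#'
#' Combines component foods into a composite food: each vitamer of the
#' result is the fraction-weighted sum of the (censor-substituted)
#' component contents. Fat combines the same way, but only when every
#' component carries a fat percentage; otherwise the result has no fat.
#' Used e.g. to derive minced meat from lean meat and subcutaneous fat.
#'
#' @param profiles List of [vitamer_profile()] objects.
#' @param fractions Numeric mass fractions, non-negative, summing to 1
#'   (absolute tolerance 1e-9).
#' @return A `vitamer_profile` with measured slots (mixing collapses the
#'   censoring state; censored inputs enter at half their LOQ).
#' @examples
#' lean <- vitamer_profile(vitd3 = 0.88, ohd3 = 0.38, fat_pct = 4.2)
#' fat  <- vitamer_profile(vitd3 = 7.27, ohd3 = 0.63, fat_pct = 76.5)
#' minced <- mixture_profile(list(lean, fat), c(0.92, 0.08))
#' round_half_up(profile_content(minced)[["vitd3"]]) # 1.39
#' @export
mixture_profile <- function(profiles, fractions) {
  if (!is.list(profiles) || length(profiles) == 0L) {
    stop("`profiles` must be a non-empty list", call. = FALSE)
  }
  if (length(fractions) != length(profiles)) {
    stop("`fractions` must match `profiles` in length", call. = FALSE)
  }
  if (any(fractions < 0)) stop("mass fractions must be non-negative", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("mass fractions must sum to 1 (got ", format(sum(fractions)), ")",
         call. = FALSE)
  }
  contents <- vapply(profiles, profile_content, numeric(length(VITAMERS)))
  mixed <- as.numeric(contents %*% fractions)
  names(mixed) <- VITAMERS
  fats <- lapply(profiles, profile_fat)
  fat <- if (all(!vapply(fats, is.null, logical(1)))) {
    sum(unlist(fats) * fractions)
  } else {
    NULL
  }
  vitamer_profile(vitd3 = mixed[["vitd3"]], vitd2 = mixed[["vitd2"]],
                  ohd3 = mixed[["ohd3"]], ohd2 = mixed[["ohd2"]],
                  fat_pct = fat)
}

#' Aggregate carcass parts into a whole-cut profile
#'
#' Mass-weighted aggregation of analysed parts into the profile of the
#' composite cut, e.g. thigh meat plus thigh skin into thigh-with-skin.
#' Inedible parts (bone) are excluded simply by leaving them out of
#' `parts`; the result is per 100 g of the edible mass supplied.
#'
#' @param parts List of parts, each a list with fields `mass` (grams, > 0)
#'   and `profile` (a [vitamer_profile()]); an optional `part_id` is
#'   carried for error messages only.
#' @return A `vitamer_profile`, identical to [mixture_profile()] with
#'   fractions `mass / sum(mass)`.
#' @examples
#' meat <- list(mass = 133, profile = vitamer_profile(ohd3 = 0.28))
#' skin <- list(mass = 21, profile = vitamer_profile(ohd3 = 0.74))
#' round_half_up(profile_content(aggregate_parts(list(meat, skin)))[["ohd3"]])
#' @export
aggregate_parts <- function(parts) {
  if (!is.list(parts) || length(parts) == 0L) {
    stop("`parts` must be a non-empty list", call. = FALSE)
  }
  masses <- vapply(parts, function(p) {
    if (is.null(p$mass) || !is.numeric(p$mass) || p$mass <= 0) {
      stop("each part needs a positive `mass` in grams", call. = FALSE)
    }
    as.numeric(p$mass)
  }, numeric(1))
  profiles <- lapply(parts, function(p) {
    if (!is_vitamer_profile(p$profile)) {
      stop("each part needs a `profile` (vitamer_profile)", call. = FALSE)
    }
    p$profile
  })
  mixture_profile(profiles, masses / sum(masses))
}

#' Convert an egg-yolk profile to a whole-egg profile
#'
#' Egg vitamers are analysed in the yolk; whole-egg content is obtained by
#' multiplying every vitamer by the yolk's mass share of the whole egg
#' (default 0.33). Censored slots stay censored, with the LOQ scaled by the
#' same factor.
#'
#' @param yolk A [vitamer_profile()] measured on yolk.
#' @param factor Yolk-to-whole-egg mass correction factor, default 0.33.
#' @return A `vitamer_profile` on the whole-egg basis.
#' @export
yolk_to_whole_egg <- function(yolk, factor = 0.33) {
  stopifnot(is_vitamer_profile(yolk))
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0) {
    stop("`factor` must be a single positive number", call. = FALSE)
  }
  scaled <- lapply(unclass(yolk)[VITAMERS], function(q) {
    if (is_censored(q)) {
      vitamer_quantity(loq = q$loq * factor)
    } else {
      vitamer_quantity(value = q$value * factor)
    }
  })
  vitamer_profile(vitd3 = scaled$vitd3, vitd2 = scaled$vitd2,
                  ohd3 = scaled$ohd3, ohd2 = scaled$ohd2,
                  fat_pct = profile_fat(yolk))
}

#' Zero-intercept fat-based prediction of dairy vitamer content
#'
#' In milk, yoghurt, cream and spreadable butter the vitamin D3 and
#' 25-hydroxyvitamin D3 contents scale linearly with fat content through
#' the origin. `fat_regression_model()` packages such a pair of slopes;
#' `fat_predict()` evaluates it. `dairy_fat_model()` returns the fitted
#' dairy model shipped with the package (slopes 0.0031 and 0.0012
#' \eqn{\mu}g/100 g per % fat). Slopes are data: fit your own with
#' [linregress()] (`zero_intercept = TRUE`) for other food groups.
#'
#' @param slope_vitd3,slope_ohd3 Slopes, \eqn{\mu}g/100 g per % fat, `>= 0`.
#' @param applicable_group Food group the model was fitted on.
#' @return `fat_regression_model()`: an object of class
#'   `fat_regression_model`. `fat_predict()`: named numeric
#'   `(vitd3, ohd3)` in \eqn{\mu}g/100 g.
#' @examples
#' fat_predict(dairy_fat_model(), 38) # close to measured cream (0.119, 0.054)
#' @export
fat_regression_model <- function(slope_vitd3, slope_ohd3,
                                 applicable_group = "dairy") {
  if (slope_vitd3 < 0 || slope_ohd3 < 0) {
    stop("slopes must be non-negative", call. = FALSE)
  }
  structure(list(slope_vitd3 = as.numeric(slope_vitd3),
                 slope_ohd3 = as.numeric(slope_ohd3),
                 applicable_group = applicable_group),
            class = "fat_regression_model")
}

#' @rdname fat_regression_model
#' @export
dairy_fat_model <- function() {
  fat_regression_model(slope_vitd3 = 0.0031, slope_ohd3 = 0.0012,
                       applicable_group = "dairy")
}

#' @rdname fat_regression_model
#' @param model A `fat_regression_model`.
#' @param fat_pct Fat content, percent by mass, in `[0, 100]`.
#' @export
fat_predict <- function(model, fat_pct) {
  stopifnot(inherits(model, "fat_regression_model"))
  if (!is.numeric(fat_pct) || any(is.na(fat_pct)) ||
      any(fat_pct < 0 | fat_pct > 100)) {
    stop("`fat_pct` must be in [0, 100]", call. = FALSE)
  }
  c(vitd3 = model$slope_vitd3 * fat_pct, ohd3 = model$slope_ohd3 * fat_pct)
}

#' Configuration of the vitamin D activity sum
#'
#' Vitamin D activity is computed as vitD3 + f x 25(OH)D3, where `factor_f`
#' converts 25-hydroxyvitamin D3 to vitamin D3 equivalents. The default
#' `factor_f = 1` treats the two as equipotent, the convention supported by
#' current reviews; bioassay work suggests 1.4-1.7, and some food databanks
#' have used 5. With `include_d2 = TRUE` the D2 vitamers are added the same
#' way (they are usually below 0.05 \eqn{\mu}g/100 g and are excluded by
#' default).
#'
#' @param factor_f Conversion factor for 25(OH)D to vitamin D equivalents,
#'   `> 0`. Default 1.
#' @param include_d2 Add vitamin D2 + f x 25(OH)D2? Default `FALSE`.
#' @return An object of class `activity_config`.
#' @export
activity_config <- function(factor_f = 1, include_d2 = FALSE) {
  if (!is.numeric(factor_f) || length(factor_f) != 1L || factor_f <= 0) {
    stop("`factor_f` must be a single positive number", call. = FALSE)
  }
  structure(list(factor_f = as.numeric(factor_f),
                 include_d2 = isTRUE(include_d2)),
            class = "activity_config")
}

#' Total vitamin D activity of a profile
#'
#' @param profile A [vitamer_profile()], or a named numeric vector with
#'   elements `vitd3`, `ohd3` (and `vitd2`, `ohd2` when `include_d2`).
#' @param cfg An [activity_config()].
#' @return Activity in \eqn{\mu}g/100 g (or the unit of the input vector).
#' @examples
#' activity(vitamer_profile(vitd3 = 1.34, ohd3 = 0.43)) # 1.77
#' @export
activity <- function(profile, cfg = activity_config()) {
  stopifnot(inherits(cfg, "activity_config"))
  x <- if (is_vitamer_profile(profile)) profile_content(profile) else profile
  out <- x[["vitd3"]] + cfg$factor_f * x[["ohd3"]]
  if (cfg$include_d2) out <- out + x[["vitd2"]] + cfg$factor_f * x[["ohd2"]]
  unname(out)
}

#' Percentage split between vitamin D3 and 25-hydroxyvitamin D3
#'
#' The share of each D3 vitamer in the unconverted vitD3 + 25(OH)D3 sum
#' (no activity conversion factor is applied: shares are defined on
#' micrograms as measured).
#'
#' @param profile A [vitamer_profile()], or a named numeric vector with
#'   elements `vitd3` and `ohd3`.
#' @return Named numeric `(pct_vitd3, pct_ohd3)` summing to 100.
#' @examples
#' vitamer_share(vitamer_profile(vitd3 = 0.014, ohd3 = 0.15)) # ~91% 25(OH)D3
#' @export
vitamer_share <- function(profile) {
  x <- if (is_vitamer_profile(profile)) profile_content(profile) else profile
  total <- x[["vitd3"]] + x[["ohd3"]]
  if (!is.finite(total) || total <= 0) {
    stop("vitamer share undefined: vitD3 + 25(OH)D3 must be positive",
         call. = FALSE)
  }
  pct_oh <- 100 * x[["ohd3"]] / total
  c(pct_vitd3 = 100 - pct_oh, pct_ohd3 = pct_oh)
}
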