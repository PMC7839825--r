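#' Create a possibly left-censored vitamer measurement
#'
#' A `vitamer_quantity` is one measurement of one vitamin D vitamer in
#' micrograms per 100 g edible portion. It is either `measured`, with an
#' observed `value`, or `below_loq`, left-censored at the method's limit of
#' quantification (`loq`). Exactly one of `value` and `loq` must be supplied.
#'
#' @param value Observed content, \eqn{\mu}g/100 g. Must be `>= 0`.
#' @param loq Limit of quantification, \eqn{\mu}g/100 g. Must be `> 0`.
#'
#' @return An object of class `vitamer_quantity` with fields `status`
#'   (`"measured"` or `"below_loq"`), `value` and `loq`.
#' @examples
#' vitamer_quantity(value = 0.88)
#' vitamer_quantity(loq = 0.01) # printed as "<0.01" in composition files
#' @export
vitamer_quantity <- function(value = NULL, loq = NULL) {
  if (is.null(value) == is.null(loq)) {
    stop("supply exactly one of `value` (measured) or `loq` (below LOQ)",
         call. = FALSE)
  }
  if (!is.null(value)) {
    if (!is.numeric(value) || length(value) != 1L || is.na(value) || value < 0) {
      stop("`value` must be a single non-negative number", call. = FALSE)
    }
    q <- list(status = "measured", value = as.numeric(value), loq = NA_real_)
  } else {
    if (!is.numeric(loq) || length(loq) != 1L || is.na(loq) || loq <= 0) {
      stop("`loq` must be a single positive number", call. = FALSE)
    }
    q <- list(status = "below_loq", value = NA_real_, loq = as.numeric(loq))
  }
  structure(q, class = "vitamer_quantity")
}

#' @rdname vitamer_quantity
#' @param x Object to test.
#' @export
is_vitamer_quantity <- function(x) inherits(x, "vitamer_quantity")

#' @rdname vitamer_quantity
#' @param q A `vitamer_quantity`.
#' @export
is_censored <- function(q) {
  stopifnot(is_vitamer_quantity(q))
  q$status == "below_loq"
}

#' @export
format.vitamer_quantity <- function(x, ...) {
  if (x$status == "measured") format(x$value, ...) else paste0("<", format(x$loq, ...))
}

#' @export
print.vitamer_quantity <- function(x, ...) {
  cat("<vitamer_quantity> ", format(x), " µg/100 g\n", sep = "")
  invisible(x)
}

as_vitamer_quantity <- function(x) {
  if (is_vitamer_quantity(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) return(vitamer_quantity(value = x))
  stop("cannot interpret object as a vitamer quantity", call. = FALSE)
}

#' Substitute a censored measurement at half its LOQ
#'
#' Left-censored (below-LOQ) measurements enter all downstream arithmetic at
#' 50% of the limit of quantification; measured values pass through
#' unchanged. This is the standard substitution convention for food
#' composition work with low censoring rates.
#'
#' @param q A `vitamer_quantity`, or a list of them.
#' @return A numeric scalar (or vector, for a list input) in \eqn{\mu}g/100 g.
#' @examples
#' censor_substitute(vitamer_quantity(loq = 0.01)) # 0.005
#' censor_substitute(vitamer_quantity(value = 0.88)) # 0.88
#' @export
censor_substitute <- function(q) {
  if (is.list(q) && !is_vitamer_quantity(q)) {
    return(vapply(q, censor_substitute, numeric(1)))
  }
  q <- as_vitamer_quantity(q)
  if (q$status == "measured") q$value else 0.5 * q$loq
}

#' Censoring-aware mean and standard deviation
#'
#' Computes the mean and sample (n - 1) standard deviation of a set of
#' possibly censored measurements, substituting censored entries at half
#' their LOQ. When more than 25% of the entries are censored the summary is
#' considered unreliable and is not computed: the result carries
#' `defined = FALSE` with `mean` and `sd` set to `NA`.
#'
#' @param values Non-empty list of `vitamer_quantity` objects (bare numerics
#'   are accepted as measured values).
#' @return A list with elements `defined`, `mean`, `sd`, `n` and
#'   `n_censored`.
#' @examples
#' qs <- list(vitamer_quantity(value = 1), vitamer_quantity(value = 2),
#'            vitamer_quantity(value = 3), vitamer_quantity(value = 4))
#' summarize_censored(qs)
#' @export
summarize_censored <- function(values) {
  if (!is.list(values) || length(values) == 0L) {
    stop("`values` must be a non-empty list of vitamer quantities", call. = FALSE)
  }
  values <- lapply(values, as_vitamer_quantity)
  n <- length(values)
  n_cens <- sum(vapply(values, is_censored, logical(1)))
  if (n_cens / n > 0.25) {
    return(list(defined = FALSE, mean = NA_real_, sd = NA_real_,
                n = n, n_censored = n_cens))
  }
  x <- vapply(values, censor_substitute, numeric(1))
  list(defined = TRUE,
       mean = mean(x),
       sd = if (n >= 2L) stats::sd(x) else NA_real_,
       n = n, n_censored = n_cens)
}

#' Round half away from zero
#'
#' Display rounding used when comparing derived cells with printed table
#' values (base R's `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
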