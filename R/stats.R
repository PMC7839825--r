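#' Group summary statistics
#'
#' Sample size, mean and sample standard deviation of one group, as
#' printed in composition tables. These are sufficient statistics for the
#' one-factor ANOVA, so published tables can be re-tested without the raw
#' data (see [anova_from_summaries()]).
#'
#' @param label Group label.
#' @param n Sample size, `>= 1` (`>= 2` when `sd` is given).
#' @param mean Group mean.
#' @param sd Sample (n - 1) standard deviation, `>= 0`; may be `NA` for
#'   `n = 1`.
#' @return A one-row tibble with columns `label`, `n`, `mean`, `sd`.
#' @export
group_summary <- function(label, n, mean, sd = NA_real_) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (!is.na(sd) && sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  if (!is.na(sd) && n < 2) stop("`sd` requires n >= 2", call. = FALSE)
  tibble::tibble(label = as.character(label), n = as.integer(n),
                 mean = as.numeric(mean), sd = as.numeric(sd))
}

test_result <- function(statistic, df, p_value, method) {
  structure(list(statistic = statistic, df = df,
                 p_value = p_value, method = method),
            class = "vitd_test")
}

#' @export
print.vitd_test <- function(x, ...) {
  cat("<", x$method, "> statistic = ", format(x$statistic),
      ", df = (", paste(format(x$df), collapse = ", "),
      "), p = ", format(x$p_value), "\n", sep = "")
  invisible(x)
}

#' One-factor analysis of variance
#'
#' Classical fixed-effects one-way ANOVA computed from between- and
#' within-group sums of squares. When every group has zero variance and
#' all means coincide the data carry no evidence of a difference and the
#' convention F = 0, p = 1 applies.
#'
#' @param groups List of numeric vectors, one per group; at least two
#'   groups with at least two observations each.
#' @return A test result with fields `statistic` (F), `df`
#'   (numerator, denominator), `p_value` and `method`.
#' @examples
#' anova_oneway(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least two groups", call. = FALSE)
  }
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("each group needs at least two observations", call. = FALSE)
  }
  summaries <- dplyr::bind_rows(lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    group_summary(paste0("g", i), length(g), mean(g), stats::sd(g))
  }))
  anova_from_summaries(summaries)
}

#' One-factor ANOVA from group means, SDs and sample sizes
#'
#' Reconstructs the one-way ANOVA F test from per-group summary
#' statistics, which are sufficient: the between-group sum of squares is
#' \eqn{\sum n_i (\bar{x}_i - \bar{x})^2} and the within-group sum of
#' squares is \eqn{\sum (n_i - 1) s_i^2}. This allows published tables of
#' means and standard deviations to be re-tested. With rounded published
#' summaries the recovered p-value is approximate (typically within a few
#' hundredths of the value computed from raw data).
#'
#' @param summaries Tibble with columns `n`, `mean`, `sd` (rows built with
#'   [group_summary()]), at least two rows, each `n >= 2`.
#' @return A test result as in [anova_oneway()].
#' @export
anova_from_summaries <- function(summaries) {
  summaries <- tibble::as_tibble(summaries)
  if (nrow(summaries) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(summaries$n < 2L)) stop("each group needs n >= 2", call. = FALSE)
  if (any(is.na(summaries$sd))) stop("each group needs an SD", call. = FALSE)
  k <- nrow(summaries)
  N <- sum(summaries$n)
  grand <- sum(summaries$n * summaries$mean) / N
  ssb <- sum(summaries$n * (summaries$mean - grand)^2)
  ssw <- sum((summaries$n - 1) * summaries$sd^2)
  df1 <- k - 1L
  df2 <- N - k
  if (ssw == 0 && ssb == 0) {
    return(test_result(0, c(df1, df2), 1, "one-way ANOVA"))
  }
  if (ssw == 0) {
    return(test_result(Inf, c(df1, df2), 0, "one-way ANOVA"))
  }
  f <- (ssb / df1) / (ssw / df2)
  test_result(f, c(df1, df2),
              stats::pf(f, df1, df2, lower.tail = FALSE), "one-way ANOVA")
}

#' Two-factor additive ANOVA with Tukey HSD comparisons
#'
#' Fits the additive two-factor model (no interaction) by least squares
#' and tests both main effects with sequential (Type-I) sums of squares:
#' factor A is tested against its one-way between-group sum of squares,
#' factor B against the additional sum of squares it explains after A;
#' both use the additive model's residual mean square. Pairwise level
#' differences within each factor are assessed with the Tukey-Kramer
#' honest-significant-difference procedure on the studentized range
#' distribution, using the same residual mean square.
#'
#' @param values Numeric response vector.
#' @param factor_a,factor_b Factors (or coercible), each with at least two
#'   levels, same length as `values`.
#' @return A list with `factor_a` and `factor_b` test results and `tukey`,
#'   a tibble of pairwise comparisons (`factor`, `level_1`, `level_2`,
#'   `diff`, `p_adj`).
#' @export
anova_twoway_tukey <- function(values, factor_a, factor_b) {
  fa <- factor(factor_a)
  fb <- factor(factor_b)
  stopifnot(length(values) == length(fa), length(values) == length(fb))
  if (nlevels(fa) < 2L || nlevels(fb) < 2L) {
    stop("each factor needs at least two levels", call. = FALSE)
  }
  n <- length(values)
  grand <- mean(values)
  sst <- sum((values - grand)^2)

  rss_of <- function(mm) {
    fit <- qr.fitted(qr(mm), values)
    sum((values - fit)^2)
  }
  rss_a <- rss_of(stats::model.matrix(~fa))
  rss_ab <- rss_of(stats::model.matrix(~fa + fb))

  ss_a <- sst - rss_a
  ss_b <- rss_a - rss_ab
  df_a <- nlevels(fa) - 1L
  df_b <- nlevels(fb) - 1L
  df_e <- n - 1L - df_a - df_b
  if (df_e < 1L) stop("no residual degrees of freedom", call. = FALSE)
  mse <- rss_ab / df_e

  main_test <- function(ss, df, label) {
    if (mse == 0) {
      if (ss == 0) return(test_result(0, c(df, df_e), 1, label))
      return(test_result(Inf, c(df, df_e), 0, label))
    }
    f <- (ss / df) / mse
    test_result(f, c(df, df_e),
                stats::pf(f, df, df_e, lower.tail = FALSE), label)
  }

  tukey_for <- function(f, which) {
    lev <- levels(f)
    means <- tapply(values, f, mean)
    ns <- tapply(rep(1, n), f, sum)
    pairs <- utils::combn(lev, 2)
    rows <- lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      d <- means[[b]] - means[[a]]
      se <- sqrt(mse / 2 * (1 / ns[[a]] + 1 / ns[[b]]))
      q <- if (se == 0) {
        if (d == 0) 0 else Inf
      } else {
        abs(d) / se
      }
      p <- if (is.infinite(q)) 0 else
        stats::ptukey(q, nmeans = length(lev), df = df_e, lower.tail = FALSE)
      tibble::tibble(factor = which, level_1 = a, level_2 = b,
                     diff = d, p_adj = p)
    })
    dplyr::bind_rows(rows)
  }

  list(factor_a = main_test(ss_a, df_a, "two-way ANOVA, factor A"),
       factor_b = main_test(ss_b, df_b, "two-way ANOVA, factor B"),
       tukey = dplyr::bind_rows(tukey_for(fa, "factor_a"),
                                tukey_for(fb, "factor_b")))
}

#' Simple linear regression with Pearson correlation
#'
#' Least-squares fit of `y` on `x` with the Pearson correlation
#' coefficient and a two-sided p-value for the slope (t distribution).
#' With `zero_intercept = TRUE` the line is forced through the origin
#' (slope \eqn{\sum x y / \sum x^2}, n - 1 residual degrees of freedom),
#' the form used to relate dairy vitamer content to fat percentage; the
#' reported `pearson_r` is always the ordinary correlation of `x` and `y`.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`; `x` must not be
#'   constant.
#' @param zero_intercept Force the fit through the origin? Default `FALSE`.
#' @return A list with `slope`, `intercept` (`NA` for the origin fit),
#'   `pearson_r`, `p_value`, `df` and `method`.
#' @examples
#' linregress(1:6, 2 * (1:6)) # slope 2, r = 1
#' @export
linregress <- function(x, y, zero_intercept = FALSE) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least three points", call. = FALSE)
  if (stats::sd(x) == 0) stop("`x` is constant", call. = FALSE)
  r <- stats::cor(x, y)
  if (zero_intercept) {
    slope <- sum(x * y) / sum(x^2)
    df <- n - 1L
    resid <- y - slope * x
    se <- sqrt(sum(resid^2) / df / sum(x^2))
    intercept <- NA_real_
  } else {
    slope <- stats::cov(x, y) / stats::var(x)
    intercept <- mean(y) - slope * mean(x)
    df <- n - 2L
    resid <- y - intercept - slope * x
    se <- sqrt(sum(resid^2) / df / sum((x - mean(x))^2))
  }
  t <- if (se == 0) {
    if (slope == 0) 0 else Inf
  } else {
    slope / se
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(slope = slope, intercept = intercept, pearson_r = r,
       p_value = p, df = df,
       method = if (zero_intercept) "zero-intercept least squares"
                else "least squares")
}
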