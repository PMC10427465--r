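#' Affine rating-scale conversion
#'
#' Maps scores linearly so the endpoints of `from` land on the endpoints of
#' `to` (an 11-point -5..+5 scale converted to a 7-point -3..+3 scale sends
#' -5 to -3, 0 to 0 and +5 to +3). Exactly invertible.
#'
#' @param scores Numeric vector within `from`.
#' @param from,to Length-2 numeric `(lo, hi)` scale bounds.
#' @return Converted scores.
#' @export
convert_scale <- function(scores, from, to) {
  stopifnot(length(from) == 2L, length(to) == 2L)
  if (from[1] == from[2]) stop("degenerate source scale", call. = FALSE)
  if (any(scores < min(from) - 1e-9 | scores > max(from) + 1e-9, na.rm = TRUE)) {
    stop("scores outside the source scale bounds", call. = FALSE)
  }
  to[1] + (scores - from[1]) * (to[2] - to[1]) / (from[2] - from[1])
}

#' Aggregate per-target attractiveness from a tidy ratings table
#'
#' Drops familiarity-flagged entries, averages over raters within each item,
#' then averages the per-item means (e.g. short- and long-term attractiveness)
#' into one score per target. Targets whose ratings are all excluded are kept
#' with `NA` and flagged.
#'
#' @param ratings Tidy tibble with columns `target_id`, `rater_id`, `item`,
#'   `score`, and optionally `familiarity` (entries equal to
#'   `familiar_level` are excluded).
#' @param items Items to aggregate over (default `c("short", "long")`).
#' @param exclude_familiar Drop familiarity-flagged entries first.
#' @param familiar_level Familiarity code meaning "knows the target well".
#' @return Tibble with `target_id`, `attractiveness`, `n_ratings`, `missing`.
#' @export
aggregate_attractiveness <- function(ratings, items = c("short", "long"),
                                     exclude_familiar = TRUE,
                                     familiar_level = 3) {
  stopifnot(all(c("target_id", "rater_id", "item", "score") %in% names(ratings)))
  present <- intersect(items, unique(ratings$item))
  if (length(present) == 0L) stop("none of the requested items are present", call. = FALSE)
  kept <- dplyr::filter(ratings, .data$item %in% items)
  if (exclude_familiar && "familiarity" %in% names(ratings)) {
    kept <- dplyr::filter(kept, is.na(.data$familiarity) |
                            .data$familiarity != familiar_level)
  }
  per_item <- kept |>
    dplyr::group_by(.data$target_id, .data$item) |>
    dplyr::summarise(item_mean = mean(.data$score), k = dplyr::n(),
                     .groups = "drop")
  out <- per_item |>
    dplyr::group_by(.data$target_id) |>
    dplyr::summarise(attractiveness = mean(.data$item_mean),
                     n_ratings = sum(.data$k), .groups = "drop")
  all_targets <- tibble::tibble(target_id = unique(ratings$target_id))
  out <- dplyr::left_join(all_targets, out, by = "target_id")
  out$n_ratings[is.na(out$n_ratings)] <- 0L
  out$missing <- is.na(out$attractiveness)
  out
}

#' Interrater reliability: two-way average-measures consistency ICC
#'
#' Computes ICC(3,k) (Shrout-Fleiss two-way mixed, consistency, average
#' measures) from the targets-by-raters ANOVA mean squares:
#' `(MS_targets - MS_error) / MS_targets`. Raters with incomplete coverage of
#' the targets are dropped to obtain a complete matrix; the model label and
#' the effective dimensions are recorded in the result.
#'
#' @param ratings Tidy tibble (`target_id`, `rater_id`, `item`, `score`).
#' @param item Which item's ratings to use; `NULL` uses all rows.
#' @return Object of class `fa_icc` with `icc`, `model`, `n_targets`,
#'   `k_raters`, `msr`, `mse`, `F`, `p`.
#' @export
interrater_icc <- function(ratings, item = NULL) {
  if (!is.null(item)) ratings <- dplyr::filter(ratings, .data$item == !!item)
  wide <- ratings |>
    dplyr::group_by(.data$target_id, .data$rater_id) |>
    dplyr::summarise(score = mean(.data$score), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "rater_id", values_from = "score")
  M <- as.matrix(wide[, -1, drop = FALSE])
  # complete matrix: drop raters missing any target
  M <- M[, colSums(is.na(M)) == 0L, drop = FALSE]
  n <- nrow(M); k <- ncol(M)
  if (n < 2L || k < 2L) stop("need at least two targets and two raters", call. = FALSE)
  grand <- mean(M)
  row_m <- rowMeans(M); col_m <- colMeans(M)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((M - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / msr
  Fv <- msr / mse
  p <- stats::pf(Fv, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  structure(list(icc = icc, model = "ICC(3,k) two-way consistency, average measures",
                 n_targets = n, k_raters = k, msr = msr, mse = mse,
                 F = Fv, p = p),
            class = "fa_icc")
}

#' @export
print.fa_icc <- function(x, ...) {
  cat(sprintf("ICC = %.3f [%s], %d targets x %d raters, F(%d,%d) = %.2f, p = %.3g\n",
              x$icc, x$model, x$n_targets, x$k_raters,
              x$n_targets - 1L, (x$n_targets - 1L) * (x$k_raters - 1L), x$F, x$p))
  invisible(x)
}

#' @export
tidy.fa_icc <- function(x, ...) {
  tibble::tibble(icc = x$icc, model = x$model, n_targets = x$n_targets,
                 k_raters = x$k_raters, statistic = x$F, p.value = x$p)
}

#' Pearson correlation with pairwise-complete cases
#'
#' Product-moment correlation with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param data Optional data frame; if given, `x` and `y` are column names
#'   (unquoted or character); otherwise numeric vectors.
#' @param x,y Variables to correlate.
#' @return Tibble with `r`, `p`, `n`.
#' @export
pearson_cor <- function(data = NULL, x, y) {
  if (!is.null(data)) {
    x <- rlang::eval_tidy(rlang::enquo(x), data)
    y <- rlang::eval_tidy(rlang::enquo(y), data)
  }
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n <= 3L) stop("need more than 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the variables", call. = FALSE)
  }
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), n - 2)
  tibble::tibble(r = r, p = p, n = n)
}

#' Pairwise correlation table
#'
#' @param data Data frame.
#' @param vars Character vector of numeric column names; default all numeric.
#' @return Tibble with one row per unordered variable pair (`var1`, `var2`,
#'   `r`, `p`, `n`), pairwise-complete.
#' @export
correlation_table <- function(data, vars = NULL) {
  if (is.null(vars)) vars <- names(data)[vapply(data, is.numeric, TRUE)]
  combos <- utils::combn(vars, 2L)
  purrr::map_dfr(seq_len(ncol(combos)), function(i) {
    v1 <- combos[1, i]; v2 <- combos[2, i]
    res <- pearson_cor(x = data[[v1]], y = data[[v2]])
    dplyr::bind_cols(tibble::tibble(var1 = v1, var2 = v2), res)
  })
}

#' Independent-samples t-test from summary statistics
#'
#' Pooled-variance Student's t by default (Welch available), with Cohen's d
#' computed against the pooled standard deviation in either case.
#'
#' @param m1,sd1,n1 Mean, SD and size of group 1.
#' @param m2,sd2,n2 Mean, SD and size of group 2.
#' @param variant `"pooled"` or `"welch"`.
#' @param labels Optional length-2 group labels.
#' @return Object of class `fa_groupcomp` with `t`, `df`, `p` (two-sided),
#'   `d`, and the group summaries.
#' @export
two_sample_t <- function(m1, sd1, n1, m2, sd2, n2,
                         variant = c("pooled", "welch"),
                         labels = c("group1", "group2")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2", call. = FALSE)
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be positive", call. = FALSE)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (variant == "pooled") {
    se <- sp * sqrt(1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
    df <- se^4 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  }
  tt <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tt), df)
  d <- (m1 - m2) / sp
  structure(list(t = tt, df = df, p = p, d = d, variant = variant,
                 groups = tibble::tibble(group = labels,
                                         mean = c(m1, m2), sd = c(sd1, sd2),
                                         n = c(n1, n2))),
            class = "fa_groupcomp")
}

#' @export
print.fa_groupcomp <- function(x, ...) {
  cat(sprintf("t(%.1f) = %.3f, p = %.3g, Cohen's d = %.3f (%s variance)\n",
              x$df, x$t, x$p, x$d, x$variant))
  invisible(x)
}

#' @export
tidy.fa_groupcomp <- function(x, ...) {
  tibble::tibble(statistic = x$t, df = x$df, p.value = x$p, cohens_d = x$d,
                 variant = x$variant)
}

#' Standardized least-squares regression
#'
#' z-scores the response and all predictors over complete cases, fits
#' ordinary least squares, and reports the standardized coefficient (beta)
#' and two-sided p-value for each predictor.
#'
#' @param data Data frame.
#' @param response Response column name (character).
#' @param predictors Character vector of predictor column names.
#' @return Object of class `fa_regression` with a `coefficients` tibble
#'   (`term`, `beta`, `se`, `statistic`, `p.value`) and `n`.
#' @export
ols_standardized <- function(data, response, predictors) {
  cols <- c(response, predictors)
  stopifnot(all(cols %in% names(data)))
  df <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  n <- nrow(df)
  if (n <= length(predictors) + 1L) stop("too few complete cases", call. = FALSE)
  z <- as.data.frame(lapply(df, function(v) as.numeric(scale(v))))
  fml <- stats::reformulate(predictors, response)
  fit <- stats::lm(fml, data = z)
  if (any(is.na(stats::coef(fit)))) stop("singular design matrix", call. = FALSE)
  sm <- summary(fit)$coefficients
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  structure(list(coefficients = tibble::tibble(
    term = rownames(sm), beta = sm[, 1], se = sm[, 2],
    statistic = sm[, 3], p.value = sm[, 4]),
    n = n, response = response),
    class = "fa_regression")
}

#' @export
print.fa_regression <- function(x, ...) {
  cat(sprintf("Standardized OLS for %s (n = %d):\n", x$response, x$n))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' @export
tidy.fa_regression <- function(x, ...) x$coefficients

#' @export
glance.fa_regression <- function(x, ...) {
  tibble::tibble(n = x$n, response = x$response)
}

#' Fisher-z equivalence test of a correlation against a bound
#'
#' Tests whether an observed correlation is reliably less negative than a
#' stated (negative) smallest effect size of interest: both `r` and `bound`
#' are Fisher z-transformed, `z = (atanh(r) - atanh(bound)) * sqrt(n - 3)`,
#' and the one-sided p-value is `P(Z > z)` under the standard normal. Small p
#' means the observed effect is statistically bounded away from (above) the
#' bound.
#'
#' @param r Observed correlation (|r| < 1).
#' @param n Sample size (> 3).
#' @param bound Equivalence bound on the correlation scale (|bound| < 1).
#' @param bound_kind Label: `"regular"` or `"conservative"`.
#' @return Object of class `fa_equivalence` with `r`, `n`, `bound`, `z`, `p`,
#'   `bound_kind`.
#' @export
equivalence_test_r <- function(r, n, bound, bound_kind = c("regular", "conservative")) {
  bound_kind <- match.arg(bound_kind)
  if (abs(r) >= 1) stop("|r| must be < 1", call. = FALSE)
  if (abs(bound) >= 1) stop("|bound| must be < 1", call. = FALSE)
  if (n <= 3) stop("need n > 3", call. = FALSE)
  z <- (atanh(r) - atanh(bound)) * sqrt(n - 3)
  p <- stats::pnorm(z, lower.tail = FALSE)
  structure(list(r = r, n = n, bound = bound, z = z, p = p,
                 bound_kind = bound_kind),
            class = "fa_equivalence")
}

#' Two one-sided tests (TOST) for a correlation against symmetric bounds
#'
#' Runs the Fisher-z one-sided test against both a lower and an upper bound
#' and reports the larger of the two one-sided p-values, the conventional
#' TOST criterion for equivalence within `(bound_low, bound_high)`.
#'
#' @inheritParams equivalence_test_r
#' @param bound_low,bound_high Lower and upper equivalence bounds.
#' @return Tibble with `r`, `n`, `bound_low`, `bound_high`, `p_lower`,
#'   `p_upper`, `p_tost`.
#' @export
equivalence_tost_r <- function(r, n, bound_low, bound_high = -bound_low) {
  stopifnot(bound_low < bound_high)
  zl <- (atanh(r) - atanh(bound_low)) * sqrt(n - 3)
  zu <- (atanh(r) - atanh(bound_high)) * sqrt(n - 3)
  p_lower <- stats::pnorm(zl, lower.tail = FALSE)
  p_upper <- stats::pnorm(zu, lower.tail = TRUE)
  tibble::tibble(r = r, n = n, bound_low = bound_low, bound_high = bound_high,
                 p_lower = p_lower, p_upper = p_upper,
                 p_tost = pmax(p_lower, p_upper))
}

#' @export
print.fa_equivalence <- function(x, ...) {
  cat(sprintf("Equivalence (Fisher z): r = %.3f (n = %d) vs %s bound %.2f: z = %.3f, one-sided p = %.4g\n",
              x$r, x$n, x$bound_kind, x$bound, x$z, x$p))
  invisible(x)
}

#' @export
tidy.fa_equivalence <- function(x, ...) {
  tibble::tibble(r = x$r, n = x$n, bound = x$bound, bound_kind = x$bound_kind,
                 statistic = x$z, p.value = x$p)
}
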