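#' Weighted frequency table for a categorical variable
#'
#' `frequency(level) = sum of weights of records at that level`;
#' `percent = 100 * frequency / total weight`. With unit weights this is the
#' ordinary count table.
#'
#' @param data A survey tibble.
#' @param variable Categorical variable name.
#' @param weight Weight column name, or `NULL` for unit weights.
#' @param levels Optional explicit level set (defaults to observed values, in
#'   order of first appearance, or the schema attribute's declared levels when
#'   present).
#' @param na.rm Drop records with a missing value of `variable` (default).
#' @return A tibble with columns `variable`, `level`, `weighted_n`,
#'   `percent`; percents sum to 100.
#' @examples
#' d <- tibble::tibble(g = c("A", "A", "B"), w = c(2, 2, 6))
#' weighted_frequency(d, "g", weight = "w")
#' @export
weighted_frequency <- function(data, variable, weight = NULL, levels = NULL,
                               na.rm = TRUE) {
  x <- data[[variable]]
  if (is.null(x)) abort(sprintf("variable '%s' not found", variable))
  w <- if (is.null(weight)) rep(1, length(x)) else data[[weight]]
  if (is.null(w)) abort(sprintf("weight column '%s' not found", weight))
  keep <- !is.na(x)
  if (!any(keep)) abort(sprintf("variable '%s' is entirely missing", variable))
  if (na.rm) { x <- x[keep]; w <- w[keep] }
  if (is.null(levels)) {
    sch <- attr(data, "schema")
    levels <- if (!is.null(sch) && variable %in% sch$variable) {
      schema_levels(sch, variable)
    } else unique(x)
  }
  f <- factor(x, levels = levels)
  freq <- as.numeric(rowsum(w, f))
  freq[is.na(freq)] <- 0
  tot <- sum(w)
  tibble(
    variable = variable,
    level = levels,
    weighted_n = freq,
    percent = 100 * freq / tot
  )
}

# Stratified with-replacement Taylor-linearization variance of the weighted
# proportion of each level; strata with a single record contribute zero
# variance (certainty-unit convention, warned once per call).
.prop_var_deff <- function(x, w, strata, levels) {
  n <- length(x)
  Wsum <- sum(w)
  s <- if (is.null(strata)) rep("all", n) else as.character(strata)
  sf <- factor(s)
  singletons <- names(which(table(sf) == 1L))
  if (length(singletons)) {
    warn(sprintf("%d stratum(-a) with a single record contribute zero variance",
                 length(singletons)))
  }
  p <- vapply(levels, function(l) sum(w[x == l]) / Wsum, numeric(1))
  V <- vapply(seq_along(levels), function(k) {
    z <- w * ((x == levels[k]) - p[k]) / Wsum
    v <- 0
    for (h in base::levels(sf)) {
      idx <- which(sf == h)
      nh <- length(idx)
      if (nh < 2L) next
      zh <- z[idx]
      v <- v + nh / (nh - 1) * sum((zh - mean(zh))^2)
    }
    v
  }, numeric(1))
  # design effect relative to the SRS variance estimator p(1-p)/(n-1), so the
  # equal-weight single-stratum case has deff exactly 1
  deff <- ifelse(p > 0 & p < 1, V / (p * (1 - p) / (n - 1)), NA_real_)
  list(p = p, var = V, deff = deff, n = n)
}

#' First-order Rao-Scott chi-square test of homogeneity
#'
#' Compares the distribution of a categorical variable between two weighted
#' samples. The Pearson homogeneity statistic is computed on the
#' design-weighted level proportions (with the actual sample sizes), then
#' divided by a first-order design-effect correction: the mean, over samples
#' and levels, of the ratio of the stratified Taylor-linearization variance
#' of each level proportion to its simple-random-sampling analogue. With unit
#' weights and a single stratum the correction is exactly 1 and the statistic
#' reduces to the ordinary Pearson chi-square. Degrees of freedom are
#' `K - 1` for `K` retained levels.
#'
#' @param data1,data2 Survey tibbles for the two samples.
#' @param variable Categorical variable present in both.
#' @param weight1,weight2 Weight column names (`NULL` = unit weights).
#' @param strata1,strata2 Stratum column names (`NULL` = one stratum).
#' @param levels Optional explicit level set; levels with zero weighted mass
#'   in both samples are dropped with a warning and the df adjusted.
#' @return A `rao_scott` object (also of class `htest`): design-corrected
#'   statistic, df, p-value, the raw Pearson statistic and the mean design
#'   effect.
#' @export
rao_scott_test <- function(data1, data2, variable,
                           weight1 = NULL, weight2 = NULL,
                           strata1 = NULL, strata2 = NULL,
                           levels = NULL) {
  get <- function(data, wcol, scol) {
    x <- data[[variable]]
    if (is.null(x)) abort(sprintf("variable '%s' not found", variable))
    w <- if (is.null(wcol)) rep(1, length(x)) else data[[wcol]]
    s <- if (is.null(scol)) NULL else data[[scol]]
    keep <- !is.na(x) & !is.na(w)
    list(x = as.character(x[keep]), w = w[keep],
         s = if (is.null(s)) NULL else s[keep])
  }
  a <- get(data1, weight1, strata1)
  b <- get(data2, weight2, strata2)
  if (is.null(levels)) levels <- union(unique(a$x), unique(b$x))
  mass <- vapply(levels, function(l) sum(a$w[a$x == l]) + sum(b$w[b$x == l]),
                 numeric(1))
  if (any(mass == 0)) {
    warn(sprintf("dropping level(s) with zero weighted mass in both samples: %s",
                 paste(levels[mass == 0], collapse = ", ")))
    levels <- levels[mass > 0]
  }
  K <- length(levels)
  if (K < 2L) abort("need at least two levels with positive mass")

  ea <- .prop_var_deff(a$x, a$w, a$s, levels)
  eb <- .prop_var_deff(b$x, b$w, b$s, levels)
  n1 <- ea$n; n2 <- eb$n
  pooled <- (n1 * ea$p + n2 * eb$p) / (n1 + n2)
  pearson <- sum(n1 * (ea$p - pooled)^2 / pooled) +
    sum(n2 * (eb$p - pooled)^2 / pooled)
  deffs <- c(ea$deff, eb$deff)
  mean_deff <- mean(deffs, na.rm = TRUE)
  if (!is.finite(mean_deff) || mean_deff <= 0) mean_deff <- 1
  stat <- pearson / mean_deff
  df <- K - 1
  structure(
    list(
      statistic = c(`X-squared (Rao-Scott)` = stat),
      parameter = c(df = df),
      p.value = pchisq(stat, df, lower.tail = FALSE),
      method = "Rao-Scott chi-square test of homogeneity (first-order correction)",
      data.name = variable,
      pearson = pearson,
      design_effect = mean_deff,
      proportions = tibble(
        level = rep(levels, 2),
        sample = rep(c("sample1", "sample2"), each = K),
        proportion = c(ea$p, eb$p),
        se = sqrt(c(ea$var, eb$var))
      )
    ),
    class = c("rao_scott", "htest")
  )
}

#' @method tidy rao_scott
#' @export
tidy.rao_scott <- function(x, ...) {
  tibble(
    statistic = unname(x$statistic),
    df = unname(x$parameter),
    p.value = x$p.value,
    pearson = x$pearson,
    design_effect = x$design_effect,
    method = x$method
  )
}

#' @method glance rao_scott
#' @export
glance.rao_scott <- function(x, ...) tidy(x)

#' Compare weighted means of a continuous variable between two samples
#'
#' Equivalent to a survey-weighted regression of the pooled variable on a
#' sample indicator: the estimate is the difference of weighted means, the
#' standard error combines the stratified Taylor-linearization variances of
#' the two means, and the p-value is a Wald normal test.
#'
#' @inheritParams rao_scott_test
#' @param variable Continuous variable present in both samples.
#' @return One-row tibble: `estimate` (mean1 - mean2), `mean1`, `mean2`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
weighted_mean_compare <- function(data1, data2, variable,
                                  weight1 = NULL, weight2 = NULL,
                                  strata1 = NULL, strata2 = NULL) {
  one <- function(data, wcol, scol) {
    y <- data[[variable]]
    if (is.null(y)) abort(sprintf("variable '%s' not found", variable))
    w <- if (is.null(wcol)) rep(1, length(y)) else data[[wcol]]
    s <- if (is.null(scol)) rep("all", length(y)) else as.character(data[[scol]])
    keep <- !is.na(y) & !is.na(w)
    y <- y[keep]; w <- w[keep]; s <- factor(s[keep])
    mu <- sum(w * y) / sum(w)
    z <- w * (y - mu) / sum(w)
    v <- 0
    for (h in base::levels(s)) {
      idx <- which(s == h)
      nh <- length(idx)
      if (nh < 2L) next
      zh <- z[idx]
      v <- v + nh / (nh - 1) * sum((zh - mean(zh))^2)
    }
    list(mean = mu, var = v, y = y)
  }
  m1 <- one(data1, weight1, strata1)
  m2 <- one(data2, weight2, strata2)
  if (var(m1$y) == 0 && var(m2$y) == 0) {
    abort("variable has zero variance in both samples; comparison is degenerate")
  }
  est <- m1$mean - m2$mean
  se <- sqrt(m1$var + m2$var)
  z <- if (se > 0) est / se else 0
  tibble(
    estimate = est, mean1 = m1$mean, mean2 = m2$mean,
    std.error = se, statistic = z,
    p.value = 2 * pnorm(-abs(z))
  )
}
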