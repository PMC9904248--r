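#' Stack probability-survey waves with composite weights
#'
#' To pool several waves of a reference probability survey, the waves are
#' stacked and every record's design weight is divided by the number of
#' waves, so the pooled weighted total estimates the (average) population
#' size rather than W times it. Wave and original stratum are combined into a
#' new stratification label, so variance strata never mix records from
#' different waves.
#'
#' @param waves Named list of survey tibbles sharing the calibration-relevant
#'   schema (names become wave labels; unnamed waves are labelled
#'   `wave1, wave2, ...`).
#' @param weight Name of the design-weight column present in every wave.
#' @param stratum Optional name of the stratum column; when absent each wave
#'   is one stratum.
#' @return A tibble of the stacked records with columns `.wave`,
#'   `.composite_weight` (original weight / number of waves) and `.stratum`
#'   (`wave:original-stratum`).
#' @examples
#' w1 <- tibble::tibble(x = c("A", "B"), wt = c(10, 20), str = "s1")
#' w2 <- tibble::tibble(x = c("B", "B"), wt = c(30, 40), str = "s1")
#' composite_combine(list(`2018` = w1, `2019` = w2), weight = "wt", stratum = "str")
#' @export
composite_combine <- function(waves, weight, stratum = NULL) {
  stopifnot(is.list(waves), length(waves) >= 1L)
  labels <- names(waves)
  if (is.null(labels) || any(labels == "")) {
    labels <- paste0("wave", seq_along(waves))
  }
  W <- length(waves)
  ref_cols <- sort(names(waves[[1]]))
  for (i in seq_along(waves)) {
    cols <- sort(names(waves[[i]]))
    if (!identical(cols, ref_cols)) {
      off <- union(setdiff(cols, ref_cols), setdiff(ref_cols, cols))
      abort(sprintf("wave '%s' schema mismatch; offending columns: %s",
                    labels[i], paste(off, collapse = ", ")))
    }
    if (!weight %in% cols) {
      abort(sprintf("weight column '%s' missing from wave '%s'", weight, labels[i]))
    }
  }
  stacked <- purrr::map2(waves, labels, function(d, lab) {
    d <- as_tibble(d)
    d$.wave <- lab
    d$.composite_weight <- d[[weight]] / W
    base_stratum <- if (!is.null(stratum)) as.character(d[[stratum]]) else "all"
    d$.stratum <- paste(lab, base_stratum, sep = ":")
    d
  })
  dplyr::bind_rows(stacked)
}

#' Benchmark totals from a probability sample
#'
#' Computes the right-hand side of the calibration constraint system: the
#' design-weighted totals \eqn{\sum_{s_A} d_i x_i} of the encoded covariate
#' indicators, against which the non-probability sample is calibrated.
#'
#' @param data Probability sample (or composite stack) tibble.
#' @param schema A [survey_schema()].
#' @param variables Categorical covariates to benchmark.
#' @param weight Name of the design-weight column (e.g. `.composite_weight`).
#' @param encoding Constraint encoding, see [encode_design_matrix()].
#' @return A `benchmark_totals` tibble with columns `constraint` and `total`;
#'   attributes carry the encoding, variable list, level sets and grand total
#'   \eqn{\hat N = \sum d_i}.
#' @export
compute_benchmarks <- function(data, schema, variables, weight,
                               encoding = c("full_margins", "reference_dropped")) {
  encoding <- match.arg(encoding)
  X <- encode_design_matrix(data, schema, variables, encoding)
  w <- data[[weight]]
  if (is.null(w)) abort(sprintf("weight column '%s' not found", weight))
  if (anyNA(w) || any(w <= 0)) abort("design weights must be positive and non-missing")
  totals <- as.numeric(crossprod(X, w))
  out <- tibble(constraint = colnames(X), total = totals)
  attr(out, "encoding") <- encoding
  attr(out, "variables") <- variables
  attr(out, "levels") <- setNames(
    purrr::map(variables, ~ schema_levels(schema, .x)), variables)
  attr(out, "grand_total") <- sum(w)
  class(out) <- c("benchmark_totals", class(out))
  out
}

# Rebuild full-margin benchmarks from a reference_dropped set (the dropped
# level's total is grand_total minus the block's other totals).
benchmarks_to_full_margins <- function(benchmarks) {
  stopifnot(attr(benchmarks, "encoding") == "reference_dropped")
  vars <- attr(benchmarks, "variables")
  lvls <- attr(benchmarks, "levels")
  Nhat <- benchmarks$total[benchmarks$constraint == "(total)"]
  rows <- purrr::map(vars, function(v) {
    lv <- lvls[[v]]
    kept <- paste0(v, "=", lv[-1])
    tk <- benchmarks$total[match(kept, benchmarks$constraint)]
    tibble(constraint = paste0(v, "=", lv),
           total = c(Nhat - sum(tk), tk))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "encoding") <- "full_margins"
  attr(out, "variables") <- vars
  attr(out, "levels") <- lvls
  attr(out, "grand_total") <- Nhat
  class(out) <- c("benchmark_totals", class(out))
  out
}

new_calibration <- function(weights, initial, method, iterations, converged,
                            benchmarks, achieved) {
  pos <- benchmarks$total > 0
  gap <- abs(achieved - benchmarks$total)
  rel <- ifelse(pos, gap / benchmarks$total, gap)
  structure(
    list(
      weights = as.numeric(weights),
      initial_weight = as.numeric(initial),
      method = method,
      iterations = iterations,
      converged = converged,
      constraints = tibble(
        constraint = benchmarks$constraint,
        target = benchmarks$total,
        achieved = achieved,
        rel_gap = rel
      ),
      max_constraint_gap = max(rel),
      weight_range = range(weights),
      distance_value = sum(0.5 * (weights / initial - 1)^2)
    ),
    class = "calibration"
  )
}

#' @method print calibration
#' @export
print.calibration <- function(x, ...) {
  cat(sprintf(
    "<calibration> method=%s  n=%d  iterations=%d  converged=%s\n",
    x$method, length(x$weights), x$iterations, x$converged))
  cat(sprintf("  max constraint gap (rel): %.3g\n", x$max_constraint_gap))
  cat(sprintf("  weight range: [%.4g, %.4g]   distance: %.6g\n",
              x$weight_range[1], x$weight_range[2], x$distance_value))
  invisible(x)
}

#' @method tidy calibration
#' @export
tidy.calibration <- function(x, ...) x$constraints

#' @method glance calibration
#' @export
glance.calibration <- function(x, ...) {
  tibble(
    method = x$method,
    n = length(x$weights),
    iterations = x$iterations,
    converged = x$converged,
    max_constraint_gap = x$max_constraint_gap,
    min_weight = x$weight_range[1],
    max_weight = x$weight_range[2],
    distance_value = x$distance_value
  )
}

#' @method autoplot calibration
#' @export
autoplot.calibration <- function(object, ...) {
  df <- tibble(ratio = object$weights / object$initial_weight)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = expression(tilde(w)[i] / w[i]),
                  y = "records",
                  title = sprintf("Calibration weight adjustment (%s)", object$method)) +
    ggplot2::theme_minimal()
}

#' Append calibrated weights to the sample they were fitted on
#'
#' @param data The non-probability sample passed to the calibration call.
#' @param calibration A `calibration` result.
#' @param name Name of the new weight column.
#' @return `data` with the calibrated-weight column appended.
#' @export
add_calibrated_weights <- function(data, calibration, name = ".calibrated_weight") {
  stopifnot(inherits(calibration, "calibration"),
            nrow(data) == length(calibration$weights))
  data[[name]] <- calibration$weights
  data
}

resolve_initial_weight <- function(data, initial_weight) {
  if (is.null(initial_weight)) {
    if (".initial_weight" %in% names(data)) data[[".initial_weight"]]
    else rep(1, nrow(data))
  } else if (is.character(initial_weight)) {
    w <- data[[initial_weight]]
    if (is.null(w)) abort(sprintf("weight column '%s' not found", initial_weight))
    w
  } else {
    stopifnot(length(initial_weight) == nrow(data))
    as.numeric(initial_weight)
  }
}

#' Closed-form quadratic-distance calibration (GREG weights)
#'
#' Minimizes the chi-square distance
#' \eqn{\sum_{s_B} \tfrac12 (\tilde w_i / w_i - 1)^2} subject to the linear
#' benchmark constraints \eqn{\sum_{s_B} \tilde w_i x_i = \sum_{s_A} d_i x_i}.
#' The stationary solution is
#' \eqn{\tilde w_i = w_i + w_i^2 \lambda^\top x_i}, with \eqn{\lambda} solving
#' \eqn{(\sum w_i^2 x_i x_i^\top)\,\lambda = T - \sum w_i x_i}. Quadratic
#' calibration can produce negative weights; the `negative_policy` controls
#' what happens then.
#'
#' @param data Non-probability sample tibble.
#' @param schema A [survey_schema()].
#' @param benchmarks A `benchmark_totals` computed with
#'   `encoding = "reference_dropped"` (a non-redundant constraint system).
#' @param initial_weight Column name, numeric vector, or `NULL` for the unit
#'   initial weights \eqn{w_i = 1}.
#' @param negative_policy What to do when the exact optimum has non-positive
#'   weights: `"raking"` (default) falls back to [calibrate_raking()] on the
#'   reconstructed full margins with a warning; `"accept"` keeps them;
#'   `"truncate"` floors them at a small positive value and re-solves the
#'   remaining weights.
#' @return A `calibration` object; see [calibrate_raking()] for the fields.
#' @export
calibrate_linear <- function(data, schema, benchmarks, initial_weight = NULL,
                             negative_policy = c("raking", "accept", "truncate")) {
  negative_policy <- match.arg(negative_policy)
  if (attr(benchmarks, "encoding") != "reference_dropped") {
    abort("calibrate_linear requires benchmarks with encoding = 'reference_dropped'")
  }
  vars <- attr(benchmarks, "variables")
  X <- encode_design_matrix(data, schema, vars, "reference_dropped")
  if (!identical(colnames(X), benchmarks$constraint)) {
    abort("benchmark constraints do not match the sample's design matrix")
  }
  w <- resolve_initial_weight(data, initial_weight)
  if (any(w <= 0)) abort("initial weights must be strictly positive")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(sprintf("constraint matrix is rank-deficient; dependent columns: %s",
                  paste(dep, collapse = ", ")))
  }
  Tvec <- benchmarks$total
  A <- crossprod(X, X * w^2)              # sum_i w_i^2 x_i x_i'
  lambda <- solve(A, Tvec - as.numeric(crossprod(X, w)))
  wt <- w + w^2 * as.numeric(X %*% lambda)

  if (any(wt <= 0) && negative_policy != "accept") {
    if (negative_policy == "raking") {
      warn("quadratic calibration produced non-positive weights; falling back to raking")
      full <- benchmarks_to_full_margins(benchmarks)
      return(calibrate_raking(data, schema, full, initial_weight = initial_weight))
    }
    # truncate-and-re-solve: fix floored weights, recalibrate the rest
    floor_val <- 1e-6 * stats::median(w)
    fixed <- rep(FALSE, length(wt))
    for (pass in 1:20) {
      neg <- wt <= 0 & !fixed
      if (!any(neg)) break
      fixed <- fixed | neg
      wt[fixed] <- floor_val
      free <- !fixed
      Tf <- Tvec - as.numeric(crossprod(X[fixed, , drop = FALSE], wt[fixed]))
      Xf <- X[free, , drop = FALSE]
      wf <- w[free]
      Af <- crossprod(Xf, Xf * wf^2)
      lam <- solve(Af, Tf - as.numeric(crossprod(Xf, wf)))
      wt[free] <- wf + wf^2 * as.numeric(Xf %*% lam)
    }
    warn(sprintf("truncated %d non-positive weight(s) and re-solved", sum(fixed)))
  } else if (any(wt <= 0)) {
    warn(sprintf("%d calibrated weight(s) are non-positive (policy = 'accept')",
                 sum(wt <= 0)))
  }
  achieved <- as.numeric(crossprod(X, wt))
  new_calibration(wt, w, "linear", iterations = 1L, converged = TRUE,
                  benchmarks = benchmarks, achieved = achieved)
}

#' Calibration by raking (iterative proportional fitting)
#'
#' Cycles over the benchmarked variables; within each variable every level
#' cell's weights are multiplied by the ratio of the benchmark total to the
#' current weighted total. Iteration stops when the largest relative margin
#' deviation falls below `tol` or `max_iter` cycles are reached. Raking keeps
#' all weights strictly positive.
#'
#' @inheritParams calibrate_linear
#' @param benchmarks A `benchmark_totals` computed with
#'   `encoding = "full_margins"`.
#' @param tol Relative margin tolerance (default `1e-8`).
#' @param max_iter Maximum number of raking cycles (default 1000).
#' @return A `calibration` object with fields `weights`, `method`,
#'   `iterations`, `converged`, per-constraint table (`tidy()`),
#'   `max_constraint_gap`, `weight_range` and the quadratic
#'   `distance_value`. Non-convergence is flagged, never silent.
#' @export
calibrate_raking <- function(data, schema, benchmarks, initial_weight = NULL,
                             tol = 1e-8, max_iter = 1000L) {
  if (attr(benchmarks, "encoding") != "full_margins") {
    abort("calibrate_raking requires benchmarks with encoding = 'full_margins'")
  }
  vars <- attr(benchmarks, "variables")
  lvls <- attr(benchmarks, "levels")
  w <- resolve_initial_weight(data, initial_weight)
  if (any(w <= 0)) abort("initial weights must be strictly positive")

  cells <- purrr::map(vars, function(v) {
    factor(data[[v]], levels = lvls[[v]])
  })
  names(cells) <- vars
  targets <- purrr::map(vars, function(v) {
    key <- paste0(v, "=", lvls[[v]])
    setNames(benchmarks$total[match(key, benchmarks$constraint)], lvls[[v]])
  })
  names(targets) <- vars

  for (v in vars) {
    if (anyNA(cells[[v]])) {
      abort(sprintf("variable '%s' has missing values; impute before calibration", v))
    }
    present <- table(cells[[v]]) > 0
    infeasible <- targets[[v]] > 0 & !present
    if (any(infeasible)) {
      abort(sprintf("infeasible raking: no sample records in cell %s=%s with positive benchmark",
                    v, names(which(infeasible))[1]))
    }
    zero_target <- targets[[v]] == 0 & present
    if (any(zero_target)) {
      abort(sprintf("cannot rake to a zero benchmark for occupied cell %s=%s",
                    v, names(which(zero_target))[1]))
    }
  }

  wt <- w
  gap <- function(wt) {
    g <- 0
    for (v in vars) {
      cur <- as.numeric(rowsum(wt, cells[[v]]))
      tg <- targets[[v]][levels(cells[[v]])]
      pos <- tg > 0
      if (any(pos)) g <- max(g, max(abs(cur[pos] - tg[pos]) / tg[pos]))
    }
    g
  }
  iter <- 0L
  converged <- gap(wt) <= tol
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    for (v in vars) {
      cur <- rowsum(wt, cells[[v]])[, 1]
      tg <- targets[[v]][names(cur)]
      f <- ifelse(cur > 0, tg / cur, 1)
      wt <- wt * f[as.integer(cells[[v]])]
    }
    converged <- gap(wt) <= tol
  }
  if (!converged) {
    warn(sprintf("raking did not converge in %d cycles (gap %.3g > tol %.3g)",
                 max_iter, gap(wt), tol))
  }
  X <- encode_design_matrix(data, schema, vars, "full_margins")
  achieved <- as.numeric(crossprod(X, wt))
  res <- new_calibration(wt, w, "raking", iterations = iter, converged = converged,
                         benchmarks = benchmarks, achieved = achieved)
  res
}
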