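# Ridge-stabilized fitters ---------------------------------------------------
#
# Two-way interactions among many categorical covariates at n of a few hundred
# are separation-prone; a small ridge penalty on the standardized predictors
# (intercept unpenalized) keeps the logistic fits finite. Because the
# intercept is unpenalized, the score equation sum(y - p) = 0 holds exactly at
# the optimum, so expected-mode self-imputation reproduces the fitting
# sample's prevalence.

.standardize <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[s == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, s, "/")
  list(X = Xs, mu = mu, s = s)
}

.ridge_logistic <- function(X, y, ridge = 1e-4, weights = NULL,
                            max_iter = 200L, tol = 1e-10) {
  n <- nrow(X)
  w <- if (is.null(weights)) rep(1, n) else weights
  std <- .standardize(X)
  Xs <- cbind(`(Intercept)` = 1, std$X)
  pvec <- c(0, rep(ridge, ncol(X)))
  # penalized negative log-likelihood, computed stably via log1p(exp(.))
  obj <- function(beta) {
    eta <- as.numeric(Xs %*% beta)
    ll <- sum(w * (y * eta - ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))))
    -ll + 0.5 * sum(pvec * beta^2)
  }
  beta <- c(qlogis(min(max(weighted.mean(y, w), 1e-6), 1 - 1e-6)),
            rep(0, ncol(X)))
  f <- obj(beta)
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(Xs %*% beta)
    p <- plogis(eta)
    Wd <- pmax(w * p * (1 - p), 1e-10)
    g <- as.numeric(crossprod(Xs, w * (y - p))) - pvec * beta
    H <- crossprod(Xs, Xs * Wd) + diag(pvec, ncol(Xs))
    step <- tryCatch(solve(H, g), error = function(e) {
      solve(H + diag(1e-8, ncol(H)), g)
    })
    # damped Newton: halve until the penalized objective decreases
    alpha <- 1
    repeat {
      cand <- beta + alpha * step
      fc <- obj(cand)
      if (fc <= f + 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    moved <- max(abs(alpha * step))
    beta <- cand
    f <- fc
    if (moved < tol) break
  }
  # back to the original predictor scale
  b <- beta[-1] / std$s
  b0 <- beta[1] - sum(beta[-1] * std$mu / std$s)
  list(coefficients = c(`(Intercept)` = b0, setNames(b, colnames(X))),
       iterations = it, separation = any(abs(beta[-1]) > 15))
}

.ridge_linear <- function(X, y, ridge = 1e-4, weights = NULL) {
  n <- nrow(X)
  w <- if (is.null(weights)) rep(1, n) else weights
  std <- .standardize(X)
  Xs <- cbind(`(Intercept)` = 1, std$X)
  P <- diag(c(0, rep(ridge, ncol(X))), ncol(Xs))
  H <- crossprod(Xs, Xs * w) + P
  beta <- solve(H, crossprod(Xs, w * y))[, 1]
  b <- beta[-1] / std$s
  b0 <- beta[1] - sum(beta[-1] * std$mu / std$s)
  fitted <- b0 + as.numeric(X %*% b)
  dof <- max(n - ncol(Xs), 1)
  sigma <- sqrt(sum(w * (y - fitted)^2) / (mean(w) * dof))
  list(coefficients = c(`(Intercept)` = b0, setNames(b, colnames(X))),
       sigma = sigma, separation = FALSE, iterations = 1L)
}

# Predictor-matrix construction ----------------------------------------------

.as_factor_frame <- function(data, schema, vars) {
  out <- purrr::map(vars, function(v) {
    kind <- schema$kind[match(v, schema$variable)]
    if (is.na(kind)) abort(sprintf("variable '%s' not in schema", v))
    if (kind %in% c("categorical", "binary")) {
      factor(data[[v]], levels = schema_levels(schema, v))
    } else {
      as.numeric(data[[v]])
    }
  })
  names(out) <- vars
  as.data.frame(out, optional = TRUE, check.names = FALSE)
}

# Main-effect dummies of the covariates plus (optionally) all pairwise
# interaction columns, via treatment-coded model.matrix. Returns the full
# matrix without the intercept column; column retention is decided at fit
# time and reused at predict time.
.predictor_matrix <- function(data, schema, covariates, interactions,
                              extra = character()) {
  ff <- .as_factor_frame(data, schema, c(covariates, extra))
  if (anyNA(ff)) {
    abort("missing values among predictors; run fcs_single_impute() first")
  }
  rhs <- if (interactions && length(covariates) > 1L) {
    sprintf("(%s)^2", paste(sprintf("`%s`", covariates), collapse = " + "))
  } else {
    paste(sprintf("`%s`", covariates), collapse = " + ")
  }
  if (length(extra)) {
    rhs <- paste(rhs, paste(sprintf("`%s`", extra), collapse = " + "), sep = " + ")
  }
  mm <- model.matrix(as.formula(paste("~", rhs)), data = ff)
  mm[, colnames(mm) != "(Intercept)", drop = FALSE]
}

# Drop zero-variance columns, then exactly collinear ones (QR pivoting).
.retain_columns <- function(X) {
  keep <- apply(X, 2, function(col) sd(col) > 0)
  dropped_zero <- colnames(X)[!keep]
  X1 <- X[, keep, drop = FALSE]
  dropped_collinear <- character()
  if (ncol(X1)) {
    q <- qr(cbind(1, X1))
    r <- q$rank
    if (r < ncol(X1) + 1L) {
      piv <- q$pivot[seq_len(r)]
      keep_idx <- sort(setdiff(piv, 1L)) - 1L
      dropped_collinear <- setdiff(colnames(X1), colnames(X1)[keep_idx])
      X1 <- X1[, keep_idx, drop = FALSE]
    }
  }
  list(X = X1, retained = colnames(X1),
       dropped_zero_variance = dropped_zero,
       dropped_collinear = dropped_collinear)
}

# Mass-imputation model set ---------------------------------------------------

#' Fit the sequential mass-imputation outcome models
#'
#' For every outcome, fits a prediction model on the non-probability sample:
#' logistic regression for binary outcomes, multinomial logistic for
#' categorical outcomes with more than two levels, linear regression for
#' continuous outcomes. Predictors are the main effects of the categorical
#' covariates plus, by default, all two-way interaction terms. Columns with
#' zero variance or exact collinearity in the fitting sample are dropped and
#' recorded; a small ridge penalty on the standardized predictors stabilizes
#' separation-prone logistic fits.
#'
#' @param data Non-probability sample tibble with complete covariates and
#'   outcomes (item-missing imputation precedes this step).
#' @param schema A [survey_schema()].
#' @param outcomes Character vector of outcome variable names.
#' @param covariates Character vector of categorical covariate names.
#' @param interactions Include all pairwise covariate interactions (default
#'   `TRUE`).
#' @param ridge Ridge penalty on standardized predictors (default `1e-4`).
#' @param weights Optional weight column name (models are fitted unweighted by
#'   default, matching unit initial weights in the convenience sample).
#' @param chained If `TRUE`, the model for each outcome additionally
#'   conditions on the previously listed outcomes (main effects), so imputed
#'   outcomes feed forward sequentially. Off by default: the canonical
#'   predictor set is covariates + interactions only.
#' @return A `mass_imputation_models` object (one entry per outcome).
#' @export
fit_mass_imputation_models <- function(data, schema, outcomes, covariates,
                                       interactions = TRUE, ridge = 1e-4,
                                       weights = NULL, chained = FALSE) {
  w <- if (is.null(weights)) NULL else data[[weights]]
  models <- list()
  for (k in seq_along(outcomes)) {
    oc <- outcomes[k]
    kind <- schema$kind[match(oc, schema$variable)]
    if (is.na(kind)) abort(sprintf("outcome '%s' not in schema", oc))
    yraw <- data[[oc]]
    if (anyNA(yraw)) {
      abort(sprintf("outcome '%s' has missing values; impute item missingness first", oc))
    }
    extra <- if (chained && k > 1L) outcomes[seq_len(k - 1L)] else character()
    Xfull <- .predictor_matrix(data, schema, covariates, interactions, extra)
    sel <- .retain_columns(Xfull)
    X <- sel$X

    if (kind %in% c("categorical", "binary")) {
      lv <- schema_levels(schema, oc)
      obs <- unique(yraw)
      if (length(obs) < 2L) {
        abort(sprintf(
          "outcome '%s' has a single observed class ('%s'); exclude it from the outcome list",
          oc, obs))
      }
      if (length(lv) == 2L) {
        y <- as.numeric(yraw == lv[2])
        fit <- .ridge_logistic(X, y, ridge = ridge, weights = w)
        models[[oc]] <- list(
          outcome = oc, type = "logistic", levels = lv, positive = lv[2],
          coefficients = fit$coefficients, retained = sel$retained,
          dropped_zero_variance = sel$dropped_zero_variance,
          dropped_collinear = sel$dropped_collinear,
          separation = fit$separation, iterations = fit$iterations,
          prevalence = mean(y), extra = extra
        )
      } else {
        df <- data.frame(.y = factor(yraw, levels = lv), X, check.names = FALSE)
        fit <- nnet::multinom(.y ~ ., data = df, decay = ridge, trace = FALSE,
                              maxit = 500, MaxNWts = 100000)
        models[[oc]] <- list(
          outcome = oc, type = "multinomial", levels = lv,
          fit = fit, retained = sel$retained,
          dropped_zero_variance = sel$dropped_zero_variance,
          dropped_collinear = sel$dropped_collinear,
          separation = FALSE, iterations = NA_integer_,
          prevalence = as.numeric(prop.table(table(factor(yraw, levels = lv)))),
          extra = extra
        )
      }
    } else {
      y <- as.numeric(yraw)
      if (var(y) == 0) {
        abort(sprintf("continuous outcome '%s' has zero variance", oc))
      }
      fit <- .ridge_linear(X, y, ridge = ridge, weights = w)
      models[[oc]] <- list(
        outcome = oc, type = "linear", coefficients = fit$coefficients,
        sigma = fit$sigma, retained = sel$retained,
        dropped_zero_variance = sel$dropped_zero_variance,
        dropped_collinear = sel$dropped_collinear,
        separation = FALSE, iterations = fit$iterations,
        prevalence = mean(y), extra = extra
      )
    }
  }
  structure(
    list(models = models, outcomes = outcomes, covariates = covariates,
         interactions = interactions, ridge = ridge, chained = chained,
         fit_n = nrow(data), schema = schema),
    class = "mass_imputation_models"
  )
}

#' @method print mass_imputation_models
#' @export
print.mass_imputation_models <- function(x, ...) {
  cat(sprintf("<mass_imputation_models> %d outcome model(s), fitted on n=%d\n",
              length(x$models), x$fit_n))
  cat(sprintf("  predictors: %d covariate(s)%s, ridge=%g%s\n",
              length(x$covariates),
              if (x$interactions) " + two-way interactions" else "",
              x$ridge, if (x$chained) ", chained on prior outcomes" else ""))
  for (m in x$models) {
    cat(sprintf("  %s [%s]: %d term(s), %d dropped%s\n", m$outcome, m$type,
                length(m$retained),
                length(m$dropped_zero_variance) + length(m$dropped_collinear),
                if (isTRUE(m$separation)) ", separation-flagged" else ""))
  }
  invisible(x)
}

#' @method tidy mass_imputation_models
#' @export
tidy.mass_imputation_models <- function(x, ...) {
  purrr::map_dfr(x$models, function(m) {
    if (m$type == "multinomial") {
      return(tibble(outcome = m$outcome, term = "(multinomial fit)",
                    estimate = NA_real_))
    }
    tibble(outcome = m$outcome, term = names(m$coefficients),
           estimate = unname(m$coefficients))
  })
}

#' @method glance mass_imputation_models
#' @export
glance.mass_imputation_models <- function(x, ...) {
  purrr::map_dfr(x$models, function(m) {
    tibble(
      outcome = m$outcome, type = m$type,
      n_terms = length(m$retained),
      n_dropped = length(m$dropped_zero_variance) + length(m$dropped_collinear),
      separation = isTRUE(m$separation),
      fit_prevalence = if (m$type == "multinomial") NA_real_ else m$prevalence
    )
  })
}

.predict_model <- function(m, data, schema, covariates, interactions,
                           unseen_policy = "reference") {
  Xfull <- .predictor_matrix(data, schema, covariates, interactions, m$extra)
  zv <- intersect(m$dropped_zero_variance, colnames(Xfull))
  if (length(zv)) {
    hit <- colSums(Xfull[, zv, drop = FALSE] != 0) > 0
    if (any(hit)) {
      msg <- sprintf(
        "recipient sample activates predictor column(s) unseen in the fitting sample: %s",
        paste(names(hit)[hit], collapse = ", "))
      if (unseen_policy == "error") abort(msg)
      warn(paste0(msg, "; mapped to the reference level"))
    }
  }
  if (m$type == "multinomial") {
    newdf <- data.frame(Xfull[, m$retained, drop = FALSE], check.names = FALSE)
    p <- predict(m$fit, newdata = newdf, type = "probs")
    if (is.null(dim(p))) p <- matrix(p, nrow = 1)
    colnames(p) <- m$fit$lev
    return(list(prob = p))
  }
  X <- Xfull[, m$retained, drop = FALSE]
  eta <- m$coefficients[1] + as.numeric(X %*% m$coefficients[m$retained])
  if (m$type == "logistic") list(prob = plogis(pmin(pmax(eta, -30), 30)))
  else list(mean = eta, sigma = m$sigma)
}

#' Sequentially impute outcomes into a probability sample
#'
#' Transfers the fitted outcome models to the recipient (probability) sample
#' and imputes the outcomes one at a time in the given order — once, producing
#' a single imputed data file. In `stochastic` mode binary outcomes are
#' independent Bernoulli draws at the predicted probability (continuous:
#' normal draws at the predicted mean with the residual SD); in `expected`
#' mode the predicted probability/mean itself is stored, for use in
#' plug-in estimators.
#'
#' @param data Recipient sample tibble carrying all covariate columns the
#'   models were fitted on.
#' @param models A [fit_mass_imputation_models()] result.
#' @param order Outcome imputation order (default: the fitted order).
#' @param draw_mode `"stochastic"` (default) or `"expected"`.
#' @param seed Integer seed; identical inputs + seed give bit-identical
#'   imputations.
#' @param unseen_policy What to do when the recipient sample activates a
#'   predictor column that had zero variance in the fitting sample:
#'   `"reference"` (map to reference level with a warning) or `"error"`.
#' @return The tibble with imputed outcome columns; attribute `"provenance"`
#'   records seed, order, draw mode and model metadata.
#' @export
mass_impute <- function(data, models, order = NULL,
                        draw_mode = c("stochastic", "expected"),
                        seed = 1L, unseen_policy = c("reference", "error")) {
  draw_mode <- match.arg(draw_mode)
  unseen_policy <- match.arg(unseen_policy)
  stopifnot(inherits(models, "mass_imputation_models"))
  order <- order %||% models$outcomes
  if (!all(order %in% models$outcomes)) {
    abort("imputation order contains outcomes without fitted models")
  }
  schema <- models$schema
  n <- nrow(data)
  out <- data
  withr::with_seed(seed, {
    for (oc in order) {
      m <- models$models[[oc]]
      pred <- .predict_model(m, out, schema, models$covariates,
                             models$interactions, unseen_policy)
      if (m$type == "logistic") {
        if (draw_mode == "stochastic") {
          draw <- runif(n) < pred$prob
          out[[oc]] <- ifelse(draw, m$positive, setdiff(m$levels, m$positive)[1])
        } else {
          out[[oc]] <- as.numeric(pred$prob)
        }
      } else if (m$type == "multinomial") {
        if (draw_mode == "stochastic") {
          cum <- t(apply(pred$prob, 1, cumsum))
          u <- runif(n)
          idx <- rowSums(u > cum) + 1L
          out[[oc]] <- colnames(pred$prob)[idx]
        } else {
          out[[oc]] <- pred$prob[, ncol(pred$prob)]
        }
      } else {
        out[[oc]] <- if (draw_mode == "stochastic") {
          rnorm(n, pred$mean, pred$sigma)
        } else pred$mean
      }
    }
  })
  attr(out, "provenance") <- list(
    seed = seed, order = order, draw_mode = draw_mode,
    fit_n = models$fit_n, chained = models$chained, ridge = models$ridge
  )
  out
}

# FCS single imputation of item missingness -----------------------------------

.hotdeck_draw <- function(observed, n) {
  tab <- table(observed)
  sample(names(tab), n, replace = TRUE, prob = as.numeric(tab))
}

#' Single imputation of item-missing values by fully conditional specification
#'
#' Fills item-missing values before data integration. Variables are visited
#' in order of ascending missing rate; each incomplete variable is modeled on
#' all other listed variables using the currently completed data (logistic
#' for binary, multinomial for categorical, linear for continuous) and its
#' missing entries are replaced by random draws from the fitted predictive
#' distribution. Observed values are never altered, and a single completed
#' data set is returned (no multiple imputation).
#'
#' @param data A survey tibble.
#' @param schema A [survey_schema()].
#' @param variables Variables to complete (default: all schema covariates and
#'   outcomes present in `data`).
#' @param cycles Number of FCS sweeps over the incomplete variables
#'   (default 5).
#' @param seed Integer seed (bit-identical output for identical inputs).
#' @param max_missing Error ceiling on the per-variable missing rate
#'   (default 0.5).
#' @return The completed tibble; attribute `"fcs"` records the visit order,
#'   per-variable missing counts and any model fallbacks.
#' @export
fcs_single_impute <- function(data, schema, variables = NULL, cycles = 5L,
                              seed = 1L, max_missing = 0.5) {
  variables <- variables %||%
    intersect(schema_vars(schema, role = c("covariate", "outcome")), names(data))
  miss_n <- vapply(variables, function(v) sum(is.na(data[[v]])), integer(1))
  incomplete <- variables[miss_n > 0]
  if (!length(incomplete)) return(data)
  rates <- miss_n[incomplete] / nrow(data)
  if (any(rates >= 1)) {
    abort(sprintf("variable '%s' is entirely missing",
                  incomplete[which(rates >= 1)[1]]))
  }
  if (any(rates > max_missing)) {
    abort(sprintf("missing rate of '%s' exceeds the ceiling of %.0f%%",
                  incomplete[which(rates > max_missing)[1]], 100 * max_missing))
  }
  visit <- incomplete[base::order(rates)]
  na_idx <- purrr::map(visit, ~ which(is.na(data[[.x]])))
  names(na_idx) <- visit
  fallbacks <- character()

  kind_of <- function(v) schema$kind[match(v, schema$variable)]

  withr::with_seed(seed, {
    # initial fill: marginal hot-deck draws
    for (v in visit) {
      idx <- na_idx[[v]]
      obs <- data[[v]][-idx]
      if (kind_of(v) == "continuous") {
        data[[v]][idx] <- sample(obs, length(idx), replace = TRUE)
      } else {
        data[[v]][idx] <- .hotdeck_draw(obs, length(idx))
      }
    }
    for (cyc in seq_len(cycles)) {
      for (v in visit) {
        idx <- na_idx[[v]]
        preds <- setdiff(variables, v)
        yobs <- data[[v]][-idx]
        if (length(unique(yobs)) < 2L) {
          data[[v]][idx] <- yobs[1]        # degenerate marginal
          next
        }
        imputed <- tryCatch({
          X <- .predictor_matrix(data, schema, preds, interactions = FALSE)
          sel <- .retain_columns(X[-idx, , drop = FALSE])
          Xo <- sel$X
          Xm <- X[idx, sel$retained, drop = FALSE]
          kind <- kind_of(v)
          if (kind == "continuous") {
            fit <- .ridge_linear(Xo, data[[v]][-idx], ridge = 1e-6)
            mu <- fit$coefficients[1] +
              as.numeric(Xm %*% fit$coefficients[sel$retained])
            rnorm(length(idx), mu, fit$sigma)
          } else {
            lv <- schema_levels(schema, v)
            if (length(lv) == 2L) {
              fit <- .ridge_logistic(Xo, as.numeric(data[[v]][-idx] == lv[2]),
                                     ridge = 1e-4)
              eta <- fit$coefficients[1] +
                as.numeric(Xm %*% fit$coefficients[sel$retained])
              ifelse(runif(length(idx)) < plogis(eta), lv[2], lv[1])
            } else {
              df <- data.frame(.y = factor(data[[v]][-idx], levels = lv), Xo,
                               check.names = FALSE)
              fit <- nnet::multinom(.y ~ ., data = df, decay = 1e-4,
                                    trace = FALSE, maxit = 300, MaxNWts = 100000)
              p <- predict(fit, newdata = data.frame(Xm, check.names = FALSE),
                           type = "probs")
              if (is.null(dim(p))) p <- matrix(p, nrow = length(idx), byrow = TRUE,
                                               dimnames = list(NULL, fit$lev))
              cum <- t(apply(p, 1, cumsum))
              u <- runif(length(idx))
              colnames(p)[rowSums(u > cum) + 1L]
            }
          }
        }, error = function(e) {
          fallbacks <<- c(fallbacks, v)
          inform(sprintf("FCS model for '%s' failed (%s); hot-deck fallback",
                         v, conditionMessage(e)))
          if (kind_of(v) == "continuous") sample(yobs, length(idx), replace = TRUE)
          else .hotdeck_draw(yobs, length(idx))
        })
        data[[v]][idx] <- imputed
      }
    }
  })
  attr(data, "fcs") <- list(
    visit_order = visit, missing_n = miss_n[visit],
    cycles = cycles, seed = seed, fallbacks = unique(fallbacks)
  )
  data
}
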