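# Synthetic finite-population harness ----------------------------------------
#
# Emulates the study setting: a finite population of adults with categorical
# demographic/health covariates and binary outcomes, a stratified reference
# survey with design weights, and a convenience sample whose inclusion
# propensity depends on the covariates (over-representing older, female,
# lower-income, higher-BMI respondents). Truth is computed by enumerating the
# realized population, so every estimator's bias is measurable.

default_covariates <- function() {
  list(
    list(name = "age", levels = c("18-34", "35-49", "50-64", "65+"),
         probs = c(0.40, 0.25, 0.22, 0.13)),
    list(name = "gender", levels = c("Male", "Female"),
         probs = c(0.49, 0.51)),
    list(name = "marital", levels = c("Married", "PreviouslyMarried", "NeverMarried"),
         probs = c(0.44, 0.25, 0.31)),
    list(name = "education", levels = c("LessThanHS", "HSGraduate", "SomeCollege", "CollegeGraduate"),
         probs = c(0.14, 0.38, 0.33, 0.15)),
    list(name = "employment", levels = c("Employed", "Unemployed", "Retired", "UnableToWork"),
         probs = c(0.58, 0.18, 0.11, 0.13)),
    list(name = "income", levels = c("Low", "Middle", "High"),
         probs = c(0.25, 0.35, 0.40)),
    list(name = "bmi", levels = c("UnderOrNormal", "Overweight", "Obese"),
         probs = c(0.24, 0.36, 0.40)),
    list(name = "genhealth", levels = c("Excellent", "VeryGood", "Good", "FairPoor"),
         probs = c(0.14, 0.29, 0.31, 0.26))
  )
}

default_outcomes <- function() {
  list(
    list(name = "smoke", intercept = -2.05,
         coef = list(income = c(Low = 0.9), education = c(LessThanHS = 0.5),
                     genhealth = c(FairPoor = 0.7))),
    list(name = "arthritis", intercept = -2.2,
         coef = list(age = c(`50-64` = 0.9, `65+` = 1.4),
                     bmi = c(Obese = 0.5), genhealth = c(FairPoor = 0.6))),
    list(name = "cvd", intercept = -3.3,
         coef = list(age = c(`50-64` = 0.8, `65+` = 1.5),
                     gender = c(Male = 0.4), genhealth = c(FairPoor = 0.9))),
    list(name = "copd", intercept = -3.4,
         coef = list(age = c(`50-64` = 0.6, `65+` = 0.9),
                     genhealth = c(FairPoor = 1.0), income = c(Low = 0.4))),
    list(name = "asthma", intercept = -2.2,
         coef = list(gender = c(Female = 0.3), bmi = c(Obese = 0.4),
                     genhealth = c(FairPoor = 0.4))),
    list(name = "cancer", intercept = -3.5,
         coef = list(age = c(`50-64` = 0.8, `65+` = 1.6))),
    list(name = "stroke", intercept = -4.0,
         coef = list(age = c(`50-64` = 0.7, `65+` = 1.4),
                     genhealth = c(FairPoor = 0.9))),
    list(name = "diabetes", intercept = -3.1,
         coef = list(bmi = c(Overweight = 0.4, Obese = 1.0),
                     age = c(`50-64` = 0.8, `65+` = 1.1),
                     income = c(Low = 0.3))),
    list(name = "healthcov", intercept = 1.2,
         coef = list(income = c(Low = -1.1, High = 0.9)))
  )
}

default_selection <- function(target_n = 635) {
  list(
    target_n = target_n,
    intercept = NULL,   # solved so the expected sample size equals target_n
    coef = list(
      gender = c(Female = 1.25),
      age = c(`35-49` = 0.2, `50-64` = 0.6, `65+` = 0.8),
      income = c(Low = 0.7, High = -0.5),
      bmi = c(Overweight = 0.1, Obese = 0.5),
      genhealth = c(Good = 0.3, FairPoor = 0.4)
    )
  )
}

default_design <- function() {
  list(
    stratum = "region",
    stratum_levels = c("R1", "R2", "R3", "R4"),
    stratum_probs = c(0.15, 0.25, 0.30, 0.30),
    waves = list(
      `2018` = list(n_per_stratum = c(R1 = 97, R2 = 122, R3 = 122, R4 = 145)),
      `2019` = list(n_per_stratum = c(R1 = 98, R2 = 122, R3 = 122, R4 = 145))
    )
  )
}

#' Configuration of the synthetic finite population
#'
#' Bundles everything the generator needs: the population size, the
#' categorical covariate distributions (optionally correlated through a
#' latent Gaussian copula), per-outcome logistic models, the
#' covariate-dependent selection mechanism of the convenience sample, and
#' the stratified design of the reference survey. The defaults mirror the
#' motivating study's scale: N = 300,000 adults, a two-wave reference survey
#' of about 973 records, a convenience sample of about 635, eight covariates
#' and nine binary outcomes, with selection favouring older, female,
#' lower-income, higher-BMI respondents.
#'
#' @param N Population size.
#' @param covariates List of covariate specs: `name`, `levels`, `probs`.
#' @param outcomes List of outcome specs: `name`, `intercept`, `coef` (named
#'   list of named level-coefficient vectors on the logit scale).
#' @param selection Convenience-sample selection spec: `target_n`, optional
#'   `intercept` (solved when `NULL`), `coef` as above.
#' @param design Reference-survey design: stratum variable, stratum level
#'   probabilities, and per-wave per-stratum sample sizes.
#' @param copula_rho Exchangeable latent correlation among covariates
#'   (default 0.3), so calibration on covariates transfers to outcomes.
#' @param missingness Item-missingness injected into drawn samples by the
#'   evaluation harness: `rate` (MCAR) and `variables`.
#' @return A `population_config` list.
#' @export
population_config <- function(N = 300000,
                              covariates = default_covariates(),
                              outcomes = default_outcomes(),
                              selection = default_selection(),
                              design = default_design(),
                              copula_rho = 0.3,
                              missingness = list(rate = 0.02,
                                                 variables = c("marital", "income"))) {
  for (cv in covariates) {
    if (abs(sum(cv$probs) - 1) > 1e-8) {
      abort(sprintf("level probabilities of '%s' must sum to 1", cv$name))
    }
    if (length(cv$probs) != length(cv$levels)) {
      abort(sprintf("'%s': probs and levels differ in length", cv$name))
    }
  }
  if (!is.null(selection$target_n) && selection$target_n > N) {
    abort("expected convenience-sample size exceeds the population size")
  }
  structure(
    list(N = N, covariates = covariates, outcomes = outcomes,
         selection = selection, design = design, copula_rho = copula_rho,
         missingness = missingness),
    class = "population_config"
  )
}

#' Schema matching a population configuration
#'
#' @param config A [population_config()].
#' @return A [survey_schema()] declaring the covariates (role `covariate`),
#'   binary outcomes (role `outcome`, levels No/Yes), the stratum variable,
#'   and the design-weight column `.design_weight`.
#' @export
synthetic_schema <- function(config) {
  vars <- c(
    purrr::map(config$covariates, function(cv) {
      schema_variable(cv$name, "categorical", levels = cv$levels)
    }),
    purrr::map(config$outcomes, function(oc) {
      schema_variable(oc$name, "binary", levels = c("No", "Yes"), role = "outcome")
    }),
    list(
      schema_variable(config$design$stratum, "categorical",
                      levels = config$design$stratum_levels, role = "stratum"),
      schema_variable(".design_weight", "continuous", role = "weight")
    )
  )
  survey_schema(vars)
}

.linpred <- function(data, intercept, coef) {
  eta <- rep(intercept, nrow(data))
  for (v in names(coef)) {
    b <- coef[[v]]
    for (l in names(b)) eta <- eta + b[[l]] * (data[[v]] == l)
  }
  eta
}

#' Generate a synthetic finite population with known truth
#'
#' Covariates are drawn through a latent Gaussian copula with exchangeable
#' correlation (`copula_rho`), categorized at the cumulative-probability
#' thresholds of each variable's declared margins; each binary outcome is a
#' Bernoulli draw at `plogis(intercept + sum of level coefficients)`. Truth
#' (per-level frequencies and percents) is computed by full enumeration of
#' the realized population, not from the generating parameters.
#'
#' @param config A [population_config()].
#' @param seed Integer seed; the same seed reproduces the population exactly.
#' @return A list: `population` (tibble), `truth` (a `synthetic_truth`
#'   tibble), `schema` (the matching [survey_schema()]), `config`.
#' @export
generate_population <- function(config, seed = 1L) {
  stopifnot(inherits(config, "population_config"))
  N <- config$N
  rho <- config$copula_rho
  pop <- withr::with_seed(seed, {
    z0 <- rnorm(N)
    cols <- purrr::map(config$covariates, function(cv) {
      z <- sqrt(rho) * z0 + sqrt(1 - rho) * rnorm(N)
      u <- pnorm(z)
      br <- c(0, cumsum(cv$probs))
      br[length(br)] <- 1
      cv$levels[findInterval(u, br, rightmost.closed = TRUE)]
    })
    names(cols) <- purrr::map_chr(config$covariates, "name")
    pop <- as_tibble(cols)
    pop[[config$design$stratum]] <- sample(
      config$design$stratum_levels, N, replace = TRUE,
      prob = config$design$stratum_probs)
    for (oc in config$outcomes) {
      p <- plogis(.linpred(pop, oc$intercept, oc$coef))
      pop[[oc$name]] <- ifelse(runif(N) < p, "Yes", "No")
    }
    pop
  })
  vars <- c(purrr::map_chr(config$covariates, "name"),
            purrr::map_chr(config$outcomes, "name"))
  truth <- purrr::map_dfr(vars, function(v) {
    tab <- table(pop[[v]])
    tibble(variable = v, level = names(tab),
           frequency = as.numeric(tab),
           percent = 100 * as.numeric(tab) / N)
  })
  attr(truth, "coefficients") <- config$outcomes
  attr(truth, "N") <- N
  class(truth) <- c("synthetic_truth", class(truth))
  list(population = pop, truth = truth, schema = synthetic_schema(config),
       config = config)
}

#' Draw a stratified probability sample with design weights
#'
#' Stratified simple random sampling without replacement; each record in
#' stratum *h* gets design weight \eqn{d_i = N_h / n_h}, so Horvitz-Thompson
#' weighted totals are design-unbiased for population totals.
#'
#' @param population Population tibble.
#' @param n_per_stratum Named vector of per-stratum sample sizes.
#' @param stratum Stratum column name (default `"region"`).
#' @param seed Integer seed.
#' @return The sampled tibble with a `.design_weight` column.
#' @export
draw_probability_sample <- function(population, n_per_stratum,
                                    stratum = "region", seed = 1L) {
  s <- population[[stratum]]
  if (is.null(s)) abort(sprintf("stratum column '%s' not found", stratum))
  strata <- names(n_per_stratum)
  if (!all(strata %in% unique(s))) {
    abort("n_per_stratum names must be population strata")
  }
  withr::with_seed(seed, {
    rows <- purrr::map(strata, function(h) {
      idx <- which(s == h)
      Nh <- length(idx)
      nh <- n_per_stratum[[h]]
      if (nh > Nh) abort(sprintf("stratum '%s': n_h = %d exceeds N_h = %d", h, nh, Nh))
      take <- if (nh == Nh) idx else sample(idx, nh)
      out <- population[take, , drop = FALSE]
      out$.design_weight <- Nh / nh
      out
    })
    dplyr::bind_rows(rows)
  })
}

#' Draw a covariate-dependent convenience (non-probability) sample
#'
#' Each population unit enters independently with propensity
#' `plogis(intercept + covariate effects)`. When the intercept is `NULL` it
#' is solved so the expected sample size equals `target_n`. Initial weights
#' are all 1. With the default coefficients the realized sample
#' over-represents women (about 78% female against roughly 51% in the
#' population), older, lower-income and higher-BMI respondents — the skew
#' pattern convenience health surveys show.
#'
#' @param population Population tibble.
#' @param selection Selection spec (see [population_config()]).
#' @param seed Integer seed.
#' @return The selected tibble with `.initial_weight = 1`; attribute
#'   `"propensity_intercept"` records the solved intercept.
#' @export
draw_nonprobability_sample <- function(population, selection, seed = 1L) {
  if (is.null(selection$target_n) && is.null(selection$intercept)) {
    abort("selection needs a target_n or an explicit intercept")
  }
  base_eta <- .linpred(population, 0, selection$coef %||% list())
  a <- selection$intercept
  if (is.null(a)) {
    if (selection$target_n <= 0) abort("expected sample size must be positive")
    a <- uniroot(function(a) sum(plogis(a + base_eta)) - selection$target_n,
                 interval = c(-30, 10), tol = 1e-10)$root
  }
  p <- plogis(a + base_eta)
  out <- withr::with_seed(seed, {
    population[runif(nrow(population)) < p, , drop = FALSE]
  })
  if (nrow(out) == 0L) abort("selection produced an empty sample")
  out$.initial_weight <- 1
  attr(out, "propensity_intercept") <- a
  out
}

#' Inject MCAR item missingness into a drawn sample
#'
#' @param data A sample tibble.
#' @param variables Columns to receive missing values.
#' @param rate Per-variable MCAR missing rate.
#' @param seed Integer seed.
#' @return The tibble with `NA`s injected.
#' @export
inject_missing <- function(data, variables, rate, seed = 1L) {
  if (rate <= 0) return(data)
  withr::with_seed(seed, {
    for (v in variables) {
      idx <- which(runif(nrow(data)) < rate)
      data[[v]][idx] <- NA
    }
  })
  data
}
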