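imp_schema <- function() {
  survey_schema(
    schema_variable("x1", "binary", levels = c("A", "B")),
    schema_variable("x2", "categorical", levels = c("P", "Q", "R")),
    schema_variable("y", "binary", levels = c("No", "Yes"), role = "outcome"),
    schema_variable("wt", "continuous", role = "weight")
  )
}

imp_sample <- function(n, seed = 1, beta = 1.5) {
  withr::with_seed(seed, {
    x1 <- sample(c("A", "B"), n, replace = TRUE)
    x2 <- sample(c("P", "Q", "R"), n, replace = TRUE)
    p <- plogis(-1 + beta * (x1 == "B") + 0.5 * (x2 == "R"))
    tibble::tibble(x1 = x1, x2 = x2,
                   y = ifelse(runif(n) < p, "Yes", "No"), wt = 1)
  })
}

test_that("a complete sample passes through FCS unchanged", {
  sch <- imp_schema()
  d <- imp_sample(50, seed = 1)
  expect_identical(fcs_single_impute(d, sch, seed = 9), d)
})

test_that("a degenerate observed marginal imputes its constant value", {
  sch <- imp_schema()
  d <- imp_sample(100, seed = 2)
  d$y <- "Yes"
  d$y[c(5, 50, 95)] <- NA
  out <- fcs_single_impute(d, sch, seed = 3)
  expect_true(all(out$y == "Yes"))
})

test_that("observed values are never altered and seeds reproduce exactly", {
  sch <- imp_schema()
  d <- imp_sample(150, seed = 4)
  miss <- c(3, 40, 77, 120)
  d$x1[miss] <- NA
  out1 <- fcs_single_impute(d, sch, seed = 11)
  out2 <- fcs_single_impute(d, sch, seed = 11)
  expect_identical(out1, out2)
  expect_identical(out1$x1[-miss], d$x1[-miss])
  expect_false(anyNA(out1$x1))
  out3 <- fcs_single_impute(d, sch, seed = 12)
  expect_false(identical(out1$x1[miss], out3$x1[miss]) &&
                 identical(out1, d))  # different seed may differ; no NA left
})

test_that("MCAR imputation preserves the observed marginal across replicates", {
  sch <- imp_schema()
  base <- imp_sample(200, seed = 6)
  p_obs <- mean(base$x1 == "B")
  props <- vapply(1:200, function(r) {
    d <- inject_missing(base, "x1", rate = 0.05, seed = r)
    idx <- which(is.na(d$x1))
    out <- fcs_single_impute(d, sch, cycles = 2L, seed = r + 1000L)
    mean(out$x1[idx] == "B")
  }, numeric(1))
  mc_se <- sd(props) / sqrt(length(props))
  expect_lt(abs(mean(props) - p_obs), 3 * mc_se)
})

test_that("a null outcome model predicts the sample prevalence", {
  sch <- imp_schema()
  d <- imp_sample(1000, seed = 7, beta = 0)
  d$y <- withr::with_seed(8, sample(c("No", "Yes"), 1000, replace = TRUE,
                                    prob = c(0.7, 0.3)))
  mods <- fit_mass_imputation_models(d, sch, "y", c("x1", "x2"),
                                     interactions = TRUE)
  imp <- mass_impute(d[c("x1", "x2", "wt")], mods, draw_mode = "expected",
                     seed = 1)
  prev <- mean(d$y == "Yes")
  se <- sqrt(prev * (1 - prev) / nrow(d))
  expect_true(all(abs(imp$y - prev) < 3 * se + 0.05))
  expect_lt(abs(mean(imp$y) - prev), 1e-6)  # score-equation property
})

test_that("a logistic generating coefficient is recovered within 3 SE", {
  sch <- imp_schema()
  d <- imp_sample(2000, seed = 9, beta = 1.0)
  mods <- fit_mass_imputation_models(d, sch, "y", c("x1", "x2"),
                                     interactions = FALSE, ridge = 1e-8)
  got <- mods$models$y$coefficients[["x1B"]]
  # oracle: unpenalized ML fit of the same correctly specified model
  oracle <- glm(I(y == "Yes") ~ x1 + x2, family = binomial, data = d)
  se <- summary(oracle)$coefficients["x1B", "Std. Error"]
  expect_lt(abs(got - 1.0), 3 * se)
  expect_lt(abs(got - coef(oracle)[["x1B"]]), 1e-4)
})

test_that("perfectly collinear predictor columns are dropped and recorded", {
  sch <- survey_schema(
    schema_variable("x1", "binary", levels = c("A", "B")),
    schema_variable("x2", "binary", levels = c("A2", "B2")),
    schema_variable("y", "binary", levels = c("No", "Yes"), role = "outcome"),
    schema_variable("wt", "continuous", role = "weight")
  )
  d <- withr::with_seed(10, {
    x1 <- sample(c("A", "B"), 200, replace = TRUE)
    tibble::tibble(x1 = x1, x2 = ifelse(x1 == "A", "A2", "B2"),
                   y = sample(c("No", "Yes"), 200, replace = TRUE), wt = 1)
  })
  mods <- fit_mass_imputation_models(d, sch, "y", c("x1", "x2"),
                                     interactions = FALSE)
  m <- mods$models$y
  expect_gte(length(c(m$dropped_collinear, m$dropped_zero_variance)), 1L)
  expect_false(anyNA(m$coefficients))
})

test_that("an outcome with a single observed class is rejected", {
  sch <- imp_schema()
  d <- imp_sample(100, seed = 11)
  d$y <- "No"
  expect_error(fit_mass_imputation_models(d, sch, "y", c("x1", "x2")),
               "single observed class")
})

test_that("degenerate certainty models impute the positive level in both modes", {
  sch <- imp_schema()
  d <- imp_sample(200, seed = 12)
  mods <- fit_mass_imputation_models(d, sch, "y", c("x1", "x2"),
                                     interactions = FALSE)
  # force a certainty model: huge intercept on the fitted object
  mods$models$y$coefficients[] <- 0
  mods$models$y$coefficients[1] <- 40
  s <- mass_impute(d[c("x1", "x2", "wt")], mods, draw_mode = "stochastic", seed = 2)
  e <- mass_impute(d[c("x1", "x2", "wt")], mods, draw_mode = "expected", seed = 2)
  expect_true(all(s$y == "Yes"))
  expect_true(all(e$y > 1 - 1e-12))
})

test_that("stochastic draws at constant probability match the binomial oracle", {
  sch <- imp_schema()
  d <- imp_sample(300, seed = 13)
  mods <- fit_mass_imputation_models(d, sch, "y", c("x1", "x2"),
                                     interactions = FALSE)
  mods$models$y$coefficients[] <- 0
  mods$models$y$coefficients[1] <- qlogis(0.3)
  big <- tibble::tibble(
    x1 = rep(c("A", "B"), 5000), x2 = rep(c("P", "Q"), 5000), wt = 1)
  imp <- mass_impute(big, mods, draw_mode = "stochastic", seed = 3)
  expect_lt(abs(mean(imp$y == "Yes") - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
})

test_that("expected-mode self-imputation reproduces each outcome's prevalence", {
  sch <- imp_schema()
  d <- imp_sample(635, seed = 14)
  mods <- fit_mass_imputation_models(d, sch, "y", c("x1", "x2"),
                                     interactions = TRUE)
  imp <- mass_impute(d[c("x1", "x2", "wt")], mods, draw_mode = "expected",
                     seed = 4)
  expect_lt(abs(mean(imp$y) - mean(d$y == "Yes")), 1e-6)
})

test_that("mass imputation is seed-deterministic", {
  sch <- imp_schema()
  d <- imp_sample(200, seed = 15)
  mods <- fit_mass_imputation_models(d, sch, "y", c("x1", "x2"))
  recip <- d[c("x1", "x2", "wt")]
  expect_identical(mass_impute(recip, mods, seed = 5),
                   mass_impute(recip, mods, seed = 5))
})

test_that("chained mode conditions later outcomes on earlier ones", {
  sch <- survey_schema(
    schema_variable("x1", "binary", levels = c("A", "B")),
    schema_variable("y1", "binary", levels = c("No", "Yes"), role = "outcome"),
    schema_variable("y2", "binary", levels = c("No", "Yes"), role = "outcome"),
    schema_variable("wt", "continuous", role = "weight")
  )
  d <- withr::with_seed(16, {
    x1 <- sample(c("A", "B"), 400, replace = TRUE)
    y1 <- ifelse(runif(400) < plogis(-0.5 + (x1 == "B")), "Yes", "No")
    y2 <- ifelse(runif(400) < plogis(-1 + 1.5 * (y1 == "Yes")), "Yes", "No")
    tibble::tibble(x1 = x1, y1 = y1, y2 = y2, wt = 1)
  })
  mods <- fit_mass_imputation_models(d, sch, c("y1", "y2"), "x1",
                                     interactions = FALSE, chained = TRUE)
  expect_equal(mods$models$y2$extra, "y1")
  expect_true("y1Yes" %in% names(mods$models$y2$coefficients))
  imp <- mass_impute(d["x1"] |> dplyr::mutate(wt = 1), mods, seed = 6)
  expect_false(anyNA(imp$y2))
})
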