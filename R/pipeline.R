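#' Run the full data-integration pipeline
#'
#' Executes, in order: single imputation of item-missing values in every
#' input file, composite combination of the probability-survey waves,
#' calibration of the non-probability sample to the combined benchmark
#' margins, mass imputation of the outcomes into the combined probability
#' sample, and four estimate sets per outcome:
#'
#' * `reference_weighted` — design (composite) weights on the probability
#'   sample's observed outcomes (the evaluation truth stand-in);
#' * `naive_unweighted` — unit weights on the convenience sample;
#' * `calibration` — calibrated weights on the convenience sample;
#' * `mass_imputation` — composite weights on the imputed outcomes in the
#'   combined probability sample.
#'
#' Pairwise Rao-Scott tests compare the outcome distributions between
#' methods. Any stage failure aborts with the stage name; partial results are
#' never returned.
#'
#' @param waves Named list of probability-sample wave tibbles.
#' @param npdata Non-probability sample tibble.
#' @param schema A [survey_schema()] covering covariates and outcomes.
#' @param covariates Categorical covariates used for calibration and as
#'   imputation predictors.
#' @param outcomes Outcome variables (must be present in `npdata`;
#'   reference estimates are computed when also present in the waves).
#' @param weight Design-weight column name in the waves.
#' @param stratum Optional stratum column name in the waves.
#' @param calibration List of calibration options: `method`
#'   (`"raking"`/`"linear"`), `tol`, `max_iter`.
#' @param imputation List of mass-imputation options: `interactions`,
#'   `ridge`, `chained`, `draw_mode`, `order`.
#' @param impute_missing Run [fcs_single_impute()] on inputs first
#'   (default `TRUE`; skipped automatically when nothing is missing).
#' @param fcs_cycles FCS sweeps for item-missing imputation.
#' @param seed Integer seed driving every stochastic stage.
#' @return A `method_comparison` object.
#' @export
run_integration <- function(waves, npdata, schema, covariates, outcomes,
                            weight, stratum = NULL,
                            calibration = list(), imputation = list(),
                            impute_missing = TRUE, fcs_cycles = 3L,
                            seed = 1L) {
  cal_opts <- modifyList(
    list(method = "raking", tol = 1e-8, max_iter = 1000L), calibration)
  imp_opts <- modifyList(
    list(interactions = TRUE, ridge = 1e-4, chained = FALSE,
         draw_mode = "stochastic", order = NULL), imputation)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  cfg_hash <- rlang::hash(list(
    waves = waves, npdata = npdata, covariates = covariates,
    outcomes = outcomes, cal = cal_opts, imp = imp_opts, seed = seed))

  if (impute_missing) {
    stage("item_missing_imputation", {
      vars <- intersect(c(covariates, outcomes), names(npdata))
      for (i in seq_along(waves)) {
        wv <- intersect(covariates, names(waves[[i]]))
        if (anyNA(waves[[i]][wv])) {
          waves[[i]] <- fcs_single_impute(waves[[i]], schema, variables = wv,
                                          cycles = fcs_cycles, seed = seed + i)
        }
      }
      if (anyNA(npdata[vars])) {
        npdata <- fcs_single_impute(npdata, schema, variables = vars,
                                    cycles = fcs_cycles, seed = seed + 101L)
      }
    })
  }

  combined <- stage("composite_combine",
                    composite_combine(waves, weight = weight, stratum = stratum))

  cal <- stage("calibration", {
    if (cal_opts$method == "raking") {
      bm <- compute_benchmarks(combined, schema, covariates,
                               weight = ".composite_weight",
                               encoding = "full_margins")
      calibrate_raking(npdata, schema, bm, tol = cal_opts$tol,
                       max_iter = cal_opts$max_iter)
    } else {
      bm <- compute_benchmarks(combined, schema, covariates,
                               weight = ".composite_weight",
                               encoding = "reference_dropped")
      calibrate_linear(npdata, schema, bm)
    }
  })
  npdata <- add_calibrated_weights(npdata, cal)

  models <- stage("fit_mass_imputation_models",
                  fit_mass_imputation_models(
                    npdata, schema, outcomes, covariates,
                    interactions = imp_opts$interactions,
                    ridge = imp_opts$ridge, chained = imp_opts$chained))
  imputed <- stage("mass_impute", {
    recip <- combined
    recip[outcomes] <- NULL   # outcomes treated as unobserved in the recipient
    mass_impute(recip, models, order = imp_opts$order,
                draw_mode = imp_opts$draw_mode, seed = seed + 500L)
  })

  positive <- setNames(purrr::map_chr(outcomes, function(oc) {
    lv <- schema_levels(schema, oc)
    lv[length(lv)]
  }), outcomes)

  estimates <- stage("estimation", purrr::map_dfr(outcomes, function(oc) {
    lv <- schema_levels(schema, oc)
    rows <- list()
    if (oc %in% names(combined)) {
      rows$reference_weighted <- weighted_frequency(
        combined, oc, weight = ".composite_weight", levels = lv)
    }
    rows$naive_unweighted <- weighted_frequency(npdata, oc, levels = lv)
    rows$calibration <- weighted_frequency(
      npdata, oc, weight = ".calibrated_weight", levels = lv)
    rows$mass_imputation <- if (imp_opts$draw_mode == "stochastic") {
      weighted_frequency(imputed, oc, weight = ".composite_weight", levels = lv)
    } else {
      w <- imputed$.composite_weight
      p <- imputed[[oc]]
      tibble(variable = oc, level = lv,
             weighted_n = c(sum(w * (1 - p)), sum(w * p)),
             percent = 100 * c(weighted.mean(1 - p, w), weighted.mean(p, w)))
    }
    dplyr::bind_rows(rows, .id = "method") |>
      dplyr::rename(outcome = "variable")
  }))

  tests <- stage("rao_scott_comparisons", {
    sources <- list(
      reference_weighted = list(data = combined, weight = ".composite_weight",
                                strata = ".stratum"),
      naive_unweighted = list(data = npdata, weight = NULL, strata = NULL),
      calibration = list(data = npdata, weight = ".calibrated_weight",
                         strata = NULL),
      mass_imputation = if (imp_opts$draw_mode == "stochastic") {
        list(data = imputed, weight = ".composite_weight", strata = ".stratum")
      }
    )
    sources <- purrr::compact(sources)
    pairs <- utils::combn(names(sources), 2, simplify = FALSE)
    purrr::map_dfr(outcomes, function(oc) {
      purrr::map_dfr(pairs, function(pr) {
        s1 <- sources[[pr[1]]]; s2 <- sources[[pr[2]]]
        if (!oc %in% names(s1$data) || !oc %in% names(s2$data)) return(NULL)
        rs <- suppressWarnings(rao_scott_test(
          s1$data, s2$data, oc,
          weight1 = s1$weight, weight2 = s2$weight,
          strata1 = s1$strata, strata2 = s2$strata,
          levels = schema_levels(schema, oc)))
        tibble(outcome = oc, method_1 = pr[1], method_2 = pr[2],
               statistic = unname(rs$statistic), df = unname(rs$parameter),
               p_value = rs$p.value)
      })
    })
  })

  structure(
    list(
      estimates = estimates,
      tests = tests,
      calibration = cal,
      models = glance(models),
      positive_levels = positive,
      meta = list(seed = seed, config_hash = cfg_hash,
                  calibration = cal_opts, imputation = imp_opts,
                  n_waves = length(waves), n_np = nrow(npdata))
    ),
    class = "method_comparison"
  )
}

#' @method print method_comparison
#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison> %d outcome(s), seed=%d, config=%s\n",
              length(unique(x$estimates$outcome)), x$meta$seed,
              substr(x$meta$config_hash, 1, 8)))
  pos <- x$positive_levels
  wide <- x$estimates |>
    dplyr::filter(.data$level == pos[.data$outcome]) |>
    dplyr::select("outcome", "method", "percent") |>
    tidyr::pivot_wider(names_from = "method", values_from = "percent")
  print(wide, n = Inf)
  invisible(x)
}

#' @method tidy method_comparison
#' @export
tidy.method_comparison <- function(x, ...) x$estimates

#' @method glance method_comparison
#' @export
glance.method_comparison <- function(x, ...) {
  tibble(
    n_outcomes = length(unique(x$estimates$outcome)),
    n_waves = x$meta$n_waves,
    n_nonprobability = x$meta$n_np,
    calibration_method = x$meta$calibration$method,
    calibration_converged = x$calibration$converged,
    max_constraint_gap = x$calibration$max_constraint_gap,
    draw_mode = x$meta$imputation$draw_mode,
    seed = x$meta$seed,
    config_hash = x$meta$config_hash
  )
}

#' @method autoplot method_comparison
#' @export
autoplot.method_comparison <- function(object, ...) {
  pos <- object$positive_levels
  df <- object$estimates |>
    dplyr::filter(.data$level == pos[.data$outcome])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome, y = .data$percent,
                                   fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "weighted percent",
                  title = "Outcome prevalence by integration method") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bias of each integration method against known truth
#'
#' Computes, per outcome and method, the percent-scale bias
#' `estimate - truth`, its absolute value, and the within-outcome rank of
#' the methods (1 = smallest absolute bias).
#'
#' @param x A `method_comparison`, or a tibble with columns `outcome`,
#'   `method`, `percent`.
#' @param truth A `synthetic_truth`, a named numeric vector of true percents
#'   per outcome, or a tibble with columns `outcome` and `percent`. For a
#'   `synthetic_truth`, the positive ("Yes") level's percent is used.
#' @return A tibble: `outcome`, `method`, `percent`, `truth`, `bias`,
#'   `abs_bias`, `rank`.
#' @export
evaluate_bias <- function(x, truth) {
  est <- if (inherits(x, "method_comparison")) {
    pos <- x$positive_levels
    x$estimates |>
      dplyr::filter(.data$level == pos[.data$outcome]) |>
      dplyr::select("outcome", "method", "percent")
  } else {
    as_tibble(x)[, c("outcome", "method", "percent")]
  }
  tr <- if (inherits(truth, "synthetic_truth")) {
    truth |>
      dplyr::filter(.data$level == "Yes") |>
      dplyr::select(outcome = "variable", truth = "percent")
  } else if (is.numeric(truth) && !is.null(names(truth))) {
    tibble(outcome = names(truth), truth = unname(truth))
  } else {
    dplyr::rename(as_tibble(truth), truth = "percent")
  }
  missing_truth <- setdiff(unique(est$outcome), tr$outcome)
  if (length(missing_truth)) {
    abort(sprintf("no truth entry for outcome(s): %s",
                  paste(missing_truth, collapse = ", ")))
  }
  est |>
    dplyr::left_join(tr, by = "outcome") |>
    dplyr::mutate(bias = .data$percent - .data$truth,
                  abs_bias = abs(.data$bias)) |>
    dplyr::group_by(.data$outcome) |>
    dplyr::mutate(rank = rank(.data$abs_bias, ties.method = "min")) |>
    dplyr::ungroup()
}

#' Monte-Carlo bias study on the synthetic population
#'
#' Generates one finite population from `config`, then repeatedly draws the
#' two reference-survey waves and the convenience sample, runs the full
#' integration pipeline, and evaluates each method's outcome estimates
#' against the enumerated population truth.
#'
#' @param config A [population_config()].
#' @param replicates Number of Monte-Carlo replicates.
#' @param seed Integer master seed (population and all replicate draws).
#' @param draw_mode Mass-imputation draw mode passed to the pipeline.
#' @param interactions Include two-way interactions in the imputation models.
#'   Default `FALSE`: the synthetic outcomes are generated from main-effects
#'   logistic models, so the main-effects imputation model is the correctly
#'   specified one; the interaction set (about 175 columns at n of a few
#'   hundred) severely overfits and inflates rare-outcome predictions.
#' @param impute_missing Inject and re-impute item missingness per the
#'   config's `missingness` block.
#' @param progress Emit a message every 10 replicates.
#' @return A tibble per outcome x method: `mean_percent`, `bias` (mean
#'   estimate minus truth), `abs_bias`, `mc_se` (MC standard error of the
#'   mean estimate), `mean_abs_error` (mean per-replicate absolute error).
#'   Attributes: `truth`, `replicates`, `per_replicate` (full results).
#' @export
run_bias_study <- function(config = population_config(), replicates = 50L,
                           seed = 1L, draw_mode = "stochastic",
                           interactions = FALSE, impute_missing = TRUE,
                           progress = FALSE) {
  gen <- generate_population(config, seed = seed)
  pop <- gen$population
  schema <- gen$schema
  covars <- purrr::map_chr(config$covariates, "name")
  outs <- purrr::map_chr(config$outcomes, "name")
  waves_cfg <- config$design$waves
  miss <- config$missingness

  rep_seeds <- withr::with_seed(seed, {
    matrix(sample.int(2^31 - 2, replicates * 4), ncol = 4)
  })
  results <- purrr::map_dfr(seq_len(replicates), function(r) {
    waves <- purrr::imap(waves_cfg, function(wc, lab) {
      i <- match(lab, names(waves_cfg))
      draw_probability_sample(pop, wc$n_per_stratum,
                              stratum = config$design$stratum,
                              seed = rep_seeds[r, i])
    })
    nps <- draw_nonprobability_sample(pop, config$selection,
                                      seed = rep_seeds[r, 3])
    use_missing <- impute_missing && !is.null(miss) && miss$rate > 0
    if (use_missing) {
      nps <- inject_missing(nps, miss$variables, miss$rate,
                            seed = rep_seeds[r, 4])
    }
    cmp <- run_integration(
      waves, nps, schema, covars, outs,
      weight = ".design_weight", stratum = config$design$stratum,
      imputation = list(interactions = interactions, draw_mode = draw_mode),
      impute_missing = use_missing, seed = rep_seeds[r, 4])
    if (progress && r %% 10 == 0) inform(sprintf("replicate %d/%d", r, replicates))
    dplyr::mutate(evaluate_bias(cmp, gen$truth), replicate = r)
  })
  summary <- results |>
    dplyr::group_by(.data$outcome, .data$method) |>
    dplyr::summarise(
      truth = .data$truth[1],
      mean_percent = mean(.data$percent),
      bias = mean(.data$bias),
      abs_bias = abs(mean(.data$bias)),
      mc_se = sd(.data$percent) / sqrt(dplyr::n()),
      mean_abs_error = mean(.data$abs_bias),
      .groups = "drop"
    )
  attr(summary, "truth") <- gen$truth
  attr(summary, "replicates") <- replicates
  attr(summary, "per_replicate") <- results
  summary
}
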