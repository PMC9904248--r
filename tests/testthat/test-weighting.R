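test_that("composite weighting divides by the number of waves and relabels strata", {
  w1 <- tibble::tibble(x = c("A", "B"), wt = c(10, 20), str = c("s1", "s2"))
  w2 <- tibble::tibble(x = c("B", "B"), wt = c(30, 40), str = c("s1", "s1"))
  cc <- composite_combine(list(`2018` = w1, `2019` = w2),
                          weight = "wt", stratum = "str")
  expect_equal(nrow(cc), 4)
  expect_equal(cc$.composite_weight, c(5, 10, 15, 20))
  expect_equal(cc$.stratum, c("2018:s1", "2018:s2", "2019:s1", "2019:s1"))
  # strata never merge records from different waves
  expect_false(any(table(cc$.stratum, cc$.wave) > 0 &
                     rowSums(table(cc$.stratum, cc$.wave) > 0) > 1))
})

test_that("a single wave leaves weights untouched", {
  w1 <- tibble::tibble(x = "A", wt = 7)
  cc <- composite_combine(list(only = w1), weight = "wt")
  expect_equal(cc$.composite_weight, 7)
})

test_that("combined weighted total is the mean of wave totals", {
  w1 <- tibble::tibble(x = c("A", "A"), wt = c(60, 40))    # total 100
  w2 <- tibble::tibble(x = c("A", "B"), wt = c(100, 200))  # total 300
  cc <- composite_combine(list(a = w1, b = w2), weight = "wt")
  expect_equal(sum(cc$.composite_weight), 200)
})

test_that("wave schema mismatch names the offending columns", {
  w1 <- tibble::tibble(x = "A", wt = 1)
  w2 <- tibble::tibble(x = "A", wt = 1, extra = 1)
  expect_error(composite_combine(list(w1, w2), weight = "wt"), "extra")
})

test_that("benchmark totals are design-weighted margins", {
  sch <- survey_schema(
    schema_variable("v", "binary", levels = c("A", "B")),
    schema_variable("wt", "continuous", role = "weight")
  )
  d <- tibble::tibble(v = c("A", "B"), wt = c(2, 3))
  bm <- compute_benchmarks(d, sch, "v", "wt", "full_margins")
  expect_equal(bm$total, c(2, 3))
  expect_equal(attr(bm, "grand_total"), 5)

  # unit weights reduce to raw level counts
  d2 <- tibble::tibble(v = c("A", "A", "B"), wt = 1)
  bm2 <- compute_benchmarks(d2, sch, "v", "wt", "full_margins")
  expect_equal(bm2$total, c(2, 1))
})

test_that("benchmarks match an independent weighted cross-tab on a larger sample", {
  sch <- demo_schema()
  d <- demo_sample(50, seed = 7)
  bm <- compute_benchmarks(d, sch, c("gender", "agegrp"), "wt", "full_margins")
  or_g <- xtabs(wt ~ factor(gender, c("Male", "Female")), d)
  or_a <- xtabs(wt ~ factor(agegrp, c("young", "mid", "old")), d)
  expect_equal(bm$total, c(as.numeric(or_g), as.numeric(or_a)), tolerance = 1e-12)
  # block-sum invariant: every variable's block sums to the grand total
  expect_equal(sum(bm$total[1:2]), attr(bm, "grand_total"))
  expect_equal(sum(bm$total[3:5]), attr(bm, "grand_total"))
})

test_that("quadratic calibration leaves feasible starting weights unchanged", {
  sch <- demo_schema()
  d <- demo_sample(40, seed = 5)
  bm <- compute_benchmarks(d, sch, c("gender", "agegrp"), "wt",
                           "reference_dropped")
  cal <- calibrate_linear(d, sch, bm, initial_weight = "wt")
  expect_equal(cal$weights, d$wt, tolerance = 1e-10)
  expect_equal(cal$distance_value, 0, tolerance = 1e-12)
})

test_that("total-only constraint scales unit weights symmetrically", {
  # n=3, w=(1,1,1), single total constraint T=6: Lagrange solution w=(2,2,2);
  # validates the KKT oracle against hand arithmetic before it is used as the
  # reference for the package's closed form below
  X <- matrix(1, 3, 1, dimnames = list(NULL, "(total)"))
  u <- qp_oracle(X, rep(1, 3), 6)
  expect_equal(u, rep(2, 3), tolerance = 1e-12)
})

test_that("quadratic calibration agrees with a generic KKT quadratic minimizer", {
  sch <- demo_schema()
  for (seed in 1:10) {
    d <- demo_sample(30, seed = seed)
    ref <- demo_sample(60, seed = seed + 100)
    bm <- compute_benchmarks(ref, sch, c("gender", "agegrp"), "wt",
                             "reference_dropped")
    cal <- suppressWarnings(
      calibrate_linear(d, sch, bm, initial_weight = "wt",
                       negative_policy = "accept"))
    X <- encode_design_matrix(d, sch, c("gender", "agegrp"),
                              "reference_dropped")
    u <- qp_oracle(X, d$wt, bm$total)
    expect_equal(cal$weights, u, tolerance = 1e-8)
    expect_lt(cal$max_constraint_gap, 1e-10)
  }
})

test_that("rank-deficient constraint systems are rejected with column names", {
  sch <- survey_schema(
    schema_variable("v", "categorical", levels = c("A", "B", "C")),
    schema_variable("wt", "continuous", role = "weight")
  )
  d <- tibble::tibble(v = c("A", "B", "A", "B"), wt = 1)  # level C unobserved
  ref <- tibble::tibble(v = c("A", "B", "C"), wt = 2)
  bm <- compute_benchmarks(ref, sch, "v", "wt", "reference_dropped")
  expect_error(calibrate_linear(d, sch, bm), "rank-deficient.*v=C")
})

test_that("raking solves a single margin in one multiplicative cycle", {
  sch <- survey_schema(
    schema_variable("v", "binary", levels = c("A", "B")),
    schema_variable("wt", "continuous", role = "weight")
  )
  d <- tibble::tibble(v = c("A", "A", "B"), wt = c(1, 2, 4))
  ref <- tibble::tibble(v = c("A", "B"), wt = c(9, 8))
  bm <- compute_benchmarks(ref, sch, "v", "wt", "full_margins")
  cal <- calibrate_raking(d, sch, bm, initial_weight = "wt")
  expect_equal(cal$iterations, 1L)
  # closed form: each cell scaled by target / current weighted cell total
  expect_equal(cal$weights, c(1 * 9 / 3, 2 * 9 / 3, 4 * 8 / 4), tolerance = 1e-12)
})

test_that("raking is a no-op when benchmarks equal the sample margins", {
  sch <- demo_schema()
  d <- demo_sample(25, seed = 8)
  bm <- compute_benchmarks(d, sch, c("gender", "agegrp"), "wt", "full_margins")
  cal <- calibrate_raking(d, sch, bm, initial_weight = "wt")
  expect_equal(cal$weights, d$wt, tolerance = 1e-12)
})

test_that("two-variable raking matches an independent table-IPF oracle", {
  sch <- demo_schema()
  d <- demo_sample(30, seed = 13)
  ref <- demo_sample(90, seed = 14)
  bm <- compute_benchmarks(ref, sch, c("gender", "agegrp"), "wt", "full_margins")
  cal <- calibrate_raking(d, sch, bm, initial_weight = "wt", tol = 1e-10)
  expect_true(cal$converged)
  expect_true(all(cal$weights > 0))

  # oracle: classic IPF on the aggregated 2x3 cell table
  cell <- xtabs(wt ~ factor(gender, c("Male", "Female")) +
                  factor(agegrp, c("young", "mid", "old")), d)
  m_g <- bm$total[1:2]; m_a <- bm$total[3:5]
  fitted <- ipf_table_oracle(as.matrix(cell), list(m_g, m_a))
  got <- xtabs(cal$weights ~ factor(d$gender, c("Male", "Female")) +
                 factor(d$agegrp, c("young", "mid", "old")))
  expect_equal(as.numeric(got), as.numeric(fitted), tolerance = 1e-6)

  # grand-total conservation under full margins
  expect_equal(sum(cal$weights), attr(bm, "grand_total"), tolerance = 1e-6)
})

test_that("raking reports infeasible empty cells by name", {
  sch <- survey_schema(
    schema_variable("v", "categorical", levels = c("A", "B", "C")),
    schema_variable("wt", "continuous", role = "weight")
  )
  d <- tibble::tibble(v = c("A", "B"), wt = 1)
  ref <- tibble::tibble(v = c("A", "B", "C"), wt = 2)
  bm <- compute_benchmarks(ref, sch, "v", "wt", "full_margins")
  expect_error(calibrate_raking(d, sch, bm), "infeasible.*v=C")
})

test_that("non-convergence is flagged, not silently accepted", {
  sch <- demo_schema()
  d <- demo_sample(30, seed = 21)
  ref <- demo_sample(90, seed = 22)
  bm <- compute_benchmarks(ref, sch, c("gender", "agegrp"), "wt", "full_margins")
  expect_warning(
    cal <- calibrate_raking(d, sch, bm, initial_weight = "wt",
                            tol = 1e-14, max_iter = 1L),
    "did not converge")
  expect_false(cal$converged)
})

test_that("single-variable raking and quadratic calibration give identical margins", {
  sch <- survey_schema(
    schema_variable("v", "categorical", levels = c("A", "B", "C")),
    schema_variable("wt", "continuous", role = "weight")
  )
  d <- tibble::tibble(v = sample(c("A", "B", "C"), 40, replace = TRUE), wt = 1)
  ref <- tibble::tibble(v = rep(c("A", "B", "C"), times = c(5, 3, 2)), wt = 10)
  bm_full <- compute_benchmarks(ref, sch, "v", "wt", "full_margins")
  bm_ref <- compute_benchmarks(ref, sch, "v", "wt", "reference_dropped")
  cal_r <- calibrate_raking(d, sch, bm_full)
  cal_l <- suppressWarnings(calibrate_linear(d, sch, bm_ref,
                                             negative_policy = "accept"))
  fr <- weighted_frequency(add_calibrated_weights(d, cal_r, "wr"), "v",
                           weight = "wr", levels = c("A", "B", "C"))
  fl <- weighted_frequency(add_calibrated_weights(d, cal_l, "wl"), "v",
                           weight = "wl", levels = c("A", "B", "C"))
  expect_equal(fr$percent, fl$percent, tolerance = 1e-7)
})

test_that("post-calibration percentages benchmark with the reference survey", {
  sch <- demo_schema()
  d <- demo_sample(60, seed = 31)
  ref <- demo_sample(120, seed = 32)
  bm <- compute_benchmarks(ref, sch, c("gender", "agegrp"), "wt", "full_margins")
  cal <- calibrate_raking(d, sch, bm)
  d <- add_calibrated_weights(d, cal)
  for (v in c("gender", "agegrp")) {
    got <- weighted_frequency(d, v, weight = ".calibrated_weight")
    want <- weighted_frequency(ref, v, weight = "wt")
    expect_equal(got$percent, want$percent, tolerance = 1e-6)
  }
})
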