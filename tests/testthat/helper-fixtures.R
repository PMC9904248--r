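# Shared fixtures and independent oracles.

demo_schema <- function() {
  survey_schema(
    schema_variable("gender", "binary", levels = c("Male", "Female")),
    schema_variable("agegrp", "categorical", levels = c("young", "mid", "old")),
    schema_variable("smoke", "binary", levels = c("No", "Yes"), role = "outcome"),
    schema_variable("wt", "continuous", role = "weight"),
    schema_variable("str", "categorical", levels = c("s1", "s2"), role = "stratum")
  )
}

# random sample conforming to demo_schema()
demo_sample <- function(n, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      gender = sample(c("Male", "Female"), n, replace = TRUE),
      agegrp = sample(c("young", "mid", "old"), n, replace = TRUE,
                      prob = c(0.5, 0.3, 0.2)),
      smoke = sample(c("No", "Yes"), n, replace = TRUE, prob = c(0.8, 0.2)),
      wt = round(runif(n, 0.5, 5), 3),
      str = sample(c("s1", "s2"), n, replace = TRUE)
    )
  })
}

# Generic equality-constrained quadratic minimizer via the KKT block system:
# min 1/2 (u - w)' D (u - w)  s.t.  X'u = T,  with D = diag(1/w^2).
# Solves for u directly; independent of the package's Lagrange-multiplier
# normal-equations route.
qp_oracle <- function(X, w, targets) {
  n <- nrow(X); p <- ncol(X)
  D <- diag(1 / w^2, n)
  K <- rbind(cbind(D, X), cbind(t(X), matrix(0, p, p)))
  rhs <- c(D %*% w, targets)
  sol <- solve(K, rhs)
  unname(sol[seq_len(n)])
}

# Independent iterative proportional fitting on the aggregated contingency
# table of cell weight totals (classic table IPF, not per-record raking).
ipf_table_oracle <- function(cell_table, margins, tol = 1e-12, max_iter = 5000) {
  tab <- cell_table
  for (it in seq_len(max_iter)) {
    for (d in seq_along(margins)) {
      cur <- apply(tab, d, sum)
      f <- ifelse(cur > 0, margins[[d]] / cur, 1)
      tab <- sweep(tab, d, f, `*`)
    }
    gaps <- vapply(seq_along(margins), function(d) {
      max(abs(apply(tab, d, sum) - margins[[d]]))
    }, numeric(1))
    if (max(gaps) < tol) break
  }
  tab
}
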