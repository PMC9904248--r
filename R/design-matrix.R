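#' Encode categorical covariates as a calibration constraint matrix
#'
#' Builds the indicator matrix \eqn{x_i} whose weighted column sums are the
#' calibration constraints. Two encodings are supported:
#'
#' * `full_margins` — one indicator column per declared level of every
#'   variable; each row carries exactly one 1 per variable block. This is the
#'   redundant margin system raking cycles over.
#' * `reference_dropped` — a leading all-ones total column plus, per variable,
#'   one indicator column for each level except the first. This non-redundant
#'   system is what the closed-form quadratic calibration solves against.
#'
#' @param data A survey tibble.
#' @param schema A [survey_schema()]; supplies the declared level sets.
#' @param variables Character vector of categorical/binary variable names.
#' @param encoding `"full_margins"` or `"reference_dropped"`.
#' @return A numeric matrix, rows = records, with column names
#'   `"variable=level"` (and `"(total)"` under `reference_dropped`).
#' @export
encode_design_matrix <- function(data, schema, variables,
                                 encoding = c("full_margins", "reference_dropped")) {
  encoding <- match.arg(encoding)
  bad_kind <- variables[!schema$kind[match(variables, schema$variable)] %in%
                          c("categorical", "binary")]
  if (length(bad_kind)) {
    abort(sprintf("design-matrix variables must be categorical: %s",
                  paste(bad_kind, collapse = ", ")))
  }
  n <- nrow(data)
  blocks <- purrr::map(variables, function(v) {
    lv <- schema_levels(schema, v)
    x <- data[[v]]
    if (anyNA(x)) {
      abort(sprintf(
        "variable '%s' has missing values; run fcs_single_impute() before encoding", v))
    }
    use <- if (encoding == "full_margins") lv else lv[-1]
    m <- vapply(use, function(l) as.numeric(x == l), numeric(n))
    m <- matrix(m, nrow = n, dimnames = list(NULL, paste0(v, "=", use)))
    m
  })
  out <- do.call(cbind, blocks)
  if (encoding == "reference_dropped") {
    out <- cbind(`(total)` = rep(1, n), out)
  }
  attr(out, "encoding") <- encoding
  attr(out, "variables") <- variables
  out
}
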