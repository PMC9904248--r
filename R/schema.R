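#' Declare the variables of a survey data file
#'
#' A schema declares, for every column of a survey file, its measurement kind
#' (categorical, binary, continuous), its role in the integration pipeline
#' (covariate, outcome, weight, stratum, id), and — for categorical and binary
#' variables — the ordered set of admissible category labels. Continuous
#' variables may declare `cuts`, the cut points used to bin them into
#' categories before calibration (calibration operates on category margins
#' only).
#'
#' @param ... One or more variable declarations built with [schema_variable()].
#' @return A `survey_schema`: a tibble with one row per variable and columns
#'   `variable`, `kind`, `role`, `levels` (list-column), `cuts` (list-column).
#'
#' @details Exactly one variable may carry `role = "weight"` and at most one
#' `role = "stratum"`. Category labels are matched case-sensitively after
#' trimming surrounding whitespace; an empty CSV field is the single missing
#' marker.
#'
#' @examples
#' sch <- survey_schema(
#'   schema_variable("gender", "binary", levels = c("Male", "Female")),
#'   schema_variable("smoke", "binary", levels = c("No", "Yes"), role = "outcome"),
#'   schema_variable("wt", "continuous", role = "weight")
#' )
#' sch
#' @export
survey_schema <- function(...) {
  vars <- list(...)
  if (length(vars) == 1L && is.list(vars[[1]]) && !is.data.frame(vars[[1]]) &&
      is.null(vars[[1]]$variable)) {
    vars <- vars[[1]]
  }
  rows <- purrr::map(vars, function(v) {
    stopifnot(is.list(v), !is.null(v$variable))
    tibble(
      variable = v$variable,
      kind = v$kind,
      role = v$role,
      levels = list(v$levels),
      cuts = list(v$cuts)
    )
  })
  out <- dplyr::bind_rows(rows)
  validate_schema(out)
  class(out) <- c("survey_schema", class(out))
  out
}

#' @rdname survey_schema
#' @param variable Column name in the data file.
#' @param kind One of `"categorical"`, `"binary"`, `"continuous"`.
#' @param levels Ordered character vector of admissible labels; required for
#'   categorical/binary (at least 2), forbidden for continuous.
#' @param role One of `"covariate"`, `"outcome"`, `"weight"`, `"stratum"`,
#'   `"id"`.
#' @param cuts Optional numeric cut points for binning a continuous variable
#'   (used by [bin_continuous()]).
#' @export
schema_variable <- function(variable,
                            kind = c("categorical", "binary", "continuous"),
                            levels = NULL,
                            role = c("covariate", "outcome", "weight", "stratum", "id"),
                            cuts = NULL) {
  kind <- match.arg(kind)
  role <- match.arg(role)
  list(variable = variable, kind = kind, levels = levels, role = role,
       cuts = cuts)
}

validate_schema <- function(schema) {
  if (anyDuplicated(schema$variable)) {
    abort("duplicate variable names in schema")
  }
  for (i in seq_len(nrow(schema))) {
    v <- schema$variable[i]
    kind <- schema$kind[i]
    lv <- schema$levels[[i]]
    if (kind %in% c("categorical", "binary")) {
      if (length(lv) < 2L) {
        abort(sprintf("variable '%s' (%s) must declare at least 2 levels", v, kind))
      }
      if (anyDuplicated(lv)) abort(sprintf("variable '%s' has duplicate levels", v))
    } else if (length(lv)) {
      abort(sprintf("continuous variable '%s' must not declare levels", v))
    }
  }
  if (sum(schema$role == "weight") > 1L) {
    abort("at most one variable may have role = 'weight'")
  }
  if (sum(schema$role == "stratum") > 1L) {
    abort("at most one variable may have role = 'stratum'")
  }
  invisible(schema)
}

#' Read a schema declaration from a YAML or JSON file
#'
#' The file holds a list of variable entries, each with fields `variable`,
#' `kind`, `role`, optional `levels` and `cuts`, mirroring
#' [schema_variable()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [survey_schema()].
#' @export
read_schema <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  vars <- purrr::map(raw, function(v) {
    schema_variable(
      variable = v$variable,
      kind = v$kind,
      levels = if (!is.null(v$levels)) as.character(unlist(v$levels)),
      role = v$role %||% "covariate",
      cuts = if (!is.null(v$cuts)) as.numeric(unlist(v$cuts))
    )
  })
  survey_schema(vars)
}

#' Declared levels of a schema variable
#'
#' @param schema A [survey_schema()].
#' @param variable Variable name.
#' @return Character vector of declared levels (`NULL` for continuous).
#' @export
schema_levels <- function(schema, variable) {
  i <- match(variable, schema$variable)
  if (is.na(i)) abort(sprintf("variable '%s' not in schema", variable))
  schema$levels[[i]]
}

schema_vars <- function(schema, role = NULL, kind = NULL) {
  keep <- rep(TRUE, nrow(schema))
  if (!is.null(role)) keep <- keep & schema$role %in% role
  if (!is.null(kind)) keep <- keep & schema$kind %in% kind
  schema$variable[keep]
}

weight_var <- function(schema) {
  w <- schema$variable[schema$role == "weight"]
  if (length(w)) w else NULL
}

stratum_var <- function(schema) {
  s <- schema$variable[schema$role == "stratum"]
  if (length(s)) s else NULL
}
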