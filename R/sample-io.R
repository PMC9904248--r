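#' Read and validate a survey sample from CSV
#'
#' Reads an RFC-4180 CSV with a header row, validates it against a
#' [survey_schema()], and returns a typed tibble. Category labels are trimmed
#' of surrounding whitespace and matched case-sensitively against the declared
#' levels; an empty field is the missing marker and becomes `NA`. Rows
#' carrying an undeclared label are rejected with an error, never coerced.
#' Nothing is imputed at read time — item-missing imputation is an explicit
#' pipeline stage ([fcs_single_impute()]).
#'
#' @param path Path to the CSV file.
#' @param schema A [survey_schema()] describing the declared columns.
#' @param kind `"probability"` for a reference survey carrying design weights,
#'   `"nonprobability"` for a convenience sample. A non-probability sample
#'   without a declared weight column gets a unit initial-weight column
#'   `.initial_weight` (the default initial weights \eqn{w_i = 1}).
#' @return A tibble whose columns follow the schema; attribute `"schema"`
#'   stores the schema and attribute `"sample_kind"` the sample kind.
#' @export
read_sample <- function(path, schema, kind = c("probability", "nonprobability")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  as_survey_sample(raw, schema, kind = kind)
}

#' Validate an in-memory data frame against a schema
#'
#' @inheritParams read_sample
#' @param data A data frame with the declared columns (character or typed).
#' @return The validated, typed tibble (see [read_sample()]).
#' @export
as_survey_sample <- function(data, schema, kind = c("probability", "nonprobability")) {
  kind <- match.arg(kind)
  data <- as_tibble(data)
  missing_cols <- setdiff(schema$variable, names(data))
  wv <- weight_var(schema)
  if (kind == "nonprobability" && !is.null(wv)) {
    missing_cols <- setdiff(missing_cols, wv)  # w_i = 1 supplied below
  }
  if (length(missing_cols)) {
    abort(sprintf("schema columns missing from data: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  for (i in seq_len(nrow(schema))) {
    v <- schema$variable[i]
    if (!v %in% names(data)) next
    x <- data[[v]]
    if (schema$kind[i] %in% c("categorical", "binary")) {
      x <- trimws(as.character(x))
      x[!is.na(x) & x == ""] <- NA_character_
      lv <- schema$levels[[i]]
      bad <- !is.na(x) & !x %in% lv
      if (any(bad)) {
        abort(sprintf(
          "variable '%s': undeclared level(s) %s at row(s) %s",
          v, paste(unique(x[bad]), collapse = ", "),
          paste(head(which(bad), 5L), collapse = ", ")))
      }
      data[[v]] <- x
    } else {
      x <- suppressWarnings(as.numeric(x))
      data[[v]] <- x
      if (schema$role[i] == "weight") {
        bad <- !is.na(x) & x <= 0
        if (any(bad) || anyNA(x)) {
          abort(sprintf("variable '%s': weights must be > 0 (first bad row: %d)",
                        v, which(is.na(x) | x <= 0)[1]))
        }
      }
    }
  }
  if (kind == "nonprobability" && (is.null(wv) || !wv %in% names(data))) {
    data[[".initial_weight"]] <- 1
  }
  attr(data, "schema") <- schema
  attr(data, "sample_kind") <- kind
  data
}

#' Write a survey sample to CSV
#'
#' Missing values are written as empty fields, the same missing marker
#' [read_sample()] accepts, so `read_sample(write_sample(x))` round-trips.
#'
#' @param data A tibble (typically from [read_sample()] or the synthetic
#'   generator).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample <- function(data, path) {
  readr::write_csv(data, path, na = "", progress = FALSE)
  invisible(path)
}

#' Bin declared continuous variables into categories
#'
#' Calibration benchmarks are category margins, so continuous covariates must
#' be binned before calibration. Each continuous schema variable with declared
#' `cuts` is replaced by a categorical column whose levels are the interval
#' labels `"[a,b)"` (right-open, final interval closed).
#'
#' @param data A survey tibble.
#' @param schema A [survey_schema()].
#' @return The tibble with binned columns; an updated schema is stored in the
#'   `"schema"` attribute.
#' @export
bin_continuous <- function(data, schema) {
  for (i in seq_len(nrow(schema))) {
    cuts <- schema$cuts[[i]]
    if (schema$kind[i] != "continuous" || is.null(cuts)) next
    v <- schema$variable[i]
    brk <- c(-Inf, sort(cuts), Inf)
    lab <- paste0("[", head(brk, -1), ",", brk[-1], ")")
    binned <- cut(data[[v]], breaks = brk, labels = lab, right = FALSE)
    data[[v]] <- as.character(binned)
    schema$kind[i] <- "categorical"
    schema$levels[[i]] <- lab
    schema$cuts[i] <- list(NULL)
  }
  attr(data, "schema") <- schema
  data
}
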