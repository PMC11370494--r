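#' Read a cohort table from CSV or TSV
#'
#' Loads a delimited table (delimiter inferred from the extension: `.tsv` /
#' `.txt` are tab-separated, anything else comma-separated) and validates the
#' columns estimators will use: the outcome must exist and be numeric, the
#' optional membership column must be boolean-coercible (logical or 0/1),
#' and no validated column may contain missing values.
#'
#' @param path Path to the delimited file (header row required).
#' @param outcome Name of the observed outcome column. Default `"cog_obs"`.
#' @param membership Optional name of the expectation-membership column.
#' @param features Optional character vector of feature columns to validate
#'   as numeric and complete; defaults to every numeric column.
#' @return A tibble; the membership column, if named, is coerced to logical.
#' @export
read_cohort <- function(path, outcome = "cog_obs", membership = NULL,
                        features = NULL) {
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  data <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)

  required <- c(outcome, membership)
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing columns in %s: %s",
                  basename(path), paste(missing_cols, collapse = ", ")))
  }
  if (!is.numeric(data[[outcome]])) {
    abort(sprintf("Outcome column '%s' is not numeric.", outcome))
  }
  if (!is.null(membership)) {
    m <- data[[membership]]
    if (is.numeric(m) && all(m %in% c(0, 1, NA))) m <- m == 1
    if (is.character(m)) {
      coerced <- as.logical(m)
      if (any(is.na(coerced) & !is.na(m))) {
        abort(sprintf("Membership column '%s' is not boolean-coercible.",
                      membership))
      }
      m <- coerced
    }
    if (!is.logical(m)) {
      abort(sprintf("Membership column '%s' is not boolean-coercible.",
                    membership))
    }
    data[[membership]] <- m
  }

  if (is.null(features)) {
    features <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                        c(outcome, membership))
  } else {
    missing_feat <- setdiff(features, names(data))
    if (length(missing_feat) > 0) {
      abort(sprintf("Missing feature columns: %s",
                    paste(missing_feat, collapse = ", ")))
    }
    non_num <- features[!vapply(data[features], is.numeric, logical(1))]
    if (length(non_num) > 0) {
      abort(sprintf("Non-numeric feature columns: %s",
                    paste(non_num, collapse = ", ")))
    }
  }
  checked <- c(features, required)
  has_na <- checked[vapply(data[checked], anyNA, logical(1))]
  if (length(has_na) > 0) {
    abort(sprintf("Missing values in columns: %s",
                  paste(has_na, collapse = ", ")))
  }
  data
}

#' Write a simulated dataset as CSV with a JSON provenance sidecar
#'
#' Writes the table to `path` and, when the dataset carries its generating
#' config, a `<path>.json` sidecar recording the configuration, per-variable
#' roles, seed and package version — enough provenance to regenerate the
#' file exactly with [simulate_dataset()].
#'
#' @param data A `cr_dataset` (or any data frame).
#' @param path Output CSV path.
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path)
  written <- path
  cfg <- attr(data, "config")
  if (!is.null(cfg)) {
    sidecar <- paste0(path, ".json")
    jsonlite::write_json(
      list(
        config = unclass(cfg),
        roles = as.list(attr(data, "roles")),
        seed = cfg$seed,
        package_version = as.character(packageVersion("crlearn"))
      ),
      sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    written <- c(written, sidecar)
  }
  invisible(written)
}

#' Write per-sample estimates and a JSON fit report
#'
#' Writes `<prefix>.csv` holding the per-sample estimates and
#' `<prefix>.json` holding metrics and provenance (seed, configuration,
#' package version), so every output can be regenerated from its report.
#'
#' @param estimates Data frame of per-sample estimates.
#' @param path_prefix Output path without extension.
#' @param metrics Optional named list or one-row data frame of scenario
#'   metrics.
#' @param config Optional [sim_config()] or arbitrary provenance list.
#' @param seed Optional seed to record.
#' @return Invisibly, the two paths written.
#' @export
write_report <- function(estimates, path_prefix, metrics = NULL,
                         config = NULL, seed = NULL) {
  csv_path <- paste0(path_prefix, ".csv")
  json_path <- paste0(path_prefix, ".json")
  readr::write_csv(tibble::as_tibble(estimates), csv_path)
  report <- list(
    package_version = as.character(packageVersion("crlearn")),
    seed = seed,
    config = if (!is.null(config)) unclass(config),
    metrics = if (!is.null(metrics)) as.list(tibble::as_tibble(metrics))
  )
  jsonlite::write_json(report[!vapply(report, is.null, logical(1))],
                       json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv_path, json_path))
}
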