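# CSV/JSON interchange: long-format observation series, prior/config
# round-tripping, and seed-stamped result metadata.

series_columns <- c("patient_id", "subgroup", "set", "period", "order",
                    "arm", "day", "outcome")

#' Write an N-of-1 series to CSV
#'
#' Fixed column set (patient_id, subgroup, set, period, order, arm, day,
#' outcome). When the series carries generator metadata (params, seed) a
#' JSON sidecar \code{<path>.json} is written alongside.
#'
#' @param series an \code{nof1_series}.
#' @param path output CSV path.
#' @param sidecar write the JSON sidecar when metadata is present.
#' @return \code{path}, invisibly.
#' @export
write_series <- function(series, path, sidecar = TRUE) {
  series <- validate_series(series)
  utils::write.csv(series[, series_columns], path, row.names = FALSE)
  seed <- attr(series, "seed")
  if (sidecar && !is.null(seed)) {
    jsonlite::write_json(list(seed = seed),
                         paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Load and validate an N-of-1 series from CSV
#'
#' Schema errors name the offending column; coercion failures and duplicate
#' (patient, set, period, day, arm) keys are reported with row numbers.
#'
#' @param path CSV path with the fixed column set.
#' @return a validated \code{nof1_series}.
#' @export
load_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(series_columns, names(df))
  if (length(miss))
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out_num <- suppressWarnings(as.numeric(df$outcome))
  bad <- which(is.na(out_num) & !is.na(df$outcome))
  if (length(bad) || anyNA(df$outcome))
    stop("non-numeric or missing outcome at row(s): ",
         paste(utils::head(unique(c(bad, which(is.na(df$outcome)))), 10L),
               collapse = ", "), call. = FALSE)
  df$outcome <- out_num
  key <- do.call(paste, c(df[c("patient_id", "set", "period", "day", "arm")],
                          sep = "\r"))
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate record(s) at row(s): ",
         paste(utils::head(dup, 10L), collapse = ", "), call. = FALSE)
  new_nof1_series(validate_series(df))
}

#' Serialize a run configuration to JSON
#'
#' @param config named list (design, model, rule, assurance, CEA sections,
#'   master seed, output directory); prior specs are serialized by kind.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  ser <- serialize_priors(config)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

serialize_priors <- function(x) {
  if (is_prior_spec(x)) return(prior_to_list(x))
  if (is.list(x)) return(lapply(x, serialize_priors))
  x
}

#' Read a run configuration from JSON
#'
#' Recognized prior sub-lists (those with a \code{kind} field) are restored
#' to \code{prior_spec} objects; the round trip through
#' \code{\link{write_config}} is lossless.
#'
#' @param path JSON path.
#' @return named list.
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  restore_priors(x)
}

restore_priors <- function(x) {
  if (is.list(x)) {
    if (!is.null(x$kind) &&
        x$kind %in% c("normal", "flat", "point", "histogram"))
      return(prior_from_list(x))
    return(lapply(x, restore_priors))
  }
  x
}
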