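# File round-tripping: the dataset CSV dialect, model files (YAML) and
# centile-table export.

CSV_HEADER <- c("age_years", "tt_value", "unit", "study_id", "assay", "is_anchor")

#' Write a testosterone dataset as CSV
#'
#' Uses the pipeline's CSV dialect with header
#' `age_years,tt_value,unit,study_id,assay,is_anchor`.
#'
#' @param data Data frame with columns `age`, `tt`, `unit`, `study`,
#'   `assay`, `is_anchor`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tt_csv <- function(data, path) {
  data <- check_tt_frame(data)
  out <- data.frame(
    age_years = data$age, tt_value = data$tt, unit = data$unit,
    study_id = data$study, assay = data$assay, is_anchor = data$is_anchor
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a testosterone dataset CSV
#'
#' @param path CSV path in the dialect of [write_tt_csv()].
#' @return Data frame with canonical columns `age`, `tt`, `unit`, `study`,
#'   `assay`, `is_anchor`.
#' @export
read_tt_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(CSV_HEADER, names(raw))
  if (length(miss)) stop(sprintf("CSV is missing column(s): %s", paste(miss, collapse = ", ")))
  data.frame(
    age = raw$age_years, tt = raw$tt_value, unit = raw$unit,
    study = raw$study_id, assay = raw$assay,
    is_anchor = as.logical(raw$is_anchor), stringsAsFactors = FALSE
  )
}

#' Serialise a normative model to a plain-text file
#'
#' Writes a YAML file with fields `form: rational`, `log_base: 10`,
#' `offset: 1`, the coefficient vectors, and optionally the SD profile
#' sampled at integer ages so the full normative distribution round-trips.
#'
#' @param model A [rational_poly()] object.
#' @param path Output path.
#' @param sd_profile Optional `sd_profile`, stored sampled at `sd_ages`.
#' @param sd_ages Ages at which to sample the SD profile.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, sd_profile = NULL, sd_ages = 3:88) {
  stopifnot(inherits(model, "rational_poly"))
  obj <- list(form = "rational", log_base = 10, offset = 1,
              num_coeffs = model$num, den_coeffs = model$den)
  if (!is.null(sd_profile)) {
    obj$sd <- list(ages = sd_ages, sigma = eval_sd(sd_profile, sd_ages))
  }
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a serialised normative model
#'
#' @param path YAML path written by [write_model()].
#' @return List with `model` ([rational_poly()]) and `sd_profile` (an
#'   `sd_profile` or `NULL`).
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path))
  obj <- yaml::read_yaml(path)
  if (!identical(obj$form, "rational")) stop("unsupported model form")
  if (!identical(as.numeric(obj$log_base), 10) ||
      !identical(as.numeric(obj$offset), 1)) {
    stop("model file uses an unsupported transform")
  }
  model <- rational_poly(as.numeric(obj$num_coeffs), as.numeric(obj$den_coeffs))
  sdp <- if (!is.null(obj$sd)) {
    sd_profile_interp(as.numeric(obj$sd$ages), as.numeric(obj$sd$sigma))
  }
  list(model = model, sd_profile = sdp)
}

#' Export a centile table as CSV
#'
#' Header `age` followed by the percentile labels; values rounded to one
#' decimal, matching the layout of the printed clinical reference table.
#'
#' @param table A [normative_table()] result.
#' @param path Output path.
#' @param digits Rounding for export.
#' @return `path`, invisibly.
#' @export
write_centile_table <- function(table, path, digits = 1) {
  out <- as.data.frame(table)
  out[-1] <- lapply(out[-1], round, digits = digits)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an exported centile table
#'
#' @param path CSV written by [write_centile_table()].
#' @return A `centile_table` data frame.
#' @export
read_centile_table <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE)
  class(out) <- c("centile_table", "data.frame")
  out
}
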