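# Pooling rules: unit standardisation, assay conversion, age censoring and
# conception anchors, producing the modelling dataset.

empty_tt_frame <- function() {
  data.frame(age = numeric(0), tt = numeric(0), unit = character(0),
             study = character(0), assay = character(0),
             is_anchor = logical(0), stringsAsFactors = FALSE)
}

check_tt_frame <- function(data) {
  needed <- c("age", "tt")
  miss <- setdiff(needed, names(data))
  if (length(miss)) {
    stop(sprintf("dataset is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (is.null(data$is_anchor)) data$is_anchor <- rep(FALSE, nrow(data))
  if (is.null(data$unit)) data$unit <- rep("nmol/L", nrow(data))
  if (is.null(data$assay)) data$assay <- rep("LC-MS/MS", nrow(data))
  if (is.null(data$study)) data$study <- rep("pooled", nrow(data))
  data
}

#' Censor a dataset below a minimum age
#'
#' Retains points with `age >= min_age` (boundary inclusive, so the youngest
#' tabulated reference age remains in-domain). Conception anchors are exempt.
#'
#' @param data Data frame with at least `age`; optional `is_anchor`.
#' @param min_age Minimum age in years retained (default 3: digitized values
#'   below this age could not be matched to their published descriptive
#'   statistics and are dropped).
#' @return The censored data frame.
#' @export
censor_by_age <- function(data, min_age = 3) {
  if (min_age < 0) stop("min_age must be non-negative")
  data <- check_tt_frame(data)
  data[data$age >= min_age | data$is_anchor, , drop = FALSE]
}

#' Append conception zero anchors
#'
#' TT at conception is the only level known exactly at any age (zero).
#' Artificial zero points are appended to force fitted curves through it;
#' they carry `is_anchor = TRUE` and are excluded from every error and fit
#' statistic downstream.
#'
#' @param data Data frame of measurements.
#' @param count Number of anchors to add (non-negative integer).
#' @param anchor_age Age assigned to the anchors, default 0 years (the
#'   origin of the postnatal age scale).
#' @return Data frame with `count` anchor rows appended.
#' @export
add_anchors <- function(data, count, anchor_age = 0) {
  if (count < 0) stop("anchor count must be non-negative")
  data <- check_tt_frame(data)
  count <- as.integer(count)
  if (count == 0) return(data)
  anchors <- data.frame(
    age = rep(anchor_age, count), tt = 0, unit = "nmol/L",
    study = "anchor", assay = "LC-MS/MS", is_anchor = TRUE,
    stringsAsFactors = FALSE
  )
  rbind(data[, names(anchors)], anchors)
}

#' Harmonize a pooled multi-assay dataset
#'
#' Runs the pooling rules in order: (1) standardise units to nmol/L;
#' (2) convert each study assay to the LC-MS/MS scale and rewrite the assay
#' tag to `"LC-MS/MS"` so conversion cannot be applied twice; (3) censor
#' below `censor_min_age`; (4) append conception zero anchors.
#'
#' @param data Data frame with columns `age`, `tt`, and optionally `unit`,
#'   `study`, `assay`, `is_anchor`.
#' @param registry Assay conversion registry.
#' @param censor_min_age Minimum age retained, years.
#' @param anchor_frac Anchors added as a fraction of the censored dataset
#'   size (default 1%); ignored when `anchor_count` is given.
#' @param anchor_count Explicit anchor count, or `NULL`.
#' @param anchor_age Age of the anchors, years.
#' @return Harmonized data frame (all `tt` in nmol/L on the LC-MS/MS scale).
#' @export
#' @examples
#' d <- simulate_cohort(seed = 1)
#' h <- harmonize(d)
#' table(h$is_anchor)
harmonize <- function(data, registry = assay_registry(), censor_min_age = 3,
                      anchor_frac = 0.01, anchor_count = NULL, anchor_age = 0) {
  data <- check_tt_frame(data)
  if (nrow(data) == 0) stop("harmonize() received an empty dataset")
  tt <- ifelse(data$unit == "ng/dL", data$tt * NGDL_TO_NMOLL, data$tt)
  if (any(!is.finite(tt) | tt < 0)) stop("negative or non-finite TT after unit standardisation")
  for (assay in unique(data$assay)) {
    sel <- data$assay == assay & !data$is_anchor
    if (any(sel)) tt[sel] <- convert_to_reference(tt[sel], assay, registry)
  }
  data$tt <- tt
  data$unit <- "nmol/L"
  data$assay <- "LC-MS/MS"
  data <- censor_by_age(data, censor_min_age)
  if (is.null(anchor_count)) anchor_count <- ceiling(anchor_frac * nrow(data))
  add_anchors(data, anchor_count, anchor_age)
}

#' Inter-observer agreement between two chart extractions
#'
#' When two observers digitize the same scatterplot, each extracted pair is
#' compared on age and on TT. A pair agrees on a coordinate when the
#' relative difference `|a - b| / max(|a|, |b|)` is at most `rel_tol`
#' (identical zeros agree). Extraction passes when the agreeing fraction
#' reaches `threshold` (default 99%) for both coordinates.
#'
#' @param extract_a,extract_b Data frames with columns `age` and `tt`, same
#'   length and point order.
#' @param rel_tol Per-point relative tolerance.
#' @param threshold Minimum agreeing fraction for a pass.
#' @return List with `age_agreement`, `tt_agreement`, `pass`, and the
#'   Bland-Altman style mean differences `age_mean_diff`, `tt_mean_diff`.
#' @export
interobserver_agreement <- function(extract_a, extract_b, rel_tol = 0.01,
                                    threshold = 0.99) {
  if (nrow(extract_a) != nrow(extract_b)) {
    stop("extractions have different lengths; points must be matched")
  }
  agree <- function(a, b) {
    denom <- pmax(abs(a), abs(b))
    ifelse(denom == 0, TRUE, abs(a - b) / denom <= rel_tol)
  }
  fa <- mean(agree(extract_a$age, extract_b$age))
  ft <- mean(agree(extract_a$tt, extract_b$tt))
  list(
    age_agreement = fa,
    tt_agreement = ft,
    pass = fa >= threshold && ft >= threshold,
    age_mean_diff = mean(extract_a$age - extract_b$age),
    tt_mean_diff = mean(extract_a$tt - extract_b$tt)
  )
}
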