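# Assay harmonization: every source study's testosterone scale is mapped to
# the LC-MS/MS (gold standard) scale before pooling. Linear conversions are
# published as y = slope * x + intercept with x the study assay and y the
# LC-MS/MS value; the radioimmunoassay conversion is published in inverse
# power-law form x = k * y^p, so its forward map is y = (x / k)^(1 / p).

NGDL_TO_NMOLL <- 0.0347

#' Registry of published assay-to-LC-MS/MS conversions
#'
#' Conversion formulae for the platform immunoassays appearing in the pooled
#' dataset (DPC, DSL, Centaur, Roche, RIA), plus the identity for LC-MS/MS
#' itself. All formulae operate on concentrations in nmol/L (units are
#' standardised first). `r` is the published correlation of each conversion.
#'
#' @return Named list of conversion descriptors with fields `name`, `form`
#'   (`"linear"`, `"power"` or `"identity"`), parameters, and `r`.
#' @export
#' @examples
#' names(assay_registry())
assay_registry <- function() {
  list(
    "DPC" = list(name = "DPC", form = "linear", slope = 1.098,
                 intercept = -0.1, r = "0.92-0.97"),
    "DSL" = list(name = "DSL", form = "linear", slope = 1.791,
                 intercept = -0.178, r = "0.85"),
    "Centaur" = list(name = "Centaur", form = "linear", slope = 1.195,
                     intercept = -0.05, r = "0.92-0.97"),
    "Roche" = list(name = "Roche", form = "linear", slope = 1.167,
                   intercept = -2.62, r = "0.92-0.97"),
    "RIA" = list(name = "RIA", form = "power", k = 0.706, p = 1.077,
                 r = "0.96"),
    "LC-MS/MS" = list(name = "LC-MS/MS", form = "identity", r = NA_character_)
  )
}

get_conversion <- function(assay, registry = assay_registry()) {
  conv <- registry[[assay]]
  if (is.null(conv)) stop(sprintf("unknown assay '%s': not in the conversion registry", assay))
  conv
}

#' Standardise testosterone units to nmol/L
#'
#' Applies the standard multiplication factor 1 ng/dL = 0.0347 nmol/L.
#' Values already in nmol/L pass through unchanged.
#'
#' @param value Non-negative concentrations.
#' @param from Unit of `value`: `"ng/dL"` or `"nmol/L"`.
#' @return Concentrations in nmol/L.
#' @export
#' @examples
#' standardise_units(100)   # 3.47
standardise_units <- function(value, from = c("ng/dL", "nmol/L")) {
  from <- match.arg(from)
  if (any(!is.finite(value) | value < 0)) {
    stop("standardise_units() requires finite non-negative values")
  }
  if (from == "ng/dL") value * NGDL_TO_NMOLL else value
}

#' Convert a study-assay measurement to the LC-MS/MS scale
#'
#' @param value Non-negative TT in nmol/L on the study assay's scale.
#' @param assay Assay name registered in `registry`.
#' @param registry Conversion registry, see [assay_registry()].
#' @param clip Clip converted values below at 0 (linear conversions have
#'   negative intercepts, so values near zero can map slightly negative).
#' @return TT in nmol/L on the LC-MS/MS scale.
#' @export
#' @examples
#' convert_to_reference(10, "Centaur")   # 1.195 * 10 - 0.05 = 11.9
convert_to_reference <- function(value, assay, registry = assay_registry(),
                                 clip = TRUE) {
  if (any(!is.finite(value) | value < 0)) {
    stop("convert_to_reference() requires finite non-negative values")
  }
  conv <- get_conversion(assay, registry)
  out <- switch(conv$form,
    identity = value,
    linear = conv$slope * value + conv$intercept,
    power = (value / conv$k)^(1 / conv$p),
    stop(sprintf("unsupported conversion form '%s'", conv$form))
  )
  if (clip) pmax(out, 0) else out
}

#' Map an LC-MS/MS-scale value back to a study assay's native scale
#'
#' The inverse of [convert_to_reference()]; used by the cohort simulator so
#' that generated raw data live on each study's native scale, as digitized
#' source data would.
#'
#' @inheritParams convert_to_reference
#' @param value TT in nmol/L on the LC-MS/MS scale.
#' @return TT in nmol/L on the study assay's scale.
#' @export
convert_from_reference <- function(value, assay, registry = assay_registry()) {
  conv <- get_conversion(assay, registry)
  switch(conv$form,
    identity = value,
    linear = (value - conv$intercept) / conv$slope,
    power = conv$k * value^conv$p,
    stop(sprintf("unsupported conversion form '%s'", conv$form))
  )
}
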