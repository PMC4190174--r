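# Age-dependent spread of log-adjusted residuals, centile curves, normative
# tables and individual scoring. The working model is Gaussian residuals on
# the log-adjusted scale with an age-dependent standard deviation sigma(age).

new_sd_profile <- function(method, fun, ...) {
  structure(c(list(method = method, fun = fun), list(...)),
            class = "sd_profile")
}

#' Evaluate an age-dependent SD profile
#'
#' @param profile An `sd_profile` object.
#' @param age Numeric ages in years.
#' @return `sigma(age)`, the SD of log-adjusted residuals at each age.
#' @export
eval_sd <- function(profile, age) {
  stopifnot(inherits(profile, "sd_profile"))
  out <- profile$fun(age)
  pmax(out, 0)
}

#' @export
print.sd_profile <- function(x, ...) {
  cat(sprintf("Age-dependent SD profile (log-adjusted scale), method '%s'\n", x$method))
  a <- c(10, 19, 40, 65, 88)
  cat("  sigma at ages", paste(a, collapse = "/"), ":",
      paste(format(round(eval_sd(x, a), 4)), collapse = " "), "\n")
  invisible(x)
}

#' Constant SD profile
#'
#' @param sigma Non-negative SD on the log-adjusted scale.
#' @return An `sd_profile`.
#' @export
sd_profile_constant <- function(sigma) {
  if (sigma < 0) stop("sigma must be non-negative")
  force(sigma)
  new_sd_profile("constant", function(age) rep(sigma, length(age)), sigma = sigma)
}

#' Piecewise-linear SD profile through anchor points
#'
#' Linear interpolation between `(ages, sigmas)` pairs, held constant beyond
#' the first/last anchor.
#'
#' @param ages Anchor ages in years, strictly increasing.
#' @param sigmas Non-negative SDs at the anchors.
#' @return An `sd_profile`.
#' @export
sd_profile_interp <- function(ages, sigmas) {
  if (length(ages) != length(sigmas) || length(ages) < 1) {
    stop("ages and sigmas must be equal-length, non-empty")
  }
  if (any(sigmas < 0)) stop("sigmas must be non-negative")
  if (is.unsorted(ages, strictly = TRUE)) stop("ages must be strictly increasing")
  force(ages); force(sigmas)
  fun <- if (length(ages) == 1) {
    function(a) rep(sigmas, length(a))
  } else {
    function(a) stats::approx(ages, sigmas, xout = a, rule = 2)$y
  }
  new_sd_profile("interp", fun, anchor_ages = ages, anchor_sigmas = sigmas)
}

#' Default spread profile for the reference testosterone model
#'
#' Sigma of log-adjusted TT anchored at 0.151 (age 19), 0.137 (age 40) and
#' 0.173 (age 88), linearly interpolated and held constant outside. The
#' anchor values are recovered by inverting the published 2.5th/97.5th
#' normative bounds at those ages under the Gaussian-in-log model; the rise
#' after age 40 encodes the key finding that TT variance grows with age
#' while the mean does not fall.
#'
#' @return An `sd_profile`.
#' @export
tt_reference_sd <- function() {
  sd_profile_interp(c(19, 40, 88), c(0.151, 0.137, 0.173))
}

#' Estimate an age-dependent SD profile from residuals
#'
#' `"kernel"` computes, at each query age, the SD of residuals weighted by a
#' Gaussian kernel in age (weighted mean removed). `"binned"` computes the
#' SD within age bins and interpolates bin centres. `"constant"` returns the
#' global SD everywhere.
#'
#' @param residuals Log-adjusted residuals (anchors excluded), length >= 30.
#' @param ages Ages matching `residuals`.
#' @param method `"kernel"`, `"binned"` or `"constant"`.
#' @param bandwidth Kernel SD in years (kernel method), > 0.
#' @param breaks Bin edges in years (binned method); default decade bins
#'   spanning the data.
#' @return An `sd_profile`; the residuals are retained on the object so
#'   empirical-quantile centiles can be formed later.
#' @export
estimate_sd_profile <- function(residuals, ages,
                                method = c("kernel", "binned", "constant"),
                                bandwidth = 5, breaks = NULL) {
  method <- match.arg(method)
  if (length(residuals) != length(ages)) stop("residuals and ages must have equal length")
  if (length(residuals) < 30) stop("at least 30 residuals are required to estimate a spread profile")
  if (method == "kernel" && bandwidth <= 0) stop("bandwidth must be positive")
  res <- as.numeric(residuals); aa <- as.numeric(ages)
  prof <- switch(method,
    constant = sd_profile_constant(stats::sd(res)),
    kernel = {
      fun <- function(query) {
        vapply(query, function(a) {
          w <- stats::dnorm(aa, mean = a, sd = bandwidth)
          if (sum(w) <= 0) return(stats::sd(res))
          w <- w / sum(w)
          mu <- sum(w * res)
          sqrt(sum(w * (res - mu)^2))
        }, numeric(1))
      }
      new_sd_profile("kernel", fun, bandwidth = bandwidth)
    },
    binned = {
      if (is.null(breaks)) {
        breaks <- seq(10 * floor(min(aa) / 10), 10 * ceiling(max(aa) / 10), by = 10)
      }
      idx <- cut(aa, breaks, include.lowest = TRUE)
      sds <- tapply(res, idx, stats::sd)
      mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
      keep <- !is.na(sds)
      if (sum(keep) < 1) stop("no populated age bins")
      sd_profile_interp(mids[keep], as.numeric(sds[keep]))
    }
  )
  prof$residuals <- res
  prof$res_ages <- aa
  prof
}

#' Centile curve of the normative distribution
#'
#' In Gaussian mode the `p`-th centile at age `a` is
#' `10^(mean(a) + z_p * sigma(a)) - 1` with `z_p` the standard normal
#' quantile. In empirical mode `z_p` is replaced by the `p`-th quantile of
#' the standardised residuals stored on the SD profile, which lets the tails
#' deviate from Gaussian shape. Values are clipped below at 0.
#'
#' @param mean_model A [rational_poly()] mean curve.
#' @param sd_profile An `sd_profile`.
#' @param percentile Percentile in (0, 100).
#' @param ages Ages in years.
#' @param mode `"gaussian"` or `"empirical"` (the latter requires a profile
#'   estimated from residuals).
#' @return TT values in nmol/L.
#' @export
#' @examples
#' centile_curve(tt_reference_model(), tt_reference_sd(), 97.5, c(19, 40))
centile_curve <- function(mean_model, sd_profile, percentile, ages,
                          mode = c("gaussian", "empirical")) {
  mode <- match.arg(mode)
  if (any(percentile <= 0 | percentile >= 100)) stop("percentile must be in (0, 100)")
  mu <- rp_eval(mean_model, ages)
  sig <- eval_sd(sd_profile, ages)
  z <- if (mode == "gaussian") {
    stats::qnorm(percentile / 100)
  } else {
    if (is.null(sd_profile$residuals)) {
      stop("empirical mode needs a profile estimated from residuals")
    }
    std <- sd_profile$residuals / eval_sd(sd_profile, sd_profile$res_ages)
    as.numeric(stats::quantile(std, percentile / 100, type = 7))
  }
  pmax(inv_log_adjust(mu + z * sig), 0)
}

TT_TABLE_PERCENTILES <- c(1, 2.5, 10, 20, 30, 40, 50, 60, 70, 80, 90, 97.5, 99)

#' Normative reference table
#'
#' Ages-by-percentiles grid of TT in nmol/L, in the layout of a clinical
#' reference table: one row per integer age 3--88, columns at percentiles
#' 1, 2.5, 10, 20, ..., 90, 97.5, 99. Values are kept at full precision
#' internally; [write_centile_table()] rounds to one decimal on export.
#'
#' @inheritParams centile_curve
#' @param ages Integer ages, default 3:88.
#' @param percentiles Percentile columns.
#' @return A data frame of class `centile_table` with first column `age`.
#' @export
normative_table <- function(mean_model, sd_profile, ages = 3:88,
                            percentiles = TT_TABLE_PERCENTILES,
                            mode = c("gaussian", "empirical")) {
  mode <- match.arg(mode)
  vals <- vapply(percentiles, function(p) {
    centile_curve(mean_model, sd_profile, p, ages, mode = mode)
  }, numeric(length(ages)))
  vals <- matrix(vals, nrow = length(ages))
  colnames(vals) <- as.character(percentiles)
  out <- data.frame(age = ages, vals, check.names = FALSE)
  class(out) <- c("centile_table", "data.frame")
  out
}

#' @export
print.centile_table <- function(x, digits = 1, ...) {
  y <- as.data.frame(x)
  y[-1] <- lapply(y[-1], round, digits = digits)
  cat(sprintf("Normative TT reference table (nmol/L), %d ages x %d percentiles\n",
              nrow(y), ncol(y) - 1L))
  print.data.frame(utils::head(y, 8), row.names = FALSE)
  if (nrow(y) > 8) cat("  ...", nrow(y) - 8, "more rows\n")
  invisible(x)
}

#' Score an individual measurement against the normative model
#'
#' @param tt Measured TT in nmol/L (LC-MS/MS scale), >= 0.
#' @param age Age in years.
#' @param mean_model A [rational_poly()] mean curve.
#' @param sd_profile An `sd_profile`.
#' @return List with `z` (standard score of the log-adjusted value) and
#'   `centile` (standard normal CDF of `z`, times 100).
#' @export
#' @examples
#' score_individual(6.6, 40, tt_reference_model(), tt_reference_sd())
score_individual <- function(tt, age, mean_model, sd_profile) {
  if (any(tt < 0)) stop("tt must be non-negative")
  sig <- eval_sd(sd_profile, age)
  if (any(sig == 0)) stop("degenerate SD profile: sigma(age) = 0")
  z <- (log_adjust(tt) - rp_eval(mean_model, age)) / sig
  list(z = z, centile = 100 * stats::pnorm(z))
}
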