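#' Fit an age-related normative model for total testosterone
#'
#' The main model-fitting entry point. Fits a rational-polynomial mean curve
#' to `log10(tt + 1)` by Levenberg-Marquardt least squares and estimates an
#' age-dependent residual SD profile, together giving a complete normative
#' distribution (mean plus spread) at every age. The response must be TT in
#' nmol/L on a single harmonized scale (see [harmonize()]); rows flagged
#' `is_anchor` in `data` are conception anchors, included in the fitting
#' loss but excluded from all fit statistics and from the SD profile.
#'
#' @param formula Two-sided formula `tt ~ age` naming the response (TT,
#'   nmol/L) and the age covariate (years).
#' @param data Data frame holding the variables, optionally with a logical
#'   `is_anchor` column.
#' @param n_params Number of free parameters of the rational polynomial;
#'   degrees are allocated as numerator `ceiling((n-1)/2)`, denominator
#'   `floor((n-1)/2)`, so the default 7 is cubic over cubic.
#' @param sd_method Spread estimation method, see [estimate_sd_profile()];
#'   falls back to `"constant"` when fewer than 30 residuals are available.
#' @param bandwidth Kernel bandwidth in years for the SD profile.
#' @param control A [rational_fit_control()].
#' @return Object of class `ttnorm` with components `model`
#'   ([rational_poly()]), `fit` (`rational_fit`), `sd_profile`, `data`,
#'   `n_params` and `call`. Supported methods: `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot`, `simulate`.
#' @export
#' @examples
#' d <- harmonize(simulate_cohort(seed = 3))
#' m <- ttnorm(tt ~ age, d)
#' m
#' predict(m, newdata = data.frame(age = c(19, 40)))
ttnorm <- function(formula, data, n_params = 7,
                   sd_method = c("kernel", "binned", "constant"),
                   bandwidth = 5, control = rational_fit_control()) {
  sd_method <- match.arg(sd_method)
  cl <- match.call()
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  if (ncol(mf) != 2) stop("formula must be of the form tt ~ age")
  tt <- stats::model.response(mf)
  age <- mf[[2]]
  is_anchor <- if (!is.null(data$is_anchor)) as.logical(data$is_anchor)
               else rep(FALSE, length(age))

  deg <- degrees_for_params(n_params)
  fit <- fit_rational(age, tt, is_anchor, deg["num"], deg["den"], control)

  res <- log_adjust(tt[!is_anchor]) - rp_eval(fit$model, age[!is_anchor])
  sdp <- if (length(res) >= 30) {
    estimate_sd_profile(res, age[!is_anchor], method = sd_method,
                        bandwidth = bandwidth)
  } else {
    sd_profile_constant(stats::sd(res))
  }

  structure(list(
    model = fit$model, fit = fit, sd_profile = sdp,
    data = data.frame(age = age, tt = tt, is_anchor = is_anchor),
    n_params = n_params, call = cl
  ), class = "ttnorm")
}

#' @export
print.ttnorm <- function(x, ...) {
  cat("Age-related normative model of total testosterone\n")
  cat("Call: "); print(x$call)
  cat(sprintf(
    "  %d-parameter rational polynomial on log10(TT+1); n = %d (+%d anchors)\n",
    x$model$n_params, x$fit$n, x$fit$n_anchor
  ))
  cat(sprintf("  r2 = %.3f, mse = %.4g (log scale, anchors excluded)\n",
              x$fit$r2, x$fit$mse))
  pk <- peak_age(x$model)
  cat(sprintf("  peak mean TT %.1f nmol/L at age %d\n",
              predict_tt(x$model, pk), pk))
  invisible(x)
}

#' @export
coef.ttnorm <- function(object, ...) {
  m <- object$model
  stats::setNames(
    c(m$num, m$den),
    c(paste0("num", seq_along(m$num) - 1L),
      if (length(m$den)) paste0("den", seq_along(m$den)))
  )
}

#' @export
summary.ttnorm <- function(object, ...) {
  pk <- peak_age(object$model)
  out <- list(
    call = object$call, coefficients = coef(object),
    r2 = object$fit$r2, mse = object$fit$mse,
    converged = object$fit$converged, n_iter = object$fit$n_iter,
    n = object$fit$n, n_anchor = object$fit$n_anchor,
    peak_age = pk, peak_tt = predict_tt(object$model, pk),
    tt40 = predict_tt(object$model, 40), tt88 = predict_tt(object$model, 88),
    sd_method = object$sd_profile$method
  )
  class(out) <- "summary.ttnorm"
  out
}

#' @export
print.summary.ttnorm <- function(x, ...) {
  cat("Age-related normative model of total testosterone\nCall: ")
  print(x$call)
  cat("\nCoefficients (log10(TT+1) = N(age)/D(age), D constant = 1):\n")
  print(round(x$coefficients, 6))
  cat(sprintf("\nn = %d non-anchor points (+%d anchors in the loss)\n", x$n, x$n_anchor))
  cat(sprintf("r2 = %.4f, mse = %.4g; %sconverged in %d iterations\n",
              x$r2, x$mse, if (x$converged) "" else "NOT ", x$n_iter))
  cat(sprintf("Mean TT: peak %.1f nmol/L at age %d; %.1f at 40; %.1f at 88\n",
              x$peak_tt, x$peak_age, x$tt40, x$tt88))
  cat(sprintf("Spread estimated by the '%s' method\n", x$sd_method))
  invisible(x)
}

#' Predict from a fitted normative model
#'
#' @param object A `ttnorm` fit.
#' @param newdata Data frame with an `age` column, or `NULL` to use the
#'   fitting data's ages.
#' @param type `"response"` (mean TT, nmol/L), `"log"` (log-adjusted mean)
#'   or `"centile"` (the `percentile`-th normative centile, nmol/L).
#' @param percentile Percentile in (0, 100), used when `type = "centile"`.
#' @param ... Unused.
#' @export
predict.ttnorm <- function(object, newdata = NULL,
                           type = c("response", "log", "centile"),
                           percentile = 50, ...) {
  type <- match.arg(type)
  age <- if (is.null(newdata)) object$data$age
         else if (is.data.frame(newdata)) newdata$age else as.numeric(newdata)
  if (is.null(age)) stop("newdata must contain an 'age' column")
  switch(type,
    response = predict_tt(object$model, age),
    log = rp_eval(object$model, age),
    centile = centile_curve(object$model, object$sd_profile, percentile, age)
  )
}

#' @export
fitted.ttnorm <- function(object, ...) {
  predict_tt(object$model, object$data$age)
}

#' Residuals of a normative model fit
#'
#' Log-adjusted observed minus predicted values on the non-anchor points
#' (the scale on which the model assumes Gaussian residuals).
#'
#' @param object A `ttnorm` fit.
#' @param ... Unused.
#' @return Numeric vector with attribute `age` (matching ages).
#' @export
residuals.ttnorm <- function(object, ...) {
  d <- object$data[!object$data$is_anchor, ]
  r <- log_adjust(d$tt) - rp_eval(object$model, d$age)
  attr(r, "age") <- d$age
  r
}

#' Plot a fitted normative model
#'
#' Scatter of the data with the mean curve and selected centile bands.
#'
#' @param x A `ttnorm` fit.
#' @param percentiles Centile curves to draw alongside the mean.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ttnorm <- function(x, percentiles = c(2.5, 97.5), ...) {
  d <- x$data[!x$data$is_anchor, ]
  ages <- seq(max(3, min(d$age)), max(d$age), length.out = 400)
  graphics::plot(d$age, d$tt, pch = 16, cex = 0.3,
                 col = grDevices::grey(0.6, 0.4),
                 xlab = "Age (years)", ylab = "Total testosterone (nmol/L)", ...)
  graphics::lines(ages, predict_tt(x$model, ages), lwd = 2, col = "red3")
  for (p in percentiles) {
    graphics::lines(ages, centile_curve(x$model, x$sd_profile, p, ages),
                    lty = 2, col = "steelblue")
  }
  invisible(x)
}

#' Simulate measurements from a fitted normative model
#'
#' Draws TT values at the given ages from the fitted normative distribution
#' (Gaussian on the log-adjusted scale around the mean curve, SD from the
#' fitted spread profile), clipped at 0.
#'
#' @param object A `ttnorm` fit.
#' @param nsim Number of simulated datasets.
#' @param seed Optional seed; the caller's RNG state is restored.
#' @param ages Ages at which to simulate; default the fitting ages.
#' @param ... Unused.
#' @return Data frame of `nsim` columns `sim_1 ...`, plus attribute `age`.
#' @export
simulate.ttnorm <- function(object, nsim = 1, seed = NULL, ages = NULL, ...) {
  if (is.null(ages)) ages <- object$data$age[!object$data$is_anchor]
  restore <- preserve_rng()
  on.exit(restore())
  if (!is.null(seed)) set.seed(seed)
  mu <- rp_eval(object$model, ages)
  sig <- eval_sd(object$sd_profile, ages)
  out <- as.data.frame(
    vapply(seq_len(nsim),
           function(i) pmax(inv_log_adjust(stats::rnorm(length(ages), mu, sig)), 0),
           numeric(length(ages)))
  )
  names(out) <- paste0("sim_", seq_len(nsim))
  attr(out, "age") <- ages
  out
}
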