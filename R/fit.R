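# Least-squares fitting of rational-polynomial mean curves on the
# log-adjusted scale, by Levenberg-Marquardt (minpack.lm). Conception
# anchors enter the loss at unit weight; error and fit statistics are
# always computed with anchors removed.

#' Control settings for rational-polynomial fitting
#'
#' @param ftol,ptol Relative convergence tolerances on the sum of squares
#'   and on the parameters (both 1e-9: convergence to nine significant
#'   figures).
#' @param maxiter Iteration cap passed to the LM optimiser (its maximum is
#'   1024; the 1e-9 tolerances are reached long before that in practice).
#' @param restarts Random restarts attempted when a fit fails or lands on a
#'   curve with a denominator root inside the age domain.
#' @param domain Age interval over which the fitted denominator must be
#'   strictly positive.
#' @param grid_step Step of the pole-check grid, years.
#' @param seed Seed for the (local) restart jitter stream.
#' @return List of class `rational_fit_control`.
#' @export
rational_fit_control <- function(ftol = 1e-9, ptol = 1e-9, maxiter = 1024,
                                 restarts = 20, domain = c(0, 105),
                                 grid_step = 0.1, seed = 1L) {
  structure(list(ftol = ftol, ptol = ptol, maxiter = min(maxiter, 1024),
                 restarts = restarts, domain = domain, grid_step = grid_step,
                 seed = as.integer(seed)),
            class = "rational_fit_control")
}

# numerator degree ceiling((n-1)/2), denominator degree floor((n-1)/2):
# 7 parameters -> cubic over cubic, the validated model's shape.
degrees_for_params <- function(n_params) {
  if (n_params < 1) stop("n_params must be at least 1")
  c(num = ceiling((n_params - 1) / 2), den = floor((n_params - 1) / 2))
}

# Linearised rational least squares: minimise || y * D(x) - N(x) ||, i.e.
# regress y on [x^0..x^p, -y x^1..-y x^q]. A classical starting point for
# iterative rational fitting.
rational_linear_init <- function(x, y, p, q) {
  X <- outer(x, 0:p, `^`)
  if (q > 0) X <- cbind(X, -y * outer(x, 1:q, `^`))
  cf <- stats::lm.fit(X, y)$coefficients
  cf[!is.finite(cf)] <- 0
  unname(cf)
}

poly_init <- function(x, y, p, q) {
  cf <- stats::lm.fit(outer(x, 0:p, `^`), y)$coefficients
  cf[!is.finite(cf)] <- 0
  c(unname(cf), rep(0, q))
}

#' Fit a rational polynomial to log-adjusted TT data
#'
#' Fits `log10(tt + 1) ~ N(age)/D(age)` by Levenberg-Marquardt least
#' squares. Anchor points are included in the loss; `r2` and `mse` are
#' computed on non-anchor points only. Candidate solutions whose
#' denominator has a root inside the configured age domain are rejected and
#' the fit restarts from a perturbed initialisation (up to
#' `control$restarts` times); initial values come from a linearised
#' rational least-squares solve, with a plain polynomial fit as fallback.
#'
#' @param age Ages in years.
#' @param tt TT in nmol/L (log-adjusted internally).
#' @param is_anchor Logical vector flagging conception anchors.
#' @param num_degree,den_degree Polynomial degrees of numerator and
#'   denominator; free parameters total `num_degree + den_degree + 1`.
#' @param control A [rational_fit_control()].
#' @return Object of class `rational_fit`: `model` ([rational_poly()]),
#'   `r2`, `mse` (non-anchor, log-adjusted scale), `converged`, `n_iter`,
#'   `n`, `n_anchor`, `message`.
#' @export
fit_rational <- function(age, tt, is_anchor = rep(FALSE, length(age)),
                         num_degree = 3, den_degree = 3,
                         control = rational_fit_control()) {
  stopifnot(length(age) == length(tt), length(age) == length(is_anchor))
  y <- log_adjust(tt)
  p <- num_degree; q <- den_degree
  n_par <- p + q + 1
  if (sum(!is_anchor) < n_par + 1) {
    stop(sprintf("need at least %d non-anchor points to fit %d parameters",
                 n_par + 1, n_par))
  }

  resid_fun <- function(par) {
    num <- polyval_cf(par[1:(p + 1)], age)
    den <- polyval_cf(c(1, par[seq_len(q) + p + 1]), age)
    r <- y - num / den
    r[!is.finite(r)] <- 1e6
    r
  }
  grid <- seq(control$domain[1], control$domain[2], by = control$grid_step)
  pole_free <- function(par) {
    if (q == 0) return(TRUE)
    all(polyval_cf(c(1, par[seq_len(q) + p + 1]), grid) > 0)
  }

  init0 <- rational_linear_init(age, y, p, q)
  starts <- list(init0, poly_init(age, y, p, q))

  restore <- preserve_rng()
  on.exit(restore())
  set.seed(control$seed)

  best <- NULL; best_dev <- Inf; last_msg <- "no attempt succeeded"
  attempt <- 0
  while (attempt < 2 + control$restarts) {
    attempt <- attempt + 1
    par0 <- if (attempt <= 2) starts[[attempt]] else
      init0 * (1 + stats::rnorm(n_par, 0, 0.2)) + stats::rnorm(n_par, 0, 0.01)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = par0, fn = resid_fun,
        control = minpack.lm::nls.lm.control(
          ftol = control$ftol, ptol = control$ptol, maxiter = control$maxiter
        )
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) { last_msg <- conditionMessage(fit); next }
    if (!pole_free(fit$par)) { last_msg <- "denominator root inside the age domain"; next }
    if (fit$deviance < best_dev) { best <- fit; best_dev <- fit$deviance }
    if (attempt >= 2 && !is.null(best)) break
  }
  if (is.null(best)) {
    stop(sprintf("no pole-free fit found after %d restarts (last: %s)",
                 control$restarts, last_msg))
  }

  model <- rational_poly(best$par[1:(p + 1)],
                         if (q > 0) best$par[seq_len(q) + p + 1] else numeric(0))
  pred <- rp_eval(model, age)
  yo <- y[!is_anchor]; po <- pred[!is_anchor]
  ss_res <- sum((yo - po)^2)
  ss_tot <- sum((yo - mean(yo))^2)
  structure(list(
    model = model,
    r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 0,
    mse = ss_res / length(yo),
    converged = best$info %in% 1:4,
    n_iter = best$niter,
    n = length(yo),
    n_anchor = sum(is_anchor),
    message = best$message
  ), class = "rational_fit")
}

#' @export
print.rational_fit <- function(x, ...) {
  cat(sprintf(
    "Rational-polynomial fit: %d parameters, n = %d (+%d anchors)\n  r2 = %.4f, mse = %.3g (log-adjusted, anchors excluded), %sconverged in %d iterations\n",
    x$model$n_params, x$n, x$n_anchor, x$r2, x$mse,
    if (x$converged) "" else "NOT ", x$n_iter
  ))
  invisible(x)
}

#' Fit and rank a set of rational-polynomial families
#'
#' Fits each `(num_degree, den_degree)` family and orders the results by
#' `r2` (descending, anchors excluded), breaking ties by fewer parameters —
#' the model-library screening step of the pipeline. Families whose fit
#' fails are skipped and reported in the `failures` attribute.
#'
#' @param data Data frame with `age`, `tt` and optionally `is_anchor`.
#' @param family_specs List of 2-vectors `c(num_degree, den_degree)`.
#' @param control A [rational_fit_control()].
#' @return List of `rational_fit` objects, best first, with attribute
#'   `failures` (named character vector of reasons).
#' @export
rank_models <- function(data, family_specs, control = rational_fit_control()) {
  if (length(family_specs) < 1) stop("family_specs must be non-empty")
  data <- check_tt_frame(data)
  fits <- list(); failures <- character(0)
  for (spec in family_specs) {
    key <- sprintf("(%d,%d)", spec[1], spec[2])
    f <- tryCatch(
      fit_rational(data$age, data$tt, data$is_anchor, spec[1], spec[2], control),
      error = function(e) e
    )
    if (inherits(f, "error")) failures[key] <- conditionMessage(f)
    else fits[[key]] <- f
  }
  if (length(fits)) {
    r2s <- vapply(fits, `[[`, numeric(1), "r2")
    np <- vapply(fits, function(f) f$model$n_params, numeric(1))
    fits <- fits[order(-r2s, np)]
  }
  attr(fits, "failures") <- failures
  fits
}
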