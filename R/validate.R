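# Model validation: k-fold cross-validation over model complexity,
# residual-Gaussianity diagnostics, and the LOESS comparator.

#' Split a dataset into k random folds
#'
#' Random partition into `k` folds whose sizes differ by at most one;
#' anchors are distributed like ordinary points. Reproducible by `seed`
#' (the caller's RNG state is restored).
#'
#' @param data Data frame.
#' @param k Number of folds, >= 2.
#' @param seed Integer seed.
#' @return Integer vector of fold labels `1..k`, one per row.
#' @export
kfold_split <- function(data, k = 5, seed = 1L) {
  n <- nrow(data)
  if (k < 2) stop("k must be at least 2")
  if (n < k) stop("fewer rows than folds")
  restore <- preserve_rng()
  on.exit(restore())
  set.seed(as.integer(seed))
  sample(rep_len(seq_len(k), n))
}

#' Cross-validate rational-polynomial model complexity
#'
#' For each candidate parameter count, fits the corresponding rational
#' polynomial (numerator degree `ceiling((n-1)/2)`, denominator degree
#' `floor((n-1)/2)`) on each set
#' of k-1 training folds and evaluates mean squared error on the held-out
#' fold, on the log-adjusted scale with anchors excluded from both error
#' terms (anchors still enter the training loss). High training and test
#' error indicates underfit; low training but high test error indicates
#' overfit.
#'
#' @param data Data frame with `age`, `tt`, optional `is_anchor`.
#' @param param_counts Candidate parameter counts, default 3--11.
#' @param k Number of folds, default 5.
#' @param seed Seed for the random split.
#' @param control A [rational_fit_control()].
#' @return Data frame of class `tt_cv`: `n_params`, `train_mse`,
#'   `test_mse` (fold means), with attributes `folds_train`/`folds_test`
#'   (per-fold matrices) and `failures`.
#' @export
cross_validate <- function(data, param_counts = 3:11, k = 5, seed = 1L,
                           control = rational_fit_control()) {
  data <- check_tt_frame(data)
  fold <- kfold_split(data, k, seed)
  y <- log_adjust(data$tt)
  tr <- te <- matrix(NA_real_, length(param_counts), k,
                     dimnames = list(param_counts, NULL))
  failures <- character(0)
  for (i in seq_along(param_counts)) {
    deg <- degrees_for_params(param_counts[i])
    for (f in seq_len(k)) {
      test <- fold == f
      fit <- tryCatch(
        fit_rational(data$age[!test], data$tt[!test], data$is_anchor[!test],
                     deg["num"], deg["den"], control),
        error = function(e) e
      )
      if (inherits(fit, "error")) {
        failures[sprintf("p%d_fold%d", param_counts[i], f)] <- conditionMessage(fit)
        next
      }
      pred <- rp_eval(fit$model, data$age)
      keep_tr <- !test & !data$is_anchor
      keep_te <- test & !data$is_anchor
      tr[i, f] <- mean((y[keep_tr] - pred[keep_tr])^2)
      te[i, f] <- mean((y[keep_te] - pred[keep_te])^2)
    }
  }
  # a candidate's mean error is only comparable when every fold succeeded;
  # partial candidates are reported NA (per-fold detail in the attributes)
  # and thereby excluded from selection
  out <- data.frame(
    n_params = param_counts,
    train_mse = rowMeans(tr),
    test_mse = rowMeans(te)
  )
  class(out) <- c("tt_cv", "data.frame")
  attr(out, "folds_train") <- tr
  attr(out, "folds_test") <- te
  attr(out, "failures") <- failures
  out
}

#' Select the optimal model complexity from cross-validation results
#'
#' Minimal mean test MSE, ties broken by fewer parameters (parsimony).
#' Candidates whose test error could not be computed are ignored.
#'
#' @param cv A [cross_validate()] result.
#' @return The selected parameter count.
#' @export
select_optimal <- function(cv) {
  ok <- is.finite(cv$test_mse)
  if (!any(ok)) stop("no candidate has a finite test error")
  cc <- cv[ok, ]
  cc <- cc[order(cc$test_mse, cc$n_params), ]
  cc$n_params[1]
}

#' Residual-Gaussianity diagnostics
#'
#' Computes log-adjusted residuals on non-anchor points, the proportions
#' within 1/2/3 residual SDs of the mean, and the goodness of fit (r2) of a
#' moment-matched Gaussian density to the residual histogram
#' (Freedman-Diaconis binning). For an ideal Gaussian the proportions are
#' 68.3%, 95.4% and 99.7%.
#'
#' @param model A [rational_poly()] or `ttnorm` object.
#' @param data Data frame with `age`, `tt`, optional `is_anchor`; ignored
#'   (taken from the fit) when `model` is a `ttnorm` object and `data` is
#'   missing.
#' @return List of class `residual_summary`: `residuals`, `ages`, `n`,
#'   `sd`, `within_1sd`, `within_2sd`, `within_3sd`, `gaussian_fit_r2`,
#'   `degenerate`.
#' @export
residual_analysis <- function(model, data = NULL) {
  if (inherits(model, "ttnorm")) {
    if (is.null(data)) data <- model$data
    model <- model$model
  }
  data <- check_tt_frame(data)
  d <- data[!data$is_anchor, ]
  if (nrow(d) == 0) stop("no non-anchor points")
  res <- log_adjust(d$tt) - rp_eval(model, d$age)
  s <- stats::sd(res)
  if (!is.finite(s) || s == 0) {
    return(structure(list(
      residuals = res, ages = d$age, n = length(res), sd = 0,
      within_1sd = 1, within_2sd = 1, within_3sd = 1,
      gaussian_fit_r2 = NA_real_, degenerate = TRUE
    ), class = "residual_summary"))
  }
  ctr <- res - mean(res)
  h <- graphics::hist(res, breaks = "FD", plot = FALSE)
  expected <- stats::dnorm(h$mids, mean(res), s)
  r2 <- 1 - sum((h$density - expected)^2) / sum((h$density - mean(h$density))^2)
  structure(list(
    residuals = res, ages = d$age, n = length(res), sd = s,
    within_1sd = mean(abs(ctr) <= s),
    within_2sd = mean(abs(ctr) <= 2 * s),
    within_3sd = mean(abs(ctr) <= 3 * s),
    gaussian_fit_r2 = r2, degenerate = FALSE
  ), class = "residual_summary")
}

#' @export
print.residual_summary <- function(x, ...) {
  cat(sprintf("Residual summary: n = %d, sd = %.4f (log-adjusted)\n", x$n, x$sd))
  cat(sprintf("  within 1/2/3 SD: %.1f%% / %.1f%% / %.1f%% (Gaussian: 68.3/95.4/99.7)\n",
              100 * x$within_1sd, 100 * x$within_2sd, 100 * x$within_3sd))
  if (x$degenerate) cat("  degenerate: all residuals identical\n")
  else cat(sprintf("  Gaussian histogram fit r2 = %.3f\n", x$gaussian_fit_r2))
  invisible(x)
}

tt_age_bands <- function() {
  c(list(c(3, 11), c(12, 19)),
    lapply(seq(20, 80, by = 10), function(lo) c(lo, lo + 9)))
}

#' Residual diagnostics by age band
#'
#' Partitions non-anchor data into the reporting age bands (3-11, 12-19,
#' then decades to 80-89; band membership is `lo <= age < hi + 1`) and
#' applies [residual_analysis()] per band. Empty bands are reported, not
#' errors.
#'
#' @inheritParams residual_analysis
#' @return Named list of `residual_summary` objects (or `NULL` for empty
#'   bands).
#' @export
residuals_by_decade <- function(model, data = NULL) {
  if (inherits(model, "ttnorm")) {
    if (is.null(data)) data <- model$data
    model <- model$model
  }
  data <- check_tt_frame(data)
  out <- list()
  for (band in tt_age_bands()) {
    key <- sprintf("%d-%d", band[1], band[2])
    sel <- !data$is_anchor & data$age >= band[1] & data$age < band[2] + 1
    out[[key]] <- if (any(sel)) residual_analysis(model, data[sel, ]) else NULL
  }
  out
}

#' r-squared of a locally weighted (LOESS) regression
#'
#' Fits LOESS of log-adjusted TT on age over non-anchor points and returns
#' the in-sample coefficient of determination — the comparator used to ask
#' whether an ensemble of local models would outperform the single global
#' rational polynomial.
#'
#' @param data Data frame with `age`, `tt`, optional `is_anchor`.
#' @param span LOESS span in (0, 1].
#' @param degree Local polynomial degree, 1 or 2.
#' @return r2 on the log-adjusted scale.
#' @export
loess_r2 <- function(data, span = 0.75, degree = 2) {
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (!degree %in% 1:2) stop("degree must be 1 or 2")
  data <- check_tt_frame(data)
  d <- data[!data$is_anchor, ]
  if (nrow(d) == 0) stop("no non-anchor points")
  y <- log_adjust(d$tt)
  fit <- stats::loess(y ~ age, data = data.frame(age = d$age, y = y),
                      span = span, degree = degree,
                      control = stats::loess.control(surface = "interpolate"))
  1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
}

#' Best LOESS r-squared over a small settings grid
#'
#' @inheritParams loess_r2
#' @param spans,degrees Grid of candidate settings.
#' @return List `r2`, `span`, `degree` of the best-fitting LOESS; settings
#'   that fail to fit are skipped.
#' @export
best_loess <- function(data, spans = c(0.2, 0.3, 0.5, 0.75), degrees = 1:2) {
  best <- list(r2 = -Inf, span = NA_real_, degree = NA_integer_)
  for (sp in spans) for (dg in degrees) {
    r2 <- tryCatch(suppressWarnings(loess_r2(data, sp, dg)), error = function(e) NA_real_)
    if (is.finite(r2) && r2 > best$r2) best <- list(r2 = r2, span = sp, degree = dg)
  }
  if (!is.finite(best$r2)) stop("no LOESS setting produced a fit")
  best
}
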