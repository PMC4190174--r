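# End-to-end pipeline runners tying the stages together, plus the YAML
# configuration they share. A thin command-line wrapper lives at
# inst/scripts/ttnorm-cli.R.

#' Default pipeline configuration
#'
#' All pipeline constants are surfaced here rather than hard-coded: the
#' unit factor (1 ng/dL = 0.0347 nmol/L), the age-censoring threshold
#' (3 years), anchor settings, cross-validation settings (k = 5,
#' 3--11 parameters), convergence settings (1e-9), and the SD-profile
#' settings. Values from a user YAML file are merged over these defaults.
#'
#' @return Nested list of settings.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    unit_factor = NGDL_TO_NMOLL,
    censor_age = 3,
    anchor = list(fraction = 0.01, count = NULL, age = 0),
    cv = list(enabled = TRUE, k = 5, param_counts = 3:11),
    fit = list(n_params = 7, ftol = 1e-9, ptol = 1e-9, maxiter = 1024,
               restarts = 20),
    sd = list(method = "kernel", bandwidth = 5),
    loess = list(spans = c(0.2, 0.3, 0.5, 0.75), degrees = 1:2),
    output_dir = "."
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      merge_config(base[[nm]], override[[nm]])
    } else override[[nm]]
  }
  base
}

#' Read a pipeline configuration file
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return Configuration list (user values merged over [default_config()]).
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

fit_control_from <- function(cfg) {
  rational_fit_control(ftol = cfg$fit$ftol, ptol = cfg$fit$ptol,
                       maxiter = cfg$fit$maxiter, restarts = cfg$fit$restarts,
                       seed = cfg$seed)
}

log_info <- function(fmt, ...) {
  message(sprintf("[ttnorm %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

write_provenance <- function(path, cfg, extra = list()) {
  cfg_file <- file.path(dirname(path), ".config_snapshot.yaml")
  yaml::write_yaml(cfg, cfg_file)
  hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  yaml::write_yaml(c(list(seed = cfg$seed, config_md5 = hash), extra), path)
  invisible(path)
}

#' Simulate a cohort and write it to disk
#'
#' Runs the synthetic-data generator with the configured seed and writes
#' the dataset CSV plus a provenance log (seed, config hash, profiles).
#'
#' @param config Configuration list (see [read_pipeline_config()]).
#' @param profiles Study profiles; default [study_profiles()].
#' @param mean_model,sd_profile Ground truth; defaults are the reference
#'   model and spread.
#' @param output Output CSV path; default `dataset.csv` in the configured
#'   output directory.
#' @return The dataset, invisibly.
#' @export
run_simulate <- function(config = default_config(),
                         profiles = study_profiles(),
                         mean_model = tt_reference_model(),
                         sd_profile = tt_reference_sd(),
                         output = NULL) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(output)) output <- file.path(config$output_dir, "dataset.csv")
  d <- simulate_cohort(profiles, mean_model, sd_profile, seed = config$seed)
  write_tt_csv(d, output)
  write_provenance(paste0(output, ".provenance.yaml"), config,
                   list(stage = "simulate", n = nrow(d),
                        studies = profiles$study))
  log_info("simulated %d records from %d studies -> %s", nrow(d),
           nrow(profiles), output)
  invisible(d)
}

#' Harmonize, fit, cross-validate and validate a dataset
#'
#' Executes the full modelling sequence on a dataset CSV: harmonization
#' (units, assay conversion, censoring, anchors), optional 5-fold
#' cross-validation over model complexity, the final rational-polynomial
#' fit at the selected complexity, residual analyses (overall and per age
#' band) and the LOESS comparison. Writes `model.yaml`, `cv.csv`,
#' `residuals.csv`, `residuals_by_band.csv` and `summary.txt` to the output
#' directory.
#'
#' @param input Dataset CSV path, or a data frame.
#' @param config Configuration list.
#' @return List with `fit` (the `ttnorm` object), `cv`, `selected_params`,
#'   `residuals`, `by_band`, `loess`, invisibly.
#' @export
run_fit <- function(input, config = default_config()) {
  t0 <- Sys.time()
  raw <- if (is.character(input)) read_tt_csv(input) else input
  if (nrow(raw) == 0) stop("fit pipeline failed at harmonization: empty dataset")
  h <- harmonize(raw, censor_min_age = config$censor_age,
                 anchor_frac = config$anchor$fraction,
                 anchor_count = config$anchor$count,
                 anchor_age = config$anchor$age)
  log_info("harmonized: %d points (+%d anchors)", sum(!h$is_anchor), sum(h$is_anchor))
  ctrl <- fit_control_from(config)

  cv <- NULL
  n_params <- config$fit$n_params
  if (isTRUE(config$cv$enabled)) {
    cv <- cross_validate(h, param_counts = config$cv$param_counts,
                         k = config$cv$k, seed = config$seed, control = ctrl)
    n_params <- select_optimal(cv)
    log_info("cross-validation selected %d parameters", n_params)
  }

  fit <- ttnorm(tt ~ age, h, n_params = n_params,
                sd_method = config$sd$method, bandwidth = config$sd$bandwidth,
                control = ctrl)
  res <- residual_analysis(fit)
  bands <- residuals_by_decade(fit)
  lo <- best_loess(h, spans = config$loess$spans, degrees = config$loess$degrees)

  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_model(fit$model, file.path(out, "model.yaml"),
              sd_profile = fit$sd_profile)
  if (!is.null(cv)) {
    utils::write.csv(as.data.frame(cv), file.path(out, "cv.csv"), row.names = FALSE)
  }
  utils::write.csv(
    data.frame(age = attr(residuals(fit), "age"), residual = as.numeric(residuals(fit))),
    file.path(out, "residuals.csv"), row.names = FALSE
  )
  band_rows <- do.call(rbind, lapply(names(bands), function(k) {
    b <- bands[[k]]
    data.frame(band = k, n = if (is.null(b)) 0L else b$n,
               sd = if (is.null(b)) NA_real_ else b$sd,
               within_1sd = if (is.null(b)) NA_real_ else b$within_1sd,
               within_2sd = if (is.null(b)) NA_real_ else b$within_2sd,
               within_3sd = if (is.null(b)) NA_real_ else b$within_3sd)
  }))
  utils::write.csv(band_rows, file.path(out, "residuals_by_band.csv"),
                   row.names = FALSE)
  s <- summary(fit)
  writeLines(c(
    utils::capture.output(print(s)),
    sprintf("Selected parameters: %d%s", n_params,
            if (is.null(cv)) " (cross-validation disabled)" else " (5-fold cross-validation)"),
    sprintf("Residuals within 1/2/3 SD: %.1f%% / %.1f%% / %.1f%%",
            100 * res$within_1sd, 100 * res$within_2sd, 100 * res$within_3sd),
    sprintf("Best LOESS r2 = %.4f (span %.2f, degree %d); model r2 = %.4f",
            lo$r2, lo$span, lo$degree, fit$fit$r2)
  ), file.path(out, "summary.txt"))
  write_provenance(file.path(out, "fit.provenance.yaml"), config,
                   list(stage = "fit", selected_params = n_params,
                        elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  log_info("fit complete in %.1f s (r2 = %.3f)",
           as.numeric(difftime(Sys.time(), t0, units = "secs")), fit$fit$r2)
  invisible(list(fit = fit, cv = cv, selected_params = n_params,
                 residuals = res, by_band = bands, loess = lo))
}

#' Produce the normative centile table
#'
#' @param model A `rational_poly`, a `ttnorm` fit, or the path of a model
#'   file written by [write_model()].
#' @param sd_profile SD profile; when `model` is a file carrying one, that
#'   is used; otherwise defaults to [tt_reference_sd()].
#' @param output Optional CSV path (values rounded to one decimal).
#' @param ages,percentiles Table layout; defaults give the 86 x 13 grid.
#' @return The `centile_table`, invisibly when writing.
#' @export
run_centiles <- function(model, sd_profile = NULL, output = NULL,
                         ages = 3:88, percentiles = TT_TABLE_PERCENTILES) {
  if (is.character(model)) {
    obj <- read_model(model)
    if (is.null(sd_profile)) sd_profile <- obj$sd_profile
    model <- obj$model
  } else if (inherits(model, "ttnorm")) {
    if (is.null(sd_profile)) sd_profile <- model$sd_profile
    model <- model$model
  }
  if (is.null(sd_profile)) sd_profile <- tt_reference_sd()
  tab <- normative_table(model, sd_profile, ages = ages,
                         percentiles = percentiles)
  if (!is.null(output)) {
    write_centile_table(tab, output)
    log_info("centile table (%d x %d) -> %s", nrow(tab), ncol(tab), output)
    return(invisible(tab))
  }
  tab
}

#' Score an individual measurement
#'
#' @inheritParams run_centiles
#' @param age Age in years; must lie in the model's reported domain
#'   (default 3--88).
#' @param tt Measured TT in nmol/L on the LC-MS/MS scale.
#' @param domain Reported age domain.
#' @return List with `z` and `centile`.
#' @export
run_score <- function(model, age, tt, sd_profile = NULL, domain = c(3, 88)) {
  if (is.character(model)) {
    obj <- read_model(model)
    if (is.null(sd_profile)) sd_profile <- obj$sd_profile
    model <- obj$model
  } else if (inherits(model, "ttnorm")) {
    if (is.null(sd_profile)) sd_profile <- model$sd_profile
    model <- model$model
  }
  if (is.null(sd_profile)) sd_profile <- tt_reference_sd()
  if (any(age < domain[1] | age > domain[2])) {
    stop(sprintf("age %g is outside the model's reported domain [%g, %g]",
                 age[which(age < domain[1] | age > domain[2])[1]],
                 domain[1], domain[2]))
  }
  score_individual(tt, age, model, sd_profile)
}
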