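# Synthetic multi-study cohort generator. It emulates a pooled
# cross-sectional dataset digitized from thirteen published studies: each
# study contributes its own sample size, age distribution (summarised by
# median and range) and assay scale, and TT values are drawn log-normally
# (Gaussian on the log-adjusted scale) around a known ground-truth mean
# curve with an age-dependent spread.

preserve_rng <- function() {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Default study profiles of the pooled testosterone dataset
#'
#' One row per source study: sample size, median and range of ages, and the
#' assay used. These are the thirteen studies underlying the reference
#' model; the total sample size is 10,360 before age censoring.
#'
#' @return Data frame with columns `study`, `n`, `age_median`, `age_min`,
#'   `age_max`, `assay`.
#' @export
#' @examples
#' sum(study_profiles()$n)   # 10360
study_profiles <- function() {
  p <- data.frame(
    study = c("Abdelrahaman", "Bergada", "Elmlinger", "Friedrich",
              "Kyriakopoulou", "Leifke", "Harman", "Morley", "Yeap",
              "Pierik", "Halmenschlager", "Sartorius", "Travison"),
    n = c(47L, 94L, 623L, 971L, 172L, 572L, 890L, 287L, 3645L,
          113L, 428L, 324L, 2194L),
    age_median = c(6.2, 0.02, 40.1, 47.4, 8.3, 40.5, 56.9, 76.2, 76.6,
                   0.2, 51.9, 59.8, 61.5),
    age_min = c(4.9, 0, 0, 20.3, 0, 20.0, 22.9, 61.2, 70.8,
                0.1, 29.8, 40.1, 44.9),
    age_max = c(9.0, 0.1, 98.9, 79.8, 18.6, 80.0, 94.4, 101.1, 87.8,
                0.4, 83.0, 86.9, 80.0),
    assay = c("DPC", "DSL", "Centaur", "Centaur", "LC-MS/MS", "DSL",
              "DSL", "DPC", "DPC", "Centaur", "Roche", "LC-MS/MS", "RIA"),
    stringsAsFactors = FALSE
  )
  p
}

# Solve for the Beta shape (at fixed concentration alpha + beta) whose
# median matches the study's relative median position in [age_min, age_max].
beta_shape_for_median <- function(m_rel, concentration = 5) {
  lo <- 0.02; hi <- concentration - 0.02
  f <- function(a) suppressWarnings(stats::qbeta(0.5, a, concentration - a)) - m_rel
  if (f(lo) >= 0) return(lo)
  if (f(hi) <= 0) return(hi)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Simulate a pooled multi-study cross-sectional cohort
#'
#' For each study profile, draws ages from a scaled Beta distribution on
#' `[age_min, age_max]` whose median matches `age_median` (bounded and
#' skewable: two targets, two constraints), then draws log-adjusted TT as
#' Gaussian around `mean_model` with SD `sd_profile`, back-transforms to
#' nmol/L (clipped at 0: concentrations are non-negative), and finally maps
#' each value onto the study's native assay scale with the inverse assay
#' conversion — so the raw dataset looks like digitized source data and the
#' harmonization step has real work to do.
#'
#' A single integer seed governs all draws; per-study substreams are derived
#' from it, so the output is fully reproducible. The caller's RNG state is
#' left untouched.
#'
#' @param profiles Study profiles as from [study_profiles()].
#' @param mean_model Ground-truth mean curve ([rational_poly()]).
#' @param sd_profile Ground-truth spread (`sd_profile`); use
#'   [sd_profile_constant()] with `sigma = 0` for noise-free data.
#' @param seed Integer seed.
#' @param concentration Beta concentration (`alpha + beta`) of the age
#'   distribution; larger values concentrate ages around the median.
#' @param unit Output unit, `"nmol/L"` (default) or `"ng/dL"`.
#' @return Data frame with columns `age`, `tt`, `unit`, `study`, `assay`,
#'   `is_anchor` (all `FALSE`; anchors are added by [harmonize()]).
#' @export
#' @examples
#' d <- simulate_cohort(seed = 7)
#' nrow(d)   # 10360
simulate_cohort <- function(profiles = study_profiles(),
                            mean_model = tt_reference_model(),
                            sd_profile = tt_reference_sd(),
                            seed = 1L, concentration = 5,
                            unit = "nmol/L") {
  stopifnot(inherits(mean_model, "rational_poly"), inherits(sd_profile, "sd_profile"))
  unit <- match.arg(unit, c("nmol/L", "ng/dL"))
  registry <- assay_registry()
  for (a in unique(profiles$assay)) get_conversion(a, registry)
  if (any(profiles$n < 1)) stop("each study must contribute at least one subject")
  if (any(profiles$age_min > profiles$age_median | profiles$age_median > profiles$age_max)) {
    stop("profiles must satisfy age_min <= age_median <= age_max")
  }
  # refuse ground truths with a pole inside any study's age range
  grid <- seq(min(profiles$age_min), max(profiles$age_max), length.out = 2048)
  den <- polyval_cf(c(1, mean_model$den), grid)
  if (any(den <= 0)) {
    stop(sprintf("mean model has a pole at age %.2f inside the simulated range",
                 grid[which(den <= 0)[1]]))
  }

  restore <- preserve_rng()
  on.exit(restore())
  set.seed(as.integer(seed))
  study_seeds <- sample.int(.Machine$integer.max, nrow(profiles))

  out <- vector("list", nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    pr <- profiles[i, ]
    set.seed(study_seeds[i])
    span <- pr$age_max - pr$age_min
    ages <- if (span <= 0) {
      rep(pr$age_min, pr$n)
    } else {
      a <- beta_shape_for_median((pr$age_median - pr$age_min) / span, concentration)
      pr$age_min + span * stats::rbeta(pr$n, a, concentration - a)
    }
    y <- stats::rnorm(pr$n, rp_eval(mean_model, ages), eval_sd(sd_profile, ages))
    tt_ref <- pmax(inv_log_adjust(y), 0)
    raw <- pmax(convert_from_reference(tt_ref, pr$assay, registry), 0)
    if (unit == "ng/dL") raw <- raw / NGDL_TO_NMOLL
    out[[i]] <- data.frame(
      age = ages, tt = raw, unit = unit, study = pr$study, assay = pr$assay,
      is_anchor = FALSE, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
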