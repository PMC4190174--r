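test_that("k-fold split is a seeded partition with near-equal sizes", {
  d <- data.frame(age = 1:10, tt = rep(5, 10))
  f <- kfold_split(d, k = 5, seed = 3)
  expect_equal(as.integer(table(f)), rep(2L, 5))
  expect_setequal(unique(f), 1:5)
  expect_identical(f, kfold_split(d, k = 5, seed = 3))
  f2 <- kfold_split(data.frame(x = 1:11), k = 5, seed = 3)
  expect_true(max(table(f2)) - min(table(f2)) <= 1)
  expect_error(kfold_split(d, k = 1), "at least 2")
})

test_that("cross-validation on zero-noise data hits zero error from the true complexity", {
  truth <- rational_poly(c(0.1, 0.05), den = 0.01)   # 3-parameter truth
  age <- seq(3, 88, length.out = 400)
  d <- data.frame(age = age, tt = pmax(inv_log_adjust(rp_eval(truth, age)), 0),
                  is_anchor = FALSE)
  cv <- cross_validate(d, param_counts = c(3, 5, 7), k = 5, seed = 8)
  expect_true(all(cv$test_mse < 1e-10))
  expect_identical(select_optimal(cv), 3)            # parsimony tie-break in action
})

test_that("training error is monotone in model complexity on shared folds", {
  h <- pooled_cohort_015()
  set.seed(2)
  sub <- h[sample(nrow(h), 1500), ]
  cv <- cross_validate(sub, param_counts = c(3, 11), k = 5, seed = 5)
  expect_lte(cv$train_mse[cv$n_params == 11], cv$train_mse[cv$n_params == 3])
})

test_that("optimal complexity is minimal test error with parsimony tie-break", {
  cv <- data.frame(n_params = c(5, 7, 9), test_mse = c(0.3, 0.1, 0.1))
  expect_identical(select_optimal(cv), 7)
  expect_identical(select_optimal(data.frame(n_params = 4, test_mse = 1)), 4)
  cv$test_mse <- c(0.3, NA, 0.2)
  expect_identical(select_optimal(cv), 9)
})

test_that("the modal cross-validated complexity is 7 across replicates of the 7-parameter truth", {
  p <- study_profiles()
  p$n <- as.integer(round(p$n * 0.5))
  sel <- vapply(101:110, function(s) {
    h <- harmonize(simulate_cohort(p, sd_profile = sd_profile_constant(0.15), seed = s))
    select_optimal(cross_validate(h, param_counts = 3:11, k = 5, seed = s))
  }, numeric(1))
  tab <- sort(table(sel), decreasing = TRUE)
  expect_identical(as.integer(names(tab)[1]), 7L)
})

test_that("residual proportions on a large Gaussian sample match normal theory", {
  model <- rational_poly(1.1)
  set.seed(6)
  n <- 1e6
  d <- data.frame(age = runif(n, 3, 88),
                  tt = inv_log_adjust(1.1 + rnorm(n, 0, 0.14)))
  rs <- residual_analysis(model, d)
  # 3 binomial SDs of the ideal proportions at this n
  expect_lt(abs(rs$within_1sd - 0.6827), 3 * sqrt(0.6827 * 0.3173 / n) + 1e-3)
  expect_lt(abs(rs$within_2sd - 0.9545), 3 * sqrt(0.9545 * 0.0455 / n) + 1e-3)
  expect_lt(abs(rs$within_3sd - 0.9973), 3 * sqrt(0.9973 * 0.0027 / n) + 1e-3)
  expect_gt(rs$gaussian_fit_r2, 0.99)
  expect_false(rs$degenerate)
})

test_that("an exactly Gaussian residual sample fits its own histogram", {
  model <- rational_poly(2)
  q <- qnorm((1:5000 - 0.5) / 5000, sd = 0.1)     # perfect Gaussian quantiles
  d <- data.frame(age = runif(5000, 3, 88), tt = inv_log_adjust(2 + q))
  expect_gt(residual_analysis(model, d)$gaussian_fit_r2, 0.99)
})

test_that("identical residuals are flagged degenerate with unit proportions", {
  d <- data.frame(age = c(10, 20, 30), tt = inv_log_adjust(rep(1.5, 3)))
  rs <- residual_analysis(rational_poly(1.5), d)
  expect_true(rs$degenerate)
  expect_equal(c(rs$within_1sd, rs$within_2sd, rs$within_3sd), c(1, 1, 1))
})

test_that("age-band residual summaries cover 3-11 first, decades to 89", {
  set.seed(14)
  d <- data.frame(age = runif(4000, 3, 89.99),
                  tt = inv_log_adjust(1 + rnorm(4000, 0, 0.12)))
  bands <- residuals_by_decade(rational_poly(1), d)
  expect_identical(names(bands)[1:3], c("3-11", "12-19", "20-29"))
  expect_length(bands, 9)
  expect_true(all(!vapply(bands, is.null, logical(1))))
  expect_equal(bands[["3-11"]]$n, sum(d$age < 12))
  # homoscedastic truth: per-band SDs agree within sampling error
  sds <- vapply(bands, `[[`, numeric(1), "sd")
  expect_lt(max(abs(sds - 0.12)), 0.015)
  # an empty band is reported as NULL, not an error
  old <- d[d$age >= 20, ]
  expect_null(residuals_by_decade(rational_poly(1), old)[["3-11"]])
})

test_that("LOESS r2 behaves: near 1 on noiseless linear data, never above 1", {
  age <- seq(5, 80, length.out = 300)
  d <- data.frame(age = age, tt = inv_log_adjust(0.2 + 0.01 * age))
  expect_equal(loess_r2(d, span = 0.5, degree = 1), 1, tolerance = 1e-4)
  h <- pooled_cohort_015()
  set.seed(3)
  r2 <- loess_r2(h[sample(nrow(h), 2000), ], span = 0.75, degree = 2)
  expect_lte(r2, 1)
  expect_error(loess_r2(d, span = 0), "span")
  expect_error(loess_r2(d, span = 1.2), "span")
})
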