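test_that("fitting noiseless data from a cubic/cubic truth recovers the curve", {
  m <- tt_reference_model()
  ages <- seq(3, 88, length.out = 1500)
  f <- fit_rational(ages, predict_tt(m, ages), num_degree = 3, den_degree = 3)
  grid <- seq(3, 88, by = 0.1)
  expect_lt(max(abs(rp_eval(f$model, grid) - rp_eval(m, grid))), 1e-6)
  expect_true(f$converged)
  expect_equal(f$r2, 1, tolerance = 1e-9)   # perfect fit
})

test_that("constant data yields the constant model with r2 defined as zero", {
  tt <- rep(99, 20)                          # log-adjusted value 2
  f <- fit_rational(seq(5, 60, length.out = 20), tt, num_degree = 0, den_degree = 0)
  expect_equal(unname(f$model$num), 2, tolerance = 1e-8)
  expect_identical(f$r2, 0)                  # zero-variance target
})

test_that("fitting requires more non-anchor points than parameters", {
  expect_error(fit_rational(1:5, rep(2, 5), num_degree = 3, den_degree = 3),
               "at least 8 non-anchor points")
})

test_that("anchors pull the curve toward zero at the anchor age", {
  set.seed(4)
  age <- runif(400, 3, 88)
  tt <- pmax(inv_log_adjust(rp_eval(tt_reference_model(), age) + rnorm(400, 0, 0.1)), 0)
  no_anchor <- fit_rational(age, tt, num_degree = 2, den_degree = 2)
  d <- add_anchors(data.frame(age = age, tt = tt, is_anchor = FALSE), 200)
  anchored <- fit_rational(d$age, d$tt, d$is_anchor, 2, 2)
  expect_lt(abs(rp_eval(anchored$model, 0)), abs(rp_eval(no_anchor$model, 0)) + 0.02)
  expect_equal(anchored$n_anchor, 200)
})

test_that("model ranking orders families by r2 and reports failures", {
  h <- pooled_cohort_015()
  set.seed(1)
  sub <- h[sample(nrow(h), 2000), ]
  rk <- rank_models(sub, list(c(3, 3), c(1, 0)))
  expect_equal(names(rk)[1], "(3,3)")        # generating family beats a line
  expect_gt(rk[[1]]$r2, rk[[2]]$r2)

  single <- rank_models(sub, list(c(2, 1)))
  expect_length(single, 1)

  tiny <- sub[1:4, ]
  allfail <- rank_models(tiny, list(c(3, 3), c(4, 4)))
  expect_length(allfail, 0)
  expect_length(attr(allfail, "failures"), 2)
})

test_that("the ttnorm interface fits, summarises and predicts coherently", {
  h <- pooled_cohort_015()
  fit <- ttnorm(tt ~ age, h)
  expect_s3_class(fit, "ttnorm")
  expect_equal(fit$model$n_params, 7)
  expect_gt(fit$fit$r2, 0.4)
  expect_equal(predict(fit, data.frame(age = 40)),
               predict_tt(fit$model, 40))
  expect_equal(predict(fit, data.frame(age = 40), type = "centile", percentile = 50),
               predict_tt(fit$model, 40))
  expect_length(residuals(fit), fit$fit$n)
  cf <- coef(fit)
  expect_named(cf, c("num0", "num1", "num2", "num3", "den1", "den2", "den3"))
  s <- summary(fit)
  expect_s3_class(s, "summary.ttnorm")
  expect_equal(s$peak_age, peak_age(fit$model))
  sims <- simulate(fit, nsim = 2, seed = 5, ages = c(20, 40, 60))
  expect_equal(dim(sims), c(3L, 2L))
  expect_true(all(sims >= 0))
})
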