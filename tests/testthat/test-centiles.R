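test_that("kernel SD estimation recovers a homoscedastic sigma within 5%", {
  set.seed(17)
  ages <- runif(10000, 3, 88)
  res <- rnorm(10000, 0, 0.15)
  prof <- estimate_sd_profile(res, ages, method = "kernel", bandwidth = 5)
  expect_equal(eval_sd(prof, c(10, 40, 80)), rep(0.15, 3), tolerance = 0.05)
  const <- estimate_sd_profile(res, ages, method = "constant")
  expect_equal(eval_sd(const, 55), sd(res))
})

test_that("kernel SD tracks a rising spread with age", {
  set.seed(18)
  ages <- runif(10000, 3, 88)
  sig <- 0.13 + 0.04 * pmax(ages - 40, 0) / 48   # 0.13 to 0.17 over 40..88
  prof <- estimate_sd_profile(rnorm(10000, 0, sig), ages, bandwidth = 5)
  expect_gt(eval_sd(prof, 88), eval_sd(prof, 40))
  expect_equal(eval_sd(prof, 85), 0.1675, tolerance = 0.1)
})

test_that("SD estimation guards its preconditions", {
  expect_error(estimate_sd_profile(rnorm(10), runif(10)), "at least 30")
  expect_error(estimate_sd_profile(rnorm(50), runif(50), bandwidth = 0), "bandwidth")
  zero <- estimate_sd_profile(rep(0, 50), runif(50, 3, 88), method = "kernel")
  expect_equal(eval_sd(zero, c(10, 50, 80)), rep(0, 3))
})

test_that("the 50th centile is the mean curve and symmetric centiles balance in log space", {
  m <- tt_reference_model()
  sdp <- tt_reference_sd()
  ages <- c(5, 19, 40, 70, 88)
  expect_equal(centile_curve(m, sdp, 50, ages), predict_tt(m, ages))
  # symmetry holds wherever the lower centile does not clip at zero
  ages <- c(19, 40, 70, 88)
  lo <- log_adjust(centile_curve(m, sdp, 10, ages))
  hi <- log_adjust(centile_curve(m, sdp, 90, ages))
  expect_equal((lo + hi) / 2, rp_eval(m, ages), tolerance = 1e-10)
  expect_error(centile_curve(m, sdp, 0, 40), "percentile")
  expect_error(centile_curve(m, sdp, 100, 40), "percentile")
})

test_that("the upper normative bound at the pubertal peak matches the derived sigma", {
  # sigma(19) = 0.151 was obtained by inverting the published 2.5-97.5 band
  # 7.2-31.1 at the peak; the forward computation must return that band
  m <- tt_reference_model()
  sdp <- tt_reference_sd()
  expect_equal(centile_curve(m, sdp, 97.5, 19), 31.1, tolerance = 0.02)
  expect_equal(centile_curve(m, sdp, 2.5, 19), 7.2, tolerance = 0.02)
})

test_that("the normative table matches the published median column and its invariants", {
  tab <- normative_table(tt_reference_model(), tt_reference_sd())
  expect_equal(dim(tab), c(86L, 14L))
  expect_equal(tab$age, 3:88)
  p50 <- tab[["50"]]
  expect_lt(abs(p50[tab$age == 3] - 0.4), 0.05)
  expect_equal(p50[tab$age == 40], 13.0, tolerance = 0.02)
  expect_equal(p50[tab$age == 88], 13.2, tolerance = 0.02)
  vals <- as.matrix(tab[, -1])
  expect_true(all(vals >= 0))
  expect_true(all(apply(vals, 1, function(r) all(diff(r) >= 0))))   # rows non-decreasing
})

test_that("with constant sigma the (value+1) centile ratio is the closed form", {
  sdp <- sd_profile_constant(0.12)
  # ages where the 2.5th centile is strictly positive (no zero-clipping)
  tab <- normative_table(tt_reference_model(), sdp, ages = 14:88)
  ratio <- (tab[["97.5"]] + 1) / (tab[["2.5"]] + 1)
  expect_equal(ratio, rep(10^(2 * qnorm(0.975) * 0.12), 75), tolerance = 1e-10)
})

test_that("scoring inverts the centile construction", {
  m <- tt_reference_model()
  sdp <- tt_reference_sd()
  expect_equal(score_individual(predict_tt(m, 40), 40, m, sdp)$z, 0)
  expect_equal(score_individual(predict_tt(m, 40), 40, m, sdp)$centile, 50)
  at25 <- centile_curve(m, sdp, 2.5, 61)
  expect_equal(score_individual(at25, 61, m, sdp)$z, qnorm(0.025), tolerance = 1e-9)
  # published lower 2.5% bound at age 40 scores at about the 2.5th centile
  expect_equal(score_individual(6.6, 40, m, sdp)$centile, 2.5, tolerance = 0.1)
  expect_error(score_individual(5, 40, m, sd_profile_constant(0)), "degenerate")
})

test_that("empirical-mode centiles follow the residual tails", {
  set.seed(23)
  ages <- runif(5000, 3, 88)
  res <- 0.1 * (rchisq(5000, 4) - 4) / sqrt(8)   # right-skewed residuals
  prof <- estimate_sd_profile(res, ages, method = "constant")
  m <- tt_reference_model()
  emp99 <- centile_curve(m, prof, 99, 40, mode = "empirical")
  gau99 <- centile_curve(m, prof, 99, 40, mode = "gaussian")
  expect_gt(emp99, gau99)    # skew pushes the upper tail out
  expect_error(centile_curve(m, tt_reference_sd(), 99, 40, mode = "empirical"),
               "residuals")
})
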