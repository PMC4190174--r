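mk_points <- function(age, tt, assay = "LC-MS/MS", unit = "nmol/L") {
  n <- length(age)
  data.frame(age = age, tt = tt, unit = rep_len(unit, n),
             study = rep_len("s", n), assay = rep_len(assay, n),
             is_anchor = rep_len(FALSE, n), stringsAsFactors = FALSE)
}

test_that("age censoring is boundary-inclusive and exempts anchors", {
  d <- mk_points(c(2.9, 3.0, 3.1), c(1, 1, 1))
  expect_equal(censor_by_age(d, 3)$age, c(3.0, 3.1))
  expect_equal(nrow(censor_by_age(mk_points(numeric(0), numeric(0)), 3)), 0)
  with_anchor <- add_anchors(d, 2, anchor_age = 0)
  kept <- censor_by_age(with_anchor, 3)
  expect_equal(sum(kept$is_anchor), 2)
})

test_that("conception anchors are zero-valued, flagged, and counted exactly", {
  d <- mk_points(c(10, 20), c(5, 12))
  expect_identical(add_anchors(d, 0), d[, names(add_anchors(d, 1))[1:6]])
  a <- add_anchors(d, 100, anchor_age = 0)
  expect_equal(sum(a$is_anchor), 100)
  expect_true(all(a$tt[a$is_anchor] == 0))
  expect_true(all(a$age[a$is_anchor] == 0))
})

test_that("fit statistics exclude anchors: r2 equals the anchor-free value", {
  set.seed(11)
  age <- runif(300, 3, 88)
  tt <- pmax(inv_log_adjust(rp_eval(tt_reference_model(), age) + rnorm(300, 0, 0.15)), 0)
  d <- add_anchors(mk_points(age, tt), 30)
  f_anchored <- fit_rational(d$age, d$tt, d$is_anchor, 1, 1)
  # recompute r2 of the same curve on the anchor-free subset
  y <- log_adjust(tt)
  pred <- rp_eval(f_anchored$model, age)
  r2_free <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  expect_equal(f_anchored$r2, r2_free)
  expect_equal(f_anchored$n, 300)
})

test_that("harmonization standardises units, converts assays once, and anchors", {
  # mixed units and assays, zero noise: harmonized values must equal the truth
  m <- tt_reference_model()
  age <- seq(25, 70, by = 0.5)
  truth <- predict_tt(m, age)
  raw_ria <- convert_from_reference(truth, "RIA") / 0.0347   # native scale, ng/dL
  d <- rbind(
    mk_points(age, raw_ria, assay = "RIA", unit = "ng/dL"),
    mk_points(age, convert_from_reference(truth, "Roche"), assay = "Roche")
  )
  h <- harmonize(d, anchor_count = 5)
  expect_equal(sum(h$is_anchor), 5)
  expect_true(all(h$assay == "LC-MS/MS"))
  expect_equal(h$tt[!h$is_anchor], c(truth, truth), tolerance = 1e-9)
  # a second pass is a no-op on values: the assay tag was rewritten
  h2 <- harmonize(h, anchor_count = 0)
  expect_equal(h2$tt, h$tt)
})

test_that("harmonize rejects empty input and defaults anchors to 1%", {
  expect_error(harmonize(mk_points(numeric(0), numeric(0))), "empty")
  d <- mk_points(runif(200, 10, 80), rep(10, 200))
  expect_equal(sum(harmonize(d)$is_anchor), 2)   # ceiling(0.01 * 200)
})

test_that("inter-observer agreement uses per-point relative tolerance at a 99% bar", {
  a <- mk_points(1:100, seq(2, 30, length.out = 100))
  res <- interobserver_agreement(a, a)
  expect_equal(res$age_agreement, 1)
  expect_equal(res$tt_agreement, 1)
  expect_true(res$pass)
  b <- a
  b$tt[1] <- b$tt[1] * 1.5   # one of 100 pairs beyond tolerance
  res2 <- interobserver_agreement(a, b)
  expect_equal(res2$tt_agreement, 0.99)
  expect_true(res2$pass)     # boundary-inclusive at the default 0.99 threshold
  b$tt[2] <- b$tt[2] * 1.5
  expect_false(interobserver_agreement(a, b)$pass)
  expect_error(interobserver_agreement(a, a[1:10, ]), "length")
})
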