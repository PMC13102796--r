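test_that("rate-corrected shortening velocity evaluates and guards its domain", {
  expect_equal(vcfc(13, 11, 1), 2 / 13)
  expect_equal(vcfc(13, 13, 1), 0)
  expect_equal(vcfc(13, 11, 0.729), (2 / 13) / 0.9, tolerance = 1e-12)
  expect_error(vcfc(11, 13, 1), "shortens")
  expect_error(vcfc(13, 11, 0), "positive")
})

test_that("contractility Z-score measures distance from the mean-normal line", {
  expect_equal(contractility_z(0.966, 60), 0, tolerance = 1e-12)
  expect_equal(contractility_z(1.026, 60), 1, tolerance = 1e-12)
  expect_equal(contractility_z(1.23, 0), 0)
  expect_error(contractility_z(1, -5), "non-negative")
})

test_that("contractility gain is 1 at normal and reciprocal under sign flip", {
  expect_equal(contractility_gain(0), 1)
  expect_equal(contractility_gain(2, 0.2), 0.4 + sqrt(1.16), tolerance = 1e-12)
  z <- seq(-5, 5, length.out = 101)
  expect_equal(contractility_gain(z) * contractility_gain(-z),
               rep(1, length(z)), tolerance = 1e-12)
  # strictly increasing
  expect_true(all(diff(contractility_gain(z)) > 0))
})

test_that("stress-stretch law gives the normal-heart stretch and inverts to PMW_AM", {
  expect_equal(lambda_es(60, 1), 1.12)
  expect_equal(lambda_es(0, 1), 1)
  expect_equal(lambda_es(60, 2), 1.06)
  expect_equal(pmw_am(11.2, 60, 1), 10, tolerance = 1e-12)
  expect_equal(pmw_am(11.2, 0, 1), 11.2)
  # monotone: more stress, smaller AM perimeter
  ess <- seq(0, 200, by = 10)
  expect_true(all(diff(pmw_am(11.2, ess, 1)) < 0))
})

test_that("two-point cubic fit reproduces both states exactly", {
  f <- fit_ab(120, 50, 12, 10)
  expect_equal(f$a, 70 / 728, tolerance = 1e-12)
  expect_equal(f$b, 33600 / 728, tolerance = 1e-12)
  expect_equal(predict(f, 12), 120, tolerance = 1e-9)
  expect_equal(predict(f, 10), 50, tolerance = 1e-9)
  expect_equal(amv(f, 9), 17430 / 728, tolerance = 1e-9)

  # pass-through exactness on arbitrary geometry-module states
  h <- mid_heart()
  es <- inflate_to_stretch(h$shape, h$am, 1.1)
  ed <- inflate_to_stretch(h$shape, h$am, 1.3)
  f2 <- fit_ab(ed$LVV, es$LVV, ed$PMW, es$PMW)
  expect_equal(predict(f2, ed$PMW), ed$LVV, tolerance = 1e-9)
  expect_equal(predict(f2, es$PMW), es$LVV, tolerance = 1e-9)

  expect_error(fit_ab(120, 50, 10, 10 * (1 + 1e-12)), "degenerate")
  expect_error(fit_ab(50, 120, 12, 10), "exceed")
})

test_that("hemispherical thin shell recovers the closed-form cubic coefficient", {
  h <- shell_from_am(lvid_am = 4, h_am = 0.004, k = 1, L = 0)
  s1 <- inflate_to_stretch(h$shape, h$am, 1.12)
  s2 <- inflate_to_stretch(h$shape, h$am, 1.30)
  f <- fit_ab(s2$LVV, s1$LVV, s2$PMW, s1$PMW)
  expect_equal(f$a, 1 / (12 * pi^2), tolerance = 1e-5)
  # within 0.2% of the rounded literature value 0.00845
  expect_lt(abs(f$a - 0.00845) / 0.00845, 0.002)
})

test_that("the full single-beat chain inverts an exactly synthesised stress pathway", {
  for (gc in c(0.7, 1, 1.4)) {
    h <- shell_from_am(3.4, 1.3, 1.6, 0.25)
    sim <- beat_from_heart(h, lam_es = 1.11, lam_ed = 1.29, g_c = gc)
    # supply the vcfc that makes the Z-score/gain reproduce gc exactly:
    # invert G_C = x + sqrt(x^2+1) at x = c_1 * z
    z <- (gc - 1 / gc) / (2 * 0.2)
    v_target <- 0.06 * z + 1.23 - 0.0044 * sim$beat$ess
    sim$beat$vcfc_override <- v_target
    fit <- amv_single_beat(sim$beat)
    expect_equal(fit$g_c, gc, tolerance = 1e-12)
    expect_equal(fit$pmw_am, h$am$PMW, tolerance = 1e-9)
    expect_length(fit$flags, 0)
    expect_lt(fit$amv, sim$beat$esv)
  }
})

test_that("zero wall stress collapses the estimate onto the end-systolic state", {
  h <- mid_heart()
  sim <- beat_from_heart(h)
  b <- sim$beat
  b$ess <- 0
  fit <- amv_single_beat(b)
  expect_equal(fit$lambda_es, 1)
  expect_equal(fit$pmw_am, b$pmw_es)
  expect_equal(fit$amv, b$esv, tolerance = 1e-9)
})

test_that("increasing stress monotonically lowers the volume estimate", {
  h <- mid_heart()
  sim <- beat_from_heart(h)
  amvs <- vapply(seq(10, 150, by = 10), function(ess) {
    b <- sim$beat
    b$ess <- ess
    b$vcfc_override <- 1.23 - 0.0044 * ess  # hold contractility at normal
    amv_single_beat(b)$amv
  }, numeric(1))
  expect_true(all(diff(amvs) < 0))
})

test_that("estimator flags pathological outcomes instead of clamping", {
  # tiny ESV with a shallow slope drives the extrapolation negative
  b <- echo_beat(lvid_ed = 4.0, h_ed = 1.0, lvid_es = 3.8, h_es = 1.1,
                 edv = 100, esv = 5, ess = 300, rr = 0.8)
  fit <- amv_single_beat(b)
  expect_lt(fit$amv, 0)
  expect_true("NEGATIVE_AMV" %in% fit$flags)

  # physiologic beat: no flags, AMV strictly inside (0, ESV)
  h <- mid_heart()
  fit2 <- amv_single_beat(beat_from_heart(h)$beat)
  expect_length(fit2$flags, 0)
  expect_true(fit2$amv > 0 && fit2$amv < fit2$beat$esv)
})

test_that("fit methods expose coefficients, predictions and summaries", {
  h <- mid_heart()
  fit <- amv_single_beat(beat_from_heart(h)$beat)
  expect_named(coef(fit), c("a", "b"))
  expect_equal(predict(fit), fit$amv)
  expect_equal(predict(fit, fit$beat$pmw_es), fit$beat$esv, tolerance = 1e-9)
  s <- summary(fit)
  expect_equal(s$ef, (fit$beat$edv - fit$beat$esv) / fit$beat$edv)
  expect_true(s$ff > s$ef)
  expect_output(print(fit), "AMV")
  # one-row data.frame input works too
  df <- data.frame(lvid_ed = 4.8, h_ed = 0.9, lvid_es = 3.2, h_es = 1.4,
                   edv = 120, esv = 50, ess = 60, rr = 0.8)
  expect_s3_class(amv_single_beat(df), "amv_fit")
})
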