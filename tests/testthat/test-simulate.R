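small_plan <- function(n = 200, seed = 11) sampling_plan(n = n, seed = seed)

test_that("plan validation rejects inconsistent ranges", {
  expect_error(sampling_plan(lambda_es = c(1.2, 1.3), lambda_ed = c(1.25, 1.36)),
               "below the end-diastolic")
  expect_error(sampling_plan(h_am = c(1, 3)), "H < LVID")
  expect_error(sampling_plan(L = c(0, 1.5)), "\\[0, 1\\]")
  expect_error(sampling_plan(n = 0), "at least 1")
})

test_that("degenerate zero-width ranges give one fully determined heart", {
  p <- sampling_plan(n = 1, seed = 1,
                     lvid_am = c(3, 3), h_am = c(1.2, 1.2), k = c(1.5, 1.5),
                     L = c(0.2, 0.2), lambda_es = c(1.1, 1.1),
                     lambda_ed = c(1.3, 1.3))
  d <- sample_hearts(p)
  h <- shell_from_am(3, 1.2, 1.5, 0.2)
  expect_equal(d$v_w, h$v_w)
  es <- inflate_to_stretch(h$shape, h$am, 1.1)
  expect_equal(d$esv, es$LVV, tolerance = 1e-12)
  expect_equal(d$pmw_es, es$PMW, tolerance = 1e-12)
})

test_that("sampled cohorts are deterministic and geometrically valid", {
  d1 <- sample_hearts(small_plan())
  d2 <- sample_hearts(small_plan())
  expect_identical(d1, d2)
  r <- small_plan()$ranges
  expect_true(all(d1$lvid_am >= r$lvid_am[1] & d1$lvid_am <= r$lvid_am[2]))
  # physical branch everywhere: H < 2B at AM, ES, ED
  expect_true(all(d1$h_am < d1$lvid_am))
  expect_true(all(d1$h_es < 2 * d1$b_es))
  expect_true(all(d1$h_ed < 2 * d1$b_ed))
  # wall volume conserved through both inflations
  v_m_es <- wall_volume(d1$k * d1$b_es, d1$b_es, d1$h_es, d1$L)
  v_m_ed <- wall_volume(d1$k * d1$b_ed, d1$b_ed, d1$h_ed, d1$L)
  expect_lt(max(abs(v_m_es - d1$v_m) / d1$v_m), 1e-9)
  expect_lt(max(abs(v_m_ed - d1$v_m) / d1$v_m), 1e-9)
})

test_that("the experiment never overshoots the end-systolic volume", {
  res <- run_experiment(small_plan())
  expect_true(all(res$amv_hat < res$esv))
  expect_true(all(res$a > 0))
})

test_that("stress-pathway mode equals true-perimeter mode under exact inversion", {
  for (gc in c(0.8, 1, 1.3)) {
    r1 <- run_experiment(small_plan(), mode = "true_pmw_am", linearity = FALSE)
    r2 <- run_experiment(small_plan(), mode = "ess_pathway", g_c = gc,
                         linearity = FALSE)
    expect_lt(max(abs(r2$amv_hat - r1$amv_hat) / r1$v_w), 1e-9)
  }
})

test_that("agreement statistics are exact under perfect agreement and flag n = 1", {
  fake <- data.frame(v_w = c(5, 10, 20, 40), amv_hat = c(5, 10, 20, 40))
  st <- agreement_stats(fake)
  expect_equal(st$bias, 0)
  expect_equal(st$rmse, 0)
  expect_equal(st$slope, 1)
  expect_equal(st$intercept, 0)
  one <- agreement_stats(data.frame(v_w = 5, amv_hat = 6))
  expect_true(one$degenerate)
  expect_equal(one$bias, 1)
  expect_true(is.na(one$slope))
  expect_error(agreement_stats(data.frame()), "empty")
})

test_that("agreement regression matches lm as an independent check", {
  res <- run_experiment(small_plan())
  st <- agreement_stats(res)
  ref <- lm(v_w ~ amv_hat, data = res)
  expect_equal(st$slope, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(st$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
  expect_equal(st$r_squared, summary(ref)$r.squared, tolerance = 1e-10)
})

test_that("vectorised linearity diagnostic matches per-heart lm", {
  res <- run_experiment(small_plan(n = 20))
  grid <- seq(1, 1.36, length.out = 50)
  for (i in c(1, 7, 20)) {
    h <- shell_from_am(res$lvid_am[i], res$h_am[i], res$k[i], res$L[i])
    tr <- shell_trajectory(h$shape, h$am, grid)
    r2 <- summary(lm(LVV_ml ~ I(PMW_cm^3), data = tr))$r.squared
    expect_equal(res$linearity_r2[i], r2, tolerance = 1e-9)
  }
})

test_that("a modest cohort reproduces the large-cohort summary within MC error", {
  big <- agreement_stats(run_experiment(sampling_plan(n = 2000, seed = 11),
                                        linearity = FALSE))
  small <- agreement_stats(run_experiment(sampling_plan(n = 100, seed = 99),
                                          linearity = FALSE))
  expect_equal(small$bias, big$bias, tolerance = 0.5)
  expect_equal(small$slope, big$slope, tolerance = 0.05)
  expect_gt(small$r_squared, 0.98)
})

test_that("figure tables are deterministic and complete", {
  res <- run_experiment(small_plan(n = 50))
  d1 <- withr::local_tempdir()
  files <- export_figures_data(res, d1)
  scatter <- read.csv(files[["scatter"]])
  expect_equal(nrow(scatter), 50)
  traj <- read.csv(files[["trajectories"]])
  expect_equal(length(unique(traj$heart_id)), 10)
  expect_setequal(unique(traj$state), c("", "AM", "ES", "ED"))
  # per-trajectory collinearity
  for (id in unique(traj$heart_id)) {
    t1 <- traj[traj$heart_id == id, ]
    expect_gt(summary(lm(LVV_ml ~ pmw3_cm3, data = t1))$r.squared, 0.99)
  }
  # second export is byte-identical
  d2 <- withr::local_tempdir()
  files2 <- export_figures_data(res, d2)
  expect_identical(readLines(files[["trajectories"]]),
                   readLines(files2[["trajectories"]]))
  expect_identical(readLines(files[["scatter"]]), readLines(files2[["scatter"]]))
})

test_that("thin-walled spherical hearts are estimated better than thick-walled ones", {
  base <- list(lvid_am = c(4, 4), k = c(1, 1), L = c(0, 0),
               lambda_es = c(1.1, 1.1), lambda_ed = c(1.3, 1.3))
  thin <- do.call(sampling_plan, c(base, list(n = 1, seed = 1, h_am = c(1.0, 1.0))))
  thick <- do.call(sampling_plan, c(base, list(n = 1, seed = 1, h_am = c(1.9, 1.9))))
  e_thin <- abs(run_experiment(thin, linearity = FALSE)$rel_err)
  e_thick <- abs(run_experiment(thick, linearity = FALSE)$rel_err)
  expect_lt(e_thin, e_thick)
})
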