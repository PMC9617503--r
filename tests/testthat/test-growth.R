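test_that("threshold scaling reproduces the published 7-month bounds", {
  th7 <- scale_thresholds(months = 7)
  expect_equal(th7$bounds, c(0.017, 0.052))
  expect_equal(scale_thresholds(months = 12)$bounds, c(0.030, 0.089))
  # pre-rounding values are the plain proportions
  expect_equal(c(0.030, 0.089) * 7 / 12, c(0.0175, 0.0519167),
               tolerance = 1e-6)
})

test_that("growth classification honours both schemes' boundary conventions", {
  # seven-month scheme: coordinated is [0.017, 0.052)
  expect_equal(as.character(classify_growth(
    c(0.016, 0.017, 0.051, 0.052), scheme = "seven_month")),
    c("decelerated", "coordinated", "coordinated", "accelerated"))
  # annual scheme: (0, 0.030], (0.030, 0.089], > 0.089
  expect_equal(as.character(classify_growth(
    c(-0.01, 0, 0.030, 0.031, 0.089, 0.090), scheme = "annual")),
    c("shortening", "shortening", "no_growth", "coordinated", "coordinated",
      "accelerated"))
  # monotone: larger change never maps to a slower category
  x <- seq(-0.2, 0.3, by = 0.001)
  for (sch in c("seven_month", "annual")) {
    codes <- as.integer(classify_growth(x, scheme = sch))
    expect_true(all(diff(codes) >= 0))
  }
})

test_that("published annual growth table classifies and adds up as printed", {
  g <- reference_growth_table()
  counts <- table(classify_growth(g$dal_w1_w2[2:9], scheme = "annual"))
  expect_equal(unname(counts[["no_growth"]]), 2)
  expect_equal(unname(counts[["coordinated"]]), 5)
  expect_equal(unname(counts[["accelerated"]]), 1)
  expect_equal(g$dal_w1_s + g$dal_s_w2, g$dal_w1_w2, tolerance = 1e-9)
})

test_that("time-matched AL evaluation is phase-fair", {
  f <- make_fit(23.92, 0.019, -8.79)
  expect_equal(model_al_at(f, f$acrophase), 23.92 + 0.019, tolerance = 1e-9)
  flat <- fit_individual(c(-16, -4, -2, 0), rep(23.9, 4))
  expect_equal(model_al_at(flat, -3), 23.9)
  # two fits differing only in MESOR keep their offset at any t_ref
  f2 <- make_fit(23.97, 0.019, -8.79)
  for (tref in list(-4:1, 0, c(-12, 3))) {
    expect_equal(model_al_at(f2, tref) - model_al_at(f, tref), 0.05,
                 tolerance = 1e-9)
  }
})

test_that("interval deltas recover the simulated growth truth", {
  base <- simulation_truth(n_participants = 16,
                           seasons = c("W1", "S", "W2"), seed = 29)
  gt <- growth_truth(n_participants = 16, seed = 29)
  co <- generate_growth_cohort(gt, base)
  ols <- blup <- list()
  for (p in c("AL", "ChT")) {
    for (s in c("W1", "S", "W2")) {
      d <- co$measurements[co$measurements$parameter == p &
                             co$measurements$season == s, ]
      f <- fit_population(d, parameter = p, season = s)
      ols[[paste(p, s)]] <- f$individual
      blup[[paste(p, s)]] <- f$subject
    }
  }
  truth <- attr(co, "growth_truth")
  # unpooled fits score per-subject MESOR-scale deltas without shrinkage
  rec <- interval_deltas(unlist(ols, recursive = FALSE))
  w1s <- rec[rec$interval == "W1-S", ]
  m <- match(w1s$participant_id, truth$participant_id)
  # a few residual SEs of the AL series, plus headroom for the systematic
  # evening-window term that the injected phase shift adds to time-matched
  # evaluation
  tol <- 3 * 0.3 * 0.022 / sqrt(6)
  expect_lt(stats::median(abs(w1s$delta_al - truth$dal_w1_s[m])), tol)
  expect_gt(stats::cor(w1s$delta_al, truth$dal_w1_s[m]), 0.98)
  # shrunken fits give usable per-subject phase shifts
  rec_b <- interval_deltas(unlist(blup, recursive = FALSE))
  w1s_b <- rec_b[rec_b$interval == "W1-S", ]
  mb <- match(w1s_b$participant_id, truth$participant_id)
  expect_gt(stats::cor(w1s_b$al_phase_shift,
                       truth$al_phase_shift_w1_s[mb]), 0.4)
  # additivity of the recovered intervals
  wide <- tidyr::pivot_wider(rec[, c("participant_id", "interval", "delta_al")],
                             names_from = "interval", values_from = "delta_al")
  expect_equal(wide$`W1-S` + wide$`S-W2`, wide$`W1-W2`, tolerance = 1e-9)
})

test_that("identical fits across seasons give zero deltas", {
  f <- fits_to_table(list(make_fit(23.9, 0.02, -8.8),
                          make_fit(350, 2, 3.1)))
  f$scope <- "individual"
  f$participant_id <- "A"
  f$parameter <- c("AL", "ChT")
  f1 <- f; f1$season <- "W1"
  f2 <- f; f2$season <- "S"
  rec <- interval_deltas(rbind(f1, f2))
  expect_equal(rec$delta_al, 0, tolerance = 1e-12)
  expect_equal(rec$delta_cht, 0, tolerance = 1e-12)
  expect_equal(rec$al_phase_shift, 0, tolerance = 1e-12)
})

test_that("association statistics match their defining models", {
  # exactly collinear records
  rec <- tibble::tibble(delta_al = seq(0.0, 0.09, length.out = 8),
                        delta_cht = -200 * seq(0.0, 0.09, length.out = 8),
                        al_phase_shift = rep(0, 8))
  st <- suppressWarnings(association_stats(rec, scheme = "seven_month"))
  r1 <- st$regressions[st$regressions$predictor == "delta_cht", ]
  expect_equal(r1$r_squared, 1, tolerance = 1e-9)
  expect_equal(r1$slope, -1 / 200, tolerance = 1e-9)
  # independent predictor: R^2 near the null expectation 1/(n-1)
  set.seed(37)
  r2s <- replicate(300, {
    rec <- tibble::tibble(delta_al = rnorm(24, 0.05, 0.05),
                          delta_cht = rnorm(24, -10, 15),
                          al_phase_shift = rnorm(24, -1, 0.5))
    association_stats(rec)$regressions$r_squared[1]
  })
  expect_lt(abs(mean(r2s) - 1 / 23), 0.015)
  # regression recovers a known planted structure
  set.seed(41)
  dal <- rnorm(100, 0.05, 0.06)
  rec3 <- tibble::tibble(delta_al = dal,
                         delta_cht = -5 - 300 * dal + rnorm(100, 0, 5),
                         al_phase_shift = -1.6 + 12 * dal + rnorm(100, 0, 0.3))
  st3 <- association_stats(rec3)
  expect_gt(st3$regressions$r_squared[2], 0.7)
  expect_false(st3$degenerate_anova)
  expect_true(!is.null(st3$tukey))
})
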