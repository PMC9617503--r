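test_that("coeffs_to_polar places pure sine and cosine peaks correctly", {
  expect_equal(coeffs_to_polar(1, 0)[c("amplitude", "acrophase")],
               list(amplitude = 1, acrophase = 6))
  expect_equal(coeffs_to_polar(0, 1)[c("amplitude", "acrophase")],
               list(amplitude = 1, acrophase = 0))
  expect_equal(coeffs_to_polar(0, -1)[c("amplitude", "acrophase")],
               list(amplitude = 1, acrophase = 12))
  # reconstruction identity over random coefficients
  set.seed(42)
  for (i in 1:50) {
    bs <- rnorm(1); bc <- rnorm(1)
    p <- coeffs_to_polar(bs, bc)
    w <- 2 * pi / 24
    expect_equal(p$amplitude * cos(w * p$phi), bs, tolerance = 1e-12)
    expect_equal(p$amplitude * sin(w * p$phi), bc, tolerance = 1e-12)
    expect_gt(p$acrophase, -12); expect_lte(p$acrophase, 12)
  }
})

test_that("fit_individual recovers noise-free sinusoids exactly", {
  cases <- list(c(10, 2, -9), c(23.9, 0.02, -8.79), c(0.87, 3.155, 3.99),
                c(354, 2, 3.1))
  for (cs in cases) {
    s <- sinusoid_series(cs[1], cs[2], cs[3])
    f <- fit_individual(s$t, s$value)
    expect_equal(f$mesor, cs[1], tolerance = 1e-9)
    expect_equal(f$amplitude, cs[2], tolerance = 1e-9)
    expect_equal(f$acrophase, cs[3], tolerance = 1e-9)
    # peak identity and periodicity
    expect_equal(evaluate_sinusoid(f, f$acrophase), cs[1] + cs[2],
                 tolerance = 1e-9)
    expect_equal(evaluate_sinusoid(f, 3.3), evaluate_sinusoid(f, 3.3 + 24),
                 tolerance = 1e-12)
    expect_equal(evaluate_sinusoid(f, f$acrophase + 12), cs[1] - cs[2],
                 tolerance = 1e-9)
  }
})

test_that("flat series yields degenerate fit with conventional acrophase", {
  f <- fit_individual(c(-16, -4, -2, 0), rep(5.5, 4))
  expect_equal(f$mesor, 5.5)
  expect_equal(f$amplitude, 0, tolerance = 1e-12)
  expect_true(f$degenerate)
  expect_equal(f$acrophase, 6)
  expect_equal(evaluate_sinusoid(f, -3), 5.5, tolerance = 1e-12)
})

test_that("fit_individual rejects underdetermined designs", {
  expect_error(fit_individual(c(0, 1, 2), c(1, 2, 3)), ">= 4 observations")
  expect_error(fit_individual(c(0, 24, 48, 72), c(1, 2, 3, 4)),
               "rank-deficient")
  expect_error(fit_individual(c(-4, -4, 20, 20), c(1, 2, 3, 4)),
               "rank-deficient")
})

test_that("fit_individual is equivariant under time and value shifts", {
  set.seed(7)
  t <- c(-16, -13, -4, -3, -2, -1, 0, 1)
  for (i in 1:20) {
    y <- 10 + 2 * sin(2 * pi / 24 * (t + 4)) + rnorm(8, 0, 0.3)
    f0 <- fit_individual(t, y)
    delta <- runif(1, -12, 12)
    f1 <- fit_individual(t + delta, y)
    expect_equal(f1$mesor, f0$mesor, tolerance = 1e-9)
    expect_equal(f1$amplitude, f0$amplitude, tolerance = 1e-9)
    expect_equal(wrap_hours(f1$acrophase - (f0$acrophase + delta)), 0,
                 tolerance = 1e-9)
    cshift <- rnorm(1)
    f2 <- fit_individual(t, y + cshift)
    expect_equal(f2$mesor, f0$mesor + cshift, tolerance = 1e-9)
    expect_equal(f2$amplitude, f0$amplitude, tolerance = 1e-9)
    expect_equal(f2$acrophase, f0$acrophase, tolerance = 1e-9)
  }
})

test_that("individual fit matches the dense grid-search RSS minimizer", {
  set.seed(11)
  t <- c(-16, -13, -4, -3, -2, -1, 0, 1)
  for (i in 1:10) {
    truth <- c(m = runif(1, 5, 25), a = runif(1, 0.5, 3),
               acro = runif(1, -11.9, 11.9))
    y <- truth["m"] + truth["a"] * sin(2 * pi / 24 * (t + 6 - truth["acro"])) +
      rnorm(8, 0, 0.3)
    f <- fit_individual(t, y)
    best <- grid_search_cosinor(
      t, y,
      m_grid = seq(f$mesor - 0.5, f$mesor + 0.5, by = 0.02),
      a_grid = seq(max(0, f$amplitude - 0.5), f$amplitude + 0.5, by = 0.02))
    # the closed-form fit can never do worse than any lattice point
    expect_lte(rss_of_fit(f, t, y), best$rss + 1e-9)
    # and the best lattice point sits within one grid step of the fit
    # best lattice point within ~1.5 grid steps of the continuous optimum
    expect_lt(abs(best$mesor - f$mesor), 0.031)
    expect_lt(abs(best$amplitude - f$amplitude), 0.031)
    expect_lt(abs(wrap_hours(best$acrophase - f$acrophase)), 0.076)
  }
})

test_that("population fit equals the individual fit for a single subject", {
  s <- sinusoid_series(13.4, 2.8, -10.1)
  d <- tibble::tibble(participant_id = "A", t_rel = s$t,
                      value = s$value + c(0.1, -0.1, 0.2, 0, -0.2, 0.1, 0, -0.1))
  pf <- fit_population(d)
  f <- fit_individual(d$t_rel, d$value)
  expect_equal(pf$population$mesor, f$mesor, tolerance = 1e-12)
  expect_equal(pf$population$amplitude, f$amplitude, tolerance = 1e-12)
  expect_equal(pf$population$scope, "population")
})

test_that("population fit on a zero-noise zero-RE cohort returns truth exactly", {
  rh <- default_rhythm_truth("W1")
  rh[, c("sd_mesor", "sd_amplitude", "sd_acrophase", "sd_resid")] <- 0
  tr <- simulation_truth(n_participants = 4, seasons = "W1", rhythm = rh,
                         hst_sd = 0, seed = 5)
  co <- generate_cohort(tr)
  for (p in c("AL", "ChT")) {
    d <- co$measurements[co$measurements$parameter == p, ]
    pf <- fit_population(d, parameter = p, season = "W1")
    truth <- rh[rh$parameter == p, ]
    expect_equal(pf$population$mesor, truth$mesor, tolerance = 1e-8)
    expect_equal(pf$population$amplitude, truth$amplitude, tolerance = 1e-8)
    expect_equal(pf$population$acrophase, truth$acrophase, tolerance = 1e-6)
  }
})

test_that("population fit on a cohort cloned from one subject equals that subject", {
  s <- sinusoid_series(16.4, 0.055, -9.0)
  y <- s$value + c(0.01, -0.02, 0.015, 0, -0.01, 0.02, -0.015, 0.01)
  d <- dplyr::bind_rows(lapply(c("A", "B", "C"), function(id) {
    tibble::tibble(participant_id = id, t_rel = s$t, value = y)
  }))
  pf <- fit_population(d)
  f <- fit_individual(s$t, y)
  expect_equal(pf$population$mesor, f$mesor, tolerance = 1e-6)
  expect_equal(pf$population$amplitude, f$amplitude, tolerance = 1e-6)
  expect_equal(pf$population$acrophase, f$acrophase, tolerance = 1e-5)
})

test_that("bootstrap CIs cover the point estimate and are seeded", {
  tr <- simulation_truth(n_participants = 12, seasons = "W1", seed = 3)
  co <- generate_cohort(tr)
  d <- co$measurements[co$measurements$parameter == "IOP", ]
  pf1 <- fit_population(d, n_boot = 50, seed = 9)
  pf2 <- fit_population(d, n_boot = 50, seed = 9)
  expect_equal(pf1$population$ci, pf2$population$ci)
  ci <- pf1$population$ci
  expect_lt(ci[1, 1], pf1$population$mesor)
  expect_gt(ci[2, 1], pf1$population$mesor)
})

test_that("diurnal variation test detects rhythm and respects the block design", {
  tr <- simulation_truth(n_participants = 10, seasons = "W1", seed = 21)
  co <- generate_cohort(tr)
  d <- co$measurements[co$measurements$parameter == "VCD", ]
  r <- diurnal_variation_test(d)
  expect_gt(r$statistic, 0)
  expect_equal(r$df, c(7, 63))
  expect_lt(r$p_value, 0.001)
  # permutation p agrees with the analytic p on a null dataset
  set.seed(2)
  null_d <- d
  null_d$value <- rep(rnorm(10), each = 8) + rnorm(80, 0, 1)
  ra <- diurnal_variation_test(null_d, n_perm = 499, seed = 4)
  expect_lt(abs(ra$p_value - ra$p_perm), 0.12)
  expect_error(diurnal_variation_test(d[d$participant_id == "P01", ]),
               ">= 2 participants")
})

test_that("normalizing to the MESOR zeroes the level but not the rhythm", {
  s <- sinusoid_series(23.9, 0.02, -8.8)
  y <- s$value + c(0.005, -0.003, 0.002, 0, -0.004, 0.003, -0.002, 0.001)
  f <- fit_individual(s$t, y)
  z <- normalize_to_mesor(y, f)
  fz <- fit_individual(s$t, z)
  expect_equal(fz$mesor, 0, tolerance = 1e-10)
  expect_equal(fz$amplitude, f$amplitude, tolerance = 1e-10)
  expect_equal(fz$acrophase, f$acrophase, tolerance = 1e-10)
  expect_equal(normalize_to_mesor(rep(3, 4), fit_individual(
    c(-16, -4, -2, 0), rep(3, 4))), rep(0, 4))
})

test_that("fits tables round-trip through table_to_fits", {
  f <- make_fit(0.87, 3.155, 3.99, log_scale = TRUE)
  tab <- fits_to_table(f)
  back <- table_to_fits(tab)[[1]]
  expect_equal(back$mesor, f$mesor)
  expect_equal(back$acrophase, f$acrophase)
  expect_true(back$log_scale)
})
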