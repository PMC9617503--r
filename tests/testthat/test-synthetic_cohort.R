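test_that("noise-free zero-RE cohorts lie exactly on the population sinusoid", {
  rh <- default_rhythm_truth("W1")
  rh[, c("sd_mesor", "sd_amplitude", "sd_acrophase", "sd_resid")] <- 0
  tr <- simulation_truth(n_participants = 3, seasons = "W1", rhythm = rh,
                         hst_sd = 0, seed = 1)
  co <- generate_cohort(tr)
  m <- co$measurements
  for (p in unique(m$parameter)) {
    d <- m[m$parameter == p, ]
    truth <- rh[rh$parameter == p, ]
    mu <- truth$mesor + truth$amplitude *
      sin(2 * pi / 24 * (d$t_rel + 6 - truth$acrophase))
    if (p == "MEL") mu <- exp(mu)
    expect_equal(d$value, mu, tolerance = 1e-12)
  }
})

test_that("generation is deterministic under a fixed seed", {
  tr <- simulation_truth(n_participants = 6, seasons = c("W1", "S"), seed = 99)
  c1 <- generate_cohort(tr)
  c2 <- generate_cohort(tr)
  expect_identical(c1$measurements, c2$measurements)
  expect_identical(c1$participants, c2$participants)
  c3 <- generate_cohort(simulation_truth(n_participants = 6,
                                         seasons = c("W1", "S"), seed = 100))
  expect_false(identical(c1$measurements$value, c3$measurements$value))
})

test_that("generated cohorts respect the design and invariants", {
  tr <- simulation_truth(n_participants = 8, seasons = c("W1", "S"), seed = 2)
  co <- generate_cohort(tr)
  m <- co$measurements
  # melatonin strictly positive and sampled at 7 epochs (no midday sample)
  expect_true(all(m$value[m$parameter == "MEL"] > 0))
  mel_epochs <- unique(m$epoch_label[m$parameter == "MEL"])
  expect_false("HWT+4" %in% mel_epochs)
  expect_length(mel_epochs, 7)
  # other parameters at all 8 epochs, both seasons
  al <- m[m$parameter == "AL", ]
  expect_equal(nrow(al), 8 * 8 * 2)
  # subject truth emitted alongside the data
  truth <- cohort_truth(co)
  expect_true(all(c("participant_id", "m_i", "a_i", "acro_i") %in%
                    names(truth)))
  expect_true(all(truth$a_i >= 0))
  expect_true(all(truth$acro_i > -12 & truth$acro_i <= 12))
  # random effects shared across seasons: subject deviation identical
  w <- truth[truth$parameter == "AL" & truth$season == "W1", ]
  s <- truth[truth$parameter == "AL" & truth$season == "S", ]
  pop <- tr$rhythm
  dev_w <- w$m_i - pop$mesor[pop$parameter == "AL" & pop$season == "W1"]
  dev_s <- s$m_i[match(w$participant_id, s$participant_id)] -
    pop$mesor[pop$parameter == "AL" & pop$season == "S"]
  expect_equal(dev_w, dev_s, tolerance = 1e-12)
})

test_that("simulation_truth rejects invalid configurations", {
  expect_error(simulation_truth(seasons = character(0)))
  expect_error(simulation_truth(n_participants = 1), "random effects")
  rh <- default_rhythm_truth("W1")
  rh$amplitude[1] <- -1
  expect_error(simulation_truth(rhythm = rh, seasons = "W1"))
})

test_that("growth cohorts carry additive per-participant interval truth", {
  gt <- growth_truth(n_participants = 12, seed = 7)
  expect_equal(gt$table$dal_w1_s + gt$table$dal_s_w2, gt$table$dal_w1_w2,
               tolerance = 1e-12)
  base <- simulation_truth(n_participants = 12, seasons = c("W1", "S", "W2"),
                           seed = 7)
  co <- generate_growth_cohort(gt, base)
  truth <- cohort_truth(co)
  gtab <- attr(co, "growth_truth")
  # AL MESOR truth shifts by exactly the drawn per-participant deltas
  # (population AL seasonal change is neutralised in growth cohorts)
  al <- truth[truth$parameter == "AL", ]
  w1 <- al[al$season == "W1", ]; s <- al[al$season == "S", ]
  w2 <- al[al$season == "W2", ]
  m <- match(w1$participant_id, s$participant_id)
  k <- match(w1$participant_id, gtab$participant_id)
  expect_equal(s$m_i[m] - w1$m_i, gtab$dal_w1_s[k], tolerance = 1e-12)
  m2 <- match(w1$participant_id, w2$participant_id)
  expect_equal(w2$m_i[m2] - w1$m_i, gtab$dal_w1_w2[k], tolerance = 1e-12)
  expect_error(generate_growth_cohort(gt, simulation_truth(
    n_participants = 12, seasons = "W1", seed = 1)), "W1 and S")
})

test_that("a zero-slope growth structure yields near-zero association R2", {
  set.seed(43)
  r2s <- replicate(60, {
    gt <- growth_truth(n_participants = 24, cht_slope = 0, cht_noise_sd = 15,
                       seed = sample.int(1e6, 1))
    tab <- gt$table
    summary(stats::lm(tab$dal_w1_s ~ tab$dcht_w1_s))$r.squared
  })
  expect_lt(abs(mean(r2s) - 1 / 23), 0.03)
})

test_that("noise_sd_for_r2 inverts the population R2 formula", {
  sd_e <- noise_sd_for_r2(12, 0.06, 0.81)
  b2x2 <- (12 * 0.06)^2
  expect_equal(b2x2 / (b2x2 + sd_e^2), 0.81, tolerance = 1e-12)
})
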