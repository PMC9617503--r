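#' Default population rhythm truth for the simulator
#'
#' Builds the per-parameter, per-season truth table used by
#' [generate_cohort()]: population MESOR, amplitude and acrophase taken
#' from the bundled reference estimates; residual SDs set to a fixed
#' fraction of the amplitude (the source study prints no variance
#' components, so this is the package's own calibration; see the methods
#' vignette); and between-subject SDs calibrated so that the sampling
#' variance of a population estimate at the reference cohort size (24)
#' matches the reference 95% CIs. Each CI reflects both between-subject
#' spread and residual-driven estimation noise, so the residual
#' contribution (per-subject OLS variance of the MESOR, amplitude and
#' acrophase over the epoch design) is subtracted before scaling:
#' `sd_b = sqrt(max(0, 24 * (width/3.92)^2 - v_resid))`.
#'
#' A requested second winter (`W2`) copies the first-winter values: the
#' null hypothesis of no annual change, which [generate_growth_cohort()]
#' then perturbs per participant.
#'
#' @param seasons Subset of `c("W1", "S", "W2")`.
#' @param residual_frac Residual SD as a fraction of the amplitude.
#' @return Tibble with columns `parameter`, `season`, `mesor`, `amplitude`,
#'   `acrophase`, `sd_mesor`, `sd_amplitude`, `sd_acrophase`, `sd_resid`.
#' @export
default_rhythm_truth <- function(seasons = c("W1", "S"),
                                 residual_frac = 0.3) {
  stopifnot(length(seasons) >= 1, all(seasons %in% season_levels))
  est <- reference_rhythm_estimates()
  n_ref <- 24
  sigma <- residual_frac * est$amplitude
  # per-subject OLS estimation variances over the canonical epoch design
  # (16-h wake span; melatonin lacks the midday point). The clustered
  # design inflates these well beyond the uniform-sampling formulas, so
  # they are computed from the actual information matrix.
  design_factors <- function(t) {
    X <- cbind(1, sin(OMEGA * t), cos(OMEGA * t))
    V <- solve(crossprod(X))
    c(m = V[1, 1], coef = (V[2, 2] + V[3, 3]) / 2)
  }
  f8 <- design_factors(c(-15, -12, -4, -3, -2, -1, 0, 1))
  f7 <- design_factors(c(-15, -4, -3, -2, -1, 0, 1))
  fac_m <- ifelse(est$parameter == "MEL", f7["m"], f8["m"])
  fac_c <- ifelse(est$parameter == "MEL", f7["coef"], f8["coef"])
  v_mesor <- sigma^2 * fac_m
  v_amp <- sigma^2 * fac_c
  v_acro <- (24 / (2 * pi))^2 * sigma^2 * fac_c / est$amplitude^2
  pop_var <- function(lo, hi) {
    n_ref * ((hi - lo) / (2 * stats::qnorm(0.975)))^2
  }
  base <- tibble::tibble(
    parameter = est$parameter, season = est$season,
    mesor = est$mesor, amplitude = est$amplitude, acrophase = est$acrophase,
    sd_mesor = sqrt(pmax(0, pop_var(est$mesor_lo, est$mesor_hi) - v_mesor)),
    sd_amplitude = sqrt(pmax(0, pop_var(est$amplitude_lo, est$amplitude_hi)
                             - v_amp)),
    sd_acrophase = sqrt(pmax(0, pop_var(est$acrophase_lo, est$acrophase_hi)
                             - v_acro)),
    sd_resid = sigma)
  out <- dplyr::bind_rows(lapply(seasons, function(s) {
    src <- if (s == "W2") "W1" else s
    d <- base[base$season == src, ]
    d$season <- s
    d
  }))
  out
}

#' Specify the simulation truth for a synthetic cohort
#'
#' Bundles the cohort design (size, seasons, sleep-timing distribution)
#' with the per-parameter rhythm truth. Melatonin truth values are on the
#' natural-log pg/mL scale; generated melatonin observations are
#' exponentiated back to pg/mL.
#'
#' @param n_participants Cohort size.
#' @param seasons Seasons to simulate.
#' @param rhythm Truth table as from [default_rhythm_truth()] (may be
#'   edited, e.g. to inject a seasonal phase shift).
#' @param hst_mean,hst_sd Habitual sleep time distribution, decimal clock
#'   hours (mean near midnight by default, matching the reference cohort's
#'   anchor of about 00:08).
#' @param wake_span,wake_span_sd Waking-day length HWT to HST, hours.
#' @param seed Integer seed; all draws come from one stream.
#' @return List with class `simulation_truth`.
#' @export
simulation_truth <- function(n_participants = 24, seasons = c("W1", "S"),
                             rhythm = default_rhythm_truth(seasons),
                             hst_mean = 0.13, hst_sd = 1.0,
                             wake_span = 16, wake_span_sd = 0.75,
                             seed = 1) {
  stopifnot(n_participants >= 1, length(seasons) >= 1,
            all(seasons %in% season_levels),
            all(rhythm$amplitude >= 0),
            all(rhythm$sd_mesor >= 0), all(rhythm$sd_amplitude >= 0),
            all(rhythm$sd_acrophase >= 0), all(rhythm$sd_resid >= 0),
            all(rhythm$acrophase > -12), all(rhythm$acrophase <= 12),
            hst_sd >= 0, wake_span > 0, wake_span < 24)
  any_re <- any(rhythm[, c("sd_mesor", "sd_amplitude", "sd_acrophase")] > 0)
  if (n_participants < 2 && any_re) {
    stop("n_participants must be >= 2 when random effects are requested",
         call. = FALSE)
  }
  structure(list(n_participants = n_participants, seasons = seasons,
                 rhythm = tibble::as_tibble(rhythm), hst_mean = hst_mean,
                 hst_sd = hst_sd, wake_span = wake_span,
                 wake_span_sd = wake_span_sd, seed = seed),
            class = "simulation_truth")
}

# Draw participants and subject-level rhythm parameters. Random effects are
# drawn once per participant x parameter and shared across seasons (the same
# people are measured each season); season differences come from the
# population truth (or per-subject shifts added by the growth generator).
draw_subject_truth <- function(truth) {
  n <- truth$n_participants
  hst <- (stats::rnorm(n, truth$hst_mean, truth$hst_sd)) %% 24
  span <- pmin(20, pmax(12, stats::rnorm(n, truth$wake_span,
                                         truth$wake_span_sd)))
  hwt <- (hst - span) %% 24
  ids <- sprintf("P%02d", seq_len(n))
  participants <- participant_table(
    id = ids, hst_clock = format_clock_frac(hst),
    hwt_clock = format_clock_frac(hwt))

  params <- unique(truth$rhythm$parameter)
  re <- expand.grid(participant_id = ids, parameter = params,
                    stringsAsFactors = FALSE)
  first_season <- truth$seasons[1]
  r1 <- truth$rhythm[truth$rhythm$season == first_season, ]
  sd_of <- function(p, col) r1[[col]][match(p, r1$parameter)]
  re$re_mesor <- stats::rnorm(nrow(re), 0, sd_of(re$parameter, "sd_mesor"))
  # amplitude effects are multiplicative lognormal (moment-matched to the
  # stated mean and SD): a positive scale parameter with additive normal
  # effects truncated at zero would hand a noticeable fraction of subjects
  # a near-zero amplitude and hence an unidentifiable phase, which real
  # diurnal biometry does not show
  cv <- sd_of(re$parameter, "sd_amplitude") /
    pmax(r1$amplitude[match(re$parameter, r1$parameter)], 1e-12)
  s2 <- log(1 + cv^2)
  re$re_amp_factor <- stats::rlnorm(nrow(re), -s2 / 2, sqrt(s2))
  re$re_acrophase <- stats::rnorm(nrow(re), 0,
                                  sd_of(re$parameter, "sd_acrophase"))

  subject <- merge(expand.grid(participant_id = ids, parameter = params,
                               season = truth$seasons,
                               stringsAsFactors = FALSE), re,
                   by = c("participant_id", "parameter"))
  pop <- truth$rhythm
  key <- match(paste(subject$parameter, subject$season),
               paste(pop$parameter, pop$season))
  subject$m_i <- pop$mesor[key] + subject$re_mesor
  subject$a_i <- pop$amplitude[key] * subject$re_amp_factor
  subject$acro_i <- wrap_hours(pop$acrophase[key] + subject$re_acrophase)
  subject$sd_resid <- pop$sd_resid[key]
  list(participants = participants, subject = tibble::as_tibble(subject))
}

# sub-minute clock rendering for internal use (keeps HST draws near-exact);
# minutes floored at 3 decimals so they never print as 60
format_clock_frac <- function(hours) {
  h <- hours %% 24
  mins <- floor((h - floor(h)) * 60 * 1000) / 1000
  sprintf("%02d:%06.3f", floor(h), mins)
}

emit_measurements <- function(participants, subject, seasons) {
  mel_epochs <- setdiff(epoch_labels, "HWT+4")  # no midday melatonin sample
  rows <- list()
  for (i in seq_len(nrow(participants))) {
    id <- participants$id[i]
    t_all <- epoch_time(epoch_labels, participants$hwt_h[i],
                        participants$hst_h[i])
    names(t_all) <- epoch_labels
    sub <- subject[subject$participant_id == id, ]
    for (j in seq_len(nrow(sub))) {
      labs <- if (sub$parameter[j] == "MEL") mel_epochs else epoch_labels
      tt <- t_all[labs]
      mu <- sub$m_i[j] +
        sub$a_i[j] * sin(OMEGA * (tt + 6 - sub$acro_i[j]))
      val <- mu + stats::rnorm(length(tt), 0, sub$sd_resid[j])
      if (sub$parameter[j] == "MEL") val <- exp(val)
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant_id = id, season = sub$season[j], epoch_label = labs,
        t_rel = unname(tt), parameter = sub$parameter[j], value = unname(val))
    }
  }
  dplyr::bind_rows(rows)
}

#' Generate a synthetic cohort
#'
#' Simulates the chronotype-anchored repeated-measures design: each
#' participant gets a habitual sleep/wake time, eight epochs per day
#' (`HWT+1`, `HWT+4`, `HST-4` ... `HST+1`; melatonin skips the midday
#' epoch), and per-parameter sinusoidal values
#' `m_i + a_i sin(2 pi (t + 6 - acro_i)/24) + noise`, with subject-level
#' MESOR and acrophase drawn from independent normals around the
#' population truth (acrophase wrapped), amplitude from a moment-matched
#' multiplicative lognormal (strictly positive), and all subject effects
#' shared across seasons. Melatonin is generated on the natural-log scale
#' and exponentiated.
#'
#' The per-subject true parameters are attached as attribute `"truth"` so
#' downstream estimates can be scored against them (see [cohort_truth()]).
#'
#' @param truth A [simulation_truth()].
#' @return A validated [cohort_table()] with a `"truth"` attribute.
#' @export
generate_cohort <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  set.seed(truth$seed)
  st <- draw_subject_truth(truth)
  m <- emit_measurements(st$participants, st$subject, truth$seasons)
  cohort <- cohort_table(st$participants, m)
  attr(cohort, "truth") <- st$subject
  cohort
}

#' Subject-level simulation truth attached to a synthetic cohort
#'
#' @param cohort A cohort from [generate_cohort()] or
#'   [generate_growth_cohort()].
#' @return Tibble of per-participant true rhythm parameters (and, for
#'   growth cohorts, the per-participant growth truth as attribute
#'   `"growth_truth"` on the cohort).
#' @export
cohort_truth <- function(cohort) attr(cohort, "truth")

#' Specify per-participant growth truth
#'
#' Defines the distribution of true winter-to-summer axial-length change
#' and its links to choroidal-thickness change and AL phase shift via
#' linear regression structures (`y = intercept + slope * dAL + noise`).
#' Noise SDs can be set directly or via [noise_sd_for_r2()] to hit a
#' target population R-squared. Interval changes are additive by
#' construction: `dAL(W1-S) + dAL(S-W2) = dAL(W1-W2)` exactly.
#'
#' @param n_participants Cohort size.
#' @param dal_mean,dal_sd Winter-to-summer AL change distribution (mm).
#' @param dal_s_w2_mean,dal_s_w2_sd Summer-to-second-winter AL change (mm).
#' @param phase_slope,phase_intercept,phase_noise_sd AL phase shift (h) as
#'   a linear function of W1-S dAL; defaults centre the shift near -1 h
#'   with a strong positive slope (smaller or negative growth goes with a
#'   larger phase advance).
#' @param cht_slope,cht_intercept,cht_noise_sd ChT MESOR change (um) as a
#'   linear function of W1-S dAL; the default negative slope encodes
#'   choroidal thickening in slow-growth eyes.
#' @param seed Integer seed.
#' @return List with class `growth_truth` holding the per-participant
#'   truth tibble (`table`) and the structure parameters.
#' @export
growth_truth <- function(n_participants = 24,
                         dal_mean = 0.05, dal_sd = 0.06,
                         dal_s_w2_mean = 0.002, dal_s_w2_sd = 0.03,
                         phase_slope = 12, phase_intercept = -1 - 12 * 0.05,
                         phase_noise_sd = noise_sd_for_r2(12, 0.06, 0.81),
                         cht_slope = -300, cht_intercept = -11 + 300 * 0.05,
                         cht_noise_sd = noise_sd_for_r2(-300, 0.06, 0.54),
                         seed = 1) {
  set.seed(seed)
  dal <- stats::rnorm(n_participants, dal_mean, dal_sd)
  dal2 <- stats::rnorm(n_participants, dal_s_w2_mean, dal_s_w2_sd)
  shift <- phase_intercept + phase_slope * dal +
    stats::rnorm(n_participants, 0, phase_noise_sd)
  dcht <- cht_intercept + cht_slope * dal +
    stats::rnorm(n_participants, 0, cht_noise_sd)
  tab <- tibble::tibble(
    participant_id = sprintf("P%02d", seq_len(n_participants)),
    dal_w1_s = dal, dal_s_w2 = dal2, dal_w1_w2 = dal + dal2,
    dcht_w1_s = dcht, al_phase_shift_w1_s = shift)
  structure(list(table = tab, phase_slope = phase_slope,
                 phase_noise_sd = phase_noise_sd, cht_slope = cht_slope,
                 cht_noise_sd = cht_noise_sd, seed = seed),
            class = "growth_truth")
}

#' Noise SD that yields a target regression R-squared
#'
#' For `y = a + b x + e` with `x ~ N(., sd_x)`, the population R-squared is
#' `b^2 sd_x^2 / (b^2 sd_x^2 + sd_e^2)`; this inverts it for `sd_e`.
#'
#' @param slope Regression slope `b`.
#' @param sd_x SD of the predictor.
#' @param r2 Target R-squared in `(0, 1]`.
#' @return Residual SD.
#' @export
noise_sd_for_r2 <- function(slope, sd_x, r2) {
  stopifnot(r2 > 0, r2 <= 1)
  abs(slope) * sd_x * sqrt(1 / r2 - 1)
}

#' Generate a synthetic cohort with per-participant seasonal AL growth
#'
#' Extends [generate_cohort()]: the per-participant axial-length MESOR is
#' shifted across seasons by the true interval changes in `growth`, the AL
#' acrophase is shifted winter-to-summer by the true phase shift, and the
#' ChT MESOR by the true choroidal change. So that those per-participant
#' deltas are the sole seasonal driver of AL and ChT, the base rhythm's
#' population AL and ChT rows for `S` and `W2` are first reset to their
#' `W1` values (the population-level seasonal change is then simply the
#' mean of the per-participant truth). Requires `W1` and `S` in the base
#' truth's seasons; `W2`, when present, receives the annual change.
#'
#' @param growth A [growth_truth()] with at least `n_participants` rows.
#' @param base A [simulation_truth()] whose seasons include `W1` and `S`.
#' @return A [cohort_table()] with attributes `"truth"` (subject rhythm
#'   truth) and `"growth_truth"` (the per-participant growth table used).
#' @export
generate_growth_cohort <- function(growth, base) {
  stopifnot(inherits(growth, "growth_truth"),
            inherits(base, "simulation_truth"))
  if (!all(c("W1", "S") %in% base$seasons)) {
    stop("base truth must include seasons W1 and S", call. = FALSE)
  }
  if (nrow(growth$table) < base$n_participants) {
    stop("growth truth has fewer participants than the base truth",
         call. = FALSE)
  }
  gt <- growth$table[seq_len(base$n_participants), ]

  # growth-relevant parameters carry no population seasonal change of
  # their own; all seasonal structure comes from the per-participant truth
  rh <- base$rhythm
  for (p in c("AL", "ChT")) {
    w1 <- rh[rh$parameter == p & rh$season == "W1", ]
    if (nrow(w1) == 1) {
      for (s in intersect(c("S", "W2"), rh$season)) {
        rh[rh$parameter == p & rh$season == s,
           setdiff(names(rh), c("parameter", "season"))] <-
          w1[, setdiff(names(rh), c("parameter", "season"))]
      }
    }
  }
  base$rhythm <- rh

  set.seed(base$seed)
  st <- draw_subject_truth(base)
  sub <- st$subject
  idx <- match(sub$participant_id, gt$participant_id)

  is_al <- sub$parameter == "AL"
  is_cht <- sub$parameter == "ChT"
  s_S <- sub$season == "S"; s_W2 <- sub$season == "W2"
  # anchor W1 at the subject draw; S and W2 move by the true deltas
  sub$m_i[is_al & s_S] <- sub$m_i[is_al & s_S] + gt$dal_w1_s[idx[is_al & s_S]]
  sub$m_i[is_al & s_W2] <- sub$m_i[is_al & s_W2] +
    gt$dal_w1_w2[idx[is_al & s_W2]]
  sub$acro_i[is_al & s_S] <- wrap_hours(
    sub$acro_i[is_al & s_S] + gt$al_phase_shift_w1_s[idx[is_al & s_S]])
  sub$m_i[is_cht & s_S] <- sub$m_i[is_cht & s_S] +
    gt$dcht_w1_s[idx[is_cht & s_S]]

  m <- emit_measurements(st$participants, sub, base$seasons)
  cohort <- cohort_table(st$participants, m)
  attr(cohort, "truth") <- sub
  attr(cohort, "growth_truth") <- gt
  cohort
}
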