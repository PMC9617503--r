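OMEGA <- 2 * pi / 24  # fixed 24-h angular frequency, rad/h

#' Convert linearized cosinor coefficients to amplitude and acrophase
#'
#' The fixed-period cosinor `y(t) = M + A sin(w (t + phi))`, `w = 2 pi/24`,
#' linearizes to `y(t) = M + bs sin(wt) + bc cos(wt)` with
#' `bs = A cos(w phi)`, `bc = A sin(w phi)`. The acrophase (time of the
#' fitted peak, hours after the time origin) is `6 - phi` wrapped into
#' `(-12, 12]`.
#'
#' @param beta_sin,beta_cos Coefficients of `sin(wt)` and `cos(wt)`.
#' @return List with `amplitude` (>= 0), `acrophase` in `(-12, 12]`, and
#'   the phase parameter `phi` in `[-6, 18)` such that `acrophase = 6 - phi`.
#' @examples
#' coeffs_to_polar(1, 0)   # amplitude 1, acrophase 6
#' coeffs_to_polar(0, 1)   # amplitude 1, acrophase 0
#' @export
coeffs_to_polar <- function(beta_sin, beta_cos) {
  amplitude <- sqrt(beta_sin^2 + beta_cos^2)
  phi <- atan2(beta_cos, beta_sin) / OMEGA   # in (-12, 12]
  acrophase <- wrap_hours(6 - phi)
  list(amplitude = amplitude, acrophase = acrophase, phi = 6 - acrophase)
}

new_cosinor_fit <- function(mesor, beta_sin, beta_cos, residual_sd, n_obs,
                            scope, parameter = NA_character_,
                            season = NA_character_,
                            participant_id = NA_character_,
                            log_scale = FALSE, degenerate_tol = 1e-12,
                            fallback = FALSE, estimator = "ols") {
  pol <- coeffs_to_polar(beta_sin, beta_cos)
  degenerate <- pol$amplitude < degenerate_tol
  if (degenerate) {
    # flat rhythm: acrophase is unidentifiable; report 6 h deterministically
    pol$acrophase <- 6
    pol$phi <- 0
  }
  structure(list(
    scope = scope, parameter = parameter, season = season,
    participant_id = participant_id,
    mesor = mesor, amplitude = pol$amplitude, acrophase = pol$acrophase,
    phi = pol$phi, beta_sin = beta_sin, beta_cos = beta_cos,
    residual_sd = residual_sd, n_obs = n_obs, log_scale = log_scale,
    degenerate = degenerate, fallback = fallback, estimator = estimator,
    ci = NULL
  ), class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "<cosinor_fit %s%s%s> MESOR %.4g, amplitude %.4g, acrophase %.3g h%s\n",
    x$scope,
    if (!is.na(x$parameter)) paste0(" ", x$parameter) else "",
    if (!is.na(x$season)) paste0(" ", x$season) else "",
    x$mesor, x$amplitude, x$acrophase,
    if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Evaluate a fitted 24-h sinusoid
#'
#' Returns `M + A sin(w (t + phi))`; for a log-scale melatonin fit the
#' value is on the natural-log pg/mL scale.
#'
#' @param fit A `cosinor_fit`.
#' @param t Hours relative to habitual sleep time (vector).
#' @return Fitted values.
#' @export
evaluate_sinusoid <- function(fit, t) {
  stopifnot(inherits(fit, "cosinor_fit"))
  fit$mesor + fit$amplitude * sin(OMEGA * (t + fit$phi))
}

#' Fit an individual fixed-period cosinor by least squares
#'
#' Ordinary least squares on the linear basis
#' `value ~ sin(wt) + cos(wt)` with `w = 2 pi / 24`; exactly equivalent to
#' nonlinear least squares in `(M, A, phi)` because the period is fixed.
#' Melatonin series must be fitted with `log_scale = TRUE`, which takes the
#' natural log of the values first.
#'
#' @param t Observation times, hours relative to habitual sleep time.
#' @param value Observed values (pg/mL for melatonin; see `log_scale`).
#' @param log_scale Fit on the natural-log scale (required for MEL).
#' @param parameter,season,participant_id Optional metadata carried on the fit.
#' @return A `cosinor_fit`.
#' @export
fit_individual <- function(t, value, log_scale = FALSE,
                           parameter = NA_character_, season = NA_character_,
                           participant_id = NA_character_) {
  keep <- is.finite(t) & is.finite(value)
  t <- t[keep]; value <- value[keep]
  if (length(t) < 4) {
    stop("need >= 4 observations to fit a 3-parameter cosinor", call. = FALSE)
  }
  if (length(unique(round((t %% 24) * 1e9))) < 3) {
    stop("rank-deficient design: need >= 3 distinct times mod 24",
         call. = FALSE)
  }
  if (log_scale) {
    if (any(value <= 0)) stop("log-scale fit requires positive values",
                              call. = FALSE)
    value <- log(value)
  }
  X <- cbind(1, sin(OMEGA * t), cos(OMEGA * t))
  co <- unname(stats::lm.fit(X, value)$coefficients)
  res <- value - X %*% c(co)
  df <- length(t) - 3
  rsd <- if (df > 0) sqrt(sum(res^2) / df) else 0
  new_cosinor_fit(co[1], co[2], co[3], rsd, length(t), "individual",
                  parameter, season, participant_id, log_scale)
}

#' Fit a population cosinor by a linear mixed model on the sin/cos basis
#'
#' Fits `value ~ sin(wt) + cos(wt)` with independent per-participant random
#' effects on intercept, sine and cosine coefficients (REML via
#' \pkg{lme4}). Fixed effects are transformed with [coeffs_to_polar()] to
#' the population MESOR, amplitude and acrophase. When the mixed model
#' cannot be fitted (non-convergence, or no residual variability), the
#' function falls back to the two-stage estimate — the mean of the
#' individual OLS coefficients — and flags the fit.
#'
#' @param data Data frame with columns `participant_id`, `t_rel`, `value`
#'   for a single parameter and season (e.g. a filtered
#'   `cohort_table$measurements`).
#' @param log_scale Fit on the natural-log scale (required for MEL).
#' @param parameter,season Optional metadata carried on the fits.
#' @param n_boot Number of nonparametric bootstrap resamples over
#'   participants for 95% confidence intervals; 0 skips CIs.
#' @param seed Seed for the bootstrap resampling.
#' @return List with `population` (a `cosinor_fit`), `individual` (list of
#'   per-participant OLS `cosinor_fit`s), and `subject` (per-participant
#'   fits from the mixed model's conditional modes, i.e. shrunken/BLUP
#'   estimates, tagged `estimator = "blup"`; identical to `individual`
#'   when the mixed model was not available). The shrunken fits are the
#'   appropriate per-individual estimates for downstream seasonal and
#'   growth contrasts, mirroring per-individual quantities derived from a
#'   hierarchical rhythm model rather than from unpooled series.
#' @export
fit_population <- function(data, log_scale = FALSE,
                           parameter = NA_character_, season = NA_character_,
                           n_boot = 0, seed = 1) {
  stopifnot(all(c("participant_id", "t_rel", "value") %in% names(data)))
  ids <- unique(data$participant_id)
  if (length(ids) < 1) stop("no participants in slice", call. = FALSE)

  indiv <- lapply(ids, function(id) {
    d <- data[data$participant_id == id, ]
    fit_individual(d$t_rel, d$value, log_scale = log_scale,
                   parameter = parameter, season = season,
                   participant_id = id)
  })
  names(indiv) <- ids

  if (length(ids) == 1) {
    pop <- indiv[[1]]
    pop$scope <- "population"
    return(list(population = pop, individual = indiv, subject = indiv))
  }

  lmm <- fit_population_lmm(data, log_scale, parameter, season, indiv)
  pop <- lmm$population
  subject <- if (is.null(lmm$subject)) indiv else lmm$subject

  if (n_boot > 0) {
    set.seed(seed)
    boots <- matrix(NA_real_, n_boot, 3,
                    dimnames = list(NULL, c("mesor", "amplitude", "acrophase")))
    for (b in seq_len(n_boot)) {
      take <- sample(ids, length(ids), replace = TRUE)
      # two-stage estimator within the bootstrap keeps resampling cheap and
      # respects the participant as the resampling unit
      cf <- vapply(take, function(id) {
        f <- indiv[[id]]
        c(f$mesor, f$beta_sin, f$beta_cos)
      }, numeric(3))
      mb <- rowMeans(cf)
      pol <- coeffs_to_polar(mb[2], mb[3])
      boots[b, ] <- c(mb[1], pol$amplitude, pol$acrophase)
    }
    # acrophase CI on the circle, centred at the point estimate
    boots[, "acrophase"] <- pop$acrophase +
      wrap_hours(boots[, "acrophase"] - pop$acrophase)
    pop$ci <- apply(boots, 2, stats::quantile, probs = c(0.025, 0.975),
                    names = FALSE)
  }
  list(population = pop, individual = indiv, subject = subject)
}

fit_population_lmm <- function(data, log_scale, parameter, season, indiv) {
  d <- data.frame(id = factor(data$participant_id),
                  s = sin(OMEGA * data$t_rel),
                  c = cos(OMEGA * data$t_rel),
                  y = if (log_scale) log(data$value) else data$value)
  two_stage <- function() {
    cf <- vapply(indiv, function(f) c(f$mesor, f$beta_sin, f$beta_cos),
                 numeric(3))
    mb <- rowMeans(cf)
    list(population = new_cosinor_fit(
      mb[1], mb[2], mb[3], NA_real_, nrow(d), "population", parameter,
      season, log_scale = log_scale, fallback = TRUE), subject = NULL)
  }
  fit <- tryCatch(
    withCallingHandlers(
      lme4::lmer(y ~ s + c + (1 | id) + (0 + s | id) + (0 + c | id),
                 data = d, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")),
      warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)
  if (is.null(fit)) return(two_stage())
  fe <- lme4::fixef(fit)
  pop <- new_cosinor_fit(fe[["(Intercept)"]], fe[["s"]], fe[["c"]],
                         stats::sigma(fit), nrow(d), "population", parameter,
                         season, log_scale = log_scale)
  # per-subject conditional-mode (shrunken) coefficients
  cm <- tryCatch(stats::coef(fit)$id, error = function(e) NULL)
  subject <- NULL
  if (!is.null(cm)) {
    subject <- lapply(rownames(cm), function(id) {
      f <- new_cosinor_fit(cm[id, "(Intercept)"], cm[id, "s"], cm[id, "c"],
                           stats::sigma(fit),
                           sum(data$participant_id == id), "individual",
                           parameter, season, id, log_scale = log_scale,
                           estimator = "blup")
      f
    })
    names(subject) <- rownames(cm)
    subject <- subject[names(indiv)]
  }
  list(population = pop, subject = subject)
}

#' Test for diurnal variation across epochs
#'
#' F test of the epoch factor in a subject-blocked two-way layout (subject
#' as random block, epoch as fixed factor), i.e. the classical
#' repeated-measures ANOVA that a linear mixed model with a subject random
#' intercept reduces to for this balanced design. Optionally adds a
#' permutation p-value obtained by shuffling epoch labels within subject.
#'
#' @param data Data frame with columns `participant_id`, `epoch_label`,
#'   `value` for one parameter and season.
#' @param log_scale Analyse natural-log values (use for MEL).
#' @param n_perm Number of within-subject label permutations for the
#'   permutation p-value; 0 skips it.
#' @param seed Seed for the permutations.
#' @return List with `statistic` (F), `df` (numerator, denominator),
#'   `p_value`, `p_perm` (or NA), `method`.
#' @export
diurnal_variation_test <- function(data, log_scale = FALSE, n_perm = 0,
                                   seed = 1) {
  stopifnot(all(c("participant_id", "epoch_label", "value") %in% names(data)))
  d <- data.frame(id = factor(data$participant_id),
                  epoch = factor(data$epoch_label),
                  y = if (log_scale) log(data$value) else data$value)
  if (nlevels(d$id) < 2) stop("need >= 2 participants", call. = FALSE)
  if (nlevels(d$epoch) < 3) stop("need >= 3 epochs", call. = FALSE)
  if (any(table(d$epoch) == 0)) {
    stop("an epoch level has no observations", call. = FALSE)
  }

  f_stat <- function(dd) {
    av <- stats::aov(y ~ epoch + Error(id), data = dd)
    tab <- summary(av)[["Error: Within"]][[1]]
    c(F = tab["epoch", "F value"],
      df1 = tab["epoch", "Df"], df2 = tab["Residuals", "Df"])
  }
  obs <- f_stat(d)
  p <- stats::pf(obs["F"], obs["df1"], obs["df2"], lower.tail = FALSE)

  p_perm <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    idx <- split(seq_len(nrow(d)), d$id)
    exceed <- 0L
    for (i in seq_len(n_perm)) {
      dp <- d
      for (rows in idx) dp$epoch[rows] <- dp$epoch[sample(rows)]
      if (f_stat(dp)["F"] >= obs["F"]) exceed <- exceed + 1L
    }
    p_perm <- (exceed + 1) / (n_perm + 1)
  }
  list(statistic = unname(obs["F"]),
       df = unname(c(obs["df1"], obs["df2"])),
       p_value = unname(p), p_perm = p_perm,
       method = "subject-blocked ANOVA (epoch fixed, subject random block)")
}

#' Centre a series on its fitted MESOR
#'
#' Subtracts the individual's fitted MESOR from each observation, the
#' normalisation used to overlay individuals when plotting group rhythms.
#' Units are preserved; re-fitting the normalised series leaves amplitude
#' and acrophase unchanged and sets MESOR to zero.
#'
#' @param value Observed values (on the fitting scale: pass log-melatonin
#'   if the fit is log-scale).
#' @param fit The individual's `cosinor_fit`.
#' @return Centred values.
#' @export
normalize_to_mesor <- function(value, fit) {
  stopifnot(inherits(fit, "cosinor_fit"))
  value - fit$mesor
}

#' Collect cosinor fits into a tidy table
#'
#' @param fits A list of `cosinor_fit` objects.
#' @return Tibble with one row per fit.
#' @export
fits_to_table <- function(fits) {
  if (inherits(fits, "cosinor_fit")) fits <- list(fits)
  purrr::map_dfr(fits, function(f) {
    tibble::tibble(
      scope = f$scope, parameter = f$parameter, season = f$season,
      participant_id = f$participant_id, mesor = f$mesor,
      amplitude = f$amplitude, acrophase = f$acrophase, phi = f$phi,
      beta_sin = f$beta_sin, beta_cos = f$beta_cos,
      residual_sd = f$residual_sd, n_obs = f$n_obs,
      log_scale = f$log_scale, degenerate = f$degenerate,
      fallback = f$fallback, estimator = f$estimator)
  })
}

# Restrict a tidy fits table to one per-individual estimate per
# participant, preferring the shrunken (blup) fits when both are present.
prefer_blup <- function(tab) {
  ind <- tab[tab$scope == "individual", ]
  if ("estimator" %in% names(ind) && any(ind$estimator == "blup")) {
    ind <- ind[ind$estimator == "blup", ]
  }
  ind
}

#' Rebuild cosinor fit objects from a tidy fits table
#'
#' Inverse of [fits_to_table()], used to resume a pipeline from its CSV
#' intermediates.
#'
#' @param tab A data frame as produced by [fits_to_table()].
#' @return List of `cosinor_fit` objects.
#' @export
table_to_fits <- function(tab) {
  if (!"estimator" %in% names(tab)) tab$estimator <- "ols"
  purrr::pmap(tab, function(scope, parameter, season, participant_id, mesor,
                            beta_sin, beta_cos, residual_sd, n_obs,
                            log_scale, estimator, ...) {
    new_cosinor_fit(mesor, beta_sin, beta_cos, residual_sd, n_obs, scope,
                    parameter, season, participant_id, log_scale,
                    estimator = estimator)
  })
}
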