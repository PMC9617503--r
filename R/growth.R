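#' Scale annual coordinated-growth thresholds to a shorter interval
#'
#' Coordinated axial growth in young adults is bracketed by annual
#' axial-length change bounds (default 0.030 and 0.089 mm over 12 months).
#' For an interval of `months` months the bounds are scaled by
#' `months / 12` and rounded to 3 decimals with exact halves rounded down,
#' the rule that reproduces the published 7-month bounds (0.017, 0.052).
#'
#' @param annual_bounds Length-2 increasing numeric, annual cut points (mm).
#' @param months Interval length in months, in `(0, 24]`.
#' @return List with class `growth_thresholds`: `scheme`
#'   (`"annual"` when `months == 12`, else `"seven_month"`-style scaled),
#'   `bounds`, `months`, `annual_bounds`.
#' @examples
#' scale_thresholds(months = 7)$bounds  # 0.017 0.052
#' @export
scale_thresholds <- function(annual_bounds = c(0.030, 0.089), months = 12) {
  stopifnot(length(annual_bounds) == 2, diff(annual_bounds) > 0,
            months > 0, months <= 24)
  round_half_down <- function(x, digits = 3) {
    s <- 10^digits
    ceiling(x * s - 0.5) / s
  }
  bounds <- round_half_down(annual_bounds * months / 12)
  structure(list(scheme = if (months == 12) "annual" else "scaled",
                 bounds = bounds, months = months,
                 annual_bounds = annual_bounds),
            class = "growth_thresholds")
}

#' Classify an interval axial-length change
#'
#' Two published schemes share the same cut points but different boundary
#' conventions:
#' \describe{
#'   \item{`seven_month`}{three categories on 7-month-scaled bounds
#'     (lo = 0.017, hi = 0.052): `decelerated` if `dAL < lo`, `coordinated`
#'     if `lo <= dAL < hi`, `accelerated` if `dAL >= hi`.}
#'   \item{`annual`}{four categories on the annual bounds (0.030, 0.089):
#'     `shortening` if `dAL <= 0`, `no_growth` if `0 < dAL <= 0.030`,
#'     `coordinated` if `0.030 < dAL <= 0.089`, `accelerated` above.}
#' }
#'
#' @param delta_al Axial-length change (mm), vectorised.
#' @param scheme `"seven_month"` or `"annual"`.
#' @param thresholds Optional `growth_thresholds`; defaults to
#'   `scale_thresholds(months = 7)` or `scale_thresholds(months = 12)`
#'   according to `scheme`.
#' @return Factor of categories (ordered slow to fast growth).
#' @examples
#' classify_growth(c(0.023, 0.052, 0.145), scheme = "annual")
#' @export
classify_growth <- function(delta_al,
                            scheme = c("seven_month", "annual"),
                            thresholds = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(thresholds)) {
    thresholds <- scale_thresholds(months = if (scheme == "annual") 12 else 7)
  }
  stopifnot(inherits(thresholds, "growth_thresholds"))
  lo <- thresholds$bounds[1]; hi <- thresholds$bounds[2]
  if (scheme == "seven_month") {
    out <- ifelse(delta_al < lo, "decelerated",
                  ifelse(delta_al < hi, "coordinated", "accelerated"))
    factor(out, levels = c("decelerated", "coordinated", "accelerated"))
  } else {
    out <- ifelse(delta_al <= 0, "shortening",
                  ifelse(delta_al <= lo, "no_growth",
                         ifelse(delta_al <= hi, "coordinated", "accelerated")))
    factor(out,
           levels = c("shortening", "no_growth", "coordinated", "accelerated"))
  }
}

#' Time-matched axial length from a fitted cosinor
#'
#' Evaluates the individual's fitted sinusoid at one or more reference
#' times (hours relative to habitual sleep time) and averages, so that
#' seasons measured at different clock times are compared at the same
#' phase of the diurnal cycle.
#'
#' @param fit `cosinor_fit` for AL.
#' @param t_ref Numeric vector of reference times; default the six evening
#'   epochs -4 ... +1.
#' @return Mean modelled AL (mm) over `t_ref`.
#' @export
model_al_at <- function(fit, t_ref = -4:1) {
  mean(evaluate_sinusoid(fit, t_ref))
}

#' Per-participant interval changes in AL, ChT and AL phase
#'
#' For each participant with AL fits in both seasons of an interval,
#' computes the time-matched axial-length change (difference of
#' [model_al_at()] values), the choroidal-thickness change as the ChT
#' MESOR difference, and the AL phase shift as the circular acrophase
#' difference (negative = advance). Intervals are `W1-S`, `S-W2` and
#' `W1-W2` according to the seasons present; the three are additive by
#' construction.
#'
#' @param fits Tidy table of individual fits ([fits_to_table()]) covering
#'   parameter `AL` (and optionally `ChT`) for two or three seasons.
#' @param t_ref Reference times passed to [model_al_at()].
#' @return Tibble with `participant_id`, `interval`, `delta_al`,
#'   `delta_cht`, `al_phase_shift`.
#' @export
interval_deltas <- function(fits, t_ref = -4:1) {
  tab <- if (is.data.frame(fits)) tibble::as_tibble(fits) else
    fits_to_table(fits)
  if (!"scope" %in% names(tab)) tab$scope <- "individual"
  tab <- prefer_blup(tab)
  al <- tab[tab$parameter == "AL", ]
  cht <- tab[tab$parameter == "ChT", ]
  if (nrow(al) == 0) stop("no individual AL fits supplied", call. = FALSE)

  eval_al <- function(row) {
    model_al_at(table_to_fits(row)[[1]], t_ref)
  }
  pairs <- list(c("W1", "S"), c("S", "W2"), c("W1", "W2"))
  out <- list()
  for (id in unique(al$participant_id)) {
    a <- al[al$participant_id == id, ]
    h <- cht[cht$participant_id == id, ]
    for (pr in pairs) {
      a1 <- a[a$season == pr[1], ]; a2 <- a[a$season == pr[2], ]
      if (nrow(a1) != 1 || nrow(a2) != 1) next
      h1 <- h[h$season == pr[1], ]; h2 <- h[h$season == pr[2], ]
      dcht <- if (nrow(h1) == 1 && nrow(h2) == 1) h2$mesor - h1$mesor else
        NA_real_
      out[[length(out) + 1]] <- tibble::tibble(
        participant_id = id, interval = paste(pr, collapse = "-"),
        delta_al = eval_al(a2) - eval_al(a1),
        delta_cht = dcht,
        al_phase_shift = circular_diff(a2$acrophase, a1$acrophase))
    }
  }
  if (!length(out)) {
    warning("no participant had AL fits in two seasons; empty result")
    return(tibble::tibble(participant_id = character(), interval = character(),
                          delta_al = numeric(), delta_cht = numeric(),
                          al_phase_shift = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Association statistics for interval growth records
#'
#' Simple linear regressions of the axial-length change on the
#' choroidal-thickness change and on the AL phase shift (slope, intercept,
#' R-squared, F, p), plus a one-way ANOVA of the AL change across growth
#' categories with Tukey HSD pairwise comparisons.
#'
#' @param records Tibble from [interval_deltas()] restricted to one
#'   interval, or any data frame with `delta_al`, `delta_cht`,
#'   `al_phase_shift`.
#' @param scheme Growth scheme for the categorisation (see
#'   [classify_growth()]).
#' @return List with `regressions` (tibble, one row per predictor),
#'   `anova` (F, df, p, or NULL when degenerate), `tukey` (matrix or
#'   NULL), `categories` (factor), `degenerate_anova` flag.
#' @export
association_stats <- function(records, scheme = "seven_month") {
  stopifnot(nrow(records) >= 4)
  reg_one <- function(x, label) {
    ok <- is.finite(x) & is.finite(records$delta_al)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0) {
      return(tibble::tibble(
        predictor = label, slope = NA_real_, intercept = NA_real_,
        r_squared = NA_real_, f = NA_real_, df1 = NA_real_, df2 = NA_real_,
        p = NA_real_, n = sum(ok)))
    }
    fit <- stats::lm(records$delta_al[ok] ~ x[ok])
    sm <- summary(fit)
    fv <- sm$fstatistic
    tibble::tibble(
      predictor = label, slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]), r_squared = sm$r.squared,
      f = unname(fv[1]), df1 = unname(fv[2]), df2 = unname(fv[3]),
      p = stats::pf(fv[1], fv[2], fv[3], lower.tail = FALSE), n = sum(ok))
  }
  regressions <- dplyr::bind_rows(
    reg_one(records$delta_cht, "delta_cht"),
    reg_one(records$al_phase_shift, "al_phase_shift"))

  cats <- classify_growth(records$delta_al, scheme = scheme)
  counts <- table(droplevels(cats))
  degenerate <- length(counts) < 2 || any(counts < 2)
  anova_res <- NULL; tukey <- NULL
  if (!degenerate) {
    d <- data.frame(y = records$delta_al, g = droplevels(cats))
    av <- stats::aov(y ~ g, data = d)
    tab <- summary(av)[[1]]
    anova_res <- list(f = tab["g", "F value"],
                      df = c(tab["g", "Df"], tab["Residuals", "Df"]),
                      p = tab["g", "Pr(>F)"])
    tukey <- stats::TukeyHSD(av)$g
  }
  list(regressions = regressions, anova = anova_res, tukey = tukey,
       categories = cats, degenerate_anova = degenerate)
}
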