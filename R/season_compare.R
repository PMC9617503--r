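#' Signed circular difference of two HST-relative times
#'
#' `a - b` on the 24-h circle, reported in `(-12, 12]`; a separation of
#' exactly 12 h maps to +12 by convention. Negative values are phase
#' advances of `a` relative to `b`.
#'
#' @param a,b Hours (any finite values).
#' @return Signed hours in `(-12, 12]`.
#' @examples
#' circular_diff(-9.81, -8.79)  # -1.02 (a 61-minute advance)
#' @export
circular_diff <- function(a, b) wrap_hours(a - b)

#' Phase relationship between two rhythms
#'
#' The signed circular acrophase separation of two fitted rhythms in the
#' same season, together with distances to the exactly in-phase (0 h) and
#' exactly antiphase (12 h) configurations. `antiphase_distance` and
#' `inphase_distance` always sum to 12.
#'
#' @param fit1,fit2 `cosinor_fit`s (or bare acrophases in hours).
#' @return List with `separation` in `(-12, 12]`, `inphase_distance` and
#'   `antiphase_distance` in `[0, 12]`.
#' @examples
#' phase_relation(3.10, -8.79)  # ChT vs AL in winter: near-exact antiphase
#' @export
phase_relation <- function(fit1, fit2) {
  a1 <- if (inherits(fit1, "cosinor_fit")) fit1$acrophase else fit1
  a2 <- if (inherits(fit2, "cosinor_fit")) fit2$acrophase else fit2
  sep <- circular_diff(a1, a2)
  list(separation = sep, inphase_distance = abs(sep),
       antiphase_distance = 12 - abs(sep))
}

#' Holm step-down adjustment of p-values
#'
#' Thin wrapper around `stats::p.adjust(method = "holm")`: sort ascending,
#' multiply the i-th smallest by `m - i + 1`, enforce monotonicity, cap at
#' one, restore input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
holm_adjust <- function(p) {
  stopifnot(is.numeric(p), all(is.na(p) | (p >= 0 & p <= 1)))
  stats::p.adjust(p, method = "holm")
}

paired_test <- function(diffs, shapiro_alpha = 0.05) {
  # paired t on the differences; signed-rank fallback when normality is
  # rejected; degenerate (all-zero or constant) differences get p = 1
  diffs <- diffs[is.finite(diffs)]
  n <- length(diffs)
  if (n < 3 || stats::sd(diffs) == 0) {
    return(list(p = if (n > 0 && all(diffs == 0)) 1 else NA_real_,
                method = "degenerate", degenerate = TRUE))
  }
  normal <- tryCatch(stats::shapiro.test(diffs)$p.value >= shapiro_alpha,
                     error = function(e) TRUE)
  if (normal) {
    list(p = stats::t.test(diffs)$p.value, method = "paired t",
         degenerate = FALSE)
  } else {
    nz <- diffs[diffs != 0]  # zeros dropped, standard signed-rank convention
    p <- if (length(nz) < 3) 1 else
      suppressWarnings(stats::wilcox.test(nz)$p.value)
    list(p = p, method = "wilcoxon signed-rank", degenerate = FALSE)
  }
}

#' Compare rhythm parameters between two seasons
#'
#' Pairs each participant's individual cosinor fits across two seasons and,
#' per measurement parameter, summarises the seasonal change in MESOR,
#' amplitude and acrophase (the latter differenced circularly; negative =
#' phase advance in the second season). Each quantity gets a paired test
#' (t, or signed-rank when normality is rejected) and a Holm adjustment
#' across parameters within the quantity.
#'
#' @param fits1,fits2 Lists of individual `cosinor_fit`s for the first and
#'   second season (e.g. the `individual` element of [fit_population()]),
#'   or tidy tables from [fits_to_table()].
#' @return Tibble with one row per parameter: `n_pairs`, `delta_mesor`,
#'   `delta_amplitude`, `delta_acrophase`, raw and Holm-adjusted p-values
#'   per quantity, and a `degenerate` flag.
#' @export
compare_seasons <- function(fits1, fits2) {
  t1 <- if (is.data.frame(fits1)) tibble::as_tibble(fits1) else
    fits_to_table(fits1)
  t2 <- if (is.data.frame(fits2)) tibble::as_tibble(fits2) else
    fits_to_table(fits2)
  if (!"scope" %in% names(t1)) t1$scope <- "individual"
  if (!"scope" %in% names(t2)) t2$scope <- "individual"
  t1 <- prefer_blup(t1); t2 <- prefer_blup(t2)
  keys <- c("participant_id", "parameter")
  joined <- dplyr::inner_join(t1, t2, by = keys, suffix = c("_1", "_2"))
  if (nrow(joined) == 0) stop("no paired participants", call. = FALSE)

  out <- joined |>
    dplyr::group_by(.data$parameter) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3) stop("need >= 3 paired participants for parameter ",
                            key$parameter, call. = FALSE)
      dm <- d$mesor_2 - d$mesor_1
      da <- d$amplitude_2 - d$amplitude_1
      dp <- circular_diff(d$acrophase_2, d$acrophase_1)
      tm <- paired_test(dm); ta <- paired_test(da); tp <- paired_test(dp)
      tibble::tibble(
        n_pairs = nrow(d),
        delta_mesor = mean(dm), delta_amplitude = mean(da),
        delta_acrophase = wrap_hours(mean(dp)),
        p_mesor = tm$p, p_amplitude = ta$p, p_acrophase = tp$p,
        method_mesor = tm$method, method_amplitude = ta$method,
        method_acrophase = tp$method,
        degenerate = tm$degenerate || ta$degenerate || tp$degenerate)
    }) |>
    dplyr::ungroup()

  out$p_mesor_adj <- holm_adjust(out$p_mesor)
  out$p_amplitude_adj <- holm_adjust(out$p_amplitude)
  out$p_acrophase_adj <- holm_adjust(out$p_acrophase)
  out
}

#' Seasonal acrophase shifts from population estimates
#'
#' Worked-example arithmetic on a table of population rhythm estimates:
#' the circular winter-to-summer acrophase change per parameter, in hours
#' and in whole minutes (negative = advance), plus both acrophases
#' rendered as standard clock times given an HST anchor.
#'
#' @param estimates Tibble as returned by [reference_rhythm_estimates()]
#'   (columns `parameter`, `season` in `{W1, S}`, `acrophase`).
#' @param hst_anchor HST clock anchor, decimal hours or `"HH:MM"`; default
#'   the melatonin-derived anchor of the bundled reference table.
#' @return Tibble with `parameter`, `acro_w1`, `acro_s`, `shift_h`,
#'   `shift_min`, `clock_w1`, `clock_s`.
#' @export
seasonal_shift_table <- function(estimates = reference_rhythm_estimates(),
                                 hst_anchor = reference_hst_anchor()) {
  if (is.character(hst_anchor)) hst_anchor <- parse_clock(hst_anchor)
  wide <- estimates |>
    dplyr::filter(.data$season %in% c("W1", "S")) |>
    dplyr::select("parameter", "season", "acrophase") |>
    tidyr::pivot_wider(names_from = "season", values_from = "acrophase")
  shift <- circular_diff(wide$S, wide$W1)
  tibble::tibble(
    parameter = wide$parameter, acro_w1 = wide$W1, acro_s = wide$S,
    shift_h = shift, shift_min = round(shift * 60),
    clock_w1 = to_clock_time(wide$W1, hst_anchor),
    clock_s = to_clock_time(wide$S, hst_anchor))
}
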