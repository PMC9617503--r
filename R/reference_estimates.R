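#' Published population rhythm estimates used as defaults and worked examples
#'
#' NLME population estimates of MESOR, amplitude and acrophase (hours
#' relative to habitual sleep time) for eight parameters in winter and the
#' following summer, from a chronotype-anchored cohort study of young
#' adults at latitude 60N (n = 24 measured in both seasons, 8 epochs per
#' day). MEL values are on the natural-log pg/mL scale; RT and ChT in
#' micrometres; other biometry in mm; IOP in mm Hg. 95% confidence bounds
#' accompany each estimate.
#'
#' These printed estimates serve two roles: defaults for the synthetic
#' cohort generator, and inputs to worked examples (clock-time conversion,
#' DLMO, seasonal-shift arithmetic).
#'
#' @return Tibble with columns `parameter`, `season` (`W1` winter, `S`
#'   summer), `mesor`, `mesor_lo`, `mesor_hi`, `amplitude`, `amplitude_lo`,
#'   `amplitude_hi`, `acrophase`, `acrophase_lo`, `acrophase_hi`.
#' @export
reference_rhythm_estimates <- function() {
  tibble::tribble(
    ~parameter, ~season, ~mesor, ~mesor_lo, ~mesor_hi,
    ~amplitude, ~amplitude_lo, ~amplitude_hi,
    ~acrophase, ~acrophase_lo, ~acrophase_hi,
    "MEL", "W1",  0.87,  0.66,  1.07, 3.155, 2.92, 3.39,   3.99,   3.62,  4.30,
    "MEL", "S",   1.04,  0.82,  1.25, 2.952, 2.71, 3.20,   3.14,   2.67,  3.54,
    "IOP", "W1", 13.36, 12.24, 14.47, 2.810, 2.38, 3.32, -10.10, -10.62, -9.57,
    "IOP", "S",  13.09, 11.89, 14.30, 2.760, 2.33, 3.29, -10.27, -10.80, -9.72,
    "ACD", "W1",  3.73,  3.62,  3.84, 0.019, 0.011, 0.028,  2.44,  1.82,  2.99,
    "ACD", "S",   3.74,  3.63,  3.84, 0.026, 0.019, 0.035,  1.64,  1.04,  2.19,
    "LT",  "W1",  3.55,  3.46,  3.65, 0.015, 0.010, 0.022,  2.64,  1.53,  3.51,
    "LT",  "S",   3.56,  3.47,  3.65, 0.013, 0.008, 0.021,  3.18,  1.98,  4.05,
    "VCD", "W1", 16.41, 15.85, 16.97, 0.055, 0.048, 0.063, -9.00, -9.43, -8.55,
    "VCD", "S",  16.44, 15.88, 17.00, 0.063, 0.053, 0.074, -9.53, -9.91, -9.15,
    "AL",  "W1", 23.92, 23.37, 24.47, 0.019, 0.015, 0.024, -8.79, -9.24, -8.34,
    "AL",  "S",  23.96, 23.41, 24.52, 0.022, 0.017, 0.028, -9.81, -10.24, -9.37,
    "RT",  "W1", 261,   256,   267,   2,     1,     3,     -9.47, -10.30, -8.60,
    "RT",  "S",  263,   257,   268,   2,     1,     2,    -11.32, -12.52, -9.97,
    "ChT", "W1", 354,   310,   397,   2,     1,     3,      3.10,   2.42,  3.66,
    "ChT", "S",  343,   302,   385,   4,     2,     7,      3.42,   2.96,  3.82
  )
}

#' Published acrophase clock times and seasonal changes
#'
#' The same acrophases as [reference_rhythm_estimates()] re-expressed in
#' standard clock time (the cohort's habitual sleep time fell at the same
#' clock time in both seasons), together with the printed winter-to-summer
#' change in minutes (negative = phase advance). The melatonin onset
#' (DLMO) row is a threshold crossing, not an acrophase, and is included
#' for comparison, as in the source table.
#'
#' Known internal inconsistencies of the printed table, preserved verbatim:
#' the LT row's clock times do not match the summer LT acrophase estimate,
#' and the DLMO change cell (-47 min) does not equal the difference of the
#' DLMO clock times (-63 min). Worked-example checks therefore exclude LT
#' and reproduce DLMO clock times rather than the change cell.
#'
#' @return Tibble with columns `parameter`, `clock_w1`, `clock_s`,
#'   `change_min`.
#' @export
reference_clock_times <- function() {
  tibble::tribble(
    ~parameter, ~clock_w1, ~clock_s, ~change_min,
    "ACD",  "02:34", "01:46",  -48,
    "LT",   "02:46", "03:02",   16,
    "ChT",  "03:14", "03:32",   18,
    "MEL",  "04:07", "03:16",  -51,
    "IOP",  "14:02", "13:51",  -11,
    "RT",   "14:40", "12:49", -111,
    "VCD",  "15:08", "14:35",  -33,
    "AL",   "15:20", "14:19",  -61,
    "DLMO", "22:20", "21:17",  -47
  )
}

#' Habitual-sleep-time anchor implied by the melatonin row
#'
#' The published clock-time table is generated from HST-relative
#' acrophases by a single HST anchor common to both seasons. The anchor is
#' recovered from the winter melatonin row: clock acrophase 04:07 minus
#' relative acrophase 3.99 h, i.e. about 00:07.6.
#'
#' @return HST anchor in decimal hours of standard clock time.
#' @export
reference_hst_anchor <- function() {
  est <- reference_rhythm_estimates()
  clk <- reference_clock_times()
  mel_rel <- est$acrophase[est$parameter == "MEL" & est$season == "W1"]
  mel_clock <- parse_clock(clk$clock_w1[clk$parameter == "MEL"])
  (mel_clock - mel_rel) %% 24
}

#' Published annual axial-length growth table
#'
#' Per-participant axial length at the first winter (W1) and its change
#' over the winter-to-summer (W1-S), summer-to-second-winter (S-W2) and
#' annual (W1-W2) intervals, with baseline spherical equivalent refraction
#' and its annual change, for the 10 participants measured in all three
#' seasons. Ordered by increasing annual change.
#'
#' @return Tibble with columns `participant`, `al_w1`, `dal_w1_s`,
#'   `dal_s_w2`, `dal_w1_w2`, `ser_w1`, `dser_w1_w2`.
#' @export
reference_growth_table <- function() {
  tibble::tribble(
    ~participant, ~al_w1, ~dal_w1_s, ~dal_s_w2, ~dal_w1_w2, ~ser_w1, ~dser_w1_w2,
    "1",  22.427, -0.011, -0.051, -0.062, -0.48, -0.17,
    "2",  22.968,  0.068, -0.045,  0.023, -0.23, -0.18,
    "3",  25.003,  0.050, -0.023,  0.027,  0.22, -0.14,
    "4",  23.596,  0.021,  0.010,  0.031, -0.91, -0.22,
    "5",  23.746,  0.044, -0.009,  0.035,  1.06, -0.19,
    "6",  24.892,  0.067, -0.015,  0.052,  0.20, -0.05,
    "7",  23.325,  0.049,  0.010,  0.059,  0.67, -0.54,
    "8",  21.938,  0.046,  0.022,  0.068,  0.25, -0.25,
    "9",  24.898,  0.125,  0.020,  0.145, -4.08, -0.04,
    "10", 24.879,  0.110,  0.105,  0.215, -0.92, -0.58
  )
}
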