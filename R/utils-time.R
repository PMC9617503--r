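#' Parse a 24-hour "HH:MM" clock string to decimal hours
#'
#' Fractional minutes are permitted after the colon (e.g. `"00:07.6"`), which
#' is how sub-minute anchors such as a habitual-sleep-time estimate are
#' carried around internally.
#'
#' @param x Character vector of clock times, `"HH:MM"` on the 24-h clock.
#' @return Numeric vector of decimal hours in `[0, 24)`.
#' @examples
#' parse_clock(c("23:30", "00:07.6"))
#' @export
parse_clock <- function(x) {
  stopifnot(is.character(x))
  ok <- grepl("^([01]?[0-9]|2[0-3]):[0-5]?[0-9](\\.[0-9]+)?$", x)
  if (any(!ok)) {
    stop("invalid clock time(s): ", paste(x[!ok], collapse = ", "),
         " (expected HH:MM, 24-h)", call. = FALSE)
  }
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) as.numeric(p[1]) + as.numeric(p[2]) / 60, 0)
}

#' Render decimal hours as an "HH:MM" clock string
#'
#' Wraps into `[0, 24)` and rounds to the nearest minute; `24:00` rounds to
#' `00:00`.
#'
#' @param hours Numeric vector of decimal hours (any finite value).
#' @return Character vector `"HH:MM"`.
#' @examples
#' format_clock(15.336)  # "15:20"
#' @export
format_clock <- function(hours) {
  stopifnot(is.numeric(hours), all(is.finite(hours)))
  mins <- round((hours %% 24) * 60) %% 1440
  sprintf("%02d:%02d", mins %/% 60, mins %% 60)
}

#' Wrap hours onto the half-open circular interval (-12, 12]
#'
#' The package-wide acrophase convention: times relative to habitual sleep
#' time live on a 24-h circle and are reported in `(-12, 12]`, so that
#' exactly opposite phases map to +12 (never -12).
#'
#' @param x Numeric vector of hours.
#' @return Wrapped values in `(-12, 12]`.
#' @export
wrap_hours <- function(x) {
  r <- x %% 24
  ifelse(r > 12, r - 24, r)
}
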