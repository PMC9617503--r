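#' Dim-light melatonin onset from a log-scale melatonin cosinor
#'
#' Solves the fitted sinusoid `log y(t) = M + A sin(w (t + phi))` for the
#' rising crossing of the natural log of a fixed melatonin threshold
#' (default 3 pg/mL):
#' `DLMO = (24 / 2 pi) asin((ln thr - M) / A) - phi`.
#' The principal asin branch places the crossing on the rising limb, in
#' the half-period before the acrophase. The onset is undefined when the
#' curve never crosses the threshold (`|(ln thr - M)/A| > 1`) or the
#' rhythm is flat.
#'
#' @param fit A `cosinor_fit` fitted to log-melatonin (`log_scale = TRUE`).
#' @param threshold Melatonin onset threshold in pg/mL.
#' @return List with class `dlmo_result`: `dlmo_rel` (hours relative to
#'   habitual sleep time, NA when undefined), `threshold`, `defined`.
#' @examples
#' f <- fit_individual(c(-16, -4, -2, 0, 1), exp(0.9 + 3 *
#'        sin(2 * pi / 24 * (c(-16, -4, -2, 0, 1) + 2))), log_scale = TRUE)
#' dlmo_relative(f)
#' @export
dlmo_relative <- function(fit, threshold = 3) {
  stopifnot(inherits(fit, "cosinor_fit"), threshold > 0)
  if (!isTRUE(fit$log_scale)) {
    stop("DLMO requires a log-scale melatonin fit", call. = FALSE)
  }
  ratio <- if (fit$amplitude > 0) (log(threshold) - fit$mesor) / fit$amplitude
           else Inf
  if (!is.finite(ratio) || abs(ratio) > 1 || fit$degenerate) {
    return(structure(list(dlmo_rel = NA_real_, threshold = threshold,
                          defined = FALSE), class = "dlmo_result"))
  }
  rel <- (24 / (2 * pi)) * asin(ratio) - fit$phi
  structure(list(dlmo_rel = rel, threshold = threshold, defined = TRUE),
            class = "dlmo_result")
}

#' @export
print.dlmo_result <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("<dlmo_result> HST %+0.2f h (threshold %g pg/mL)\n",
                x$dlmo_rel, x$threshold))
  } else {
    cat("<dlmo_result> undefined (threshold not crossed)\n")
  }
  invisible(x)
}

#' Convert a melatonin onset to standard clock time
#'
#' @param result A defined `dlmo_result`.
#' @param hst_clock Habitual sleep time anchor (`"HH:MM"` or decimal hours).
#' @return Clock string `"HH:MM"`.
#' @export
dlmo_clock <- function(result, hst_clock) {
  stopifnot(inherits(result, "dlmo_result"))
  if (!result$defined) {
    stop("DLMO is undefined for this fit; cannot convert to clock time",
         call. = FALSE)
  }
  to_clock_time(result$dlmo_rel, hst_clock)
}
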