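# Independent brute-force oracles, deliberately kept free of the package's
# estimation code paths.

# Dense grid search minimizing the residual sum of squares of
# y ~ M + A sin(2 pi (t + 6 - acro)/24) over an (M, A, acro) lattice.
grid_search_cosinor <- function(t, value, m_grid, a_grid,
                                acro_grid = seq(-11.95, 12, by = 0.05)) {
  w <- 2 * pi / 24
  best <- list(rss = Inf)
  for (acro in acro_grid) {
    basis <- sin(w * (t + 6 - acro))
    for (a in a_grid) {
      pred0 <- a * basis
      # profile M on the grid too, but scanning m_grid keeps the oracle a
      # pure lattice search
      for (m in m_grid) {
        rss <- sum((value - m - pred0)^2)
        if (rss < best$rss) best <- list(rss = rss, mesor = m,
                                         amplitude = a, acrophase = acro)
      }
    }
  }
  best
}

rss_of_fit <- function(fit, t, value) {
  sum((value - evaluate_sinusoid(fit, t))^2)
}

# Earliest rising crossing of log(threshold) located by dense scan of the
# fitted curve over (acrophase - 12, acrophase).
dlmo_scan <- function(fit, threshold = 3, resolution = 1e-3) {
  ts <- seq(fit$acrophase - 12, fit$acrophase, by = resolution)
  y <- evaluate_sinusoid(fit, ts)
  above <- y >= log(threshold)
  i <- which(!above[-length(above)] & above[-1])
  if (length(i) == 0) {
    if (all(above)) return(ts[1])  # crosses at/before the scan start
    return(NA_real_)
  }
  ts[i[1] + 1]
}
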