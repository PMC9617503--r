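# Small in-code fixtures shared across test files.

tiny_participants <- function() {
  participant_table(
    id = c("A", "B"),
    hst_clock = c("23:30", "00:15"),
    hwt_clock = c("07:30", "08:15"),
    sphere = c(-3.00, 1.00), cylinder = c(-0.50, 0.50),
    sex = c("F", "M"), age = c(21, 19))
}

tiny_measurements <- function(participants = tiny_participants()) {
  rows <- list()
  for (i in seq_len(nrow(participants))) {
    t_rel <- epoch_time(epoch_labels, participants$hwt_h[i],
                        participants$hst_h[i])
    rows[[i]] <- tibble::tibble(
      participant_id = participants$id[i], season = "W1",
      epoch_label = epoch_labels, t_rel = t_rel, parameter = "AL",
      value = 23.9 + 0.02 * sin(2 * pi / 24 * (t_rel + 14.8)))
  }
  dplyr::bind_rows(rows)
}

tiny_cohort <- function() cohort_table(tiny_participants(),
                                       tiny_measurements())

# exact sinusoid series at the 8 standard epoch offsets for one subject
sinusoid_series <- function(mesor, amplitude, acrophase,
                            t = c(-16, -13, -4, -3, -2, -1, 0, 1)) {
  list(t = t,
       value = mesor + amplitude * sin(2 * pi / 24 * (t + 6 - acrophase)))
}

# reference cosinor fit built directly from (M, A, acrophase), bypassing
# estimation, for worked-example inputs
make_fit <- function(mesor, amplitude, acrophase, log_scale = FALSE) {
  s <- sinusoid_series(mesor, amplitude, acrophase)
  v <- if (log_scale) exp(s$value) else s$value
  fit_individual(s$t, v, log_scale = log_scale)
}
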