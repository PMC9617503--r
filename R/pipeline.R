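#' Build a validated pipeline run configuration
#'
#' @param out_dir Output directory for the run.
#' @param seed Integer seed governing every stochastic stage.
#' @param n_participants Cohort size for the simulation stage (ignored if
#'   `input_dir` is given).
#' @param seasons Seasons to simulate/analyse.
#' @param input_dir Optional directory with an existing cohort
#'   (participants.csv + measurements.csv); when NULL a cohort is simulated.
#' @param growth Simulate per-participant growth structure (requires
#'   seasons to include W1 and S).
#' @param scheme Growth classification scheme, `"seven_month"` or
#'   `"annual"`.
#' @param dlmo_threshold Melatonin onset threshold, pg/mL (> 0).
#' @param n_boot Bootstrap resamples for population CIs (>= 0).
#' @param n_perm Within-subject permutations for the diurnal test (>= 0).
#' @param hst_anchor HST clock anchor used to render clock times.
#' @return List with class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, n_participants = 24,
                       seasons = c("W1", "S"), input_dir = NULL,
                       growth = FALSE, scheme = "seven_month",
                       dlmo_threshold = 3, n_boot = 0, n_perm = 0,
                       hst_anchor = reference_hst_anchor()) {
  seasons <- as.character(unlist(seasons))
  if (!scheme %in% c("seven_month", "annual")) {
    stop("unknown growth scheme: ", scheme, call. = FALSE)
  }
  stopifnot(dlmo_threshold > 0, n_boot >= 0, n_perm >= 0,
            all(seasons %in% season_levels))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_participants = n_participants, seasons = seasons,
                 input_dir = input_dir, growth = growth, scheme = scheme,
                 dlmo_threshold = dlmo_threshold, n_boot = n_boot,
                 n_perm = n_perm, hst_anchor = hst_anchor),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Run the full rhythmometry pipeline
#'
#' simulate (or load) -> cosinor fits -> DLMO -> season comparison ->
#' growth classification -> report, with every intermediate written as a
#' CSV under `config$out_dir` so each stage can be re-run independently. A
#' JSON manifest records the seed and configuration; the run is
#' deterministic given the config.
#'
#' @param config A [run_config()] (or path to a YAML config).
#' @return Invisibly, a list of the stage outputs (`cohort`, `fits`,
#'   `dlmo`, `diurnal`, `comparison`, `growth`, `report`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- stage("simulate", {
    if (!is.null(config$input_dir)) {
      read_cohort(config$input_dir)
    } else {
      base <- simulation_truth(n_participants = config$n_participants,
                               seasons = config$seasons, seed = config$seed)
      if (config$growth) {
        generate_growth_cohort(
          growth_truth(config$n_participants, seed = config$seed), base)
      } else {
        generate_cohort(base)
      }
    }
  })
  write_cohort(cohort, config$out_dir)
  truth <- cohort_truth(cohort)
  if (!is.null(truth)) {
    readr::write_csv(truth, file.path(config$out_dir, "truth.csv"),
                     progress = FALSE)
  }

  fits <- stage("fit", {
    combos <- unique(cohort$measurements[, c("parameter", "season")])
    res <- list()
    for (k in seq_len(nrow(combos))) {
      p <- combos$parameter[k]; s <- combos$season[k]
      d <- dplyr::filter(cohort$measurements,
                         .data$parameter == p, .data$season == s)
      f <- fit_population(d, log_scale = (p == "MEL"), parameter = p,
                          season = s, n_boot = config$n_boot,
                          seed = config$seed)
      tabs <- list(fits_to_table(f$population), fits_to_table(f$individual))
      subj <- fits_to_table(f$subject)
      if (any(subj$estimator == "blup")) tabs <- c(tabs, list(subj))
      res[[k]] <- dplyr::bind_rows(tabs)
    }
    dplyr::bind_rows(res)
  })
  readr::write_csv(fits, file.path(config$out_dir, "fits.csv"),
                   progress = FALSE)

  diurnal <- stage("diurnal_test", {
    combos <- unique(cohort$measurements[, c("parameter", "season")])
    purrr::pmap_dfr(combos, function(parameter, season) {
      d <- cohort$measurements[cohort$measurements$parameter == parameter &
                                 cohort$measurements$season == season, ]
      r <- diurnal_variation_test(d, log_scale = (parameter == "MEL"),
                                  n_perm = config$n_perm, seed = config$seed)
      tibble::tibble(parameter = parameter, season = season,
                     f = r$statistic, df1 = r$df[1], df2 = r$df[2],
                     p_value = r$p_value, p_perm = r$p_perm)
    })
  })
  readr::write_csv(diurnal, file.path(config$out_dir, "diurnal.csv"),
                   progress = FALSE)

  # per-individual contrasts use the shrunken (conditional-mode) fits when
  # the mixed model provided them
  subject_rows <- function(tab) {
    ind <- tab[tab$scope == "individual", ]
    if (any(ind$estimator == "blup")) ind[ind$estimator == "blup", ] else ind
  }

  dlmo_tab <- stage("dlmo", {
    mel <- subject_rows(fits[fits$parameter == "MEL", ])
    if (nrow(mel) == 0) NULL else {
      hst <- cohort$participants$hst_h[
        match(mel$participant_id, cohort$participants$id)]
      purrr::map_dfr(seq_len(nrow(mel)), function(i) {
        r <- dlmo_relative(table_to_fits(mel[i, ])[[1]],
                           threshold = config$dlmo_threshold)
        tibble::tibble(
          participant_id = mel$participant_id[i], season = mel$season[i],
          dlmo_rel = r$dlmo_rel, defined = r$defined,
          dlmo_clock = ifelse(r$defined, to_clock_time(r$dlmo_rel, hst[i]),
                              NA_character_))
      })
    }
  })
  if (!is.null(dlmo_tab)) {
    readr::write_csv(dlmo_tab, file.path(config$out_dir, "dlmo.csv"),
                     progress = FALSE)
  }

  comparison <- NULL
  if (all(c("W1", "S") %in% fits$season)) {
    comparison <- stage("compare", {
      ind <- subject_rows(fits)
      compare_seasons(ind[ind$season == "W1", ], ind[ind$season == "S", ])
    })
    readr::write_csv(comparison, file.path(config$out_dir, "seasons.csv"),
                     progress = FALSE)
  }

  growth_tab <- NULL
  if (all(c("W1", "S") %in% fits$season)) {
    growth_tab <- stage("classify", {
      rec <- interval_deltas(subject_rows(fits))
      sch <- ifelse(rec$interval == "W1-W2", "annual", config$scheme)
      rec$category <- NA_character_
      for (i in seq_len(nrow(rec))) {
        rec$category[i] <- as.character(
          classify_growth(rec$delta_al[i], scheme = sch[i]))
      }
      rec
    })
    readr::write_csv(growth_tab, file.path(config$out_dir, "growth.csv"),
                     progress = FALSE)
  }

  report <- stage("report", {
    pop <- fits[fits$scope == "population", ]
    tibble::tibble(
      parameter = pop$parameter, season = pop$season, mesor = pop$mesor,
      amplitude = pop$amplitude, acrophase = pop$acrophase,
      acrophase_clock = to_clock_time(pop$acrophase, config$hst_anchor))
  })
  readr::write_csv(report, file.path(config$out_dir, "report.csv"),
                   progress = FALSE)

  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("oculorhythm")),
    config = config[setdiff(names(config), "out_dir")],
    files = c("participants.csv", "measurements.csv", "fits.csv",
              "diurnal.csv", "seasons.csv", "growth.csv", "report.csv"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(cohort = cohort, fits = fits, diurnal = diurnal,
                 dlmo = dlmo_tab, comparison = comparison,
                 growth = growth_tab, report = report))
}
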