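#!/usr/bin/env Rscript
# Thin command-line wrapper over the oculorhythm package.
#
#   Rscript scripts/oculorhythm.R run      --config cfg.yaml
#   Rscript scripts/oculorhythm.R run      --out dir/ [--seed N] [--n 24]
#                                          [--seasons W1,S] [--growth]
#                                          [--scheme seven_month|annual]
#   Rscript scripts/oculorhythm.R simulate --out dir/ [--seed N] [--n 24]
#                                          [--seasons W1,S]
#
# `run` executes simulate -> fit -> dlmo -> compare -> classify -> report
# and writes all stage CSVs plus a manifest; `simulate` writes only the
# synthetic cohort (participants.csv, measurements.csv, truth.csv).

suppressMessages({
  library(oculorhythm)
  library(optparse)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || !args[1] %in% c("run", "simulate")) {
  stop("usage: oculorhythm.R run|simulate [options]; see script header")
}
cmd <- args[1]

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--out", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--n", type = "integer", default = 24L),
  make_option("--seasons", type = "character", default = "W1,S"),
  make_option("--growth", action = "store_true", default = FALSE),
  make_option("--scheme", type = "character", default = "seven_month")
)), args = args[-1])

if (cmd == "run") {
  cfg <- if (!is.null(opts$config)) {
    read_run_config(opts$config)
  } else {
    if (is.null(opts$out)) stop("run requires --config or --out")
    run_config(out_dir = opts$out, seed = opts$seed,
               n_participants = opts$n,
               seasons = strsplit(opts$seasons, ",")[[1]],
               growth = opts$growth, scheme = opts$scheme)
  }
  run_pipeline(cfg)
  cat("run complete:", cfg$out_dir, "\n")
} else {
  if (is.null(opts$out)) stop("simulate requires --out")
  seasons <- strsplit(opts$seasons, ",")[[1]]
  truth <- simulation_truth(n_participants = opts$n, seasons = seasons,
                            seed = opts$seed)
  cohort <- if (opts$growth) {
    generate_growth_cohort(growth_truth(opts$n, seed = opts$seed), truth)
  } else {
    generate_cohort(truth)
  }
  write_cohort(cohort, opts$out)
  readr::write_csv(cohort_truth(cohort), file.path(opts$out, "truth.csv"))
  cat("cohort written:", opts$out, "\n")
}
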