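#' @importFrom rlang .data
NULL

#' Measurement parameters, seasons and epoch labels
#'
#' Controlled vocabularies for the cohort tables. `MEL` is salivary
#' melatonin in pg/mL (modelled on the natural-log scale); `IOP` is
#' intraocular pressure in mm Hg; `ACD`, `LT`, `VCD`, `AL` are anterior
#' chamber depth, lens thickness, vitreous chamber depth and axial length in
#' mm; `RT` and `ChT` are central 1-mm retinal and choroidal thickness in
#' micrometres. Seasons are first winter (`W1`), summer (`S`) and second
#' winter (`W2`). Epochs are anchored to habitual wake time (`HWT`) and
#' habitual sleep time (`HST`).
#'
#' @format Character vectors.
#' @name vocab
NULL

#' @rdname vocab
#' @export
ocular_parameters <- c("MEL", "IOP", "ACD", "LT", "VCD", "AL", "RT", "ChT")

#' @rdname vocab
#' @export
season_levels <- c("W1", "S", "W2")

#' @rdname vocab
#' @export
epoch_labels <- c("HWT+1", "HWT+4", "HST-4", "HST-3", "HST-2", "HST-1",
                  "HST+0", "HST+1")

#' Units of each measurement parameter
#' @return Named character vector of units keyed by parameter.
#' @export
parameter_units <- function() {
  c(MEL = "pg/mL", IOP = "mm Hg", ACD = "mm", LT = "mm", VCD = "mm",
    AL = "mm", RT = "um", ChT = "um")
}

#' Construct a participant table
#'
#' One row per participant: habitual sleep/wake clock times and baseline
#' refraction. Clock strings are validated but stored as given; the decimal
#' forms are added as `hst_h` / `hwt_h`.
#'
#' @param id Character ids (unique).
#' @param hst_clock,hwt_clock Habitual sleep / wake clock times, `"HH:MM"`.
#' @param sphere,cylinder Subjective refraction components, diopters.
#' @param sex `"M"`, `"F"` or `"unknown"`.
#' @param age Age in years (> 0).
#' @return A tibble with class `participant_table`.
#' @export
participant_table <- function(id, hst_clock, hwt_clock,
                              sphere = 0, cylinder = 0,
                              sex = "unknown", age = 20) {
  tb <- tibble::tibble(
    id = as.character(id), sex = sex, age = age,
    hst_clock = hst_clock, hwt_clock = hwt_clock,
    sphere = sphere, cylinder = cylinder,
    hst_h = parse_clock(hst_clock), hwt_h = parse_clock(hwt_clock)
  )
  if (anyDuplicated(tb$id)) {
    stop("duplicate participant id(s): ",
         paste(unique(tb$id[duplicated(tb$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(tb$sex %in% c("M", "F", "unknown"))) {
    stop("sex must be one of M, F, unknown", call. = FALSE)
  }
  if (any(tb$age <= 0)) stop("age must be positive", call. = FALSE)
  class(tb) <- c("participant_table", class(tb))
  tb
}

#' Assemble and validate a cohort table
#'
#' A cohort is a participant table plus a long measurement table with one
#' row per (participant, season, epoch, parameter) observation. Validation
#' enforces the controlled vocabularies, referential integrity, key
#' uniqueness, positivity of melatonin, and that evening epoch labels carry
#' their literal offset in `t_rel`.
#'
#' @param participants A `participant_table` (or coercible data frame).
#' @param measurements Data frame with columns `participant_id`, `season`,
#'   `epoch_label`, `t_rel` (hours relative to HST), `parameter`, `value`.
#' @return A list with class `cohort_table` and elements `participants`,
#'   `measurements`.
#' @export
cohort_table <- function(participants, measurements) {
  participants <- tibble::as_tibble(participants)
  m <- tibble::as_tibble(measurements)
  need <- c("participant_id", "season", "epoch_label", "t_rel", "parameter",
            "value")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols)) {
    stop("measurement table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  m$participant_id <- as.character(m$participant_id)

  bad <- which(!m$season %in% season_levels)
  if (length(bad)) stop("unknown season at measurement row ", bad[1], ": ",
                        m$season[bad[1]], call. = FALSE)
  bad <- which(!m$epoch_label %in% epoch_labels)
  if (length(bad)) stop("unknown epoch label at measurement row ", bad[1],
                        ": ", m$epoch_label[bad[1]], call. = FALSE)
  bad <- which(!m$parameter %in% ocular_parameters)
  if (length(bad)) stop("unknown parameter at measurement row ", bad[1],
                        ": ", m$parameter[bad[1]], call. = FALSE)
  bad <- which(!m$participant_id %in% participants$id)
  if (length(bad)) stop("measurement row ", bad[1],
                        " references unknown participant id '",
                        m$participant_id[bad[1]], "'", call. = FALSE)
  key <- paste(m$participant_id, m$season, m$epoch_label, m$parameter)
  bad <- which(duplicated(key))
  if (length(bad)) stop("duplicate (participant, season, epoch, parameter) ",
                        "key at measurement row ", bad[1], ": ", key[bad[1]],
                        call. = FALSE)
  bad <- which(!is.finite(m$t_rel) | m$t_rel < -24 | m$t_rel > 2)
  if (length(bad)) stop("t_rel out of [-24, 2] at measurement row ", bad[1],
                        call. = FALSE)
  evening <- grepl("^HST", m$epoch_label)
  lit <- as.numeric(sub("^HST", "", m$epoch_label[evening]))
  bad <- which(abs(m$t_rel[evening] - lit) > 1e-9)
  if (length(bad)) {
    i <- which(evening)[bad[1]]
    stop("evening epoch ", m$epoch_label[i], " at measurement row ", i,
         " has t_rel ", m$t_rel[i], " != its label offset", call. = FALSE)
  }
  bad <- which(m$parameter == "MEL" & m$value <= 0)
  if (length(bad)) stop("non-positive MEL value at measurement row ", bad[1],
                        call. = FALSE)

  structure(list(participants = participants, measurements = m),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", nrow(x$participants), " participants, ",
      nrow(x$measurements), " measurements (",
      paste(unique(x$measurements$season), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Read a cohort from CSV files
#'
#' @param path Either a directory containing `participants.csv` and
#'   `measurements.csv`, or a character vector of the two file paths
#'   (participants first).
#' @return A validated [cohort_table()].
#' @export
read_cohort <- function(path) {
  if (length(path) == 1 && dir.exists(path)) {
    path <- file.path(path, c("participants.csv", "measurements.csv"))
  }
  stopifnot(length(path) == 2)
  if (!all(file.exists(path))) {
    stop("missing cohort file(s): ",
         paste(path[!file.exists(path)], collapse = ", "), call. = FALSE)
  }
  p <- readr::read_csv(path[1], show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         id = readr::col_character(),
                         hst_clock = readr::col_character(),
                         hwt_clock = readr::col_character()))
  m <- readr::read_csv(path[2], show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         participant_id = readr::col_character()))
  p <- participant_table(p$id, p$hst_clock, p$hwt_clock, p$sphere,
                         p$cylinder, p$sex, p$age)
  cohort_table(p, m)
}

#' Write a cohort to CSV files
#'
#' Inverse of [read_cohort()]: writes `participants.csv` and
#' `measurements.csv` into `dir`.
#'
#' @param cohort A `cohort_table`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- cohort$participants[, c("id", "sex", "age", "hst_clock", "hwt_clock",
                               "sphere", "cylinder")]
  readr::write_csv(p, file.path(dir, "participants.csv"), progress = FALSE)
  readr::write_csv(cohort$measurements, file.path(dir, "measurements.csv"),
                   progress = FALSE)
  invisible(dir)
}

#' Time of an epoch relative to habitual sleep time
#'
#' Evening epochs (`HST-4` ... `HST+1`) sit at their literal hour offsets.
#' Morning epochs (`HWT+1`, `HWT+4`) are placed at the previous wake time:
#' the wake-to-sleep gap is wrapped into `(-24, 0)` and the label's offset
#' added, giving large negative values (typically -17 to -11 h).
#'
#' @param epoch_label One of [epoch_labels].
#' @param hwt_clock,hst_clock Habitual wake / sleep clock times (`"HH:MM"`
#'   strings or decimal hours).
#' @return Hours relative to HST (signed decimal), vectorised over labels.
#' @examples
#' epoch_time("HWT+1", "07:30", "23:30")  # -15
#' @export
epoch_time <- function(epoch_label, hwt_clock, hst_clock) {
  stopifnot(all(epoch_label %in% epoch_labels))
  hwt <- if (is.character(hwt_clock)) parse_clock(hwt_clock) else hwt_clock
  hst <- if (is.character(hst_clock)) parse_clock(hst_clock) else hst_clock
  span <- (hst - hwt) %% 24  # waking-day length
  if (any(span <= 0 | span >= 24)) {
    stop("wake-to-sleep span must lie strictly inside (0, 24) hours",
         call. = FALSE)
  }
  offset <- as.numeric(sub("^H[WS]T", "", epoch_label))
  ifelse(grepl("^HWT", epoch_label), -span + offset, offset)
}

#' Convert HST-relative hours to a standard clock time
#'
#' @param t_rel Hours relative to habitual sleep time.
#' @param hst_clock HST anchor (`"HH:MM"` string or decimal hours).
#' @return Clock string `"HH:MM"`, rounded to the nearest minute.
#' @examples
#' to_clock_time(-8.79, "00:07.6")  # "15:20"
#' @export
to_clock_time <- function(t_rel, hst_clock) {
  hst <- if (is.character(hst_clock)) parse_clock(hst_clock) else hst_clock
  format_clock(hst + t_rel)
}

#' Vitreous chamber depth from component biometry
#'
#' VCD = AL - (ACD + LT + RT), with retinal thickness supplied in
#' micrometres and converted to mm.
#'
#' @param al,acd,lt Axial length, anterior chamber depth, lens thickness (mm).
#' @param rt_um Central retinal thickness (micrometres).
#' @return VCD in mm.
#' @examples
#' derive_vcd(24.0, 3.5, 3.6, 250)  # 16.65
#' @export
derive_vcd <- function(al, acd, lt, rt_um) {
  stopifnot(all(al > 0), all(acd >= 0), all(lt >= 0), all(rt_um >= 0))
  vcd <- al - (acd + lt + rt_um / 1000)
  if (any(vcd < 0)) stop("implausible biometry: derived VCD is negative",
                         call. = FALSE)
  vcd
}

#' Spherical equivalent refraction
#'
#' @param sphere,cylinder Refraction components in diopters.
#' @return SER = sphere + cylinder / 2, diopters.
#' @export
compute_ser <- function(sphere, cylinder) sphere + cylinder / 2

#' Refractive group from spherical equivalent
#'
#' Myopia is SER <= -0.50 D, hyperopia SER >= +0.50 D, emmetropia the open
#' interval between.
#'
#' @param ser Spherical equivalent refraction, diopters.
#' @return Factor with levels `myopia`, `emmetropia`, `hyperopia`.
#' @export
classify_ser <- function(ser) {
  stopifnot(is.numeric(ser), !anyNA(ser))
  out <- ifelse(ser <= -0.5, "myopia",
                ifelse(ser >= 0.5, "hyperopia", "emmetropia"))
  factor(out, levels = c("myopia", "emmetropia", "hyperopia"))
}
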