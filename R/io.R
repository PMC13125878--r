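# Tabular I/O: surrogate signals, trigger times, result tables, and the
# run configuration (YAML or JSON).

#' Signal file I/O
#'
#' Respiratory waveforms are stored as 2-column CSV (`time_s`,
#' `amplitude`); trigger times as 1-column CSV (`trigger_time_s`).
#'
#' @param waveform a `resp_waveform`.
#' @param triggers a `cardiac_triggers`.
#' @param path CSV path.
#' @param period respiratory period in seconds, re-attached on read
#'   (not stored in the CSV).
#' @return Readers return `resp_waveform` / `cardiac_triggers` objects;
#'   writers return the path invisibly.
#' @export
write_signals <- function(waveform, path) {
  stopifnot(inherits(waveform, "resp_waveform"))
  write.csv(data.frame(time_s = waveform$times,
                       amplitude = waveform$amplitudes),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signals
#' @export
read_signals <- function(path, period = NULL) {
  d <- read.csv(path)
  if (!all(c("time_s", "amplitude") %in% names(d)))
    stop("signal CSV must have columns time_s, amplitude", call. = FALSE)
  dts <- diff(d$time_s)
  if (length(dts) < 1L || any(dts <= 0))
    stop("signal times must be strictly increasing", call. = FALSE)
  if (diff(range(dts)) > 1e-6 * mean(dts))
    stop("signal times must be uniformly sampled", call. = FALSE)
  structure(
    list(times = d$time_s, amplitudes = d$amplitude, period = period,
         dt = mean(dts), amplitude = NA_real_, baseline = NA_real_,
         drift_rate = NA_real_, noise_sd = NA_real_, seed = NULL),
    class = "resp_waveform")
}

#' @rdname write_signals
#' @export
write_triggers <- function(triggers, path) {
  stopifnot(inherits(triggers, "cardiac_triggers"))
  write.csv(data.frame(trigger_time_s = triggers$trigger_times), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_signals
#' @export
read_triggers <- function(path) {
  d <- read.csv(path)
  if (!"trigger_time_s" %in% names(d))
    stop("trigger CSV must have column trigger_time_s", call. = FALSE)
  tt <- d$trigger_time_s
  if (length(tt) < 2L || any(diff(tt) <= 0))
    stop("trigger times must be strictly increasing", call. = FALSE)
  structure(list(trigger_times = tt, mean_rr = mean(diff(tt)),
                 rr_jitter_sd = NA_real_, seed = NULL),
            class = "cardiac_triggers")
}

#' Default run configuration
#'
#' The resolved configuration used by [run_full()]; every field can be
#' overridden from a YAML or JSON file via [read_run_config()]. Units:
#' mm for amplitudes/thresholds, Gy for dose, cc for the D_v volume.
#'
#' @param seed integer seed for all randomness in the run.
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1) {
  structure(list(
    mode = "full",
    seed = seed,
    phantom = list(
      n_subjects = 10,
      grid_shape = c(96, 96, 96),
      spacing = 1.56,
      cardiac_amp = c(-5.5, 3.8, -3.6),
      resp_amp = c(0, 1, -4),
      cardiac_sd = 0,
      resp_sd = 0,
      hysteresis_range = c(0, 6)
    ),
    signals = list(
      duration = 300, dt = 0.1, period = 4, amplitude = 1,
      drift_rate = 0, noise_sd = 0.02, mean_rr = 1, rr_jitter_sd = 0.05
    ),
    binning = list(n_cardiac = 10, lower = 0.10, upper = 0.90),
    thresholds = list(motion_mm = 5),
    dose = list(mode = "linear_gradient", level = 30,
                gradient = c(0, 0, 1), v_cc = 0.03),
    io = list(compress = FALSE, write_masks = TRUE)
  ), class = "run_config")
}

# recursive list merge: values in `over` override `base`
merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Read a run configuration file
#'
#' Reads YAML (`.yaml`/`.yml`) or JSON (`.json`) and merges it over
#' [default_run_config()], so partial configs are valid.
#'
#' @param path config file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  over <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("config must be .yaml, .yml or .json", call. = FALSE))
  cfg <- merge_config(unclass(default_run_config()), over)
  valid_modes <- c("simulate", "analyze", "margins", "dosimetry", "stats",
                   "full")
  if (!cfg$mode %in% valid_modes)
    stop(sprintf("invalid mode '%s' (expected one of %s)", cfg$mode,
                 paste(valid_modes, collapse = ", ")), call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' Write a result table with units in headers
#'
#' Thin wrapper over [utils::write.csv()] (no row names) used for all
#' pipeline outputs; column names are expected to carry units (`_mm`,
#' `_gy`, `_cc`).
#'
#' @param df data.frame.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_table <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
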