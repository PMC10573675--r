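#' Ablation-rate calibration table
#'
#' Lithotripsy duration is modeled structurally as segmented stone volume
#' divided by an ablation speed; the speed depends on the laser source and
#' settings, the fiber diameter and the stone composition, and must be
#' supplied by the user as a calibration table. Lookup is exact -- a missing
#' combination is an error, never a silently substituted nearest match.
#' No calibration ships enabled; [example_rate_table()] provides clearly
#' illustrative values for demonstrations and tests only.
#'
#' @param entries data.frame with columns `laser_source` (one of `"HoYAG"`,
#'   `"HoYAG_MOSES"`, `"TFL"`), `fiber_diameter_um` (> 0), `composition`
#'   (free-text key), `pulse_energy_J` (> 0), `frequency_Hz` (> 0),
#'   `ablation_speed_mm3_per_s` (> 0).
#' @return An object of class `ablation_rate_table`.
#' @seealso [estimate_ld()], [read_rate_table()]
#' @export
ablation_rate_table <- function(entries) {
  needed <- c("laser_source", "fiber_diameter_um", "composition",
              "pulse_energy_J", "frequency_Hz", "ablation_speed_mm3_per_s")
  missing_cols <- setdiff(needed, names(entries))
  if (length(missing_cols))
    stop("rate table missing columns: ", paste(missing_cols, collapse = ", "))
  entries <- as.data.frame(entries)[needed]
  if (!all(entries$laser_source %in% c("HoYAG", "HoYAG_MOSES", "TFL")))
    stop("laser_source must be one of HoYAG, HoYAG_MOSES, TFL")
  num_pos <- c("fiber_diameter_um", "pulse_energy_J", "frequency_Hz",
               "ablation_speed_mm3_per_s")
  for (cn in num_pos)
    if (any(!is.finite(entries[[cn]]) | entries[[cn]] <= 0))
      stop(sprintf("`%s` must be positive throughout", cn))
  structure(list(entries = entries), class = "ablation_rate_table")
}

#' @export
print.ablation_rate_table <- function(x, ...) {
  cat(sprintf("<ablation_rate_table> %d calibration entr%s\n",
              nrow(x$entries), ifelse(nrow(x$entries) == 1, "y", "ies")))
  print(x$entries)
  invisible(x)
}

#' Read / write an ablation-rate table as JSON
#'
#' JSON schema: an array of objects with the fields of
#' [ablation_rate_table()].
#'
#' @param path JSON file path.
#' @param x an `ablation_rate_table` (for writing).
#' @return `read_rate_table`: an `ablation_rate_table`; `write_rate_table`:
#'   `path` invisibly.
#' @export
read_rate_table <- function(path) {
  ablation_rate_table(jsonlite::fromJSON(path))
}

#' @rdname read_rate_table
#' @export
write_rate_table <- function(x, path) {
  stopifnot(inherits(x, "ablation_rate_table"))
  jsonlite::write_json(x$entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Illustrative ablation-rate table
#'
#' Example calibration with made-up but plausible speeds, for demonstrations
#' and tests only. Real use requires a user-supplied calibration measured for
#' the actual laser, fiber and stone composition.
#' @return An `ablation_rate_table`.
#' @export
example_rate_table <- function() {
  ablation_rate_table(data.frame(
    laser_source = c("HoYAG", "HoYAG_MOSES", "TFL", "TFL"),
    fiber_diameter_um = c(272, 272, 272, 150),
    composition = c("COM", "COM", "COM", "UA"),
    pulse_energy_J = c(0.8, 0.8, 0.5, 0.5),
    frequency_Hz = c(10, 10, 20, 20),
    ablation_speed_mm3_per_s = c(1.0, 1.6, 2.5, 2.0),
    stringsAsFactors = FALSE
  ))
}

#' Estimate lithotripsy duration from stone volume
#'
#' `duration_s = volume_mm3 / ablation_speed` for the exactly matching
#' calibration entry; the laser power (`pulse_energy_J * frequency_Hz`, W)
#' and all inputs are echoed for audit. Whether real procedures add overhead
#' (duty cycle, basketing pauses) on top of pure ablation time is outside
#' this structural model.
#'
#' @param volume_mm3 segmented stone volume (mm^3), >= 0.
#' @param table an [ablation_rate_table()].
#' @param laser_source,fiber_diameter_um,composition,pulse_energy_J,frequency_Hz
#'   the settings key; must match one table entry exactly.
#' @return An object of class `ld_estimate` with `duration_s`, `power_W`,
#'   `ablation_speed_mm3_per_s` and the echoed inputs.
#' @examples
#' est <- estimate_ld(923, example_rate_table(), "TFL", 272, "COM", 0.5, 20)
#' est$duration_s
#' @export
estimate_ld <- function(volume_mm3, table, laser_source, fiber_diameter_um,
                        composition, pulse_energy_J, frequency_Hz) {
  if (!inherits(table, "ablation_rate_table"))
    stop("`table` must be an ablation_rate_table")
  if (!is.numeric(volume_mm3) || length(volume_mm3) != 1L ||
      !is.finite(volume_mm3) || volume_mm3 < 0)
    stop("`volume_mm3` must be a single non-negative number")
  e <- table$entries
  hit <- e$laser_source == laser_source &
    e$fiber_diameter_um == fiber_diameter_um &
    e$composition == composition &
    e$pulse_energy_J == pulse_energy_J &
    e$frequency_Hz == frequency_Hz
  if (sum(hit) == 0L)
    stop(sprintf(paste0("no calibration for (%s, %g um, %s, %g J, %g Hz); ",
                        "add an entry to the rate table"),
                 laser_source, fiber_diameter_um, composition,
                 pulse_energy_J, frequency_Hz))
  if (sum(hit) > 1L) stop("ambiguous calibration: multiple entries match")
  speed <- e$ablation_speed_mm3_per_s[hit]
  if (!is.finite(speed) || speed <= 0) stop("calibrated ablation speed must be > 0")
  structure(list(
    duration_s = volume_mm3 / speed,
    power_W = pulse_energy_J * frequency_Hz,
    ablation_speed_mm3_per_s = speed,
    inputs = list(volume_mm3 = volume_mm3, laser_source = laser_source,
                  fiber_diameter_um = fiber_diameter_um,
                  composition = composition, pulse_energy_J = pulse_energy_J,
                  frequency_Hz = frequency_Hz)
  ), class = "ld_estimate")
}

#' @export
print.ld_estimate <- function(x, ...) {
  cat(sprintf("<ld_estimate> %.1f s (%.1f min) for %.1f mm^3\n",
              x$duration_s, x$duration_s / 60, x$inputs$volume_mm3))
  cat(sprintf("  %s, %g um fiber, %s, %g J x %g Hz = %.1f W, ablation %.3g mm^3/s\n",
              x$inputs$laser_source, x$inputs$fiber_diameter_um,
              x$inputs$composition, x$inputs$pulse_energy_J,
              x$inputs$frequency_Hz, x$power_W, x$ablation_speed_mm3_per_s))
  invisible(x)
}
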