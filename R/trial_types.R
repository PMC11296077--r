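## In-memory trial containers.
##
## Sagittal-plane convention throughout the package: y is the fore-aft axis,
## positive in the runner's direction of progression; z is vertical,
## positive up; the frame is fixed to the treadmill machine (lab frame), so
## the belt surface moves at -belt_speed along y.  The force series is the
## master clock; marker data are aligned to it downstream.

#' Trial metadata
#'
#' Subject and recording metadata for one treadmill trial.
#'
#' @param subject_id character label.
#' @param mass body mass, kg.
#' @param height stature, m.
#' @param belt_speed mean treadmill belt speed, m/s (>= 0).
#' @param target_step_frequency metronome step frequency, steps/s.
#' @param force_rate force sampling rate, Hz.
#' @param marker_rate marker sampling rate, Hz (<= force_rate).
#' @param gravity gravitational acceleration, m/s^2.
#' @return object of class `bw_meta` (a named list).
#' @export
trial_meta <- function(subject_id = "S01", mass, height = NA_real_,
                       belt_speed, target_step_frequency = NA_real_,
                       force_rate = 1000, marker_rate = 200,
                       gravity = 9.81) {
  stopifnot(is.numeric(mass), length(mass) == 1)
  if (!is.finite(mass) || mass <= 0) stop("mass must be > 0", call. = FALSE)
  if (belt_speed < 0) stop("belt_speed must be >= 0", call. = FALSE)
  if (!(force_rate >= marker_rate && marker_rate > 0))
    stop("need force_rate >= marker_rate > 0", call. = FALSE)
  structure(list(subject_id = as.character(subject_id), mass = mass,
                 height = height, belt_speed = belt_speed,
                 target_step_frequency = target_step_frequency,
                 force_rate = force_rate, marker_rate = marker_rate,
                 gravity = gravity),
            class = "bw_meta")
}

#' Force-platform series
#'
#' @param time time stamps, s, uniformly sampled.
#' @param Fy fore-aft ground reaction force, N (positive = direction of
#'   progression).
#' @param Fz vertical ground reaction force, N (positive up).
#' @param COPy fore-aft centre-of-pressure position, m, lab frame.
#' @param cop_threshold vertical force (N) below which the COP is flagged
#'   invalid (default 300 N).
#' @return data.frame of class `bw_forces` with columns time, Fy, Fz, COPy,
#'   valid_cop, and attribute `rate`.
#' @export
force_series <- function(time, Fy, Fz, COPy, cop_threshold = 300) {
  n <- length(time)
  stopifnot(length(Fy) == n, length(Fz) == n, length(COPy) == n, n >= 2)
  dt <- diff(time)
  if (any(abs(dt - dt[1]) > 1e-6 * abs(dt[1])))
    stop("force time stamps are not uniform within 1 ppm", call. = FALSE)
  df <- data.frame(time = time, Fy = Fy, Fz = Fz, COPy = COPy,
                   valid_cop = Fz >= cop_threshold)
  attr(df, "rate") <- 1 / dt[1]
  attr(df, "cop_threshold") <- cop_threshold
  class(df) <- c("bw_forces", "data.frame")
  df
}

#' Marker trajectory table
#'
#' Planar (y, z) marker positions on a common time grid.  Column layout is
#' `<marker>_y`, `<marker>_z` for each marker name.
#'
#' @param time time stamps, s.
#' @param ... named numeric matrices / data.frames with columns y, z, one
#'   per marker, or a single named list passed as `coords`.
#' @param coords optional named list of n-by-2 matrices (y, z).
#' @return data.frame of class `bw_markers` with attribute `markers`
#'   (character vector of names) and `rate`.
#' @export
marker_trajectories <- function(time, ..., coords = NULL) {
  if (is.null(coords)) coords <- list(...)
  stopifnot(length(coords) > 0, !is.null(names(coords)))
  n <- length(time)
  out <- data.frame(time = time)
  for (nm in names(coords)) {
    m <- as.matrix(coords[[nm]])
    stopifnot(nrow(m) == n, ncol(m) == 2)
    out[[paste0(nm, "_y")]] <- m[, 1]
    out[[paste0(nm, "_z")]] <- m[, 2]
  }
  dt <- diff(time)
  attr(out, "rate") <- 1 / stats::median(dt)
  attr(out, "markers") <- names(coords)
  class(out) <- c("bw_markers", "data.frame")
  out
}

#' Names of markers present in a marker table
#' @param markers a `bw_markers` table.
#' @return character vector of marker names.
#' @export
marker_names <- function(markers) attr(markers, "markers")

#' Extract one marker as an n-by-2 (y, z) matrix
#' @param markers a `bw_markers` table.
#' @param name marker name.
#' @return numeric matrix with columns y, z.
#' @export
marker_xy <- function(markers, name) {
  cy <- paste0(name, "_y"); cz <- paste0(name, "_z")
  if (!all(c(cy, cz) %in% names(markers)))
    stop(sprintf("marker '%s' not present", name), call. = FALSE)
  cbind(y = markers[[cy]], z = markers[[cz]])
}

## Markers the lower-limb pipeline cannot run without.
required_markers <- function() {
  c("GT_R", "GT_L", "knee_R", "knee_L", "ankle_R", "ankle_L",
    "heel_R", "heel_L", "VM_R", "VM_L",
    "waist", "backwaist", "neck")
}

#' Raw trial container
#'
#' @param meta a `bw_meta` object.
#' @param forces a `bw_forces` table.
#' @param markers a `bw_markers` table.
#' @return object of class `bw_trial`.
#' @export
raw_trial <- function(meta, forces, markers) {
  stopifnot(inherits(meta, "bw_meta"), inherits(forces, "bw_forces"),
            inherits(markers, "bw_markers"))
  structure(list(meta = meta, forces = forces, markers = markers),
            class = "bw_trial")
}

#' @export
print.bw_trial <- function(x, ...) {
  cat(sprintf("<bw_trial> subject %s, mass %.1f kg, belt %.2f m/s\n",
              x$meta$subject_id, x$meta$mass, x$meta$belt_speed))
  cat(sprintf("  forces : %d samples @ %g Hz (%.2f s)\n", nrow(x$forces),
              attr(x$forces, "rate"), diff(range(x$forces$time))))
  cat(sprintf("  markers: %d samples @ %g Hz, %d markers\n", nrow(x$markers),
              attr(x$markers, "rate"), length(marker_names(x$markers))))
  invisible(x)
}

#' Analysis configuration
#'
#' Tunable parameters of the processing pipeline, with the defaults used
#' throughout the package.
#'
#' @param force_cutoff_hz low-pass cutoff for force channels, Hz.
#' @param marker_cutoff_hz low-pass cutoff for marker channels, Hz.
#' @param filter_order Bessel filter order (even).
#' @param contact_threshold_fraction fraction of body weight defining foot
#'   contact (default 0.10).
#' @param cop_force_threshold_n vertical force below which the centre of
#'   pressure is treated as invalid, N (default 300).
#' @param anthropometric_table_name name of the segment-inertia table
#'   (see [anthropometric_table()]).
#' @param delta_area_mode `"loop"` (hysteresis loop area, default) or
#'   `"literal"` (signed split-integral difference) -- see
#'   [hysteresis_area()].
#' @param random_seed optional integer seed recorded with results.
#' @return object of class `bw_config` (a named list).
#' @export
analysis_config <- function(force_cutoff_hz = 30, marker_cutoff_hz = 30,
                            filter_order = 8,
                            contact_threshold_fraction = 0.10,
                            cop_force_threshold_n = 300,
                            anthropometric_table_name = "winter",
                            delta_area_mode = c("loop", "literal"),
                            random_seed = NULL) {
  if (!(contact_threshold_fraction > 0 && contact_threshold_fraction < 1))
    stop("contact_threshold_fraction must be in (0, 1)", call. = FALSE)
  structure(list(force_cutoff_hz = force_cutoff_hz,
                 marker_cutoff_hz = marker_cutoff_hz,
                 filter_order = filter_order,
                 contact_threshold_fraction = contact_threshold_fraction,
                 cop_force_threshold_n = cop_force_threshold_n,
                 anthropometric_table_name = anthropometric_table_name,
                 delta_area_mode = match.arg(delta_area_mode),
                 random_seed = random_seed),
            class = "bw_config")
}
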