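## End-to-end analysis of one trial.

#' Analyze a treadmill-running trial
#'
#' Runs the full pipeline: filtering and resampling, gait-event
#' segmentation, CoM mechanics and external work, segmental internal work,
#' sagittal inverse dynamics and joint work, the total / soft-tissue work
#' partition, and the per-step spring-mass-actuator fits.
#'
#' @param trial a `bw_trial` (see [read_trial()], [simulate_trial()]).
#' @param config a `bw_config` (defaults from [analysis_config()]).
#' @return list of class `bw_analysis`:
#'   `breakdown` per-stride work partition ([partition_work()]),
#'   `fits` per-step spring fits ([spring_fits_by_step()]),
#'   `summary` one-row condition summary ([aggregate_trial()]),
#'   `curves` data.frame of the energy curves (time, E_kf, E_v, E_com,
#'   E_int per limb and trunk, E_j per limb),
#'   `com` the integrated CoM state, `strides`, `prepared`.
#' @export
analyze_trial <- function(trial, config = analysis_config()) {
  prep <- preprocess_trial(trial, config)
  meta <- prep$meta
  if (nrow(prep$strides$strides) < 1)
    stop("no complete stride found in the trial", call. = FALSE)

  acc <- com_acceleration(prep$forces, meta$mass, meta$gravity)
  com <- integrate_com(acc$a_f, acc$a_v, prep$forces$time, prep$strides)
  en <- external_energies(com, meta$mass, meta$belt_speed, meta$gravity)
  w_com <- stride_work(en$E_com, com)

  tab <- anthropometric_table(config$anthropometric_table_name)
  segs <- build_segments(prep$markers, meta$mass, tab)
  E_int_R <- internal_energy_limb(segs[c("thigh_R", "shank_R", "foot_R")], com)
  E_int_L <- internal_energy_limb(segs[c("thigh_L", "shank_L", "foot_L")], com)
  E_int_tr <- internal_energy_limb(segs["trunk"], com)
  w_int_R <- stride_work(E_int_R, com)
  w_int_L <- stride_work(E_int_L, com)
  w_int_tr <- stride_work(E_int_tr, com)

  joints <- list(); E_j <- list(); w_j <- list()
  for (side in c("R", "L")) {
    ff <- foot_forces(prep$forces, prep$strides, side)
    joints[[side]] <- inverse_dynamics_limb(ff$Fy, ff$Fz, prep$forces$COPy,
                                            prep$forces$valid_cop, ff$loaded,
                                            segs, side, meta$gravity)
    jw <- joint_power_work(joints[[side]], prep$forces$time, com)
    E_j[[side]] <- jw$E_j
    w_j[[side]] <- jw$work
  }

  breakdown <- partition_work(w_com, w_int_R, w_int_L, w_int_tr,
                              w_j$R, w_j$L, meta$mass)
  fits <- spring_fits_by_step(prep)
  summary <- aggregate_trial(breakdown, fits, meta)

  curves <- data.frame(time = prep$forces$time, E_kf = en$E_kf, E_v = en$E_v,
                       E_com = en$E_com, E_int_R = E_int_R, E_int_L = E_int_L,
                       E_int_trunk = E_int_tr, E_j_R = E_j$R, E_j_L = E_j$L)
  structure(list(breakdown = breakdown, fits = fits, summary = summary,
                 curves = curves, com = com, joints = joints,
                 strides = prep$strides, prepared = prep, config = config),
            class = "bw_analysis")
}

#' @export
print.bw_analysis <- function(x, ...) {
  b <- x$breakdown
  cat(sprintf("<bw_analysis> %d strides, %d step fits\n", nrow(b), nrow(x$fits)))
  cat(sprintf("  W_tot+ %.2f  W_tot- %.2f  W_ST+ %.2f  W_ST- %.2f  (J/kg, stride mean)\n",
              mean(b$W_tot_plus_kg), mean(b$W_tot_minus_kg),
              mean(b$W_ST_plus_kg), mean(b$W_ST_minus_kg)))
  if (nrow(x$fits) > 0)
    cat(sprintf("  spring fit: k %.1f N/kg/m, c %.1f N s/kg/m, R2 %.3f, delta_area %.3f J/kg\n",
                mean(x$fits$k), mean(x$fits$c), mean(x$fits$r_squared),
                mean(x$fits$delta_area, na.rm = TRUE)))
  invisible(x)
}

#' Export the per-stride work table
#' @param analysis a `bw_analysis`.
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_breakdown <- function(analysis, path) {
  utils::write.table(analysis$breakdown, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export the per-step spring-fit table
#' @param analysis a `bw_analysis`.
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_spring_fits <- function(analysis, path) {
  utils::write.table(analysis$fits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
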