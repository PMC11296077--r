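## Anthropometry and planar segment kinematics.
##
## Segments are straight lines between marker pairs; inertial properties
## come from a swappable table of standard body-segment fractions.  All
## derivatives are central finite differences on the (filtered) 1 kHz grid,
## with second-order one-sided stencils at the record ends.

#' Anthropometric segment-parameter table
#'
#' Per-segment mass fraction of body mass, CoM position as a fraction of
#' segment length from the proximal end, and radius of gyration about the
#' segment CoM as a fraction of segment length.  The default `"winter"`
#' table carries the standard Winter/Dempster values; the trunk row is the
#' trunk-head-arms compound measured from the hip end.
#'
#' @param name table name; only `"winter"` ships with the package.
#' @param custom optional data.frame with columns `segment`,
#'   `mass_fraction`, `com_fraction`, `gyration_fraction` overriding the
#'   named table (all fractions in (0, 1), summed mass fractions <= 1).
#' @return data.frame with one row per segment (foot, shank, thigh, trunk).
#' @export
anthropometric_table <- function(name = "winter", custom = NULL) {
  if (!is.null(custom)) {
    tab <- custom
  } else if (identical(name, "winter")) {
    tab <- data.frame(
      segment = c("foot", "shank", "thigh", "trunk"),
      mass_fraction = c(0.0145, 0.0465, 0.100, 0.678),
      com_fraction = c(0.50, 0.433, 0.433, 0.626),
      gyration_fraction = c(0.475, 0.302, 0.323, 0.496))
  } else {
    stop(sprintf("unknown anthropometric table '%s'", name), call. = FALSE)
  }
  with(tab, {
    if (any(mass_fraction <= 0 | mass_fraction >= 1) ||
        any(com_fraction <= 0 | com_fraction >= 1) ||
        any(gyration_fraction <= 0 | gyration_fraction >= 1))
      stop("all anthropometric fractions must lie in (0, 1)", call. = FALSE)
    if (sum(mass_fraction) > 1 + 1e-9)
      stop("modelled mass fractions sum to more than 1", call. = FALSE)
  })
  tab
}

## first and second time derivative by central differences, uniform grid
fd_velocity <- function(x, dt) {
  n <- length(x)
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  v[1] <- (-3 * x[1] + 4 * x[2] - x[3]) / (2 * dt)
  v[n] <- (3 * x[n] - 4 * x[n - 1] + x[n - 2]) / (2 * dt)
  v
}

fd_acceleration <- function(x, dt) {
  n <- length(x)
  a <- numeric(n)
  a[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) / dt^2
  a[1] <- (2 * x[1] - 5 * x[2] + 4 * x[3] - x[4]) / dt^2
  a[n] <- (2 * x[n] - 5 * x[n - 1] + 4 * x[n - 2] - x[n - 3]) / dt^2
  a
}

make_segment <- function(prox, dist, mass_total, frac, dt, label) {
  len <- sqrt(rowSums((dist - prox)^2))
  L <- stats::median(len)
  if (L < 0.01)
    stop(sprintf("segment '%s' has near-zero length (%.3f m)", label, L),
         call. = FALSE)
  if (stats::sd(len) / L > 0.05)
    warning(sprintf("segment '%s' length varies by more than 5%% (CV %.1f%%)",
                    label, 100 * stats::sd(len) / L), call. = FALSE)
  m <- mass_total * frac$mass_fraction
  I <- m * (frac$gyration_fraction * L)^2
  com <- prox + frac$com_fraction * (dist - prox)
  vel <- cbind(fd_velocity(com[, 1], dt), fd_velocity(com[, 2], dt))
  acc <- cbind(fd_acceleration(com[, 1], dt), fd_acceleration(com[, 2], dt))
  ang_raw <- atan2(dist[, 2] - prox[, 2], dist[, 1] - prox[, 1])
  ang <- unwrap_angle(ang_raw)
  omega <- fd_velocity(ang, dt)
  alpha <- fd_acceleration(ang, dt)
  list(label = label, prox = prox, dist = dist, com = com, vel = vel,
       acc = acc, angle = ang, omega = omega, alpha = alpha,
       mass = m, inertia = I, length = L)
}

unwrap_angle <- function(a) {
  d <- diff(a)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(a[1], a[1] + cumsum(d))
}

#' Build planar segment states from markers
#'
#' Segment definitions: thigh GT-knee, shank knee-ankle, foot
#' ankle-midpoint(heel, VM), per side; trunk midpoint(waist, backwaist)-neck.
#' Angles are measured from the horizontal (y axis); angular and linear
#' velocities and accelerations come from central differences.
#'
#' @param markers a `bw_markers` table on a uniform grid (filtered).
#' @param mass body mass, kg.
#' @param table anthropometric table from [anthropometric_table()].
#' @return named list of segment states (`thigh_R`, `shank_R`, `foot_R`,
#'   same for `_L`, and `trunk`), each a list with fields `com`, `vel`,
#'   `acc` (n-by-2), `angle`, `omega`, `alpha`, `mass`, `inertia`,
#'   `length`, `prox`, `dist`.
#' @export
build_segments <- function(markers, mass, table = anthropometric_table()) {
  dt <- 1 / attr(markers, "rate")
  row <- function(seg) table[table$segment == seg, ]
  segs <- list()
  for (side in c("R", "L")) {
    gt <- marker_xy(markers, paste0("GT_", side))
    kn <- marker_xy(markers, paste0("knee_", side))
    ak <- marker_xy(markers, paste0("ankle_", side))
    he <- marker_xy(markers, paste0("heel_", side))
    vm <- marker_xy(markers, paste0("VM_", side))
    segs[[paste0("thigh_", side)]] <- make_segment(gt, kn, mass, row("thigh"),
                                                   dt, paste0("thigh_", side))
    segs[[paste0("shank_", side)]] <- make_segment(kn, ak, mass, row("shank"),
                                                   dt, paste0("shank_", side))
    segs[[paste0("foot_", side)]] <- make_segment(ak, (he + vm) / 2, mass,
                                                  row("foot"), dt,
                                                  paste0("foot_", side))
  }
  hip <- (marker_xy(markers, "waist") + marker_xy(markers, "backwaist")) / 2
  segs$trunk <- make_segment(hip, marker_xy(markers, "neck"), mass,
                             row("trunk"), dt, "trunk")
  segs
}

#' Segment CoM velocity relative to the whole-body CoM
#'
#' @param seg one segment state from [build_segments()].
#' @param com a `bw_com` (force-derived CoM velocities).
#' @return numeric vector: magnitude of the relative velocity, m/s (NA
#'   outside complete strides, where the CoM velocity is undefined).
#' @export
segment_relative_velocity <- function(seg, com) {
  sqrt((seg$vel[, 1] - com$v_f)^2 + (seg$vel[, 2] - com$v_v)^2)
}
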