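## Centre-of-mass mechanics from ground reaction forces.
##
## The CoM acceleration comes straight from Newton's law per axis
## (a_f = F_y/m, a_v = F_z/m - g); velocities and the vertical displacement
## follow by trapezoidal integration per stride, with the integration
## constants fixed so that the stride-mean lab-frame velocity is zero on
## both axes (steady treadmill running: the runner is stationary on
## average in the machine frame).

#' CoM acceleration from forces
#'
#' @param forces a `bw_forces` table (filtered).
#' @param mass body mass, kg (> 0).
#' @param gravity gravitational acceleration, m/s^2.
#' @return list with numeric vectors `a_f` (fore-aft) and `a_v` (vertical),
#'   m/s^2.
#' @export
com_acceleration <- function(forces, mass, gravity = 9.81) {
  if (!is.finite(mass) || mass <= 0) stop("mass must be > 0", call. = FALSE)
  list(a_f = forces$Fy / mass, a_v = forces$Fz / mass - gravity)
}

cumtrapz1 <- function(t, x) as.numeric(pracma::cumtrapz(t, x))

## time average over the stride by the trapezoidal rule -- the natural
## mean for trapezoid-integrated series (plain sample means double-count
## the shared boundary sample of consecutive strides)
tmean <- function(t, x) pracma::trapz(t, x) / (t[length(t)] - t[1])

#' Integrate CoM acceleration per stride
#'
#' Trapezoidal cumulative integration of the CoM accelerations over each
#' stride.  Integration constants are applied per stride: the stride time
#' average (trapezoidal) of v_f and of v_v is zero in the lab frame, and
#' the vertical displacement S_v is re-zeroed to stride time average 0.
#'
#' @param a_f,a_v CoM accelerations, m/s^2, on the force grid.
#' @param time time stamps, s.
#' @param strides a `bw_strides` segmentation (>= 1 complete stride).
#' @return list of class `bw_com`: `v_f`, `v_v` (m/s), `S_v` (m), all NA
#'   outside complete strides; `stride_rows` (list of index vectors,
#'   one per stride).
#' @export
integrate_com <- function(a_f, a_v, time, strides) {
  st <- strides$strides
  if (nrow(st) < 1) stop("no complete stride to integrate", call. = FALSE)
  n <- length(time)
  v_f <- rep(NA_real_, n); v_v <- rep(NA_real_, n); S_v <- rep(NA_real_, n)
  rows <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    # stride rows inclusive of the closing touchdown sample, so consecutive
    # stride curves share their boundary sample
    r <- st$start[i]:st$end[i]
    if (length(r) < 3) stop("stride shorter than 3 samples", call. = FALSE)
    tt <- time[r]
    vf <- cumtrapz1(tt, a_f[r]); vf <- vf - tmean(tt, vf)
    vv <- cumtrapz1(tt, a_v[r]); vv <- vv - tmean(tt, vv)
    sv <- cumtrapz1(tt, vv);     sv <- sv - tmean(tt, sv)
    v_f[r] <- vf; v_v[r] <- vv; S_v[r] <- sv
    rows[[i]] <- r
  }
  structure(list(v_f = v_f, v_v = v_v, S_v = S_v, time = time,
                 stride_rows = rows),
            class = "bw_com")
}

#' External energy curves of the CoM
#'
#' Closed-form energy curves from the integrated CoM state:
#' `E_kf = 1/2 m (v_f - v_belt)^2` -- the fore-aft kinetic energy in the
#' frame of the belt surface, which moves at `-V_avg` along the
#' progression axis, so `E_kf = 1/2 m (v_f + V_avg)^2`;
#' `E_v = 1/2 m v_v^2 + m g S_v`; `E_com = E_kf + E_v`.
#'
#' @param com a `bw_com` from [integrate_com()].
#' @param mass body mass, kg.
#' @param V_avg mean belt speed, m/s.
#' @param gravity gravitational acceleration, m/s^2.
#' @return list with vectors `E_kf`, `E_v`, `E_com` (J) on the force grid.
#' @export
external_energies <- function(com, mass, V_avg, gravity = 9.81) {
  E_kf <- 0.5 * mass * (com$v_f + V_avg)^2
  E_v <- 0.5 * mass * com$v_v^2 + mass * gravity * com$S_v
  list(E_kf = E_kf, E_v = E_v, E_com = E_kf + E_v)
}

#' Signed work increments of an energy curve over a stride
#'
#' Sums the positive and the negative sample-to-sample increments of an
#' energy curve, with no smoothing or dead band.  The two sums telescope:
#' `W_plus + W_minus == E_end - E_start` exactly.
#'
#' @param E energy curve, J.
#' @param rows index vector of the stride (ordered).
#' @return list with `W_plus` (>= 0) and `W_minus` (<= 0), J.
#' @export
work_increments <- function(E, rows) {
  dE <- diff(E[rows])
  list(W_plus = sum(pmax(dE, 0)), W_minus = sum(pmin(dE, 0)))
}

#' Work increments per stride for one curve
#' @param E energy curve, J.
#' @param com a `bw_com` (provides the stride index rows).
#' @return data.frame stride_id, W_plus, W_minus.
#' @export
stride_work <- function(E, com) {
  out <- lapply(seq_along(com$stride_rows), function(i) {
    w <- work_increments(E, com$stride_rows[[i]])
    data.frame(stride_id = i, W_plus = w$W_plus, W_minus = w$W_minus)
  })
  do.call(rbind, out)
}
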