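## Synthetic treadmill-running trials with known ground truth.
##
## Construction (force-first, kinematics constrained to match):
##   1. Prescribe a feasible periodic ground reaction force: one half-sine
##      vertical burst per step whose stride impulse balances body weight
##      (flight force exactly zero), and a braking-then-propulsion
##      fore-aft sinusoid with zero net impulse.
##   2. Integrate the force to the exact CoM trajectory (trapezoidal rule,
##      the same scheme the pipeline uses).
##   3. Prescribe foot trajectories: the stance foot rides the belt
##      (translation at -V, no rotation); swing is a C2 quintic with a
##      clearance bump.  Knees follow by two-link inverse kinematics.
##   4. Solve the trunk position per frame so that the anthropometric
##      mass-weighted CoM of all seven model segments equals the
##      force-derived CoM exactly.  Global Newton consistency is then an
##      identity: the emitted force IS the rigid-segment total, which is
##      what makes the rigid-mode soft-tissue null test meaningful.
##   5. Optional wobble mode: the trunk is split into a rigid remainder and
##      a wobbling point mass connected by a vertical spring-damper.
##      During stance the wobble's inertial force flows into the ground
##      reaction force (the whole-body CoM deviates accordingly); during
##      flight it flows into a recoil of the rigid skeleton so the force
##      stays exactly zero; a smooth stance weight blends the two routes.
##      The oscillator is integrated in the time domain including the
##      recoil feedback, and the damper's dissipated energy per stride
##      goes to the ledger.  The construction stays dynamically consistent
##      at every instant, so the net joint work per stride equals the
##      ledger dissipation identically -- that is what the differencing
##      test recovers.
##   6. Configured instrument noise is applied last.

#' Simulation parameters
#'
#' Defaults mirror the study population and protocol: a 73.7 kg, 1.84 m
#' runner on a treadmill grid of 8-17 km/h and 2.0-3.6 steps/s.
#'
#' @param mass body mass, kg.
#' @param height stature, m.
#' @param belt_speed belt speed, m/s.
#' @param step_frequency target step frequency, steps/s (snapped to the
#'   force grid so a stride is a whole number of samples).
#' @param duty_factor contact time / step period, in (0, 1); `NULL`
#'   (default) picks a speed-dependent contact time typical of running.
#' @param n_strides number of complete strides to generate (default 10,
#'   the study's per-trial count).
#' @param impact_amplitude_bw amplitude of the early-stance impact
#'   transient added to the vertical force, in body weights (default 0.5,
#'   a typical rearfoot impact peak); the transient lasts 60 ms and the
#'   active-peak amplitude is rescaled so the stride impulse still
#'   balances body weight.
#' @param spring numeric `c(cst, k, c)` for [simulate_spring_loop()].
#' @param wobble `NULL` for rigid mode, or a list/vector with
#'   `mass_fraction` (< 0.3), `freq_hz`, `zeta` for the wobbling-mass
#'   element (defaults 0.15, 10 Hz, 0.4).
#' @param force_noise_sd additive force noise SD, N (default 0).
#' @param marker_noise_sd additive marker noise SD, m (default 0).
#' @param seed integer seed; mandatory when any noise SD is nonzero.
#' @param force_rate,marker_rate sampling rates, Hz.
#' @return object of class `bw_simparams`.
#' @export
sim_params <- function(mass = 73.7, height = 1.84, belt_speed = 14 / 3.6,
                       step_frequency = 2.8, duty_factor = NULL,
                       n_strides = 10, impact_amplitude_bw = 0.5,
                       spring = c(cst = 2, k = 30, c = -5),
                       wobble = NULL, force_noise_sd = 0,
                       marker_noise_sd = 0, seed = NULL,
                       force_rate = 1000, marker_rate = 200) {
  if (!is.null(duty_factor) && !(duty_factor > 0 && duty_factor < 1))
    stop("duty_factor must be in (0, 1)", call. = FALSE)
  if (!is.null(wobble)) {
    wobble <- as.list(wobble)
    wobble$mass_fraction <- wobble$mass_fraction %||% 0.15
    wobble$freq_hz <- wobble$freq_hz %||% 10
    wobble$zeta <- wobble$zeta %||% 0.4
    if (wobble$mass_fraction >= 0.3)
      stop("wobble mass fraction must be < 0.3", call. = FALSE)
  }
  if ((force_noise_sd > 0 || marker_noise_sd > 0) && is.null(seed))
    stop("a seed is mandatory when noise is enabled", call. = FALSE)
  structure(list(mass = mass, height = height, belt_speed = belt_speed,
                 step_frequency = step_frequency, duty_factor = duty_factor,
                 n_strides = n_strides,
                 impact_amplitude_bw = impact_amplitude_bw,
                 spring = spring, wobble = wobble,
                 force_noise_sd = force_noise_sd,
                 marker_noise_sd = marker_noise_sd, seed = seed,
                 force_rate = force_rate, marker_rate = marker_rate),
            class = "bw_simparams")
}

## Default contact time, s: rough fit to published running contact times
## over the study's speed range, capped so the stance sweep V*t_c stays
## inside the reach of the model leg and below the step period.
default_contact_time <- function(V, T_step) {
  min(0.13 + 0.25 / max(V, 0.5), 0.80 * T_step, 0.70 / max(V, 0.5))
}

## quintic Hermite with endpoint position/velocity/acceleration
quintic <- function(tau, T, p0, p1, v0, v1, a0 = 0, a1 = 0) {
  s <- tau / T
  h <- cbind(1 - 10 * s^3 + 15 * s^4 - 6 * s^5,
             s - 6 * s^3 + 8 * s^4 - 3 * s^5,
             0.5 * s^2 - 1.5 * s^3 + 1.5 * s^4 - 0.5 * s^5,
             10 * s^3 - 15 * s^4 + 6 * s^5,
             -4 * s^3 + 7 * s^4 - 3 * s^5,
             0.5 * s^3 - s^4 + 0.5 * s^5)
  h %*% c(p0, v0 * T, a0 * T^2, p1, v1 * T, a1 * T^2)
}

## model geometry shared by generator and vignette; the CoM sits lower than
## a standing posture (crouched running model) so the leg keeps flexion
## reserve at touchdown across the whole speed/frequency grid
model_geometry <- function(height) {
  list(thigh_len = 0.245 * height,
       shank_len = 0.246 * height,
       trunk_len = 0.30 * height,
       ankle_h = 0.08,
       z_com0 = 0.49 * height,
       heel_off = c(-0.07, -0.06),
       vm_off = c(0.15, -0.06))
}

## two-link inverse kinematics, anterior knee branch (vectorized)
knee_ik <- function(hip, ankle, L1, L2, when = "") {
  d2 <- rowSums((ankle - hip)^2)
  d <- sqrt(d2)
  if (any(d > 0.995 * (L1 + L2)))
    stop(sprintf("infeasible parameters: leg reach exceeded%s (max %.3f of %.3f m)",
                 when, max(d), L1 + L2), call. = FALSE)
  x <- (d2 + L1^2 - L2^2) / (2 * d)
  h <- sqrt(pmax(L1^2 - x^2, 0))
  u <- (ankle - hip) / d
  n <- cbind(-u[, 2], u[, 1])          # +90 deg: anterior for a downward leg
  hip + u * x + n * h
}

#' Simulate one treadmill-running trial with ground truth
#'
#' @param params a [sim_params()] object.
#' @param seed optional integer overriding `params$seed`.
#' @return list of class `bw_simtrial` with elements
#'   `trial` (a [raw_trial()]: forces at 1 kHz, markers at 200 Hz) and
#'   `truth` (ledger): `params` (with grid-snapped frequency), `com`
#'   (time, y, z, vy, vz of the true CoM), `contacts` (foot, onset,
#'   offset indices and times on the force grid), `strides` (start/end
#'   indices), `joints` (per side: time, M/P per joint from the
#'   construction's own Newton-Euler balance on the clean signals),
#'   `wobble` (per-stride dissipated energy, J; zero rows in rigid mode),
#'   `markers_1khz` (clean 1 kHz marker table), `forces_clean` (clean
#'   force table).
#' @export
simulate_trial <- function(params, seed = NULL) {
  p <- params
  seed <- seed %||% p$seed
  fs <- p$force_rate
  m <- p$mass; g <- 9.81; V <- p$belt_speed
  geom <- model_geometry(p$height)

  ## --- timing, snapped to the force grid ---
  n_step <- round(fs / p$step_frequency)
  T_step <- n_step / fs
  f_actual <- 1 / T_step
  t_c <- if (is.null(p$duty_factor)) default_contact_time(V, T_step)
         else p$duty_factor * T_step
  n_c <- max(20L, round(t_c * fs)); t_c <- n_c / fs
  if (n_c >= n_step) stop("infeasible parameters: no flight phase (duty >= 1)",
                          call. = FALSE)
  n_stride <- 2L * n_step
  ## long flight phases need extension reserve: crouch deeper when the
  ## ballistic rise exceeds 5 cm so the legs can still reach the belt
  flight_rise <- g * (T_step - t_c)^2 / 8
  geom$z_com0 <- geom$z_com0 - 0.5 * max(0, flight_rise - 0.05)
  lead <- round(0.25 * n_step)               # samples before the first right TD
  ## the record ends inside the closing right contact so the force never
  ## leaves the body in free fall beyond the analysed span
  n_tot <- lead + p$n_strides * n_stride + round(0.6 * n_c)
  time <- (seq_len(n_tot) - 1) / fs
  t_td_R <- lead / fs + (0:p$n_strides) * (n_stride / fs)
  t_td_L <- t_td_R[-length(t_td_R)] + T_step

  ## --- prescribed GRF: half-sine active peak + early-stance impact
  ##     transient, with the stride impulse balancing body weight ---
  t_imp <- min(0.06, 0.4 * t_c)              # impact transient duration
  A_imp <- p$impact_amplitude_bw * m * g
  I_imp <- A_imp * t_imp / 2                 # impulse of the sin^2 bump
  Fpk <- pi / 2 * (m * g * T_step - I_imp) / t_c
  if (Fpk <= 0) stop("infeasible parameters: impact transient carries more than
 the body-weight impulse", call. = FALSE)
  Apk <- m * g * min(0.10 + 0.06 * V, 0.45)  # fore-aft amplitude
  burst <- function(td) {
    Fz <- numeric(n_tot); Fy <- numeric(n_tot)
    for (t0 in td) {
      i0 <- round(t0 * fs) + 1L
      ii <- i0:(i0 + n_c - 1L)
      keep <- ii >= 1 & ii <= n_tot
      tau <- (ii[keep] - i0) / fs
      Fz[ii[keep]] <- Fz[ii[keep]] + Fpk * sin(pi * tau / t_c) +
        A_imp * ifelse(tau < t_imp, sin(pi * tau / t_imp)^2, 0)
      Fy[ii[keep]] <- Fy[ii[keep]] - Apk * sin(2 * pi * tau / t_c)
    }
    list(Fz = Fz, Fy = Fy)
  }
  bR <- burst(t_td_R); bL <- burst(t_td_L)
  Fz_rigid <- bR$Fz + bL$Fz
  Fy_tot <- bR$Fy + bL$Fy

  ## --- exact CoM by trapezoidal integration (the pipeline's scheme) ---
  a_v <- Fz_rigid / m - g
  a_f <- Fy_tot / m
  ## analysis span: complete strides only, for the zero-mean constants
  i_first <- round(t_td_R[1] * fs) + 1L
  i_last <- round(t_td_R[length(t_td_R)] * fs) + 1L
  span <- i_first:i_last
  vy <- cumtrapz1(time, a_f); vy <- vy - mean(vy[span])
  vz <- cumtrapz1(time, a_v); vz <- vz - mean(vz[span])
  y_com <- cumtrapz1(time, vy); y_com <- y_com - mean(y_com[span])
  z_com <- geom$z_com0 + {s <- cumtrapz1(time, vz); s - mean(s[span])}

  ## --- foot (ankle-point) trajectories ---
  ## stance: the foot rides the belt (velocity -V, no rotation).  Swing has
  ## three C2-joined quintic phases: (A) decelerate from belt speed to rest,
  ## (B) carry the foot forward past the hip, (C) "paw back" so the foot
  ## meets the belt already moving at -V when it touches down.
  y_td <- V * t_c / 2                    # full swept span centred under the hip
  T_sw <- n_stride / fs - t_c
  t1 <- min(0.05, 0.20 * T_sw)           # phase A duration
  t3 <- min(0.05, 0.15 * T_sw)           # phase C duration
  y_to <- y_td - V * t_c
  y_A <- y_to - 0.45 * V * t1            # rest point behind the body
  y_C <- y_td + 0.45 * V * t3            # forward-most point before paw-back
  swing_y <- function(tau) {
    out <- numeric(length(tau))
    a <- tau < t1
    b <- tau >= t1 & tau < T_sw - t3
    cc <- tau >= T_sw - t3
    if (any(a)) out[a] <- quintic(tau[a], t1, y_to, y_A, -V, 0)
    if (any(b)) out[b] <- quintic(tau[b] - t1, T_sw - t1 - t3, y_A, y_C, 0, 0)
    if (any(cc)) out[cc] <- quintic(tau[cc] - (T_sw - t3), t3, y_C, y_td, 0, -V)
    out
  }
  ankle_path <- function(td) {
    y <- numeric(n_tot); z <- rep(geom$ankle_h, n_tot)
    for (t0 in c(td[1] - n_stride / fs, td)) {       # include the cycle before
      i0 <- round(t0 * fs) + 1L
      ii_st <- i0:(i0 + n_c - 1L)
      tau <- (ii_st - i0) / fs
      keep <- ii_st >= 1 & ii_st <= n_tot
      y[ii_st[keep]] <- y_td - V * tau[keep]
      ii_sw <- (i0 + n_c):(i0 + n_stride - 1L)
      tau <- (ii_sw - i0 - n_c) / fs
      keep <- ii_sw >= 1 & ii_sw <= n_tot
      y[ii_sw[keep]] <- swing_y(tau[keep])
      z[ii_sw[keep]] <- geom$ankle_h + 0.12 * sin(pi * tau[keep] / T_sw)^3
    }
    cbind(y, z)
  }
  ank_R <- ankle_path(t_td_R)
  ank_L <- ankle_path(t_td_L)

  ## --- solve the trunk so the model CoM equals the force CoM ---
  tab <- anthropometric_table()
  frac <- function(s, f) tab[tab$segment == s, f]
  mT <- frac("thigh", "mass_fraction"); cT <- frac("thigh", "com_fraction")
  mS <- frac("shank", "mass_fraction"); cS <- frac("shank", "com_fraction")
  mF <- frac("foot", "mass_fraction"); cF <- frac("foot", "com_fraction")
  mTr <- frac("trunk", "mass_fraction"); cTr <- frac("trunk", "com_fraction")
  foot_dist_off <- (geom$heel_off + geom$vm_off) / 2
  com_target <- cbind(y_com, z_com)
  o_hip <- c(0, -cTr * geom$trunk_len)       # hip point relative to trunk CoM
  hip <- cbind(y_com, z_com - 0.15)          # initial guess
  leg_mass_moment <- function(hip, ankle) {
    knee <- knee_ik(hip, ankle, geom$thigh_len, geom$shank_len)
    foot_com <- ankle + matrix(cF * foot_dist_off, n_tot, 2, byrow = TRUE)
    list(knee = knee,
         mm = mT * ((1 - cT) * hip + cT * knee) +
              mS * ((1 - cS) * knee + cS * ankle) + mF * foot_com)
  }
  ## place the trunk rigid part: its CoM absorbs the wobble bookkeeping
  ## term -(m_w/m) (1 - chi) r so the whole-body CoM lands exactly on
  ## com_target + d (d = the wobble-induced CoM deviation, stance only)
  solve_hip <- function(wob_term) {
    hip <- cbind(y_com, z_com - 0.15)
    off <- matrix(o_hip, n_tot, 2, byrow = TRUE)
    delta <- Inf
    for (it in 1:80) {
      lr <- leg_mass_moment(hip, ank_R)
      ll <- leg_mass_moment(hip, ank_L)
      trunk_part <- (com_target - lr$mm - ll$mm) / mTr
      trunk_part[, 2] <- trunk_part[, 2] - wob_term / mTr
      hip_new <- trunk_part + off
      delta <- max(abs(hip_new - hip))
      hip <- hip_new
      if (delta < 1e-12) break
    }
    if (delta >= 1e-9)
      stop("trunk placement did not converge; parameters likely infeasible",
           call. = FALSE)
    list(hip = hip, trunk_part = trunk_part)
  }
  sol <- solve_hip(numeric(n_tot))

  ## --- wobble element ---
  Fz_tot <- Fz_rigid
  wobble_df <- data.frame(stride_id = integer(), dissipation = numeric())
  d_dev <- numeric(n_tot)                # CoM deviation (z) from the wobble
  if (!is.null(p$wobble)) {
    w <- as.list(p$wobble)
    w$mass_fraction <- w$mass_fraction %||% 0.15
    w$freq_hz <- w$freq_hz %||% 10
    w$zeta <- w$zeta %||% 0.4
    p$wobble <- w
    m_t <- mTr * m                       # trunk assembly mass
    m_w <- w$mass_fraction * m
    if (m_w >= m_t)
      stop("wobble mass fraction must be below the trunk mass fraction",
           call. = FALSE)
    om_w <- 2 * pi * w$freq_hz
    c_w <- 2 * w$zeta * om_w * m_w       # damper coefficient, N s/m
    ## stance weight: quintic-smoothstep time ramps inside each contact,
    ## exactly 0 in flight, with zero slope and curvature at the edges
    chi <- numeric(n_tot)
    t_r <- 0.30 * t_c
    sstep <- function(x) ifelse(x <= 0, 0, ifelse(x >= 1, 1,
                                x^3 * (10 - 15 * x + 6 * x^2)))
    for (t0 in c(t_td_R, t_td_L)) {
      i0 <- round(t0 * fs) + 1L
      ii <- i0:(i0 + n_c - 1L)
      keep <- ii >= 1 & ii <= n_tot
      tau <- (ii[keep] - i0) / fs
      chi[ii[keep]] <- pmin(sstep(tau / t_r), sstep((t_c - tau) / t_r))
    }
    dt <- 1 / fs
    r <- numeric(n_tot); rd <- numeric(n_tot)
    for (outer in 1:4) {
      ## forcing = -(g + acc of the trunk rigid part); the recoil feedback
      ## enters through x_t from the previous pass
      axt <- fd_acceleration(sol$trunk_part[, 2], dt)
      f_in <- -(g + axt)
      ## RK4 on r'' = -om^2 r - 2 zeta om r' + f_in, from rest equilibrium
      r[1] <- f_in[1] / om_w^2; rd[1] <- 0
      for (i in seq_len(n_tot - 1L)) {
        fi <- f_in[i]; fm <- 0.5 * (f_in[i] + f_in[i + 1L]); fp <- f_in[i + 1L]
        acc <- function(rr, vv, ff) ff - om_w^2 * rr - 2 * w$zeta * om_w * vv
        k1r <- rd[i];            k1v <- acc(r[i], rd[i], fi)
        k2r <- rd[i] + dt/2*k1v; k2v <- acc(r[i] + dt/2*k1r, k2r, fm)
        k3r <- rd[i] + dt/2*k2v; k3v <- acc(r[i] + dt/2*k2r, k3r, fm)
        k4r <- rd[i] + dt*k3v;   k4v <- acc(r[i] + dt*k3r, k4r, fp)
        r[i + 1L] <- r[i] + dt/6*(k1r + 2*k2r + 2*k3r + k4r)
        rd[i + 1L] <- rd[i] + dt/6*(k1v + 2*k2v + 2*k3v + k4v)
      }
      sol <- solve_hip((m_w / m) * (1 - chi) * r)
    }
    d_dev <- (m_w / m) * chi * r
    Fz_tot <- Fz_rigid + m * fd_acceleration(d_dev, dt)
    if (min(Fz_tot) < 0) {
      if (min(Fz_tot) < -10)
        stop("infeasible parameters: wobble drives the vertical force negative",
             call. = FALSE)
      ## clamp the few-N dips at contact edges; the consistency error this
      ## introduces is millijoule-scale
      Fz_tot <- pmax(Fz_tot, 0)
    }
    ## damper loss per stride
    diss <- vapply(seq_len(p$n_strides), function(k) {
      rows <- (i_first + (k - 1L) * n_stride):(i_first + k * n_stride)
      c_w * pracma::trapz(time[rows], rd[rows]^2)
    }, numeric(1))
    wobble_df <- data.frame(stride_id = seq_len(p$n_strides),
                            dissipation = diss)
    ## true CoM now includes the wobble deviation
    z_com <- z_com + d_dev
    vz <- vz + fd_velocity(d_dev, dt)
  }
  hip <- sol$hip
  knee_R <- knee_ik(hip, ank_R, geom$thigh_len, geom$shank_len)
  knee_L <- knee_ik(hip, ank_L, geom$thigh_len, geom$shank_len)

  ## --- COP ---
  copy <- rep(NA_real_, n_tot)
  fill_cop <- function(copy, td, ank) {
    for (t0 in td) {
      i0 <- round(t0 * fs) + 1L
      ii <- i0:(i0 + n_c - 1L)
      keep <- ii >= 1 & ii <= n_tot
      tau <- (ii[keep] - i0) / fs
      copy[ii[keep]] <- ank[ii[keep], 1] + (-0.05 + 0.17 * tau / t_c)
    }
    copy
  }
  copy <- fill_cop(copy, t_td_R, ank_R)
  copy <- fill_cop(copy, t_td_L, ank_L)
  copy <- stats::approx(time[!is.na(copy)], copy[!is.na(copy)], xout = time,
                        rule = 2)$y

  ## --- markers (clean, 1 kHz) ---
  rep_off <- function(off) matrix(off, n_tot, 2, byrow = TRUE)
  mk <- list(
    GT_R = hip, GT_L = hip,
    knee_R = knee_R, knee_L = knee_L,
    ankle_R = ank_R, ankle_L = ank_L,
    heel_R = ank_R + rep_off(geom$heel_off),
    heel_L = ank_L + rep_off(geom$heel_off),
    VM_R = ank_R + rep_off(geom$vm_off),
    VM_L = ank_L + rep_off(geom$vm_off),
    waist = hip + rep_off(c(0.06, 0)),
    backwaist = hip + rep_off(c(-0.06, 0)),
    neck = hip + rep_off(c(0, geom$trunk_len)))
  markers_1k <- marker_trajectories(time, coords = mk)

  ## --- contact / stride truth tables ---
  idx_td_R <- round(t_td_R * fs) + 1L
  idx_td_L <- round(t_td_L * fs) + 1L
  contacts <- rbind(
    data.frame(foot = "R", onset = idx_td_R, offset = pmin(idx_td_R + n_c, n_tot + 1L)),
    data.frame(foot = "L", onset = idx_td_L, offset = pmin(idx_td_L + n_c, n_tot + 1L)))
  contacts <- contacts[order(contacts$onset), ]
  strides_truth <- data.frame(stride_id = seq_len(p$n_strides),
                              start = idx_td_R[-length(idx_td_R)],
                              end = idx_td_R[-1])

  ## --- ledger joint kinetics from the clean construction ---
  forces_clean <- force_series(time, Fy_tot, Fz_tot, copy)
  segs_clean <- build_segments(markers_1k, m)
  joints <- list()
  for (side in c("R", "L")) {
    td <- if (side == "R") t_td_R else t_td_L
    loaded <- rep(FALSE, n_tot)
    for (t0 in td) {
      i0 <- round(t0 * fs) + 1L
      ii <- i0:(i0 + n_c - 1L)
      loaded[ii[ii >= 1 & ii <= n_tot]] <- TRUE
    }
    jj <- inverse_dynamics_limb(ifelse(loaded, Fy_tot, 0),
                                ifelse(loaded, Fz_tot, 0),
                                copy, forces_clean$valid_cop, loaded,
                                segs_clean, side, g)
    joints[[side]] <- data.frame(time = time,
                                 M_ankle = jj$ankle$M, M_knee = jj$knee$M,
                                 M_hip = jj$hip$M, P_ankle = jj$ankle$P,
                                 P_knee = jj$knee$P, P_hip = jj$hip$P,
                                 P_limb = jj$P_limb)
  }

  ## --- noise, output containers ---
  Fy_out <- Fy_tot; Fz_out <- Fz_tot
  mk_out <- mk
  if (p$force_noise_sd > 0 || p$marker_noise_sd > 0) {
    set.seed(seed)
    if (p$force_noise_sd > 0) {
      Fy_out <- Fy_out + stats::rnorm(n_tot, 0, p$force_noise_sd)
      Fz_out <- pmax(Fz_out + stats::rnorm(n_tot, 0, p$force_noise_sd), 0)
    }
    if (p$marker_noise_sd > 0)
      mk_out <- lapply(mk_out, function(x)
        x + matrix(stats::rnorm(length(x), 0, p$marker_noise_sd), nrow(x), 2))
  }
  dec <- seq(1, n_tot, by = round(fs / p$marker_rate))
  markers_out <- marker_trajectories(time[dec],
                                     coords = lapply(mk_out, function(x)
                                       x[dec, , drop = FALSE]))
  meta <- trial_meta(subject_id = "sim", mass = m, height = p$height,
                     belt_speed = V, target_step_frequency = f_actual,
                     force_rate = fs, marker_rate = p$marker_rate, gravity = g)
  trial <- raw_trial(meta, force_series(time, Fy_out, Fz_out, copy),
                     markers_out)

  p$step_frequency_actual <- f_actual
  p$contact_time <- t_c
  truth <- list(params = p,
                com = data.frame(time = time, y = y_com, z = z_com,
                                 vy = vy, vz = vz),
                contacts = contacts, strides = strides_truth,
                joints = joints, wobble = wobble_df,
                markers_1khz = markers_1k, forces_clean = forces_clean)
  structure(list(trial = trial, truth = truth), class = "bw_simtrial")
}

#' Simulate force-length loops driven by a known spring-actuator law
#'
#' Direct test harness for the spring-actuator regression: per step,
#' `L_leg(t) = L0 - A (1 - cos(w t))` over one full cycle and
#' `F_projected = cst + k L_leg + c V_leg` plus optional noise.  The true
#' hysteresis area of the law, `-c * integral(V^2) dt` by quadrature, goes
#' to the ledger.
#'
#' @param n_steps number of simulated steps.
#' @param spring numeric `c(cst, k, c)` in mass-specific units (N/kg,
#'   N kg^-1 m^-1, N s kg^-1 m^-1).
#' @param L0 leg length at touchdown, m.
#' @param amplitude compression amplitude A, m.
#' @param period loop period, s (angular frequency `2*pi/period`).
#' @param rate sampling rate, Hz.
#' @param noise_sd additive noise on the projected force, N/kg.
#' @param seed integer seed (mandatory when `noise_sd > 0`).
#' @return list of class `bw_simloop`: `steps` (list of data.frames with
#'   `time`, `L_leg`, `V_leg`, `F_projected`), `truth` (list: `spring`,
#'   `delta_area` -- quadrature value of `-c * int V^2 dt`).
#' @export
simulate_spring_loop <- function(n_steps = 50, spring = c(cst = 2, k = 30, c = -5),
                                 L0 = 1.0, amplitude = 0.05, period = 0.3,
                                 rate = 1000, noise_sd = 0, seed = NULL) {
  if (noise_sd > 0 && is.null(seed))
    stop("a seed is mandatory when noise is enabled", call. = FALSE)
  k <- unname(spring[2])
  if (k <= 0) stop("spring stiffness k must be > 0", call. = FALSE)
  om <- 2 * pi / period
  tt <- seq(0, period, by = 1 / rate)
  L <- L0 - amplitude * (1 - cos(om * tt))
  Vl <- -amplitude * om * sin(om * tt)
  F0 <- unname(spring[1]) + k * L + unname(spring[3]) * Vl
  true_delta <- -unname(spring[3]) * pracma::trapz(tt, Vl^2)
  if (!is.null(seed)) set.seed(seed)
  steps <- lapply(seq_len(n_steps), function(i) {
    Fp <- F0
    if (noise_sd > 0) Fp <- Fp + stats::rnorm(length(F0), 0, noise_sd)
    data.frame(time = tt, L_leg = L, V_leg = Vl, F_projected = Fp)
  })
  structure(list(steps = steps,
                 truth = list(spring = spring, delta_area = true_delta)),
            class = "bw_simloop")
}

#' Sweep a parameter grid of synthetic trials
#'
#' One trial per grid row; the ledger table collects the truth needed for
#' the correlation analysis.
#'
#' @param grid data.frame whose columns override [sim_params()] arguments
#'   (e.g. `belt_speed`, `step_frequency`, `wobble_zeta`: a `wobble_zeta`
#'   column builds a wobble element with that damping ratio, `NA` meaning
#'   rigid mode).
#' @param seed integer seed, split deterministically across trials.
#' @param base a [sim_params()] object supplying the non-swept parameters.
#' @return list of class `bw_sweep`: `trials` (list of `bw_simtrial`) and
#'   `ledger` (data.frame: grid columns + `wobble_dissipation` J/stride,
#'   `wobble_c` N s/m).
#' @export
simulate_sweep <- function(grid, seed = 1, base = sim_params()) {
  stopifnot(nrow(grid) > 0)
  trials <- vector("list", nrow(grid))
  led <- grid
  led$wobble_dissipation <- NA_real_
  led$wobble_c <- NA_real_
  for (i in seq_len(nrow(grid))) {
    p <- base
    for (cn in setdiff(names(grid), "wobble_zeta"))
      p[[cn]] <- grid[[cn]][i]
    if ("wobble_zeta" %in% names(grid)) {
      z <- grid$wobble_zeta[i]
      p$wobble <- if (is.na(z) || z == 0) NULL else
        list(mass_fraction = 0.15, freq_hz = 10, zeta = z)
    }
    p$seed <- seed + i
    sim <- simulate_trial(p)
    trials[[i]] <- sim
    if (nrow(sim$truth$wobble) > 0) {
      led$wobble_dissipation[i] <- mean(sim$truth$wobble$dissipation)
      w <- sim$truth$params$wobble
      led$wobble_c[i] <- -2 * w$zeta * (2 * pi * w$freq_hz) *
        w$mass_fraction * sim$truth$params$mass
    } else {
      led$wobble_dissipation[i] <- 0
      led$wobble_c[i] <- 0
    }
  }
  structure(list(trials = trials, ledger = led), class = "bw_sweep")
}
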