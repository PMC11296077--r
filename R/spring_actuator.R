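## Spring-mass-actuator analysis of the bouncing mechanism.
##
## During each contact the leg is the line from the centre of pressure to
## the greater-trochanter (GT) marker.  The ground reaction force is
## projected onto that line and normalized by body mass; a linear model
## F_projected = cst + k L_leg + c V_leg is fit per step (ordinary least
## squares), and the hysteresis of the force-length loop quantifies the
## deviation from ideal elastic rebound.

#' Leg length, leg velocity and projected force over one contact
#'
#' @param forces a `bw_forces` table (filtered).
#' @param gt n-by-2 (y, z) trajectory of the GT marker on the force grid.
#' @param onset,offset half-open index interval of the contact.
#' @param mass body mass, kg.
#' @return data.frame of class `bw_leg`: `idx`, `time`, `L_leg` (m),
#'   `V_leg` (m/s), `leg_angle` (rad from vertical), `F_projected` (N/kg),
#'   `valid` (vertical force at or above the COP threshold).  `L_leg`,
#'   `V_leg`, `F_projected` are NA on invalid frames.
#' @export
leg_series <- function(forces, gt, onset, offset, mass) {
  idx <- onset:(offset - 1L)
  g <- gt[idx, , drop = FALSE]
  if (anyNA(g)) stop("GT marker gap inside contact", call. = FALSE)
  copy <- forces$COPy[idx]
  dy <- g[, 1] - copy
  dz <- g[, 2] - 0                       # COP lies on the belt plane z = 0
  L <- sqrt(dy^2 + dz^2)
  Fp <- (forces$Fy[idx] * dy / L + forces$Fz[idx] * dz / L) / mass
  valid <- forces$valid_cop[idx]
  dt <- 1 / attr(forces, "rate")
  vsp <- which(valid)
  V <- rep(NA_real_, length(idx))
  if (length(vsp) >= 3) {
    r <- vsp[1]:vsp[length(vsp)]
    V[r] <- fd_velocity(L[r], dt)
  }
  out <- data.frame(idx = idx, time = forces$time[idx], L_leg = L, V_leg = V,
                    leg_angle = atan2(dy, dz), F_projected = Fp, valid = valid)
  out$L_leg[!valid] <- NA_real_
  out$V_leg[!valid] <- NA_real_
  out$F_projected[!valid] <- NA_real_
  class(out) <- c("bw_leg", "data.frame")
  out
}

#' Split a contact into compression and decompression
#'
#' Compression runs from touchdown to the global minimum of the leg length
#' (earliest index on ties); decompression is the remainder.
#'
#' @param leg a `bw_leg` series.
#' @return list with integer index vectors `compression`,
#'   `decompression` (positions within `leg`, valid span only) and
#'   `min_pos`; or `NULL` with a warning when the valid leg length is
#'   monotone (no rebound).
#' @export
compression_split <- function(leg) {
  v <- which(leg$valid)
  if (length(v) < 5) {
    warning("contact has fewer than 5 valid frames", call. = FALSE)
    return(NULL)
  }
  L <- leg$L_leg[v]
  mp <- which.min(L)               # which.min takes the earliest tie
  if (mp == 1 || mp == length(v)) {
    warning("monotone leg length: degenerate contact excluded", call. = FALSE)
    return(NULL)
  }
  list(compression = v[1:mp], decompression = v[mp:length(v)], min_pos = v[mp])
}

#' Hysteresis area of the force-length loop
#'
#' The net mechanical energy absorbed across the contact loop,
#' `delta_area = (work absorbed in compression) - (work returned in
#' decompression) = -closed-loop integral of F dL`, by trapezoidal path
#' integration over the valid span.  Zero for any conservative F(L)
#' traversed down and back; positive when energy is absorbed (damper-like
#' leg).  `mode = "literal"` instead evaluates the signed split-integral
#' difference (decompression integral minus compression integral with
#' signed dL), retained for auditing.
#'
#' @param leg a `bw_leg` series.
#' @param mode `"loop"` (default) or `"literal"`.
#' @return list with `delta_area` (J/kg), `open_loop` (TRUE when the loop
#'   end points differ by more than 10% of the compression depth) or
#'   `NULL` for degenerate contacts.
#' @export
hysteresis_area <- function(leg, mode = c("loop", "literal")) {
  mode <- match.arg(mode)
  sp <- compression_split(leg)
  if (is.null(sp)) return(NULL)
  Lc <- leg$L_leg[sp$compression]; Fc <- leg$F_projected[sp$compression]
  Ld <- leg$L_leg[sp$decompression]; Fd <- leg$F_projected[sp$decompression]
  w_comp <- -pracma::trapz(Lc, Fc)        # F dL < 0 while shortening
  w_dec <- pracma::trapz(Ld, Fd)
  delta <- if (mode == "loop") w_comp - w_dec else w_dec - (-w_comp)
  depth <- max(Lc) - min(Lc)
  open_loop <- abs(Ld[length(Ld)] - Lc[1]) > 0.10 * depth
  if (open_loop)
    warning(sprintf("open force-length loop (end gap %.1f%% of depth)",
                    100 * abs(Ld[length(Ld)] - Lc[1]) / depth), call. = FALSE)
  list(delta_area = delta, open_loop = open_loop)
}

#' Fit the spring-mass-actuator model to one step
#'
#' Ordinary least squares of the projected force on leg length and leg
#' velocity, `F_projected = cst + k L_leg + c V_leg`.  `k` is the overall
#' leg stiffness; `c` is the actuator coefficient, negative when the
#' actuator behaves as an energy-absorbing damper.
#'
#' @param leg a `bw_leg` series (>= 10 valid frames).
#' @param delta_area_mode passed to [hysteresis_area()].
#' @return one-row data.frame of class `bw_springfit`: `cst` (N/kg),
#'   `k` (N kg^-1 m^-1), `c` (N s kg^-1 m^-1), `rmse` (N/kg),
#'   `r_squared`, `delta_area` (J/kg, NA for degenerate loops),
#'   `n_frames`.
#' @export
fit_spring_actuator <- function(leg, delta_area_mode = "loop") {
  ok <- leg$valid & !is.na(leg$V_leg)
  if (sum(ok) < 10) stop("fewer than 10 valid frames in contact", call. = FALSE)
  X <- cbind(1, leg$L_leg[ok], leg$V_leg[ok])
  y <- leg$F_projected[ok]
  qrX <- qr(X)
  if (qrX$rank < 3)
    stop("rank-deficient design: leg length and velocity are collinear",
         call. = FALSE)
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  rmse <- sqrt(mean(res^2))
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  ha <- suppressWarnings(hysteresis_area(leg, delta_area_mode))
  data.frame(cst = beta[1], k = beta[2], c = beta[3], rmse = rmse,
             r_squared = r2,
             delta_area = if (is.null(ha)) NA_real_ else ha$delta_area,
             n_frames = sum(ok)) |>
    structure(class = c("bw_springfit", "data.frame"))
}

#' Spring-actuator fits for every step of a prepared trial
#'
#' Runs [leg_series()] and [fit_spring_actuator()] on each labelled
#' contact that lies inside a complete stride.
#'
#' @param prep a `bw_prepared` trial from [preprocess_trial()].
#' @return data.frame: step rows with `stride_id`, `foot`, the
#'   `bw_springfit` columns.
#' @export
spring_fits_by_step <- function(prep) {
  strides <- prep$strides
  mass <- prep$meta$mass
  rows <- list()
  for (i in seq_len(nrow(strides$steps))) {
    st <- strides$steps[i, ]
    cc <- strides$contacts
    j <- which(cc$foot == st$foot & cc$onset >= st$start & cc$onset < st$end)
    if (!length(j)) next
    cc <- cc[j[1], ]
    gt <- marker_xy(prep$markers, paste0("GT_", st$foot))
    leg <- leg_series(prep$forces, gt, cc$onset, cc$offset, mass)
    fit <- tryCatch(fit_spring_actuator(leg, prep$config$delta_area_mode),
                    error = function(e) NULL)
    if (is.null(fit)) next
    rows[[length(rows) + 1L]] <- cbind(data.frame(stride_id = st$stride_id,
                                                  foot = st$foot), fit)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(stride_id = integer(), foot = character(), cst = numeric(),
                      k = numeric(), c = numeric(), rmse = numeric(),
                      r_squared = numeric(), delta_area = numeric(),
                      n_frames = integer())
  out
}
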