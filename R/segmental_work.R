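## Internal work, sagittal inverse dynamics, and the total / soft-tissue
## work partition.
##
## Internal energy follows the classic segmental formulation: per segment
## E = 1/2 (m V'^2 + I w^2) with V' relative to the force-derived CoM,
## SUMMED over the segments of one limb before increments are taken
## (energy may transfer within a limb but not between limbs or with the
## CoM).  Joint kinetics are bottom-up Newton-Euler in the sagittal plane
## with hinge joints at the ankle, knee and hip.

#' Internal energy curve of one limb (or the trunk)
#'
#' @param segments list of segment states belonging to ONE limb (thigh,
#'   shank, foot) or a single-element list with the trunk.
#' @param com a `bw_com` with force-derived CoM velocities.
#' @return numeric vector: E_int(t), J (NA outside complete strides).
#' @export
internal_energy_limb <- function(segments, com) {
  E <- 0
  for (seg in segments) {
    Vrel2 <- (seg$vel[, 1] - com$v_f)^2 + (seg$vel[, 2] - com$v_v)^2
    E <- E + 0.5 * (seg$mass * Vrel2 + seg$inertia * seg$omega^2)
  }
  E
}

## 2D cross product (moment about the out-of-plane axis)
cross2 <- function(r, F) r[, 1] * F[, 2] - r[, 2] * F[, 1]

#' Sagittal inverse dynamics of one lower limb
#'
#' Bottom-up Newton-Euler: the foot receives the ground reaction force at
#' the centre of pressure (zero during that foot's swing); ankle, knee and
#' hip are solved in turn as hinge joints.  COP samples flagged invalid
#' (vertical force under the COP threshold) inside a loaded frame are
#' replaced by the nearest valid COP sample; the count of such frames is
#' attached as attribute `cop_clamped`.
#'
#' Reported moments follow the extension-positive convention for the ankle
#' and hip and flexion-positive for the knee; joint angular velocities
#' carry the matching sign so that `P_j = M_j * w_j` holds exactly at every
#' frame.
#'
#' @param Fy,Fz ground reaction force assigned to this foot, N.
#' @param cop_y fore-aft COP, m (lab frame).
#' @param valid_cop logical COP validity mask.
#' @param loaded logical mask of frames loaded on this foot.
#' @param segments the full segment list from [build_segments()].
#' @param side `"R"` or `"L"`.
#' @param gravity gravitational acceleration, m/s^2.
#' @return list of class `bw_joints`: per joint (`ankle`, `knee`, `hip`)
#'   a list with `M` (N·m), `omega` (rad/s), `P` (W); plus `P_limb`
#'   (summed joint power, W).
#' @export
inverse_dynamics_limb <- function(Fy, Fz, cop_y, valid_cop, loaded,
                                  segments, side, gravity = 9.81) {
  foot <- segments[[paste0("foot_", side)]]
  shank <- segments[[paste0("shank_", side)]]
  thigh <- segments[[paste0("thigh_", side)]]
  trunk <- segments$trunk
  n <- length(Fy)

  ## COP handling: nearest valid sample among this foot's loaded frames
  cop <- cop_y
  need <- loaded & !valid_cop
  have <- which(loaded & valid_cop)
  clamped <- 0L
  if (any(need)) {
    if (!length(have))
      stop("no valid COP sample inside loaded frames", call. = FALSE)
    ni <- which(need)
    nearest <- have[pmax(1L, findInterval(ni, have))]
    alt <- have[pmin(length(have), findInterval(ni, have) + 1L)]
    pick <- ifelse(abs(ni - nearest) <= abs(ni - alt), nearest, alt)
    cop[ni] <- cop[pick]
    clamped <- length(ni)
  }
  grf <- cbind(Fy, Fz)
  cop_pt <- cbind(cop, 0)          # COP lies on the belt surface (z = 0)
  grf[!loaded, ] <- 0

  g_vec <- c(0, -gravity)
  ## foot -> ankle
  F_ankle <- cbind(foot$mass * foot$acc[, 1] - grf[, 1] - foot$mass * g_vec[1],
                   foot$mass * foot$acc[, 2] - grf[, 2] - foot$mass * g_vec[2])
  M_ankle <- foot$inertia * foot$alpha -
    cross2(cop_pt - foot$com, grf) -
    cross2(foot$prox - foot$com, F_ankle)
  ## shank -> knee (reaction of ankle acts distally on the shank)
  F_knee <- cbind(shank$mass * shank$acc[, 1] + F_ankle[, 1] - shank$mass * g_vec[1],
                  shank$mass * shank$acc[, 2] + F_ankle[, 2] - shank$mass * g_vec[2])
  M_knee <- shank$inertia * shank$alpha + M_ankle -
    cross2(shank$dist - shank$com, -F_ankle) -
    cross2(shank$prox - shank$com, F_knee)
  ## thigh -> hip
  F_hip <- cbind(thigh$mass * thigh$acc[, 1] + F_knee[, 1] - thigh$mass * g_vec[1],
                 thigh$mass * thigh$acc[, 2] + F_knee[, 2] - thigh$mass * g_vec[2])
  M_hip <- thigh$inertia * thigh$alpha + M_knee -
    cross2(thigh$dist - thigh$com, -F_knee) -
    cross2(thigh$prox - thigh$com, F_hip)

  ## joint angular velocities: distal segment relative to proximal segment
  w_ankle <- foot$omega - shank$omega
  w_knee <- shank$omega - thigh$omega
  w_hip <- thigh$omega - trunk$omega

  ## anatomical sign remap (extension-positive ankle/hip, flexion-positive
  ## knee); M and w flip together so P is untouched
  s <- c(ankle = -1, knee = -1, hip = -1)
  out <- list(
    ankle = list(M = s["ankle"] * M_ankle, omega = s["ankle"] * w_ankle),
    knee = list(M = s["knee"] * M_knee, omega = s["knee"] * w_knee),
    hip = list(M = s["hip"] * M_hip, omega = s["hip"] * w_hip))
  for (j in names(out)) out[[j]]$P <- out[[j]]$M * out[[j]]$omega
  out$P_limb <- out$ankle$P + out$knee$P + out$hip$P
  attr(out, "cop_clamped") <- clamped
  class(out) <- "bw_joints"
  out
}

#' Joint energy curve and per-stride joint work of one limb
#'
#' Joint powers of the limb are summed per frame (ipsilateral inter-joint
#' transfer allowed), time-integrated by the trapezoidal rule into the
#' limb's joint energy curve, whose signed increments give the joint work.
#'
#' @param joints a `bw_joints` from [inverse_dynamics_limb()].
#' @param time time stamps, s.
#' @param com a `bw_com` (stride index rows).
#' @return list with `E_j` (J, curve) and `work` (data.frame stride_id,
#'   W_plus, W_minus).
#' @export
joint_power_work <- function(joints, time, com) {
  E_j <- cumtrapz1(time, joints$P_limb)
  list(E_j = E_j, work = stride_work(E_j, com))
}

#' Assemble the per-stride work partition
#'
#' Applies the two partition identities:
#' `W_tot± = W_com± + W_int,R± + W_int,L± + W_int,trunk±` (no transfer
#' between external and internal energies) and
#' `W_ST± = W_tot± − W_j,R± − W_j,L±` (soft-tissue residual).
#'
#' @param w_com,w_int_R,w_int_L,w_int_trunk,w_j_R,w_j_L data.frames from
#'   [stride_work()] on an identical stride set.
#' @param mass body mass, kg (for the mass-specific columns).
#' @return data.frame of class `bw_breakdown`: one row per stride with
#'   all signed work terms in J and, suffixed `_kg`, in J/kg.
#' @export
partition_work <- function(w_com, w_int_R, w_int_L, w_int_trunk,
                           w_j_R, w_j_L, mass) {
  ids <- w_com$stride_id
  parts <- list(w_int_R, w_int_L, w_int_trunk, w_j_R, w_j_L)
  for (p in parts)
    if (!identical(p$stride_id, ids))
      stop("work tables computed on different stride sets", call. = FALSE)
  out <- data.frame(
    stride_id = ids,
    W_com_plus = w_com$W_plus, W_com_minus = w_com$W_minus,
    W_int_R_plus = w_int_R$W_plus, W_int_R_minus = w_int_R$W_minus,
    W_int_L_plus = w_int_L$W_plus, W_int_L_minus = w_int_L$W_minus,
    W_int_trunk_plus = w_int_trunk$W_plus, W_int_trunk_minus = w_int_trunk$W_minus,
    W_j_R_plus = w_j_R$W_plus, W_j_R_minus = w_j_R$W_minus,
    W_j_L_plus = w_j_L$W_plus, W_j_L_minus = w_j_L$W_minus)
  out$W_tot_plus <- out$W_com_plus + out$W_int_R_plus + out$W_int_L_plus +
    out$W_int_trunk_plus
  out$W_tot_minus <- out$W_com_minus + out$W_int_R_minus + out$W_int_L_minus +
    out$W_int_trunk_minus
  out$W_ST_plus <- out$W_tot_plus - out$W_j_R_plus - out$W_j_L_plus
  out$W_ST_minus <- out$W_tot_minus - out$W_j_R_minus - out$W_j_L_minus
  kg <- setdiff(names(out), "stride_id")
  for (cn in kg) out[[paste0(cn, "_kg")]] <- out[[cn]] / mass
  class(out) <- c("bw_breakdown", "data.frame")
  out
}
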