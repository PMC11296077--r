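## Filtering, resampling and gait-event segmentation.

#' Resample marker trajectories by cubic splines
#'
#' Oversamples marker data onto a faster uniform grid (typically the 1 kHz
#' force grid) with cubic-spline interpolation.  Values at the original
#' sample times are reproduced exactly.
#'
#' @param markers a `bw_markers` table.
#' @param times target time stamps (s); must lie within the source span.
#' @return a `bw_markers` table on the target grid.
#' @export
resample_spline <- function(markers, times) {
  src <- markers$time
  if (length(times) > 1 && stats::median(diff(times)) > stats::median(diff(src)) * (1 + 1e-9))
    stop("target rate must be >= source rate", call. = FALSE)
  nms <- marker_names(markers)
  coords <- vector("list", length(nms)); names(coords) <- nms
  for (nm in nms) {
    xy <- marker_xy(markers, nm)
    if (anyNA(xy))
      stop(sprintf("marker '%s' has gaps; fill before resampling", nm), call. = FALSE)
    coords[[nm]] <- cbind(stats::spline(src, xy[, 1], xout = times, method = "fmm")$y,
                          stats::spline(src, xy[, 2], xout = times, method = "fmm")$y)
  }
  marker_trajectories(times, coords = coords)
}

#' Detect foot-contact intervals from the vertical force
#'
#' A contact is a maximal run of samples where the (filtered) vertical
#' force exceeds a fraction of body weight.  Runs shorter than
#' `debounce_s` are discarded as threshold chatter.
#'
#' @param Fz vertical force, N (filtered).
#' @param body_weight subject weight, N (> 0).
#' @param threshold_fraction contact threshold as a fraction of body weight
#'   (default 0.10).
#' @param rate sampling rate, Hz.
#' @param debounce_s minimum contact duration, s (default 0.020).
#' @return data.frame with columns `onset`, `offset`: half-open 1-based
#'   index intervals `[onset, offset)`, sorted and non-overlapping.  Zero
#'   rows (with a warning) when no contact is found.
#' @export
detect_contacts <- function(Fz, body_weight, threshold_fraction = 0.10,
                            rate = 1000, debounce_s = 0.020) {
  stopifnot(body_weight > 0)
  above <- Fz > threshold_fraction * body_weight
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= max(1L, round(debounce_s * rate))
  out <- data.frame(onset = as.integer(starts[keep]),
                    offset = as.integer(ends[keep] + 1L))
  if (nrow(out) == 0) warning("no foot contact found", call. = FALSE)
  out
}

#' Label contacts left/right and build the stride segmentation
#'
#' Each contact is attributed to the foot whose ankle marker is nearer the
#' centre of pressure at mid-contact.  Strides run from one right-foot
#' touchdown to the next; steps split each stride at the intervening
#' left-foot touchdown.  Running is assumed: overlapping contacts raise an
#' error.
#'
#' @param contacts unlabelled contact table from [detect_contacts()].
#' @param forces a `bw_forces` table on the same grid.
#' @param markers a `bw_markers` table resampled to the force grid.
#' @return list of class `bw_strides` with elements
#'   `contacts` (foot-labelled contact table),
#'   `strides` (stride_id, start, end index, half-open on the force grid),
#'   `steps` (stride_id, foot, start, end).
#' @export
assign_feet_and_strides <- function(contacts, forces, markers) {
  n <- nrow(contacts)
  if (n >= 2) {
    o <- order(contacts$onset)
    contacts <- contacts[o, , drop = FALSE]
    if (any(contacts$onset[-1] < contacts$offset[-n]))
      stop("overlapping contacts: bilateral support violates the running assumption",
           call. = FALSE)
  }
  aR <- marker_xy(markers, "ankle_R")[, 1]
  aL <- marker_xy(markers, "ankle_L")[, 1]
  cop <- forces$COPy
  foot <- character(n)
  for (i in seq_len(n)) {
    span <- contacts$onset[i]:(contacts$offset[i] - 1L)
    mid <- span[span >= stats::quantile(span, 0.25) & span <= stats::quantile(span, 0.75)]
    use <- mid[forces$valid_cop[mid]]
    if (!length(use)) use <- mid
    dR <- mean(abs(aR[use] - cop[use]))
    dL <- mean(abs(aL[use] - cop[use]))
    foot[i] <- if (dR <= dL) "R" else "L"
  }
  contacts$foot <- foot

  rtd <- contacts$onset[contacts$foot == "R"]
  if (length(rtd) < 2) {
    warning("fewer than two right-foot contacts: no complete stride", call. = FALSE)
    strides <- data.frame(stride_id = integer(), start = integer(), end = integer())
    steps <- data.frame(stride_id = integer(), foot = character(),
                        start = integer(), end = integer())
  } else {
    strides <- data.frame(stride_id = seq_len(length(rtd) - 1L),
                          start = rtd[-length(rtd)], end = rtd[-1])
    steps_list <- lapply(seq_len(nrow(strides)), function(i) {
      s <- strides$start[i]; e <- strides$end[i]
      ltd <- contacts$onset[contacts$foot == "L" & contacts$onset > s &
                              contacts$onset < e]
      if (length(ltd) != 1) return(NULL)   # malformed stride: drop
      data.frame(stride_id = i, foot = c("R", "L"),
                 start = c(s, ltd), end = c(ltd, e))
    })
    steps <- do.call(rbind, steps_list)
    ok <- strides$stride_id %in% steps$stride_id
    strides <- strides[ok, , drop = FALSE]
  }
  structure(list(contacts = contacts, strides = strides, steps = steps),
            class = "bw_strides")
}

#' @export
print.bw_strides <- function(x, ...) {
  cat(sprintf("<bw_strides> %d contacts (%d R / %d L), %d complete strides\n",
              nrow(x$contacts), sum(x$contacts$foot == "R"),
              sum(x$contacts$foot == "L"), nrow(x$strides)))
  invisible(x)
}

#' Per-foot force assignment
#'
#' Returns the ground reaction force attributed wholly to one foot: equal
#' to the measured force during that foot's contacts, zero elsewhere
#' (running: single support only).
#'
#' @param forces a `bw_forces` table.
#' @param strides a `bw_strides` segmentation.
#' @param foot `"R"` or `"L"`.
#' @return list with vectors `Fy`, `Fz`, `loaded` (logical mask).
#' @export
foot_forces <- function(forces, strides, foot) {
  loaded <- rep(FALSE, nrow(forces))
  cc <- strides$contacts[strides$contacts$foot == foot, , drop = FALSE]
  for (i in seq_len(nrow(cc))) loaded[cc$onset[i]:(cc$offset[i] - 1L)] <- TRUE
  list(Fy = ifelse(loaded, forces$Fy, 0), Fz = ifelse(loaded, forces$Fz, 0),
       loaded = loaded)
}

#' Filter and resample a raw trial
#'
#' Applies the zero-phase Bessel filter to force channels, spline-resamples
#' markers onto the force grid and filters them, recomputes the COP
#' validity mask, and segments gait events.
#'
#' @param trial a `bw_trial`.
#' @param config a `bw_config` (defaults from [analysis_config()]).
#' @return list of class `bw_prepared`: `meta`, `forces` (filtered),
#'   `markers` (1 kHz, filtered), `strides`, `config`.
#' @export
preprocess_trial <- function(trial, config = analysis_config()) {
  meta <- trial$meta
  rate <- attr(trial$forces, "rate")
  f <- trial$forces
  Fy <- lowpass_zero_phase(f$Fy, config$force_cutoff_hz, rate, config$filter_order)
  Fz <- lowpass_zero_phase(f$Fz, config$force_cutoff_hz, rate, config$filter_order)
  Fz <- pmax(Fz, 0)      # filtered vertical force must stay non-negative
  forces <- force_series(f$time, Fy, Fz, f$COPy,
                         cop_threshold = config$cop_force_threshold_n)

  ## markers: clip the force grid to the marker span, resample, filter
  tmk <- trial$markers$time
  idx <- which(f$time >= tmk[1] - 1e-9 & f$time <= tmk[length(tmk)] + 1e-9)
  markers <- resample_spline(trial$markers, f$time[idx])
  nms <- marker_names(markers)
  for (nm in nms) {
    cy <- paste0(nm, "_y"); cz <- paste0(nm, "_z")
    markers[[cy]] <- lowpass_zero_phase(markers[[cy]], config$marker_cutoff_hz,
                                        rate, config$filter_order)
    markers[[cz]] <- lowpass_zero_phase(markers[[cz]], config$marker_cutoff_hz,
                                        rate, config$filter_order)
  }

  ## restrict forces to the common span so indices line up one-to-one
  forces <- forces[idx, , drop = FALSE]
  class(forces) <- c("bw_forces", "data.frame")
  attr(forces, "rate") <- rate
  attr(forces, "cop_threshold") <- config$cop_force_threshold_n

  contacts <- detect_contacts(forces$Fz, meta$mass * meta$gravity,
                              config$contact_threshold_fraction, rate)
  strides <- assign_feet_and_strides(contacts, forces, markers)
  structure(list(meta = meta, forces = forces, markers = markers,
                 strides = strides, config = config),
            class = "bw_prepared")
}
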