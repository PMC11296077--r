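## On-disk trial format and validation.
##
## A trial is three tab-separated text files sharing a base name:
##   <base>_meta.tsv    key<TAB>value lines
##   <base>_force.tsv   '# key=value' header block, then time, Fy, Fz, COPy
##   <base>_markers.tsv same header style, then time, <marker>_y, <marker>_z ...
## Units are SI throughout (s, N, m); a `units=` header line is checked.

write_kv_header <- function(con, kv) {
  for (k in names(kv)) cat(sprintf("# %s=%s\n", k, kv[[k]]), file = con)
}

read_kv_header <- function(path) {
  lines <- readLines(path, n = 50)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^=]+)=(.*)$", h))[[1]]
    if (length(m) == 3) kv[[trimws(m[2])]] <- trimws(m[3])
  }
  kv
}

#' Write a trial to the tab-separated trial format
#'
#' @param trial a `bw_trial`.
#' @param base path prefix; `<base>_meta.tsv`, `<base>_force.tsv` and
#'   `<base>_markers.tsv` are written.
#' @return `base`, invisibly.
#' @export
write_trial <- function(trial, base) {
  meta <- trial$meta
  mpath <- paste0(base, "_meta.tsv")
  con <- file(mpath, "w")
  for (k in setdiff(names(meta), "")) {
    v <- meta[[k]]
    cat(sprintf("%s\t%s\n", k, format(v, digits = 17)), file = con)
  }
  close(con)

  fpath <- paste0(base, "_force.tsv")
  con <- file(fpath, "w")
  write_kv_header(con, list(rate_hz = format(attr(trial$forces, "rate"), digits = 17),
                            units = "s,N,N,m"))
  f <- trial$forces[, c("time", "Fy", "Fz", "COPy")]
  utils::write.table(format(f, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  kpath <- paste0(base, "_markers.tsv")
  con <- file(kpath, "w")
  write_kv_header(con, list(rate_hz = format(attr(trial$markers, "rate"), digits = 17),
                            units = "s,m"))
  k <- as.data.frame(trial$markers)
  utils::write.table(format(k, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(base)
}

read_tsv_block <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE)
}

#' Read a trial from the tab-separated trial format
#'
#' @param force_path path to the force table.
#' @param marker_path path to the marker table.
#' @param meta_path path to the key/value metadata file.
#' @return a validated [raw_trial()] in SI units with force and marker
#'   clocks on a common zero.
#' @export
read_trial <- function(force_path, marker_path, meta_path) {
  for (p in c(force_path, marker_path, meta_path))
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)

  kv <- utils::read.table(meta_path, sep = "\t", header = FALSE,
                          col.names = c("key", "value"),
                          colClasses = "character")
  meta_list <- stats::setNames(as.list(kv$value), kv$key)
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  meta <- trial_meta(subject_id = meta_list$subject_id %||% "unknown",
                     mass = num(meta_list$mass),
                     height = num(meta_list$height),
                     belt_speed = num(meta_list$belt_speed),
                     target_step_frequency = num(meta_list$target_step_frequency),
                     force_rate = num(meta_list$force_rate),
                     marker_rate = num(meta_list$marker_rate),
                     gravity = num(meta_list$gravity))

  fh <- read_kv_header(force_path)
  if (!is.null(fh$units) && fh$units != "s,N,N,m")
    stop(sprintf("force file declares units '%s'; expected 's,N,N,m'", fh$units),
         call. = FALSE)
  f <- read_tsv_block(force_path)
  for (cn in c("time", "Fy", "Fz", "COPy"))
    if (!cn %in% names(f))
      stop(sprintf("force file is missing required column '%s'", cn), call. = FALSE)
  dt <- diff(f$time)
  if (any(abs(dt - stats::median(dt)) > 1e-6 * stats::median(dt)))
    stop("non-uniform force time stamps (beyond 1 ppm)", call. = FALSE)
  forces <- force_series(f$time, f$Fy, f$Fz, f$COPy)

  mh <- read_kv_header(marker_path)
  if (!is.null(mh$units) && mh$units != "s,m")
    stop(sprintf("marker file declares units '%s'; expected 's,m'", mh$units),
         call. = FALSE)
  k <- read_tsv_block(marker_path)
  if (!"time" %in% names(k))
    stop("marker file is missing required column 'time'", call. = FALSE)
  ys <- grep("_y$", names(k), value = TRUE)
  nms <- sub("_y$", "", ys)
  coords <- lapply(nms, function(nm) cbind(k[[paste0(nm, "_y")]],
                                           k[[paste0(nm, "_z")]]))
  names(coords) <- nms
  markers <- marker_trajectories(k$time, coords = coords)

  ## common zero: shift both clocks so the earliest sample is t = 0
  t0 <- min(forces$time[1], markers$time[1])
  forces$time <- forces$time - t0
  markers$time <- markers$time - t0
  raw_trial(meta, forces, markers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a trial against the container invariants
#'
#' Checks the invariants of the trial containers (positive mass, uniform
#' sampling, non-negative vertical force, COP validity mask, required
#' markers, marker gaps, force/marker overlap) and returns findings rather
#' than raising conditions.
#'
#' @param trial a `bw_trial`.
#' @param require_lower_limb if `TRUE` (default) the markers needed for the
#'   lower-limb analysis must be present.
#' @return data.frame with columns `severity` ("error"/"warning"),
#'   `location`, `message`; zero rows when the trial is clean.
#' @export
validate_trial <- function(trial, require_lower_limb = TRUE) {
  f <- list(severity = character(), location = character(), message = character())
  add <- function(sev, loc, msg) {
    f$severity <<- c(f$severity, sev)
    f$location <<- c(f$location, loc)
    f$message <<- c(f$message, msg)
  }
  meta <- trial$meta
  if (!is.finite(meta$mass) || meta$mass <= 0)
    add("error", "meta", "mass must be > 0")
  if (is.finite(meta$belt_speed) && meta$belt_speed < 0)
    add("error", "meta", "belt_speed must be >= 0")
  if (!(meta$force_rate >= meta$marker_rate && meta$marker_rate > 0))
    add("error", "meta", "need force_rate >= marker_rate > 0")

  fz <- trial$forces$Fz
  if (any(fz < 0))
    add("error", "forces",
        sprintf("negative vertical force (min %.1f N)", min(fz)))
  thr <- attr(trial$forces, "cop_threshold") %||% 300
  bad <- trial$forces$valid_cop & fz < thr
  if (any(bad))
    add("error", "forces",
        sprintf("valid_cop true on %d frames with Fz < %g N", sum(bad), thr))

  mk <- trial$markers
  if (require_lower_limb) {
    missing <- setdiff(required_markers(), marker_names(mk))
    if (length(missing))
      add("error", "markers",
          paste0("missing required markers: ", paste(missing, collapse = ", ")))
  }
  for (nm in marker_names(mk)) {
    xy <- marker_xy(mk, nm)
    nas <- which(!stats::complete.cases(xy))
    if (length(nas)) {
      runs <- rle(diff(nas) == 1)
      longest <- if (length(nas) == 1) 1 else max(runs$lengths[runs$values], 0) + 1
      add("warning", paste0("markers/", nm),
          sprintf("gap: %s, %d frames", nm, longest))
    }
  }

  tf <- range(trial$forces$time); tm <- range(mk$time)
  ov <- max(0, min(tf[2], tm[2]) - max(tf[1], tm[1]))
  span <- max(diff(tf), diff(tm))
  if (span > 0 && ov / span < 0.95)
    add("error", "trial",
        sprintf("force and marker time ranges overlap only %.0f%%", 100 * ov / span))
  data.frame(severity = f$severity, location = f$location, message = f$message,
             stringsAsFactors = FALSE)
}

#' Read an analysis configuration from a key: value text file
#'
#' The file mirrors [analysis_config()] field-for-field (YAML syntax).
#' Unknown keys raise an error; omitted keys take their defaults.
#'
#' @param path file path.
#' @return a `bw_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop(paste0("unknown config keys: ", paste(unknown, collapse = ", ")),
         call. = FALSE)
  do.call(analysis_config, vals)
}

#' Write an analysis configuration
#' @param config a `bw_config`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}
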