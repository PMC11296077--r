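## Minimal C3D support (Intel/float flavour).
##
## Covers the subset of the motion-capture C3D standard this package needs:
## labelled 3D points + analog channels, float data, one parameter section
## with POINT / ANALOG / SUBJECT groups.  The sagittal convention maps the
## package's (y, z) onto C3D (X, Z); C3D Y is written as zero.  Written
## and read files round-trip bit-exactly through this module; files from
## other software are readable as long as they use the Intel float layout.

c3d_marker_aliases <- function() {
  ## default alias table: common vendor label styles -> package names
  c(RGT = "GT_R", LGT = "GT_L", RKNEE = "knee_R", LKNEE = "knee_L",
    RANK = "ankle_R", LANK = "ankle_L", RHEE = "heel_R", LHEE = "heel_L",
    RVM = "VM_R", LVM = "VM_L", WAIST = "waist", BACKWAIST = "backwaist",
    NECK = "neck")
}

c3d_pad <- function(s, n) {
  s <- substr(s, 1, n)
  paste0(s, strrep(" ", n - nchar(s)))
}

## ---- writer -------------------------------------------------------------

c3d_param_bytes <- function(name, gid, value, type) {
  ## one parameter record; type: -1 char, 2 int16, 4 float
  nameb <- charToRaw(name)
  if (type == -1) {
    value <- as.character(value)
    width <- max(nchar(value), 1L)
    dims <- if (length(value) > 1) c(width, length(value)) else width
    datab <- unlist(lapply(value, function(v) charToRaw(c3d_pad(v, width))))
  } else if (type == 2) {
    dims <- if (length(value) > 1) length(value) else integer(0)
    datab <- writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else {
    dims <- if (length(value) > 1) length(value) else integer(0)
    datab <- writeBin(as.numeric(value), raw(), size = 4, endian = "little")
  }
  body <- c(as.raw(type %% 256), as.raw(length(dims)),
            as.raw(dims), datab, as.raw(0))   # zero-length description
  head <- c(as.raw(length(nameb)), as.raw(gid), nameb)
  offset <- length(body) + 2L                  # to the next record
  c(head, writeBin(as.integer(offset), raw(), size = 2, endian = "little"), body)
}

c3d_group_bytes <- function(name, gid) {
  nameb <- charToRaw(name)
  body <- as.raw(0)                            # zero-length description
  head <- c(as.raw(length(nameb)), as.raw(256 - gid), nameb)  # negative id
  offset <- length(body) + 2L
  c(head, writeBin(as.integer(offset), raw(), size = 2, endian = "little"), body)
}

#' Write a trial as a C3D file
#'
#' @param trial a `bw_trial`; marker (y, z) map to C3D (X, Z).  Analog
#'   channels Fy, Fz, COPy carry the force series; subject metadata goes
#'   to a SUBJECT parameter group.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_c3d <- function(trial, path) {
  mk <- trial$markers
  nms <- marker_names(mk)
  npts <- length(nms)
  nframes <- nrow(mk)
  ratio <- round(attr(trial$forces, "rate") / attr(mk, "rate"))
  nanalog <- 3L
  ## clip forces to an exact multiple of the marker frames
  need <- nframes * ratio
  f <- trial$forces[seq_len(min(need, nrow(trial$forces))), ]
  if (nrow(f) < need) {
    pad <- need - nrow(f)
    f <- rbind(f, f[rep(nrow(f), pad), ])
  }

  params <- c(
    c3d_group_bytes("POINT", 1),
    c3d_param_bytes("USED", 1, npts, 2),
    c3d_param_bytes("FRAMES", 1, nframes, 2),
    c3d_param_bytes("SCALE", 1, -1, 4),        # negative: float data
    c3d_param_bytes("RATE", 1, attr(mk, "rate"), 4),
    c3d_param_bytes("LABELS", 1, nms, -1),
    c3d_param_bytes("UNITS", 1, "m", -1),
    c3d_group_bytes("ANALOG", 2),
    c3d_param_bytes("USED", 2, nanalog, 2),
    c3d_param_bytes("RATE", 2, attr(trial$forces, "rate"), 4),
    c3d_param_bytes("LABELS", 2, c("Fy", "Fz", "COPy"), -1),
    c3d_group_bytes("SUBJECT", 3),
    c3d_param_bytes("ID", 3, trial$meta$subject_id, -1),
    c3d_param_bytes("MASS", 3, trial$meta$mass, 4),
    c3d_param_bytes("HEIGHT", 3, trial$meta$height, 4),
    c3d_param_bytes("BELT_SPEED", 3, trial$meta$belt_speed, 4),
    c3d_param_bytes("STEP_FREQ", 3, trial$meta$target_step_frequency, 4),
    c3d_param_bytes("GRAVITY", 3, trial$meta$gravity, 4))
  params <- c(as.raw(c(1, 80)), as.raw(0), as.raw(0), params, as.raw(0))
  nparam_blocks <- ceiling(length(params) / 512)
  params <- c(params, raw(nparam_blocks * 512 - length(params)))
  data_start <- 2L + nparam_blocks

  header <- raw(512)
  put16 <- function(h, word, value) {
    b <- writeBin(as.integer(value), raw(), size = 2, endian = "little")
    h[(2 * word - 1):(2 * word)] <- b; h
  }
  putf <- function(h, word, value) {
    b <- writeBin(as.numeric(value), raw(), size = 4, endian = "little")
    h[(2 * word - 1):(2 * word + 2)] <- b; h
  }
  header[1] <- as.raw(2); header[2] <- as.raw(80)
  header <- put16(header, 2, npts)
  header <- put16(header, 3, nanalog * ratio)
  header <- put16(header, 4, 1)
  header <- put16(header, 5, nframes)
  header <- put16(header, 6, 0)
  header <- putf(header, 7, -1)
  header <- put16(header, 9, data_start)
  header <- put16(header, 10, ratio)
  header <- putf(header, 11, attr(mk, "rate"))

  ## frame-interleaved float data
  pts <- array(0, c(4, npts, nframes))
  for (i in seq_along(nms)) {
    xy <- marker_xy(mk, nms[i])
    pts[1, i, ] <- xy[, 1]; pts[3, i, ] <- xy[, 2]
  }
  ana <- rbind(f$Fy, f$Fz, f$COPy)             # 3 x (nframes*ratio)
  dim(ana) <- c(3, ratio, nframes)
  blob <- vapply(seq_len(nframes), function(fr)
    c(as.numeric(pts[, , fr]), as.numeric(aperm(ana[, , fr, drop = FALSE],
                                                c(1, 2, 3)))),
    numeric(4 * npts + 3 * ratio))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  writeBin(params, con)
  writeBin(as.numeric(blob), con, size = 4, endian = "little")
  invisible(path)
}

## ---- reader -------------------------------------------------------------

read_c3d_params <- function(raw_params) {
  pos <- 5L                                    # skip 4-byte section header
  groups <- list(); params <- list()
  repeat {
    if (pos + 1L > length(raw_params)) break
    nchars <- as.integer(raw_params[pos])
    if (nchars > 127) nchars <- nchars - 256L  # locked: negative length
    nchars <- abs(nchars)
    gid <- as.integer(raw_params[pos + 1L])
    if (gid > 127) gid <- gid - 256L
    if (nchars == 0 || gid == 0) break
    name <- rawToChar(raw_params[(pos + 2L):(pos + 1L + nchars)])
    p <- pos + 2L + nchars
    offset <- readBin(raw_params[p:(p + 1L)], integer(), size = 2,
                      endian = "little")
    if (gid < 0) {
      groups[[as.character(-gid)]] <- name
    } else {
      q <- p + 2L
      type <- as.integer(raw_params[q]); if (type > 127) type <- type - 256L
      nd <- as.integer(raw_params[q + 1L])
      dims <- if (nd > 0) as.integer(raw_params[(q + 2L):(q + 1L + nd)]) else integer(0)
      n <- prod(c(dims, 1L))
      dstart <- q + 2L + nd
      value <- switch(as.character(type),
        `-1` = {
          chars <- rawToChar(raw_params[dstart:(dstart + n - 1L)])
          if (length(dims) >= 2) {
            w <- dims[1]
            trimws(substring(chars, seq(1, n, w), seq(w, n, w)))
          } else trimws(chars)
        },
        `1` = as.integer(raw_params[dstart:(dstart + n - 1L)]),
        `2` = readBin(raw_params[dstart:(dstart + 2L * n - 1L)], integer(),
                      n = n, size = 2, endian = "little"),
        `4` = readBin(raw_params[dstart:(dstart + 4L * n - 1L)], numeric(),
                      n = n, size = 4, endian = "little"),
        stop("unsupported C3D parameter type ", type, call. = FALSE))
      params[[paste0(gid, ":", name)]] <- value
    }
    if (offset <= 0) break
    pos <- p + offset
  }
  list(groups = groups, params = params)
}

#' Read a trial from a C3D file
#'
#' Reads the Intel-float C3D subset written by [write_c3d()] (and files of
#' the same flavour from other software).  Point labels are mapped to the
#' package marker names through an alias table; analog channels must
#' include the fore-aft force, vertical force and fore-aft COP.
#'
#' @param path file path.
#' @param alias named character vector mapping file labels to package
#'   marker names, merged over the built-in table (e.g.
#'   `c(RGT = "GT_R")`).
#' @return a validated [raw_trial()].
#' @export
read_c3d <- function(path, alias = NULL) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  allbytes <- readBin(con, raw(), n = sz)
  hdr <- allbytes[1:512]
  get16 <- function(word) readBin(hdr[(2 * word - 1):(2 * word)], integer(),
                                  size = 2, endian = "little")
  getf <- function(word) readBin(hdr[(2 * word - 1):(2 * word + 2)], numeric(),
                                 size = 4, endian = "little")
  param_block <- as.integer(hdr[1])
  if (as.integer(hdr[2]) != 80) stop("not a C3D file", call. = FALSE)
  npts <- get16(2); tot_analog <- get16(3)
  first <- get16(4); last <- get16(5)
  data_start <- get16(9); ratio <- get16(10)
  point_rate <- getf(11)
  nframes <- last - first + 1L
  nanalog <- if (ratio > 0) tot_analog %/% ratio else 0L

  pstart <- (param_block - 1L) * 512L + 1L
  proc <- as.integer(allbytes[pstart + 3L])
  if (!proc %in% c(0L, 84L))
    stop("unsupported C3D processor type (Intel expected)", call. = FALSE)
  pp <- read_c3d_params(allbytes[pstart:((data_start - 1L) * 512L)])
  getp <- function(gname, pname) {
    gid <- names(pp$groups)[match(gname, unlist(pp$groups))]
    if (is.na(gid) || !length(gid)) return(NULL)
    pp$params[[paste0(gid, ":", pname)]]
  }
  scale <- getp("POINT", "SCALE") %||% -1
  if (scale >= 0)
    stop("integer C3D data not supported (float expected)", call. = FALSE)
  labels <- getp("POINT", "LABELS")
  alabels <- getp("ANALOG", "LABELS")
  if (nanalog == 0 || is.null(alabels))
    stop("C3D file has no analog force channels", call. = FALSE)

  dstart <- (data_start - 1L) * 512L + 1L
  per_frame <- 4L * npts + nanalog * ratio
  vals <- readBin(allbytes[dstart:sz], numeric(),
                  n = per_frame * nframes, size = 4, endian = "little")
  if (length(vals) < per_frame * nframes)
    stop("C3D data section truncated", call. = FALSE)
  vals <- array(vals, c(per_frame, nframes))
  pts <- array(vals[seq_len(4L * npts), , drop = FALSE], c(4, npts, nframes))
  ana <- array(vals[(4L * npts + 1L):per_frame, , drop = FALSE],
               c(nanalog, ratio, nframes))

  ## label mapping
  amap <- c3d_marker_aliases()
  if (!is.null(alias)) amap[names(alias)] <- alias
  mapped <- ifelse(labels %in% names(amap), amap[labels], labels)
  missing <- setdiff(required_markers(), mapped)
  if (length(missing))
    stop(sprintf("C3D labels could not be mapped to required markers: %s (file labels: %s)",
                 paste(missing, collapse = ", "),
                 paste(labels, collapse = ", ")), call. = FALSE)

  t_mark <- (seq_len(nframes) - 1L) / point_rate
  coords <- lapply(seq_len(npts), function(i)
    cbind(pts[1, i, ], pts[3, i, ]))
  names(coords) <- mapped
  markers <- marker_trajectories(t_mark, coords = coords)

  need <- c("Fy", "Fz", "COPy")
  ai <- match(need, alabels)
  if (anyNA(ai))
    stop(sprintf("C3D analog channels missing: %s",
                 paste(need[is.na(ai)], collapse = ", ")), call. = FALSE)
  arate <- point_rate * ratio
  t_force <- (seq_len(nframes * ratio) - 1L) / arate
  getan <- function(i) as.numeric(ana[i, , ])
  forces <- force_series(t_force, getan(ai[1]), pmax(getan(ai[2]), 0),
                         getan(ai[3]))

  meta <- trial_meta(subject_id = getp("SUBJECT", "ID") %||% "c3d",
                     mass = getp("SUBJECT", "MASS") %||% NA_real_,
                     height = getp("SUBJECT", "HEIGHT") %||% NA_real_,
                     belt_speed = getp("SUBJECT", "BELT_SPEED") %||% 0,
                     target_step_frequency = getp("SUBJECT", "STEP_FREQ") %||% NA_real_,
                     force_rate = arate, marker_rate = point_rate,
                     gravity = getp("SUBJECT", "GRAVITY") %||% 9.81)
  raw_trial(meta, forces, markers)
}
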