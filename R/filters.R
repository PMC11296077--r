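## Zero-phase low-pass Bessel filtering.
##
## Force and marker channels are conditioned with an 8th-order low-pass
## Bessel filter run forward and backward (zero phase).  The analog
## prototype is designed from the reverse Bessel polynomial, rescaled so
## that the TWO-PASS -3 dB point lands at the requested cutoff, pre-warped
## and mapped to z by the bilinear transform, and applied as a cascade of
## biquads (direct 8th-order recursions are ill-conditioned at cutoff/rate
## ratios this small).

# Reverse Bessel polynomial coefficients, ascending powers s^0..s^n.
bessel_poly_coef <- function(n) {
  k <- 0:n
  exp(lgamma(2 * n - k + 1) - (n - k) * log(2) - lgamma(k + 1) - lgamma(n - k + 1))
}

# |H(jw)|^2 of the delay-normalized prototype H(s) = c0 / theta_n(s).
bessel_gain2 <- function(w, coef) {
  s <- 1i * w
  th <- vapply(s, function(si) sum(coef * si^(seq_along(coef) - 1)), complex(1))
  (coef[1] / Mod(th))^2
}

# Analog prototype poles normalized so a single pass is `gain_db` down at
# w = 1 (gain_db = -1.5 gives a -3 dB two-pass response at w = 1).
bessel_prototype <- function(order, gain_db = -3) {
  coef <- bessel_poly_coef(order)
  poles <- polyroot(coef)
  target <- 10^(gain_db / 10)
  wx <- stats::uniroot(function(w) bessel_gain2(w, coef) - target,
                       lower = 1e-6, upper = 50, tol = 1e-14)$root
  poles / wx
}

# Cascade of biquads (list of lists b, a; a[1] = 1) for a digital low-pass
# of Bessel character with two-pass -3 dB at `cutoff`.
design_bessel_lowpass <- function(cutoff, rate, order = 8) {
  if (order %% 2 != 0 || order < 2)
    stop("filter order must be a positive even integer", call. = FALSE)
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  if (cutoff >= rate / 2)
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff, rate / 2), call. = FALSE)
  proto <- bessel_prototype(order, gain_db = -1.5)
  warp <- 2 * rate * tan(pi * cutoff / rate)   # pre-warped analog cutoff
  p <- proto * warp
  ## pair complex-conjugate poles into biquads
  p <- p[order(Im(p))]
  upper <- p[Im(p) > 0]
  sections <- lapply(upper, function(pk) {
    zp <- (1 + pk / (2 * rate)) / (1 - pk / (2 * rate))  # bilinear
    a1 <- -2 * Re(zp)
    a2 <- Mod(zp)^2
    g <- (1 + a1 + a2) / 4                               # DC gain 1
    list(b = g * c(1, 2, 1), a = c(1, a1, a2))
  })
  sections
}

# One biquad, one direction, via C-level stats::filter.
apply_biquad <- function(x, b, a) {
  xb <- b[1] * x
  n <- length(x)
  if (n > 1) xb[2:n] <- xb[2:n] + b[2] * x[1:(n - 1)]
  if (n > 2) xb[3:n] <- xb[3:n] + b[3] * x[1:(n - 2)]
  as.numeric(stats::filter(xb, -a[2:3], method = "recursive"))
}

#' Zero-phase low-pass Bessel filter
#'
#' Filters a uniformly sampled signal with an even-order low-pass filter of
#' Bessel character applied forward and then backward, so the net response
#' has zero phase lag and unit DC gain.  The analog cutoff is pre-warped so
#' that the two-pass attenuation at `cutoff` is exactly -3 dB.
#'
#' Edge transients are suppressed by odd reflection padding before the two
#' passes; the padding is removed from the returned signal.
#'
#' @param x numeric vector, uniformly sampled signal (NA not allowed).
#' @param cutoff low-pass cutoff frequency in Hz (below Nyquist).
#' @param rate sampling rate in Hz.
#' @param order filter order; positive even integer (default 8).
#' @return numeric vector of the same length as `x`.
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' x <- sin(2 * pi * 2 * t) + sin(2 * pi * 200 * t)
#' y <- lowpass_zero_phase(x, cutoff = 30, rate = 1000)
#' @export
lowpass_zero_phase <- function(x, cutoff, rate, order = 8) {
  if (anyNA(x)) stop("signal contains NA; fill gaps before filtering", call. = FALSE)
  n <- length(x)
  sections <- design_bessel_lowpass(cutoff, rate, order)
  npad <- min(n - 1, max(3 * ceiling(rate / cutoff), 50))
  if (n <= 3) return(x)
  ## odd reflection about the end points
  head_pad <- 2 * x[1] - x[(npad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - npad)]
  y <- c(head_pad, x, tail_pad)
  for (s in sections) y <- apply_biquad(y, s$b, s$a)
  y <- rev(y)
  for (s in sections) y <- apply_biquad(y, s$b, s$a)
  y <- rev(y)
  y[(npad + 1):(npad + n)]
}
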