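test_that("zero-phase filter has unit DC gain and preserves pass-band tones", {
  fs <- 1000
  tt <- seq(0, 2, by = 1 / fs)
  expect_lt(max(abs(lowpass_zero_phase(rep(3.7, length(tt)), 30, fs) - 3.7)), 1e-9)

  x <- sin(2 * pi * tt)
  y <- lowpass_zero_phase(x, 30, fs)
  mid <- tt > 0.5 & tt < 1.5
  fit <- stats::lm(y[mid] ~ sin(2 * pi * tt[mid]) + cos(2 * pi * tt[mid]) - 1)
  amp <- sqrt(sum(stats::coef(fit)^2))
  expect_lt(abs(amp - 1), 0.01)
  ## peak alignment: zero phase within one sample
  i_in <- which.max(x[mid]); i_out <- which.max(y[mid])
  expect_lte(abs(i_in - i_out), 1)
})

test_that("stop-band tones are attenuated by more than 40 dB", {
  fs <- 1000
  tt <- seq(0, 2, by = 1 / fs)
  y <- lowpass_zero_phase(sin(2 * pi * 200 * tt), 30, fs)
  mid <- tt > 0.5 & tt < 1.5
  expect_lt(20 * log10(max(abs(y[mid]))), -40)
})

test_that("filtering a time-symmetric pulse leaves its peak in place", {
  fs <- 1000
  tt <- seq(0, 2, by = 1 / fs)
  for (width in c(0.02, 0.05, 0.2)) {
    x <- exp(-((tt - 1) / width)^2)
    y <- lowpass_zero_phase(x, 30, fs)
    expect_lte(abs(which.max(y) - which.max(x)), 1)
  }
  expect_error(lowpass_zero_phase(sin(tt), 600, fs), "Nyquist")
})

test_that("spline resampling is exact at knots and on cubics", {
  t200 <- seq(0, 1, by = 1 / 200)
  poly <- function(t) 2 - 3 * t + 0.5 * t^2 + 4 * t^3
  mk <- marker_trajectories(t200, a = cbind(poly(t200), 1 + t200))
  same <- resample_spline(mk, t200)
  expect_equal(marker_xy(same, "a"), marker_xy(mk, "a"), tolerance = 1e-12,
               ignore_attr = TRUE)
  t1k <- seq(0, 1, by = 1 / 1000)
  up <- resample_spline(mk, t1k)
  interior <- t1k >= 0.05 & t1k <= 0.95
  expect_lt(max(abs(marker_xy(up, "a")[interior, 1] - poly(t1k)[interior])), 1e-9)
})

test_that("spline resampling reproduces a slow sine to 1e-4 of amplitude", {
  t200 <- seq(0, 1, by = 1 / 200)
  t1k <- seq(0, 1, by = 1 / 1000)
  mk <- marker_trajectories(t200, a = cbind(sin(2 * pi * 5 * t200), t200))
  up <- resample_spline(mk, t1k)
  interior <- t1k >= 0.05 & t1k <= 0.95
  expect_lt(max(abs(marker_xy(up, "a")[interior, 1] -
                    sin(2 * pi * 5 * t1k)[interior])), 1e-4)
  mk$a_y[3] <- NA
  expect_error(resample_spline(mk, t1k), "gap")
})

test_that("contact detection matches the analytic half-sine crossing", {
  fs <- 1000; m <- 70; g <- 9.81
  tt <- seq(0, 3.5, by = 1 / fs)
  Fz <- numeric(length(tt))
  for (t0 in seq(0.2, 3, by = 0.7)) {
    idx <- tt >= t0 & tt < t0 + 0.3
    Fz[idx] <- 1600 * sin(pi * (tt[idx] - t0) / 0.3)
  }
  cc <- detect_contacts(Fz, m * g, 0.10, fs)
  expect_identical(nrow(cc), 5L)
  t_star <- (0.3 / pi) * asin(0.1 * m * g / 1600)
  for (i in seq_len(nrow(cc))) {
    t0 <- 0.2 + (i - 1) * 0.7
    expect_lt(abs(tt[cc$onset[i]] - (t0 + t_star)), 1.5 / fs)
    expect_lt(abs(tt[cc$offset[i]] - (t0 + 0.3 - t_star)), 1.5 / fs)
  }
  expect_warning(detect_contacts(rep(0, 1000), m * g), "no foot contact")
  quiet <- detect_contacts(rep(m * g, 1000), m * g, 0.10, fs)
  expect_identical(nrow(quiet), 1L)
  expect_identical(c(quiet$onset, quiet$offset), c(1L, 1001L))
})

test_that("raising the contact threshold never lengthens a contact", {
  sim <- rigid_sim()
  Fz <- sim$trial$forces$Fz
  bw <- sim$trial$meta$mass * 9.81
  prev <- detect_contacts(Fz, bw, 0.05)
  for (thr in c(0.10, 0.20, 0.40)) {
    cur <- detect_contacts(Fz, bw, thr)
    expect_lte(nrow(cur), nrow(prev))
    for (i in seq_len(nrow(cur))) {
      j <- which(prev$onset <= cur$onset[i] & prev$offset >= cur$offset[i])
      expect_identical(length(j), 1L)
    }
    prev <- cur
  }
})

test_that("feet are labelled correctly and strides partition the record", {
  sim <- rigid_sim()
  an <- rigid_analysis()
  off <- grid_offset(sim, an)
  det <- an$strides$contacts
  truth <- sim$truth$contacts
  for (i in seq_len(nrow(det))) {
    mid <- (det$onset[i] + det$offset[i]) / 2 + off
    j <- which(truth$onset <= mid & truth$offset > mid)
    if (length(j) == 1) expect_identical(det$foot[i], truth$foot[j])
  }
  st <- an$strides$strides
  expect_identical(st$start[-1], st$end[-nrow(st)])  # strides partition
  expect_identical(nrow(st), 6L)
  ## each stride holds exactly one left touchdown
  for (i in seq_len(nrow(st))) {
    ltd <- det$onset[det$foot == "L" & det$onset > st$start[i] &
                       det$onset < st$end[i]]
    expect_identical(length(ltd), 1L)
  }
})

test_that("degenerate contact streams are handled with warnings", {
  sim <- cached("io_sim", simulate_trial(sim_params(n_strides = 2)))
  an2 <- suppressWarnings(analyze_trial(sim$trial))
  one <- an2$strides$contacts[1, c("onset", "offset")]
  expect_warning(
    assign_feet_and_strides(one, an2$prepared$forces, an2$prepared$markers),
    "no complete stride")
  two <- an2$strides$contacts[1:2, c("onset", "offset")]
  two$offset[1] <- two$onset[2] + 10L
  expect_error(
    assign_feet_and_strides(two, an2$prepared$forces, an2$prepared$markers),
    "running")
})

test_that("expected stride count comes out of a fixed-duration trial", {
  ## 7 strides at 2.8 steps/s span 5 s; the pipeline must find all 7
  sim <- cached("count_sim", simulate_trial(sim_params(n_strides = 7)))
  an <- suppressWarnings(analyze_trial(sim$trial))
  expect_gte(nrow(an$strides$strides), 6L)
  expect_lte(nrow(an$strides$strides), 8L)
})
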