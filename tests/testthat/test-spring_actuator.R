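# Build a bw_leg series directly from prescribed L(t) and F(t).
make_leg <- function(tt, L, Fp, valid = rep(TRUE, length(tt)), rate = 1000) {
  V <- rep(NA_real_, length(tt))
  v <- which(valid)
  V[v[1]:v[length(v)]] <- bouncework:::fd_velocity(L[v[1]:v[length(v)]],
                                                   1 / rate)
  out <- data.frame(idx = seq_along(tt), time = tt, L_leg = L, V_leg = V,
                    leg_angle = 0, F_projected = Fp, valid = valid)
  class(out) <- c("bw_leg", "data.frame")
  out
}

test_that("force projection onto the leg axis is geometric", {
  tt <- seq(0, 0.2, by = 1e-3)
  n <- length(tt)
  f <- force_series(tt, rep(0, n), rep(800, n), rep(0, n))
  ## vertical leg: COP directly below GT
  gt <- cbind(rep(0, n), rep(0.9, n))
  leg <- leg_series(f, gt, 1L, n + 1L, mass = 80)
  expect_equal(leg$F_projected, rep(10, n))
  expect_equal(leg$L_leg, rep(0.9, n))
  ## 45 degrees: projection scales by cos(45)
  gt45 <- cbind(rep(0.9, n), rep(0.9, n))
  leg45 <- leg_series(f, gt45, 1L, n + 1L, mass = 80)
  expect_equal(leg45$F_projected, rep(10 * cos(pi / 4), n), tolerance = 1e-12)
  expect_equal(leg45$F_projected[1], 7.07, tolerance = 1e-3)
})

test_that("a rotating leg of constant length has zero leg velocity", {
  tt <- seq(0, 0.3, by = 1e-3)
  n <- length(tt)
  ang <- seq(-0.4, 0.4, length.out = n)
  L0 <- 0.92
  gt <- cbind(L0 * sin(ang), L0 * cos(ang))
  f <- force_series(tt, rep(0, n), rep(800, n), rep(0, n))
  leg <- leg_series(f, gt, 1L, n + 1L, mass = 80)
  expect_lt(max(abs(leg$V_leg), na.rm = TRUE), 1e-4)
  gt[5, 1] <- NA
  expect_error(leg_series(f, gt, 1L, n + 1L, 80), "gap")
})

test_that("low-force frames are masked out of the leg series", {
  tt <- seq(0, 0.3, by = 1e-3)
  n <- length(tt)
  Fz <- 1600 * sin(pi * tt / 0.3)
  f <- force_series(tt, rep(0, n), Fz, rep(0, n))
  gt <- cbind(rep(0, n), rep(0.9, n))
  leg <- leg_series(f, gt, 1L, n + 1L, mass = 80)
  expect_true(all(is.na(leg$L_leg[!leg$valid])))
  expect_identical(leg$valid, Fz >= 300)
})

test_that("compression splits at the leg-length minimum, earliest on ties", {
  tt <- seq(0, 0.3, by = 1e-3)
  L <- 1 - 0.05 * (1 - cos(2 * pi * tt / 0.3))
  leg <- make_leg(tt, L, 10 + 0 * tt)
  sp <- compression_split(leg)
  expect_equal(tt[sp$min_pos], 0.15, tolerance = 1e-3)
  ## V shape
  Lv <- c(seq(1, 0.9, length.out = 151), seq(0.9, 1, length.out = 151)[-1])
  spv <- compression_split(make_leg(tt, Lv, 10 + 0 * tt))
  expect_identical(spv$min_pos, 151L)
  ## two equal minima: earliest chosen
  L2 <- 1 - 0.05 * abs(sin(2 * pi * tt / 0.3))
  sp2 <- compression_split(make_leg(tt, L2, 10 + 0 * tt))
  expect_equal(tt[sp2$min_pos], 0.075, tolerance = 2e-3)
  ## monotone: degenerate
  expect_warning(out <- compression_split(make_leg(tt, 1 - 0.1 * tt, 10 + 0 * tt)),
                 "monotone|degenerate")
  expect_null(out)
})

test_that("hysteresis area is zero for a conservative spring", {
  tt <- seq(0, 0.3, by = 1e-3)
  L <- 1 - 0.05 * (1 - cos(2 * pi * tt / 0.3))
  Fk <- 2 + 30 * L
  ha <- hysteresis_area(make_leg(tt, L, Fk))
  expect_lt(abs(ha$delta_area), 1e-6)
  expect_false(ha$open_loop)
})

test_that("hysteresis area matches the closed form for a damped loop", {
  A <- 0.05; om <- 2 * pi / 0.3; cc <- -100
  tt <- seq(0, 0.3, by = 1e-3)
  L <- 1 - A * (1 - cos(om * tt))
  V <- -A * om * sin(om * tt)
  Fp <- 2 + 30 * L + cc * V
  ha <- hysteresis_area(make_leg(tt, L, Fp))
  closed <- -cc * pi * A^2 * om
  expect_equal(closed, 16.45, tolerance = 1e-3)
  expect_equal(ha$delta_area, closed, tolerance = 0.005)
  ## independent quadrature oracle: -c * integral of V^2 dt
  oracle <- -cc * pracma::trapz(tt, V^2)
  expect_equal(ha$delta_area, oracle, tolerance = 0.005)
  ## literal split-integral variant: signed decompression integral minus
  ## signed compression integral, computed here independently
  lit <- hysteresis_area(make_leg(tt, L, Fp), mode = "literal")
  i_min <- which.min(L)
  lit_oracle <- pracma::trapz(L[i_min:length(L)], Fp[i_min:length(L)]) -
    pracma::trapz(L[1:i_min], Fp[1:i_min])
  expect_equal(lit$delta_area, lit_oracle, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(lit$delta_area, ha$delta_area)))
})

test_that("hysteresis area is stable under 2x resampling", {
  A <- 0.05; om <- 2 * pi / 0.3; cc <- -40
  for (rate in c(1000, 2000)) {
    tt <- seq(0, 0.3, by = 1 / rate)
    L <- 1 - A * (1 - cos(om * tt))
    Fp <- 2 + 30 * L + cc * (-A * om * sin(om * tt))
    ha <- hysteresis_area(make_leg(tt, L, Fp, rate = rate))
    if (rate == 1000) base <- ha$delta_area
  }
  expect_lt(abs(ha$delta_area - base) / base, 0.005)
})

test_that("the spring-actuator fit is exact on noiseless data", {
  tt <- seq(0, 0.3, by = 1e-3)
  L <- 1 - 0.05 * (1 - cos(2 * pi * tt / 0.3))
  V <- -0.05 * (2 * pi / 0.3) * sin(2 * pi * tt / 0.3)
  leg <- make_leg(tt, L, 2 + 30 * L - 5 * V)
  ## make_leg's finite-difference V differs from the analytic V at
  ## O(dt^2); rebuild F from the stored V so the model is exactly linear
  leg$F_projected <- 2 + 30 * leg$L_leg - 5 * leg$V_leg
  fit <- fit_spring_actuator(leg)
  expect_equal(fit$cst, 2, tolerance = 1e-9)
  expect_equal(fit$k, 30, tolerance = 1e-9)
  expect_equal(fit$c, -5, tolerance = 1e-9)
  expect_equal(fit$rmse, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("fit coefficients match an independent normal-equations oracle", {
  sim <- simulate_spring_loop(n_steps = 5, noise_sd = 0.8, seed = 7)
  for (st in sim$steps) {
    leg <- make_leg(st$time, st$L_leg, st$F_projected)
    leg$V_leg <- st$V_leg                 # analytic velocity from the law
    fit <- fit_spring_actuator(leg)
    ok <- leg$valid & !is.na(leg$V_leg)
    X <- cbind(1, leg$L_leg[ok], leg$V_leg[ok])
    beta <- solve(t(X) %*% X, t(X) %*% st$F_projected[ok])
    expect_equal(unname(c(fit$cst, fit$k, fit$c)), as.numeric(beta),
                 tolerance = 1e-8)
    ## R^2 and RMSE from their textbook definitions
    res <- st$F_projected[ok] - X %*% beta
    expect_equal(fit$rmse, sqrt(mean(res^2)), tolerance = 1e-10)
    expect_equal(fit$r_squared,
                 1 - sum(res^2) / sum((st$F_projected[ok] -
                                         mean(st$F_projected[ok]))^2),
                 tolerance = 1e-10)
  }
})

test_that("rank-deficient designs are rejected", {
  tt <- seq(0, 0.3, by = 1e-3)
  leg <- make_leg(tt, rep(1, length(tt)), rep(10, length(tt)))
  leg$V_leg <- rep(0, length(tt))         # constant L and V: collinear
  expect_error(fit_spring_actuator(leg), "collinear|rank")
  short <- make_leg(tt[1:8], rep(1, 8), rep(10, 8))
  expect_error(fit_spring_actuator(short), "10 valid")
})

test_that("noisy Monte-Carlo recovery of the spring law is unbiased", {
  sim <- simulate_spring_loop(n_steps = 50, spring = c(2, 30, -5),
                              noise_sd = 1, seed = 11)
  fits <- do.call(rbind, lapply(sim$steps, function(st) {
    leg <- make_leg(st$time, st$L_leg, st$F_projected)
    leg$V_leg <- st$V_leg
    fit_spring_actuator(leg)
  }))
  expect_lt(abs(mean(fits$k) - 30) / 30, 0.02)
  expect_lt(abs(mean(fits$c) - (-5)) / 5, 0.05)
  expect_lt(abs(mean(fits$rmse) - 1), 0.10)
})
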