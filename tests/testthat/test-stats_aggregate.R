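test_that("stride aggregation averages right/left first, then strides", {
  bd <- partition_work(
    data.frame(stride_id = 1:3, W_plus = c(1, 2, 3), W_minus = c(-1, -2, -3)),
    data.frame(stride_id = 1:3, W_plus = 0, W_minus = 0),
    data.frame(stride_id = 1:3, W_plus = 0, W_minus = 0),
    data.frame(stride_id = 1:3, W_plus = 0, W_minus = 0),
    data.frame(stride_id = 1:3, W_plus = 0, W_minus = 0),
    data.frame(stride_id = 1:3, W_plus = 0, W_minus = 0), mass = 1)
  fits <- data.frame(stride_id = c(1, 1, 2, 2, 3, 3),
                     foot = rep(c("R", "L"), 3),
                     cst = 0, k = c(4, 6, 4, 6, 4, 6), c = -1, rmse = 0,
                     r_squared = 1, delta_area = 0.5, n_frames = 100)
  s <- aggregate_trial(bd, fits)
  expect_equal(s$W_com_plus_kg, 2)          # mean of 1, 2, 3
  expect_equal(s$k, 5)                      # left/right averaged per stride
  expect_equal(s$n_strides, 3L)
  ## order of left and right within the stride must not matter
  s2 <- aggregate_trial(bd, fits[c(2, 1, 4, 3, 6, 5), ])
  expect_equal(s2$k, s$k)
  ## single stride: the summary is that stride
  s1 <- aggregate_trial(bd[1, ], fits[1:2, ])
  expect_equal(s1$W_com_plus_kg, 1)
})

test_that("pearson_ci reproduces the published Fisher-interval arithmetic", {
  r70 <- pearson_ci(r = 0.70, n = 193)
  expect_identical(r70$df, 191)
  expect_equal(round(r70$ci95[1], 2), 0.62)
  r61 <- pearson_ci(r = 0.61, n = 193)
  expect_equal(round(r61$ci95, 2), c(0.51, 0.69))
  expect_lt(r61$p, 0.001)
})

test_that("pearson_ci handles exact, null and degenerate correlations", {
  x <- c(1, 2, 4, 7, 9, 12)
  out <- suppressWarnings(pearson_ci(x, 2 * x + 1))
  expect_equal(out$r, 1)
  expect_equal(out$ci95, c(1, 1))
  ## closed-form Fisher interval at r = 0, n = 50
  r0 <- pearson_ci(r = 0, n = 50)
  expect_equal(round(r0$ci95, 3), c(-0.278, 0.278))
  expect_error(pearson_ci(x, rep(1, 6)), "variance")
  expect_error(pearson_ci(x[1:3], x[1:3]), "at least 4")
  ## the interval always contains r
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(12); b <- rnorm(12) + 0.5 * a
    ci <- pearson_ci(a, b)
    expect_true(ci$ci95[1] <= ci$r && ci$r <= ci$ci95[2])
  }
})

test_that("fisher interval coverage is near nominal", {
  set.seed(2024)
  rho <- 0.7; n <- 193
  hits <- 0; reps <- 500
  for (i in seq_len(reps)) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    ci <- pearson_ci(x, y)
    hits <- hits + (ci$ci95[1] <= rho && rho <= ci$ci95[2])
  }
  expect_gt(hits / reps, 0.91)
  expect_lt(hits / reps, 0.99)
})

test_that("correlation table finds constructed dependence and independence", {
  ## damping sweep of the loop law: dissipation is the only varying factor
  cs <- c(0, -25, -50, -75, -100)
  rows <- do.call(rbind, lapply(seq_along(cs), function(i) {
    sim <- simulate_spring_loop(n_steps = 3, spring = c(2, 30, cs[i]),
                                noise_sd = 0.5, seed = 100 + i)
    da <- vapply(sim$steps, function(st) {
      leg <- data.frame(idx = seq_along(st$time), time = st$time,
                        L_leg = st$L_leg, V_leg = st$V_leg, leg_angle = 0,
                        F_projected = st$F_projected, valid = TRUE)
      class(leg) <- c("bw_leg", "data.frame")
      hysteresis_area(leg)$delta_area
    }, numeric(1))
    data.frame(delta_area = mean(da), W_ST_total_kg = sim$truth$delta_area,
               c = cs[i], k = 30 + rnorm(1, 0, 0.5))
  }))
  tab <- correlation_table(rows)
  r_st <- tab$r[tab$pair == "delta_area vs W_ST_total_kg"]
  expect_gt(r_st, 0.9)
  ## k varied with c fixed at zero: delta_area carries no k information
  set.seed(5)
  ks <- seq(20, 60, length.out = 12)
  rows_k <- do.call(rbind, lapply(seq_along(ks), function(i) {
    sim <- simulate_spring_loop(n_steps = 2, spring = c(2, ks[i], 0),
                                noise_sd = 0.5, seed = 200 + i)
    leg <- data.frame(idx = seq_along(sim$steps[[1]]$time),
                      time = sim$steps[[1]]$time,
                      L_leg = sim$steps[[1]]$L_leg,
                      V_leg = sim$steps[[1]]$V_leg, leg_angle = 0,
                      F_projected = sim$steps[[1]]$F_projected, valid = TRUE)
    class(leg) <- c("bw_leg", "data.frame")
    data.frame(delta_area = hysteresis_area(leg)$delta_area,
               W_ST_total_kg = 0.1, c = 0, k = ks[i])
  }))
  rows_k$W_ST_total_kg <- rnorm(nrow(rows_k))   # uninformative axis
  rows_k$c <- rnorm(nrow(rows_k), 0, 1e-3)      # c pinned at (almost) zero
  tab_k <- correlation_table(rows_k)
  expect_lt(abs(tab_k$r[tab_k$pair == "delta_area vs k"]), 0.3)
  ## duplicating rows leaves r unchanged
  tab_dup <- correlation_table(rbind(rows, rows))
  expect_equal(tab_dup$r, tab$r, tolerance = 1e-12)
})
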