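fake_seg <- function(vel_y, vel_z = 0 * vel_y, mass = 1, inertia = 0,
                     omega = 0 * vel_y) {
  list(vel = cbind(vel_y, vel_z), mass = mass, inertia = inertia,
       omega = omega)
}

test_that("internal energy evaluates the segmental formula", {
  n <- 100
  com <- list(v_f = rep(1, n), v_v = rep(0, n))
  moving_with <- fake_seg(rep(1, n))
  expect_equal(internal_energy_limb(list(moving_with), com), rep(0, n))
  seg <- fake_seg(rep(1 + 2, n), mass = 3, inertia = 0.05,
                  omega = rep(10, n))
  E <- internal_energy_limb(list(seg), com)
  expect_equal(E, rep(0.5 * (3 * 4 + 0.05 * 100), n))
  expect_equal(E[1], 8.5)
})

test_that("ipsilateral transfer is allowed: antiphase segments cancel", {
  n <- 1001
  tt <- seq(0, 1, length.out = n)
  e <- 2 + sin(2 * pi * 3 * tt)           # energy of segment 1, J
  com <- list(v_f = rep(0, n), v_v = rep(0, n))
  seg1 <- fake_seg(sqrt(2 * e), mass = 1)            # 1/2 m v^2 = e
  seg2 <- fake_seg(sqrt(2 * (4 - e)), mass = 1)      # antiphase + offset
  E_limb <- internal_energy_limb(list(seg1, seg2), com)
  w_limb <- work_increments(E_limb, 1:n)
  expect_lt(w_limb$W_plus, 1e-9)
  ## without the transfer rule the positive work would be substantial
  w_sep <- work_increments(internal_energy_limb(list(seg1), com), 1:n)$W_plus +
    work_increments(internal_energy_limb(list(seg2), com), 1:n)$W_plus
  expect_gt(w_sep, 1)
})

test_that("static stance reproduces the hand-derived ankle moment balance", {
  m <- 70; g <- 9.81
  fx <- static_fixture(mass = m, cop_ahead = 0.10)
  loaded <- rep(TRUE, fx$n)
  jk <- inverse_dynamics_limb(fx$forces$Fy, fx$forces$Fz, fx$forces$COPy,
                              rep(TRUE, fx$n), loaded, fx$segs, "R", g)
  ## independent static oracle: moments about the ankle joint
  foot <- fx$segs$foot_R
  com_off <- unname(foot$com[1, ] - c(0, 0.08))  # foot CoM relative to ankle
  oracle <- m * g * 0.10 - foot$mass * g * com_off[1]
  expect_equal(jk$ankle$M[25], oracle, tolerance = 1e-9)
  expect_equal(m * g * 0.10, 68.67, tolerance = 1e-4)

  ## massless-foot limit with the COP under the ankle: no lever, no moment
  fx0 <- static_fixture(mass = m, cop_ahead = 0, foot_fraction = 1e-9)
  jk0 <- inverse_dynamics_limb(fx0$forces$Fy, fx0$forces$Fz, fx0$forces$COPy,
                               rep(TRUE, fx0$n), loaded, fx0$segs, "R", g)
  expect_lt(max(abs(jk0$ankle$M)), 1e-6)
})

test_that("joint power is exactly moment times angular velocity", {
  an <- rigid_analysis()
  for (side in c("R", "L")) {
    jj <- an$joints[[side]]
    for (j in c("ankle", "knee", "hip"))
      expect_equal(jj[[j]]$P, jj[[j]]$M * jj[[j]]$omega, tolerance = 1e-12)
    expect_equal(jj$P_limb, jj$ankle$P + jj$knee$P + jj$hip$P,
                 tolerance = 1e-12)
  }
})

test_that("pipeline joint moments track the ledger at matched bandwidth", {
  ## the construction carries supra-physiological transients above the
  ## 30 Hz analysis band, so ledger moments are band-limited the same way
  ## before comparison
  sim <- rigid_sim()
  an <- rigid_analysis()
  off <- grid_offset(sim, an)
  st <- an$strides$strides
  span <- st$start[2]:st$end[nrow(st) - 1]
  for (side in c("R", "L")) {
    for (j in c("ankle", "knee", "hip")) {
      truth <- lowpass_zero_phase(sim$truth$joints[[side]][[paste0("M_", j)]],
                                  30, 1000)
      Mp <- an$joints[[side]][[j]]$M[span]
      Mt <- truth[span + off]
      expect_lt(sqrt(mean((Mp - Mt)^2)) / sqrt(mean(Mt^2)), 0.03)
    }
  }
})

test_that("COP clamping inside low-force frames is counted", {
  an <- rigid_analysis()
  prep <- an$prepared
  ff <- foot_forces(prep$forces, an$strides, "R")
  jk <- inverse_dynamics_limb(ff$Fy, ff$Fz, prep$forces$COPy,
                              prep$forces$valid_cop, ff$loaded,
                              build_segments(prep$markers, prep$meta$mass),
                              "R")
  expect_gt(attr(jk, "cop_clamped"), 0)   # contact edges sit under 300 N
})

test_that("constant limb power integrates to the rectangle work", {
  n <- 701
  tt <- seq(0, 0.7, length.out = n)
  joints <- structure(list(P_limb = rep(50, n)), class = "bw_joints")
  com <- list(stride_rows = list(1:n))
  out <- joint_power_work(joints, tt, com)
  expect_equal(out$work$W_plus, 35, tolerance = 1e-9)
  expect_equal(out$work$W_minus, 0)
  ## antiphase joint powers cancel before integration
  joints2 <- structure(list(P_limb = sin(2 * pi * tt) - sin(2 * pi * tt)),
                       class = "bw_joints")
  out2 <- joint_power_work(joints2, tt, com)
  expect_equal(out2$work$W_plus, 0)
})

test_that("partition identities hold exactly and misalignment errors", {
  w <- function(p, m) data.frame(stride_id = 1:2, W_plus = p, W_minus = m)
  bd <- partition_work(w(c(2, 2), c(-2, -2)), w(c(0.5, 0.5), c(-0.4, -0.4)),
                       w(c(0.5, 0.5), c(-0.4, -0.4)), w(c(0.2, 0.2), c(-0.1, -0.1)),
                       w(c(0.8, 0.8), c(-1, -1)), w(c(0.8, 0.8), c(-1, -1)),
                       mass = 1)
  expect_equal(bd$W_tot_plus, c(3.2, 3.2))
  expect_equal(bd$W_ST_plus, c(3.2 - 1.6, 3.2 - 1.6))
  expect_equal(bd$W_ST_minus, c(-2.9 + 2, -2.9 + 2))
  ## the same arithmetic in J/kg
  expect_equal(2.0 - 0.8 - 0.8, 0.4)
  bad <- w(c(1, 1), c(-1, -1)); bad$stride_id <- c(5L, 6L)
  expect_error(partition_work(w(c(2, 2), c(-2, -2)), bad, bad, bad, bad, bad, 1),
               "stride sets")
})

test_that("work partition invariants hold on rigid synthetic running", {
  an <- rigid_analysis()
  b <- an$breakdown
  expect_equal(b$W_tot_plus,
               b$W_com_plus + b$W_int_R_plus + b$W_int_L_plus + b$W_int_trunk_plus)
  expect_equal(b$W_ST_plus, b$W_tot_plus - b$W_j_R_plus - b$W_j_L_plus)
  ## rigid-mode null: the soft-tissue residual is bounded
  expect_lt(abs(mean(b$W_ST_minus)) / mean(b$W_tot_plus), 0.10)
  ## steady state: positive and negative total work balance
  expect_lt(abs(mean(b$W_tot_plus) + mean(b$W_tot_minus)) / mean(b$W_tot_plus),
            0.02)
})

test_that("soft tissues do more negative than positive work with a wobble", {
  a_r <- rigid_analysis()
  a_w <- wobble_analysis()
  d_minus <- mean(a_w$breakdown$W_ST_minus) - mean(a_r$breakdown$W_ST_minus)
  d_plus <- mean(a_w$breakdown$W_ST_plus) - mean(a_r$breakdown$W_ST_plus)
  expect_lt(d_minus, 0)
  expect_gte(d_plus, 0)
  expect_gt(abs(d_minus), abs(d_plus))
})
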