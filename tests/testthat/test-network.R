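test_that("resting state carries zero current in every branch", {
  for (N in c(1, 3, 40)) {
    sc <- std_scaling(N)
    r <- resting_state(sc)
    expect_equal(r$u, rep(-97, N))
    expect_equal(r$V_is, -62)
    expect_equal(r$V_a, 35)       # transepithelial potential
    expect_equal(r$V_ed, rep(35, N))
    cur <- circuit_currents(r, sc)
    expect_equal(max(abs(unlist(cur))), 0)
  }
})

test_that("inconsistent batteries give a numerically solved rest", {
  b <- sensillum_base_params(E_a = -20)  # E_ld stays E_ls + E_a: consistent
  expect_true(check_battery_consistency(derive_cable_params(b)))
  # force inconsistency by editing the derived battery directly
  sc <- std_scaling(4)
  sc$derived$E_ld <- -90
  expect_warning(r <- resting_state(sc), "inconsistent")
  # the numeric rest still balances Kirchhoff at every node
  st <- steady_state_numeric_residual(sc, r)
  expect_lt(st, 1e-9)
})

test_that("axial currents respond to node differences, not offsets", {
  sc <- std_scaling(2)
  r <- resting_state(sc)
  # uniform offset of all intracellular nodes leaves axial currents at 0
  r2 <- r
  r2$V_id <- r$V_id + 1
  r2$u <- r2$V_id - r2$V_ed
  cur <- circuit_currents(r2, sc)
  expect_equal(cur$I_i[1], 0)  # between the two dendritic compartments
  # a 10 mV difference across g_ic drives g_ic * 10 pA
  r3 <- r
  r3$V_id <- r$V_id + c(10, 0)
  r3$u <- r3$V_id - r3$V_ed
  cur3 <- circuit_currents(r3, sc)
  expect_equal(cur3$I_i[1], sc$g_ic * 10)
})

test_that("unstimulated trajectories stay at rest with RP = SP = 0", {
  sc <- std_scaling(5)
  tr <- integrate_simplified(sc, conductance_protocol("step", G_p = 0),
                             t_end = 0.05, dt_out = 1e-3)
  expect_lt(max(abs(tr$RP)), 1e-8)
  expect_lt(max(abs(tr$SP)), 1e-8)
  expect_lt(max(abs(tr$RP_s)), 1e-8)
  pot <- extract_potentials(tr)
  expect_equal(pot$RP_b, rep(0, nrow(pot)), tolerance = 1e-8)
  # zero-drive complete model stays at rest too
  scc <- std_scaling(3)
  drv <- drive_protocol()
  trc <- integrate_complete(scc, drv, U = 0, t_end = 0.2, dt_out = 0.01)
  expect_lt(max(abs(trc$RP)), 1e-6)
  expect_lt(max(abs(trc$SP)), 1e-6)
})

test_that("trajectories not starting at rest are refused for RP extraction", {
  sc <- std_scaling(3)
  tr <- integrate_simplified(sc, conductance_protocol("step", G_p = 1),
                             t_end = 0.05, dt_out = 1e-3)
  tr$u[1, ] <- tr$u[1, ] + 5
  expect_error(extract_potentials(tr), "resting state")
})

test_that("stimulation depolarizes RP and drives SP negative", {
  sc <- std_scaling(10)
  tr <- integrate_simplified(sc, conductance_protocol("step", G_p = 1),
                             t_end = 0.1, dt_out = 1e-3)
  expect_gt(min(tail(tr$RP_b, 5)), 0)
  expect_lt(max(tail(tr$SP, 5)), 0)
  expect_gt(min(tail(tr$RP_s, 5)), 0)
  # RP declines monotonically from tip to base at steady state
  prof <- tr$RP[nrow(tr$RP), ]
  expect_true(all(diff(prof) < 0))
})

test_that("Kirchhoff balance holds along simplified trajectories", {
  sc <- std_scaling(6)
  tr <- integrate_simplified(sc, conductance_protocol("square", G_p = 2,
                                                      onset = 0.01,
                                                      offset = 0.06),
                             t_end = 0.1, dt_out = 1e-3)
  # the wire-sum constraint (axial inflows on both wires balance the same
  # membrane current) must hold at every stored sample
  for (k in seq(1, length(tr$time), by = 10)) {
    st <- list(u = tr$u[k, ], V_is = tr$V_is[k], V_a = tr$V_a[k],
               V_ed = tr$V_ed[k, ], V_id = tr$V_id[k, ])
    expect_lt(wire_sum_residual(st, sc), 1e-8)
  }
})

test_that("steady integration matches the direct steady linear solve", {
  sc <- std_scaling(12)
  G_p <- 2.5
  tr <- integrate_simplified(sc, conductance_protocol("step", G_p = G_p),
                             t_end = 0.15, dt_out = 5e-3)
  st <- steady_state_simplified(sc, G_p)
  expect_equal(tr$u[nrow(tr$u), ], st$u, tolerance = 1e-5)
  expect_equal(tail(tr$V_is, 1), st$V_is, tolerance = 1e-5)
  expect_equal(tail(tr$SP, 1), attr(st, "SP"), tolerance = 1e-4)
})

test_that("steady-state SP is proportional to RP across stimulus strength", {
  sc <- std_scaling(20)
  G <- c(0.064, 0.25, 1, 4)
  ratio <- vapply(G, function(g) {
    st <- steady_state_simplified(sc, g)
    attr(st, "SP") / attr(st, "RP_b")
  }, numeric(1))
  # dose-independent to within 1% over the physiological conductance range
  expect_lt(max(ratio) - min(ratio), 0.01 * abs(mean(ratio)))
  expect_lt(mean(ratio), 0)
})

test_that("negative or mismatched conductance protocols are rejected", {
  sc <- std_scaling(3)
  expect_error(conductance_protocol("step", G_p = -1), "non-negative")
  expect_error(conductance_protocol("table", time = 1:3,
                                    g = matrix(-1, 3, 3)), "non-negative")
  expect_error(steady_state_simplified(sc, g_p = c(1, 1)), "length N")
  expect_error(steady_state_simplified(sc), "G_p")
})

test_that("lumped replay reproduces the complete model's potentials", {
  sc <- std_scaling(6)
  drv <- drive_protocol()
  tt <- sort(unique(c(seq(0, 0.3, 2.5e-4), seq(0, 3, 2e-3),
                      2 + seq(0, 0.3, 2.5e-4))))
  tr <- integrate_complete(sc, drv, U = 0.25, t_end = 3, times = tt,
                           solver = slow_solver)
  proto <- replay_conductances(tr)
  tr2 <- integrate_simplified(sc, proto, E_p = 0, t_end = 3,
                              times = tr$time, solver = slow_solver)
  scale <- max(abs(tr$RP))
  expect_lt(max(abs(tr2$RP - tr$RP)) / scale, 1e-3)
  expect_lt(max(abs(tr2$SP - tr$SP)) / scale, 1e-3)
  expect_lt(max(abs(tr2$RP_s - tr$RP_s)) / scale, 1e-3)
})

test_that("complete-model responses have opposite-signed RP and SP", {
  sc <- std_scaling(6)
  drv <- drive_protocol()
  tr <- integrate_complete(sc, drv, U = 0.5, t_end = 4, dt_out = 0.01,
                           solver = slow_solver)
  expect_gt(max(tr$RP_s), 1)
  expect_lt(min(tr$SP), -1)
  # similar kinetics of opposite signs: strong anticorrelation
  expect_lt(cor(tr$RP_s, tr$SP), -0.98)
  # RP height declines from tip to base at the kinetic maximum
  prof <- tr$RP[which.max(tr$RP_b), ]
  expect_true(all(diff(prof) < 0))
  # intradendritic Ca2+ stays within the physiological screen
  expect_lt(max(tr$extras$Ca), 200)
})
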