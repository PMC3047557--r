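test_that("steady closed forms vanish at zero conductance", {
  d <- std_derived
  x <- seq(0, 220, by = 20)
  expect_equal(steady_rp_profile(d, 0, x), rep(0, length(x)))
  expect_equal(steady_rp_base(d, 0), 0)
  expect_equal(steady_sp(d, 0), 0)
  expect_equal(steady_rp_soma(d, 0), 0)
  expect_error(steady_rp_profile(d, 5, 300), "within")
  expect_error(steady_rp_base(d, -1), "non-negative")
})

test_that("steady RP profile is monotone, tip-high, and continuous", {
  d <- std_derived
  x <- seq(0, 220, by = 5)
  for (G_p in c(0.064, 0.5, 4)) {
    rp <- steady_rp_profile(d, G_p, x)
    expect_true(all(rp > 0))
    expect_true(all(diff(rp) < 0))
    expect_equal(rp[length(rp)], steady_rp_base(d, G_p))
  }
  # tip-to-base drop grows with conductance
  drop <- vapply(c(0.064, 0.5, 4), function(g) {
    p <- steady_rp_profile(d, g, c(0, 220))
    p[1] - p[2]
  }, numeric(1))
  expect_true(all(diff(drop) > 0))
  # RP_b increases and saturates in g
  G <- 10^seq(-2, 2, by = 0.5)
  rpb <- vapply(G, function(g) steady_rp_base(d, g), numeric(1))
  expect_true(all(diff(rpb) > 0))
  expect_true(all(diff(diff(log(rpb))) < 0))
  expect_lt(rpb[length(rpb)], -d$E_ld)
})

test_that("fine-grid compartmental solve certifies the closed forms", {
  d <- std_derived
  sc <- std_scaling(2000, channels = NULL)
  for (G_p in c(0.1, 5)) {
    st <- steady_state_simplified(sc, G_p)
    expect_lt(relative_error(attr(st, "RP_b"), steady_rp_base(d, G_p)),
              5e-4)
    expect_lt(relative_error(attr(st, "SP"), steady_sp(d, G_p)), 5e-4)
    expect_lt(relative_error(attr(st, "RP_s"), steady_rp_soma(d, G_p)),
              5e-4)
    # mid-dendrite profile value against the compartment at the same site
    j <- 1000
    x_j <- (j - 0.5) * 220 / 2000
    expect_lt(relative_error(attr(st, "RP")[j],
                             steady_rp_profile(d, G_p, x_j)), 5e-4)
  }
})

test_that("SP/RP_b ratio at E_p = 0 is battery-independent", {
  # jointly rescaling every battery leaves the ratio unchanged
  ratio <- function(base) {
    d <- derive_cable_params(base)
    steady_sp(d, 1) / steady_rp_base(d, 1)
  }
  r1 <- ratio(std_base)
  r2 <- ratio(sensillum_base_params(E_ls = -31, E_a = -17.5))
  expect_equal(r1, r2, tolerance = 1e-10)
  # and SP itself scales linearly with the batteries
  d_half <- derive_cable_params(sensillum_base_params(E_ls = -31,
                                                      E_a = -17.5))
  expect_equal(steady_sp(d_half, 1), steady_sp(std_derived, 1) / 2,
               tolerance = 1e-10)
})

test_that("results are invariant under unit-preserving rescaling", {
  # scaling every resistance by k and the stimulus conductance by 1/k
  # preserves all dimensionless groups (g, l_d, r_in, a); RP(x) in mV must
  # be unchanged
  k <- 2
  b2 <- sensillum_base_params(rho_ld = k * std_base$rho_ld,
                              rho_e = k * std_base$rho_e,
                              rho_i = k * std_base$rho_i,
                              rho_ls = k * std_base$rho_ls,
                              R_api = k * std_base$R_api,
                              R_bas = k * std_base$R_bas,
                              rho_bas = k * std_base$rho_bas)
  d2 <- derive_cable_params(b2)
  expect_equal(d2$l_d, std_derived$l_d)
  expect_equal(d2$r_in, std_derived$r_in)
  expect_equal(d2$a, std_derived$a)
  for (s in c(0, 0.5, 1)) {
    expect_equal(steady_rp_profile(d2, 5 / k, s * 220),
                 steady_rp_profile(std_derived, 5, s * 220),
                 tolerance = 1e-12)
  }
  expect_equal(steady_sp(d2, 5 / k), steady_sp(std_derived, 5),
               tolerance = 1e-12)
})

test_that("small-signal series is zero for a null step and converges", {
  d <- std_derived
  tt <- seq(0, 0.05, by = 1e-3)
  V0 <- transient_small_signal(d, 0, c(0, 110, 220), tt)
  expect_equal(max(abs(V0)), 0)
  V <- transient_small_signal(d, 0.1, c(0, 110, 220), tt)
  expect_equal(V[1, ], rep(0, 3), tolerance = 1e-9)
  expect_true(all(diff(V[, 1]) > 0))
})

test_that("series long-time limit solves the linearized steady problem", {
  # independent oracle: second-order finite differences on the sealed
  # cable, v'' - v + F 1_[0,ld] = 0, v'(0) = v'(L') = 0
  d <- std_derived
  G_p <- 0.1
  g <- 0.1 * 1e-9 / (220e-4) * d$r_ld * 1e6
  Fo <- g * (0 - d$E_ld)
  Lp <- (220 + 3 * d$lambda) / d$lambda
  n <- 4000
  h <- Lp / n
  xg <- (seq_len(n) - 0.5) * h
  main <- rep(-2 / h^2 - 1, n)
  main[1] <- -1 / h^2 - 1          # sealed ends (reflecting)
  main[n] <- -1 / h^2 - 1
  A <- diag(main)
  A[cbind(1:(n - 1), 2:n)] <- 1 / h^2
  A[cbind(2:n, 1:(n - 1))] <- 1 / h^2
  rhs <- -Fo * as.numeric(xg <= d$l_d)
  v_fd <- solve(A, rhs)
  xs <- c(5.5, 110, 220)
  v_ana <- transient_small_signal(d, G_p, xs, t_s = 10)
  v_ref <- approx(xg * d$lambda, v_fd, xout = xs)$y
  expect_equal(as.numeric(v_ana), v_ref, tolerance = 1e-4)
})

test_that("series tracks the numerical step response at small steps", {
  sc <- std_scaling(40, channels = NULL)
  times <- c(seq(0, 0.05, by = 2e-4), seq(0.06, 0.25, by = 0.01))
  p <- conductance_protocol("step", G_p = 0.05, onset = 0)
  tr <- integrate_simplified(sc, p, t_end = 0.25, times = times,
                             solver = fine_solver)
  ana <- transient_small_signal(std_derived, 0.05, c(5.5, 110, 220), times)
  for (k in 1:3) {
    num <- tr$RP[, c(1, 20, 40)[k]]
    expect_lt(max(abs(num - ana[, k])) / max(abs(num)), 0.25)
  }
})
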