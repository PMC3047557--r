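test_that("characterize recovers closed-form half-rise and half-fall", {
  # saturating exponential rise from onset, exponential decay after offset:
  # tau_rise = theta log 2, tau_fall = theta2 log 2
  theta <- 0.3
  theta2 <- 1.2
  onset <- 0.5
  offset <- 2.5
  tt <- seq(0, 10, by = 1e-3)
  A <- 7
  v <- numeric(length(tt))
  rise <- tt >= onset & tt <= offset
  v[rise] <- A * (1 - exp(-(tt[rise] - onset) / theta))
  v_off <- A * (1 - exp(-(offset - onset) / theta))
  fall <- tt > offset
  v[fall] <- v_off * exp(-(tt[fall] - offset) / theta2)
  k <- characterize(tt, v, onset, offset)
  expect_equal(k$height, v_off, tolerance = 1e-6)
  # half of height, not of the asymptote A: theta*log(A/(A - h/2))
  expect_equal(k$tau_rise, theta * log(A / (A - k$height / 2)),
               tolerance = 1e-3)
  expect_equal(k$tau_fall, theta2 * log(2), tolerance = 1e-3)

  # refining the grid leaves the interpolated crossings in place
  tt2 <- seq(0, 10, by = 1e-4)
  v2 <- numeric(length(tt2))
  r2 <- tt2 >= onset & tt2 <= offset
  v2[r2] <- A * (1 - exp(-(tt2[r2] - onset) / theta))
  f2 <- tt2 > offset
  v2[f2] <- v_off * exp(-(tt2[f2] - offset) / theta2)
  k2 <- characterize(tt2, v2, onset, offset)
  expect_equal(k2$tau_rise, k$tau_rise, tolerance = 1e-3)
  expect_equal(k2$tau_fall, k$tau_fall, tolerance = 1e-3)
})

test_that("characterize handles signed, early-declining and flat curves", {
  tt <- seq(0, 4, by = 1e-3)
  # negative-going curve (SP-like): signed height, same timing logic
  v <- -5 * pmin(tt / 0.2, 1) * exp(-pmax(tt - 0.5, 0) / 0.4)
  k <- characterize(tt, v, 0, 2)
  expect_lt(k$height, 0)
  expect_gt(k$tau_rise, 0)
  # the curve decays below half-max before offset: negative fall time
  expect_lt(k$tau_fall, 0)
  # all-zero curve: zero height, undefined times
  k0 <- characterize(tt, numeric(length(tt)), 0, 2)
  expect_equal(k0$height, 0)
  expect_true(is.na(k0$tau_rise) && is.na(k0$tau_fall))
  expect_error(characterize(tt, v, 2, 1), "onset < offset")
})

test_that("EC50 interpolates Hill curves exactly in log-dose", {
  doses <- 10^seq(-4, 2, by = 0.25)
  K <- 0.07
  resp <- doses / (K + doses)
  expect_equal(ec50(doses, resp), K, tolerance = 0.02)
  # steep curve, exact crossing between grid points
  resp2 <- doses^2 / (0.5^2 + doses^2)
  expect_equal(ec50(doses, resp2), 0.5, tolerance = 0.02)
  # an already-relative curve saturating below half-maximum: undefined
  expect_true(is.na(ec50(doses, 0.4 * resp, normalize = FALSE)))
  # sensitivity gain between two cascade stages as an EC50 ratio
  r_in <- doses / (11.75 + doses)
  r_out <- doses / (0.069 + doses)
  gain <- ec50(doses, r_in, normalize = FALSE) /
    ec50(doses, r_out, normalize = FALSE)
  expect_equal(gain, 11.75 / 0.069, tolerance = 0.02)
  expect_error(ec50(c(-1, 1), c(0, 1)), "positive")
})

test_that("relative error is a plain fraction with guarded zeros", {
  expect_equal(relative_error(5, 5), 0)
  expect_equal(relative_error(1.1, 1), 0.1, tolerance = 1e-12)
  expect_equal(relative_error(-22, -20), 0.1, tolerance = 1e-12)
  expect_warning(e <- relative_error(1, 0), "undefined")
  expect_true(is.na(e))
})

test_that("amplification ratios are 1 at the grid maximum, constant when
           linear", {
  G <- c(0.01, 0.1, 1, 10)
  # linear (unsaturated) response: f_r constant 1
  fr <- amplification_ratios(G, RP_s = 3 * G)
  expect_equal(fr$f_r, rep(1, 4))
  # saturating response: f_r > 1 at weak stimulation, declining to 1
  fr2 <- amplification_ratios(G, RP_s = 50 * G / (1 + G))
  expect_equal(fr2$f_r[4], 1)
  expect_true(all(diff(fr2$f_r) < 0))
  expect_gt(fr2$f_r[1], 1)
  expect_error(amplification_ratios(G, rep(0, 4)), "zero")
})

test_that("parameter sweeps re-derive the cable chain per value", {
  rp_metric <- function(derived, channels) {
    sigma_p <- 5e-6  # S/cm^2, fixed conductivity
    steady_rp_base(derived, sigma_p * derived$S_d * 1e-8 * 1e9)
  }
  # RP_b grows monotonically with dendrite length at fixed conductivity
  sw_L <- parameter_sweep("L_d", c(55, 110, 220, 440, 880), rp_metric)
  expect_true(all(diff(sw_L$metric) > 0))
  # and decreases monotonically with the soma/inner-dendrite area
  sw_S <- parameter_sweep("S_s", c(36, 72, 144, 288, 576), rp_metric)
  expect_true(all(diff(sw_S$metric) < 0))
  # hair-lumen diameter widens the lymph return path: RP_b grows
  sw_D <- parameter_sweep("D_e", c(1, 1.4, 1.8, 2.6), rp_metric)
  expect_true(all(diff(sw_D$metric) > 0))
  expect_error(parameter_sweep("nope", 1, rp_metric), "unknown parameter")
})

test_that("soma K+ conductance trades RP_s against SP linearly", {
  # steady-state sweep of G_MK in the full circuit: |SP| grows, RP_s
  # shrinks, and their ratio grows linearly with G_MK at fixed drive
  sc <- std_scaling(10)
  gk <- seq(0, 5, by = 1)
  out <- t(vapply(gk, function(g) {
    st <- steady_state_simplified(sc, G_p = 1, g_K = g)
    c(rp = attr(st, "RP_s"), sp = attr(st, "SP"))
  }, numeric(2)))
  expect_true(all(diff(out[, "rp"]) < 0))
  expect_true(all(diff(abs(out[, "sp"])) > 0))
  ratio <- abs(out[, "sp"]) / out[, "rp"]
  expect_true(all(diff(ratio) > 0))
  slopes <- diff(ratio)
  expect_lt(max(slopes) - min(slopes), 0.05 * mean(slopes))
})

test_that("dose-response tables cover every signal at every uptake", {
  sc <- std_scaling(3)
  tab <- dose_response(sc, drive_protocol(), doses = c(0.01, 1),
                       t_end = 2.5, dt_out = 0.02, solver = slow_solver)
  expect_equal(nrow(tab), 2 * 5)
  expect_setequal(unique(tab$signal),
                  c("RP_1", "RP_mid", "RP_b", "RP_s", "SP"))
  h <- tab[tab$signal == "RP_s", ]
  expect_true(all(diff(h$height) > 0))        # heights grow with uptake
  expect_true(all(tab$tau_rise > 0, na.rm = TRUE))
  sp <- tab[tab$signal == "SP", "height"]
  expect_true(all(sp < 0))
})
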