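# Shared fixtures: standard Antheraea parameterization at a few compartment
# counts, and a fast solver profile for second-scale kinetics.

std_base <- sensillum_base_params()
std_derived <- derive_cable_params(std_base)
std_channels <- channel_params()

std_scaling <- function(N, channels = std_channels) {
  scale_to_compartments(std_derived, channels, N)
}

fine_solver <- list(method = "lsoda", rtol = 1e-8, atol = 1e-10, hmax = 5e-4)
slow_solver <- list(method = "lsoda", rtol = 1e-6, atol = 1e-9, hmax = 0.05)

# dense sampling around the switch times of a square pulse, coarse elsewhere
pulse_times <- function(onset = 0, offset = 2, t_end = offset + 0.2,
                        fine = 2e-5, span = 0.03) {
  sort(unique(c(seq(onset, min(onset + span, t_end), by = fine),
                seq(0, t_end, by = 0.01),
                seq(offset, min(offset + span, t_end), by = fine))))
}

# Independent Kirchhoff residuals, recomputed from stored node potentials.

# axial inflows on the two wires must carry the same membrane current, so
# their per-compartment sum vanishes (tip sealed, base linked to soma/aux)
wire_sum_residual <- function(st, sc) {
  N <- sc$N
  nb_i <- if (N > 1L) c(st$V_id[-1L], st$V_is) else st$V_is
  nb_e <- if (N > 1L) c(st$V_ed[-1L], st$V_a) else st$V_a
  left_i <- if (N > 1L) c(0, sc$g_ic * (st$V_id[-N] - st$V_id[-1L])) else 0
  left_e <- if (N > 1L) c(0, sc$g_ec * (st$V_ed[-N] - st$V_ed[-1L])) else 0
  A_i <- left_i + sc$g_ic * (nb_i - st$V_id)
  A_e <- left_e + sc$g_ec * (nb_e - st$V_ed)
  max(abs(A_i + A_e))
}

# full steady-state nodal residual with all pheromone conductances zero
steady_state_numeric_residual <- function(sc, st, g_p = rep(0, sc$N)) {
  d <- sc$derived
  N <- sc$N
  I_m <- sc$g_ldc * (st$u - d$E_ld) + g_p * st$u
  nb_i <- if (N > 1L) c(st$V_id[-1L], st$V_is) else st$V_is
  nb_e <- if (N > 1L) c(st$V_ed[-1L], st$V_a) else st$V_a
  left_i <- if (N > 1L) c(0, sc$g_ic * (st$V_id[-N] - st$V_id[-1L])) else 0
  left_e <- if (N > 1L) c(0, sc$g_ec * (st$V_ed[-N] - st$V_ed[-1L])) else 0
  A_i <- left_i + sc$g_ic * (nb_i - st$V_id)
  A_e <- left_e + sc$g_ec * (nb_e - st$V_ed)
  r_id <- A_i - I_m
  r_ed <- A_e + I_m
  r_is <- sc$g_ic * (st$V_id[N] - st$V_is) - d$G_ls * (st$V_is - d$E_ls)
  r_a <- sc$g_ec * (st$V_ed[N] - st$V_a) - d$G_a * (st$V_a + d$E_a)
  max(abs(c(r_id, r_ed, r_is, r_a)))
}
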