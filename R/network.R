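## Circuit assembly and ODE integration for the multicompartment sensillum.
##
## Node layout: V_id[1..N] (intradendritic), V_ed[1..N] (sensillar lymph),
## V_is (inner dendrite/soma), V_a (lymph at hair base / auxiliary apical
## node). Hemolymph is ground (0 mV). The hair tip is sealed on both wires
## (ideal high-impedance recording electrode at V_ed[1]). Adjacent
## compartments are linked by full-segment axial conductances g_ic
## (intracellular) and g_ec (lymph); compartment N links to the soma node
## (g_ic) and to the auxiliary node (g_ec). Transmembrane currents are
## positive outward. Membrane capacitance sits across (V_id - V_ed), so the
## ODE states are the transmembrane potentials u_j = V_id_j - V_ed_j plus
## V_is and V_a; the individual wire potentials follow from an algebraic
## Kirchhoff balance (a constant tridiagonal solve).

# Constant tridiagonal operator giving V_ed from (u, V_is, V_a).
# Row j (sum of axial inflows on both wires, membrane current eliminated):
#   (g_ic+g_ec) * lap(V_ed) = -g_ic * lap(u) + boundary terms
circuit_operator <- function(scaling) {
  N <- scaling$N
  g_ic <- scaling$g_ic
  g_ec <- scaling$g_ec
  s <- g_ic + g_ec
  if (N == 1L) {
    M <- matrix(-s, 1, 1)
  } else {
    M <- matrix(0, N, N)
    for (j in seq_len(N)) {
      nb <- 0L
      if (j > 1L) { M[j, j - 1L] <- s; nb <- nb + 1L }
      if (j < N) { M[j, j + 1L] <- s; nb <- nb + 1L }
      M[j, j] <- -s * nb
    }
    M[N, N] <- M[N, N] - s  # soma + auxiliary links
  }
  list(Minv = solve(M), N = N, g_ic = g_ic, g_ec = g_ec)
}

# b vector(s) of the V_ed system; u may be a vector (length N) or an N x T
# matrix for batch evaluation.
ved_rhs <- function(op, u, V_is, V_a) {
  N <- op$N
  u <- if (is.matrix(u)) u else matrix(u, nrow = N)
  g_ic <- op$g_ic
  g_ec <- op$g_ec
  b <- -g_ic * lap_interior(u)
  b[N, ] <- b[N, ] + g_ic * u[N, , drop = TRUE] -
    g_ic * V_is - g_ec * V_a
  b
}

# graph Laplacian contribution of the dendrite-interior links applied to u,
# i.e. row j = u[j-1] - 2u[j] + u[j+1] with missing neighbours dropped
lap_interior <- function(u) {
  N <- nrow(u)
  out <- matrix(0, N, ncol(u))
  if (N == 1L) return(out)
  out[1, ] <- u[2, ] - u[1, ]
  if (N > 2L) {
    mid <- 2:(N - 1L)
    out[mid, ] <- u[mid - 1L, , drop = FALSE] - 2 * u[mid, , drop = FALSE] +
      u[mid + 1L, , drop = FALSE]
  }
  out[N, ] <- u[N - 1L, ] - u[N, ]
  out
}

solve_ved <- function(op, u, V_is, V_a) {
  op$Minv %*% ved_rhs(op, u, V_is, V_a)
}

# axial intracellular inflow into each dendritic intracellular node (pA)
axial_inflow_i <- function(op, V_id, V_is) {
  N <- op$N
  nb_right <- if (N > 1L) c(V_id[-1L], V_is) else V_is
  right <- op$g_ic * (nb_right - V_id)
  left <- if (N > 1L) c(0, op$g_ic * (V_id[-N] - V_id[-1L])) else 0
  left + right
}

#' Resting state of the sensillum circuit
#'
#' Solves the circuit with every pheromone-dependent conductance zero. When
#' the batteries are consistent (`E_ld = E_ls + E_a`) the rest state carries
#' zero current in every branch: `u_j = E_ld`, `V_is = E_ls`,
#' `V_ed_j = V_a = -E_a` (the transepithelial potential). Otherwise the
#' resting potentials are obtained by a numerical steady solve and a warning
#' is issued (currents then circulate at rest).
#'
#' @param scaling A `sensillum_scaling` object.
#' @return An object of class `sensillum_state`: list with `u` (mV, length
#'   N), `V_is`, `V_a`, `V_ed`, `V_id` (mV).
#' @export
resting_state <- function(scaling) {
  d <- scaling$derived
  if (d$G_ls <= 0 && d$G_a <= 0) {
    stop("singular circuit: no conductance ties the circuit to the hemolymph")
  }
  if (check_battery_consistency(d)) {
    N <- scaling$N
    tep <- -d$E_a
    st <- list(u = rep(d$E_ld, N), V_is = d$E_ls, V_a = tep,
               V_ed = rep(tep, N), V_id = rep(d$E_ld + tep, N))
  } else {
    warning("batteries are inconsistent (E_ld != E_ls + E_a); ",
            "resting state solved numerically, currents circulate at rest")
    st <- steady_state_numeric(scaling, g_p = rep(0, scaling$N))
  }
  structure(st, class = "sensillum_state")
}

#' Steady-state potentials of the simplified circuit by direct linear solve
#'
#' Solves the full nodal system (2N + 2 potentials) of the single-conductance
#' circuit at fixed per-compartment pheromone-dependent conductance. Used for
#' steady-state characterization and as a fine-grid (large N) oracle for the
#' closed-form cable solutions.
#'
#' @param scaling A `sensillum_scaling` object.
#' @param G_p Total pheromone-dependent conductance (nS), distributed
#'   uniformly (`g_p = G_p/N` per compartment); alternatively pass `g_p`.
#' @param g_p Per-compartment conductance vector (nS), overrides `G_p`.
#' @param E_p Reversal potential of the lumped current (mV).
#' @param g_K Soma K+ conductance (nS), 0 in the simplified model.
#' @return A `sensillum_state` (potentials at steady state), with attributes
#'   `RP` (per-compartment), `RP_b`, `RP_s`, `SP` (mV, relative to rest).
#' @export
steady_state_simplified <- function(scaling, G_p = NULL, g_p = NULL,
                                    E_p = 0, g_K = 0) {
  if (is.null(g_p)) {
    if (is.null(G_p)) stop("give G_p (total) or g_p (per compartment)")
    g_p <- rep(G_p / scaling$N, scaling$N)
  }
  if (length(g_p) != scaling$N) stop("g_p must have length N")
  if (any(g_p < 0)) stop("conductances must be non-negative")
  st <- steady_state_numeric(scaling, g_p = g_p, E_p = E_p, g_K = g_K)
  rest <- resting_state(scaling)
  st <- structure(st, class = "sensillum_state")
  attr(st, "RP") <- st$u - rest$u
  attr(st, "RP_b") <- st$u[scaling$N] - rest$u[scaling$N]
  attr(st, "RP_s") <- st$V_is - rest$V_is
  attr(st, "SP") <- st$V_ed[1] - rest$V_ed[1]
  st
}

# sparse nodal steady solve; unknowns (V_id, V_ed, V_is, V_a)
steady_state_numeric <- function(scaling, g_p, E_p = 0, g_K = 0) {
  N <- scaling$N
  d <- scaling$derived
  g_ic <- scaling$g_ic
  g_ec <- scaling$g_ec
  g_ldc <- scaling$g_ldc
  id <- seq_len(N)
  ed <- N + id
  is_ <- 2L * N + 1L
  a_ <- 2L * N + 2L
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  rhs <- numeric(2L * N + 2L)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  gm <- g_ldc + g_p                      # membrane conductance per compartment
  for (j in id) {
    # intracellular node j
    add(j, id[j], gm[j]); add(j, ed[j], -gm[j])
    rhs[j] <- rhs[j] + g_ldc * d$E_ld + g_p[j] * E_p
    # lymph node j (membrane current entering)
    add(ed[j], id[j], -gm[j]); add(ed[j], ed[j], gm[j])
    rhs[ed[j]] <- rhs[ed[j]] - g_ldc * d$E_ld - g_p[j] * E_p
    # axial links
    right_i <- if (j < N) id[j + 1L] else is_
    add(j, id[j], g_ic); add(j, right_i, -g_ic)
    add(right_i, right_i, g_ic); add(right_i, id[j], -g_ic)
    right_e <- if (j < N) ed[j + 1L] else a_
    add(ed[j], ed[j], g_ec); add(ed[j], right_e, -g_ec)
    add(right_e, right_e, g_ec); add(right_e, ed[j], -g_ec)
  }
  # soma and auxiliary membrane branches to ground
  add(is_, is_, d$G_ls + g_K)
  rhs[is_] <- rhs[is_] + d$G_ls * d$E_ls + g_K * scalar_or(scaling, "E_K", -62)
  add(a_, a_, d$G_a)
  rhs[a_] <- rhs[a_] - d$G_a * d$E_a
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(2L * N + 2L, 2L * N + 2L))
  v <- as.numeric(Matrix::solve(A, rhs))
  list(u = v[id] - v[ed], V_is = v[is_], V_a = v[a_],
       V_ed = v[ed], V_id = v[id])
}

scalar_or <- function(scaling, field, default) {
  ch <- scaling$channels
  if (!is.null(ch) && !is.null(ch$K$E)) ch$K$E else default
}

#' Conductance protocol for the simplified model
#'
#' @param kind `"step"` (conductance switched on at `onset` and held),
#'   `"square"` (on between `onset` and `offset`), or `"table"` (prescribed
#'   per-compartment conductance time series, e.g. from
#'   [replay_conductances()]).
#' @param G_p Total conductance (nS), distributed uniformly over
#'   compartments. For `"table"`, ignored.
#' @param onset,offset Switch times (s).
#' @param time,g For `"table"`: sample times (s) and a `length(time) x N`
#'   matrix of per-compartment conductances (nS), linearly interpolated.
#' @param g_K Optional soma conductance time series (same `time` grid, nS)
#'   replayed alongside (used to reproduce the complete model exactly).
#' @return An object of class `sensillum_gp`.
#' @export
conductance_protocol <- function(kind = c("step", "square", "table"),
                                 G_p = 1, onset = 0, offset = 2,
                                 time = NULL, g = NULL, g_K = NULL) {
  kind <- match.arg(kind)
  if (kind != "table") {
    if (G_p < 0) stop("G_p must be non-negative")
    if (onset < 0 || (kind == "square" && offset < onset)) {
      stop("need 0 <= onset <= offset")
    }
  } else {
    if (is.null(time) || is.null(g)) stop("table protocol needs time and g")
    g <- as.matrix(g)
    if (nrow(g) != length(time)) stop("nrow(g) must equal length(time)")
    if (any(g < 0)) stop("conductances must be non-negative")
  }
  structure(list(kind = kind, G_p = G_p, onset = onset, offset = offset,
                 time = time, g = g, g_K = g_K), class = "sensillum_gp")
}

# per-compartment conductance (vector, nS) at time t; and breakpoints
gp_eval <- function(proto, t, N) {
  switch(proto$kind,
    step = if (t >= proto$onset) rep(proto$G_p / N, N) else rep(0, N),
    square = if (t >= proto$onset && t <= proto$offset)
      rep(proto$G_p / N, N) else rep(0, N),
    table = {
      g <- vapply(seq_len(N), function(j) {
        stats::approx(proto$time, proto$g[, j], xout = t, rule = 2)$y
      }, numeric(1))
      pmax(g, 0)
    })
}

gp_breaks <- function(proto) {
  switch(proto$kind,
    step = proto$onset,
    square = c(proto$onset, proto$offset),
    table = numeric(0))
}

gk_eval <- function(proto, t) {
  if (is.null(proto$g_K)) return(0)
  max(stats::approx(proto$time, proto$g_K, xout = t, rule = 2)$y, 0)
}

default_solver <- function() {
  list(method = "lsoda", rtol = 1e-6, atol = 1e-9, hmax = 1e-3)
}

#' Integrate the simplified single-conductance sensillum model
#'
#' Same circuit as the complete model, with the four pheromone-dependent
#' branches of each compartment replaced by one branch (conductance
#' `g_p_j(t)`, battery `E_p`) and the soma K+ current removed (repolarization
#' by the leak currents alone), unless a replayed `g_K` series is attached to
#' the protocol.
#'
#' @param scaling A `sensillum_scaling` object.
#' @param g_p A `sensillum_gp` protocol from [conductance_protocol()].
#' @param E_p Reversal potential of the lumped current (mV), default 0.
#' @param t_end End of the simulation (s).
#' @param dt_out Uniform output sampling interval (s), default 1 ms.
#' @param times Optional explicit output times (s), overrides `dt_out` (use
#'   a finer grid around conductance switch times to resolve the ms-scale
#'   electrical transients).
#' @param solver List with `method`, `rtol`, `atol`, `hmax` (s); defaults
#'   `lsoda`, 1e-6, 1e-9, 1 ms.
#' @return A `sensillum_trajectory`: list with `time` (s), matrices `u`,
#'   `V_ed`, `V_id`, `RP` (T x N, mV), vectors `V_is`, `V_a`, `RP_b`, `RP_s`,
#'   `SP` (mV), `g_p` (T x N, nS), the `rest` state and `scaling`.
#' @export
integrate_simplified <- function(scaling, g_p, E_p = 0, t_end = 2.2,
                                 dt_out = 1e-3, times = NULL,
                                 solver = default_solver()) {
  stopifnot(inherits(g_p, "sensillum_gp"))
  N <- scaling$N
  d <- scaling$derived
  op <- circuit_operator(scaling)
  rest <- resting_state(scaling)
  c_dc_nF <- scaling$c_dc / 1e3
  C_s_nF <- d$C_s / 1e3
  C_a_nF <- d$C_a / 1e3
  E_K <- scalar_or(scaling, "E_K", -62)

  rhs <- function(t, y, parms) {
    u <- y[seq_len(N)]
    V_is <- y[N + 1L]
    V_a <- y[N + 2L]
    V_ed <- as.numeric(solve_ved(op, u, V_is, V_a))
    V_id <- V_ed + u
    gp <- gp_eval(g_p, t, N)
    gk <- gk_eval(g_p, t)
    I_ion <- scaling$g_ldc * (u - d$E_ld) + gp * (u - E_p)
    A_i <- axial_inflow_i(op, V_id, V_is)
    du <- (A_i - I_ion) / c_dc_nF
    dVis <- (scaling$g_ic * (V_id[N] - V_is) - d$G_ls * (V_is - d$E_ls) -
               gk * (V_is - E_K)) / C_s_nF
    dVa <- (scaling$g_ec * (V_ed[N] - V_a) - d$G_a * (V_a + d$E_a)) / C_a_nF
    list(c(du, dVis, dVa))
  }

  if (is.null(times)) times <- seq(0, t_end, by = dt_out)
  y0 <- c(rest$u, rest$V_is, rest$V_a)
  out <- integrate_segments(rhs, y0, times, gp_breaks(g_p), solver)
  traj_from_states(out, scaling, op, rest,
                   g_p_fun = function(t) gp_eval(g_p, t, N), E_p = E_p)
}

# integrate across conductance discontinuities segment by segment
integrate_segments <- function(rhs, y0, times, breaks, solver) {
  breaks <- breaks[breaks > min(times) & breaks < max(times)]
  edges <- sort(unique(c(min(times), breaks, max(times))))
  pieces <- list()
  y <- y0
  eps <- 1e-12
  for (k in seq_len(length(edges) - 1L)) {
    t0 <- edges[k]; t1 <- edges[k + 1L]
    tt <- times[times >= t0 - eps & times <= t1 + eps]
    tt <- sort(unique(c(t0, tt, t1)))
    seg <- deSolve::ode(y = y, times = tt, func = rhs, parms = NULL,
                        method = solver$method, rtol = solver$rtol,
                        atol = solver$atol, hmax = solver$hmax)
    if (any(!is.finite(seg))) {
      stop("solver produced non-finite state near t = ", t1)
    }
    y <- as.numeric(seg[nrow(seg), -1L])
    keep <- seg[, 1L] %in% times
    pieces[[k]] <- seg[keep, , drop = FALSE]
  }
  out <- do.call(rbind, pieces)
  out[!duplicated(out[, 1L]), , drop = FALSE]
}

# build a sensillum_trajectory from an ode output matrix whose first N+2
# state columns are (u, V_is, V_a); extra columns are passed through
traj_from_states <- function(out, scaling, op, rest, g_p_fun = NULL,
                             E_p = 0, extras = NULL) {
  N <- scaling$N
  dimnames(out) <- NULL
  time <- out[, 1L]
  u <- out[, 1L + seq_len(N), drop = FALSE]
  V_is <- out[, N + 2L]
  V_a <- out[, N + 3L]
  # batch Kirchhoff solve for the lymph potentials (V_is/V_a vary per row)
  b <- ved_rhs(op, t(u), 0, 0)
  b[N, ] <- b[N, ] - op$g_ic * V_is - op$g_ec * V_a
  V_ed <- t(op$Minv %*% b)
  V_id <- V_ed + u
  RP <- sweep(u, 2L, rest$u)
  g_p <- NULL
  if (!is.null(g_p_fun)) {
    g_p <- t(vapply(time, g_p_fun, numeric(N)))
  }
  structure(list(
    time = time, u = u, V_ed = V_ed, V_id = V_id,
    V_is = V_is, V_a = V_a,
    RP = RP, RP_b = RP[, N], RP_s = V_is - rest$V_is,
    SP = V_ed[, 1L] - rest$V_ed[1L],
    g_p = g_p, E_p = E_p, rest = rest, scaling = scaling,
    extras = extras
  ), class = "sensillum_trajectory")
}

#' Integrate the complete multichannel sensillum model
#'
#' Couples the circuit to the transduction machinery of every dendritic
#' compartment: prescribed IP3/DAG waveforms (see [drive_protocol()]) gate
#' the Ca2+ and cationic channels (with CaCaM feedback raising their EC50s),
#' the Ca2+ mass balance of each compartment integrates the Ca-carrying
#' currents, intradendritic Ca2+ gates the Cl- channel (PKC* feedback) and
#' the NCX current, and low-pass-filtered somatic Ca2+ gates the soma K+
#' current.
#'
#' @param scaling A `sensillum_scaling` built with a `sensillum_channels`
#'   object.
#' @param drive A `sensillum_drive` protocol.
#' @param U Pheromone uptake (uM/s).
#' @param t_end End time (s).
#' @param dt_out Output sampling (s).
#' @param times Optional explicit output times (s).
#' @param solver Solver settings, see [integrate_simplified()].
#' @param extras Record the transduction time courses (concentrations,
#'   gated conductances, channel currents) alongside the potentials. Skip
#'   for speed inside fitting loops.
#' @return A `sensillum_trajectory` whose `extras` holds per-compartment
#'   `Ca`, `CaCaM`, `PKC` (T x N, uM), `Ca_soma` (uM), the gated
#'   conductances `g_Ca`, `g_cat`, `g_Cl`, `g_x` (T x N, nS), `g_K` (nS) and
#'   the channel currents `I_Ca`, `I_cat`, `I_Cl`, `I_x` (T x N, pA).
#' @export
integrate_complete <- function(scaling, drive, U, t_end = 8,
                               dt_out = 1e-2, times = NULL,
                               solver = default_solver(), extras = TRUE) {
  ch <- scaling$channels
  if (is.null(ch)) stop("scaling must carry channel parameters")
  stopifnot(inherits(drive, "sensillum_drive"))
  N <- scaling$N
  d <- scaling$derived
  op <- circuit_operator(scaling)
  rest <- resting_state(scaling)
  c_dc_nF <- scaling$c_dc / 1e3
  C_s_nF <- d$C_s / 1e3
  C_a_nF <- d$C_a / 1e3
  g_M <- scaling$g_M
  iu <- seq_len(N)

  rhs <- function(t, y, parms) {
    u <- y[iu]
    V_is <- y[N + 1L]
    V_a <- y[N + 2L]
    Ca <- pmax(y[N + 2L + iu], 0)
    CaCaM <- pmax(y[2L * N + 2L + iu], 0)
    PKC <- pmax(y[3L * N + 2L + iu], 0)
    Ca_s <- max(y[4L * N + 3L], 0)

    m <- synthetic_modulators(drive, t, U)
    g <- complete_conductances(ch, g_M, m$IP3, m$DAG, Ca, CaCaM, PKC)
    V_ed <- as.numeric(solve_ved(op, u, V_is, V_a))
    V_id <- V_ed + u
    I_Ca <- g$Ca * (u - ch$Ca$E)
    I_cat <- g$cat * (u - ch$cat$E)
    I_Cl <- g$Cl * (u - ch$Cl$E)
    I_x <- g$x * (u - ch$x$E)
    I_ion <- scaling$g_ldc * (u - d$E_ld) + I_Ca + I_cat + I_Cl + I_x
    A_i <- axial_inflow_i(op, V_id, V_is)
    du <- (A_i - I_ion) / c_dc_nF
    g_K <- k_conductance(Ca_s, V_is, ch)
    dVis <- (scaling$g_ic * (V_id[N] - V_is) - d$G_ls * (V_is - d$E_ls) -
               g_K * (V_is - ch$K$E)) / C_s_nF
    dVa <- (scaling$g_ec * (V_ed[N] - V_a) - d$G_a * (V_a + d$E_a)) / C_a_nF
    dCa <- calcium_balance(y[N + 2L + iu], I_Ca, I_cat, I_x, ch, N)
    dCaCaM <- (drive$cacam_gain * Ca - CaCaM) / drive$cacam_tau
    dPKC <- (drive$pkc_gain * Ca - PKC) / drive$pkc_tau
    dCa_s <- (drive$casoma_gain * Ca[N] - Ca_s) / drive$casoma_tau
    list(c(du, dVis, dVa, dCa, dCaCaM, dPKC, dCa_s))
  }

  if (is.null(times)) times <- seq(0, t_end, by = dt_out)
  y0 <- c(rest$u, rest$V_is, rest$V_a, rep(0, 3L * N), 0)
  out <- integrate_segments(rhs, y0, times,
                            c(drive$onset, drive$offset), solver)
  traj <- traj_from_states(out[, 1:(N + 3L), drop = FALSE], scaling, op, rest,
                           E_p = 0)
  if (extras) traj$extras <- complete_extras(out, traj, scaling, drive, U)
  traj
}

# gated conductances of the four pheromone-dependent channels (vectors N)
complete_conductances <- function(ch, g_M, IP3, DAG, Ca, CaCaM, PKC) {
  K_Ca <- inhibited_ec50(ch$Ca$K_m, CaCaM, ch$Ca$K_i, ch$Ca$n_i, ch$Ca$i_M)
  K_cat <- inhibited_ec50(ch$cat$K_m, CaCaM, ch$cat$K_i, ch$cat$n_i,
                          ch$cat$i_M)
  K_Cl <- inhibited_ec50(ch$Cl$K_m, PKC, ch$Cl$K_i, ch$Cl$n_i, ch$Cl$i_M)
  list(
    Ca = hill_vec(g_M[["Ca"]], IP3, K_Ca, ch$Ca$n),
    cat = hill_vec(g_M[["cat"]], DAG, K_cat, ch$cat$n),
    Cl = hill_vec(g_M[["Cl"]], Ca, K_Cl, ch$Cl$n),
    x = hill_vec(g_M[["x"]], Ca, ch$x$K_m, ch$x$n)
  )
}

# Hill form without input validation, safe at Y = 0 (hot path)
hill_vec <- function(g_max, Y, K, n) {
  Yn <- pmax(Y, 0)^n
  g_max * Yn / (K^n + Yn)
}

complete_extras <- function(out, traj, scaling, drive, U) {
  N <- scaling$N
  ch <- scaling$channels
  iu <- seq_len(N)
  time <- out[, 1L]
  Ca <- pmax(out[, 1L + N + 2L + iu, drop = FALSE], 0)
  CaCaM <- pmax(out[, 1L + 2L * N + 2L + iu, drop = FALSE], 0)
  PKC <- pmax(out[, 1L + 3L * N + 2L + iu, drop = FALSE], 0)
  Ca_soma <- pmax(out[, 1L + 4L * N + 3L], 0)
  g_Ca <- g_cat <- g_Cl <- g_x <- matrix(0, length(time), N)
  for (k in seq_along(time)) {
    m <- synthetic_modulators(drive, time[k], U)
    g <- complete_conductances(ch, scaling$g_M, m$IP3, m$DAG,
                               Ca[k, ], CaCaM[k, ], PKC[k, ])
    g_Ca[k, ] <- g$Ca; g_cat[k, ] <- g$cat
    g_Cl[k, ] <- g$Cl; g_x[k, ] <- g$x
  }
  u <- traj$u
  list(
    Ca = Ca, CaCaM = CaCaM, PKC = PKC, Ca_soma = Ca_soma,
    g_Ca = g_Ca, g_cat = g_cat, g_Cl = g_Cl, g_x = g_x,
    g_K = k_conductance(Ca_soma, traj$V_is, ch),
    I_Ca = g_Ca * (u - ch$Ca$E), I_cat = g_cat * (u - ch$cat$E),
    I_Cl = g_Cl * (u - ch$Cl$E), I_x = g_x * (u - ch$x$E),
    U = U
  )
}

#' Receptor and sensillar potentials of a trajectory
#'
#' Potentials referenced to the resting state: `RP_j(t)` is the change of the
#' transmembrane potential of compartment `j`, `RP_b` its value at the
#' dendrite base (compartment N), `RP_s` the change of the soma potential,
#' and `SP` the change of the lymph potential at the sealed hair tip (the
#' tip-recorded sensillar potential). All are 0 at t = 0 by construction.
#'
#' @param traj A `sensillum_trajectory` starting at rest.
#' @return A data.frame with columns `time`, `RP_b`, `RP_s`, `SP` and one
#'   `RP_<j>` column per compartment.
#' @export
extract_potentials <- function(traj) {
  dev0 <- max(abs(traj$u[1L, ] - traj$rest$u),
              abs(traj$V_is[1L] - traj$rest$V_is),
              abs(traj$V_a[1L] - traj$rest$V_a))
  if (dev0 > 1e-6) {
    stop("trajectory does not start at the resting state ",
         "(max deviation ", format(dev0), " mV); RP/SP reference undefined")
  }
  rp <- as.data.frame(traj$RP)
  names(rp) <- paste0("RP_", seq_len(ncol(rp)))
  cbind(data.frame(time = traj$time, RP_b = traj$RP_b,
                   RP_s = traj$RP_s, SP = traj$SP), rp)
}

#' Leak, channel and axial currents at one instant
#'
#' Evaluates every branch current of the circuit at a given state, under the
#' outward-positive convention: per-compartment leak `I_ld`, lumped or
#' channel currents, axial intracellular and lymph currents (positive from
#' tip toward base), soma leak `I_ls` and K+ current `I_K`, and the
#' auxiliary-cell current `I_a`. At a battery-consistent rest every entry
#' is zero.
#'
#' @param state A `sensillum_state`.
#' @param scaling A `sensillum_scaling`.
#' @param g_p Per-compartment pheromone-dependent conductance (nS), default
#'   all zero.
#' @param E_p Lumped battery (mV).
#' @param g_K Soma K+ conductance (nS).
#' @return List with `I_ld`, `I_p` (length N), `I_i`, `I_e` (length N, the
#'   axial currents leaving compartment j toward the base; entry N couples
#'   to soma/auxiliary), `I_ls`, `I_K`, `I_a` (pA).
#' @export
circuit_currents <- function(state, scaling, g_p = rep(0, scaling$N),
                             E_p = 0, g_K = 0) {
  N <- scaling$N
  if (length(state$u) != N || length(g_p) != N) {
    stop("state/conductance dimensions do not match N = ", N)
  }
  d <- scaling$derived
  I_ld <- scaling$g_ldc * (state$u - d$E_ld)
  I_p <- g_p * (state$u - E_p)
  nb_i <- if (N > 1L) c(state$V_id[-1L], state$V_is) else state$V_is
  I_i <- scaling$g_ic * (state$V_id - nb_i)
  nb_e <- if (N > 1L) c(state$V_ed[-1L], state$V_a) else state$V_a
  I_e <- scaling$g_ec * (state$V_ed - nb_e)
  E_K <- scalar_or(scaling, "E_K", -62)
  list(I_ld = I_ld, I_p = I_p, I_i = I_i, I_e = I_e,
       I_ls = d$G_ls * (state$V_is - d$E_ls),
       I_K = g_K * (state$V_is - E_K),
       I_a = d$G_a * (state$V_a + d$E_a))
}

#' Lumped-conductance replay of a complete-model trajectory
#'
#' Computes, at every stored sample and compartment, the single equivalent
#' conductance `g_p_j(t)` that carries the summed pheromone-dependent current
#' (see [lumped_conductance()]), plus the soma K+ conductance series, packed
#' as a `"table"` [conductance_protocol()]. Feeding it back to
#' [integrate_simplified()] reproduces the complete model's potentials.
#'
#' @param traj A `sensillum_trajectory` from [integrate_complete()].
#' @param E_p Lumped battery (mV), default 0.
#' @param floor Driving-force floor (mV); flagged samples are interpolated
#'   from their temporal neighbours.
#' @return A `sensillum_gp` protocol of kind `"table"`.
#' @export
replay_conductances <- function(traj, E_p = 0, floor = 1e-6) {
  ex <- traj$extras
  if (is.null(ex)) stop("trajectory has no channel currents to lump")
  N <- ncol(traj$u)
  g <- matrix(NA_real_, length(traj$time), N)
  for (j in seq_len(N)) {
    gj <- lumped_conductance(ex$I_Ca[, j], ex$I_cat[, j], ex$I_Cl[, j],
                             ex$I_x[, j], traj$u[, j], E_p, floor)
    if (anyNA(gj)) {
      ok <- !is.na(gj)
      gj <- stats::approx(traj$time[ok], gj[ok], xout = traj$time,
                          rule = 2)$y
    }
    g[, j] <- pmax(gj, 0)
  }
  conductance_protocol(kind = "table", time = traj$time, g = g,
                       g_K = ex$g_K)
}
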