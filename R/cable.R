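## Closed-form steady-state solutions of the two-wire (lymph/intracellular)
## cable with uniform pheromone-dependent conductance, sealed tip and a
## lumped soma + auxiliary load at the base, and the small-signal
## eigenfunction transient for a step of uniform conductance.
##
## Derivation sketch (steady state). Let W(x) = V_i - V_e be the
## transmembrane potential at electrotonic distance x from the tip, g the
## pheromone-dependent conductance in units of the resting membrane
## conductance (g = r_ld g_p per unit length), q = sqrt(1 + g). Since both
## wires are sealed at the tip the total longitudinal current vanishes
## everywhere, which gives a single second-order equation
##   W'' = (1 + g) W - (E_ld + g E_p),
## so W(x) = W_inf + A cosh(qx), W_inf = (E_ld + g E_p)/(1 + g). The sealed
## tip kills the sinh term; the base load (axial current through R_ls + E_ls
## intracellularly and R_a + E_a extracellularly, equal and opposite) yields
##   A = (E_ls + E_a - W_inf) / (cosh(q l_d) + r_in q sinh(q l_d)).
## The axial current at the base is I = -A q sinh(q l_d)/(lambda (r_e+r_i)),
## and the lymph potential follows from dV_e/dx = -(r_e/(r_e+r_i)) W'(x).
## Correctness is certified against a fine-grid compartmental solve, not
## against transcription.

# dimensionless cable solution pieces for one uniform conductance
cable_solution <- function(derived, g, E_p = 0) {
  d <- derived
  q <- sqrt(1 + g)
  W_inf <- (d$E_ld + g * E_p) / (1 + g)
  E_b <- d$E_ls + d$E_a
  D <- cosh(q * d$l_d) + d$r_in * q * sinh(q * d$l_d)
  A <- (E_b - W_inf) / D
  R_char <- d$lambda * 1e-4 * (d$r_e + d$r_i) * 1e9 / 1e6  # MOhm
  I_base <- -A * q * sinh(q * d$l_d) / R_char              # nA (mV/MOhm)
  list(q = q, W_inf = W_inf, A = A, I_base = I_base, R_char = R_char)
}

#' Convert a total conductance to the dimensionless cable conductance
#'
#' `g = r_ld g_p` with `g_p = G_p / L_d` the conductance per unit length;
#' equivalently `g = rho_ld sigma_p` for a conductivity `sigma_p` (S/cm^2).
#'
#' @param derived A `sensillum_derived` object.
#' @param G_p Total pheromone-dependent conductance of the dendrite (nS).
#' @return Dimensionless conductance (units of resting membrane
#'   conductance).
#' @export
dimensionless_conductance <- function(derived, G_p) {
  r_ld_ohmcm <- derived$r_ld * 1e6
  gp_S_per_cm <- G_p * 1e-9 / (derived$base$L_d * 1e-4)
  r_ld_ohmcm * gp_S_per_cm
}

#' Steady-state receptor potential along the outer dendrite (closed form)
#'
#' RP at distance `x_um` from the sealed tip under a maintained uniform
#' total conductance `G_p`, relative to the `g = 0` rest solution. The
#' profile is a hyperbolic cosine, maximal at the tip and decreasing toward
#' the loaded base.
#'
#' @param derived A `sensillum_derived` object.
#' @param G_p Total pheromone-dependent conductance (nS), >= 0.
#' @param x_um Position(s) along the dendrite (um), in `[0, L_d]`.
#' @param E_p Reversal potential of the pheromone-dependent current (mV).
#' @return RP in mV (vector over `x_um`).
#' @export
steady_rp_profile <- function(derived, G_p, x_um, E_p = 0) {
  if (G_p < 0) stop("G_p must be non-negative")
  if (any(x_um < 0 | x_um > derived$base$L_d + 1e-9)) {
    stop("x_um must lie within [0, L_d]")
  }
  x <- x_um / derived$lambda
  s <- cable_solution(derived, dimensionless_conductance(derived, G_p), E_p)
  s0 <- cable_solution(derived, 0, E_p)
  (s$W_inf + s$A * cosh(s$q * x)) - (s0$W_inf + s0$A * cosh(x))
}

#' Steady-state receptor potential at the dendrite base (closed form)
#'
#' @inheritParams steady_rp_profile
#' @return RP_b in mV.
#' @export
steady_rp_base <- function(derived, G_p, E_p = 0) {
  steady_rp_profile(derived, G_p, derived$base$L_d, E_p)
}

#' Steady-state receptor potential at the soma (closed form)
#'
#' The soma potential is `E_ls + R_ls I_base` with `I_base` the axial
#' intracellular current entering the base load; RP_s is its change from
#' rest.
#'
#' @inheritParams steady_rp_profile
#' @return RP_s in mV.
#' @export
steady_rp_soma <- function(derived, G_p, E_p = 0) {
  s <- cable_solution(derived, dimensionless_conductance(derived, G_p), E_p)
  s0 <- cable_solution(derived, 0, E_p)
  derived$R_ls * (s$I_base - s0$I_base)  # MOhm * nA = mV
}

#' Steady-state tip-recorded sensillar potential (closed form)
#'
#' Change of the lymph potential at the sealed tip. With `E_p = 0` the ratio
#' `SP/RP_b` is independent of the battery values and depends only on
#' `r_e/(r_e + r_i)`, the auxiliary load fraction `a`, and `l_d`.
#'
#' @inheritParams steady_rp_profile
#' @return SP in mV (negative-going for a depolarizing stimulus).
#' @export
steady_sp <- function(derived, G_p, E_p = 0) {
  if (G_p < 0) stop("G_p must be non-negative")
  d <- derived
  beta <- d$r_e / (d$r_e + d$r_i)
  ve_tip <- function(s) {
    W_base <- s$W_inf + s$A * cosh(s$q * d$l_d)
    W_tip <- s$W_inf + s$A
    -d$E_a - d$R_a * s$I_base + beta * (W_base - W_tip)
  }
  s <- cable_solution(d, dimensionless_conductance(d, G_p), E_p)
  s0 <- cable_solution(d, 0, E_p)
  ve_tip(s) - ve_tip(s0)
}

#' Small-signal transient response to a conductance step (cosine series)
#'
#' Linearized depolarization `V(x, t)` of a sealed-sealed cable of total
#' electrotonic length `L'` whose sensory span `[0, l_d]` receives a uniform
#' conductance step `g` at t = 0, valid for depolarizations much smaller
#' than the driving potential (total conductance up to about 0.2 nS):
#' `V(x,t') = sum_n F_n/mu_n (1 - exp(-mu_n t')) cos(n pi x/L')` with
#' `mu_n = 1 + (n pi/L')^2` and `F_n` the cosine coefficients of the uniform
#' forcing `g (E_p - E_ld)` over `[0, l_d]`. The passive cable portion
#' beyond the dendrite stands in for the non-sensory part of the neuron and
#' its load (see `L_extra_um`).
#'
#' @param derived A `sensillum_derived` object.
#' @param G_p Total conductance step (nS).
#' @param x_um Position(s) (um) within `[0, L_d]`.
#' @param t_s Time(s) after the step (s).
#' @param E_p Reversal potential (mV), default 0.
#' @param L_extra_um Length of the sealed non-sensory extension (um).
#'   Default: three space constants. The extension stands in for the soma
#'   and auxiliary-cell load; since that load is close to the cable's
#'   characteristic (matched) resistance (1/r_in ~ 1.08), a long extension,
#'   whose input conductance approaches the characteristic value, emulates
#'   it far better than a short stub, which is nearly an open circuit.
#' @param tol Series truncation: stop when the added term's amplitude is
#'   below `tol` mV.
#' @param max_terms Hard cap on the number of series terms.
#' @return A `length(t_s) x length(x_um)` matrix of depolarizations (mV).
#' @export
transient_small_signal <- function(derived, G_p, x_um, t_s, E_p = 0,
                                   L_extra_um = NULL, tol = 1e-10,
                                   max_terms = 10000) {
  d <- derived
  if (is.null(L_extra_um)) L_extra_um <- 3 * d$lambda
  g <- dimensionless_conductance(d, G_p)
  if (g < 0) stop("G_p must be non-negative")
  l_d <- d$l_d
  Lp <- (d$base$L_d + L_extra_um) / d$lambda
  x <- x_um / d$lambda
  tp <- t_s * 1e3 / d$tau                       # time in membrane tau
  Fo <- g * (E_p - d$E_ld)                      # forcing, mV
  V <- matrix(0, length(tp), length(x))
  if (g == 0) return(V)
  n <- 0
  repeat {
    if (n == 0) {
      Fn <- Fo * l_d / Lp
      mu <- 1
      cosx <- rep(1, length(x))
    } else {
      Fn <- 2 * Fo * sin(n * pi * l_d / Lp) / (n * pi)
      mu <- 1 + (n * pi / Lp)^2
      cosx <- cos(n * pi * x / Lp)
    }
    amp <- abs(Fn) / mu
    V <- V + (Fn / mu) * outer(1 - exp(-mu * tp), cosx)
    n <- n + 1
    if ((n > 1 && amp < tol) || n >= max_terms) break
  }
  if (n >= max_terms) {
    warning("cosine series truncated at ", max_terms,
            " terms before reaching tol = ", tol)
  }
  V
}
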