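#' Hill-gated conductance
#'
#' Ensemble-mean conductance of a ligand-gated channel population,
#' `g = g_max * Y^n / (K^n + Y^n)`. At the EC50 (`Y = K_y`) the conductance
#' is half-maximal; it is zero at zero agonist and saturates below `g_max`.
#'
#' @param g_max Maximal conductance (nS), > 0.
#' @param Y Agonist concentration (uM), >= 0. Vectorized.
#' @param K_y Effective EC50 (uM), > 0.
#' @param n_y Hill coefficient, > 0.
#' @return Conductance in nS, same length as `Y`.
#' @export
hill_conductance <- function(g_max, Y, K_y, n_y) {
  if (any(g_max <= 0) || any(K_y <= 0)) stop("g_max and K_y must be positive")
  if (any(Y < 0)) stop("agonist concentration Y must be non-negative")
  Yn <- Y^n_y
  g_max * Yn / (K_y^n_y + Yn)
}

#' Antagonist-shifted effective EC50
#'
#' Feedback inhibition by an antagonist Z (CaCaM or PKC*) raises a channel's
#' effective agonist EC50 from its uninhibited value `K_my` (at Z = 0) toward
#' the fully inhibited value `K_my * i_My` (Z -> Inf), following a Hill
#' interpolation with the antagonist IC50 `K_iy`:
#' `K_y = K_my * (1 + (i_My - 1) * Z^n_iy / (K_iy^n_iy + Z^n_iy))`.
#'
#' @param K_my Uninhibited EC50 (uM), > 0.
#' @param Z Antagonist concentration (uM), >= 0. Vectorized.
#' @param K_iy Antagonist IC50 (uM), > 0.
#' @param n_iy Antagonist Hill coefficient.
#' @param i_My Maximal inhibition (dimensionless, >= 1).
#' @return Effective EC50 (uM), bounded in `[K_my, K_my * i_My]`.
#' @export
inhibited_ec50 <- function(K_my, Z, K_iy, n_iy, i_My) {
  if (any(K_my <= 0) || any(K_iy <= 0)) stop("K_my and K_iy must be positive")
  if (any(i_My < 1)) stop("maximal inhibition i_My must be >= 1")
  if (any(Z < 0)) stop("antagonist concentration Z must be non-negative")
  Zn <- Z^n_iy
  K_my * (1 + (i_My - 1) * Zn / (K_iy^n_iy + Zn))
}

#' Ohmic channel current
#'
#' Transmembrane current through a branch with conductance `g` and battery
#' `E_y`, positive outward (intracellular to extracellular):
#' `I = g * ((V_in - V_out) - E_y)` so that nS * mV = pA. Depolarizing
#' pheromone-gated currents are negative under this convention.
#'
#' @param g Conductance (nS), >= 0.
#' @param V_in Intracellular potential (mV).
#' @param V_out Extracellular potential (mV).
#' @param E_y Reversal potential (mV).
#' @return Current in pA.
#' @export
channel_current <- function(g, V_in, V_out, E_y) {
  if (any(g < 0)) stop("conductance must be non-negative")
  g * ((V_in - V_out) - E_y)
}

#' Ca2+- and voltage-gated K+ conductance
#'
#' Soma/inner-dendrite K+ conductance gated multiplicatively by intracellular
#' Ca2+ (Hill factor with EC50 `K_m`, coefficient 1) and by membrane voltage
#' (logistic factor with slope parameter `A_K` and half-activation `V_h`):
#' `G_K = G_MK * Ca/(K_m + Ca) * 1/(1 + exp(-(V - V_h)/A_K))`.
#'
#' @param Ca_soma Intracellular Ca2+ at the soma (uM), >= 0.
#' @param V Soma membrane potential (mV).
#' @param channels A `sensillum_channels` object (record `K` is used).
#' @return Conductance in nS, in `[0, G_MK)`.
#' @export
k_conductance <- function(Ca_soma, V, channels) {
  if (any(Ca_soma < 0)) stop("Ca_soma must be non-negative")
  K <- channels$K
  K$G_M * (Ca_soma / (K$K_m + Ca_soma)) / (1 + exp(-(V - K$V_h) / K$A_K))
}

#' Lumped equivalent pheromone-dependent conductance
#'
#' The four pheromone-dependent currents of a compartment can be replaced by
#' a single branch with battery `E_p` and conductance
#' `g_p = (I_Ca + I_cat + I_Cl + I_x) / (V_m - E_p)`, which reproduces the
#' summed current exactly when reinserted. Samples whose driving force
#' `|V_m - E_p|` falls below `floor` cannot be divided reliably; they are
#' returned as `NA` and flagged, to be interpolated from neighbours by the
#' caller (see [replay_conductances()]).
#'
#' @param I_Ca,I_cat,I_Cl,I_x Currents (pA), outward positive. Vectorized.
#' @param V_m Transmembrane potential `V_id - V_ed` (mV).
#' @param E_p Lumped battery (mV), default 0.
#' @param floor Minimal driving force (mV) below which the sample is flagged.
#' @return Conductance in nS; `NA` where the driving force is below `floor`,
#'   with attribute `flagged` giving the indices.
#' @export
lumped_conductance <- function(I_Ca, I_cat, I_Cl, I_x, V_m, E_p = 0,
                               floor = 1e-6) {
  drive <- V_m - E_p
  bad <- abs(drive) < floor
  g <- (I_Ca + I_cat + I_Cl + I_x) / drive
  g[bad] <- NA_real_
  if (any(bad)) attr(g, "flagged") <- which(bad)
  g
}

#' Export gating curves over an agonist grid
#'
#' Tabulates [hill_conductance()] for one channel record over a grid of
#' agonist concentrations at a fixed antagonist level.
#'
#' @param channels A `sensillum_channels` object.
#' @param which One of `"Ca"`, `"cat"`, `"Cl"`, `"x"`.
#' @param agonist Agonist grid (uM).
#' @param Z Antagonist concentration (uM), default 0.
#' @param N Number of compartments the maximal conductance is divided by.
#' @return A data.frame with columns `agonist` and `conductance` (nS).
#' @export
gating_curve <- function(channels, which = c("Ca", "cat", "Cl", "x"),
                         agonist, Z = 0, N = 1) {
  which <- match.arg(which)
  rec <- channels[[which]]
  K_y <- if (!is.null(rec$i_M)) {
    inhibited_ec50(rec$K_m, Z, rec$K_i, rec$n_i, rec$i_M)
  } else {
    rec$K_m
  }
  data.frame(agonist = agonist,
             conductance = hill_conductance(rec$G_M / N, agonist, K_y, rec$n))
}
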