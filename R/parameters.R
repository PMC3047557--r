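#' Load the basic morphological and electrical sensillum parameters
#'
#' Reads the base parameter set (outer-dendrite geometry, membrane and medium
#' resistivities, soma and auxiliary-cell passive properties) from a YAML file
#' keyed by the standard symbols. The bundled default describes the
#' *Antheraea polyphemus* pheromone-sensitive sensillum in tip-recording
#' conditions.
#'
#' @param file Path to a YAML parameter file. Default: the bundled
#'   `antheraea_base.yaml`.
#' @param ... Named overrides applied after loading (e.g. `L_d = 300`).
#' @return An object of class `sensillum_base`: a named list with fields
#'   `L_d`, `D_i` (um), `rho_ld` (Ohm cm^2), `D_e` (um), `rho_e`, `rho_i`
#'   (Ohm cm), `S_s` (um^2), `rho_ls` (Ohm cm^2), `E_ls` (mV), `C_api` (pF),
#'   `R_api` (MOhm), `rho_bas` (Ohm cm^2), `R_bas` (MOhm), `E_a` (mV),
#'   `c` (uF/cm^2).
#' @seealso [derive_cable_params()], [channel_params()]
#' @export
sensillum_base_params <- function(file = NULL, ...) {
  if (is.null(file)) {
    file <- system.file("extdata", "antheraea_base.yaml", package = "sensillum")
  }
  vals <- yaml::read_yaml(file)
  known <- c("L_d", "D_i", "rho_ld", "D_e", "rho_e", "rho_i", "S_s", "rho_ls",
             "E_ls", "C_api", "R_api", "rho_bas", "R_bas", "E_a", "c")
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("unknown parameter key(s) in ", file, ": ",
         paste(unknown, collapse = ", "))
  }
  missing <- setdiff(known, names(vals))
  if (length(missing) > 0L) {
    stop("missing parameter key(s) in ", file, ": ",
         paste(missing, collapse = ", "))
  }
  over <- list(...)
  bad <- setdiff(names(over), known)
  if (length(bad) > 0L) {
    stop("unknown parameter override(s): ", paste(bad, collapse = ", "))
  }
  vals[names(over)] <- over
  base <- structure(lapply(vals, as.numeric), class = "sensillum_base")
  validate_base_params(base)
  base
}

validate_base_params <- function(base) {
  positive <- c("L_d", "D_i", "rho_ld", "D_e", "rho_e", "rho_i", "S_s",
                "rho_ls", "C_api", "R_api", "rho_bas", "R_bas", "c")
  for (f in positive) {
    v <- base[[f]]
    if (!is.finite(v) || v <= 0) {
      stop("base parameter '", f, "' must be strictly positive, got ", v)
    }
  }
  for (f in c("E_ls", "E_a")) {
    if (!is.finite(base[[f]])) stop("base parameter '", f, "' must be finite")
  }
  if (base$D_e <= base$D_i) {
    stop("D_e (", base$D_e, " um) must exceed D_i (", base$D_i,
         " um): the sensillar-lymph annulus around the dendrite must exist")
  }
  invisible(base)
}

#' Derive the cable and circuit parameters from the base set
#'
#' Computes the whole derived chain: dendrite membrane area, leak battery,
#' capacitance and resistance per unit length and in total, the passive space
#' constant `lambda`, time constant `tau` and electrotonic length `l_d`, the
#' sensillar-lymph and intracellular axial resistances, the soma membrane
#' values, the dimensionless load ratios `r_in` and `a`, and the lumped
#' auxiliary-cell membrane values (apical and basolateral membranes in
#' series).
#'
#' @param base A `sensillum_base` object from [sensillum_base_params()].
#' @return An object of class `sensillum_derived`, a named list holding
#'   `base` plus: `S_d` (um^2), `V_d` (um^3), `E_ld` (mV), `c_d` (F/cm),
#'   `C_d` (pF), `r_ld` (MOhm cm), `R_ld` (GOhm), `G_ld` (nS), `lambda` (um),
#'   `tau` (ms), `l_d` (-), `r_e`, `r_i` (GOhm/cm), `g_e`, `g_i` (nS cm),
#'   `R_e`, `R_i` (MOhm), `G_e`, `G_i` (nS), `R_ls` (MOhm), `G_ls` (nS),
#'   `C_s` (pF), `r_in`, `a` (-), `S_api`, `S_bas` (um^2), `rho_api`
#'   (Ohm cm^2), `C_bas`, `C_a` (pF), `R_a` (MOhm), `G_a` (nS).
#' @examples
#' d <- derive_cable_params(sensillum_base_params())
#' c(lambda = d$lambda, tau = d$tau, l_d = d$l_d, E_ld = d$E_ld)
#' @export
derive_cable_params <- function(base) {
  if (!inherits(base, "sensillum_base")) {
    base <- structure(as.list(base), class = "sensillum_base")
  }
  validate_base_params(base)
  um2cm <- 1e-4

  S_d <- pi * base$L_d * base$D_i                 # um^2
  V_d <- pi * base$L_d * base$D_i^2 / 4           # um^3
  E_ld <- base$E_ls + base$E_a                    # mV

  D_i_cm <- base$D_i * um2cm
  D_e_cm <- base$D_e * um2cm
  L_d_cm <- base$L_d * um2cm
  S_d_cm2 <- S_d * 1e-8
  S_s_cm2 <- base$S_s * 1e-8

  c_d <- base$c * 1e-6 * pi * D_i_cm              # F/cm
  C_d <- base$c * S_d * 1e-2                      # pF (uF/cm^2 * um^2)
  r_ld_ohmcm <- base$rho_ld / (pi * D_i_cm)       # Ohm cm
  R_ld <- base$rho_ld / S_d_cm2 / 1e9             # GOhm
  G_ld <- 1 / R_ld                                # nS

  r_e_ohm <- 4 * base$rho_e / (pi * (D_e_cm^2 - D_i_cm^2))  # Ohm/cm
  r_i_ohm <- 4 * base$rho_i / (pi * D_i_cm^2)               # Ohm/cm
  lambda_cm <- sqrt(r_ld_ohmcm / (r_e_ohm + r_i_ohm))
  lambda <- lambda_cm / um2cm                     # um
  tau <- r_ld_ohmcm * c_d * 1e3                   # ms
  l_d <- base$L_d / lambda

  R_e <- r_e_ohm * L_d_cm / 1e6                   # MOhm
  R_i <- r_i_ohm * L_d_cm / 1e6
  G_e <- 1e3 / R_e                                # nS
  G_i <- 1e3 / R_i

  R_ls <- base$rho_ls / S_s_cm2 / 1e6             # MOhm
  G_ls <- 1e3 / R_ls
  C_s <- base$c * base$S_s * 1e-2                 # pF

  S_api <- base$C_api / base$c * 1e2              # um^2 (pF / uF.cm^-2)
  rho_api <- S_api * 1e-8 * base$R_api * 1e6      # Ohm cm^2
  S_bas <- base$rho_bas / (base$R_bas * 1e6) * 1e8  # um^2
  C_bas <- base$c * S_bas * 1e-2                  # pF
  R_a <- base$R_api + base$R_bas                  # MOhm (apical+basolateral in series)
  G_a <- 1e3 / R_a
  C_a <- base$C_api * C_bas / (base$C_api + C_bas)  # pF (series combination)

  r_in <- (R_ls + R_a) * 1e6 / (lambda_cm * (r_e_ohm + r_i_ohm))
  a <- R_a / (R_ls + R_a)

  structure(list(
    base = base,
    S_d = S_d, V_d = V_d, E_ld = E_ld,
    c_d = c_d, C_d = C_d,
    r_ld = r_ld_ohmcm / 1e6, R_ld = R_ld, G_ld = G_ld,
    lambda = lambda, tau = tau, l_d = l_d,
    r_e = r_e_ohm / 1e9, g_e = 1e9 / r_e_ohm,
    r_i = r_i_ohm / 1e9, g_i = 1e9 / r_i_ohm,
    R_e = R_e, G_e = G_e, R_i = R_i, G_i = G_i,
    R_ls = R_ls, G_ls = G_ls, C_s = C_s,
    r_in = r_in, a = a,
    S_api = S_api, rho_api = rho_api, S_bas = S_bas,
    C_bas = C_bas, R_a = R_a, G_a = G_a, C_a = C_a,
    E_ls = base$E_ls, E_a = base$E_a
  ), class = "sensillum_derived")
}

#' Check resting-battery consistency
#'
#' The circuit has a zero-circulating-current resting state exactly when the
#' dendritic leak battery equals the sum of the soma leak battery and the
#' auxiliary battery, `E_ld = E_ls + E_a`. With the bundled parameters this
#' holds by construction (-97 = -62 + -35 mV).
#'
#' @param derived A `sensillum_derived` object.
#' @param tol Absolute tolerance in mV.
#' @return `TRUE` iff `E_ld = E_ls + E_a` within `tol`.
#' @export
check_battery_consistency <- function(derived, tol = 1e-9) {
  abs(derived$E_ld - (derived$E_ls + derived$E_a)) <= tol
}

#' Load the channel and second-messenger parameter set
#'
#' Reads reversal potentials, whole-dendrite maximal conductances, agonist
#' EC50s and Hill coefficients, antagonist IC50s and maximal inhibitions for
#' the four outer-dendritic pheromone-dependent currents (`Ca`, `cat`, `Cl`,
#' `x`), the soma K+ channel, and the charge-to-concentration conversion
#' factors.
#'
#' @param file Path to a YAML channel file. Default: the bundled
#'   `antheraea_channels.yaml`.
#' @param V_h Half-activation voltage (mV) of the K+ channel's logistic
#'   voltage factor. Defaults to the soma resting potential `E_ls` of the
#'   bundled base set (-62 mV).
#' @return An object of class `sensillum_channels`: a list with per-current
#'   records `Ca`, `cat`, `Cl`, `x` (fields `E` mV, `G_M` nS, `K_m` uM, `n`,
#'   and for inhibited channels `i_M`, `K_i` uM, `n_i`), the `K` record
#'   (`E`, `G_M`, `K_m`, `A_K`, `V_h`), `s_M` (1/s) and conversion factors
#'   `F`, `f_Ca`, `f_cat` (uM/pC).
#' @export
channel_params <- function(file = NULL, V_h = -62) {
  if (is.null(file)) {
    file <- system.file("extdata", "antheraea_channels.yaml",
                        package = "sensillum")
  }
  vals <- yaml::read_yaml(file)
  known <- c("s_M", "Ca", "cat", "Cl", "x", "K", "F", "f_Ca", "f_cat")
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("unknown channel key(s): ", paste(unknown, collapse = ", "))
  }
  for (y in c("Ca", "cat", "Cl", "x")) {
    rec <- vals[[y]]
    if (rec$G_M <= 0 || rec$K_m <= 0) {
      stop("channel '", y, "': G_M and K_m must be positive")
    }
    if (!is.null(rec$i_M) && rec$i_M < 1) {
      stop("channel '", y, "': maximal inhibition i_M must be >= 1")
    }
  }
  vals$K$V_h <- V_h
  structure(vals, class = "sensillum_channels")
}

#' Distribute whole-dendrite quantities over N compartments
#'
#' Membrane quantities (capacitance, leak and maximal channel conductances)
#' are divided by `N`; axial series conductances are multiplied by `N`, since
#' each compartment spans 1/N of the dendrite length.
#'
#' @param derived A `sensillum_derived` object.
#' @param channels A `sensillum_channels` object (optional; per-compartment
#'   maximal conductances are included when given).
#' @param N Number of outer-dendrite compartments (integer >= 1).
#' @return An object of class `sensillum_scaling`: a list with `N`, `c_dc`
#'   (pF), `g_ldc` (nS), `g_ec`, `g_ic` (nS), per-compartment maximal
#'   conductances `g_M` (named vector, nS), and the `derived` and `channels`
#'   inputs.
#' @examples
#' d <- derive_cable_params(sensillum_base_params())
#' s <- scale_to_compartments(d, channel_params(), N = 40)
#' s$g_ldc * s$N == d$G_ld
#' @export
scale_to_compartments <- function(derived, channels = NULL, N) {
  if (length(N) != 1L || !is.finite(N) || N < 1 || N != round(N)) {
    stop("N must be a single integer >= 1, got ", N)
  }
  N <- as.integer(N)
  g_M <- NULL
  if (!is.null(channels)) {
    g_M <- c(Ca = unname(channels$Ca$G_M), cat = unname(channels$cat$G_M),
             Cl = unname(channels$Cl$G_M), x = unname(channels$x$G_M)) / N
  }
  structure(list(
    N = N,
    c_dc = derived$C_d / N,
    g_ldc = derived$G_ld / N,
    g_ec = N * derived$G_e,
    g_ic = N * derived$G_i,
    g_M = g_M,
    derived = derived,
    channels = channels
  ), class = "sensillum_scaling")
}

#' @export
print.sensillum_derived <- function(x, ...) {
  cat("Derived sensillum cable parameters:\n")
  cat(sprintf("  S_d = %.1f um^2, C_d = %.3f pF, G_ld = %.4f nS\n",
              x$S_d, x$C_d, x$G_ld))
  cat(sprintf("  lambda = %.1f um, tau = %.2f ms, l_d = %.4f\n",
              x$lambda, x$tau, x$l_d))
  cat(sprintf("  E_ld = %.1f mV, r_in = %.4f, a = %.4f\n",
              x$E_ld, x$r_in, x$a))
  cat(sprintf("  G_e = %.2f nS, G_i = %.3f nS, G_ls = %.3f nS, G_a = %.3f nS\n",
              x$G_e, x$G_i, x$G_ls, x$G_a))
  invisible(x)
}
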