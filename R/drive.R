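#' Logarithmic dose grid of pheromone uptakes
#'
#' Inclusive log-spaced grid of uptake values. The reference protocol uses 26
#' uptakes separated by 0.25 log units from 10^-4.75 to 10^1.5 uM/s.
#'
#' @param min_exp,max_exp log10 of the smallest/largest uptake (uM/s),
#'   `max_exp >= min_exp`.
#' @param step Grid step in log10 units, > 0.
#' @return Numeric vector of uptakes (uM/s).
#' @examples
#' length(dose_grid(-4.75, 1.5, 0.25))  # 26
#' @export
dose_grid <- function(min_exp = -4.75, max_exp = 1.5, step = 0.25) {
  if (step <= 0) stop("step must be positive")
  if (max_exp < min_exp) stop("max_exp must be >= min_exp")
  10^seq(min_exp, max_exp, by = step)
}

#' Synthetic modulator drive protocol
#'
#' Defines the per-compartment second-messenger and modulator waveforms that
#' stand in for the upstream transduction cascade (receptor, G-protein and
#' effector kinetics are not modelled here; the module exposes this pluggable
#' surface instead). Second messengers IP3 and DAG are prescribed waveforms,
#' uniform along the dendrite; intradendritic Ca2+ follows the charge mass
#' balance of the Ca-carrying currents; CaCaM, PKC* and somatic Ca2+ are
#' low-pass-filtered copies of Ca2+.
#'
#' Dose scaling: waveform amplitudes are multiplied by
#' `U^h / (K_U^h + U^h)`, giving saturating sigmoidal dose-response shapes.
#'
#' @param kind Waveform family: `"biphasic"` (transient messenger surge
#'   followed by a sustained plateau, the default), `"square"` (plateau
#'   only), `"exponential"` (first-order rise and decay), or `"external"`
#'   (tabulated time series, see `table`).
#' @param onset,offset Stimulus start/end (s).
#' @param IP3_max,DAG_max Peak messenger concentrations at saturating uptake
#'   (uM).
#' @param h,K_U Hill exponent and half-saturation uptake (uM/s) of the dose
#'   scaling rule.
#' @param tau_rise,tau_decay Rise and decay time constants (s) of the
#'   transient messenger component.
#' @param tau_sustained Time constant (s) of the sustained component
#'   (biphasic kind) and of the post-offset relaxation.
#' @param frac_sustained Fraction of the messenger amplitude carried by the
#'   sustained component (biphasic kind).
#' @param cacam_gain,cacam_tau,pkc_gain,pkc_tau Gain (uM per uM Ca2+) and
#'   time constant (s) of the CaCaM and PKC* low-pass filters.
#' @param casoma_gain,casoma_tau Gain and time constant (s) of the somatic
#'   Ca2+ low-pass filter (driven by Ca2+ in the basal compartment).
#' @param table For `kind = "external"`: a data.frame with column `time` (s)
#'   and columns `IP3` and `DAG` (uM); linearly interpolated.
#' @return An object of class `sensillum_drive`.
#' @export
drive_protocol <- function(kind = c("biphasic", "square", "exponential",
                                    "external"),
                           onset = 0, offset = 2,
                           IP3_max = 10, DAG_max = 0.1,
                           h = 1, K_U = 0.2,
                           tau_rise = 0.05, tau_decay = 0.4,
                           tau_sustained = 1.5, frac_sustained = 0.35,
                           cacam_gain = 0.02, cacam_tau = 0.5,
                           pkc_gain = 0.005, pkc_tau = 1,
                           casoma_gain = 0.01, casoma_tau = 0.3,
                           table = NULL) {
  kind <- match.arg(kind)
  if (onset < 0 || offset < onset) {
    stop("need 0 <= onset <= offset")
  }
  if (IP3_max < 0 || DAG_max < 0) stop("amplitudes must be non-negative")
  if (kind == "external") {
    if (is.null(table) || !all(c("time", "IP3", "DAG") %in% names(table))) {
      stop("external drive needs a table with columns time, IP3, DAG")
    }
  }
  structure(as.list(environment()), class = "sensillum_drive")
}

#' Evaluate the prescribed messenger waveforms
#'
#' Returns the IP3 and DAG concentrations at times `t` for uptake `U`
#' under a drive protocol. Deterministic and continuous; zero before onset.
#'
#' @param protocol A `sensillum_drive` object.
#' @param t Time(s) in s.
#' @param U Pheromone uptake (uM/s), ignored for `kind = "external"`.
#' @return A list with numeric vectors `IP3` and `DAG` (uM).
#' @export
synthetic_modulators <- function(protocol, t, U = 1) {
  p <- protocol
  if (!inherits(p, "sensillum_drive")) stop("protocol must be a sensillum_drive")
  if (p$kind == "external") {
    IP3 <- stats::approx(p$table$time, p$table$IP3, xout = t, rule = 2)$y
    DAG <- stats::approx(p$table$time, p$table$DAG, xout = t, rule = 2)$y
    return(list(IP3 = pmax(IP3, 0), DAG = pmax(DAG, 0)))
  }
  dose <- U^p$h / (p$K_U^p$h + U^p$h)
  s <- drive_shape(p, t)
  list(IP3 = p$IP3_max * dose * s, DAG = p$DAG_max * dose * s)
}

# dimensionless waveform in [0, ~1]; shared by IP3 and DAG
drive_shape <- function(p, t) {
  tt <- t - p$onset
  on <- tt >= 0
  s <- numeric(length(t))
  if (p$kind == "square") {
    s[on & t <= p$offset] <- 1
    rel <- t > p$offset
    s[rel] <- exp(-(t[rel] - p$offset) / p$tau_sustained)
    return(s)
  }
  dur <- pmin(tt, p$offset - p$onset)  # stimulus-driven time
  # transient component, peak-normalized double exponential
  tr <- exp(-dur / p$tau_decay) - exp(-dur / p$tau_rise)
  tpk <- log(p$tau_decay / p$tau_rise) /
    (1 / p$tau_rise - 1 / p$tau_decay)
  tr <- tr / (exp(-tpk / p$tau_decay) - exp(-tpk / p$tau_rise))
  # sustained component
  su <- 1 - exp(-dur / p$tau_sustained)
  rel <- t > p$offset
  fade <- rep(1, length(t))
  fade[rel] <- exp(-(t[rel] - p$offset) / p$tau_sustained)
  w <- switch(p$kind,
              biphasic = (1 - p$frac_sustained) * tr + p$frac_sustained * su,
              exponential = su)
  s[on] <- (w * fade)[on]
  pmax(s, 0)
}

#' Calcium mass balance of one compartment
#'
#' Rate of change of intradendritic Ca2+ from the Ca-carrying currents:
#' influx through IP3-gated Ca2+ channels and DAG-gated cationic channels
#' (conversion factors `f_Ca`, `f_cat`), extrusion through the Na+/Ca2+
#' exchanger (factor `F`). Currents are outward-positive, so an inward
#' (negative) current through the Ca2+-permeable channels raises Ca2+. The
#' exchanger's Ca2+ flux opposes its charge flux (3 Na+ enter per Ca2+
#' extruded), so an inward NCX current lowers Ca2+ and the reversed
#' (outward) mode imports it. Conversion factors are calibrated for the
#' whole-dendrite volume; for a compartment of 1/N of the volume the per-pA
#' concentration change is N-fold larger, so rates scale with `N`.
#'
#' @param Ca Current Ca2+ concentration (uM), >= 0 (used only for clamping).
#' @param I_Ca,I_cat,I_x Per-compartment currents (pA), outward positive.
#' @param channels A `sensillum_channels` object (factors `F`, `f_Ca`,
#'   `f_cat`).
#' @param N Number of dendritic compartments.
#' @return dCa/dt in uM/s; non-negative when `Ca <= 0`.
#' @export
calcium_balance <- function(Ca, I_Ca, I_cat, I_x, channels, N = 1) {
  rate <- -N * (channels$f_Ca * I_Ca + channels$f_cat * I_cat) +
    N * channels$F * I_x
  ifelse(Ca <= 0, pmax(rate, 0), rate)
}
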