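#' Summarize a kinetic curve by height, half-rise and half-fall times
#'
#' Reduces a response time course to the three standard characteristics:
#' signed extremum height, time from stimulus onset to the first crossing of
#' half the height (`tau_rise`), and time from stimulus offset to the first
#' half-height crossing after the extremum (`tau_fall`, negative when the
#' response decays below half-maximum before the stimulus ends). Crossings
#' are located by linear interpolation between samples; ties break toward
#' earlier times. Curves that never reach half-height yield `NA` times.
#'
#' @param time Sample times (s), increasing.
#' @param value Response samples (mV or nS), starting at baseline 0.
#' @param onset,offset Stimulus start and end (s), `onset < offset`.
#' @return A list with `height`, `tau_rise` (s), `tau_fall` (s).
#' @export
characterize <- function(time, value, onset, offset) {
  if (onset >= offset) stop("need onset < offset")
  if (length(time) != length(value)) stop("time/value length mismatch")
  ipk <- which.max(abs(value))
  height <- value[ipk]
  if (height == 0) {
    return(list(height = 0, tau_rise = NA_real_, tau_fall = NA_real_))
  }
  half <- height / 2
  sgn <- sign(height)
  # work on the curve folded to positive-going
  v <- sgn * value
  h2 <- sgn * half
  tau_rise <- first_crossing(time, v, h2, from = onset,
                             direction = "up")
  t_fall <- first_crossing(time, v, h2, from = time[ipk],
                           direction = "down")
  tau_rise <- if (is.na(tau_rise)) NA_real_ else tau_rise - onset
  tau_fall <- if (is.na(t_fall)) NA_real_ else t_fall - offset
  list(height = height, tau_rise = tau_rise, tau_fall = tau_fall)
}

# first time >= from where v crosses level going up (or down); linear
# interpolation within the bracketing interval
first_crossing <- function(time, v, level, from, direction) {
  ok <- time >= from
  if (!any(ok)) return(NA_real_)
  tt <- time[ok]
  vv <- v[ok]
  if (direction == "up") {
    hit <- vv >= level
  } else {
    hit <- vv <= level
  }
  if (hit[1L]) return(tt[1L])
  i <- which(hit)[1L]
  if (is.na(i)) return(NA_real_)
  v0 <- vv[i - 1L]; v1 <- vv[i]
  if (v1 == v0) return(tt[i])
  tt[i - 1L] + (level - v0) / (v1 - v0) * (tt[i] - tt[i - 1L])
}

#' Half-maximal effective dose from a dose-response curve
#'
#' Normalizes responses by their maximum over the grid (unless they are
#' supplied already as relative heights) and interpolates the first upward
#' crossing of 0.5 linearly in log-dose.
#'
#' @param dose Dose grid (uM/s or nS), positive, increasing.
#' @param response Response heights (any unit); sign is removed.
#' @param normalize Divide by the maximum over the grid (default). Set to
#'   `FALSE` when `response` is already relative to a reference maximum, in
#'   which case a curve saturating below 0.5 yields `NA`.
#' @return The EC50 in dose units, or `NA` if the relative curve never
#'   crosses 0.5.
#' @export
ec50 <- function(dose, response, normalize = TRUE) {
  if (any(dose <= 0)) stop("doses must be positive")
  rel <- abs(response)
  if (normalize) rel <- rel / max(rel)
  ld <- log10(dose)
  lx <- first_crossing(ld, rel, 0.5, from = ld[1L], direction = "up")
  if (is.na(lx)) NA_real_ else 10^lx
}

#' Relative error of a numerical value against an analytic reference
#'
#' @param numeric Numerical value(s).
#' @param analytic Analytic reference value(s), nonzero.
#' @return `|numeric - analytic| / |analytic|` (fraction); `NA` with a
#'   warning where the reference is zero.
#' @export
relative_error <- function(numeric, analytic) {
  out <- abs(numeric - analytic) / abs(analytic)
  if (any(analytic == 0)) {
    warning("relative error undefined where the analytic reference is 0")
    out[analytic == 0] <- NA_real_
  }
  out
}

#' Conductance-to-voltage amplification ratios
#'
#' For a grid of total conductances and the corresponding steady soma
#' receptor potentials, computes the relative response `H_r =
#' RP_s/max(RP_s)`, the relative conductance `G_r = G_p/max(G_p)`, and the
#' relative amplification ratio `f_r = H_r/G_r`. A saturating (sub-linear)
#' conductance-to-voltage conversion yields `f_r > 1` at weak stimulation,
#' declining to exactly 1 at the grid maximum.
#'
#' @param G_p Conductance grid (nS), containing its maximum.
#' @param RP_s Steady-state soma receptor potentials (mV) per grid point.
#' @return A data.frame with columns `G_p`, `RP_s`, `H_r`, `G_r`, `f_r`.
#' @export
amplification_ratios <- function(G_p, RP_s) {
  if (max(abs(RP_s)) == 0) stop("all responses are zero")
  H_r <- RP_s / RP_s[which.max(G_p)]
  G_r <- G_p / max(G_p)
  data.frame(G_p = G_p, RP_s = RP_s, H_r = H_r, G_r = G_r, f_r = H_r / G_r)
}

#' Sweep one base parameter and tabulate a response metric
#'
#' Substitutes each value into the base parameter set (or the K+ maximal
#' conductance `G_MK` into the channel set), re-derives the whole dependent
#' cable chain, and evaluates a user metric on the re-derived parameters.
#'
#' @param name A field of [sensillum_base_params()] (e.g. `"L_d"`, `"S_s"`)
#'   or `"G_MK"`.
#' @param values Numeric values to substitute.
#' @param metric A function `(derived, channels) -> scalar`, e.g. an
#'   analytic steady-state RP at fixed conductivity.
#' @param base,channels Parameter objects to start from.
#' @return A data.frame with columns `value` and `metric`.
#' @examples
#' # steady RP_b vs dendrite length at fixed membrane conductivity
#' m <- function(derived, channels) {
#'   sigma_p <- 5e-6  # S/cm^2
#'   steady_rp_base(derived, sigma_p * derived$S_d * 1e-8 * 1e9)
#' }
#' parameter_sweep("L_d", c(110, 220, 440), m)
#' @export
parameter_sweep <- function(name, values, metric,
                            base = sensillum_base_params(),
                            channels = channel_params()) {
  out <- vapply(values, function(v) {
    if (name == "G_MK") {
      ch <- channels
      ch$K$G_M <- v
      metric(derive_cable_params(base), ch)
    } else if (name %in% names(base)) {
      b <- base
      b[[name]] <- v
      metric(derive_cable_params(b), channels)
    } else {
      stop("unknown parameter id '", name, "'")
    }
  }, numeric(1))
  data.frame(value = values, metric = out)
}

#' Dose-response characteristics of the complete model
#'
#' Runs the complete model over a dose grid of uptakes and characterizes RP
#' at the tip, mid-length and base of the dendrite, RP at the soma, and SP.
#'
#' @param scaling A `sensillum_scaling` with channels.
#' @param drive A `sensillum_drive` protocol.
#' @param doses Uptake grid (uM/s), see [dose_grid()].
#' @param t_end Simulation end (s).
#' @param dt_out Output sampling (s).
#' @param solver Solver settings.
#' @return A data.frame with one row per (dose, signal): columns `U`,
#'   `signal`, `height`, `tau_rise`, `tau_fall`.
#' @export
dose_response <- function(scaling, drive, doses = dose_grid(),
                          t_end = 8, dt_out = 1e-2,
                          solver = default_solver()) {
  N <- scaling$N
  mid <- max(1L, round(N / 2))
  rows <- list()
  for (U in doses) {
    traj <- integrate_complete(scaling, drive, U, t_end = t_end,
                               dt_out = dt_out, solver = solver)
    sigs <- list(RP_1 = traj$RP[, 1L], RP_mid = traj$RP[, mid],
                 RP_b = traj$RP_b, RP_s = traj$RP_s, SP = traj$SP)
    for (s in names(sigs)) {
      ch <- characterize(traj$time, sigs[[s]], drive$onset, drive$offset)
      rows[[length(rows) + 1L]] <- data.frame(
        U = U, signal = s, height = ch$height,
        tau_rise = ch$tau_rise, tau_fall = ch$tau_fall)
    }
  }
  do.call(rbind, rows)
}
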