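#' Fit target: dose-response characteristics to be matched
#'
#' @param H Heights per dose (mV).
#' @param tau_rise,tau_fall Half-rise/half-fall times per dose (s).
#' @param w_H,w_rise,w_fall Non-negative weights (per mV and per s). The
#'   defaults weight 0.1 s of kinetic mismatch like 1 mV of height mismatch.
#' @return An object of class `sensillum_fit_target`.
#' @export
fit_target <- function(H, tau_rise, tau_fall,
                       w_H = 1, w_rise = 10, w_fall = 10) {
  n <- length(H)
  if (n < 1L || length(tau_rise) != n || length(tau_fall) != n) {
    stop("H, tau_rise, tau_fall must have equal length >= 1")
  }
  if (any(c(w_H, w_rise, w_fall) < 0)) stop("weights must be >= 0")
  structure(list(H = H, tau_rise = tau_rise, tau_fall = tau_fall,
                 w_H = w_H, w_rise = w_rise, w_fall = w_fall, n = n),
            class = "sensillum_fit_target")
}

#' Weighted sum-of-differences cost over dose-response characteristics
#'
#' `J(theta) = sum_i w_H |dH_i| + w_rise |dtau_rise_i| + w_fall
#' |dtau_fall_i|` between the characteristics predicted by the model at
#' `theta` and the target. A characteristic missing on one side only (no
#' half-crossing) contributes `penalty_missing` times its weight; a model
#' failure at any dose yields a large finite penalty instead of an error.
#'
#' @param theta Parameter vector.
#' @param target A `sensillum_fit_target`.
#' @param runner Function `theta -> data.frame(H, tau_rise, tau_fall)` with
#'   one row per dose of the target.
#' @param penalty_missing Penalty units per missing characteristic.
#' @param penalty_fail Cost returned when the runner errors.
#' @return Non-negative scalar cost; zero iff all weighted characteristics
#'   match.
#' @export
fit_cost <- function(theta, target, runner, penalty_missing = 10,
                     penalty_fail = 1e6) {
  pred <- tryCatch(runner(theta), error = function(e) {
    message("model failure at theta = ",
            paste(signif(theta, 4), collapse = ", "), ": ",
            conditionMessage(e))
    NULL
  })
  if (is.null(pred) || nrow(pred) != target$n) return(penalty_fail)
  term <- function(obs, hat, w) {
    d <- abs(obs - hat)
    miss <- xor(is.na(obs), is.na(hat))
    d[is.na(d)] <- 0
    sum(w * d) + sum(miss) * penalty_missing * w
  }
  term(target$H, pred$H, target$w_H) +
    term(target$tau_rise, pred$tau_rise, target$w_rise) +
    term(target$tau_fall, pred$tau_fall, target$w_fall)
}

#' Fit specification: free parameters, bounds and optimizer settings
#'
#' @param par_names Names of the free parameters.
#' @param init Initial vector (within bounds).
#' @param lower,upper Finite physiological bounds.
#' @param maxit Maximal Nelder-Mead iterations per start.
#' @param reltol Convergence tolerance of [stats::optim()].
#' @param restarts Additional jittered restarts from the best point so far.
#' @param jitter_sd Relative s.d. of the restart jitter.
#' @param seed Seed for the restart jitter.
#' @return An object of class `sensillum_fit_spec`.
#' @export
fit_spec <- function(par_names, init, lower, upper, maxit = 400,
                     reltol = 1e-8, restarts = 1, jitter_sd = 0.05,
                     seed = 1) {
  k <- length(par_names)
  if (length(init) != k || length(lower) != k || length(upper) != k) {
    stop("init, lower, upper must match par_names in length")
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("bounds must be finite")
  }
  if (any(init < lower | init > upper)) {
    bad <- par_names[init < lower | init > upper]
    stop("initial value outside bounds for: ", paste(bad, collapse = ", "))
  }
  structure(list(par_names = par_names, init = init, lower = lower,
                 upper = upper, maxit = maxit, reltol = reltol,
                 restarts = restarts, jitter_sd = jitter_sd, seed = seed),
            class = "sensillum_fit_spec")
}

#' Nelder-Mead minimization of the characteristics cost
#'
#' Local simplex optimization of [fit_cost()]. The simplex itself is
#' unconstrained; bounds are enforced by a smooth quadratic penalty added
#' outside the box. Optional restarts jitter the best point with seeded
#' relative noise.
#'
#' @param spec A `sensillum_fit_spec`.
#' @param target A `sensillum_fit_target`.
#' @param runner Model runner, see [fit_cost()].
#' @param ... Passed to [fit_cost()].
#' @return List with `theta` (named best parameters), `value` (cost),
#'   `trace` (data.frame of evaluated costs), `starts` (per-start summary),
#'   `convergence` (0 = converged).
#' @export
optimize_fit <- function(spec, target, runner, ...) {
  stopifnot(inherits(spec, "sensillum_fit_spec"),
            inherits(target, "sensillum_fit_target"))
  evals <- new.env()
  evals$J <- numeric(0)
  penalized <- function(theta) {
    out <- sum(pmax(theta - spec$upper, 0)^2 + pmax(spec$lower - theta, 0)^2)
    J <- fit_cost(pmin(pmax(theta, spec$lower), spec$upper), target,
                  runner, ...) + 1e3 * out
    evals$J <- c(evals$J, J)
    J
  }
  best <- NULL
  starts <- list()
  theta0 <- spec$init
  rng <- local({ set.seed(spec$seed); function(k, s) stats::rnorm(k, 0, s) })
  for (s in seq_len(1L + spec$restarts)) {
    fit <- stats::optim(theta0, penalized, method = "Nelder-Mead",
                        control = list(maxit = spec$maxit,
                                       reltol = spec$reltol))
    starts[[s]] <- data.frame(start = s, value = fit$value,
                              convergence = fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
    theta0 <- best$par * (1 + rng(length(best$par), spec$jitter_sd))
    theta0 <- pmin(pmax(theta0, spec$lower), spec$upper)
  }
  theta <- pmin(pmax(best$par, spec$lower), spec$upper)
  names(theta) <- spec$par_names
  if (best$convergence != 0) {
    warning("Nelder-Mead did not report convergence; returning best-so-far")
  }
  list(theta = theta, value = best$value,
       trace = data.frame(eval = seq_along(evals$J), J = evals$J),
       starts = do.call(rbind, starts), convergence = best$convergence)
}

#' Qualitative post-fit screens on a complete-model trajectory
#'
#' Boolean checks reported alongside a fit (not folded into the cost):
#' the DAG-gated cationic conductance is transient (declines from its peak
#' before stimulus offset), the Cl- conductance is sustained (still above
#' half its peak at offset), and intradendritic Ca2+ stays below 200 uM.
#'
#' @param traj A `sensillum_trajectory` from [integrate_complete()].
#' @param drive The `sensillum_drive` used.
#' @return Named logical vector.
#' @export
post_fit_checks <- function(traj, drive) {
  ex <- traj$extras
  if (is.null(ex)) stop("trajectory has no transduction record")
  gcat <- rowMeans(ex$g_cat)
  gcl <- rowMeans(ex$g_Cl)
  tpk <- traj$time[which.max(gcat)]
  at_off <- which.min(abs(traj$time - drive$offset))
  c(cat_transient = tpk < drive$offset &&
      gcat[at_off] < 0.9 * max(gcat),
    cl_sustained = gcl[at_off] > 0.5 * max(gcl),
    ca_below_200 = max(ex$Ca) < 200)
}
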