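#' Parameters of the multi-compartment deflation model
#'
#' Passive expiration of parallel lobar RC compartments through a shared
#' central resistance into a pressure source at PEEP.  Each compartment
#' carries a linear compliance and a resistance; airways are rigid and
#' inertance is neglected (quasi-static, laminar framing).
#'
#' @param resistance Named numeric vector of per-lobe resistances,
#'   cmH2O s/L (> 0).
#' @param compliance Named numeric vector of per-lobe compliances,
#'   L/cmH2O (> 0), same names as `resistance`.
#' @param central_resistance Shared central resistance, cmH2O s/L (>= 0).
#' @param peep Outlet pressure, cmH2O.
#' @param initial_volume Named numeric vector of initial lobar volumes
#'   above the relaxed volume, L (>= 0).
#' @return A list of class `"deflation_params"`.
#' @export
deflation_params <- function(resistance, compliance, central_resistance = 0,
                             peep = 0, initial_volume) {
  if (is.null(names(resistance)) || is.null(names(compliance)) ||
      is.null(names(initial_volume))) {
    abort("`resistance`, `compliance` and `initial_volume` must be named by lobe.")
  }
  lobes <- names(resistance)
  if (!setequal(lobes, names(compliance)) ||
      !setequal(lobes, names(initial_volume))) {
    abort("lobe names must agree across resistance, compliance and initial_volume.")
  }
  compliance <- compliance[lobes]
  initial_volume <- initial_volume[lobes]
  if (any(resistance <= 0)) abort("per-lobe resistances must be > 0.")
  if (any(compliance <= 0)) abort("compliances must be > 0.")
  if (central_resistance < 0) abort("central_resistance must be >= 0.")
  if (any(initial_volume < 0)) abort("initial volumes must be >= 0.")
  structure(
    list(resistance = resistance, compliance = compliance,
         central_resistance = central_resistance, peep = peep,
         initial_volume = initial_volume),
    class = "deflation_params"
  )
}

## Airway-opening pressure above PEEP: one scalar balance equating lobar
## outflows with the flow through the central resistance.
airway_opening_excess <- function(v, params) {
  e <- v / params$compliance                  # lobar recoil above PEEP
  g <- 1 / params$resistance
  if (params$central_resistance <= 0) return(0)
  sum(e * g) / (1 / params$central_resistance + sum(g))
}

#' Simulate passive multi-compartment deflation
#'
#' Integrates `dV_L/dt = -(P_L - P_aw) / R_L` with `P_L = V_L/C_L + PEEP`
#' and the shared airway-opening pressure `P_aw` solved algebraically at
#' each step from the central-resistance flow balance.  With zero central
#' resistance every compartment decays exponentially with its own time
#' constant `R_L * C_L`.
#'
#' @param params A [deflation_params()] object.
#' @param t_end Simulation end time, s.
#' @param dt Output (and fixed-step) time step, s; default `t_end / 500`.
#' @param method `"adaptive"` (lsoda, relative tolerance 1e-8, default)
#'   or `"fixed"` (classical RK4 at step `dt`; errors when `dt` exceeds a
#'   fifth of the smallest compartment time constant).
#' @return Tibble of class `"deflation_trace"`: `time_s`, one
#'   `volume_<lobe>_L` and `flow_<lobe>_L_s` column per compartment,
#'   `tracheal_flow_L_s` and `tracheal_pressure_cmH2O`.
#' @export
simulate_deflation <- function(params, t_end, dt = NULL,
                               method = c("adaptive", "fixed")) {
  method <- match.arg(method)
  if (is.null(dt)) dt <- t_end / 500
  if (dt <= 0 || t_end <= dt) abort("need dt > 0 and t_end > dt.")
  tau_min <- min(params$resistance * params$compliance)
  if (method == "fixed" && dt > tau_min / 5) {
    abort(paste0("stability error: dt = ", dt, " exceeds min(tau)/5 = ",
                 tau_min / 5, " in fixed-step mode."))
  }
  lobes <- names(params$resistance)
  deriv <- function(t, v, p) {
    x <- airway_opening_excess(v, params)
    list(-(v / params$compliance - x) / params$resistance)
  }
  times <- seq(0, t_end, by = dt)
  sol <- if (method == "adaptive") {
    deSolve::ode(y = params$initial_volume, times = times, func = deriv,
                 parms = NULL, method = "lsoda", rtol = 1e-8, atol = 1e-12)
  } else {
    deSolve::ode(y = params$initial_volume, times = times, func = deriv,
                 parms = NULL, method = "rk4")
  }
  vols <- pmax(sol[, -1, drop = FALSE], 0)
  x <- apply(vols, 1, airway_opening_excess, params = params)
  flows <- sweep(sweep(vols, 2, params$compliance, "/") , 1, x, "-") |>
    sweep(2, params$resistance, "/")
  out <- tibble(time_s = sol[, 1])
  for (j in seq_along(lobes)) {
    out[[paste0("volume_", lobes[j], "_L")]] <- vols[, j]
    out[[paste0("flow_", lobes[j], "_L_s")]] <- flows[, j]
  }
  out$tracheal_flow_L_s <- rowSums(flows)
  out$tracheal_pressure_cmH2O <- params$peep + x
  attr(out, "params") <- params
  class(out) <- c("deflation_trace", class(tibble()))
  out
}

#' Fit a single-exponential time constant to a deflation trace
#'
#' Least-squares slope of `log(total volume above relaxed volume)` versus
#' time; the time constant estimate is `-1/slope`.  This is the standard
#' pneumotach-style estimate used to cross-check the FRI `tau = R/E`
#' value.
#'
#' @param trace A [simulate_deflation()] result.
#' @param window Optional `c(t0, t1)` restricting the fit (e.g. a late
#'   window to read the slow compartment of a bi-exponential decay).
#' @return Estimated time constant, s.
#' @export
fit_single_exponential <- function(trace, window = NULL) {
  vol_cols <- grep("^volume_", names(trace), value = TRUE)
  v <- rowSums(trace[, vol_cols, drop = FALSE])
  t <- trace$time_s
  keep <- v > 0
  if (!is.null(window)) keep <- keep & t >= window[1] & t <= window[2]
  if (sum(keep) < 10) {
    abort("fit error: need >= 10 samples with positive volume in the window.")
  }
  v <- v[keep]; t <- t[keep]
  if (any(diff(v) > 1e-12 * max(v))) {
    abort("fit error: volume signal is not monotone non-increasing.")
  }
  slope <- coef(lm(log(v) ~ t))[["t"]]
  if (!is.finite(slope) || slope >= 0) {
    abort("fit error: non-decaying signal.")
  }
  -1 / slope
}

#' Write a deflation trace to CSV
#' @param trace A [simulate_deflation()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_deflation_trace <- function(trace, path) {
  readr::write_csv(as_tibble(trace), path)
  invisible(path)
}
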