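#' Sigmoid Emax response of a lipid to CETP activity
#'
#' RES(R) = rmax R^gamma / (R^gamma + r50^gamma); bounded in [0, rmax),
#' monotone increasing, half-maximal at R = r50. The limit at R = 0 is 0.
#'
#' @param R CETP activity (pmole, >= 0); vectorized.
#' @param rmax Maximal response (unitless).
#' @param r50 Activity of half-maximal response (pmole).
#' @param gamma Hill steepness (unitless, > 0).
#' @return Unitless response value(s).
#' @export
res_cetp <- function(R, rmax, r50, gamma) {
  if (any(R < 0)) stop_invalid("R must be >= 0")
  # (r50/R)^gamma form is stable for large R; handle R = 0 as the limit
  out <- ifelse(R == 0, 0, rmax / (1 + (r50 / pmax(R, .Machine$double.xmin))^gamma))
  unname(out)
}

#' Linear placebo ramp on LDL-C production
#'
#' PLA(t) = beta t; an unbounded linear time trend multiplying production.
#'
#' @param t Time (h, >= 0); vectorized.
#' @param beta Slope (1/h).
#' @return Unitless term(s).
#' @export
ldl_placebo_term <- function(t, beta) {
  if (any(t < 0)) stop_invalid("t must be >= 0")
  beta * t
}

#' Right-hand sides of the lipid turnover models
#'
#' HDL-C: dH/dt = ksyn - kdeg H (1 + RES(R)) (CETP response stimulates loss).
#' LDL-C: dL/dt = ksyn (1 + beta t) - kdeg L (1 - RES(R)) (CETP response
#' inhibits loss; production carries the linear placebo ramp).
#'
#' @param H,L Lipid concentration (mg/dL, >= 0).
#' @param t Time (h).
#' @param R_at Function of time returning CETP activity (pmole).
#' @param p A [lipid_params()] object of the matching direction.
#' @return d/dt in mg/dL/h.
#' @export
hdl_rhs <- function(H, t, R_at, p) {
  p$ksyn - p$kdeg * H * (1 + res_cetp(R_at(t), p$rmax, p$r50, p$gamma))
}

#' @rdname hdl_rhs
#' @export
ldl_rhs <- function(L, t, R_at, p) {
  p$ksyn * (1 + p$beta * t) -
    p$kdeg * L * (1 - res_cetp(R_at(t), p$rmax, p$r50, p$gamma))
}

# internal: lipid trajectory given a CETP activity function
lipid_traj_given_R <- function(p, R_at, times, rtol = 1e-8, atol = 1e-8) {
  sgn <- if (p$direction == "stimulation") 1 else -1
  rhs <- function(t, y, parms) {
    res <- res_cetp(max(R_at(t), 0), p$rmax, p$r50, p$gamma)
    list(p$ksyn * (1 + p$beta * t) - p$kdeg * y[1L] * (1 + sgn * res))
  }
  tms <- sort(unique(c(0, times)))
  sol <- deSolve::lsoda(c(X = p$rb), tms, rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("lipid ODE solver failed near t = ", utils::tail(sol[, "time"], 1L))
  sol[match(round(times, 9), round(sol[, "time"], 9)), "X"]
}

#' Simulate HDL-C and LDL-C given a CETP activity trajectory
#'
#' Solves the lipid turnover models with X(0) = rb. The CETP input is a
#' function of time or a dense trajectory (data frame with `time_h`,
#' `cetp_pmole`), linearly interpolated; the trajectory must cover the span.
#'
#' @param cetp Function of time, or a CETP trajectory data frame.
#' @param hdl,ldl [lipid_params()] objects; either may be `NULL` to skip.
#' @param output_times Sorted non-negative times (h).
#' @return A data frame with columns `time_h` and, as requested, `hdl_mg_dl`
#'   and/or `ldl_mg_dl`.
#' @export
simulate_lipids <- function(cetp, hdl = NULL, ldl = NULL, output_times) {
  stopifnot(!is.unsorted(output_times), all(output_times >= 0))
  R_at <-
    if (is.function(cetp)) cetp
    else {
      stopifnot(all(c("time_h", "cetp_pmole") %in% names(cetp)))
      if (max(output_times) > max(cetp$time_h) + 1e-9)
        stop("CETP trajectory does not cover the simulation span")
      stats::approxfun(cetp$time_h, cetp$cetp_pmole, rule = 2)
    }
  out <- data.frame(time_h = output_times)
  if (!is.null(hdl)) {
    stopifnot(hdl$direction == "stimulation")
    out$hdl_mg_dl <- lipid_traj_given_R(hdl, R_at, output_times)
  }
  if (!is.null(ldl)) {
    stopifnot(ldl$direction == "inhibition")
    out$ldl_mg_dl <- lipid_traj_given_R(ldl, R_at, output_times)
  }
  out
}
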