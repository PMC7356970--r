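#' Placebo (time) effect on CETP production
#'
#' Emax function of time, attributed to the study-wide dietary time trend:
#' kmax t / (k50 + t). Zero at t = 0, approaching kmax.
#'
#' @param t Time (h, >= 0); vectorized.
#' @param kmax Maximal effect (unitless).
#' @param k50 Time of half-maximal effect (h).
#' @return Unitless effect value(s).
#' @export
placebo_effect <- function(t, kmax, k50) {
  if (any(t < 0)) stop_invalid("t must be >= 0")
  kmax * t / (k50 + t)
}

#' Drug effect on CETP loss
#'
#' Emax function of plasma concentration: emax cp / (ec50 + cp); bounded in
#' [0, emax), monotone increasing, half-maximal at cp = ec50.
#'
#' @param cp Plasma concentration (ng/mL, >= 0); vectorized.
#' @param emax Maximal effect (unitless).
#' @param ec50 Concentration of half-maximal effect (ng/mL).
#' @return Unitless effect value(s).
#' @export
drug_effect <- function(cp, emax, ec50) {
  if (any(cp < 0)) stop_invalid("cp must be >= 0")
  emax * cp / (ec50 + cp)
}

#' Right-hand side of the CETP-activity turnover model
#'
#' dR/dt = kin_base (1 + Placebo(t)) - kout R (1 + Drug(cp(t))); production is
#' stimulated by the placebo time effect, first-order loss is stimulated by
#' drug concentration.
#'
#' @param R CETP activity (pmole, >= 0).
#' @param t Time (h).
#' @param cp_at A function of time returning plasma concentration (ng/mL).
#' @param p A [cetp_params()] object.
#' @return dR/dt (pmole/h).
#' @export
cetp_rhs <- function(R, t, cp_at, p) {
  p$kin_base * (1 + placebo_effect(t, p$kmax, p$k50)) -
    p$kout * R * (1 + drug_effect(cp_at(t), p$emax, p$ec50))
}

# internal: solve the CETP ODE given a concentration function
cetp_traj_given_cp <- function(p, cp_at, times, rtol = 1e-8, atol = 1e-8) {
  rhs <- function(t, y, parms) {
    list(p$kin_base * (1 + p$kmax * t / (p$k50 + t)) -
           p$kout * y[1L] * (1 + p$emax * cp_at(t) / (p$ec50 + cp_at(t))))
  }
  tms <- sort(unique(c(0, times)))
  sol <- deSolve::lsoda(c(R = p$cetp_base), tms, rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("CETP ODE solver failed near t = ", utils::tail(sol[, "time"], 1L))
  sol[match(round(times, 9), round(sol[, "time"], 9)), "R"]
}

#' Simulate CETP activity given a concentration input
#'
#' Solves the turnover model with R(0) = cetp_base. The concentration input is
#' either a function of time or a dense concentration series (data frame with
#' `time_h`, `conc_ng_ml`) which is linearly interpolated; the series must
#' cover the simulation span. The placebo clock starts at t = 0 in all arms.
#'
#' @param conc Function of time, or a concentration series data frame, or
#'   `NULL` for a placebo arm (cp = 0).
#' @param p A [cetp_params()] object.
#' @param output_times Sorted non-negative times (h).
#' @return A data frame with columns `time_h`, `cetp_pmole`.
#' @export
simulate_cetp <- function(conc, p, output_times) {
  stopifnot(!is.unsorted(output_times), all(output_times >= 0))
  cp_at <-
    if (is.null(conc)) function(t) rep(0, length(t))
    else if (is.function(conc)) conc
    else {
      stopifnot(all(c("time_h", "conc_ng_ml") %in% names(conc)))
      if (max(output_times) > max(conc$time_h) + 1e-9)
        stop("concentration series does not cover the simulation span")
      stats::approxfun(conc$time_h, conc$conc_ng_ml, rule = 2)
    }
  R <- cetp_traj_given_cp(p, cp_at, output_times)
  data.frame(time_h = output_times, cetp_pmole = unname(R))
}
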