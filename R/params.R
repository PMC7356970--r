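#' @keywords internal
stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = "invalid_parameter"))
}

check_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_invalid(what, " must be a single strictly positive number, got ",
                 paste(format(x), collapse = ", "))
  invisible(x)
}

check_nonneg <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop_invalid(what, " must be a single non-negative number, got ",
                 paste(format(x), collapse = ", "))
  invisible(x)
}

#' Structural pharmacokinetic parameters
#'
#' Apparent (dose-scaled, oral) parameters of the three-compartment disposition
#' model with an Erlang transit-absorption chain: clearance `cl` (L/h), central
#' volume `v` (L), peripheral volumes `v2`, `v3` (L), inter-compartmental
#' clearances `q2`, `q3` (L/h), first-order absorption rate `ka` (1/h), transit
#' rate `ktr` (1/h) shared by the `n_transit` sequential transit compartments.
#'
#' @param cl,v,v2,v3,q2,q3,ka,ktr Strictly positive scalars (units above).
#' @param n_transit Integer number of transit compartments, at least 1.
#' @return An object of class `pk_params` (named list).
#' @export
pk_params <- function(cl, v, v2, v3, q2, q3, ka, ktr, n_transit = 5L) {
  for (nm in c("cl", "v", "v2", "v3", "q2", "q3", "ka", "ktr"))
    check_positive(get(nm), nm)
  if (length(n_transit) != 1L || n_transit < 1 || n_transit != round(n_transit))
    stop_invalid("n_transit must be an integer >= 1")
  structure(list(cl = cl, v = v, v2 = v2, v3 = v3, q2 = q2, q3 = q3,
                 ka = ka, ktr = ktr, n_transit = as.integer(n_transit)),
            class = "pk_params")
}

#' Dose- and time-dependent relative bioavailability parameters
#'
#' Relative bioavailability F = BA x FT with
#' BA = bmax (1 - dose/(ba50 + dose)) and FT = exp(-alpha(dose) x time),
#' where `alpha_low` applies below `dose_threshold` (mg) and `alpha_high`
#' (conventionally fixed at 0) at or above it.
#'
#' @param bmax Maximal relative bioavailability (unitless, > 0).
#' @param ba50 Dose of half-maximal effect on bioavailability (mg, > 0).
#' @param alpha_low Time-decay coefficient for the lower dose groups (1/h, >= 0).
#' @param alpha_high Time-decay coefficient for the highest dose group (1/h, >= 0).
#' @param dose_threshold Dose (mg) at/above which `alpha_high` applies.
#' @return An object of class `ba_params`.
#' @export
ba_params <- function(bmax, ba50, alpha_low, alpha_high = 0, dose_threshold = 400) {
  check_positive(bmax, "bmax"); check_positive(ba50, "ba50")
  check_nonneg(alpha_low, "alpha_low"); check_nonneg(alpha_high, "alpha_high")
  check_positive(dose_threshold, "dose_threshold")
  structure(list(bmax = bmax, ba50 = ba50, alpha_low = alpha_low,
                 alpha_high = alpha_high, dose_threshold = dose_threshold),
            class = "ba_params")
}

#' CETP-activity turnover parameters
#'
#' Parameters of the indirect-response model
#' dR/dt = kin_base (1 + Placebo(t)) - kout R (1 + Drug(Cp)), with an Emax
#' placebo effect of time on production and an Emax drug effect of plasma
#' concentration on loss. The loss rate `kout` is not free: baseline
#' stationarity fixes kout = kin_base / cetp_base (see [derive_kout()]).
#'
#' @param cetp_base Baseline CETP activity (pmole, > 0).
#' @param kin_base Baseline production rate (pmole/h, > 0).
#' @param kmax Maximal placebo (time) effect on production (unitless, >= 0).
#' @param k50 Time of half-maximal placebo effect (h, > 0).
#' @param emax Maximal drug effect on loss (unitless, >= 0).
#' @param ec50 Concentration of half-maximal drug effect (ng/mL, > 0).
#' @return An object of class `cetp_params` with derived element `kout` (1/h).
#' @export
cetp_params <- function(cetp_base, kin_base, kmax, k50, emax, ec50) {
  check_positive(cetp_base, "cetp_base"); check_positive(kin_base, "kin_base")
  check_nonneg(kmax, "kmax"); check_positive(k50, "k50")
  check_nonneg(emax, "emax"); check_positive(ec50, "ec50")
  structure(list(cetp_base = cetp_base, kin_base = kin_base, kmax = kmax,
                 k50 = k50, emax = emax, ec50 = ec50,
                 kout = derive_kout(kin_base, cetp_base)),
            class = "cetp_params")
}

#' Lipid (HDL-C or LDL-C) turnover parameters
#'
#' Parameters of the lipid indirect-response model driven by CETP activity
#' through a sigmoid Emax response RES(R) = rmax R^gamma / (R^gamma + r50^gamma).
#' For HDL-C the CETP response stimulates loss (`direction = "stimulation"`);
#' for LDL-C it inhibits loss (`direction = "inhibition"`) and a linear placebo
#' ramp `beta` x time multiplies production. The loss rate `kdeg` is tied by
#' baseline stationarity at `reference_cetp` (see [derive_kdeg()]).
#'
#' @param rb Baseline lipid concentration (mg/dL, > 0).
#' @param ksyn Zero-order production rate (mg/dL/h, > 0).
#' @param rmax Maximal CETP-driven response (unitless, > 0).
#' @param r50 CETP activity of half-maximal response (pmole, > 0).
#' @param gamma Hill steepness (unitless, > 0).
#' @param beta Placebo slope on production (1/h, >= 0; 0 for HDL-C).
#' @param direction `"stimulation"` (HDL-C) or `"inhibition"` (LDL-C) of loss.
#' @param reference_cetp CETP activity (pmole) at which the baseline is
#'   stationary; by convention the baseline CETP activity of the linked model.
#' @return An object of class `lipid_params` with derived element `kdeg` (1/h).
#' @export
lipid_params <- function(rb, ksyn, rmax, r50, gamma, beta = 0,
                         direction = c("stimulation", "inhibition"),
                         reference_cetp) {
  direction <- match.arg(direction)
  check_positive(rb, "rb"); check_positive(ksyn, "ksyn")
  check_nonneg(rmax, "rmax"); check_positive(r50, "r50")
  check_positive(gamma, "gamma"); check_nonneg(beta, "beta")
  check_positive(reference_cetp, "reference_cetp")
  obj <- structure(list(rb = rb, ksyn = ksyn, rmax = rmax, r50 = r50,
                        gamma = gamma, beta = beta, direction = direction,
                        reference_cetp = reference_cetp),
                   class = "lipid_params")
  obj$kdeg <- derive_kdeg(obj, reference_cetp)
  obj
}

#' Derive the CETP loss rate constant from baseline stationarity
#'
#' The published model reports the baseline activity and the baseline
#' production rate but not the first-order loss rate; with no drug and no
#' placebo effect, stationarity at baseline (0 = kin_base - kout x cetp_base)
#' determines it uniquely.
#'
#' @param kin_base Baseline production rate (pmole/h, > 0).
#' @param cetp_base Baseline CETP activity (pmole, > 0).
#' @return The loss rate constant kout (1/h).
#' @export
derive_kout <- function(kin_base, cetp_base) {
  check_positive(kin_base, "kin_base")
  check_positive(cetp_base, "cetp_base")
  kin_base / cetp_base
}

#' Derive the lipid loss rate constant from baseline stationarity
#'
#' With CETP activity held at `reference_cetp`, the lipid baseline `rb` is
#' stationary when ksyn = kdeg x rb x (1 + RES) (stimulation of loss, HDL-C)
#' or ksyn = kdeg x rb x (1 - RES) (inhibition of loss, LDL-C), where RES is
#' the sigmoid Emax response evaluated at the reference activity.
#'
#' @param lipid A [lipid_params()] object (the `kdeg` element is ignored).
#' @param reference_cetp CETP activity (pmole) at which the baseline holds.
#' @return The loss rate constant kdeg (1/h).
#' @export
derive_kdeg <- function(lipid, reference_cetp) {
  check_positive(reference_cetp, "reference_cetp")
  res <- res_cetp(reference_cetp, lipid$rmax, lipid$r50, lipid$gamma)
  fac <- if (lipid$direction == "stimulation") 1 + res else 1 - res
  if (fac <= 0)
    stop_invalid("baseline stationarity impossible: loss multiplier ",
                 "(1 - RES) = ", format(fac), " is non-positive at the ",
                 "reference CETP activity")
  lipid$ksyn / (lipid$rb * fac)
}

#' Inter-individual variability specification
#'
#' Coefficients of variation (percent) of the log-normally distributed
#' individual parameters, by model stage. Only the parameters named here carry
#' variability; a CV of 0 disables it. CV% is interpreted as the standard
#' deviation of the log-scale deviation times 100 (small-CV convention of
#' exponential IIV models).
#'
#' @param pk,cetp,hdl,ldl Named numeric vectors of CV% (>= 0). Allowed names:
#'   pk: cl, v3, bmax, ktr; cetp: kin_base, emax; hdl: rb; ldl: rb, beta, gamma.
#' @return An object of class `iiv_spec`.
#' @export
iiv_spec <- function(pk = numeric(), cetp = numeric(),
                     hdl = numeric(), ldl = numeric()) {
  allowed <- list(pk = c("cl", "v3", "bmax", "ktr"),
                  cetp = c("kin_base", "emax"),
                  hdl = "rb", ldl = c("rb", "beta", "gamma"))
  out <- list(pk = pk, cetp = cetp, hdl = hdl, ldl = ldl)
  for (stage in names(out)) {
    x <- out[[stage]]
    if (length(x)) {
      if (is.null(names(x)) || any(!names(x) %in% allowed[[stage]]))
        stop_invalid("iiv_spec[", stage, "]: names must be among ",
                     paste(allowed[[stage]], collapse = ", "))
      if (any(!is.finite(x)) || any(x < 0))
        stop_invalid("iiv_spec[", stage, "]: CV% must be finite and >= 0")
    }
  }
  structure(out, class = "iiv_spec")
}

#' Residual (observation-level) error specification
#'
#' Combined additive + proportional error model:
#' obs = pred (1 + eps_p) + eps_a with eps_p ~ N(0, prop^2),
#' eps_a ~ N(0, add^2).
#'
#' @param add Additive SD, in the units of the endpoint (>= 0).
#' @param prop Proportional SD, as a fraction (>= 0). Not both may be zero.
#' @return An object of class `residual_spec`.
#' @export
residual_spec <- function(add, prop) {
  check_nonneg(add, "add"); check_nonneg(prop, "prop")
  if (add == 0 && prop == 0)
    stop_invalid("residual_spec: additive and proportional SD must not both be 0")
  structure(list(add = add, prop = prop), class = "residual_spec")
}

#' Published population parameter set
#'
#' The package's default truth set: the final population fixed effects,
#' inter-individual variability magnitudes and residual-error terms of the
#' CETP-inhibitor PK-PD model chain, with the loss rates `kout` and `kdeg`
#' derived by baseline stationarity.
#'
#' @return An object of class `pkpd_params`: a list with elements `pk`
#'   ([pk_params()]), `ba` ([ba_params()]), `cetp` ([cetp_params()]), `hdl`
#'   and `ldl` ([lipid_params()]), `iiv` ([iiv_spec()]) and `residual`
#'   (a list of [residual_spec()] per endpoint).
#' @examples
#' p <- published_params()
#' p$pk$cl            # 6.4 L/h
#' p$cetp$kout        # 164/350 1/h, derived
#' @export
published_params <- function() {
  pkpd_params(
    pk = pk_params(cl = 6.4, v = 11.4, v2 = 45.4, v3 = 1006.0,
                   q2 = 2.6, q3 = 3.3, ka = 1.09, ktr = 1.10, n_transit = 5L),
    ba = ba_params(bmax = 1.6, ba50 = 90.1, alpha_low = 0.002,
                   alpha_high = 0, dose_threshold = 400),
    cetp = cetp_params(cetp_base = 350.0, kin_base = 164.0, kmax = 9.6,
                       k50 = 9700.0, emax = 18.2, ec50 = 587.0),
    hdl = lipid_params(rb = 50.0, ksyn = 1.26, rmax = 1.5, r50 = 185.0,
                       gamma = 2.1, beta = 0, direction = "stimulation",
                       reference_cetp = 350.0),
    ldl = lipid_params(rb = 97.4, ksyn = 0.435, rmax = 0.8, r50 = 80.7,
                       gamma = 2.2, beta = 0.0009, direction = "inhibition",
                       reference_cetp = 350.0),
    iiv = iiv_spec(pk = c(cl = 15.6, v3 = 58.1, bmax = 28.2, ktr = 14.1),
                   cetp = c(kin_base = 19.7, emax = 39.5),
                   hdl = c(rb = 17.2),
                   ldl = c(rb = 23.6, beta = 97.4, gamma = 50.9)),
    residual = list(pk = residual_spec(add = 0.0001, prop = 0.30),
                    cetp = residual_spec(add = 40.4, prop = 0.112),
                    hdl = residual_spec(add = 4.6, prop = 0),
                    ldl = residual_spec(add = 0, prop = 0.07))
  )
}

#' Assemble a full PK-PD parameter collection
#'
#' @param pk,ba,cetp,hdl,ldl,iiv,residual Components as produced by the
#'   respective constructors; `residual` is a list with elements `pk`, `cetp`,
#'   `hdl`, `ldl`.
#' @return An object of class `pkpd_params`.
#' @export
pkpd_params <- function(pk, ba, cetp, hdl, ldl, iiv = iiv_spec(),
                        residual = NULL) {
  stopifnot(inherits(pk, "pk_params"), inherits(ba, "ba_params"),
            inherits(cetp, "cetp_params"), inherits(hdl, "lipid_params"),
            inherits(ldl, "lipid_params"), inherits(iiv, "iiv_spec"))
  if (!is.null(residual)) {
    if (!all(c("pk", "cetp", "hdl", "ldl") %in% names(residual)) ||
        !all(vapply(residual, inherits, TRUE, "residual_spec")))
      stop_invalid("residual must be a list of residual_spec for pk, cetp, hdl, ldl")
  }
  structure(list(pk = pk, ba = ba, cetp = cetp, hdl = hdl, ldl = ldl,
                 iiv = iiv, residual = residual),
            class = "pkpd_params")
}

#' @export
print.pkpd_params <- function(x, ...) {
  cat("PK-PD parameter collection\n")
  fmt <- function(l, skip = character()) {
    nm <- setdiff(names(l), skip)
    paste(sprintf("%s=%s", nm,
                  vapply(l[nm], function(v) format(v, digits = 6), "")),
          collapse = ", ")
  }
  cat("  PK:   ", fmt(unclass(x$pk)), "\n")
  cat("  F:    ", fmt(unclass(x$ba)), "\n")
  cat("  CETP: ", fmt(unclass(x$cetp)), "\n")
  cat("  HDL:  ", fmt(unclass(x$hdl), "direction"), "\n")
  cat("  LDL:  ", fmt(unclass(x$ldl), "direction"), "\n")
  if (!is.null(x$residual))
    cat("  residual SDs: pk(", x$residual$pk$add, ",", x$residual$pk$prop,
        ") cetp(", x$residual$cetp$add, ",", x$residual$cetp$prop,
        ") hdl(", x$residual$hdl$add, ",", x$residual$hdl$prop,
        ") ldl(", x$residual$ldl$add, ",", x$residual$ldl$prop, ")\n")
  invisible(x)
}

## ---- serialization ---------------------------------------------------------

params_to_list <- function(params) {
  list(
    pk = unclass(params$pk),
    bioavailability = unclass(params$ba),
    cetp = unclass(params$cetp)[c("cetp_base", "kin_base", "kmax", "k50",
                                  "emax", "ec50")],
    hdl = unclass(params$hdl)[c("rb", "ksyn", "rmax", "r50", "gamma", "beta",
                                "direction", "reference_cetp")],
    ldl = unclass(params$ldl)[c("rb", "ksyn", "rmax", "r50", "gamma", "beta",
                                "direction", "reference_cetp")],
    iiv = lapply(unclass(params$iiv), as.list),
    residual = lapply(params$residual, unclass)
  )
}

params_from_list <- function(lst) {
  # JSON/YAML readers return whole numbers as integers; the constructors
  # expect doubles everywhere except the transit count
  lst <- rapply(lst, function(x)
    if (is.integer(x)) as.double(x) else x, how = "replace")
  lst$pk$n_transit <- as.integer(lst$pk$n_transit)
  lip <- function(l) do.call(lipid_params, l)
  iiv <- lapply(lst$iiv, function(x) unlist(x) %||% numeric())
  pkpd_params(
    pk = do.call(pk_params, lst$pk),
    ba = do.call(ba_params, lst$bioavailability),
    cetp = do.call(cetp_params, lst$cetp),
    hdl = lip(lst$hdl), ldl = lip(lst$ldl),
    iiv = do.call(iiv_spec, lapply(lst$iiv, function(x)
      if (length(x)) unlist(x) else numeric())),
    residual = lapply(lst$residual, function(r) do.call(residual_spec, r))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a parameter collection
#'
#' Serializes the primitive (non-derived) fields of a [pkpd_params()] object to
#' YAML (`.yaml`/`.yml`) or JSON (`.json`), one block per sub-model. Reading
#' re-runs the constructors, so validation is applied and the derived rates
#' (`kout`, `kdeg`) are repopulated; a write/read round trip is exact.
#'
#' @param params A `pkpd_params` object.
#' @param path File path; the extension selects the format.
#' @return `read_params` returns a `pkpd_params` object; `write_params` returns
#'   `path` invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "pkpd_params"))
  lst <- params_to_list(params)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(lst, path, precision = 15L)
  } else if (ext == "json") {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else stop("unsupported parameter file extension: ", ext)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("unsupported parameter file extension: ", ext)
  params_from_list(lst)
}
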