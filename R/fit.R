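#' Extended least-squares objective
#'
#' Sum over matched observation/prediction pairs of
#' (obs - pred)^2 / var + log(var), with var = add^2 + (prop x pred)^2 under
#' `weighting = "prediction"` (the reporting convention) or
#' var = add^2 + (prop x obs)^2 under `weighting = "observation"`, in which
#' case the log-variance term is constant in the parameters and the criterion
#' is a fixed-weight least squares (the form the stage fits minimise).
#'
#' @param obs,pred Numeric vectors of equal length.
#' @param spec A [residual_spec()].
#' @param weighting `"prediction"` or `"observation"`.
#' @return The scalar objective value.
#' @export
els_objective <- function(obs, pred, spec,
                          weighting = c("prediction", "observation")) {
  weighting <- match.arg(weighting)
  stopifnot(length(obs) == length(pred), inherits(spec, "residual_spec"))
  base <- if (weighting == "prediction") pred else obs
  v <- spec$add^2 + (spec$prop * base)^2
  if (any(v == 0)) stop("zero residual variance in objective")
  sum((obs - pred)^2 / v + log(v))
}

# observation-based residual SDs used as fixed weights in the stage fits
obs_sd <- function(obs, spec) {
  v <- spec$add^2 + (spec$prop * obs)^2
  if (any(v == 0)) stop("zero residual variance: cannot weight observations")
  sqrt(v)
}

lm_control <- function(maxiter = 400L) {
  minpack.lm::nls.lm.control(maxiter = maxiter, ftol = 1e-13, ptol = 1e-13)
}

# Multi-start Levenberg-Marquardt on log-transformed positive parameters.
# resid_fun(values) takes a named vector on the natural scale and returns the
# weighted residual vector. Starts are the init multiplied by independent
# U(1 - perturb, 1 + perturb) factors (seeded).
fit_engine <- function(resid_fun, init, n_starts, perturb, seed,
                       control = lm_control()) {
  stopifnot(all(init > 0), n_starts >= 1)
  free <- names(init)
  if (!is.null(seed)) set.seed(seed)
  starts <- lapply(seq_len(n_starts), function(s)
    log(init) + log(stats::runif(length(init), 1 - perturb, 1 + perturb)))
  fn <- function(theta) resid_fun(stats::setNames(exp(theta), free))
  best <- NULL
  tab <- data.frame(start = seq_len(n_starts), ssr = NA_real_,
                    info = NA_integer_, niter = NA_integer_)
  for (s in seq_len(n_starts)) {
    res <- tryCatch(minpack.lm::nls.lm(par = starts[[s]], fn = fn,
                                       control = control),
                    error = function(e) NULL)
    if (is.null(res)) next
    tab$ssr[s] <- res$deviance
    tab$info[s] <- res$info
    tab$niter[s] <- res$niter
    if (res$info %in% 1:4 &&
        (is.null(best) || res$deviance < best$deviance)) best <- res
  }
  if (is.null(best))
    return(list(converged = FALSE, estimates = init, ssr = NA_real_,
                niter = NA_integer_, info = NA_integer_, starts = tab))
  list(converged = TRUE, estimates = stats::setNames(exp(best$par), free),
       ssr = best$deviance, niter = best$niter, info = best$info,
       message = best$message, starts = tab)
}

new_pkpd_fit <- function(stage, engine_out, params, fixed, flags, obs_tab,
                         spec, init) {
  obj <- tryCatch(
    els_objective(obs_tab$obs, obs_tab$pred, spec, "prediction"),
    error = function(e) NA_real_)
  structure(list(stage = stage, estimates = engine_out$estimates,
                 params = params, fixed = fixed, flags = flags,
                 converged = engine_out$converged, ssr = engine_out$ssr,
                 objective = obj, niter = engine_out$niter,
                 info = engine_out$info, starts = engine_out$starts,
                 init = init, n_obs = nrow(obs_tab), residual = spec,
                 predictions = obs_tab),
            class = "pkpd_fit")
}

#' @export
print.pkpd_fit <- function(x, ...) {
  cat("Pooled", toupper(x$stage), "stage fit:", x$n_obs, "observations\n")
  est <- format(signif(x$estimates, 6))
  cat("  estimates:\n")
  for (nm in names(x$estimates)) cat(sprintf("    %-10s %s\n", nm, est[nm]))
  if (length(x$fixed)) {
    cat("  fixed:\n")
    for (nm in names(x$fixed))
      cat(sprintf("    %-10s %s\n", nm, format(signif(x$fixed[nm], 6))))
  }
  cat(sprintf("  weighted SSR %.6g | ELS objective %.6g | %s (%d iter)\n",
              x$ssr, x$objective,
              if (x$converged) "converged" else "NOT CONVERGED",
              if (is.na(x$niter)) 0L else x$niter))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.pkpd_fit <- function(object, ...) {
  print(object)
  cat("  multi-start SSRs:",
      paste(signif(object$starts$ssr, 6), collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.pkpd_fit <- function(object, ...) object$estimates

#' @export
residuals.pkpd_fit <- function(object, ...) object$predictions$wres

#' Fitted per-record predictions of a stage fit
#'
#' @param object A `pkpd_fit`.
#' @param ... Unused.
#' @return A data frame with columns `ID`, `TIME_H`, `obs`, `pred`, `wres`.
#' @export
predict.pkpd_fit <- function(object, ...) object$predictions

## ---- PK stage --------------------------------------------------------------

pk_free_all <- c("cl", "v", "v2", "v3", "q2", "q3", "ka", "ktr",
                 "ba50", "alpha_low")

get_pk_value <- function(params, nm) {
  if (nm %in% names(params$pk)) params$pk[[nm]] else params$ba[[nm]]
}

set_pk_values <- function(params, values) {
  for (nm in names(values)) {
    if (nm %in% names(params$pk)) params$pk[[nm]] <- values[[nm]]
    else params$ba[[nm]] <- values[[nm]]
  }
  params
}

#' Fit the PK stage by pooled weighted least squares
#'
#' Minimises the observation-weighted least-squares criterion (see
#' [els_objective()]) over the structural PK and bioavailability parameters,
#' pooling all quantifiable drug-concentration records. `bmax` is fixed by
#' default: oral data identify only dose-scaled quantities, so the maximal
#' relative bioavailability and the apparent clearances/volumes trade off as a
#' pure scale; anchoring `bmax` removes the flat likelihood direction. The
#' time-decay coefficient of the highest dose group is structurally fixed at
#' zero; if the dataset contains no cohort below the dose threshold,
#' `alpha_low` is unidentifiable and is automatically fixed and flagged.
#'
#' @param dataset A trial dataset (see [synthesize_trial()]).
#' @param init A [pkpd_params()] collection providing starting values and the
#'   fixed-parameter anchor (default: the published set).
#' @param fixed Names of parameters to hold at their `init` values (default
#'   `"bmax"`, the identifiability anchor).
#' @param include_blq Include below-LLOQ records (default drops them, M1).
#' @param n_starts Number of multi-start optimizer runs.
#' @param perturb Relative perturbation of each start (0.3 = +/-30%).
#' @param seed Seed for start generation.
#' @param residual Residual spec used for weighting (default `init$residual$pk`).
#' @return A `pkpd_fit` object; `$params` is `init` with the estimates applied.
#' @export
fit_pk <- function(dataset, init = published_params(), fixed = "bmax",
                   include_blq = FALSE, n_starts = 5L, perturb = 0.3,
                   seed = 1L, residual = init$residual$pk) {
  obs <- dataset[dataset$EVID == 0L & dataset$DVID == 1L & dataset$MDV == 0L &
                   !is.na(dataset$DV), , drop = FALSE]
  if (!include_blq) obs <- obs[obs$BLQ == 0L, , drop = FALSE]
  if (!nrow(obs)) stop("no quantifiable PK records in dataset")

  ids <- unique(obs$ID)
  regs <- lapply(ids, function(id) regimen_from_records(dataset, id))
  names(regs) <- ids
  keys <- vapply(regs, function(r)
    paste(r$time, r$dose, sep = ":", collapse = ","), "")
  obs$group <- keys[match(obs$ID, ids)]
  groups <- split(obs, obs$group)
  flags <- character()

  free <- setdiff(pk_free_all, fixed)
  all_doses <- unlist(lapply(regs, function(r) r$dose))
  if ("alpha_low" %in% free && all(all_doses >= init$ba$dose_threshold)) {
    free <- setdiff(free, "alpha_low")
    flags <- c(flags, "alpha_low not identifiable (no cohort below the dose threshold); fixed at init")
  }
  init_vals <- vapply(free, function(nm) get_pk_value(init, nm), 0)
  if (any(init_vals <= 0))
    stop_invalid("initial values of free parameters must be > 0")

  grp_info <- lapply(groups, function(g) {
    reg <- regs[[as.character(g$ID[1L])]]
    ut <- sort(unique(g$TIME_H))
    list(reg = reg, ut = ut, idx = match(round(g$TIME_H, 9), round(ut, 9)),
         obs = g$DV, w = obs_sd(g$DV, residual))
  })
  dt <- common_dt(unlist(lapply(grp_info, function(gi) c(gi$ut, gi$reg$time))))

  resid_fun <- function(values, detail = FALSE) {
    p <- set_pk_values(init, values)
    out <- lapply(grp_info, function(gi) {
      ev <- build_dose_events(gi$reg, p$ba)
      pred <- if (!is.null(dt)) pk_conc_grid(p$pk, ev, gi$ut, dt)
              else simulate_pk(p$pk, p$ba, gi$reg, gi$ut)$conc_ng_ml
      pred <- pred[gi$idx]
      cbind(obs = gi$obs, pred = pred, wres = (gi$obs - pred) / gi$w)
    })
    m <- do.call(rbind, out)
    if (detail) m else m[, "wres"]
  }

  eo <- fit_engine(resid_fun, init_vals, n_starts, perturb, seed)
  det <- resid_fun(eo$estimates, detail = TRUE)
  obs_tab <- data.frame(ID = unlist(lapply(groups, `[[`, "ID")),
                        TIME_H = unlist(lapply(groups, `[[`, "TIME_H")),
                        obs = det[, "obs"], pred = det[, "pred"],
                        wres = det[, "wres"], row.names = NULL)
  fixed_vals <- vapply(setdiff(pk_free_all, free), function(nm)
    get_pk_value(init, nm), 0)
  fixed_vals <- c(fixed_vals, bmax = if (!"bmax" %in% free) init$ba$bmax)
  fixed_vals <- fixed_vals[!duplicated(names(fixed_vals))]
  new_pkpd_fit("pk", eo, set_pk_values(init, eo$estimates),
               fixed_vals, flags, obs_tab, residual, init_vals)
}

## ---- CETP stage ------------------------------------------------------------

cetp_free_all <- c("cetp_base", "kin_base", "kmax", "k50", "emax", "ec50")

# per-subject concentration functions from fixed individual PK parameters
subject_cp_funs <- function(dataset, ids, individual_params, dt = 0.25) {
  t_end <- max(dataset$TIME_H)
  lapply(ids, function(id) {
    reg <- regimen_from_records(dataset, id)
    p <- individual_params[[id]]
    if (is.null(reg) || nrow(reg) == 0L)
      return(function(t) rep(0, length(t)))
    ev <- build_dose_events(reg, p$ba)
    pk_conc_fun(p$pk, ev, t_end, dt)
  })
}

subject_group_key <- function(dataset, id, params) {
  reg <- regimen_from_records(dataset, id)
  paste(c(if (!is.null(reg)) paste(reg$time, reg$dose),
          format(unlist(params[c("pk", "ba", "cetp")]), digits = 15)),
        collapse = "|")
}

#' Fit the CETP stage with individual PK fixed
#'
#' Sequential second stage: with each subject's PK parameters fixed (the
#' generating or previously estimated individual values), minimises the pooled
#' observation-weighted least-squares criterion over the CETP turnover
#' parameters. The loss rate `kout` is tied to `kin_base / cetp_base`
#' throughout (baseline stationarity). Placebo-arm records inform the placebo
#' time-effect sub-model. If the dataset contains no drug exposure at all, the
#' drug-effect parameters are unidentifiable and are fixed and flagged.
#'
#' @param dataset A trial dataset containing CETP records (DVID = 2).
#' @param individual_pk List of per-subject [pkpd_params()] collections,
#'   indexed by subject ID (default: the generating sets attached to the
#'   dataset).
#' @param init,fixed,n_starts,perturb,seed,residual As in [fit_pk()];
#'   `residual` defaults to `init$residual$cetp`.
#' @param dt Grid step (h) of the precomputed individual concentration curves.
#' @return A `pkpd_fit` object.
#' @export
fit_cetp <- function(dataset, individual_pk = attr(dataset, "individual_params"),
                     init = published_params(), fixed = character(),
                     n_starts = 5L, perturb = 0.3, seed = 1L,
                     residual = init$residual$cetp, dt = 0.25) {
  if (is.null(individual_pk)) stop("individual_pk is required (PK stage first)")
  obs <- dataset[dataset$EVID == 0L & dataset$DVID == 2L & dataset$MDV == 0L &
                   !is.na(dataset$DV), , drop = FALSE]
  if (!nrow(obs)) stop("no CETP records in dataset")

  ids <- sort(unique(obs$ID))
  cp_funs <- subject_cp_funs(dataset, ids, individual_pk, dt)
  names(cp_funs) <- ids
  keys <- vapply(ids, function(id)
    subject_group_key(dataset, id, individual_pk[[id]]), "")
  obs$group <- keys[match(obs$ID, ids)]
  groups <- split(obs, obs$group)
  flags <- character()

  free <- setdiff(cetp_free_all, fixed)
  has_drug <- any(vapply(ids, function(id)
    !is.null(regimen_from_records(dataset, id)), TRUE))
  if (!has_drug && any(c("emax", "ec50") %in% free)) {
    free <- setdiff(free, c("emax", "ec50"))
    flags <- c(flags, "emax/ec50 not identifiable (no drug exposure); fixed at init")
  }
  init_vals <- vapply(free, function(nm) init$cetp[[nm]], 0)
  if (any(init_vals <= 0))
    stop_invalid("initial values of free parameters must be > 0 (fix parameters at 0 instead)")

  grp_info <- lapply(groups, function(g) {
    ut <- sort(unique(g$TIME_H))
    list(cp = cp_funs[[as.character(g$ID[1L])]], ut = ut,
         idx = match(round(g$TIME_H, 9), round(ut, 9)),
         obs = g$DV, w = obs_sd(g$DV, residual))
  })

  base <- init$cetp
  resid_fun <- function(values, detail = FALSE) {
    for (nm in names(values)) base[[nm]] <- values[[nm]]
    ce <- cetp_params(base$cetp_base, base$kin_base, base$kmax, base$k50,
                      base$emax, base$ec50)
    out <- lapply(grp_info, function(gi) {
      pred <- cetp_traj_fast(ce, gi$cp, gi$ut, dt)$X[gi$idx]
      cbind(obs = gi$obs, pred = pred, wres = (gi$obs - pred) / gi$w)
    })
    m <- do.call(rbind, out)
    if (detail) m else m[, "wres"]
  }

  eo <- fit_engine(resid_fun, init_vals, n_starts, perturb, seed)
  det <- resid_fun(eo$estimates, detail = TRUE)
  obs_tab <- data.frame(ID = unlist(lapply(groups, `[[`, "ID")),
                        TIME_H = unlist(lapply(groups, `[[`, "TIME_H")),
                        obs = det[, "obs"], pred = det[, "pred"],
                        wres = det[, "wres"], row.names = NULL)
  upd <- init
  for (nm in names(eo$estimates)) upd$cetp[[nm]] <- eo$estimates[[nm]]
  upd$cetp$kout <- derive_kout(upd$cetp$kin_base, upd$cetp$cetp_base)
  fixed_vals <- vapply(setdiff(cetp_free_all, free),
                       function(nm) init$cetp[[nm]], 0)
  new_pkpd_fit("cetp", eo, upd, fixed_vals, flags, obs_tab, residual, init_vals)
}

## ---- lipid stages ----------------------------------------------------------

lipid_free_all <- function(endpoint)
  c("rb", "ksyn", "rmax", "r50", "gamma", if (endpoint == "ldl") "beta")

# per-subject CETP activity functions from fixed individual PK + CETP params
subject_R_funs <- function(dataset, ids, individual_params, dt = 0.25) {
  cp_funs <- subject_cp_funs(dataset, ids, individual_params, dt)
  t_end <- max(dataset$TIME_H)
  out <- lapply(seq_along(ids), function(j)
    cetp_traj_fast(individual_params[[ids[j]]]$cetp, cp_funs[[j]],
                   t_end, dt)$fun)
  names(out) <- ids
  out
}

#' Fit an HDL-C or LDL-C stage with individual CETP parameters fixed
#'
#' Sequential third stage: with each subject's PK and CETP parameters fixed,
#' minimises the pooled observation-weighted least-squares criterion over the
#' lipid turnover parameters (baseline, production, sigmoid Emax triple, plus
#' the placebo slope `beta` for LDL-C). The loss rate `kdeg` is tied by
#' baseline stationarity at the subject's baseline CETP activity throughout.
#'
#' @param dataset A trial dataset containing lipid records (DVID 3 or 4).
#' @param individual_cetp List of per-subject [pkpd_params()] collections
#'   (PK + CETP components are used), indexed by subject ID.
#' @param endpoint `"hdl"` or `"ldl"`.
#' @param init,fixed,n_starts,perturb,seed,residual As in [fit_pk()];
#'   `residual` defaults to the endpoint's spec in `init$residual`.
#' @param dt Grid step (h) of the precomputed CETP activity curves.
#' @return A `pkpd_fit` object.
#' @export
fit_lipid <- function(dataset,
                      individual_cetp = attr(dataset, "individual_params"),
                      endpoint = c("hdl", "ldl"),
                      init = published_params(), fixed = character(),
                      n_starts = 5L, perturb = 0.3, seed = 1L,
                      residual = init$residual[[endpoint]], dt = 0.25) {
  endpoint <- match.arg(endpoint)
  if (is.null(individual_cetp))
    stop("individual_cetp is required (CETP stage first)")
  dvid <- if (endpoint == "hdl") 3L else 4L
  obs <- dataset[dataset$EVID == 0L & dataset$DVID == dvid &
                   dataset$MDV == 0L & !is.na(dataset$DV), , drop = FALSE]
  if (!nrow(obs)) stop("no ", endpoint, " records in dataset")

  ids <- sort(unique(obs$ID))
  R_funs <- subject_R_funs(dataset, ids, individual_cetp, dt)
  keys <- vapply(ids, function(id)
    subject_group_key(dataset, id, individual_cetp[[id]]), "")
  obs$group <- keys[match(obs$ID, ids)]
  groups <- split(obs, obs$group)

  free <- setdiff(lipid_free_all(endpoint), fixed)
  init_vals <- vapply(free, function(nm) init[[endpoint]][[nm]], 0)
  if (any(init_vals <= 0))
    stop_invalid("initial values of free parameters must be > 0 (fix parameters at 0 instead)")

  grp_info <- lapply(groups, function(g) {
    id <- as.character(g$ID[1L])
    ut <- sort(unique(g$TIME_H))
    list(R = R_funs[[id]],
         ref = individual_cetp[[g$ID[1L]]]$cetp$cetp_base, ut = ut,
         idx = match(round(g$TIME_H, 9), round(ut, 9)),
         obs = g$DV, w = obs_sd(g$DV, residual))
  })

  base <- init[[endpoint]]
  direction <- base$direction
  resid_fun <- function(values, detail = FALSE) {
    for (nm in names(values)) base[[nm]] <- values[[nm]]
    out <- lapply(grp_info, function(gi) {
      lp <- lipid_params(base$rb, base$ksyn, base$rmax, base$r50, base$gamma,
                         base$beta, direction, reference_cetp = gi$ref)
      pred <- lipid_traj_fast(lp, gi$R, gi$ut, dt)[gi$idx]
      cbind(obs = gi$obs, pred = pred, wres = (gi$obs - pred) / gi$w)
    })
    m <- do.call(rbind, out)
    if (detail) m else m[, "wres"]
  }

  eo <- fit_engine(resid_fun, init_vals, n_starts, perturb, seed)
  det <- resid_fun(eo$estimates, detail = TRUE)
  obs_tab <- data.frame(ID = unlist(lapply(groups, `[[`, "ID")),
                        TIME_H = unlist(lapply(groups, `[[`, "TIME_H")),
                        obs = det[, "obs"], pred = det[, "pred"],
                        wres = det[, "wres"], row.names = NULL)
  upd <- init
  for (nm in names(eo$estimates)) upd[[endpoint]][[nm]] <- eo$estimates[[nm]]
  upd[[endpoint]]$kdeg <- derive_kdeg(upd[[endpoint]],
                                      upd[[endpoint]]$reference_cetp)
  fixed_vals <- vapply(setdiff(lipid_free_all(endpoint), free),
                       function(nm) init[[endpoint]][[nm]], 0)
  new_pkpd_fit(endpoint, eo, upd, fixed_vals, character(), obs_tab,
               residual, init_vals)
}
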