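#' Default phase-I multiple-ascending-dose study design
#'
#' Four dose cohorts (50/100/200/400 mg once daily for 14 days), six active and
#' two placebo subjects per cohort. All four endpoints (drug concentration,
#' CETP activity, HDL-C, LDL-C) are sampled richly on day 1
#' (0,1,2,3,4,5,6,7,8,10,12,18,24 h) and day 14 (the same 13 offsets plus
#' 32,48,72,96,120,144,168 h after the day-14 dose), with daily pre-dose
#' troughs on days 2-13. The last sample falls 480 h after the first dose.
#'
#' @param cohorts Data frame with columns `dose`, `n_active`, `n_placebo`.
#' @param n_days Number of once-daily doses.
#' @param interval Dosing interval (h).
#' @param day1_times,day14_times Sampling offsets (h) relative to the day-1 and
#'   day-14 doses.
#' @param trough_days Days (2-based) on which a pre-dose trough is drawn.
#' @param endpoints Endpoint codes sampled (1 = PK ng/mL, 2 = CETP pmole,
#'   3 = HDL-C mg/dL, 4 = LDL-C mg/dL).
#' @return An object of class `study_design`.
#' @export
default_design <- function(cohorts = data.frame(dose = c(50, 100, 200, 400),
                                                n_active = 6L, n_placebo = 2L),
                           n_days = 14L, interval = 24,
                           day1_times = c(0, 1, 2, 3, 4, 5, 6, 7, 8, 10, 12, 18, 24),
                           day14_times = c(0, 1, 2, 3, 4, 5, 6, 7, 8, 10, 12, 18,
                                           24, 32, 48, 72, 96, 120, 144, 168),
                           trough_days = 2:13,
                           endpoints = 1:4) {
  stopifnot(all(c("dose", "n_active", "n_placebo") %in% names(cohorts)),
            all(cohorts$n_active >= 0), all(cohorts$n_placebo >= 0),
            all(day1_times >= 0), all(day14_times >= 0),
            all(trough_days >= 2), n_days >= 1)
  structure(list(cohorts = cohorts, n_days = as.integer(n_days),
                 interval = interval, day1_times = day1_times,
                 day14_times = day14_times, trough_days = trough_days,
                 endpoints = endpoints),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", sum(x$cohorts$n_active + x$cohorts$n_placebo),
      "subjects in", nrow(x$cohorts), "cohorts\n")
  cat("  doses (mg):", paste(x$cohorts$dose, collapse = ", "),
      " QD x", x$n_days, "days\n")
  cat("  samples/subject/endpoint:", length(design_times(x)), "\n")
  invisible(x)
}

#' Scheduled observation times of a design
#'
#' Day-1 offsets, daily pre-dose troughs, and day-14 offsets (relative to the
#' day-14 dose), on the absolute clock of hours since the first dose. Nominal
#' times that coincide (the day-1 24 h sample and the day-2 trough) are kept
#' as separate scheduled records.
#'
#' @param design A [default_design()] object.
#' @return Numeric vector of scheduled times (h), sorted, possibly with
#'   duplicated nominal times.
#' @export
design_times <- function(design) {
  last_dose <- (design$n_days - 1L) * design$interval
  sort(c(design$day1_times,
         (design$trough_days - 1L) * design$interval,
         last_dose + design$day14_times))
}

#' Draw individual parameter sets under log-normal IIV
#'
#' parameter_i = population value x exp(eta_i), eta_i ~ N(0, (CV/100)^2),
#' independent across parameters and subjects. Derived rates are recomputed
#' per individual (kout from that individual's kin_base and cetp_base, kdeg
#' from that individual's lipid baselines) so every subject starts at steady
#' state.
#'
#' @param params Population [pkpd_params()] collection.
#' @param n Number of subjects.
#' @param iiv An [iiv_spec()]; defaults to the one inside `params`.
#' @param seed Optional integer seed; if `NULL` the current RNG state is used.
#' @return A list of `n` individual `pkpd_params` objects.
#' @export
sample_individual_params <- function(params, n, iiv = params$iiv, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i) perturb_params(params, iiv))
}

perturb_params <- function(params, iiv) {
  p <- params
  draw <- function(value, cv) value * exp(stats::rnorm(1L, 0, cv / 100))
  for (nm in names(iiv$pk)) {
    if (iiv$pk[[nm]] == 0) next
    if (nm == "bmax") p$ba$bmax <- draw(p$ba$bmax, iiv$pk[[nm]])
    else p$pk[[nm]] <- draw(p$pk[[nm]], iiv$pk[[nm]])
  }
  for (nm in names(iiv$cetp))
    if (iiv$cetp[[nm]] > 0) p$cetp[[nm]] <- draw(p$cetp[[nm]], iiv$cetp[[nm]])
  p$cetp$kout <- derive_kout(p$cetp$kin_base, p$cetp$cetp_base)
  for (nm in names(iiv$hdl))
    if (iiv$hdl[[nm]] > 0) p$hdl[[nm]] <- draw(p$hdl[[nm]], iiv$hdl[[nm]])
  p$hdl$kdeg <- derive_kdeg(p$hdl, p$hdl$reference_cetp)
  for (nm in names(iiv$ldl))
    if (iiv$ldl[[nm]] > 0) p$ldl[[nm]] <- draw(p$ldl[[nm]], iiv$ldl[[nm]])
  p$ldl$kdeg <- derive_kdeg(p$ldl, p$ldl$reference_cetp)
  p
}

#' Apply combined residual error to model predictions
#'
#' obs = pred (1 + eps_p) + eps_a, eps_p ~ N(0, prop^2), eps_a ~ N(0, add^2).
#' Draws that land below zero are truncated to 0 with a warning reporting the
#' count (relevant for near-zero predictions with a large additive SD).
#'
#' @param prediction Non-negative predicted values; vectorized.
#' @param spec A [residual_spec()].
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return Simulated observations, same length as `prediction`.
#' @export
apply_residual_error <- function(prediction, spec, seed = NULL) {
  stopifnot(inherits(spec, "residual_spec"), all(prediction >= 0))
  if (!is.null(seed)) set.seed(seed)
  m <- length(prediction)
  obs <- prediction * (1 + stats::rnorm(m, 0, spec$prop)) +
    stats::rnorm(m, 0, spec$add)
  neg <- obs < 0
  if (any(neg)) {
    warning(sum(neg), " simulated observation(s) below zero truncated to 0")
    obs[neg] <- 0
  }
  obs
}

#' Generate a synthetic trial dataset
#'
#' For each subject: draw individual parameters (unless `iiv = FALSE`),
#' simulate the coupled PK-CETP-HDL-LDL system under the cohort regimen,
#' evaluate at the scheduled times, apply endpoint-specific residual error
#' (unless `noise = FALSE`) and emit long-format records. Placebo subjects
#' receive no dose records and their drug-concentration observations are
#' flagged missing (`MDV = 1`, `DV = NA`). Drug-concentration observations
#' below `lloq` are flagged `BLQ = 1` (excluded from fitting by default).
#'
#' @param design A [default_design()] object.
#' @param params Population truth [pkpd_params()] (must include `residual`
#'   when `noise = TRUE`).
#' @param iiv Logical: draw inter-individual variability?
#' @param noise Logical: apply residual error?
#' @param seed Optional integer seed (byte-identical datasets under a fixed
#'   seed).
#' @param lloq Lower limit of quantification for drug concentration (ng/mL).
#' @param engine Simulation engine, see [simulate_subject()].
#' @param rtol,atol Coupled-engine solver tolerances; tighter than the
#'   simulator defaults so that noise-free observations pin the fitting
#'   forward model to ~1e-10 relative.
#' @return A data frame with columns `ID`, `ARM`, `COHORT_MG`, `TIME_H`,
#'   `EVID` (1 dose / 0 observation), `AMT_MG`, `DV`, `DVID` (1 PK, 2 CETP,
#'   3 HDL-C, 4 LDL-C), `MDV`, `BLQ`, sorted by (ID, TIME_H, dose before
#'   observation at ties). The generating individual parameter sets are
#'   attached as `attr(, "individual_params")` and the design as
#'   `attr(, "design")`.
#' @export
synthesize_trial <- function(design, params, iiv = TRUE, noise = TRUE,
                             seed = NULL, lloq = 1.0,
                             engine = c("coupled", "staged"),
                             rtol = 1e-10, atol = 1e-12) {
  engine <- match.arg(engine)
  stopifnot(inherits(design, "study_design"), inherits(params, "pkpd_params"))
  if (noise && is.null(params$residual))
    stop("params$residual is required when noise = TRUE")
  if (!is.null(seed)) set.seed(seed)

  subj <- do.call(rbind, lapply(seq_len(nrow(design$cohorts)), function(k) {
    co <- design$cohorts[k, ]
    data.frame(cohort = co$dose,
               arm = rep(c("active", "placebo"),
                         c(co$n_active, co$n_placebo)))
  }))
  subj$id <- seq_len(nrow(subj))
  n <- nrow(subj)

  inds <- if (iiv) sample_individual_params(params, n)
          else rep(list(params), n)

  sched <- design_times(design)
  utimes <- sort(unique(sched))
  ep_names <- c("conc_ng_ml", "cetp_pmole", "hdl_mg_dl", "ldl_mg_dl")

  recs <- vector("list", n)
  n_trunc <- 0L
  sim_cache <- new.env(parent = emptyenv())  # IIV-free subjects repeat per arm/cohort
  for (i in seq_len(n)) {
    active <- subj$arm[i] == "active"
    regimen <- if (active)
      regimen_qd(subj$cohort[i], design$n_days, design$interval) else NULL
    key <- paste(subj$arm[i], if (active) subj$cohort[i] else 0)
    sim <- if (!iiv && !is.null(sim_cache[[key]])) sim_cache[[key]]
    else tryCatch(
      simulate_subject(inds[[i]], regimen, utimes, engine = engine,
                       rtol = rtol, atol = atol),
      error = function(e) stop("simulation failed for subject ", subj$id[i],
                               ": ", conditionMessage(e)))
    if (!iiv) sim_cache[[key]] <- sim
    dose_rec <- if (active)
      data.frame(ID = subj$id[i], ARM = "active", COHORT_MG = subj$cohort[i],
                 TIME_H = regimen$time, EVID = 1L, AMT_MG = regimen$dose,
                 DV = NA_real_, DVID = NA_integer_, MDV = 1L, BLQ = 0L)
    obs_rec <- do.call(rbind, lapply(design$endpoints, function(ep) {
      pred <- sim[[ep_names[ep]]][match(round(sched, 9), round(utimes, 9))]
      missing_pk <- ep == 1L && !active
      dv <- if (missing_pk) rep(NA_real_, length(pred))
            else if (noise) {
              spec <- params$residual[[c("pk", "cetp", "hdl", "ldl")[ep]]]
              o <- pred * (1 + stats::rnorm(length(pred), 0, spec$prop)) +
                stats::rnorm(length(pred), 0, spec$add)
              neg <- o < 0
              if (any(neg)) { n_trunc <<- n_trunc + sum(neg); o[neg] <- 0 }
              o
            } else pred
      data.frame(ID = subj$id[i], ARM = subj$arm[i],
                 COHORT_MG = subj$cohort[i], TIME_H = sched, EVID = 0L,
                 AMT_MG = NA_real_, DV = dv, DVID = ep,
                 MDV = as.integer(missing_pk),
                 BLQ = as.integer(ep == 1L & !missing_pk & dv < lloq))
    }))
    recs[[i]] <- rbind(dose_rec, obs_rec)
  }
  if (n_trunc > 0)
    warning(n_trunc, " simulated observation(s) below zero truncated to 0")
  ds <- do.call(rbind, recs)
  ds <- ds[order(ds$ID, ds$TIME_H, -ds$EVID), ]
  rownames(ds) <- NULL
  attr(ds, "individual_params") <- inds
  attr(ds, "design") <- design
  ds
}

dataset_columns <- c("ID", "ARM", "COHORT_MG", "TIME_H", "EVID", "AMT_MG",
                     "DV", "DVID", "MDV", "BLQ")

#' Write / read a trial dataset as CSV
#'
#' Numeric columns are written with 17 significant digits so that a write/read
#' round trip reproduces the dataset exactly. `read_dataset` validates the
#' column layout and the event/endpoint codes and reports the offending data
#' line on failure.
#'
#' @param ds A dataset from [synthesize_trial()] (attributes are not written).
#' @param path CSV file path.
#' @return `read_dataset` returns the dataset data frame; `write_dataset`
#'   returns `path` invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(all(dataset_columns %in% names(ds)))
  out <- ds[, dataset_columns]
  for (nm in c("COHORT_MG", "TIME_H", "AMT_MG", "DV"))
    out[[nm]] <- ifelse(is.na(out[[nm]]), "", sprintf("%.17g", out[[nm]]))
  for (nm in c("ID", "EVID", "DVID", "MDV", "BLQ"))
    out[[nm]] <- ifelse(is.na(out[[nm]]), "", format(out[[nm]]))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  ds <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(ID = "integer", ARM = "character",
                                       COHORT_MG = "numeric", TIME_H = "numeric",
                                       EVID = "integer", AMT_MG = "numeric",
                                       DV = "numeric", DVID = "integer",
                                       MDV = "integer", BLQ = "integer"))
  if (!identical(names(ds), dataset_columns))
    stop("malformed dataset file: expected columns ",
         paste(dataset_columns, collapse = ", "))
  bad <- which(!(ds$DVID %in% c(NA, 1:4)))
  if (length(bad))
    stop("unknown endpoint code at data line ", bad[1L], ": DVID = ",
         ds$DVID[bad[1L]])
  bad <- which(!(ds$EVID %in% c(0L, 1L)))
  if (length(bad))
    stop("unknown event code at data line ", bad[1L], ": EVID = ",
         ds$EVID[bad[1L]])
  if (any(ds$EVID == 0L & !is.na(ds$DV) & ds$DV < 0))
    stop("negative observation value in dataset")
  ds
}

# regimen of one subject reconstructed from their dose records
regimen_from_records <- function(ds, id) {
  d <- ds[ds$ID == id & ds$EVID == 1L, , drop = FALSE]
  if (!nrow(d)) return(NULL)
  data.frame(time = d$TIME_H, dose = d$AMT_MG)
}
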