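stage_fit_fun <- function(stage) {
  switch(stage,
         pk = function(dataset, individual_params = NULL, ...)
           fit_pk(dataset, ...),
         cetp = function(dataset, individual_params = NULL, ...)
           fit_cetp(dataset, individual_pk = individual_params, ...),
         hdl = function(dataset, individual_params = NULL, ...)
           fit_lipid(dataset, individual_cetp = individual_params,
                     endpoint = "hdl", ...),
         ldl = function(dataset, individual_params = NULL, ...)
           fit_lipid(dataset, individual_cetp = individual_params,
                     endpoint = "ldl", ...))
}

stage_dvid <- c(pk = 1L, cetp = 2L, hdl = 3L, ldl = 4L)

#' Two-stage (per-subject) estimates and variability summaries
#'
#' Fits the variability-carrying parameters of one model stage independently
#' for every subject, holding all other parameters at the pooled values, and
#' summarises the between-subject spread as CV% (SD of the log individual
#' estimates x 100), comparable to the reported omega magnitudes. This is the
#' package's stand-in for the empirical-Bayes individual estimates of a
#' nonlinear mixed-effects fit.
#'
#' @param dataset A trial dataset.
#' @param stage `"pk"`, `"cetp"`, `"hdl"` or `"ldl"`.
#' @param params Pooled parameter collection (point estimates or truth).
#' @param iiv_names Parameters fitted per subject; defaults to the stage's
#'   variability-carrying set.
#' @param min_records Minimum usable records per subject; subjects below it
#'   are skipped with a warning.
#' @param individual_params Upstream per-subject parameter sets (needed for
#'   the cetp/hdl/ldl stages).
#' @param ... Further arguments to the stage fit.
#' @return A list of class `two_stage_summary`: per-subject estimates, CV%
#'   per parameter (`NA` with a flag when fewer than two subjects were fit),
#'   and skipped subject IDs.
#' @export
two_stage <- function(dataset, stage = c("pk", "cetp", "hdl", "ldl"),
                      params = published_params(), iiv_names = NULL,
                      min_records = 4L,
                      individual_params = attr(dataset, "individual_params"),
                      ...) {
  stage <- match.arg(stage)
  if (is.null(iiv_names))
    iiv_names <- switch(stage, pk = c("cl", "v3", "bmax", "ktr"),
                        cetp = c("kin_base", "emax"), hdl = "rb",
                        ldl = c("rb", "beta", "gamma"))
  all_free <- switch(stage, pk = c(pk_free_all, "bmax"), cetp = cetp_free_all,
                     hdl = lipid_free_all("hdl"), ldl = lipid_free_all("ldl"))
  fixed <- setdiff(all_free, iiv_names)
  fitter <- stage_fit_fun(stage)
  dvid <- stage_dvid[[stage]]

  usable <- dataset$EVID == 0L & dataset$DVID == dvid & dataset$MDV == 0L &
    !is.na(dataset$DV) & (dvid != 1L | dataset$BLQ == 0L)
  counts <- table(dataset$ID[usable])
  ids <- as.integer(names(counts))
  skipped <- ids[counts < min_records]
  if (stage == "pk") {  # placebo subjects carry no quantifiable PK records
    has_dose <- unique(dataset$ID[dataset$EVID == 1L])
    skipped <- union(skipped, setdiff(ids, has_dose))
  }
  fit_ids <- setdiff(ids[counts >= min_records], skipped)
  if (length(skipped))
    warning("skipping subject(s) with too few usable records: ",
            paste(skipped, collapse = ", "))

  est <- lapply(fit_ids, function(id) {
    sub <- dataset[dataset$ID == id, , drop = FALSE]
    f <- fitter(sub, individual_params = individual_params, init = params,
                fixed = fixed, n_starts = 1L, perturb = 0, ...)
    coef(f)[intersect(iiv_names, names(coef(f)))]
  })
  est_mat <- do.call(rbind, est)
  cv <- if (length(fit_ids) >= 2L)
    apply(est_mat, 2L, function(x) stats::sd(log(x)) * 100)
  else stats::setNames(rep(NA_real_, ncol(est_mat) %||% 0L),
                       colnames(est_mat))
  structure(list(stage = stage,
                 estimates = data.frame(ID = fit_ids, est_mat,
                                        row.names = NULL),
                 cv = cv, n_fit = length(fit_ids), skipped = skipped,
                 flag = if (length(fit_ids) < 2L)
                   "fewer than two subjects: CV% undefined"),
            class = "two_stage_summary")
}

#' @export
print.two_stage_summary <- function(x, ...) {
  cat("Two-stage", toupper(x$stage), "summary over", x$n_fit, "subjects\n")
  cat("  CV% (SD of log estimates x 100):\n")
  for (nm in names(x$cv))
    cat(sprintf("    %-10s %s\n", nm, format(signif(x$cv[nm], 4))))
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Nonparametric bootstrap of a stage fit
#'
#' Resamples subjects with replacement, stratified by dose cohort (preserving
#' the per-cohort subject count), refits the stage per replicate starting from
#' the point estimates, and reports 2.5/50/97.5 percentile intervals of the
#' estimated parameters. Replicates whose fit fails are excluded and counted.
#'
#' @param dataset A trial dataset.
#' @param stage `"pk"`, `"cetp"`, `"hdl"` or `"ldl"`.
#' @param n_resamples Number of bootstrap replicates (>= 1).
#' @param seed Seed for the resampling.
#' @param individual_params Upstream per-subject parameter sets (sequential
#'   stages); resampled alongside the subjects.
#' @param resamples Optional list of ID vectors overriding the random
#'   resampling (one vector per replicate).
#' @param ... Further arguments to the stage fit (applied to the point fit;
#'   replicates always use a single unperturbed start from the point
#'   estimates).
#' @return A list of class `pkpd_bootstrap` with the point fit, the replicate
#'   estimates, the percentile table, and the ID draws used per replicate.
#' @export
bootstrap <- function(dataset, stage = c("pk", "cetp", "hdl", "ldl"),
                      n_resamples = 100L, seed = 1L,
                      individual_params = attr(dataset, "individual_params"),
                      resamples = NULL, ...) {
  stage <- match.arg(stage)
  stopifnot(n_resamples >= 1L)
  fitter <- stage_fit_fun(stage)
  point <- fitter(dataset, individual_params = individual_params, ...)

  subj <- unique(dataset[, c("ID", "COHORT_MG")])
  strata <- split(subj$ID, subj$COHORT_MG)
  set.seed(seed)
  draw_ids <- function() unlist(lapply(strata, function(ids)
    sample(ids, length(ids), replace = TRUE)), use.names = FALSE)
  if (is.null(resamples))
    resamples <- replicate(n_resamples, draw_ids(), simplify = FALSE)

  reps <- lapply(resamples, function(ids) {
    slices <- lapply(seq_along(ids), function(j) {
      s <- dataset[dataset$ID == ids[j], , drop = FALSE]
      s$ID <- j
      s
    })
    ds_r <- do.call(rbind, slices)
    rownames(ds_r) <- NULL
    ind_r <- if (!is.null(individual_params)) individual_params[ids]
    tryCatch(
      coef(fitter(ds_r, individual_params = ind_r, init = point$params,
                  n_starts = 1L, perturb = 0)),
      error = function(e) NULL)
  })
  ok <- !vapply(reps, is.null, TRUE)
  est <- do.call(rbind, reps[ok])
  qs <- apply(est, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975))
  structure(list(stage = stage, point = point, estimates = est,
                 quantiles = qs, resamples = resamples,
                 n_resamples = length(resamples), n_failed = sum(!ok)),
            class = "pkpd_bootstrap")
}

#' @export
print.pkpd_bootstrap <- function(x, ...) {
  cat("Bootstrap of the", toupper(x$stage), "stage:",
      x$n_resamples, "resamples,", x$n_failed, "failed\n")
  tab <- rbind(point = coef(x$point)[colnames(x$quantiles)], x$quantiles)
  print(signif(tab, 5))
  invisible(x)
}

#' Visual predictive check
#'
#' Simulates replicate trials under the dataset's own design (each subject's
#' regimen and sampling times) with inter-individual variability and residual
#' error drawn from `params`, and summarises the 5th/50th/95th percentiles of
#' the simulated observations per nominal sampling time, next to the observed
#' percentiles. Binning is by nominal (design) time.
#'
#' @param dataset A trial dataset.
#' @param params Parameter collection used for simulation (with `iiv` and
#'   `residual`).
#' @param n_sim Number of simulated replicate trials (>= 100).
#' @param seed Seed for the simulations.
#' @param endpoint Endpoint code (1 PK, 2 CETP, 3 HDL-C, 4 LDL-C).
#' @param iiv,noise Logical switches for variability components (both `TRUE`
#'   for a standard VPC; both `FALSE` collapses all bands onto the model
#'   prediction).
#' @param dt Simulation grid step (h).
#' @return A list of class `vpc_bands`: per-bin simulated and observed
#'   percentiles, and per-record band membership.
#' @export
vpc <- function(dataset, params, n_sim = 200L, seed = 1L, endpoint = 2L,
                iiv = TRUE, noise = TRUE, dt = 0.5) {
  if (n_sim < 100L) stop("n_sim must be at least 100")
  obs <- dataset[dataset$EVID == 0L & dataset$DVID == endpoint &
                   dataset$MDV == 0L & !is.na(dataset$DV), , drop = FALSE]
  if (!nrow(obs)) stop("no observed records for endpoint ", endpoint)
  spec <- params$residual[[c("pk", "cetp", "hdl", "ldl")[endpoint]]]

  ids <- sort(unique(obs$ID))
  subj <- lapply(ids, function(id) {
    times <- obs$TIME_H[obs$ID == id]
    ut <- sort(unique(times))
    list(reg = regimen_from_records(dataset, id), times = times,
         ut = ut, idx = match(round(times, 9), round(ut, 9)))
  })

  set.seed(seed)
  sims <- matrix(NA_real_, nrow(obs), n_sim)
  row0 <- cumsum(c(0, vapply(subj, function(s) length(s$times), 0L)))
  for (s in seq_len(n_sim)) {
    for (j in seq_along(ids)) {
      p <- if (iiv) perturb_params(params, params$iiv) else params
      sb <- subj[[j]]
      tr <- endpoint_traj(p, sb$reg, sb$ut, endpoint, dt)[sb$idx]
      if (noise) {
        tr <- tr * (1 + stats::rnorm(length(tr), 0, spec$prop)) +
          stats::rnorm(length(tr), 0, spec$add)
        tr[tr < 0] <- 0
      }
      sims[(row0[j] + 1L):row0[j + 1L], s] <- tr
    }
  }
  obs_long <- do.call(rbind, lapply(seq_along(ids), function(j)
    data.frame(ID = ids[j], TIME_H = subj[[j]]$times)))
  obs_long$DV <- unlist(lapply(seq_along(ids), function(j)
    obs$DV[obs$ID == ids[j]]))

  bins <- sort(unique(obs_long$TIME_H))
  band <- t(vapply(bins, function(tm) {
    sel <- obs_long$TIME_H == tm
    c(stats::quantile(sims[sel, , drop = FALSE], c(0.05, 0.5, 0.95)),
      stats::quantile(obs_long$DV[sel], c(0.05, 0.5, 0.95)), sum(sel))
  }, numeric(7L)))
  colnames(band) <- c("p5", "p50", "p95", "obs_p5", "obs_p50", "obs_p95", "n")
  bins_df <- data.frame(time_h = bins, band)

  ib <- match(obs_long$TIME_H, bins)
  obs_long$inside <- obs_long$DV >= bins_df$p5[ib] &
    obs_long$DV <= bins_df$p95[ib]
  structure(list(bins = bins_df, observed = obs_long, n_sim = n_sim,
                 endpoint = endpoint),
            class = "vpc_bands")
}

# trajectory of a single endpoint for one subject (lean path used by the VPC)
endpoint_traj <- function(params, regimen, times, endpoint, dt = 0.5) {
  events <- build_dose_events(regimen, params$ba)
  t_end <- max(times)
  if (endpoint == 1L) {
    if (!nrow(events)) return(rep(0, length(times)))
    return(pk_conc_grid(params$pk, events, times, dt))
  }
  cp_at <- pk_conc_fun(params$pk, events, t_end, dt)
  ct <- cetp_traj_fast(params$cetp, cp_at, times, dt, t_end)
  if (endpoint == 2L) return(ct$X)
  lp <- if (endpoint == 3L) params$hdl else params$ldl
  lipid_traj_fast(lp, ct$fun, times, dt, t_end)
}

#' Fraction of observations inside the 5th-95th VPC band
#'
#' @param x A `vpc_bands` object.
#' @return Scalar coverage fraction.
#' @export
vpc_coverage <- function(x) {
  stopifnot(inherits(x, "vpc_bands"))
  mean(x$observed$inside)
}

#' @export
print.vpc_bands <- function(x, ...) {
  cat("VPC (endpoint", x$endpoint, "):", x$n_sim, "simulated trials,",
      nrow(x$observed), "observations,",
      sprintf("coverage %.3f", vpc_coverage(x)), "\n")
  invisible(x)
}

#' @export
plot.vpc_bands <- function(x, xlab = "time (h)", ylab = "observation",
                           main = NULL, ...) {
  b <- x$bins
  ylim <- range(b$p5, b$p95, x$observed$DV)
  graphics::plot(b$time_h, b$p50, type = "n", ylim = ylim, xlab = xlab,
                 ylab = ylab, main = main, ...)
  graphics::polygon(c(b$time_h, rev(b$time_h)), c(b$p5, rev(b$p95)),
                    col = "grey85", border = NA)
  graphics::lines(b$time_h, b$p50, lwd = 2)
  graphics::lines(b$time_h, b$p5, lty = 2)
  graphics::lines(b$time_h, b$p95, lty = 2)
  graphics::points(x$observed$TIME_H, x$observed$DV, pch = 1, cex = 0.5)
  invisible(x)
}
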