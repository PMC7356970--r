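test_that("two-stage fits collapse to the population values without IIV", {
  ds <- tiny_trial(seed = 41)
  ts <- two_stage(ds, "pk", params = pub, iiv_names = c("cl", "ktr"))
  expect_true(all(abs(ts$estimates$cl / 6.4 - 1) < 1e-4))
  expect_true(all(ts$cv < 0.1))
  expect_equal(ts$n_fit, 6L)  # placebo subjects carry no PK information
})

test_that("two-stage summaries recover a known clearance CV", {
  d <- default_design(cohorts = data.frame(dose = 100, n_active = 24L,
                                           n_placebo = 0L),
                      n_days = 7L,
                      day1_times = c(0, 1, 2, 4, 8, 12, 24),
                      day14_times = c(0, 2, 4, 8, 12, 24, 48),
                      trough_days = 2:6)
  p <- pub
  p$iiv <- iiv_spec(pk = c(cl = 15.6))   # variability on clearance only
  ds <- suppressWarnings(synthesize_trial(d, p, iiv = TRUE, noise = FALSE,
                                          seed = 77, engine = "staged"))
  ts <- two_stage(ds, "pk", params = pub, iiv_names = c("cl", "ktr"))
  expect_equal(unname(ts$cv["cl"]), 15.6, tolerance = 5 / 15.6)
  expect_lt(unname(ts$cv["ktr"]), 3)
})

test_that("single-subject datasets yield an undefined CV with a flag", {
  ds <- tiny_trial(seed = 42, doses = 50, n_active = 1L, n_placebo = 0L)
  ts <- two_stage(ds, "pk", params = pub, iiv_names = "cl")
  expect_equal(ts$n_fit, 1L)
  expect_true(is.na(ts$cv["cl"]))
  expect_match(ts$flag, "fewer than two")
})

test_that("bootstrap resamples preserve strata and degenerate to the point fit", {
  ds <- tiny_trial(seed = 43)
  ids <- sort(unique(ds$ID))
  # identity resample: interval collapses onto the point estimate
  bs <- bootstrap(ds, "cetp", resamples = list(ids), n_starts = 1L,
                  perturb = 0)
  expect_equal(unname(bs$quantiles["50%", ]), unname(coef(bs$point)),
               tolerance = 1e-6)
  expect_equal(bs$n_failed, 0L)
  # random resampling keeps the per-cohort subject count
  bs2 <- bootstrap(ds, "cetp", n_resamples = 2L, seed = 9, n_starts = 1L,
                   perturb = 0)
  subj <- unique(ds[, c("ID", "COHORT_MG")])
  for (r in bs2$resamples) {
    expect_equal(length(r), nrow(subj))
    drawn <- subj$COHORT_MG[match(r, subj$ID)]
    expect_equal(as.vector(table(drawn)), as.vector(table(subj$COHORT_MG)))
  }
})

test_that("bootstrap medians sit near the point estimate on noisy data", {
  ds <- suppressWarnings(synthesize_trial(tiny_design(), pub, iiv = TRUE,
                                          noise = TRUE, seed = 44,
                                          engine = "staged"))
  bs <- bootstrap(ds, "cetp", n_resamples = 10L, seed = 10, n_starts = 1L,
                  perturb = 0)
  expect_lt(abs(bs$quantiles["50%", "cetp_base"] /
                  coef(bs$point)[["cetp_base"]] - 1), 0.15)
  expect_true(all(bs$quantiles["2.5%", ] <= bs$quantiles["97.5%", ]))
})

test_that("VPC bands are ordered, deterministic, and collapse without noise", {
  ds <- tiny_trial(seed = 45, iiv = TRUE, noise = TRUE)
  v1 <- vpc(ds, pub, n_sim = 100L, seed = 3, endpoint = 2L)
  v2 <- vpc(ds, pub, n_sim = 100L, seed = 3, endpoint = 2L)
  expect_identical(v1$bins, v2$bins)
  expect_true(all(v1$bins$p5 <= v1$bins$p50 & v1$bins$p50 <= v1$bins$p95))
  # no IIV, no noise, homogeneous arm: all bands coincide with the prediction
  # (bands are pooled over subjects, so this needs a single-cohort design)
  ds0 <- tiny_trial(seed = 46, doses = 100, n_active = 4L, n_placebo = 0L)
  v0 <- vpc(ds0, pub, n_sim = 100L, seed = 4, endpoint = 2L,
            iiv = FALSE, noise = FALSE)
  expect_equal(v0$bins$p5, v0$bins$p95, tolerance = 1e-12)
  expect_equal(v0$bins$p50, v0$bins$obs_p50, tolerance = 1e-3)
  expect_error(vpc(ds, pub, n_sim = 50L), "at least 100")
})
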