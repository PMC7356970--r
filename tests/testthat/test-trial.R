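test_that("the default design encodes the phase-I study", {
  d <- default_design()
  expect_equal(sum(d$cohorts$n_active + d$cohorts$n_placebo), 32L)
  expect_equal(d$cohorts$dose, c(50, 100, 200, 400))
  expect_equal(length(d$day1_times), 13L)
  expect_equal(max(design_times(d)), 13 * 24 + 168)  # 480 h after first dose
  # per-subject schedule size: day-1 + troughs + day-14 extended
  expect_equal(length(design_times(d)), 13L + 12L + 20L)
})

test_that("individual parameter draws follow the log-normal IIV model", {
  # all CVs zero: every subject identical to the population values
  iiv0 <- iiv_spec()
  inds <- sample_individual_params(pub, 5, iiv = iiv0, seed = 1)
  for (ind in inds) expect_identical(ind, pub)
  # same seed, same draws
  a <- sample_individual_params(pub, 8, seed = 42)
  b <- sample_individual_params(pub, 8, seed = 42)
  expect_identical(a, b)
  # law of large numbers: sample SD of log(cl_i / cl) approaches CV/100
  many <- sample_individual_params(pub, 1e4, seed = 7)
  lcl <- log(vapply(many, function(x) x$pk$cl, 0) / pub$pk$cl)
  expect_equal(sd(lcl), 0.156, tolerance = 0.02)
  expect_equal(mean(lcl), 0, tolerance = 0.01)
  # derived rates are re-derived per individual
  for (ind in many[1:20]) {
    expect_equal(ind$cetp$kout, ind$cetp$kin_base / ind$cetp$cetp_base)
    expect_lt(abs(hdl_rhs(ind$hdl$rb, 0, function(t) 350, ind$hdl)), 1e-10)
    expect_lt(abs(ldl_rhs(ind$ldl$rb, 0, function(t) 350, ind$ldl)), 1e-10)
  }
})

test_that("residual error reproduces the specified magnitudes", {
  set.seed(5)
  # proportional-only PK error: sample CV near 30%
  o <- suppressWarnings(
    apply_residual_error(rep(100, 1e4), residual_spec(1e-4, 0.30)))
  expect_equal(sd(o) / mean(o), 0.30, tolerance = 0.02)
  # additive HDL error: sample SD near 4.6 mg/dL
  o2 <- apply_residual_error(rep(50, 1e4), pub$residual$hdl)
  expect_equal(sd(o2), 4.6, tolerance = 0.02 * 4.6)
  # zero spec passes predictions through
  expect_equal(apply_residual_error(c(1, 5), residual_spec(1e-300, 0)),
               c(1, 5))
  # near-zero predictions with a large additive SD truncate with a warning
  expect_warning(apply_residual_error(rep(0.01, 100), residual_spec(10, 0)),
                 "truncated")
})

test_that("synthetic trials are reproducible and respect the design", {
  d <- tiny_design()
  ds1 <- suppressWarnings(synthesize_trial(d, pub, iiv = TRUE, noise = TRUE,
                                           seed = 99))
  ds2 <- suppressWarnings(synthesize_trial(d, pub, iiv = TRUE, noise = TRUE,
                                           seed = 99))
  f1 <- tempfile(); f2 <- tempfile()
  write_dataset(ds1, f1); write_dataset(ds2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(f1, f2))

  n_sched <- length(design_times(d))
  for (id in unique(ds1$ID)) {
    sub <- ds1[ds1$ID == id, ]
    active <- sub$ARM[1] == "active"
    expect_equal(sum(sub$EVID == 1), if (active) d$n_days else 0L)
    for (ep in 1:4)
      expect_equal(sum(sub$EVID == 0 & sub$DVID == ep), n_sched)
  }
  # placebo subjects: no doses, PK flagged missing
  plc <- ds1[ds1$ARM == "placebo", ]
  expect_true(all(plc$EVID == 0))
  expect_true(all(is.na(plc$DV[plc$DVID == 1])))
  expect_true(all(plc$MDV[plc$DVID == 1] == 1))
  expect_true(all(plc$MDV[plc$DVID %in% 2:4] == 0))
  # observations are non-negative, doses only in active arms
  expect_true(all(ds1$DV[!is.na(ds1$DV)] >= 0))
  expect_true(all(ds1$ARM[ds1$EVID == 1] == "active"))
  # dose records precede observations at tied times
  sub <- ds1[ds1$ID == 1 & ds1$TIME_H == 24, ]
  expect_equal(sub$EVID[1], 1L)
})

test_that("noise-free IIV-free observations equal the model predictions", {
  ds <- tiny_trial(seed = 3)
  p1 <- ds[ds$ID == 1 & ds$EVID == 0, ]
  reg <- regimen_qd(ds$COHORT_MG[1], attr(ds, "design")$n_days)
  ut <- sort(unique(p1$TIME_H))
  sim <- simulate_subject(pub, reg, ut, rtol = 1e-10, atol = 1e-12)
  cols <- c("conc_ng_ml", "cetp_pmole", "hdl_mg_dl", "ldl_mg_dl")
  for (ep in 1:4) {
    got <- p1$DV[p1$DVID == ep]
    want <- sim[[cols[ep]]][match(p1$TIME_H[p1$DVID == ep], ut)]
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("drug observations below the LLOQ are flagged", {
  ds <- tiny_trial(seed = 3)
  pk <- ds[ds$EVID == 0 & ds$DVID == 1 & ds$MDV == 0, ]
  expect_true(all(pk$BLQ[pk$DV < 1.0] == 1))
  expect_true(all(pk$BLQ[pk$DV >= 1.0] == 0))
  expect_true(any(pk$BLQ == 1))  # the pre-first-dose sample at least
})

test_that("datasets round-trip through CSV exactly", {
  ds <- suppressWarnings(synthesize_trial(tiny_design(), pub, iiv = TRUE,
                                          noise = TRUE, seed = 12))
  f <- tempfile(fileext = ".csv")
  write_dataset(ds, f)
  back <- read_dataset(f)
  plain <- ds
  attributes(plain) <- attributes(plain)[c("names", "row.names", "class")]
  expect_equal(back, plain)
  unlink(f)
  # empty dataset still round-trips with a header
  empty <- plain[0, ]
  write_dataset(empty, f)
  expect_equal(nrow(read_dataset(f)), 0L)
  unlink(f)
})

test_that("malformed dataset files are rejected with the offending line", {
  ds <- tiny_trial(seed = 3)
  f <- tempfile(fileext = ".csv")
  ds_bad <- ds
  ds_bad$DVID[ds_bad$EVID == 0][1] <- 9L
  write_dataset(ds_bad, f)
  expect_error(read_dataset(f), "endpoint code")
  unlink(f)
})
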