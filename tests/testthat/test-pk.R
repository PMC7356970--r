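test_that("bioavailability follows the dose-Emax times time-decay form", {
  ba <- pub$ba
  # dose equal to BA50 halves the dose term: 1.6 * 0.5
  expect_equal(bioavailability_fraction(90.1, 0, ba), 0.8)
  # hand evaluation at 50 mg, 336 h
  expect_equal(bioavailability_fraction(50, 336, ba),
               1.6 * (1 - 50 / 140.1) * exp(-0.002 * 336))
  expect_equal(bioavailability_fraction(50, 336, ba), 0.5255, tolerance = 1e-3)
  # the 400 mg group has no time decay
  expect_equal(bioavailability_fraction(400, 336, ba),
               bioavailability_fraction(400, 0, ba))
  # BA strictly decreasing in dose, FT non-increasing in time, F <= bmax
  d <- c(25, 50, 100, 200, 399)
  expect_true(all(diff(bioavailability_fraction(d, 0, ba)) < 0))
  tt <- seq(0, 480, by = 24)
  f50 <- bioavailability_fraction(rep(50, length(tt)), tt, ba)
  expect_true(all(diff(f50) < 0))
  expect_true(all(bioavailability_fraction(c(1, 50, 400), 0, ba) <= ba$bmax))
})

test_that("dose events apply the bioavailability model per administration", {
  ev400 <- build_dose_events(regimen_qd(400, 14), pub$ba)
  expect_equal(length(unique(round(ev400$bioavailable_amount, 12))), 1L)
  ev50 <- build_dose_events(regimen_qd(50, 14), pub$ba)
  expect_true(all(diff(ev50$bioavailable_amount) < 0))
  expect_equal(nrow(build_dose_events(regimen_qd(0, 14), pub$ba)), 0L)
  expect_error(build_dose_events(data.frame(time = c(0, 0), dose = 50),
                                 pub$ba), "duplicate")
})

test_that("PK right-hand side conserves mass and moves the transit chain", {
  p <- pub$pk
  z <- numeric(p$n_transit + 4L)
  expect_equal(pk_rhs(z, 0, p), z)
  # closed system when clearance is zero
  p0 <- p; p0$cl <- 1e-300
  s <- c(1, 0.5, 0.2, 0.1, 0.05, 2, 3, 1, 0.5)
  expect_equal(sum(pk_rhs(s, 0, p0)), 0, tolerance = 1e-12)
  # unit bolus in the first transit compartment with ktr = 1
  p1 <- p; p1$ktr <- 1
  d <- pk_rhs(c(1, rep(0, 8)), 0, p1)
  expect_equal(d[1:2], c(-1, 1))
})

test_that("grid propagation, ODE solution and single-dose oracle agree", {
  reg <- data.frame(time = 0, dose = 50)
  ev <- build_dose_events(reg, pub$ba)
  tt <- c(0, 1, 2, 4, 8, 12, 24, 48, 96, 168)
  ode <- simulate_pk(pub$pk, pub$ba, reg, tt)
  ora <- analytic_pk_oracle(pub$pk, ev, tt)
  grd <- simulate_pk(pub$pk, pub$ba, reg, tt, method = "matexp")
  expect_equal(ode$conc_ng_ml[1], 0)
  expect_lt(max(abs(ode$conc_ng_ml - ora$conc_ng_ml) /
                  pmax(ora$conc_ng_ml, 1e-9)), 1e-5)
  expect_lt(max(abs(grd$conc_ng_ml - ora$conc_ng_ml) /
                  pmax(ora$conc_ng_ml, 1e-9)), 1e-8)
  # no doses: identically zero
  expect_true(all(simulate_pk(pub$pk, pub$ba, NULL, tt)$conc_ng_ml == 0))
})

test_that("total exposure matches the clearance identity", {
  ev <- build_dose_events(data.frame(time = 0, dose = 100), pub$ba)
  f <- function(t) vapply(t, function(ti)
    analytic_pk_oracle(pub$pk, ev, ti)$conc_ng_ml, 0)
  auc <- stats::integrate(f, 0, Inf, rel.tol = 1e-7)$value
  expect_equal(auc, ev$bioavailable_amount / pub$pk$cl * 1000,
               tolerance = 1e-3)
})

test_that("multi-dose solution is the superposition of shifted single doses", {
  reg <- regimen_qd(100, 5)
  ev <- build_dose_events(reg, pub$ba)
  tt <- c(2, 12, 26, 50, 75, 100, 140)
  multi <- simulate_pk(pub$pk, pub$ba, reg, tt)$conc_ng_ml
  single <- rowSums(vapply(seq_len(nrow(ev)), function(k)
    analytic_pk_oracle(pub$pk, ev[k, ], tt)$conc_ng_ml, numeric(length(tt))))
  expect_lt(max(abs(multi - single) / pmax(single, 1e-9)), 1e-5)
})

test_that("doubling the bioavailable amounts doubles every concentration", {
  reg <- regimen_qd(100, 3)
  ev <- build_dose_events(reg, pub$ba)
  ev2 <- ev; ev2$bioavailable_amount <- 2 * ev$bioavailable_amount
  tt <- seq(0, 96, by = 4)
  c1 <- cetpkpd:::pk_conc_grid(pub$pk, ev, tt, 1)
  c2 <- cetpkpd:::pk_conc_grid(pub$pk, ev2, tt, 1)
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
})

test_that("mass balance holds with zero clearance and states stay non-negative", {
  p0 <- pub$pk; p0$cl <- 1e-300
  reg <- regimen_qd(100, 5)
  ev <- build_dose_events(reg, pub$ba)
  st <- cetpkpd:::pk_grid_states(p0, ev, 120, 1)
  total <- rowSums(st)
  cum_dose <- vapply(seq(0, 120, 1), function(t)
    sum(ev$bioavailable_amount[ev$time <= t]), 0)
  expect_lt(max(abs(total - cum_dose) / cum_dose), 1e-6)
  # non-negativity under the published parameters (with elimination)
  st2 <- cetpkpd:::pk_grid_states(pub$pk, ev, 120, 1)
  expect_true(all(st2 > -1e-8))
})
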