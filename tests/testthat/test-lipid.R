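test_that("the sigmoid CETP response has the stated anchors and limits", {
  expect_equal(res_cetp(185, 1.5, 185, 2.1), 0.75)  # half-maximal at R50
  expect_equal(res_cetp(0, 1.5, 185, 2.1), 0)
  expect_equal(res_cetp(350, 1.5, 185, 2.1), sigmoid_val(350, 1.5, 185, 2.1))
  expect_equal(res_cetp(350, 1.5, 185, 2.1), 1.18847, tolerance = 1e-4)
  R <- c(0, 10, 80, 185, 350, 1e4, 1e8)
  v <- res_cetp(R, 1.5, 185, 2.1)
  expect_true(all(diff(v) > 0) && all(v >= 0) && all(v < 1.5))
  expect_error(res_cetp(-1, 1.5, 185, 2.1), class = "invalid_parameter")
})

test_that("the LDL placebo ramp is linear and unbounded", {
  expect_equal(ldl_placebo_term(0, 0.0009), 0)
  expect_equal(ldl_placebo_term(504, 0.0009), 0.4536)
  expect_equal(ldl_placebo_term(123, 0), 0)
})

test_that("lipid baselines are stationary and move to the algebraic steady states", {
  # baseline stationarity at the reference CETP activity
  expect_lt(abs(hdl_rhs(50, 0, function(t) 350, pub$hdl)), 1e-10)
  expect_lt(abs(ldl_rhs(97.4, 0, function(t) 350, pub$ldl)), 1e-10)
  # CETP driven to zero: steady states ksyn/kdeg
  ldl0 <- pub$ldl; ldl0$beta <- 0
  tt <- c(0, 100, 500, 2000, 5000)
  sim <- simulate_lipids(function(t) rep(0, length(t)), hdl = pub$hdl,
                         ldl = ldl0, output_times = tt)
  expect_equal(tail(sim$hdl_mg_dl, 1), 50 * (1 + 1.18848), tolerance = 1e-4)
  expect_equal(tail(sim$ldl_mg_dl, 1), 97.4 * (1 - 0.76949), tolerance = 1e-4)
})

test_that("baselines drift by less than 1e-6 over 504 h with all effects off", {
  ce0 <- cetp_params(350, 164, kmax = 0, k50 = 9700, emax = 18.2, ec50 = 587)
  ldl0 <- pub$ldl; ldl0$beta <- 0
  p0 <- pkpd_params(pub$pk, pub$ba, ce0, pub$hdl, ldl0, pub$iiv, pub$residual)
  tt <- seq(0, 504, by = 4)
  sim <- simulate_subject(p0, NULL, tt)
  expect_lt(max(abs(sim$cetp_pmole - 350)) / 350, 1e-6)
  expect_lt(max(abs(sim$hdl_mg_dl - 50)) / 50, 1e-6)
  expect_lt(max(abs(sim$ldl_mg_dl - 97.4)) / 97.4, 1e-6)
})

test_that("placebo arm shows rising LDL-C and slightly falling HDL-C", {
  tt <- seq(0, 504, by = 8)
  sim <- simulate_subject(pub, NULL, tt)
  expect_gt(tail(sim$ldl_mg_dl, 1), 97.4)
  expect_lt(tail(sim$hdl_mg_dl, 1), 50)   # rising CETP stimulates HDL loss
  expect_true(all(sim$hdl_mg_dl > 0 & sim$ldl_mg_dl > 0))
})

test_that("active dosing raises HDL-C and lowers LDL-C against baseline", {
  tt <- seq(0, 336, by = 8)
  sim <- simulate_subject(pub, regimen_qd(400, 14), tt)
  expect_gt(max(sim$hdl_mg_dl), 50)
  expect_lt(min(sim$ldl_mg_dl), 97.4)
  expect_true(all(sim$hdl_mg_dl > 0 & sim$ldl_mg_dl > 0))
})

test_that("a pointwise-lower CETP trajectory raises HDL-C and lowers LDL-C", {
  tt <- seq(0, 504, by = 8)
  ldl0 <- pub$ldl; ldl0$beta <- 0
  lo <- simulate_lipids(function(t) rep(100, length(t)), pub$hdl, ldl0, tt)
  hi <- simulate_lipids(function(t) rep(300, length(t)), pub$hdl, ldl0, tt)
  expect_true(all(lo$hdl_mg_dl[-1] > hi$hdl_mg_dl[-1]))
  expect_true(all(lo$ldl_mg_dl[-1] < hi$ldl_mg_dl[-1]))
})

test_that("coupled and staged full-chain integration differ by less than 0.1%", {
  tt <- c(0, 1, 2, 4, 8, 12, 24, 48, 96, 168, 312, 336, 480)
  for (dose in c(50, 400)) {
    reg <- regimen_qd(dose, 14)
    a <- simulate_subject(pub, reg, tt, engine = "coupled")
    b <- simulate_subject(pub, reg, tt, engine = "staged")
    expect_lt(max(abs(a$conc_ng_ml - b$conc_ng_ml) /
                    pmax(a$conc_ng_ml, 1e-6)), 1e-3)
    expect_lt(max(abs(a$cetp_pmole - b$cetp_pmole) / a$cetp_pmole), 1e-3)
    expect_lt(max(abs(a$hdl_mg_dl - b$hdl_mg_dl) / a$hdl_mg_dl), 1e-3)
    expect_lt(max(abs(a$ldl_mg_dl - b$ldl_mg_dl) / a$ldl_mg_dl), 1e-3)
  }
})
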