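test_that("the extended least-squares objective matches hand arithmetic", {
  sp <- residual_spec(1e-300, 0.3)
  # one pair: obs 110, pred 100, proportional SD 0.3
  expect_equal(els_objective(110, 100, sp), 10^2 / 30^2 + log(900))
  expect_equal(els_objective(110, 100, sp), 0.1111 + 6.8024, tolerance = 1e-4)
  # perfect fit under additive-only error leaves the constant log-variance term
  spa <- residual_spec(2, 0)
  expect_equal(els_objective(c(5, 7), c(5, 7), spa), 2 * log(4))
  # doubling all residuals quadruples the quadratic part
  obs <- c(100, 200, 300); pred <- obs - c(1, 2, 3)
  pred2 <- obs - 2 * c(1, 2, 3)
  q1 <- els_objective(obs, pred, spa) - 3 * log(4)
  q2 <- els_objective(obs, pred2, spa) - 3 * log(4)
  expect_equal(q2, 4 * q1)
  expect_error(els_objective(1, 0, residual_spec(1e-300, 0.3)), "variance")
})

test_that("a start at the truth converges immediately to zero residual", {
  ds <- tiny_trial(seed = 21)
  f <- fit_pk(ds, init = pub, n_starts = 1L, perturb = 0, seed = 1)
  expect_true(f$converged)
  expect_lt(f$ssr, 1e-8)
  expect_lt(f$niter, 25)
  expect_equal(coef(f)[["cl"]], 6.4, tolerance = 1e-4)
})

test_that("alpha_low is flagged unidentifiable when only the top cohort is present", {
  ds <- tiny_trial(seed = 22, doses = 400)
  f <- fit_pk(ds, init = pub, n_starts = 1L, perturb = 0)
  expect_false("alpha_low" %in% names(coef(f)))
  expect_match(f$flags, "alpha_low", all = FALSE)
  expect_equal(f$params$ba$alpha_low, pub$ba$alpha_low)  # held at init
})

test_that("drug parameters are flagged unidentifiable on placebo-only data", {
  ds <- tiny_trial(seed = 23, n_active = 0L, n_placebo = 3L)
  f <- fit_cetp(ds, init = pub, n_starts = 1L, perturb = 0)
  expect_false(any(c("emax", "ec50") %in% names(coef(f))))
  expect_match(f$flags, "emax/ec50", all = FALSE)
  expect_true(f$converged)
})

test_that("the reduced placebo-free CETP model still recovers baselines", {
  # generate without the placebo time trend, then fit the reduced model
  # (kmax fixed at 0): the baseline pair is still recovered
  p0 <- pub
  p0$cetp <- cetp_params(350, 164, kmax = 0, k50 = 9700,
                         emax = 18.2, ec50 = 587)
  ds <- suppressWarnings(synthesize_trial(tiny_design(), p0, iiv = FALSE,
                                          noise = FALSE, seed = 24))
  f <- fit_cetp(ds, init = p0, fixed = "kmax", n_starts = 1L, perturb = 0)
  expect_true(f$converged)
  expect_equal(coef(f)[["cetp_base"]], 350, tolerance = 0.01)
  expect_equal(coef(f)[["kin_base"]], 164, tolerance = 0.01)
})

test_that("each stage recovers its generating values on a reduced noise-free trial", {
  ds <- tiny_trial(seed = 25)
  fpk <- fit_pk(ds, init = pub, n_starts = 2L, perturb = 0.3, seed = 31)
  expect_lt(abs(coef(fpk)[["cl"]] / 6.4 - 1), 0.02)
  expect_lt(abs(coef(fpk)[["ktr"]] / 1.10 - 1), 0.02)
  fce <- fit_cetp(ds, init = pub, n_starts = 2L, perturb = 0.3, seed = 32)
  expect_lt(abs(coef(fce)[["emax"]] / 18.2 - 1), 0.02)
  expect_lt(abs(coef(fce)[["ec50"]] / 587 - 1), 0.02)
  fh <- fit_lipid(ds, endpoint = "hdl", init = pub, n_starts = 2L,
                  perturb = 0.3, seed = 33)
  expect_lt(abs(coef(fh)[["r50"]] / 185 - 1), 0.02)

  # sequential invariance: with noise-free data, fitting from the estimated
  # pooled PK equals fitting from the generating PK to within 0.5%
  ind_est <- rep(list(fpk$params), length(unique(ds$ID)))
  fce2 <- fit_cetp(ds, individual_pk = ind_est, init = pub, n_starts = 1L,
                   perturb = 0)
  expect_lt(max(abs(coef(fce2)[c("emax", "ec50", "cetp_base")] /
                      coef(fce)[c("emax", "ec50", "cetp_base")] - 1)), 0.005)
})

test_that("optimization reports a finite objective and decreasing multi-start SSR", {
  ds <- tiny_trial(seed = 26)
  f <- fit_pk(ds, init = pub, n_starts = 2L, perturb = 0.2, seed = 5)
  expect_true(is.finite(f$objective))
  expect_true(all(is.finite(f$starts$ssr)))
  expect_lte(f$ssr, min(f$starts$ssr) + 1e-12)
  expect_s3_class(f, "pkpd_fit")
  expect_named(predict(f), c("ID", "TIME_H", "obs", "pred", "wres"))
  expect_equal(length(residuals(f)), f$n_obs)
})
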