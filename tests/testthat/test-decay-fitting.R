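test_that("tau0 closed form: exact special cases and domain errors", {
  expect_equal(tau0_from_kww(5, 1), 5)          # Gamma(1) = 1
  expect_equal(tau0_from_kww(1, 0.5), 2)        # Gamma(2)/0.5 = 2
  expect_equal(tau0_from_kww(c(1, 5), c(0.5, 1)), c(2, 5))
  expect_error(tau0_from_kww(1, 0), class = "ringhet_domain_error")
  expect_error(tau0_from_kww(1, -0.2), class = "ringhet_domain_error")
  expect_error(tau0_from_kww(-1, 0.5), class = "ringhet_domain_error")
})

test_that("KWW fit with beta = 1 reduces to the pure exponential", {
  cv <- tacf_curve(seq(0, 50, by = 0.1), exp(-seq(0, 50, by = 0.1) / 5))
  fit <- fit_kww(cv)
  expect_true(fit$converged)
  expect_equal(fit$beta, 1, tolerance = 1e-6)
  expect_equal(fit$tau_kww, 5, tolerance = 1e-6)
  expect_equal(fit$tau0, 5, tolerance = 1e-5)
})

test_that("noiseless stretched exponentials are recovered to 1e-3 relative", {
  t <- log_grid(0.01, 2000, 300)
  fit <- fit_kww(kww_curve(50, 0.6, t))
  expect_equal(fit$tau_kww, 50, tolerance = 1e-3)
  expect_equal(fit$beta, 0.6, tolerance = 1e-3)
  # blend-like parameters: strong stretching
  t2 <- log_grid(0.01, 3000, 300)
  fit2 <- fit_kww(kww_curve(91, 0.51, t2))
  expect_equal(fit2$tau_kww, 91, tolerance = 1e-3)
  expect_equal(fit2$beta, 0.51, tolerance = 1e-3)
  expect_equal(fit2$tau0, 174, tolerance = 0.02)   # printed-rounding band
})

test_that("every KWW fit satisfies the closed-form tau0 identity to machine precision", {
  t <- log_grid(0.01, 500, 150)
  for (pars in list(c(5, 0.9), c(20, 0.7), c(3, 0.55))) {
    fit <- fit_kww(kww_curve(pars[1], pars[2], t))
    expect_equal(fit$tau0, tau0_from_kww(fit$tau_kww, fit$beta),
                 tolerance = 1e-12)
  }
})

test_that("KWW fit handles short curves, noise floor and non-convergence contract", {
  expect_error(fit_kww(tacf_curve(0:5, exp(-(0:5)))),
               class = "ringhet_fit_error")
  # noise floor excludes deep-tail points from the 10-lag requirement
  t <- seq(0, 3, by = 0.25)
  expect_error(fit_kww(tacf_curve(t, exp(-t * 5)),
                       kww_control(noise_floor = 0.5)),
               class = "ringhet_fit_error")
  # a pathological flat-then-drop curve still returns (possibly unconverged)
  vals <- c(1, rep(0.999, 15), rep(1e-6, 10))
  cv <- tacf_curve(seq_len(26) - 1, vals)
  fit <- fit_kww(cv)
  expect_s3_class(fit, "kww_fit")
  expect_type(fit$converged, "logical")
})

test_that("numeric tau0: analytic integrals and truncation at the zero crossing", {
  # exponential tabulated densely to 12 tau
  t <- seq(0, 12 * 4, by = 0.02)
  rel <- tau0_numeric(tacf_curve(t, exp(-t / 4)))
  expect_equal(rel$tau0_numeric, 4, tolerance = 1e-3)
  expect_true(rel$truncated)
  expect_identical(rel$t_max, NA_real_)

  # KWW beta = 0.5, tau = 1 integrates to Gamma(2)/0.5 = 2
  t2 <- c(seq(0, 10, by = 0.001), seq(10.01, 1e4, by = 0.25))
  rel2 <- tau0_numeric(tacf_curve(t2, exp(-sqrt(t2))))
  expect_equal(rel2$tau0_numeric, 2, tolerance = 0.005)

  # noisy curve: integration window ends exactly at the scanned crossing
  set.seed(6)
  tt <- seq(0, 30, by = 0.1)
  vals <- exp(-tt / 3) + c(0, rnorm(length(tt) - 1, 0, 0.04))
  cv <- tacf_curve(tt, vals)
  rel3 <- tau0_numeric(cv)
  crossing <- first_negative_crossing(cv)
  expect_false(rel3$truncated)
  expect_identical(rel3$t_max, crossing)
  keep <- tt <= crossing
  riemann <- sum(diff(tt[keep]) * (head(vals[keep], -1) + tail(vals[keep], -1)) / 2)
  expect_equal(rel3$tau0_numeric, riemann)
  expect_error(tau0_numeric(tacf_curve(0, 1)), class = "ringhet_value_error")
})

test_that("single exponential is recovered exactly by a one-mode fit", {
  cv <- multiexp_curve(3, 1, log_grid(0.01, 50, 150))
  fit <- fit_multiexp(cv, 1)
  expect_equal(fit$modes$tau_ns, 3, tolerance = 1e-6)
  expect_equal(fit$modes$amplitude, 1)
  expect_true(fit$converged)
})

test_that("two- and three-mode spectra are recovered within 1% relative", {
  cv2 <- multiexp_curve(c(1, 100), c(0.5, 0.5), log_grid(0.005, 1500, 250))
  fit2 <- fit_multiexp(cv2, 2)
  expect_equal(fit2$modes$tau_ns, c(1, 100), tolerance = 0.01)
  expect_equal(fit2$modes$amplitude, c(0.5, 0.5), tolerance = 0.01)

  cv3 <- multiexp_curve(r2k_modes$tau, r2k_modes$A, log_grid(0.01, 200, 250))
  fit3 <- fit_multiexp(cv3, 3)
  expect_equal(fit3$modes$tau_ns, r2k_modes$tau, tolerance = 0.01)
  expect_equal(fit3$modes$amplitude, r2k_modes$A, tolerance = 0.01)
})

test_that("amplitude constraints hold for every returned fit", {
  grids <- list(log_grid(0.01, 200, 200), log_grid(0.05, 500, 150))
  cases <- list(list(tau = c(0.5, 20), A = c(0.3, 0.7), n = 2),
                list(tau = c(0.1, 1.1, 10), A = c(0.06, 0.17, 0.77), n = 3),
                list(tau = 7, A = 1, n = 1),
                list(tau = c(0.1, 1.1, 10), A = c(0.06, 0.17, 0.77), n = 4))
  for (g in grids) for (cs in cases) {
    fit <- fit_multiexp(multiexp_curve(cs$tau, cs$A, g), cs$n)
    expect_true(all(fit$modes$amplitude >= 0))
    expect_lt(abs(sum(fit$modes$amplitude) - 1), 1e-6)
    expect_true(all(diff(fit$modes$tau_ns) > 0))
  }
})

test_that("time rescaling scales fitted taus and leaves beta and amplitudes alone", {
  s <- 7.5
  t <- log_grid(0.01, 300, 200)
  k1 <- fit_kww(kww_curve(12, 0.65, t))
  k2 <- fit_kww(kww_curve(12 * s, 0.65, t * s))
  expect_equal(k2$tau_kww / k1$tau_kww, s, tolerance = 1e-4)
  expect_equal(k2$beta, k1$beta, tolerance = 1e-4)

  m1 <- fit_multiexp(multiexp_curve(c(1, 15), c(0.4, 0.6), t), 2)
  m2 <- fit_multiexp(multiexp_curve(c(1, 15) * s, c(0.4, 0.6), t * s), 2)
  expect_equal(m2$modes$tau_ns / m1$modes$tau_ns, c(s, s), tolerance = 1e-4)
  expect_equal(m2$modes$amplitude, m1$modes$amplitude, tolerance = 1e-4)
})

test_that("amplitude-weighted mean time equals the exact curve integral", {
  taus <- c(0.2, 5, 40); As <- c(0.2, 0.5, 0.3)
  fit <- fit_multiexp(multiexp_curve(taus, As, log_grid(0.01, 600, 250)), 3)
  expect_equal(sum(fit$modes$tau_ns * fit$modes$amplitude),
               sum(taus * As), tolerance = 1e-3)
})

test_that("multi-exponential integral approaches the KWW tau0 as modes are added", {
  t <- log_grid(0.01, 400, 250)
  cv <- kww_curve(5, 0.6, t)
  tau0 <- tau0_from_kww(5, 0.6)
  err <- vapply(1:3, function(n) {
    fit <- fit_multiexp(cv, n)
    abs(sum(fit$modes$tau_ns * fit$modes$amplitude) - tau0)
  }, 0)
  expect_true(all(diff(err) < 0))
  expect_lt(err[3] / tau0, 0.1)
})

test_that("mode-count selection: 1 for pure exponential, 3 and 4 for designed spectra", {
  expect_identical(select_num_modes(multiexp_curve(3, 1, log_grid(0.01, 60, 150)))$n_m, 1L)
  sel3 <- select_num_modes(multiexp_curve(r2k_modes$tau, r2k_modes$A,
                                          log_grid(0.01, 200, 250)))
  expect_identical(sel3$n_m, 3L)
  sel4 <- select_num_modes(multiexp_curve(c(0.1, 1, 10, 100),
                                          c(0.15, 0.25, 0.3, 0.3),
                                          log_grid(0.005, 1500, 300)))
  expect_identical(sel4$n_m, 4L)
  expect_s3_class(sel4$fit, "multiexp_fit")
})

test_that("mode-count ceiling and degenerate inputs are rejected", {
  cv <- multiexp_curve(3, 1, log_grid(0.01, 50, 100))
  expect_error(fit_multiexp(cv, 7), "maximum", class = "ringhet_value_error")
  expect_error(fit_multiexp(cv, 0), class = "ringhet_value_error")
  expect_error(fit_multiexp(tacf_curve(0:3, exp(-(0:3))), 2),
               class = "ringhet_fit_error")
})

test_that("fit objects behave like classed models (coef/predict/residuals/print)", {
  t <- log_grid(0.01, 100, 150)
  kf <- fit_kww(kww_curve(8, 0.75, t))
  expect_named(coef(kf), c("tau_kww", "beta", "tau0"))
  expect_equal(predict(kf, 0), 1)
  expect_lt(max(abs(residuals(kf))), 1e-5)
  expect_output(print(kf), "KWW")
  expect_output(print(summary(kf)), "fit points")

  mf <- fit_multiexp(multiexp_curve(c(1, 10), c(0.5, 0.5), t), 2)
  expect_identical(dim(coef(mf)), c(2L, 2L))
  expect_equal(predict(mf, 0), 1, tolerance = 1e-6)
  expect_output(print(summary(mf)), "mean relaxation time")
})
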