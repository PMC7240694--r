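test_that("generators are bit-reproducible from spec + seed", {
  rspec <- rotdiff_spec(5, 0.2, 0.05, 50, seed = 17)
  a <- generate_rotational_diffusion(rspec)
  b <- generate_rotational_diffusion(rspec)
  expect_identical(lapply(a, `[[`, "vectors"), lapply(b, `[[`, "vectors"))

  cspec <- rouse_spec("ring", 6, k = 2, zeta = 1, dt = 0.05, n_steps = 100,
                      seed = 23, warmup_steps = 10)
  expect_identical(generate_rouse_chain(cspec)$coordinates,
                   generate_rouse_chain(cspec)$coordinates)

  mspec <- mixture_spec(list(list(weight = 1, kind = "kww", tau_ns = 2,
                                  beta = 0.7)),
                        n_molecules = 4, dt = 0.05, n_frames = 60, seed = 5)
  expect_identical(generate_mixture_ensemble(mspec)$ground_truth,
                   generate_mixture_ensemble(mspec)$ground_truth)
})

test_that("rotational-diffusion vectors stay unit length; near-frozen limit stays at 1", {
  spec <- rotdiff_spec(10, 0.3, 0.05, 200, seed = 31)
  for (s in generate_rotational_diffusion(spec)) {
    nrm <- sqrt(s$vectors[, 1, 1]^2 + s$vectors[, 1, 2]^2 + s$vectors[, 1, 3]^2)
    expect_true(max(abs(nrm - 1)) < 1e-9)
  }
  frozen <- generate_rotational_diffusion(rotdiff_spec(20, 1e-12, 0.05, 100,
                                                       seed = 8))
  cv <- ensemble_tacf(frozen)
  expect_true(all(cv$values > 1 - 1e-6))
})

test_that("spec invariants are enforced (step bias bound, stability bound, weights)", {
  expect_error(rotdiff_spec(5, 2, 0.05, 100, seed = 1), "0.05",
               class = "ringhet_spec_error")
  expect_error(rotdiff_spec(5, 0, 0.01, 100, seed = 1),
               class = "ringhet_spec_error")
  expect_error(rouse_spec("ring", 6, k = 1, zeta = 1, dt = 0.3, n_steps = 10),
               "zeta/\\(4k\\)", class = "ringhet_spec_error")
  expect_error(rouse_spec("ring", 2, k = 1, zeta = 1, dt = 0.01, n_steps = 10),
               class = "ringhet_spec_error")
  expect_error(mixture_spec(list(list(weight = -1, tau_ns = 1)), 5, 0.01, 10, 1),
               class = "ringhet_spec_error")
  expect_error(mixture_spec(list(list(weight = 1, kind = "kww", tau_ns = 1)),
                            5, 0.01, 10, 1),
               class = "ringhet_spec_error")   # kww needs beta
  # too-coarse clock for the fastest population
  expect_error(generate_mixture_ensemble(
    mixture_spec(list(list(weight = 1, kind = "exponential", tau_ns = 0.05)),
                 5, dt = 0.05, n_frames = 20, seed = 1)),
    class = "ringhet_spec_error")
})

test_that("bead-spring chain obeys equipartition and free-draining COM diffusion", {
  N <- 8; k <- 2; zeta <- 1; dt <- 0.01
  spec <- rouse_spec("ring", N, k = k, zeta = zeta, dt = dt,
                     n_steps = 40000, save_stride = 4, seed = 41)
  traj <- generate_rouse_chain(spec)
  xyz <- traj$coordinates
  bond <- xyz[, c(2:N, 1), ] - xyz
  msb <- mean(bond[, , 1]^2 + bond[, , 2]^2 + bond[, , 3]^2)
  ## ring closure reduces the open-chain value 3/k by (N-1)/N;
  ## Euler-Maruyama inflates it by O(k dt / zeta)
  expect_equal(msb, 3 * (N - 1) / (N * k), tolerance = 0.05)

  com <- apply(xyz, c(1, 3), mean)
  nf <- nrow(com)
  lags <- c(5, 10, 20, 40)
  msd <- vapply(lags, function(L) {
    d <- com[seq_len(nf - L) + L, ] - com[seq_len(nf - L), ]
    mean(rowSums(d^2))
  }, 0)
  slope <- coef(lm(msd ~ 0 + I(lags * traj$system$dt_frame)))[[1]]
  expect_equal(slope, 6 / (N * zeta), tolerance = 0.2)
})

test_that("analytic ring mode spectrum agrees with an eigendecomposition brute force (N=6)", {
  N <- 6; k <- 1.5; zeta <- 2; m <- N / 2 - 1
  L <- diag(2, N)
  for (i in seq_len(N)) {
    j <- i %% N + 1L
    L[i, j] <- L[i, j] - 1; L[j, i] <- L[j, i] - 1
  }
  ev <- eigen(L, symmetric = TRUE)
  a <- rep(0, N); a[1] <- -1; a[1 + m] <- 1
  proj <- drop(t(ev$vectors) %*% a)
  keep <- ev$values > 1e-9
  tt <- seq(0, 8, by = 0.2)
  raw <- vapply(tt, function(t0)
    sum(proj[keep]^2 / (k * ev$values[keep]) *
          exp(-k * ev$values[keep] * t0 / zeta)), 0)
  brute <- raw / raw[1]
  expect_equal(rouse_ring_diameter_tacf(tt, N, k, zeta), brute,
               tolerance = 1e-12)
  md <- rouse_ring_diameter_modes(N, k, zeta)
  expect_equal(sum(md$weight), 1)
  expect_equal(md$tau_ns, zeta / (4 * k * sin(md$p * pi / N)^2))
})

test_that("simulated ring diameter relaxation matches the analytic mode sum", {
  N <- 8; k <- 1; zeta <- 1
  spec <- rouse_spec("ring", N, k = k, zeta = zeta, dt = 0.02,
                     n_steps = 50000, save_stride = 5, seed = 53)
  traj <- generate_rouse_chain(spec)
  xyz <- traj$coordinates
  partner <- ((seq_len(N) - 1 + (N / 2 - 1)) %% N) + 1
  d <- xyz[, partner, ] - xyz
  nf <- dim(d)[1]
  lag_frames <- c(0:10, seq(12, 60, by = 4))
  Cr <- vapply(lag_frames, function(L) {
    o <- seq_len(nf - L)
    sum(d[o, , ] * d[o + L, , ]) / (length(o) * N)
  }, 0)
  Cr <- Cr / Cr[1]
  tt <- lag_frames * traj$system$dt_frame
  Can <- rouse_ring_diameter_tacf(tt, N, k, zeta)
  ## raw-vector correlation within a 3-sigma MC band (time averaging over
  ## T_total, ~N/2 effectively independent tracer directions)
  tau_slow <- max(rouse_ring_diameter_modes(N, k, zeta)$tau_ns)
  mc_tol <- 3 * sqrt(2 * tau_slow / (nf * traj$system$dt_frame * N / 2))
  expect_lt(max(abs(Cr - Can)), mc_tol)

  ## unit-vector TACF tracks the mode sum up to the known normalization
  ## offset of a Gaussian vector (< ~0.07) plus sampling noise
  cv <- molecule_tacf(diameter_series(traj, "mol1"), max_lag_fraction = 0.01)
  Cu <- approx(cv$lags, cv$values, xout = tt[tt <= max(cv$lags)])$y
  expect_lt(max(abs(Cu - Can[tt <= max(cv$lags)])), 0.1)
  expect_true(all(Cu - Can[tt <= max(cv$lags)] < 0.02))  # offset is downward
})

test_that("mixture ground truth matches design and drives downstream estimates", {
  spec <- mixture_spec(list(list(weight = 0.5, kind = "exponential", tau_ns = 1),
                            list(weight = 0.5, kind = "exponential", tau_ns = 4)),
                       n_molecules = 150, dt = 0.04, n_frames = 700,
                       seed = 67, n_tracers = 3)
  mix <- generate_mixture_ensemble(spec)
  gt <- mix$ground_truth
  expect_identical(nrow(gt), 150L)
  expect_setequal(unique(gt$tau_ns), c(1, 4))
  # mean per-molecule numeric tau0 ~ realized mixture mean
  relax <- vapply(mix$series, function(s)
    tau0_numeric(molecule_tacf(s))$tau0_numeric, 0)
  expect_equal(mean(relax), mean(gt$tau_ns), tolerance = 0.15)

  # homogeneous exponential ensemble: fitted beta ~ 1
  one <- mixture_spec(list(list(weight = 1, kind = "exponential", tau_ns = 2)),
                      n_molecules = 100, dt = 0.04, n_frames = 700, seed = 71,
                      n_tracers = 2)
  ens <- ensemble_tacf(generate_mixture_ensemble(one)$series,
                       max_lag_fraction = 0.3)
  fit <- fit_kww(ens)
  expect_equal(fit$beta, 1, tolerance = 0.05)
  expect_equal(fit$tau0, 2, tolerance = 0.1)
})

test_that("kww surrogate population realizes the prescribed stretched decay", {
  ## the warped clock is non-stationary: the prescribed curve is defined
  ## from the initial time origin, so use a single origin (large stride)
  spec <- mixture_spec(list(list(weight = 1, kind = "kww", tau_ns = 3,
                                 beta = 0.6)),
                       n_molecules = 800, dt = 0.05, n_frames = 400, seed = 83)
  mix <- generate_mixture_ensemble(spec)
  ens <- ensemble_tacf(mix$series, origin_stride = 400,
                       max_lag_fraction = 0.3)
  expected <- exp(-(ens$lags / 3)^0.6)
  tol <- 3 / sqrt(800) + 0.01   # single-origin MC band over 800 molecules
  expect_lt(max(abs(ens$values - expected)), tol)
  expect_equal(mix$ground_truth$tau0_ns[1], tau0_from_kww(3, 0.6))
})
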