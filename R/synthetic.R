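## Seeded synthetic-data generators with analytically known relaxation
## behavior. These define the ground truth every downstream stage is
## validated against: isotropic rotational diffusion (single-exponential
## TACF), free-draining bead-spring chains (multi-exponential TACF with a
## closed-form mode spectrum), and designed fast/slow mixtures emulating
## the phenomenology of unthreaded vs multiply-threaded rings in
## ring-linear blends.
##
## Energy units are kBT = 1 throughout, so spring constants are in
## kBT/nm^2 and friction coefficients in kBT*ns/nm^2.

#' Specification of a rotational-diffusion ensemble
#'
#' Each molecule carries one unit vector performing isotropic rotational
#' diffusion on the sphere with coefficient `D_r`; its orientational TACF
#' is exactly \eqn{\exp(-2 D_r t)} (the l = 1 correlation), which makes
#' the ensemble a calibration standard for the TACF and KWW stages.
#'
#' @param n_molecules number of molecules.
#' @param D_r rotational diffusion coefficient in 1/ns; a scalar or one
#'   value per molecule.
#' @param dt time step between frames, ns. `dt * D_r` must not exceed
#'   0.05, the bound below which the tangent-plane discretization bias is
#'   negligible.
#' @param n_frames number of frames (>= 2).
#' @param seed RNG seed; identical specs yield bit-identical output.
#' @return A list of class `rotdiff_spec`.
#' @export
rotdiff_spec <- function(n_molecules, D_r, dt, n_frames, seed) {
  n_molecules <- as.integer(n_molecules)
  D_r <- as.numeric(D_r)
  if (!length(D_r) %in% c(1L, n_molecules))
    stop_ringhet("D_r must be scalar or one value per molecule",
                 class = "ringhet_spec_error")
  if (any(D_r <= 0))
    stop_ringhet("D_r must be positive", class = "ringhet_spec_error")
  if (!is_scalar_number(dt) || dt <= 0)
    stop_ringhet("dt must be positive", class = "ringhet_spec_error")
  if (any(dt * D_r > 0.05))
    stop_ringhet("dt * D_r exceeds 0.05: the tangent-plane step would bias ",
                 "the correlation; reduce dt", class = "ringhet_spec_error")
  if (n_frames < 2L)
    stop_ringhet("n_frames must be >= 2", class = "ringhet_spec_error")
  structure(list(n_molecules = n_molecules, D_r = D_r, dt = dt,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "rotdiff_spec")
}

## Core spherical random walk shared by the generators.
## ds: (n_frames - 1) x n_mol matrix of per-component variance increments.
## Returns array (n_frames, n_mol, 3) of unit vectors.
sphere_walk <- function(n_mol, n_frames, ds, seed) {
  set.seed(seed)
  V <- matrix(stats::rnorm(n_mol * 3L), n_mol, 3L)
  V <- V / sqrt(rowSums(V^2))
  out <- array(NA_real_, c(n_frames, n_mol, 3L))
  out[1L, , ] <- V
  sd_step <- sqrt(ds)
  for (j in seq_len(n_frames - 1L)) {
    V <- V + matrix(stats::rnorm(n_mol * 3L), n_mol, 3L) * sd_step[j, ]
    V <- V / sqrt(rowSums(V^2))
    out[j + 1L, , ] <- V
  }
  out
}

#' Generate a rotational-diffusion orientation ensemble
#'
#' Small-step spherical random walk: per frame, a tangent-space Gaussian
#' displacement of variance `2 * D_r * dt` per component followed by
#' renormalization to the unit sphere.
#'
#' @param spec a [rotdiff_spec()].
#' @return A list of `orientation_series`, one per molecule (ids
#'   `mol_0001`, ...), each with a single tracer vector.
#' @export
generate_rotational_diffusion <- function(spec) {
  stopifnot(inherits(spec, "rotdiff_spec"))
  D_r <- rep_len(spec$D_r, spec$n_molecules)
  ds <- matrix(rep(2 * D_r * spec$dt, each = spec$n_frames - 1L),
               spec$n_frames - 1L, spec$n_molecules)
  u <- sphere_walk(spec$n_molecules, spec$n_frames, ds, spec$seed)
  lapply(seq_len(spec$n_molecules), function(m)
    new_orientation_series(u[, m, , drop = FALSE], "end_to_end", spec$dt,
                           sprintf("mol_%04d", m)))
}

#' Specification of a free-draining bead-spring chain
#'
#' Overdamped Langevin (Euler-Maruyama) dynamics of beads connected by
#' harmonic springs along a ring or linear backbone, with no excluded
#' volume or hydrodynamics. This free-draining model is chosen because
#' its orientational correlations are exactly solvable: the diameter or
#' end-to-end vector relaxes as a known finite sum of exponentials (see
#' [rouse_ring_diameter_modes()]), providing analytic ground truth for
#' the multi-exponential fitting stage.
#'
#' @param topology `"ring"` or `"linear"`.
#' @param n_beads bead count N (>= 3 for rings).
#' @param k spring constant, kBT/nm^2.
#' @param zeta bead friction coefficient, kBT*ns/nm^2.
#' @param dt integration step, ns; must satisfy `dt < zeta / (4 k)` for a
#'   stable, accurate discretization of the stiffest mode.
#' @param n_steps number of production steps after warm-up.
#' @param save_stride store every `save_stride`-th step.
#' @param seed RNG seed.
#' @param warmup_steps equilibration steps discarded before production;
#'   default ten times the slowest mode time.
#' @return A list of class `rouse_spec`.
#' @export
rouse_spec <- function(topology = c("ring", "linear"), n_beads, k, zeta,
                       dt, n_steps, save_stride = 1L, seed = 1L,
                       warmup_steps = NULL) {
  topology <- match.arg(topology)
  n_beads <- as.integer(n_beads)
  if (topology == "ring" && n_beads < 3L)
    stop_ringhet("rings need at least 3 beads", class = "ringhet_spec_error")
  if (topology == "linear" && n_beads < 2L)
    stop_ringhet("linear chains need at least 2 beads",
                 class = "ringhet_spec_error")
  if (!is_scalar_number(k) || k <= 0 || !is_scalar_number(zeta) || zeta <= 0)
    stop_ringhet("k and zeta must be positive", class = "ringhet_spec_error")
  bound <- zeta / (4 * k)
  if (!is_scalar_number(dt) || dt <= 0 || dt >= bound)
    stop_ringhet("unstable time step: dt must satisfy dt < zeta/(4k) = ",
                 signif(bound, 4), " ns", class = "ringhet_spec_error")
  ## slowest internal mode time sets the default equilibration length
  tau_slow <- if (topology == "ring")
    zeta / (4 * k * sin(pi / n_beads)^2)
  else
    zeta / (4 * k * sin(pi / (2 * n_beads))^2)
  warmup_steps <- as.integer(warmup_steps %||% ceiling(10 * tau_slow / dt))
  structure(list(topology = topology, n_beads = n_beads, k = k, zeta = zeta,
                 dt = dt, n_steps = as.integer(n_steps),
                 save_stride = as.integer(save_stride),
                 seed = as.integer(seed), warmup_steps = warmup_steps,
                 tau_slow = tau_slow),
            class = "rouse_spec")
}

#' Simulate a free-draining bead-spring chain
#'
#' @param spec a [rouse_spec()].
#' @return A [trajectory()] containing one molecule (`mol1`) with
#'   `dt_frame = dt * save_stride`; the generator's seed, warm-up length
#'   and stride are echoed in the trajectory system label.
#' @export
generate_rouse_chain <- function(spec) {
  stopifnot(inherits(spec, "rouse_spec"))
  N <- spec$n_beads
  a <- spec$k * spec$dt / spec$zeta
  noise_sd <- sqrt(2 * spec$dt / spec$zeta)
  ring <- spec$topology == "ring"
  ip <- c(2:N, 1L); im <- c(N, 1:(N - 1L))
  set.seed(spec$seed)
  r <- matrix(stats::rnorm(N * 3L, sd = sqrt(1 / spec$k)), N, 3L)
  step <- function(r) {
    if (ring) {
      lap <- r[ip, , drop = FALSE] + r[im, , drop = FALSE] - 2 * r
    } else {
      lap <- matrix(0, N, 3L)
      lap[2:(N - 1L), ] <- r[3:N, , drop = FALSE] +
        r[1:(N - 2L), , drop = FALSE] - 2 * r[2:(N - 1L), , drop = FALSE]
      lap[1L, ] <- r[2L, ] - r[1L, ]
      lap[N, ] <- r[N - 1L, ] - r[N, ]
    }
    r + a * lap + matrix(stats::rnorm(N * 3L), N, 3L) * noise_sd
  }
  for (s in seq_len(spec$warmup_steps)) r <- step(r)
  n_frames <- spec$n_steps %/% spec$save_stride + 1L
  coords <- array(NA_real_, c(n_frames, N, 3L))
  coords[1L, , ] <- r
  f <- 1L
  for (s in seq_len(spec$n_steps)) {
    r <- step(r)
    if (s %% spec$save_stride == 0L) {
      f <- f + 1L
      coords[f, , ] <- r
    }
  }
  sys <- system_spec(
    data.frame(molecule_id = "mol1", kind = spec$topology, n_beads = N),
    dt_frame = spec$dt * spec$save_stride,
    label = sprintf("bead-spring %s N=%d k=%g zeta=%g seed=%d warmup=%d stride=%d",
                    spec$topology, N, spec$k, spec$zeta, spec$seed,
                    spec$warmup_steps, spec$save_stride))
  trajectory(coords[seq_len(f), , , drop = FALSE], sys)
}

#' Analytic diameter-vector relaxation modes of a harmonic ring
#'
#' For a free-draining harmonic ring of N beads (spring constant k,
#' friction zeta), the normalized autocorrelation of the raw diameter
#' vector \eqn{d_i = r_{i+m} - r_i} is an exact finite sum of
#' exponentials over the ring's discrete Fourier modes p = 1..N-1:
#' \deqn{C_d(t) = \sum_p w_p e^{-t/\tau_p},\qquad
#'   \tau_p = \frac{\zeta}{4k\sin^2(p\pi/N)},\qquad
#'   w_p \propto \frac{\sin^2(p m \pi/N)}{\sin^2(p\pi/N)},}
#' with the weights normalized to sum to 1. The mode times are
#' independent of the bead offset m; the offset only redistributes the
#' weights.
#'
#' @param n_beads ring size N.
#' @param k spring constant, kBT/nm^2.
#' @param zeta bead friction, kBT*ns/nm^2.
#' @param offset contour offset m of the diameter pairing; default
#'   `N/2 - 1` as in [diameter_series()].
#' @return Data frame with columns `p`, `tau_ns`, `weight` (weights sum
#'   to 1, rows with zero weight dropped).
#' @seealso [rouse_ring_diameter_tacf()]
#' @export
rouse_ring_diameter_modes <- function(n_beads, k, zeta, offset = NULL) {
  N <- as.integer(n_beads)
  m <- as.integer(offset %||% (N %/% 2L - 1L))
  p <- seq_len(N - 1L)
  tau <- zeta / (4 * k * sin(p * pi / N)^2)
  w <- sin(p * m * pi / N)^2 / sin(p * pi / N)^2
  keep <- w > 1e-12
  data.frame(p = p[keep], tau_ns = tau[keep],
             weight = w[keep] / sum(w[keep]))
}

#' @rdname rouse_ring_diameter_modes
#' @param t lag times, ns.
#' @return `rouse_ring_diameter_tacf()` returns \eqn{C_d(t)} evaluated at
#'   `t`.
#' @export
rouse_ring_diameter_tacf <- function(t, n_beads, k, zeta, offset = NULL) {
  md <- rouse_ring_diameter_modes(n_beads, k, zeta, offset)
  drop(exp(-outer(t, 1 / md$tau_ns)) %*% md$weight)
}

#' Specification of a designed fast/slow mixture ensemble
#'
#' A finite mixture of orientational relaxation populations emulating the
#' phenomenology of ring-linear blends, where unthreaded or singly
#' threaded rings relax like rings in their own melt while multiply
#' threaded rings relax much slower. Each population decays either
#' exponentially with time constant `tau_ns` (implemented as rotational
#' diffusion with \eqn{D_r = 1/(2\tau)}) or as a KWW stretched
#' exponential (implemented as a deterministic time-dilation of a
#' unit-exponential diffusion clock -- a sampling surrogate with the
#' prescribed decay law, not a physical model). The warped clock is
#' non-stationary (its rate slows with elapsed time), so a kww
#' population's prescribed curve is realized by correlations measured
#' from the initial time origin; multi-origin averaging biases it upward.
#' Exponential populations are stationary and origin-average cleanly.
#'
#' @param populations list of population descriptors, each a list with
#'   `weight` (positive; weights are normalized to sum to 1), `kind`
#'   (`"exponential"` or `"kww"`), `tau_ns`, and for kww populations
#'   `beta` in (0, 1].
#' @param n_molecules ensemble size.
#' @param dt frame spacing, ns.
#' @param n_frames frames per molecule.
#' @param seed RNG seed.
#' @param n_tracers independent tracer vectors per molecule (default 1).
#'   Several tracers emulate the multiple diameter tracers of a real ring
#'   and sharpen per-molecule relaxation-time estimates.
#' @return A list of class `mixture_spec`.
#' @export
mixture_spec <- function(populations, n_molecules, dt, n_frames, seed,
                         n_tracers = 1L) {
  if (!is.list(populations) || length(populations) == 0L)
    stop_ringhet("populations must be a non-empty list",
                 class = "ringhet_spec_error")
  w <- vapply(populations, function(p) as.numeric(p$weight %||% NA_real_), 0)
  if (any(!is.finite(w)) || any(w <= 0))
    stop_ringhet("every population needs a positive weight",
                 class = "ringhet_spec_error")
  for (p in populations) {
    kind <- p$kind %||% "exponential"
    if (!kind %in% c("exponential", "kww"))
      stop_ringhet("unknown population kind '", kind, "'",
                   class = "ringhet_spec_error")
    if (!is_scalar_number(p$tau_ns %||% NA_real_) || p$tau_ns <= 0)
      stop_ringhet("every population needs a positive tau_ns",
                   class = "ringhet_spec_error")
    if (kind == "kww") {
      b <- p$beta %||% NA_real_
      if (!is_scalar_number(b) || b <= 0 || b > 1)
        stop_ringhet("kww populations need beta in (0, 1]",
                     class = "ringhet_spec_error")
    }
  }
  if (!is_scalar_number(dt) || dt <= 0 || n_frames < 2L)
    stop_ringhet("dt must be positive and n_frames >= 2",
                 class = "ringhet_spec_error")
  n_tracers <- as.integer(n_tracers)
  if (n_tracers < 1L)
    stop_ringhet("n_tracers must be >= 1", class = "ringhet_spec_error")
  structure(list(populations = populations, weights = w / sum(w),
                 n_molecules = as.integer(n_molecules), dt = dt,
                 n_frames = as.integer(n_frames), seed = as.integer(seed),
                 n_tracers = n_tracers),
            class = "mixture_spec")
}

#' Generate a designed mixture of relaxation populations
#'
#' Molecules are assigned to populations by a seeded categorical draw;
#' each then performs a spherical random walk whose clock realizes the
#' population's decay law. The per-molecule ground-truth assignment is
#' returned alongside the series, so downstream recovery (KWW beta,
#' multi-exponential weights, tail fractions, medians) can be checked
#' against design.
#'
#' @param spec a [mixture_spec()].
#' @return A list with `series` (list of single-tracer
#'   `orientation_series`) and `ground_truth` (data frame with
#'   `molecule_id`, `population`, `kind`, `tau_ns`, `beta`,
#'   `tau0_ns` -- the population's exact terminal time).
#' @export
generate_mixture_ensemble <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  set.seed(spec$seed)
  assign <- sample.int(length(spec$populations), spec$n_molecules,
                       replace = TRUE, prob = spec$weights)
  t_grid <- (seq_len(spec$n_frames) - 1) * spec$dt
  ## per-molecule clock increments: variance of each tangent-plane step
  ds <- matrix(NA_real_, spec$n_frames - 1L, spec$n_molecules)
  gt_tau <- numeric(spec$n_molecules)
  gt_beta <- numeric(spec$n_molecules)
  gt_kind <- character(spec$n_molecules)
  gt_tau0 <- numeric(spec$n_molecules)
  for (m in seq_len(spec$n_molecules)) {
    p <- spec$populations[[assign[m]]]
    kind <- p$kind %||% "exponential"
    if (kind == "exponential") {
      ## D_r = 1/(2 tau): C(t) = exp(-2 D_r t) = exp(-t/tau)
      ds[, m] <- spec$dt / p$tau_ns
      gt_beta[m] <- 1
      gt_tau0[m] <- p$tau_ns
    } else {
      ## warped clock s(t) = (t/tau)^beta with unit-rate diffusion:
      ## C(t) = exp(-s(t)) = exp(-(t/tau)^beta)
      s <- (t_grid / p$tau_ns)^p$beta
      ds[, m] <- diff(s)
      gt_beta[m] <- p$beta
      gt_tau0[m] <- tau0_from_kww(p$tau_ns, p$beta)
    }
    gt_tau[m] <- p$tau_ns
    gt_kind[m] <- kind
  }
  if (max(ds) > 0.1)
    stop_ringhet("a population's per-frame angular step variance exceeds ",
                 "0.1 (discretization bias bound); reduce dt relative to ",
                 "the fastest tau", class = "ringhet_spec_error")
  K <- spec$n_tracers
  ## tracer walkers of one molecule share its clock but are independent
  ds_all <- ds[, rep(seq_len(spec$n_molecules), each = K), drop = FALSE]
  u <- sphere_walk(spec$n_molecules * K, spec$n_frames, ds_all, spec$seed + 1L)
  ids <- sprintf("mol_%04d", seq_len(spec$n_molecules))
  series <- lapply(seq_len(spec$n_molecules), function(m) {
    cols <- (m - 1L) * K + seq_len(K)
    new_orientation_series(u[, cols, , drop = FALSE], "end_to_end", spec$dt,
                           ids[m])
  })
  list(series = series,
       ground_truth = data.frame(molecule_id = ids, population = assign,
                                 kind = gt_kind, tau_ns = gt_tau,
                                 beta = gt_beta, tau0_ns = gt_tau0))
}
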