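## Shared fixtures, all built in code.

## One ring molecule system.
ring_system <- function(n_beads, dt_frame = 0.1, id = "r1") {
  system_spec(data.frame(molecule_id = id, kind = "ring", n_beads = n_beads),
              dt_frame = dt_frame)
}

linear_system <- function(n_beads, dt_frame = 0.1, id = "l1") {
  system_spec(data.frame(molecule_id = id, kind = "linear", n_beads = n_beads),
              dt_frame = dt_frame)
}

## Random-coordinate trajectory for a given system.
random_trajectory <- function(system, n_frames, seed = 1) {
  set.seed(seed)
  nb <- total_beads(system)
  trajectory(array(rnorm(n_frames * nb * 3), c(n_frames, nb, 3)), system)
}

## Straight 3-bead chain along +x, identical in every frame.
straight_chain_trajectory <- function(n_frames = 4) {
  sys <- linear_system(3)
  coords <- array(0, c(n_frames, 3, 3))
  coords[, , 1] <- matrix(rep(c(0, 1, 2), each = n_frames), n_frames, 3)
  trajectory(coords, sys)
}

## N=4 ring on the unit square in the xy plane, static.
square_ring_trajectory <- function(n_frames = 2) {
  sys <- ring_system(4)
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  coords <- array(NA_real_, c(n_frames, 4, 3))
  for (f in seq_len(n_frames)) coords[f, , ] <- sq
  trajectory(coords, sys)
}

## Uniformly random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

## Apply a rotation (and optional translation) to a whole trajectory.
transform_trajectory <- function(traj, R = diag(3), shift = c(0, 0, 0)) {
  d <- dim(traj$coordinates)
  out <- traj$coordinates
  for (f in seq_len(d[1]))
    out[f, , ] <- traj$coordinates[f, , ] %*% t(R) +
      matrix(shift, d[2], 3, byrow = TRUE)
  trajectory(out, traj$system)
}

## Tabulated decay curves as TACF objects.
kww_curve <- function(tau, beta, t) tacf_curve(t, exp(-(t / tau)^beta))

multiexp_curve <- function(taus, As, t) {
  vals <- drop(exp(-outer(t, 1 / taus)) %*% As)
  tacf_curve(t, vals / vals[1])
}

## Log-spaced lag grid starting at 0.
log_grid <- function(lo, hi, n) c(0, exp(seq(log(lo), log(hi), length.out = n)))

## Pure R-2k melt three-mode parameter set used across fitting tests.
r2k_modes <- list(tau = c(0.10, 1.1, 10), A = c(0.06, 0.17, 0.77))
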