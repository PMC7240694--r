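## Orientation-vector extraction: end-to-end vectors for linear chains,
## the full family of diameter vectors for rings. All vectors are
## normalized to unit length; a zero-length raw vector is an error, never
## silently normalized.

new_orientation_series <- function(vectors, vector_kind, dt_frame,
                                   molecule_id = NA_character_) {
  structure(
    list(vectors = vectors, vector_kind = vector_kind,
         dt_frame = dt_frame, molecule_id = molecule_id),
    class = "orientation_series")
}

#' @export
print.orientation_series <- function(x, ...) {
  d <- dim(x$vectors)
  cat("Orientation series (", x$vector_kind, ")", sep = "")
  if (!is.na(x$molecule_id)) cat(" for molecule ", x$molecule_id, sep = "")
  cat(": ", d[1], " frames x ", d[2], " tracer vector(s), dt_frame = ",
      x$dt_frame, " ns\n", sep = "")
  invisible(x)
}

## Normalize an (n_frames, n_vectors, 3) array of raw vectors to unit
## length, erroring on the first degenerate (near-zero) vector.
normalize_vectors <- function(raw, what, molecule_id) {
  nrm <- sqrt(raw[, , 1]^2 + raw[, , 2]^2 + raw[, , 3]^2)
  nrm <- matrix(nrm, nrow = dim(raw)[1])
  if (any(nrm < 1e-12)) {
    bad <- which(nrm < 1e-12, arr.ind = TRUE)[1L, ]
    stop_ringhet("degenerate ", what, " for molecule ", molecule_id,
                 " at frame ", bad[1L] - 1L, " (vector index ", bad[2L] - 1L,
                 "): zero length", class = "ringhet_degenerate_error")
  }
  raw / array(rep(nrm, 3L), dim(raw))
}

#' End-to-end orientation series of a linear chain
#'
#' The unit vector along the chain end-to-end vector, pointing from the
#' first bead to the last bead, one vector per frame.
#'
#' @param traj a [trajectory()].
#' @param molecule_id id of a linear molecule in the trajectory's system
#'   spec.
#' @return An `orientation_series` with one tracer vector
#'   (`vector_kind = "end_to_end"`).
#' @seealso [diameter_series()]
#' @export
end_to_end_series <- function(traj, molecule_id) {
  stopifnot(inherits(traj, "trajectory"))
  sl <- molecule_slice(traj$system, molecule_id)
  if (sl$kind != "linear")
    stop_ringhet("molecule '", molecule_id, "' is a ", sl$kind,
                 "; end-to-end vectors are defined for linear chains only",
                 class = "ringhet_kind_error")
  xyz <- molecule_coordinates(traj, molecule_id)
  raw <- xyz[, sl$n_beads, , drop = FALSE] - xyz[, 1L, , drop = FALSE]
  u <- normalize_vectors(raw, "end-to-end vector", molecule_id)
  new_orientation_series(u, "end_to_end", traj$system$dt_frame,
                         as.character(molecule_id))
}

#' Diameter-vector orientation series of a ring
#'
#' For a ring of N beads (N even), the diameter vectors connect bead pairs
#' `offset` bonds apart along the contour; the default offset is
#' `N/2 - 1`, i.e. beads roughly half a contour apart. All N cyclic
#' placements are used, giving N directed unit vectors per frame; each
#' placement index is a consistent tracer over time (same bead pair in
#' every frame), so per-tracer TACFs are sign-consistent. Vectors are
#' directed (not head-tail symmetrized).
#'
#' Odd N is rejected: half-contour pairing is only defined for even rings,
#' and silent rounding would change the observable.
#'
#' @param traj a [trajectory()].
#' @param molecule_id id of a ring molecule.
#' @param offset contour separation, in bonds, between the paired beads;
#'   defaults to `N/2 - 1`. Exposed because the half-contour pairing
#'   convention admits nearby variants (`N/2 - 1`, `N/2`); the default
#'   maximizes statistics by enumerating every cyclic placement.
#' @return An `orientation_series` with N tracer vectors
#'   (`vector_kind = "diameter"`).
#' @export
diameter_series <- function(traj, molecule_id, offset = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  sl <- molecule_slice(traj$system, molecule_id)
  if (sl$kind != "ring")
    stop_ringhet("molecule '", molecule_id, "' is a ", sl$kind,
                 "; diameter vectors are defined for rings only",
                 class = "ringhet_kind_error")
  N <- sl$n_beads
  if (N %% 2L != 0L)
    stop_ringhet("ring '", molecule_id, "' has odd bead count N = ", N,
                 "; diameter vectors require even N",
                 class = "ringhet_odd_ring_error")
  offset <- as.integer(offset %||% (N %/% 2L - 1L))
  if (offset < 1L || offset >= N)
    stop_ringhet("offset must be in [1, N-1]", class = "ringhet_value_error")
  xyz <- molecule_coordinates(traj, molecule_id)
  ## pair (i, i + offset mod N) for i = 0..N-1, 0-based
  partner <- ((seq_len(N) - 1L + offset) %% N) + 1L
  raw <- xyz[, partner, , drop = FALSE] - xyz
  u <- normalize_vectors(raw, "diameter vector", molecule_id)
  s <- new_orientation_series(u, "diameter", traj$system$dt_frame,
                              as.character(molecule_id))
  s$pairs <- cbind(from = seq_len(N) - 1L, to = partner - 1L)
  s
}

#' Stack several orientation series into one multi-tracer series
#'
#' Concatenates the tracer dimension of series that share a frame grid,
#' e.g. to treat the molecules of an ensemble as tracers of a single
#' series so that one [molecule_tacf()] call averages over all of them.
#'
#' @param series_list list of `orientation_series` with identical frame
#'   counts and `dt_frame`.
#' @return A single `orientation_series`.
#' @export
stack_series <- function(series_list) {
  stopifnot(length(series_list) >= 1L,
            all(vapply(series_list, inherits, TRUE, "orientation_series")))
  nf <- vapply(series_list, function(s) dim(s$vectors)[1], integer(1))
  dt <- vapply(series_list, function(s) s$dt_frame, numeric(1))
  if (length(unique(nf)) != 1L || length(unique(dt)) != 1L)
    stop_ringhet("all series must share frame count and dt_frame to be stacked",
                 class = "ringhet_value_error")
  nv <- vapply(series_list, function(s) dim(s$vectors)[2], integer(1))
  out <- array(NA_real_, c(nf[1], sum(nv), 3L))
  at <- 0L
  for (s in series_list) {
    k <- dim(s$vectors)[2]
    out[, at + seq_len(k), ] <- s$vectors
    at <- at + k
  }
  new_orientation_series(out, series_list[[1L]]$vector_kind, dt[1])
}

#' Export an orientation series as a data frame
#'
#' @param x an `orientation_series`.
#' @param ... unused.
#' @return Data frame with columns `frame`, `molecule_id`, `vector_index`
#'   (0-based), `ux`, `uy`, `uz`.
#' @export
as.data.frame.orientation_series <- function(x, ...) {
  d <- dim(x$vectors)
  data.frame(
    frame = rep(seq_len(d[1]) - 1L, times = d[2]),
    molecule_id = x$molecule_id,
    vector_index = rep(seq_len(d[2]) - 1L, each = d[1]),
    ux = as.vector(x$vectors[, , 1]),
    uy = as.vector(x$vectors[, , 2]),
    uz = as.vector(x$vectors[, , 3]))
}
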