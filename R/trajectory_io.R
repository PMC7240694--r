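#' Construct a trajectory object
#'
#' The canonical in-memory trajectory: a dense coordinate array of shape
#' (frames, beads, 3) in nm, paired with the [system_spec()] that declares
#' how beads partition into molecules. Frame times are derived as
#' `frame_index * dt_frame` (first frame at t = 0). Coordinates must be
#' finite and already unwrapped (continuous molecule images); the package
#' performs no periodic-image reconstruction.
#'
#' @param coordinates numeric array `(n_frames, total_beads, 3)` in nm.
#' @param system a [system_spec()]; its total bead count must match.
#' @return An object of class `trajectory` with elements `coordinates`,
#'   `system` and `frame_times` (ns).
#' @export
trajectory <- function(coordinates, system) {
  stopifnot(inherits(system, "system_spec"))
  d <- dim(coordinates)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop_ringhet("coordinates must be an (n_frames, n_beads, 3) array",
                 class = "ringhet_format_error")
  if (d[1] < 1L)
    stop_ringhet("trajectory must contain at least one frame",
                 class = "ringhet_format_error")
  if (d[2] != total_beads(system))
    stop_ringhet("coordinate array has ", d[2], " beads per frame but the ",
                 "system spec declares ", total_beads(system),
                 class = "ringhet_format_error")
  if (!all(is.finite(coordinates)))
    stop_ringhet("coordinates contain non-finite values",
                 class = "ringhet_format_error")
  structure(
    list(coordinates = coordinates, system = system,
         frame_times = (seq_len(d[1]) - 1) * system$dt_frame),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coordinates)
  cat("Trajectory: ", d[1], " frames x ", d[2], " beads, dt_frame = ",
      x$system$dt_frame, " ns (", round(x$frame_times[d[1]], 4),
      " ns total)\n", sep = "")
  invisible(x)
}

#' @export
dim.trajectory <- function(x) dim(x$coordinates)

## Coordinates of one molecule: array (n_frames, n_beads, 3).
molecule_coordinates <- function(traj, molecule_id) {
  sl <- molecule_slice(traj$system, molecule_id)
  traj$coordinates[, sl$start:sl$end, , drop = FALSE]
}

#' Read a multi-frame XYZ trajectory
#'
#' Standard XYZ layout per frame: an atom-count line, a comment line, then
#' one `symbol x y z` line per bead. Coordinates are interpreted as nm.
#' Bead order within a frame must follow the system spec's molecule order.
#' Frame indices in error messages are 0-based, matching the internal bead
#' indexing convention.
#'
#' @param path path to an XYZ file.
#' @param system a [system_spec()]; each frame must contain exactly
#'   `total_beads(system)` beads.
#' @return A [trajectory()].
#' @seealso [write_xyz_trajectory()]
#' @export
read_xyz_trajectory <- function(path, system) {
  stopifnot(inherits(system, "system_spec"))
  lines <- readLines(path)
  nb <- total_beads(system)
  n_total <- length(lines)
  ## trailing blank lines are tolerated
  while (n_total > 0L && !nzchar(trimws(lines[n_total]))) n_total <- n_total - 1L
  block <- nb + 2L
  if (n_total == 0L)
    stop_ringhet("empty XYZ file", class = "ringhet_format_error")
  n_frames <- (n_total + block - 1L) %/% block
  coords <- array(NA_real_, c(n_frames, nb, 3L))
  for (f in seq_len(n_frames)) {
    base <- (f - 1L) * block
    declared <- suppressWarnings(as.integer(trimws(lines[base + 1L])))
    if (is.na(declared) || declared != nb)
      stop_ringhet("format error at frame ", f - 1L, ": frame declares '",
                   trimws(lines[base + 1L]), "' atoms but the system spec ",
                   "requires ", nb, class = "ringhet_format_error")
    if (base + block > n_total)
      stop_ringhet("format error at frame ", f - 1L,
                   ": file ends mid-frame", class = "ringhet_format_error")
    body <- lines[base + 2L + seq_len(nb)]
    fields <- strsplit(trimws(body), "[[:space:]]+")
    for (b in seq_len(nb)) {
      fl <- fields[[b]]
      if (length(fl) < 4L)
        stop_ringhet("parse error at line ", base + 2L + b,
                     ": expected 'symbol x y z'", class = "ringhet_parse_error")
      xyz <- suppressWarnings(as.numeric(fl[2:4]))
      if (anyNA(xyz))
        stop_ringhet("parse error at line ", base + 2L + b,
                     ": non-numeric coordinate '",
                     paste(fl[2:4], collapse = " "), "'",
                     class = "ringhet_parse_error")
      coords[f, b, ] <- xyz
    }
  }
  trajectory(coords, system)
}

#' Write a trajectory as multi-frame XYZ
#'
#' Coordinates are printed with 6 decimal digits (noted in each frame's
#' comment line), so a write/read round trip preserves them to 1e-6 nm.
#' All beads are written with the placeholder element symbol `C`.
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  d <- dim(traj$coordinates)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(d[1])) {
    writeLines(as.character(d[2]), con)
    writeLines(sprintf("frame %d t= %.6f ns (coords in nm, 6 decimals)",
                       f - 1L, traj$frame_times[f]), con)
    writeLines(sprintf("C %.6f %.6f %.6f",
                       traj$coordinates[f, , 1],
                       traj$coordinates[f, , 2],
                       traj$coordinates[f, , 3]), con)
  }
  invisible(path)
}

RINGHET_ARCHIVE_VERSION <- 1L

#' Save or load a trajectory as a lossless native archive
#'
#' The archive bundles the coordinate array and the full system spec in a
#' single versioned RDS payload; the round trip is bit-exact. Loading
#' validates the schema tag and the presence of every required field.
#'
#' @param traj a [trajectory()].
#' @param path archive file path.
#' @return `save_trajectory()` returns `path` invisibly;
#'   `load_trajectory()` returns a [trajectory()].
#' @export
save_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  payload <- list(schema_version = RINGHET_ARCHIVE_VERSION,
                  coordinates = traj$coordinates,
                  molecules = traj$system$molecules,
                  dt_frame = traj$system$dt_frame,
                  phi_L = traj$system$phi_L,
                  molar_mass = traj$system$molar_mass,
                  label = traj$system$label)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_trajectory
#' @export
load_trajectory <- function(path) {
  payload <- readRDS(path)
  if (!is.list(payload) || is.null(payload$schema_version))
    stop_ringhet("not a ringhet trajectory archive (no schema tag)",
                 class = "ringhet_archive_error")
  if (payload$schema_version != RINGHET_ARCHIVE_VERSION)
    stop_ringhet("archive schema version ", payload$schema_version,
                 " is not supported (expected ", RINGHET_ARCHIVE_VERSION, ")",
                 class = "ringhet_archive_error")
  required <- c("coordinates", "molecules", "dt_frame")
  missing <- setdiff(required, names(payload)[!vapply(payload, is.null, TRUE)])
  if (length(missing))
    stop_ringhet("archive is missing required field(s): ",
                 paste(missing, collapse = ", "),
                 class = "ringhet_archive_error")
  sys <- system_spec(payload$molecules, dt_frame = payload$dt_frame,
                     phi_L = payload$phi_L, molar_mass = payload$molar_mass,
                     label = payload$label %||% "")
  trajectory(payload$coordinates, sys)
}
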