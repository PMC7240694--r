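#' Declare the molecular topology of a trajectory
#'
#' A system spec names every molecule in the trajectory, its architecture
#' (ring or linear), and its bead count, plus the time between stored
#' frames. Beads of one molecule occupy a contiguous slice of each frame,
#' in the order the molecules are declared.
#'
#' @param molecules data frame with columns `molecule_id` (unique character
#'   or integer ids), `kind` (`"ring"` or `"linear"`), and `n_beads`
#'   (integer bead counts; at least 3 for rings, at least 2 for linear
#'   chains).
#' @param dt_frame time between stored frames, in ns; must be positive.
#' @param phi_L optional molar fraction of the linear component in a
#'   ring-linear blend (metadata only, in `[0, 1]`).
#' @param molar_mass optional molar mass in g/mol (metadata only).
#' @param label free-text system label.
#'
#' @return An object of class `system_spec`.
#' @seealso [read_system_spec()], [read_xyz_trajectory()]
#' @examples
#' sys <- system_spec(
#'   molecules = data.frame(molecule_id = c("r1", "l1"),
#'                          kind = c("ring", "linear"),
#'                          n_beads = c(8, 5)),
#'   dt_frame = 0.1, phi_L = 0.5)
#' sys
#' @export
system_spec <- function(molecules, dt_frame, phi_L = NULL, molar_mass = NULL,
                        label = "") {
  if (!is.data.frame(molecules) ||
      !all(c("molecule_id", "kind", "n_beads") %in% names(molecules)))
    stop_ringhet("'molecules' must be a data frame with columns ",
                 "molecule_id, kind, n_beads", class = "ringhet_spec_error")
  molecules$molecule_id <- as.character(molecules$molecule_id)
  molecules$kind <- as.character(molecules$kind)
  molecules$n_beads <- as.integer(molecules$n_beads)
  if (anyDuplicated(molecules$molecule_id))
    stop_ringhet("molecule ids must be unique", class = "ringhet_spec_error")
  bad_kind <- !molecules$kind %in% c("ring", "linear")
  if (any(bad_kind))
    stop_ringhet("unknown molecule kind(s): ",
                 paste(unique(molecules$kind[bad_kind]), collapse = ", "),
                 class = "ringhet_spec_error")
  too_small <- (molecules$kind == "ring" & molecules$n_beads < 3L) |
    (molecules$kind == "linear" & molecules$n_beads < 2L)
  if (any(too_small))
    stop_ringhet("bead counts too small (rings need >= 3, linear chains >= 2) for: ",
                 paste(molecules$molecule_id[too_small], collapse = ", "),
                 class = "ringhet_spec_error")
  if (!is_scalar_number(dt_frame) || dt_frame <= 0)
    stop_ringhet("dt_frame must be a positive number (ns)",
                 class = "ringhet_spec_error")
  if (!is.null(phi_L)) {
    if (!is_scalar_number(phi_L) || phi_L < 0 || phi_L > 1)
      stop_ringhet("phi_L must lie in [0, 1]", class = "ringhet_spec_error")
  }
  structure(
    list(molecules = molecules, dt_frame = as.numeric(dt_frame),
         phi_L = phi_L, molar_mass = molar_mass, label = as.character(label)),
    class = "system_spec")
}

#' @export
print.system_spec <- function(x, ...) {
  cat("System spec", if (nzchar(x$label)) paste0(" '", x$label, "'"), "\n", sep = "")
  cat("  molecules: ", nrow(x$molecules), " (",
      sum(x$molecules$kind == "ring"), " ring, ",
      sum(x$molecules$kind == "linear"), " linear), total beads ",
      total_beads(x), "\n", sep = "")
  cat("  dt_frame: ", x$dt_frame, " ns", sep = "")
  if (!is.null(x$phi_L)) cat("; phi_L = ", x$phi_L, sep = "")
  cat("\n")
  invisible(x)
}

#' Total bead count declared by a system spec
#' @param system a [system_spec()] object.
#' @return Integer total number of beads per frame.
#' @export
total_beads <- function(system) {
  stopifnot(inherits(system, "system_spec"))
  sum(system$molecules$n_beads)
}

## Bead index range (1-based, contiguous) of one molecule within a frame.
molecule_slice <- function(system, molecule_id) {
  idx <- match(as.character(molecule_id), system$molecules$molecule_id)
  if (is.na(idx))
    stop_ringhet("unknown molecule id '", molecule_id, "'",
                 class = "ringhet_spec_error")
  ends <- cumsum(system$molecules$n_beads)
  starts <- c(1L, head(ends, -1L) + 1L)
  list(start = starts[idx], end = ends[idx],
       kind = system$molecules$kind[idx],
       n_beads = system$molecules$n_beads[idx])
}

#' Read or write a system spec as a YAML file
#'
#' The on-disk schema is a YAML mapping with keys `dt_frame_ns`, optional
#' `phi_L`, `molar_mass`, `label`, and a `molecules` sequence of mappings
#' with keys `kind`, `n_beads` and `count` (expanded to `count` molecules
#' with generated ids) or an explicit `molecule_id`.
#'
#' @param path file path.
#' @return `read_system_spec()` returns a [system_spec()];
#'   `write_system_spec()` returns `path` invisibly.
#' @export
read_system_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$molecules) || is.null(raw$dt_frame_ns))
    stop_ringhet("system spec file must define 'molecules' and 'dt_frame_ns'",
                 class = "ringhet_spec_error")
  rows <- lapply(seq_along(raw$molecules), function(i) {
    m <- raw$molecules[[i]]
    count <- m$count %||% 1L
    ids <- m$molecule_id %||%
      sprintf("%s%03d_%d", substr(m$kind %||% "m", 1, 1), i, seq_len(count))
    data.frame(molecule_id = ids, kind = m$kind,
               n_beads = m$n_beads, stringsAsFactors = FALSE)
  })
  system_spec(do.call(rbind, rows), dt_frame = raw$dt_frame_ns,
              phi_L = raw$phi_L, molar_mass = raw$molar_mass,
              label = raw$label %||% "")
}

#' @rdname read_system_spec
#' @param system a [system_spec()] object.
#' @export
write_system_spec <- function(system, path) {
  stopifnot(inherits(system, "system_spec"))
  mol <- lapply(seq_len(nrow(system$molecules)), function(i)
    list(molecule_id = system$molecules$molecule_id[i],
         kind = system$molecules$kind[i],
         n_beads = system$molecules$n_beads[i]))
  out <- list(dt_frame_ns = system$dt_frame, molecules = mol)
  if (!is.null(system$phi_L)) out$phi_L <- system$phi_L
  if (!is.null(system$molar_mass)) out$molar_mass <- system$molar_mass
  if (nzchar(system$label)) out$label <- system$label
  yaml::write_yaml(out, path)
  invisible(path)
}
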