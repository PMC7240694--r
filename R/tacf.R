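## Multi-time-origin orientational time autocorrelation functions.
## C(t) = mean over tracers and admissible time origins t0 of
## u(t0 + t) . u(t0). Because the vectors are unit by construction,
## C(0) = 1 structurally -- no normalization division is applied.
## The lag grid is the native frame grid; log-spaced thinning happens only
## at fit time so that the per-lag sampling counts stay interpretable.

new_tacf_curve <- function(lags, values, counts, scope,
                           molecule_id = NA_character_, meta = list()) {
  structure(
    list(lags = lags, values = values, counts = counts, scope = scope,
         molecule_id = molecule_id, meta = meta),
    class = "tacf_curve")
}

#' Build a TACF curve from precomputed values
#'
#' Mainly useful for feeding tabulated or analytic decay curves to the
#' fitting functions. Lags must start at 0 and increase strictly;
#' `values[1]` must be 1 (unit-vector normalization).
#'
#' @param lags lag times in ns, starting at 0, strictly increasing.
#' @param values correlation values, `|C(t)| <= 1` is not enforced here so
#'   that noisy curves can be represented, but `C(0)` must be 1 within
#'   1e-9.
#' @param counts per-lag sampling counts (default 1).
#' @param scope `"molecule"` or `"ensemble"`.
#' @param molecule_id optional molecule id for molecule-scope curves.
#' @return A `tacf_curve`.
#' @export
tacf_curve <- function(lags, values, counts = rep(1, length(lags)),
                       scope = c("molecule", "ensemble"),
                       molecule_id = NA_character_) {
  scope <- match.arg(scope)
  if (length(lags) != length(values) || length(lags) != length(counts))
    stop_ringhet("lags, values and counts must have equal length",
                 class = "ringhet_value_error")
  if (lags[1] != 0 || any(diff(lags) <= 0))
    stop_ringhet("lags must start at 0 and be strictly increasing",
                 class = "ringhet_value_error")
  if (abs(values[1] - 1) > 1e-9)
    stop_ringhet("C(0) must equal 1 (unit orientation vectors)",
                 class = "ringhet_value_error")
  if (any(counts <= 0))
    stop_ringhet("counts must be positive", class = "ringhet_value_error")
  new_tacf_curve(as.numeric(lags), as.numeric(values), as.numeric(counts),
                 scope, molecule_id)
}

#' @export
print.tacf_curve <- function(x, ...) {
  cat("TACF curve (", x$scope,
      if (!is.na(x$molecule_id)) paste0(", molecule ", x$molecule_id),
      "): ", length(x$lags), " lags over [0, ",
      round(max(x$lags), 4), "] ns\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.tacf_curve <- function(x, ...) {
  data.frame(lag_ns = x$lags, value = x$values, count = x$counts,
             scope = x$scope, molecule_id = x$molecule_id)
}

#' @export
plot.tacf_curve <- function(x, log = "x", xlab = "t (ns)",
                            ylab = expression(C(t)), ...) {
  keep <- if (grepl("x", log)) x$lags > 0 else rep(TRUE, length(x$lags))
  graphics::plot(x$lags[keep], x$values[keep], log = log, type = "l",
                 xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Multi-time-origin TACF of one orientation series
#'
#' For each lag t on the native frame grid, averages
#' \eqn{u(t_0+t)\cdot u(t_0)} over every tracer vector of the series and
#' over all admissible time origins \eqn{t_0} (stepped by
#' `origin_stride`). All origins are used by default, the standard
#' equilibrium-dynamics estimator; lags run up to `max_lag_fraction` of
#' the trajectory length because long lags average over few origins and
#' are noise-dominated.
#'
#' @param series an `orientation_series`.
#' @param origin_stride spacing, in frames, between time origins
#'   (default 1 = all origins).
#' @param max_lag_fraction largest lag as a fraction of the trajectory
#'   length, in (0, 1]; default 0.5.
#' @return A `tacf_curve` with scope `"molecule"`. `counts` holds the
#'   number of origin x tracer products averaged at each lag.
#' @export
molecule_tacf <- function(series, origin_stride = 1L, max_lag_fraction = 0.5) {
  stopifnot(inherits(series, "orientation_series"))
  d <- dim(series$vectors)
  n_frames <- d[1]; n_vec <- d[2]
  if (n_frames < 2L)
    stop_ringhet("series must span at least 2 frames",
                 class = "ringhet_value_error")
  if (!is_scalar_number(max_lag_fraction) || max_lag_fraction <= 0 ||
      max_lag_fraction > 1)
    stop_ringhet("max_lag_fraction must lie in (0, 1]",
                 class = "ringhet_value_error")
  origin_stride <- as.integer(origin_stride)
  if (origin_stride < 1L)
    stop_ringhet("origin_stride must be >= 1", class = "ringhet_value_error")
  max_lag <- floor(max_lag_fraction * (n_frames - 1L))
  u <- series$vectors
  lags <- 0:max_lag
  values <- numeric(length(lags))
  counts <- numeric(length(lags))
  for (j in seq_along(lags)) {
    L <- lags[j]
    origins <- seq.int(1L, n_frames - L, by = origin_stride)
    a <- u[origins, , , drop = FALSE]
    b <- u[origins + L, , , drop = FALSE]
    values[j] <- sum(a * b) / (length(origins) * n_vec)
    counts[j] <- length(origins) * n_vec
  }
  keep <- counts > 0
  new_tacf_curve(lags[keep] * series$dt_frame, values[keep], counts[keep],
                 scope = "molecule", molecule_id = series$molecule_id,
                 meta = list(origin_stride = origin_stride,
                             max_lag_fraction = max_lag_fraction))
}

#' Ensemble-average TACF
#'
#' Count-weighted mean of per-molecule TACF curves sharing one lag grid.
#' Alternatively accepts a list of orientation series, in which case the
#' series are stacked (all tracers pooled) and a single multi-origin TACF
#' is computed.
#'
#' @param curves list of `tacf_curve` objects on identical lag grids, or a
#'   list of `orientation_series` on identical frame grids.
#' @param ... passed to [molecule_tacf()] when series are given.
#' @return A `tacf_curve` with scope `"ensemble"`.
#' @export
ensemble_tacf <- function(curves, ...) {
  stopifnot(is.list(curves), length(curves) >= 1L)
  if (inherits(curves[[1L]], "orientation_series")) {
    out <- molecule_tacf(stack_series(curves), ...)
    out$scope <- "ensemble"
    out$molecule_id <- NA_character_
    return(out)
  }
  stopifnot(all(vapply(curves, inherits, TRUE, "tacf_curve")))
  ref <- curves[[1L]]$lags
  for (cv in curves[-1L])
    if (length(cv$lags) != length(ref) || any(abs(cv$lags - ref) > 1e-9))
      stop_ringhet("mismatched lag grids; curves are never silently resampled",
                   class = "ringhet_grid_error")
  vals <- vapply(curves, function(cv) cv$values, numeric(length(ref)))
  cnts <- vapply(curves, function(cv) cv$counts, numeric(length(ref)))
  vals <- matrix(vals, nrow = length(ref))
  cnts <- matrix(cnts, nrow = length(ref))
  tot <- rowSums(cnts)
  new_tacf_curve(ref, rowSums(vals * cnts) / tot, tot, scope = "ensemble")
}

#' First negative crossing of a TACF curve
#'
#' The terminal integration cutoff: the smallest lag at which the curve is
#' observed to cross over to negative values for the first time.
#'
#' @param curve a `tacf_curve`.
#' @return The lag time in ns, or `NA_real_` if the curve never goes
#'   negative within its window (a valid outcome, flagged downstream as a
#'   truncated integral).
#' @export
first_negative_crossing <- function(curve) {
  stopifnot(inherits(curve, "tacf_curve"))
  idx <- which(curve$values < 0)
  if (length(idx) == 0L) return(NA_real_)
  curve$lags[idx[1L]]
}
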