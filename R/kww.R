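#' Terminal relaxation time from KWW parameters
#'
#' Closed-form time integral of the stretched exponential
#' \eqn{\exp[-(t/\tau_{KWW})^\beta]}:
#' \deqn{\tau_0 = \tau_{KWW}\,\Gamma(1/\beta)/\beta.}
#' At \eqn{\beta = 1} this reduces to \eqn{\tau_0 = \tau_{KWW}}.
#'
#' @param tau_kww KWW relaxation time in ns (positive; vectorized).
#' @param beta stretching exponent in (0, 1] (vectorized).
#' @return Terminal relaxation time \eqn{\tau_0} in ns.
#' @examples
#' tau0_from_kww(7.1, 0.78)   # ~8.2 ns
#' tau0_from_kww(1, 0.5)      # exactly 2
#' @export
tau0_from_kww <- function(tau_kww, beta) {
  if (any(!is.finite(tau_kww)) || any(tau_kww <= 0))
    stop_ringhet("tau_kww must be positive", class = "ringhet_domain_error")
  if (any(!is.finite(beta)) || any(beta <= 0) || any(beta > 1))
    stop_ringhet("beta must lie in (0, 1]", class = "ringhet_domain_error")
  tau_kww * gamma(1 / beta) / beta
}

#' Control parameters for [fit_kww()]
#'
#' @param window upper lag limit (ns) of the fit window; `NULL` (default)
#'   truncates at the curve's first negative crossing, or uses the full
#'   window when the curve never crosses zero.
#' @param noise_floor curves must supply at least 10 lags with
#'   `C(t) > noise_floor` inside the window; default 0.
#' @param n_points maximum number of fit points after log-uniform thinning
#'   of the lag grid (t = 0 always kept). Equal weighting on a log-thinned
#'   grid keeps the tail decades from being swamped by the dense early grid.
#' @param weighting `"equal"` (default) or `"counts"`
#'   (weight proportional to per-lag sampling counts).
#' @param beta_min lower bound on the stretching exponent.
#' @param start_betas multistart grid over beta.
#' @param n_start_taus number of log-spaced multistart tau guesses.
#' @param seed seed for the (tiny) multistart jitter; echoed in the fit.
#' @return A list of class `kww_control`.
#' @export
kww_control <- function(window = NULL, noise_floor = 0, n_points = 200L,
                        weighting = c("equal", "counts"), beta_min = 0.05,
                        start_betas = c(0.4, 0.7, 1.0), n_start_taus = 5L,
                        seed = 20200330L) {
  structure(list(window = window, noise_floor = noise_floor,
                 n_points = as.integer(n_points),
                 weighting = match.arg(weighting), beta_min = beta_min,
                 start_betas = start_betas,
                 n_start_taus = as.integer(n_start_taus),
                 seed = as.integer(seed)),
            class = "kww_control")
}

## Select the fit window and a log-thinned weighted point set from a curve.
fit_points <- function(curve, window, n_points, weighting) {
  if (is.null(window)) {
    tmax <- first_negative_crossing(curve)
    window <- if (is.na(tmax)) max(curve$lags) else tmax
  }
  keep <- curve$lags <= window
  lags <- curve$lags[keep]; vals <- curve$values[keep]
  cnts <- curve$counts[keep]
  idx <- log_thin_indices(lags, n_points)
  w <- if (weighting == "counts") cnts[idx] / mean(cnts[idx]) else rep(1, length(idx))
  list(lags = lags[idx], values = vals[idx], weights = w, window = window)
}

#' Fit a KWW stretched exponential to a TACF curve
#'
#' Weighted nonlinear least squares of
#' \eqn{C(t) = \exp[-(t/\tau_{KWW})^\beta]} on the curve's fit window
#' (by default up to the first negative crossing), on a log-thinned point
#' set. A deterministic multistart over log-spaced \eqn{\tau} guesses and
#' a small beta grid guards against local minima; ties resolve to the
#' lowest residual, then to the earliest start. Non-convergence never
#' raises: the best-effort parameters are returned with
#' `converged = FALSE`.
#'
#' @param curve a `tacf_curve`.
#' @param control a [kww_control()].
#' @return An object of class `kww_fit` with components `tau_kww`, `beta`,
#'   `tau0` (via [tau0_from_kww()], so the closed-form identity holds to
#'   machine precision by construction), `rms_residual`, `fit_window`,
#'   `converged`, `beta_at_bound`, and the thinned `data` used.
#'   Supports [coef()], [predict()], [residuals()], [summary()] and
#'   [plot()].
#' @examples
#' t <- seq(0, 50, by = 0.1)
#' cv <- tacf_curve(t, exp(-t / 5))
#' fit <- fit_kww(cv)
#' coef(fit)
#' @export
fit_kww <- function(curve, control = kww_control()) {
  stopifnot(inherits(curve, "tacf_curve"), inherits(control, "kww_control"))
  pts <- fit_points(curve, control$window, control$n_points, control$weighting)
  usable <- sum(pts$values > control$noise_floor)
  if (usable < 10L)
    stop_ringhet("curve supplies only ", usable, " lags above the noise ",
                 "floor (", control$noise_floor, "); at least 10 required",
                 class = "ringhet_fit_error")
  tt <- pts$lags; cc <- pts$values; w <- pts$weights
  dt_min <- min(tt[tt > 0])
  tau_lo <- dt_min / 10
  tau_hi <- 1e4 * pts$window
  obj <- function(par) {
    tau <- exp(par[1L]); beta <- par[2L]
    r <- cc - exp(-(tt / tau)^beta)
    sum(w * r * r)
  }
  start_taus <- exp(seq(log(max(dt_min, pts$window / 1e3)), log(pts$window),
                        length.out = control$n_start_taus))
  set.seed(control$seed)
  jitter <- exp(stats::runif(control$n_start_taus * length(control$start_betas),
                             -0.05, 0.05))
  best <- NULL; best_val <- Inf; j <- 0L
  for (tau0_guess in start_taus) for (b0 in control$start_betas) {
    j <- j + 1L
    fit <- stats::optim(c(log(tau0_guess * jitter[j]), min(b0, 1)),
                        obj, method = "L-BFGS-B",
                        lower = c(log(tau_lo), control$beta_min),
                        upper = c(log(tau_hi), 1),
                        control = list(maxit = 500L))
    if (fit$value < best_val - 1e-15) {
      best <- fit; best_val <- fit$value
    }
  }
  tau_kww <- exp(best$par[1L]); beta <- best$par[2L]
  beta_at_bound <- beta <= control$beta_min + 1e-8
  structure(
    list(tau_kww = tau_kww, beta = beta,
         tau0 = tau0_from_kww(tau_kww, beta),
         rms_residual = sqrt(best_val / sum(w)),
         fit_window = c(0, pts$window),
         converged = best$convergence == 0L,
         beta_at_bound = beta_at_bound,
         data = data.frame(lag_ns = tt, value = cc, weight = w),
         control = control, call = match.call()),
    class = "kww_fit")
}

#' @export
coef.kww_fit <- function(object, ...) {
  c(tau_kww = object$tau_kww, beta = object$beta, tau0 = object$tau0)
}

#' @export
print.kww_fit <- function(x, digits = 4, ...) {
  cat("KWW stretched-exponential fit\n")
  cat("  tau_KWW = ", signif(x$tau_kww, digits), " ns,  beta = ",
      signif(x$beta, digits), ",  tau0 = ", signif(x$tau0, digits),
      " ns\n", sep = "")
  cat("  rms residual ", signif(x$rms_residual, 3), " on window [0, ",
      signif(x$fit_window[2], digits), "] ns",
      if (!x$converged) "  [NOT CONVERGED]",
      if (x$beta_at_bound) "  [beta at lower bound]", "\n", sep = "")
  invisible(x)
}

#' @export
summary.kww_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.kww_fit")
}

#' @export
print.summary.kww_fit <- function(x, ...) {
  print(x$fit)
  cat("  fit points: ", nrow(x$fit$data), " (log-thinned), weighting: ",
      x$fit$control$weighting, "\n", sep = "")
  cat("  residual quartiles: ",
      paste(signif(stats::quantile(residuals(x$fit)), 3), collapse = "  "),
      "\n", sep = "")
  invisible(x)
}

#' @export
predict.kww_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$lag_ns
       else if (is.data.frame(newdata)) newdata$lag_ns
       else as.numeric(newdata)
  exp(-(t / object$tau_kww)^object$beta)
}

#' @export
residuals.kww_fit <- function(object, ...) {
  object$data$value - predict(object)
}

#' @export
plot.kww_fit <- function(x, ...) {
  d <- x$data[x$data$lag_ns > 0, ]
  graphics::plot(d$lag_ns, d$value, log = "x", xlab = "t (ns)",
                 ylab = expression(C(t)), ...)
  tg <- exp(seq(log(min(d$lag_ns)), log(max(d$lag_ns)), length.out = 200))
  graphics::lines(tg, predict(x, tg), col = 2)
  graphics::legend("topright", bty = "n", legend = sprintf(
    "KWW: tau=%.3g ns, beta=%.3g", x$tau_kww, x$beta))
  invisible(x)
}

#' Per-molecule terminal relaxation time by truncated integration
#'
#' Trapezoidal integral of a molecule's TACF from t = 0 up to the first
#' lag where the curve crosses to negative values (the standard cutoff
#' for noisy terminal decays); if the curve never crosses zero inside its
#' window the full window is integrated and the result is flagged
#' truncated rather than dropped, since discarding slow molecules would
#' bias exactly the slow tail that heterogeneity analysis targets.
#'
#' @param curve a per-molecule `tacf_curve` with at least 2 lags.
#' @return An object of class `molecule_relaxation`: a list with
#'   `molecule_id`, `tau0_numeric` (ns), `t_max` (ns, `NA` if no
#'   crossing) and `truncated` flag.
#' @seealso [first_negative_crossing()], [build_ensemble()]
#' @export
tau0_numeric <- function(curve) {
  stopifnot(inherits(curve, "tacf_curve"))
  if (length(curve$lags) < 2L)
    stop_ringhet("curve needs at least 2 lags to integrate",
                 class = "ringhet_value_error")
  t_max <- first_negative_crossing(curve)
  truncated <- is.na(t_max)
  upper <- if (truncated) max(curve$lags) else t_max
  keep <- curve$lags <= upper
  val <- trapz(curve$lags[keep], curve$values[keep])
  structure(list(molecule_id = curve$molecule_id, tau0_numeric = val,
                 t_max = t_max, truncated = truncated),
            class = "molecule_relaxation")
}

#' @export
print.molecule_relaxation <- function(x, ...) {
  cat("Molecule ", x$molecule_id, ": tau0 = ", signif(x$tau0_numeric, 4),
      " ns", if (x$truncated) " (window-truncated: no zero crossing)"
      else paste0(" (integrated to t_max = ", signif(x$t_max, 4), " ns)"),
      "\n", sep = "")
  invisible(x)
}
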