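#' Control parameters for [fit_multiexp()]
#'
#' @inheritParams kww_control
#' @param max_modes hard ceiling on the mode count (default 6).
#' @param n_starts number of multistart tau initializations per fit.
#' @param seed seed for the multistart jitter; echoed in the fit.
#' @return A list of class `multiexp_control`.
#' @export
multiexp_control <- function(window = NULL, n_points = 200L,
                             weighting = c("equal", "counts"),
                             max_modes = 6L, n_starts = 8L,
                             seed = 20200330L) {
  structure(list(window = window, n_points = as.integer(n_points),
                 weighting = match.arg(weighting),
                 max_modes = as.integer(max_modes),
                 n_starts = as.integer(n_starts), seed = as.integer(seed)),
            class = "multiexp_control")
}

## Model evaluation: C(t) = sum_i A_i exp(-t / tau_i).
multiexp_eval <- function(t, tau, A) {
  drop(exp(-outer(t, 1 / tau)) %*% A)
}

#' Constrained multi-exponential decomposition of a TACF curve
#'
#' Least-squares fit of \eqn{C(t) = \sum_{i=1}^{n_m} A_i \exp(-t/\tau_i)}
#' under the physical constraints \eqn{A_i \ge 0},
#' \eqn{\sum_i A_i = 1} and \eqn{\tau_i > 0}. The amplitude sum is
#' enforced by optimizing \eqn{n_m - 1} free amplitudes with the last as
#' remainder, penalizing negative remainders; each mode's relaxation time
#' is optimized in log space. A seeded multistart over log-spaced tau
#' initializations (with small jitter) guards against local minima; modes
#' are returned tau-ascending.
#'
#' @param curve a `tacf_curve`.
#' @param n_m number of exponential modes (1 to `control$max_modes`).
#' @param control a [multiexp_control()].
#' @return An object of class `multiexp_fit` with `modes` (data frame of
#'   `tau_ns`, `amplitude`, tau-ascending), `n_m`, `rms_residual`,
#'   `fit_window`, `converged`, and the thinned `data`. Supports
#'   [coef()], [predict()], [residuals()], [summary()] and [plot()].
#' @examples
#' t <- exp(seq(log(0.01), log(50), length.out = 120))
#' cv <- tacf_curve(c(0, t), c(1, exp(-t / 3)))
#' fit <- fit_multiexp(cv, n_m = 1)
#' coef(fit)
#' @export
fit_multiexp <- function(curve, n_m, control = multiexp_control()) {
  stopifnot(inherits(curve, "tacf_curve"), inherits(control, "multiexp_control"))
  n_m <- as.integer(n_m)
  if (n_m < 1L)
    stop_ringhet("n_m must be >= 1", class = "ringhet_value_error")
  if (n_m > control$max_modes)
    stop_ringhet("n_m = ", n_m, " exceeds the configured maximum of ",
                 control$max_modes, " modes", class = "ringhet_value_error")
  pts <- fit_points(curve, control$window, control$n_points, control$weighting)
  if (length(pts$lags) < n_m * 2L + 1L)
    stop_ringhet("curve supplies too few points (", length(pts$lags),
                 ") for a ", n_m, "-mode fit", class = "ringhet_fit_error")
  tt <- pts$lags; cc <- pts$values; w <- pts$weights
  dt_min <- min(tt[tt > 0])
  log_lo <- log(dt_min / 10); log_hi <- log(1e4 * pts$window)
  sw <- sum(w)
  obj <- function(par) {
    tau <- exp(par[seq_len(n_m)])
    A_free <- if (n_m > 1L) par[n_m + seq_len(n_m - 1L)] else numeric(0)
    A_last <- 1 - sum(A_free)
    A <- c(A_free, A_last)
    r <- cc - multiexp_eval(tt, tau, A)
    sum(w * r * r) + 1e4 * sw * max(0, -A_last)^2
  }
  ## deterministic spread of start grids + seeded jitter
  set.seed(control$seed + n_m)
  span_lo <- log(max(dt_min, pts$window / 10^(n_m + 1)))
  span_hi <- log(pts$window)
  best <- NULL; best_val <- Inf
  for (s in seq_len(control$n_starts)) {
    frac <- (s - 1) / max(1L, control$n_starts - 1L)
    lo <- span_lo + 0.5 * frac * (span_hi - span_lo)
    taus0 <- seq(lo, span_hi, length.out = n_m + 1L)[seq_len(n_m)] +
      stats::runif(n_m, -0.2, 0.2)
    par0 <- c(pmin(pmax(taus0, log_lo), log_hi),
              if (n_m > 1L) rep(1 / n_m, n_m - 1L))
    fit <- try(stats::optim(par0, obj, method = "L-BFGS-B",
                            lower = c(rep(log_lo, n_m), rep(0, n_m - 1L)),
                            upper = c(rep(log_hi, n_m), rep(1, n_m - 1L)),
                            control = list(maxit = 1000L)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (fit$value < best_val - 1e-15) {
      best <- fit; best_val <- fit$value
    }
  }
  if (is.null(best))
    stop_ringhet("all multistart optimizations failed",
                 class = "ringhet_fit_error")
  tau <- exp(best$par[seq_len(n_m)])
  A_free <- if (n_m > 1L) best$par[n_m + seq_len(n_m - 1L)] else numeric(0)
  A <- c(A_free, 1 - sum(A_free))
  converged <- best$convergence == 0L && all(A > -1e-6)
  A <- pmax(A, 0); A <- A / sum(A)
  ord <- order(tau)
  tau <- tau[ord]; A <- A[ord]
  ## collapse numerically coincident modes so taus are strictly increasing
  if (n_m > 1L) {
    grp <- cumsum(c(TRUE, diff(log(tau)) > 1e-8))
    if (max(grp) < n_m) {
      A <- as.numeric(tapply(A, grp, sum))
      tau <- as.numeric(tapply(tau, grp, function(z) z[1L]))
    }
  }
  r <- cc - multiexp_eval(tt, tau, A)
  structure(
    list(modes = data.frame(tau_ns = tau, amplitude = A),
         n_m = length(tau),
         rms_residual = sqrt(sum(w * r * r) / sw),
         fit_window = c(0, pts$window), converged = converged,
         data = data.frame(lag_ns = tt, value = cc, weight = w),
         control = control, call = match.call()),
    class = "multiexp_fit")
}

#' @export
coef.multiexp_fit <- function(object, ...) {
  m <- as.matrix(object$modes)
  rownames(m) <- paste0("mode", seq_len(nrow(m)))
  m
}

#' @export
print.multiexp_fit <- function(x, digits = 4, ...) {
  cat("Multi-exponential decomposition, n_m = ", x$n_m, "\n", sep = "")
  for (i in seq_len(x$n_m))
    cat(sprintf("  mode %d: tau = %s ns, A = %s\n", i,
                signif(x$modes$tau_ns[i], digits),
                signif(x$modes$amplitude[i], digits)))
  cat("  sum(A) = ", format(sum(x$modes$amplitude), digits = 8),
      ", rms residual ", signif(x$rms_residual, 3),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  invisible(x)
}

#' @export
summary.multiexp_fit <- function(object, ...) {
  structure(list(fit = object,
                 mean_time = sum(object$modes$tau_ns * object$modes$amplitude)),
            class = "summary.multiexp_fit")
}

#' @export
print.summary.multiexp_fit <- function(x, ...) {
  print(x$fit)
  cat("  amplitude-weighted mean relaxation time sum(A_i tau_i) = ",
      signif(x$mean_time, 5), " ns\n", sep = "")
  cat("  fit window [", signif(x$fit$fit_window[1], 4), ", ",
      signif(x$fit$fit_window[2], 4), "] ns on ", nrow(x$fit$data),
      " log-thinned points\n", sep = "")
  invisible(x)
}

#' @export
predict.multiexp_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$lag_ns
       else if (is.data.frame(newdata)) newdata$lag_ns
       else as.numeric(newdata)
  multiexp_eval(t, object$modes$tau_ns, object$modes$amplitude)
}

#' @export
residuals.multiexp_fit <- function(object, ...) {
  object$data$value - predict(object)
}

#' @export
plot.multiexp_fit <- function(x, ...) {
  d <- x$data[x$data$lag_ns > 0, ]
  graphics::plot(d$lag_ns, d$value, log = "x", xlab = "t (ns)",
                 ylab = expression(C(t)), ...)
  tg <- exp(seq(log(min(d$lag_ns)), log(max(d$lag_ns)), length.out = 200))
  graphics::lines(tg, predict(x, tg), col = 2)
  graphics::legend("topright", bty = "n",
                   legend = sprintf("n_m = %d", x$n_m))
  invisible(x)
}

#' Smallest adequate number of exponential modes
#'
#' Fits 1 to `max_modes` exponential modes and returns the smallest mode
#' count that describes the curve: the first `n_m` whose residual is
#' already below `abs_tol`, or whose improvement when adding one more
#' mode falls below `rel_improvement` (relative RMS-residual change).
#' Ties resolve to fewer modes. This makes the qualitative "smallest
#' number of modes needed" criterion reproducible.
#'
#' @param curve a `tacf_curve`.
#' @param max_modes largest mode count to consider.
#' @param control a [multiexp_control()].
#' @param rel_improvement relative RMS-residual improvement below which an
#'   extra mode is judged unnecessary (default 0.1).
#' @param abs_tol RMS residual below which a fit is accepted outright
#'   (default 1e-6, i.e. numerically exact for noiseless curves).
#' @return A list with `n_m` (selected count) and `fit` (its
#'   `multiexp_fit`), plus `rms_by_n` for diagnostics.
#' @export
select_num_modes <- function(curve, max_modes = 6L,
                             control = multiexp_control(),
                             rel_improvement = 0.1, abs_tol = 1e-6) {
  max_modes <- as.integer(max_modes)
  if (max_modes < 1L)
    stop_ringhet("max_modes must be >= 1", class = "ringhet_value_error")
  fits <- vector("list", max_modes)
  rms <- rep(NA_real_, max_modes)
  get_fit <- function(n) {
    if (is.null(fits[[n]])) {
      fits[[n]] <<- fit_multiexp(curve, n, control)
      rms[n] <<- fits[[n]]$rms_residual
    }
    fits[[n]]
  }
  for (n in seq_len(max_modes)) {
    f <- get_fit(n)
    if (f$rms_residual <= abs_tol)
      return(list(n_m = n, fit = f, rms_by_n = rms[seq_len(n)]))
    if (n < max_modes) {
      f_next <- get_fit(n + 1L)
      if ((f$rms_residual - f_next$rms_residual) / f$rms_residual <
          rel_improvement)
        return(list(n_m = n, fit = f, rms_by_n = rms[seq_len(n + 1L)]))
    }
  }
  list(n_m = max_modes, fit = get_fit(max_modes), rms_by_n = rms)
}
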