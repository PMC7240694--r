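`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ringhet <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "ringhet_error")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_scalar_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x)
}

## Indices of a log-uniform thinning of a lag grid, always keeping the first
## (t = 0) and last points. Used at fit time only; TACFs keep the native grid.
log_thin_indices <- function(lags, n_max) {
  n <- length(lags)
  if (n <= n_max) return(seq_len(n))
  pos <- which(lags > 0)
  targets <- exp(seq(log(lags[pos[1L]]), log(lags[n]), length.out = n_max - 1L))
  idx <- vapply(targets, function(tt) pos[which.min(abs(log(lags[pos]) - log(tt)))], integer(1))
  sort(unique(c(1L, idx)))
}

## Trapezoidal rule on an irregular grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) stop_ringhet("trapezoidal integration needs at least 2 points",
                           class = "ringhet_value_error")
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}
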