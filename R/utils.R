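`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trapezoidal integration on a uniform time grid
#'
#' @param y numeric vector (samples) or matrix (samples in rows, one series
#'   per column).
#' @param dx spacing between samples.
#' @return `trapz`: the integral (scalar, or one value per column).
#'   `cumtrapz`: the running integral, same shape as `y`, starting at 0.
#' @keywords internal
trapz <- function(y, dx = 1) {
  if (is.matrix(y)) {
    n <- nrow(y)
    dx * (colSums(y) - 0.5 * (y[1, ] + y[n, ]))
  } else {
    n <- length(y)
    dx * (sum(y) - 0.5 * (y[1] + y[n]))
  }
}

#' @rdname trapz
#' @keywords internal
cumtrapz <- function(y, dx = 1) {
  if (is.matrix(y)) {
    n <- nrow(y)
    out <- apply(0.5 * dx * (y[-1, , drop = FALSE] + y[-n, , drop = FALSE]),
                 2, cumsum)
    if (is.null(dim(out))) out <- matrix(out, ncol = ncol(y))
    rbind(0, out)
  } else {
    c(0, cumsum(0.5 * dx * (y[-1] + y[-length(y)])))
  }
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

# linear-interpolation shift of sampled curves: value at (t - delay), zero
# before the first sample; columns of `y` share the delay
shift_curves <- function(y, dt, delay) {
  if (delay == 0) return(y)
  y <- as.matrix(y)
  n <- nrow(y)
  k <- delay / dt              # fractional frame shift
  i0 <- floor(k); w <- k - i0
  idx <- seq_len(n) - i0       # source row for each output row (upper)
  lo <- idx - 1                # source row shifted one earlier
  pick <- function(rows) {
    ok <- rows >= 1 & rows <= n
    out <- matrix(0, n, ncol(y))
    out[ok, ] <- y[rows[ok], , drop = FALSE]
    out
  }
  (1 - w) * pick(idx) + w * pick(lo)
}
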