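#' Uniformly sampled time-series signal
#'
#' Lightweight container for a uniformly sampled signal: a numeric vector of
#' samples, a start time and a sampling period, both in minutes.  Used
#' throughout the package for CGM traces, glucose rate-of-appearance (Ra)
#' and insulin-on-board (IOB) signals.
#'
#' Sample `i` (1-based) holds the value at time `t0 + (i - 1) * dt`.
#'
#' @param values numeric vector of samples (length >= 1).
#' @param t0 start time in minutes (default 0).
#' @param dt sampling period in minutes (> 0).
#' @return An object of class `uniform_signal`.
#' @examples
#' s <- uniform_signal(sin(seq(0, 2 * pi, length.out = 288)), t0 = 0, dt = 5)
#' signal_time(s)[1:3]
#' @export
uniform_signal <- function(values, t0 = 0, dt = 1) {
  if (!is.numeric(values) || length(values) < 1L)
    stop("'values' must be a numeric vector of length >= 1")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number (minutes)")
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop("'t0' must be a single finite number (minutes)")
  structure(list(values = as.numeric(values), t0 = as.numeric(t0),
                 dt = as.numeric(dt)),
            class = "uniform_signal")
}

#' @rdname uniform_signal
#' @param x a `uniform_signal`.
#' @export
signal_time <- function(x) {
  stopifnot(inherits(x, "uniform_signal"))
  x$t0 + (seq_along(x$values) - 1) * x$dt
}

#' @rdname uniform_signal
#' @param t times (minutes) at which to read the signal; must fall on the grid.
#' @export
signal_at <- function(x, t) {
  stopifnot(inherits(x, "uniform_signal"))
  i <- (t - x$t0) / x$dt
  if (any(abs(i - round(i)) > 1e-8))
    stop("requested times do not fall on the sampling grid")
  i <- round(i) + 1L
  if (any(i < 1L | i > length(x$values)))
    stop("requested times outside the signal support")
  x$values[i]
}

#' @export
print.uniform_signal <- function(x, ...) {
  cat(sprintf("<uniform_signal> %d samples, dt = %g min, t = [%g, %g] min\n",
              length(x$values), x$dt, x$t0,
              x$t0 + (length(x$values) - 1) * x$dt))
  invisible(x)
}

#' @export
length.uniform_signal <- function(x) length(x$values)

# Subsample a 1-min-grid signal at a coarser period (used to bring Ra/IOB
# onto the 5-min CGM grid).  Keeps the sample at each coarse timestamp.
subsample_signal <- function(x, dt_out) {
  stopifnot(inherits(x, "uniform_signal"))
  step <- dt_out / x$dt
  if (abs(step - round(step)) > 1e-8 || step < 1)
    stop("'dt_out' must be an integer multiple of the signal period")
  idx <- seq(1L, length(x$values), by = round(step))
  uniform_signal(x$values[idx], t0 = x$t0, dt = dt_out)
}
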