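# Zero-phase low-pass filtering.
#
# Coefficients come from signal::butter; the zero-phase application is done
# here with odd-reflection padding and steady-state initial conditions
# (matched step response), so constant signals pass through exactly and
# edge transients stay inside the discarded pad.

# Steady-state filter state for a unit-amplitude step (direct form II
# transposed), so filtering a constant c from state c * zi yields c
# immediately.
lfilter_zi <- function(b, a) {
  m <- max(length(a), length(b))
  a <- c(a, numeric(m - length(a)))
  b <- c(b, numeric(m - length(b)))
  b <- b / a[1L]; a <- a / a[1L]
  n <- m - 1L
  comp <- matrix(0, n, n)
  comp[1L, ] <- -a[-1L]
  if (n > 1L) comp[cbind(2:n, 1:(n - 1L))] <- 1
  solve(diag(n) - t(comp), b[-1L] - a[-1L] * b[1L])
}

# IIR filter, direct form II transposed, with initial state zi.
lfilter <- function(b, a, x, zi) {
  m <- max(length(a), length(b))
  a <- c(a, numeric(m - length(a)))
  b <- c(b, numeric(m - length(b)))
  b <- b / a[1L]; a <- a / a[1L]
  n <- length(x)
  y <- numeric(n)
  z <- c(zi, 0)
  nz <- m - 1L
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- b[1L] * xi + z[1L]
    for (k in seq_len(nz)) z[k] <- b[k + 1L] * xi + z[k + 1L] - a[k + 1L] * yi
    y[i] <- yi
  }
  y
}

# Forward-backward application of an IIR filter to one channel.
zero_phase <- function(b, a, x, padlen) {
  n <- length(x)
  padlen <- min(padlen, n - 1L)
  if (padlen < 1L) stop("signal too short for zero-phase filtering")
  ext <- c(2 * x[1L] - x[(padlen + 1L):2],
           x,
           2 * x[n] - x[(n - 1L):(n - padlen)])
  zi <- lfilter_zi(b, a)
  y <- lfilter(b, a, ext, zi * ext[1L])
  y <- rev(lfilter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + n)]
}

#' Zero-phase Butterworth low-pass filter
#'
#' Filters each coordinate of a trajectory forward and backward with a
#' Butterworth low-pass of the given order per pass, giving zero phase lag
#' and doubled effective order. The signal is extended by odd reflection
#' and the filter is started from its matched steady state, so constant
#' signals are preserved to machine precision and boundary transients are
#' suppressed.
#'
#' @param traj A [trajectory()] (or plain numeric vector/matrix plus
#'   `sample_rate`).
#' @param cutoff Cutoff frequency in Hz; must be below the Nyquist
#'   frequency.
#' @param order Filter order per pass (default 2).
#' @param sample_rate Required only when `traj` is not a trajectory.
#' @return Filtered object of the same shape as the input.
#' @examples
#' tr <- trajectory(seq(0, 1, by = 1/120), c(0, 0, 1))
#' lowpass(tr, 10)
#' @export
lowpass <- function(traj, cutoff, order = 2, sample_rate = NULL) {
  is_traj <- inherits(traj, "trajectory")
  if (is_traj) {
    sample_rate <- 1 / traj$dt
    x <- traj$v
  } else {
    if (is.null(sample_rate)) stop("'sample_rate' required for plain input")
    x <- as.matrix(traj)
  }
  if (!is.finite(cutoff) || cutoff <= 0) stop("'cutoff' must be positive (Hz)")
  if (cutoff >= sample_rate / 2) {
    stop(sprintf("cutoff %.4g Hz is not below the Nyquist frequency %.4g Hz",
                 cutoff, sample_rate / 2))
  }
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "low")
  b <- bf$b; a <- bf$a
  # pad generously: several filter time constants at the cutoff frequency
  padlen <- max(3L * (max(length(a), length(b)) - 1L),
                as.integer(ceiling(3 * sample_rate / cutoff)))
  y <- apply(x, 2L, function(col) zero_phase(b, a, col, padlen))
  if (is_traj) trajectory(traj$t, y, endpoint = traj$endpoint) else y
}

#' Running median filter
#'
#' Plain odd-window running median (via [stats::runmed()]), useful against
#' impulsive or mains-hum artefacts in measured force signals. Not part of
#' the reference prediction pipeline.
#'
#' @param x Numeric vector or matrix (filtered columnwise).
#' @param window Odd window length in samples.
#' @return Filtered vector/matrix of the same shape.
#' @export
median_filter <- function(x, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("'window' must be odd and >= 1")
  if (is.matrix(x)) {
    apply(x, 2L, stats::runmed, k = window, endrule = "median")
  } else {
    as.numeric(stats::runmed(x, k = window, endrule = "median"))
  }
}
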