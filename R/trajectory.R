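#' Uniformly sampled 3-vector time series
#'
#' The basic container for positions, velocities and forces in the lab frame.
#' The frame convention throughout the package is right-handed with x
#' anterior, y left-lateral, z vertical-up and the ground plane at z = 0.
#'
#' @param t Numeric vector of sample times in seconds, strictly increasing
#'   and uniformly spaced (within 1e-9 s).
#' @param v Numeric matrix with one row per sample and three columns
#'   (x, y, z). A single 3-vector is recycled to all samples.
#' @param endpoint Optional logical vector marking samples whose derivatives
#'   were obtained with one-sided stencils (set by [compute_com_force()]).
#'
#' @return An object of class `"trajectory"`: a list with elements `t`
#'   (times), `v` (n x 3 matrix), `dt` (sample interval) and `endpoint`.
#' @examples
#' tr <- trajectory(seq(0, 1, by = 0.01), c(0, 0, 1))
#' tr
#' @export
trajectory <- function(t, v, endpoint = NULL) {
  t <- as.numeric(t)
  if (length(t) < 1L) stop("trajectory needs at least one sample")
  if (is.null(dim(v))) {
    if (length(v) == 3L) {
      v <- matrix(v, nrow = length(t), ncol = 3L, byrow = TRUE)
    } else {
      stop("'v' must be an n x 3 matrix or a single 3-vector")
    }
  }
  v <- as.matrix(v)
  storage.mode(v) <- "double"
  if (ncol(v) != 3L) stop("'v' must have 3 columns (x, y, z)")
  if (nrow(v) != length(t)) {
    stop(sprintf("length mismatch: %d times but %d samples", length(t), nrow(v)))
  }
  if (anyNA(t) || any(!is.finite(t))) stop("non-finite sample times")
  if (any(!is.finite(v))) stop("non-finite trajectory values")
  dt <- NA_real_
  if (length(t) >= 2L) {
    d <- diff(t)
    if (any(d <= 0)) stop("sample times must be strictly increasing")
    if (max(d) - min(d) > 1e-9) {
      stop(sprintf("non-uniform sampling: time step varies from %.3g to %.3g s",
                   min(d), max(d)))
    }
    dt <- mean(d)
  }
  if (is.null(endpoint)) endpoint <- rep(FALSE, length(t))
  colnames(v) <- c("x", "y", "z")
  structure(list(t = t, v = v, dt = dt, endpoint = endpoint),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d samples", length(x$t)))
  if (!is.na(x$dt)) cat(sprintf(" @ %.6g Hz", 1 / x$dt))
  cat(sprintf(", t in [%.4g, %.4g] s\n", x$t[1L], x$t[length(x$t)]))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$t)

#' Subject anthropometric parameters
#'
#' @param M Total body mass in kg.
#' @param BH Body height in m.
#' @param g_mag Gravitational acceleration magnitude in m/s^2.
#'
#' @return An object of class `"subject_params"` with fields `M`, `BH`,
#'   `g_mag` and the derived body weight `BW = M * g_mag` in N.
#' @examples
#' subject_params(M = 80, BH = 1.80)
#' @export
subject_params <- function(M, BH, g_mag = 9.81) {
  if (!is.numeric(M) || length(M) != 1L || !is.finite(M) || M <= 0)
    stop("body mass 'M' must be a positive number (kg)")
  if (!is.numeric(BH) || length(BH) != 1L || !is.finite(BH) || BH <= 0)
    stop("body height 'BH' must be a positive number (m)")
  if (!is.numeric(g_mag) || length(g_mag) != 1L || !is.finite(g_mag) || g_mag <= 0)
    stop("'g_mag' must be a positive number (m/s^2)")
  structure(list(M = M, BH = BH, g_mag = g_mag, BW = M * g_mag),
            class = "subject_params")
}

#' @export
print.subject_params <- function(x, ...) {
  cat(sprintf("<subject> M = %.4g kg, BH = %.4g m, BW = %.4g N\n",
              x$M, x$BH, x$BW))
  invisible(x)
}

# Second-order finite differences on a uniformly sampled matrix (columnwise).
# Interior: central stencils; endpoints: one-sided second-order stencils.
# Columns with fewer than 4 rows fall back to copying the nearest interior
# value at the ends (n = 3) and are rejected below that.
fd_derivative <- function(x, dt, order = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L) stop("differentiation needs at least 3 samples")
  d <- matrix(NA_real_, n, ncol(x))
  i <- 2:(n - 1L)
  if (order == 1L) {
    d[i, ] <- (x[i + 1L, , drop = FALSE] - x[i - 1L, , drop = FALSE]) / (2 * dt)
    if (n >= 3L) {
      d[1L, ] <- (-3 * x[1L, ] + 4 * x[2L, ] - x[3L, ]) / (2 * dt)
      d[n, ] <- (3 * x[n, ] - 4 * x[n - 1L, ] + x[n - 2L, ]) / (2 * dt)
    }
  } else if (order == 2L) {
    d[i, ] <- (x[i + 1L, , drop = FALSE] - 2 * x[i, , drop = FALSE] +
                 x[i - 1L, , drop = FALSE]) / dt^2
    if (n >= 4L) {
      d[1L, ] <- (2 * x[1L, ] - 5 * x[2L, ] + 4 * x[3L, ] - x[4L, ]) / dt^2
      d[n, ] <- (2 * x[n, ] - 5 * x[n - 1L, ] + 4 * x[n - 2L, ] - x[n - 3L, ]) / dt^2
    } else {
      d[1L, ] <- d[2L, ]
      d[n, ] <- d[n - 1L, ]
    }
  } else stop("order must be 1 or 2")
  d
}
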