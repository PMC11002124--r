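#' Body segment set
#'
#' Bundles per-segment centre-of-mass trajectories with the dimensionless
#' mass fractions used to form the whole-body centre of mass. Mass fractions
#' are configurable input (anthropometric tables are data, not code) and
#' must sum to 1.
#'
#' @param segments Named list; each element is a list with fields
#'   `mass_fraction` (dimensionless) and `com` (a [trajectory()] of that
#'   segment's COM position in m).
#' @return An object of class `"segment_set"`.
#' @examples
#' t <- seq(0, 1, by = 0.1)
#' segs <- segment_set(list(
#'   trunk = list(mass_fraction = 0.6, com = trajectory(t, c(0, 0, 1.1))),
#'   legs  = list(mass_fraction = 0.4, com = trajectory(t, c(0, 0, 0.5)))
#' ))
#' @export
segment_set <- function(segments) {
  if (!is.list(segments) || length(segments) == 0L)
    stop("'segments' must be a non-empty list")
  if (is.null(names(segments)) || any(names(segments) == ""))
    stop("all segments must be named")
  fr <- vapply(segments, function(s) as.numeric(s$mass_fraction), numeric(1))
  if (any(!is.finite(fr)) || any(fr < 0))
    stop("mass fractions must be finite and non-negative")
  if (abs(sum(fr) - 1) > 1e-9)
    stop(sprintf("mass fractions must sum to 1 (got %.12g)", sum(fr)))
  n <- length(segments[[1L]]$com$t)
  t0 <- segments[[1L]]$com$t
  for (nm in names(segments)) {
    tr <- segments[[nm]]$com
    if (!inherits(tr, "trajectory"))
      stop(sprintf("segment '%s': 'com' must be a trajectory", nm))
    if (length(tr$t) != n)
      stop(sprintf("segment '%s': trajectory length %d does not match %d",
                   nm, length(tr$t), n))
    if (max(abs(tr$t - t0)) > 1e-9)
      stop(sprintf("segment '%s': sample times differ from the first segment", nm))
  }
  structure(list(segments = segments), class = "segment_set")
}

#' Whole-body centre of mass from segment trajectories
#'
#' The COM is the mass-fraction-weighted mean of the segment COM positions,
#' frame by frame.
#'
#' @param segments A [segment_set()].
#' @return A [trajectory()] of COM positions (m) on the shared time base.
#' @export
compute_com <- function(segments) {
  if (!inherits(segments, "segment_set")) segments <- segment_set(segments)
  segs <- segments$segments
  acc <- 0
  for (s in segs) acc <- acc + s$mass_fraction * s$com$v
  trajectory(segs[[1L]]$com$t, acc)
}

#' Resultant force at the centre of mass
#'
#' Applies the Newton equation for the whole body: the sum of external
#' forces equals COM acceleration times body mass. When the only external
#' forces are gravity and the ground reaction, the total GRF is
#' `F_COM(t) = M * a_COM(t) + M * g_mag * zhat`, so a subject standing
#' still yields `(0, 0, BW)`. Acceleration is obtained by second-order
#' central finite differences of the COM position (one-sided second-order
#' stencils at the endpoints, which are flagged via the returned
#' trajectory's `endpoint` field so evaluation can exclude them).
#'
#' @param com COM position [trajectory()] (m) with at least 3 samples.
#' @param subject A [subject_params()].
#' @param cutoff Optional low-pass cutoff (Hz) applied to the COM position
#'   with [lowpass()] before differentiation; `NULL` (default) disables
#'   smoothing. Use for noisy measured or synthetic kinematics.
#' @return A [trajectory()] of forces in N.
#' @examples
#' tr <- trajectory(seq(0, 1, by = 0.01), c(0, 0, 1))
#' f <- compute_com_force(tr, subject_params(80, 1.8))
#' f$v[5, ]  # (0, 0, 784.8) N: standing still
#' @export
compute_com_force <- function(com, subject, cutoff = NULL) {
  stopifnot(inherits(com, "trajectory"), inherits(subject, "subject_params"))
  n <- length(com$t)
  if (n < 3L) stop("compute_com_force needs at least 3 samples")
  if (!is.null(cutoff)) com <- lowpass(com, cutoff)
  a <- fd_derivative(com$v, com$dt, order = 2L)
  f <- subject$M * a
  f[, 3L] <- f[, 3L] + subject$BW
  ep <- rep(FALSE, n)
  ep[c(1L, n)] <- TRUE  # one-sided stencils
  trajectory(com$t, f, endpoint = ep)
}
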