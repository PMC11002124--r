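#' Contact-model parameters
#'
#' Governs the smooth transition from airborne to full ground contact of
#' each foot contact point, and when a foot counts as being in contact at
#' all.
#'
#' @param z_lim Vertical transition limit in m: a point higher than this
#'   carries no weight; full weight below 0.8 * z_lim.
#' @param v_lim Horizontal-speed transition limit in m/s: a point moving
#'   faster carries no weight; full weight below 0.15 * v_lim.
#' @param w_support_threshold Minimum total point weight for the foot to
#'   count as supporting (its COP defined).
#' @param project_cop Project the COP onto the ground plane z = 0 (default
#'   `TRUE`); the raw weighted mean has non-zero z when points hover.
#' @return An object of class `"contact_params"`.
#' @export
contact_params <- function(z_lim = 0.04, v_lim = 1.3,
                           w_support_threshold = 0.05, project_cop = TRUE) {
  if (z_lim <= 0) stop("'z_lim' must be positive")
  if (v_lim <= 0) stop("'v_lim' must be positive")
  if (w_support_threshold <= 0) stop("'w_support_threshold' must be positive")
  structure(list(z_lim = z_lim, v_lim = v_lim,
                 w_support_threshold = w_support_threshold,
                 project_cop = isTRUE(project_cop)),
            class = "contact_params")
}

#' Contact points of one foot
#'
#' @param t Sample times (s), uniform.
#' @param pos Numeric array `[frame, point, coord]` with coord = (x, y, z)
#'   of the contact-point positions in m.
#' @return An object of class `"contact_points"` with fields `t`, `pos`,
#'   `dt` and `n_cp`.
#' @export
contact_points <- function(t, pos) {
  t <- as.numeric(t)
  pos <- unclass(pos)
  if (length(dim(pos)) != 3L || dim(pos)[3L] != 3L)
    stop("'pos' must be an [frame, point, 3] array")
  if (dim(pos)[1L] != length(t))
    stop("number of frames in 'pos' does not match 't'")
  if (dim(pos)[2L] < 1L) stop("need at least one contact point")
  if (any(!is.finite(pos))) stop("non-finite contact-point positions")
  d <- diff(t)
  if (length(d) && (any(d <= 0) || max(d) - min(d) > 1e-9))
    stop("sample times must be strictly increasing and uniform")
  structure(list(t = t, pos = pos, dt = if (length(d)) mean(d) else NA_real_,
                 n_cp = dim(pos)[2L]),
            class = "contact_points")
}

#' Position transition weight of a contact point
#'
#' Smooth transition from full ground contact to no contact as a point
#' rises: 1 for `z <= 0.8 * z_lim`, 0 for `z >= z_lim`, and a raised-cosine
#' half-wave in between. The cosine expression is clamped outside the
#' transition band, the only reading under which the function is a
#' monotone smooth transition.
#'
#' @param z Vertical position(s) in m (vectorised).
#' @param params A [contact_params()].
#' @return Weight(s) in `[0, 1]`.
#' @examples
#' position_weight(c(0, 0.036, 0.04))  # 1, 0.5, 0
#' @export
position_weight <- function(z, params = contact_params()) {
  u <- z / params$z_lim
  w <- 0.5 * (cos(pi * (u - 0.8) / (1 - 0.8)) + 1)
  w[u <= 0.8] <- 1
  w[u >= 1] <- 0
  w
}

#' Velocity transition weight of a contact point
#'
#' As [position_weight()] but on the absolute horizontal velocity of the
#' point: 1 for `v_h <= 0.15 * v_lim`, 0 for `v_h >= v_lim`, raised cosine
#' in between.
#'
#' @param v_h Absolute horizontal speed(s) in m/s (vectorised,
#'   non-negative).
#' @param params A [contact_params()].
#' @return Weight(s) in `[0, 1]`.
#' @examples
#' velocity_weight(c(0, 0.7475, 1.3))  # 1, 0.5, 0
#' @export
velocity_weight <- function(v_h, params = contact_params()) {
  u <- v_h / params$v_lim
  w <- 0.5 * (cos(pi * (u - 0.15) / (1 - 0.15)) + 1)
  w[u <= 0.15] <- 1
  w[u >= 1] <- 0
  w
}

#' Per-point contact weights over a trial
#'
#' Each point's weight is the product of its position weight (on vertical
#' position) and its velocity weight (on horizontal speed, obtained by
#' central finite differences of the point positions).
#'
#' @param cps A [contact_points()] object (one foot).
#' @param params A [contact_params()].
#' @return Numeric matrix `[frame, point]` of weights in `[0, 1]`.
#' @export
contact_weights <- function(cps, params = contact_params()) {
  stopifnot(inherits(cps, "contact_points"))
  z <- cps$pos[, , 3L, drop = FALSE]
  dim(z) <- dim(cps$pos)[1:2]
  n <- dim(cps$pos)[1L]
  if (n >= 3L) {
    vx <- fd_derivative(cps$pos[, , 1L], cps$dt, order = 1L)
    vy <- fd_derivative(cps$pos[, , 2L], cps$dt, order = 1L)
    vh <- sqrt(vx^2 + vy^2)
  } else {
    vh <- matrix(0, n, cps$n_cp)  # too short to differentiate: treat as static
  }
  position_weight(z, params) * velocity_weight(vh, params)
}

#' Centre of pressure of one foot
#'
#' The COP is the weight-weighted mean of the contact-point positions,
#' projected onto the ground plane. Frames whose total weight falls below
#' `w_support_threshold` get an undefined COP (`NA`) and count as airborne.
#'
#' @param weights `[frame, point]` matrix from [contact_weights()].
#' @param cps The matching [contact_points()].
#' @param params A [contact_params()].
#' @return An object of class `"foot_contact"`: list with `t`, `cop`
#'   (n x 3, `NA` rows where undefined), `w_total`, `defined` (logical)
#'   and `weights`.
#' @export
compute_cop <- function(weights, cps, params = contact_params()) {
  stopifnot(inherits(cps, "contact_points"))
  weights <- as.matrix(weights)
  if (!all(dim(weights) == dim(cps$pos)[1:2]))
    stop("'weights' dimensions do not match the contact points")
  wt <- rowSums(weights)
  defined <- wt >= params$w_support_threshold
  cop <- matrix(NA_real_, nrow(weights), 3L,
                dimnames = list(NULL, c("x", "y", "z")))
  for (k in 1:3) {
    cop[defined, k] <- rowSums(weights[defined, , drop = FALSE] *
                                 cps$pos[defined, , k]) / wt[defined]
  }
  if (params$project_cop) cop[defined, 3L] <- 0
  structure(list(t = cps$t, cop = cop, w_total = wt, defined = defined,
                 weights = weights),
            class = "foot_contact")
}

#' Convenience: weights + COP for one foot in one call
#'
#' @inheritParams compute_cop
#' @inheritParams contact_weights
#' @return A `"foot_contact"` object (see [compute_cop()]).
#' @export
foot_contact <- function(cps, params = contact_params()) {
  compute_cop(contact_weights(cps, params), cps, params)
}

#' Classify the support phase per frame
#'
#' @param left,right `"foot_contact"` objects for the two feet.
#' @return Character vector per frame: `"double"`, `"single_L"`,
#'   `"single_R"` or `"flight"`.
#' @export
classify_support <- function(left, right) {
  stopifnot(inherits(left, "foot_contact"), inherits(right, "foot_contact"))
  if (length(left$defined) != length(right$defined))
    stop("left and right sequences have different lengths")
  ifelse(left$defined & right$defined, "double",
         ifelse(left$defined, "single_L",
                ifelse(right$defined, "single_R", "flight")))
}

#' Default 18-point sole layout
#'
#' A deterministic grid over the sole rectangle, in the foot frame (x from
#' heel 0 to toe `foot_length`, y across the sole): 2 heel points, 4
#' midfoot, two forefoot rows of 4, and 4 toe points (layout version 1).
#' The right-foot layout mirrors the left across the foot's long axis.
#'
#' @param foot_length Sole length in m.
#' @param foot_width Sole width in m.
#' @param side `"L"` or `"R"`.
#' @return An 18 x 3 matrix of local coordinates (z = 0).
#' @export
default_foot_layout <- function(foot_length = 0.25, foot_width = 0.10,
                                side = c("L", "R")) {
  side <- match.arg(side)
  if (foot_length <= 0 || foot_width <= 0)
    stop("foot dimensions must be positive")
  xf <- c(rep(0.05, 2), rep(0.35, 4), rep(0.60, 4), rep(0.78, 4), rep(0.95, 4))
  yf <- c(-0.20, 0.20,
          -0.35, -0.12, 0.12, 0.35,
          -0.45, -0.15, 0.15, 0.45,
          -0.45, -0.15, 0.15, 0.45,
          -0.35, -0.12, 0.12, 0.35)
  pts <- cbind(x = xf * foot_length, y = yf * foot_width, z = 0)
  if (side == "R") pts[, 2L] <- -pts[, 2L]
  pts
}
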