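# Synthetic trial generators.
#
# Each generator builds lab-frame kinematics (COM + per-foot contact
# points), classifies support with the package's own contact model, and
# constructs ground-truth per-foot GRFs that (a) sum to the Newton COM
# force at every frame and (b) pass through a VPP at the known true
# VPPscale on double-support frames. The truth decomposition solves the
# 3 x 2 system with qr.solve, a different numerical path from the
# production solver's closed-form normal equations, so round-trip
# agreement is a meaningful check of both.

.rotate_sagittal <- function(layout, theta) {
  # pitch the sole about the lab y-axis (positive = toe up), heel at x = 0
  xl <- layout[, 1L]
  cbind(x = cos(theta) * xl, y = layout[, 2L], z = sin(theta) * xl)
}

# contact-point global positions for one foot over all frames
# foot_x/foot_y: centre of the sole rectangle; theta: pitch; z_base: lift
.foot_point_frames <- function(layout, foot_x, foot_y, theta, z_base,
                               foot_length) {
  n <- length(foot_x)
  ncp <- nrow(layout)
  pos <- array(NA_real_, c(n, ncp, 3L))
  for (i in seq_len(n)) {
    p <- .rotate_sagittal(layout, theta[i])
    p[, 3L] <- p[, 3L] - min(p[, 3L]) + z_base[i]  # lowest point at z_base
    pos[i, , 1L] <- foot_x[i] - foot_length / 2 + p[, 1L]
    pos[i, , 2L] <- foot_y[i] + p[, 2L]
    pos[i, , 3L] <- p[, 3L]
  }
  pos
}

# ground-truth forces from a known VPPscale, via qr.solve
.construct_truth <- function(com, subject, fc_l, fc_r, labels,
                             true_vppscale) {
  f_com <- compute_com_force(com, subject)
  n <- length(com$t)
  grf_l <- matrix(0, n, 3L, dimnames = list(NULL, c("x", "y", "z")))
  grf_r <- grf_l
  neg <- 0L
  h <- true_vppscale * subject$BH
  for (i in seq_len(n)) {
    f <- f_com$v[i, ]
    if (labels[i] == "double") {
      ratio <- if (abs(f[3L]) > 1e-6 * subject$BW) com$v[i, 3L] / f[3L] else 0
      vpp <- c(com$v[i, 1:2] + ratio * f[1:2], h)
      dl <- vpp - fc_l$cop[i, ]
      dr <- vpp - fc_r$cop[i, ]
      A <- cbind(dl / sqrt(sum(dl^2)), dr / sqrt(sum(dr^2)))
      mag <- qr.solve(A, f)
      if (any(mag < 0)) neg <- neg + 1L
      grf_l[i, ] <- mag[1L] * A[, 1L]
      grf_r[i, ] <- mag[2L] * A[, 2L]
    } else if (labels[i] == "single_L") {
      grf_l[i, ] <- f
    } else if (labels[i] == "single_R") {
      grf_r[i, ] <- f
    }
  }
  if (neg > 0L)
    warning(sprintf("truth construction: %d frame(s) with a negative force magnitude", neg))
  closure <- sqrt(rowSums((grf_l + grf_r - f_com$v)^2))
  list(grf_l = grf_l, grf_r = grf_r, f_com = f_com,
       closure_err = max(closure) / subject$BW)
}

.finish_trial <- function(kind, subject, sample_rate, t, com_clean,
                          contacts_l, contacts_r, true_vppscale,
                          noise_sigma, seed, schedule = NULL,
                          cparams = contact_params()) {
  fc_l <- foot_contact(contacts_l, cparams)
  fc_r <- foot_contact(contacts_r, cparams)
  labels <- classify_support(fc_l, fc_r)
  truth <- .construct_truth(com_clean, subject, fc_l, fc_r, labels,
                            true_vppscale)
  if (truth$closure_err > 1e-9)
    warning(sprintf("truth force closure violated: max %.3g BW", truth$closure_err))
  com <- com_clean
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    com <- trajectory(t, com_clean$v +
                        matrix(stats::rnorm(3L * length(t), sd = noise_sigma),
                               ncol = 3L))
  }
  structure(list(kind = kind, subject = subject, sample_rate = sample_rate,
                 com = com, com_clean = com_clean,
                 contacts_l = contacts_l, contacts_r = contacts_r,
                 true_vppscale = true_vppscale,
                 truth_grf_l = truth$grf_l, truth_grf_r = truth$grf_r,
                 truth_f_com = truth$f_com, labels = labels,
                 closure_err = truth$closure_err,
                 noise_sigma = noise_sigma, seed = seed,
                 schedule = schedule),
            class = "vpp_trial")
}

#' @export
print.vpp_trial <- function(x, ...) {
  cat(sprintf("<vpp_trial> %s, %d frames @ %g Hz", x$kind,
              length(x$com$t), x$sample_rate))
  if (!is.null(x$true_vppscale))
    cat(sprintf(", true VPPscale %.3g", x$true_vppscale))
  if (!is.null(x$noise_sigma) && x$noise_sigma > 0)
    cat(sprintf(", COM noise sd %g m", x$noise_sigma))
  cat("\n")
  invisible(x)
}

# shared machinery for the two static-stance tasks (squat: stride = 0)
.simulate_stance <- function(kind, subject, depth, period, n_cycles, stride,
                             stance_width, true_vppscale, noise_sigma, seed,
                             sample_rate, lead_in, foot_length, foot_width) {
  stopifnot(inherits(subject, "subject_params"))
  if (depth < 0) stop("'depth' must be non-negative")
  if (period <= 0) stop("'period' must be positive")
  if (stride < 0) stop("'stride' must be non-negative")
  z0 <- 0.55 * subject$BH
  if (depth >= z0)
    stop(sprintf("depth %.3g m would push the COM below the ground (standing COM %.3g m)",
                 depth, z0))
  dt <- 1 / sample_rate
  t <- seq(0, 2 * lead_in + n_cycles * period, by = dt)
  n <- length(t)
  s <- pmin(pmax(t - lead_in, 0), n_cycles * period)
  z <- z0 - depth / 2 * (1 - cos(2 * pi * s / period))
  lay_l <- default_foot_layout(foot_length, foot_width, "L")
  lay_r <- default_foot_layout(foot_length, foot_width, "R")
  # static equilibrium: the COM stands above the centroid of the two COPs
  # (the sole layout's weight centroid is slightly anterior of the sole
  # centre), otherwise a vertical COM force could not close over the feet
  cop_x_offset <- mean(lay_l[, 1L]) - foot_length / 2
  com <- trajectory(t, cbind(cop_x_offset, 0, z))
  zero <- numeric(n)
  pos_l <- .foot_point_frames(lay_l, rep(stride / 2, n),
                              rep(stance_width / 2, n), zero, zero,
                              foot_length)
  pos_r <- .foot_point_frames(lay_r, rep(-stride / 2, n),
                              rep(-stance_width / 2, n), zero, zero,
                              foot_length)
  .finish_trial(kind, subject, sample_rate, t, com,
                contact_points(t, pos_l), contact_points(t, pos_r),
                true_vppscale, noise_sigma, seed,
                schedule = list(descent_onset = lead_in,
                                ascent_end = lead_in + n_cycles * period,
                                depth = depth, period = period))
}

#' Simulate a squat trial
#'
#' Both feet planted symmetrically about the origin, COM descending and
#' ascending along a raised-cosine profile; double support throughout.
#' Ground-truth per-foot GRFs are constructed from the VPP decomposition
#' at `true_vppscale`. Optional seeded Gaussian position noise is added to
#' the exported COM only; the truth stays clean.
#'
#' @param subject A [subject_params()].
#' @param depth Squat depth in m (COM excursion; 0 gives quiet standing).
#' @param period Duration of one descent/ascent cycle in s.
#' @param n_cycles Number of squat cycles.
#' @param true_vppscale VPPscale used to construct the ground truth.
#' @param noise_sigma Standard deviation (m) of the COM position noise.
#' @param seed RNG seed for the noise (calls `set.seed` when non-`NULL`).
#' @param sample_rate Sampling rate in Hz.
#' @param stance_width Lateral distance between foot centres in m.
#' @param lead_in Quiet standing before and after the cycles, in s.
#' @param foot_length,foot_width Sole dimensions in m (see
#'   [default_foot_layout()]).
#' @return A `"vpp_trial"` with kinematics, contact points, support
#'   labels and ground-truth per-foot GRFs.
#' @examples
#' tr <- simulate_squat(subject_params(75, 1.75), depth = 0.3)
#' tr
#' @export
simulate_squat <- function(subject, depth = 0.30, period = 3, n_cycles = 2,
                           true_vppscale = 0.9, noise_sigma = 0, seed = NULL,
                           sample_rate = 120, stance_width = 0.35,
                           lead_in = 1, foot_length = 0.25,
                           foot_width = 0.10) {
  .simulate_stance("squat", subject, depth, period, n_cycles, stride = 0,
                   stance_width, true_vppscale, noise_sigma, seed,
                   sample_rate, lead_in, foot_length, foot_width)
}

#' Simulate an inline-lunge trial
#'
#' As [simulate_squat()] but with the feet offset antero-posteriorly by
#' `stride` (left foot forward), which makes the truth's anterior force
#' components non-zero and of opposite sign between the feet whenever the
#' VPP lies between the two COPs.
#'
#' @inheritParams simulate_squat
#' @param stride Antero-posterior distance between foot centres in m;
#'   `stride = 0` reproduces [simulate_squat()] exactly.
#' @return A `"vpp_trial"`.
#' @export
simulate_lunge <- function(subject, stride = 0.60, depth = 0.25, period = 3,
                           n_cycles = 2, true_vppscale = 0.9,
                           noise_sigma = 0, seed = NULL, sample_rate = 120,
                           stance_width = 0.35, lead_in = 1,
                           foot_length = 0.25, foot_width = 0.10) {
  .simulate_stance("lunge", subject, depth, period, n_cycles, stride,
                   stance_width, true_vppscale, noise_sigma, seed,
                   sample_rate, lead_in, foot_length, foot_width)
}

#' Simulate a walking trial
#'
#' Alternating single and double support over several steps. The feet
#' progress along the line y = 0 (zero step width, so the COM force stays
#' in the span of the two pivot directions and force closure is exact);
#' each sole rolls heel-to-toe through a pitch profile, which makes the
#' contact-model COP travel forward under the foot. Single-support truth
#' is the full COM force at the stance COP; double-support truth is the
#' VPP decomposition at `true_vppscale`.
#'
#' @inheritParams simulate_squat
#' @param speed Mean forward speed in m/s.
#' @param step_length Distance between successive heel strikes in m.
#' @param ds_fraction Fraction of each step period spent in double
#'   support, in (0, 0.5).
#' @param n_steps Number of heel strikes after the first left contact
#'   (>= 3 so a full left-to-left double step exists).
#' @param z_amplitude Amplitude of the vertical COM oscillation in m.
#' @param clearance Peak swing-foot ground clearance in m.
#' @return A `"vpp_trial"`; `$schedule` holds the intended phase timing
#'   (heel strikes, toe-offs) for bookkeeping tests.
#' @export
simulate_walk <- function(subject, speed = 1.2, step_length = 0.65,
                          ds_fraction = 0.2, true_vppscale = 0.9,
                          noise_sigma = 0, seed = NULL, sample_rate = 120,
                          n_steps = 4, z_amplitude = 0.012,
                          clearance = 0.08, foot_length = 0.25,
                          foot_width = 0.10) {
  stopifnot(inherits(subject, "subject_params"))
  if (speed <= 0 || step_length <= 0) stop("'speed' and 'step_length' must be positive")
  if (ds_fraction <= 0 || ds_fraction >= 0.5)
    stop("'ds_fraction' must lie in (0, 0.5)")
  if (n_steps < 3L) stop("'n_steps' must be at least 3")
  T_step <- step_length / speed
  stance_dur <- (1 + ds_fraction) * T_step
  swing_dur <- (1 - ds_fraction) * T_step
  dt <- 1 / sample_rate
  t_end <- n_steps * T_step + ds_fraction * T_step
  t <- seq(0, t_end, by = dt)
  n <- length(t)

  # heel strikes: k = 0..n_steps at x = k * step_length; even k = left.
  # each foot also has a virtual prior stance one stride back so both feet
  # are grounded at t = 0.
  strikes <- function(parity) {
    k <- seq.int(parity - 2L, n_steps, by = 2L)
    list(time = k * T_step, x = k * step_length)
  }
  theta_hs <- 12 * pi / 180
  theta_to <- 20 * pi / 180
  foot_state <- function(st) {
    fx <- numeric(n); th <- numeric(n); zb <- numeric(n)
    for (i in seq_len(n)) {
      ti <- t[i]
      j <- findInterval(ti, st$time)  # latest strike at or before ti
      if (j < 1L) stop("walking schedule error: no stance covers trial start")
      if (ti <= st$time[j] + stance_dur || j == length(st$time)) {
        q <- min((ti - st$time[j]) / stance_dur, 1)
        fx[i] <- st$x[j]
        zb[i] <- 0
        if (q < 0.22) {
          th[i] <- theta_hs * 0.5 * (1 + cos(pi * q / 0.22))
        } else if (q > 0.72) {
          th[i] <- -theta_to * 0.5 * (1 - cos(pi * (q - 0.72) / 0.28))
        } else th[i] <- 0
      } else {
        u <- (ti - (st$time[j] + stance_dur)) / swing_dur
        h <- (1 - cos(pi * u)) / 2
        fx[i] <- st$x[j] + (st$x[j + 1L] - st$x[j]) * h
        # fast lift-off / late touchdown so the contact model's transitions
        # stay close to the scheduled toe-off and heel-strike instants
        zb[i] <- clearance *
          if (u < 0.08) (1 - cos(pi * u / 0.08)) / 2
          else if (u > 0.92) (1 + cos(pi * (u - 0.92) / 0.08)) / 2
          else 1
        th[i] <- -theta_to + (theta_hs + theta_to) * h
      }
    }
    list(x = fx, theta = th, z_base = zb)
  }
  st_l <- strikes(0L)  # left strikes at even k (incl. virtual k = -2)
  st_r <- strikes(1L)  # right strikes at odd k (incl. virtual k = -1)
  fs_l <- foot_state(st_l)
  fs_r <- foot_state(st_r)
  lay_l <- default_foot_layout(foot_length, foot_width, "L")
  lay_r <- default_foot_layout(foot_length, foot_width, "R")
  pos_l <- .foot_point_frames(lay_l, fs_l$x, numeric(n), fs_l$theta,
                              fs_l$z_base, foot_length)
  pos_r <- .foot_point_frames(lay_r, fs_r$x, numeric(n), fs_r$theta,
                              fs_r$z_base, foot_length)

  z0 <- 0.55 * subject$BH
  x_com <- -step_length / 2 + speed * t
  z_com <- z0 - z_amplitude * cos(2 * pi * t / T_step)
  com <- trajectory(t, cbind(x_com, 0, z_com))
  sched <- list(T_step = T_step, stance_dur = stance_dur,
                ds_fraction = ds_fraction,
                heel_strikes_L = st_l$time, heel_strikes_R = st_r$time,
                toe_offs_L = st_l$time + stance_dur,
                toe_offs_R = st_r$time + stance_dur)
  .finish_trial("walking", subject, sample_rate, t, com,
                contact_points(t, pos_l), contact_points(t, pos_r),
                true_vppscale, noise_sigma, seed, schedule = sched)
}
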