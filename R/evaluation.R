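#' Body-weight-normalised RMSE per force direction
#'
#' Root-mean-square error between predicted and reference per-foot GRFs,
#' computed separately for the anterior (x), lateral (y) and vertical (z)
#' directions, pooling both feet and all frames, and normalised by body
#' weight.
#'
#' @param pred_l,pred_r Predicted per-foot GRFs, n x 3 matrices (N).
#' @param ref_l,ref_r Reference per-foot GRFs, same shapes (N).
#' @param subject A [subject_params()] (provides BW).
#' @param frames Optional integer/logical index restricting which frames
#'   enter the error (e.g. a movement segment, or excluding endpoint
#'   frames).
#' @return Named numeric 3-vector (`anterior`, `lateral`, `vertical`) in
#'   BW units.
#' @export
rmse_by_direction <- function(pred_l, pred_r, ref_l, ref_r, subject,
                              frames = NULL) {
  stopifnot(inherits(subject, "subject_params"))
  pred_l <- as.matrix(pred_l); pred_r <- as.matrix(pred_r)
  ref_l <- as.matrix(ref_l); ref_r <- as.matrix(ref_r)
  if (!all(dim(pred_l) == dim(ref_l)) || !all(dim(pred_r) == dim(ref_r)) ||
      nrow(pred_l) != nrow(pred_r))
    stop("prediction and reference GRF lengths differ")
  if (!is.null(frames)) {
    pred_l <- pred_l[frames, , drop = FALSE]
    pred_r <- pred_r[frames, , drop = FALSE]
    ref_l <- ref_l[frames, , drop = FALSE]
    ref_r <- ref_r[frames, , drop = FALSE]
  }
  if (nrow(pred_l) == 0L) stop("no frames selected for RMSE")
  d2 <- rbind((pred_l - ref_l)^2, (pred_r - ref_r)^2)
  out <- sqrt(colMeans(d2)) / subject$BW
  names(out) <- c("anterior", "lateral", "vertical")
  out
}

#' Segment a trial for evaluation
#'
#' Walking: from the first frame the left foot gains ground contact
#' through the frame before its next contact (one double step). Squat and
#' inline lunge: from the first frame the (optionally smoothed) COM
#' vertical velocity drops below `-v_thresh` through the last frame it
#' exceeds `+v_thresh` (downward onset to end of rise).
#'
#' @param kind `"walking"`, `"squat"` or `"lunge"`.
#' @param com COM position [trajectory()] (m).
#' @param labels Per-frame support labels (needed for walking).
#' @param v_thresh Vertical-velocity threshold in m/s for squat/lunge.
#' @param smooth_cutoff Optional low-pass cutoff (Hz) applied to the COM
#'   before the velocity is formed; `NULL` for none.
#' @return An object of class `"movement_segment"`: list with `kind`,
#'   `start`, `end` (frame indices, inclusive) and `rule` (which rule
#'   fired).
#' @export
segment_trial <- function(kind = c("walking", "squat", "lunge"), com,
                          labels = NULL, v_thresh = 0.02,
                          smooth_cutoff = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(com, "trajectory"))
  n <- length(com$t)
  if (kind == "walking") {
    if (is.null(labels) || length(labels) != n)
      stop("walking segmentation needs per-frame support labels")
    left_on <- labels %in% c("double", "single_L")
    rises <- which(left_on & !c(FALSE, left_on[-n]))
    if (length(rises) < 2L)
      stop("segmentation failed: need two left-foot contacts for a double step")
    structure(list(kind = kind, start = rises[1L], end = rises[2L] - 1L,
                   rule = "left_contact_to_next_left_contact"),
              class = "movement_segment")
  } else {
    if (!is.null(smooth_cutoff)) com <- lowpass(com, smooth_cutoff)
    vz <- fd_derivative(com$v, com$dt, order = 1L)[, 3L]
    start <- which(vz < -v_thresh)[1L]
    up <- which(vz > v_thresh)
    if (is.na(start) || !length(up) || max(up) <= start)
      stop("segmentation failed: no downward-then-upward COM excursion found")
    structure(list(kind = kind, start = start, end = max(up),
                   rule = "com_vertical_velocity_threshold"),
              class = "movement_segment")
  }
}

#' @export
print.movement_segment <- function(x, ...) {
  cat(sprintf("<segment> %s: frames [%d, %d] (%s)\n",
              x$kind, x$start, x$end, x$rule))
  invisible(x)
}

#' Run the full prediction pipeline on a trial
#'
#' Convenience chaining for a trial object (synthetic or imported):
#' COM force by the Newton rule (optionally low-passing the COM position
#' first), per-foot contact weights and COPs, support classification, and
#' the VPP force decomposition.
#'
#' @param trial A `"vpp_trial"` (see [simulate_squat()] and friends, or
#'   [read_trial()]).
#' @param vppscale VPPscale to predict with (default: the trial's true
#'   scale if present, else 0.9).
#' @param cparams A [contact_params()].
#' @param vparams A [vpp_params()]; its `vppscale` is overridden by the
#'   `vppscale` argument.
#' @param com_cutoff Optional COM low-pass cutoff (Hz) before
#'   differentiation; recommended for noisy kinematics.
#' @return A `"vpp_solution"` (see [predict_grf()]).
#' @export
predict_trial_grf <- function(trial, vppscale = NULL,
                              cparams = contact_params(),
                              vparams = vpp_params(),
                              com_cutoff = NULL) {
  stopifnot(inherits(trial, "vpp_trial"))
  if (is.null(vppscale))
    vppscale <- if (!is.null(trial$true_vppscale)) trial$true_vppscale else 0.9
  vparams$vppscale <- vppscale
  fc_l <- foot_contact(trial$contacts_l, cparams)
  fc_r <- foot_contact(trial$contacts_r, cparams)
  labels <- classify_support(fc_l, fc_r)
  f_com <- compute_com_force(trial$com, trial$subject, cutoff = com_cutoff)
  com <- if (is.null(com_cutoff)) trial$com else lowpass(trial$com, com_cutoff)
  predict_grf(f_com, com, fc_l, fc_r, labels, vparams, trial$subject)
}

#' Sweep the VPPscale over a grid
#'
#' Runs the prediction pipeline at each grid value and scores it against
#' the trial's reference per-foot GRFs with [rmse_by_direction()] over the
#' trial's movement segment. The default grid is 0.2 to 2.0 in steps of
#' 0.1 (19 values).
#'
#' @param trial A `"vpp_trial"` carrying reference GRFs (`truth_grf_l`,
#'   `truth_grf_r`).
#' @param grid Strictly increasing vector of VPPscale values.
#' @param segment Use the trial-kind segmentation rule to restrict the
#'   scored frames (default `TRUE`; endpoint frames are always excluded).
#' @inheritParams predict_trial_grf
#' @return An object of class `"vppscale_sweep"`: list with `scales`,
#'   `rmse` (length(grid) x 3 matrix, BW), `total` (row sums), `optimum`
#'   (scale minimising `total`, ties to the smaller scale), `kind`,
#'   `frames`.
#' @export
sweep_vppscale <- function(trial, grid = seq(0.2, 2.0, by = 0.1),
                           cparams = contact_params(),
                           vparams = vpp_params(),
                           com_cutoff = NULL, segment = TRUE) {
  stopifnot(inherits(trial, "vpp_trial"))
  if (!length(grid)) stop("empty VPPscale grid")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  if (is.null(trial$truth_grf_l) || is.null(trial$truth_grf_r))
    stop("trial has no reference GRFs to sweep against")
  n <- length(trial$com$t)
  keep <- rep(TRUE, n)
  if (segment) {
    seg <- tryCatch(
      segment_trial(if (trial$kind == "walking") "walking" else trial$kind,
                    trial$com,
                    labels = trial$labels,
                    smooth_cutoff = com_cutoff),
      error = function(e) NULL)
    if (!is.null(seg)) keep <- seq_len(n) >= seg$start & seq_len(n) <= seg$end
  }
  keep[c(1L, n)] <- FALSE  # one-sided differentiation stencils
  rmse <- matrix(NA_real_, length(grid), 3L,
                 dimnames = list(NULL, c("anterior", "lateral", "vertical")))
  for (i in seq_along(grid)) {
    sol <- predict_trial_grf(trial, vppscale = grid[i], cparams = cparams,
                             vparams = vparams, com_cutoff = com_cutoff)
    rmse[i, ] <- rmse_by_direction(sol$grf_l, sol$grf_r,
                                   trial$truth_grf_l, trial$truth_grf_r,
                                   trial$subject, frames = keep)
  }
  total <- rowSums(rmse)
  structure(list(scales = grid, rmse = rmse, total = total,
                 optimum = grid[which.min(total)],
                 kind = trial$kind, frames = which(keep)),
            class = "vppscale_sweep")
}

#' @export
print.vppscale_sweep <- function(x, ...) {
  cat(sprintf("<vppscale_sweep> %s trial, %d scales in [%.2g, %.2g]\n",
              x$kind, length(x$scales), min(x$scales), max(x$scales)))
  cat(sprintf("  optimum %.2g (summed RMSE %.4g BW)\n",
              x$optimum, min(x$total)))
  invisible(x)
}

#' Select the optimal VPPscale across trials
#'
#' Reproducible replacement for a visual read-off: for each grid value the
#' three directional RMSEs are summed per trial, the median across trials
#' is taken, and the grid argmin is returned; exact ties break toward the
#' smaller scale.
#'
#' @param sweeps A single `"vppscale_sweep"` or a list of them sharing one
#'   grid.
#' @return The selected VPPscale (scalar).
#' @export
select_optimal_scale <- function(sweeps) {
  if (inherits(sweeps, "vppscale_sweep")) sweeps <- list(sweeps)
  if (!length(sweeps)) stop("empty sweep collection")
  grid <- sweeps[[1L]]$scales
  for (s in sweeps) {
    if (!inherits(s, "vppscale_sweep")) stop("all elements must be sweeps")
    if (length(s$scales) != length(grid) || max(abs(s$scales - grid)) > 1e-12)
      stop("sweeps do not share a common grid")
  }
  totals <- vapply(sweeps, function(s) s$total, numeric(length(grid)))
  med <- apply(matrix(totals, nrow = length(grid)), 1L, stats::median)
  grid[which.min(med)]  # which.min takes the first (smallest scale) on ties
}
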