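#' VPP solver parameters
#'
#' @param vppscale Dimensionless VPP height as a fraction of body height;
#'   the VPP sits at `vppscale * BH` above the ground. 0.9 is the value
#'   that minimises prediction error across walking, squat and lunge.
#' @param eps_fz Minimum `|F_COM(z)|` (N) below which the planar VPP offset
#'   is undefined and the solver falls back to placing the VPP directly
#'   above the COM. Default `NULL` means `1e-6 * BW`, resolved per call.
#' @param nonneg_policy `"clamp_reassign"` (default): a negative force
#'   magnitude is clamped to zero and the other foot refit by 1-D
#'   projection — the ground cannot pull a foot down. `"allow_negative"`
#'   keeps the raw least-squares solution.
#' @param cond_limit Maximum condition number of the 3 x 2 direction matrix
#'   before the frame is declared ill-conditioned and the force is split
#'   50/50 along the mean direction.
#' @return An object of class `"vpp_params"`.
#' @export
vpp_params <- function(vppscale = 0.9, eps_fz = NULL,
                       nonneg_policy = c("clamp_reassign", "allow_negative"),
                       cond_limit = 1e8) {
  if (!is.numeric(vppscale) || vppscale <= 0)
    stop("'vppscale' must be positive")
  if (!is.null(eps_fz) && (!is.numeric(eps_fz) || eps_fz < 0))
    stop("'eps_fz' must be non-negative")
  if (cond_limit <= 1) stop("'cond_limit' must exceed 1")
  structure(list(vppscale = vppscale, eps_fz = eps_fz,
                 nonneg_policy = match.arg(nonneg_policy),
                 cond_limit = cond_limit),
            class = "vpp_params")
}

.resolve_eps_fz <- function(params, subject) {
  if (is.null(params$eps_fz)) 1e-6 * subject$BW else params$eps_fz
}

#' Place the virtual pivot point
#'
#' The VPP's planar coordinates follow the COM force direction:
#' `VPP(x,y) = COM(x,y) + (COM(z) / F_COM(z)) * F_COM(x,y)`; its height is
#' fixed at `vppscale * BH`. Frames with `|F_COM(z)|` below `eps_fz` are
#' degenerate (near-flight): the VPP falls back to sitting vertically
#' above the COM and the frame is flagged.
#'
#' @param com COM position(s): 3-vector or n x 3 matrix (m).
#' @param f_com COM force(s), same shape (N).
#' @param params A [vpp_params()].
#' @param subject A [subject_params()].
#' @return List with `vpp` (n x 3 matrix) and `degenerate` (logical).
#' @examples
#' s <- subject_params(80, 1.80)
#' compute_vpp(c(0, 0, 1), c(0, 0, 800), vpp_params(0.9), s)$vpp
#' @export
compute_vpp <- function(com, f_com, params = vpp_params(),
                        subject) {
  stopifnot(inherits(subject, "subject_params"))
  com <- if (is.null(dim(com))) matrix(com, ncol = 3L) else as.matrix(com)
  f_com <- if (is.null(dim(f_com))) matrix(f_com, ncol = 3L) else as.matrix(f_com)
  if (!all(dim(com) == dim(f_com))) stop("'com' and 'f_com' shapes differ")
  eps <- .resolve_eps_fz(params, subject)
  fz <- f_com[, 3L]
  degen <- abs(fz) < eps
  ratio <- ifelse(degen, 0, com[, 3L] / ifelse(degen, 1, fz))
  vpp <- cbind(com[, 1L] + ratio * f_com[, 1L],
               com[, 2L] + ratio * f_com[, 2L],
               rep(params$vppscale * subject$BH, nrow(com)))
  colnames(vpp) <- c("x", "y", "z")
  list(vpp = vpp, degenerate = degen)
}

#' Virtual pivot vector
#'
#' The unit vector pointing from a foot's centre of pressure to the VPP;
#' the foot's GRF is assumed to act along this line.
#'
#' @param vpp VPP position(s): 3-vector or n x 3 matrix (m).
#' @param cop COP position(s), same shape (m).
#' @return List with `vpv` (n x 3 unit rows) and `degenerate` (logical,
#'   `TRUE` where VPP and COP coincide and no direction exists).
#' @export
compute_vpv <- function(vpp, cop) {
  vpp <- if (is.null(dim(vpp))) matrix(vpp, ncol = 3L) else as.matrix(vpp)
  cop <- if (is.null(dim(cop))) matrix(cop, ncol = 3L) else as.matrix(cop)
  if (!all(dim(vpp) == dim(cop))) stop("'vpp' and 'cop' shapes differ")
  d <- vpp - cop
  nrm <- sqrt(rowSums(d^2))
  degen <- !is.na(nrm) & nrm == 0
  nrm[degen] <- 1
  list(vpv = d / nrm, degenerate = degen)
}

# Closed-form least squares for [v_l v_r] (a, b)' = f with 3-vector columns,
# via the 2x2 normal equations. All quantities are dot products, which are
# invariant under a sagittal reflection (y -> -y), so mirrored inputs give
# bit-identical magnitudes. Vectorised over frames (n x 3 matrices).
.ls2_solve <- function(vl, vr, f) {
  g11 <- rowSums(vl * vl)
  g22 <- rowSums(vr * vr)
  g12 <- rowSums(vl * vr)
  bl <- rowSums(vl * f)
  br <- rowSums(vr * f)
  det <- g11 * g22 - g12 * g12
  a <- (g22 * bl - g12 * br) / det
  b <- (g11 * br - g12 * bl) / det
  # condition number of the 3x2 direction matrix from the Gram eigenvalues
  tr <- g11 + g22
  disc <- sqrt(pmax((g11 - g22)^2 + 4 * g12^2, 0))
  lam1 <- (tr + disc) / 2
  lam2 <- pmax((tr - disc) / 2, 0)
  cond <- sqrt(lam1 / pmax(lam2, .Machine$double.xmin))
  list(a = a, b = b, cond = cond)
}

#' Distribute the COM force over both feet in double support
#'
#' Solves the 3 x 2 linear system `[VPV_L VPV_R] (a, b)' = F_COM` for the
#' scalar force magnitudes in the least-squares sense (the standard
#' semantics of the matrix backslash on an overdetermined system). Under
#' the default non-negativity policy, a negative magnitude is clamped to
#' zero and the other foot refit as the 1-D projection of the force onto
#' its direction. Near-parallel directions beyond `cond_limit` trigger a
#' flagged 50/50 split along the mean direction.
#'
#' @param f_com COM force(s): 3-vector or n x 3 matrix (N).
#' @param vpv_l,vpv_r Unit direction(s) from each COP to the VPP.
#' @param params A [vpp_params()].
#' @return List of per-frame vectors: `mag_l`, `mag_r` (N), `residual`
#'   (N, norm of `a * VPV_L + b * VPV_R - F_COM` for the returned
#'   magnitudes), and flags `clamped`, `ill_conditioned`.
#' @examples
#' vl <- c(0, -0.2, 1.62) / sqrt(0.04 + 1.62^2)
#' vr <- c(0, 0.2, 1.62) / sqrt(0.04 + 1.62^2)
#' solve_double_support(c(0, 0, 800), vl, vr)
#' @export
solve_double_support <- function(f_com, vpv_l, vpv_r, params = vpp_params()) {
  f <- if (is.null(dim(f_com))) matrix(f_com, ncol = 3L) else as.matrix(f_com)
  vl <- if (is.null(dim(vpv_l))) matrix(vpv_l, ncol = 3L) else as.matrix(vpv_l)
  vr <- if (is.null(dim(vpv_r))) matrix(vpv_r, ncol = 3L) else as.matrix(vpv_r)
  n <- nrow(f)
  if (nrow(vl) != n || nrow(vr) != n) stop("frame counts differ")
  ls <- .ls2_solve(vl, vr, f)
  a <- ls$a; b <- ls$b
  ill <- !is.finite(a) | !is.finite(b) | ls$cond > params$cond_limit
  if (any(ill)) {
    m <- vl[ill, , drop = FALSE] + vr[ill, , drop = FALSE]
    mn <- sqrt(rowSums(m^2))
    mn[mn == 0] <- 1
    m <- m / mn
    proj <- rowSums(f[ill, , drop = FALSE] * m)
    a[ill] <- proj / 2
    b[ill] <- proj / 2
  }
  clamped <- rep(FALSE, n)
  if (params$nonneg_policy == "clamp_reassign") {
    neg_a <- !ill & a < 0
    neg_b <- !ill & b < 0 & !neg_a
    if (any(neg_a)) {
      a[neg_a] <- 0
      b[neg_a] <- pmax(rowSums(f[neg_a, , drop = FALSE] *
                                 vr[neg_a, , drop = FALSE]) /
                         rowSums(vr[neg_a, , drop = FALSE]^2), 0)
    }
    if (any(neg_b)) {
      b[neg_b] <- 0
      a[neg_b] <- pmax(rowSums(f[neg_b, , drop = FALSE] *
                                 vl[neg_b, , drop = FALSE]) /
                         rowSums(vl[neg_b, , drop = FALSE]^2), 0)
    }
    clamped <- neg_a | neg_b
  }
  res <- sqrt(rowSums((a * vl + b * vr - f)^2))
  list(mag_l = a, mag_r = b, residual = res,
       clamped = clamped, ill_conditioned = ill)
}

#' Predict per-foot ground reaction forces
#'
#' Frame-by-frame dispatch on the support phase. Double support engages
#' the VPP construction: place the VPP, form the two virtual pivot
#' vectors from the COPs, and split the COM force between the feet by
#' least squares. In single support the whole COM force acts at the
#' stance foot's COP; in flight both feet carry zero force. Degenerate or
#' ill-conditioned frames are flagged, never fatal.
#'
#' @param f_com COM force [trajectory()] (N) from [compute_com_force()].
#' @param com COM position [trajectory()] (m).
#' @param left,right `"foot_contact"` objects (see [compute_cop()]).
#' @param labels Per-frame support labels from [classify_support()];
#'   recomputed from `left`/`right` when `NULL`.
#' @param params A [vpp_params()].
#' @param subject A [subject_params()].
#' @return An object of class `"vpp_solution"`: list with `t`, `support`,
#'   matrices `grf_l`, `grf_r`, `vpp`, `vpv_l`, `vpv_r`, vectors `mag_l`,
#'   `mag_r`, `residual`, per-frame `flags` (comma-separated), plus the
#'   COPs (`cop_l`, `cop_r`) and `endpoint` markers carried through for
#'   output and evaluation.
#' @export
predict_grf <- function(f_com, com, left, right, labels = NULL,
                        params = vpp_params(), subject) {
  stopifnot(inherits(f_com, "trajectory"), inherits(com, "trajectory"),
            inherits(left, "foot_contact"), inherits(right, "foot_contact"),
            inherits(subject, "subject_params"))
  n <- length(f_com$t)
  if (length(com$t) != n || length(left$defined) != n ||
      length(right$defined) != n)
    stop("input sequences have different lengths")
  if (is.null(labels)) labels <- classify_support(left, right)
  if (length(labels) != n) stop("'labels' length does not match the trial")

  grf_l <- matrix(0, n, 3L, dimnames = list(NULL, c("x", "y", "z")))
  grf_r <- grf_l
  vpp <- matrix(NA_real_, n, 3L, dimnames = list(NULL, c("x", "y", "z")))
  vpv_l <- vpp; vpv_r <- vpp
  mag_l <- numeric(n); mag_r <- numeric(n)
  residual <- numeric(n)
  flags <- character(n)

  ds <- which(labels == "double")
  if (length(ds)) {
    vp <- compute_vpp(com$v[ds, , drop = FALSE], f_com$v[ds, , drop = FALSE],
                      params, subject)
    vpp[ds, ] <- vp$vpp
    pl <- compute_vpv(vp$vpp, left$cop[ds, , drop = FALSE])
    pr <- compute_vpv(vp$vpp, right$cop[ds, , drop = FALSE])
    vpv_l[ds, ] <- pl$vpv
    vpv_r[ds, ] <- pr$vpv
    sol <- solve_double_support(f_com$v[ds, , drop = FALSE], pl$vpv, pr$vpv,
                                params)
    mag_l[ds] <- sol$mag_l
    mag_r[ds] <- sol$mag_r
    residual[ds] <- sol$residual
    grf_l[ds, ] <- sol$mag_l * pl$vpv
    grf_r[ds, ] <- sol$mag_r * pr$vpv
    fl <- character(length(ds))
    add_flag <- function(fl, which, tag)
      ifelse(which, ifelse(fl == "", tag, paste(fl, tag, sep = ",")), fl)
    fl <- add_flag(fl, vp$degenerate, "degenerate_fz")
    fl <- add_flag(fl, pl$degenerate | pr$degenerate, "coincident_cop")
    fl <- add_flag(fl, sol$ill_conditioned, "ill_conditioned")
    fl <- add_flag(fl, sol$clamped, "clamped")
    flags[ds] <- fl
  }
  sl <- which(labels == "single_L")
  if (length(sl)) {
    grf_l[sl, ] <- f_com$v[sl, , drop = FALSE]
    mag_l[sl] <- sqrt(rowSums(f_com$v[sl, , drop = FALSE]^2))
  }
  sr <- which(labels == "single_R")
  if (length(sr)) {
    grf_r[sr, ] <- f_com$v[sr, , drop = FALSE]
    mag_r[sr] <- sqrt(rowSums(f_com$v[sr, , drop = FALSE]^2))
  }

  structure(list(t = f_com$t, support = labels,
                 grf_l = grf_l, grf_r = grf_r,
                 vpp = vpp, vpv_l = vpv_l, vpv_r = vpv_r,
                 mag_l = mag_l, mag_r = mag_r, residual = residual,
                 flags = flags, cop_l = left$cop, cop_r = right$cop,
                 endpoint = f_com$endpoint, subject = subject,
                 vppscale = params$vppscale),
            class = "vpp_solution")
}

#' @export
print.vpp_solution <- function(x, ...) {
  tab <- table(factor(x$support,
                      levels = c("double", "single_L", "single_R", "flight")))
  cat(sprintf("<vpp_solution> %d frames (VPPscale %.3g): %s\n",
              length(x$t), x$vppscale,
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  nf <- sum(x$flags != "")
  if (nf) cat(sprintf("  flagged frames: %d\n", nf))
  invisible(x)
}

#' COM-force split baseline (no VPP)
#'
#' The baseline the VPP method improves on: each foot in contact receives
#' an equal share of the COM force, with no geometric redistribution. With
#' near-zero lateral COM acceleration this baseline predicts identically
#' zero lateral foot forces, while measured (and VPP-predicted) lateral
#' forces are non-zero and opposite between feet.
#'
#' @inheritParams predict_grf
#' @return A `"vpp_solution"`-like list with `grf_l`, `grf_r`, `support`,
#'   `t`.
#' @export
baseline_split_grf <- function(f_com, left, right, labels = NULL) {
  stopifnot(inherits(f_com, "trajectory"))
  if (is.null(labels)) labels <- classify_support(left, right)
  n <- length(f_com$t)
  grf_l <- matrix(0, n, 3L, dimnames = list(NULL, c("x", "y", "z")))
  grf_r <- grf_l
  ds <- labels == "double"
  grf_l[ds, ] <- f_com$v[ds, , drop = FALSE] / 2
  grf_r[ds, ] <- f_com$v[ds, , drop = FALSE] / 2
  sl <- labels == "single_L"
  grf_l[sl, ] <- f_com$v[sl, , drop = FALSE]
  sr <- labels == "single_R"
  grf_r[sr, ] <- f_com$v[sr, , drop = FALSE]
  list(t = f_com$t, support = labels, grf_l = grf_l, grf_r = grf_r)
}
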