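# CSV / YAML / JSON input-output.
#
# All files carry seconds, metres and newtons; body-weight normalisation
# happens only in evaluation outputs. Numeric values are written with 17
# significant digits so write-then-read round-trips are exact.

.fmt_num <- function(x) sprintf("%.17g", x)

.write_num_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  utils::read.csv(path, check.names = FALSE)
}

.require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  extra <- setdiff(names(df), cols)
  if (length(extra))
    message(sprintf("%s: ignoring unknown column(s) %s", path,
                    paste(extra, collapse = ", ")))
}

.check_numeric <- function(df, cols, path) {
  for (cl in cols) {
    v <- df[[cl]]
    if (!is.numeric(v))
      stop(sprintf("%s: column '%s' is not numeric", path, cl))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("%s: non-finite value in column '%s', row %d",
                   path, cl, bad[1L]))
  }
}

.check_time <- function(tm, path) {
  d <- diff(tm)
  if (any(d <= 0)) {
    stop(sprintf("%s: 'time' not strictly increasing at row %d",
                 path, which(d <= 0)[1L] + 1L))
  }
  if (length(d) && max(d) - min(d) > 1e-9) {
    bad <- which.max(abs(d - stats::median(d)))
    stop(sprintf("%s: non-uniform 'time' step at row %d (%.6g s vs median %.6g s)",
                 path, bad + 1L, d[bad], stats::median(d)))
  }
}

#' Write / read a COM kinematics CSV
#'
#' Schema: `time,com_x,com_y,com_z` (s, m). Round-trips are lossless.
#'
#' @param traj A [trajectory()] of COM positions.
#' @param path File path.
#' @return `write_kinematics_csv`: the path, invisibly.
#'   `read_kinematics_csv`: a [trajectory()].
#' @export
write_kinematics_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  .write_num_csv(data.frame(time = traj$t, com_x = traj$v[, 1L],
                            com_y = traj$v[, 2L], com_z = traj$v[, 3L]),
                 path)
}

#' @rdname write_kinematics_csv
#' @export
read_kinematics_csv <- function(path) {
  df <- .read_csv(path)
  cols <- c("time", "com_x", "com_y", "com_z")
  .require_cols(df, cols, path)
  .check_numeric(df, cols, path)
  .check_time(df$time, path)
  trajectory(df$time, cbind(df$com_x, df$com_y, df$com_z))
}

#' Read segment trajectories and mass fractions from CSV
#'
#' Schema: `time,<seg>_x,<seg>_y,<seg>_z,...` (s, m), one column triple
#' per segment. Mass fractions are supplied by name (tables are data, not
#' code).
#'
#' @param path File path.
#' @param mass_fractions Named numeric vector of dimensionless fractions,
#'   names matching the `<seg>` prefixes; must sum to 1.
#' @return A [segment_set()].
#' @export
read_segment_csv <- function(path, mass_fractions) {
  df <- .read_csv(path)
  if (!"time" %in% names(df)) stop(sprintf("%s: missing column 'time'", path))
  .check_time(df$time, path)
  segs <- list()
  for (nm in names(mass_fractions)) {
    cols <- paste0(nm, c("_x", "_y", "_z"))
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s: missing column(s) %s for segment '%s'",
                   path, paste(miss, collapse = ", "), nm))
    .check_numeric(df, cols, path)
    segs[[nm]] <- list(mass_fraction = unname(mass_fractions[nm]),
                       com = trajectory(df$time,
                                        cbind(df[[cols[1L]]], df[[cols[2L]]],
                                              df[[cols[3L]]])))
  }
  segment_set(segs)
}

.cp_cols <- function(side, n_cp) {
  as.vector(t(outer(sprintf("%s_cp%02d", side, seq_len(n_cp)),
                    c("_x", "_y", "_z"), paste0)))
}

#' Write / read a contact-point CSV (both feet)
#'
#' Schema: `time,L_cp01_x,L_cp01_y,L_cp01_z,...,R_cp18_z` (s, m).
#'
#' @param left,right [contact_points()] objects for the two feet.
#' @param path File path.
#' @return `write_contacts_csv`: the path, invisibly.
#'   `read_contacts_csv`: list with elements `left` and `right`.
#' @export
write_contacts_csv <- function(left, right, path) {
  stopifnot(inherits(left, "contact_points"), inherits(right, "contact_points"))
  df <- data.frame(time = left$t)
  for (side in c("L", "R")) {
    cp <- if (side == "L") left else right
    for (i in seq_len(cp$n_cp)) {
      for (k in 1:3) {
        df[[sprintf("%s_cp%02d_%s", side, i, c("x", "y", "z")[k])]] <-
          cp$pos[, i, k]
      }
    }
  }
  .write_num_csv(df, path)
}

#' @rdname write_contacts_csv
#' @export
read_contacts_csv <- function(path) {
  df <- .read_csv(path)
  if (!"time" %in% names(df)) stop(sprintf("%s: missing column 'time'", path))
  .check_time(df$time, path)
  n <- nrow(df)
  out <- list()
  for (side in c("L", "R")) {
    pat <- sprintf("^%s_cp([0-9]+)_x$", side)
    idx <- sort(as.integer(sub(pat, "\\1",
                               grep(pat, names(df), value = TRUE))))
    if (!length(idx))
      stop(sprintf("%s: no contact-point columns for side %s", path, side))
    cols <- .cp_cols(side, max(idx))
    .require_cols(df[grep(sprintf("^(time|%s_)", side), names(df))],
                  c("time", cols), path)
    .check_numeric(df, cols, path)
    pos <- array(NA_real_, c(n, length(idx), 3L))
    for (i in seq_along(idx)) {
      for (k in 1:3) {
        pos[, i, k] <- df[[sprintf("%s_cp%02d_%s", side, idx[i],
                                   c("x", "y", "z")[k])]]
      }
    }
    out[[if (side == "L") "left" else "right"]] <-
      contact_points(df$time, pos)
  }
  out
}

#' Write / read a per-foot GRF CSV
#'
#' Schema: `time,grf_l_x,grf_l_y,grf_l_z,grf_r_x,grf_r_y,grf_r_z` (s, N).
#' Unknown extra columns are accepted with a message on read.
#'
#' @param t Sample times (s).
#' @param grf_l,grf_r n x 3 matrices of per-foot forces (N).
#' @param path File path.
#' @return `write_grf_csv`: the path, invisibly. `read_grf_csv`: list
#'   with `t`, `grf_l`, `grf_r`.
#' @export
write_grf_csv <- function(t, grf_l, grf_r, path) {
  .write_num_csv(data.frame(time = t,
                            grf_l_x = grf_l[, 1L], grf_l_y = grf_l[, 2L],
                            grf_l_z = grf_l[, 3L],
                            grf_r_x = grf_r[, 1L], grf_r_y = grf_r[, 2L],
                            grf_r_z = grf_r[, 3L]),
                 path)
}

#' @rdname write_grf_csv
#' @export
read_grf_csv <- function(path) {
  df <- .read_csv(path)
  cols <- c("time", "grf_l_x", "grf_l_y", "grf_l_z",
            "grf_r_x", "grf_r_y", "grf_r_z")
  .require_cols(df, cols, path)
  .check_numeric(df, cols, path)
  .check_time(df$time, path)
  list(t = df$time,
       grf_l = as.matrix(df[, c("grf_l_x", "grf_l_y", "grf_l_z")]),
       grf_r = as.matrix(df[, c("grf_r_x", "grf_r_y", "grf_r_z")]))
}

#' Write a per-frame prediction CSV
#'
#' Schema: `time,support,grf_l_x..z,grf_r_x..z,cop_l_x,cop_l_y,cop_r_x,`
#' `cop_r_y,vpp_x,vpp_y,vpp_z,residual,flags`.
#'
#' @param sol A `"vpp_solution"` from [predict_grf()].
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_solution_csv <- function(sol, path) {
  stopifnot(inherits(sol, "vpp_solution"))
  df <- data.frame(time = sol$t, support = sol$support,
                   grf_l_x = sol$grf_l[, 1L], grf_l_y = sol$grf_l[, 2L],
                   grf_l_z = sol$grf_l[, 3L],
                   grf_r_x = sol$grf_r[, 1L], grf_r_y = sol$grf_r[, 2L],
                   grf_r_z = sol$grf_r[, 3L],
                   cop_l_x = sol$cop_l[, 1L], cop_l_y = sol$cop_l[, 2L],
                   cop_r_x = sol$cop_r[, 1L], cop_r_y = sol$cop_r[, 2L],
                   vpp_x = sol$vpp[, 1L], vpp_y = sol$vpp[, 2L],
                   vpp_z = sol$vpp[, 3L],
                   residual = sol$residual, flags = sol$flags)
  .write_num_csv(df, path)
}

#' Write / read a VPPscale sweep report CSV
#'
#' Long format: `scale,direction,trial,rmse_bw`.
#'
#' @param sweeps A `"vppscale_sweep"` or list of them.
#' @param path File path.
#' @param trial_ids Optional character vector naming the trials.
#' @return `write_sweep_csv`: the path, invisibly. `read_sweep_csv`: the
#'   long-format data frame.
#' @export
write_sweep_csv <- function(sweeps, path, trial_ids = NULL) {
  if (inherits(sweeps, "vppscale_sweep")) sweeps <- list(sweeps)
  if (is.null(trial_ids)) trial_ids <- paste0("trial", seq_along(sweeps))
  rows <- do.call(rbind, lapply(seq_along(sweeps), function(i) {
    s <- sweeps[[i]]
    data.frame(scale = rep(s$scales, times = 3L),
               direction = rep(colnames(s$rmse), each = length(s$scales)),
               trial = trial_ids[i],
               rmse_bw = as.vector(s$rmse))
  }))
  .write_num_csv(rows, path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  df <- .read_csv(path)
  .require_cols(df, c("scale", "direction", "trial", "rmse_bw"), path)
  .check_numeric(df, c("scale", "rmse_bw"), path)
  df
}

#' Write a sweep summary JSON
#'
#' Stores the selected optimum and, per direction, the median and
#' interquartile range of the RMSE across trials at that optimum.
#'
#' @param sweeps A `"vppscale_sweep"` or list of them (shared grid).
#' @param path File path.
#' @return The summary list, invisibly.
#' @export
write_sweep_summary <- function(sweeps, path) {
  if (inherits(sweeps, "vppscale_sweep")) sweeps <- list(sweeps)
  opt <- select_optimal_scale(sweeps)
  grid <- sweeps[[1L]]$scales
  i <- which.min(abs(grid - opt))
  per_dir <- lapply(c(anterior = "anterior", lateral = "lateral",
                      vertical = "vertical"), function(d) {
    v <- vapply(sweeps, function(s) s$rmse[i, d], numeric(1))
    list(median = stats::median(v),
         iqr = unname(stats::quantile(v, c(0.25, 0.75))))
  })
  summ <- list(optimum_vppscale = opt, n_trials = length(sweeps),
               rmse_bw_at_optimum = per_dir)
  jsonlite::write_json(summ, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(summ)
}

#' Run configuration
#'
#' Bundles subject, contact, solver, sweep and filter settings, mirrored
#' one-to-one by the YAML config file. Filter defaults follow standard
#' force-plate processing: 40 Hz for COP signals and 20 Hz for force
#' signals (zero-phase Butterworth, order 2 per pass); `com_cutoff`
#' optionally smooths COM kinematics before double differentiation
#' (`NULL` = off).
#'
#' @param subject A [subject_params()].
#' @param cparams A [contact_params()].
#' @param vparams A [vpp_params()].
#' @param grid VPPscale sweep grid.
#' @param cop_cutoff,force_cutoff,com_cutoff Low-pass cutoffs in Hz.
#' @param filter_order Butterworth order per pass.
#' @param seed Integer seed for stochastic steps.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(subject, cparams = contact_params(),
                       vparams = vpp_params(),
                       grid = seq(0.2, 2.0, by = 0.1),
                       cop_cutoff = 40, force_cutoff = 20,
                       com_cutoff = NULL, filter_order = 2, seed = 1L) {
  stopifnot(inherits(subject, "subject_params"))
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  structure(list(subject = subject, cparams = cparams, vparams = vparams,
                 grid = grid, cop_cutoff = cop_cutoff,
                 force_cutoff = force_cutoff, com_cutoff = com_cutoff,
                 filter_order = filter_order, seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `write_run_config`: the path, invisibly. `read_run_config`: a
#'   [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lst <- list(
    subject = list(M = config$subject$M, BH = config$subject$BH,
                   g_mag = config$subject$g_mag),
    contact = list(z_lim = config$cparams$z_lim,
                   v_lim = config$cparams$v_lim,
                   w_support_threshold = config$cparams$w_support_threshold,
                   project_cop = config$cparams$project_cop),
    vpp = list(vppscale = config$vparams$vppscale,
               eps_fz = config$vparams$eps_fz,
               nonneg_policy = config$vparams$nonneg_policy,
               cond_limit = config$vparams$cond_limit),
    grid = as.numeric(config$grid),
    filters = list(cop_cutoff = config$cop_cutoff,
                   force_cutoff = config$force_cutoff,
                   com_cutoff = config$com_cutoff,
                   order = config$filter_order),
    seed = config$seed)
  yaml::write_yaml(lst, path, precision = 17L)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lst <- yaml::read_yaml(path)
  run_config(
    subject = subject_params(lst$subject$M, lst$subject$BH,
                             lst$subject$g_mag),
    cparams = contact_params(lst$contact$z_lim, lst$contact$v_lim,
                             lst$contact$w_support_threshold,
                             lst$contact$project_cop),
    vparams = vpp_params(lst$vpp$vppscale, lst$vpp$eps_fz,
                         lst$vpp$nonneg_policy, lst$vpp$cond_limit),
    grid = as.numeric(lst$grid),
    cop_cutoff = lst$filters$cop_cutoff,
    force_cutoff = lst$filters$force_cutoff,
    com_cutoff = lst$filters$com_cutoff,
    filter_order = lst$filters$order,
    seed = lst$seed)
}

#' Write / read a complete trial as a set of plain-text files
#'
#' Writes `<prefix>_kinematics.csv`, `<prefix>_contacts.csv`,
#' `<prefix>_grf.csv` (reference forces, when present) and
#' `<prefix>_meta.yaml` into `dir`, using exactly the schemas the readers
#' consume, so generated and imported trials are interchangeable.
#'
#' @param trial A `"vpp_trial"`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return `write_trial`: the prefix path, invisibly. `read_trial`: a
#'   `"vpp_trial"` (support labels recomputed with the contact model).
#' @export
write_trial <- function(trial, dir, prefix = trial$kind) {
  stopifnot(inherits(trial, "vpp_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- file.path(dir, prefix)
  write_kinematics_csv(trial$com, paste0(p, "_kinematics.csv"))
  write_contacts_csv(trial$contacts_l, trial$contacts_r,
                     paste0(p, "_contacts.csv"))
  if (!is.null(trial$truth_grf_l))
    write_grf_csv(trial$com$t, trial$truth_grf_l, trial$truth_grf_r,
                  paste0(p, "_grf.csv"))
  meta <- list(kind = trial$kind, sample_rate = trial$sample_rate,
               subject = list(M = trial$subject$M, BH = trial$subject$BH,
                              g_mag = trial$subject$g_mag),
               true_vppscale = trial$true_vppscale,
               noise_sigma = trial$noise_sigma, seed = trial$seed)
  yaml::write_yaml(meta, paste0(p, "_meta.yaml"), precision = 17L)
  invisible(p)
}

#' @rdname write_trial
#' @export
read_trial <- function(dir, prefix) {
  p <- file.path(dir, prefix)
  meta <- yaml::read_yaml(paste0(p, "_meta.yaml"))
  subject <- subject_params(meta$subject$M, meta$subject$BH,
                            meta$subject$g_mag)
  com <- read_kinematics_csv(paste0(p, "_kinematics.csv"))
  cps <- read_contacts_csv(paste0(p, "_contacts.csv"))
  fc_l <- foot_contact(cps$left)
  fc_r <- foot_contact(cps$right)
  trial <- structure(
    list(kind = meta$kind, subject = subject,
         sample_rate = meta$sample_rate, com = com, com_clean = NULL,
         contacts_l = cps$left, contacts_r = cps$right,
         true_vppscale = meta$true_vppscale,
         truth_grf_l = NULL, truth_grf_r = NULL,
         labels = classify_support(fc_l, fc_r),
         noise_sigma = meta$noise_sigma, seed = meta$seed,
         schedule = NULL),
    class = "vpp_trial")
  grf_path <- paste0(p, "_grf.csv")
  if (file.exists(grf_path)) {
    g <- read_grf_csv(grf_path)
    trial$truth_grf_l <- g$grf_l
    trial$truth_grf_r <- g$grf_r
  }
  trial
}
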