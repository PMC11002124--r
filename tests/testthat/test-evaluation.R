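test_that("directional RMSE matches closed forms and brute force", {
  s <- subject_params(80, 1.80)
  n <- 50
  set.seed(5)
  ref_l <- matrix(rnorm(3 * n, sd = 100), ncol = 3)
  ref_r <- matrix(rnorm(3 * n, sd = 100), ncol = 3)
  # identity
  expect_identical(unname(rmse_by_direction(ref_l, ref_r, ref_l, ref_r, s)),
                   c(0, 0, 0))
  # constant vertical offset of 0.1 BW on one foot: pooled over two feet
  # the mean square halves -> 0.1 / sqrt(2) BW
  off <- ref_l
  off[, 3] <- off[, 3] + 0.1 * s$BW
  r <- rmse_by_direction(off, ref_r, ref_l, ref_r, s)
  expect_equal(unname(r), c(0, 0, 0.1 / sqrt(2)), tolerance = 1e-12)
  # random pair against a per-sample accumulation loop
  pred_l <- ref_l + matrix(rnorm(3 * n, sd = 30), ncol = 3)
  pred_r <- ref_r + matrix(rnorm(3 * n, sd = 30), ncol = 3)
  r2 <- rmse_by_direction(pred_l, pred_r, ref_l, ref_r, s)
  for (d in 1:3) {
    acc <- 0
    for (i in 1:n) acc <- acc + (pred_l[i, d] - ref_l[i, d])^2 +
        (pred_r[i, d] - ref_r[i, d])^2
    expect_equal(unname(r2[d]), sqrt(acc / (2 * n)) / s$BW, tolerance = 1e-12)
  }
  # invariant under a common rigid translation of pred and ref
  shift <- matrix(c(3, -7, 11), n, 3, byrow = TRUE)
  expect_equal(rmse_by_direction(pred_l + shift, pred_r, ref_l + shift,
                                 ref_r, s), r2)
  expect_error(rmse_by_direction(pred_l[-1, ], pred_r, ref_l, ref_r, s),
               "lengths differ")
})

test_that("squat segmentation finds the descent via the velocity threshold", {
  s <- default_subject()
  depth <- 0.3; period <- 3; lead_in <- 1
  tr <- simulate_squat(s, depth = depth, period = period, lead_in = lead_in)
  seg <- segment_trial("squat", tr$com)
  # oracle: the analytic first |vz| > v_thresh crossing of the generator's
  # raised-cosine profile, vz = -(depth/2) * omega * sin(omega * (t - lead_in))
  omega <- 2 * pi / period
  t_cross <- lead_in + asin(0.02 / (depth / 2 * omega)) / omega
  expect_lt(abs(seg$start - (round(t_cross * tr$sample_rate) + 1)), 3)
  # the segment ends when the final ascent slows below the threshold
  t_end_cross <- lead_in + 2 * period -
    asin(0.02 / (depth / 2 * omega)) / omega
  expect_lt(abs(seg$end - (round(t_end_cross * tr$sample_rate) + 1)), 3)
  # monotonically rising COM: no descent to find
  t <- seq(0, 2, by = 1 / 120)
  expect_error(segment_trial("squat", trajectory(t, cbind(0, 0, 1 + 0.1 * t))),
               "segmentation failed")
})

test_that("walking segmentation spans one left-to-left double step", {
  s <- default_subject()
  tr <- simulate_walk(s)
  seg <- segment_trial("walking", tr$com, labels = tr$labels)
  on <- tr$labels %in% c("double", "single_L")
  rises <- which(on & !c(FALSE, on[-length(on)]))
  expect_identical(seg$start, rises[1])
  expect_identical(seg$end, rises[2] - 1L)
  # roughly one gait cycle at the scheduled step time
  expect_equal(seg$end - seg$start + 1,
               2 * tr$schedule$T_step * tr$sample_rate, tolerance = 0.1)
  expect_error(segment_trial("walking", tr$com), "labels")
})

test_that("the sweep recovers the generating scale and is deterministic", {
  s <- default_subject()
  tr <- simulate_squat(s, true_vppscale = 0.9)
  sw <- sweep_vppscale(tr)
  expect_identical(length(sw$scales), 19L)  # 0.2 to 2.0 by 0.1
  expect_equal(sw$optimum, 0.9)
  expect_lt(min(sw$total), 1e-9)
  sw2 <- sweep_vppscale(tr)
  expect_identical(sw$rmse, sw2$rmse)  # bit-identical rerun
  # noisy trials: recovery within one grid step (seed-fixed)
  for (sd in 1:2) {
    trn <- simulate_squat(s, true_vppscale = 0.9, noise_sigma = 0.002,
                          seed = sd)
    expect_lt(abs(sweep_vppscale(trn, com_cutoff = 1.5)$optimum - 0.9),
              0.1 + 1e-9)
  }
  expect_error(sweep_vppscale(tr, grid = numeric(0)), "empty")
  # single-point grid still evaluates
  sw1 <- sweep_vppscale(tr, grid = 0.7)
  expect_identical(length(sw1$total), 1L)
})

test_that("optimal-scale selection aggregates by median with a low tie-break", {
  mk <- function(total, scales = seq(0.2, 2, by = 0.1))
    structure(list(scales = scales, total = total,
                   rmse = cbind(total / 3, total / 3, total / 3),
                   optimum = scales[which.min(total)]),
              class = "vppscale_sweep")
  g <- seq(0.2, 2, by = 0.1)
  # single trial, single minimum
  t1 <- (g - 1.3)^2
  expect_equal(select_optimal_scale(mk(t1)), 1.3)
  # two trials with adjacent minima: brute-force the median aggregate
  t2 <- (g - 1.4)^2
  med <- apply(cbind(t1, t2), 1, stats::median)
  expect_equal(select_optimal_scale(list(mk(t1), mk(t2))),
               g[which.min(med)])
  # exact tie between 0.9 and 1.0 -> 0.9
  tt <- rep(1, length(g))
  tt[abs(g - 0.9) < 1e-9 | abs(g - 1.0) < 1e-9] <- 0.5
  expect_equal(select_optimal_scale(mk(tt)), 0.9)
  expect_error(select_optimal_scale(list()), "empty")
})
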