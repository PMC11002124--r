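test_that("generated trials satisfy their construction invariants", {
  s <- default_subject()
  for (tr in list(simulate_squat(s), simulate_lunge(s), simulate_walk(s))) {
    # force closure at every frame
    expect_lt(tr$closure_err, 1e-9)
    # truth force lines pass through the true VPP on double support
    f_com <- tr$truth_f_com
    h <- tr$true_vppscale * s$BH
    ds <- which(tr$labels == "double")
    fc_l <- foot_contact(tr$contacts_l)
    for (i in sample(ds, min(30, length(ds)))) {
      ratio <- tr$com_clean$v[i, 3] / f_com$v[i, 3]
      vpp <- c(tr$com_clean$v[i, 1:2] + ratio * f_com$v[i, 1:2], h)
      g <- tr$truth_grf_l[i, ]
      u <- g / sqrt(sum(g^2))
      d <- vpp - fc_l$cop[i, ]
      expect_lt(sqrt(sum((d - sum(d * u) * u)^2)), 1e-9)
    }
  }
})

test_that("the pipeline reproduces the truth at the generating scale", {
  s <- default_subject()
  for (sc in c(0.5, 1.4)) {
    tr <- simulate_lunge(s, true_vppscale = sc)
    sol <- predict_trial_grf(tr, vppscale = sc)
    expect_lt(max_rel_err(sol$grf_l, tr$truth_grf_l, s$BW), 1e-9)
    expect_lt(max_rel_err(sol$grf_r, tr$truth_grf_r, s$BW), 1e-9)
  }
})

test_that("zero-depth squat reduces to quiet standing statics", {
  s <- default_subject()
  tr <- simulate_squat(s, depth = 0)
  inner <- 3:(length(tr$com$t) - 2)
  # each foot: zero anterior force, half body weight vertically,
  # equal-opposite lateral components
  expect_lt(max(abs(tr$truth_grf_l[inner, 1])), 1e-9 * s$BW)
  expect_equal(tr$truth_grf_l[inner, 3], rep(s$BW / 2, length(inner)),
               tolerance = 1e-12)
  expect_equal(tr$truth_grf_l[inner, 2], -tr$truth_grf_r[inner, 2],
               tolerance = 1e-12)
  expect_gt(min(abs(tr$truth_grf_l[inner, 2])), 1)  # genuinely non-zero
})

test_that("same seed gives bit-identical trials; lunge at stride 0 is a squat", {
  s <- default_subject()
  a <- simulate_squat(s, noise_sigma = 0.002, seed = 7)
  b <- simulate_squat(s, noise_sigma = 0.002, seed = 7)
  expect_identical(a$com$v, b$com$v)
  expect_identical(a$truth_grf_l, b$truth_grf_l)
  c <- simulate_squat(s, noise_sigma = 0.002, seed = 8)
  expect_false(identical(a$com$v, c$com$v))
  sq <- simulate_squat(s, depth = 0.25)
  lu <- simulate_lunge(s, stride = 0, depth = 0.25)
  expect_equal(lu$com$v, sq$com$v, tolerance = 1e-12)
  expect_equal(lu$truth_grf_l, sq$truth_grf_l, tolerance = 1e-9)
})

test_that("lunge anterior components oppose between feet", {
  s <- default_subject()
  tr <- simulate_lunge(s, stride = 0.6)
  ds <- tr$labels == "double"
  expect_true(all(tr$truth_grf_l[ds, 1] * tr$truth_grf_r[ds, 1] < 0))
  # vertical components always sum to the vertical COM force
  expect_equal(tr$truth_grf_l[, 3] + tr$truth_grf_r[, 3],
               tr$truth_f_com$v[, 3], tolerance = 1e-9)
})

test_that("walking alternates phases close to the schedule", {
  s <- default_subject()
  ds_frac <- 0.2
  tr <- simulate_walk(s, ds_fraction = ds_frac)
  expect_setequal(unique(tr$labels), c("double", "single_L", "single_R"))
  # each label transition within 3 frames of the scheduled contact event
  fs <- tr$sample_rate
  events <- sort(c(tr$schedule$heel_strikes_L, tr$schedule$heel_strikes_R,
                   tr$schedule$toe_offs_L, tr$schedule$toe_offs_R))
  events <- events[events > 0 & events < max(tr$com$t)]
  trans <- which(tr$labels[-1] != tr$labels[-length(tr$labels)])
  for (tf in trans) {
    expect_lt(min(abs(tr$com$t[tf] - events)) * fs, 3.5)
  }
  # during single support the swing foot's truth force is identically zero
  expect_identical(max(abs(tr$truth_grf_r[tr$labels == "single_L", ])), 0)
  expect_identical(max(abs(tr$truth_grf_l[tr$labels == "single_R", ])), 0)
})

test_that("the vertical impulse over a gait cycle balances body weight", {
  s <- default_subject()
  tr <- simulate_walk(s)
  seg <- segment_trial("walking", tr$com, labels = tr$labels)
  i <- seg$start:seg$end
  mean_fz <- mean(tr$truth_grf_l[i, 3] + tr$truth_grf_r[i, 3])
  expect_lt(abs(mean_fz - s$BW) / s$BW, 0.02)
})

test_that("more COM noise never reduces the error at the true scale", {
  s <- default_subject()
  rmse_at_true <- function(sigma, seed) {
    tr <- simulate_squat(s, true_vppscale = 0.9, noise_sigma = sigma,
                         seed = seed)
    sweep_vppscale(tr, grid = 0.9, com_cutoff = 1.5)$total
  }
  seeds <- 1:10
  lo <- mean(vapply(seeds, function(sd) rmse_at_true(0.002, sd), numeric(1)))
  hi <- mean(vapply(seeds, function(sd) rmse_at_true(0.004, sd), numeric(1)))
  expect_gte(hi, lo)
})

test_that("generator input validation", {
  s <- default_subject()
  expect_error(simulate_squat(s, depth = 2), "below the ground")
  expect_error(simulate_squat(s, depth = -0.1), "non-negative")
  expect_error(simulate_walk(s, ds_fraction = 0.6), "0, 0.5")
  expect_error(simulate_walk(s, speed = 0), "positive")
})
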