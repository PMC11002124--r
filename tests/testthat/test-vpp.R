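test_that("VPP placement follows the force line and the scaled height", {
  s <- subject_params(80, 1.80)
  p <- vpp_params(vppscale = 0.9)
  # vertical force: planar offset zero, height 0.9 * 1.80
  r <- compute_vpp(c(0, 0, 1), c(0, 0, 800), p, s)
  expect_equal(unname(r$vpp[1, ]), c(0, 0, 1.62))
  expect_false(r$degenerate[1])
  # tilted force: offset = (COM_z / F_z) * F_xy
  r2 <- compute_vpp(c(0, 0, 1), c(80, 0, 800), p, s)
  expect_equal(unname(r2$vpp[1, ]), c(0.1, 0, 1.62), tolerance = 1e-12)
  # near-zero vertical force: degenerate, fall back above the COM
  r3 <- compute_vpp(c(0.3, -0.1, 1), c(5, 2, 0), p, s)
  expect_true(r3$degenerate[1])
  expect_equal(unname(r3$vpp[1, 1:2]), c(0.3, -0.1))
})

test_that("virtual pivot vectors are unit and point from COP to VPP", {
  r <- compute_vpv(c(0, 0, 1.62), c(0, 0, 0))
  expect_equal(unname(r$vpv[1, ]), c(0, 0, 1))
  # oracle: normalise (0, -0.2, 1.62), norm 1.63230
  r2 <- compute_vpv(c(0, 0, 1.62), c(0, 0.2, 0))
  expect_equal(unname(r2$vpv[1, ]), c(0, -0.12253, 0.99246), tolerance = 1e-4)
  set.seed(3)
  vpp <- matrix(rnorm(300), ncol = 3)
  cop <- matrix(rnorm(300), ncol = 3)
  r3 <- compute_vpv(vpp, cop)
  expect_equal(sqrt(rowSums(r3$vpv^2)), rep(1, 100), tolerance = 1e-12)
  expect_true(compute_vpv(c(1, 2, 3), c(1, 2, 3))$degenerate[1])
})

test_that("double-support solve matches analytic geometry and construction", {
  # symmetric squat: COPs at (0, +-0.2, 0), VPP (0, 0, 1.62), F (0,0,800)
  h <- 1.62; w <- 0.2; rho <- sqrt(h^2 + w^2)
  vl <- c(0, -w, h) / rho
  vr <- c(0, w, h) / rho
  sol <- solve_double_support(c(0, 0, 800), vl, vr)
  a_true <- 400 * rho / h  # independent geometric derivation
  expect_equal(sol$mag_l, a_true, tolerance = 0.01 / a_true)
  expect_equal(sol$mag_r, a_true, tolerance = 0.01 / a_true)
  grf_l <- sol$mag_l * vl
  expect_equal(unname(grf_l), c(0, -49.39, 400), tolerance = 0.01 / 400)
  # F along one direction: exact representation
  v2 <- c(0.3, 0.1, 0.9); v2 <- v2 / sqrt(sum(v2^2))
  sol2 <- solve_double_support(500 * vl, vl, v2)
  expect_equal(sol2$mag_l, 500, tolerance = 1e-12)
  expect_equal(sol2$mag_r, 0, tolerance = 1e-9)
  expect_lt(sol2$residual, 1e-9 * 500)
  # random consistent instances: recover the constructed magnitudes
  set.seed(21)
  for (i in 1:50) {
    u1 <- rnorm(3); u1 <- u1 / sqrt(sum(u1^2))
    u2 <- rnorm(3); u2 <- u2 / sqrt(sum(u2^2))
    if (abs(sum(u1 * u2)) > 0.99) next
    ab <- runif(2, 0, 900)
    f <- ab[1] * u1 + ab[2] * u2
    si <- solve_double_support(f, u1, u2)
    expect_equal(si$mag_l, ab[1], tolerance = 1e-9)
    expect_equal(si$mag_r, ab[2], tolerance = 1e-9)
    expect_lt(si$residual, 1e-9 * sqrt(sum(f^2)))
  }
})

test_that("residual equals the orthogonal-projection oracle", {
  set.seed(8)
  p <- vpp_params(nonneg_policy = "allow_negative")
  for (i in 1:25) {
    u1 <- rnorm(3); u1 <- u1 / sqrt(sum(u1^2))
    u2 <- rnorm(3); u2 <- u2 / sqrt(sum(u2^2))
    if (abs(sum(u1 * u2)) > 0.99) next
    f <- rnorm(3, sd = 300)
    sol <- solve_double_support(f, u1, u2, p)
    A <- cbind(u1, u2)
    oracle <- sqrt(sum((f - A %*% qr.solve(A, f))^2))
    expect_equal(sol$residual, oracle, tolerance = 1e-9 + 1e-9 * oracle)
  }
})

test_that("negative magnitudes are clamped and the other foot refit", {
  # force pointing away from vl's side -> raw LS gives a negative mag
  vl <- c(-0.5, 0, 0.866)
  vr <- c(0.5, 0, 0.866)
  f <- c(500, 0, 300)  # strongly anterior
  raw <- solve_double_support(f, vl, vr, vpp_params(nonneg_policy = "allow_negative"))
  expect_lt(raw$mag_l, 0)
  cl <- solve_double_support(f, vl, vr, vpp_params(nonneg_policy = "clamp_reassign"))
  expect_identical(cl$mag_l, 0)
  expect_true(cl$clamped[1])
  # refit is the 1-D projection onto vr
  expect_equal(cl$mag_r, sum(f * vr) / sum(vr^2), tolerance = 1e-12)
})

test_that("near-parallel directions trigger the flagged 50/50 fallback", {
  v <- c(0.01, 0, 0.99995)
  v2 <- v + c(1e-12, 0, 0)
  sol <- solve_double_support(c(0, 0, 800), v, v2, vpp_params(cond_limit = 1e6))
  expect_true(sol$ill_conditioned[1])
  expect_equal(sol$mag_l, sol$mag_r)
})

test_that("predicted force lines pass through the VPP", {
  s <- default_subject()
  tr <- simulate_lunge(s, true_vppscale = 0.9)
  sol <- predict_trial_grf(tr, vppscale = 0.9)
  ds <- which(sol$support == "double" & sol$flags == "")
  for (i in sample(ds, 50)) {
    for (side in c("l", "r")) {
      g <- sol[[paste0("grf_", side)]][i, ]
      cop <- sol[[paste0("cop_", side)]][i, ]
      u <- g / sqrt(sum(g^2))
      d <- sol$vpp[i, ] - cop
      dist <- sqrt(sum((d - sum(d * u) * u)^2))  # point-line distance
      expect_lt(dist, 1e-9)
    }
  }
})

test_that("sagittal mirroring swaps and mirrors the per-foot forces exactly", {
  s <- default_subject()
  tr <- simulate_lunge(s, stride = 0.5, true_vppscale = 0.9)
  sol <- predict_trial_grf(tr, vppscale = 0.9)
  solm <- predict_trial_grf(mirror_trial(tr), vppscale = 0.9)
  flip <- function(m) m %*% diag(c(1, -1, 1))
  expect_identical(max(abs(solm$grf_l - flip(sol$grf_r))), 0)
  expect_identical(max(abs(solm$grf_r - flip(sol$grf_l))), 0)
})

test_that("single-support and flight frames bypass the VPP solve", {
  s <- subject_params(70, 1.70)
  t <- seq(0, 0.5, by = 1 / 120)
  com <- trajectory(t, cbind(0.1 * t, 0, 0.9 + 0.01 * sin(7 * t)))
  f <- compute_com_force(com, s)
  n <- length(t)
  left <- fake_foot(t, c(0.1, 0.1, 0))
  right <- airborne_foot(t)
  sol <- predict_grf(f, com, left, right, params = vpp_params(), subject = s)
  expect_identical(sol$support, rep("single_L", n))
  expect_identical(sol$grf_l, f$v)          # componentwise, no solve
  expect_identical(max(abs(sol$grf_r)), 0)
  solf <- predict_grf(f, com, airborne_foot(t), airborne_foot(t),
                      params = vpp_params(), subject = s)
  expect_identical(max(abs(solf$grf_l)), 0)
  expect_identical(max(abs(solf$grf_r)), 0)
  expect_identical(solf$support, rep("flight", n))
})

test_that("prediction error is much less scale-sensitive above the optimum", {
  s <- default_subject()
  tr <- simulate_squat(s, true_vppscale = 0.9)
  sw <- sweep_vppscale(tr)
  g <- sw$scales
  slope <- abs(diff(sw$total) / diff(g))
  below <- mean(slope[g[-1] <= 0.8])
  above <- mean(slope[g[-length(g)] >= 0.9])
  expect_lt(above, below)
})
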