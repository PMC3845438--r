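# DFT normalization, angular energy, direction extraction, detection.

test_that("dft2 obeys the stated normalization and symmetries", {
  # constant image: everything in the centered DC bin
  s <- dft2(matrix(7, 16, 16))
  expect_equal(Mod(s$F[s$center[1], s$center[2]]), 7)
  off <- Mod(s$F)
  off[s$center[1], s$center[2]] <- 0
  expect_lt(max(off), 1e-12)
  # Parseval under the 1/(MN) scaling
  set.seed(4)
  f <- matrix(rnorm(16 * 16), 16, 16)
  s <- dft2(f)
  expect_equal(sum(Mod(s$F)^2), sum(f^2) / (16 * 16), tolerance = 1e-12)
  # real input -> conjugate symmetry: |F| even under (u,v) -> (-u,-v)
  mag <- s$magnitude
  flip <- mag[c(1, 16:2), c(1, 16:2)] # index -k mod 16
  expect_equal(mag, flip, tolerance = 1e-12)
  expect_error(dft2(array(1, c(8, 8, 2))), class = "vg_invalid_parameter")
  expect_error(dft2(matrix(1, 4, 4)), class = "vg_invalid_parameter")
})

test_that("dft2 agrees with the brute-force double-sum oracle", {
  set.seed(11)
  f <- matrix(runif(8 * 8, 0, 255), 8, 8)
  expect_equal(dft2(f)$F, brute_dft2(f), tolerance = 1e-10)
})

test_that("angular profile: wedge tiling, monotonicity in omega, periodic domain", {
  set.seed(2)
  s <- dft2(matrix(rnorm(32 * 32, 100, 20), 32, 32))
  # disjoint wedges (omega = dtheta/2) tile the off-DC plane exactly
  pr <- angular_energy_profile(s, dtheta = 1, omega = 0.5)
  expect_equal(sum(pr$energy), pr$total, tolerance = 1e-9)
  expect_true(all(pr$energy >= 0))
  expect_equal(pr$theta, 0:179)
  # enlarging the wedge never loses energy
  pr2 <- angular_energy_profile(s, dtheta = 1, omega = 1)
  expect_true(all(pr2$energy >= pr$energy - 1e-12))
  expect_error(angular_energy_profile(s, omega = 0),
               class = "vg_invalid_parameter")
  expect_error(angular_energy_profile(s, dtheta = 7),
               class = "vg_invalid_parameter")
})

test_that("white-noise profiles are flat on average", {
  pr_sum <- numeric(180)
  withr::with_seed(6, {
    for (i in 1:100) {
      img <- matrix(60 + rnorm(64 * 64, sd = 10), 64, 64)
      pr_sum <- pr_sum + angular_energy_profile(dft2(img))$energy
    }
  })
  avg <- pr_sum / 100
  expect_lt(max(avg) / min(avg), 1.5)
})

test_that("bar phantoms put the spectral peak perpendicular to the tube", {
  # 30-degree bar: spectral line at 120 degrees
  p <- make_tube_2d(64, 30, 2, 100, 0)
  pr <- angular_energy_profile(dft2(p$image, window = TRUE))
  argmax <- pr$theta[which.max(pr$energy)]
  expect_lte(min(abs(argmax - 120), 180 - abs(argmax - 120)),
             max(pr$dtheta, 5))
  # sub-grid refinement keeps the peak within the recovery tolerance
  dirs <- find_feature_directions(pr)
  expect_lte(min(abs(dirs$theta_refined[1] - 120),
                 180 - abs(dirs$theta_refined[1] - 120)), 5)
  # rotating the ROI by 90 degrees shifts the argmax by 90 (mod 180)
  pr_rot <- angular_energy_profile(dft2(t(p$image)[64:1, ], window = TRUE))
  argmax_rot <- pr_rot$theta[which.max(pr_rot$energy)]
  d <- abs(argmax_rot - argmax) %% 180
  expect_lte(min(abs(d - 90), abs(90 - d)), max(2 * pr$dtheta, 2))
})

test_that("feature directions: peak counts and direction vectors", {
  # single bar -> exactly one reported direction after merging
  p <- make_tube_2d(64, 30, 2, 100, 0)
  dirs <- find_feature_directions(
    angular_energy_profile(dft2(p$image, window = TRUE)))
  expect_identical(nrow(dirs), 1L)
  expect_lt(abs(dirs$structure_angle - 30), 5)
  # Y-branch with well-separated limbs -> at least two directions
  y <- make_branch_2d(96, 0, 60, 2, 100, 0)
  dirsy <- find_feature_directions(
    angular_energy_profile(dft2(y$image, window = TRUE)), min_rel = 0.3)
  expect_gte(nrow(dirsy), 2L)
  # flat profile -> no directions
  flat <- structure(
    list(theta = 0:179, energy = rep(1, 180), normalized = rep(1 / 180, 180),
         omega = 5, dtheta = 1, total = 180, measure = "magnitude",
         bin_angle = numeric(0), bin_weight = numeric(0)),
    class = "angular_profile")
  expect_identical(nrow(find_feature_directions(flat)), 0L)
})

test_that("direction_vector follows the printed component-swap rule", {
  expect_equal(direction_vector(30), c(cospi(30 / 180), sinpi(30 / 180)))
  expect_equal(direction_vector(120), c(sinpi(120 / 180), cospi(120 / 180)))
  expect_equal(direction_vector(120, formula = "continuous"),
               c(cospi(120 / 180), sinpi(120 / 180)))
  # the swap rule is not rotation-consistent; the continuous form is
  expect_equal(sum(direction_vector(120, "continuous")^2), 1)
})

synthetic_profile <- function(energy, dtheta = 1, omega = 5) {
  structure(
    list(theta = seq(0, 180 - dtheta, by = dtheta), energy = energy,
         normalized = energy / sum(energy), omega = omega, dtheta = dtheta,
         total = sum(energy), measure = "magnitude",
         bin_angle = numeric(0), bin_weight = numeric(0)),
    class = "angular_profile")
}

test_that("trough-peak-trough arithmetic matches the printed criterion", {
  # triangular lobe: peak 100 at 90 deg, troughs 10 at +/-30 deg
  g <- rep(10, 180)
  ramp <- seq(10, 100, length.out = 31)
  g[(60:90) + 1] <- ramp
  g[(90:120) + 1] <- rev(ramp)
  d <- detect_vessel(synthetic_profile(g), threshold = 2, normalize = FALSE)
  expect_true(d$detected)
  expect_equal(d$peak, 100)
  expect_equal(d$valley_left, 10)
  expect_equal(d$valley_right, 10)
  expect_equal(d$distance_left, 30)
  expect_equal(d$distance_right, 30)
  expect_equal(d$ratio_left, 3)
  expect_equal(d$ratio_right, 3)
  # ratio 3 < threshold 4 -> rejected
  expect_false(detect_vessel(synthetic_profile(g), threshold = 4,
                             normalize = FALSE)$detected)
  # flat profile -> not detected
  expect_false(detect_vessel(synthetic_profile(rep(5, 180)),
                             threshold = 0.001)$detected)
})

test_that("both sides must satisfy the slope test simultaneously", {
  # steep on the left of the peak, flat shelf on the right
  g <- rep(10, 180)
  g[(60:90) + 1] <- seq(10, 100, length.out = 31)
  g[(91:180)] <- 98 # barely below the peak for 90 degrees
  d <- detect_vessel(synthetic_profile(g), threshold = 2, normalize = FALSE)
  expect_gte(d$ratio_left, 2)
  expect_lt(d$ratio_right, 2)
  expect_false(d$detected)
})

test_that("direction recovery survives noise across orientations and radii", {
  bad <- 0; n <- 0
  for (radius in c(2, 3)) {
    for (ang in seq(0, 165, by = 15)) {
      for (sd0 in 1:2) {
        p <- make_tube_2d(64, ang, radius, 100, 5, seed = sd0)
        dirs <- find_feature_directions(
          angular_energy_profile(dft2(p$image, window = TRUE)))
        err <- abs(dirs$structure_angle[1] - ang) %% 180
        err <- min(err, 180 - err)
        n <- n + 1
        if (err > 5) bad <- bad + 1
      }
    }
  }
  expect_lte(bad / n, 0.05)
})
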