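# Hessian field, eigenvalue ratios, vesselness, multiscale fusion.

test_that("Hessian of trivial images behaves like the continuous operator", {
  const <- matrix(42, 32, 32)
  h <- gaussian_hessian(const, 2)
  expect_equal(max(abs(h$lambda1)), 0, tolerance = 1e-10)
  expect_equal(max(abs(h$lambda2)), 0, tolerance = 1e-10)
  expect_equal(h$S, matrix(0, 32, 32), tolerance = 1e-10)
  # derivative kills a constant offset
  p <- make_tube_2d(48, 20, 3, 100, 0)
  h1 <- gaussian_hessian(p$image, 2)
  h2 <- gaussian_hessian(p$image + 17, 2)
  expect_equal(h1$lambda2, h2$lambda2, tolerance = 1e-12)
  expect_equal(h1$S, h2$S, tolerance = 1e-12)
  expect_error(gaussian_hessian(p$image, 0), class = "vg_invalid_parameter")
})

test_that("Hessian matrix is symmetric and eigenvalues are |.|-ordered", {
  p <- make_tree_2d(96, 2, 3, 100, 10, seed = 3)
  h <- gaussian_hessian(p$image, 3)
  expect_true(all(abs(h$lambda1) <= abs(h$lambda2) + 1e-12))
  # eigenvalues solve the characteristic equation of (xx, xy; xy, yy)
  expect_equal(h$lambda1 + h$lambda2, h$xx + h$yy, tolerance = 1e-9)
  expect_equal(h$lambda1 * h$lambda2, h$xx * h$yy - h$xy^2, tolerance = 1e-6)
})

test_that("center eigenvalues match the closed-form Gaussian oracle (2D ridge)", {
  w <- 3; sigma <- 2; contrast <- 100
  p <- make_tube_2d(49, 0, w, contrast, 0) # odd size: exact center pixel
  h <- gaussian_hessian(p$image, sigma)
  truth <- analytic_center_eigs("tube", w, sigma, contrast, ndim = 2)
  # lambda1 ~ 0 along the ridge, lambda2 the cross-section curvature
  expect_lt(abs(h$lambda1[25, 25]), 0.05 * abs(truth[2]))
  expect_equal(h$lambda2[25, 25], truth[2], tolerance = 0.05)
})

test_that("center eigenvalues match the analytic oracle for 3D blob/sheet/tube", {
  w <- 3; sigma <- 2; contrast <- 100
  for (kind in c("blob", "sheet", "tube")) {
    p <- make_blob_sheet_tube_3d(31, kind, w, contrast)
    h <- gaussian_hessian(p$image, sigma)
    got <- sort(c(h$lambda1[16, 16, 16], h$lambda2[16, 16, 16],
                  h$lambda3[16, 16, 16]))
    truth <- sort(analytic_center_eigs(kind, w, sigma, contrast))
    for (i in 1:3) {
      if (truth[i] == 0) {
        expect_lt(abs(got[i]), 0.05 * max(abs(truth)))
      } else {
        expect_equal(got[i], truth[i], tolerance = 0.05)
      }
    }
  }
})

test_that("closed-form 3x3 eigenvalues agree with base eigen()", {
  set.seed(1)
  for (i in 1:50) {
    m <- matrix(rnorm(9), 3)
    m <- (m + t(m)) / 2
    got <- sort(unlist(vesselgrow:::sym3_eigenvalues(
      m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])))
    expect_equal(got, sort(eigen(m, symmetric = TRUE)$values),
                 tolerance = 1e-8)
  }
})

test_that("eigenvalue ratios evaluate as defined, with guarded degeneracies", {
  expect_equal(blobness_ratio_2d(0, -10), 0)
  expect_equal(blobness_ratio_2d(-7, -7), 1)
  expect_equal(blobness_ratio_2d(-1, -4), 0.25)
  expect_equal(blobness_ratio_2d(0, 0), 0)
  expect_equal(blobness_ratio_3d(0, -5, -5), 0)
  expect_equal(blobness_ratio_3d(-1, -2, -8), 0.25)
  expect_equal(blobness_ratio_3d(-3, -3, -3), 1)
  expect_equal(blobness_ratio_3d(0, 0, 0), 0)
  expect_equal(anisotropy_ratio_3d(-5, -10), 0.5)
  expect_equal(anisotropy_ratio_3d(-9, -9), 1)
  expect_equal(anisotropy_ratio_3d(0, -10), 0)
  expect_equal(anisotropy_ratio_3d(0, 0), 0)
})

make_field_2d <- function(l1, l2, S, sigma = 1) {
  structure(list(sigma = sigma, ndim = 2L,
                 lambda1 = matrix(l1), lambda2 = matrix(l2),
                 S = matrix(S)),
            class = "hessian_field")
}

make_field_3d <- function(l1, l2, l3, S, sigma = 1) {
  structure(list(sigma = sigma, ndim = 3L,
                 lambda1 = array(l1, c(1, 1, 1)),
                 lambda2 = array(l2, c(1, 1, 1)),
                 lambda3 = array(l3, c(1, 1, 1)),
                 S = array(S, c(1, 1, 1))),
            class = "hessian_field")
}

test_that("2D vesselness formula: zero branch and limiting values", {
  pr <- vesselness_params(c = 1, c_mode = "constant")
  # positive lambda2 -> 0 regardless of everything else
  expect_equal(as.numeric(vesselness_2d(make_field_2d(1, 3, 100), pr)), 0)
  # ideal line (RB = 0) with S >> c -> both factors -> 1
  expect_equal(as.numeric(vesselness_2d(make_field_2d(0, -50, 50), pr)), 1,
               tolerance = 1e-6)
  # RB = 1, beta = 0.5, S >> c -> exp(-2)
  expect_equal(as.numeric(vesselness_2d(make_field_2d(-40, -40, 60), pr)),
               exp(-2), tolerance = 1e-6)
})

test_that("3D vesselness formula: zero branch, ideal tube, tube > blob", {
  pr <- vesselness_params(c = 1, c_mode = "constant")
  expect_equal(as.numeric(vesselness_3d(make_field_3d(0, -2, 1, 10), pr)), 0)
  # ideal tube (0, -k, -k): RA = 1, RB = 0 -> (1 - exp(-2))
  v_tube <- as.numeric(vesselness_3d(make_field_3d(0, -40, -40, 60), pr))
  expect_equal(v_tube, 1 - exp(-2), tolerance = 1e-6)
  # ideal blob (-k, -k, -k) scores below the tube at the same S
  v_blob <- as.numeric(vesselness_3d(make_field_3d(-40, -40, -40, 70), pr))
  expect_equal(v_blob, (1 - exp(-2)) * exp(-2), tolerance = 1e-6)
  expect_lt(v_blob, v_tube)
})

test_that("vesselness lies in [0, 1] and ignores constant offsets", {
  p <- make_tree_2d(96, 3, 3, 100, 10, seed = 5)
  e1 <- multiscale_enhance(p$image)
  expect_true(all(e1$enhanced >= 0 & e1$enhanced <= 1))
  e2 <- multiscale_enhance(p$image + 30)
  expect_equal(e1$enhanced, e2$enhanced, tolerance = 1e-9)
  v3 <- make_blob_sheet_tube_3d(24, "tube", 2, 100, noise_sd = 5, seed = 2)
  e3 <- multiscale_enhance(v3$image, vesselness_params(scales = c(1, 2)))
  expect_true(all(e3$enhanced >= 0 & e3$enhanced <= 1))
})

test_that("tube outscores blob and sheet at the center voxel", {
  pr <- vesselness_params(scales = c(2))
  vals <- vapply(c("tube", "blob", "sheet"), function(kind) {
    p <- make_blob_sheet_tube_3d(31, kind, 3, 100)
    multiscale_enhance(p$image, pr)$enhanced[16, 16, 16]
  }, numeric(1))
  expect_gt(vals["tube"], vals["blob"])
  expect_gt(vals["tube"], vals["sheet"])
})

test_that("multiscale fusion is an argmax over the single-scale responses", {
  p <- make_tube_2d(64, 0, 3, 100, 5, seed = 9)
  pr <- vesselness_params()
  e <- multiscale_enhance(p$image, pr)
  singles <- lapply(pr$scales, function(s) {
    vesselness_2d(gaussian_hessian(p$image, s), pr)
  })
  # fused response dominates every single scale pointwise...
  for (v in singles) expect_true(all(e$enhanced >= v - 1e-12))
  # ...and equals the exhaustive per-pixel maximum
  expect_equal(e$enhanced, Reduce(pmax, singles), tolerance = 1e-12)
  # single-scale run is the identity
  pr1 <- vesselness_params(scales = 3)
  e1 <- multiscale_enhance(p$image, pr1)
  expect_equal(e1$enhanced, vesselness_2d(gaussian_hessian(p$image, 3), pr1))
  expect_true(all(e1$scale_map == 3))
  expect_error(vesselness_params(scales = numeric(0)),
               class = "vg_invalid_parameter")
})

test_that("argmax scale on the centerline tracks the exhaustive evaluation", {
  pr <- vesselness_params()
  for (radius in c(2, 5)) {
    p <- make_tube_2d(63, 0, radius, 100, 0)
    singles <- vapply(pr$scales, function(s) {
      vesselness_2d(gaussian_hessian(p$image, s), pr)[32, 32]
    }, numeric(1))
    e <- multiscale_enhance(p$image, pr)
    expect_equal(e$scale_map[32, 32], pr$scales[which.max(singles)])
  }
})
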