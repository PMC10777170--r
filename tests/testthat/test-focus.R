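test_that("convolution kernels behave on constants, impulses and ramps", {
  expect_equal(sum(gaussian_kernel(1)), 1, tolerance = 1e-15)
  expect_identical(sum(laplacian_kernel()), 0)
  const <- matrix(5, 9, 9)
  expect_equal(gaussian_blur(const), const, tolerance = 1e-12)
  expect_equal(laplacian(const), matrix(0, 9, 9))
  # impulse response reproduces the kernel
  imp <- matrix(0, 11, 11); imp[6, 6] <- 1
  expect_equal(gaussian_blur(imp)[4:8, 4:8], gaussian_kernel(1),
               tolerance = 1e-12)
  # Laplacian annihilates an affine ramp in the interior
  ramp <- outer(1:12, 1:12, function(i, j) 3 * i - 2 * j + 1)
  expect_equal(laplacian(ramp)[3:10, 3:10], matrix(0, 8, 8))
  expect_error(laplacian(matrix(0, 3, 3)), "smaller")
})

test_that("convolutions equal the brute-force dense oracle bit for bit", {
  set.seed(5)
  ramp <- outer(1:7, 1:7, `+`) + 0.1
  expect_identical(laplacian(ramp), brute_conv2(ramp, laplacian_kernel()))
  img <- matrix(rnorm(15 * 12, 200, 2), 15, 12)
  expect_identical(laplacian(img), brute_conv2(img, laplacian_kernel()))
  expect_identical(gaussian_blur(img), brute_blur(img))
  # step edge: antisymmetric response about the edge
  step <- cbind(matrix(0, 12, 6), matrix(1, 12, 6))
  L <- laplacian(step)
  expect_identical(L, brute_conv2(step, laplacian_kernel()))
  expect_equal(L[6, ], -rev(L[6, ]), tolerance = 1e-12)
  # masked blur ignores invalid pixels
  img[3, 4] <- NA
  expect_identical(gaussian_blur(img), brute_blur(img))
})

test_that("sharpness peaks at the plane where the edge is sharpest", {
  st <- edge_stack(sigmas = c(2, 0.5, 3))
  s <- sharpness(st)
  edge_px <- 16  # column adjacent to the edge
  expect_equal(which.max(s$values[edge_px, 16, ]), 2)
  # constant stack: zero sharpness
  cs <- make_stack(array(7, c(16, 16, 3)), c(0, 10, 20))
  expect_lt(max(sharpness(cs)$values), 1e-9)
  # single plane passes through
  s1 <- sharpness(make_stack(array(rnorm(64), c(8, 8, 1)), 5))
  expect_equal(dim(s1$values)[3], 1)
})

test_that("Savitzky-Golay depth smoothing: polynomials, identity, external check", {
  nd <- 31
  poly <- 0.5 + 0.1 * (1:nd) - 0.003 * (1:nd)^2 + 1e-4 * (1:nd)^3
  st <- make_stack(array(rep(poly, each = 36), c(6, 6, nd)), 1:nd)
  s <- structure(list(values = st$images, depths = st$depths, grid = st$grid),
                 class = "sharpness_stack")
  sm <- smooth_depth_profiles(s, 11, 3)
  # a cubic is reproduced everywhere (endpoint fits included)
  expect_equal(sm$values[3, 3, ], poly, tolerance = 1e-10)
  # window = 1 is the identity
  expect_identical(smooth_depth_profiles(s, 1, 3)$values, s$values)
  # independent cross-check against signal::sgolayfilt on a random profile
  set.seed(9)
  prof <- abs(rnorm(nd, 1, 0.3))
  s2 <- structure(list(values = array(rep(prof, each = 1), c(1, 1, nd)),
                       depths = 1:nd, grid = st$grid),
                  class = "sharpness_stack")
  ours <- smooth_depth_profiles(s2, 11, 3)$values[1, 1, ]
  ref <- as.numeric(signal::sgolayfilt(prof, p = 3, n = 11))
  ref[ref < 0] <- 0
  expect_equal(ours, ref, tolerance = 1e-10)
  # our coefficient rows equal explicit least-squares fits
  expect_equal(as.numeric(signal::sgolay(3, 11)[6, ]), sg_weights_ls(11, 3, 6),
               tolerance = 1e-10)
  expect_equal(as.numeric(signal::sgolay(3, 11)[2, ]), sg_weights_ls(11, 3, 2),
               tolerance = 1e-10)
  expect_error(smooth_depth_profiles(s, 10, 3), "odd")
  expect_error(smooth_depth_profiles(s, 3, 3), "odd|polyorder")
})

test_that("smoothing keeps the argmax of noisy unimodal profiles near the truth", {
  nd <- 51; k0 <- 26
  set.seed(123)
  hits <- 0
  for (r in 1:1000) {
    prof <- exp(-((1:nd) - k0)^2 / (2 * 5^2)) + rnorm(nd, 0, 0.15)
    s <- structure(list(values = array(prof, c(1, 1, nd)), depths = 1:nd,
                        grid = NULL), class = "sharpness_stack")
    sm <- smooth_depth_profiles(s, 11, 3)$values[1, 1, ]
    if (abs(which.max(sm) - k0) <= 2) hits <- hits + 1
  }
  expect_gte(hits, 950)
})

test_that("focus stacking identities: constant stacks and single planes", {
  img <- matrix(rnorm(100, 200, 1), 10, 10)
  st <- make_stack(array(rep(img, 5), c(10, 10, 5)), seq(0, 40, 10))
  fs <- focus_stack(st)
  expect_identical(fs$fs_image, img)
  # all planes tie exactly (no depth smoothing): shallowest depth wins
  fs0 <- focus_stack(st, sg_window = 1)
  expect_identical(fs0$fs_image, img)
  expect_true(all(fs0$focal_depth_map == 0))
  # single-plane stack is idempotent
  fs1 <- focus_stack(make_stack(array(img, c(10, 10, 1)), 7))
  expect_identical(fs1$fs_image, img)
  expect_true(all(fs1$focal_depth_map == 7))
})

test_that("focus stacking selects the sharpest plane at an edge", {
  st <- edge_stack(sigmas = c(2, 0.5, 3), depths = c(10, 20, 30))
  fs <- focus_stack(st)
  # pixels adjacent to the edge come from plane 2
  expect_true(all(fs$focal_depth_map[15:17, 8:24] == 20))
  # selection property: every valid pixel value is an element of its profile
  for (i in sample(32, 10)) {
    for (j in sample(32, 10)) {
      expect_true(fs$fs_image[i, j] %in% st$images[i, j, ])
    }
  }
})

test_that("focus stacking equals the brute-force per-pixel argmax oracle", {
  set.seed(77)
  for (r in 1:4) {
    imgs <- array(rnorm(16 * 16 * 8, 200, 1), c(16, 16, 8))
    if (r >= 3) imgs[sample(length(imgs), 40)] <- NA  # invalid pixels
    st <- make_stack(imgs, seq(0, 70, 10))
    win <- if (r %% 2 == 0) 5 else 7
    fs <- focus_stack(st, sigma = 1, sg_window = win, sg_polyorder = 3)
    br <- brute_focus_stack(st, sigma = 1, sg_window = win, sg_polyorder = 3)
    expect_identical(fs$fs_image, br$fs_image)
    expect_identical(fs$focal_depth_map, br$focal_depth_map)
  }
})

test_that("invalid pixels fall back to valid planes or are marked invalid", {
  imgs <- array(rnorm(8 * 8 * 3, 200, 1), c(8, 8, 3))
  imgs[4, 4, 2] <- NA          # invalid in one plane only
  imgs[2, 2, ] <- NA           # invalid everywhere
  st <- make_stack(imgs, c(0, 10, 20))
  fs <- focus_stack(st, sg_window = 1)
  expect_false(fs$valid[2, 2])
  expect_true(is.na(fs$fs_image[2, 2]))
  expect_true(fs$valid[4, 4])
  expect_true(fs$focal_depth_map[4, 4] %in% c(0, 20))
  expect_false(is.na(fs$fs_image[4, 4]))
})
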