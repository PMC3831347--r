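test_that("transform algebra: composition, kinds, serialization", {
  th <- 0.3
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  r1 <- spatial_transform("rigid", R, c(1, 2, 3))
  r2 <- rigid_from_params(c(0.5, 0, 0, 0, 0.2, 0), center = c(5, 5, 5))
  comp <- compose_transforms(r1, r2)
  expect_identical(comp$kind, "rigid")
  expect_lt(max(abs(crossprod(comp$A) - diag(3))), 1e-9)
  # associativity on points
  p <- matrix(rnorm(30), 10, 3)
  lhs <- transform_points(compose_transforms(r1, r2), p)
  rhs <- transform_points(r1, transform_points(r2, p))
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_error(spatial_transform("rigid", diag(3) * 2), "orthonormal")

  dir <- withr::local_tempdir()
  path <- file.path(dir, "tf.txt")
  write_transform(comp, path)
  back <- read_transform(path, "rigid")
  expect_equal(back$A, comp$A, tolerance = 1e-12)
  expect_equal(back$t, comp$t, tolerance = 1e-12)
})

test_that("resample: identity is exact, integer shifts match the shift oracle", {
  set.seed(40)
  v <- mri_volume(array(runif(10^3), c(10, 10, 10)))
  r_id <- resample(v, transform_identity(), v)
  expect_equal(r_id$data, v$data, tolerance = 1e-12)

  tf <- spatial_transform("rigid", diag(3), c(2, 0, 0))
  r <- resample(v, tf, v, "nearest")
  want <- emtseg:::shift_array(v$data, c(-2, 0, 0))
  expect_equal(r$data[1:8, , ], want[1:8, , ])
  # labels use nearest and keep integer codes
  lab <- label_volume(array(sample(0:2, 10^3, TRUE), c(10, 10, 10)),
                      c(a = 0, b = 1, c = 2))
  rl <- resample(lab, tf, lab, "nearest")
  expect_true(all(rl$data %in% 0:2))
  want_lab <- emtseg:::shift_array(lab$data, c(-2, 0, 0))[1:8, , ]
  storage.mode(want_lab) <- "integer"
  expect_identical(rl$data[1:8, , ], want_lab)
})

test_that("resampled prior stacks renormalize to per-voxel sum 1", {
  ph <- small_phantom(n = 12, pn = 0, rf = 0, blur = 1)
  tf <- spatial_transform("affine", diag(c(1.02, 1, 0.98)), c(0.3, -0.2, 0))
  warped <- resample_atlas(ph$atlas, tf, ph$atlas$priors[[1]])
  tot <- Reduce(`+`, lapply(warped$priors, function(v) v$data))
  inside <- tot > 0
  expect_lt(max(abs(tot[inside] - 1)), 1e-10)
  expect_true(all(vapply(warped$priors, function(v) min(v$data), 0) >= 0))
})

test_that("rigid registration recovers known translations and rotations", {
  ctr <- rep(6 + (32 - 1) / 2, 3)
  # translation by 3 voxels along x
  tft <- spatial_transform("rigid", diag(3), c(3, 0, 0))
  rp <- reg_pair(11, tft)
  tf <- register_rigid(rp$fixed, rp$moving)
  expect_lt(max(abs(tf$t - c(-3, 0, 0))), 0.5)
  expect_lt(max(abs(tf$A - diag(3))), 0.02)
  # 5-degree rotation about z
  th <- 5 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  tfr <- spatial_transform("rigid", R, as.numeric(ctr - R %*% ctr))
  rp2 <- reg_pair(11, tfr)
  tf2 <- register_rigid(rp2$fixed, rp2$moving)
  ang_err <- acos(min(1, (sum(diag(tf2$A %*% R)) - 1) / 2)) * 180 / pi
  expect_lt(ang_err, 1)
  # identity in, identity out
  fixed <- rp$fixed
  tfi <- register_rigid(fixed, fixed)
  expect_lt(max(abs(tfi$t)), 0.05)
  expect_lt(max(abs(tfi$A - diag(3))), 0.001)
})

test_that("affine registration recovers anisotropic scale within 2%", {
  ctr <- rep(6 + (32 - 1) / 2, 3)
  S <- diag(c(1.1, 1.0, 0.9))
  tfs <- spatial_transform("affine", S, as.numeric(ctr - S %*% ctr))
  rp <- reg_pair(12, tfs)
  tf <- register_affine(rp$fixed, rp$moving)
  expect_lt(max(abs(diag(tf$A) - 1 / c(1.1, 1.0, 0.9))), 0.02)
  # residual misalignment: compose recovered with the generating transform
  comp <- compose_transforms(tf, tfs)
  pts <- emtseg:::grid_points(emtseg:::grid_of(rp$fixed))
  disp <- transform_points(comp, pts) - pts
  expect_lt(mean(sqrt(rowSums(disp^2))), 1)
})

test_that("deformable plug-in contract: stub fields and affine fallback", {
  v <- smooth_random_volume(13, n = 16)
  zero_plugin <- function(fixed, moving)
    lapply(1:3, function(i) array(0, dim(fixed$data)))
  tf0 <- deformable_backend(v, v, zero_plugin)
  expect_identical(tf0$kind, "displacement")
  expect_equal(resample(v, tf0, v)$data, v$data, tolerance = 1e-12)

  shift_plugin <- function(fixed, moving)
    list(array(2, dim(fixed$data)), array(0, dim(fixed$data)),
         array(0, dim(fixed$data)))
  tfs <- deformable_backend(v, v, shift_plugin)
  r <- resample(v, tfs, v, "nearest")
  want <- emtseg:::shift_array(v$data, c(-2, 0, 0))
  expect_equal(r$data[1:14, , ], want[1:14, , ])

  moving <- resample(v, spatial_transform("rigid", diag(3), c(1, 0, 0)), v)
  expect_warning(tff <- deformable_backend(v, moving, NULL),
                 "falling back to affine")
  expect_true(isTRUE(attr(tff, "fallback")))
  expect_identical(tff$kind, "affine")

  bad_plugin <- function(fixed, moving) list(array(0, c(2, 2, 2)),
                                             array(0, c(2, 2, 2)),
                                             array(0, c(2, 2, 2)))
  expect_error(deformable_backend(v, v, bad_plugin), "grid")
})

test_that("repeat fusion averages and reduces noise by sqrt(k)", {
  v <- mri_volume(array(50, c(24, 24, 24)))
  expect_identical(fuse_repeats(v)$data, v$data)
  expect_identical(fuse_repeats(list(v, v, v))$data, v$data)
  r1 <- add_noise(v, 10, 50, seed = 1)
  r2 <- add_noise(v, 10, 50, seed = 2)
  fused <- fuse_repeats(list(r1, r2))
  sd1 <- sd(r1$data - v$data)
  sdf <- sd(fused$data - v$data)
  expect_equal(sdf, sd1 / sqrt(2), tolerance = 0.05)
})
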