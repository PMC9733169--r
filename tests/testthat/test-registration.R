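test_that("SBI extraction finds each well-separated particle once, within a voxel", {
  cfg <- small_phantom_config(seed = 8, days = c(27), dim = c(64, 96, 96),
                              n_roots = 1, n_particles = 30,
                              final_length_mm_range = c(6, 7),
                              particle_min_sep = 10,
                              rotation_range_deg = c(0, 0),
                              translation_range_vox = c(0, 0))
  sim <- generate_phantom_series(cfg)
  # absolute threshold above root signal (~120) and below particle gray values
  cloud <- extract_sbi(sim$volumes[[1]], threshold_abs = 150)
  expect_equal(nrow(cloud$points), 30)
  truth_xy <- as.matrix(sim$truth$particles[, c("x", "y")])
  for (i in seq_len(nrow(cloud$points))) {
    d <- sqrt(colSums((t(truth_xy) - cloud$points[i, ])^2))
    expect_lt(min(d), 1)
  }
})

test_that("SBI extraction errors on featureless volumes and merges touching blobs", {
  flat <- volume3d(array(100L, c(10, 20, 20)), 0.3, 1)
  expect_error(extract_sbi(flat), "threshold")

  # two overlapping balls form one 26-connected component -> one centroid
  v <- array(0, c(30, 30, 30))
  co <- as.matrix(expand.grid(z = 1:30, y = 1:30, x = 1:30))
  v[rowSums(sweep(co, 2, c(15, 15, 12))^2) <= 9] <- 200
  v[rowSums(sweep(co, 2, c(15, 15, 16))^2) <= 9] <- 200
  vol <- volume3d(v, 0.3, 1)
  cloud <- extract_sbi(vol, threshold_abs = 100, min_points = 1)
  expect_equal(nrow(cloud$points), 1)

  # adding a uniform offset below the threshold does not change the cloud
  cfg <- small_phantom_config(seed = 8, days = c(27), dim = c(48, 64, 64),
                              n_roots = 1, n_particles = 20,
                              final_length_mm_range = c(6, 7))
  sim <- generate_phantom_series(cfg)
  v1 <- sim$volumes[[1]]
  v2 <- volume3d(v1$intensities + 10L, v1$voxel_size_mm, v1$day)
  c1 <- extract_sbi(v1, threshold_percentile = 99.9, min_points = 5)
  c2 <- extract_sbi(v2, threshold_percentile = 99.9, min_points = 5)
  expect_equal(c1$points, c2$points)
})

test_that("pairwise ICP recovers known transforms", {
  # moving == reference -> identity
  cl <- withr::with_seed(5, make_disc_cloud(100))
  tr <- register_pair(cl, cl)
  expect_lt(abs(tr$theta_deg), 1e-6)
  expect_lt(sqrt(tr$tx^2 + tr$ty^2), 1e-6)

  # known rotation + translation, clean points
  tru <- rigid2d(5, 3, -2, center = c(80, 80))
  moved <- transform_points(tru, cl)
  rec <- register_pair(moved, cl)
  dev <- transform_deviation(compose_transforms(rec, tru), at = c(80, 80))
  expect_lt(dev[1], 0.5)
  expect_lt(dev[2], 0.5)

  # Monte-Carlo: dropout + jitter over 20 seeds
  for (s in 1:20) {
    withr::with_seed(300 + s, {
      P <- make_disc_cloud(150)
      tru <- rigid2d(runif(1, -10, 10), runif(1, -5, 5), runif(1, -5, 5),
                     center = c(80, 80))
      Q <- transform_points(tru, P)
      keep <- runif(150) > 0.1
      Q <- Q[keep, ] + matrix(rnorm(2 * sum(keep), 0, 0.2), ncol = 2)
      rec <- register_pair(Q, P)
      dev <- transform_deviation(compose_transforms(rec, tru), at = c(80, 80))
      expect_lt(dev[1], 0.5)
      expect_lt(dev[2], 0.5)
    })
  }
})

test_that("series registration returns identities for identical clouds", {
  cl <- sbi_cloud(withr::with_seed(2, make_disc_cloud(60)), day = 1)
  trs <- register_series(list(cl, cl, cl))
  for (tr in trs) {
    expect_lt(abs(tr$theta_deg), 1e-6)
    expect_lt(sqrt(tr$tx^2 + tr$ty^2), 1e-6)
  }
  expect_error(register_series(list(cl)), "at least 2")
})

test_that("volume resampling honors the transform contracts", {
  v <- withr::with_seed(3, array(sample.int(100, 5 * 40 * 40, TRUE), c(5, 40, 40)))
  vol <- volume3d(v, 0.3, 1)

  # identity, nearest: voxel-identical
  ident <- apply_transform(vol, rigid2d(0, 0, 0), "nearest")
  expect_identical(ident$intensities, vol$intensities)

  # +3 then -3 in x, nearest: identical away from the border
  fwd <- apply_transform(vol, rigid2d(0, 3, 0), "nearest")
  back <- apply_transform(fwd, rigid2d(0, -3, 0), "nearest")
  core <- 4:37
  expect_identical(back$intensities[, core, core], vol$intensities[, core, core])

  # 90 degree rotation about the center maps an x-aligned bar onto y
  bar <- array(0L, c(1, 21, 21))
  bar[1, 11, 3:19] <- 1L
  rot <- apply_transform(volume3d(bar, 1, 1), rigid2d(90, 0, 0, center = c(10, 10)),
                         "nearest")
  expect_equal(rot$intensities[1, 3:19, 11], rep(1L, 17))
  expect_equal(sum(rot$intensities), sum(bar))

  expect_error(apply_transform(vol, rigid2d(0, 0, 0), "cubic"))
})

test_that("alignment error matches the brute-force oracle", {
  A <- withr::with_seed(10, make_disc_cloud(40))
  expect_lt(alignment_error(A, A), 1e-6)
  B <- A; B[, 1] <- B[, 1] + 1
  expect_equal(alignment_error(A, B), 1)
  C <- withr::with_seed(11, make_disc_cloud(25))
  expect_equal(alignment_error(A, C), oracle_alignment_error(A, C), tolerance = 1e-12)
  expect_error(alignment_error(A, A[0, , drop = FALSE]), "empty")
})
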