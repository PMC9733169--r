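test_that("step fitting matches its exhaustive definition", {
  expect_equal(fit_step(c(0, 0, 0, 1, 1, 1)), list(xthr = 3L, mse = 0))
  expect_equal(fit_step(rep(1, 5)), list(xthr = 0L, mse = 0))
  expect_equal(fit_step(rep(0, 5))$xthr, 5L)

  y <- c(0.1, 0.05, 0.2, 0.9, 0.8, 1.0)
  expect_equal(fit_step(y)[c("xthr", "mse")],
               oracle_fit_step(y)[c("xthr", "mse")],
               tolerance = 1e-12)

  # ties go to the smallest xthr: a constant 0.5 profile ties everywhere
  expect_equal(fit_step(rep(0.5, 4))$xthr, 0L)

  # random profiles against the independent oracle
  withr::with_seed(77, {
    for (i in 1:200) {
      y <- runif(sample(1:40, 1))
      got <- fit_step(y)
      want <- oracle_fit_step(y)
      expect_equal(got$xthr, want$xthr)
      expect_equal(got$mse, want$mse, tolerance = 1e-12)
    }
  })
  expect_error(fit_step(numeric()), "empty")
})

test_that("node index converts to relative length by arc length", {
  u <- make_straight_root(n = 11, spacing = 3)
  expect_equal(node_index_to_rl(u, 0), 0)
  expect_equal(node_index_to_rl(u, 5), 0.5)
  expect_equal(node_index_to_rl(u, 11), 1)
  expect_error(node_index_to_rl(u, 12), "out of range")

  # uneven spacing: cumulative tip-side arcs 0, 1, 3, 6
  r <- list(id = "r", nodes = rbind(c(0, 0, 0), c(0, 0, 3), c(0, 0, 5), c(0, 0, 6)))
  expect_equal(node_index_to_rl(r, 2), 0.5)
  expect_equal(node_index_to_rl(r, 1), 1 / 6)
})

test_that("trajectories track phantom truth with the baseline scorer", {
  cfg <- small_phantom_config(seed = 19, days = seq(8, 20, by = 2),
                              dim = c(96, 112, 112), n_roots = 2,
                              n_particles = 30,
                              final_length_mm_range = c(14, 16),
                              x1_range = c(9, 11), x2_range = c(15, 18),
                              rotation_range_deg = c(0, 0),
                              translation_range_vox = c(0, 0))
  sim <- generate_phantom_series(cfg)
  segmented <- lapply(sim$volumes, segment_roots)
  traj <- build_trajectories(NULL, segmented, sim$vector)
  expect_equal(sort(unique(traj$day)), cfg$days)
  expect_true(all(traj$rl[traj$day == 20] == 0))
  for (i in seq_len(nrow(traj))) {
    r <- sim$vector$roots[[traj$root_id[i]]]
    spacing_rl <- 2 / root_length_mm(r, 1)   # ~2-voxel node spacing, in RL units
    expect_lt(abs(traj$rl[i] - true_rl(sim$truth, traj$root_id[i], traj$day[i])),
              1.5 * spacing_rl + 1e-9)
  }
})

test_that("single-day series yields the trivial trajectory and missing days error", {
  seg <- volume3d(array(0L, c(20, 30, 30)), 0.3, 27)
  vec <- rsa_vector(list(make_straight_root("a", n = 5, z0 = 10, y0 = 15, x0 = 5)),
                    0.3, 27)
  traj <- build_trajectories(NULL, list(seg), vec)
  expect_equal(traj, data.frame(root_id = "a", day = 27, rl = 0))
  expect_error(build_trajectories(NULL, list(seg), vec, expected_days = c(20, 27)),
               "day\\(s\\): 20")
})

test_that("noiseless model trajectories are recovered exactly on the grid", {
  days <- 7:27
  grid <- growth_grid(days)
  # plain two-bend line
  y <- growth_model_curve(10, 20, 1, days)
  f <- fit_trajectory(data.frame(day = days, rl = y), grid)
  expect_equal(f[c("x1", "x2", "ythr")], list(x1 = 10, x2 = 20, ythr = 1))
  expect_equal(f$mse, 0, tolerance = 1e-12)
  expect_equal(f$classification, "basic")

  # overlap plateau
  y2 <- growth_model_curve(12, 24, 0.6, days)
  f2 <- fit_trajectory(data.frame(day = days, rl = y2), grid)
  expect_lte(abs(f2$x1 - 12), grid$x_step)
  expect_lte(abs(f2$x2 - 24), grid$x_step)
  expect_equal(f2$ythr, 0.6)
  expect_equal(f2$classification, "overlapped")

  # flat zero trajectory: the pre-existing root case
  f3 <- fit_trajectory(data.frame(day = days, rl = rep(0, length(days))), grid)
  expect_equal(f3$classification, "pre_existing")
  expect_true(is.na(f3$x1) && is.na(f3$x2))

  # elongation under way before the first scan
  y4 <- growth_model_curve(4, 15, 1, days)
  f4 <- fit_trajectory(data.frame(day = days, rl = y4), grid)
  expect_equal(f4$x1, 4)
  expect_equal(f4$classification, "incomplete")

  expect_error(fit_trajectory(data.frame(day = 7, rl = 1), grid), "2 distinct days")
})

test_that("fitted curves are monotone and parameter recovery survives noise", {
  days <- 7:27
  grid <- growth_grid(days)
  ok <- 0
  n_rep <- 60
  withr::with_seed(123, {
    for (i in seq_len(n_rep)) {
      x1 <- runif(1, 8, 16); x2 <- x1 + runif(1, 3, 9)
      y <- growth_model_curve(x1, x2, 1, days) + rnorm(length(days), 0, 0.05)
      f <- fit_trajectory(data.frame(day = days, rl = pmin(pmax(y, 0), 1)), grid)
      curve <- growth_model_curve(f$x1, f$x2, f$ythr, days)
      expect_true(all(diff(curve) <= 1e-12))
      expect_true(all(curve >= 0 & curve <= f$ythr + 1e-12))
      if (abs(f$x1 - x1) <= 1 && abs(f$x2 - x2) <= 1) ok <- ok + 1
    }
  })
  expect_gte(ok / n_rep, 0.95)
})
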