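test_that("block extraction zero-pads at borders", {
  v <- array(1L, c(20, 20, 20))
  blk <- extract_block(v, c(0, 0, 0), 17)
  expect_equal(dim(blk), c(17, 17, 17))
  # the corner block keeps the 9^3 in-bounds octant, zero elsewhere
  expect_equal(sum(blk), 9^3)
  expect_equal(blk[9:17, 9:17, 9:17], array(1, c(9, 9, 9)))
  expect_equal(blk[1:8, , ], array(0, c(8, 17, 17)))

  mid <- extract_block(v, c(10, 10, 10), 17)
  expect_equal(sum(mid), 17^3)
})

test_that("training-block sampling honors counts, separation and determinism", {
  seg <- volume3d(array(0L, c(40, 60, 60)), 0.3, 27)
  vec <- rsa_vector(list(make_straight_root("a", n = 15, z0 = 20, y0 = 20, x0 = 10),
                         make_straight_root("b", n = 10, z0 = 20, y0 = 40, x0 = 10)),
                    0.3, 27)
  s <- sample_training_blocks(seg, vec, seed = 42)
  expect_equal(length(s$blocks), 50)          # 25 positives + 25 negatives
  expect_equal(sum(s$label), 25)
  expect_equal(s$root_id[1:15], rep("a", 15))

  pos <- s$center[s$label == 1, ]
  neg <- s$center[s$label == 0, ]
  cheb <- apply(neg, 1, function(p) min(apply(abs(sweep(pos, 2, p)), 1, max)))
  expect_true(all(cheb >= 5))

  s2 <- sample_training_blocks(seg, vec, seed = 42)
  expect_identical(s$center, s2$center)
})

test_that("a vector with 2835 nodes yields 5670 balanced samples", {
  seg <- volume3d(array(0L, c(24, 128, 128)), 0.3, 27)
  roots <- lapply(1:27, function(i)
    make_straight_root(sprintf("r%02d", i), n = 105, z0 = 4 + (i - 1) %/% 9 * 8,
                       y0 = 8 + (i - 1) %% 9 * 13, x0 = 12))
  vec <- rsa_vector(roots, 0.3, 27)
  s <- sample_training_blocks(seg, vec, seed = 1, block_size = 7)
  expect_equal(length(s$blocks), 5670)
  expect_equal(sum(s$label == 1), 2835)
})

test_that("analytic gradients match finite differences", {
  m <- new_discriminator(channels = 3, seed = 3)
  X <- withr::with_seed(7, matrix(runif(nrow(m$idx) * ncol(m$idx)), nrow(m$idx)))
  y <- 1
  fw <- rsa4d:::disc_forward(m, X)
  gr <- rsa4d:::disc_backward(m, X, fw, y)
  eps <- 1e-6
  for (nm in c("W", "gamma", "beta", "w2", "b2")) {
    i <- if (length(m[[nm]]) > 1) withr::with_seed(9, sample(length(m[[nm]]), 1)) else 1
    mp <- m; mp[[nm]][i] <- mp[[nm]][i] + eps
    mm <- m; mm[[nm]][i] <- mm[[nm]][i] - eps
    num <- ((rsa4d:::disc_forward(mp, X)$score - y)^2 -
              (rsa4d:::disc_forward(mm, X)$score - y)^2) / (2 * eps)
    expect_equal(gr[[nm]][i], num, tolerance = 1e-5)
  }
})

test_that("training separates trivially separable blocks and stops early", {
  n <- 120
  blocks <- c(lapply(seq_len(n), function(i) make_toy_block(TRUE, i)),
              lapply(seq_len(n), function(i) make_toy_block(FALSE, 10000 + i)))
  samples <- list(blocks = blocks, label = rep(c(1, 0), each = n))
  model <- new_discriminator(seed = 2)

  expect_identical(train_discriminator(model, samples, max_epochs = 0), model)

  trained <- train_discriminator(model, samples, learning_rate = 1e-4,
                                 max_epochs = 100, seed = 5)
  h <- trained$history$loss
  expect_lt(length(h), 100)                       # stopping rule fired
  expect_lt(tail(h, 1), head(h, 1))               # loss decreased
  # the rule requires 5 consecutive sub-threshold epochs
  expect_true(all(tail(h, 5) < 0.05))

  sc <- vapply(blocks, function(b) score_block(trained, b), numeric(1))
  expect_true(all(sc > 0 & sc < 1))
  expect_gte(mean(sc[1:n]) - mean(sc[(n + 1):(2 * n)]), 0.5)

  # reproducible end-to-end
  trained2 <- train_discriminator(model, samples, learning_rate = 1e-4,
                                  max_epochs = 100, seed = 5)
  expect_identical(trained$W, trained2$W)
  expect_identical(trained$history, trained2$history)
})

test_that("fine-tuning bookkeeping and no-op behavior", {
  m <- new_discriminator(seed = 1)
  samples <- list(blocks = lapply(1:4, function(i) make_toy_block(TRUE, i)),
                  label = c(1, 1, 0, 0))
  same <- fine_tune(m, "rX", samples, max_epochs = 0)
  expect_identical(same$W, m$W)
  expect_equal(same$provenance, list(kind = "fine_tuned", root_id = "rX"))

  ft1 <- fine_tune(m, "r1", samples, max_epochs = 2, seed = 1)
  ft2 <- fine_tune(m, "r2", samples, max_epochs = 2, seed = 2)
  expect_equal(ft1$provenance$root_id, "r1")
  expect_equal(ft2$provenance$root_id, "r2")
  expect_false(identical(ft1$W, ft2$W))
})

test_that("score profiles are tip-indexed with one score per node", {
  seg <- volume3d(array(0L, c(30, 40, 40)), 0.3, 20)
  root <- make_straight_root("a", n = 12, z0 = 15, y0 = 20, x0 = 5)
  m <- new_discriminator(seed = 1)
  prof <- score_nodes(m, seg, root)
  expect_equal(nrow(prof), 12)
  expect_equal(prof$node_index_from_tip, 0:11)
  # empty volume: every block identical -> constant scores
  expect_equal(length(unique(round(prof$score, 12))), 1)
  expect_true(all(prof$score > 0 & prof$score < 1))
})

test_that("the occupancy baseline equals brute-force voxel counting", {
  d <- c(40, 40, 40)
  v <- array(0L, d)
  # solid tube of radius 8 along x at (20, 20)
  co <- as.matrix(expand.grid(z = 0:39, y = 0:39, x = 0:39))
  v[(co[, 1] - 20)^2 + (co[, 2] - 20)^2 <= 64] <- 1L
  seg <- volume3d(v, 0.3, 20)
  root <- make_straight_root("a", n = 8, spacing = 2, z0 = 20, y0 = 20, x0 = 10)
  prof <- baseline_score_nodes(seg, root, block_size = 7)
  expect_equal(prof$score, rep(1, 8))

  empty <- volume3d(array(0L, d), 0.3, 20)
  expect_equal(baseline_score_nodes(empty, root)$score, rep(0, 8))

  # partially occupied block: score equals the exact voxel fraction when the
  # normalizer is 1 (tip-index 0 is the storage-order last node)
  v2 <- array(0L, d); v2[, , 1:20] <- 1L
  seg2 <- volume3d(v2, 0.3, 20)
  root2 <- list(id = "b", nodes = rbind(c(20, 20, 25), c(20, 20, 19.5)))
  prof2 <- baseline_score_nodes(seg2, root2, block_size = 7, occupancy_norm = 1)
  blk_tip <- extract_block(seg2, c(20, 20, 19.5), 7)
  blk_base <- extract_block(seg2, c(20, 20, 25), 7)
  expect_equal(prof2$score[1], sum(blk_tip != 0) / 7^3)
  expect_equal(prof2$score[2], sum(blk_base != 0) / 7^3)
  expect_equal(prof2$score[1], 3 / 7)
})
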