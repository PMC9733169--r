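# shared fixtures, all generated in code

# a small, fast phantom: ~30 s of the full study conditions squeezed into a
# 96^3 grid with short roots and few particles
small_phantom_config <- function(seed = 1, ...) {
  args <- list(dim = c(96, 112, 112), days = 7:18, n_roots = 3,
               final_length_mm_range = c(12, 18), x1_range = c(8, 13),
               x2_range = c(12, 17), n_particles = 50,
               basal_radius_range = c(3, 8), seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_config, args)
}

# synthetic disc-shaped 2D cloud, mimicking particle centroids
make_disc_cloud <- function(n, radius = 60, center = c(80, 80)) {
  rr <- radius * sqrt(runif(n))
  ang <- runif(n, 0, 2 * pi)
  cbind(center[1] + rr * cos(ang), center[2] + rr * sin(ang))
}

# straight-line root along +x at (z0, y0), n nodes, spacing vox
make_straight_root <- function(id = "r1", n = 11, spacing = 1,
                               z0 = 10, y0 = 10, x0 = 0) {
  nodes <- cbind(z0, y0, x0 + spacing * (seq_len(n) - 1))
  list(id = id, nodes = unname(nodes))
}

# toy training blocks: bright tube through the center vs sparse noise
make_toy_block <- function(positive, seed, value = 1, size = 17) {
  withr::with_seed(seed, {
    B <- array(0, c(size, size, size))
    mid <- (size + 1) / 2
    if (positive) {
      d <- rnorm(3); d <- d / sqrt(sum(d^2))
      co <- as.matrix(expand.grid(z = 1:size, y = 1:size, x = 1:size)) - mid
      pr <- co %*% d
      B[rowSums(co^2) - pr^2 <= 2.5^2] <- value
    } else {
      B[sample(size^3, rpois(1, 8))] <- 1
    }
    B
  })
}

# independent exhaustive step-fit oracle (plain double loop)
oracle_fit_step <- function(y) {
  n <- length(y)
  best <- NULL
  for (xthr in 0:n) {
    pred <- c(rep(0, xthr), rep(1, n - xthr))
    mse <- mean((y - pred)^2)
    if (is.null(best) || mse < best$mse - 1e-15) best <- list(xthr = xthr, mse = mse)
  }
  best
}

# brute-force symmetric mean NN distance
oracle_alignment_error <- function(A, B) {
  da <- sapply(seq_len(nrow(A)), function(i) min(sqrt(colSums((t(B) - A[i, ])^2))))
  db <- sapply(seq_len(nrow(B)), function(i) min(sqrt(colSums((t(A) - B[i, ])^2))))
  (mean(da) + mean(db)) / 2
}

# expected transform mapping day i into the reference day's frame
expected_series_transform <- function(truth, i, ref = length(truth$days)) {
  compose_transforms(truth$transforms[[ref]], invert_transform(truth$transforms[[i]]))
}

# deviation of recovered vs expected transform, measured at the grid center
recovery_deviation <- function(recovered, expected, dim_yx = c(160, 160)) {
  cen <- c((dim_yx[2] - 1) / 2, (dim_yx[1] - 1) / 2)
  comp <- compose_transforms(recovered, invert_transform(expected))
  transform_deviation(comp, at = cen)
}
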