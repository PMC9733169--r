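#' Extract a cubic block centered on a voxel, zero-padded at borders
#'
#' @param volume a [volume3d()] or bare 3D array.
#' @param center length-3 `(z, y, x)` 0-based voxel coordinate (rounded to
#'   the nearest voxel).
#' @param size block edge length (odd).
#' @return a `size^3` array.
#' @export
extract_block <- function(volume, center, size = 17) {
  v <- if (inherits(volume, "volume3d")) volume$intensities else volume
  d <- dim(v)
  h <- (size - 1) %/% 2
  c0 <- round(center)
  out <- array(0, c(size, size, size))
  lo <- pmax(c0 - h, 0); hi <- pmin(c0 + h, d - 1)
  if (any(lo > hi)) return(out)
  dlo <- lo - (c0 - h) + 1; dhi <- dlo + (hi - lo)
  out[dlo[1]:dhi[1], dlo[2]:dhi[2], dlo[3]:dhi[3]] <-
    v[(lo[1] + 1):(hi[1] + 1), (lo[2] + 1):(hi[2] + 1), (lo[3] + 1):(hi[3] + 1)]
  out
}

#' Sample positive and negative training blocks
#'
#' Positives are one block per vector node (every node of every root);
#' negatives are uniformly random in-bounds voxel coordinates at least
#' `min_separation` (Chebyshev) away from every positive node, matched in
#' number to the positives by default.
#'
#' @param seg_volume the root-segmented [volume3d()] at the last day.
#' @param vector the [rsa_vector()] traced on that volume.
#' @param n_negatives number of negatives; defaults to the positive count.
#' @param min_separation minimum Chebyshev distance (voxels) between a
#'   negative coordinate and any positive node.
#' @param seed RNG seed for the negative draws.
#' @param block_size block edge length.
#' @return a list with `blocks` (list of arrays), `label` (1/0),
#'   `root_id` (`NA` for negatives) and `center` (`n x 3` matrix).
#' @export
sample_training_blocks <- function(seg_volume, vector, n_negatives = NULL,
                                   min_separation = 5, seed = NULL,
                                   block_size = 17) {
  stopifnot(inherits(seg_volume, "volume3d"), inherits(vector, "rsa_vector"))
  d <- dim(seg_volume$intensities)
  pos <- do.call(rbind, lapply(vector$roots, function(r) round(r$nodes)))
  rownames(pos) <- NULL
  pos_id <- rep(unname(vapply(vector$roots, `[[`, character(1), "id")),
                unname(vapply(vector$roots, function(r) nrow(r$nodes), integer(1))))
  if (any(pos < 0) || any(sweep(pos, 2, d - 1) > 0))
    stopf("vector nodes outside volume bounds")
  n_pos <- nrow(pos)
  if (is.null(n_negatives)) n_negatives <- n_pos
  neg <- with_seed(seed, {
    acc <- matrix(NA_real_, 0, 3)
    attempts <- 0
    while (nrow(acc) < n_negatives) {
      attempts <- attempts + 1
      if (attempts > 200) stopf("volume too small to place %d negatives %d voxels away from all positives",
                                n_negatives, min_separation)
      m <- max(n_negatives * 2, 64)
      cand <- cbind(floor(runif(m, 0, d[1])), floor(runif(m, 0, d[2])),
                    floor(runif(m, 0, d[3])))
      # Chebyshev distance to nearest positive node
      ok <- vapply(seq_len(m), function(i) {
        min(pmax(abs(pos[, 1] - cand[i, 1]),
                 pmax(abs(pos[, 2] - cand[i, 2]), abs(pos[, 3] - cand[i, 3])))) >= min_separation
      }, logical(1))
      acc <- rbind(acc, cand[ok, , drop = FALSE])
    }
    acc[seq_len(n_negatives), , drop = FALSE]
  })
  centers <- rbind(pos, neg)
  blocks <- lapply(seq_len(nrow(centers)), function(i)
    extract_block(seg_volume, centers[i, ], block_size))
  list(blocks = blocks,
       label = c(rep(1, n_pos), rep(0, n_negatives)),
       root_id = c(pos_id, rep(NA_character_, n_negatives)),
       center = centers)
}

im2col_indices <- function(size, kernel, stride) {
  starts <- seq(1, size - kernel + 1, by = stride)
  pos <- as.matrix(expand.grid(z = starts, y = starts, x = starts))
  off <- as.matrix(expand.grid(dz = 0:(kernel - 1), dy = 0:(kernel - 1),
                               dx = 0:(kernel - 1)))
  idx <- matrix(0L, nrow(pos), nrow(off))
  for (i in seq_len(nrow(pos))) {
    zz <- pos[i, 1] + off[, 1]; yy <- pos[i, 2] + off[, 2]; xx <- pos[i, 3] + off[, 3]
    idx[i, ] <- (xx - 1L) * size * size + (yy - 1L) * size + zz
  }
  idx
}

#' Create an untrained block discriminator
#'
#' A small 3D convolutional scorer: one 3D convolution (`channels` filters,
#' `kernel^3`, stride `stride`) over the block, per-channel normalization by
#' running activation statistics with learned scale/shift, ReLU, global mean
#' pooling, a dense layer to a scalar, and a sigmoid. Scores are therefore
#' always in (0, 1): 1 means the block looks like a root segment under a
#' vector node, 0 means it does not. The running normalization statistics
#' are accumulated during training (momentum `bn_momentum`) and treated as
#' constants in the gradient, so that scoring is deterministic and
#' magnitude contrasts between occupied and empty blocks are preserved.
#'
#' @param channels number of convolution filters.
#' @param kernel,stride convolution kernel size and stride.
#' @param block_size input block edge length.
#' @param bn_momentum momentum of the running normalization statistics.
#' @param seed seed for weight initialization.
#' @return an object of class `root_discriminator`.
#' @export
new_discriminator <- function(channels = 8, kernel = 5, stride = 4,
                              block_size = 17, bn_momentum = 0.01, seed = 0) {
  k3 <- kernel^3
  with_seed(seed, {
    structure(list(
      W = matrix(rnorm(k3 * channels, 0, sqrt(2 / k3)), k3, channels),
      b = numeric(channels),
      gamma = rep(1, channels), beta = numeric(channels),
      w2 = rnorm(channels, 0, sqrt(1 / channels)), b2 = 0,
      rmu = numeric(channels), rvar = rep(1, channels),
      block_size = block_size, kernel = kernel, stride = stride,
      channels = channels, bn_momentum = bn_momentum,
      idx = im2col_indices(block_size, kernel, stride),
      history = data.frame(epoch = integer(), loss = numeric()),
      provenance = list(kind = "base", root_id = NA_character_)),
      class = "root_discriminator")
  })
}

#' @export
print.root_discriminator <- function(x, ...) {
  cat(sprintf("root_discriminator (%s%s): %d filters %dx%dx%d stride %d, %d epochs trained\n",
              x$provenance$kind,
              if (!is.na(x$provenance$root_id)) paste0(", root ", x$provenance$root_id) else "",
              x$channels, x$kernel, x$kernel, x$kernel, x$stride, nrow(x$history)))
  invisible(x)
}

disc_forward <- function(m, X, update_stats = FALSE) {
  H <- X %*% m$W + matrix(m$b, nrow(X), m$channels, byrow = TRUE)
  if (update_stats) {
    mom <- m$bn_momentum
    mu <- colMeans(H); v <- colMeans(H^2) - mu^2
    m$rmu <- (1 - mom) * m$rmu + mom * mu
    m$rvar <- (1 - mom) * m$rvar + mom * v
  }
  sdv <- sqrt(m$rvar + 1e-5)
  Hn <- sweep(sweep(H, 2, m$rmu), 2, sdv, "/")
  G <- sweep(sweep(Hn, 2, m$gamma, "*"), 2, m$beta, "+")
  A <- pmax(G, 0)
  p <- colMeans(A)
  z <- sum(m$w2 * p) + m$b2
  list(model = m, Hn = Hn, G = G, p = p, sdv = sdv,
       score = 1 / (1 + exp(-z)))
}

disc_backward <- function(m, X, fw, y) {
  npos <- nrow(X)
  dz <- 2 * (fw$score - y) * fw$score * (1 - fw$score)
  dA <- matrix(dz * m$w2 / npos, npos, m$channels, byrow = TRUE)
  dG <- dA * (fw$G > 0)
  dHn <- sweep(dG, 2, m$gamma, "*")
  dH <- sweep(dHn, 2, fw$sdv, "/")
  list(W = crossprod(X, dH), b = colSums(dH),
       gamma = colSums(dG * fw$Hn), beta = colSums(dG),
       w2 = dz * fw$p, b2 = dz)
}

disc_param_names <- c("W", "b", "gamma", "beta", "w2", "b2")

#' Train a block discriminator
#'
#' Minimizes the mean squared error between sigmoid scores and the 0/1
#' labels with the Adam optimizer, one update per sample. Training stops at
#' `max_epochs` or as soon as the epoch-mean loss has been below `stop_loss`
#' for `stop_patience` consecutive epochs.
#'
#' @param model a [new_discriminator()] (or previously trained model).
#' @param samples output of [sample_training_blocks()].
#' @param learning_rate Adam learning rate.
#' @param max_epochs epoch cap; 0 returns the model unchanged.
#' @param stop_loss,stop_patience early-stopping rule (see above).
#' @param seed seed for the per-epoch sample shuffles.
#' @return the trained `root_discriminator`, with `$history` holding the
#'   per-epoch mean loss.
#' @export
train_discriminator <- function(model, samples, learning_rate = 1e-5,
                                max_epochs = 100, stop_loss = 0.05,
                                stop_patience = 5, seed = 0) {
  stopifnot(inherits(model, "root_discriminator"))
  n <- length(samples$blocks)
  if (max_epochs > 0 && n == 0L) stopf("no training samples")
  if (max_epochs == 0) return(model)
  Xs <- lapply(samples$blocks, function(b) matrix(b[model$idx], nrow(model$idx)))
  ys <- samples$label
  adam <- lapply(disc_param_names, function(nm)
    list(m = model[[nm]] * 0, v = model[[nm]] * 0))
  names(adam) <- disc_param_names
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t0 <- 0; streak <- 0
  hist <- data.frame(epoch = integer(), loss = numeric())
  with_seed(seed, {
    for (ep in seq_len(max_epochs)) {
      ord <- sample.int(n)
      tot <- 0
      for (i in ord) {
        fw <- disc_forward(model, Xs[[i]], update_stats = TRUE)
        model <- fw$model
        tot <- tot + (fw$score - ys[i])^2
        gr <- disc_backward(model, Xs[[i]], fw, ys[i])
        t0 <- t0 + 1
        for (nm in disc_param_names) {
          adam[[nm]]$m <- b1 * adam[[nm]]$m + (1 - b1) * gr[[nm]]
          adam[[nm]]$v <- b2 * adam[[nm]]$v + (1 - b2) * gr[[nm]]^2
          mh <- adam[[nm]]$m / (1 - b1^t0)
          vh <- adam[[nm]]$v / (1 - b2^t0)
          model[[nm]] <- model[[nm]] - learning_rate * mh / (sqrt(vh) + eps)
        }
      }
      loss <- tot / n
      if (!is.finite(loss)) stopf("training diverged: non-finite loss at epoch %d", ep)
      hist <- rbind(hist, data.frame(epoch = ep, loss = loss))
      streak <- if (loss < stop_loss) streak + 1 else 0
      if (streak >= stop_patience) break
    }
  })
  model$history <- rbind(model$history, hist)
  model
}

#' Fine-tune a trained discriminator for one root
#'
#' Starts from the base model's weights and continues training on samples
#' restricted to one root's positive nodes (plus freshly drawn negatives),
#' with a reduced epoch cap. This recovers scoring sensitivity on faint
#' root segments that the base model, trained on all roots, underrates.
#'
#' @param base_model a trained `root_discriminator`.
#' @param root_id identifier of the root the sub-model is for.
#' @param samples_for_root training samples restricted to that root
#'   (e.g. from [sample_training_blocks()] on a one-root vector).
#' @param max_epochs fine-tuning epoch cap.
#' @param ... further arguments passed to [train_discriminator()].
#' @return a per-root `root_discriminator`.
#' @export
fine_tune <- function(base_model, root_id, samples_for_root,
                      max_epochs = 20, ...) {
  n_pos <- sum(samples_for_root$label == 1)
  if (max_epochs > 0 && n_pos < 2) stopf("root %s has fewer than 2 positive nodes", root_id)
  out <- train_discriminator(base_model, samples_for_root,
                             max_epochs = max_epochs, ...)
  out$provenance <- list(kind = "fine_tuned", root_id = as.character(root_id))
  out
}

#' Score a discriminator on a block
#'
#' @param model a `root_discriminator`.
#' @param block a `block_size^3` array.
#' @return score in (0, 1).
#' @export
score_block <- function(model, block) {
  disc_forward(model, matrix(block[model$idx], nrow(model$idx)))$score
}

make_score_profile <- function(root, day, scores) {
  structure(data.frame(root_id = root$id, day = day,
                       node_index_from_tip = seq_along(scores) - 1L,
                       score = scores),
            class = c("score_profile", "data.frame"))
}

#' Score every node of a root against a segmented volume
#'
#' Nodes are scored in tip-origin order: row `x` of the profile is the node
#' `x` nodes away from the tip (tip itself is index 0). Nodes whose block
#' extends past the volume border are scored on the zero-padded block (a
#' warning is issued when the node center itself is out of bounds).
#'
#' @param model a `root_discriminator`.
#' @param seg_volume a root-segmented [volume3d()] in the reference frame.
#' @param root one element of `rsa_vector$roots`.
#' @return a `score_profile` data frame with columns `root_id`, `day`,
#'   `node_index_from_tip`, `score`.
#' @export
score_nodes <- function(model, seg_volume, root) {
  stopifnot(inherits(model, "root_discriminator"))
  n <- nrow(root$nodes)
  d <- dim(seg_volume$intensities)
  scores <- numeric(n)
  for (x in 0:(n - 1)) {
    c0 <- root$nodes[n - x, ]
    if (any(round(c0) < 0) || any(round(c0) > d - 1))
      warnf("root %s: node %d center outside volume; scored on padded block", root$id, x)
    scores[x + 1] <- score_block(model, extract_block(seg_volume, c0, model$block_size))
  }
  make_score_profile(root, seg_volume$day, scores)
}

#' Deterministic occupancy scorer
#'
#' A reproducible baseline standing in for the learned discriminator: the
#' score of a node is the fraction of nonzero voxels in the block centered
#' on it, divided by `occupancy_norm` and clipped to `[0, 1]`. With
#' `occupancy_norm = 1` the score is exactly the occupied-voxel fraction.
#' The default block is deliberately smaller than the discriminator's
#' (7 instead of 17): the occupancy count has no notion of where voxels sit
#' inside the block, so a tight block is what keeps the score local to the
#' node rather than lighting up on a neighboring root crossing the
#' periphery.
#'
#' @param seg_volume a binary root-segmented [volume3d()].
#' @param root one element of `rsa_vector$roots`.
#' @param block_size block edge length.
#' @param occupancy_norm occupancy giving score 1. The default is calibrated
#'   so that a tube of radius ~2.5 voxels running through the whole default
#'   block saturates the score, which places the score-0.5 crossing at the
#'   tube's end cap -- the step-fit borderline then sits at the growth front
#'   rather than a few voxels beyond it.
#' @return a `score_profile` data frame (tip-origin node order).
#' @export
baseline_score_nodes <- function(seg_volume, root, block_size = 7,
                                 occupancy_norm = 0.35) {
  n <- nrow(root$nodes)
  scores <- numeric(n)
  nb <- block_size^3
  for (x in 0:(n - 1)) {
    blk <- extract_block(seg_volume, root$nodes[n - x, ], block_size)
    scores[x + 1] <- min(max(sum(blk != 0) / nb / occupancy_norm, 0), 1)
  }
  make_score_profile(root, seg_volume$day, scores)
}
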