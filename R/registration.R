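#' Soil-block-identifier point cloud
#'
#' Planar point cloud of high-intensity soil-particle centroids for one
#' volume. Vertical positions are dropped because only horizontal alignment
#' is needed: the pot is repositioned on the scanner turntable between days,
#' which rotates it about the vertical axis and shifts it horizontally.
#'
#' @param points `n x 2` matrix of `(x, y)` centroids, voxel units, 0-based.
#' @param day source day label.
#' @return an object of class `sbi_cloud`.
#' @export
sbi_cloud <- function(points, day = NA_integer_) {
  points <- rbind(points)
  stopifnot(is.numeric(points), ncol(points) == 2L, all(is.finite(points)))
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(list(points = points, day = as.integer(day)), class = "sbi_cloud")
}

#' @export
print.sbi_cloud <- function(x, ...) {
  cat(sprintf("sbi_cloud: %d points, day %s\n", nrow(x$points), x$day))
  invisible(x)
}

#' Extract the soil-block-identifier cloud from a volume
#'
#' Thresholds the volume at an intensity percentile (or an absolute value),
#' labels connected components (26-connectivity), keeps components whose
#' voxel count lies in `[min_size, max_size]` (excluding single-voxel noise
#' and large artifacts such as pot walls), and returns their centroids
#' projected to the horizontal plane.
#'
#' @param volume a [volume3d()].
#' @param threshold_percentile percentile (0-100) defining "high intensity";
#'   ignored when `threshold_abs` is given.
#' @param threshold_abs optional absolute intensity threshold.
#' @param min_size,max_size component voxel-count gates.
#' @param min_points minimum number of surviving centroids; fewer is an error.
#' @return an [sbi_cloud()].
#' @export
extract_sbi <- function(volume, threshold_percentile = 99.95,
                        threshold_abs = NULL,
                        min_size = 2, max_size = 1000, min_points = 10) {
  stopifnot(inherits(volume, "volume3d"))
  v <- volume$intensities
  thr <- if (!is.null(threshold_abs)) threshold_abs
         else quantile(v, threshold_percentile / 100, names = FALSE)
  lab <- label_components_3d(v > thr)
  if (nrow(lab$coords) == 0L)
    stopf("no voxels above threshold %.4g (percentile %.4g)", thr, threshold_percentile)
  sizes <- tabulate(lab$label)
  keep_comp <- which(sizes >= min_size & sizes <= max_size)
  if (length(keep_comp) < min_points)
    stopf("only %d particle components above threshold %.4g (percentile %.4g); need >= %d",
          length(keep_comp), thr, threshold_percentile, min_points)
  sel <- lab$label %in% keep_comp
  # 0-based centroids; arr.ind columns are (z, y, x)
  cz <- tapply(lab$coords[sel, 2] - 1, lab$label[sel], mean)  # y
  cx <- tapply(lab$coords[sel, 3] - 1, lab$label[sel], mean)  # x
  sbi_cloud(cbind(x = as.numeric(cx), y = as.numeric(cz)), volume$day)
}

# brute-force nearest neighbours: for each row of a, index and distance of
# nearest row of b
nn_bruteforce <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  j <- max.col(-d2, ties.method = "first")
  list(index = j, dist = sqrt(pmax(d2[cbind(seq_len(nrow(a)), j)], 0)))
}

# core point-to-point ICP loop starting from the transform (R, t)
icp_core <- function(M, B, R, t, max_dist, max_iterations, tolerance) {
  prev_rms <- Inf; converged <- FALSE; rms <- NA_real_; ncorr <- 0L
  for (it in seq_len(max_iterations)) {
    cur <- M %*% t(R) + matrix(t, nrow(M), 2, byrow = TRUE)
    nn <- nn_bruteforce(cur, B)
    keep <- nn$dist <= max_dist
    ncorr <- sum(keep)
    if (ncorr < 3L) break
    A <- M[keep, , drop = FALSE]
    Bc <- B[nn$index[keep], , drop = FALSE]
    ca <- colMeans(A); cb <- colMeans(Bc)
    H <- crossprod(sweep(A, 2, ca), sweep(Bc, 2, cb))
    sv <- svd(H)
    Rn <- sv$v %*% t(sv$u)
    if (det(Rn) < 0) { sv$v[, 2] <- -sv$v[, 2]; Rn <- sv$v %*% t(sv$u) }
    R <- Rn
    t <- cb - as.vector(Rn %*% ca)
    rms <- sqrt(mean(nn$dist[keep]^2))
    if (is.finite(prev_rms) && abs(prev_rms - rms) <= tolerance * max(rms, 1e-12)) {
      converged <- TRUE
      break
    }
    prev_rms <- rms
  }
  list(R = R, t = t, rms = rms, ncorr = ncorr, converged = converged)
}

#' Register one SBI cloud onto another (planar ICP)
#'
#' Point-to-point iterative closest point: alternate nearest-neighbor
#' correspondence (capped at `max_correspondence_distance`) with the
#' least-squares rigid update (SVD/Kabsch). Iterations stop at
#' `max_iterations` or when the RMS correspondence distance changes by less
#' than a relative `tolerance`. By default the search starts from the
#' identity; because plain ICP has a narrow rotational convergence basin,
#' `init_rotations_deg` can list additional starting rotations (applied
#' about the moving cloud's centroid, with the centroids pre-aligned), in
#' which case the start with the lowest final RMS wins --
#' [register_series()] uses this multi-start mode. Non-convergence is
#' flagged on the result, not raised.
#'
#' @param moving,reference [sbi_cloud()] objects (or bare `n x 2` matrices).
#' @param max_correspondence_distance correspondences farther than this
#'   (voxels) are discarded each iteration.
#' @param max_iterations iteration cap (per start).
#' @param tolerance relative RMS-change convergence threshold.
#' @param min_points minimum cloud size.
#' @param init_rotations_deg numeric vector of starting rotations; the
#'   default `0` is the plain identity start.
#' @return a [rigid2d()] mapping `moving` into `reference`'s frame, with
#'   attributes `converged`, `rms` (final RMS correspondence distance) and
#'   `n_correspondences`.
#' @export
register_pair <- function(moving, reference,
                          max_correspondence_distance = 10,
                          max_iterations = 100, tolerance = 1e-6,
                          min_points = 10, init_rotations_deg = 0) {
  M <- if (inherits(moving, "sbi_cloud")) moving$points else rbind(moving)
  B <- if (inherits(reference, "sbi_cloud")) reference$points else rbind(reference)
  if (nrow(M) < min_points || nrow(B) < min_points)
    stopf("both clouds need at least %d points", min_points)
  multi <- length(init_rotations_deg) > 1L || any(init_rotations_deg != 0)
  cm <- colMeans(M); cb <- colMeans(B)
  best <- NULL
  for (th0 in init_rotations_deg) {
    if (multi) {
      R0 <- rot2(th0)
      t0 <- cb - as.vector(R0 %*% cm)  # rotate about centroid, align centroids
    } else {
      R0 <- diag(2); t0 <- c(0, 0)
    }
    res <- icp_core(M, B, R0, t0, max_correspondence_distance,
                    max_iterations, tolerance)
    # prefer fits that keep a healthy share of correspondences
    score <- if (res$ncorr >= 0.3 * nrow(M)) res$rms else res$rms + 1e6
    if (is.null(best) || (is.finite(score) && score < best$score))
      best <- c(res, list(score = score))
  }
  out <- matrix_to_rigid2d(rbind(cbind(best$R, best$t), c(0, 0, 1)))
  attr(out, "converged") <- best$converged
  attr(out, "rms") <- best$rms
  attr(out, "n_correspondences") <- best$ncorr
  out
}

#' Register a series of SBI clouds to a common reference day
#'
#' @param clouds list of [sbi_cloud()] objects (>= 2).
#' @param reference_index index of the reference cloud; defaults to the last
#'   day, where the manual root-system vector is defined.
#' @param init_rotations_deg starting rotations for the multi-start search
#'   (see [register_pair()]); the default spans the pairwise misalignments
#'   that arise when both days are independently rotated by up to ~10 deg.
#' @param ... passed to [register_pair()].
#' @return a list of [rigid2d()], one per cloud, mapping each day into the
#'   reference day's frame (exact identity for the reference itself).
#' @export
register_series <- function(clouds, reference_index = length(clouds),
                            init_rotations_deg = seq(-20, 20, by = 4), ...) {
  if (length(clouds) < 2L) stopf("need at least 2 clouds")
  stopifnot(reference_index >= 1L, reference_index <= length(clouds))
  ref <- clouds[[reference_index]]
  lapply(seq_along(clouds), function(i) {
    if (i == reference_index) {
      out <- rigid2d(0, 0, 0)
      attr(out, "converged") <- TRUE
      attr(out, "rms") <- 0
      return(out)
    }
    tryCatch(register_pair(clouds[[i]], ref,
                           init_rotations_deg = init_rotations_deg, ...),
             error = function(e) stopf("registration of day %s failed: %s",
                                       clouds[[i]]$day, conditionMessage(e)))
  })
}

#' Resample a volume under a planar rigid transform
#'
#' Every z-slice is resampled under the inverse mapping so that the output
#' volume is the input moved by `transform`. Out-of-bounds voxels are 0.
#'
#' @param volume a [volume3d()].
#' @param transform a [rigid2d()].
#' @param interpolation `"linear"` (bilinear; grayscale volumes) or
#'   `"nearest"` (binary masks stay binary).
#' @return a [volume3d()] of the same shape.
#' @export
apply_transform <- function(volume, transform,
                            interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(volume, "volume3d"), inherits(transform, "rigid2d"))
  d <- dim(volume$intensities)
  ny <- d[2]; nx <- d[3]
  # output voxel centers (x, y), 0-based
  xx <- rep(0:(nx - 1), each = ny)
  yy <- rep(0:(ny - 1), times = nx)
  src <- transform_points(invert_transform(transform), cbind(xx, yy))
  sx <- src[, 1]; sy <- src[, 2]
  v <- volume$intensities
  out <- array(if (is.integer(v) && interpolation == "nearest") 0L else 0, d)
  if (interpolation == "nearest") {
    ix <- round(sx); iy <- round(sy)
    ok <- ix >= 0 & ix <= nx - 1 & iy >= 0 & iy <= ny - 1
    dst <- which(ok)
    srcidx <- cbind(iy[ok] + 1, ix[ok] + 1)
    for (k in seq_len(d[1])) {
      sl <- v[k, , ]
      o <- matrix(if (is.integer(v)) 0L else 0, ny, nx)
      o[dst] <- sl[srcidx]
      out[k, , ] <- o
    }
  } else {
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    ok <- x0 >= -1 & x0 <= nx - 1 & y0 >= -1 & y0 <= ny - 1
    dst <- which(ok)
    x0k <- x0[ok]; y0k <- y0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
    # corner validity (zero padding outside)
    in00 <- x0k >= 0 & y0k >= 0
    in01 <- x0k >= 0 & y0k + 1 <= ny - 1
    in10 <- x0k + 1 <= nx - 1 & y0k >= 0
    in11 <- x0k + 1 <= nx - 1 & y0k + 1 <= ny - 1
    i00 <- cbind(pmax(y0k, 0) + 1, pmax(x0k, 0) + 1)
    i01 <- cbind(pmin(y0k + 1, ny - 1) + 1, pmax(x0k, 0) + 1)
    i10 <- cbind(pmax(y0k, 0) + 1, pmin(x0k + 1, nx - 1) + 1)
    i11 <- cbind(pmin(y0k + 1, ny - 1) + 1, pmin(x0k + 1, nx - 1) + 1)
    w00 <- (1 - fxk) * (1 - fyk) * in00
    w01 <- (1 - fxk) * fyk * in01
    w10 <- fxk * (1 - fyk) * in10
    w11 <- fxk * fyk * in11
    for (k in seq_len(d[1])) {
      sl <- v[k, , ]
      o <- matrix(0, ny, nx)
      o[dst] <- w00 * sl[i00] + w01 * sl[i01] + w10 * sl[i10] + w11 * sl[i11]
      out[k, , ] <- o
    }
  }
  volume3d(out, volume$voxel_size_mm, volume$day)
}

#' Symmetric mean nearest-neighbor distance between two clouds
#'
#' The average of the two directed mean nearest-neighbor distances; used to
#' quantify how well two SBI clouds overlap before and after registration.
#'
#' @param cloud_a,cloud_b [sbi_cloud()] objects (or `n x 2` matrices).
#' @return mean distance in voxels.
#' @export
alignment_error <- function(cloud_a, cloud_b) {
  A <- if (inherits(cloud_a, "sbi_cloud")) cloud_a$points else rbind(cloud_a)
  B <- if (inherits(cloud_b, "sbi_cloud")) cloud_b$points else rbind(cloud_b)
  if (nrow(A) == 0L || nrow(B) == 0L) stopf("empty cloud")
  (mean(nn_bruteforce(A, B)$dist) + mean(nn_bruteforce(B, A)$dist)) / 2
}
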