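#' Configuration for the synthetic soil-and-root phantom
#'
#' The phantom emulates the features of a potted X-ray CT time series that
#' the pipeline relies on: bright mineral-like particles fixed in the soil
#' frame, tubular roots that elongate linearly between per-root start (`x1`)
#' and end (`x2`) days and never move once grown, a per-day rigid
#' misalignment (rotation about the vertical axis plus horizontal
#' translation), and additive Gaussian noise on a constant soil background.
#'
#' @param dim grid shape `(nz, ny, nx)` in voxels.
#' @param voxel_size_mm voxel size in mm.
#' @param days strictly increasing integer acquisition days.
#' @param n_roots number of roots.
#' @param root_radius_vox tube radius, voxels.
#' @param final_length_mm_range per-root final length range, mm.
#' @param x1_range,x2_range per-root elongation start/end day ranges;
#'   sampled `x2` is forced above `x1 + 1`.
#' @param root_intensity,faint_intensity tube gray values; `faint_root_ids`
#'   names roots rendered at the faint value (emulating hard-to-score faint
#'   segments such as a seminal root).
#' @param n_particles number of soil particles (>= 10).
#' @param particle_radius_range particle blob radius range, voxels.
#' @param particle_intensity_range particle gray-value range; keep well above
#'   `background` so percentile thresholding finds them.
#' @param particle_min_sep minimum center separation between particles,
#'   voxels (keeps blobs from merging).
#' @param background,noise_sd soil background gray value and noise SD.
#' @param rotation_range_deg,translation_range_vox per-day misalignment
#'   ranges (uniform).
#' @param basal_radius_range horizontal radius range (voxels) of the shared
#'   basal region root bases are drawn from; widen it for many roots.
#' @param basal_arc_vox arc length (voxels) of the basal stretch exempt from
#'   the separation check (roots necessarily crowd near the crown).
#' @param roots_spec optional data frame with columns `x1`, `x2`,
#'   `final_length_mm` fixing each root's parameters explicitly instead of
#'   sampling them (e.g. to construct elongation rates that covary with
#'   emergence day); overrides `n_roots` and the sampling ranges.
#' @param root_min_separation_vox minimum distance (voxels) between the
#'   centerlines of different roots outside the shared basal region;
#'   candidate centerlines closer than this are redrawn. Keeps tubes from
#'   merging, which would make their backward histories inseparable.
#' @param growth_mode `"linear"` (default; matches the piecewise-linear model
#'   the trajectory fitter assumes) or `"sigmoid"` for robustness tests.
#' @param seed integer driving all randomness. Stream order: particles,
#'   then root parameters and centerlines, then per-day transforms, then
#'   per-day noise.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(dim = c(160, 160, 160),
                           voxel_size_mm = 0.3,
                           days = 7:27,
                           n_roots = 8,
                           root_radius_vox = 2.5,
                           final_length_mm_range = c(28, 42),
                           x1_range = c(8, 18),
                           x2_range = c(14, 26),
                           root_intensity = 120,
                           faint_root_ids = character(),
                           faint_intensity = 70,
                           n_particles = 200,
                           particle_radius_range = c(1, 3),
                           particle_intensity_range = c(180, 255),
                           particle_min_sep = 8,
                           background = 50,
                           noise_sd = 5,
                           basal_radius_range = c(3, 6),
                           basal_arc_vox = 16,
                           roots_spec = NULL,
                           root_min_separation_vox = 9,
                           rotation_range_deg = c(-10, 10),
                           translation_range_vox = c(-5, 5),
                           growth_mode = c("linear", "sigmoid"),
                           seed = 1L) {
  growth_mode <- match.arg(growth_mode)
  days <- as.numeric(days)
  if (length(days) < 1L || is.unsorted(days, strictly = TRUE))
    stopf("days must be strictly increasing")
  if (n_particles < 10L) stopf("n_particles must be >= 10")
  if (diff(range(x1_range)) < 0 || diff(range(x2_range)) < 0)
    stopf("invalid x1/x2 ranges")
  if (!is.null(roots_spec)) {
    stopifnot(all(c("x1", "x2", "final_length_mm") %in% names(roots_spec)))
    if (any(roots_spec$x2 <= roots_spec$x1)) stopf("roots_spec requires x2 > x1")
    n_roots <- nrow(roots_spec)
  }
  cfg <- as.list(environment())
  class(cfg) <- "phantom_config"
  cfg
}

# growth fraction in [0, 1] at day d
growth_fraction <- function(d, x1, x2, mode = "linear") {
  f <- pmin(pmax((d - x1) / (x2 - x1), 0), 1)
  if (mode == "sigmoid") {
    k <- 8
    lo <- stats::plogis(-k / 2); hi <- stats::plogis(k / 2)
    f <- (stats::plogis(k * (f - 0.5)) - lo) / (hi - lo)
    f[d <= x1] <- 0; f[d >= x2] <- 1
  }
  f
}

# random downward-biased centerline from `start` (z,y,x), ~2-voxel steps,
# steered away from grid borders; base -> tip. The initial heading fans
# outward around `azimuth` so roots from the shared basal region diverge.
make_centerline <- function(start, length_vox, dm, margin = 18, step = 2,
                            azimuth = NULL) {
  tilt <- runif(1, 20, 55) * pi / 180
  az <- if (is.null(azimuth)) runif(1, 0, 2 * pi) else azimuth + runif(1, -0.5, 0.5)
  dir <- c(cos(tilt), sin(tilt) * sin(az), sin(tilt) * cos(az))  # (z, y, x)
  nodes <- matrix(start, 1, 3)
  p <- start
  total <- 0
  cen <- c(NA, (dm[2] - 1) / 2, (dm[3] - 1) / 2)
  n_steps <- ceiling(length_vox / step) + 2L
  for (i in seq_len(n_steps)) {
    jit <- rnorm(3, 0, 0.12)
    dir <- dir + jit + c(0.04, 0, 0)  # downward bias
    # steer inward when close to lateral borders or bottom
    lat <- p[2:3] - cen[2:3]
    latr <- sqrt(sum(lat^2))
    rmax <- min(dm[2], dm[3]) / 2 - margin
    if (latr > rmax * 0.85 && latr > 0)
      dir[2:3] <- dir[2:3] - 0.6 * lat / latr
    if (p[1] > dm[1] - 1 - margin) dir[1] <- dir[1] - 0.5
    dir <- dir / sqrt(sum(dir^2))
    p <- p + step * dir
    if (p[1] < 1 || p[1] > dm[1] - 2 ||
        sqrt(sum((p[2:3] - cen[2:3])^2)) > min(dm[2], dm[3]) / 2 - margin / 2)
      stopf("root centerline would exit the grid; enlarge the grid or shorten roots")
    nodes <- rbind(nodes, p)
    total <- total + step
    if (total >= length_vox) break
  }
  unname(nodes)
}

# minimum node-to-node distance between a candidate centerline (outside its
# basal stretch) and the nodes of previously placed roots
centerline_separation <- function(cand, prev_nodes, basal_arc = 16) {
  cum <- polyline_arclength(cand)
  body <- cand[cum > basal_arc, , drop = FALSE]
  if (nrow(body) == 0L) return(Inf)
  d2 <- outer(rowSums(body^2), rowSums(prev_nodes^2), "+") -
    2 * tcrossprod(body, prev_nodes)
  sqrt(max(min(d2), 0))
}

render_balls <- function(vol, centers, radii, values) {
  dm <- dim(vol)
  for (i in seq_len(nrow(centers))) {
    c0 <- centers[i, ]; r <- radii[i]
    lo <- pmax(floor(c0 - r), 0); hi <- pmin(ceiling(c0 + r), dm - 1)
    if (any(lo > hi)) next
    zz <- lo[1]:hi[1]; yy <- lo[2]:hi[2]; xx <- lo[3]:hi[3]
    g <- expand.grid(z = zz, y = yy, x = xx)
    d2 <- (g$z - c0[1])^2 + (g$y - c0[2])^2 + (g$x - c0[3])^2
    sel <- d2 <= r^2
    if (!any(sel)) next
    idx <- cbind(g$z[sel] + 1, g$y[sel] + 1, g$x[sel] + 1)
    vol[idx] <- pmax(vol[idx], values[i])
  }
  vol
}

render_tube <- function(vol, nodes, radius, value) {
  if (is.null(nodes) || nrow(nodes) < 2L) return(vol)
  dm <- dim(vol)
  for (i in seq_len(nrow(nodes) - 1L)) {
    a <- nodes[i, ]; b <- nodes[i + 1L, ]
    lo <- pmax(floor(pmin(a, b) - radius), 0)
    hi <- pmin(ceiling(pmax(a, b) + radius), dm - 1)
    if (any(lo > hi)) next
    g <- expand.grid(z = lo[1]:hi[1], y = lo[2]:hi[2], x = lo[3]:hi[3])
    ab <- b - a
    len2 <- sum(ab^2)
    ap <- cbind(g$z - a[1], g$y - a[2], g$x - a[3])
    t <- pmin(pmax((ap %*% ab) / len2, 0), 1)
    d2 <- rowSums((ap - t %*% t(ab))^2)
    sel <- d2 <= radius^2
    if (!any(sel)) next
    idx <- cbind(g$z[sel] + 1, g$y[sel] + 1, g$x[sel] + 1)
    vol[idx] <- pmax(vol[idx], value)
  }
  vol
}

# apply a day transform (horizontal rigid motion) to (z,y,x) points
transform_zyx <- function(transform, nodes) {
  xy <- transform_points(transform, nodes[, c(3, 2), drop = FALSE])
  cbind(nodes[, 1], xy[, 2], xy[, 1])
}

#' Generate a time-series phantom with ground truth
#'
#' Renders one volume per configured day. Particles are fixed in the soil
#' frame; each root is rendered as a tube along the leading fraction of its
#' centerline given by its growth curve, so the grown part is voxel-identical
#' across days in the soil frame. Each day's scene is then moved by that
#' day's rigid misalignment before noise is added. Also returns the
#' ground-truth vector at the last day (in the last day's frame), with nodes
#' spaced about 2 voxels of arc length apart.
#'
#' @param config a [phantom_config()].
#' @param render if `FALSE`, skip volume rendering and return only the truth
#'   and last-day vector (cheap; useful for cloud-level studies).
#' @return a list with elements `volumes` (list of [volume3d()], one per
#'   day), `truth` (a `phantom_truth` object), and `vector`
#'   (an [rsa_vector()] at the last day).
#' @export
generate_phantom_series <- function(config, render = TRUE) {
  stopifnot(inherits(config, "phantom_config"))
  dm <- config$dim
  with_seed(config$seed, {
    # --- particles (soil frame) ---
    margin <- 16
    cen <- c((dm[2] - 1) / 2, (dm[3] - 1) / 2)
    rmax <- min(dm[2], dm[3]) / 2 - margin
    pts <- matrix(NA_real_, 0, 3)
    tries <- 0
    while (nrow(pts) < config$n_particles && tries < config$n_particles * 200) {
      tries <- tries + 1
      rr <- rmax * sqrt(runif(1)); ang <- runif(1, 0, 2 * pi)
      cand <- c(runif(1, 2, dm[1] - 3),
                cen[1] + rr * sin(ang), cen[2] + rr * cos(ang))
      if (nrow(pts) == 0 ||
          min(rowSums(sweep(pts, 2, cand)^2)) >= config$particle_min_sep^2)
        pts <- rbind(pts, cand)
    }
    if (nrow(pts) < config$n_particles)
      stopf("could not place %d particles with separation %.1f",
            config$n_particles, config$particle_min_sep)
    radii <- runif(config$n_particles, config$particle_radius_range[1],
                   config$particle_radius_range[2])
    pint <- runif(config$n_particles, config$particle_intensity_range[1],
                  config$particle_intensity_range[2])

    # --- roots (soil frame) ---
    roots <- vector("list", config$n_roots)
    for (i in seq_len(config$n_roots)) {
      if (!is.null(config$roots_spec)) {
        x1 <- config$roots_spec$x1[i]
        x2 <- config$roots_spec$x2[i]
        L_mm <- config$roots_spec$final_length_mm[i]
      } else {
        x1 <- runif(1, config$x1_range[1], config$x1_range[2])
        x2 <- max(runif(1, config$x2_range[1], config$x2_range[2]), x1 + 1)
        L_mm <- runif(1, config$final_length_mm_range[1], config$final_length_mm_range[2])
      }
      L_vox <- L_mm / config$voxel_size_mm
      ang0 <- 2 * pi * (i - 1) / config$n_roots + runif(1, -0.2, 0.2)
      br <- config$basal_radius_range
      start <- c(runif(1, 4, 8),
                 cen[1] + runif(1, br[1], br[2]) * sin(ang0),
                 cen[2] + runif(1, br[1], br[2]) * cos(ang0))
      # redraw centerlines that run too close to an earlier root outside the
      # shared basal region; fall back to the best-separated candidate
      prev_nodes <- do.call(rbind, lapply(roots[seq_len(i - 1)],
                                          function(r) if (!is.null(r)) r$nodes))
      nodes <- NULL
      best <- NULL; best_sep <- -Inf
      for (attempt in 1:25) {
        cand <- tryCatch(make_centerline(start, L_vox, dm, azimuth = ang0),
                         error = function(e) NULL)  # rare grid-exit draw
        if (is.null(cand)) next
        sep <- if (is.null(prev_nodes)) Inf
               else centerline_separation(cand, prev_nodes, config$basal_arc_vox)
        if (sep >= config$root_min_separation_vox) {
          nodes <- cand
          break
        }
        if (sep > best_sep) { best <- cand; best_sep <- sep }
      }
      if (is.null(nodes)) {
        if (is.null(best))
          stopf("root %d: no centerline fits the grid; enlarge the grid or shorten roots", i)
        warnf("root %d placed at separation %.1f (< requested %.1f)",
              i, best_sep, config$root_min_separation_vox)
        nodes <- best
      }
      arc <- polyline_arclength(nodes)
      roots[[i]] <- list(id = sprintf("r%02d", i), nodes = nodes,
                         x1 = x1, x2 = x2,
                         final_length_mm = arc[length(arc)] * config$voxel_size_mm)
    }
    names(roots) <- vapply(roots, `[[`, character(1), "id")

    # --- per-day transforms ---
    transforms <- lapply(config$days, function(d)
      rigid2d(runif(1, config$rotation_range_deg[1], config$rotation_range_deg[2]),
              runif(1, config$translation_range_vox[1], config$translation_range_vox[2]),
              runif(1, config$translation_range_vox[1], config$translation_range_vox[2]),
              center = c((dm[3] - 1) / 2, (dm[2] - 1) / 2)))
    names(transforms) <- as.character(config$days)

    truth <- structure(list(days = config$days, dim = dm,
                            voxel_size_mm = config$voxel_size_mm,
                            transforms = transforms,
                            particles = data.frame(z = pts[, 1], y = pts[, 2],
                                                   x = pts[, 3], radius = radii,
                                                   intensity = pint),
                            roots = roots, config = config),
                       class = "phantom_truth")

    # --- last-day vector, in the last day's frame ---
    last <- config$days[length(config$days)]
    vec_roots <- list()
    for (r in roots) {
      fr <- growth_fraction(last, r$x1, r$x2, config$growth_mode)
      arc <- polyline_arclength(r$nodes)
      part <- polyline_truncate(r$nodes, fr * arc[length(arc)])
      if (is.null(part) || nrow(part) < 2L) next
      vec_roots[[r$id]] <- list(id = r$id,
                                nodes = transform_zyx(transforms[[as.character(last)]], part))
    }
    vec <- rsa_vector(vec_roots, config$voxel_size_mm, last)

    volumes <- NULL
    if (render) {
      volumes <- lapply(seq_along(config$days), function(di) {
        d <- config$days[di]
        tr <- transforms[[as.character(d)]]
        vol <- array(config$background, dm)
        vol <- render_balls(vol, transform_zyx(tr, pts), radii, pint)
        for (r in roots) {
          fr <- growth_fraction(d, r$x1, r$x2, config$growth_mode)
          if (fr <= 0) next
          arc <- polyline_arclength(r$nodes)
          part <- polyline_truncate(r$nodes, fr * arc[length(arc)])
          val <- if (r$id %in% config$faint_root_ids) config$faint_intensity
                 else config$root_intensity
          vol <- render_tube(vol, transform_zyx(tr, part), config$root_radius_vox, val)
        }
        vol <- vol + rnorm(length(vol), 0, config$noise_sd)
        vol <- round(pmin(pmax(vol, 0), 255))
        storage.mode(vol) <- "integer"
        volume3d(vol, config$voxel_size_mm, d)
      })
    }
    list(volumes = volumes, truth = truth, vector = vec)
  })
}

#' Ground-truth relative length of a phantom root
#'
#' Relative length (RL) is the missing fraction of the root measured from
#' the tip: 0 means full length, 1 means the root is absent.
#'
#' @param truth a `phantom_truth` object.
#' @param root_id root identifier.
#' @param day day to evaluate at.
#' @return RL in `[0, 1]`.
#' @export
true_rl <- function(truth, root_id, day) {
  stopifnot(inherits(truth, "phantom_truth"))
  r <- truth$roots[[root_id]]
  if (is.null(r)) stopf("unknown root id: %s", root_id)
  1 - growth_fraction(day, r$x1, r$x2, truth$config$growth_mode)
}

#' Render the ground-truth binary root mask of a phantom day
#'
#' Used to validate segmentation: voxels within the tube radius of any
#' grown centerline portion, in the requested frame.
#'
#' @param truth a `phantom_truth` object.
#' @param day day to render.
#' @param frame `"soil"` for the common soil frame or `"day"` for that
#'   day's misaligned frame.
#' @return a logical array of the phantom's grid shape.
#' @export
true_root_mask <- function(truth, day, frame = c("day", "soil")) {
  frame <- match.arg(frame)
  cfg <- truth$config
  vol <- array(0, truth$dim)
  tr <- truth$transforms[[as.character(day)]]
  for (r in truth$roots) {
    fr <- growth_fraction(day, r$x1, r$x2, cfg$growth_mode)
    if (fr <= 0) next
    arc <- polyline_arclength(r$nodes)
    part <- polyline_truncate(r$nodes, fr * arc[length(arc)])
    if (frame == "day") part <- transform_zyx(tr, part)
    vol <- render_tube(vol, part, cfg$root_radius_vox, 1)
  }
  vol > 0
}
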