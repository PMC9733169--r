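#' Fit a unit step to a score profile
#'
#' Finds the borderline `xthr` between scores ~0 (tip side, not yet grown)
#' and ~1 (base side, grown) by exhaustive search: for every candidate
#' `xthr` in `0..N`, the predicted score is 0 for tip-origin node index
#' `x < xthr` and 1 for `x >= xthr`; the candidate with the smallest mean
#' squared error wins, ties going to the smallest `xthr`.
#'
#' @param profile a `score_profile` data frame (or a bare numeric vector of
#'   scores in tip-origin order).
#' @return a list with `xthr` (integer in `0..N`) and `mse`.
#' @export
fit_step <- function(profile) {
  y <- if (is.data.frame(profile)) profile$score else as.numeric(profile)
  n <- length(y)
  if (n < 1L) stopf("empty profile")
  # sse(xthr) = sum_{x < xthr} y^2 + sum_{x >= xthr} (1 - y)^2
  sse <- c(0, cumsum(y^2)) + rev(c(0, cumsum(rev((1 - y)^2))))
  xthr <- which.min(sse) - 1L  # first minimum = smallest xthr
  list(xthr = xthr, mse = sse[xthr + 1L] / n)
}

#' Convert a step-fit node index into relative length
#'
#' Relative length (RL) is the missing fraction of the root measured from
#' the tip, computed on polyline arc length (nodes may be unevenly spaced):
#' `RL = arc(tip..node xthr) / arc(total)`, so `xthr = 0` gives 0 (full
#' length) and `xthr = N` gives 1 (root absent).
#'
#' @param root one element of `rsa_vector$roots` (nodes base to tip).
#' @param xthr tip-origin node index in `0..N`.
#' @return RL in `[0, 1]`.
#' @export
node_index_to_rl <- function(root, xthr) {
  n <- nrow(root$nodes)
  if (xthr < 0 || xthr > n) stopf("xthr %s out of range 0..%d", xthr, n)
  if (xthr >= n) return(1)
  cum <- polyline_arclength(root$nodes)   # from base
  total <- cum[n]
  (total - cum[n - xthr]) / total
}

#' Backward-predict relative-length trajectories for every root
#'
#' For each root and each day before the last, scores the last-day vector
#' nodes against that day's segmented volume, fits the step borderline, and
#' converts it to relative length; the last day is appended with RL 0 by
#' construction (the vector was traced there).
#'
#' @param models_per_root scorer choice: `NULL` for the deterministic
#'   occupancy baseline, a single `root_discriminator` shared by all roots,
#'   or a named list of per-root (fine-tuned) models.
#' @param segmented_series list of root-segmented [volume3d()]s, one per
#'   day, all registered to the reference (last-day) frame, with `day` set.
#' @param vector_last_day the [rsa_vector()] at the last day.
#' @param expected_days optional vector of days that must be present in the
#'   series; any missing ones are reported in an error rather than skipped.
#' @param ... extra arguments for [baseline_score_nodes()].
#' @return a data frame with columns `root_id`, `day`, `rl`, ordered by
#'   root then day.
#' @export
build_trajectories <- function(models_per_root, segmented_series,
                               vector_last_day, expected_days = NULL, ...) {
  stopifnot(inherits(vector_last_day, "rsa_vector"))
  days <- vapply(segmented_series, function(v) as.numeric(v$day), numeric(1))
  if (anyNA(days)) stopf("segmented volumes must carry day labels")
  if (!is.null(expected_days)) {
    miss <- setdiff(expected_days, days)
    if (length(miss))
      stopf("segmented volumes missing for day(s): %s", paste(miss, collapse = ", "))
  }
  o <- order(days)
  segmented_series <- segmented_series[o]; days <- days[o]
  last_day <- vector_last_day$day
  earlier <- days < last_day
  out <- list()
  for (r in vector_last_day$roots) {
    model <- if (is.null(models_per_root)) NULL
             else if (inherits(models_per_root, "root_discriminator")) models_per_root
             else models_per_root[[r$id]]
    if (!is.null(models_per_root) && is.null(model))
      stopf("no model supplied for root %s", r$id)
    rls <- vapply(which(earlier), function(i) {
      prof <- if (is.null(model))
        baseline_score_nodes(segmented_series[[i]], r, ...)
      else score_nodes(model, segmented_series[[i]], r)
      node_index_to_rl(r, fit_step(prof)$xthr)
    }, numeric(1))
    out[[r$id]] <- data.frame(root_id = r$id,
                              day = c(days[earlier], last_day),
                              rl = c(rls, 0))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Candidate grid for the piecewise-linear growth fit
#'
#' Precomputes every candidate `(x1, x2, ythr)` and the corresponding model
#' curve evaluated at the observation days, ordered by the fit's tie-break
#' (ythr descending, then x1 ascending, then x2 ascending). Build it once
#' when fitting many trajectories observed on the same days.
#'
#' @param days observation days.
#' @param x_step grid step for `x1` and `x2`, days. `x1` ranges from 0 (so
#'   elongation that started before the first scan is handled by letting
#'   the slope extend to day 0) to the last day; `x2` ranges over
#'   `(x1, last day]`.
#' @param ythr_step grid step for the plateau level `ythr` in `(0, 1]`.
#' @return an object of class `growth_grid`.
#' @export
growth_grid <- function(days, x_step = 0.25, ythr_step = 0.05) {
  days <- sort(as.numeric(days))
  last <- days[length(days)]
  xs <- seq(0, last, by = x_step)
  pairs <- do.call(rbind, lapply(seq_along(xs), function(i) {
    x2 <- xs[xs > xs[i]]
    if (!length(x2)) return(NULL)
    cbind(x1 = xs[i], x2 = x2)
  }))
  ythr <- seq(ythr_step, 1, by = ythr_step)
  cand <- cbind(pairs[rep(seq_len(nrow(pairs)), times = length(ythr)), ],
                ythr = rep(ythr, each = nrow(pairs)))
  # tie-break order: ythr descending, x1 ascending, x2 ascending
  cand <- cand[order(-cand[, "ythr"], cand[, "x1"], cand[, "x2"]), ]
  M <- growth_model_curve(cand[, "x1"], cand[, "x2"], cand[, "ythr"], days)
  structure(list(days = days, cand = cand, M = M, q = rowMeans(M^2),
                 x_step = x_step, ythr_step = ythr_step),
            class = "growth_grid")
}

#' Piecewise-linear growth model curve
#'
#' The fitted relative-length model
#' `y(x) = min(max((x - x2) / (x1 - x2), 0), ythr)`: RL is `ythr` (at most
#' 1) before elongation starts at day `x1`, falls linearly to 0 at day
#' `x2`, and stays 0 afterwards.
#'
#' @param x1,x2 elongation start and end days (vectorized).
#' @param ythr plateau level in `(0, 1]`.
#' @param days days to evaluate at.
#' @return a `length(x1) x length(days)` matrix (dropped to a vector for a
#'   single parameter set).
#' @export
growth_model_curve <- function(x1, x2, ythr, days) {
  k <- length(x1)
  D <- matrix(days, k, length(days), byrow = TRUE)
  y <- (D - x2) / (x1 - x2)
  y <- pmin(pmax(y, 0), ythr)
  if (k == 1L) as.numeric(y) else y
}

#' Fit the piecewise-linear elongation model to an RL trajectory
#'
#' Exhaustive grid search for the elongation start day `x1`, end day `x2`
#' and plateau `ythr` minimizing the mean squared error against the
#' observed relative lengths, with tie-break ythr descending, x1 ascending,
#' x2 ascending. The fit is classified as:
#' \describe{
#'   \item{pre_existing}{the trajectory never rises above
#'     `pre_existing_max_rl` -- the root was already full length at the
#'     first scan; no `(x1, x2)` is reported.}
#'   \item{overlapped}{fitted `ythr < 1` with the plateau expressed in the
#'     data (another root's segment kept scores high near the base).}
#'   \item{incomplete}{fitted `x1` earlier than the first observed day
#'     (elongation was already under way at the first scan; the slope is
#'     extended toward day 0).}
#'   \item{basic}{everything else.}
#' }
#'
#' @param traj data frame with columns `day` and `rl` for one root (the
#'   output of [build_trajectories()], subset to one root).
#' @param grid a [growth_grid()] for the trajectory's days; built on the
#'   fly when `NULL`.
#' @param pre_existing_max_rl RL ceiling below which a trajectory counts as
#'   pre-existing.
#' @return a list with `x1`, `x2`, `ythr`, `mse`, `classification`.
#' @export
fit_trajectory <- function(traj, grid = NULL, pre_existing_max_rl = 0.05) {
  stopifnot(all(c("day", "rl") %in% names(traj)))
  traj <- traj[order(traj$day), ]
  days <- traj$day; y <- traj$rl
  if (length(unique(days)) < 2L) stopf("need at least 2 distinct days")
  if (max(y) < pre_existing_max_rl) {
    return(list(x1 = NA_real_, x2 = NA_real_, ythr = NA_real_,
                mse = mean(y^2), classification = "pre_existing"))
  }
  if (is.null(grid)) grid <- growth_grid(days)
  if (!isTRUE(all.equal(grid$days, days)))
    stopf("grid was built for different observation days")
  n <- length(days)
  mse <- grid$q - 2 * as.numeric(grid$M %*% y) / n + mean(y^2)
  best <- min(mse)
  k <- which(mse <= best + 1e-12)[1L]  # grid rows are in tie-break order
  fit <- list(x1 = unname(grid$cand[k, "x1"]), x2 = unname(grid$cand[k, "x2"]),
              ythr = unname(grid$cand[k, "ythr"]), mse = max(mse[k], 0))
  plateau_expressed <- max(y) >= fit$ythr - grid$ythr_step / 2
  fit$classification <-
    if (fit$ythr < 1 - 1e-9 && plateau_expressed) "overlapped"
    else if (fit$x1 < days[1]) "incomplete"
    else "basic"
  fit
}

#' Fit every root's trajectory
#'
#' @param trajectories data frame from [build_trajectories()].
#' @param grid optional shared [growth_grid()].
#' @param ... passed to [fit_trajectory()].
#' @return a data frame with one row per root: `root_id`, `x1`, `x2`,
#'   `ythr`, `mse`, `classification`.
#' @export
fit_trajectories <- function(trajectories, grid = NULL, ...) {
  ids <- unique(trajectories$root_id)
  if (is.null(grid)) {
    d0 <- sort(unique(trajectories$day[trajectories$root_id == ids[1]]))
    grid <- growth_grid(d0)
  }
  rows <- lapply(ids, function(id) {
    f <- fit_trajectory(trajectories[trajectories$root_id == id, ], grid, ...)
    data.frame(root_id = id, x1 = f$x1, x2 = f$x2, ythr = f$ythr,
               mse = f$mse, classification = f$classification)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}
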