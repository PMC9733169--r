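#' Configuration for an end-to-end run
#'
#' Either a phantom configuration (the built-in synthetic generator) or a
#' list of on-disk volumes plus the manually traced last-day vector.
#'
#' @param phantom a [phantom_config()], or `NULL` when loading real data.
#' @param volume_paths character vector of volume paths (one per day, see
#'   [load_volume()]); ignored when `phantom` is given.
#' @param days acquisition days for `volume_paths`.
#' @param voxel_size_mm voxel size for loaded volumes.
#' @param vector_path last-day vector JSON; required unless `phantom`.
#' @param scorer `"baseline"` (deterministic occupancy scorer) or `"cnn"`
#'   (trained block discriminator with per-root fine-tuning).
#' @param seed global seed; stage seeds are derived from it.
#' @param out_dir output directory.
#' @param sbi_params,segment_params,icp_params,score_params,train_params
#'   named lists of overrides passed to [extract_sbi()], [segment_roots()],
#'   [register_pair()], [baseline_score_nodes()] and
#'   [train_discriminator()].
#' @param crop_diameter_mm optional cylinder crop applied before SBI
#'   extraction and segmentation.
#' @param write_volumes also write the aligned segmented volumes (large).
#' @return a `run_config` list.
#' @export
run_config <- function(phantom = NULL, volume_paths = NULL, days = NULL,
                       voxel_size_mm = NULL, vector_path = NULL,
                       scorer = c("baseline", "cnn"), seed = 1L,
                       out_dir = "rsa4d_out",
                       sbi_params = list(), segment_params = list(),
                       icp_params = list(), score_params = list(),
                       train_params = list(),
                       crop_diameter_mm = NULL, write_volumes = FALSE) {
  scorer <- match.arg(scorer)
  if (is.null(phantom)) {
    if (is.null(volume_paths) || length(volume_paths) < 2L)
      stopf("need a phantom config or at least 2 volume paths")
    if (is.null(vector_path))
      stopf("missing required input: the last-day vector (vector_path)")
    if (is.null(days) || length(days) != length(volume_paths))
      stopf("days must match volume_paths")
  }
  structure(as.list(environment()), class = "run_config")
}

stage <- function(name, manifest, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- withCallingHandlers(
    tryCatch(force(expr),
             error = function(e) stopf("stage '%s' failed: %s", name, conditionMessage(e))),
    warning = function(w) {
      manifest$warnings[[length(manifest$warnings) + 1L]] <-
        list(stage = name, message = conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  manifest$timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 2)
  res
}

#' Run the full backward-prediction workflow
#'
#' Executes simulate/load, SBI extraction, series registration, alignment
#' and segmentation, scorer preparation, backward prediction, trajectory
#' fitting and quantification, writing all outputs plus a manifest (seed,
#' parameters, per-stage timing, collected warnings) to `config$out_dir`.
#' The only manual input is the last-day vector; every other step is
#' automatic.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the in-memory results: `transforms`,
#'   `trajectories`, `fits`, `table`, `counts`, `correlation`, `vectors`,
#'   `truth` (phantom runs only), and the output directory.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- new.env()
  manifest$timings <- list()
  manifest$warnings <- list()

  truth <- NULL
  if (!is.null(config$phantom)) {
    sim <- stage("simulate", manifest, generate_phantom_series(config$phantom))
    volumes <- sim$volumes
    vec <- sim$vector
    truth <- sim$truth
    days <- config$phantom$days
    stage("simulate_outputs", manifest, {
      save_vector(vec, file.path(config$out_dir, "vector_last_day.json"))
      save_truth_json(truth, file.path(config$out_dir, "phantom_truth.json"))
    })
  } else {
    volumes <- stage("load", manifest,
                     Map(function(p, d) load_volume(p, config$voxel_size_mm, d),
                         config$volume_paths, config$days))
    vec <- stage("load_vector", manifest, load_vector(config$vector_path))
    days <- config$days
  }
  if (!is.null(config$crop_diameter_mm))
    volumes <- lapply(volumes, crop_cylinder, diameter_mm = config$crop_diameter_mm)

  clouds <- stage("extract_sbi", manifest,
                  lapply(volumes, function(v) do.call(extract_sbi, c(list(v), config$sbi_params))))
  transforms <- stage("register", manifest,
                      do.call(register_series, c(list(clouds), config$icp_params)))
  stage("register_outputs", manifest, {
    tr_df <- do.call(rbind, Map(function(tr, d)
      data.frame(day = d, theta_deg = tr$theta_deg, tx = tr$tx, ty = tr$ty,
                 converged = isTRUE(attr(tr, "converged")),
                 rms = if (is.null(attr(tr, "rms"))) NA_real_ else attr(tr, "rms")),
      transforms, days))
    jsonlite::write_json(tr_df, file.path(config$out_dir, "transforms.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    for (i in seq_along(clouds))
      save_cloud_ply(clouds[[i]],
                     file.path(config$out_dir, sprintf("sbi_day%03d.ply", days[i])))
  })

  segmented <- stage("segment", manifest, {
    lapply(seq_along(volumes), function(i) {
      aligned <- apply_transform(volumes[[i]], transforms[[i]], "linear")
      seg <- do.call(segment_roots, c(list(aligned), config$segment_params))
      if (config$write_volumes)
        save_volume(seg, file.path(config$out_dir, sprintf("seg_day%03d.tif", days[i])))
      seg
    })
  })

  models <- NULL
  if (config$scorer == "cnn") {
    models <- stage("train", manifest, {
      last_seg <- segmented[[length(segmented)]]
      samples <- sample_training_blocks(last_seg, vec, seed = config$seed)
      base <- do.call(train_discriminator,
                      c(list(new_discriminator(seed = config$seed), samples),
                        config$train_params, list(seed = config$seed)))
      write.csv(base$history, file.path(config$out_dir, "training_history.csv"),
                row.names = FALSE)
      per_root <- lapply(vec$roots, function(r) {
        sub_vec <- rsa_vector(list(r), vec$voxel_size_mm, vec$day)
        sub_samples <- sample_training_blocks(last_seg, sub_vec,
                                              seed = config$seed + match(r$id, names(vec$roots)))
        do.call(fine_tune, c(list(base, r$id, sub_samples),
                             config$train_params[setdiff(names(config$train_params), "max_epochs")],
                             list(seed = config$seed)))
      })
      names(per_root) <- names(vec$roots)
      per_root
    })
  }

  trajectories <- stage("predict", manifest, {
    tr <- do.call(build_trajectories,
                  c(list(models, segmented, vec, expected_days = days),
                    if (config$scorer == "baseline") config$score_params))
    write.csv(tr, file.path(config$out_dir, "trajectories.csv"), row.names = FALSE)
    tr
  })
  fits <- stage("fit", manifest, {
    f <- fit_trajectories(trajectories)
    write.csv(f, file.path(config$out_dir, "fits.csv"), row.names = FALSE)
    f
  })

  out <- stage("quantify", manifest, {
    table <- growth_table(fits, vec, days, trajectories)
    counts <- root_count_series(table)
    corr <- tryCatch(emergence_rate_correlation(table),
                     error = function(e) list(r = NA_real_, p_value = NA_real_, n = 0L))
    vectors <- reconstruct_vectors(vec, table)
    write.csv(table$roots, file.path(config$out_dir, "growth_table.csv"), row.names = FALSE)
    write.csv(table$lengths, file.path(config$out_dir, "lengths.csv"), row.names = FALSE)
    write.csv(counts, file.path(config$out_dir, "root_counts.csv"), row.names = FALSE)
    jsonlite::write_json(corr, file.path(config$out_dir, "correlation.json"),
                         auto_unbox = TRUE, digits = NA)
    vdir <- file.path(config$out_dir, "vectors")
    dir.create(vdir, showWarnings = FALSE)
    for (d in names(vectors))
      save_vector(vectors[[d]], file.path(vdir, sprintf("vector_day%03s.json", d)))
    list(table = table, counts = counts, correlation = corr, vectors = vectors)
  })

  manifest_doc <- list(
    package = "rsa4d",
    version = as.character(utils::packageVersion("rsa4d")),
    r_version = R.version.string,
    seed = config$seed,
    scorer = config$scorer,
    days = days,
    parameters = config[c("sbi_params", "segment_params", "icp_params",
                          "score_params", "train_params", "crop_diameter_mm")],
    timings = manifest$timings,
    warnings = manifest$warnings)
  jsonlite::write_json(manifest_doc, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(transforms = transforms, trajectories = trajectories,
                 fits = fits, table = out$table, counts = out$counts,
                 correlation = out$correlation, vectors = out$vectors,
                 truth = truth, clouds = clouds, segmented = segmented,
                 models = models, vector = vec, out_dir = config$out_dir))
}

# minimal ASCII PLY export of an SBI cloud (z = 0 plane), for inspection
save_cloud_ply <- function(cloud, path) {
  pts <- cloud$points
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(pts)),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  writeLines(sprintf("%.4f %.4f 0", pts[, 1], pts[, 2]), con)
  invisible(path)
}

save_truth_json <- function(truth, path) {
  doc <- list(days = truth$days, voxel_size_mm = truth$voxel_size_mm,
              dim = truth$dim,
              transforms = lapply(truth$transforms, function(tr)
                list(theta_deg = tr$theta_deg, tx = tr$tx, ty = tr$ty,
                     center = tr$center)),
              roots = lapply(truth$roots, function(r)
                list(id = r$id, x1 = r$x1, x2 = r$x2,
                     final_length_mm = r$final_length_mm, nodes = r$nodes)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
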