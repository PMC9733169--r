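#' Construct a 3D grayscale volume
#'
#' @param intensities numeric or integer array with `dim = c(nz, ny, nx)`;
#'   voxel `(z, y, x)` (0-based) lives at `intensities[z + 1, y + 1, x + 1]`.
#' @param voxel_size_mm positive scalar, isotropic voxel edge length in mm.
#' @param day integer day label (days after sowing).
#' @return an object of class `volume3d`.
#' @export
volume3d <- function(intensities, voxel_size_mm, day = NA_integer_) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stopf("intensities must be a 3D array")
  if (any(dim(intensities) < 1L)) stopf("all three dimensions must be >= 1")
  if (!all(is.finite(intensities))) stopf("intensities must be finite")
  if (!is_scalar_num(voxel_size_mm) || voxel_size_mm <= 0)
    stopf("voxel_size_mm must be a positive scalar")
  structure(list(intensities = intensities,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 day = as.integer(day)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("volume3d: %d x %d x %d (z,y,x), voxel %.3g mm, day %s\n",
              d[1], d[2], d[3], x$voxel_size_mm, x$day))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$intensities)

slice_files <- function(path) {
  f <- list.files(path, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE,
                  full.names = TRUE)
  sort(f, method = "radix")
}

read_slice <- function(f) {
  ext <- tolower(tools::file_ext(f))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(f, as.is = TRUE)
  } else if (ext == "png") {
    img <- png::readPNG(f)
  } else stopf("unreadable slice format: %s", f)
  if (length(dim(img)) == 3L) img <- img[, , 1]  # first channel of RGB input
  img
}

#' Load a 3D volume from disk
#'
#' Accepts either a directory of equally sized 2D grayscale slices (TIFF or
#' PNG; one file per z, sorted lexicographically) or a single multi-page TIFF.
#' 8/16-bit TIFF slices are kept as integers. A sidecar JSON
#' (`<path>.json` or `<dir>/volume.json`) with fields `voxel_size_mm` and
#' `day` is honored when the arguments are missing.
#'
#' @param path slice directory or multi-page TIFF file.
#' @param voxel_size_mm voxel size in mm; read from the sidecar if `NULL`.
#' @param day acquisition day label; read from the sidecar if `NULL`.
#' @return a [volume3d()].
#' @export
load_volume <- function(path, voxel_size_mm = NULL, day = NULL) {
  if (!file.exists(path)) stopf("missing path: %s", path)
  if (dir.exists(path)) {
    files <- slice_files(path)
    if (length(files) == 0L) stopf("no slices found in %s", path)
    slices <- lapply(files, read_slice)
    sidecar <- file.path(path, "volume.json")
  } else {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("tif", "tiff")) stopf("unreadable format: %s", path)
    slices <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(slices)) slices <- list(slices)
    slices <- lapply(slices, function(s) if (length(dim(s)) == 3L) s[, , 1] else s)
    sidecar <- paste0(path, ".json")
  }
  shp <- dim(slices[[1L]])
  if (!all(vapply(slices, function(s) identical(dim(s), shp), logical(1))))
    stopf("inconsistent slice shapes in %s", path)
  if ((is.null(voxel_size_mm) || is.null(day)) && file.exists(sidecar)) {
    meta <- jsonlite::fromJSON(sidecar)
    if (is.null(voxel_size_mm)) voxel_size_mm <- meta$voxel_size_mm
    if (is.null(day)) day <- meta$day
  }
  if (is.null(voxel_size_mm)) stopf("voxel_size_mm not given and no sidecar found")
  if (is.null(day)) day <- NA_integer_
  vol <- aperm(array(unlist(slices), dim = c(shp[1], shp[2], length(slices))),
               c(3, 1, 2))
  if (all(vol == round(vol))) storage.mode(vol) <- "integer"
  volume3d(vol, voxel_size_mm, day)
}

#' Save a 3D volume to disk
#'
#' Writes a 16-bit multi-page TIFF plus a sidecar JSON carrying the voxel
#' size and day label, so that [load_volume()] round-trips exactly for
#' integer volumes in `[0, 65535]`.
#'
#' @param volume a [volume3d()].
#' @param path output file name (`.tif`).
#' @export
save_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume3d"))
  v <- volume$intensities
  if (any(v < 0) || any(v > 65535))
    stopf("intensities outside [0, 65535] cannot be written as 16-bit TIFF")
  nz <- dim(v)[1]
  pages <- lapply(seq_len(nz), function(k) v[k, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(voxel_size_mm = volume$voxel_size_mm, day = volume$day),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Construct a root-system vector
#'
#' @param roots list of roots; each root is a list with fields `id` (string)
#'   and `nodes` (an `n x 3` numeric matrix of 0-based `(z, y, x)` voxel
#'   coordinates, ordered base to tip, `n >= 2`).
#' @param voxel_size_mm positive scalar, voxel size in mm.
#' @param day integer day label of the volume the vector was traced on.
#' @return an object of class `rsa_vector`.
#' @export
rsa_vector <- function(roots, voxel_size_mm, day = NA_integer_) {
  if (!is.list(roots)) stopf("roots must be a list")
  ids <- vapply(roots, function(r) as.character(r$id), character(1))
  if (anyDuplicated(ids)) stopf("duplicate root id: %s", ids[duplicated(ids)][1])
  if (!is_scalar_num(voxel_size_mm) || voxel_size_mm <= 0)
    stopf("voxel_size_mm must be a positive scalar")
  roots <- lapply(roots, function(r) {
    nodes <- rbind(r$nodes)
    if (!is.numeric(nodes) || ncol(nodes) != 3L)
      stopf("root %s: nodes must be an n x 3 matrix of (z, y, x)", r$id)
    if (nrow(nodes) < 2L) stopf("root %s has fewer than 2 nodes", r$id)
    if (!all(is.finite(nodes))) stopf("root %s: non-finite node coordinates", r$id)
    d <- rowSums((nodes[-1, , drop = FALSE] - nodes[-nrow(nodes), , drop = FALSE])^2)
    if (any(d == 0)) stopf("root %s: consecutive duplicate nodes", r$id)
    dimnames(nodes) <- NULL
    list(id = as.character(r$id), nodes = nodes)
  })
  names(roots) <- ids
  structure(list(roots = roots, voxel_size_mm = as.numeric(voxel_size_mm),
                 day = as.integer(day)),
            class = "rsa_vector")
}

#' @export
print.rsa_vector <- function(x, ...) {
  nn <- vapply(x$roots, function(r) nrow(r$nodes), integer(1))
  cat(sprintf("rsa_vector: %d roots, %d nodes total, voxel %.3g mm, day %s\n",
              length(x$roots), sum(nn), x$voxel_size_mm, x$day))
  invisible(x)
}

#' @export
length.rsa_vector <- function(x) length(x$roots)

#' Total arc length of one root, in mm
#'
#' @param root one element of `rsa_vector$roots`.
#' @param voxel_size_mm voxel size in mm.
#' @export
root_length_mm <- function(root, voxel_size_mm) {
  cum <- polyline_arclength(root$nodes)
  cum[length(cum)] * voxel_size_mm
}

#' Read / write root-system vectors as JSON
#'
#' The on-disk schema is
#' `{"version": 1, "voxel_size_mm": x, "day": d, "roots":
#'  [{"id": "...", "nodes": [[z, y, x], ...]}, ...]}`
#' with 0-based voxel coordinates ordered base to tip.
#'
#' @param path JSON file.
#' @return [load_vector()] returns an [rsa_vector()].
#' @export
load_vector <- function(path) {
  if (!file.exists(path)) stopf("missing path: %s", path)
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE, simplifyDataFrame = FALSE)
  if (is.null(doc$voxel_size_mm) || is.null(doc$roots))
    stopf("not a root-system vector file: %s", path)
  roots <- lapply(doc$roots, function(r) {
    nodes <- r$nodes
    if (is.list(nodes)) nodes <- do.call(rbind, nodes)
    list(id = r$id, nodes = nodes)
  })
  rsa_vector(roots, doc$voxel_size_mm, if (is.null(doc$day)) NA_integer_ else doc$day)
}

#' @param vector an [rsa_vector()].
#' @rdname load_vector
#' @export
save_vector <- function(vector, path) {
  stopifnot(inherits(vector, "rsa_vector"))
  doc <- list(version = 1L, voxel_size_mm = vector$voxel_size_mm,
              day = vector$day,
              roots = unname(lapply(vector$roots, function(r)
                list(id = r$id, nodes = r$nodes))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Zero out voxels outside a vertical cylinder
#'
#' Retains the vertical cylinder of the given diameter centered on the
#' volume's horizontal center (used to discard roots deflected by the pot
#' wall); everything outside is set to 0. The grid shape is unchanged.
#'
#' @param volume a [volume3d()].
#' @param diameter_mm cylinder diameter in mm; must not exceed the horizontal
#'   extent of the volume.
#' @return a [volume3d()] of the same shape.
#' @export
crop_cylinder <- function(volume, diameter_mm) {
  stopifnot(inherits(volume, "volume3d"))
  d <- dim(volume$intensities)
  extent <- min(d[2], d[3]) * volume$voxel_size_mm
  if (diameter_mm > extent)
    stopf("diameter %.3g mm exceeds horizontal extent %.3g mm", diameter_mm, extent)
  r_vox <- diameter_mm / 2 / volume$voxel_size_mm
  cy <- (d[2] - 1) / 2; cx <- (d[3] - 1) / 2
  yy <- matrix(0:(d[2] - 1), d[2], d[3])
  xx <- matrix(0:(d[3] - 1), d[2], d[3], byrow = TRUE)
  keep <- (xx - cx)^2 + (yy - cy)^2 <= r_vox^2
  v <- volume$intensities
  zero <- if (is.integer(v)) 0L else 0
  for (k in seq_len(d[1])) {
    s <- v[k, , ]
    s[!keep] <- zero
    v[k, , ] <- s
  }
  volume3d(v, volume$voxel_size_mm, volume$day)
}
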