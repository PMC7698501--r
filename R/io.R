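#' Read an 8-bit grayscale image
#'
#' Reads a PNG or TIFF file into the package's image convention: an
#' integer matrix with rows top to bottom along the flow axis and
#' intensities in `0 .. bit_depth - 1`. Color images are reduced to
#' their first channel.
#'
#' @param path File path (`.png`, `.tif` or `.tiff`).
#' @param bit_depth Intensity levels of the output (default 256).
#' @return Integer matrix.
#' @export
read_gray_image <- function(path, bit_depth = 256) {
  if (!file.exists(path))
    stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the 'tiff' package is required to read TIFF files")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext))
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  quantize_intensity(arr * (bit_depth - 1), bit_depth)
}

#' Write an 8-bit grayscale image
#'
#' @param image Integer matrix in `0 .. bit_depth - 1`.
#' @param path Output path (`.png`, `.tif` or `.tiff`).
#' @param bit_depth Intensity levels of the input scale.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path, bit_depth = 256) {
  assert_gray_image(image)
  norm <- image / (bit_depth - 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(norm, target = path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the 'tiff' package is required to write TIFF files")
      tiff::writeTIFF(norm, where = path)
    },
    stop("unsupported image format: .", ext))
  invisible(path)
}

#' Serialize / read scene ground truth as JSON
#'
#' The ground truth of a synthetic scene (particle positions, diameters,
#' velocities, the noise level and seed) is stored as JSON next to the
#' rendered channel images so downstream recovery tests can compare
#' estimates against it.
#'
#' @param scene A [flow_scene()].
#' @param path Output / input JSON path.
#' @return `write_scene_truth()`: `path` invisibly;
#'   `read_scene_truth()`: a `"flow_scene"`.
#' @export
write_scene_truth <- function(scene, path) {
  stopifnot(inherits(scene, "flow_scene"))
  particles <- lapply(scene$particles, unclass)
  payload <- list(particles = particles,
                  channel_width_um = scene$channel_width_um,
                  field_length_um = scene$field_length_um,
                  channel_depth_um = scene$channel_depth_um,
                  background_level = scene$background_level,
                  noise_sigma = scene$noise_sigma,
                  rng_seed = scene$rng_seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scene_truth
#' @export
read_scene_truth <- function(path) {
  if (!file.exists(path)) stop("truth file not found: ", path)
  d <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  parts <- lapply(d$particles, function(p)
    particle_spec(p$center_x_um, p$center_y_um, p$diameter_um,
                  p$velocity_mps, p$intensity))
  flow_scene(parts, channel_width_um = d$channel_width_um,
             field_length_um = d$field_length_um,
             channel_depth_um = d$channel_depth_um,
             background_level = d$background_level,
             noise_sigma = d$noise_sigma, rng_seed = d$rng_seed)
}

# Square crop around a centroid (0-based pixel-center coordinates),
# clamped to the image bounds.
crop_around <- function(image, centroid_row, centroid_col, crop_px) {
  nr <- nrow(image); nc <- ncol(image)
  r0 <- max(1L, as.integer(round(centroid_row + 0.5 - crop_px / 2)))
  c0 <- max(1L, as.integer(round(centroid_col + 0.5 - crop_px / 2)))
  r1 <- min(nr, r0 + crop_px - 1L); c1 <- min(nc, c0 + crop_px - 1L)
  image[r0:r1, c0:c1, drop = FALSE]
}
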