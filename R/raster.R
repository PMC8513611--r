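#' Multi-channel field image
#'
#' Container for a calibrated multi-channel 2D raster, e.g. a stitched and
#' background-corrected imaging field holding several colonies.
#'
#' @param raster Numeric array `[x, y, channel]` (a single-channel matrix is
#'   promoted to one channel). Values are arbitrary fluorescence units.
#' @param pixel_size Pixel size in micrometres per pixel (> 0).
#' @param channel_names Character vector naming the channels, e.g.
#'   `c("DAPI", "SOX2", "BRA")`.
#' @return An object of class `field_image`.
#' @export
field_image <- function(raster, pixel_size, channel_names) {
  if (is.matrix(raster)) dim(raster) <- c(dim(raster), 1L)
  stopifnot(length(dim(raster)) == 3L, pixel_size > 0,
            length(channel_names) == dim(raster)[3])
  dimnames(raster) <- list(NULL, NULL, channel_names)
  structure(list(raster = raster, pixel_size = pixel_size,
                 channel_names = channel_names),
            class = "field_image")
}

#' Extracted colony image
#'
#' A multi-channel crop of one detected colony, with the colony centre and
#' the analysis radius recorded in the crop coordinate frame.
#'
#' @param raster Numeric array `[x, y, channel]`.
#' @param center Numeric length-2, colony centre `(x, y)` in micrometres in
#'   the crop frame.
#' @param analysis_radius Radius (um) of the disc over which the colony is
#'   analysed; the crop must fully contain this disc.
#' @param pixel_size um/px.
#' @param channel_names Channel names.
#' @return An object of class `colony_image`.
#' @export
colony_image <- function(raster, center, analysis_radius, pixel_size,
                         channel_names) {
  if (is.matrix(raster)) dim(raster) <- c(dim(raster), 1L)
  stopifnot(length(dim(raster)) == 3L, length(center) == 2L,
            analysis_radius > 0, pixel_size > 0,
            length(channel_names) == dim(raster)[3])
  ext <- (dim(raster)[1:2] - 1) * pixel_size
  if (center[1] - analysis_radius < -pixel_size / 2 ||
      center[2] - analysis_radius < -pixel_size / 2 ||
      center[1] + analysis_radius > ext[1] + pixel_size / 2 ||
      center[2] + analysis_radius > ext[2] + pixel_size / 2)
    stop("crop does not contain the analysis disc")
  dimnames(raster) <- list(NULL, NULL, channel_names)
  structure(list(raster = raster, center = as.numeric(center),
                 analysis_radius = analysis_radius, pixel_size = pixel_size,
                 channel_names = channel_names),
            class = "colony_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$raster)
  cat(sprintf("field_image: %d x %d px (%.0f x %.0f um), %d channel(s): %s\n",
              d[1], d[2], d[1] * x$pixel_size, d[2] * x$pixel_size, d[3],
              paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' @export
print.colony_image <- function(x, ...) {
  d <- dim(x$raster)
  cat(sprintf(
    "colony_image: %d x %d px, center (%.1f, %.1f) um, analysis radius %.0f um, channels: %s\n",
    d[1], d[2], x$center[1], x$center[2], x$analysis_radius,
    paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

# pick one channel as a plain matrix
get_channel <- function(img, channel) {
  stopifnot(inherits(img, c("field_image", "colony_image")))
  if (is.character(channel)) {
    if (!channel %in% img$channel_names)
      stop(sprintf("channel '%s' not present (have: %s)", channel,
                   paste(img$channel_names, collapse = ", ")))
    channel <- match(channel, img$channel_names)
  }
  img$raster[, , channel]
}

#' Render anti-aliased nuclei onto a raster
#'
#' Draws each nucleus as a filled disc with one-pixel-wide anti-aliased edge,
#' on top of a constant background. Where discs overlap, the brighter value
#' wins (no additive blending), mimicking a thin epithelial monolayer.
#'
#' @param dim_px Integer length-2, raster dimensions `(nx, ny)` in pixels.
#' @param centers_um Two-column matrix of nucleus centres (um).
#' @param nucleus_radius Nucleus radius (um).
#' @param values Per-nucleus intensity (arbitrary units), recycled if scalar.
#' @param pixel_size um/px.
#' @param background Constant background level.
#' @return A numeric matrix `[x, y]`.
#' @export
render_nuclei <- function(dim_px, centers_um, nucleus_radius, values,
                          pixel_size = 1, background = 0) {
  r <- matrix(background, dim_px[1], dim_px[2])
  if (is.null(dim(centers_um))) centers_um <- matrix(centers_um, ncol = 2)
  n <- nrow(centers_um)
  if (n == 0L) return(r)
  values <- rep_len(values, n)
  rn <- nucleus_radius / pixel_size
  for (i in seq_len(n)) {
    cx <- centers_um[i, 1] / pixel_size + 1
    cy <- centers_um[i, 2] / pixel_size + 1
    ix <- max(1L, floor(cx - rn - 1)):min(dim_px[1], ceiling(cx + rn + 1))
    iy <- max(1L, floor(cy - rn - 1)):min(dim_px[2], ceiling(cy + rn + 1))
    if (!length(ix) || !length(iy)) next
    d <- sqrt(outer((ix - cx)^2, (iy - cy)^2, "+"))
    cov <- pmin(pmax(rn - d + 0.5, 0), 1)
    r[ix, iy] <- pmax(r[ix, iy], background + (values[i] - background) * cov)
  }
  r
}

add_pixel_noise <- function(m, sd) {
  if (sd <= 0) return(m)
  pmax(m + rnorm(length(m), 0, sd), 0)
}

#' Write / read a multi-channel field as TIFF plus JSON sidecar
#'
#' Channels are stored as 32-bit float TIFF pages; a `<path>.json` sidecar
#' records channel names and pixel size (the package's lightweight stand-in
#' for OME metadata).
#'
#' @param field A [field_image] or [colony_image].
#' @param path Output TIFF path.
#' @return `write_field_tiff` returns `path` invisibly; `read_field_tiff`
#'   returns a [field_image].
#' @export
write_field_tiff <- function(field, path) {
  sc <- max(1, max(field$raster))  # TIFF pages carry [0, 1]
  pages <- lapply(seq_along(field$channel_names),
                  function(k) t(field$raster[, , k]) / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(channel_names = field$channel_names,
               pixel_size_um = field$pixel_size, intensity_scale = sc)
  if (inherits(field, "colony_image")) {
    meta$center_um <- field$center
    meta$analysis_radius_um <- field$analysis_radius
  }
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_field_tiff
#' @param pixel_size,channel_names Used when no JSON sidecar is found.
#' @export
read_field_tiff <- function(path, pixel_size = NULL, channel_names = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".json")
  sc <- 1
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    pixel_size <- pixel_size %||% meta$pixel_size_um
    channel_names <- channel_names %||% meta$channel_names
    sc <- meta$intensity_scale %||% 1
  }
  if (is.null(pixel_size)) stop("pixel_size unknown: no sidecar, none given")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_along(pages))
  arr <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]]) * sc
  field_image(arr, pixel_size, channel_names)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
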