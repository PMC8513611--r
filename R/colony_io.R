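#' Stitch an overlapping tile grid into one field
#'
#' Reassembles a complete rectangular grid of tiles (e.g. from [tile_field()]
#' or from files) into a single [field_image]. Overlapping strips are blended
#' by linear feathering: each tile's contribution is weighted by its distance
#' to its own border, so seams fade linearly across the overlap.
#'
#' @param tiles List of [field_image] tiles, row-major.
#' @param grid Data frame with columns `row`, `col`, `x0`, `y0` (pixel
#'   offsets of each tile's top-left corner), as produced by [tile_field()].
#' @return A [field_image].
#' @export
stitch_tiles <- function(tiles, grid) {
  if (!nrow(grid)) stop("empty grid")
  nr <- max(grid$row); ncg <- max(grid$col)
  want <- expand.grid(row = seq_len(nr), col = seq_len(ncg))
  have <- paste(grid$row, grid$col)
  miss <- !paste(want$row, want$col) %in% have
  if (any(miss))
    stop("missing tile at grid slot (row, col): ",
         paste(sprintf("(%d, %d)", want$row[miss], want$col[miss]),
               collapse = ", "))
  d1 <- dim(tiles[[1]]$raster)
  if (!all(vapply(tiles, function(t) identical(dim(t$raster), d1), logical(1))))
    stop("inconsistent tile shapes")
  if (length(tiles) == 1L) return(tiles[[1]])
  D <- c(max(grid$x0) + d1[1], max(grid$y0) + d1[2], d1[3])
  acc <- array(0, D)
  wacc <- matrix(0, D[1], D[2])
  # feather weight: distance to the nearest tile border (in px), >= 1
  wx <- pmin(seq_len(d1[1]), rev(seq_len(d1[1])))
  wy <- pmin(seq_len(d1[2]), rev(seq_len(d1[2])))
  w <- outer(wx, wy, pmin)
  for (k in seq_along(tiles)) {
    ix <- grid$x0[k] + seq_len(d1[1])
    iy <- grid$y0[k] + seq_len(d1[2])
    wacc[ix, iy] <- wacc[ix, iy] + w
    for (ch in seq_len(d1[3]))
      acc[ix, iy, ch] <- acc[ix, iy, ch] + tiles[[k]]$raster[, , ch] * w
  }
  for (ch in seq_len(D[3])) acc[, , ch] <- acc[, , ch] / wacc
  field_image(acc, tiles[[1]]$pixel_size, tiles[[1]]$channel_names)
}

#' Subtract a smooth background estimate
#'
#' Estimates the background of each channel by morphological opening with a
#' disc of diameter `window` (which must be well above the nucleus scale so
#' nuclei are removed, and below the colony scale so real structure is kept),
#' subtracts it, and clips at 0. A flat field maps to ~0.
#'
#' @param field A [field_image] or [colony_image].
#' @param window Opening window (um).
#' @param nucleus_radius Expected nucleus radius (um); windows below 4x this
#'   (two nucleus diameters) are rejected because they would erase nuclei.
#' @param colony_radius Optional expected colony radius (um); windows above
#'   one colony diameter are rejected.
#' @return Object of the same class with corrected raster.
#' @export
correct_background <- function(field, window = 50, nucleus_radius = 5,
                               colony_radius = NULL) {
  if (window < 4 * nucleus_radius)
    stop("window smaller than two nucleus diameters would erase nuclei")
  if (!is.null(colony_radius) && window > 2 * colony_radius)
    stop("window larger than one colony diameter")
  wpx <- max(3L, round(window / field$pixel_size))
  if (wpx %% 2L == 0L) wpx <- wpx + 1L
  brush <- EBImage::makeBrush(wpx, "disc")
  out <- field
  for (ch in seq_len(dim(field$raster)[3])) {
    bg <- EBImage::opening(field$raster[, , ch], brush)
    out$raster[, , ch] <- pmax(field$raster[, , ch] - bg, 0)
  }
  out
}

#' Detect colonies in a field
#'
#' Thresholds a heavily smoothed DAPI channel (Otsu), closes the foreground
#' with a disc of radius `expected_radius / 5` to obtain solid colony
#' footprints, and returns one region per connected component whose area lies
#' within `[0.25, 4]` times the expected disc area. Centres are footprint
#' centroids in micrometres.
#'
#' @param field A [field_image] with a DAPI channel.
#' @param expected_radius Expected colony radius (um).
#' @param dapi Name of the DAPI channel.
#' @param nucleus_radius Smoothing scale (um) for the foreground mask.
#' @return List of `colony_region` objects: `center` (um), `effective_radius`
#'   (um, radius of the equal-area disc), `area_um2`, `footprint` (polygon,
#'   px coords), `circularity`, `status` (`"detected"`).
#' @export
detect_colonies <- function(field, expected_radius, dapi = "DAPI",
                            nucleus_radius = 5) {
  v <- get_channel(field, dapi)
  px <- field$pixel_size
  sm <- EBImage::gblur(v, sigma = max(1, nucleus_radius / px))
  th <- otsu_threshold(as.numeric(sm))
  fg <- sm > th
  if (!any(fg)) return(list())
  alpha_px <- max(3L, 2L * round(expected_radius / 5 / px) + 1L)
  fg <- EBImage::closing(fg, EBImage::makeBrush(alpha_px, "disc"))
  fg <- EBImage::fillHull(fg)
  lab <- EBImage::bwlabel(fg)
  nlab <- max(lab)
  if (nlab == 0L) return(list())
  feats <- EBImage::computeFeatures.shape(lab)
  mom <- EBImage::computeFeatures.moment(lab)
  disc_area_px <- pi * (expected_radius / px)^2
  regions <- list()
  contours <- EBImage::ocontour(lab)
  for (i in seq_len(nlab)) {
    a <- feats[i, "s.area"]
    if (a < 0.25 * disc_area_px || a > 4 * disc_area_px) next
    per <- feats[i, "s.perimeter"]
    regions[[length(regions) + 1L]] <- structure(list(
      center = c(mom[i, "m.cx"] - 1, mom[i, "m.cy"] - 1) * px,
      area_um2 = a * px^2,
      effective_radius = sqrt(a / pi) * px,
      circularity = min(1, 4 * pi * a / per^2),
      footprint = contours[[i]],
      label = i, status = "detected", reason = NA_character_),
      class = "colony_region")
  }
  regions
}

#' Filter detected colonies by size and shape
#'
#' Applies the exclusion rule for merged or poorly isolated colonies:
#' regions with area above `1.5x` or below `0.5x` the expected disc area, or
#' circularity (`4 pi area / perimeter^2`) below `min_circularity`, are
#' rejected with an explicit reason; the rest are accepted.
#'
#' @param regions List of `colony_region` from [detect_colonies()].
#' @param expected_radius Expected colony radius (um).
#' @param min_circularity Circularity cut (default 0.8).
#' @return The same list with `status` set to `"accepted"` or `"rejected"`
#'   and `reason` filled for rejections.
#' @export
filter_colonies <- function(regions, expected_radius, min_circularity = 0.8) {
  disc_area <- pi * expected_radius^2
  lapply(regions, function(rg) {
    reason <- NULL
    if (rg$area_um2 > 1.5 * disc_area) reason <- c(reason, "area too large (merged?)")
    if (rg$area_um2 < 0.5 * disc_area) reason <- c(reason, "area too small")
    if (rg$circularity < min_circularity) reason <- c(reason, "low circularity")
    if (is.null(reason)) {
      rg$status <- "accepted"
    } else {
      rg$status <- "rejected"
      rg$reason <- paste(reason, collapse = "; ")
    }
    rg
  })
}

#' Extract a colony crop from a field
#'
#' Cuts a square crop centred on an accepted region's centre, with side
#' `2 * (analysis_radius + margin)`, and records the colony centre in crop
#' coordinates.
#'
#' @param field A [field_image].
#' @param region An accepted `colony_region`.
#' @param analysis_radius Analysis radius (um), e.g. 250.
#' @param margin Extra margin (um).
#' @return A [colony_image].
#' @export
extract_colony <- function(field, region, analysis_radius, margin = 10) {
  if (!identical(region$status, "accepted") &&
      !identical(region$status, "detected"))
    stop("region not accepted: ", region$reason)
  px <- field$pixel_size
  half <- analysis_radius + margin
  cpx <- region$center / px + 1  # pixel coords
  ix0 <- round(cpx[1] - half / px); ix1 <- round(cpx[1] + half / px)
  iy0 <- round(cpx[2] - half / px); iy1 <- round(cpx[2] + half / px)
  d <- dim(field$raster)
  if (ix0 < 1 || iy0 < 1 || ix1 > d[1] || iy1 > d[2])
    stop("crop exceeds field bounds")
  sub <- field$raster[ix0:ix1, iy0:iy1, , drop = FALSE]
  center <- region$center - c(ix0 - 1, iy0 - 1) * px
  colony_image(sub, center, analysis_radius, px, field$channel_names)
}

#' @export
print.colony_region <- function(x, ...) {
  cat(sprintf(
    "colony_region: center (%.1f, %.1f) um, r_eff %.1f um, circ %.2f, %s%s\n",
    x$center[1], x$center[2], x$effective_radius, x$circularity, x$status,
    if (!is.na(x$reason)) paste0(" (", x$reason, ")") else ""))
  invisible(x)
}

#' Summarize detected colonies as a manifest table
#'
#' @param regions List of `colony_region`.
#' @return Data frame (id, center_x_um, center_y_um, radius_um, circularity,
#'   status, reason).
#' @export
colony_manifest <- function(regions) {
  if (!length(regions))
    return(data.frame(id = integer(0), center_x_um = numeric(0),
                      center_y_um = numeric(0), radius_um = numeric(0),
                      circularity = numeric(0), status = character(0),
                      reason = character(0)))
  data.frame(
    id = seq_along(regions),
    center_x_um = vapply(regions, function(r) r$center[1], numeric(1)),
    center_y_um = vapply(regions, function(r) r$center[2], numeric(1)),
    radius_um = vapply(regions, function(r) r$effective_radius, numeric(1)),
    circularity = vapply(regions, function(r) r$circularity, numeric(1)),
    status = vapply(regions, function(r) r$status, character(1)),
    reason = vapply(regions, function(r) r$reason, character(1)))
}
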