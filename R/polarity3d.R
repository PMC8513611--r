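# per-lateral-position intensity centroid along z, after per-profile
# background subtraction (10th percentile, clipped at 0); returns the
# centroid heights and the background-subtracted profile totals
z_centroid <- function(arr, z_step) {
  d <- dim(arr)
  M <- matrix(arr, d[1] * d[2], d[3])
  bg <- apply(M, 1, quantile, probs = 0.1, names = FALSE)
  M <- pmax(M - bg, 0)
  tot <- rowSums(M)
  zs <- (seq_len(d[3]) - 1) * z_step
  zc <- as.numeric(M %*% zs) / tot
  list(z = matrix(zc, d[1], d[2]), total = matrix(tot, d[1], d[2]))
}

# fill NA entries by iterative 4-neighbour averaging of known values
fill_holes_2d <- function(m) {
  while (anyNA(m)) {
    na <- which(is.na(m), arr.ind = TRUE)
    nx <- nrow(m); ny <- ncol(m)
    filled <- FALSE
    for (k in seq_len(nrow(na))) {
      i <- na[k, 1]; j <- na[k, 2]
      nb <- c(if (i > 1) m[i - 1, j], if (i < nx) m[i + 1, j],
              if (j > 1) m[i, j - 1], if (j < ny) m[i, j + 1])
      nb <- nb[!is.na(nb)]
      if (length(nb)) { m[i, j] <- mean(nb); filled <- TRUE }
    }
    if (!filled) stop("cannot fill surface: no valid neighbours")
  }
  m
}

#' Interpolate the apical surface from a ZO-1 z-stack channel
#'
#' Per lateral position, the surface height is the intensity-weighted mean z
#' (centroid) of the background-subtracted ZO-1 profile. Positions whose
#' total ZO-1 signal falls below a noise floor (default: 20% of the median
#' profile total) are masked invalid and filled by smooth interpolation from
#' their neighbours; the whole height map is then smoothed laterally
#' (Gaussian, `smooth` um).
#'
#' @param stack A `zstack_image` (from [generate_zstack()] or
#'   [read_stack_tiff()]).
#' @param channel ZO-1 channel name.
#' @param noise_floor Absolute total-intensity floor; `NULL` for the
#'   automatic fraction-of-median rule.
#' @param smooth Lateral smoothing sigma (um).
#' @return An `apical_surface`: `z_um` (height matrix, um), `valid` (logical
#'   matrix), `z_step`, `pixel_size`.
#' @export
interpolate_apical_surface <- function(stack, channel = "ZO1",
                                       noise_floor = NULL, smooth = 2) {
  stopifnot(inherits(stack, "zstack_image"))
  arr <- stack$channels[[channel]]
  if (is.null(arr)) stop("channel not present: ", channel)
  if (dim(arr)[3] < 5L) stop("need at least 5 z planes")
  zc <- z_centroid(arr, stack$z_step)
  floor_ <- noise_floor %||% (0.2 * median(zc$total))
  valid <- zc$total > floor_ & is.finite(zc$z)
  if (!any(valid)) stop("no apical surface: stack below noise floor")
  h <- zc$z
  h[!valid] <- NA_real_
  h <- fill_holes_2d(h)
  sig <- smooth / stack$pixel_size
  if (sig > 0) h <- EBImage::gblur(h, sigma = sig)
  z_max <- (dim(arr)[3] - 1L) * stack$z_step
  h <- pmin(pmax(h, 0), z_max)
  structure(list(z_um = h, valid = valid, z_step = stack$z_step,
                 pixel_size = stack$pixel_size),
            class = "apical_surface")
}

#' Signed distance of a channel to the apical surface
#'
#' Per valid lateral position, the channel's depth is its intensity-weighted
#' mean z; the signed distance is `depth - surface height`, so positive
#' distances lie basal (below) to the apical plane and negative ones apical
#' (above) of it.
#'
#' @param stack A `zstack_image`.
#' @param channel Channel name.
#' @param surface An `apical_surface` from the same stack geometry.
#' @param min_total Positions whose background-subtracted channel total is
#'   below this fraction of the median are skipped.
#' @return A `polarity_distribution`: `distance_um` (vector over valid
#'   positions), `median`, `q1`, `q3`, `n`. The median and quartiles are
#'   `NA` when fewer than 100 valid positions remain.
#' @export
distance_to_apical <- function(stack, channel, surface, min_total = 0.1) {
  stopifnot(inherits(stack, "zstack_image"),
            inherits(surface, "apical_surface"))
  arr <- stack$channels[[channel]]
  if (is.null(arr)) stop("channel not present: ", channel)
  if (!identical(dim(arr)[1:2], dim(surface$z_um)))
    stop("surface does not match stack geometry")
  zc <- z_centroid(arr, stack$z_step)
  if (max(zc$total) <= 0) stop("channel is all background")
  ok <- surface$valid & is.finite(zc$z) &
    zc$total > min_total * median(zc$total)
  if (!any(ok)) stop("channel is all background")
  dist <- (zc$z - surface$z_um)[ok]
  n <- length(dist)
  qs <- if (n >= 100L) quantile(dist, c(0.25, 0.5, 0.75), names = FALSE)
        else rep(NA_real_, 3L)
  structure(list(distance_um = dist, median = qs[2], q1 = qs[1], q3 = qs[3],
                 n = n),
            class = "polarity_distribution")
}

#' Tabulate polarity distributions across conditions
#'
#' @param dists Named list of `polarity_distribution` objects; names are the
#'   condition labels and input order is preserved.
#' @return Data frame (condition, median_um, q1_um, q3_um, n). No inference
#'   is performed; see [compare_groups()].
#' @export
compare_polarity <- function(dists) {
  stopifnot(length(dists) >= 2L, !is.null(names(dists)))
  data.frame(condition = names(dists),
             median_um = vapply(dists, function(d) d$median, numeric(1)),
             q1_um = vapply(dists, function(d) d$q1, numeric(1)),
             q3_um = vapply(dists, function(d) d$q3, numeric(1)),
             n = vapply(dists, function(d) d$n, numeric(1)),
             row.names = NULL)
}

#' Write / read a z-stack or time series as TIFF plus JSON sidecar
#'
#' Pages are ordered channel-major then z; the sidecar records channel
#' names, z geometry and pixel size.
#'
#' @param stack A `zstack_image`.
#' @param path Output TIFF path.
#' @export
write_stack_tiff <- function(stack, path) {
  sc <- max(1, vapply(stack$channels, max, numeric(1)))  # pages carry [0, 1]
  pages <- list()
  for (nm in stack$channel_names) {
    arr <- stack$channels[[nm]]
    for (k in seq_len(dim(arr)[3]))
      pages[[length(pages) + 1L]] <- t(arr[, , k]) / sc
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(channel_names = stack$channel_names,
         z_planes = dim(stack$channels[[1]])[3],
         z_step_um = stack$z_step, pixel_size_um = stack$pixel_size,
         intensity_scale = sc),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- meta$z_planes
  sc <- meta$intensity_scale %||% 1
  channels <- list()
  for (ci in seq_along(meta$channel_names)) {
    arr <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), nz))
    for (k in seq_len(nz)) arr[, , k] <- t(pages[[(ci - 1L) * nz + k]]) * sc
    channels[[meta$channel_names[ci]]] <- arr
  }
  structure(list(channels = channels, z_step = meta$z_step_um,
                 pixel_size = meta$pixel_size_um,
                 channel_names = meta$channel_names),
            class = "zstack_image")
}
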