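# Laplacian-of-Gaussian kernel, zero-sum, sign flipped so bright blobs of
# radius ~ sigma*sqrt(2) give positive peaks
log_kernel <- function(sigma) {
  half <- max(2L, ceiling(3 * sigma))
  xs <- -half:half
  g <- outer(xs, xs, function(x, y) {
    r2 <- x^2 + y^2
    (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  })
  k <- -g
  k - mean(k)
}

#' Find nucleus seed points in a DAPI image
#'
#' Band-pass blob detection at the nucleus scale: the image is convolved
#' with a Laplacian-of-Gaussian kernel (`sigma = nucleus_radius / sqrt(2)`,
#' the matched scale for a disc of that radius), and seeds are local maxima
#' of the response above an Otsu cut on the response, with a minimum
#' separation of `1.5 * nucleus_radius`.
#'
#' @param dapi Single-channel matrix `[x, y]`.
#' @param nucleus_radius Expected nucleus radius (um).
#' @param pixel_size um/px.
#' @return Two-column matrix of seed coordinates (um); zero rows if the
#'   image is blank.
#' @export
find_nucleus_seeds <- function(dapi, nucleus_radius, pixel_size = 1) {
  rn <- nucleus_radius / pixel_size
  if (rn <= 2) stop("nucleus_radius must exceed 2 px at this pixel size")
  resp <- EBImage::filter2(dapi, log_kernel(rn / sqrt(2)))
  if (diff(range(resp)) < .Machine$double.eps)
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  cut <- otsu_threshold(as.numeric(resp))
  minsep <- 1.5 * rn
  bw <- max(3L, 2L * floor(minsep / 2) + 1L)
  mx <- EBImage::dilate(resp, EBImage::makeBrush(bw, "disc"))
  cand <- which(resp >= mx & resp > cut, arr.ind = TRUE)
  if (!nrow(cand))
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  v <- resp[cand]
  o <- order(v, decreasing = TRUE)
  cand <- cand[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  # greedy minimum-separation enforcement (plateaus yield duplicates)
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1L):nrow(cand)
      d2 <- (cand[j, 1] - cand[i, 1])^2 + (cand[j, 2] - cand[i, 2])^2
      keep[j][d2 < minsep^2] <- FALSE
    }
  }
  pts <- cand[keep, , drop = FALSE]
  out <- cbind(x = (pts[, 1] - 1) * pixel_size,
               y = (pts[, 2] - 1) * pixel_size)
  out
}

#' Segment nuclei by seeded watershed
#'
#' Region growing from the given seeds over the smoothed DAPI landscape
#' (EBImage's `propagate`, a seeded watershed on the image manifold),
#' intersected with a foreground mask obtained by Otsu thresholding of the
#' smoothed DAPI. Seeds falling outside the foreground produce empty
#' regions and are dropped with a message.
#'
#' @param dapi Single-channel matrix `[x, y]`.
#' @param seeds Seed coordinates (um), as from [find_nucleus_seeds()].
#' @param nucleus_radius Nucleus radius (um), sets the smoothing scale.
#' @param pixel_size um/px.
#' @return Integer label matrix; label `k` is the region grown from seed
#'   row `k` (labels of dropped seeds are absent).
#' @export
segment_nuclei <- function(dapi, seeds, nucleus_radius, pixel_size = 1) {
  if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 2)
  if (!nrow(seeds)) stop("need at least one seed")
  rn <- nucleus_radius / pixel_size
  sm <- EBImage::gblur(dapi, sigma = max(1, rn / 2))
  # foreground from the raw image: smoothing before thresholding dilates
  # nuclei by roughly the smoothing scale and inflates areas
  fg <- dapi > otsu_threshold(as.numeric(dapi))
  seed_img <- matrix(0L, nrow(dapi), ncol(dapi))
  ix <- pmin(pmax(round(seeds[, 1] / pixel_size) + 1L, 1L), nrow(dapi))
  iy <- pmin(pmax(round(seeds[, 2] / pixel_size) + 1L, 1L), ncol(dapi))
  seed_img[cbind(ix, iy)] <- seq_len(nrow(seeds))
  lab <- EBImage::propagate(sm, seed_img, mask = fg)
  lab <- matrix(as.integer(lab), nrow(dapi), ncol(dapi))
  present <- sort(unique(lab[lab > 0L]))
  dropped <- setdiff(seq_len(nrow(seeds)), present)
  if (length(dropped))
    message(length(dropped), " seed(s) outside foreground dropped: ",
            paste(head(dropped, 10L), collapse = ", "))
  lab
}

#' Extract the per-cell table from a label map
#'
#' One row per nucleus: centroid (um, crop frame), area (um^2), radial
#' distance of the centroid from the colony centre, and the median intensity
#' for every channel. Medians are taken over the label's 1-px-eroded core:
#' boundary pixels carry anti-aliased rims and bleed-over from adjacent
#' nuclei, and excluding them keeps the per-cell intensities clean. Labels
#' too small to erode fall back to all their pixels.
#'
#' @param labels Integer label matrix aligned to `colony$raster`.
#' @param colony A [colony_image].
#' @return A `cell_table`: data frame with columns `id`, `x_um`, `y_um`,
#'   `radial_um`, `area_um2` and `median_<channel>`; colony centre, analysis
#'   radius and pixel size kept as attributes.
#' @export
extract_cell_table <- function(labels, colony) {
  stopifnot(inherits(colony, "colony_image"))
  d <- dim(colony$raster)
  if (!identical(dim(labels), d[1:2]))
    stop("label map does not match colony raster dimensions")
  px <- colony$pixel_size
  idx <- which(labels > 0L)
  if (!length(idx)) stop("empty label map")
  lab <- labels[idx]
  groups <- split(idx, lab)
  ids <- as.integer(names(groups))
  nxp <- d[1]
  cx <- vapply(groups, function(ii) mean((ii - 1L) %% nxp), numeric(1))
  cy <- vapply(groups, function(ii) mean((ii - 1L) %/% nxp), numeric(1))
  area <- lengths(groups) * px^2
  tab <- data.frame(id = ids, x_um = cx * px, y_um = cy * px,
                    area_um2 = as.numeric(area))
  tab$radial_um <- sqrt((tab$x_um - colony$center[1])^2 +
                        (tab$y_um - colony$center[2])^2)
  # per-label 1-px erosion: a pixel is core if its 4-neighbours share its
  # label (handles touching labels, which a mask erosion would not)
  pad <- matrix(0L, d[1] + 2L, d[2] + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- labels
  ctr <- pad[2:(d[1] + 1L), 2:(d[2] + 1L)]
  core <- ctr > 0L &
    pad[1:d[1], 2:(d[2] + 1L)] == ctr &
    pad[3:(d[1] + 2L), 2:(d[2] + 1L)] == ctr &
    pad[2:(d[1] + 1L), 1:d[2]] == ctr &
    pad[2:(d[1] + 1L), 3:(d[2] + 2L)] == ctr
  core_idx <- which(core)
  has_core <- ids %in% unique(labels[core_idx])
  med_idx <- c(core_idx, idx[!lab %in% ids[has_core]])
  med_lab <- labels[med_idx]
  for (k in seq_len(d[3])) {
    v <- colony$raster[, , k][med_idx]
    tab[[paste0("median_", colony$channel_names[k])]] <-
      vapply(split(v, med_lab), median, numeric(1))
  }
  attr(tab, "center_um") <- colony$center
  attr(tab, "analysis_radius") <- colony$analysis_radius
  attr(tab, "pixel_size") <- px
  class(tab) <- c("cell_table", "data.frame")
  tab
}

#' Segment a colony end to end
#'
#' Convenience wrapper: seeds, watershed and cell-table extraction on a
#' colony's DAPI channel.
#'
#' @param colony A [colony_image].
#' @param nucleus_radius Nucleus radius (um).
#' @param dapi DAPI channel name.
#' @return A `cell_table`.
#' @export
segment_colony_cells <- function(colony, nucleus_radius = 5, dapi = "DAPI") {
  v <- get_channel(colony, dapi)
  seeds <- find_nucleus_seeds(v, nucleus_radius, colony$pixel_size)
  if (!nrow(seeds)) stop("no nuclei detected")
  lab <- segment_nuclei(v, seeds, nucleus_radius, colony$pixel_size)
  extract_cell_table(lab, colony)
}
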