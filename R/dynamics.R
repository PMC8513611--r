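#' Maximum-intensity projection along z
#'
#' @param x A 3D array `[x, y, z]`, or a list of such arrays (one per
#'   frame).
#' @return A matrix, or a list of matrices for list input; single-plane
#'   input is returned unchanged.
#' @export
max_project <- function(x) {
  if (is.list(x)) return(lapply(x, max_project))
  if (is.matrix(x)) return(x)
  stopifnot(length(dim(x)) == 3L)
  apply(x, c(1, 2), max)
}

#' Reporter-positive radius over a time-lapse
#'
#' Per frame, reporter-high pixels are isolated by the upper cut of a
#' three-region Otsu split of the frame histogram (background,
#' reporter-negative nuclei, reporter-positive nuclei), the mask occupancy
#' is profiled radially (pixel mode), and the
#' domain radius is the outermost half-max crossing of the occupancy
#' profile, linearly interpolated between bin centres. Frames with no
#' foreground get radius 0 and a flag.
#'
#' @param series Time-lapse as returned by [generate_timelapse()], or a list
#'   of frames with `center_um`, `pixel_size`, `analysis_radius` given
#'   explicitly.
#' @param reporter Reporter channel name.
#' @param center,pixel_size,analysis_radius Geometry; defaults from the
#'   series object.
#' @param bin_width Radial bin width (um).
#' @param t0_frame Frame index of stimulation (time 0).
#' @param frame_interval Minutes between frames; default from the series.
#' @return A `radius_trace` data frame: `frame`, `time_h` (hours since
#'   `t0_frame`), `radius_um`, `no_signal`.
#' @export
reporter_radius_trace <- function(series, reporter = "SOX2", center = NULL,
                                  pixel_size = NULL, analysis_radius = NULL,
                                  bin_width = 5, t0_frame = 1L,
                                  frame_interval = NULL) {
  frames <- if (is.list(series) && !is.null(series$frames)) series$frames
            else series
  if (length(frames) < 3L) stop("need at least 3 frames")
  center <- center %||% series$center_um
  pixel_size <- pixel_size %||% series$pixel_size
  analysis_radius <- analysis_radius %||% series$analysis_radius
  frame_interval <- frame_interval %||% series$frame_interval %||% 30
  radii <- numeric(length(frames))
  flag <- logical(length(frames))
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    v <- if (length(dim(fr)) == 3L) {
      k <- match(reporter, dimnames(fr)[[3]])
      if (is.na(k)) stop("reporter channel not found in frame ", f)
      fr[, , k]
    } else fr
    # blank-frame guard: a frame with no foreground has negligible
    # contrast between its bright tail and its median
    qs <- quantile(v, c(0.5, 0.99), names = FALSE)
    if (sum(qs) <= 0 || (qs[2] - qs[1]) / sum(qs) < 0.3) {
      radii[f] <- 0; flag[f] <- TRUE; next
    }
    # reporter-high mask: upper class of the three-region histogram
    # (background | reporter-negative nuclei | reporter-positive nuclei)
    mask <- v > multi_otsu3(as.numeric(v))[2]
    if (!any(mask)) { radii[f] <- 0; flag[f] <- TRUE; next }
    prof <- radial_profile(mask + 0, center = center,
                           analysis_radius = analysis_radius,
                           bin_width = bin_width, pixel_size = pixel_size)
    radii[f] <- outer_half_max_radius(prof, analysis_radius)
  }
  out <- data.frame(frame = seq_along(frames),
                    time_h = (seq_along(frames) - t0_frame) *
                      frame_interval / 60,
                    radius_um = radii, no_signal = flag)
  class(out) <- c("radius_trace", "data.frame")
  out
}

# outermost half-max crossing: scanning inward from the colony edge, find
# the first bin above half of the profile range, interpolate to the next
# outer bin; a profile above half-max everywhere returns analysis_radius
outer_half_max_radius <- function(prof, analysis_radius) {
  ok <- is.finite(prof$mean)
  bc <- prof$bin_center_um[ok]; mu <- prof$mean[ok]
  half <- (min(mu) + max(mu)) / 2
  above <- mu > half
  if (!any(above)) return(0)
  i <- max(which(above))  # outermost bin above half
  if (i == length(mu)) return(analysis_radius)
  bc[i] + (bc[i + 1L] - bc[i]) * (mu[i] - half) / (mu[i] - mu[i + 1L])
}

#' Nuclear-to-cytoplasmic reporter traces
#'
#' Per frame, nuclei are segmented from the nuclear-marker channel (LoG
#' seeds + seeded watershed); the nuclear mean is the reporter mean over the
#' 1-px-eroded nuclear mask and the cytoplasmic mean over a 2-px-wide ring
#' outside the nucleus excluding all other nuclei. Cells are tracked across
#' frames by nearest-centroid linking with a maximum step of `max_step` um
#' per frame; lost tracks are truncated.
#'
#' @param series Time-lapse as from [generate_timelapse()], or a list of
#'   `[x, y, channel]` frame arrays.
#' @param reporter,nuclear Channel names.
#' @param nucleus_radius Nucleus radius (um).
#' @param pixel_size um/px; default from the series.
#' @param max_step Maximum tracking step (um/frame).
#' @param t0_frame,frame_interval Timing as in [reporter_radius_trace()].
#' @return An `nc_trace` data frame: `cell`, `frame`, `time_h`, `x_um`,
#'   `y_um`, `nuclear`, `cytoplasmic`, `nc_ratio`.
#' @export
nc_ratio_trace <- function(series, reporter = "SOX2", nuclear = "H2B",
                           nucleus_radius = 5, pixel_size = NULL,
                           max_step = 10, t0_frame = 1L,
                           frame_interval = NULL) {
  frames <- if (is.list(series) && !is.null(series$frames)) series$frames
            else series
  pixel_size <- pixel_size %||% series$pixel_size %||% 1
  frame_interval <- frame_interval %||% series$frame_interval %||% 30
  per_frame <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    cn <- dimnames(fr)[[3]]
    vn <- fr[, , match(nuclear, cn)]
    vr <- fr[, , match(reporter, cn)]
    seeds <- find_nucleus_seeds(vn, nucleus_radius, pixel_size)
    if (!nrow(seeds)) next
    lab <- segment_nuclei(vn, seeds, nucleus_radius, pixel_size)
    mask <- lab > 0L
    er <- EBImage::erode(mask, EBImage::makeBrush(3L, "box"))
    core <- lab; core[!er] <- 0L
    ring_lab <- EBImage::dilate(lab, EBImage::makeBrush(5L, "disc"))
    ring_lab[mask] <- 0L
    stats_one <- function(l) {
      idx <- which(l > 0L)
      if (!length(idx)) return(NULL)
      g <- split(vr[idx], l[idx])
      data.frame(id = as.integer(names(g)),
                 mean = vapply(g, mean, numeric(1)))
    }
    nucm <- stats_one(core)
    cytm <- stats_one(ring_lab)
    if (is.null(nucm) || is.null(cytm)) next
    idx <- which(lab > 0L)
    gl <- split(idx, lab[idx])
    nxp <- nrow(vn)
    cen <- data.frame(
      id = as.integer(names(gl)),
      x_um = vapply(gl, function(ii) mean((ii - 1L) %% nxp), numeric(1)) *
        pixel_size,
      y_um = vapply(gl, function(ii) mean((ii - 1L) %/% nxp), numeric(1)) *
        pixel_size)
    m <- merge(merge(cen, nucm, by = "id"), cytm, by = "id",
               suffixes = c("_nuc", "_cyt"))
    m <- m[m$mean_cyt > 0, , drop = FALSE]  # empty/zero ring: skip cell
    m$nc <- m$mean_nuc / m$mean_cyt
    per_frame[[f]] <- m
  }
  # nearest-centroid linking
  traces <- NULL
  active <- NULL  # data.frame: cell, x, y
  next_cell <- 1L
  for (f in seq_along(frames)) {
    m <- per_frame[[f]]
    if (is.null(m) || !nrow(m)) { active <- NULL; next }
    assigned <- rep(NA_integer_, nrow(m))
    if (!is.null(active) && nrow(active)) {
      D <- outer(active$x, m$x_um, "-")^2 + outer(active$y, m$y_um, "-")^2
      ord <- order(D)
      used_a <- logical(nrow(active)); used_m <- logical(nrow(m))
      for (k in ord) {
        if (sqrt(D[k]) > max_step) break
        ai <- (k - 1L) %% nrow(active) + 1L
        mi <- (k - 1L) %/% nrow(active) + 1L
        if (used_a[ai] || used_m[mi]) next
        used_a[ai] <- TRUE; used_m[mi] <- TRUE
        assigned[mi] <- active$cell[ai]
      }
    }
    new_ids <- which(is.na(assigned))
    if (length(new_ids)) {
      assigned[new_ids] <- next_cell + seq_along(new_ids) - 1L
      next_cell <- next_cell + length(new_ids)
    }
    traces <- rbind(traces, data.frame(
      cell = assigned, frame = f,
      time_h = (f - t0_frame) * frame_interval / 60,
      x_um = m$x_um, y_um = m$y_um,
      nuclear = m$mean_nuc, cytoplasmic = m$mean_cyt, nc_ratio = m$nc))
    active <- data.frame(cell = assigned, x = m$x_um, y = m$y_um)
  }
  if (is.null(traces)) stop("no cells segmented in any frame")
  class(traces) <- c("nc_trace", "data.frame")
  traces
}

#' Cohort summary of N:C traces
#'
#' Frame-aligned mean, sd and cell count of the N:C ratio over all cells
#' present in each frame.
#'
#' @param traces An `nc_trace` data frame.
#' @return Data frame (frame, time_h, mean, sd, n).
#' @export
summarize_nc_cohort <- function(traces) {
  stopifnot(nrow(traces) >= 1L)
  g <- split(traces$nc_ratio, traces$frame)
  fr <- as.integer(names(g))
  th <- vapply(split(traces$time_h, traces$frame), `[`, numeric(1), 1L)
  data.frame(frame = fr, time_h = th,
             mean = vapply(g, mean, numeric(1)),
             sd = vapply(g, function(v) if (length(v) > 1) sd(v) else NA_real_,
                         numeric(1)),
             n = lengths(g), row.names = NULL)
}
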