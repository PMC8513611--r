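#' Scene specification for synthetic colony images
#'
#' Parameterizes a synthetic micropatterned colony: geometry, nuclear packing,
#' per-channel spatial rules and the intensity model. All lengths are in
#' micrometres; rasters are rendered at `pixel_size` um/px. A DAPI channel is
#' always generated; further channels are given as named `channel_models`.
#'
#' Default packing density (3700 nuclei/mm^2) emulates a dense pluripotent
#' epithelium and yields roughly 730 nuclei on a 500 um diameter colony.
#'
#' @param pixel_size um per pixel.
#' @param colony_radius Colony radius (um).
#' @param n_nuclei Number of nuclei; alternatively give `density`.
#' @param density Nuclei per mm^2 (used when `n_nuclei` is `NULL`).
#' @param nucleus_radius Nucleus radius (um). Nuclei are placed with minimum
#'   centre separation `1.6 * nucleus_radius`.
#' @param channel_models Named list of spatial rules built with
#'   [chan_uniform()], [chan_central_disc()], [chan_ring()],
#'   [chan_edge_band()], [chan_mixture()], [chan_secretor()],
#'   [chan_suppression()].
#' @param intensity Intensity model from [intensity_model()].
#' @param margin Margin (um) between the colony edge and the raster border.
#' @param seed RNG seed; identical spec + seed gives bit-identical output.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(pixel_size = 1, colony_radius = 250,
                       n_nuclei = NULL, density = 3700, nucleus_radius = 5,
                       channel_models = list(),
                       intensity = intensity_model(),
                       margin = 10, seed = 1L) {
  stopifnot(pixel_size > 0, colony_radius > 0, nucleus_radius > 0)
  if (is.null(n_nuclei)) {
    stopifnot(density > 0)
    n_nuclei <- round(density * pi * (colony_radius / 1000)^2)
  }
  if (length(channel_models) && is.null(names(channel_models)))
    stop("channel_models must be a named list")
  structure(list(pixel_size = pixel_size, colony_radius = colony_radius,
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radius = nucleus_radius,
                 channel_models = channel_models, intensity = intensity,
                 margin = margin, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Intensity model for synthetic scenes
#'
#' Per-class nuclear intensity distributions (arbitrary units), the constant
#' background level, and the additive Gaussian pixel noise (clipped at 0).
#' The default marker classes are separated by four class standard
#' deviations; DAPI is a tight stoichiometric stain shared by all cells.
#'
#' @param background Background level.
#' @param noise_sd Additive per-pixel Gaussian noise sd.
#' @param dapi `(mean, sd)` of the per-nucleus DAPI level.
#' @param neg,pos `(mean, sd)` of the negative / positive marker class.
#' @export
intensity_model <- function(background = 0.05, noise_sd = 0.01,
                            dapi = c(0.5, 0.02),
                            neg = c(0.2, 0.05), pos = c(0.4, 0.05)) {
  list(background = background, noise_sd = noise_sd,
       dapi = dapi, neg = neg, pos = pos)
}

# ---- per-channel spatial rules ---------------------------------------------

#' Channel spatial rules
#'
#' Constructors describing where a channel's positive class lies within a
#' colony. `levels` optionally overrides the spec-wide negative/positive
#' class `(mean, sd)` for that channel.
#'
#' * `chan_uniform()` — every nucleus positive.
#' * `chan_central_disc(radius)` — positive where the nucleus centre lies at
#'   radial position `< radius`.
#' * `chan_ring(r_in, r_out)` — positive for radial position in
#'   `[r_in, r_out)`; `r_out = Inf` gives an edge-open band.
#' * `chan_edge_band(width)` — positive within `width` of the colony edge.
#' * `chan_mixture(fraction_positive)` — a random fraction is positive,
#'   irrespective of position.
#' * `chan_secretor(cluster_radius, n_ring, include_center)` — marks a
#'   deliberately placed secretor cluster: one nucleus at the colony centre
#'   (optional) plus `n_ring` equally spaced on the circle of
#'   `cluster_radius`; these nuclei are placed before random packing.
#' * `chan_suppression(boundary, secretor_channel)` — positive everywhere
#'   except nuclei lying within `boundary` of the nearest secretor of
#'   `secretor_channel` (which must appear earlier in `channel_models`).
#'
#' @param radius,r_in,r_out,width,boundary Distances in um.
#' @param fraction_positive Fraction in `[0, 1]`.
#' @param cluster_radius,n_ring,include_center Secretor cluster layout.
#' @param secretor_channel Name of the secretor channel.
#' @param levels Optional `list(neg = c(mean, sd), pos = c(mean, sd))`.
#' @name channel_models
NULL

#' @rdname channel_models
#' @export
chan_uniform <- function(levels = NULL)
  list(type = "uniform", levels = levels)

#' @rdname channel_models
#' @export
chan_central_disc <- function(radius, levels = NULL)
  list(type = "central_disc", radius = radius, levels = levels)

#' @rdname channel_models
#' @export
chan_ring <- function(r_in, r_out, levels = NULL) {
  stopifnot(r_in < r_out)
  list(type = "ring", r_in = r_in, r_out = r_out, levels = levels)
}

#' @rdname channel_models
#' @export
chan_edge_band <- function(width, levels = NULL)
  list(type = "edge_band", width = width, levels = levels)

#' @rdname channel_models
#' @export
chan_mixture <- function(fraction_positive, levels = NULL) {
  stopifnot(fraction_positive >= 0, fraction_positive <= 1)
  list(type = "mixture", fraction_positive = fraction_positive,
       levels = levels)
}

#' @rdname channel_models
#' @export
chan_secretor <- function(cluster_radius = 10, n_ring = 6,
                          include_center = TRUE, levels = NULL) {
  # a secretor transgene marker is essentially off outside the induced
  # cells, so the default negative level sits at the background
  if (is.null(levels))
    levels <- list(neg = c(0.02, 0.005), pos = c(0.4, 0.05))
  list(type = "secretor", cluster_radius = cluster_radius,
       n_ring = as.integer(n_ring), include_center = include_center,
       levels = levels)
}

#' @rdname channel_models
#' @export
chan_suppression <- function(boundary, secretor_channel, levels = NULL)
  list(type = "suppression", boundary = boundary,
       secretor_channel = secretor_channel, levels = levels)

# ---- placement --------------------------------------------------------------

# dart throwing with minimum-separation rejection; `fixed` are pre-placed
# points that also repel. Coordinates relative to (0, 0) centre.
place_points_disc <- function(n, radius, min_sep, fixed = NULL,
                              max_attempts = 10L * n) {
  xs <- numeric(n); ys <- numeric(n); placed <- 0L
  fx <- if (is.null(fixed)) numeric(0) else fixed[, 1]
  fy <- if (is.null(fixed)) numeric(0) else fixed[, 2]
  s2 <- min_sep^2
  attempts <- 0L
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    r <- radius * sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
    x <- r * cos(th); y <- r * sin(th)
    if (placed > 0L &&
        min((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2) < s2)
      next
    if (length(fx) && min((fx - x)^2 + (fy - y)^2) < s2) next
    placed <- placed + 1L; xs[placed] <- x; ys[placed] <- y
  }
  if (placed < n)
    stop(sprintf(
      "infeasible packing: placed %d of %d nuclei within %d attempts (achievable maximum here ~%d)",
      placed, n, max_attempts, placed))
  cbind(x = xs, y = ys)
}

place_points_rect <- function(n, dim_um, min_sep, fixed = NULL,
                              max_attempts = 10L * n) {
  xs <- numeric(n); ys <- numeric(n); placed <- 0L
  fx <- if (is.null(fixed)) numeric(0) else fixed[, 1]
  fy <- if (is.null(fixed)) numeric(0) else fixed[, 2]
  s2 <- min_sep^2; attempts <- 0L
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    x <- runif(1, 0, dim_um[1]); y <- runif(1, 0, dim_um[2])
    if (placed > 0L &&
        min((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2) < s2)
      next
    if (length(fx) && min((fx - x)^2 + (fy - y)^2) < s2) next
    placed <- placed + 1L; xs[placed] <- x; ys[placed] <- y
  }
  if (placed < n)
    stop(sprintf(
      "infeasible packing: placed %d of %d nuclei within %d attempts (achievable maximum here ~%d)",
      placed, n, max_attempts, placed))
  cbind(x = xs, y = ys)
}

# class labels for one channel model given radial positions (um) and, for
# suppression, distances to the nearest secretor
channel_classes <- function(model, r, n, secretor_dist = NULL,
                            secretor_ids = NULL) {
  switch(model$type,
    uniform = rep(TRUE, n),
    central_disc = r < model$radius,
    ring = r >= model$r_in & r < model$r_out,
    edge_band = NA,  # resolved by caller (needs colony radius)
    mixture = seq_len(n) %in% sample.int(n, round(model$fraction_positive * n)),
    secretor = seq_len(n) %in% secretor_ids,
    suppression = secretor_dist >= model$boundary,
    stop("unknown channel model type: ", model$type))
}

channel_levels <- function(model, intensity) {
  lv <- model$levels
  list(neg = lv$neg %||% intensity$neg, pos = lv$pos %||% intensity$pos)
}

#' Generate a synthetic colony image with ground truth
#'
#' Renders one circular colony: nuclei are dart-thrown into the colony disc
#' with minimum-separation rejection, assigned a class per channel by the
#' spec's spatial rules, and drawn as anti-aliased discs over a constant
#' background with additive Gaussian pixel noise. The returned truth is
#' sufficient to score every downstream operation.
#'
#' @param spec A [scene_spec()].
#' @return `list(image, truth)`: `image` is a [colony_image] whose first
#'   channel is DAPI; `truth` holds the nucleus table (positions in the crop
#'   frame and radial positions, one class column per channel), secretor ids,
#'   domain radii implied by the channel rules, and the spec.
#' @export
generate_colony_image <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  out <- build_colony_nuclei(spec)
  render_colony_scene(spec, out$nuclei, out$secretor_ids)
}

# place nuclei (secretor cluster first) and assign classes
build_colony_nuclei <- function(spec) {
  R <- spec$colony_radius
  minsep <- 1.6 * spec$nucleus_radius
  sec_model <- Filter(function(m) m$type == "secretor", spec$channel_models)
  fixed <- NULL
  if (length(sec_model)) {
    m <- sec_model[[1]]
    ang <- seq(0, 2 * pi, length.out = m$n_ring + 1L)[seq_len(m$n_ring)]
    ring <- cbind(m$cluster_radius * cos(ang), m$cluster_radius * sin(ang))
    fixed <- if (m$include_center) rbind(c(0, 0), ring) else ring
  }
  n_fixed <- if (is.null(fixed)) 0L else nrow(fixed)
  n_rand <- spec$n_nuclei - n_fixed
  if (n_rand < 0L) stop("n_nuclei smaller than the secretor cluster")
  pts <- place_points_disc(n_rand, R - spec$nucleus_radius / 2, minsep,
                           fixed = fixed)
  centers <- rbind(fixed, pts)
  r <- sqrt(centers[, 1]^2 + centers[, 2]^2)
  secretor_ids <- if (n_fixed) seq_len(n_fixed) else integer(0)
  nuclei <- data.frame(id = seq_len(nrow(centers)),
                       dx_um = centers[, 1], dy_um = centers[, 2], r_um = r)
  list(nuclei = nuclei, secretor_ids = secretor_ids)
}

render_colony_scene <- function(spec, nuclei, secretor_ids) {
  R <- spec$colony_radius
  n <- nrow(nuclei)
  r <- nuclei$r_um
  sec_dist <- NULL
  if (length(secretor_ids)) {
    sx <- nuclei$dx_um[secretor_ids]; sy <- nuclei$dy_um[secretor_ids]
    sec_dist <- vapply(seq_len(n), function(i)
      sqrt(min((sx - nuclei$dx_um[i])^2 + (sy - nuclei$dy_um[i])^2)),
      numeric(1))
  }
  classes <- list()
  domain_radii <- list()
  for (nm in names(spec$channel_models)) {
    m <- spec$channel_models[[nm]]
    cl <- channel_classes(m, r, n, sec_dist, secretor_ids)
    if (m$type == "edge_band") cl <- r >= R - m$width
    classes[[nm]] <- cl
    domain_radii[[nm]] <- switch(m$type,
      central_disc = c(0, m$radius),
      ring = c(m$r_in, min(m$r_out, R)),
      edge_band = c(R - m$width, R),
      NULL)
  }

  side_um <- 2 * (R + spec$margin)
  dim_px <- rep(round(side_um / spec$pixel_size) + 1L, 2L)
  center <- rep(side_um / 2, 2L)
  xs <- nuclei$dx_um + center[1]
  ys <- nuclei$dy_um + center[2]

  im <- spec$intensity
  nm_all <- c("DAPI", names(spec$channel_models))
  arr <- array(0, c(dim_px, length(nm_all)))
  vals <- list(DAPI = pmax(rnorm(n, im$dapi[1], im$dapi[2]), 0))
  for (nm in names(spec$channel_models)) {
    lv <- channel_levels(spec$channel_models[[nm]], im)
    v <- ifelse(classes[[nm]],
                rnorm(n, lv$pos[1], lv$pos[2]),
                rnorm(n, lv$neg[1], lv$neg[2]))
    vals[[nm]] <- pmax(v, 0)
  }
  for (k in seq_along(nm_all)) {
    arr[, , k] <- add_pixel_noise(
      render_nuclei(dim_px, cbind(xs, ys), spec$nucleus_radius,
                    vals[[nm_all[k]]], spec$pixel_size, im$background),
      im$noise_sd)
  }

  truth_nuclei <- data.frame(id = nuclei$id, x_um = xs, y_um = ys,
                             r_um = nuclei$r_um)
  for (nm in names(classes)) truth_nuclei[[paste0("class_", nm)]] <- classes[[nm]]
  for (nm in names(vals)) truth_nuclei[[paste0("value_", nm)]] <- vals[[nm]]
  truth <- list(nuclei = truth_nuclei, center_um = center,
                colony_radius = R, domain_radii = domain_radii,
                secretor_ids = secretor_ids, spec = spec)
  list(image = colony_image(arr, center, R, spec$pixel_size, nm_all),
       truth = truth)
}

#' Generate a multi-colony field, optionally with a merged pair
#'
#' Places one synthetic colony per layout centre into a larger field.
#' With `include_merged = TRUE` an extra pair of colonies is added at a
#' centre distance of `1.6 * colony_radius` (closer than one diameter), which
#' fuses them into a single foreground object for exercising colony
#' detection and exclusion.
#'
#' @param spec A [scene_spec()]; its channel models are applied per colony
#'   relative to that colony's centre.
#' @param layout Two-column matrix of colony centres (um, field frame).
#' @param include_merged Add the merged pair?
#' @param margin Field margin (um) beyond the outermost colony edge.
#' @return `list(field, truth)` where `field` is a [field_image] and `truth`
#'   lists colony centres (with the merged pair flagged), all nuclei with
#'   their colony id, and the spec.
#' @export
generate_multicolony_field <- function(spec, layout, include_merged = FALSE,
                                       margin = 20) {
  stopifnot(inherits(spec, "scene_spec"))
  layout <- matrix(as.numeric(layout), ncol = 2)
  set.seed(spec$seed)
  R <- spec$colony_radius
  merged <- logical(nrow(layout))
  if (include_merged) {
    cx <- max(layout[, 1]) + 3.4 * R
    cy <- mean(layout[, 2])
    layout <- rbind(layout, c(cx - 0.8 * R, cy), c(cx + 0.8 * R, cy))
    merged <- c(merged, TRUE, TRUE)
  }
  nc <- nrow(layout)
  if (nc > 1L) {
    dd <- as.matrix(dist(layout)); diag(dd) <- Inf
    close_pairs <- which(dd < 2 * R + 2 * spec$nucleus_radius, arr.ind = TRUE)
    close_pairs <- close_pairs[!(merged[close_pairs[, 1]] &
                                 merged[close_pairs[, 2]]), , drop = FALSE]
    if (nrow(close_pairs))
      stop("layout causes unintended colony overlap between colonies ",
           paste(unique(pmin(close_pairs[, 1], close_pairs[, 2])),
                 collapse = ", "))
  }
  off <- c(min(layout[, 1]), min(layout[, 2])) - R - margin
  layout <- sweep(layout, 2, off)
  dim_um <- c(max(layout[, 1]), max(layout[, 2])) + R + margin
  dim_px <- round(dim_um / spec$pixel_size) + 1L

  all_nuc <- list()
  for (ci in seq_len(nc)) {
    b <- build_colony_nuclei(spec)
    nuc <- b$nuclei
    nuc$colony <- ci
    nuc$x_um <- nuc$dx_um + layout[ci, 1]
    nuc$y_um <- nuc$dy_um + layout[ci, 2]
    all_nuc[[ci]] <- nuc
  }
  nuc <- do.call(rbind, all_nuc)
  im <- spec$intensity
  n <- nrow(nuc)
  classes <- list()
  for (nm in names(spec$channel_models)) {
    m <- spec$channel_models[[nm]]
    cl <- channel_classes(m, nuc$r_um, n)
    if (m$type == "edge_band") cl <- nuc$r_um >= R - m$width
    classes[[nm]] <- cl
  }
  nm_all <- c("DAPI", names(spec$channel_models))
  vals <- list(DAPI = pmax(rnorm(n, im$dapi[1], im$dapi[2]), 0))
  for (nm in names(spec$channel_models)) {
    lv <- channel_levels(spec$channel_models[[nm]], im)
    vals[[nm]] <- pmax(ifelse(classes[[nm]],
                              rnorm(n, lv$pos[1], lv$pos[2]),
                              rnorm(n, lv$neg[1], lv$neg[2])), 0)
  }
  arr <- array(0, c(dim_px, length(nm_all)))
  for (k in seq_along(nm_all)) {
    arr[, , k] <- add_pixel_noise(
      render_nuclei(dim_px, cbind(nuc$x_um, nuc$y_um), spec$nucleus_radius,
                    vals[[nm_all[k]]], spec$pixel_size, im$background),
      im$noise_sd)
  }
  colonies <- data.frame(id = seq_len(nc), x_um = layout[, 1],
                         y_um = layout[, 2], merged = merged)
  truth_nuclei <- data.frame(id = seq_len(n), colony = nuc$colony,
                             x_um = nuc$x_um, y_um = nuc$y_um,
                             r_um = nuc$r_um)
  for (nm in names(classes)) truth_nuclei[[paste0("class_", nm)]] <- classes[[nm]]
  list(field = field_image(arr, spec$pixel_size, nm_all),
       truth = list(colonies = colonies, nuclei = truth_nuclei,
                    merged_pair = which(merged), spec = spec))
}

#' Cut a field into an overlapping tile grid
#'
#' Splits a [field_image] into an `nx` by `ny` grid of tiles whose adjacent
#' tiles share `overlap` of the tile width/height, the inverse operation of
#' [stitch_tiles()].
#'
#' @param field A [field_image].
#' @param nx,ny Grid dimensions.
#' @param overlap Overlap fraction in `[0, 0.5)`.
#' @return `list(tiles, grid, overlap)`: `tiles` is a list of [field_image]
#'   tiles in row-major order; `grid` a data frame of grid rows/cols and
#'   pixel offsets.
#' @export
tile_field <- function(field, nx, ny, overlap = 0.1) {
  stopifnot(inherits(field, "field_image"), overlap >= 0, overlap < 0.5)
  d <- dim(field$raster)
  # tile size T with step s = T(1 - overlap): (n-1)s + T = D
  tw <- ceiling(d[1] / ((nx - 1) * (1 - overlap) + 1))
  th <- ceiling(d[2] / ((ny - 1) * (1 - overlap) + 1))
  sx <- if (nx > 1) floor((d[1] - tw) / (nx - 1)) else 0L
  sy <- if (ny > 1) floor((d[2] - th) / (ny - 1)) else 0L
  tiles <- list(); grid <- NULL
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    x0 <- if (i < nx) (i - 1L) * sx else d[1] - tw
    y0 <- if (j < ny) (j - 1L) * sy else d[2] - th
    sub <- field$raster[x0 + seq_len(tw), y0 + seq_len(th), , drop = FALSE]
    tiles[[length(tiles) + 1L]] <-
      field_image(sub, field$pixel_size, field$channel_names)
    grid <- rbind(grid, data.frame(row = j, col = i, x0 = x0, y0 = y0))
  }
  list(tiles = tiles, grid = grid, overlap = overlap)
}

#' Z-stack scene specification
#'
#' Describes a synthetic confocal z-stack of an epithelial sheet: a smooth
#' apical surface (base height plus sinusoidal undulation) marked by a ZO-1
#' channel, and further channels placed at signed micrometre offsets from
#' that surface (positive = basal, i.e. deeper than the apical plane).
#'
#' @param z_planes Number of z planes (>= 5).
#' @param z_step Plane spacing (um); plane `k` sits at `(k - 1) * z_step`.
#' @param apical_base Mean surface height (um).
#' @param apical_amplitude,apical_wavelength Sinusoidal undulation (um).
#' @param channel_offsets Named list; each element is
#'   `list(offsets = <um>, weights = <probabilities>)` sampled per lateral
#'   position (a single offset means a point mass).
#' @param gap_patches Optional data frame `(x_um, y_um, r_um)` of lateral
#'   patches where ZO-1 is absent.
#' @param axial_sd Axial spread (um) of each channel about its plane.
#' @param lateral_dim Lateral extent `(x, y)` in um.
#' @return An object of class `zscene_spec`.
#' @export
zscene_spec <- function(z_planes = 15L, z_step = 1, apical_base = 7,
                        apical_amplitude = 0, apical_wavelength = 50,
                        channel_offsets = list(),
                        gap_patches = NULL, axial_sd = 1,
                        lateral_dim = c(100, 100)) {
  stopifnot(z_planes >= 5L, z_step > 0)
  max_off <- if (length(channel_offsets))
    max(abs(unlist(lapply(channel_offsets, `[[`, "offsets")))) else 0
  z_max <- (z_planes - 1L) * z_step
  if (apical_base - apical_amplitude - max_off - 2 * axial_sd < 0 ||
      apical_base + apical_amplitude + max_off + 2 * axial_sd > z_max)
    stop("z extent does not cover the apical surface plus channel offsets")
  structure(list(z_planes = as.integer(z_planes), z_step = z_step,
                 apical_base = apical_base,
                 apical_amplitude = apical_amplitude,
                 apical_wavelength = apical_wavelength,
                 channel_offsets = channel_offsets,
                 gap_patches = gap_patches, axial_sd = axial_sd,
                 lateral_dim = lateral_dim),
            class = "zscene_spec")
}

#' Generate a synthetic z-stack with a ZO-1 apical surface
#'
#' Renders a ZO-1 channel concentrated (Gaussian in z) on the analytic apical
#' surface and each further channel at its sampled signed offset from that
#' surface. Intensities use the scene's background and noise model.
#'
#' @param zspec A [zscene_spec()].
#' @param spec A [scene_spec()]; supplies `pixel_size`, the intensity model
#'   and the RNG seed.
#' @return `list(stack, truth)`: `stack` is a `zstack_image`
#'   (named channel arrays `[x, y, z]`, `z_step`, `pixel_size`); `truth`
#'   carries the analytic surface heights, per-position channel offsets and
#'   gap patches.
#' @export
generate_zstack <- function(zspec, spec) {
  stopifnot(inherits(zspec, "zscene_spec"), inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  px <- spec$pixel_size
  nx <- round(zspec$lateral_dim[1] / px) + 1L
  ny <- round(zspec$lateral_dim[2] / px) + 1L
  nz <- zspec$z_planes
  xs <- (seq_len(nx) - 1) * px; ys <- (seq_len(ny) - 1) * px
  h <- zspec$apical_base + zspec$apical_amplitude *
    outer(sin(2 * pi * xs / zspec$apical_wavelength),
          cos(2 * pi * ys / zspec$apical_wavelength))
  zo1_amp <- matrix(1, nx, ny)
  if (!is.null(zspec$gap_patches)) {
    for (g in seq_len(nrow(zspec$gap_patches))) {
      d2 <- outer((xs - zspec$gap_patches$x_um[g])^2,
                  (ys - zspec$gap_patches$y_um[g])^2, "+")
      zo1_amp[d2 < zspec$gap_patches$r_um[g]^2] <- 0
    }
  }
  im <- spec$intensity
  zs <- (seq_len(nz) - 1) * zspec$z_step
  render_channel <- function(center_z, amp) {
    a <- array(0, c(nx, ny, nz))
    for (k in seq_len(nz)) {
      plane <- amp * exp(-(zs[k] - center_z)^2 / (2 * zspec$axial_sd^2))
      a[, , k] <- add_pixel_noise(im$background + plane, im$noise_sd)
    }
    a
  }
  channels <- list(ZO1 = render_channel(h, zo1_amp))
  offsets_truth <- list()
  for (nm in names(zspec$channel_offsets)) {
    co <- zspec$channel_offsets[[nm]]
    offs <- co$offsets
    w <- co$weights %||% rep(1 / length(offs), length(offs))
    o <- matrix(offs[sample.int(length(offs), nx * ny, replace = TRUE,
                                prob = w)], nx, ny)
    offsets_truth[[nm]] <- o
    channels[[nm]] <- render_channel(h + o, matrix(1, nx, ny))
  }
  stack <- structure(list(channels = channels, z_step = zspec$z_step,
                          pixel_size = px,
                          channel_names = names(channels)),
                     class = "zstack_image")
  list(stack = stack,
       truth = list(surface_um = h, offsets_um = offsets_truth,
                    gap_patches = zspec$gap_patches, zspec = zspec))
}

#' Time-lapse scene specification
#'
#' A reporter-positive disc whose radius follows a per-frame schedule, on a
#' fixed nuclear packing — emulating the shrinking SOX2 domain of a live
#' reporter colony imaged at fixed intervals.
#'
#' @param n_frames Number of frames.
#' @param frame_interval Minutes between frames (default 30).
#' @param radius_schedule Reporter-positive disc radius (um) per frame;
#'   recycled if scalar. Values must lie in `[0, colony_radius]`.
#' @return An object of class `timescene_spec`.
#' @export
timescene_spec <- function(n_frames, frame_interval = 30, radius_schedule) {
  radius_schedule <- rep_len(radius_schedule, n_frames)
  stopifnot(n_frames >= 1L, frame_interval > 0, all(radius_schedule >= 0))
  structure(list(n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 radius_schedule = radius_schedule),
            class = "timescene_spec")
}

#' Generate a reporter time-lapse series
#'
#' All frames share one nucleus placement and per-nucleus base intensities;
#' per frame, a nucleus is reporter-positive iff its radial position is below
#' that frame's scheduled radius. Channels per frame: `H2B` (constant nuclear
#' marker) and `SOX2` (the reporter).
#'
#' @param tspec A [timescene_spec()].
#' @param spec A [scene_spec()].
#' @return `list(frames, truth, center_um, pixel_size, analysis_radius,
#'   frame_interval, time_h)`; `frames` is a list of `[x, y, channel]`
#'   arrays, `time_h` hours since the first frame.
#' @export
generate_timelapse <- function(tspec, spec) {
  stopifnot(inherits(tspec, "timescene_spec"), inherits(spec, "scene_spec"))
  if (any(tspec$radius_schedule > spec$colony_radius))
    stop("radius_schedule exceeds colony_radius")
  set.seed(spec$seed)
  b <- build_colony_nuclei(spec)
  nuc <- b$nuclei
  n <- nrow(nuc)
  im <- spec$intensity
  side_um <- 2 * (spec$colony_radius + spec$margin)
  dim_px <- rep(round(side_um / spec$pixel_size) + 1L, 2L)
  center <- rep(side_um / 2, 2L)
  xs <- nuc$dx_um + center[1]; ys <- nuc$dy_um + center[2]
  v_h2b <- pmax(rnorm(n, im$dapi[1], im$dapi[2]), 0)
  v_pos <- pmax(rnorm(n, im$pos[1], im$pos[2]), 0)
  v_neg <- pmax(rnorm(n, im$neg[1], im$neg[2]), 0)
  h2b <- render_nuclei(dim_px, cbind(xs, ys), spec$nucleus_radius, v_h2b,
                       spec$pixel_size, im$background)
  frames <- vector("list", tspec$n_frames)
  for (f in seq_len(tspec$n_frames)) {
    pos <- nuc$r_um < tspec$radius_schedule[f]
    rep_f <- render_nuclei(dim_px, cbind(xs, ys), spec$nucleus_radius,
                           ifelse(pos, v_pos, v_neg),
                           spec$pixel_size, im$background)
    a <- array(0, c(dim_px, 2L))
    a[, , 1] <- add_pixel_noise(h2b, im$noise_sd)
    a[, , 2] <- add_pixel_noise(rep_f, im$noise_sd)
    dimnames(a) <- list(NULL, NULL, c("H2B", "SOX2"))
    frames[[f]] <- a
  }
  truth_nuclei <- data.frame(id = nuc$id, x_um = xs, y_um = ys,
                             r_um = nuc$r_um)
  list(frames = frames, channel_names = c("H2B", "SOX2"),
       center_um = center, pixel_size = spec$pixel_size,
       analysis_radius = spec$colony_radius,
       frame_interval = tspec$frame_interval,
       time_h = (seq_len(tspec$n_frames) - 1) * tspec$frame_interval / 60,
       truth = list(nuclei = truth_nuclei,
                    radius_schedule = tspec$radius_schedule,
                    tspec = tspec, spec = spec))
}

#' Generate a transwell monolayer sheet
#'
#' A rectangular sheet of nuclei with an exact number of response-positive
#' cells, optionally with inducible secretor cells and a suppression zone:
#' the response channel is negative for every nucleus within
#' `suppression_distance` of the nearest secretor.
#'
#' @param spec A [scene_spec()] (supplies nucleus size, intensity model,
#'   seed; `n_nuclei` is the sheet's cell count).
#' @param n_positive Number of response-positive nuclei (ignored when
#'   `secretors` is given — then all non-suppressed cells are positive).
#' @param response_channel Name of the response channel.
#' @param secretors Optional list with `center` (um), `cluster_radius`,
#'   `n_ring`, `include_center`, `suppression_distance` and
#'   `secretor_channel` (default `"NOG"`).
#' @param field_dim Sheet extent `(x, y)` um.
#' @return `list(field, truth)`: `field` is a [field_image]
#'   (DAPI + response channel + optional secretor channel); `truth` has the
#'   nucleus table with class labels, the positive fraction and secretor ids.
#' @export
generate_transwell_field <- function(spec, n_positive,
                                     response_channel = "SMAD23",
                                     secretors = NULL,
                                     field_dim = c(500, 500)) {
  stopifnot(inherits(spec, "scene_spec"))
  n <- spec$n_nuclei
  if (is.null(secretors) && n_positive > n)
    stop("n_positive exceeds n_nuclei")
  set.seed(spec$seed)
  minsep <- 1.6 * spec$nucleus_radius
  fixed <- NULL
  if (!is.null(secretors)) {
    cr <- secretors$cluster_radius %||% 10
    nr <- secretors$n_ring %||% 6L
    ic <- secretors$include_center %||% TRUE
    ang <- seq(0, 2 * pi, length.out = nr + 1L)[seq_len(nr)]
    ring <- cbind(secretors$center[1] + cr * cos(ang),
                  secretors$center[2] + cr * sin(ang))
    fixed <- if (ic) rbind(secretors$center, ring) else ring
  }
  n_fixed <- if (is.null(fixed)) 0L else nrow(fixed)
  pts <- place_points_rect(n - n_fixed, field_dim, minsep, fixed = fixed)
  centers <- rbind(fixed, pts)
  n <- nrow(centers)
  secretor_ids <- if (n_fixed) seq_len(n_fixed) else integer(0)

  if (is.null(secretors)) {
    pos <- seq_len(n) %in% sample.int(n, n_positive)
  } else {
    sd2 <- vapply(seq_len(n), function(i)
      min((centers[secretor_ids, 1] - centers[i, 1])^2 +
          (centers[secretor_ids, 2] - centers[i, 2])^2), numeric(1))
    pos <- sqrt(sd2) >= secretors$suppression_distance
  }
  im <- spec$intensity
  dim_px <- round(field_dim / spec$pixel_size) + 1L
  nm_all <- c("DAPI", response_channel)
  vals <- list(pmax(rnorm(n, im$dapi[1], im$dapi[2]), 0),
               pmax(ifelse(pos, rnorm(n, im$pos[1], im$pos[2]),
                           rnorm(n, im$neg[1], im$neg[2])), 0))
  if (!is.null(secretors)) {
    sch <- secretors$secretor_channel %||% "NOG"
    nm_all <- c(nm_all, sch)
    vals[[3]] <- pmax(ifelse(seq_len(n) %in% secretor_ids,
                             rnorm(n, im$pos[1], im$pos[2]),
                             rnorm(n, 0.02, 0.005)), 0)
  }
  arr <- array(0, c(dim_px, length(nm_all)))
  for (k in seq_along(nm_all)) {
    arr[, , k] <- add_pixel_noise(
      render_nuclei(dim_px, centers, spec$nucleus_radius, vals[[k]],
                    spec$pixel_size, im$background),
      im$noise_sd)
  }
  truth_nuclei <- data.frame(id = seq_len(n), x_um = centers[, 1],
                             y_um = centers[, 2], positive = pos,
                             secretor = seq_len(n) %in% secretor_ids)
  list(field = field_image(arr, spec$pixel_size, nm_all),
       truth = list(nuclei = truth_nuclei,
                    fraction_positive = mean(pos[!truth_nuclei$secretor]),
                    secretor_ids = secretor_ids, spec = spec))
}
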