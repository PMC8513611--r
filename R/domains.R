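# marker-high pixel mask inside the disc. The in-disc histogram has three
# regions (background | marker-negative nuclei | marker-positive nuclei):
# a first Otsu cut removes the dominant background, nucleus-core pixels
# (eroded, so anti-aliased rims do not smear the classes) provide the
# negative/positive statistics, and a second Otsu on the core values sets
# the high cut. A channel with no genuine positive population — the core
# distribution is unimodal by mixture BIC, or its two components are not
# separated by at least twice the larger sd — yields an empty mask rather
# than the upper noise tail.
marker_high_mask <- function(v, disc) {
  empty <- disc & FALSE
  vals <- v[disc]
  if (diff(range(vals)) < 1e-9) return(empty)
  th1 <- multi_otsu3(vals)[1]  # background | nuclei (robust to class mix)
  nucmask <- disc & v > th1
  # 2 px erosion keeps only full-coverage nucleus interiors, so the class
  # statistics are not smeared by partial-coverage rim pixels
  core <- EBImage::erode(nucmask, EBImage::makeBrush(5L, "disc"))
  cv <- v[core]
  if (length(cv) < 50L) return(empty)
  sub <- sort(cv)[unique(round(seq(1, length(cv),
                                   length.out = min(4000L, length(cv)))))]
  # equal-variance mixture: with free variances one component can absorb
  # the other class's tail and mask a genuinely bimodal sample
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(sub, G = 1:2, modelNames = "E",
                                    verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit) || fit$G == 1L) return(empty)
  m <- sort(fit$parameters$mean)
  s <- sqrt(fit$parameters$variance$sigmasq)
  if (diff(m) < 2 * max(s)) return(empty)
  disc & v > otsu_threshold(cv)
}

#' Segment a colony into three germ-layer domains
#'
#' Pixels inside the analysis disc are split into three intensity classes by
#' a two-threshold (three-region) Otsu cut that minimizes the weighted
#' within-class variance of the first marker channel's histogram — the
#' brightest class marks the central (e.g. SOX2-high) domain. The second
#' marker channel, cut by binary Otsu, marks the middle ring. Each candidate
#' region is closed into a solid footprint with a disc structuring element
#' of radius `alpha` (the raster form of an alpha shape on the positive
#' pixels); components smaller than `min_component` are merged into the
#' surrounding label. The outer domain is the remainder of the disc, so the
#' three labels partition the disc exactly.
#'
#' @param colony A [colony_image].
#' @param channels Ordered channel names: `c(central_marker, middle_marker)`,
#'   e.g. `c("SOX2", "BRA")`.
#' @param alpha Closing radius (um).
#' @param min_component Minimum component area (um^2).
#' @return A `domain_map`: `labels` (0 outside the disc; 1 central, 2
#'   middle, 3 outer), `areas_um2` (named), `analysis_area_um2`,
#'   `pixel_size`, `ordered` (FALSE when the central domain is not innermost
#'   by mean radius).
#' @export
segment_domains <- function(colony, channels = c("SOX2", "BRA"),
                            alpha = 20, min_component = 50) {
  stopifnot(inherits(colony, "colony_image"), length(channels) >= 2L)
  px <- colony$pixel_size
  d <- dim(colony$raster)[1:2]
  xs <- (seq_len(d[1]) - 1) * px
  ys <- (seq_len(d[2]) - 1) * px
  r2 <- outer((xs - colony$center[1])^2, (ys - colony$center[2])^2, "+")
  disc <- r2 <= colony$analysis_radius^2
  v1 <- get_channel(colony, channels[1])
  v2 <- get_channel(colony, channels[2])
  if (diff(range(v1[disc])) < 1e-9) stop("domains not separable")
  bpx <- max(3L, 2L * round(alpha / px) + 1L)  # disc of radius alpha
  brush <- EBImage::makeBrush(bpx, "disc")
  close_solid <- function(mask) {
    m <- EBImage::fillHull(EBImage::closing(mask, brush))
    m & disc
  }
  drop_small <- function(mask) {
    lab <- EBImage::bwlabel(mask)
    if (max(lab) == 0L) return(mask)
    sizes <- tabulate(lab[lab > 0L])
    small <- which(sizes * px^2 < min_component)
    if (length(small)) mask[lab %in% small] <- FALSE
    mask
  }
  largest_component <- function(mask) {
    lab <- EBImage::bwlabel(mask)
    if (max(lab) <= 1L) return(mask)
    lab == which.max(tabulate(lab[lab > 0L]))
  }
  # the central footprint is a single connected region by construction
  central <- largest_component(drop_small(close_solid(marker_high_mask(v1, disc))))
  middle <- drop_small(close_solid(marker_high_mask(v2, disc))) & !central
  labels <- matrix(0L, d[1], d[2])
  labels[disc] <- 3L
  labels[middle] <- 2L
  labels[central] <- 1L
  areas <- c(central = sum(labels == 1L),
             middle = sum(labels == 2L),
             outer = sum(labels == 3L)) * px^2
  r <- sqrt(r2)
  ordered <- TRUE
  if (areas["central"] > 0 && areas["middle"] > 0)
    ordered <- mean(r[labels == 1L]) < mean(r[labels == 2L])
  structure(list(labels = labels, areas_um2 = areas,
                 analysis_area_um2 = pi * colony$analysis_radius^2,
                 analysis_radius = colony$analysis_radius,
                 pixel_size = px, ordered = ordered),
            class = "domain_map")
}

#' Domain areas and fractions of the analysis disc
#'
#' @param map A `domain_map`.
#' @return Data frame (domain, area_um2, fraction) where fraction is the
#'   area over the analytic analysis-disc area.
#' @export
domain_areas <- function(map) {
  stopifnot(inherits(map, "domain_map"))
  data.frame(domain = names(map$areas_um2),
             area_um2 = as.numeric(map$areas_um2),
             fraction = as.numeric(map$areas_um2) / map$analysis_area_um2)
}

#' Relative change of the central-domain area between conditions
#'
#' Percent change of the test-cohort mean central area relative to the
#' reference-cohort mean: `100 * (mean(test) - mean(ref)) / mean(ref)`.
#' Negative values are reductions. Per-colony normalized areas
#' (`test / mean(ref)`) are returned for scatter plotting.
#'
#' @param test,reference Numeric vectors of per-colony central-domain areas
#'   (um^2).
#' @return `list(percent_change, test_mean, reference_mean,
#'   normalized_test)`.
#' @export
relative_central_change <- function(test, reference) {
  stopifnot(length(test) > 0, length(reference) > 0)
  mr <- mean(reference)
  if (!(mr > 0)) stop("reference mean must be positive")
  list(percent_change = 100 * (mean(test) - mr) / mr,
       test_mean = mean(test), reference_mean = mr,
       normalized_test = test / mr)
}

#' Central-domain area from classified cells (cross-check)
#'
#' An independent, cell-based estimate of the central-domain area: the
#' fraction of cells called positive for the central marker times the
#' analysis-disc area. Useful to sanity-check the pixel-based
#' [segment_domains()] path.
#'
#' @param cells A `cell_table` with a `call_<channel>` column.
#' @param channel Central marker channel.
#' @param analysis_radius Analysis radius (um); default from attributes.
#' @return Area (um^2).
#' @export
central_area_from_cells <- function(cells, channel, analysis_radius = NULL) {
  analysis_radius <- analysis_radius %||% attr(cells, "analysis_radius")
  fp <- fraction_positive(cells, channel)
  fp$fraction * pi * analysis_radius^2
}
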