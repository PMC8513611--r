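#' Normalize a channel to nuclear DAPI
#'
#' Adds a per-cell normalized intensity column: channel median divided by
#' DAPI median. Cells with a non-positive DAPI median, or with a DAPI median
#' below `min_dapi_frac` of the cohort median (debris and rim fragments,
#' whose ratios are unstable), are excluded with a message.
#'
#' @param cells A `cell_table`.
#' @param channel Channel name to normalize.
#' @param dapi DAPI channel name.
#' @param min_dapi_frac Relative DAPI floor for the debris filter.
#' @return The table with a `norm_<channel>` column.
#' @export
normalize_to_dapi <- function(cells, channel, dapi = "DAPI",
                              min_dapi_frac = 0.2) {
  mcol <- paste0("median_", channel)
  dcol <- paste0("median_", dapi)
  stopifnot(mcol %in% names(cells), dcol %in% names(cells))
  floor_ <- min_dapi_frac * median(cells[[dcol]])
  bad <- !(cells[[dcol]] > max(0, floor_))
  if (any(bad)) {
    message(sum(bad), " cell(s) with zero or near-zero DAPI median excluded")
    cells <- cells[!bad, , drop = FALSE]
  }
  cells[[paste0("norm_", channel)]] <- cells[[mcol]] / cells[[dcol]]
  cells
}

#' Fit the two-population intensity model and its cut-off
#'
#' Fits a two-component Gaussian mixture (EM, via mclust) to the normalized
#' intensity distribution for QC, and sets the positive/negative cut-off by
#' Otsu's criterion on the value histogram. The fit is flagged as not
#' converged when the sample is better explained by a single component
#' (mixture BIC) or when the two components overlap (`|mean difference| <
#' max(component sd)`); the Otsu threshold is still returned in that case.
#'
#' @param values Numeric vector of normalized intensities (>= 20 values).
#' @return A `mixture_fit`: `means`, `sds`, `weights` (low class first),
#'   `threshold`, `converged`.
#' @export
fit_binary_threshold <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 20L)
    stop("need at least 20 values to fit the two-population model")
  threshold <- otsu_threshold(values)
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(values, G = 2, modelNames = "V",
                                    verbose = FALSE)),
    error = function(e) NULL)
  # unimodality check: does one component explain the data better?
  fit1 <- tryCatch(
    suppressWarnings(mclust::Mclust(values, G = 1:2, modelNames = "V",
                                    verbose = FALSE)),
    error = function(e) NULL)
  unimodal <- !is.null(fit1) && fit1$G == 1L
  if (is.null(fit)) {
    m <- c(mean(values), mean(values)); s <- c(sd(values), sd(values))
    w <- c(0.5, 0.5)
  } else {
    o <- order(fit$parameters$mean)
    m <- fit$parameters$mean[o]
    s <- sqrt(fit$parameters$variance$sigmasq)
    if (length(s) == 1L) s <- rep(s, 2L)
    s <- s[o]
    w <- fit$parameters$pro[o]
  }
  converged <- !unimodal && is.finite(diff(m)) && abs(diff(m)) >= max(s)
  structure(list(means = unname(m), sds = unname(s), weights = unname(w),
                 threshold = threshold, converged = converged),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "mixture_fit: means %.3f / %.3f, sds %.3f / %.3f, weights %.2f / %.2f, threshold %.3f%s\n",
    x$means[1], x$means[2], x$sds[1], x$sds[2], x$weights[1], x$weights[2],
    x$threshold, if (x$converged) "" else " (poorly separated)"))
  invisible(x)
}

#' Call positive cells
#'
#' A cell is positive iff its normalized intensity is strictly above the
#' threshold (ties are negative).
#'
#' @param cells A `cell_table` with a `norm_<channel>` column.
#' @param channel Channel name.
#' @param fit A `mixture_fit` (or a bare numeric threshold).
#' @return The table with a logical `call_<channel>` column.
#' @export
classify_positive <- function(cells, channel, fit) {
  ncol_ <- paste0("norm_", channel)
  stopifnot(ncol_ %in% names(cells))
  th <- if (inherits(fit, "mixture_fit")) fit$threshold else as.numeric(fit)
  cells[[paste0("call_", channel)]] <- cells[[ncol_]] > th
  cells
}

#' Radial intensity profile
#'
#' Bins intensity by distance from the colony centre, in contiguous bins
#' from 0 to the analysis radius. In cell mode the per-cell (normalized or
#' median) intensities are averaged per bin; in pixel mode raw pixels are.
#' Empty bins report `n = 0` and `NA` mean; the sd is `NA` where `n < 2`.
#'
#' @param x A `cell_table` (cell mode) or a single-channel matrix
#'   (pixel mode).
#' @param value For cell mode, the column to profile (e.g. `"norm_pSMAD1"`);
#'   ignored in pixel mode.
#' @param center Colony centre (um); defaults to the table's attribute.
#' @param analysis_radius Analysis radius (um); default from attributes.
#' @param bin_width Bin width (um), in `[2, 50]`.
#' @param pixel_size um/px (pixel mode).
#' @param mask Optional logical matrix (pixel mode): profile only pixels
#'   where the mask is `TRUE` (e.g. a nuclear foreground mask).
#' @return A `radial_profile` data frame: `bin_center_um`, `mean`, `sd`, `n`.
#' @export
radial_profile <- function(x, value = NULL, center = NULL,
                           analysis_radius = NULL, bin_width = 10,
                           pixel_size = 1, mask = NULL) {
  stopifnot(bin_width >= 2, bin_width <= 50)
  if (inherits(x, "cell_table") || is.data.frame(x)) {
    center <- center %||% attr(x, "center_um")
    analysis_radius <- analysis_radius %||% attr(x, "analysis_radius")
    stopifnot(!is.null(value), value %in% names(x))
    r <- sqrt((x$x_um - center[1])^2 + (x$y_um - center[2])^2)
    v <- x[[value]]
    mode <- "cell"
  } else {
    stopifnot(is.matrix(x), !is.null(center), !is.null(analysis_radius))
    xs <- (seq_len(nrow(x)) - 1) * pixel_size
    ys <- (seq_len(ncol(x)) - 1) * pixel_size
    r <- sqrt(outer((xs - center[1])^2, (ys - center[2])^2, "+"))
    keep <- r <= analysis_radius
    if (!is.null(mask)) keep <- keep & mask
    v <- x[keep]; r <- r[keep]
    mode <- "pixel"
  }
  edges <- seq(0, analysis_radius, by = bin_width)
  if (edges[length(edges)] < analysis_radius)
    edges <- c(edges, analysis_radius)
  nb <- length(edges) - 1L
  bin <- findInterval(r, edges, rightmost.closed = TRUE, all.inside = TRUE)
  inside <- r <= analysis_radius
  bin <- bin[inside]; v <- v[inside]
  n <- tabulate(bin, nb)
  mu <- rep(NA_real_, nb); s <- rep(NA_real_, nb)
  gs <- split(v, factor(bin, levels = seq_len(nb)))
  mu[n > 0] <- vapply(gs[n > 0], mean, numeric(1))
  s[n > 1] <- vapply(gs[n > 1], sd, numeric(1))
  out <- data.frame(bin_center_um = (edges[-1] + edges[-(nb + 1L)]) / 2,
                    mean = mu, sd = s, n = n)
  attr(out, "bin_width") <- bin_width
  attr(out, "mode") <- mode
  attr(out, "analysis_radius") <- analysis_radius
  class(out) <- c("radial_profile", "data.frame")
  out
}

# half-max crossing of the outward transition: the upward crossing of
# (min + max) / 2 beyond which the profile stays high, linearly
# interpolated between bin centres. Taking the last upward crossing makes
# the estimate robust to sparse noisy bins near the colony centre.
half_max_crossing_inward <- function(bc, mu) {
  ok <- is.finite(mu)
  bc <- bc[ok]; mu <- mu[ok]
  # flat profile: no internal boundary to find (e.g. a uniformly positive
  # colony) - treat as everywhere-high
  if (diff(range(mu)) < 0.1 * max(abs(mu)))
    return(list(r = 0, all_above = TRUE, none = FALSE))
  half <- (min(mu) + max(mu)) / 2
  above <- mu > half
  if (all(above)) return(list(r = 0, all_above = TRUE, none = FALSE))
  if (!any(above)) return(list(r = NA_real_, all_above = FALSE, none = TRUE))
  up <- which(diff(above) == 1L) + 1L  # bins entering the high state
  if (!length(up)) return(list(r = NA_real_, all_above = FALSE, none = TRUE))
  i <- up[length(up)]
  r <- bc[i - 1L] + (bc[i] - bc[i - 1L]) *
    (half - mu[i - 1L]) / (mu[i] - mu[i - 1L])
  list(r = r, all_above = FALSE, none = FALSE)
}

#' Width of the signaling-positive edge ring
#'
#' The ring width is measured inward from the colony edge: `width =
#' analysis_radius - r_half`, where `r_half` is the innermost radius at
#' which the radial profile crosses half of its range (`(min + max) / 2`),
#' linearly interpolated between bin centres. A profile entirely above
#' half-max (a uniformly positive colony) returns the full analysis radius;
#' a profile that never reaches half-max returns width 0 with a `no_ring`
#' flag.
#'
#' @param profile A `radial_profile` with >= 10 non-empty bins.
#' @param analysis_radius Analysis radius (um); default from the profile.
#' @return `list(width_um, r_half_um, no_ring)`.
#' @export
ring_width <- function(profile, analysis_radius = NULL) {
  analysis_radius <- analysis_radius %||% attr(profile, "analysis_radius")
  if (sum(is.finite(profile$mean)) < 10L)
    stop("profile needs at least 10 non-empty bins")
  hc <- half_max_crossing_inward(profile$bin_center_um, profile$mean)
  if (hc$none)
    return(list(width_um = 0, r_half_um = NA_real_, no_ring = TRUE))
  if (hc$all_above)
    return(list(width_um = analysis_radius, r_half_um = 0, no_ring = FALSE))
  list(width_um = analysis_radius - hc$r, r_half_um = hc$r, no_ring = FALSE)
}

#' Centre-versus-edge intensity summary
#'
#' Means (over per-cell values) for the colony centre group
#' (`radial < center_radius`) and the edge group (within `edge_band` of the
#' analysis radius).
#'
#' @param cells A `cell_table`.
#' @param value Column to summarize (e.g. `"norm_SMAD23"`).
#' @param center_radius Centre group radius (um).
#' @param edge_band Edge band width (um).
#' @param analysis_radius Analysis radius (um); default from attributes.
#' @return Data frame with rows `center` and `edge`: mean, sd, n.
#' @export
center_edge_summary <- function(cells, value, center_radius = 100,
                                edge_band = 50, analysis_radius = NULL) {
  analysis_radius <- analysis_radius %||% attr(cells, "analysis_radius")
  if (center_radius > analysis_radius - edge_band)
    stop("center and edge bands overlap")
  stopifnot(value %in% names(cells))
  ctr <- cells$radial_um < center_radius
  edg <- cells$radial_um >= analysis_radius - edge_band &
    cells$radial_um <= analysis_radius
  if (!any(ctr)) stop("empty group: center band")
  if (!any(edg)) stop("empty group: edge band")
  data.frame(
    group = c("center", "edge"),
    mean = c(mean(cells[[value]][ctr]), mean(cells[[value]][edg])),
    sd = c(sd(cells[[value]][ctr]), sd(cells[[value]][edg])),
    n = c(sum(ctr), sum(edg)))
}

#' Fraction of positive cells
#'
#' @param cells A `cell_table` with a `call_<channel>` column.
#' @param channel Channel name.
#' @return `list(fraction, positive, n)`.
#' @export
fraction_positive <- function(cells, channel) {
  ccol <- paste0("call_", channel)
  stopifnot(ccol %in% names(cells))
  if (!nrow(cells)) stop("empty cell table")
  list(fraction = mean(cells[[ccol]]), positive = sum(cells[[ccol]]),
       n = nrow(cells))
}

#' Response intensity versus distance to the nearest secretor
#'
#' For every non-secretor cell, computes the distance to the nearest
#' secretor-positive cell, bins the response intensity by that distance, and
#' reports the inhibition range: the innermost distance at which the binned
#' response crosses half of its range (linear interpolation), i.e. where the
#' response recovers from suppression around the secretors.
#'
#' @param cells A `cell_table` with a `call_<secretor_channel>` column and a
#'   response intensity column.
#' @param secretor_channel Secretor channel name.
#' @param response Response column (e.g. `"norm_pSMAD1"`).
#' @param bin_width Distance bin width (um).
#' @return `list(profile, inhibition_range_um, no_inhibition)`; `profile` is
#'   a data frame of distance bins with mean, sd, n.
#' @export
secretor_proximity <- function(cells, secretor_channel, response,
                               bin_width = 10) {
  scol <- paste0("call_", secretor_channel)
  stopifnot(scol %in% names(cells), response %in% names(cells))
  sec <- which(cells[[scol]])
  if (!length(sec)) stop("no secretor cells detected")
  oth <- setdiff(seq_len(nrow(cells)), sec)
  sx <- cells$x_um[sec]; sy <- cells$y_um[sec]
  d <- vapply(oth, function(i)
    sqrt(min((sx - cells$x_um[i])^2 + (sy - cells$y_um[i])^2)), numeric(1))
  v <- cells[[response]][oth]
  edges <- seq(0, max(d) + bin_width, by = bin_width)
  nb <- length(edges) - 1L
  bin <- findInterval(d, edges, rightmost.closed = TRUE, all.inside = TRUE)
  n <- tabulate(bin, nb)
  mu <- rep(NA_real_, nb); s <- rep(NA_real_, nb)
  gs <- split(v, factor(bin, levels = seq_len(nb)))
  mu[n > 0] <- vapply(gs[n > 0], mean, numeric(1))
  s[n > 1] <- vapply(gs[n > 1], sd, numeric(1))
  prof <- data.frame(bin_center_um = (edges[-1] + edges[-(nb + 1L)]) / 2,
                     mean = mu, sd = s, n = n)
  hc <- half_max_crossing_inward(prof$bin_center_um, prof$mean)
  if (hc$all_above)
    return(list(profile = prof, inhibition_range_um = 0,
                no_inhibition = TRUE))
  if (hc$none)
    return(list(profile = prof, inhibition_range_um = NA_real_,
                no_inhibition = FALSE))
  list(profile = prof, inhibition_range_um = hc$r, no_inhibition = FALSE)
}
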