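#' Otsu threshold of a numeric sample
#'
#' Histogram-based Otsu cut maximizing the between-class variance, applied to
#' a vector of values (per-cell normalized intensities, pixel intensities).
#' Returns the bin edge separating the two classes.
#'
#' @param x Numeric vector.
#' @param n_bins Number of histogram bins; the default scales with the
#'   sample size (`~2 sqrt(n)`, capped at 256) so that per-cell samples of a
#'   few hundred values get a smooth histogram while pixel samples keep full
#'   resolution.
#' @return The threshold value; values strictly above it belong to the upper
#'   class. For a constant input the common value is returned.
#' @export
otsu_threshold <- function(x, n_bins = NULL) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("need at least 2 finite values")
  if (is.null(n_bins))
    n_bins <- min(256L, max(32L, ceiling(2 * sqrt(length(x)))))
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, edges, rightmost.closed = TRUE,
                             all.inside = TRUE), n_bins)
  w <- h / sum(h)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  sb <- sb[-n_bins]
  # well-separated classes leave a plateau of maximal between-class
  # variance across the empty gap; cut in its middle
  top <- which(sb >= max(sb) - 1e-12 * abs(max(sb)))
  k <- top[ceiling(length(top) / 2)]
  edges[k + 1L]
}

#' Three-class Otsu thresholds
#'
#' Exhaustive two-threshold Otsu: picks the pair of cuts minimizing the
#' weighted within-class variance (equivalently maximizing the between-class
#' variance) of a three-class split of the value histogram. Used for the
#' joint-histogram germ-layer domain segmentation.
#'
#' @param x Numeric vector.
#' @param n_bins Number of histogram bins.
#' @return Numeric length-2 `(t1, t2)` with `t1 < t2`; classes are
#'   `x <= t1`, `t1 < x <= t2`, `x > t2`.
#' @export
multi_otsu3 <- function(x, n_bins = 128L) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) stop("need at least 3 finite values")
  rng <- range(x)
  if (diff(rng) == 0) stop("domains not separable: constant input")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, edges, rightmost.closed = TRUE,
                             all.inside = TRUE), n_bins)
  w <- h / sum(h)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  W <- c(0, cumsum(w))
  M <- c(0, cumsum(w * mids))
  # between-class variance of class over bins (a, b]
  cls <- function(a, b) {
    ww <- W[b + 1L] - W[a + 1L]
    mm <- M[b + 1L] - M[a + 1L]
    ifelse(ww > 0, mm^2 / ww, 0)
  }
  best <- -Inf; bk <- c(1L, 2L)
  for (k1 in 1:(n_bins - 2L)) {
    c1 <- cls(0L, k1)
    k2 <- (k1 + 1L):(n_bins - 1L)
    s <- c1 + cls(k1, k2) + cls(k2, n_bins)
    j <- which.max(s)
    if (s[j] > best) { best <- s[j]; bk <- c(k1, k2[j]) }
  }
  c(edges[bk[1] + 1L], edges[bk[2] + 1L])
}
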