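make_cells <- function(df, analysis_radius = 250, center = c(0, 0)) {
  attr(df, "analysis_radius") <- analysis_radius
  attr(df, "center_um") <- center
  class(df) <- c("cell_table", "data.frame")
  df
}

test_that("DAPI normalization is a per-cell ratio and drops zero-DAPI rows", {
  df <- make_cells(data.frame(id = 1:3, median_DAPI = c(0.5, 0.4, 0),
                              median_M = c(0.5, 0.8, 0.3)))
  expect_message(out <- normalize_to_dapi(df, "M"), "zero DAPI")
  expect_equal(nrow(out), 2)
  expect_equal(out$norm_M, c(1, 2))
  expect_equal(normalize_to_dapi(out, "DAPI")$norm_DAPI, c(1, 1))
})

test_that("the two-population fit recovers means, weights and a sane cut", {
  set.seed(42)
  v <- c(rnorm(500, 0.2, 0.05), rnorm(500, 0.8, 0.05))
  fit <- fit_binary_threshold(v)
  expect_true(fit$converged)
  expect_gt(fit$threshold, 0.4)  # brute-force Bayes boundary is 0.5
  expect_lt(fit$threshold, 0.6)
  expect_lt(abs(fit$means[1] - 0.2), 0.02)
  expect_lt(abs(fit$means[2] - 0.8), 0.02)
  # unbalanced mixture: high-class weight recovered
  v2 <- c(rnorm(800, 0.2, 0.05), rnorm(200, 0.8, 0.05))
  fit2 <- fit_binary_threshold(v2)
  expect_lt(abs(fit2$weights[2] - 0.2), 0.03)
  # degenerate unimodal sample is flagged
  fit3 <- fit_binary_threshold(rnorm(300, 0.5, 0.05))
  expect_false(fit3$converged)
  expect_error(fit_binary_threshold(rnorm(10)), "20 values")
})

test_that("positive calls use a strict threshold and match truth at zero noise", {
  df <- make_cells(data.frame(id = 1:3, norm_M = c(0.3, 0.5, 0.7)))
  out <- classify_positive(df, "M", 0.5)
  expect_identical(out$call_M, c(FALSE, FALSE, TRUE))  # tie is negative
  sp <- small_spec(seed = 31, intensity = exact_intensity(),
                   channel_models = list(M = chan_mixture(0.35)))
  g <- generate_colony_image(sp)
  tab <- classified_cells(g$image, "M")
  tr <- g$truth$nuclei
  cls <- tr$class_M[apply(
    cbind(tab$x_um, tab$y_um), 1,
    function(p) which.min((tr$x_um - p[1])^2 + (tr$y_um - p[2])^2))]
  expect_gte(mean(tab$call_M == cls), 0.995)
})

test_that("classification error stays within 2 points of the Bayes rate", {
  set.seed(7)
  n <- 4000
  truth <- runif(n) < 0.5
  delta <- 0.4
  sdv <- 0.25 * delta  # 4-sd class separation
  v <- ifelse(truth, rnorm(n, 0.4 + delta, sdv), rnorm(n, 0.4, sdv))
  # Monte-Carlo Bayes oracle: classify at the true midpoint boundary
  bayes_err <- mean((v > 0.4 + delta / 2) != truth)
  df <- make_cells(data.frame(id = seq_len(n), norm_M = v))
  out <- classify_positive(df, "M", fit_binary_threshold(v))
  err <- mean(out$call_M != truth)
  expect_lte(err, bayes_err + 0.02)
})

test_that("radial profiles are flat for uniform signal and conserve the mean", {
  sp <- small_spec(seed = 17, channel_models = list(M = chan_uniform()))
  g <- generate_colony_image(sp)
  tab <- segment_colony_cells(g$image)
  tab <- normalize_to_dapi(tab, "M")
  prof <- radial_profile(tab, "norm_M", bin_width = 10)
  mu <- prof$mean[prof$n >= 5]
  expect_lt(diff(range(mu)), 0.15 * mean(mu))
  # conservation: cell-count-weighted bin mean equals the global mean
  ok <- prof$n > 0
  expect_equal(sum(prof$mean[ok] * prof$n[ok]) / sum(prof$n),
               mean(tab$norm_M), tolerance = 1e-10)
  # empty bins are NA, never interpolated
  tiny <- make_cells(data.frame(id = 1:2, x_um = c(0, 1), y_um = c(0, 0),
                                norm_M = c(1, 2)), analysis_radius = 100)
  p2 <- radial_profile(tiny, "norm_M", center = c(0, 0), bin_width = 10)
  expect_true(all(is.na(p2$mean[p2$n == 0])))
})

test_that("edge-band scenes transition at the band edge in both modes", {
  sp <- scene_spec(seed = 23, intensity = exact_intensity(),
                   channel_models = list(M = chan_edge_band(80)))
  g <- generate_colony_image(sp)
  tab <- segment_colony_cells(g$image)
  tab <- normalize_to_dapi(tab, "M")
  prof <- radial_profile(tab, "norm_M", bin_width = 10)
  inner <- prof$mean[prof$bin_center_um < 150]
  outer_ <- prof$mean[prof$bin_center_um > 180]
  expect_lt(max(inner, na.rm = TRUE), min(outer_, na.rm = TRUE))
  # pixel mode on the nuclear mask agrees with the cell mode
  m <- get_channel(g$image, "M")
  dapi <- get_channel(g$image, "DAPI")
  # nuclear-core mask: erode away anti-aliased rims
  maskpx <- EBImage::erode(dapi > otsu_threshold(as.numeric(dapi)),
                           EBImage::makeBrush(3, "box"))
  pp <- radial_profile(m, center = g$image$center, analysis_radius = 250,
                       bin_width = 10, mask = maskpx)
  cellp <- radial_profile(tab, "median_M", bin_width = 10)
  # the bin straddling the band edge mixes the classes with mode-dependent
  # weights; compare the modes away from it
  ok <- cellp$n >= 5 & pp$n >= 50 & abs(cellp$bin_center_um - 170) > 10
  expect_lt(max(abs(pp$mean[ok] - cellp$mean[ok]) / cellp$mean[ok]), 0.05)
})

test_that("ring width is measured inward from the colony edge", {
  # analytic profile: low inside, high beyond 170 um
  mkprof <- function(r_on, R = 250) {
    bc <- seq(5, R - 5, by = 10)
    data.frame(bin_center_um = bc, mean = ifelse(bc < r_on, 0.4, 0.8),
               sd = 0.05, n = 30)
  }
  rw <- ring_width(mkprof(170), analysis_radius = 250)
  expect_false(rw$no_ring)
  expect_lt(abs(rw$width_um - 80), 10)
  # uniformly positive colony spans the whole analysis radius
  up <- mkprof(0)
  up$mean <- 0.8
  expect_equal(ring_width(up, 250)$width_um, 250)
  # monotonicity across true widths
  w <- vapply(c(40, 80, 120), function(wd)
    ring_width(mkprof(250 - wd), 250)$width_um, numeric(1))
  expect_true(all(diff(w) > 0))
  expect_error(ring_width(mkprof(170)[1:5, ], 250), "10 non-empty")
})

test_that("centre and edge groups summarize their own cells only", {
  df <- make_cells(data.frame(
    id = 1:40, x_um = 0, y_um = 0,
    radial_um = c(runif(20, 0, 90), runif(20, 210, 250)),
    norm_M = c(rep(0.4, 20), rep(0.8, 20))))
  s <- center_edge_summary(df, "norm_M", center_radius = 100, edge_band = 50)
  expect_equal(s$mean[s$group == "center"], 0.4)
  expect_equal(s$mean[s$group == "edge"], 0.8)
  expect_equal(s$n, c(20, 20))
  tiny <- make_cells(data.frame(id = 1:5, radial_um = runif(5, 0, 30),
                                norm_M = 1))
  expect_error(center_edge_summary(tiny, "norm_M"), "edge band")
  expect_error(center_edge_summary(df, "norm_M", center_radius = 220,
                                   edge_band = 50), "overlap")
})

test_that("fraction positive tracks the truth across mixture weights", {
  set.seed(11)
  for (frac in c(0.05, 0.2, 0.5, 0.8)) {
    n <- 1000
    truth <- runif(n) < frac
    v <- ifelse(truth, rnorm(n, 0.8, 0.05), rnorm(n, 0.4, 0.05))
    df <- make_cells(data.frame(id = seq_len(n), norm_M = v))
    df <- classify_positive(df, "M", fit_binary_threshold(v))
    expect_lt(abs(fraction_positive(df, "M")$fraction - frac), 0.03)
  }
  # all-negative with a supplied reference threshold
  neg <- make_cells(data.frame(id = 1:50, norm_M = rnorm(50, 0.4, 0.05)))
  neg <- classify_positive(neg, "M", 0.6)
  expect_equal(fraction_positive(neg, "M")$fraction, 0)
})

test_that("secretor distances use the nearest of several clusters", {
  # two clusters; brute-force all-pairs oracle
  set.seed(5)
  cells <- data.frame(id = 1:200,
                      x_um = runif(200, 0, 400), y_um = runif(200, 0, 400))
  cells$call_NOG <- FALSE
  cells$call_NOG[c(1, 2)] <- TRUE
  cells$x_um[1:2] <- c(50, 350); cells$y_um[1:2] <- c(50, 350)
  d_oracle <- pmin(
    sqrt((cells$x_um - 50)^2 + (cells$y_um - 50)^2),
    sqrt((cells$x_um - 350)^2 + (cells$y_um - 350)^2))[-(1:2)]
  cells$norm_R <- ifelse(c(0, 0, d_oracle) < 100, 0.4, 0.8)
  out <- secretor_proximity(make_cells(cells), "NOG", "norm_R",
                            bin_width = 10)
  expect_lt(abs(out$inhibition_range_um - 100), 10)
  expect_false(out$no_inhibition)
  # no suppression anywhere: range 0 with flag
  cells$norm_R <- 0.8
  out2 <- secretor_proximity(make_cells(cells), "NOG", "norm_R")
  expect_true(out2$no_inhibition)
  expect_equal(out2$inhibition_range_um, 0)
  cells$call_NOG <- FALSE
  expect_error(secretor_proximity(make_cells(cells), "NOG", "norm_R"),
               "no secretor")
})

test_that("normalize-then-classify is invariant to global intensity scale", {
  sp <- small_spec(seed = 19, channel_models = list(M = chan_mixture(0.3)))
  g <- generate_colony_image(sp)
  tab <- segment_colony_cells(g$image)
  scaled <- tab
  scaled$median_DAPI <- scaled$median_DAPI * 3.7
  scaled$median_M <- scaled$median_M * 3.7
  n1 <- normalize_to_dapi(tab, "M")
  n2 <- normalize_to_dapi(scaled, "M")
  c1 <- classify_positive(n1, "M", fit_binary_threshold(n1$norm_M))
  c2 <- classify_positive(n2, "M", fit_binary_threshold(n2$norm_M))
  expect_identical(c1$call_M, c2$call_M)
})
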