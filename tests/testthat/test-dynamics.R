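test_that("maximum projection collapses z and commutes with frame order", {
  a <- array(0, c(10, 10, 3))
  a[2, 2, 1] <- 1; a[8, 8, 3] <- 2
  p <- max_project(a)
  expect_equal(p[2, 2], 1)
  expect_equal(p[8, 8], 2)
  expect_identical(max_project(matrix(1:4, 2)), matrix(1:4, 2))
  fl <- list(a, a * 2)
  expect_identical(max_project(fl)[[2]], max_project(a * 2))
  expect_identical(rev(max_project(fl)), max_project(rev(fl)))
})

test_that("the reporter radius follows constant and shrinking schedules", {
  sp <- small_spec(seed = 4)
  const <- generate_timelapse(timescene_spec(4, 30, 80), sp)
  tr <- reporter_radius_trace(const)
  expect_lt(max(abs(tr$radius_um - 80)), 5)
  lin <- generate_timelapse(
    timescene_spec(10, 30, seq(110, 50, length.out = 10)), sp)
  tr2 <- reporter_radius_trace(lin)
  expect_lt(max(abs(tr2$radius_um - lin$truth$radius_schedule)), 5)
  expect_true(all(diff(tr2$radius_um) <= 2))  # monotone within jitter
  expect_equal(tr2$time_h, (0:9) * 0.5)
  # full-colony signal reaches the analysis radius (within one bin of the
  # rim, where packing thins out)
  full <- generate_timelapse(timescene_spec(3, 30, 120), sp)
  tr3 <- reporter_radius_trace(full)
  expect_true(all(tr3$radius_um > 110))
  expect_true(all(tr3$radius_um <= 120))
})

test_that("blank frames yield radius zero with a flag", {
  set.seed(1)
  blank <- array(pmax(rnorm(101 * 101, 0.05, 0.01), 0), c(101, 101, 1))
  dimnames(blank) <- list(NULL, NULL, "SOX2")
  tr <- reporter_radius_trace(
    list(frames = list(blank, blank, blank), center_um = c(50, 50),
         pixel_size = 1, analysis_radius = 50, frame_interval = 30))
  expect_true(all(tr$no_signal))
  expect_true(all(tr$radius_um == 0))
})

# grid colony: nuclei on a regular lattice, reporter controllable per frame
grid_frames <- function(nuc_values_by_frame, cyto = 0.05, spacing = 25,
                        n_side = 5, h2b = 0.5) {
  ctr <- expand.grid(x = spacing * (seq_len(n_side)) + 10,
                     y = spacing * (seq_len(n_side)) + 10)
  dimpx <- rep(spacing * (n_side + 1) + 21, 2)
  lapply(nuc_values_by_frame, function(v) {
    a <- array(0, c(dimpx, 2))
    a[, , 1] <- render_nuclei(dimpx, as.matrix(ctr), 5, h2b,
                              background = 0.02)
    a[, , 2] <- render_nuclei(dimpx, as.matrix(ctr), 5, v,
                              background = cyto)
    dimnames(a) <- list(NULL, NULL, c("H2B", "SOX2"))
    a
  })
}

test_that("uniform reporters give unit N:C and nuclear-only reporters high N:C", {
  fr <- grid_frames(list(0.3, 0.3))
  for (f in seq_along(fr)) fr[[f]][, , 2] <- 0.3  # uniform
  nc <- nc_ratio_trace(list(frames = fr, pixel_size = 1,
                            frame_interval = 30))
  expect_true(all(abs(nc$nc_ratio - 1) < 0.05))
  fr2 <- grid_frames(list(0.5, 0.5), cyto = 0.05)
  nc2 <- nc_ratio_trace(list(frames = fr2, pixel_size = 1,
                             frame_interval = 30))
  expect_true(all(nc2$nc_ratio > 3))
  # N:C is invariant to global reporter scaling
  fr3 <- lapply(fr2, function(a) { a[, , 2] <- a[, , 2] * 7; a })
  nc3 <- nc_ratio_trace(list(frames = fr3, pixel_size = 1,
                             frame_interval = 30))
  expect_equal(nc3$nc_ratio, nc2$nc_ratio, tolerance = 1e-10)
})

test_that("tracking keeps identities on well-separated nuclei", {
  fr <- grid_frames(list(0.4, 0.4, 0.4, 0.4))
  nc <- nc_ratio_trace(list(frames = fr, pixel_size = 1,
                            frame_interval = 30))
  # 25 lattice cells tracked through 4 frames, no extra identities
  expect_equal(length(unique(nc$cell)), 25)
  expect_equal(nrow(nc), 100)
  per_cell <- split(nc, nc$cell)
  expect_true(all(vapply(per_cell, function(d)
    max(abs(d$x_um - d$x_um[1])) < 1e-9, logical(1))))
})

test_that("an adaptive nuclear pulse appears in the cohort trace", {
  sched <- c(0.1, 0.2, 0.45, 0.3, 0.25, 0.25)
  fr <- grid_frames(as.list(sched), cyto = 0.1)
  nc <- nc_ratio_trace(list(frames = fr, pixel_size = 1,
                            frame_interval = 30))
  s <- summarize_nc_cohort(nc)
  expect_equal(which.max(s$mean), 3)          # peak at the scheduled frame
  expect_gt(s$mean[6], s$mean[1])             # plateau above baseline
  expect_equal(s$n, rep(25L, 6), ignore_attr = TRUE)
  # identical traces have zero spread
  same <- grid_frames(list(0.4, 0.4))
  ncs <- nc_ratio_trace(list(frames = same, pixel_size = 1,
                             frame_interval = 30))
  ss <- summarize_nc_cohort(ncs)
  expect_true(all(ss$sd < 1e-9))
})
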