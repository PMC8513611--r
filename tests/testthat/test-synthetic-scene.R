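test_that("noise-free colonies render the requested nuclei at class means", {
  sp <- small_spec(seed = 3, n_nuclei = 50, intensity = exact_intensity(),
                   channel_models = list(M = chan_mixture(0.4)))
  g <- generate_colony_image(sp)
  tr <- g$truth$nuclei
  expect_equal(nrow(tr), 50)
  # pixel at every nucleus centre carries exactly the class value
  ix <- round(tr$x_um) + 1L
  iy <- round(tr$y_um) + 1L
  dapi <- g$image$raster[, , "DAPI"]
  expect_true(all(abs(dapi[cbind(ix, iy)] - 0.5) < 1e-9))
  m <- g$image$raster[, , "M"]
  want <- ifelse(tr$class_M, 0.4, 0.2)
  expect_true(all(abs(m[cbind(ix, iy)] - want) < 1e-9))
  # minimum separation invariant
  d <- as.matrix(dist(tr[, c("x_um", "y_um")]))
  diag(d) <- Inf
  expect_gte(min(d), 1.6 * sp$nucleus_radius - 1e-9)
})

test_that("identical spec and seed reproduce scenes bit for bit", {
  sp <- small_spec(seed = 11, channel_models = list(M = chan_mixture(0.3)))
  g1 <- generate_colony_image(sp)
  g2 <- generate_colony_image(sp)
  expect_identical(g1$image$raster, g2$image$raster)
  expect_identical(g1$truth$nuclei, g2$truth$nuclei)
})

test_that("default packing density gives the expected per-colony cell count", {
  sp <- scene_spec(seed = 1)  # r = 250 um, default density
  g <- generate_colony_image(sp)
  expect_gte(nrow(g$truth$nuclei), 683)
  expect_lte(nrow(g$truth$nuclei), 785)
})

test_that("infeasible packing fails and names the achievable maximum", {
  sp <- scene_spec(colony_radius = 30, n_nuclei = 200, seed = 1)
  expect_error(generate_colony_image(sp), "infeasible packing.*placed")
})

test_that("multicolony fields carry truth for every colony and merged pairs", {
  sp <- small_spec(seed = 5, colony_radius = 80,
                   channel_models = list(SOX2 = chan_central_disc(50)))
  f <- generate_multicolony_field(sp, cbind(c(0, 300, 0), c(0, 0, 300)))
  expect_equal(nrow(f$truth$colonies), 3)
  expect_false(any(f$truth$colonies$merged))
  fm <- generate_multicolony_field(sp, cbind(0, 0), include_merged = TRUE)
  expect_equal(sum(fm$truth$colonies$merged), 2)
  expect_length(fm$truth$merged_pair, 2)
  # an unintentionally overlapping layout is refused
  expect_error(
    generate_multicolony_field(sp, cbind(c(0, 100), c(0, 0))),
    "overlap")
})

test_that("tiling and re-stitching reproduce the single-shot field", {
  sp <- small_spec(seed = 7, colony_radius = 80)
  f <- generate_multicolony_field(sp, cbind(c(0, 250), c(0, 120)))
  tl <- tile_field(f$field, 2, 2, overlap = 0.1)
  st <- stitch_tiles(tl$tiles, tl$grid)
  expect_equal(dim(st$raster), dim(f$field$raster))
  expect_lt(max(abs(st$raster - f$field$raster)), 1e-9)
  # 0% overlap is pure concatenation
  tl0 <- tile_field(f$field, 2, 2, overlap = 0)
  st0 <- stitch_tiles(tl0$tiles, tl0$grid)
  expect_lt(max(abs(st0$raster - f$field$raster)), 1e-9)
})

test_that("transwell sheets honour exact positive counts and suppression zones", {
  sp <- scene_spec(n_nuclei = 300, seed = 9)
  tw0 <- generate_transwell_field(sp, n_positive = 0, field_dim = c(350, 350))
  expect_equal(sum(tw0$truth$nuclei$positive), 0)
  tw <- generate_transwell_field(sp, n_positive = 60, field_dim = c(350, 350))
  expect_equal(tw$truth$fraction_positive, 0.2)
  # suppression: brute-force distance check on the truth
  tws <- generate_transwell_field(
    sp, n_positive = 0, field_dim = c(350, 350),
    secretors = list(center = c(175, 175), suppression_distance = 60))
  tr <- tws$truth$nuclei
  sec <- tr[tr$secretor, ]
  d <- vapply(seq_len(nrow(tr)), function(i)
    sqrt(min((sec$x_um - tr$x_um[i])^2 + (sec$y_um - tr$y_um[i])^2)),
    numeric(1))
  expect_identical(tr$positive, d >= 60)
})

test_that("time-lapse frames share placements and span the stated course", {
  sp <- small_spec(seed = 2, colony_radius = 40,
                   intensity = exact_intensity())
  ts <- timescene_spec(n_frames = 101, frame_interval = 30,
                       radius_schedule = 30)
  tl <- generate_timelapse(ts, sp)
  expect_equal(length(tl$frames), 101)
  expect_equal(tl$time_h[101], 50)  # 101 frames every 30 min span 50 h
  expect_identical(tl$truth$radius_schedule, rep(30, 101))
  # constant schedule + zero noise: frames identical
  expect_identical(tl$frames[[1]], tl$frames[[60]])
  expect_error(
    generate_timelapse(timescene_spec(5, 30, 60), sp),
    "radius_schedule exceeds")
})

test_that("z-stacks place channels at their stated offsets from the surface", {
  sp <- scene_spec(seed = 4)
  zs <- zscene_spec(z_planes = 21, z_step = 1, apical_base = 9,
                    channel_offsets = list(A0 = list(offsets = 0),
                                           A5 = list(offsets = 5)),
                    gap_patches = data.frame(x_um = 20, y_um = 20, r_um = 8),
                    lateral_dim = c(60, 60))
  g <- generate_zstack(zs, sp)
  # zero offset: channel z-profile peaks on the apical surface
  i <- 40; j <- 40
  prof <- g$stack$channels$A0[i, j, ]
  expect_lt(abs(which.max(prof) - 1 - g$truth$surface_um[i, j]), 1)
  expect_true(all(g$truth$offsets_um$A5 == 5))
  # ZO-1 integral over the gap patch is at background level
  tot <- apply(g$stack$channels$ZO1, c(1, 2), sum)
  in_gap <- tot[21, 21]   # patch centre (20, 20) um
  outside <- median(tot)
  expect_lt(in_gap, 0.35 * outside)
})
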