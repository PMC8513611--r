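test_that("TEER per unit area is the control-subtracted linear form", {
  out <- teer_unit_area(1500, 300, 0.33)
  expect_equal(out$teer_ohm_cm2, 396)
  expect_false(out$warning)
  expect_equal(teer_unit_area(300, 300, 0.33)$teer_ohm_cm2, 0)
  # linear in area and in the resistance difference
  expect_equal(teer_unit_area(1500, 300, 0.165)$teer_ohm_cm2, 198)
  expect_equal(teer_unit_area(900, 300, 0.33)$teer_ohm_cm2, 396 / 2)
  expect_warning(out2 <- teer_unit_area(200, 300, 0.33), "below control")
  expect_true(out2$warning)
})

qpcr_table <- function(folds, noise_sd = 0, n_samples = 3, n_tech = 4,
                       seed = 1) {
  set.seed(seed)
  rows <- NULL
  for (tp in seq_along(folds)) for (s in seq_len(n_samples)) {
    base_ref <- 20
    base_gene <- 25
    for (r in seq_len(n_tech)) {
      rows <- rbind(rows,
        data.frame(sample = sprintf("s%d_t%d", s, tp), gene = "GAPDH",
                   condition = "A", timepoint = tp - 1,
                   ct = base_ref + rnorm(1, 0, noise_sd)),
        data.frame(sample = sprintf("s%d_t%d", s, tp), gene = "EOMES",
                   condition = "A", timepoint = tp - 1,
                   ct = base_gene - log2(folds[tp]) + rnorm(1, 0, noise_sd)))
    }
  }
  rows
}

test_that("delta-delta-Ct recovers known fold changes", {
  tab <- qpcr_table(c(1, 2, 8))
  out <- qpcr_fold_change(tab, "GAPDH", baseline_condition = "A",
                          baseline_timepoint = 0)
  expect_equal(out$fold[out$timepoint == 0], 1)
  expect_equal(out$fold[out$timepoint == 1], 2)
  expect_equal(out$fold[out$timepoint == 2], 8)
  # noisy Ct values: folds within 15%
  tabn <- qpcr_table(c(1, 2, 8), noise_sd = 0.2, seed = 3)
  outn <- qpcr_fold_change(tabn, "GAPDH", "A", 0)
  for (tp in 0:2)
    expect_lt(abs(outn$fold[outn$timepoint == tp] - c(1, 2, 8)[tp + 1]) /
              c(1, 2, 8)[tp + 1], 0.15)
  # a ddCt of -1 doubles expression
  t2 <- data.frame(sample = rep(c("a", "b"), each = 2),
                   gene = rep(c("GAPDH", "G1"), 2),
                   condition = c("A", "A", "B", "B"),
                   timepoint = 0, ct = c(20, 25, 20, 24))
  o2 <- qpcr_fold_change(t2, "GAPDH", "A", 0)
  expect_equal(o2$fold[o2$condition == "B"], 2)
  # samples missing the reference gene are dropped with a message
  t3 <- rbind(t2, data.frame(sample = "c", gene = "G1", condition = "B",
                             timepoint = 0, ct = 23))
  expect_message(qpcr_fold_change(t3, "GAPDH", "A", 0), "dropped")
})

test_that("group comparisons delegate to the standard rank tests", {
  x <- c(1, 2, 3, 4, 5)
  out <- compare_groups(c(x, x), rep(c("a", "b"), each = 5))
  expect_match(out$test, "Wilcoxon")
  expect_gt(out$p_value, 0.5)
  set.seed(2)
  a <- rnorm(50); b <- rnorm(50, 5)
  out2 <- compare_groups(c(a, b), rep(c("a", "b"), each = 50))
  expect_lt(out2$p_value, 0.001)
  out3 <- compare_groups(c(a, b, rnorm(50, 10)),
                         rep(c("a", "b", "c"), each = 50))
  expect_match(out3$test, "Kruskal")
  expect_equal(nrow(out3$posthoc), 3)
  expect_error(compare_groups(c(1, 2, 1, 2, 3), c("a", "a", "b", "b", "b")),
               "n < 3")
  # parametric two-group design
  out4 <- compare_groups(c(a, b), rep(c("a", "b"), each = 50),
                         parametric = TRUE)
  expect_match(out4$test, "t-test")
})

test_that("the pipeline quantifies a simulated chip end to end, reproducibly", {
  sp <- small_spec(seed = 33, colony_radius = 80,
                   channel_models = list(SOX2 = chan_central_disc(55)))
  lay <- as.matrix(expand.grid(x = c(0, 280, 560), y = c(0, 280)))
  f <- generate_multicolony_field(sp, lay)
  cfg <- list(channels = list(dapi = "DAPI", markers = "SOX2"),
              expected_radius = 80, analysis_radius = 80)
  out <- run_pipeline(cfg, field = f$field)
  expect_equal(nrow(out$summary), 6)
  expect_equal(sum(out$manifest$status == "accepted"), 6)
  # SOX2 fraction close to the geometric truth for every colony
  truth_frac <- vapply(split(f$truth$nuclei$class_SOX2,
                             f$truth$nuclei$colony), mean, numeric(1))
  expect_lt(max(abs(sort(out$summary$fraction_SOX2) - sort(truth_frac))),
            0.06)
  # a second run is bit-identical
  out2 <- run_pipeline(cfg, field = f$field)
  expect_identical(out$summary, out2$summary)
  # misconfigured channel role fails before any computation
  bad <- cfg; bad$channels$markers <- "BRA"
  expect_error(run_pipeline(bad, field = f$field), "absent")
  expect_error(run_pipeline(list(channels = cfg$channels), field = f$field),
               "missing entry")
  # on-disk outputs
  od <- tempfile()
  run_pipeline(cfg, field = f$field, out_dir = od)
  expect_true(file.exists(file.path(od, "colony_summary.csv")))
  man <- jsonlite::read_json(file.path(od, "manifest.json"))
  expect_equal(man$package, "colonyquant")
  unlink(od, recursive = TRUE)
})
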