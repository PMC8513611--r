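#' Transepithelial resistance per unit membrane area
#'
#' Subtracts the mean no-cell control resistance from the sample resistance
#' and scales by the membrane area: `(sample - control) * area`, in
#' Ohm * cm^2. A sample below control yields a negative value with a
#' warning flag.
#'
#' @param sample_ohm Sample resistance (Ohm).
#' @param control_ohm Control (laminin-only well) resistance (Ohm); a vector
#'   is averaged.
#' @param area_cm2 Membrane area (cm^2).
#' @return `list(teer_ohm_cm2, warning)`.
#' @export
teer_unit_area <- function(sample_ohm, control_ohm, area_cm2) {
  stopifnot(area_cm2 > 0, sample_ohm > 0, all(control_ohm > 0))
  ctrl <- mean(control_ohm)
  warn <- sample_ohm < ctrl
  if (warn) warning("sample resistance below control")
  list(teer_ohm_cm2 = (sample_ohm - ctrl) * area_cm2, warning = warn)
}

#' Delta-delta-Ct fold changes with double normalization
#'
#' Technical replicates are averaged on the Ct scale first. Per sample,
#' `dCt = Ct(gene) - Ct(reference gene)`; per (gene, condition, timepoint),
#' `ddCt = mean(dCt) - mean(dCt at the baseline condition/timepoint)` and
#' `fold = 2^-ddCt` (efficiency-2 arithmetic). The spread over biological
#' samples is propagated on the log2 scale.
#'
#' @param table Data frame with columns `sample`, `gene`, `condition`,
#'   `timepoint`, `ct` (and optionally `replicate` for technical
#'   replicates).
#' @param reference_gene Internal normalizer (e.g. `"GAPDH"`).
#' @param baseline_condition,baseline_timepoint The pre-stimulus baseline
#'   whose mean dCt defines fold = 1 for each gene.
#' @return Data frame (gene, condition, timepoint, fold, log2_fold,
#'   sd_log2, n).
#' @export
qpcr_fold_change <- function(table, reference_gene = "GAPDH",
                             baseline_condition, baseline_timepoint = 0) {
  need <- c("sample", "gene", "condition", "timepoint", "ct")
  stopifnot(all(need %in% names(table)), all(table$ct > 0))
  # Ct first: average technical replicates per (sample, gene, cond, time)
  agg <- aggregate(ct ~ sample + gene + condition + timepoint, table, mean)
  ref <- agg[agg$gene == reference_gene, ]
  names(ref)[names(ref) == "ct"] <- "ct_ref"
  ref$gene <- NULL
  m <- merge(agg[agg$gene != reference_gene, ], ref,
             by = c("sample", "condition", "timepoint"))
  dropped <- setdiff(unique(agg$sample[agg$gene != reference_gene]),
                     unique(m$sample))
  if (length(dropped))
    message("sample(s) without reference gene dropped: ",
            paste(dropped, collapse = ", "))
  m$dct <- m$ct - m$ct_ref
  out <- NULL
  for (g in unique(m$gene)) {
    mg <- m[m$gene == g, ]
    base <- mg$dct[mg$condition == baseline_condition &
                   mg$timepoint == baseline_timepoint]
    if (!length(base))
      stop("no baseline rows for gene ", g)
    b <- mean(base)
    for (key in split(mg, interaction(mg$condition, mg$timepoint,
                                      drop = TRUE))) {
      ddct <- key$dct - b
      out <- rbind(out, data.frame(
        gene = g, condition = key$condition[1],
        timepoint = key$timepoint[1],
        fold = 2^(-mean(ddct)), log2_fold = -mean(ddct),
        sd_log2 = if (nrow(key) > 1) sd(-ddct) else NA_real_,
        n = nrow(key)))
    }
  }
  rownames(out) <- NULL
  out[order(out$gene, out$condition, out$timepoint), ]
}

#' Compare intensity or area measurements between groups
#'
#' Thin delegation to the standard tests: two groups use a two-sided
#' rank-sum (Mann-Whitney) test or an unpaired two-tailed t-test; three or
#' more use Kruskal-Wallis followed by pairwise rank-sum post-hoc tests
#' with Holm adjustment. No statistics are computed in-package.
#'
#' @param values Numeric vector of measurements.
#' @param group Grouping factor/vector, each group with n >= 3.
#' @param parametric Use t-test for the two-group design?
#' @return `list(test, statistic, p_value, posthoc, summaries)`; `posthoc`
#'   is a data frame of pairwise comparisons (multi-group only).
#' @export
compare_groups <- function(values, group, parametric = FALSE) {
  group <- factor(group)
  stopifnot(length(values) == length(group))
  ns <- table(group)
  if (length(ns) < 2L) stop("need at least 2 groups")
  if (any(ns < 3L))
    stop("group(s) with n < 3: ", paste(names(ns)[ns < 3], collapse = ", "))
  summaries <- data.frame(group = names(ns), n = as.integer(ns),
                          mean = as.numeric(tapply(values, group, mean)),
                          median = as.numeric(tapply(values, group, median)),
                          sd = as.numeric(tapply(values, group, sd)))
  if (length(ns) == 2L) {
    ht <- if (parametric) t.test(values ~ group)
          else wilcox.test(values ~ group, exact = FALSE)
    return(list(test = ht$method, statistic = unname(ht$statistic),
                p_value = ht$p.value, posthoc = NULL,
                summaries = summaries))
  }
  kw <- kruskal.test(values, group)
  pw <- pairwise.wilcox.test(values, group, p.adjust.method = "holm",
                             exact = FALSE)
  idx <- which(!is.na(pw$p.value), arr.ind = TRUE)
  posthoc <- data.frame(
    group1 = rownames(pw$p.value)[idx[, 1]],
    group2 = colnames(pw$p.value)[idx[, 2]],
    p_adj = pw$p.value[idx])
  list(test = kw$method, statistic = unname(kw$statistic),
       p_value = kw$p.value, posthoc = posthoc, summaries = summaries)
}

#' Run the colony quantification pipeline on a field
#'
#' Orchestrates detect -> filter -> extract -> segment -> normalize ->
#' classify for every accepted colony of a field and reports per-colony
#' marker fractions, with an exclusion log and a manifest. The
#' configuration is a list (or YAML file path) with entries:
#' `channels` (named roles, must include `dapi` and `markers`),
#' `expected_radius`, `analysis_radius`, `nucleus_radius`, and optionally
#' `background_window`.
#'
#' @param config List or path to a YAML file.
#' @param field A [field_image]; alternatively `config$field_tiff` names a
#'   TIFF written by [write_field_tiff()].
#' @param out_dir Optional output directory: writes per-colony cell tables
#'   (CSV), a colony summary CSV and a JSON manifest.
#' @return `list(summary, manifest, cells)`: `summary` is a per-colony data
#'   frame with status and per-marker positive fractions; `cells` the list
#'   of accepted colonies' cell tables.
#' @export
run_pipeline <- function(config, field = NULL, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (need in c("channels", "expected_radius", "analysis_radius"))
    if (is.null(config[[need]])) stop("config missing entry: ", need)
  if (is.null(config$channels$dapi) || is.null(config$channels$markers))
    stop("config$channels must name 'dapi' and 'markers' roles")
  if (is.null(field)) {
    if (is.null(config$field_tiff)) stop("no field given")
    field <- read_field_tiff(config$field_tiff)
  }
  if (!all(c(config$channels$dapi, config$channels$markers) %in%
           field$channel_names))
    stop("configured channels absent from field: ",
         paste(setdiff(c(config$channels$dapi, config$channels$markers),
                       field$channel_names), collapse = ", "))
  nucleus_radius <- config$nucleus_radius %||% 5
  if (!is.null(config$background_window))
    field <- correct_background(field, config$background_window,
                                nucleus_radius)
  regions <- detect_colonies(field, config$expected_radius,
                             dapi = config$channels$dapi,
                             nucleus_radius = nucleus_radius)
  regions <- filter_colonies(regions, config$expected_radius)
  manifest <- colony_manifest(regions)
  cells <- list(); rows <- NULL
  for (i in seq_along(regions)) {
    rg <- regions[[i]]
    if (!identical(rg$status, "accepted")) next
    colony <- extract_colony(field, rg, config$analysis_radius)
    tab <- segment_colony_cells(colony, nucleus_radius,
                                dapi = config$channels$dapi)
    row <- data.frame(colony = i, n_cells = nrow(tab))
    for (mk in config$channels$markers) {
      tab <- normalize_to_dapi(tab, mk, dapi = config$channels$dapi)
      fit <- fit_binary_threshold(tab[[paste0("norm_", mk)]])
      tab <- classify_positive(tab, mk, fit)
      row[[paste0("fraction_", mk)]] <- fraction_positive(tab, mk)$fraction
    }
    cells[[as.character(i)]] <- tab
    rows <- rbind(rows, row)
  }
  out <- list(summary = rows, manifest = manifest, cells = cells)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    f <- file.path(out_dir, "colony_manifest.csv")
    write.csv(manifest, f, row.names = FALSE); files <- c(files, f)
    if (!is.null(rows)) {
      f <- file.path(out_dir, "colony_summary.csv")
      write.csv(rows, f, row.names = FALSE); files <- c(files, f)
    }
    for (nm in names(cells)) {
      f <- file.path(out_dir, sprintf("cells_colony%s.csv", nm))
      write.csv(as.data.frame(cells[[nm]]), f, row.names = FALSE)
      files <- c(files, f)
    }
    jsonlite::write_json(
      list(package = "colonyquant",
           version = as.character(packageVersion("colonyquant")),
           config = config[setdiff(names(config), "field")],
           excluded = manifest[manifest$status == "rejected",
                               c("id", "reason")],
           files = basename(files)),
      file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
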