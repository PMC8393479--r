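#' Pipeline configuration
#'
#' Collects every tunable criterion in one object. The edge margin defaults
#' to 0 here because synthetic sections have no slide-edge artifact; for
#' scanned slides 100 um is the recommended margin (see [exclude_edge()]).
#'
#' @param vessel a [vessel_criteria()].
#' @param hb an [hb_criteria()].
#' @param neuron a [neuron_criteria()].
#' @param inclusion an [inclusion_criteria()].
#' @param leak_window_um,leak_k,leak_min_area_um2 [leakage_mask()]
#'   parameters.
#' @param leak_rule,leak_overlap_frac [classify_vessel_leakage()] rule.
#' @param edge_margin_um margin removed by [exclude_edge()] before any
#'   quantification (0 disables).
#' @export
quant_config <- function(vessel = vessel_criteria(), hb = hb_criteria(),
                         neuron = neuron_criteria(),
                         inclusion = inclusion_criteria(),
                         leak_window_um = 200, leak_k = 2,
                         leak_min_area_um2 = 300,
                         leak_rule = "centroid", leak_overlap_frac = 0.5,
                         edge_margin_um = 0) {
  structure(list(vessel = vessel, hb = hb, neuron = neuron,
                 inclusion = inclusion, leak_window_um = leak_window_um,
                 leak_k = leak_k, leak_min_area_um2 = leak_min_area_um2,
                 leak_rule = leak_rule, leak_overlap_frac = leak_overlap_frac,
                 edge_margin_um = edge_margin_um),
            class = "quant_config")
}

#' Quantify one section
#'
#' Runs the full vessel-centric pipeline on a section: vessel detection,
#' gray/white hemoglobin scores, adaptive leakage mask and leaked/non-leaked
#' classification, motor-neuron and inclusion counts (when the channels are
#' present), and area normalization. `hb_total` is the area-weighted
#' combination of the gray and white scores (integrated intensity over the
#' whole tissue per mm^2).
#'
#' @param image a `section_image` with at least `lectin` and `hemoglobin`
#'   channels.
#' @param regions the section's `region_set`.
#' @param config a [quant_config()].
#' @return one-row data.frame of section scalars.
#' @export
quantify_section <- function(image, regions, config = quant_config()) {
  stopifnot(inherits(image, "section_image"), inherits(regions, "region_set"))
  px <- image$pixel_size_um
  if (config$edge_margin_um > 0) {
    regions <- exclude_edge(regions, config$edge_margin_um, px)
  }
  ch <- image$channels
  stopifnot(all(c("lectin", "hemoglobin") %in% names(ch)))

  vessels <- detect_vessels(ch$lectin, regions, config$vessel, px)
  gm <- gm_hb_score(ch$hemoglobin, vessels, regions, config$hb, px)
  wm <- wm_hb_score(ch$hemoglobin, regions, config$hb, px)
  gm_area <- mask_area_mm2(region_mask(regions, "gray"), px)
  wm_area <- mask_area_mm2(region_mask(regions, "white"), px)
  hb_total <- (gm * gm_area + wm * wm_area) / (gm_area + wm_area)

  lmask <- leakage_mask(ch$hemoglobin, regions, px,
                        window_um = config$leak_window_um, k = config$leak_k,
                        min_area_um2 = config$leak_min_area_um2)
  vessels <- classify_vessel_leakage(vessels, lmask, rule = config$leak_rule,
                                     overlap_frac = config$leak_overlap_frac)

  neuron_count <- NA_integer_; neuron_density <- NA_real_
  if ("smi32" %in% names(ch)) {
    mn <- count_motor_neurons(ch$smi32, regions, config$neuron, px)
    neuron_count <- mn$count; neuron_density <- mn$density_per_mm2
  }
  inclusion_count <- NA_integer_; load <- NA_real_
  if ("ptdp43" %in% names(ch)) {
    inclusion_count <- count_inclusions(ch$ptdp43, regions, config$inclusion,
                                        px)
    load <- if (!is.na(neuron_count)) {
      suppressWarnings(inclusion_load(inclusion_count, neuron_count))
    } else NA_real_
  }

  data.frame(
    case = image$case, level = image$level, section = image$section,
    gm_hb = gm, wm_hb = wm, hb_total = hb_total,
    gm_vessel_density = vessel_density(vessels$records, regions, "gray", px),
    wm_vessel_density = vessel_density(vessels$records, regions, "white", px),
    neuron_count = neuron_count, neuron_density = neuron_density,
    inclusion_count = inclusion_count, inclusion_load = load,
    leaked_vessel_count = sum(vessels$records$leaked, na.rm = TRUE),
    total_vessel_count = nrow(vessels$records),
    stringsAsFactors = FALSE
  )
}

#' Quantify every section of a cohort
#'
#' @param cohort result of [generate_cohort()], or a directory containing a
#'   `manifest.csv` written by it.
#' @param config a [quant_config()].
#' @return data.frame of [quantify_section()] rows in manifest order.
#' @export
quantify_cohort <- function(cohort, config = quant_config()) {
  if (is.character(cohort)) {
    manifest <- read.csv(file.path(cohort, "manifest.csv"))
    rows <- lapply(seq_len(nrow(manifest)), function(i) {
      img <- read_section(manifest$path[i])
      reg <- read_regions(sub("\\.tif$", "_regions.tif", manifest$path[i]))
      quantify_section(img, reg, config)
    })
  } else {
    rows <- lapply(cohort$sections, function(sec) {
      quantify_section(sec$image, sec$truth$regions, config)
    })
  }
  do.call(rbind, rows)
}

#' Per-section NVU marker means in leaked and non-leaked vessels
#'
#' Detects vessels, classifies them against the leakage mask, measures the
#' per-vessel marker mean inside the requested vessel-compartment mask, and
#' averages over the four leak-status x gray/white groups.
#'
#' @param image section with `lectin`, `hemoglobin` and `marker` channels.
#' @param regions the section's `region_set`.
#' @param marker channel name (default `"nvu"`).
#' @param mask_kind `"vascular"`, `"perivascular"` or `"glia_limitans"`.
#' @param intensity_window absolute-intensity window for qualifying pixels.
#' @param config a [quant_config()].
#' @return data.frame from [nvu_group_means()].
#' @export
nvu_section_means <- function(image, regions, marker = "nvu",
                              mask_kind = "glia_limitans",
                              intensity_window = c(-Inf, Inf),
                              config = quant_config()) {
  px <- image$pixel_size_um
  ch <- image$channels
  stopifnot(marker %in% names(ch))
  vessels <- detect_vessels(ch$lectin, regions, config$vessel, px)
  lmask <- leakage_mask(ch$hemoglobin, regions, px,
                        window_um = config$leak_window_um, k = config$leak_k,
                        min_area_um2 = config$leak_min_area_um2)
  vessels <- classify_vessel_leakage(vessels, lmask, rule = config$leak_rule,
                                     overlap_frac = config$leak_overlap_frac)
  vessels <- per_vessel_marker_intensity(ch[[marker]], vessels, mask_kind,
                                         intensity_window, px)
  nvu_group_means(vessels$records)
}

#' Aggregate section results to case-level values
#'
#' @param results data.frame of [quantify_section()] rows.
#' @param metadata data.frame with `case` and `group` columns.
#' @param variables result columns to aggregate.
#' @return long data.frame: `case`, `group`, `level`, `variable`, `value`,
#'   `n_sections`.
#' @export
aggregate_sections <- function(results, metadata,
                               variables = c("gm_hb", "wm_hb", "hb_total",
                                             "gm_vessel_density",
                                             "wm_vessel_density",
                                             "neuron_density",
                                             "inclusion_load")) {
  stopifnot(all(c("case", "group") %in% names(metadata)))
  variables <- intersect(variables, names(results))
  out <- list()
  for (v in variables) {
    if (all(is.na(results[[v]]))) next
    agg <- stats::aggregate(results[[v]],
                            by = list(case = results$case,
                                      level = results$level),
                            FUN = function(x) {
                              x <- x[!is.na(x)]
                              if (!length(x)) return(c(NA_real_, 0))
                              a <- aggregate_case(x)
                              c(a$value, a$n)
                            })
    out[[v]] <- data.frame(case = agg$case, level = agg$level, variable = v,
                           value = agg$x[, 1], n_sections = agg$x[, 2])
  }
  if (!length(out)) stop("no aggregatable variables in results")
  long <- do.call(rbind, out)
  rownames(long) <- NULL
  long$group <- metadata$group[match(long$case, metadata$case)]
  long[order(long$variable, long$case, long$level), ]
}

#' Run the full cohort comparison battery
#'
#' Aggregates sections to cases, applies the one-pass Grubbs screen (alpha
#' 0.2) to the control cohort on motor-neuron density and total hemoglobin
#' (the flagged case, if any, is excluded from every table), then runs one
#' analysis per readout: two-way group x level ANOVA with Sidak
#' (group-at-each-level, m = number of levels) and Tukey (levels within
#' group) post-test families for the hemoglobin scores, vessel densities and
#' neuron density; a Welch t-test on the pooled inclusion load; a one-way
#' Tukey ANOVA of inclusion load across levels within the disease group; and
#' optionally a repeated-measures two-way ANOVA with Sidak post-tests on NVU
#' marker means in leaked vs non-leaked vessels.
#'
#' @param results data.frame of section rows ([quantify_section()]).
#' @param metadata data.frame with `case`, `group` (`"control"` / `"ALS"`).
#' @param nvu optional data.frame `case`, `compartment`, `leaked`,
#'   `mean_intensity` for the NVU comparison.
#' @param grubbs_alpha alpha for the control-cohort outlier screen.
#' @return list with `tables` (named list of test results), `excluded_case`,
#'   `cohort_n` (per-group case counts after exclusion), `case_values` (the
#'   aggregated data all tables used).
#' @export
run_cohort_battery <- function(results, metadata, nvu = NULL,
                              grubbs_alpha = 0.2) {
  long <- aggregate_sections(results, metadata)
  ctrl_name <- "control"

  ## Grubbs screen on the control cohort, one pass per screening variable
  excluded <- character(0)
  for (v in intersect(c("neuron_density", "hb_total"),
                      unique(long$variable))) {
    dd <- long[long$variable == v & long$group == ctrl_name, ]
    if (!nrow(dd)) next
    per_case <- tapply(dd$value, dd$case, mean, na.rm = TRUE)
    per_case <- per_case[is.finite(per_case)]
    if (length(per_case) >= 3) {
      g <- grubbs_outlier(as.numeric(per_case), alpha = grubbs_alpha)
      if (!is.na(g$index)) excluded <- union(excluded,
                                             names(per_case)[g$index])
    }
  }
  keep <- !(long$case %in% excluded)
  long <- long[keep, ]

  tables <- list()
  two_way_vars <- intersect(c("hb_total", "gm_hb", "wm_hb",
                              "gm_vessel_density", "wm_vessel_density",
                              "neuron_density"), unique(long$variable))
  for (v in two_way_vars) {
    dd <- long[long$variable == v & is.finite(long$value), ]
    cases_complete <- names(which(tapply(dd$level, dd$case,
                                         function(x) length(unique(x))) ==
                                  length(unique(dd$level))))
    dd <- dd[dd$case %in% cases_complete, ]
    if (length(unique(dd$group)) >= 2 && length(unique(dd$level)) >= 2) {
      tab <- tryCatch(
        two_way_anova(dd, "value", "group", "level", posthoc = "both"),
        error = function(e) {
          warning("'", v, "' table skipped: ", conditionMessage(e))
          NULL
        }
      )
      if (!is.null(tab)) tables[[v]] <- tab
    }
  }
  if ("inclusion_load" %in% long$variable) {
    dd <- long[long$variable == "inclusion_load" & is.finite(long$value), ]
    pooled <- stats::aggregate(value ~ case + group, data = dd, FUN = mean)
    grp <- split(pooled$value, pooled$group)
    if (length(grp) == 2 && all(lengths(grp) >= 2)) {
      tables$inclusion_load_pooled <- welch_t(grp[[ctrl_name]],
                                              grp[[setdiff(names(grp),
                                                           ctrl_name)]])
    }
    als <- dd[dd$group != ctrl_name, ]
    if (length(unique(als$level)) >= 2) {
      tables$inclusion_load_levels <- one_way_anova(als, "value", "level")
    }
  }
  if (!is.null(nvu)) {
    nvu_ok <- nvu[is.finite(nvu$mean_intensity), ]
    tables$nvu <- two_way_anova(nvu_ok, "mean_intensity", "leaked",
                                "compartment", posthoc = "sidak",
                                repeated = "both", subject = "case")
  }
  cohort_n <- table(unique(long[, c("case", "group")])$group)
  list(tables = tables, excluded_case = excluded,
       cohort_n = as.list(cohort_n), case_values = long)
}

#' Design table for a two-arm cohort with a level-specific leak amplitude
#'
#' Convenience builder for simulation studies: control cases leak uniformly
#' at a low rate; disease-arm cases leak more, with the thoracic amplitude
#' scaled by `thoracic_factor` (1 = null cohort).
#'
#' @param n_control,n_als cases per arm.
#' @param thoracic_factor multiplier on `leak_amplitude` at the thoracic
#'   level of the disease arm.
#' @param leak_amplitude halo rim intensity shared by all other levels.
#' @param control_leak_fraction,als_leak_fraction leaked-vessel fractions.
#' @param sections_per_level sections rendered per case and level.
#' @return data.frame accepted by [generate_cohort()].
#' @export
leakage_cohort_design <- function(n_control = 3, n_als = 5,
                                  thoracic_factor = 2, leak_amplitude = 150,
                                  control_leak_fraction = 0.15,
                                  als_leak_fraction = 0.3,
                                  sections_per_level = 1) {
  levels <- c("cervical", "thoracic", "lumbar")
  rows <- list()
  add <- function(case, group, lf, amp_by_level) {
    for (lv in levels) for (s in seq_len(sections_per_level)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        case = case, group = group, level = lv, section = s,
        leak_fraction = lf, leak_amplitude = amp_by_level[[lv]]
      )
    }
  }
  flat <- setNames(rep(leak_amplitude, 3), levels)
  bumped <- flat; bumped[["thoracic"]] <- leak_amplitude * thoracic_factor
  for (i in seq_len(n_control)) {
    add(sprintf("C%02d", i), "control", control_leak_fraction, flat)
  }
  for (i in seq_len(n_als)) {
    add(sprintf("A%02d", i), "ALS", als_leak_fraction, bumped)
  }
  do.call(rbind, rows)
}

#' Leaked/non-leaked classification accuracy against ground truth
#'
#' Runs vessel detection and leak classification on a generated section and
#' scores the result against the generator's leaked flags (each detected
#' vessel is matched to the nearest true vessel centre).
#'
#' @param section a [generate_section()] result.
#' @param config a [quant_config()].
#' @return list with `sensitivity`, `specificity`, `n_detected`, `n_true`.
#' @export
classification_accuracy <- function(section, config = quant_config()) {
  px <- section$image$pixel_size_um
  regions <- section$truth$regions
  v <- detect_vessels(section$image$channels$lectin, regions, config$vessel,
                      px)
  lmask <- leakage_mask(section$image$channels$hemoglobin, regions, px,
                        window_um = config$leak_window_um, k = config$leak_k,
                        min_area_um2 = config$leak_min_area_um2)
  v <- classify_vessel_leakage(v, lmask, rule = config$leak_rule,
                               overlap_frac = config$leak_overlap_frac)
  tv <- section$truth$vessels
  idx <- vapply(seq_len(nrow(v$records)), function(i) {
    which.min((tv$row - v$records$row[i])^2 + (tv$col - v$records$col[i])^2)
  }, integer(1))
  truth <- tv$leaked[idx]
  pred <- v$records$leaked
  list(
    sensitivity = if (any(truth)) sum(pred & truth) / sum(truth) else NA_real_,
    specificity = if (any(!truth)) sum(!pred & !truth) / sum(!truth)
                  else NA_real_,
    n_detected = nrow(v$records), n_true = nrow(tv)
  )
}
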