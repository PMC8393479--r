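#' Hemoglobin object criteria
#'
#' Size, intensity and vessel-proximity criteria for extravascular
#' hemoglobin objects. The proximity radius implements the requirement that
#' gray-matter hemoglobin be "within a defined radius" of a lectin-positive
#' vessel; the published analysis never states the radius, so results must
#' be reported together with the value used (default 25 um).
#'
#' @param min_area_um2,max_area_um2 object area bounds in um^2.
#' @param intensity_k `k` for [threshold_relative()].
#' @param proximity_radius_um maximum distance from an object to the nearest
#'   qualifying vessel for the object to count (gray matter only).
#' @export
hb_criteria <- function(min_area_um2 = 10, max_area_um2 = 50000,
                        intensity_k = 3, proximity_radius_um = 25) {
  stopifnot(min_area_um2 > 0, max_area_um2 > min_area_um2,
            proximity_radius_um > 0)
  structure(list(min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 intensity_k = intensity_k,
                 proximity_radius_um = proximity_radius_um),
            class = "hb_criteria")
}

# Shared scorer: threshold hb within `region`, label components, filter by
# area (and optionally by distance to the vessel mask), return the
# background-subtracted integrated intensity of surviving components per
# mm^2 of region.
hb_score_engine <- function(hb, region, crit, pixel_size_um,
                            vessel_mask = NULL, proximity_radius_um = NULL,
                            background_subtract = TRUE) {
  area_mm2 <- mask_area_mm2(region, pixel_size_um)
  if (area_mm2 <= 0) stop("scoring region has zero area")
  m <- suppressWarnings(threshold_relative(hb, region, crit$intensity_k))
  bg_med <- attr(m, "background_median")
  labs <- label_components(m)
  tab <- component_table(labs, pixel_size_um)
  tab <- tab[tab$area_um2 >= crit$min_area_um2 &
             tab$area_um2 <= crit$max_area_um2, , drop = FALSE]
  if (!nrow(tab)) return(0)
  keep_labels <- tab$label
  if (!is.null(proximity_radius_um)) {
    if (is.null(vessel_mask) || !any(vessel_mask)) {
      warning("no vessels available; proximity-conditioned score is 0")
      return(0)
    }
    dist_px <- EBImage::distmap((!vessel_mask) * 1)
    dist_um <- dist_px * pixel_size_um
    mind <- tapply(dist_um[labs > 0L], labs[labs > 0L], min)
    near <- as.integer(names(mind))[mind <= proximity_radius_um]
    keep_labels <- intersect(keep_labels, near)
    if (!length(keep_labels)) return(0)
  }
  sel <- labs %in% keep_labels
  vals <- hb[sel]
  total <- if (background_subtract) sum(vals - bg_med) else sum(vals)
  total / area_mm2
}

#' Gray-matter hemoglobin score (vessel-proximity conditioned)
#'
#' Integrated intensity per mm^2 of thresholded hemoglobin objects in the
#' gray matter that meet the size criteria and lie within
#' `crit$proximity_radius_um` of a detected vessel. Intensities are
#' background-subtracted (the threshold's background median) by default, so
#' a leak-free section scores ~0; set `background_subtract = FALSE` for a
#' raw integrated sum.
#'
#' @param hb hemoglobin channel (numeric matrix).
#' @param vessels result of [detect_vessels()].
#' @param regions a `region_set`.
#' @param crit an [hb_criteria()].
#' @param pixel_size_um pixel edge length in um.
#' @param background_subtract subtract the background median from every
#'   object pixel before summing (default TRUE).
#' @return integrated intensity per mm^2.
#' @export
gm_hb_score <- function(hb, vessels, regions, crit = hb_criteria(),
                        pixel_size_um, background_subtract = TRUE) {
  gray <- region_mask(regions, "gray")
  if (!any(gray)) stop("gray-matter region is empty")
  hb_score_engine(hb, gray, crit, pixel_size_um,
                  vessel_mask = vessels$mask,
                  proximity_radius_um = crit$proximity_radius_um,
                  background_subtract = background_subtract)
}

#' White-matter hemoglobin score (no proximity condition)
#'
#' As [gm_hb_score()] but without the vessel-proximity requirement: white
#' matter vessels are scant, so any qualifying hemoglobin object counts.
#'
#' @inheritParams gm_hb_score
#' @export
wm_hb_score <- function(hb, regions, crit = hb_criteria(), pixel_size_um,
                        background_subtract = TRUE) {
  white <- region_mask(regions, "white")
  if (!any(white)) stop("white-matter region is empty")
  hb_score_engine(hb, white, crit, pixel_size_um,
                  background_subtract = background_subtract)
}

#' Build the hemoglobin leakage mask
#'
#' Adaptive threshold on the hemoglobin channel within the tissue, followed
#' by removal of components smaller than `min_area_um2`. The size gate
#' separates genuine leakage patches (hundreds to thousands of um^2, set by
#' the halo extent) from isolated intravascular lumen signal, which would
#' otherwise mark every vessel as leaked.
#'
#' @param hb hemoglobin channel.
#' @param regions a `region_set`.
#' @param pixel_size_um pixel edge length in um.
#' @param window_um,k adaptive-threshold parameters (see
#'   [adaptive_threshold()]).
#' @param min_area_um2 minimum patch area retained (default 300 um^2).
#' @return logical leakage mask.
#' @export
leakage_mask <- function(hb, regions, pixel_size_um, window_um = 200, k = 2,
                         min_area_um2 = 300) {
  tissue <- region_mask(regions, "tissue")
  m <- adaptive_threshold(hb, window_um = window_um, k = k,
                          pixel_size_um = pixel_size_um, region = tissue)
  # a leakage patch surrounds its vessel: include the enclosed lumen so the
  # vessel itself lies "within the area" of leakage
  m <- fill_holes(m)
  labs <- label_components(m)
  tab <- component_table(labs, pixel_size_um)
  keep <- tab$label[tab$area_um2 >= min_area_um2]
  out <- matrix(FALSE, nrow(m), ncol(m))
  if (length(keep)) out[labs %in% keep] <- TRUE
  out
}

#' Classify vessels as leaked or non-leaked
#'
#' Default rule: a vessel is leaked iff its centroid lies inside the
#' leakage mask (the closest literal reading of a vessel "located within
#' the area" of leakage). Alternative rule `"overlap"`: leaked iff at least
#' `overlap_frac` of the vessel mask overlaps the leakage mask.
#'
#' @param vessels result of [detect_vessels()].
#' @param leak_mask logical leakage mask (from [leakage_mask()]).
#' @param rule `"centroid"` (default) or `"overlap"`.
#' @param overlap_frac overlap threshold for the `"overlap"` rule.
#' @return `vessels` with `records$leaked` filled and attributes
#'   `leaked_count` / `total_count` on the records.
#' @export
classify_vessel_leakage <- function(vessels, leak_mask,
                                    rule = c("centroid", "overlap"),
                                    overlap_frac = 0.5) {
  rule <- match.arg(rule)
  records <- vessels$records
  if (!nrow(records)) {
    vessels$records <- records
    return(vessels)
  }
  if (is.null(leak_mask)) {
    records$leaked <- NA
    vessels$records <- records
    return(vessels)
  }
  leak_mask <- as_binary(leak_mask)
  if (rule == "centroid") {
    cr <- pmin(pmax(round(records$row), 1L), nrow(leak_mask))
    cc <- pmin(pmax(round(records$col), 1L), ncol(leak_mask))
    records$leaked <- leak_mask[cbind(cr, cc)]
  } else {
    labs <- vessels$labels
    inlab <- labs[labs > 0L]
    tot <- tabulate(inlab, nbins = nrow(records))
    ov <- tabulate(labs[labs > 0L & leak_mask], nbins = nrow(records))
    records$leaked <- ov / pmax(tot, 1L) >= overlap_frac
  }
  attr(records, "leaked_count") <- sum(records$leaked)
  attr(records, "total_count") <- nrow(records)
  vessels$records <- records
  vessels
}

#' Group means of per-vessel marker intensity
#'
#' Means of `marker_mean` over the four leak-status x compartment groups,
#' excluding vessels whose intensity is missing; group sizes are reported
#' and empty groups yield `NA` means.
#'
#' @param records vessel records with `leaked`, `compartment` and
#'   `marker_mean` populated.
#' @return data.frame with `compartment`, `leaked`, `mean_intensity`, `n`.
#' @export
nvu_group_means <- function(records) {
  stopifnot(all(c("leaked", "compartment", "marker_mean") %in% names(records)))
  grid <- expand.grid(compartment = c("gray", "white"),
                      leaked = c(TRUE, FALSE), stringsAsFactors = FALSE)
  grid$mean_intensity <- NA_real_
  grid$n <- 0L
  for (i in seq_len(nrow(grid))) {
    sel <- records$compartment == grid$compartment[i] &
      records$leaked == grid$leaked[i] & !is.na(records$marker_mean)
    grid$n[i] <- sum(sel, na.rm = TRUE)
    if (grid$n[i] > 0) {
      grid$mean_intensity[i] <- mean(records$marker_mean[sel])
    }
  }
  grid
}
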