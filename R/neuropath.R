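#' Motor-neuron and inclusion criteria
#'
#' @param min_soma_area_um2,max_soma_area_um2 soma area bounds in um^2; the
#'   defaults bracket alpha-motor-neuron somata (15-60 um diameter).
#' @param intensity_k `k` for [threshold_relative()].
#' @export
neuron_criteria <- function(min_soma_area_um2 = 150,
                            max_soma_area_um2 = 3000, intensity_k = 3) {
  stopifnot(min_soma_area_um2 > 0, max_soma_area_um2 > min_soma_area_um2)
  structure(list(min_soma_area_um2 = min_soma_area_um2,
                 max_soma_area_um2 = max_soma_area_um2,
                 intensity_k = intensity_k), class = "neuron_criteria")
}

#' @param min_equiv_diameter_um inclusions below this equivalent diameter
#'   (diameter of the equal-area circle) are not counted; default 8 um, the
#'   gate that selects neuronal over glial cytoplasmic inclusions.
#' @rdname neuron_criteria
#' @export
inclusion_criteria <- function(min_equiv_diameter_um = 8, intensity_k = 3) {
  stopifnot(min_equiv_diameter_um > 0)
  structure(list(min_equiv_diameter_um = min_equiv_diameter_um,
                 intensity_k = intensity_k), class = "inclusion_criteria")
}

#' Count SMI-32-positive motor neurons in the anterior horns
#'
#' Automated soma detection: threshold relative to background within the
#' pooled anterior horns, 8-connected components, soma-area filter. The
#' count is normalized to the pooled horn area. A manual click list (one
#' point per soma) may be supplied instead of the raster, reproducing a
#' manual-count workflow with identical normalization.
#'
#' @param smi32 SMI-32 channel (numeric matrix), or NULL when `clicks` is
#'   given.
#' @param regions a `region_set` with anterior-horn labels.
#' @param crit a [neuron_criteria()].
#' @param pixel_size_um pixel edge length in um.
#' @param clicks optional data.frame of manual points (`row`, `col`); points
#'   inside the horns are counted, detection is skipped.
#' @return list with `count` and `density_per_mm2`.
#' @export
count_motor_neurons <- function(smi32, regions, crit = neuron_criteria(),
                                pixel_size_um, clicks = NULL) {
  horns <- region_mask(regions, "anterior_horn")
  if (!any(horns)) stop("no anterior-horn labels in regions")
  horn_area <- mask_area_mm2(horns, pixel_size_um)
  if (!is.null(clicks)) {
    cr <- round(clicks$row); cc <- round(clicks$col)
    inside <- cr >= 1 & cr <= nrow(horns) & cc >= 1 & cc <= ncol(horns)
    inside[inside] <- horns[cbind(cr[inside], cc[inside])]
    n <- sum(inside)
    return(list(count = n, density_per_mm2 = n / horn_area))
  }
  m <- suppressWarnings(threshold_relative(smi32, horns, crit$intensity_k))
  tab <- component_table(label_components(m), pixel_size_um)
  n <- sum(tab$area_um2 >= crit$min_soma_area_um2 &
           tab$area_um2 <= crit$max_soma_area_um2)
  list(count = n, density_per_mm2 = n / horn_area)
}

#' Count size-gated pTDP-43 inclusions in the anterior horns
#'
#' Threshold, 8-connected components, then keep components whose equivalent
#' diameter `2 * sqrt(area / pi)` meets the gate. Touching inclusions are
#' not split (no watershed); this is a documented limitation of
#' threshold-plus-gate counting.
#'
#' @param ptdp pTDP-43 channel (numeric matrix).
#' @param regions a `region_set`.
#' @param crit an [inclusion_criteria()].
#' @param pixel_size_um pixel edge length in um.
#' @return integer count.
#' @export
count_inclusions <- function(ptdp, regions, crit = inclusion_criteria(),
                             pixel_size_um) {
  horns <- region_mask(regions, "anterior_horn")
  if (!any(horns)) stop("no anterior-horn labels in regions")
  m <- suppressWarnings(threshold_relative(ptdp, horns, crit$intensity_k))
  tab <- component_table(label_components(m), pixel_size_um)
  if (!nrow(tab)) return(0L)
  equiv_d <- 2 * sqrt(tab$area_um2 / pi)
  sum(equiv_d >= crit$min_equiv_diameter_um)
}

#' Inclusion load per motor neuron
#'
#' @param inclusion_count,neuron_count nonnegative counts.
#' @return `inclusion_count / neuron_count`; `NA` with a warning (never
#'   infinity) when no neurons were found.
#' @export
inclusion_load <- function(inclusion_count, neuron_count) {
  if (inclusion_count < 0 || neuron_count < 0) {
    stop("counts must be nonnegative")
  }
  if (neuron_count == 0) {
    warning("no motor neurons counted; inclusion load undefined")
    return(NA_real_)
  }
  inclusion_count / neuron_count
}
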