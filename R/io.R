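#' Read and write section images and region rasters
#'
#' Images travel as multi-page TIFF (one 32-bit float page per channel) plus
#' a JSON sidecar holding channel names, pixel size and identifiers. TIFF
#' float storage is defined on \[0, 1\], so channels are rescaled by a single
#' `intensity_scale` factor recorded in the sidecar; the reader undoes it.
#'
#' @param image a `section_image`.
#' @param path TIFF path; the sidecar is written at `<path>.json`.
#' @return `write_section()` returns `path` invisibly; `read_section()` the
#'   reconstructed `section_image`.
#' @export
write_section <- function(image, path) {
  stopifnot(inherits(image, "section_image"))
  hi <- max(1, vapply(image$channels, max, numeric(1)))
  pages <- lapply(image$channels, function(ch) ch / hi)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  sidecar <- list(
    channels = names(image$channels),
    pixel_size_um = image$pixel_size_um,
    case = image$case, level = image$level, section = image$section,
    intensity_scale = hi
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_section
#' @export
read_section <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  channels <- lapply(pages, function(p) p * sidecar$intensity_scale)
  names(channels) <- sidecar$channels
  section_image(channels, pixel_size_um = sidecar$pixel_size_um,
                case = sidecar$case %||% NA_character_,
                level = sidecar$level %||% NA_character_,
                section = sidecar$section %||% NA_integer_)
}

#' @param regions a `region_set`.
#' @rdname write_section
#' @export
write_regions <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  tiff::writeTIFF(regions$labels / 255, path, bits.per.sample = 32,
                  reduce = FALSE)
  invisible(path)
}

#' @param edge_margin_applied flag to set on the re-read `region_set` (the
#'   raster itself does not record whether [exclude_edge()] was applied).
#' @rdname write_section
#' @export
read_regions <- function(path, edge_margin_applied = FALSE) {
  m <- tiff::readTIFF(path)
  region_set(matrix(as.integer(round(m * 255)), nrow(m), ncol(m)),
             edge_margin_applied = edge_margin_applied)
}
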