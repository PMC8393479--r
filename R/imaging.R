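#' Raster, region and binary-morphology primitives
#'
#' All rasters are numeric matrices indexed `[row, col]` (1-based, as is
#' idiomatic in R); masks are logical matrices of the same shape. Physical
#' quantities carry explicit units: lengths in micrometres (um), areas in
#' um^2 or mm^2 as stated by each function.
#'
#' @name imaging
NULL

# Region label codes used throughout. Anterior horns are part of the gray
# matter: "gray" accessors include them.
REGION_CODES <- c(
  background = 0L, gray = 1L, white = 2L,
  anterior_horn_left = 3L, anterior_horn_right = 4L
)

#' Construct a multichannel section image
#'
#' @param channels named list of numeric matrices, all of identical shape and
#'   nonnegative intensity.
#' @param pixel_size_um pixel edge length in micrometres (> 0). Default 0.65,
#'   typical of 10x slide scans.
#' @param case,level,section optional identifiers; `level` is one of
#'   `"cervical"`, `"thoracic"`, `"lumbar"` when given.
#' @return A `section_image` object.
#' @export
section_image <- function(channels, pixel_size_um = 0.65,
                          case = NA_character_, level = NA_character_,
                          section = NA_integer_) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), all(nzchar(names(channels))))
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1) {
    stop("all channel rasters must share the same shape")
  }
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a positive real")
  }
  if (!is.na(level) && !level %in% c("cervical", "thoracic", "lumbar")) {
    stop("level must be one of cervical, thoracic, lumbar")
  }
  structure(
    list(channels = channels, pixel_size_um = pixel_size_um,
         case = case, level = level, section = section),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<section_image> %d x %d px @ %.3g um/px\n", d[1], d[2],
              x$pixel_size_um))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  if (!is.na(x$case)) {
    cat(sprintf("  case %s, level %s, section %s\n", x$case, x$level,
                x$section))
  }
  invisible(x)
}

#' Construct a region set from a label raster
#'
#' @param labels integer matrix with codes 0 = background, 1 = gray,
#'   2 = white, 3 = anterior horn (left), 4 = anterior horn (right). Horn
#'   pixels are gray matter; `region_mask(r, "gray")` includes them.
#' @param edge_margin_applied has [exclude_edge()] already been applied?
#' @return A `region_set` object.
#' @export
region_set <- function(labels, edge_margin_applied = FALSE) {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), unname(REGION_CODES))
  if (length(bad)) stop("unknown region codes: ", paste(bad, collapse = ", "))
  structure(list(labels = labels, edge_margin_applied = edge_margin_applied),
            class = "region_set")
}

#' Extract a named compartment mask from a region set
#'
#' @param regions a `region_set`.
#' @param what one of `"tissue"`, `"gray"`, `"white"`, `"anterior_horn"`,
#'   `"anterior_horn_left"`, `"anterior_horn_right"`. `"gray"` includes the
#'   anterior horns; `"tissue"` is gray plus white.
#' @return logical matrix.
#' @export
region_mask <- function(regions, what = "tissue") {
  stopifnot(inherits(regions, "region_set"))
  l <- regions$labels
  switch(what,
    tissue = l != 0L,
    gray = l == 1L | l == 3L | l == 4L,
    white = l == 2L,
    anterior_horn = l == 3L | l == 4L,
    anterior_horn_left = l == 3L,
    anterior_horn_right = l == 4L,
    stop("unknown compartment: ", what)
  )
}

#' Convert a physical distance to a pixel radius
#'
#' Rounds half away from zero and never returns less than 1 px, so that a
#' nonzero physical radius always has a nonzero structuring element.
#'
#' @param distance_um distance in micrometres (> 0).
#' @param pixel_size_um pixel edge length in micrometres (> 0).
#' @return integer pixel radius >= 1.
#' @export
#' @examples
#' um_to_px(10, 4)  # 2.5 px rounds away from zero to 3
um_to_px <- function(distance_um, pixel_size_um) {
  if (!is.numeric(distance_um) || distance_um <= 0 ||
      !is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("distance_um and pixel_size_um must be positive")
  }
  max(1L, as.integer(floor(distance_um / pixel_size_um + 0.5)))
}

# Disc structuring element of pixel radius r (odd-sized EBImage brush).
disc_kernel <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, "disc")

as_binary <- function(m) {
  if (is.logical(m)) m else m > 0.5
}

#' Pixel area of a mask in square millimetres
#' @param mask logical matrix.
#' @param pixel_size_um pixel edge length in um.
#' @return area in mm^2.
#' @export
mask_area_mm2 <- function(mask, pixel_size_um) {
  sum(mask) * pixel_size_um^2 / 1e6
}

#' Global robust threshold relative to background
#'
#' Within `region`, pixels not in the top intensity decile are treated as
#' background; the mask keeps region pixels whose intensity exceeds
#' `median(bg) + k * mad(bg)`. This is a reproducible stand-in for an
#' "intensity relative to background" criterion whose vendor rule is
#' unpublished. Pixels outside `region` are always FALSE.
#'
#' @param raster numeric matrix.
#' @param region logical matrix (nonempty).
#' @param k robustness multiplier (default 3).
#' @return logical mask with attributes `background_median` and
#'   `background_mad`.
#' @export
threshold_relative <- function(raster, region, k = 3) {
  stopifnot(is.matrix(raster), is.matrix(region) %||% TRUE)
  region <- as_binary(region)
  if (!any(region)) stop("region is empty")
  vals <- raster[region]
  if (max(vals) == min(vals)) {
    warning("constant raster within region; returning empty mask")
    out <- matrix(FALSE, nrow(raster), ncol(raster))
    attr(out, "background_median") <- vals[1]
    attr(out, "background_mad") <- 0
    return(out)
  }
  q90 <- quantile(vals, 0.9, names = FALSE, type = 7)
  bg <- vals[vals <= q90]
  bg_med <- median(bg)
  bg_mad <- mad(bg)
  thr <- bg_med + k * bg_mad
  out <- region & (raster > thr)
  attr(out, "background_median") <- bg_med
  attr(out, "background_mad") <- bg_mad
  attr(out, "threshold") <- thr
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adaptive (local mean + k sd) threshold
#'
#' A pixel is kept iff its intensity exceeds the local mean plus `k` local
#' standard deviations, both computed over a square window of side
#' `window_um`. Insensitive to smooth background gradients, which is the
#' point: leakage patches must stand out of their own neighbourhood. Pixels
#' outside `region` (e.g. tissue exterior) are forced FALSE.
#'
#' @param raster numeric matrix.
#' @param window_um window side in micrometres; must be at least 5 px after
#'   conversion. If the window exceeds the image, falls back to
#'   [threshold_relative()] with a warning.
#' @param k multiplier on the local standard deviation (default 3).
#' @param pixel_size_um pixel edge length in um.
#' @param region optional logical matrix restricting the mask.
#' @return logical mask.
#' @export
adaptive_threshold <- function(raster, window_um = 200, k = 3,
                               pixel_size_um = 0.65, region = NULL) {
  w <- um_to_px(window_um, pixel_size_um)
  if (w %% 2L == 0L) w <- w + 1L
  if (w < 5L) stop("adaptive window must be at least 5 px after conversion")
  if (w > min(dim(raster))) {
    warning("adaptive window exceeds image; falling back to global threshold")
    reg <- if (is.null(region)) matrix(TRUE, nrow(raster), ncol(raster))
           else as_binary(region)
    out <- threshold_relative(raster, reg, k)
    attributes(out) <- list(dim = dim(out))
    return(out)
  }
  kern <- matrix(1 / (w * w), w, w)
  mu <- EBImage::filter2(raster, kern, boundary = "replicate")
  mu2 <- EBImage::filter2(raster^2, kern, boundary = "replicate")
  sdv <- sqrt(pmax(mu2 - mu^2, 0))
  # FFT-based convolution leaves ~1e-13 relative jitter on flat regions; a
  # relative guard keeps exactly-at-mean pixels out of the mask
  out <- (raster - (mu + k * sdv)) > 1e-6 * pmax(abs(raster), 1)
  if (!is.null(region)) out <- out & as_binary(region)
  out
}

#' Binary morphology with disc structuring elements
#'
#' `fill_holes()` closes fully enclosed background regions; `mask_dilate()`
#' and `mask_erode()` use a disc of radius `radius_um` converted with
#' [um_to_px()].
#'
#' @param mask logical matrix.
#' @param radius_um disc radius in micrometres.
#' @param pixel_size_um pixel edge length in um.
#' @return logical mask of the same shape.
#' @export
fill_holes <- function(mask) {
  m <- as_binary(mask)
  as_binary(EBImage::fillHull(m * 1))
}

#' @rdname fill_holes
#' @export
mask_dilate <- function(mask, radius_um, pixel_size_um) {
  m <- as_binary(mask)
  if (!any(m)) return(m)
  r <- um_to_px(radius_um, pixel_size_um)
  as_binary(EBImage::dilate(m * 1, disc_kernel(r)))
}

#' @rdname fill_holes
#' @export
mask_erode <- function(mask, radius_um, pixel_size_um) {
  m <- as_binary(mask)
  if (!any(m)) return(m)
  r <- um_to_px(radius_um, pixel_size_um)
  as_binary(EBImage::erode(m * 1, disc_kernel(r)))
}

#' Remove an edge band from every tissue compartment
#'
#' Erodes the tissue mask by `margin_um` and intersects every region class
#' with the result. Tissue edges show elevated nonspecific labelling, so a
#' band of stated width is excluded before any quantification. Calling twice
#' erodes twice; the function is deliberately not idempotent.
#'
#' @param regions a `region_set`.
#' @param margin_um band width in micrometres; 0 returns the input with the
#'   flag set.
#' @param pixel_size_um pixel edge length in um.
#' @return a `region_set` with `edge_margin_applied = TRUE`.
#' @export
exclude_edge <- function(regions, margin_um = 100, pixel_size_um = 0.65) {
  stopifnot(inherits(regions, "region_set"))
  tissue <- region_mask(regions, "tissue")
  if (!any(tissue)) stop("tissue mask is empty")
  if (margin_um <= 0) {
    regions$edge_margin_applied <- TRUE
    return(regions)
  }
  keep <- mask_erode(tissue, margin_um, pixel_size_um)
  if (!any(keep)) stop("edge margin erodes the tissue to empty")
  labels <- regions$labels
  labels[!keep] <- 0L
  region_set(labels, edge_margin_applied = TRUE)
}

#' Label connected components (8-connectivity)
#'
#' EBImage's `bwlabel` uses 4-connectivity; diagonally adjacent components
#' are merged here with a union-find pass so blobs touching at corners count
#' once, the usual convention for object detection.
#'
#' @param mask logical matrix.
#' @return integer matrix of labels (0 = background), with attribute
#'   `n` giving the number of components.
#' @export
label_components <- function(mask) {
  m <- as_binary(mask)
  lab <- EBImage::bwlabel(m * 1)
  storage.mode(lab) <- "integer"
  nl <- max(lab)
  if (nl > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    pairs <- rbind(
      cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
      cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))
    )
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
    parent <- seq_len(nl)
    if (nrow(pairs)) {
      pairs <- unique(pairs)
      for (r in seq_len(nrow(pairs))) {
        a <- pairs[r, 1]; b <- pairs[r, 2]
        while (parent[a] != a) a <- parent[a]
        while (parent[b] != b) b <- parent[b]
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
    }
    root <- vapply(seq_len(nl), function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }, integer(1))
    remap <- match(root, sort(unique(root)))
    pos <- lab > 0L
    lab[pos] <- remap[lab[pos]]
  }
  attr(lab, "n") <- if (nl > 0L) max(lab) else 0L
  lab
}

#' Per-component pixel areas and centroids
#'
#' @param labels integer label matrix from [label_components()].
#' @param pixel_size_um pixel edge length in um.
#' @return data.frame with `label`, `n_px`, `area_um2`, `row`, `col`
#'   (centroid, 1-based pixel coordinates).
#' @export
component_table <- function(labels, pixel_size_um) {
  n <- attr(labels, "n") %||% max(labels)
  if (n == 0L) {
    return(data.frame(label = integer(0), n_px = integer(0),
                      area_um2 = numeric(0), row = numeric(0),
                      col = numeric(0)))
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rows <- (idx - 1L) %% nrow(labels) + 1L
  cols <- (idx - 1L) %/% nrow(labels) + 1L
  n_px <- tabulate(lab, nbins = n)
  data.frame(
    label = seq_len(n),
    n_px = n_px,
    area_um2 = n_px * pixel_size_um^2,
    row = as.vector(tapply(rows, lab, mean)),
    col = as.vector(tapply(cols, lab, mean))
  )
}
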