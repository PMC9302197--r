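#' Construct a calibrated CT slice
#'
#' Wraps a 2-D raster of Hounsfield units (HU) with its physical pixel
#' spacing and an optional region-of-interest mask restricting any later
#' segmentation to an anatomically delineated region.
#'
#' @param hu Numeric matrix of calibrated HU values (air -1000, water 0);
#'   values below -1024 are rejected as uncalibrated.
#' @param spacing_mm Pixel spacing in mm, length 1 (isotropic) or 2
#'   (row, column).
#' @param roi Optional logical matrix of identical dimensions; segmentation
#'   is confined to TRUE pixels.
#' @param source Optional provenance string (e.g. the file the slice was
#'   read from).
#' @return Object of class `ct_slice`.
#' @export
ct_slice <- function(hu, spacing_mm, roi = NULL, source = NULL) {
  if (!is.matrix(hu) || !is.numeric(hu)) stop("hu must be a numeric matrix")
  if (length(hu) == 0) stop("empty CT slice")
  if (any(!is.finite(hu))) stop("hu must be finite")
  if (any(hu < -1024)) stop("HU below -1024: slice appears uncalibrated")
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 2)
  if (length(spacing_mm) != 2 || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("spacing_mm must be positive, length 1 or 2")
  if (!is.null(roi)) {
    if (!is.logical(roi) || !identical(dim(roi), dim(hu)))
      stop("roi must be a logical matrix with the same dimensions as hu")
  }
  structure(list(hu = hu, spacing_mm = as.numeric(spacing_mm), roi = roi,
                 source = source),
            class = "ct_slice")
}

#' @export
print.ct_slice <- function(x, ...) {
  cat("CT slice ", nrow(x$hu), " x ", ncol(x$hu), " px, spacing ",
      paste(signif(x$spacing_mm, 4), collapse = " x "), " mm, HU range [",
      min(x$hu), ", ", max(x$hu), "]",
      if (!is.null(x$roi)) sprintf(", ROI %d px", sum(x$roi)) else "",
      "\n", sep = "")
  invisible(x)
}

# Pixel area in cm^2 (spacing is mm per axis; 1 cm^2 = 100 mm^2).
pixel_area_cm2 <- function(slice) prod(slice$spacing_mm) / 100

# Threshold segmentation shared by muscle and fat: closed HU window
# intersected with the ROI, optional removal of small 8-connected
# components.
segment_window <- function(slice, window, min_component_px, tissue) {
  stopifnot(inherits(slice, "ct_slice"))
  if (length(window) != 2 || window[1] > window[2])
    stop("window must be c(low, high) with low <= high")
  mask <- slice$hu >= window[1] & slice$hu <= window[2]
  if (!is.null(slice$roi)) mask <- mask & slice$roi
  if (min_component_px > 0) mask <- drop_small_components(mask, min_component_px)
  area <- sum(mask) * pixel_area_cm2(slice)
  if (area == 0)
    warning(sprintf("empty %s mask: area is 0 cm^2", tissue))
  structure(list(mask = mask, area_cm2 = area, window_hu = window,
                 tissue = tissue, spacing_mm = slice$spacing_mm),
            class = "segmentation_result")
}

#' Segment skeletal muscle on an L3 CT slice
#'
#' Selects every ROI pixel whose HU lies in the closed muscle attenuation
#' window, by default -29 to +150 HU -- the prespecified range for skeletal
#' muscle in single-slice CT body composition. The boundary values are
#' included. The skeletal muscle area (SMA) is the pixel count times the
#' physical pixel area.
#'
#' Pure thresholding (the default, `min_component_px = 0`) mirrors
#' threshold-based workflows in which stray components are edited manually;
#' setting `min_component_px > 0` removes 8-connected components smaller
#' than that many pixels as an automated cleanup.
#'
#' @param slice A [ct_slice()].
#' @param window Closed HU window `c(low, high)`; default `c(-29, 150)`.
#' @param min_component_px Minimum connected-component size kept, in
#'   pixels; 0 disables the cleanup.
#' @return Object of class `segmentation_result` with elements `mask`
#'   (logical matrix), `area_cm2`, `window_hu`, `tissue`.
#' @export
segment_muscle <- function(slice, window = c(-29, 150), min_component_px = 0) {
  segment_window(slice, window, min_component_px, "muscle")
}

#' Segment adipose tissue on a CT slice
#'
#' As [segment_muscle()], with the conventional adipose attenuation window
#' of -190 to -30 HU (closed on both ends).
#'
#' @inheritParams segment_muscle
#' @param window Closed HU window; default `c(-190, -30)`.
#' @return Object of class `segmentation_result`.
#' @export
segment_fat <- function(slice, window = c(-190, -30), min_component_px = 0) {
  segment_window(slice, window, min_component_px, "fat")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("Segmentation (", x$tissue, "): window [", x$window_hu[1], ", ",
      x$window_hu[2], "] HU, ", sum(x$mask), " px, area ",
      formatC(x$area_cm2, format = "f", digits = 2), " cm^2\n", sep = "")
  invisible(x)
}

# Remove 8-connected components smaller than min_px pixels. Two-pass
# label propagation with union-find over a logical matrix; adequate for
# slice-sized rasters without compiled code.
drop_small_components <- function(mask, min_px) {
  if (!any(mask)) return(mask)
  lab <- label_components(mask)
  keep <- which(tabulate(lab[mask]) >= min_px)
  mask & matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# 8-connectivity connected-component labelling (union-find).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nxt <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j]) next
      # previously visited 8-neighbours (left column and above)
      nb <- integer(0)
      if (i > 1 && mask[i - 1, j]) nb <- c(nb, lab[i - 1, j])
      if (j > 1) {
        if (mask[i, j - 1]) nb <- c(nb, lab[i, j - 1])
        if (i > 1 && mask[i - 1, j - 1]) nb <- c(nb, lab[i - 1, j - 1])
        if (i < nr && mask[i + 1, j - 1]) nb <- c(nb, lab[i + 1, j - 1])
      }
      if (length(nb) == 0) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[i, j] <- nxt
      } else {
        roots <- unique(vapply(nb, find, integer(1)))
        r <- min(roots)
        lab[i, j] <- r
        for (o in roots) parent[o] <- r
      }
    }
  }
  if (nxt > 0) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    dense <- match(roots, unique(roots))
    lab[mask] <- dense[lab[mask]]
  }
  lab
}
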