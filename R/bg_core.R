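#' Segmentation parameters for the B-G pipeline
#'
#' @param t0 intensity threshold applied to the B-G difference map. Stained
#'   nuclei sit above 110 and dye stains below 50 on well-prepared smears, so
#'   any fixed threshold inside the empirical band \[50, 100\] separates them
#'   without any per-image threshold search; the default 80 is the band
#'   midpoint. Values outside the band are allowed but flagged with a warning
#'   as non-compliant.
#' @param min_nucleus_area_px size-filter cutoff (pixels) removing platelets,
#'   which share the nucleus color but are far smaller. Default 500 px at the
#'   nominal 1024x768 magnification; scale-dependent.
#' @param connectivity pixel connectivity for region labeling, 4 or 8.
#'   Default 8: thin chromatin strands joining neutrophil lobes favor the
#'   more permissive connectivity.
#' @return a `segmentation_params` list.
#' @export
segmentation_params <- function(t0 = 80L, min_nucleus_area_px = 500L,
                                connectivity = 8L) {
  t0 <- as.integer(t0)
  if (is.na(t0) || t0 < 0L || t0 > 255L) stop("t0 must be in 0..255")
  if (t0 < 50L || t0 > 100L)
    warning("t0 = ", t0, " is outside the empirical band [50, 100]; ",
            "running in non-compliant mode", call. = FALSE)
  min_nucleus_area_px <- as.integer(min_nucleus_area_px)
  if (is.na(min_nucleus_area_px) || min_nucleus_area_px < 1L)
    stop("min_nucleus_area_px must be >= 1")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  structure(list(t0 = t0, min_nucleus_area_px = min_nucleus_area_px,
                 connectivity = connectivity),
            class = "segmentation_params")
}

#' Saturated B-G difference map
#'
#' Per pixel, `max(B - G, 0)`: a single saturating 8-bit subtraction, the
#' entire per-pixel cost of the method. Saturation (clamp at zero) rather
#' than modular wrap-around is essential: pink erythrocytes and background
#' have G > B, and a wrap-around would turn them into bright foreground.
#'
#' @param img an [rgb_image].
#' @return integer matrix (same shape as the image) with values in 0..255.
#' @export
bg_difference <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  d <- channel(img, 3L) - channel(img, 2L)
  d[d < 0L] <- 0L
  d
}

#' Binarize a difference map at a fixed threshold
#'
#' Foreground (1) where the difference is `>= t0` (inclusive: with the band
#' endpoint t0 = 50, stain pixels, which are strictly below 50, stay
#' background).
#'
#' @param diff integer matrix from [bg_difference()].
#' @param params a [segmentation_params] object (only `t0` is used).
#' @return binary mask (integer matrix of 0/1).
#' @export
binarize <- function(diff, params = segmentation_params()) {
  stopifnot(is.matrix(diff))
  m <- matrix(0L, nrow(diff), ncol(diff))
  m[diff >= params$t0] <- 1L
  m
}

#' Label connected foreground regions
#'
#' Maximal connected components of the foreground under 4- or
#' 8-connectivity; background stays 0 and labels are contiguous from 1,
#' ordered by each component's first pixel in raster-scan (row-major) order.
#'
#' @param mask binary mask.
#' @param connectivity 4 or 8.
#' @return labeled mask with an `n_labels` attribute.
#' @export
label_regions <- function(mask, connectivity = 8L) {
  mask <- as_binary_mask(mask)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  .cc_label_cpp(mask, connectivity)
}

#' Remove small components (platelet filter)
#'
#' Components with area below `min_area` are set to background; survivors
#' are relabeled contiguously, preserving raster-scan order. The boundary is
#' inclusive: a component of exactly `min_area` pixels survives.
#'
#' @param labeled labeled mask.
#' @param min_area minimum surviving area in pixels.
#' @return labeled mask of the survivors.
#' @export
size_filter <- function(labeled, min_area) {
  labeled <- as_labeled_mask(labeled)
  min_area <- as.integer(min_area)
  n <- n_labels(labeled)
  if (n == 0L) return(labeled)
  areas <- tabulate(labeled[labeled > 0L], nbins = n)
  keep <- which(areas >= min_area)
  remap <- integer(n)
  # survivors keep their relative order, hence their raster order
  remap[keep] <- seq_along(keep)
  out <- labeled
  pos <- labeled > 0L
  out[pos] <- remap[labeled[pos]]
  attr(out, "n_labels") <- length(keep)
  out
}
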