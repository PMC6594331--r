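#' Artifact-rejection parameters
#'
#' Dye debris can match the nucleus color and size and survive every earlier
#' stage; what it lacks is cytoplasm. A segmented object is discarded as an
#' artifact when its cytoplasm-to-nucleus area ratio falls below
#' `ratio_min`. The floor 0.26 is an empirical minimum for genuine
#' leukocytes; the comparison is strict, so a ratio of exactly 0.26 is kept.
#'
#' @param ratio_min minimum cytoplasm/nucleus area ratio of a genuine cell.
#' @param roi_margin_factor the cytoplasm is searched in a window obtained
#'   by scaling the nucleus bounding box about its center by this factor
#'   (clipped to the image).
#' @param cyto_method cytoplasm segmentation procedure; only
#'   `"s_otsu_minus_nucleus"` is implemented (see [segment_cytoplasm()]).
#' @return an `artifact_params` list.
#' @export
artifact_params <- function(ratio_min = 0.26, roi_margin_factor = 1.5,
                            cyto_method = "s_otsu_minus_nucleus") {
  if (!is.numeric(ratio_min) || ratio_min <= 0) stop("ratio_min must be > 0")
  if (!is.numeric(roi_margin_factor) || roi_margin_factor < 1)
    stop("roi_margin_factor must be >= 1")
  cyto_method <- match.arg(cyto_method, "s_otsu_minus_nucleus")
  structure(list(ratio_min = ratio_min,
                 roi_margin_factor = roi_margin_factor,
                 cyto_method = cyto_method),
            class = "artifact_params")
}

#' Saturation component of an RGB image
#'
#' HSV-style saturation kept on the 8-bit integer scale: per pixel,
#' `S = 0` when `max(R,G,B) = 0`, else
#' `S = round(255 * (max - min) / max)` (half-up rounding).
#'
#' @param img an [rgb_image].
#' @return integer matrix with values in 0..255.
#' @export
rgb_to_saturation <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  r <- channel(img, 1L); g <- channel(img, 2L); b <- channel(img, 3L)
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  s <- matrix(0L, nrow(r), ncol(r))
  nz <- mx > 0L
  s[nz] <- as.integer(floor(255 * (mx[nz] - mn[nz]) / mx[nz] + 0.5))
  s
}

# expand a closed bbox about its center by `factor`, clip to image dims
.expand_roi <- function(bbox, factor, h, w) {
  cx <- (bbox[["x_l"]] + bbox[["x_r"]]) / 2
  cy <- (bbox[["y_t"]] + bbox[["y_b"]]) / 2
  hw <- (bbox[["x_r"]] - bbox[["x_l"]] + 1) / 2 * factor
  hh <- (bbox[["y_b"]] - bbox[["y_t"]] + 1) / 2 * factor
  c(x_l = max(0L, as.integer(floor(cx - hw))),
    x_r = min(w - 1L, as.integer(ceiling(cx + hw))),
    y_t = max(0L, as.integer(floor(cy - hh))),
    y_b = min(h - 1L, as.integer(ceiling(cy + hh))))
}

#' Segment the cytoplasm around a segmented nucleus
#'
#' Cytoplasm is recovered inside a region of interest around the nucleus by
#' an Otsu threshold on the saturation (S) component intersected with an
#' Otsu threshold on the blue (B) component. Because the nucleus itself is
#' already segmented at this stage, its pixels are excluded from both
#' histograms: the remaining ROI is an (approximately) two-class
#' background-versus-cytoplasm population, which is the regime Otsu's
#' criterion is designed for. The whole-cell mask is the nucleus united with
#' every S-and-B foreground component touching it; cytoplasm is the cell
#' minus the nucleus.
#'
#' Degenerate ROIs (constant channels, or no non-nucleus pixels) yield a
#' cytoplasm area of 0 without error.
#'
#' @param img an [rgb_image].
#' @param nucleus_mask binary mask (full image size) of the nucleus whose
#'   cytoplasm is sought.
#' @param roi optional named vector `x_l, x_r, y_t, y_b` (0-based,
#'   inclusive); default: the nucleus bounding box scaled by
#'   `params$roi_margin_factor`.
#' @param params an [artifact_params] object.
#' @param exclude_mask binary mask of pixels excluded from the threshold
#'   histograms; defaults to `nucleus_mask`. When several nuclei sit close
#'   together (clumped leukocytes), pass the union of all segmented nuclei
#'   so a neighbour's nucleus inside the ROI cannot skew the thresholds;
#'   cytoplasm connected to the nucleus through a neighbouring cell is then
#'   over- rather than under-counted, which errs on the side of keeping
#'   genuine cells.
#' @return list with `cell_mask`, `cytoplasm_mask` (full-size binary masks,
#'   zero outside the ROI) and `cyto_area_px`.
#' @export
segment_cytoplasm <- function(img, nucleus_mask, roi = NULL,
                              params = artifact_params(),
                              exclude_mask = nucleus_mask) {
  stopifnot(inherits(img, "rgb_image"))
  nucleus_mask <- as_binary_mask(nucleus_mask)
  exclude_mask <- as_binary_mask(exclude_mask)
  h <- nrow(nucleus_mask); w <- ncol(nucleus_mask)
  if (sum(nucleus_mask) == 0L) stop("segment_cytoplasm: empty nucleus mask")
  if (is.null(roi))
    roi <- .expand_roi(project_bbox(nucleus_mask), params$roi_margin_factor, h, w)
  rows <- (roi[["y_t"]]:roi[["y_b"]]) + 1L
  cols <- (roi[["x_l"]]:roi[["x_r"]]) + 1L
  sub <- rgb_image(unclass(img)[rows, cols, , drop = FALSE])
  s <- rgb_to_saturation(sub)
  b <- channel(sub, 3L)
  nuc <- nucleus_mask[rows, cols, drop = FALSE]
  bg <- exclude_mask[rows, cols, drop = FALSE] == 0L & nuc == 0L
  empty <- function() {
    cyto <- matrix(0L, h, w)
    cell <- matrix(0L, h, w)
    cell[rows, cols][nuc == 1L] <- 1L
    list(cell_mask = cell, cytoplasm_mask = cyto, cyto_area_px = 0L)
  }
  if (!any(bg)) return(empty())
  sv <- s[bg]; bv <- b[bg]
  if (min(sv) == max(sv) || min(bv) == max(bv)) return(empty())
  # Otsu always splits, even a unimodal noise histogram; demand a minimal
  # 8-bit contrast between the two classes, otherwise there is no
  # cytoplasm-like population in the ROI at all (the artifact case)
  split_ok <- function(v, t) {
    lo <- v[v <= t]; hi <- v[v > t]
    length(hi) > 0 && length(lo) > 0 && mean(hi) - mean(lo) >= 15
  }
  ts <- as.integer(otsu_threshold(histogram256(sv)))
  tb <- as.integer(otsu_threshold(histogram256(bv)))
  if (!split_ok(sv, ts) || !split_ok(bv, tb)) return(empty())
  fg <- matrix(0L, nrow(nuc), ncol(nuc))
  fg[(s > ts & b > tb) | nuc == 1L] <- 1L
  lab <- label_regions(fg, 8L)
  keep <- unique(lab[nuc == 1L & lab > 0L])
  cell_roi <- matrix(0L, nrow(nuc), ncol(nuc))
  cell_roi[lab %in% keep] <- 1L
  cyto_roi <- cell_roi
  cyto_roi[nuc == 1L] <- 0L
  cell <- matrix(0L, h, w); cell[rows, cols] <- cell_roi
  cyto <- matrix(0L, h, w); cyto[rows, cols] <- cyto_roi
  list(cell_mask = cell, cytoplasm_mask = cyto,
       cyto_area_px = sum(cyto_roi))
}

#' Artifact judgment from the cytoplasm/nucleus area ratio
#'
#' @param cyto_area_px cytoplasm area, pixels.
#' @param nucleus_area_px nucleus area, pixels (must be >= 1).
#' @param params an [artifact_params] object.
#' @return list with `is_artifact` (TRUE iff ratio is strictly below
#'   `ratio_min`) and `ratio`.
#' @export
is_artifact <- function(cyto_area_px, nucleus_area_px,
                        params = artifact_params()) {
  if (length(nucleus_area_px) != 1L || is.na(nucleus_area_px) ||
      nucleus_area_px < 1)
    stop("is_artifact: nucleus_area_px must be >= 1")
  ratio <- as.numeric(cyto_area_px) / as.numeric(nucleus_area_px)
  list(is_artifact = ratio < params$ratio_min, ratio = ratio)
}
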