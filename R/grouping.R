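#' Lobe-grouping parameters
#'
#' Multilobed (chiefly neutrophil) nuclei can segment into several regions
#' that must be re-grouped into one nucleus. Two empirical constants drive
#' the judgment: `s0`, the largest area a single lobe can have (regions
#' larger than `s0` are whole nuclei, never lobes), and `d0`, the largest
#' centroid-to-centroid Euclidean distance at which two small regions are
#' lobes of the same nucleus.
#'
#' Neither constant is a published number; both are calibration values.
#' Defaults (`s0` = 2500 px, `d0` = 60 px) are tuned to the synthetic
#' generator's geometry at the nominal 1024x768 image size and are fully
#' configurable.
#'
#' @param s0 maximum lobe area, pixels.
#' @param d0 maximum same-nucleus centroid distance, pixels.
#' @return a `grouping_params` list.
#' @export
grouping_params <- function(s0 = 2500L, d0 = 60) {
  s0 <- as.integer(s0)
  if (is.na(s0) || s0 < 1L) stop("s0 must be >= 1")
  d0 <- as.numeric(d0)
  if (is.na(d0) || d0 <= 0) stop("d0 must be > 0")
  structure(list(s0 = s0, d0 = d0), class = "grouping_params")
}

#' Region areas and centroids of a labeled mask
#'
#' @param labeled labeled mask.
#' @return data frame with one row per positive label: `label`, `area_px`,
#'   and the centroid `cx`, `cy` (arithmetic mean of member 0-based
#'   column/row coordinates).
#' @export
extract_regions <- function(labeled) {
  labeled <- as_labeled_mask(labeled)
  n <- n_labels(labeled)
  if (n == 0L)
    return(data.frame(label = integer(), area_px = integer(),
                      cx = numeric(), cy = numeric()))
  pos <- which(labeled > 0L)
  lab <- labeled[pos]
  h <- nrow(labeled)
  y <- (pos - 1L) %% h          # 0-based row
  x <- (pos - 1L) %/% h         # 0-based col
  area <- tabulate(lab, nbins = n)
  data.frame(label = seq_len(n),
             area_px = area,
             cx = as.vector(rowsum(as.numeric(x), lab)) / area,
             cy = as.vector(rowsum(as.numeric(y), lab)) / area)
}

#' Group segmented regions into nuclei (lobe judgment)
#'
#' Regions with area exceeding `s0` cannot be lobes: each forms a singleton
#' group (they are still emitted as nuclei). Among the remaining regions,
#' two belong to the same nucleus iff they are connected by a chain of
#' pairwise centroid distances `<= d0` (single-linkage transitive closure;
#' ties at exactly `d0` merge). The closure makes the partition independent
#' of the order regions are visited in.
#'
#' @param regions data frame from [extract_regions()].
#' @param params a [grouping_params] object.
#' @return list of integer vectors of region labels, one per nucleus, each
#'   sorted ascending; groups ordered by their smallest member label.
#' @export
group_lobes <- function(regions, params = grouping_params()) {
  n <- nrow(regions)
  if (n == 0L) return(list())
  small <- regions$area_px <= params$s0
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  idx <- which(small)
  if (length(idx) >= 2L) {
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in (a + 1L):length(idx)) {
        i <- idx[a]; j <- idx[b]
        d <- sqrt((regions$cx[i] - regions$cx[j])^2 +
                  (regions$cy[i] - regions$cy[j])^2)
        if (d <= params$d0) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(regions$label, root)
  groups <- lapply(unname(groups), function(g) sort(as.integer(g)))
  groups[order(vapply(groups, min, integer(1)))]
}

#' Projection-profile bounding box of a mask
#'
#' The vertical projection (column sums) and horizontal projection (row
#' sums) of the binary mask delimit the nucleus: `x_l`/`x_r` are the first
#' and last columns with nonzero vertical projection, `y_t`/`y_b` the first
#' and last rows with nonzero horizontal projection. The center is the
#' integerized midpoint `x_c = floor((x_l + x_r) / 2)` (likewise `y_c`), and
#' the extents are `w = x_r - x_l`, `h = y_b - y_t` (closed boxes: a single
#' pixel has `w = h = 0`). This is exactly the coordinate min/max of the
#' foreground, which the tests exploit as an independent oracle.
#'
#' @param group_mask binary mask with at least one foreground pixel.
#' @return named integer vector `x_l, x_r, y_t, y_b, x_c, y_c, w, h`
#'   (0-based coordinates).
#' @export
project_bbox <- function(group_mask) {
  stopifnot(is.matrix(group_mask))
  prj_v <- colSums(group_mask)   # per-column mass -> x bounds
  prj_h <- rowSums(group_mask)   # per-row mass -> y bounds
  xs <- which(prj_v > 0)
  ys <- which(prj_h > 0)
  if (length(xs) == 0L) stop("project_bbox: mask has no foreground pixel")
  x_l <- xs[1L] - 1L; x_r <- xs[length(xs)] - 1L
  y_t <- ys[1L] - 1L; y_b <- ys[length(ys)] - 1L
  c(x_l = x_l, x_r = x_r, y_t = y_t, y_b = y_b,
    x_c = (x_l + x_r) %/% 2L, y_c = (y_t + y_b) %/% 2L,
    w = x_r - x_l, h = y_b - y_t)
}
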