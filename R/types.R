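#' Construct an 8-bit RGB image
#'
#' The raster container used throughout the package: an integer array of
#' dimension `height x width x 3` with channel values in 0..255, channels
#' ordered R, G, B.
#'
#' @section Coordinate convention:
#' All coordinates in this package are 0-based: `x` is the column index,
#' `y` the row index, `y` increasing downward. A matrix cell `(row r, col c)`
#' (1-based R indexing) therefore corresponds to `(x = c - 1, y = r - 1)` in
#' every serialized record. Bounding boxes are closed intervals
#' `x_l..x_r`, `y_t..y_b` (inclusive), so a single-column box has width
#' `w = x_r - x_l = 0`.
#'
#' @param px numeric or integer array, `h x w x 3`, values in 0..255.
#' @return an integer array of class `rgb_image`.
#' @export
rgb_image <- function(px) {
  if (!is.array(px) || length(dim(px)) != 3L || dim(px)[3] != 3L)
    stop("rgb_image: `px` must be an h x w x 3 array")
  if (dim(px)[1] < 1L || dim(px)[2] < 1L)
    stop("rgb_image: height and width must be >= 1")
  storage.mode(px) <- "integer"
  if (anyNA(px) || min(px) < 0L || max(px) > 255L)
    stop("rgb_image: channel values must be integers in [0, 255]")
  class(px) <- "rgb_image"
  px
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d, 8-bit RGB>\n", d[1], d[2]))
  invisible(x)
}

# internal: channel matrix extraction keeping integer mode
channel <- function(img, i) {
  m <- img[, , i, drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, nrow = dim(img)[1])
  storage.mode(m) <- "integer"
  m
}

#' Validate a binary mask
#'
#' A binary mask is an integer matrix containing only 0 and 1.
#'
#' @param m matrix to check.
#' @return `m`, as an integer matrix, invisibly validated.
#' @export
as_binary_mask <- function(m) {
  if (!is.matrix(m)) stop("binary mask must be a matrix")
  storage.mode(m) <- "integer"
  if (anyNA(m) || !all(m == 0L | m == 1L))
    stop("binary mask must contain only 0 and 1")
  m
}

#' Validate a labeled mask
#'
#' A labeled mask is an integer matrix of non-negative region labels
#' (0 = background) whose positive values form the contiguous set
#' `1..n_labels`; the count is carried in the `n_labels` attribute.
#'
#' @param m integer matrix of labels.
#' @return `m` with a consistent `n_labels` attribute.
#' @export
as_labeled_mask <- function(m) {
  if (!is.matrix(m)) stop("labeled mask must be a matrix")
  storage.mode(m) <- "integer"
  if (anyNA(m) || min(m) < 0L) stop("labels must be non-negative integers")
  u <- sort(unique(m[m > 0L]))
  n <- length(u)
  if (n > 0L && !identical(u, seq_len(n)))
    stop("positive labels must form the contiguous set 1..n_labels")
  attr(m, "n_labels") <- n
  m
}

#' Number of labels of a labeled mask
#' @param m labeled mask.
#' @return integer count of positive labels.
#' @export
n_labels <- function(m) {
  n <- attr(m, "n_labels")
  if (is.null(n)) n <- length(unique(m[m > 0L]))
  as.integer(n)
}
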