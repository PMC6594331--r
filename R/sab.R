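#' 256-bin histogram of 8-bit values
#'
#' @param values integer vector or matrix with values in 0..255.
#' @return integer vector of length 256, `counts[v + 1]` = multiplicity of
#'   value `v`.
#' @export
histogram256 <- function(values) {
  v <- as.integer(values)
  if (length(v) && (min(v) < 0L || max(v) > 255L))
    stop("histogram256: values must be in 0..255")
  tabulate(v + 1L, nbins = 256L)
}

#' Otsu's threshold from a 256-bin histogram
#'
#' Returns the threshold `t` in 0..255 maximizing the between-class variance
#' of the split into values `<= t` versus `> t`; on ties the smallest
#' maximizing `t` is returned (fixed for determinism). A histogram with a
#' single occupied bin is degenerate (there is nothing to split): that bin's
#' index is returned with attribute `degenerate = TRUE`.
#'
#' @param counts integer vector of length 256 (see [histogram256()]).
#' @return integer threshold with logical attribute `degenerate`.
#' @export
otsu_threshold <- function(counts) {
  if (length(counts) != 256L) stop("otsu_threshold: need 256 bin counts")
  counts <- as.numeric(counts)
  total <- sum(counts)
  if (total < 1) stop("otsu_threshold: empty histogram")
  occupied <- which(counts > 0)
  if (length(occupied) == 1L) {
    t <- occupied - 1L
    attr(t, "degenerate") <- TRUE
    return(t)
  }
  p <- counts / total
  v <- 0:255
  w0 <- cumsum(p)
  m0 <- cumsum(p * v)
  mt <- m0[256L]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, 256L)
  sigma_b[valid] <- (mt * w0[valid] - m0[valid])^2 / (w0[valid] * w1[valid])
  t <- which.max(sigma_b) - 1L   # which.max takes the first (smallest) tie
  attr(t, "degenerate") <- FALSE
  t
}

#' SAB baseline nucleus segmentation (Otsu on S and B)
#'
#' The comparator method: Otsu-binarize the saturation component and the
#' blue component of the image (foreground = strictly above threshold; in
#' stained smears nuclei are the saturated, blue extreme), intersect the two
#' foregrounds, and remove components smaller than the shared minimum
#' nucleus area. Unlike the B-G method the thresholds here are recomputed
#' per image, which is exactly the cost the fixed-threshold method avoids.
#'
#' @param img an [rgb_image].
#' @param params a [segmentation_params] (uses `min_nucleus_area_px` and
#'   `connectivity`).
#' @return binary mask of segmented nucleus pixels.
#' @export
segment_nucleus_sab <- function(img, params = segmentation_params()) {
  stopifnot(inherits(img, "rgb_image"))
  s <- rgb_to_saturation(img)
  b <- channel(img, 3L)
  ts <- otsu_threshold(histogram256(s))
  tb <- otsu_threshold(histogram256(b))
  fg <- matrix(0L, nrow(s), ncol(s))
  fg[s > as.integer(ts) & b > as.integer(tb)] <- 1L
  lab <- label_regions(fg, params$connectivity)
  lab <- size_filter(lab, params$min_nucleus_area_px)
  out <- matrix(0L, nrow(s), ncol(s))
  out[lab > 0L] <- 1L
  out
}
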