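#' Read a raster image as an 8-bit RGB image
#'
#' Supported containers: PNG and JPEG (via the \pkg{png} / \pkg{jpeg}
#' packages), plus uncompressed baseline BMP (24-bit) and uncompressed
#' baseline TIFF (8-bit grayscale or RGB) read natively. The format is
#' sniffed from the file's magic bytes, not its extension. Grayscale inputs
#' are replicated across the three channels; an alpha channel is dropped.
#' Inputs deeper than 8 bits per sample are rejected: the whole pipeline is
#' an 8-bit pipeline.
#'
#' @param path path to a PNG, TIFF, BMP or JPEG file.
#' @return an [rgb_image].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("read_image: no such file: ", path)
  magic <- readBin(path, "raw", n = 4L)
  if (length(magic) < 4L) stop("read_image: unreadable or truncated file: ", path)
  if (identical(magic, as.raw(c(0x89, 0x50, 0x4e, 0x47)))) {
    a <- png::readPNG(path, info = TRUE)
    info <- attr(a, "info")
    if (!is.null(info$bit.depth) && info$bit.depth > 8L)
      stop("read_image: ", path, ": ", info$bit.depth,
           "-bit PNG not supported (8-bit contract)")
    return(.planes_to_rgb(a))
  }
  if (identical(magic[1:2], as.raw(c(0xff, 0xd8)))) {
    return(.planes_to_rgb(jpeg::readJPEG(path)))
  }
  if (identical(magic[1:2], as.raw(c(0x42, 0x4d)))) {
    return(.read_bmp(path))
  }
  if (identical(magic, as.raw(c(0x49, 0x49, 0x2a, 0x00))) ||
      identical(magic, as.raw(c(0x4d, 0x4d, 0x00, 0x2a)))) {
    return(.read_tiff(path))
  }
  stop("read_image: ", path, ": unsupported image format")
}

# normalized [0,1] array/matrix from png/jpeg -> rgb_image
.planes_to_rgb <- function(a) {
  v <- as.integer(round(a * 255))
  if (is.matrix(a)) {
    arr <- array(v, dim = c(nrow(a), ncol(a), 3L))
  } else {
    d <- dim(a)
    a <- array(v, dim = d)
    if (d[3] >= 3L) {
      arr <- a[, , 1:3, drop = FALSE]
    } else {
      # grayscale (+ optional alpha): replicate the first plane
      arr <- array(a[, , 1L], dim = c(d[1], d[2], 3L))
    }
  }
  rgb_image(arr)
}

.read_bmp <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  le32 <- function(i) sum(as.integer(raw[i + 1:4]) * c(1, 256, 65536, 16777216))
  le16 <- function(i) sum(as.integer(raw[i + 1:2]) * c(1, 256))
  data_off <- le32(10L)
  w <- le32(18L)
  h0 <- le32(22L)
  top_down <- h0 > 2^31 - 1
  h <- if (top_down) 2^32 - h0 else h0
  bpp <- le16(28L)
  comp <- le32(30L)
  if (comp != 0 || bpp != 24)
    stop("read_image: only uncompressed 24-bit BMP is supported")
  stride <- ((w * 3 + 3) %/% 4) * 4
  px <- array(0L, dim = c(h, w, 3L))
  for (r in seq_len(h)) {
    # BMP rows are bottom-up unless height was negative
    file_row <- if (top_down) r else h - r + 1L
    off <- data_off + (file_row - 1L) * stride
    row <- as.integer(raw[off + seq_len(w * 3)])
    px[r, , 3L] <- row[seq(1L, by = 3L, length.out = w)]  # B
    px[r, , 2L] <- row[seq(2L, by = 3L, length.out = w)]  # G
    px[r, , 1L] <- row[seq(3L, by = 3L, length.out = w)]  # R
  }
  rgb_image(px)
}

.read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  big <- identical(raw[1:2], charToRaw("MM"))
  rd <- function(off, n, size) {
    # read n unsigned ints of `size` bytes at 0-based offset
    m <- matrix(as.integer(raw[off + seq_len(n * size)]), nrow = size)
    mult <- 256^(0:(size - 1))
    if (big) mult <- rev(mult)
    as.numeric(colSums(m * mult))
  }
  ifd_off <- rd(4L, 1L, 4L)
  n_ent <- rd(ifd_off, 1L, 2L)
  tags <- list()
  type_size <- c(1, 1, 2, 4, 8)  # BYTE ASCII SHORT LONG RATIONAL
  for (k in seq_len(n_ent)) {
    e <- ifd_off + 2L + (k - 1L) * 12L
    tag <- rd(e, 1L, 2L)
    typ <- rd(e + 2L, 1L, 2L)
    cnt <- rd(e + 4L, 1L, 4L)
    sz <- if (typ >= 1 && typ <= 5) type_size[typ] else 1
    esz <- if (typ == 3) 2L else 4L
    if (cnt * sz <= 4) {
      val <- rd(e + 8L, cnt, esz)
    } else {
      off <- rd(e + 8L, 1L, 4L)
      val <- rd(off, cnt, esz)
    }
    tags[[as.character(tag)]] <- val
  }
  need <- function(t, default = NULL) {
    v <- tags[[as.character(t)]]
    if (is.null(v)) {
      if (is.null(default)) stop("read_image: TIFF missing tag ", t)
      v <- default
    }
    v
  }
  w <- need(256); h <- need(257)
  bits <- need(258, 8)
  if (any(bits != 8))
    stop("read_image: ", max(bits), "-bit TIFF not supported (8-bit contract)")
  if (need(259, 1) != 1)
    stop("read_image: only uncompressed TIFF is supported")
  spp <- need(277, 1)
  offs <- need(273)
  cnts <- need(279, w * h * spp)
  rps <- need(278, h)
  bytes <- unlist(lapply(seq_along(offs), function(i)
    as.integer(raw[offs[i] + seq_len(cnts[i])])), use.names = FALSE)
  if (length(bytes) < w * h * spp) stop("read_image: truncated TIFF data")
  if (spp >= 3) {
    # chunky RGB(+extra): pixel-interleaved, row-major
    pix <- matrix(bytes[seq_len(w * h * spp)], nrow = spp)
    px <- array(0L, dim = c(h, w, 3L))
    for (ch in 1:3) px[, , ch] <- matrix(pix[ch, ], nrow = h, byrow = TRUE)
  } else {
    g <- matrix(bytes[seq_len(w * h)], nrow = h, byrow = TRUE)
    px <- array(g, dim = c(h, w, 3L))
  }
  rgb_image(px)
}

#' Write an RGB image as PNG
#'
#' @param img an [rgb_image].
#' @param path output path (PNG).
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  a <- unclass(img) / 255
  png::writePNG(a, path)
  invisible(NULL)
}

#' Write a binary or labeled mask as PNG
#'
#' Binary masks (values 0/1) are written as 8-bit grayscale PNG scaled to
#' 0/255. Labeled masks are written as 16-bit grayscale PNG carrying the raw
#' label values, so up to 65535 labels round-trip exactly.
#'
#' @param mask binary mask or labeled mask (integer matrix).
#' @param path output path (PNG).
#' @export
write_mask <- function(mask, path) {
  if (!is.matrix(mask)) stop("write_mask: mask must be a matrix")
  storage.mode(mask) <- "integer"
  mx <- if (length(mask)) max(mask) else 0L
  if (mx <= 1L) {
    png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  } else {
    if (mx > 65535L) stop("write_mask: more than 65535 labels cannot be stored")
    .write_png16(mask, path)
  }
  invisible(NULL)
}

#' Read a mask written by [write_mask()]
#'
#' @param path PNG path.
#' @return integer matrix; binary masks come back as 0/1, labeled masks with
#'   their original labels (via [as_labeled_mask()] if labels are present).
#' @export
read_mask <- function(path) {
  a <- png::readPNG(path, info = TRUE)
  info <- attr(a, "info")
  depth <- if (is.null(info$bit.depth)) 8L else info$bit.depth
  if (!is.matrix(a)) a <- a[, , 1L]
  m <- matrix(as.integer(round(a * (2^depth - 1))), nrow(a))
  if (depth == 8L) m <- m %/% 255L else m <- as_labeled_mask(m)
  m
}

# minimal 16-bit grayscale PNG encoder (png::writePNG is 8-bit only);
# deflate stream via memCompress (zlib format), CRC-32 from src/.
.write_png16 <- function(m, path) {
  h <- nrow(m); w <- ncol(m)
  be <- function(x, n) {
    out <- raw(n)
    for (i in n:1) { out[i] <- as.raw(x %% 256); x <- x %/% 256 }
    out
  }
  chunk <- function(type, data) {
    body <- c(charToRaw(type), data)
    crc <- .crc32_cpp(body)
    c(be(length(data), 4L), body, be(crc, 4L))
  }
  ihdr <- c(be(w, 4L), be(h, 4L), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  v <- as.vector(t(m))                        # row-major pixel stream
  bytes <- matrix(as.raw(rbind(v %/% 256L, v %% 256L)), nrow = 2L * w)
  scan <- as.vector(rbind(matrix(as.raw(0L), 1L, h), bytes))  # filter byte 0
  idat <- memCompress(scan, type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  writeBin(chunk("IHDR", ihdr), con)
  writeBin(chunk("IDAT", idat), con)
  writeBin(chunk("IEND", raw(0)), con)
  invisible(NULL)
}

.DET_FIELDS <- c("x_l", "x_r", "y_t", "y_b", "x_c", "y_c", "w", "h",
                 "area_px", "n_lobes", "is_artifact", "cyto_nucleus_ratio")

#' An empty detection table
#'
#' Detections are plain data frames with one row per located nucleus and the
#' fixed column schema `x_l, x_r, y_t, y_b, x_c, y_c, w, h, area_px, n_lobes,
#' is_artifact, cyto_nucleus_ratio` (coordinates 0-based, boxes inclusive).
#'
#' @return a zero-row detection data frame.
#' @export
empty_detections <- function() {
  d <- data.frame(x_l = integer(), x_r = integer(), y_t = integer(),
                  y_b = integer(), x_c = integer(), y_c = integer(),
                  w = integer(), h = integer(), area_px = integer(),
                  n_lobes = integer(), is_artifact = logical(),
                  cyto_nucleus_ratio = numeric())
  class(d) <- c("nucleus_detections", "data.frame")
  d
}

.validate_detections <- function(dets) {
  if (!is.data.frame(dets) || !all(.DET_FIELDS %in% names(dets)))
    stop("detections must be a data frame with the 12-column schema")
  dets[.DET_FIELDS]
}

#' Serialize nucleus detections
#'
#' Writes one record per detection with the fixed field order documented in
#' [empty_detections()]; output is deterministic for a fixed input.
#'
#' @param dets detection data frame.
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @export
write_detections <- function(dets, path, format = c("csv", "json")) {
  format <- match.arg(format)
  dets <- .validate_detections(dets)
  if (format == "csv") {
    utils::write.table(dets, path, sep = ",", row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
  } else {
    jsonlite::write_json(dets, path, dataframe = "rows", digits = NA,
                         auto_unbox = FALSE)
  }
  invisible(NULL)
}

#' Read detections written by [write_detections()]
#'
#' @param path input path.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @return detection data frame.
#' @export
read_detections <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  d <- if (format == "json") {
    x <- jsonlite::fromJSON(path)
    if (length(x) == 0) empty_detections() else as.data.frame(x)
  } else {
    utils::read.csv(path)
  }
  if (nrow(d) == 0) return(empty_detections())
  d$is_artifact <- as.logical(d$is_artifact)
  for (f in setdiff(.DET_FIELDS, c("is_artifact", "cyto_nucleus_ratio")))
    d[[f]] <- as.integer(d[[f]])
  d <- d[.DET_FIELDS]
  class(d) <- c("nucleus_detections", "data.frame")
  d
}
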