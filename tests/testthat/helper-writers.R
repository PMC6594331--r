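# Independent minimal encoders used as round-trip oracles for read_image():
# written directly from the BMP / TIFF format descriptions, sharing nothing
# with the package's readers.

le_bytes <- function(x, n) as.raw((x %/% 256^(0:(n - 1))) %% 256)

# 24-bit uncompressed bottom-up BMP from an rgb_image-like array
write_bmp24_oracle <- function(px, path) {
  h <- dim(px)[1]; w <- dim(px)[2]
  stride <- ((w * 3 + 3) %/% 4) * 4
  body <- raw(stride * h)
  for (r in seq_len(h)) {
    row <- h - r + 1L   # bottom-up
    off <- (r - 1L) * stride
    for (c in seq_len(w)) {
      body[off + (c - 1L) * 3L + 1:3] <-
        as.raw(c(px[row, c, 3], px[row, c, 2], px[row, c, 1]))  # BGR
    }
  }
  hdr <- c(charToRaw("BM"), le_bytes(54 + length(body), 4),
           raw(4), le_bytes(54, 4),
           le_bytes(40, 4), le_bytes(w, 4), le_bytes(h, 4),
           le_bytes(1, 2), le_bytes(24, 2), raw(4),
           le_bytes(length(body), 4), raw(16))
  writeBin(c(hdr, body), path)
}

# little-endian baseline uncompressed TIFF; gray matrix (spp = 1) or
# h x w x 3 array (spp = 3); `bits` per sample (8 or 16 for contract tests)
write_tiff_oracle <- function(px, path, bits = 8L) {
  gray <- is.matrix(px)
  h <- if (gray) nrow(px) else dim(px)[1]
  w <- if (gray) ncol(px) else dim(px)[2]
  spp <- if (gray) 1L else 3L
  vals <- if (gray) as.vector(t(px)) else {
    # pixel-interleaved, row-major
    a <- aperm(px, c(3, 2, 1))
    as.vector(a)
  }
  data <- if (bits == 8L) as.raw(vals) else
    as.raw(rbind(vals %% 256, vals %/% 256))  # 16-bit little-endian
  entry <- function(tag, type, count, value_bytes) {
    c(le_bytes(tag, 2), le_bytes(type, 2), le_bytes(count, 4),
      value_bytes, raw(4 - length(value_bytes)))
  }
  n_entries <- if (gray) 8L else 8L
  ifd_off <- 8L
  data_off <- ifd_off + 2L + n_entries * 12L + 4L
  bits_bytes <- if (spp == 3L) NULL else le_bytes(bits, 2)
  bits_off <- data_off + length(data)
  entries <- c(
    entry(256, 4, 1, le_bytes(w, 4)),
    entry(257, 4, 1, le_bytes(h, 4)),
    if (spp == 3L) entry(258, 3, 3, le_bytes(bits_off, 4))
    else entry(258, 3, 1, le_bytes(bits, 2)),
    entry(259, 3, 1, le_bytes(1, 2)),
    entry(262, 3, 1, le_bytes(if (gray) 1 else 2, 2)),
    entry(273, 4, 1, le_bytes(data_off, 4)),
    entry(277, 3, 1, le_bytes(spp, 2)),
    entry(279, 4, 1, le_bytes(length(data), 4)))
  out <- c(charToRaw("II"), le_bytes(42, 2), le_bytes(ifd_off, 4),
           le_bytes(n_entries, 2), entries, le_bytes(0, 4), data)
  if (spp == 3L)
    out <- c(out, le_bytes(bits, 2), le_bytes(bits, 2), le_bytes(bits, 2))
  writeBin(out, path)
}
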