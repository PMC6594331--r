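test_that("PNG round-trip is bit-exact and coordinate convention holds", {
  px <- array(0L, c(3, 3, 3))
  px[, , 1] <- 10L; px[, , 2] <- 20L; px[, , 3] <- 30L
  img <- rgb_image(px)
  f <- withr::local_tempfile(fileext = ".png")
  write_image(img, f)
  back <- read_image(f)
  expect_identical(unclass(back), unclass(img))

  # (row r, col c) maps to (x = c-1, y = r-1): put one odd pixel and check
  px[2, 3, ] <- c(1L, 2L, 3L)
  write_image(rgb_image(px), f)
  back <- read_image(f)
  expect_identical(back[2, 3, ], c(1L, 2L, 3L))
})

test_that("16-bit input is rejected (8-bit contract), grayscale replicated", {
  f16 <- withr::local_tempfile(fileext = ".png")
  leukoseg:::.write_png16(matrix(c(0L, 300L, 70000 %/% 2L, 5L), 2), f16)
  expect_error(read_image(f16), "16-bit")

  ft <- withr::local_tempfile(fileext = ".tif")
  write_tiff_oracle(matrix(c(1L, 2L, 3L, 4L), 2), ft, bits = 16L)
  expect_error(read_image(ft), "16-bit")

  # grayscale PNG replicates across channels
  fg <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(c(0, 0.5, 1, 0.2), 2), fg)
  g <- read_image(fg)
  expect_identical(g[, , 1], g[, , 3])
})

test_that("BMP and TIFF readers agree with independent encoders", {
  set.seed(11)
  for (i in 1:5) {
    h <- sample(2:9, 1); w <- sample(2:9, 1)
    px <- unclass(random_rgb(h, w))
    fb <- withr::local_tempfile(fileext = ".bmp")
    write_bmp24_oracle(px, fb)
    expect_identical(unclass(read_image(fb)), px)
    ft <- withr::local_tempfile(fileext = ".tif")
    write_tiff_oracle(px, ft)
    expect_identical(unclass(read_image(ft)), px)
  }
  # grayscale TIFF replicates channels
  g <- matrix(sample(0:255, 24, TRUE), 4)
  ft <- withr::local_tempfile(fileext = ".tif")
  write_tiff_oracle(g, ft)
  r <- read_image(ft)
  expect_identical(r[, , 2], g)
  expect_identical(r[, , 1], r[, , 3])
})

test_that("mask round-trips: binary 0/255, labels in 16-bit, capacity error", {
  f <- withr::local_tempfile(fileext = ".png")
  empty <- matrix(0L, 4, 5)
  write_mask(empty, f)
  expect_identical(read_mask(f), empty)
  expect_true(all(png::readPNG(f) %in% c(0, 1)))  # stored as {0,255}/255

  set.seed(7)
  for (i in 1:20) {
    m <- random_mask(sample(3:20, 1), sample(3:20, 1))
    lab <- label_regions(m, 8L)
    write_mask(lab, f)
    back <- read_mask(f)
    expect_identical(matrix(as.integer(back), nrow(back)),
                     matrix(as.integer(lab), nrow(lab)))
  }
  # labels beyond 255 need the 16-bit path
  big <- as_labeled_mask(matrix(seq_len(300L), 1))
  write_mask(big, f)
  expect_identical(as.integer(read_mask(f)), as.integer(big))
  expect_error(write_mask(matrix(70000L, 1), f), "65535")
})

test_that("detection serialization round-trips in CSV and JSON", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_detections(empty_detections(), f)
  expect_identical(readLines(f), paste(names(empty_detections()), collapse = ","))
  fj <- withr::local_tempfile(fileext = ".json")
  write_detections(empty_detections(), fj, format = "json")
  expect_identical(nrow(read_detections(fj)), 0L)

  set.seed(21)
  d <- random_detections(25)
  write_detections(d, f)
  write_detections(d, fj, format = "json")
  for (back in list(read_detections(f), read_detections(fj))) {
    expect_identical(names(back), names(empty_detections()))
    for (col in names(d)) expect_equal(back[[col]], d[[col]], tolerance = 1e-9)
  }
  # deterministic bytes for fixed input
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_detections(d, f2)
  expect_identical(readLines(f), readLines(f2))
})
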