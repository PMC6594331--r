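test_that("extract_regions reports exact areas and centroids", {
  m <- matrix(0L, 8, 10); m[5, 8] <- 1L   # r=5,c=8 -> (x=7, y=4)
  r <- extract_regions(label_regions(m))
  expect_equal(r$area_px, 1L)
  expect_equal(c(r$cx, r$cy), c(7, 4))

  m <- matrix(0L, 5, 5); m[1:2, 1:2] <- 1L
  r <- extract_regions(label_regions(m))
  expect_equal(r$area_px, 4L)
  expect_equal(c(r$cx, r$cy), c(0.5, 0.5))

  set.seed(9)
  for (i in 1:20) {
    m <- random_mask(sample(4:15, 1), sample(4:15, 1))
    lab <- label_regions(m, 8L)
    got <- extract_regions(lab)
    for (l in seq_len(n_labels(lab))) {
      pos <- which(lab == l, arr.ind = TRUE)
      expect_identical(got$area_px[l], nrow(pos))
      expect_equal(got$cx[l], mean(pos[, 2] - 1))
      expect_equal(got$cy[l], mean(pos[, 1] - 1))
    }
  }
})

regions_df <- function(areas, cx, cy) {
  data.frame(label = seq_along(areas), area_px = as.integer(areas),
             cx = cx, cy = cy)
}

test_that("group_lobes implements the S0/D0 judgment", {
  gp <- grouping_params(s0 = 100, d0 = 10)
  # two small regions beyond d0: independent nuclei
  expect_length(group_lobes(regions_df(c(50, 50), c(0, 20), c(0, 0)), gp), 2L)
  # a single region is one nucleus
  expect_length(group_lobes(regions_df(40, 3, 3), gp), 1L)
  # chain A-B-C merges transitively even though d(A,C) > d0
  g <- group_lobes(regions_df(c(10, 10, 10), c(0, 9, 18), c(0, 0, 0)), gp)
  expect_identical(g, list(1:3))
  # a large region is exempt from merging even when adjacent
  g <- group_lobes(regions_df(c(500, 10), c(0, 5), c(0, 0)), gp)
  expect_length(g, 2L)
  # ties at exactly d0 merge
  g <- group_lobes(regions_df(c(10, 10), c(0, 10), c(0, 0)), gp)
  expect_length(g, 1L)
  expect_identical(group_lobes(regions_df(integer(), numeric(), numeric()), gp),
                   list())
})

test_that("group_lobes equals the closure oracle and is order-invariant", {
  set.seed(10)
  for (i in 1:60) {
    n <- sample(1:9, 1)
    reg <- regions_df(sample(c(10, 20, 3000), n, TRUE),
                      runif(n, 0, 100), runif(n, 0, 100))
    gp <- grouping_params(s0 = 2500, d0 = runif(1, 5, 40))
    expect_identical(group_lobes(reg, gp), oracle_groups(reg, gp$s0, gp$d0))
    # permuting the input rows yields the same partition
    perm <- sample(n)
    shuffled <- reg[perm, ]
    expect_identical(group_lobes(shuffled, gp), group_lobes(reg, gp))
  }
})

test_that("project_bbox matches the spec'd arithmetic and min/max oracle", {
  m <- matrix(0L, 10, 12); m[6, 10] <- 1L   # single pixel (x=9, y=5)
  expect_identical(project_bbox(m),
                   c(x_l = 9L, x_r = 9L, y_t = 5L, y_b = 5L,
                     x_c = 9L, y_c = 5L, w = 0L, h = 0L))

  m <- matrix(0L, 40, 60); m[11:21, 31:52] <- 1L  # rows 10..20, cols 30..51
  bb <- project_bbox(m)
  expect_identical(bb, c(x_l = 30L, x_r = 51L, y_t = 10L, y_b = 20L,
                         x_c = 40L, y_c = 15L, w = 21L, h = 10L))

  expect_error(project_bbox(matrix(0L, 3, 3)), "foreground")

  set.seed(12)
  for (i in 1:60) {
    m <- random_mask(sample(3:25, 1), sample(3:25, 1), p = 0.15)
    if (!any(m > 0)) next
    bb <- project_bbox(m)
    expect_identical(bb, oracle_bbox(m))
    # every foreground pixel lies inside the box
    pos <- which(m > 0, arr.ind = TRUE)
    expect_true(all(pos[, 2] - 1 >= bb[["x_l"]] & pos[, 2] - 1 <= bb[["x_r"]]))
    expect_true(all(pos[, 1] - 1 >= bb[["y_t"]] & pos[, 1] - 1 <= bb[["y_b"]]))
  }

  # merging two groups never shrinks the box
  a <- matrix(0L, 10, 10); a[2:3, 2:3] <- 1L
  b <- matrix(0L, 10, 10); b[7:8, 8:9] <- 1L
  u <- a | b; storage.mode(u) <- "integer"
  ba <- project_bbox(a); bu <- project_bbox(u)
  expect_true(bu[["x_l"]] <= ba[["x_l"]] && bu[["x_r"]] >= ba[["x_r"]])
  expect_true(bu[["y_t"]] <= ba[["y_t"]] && bu[["y_b"]] >= ba[["y_b"]])
})
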