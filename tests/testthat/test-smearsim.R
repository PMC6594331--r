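test_that("empty scene is pure background, generation is deterministic", {
  p <- scene_params(width = 128, height = 96, n_leukocytes = 0,
                    n_platelets = 0, n_stains = 0, n_erythrocytes = 0,
                    n_artifacts = 0, seed = 3)
  sc <- generate_scene(p)
  expect_length(sc$truth$objects, 0L)
  # background has G > B with margin: even after noise B-G stays <= 10,
  # so the pipeline finds nothing at any compliant threshold
  expect_lte(max(bg_difference(sc$image)), 10L)
  expect_identical(nrow(run_pipeline(sc$image, pipeline_config())$detections), 0L)

  sc2 <- generate_scene(p)
  expect_identical(sc$image, sc2$image)
  expect_identical(sc$truth, sc2$truth)

  sc3 <- tiny_scene(seed = 41)
  sc4 <- tiny_scene(seed = 41)
  expect_identical(sc3$image, sc4$image)
})

test_that("truth and rendered scene are mutually consistent", {
  sc <- tiny_scene(seed = 42, n_leukocytes = 2, n_artifacts = 1)
  validate_palette(sc$image, sc$truth)
  h <- sc$truth$height
  classes <- vapply(sc$truth$objects, function(o) o$class, "")
  expect_identical(sum(classes == "leukocyte"), 2L)
  expect_identical(sum(classes == "artifact"), 1L)
  for (ob in sc$truth$objects) {
    px <- unlist(ob$lobes)
    if (length(px) == 0L) {
      # only an erythrocyte can vanish under later erythrocytes
      expect_identical(ob$class, "erythrocyte")
      next
    }
    # bbox and center recomputable from the masks by coordinate min/max
    m <- matrix(0L, h, sc$truth$width); m[px] <- 1L
    bb <- project_bbox(m)
    expect_identical(unname(bb[c("x_l", "x_r", "y_t", "y_b")]),
                     unname(ob$bbox))
    expect_identical(unname(bb[c("x_c", "y_c")]), unname(ob$center))
    if (ob$class == "leukocyte") {
      expect_identical(ob$nucleus_area_px, length(px))
      expect_gte(ob$cytoplasm_area_px / ob$nucleus_area_px, 0.4)
    }
    if (ob$class == "platelet") expect_lt(length(px), 200L)
  }
  # planted nuclei are pairwise disjoint
  nucs <- lapply(sc$truth$objects[classes %in% c("leukocyte", "artifact")],
                 function(o) unlist(o$lobes))
  expect_identical(anyDuplicated(unlist(nucs)), 0L)
})

test_that("equal B/G illumination shift cancels in the difference map", {
  base <- tiny_scene(seed = 43, illumination_shift = c(0L, 0L, 0L))
  shifted <- tiny_scene(seed = 43, illumination_shift = c(10L, -15L, -15L))
  expect_identical(bg_difference(shifted$image), bg_difference(base$image))
  expect_error(scene_params(illumination_shift = c(0L, 5L, -5L)), "equal")
})

test_that("infeasible scenes raise a capacity error", {
  expect_error(generate_scene(scene_params(width = 64, height = 64,
                                           n_leukocytes = 10, seed = 1)),
               "capacity")
})

test_that("scene_gallery writes reproducible scenes with valid truth", {
  d1 <- withr::local_tempdir()
  manifest <- scene_gallery(d1, 0, seed = 5)
  expect_identical(jsonlite::fromJSON(manifest)$n, 0L)

  # full frame size: gallery scenes span lobe counts and clumping modes,
  # which need the nominal 1024x768 clearance
  d2 <- withr::local_tempdir()
  scene_gallery(d2, 3, seed = 5)
  files <- list.files(d2)
  expect_length(grep("^scene_\\d+\\.png$", files), 3L)
  expect_length(grep("_truth\\.json$", files), 3L)
  for (i in 1:3) {
    img <- read_image(file.path(d2, sprintf("scene_%03d.png", i)))
    lobes <- read_mask(file.path(d2, sprintf("scene_%03d_lobes.png", i)))
    raw <- jsonlite::fromJSON(file.path(d2, sprintf("scene_%03d_truth.json", i)),
                              simplifyVector = FALSE)
    d <- bg_difference(img)
    for (ob in raw) {
      px <- which(lobes %in% unlist(ob$lobe_labels))
      if (ob$class %in% c("leukocyte", "platelet", "artifact"))
        expect_gt(min(d[px]), 110)
      if (ob$class == "stain")
        expect_lt(max(d[px]), 50)
    }
  }
  # re-running with the same seed reproduces identical bytes
  d3 <- withr::local_tempdir()
  scene_gallery(d3, 3, seed = 5)
  for (f in setdiff(files, "manifest.json"))
    expect_identical(readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     readBin(file.path(d3, f), "raw", file.size(file.path(d3, f))))
})
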