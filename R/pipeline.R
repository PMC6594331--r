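#' Assemble a full pipeline configuration
#'
#' @param segmentation a [segmentation_params] object.
#' @param grouping a [grouping_params] object.
#' @param artifact an [artifact_params] object.
#' @param method `"bg"` (fixed-threshold B-G differencing, the package's
#'   method) or `"sab"` (the Otsu-on-S-and-B baseline).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(segmentation = segmentation_params(),
                            grouping = grouping_params(),
                            artifact = artifact_params(),
                            method = c("bg", "sab")) {
  method <- match.arg(method)
  stopifnot(inherits(segmentation, "segmentation_params"),
            inherits(grouping, "grouping_params"),
            inherits(artifact, "artifact_params"))
  structure(list(segmentation = segmentation, grouping = grouping,
                 artifact = artifact, method = method),
            class = "pipeline_config")
}

.CONFIG_KEYS <- c("t0", "min_nucleus_area_px", "connectivity",
                  "s0_px", "d0_px", "ratio_min", "roi_margin_factor",
                  "method")

#' Read a pipeline configuration from YAML or JSON
#'
#' Recognized keys: `t0`, `min_nucleus_area_px`, `connectivity`, `s0_px`,
#' `d0_px`, `ratio_min`, `roi_margin_factor`, `method`; unknown keys are
#' rejected. Missing keys take the package defaults.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  pick <- function(key, default) if (is.null(cfg[[key]])) default else cfg[[key]]
  pipeline_config(
    segmentation = segmentation_params(
      t0 = pick("t0", 80L),
      min_nucleus_area_px = pick("min_nucleus_area_px", 500L),
      connectivity = pick("connectivity", 8L)),
    grouping = grouping_params(s0 = pick("s0_px", 2500L),
                               d0 = pick("d0_px", 60)),
    artifact = artifact_params(ratio_min = pick("ratio_min", 0.26),
                               roi_margin_factor = pick("roi_margin_factor", 1.5)),
    method = pick("method", "bg"))
}

#' Run the full nucleus segmentation pipeline on one image
#'
#' Executes, in order: B-G differencing, fixed-threshold binarization,
#' connected-region labeling, platelet size filtering, region extraction,
#' lobe grouping, projection-profile localization, cytoplasm segmentation
#' and the artifact-ratio judgment (with `method = "sab"` the first four
#' stages are replaced by the Otsu-based baseline segmenter). Artifact
#' detections are flagged, never deleted: whether to drop them is the
#' consumer's choice (counting does). The pipeline is a pure function of
#' the image and the configuration.
#'
#' @param img an [rgb_image].
#' @param config a [pipeline_config] object.
#' @param debug_dir if non-NULL, every intermediate mask is written there as
#'   PNG (stages: `01_captured`, `02_b_minus_g`, `03_binarization`,
#'   `04_segmented_nuclei`, `05_labeled_regions`).
#' @return list with `detections` (data frame, see [empty_detections()];
#'   attribute `member_labels` lists the member region labels per row) and
#'   `intermediates` (`difference`, `binary`, `labeled`, `filtered` masks).
#' @export
run_pipeline <- function(img, config = pipeline_config(), debug_dir = NULL) {
  stopifnot(inherits(img, "rgb_image"), inherits(config, "pipeline_config"))
  seg <- config$segmentation
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  if (config$method == "bg") {
    diffm <- stage("bg_difference", bg_difference(img))
    binm <- stage("binarize", binarize(diffm, seg))
    lab <- stage("label_regions", label_regions(binm, seg$connectivity))
    filt <- stage("size_filter", size_filter(lab, seg$min_nucleus_area_px))
  } else {
    diffm <- stage("bg_difference", bg_difference(img))
    binm <- stage("segment_nucleus_sab", segment_nucleus_sab(img, seg))
    lab <- stage("label_regions", label_regions(binm, seg$connectivity))
    filt <- lab   # the SAB segmenter is already size-filtered
  }
  regions <- stage("extract_regions", extract_regions(filt))
  groups <- stage("group_lobes", group_lobes(regions, config$grouping))
  h <- nrow(filt); w <- ncol(filt)
  # exclude every first-stage foreground pixel (all nuclei AND platelets)
  # from the cytoplasm threshold histograms: nucleus-coloured material in a
  # ROI would otherwise pull the Otsu split above the cytoplasm mode
  all_nuclei <- as_binary_mask(binm)
  dets <- empty_detections()
  members <- list()
  for (g in groups) {
    gmask <- matrix(0L, h, w)
    gmask[filt %in% g] <- 1L
    bb <- stage("project_bbox", project_bbox(gmask))
    nucleus_area <- sum(regions$area_px[match(g, regions$label)])
    cs <- stage("segment_cytoplasm",
                segment_cytoplasm(img, gmask, params = config$artifact,
                                  exclude_mask = all_nuclei))
    aj <- stage("is_artifact",
                is_artifact(cs$cyto_area_px, nucleus_area, config$artifact))
    dets[nrow(dets) + 1L, ] <- list(
      bb[["x_l"]], bb[["x_r"]], bb[["y_t"]], bb[["y_b"]],
      bb[["x_c"]], bb[["y_c"]], bb[["w"]], bb[["h"]],
      as.integer(nucleus_area), length(g), aj$is_artifact, aj$ratio)
    members[[length(members) + 1L]] <- g
  }
  attr(dets, "member_labels") <- members
  if (!is.null(debug_dir)) {
    dir.create(debug_dir, showWarnings = FALSE, recursive = TRUE)
    write_image(img, file.path(debug_dir, "01_captured.png"))
    png::writePNG(diffm / 255, file.path(debug_dir, "02_b_minus_g.png"))
    write_mask(binm, file.path(debug_dir, "03_binarization.png"))
    segm <- matrix(0L, h, w); segm[filt > 0L] <- 1L
    write_mask(segm, file.path(debug_dir, "04_segmented_nuclei.png"))
    write_mask(filt, file.path(debug_dir, "05_labeled_regions.png"))
  }
  list(detections = dets,
       intermediates = list(difference = diffm, binary = binm,
                            labeled = lab, filtered = filt))
}

#' Run the pipeline over a batch of images
#'
#' Images are processed in lexicographic path order. Unreadable inputs are
#' skipped with a warning; it is an error if every input fails. The
#' aggregate simply sums non-artifact detections, so it is invariant to the
#' order the paths were supplied in.
#'
#' @param paths image paths.
#' @param config a [pipeline_config] object.
#' @param out_dir if non-NULL, per-image detection CSVs are written there.
#' @return list with `per_image` (named list of detection data frames),
#'   `n_per_image` (named integer vector of non-artifact detections) and
#'   `total_detections`.
#' @export
run_batch <- function(paths, config = pipeline_config(), out_dir = NULL) {
  if (length(paths) < 1L) stop("run_batch: need at least one input path")
  paths <- sort(paths, method = "radix")
  per_image <- list()
  failed <- character()
  for (p in paths) {
    res <- tryCatch(run_pipeline(read_image(p), config),
                    error = function(e) {
                      warning("skipping ", p, ": ", conditionMessage(e),
                              call. = FALSE)
                      NULL
                    })
    if (is.null(res)) { failed <- c(failed, p); next }
    per_image[[p]] <- res$detections
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_detections(res$detections,
                       file.path(out_dir, paste0(basename(p), ".detections.csv")))
    }
  }
  if (length(per_image) == 0L)
    stop("run_batch: all inputs failed (", length(failed), " file(s))")
  n_per <- vapply(per_image, function(d) sum(!d$is_artifact), integer(1))
  list(per_image = per_image, n_per_image = n_per,
       total_detections = sum(n_per), failed = failed)
}
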