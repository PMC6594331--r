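.WBC_CLASSES <- c("Neu", "Lym", "Mon", "Eos", "Bas")

#' Match detections against ground-truth leukocytes
#'
#' Greedy one-to-one matching under the center-in-truth-bbox criterion: a
#' detection matches a truth leukocyte iff its center `(x_c, y_c)` lies
#' inside the truth bounding box and that truth object is still unmatched.
#' Detections are processed in `(x_c, y_c)` lexicographic order, making the
#' result deterministic regardless of input order; artifact-flagged
#' detections are excluded. On scenes with disjoint truth boxes (the
#' generator guarantees disjoint nuclei) the greedy matching coincides with
#' the optimal bipartite matching.
#'
#' @param truth a `scene_truth` from [generate_scene()].
#' @param dets detection data frame.
#' @return list with `true_positives`, `false_positives`,
#'   `false_negatives`, `n_truth` and `matches` (data frame of
#'   `truth_index`, `det_index` pairs).
#' @export
match_detections <- function(truth, dets) {
  is_leuk <- vapply(truth$objects, function(o) o$class == "leukocyte", logical(1))
  leuk_idx <- which(is_leuk)
  boxes <- lapply(truth$objects[leuk_idx], `[[`, "bbox")
  dets <- dets[!dets$is_artifact, , drop = FALSE]
  ord <- order(dets$x_c, dets$y_c)
  matched_truth <- rep(FALSE, length(leuk_idx))
  pairs_t <- integer(); pairs_d <- integer()
  for (i in ord) {
    xc <- dets$x_c[i]; yc <- dets$y_c[i]
    for (j in seq_along(leuk_idx)) {
      if (matched_truth[j]) next
      b <- boxes[[j]]
      if (xc >= b[["x_l"]] && xc <= b[["x_r"]] &&
          yc >= b[["y_t"]] && yc <= b[["y_b"]]) {
        matched_truth[j] <- TRUE
        pairs_t <- c(pairs_t, leuk_idx[j])
        pairs_d <- c(pairs_d, i)
        break
      }
    }
  }
  tp <- length(pairs_t)
  list(true_positives = tp,
       false_positives = nrow(dets) - tp,
       false_negatives = length(leuk_idx) - tp,
       n_truth = length(leuk_idx),
       matches = data.frame(truth_index = pairs_t, det_index = pairs_d))
}

#' Detection-level segmentation accuracy, percent
#'
#' `100 * TP / n_truth`, reported to one decimal using round-half-up (the
#' convention that reproduces the published per-type accuracy tables from
#' their counts, e.g. 245 of 246 -> 99.6).
#'
#' @param match a match result from [match_detections()], or a TP count if
#'   `n_truth` is given.
#' @param n_truth number of ground-truth leukocytes (when `match` is a bare
#'   count).
#' @return accuracy in percent, one decimal.
#' @export
accuracy <- function(match, n_truth = NULL) {
  if (is.list(match)) {
    tp <- match$true_positives
    n_truth <- match$n_truth
  } else {
    tp <- match
  }
  if (is.null(n_truth) || n_truth < 1) stop("accuracy: n_truth must be >= 1")
  floor(1000 * tp / n_truth + 0.5) / 10
}

#' Differential count report
#'
#' Counts and percent proportions per leukocyte class over a vector of
#' per-detection class labels (labels come from ground truth on synthetic
#' data, or from an external classification; classifying is out of scope
#' here).
#'
#' @param labels character vector with values among
#'   `Neu, Lym, Mon, Eos, Bas`.
#' @return list with `counts`, `proportions` (percent, named by class) and
#'   `total`; an empty input gives all-zero counts and proportions.
#' @export
count_report <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), .WBC_CLASSES)
  if (length(bad))
    stop("count_report: unknown class label(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(labels, levels = .WBC_CLASSES))
  counts <- stats::setNames(as.integer(counts), .WBC_CLASSES)
  total <- sum(counts)
  props <- if (total == 0) stats::setNames(rep(0, 5L), .WBC_CLASSES)
           else 100 * counts / total
  list(counts = counts, proportions = props, total = total)
}
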