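# Independent brute-force oracles. These deliberately re-derive each
# quantity by the most naive route available (per-pixel loops, exhaustive
# search, closure by repeated passes) and share no code with the package.

# flood-fill connected-component labeling, raster-scan label order
oracle_flood_fill <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8L)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  nxt <- 0L
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (mask[r, c] == 0L || lab[r, c] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r, c))
    lab[r, c] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        rr <- p[1] + nb[k, 1]; cc <- p[2] + nb[k, 2]
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
            mask[rr, cc] != 0L && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  attr(lab, "n") <- nxt
  lab
}

# bounding box as plain coordinate min/max over foreground pixels
oracle_bbox <- function(mask) {
  pos <- which(mask != 0L, arr.ind = TRUE)
  x <- pos[, 2] - 1L; y <- pos[, 1] - 1L
  c(x_l = min(x), x_r = max(x), y_t = min(y), y_b = max(y),
    x_c = (min(x) + max(x)) %/% 2L, y_c = (min(y) + max(y)) %/% 2L,
    w = max(x) - min(x), h = max(y) - min(y))
}

# exhaustive Otsu: between-class variance of every split, via class means
oracle_otsu <- function(counts) {
  v <- 0:255
  best_t <- NA_integer_; best <- -Inf
  for (t in 0:255) {
    lo <- counts[v <= t]; hi <- counts[v > t]
    w0 <- sum(lo); w1 <- sum(hi)
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(v[v <= t] * lo) / w0
    mu1 <- sum(v[v > t] * hi) / w1
    s <- (w0 / (w0 + w1)) * (w1 / (w0 + w1)) * (mu0 - mu1)^2
    if (s > best + 1e-12) { best <- s; best_t <- t }
  }
  best_t
}

# transitive closure of the "small and within d0" relation by repeated
# sweeps until the group assignment stabilizes
oracle_groups <- function(regions, s0, d0) {
  n <- nrow(regions)
  grp <- seq_len(n)
  small <- regions$area_px <= s0
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || !small[i] || !small[j]) next
      d <- sqrt((regions$cx[i] - regions$cx[j])^2 +
                (regions$cy[i] - regions$cy[j])^2)
      if (d <= d0 && grp[i] != grp[j]) {
        g <- min(grp[i], grp[j])
        grp[grp == grp[i] | grp == grp[j]] <- g
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  parts <- split(regions$label, grp)
  parts <- lapply(unname(parts), function(x) sort(as.integer(x)))
  parts[order(vapply(parts, min, integer(1)))]
}

# rational-arithmetic saturation of one pixel
oracle_saturation <- function(r, g, b) {
  mx <- max(r, g, b); mn <- min(r, g, b)
  if (mx == 0) return(0L)
  as.integer(floor(255 * (mx - mn) / mx + 0.5))
}

# exhaustive one-to-one matching: maximum number of detection-truth pairs
# under the center-in-bbox criterion (truth boxes disjoint in our scenes,
# but the oracle does not assume it)
oracle_max_matching <- function(boxes, centers) {
  nt <- length(boxes); nd <- nrow(centers)
  if (nt == 0 || nd == 0) return(0L)
  compat <- matrix(FALSE, nd, nt)
  for (i in seq_len(nd)) for (j in seq_len(nt)) {
    b <- boxes[[j]]
    compat[i, j] <- centers[i, 1] >= b[["x_l"]] && centers[i, 1] <= b[["x_r"]] &&
      centers[i, 2] >= b[["y_t"]] && centers[i, 2] <= b[["y_b"]]
  }
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (nd - i + 1L) <= best) return()
    if (i > nd) { best <<- max(best, count); return() }
    for (j in which(compat[i, ] & !used)) {
      used[j] <- TRUE
      recurse(i + 1L, used, count + 1L)
      used[j] <- FALSE
    }
    recurse(i + 1L, used, count)
  }
  recurse(1L, rep(FALSE, nt), 0L)
  best
}

random_mask <- function(h, w, p = 0.35) {
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}

random_rgb <- function(h, w) {
  rgb_image(array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3L)))
}

random_detections <- function(n) {
  d <- empty_detections()
  for (i in seq_len(n)) {
    x_l <- sample(0:500, 1); x_r <- x_l + sample(0:80, 1)
    y_t <- sample(0:400, 1); y_b <- y_t + sample(0:80, 1)
    d[i, ] <- list(x_l, x_r, y_t, y_b,
                   (x_l + x_r) %/% 2L, (y_t + y_b) %/% 2L,
                   x_r - x_l, y_b - y_t,
                   sample(500:5000, 1), sample(1:5, 1),
                   sample(c(TRUE, FALSE), 1),
                   round(stats::runif(1, 0, 2), 6))
  }
  d
}

# a small, fast scene for unit tests (leukocytes need ~80 px of clearance)
tiny_scene <- function(seed = 1L, n_leukocytes = 2L, n_artifacts = 0L,
                       n_platelets = 4L, n_stains = 1L, n_erythrocytes = 5L,
                       lobe_count_range = c(1L, 2L), ...) {
  generate_scene(scene_params(
    width = 384L, height = 288L, n_leukocytes = n_leukocytes,
    lobe_count_range = lobe_count_range,
    n_platelets = n_platelets, n_stains = n_stains,
    n_erythrocytes = n_erythrocytes, n_artifacts = n_artifacts,
    seed = seed, ...))
}
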