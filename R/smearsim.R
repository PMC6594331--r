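#' Parameters of a synthetic stained-smear scene
#'
#' The generator emulates the color statistics of a Wright-Giemsa stained
#' peripheral blood smear as seen by an 8-bit RGB camera: purple leukocyte
#' nuclei whose B-G difference stays above 110 even after noise, platelets
#' of the same color but far smaller, dye stains with B-G below 50, pale
#' pink erythrocytes and background with near-zero B-G, pale-blue cytoplasm,
#' and nucleus-colored cytoplasm-free artifacts. Planted nuclei are pairwise
#' non-overlapping (the method's working assumption) and, with default
#' grouping parameters, lobes of one nucleus are chained within `d0` of each
#' other while nuclei of different cells stay further than `d0` apart.
#'
#' @param width,height scene size in pixels (nominal camera frame 1024x768).
#' @param n_leukocytes,n_platelets,n_stains,n_erythrocytes,n_artifacts
#'   object counts.
#' @param lobe_count_range integer range (inclusive) of lobes per nucleus.
#' @param clumping `"none"` (well-spread smear) or
#'   `"adjacent_nonoverlapping"` (leukocytes placed with touching cytoplasm
#'   but disjoint nuclei).
#' @param illumination_shift integer length-3 per-channel offset in -20..20
#'   added to every pixel. The B-G separability bands are guaranteed only
#'   when the G and B shifts are equal (equal shifts cancel in B-G);
#'   unequal G/B shifts are rejected.
#' @param noise_sigma per-channel Gaussian noise s.d.; the noise is
#'   truncated at +/- 2 sigma so the separability bands hold by
#'   construction, not just in probability.
#' @param seed RNG seed; a fixed seed gives a bit-identical scene.
#' @return a `scene_params` list.
#' @export
scene_params <- function(width = 1024L, height = 768L,
                         n_leukocytes = 3L, lobe_count_range = c(1L, 5L),
                         n_platelets = 15L, n_stains = 2L,
                         n_erythrocytes = 40L, n_artifacts = 1L,
                         clumping = c("none", "adjacent_nonoverlapping"),
                         illumination_shift = c(0L, 0L, 0L),
                         noise_sigma = 3, seed = 1L) {
  clumping <- match.arg(clumping)
  stopifnot(width >= 64, height >= 64,
            n_leukocytes >= 0, n_platelets >= 0, n_stains >= 0,
            n_erythrocytes >= 0, n_artifacts >= 0,
            length(lobe_count_range) == 2L,
            lobe_count_range[1] >= 1, lobe_count_range[2] <= 5,
            lobe_count_range[1] <= lobe_count_range[2],
            length(illumination_shift) == 3L,
            all(abs(illumination_shift) <= 20),
            noise_sigma >= 0, noise_sigma <= 5)
  if (illumination_shift[2] != illumination_shift[3])
    stop("scene_params: G and B illumination shifts must be equal ",
         "(unequal shifts would destroy the B-G separability bands)")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_leukocytes = as.integer(n_leukocytes),
                 lobe_count_range = as.integer(lobe_count_range),
                 n_platelets = as.integer(n_platelets),
                 n_stains = as.integer(n_stains),
                 n_erythrocytes = as.integer(n_erythrocytes),
                 n_artifacts = as.integer(n_artifacts),
                 clumping = clumping,
                 illumination_shift = as.integer(illumination_shift),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "scene_params")
}

# pre-noise palette; bands are strict subsets of the documented ranges so
# that +/- 2 sigma truncated noise cannot cross the 110 / 50 thresholds
.PAL <- list(
  background = c(215, 185, 178),
  ery_ring   = c(228, 190, 183),
  ery_center = c(235, 207, 200)
)

.nucleus_color <- function() {
  b <- sample(205:215, 1L)
  d <- sample(140:165, 1L)       # B-G in [140,165], noise keeps it > 110
  c(sample(75:110, 1L), b - d, b)
}

.cyto_color <- function() {
  b <- sample(195:205, 1L)
  c(b - sample(58:66, 1L), b - sample(30:37, 1L), b)
}

.stain_color <- function() {
  d <- sample(13:37, 1L)         # B-G in [13,37], noise keeps it < 50
  c(175, 160, 160 + d)
}

# linear pixel indices of a rotated filled ellipse, pixel centers at
# integer 0-based (x = col, y = row) coordinates
.ellipse_idx <- function(cx, cy, a, b, theta, h, w) {
  ext <- max(a, b)
  r0 <- max(1L, as.integer(floor(cy - ext)) + 1L)
  r1 <- min(h, as.integer(ceiling(cy + ext)) + 1L)
  c0 <- max(1L, as.integer(floor(cx - ext)) + 1L)
  c1 <- min(w, as.integer(ceiling(cx + ext)) + 1L)
  if (r0 > r1 || c0 > c1) return(integer())
  ys <- (r0:r1) - 1L
  xs <- (c0:c1) - 1L
  X <- outer(rep(1, length(ys)), xs) - cx
  Y <- outer(ys, rep(1, length(xs))) - cy
  ct <- cos(theta); st <- sin(theta)
  u <- (X * ct + Y * st) / a
  v <- (Y * ct - X * st) / b
  inside <- which(u * u + v * v <= 1)
  rr <- (inside - 1L) %% length(ys) + r0
  cc <- (inside - 1L) %/% length(ys) + c0
  (cc - 1L) * h + rr
}

# pixels within `halfwidth` of the segment p1-p2 (nuclear bridges)
.bridge_idx <- function(p1, p2, halfwidth, h, w) {
  r0 <- max(1L, as.integer(floor(min(p1[2], p2[2]) - halfwidth)) + 1L)
  r1 <- min(h, as.integer(ceiling(max(p1[2], p2[2]) + halfwidth)) + 1L)
  c0 <- max(1L, as.integer(floor(min(p1[1], p2[1]) - halfwidth)) + 1L)
  c1 <- min(w, as.integer(ceiling(max(p1[1], p2[1]) + halfwidth)) + 1L)
  if (r0 > r1 || c0 > c1) return(integer())
  ys <- (r0:r1) - 1L
  xs <- (c0:c1) - 1L
  X <- outer(rep(1, length(ys)), xs)
  Y <- outer(ys, rep(1, length(xs)))
  dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((X - p1[1]) * dx + (Y - p1[2]) * dy) / len2))
  d2 <- (X - (p1[1] + t * dx))^2 + (Y - (p1[2] + t * dy))^2
  inside <- which(d2 <= halfwidth^2)
  rr <- (inside - 1L) %% length(ys) + r0
  cc <- (inside - 1L) %/% length(ys) + c0
  (cc - 1L) * h + rr
}

# sample the geometry of one leukocyte, local coordinates (cell center 0,0)
.sample_leukocyte <- function(lobe_range, clump) {
  if (clump) {
    n_lobes <- 1L
    lob <- list(list(cx = 0, cy = 0, a = stats::runif(1, 23, 26),
                     b = stats::runif(1, 23, 26),
                     theta = stats::runif(1, 0, pi)))
    connected <- FALSE
  } else {
    n_lobes <- sample(lobe_range[1]:lobe_range[2], 1L)
    if (n_lobes == 1L) {
      lob <- list(list(cx = 0, cy = 0, a = stats::runif(1, 17, 26),
                       b = stats::runif(1, 17, 26),
                       theta = stats::runif(1, 0, pi)))
      connected <- FALSE
    } else {
      a <- stats::runif(n_lobes, 18, 22)
      b <- stats::runif(n_lobes, 15, 18)
      phi <- stats::runif(1, 0, 2 * pi)
      cx <- numeric(n_lobes); cy <- numeric(n_lobes)
      for (i in 2:n_lobes) {
        phi <- phi + stats::runif(1, -0.6, 0.6)
        step <- min(a[i - 1] + a[i] + stats::runif(1, 4, 12), 57)
        cx[i] <- cx[i - 1] + step * cos(phi)
        cy[i] <- cy[i - 1] + step * sin(phi)
      }
      cx <- cx - mean(cx); cy <- cy - mean(cy)
      lob <- lapply(seq_len(n_lobes), function(i)
        list(cx = cx[i], cy = cy[i], a = a[i], b = b[i],
             theta = stats::runif(1, 0, pi)))
      connected <- stats::runif(1) < 0.5
    }
  }
  ratio <- stats::runif(1, if (clump) 0.6 else 0.5, 0.9)
  list(lobes = lob, connected = connected, target_ratio = ratio,
       # nucleus radial extent and centroid spread, used for placement
       nu = max(vapply(lob, function(l)
         sqrt(l$cx^2 + l$cy^2), numeric(1))),
       ext0 = max(vapply(lob, function(l)
         sqrt(l$cx^2 + l$cy^2) + max(l$a, l$b), numeric(1))))
}

#' Generate a synthetic blood-smear scene with ground truth
#'
#' Deterministic for a fixed seed (bit-identical image and truth). See
#' [scene_params()] for what the scene emulates. Ground truth records, per
#' planted object, its class, the final per-lobe pixel sets, nucleus and
#' cytoplasm pixel areas, and the expected bounding box and center computed
#' by the same coordinate min/max rule the projection localizer implements.
#'
#' @param params a [scene_params] object.
#' @return list with `image` (an [rgb_image]) and `truth` (a `scene_truth`:
#'   `width`, `height`, and `objects`, each with `class`
#'   (`leukocyte`/`platelet`/`stain`/`erythrocyte`/`artifact`), `lobes`
#'   (list of linear pixel-index vectors), `nucleus_area_px`,
#'   `cytoplasm_area_px`, `bbox` `(x_l,x_r,y_t,y_b)` and `center`
#'   `(x_c,y_c)`).
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(params$seed)

  h <- params$height; w <- params$width
  # feasibility guard: crude upper bound on painted area
  max_area <- params$n_leukocytes * 4300 + params$n_platelets * 160 +
    params$n_stains * 1300 + params$n_erythrocytes * 2500 +
    params$n_artifacts * 2200
  if (max_area > 0.5 * h * w)
    stop("generate_scene: capacity error, objects cannot fit the scene")

  Rm <- matrix(.PAL$background[1], h, w)
  Gm <- matrix(.PAL$background[2], h, w)
  Bm <- matrix(.PAL$background[3], h, w)
  owner_obj <- matrix(0L, h, w)    # planted object index
  owner_part <- matrix(0L, h, w)   # 1 nucleus/body, 2 cytoplasm
  owner_lobe <- matrix(0L, h, w)   # lobe index within the object

  paint <- function(idx, col, obj, part, lobe) {
    if (length(idx) == 0L) return()
    Rm[idx] <<- col[1]; Gm[idx] <<- col[2]; Bm[idx] <<- col[3]
    owner_obj[idx] <<- obj; owner_part[idx] <<- part; owner_lobe[idx] <<- lobe
  }

  # placed objects as circle sets: a leukocyte is one circle per lobe
  # (center = lobe center, radius = its cytoplasm reach), everything else a
  # single bounding circle. Collision rules: circles of different objects
  # must not intersect; additionally, lobe centers of different
  # nucleus-like objects (leukocyte/artifact) must stay >= 63 px apart so
  # the d0 = 60 grouping rule can never merge across cells.
  placed <- list()   # each: list(cls, circ = matrix[x, y, r])
  place <- function(circ_local, cls, adjacent_to = NULL) {
    ext <- max(sqrt(circ_local[, 1]^2 + circ_local[, 2]^2) + circ_local[, 3])
    if (ext + 2 >= w - ext - 3 || ext + 2 >= h - ext - 3)
      stop("generate_scene: capacity error, a ", cls,
           " does not fit a ", w, "x", h, " scene")
    nucleus_like <- cls %in% c("leukocyte", "artifact")
    for (try in 1:600) {
      anchor <- NULL
      if (is.null(adjacent_to)) {
        cx <- stats::runif(1, ext + 2, w - ext - 3)
        cy <- stats::runif(1, ext + 2, h - ext - 3)
      } else {
        anchor <- adjacent_to[sample.int(length(adjacent_to), 1L)]
        o <- placed[[anchor]]$circ
        j <- sample.int(nrow(o), 1L)
        phi <- stats::runif(1, 0, 2 * pi)
        d <- max(o[j, 3] + max(circ_local[, 3]) - 1, 63)
        cx <- o[j, 1] + d * cos(phi); cy <- o[j, 2] + d * sin(phi)
        if (cx < ext + 2 || cx > w - ext - 3 ||
            cy < ext + 2 || cy > h - ext - 3) next
      }
      circ <- cbind(circ_local[, 1] + cx, circ_local[, 2] + cy,
                    circ_local[, 3])
      ok <- TRUE
      for (oi in seq_along(placed)) {
        o <- placed[[oi]]
        if (cls == "erythrocyte" && o$cls == "erythrocyte") next
        both_nuclear <- nucleus_like && o$cls %in% c("leukocyte", "artifact")
        slack <- if (!is.null(anchor) && oi == anchor) -1.5 else 1
        for (k in seq_len(nrow(circ))) {
          dd <- sqrt((o$circ[, 1] - circ[k, 1])^2 +
                     (o$circ[, 2] - circ[k, 2])^2)
          lim <- o$circ[, 3] + circ[k, 3] + slack
          if (both_nuclear) lim <- pmax(lim, 63)
          if (any(dd < lim)) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) {
        placed[[length(placed) + 1L]] <<- list(cls = cls, circ = circ)
        return(c(cx, cy))
      }
    }
    stop("generate_scene: capacity error, could not place a ", cls)
  }

  objects <- list()
  obj_id <- 0L
  clump <- params$clumping == "adjacent_nonoverlapping"

  # --- leukocytes ------------------------------------------------------
  leuk_rows <- integer()
  for (i in seq_len(params$n_leukocytes)) {
    geo <- .sample_leukocyte(params$lobe_count_range, clump)
    k <- sqrt(1 + geo$target_ratio)
    obj_id <- obj_id + 1L
    for (attempt in 1:6) {
      circ <- do.call(rbind, lapply(geo$lobes, function(l)
        c(l$cx, l$cy, max(l$a, l$b) * k + 2)))
      if (length(geo$lobes) > 1L) {
        # thin bridges run between consecutive lobes; cover their midpoints
        for (j in 2:length(geo$lobes))
          circ <- rbind(circ, c((geo$lobes[[j - 1]]$cx + geo$lobes[[j]]$cx) / 2,
                                (geo$lobes[[j - 1]]$cy + geo$lobes[[j]]$cy) / 2,
                                8))
      }
      ctr <- if (clump && length(leuk_rows))
        place(circ, "leukocyte", adjacent_to = leuk_rows)
      else place(circ, "leukocyte")
      leuk_rows <- c(leuk_rows, length(placed))
      # cytoplasm: scaled lobes (plus widened bridges when connected)
      cyto_idx <- unlist(lapply(geo$lobes, function(l)
        .ellipse_idx(ctr[1] + l$cx, ctr[2] + l$cy, l$a * k, l$b * k,
                     l$theta, h, w)))
      nuc_idx_lobes <- lapply(geo$lobes, function(l)
        .ellipse_idx(ctr[1] + l$cx, ctr[2] + l$cy, l$a, l$b, l$theta, h, w))
      if (geo$connected && length(geo$lobes) > 1L) {
        for (j in 2:length(geo$lobes)) {
          p1 <- c(ctr[1] + geo$lobes[[j - 1]]$cx, ctr[2] + geo$lobes[[j - 1]]$cy)
          p2 <- c(ctr[1] + geo$lobes[[j]]$cx, ctr[2] + geo$lobes[[j]]$cy)
          cyto_idx <- c(cyto_idx, .bridge_idx(p1, p2, 1.6 * k + 1, h, w))
          # bridges are nuclear material; attach them to the earlier lobe
          nuc_idx_lobes[[j - 1L]] <-
            c(nuc_idx_lobes[[j - 1L]], .bridge_idx(p1, p2, 1.6, h, w))
        }
      }
      nuc_all <- unique(unlist(nuc_idx_lobes))
      cyto_only <- setdiff(unique(cyto_idx), nuc_all)
      ratio <- length(cyto_only) / length(nuc_all)
      if (ratio >= 0.42 || attempt == 6) break
      k <- k * 1.07
      placed <- placed[-length(placed)]   # retry with a fatter rim
      leuk_rows <- leuk_rows[-length(leuk_rows)]
    }
    ccol <- .cyto_color()
    ncol <- .nucleus_color()
    paint(cyto_only, ccol, obj_id, 2L, 0L)
    seen <- integer()
    for (j in seq_along(nuc_idx_lobes)) {
      lob_px <- setdiff(unique(nuc_idx_lobes[[j]]), seen)
      paint(lob_px, ncol, obj_id, 1L, j)
      seen <- c(seen, lob_px)
    }
    objects[[obj_id]] <- list(class = "leukocyte", n_lobes = length(nuc_idx_lobes))
  }

  # --- artifacts (nucleus palette, no cytoplasm) -----------------------
  for (i in seq_len(params$n_artifacts)) {
    a <- stats::runif(1, 17, 26); b <- stats::runif(1, 17, 26)
    obj_id <- obj_id + 1L
    ctr <- place(matrix(c(0, 0, max(a, b) + 2), 1), "artifact")
    idx <- .ellipse_idx(ctr[1], ctr[2], a, b, stats::runif(1, 0, pi), h, w)
    paint(idx, .nucleus_color(), obj_id, 1L, 1L)
    objects[[obj_id]] <- list(class = "artifact", n_lobes = 1L)
  }

  # --- stains ----------------------------------------------------------
  for (i in seq_len(params$n_stains)) {
    a <- stats::runif(1, 8, 20); b <- stats::runif(1, 8, 20)
    obj_id <- obj_id + 1L
    ctr <- place(matrix(c(0, 0, max(a, b) + 1), 1), "stain")
    idx <- .ellipse_idx(ctr[1], ctr[2], a, b, stats::runif(1, 0, pi), h, w)
    paint(idx, .stain_color(), obj_id, 1L, 1L)
    objects[[obj_id]] <- list(class = "stain", n_lobes = 1L)
  }

  # --- erythrocytes (pale rings, may overlap each other) ---------------
  for (i in seq_len(params$n_erythrocytes)) {
    r <- stats::runif(1, 20, 28)
    obj_id <- obj_id + 1L
    ctr <- place(matrix(c(0, 0, r + 1), 1), "erythrocyte")
    disk <- .ellipse_idx(ctr[1], ctr[2], r, r, 0, h, w)
    inner <- .ellipse_idx(ctr[1], ctr[2], 0.55 * r, 0.55 * r, 0, h, w)
    paint(setdiff(disk, inner), .PAL$ery_ring, obj_id, 1L, 1L)
    paint(inner, .PAL$ery_center, obj_id, 1L, 1L)
    objects[[obj_id]] <- list(class = "erythrocyte", n_lobes = 1L)
  }

  # --- platelets (nucleus palette, tiny) -------------------------------
  for (i in seq_len(params$n_platelets)) {
    r <- stats::runif(1, 3.5, 7)
    obj_id <- obj_id + 1L
    ctr <- place(matrix(c(0, 0, r + 1), 1), "platelet")
    idx <- .ellipse_idx(ctr[1], ctr[2], r, r, 0, h, w)
    paint(idx, .nucleus_color(), obj_id, 1L, 1L)
    objects[[obj_id]] <- list(class = "platelet", n_lobes = 1L)
  }

  # --- illumination shift + truncated noise, clip, quantize ------------
  sh <- params$illumination_shift
  sig <- params$noise_sigma
  addnoise <- function(m, s) {
    n <- stats::rnorm(length(m), 0, sig)
    n <- pmin(pmax(n, -2 * sig), 2 * sig)
    matrix(as.integer(pmin(pmax(round(m + s + n), 0), 255)), nrow(m))
  }
  img <- rgb_image(array(c(addnoise(Rm, sh[1]), addnoise(Gm, sh[2]),
                           addnoise(Bm, sh[3])), dim = c(h, w, 3L)))

  # --- truth from final pixel ownership --------------------------------
  truth_objects <- vector("list", obj_id)
  for (id in seq_len(obj_id)) {
    px <- which(owner_obj == id)
    meta <- objects[[id]]
    nuc_px <- px[owner_part[px] == 1L]
    cyto_n <- sum(owner_part[px] == 2L)
    lobes <- split(nuc_px, owner_lobe[nuc_px])
    lobes <- lapply(unname(lobes), as.integer)
    ref <- if (length(nuc_px)) nuc_px else px
    if (length(ref)) {
      y <- (ref - 1L) %% h
      x <- (ref - 1L) %/% h
      bbox <- c(x_l = min(x), x_r = max(x), y_t = min(y), y_b = max(y))
      center <- c(x_c = (bbox[["x_l"]] + bbox[["x_r"]]) %/% 2L,
                  y_c = (bbox[["y_t"]] + bbox[["y_b"]]) %/% 2L)
    } else {
      # an erythrocyte can be fully overpainted by later erythrocytes
      bbox <- c(x_l = NA_integer_, x_r = NA_integer_,
                y_t = NA_integer_, y_b = NA_integer_)
      center <- c(x_c = NA_integer_, y_c = NA_integer_)
    }
    truth_objects[[id]] <- list(
      class = meta$class,
      lobes = lobes,
      nucleus_area_px = length(nuc_px),
      cytoplasm_area_px = as.integer(cyto_n),
      bbox = bbox,
      center = center)
  }
  truth <- structure(list(width = w, height = h, objects = truth_objects),
                     class = "scene_truth")
  list(image = img, truth = truth)
}

#' Check the separability bands of a generated scene
#'
#' Direct pixel inspection of the (noisy) rendered image against its truth:
#' every nucleus and platelet pixel must have B-G strictly above 110 and
#' every stain pixel strictly below 50; erythrocyte and untouched background
#' pixels must sit at or below 10.
#'
#' @param image an [rgb_image] from [generate_scene()].
#' @param truth the matching `scene_truth`.
#' @return TRUE invisibly; stops with a message on any violation.
#' @export
validate_palette <- function(image, truth) {
  d <- bg_difference(image)
  covered <- logical(length(d))
  for (ob in truth$objects) {
    px <- unlist(ob$lobes)
    covered[px] <- TRUE
    if (ob$class %in% c("leukocyte", "platelet", "artifact")) {
      if (length(px) && min(d[px]) <= 110)
        stop("palette violation: ", ob$class, " pixel with B-G <= 110")
    } else if (ob$class == "stain") {
      if (length(px) && max(d[px]) >= 50)
        stop("palette violation: stain pixel with B-G >= 50")
    } else {
      if (length(px) && max(d[px]) > 10)
        stop("palette violation: erythrocyte pixel with B-G > 10")
    }
  }
  invisible(TRUE)
}

#' Write a gallery of synthetic scenes with truth files
#'
#' Writes `n` scenes spanning the lobe-count range, both clumping modes and
#' the illumination-shift range: for scene `i`, `scene_<i>.png` (the image),
#' `scene_<i>_lobes.png` (16-bit labeled mask whose labels are the lobe ids
#' referenced by the truth), and `scene_<i>_truth.json`. A `manifest.json`
#' lists the files and the parameters used.
#'
#' @param out_dir output directory (created if needed).
#' @param n number of scenes.
#' @param seed base seed; scene `i` uses `seed + i - 1`.
#' @param width,height scene size passed through to [scene_params()].
#' @return path of the manifest file, invisibly.
#' @export
scene_gallery <- function(out_dir, n, seed = 1L, width = 1024L, height = 768L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (i in seq_len(n)) {
    p <- scene_params(
      width = width, height = height,
      n_leukocytes = 2L + (i %% 4L),
      lobe_count_range = c(1L, 1L + (i - 1L) %% 5L),
      n_platelets = 8L, n_stains = 2L, n_erythrocytes = 12L,
      n_artifacts = i %% 2L,
      clumping = if (i %% 2L == 0L) "adjacent_nonoverlapping" else "none",
      illumination_shift = rep(c(-15L, 0L, 15L)[1L + (i %% 3L)], 3L),
      seed = seed + i - 1L)
    sc <- generate_scene(p)
    img_file <- file.path(out_dir, sprintf("scene_%03d.png", i))
    lob_file <- file.path(out_dir, sprintf("scene_%03d_lobes.png", i))
    truth_file <- file.path(out_dir, sprintf("scene_%03d_truth.json", i))
    write_image(sc$image, img_file)
    lab <- matrix(0L, p$height, p$width)
    lid <- 0L
    tr_json <- lapply(sc$truth$objects, function(ob) {
      ids <- integer(length(ob$lobes))
      for (j in seq_along(ob$lobes)) {
        lid <<- lid + 1L
        lab[ob$lobes[[j]]] <<- lid
        ids[j] <- lid
      }
      list(class = ob$class, lobe_labels = ids,
           nucleus_area_px = ob$nucleus_area_px,
           cytoplasm_area_px = ob$cytoplasm_area_px,
           bbox = unname(ob$bbox), center = unname(ob$center))
    })
    write_mask(as_labeled_mask(lab), lob_file)
    jsonlite::write_json(tr_json, truth_file, auto_unbox = TRUE, digits = NA)
    entries[[i]] <- list(image = basename(img_file),
                         lobe_mask = basename(lob_file),
                         truth = basename(truth_file),
                         params = unclass(p))
  }
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(n = n, seed = seed, scenes = entries),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
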