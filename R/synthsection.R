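# Synthetic stem cross-section generator: a bright-field stem disk with a
# central cavity, an inner ring of large vascular bundles and an outer ring
# of small ones, degraded by blur, uneven illumination, texture noise and
# contrast compression.  Boxes are emitted from the rendered geometry before
# degradation, so annotations are exact by construction.

#' Scene configuration for the synthetic generator
#'
#' Defaults reproduce the statistical structure of a stem-section dataset
#' with on average 28.28 small and 30.88 large bundles per image, one cavity
#' ("in") and one stem perimeter ("out") region, small bundle radii of 3-8
#' px at a 640-px image (radii scale with image size), dense ring
#' arrangement, soft edges and low contrast.
#'
#' @param image_size Square image side in pixels (default 640).
#' @param stem_radius_frac Range of the stem disk radius as a fraction of
#'   the image side.
#' @param cavity_frac Range of the cavity radius as a fraction of the stem
#'   radius.
#' @param n_small_mean,n_big_mean Mean per-image counts of small and large
#'   bundles.
#' @param count_dist \code{"poisson"} (default) or \code{"fixed"}
#'   (deterministic rounded mean).
#' @param small_radius_frac,big_radius_frac Bundle radius ranges as
#'   fractions of the image side; small radii must stay below big radii.
#' @param small_band,big_band Radial placement bands (fractions of the stem
#'   radius) for the two bundle classes.
#' @param contrast_level Contrast retained after compression toward
#'   mid-gray, in \code{(0, 1]} (low values = low contrast).
#' @param blur_sigma Gaussian blur standard deviation in pixels (0 = none).
#' @param illumination_gradient Amplitude of the multiplicative linear
#'   illumination ramp.
#' @param background_texture Standard deviation of additive Gaussian
#'   texture noise.
#' @param max_overlap Maximum allowed fractional center-distance overlap
#'   between bundles during placement.
#' @param seed Integer seed; the whole scene is a deterministic function of
#'   the configuration.
#' @return A \code{scene_config}.
#' @export
scene_config <- function(image_size = 640L,
                         stem_radius_frac = c(0.40, 0.46),
                         cavity_frac = c(0.28, 0.36),
                         n_small_mean = 28.28,
                         n_big_mean = 30.88,
                         count_dist = c("poisson", "fixed"),
                         small_radius_frac = c(3, 8) / 640,
                         big_radius_frac = c(9, 16) / 640,
                         small_band = c(0.78, 0.95),
                         big_band = c(0.42, 0.72),
                         contrast_level = 0.4,
                         blur_sigma = 1.5,
                         illumination_gradient = 0.25,
                         background_texture = 0.04,
                         max_overlap = 0.1,
                         seed = 0L) {
  count_dist <- match.arg(count_dist)
  if (max(small_radius_frac) >= min(big_radius_frac) && n_big_mean > 0)
    stop("small bundle radii must stay below big bundle radii")
  if (contrast_level <= 0 || contrast_level > 1)
    stop("contrast_level must lie in (0, 1]")
  if (blur_sigma < 0) stop("blur_sigma must be >= 0")
  structure(list(image_size = as.integer(image_size),
                 stem_radius_frac = stem_radius_frac,
                 cavity_frac = cavity_frac,
                 n_small_mean = n_small_mean, n_big_mean = n_big_mean,
                 count_dist = count_dist,
                 small_radius_frac = small_radius_frac,
                 big_radius_frac = big_radius_frac,
                 small_band = small_band, big_band = big_band,
                 contrast_level = contrast_level, blur_sigma = blur_sigma,
                 illumination_gradient = illumination_gradient,
                 background_texture = background_texture,
                 max_overlap = max_overlap, seed = as.integer(seed)),
            class = "scene_config")
}

#' Preset scene configurations
#'
#' \code{"paper-like"} keeps the dense, low-contrast, blurred defaults;
#' \code{"easy"} uses high contrast, no blur and a handful of larger small
#' bundles (no big bundles) for CPU smoke training.
#'
#' @param difficulty \code{"easy"} or \code{"paper-like"}.
#' @param image_size Image side in pixels.
#' @param seed Integer seed.
#' @param ... Overrides passed to \code{\link{scene_config}}.
#' @export
scene_preset <- function(difficulty = c("paper-like", "easy"),
                         image_size = 640L, seed = 0L, ...) {
  difficulty <- match.arg(difficulty)
  if (difficulty == "paper-like") {
    scene_config(image_size = image_size, seed = seed, ...)
  } else {
    scene_config(image_size = image_size, seed = seed,
                 n_small_mean = 5, n_big_mean = 0,
                 small_radius_frac = c(0.035, 0.055),
                 small_band = c(0.30, 0.88),
                 contrast_level = 0.9, blur_sigma = 0,
                 illumination_gradient = 0.05, background_texture = 0.01,
                 ...)
  }
}

sample_count <- function(mean, dist) {
  if (dist == "fixed") as.integer(round(mean)) else stats::rpois(1, mean)
}

# Place n ellipses in an annulus band; returns data.frame(cx, cy, a, b) or
# errors naming the violated packing constraint.
place_bundles <- function(n, center, band_r, radius_range, placed,
                          max_overlap, image_size, max_attempts = 400L) {
  out <- data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0),
                    b = numeric(0))
  for (i in seq_len(n)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      rr <- stats::runif(1, band_r[1], band_r[2])
      th <- stats::runif(1, 0, 2 * pi)
      cx <- center[1] + rr * cos(th)
      cy <- center[2] + rr * sin(th)
      a <- stats::runif(1, radius_range[1], radius_range[2])
      b <- stats::runif(1, radius_range[1], radius_range[2])
      r <- max(a, b)
      if (cx - a < 1 || cy - b < 1 || cx + a > image_size - 1 ||
          cy + b > image_size - 1) next
      clear <- TRUE
      all_placed <- rbind(placed, out)
      if (nrow(all_placed)) {
        d <- sqrt((all_placed$cx - cx)^2 + (all_placed$cy - cy)^2)
        lim <- (pmax(all_placed$a, all_placed$b) + r) * (1 - max_overlap)
        clear <- all(d > lim)
      }
      if (clear) { out <- rbind(out, data.frame(cx = cx, cy = cy, a = a, b = b)); ok <- TRUE; break }
    }
    if (!ok)
      stop(sprintf(paste0("infeasible packing: could not place bundle %d of %d ",
                          "in band [%.1f, %.1f] px without exceeding ",
                          "max_overlap = %.2f"), i, n, band_r[1], band_r[2],
                   max_overlap))
  }
  out
}

gauss_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  x <- array(mat, dim = c(1L, nrow(mat), ncol(mat)))
  ky <- array(k, dim = c(1L, 1L, 2L * r + 1L, 1L))
  kx <- array(k, dim = c(1L, 1L, 1L, 2L * r + 1L))
  x <- cpp_conv2d(x, ky, 0, 1L, r, 0L)
  x <- cpp_conv2d(x, kx, 0, 1L, 0L, r)
  matrix(x, nrow(mat), ncol(mat))
}

draw_ellipse <- function(img, cx, cy, a, b, value) {
  n <- nrow(img)
  xs <- max(1L, floor(cx - a)):min(n, ceiling(cx + a))
  ys <- max(1L, floor(cy - b)):min(n, ceiling(cy + b))
  px <- xs - 0.5; py <- ys - 0.5
  mask <- outer(((py - cy) / b)^2, ((px - cx) / a)^2, `+`) <= 1
  sub <- img[ys, xs, drop = FALSE]
  sub[mask] <- value
  img[ys, xs] <- sub
  img
}

#' Generate one synthetic stem cross-section scene
#'
#' Renders (in fixed order) the background, stem disk, cavity, large-bundle
#' inner ring and small-bundle outer ring, then degrades the image with
#' Gaussian blur, a multiplicative illumination ramp, additive texture
#' noise, and contrast compression — degradations never move geometry, so
#' every emitted box tightly bounds its rendered ellipse.  The whole scene
#' is a deterministic function of the configuration (including the seed).
#'
#' @param cfg A \code{\link{scene_config}}.
#' @return A \code{ground_truth_scene}: list with \code{image}
#'   (\code{H x W x 3}), \code{boxes} (small/big bundles plus exactly one
#'   \code{"in"} and one \code{"out"} box), and \code{log} (placed centers,
#'   radii, seed).
#' @export
generate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  n <- cfg$image_size
  center <- n / 2 + stats::runif(2, -0.02 * n, 0.02 * n)
  stem_r <- stats::runif(1, cfg$stem_radius_frac[1], cfg$stem_radius_frac[2]) * n
  cav_r <- stats::runif(1, cfg$cavity_frac[1], cfg$cavity_frac[2]) * stem_r
  n_small <- sample_count(cfg$n_small_mean, cfg$count_dist)
  n_big <- sample_count(cfg$n_big_mean, cfg$count_dist)
  big <- place_bundles(n_big, center, cfg$big_band * stem_r,
                       cfg$big_radius_frac * n, NULL, cfg$max_overlap, n)
  small <- place_bundles(n_small, center, cfg$small_band * stem_r,
                         cfg$small_radius_frac * n, big, cfg$max_overlap, n)
  # render (values before contrast compression)
  img <- matrix(0.85, n, n)
  img <- draw_ellipse(img, center[1], center[2], stem_r, stem_r, 0.62)
  img <- draw_ellipse(img, center[1], center[2], cav_r, cav_r, 0.88)
  for (i in seq_len(nrow(big)))
    img <- draw_ellipse(img, big$cx[i], big$cy[i], big$a[i], big$b[i], 0.30)
  for (i in seq_len(nrow(small)))
    img <- draw_ellipse(img, small$cx[i], small$cy[i], small$a[i], small$b[i],
                        0.28)
  # degrade: blur -> illumination -> noise -> contrast
  img <- gauss_blur(img, cfg$blur_sigma)
  if (cfg$illumination_gradient > 0) {
    th <- stats::runif(1, 0, 2 * pi)
    gx <- (seq_len(n) - 0.5) / n - 0.5
    ramp <- 1 + cfg$illumination_gradient *
      (outer(gx * sin(th), gx * cos(th), `+`) * 2)
    img <- img * ramp
  }
  if (cfg$background_texture > 0)
    img <- img + matrix(stats::rnorm(n * n, sd = cfg$background_texture), n, n)
  img <- 0.5 + (img - 0.5) * cfg$contrast_level
  img <- pmin(pmax(img, 0), 1)
  boxes <- list()
  for (i in seq_len(nrow(small)))
    boxes[[length(boxes) + 1]] <- bbox(small$cx[i] - small$a[i],
                                       small$cy[i] - small$b[i],
                                       small$cx[i] + small$a[i],
                                       small$cy[i] + small$b[i], "small")
  for (i in seq_len(nrow(big)))
    boxes[[length(boxes) + 1]] <- bbox(big$cx[i] - big$a[i],
                                       big$cy[i] - big$b[i],
                                       big$cx[i] + big$a[i],
                                       big$cy[i] + big$b[i], "big")
  boxes[[length(boxes) + 1]] <- bbox(center[1] - cav_r, center[2] - cav_r,
                                     center[1] + cav_r, center[2] + cav_r,
                                     "in")
  boxes[[length(boxes) + 1]] <- bbox(center[1] - stem_r, center[2] - stem_r,
                                     center[1] + stem_r, center[2] + stem_r,
                                     "out")
  arr <- array(rep(img, 3), dim = c(n, n, 3))
  structure(list(image = arr, boxes = boxes,
                 log = list(center = center, stem_r = stem_r, cavity_r = cav_r,
                            small = small, big = big, seed = cfg$seed)),
            class = "ground_truth_scene")
}

#' Write a synthetic dataset to disk
#'
#' Produces \code{images/scene_XXXX.tif}, matching LabelMe JSON files (next
#' to the images), YOLO label files under \code{labels/}, and a manifest
#' YAML recording the class map, the 8:1:1 split, the preset and the seed.
#'
#' @param n_scenes Number of scenes.
#' @param cfg Base \code{\link{scene_config}}; scene i uses seed
#'   \code{cfg$seed + i}.
#' @param out_dir Output directory (created if needed).
#' @param difficulty Recorded in the manifest (\code{"easy"} or
#'   \code{"paper-like"}); purely informational — the geometry comes from
#'   \code{cfg}.
#' @return The manifest path (invisibly readable with
#'   \code{\link{read_manifest}}).
#' @export
write_dataset <- function(n_scenes, cfg, out_dir,
                          difficulty = c("paper-like", "easy")) {
  difficulty <- match.arg(difficulty)
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "labels"), showWarnings = FALSE)
  ids <- sprintf("scene_%04d", seq_len(n_scenes))
  for (i in seq_len(n_scenes)) {
    ci <- cfg; ci$seed <- cfg$seed + i
    sc <- generate_scene(ci)
    img_path <- file.path(out_dir, "images", paste0(ids[i], ".tif"))
    write_image(sc$image, img_path)
    ls <- labeled_scene(image = sc$image, image_path = img_path,
                        boxes = sc$boxes)
    write_labelme(ls, file.path(out_dir, "images", paste0(ids[i], ".json")))
    write_yolo_labels(ls, file.path(out_dir, "labels", paste0(ids[i], ".txt")))
  }
  split <- split_dataset(ids, seed = cfg$seed)
  manifest <- list(classes = VB_CLASSES, image_size = cfg$image_size,
                   difficulty = difficulty, seed = cfg$seed,
                   n_scenes = n_scenes, split = split)
  mp <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, mp)
  mp
}

#' Read a dataset manifest
#' @param path Path to \code{manifest.yaml} (or its directory).
#' @return The manifest list with an added \code{dir} element.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.yaml")
  m <- yaml::read_yaml(path)
  m$dir <- dirname(normalizePath(path))
  m
}

#' Load a scene written by \code{\link{write_dataset}}
#' @param manifest Manifest from \code{\link{read_manifest}}.
#' @param id Scene identifier (e.g. \code{"scene_0001"}).
#' @return A \code{\link{labeled_scene}}.
#' @export
load_scene <- function(manifest, id) {
  read_labelme(file.path(manifest$dir, "images", paste0(id, ".json")))
}
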