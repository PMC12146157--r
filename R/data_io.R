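# Readers/writers for LabelMe JSON annotations, YOLO-format label files,
# TIFF/PNG images, and deterministic dataset splitting.

VB_CLASSES <- c("small", "big", "in", "out")

#' Labeled scene container
#'
#' One image together with its annotation set.
#'
#' @param image Numeric array \code{H x W x 3} in \code{[0, 1]}, or
#'   \code{NULL} when lazily loaded.
#' @param image_path Path to the image file (may be empty).
#' @param boxes List of \code{\link{bbox}}.
#' @param image_size \code{c(H, W)}; inferred from \code{image} when absent.
#' @param source_polygons Optional raw vertex lists, one per box, retained
#'   for provenance.
#' @return A \code{labeled_scene}.
#' @export
labeled_scene <- function(image = NULL, image_path = "", boxes = list(),
                          image_size = NULL, source_polygons = NULL) {
  if (is.null(image_size)) {
    if (is.null(image)) stop("image_size is required when image is NULL")
  } else image_size <- as.integer(image_size)
  if (!is.null(image)) image_size <- as.integer(dim(image)[1:2])
  structure(list(image = image, image_path = image_path, boxes = boxes,
                 image_size = image_size, source_polygons = source_polygons),
            class = "labeled_scene")
}

#' @export
print.labeled_scene <- function(x, ...) {
  cls <- table(vapply(x$boxes, function(b) b$class_id, character(1)))
  cat(sprintf("<labeled_scene %dx%d, %d boxes (%s)>\n", x$image_size[1],
              x$image_size[2], length(x$boxes),
              paste(names(cls), cls, sep = ":", collapse = ", ")))
  invisible(x)
}

#' Read a LabelMe annotation file
#'
#' Rectangle shapes are taken directly; polygon shapes are reduced to their
#' axis-aligned bounding boxes (the raw vertices are retained in
#' \code{source_polygons}).  Labels are lower-cased; labels outside the
#' stem-section vocabulary are rejected unless listed in \code{allow}.
#' The image referenced by \code{imagePath} is loaded when found next to
#' the JSON file, otherwise a warning is emitted and loading is deferred.
#'
#' @param json_path Path to a LabelMe-dialect JSON file.
#' @param allow Optional character vector of extra permitted labels.
#' @return A \code{\link{labeled_scene}}.
#' @export
read_labelme <- function(json_path, allow = NULL) {
  doc <- tryCatch(jsonlite::fromJSON(json_path, simplifyVector = FALSE),
                  error = function(e)
                    stop(sprintf("failed to parse LabelMe JSON '%s': %s",
                                 json_path, conditionMessage(e))))
  ok_labels <- c(VB_CLASSES, allow)
  boxes <- list(); polys <- list()
  for (sh in doc$shapes) {
    lab <- tolower(sh$label)
    if (!(lab %in% ok_labels))
      stop(sprintf("unknown label '%s' in %s (set allow= to accept it)",
                   sh$label, json_path))
    pts <- do.call(rbind, lapply(sh$points, unlist))
    x1 <- min(pts[, 1]); x2 <- max(pts[, 1])
    y1 <- min(pts[, 2]); y2 <- max(pts[, 2])
    boxes[[length(boxes) + 1]] <- bbox(x1, y1, x2, y2, class_id = lab)
    polys[[length(polys) + 1]] <- pts
  }
  h <- doc$imageHeight; w <- doc$imageWidth
  img <- NULL
  img_path <- if (!is.null(doc$imagePath)) doc$imagePath else ""
  if (nzchar(img_path)) {
    full <- file.path(dirname(json_path), img_path)
    if (file.exists(full)) {
      img <- read_image(full)
      img_path <- full
    } else {
      warning(sprintf("image file '%s' not found; loading deferred", full))
    }
  }
  labeled_scene(image = img, image_path = img_path, boxes = boxes,
                image_size = c(h, w), source_polygons = polys)
}

#' Write predictions or annotations as LabelMe JSON
#'
#' @param scene A \code{\link{labeled_scene}}.
#' @param json_path Output path.
#' @param image_path Value for the \code{imagePath} field (default: the
#'   scene's, basename only).
#' @export
write_labelme <- function(scene, json_path, image_path = NULL) {
  if (is.null(image_path))
    image_path <- if (nzchar(scene$image_path)) basename(scene$image_path) else ""
  shapes <- lapply(scene$boxes, function(b) {
    sh <- list(label = b$class_id,
               points = list(list(b$x1, b$y1), list(b$x2, b$y2)),
               group_id = NULL, shape_type = "rectangle", flags = c())
    if (!is.na(b$confidence)) sh$description <- sprintf("%.6f", b$confidence)
    sh
  })
  doc <- list(version = "5.2.1", flags = c(), shapes = shapes,
              imagePath = image_path, imageData = NULL,
              imageHeight = scene$image_size[1],
              imageWidth = scene$image_size[2])
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(json_path)
}

#' Write YOLO-format labels for a scene
#'
#' One line per box: \code{class_index x_center y_center width height}, all
#' normalized to \code{[0, 1]} with 6-decimal fixed formatting.  The class
#' order is small=0, big=1, in=2, out=3.  Boxes exceeding the image bounds
#' are clipped with a warning.
#'
#' @param scene A \code{\link{labeled_scene}} with known image size.
#' @param out_path Output text file.
#' @param classes Class ordering (index = position - 1).
#' @export
write_yolo_labels <- function(scene, out_path, classes = VB_CLASSES) {
  H <- scene$image_size[1]; W <- scene$image_size[2]
  lines <- character(0)
  for (b in scene$boxes) {
    x1 <- b$x1; y1 <- b$y1; x2 <- b$x2; y2 <- b$y2
    if (x1 < 0 || y1 < 0 || x2 > W || y2 > H) {
      warning("box exceeds image bounds; clipped")
      x1 <- max(0, x1); y1 <- max(0, y1); x2 <- min(W, x2); y2 <- min(H, y2)
    }
    ci <- match(b$class_id, classes) - 1L
    if (is.na(ci)) stop(sprintf("class '%s' not in class map", b$class_id))
    lines <- c(lines, sprintf("%d %.6f %.6f %.6f %.6f", ci,
                              (x1 + x2) / 2 / W, (y1 + y2) / 2 / H,
                              (x2 - x1) / W, (y2 - y1) / H))
  }
  writeLines(lines, out_path)
  invisible(out_path)
}

#' Read YOLO-format labels
#'
#' @param path Label text file.
#' @param image_size \code{c(H, W)} used to denormalize.
#' @param classes Class ordering matching \code{\link{write_yolo_labels}}.
#' @return List of \code{\link{bbox}}.
#' @export
read_yolo_labels <- function(path, image_size, classes = VB_CLASSES) {
  H <- image_size[1]; W <- image_size[2]
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    v <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    cx <- v[2] * W; cy <- v[3] * H; w <- v[4] * W; h <- v[5] * H
    bbox(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2,
         class_id = classes[v[1] + 1])
  })
}

#' Deterministic 8:1:1 dataset split
#'
#' Seeded shuffle followed by contiguous slicing: \code{floor} rounding for
#' the train and validation shares, remainder to test.
#'
#' @param scene_ids Character or integer identifiers (>= 3).
#' @param ratios Length-3 positive weights, default \code{c(8, 1, 1)}.
#' @param seed Integer seed.
#' @return List with \code{train}, \code{val}, \code{test} (disjoint,
#'   exhaustive).
#' @export
split_dataset <- function(scene_ids, ratios = c(8, 1, 1), seed = 0L) {
  n <- length(scene_ids)
  if (n < 3) stop("need at least 3 scenes to split")
  if (length(ratios) != 3 || any(ratios <= 0)) stop("ratios must be 3 positive numbers")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  ids <- sample(scene_ids)
  rt <- ratios / sum(ratios)
  n_train <- floor(n * rt[1]); n_val <- floor(n * rt[2])
  list(train = ids[seq_len(n_train)],
       val = ids[n_train + seq_len(n_val)],
       test = ids[(n_train + n_val + 1):n])
}

#' Read an image file as an H x W x 3 array in [0, 1]
#'
#' TIFF, PNG and grayscale inputs are accepted; grayscale is replicated to
#' three channels.
#'
#' @param path Image path (.tif/.tiff/.png).
#' @return Numeric array \code{H x W x 3}.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop(sprintf("unsupported image format '%s'", ext)))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1) img <- array(rep(img[, , 1], 3), dim = c(dim(img)[1:2], 3))
  img
}

#' Write an H x W x 3 (or H x W) array in [0, 1] to TIFF or PNG
#' @param img Numeric array.
#' @param path Output path; format chosen by extension.
#' @export
write_image <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    png = png::writePNG(img, path),
    stop(sprintf("unsupported image format '%s'", ext)))
  invisible(path)
}
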