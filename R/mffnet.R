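# Detector assembly: C2f(-DSConv) backbone emitting P2..P5, multi-scale
# feature-fusion neck (FPN upsample paths + PAN down paths with an extra
# stride-4 head), anchor-free heads, prediction decoding and target
# assignment.

#' Detector configuration
#'
#' @param input_size \code{c(H, W)}, both divisible by 32.
#' @param num_classes Number of object classes (>= 1).
#' @param class_names Character vector of class names, length
#'   \code{num_classes}; defaults to the stem-section classes
#'   \code{c("small", "big", "in", "out")} truncated/extended as needed.
#' @param widths Channel widths of stages P1..P5.
#' @param depth Number of bottlenecks per C2f block.
#' @param use_dsconv Use snake convolutions in the backbone C2f blocks
#'   (ablation flag; \code{FALSE} gives plain convolutions).
#' @param use_mff Use the multi-scale feature-fusion neck with the extra
#'   stride-4 head (ablation flag; \code{FALSE} gives the 3-head baseline
#'   neck at strides 8/16/32).
#' @param loss Box regression loss, \code{"piou"} or \code{"ciou"}
#'   (ablation axis).
#' @param piou A \code{\link{piou_config}} used when \code{loss = "piou"};
#'   the training default is the corrected loss form with the corner
#'   penalty.
#' @param fusion Down-path fusion operator, \code{"concat"} (default) or
#'   \code{"add"}.
#' @param preset \code{"tiny"} shrinks widths for CPU work; \code{"default"}
#'   keeps \code{widths} as given.
#' @param seed Integer seed for parameter initialization.
#' @return A \code{detector_config} list.
#' @export
detector_config <- function(input_size = c(640L, 640L),
                            num_classes = 4L,
                            class_names = NULL,
                            widths = c(16L, 32L, 48L, 64L, 96L),
                            depth = 1L,
                            use_dsconv = TRUE,
                            use_mff = TRUE,
                            loss = c("piou", "ciou"),
                            piou = piou_config(penalty_mode = "corner",
                                               loss_form = "corrected"),
                            fusion = c("concat", "add"),
                            preset = c("default", "tiny"),
                            seed = 0L) {
  loss <- match.arg(loss)
  fusion <- match.arg(fusion)
  preset <- match.arg(preset)
  if (length(input_size) == 1) input_size <- rep(input_size, 2)
  input_size <- as.integer(input_size)
  if (any(input_size %% 32L != 0L) || any(input_size < 32L))
    stop("input_size must be divisible by 32")
  if (preset == "tiny") widths <- c(4L, 8L, 12L, 16L, 24L)
  widths <- as.integer(widths)
  if (length(widths) != 5) stop("widths must give 5 stage widths (P1..P5)")
  num_classes <- as.integer(num_classes)
  if (num_classes < 1L) stop("num_classes must be >= 1")
  if (is.null(class_names)) {
    base <- c("small", "big", "in", "out")
    class_names <- if (num_classes <= 4L) base[seq_len(num_classes)]
                   else c(base, paste0("class", seq_len(num_classes - 4L)))
  }
  if (length(class_names) != num_classes)
    stop("class_names must have length num_classes")
  structure(list(input_size = input_size, num_classes = num_classes,
                 class_names = class_names, widths = widths,
                 depth = as.integer(depth), use_dsconv = isTRUE(use_dsconv),
                 use_mff = isTRUE(use_mff), loss = loss, piou = piou,
                 fusion = fusion, seed = as.integer(seed)),
            class = "detector_config")
}

head_strides <- function(cfg) if (cfg$use_mff) c(4L, 8L, 16L, 32L) else c(8L, 16L, 32L)

#' Build the detector
#'
#' Assembles the backbone (stride-2 stem, then four stride-2 stages each
#' followed by a C2f block, emitting P2/4, P3/8, P4/16, P5/32), the neck
#' (upsample-fuse paths; with MFF an extra stride-4 level and three
#' down-fuse paths feeding four heads, without it the 3-head baseline), and
#' one detection head per level predicting 4 box values, an objectness logit
#' and per-class logits.  Parameter initialization is seeded from
#' \code{cfg$seed}.
#'
#' @param cfg A \code{\link{detector_config}}.
#' @return A \code{vb_detector} object.
#' @export
build_detector <- function(cfg) {
  stopifnot(inherits(cfg, "detector_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  w <- cfg$widths
  n <- cfg$depth
  ds <- cfg$use_dsconv
  L <- list()
  L$stem  <- new_conv_layer(3L, w[1], k = 3L, stride = 2L, mode = "dense")
  L$down1 <- new_conv_layer(w[1], w[2], k = 3L, stride = 2L, mode = "dense")
  L$c2f2  <- c2f_block(w[2], w[2], n = n, dsconv = ds)
  L$down2 <- new_conv_layer(w[2], w[3], k = 3L, stride = 2L, mode = "dense")
  L$c2f3  <- c2f_block(w[3], w[3], n = n, dsconv = ds)
  L$down3 <- new_conv_layer(w[3], w[4], k = 3L, stride = 2L, mode = "dense")
  L$c2f4  <- c2f_block(w[4], w[4], n = n, dsconv = ds)
  L$down4 <- new_conv_layer(w[4], w[5], k = 3L, stride = 2L, mode = "dense")
  L$c2f5  <- c2f_block(w[5], w[5], n = n, dsconv = ds)
  # FPN up path (plain convolutions in the neck)
  L$f4 <- c2f_block(w[5] + w[4], w[4], n = n, dsconv = FALSE)
  L$f3 <- c2f_block(w[4] + w[3], w[3], n = n, dsconv = FALSE)
  fuse_in <- function(a, b) if (cfg$fusion == "concat") a + b else b
  if (cfg$use_mff) {
    L$f2 <- c2f_block(w[3] + w[2], w[2], n = n, dsconv = FALSE)
    L$t2 <- new_conv_layer(w[2], w[2], k = 3L, stride = 2L, mode = "dense")
    L$d3 <- c2f_block(fuse_in(w[2], w[3]), w[3], n = n, dsconv = FALSE)
    L$t4 <- new_conv_layer(w[3], w[3], k = 3L, stride = 2L, mode = "dense")
    L$d4 <- c2f_block(fuse_in(w[3], w[4]), w[4], n = n, dsconv = FALSE)
    L$t5 <- new_conv_layer(w[4], w[4], k = 3L, stride = 2L, mode = "dense")
    L$d5 <- c2f_block(fuse_in(w[4], w[5]), w[5], n = n, dsconv = FALSE)
    head_ch <- c(w[2], w[3], w[4], w[5])
  } else {
    L$t4 <- new_conv_layer(w[3], w[3], k = 3L, stride = 2L, mode = "dense")
    L$d4 <- c2f_block(fuse_in(w[3], w[4]), w[4], n = n, dsconv = FALSE)
    L$t5 <- new_conv_layer(w[4], w[4], k = 3L, stride = 2L, mode = "dense")
    L$d5 <- c2f_block(fuse_in(w[4], w[5]), w[5], n = n, dsconv = FALSE)
    head_ch <- c(w[3], w[4], w[5])
  }
  A <- 5L + cfg$num_classes
  heads <- lapply(head_ch, function(ch) {
    list(conv = new_conv_layer(ch, ch, k = 3L, mode = "dense"),
         out = new_conv_layer(ch, A, k = 1L, mode = "dense", act = FALSE))
  })
  strides <- head_strides(cfg)
  graph <- data.frame(
    name = c("P1", "P2", "P3", "P4", "P5", "F4", "F3",
             if (cfg$use_mff) c("F2", "T2", "T4", "T5") else c("T4", "T5"),
             paste0("head", strides)),
    stride = c(2L, 4L, 8L, 16L, 32L, 16L, 8L,
               if (cfg$use_mff) c(4L, 8L, 16L, 32L) else c(16L, 32L),
               strides),
    stringsAsFactors = FALSE)
  structure(list(cfg = cfg, layers = L, heads = heads, strides = strides,
                 graph = graph),
            class = "vb_detector")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.vb_detector <- function(x, ...) {
  cat(sprintf("<vb_detector: %d heads (strides %s), %s, %s neck, %s loss, %d params>\n",
              length(x$heads), paste(x$strides, collapse = "/"),
              if (x$cfg$use_dsconv) "snake-conv backbone" else "plain backbone",
              if (x$cfg$use_mff) "MFF" else "baseline",
              x$cfg$loss, n_params(x)))
  invisible(x)
}

detector_params <- function(model) {
  ps <- list()
  for (nm in names(model$layers)) {
    l <- model$layers[[nm]]
    ps <- c(ps, if (inherits(l, "c2f_block")) c2f_params(l) else layer_params(l))
  }
  for (h in model$heads) ps <- c(ps, layer_params(h$conv), layer_params(h$out))
  ps
}

detector_clamp_offsets <- function(model) {
  for (nm in names(model$layers)) {
    l <- model$layers[[nm]]
    if (inherits(l, "c2f_block")) {
      clamp_layer_offsets(l$cv1); clamp_layer_offsets(l$cv2)
      for (bn in l$bottlenecks) { clamp_layer_offsets(bn$a); clamp_layer_offsets(bn$b) }
    } else clamp_layer_offsets(l)
  }
  invisible(NULL)
}

#' Upsample-and-fuse two pyramid levels
#'
#' Nearest-neighbor 2x upsampling of the deeper map, channel concatenation
#' with the shallower map — in the fixed order (upsampled deep, shallow) —
#' and an optional C2f mixing block.
#'
#' @param deep \code{\link{feature_map}} at stride \code{2 * shallow$stride}.
#' @param shallow \code{\link{feature_map}}.
#' @param block Optional \code{\link{c2f_block}} mixing the concatenation.
#' @return A \code{feature_map} at the shallow stride.
#' @export
upsample_fuse <- function(deep, shallow, block = NULL) {
  stopifnot(inherits(deep, "feature_map"), inherits(shallow, "feature_map"))
  if (deep$stride != 2L * shallow$stride)
    stop("stride mismatch: deep stride must be twice the shallow stride")
  up <- cpp_upsample2x(deep$values)
  out <- ag_concat(NULL, list(up, shallow$values))
  if (!is.null(block)) out <- c2f_forward_node(NULL, block, out)
  feature_map(out, stride = shallow$stride)
}

#' Downsample-and-fuse two pyramid levels
#'
#' Stride-2 convolution of the current (shallower) map, fusion with the
#' lateral map — channel concatenation by default, element-wise addition as
#' the alternative — and an optional C2f mixing block.
#'
#' @param current \code{\link{feature_map}} at stride \code{lateral$stride / 2}.
#' @param lateral \code{\link{feature_map}}.
#' @param down_layer Stride-2 convolution layer (from the detector) applied
#'   to \code{current}.
#' @param block Optional \code{\link{c2f_block}}.
#' @param fusion \code{"concat"} or \code{"add"}.
#' @return A \code{feature_map} at the lateral stride.
#' @export
downsample_fuse <- function(current, lateral, down_layer, block = NULL,
                            fusion = c("concat", "add")) {
  fusion <- match.arg(fusion)
  stopifnot(inherits(current, "feature_map"), inherits(lateral, "feature_map"))
  if (2L * current$stride != lateral$stride)
    stop("stride mismatch: current stride must be half the lateral stride")
  dn <- layer_forward(NULL, down_layer, current$values)
  out <- if (fusion == "concat") ag_concat(NULL, list(dn, lateral$values))
         else dn + lateral$values
  if (!is.null(block)) out <- c2f_forward_node(NULL, block, out)
  feature_map(out, stride = lateral$stride)
}

# Forward pass; returns list(heads = list of (A,Hg,Wg) arrays or tape nodes,
# strides).  tape = NULL for inference.
detector_forward <- function(model, x, tape = NULL) {
  cfg <- model$cfg
  d <- dim(ag_val(x))
  if (d[1] != 3L) stop("input must have 3 channels")
  if (d[2] != cfg$input_size[1] || d[3] != cfg$input_size[2])
    stop(sprintf("input is %dx%d but the detector expects %dx%d",
                 d[2], d[3], cfg$input_size[1], cfg$input_size[2]))
  L <- model$layers
  fuse <- function(a, b) {
    if (cfg$fusion == "concat") ag_concat(tape, list(a, b)) else ag_add(tape, a, b)
  }
  p1 <- layer_forward(tape, L$stem, x)
  p2 <- c2f_forward_node(tape, L$c2f2, layer_forward(tape, L$down1, p1))
  p3 <- c2f_forward_node(tape, L$c2f3, layer_forward(tape, L$down2, p2))
  p4 <- c2f_forward_node(tape, L$c2f4, layer_forward(tape, L$down3, p3))
  p5 <- c2f_forward_node(tape, L$c2f5, layer_forward(tape, L$down4, p4))
  f4 <- c2f_forward_node(tape, L$f4,
          ag_concat(tape, list(ag_upsample2x(tape, p5), p4)))
  f3 <- c2f_forward_node(tape, L$f3,
          ag_concat(tape, list(ag_upsample2x(tape, f4), p3)))
  if (cfg$use_mff) {
    f2 <- c2f_forward_node(tape, L$f2,
            ag_concat(tape, list(ag_upsample2x(tape, f3), p2)))
    d3 <- c2f_forward_node(tape, L$d3, fuse(layer_forward(tape, L$t2, f2), f3))
    d4 <- c2f_forward_node(tape, L$d4, fuse(layer_forward(tape, L$t4, d3), f4))
    d5 <- c2f_forward_node(tape, L$d5, fuse(layer_forward(tape, L$t5, d4), p5))
    feats <- list(f2, d3, d4, d5)
  } else {
    d4 <- c2f_forward_node(tape, L$d4, fuse(layer_forward(tape, L$t4, f3), f4))
    d5 <- c2f_forward_node(tape, L$d5, fuse(layer_forward(tape, L$t5, d4), p5))
    feats <- list(f3, d4, d5)
  }
  outs <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    h <- model$heads[[i]]
    outs[[i]] <- layer_forward(tape, h$out, layer_forward(tape, h$conv, feats[[i]]))
  }
  list(heads = outs, strides = model$strides)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Decode the 4 raw box activations of grid cell (gi, gj) at stride s into
# (x1, y1, x2, y2).  Center offsets span (-0.5, 1.5) cells, sizes (0, 4s).
decode_cell_box <- function(t4, gi, gj, s) {
  cx <- (gj - 1 + 2 * sigmoid(t4[1]) - 0.5) * s
  cy <- (gi - 1 + 2 * sigmoid(t4[2]) - 0.5) * s
  w <- (2 * sigmoid(t4[3]))^2 * s
  h <- (2 * sigmoid(t4[4]))^2 * s
  c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
}

#' Decode raw head outputs into boxes
#'
#' Grid activations are decoded into image-space boxes (cell-relative center
#' offsets, stride-scaled sizes), scored as
#' \code{sigmoid(objectness) * sigmoid(best class logit)}, thresholded,
#' clipped to the image, and filtered by per-class non-maximum suppression.
#'
#' @param raw Output of the forward pass: list with \code{heads} (list of
#'   \code{(5+nc, Hg, Wg)} arrays) and \code{strides}.
#' @param input_size \code{c(H, W)} of the network input.
#' @param class_names Character vector of class names.
#' @param score_threshold Minimum score in \code{[0, 1]}.
#' @param nms_iou IoU threshold for suppression, in \code{[0, 1]}.
#' @return List of \code{\link{bbox}} sorted by confidence (may be empty).
#' @export
decode_predictions <- function(raw, input_size, class_names,
                               score_threshold = 0.25, nms_iou = 0.5) {
  if (score_threshold < 0 || score_threshold > 1 || nms_iou < 0 || nms_iou > 1)
    stop("thresholds must lie in [0, 1]")
  nc <- length(class_names)
  H <- input_size[1]; W <- input_size[2]
  rows <- list()
  for (k in seq_along(raw$heads)) {
    V <- ag_val(raw$heads[[k]])
    s <- raw$strides[k]
    Hg <- dim(V)[2]; Wg <- dim(V)[3]
    obj <- matrix(sigmoid(V[5, , ]), Hg, Wg)
    for (gi in seq_len(Hg)) for (gj in seq_len(Wg)) {
      o <- obj[gi, gj]
      if (o < score_threshold) next  # class prob <= 1 cannot recover
      cl <- sigmoid(V[5 + seq_len(nc), gi, gj])
      ci <- which.max(cl)
      sc <- o * cl[ci]
      if (sc < score_threshold) next
      bb <- decode_cell_box(V[1:4, gi, gj], gi, gj, s)
      x1 <- max(0, min(bb[1], W)); y1 <- max(0, min(bb[2], H))
      x2 <- max(0, min(bb[3], W)); y2 <- max(0, min(bb[4], H))
      if (x2 - x1 <= 1e-6 || y2 - y1 <= 1e-6) next
      rows[[length(rows) + 1]] <- list(x1, y1, x2, y2, ci, sc)
    }
  }
  if (!length(rows)) return(list())
  m <- do.call(rbind, lapply(rows, function(r) unlist(r)))
  keep <- nms_per_class(m, nms_iou)
  m <- m[keep, , drop = FALSE]
  ord <- order(-m[, 6])
  lapply(ord, function(i)
    bbox(m[i, 1], m[i, 2], m[i, 3], m[i, 4],
         class_id = class_names[m[i, 5]], confidence = m[i, 6]))
}

# m: matrix with columns x1,y1,x2,y2,class,score.  Returns kept row indices.
nms_per_class <- function(m, nms_iou) {
  keep <- integer(0)
  for (cl in unique(m[, 5])) {
    idx <- which(m[, 5] == cl)
    idx <- idx[order(-m[idx, 6], idx)]
    taken <- integer(0)
    for (i in idx) {
      ok <- TRUE
      for (j in taken) {
        if (box_iou_xyxy(m[i, 1:4], m[j, 1:4]) > nms_iou) { ok <- FALSE; break }
      }
      if (ok) taken <- c(taken, i)
    }
    keep <- c(keep, taken)
  }
  sort(keep)
}

box_iou_xyxy <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (ua <= 0) 0 else inter / ua
}

#' Assign ground-truth boxes to head grid cells
#'
#' Each box is routed to the head whose stride covers its size (the smallest
#' stride \code{s} with \code{max(w, h) <= 4 s}, clamped to the available
#' strides) and claims its center cell plus the nearest neighbor cell along
#' each axis.  Cell collisions are resolved first-come (ground-truth order);
#' boxes lying outside the image are skipped with a warning.
#'
#' @param gt List of ground-truth \code{\link{bbox}}.
#' @param cfg A \code{\link{detector_config}} (supplies strides, grid sizes,
#'   classes).
#' @return List with one data frame per head (\code{gi}, \code{gj},
#'   \code{class_idx}, \code{x1}, \code{y1}, \code{x2}, \code{y2}).
#' @export
assign_targets <- function(gt, cfg) {
  strides <- head_strides(cfg)
  H <- cfg$input_size[1]; W <- cfg$input_size[2]
  grids <- lapply(strides, function(s) c(H %/% s, W %/% s))
  out <- lapply(seq_along(strides), function(i)
    data.frame(gi = integer(0), gj = integer(0), class_idx = integer(0),
               x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
               y2 = numeric(0)))
  claimed <- lapply(grids, function(g) matrix(FALSE, g[1], g[2]))
  for (b in gt) {
    cx <- (b$x1 + b$x2) / 2; cy <- (b$y1 + b$y2) / 2
    if (cx < 0 || cx > W || cy < 0 || cy > H) {
      warning(sprintf("ground-truth box centered at (%.1f, %.1f) lies outside the %dx%d image; skipped",
                      cx, cy, W, H))
      next
    }
    msize <- max(bbox_width(b), bbox_height(b))
    k <- which(msize <= 4 * strides)
    k <- if (length(k)) k[1] else length(strides)
    s <- strides[k]
    Hg <- grids[[k]][1]; Wg <- grids[[k]][2]
    gj <- min(Wg, max(1L, as.integer(floor(cx / s)) + 1L))
    gi <- min(Hg, max(1L, as.integer(floor(cy / s)) + 1L))
    fx <- cx / s - (gj - 1); fy <- cy / s - (gi - 1)
    cells <- list(c(gi, gj))
    gj2 <- gj + if (fx < 0.5) -1L else 1L
    gi2 <- gi + if (fy < 0.5) -1L else 1L
    if (gj2 >= 1 && gj2 <= Wg) cells <- c(cells, list(c(gi, gj2)))
    if (gi2 >= 1 && gi2 <= Hg) cells <- c(cells, list(c(gi2, gj)))
    ci <- match(b$class_id, cfg$class_names)
    if (is.na(ci)) stop(sprintf("unknown class '%s'", b$class_id))
    for (cc in cells) {
      if (claimed[[k]][cc[1], cc[2]]) next
      claimed[[k]][cc[1], cc[2]] <- TRUE
      out[[k]] <- rbind(out[[k]],
        data.frame(gi = cc[1], gj = cc[2], class_idx = ci,
                   x1 = b$x1, y1 = b$y1, x2 = b$x2, y2 = b$y2))
    }
  }
  out
}

# Box regression loss on one decoded box (chosen by cfg).
box_loss_value <- function(pred_xyxy, gt_xyxy, cfg) {
  if (pred_xyxy[3] - pred_xyxy[1] <= 1e-9 || pred_xyxy[4] - pred_xyxy[2] <= 1e-9)
    return(4)  # collapsed decode; worst-case constant keeps the loss finite
  p <- bbox(pred_xyxy[1], pred_xyxy[2], pred_xyxy[3], pred_xyxy[4])
  g <- bbox(gt_xyxy[1], gt_xyxy[2], gt_xyxy[3], gt_xyxy[4])
  if (cfg$loss == "ciou") ciou_loss(p, g) else piou_loss(p, g, cfg$piou)
}

# Detection loss for one image.  Builds per-head gradient arrays analytically
# (objectness/class BCE) and by central differences (box loss w.r.t. the four
# raw activations), attaches them to the tape, and returns the scalar node.
# weight scales the contribution (1/batch_size when accumulating).
detection_loss <- function(model, tape, raw, targets, weight = 1,
                           lambda_box = 5, lambda_obj = 1, lambda_cls = 0.5,
                           pos_weight = 3) {
  cfg <- model$cfg
  nc <- cfg$num_classes
  parts <- list()
  total_val <- 0
  for (k in seq_along(raw$heads)) {
    node <- raw$heads[[k]]
    V <- ag_val(node)
    s <- raw$strides[k]
    A <- dim(V)[1]; Hg <- dim(V)[2]; Wg <- dim(V)[3]
    G <- array(0, dim = dim(V))
    tgt <- targets[[k]]
    ncell <- Hg * Wg
    # objectness BCE over all cells
    p <- matrix(sigmoid(V[5, , ]), Hg, Wg)
    tm <- matrix(0, Hg, Wg)
    wm <- matrix(1, Hg, Wg)
    if (nrow(tgt)) {
      tm[cbind(tgt$gi, tgt$gj)] <- 1
      wm[cbind(tgt$gi, tgt$gj)] <- pos_weight
    }
    eps <- 1e-9
    lobj <- sum(wm * (-(tm * log(p + eps) + (1 - tm) * log(1 - p + eps)))) / ncell
    G[5, , ] <- lambda_obj * weight * wm * (p - tm) / ncell
    lval <- lambda_obj * lobj
    # per-cell class BCE and box loss at positive cells
    if (nrow(tgt)) {
      npos <- nrow(tgt)
      lcls <- 0; lbox <- 0
      hstep <- 1e-3
      for (r in seq_len(npos)) {
        gi <- tgt$gi[r]; gj <- tgt$gj[r]
        zc <- V[5 + seq_len(nc), gi, gj]
        pc <- sigmoid(zc)
        tc <- as.numeric(seq_len(nc) == tgt$class_idx[r])
        lcls <- lcls + sum(-(tc * log(pc + eps) + (1 - tc) * log(1 - pc + eps)))
        G[5 + seq_len(nc), gi, gj] <- G[5 + seq_len(nc), gi, gj] +
          lambda_cls * weight * (pc - tc) / (npos * nc)
        gtb <- c(tgt$x1[r], tgt$y1[r], tgt$x2[r], tgt$y2[r])
        t4 <- V[1:4, gi, gj]
        f0 <- box_loss_value(decode_cell_box(t4, gi, gj, s), gtb, cfg)
        lbox <- lbox + f0
        for (d in 1:4) {
          tp <- t4; tp[d] <- tp[d] + hstep
          tmn <- t4; tmn[d] <- tmn[d] - hstep
          gd <- (box_loss_value(decode_cell_box(tp, gi, gj, s), gtb, cfg) -
                 box_loss_value(decode_cell_box(tmn, gi, gj, s), gtb, cfg)) /
                (2 * hstep)
          G[d, gi, gj] <- G[d, gi, gj] + lambda_box * weight * gd / npos
        }
      }
      lval <- lval + lambda_cls * lcls / (npos * nc) + lambda_box * lbox / npos
    }
    total_val <- total_val + lval
    if (!is.null(tape))
      parts[[length(parts) + 1]] <- ag_adjoint(tape, node, weight * lval, G)
  }
  if (is.null(tape)) return(weight * total_val)
  ag_sum_scalars(tape, parts)
}
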