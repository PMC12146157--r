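# Detection evaluation: greedy matching, precision/recall, AP/mAP over IoU
# thresholds, MAPE/RMSE on scalar summaries, Dice and region-IoU scores.

boxes_to_df <- function(boxes) {
  if (!length(boxes)) {
    return(data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), class_id = character(0),
                      confidence = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(boxes, function(b)
    data.frame(x1 = b$x1, y1 = b$y1, x2 = b$x2, y2 = b$y2,
               class_id = b$class_id, confidence = b$confidence,
               stringsAsFactors = FALSE)))
}

#' Match detections to ground truth
#'
#' Greedy one-to-one matching: predictions are visited in descending
#' confidence (ties broken by prediction index) and each claims the
#' still-unmatched ground-truth box of the same class with the highest IoU
#' at or above the threshold (IoU ties broken by ground-truth index).
#'
#' @param preds List of predicted \code{\link{bbox}} carrying confidences.
#' @param gts List of ground-truth \code{\link{bbox}}.
#' @param iou_threshold Matching threshold in \code{(0, 1]}.
#' @return A \code{match_result} list: \code{tp}, \code{fp}, \code{fn},
#'   and \code{pairs} (data frame of matched pred/gt indices with IoU).
#' @export
match_detections <- function(preds, gts, iou_threshold = 0.5) {
  if (iou_threshold <= 0 || iou_threshold > 1)
    stop("iou_threshold must be in (0, 1]")
  np <- length(preds); ng <- length(gts)
  ord <- if (np) order(-vapply(preds, function(b) b$confidence, numeric(1)),
                       seq_len(np)) else integer(0)
  gt_used <- rep(FALSE, ng)
  pairs <- data.frame(pred = integer(0), gt = integer(0), iou = numeric(0))
  for (i in ord) {
    best <- 0; bj <- 0L
    for (j in seq_len(ng)) {
      if (gt_used[j] || gts[[j]]$class_id != preds[[i]]$class_id) next
      ov <- iou(preds[[i]], gts[[j]])
      if (ov >= iou_threshold && ov > best) { best <- ov; bj <- j }
    }
    if (bj > 0L) {
      gt_used[bj] <- TRUE
      pairs <- rbind(pairs, data.frame(pred = i, gt = bj, iou = best))
    }
  }
  tp <- nrow(pairs)
  structure(list(tp = tp, fp = np - tp, fn = ng - tp, pairs = pairs),
            class = "match_result")
}

#' Precision and recall from a match result
#'
#' \code{P = TP / (TP + FP)} and \code{R = TP / (TP + FN)}, each defined as
#' 0 when its denominator is 0.
#'
#' @param m A \code{match_result} (or list with \code{tp}, \code{fp},
#'   \code{fn}).
#' @return Named numeric \code{c(precision, recall)}.
#' @export
precision_recall <- function(m) {
  p <- if (m$tp + m$fp == 0) 0 else m$tp / (m$tp + m$fp)
  r <- if (m$tp + m$fn == 0) 0 else m$tp / (m$tp + m$fn)
  c(precision = p, recall = r)
}

# Per-prediction TP/FP flags for one class at one threshold, in ranked order.
rank_flags <- function(preds, gts, iou_threshold) {
  np <- length(preds); ng <- length(gts)
  ord <- if (np) order(-vapply(preds, function(b) b$confidence, numeric(1)),
                       seq_len(np)) else integer(0)
  gt_used <- rep(FALSE, ng)
  tp <- logical(np)
  pos <- 0L
  for (i in ord) {
    pos <- pos + 1L
    best <- 0; bj <- 0L
    for (j in seq_len(ng)) {
      if (gt_used[j]) next
      ov <- iou(preds[[i]], gts[[j]])
      if (ov >= iou_threshold && ov > best) { best <- ov; bj <- j }
    }
    if (bj > 0L) { gt_used[bj] <- TRUE; tp[pos] <- TRUE }
  }
  tp
}

#' Average precision for one class
#'
#' Builds the precision-recall curve by sweeping the confidence ranking and
#' integrates it.  \code{"101point"} (the dominant convention) averages the
#' monotone precision envelope at recalls 0, 0.01, ..., 1; \code{"exact"}
#' integrates the envelope staircase exactly over recall.
#'
#' @param preds Predictions of a single class (confidences required).
#' @param gts Ground truth of the same class.
#' @param iou_threshold Matching threshold.
#' @param interpolation \code{"101point"} or \code{"exact"}.
#' @return AP in \code{[0, 1]}; \code{NA} (with a warning) when there is no
#'   ground truth for the class.
#' @export
average_precision <- function(preds, gts, iou_threshold = 0.5,
                              interpolation = c("101point", "exact")) {
  interpolation <- match.arg(interpolation)
  if (!length(gts)) {
    warning("no ground-truth boxes for this class; AP undefined")
    return(NA_real_)
  }
  if (!length(preds)) return(0)
  tp <- rank_flags(preds, gts, iou_threshold)
  ctp <- cumsum(tp); cfp <- cumsum(!tp)
  rec <- ctp / length(gts)
  prec <- ctp / (ctp + cfp)
  # monotone (non-increasing) precision envelope from the right
  env <- rev(cummax(rev(prec)))
  if (interpolation == "101point") {
    rs <- seq(0, 1, by = 0.01)
    pv <- vapply(rs, function(r) {
      i <- which(rec >= r - 1e-12)
      if (length(i)) env[i[1]] else 0
    }, numeric(1))
    mean(pv)
  } else {
    r0 <- c(0, rec)
    sum((rec - r0[-length(r0)]) * env)
  }
}

#' Mean average precision over classes and IoU thresholds
#'
#' AP is computed per class (restricting predictions and ground truth to the
#' class) at each threshold, averaged over thresholds, then averaged over
#' the classes that have ground truth.  \code{thresholds = 0.5} gives
#' mAP@.5; \code{seq(0.5, 0.95, 0.05)} gives mAP@.5:.95.
#'
#' @param preds,gts Mixed-class box lists.
#' @param thresholds Numeric vector of IoU thresholds.
#' @param classes Classes to evaluate; defaults to the classes present in
#'   the ground truth.
#' @param interpolation Passed to \code{\link{average_precision}}.
#' @return Mean AP; classes without ground truth are excluded with a
#'   warning.
#' @export
mean_ap <- function(preds, gts, thresholds = 0.5, classes = NULL,
                    interpolation = c("101point", "exact")) {
  interpolation <- match.arg(interpolation)
  if (is.null(classes))
    classes <- unique(vapply(gts, function(b) b$class_id, character(1)))
  if (!length(classes)) stop("no classes with ground truth to evaluate")
  aps <- numeric(0)
  for (cl in classes) {
    pc <- Filter(function(b) b$class_id == cl, preds)
    gc <- Filter(function(b) b$class_id == cl, gts)
    if (!length(gc)) {
      warning(sprintf("class '%s' has no ground truth; excluded from mAP", cl))
      next
    }
    ap_t <- vapply(thresholds, function(th)
      average_precision(pc, gc, th, interpolation), numeric(1))
    aps <- c(aps, mean(ap_t))
  }
  if (!length(aps)) stop("no classes with ground truth to evaluate")
  mean(aps)
}

#' MAPE and RMSE between actual and predicted scalar summaries
#'
#' \code{MAPE = mean(|y - yhat| / |y|) * 100} (entries with \code{y = 0} are
#' excluded with a warning); \code{RMSE = sqrt(mean((y - yhat)^2))}.  Used
#' for per-image bundle counts and total bundle areas.
#'
#' @param actual,predicted Numeric vectors of equal length.
#' @return Named numeric \code{c(mape, rmse)} (MAPE in percent).
#' @export
regression_errors <- function(actual, predicted) {
  if (!length(actual)) stop("empty input")
  if (length(actual) != length(predicted))
    stop("actual and predicted must have the same length")
  rmse <- sqrt(mean((actual - predicted)^2))
  nz <- actual != 0
  if (!all(nz)) warning(sprintf("%d zero-valued actual entries excluded from MAPE",
                                sum(!nz)))
  mape <- if (any(nz)) mean(abs((actual[nz] - predicted[nz]) / actual[nz])) * 100
          else NA_real_
  c(mape = mape, rmse = rmse)
}

rasterize_boxes <- function(boxes, image_size) {
  H <- image_size[1]; W <- image_size[2]
  m <- matrix(FALSE, H, W)
  for (b in boxes) {
    xs <- which(seq_len(W) - 0.5 >= b$x1 & seq_len(W) - 0.5 <= b$x2)
    ys <- which(seq_len(H) - 0.5 >= b$y1 & seq_len(H) - 0.5 <= b$y2)
    if (length(xs) && length(ys)) m[ys, xs] <- TRUE
  }
  m
}

#' Region Dice and IoU between predicted and ground-truth box sets
#'
#' Per class, the union of predicted boxes and the union of ground-truth
#' boxes are rasterized into binary masks (pixel centers on the integer
#' grid); Dice \code{= 2|A&B| / (|A| + |B|)} and IoU \code{= |A&B| / |A|B|}
#' are computed and averaged over classes (a class with both masks empty is
#' skipped).
#'
#' @param pred_boxes,gt_boxes Box lists.
#' @param image_size \code{c(H, W)} in pixels.
#' @return Named numeric \code{c(dice, iou)}.
#' @export
overlap_scores <- function(pred_boxes, gt_boxes, image_size) {
  if (any(image_size <= 0)) stop("image size must be positive")
  classes <- unique(c(vapply(pred_boxes, function(b) b$class_id, character(1)),
                      vapply(gt_boxes, function(b) b$class_id, character(1))))
  dice <- numeric(0); riou <- numeric(0)
  for (cl in classes) {
    A <- rasterize_boxes(Filter(function(b) b$class_id == cl, pred_boxes),
                         image_size)
    B <- rasterize_boxes(Filter(function(b) b$class_id == cl, gt_boxes),
                         image_size)
    na <- sum(A); nb <- sum(B)
    if (na + nb == 0) next
    ni <- sum(A & B)
    dice <- c(dice, 2 * ni / (na + nb))
    riou <- c(riou, ni / (na + nb - ni))
  }
  if (!length(dice)) return(c(dice = NA_real_, iou = NA_real_))
  c(dice = mean(dice), iou = mean(riou))
}

#' Build a full evaluation report
#'
#' Per class: precision, recall (greedy matching at IoU 0.5), AP@.5 and
#' AP@.5:.95; aggregate mAP@.5 and mAP@.5:.95; region Dice/IoU; MAPE and
#' RMSE on per-image counts and total box areas of the \code{count_class}.
#'
#' @param pred_scenes,gt_scenes Lists (one element per image) of box lists.
#' @param image_size \code{c(H, W)}.
#' @param classes Classes to report; default: classes present in the ground
#'   truth.
#' @param count_class Class used for the count/area regression errors
#'   (default \code{"small"} when present, else the first class).
#' @return An \code{eval_report} list.
#' @export
eval_report <- function(pred_scenes, gt_scenes, image_size, classes = NULL,
                        count_class = NULL) {
  stopifnot(length(pred_scenes) == length(gt_scenes))
  preds <- do.call(c, c(pred_scenes, list()))
  gts <- do.call(c, c(gt_scenes, list()))
  if (is.null(classes))
    classes <- unique(vapply(gts, function(b) b$class_id, character(1)))
  thr_full <- seq(0.5, 0.95, by = 0.05)
  per_class <- lapply(classes, function(cl) {
    pc <- Filter(function(b) b$class_id == cl, preds)
    gc <- Filter(function(b) b$class_id == cl, gts)
    m <- match_detections(pc, gc, 0.5)
    pr <- precision_recall(m)
    ap50 <- if (length(gc)) average_precision(pc, gc, 0.5) else NA_real_
    ap5095 <- if (length(gc))
      mean(vapply(thr_full, function(th) average_precision(pc, gc, th),
                  numeric(1))) else NA_real_
    list(class = cl, precision = unname(pr[1]), recall = unname(pr[2]),
         ap50 = ap50, ap5095 = ap5095, n_gt = length(gc), n_pred = length(pc))
  })
  names(per_class) <- classes
  valid <- !vapply(per_class, function(x) is.na(x$ap50), logical(1))
  map50 <- mean(vapply(per_class[valid], `[[`, numeric(1), "ap50"))
  map5095 <- mean(vapply(per_class[valid], `[[`, numeric(1), "ap5095"))
  ov <- overlap_scores(preds, gts, image_size)
  if (is.null(count_class))
    count_class <- if ("small" %in% classes) "small" else classes[1]
  cnt_a <- vapply(gt_scenes, function(g)
    sum(vapply(g, function(b) b$class_id == count_class, logical(1))), numeric(1))
  cnt_p <- vapply(pred_scenes, function(g)
    sum(vapply(g, function(b) b$class_id == count_class, logical(1))), numeric(1))
  area_a <- vapply(gt_scenes, function(g)
    sum(vapply(g, function(b)
      if (b$class_id == count_class) bbox_area(b) else 0, numeric(1))), numeric(1))
  area_p <- vapply(pred_scenes, function(g)
    sum(vapply(g, function(b)
      if (b$class_id == count_class) bbox_area(b) else 0, numeric(1))), numeric(1))
  counts <- suppressWarnings(regression_errors(cnt_a, cnt_p))
  areas <- suppressWarnings(regression_errors(area_a, area_p))
  structure(list(per_class = per_class, map50 = map50, map5095 = map5095,
                 dice = unname(ov[1]), iou = unname(ov[2]),
                 count_mape = unname(counts[1]), count_rmse = unname(counts[2]),
                 area_mape = unname(areas[1]), area_rmse = unname(areas[2]),
                 count_class = count_class, n_images = length(gt_scenes)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d images\n", x$n_images))
  cat(sprintf("%-8s %9s %9s %9s %12s\n", "class", "P", "R", "mAP@.5",
              "mAP@.5:.95"))
  for (pc in x$per_class)
    cat(sprintf("%-8s %9.3f %9.3f %9.3f %12.3f\n", pc$class, pc$precision,
                pc$recall, pc$ap50, pc$ap5095))
  cat(sprintf("%-8s %9s %9s %9.3f %12.3f\n", "all", "", "", x$map50,
              x$map5095))
  cat(sprintf("Dice %.3f  IoU %.3f\n", x$dice, x$iou))
  cat(sprintf("%s count MAPE %.2f%%  RMSE %.3f | area MAPE %.2f%%  RMSE %.3f\n",
              x$count_class, x$count_mape, x$count_rmse, x$area_mape,
              x$area_rmse))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#' @param x An \code{eval_report}.
#' @param path Optional output path; when \code{NULL} the JSON string is
#'   returned.
#' @export
eval_report_json <- function(x, path = NULL) {
  obj <- unclass(x)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
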