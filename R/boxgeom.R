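# Box geometry and the bounding-box regression losses (IoU, CIoU, PIoU).

#' Construct an axis-aligned bounding box
#'
#' Boxes use continuous pixel coordinates with the origin at the top-left
#' corner, x increasing rightward and y downward.  A box is the closed region
#' \code{[x1, x2] x [y1, y2]} with strictly positive width and height.
#'
#' @param x1,y1 Top-left corner.
#' @param x2,y2 Bottom-right corner; must satisfy \code{x2 > x1}, \code{y2 > y1}.
#' @param class_id Class label, one of \code{"small"}, \code{"big"}, \code{"in"},
#'   \code{"out"} (or any label when used outside the stem-section task).
#' @param confidence Optional detection confidence in \code{[0, 1]}; \code{NA}
#'   for ground truth.
#' @return An object of class \code{bbox}: a named numeric/character list.
#' @examples
#' b <- bbox(0, 0, 4, 2, class_id = "small")
#' bbox_width(b)   # 4
#' bbox_height(b)  # 2
#' @export
bbox <- function(x1, y1, x2, y2, class_id = "small", confidence = NA_real_) {
  if (!is.finite(x1) || !is.finite(y1) || !is.finite(x2) || !is.finite(y2))
    stop("box coordinates must be finite")
  if (x2 <= x1 || y2 <= y1)
    stop(sprintf("degenerate box: need x2 > x1 and y2 > y1, got (%g,%g,%g,%g)",
                 x1, y1, x2, y2))
  structure(list(x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                 class_id = class_id, confidence = confidence),
            class = "bbox")
}

#' @export
print.bbox <- function(x, ...) {
  conf <- if (is.na(x$confidence)) "" else sprintf(" conf=%.3f", x$confidence)
  cat(sprintf("<bbox %s (%.2f, %.2f, %.2f, %.2f)%s>\n",
              x$class_id, x$x1, x$y1, x$x2, x$y2, conf))
  invisible(x)
}

#' @rdname bbox
#' @param b A \code{bbox}.
#' @export
bbox_width <- function(b) b$x2 - b$x1

#' @rdname bbox
#' @export
bbox_height <- function(b) b$y2 - b$y1

#' @rdname bbox
#' @export
bbox_area <- function(b) (b$x2 - b$x1) * (b$y2 - b$y1)

as_bbox <- function(b) {
  if (inherits(b, "bbox")) return(b)
  bbox(b[[1]], b[[2]], b[[3]], b[[4]])
}

check_valid_box <- function(b, what = "box") {
  if (b$x2 <= b$x1 || b$y2 <= b$y1)
    stop(sprintf("%s is degenerate (zero or negative area)", what))
  invisible(b)
}

#' Intersection over union of two boxes
#'
#' @param a,b Valid \code{\link{bbox}} objects (or length-4 numeric vectors
#'   \code{c(x1, y1, x2, y2)}).
#' @return The ratio of intersection area to union area, in \code{[0, 1]}.
#'   Symmetric in its arguments; equals 1 iff the boxes are identical.
#' @examples
#' iou(bbox(0, 0, 2, 2), bbox(1, 1, 3, 3))  # 1/7
#' @export
iou <- function(a, b) {
  a <- as_bbox(a); b <- as_bbox(b)
  check_valid_box(a, "first box"); check_valid_box(b, "second box")
  iw <- min(a$x2, b$x2) - max(a$x1, b$x1)
  ih <- min(a$y2, b$y2) - max(a$y1, b$y1)
  inter <- max(iw, 0) * max(ih, 0)
  union <- bbox_area(a) + bbox_area(b) - inter
  inter / union
}

#' CIoU bounding-box regression loss
#'
#' The complete-IoU loss combines the overlap term with a normalized
#' center-distance penalty and an aspect-ratio consistency penalty:
#' \deqn{L = 1 - IoU + \rho^2(b, b^{gt})/c^2 + \alpha v}
#' where \eqn{\rho} is the distance between box centers, \eqn{c} the diagonal
#' of the smallest enclosing axis-aligned box,
#' \eqn{v = (4/\pi^2)(\arctan(w_{gt}/h_{gt}) - \arctan(w/h))^2} and
#' \eqn{\alpha = v / ((1 - IoU) + v)} (defined as 0 when both \eqn{1 - IoU}
#' and \eqn{v} vanish).
#'
#' @param pred,gt Valid boxes (predicted and ground truth).
#' @param terms If \code{TRUE}, return the individual terms alongside the loss.
#' @return The scalar loss, or (with \code{terms = TRUE}) a list with elements
#'   \code{iou}, \code{center_dist_sq}, \code{enclosing_diag_sq}, \code{v},
#'   \code{alpha}, \code{loss}.
#' @export
ciou_loss <- function(pred, gt, terms = FALSE) {
  pred <- as_bbox(pred); gt <- as_bbox(gt)
  check_valid_box(pred, "pred"); check_valid_box(gt, "gt")
  i <- iou(pred, gt)
  cxp <- (pred$x1 + pred$x2) / 2; cyp <- (pred$y1 + pred$y2) / 2
  cxg <- (gt$x1 + gt$x2) / 2;     cyg <- (gt$y1 + gt$y2) / 2
  rho2 <- (cxp - cxg)^2 + (cyp - cyg)^2
  cw <- max(pred$x2, gt$x2) - min(pred$x1, gt$x1)
  ch <- max(pred$y2, gt$y2) - min(pred$y1, gt$y1)
  c2 <- cw^2 + ch^2
  v <- (4 / pi^2) *
    (atan(bbox_width(gt) / bbox_height(gt)) -
     atan(bbox_width(pred) / bbox_height(pred)))^2
  denom <- (1 - i) + v
  alpha <- if (denom <= 0) 0 else v / denom
  loss <- 1 - i + rho2 / c2 + alpha * v
  if (!terms) return(loss)
  list(iou = i, center_dist_sq = rho2, enclosing_diag_sq = c2,
       v = v, alpha = alpha, loss = loss)
}

#' PIoU loss configuration
#'
#' The PIoU loss adds to the IoU term a size/corner penalty \eqn{P} with a
#' focusing prefactor \eqn{3u e^{-u^2}} where \eqn{u = \lambda q}.  Two
#' published formulations of the penalty and of the combined loss circulate;
#' both are implemented and selected here.
#'
#' @param lambda Positive weight coefficient for the penalty term
#'   (default 1.3).
#' @param penalty_mode \code{"printed"} computes the penalty from box widths
#'   and heights only (translation invariant); \code{"corner"} computes it
#'   from the four corner-coordinate distances, which is the reading implied
#'   by "minimizing the distance between corner points" and is the
#'   recommended training setting.
#' @param loss_form \code{"printed"} uses the factor
#'   \eqn{(1 - IoU - e^{-P^2})}, which is negative at perfect overlap;
#'   \code{"corrected"} uses \eqn{(1 - IoU) + (1 - e^{-P^2})}, which is zero
#'   at perfect overlap and is the recommended training setting.
#' @param q_form Focusing factor \eqn{q = e^{-P^2}} (\code{"exp_neg_P2"},
#'   default) or \eqn{q = e^{-P}} (\code{"exp_neg_P"}).
#' @return A \code{piou_config} list.
#' @export
piou_config <- function(lambda = 1.3,
                        penalty_mode = c("printed", "corner"),
                        loss_form = c("printed", "corrected"),
                        q_form = c("exp_neg_P2", "exp_neg_P")) {
  if (!is.numeric(lambda) || length(lambda) != 1 || !is.finite(lambda) ||
      lambda <= 0)
    stop("lambda must be a positive finite scalar")
  structure(list(lambda = lambda,
                 penalty_mode = match.arg(penalty_mode),
                 loss_form = match.arg(loss_form),
                 q_form = match.arg(q_form)),
            class = "piou_config")
}

#' PIoU size/corner penalty term
#'
#' In \code{"printed"} mode the four distances are
#' \eqn{d_{w1} = |w_1 - w_2|}, \eqn{d_{w2} = |w_1 + w_2|},
#' \eqn{d_{h1} = |h_1 - h_2|}, \eqn{d_{h2} = |h_1 + h_2|} (widths/heights of
#' the two boxes), so the penalty depends only on box sizes.  In
#' \code{"corner"} mode they are the absolute differences of the matching
#' corner coordinates.  Both modes then combine as
#' \deqn{P = \frac{1}{4}\left(\frac{d_{w1} + d_{w2}}{w_{gt}} +
#'         \frac{d_{h1} + d_{h2}}{h_{gt}}\right).}
#'
#' @inheritParams ciou_loss
#' @param mode \code{"printed"} or \code{"corner"}; see Details.
#' @return Nonnegative penalty value.
#' @export
piou_penalty <- function(pred, gt, mode = c("printed", "corner")) {
  mode <- match.arg(mode)
  pred <- as_bbox(pred); gt <- as_bbox(gt)
  check_valid_box(pred, "pred"); check_valid_box(gt, "gt")
  wgt <- bbox_width(gt); hgt <- bbox_height(gt)
  if (mode == "printed") {
    w1 <- bbox_width(pred); w2 <- wgt
    h1 <- bbox_height(pred); h2 <- hgt
    dw1 <- abs(w1 - w2); dw2 <- abs(w1 + w2)
    dh1 <- abs(h1 - h2); dh2 <- abs(h1 + h2)
  } else {
    dw1 <- abs(pred$x1 - gt$x1); dw2 <- abs(pred$x2 - gt$x2)
    dh1 <- abs(pred$y1 - gt$y1); dh2 <- abs(pred$y2 - gt$y2)
  }
  ((dw1 + dw2) / wgt + (dh1 + dh2) / hgt) / 4
}

#' PIoU bounding-box regression loss
#'
#' \deqn{L = 3 (\lambda q) e^{-(\lambda q)^2} \cdot f(IoU, P)}
#' where the penalty \eqn{P} comes from \code{\link{piou_penalty}}, the
#' focusing factor \eqn{q} and the overlap factor \eqn{f} are selected by the
#' configuration.  With \code{loss_form = "printed"},
#' \eqn{f = 1 - IoU - e^{-P^2}}; with \code{"corrected"},
#' \eqn{f = (1 - IoU) + (1 - e^{-P^2})}, which is nonnegative and vanishes
#' exactly at perfect overlap.
#'
#' @inheritParams ciou_loss
#' @param cfg A \code{\link{piou_config}}.
#' @return Scalar loss value.
#' @export
piou_loss <- function(pred, gt, cfg = piou_config()) {
  if (!inherits(cfg, "piou_config")) stop("cfg must be a piou_config")
  P <- piou_penalty(pred, gt, mode = cfg$penalty_mode)
  i <- iou(pred, gt)
  q <- if (cfg$q_form == "exp_neg_P2") exp(-P^2) else exp(-P)
  u <- cfg$lambda * q
  prefac <- 3 * u * exp(-u^2)
  f <- if (cfg$loss_form == "printed") 1 - i - exp(-P^2)
       else (1 - i) + (1 - exp(-P^2))
  prefac * f
}
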