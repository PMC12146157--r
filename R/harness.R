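# Training, evaluation and detection orchestration.

#' Training configuration
#'
#' The faithful preset follows the reference protocol (100 epochs, Adam,
#' learning rate 0.01, batch size 16, input 640); the \code{"tiny"} model
#' preset defaults to a learning rate of 0.001, which is better behaved at
#' very small widths.
#'
#' @param epochs Number of epochs.
#' @param learning_rate Adam learning rate.
#' @param batch_size Images per optimizer step.
#' @param input_size Square input side, divisible by 32.
#' @param loss \code{"piou"} or \code{"ciou"} (ablation axis).
#' @param use_dsconv,use_mff Ablation flags for the snake-convolution
#'   backbone and the multi-scale fusion neck.
#' @param piou \code{\link{piou_config}} used when \code{loss = "piou"}.
#' @param classes Class names to train on (boxes of other classes are
#'   dropped from the ground truth).
#' @param preset Model width preset, \code{"default"} or \code{"tiny"}.
#' @param depth Bottlenecks per C2f block.
#' @param widths Optional explicit stage widths (overrides \code{preset}).
#' @param augment_flips Random horizontal flips (off by default).
#' @param seed Seed for initialization and data order.
#' @param device Only \code{"cpu"} is supported.
#' @param lambda_box,lambda_obj,lambda_cls Loss term weights.
#' @param score_threshold,nms_iou Decoding thresholds used for validation.
#' @return A \code{train_config}.
#' @export
train_config <- function(epochs = 100L, learning_rate = 0.01,
                         batch_size = 16L, input_size = 640L,
                         loss = c("piou", "ciou"),
                         use_dsconv = TRUE, use_mff = TRUE,
                         piou = piou_config(penalty_mode = "corner",
                                            loss_form = "corrected"),
                         classes = VB_CLASSES,
                         preset = c("default", "tiny"), depth = 1L,
                         widths = NULL, augment_flips = FALSE, seed = 0L,
                         device = "cpu",
                         lambda_box = 5, lambda_obj = 1, lambda_cls = 0.5,
                         score_threshold = 0.25, nms_iou = 0.5) {
  loss <- match.arg(loss)
  preset <- match.arg(preset)
  if (!identical(device, "cpu")) stop("only device = 'cpu' is supported")
  if (epochs < 1 || learning_rate <= 0 || batch_size < 1)
    stop("hyperparameters must be positive")
  if (preset == "tiny" && missing(learning_rate)) learning_rate <- 0.001
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 input_size = as.integer(input_size), loss = loss,
                 use_dsconv = isTRUE(use_dsconv), use_mff = isTRUE(use_mff),
                 piou = piou, classes = classes, preset = preset,
                 depth = as.integer(depth), widths = widths,
                 augment_flips = isTRUE(augment_flips),
                 seed = as.integer(seed), device = device,
                 lambda_box = lambda_box, lambda_obj = lambda_obj,
                 lambda_cls = lambda_cls,
                 score_threshold = score_threshold, nms_iou = nms_iou),
            class = "train_config")
}

#' Read a training configuration from YAML
#' @param path YAML file whose keys match \code{\link{train_config}}
#'   arguments.
#' @export
train_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$piou)) vals$piou <- do.call(piou_config, vals$piou)
  do.call(train_config, vals)
}

detector_config_from_train <- function(cfg) {
  args <- list(input_size = cfg$input_size,
               num_classes = length(cfg$classes), class_names = cfg$classes,
               depth = cfg$depth, use_dsconv = cfg$use_dsconv,
               use_mff = cfg$use_mff, loss = cfg$loss, piou = cfg$piou,
               preset = cfg$preset, seed = cfg$seed)
  if (!is.null(cfg$widths)) { args$widths <- cfg$widths; args$preset <- "default" }
  do.call(detector_config, args)
}

vb_log <- function(level, fmt, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), level,
                  sprintf(fmt, ...)))
}

load_split_scenes <- function(manifest, ids, classes, input_size) {
  lapply(ids, function(id) {
    sc <- load_scene(manifest, id)
    if (!all(sc$image_size == input_size))
      stop(sprintf("scene %s is %dx%d but the model expects %dx%d", id,
                   sc$image_size[1], sc$image_size[2], input_size, input_size))
    sc$boxes <- Filter(function(b) b$class_id %in% classes, sc$boxes)
    sc
  })
}

scene_input <- function(scene) aperm(scene$image, c(3, 1, 2))

flip_scene_h <- function(x, boxes, W) {
  xf <- x[, , dim(x)[3]:1, drop = FALSE]
  bf <- lapply(boxes, function(b)
    bbox(W - b$x2, b$y1, W - b$x1, b$y2, class_id = b$class_id))
  list(x = xf, boxes = bf)
}

#' Train a detector
#'
#' Runs the seeded training loop: per epoch a shuffled pass over the
#' training scenes in minibatches, each step accumulating gradients of the
#' detection loss (objectness/class binary cross-entropy plus the selected
#' box regression loss at assigned cells) and applying one Adam update.
#' Snake offsets are clamped after every step.  A non-finite loss aborts
#' with diagnostics.
#'
#' @param cfg A \code{\link{train_config}}.
#' @param manifest A dataset manifest (path, directory, or list from
#'   \code{\link{read_manifest}}).
#' @param out_dir Optional directory for the checkpoint and run record.
#' @param validate Compute a validation \code{\link{eval_report}} at the end.
#' @param verbose Log per-epoch losses.
#' @return A \code{run_record}: per-epoch losses, validation report,
#'   checkpoint path (when \code{out_dir} given), the model, and a config
#'   snapshot sufficient to re-run identically.
#' @export
train <- function(cfg, manifest, out_dir = NULL, validate = TRUE,
                  verbose = TRUE) {
  stopifnot(inherits(cfg, "train_config"))
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  det_cfg <- detector_config_from_train(cfg)
  model <- build_detector(det_cfg)
  params <- detector_params(model)
  train_sc <- load_split_scenes(manifest, manifest$split$train, cfg$classes,
                                det_cfg$input_size)
  if (!length(train_sc)) stop("empty training split")
  inputs <- lapply(train_sc, scene_input)
  targets <- lapply(train_sc, function(s) assign_targets(s$boxes, det_cfg))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed + 1L)
  n <- length(train_sc)
  losses <- numeric(cfg$epochs)
  step <- 0L
  W <- det_cfg$input_size[2]
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(n)
    ep_loss <- 0
    for (bi in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[bi:min(bi + cfg$batch_size - 1, n)]
      ag_zero_grads(params)
      bw <- 1 / length(idx)
      for (i in idx) {
        x <- inputs[[i]]
        tg <- targets[[i]]
        if (cfg$augment_flips && stats::runif(1) < 0.5) {
          fl <- flip_scene_h(x, train_sc[[i]]$boxes, W)
          x <- fl$x
          tg <- assign_targets(fl$boxes, det_cfg)
        }
        tape <- ag_tape()
        raw <- detector_forward(model, ag_node(tape, x), tape)
        lnode <- detection_loss(model, tape, raw, tg, weight = bw,
                                lambda_box = cfg$lambda_box,
                                lambda_obj = cfg$lambda_obj,
                                lambda_cls = cfg$lambda_cls)
        lval <- ag_val(lnode)
        if (!is.finite(lval))
          stop(sprintf("non-finite loss at epoch %d, scene index %d", ep, i))
        ep_loss <- ep_loss + lval
        ag_backward(tape, lnode)
      }
      step <- step + 1L
      ag_adam_step(params, lr = cfg$learning_rate, t = step)
      detector_clamp_offsets(model)
    }
    losses[ep] <- ep_loss * cfg$batch_size / n
    if (verbose) vb_log("INFO", "epoch %d/%d  loss %.4f", ep, cfg$epochs,
                        losses[ep])
  }
  ckpt <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ckpt <- file.path(out_dir, "checkpoint.rds")
    save_checkpoint(model, ckpt)
  }
  val_report <- NULL
  if (validate && length(manifest$split$val)) {
    val_sc <- load_split_scenes(manifest, manifest$split$val, cfg$classes,
                                det_cfg$input_size)
    val_report <- evaluate(model, val_sc,
                           score_threshold = cfg$score_threshold,
                           nms_iou = cfg$nms_iou)
  }
  rec <- structure(list(losses = losses, val_report = val_report,
                        checkpoint = ckpt, config = cfg, det_cfg = det_cfg,
                        model = model,
                        version = as.character(utils::packageVersion("vbdetect"))),
                   class = "run_record")
  if (!is.null(out_dir))
    saveRDS(rec[setdiff(names(rec), "model")],
            file.path(out_dir, "run_record.rds"))
  rec
}

#' Save / load a detector checkpoint
#'
#' Checkpoints hold the configuration and flat parameter values and are
#' written with \code{saveRDS}.
#'
#' @param model A \code{vb_detector}.
#' @param path Output path (.rds).
#' @export
save_checkpoint <- function(model, path) {
  params <- detector_params(model)
  saveRDS(list(cfg = model$cfg,
               values = lapply(params, function(p) p$value)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_detector(ck$cfg)
  params <- detector_params(model)
  stopifnot(length(params) == length(ck$values))
  for (i in seq_along(params)) params[[i]]$value <- ck$values[[i]]
  model
}

#' Run a detector on one image
#'
#' @param model A \code{vb_detector} (or checkpoint path).
#' @param image \code{H x W x 3} array in \code{[0, 1]}.
#' @param score_threshold,nms_iou Decoding thresholds.
#' @return List of predicted \code{\link{bbox}}.
#' @export
predict_boxes <- function(model, image, score_threshold = 0.25,
                          nms_iou = 0.5) {
  if (is.character(model)) model <- load_checkpoint(model)
  raw <- detector_forward(model, aperm(image, c(3, 1, 2)), tape = NULL)
  decode_predictions(raw, model$cfg$input_size, model$cfg$class_names,
                     score_threshold, nms_iou)
}

#' Evaluate a detector on a set of scenes
#'
#' Runs the forward pass and decoding on every scene, then computes the
#' full \code{\link{eval_report}} (per-class P/R/AP, mAP@.5, mAP@.5:.95,
#' Dice/IoU, count and area MAPE/RMSE).
#'
#' @param model A \code{vb_detector} or checkpoint path.
#' @param scenes List of \code{\link{labeled_scene}} (e.g. a loaded split),
#'   or a manifest plus \code{split} name.
#' @param split When \code{scenes} is a manifest: which split to evaluate.
#' @param score_threshold,nms_iou Decoding thresholds.
#' @return An \code{\link{eval_report}}.
#' @export
evaluate <- function(model, scenes, split = "test", score_threshold = 0.25,
                     nms_iou = 0.5) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (is.character(scenes) || (is.list(scenes) && !is.null(scenes$split))) {
    manifest <- if (is.character(scenes)) read_manifest(scenes) else scenes
    ids <- manifest$split[[split]]
    scenes <- load_split_scenes(manifest, ids, model$cfg$class_names,
                                model$cfg$input_size)
  }
  if (!length(scenes)) stop("empty evaluation split")
  preds <- lapply(scenes, function(sc)
    predict_boxes(model, sc$image, score_threshold, nms_iou))
  gts <- lapply(scenes, function(sc) sc$boxes)
  eval_report(preds, gts, model$cfg$input_size,
              classes = model$cfg$class_names)
}

draw_box_outline <- function(img, b, col = c(1, 0, 0)) {
  H <- dim(img)[1]; W <- dim(img)[2]
  x1 <- max(1L, round(b$x1)); x2 <- min(W, max(x1, round(b$x2)))
  y1 <- max(1L, round(b$y1)); y2 <- min(H, max(y1, round(b$y2)))
  for (ch in 1:3) {
    img[y1:y2, c(x1, x2), ch] <- col[ch]
    img[c(y1, y2), x1:x2, ch] <- col[ch]
  }
  img
}

#' Detect objects in image files
#'
#' Writes, per input image, a LabelMe JSON with the predictions and a PNG
#' overlay with the boxes drawn.  Unreadable images are reported and
#' skipped.
#'
#' @param model A \code{vb_detector} or checkpoint path.
#' @param image_paths Character vector of image files.
#' @param out_dir Output directory.
#' @param score_threshold,nms_iou Decoding thresholds.
#' @return Invisibly, a data frame of per-image outputs with a
#'   \code{status} column; attribute \code{"n_failed"} counts failures.
#' @export
detect <- function(model, image_paths, out_dir, score_threshold = 0.25,
                   nms_iou = 0.5) {
  if (is.character(model)) model <- load_checkpoint(model)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (p in image_paths) {
    res <- tryCatch({
      img <- read_image(p)
      boxes <- predict_boxes(model, img, score_threshold, nms_iou)
      stem <- tools::file_path_sans_ext(basename(p))
      jp <- file.path(out_dir, paste0(stem, "_pred.json"))
      write_labelme(labeled_scene(image = img, image_path = p,
                                  boxes = boxes), jp)
      ov <- img
      for (b in boxes) ov <- draw_box_outline(ov, b)
      op <- file.path(out_dir, paste0(stem, "_overlay.png"))
      write_image(ov, op)
      vb_log("INFO", "%s: %d detections", basename(p), length(boxes))
      list(json = jp, overlay = op, n = length(boxes), status = "ok")
    }, error = function(e) {
      vb_log("ERROR", "%s: %s", p, conditionMessage(e))
      list(json = NA, overlay = NA, n = NA_integer_, status = "error")
    })
    rows[[length(rows) + 1]] <- data.frame(image = p, json = res$json,
                                           overlay = res$overlay, n = res$n,
                                           status = res$status)
  }
  out <- do.call(rbind, rows)
  attr(out, "n_failed") <- sum(out$status == "error")
  invisible(out)
}
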