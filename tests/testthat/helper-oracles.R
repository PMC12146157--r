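# Independent oracles used by the tests.  These deliberately avoid the
# package's own computational paths.

# Plain-R dense convolution, stride 1, zero padding to SAME size.
# x: (C,H,W) array; w: (O,C,kh,kw); b: length O.
dense_conv_oracle <- function(x, w, b = NULL) {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  O <- dim(w)[1]; kh <- dim(w)[3]; kw <- dim(w)[4]
  if (is.null(b)) b <- numeric(O)
  py <- (kh - 1) %/% 2; px <- (kw - 1) %/% 2
  out <- array(0, dim = c(O, H, W))
  for (o in seq_len(O)) for (y in seq_len(H)) for (xc in seq_len(W)) {
    s <- b[o]
    for (ky in seq_len(kh)) for (kx in seq_len(kw)) {
      yi <- y + ky - 1 - py; xi <- xc + kx - 1 - px
      if (yi >= 1 && yi <= H && xi >= 1 && xi <= W)
        s <- s + sum(w[o, , ky, kx] * x[, yi, xi])
    }
    out[o, y, xc] <- s
  }
  out
}

# Exhaustive average-precision oracle: walks every prefix of the
# confidence-ranked prediction list, recomputes TP counts by greedy
# same-rule matching from scratch at each prefix, and integrates the exact
# precision envelope staircase over recall.
ap_staircase_oracle <- function(preds, gts, iou_threshold) {
  if (!length(gts)) return(NA_real_)
  if (!length(preds)) return(0)
  conf <- vapply(preds, function(b) b$confidence, numeric(1))
  ord <- order(-conf, seq_along(preds))
  n <- length(ord)
  prec <- numeric(n); rec <- numeric(n)
  for (k in seq_len(n)) {
    used <- rep(FALSE, length(gts))
    tp <- 0L
    for (i in ord[seq_len(k)]) {
      best <- 0; bj <- 0L
      for (j in seq_along(gts)) {
        if (used[j]) next
        ov <- iou(preds[[i]], gts[[j]])
        if (ov >= iou_threshold && ov > best) { best <- ov; bj <- j }
      }
      if (bj > 0L) { used[bj] <- TRUE; tp <- tp + 1L }
    }
    prec[k] <- tp / k
    rec[k] <- tp / length(gts)
  }
  env <- numeric(n)
  for (k in seq_len(n)) env[k] <- max(prec[k:n])
  ap <- 0
  prev_r <- 0
  for (k in seq_len(n)) {
    ap <- ap + (rec[k] - prev_r) * env[k]
    prev_r <- rec[k]
  }
  ap
}

# Random single-class box within a wxh image.
random_box <- function(W = 100, H = 100, class_id = "small",
                       confidence = NA_real_) {
  x1 <- runif(1, 0, W - 4); y1 <- runif(1, 0, H - 4)
  bbox(x1, y1, x1 + runif(1, 2, W - x1), y1 + runif(1, 2, H - y1),
       class_id = class_id, confidence = confidence)
}

# Random small detection instance for AP oracle tests.
random_instance <- function(max_preds = 6, max_gts = 4, n_classes = 2) {
  classes <- c("small", "big")[seq_len(n_classes)]
  ng <- sample.int(max_gts, 1)
  np <- sample.int(max_preds + 1, 1) - 1L
  gts <- lapply(seq_len(ng), function(i)
    random_box(class_id = sample(classes, 1)))
  preds <- lapply(seq_len(np), function(i) {
    if (runif(1) < 0.6 && ng > 0) {
      g <- gts[[sample.int(ng, 1)]]
      j <- runif(4, -8, 8)
      x1 <- min(g$x1 + j[1], g$x2 - 1); y1 <- min(g$y1 + j[2], g$y2 - 1)
      bbox(x1, y1, max(g$x2 + j[3], x1 + 1), max(g$y2 + j[4], y1 + 1),
           class_id = g$class_id, confidence = runif(1))
    } else random_box(class_id = sample(classes, 1), confidence = runif(1))
  })
  list(preds = preds, gts = gts)
}

tiny_easy_dataset <- function(dir, n = 20, image_size = 64, seed = 100) {
  cfg <- scene_preset("easy", image_size = image_size, seed = seed)
  write_dataset(n, cfg, dir, difficulty = "easy")
  read_manifest(dir)
}
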