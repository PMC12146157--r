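tiny_cfg <- function(...) {
  detector_config(input_size = 64, num_classes = 1, class_names = "small",
                  preset = "tiny", seed = 5, ...)
}

test_that("head grids equal input size over stride", {
  m <- build_detector(tiny_cfg())
  raw <- vbdetect:::detector_forward(m, array(0.1, c(3, 64, 64)))
  expect_equal(raw$strides, c(4L, 8L, 16L, 32L))
  for (k in seq_along(raw$heads))
    expect_equal(dim(raw$heads[[k]])[2:3], c(64, 64) / raw$strides[k])
  # 640 input: grids 160/80/40/20 (by the same arithmetic, not run)
  cfg640 <- detector_config(input_size = 640, preset = "tiny")
  expect_equal(640 / vbdetect:::head_strides(cfg640), c(160, 80, 40, 20))
  expect_error(detector_config(input_size = 100), "divisible by 32")
})

test_that("all eight ablation flag combinations build and run", {
  grid <- expand.grid(ds = c(FALSE, TRUE), mff = c(FALSE, TRUE),
                      piou = c(FALSE, TRUE))
  x <- array(0.1, c(3, 64, 64))
  for (i in seq_len(nrow(grid))) {
    cfg <- tiny_cfg(use_dsconv = grid$ds[i], use_mff = grid$mff[i],
                    loss = if (grid$piou[i]) "piou" else "ciou")
    m <- build_detector(cfg)
    raw <- vbdetect:::detector_forward(m, x)
    expect_equal(length(raw$heads), if (grid$mff[i]) 4L else 3L)
  }
})

test_that("the fusion neck adds parameters and a fourth stride-4 head", {
  m_on <- build_detector(tiny_cfg(use_mff = TRUE))
  m_off <- build_detector(tiny_cfg(use_mff = FALSE))
  expect_gt(n_params(m_on), n_params(m_off))
  expect_equal(length(m_on$heads) - length(m_off$heads), 1L)
  expect_equal(setdiff(m_on$strides, m_off$strides), 4L)
  # baseline topology: stride set and node count match the 3-head design
  expect_setequal(m_off$strides, c(8L, 16L, 32L))
  expect_equal(sum(grepl("^head", m_off$graph$name)), 3L)
  expect_false("F2" %in% m_off$graph$name)
  expect_true(all(c("F2", "T2", "T4", "T5") %in% m_on$graph$name))
})

test_that("upsample-fuse concatenates in the documented order", {
  deep <- feature_map(array(7, c(2, 4, 4)), stride = 8L)
  shallow <- feature_map(array(3, c(3, 8, 8)), stride = 4L)
  out <- upsample_fuse(deep, shallow)
  expect_equal(dim(out$values), c(5, 8, 8))
  expect_equal(out$stride, 4L)
  # provenance probe: first channels carry the upsampled deep values
  expect_true(all(out$values[1:2, , ] == 7))
  expect_true(all(out$values[3:5, , ] == 3))
  expect_error(upsample_fuse(shallow, deep), "stride mismatch")
})

test_that("downsample-fuse halves resolution and fuses with the lateral map", {
  set.seed(41)
  cur <- feature_map(array(rnorm(2 * 8 * 8), c(2, 8, 8)), stride = 4L)
  lat <- feature_map(array(rnorm(3 * 4 * 4), c(3, 4, 4)), stride = 8L)
  dl <- vbdetect:::new_conv_layer(2, 2, k = 3, stride = 2, mode = "dense")
  out <- downsample_fuse(cur, lat, dl)
  expect_equal(dim(out$values), c(5, 4, 4))
  expect_equal(out$stride, 8L)
  # lateral channels pass through unchanged under concat fusion
  expect_equal(out$values[3:5, , ], lat$values)
  out_add <- downsample_fuse(cur, lat, vbdetect:::new_conv_layer(
    2, 3, k = 3, stride = 2, mode = "dense"), fusion = "add")
  expect_equal(dim(out_add$values), c(3, 4, 4))
  expect_error(downsample_fuse(lat, cur, dl), "stride mismatch")
})

test_that("decoded predictions respect box invariants, thresholds and NMS", {
  cfg <- tiny_cfg()
  set.seed(42)
  raw <- list(heads = lapply(c(4, 8, 16, 32), function(s)
    array(rnorm(6 * 64 / s * 64 / s), c(6, 64 / s, 64 / s))),
    strides = c(4L, 8L, 16L, 32L))
  # impossible threshold: empty result
  expect_equal(decode_predictions(raw, c(64, 64), "small",
                                  score_threshold = 0.999999), list())
  boxes <- decode_predictions(raw, c(64, 64), "small",
                              score_threshold = 0.3, nms_iou = 0.5)
  for (b in boxes) {
    expect_gt(b$x2, b$x1); expect_gt(b$y2, b$y1)
    expect_gte(b$x1, 0); expect_gte(b$y1, 0)
    expect_lte(b$x2, 64); expect_lte(b$y2, 64)
    expect_gte(b$confidence, 0.3)
  }
  # sorted by confidence descending
  confs <- vapply(boxes, function(b) b$confidence, numeric(1))
  expect_true(all(diff(confs) <= 0))
  # NMS keeps one of two identical same-class boxes
  raw1 <- list(heads = list(array(-20, c(6, 16, 16))), strides = 4L)
  raw1$heads[[1]][, 4, 4] <- c(0, 0, 0, 0, 8, 8)
  raw1$heads[[1]][, 4, 5] <- c(-4.5, 0, 0, 0, 8, 8)  # near-identical neighbor
  kept <- decode_predictions(raw1, c(64, 64), "small", 0.25, 0.5)
  expect_equal(length(kept), 1L)
  expect_error(decode_predictions(raw1, c(64, 64), "small", 1.5, 0.5),
               "thresholds")
})

test_that("target assignment routes boxes by scale and reaches the stride-4 head", {
  cfg <- detector_config(input_size = 640, num_classes = 4, preset = "tiny")
  # large centered box -> deepest (stride 32) head
  tg <- assign_targets(list(bbox(170, 170, 470, 470, "out")), cfg)
  expect_equal(vapply(tg, nrow, integer(1))[4] > 0, TRUE)
  expect_equal(sum(vapply(tg, nrow, integer(1))[1:3]), 0L)
  # 6x6-pixel box -> stride-4 head
  tg2 <- assign_targets(list(bbox(100, 100, 106, 106, "small")), cfg)
  expect_gt(nrow(tg2[[1]]), 0)
  expect_equal(sum(vapply(tg2[-1], nrow, integer(1))), 0L)
  # every gt lands on at least one cell of one head
  set.seed(43)
  for (i in 1:20) {
    gt <- lapply(1:5, function(j) random_box(640, 640, class_id = "small"))
    tg3 <- assign_targets(gt, cfg)
    expect_gte(sum(vapply(tg3, nrow, integer(1))), length(gt))
  }
  # zero gt: all-background targets, loss stays finite
  tg0 <- assign_targets(list(), cfg)
  expect_equal(sum(vapply(tg0, nrow, integer(1))), 0L)
  m <- build_detector(tiny_cfg())
  raw <- vbdetect:::detector_forward(m, array(0.1, c(3, 64, 64)))
  l0 <- vbdetect:::detection_loss(m, NULL, raw,
                                  assign_targets(list(), m$cfg))
  expect_true(is.finite(l0))
  expect_warning(assign_targets(list(bbox(700, 700, 720, 720, "small")), cfg),
                 "outside")
})

test_that("one seeded optimization step decreases the loss for both box losses", {
  set.seed(44)
  x <- array(runif(3 * 64 * 64), c(3, 64, 64))
  gt <- list(bbox(12, 10, 22, 20, "small"), bbox(40, 36, 52, 50, "small"))
  for (loss in c("piou", "ciou")) {
    cfg <- tiny_cfg(loss = loss)
    m <- build_detector(cfg)
    params <- vbdetect:::detector_params(m)
    tg <- assign_targets(gt, cfg)
    step_loss <- function() {
      tape <- vbdetect:::ag_tape()
      raw <- vbdetect:::detector_forward(m, vbdetect:::ag_node(tape, x), tape)
      ln <- vbdetect:::detection_loss(m, tape, raw, tg)
      list(tape = tape, node = ln, val = vbdetect:::ag_val(ln))
    }
    s1 <- step_loss()
    vbdetect:::ag_zero_grads(params)
    vbdetect:::ag_backward(s1$tape, s1$node)
    vbdetect:::ag_adam_step(params, lr = 1e-3, t = 1)
    s2 <- step_loss()
    expect_lt(s2$val, s1$val)
  }
})

test_that("checkpoints round-trip through save and load", {
  m <- build_detector(tiny_cfg())
  x <- array(runif(3 * 64 * 64), c(3, 64, 64))
  r1 <- vbdetect:::detector_forward(m, x)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  r2 <- vbdetect:::detector_forward(m2, x)
  for (k in seq_along(r1$heads))
    expect_equal(r1$heads[[k]], r2$heads[[k]])
})
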