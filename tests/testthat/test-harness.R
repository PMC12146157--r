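make_tiny_run <- function(dir, n = 12, epochs = 2, loss = "piou", seed = 1,
                          ...) {
  man <- tiny_easy_dataset(dir, n = n, image_size = 64, seed = 200)
  cfg <- train_config(epochs = epochs, learning_rate = 1e-3, batch_size = 4,
                      input_size = 64, loss = loss, classes = "small",
                      preset = "tiny", seed = seed, ...)
  train(cfg, man, validate = FALSE, verbose = FALSE)
}

test_that("the training loop reduces the loss on a tiny smoke run", {
  dir <- withr::local_tempdir()
  rec <- make_tiny_run(dir, epochs = 4)
  expect_equal(length(rec$losses), 4L)
  expect_true(all(is.finite(rec$losses)))
  expect_lt(rec$losses[4], rec$losses[1])
})

test_that("training is bit-reproducible under a fixed seed on CPU", {
  dir <- withr::local_tempdir()
  r1 <- make_tiny_run(dir, epochs = 1, seed = 3)
  r2 <- make_tiny_run(dir, epochs = 1, seed = 3)
  expect_identical(r1$losses, r2$losses)
  p1 <- vbdetect:::detector_params(r1$model)
  p2 <- vbdetect:::detector_params(r2$model)
  for (i in seq_along(p1)) expect_identical(p1[[i]]$value, p2[[i]]$value)
  r3 <- make_tiny_run(dir, epochs = 1, seed = 4)
  expect_false(identical(r1$losses, r3$losses))
})

test_that("every ablation flag combination trains for one epoch", {
  dir <- withr::local_tempdir()
  man <- tiny_easy_dataset(dir, n = 8, image_size = 64, seed = 210)
  grid <- expand.grid(ds = c(FALSE, TRUE), mff = c(FALSE, TRUE),
                      piou = c(FALSE, TRUE))
  for (i in seq_len(nrow(grid))) {
    cfg <- train_config(epochs = 1, learning_rate = 1e-3, batch_size = 4,
                        input_size = 64,
                        loss = if (grid$piou[i]) "piou" else "ciou",
                        use_dsconv = grid$ds[i], use_mff = grid$mff[i],
                        classes = "small", preset = "tiny", seed = 1)
    rec <- train(cfg, man, validate = FALSE, verbose = FALSE)
    expect_true(is.finite(rec$losses[1]))
  }
})

test_that("evaluating ground truth injected as predictions is perfect", {
  dir <- withr::local_tempdir()
  man <- tiny_easy_dataset(dir, n = 6, image_size = 64, seed = 220)
  scenes <- vbdetect:::load_split_scenes(man, man$split$train,
                                         c("small", "in", "out"), c(64, 64))
  gts <- lapply(scenes, function(s) s$boxes)
  preds <- lapply(gts, function(g) lapply(g, function(b)
    bbox(b$x1, b$y1, b$x2, b$y2, class_id = b$class_id, confidence = 1)))
  rep <- eval_report(preds, gts, c(64, 64))
  expect_equal(rep$map50, 1.0)
  expect_equal(rep$map5095, 1.0)
  expect_gte(rep$map50, rep$map5095)
  expect_equal(rep$dice, 1.0)
  expect_equal(rep$iou, 1.0)
  expect_equal(rep$count_mape, 0)
  expect_equal(rep$count_rmse, 0)
  expect_equal(rep$area_rmse, 0)
  # all present classes reported
  expect_setequal(names(rep$per_class), c("small", "in", "out"))
})

test_that("evaluate errors on an empty split", {
  dir <- withr::local_tempdir()
  rec <- make_tiny_run(dir, epochs = 1)
  expect_error(evaluate(rec$model, list()), "empty")
})

test_that("detect writes re-readable annotations and overlays", {
  dir <- withr::local_tempdir()
  rec <- make_tiny_run(dir, epochs = 1)
  # blank image: valid empty-ish prediction set, json still readable
  blank <- file.path(dir, "blank.png")
  write_image(array(0, c(64, 64, 3)), blank)
  outd <- file.path(dir, "out")
  res <- suppressMessages(detect(rec$model, blank, outd,
                                 score_threshold = 0.9))
  expect_equal(attr(res, "n_failed"), 0L)
  sc <- suppressWarnings(read_labelme(res$json[1]))
  expect_true(length(sc$boxes) >= 0)
  expect_true(file.exists(res$overlay[1]))
  # unreadable image: per-file error, nonzero failure count, continues
  res2 <- suppressMessages(detect(rec$model,
                                  c(file.path(dir, "nope.png"), blank), outd))
  expect_equal(attr(res2, "n_failed"), 1L)
  expect_equal(res2$status, c("error", "ok"))
})

test_that("a smoke-trained model finds an easy bundle at IoU 0.5", {
  dir <- withr::local_tempdir()
  rec <- make_tiny_run(dir, n = 24, epochs = 15)
  man <- read_manifest(file.path(dir, "manifest.yaml"))
  sc <- vbdetect:::load_split_scenes(man, man$split$val, "small", c(64, 64))[[1]]
  preds <- predict_boxes(rec$model, sc$image, score_threshold = 0.1)
  hit <- any(vapply(preds, function(p)
    any(vapply(sc$boxes, function(g) iou(p, g) >= 0.5, logical(1))),
    logical(1)))
  expect_true(hit)
})

test_that("train config validates and loads from yaml", {
  expect_error(train_config(epochs = 0), "positive")
  expect_error(train_config(device = "gpu"), "cpu")
  dir <- withr::local_tempdir()
  yp <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(list(epochs = 3, learning_rate = 0.005, batch_size = 2,
                        input_size = 64, loss = "ciou", classes = "small",
                        preset = "tiny",
                        piou = list(lambda = 1.1, penalty_mode = "corner",
                                    loss_form = "corrected")), yp)
  cfg <- train_config_from_yaml(yp)
  expect_equal(cfg$epochs, 3L)
  expect_equal(cfg$loss, "ciou")
  expect_equal(cfg$piou$lambda, 1.1)
})

test_that("the command-line interface dispatches and reports errors", {
  dir <- withr::local_tempdir()
  st <- suppressMessages(vbdetect_cli(c("generate", "--out",
                                        file.path(dir, "ds"), "--n", "4",
                                        "--size", "64",
                                        "--difficulty", "easy")))
  expect_equal(st, 0L)
  expect_true(file.exists(file.path(dir, "ds", "manifest.yaml")))
  expect_equal(suppressMessages(vbdetect_cli(c("evaluate"))), 1L)
  expect_output(vbdetect_cli(character(0)), "usage")
})
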