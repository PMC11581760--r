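# A single tiny ensemble, memorising one case, is shared by the tests in
# this file; real generalisation performance is covered by the
# acceptance suite.
memo_case <- tiny_case("hand", noise_sd = 3, image_size = 64, seed = 50)
memo_ens <- train_task(
  seg_task("hand_subregions"),
  train_cases = rep(list(memo_case), 4),
  val_cases = list(memo_case),
  config = train_config(epochs = 45, members = 2, input_size = 64,
                        lr = 1e-2, batch = 1, seed = 6))

test_that("task definitions carry the annotation scheme's class structure", {
  expect_gte(length(seg_task("hand_subregions")$classes), 4)
  expect_gte(length(seg_task("hand_whole")$classes), 2)
  expect_identical(seg_task("hand_whole")$phases, 1:2)
  expect_identical(seg_task("foot_whole")$phases, 1:3)
  expect_error(seg_task("leg"), "arg")
})

test_that("training on copies of one case memorises it (validation Dice near 1)", {
  best <- max(memo_ens$logs[[1]]$val_dice)
  expect_gt(best, 0.8)
  expect_true(all(is.finite(memo_ens$logs[[1]]$loss)))
})

test_that("member replicas differ by their seed-derived initialisation", {
  checksum <- function(p) sum(vapply(p, function(l) sum(l$W), numeric(1)))
  expect_false(isTRUE(all.equal(checksum(memo_ens$members[[1]]),
                                checksum(memo_ens$members[[2]]))))
})

test_that("predictions are deterministic, legally labelled, and confidence-bounded", {
  a <- predict_image(memo_ens, memo_case$images[[3]])
  b <- predict_image(memo_ens, memo_case$images[[3]])
  expect_identical(a$classes, b$classes)
  expect_identical(a$uncertainty, b$uncertainty)
  expect_true(all(a$classes %in% seq_along(memo_ens$task$classes)))
  expect_true(all(a$confidence >= 0 & a$confidence <= 1))
  expect_gte(a$uncertainty, 0)
  expect_lte(a$uncertainty, log(memo_ens$n_class))
  expect_setequal(a$mask$legend$region, c("carpal", "mcp", "pip"))
})

test_that("phase/task mismatch is a usage error", {
  expect_error(predict_image(memo_ens, memo_case$images[[1]]),
               "usage error: phase 1")
})

test_that("side assignment splits predicted components at the vertical midline", {
  pred <- predict_image(memo_ens, memo_case$images[[3]])
  W <- ncol(pred$mask$labels)
  left_labels <- pred$mask$legend$label[pred$mask$legend$side == "left"]
  lab_left <- pred$mask$labels[, seq_len(W %/% 2)]
  expect_true(all(lab_left[lab_left != 0] %in% left_labels))
})

test_that("the calibration threshold follows the linear-interpolation percentile rule", {
  expect_equal(tpbsquant:::uncertainty_threshold_from(1:100, 95), 95.05)
  expect_equal(tpbsquant:::uncertainty_threshold_from(rep(0.3, 10), 95), 0.3)
  # flagged fraction after calibration is bounded by 5% + 1/n
  set.seed(33)
  for (i in 1:20) {
    u <- rexp(sample(5:60, 1))
    thr <- tpbsquant:::uncertainty_threshold_from(u, 95)
    expect_lte(mean(u > thr), 0.05 + 1 / length(u))
  }
})

test_that("calibrated ensembles flag inputs against the stored threshold", {
  ens <- calibrate_uncertainty(memo_ens, rep(list(memo_case), 3))
  expect_true(is.finite(ens$uncertainty_threshold))
  pred <- predict_image(ens, memo_case$images[[3]])
  expect_identical(pred$ood_flag, pred$uncertainty > ens$uncertainty_threshold)
  expect_error(calibrate_uncertainty(memo_ens, list()), "at least 3")
})

test_that("an exhausting active-learning budget labels the whole pool", {
  pool <- lapply(51:52, function(s)
    tiny_case("hand", noise_sd = 3, image_size = 64, seed = s))
  n_before <- length(memo_ens$train_cases)
  res <- active_learning_round(memo_ens, pool, budget = 10, epochs = 1)
  expect_true(all(res$audit$selected))
  expect_true(all(res$audit$labelled))
  expect_length(res$ensemble$train_cases, n_before + 2)
  expect_true(is.finite(res$pre_val_dice) && is.finite(res$post_val_dice))
})

test_that("oracle failures are recorded and skipped, not fatal", {
  pool <- list(tiny_case("hand", noise_sd = 3, image_size = 64, seed = 53))
  failing <- function(case) stop("annotator unavailable")
  expect_warning(
    res <- active_learning_round(memo_ens, pool, oracle = failing,
                                 budget = 1, epochs = 1),
    "oracle failed")
  expect_false(any(res$audit$labelled))
  expect_length(res$ensemble$train_cases, length(memo_ens$train_cases))
})

test_that("ensemble checkpoints round-trip through disk", {
  path <- withr::local_tempfile(fileext = ".rds")
  save_ensemble(memo_ens, path)
  back <- load_ensemble(path)
  expect_identical(back$members, memo_ens$members)
  expect_identical(back$task$name, "hand_subregions")
  a <- predict_image(back, memo_case$images[[3]])
  b <- predict_image(memo_ens, memo_case$images[[3]])
  expect_identical(a$classes, b$classes)
})

test_that("masks collapse to side-agnostic task classes correctly", {
  task <- seg_task("hand_subregions")
  cls <- mask_to_classes(task, memo_case$masks[[3]])
  expect_setequal(unique(as.vector(cls)), 1:4)
  # left and right MCP both collapse to the same class
  m <- memo_case$masks[[3]]
  for (side in c("left", "right")) {
    lab <- tpbsquant:::mask_label(m, "mcp", side)
    expect_true(all(cls[m$labels == lab] == match("mcp", task$classes)))
  }
})
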