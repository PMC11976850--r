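# Model inputs, label rasterization, weighted IoU, segmentation and
# scoring training behaviour, and the AUC metric.

test_that("model inputs scale channels and place hints correctly", {
  img <- precursor_image(matrix(0, 5, 4), seq(10, 10.4, length.out = 5),
                         seq(0.90, 0.93, length.out = 4))
  inp <- build_model_input(img, c(10.2, 0.915), size = 32)
  expect_equal(dim(inp$channels$activation), c(32, 32))
  expect_true(all(inp$channels$activation == 0))  # constant image rule
  expect_true(all(inp$channels$log_activation == 0))
  expect_equal(sum(inp$channels$hint == 1), 1)
  expect_equal(sum(inp$channels$hint != 0), 1)

  # target and competitor on the same pixel cancel to 0
  inp2 <- build_model_input(img, c(10.2, 0.915),
                            competitor_hints = rbind(c(10.2, 0.915)),
                            size = 32)
  expect_true(all(inp2$channels$hint == 0))

  # out-of-crop hints clip to the border and are counted
  inp3 <- build_model_input(img, c(99, 0.915), size = 32)
  expect_equal(inp3$target_pixel[1], 32L)
  expect_gte(inp3$n_clipped, 1)

  # non-constant channels live in [0, 1]
  set.seed(4)
  img2 <- precursor_image(matrix(abs(rnorm(20)), 5, 4),
                          img$rt_coords, img$im_coords)
  inp4 <- build_model_input(img2, c(10.2, 0.915), size = 32)
  expect_true(all(inp4$channels$activation >= 0 &
                    inp4$channels$activation <= 1))
  expect_equal(range(inp4$channels$activation), c(0, 1))
})

test_that("label rectangles rasterize by pixel-center membership", {
  img <- precursor_image(matrix(1, 10, 8), seq(0, 1, length.out = 10),
                         seq(0.9, 1.0, length.out = 8))
  inp <- build_model_input(img, c(0.5, 0.95), size = 258)
  full <- rasterize_label(list(rt_start = -1, rt_end = 2, im_lo = 0.8,
                               im_hi = 1.1), inp)
  expect_true(all(full == 1))

  rt_mid <- mean(inp$rt_extent)
  half <- rasterize_label(list(rt_start = inp$rt_extent[1], rt_end = rt_mid,
                               im_lo = 0.8, im_hi = 1.1), inp)
  expect_lt(abs(mean(half) - 0.5), 1 / 258)

  expect_warning(
    none <- rasterize_label(list(rt_start = 5, rt_end = 6, im_lo = 0.8,
                                 im_hi = 1.1), inp),
    "does not intersect")
  expect_true(all(none == 0))
})

test_that("weighted IoU matches its definition and the printed bound", {
  I <- matrix(1, 10, 10)
  a <- matrix(0, 10, 10); a[2:9, 2:9] <- 1
  expect_equal(weighted_iou(a, a, I), 1.0)
  b <- matrix(0, 10, 10); b[1, 1] <- 1
  expect_equal(weighted_iou(a, b, I), 0.0)

  # nested masks, uniform intensity, prediction covers 80% of the truth
  truth <- matrix(0, 10, 10); truth[1:10, 1:10] <- 1
  pred <- matrix(0, 10, 10); pred[1:8, 1:10] <- 1
  expect_equal(weighted_iou(pred, truth, I), 0.8)
  ratio <- sum(I[pred == 1]) / sum(I[truth == 1])
  expect_equal(abs(log2(ratio)), 0.32, tolerance = 0.01)

  # symmetry, boundedness, zero-intensity union
  set.seed(11)
  for (i in 1:10) {
    m1 <- matrix(rbinom(100, 1, 0.4), 10)
    m2 <- matrix(rbinom(100, 1, 0.4), 10)
    W <- matrix(abs(rnorm(100)), 10)
    v <- weighted_iou(m1, m2, W)
    expect_equal(v, weighted_iou(m2, m1, W))
    expect_true(v >= 0 && v <= 1)
  }
  expect_equal(weighted_iou(a, b, matrix(0, 10, 10)), 0)
  expect_error(weighted_iou(a, matrix(1, 3, 3), I), "shape")
})

test_that("mask back-projection preserves axis-aligned rectangles", {
  img <- precursor_image(matrix(1, 20, 16), seq(0, 1, length.out = 20),
                         seq(0.9, 1.0, length.out = 16))
  inp <- build_model_input(img, c(0.5, 0.95), size = 64)
  rect <- list(rt_start = 0.22, rt_end = 0.71, im_lo = 0.92, im_hi = 0.97)
  mask <- rasterize_label(rect, inp)
  native <- project_mask_to_native(mask, img)
  # oracle: native pixel centers inside the rectangle
  rc <- img$rt_coords; ic <- img$im_coords
  oracle <- outer(rc >= rect$rt_start & rc <= rect$rt_end,
                  ic >= rect$im_lo & ic <= rect$im_hi) * 1
  expect_gte(mean(native == oracle), 0.95)
})

test_that("a perfect prediction has near-zero combo loss and training is deterministic", {
  pool <- make_peak_pool(14, size = 32, seed = 2)
  pool <- lapply(pool, function(p) p[c("input", "label")])
  y <- as.vector(pool[[1]]$label)
  perfect_logits <- ifelse(y == 1, 30, -30)
  loss <- ms1prop:::combo_loss(perfect_logits, y)$loss
  expect_lt(loss, 1e-3)

  cfg <- ms1prop_config(epochs = 3, image_size = 32)
  m1 <- train_segmentation(pool, cfg, seed = 99)
  m2 <- train_segmentation(pool, cfg, seed = 99)
  expect_equal(m1$report$loss_curve, m2$report$loss_curve)
  expect_equal(m1$layers, m2$layers)
  expect_error(train_segmentation(pool[1:5], cfg), ">= 10")
})

test_that("the segmentation model can overfit separable fixtures", {
  pool <- make_peak_pool(12, size = 48, seed = 7, decoy_fraction = 0)
  train_items <- lapply(pool[1:8], function(p) p[c("input", "label")])
  # pad the pool to satisfy the minimum size; fit is judged on the 8
  items <- c(train_items,
             lapply(pool[9:12], function(p) p[c("input", "label")]))
  cfg <- ms1prop_config(epochs = 100, patience = 100, image_size = 48)
  model <- train_segmentation(items, cfg,
                              split = list(train = 1:8, validation = 9:10,
                                           test = 11:12))
  ious <- vapply(1:8, function(i) {
    pred <- predict_mask_and_intensity(model, pool[[i]]$input,
                                       pool[[i]]$image)
    I_native <- pool[[i]]$image$values
    truth <- rasterize_label(pool[[i]]$rect, pool[[i]]$input)
    weighted_iou(pred$mask, truth,
                 ms1prop:::resize_bilinear(I_native, 48))
  }, numeric(1))
  expect_gte(median(ious), 0.9)
})

test_that("probability maps threshold idempotently and masks only remove signal", {
  pool <- make_peak_pool(12, size = 32, seed = 5)
  items <- lapply(pool, function(p) p[c("input", "label")])
  cfg <- ms1prop_config(epochs = 5, image_size = 32)
  model <- train_segmentation(items, cfg)
  pr <- predict_seg_prob(model, pool[[1]]$input)
  expect_true(all(pr >= 0 & pr <= 1))
  mask <- (pr >= 0.5) * 1
  expect_equal(((mask >= 0.5) * 1), mask)  # idempotent re-threshold
  res <- predict_mask_and_intensity(model, pool[[1]]$input, pool[[1]]$image)
  expect_lte(res$intensity, naive_intensity(pool[[1]]$image) + 1e-9)
  # all-on and all-off masks bound the intensity
  img <- pool[[1]]$image
  expect_equal(sum(img$values[matrix(TRUE, nrow(img$values),
                                     ncol(img$values))]),
               naive_intensity(img))
})

test_that("the scorer separates targets from decoys and is seed-stable", {
  pool <- make_peak_pool(120, size = 32, seed = 13)
  cfg <- ms1prop_config(epochs = 40, image_size = 32)
  items <- lapply(pool, function(p) {
    # stand-in segmentation channel: smoothed activation
    seg <- ms1prop:::box_blur(p$input$channels$activation, 2)
    list(input = with_segmentation_channel(p$input, seg),
         label = as.numeric(!p$is_decoy))
  })
  split <- ms1prop:::split_pool(length(items), c(0.8, 0.1, 0.1), 42)
  model <- train_scorer(items, cfg, split = split, seed = 3)
  scores <- vapply(items[split$test], function(it) {
    predict_confidence(model, it$input)
  }, numeric(1))
  labels <- vapply(items[split$test], `[[`, numeric(1), "label")
  expect_gte(evaluate_scorer(scores, labels), 0.9)
  expect_true(all(scores >= 0 & scores <= 1))

  model2 <- train_scorer(items, cfg, split = split, seed = 3)
  scores2 <- vapply(items[split$test], function(it) {
    predict_confidence(model2, it$input)
  }, numeric(1))
  expect_equal(scores, scores2)

  one_class <- lapply(items[1:20], function(it) {
    it$label <- 1
    it
  })
  expect_error(train_scorer(one_class, cfg), "both classes")
})

test_that("random labels give chance-level AUC", {
  pool <- make_peak_pool(100, size = 32, seed = 31)
  cfg <- ms1prop_config(epochs = 15, image_size = 32)
  set.seed(17)
  items <- lapply(pool, function(p) {
    seg <- ms1prop:::box_blur(p$input$channels$activation, 2)
    list(input = with_segmentation_channel(p$input, seg),
         label = rbinom(1, 1, 0.5))
  })
  labels <- vapply(items, `[[`, numeric(1), "label")
  if (length(unique(labels)) < 2) labels[1] <- 1 - labels[1]
  split <- ms1prop:::split_pool(length(items), c(0.6, 0.2, 0.2), 7)
  model <- train_scorer(items, cfg, split = split, seed = 5)
  test_idx <- split$test
  if (length(unique(labels[test_idx])) < 2) test_idx <- c(split$validation,
                                                          split$test)
  scores <- vapply(items[test_idx], function(it) {
    predict_confidence(model, it$input)
  }, numeric(1))
  auc <- evaluate_scorer(scores, labels[test_idx])
  expect_gte(auc, 0.25)
  expect_lte(auc, 0.75)
})

test_that("rank AUC matches the pairwise brute-force oracle and pROC", {
  set.seed(23)
  scores <- round(runif(50), 2)  # duplicates induce ties
  labels <- rbinom(50, 1, 0.5)
  labels[1:2] <- c(0, 1)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  brute <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(evaluate_scorer(scores, labels), brute)
  expect_equal(evaluate_scorer(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE,
                                              direction = "<"))))
  expect_equal(evaluate_scorer(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1.0)
  expect_error(evaluate_scorer(1:3, c(1, 1, 1)), "both classes")
})
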