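# Peak-selection segmentation and confidence scoring.
#
# Both models consume the standardized multi-channel model input built
# from a precursor activation image. The segmentation model is a pixelwise
# multilayer perceptron over multiscale contextual features (activation,
# log-activation, box-averaged context, hint-window indicators and
# normalized offsets from the positive hint); the scorer summarises the
# four channels into image-level features feeding a small network with a
# logistic head. Training uses Adam with a one-cycle schedule, seeded
# 8:1:1 splits, early stopping, and the combo (BCE + dice + focal) loss
# for segmentation / BCE-with-logits for scoring.

coord_extent <- function(coords) {
  if (length(coords) == 1) return(c(coords - 0.5, coords + 0.5))
  steps <- diff(coords)
  c(coords[1] - steps[1] / 2, coords[length(coords)] + steps[length(steps)] / 2)
}

# physical coordinate -> resized pixel index; returns index and clipped flag
coord_to_pixel <- function(x, extent, size) {
  frac <- (x - extent[1]) / (extent[2] - extent[1])
  clipped <- frac < 0 | frac > 1
  idx <- pmin(pmax(ceiling(frac * size), 1L), size)
  list(idx = as.integer(idx), clipped = clipped)
}

#' Build the multi-channel model input for one precursor image
#'
#' Channel 1 is the min-max-scaled activation, channel 2 the min-max-scaled
#' `log10(activation + eps)`, both bilinearly resized to
#' `size x size` (a constant image scales to all zeros). Channel 3 is the
#' hint channel: +1 added at the target's predicted (RT, 1/K0) pixel and -1
#' at each isobaric competitor's predicted pixel (values sum when hints
#' coincide). Hints outside the crop are clipped to the border pixel and
#' counted. An optional channel 4 carries the segmentation output for the
#' scoring model.
#'
#' @param image `precursor_image`.
#' @param target_hint numeric `c(rt, im)` predicted coordinates of the
#'   target.
#' @param competitor_hints optional 2-column matrix (rt, im) of isobaric
#'   competitors' predicted coordinates.
#' @param seg_output optional `size x size` segmentation probability map.
#' @param size output side length. Default 258.
#' @param log_eps value added before log10. Default 1.
#' @return object of class `model_input`.
#' @export
build_model_input <- function(image, target_hint, competitor_hints = NULL,
                              seg_output = NULL, size = 258, log_eps = 1) {
  vals <- image$values
  ch1 <- minmax_scale(resize_bilinear(vals, size))
  ch2 <- minmax_scale(resize_bilinear(log10(vals + log_eps), size))
  rt_extent <- coord_extent(image$rt_coords)
  im_extent <- coord_extent(image$im_coords)
  hint <- matrix(0, size, size)
  tp_r <- coord_to_pixel(target_hint[1], rt_extent, size)
  tp_c <- coord_to_pixel(target_hint[2], im_extent, size)
  hint[tp_r$idx, tp_c$idx] <- hint[tp_r$idx, tp_c$idx] + 1
  n_clipped <- sum(tp_r$clipped, tp_c$clipped)
  comp_px <- NULL
  if (!is.null(competitor_hints) && NROW(competitor_hints) > 0) {
    competitor_hints <- matrix(competitor_hints, ncol = 2)
    cp_r <- coord_to_pixel(competitor_hints[, 1], rt_extent, size)
    cp_c <- coord_to_pixel(competitor_hints[, 2], im_extent, size)
    for (i in seq_len(nrow(competitor_hints))) {
      hint[cp_r$idx[i], cp_c$idx[i]] <- hint[cp_r$idx[i], cp_c$idx[i]] - 1
    }
    n_clipped <- n_clipped + sum(cp_r$clipped | cp_c$clipped)
    comp_px <- cbind(cp_r$idx, cp_c$idx)
  }
  channels <- list(activation = ch1, log_activation = ch2, hint = hint)
  if (!is.null(seg_output)) channels$segmentation <- seg_output
  structure(list(channels = channels, size = size,
                 rt_coords = image$rt_coords, im_coords = image$im_coords,
                 rt_extent = rt_extent, im_extent = im_extent,
                 target_pixel = c(tp_r$idx, tp_c$idx),
                 competitor_pixels = comp_px,
                 n_clipped = n_clipped,
                 candidate_id = image$candidate_id),
            class = "model_input")
}

#' Attach a segmentation output channel to a model input
#'
#' @param input `model_input`.
#' @param seg_output `size x size` probability map.
#' @return the input with channel 4 set.
#' @export
with_segmentation_channel <- function(input, seg_output) {
  stopifnot(all(dim(seg_output) == input$size))
  input$channels$segmentation <- seg_output
  input
}

#' Rasterize a label rectangle onto the model grid
#'
#' A pixel is labelled 1 iff its (RT, 1/K0) center lies inside the
#' rectangle; the mask is rendered directly on the `size x size` grid
#' through the crop's coordinate transform, never resampled.
#'
#' @param rect list/vector with `rt_start`, `rt_end`, `im_lo`, `im_hi`.
#' @param input `model_input` (supplies the crop geometry), or a
#'   `precursor_image`.
#' @param size grid side when `input` is a `precursor_image`. Default 258.
#' @return binary `size x size` matrix.
#' @export
rasterize_label <- function(rect, input, size = 258) {
  if (inherits(input, "model_input")) {
    rt_extent <- input$rt_extent
    im_extent <- input$im_extent
    size <- input$size
  } else {
    rt_extent <- coord_extent(input$rt_coords)
    im_extent <- coord_extent(input$im_coords)
  }
  rect <- as.list(rect)
  stopifnot(rect$rt_start <= rect$rt_end, rect$im_lo <= rect$im_hi)
  rt_centers <- rt_extent[1] + (seq_len(size) - 0.5) / size * diff(rt_extent)
  im_centers <- im_extent[1] + (seq_len(size) - 0.5) / size * diff(im_extent)
  mask <- outer(rt_centers >= rect$rt_start & rt_centers <= rect$rt_end,
                im_centers >= rect$im_lo & im_centers <= rect$im_hi) * 1
  if (sum(mask) == 0) {
    warning("label rectangle does not intersect the crop; all-zero mask")
  }
  mask
}

# --- segmentation features ---------------------------------------------

seg_feature_names <- c("act", "logact", "ctx_small", "ctx_large",
                       "pos_small", "pos_large", "neg_small", "neg_large",
                       "adr", "adc", "dr", "dc")

# per-pixel feature matrix (size^2 x F) for the segmentation model
seg_features <- function(input) {
  S <- input$size
  ch1 <- input$channels$activation
  ch2 <- input$channels$log_activation
  hint <- input$channels$hint
  pos <- pmax(hint, 0)
  neg <- pmax(-hint, 0)
  r_small <- max(1L, S %/% 16L)
  r_large <- max(2L, S %/% 4L)
  r3 <- max(1L, S %/% 32L)
  r8 <- max(1L, S %/% 8L)
  feats <- cbind(
    as.vector(ch1),
    as.vector(ch2),
    as.vector(box_blur(ch1, r3)),
    as.vector(box_blur(ch1, r8)),
    as.vector(box_blur(pos, r_small) * (2 * r_small + 1)^2),
    as.vector(box_blur(pos, r_large) * (2 * r_large + 1)^2),
    as.vector(box_blur(neg, r_small) * (2 * r_small + 1)^2),
    as.vector(box_blur(neg, r_large) * (2 * r_large + 1)^2)
  )
  rows <- rep(seq_len(S), times = S)
  cols <- rep(seq_len(S), each = S)
  dr <- (rows - input$target_pixel[1]) / S
  dc <- (cols - input$target_pixel[2]) / S
  feats <- cbind(feats, abs(dr), abs(dc), dr, dc)
  colnames(feats) <- seg_feature_names
  feats
}

train_report <- function(epochs_run, best_metric, split, seed, loss_curve) {
  structure(list(epochs_run = epochs_run, best_metric = best_metric,
                 split_sizes = vapply(split, length, integer(1)),
                 seed = seed, loss_curve = loss_curve),
            class = "train_report")
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf("<train_report> %d epochs, best validation metric %.5f, split %s, seed %d\n",
              x$epochs_run, x$best_metric,
              paste(x$split_sizes, collapse = "/"), x$seed))
  invisible(x)
}

# subsample pixels of one labelled image for training (balanced classes)
sample_pixels <- function(feats, label, seed, cap = 1500L) {
  set.seed(seed)
  y <- as.vector(label)
  pos <- which(y == 1)
  neg <- which(y == 0)
  if (length(pos) > cap) pos <- sample(pos, cap)
  n_neg <- min(length(neg), max(length(pos), 200L))
  if (length(neg) > n_neg) neg <- sample(neg, n_neg)
  idx <- c(pos, neg)
  list(X = feats[idx, , drop = FALSE], y = y[idx])
}

#' Train the peak-selection segmentation model
#'
#' Pixelwise classifier trained with the combo loss (1 x BCE + 4 x dice +
#' 1 x focal by default), Adam, a one-cycle learning-rate schedule, a
#' seeded train/validation/test split, and early stopping on validation
#' loss. Deterministic given the seed.
#'
#' @param pool list of `list(input = model_input, label = mask)` pairs;
#'   the pool must come from experiment-library candidates and their
#'   decoys, whose label rectangles are known.
#' @param config `ms1prop_config`.
#' @param split optional list(train, validation, test) of indices into
#'   `pool`; default a seeded split by `config$split`.
#' @param seed training seed; default derived from the config master seed.
#' @param hidden hidden layer sizes. Default c(16, 8).
#' @return object of class `seg_model` with the fitted layers, the split
#'   and a `train_report`.
#' @export
train_segmentation <- function(pool, config = ms1prop_config(), split = NULL,
                               seed = stage_seed(config, "segmentation"),
                               hidden = c(16, 8)) {
  if (length(pool) < 10) stop("segmentation training pool must have >= 10 items")
  if (is.null(split)) split <- split_pool(length(pool), config$split, seed)
  data <- lapply(seq_along(pool), function(i) {
    feats <- seg_features(pool[[i]]$input)
    sample_pixels(feats, pool[[i]]$label, seed = seed + i)
  })
  F <- ncol(data[[1]]$X)
  layers <- mlp_init(c(F, hidden, 1), seed)
  state <- adam_init(layers)
  n_batches <- max(1, ceiling(length(split$train) / config$batch_size))
  total_steps <- config$epochs * n_batches
  val_X <- do.call(rbind, lapply(data[split$validation], `[[`, "X"))
  val_y <- unlist(lapply(data[split$validation], `[[`, "y"))
  best <- Inf; best_layers <- layers; wait <- 0; step <- 0
  curve <- data.frame(epoch = integer(0), train = numeric(0), val = numeric(0))
  for (epoch in seq_len(config$epochs)) {
    set.seed(seed + 7919 * epoch)
    order_tr <- sample(split$train)
    batches <- split(order_tr, ceiling(seq_along(order_tr) / config$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      step <- step + 1
      X <- do.call(rbind, lapply(data[bt], `[[`, "X"))
      y <- unlist(lapply(data[bt], `[[`, "y"))
      fw <- mlp_forward(X, layers)
      ls <- combo_loss(drop(fw$logits), y, weights = config$loss_weights)
      grads <- mlp_backward(fw, layers, matrix(ls$dlogits, ncol = 1))
      lr <- one_cycle_lr(step, total_steps, config$max_lr)
      upd <- adam_step(layers, grads, state, lr, step)
      layers <- upd$layers; state <- upd$state
      ep_loss <- ep_loss + ls$loss
    }
    val_loss <- combo_loss(drop(mlp_forward(val_X, layers)$logits), val_y,
                           weights = config$loss_weights)$loss
    curve <- rbind(curve, data.frame(epoch = epoch,
                                     train = ep_loss / length(batches),
                                     val = val_loss))
    if (val_loss < best - 1e-6) {
      best <- val_loss; best_layers <- layers; wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= config$patience) break
    }
  }
  structure(list(layers = best_layers, config = config, split = split,
                 report = train_report(nrow(curve), best, split, seed, curve)),
            class = "seg_model")
}

#' Segmentation probability map for one input
#'
#' @param model `seg_model`.
#' @param input `model_input`.
#' @return `size x size` matrix of probabilities in `[0, 1]`.
#' @export
predict_seg_prob <- function(model, input) {
  S <- input$size
  logits <- mlp_forward(seg_features(input), model$layers)$logits
  matrix(sigmoid(drop(logits)), S, S)
}

#' Back-project a model-grid mask to native image resolution
#'
#' A native pixel is on iff the majority of its area maps to on pixels of
#' the model-grid mask (area-overlap weighting).
#'
#' @param mask binary `size x size` matrix.
#' @param image `precursor_image` providing the native geometry.
#' @return binary native `m_p x n_p` matrix.
#' @export
project_mask_to_native <- function(mask, image) {
  W_rt <- overlap_matrix(nrow(image$values), nrow(mask))
  W_im <- overlap_matrix(ncol(image$values), ncol(mask))
  (W_rt %*% mask %*% t(W_im) >= 0.5 - 1e-9) * 1
}

#' Predict the peak mask and the inferred intensity
#'
#' Thresholds the segmentation probability map, maps the binary mask back
#' to the native image resolution by majority area, and sums the native
#' activation over the mask.
#'
#' @param model `seg_model`.
#' @param input `model_input`.
#' @param image the native `precursor_image` the input was built from.
#' @param threshold probability cut. Default `model$config$mask_threshold`.
#' @return list with `prob` (model grid), `mask` (binary model grid),
#'   `native_mask`, and `intensity`.
#' @export
predict_mask_and_intensity <- function(model, input, image,
                                       threshold = model$config$mask_threshold) {
  prob <- predict_seg_prob(model, input)
  mask <- (prob >= threshold) * 1
  native <- project_mask_to_native(mask, image)
  list(prob = prob, mask = mask, native_mask = native,
       intensity = sum(image$values[native == 1]))
}

#' Intensity-weighted intersection over union
#'
#' `sum(I over pred & true) / sum(I over pred | true)`; defined as 0 when
#' the union carries zero intensity. Symmetric, bounded in `[0, 1]`, and
#' equal to plain IoU under uniform intensity.
#'
#' @param mask_pred,mask_true binary matrices of identical shape.
#' @param intensity_image nonnegative intensity matrix (non-log scale),
#'   same shape.
#' @return scalar in `[0, 1]`.
#' @export
weighted_iou <- function(mask_pred, mask_true, intensity_image) {
  if (!all(dim(mask_pred) == dim(mask_true)) ||
      !all(dim(mask_pred) == dim(intensity_image))) {
    stop("weighted_iou: shape mismatch")
  }
  inter <- sum(intensity_image[mask_pred == 1 & mask_true == 1])
  union <- sum(intensity_image[mask_pred == 1 | mask_true == 1])
  if (union <= 0) return(0)
  inter / union
}

# --- scoring model -----------------------------------------------------

scorer_feature_names <- c("mean_act", "max_act", "hint_act_small",
                          "hint_act_large", "hint_act", "mean_seg",
                          "seg_weighted_act", "hint_seg", "apex_dist",
                          "n_comp", "comp_act", "mean_logact")

# image-level feature vector for the scoring model (needs 4 channels)
scorer_features <- function(input) {
  if (is.null(input$channels$segmentation)) {
    stop("scorer input needs the segmentation output as channel 4")
  }
  S <- input$size
  ch1 <- input$channels$activation
  ch2 <- input$channels$log_activation
  seg <- input$channels$segmentation
  tp <- input$target_pixel
  r_small <- max(1L, S %/% 16L)
  r_large <- max(2L, S %/% 4L)
  b_small <- box_blur(ch1, r_small)
  b_large <- box_blur(ch1, r_large)
  seg_small <- box_blur(seg, r_small)
  apex <- which(ch1 == max(ch1), arr.ind = TRUE)[1, ]
  comp <- input$competitor_pixels
  comp_act <- if (!is.null(comp) && nrow(comp) > 0) {
    max(b_small[comp])
  } else 0
  c(mean(ch1), max(ch1),
    b_small[tp[1], tp[2]], b_large[tp[1], tp[2]], ch1[tp[1], tp[2]],
    mean(seg), sum(ch1 * seg) / (sum(ch1) + 1e-9),
    seg_small[tp[1], tp[2]],
    sqrt(sum((apex - tp)^2)) / S,
    min(NROW(comp), 10) / 10, comp_act, mean(ch2))
}

#' Train the confidence scoring model
#'
#' Image-summary features from the four input channels feed a small
#' network with a single logit output, trained with binary cross-entropy
#' with logits, Adam and a one-cycle schedule, early stopping on
#' validation loss. Positives must be experiment-library targets and
#' negatives their decoys. The sigmoid of the logit is the confidence
#' score in `[0, 1]`.
#'
#' @param pool list of `list(input = model_input with 4 channels,
#'   label = 0/1)` (1 = target).
#' @param config `ms1prop_config`.
#' @param split optional index split; default seeded by `config$split`.
#' @param seed training seed.
#' @param hidden hidden sizes. Default 8.
#' @return object of class `score_model`.
#' @export
train_scorer <- function(pool, config = ms1prop_config(), split = NULL,
                         seed = stage_seed(config, "scorer"), hidden = 8) {
  labels <- vapply(pool, function(p) p$label, numeric(1))
  if (length(unique(labels)) < 2) stop("scorer pool must contain both classes")
  if (is.null(split)) split <- split_pool(length(pool), config$split, seed)
  X_all <- t(vapply(pool, function(p) scorer_features(p$input),
                    numeric(length(scorer_feature_names))))
  mu <- colMeans(X_all[split$train, , drop = FALSE])
  sdv <- pmax(apply(X_all[split$train, , drop = FALSE], 2, stats::sd), 1e-6)
  X_all <- sweep(sweep(X_all, 2, mu), 2, sdv, `/`)
  layers <- mlp_init(c(ncol(X_all), hidden, 1), seed)
  state <- adam_init(layers)
  n_batches <- max(1, ceiling(length(split$train) / config$batch_size))
  total_steps <- config$epochs * n_batches
  best <- Inf; best_layers <- layers; wait <- 0; step <- 0
  curve <- data.frame(epoch = integer(0), train = numeric(0), val = numeric(0))
  for (epoch in seq_len(config$epochs)) {
    set.seed(seed + 104729 * epoch)
    order_tr <- sample(split$train)
    batches <- split(order_tr, ceiling(seq_along(order_tr) / config$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      step <- step + 1
      fw <- mlp_forward(X_all[bt, , drop = FALSE], layers)
      ls <- bce_with_logits(drop(fw$logits), labels[bt])
      grads <- mlp_backward(fw, layers, matrix(ls$dlogits, ncol = 1))
      lr <- one_cycle_lr(step, total_steps, config$max_lr)
      upd <- adam_step(layers, grads, state, lr, step)
      layers <- upd$layers; state <- upd$state
      ep_loss <- ep_loss + ls$loss
    }
    val_loss <- bce_with_logits(
      drop(mlp_forward(X_all[split$validation, , drop = FALSE], layers)$logits),
      labels[split$validation])$loss
    curve <- rbind(curve, data.frame(epoch = epoch,
                                     train = ep_loss / length(batches),
                                     val = val_loss))
    if (val_loss < best - 1e-6) {
      best <- val_loss; best_layers <- layers; wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= config$patience) break
    }
  }
  structure(list(layers = best_layers, mu = mu, sd = sdv, config = config,
                 split = split,
                 report = train_report(nrow(curve), best, split, seed, curve)),
            class = "score_model")
}

#' Confidence score of one input
#'
#' @param model `score_model`.
#' @param input `model_input` with 4 channels.
#' @return scalar confidence in `[0, 1]`.
#' @export
predict_confidence <- function(model, input) {
  x <- (scorer_features(input) - model$mu) / model$sd
  sigmoid(drop(mlp_forward(matrix(x, nrow = 1), model$layers)$logits))
}

#' Rank-based ROC AUC
#'
#' Probability that a random positive scores above a random negative,
#' with ties counted half.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (1 = positive); both classes must be present.
#' @return scalar AUC in `[0, 1]`.
#' @export
evaluate_scorer <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
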