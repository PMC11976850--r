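# End-to-end orchestration: dictionary -> scan-wise activation -> models
# -> post-processing chain -> FDR sweep -> reports.

#' Isobaric competitors of a candidate
#'
#' Candidates sharing the monoisotopic m/z bin whose RT and 1/K0 windows
#' both intersect the candidate's windows.
#'
#' @param dictionary `precursor_dictionary`.
#' @param id candidate id.
#' @return data.frame of competitor rows (possibly empty).
#' @export
competitors_of <- function(dictionary, id) {
  cand <- dictionary$candidates
  row <- cand[match(id, cand$id), ]
  hit <- cand$mono_bin == row$mono_bin & cand$id != id &
    cand$rt_lo <= row$rt_hi & cand$rt_hi >= row$rt_lo &
    cand$im_lo <= row$im_hi & cand$im_hi >= row$im_lo
  cand[which(hit), , drop = FALSE]
}

label_rect_of <- function(row) {
  if (is.na(row$rt_start_exp) || is.na(row$im_exp) || is.na(row$im_len_exp)) {
    return(NULL)
  }
  list(rt_start = row$rt_start_exp, rt_end = row$rt_end_exp,
       im_lo = row$im_exp - row$im_len_exp / 2,
       im_hi = row$im_exp + row$im_len_exp / 2)
}

build_all_inputs <- function(images, dictionary, config) {
  cand <- dictionary$candidates
  lapply(names(images), function(key) {
    id <- as.integer(key)
    row <- cand[match(id, cand$id), ]
    comp <- competitors_of(dictionary, id)
    hints <- if (nrow(comp)) cbind(comp$rt_pred, comp$im_center) else NULL
    build_model_input(images[[key]], c(row$rt_pred, row$im_center),
                      competitor_hints = hints, size = config$image_size,
                      log_eps = config$log_eps)
  })
}

# oracle-mode confidence: share of image intensity inside the rectangle
# around the hint (label rect when known, median-sized box otherwise)
oracle_score <- function(image, rect, row, med_rt_half, med_im_half) {
  if (is.null(rect)) {
    rect <- list(rt_start = row$rt_pred - med_rt_half,
                 rt_end = row$rt_pred + med_rt_half,
                 im_lo = row$im_center - med_im_half,
                 im_hi = row$im_center + med_im_half)
  }
  rsel <- image$rt_coords >= rect$rt_start & image$rt_coords <= rect$rt_end
  csel <- image$im_coords >= rect$im_lo & image$im_coords <= rect$im_hi
  total <- sum(image$values)
  if (total <= 0) return(list(intensity = 0, confidence = 0))
  inside <- sum(image$values[rsel, csel, drop = FALSE])
  list(intensity = inside, confidence = inside / total)
}

#' Run the full identity-propagation pipeline
#'
#' Executes dictionary construction, per-scan deconvolution (targets and
#' decoys searched separately), peak selection and confidence scoring,
#' the post-processing filter chain (intensity filter, target-decoy
#' competition, signal competition) and the FDR threshold sweep, writing
#' result tables and a stage-count log.
#'
#' @param config `ms1prop_config` (or a path to a YAML config). Must
#'   carry `experiment_library` and `frames` paths; optional
#'   `reference_library`, `prediction_table`, `rt_method`, `window_mode`,
#'   `im_mode`.
#' @param mode `"train"` fits the segmentation and scoring models;
#'   `"oracle"` uses the evidence label rectangles as masks and an
#'   in-rectangle intensity-fraction score (diagnostic mode for parameter
#'   recovery on synthetic data).
#' @param out_dir optional output directory for result files.
#' @param quiet suppress stage messages. Default FALSE.
#' @return list with `report` (all scored candidates + stage flags),
#'   `accepted` (rows surviving every filter at the chosen threshold),
#'   `sweep` (FDR sweep result), `counts` (stage count table),
#'   `dictionary`, and the fitted `models` (train mode).
#' @export
run_pipeline <- function(config, mode = c("train", "oracle"),
                         out_dir = NULL, quiet = FALSE) {
  mode <- match.arg(mode)
  if (is.character(config)) config <- read_config(config)
  counts <- list()
  fail <- function(stage, e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  # --- stage: library ---------------------------------------------------
  dict <- tryCatch({
    experiment <- read_evidence_table(config$experiment_library, "experiment")
    reference <- if (!is.null(config$reference_library) &&
                     !is.na(config$reference_library)) {
      read_evidence_table(config$reference_library, "reference")
    } else NULL
    rt_method <- if (!is.null(config$rt_method)) config$rt_method
                 else if (is.null(reference)) "observed" else "lowess"
    window_mode <- if (!is.null(config$window_mode)) config$window_mode
                   else if (rt_method == "observed") "evidence" else "calibrated"
    prediction_table <- if (!is.null(config$prediction_table)) {
      utils::read.delim(config$prediction_table, stringsAsFactors = FALSE)
    } else NULL
    build_dictionary(experiment, reference, config,
                     rt_method = rt_method,
                     prediction_table = prediction_table,
                     im_mode = if (!is.null(config$im_mode)) config$im_mode
                               else "experimental",
                     window_mode = window_mode)
  }, error = function(e) fail("build_library", e))
  cand <- dict$candidates
  counts$library <- stage_log("build_library", nrow(cand),
                              sum(cand$window_ok),
                              sprintf("%d targets, %d decoys",
                                      sum(!cand$is_decoy),
                                      sum(cand$is_decoy)), quiet)

  # --- stage: activation ------------------------------------------------
  images <- tryCatch({
    frames <- read_frames(config$frames)
    cube_t <- deconvolute_run(frames, dict, config,
                              subset = which(!cand$is_decoy))
    cube_d <- deconvolute_run(frames, dict, config,
                              subset = which(cand$is_decoy))
    c(assemble_and_slice(cube_t, dict,
                         ids = cand$id[!cand$is_decoy & cand$window_ok]),
      assemble_and_slice(cube_d, dict,
                         ids = cand$id[cand$is_decoy & cand$window_ok]))
  }, error = function(e) fail("activation", e))
  counts$activation <- stage_log("activation", sum(cand$window_ok),
                                 length(images), "", quiet)

  # --- stage: models ----------------------------------------------------
  scored <- tryCatch({
    inputs <- build_all_inputs(images, dict, config)
    names(inputs) <- names(images)
    ids <- as.integer(names(images))
    rows <- cand[match(ids, cand$id), ]
    models <- NULL
    if (mode == "oracle") {
      rects <- lapply(seq_len(nrow(rows)), function(i) {
        label_rect_of(rows[i, ])
      })
      med_rt_half <- stats::median(
        (rows$rt_end_exp - rows$rt_start_exp) / 2, na.rm = TRUE)
      med_im_half <- stats::median(rows$im_len_exp / 2, na.rm = TRUE)
      res <- lapply(seq_along(ids), function(i) {
        oracle_score(images[[i]], rects[[i]], rows[i, ],
                     med_rt_half, med_im_half)
      })
      intensity <- vapply(res, `[[`, numeric(1), "intensity")
      confidence <- vapply(res, `[[`, numeric(1), "confidence")
    } else {
      S <- config$image_size
      has_rect <- !is.na(rows$rt_start_exp) & !is.na(rows$im_exp) &
        !is.na(rows$im_len_exp)
      # training pool: experiment-library targets (rect labels) plus their
      # decoys (all-zero masks); split shared by both models
      exp_target_pos <- which(has_rect & !rows$is_decoy)
      exp_target_ids <- ids[exp_target_pos]
      decoy_pos <- which(rows$is_decoy & rows$pair_id %in% exp_target_ids)
      pool_pos <- c(exp_target_pos, decoy_pos)
      seg_pool <- lapply(pool_pos, function(i) {
        lab <- if (has_rect[i] && !rows$is_decoy[i]) {
          rasterize_label(label_rect_of(rows[i, ]), inputs[[i]])
        } else {
          matrix(0, S, S)
        }
        list(input = inputs[[i]], label = lab)
      })
      split <- split_pool(length(seg_pool), config$split,
                          stage_seed(config, "model_split"))
      seg_model <- train_segmentation(seg_pool, config, split = split)
      seg_prob <- lapply(inputs, function(inp) predict_seg_prob(seg_model, inp))
      pred <- lapply(seq_along(ids), function(i) {
        mask <- (seg_prob[[i]] >= config$mask_threshold) * 1
        native <- project_mask_to_native(mask, images[[i]])
        sum(images[[i]]$values[native == 1])
      })
      intensity <- unlist(pred)
      score_pool <- lapply(pool_pos, function(i) {
        list(input = with_segmentation_channel(inputs[[i]], seg_prob[[i]]),
             label = as.numeric(!rows$is_decoy[i]))
      })
      score_model <- train_scorer(score_pool, config, split = split)
      confidence <- vapply(seq_along(ids), function(i) {
        predict_confidence(score_model,
                           with_segmentation_channel(inputs[[i]],
                                                     seg_prob[[i]]))
      }, numeric(1))
      models <- list(segmentation = seg_model, scorer = score_model)
    }
    list(tab = data.frame(
      id = ids, pair_id = rows$pair_id, is_decoy = rows$is_decoy,
      sequence = rows$modified_sequence, charge = rows$charge,
      mono_bin = rows$mono_bin, rt_pred = rows$rt_pred,
      im_center = rows$im_center, species = rows$species,
      inferred_intensity = intensity, confidence = confidence,
      stringsAsFactors = FALSE), models = models)
  }, error = function(e) fail("models", e))
  models <- scored$models
  scored <- scored$tab
  counts$scoring <- stage_log("scoring", length(images), nrow(scored), "",
                              quiet)

  # --- stage: post-processing chain ------------------------------------
  post <- tryCatch({
    s1 <- intensity_filter(scored, config$intensity_threshold)
    s2 <- target_decoy_competition(s1)
    s3 <- signal_competition(s2, dict$stats,
                             im_mode = if (!is.null(config$im_mode))
                               config$im_mode else "experimental")
    sweep <- fdr_sweep(s3, config$max_fdr)
    list(s1 = s1, s2 = s2, s3 = s3, sweep = sweep)
  }, error = function(e) fail("fdr_control", e))
  counts$intensity <- stage_log("intensity_filter", nrow(scored),
                                nrow(post$s1), "", quiet)
  counts$tdc <- stage_log("target_decoy_competition", nrow(post$s1),
                          nrow(post$s2), "", quiet)
  counts$signal <- stage_log("signal_competition", nrow(post$s2),
                             nrow(post$s3), "", quiet)
  accepted <- post$s3[post$s3$confidence >= post$sweep$threshold, ,
                      drop = FALSE]
  counts$threshold <- stage_log(
    "score_threshold", nrow(post$s3), nrow(accepted),
    sprintf("threshold=%.4f fdr=%.4f", post$sweep$threshold,
            post$sweep$fdr_at_threshold), quiet)

  # --- report -----------------------------------------------------------
  report <- scored
  report$passed_intensity_filter <-
    report$inferred_intensity >= config$intensity_threshold
  report$passed_tdc <- ifelse(report$passed_intensity_filter,
                              report$id %in% post$s2$id, NA)
  report$passed_signal_competition <- ifelse(
    isTRUE_or_na(report$passed_tdc), report$id %in% post$s3$id, NA)
  tabmatch <- match(report$confidence, post$sweep$table$threshold)
  report$fdr_at_score <- ifelse(report$id %in% post$s3$id,
                                post$sweep$table$fdr[tabmatch], NA)
  names(report)[names(report) == "sequence"] <- "sequence"
  counts_tab <- do.call(rbind, counts)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(report, post$sweep$table, file.path(out_dir, "results"))
    utils::write.table(counts_tab, file.path(out_dir, "stage_counts.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(report = report, accepted = accepted, sweep = post$sweep,
       counts = counts_tab, dictionary = dict, models = models)
}

isTRUE_or_na <- function(x) !is.na(x) & x
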