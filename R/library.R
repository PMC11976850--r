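# Precursor dictionary construction: library merging, RT prediction /
# alignment, calibration windows, isotope envelopes, and mutation decoys.

#' Merge evidence libraries into a unique candidate set
#'
#' Concatenates evidence records and removes duplicate (modified sequence,
#' charge) keys, keeping the record with the highest observed intensity.
#' The surviving record's source is the union of the sources seen for the
#' key (`both` when a key occurs in experiment and reference records).
#' Ties on intensity are resolved deterministically: experiment-sourced
#' records win, then the lexicographically smaller source tag.
#'
#' @param experiment evidence data.frame (source tag `experiment`), may be
#'   NULL or empty.
#' @param reference evidence data.frame (source tag `reference`), may be
#'   NULL or empty.
#' @return deduplicated evidence data.frame with a `source` column in
#'   `{experiment, reference, both}`.
#' @export
merge_libraries <- function(experiment, reference) {
  tabs <- Filter(function(x) !is.null(x) && nrow(x) > 0,
                 list(experiment, reference))
  if (length(tabs) == 0) {
    return(empty_evidence())
  }
  all <- do.call(rbind, tabs)
  key <- paste(all$modified_sequence, all$charge, sep = "\r")
  # union of sources per key ("both" counts as both)
  has_exp <- tapply(all$source %in% c("experiment", "both"), key, any)
  has_ref <- tapply(all$source %in% c("reference", "both"), key, any)
  # deterministic pick: max intensity, tie -> experiment first, then source tag
  src_rank <- ifelse(all$source == "experiment", 0L,
                     ifelse(all$source == "both", 1L, 2L))
  ord <- order(key, -all$intensity, src_rank)
  all <- all[ord, , drop = FALSE]
  key <- key[ord]
  out <- all[!duplicated(key), , drop = FALSE]
  ukey <- key[!duplicated(key)]
  out$source <- ifelse(has_exp[ukey] & has_ref[ukey], "both",
                       ifelse(has_exp[ukey], "experiment", "reference"))
  out <- out[order(out$modified_sequence, out$charge), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_evidence <- function() {
  data.frame(modified_sequence = character(0), charge = integer(0),
             rt_obs = numeric(0), rt_start = numeric(0), rt_end = numeric(0),
             im_center = numeric(0), im_length = numeric(0),
             intensity = numeric(0), species = character(0),
             source = character(0), stringsAsFactors = FALSE)
}

#' Monotone-smooth retention-time alignment
#'
#' Fits a LOWESS curve through paired retention times of precursors shared
#' by two runs and returns a single-valued monotone mapping from source-run
#' RT to target-run RT. Outside the fitted range the mapping extrapolates
#' with the boundary value plus the local offset (rule-2 interpolation on
#' the residual-corrected curve).
#'
#' @param rt_source RTs in the source run (minutes).
#' @param rt_target RTs of the same precursors in the target run.
#' @param span LOWESS smoother span. Default 0.3.
#' @return a function mapping numeric source RTs to target RTs, with the
#'   fitting residuals attached as attribute `residuals`.
#' @export
lowess_rt_alignment <- function(rt_source, rt_target, span = 0.3) {
  stopifnot(length(rt_source) == length(rt_target))
  if (length(rt_source) < 20) {
    stop("need at least 20 common precursors for LOWESS alignment; ",
         "supply an external prediction table instead")
  }
  fit <- stats::lowess(rt_source, rt_target, f = span)
  # enforce monotone non-decreasing output so the mapping is single-valued
  y <- cummax(fit$y)
  x <- fit$x
  dup <- duplicated(x)
  mapping <- stats::approxfun(x[!dup], y[!dup], rule = 2)
  res <- rt_target - mapping(rt_source)
  attr(mapping, "residuals") <- res
  mapping
}

#' Calibration statistics for search-window sizing
#'
#' 95th percentiles of absolute RT / ion-mobility prediction error on the
#' holdout pairs, and the upper percentile of experimental 1/K0 lengths.
#' All percentiles use linear interpolation between order statistics
#' (R quantile type 7).
#'
#' @param rt_pred,rt_obs holdout retention-time pairs (minutes).
#' @param im_pred,im_obs optional ion-mobility pairs (1/K0); NULL if
#'   predictions are not available.
#' @param im_lengths experimental 1/K0 lengths of the experiment library.
#' @param im_length_percentile percentile for the length term. Default 99.9.
#' @param delta_im_cross optional cross-library 1/K0 deviation (95th
#'   percentile of |experiment - reference| on shared precursors).
#' @return object of class `calibration_stats` with fields `delta_rt95`,
#'   `delta_im95`, `im_length_q999`, `delta_im_cross`, `n_holdout`.
#' @export
compute_calibration_stats <- function(rt_pred, rt_obs,
                                      im_pred = NULL, im_obs = NULL,
                                      im_lengths,
                                      im_length_percentile = 99.9,
                                      delta_im_cross = NA_real_) {
  if (length(rt_pred) == 0 || length(im_lengths) == 0) {
    stop("empty calibration input")
  }
  stopifnot(length(rt_pred) == length(rt_obs))
  delta_rt95 <- unname(stats::quantile(abs(rt_pred - rt_obs), 0.95, type = 7))
  delta_im95 <- if (!is.null(im_pred) && length(im_pred)) {
    unname(stats::quantile(abs(im_pred - im_obs), 0.95, type = 7))
  } else {
    NA_real_
  }
  q <- im_length_percentile / 100
  structure(list(
    delta_rt95 = delta_rt95,
    delta_im95 = delta_im95,
    im_length_q999 = unname(stats::quantile(im_lengths, q, type = 7)),
    delta_im_cross = delta_im_cross,
    n_holdout = length(rt_pred)
  ), class = "calibration_stats")
}

#' @export
print.calibration_stats <- function(x, ...) {
  cat(sprintf(paste0("<calibration_stats> dRT95=%.4f min, dIM95=%s, ",
                     "IM length q=%.4f, cross dIM=%s (n=%d)\n"),
              x$delta_rt95,
              ifelse(is.na(x$delta_im95), "NA", sprintf("%.4f", x$delta_im95)),
              x$im_length_q999,
              ifelse(is.na(x$delta_im_cross), "NA",
                     sprintf("%.4f", x$delta_im_cross)),
              x$n_holdout))
  invisible(x)
}

#' Assign RT and ion-mobility search windows to candidates
#'
#' RT window is `rt_pred +/- delta_rt95`. The 1/K0 window is
#' `im_center +/- (delta_im + im_length_q999 / 2)` where `delta_im` is the
#' predicted-mode 95th-percentile prediction error, or the cross-library
#' deviation when experimental ion mobilities are used.
#'
#' @param candidates data.frame with `rt_pred` and `im_center` columns.
#' @param stats `calibration_stats`.
#' @param im_mode `"experimental"` or `"predicted"`.
#' @return `candidates` with `rt_lo`, `rt_hi`, `im_lo`, `im_hi` columns and
#'   a logical `window_ok` flag; candidates missing `rt_pred`/`im_center`
#'   are flagged FALSE and their count logged.
#' @export
assign_search_windows <- function(candidates, stats,
                                  im_mode = c("experimental", "predicted")) {
  im_mode <- match.arg(im_mode)
  delta_im <- if (im_mode == "predicted") stats$delta_im95 else stats$delta_im_cross
  if (is.na(delta_im)) {
    stop("no ", im_mode, "-mode ion-mobility deviation available in stats")
  }
  ok <- !is.na(candidates$rt_pred) & !is.na(candidates$im_center)
  half_im <- delta_im + stats$im_length_q999 / 2
  candidates$rt_lo <- candidates$rt_pred - stats$delta_rt95
  candidates$rt_hi <- candidates$rt_pred + stats$delta_rt95
  candidates$im_lo <- candidates$im_center - half_im
  candidates$im_hi <- candidates$im_center + half_im
  candidates$window_ok <- ok
  if (any(!ok)) {
    stage_log("assign_search_windows", nrow(candidates), sum(ok),
              sprintf("%d candidates lack predictions, excluded", sum(!ok)))
  }
  candidates
}

# --- decoys ------------------------------------------------------------

#' Read an amino-acid mutation map
#'
#' Two-column TSV (`from_residue`, `to_residue`); must be a total map over
#' the residues it is applied to.
#'
#' @param path TSV path; default is the packaged fixed mapping.
#' @return named character vector (from -> to).
#' @export
read_mutation_map <- function(path = system.file("extdata",
                                                 "mutation_map.tsv",
                                                 package = "ms1prop")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab$to_residue, tab$from_residue)
}

# split a modified sequence into residues with attached mods
tokenize_sequence <- function(modified_sequence) {
  nterm <- ""
  s <- modified_sequence
  m <- regmatches(s, regexpr("^\\[[^]]*\\]", s))
  if (length(m) == 1 && nzchar(m)) {
    nterm <- m
    s <- sub("^\\[[^]]*\\]", "", s)
  }
  toks <- regmatches(s, gregexpr("[A-Z](\\[[^]]*\\])?", s))[[1]]
  if (nchar(paste(toks, collapse = "")) != nchar(s)) {
    stop("cannot tokenize sequence: ", modified_sequence)
  }
  list(nterm = nterm, tokens = toks)
}

mutate_residue <- function(token, mutation_map) {
  res <- substr(token, 1, 1)
  if (!res %in% names(mutation_map)) {
    stop("mutation map does not cover residue ", res)
  }
  # a residue-specific modification travels with the position, not the residue
  paste0(mutation_map[[res]], substr(token, 2, nchar(token)))
}

#' Generate sequence-mutation decoys
#'
#' For every eligible target (length >= 4) the second and second-to-last
#' residues are mutated by the fixed residue map. If the resulting decoy's
#' isotope pattern is close to the target's (neutral monoisotopic masses
#' within `closeness_tol * charge`), the third-to-last residue is also
#' mutated. Decoys whose mutated sequence equals any target sequence are
#' removed. Decoys inherit charge, predicted RT and ion mobility from
#' their target; `pair_id` links each decoy to its source target id.
#'
#' @param targets candidate data.frame with at least `id`,
#'   `modified_sequence`, `charge` (plus any coordinate columns, inherited).
#' @param mutation_map named character vector from [read_mutation_map()].
#' @param closeness_tol neutral-mass closeness tolerance per charge unit
#'   (Th scale). Default 0.01.
#' @return data.frame of decoys (columns of `targets` plus `is_decoy`,
#'   `pair_id`, `decoy_rounds`), with attributes `n_short` (targets too
#'   short for a decoy) and `n_collision` (decoys removed for colliding
#'   with a target sequence).
#' @export
generate_decoys <- function(targets, mutation_map, closeness_tol = 0.01) {
  n <- nrow(targets)
  seqs <- targets$modified_sequence
  plain_len <- nchar(strip_modifications(seqs))
  eligible <- plain_len >= 4
  out <- targets[eligible, , drop = FALSE]
  decoy_seq <- character(nrow(out))
  rounds <- integer(nrow(out))
  for (i in seq_len(nrow(out))) {
    tk <- tokenize_sequence(out$modified_sequence[i])
    L <- length(tk$tokens)
    tk$tokens[2] <- mutate_residue(tk$tokens[2], mutation_map)
    tk$tokens[L - 1] <- mutate_residue(tk$tokens[L - 1], mutation_map)
    d1 <- paste0(tk$nterm, paste(tk$tokens, collapse = ""))
    dm <- abs(monoisotopic_mass(d1) - monoisotopic_mass(out$modified_sequence[i]))
    if (dm < closeness_tol * out$charge[i]) {
      tk$tokens[L - 2] <- mutate_residue(tk$tokens[L - 2], mutation_map)
      d1 <- paste0(tk$nterm, paste(tk$tokens, collapse = ""))
      rounds[i] <- 2L
    } else {
      rounds[i] <- 1L
    }
    decoy_seq[i] <- d1
  }
  collision <- decoy_seq %in% seqs
  out$pair_id <- out$id
  out$modified_sequence <- decoy_seq
  out$is_decoy <- TRUE
  out$decoy_rounds <- rounds
  out <- out[!collision, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_short") <- sum(!eligible)
  attr(out, "n_collision") <- sum(collision)
  stage_log("generate_decoys", n, nrow(out),
            sprintf("%d too short, %d target collisions removed",
                    sum(!eligible), sum(collision)), quiet = TRUE)
  out
}

# --- dictionary orchestration ------------------------------------------

#' Build the target + decoy precursor dictionary
#'
#' End-to-end dictionary construction: merge experiment and reference
#' evidence, obtain RT predictions (external table, LOWESS alignment onto
#' the experiment run, or observed RTs), estimate calibration windows on a
#' seeded holdout of the experiment library, compute isotope envelopes,
#' assign search windows, and generate mutation decoys.
#'
#' @param experiment experiment-library evidence data.frame.
#' @param reference optional reference-library evidence data.frame.
#' @param config `ms1prop_config`.
#' @param rt_method one of `"observed"` (exact-dictionary mode; observed
#'   RTs are the predictions), `"lowess"` (align reference RTs onto the
#'   experiment run through shared precursors), `"table"` (external
#'   predictions).
#' @param prediction_table data.frame (modified_sequence, charge, rt_pred
#'   [, im_pred]) for `rt_method = "table"`.
#' @param im_mode `"experimental"` uses library 1/K0 values (reference
#'   values preferred for shared candidates); `"predicted"` uses `im_pred`
#'   from the prediction table.
#' @param window_mode `"calibrated"` derives windows from the calibration
#'   deltas; `"evidence"` (exact-dictionary mode) takes the RT range and
#'   1/K0 center +/- half length straight from the experiment evidence
#'   where available, falling back to calibrated windows otherwise.
#' @param mutation_map named vector; default the packaged fixed mapping.
#' @return object of class `precursor_dictionary`: list with `candidates`
#'   (data.frame incl. decoys), `envelopes` (list keyed by candidate id),
#'   `stats` (`calibration_stats`), `log` (stage count data.frame).
#' @export
build_dictionary <- function(experiment, reference = NULL, config = ms1prop_config(),
                             rt_method = c("observed", "lowess", "table"),
                             prediction_table = NULL,
                             im_mode = c("experimental", "predicted"),
                             window_mode = c("calibrated", "evidence"),
                             mutation_map = read_mutation_map()) {
  rt_method <- match.arg(rt_method)
  im_mode <- match.arg(im_mode)
  window_mode <- match.arg(window_mode)
  logs <- list()

  merged <- merge_libraries(experiment, reference)
  logs$merge <- stage_log("merge_libraries",
                          nrow(experiment) + NROW(reference), nrow(merged),
                          quiet = TRUE)
  if (nrow(merged) == 0) stop("empty merged library")

  key <- function(d) paste(d$modified_sequence, d$charge, sep = "\r")
  exp_key <- key(experiment)
  mkey <- key(merged)
  # per-key experiment/reference coordinates (max-intensity row of each)
  exp_best <- experiment[order(-experiment$intensity), , drop = FALSE]
  exp_best <- exp_best[!duplicated(key(exp_best)), , drop = FALSE]
  idx_exp <- match(mkey, key(exp_best))
  merged$rt_obs_exp <- exp_best$rt_obs[idx_exp]
  merged$im_exp <- exp_best$im_center[idx_exp]
  merged$im_len_exp <- exp_best$im_length[idx_exp]
  merged$rt_start_exp <- exp_best$rt_start[idx_exp]
  merged$rt_end_exp <- exp_best$rt_end[idx_exp]
  if (!is.null(reference) && nrow(reference) > 0) {
    ref_best <- reference[order(-reference$intensity), , drop = FALSE]
    ref_best <- ref_best[!duplicated(key(ref_best)), , drop = FALSE]
    idx_ref <- match(mkey, key(ref_best))
    merged$rt_obs_ref <- ref_best$rt_obs[idx_ref]
    merged$im_ref <- ref_best$im_center[idx_ref]
  } else {
    merged$rt_obs_ref <- NA_real_
    merged$im_ref <- NA_real_
  }

  # --- RT (and optionally IM) predictions
  pred_im <- rep(NA_real_, nrow(merged))
  if (rt_method == "observed") {
    merged$rt_pred <- ifelse(!is.na(merged$rt_obs_exp), merged$rt_obs_exp,
                             merged$rt_obs_ref)
  } else if (rt_method == "lowess") {
    shared <- !is.na(merged$rt_obs_exp) & !is.na(merged$rt_obs_ref)
    mapping <- lowess_rt_alignment(merged$rt_obs_ref[shared],
                                   merged$rt_obs_exp[shared])
    merged$rt_pred <- ifelse(!is.na(merged$rt_obs_exp), merged$rt_obs_exp,
                             mapping(merged$rt_obs_ref))
  } else {
    if (is.null(prediction_table)) stop("rt_method='table' needs prediction_table")
    pidx <- match(mkey, key(prediction_table))
    merged$rt_pred <- prediction_table$rt_pred[pidx]
    if ("im_pred" %in% names(prediction_table)) {
      pred_im <- prediction_table$im_pred[pidx]
    }
  }

  # --- ion-mobility centers: reference values preferred when available
  if (im_mode == "experimental") {
    merged$im_center <- ifelse(!is.na(merged$im_ref), merged$im_ref,
                               merged$im_exp)
  } else {
    merged$im_center <- ifelse(!is.na(pred_im), pred_im, merged$im_exp)
  }

  # --- calibration on a seeded holdout of the experiment library
  is_exp <- !is.na(merged$rt_obs_exp)
  exp_rows <- which(is_exp & !is.na(merged$rt_pred))
  set.seed(stage_seed(config, "calibration"))
  n_hold <- max(1L, round(config$rt_holdout_fraction * length(exp_rows)))
  hold <- sort(sample(exp_rows, n_hold))
  shared <- which(!is.na(merged$im_exp) & !is.na(merged$im_ref))
  delta_im_cross <- if (length(shared) >= 5) {
    unname(stats::quantile(abs(merged$im_exp[shared] - merged$im_ref[shared]),
                           0.95, type = 7))
  } else {
    config$im_delta_experimental
  }
  stats <- compute_calibration_stats(
    rt_pred = merged$rt_pred[hold], rt_obs = merged$rt_obs_exp[hold],
    im_pred = if (any(!is.na(pred_im[hold]))) pred_im[hold] else NULL,
    im_obs = merged$im_exp[hold],
    im_lengths = merged$im_len_exp[is_exp & !is.na(merged$im_len_exp)],
    im_length_percentile = config$im_length_percentile,
    delta_im_cross = delta_im_cross
  )

  # --- candidate table
  cand <- merged
  cand$id <- seq_len(nrow(cand))
  cand$is_decoy <- FALSE
  cand$pair_id <- NA_integer_
  cand$library_intensity <- cand$intensity
  cand <- assign_search_windows(cand, stats, im_mode)
  if (window_mode == "evidence") {
    ev <- !is.na(cand$rt_start_exp) & !is.na(cand$rt_end_exp)
    cand$rt_lo[ev] <- cand$rt_start_exp[ev]
    cand$rt_hi[ev] <- cand$rt_end_exp[ev]
    evi <- !is.na(cand$im_exp) & !is.na(cand$im_len_exp)
    cand$im_lo[evi] <- cand$im_exp[evi] - cand$im_len_exp[evi] / 2
    cand$im_hi[evi] <- cand$im_exp[evi] + cand$im_len_exp[evi] / 2
    cand$window_ok <- cand$window_ok | (ev & evi)
  }

  # --- decoys (inherit coordinates/windows from targets)
  tol <- if (is.null(config$decoy_closeness_tol)) config$mz_bin_width else config$decoy_closeness_tol
  decoys <- generate_decoys(cand, mutation_map, closeness_tol = tol)
  if (nrow(decoys) > 0) decoys$id <- max(cand$id) + seq_len(nrow(decoys))
  logs$decoys <- stage_log("generate_decoys", nrow(cand), nrow(decoys),
                           quiet = TRUE)
  all_cand <- rbind(cand, decoys[, names(cand), drop = FALSE])
  rownames(all_cand) <- NULL

  # --- envelopes
  envs <- vector("list", nrow(all_cand))
  env_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(all_cand))) {
    ck <- paste(all_cand$modified_sequence[i], all_cand$charge[i], sep = "\r")
    if (is.null(env_cache[[ck]])) {
      env_cache[[ck]] <- compute_isotope_envelope(
        all_cand$modified_sequence[i], all_cand$charge[i],
        min_abundance = config$isotope_min_abundance,
        mz_bin_width = config$mz_bin_width
      )
    }
    envs[[i]] <- env_cache[[ck]]
  }
  all_cand$mono_mz <- vapply(envs, function(e) e$mono_mz, numeric(1))
  all_cand$mono_bin <- as.integer(floor(all_cand$mono_mz / config$mz_bin_width))
  names(envs) <- as.character(all_cand$id)

  structure(list(candidates = all_cand, envelopes = envs, stats = stats,
                 config = config, log = do.call(rbind, logs)),
            class = "precursor_dictionary")
}

#' @export
print.precursor_dictionary <- function(x, ...) {
  cat(sprintf("<precursor_dictionary> %d candidates (%d targets, %d decoys)\n",
              nrow(x$candidates), sum(!x$candidates$is_decoy),
              sum(x$candidates$is_decoy)))
  print(x$stats)
  invisible(x)
}
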