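# Post-processing filter chain and target-decoy FDR control.
#
# Fixed stage order: intensity filter -> target-decoy competition ->
# signal competition -> confidence-score threshold sweep. Each stage only
# removes candidates.

#' Remove candidates below the inferred-intensity threshold
#'
#' Candidates with inferred intensity strictly below the threshold are
#' removed (the boundary value is kept).
#'
#' @param scored data.frame with an `inferred_intensity` column.
#' @param threshold intensity cutoff. Default 100.
#' @return filtered data.frame with `passed_intensity_filter` set.
#' @export
intensity_filter <- function(scored, threshold = 100) {
  keep <- scored$inferred_intensity >= threshold
  scored$passed_intensity_filter <- keep
  scored[keep, , drop = FALSE]
}

#' Target-decoy competition
#'
#' Within each surviving target/decoy pair only the member with the higher
#' confidence score remains; on an exact tie the decoy is kept (the
#' conservative choice). Candidates whose partner was already filtered
#' pass unopposed.
#'
#' @param scored data.frame with `id`, `pair_id`, `is_decoy`, `confidence`.
#' @return filtered data.frame with `passed_tdc` set.
#' @export
target_decoy_competition <- function(scored) {
  # pair key: target id for targets, pair_id (= source target id) for decoys
  pk <- ifelse(scored$is_decoy, scored$pair_id, scored$id)
  keep <- rep(TRUE, nrow(scored))
  for (key in unique(pk[duplicated(pk)])) {
    members <- which(pk == key)
    if (length(members) < 2) next
    conf <- scored$confidence[members]
    best <- max(conf)
    winners <- members[conf == best]
    if (length(winners) > 1) {
      # tie: keep the decoy
      winners <- winners[scored$is_decoy[winners]][1]
    }
    keep[setdiff(members, winners)] <- FALSE
  }
  scored$passed_tdc <- keep
  scored[keep, , drop = FALSE]
}

#' Signal competition
#'
#' Two candidates compete for the same MS1 feature when they share a
#' monoisotopic m/z bin, their predicted RTs differ by less than
#' `2 * delta_rt95` and their ion-mobility centers by less than
#' `2 * delta_im`. Within such a pair, if the absolute difference in log10
#' inferred intensity is below `log10_tol` the two activations are deemed
#' the same feature and the lower-confidence member is removed. Competitor
#' edges are processed in descending order of their larger confidence;
#' already-removed candidates cannot eliminate others.
#'
#' @param scored data.frame with `mono_bin`, `rt_pred`, `im_center`,
#'   `confidence`, `inferred_intensity`.
#' @param stats `calibration_stats`.
#' @param im_mode which ion-mobility deviation to use ("experimental" uses
#'   the cross-library delta). Default "experimental".
#' @param log10_tol log10 intensity closeness. Default 0.01.
#' @return filtered data.frame with `passed_signal_competition` set.
#' @export
signal_competition <- function(scored, stats,
                               im_mode = c("experimental", "predicted"),
                               log10_tol = 0.01) {
  im_mode <- match.arg(im_mode)
  delta_im <- if (im_mode == "predicted") stats$delta_im95 else stats$delta_im_cross
  n <- nrow(scored)
  alive <- rep(TRUE, n)
  if (n >= 2) {
    edges <- list()
    by_bin <- split(seq_len(n), scored$mono_bin)
    for (members in by_bin) {
      if (length(members) < 2) next
      for (a in seq_along(members)) {
        for (b in seq_len(a - 1)) {
          i <- members[a]; j <- members[b]
          if (abs(scored$rt_pred[i] - scored$rt_pred[j]) < 2 * stats$delta_rt95 &&
              abs(scored$im_center[i] - scored$im_center[j]) < 2 * delta_im) {
            li <- log10(pmax(scored$inferred_intensity[i], 1e-12))
            lj <- log10(pmax(scored$inferred_intensity[j], 1e-12))
            if (abs(li - lj) < log10_tol) {
              edges[[length(edges) + 1]] <-
                c(i, j, max(scored$confidence[i], scored$confidence[j]))
            }
          }
        }
      }
    }
    if (length(edges)) {
      em <- do.call(rbind, edges)
      em <- em[order(-em[, 3]), , drop = FALSE]
      for (r in seq_len(nrow(em))) {
        i <- em[r, 1]; j <- em[r, 2]
        if (!alive[i] || !alive[j]) next
        ci <- scored$confidence[i]; cj <- scored$confidence[j]
        loser <- if (ci < cj) i else if (cj < ci) j else max(i, j)
        alive[loser] <- FALSE
      }
    }
  }
  scored$passed_signal_competition <- alive
  scored[alive, , drop = FALSE]
}

#' False discovery rate from target and decoy counts
#'
#' `FDR = N_decoy / N_target`; undefined (NaN, with a warning) when no
#' targets remain.
#'
#' @param n_target,n_decoy nonnegative counts.
#' @return scalar FDR.
#' @export
compute_fdr <- function(n_target, n_decoy) {
  if (n_target < 0 || n_decoy < 0) stop("negative counts")
  if (n_target == 0) {
    if (n_decoy > 0) warning("no targets; FDR undefined")
    return(if (n_decoy == 0) 0 else NaN)
  }
  n_decoy / n_target
}

#' Confidence-threshold sweep with FDR control
#'
#' Tabulates target/decoy counts and FDR at every distinct confidence
#' value (descending, with 0 appended) and picks the smallest threshold
#' whose FDR does not exceed `max_fdr` — which may be 0 when the unfiltered
#' set already satisfies the bound. When no threshold qualifies, the
#' highest distinct score is returned and flagged.
#'
#' @param scored post-competition data.frame with `confidence`, `is_decoy`.
#' @param max_fdr maximum tolerated FDR. Default 0.20.
#' @param monotone also add a q-value-style cumulative-minimum column
#'   (`fdr_monotone`); an extension, the selection always uses the raw FDR.
#' @return list with `table` (columns threshold, n_target, n_decoy, fdr
#'   and optionally fdr_monotone), `threshold`, `fdr_at_threshold`,
#'   `satisfied`.
#' @export
fdr_sweep <- function(scored, max_fdr = 0.20, monotone = TRUE) {
  thr <- sort(unique(c(0, scored$confidence)), decreasing = TRUE)
  n_target <- vapply(thr, function(t) {
    sum(!scored$is_decoy & scored$confidence >= t)
  }, numeric(1))
  n_decoy <- vapply(thr, function(t) {
    sum(scored$is_decoy & scored$confidence >= t)
  }, numeric(1))
  fdr <- mapply(function(a, b) suppressWarnings(compute_fdr(a, b)),
                n_target, n_decoy)
  tab <- data.frame(threshold = thr, n_target = n_target,
                    n_decoy = n_decoy, fdr = fdr)
  if (monotone) {
    f <- ifelse(is.nan(fdr), Inf, fdr)
    qv <- rev(cummin(rev(f)))  # min FDR over all thresholds at most this one
    tab$fdr_monotone <- ifelse(is.infinite(qv), NA_real_, qv)
  }
  ok <- which(!is.nan(tab$fdr) & tab$fdr <= max_fdr)
  if (length(ok)) {
    pick <- ok[which.min(tab$threshold[ok])]
    satisfied <- TRUE
  } else {
    pick <- which.max(tab$threshold)
    satisfied <- FALSE
  }
  list(table = tab, threshold = tab$threshold[pick],
       fdr_at_threshold = tab$fdr[pick], satisfied = satisfied)
}
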