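#' Pipeline configuration
#'
#' Creates the flat configuration object used by every stage of the
#' pipeline. Every tunable constant of the method is a field here and can
#' be overridden; the defaults are the method's canonical operating values.
#'
#' @param mz_bin_width m/z raster width in Thomson used for frame binning
#'   and envelope aggregation. Default 0.01 Th.
#' @param intensity_threshold candidates with inferred intensity strictly
#'   below this are removed in post-processing. Default 100.
#' @param confidence_threshold default confidence score cut used when
#'   reporting (the FDR sweep may choose a different one). Default 0.2.
#' @param max_fdr maximum tolerated FDR for the threshold sweep. Default 0.20.
#' @param isotope_min_abundance isotopologue peaks with abundance (as a
#'   fraction of the total distribution) at or below this are dropped from
#'   envelopes, without renormalisation. Default 0.01.
#' @param im_length_percentile percentile of experimental 1/K0 lengths used
#'   as the ion-mobility half-window padding term. Default 99.9.
#' @param rt_holdout_fraction fraction of the experiment library held out to
#'   estimate retention-time / ion-mobility calibration error. Default 0.10.
#' @param image_size side length of the square model input images. Default 258.
#' @param random_seed master seed; all stage randomness is fanned out from it.
#' @param epochs maximum training epochs. Default 100.
#' @param patience early-stopping patience in epochs. Default 10.
#' @param split train/validation/test proportions (length-3, sums to 1).
#'   Default 8:1:1.
#' @param loss_weights named weights of the segmentation combo loss
#'   (binary cross-entropy, dice, focal). Default c(bce = 1, dice = 4,
#'   focal = 1).
#' @param mask_threshold probability cut for binarising segmentation output.
#'   Default 0.5.
#' @param batch_size minibatch size for model training. Default 32.
#' @param max_lr peak learning rate of the one-cycle schedule. Default 0.03.
#' @param nnls_tol convergence tolerance of the non-negative least squares
#'   solver. Default 1e-10.
#' @param decoy_closeness_tol neutral-mass tolerance (Th scale, multiplied by
#'   charge at use) under which a decoy's isotope pattern counts as "close"
#'   to its target's; NULL means mz_bin_width is used. Default NULL.
#' @param im_delta_experimental cross-library 1/K0 95th-percentile deviation
#'   used when experimental ion mobilities are taken from the reference
#'   library. Default 0.025.
#' @param log_eps value added to activations before log10. Default 1.
#' @param ... further named fields stored verbatim (forward compatibility).
#'
#' @return A list of class `ms1prop_config`.
#' @export
ms1prop_config <- function(mz_bin_width = 0.01,
                           intensity_threshold = 100,
                           confidence_threshold = 0.2,
                           max_fdr = 0.20,
                           isotope_min_abundance = 0.01,
                           im_length_percentile = 99.9,
                           rt_holdout_fraction = 0.10,
                           image_size = 258,
                           random_seed = 1L,
                           epochs = 100L,
                           patience = 10L,
                           split = c(train = 0.8, validation = 0.1, test = 0.1),
                           loss_weights = c(bce = 1, dice = 4, focal = 1),
                           mask_threshold = 0.5,
                           batch_size = 32L,
                           max_lr = 0.03,
                           nnls_tol = 1e-10,
                           decoy_closeness_tol = NULL,
                           im_delta_experimental = 0.025,
                           log_eps = 1,
                           ...) {
  cfg <- list(
    mz_bin_width = mz_bin_width,
    intensity_threshold = intensity_threshold,
    confidence_threshold = confidence_threshold,
    max_fdr = max_fdr,
    isotope_min_abundance = isotope_min_abundance,
    im_length_percentile = im_length_percentile,
    rt_holdout_fraction = rt_holdout_fraction,
    image_size = image_size,
    random_seed = as.integer(random_seed),
    epochs = as.integer(epochs),
    patience = as.integer(patience),
    split = split,
    loss_weights = loss_weights,
    mask_threshold = mask_threshold,
    batch_size = as.integer(batch_size),
    max_lr = max_lr,
    nnls_tol = nnls_tol,
    decoy_closeness_tol = decoy_closeness_tol,
    im_delta_experimental = im_delta_experimental,
    log_eps = log_eps
  )
  extra <- list(...)
  cfg[names(extra)] <- extra
  stopifnot(
    mz_bin_width > 0,
    intensity_threshold >= 0, confidence_threshold >= 0,
    max_fdr >= 0, isotope_min_abundance >= 0,
    rt_holdout_fraction > 0, rt_holdout_fraction < 1,
    image_size >= 2,
    abs(sum(split) - 1) < 1e-8
  )
  class(cfg) <- "ms1prop_config"
  cfg
}

#' Read a configuration file
#'
#' Flat key-value YAML; unknown keys are carried along, missing keys take
#' their defaults.
#'
#' @param path YAML file.
#' @return `ms1prop_config`
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$split)) vals$split <- unlist(vals$split)
  if (!is.null(vals$loss_weights)) vals$loss_weights <- unlist(vals$loss_weights)
  do.call(ms1prop_config, vals)
}

#' Write a configuration file
#'
#' @param config `ms1prop_config`
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  vals <- unclass(config)
  vals$split <- as.list(vals$split)
  vals$loss_weights <- as.list(vals$loss_weights)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Derive a named sub-seed from the master seed
#'
#' Every stage with randomness draws its own seed deterministically from the
#' master seed and its stage name, so stages can be re-run in isolation
#' without perturbing one another.
#'
#' @param config `ms1prop_config` (or a bare integer master seed).
#' @param stage character stage name.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(config, stage) {
  seed <- if (inherits(config, "ms1prop_config")) config$random_seed else as.integer(config)
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 1000000007
  as.integer((seed %% 65011 + 1) * 32749 + h) %% 2147483646L
}

#' @export
print.ms1prop_config <- function(x, ...) {
  cat("<ms1prop_config>\n")
  flat <- vapply(
    x, function(v) paste(format(v, digits = 6), collapse = "/"),
    character(1)
  )
  cat(paste0("  ", format(names(flat)), " : ", flat, collapse = "\n"), "\n")
  invisible(x)
}

# one structured log line per stage: "stage | in=<n> out=<m> | note"
stage_log <- function(stage, n_in, n_out, note = "", quiet = FALSE) {
  if (!quiet) {
    message(sprintf("[%s] in=%d out=%d%s", stage, n_in, n_out,
                    if (nzchar(note)) paste0(" | ", note) else ""))
  }
  data.frame(stage = stage, n_in = n_in, n_out = n_out, note = note,
             stringsAsFactors = FALSE)
}
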