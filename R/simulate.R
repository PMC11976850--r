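# Synthetic libraries and MS1 runs with known ground truth, emulating the
# defined-ratio multi-species (human/yeast/E. coli) mixture design.
#
# Peaks are separable Gaussian elution x ion-mobility profiles of the
# candidate's isotope envelope, truncated at +/- 4 sigma with the discrete
# profile renormalised so the deposited total matches the ledger exactly.

AA_POOL <- c("A", "D", "E", "F", "G", "H", "I", "L", "M", "N",
             "P", "Q", "S", "T", "V", "W", "Y")
AA_FREQ <- c(8.3, 5.4, 6.8, 3.9, 7.1, 2.3, 6.0, 9.7, 2.4, 4.1,
             4.7, 4.0, 6.6, 5.4, 6.9, 1.1, 2.9)

#' Species mixture specification
#'
#' Fractions per condition; each condition must sum to 1. The canonical
#' two-condition design is condition A = 65% human / 30% yeast / 5%
#' E. coli and condition B = 65% / 15% / 20%.
#'
#' @param ... named numeric vectors, one per condition.
#' @return object of class `mixture_spec`.
#' @export
mixture_spec <- function(...) {
  conditions <- list(...)
  stopifnot(length(conditions) >= 1)
  for (nm in names(conditions)) {
    if (abs(sum(conditions[[nm]]) - 1) > 1e-8) {
      stop("fractions of condition ", nm, " must sum to 1")
    }
  }
  structure(conditions, class = "mixture_spec")
}

#' Default two-condition three-species mixture
#'
#' @return `mixture_spec` with conditions A (human 0.65, yeast 0.30,
#'   ecoli 0.05) and B (human 0.65, yeast 0.15, ecoli 0.20).
#' @export
default_hye_mixture <- function() {
  mixture_spec(A = c(human = 0.65, yeast = 0.30, ecoli = 0.05),
               B = c(human = 0.65, yeast = 0.15, ecoli = 0.20))
}

random_tryptic_sequence <- function(len) {
  interior <- sample(AA_POOL, len - 1, replace = TRUE, prob = AA_FREQ)
  paste0(paste(interior, collapse = ""), sample(c("K", "R"), 1))
}

#' Simulate an evidence library with ground truth
#'
#' Draws `n` unique (sequence, charge) precursors with tryptic-like random
#' sequences (length 7-30, C-terminal K/R), retention time uniform over
#' the gradient, ion mobility correlated with m/z and charge, log10
#' intensities normal, and 1/K0 lengths log-normal with median 0.072 and
#' 75th percentile 0.096 at defaults. Species labels follow the mixture
#' fractions of the chosen condition.
#'
#' @param n number of precursors.
#' @param gradient_length gradient length in minutes. Default 30.
#' @param seed RNG seed.
#' @param mixture optional `mixture_spec`; labels use `condition`.
#' @param condition condition name within `mixture`. Default first.
#' @param rt_length_median median elution length in minutes (absolute,
#'   independent of gradient length). Default 0.16.
#' @param im_length_median,im_length_q75 targets of the 1/K0 length
#'   distribution. Defaults 0.072 / 0.096.
#' @param log10_intensity_mean,log10_intensity_sd intensity distribution.
#'   Defaults 5.5 / 0.6.
#' @return list with `evidence` (data.frame, source = "experiment") and
#'   `ledger` (ground-truth data.frame).
#' @export
simulate_library <- function(n, gradient_length = 30, seed = 1L,
                             mixture = NULL, condition = NULL,
                             rt_length_median = 0.16,
                             im_length_median = 0.072,
                             im_length_q75 = 0.096,
                             log10_intensity_mean = 5.5,
                             log10_intensity_sd = 0.6) {
  stopifnot(n >= 1)
  set.seed(seed)
  seqs <- character(0)
  charges <- integer(0)
  while (length(seqs) < n) {
    need <- n - length(seqs)
    new_seq <- vapply(sample(7:30, need, replace = TRUE),
                      random_tryptic_sequence, character(1))
    new_z <- sample(c(2L, 3L, 4L), need, replace = TRUE,
                    prob = c(0.6, 0.3, 0.1))
    key <- paste(c(seqs, new_seq), c(charges, new_z))
    keep <- !duplicated(key)
    seqs <- c(seqs, new_seq)[keep]
    charges <- c(charges, new_z)[keep]
  }
  mono <- vapply(seqs, monoisotopic_mass, numeric(1), USE.NAMES = FALSE)
  mz <- (mono + charges * PROTON_MASS) / charges
  rt_apex <- stats::runif(n, 0.02, 0.98) * gradient_length
  rt_len <- stats::rlnorm(n, log(rt_length_median), 0.35)
  rt_sigma <- rt_len / 4
  sdlog_im <- log(im_length_q75 / im_length_median) / stats::qnorm(0.75)
  im_len <- stats::rlnorm(n, log(im_length_median), sdlog_im)
  im_sigma <- im_len / 4
  im_center <- 0.55 + 0.0005 * mz + 0.03 * (charges - 2) +
    stats::rnorm(n, 0, 0.015)
  im_center <- pmin(pmax(im_center, 0.7), 1.4)
  intensity <- 10^stats::rnorm(n, log10_intensity_mean, log10_intensity_sd)
  species <- if (is.null(mixture)) {
    rep("human", n)
  } else {
    if (is.null(condition)) condition <- names(mixture)[1]
    fr <- mixture[[condition]]
    sample(names(fr), n, replace = TRUE, prob = fr)
  }
  evidence <- data.frame(
    modified_sequence = seqs, charge = charges,
    rt_obs = rt_apex, rt_start = rt_apex - rt_len / 2,
    rt_end = rt_apex + rt_len / 2,
    im_center = im_center, im_length = im_len,
    intensity = intensity, species = species,
    source = "experiment", stringsAsFactors = FALSE
  )
  ledger <- data.frame(
    modified_sequence = seqs, charge = charges, species = species,
    true_total = intensity, rt_apex = rt_apex, rt_sigma = rt_sigma,
    im_center = im_center, im_sigma = im_sigma, mono_mz = mz,
    stringsAsFactors = FALSE
  )
  list(evidence = evidence, ledger = ledger)
}

#' Simulate MS1 frames from a ground-truth ledger
#'
#' Each precursor deposits `total x w_rt(T) x w_im(col) x abundance` at
#' every (frame, 1/K0 grid point, isotope m/z) triple, where the discrete
#' Gaussian weights `w` are truncated at +/- 4 sigma and normalised to sum
#' to 1, so the deposited total equals `true_total x sum(abundance)`
#' exactly in noiseless mode. Optional noise adds uniform-m/z points with
#' exponential intensities; noise never alters the ledger.
#'
#' @param ledger ground-truth data.frame from [simulate_library()].
#' @param gradient_length run length in minutes.
#' @param frame_interval scan spacing in minutes. Default 0.02.
#' @param im_grid 1/K0 grid; default `seq(0.7, 1.45, by = 0.005)`.
#' @param noise_points noise points per frame. Default 0.
#' @param noise_mean mean exponential noise intensity. Default 50.
#' @param min_abundance,mz_bin_width envelope parameters.
#' @param seed RNG seed (noise only).
#' @return list with `frames` (list of `ms1_frame`), `im_grid`,
#'   `envelopes` (keyed by "sequence charge"), and `truth` (per precursor:
#'   deposited totals and the deposit inside the evidence-style label
#'   rectangle apex +/- 2 sigma in both axes).
#' @export
simulate_ms1_frames <- function(ledger, gradient_length,
                                frame_interval = 0.02, im_grid = NULL,
                                noise_points = 0, noise_mean = 50,
                                min_abundance = 0.01, mz_bin_width = 0.01,
                                seed = 1L) {
  set.seed(seed)
  if (is.null(im_grid)) im_grid <- seq(0.7, 1.45, by = 0.005)
  scan_times <- seq(frame_interval / 2, gradient_length, by = frame_interval)
  n_frames <- length(scan_times)
  frame_pts <- vector("list", n_frames)
  for (i in seq_len(n_frames)) frame_pts[[i]] <- list()
  envelopes <- list()
  truth <- ledger
  truth$envelope_sum <- NA_real_
  truth$deposited_total <- 0
  truth$deposited_in_rect <- 0
  for (p in seq_len(nrow(ledger))) {
    key <- paste(ledger$modified_sequence[p], ledger$charge[p])
    if (is.null(envelopes[[key]])) {
      envelopes[[key]] <- compute_isotope_envelope(
        ledger$modified_sequence[p], ledger$charge[p],
        min_abundance = min_abundance, mz_bin_width = mz_bin_width
      )
    }
    env <- envelopes[[key]]
    truth$envelope_sum[p] <- sum(env$peaks$abundance)
    apex <- ledger$rt_apex[p]; s_rt <- ledger$rt_sigma[p]
    ctr <- ledger$im_center[p]; s_im <- ledger$im_sigma[p]
    fr <- which(abs(scan_times - apex) <= 4 * s_rt)
    if (length(fr) == 0) next
    w_rt <- stats::dnorm(scan_times[fr], apex, s_rt)
    w_rt <- w_rt / sum(w_rt)
    gi <- which(abs(im_grid - ctr) <= 4 * s_im)
    if (length(gi) == 0) gi <- which.min(abs(im_grid - ctr))
    w_im <- stats::dnorm(im_grid[gi], ctr, s_im)
    w_im <- w_im / sum(w_im)
    total <- ledger$true_total[p]
    in_rt <- abs(scan_times[fr] - apex) <= 2 * s_rt
    in_im <- abs(im_grid[gi] - ctr) <= 2 * s_im
    truth$deposited_total[p] <- total * sum(env$peaks$abundance)
    truth$deposited_in_rect[p] <- total * sum(w_rt[in_rt]) *
      sum(w_im[in_im]) * sum(env$peaks$abundance)
    for (fi in seq_along(fr)) {
      amp <- total * w_rt[fi]
      pts <- data.frame(
        mz = rep(env$peaks$mz, times = length(gi)),
        im = rep(im_grid[gi], each = nrow(env$peaks)),
        intensity = amp * as.vector(outer(env$peaks$abundance, w_im))
      )
      frame_pts[[fr[fi]]][[length(frame_pts[[fr[fi]]]) + 1]] <- pts
    }
  }
  mz_range <- range(unlist(lapply(envelopes, function(e) e$peaks$mz)),
                    na.rm = TRUE) + c(-5, 5)
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    pts <- if (length(frame_pts[[i]])) {
      do.call(rbind, frame_pts[[i]])
    } else {
      data.frame(mz = numeric(0), im = numeric(0), intensity = numeric(0))
    }
    if (noise_points > 0) {
      noise <- data.frame(
        mz = stats::runif(noise_points, mz_range[1], mz_range[2]),
        im = sample(im_grid, noise_points, replace = TRUE),
        intensity = stats::rexp(noise_points, 1 / noise_mean)
      )
      pts <- rbind(pts, noise)
    }
    frames[[i]] <- ms1_frame(i, scan_times[i], pts)
  }
  list(frames = frames, im_grid = im_grid, envelopes = envelopes,
       truth = truth)
}

#' Simulate a two-condition run pair with species-scaled intensities
#'
#' A shared precursor set is drawn once; per-species intensity ratios
#' between the two runs follow the mixture fractions (fold map =
#' fraction in B / fraction in A).
#'
#' @param mixture `mixture_spec` with exactly two conditions.
#' @param n precursors.
#' @param seed RNG seed.
#' @param gradient_length minutes. Default 2.
#' @param frame_interval minutes. Default 0.02.
#' @param ... further arguments to [simulate_ms1_frames()].
#' @return list with `evidence`, per-condition `ledgers`, `runs` (frame
#'   simulations) and `fold_map`.
#' @export
simulate_condition_pair <- function(mixture = default_hye_mixture(), n = 100,
                                    seed = 1L, gradient_length = 2,
                                    frame_interval = 0.02, ...) {
  stopifnot(length(mixture) == 2)
  cond <- names(mixture)
  fold_map <- mixture[[cond[2]]][names(mixture[[cond[1]]])] /
    mixture[[cond[1]]]
  lib <- simulate_library(n, gradient_length, seed = seed, mixture = mixture,
                          condition = cond[1])
  ledgers <- list()
  ledgers[[cond[1]]] <- lib$ledger
  ledger_b <- lib$ledger
  ledger_b$true_total <- ledger_b$true_total *
    fold_map[ledger_b$species]
  ledgers[[cond[2]]] <- ledger_b
  runs <- list()
  runs[[cond[1]]] <- simulate_ms1_frames(ledgers[[cond[1]]], gradient_length,
                                         frame_interval,
                                         seed = seed + 1L, ...)
  runs[[cond[2]]] <- simulate_ms1_frames(ledgers[[cond[2]]], gradient_length,
                                         frame_interval,
                                         seed = seed + 2L, ...)
  list(evidence = lib$evidence, ledgers = ledgers, runs = runs,
       fold_map = fold_map)
}

# shuffle interior residues, preserving composition (isobaric partner)
permute_interior <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  mid <- chars[2:(n - 1)]
  chars[2:(n - 1)] <- sample(mid)
  paste(chars, collapse = "")
}

#' Write a ready-to-run fixture bundle
#'
#' Generates a library, frames and configuration for one of the presets
#' and writes them in the pipeline's file formats:
#' \describe{
#'   \item{tiny}{40 precursors, 6 min gradient, 60 frames; noiseless.}
#'   \item{mbr}{experiment library is a 60\% subset; reference library
#'     carries all precursors with warped retention times, exercising
#'     LOWESS alignment.}
#'   \item{hye}{three-species mixture labels with condition-A fractions.}
#'   \item{interference}{about a third of precursors get an isobaric
#'     partner (composition-preserving interior permutation) at distinct
#'     ion mobility, so at least 20\% share an m/z bin.}
#' }
#'
#' @param out_dir output directory.
#' @param preset one of "tiny", "mbr", "hye", "interference".
#' @param seed RNG seed. Default 1.
#' @param force overwrite a non-empty directory. Default FALSE.
#' @return named list of file paths, invisibly.
#' @export
write_fixture_bundle <- function(out_dir,
                                 preset = c("tiny", "mbr", "hye",
                                            "interference"),
                                 seed = 1L, force = FALSE) {
  preset <- match.arg(preset)
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    stop("output directory not empty (use force = TRUE): ", out_dir)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gradient <- 1.2
  frame_interval <- 0.02
  n <- 40
  mixture <- if (preset == "hye") default_hye_mixture() else NULL
  lib <- simulate_library(n, gradient, seed = seed, mixture = mixture,
                          condition = if (!is.null(mixture)) "A" else NULL)
  evidence <- lib$evidence
  ledger <- lib$ledger
  if (preset == "interference") {
    set.seed(seed + 17L)
    pick <- which(nchar(ledger$modified_sequence) >= 8)
    pick <- pick[seq_len(max(1, round(length(pick) * 0.35)))]
    extra_ev <- evidence[pick, , drop = FALSE]
    extra_ld <- ledger[pick, , drop = FALSE]
    for (i in seq_along(pick)) {
      partner <- permute_interior(extra_ld$modified_sequence[i])
      extra_ev$modified_sequence[i] <- partner
      extra_ld$modified_sequence[i] <- partner
      shift_im <- sample(c(-1, 1), 1) * stats::runif(1, 0.05, 0.1)
      extra_ev$im_center[i] <- extra_ev$im_center[i] + shift_im
      extra_ld$im_center[i] <- extra_ld$im_center[i] + shift_im
      shift_rt <- sample(c(-1, 1), 1) * stats::runif(1, 0.15, 0.4)
      for (col in c("rt_obs", "rt_start", "rt_end")) {
        extra_ev[[col]][i] <- min(max(extra_ev[[col]][i] + shift_rt, 0.1),
                                  gradient - 0.1)
      }
      extra_ld$rt_apex[i] <- extra_ev$rt_obs[i]
    }
    dup <- paste(extra_ev$modified_sequence, extra_ev$charge) %in%
      paste(evidence$modified_sequence, evidence$charge)
    evidence <- rbind(evidence, extra_ev[!dup, , drop = FALSE])
    ledger <- rbind(ledger, extra_ld[!dup, , drop = FALSE])
    ledger$mono_mz <- (vapply(ledger$modified_sequence, monoisotopic_mass,
                              numeric(1), USE.NAMES = FALSE) +
                         ledger$charge * PROTON_MASS) / ledger$charge
  }
  sim <- simulate_ms1_frames(ledger, gradient, frame_interval,
                             noise_points = if (preset == "tiny") 0 else 20,
                             seed = seed + 2L)
  reference <- NULL
  if (preset == "mbr") {
    set.seed(seed + 5L)
    keep <- sort(sample(nrow(evidence), round(0.6 * nrow(evidence))))
    reference <- evidence
    reference$source <- "reference"
    # mild monotone RT warp emulating a different gradient
    reference$rt_obs <- reference$rt_obs * 1.05 + 0.3
    reference$rt_start <- reference$rt_start * 1.05 + 0.3
    reference$rt_end <- reference$rt_end * 1.05 + 0.3
    evidence <- evidence[keep, , drop = FALSE]
  }
  paths <- list(
    experiment_library = file.path(out_dir, "experiment_library.tsv"),
    frames = file.path(out_dir, "frames.tsv"),
    ledger = file.path(out_dir, "ledger.tsv"),
    config = file.path(out_dir, "config.yaml")
  )
  write_evidence_table(evidence, paths$experiment_library)
  write_frames(sim$frames, paths$frames)
  utils::write.table(sim$truth, paths$ledger, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(reference)) {
    paths$reference_library <- file.path(out_dir, "reference_library.tsv")
    write_evidence_table(reference, paths$reference_library)
  }
  cfg <- ms1prop_config(random_seed = seed, image_size = 64)
  cfg$experiment_library <- paths$experiment_library
  cfg$reference_library <- paths$reference_library
  cfg$frames <- paths$frames
  cfg$preset <- preset
  write_config(cfg, paths$config)
  invisible(paths)
}
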