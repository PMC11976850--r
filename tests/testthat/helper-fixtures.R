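# Shared fixture builders. Everything is generated in code at test time.

# explicit toy mutation map so decoy tests never depend on the packaged
# default mapping
toy_mutation_map <- function() {
  c(E = "D", D = "E", I = "V", V = "I", P = "L", L = "P", T = "S", S = "T",
    G = "A", A = "G", K = "R", R = "K", F = "Y", Y = "F", N = "Q", Q = "N",
    M = "C", C = "M", W = "H", H = "W")
}

# independent residue monoisotopic mass table (literature values), used as
# the oracle against the composition-based masses
ORACLE_RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)
ORACLE_WATER <- 18.010565
ORACLE_PROTON <- 1.0072765

oracle_peptide_mass <- function(seq) {
  sum(ORACLE_RESIDUE_MASS[strsplit(seq, "")[[1]]]) + ORACLE_WATER
}

random_sequences <- function(n, len_range = 7:20, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    len <- sample(len_range, 1)
    paste(c(sample(names(ORACLE_RESIDUE_MASS)[1:17], len - 1, TRUE),
            sample(c("K", "R"), 1)), collapse = "")
  }, character(1))
}

# minimal well-formed evidence data.frame
make_evidence <- function(seqs, charges = 2L, rt = NULL, intensity = 1e5,
                          source = "experiment") {
  n <- length(seqs)
  if (is.null(rt)) rt <- seq(5, 25, length.out = n)
  data.frame(
    modified_sequence = seqs, charge = rep_len(charges, n),
    rt_obs = rt, rt_start = rt - 0.1, rt_end = rt + 0.1,
    im_center = seq(0.9, 1.1, length.out = n),
    im_length = rep(0.07, n),
    intensity = rep_len(intensity, n),
    species = NA_character_, source = source,
    stringsAsFactors = FALSE
  )
}

# synthetic scan dictionary with random envelopes (no chemistry involved)
make_random_scan_dict <- function(n_cand, n_bins = 400, seed = 1) {
  set.seed(seed)
  bins <- integer(0); cols <- integer(0); ab <- numeric(0)
  for (j in seq_len(n_cand)) {
    k <- sample(3:5, 1)
    b <- sort(sample.int(n_bins, k))
    bins <- c(bins, b)
    cols <- c(cols, rep.int(j, k))
    a <- runif(k)
    ab <- c(ab, a / sum(a))
  }
  structure(list(cand_ids = seq_len(n_cand), bin = bins, col = cols,
                 abundance = ab),
            class = "scan_dictionary")
}

# a separable labelled image pool: targets carry a Gaussian peak at the
# hint with a rectangle label, decoys an off-hint peak and an empty label
make_peak_pool <- function(n, size = 48, m = 30, k = 24, seed = 1,
                           decoy_fraction = 0.5) {
  set.seed(seed)
  pool <- vector("list", n)
  for (i in seq_len(n)) {
    is_decoy <- i > n * (1 - decoy_fraction)
    rt_coords <- seq(10, 12, length.out = m)
    im_coords <- seq(0.9, 1.0, length.out = k)
    cr <- runif(1, 11, 11.4)  # true peak location
    cc <- runif(1, 0.93, 0.97)
    sr <- 0.06; sc <- 0.008
    peak <- outer(exp(-(rt_coords - cr)^2 / (2 * sr^2)),
                  exp(-(im_coords - cc)^2 / (2 * sc^2))) *
      10^runif(1, 3, 5)
    vals <- peak + matrix(runif(m * k, 0, 2), m, k)
    # an interfering blob away from the true peak
    ir <- cr + sample(c(-1, 1), 1) * runif(1, 0.35, 0.5)
    ic <- cc + sample(c(-1, 1), 1) * runif(1, 0.025, 0.04)
    vals <- vals + outer(exp(-(rt_coords - ir)^2 / (2 * sr^2)),
                         exp(-(im_coords - ic)^2 / (2 * sc^2))) *
      10^runif(1, 2.5, 4.5)
    img <- precursor_image(vals, rt_coords, im_coords, candidate_id = i)
    if (is_decoy) {
      # hint points away from any signal
      hint <- c(cr - sample(c(-1, 1), 1) * 0.45, cc + 0.035)
      label <- matrix(0, size, size)
    } else {
      hint <- c(cr + rnorm(1, 0, 0.01), cc + rnorm(1, 0, 0.002))
      label <- NULL
    }
    input <- build_model_input(img, hint, competitor_hints = rbind(c(ir, ic)),
                               size = size)
    if (is.null(label)) {
      label <- rasterize_label(list(rt_start = cr - 2 * sr,
                                    rt_end = cr + 2 * sr,
                                    im_lo = cc - 2 * sc, im_hi = cc + 2 * sc),
                               input)
    }
    pool[[i]] <- list(input = input, label = label, image = img,
                      is_decoy = is_decoy,
                      rect = list(rt_start = cr - 2 * sr, rt_end = cr + 2 * sr,
                                  im_lo = cc - 2 * sc, im_hi = cc + 2 * sc))
  }
  pool
}

# scored-candidate table for FDR calibration: correct targets score high;
# planted incorrect targets and decoys draw from the same null
make_calibration_scored <- function(n_correct, n_incorrect, seed = 1) {
  set.seed(seed)
  n_t <- n_correct + n_incorrect
  conf_t <- c(rbeta(n_correct, 8, 2), rbeta(n_incorrect, 2, 6))
  conf_d <- rbeta(n_t, 2, 6)
  data.frame(
    id = c(seq_len(n_t), n_t + seq_len(n_t)),
    pair_id = c(rep(NA_integer_, n_t), seq_len(n_t)),
    is_decoy = rep(c(FALSE, TRUE), each = n_t),
    planted_incorrect = c(rep(c(FALSE, TRUE), c(n_correct, n_incorrect)),
                          rep(NA, n_t)),
    mono_bin = seq_len(2 * n_t),  # no signal competition by construction
    rt_pred = runif(2 * n_t, 0, 30),
    im_center = runif(2 * n_t, 0.8, 1.3),
    inferred_intensity = 10^runif(2 * n_t, 3, 6),
    confidence = c(conf_t, conf_d)
  )
}

quiet <- function(expr) suppressMessages(expr)
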