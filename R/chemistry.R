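# Peptide elemental composition and aggregated isotope envelopes.
#
# Compositions are counts over C/H/N/O/S. Envelopes are computed by exact
# convolution of per-element isotope distributions aggregated by neutron
# count; each aggregated peak carries its abundance-weighted mean mass.
# The monoisotopic (zero extra neutrons) peak mass is exact.

MONO_MASS <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
               O = 15.9949146196, S = 31.97207100)
PROTON_MASS <- 1.007276466879
NEUTRON_SPACING <- 1.00335483778  # 13C - 12C, the envelope peak spacing

# residue compositions (peptide-bond residues; add H2O once per peptide)
RESIDUE_COMP <- list(
  G = c(C = 2, H = 3,  N = 1, O = 1, S = 0),
  A = c(C = 3, H = 5,  N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5,  N = 1, O = 2, S = 0),
  P = c(C = 5, H = 7,  N = 1, O = 1, S = 0),
  V = c(C = 5, H = 9,  N = 1, O = 1, S = 0),
  T = c(C = 4, H = 7,  N = 1, O = 2, S = 0),
  C = c(C = 3, H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4, H = 6,  N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5,  N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8,  N = 2, O = 2, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5, H = 7,  N = 1, O = 3, S = 0),
  M = c(C = 5, H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7,  N = 3, O = 1, S = 0),
  F = c(C = 9, H = 9,  N = 1, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9, H = 9,  N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

# supported modification deltas (bracketed notation in sequences)
MOD_COMP <- list(
  cam = c(C = 2, H = 3, N = 1, O = 1, S = 0),  # carbamidomethyl (C)
  ox  = c(C = 0, H = 0, N = 0, O = 1, S = 0),  # oxidation (M)
  ac  = c(C = 2, H = 2, N = 0, O = 1, S = 0)   # N-terminal acetyl
)

WATER_COMP <- c(C = 0, H = 2, N = 0, O = 1, S = 0)

# isotope tables: extra neutron count, mass, natural abundance
ISOTOPES <- list(
  C = data.frame(k = c(0, 1),
                 mass = c(12.0, 13.00335483778),
                 p = c(0.9893, 0.0107)),
  H = data.frame(k = c(0, 1),
                 mass = c(1.00782503207, 2.01410177785),
                 p = c(0.999885, 0.000115)),
  N = data.frame(k = c(0, 1),
                 mass = c(14.0030740048, 15.0001088982),
                 p = c(0.99636, 0.00364)),
  O = data.frame(k = c(0, 1, 2),
                 mass = c(15.9949146196, 16.9991317012, 17.9991610070),
                 p = c(0.99757, 0.00038, 0.00205)),
  S = data.frame(k = c(0, 1, 2, 4),
                 mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
                 p = c(0.9499, 0.0075, 0.0425, 0.0001))
)

#' Strip modification annotations from a modified sequence
#'
#' @param modified_sequence sequence with optional bracketed modifications,
#'   e.g. `"[ac]PEPTM[ox]IDE"`.
#' @return the plain amino-acid string.
#' @export
strip_modifications <- function(modified_sequence) {
  gsub("\\[[^]]*\\]", "", modified_sequence)
}

parse_modified_sequence <- function(modified_sequence) {
  s <- modified_sequence
  mods <- character(0)
  # leading N-terminal mod
  m <- regmatches(s, regexpr("^\\[[^]]*\\]", s))
  if (length(m) == 1 && nzchar(m)) {
    mods <- c(mods, substr(m, 2, nchar(m) - 1))
    s <- sub("^\\[[^]]*\\]", "", s)
  }
  residues <- character(0)
  i <- 1
  while (i <= nchar(s)) {
    ch <- substr(s, i, i)
    if (ch == "[") {
      j <- regexpr("\\]", substr(s, i, nchar(s)))
      if (j < 0) stop("unbalanced '[' in sequence: ", modified_sequence)
      mods <- c(mods, substr(s, i + 1, i + j - 2))
      i <- i + j
    } else {
      residues <- c(residues, ch)
      i <- i + 1
    }
  }
  list(residues = residues, mods = mods)
}

#' Elemental composition of a modified peptide
#'
#' Sums residue compositions plus one water plus any modification deltas.
#' Cysteines are assumed carbamidomethylated when `fixed_cam` is TRUE (the
#' usual fixed modification), without requiring explicit `[cam]` tags.
#'
#' @param modified_sequence peptide with bracketed modifications; supported
#'   tags are `[cam]`, `[ox]` and N-terminal `[ac]`.
#' @param fixed_cam treat every C as carbamidomethylated. Default FALSE.
#' @return named integer vector over C, H, N, O, S.
#' @export
peptide_composition <- function(modified_sequence, fixed_cam = FALSE) {
  parsed <- parse_modified_sequence(modified_sequence)
  unknown <- setdiff(parsed$residues, names(RESIDUE_COMP))
  if (length(unknown)) {
    stop("unknown residue(s): ", paste(unique(unknown), collapse = ", "))
  }
  comp <- WATER_COMP
  for (r in parsed$residues) comp <- comp + RESIDUE_COMP[[r]]
  mods <- parsed$mods
  if (fixed_cam) mods <- c(mods, rep("cam", sum(parsed$residues == "C")))
  for (m in mods) {
    if (!m %in% names(MOD_COMP)) stop("unknown modification: [", m, "]")
    comp <- comp + MOD_COMP[[m]]
  }
  comp
}

#' Monoisotopic neutral mass of a composition or sequence
#'
#' @param x either a composition vector (from [peptide_composition()]) or a
#'   modified sequence string.
#' @param fixed_cam passed to [peptide_composition()] when `x` is a string.
#' @return neutral monoisotopic mass in Da.
#' @export
monoisotopic_mass <- function(x, fixed_cam = FALSE) {
  if (is.character(x)) x <- peptide_composition(x, fixed_cam = fixed_cam)
  sum(x * MONO_MASS[names(x)])
}

# distribution of one element repeated n times, aggregated by neutron count;
# columns k (extra neutrons), p (probability), mass (weighted mean mass sum)
element_distribution <- function(element, n, prune = 1e-12) {
  iso <- ISOTOPES[[element]]
  base <- list(k = iso$k, p = iso$p, m = iso$mass)
  acc <- list(k = 0, p = 1, m = 0)
  # binary exponentiation over convolution
  while (n > 0) {
    if (n %% 2 == 1) acc <- convolve_dist(acc, base, prune)
    n <- n %/% 2
    if (n > 0) base <- convolve_dist(base, base, prune)
  }
  acc
}

convolve_dist <- function(a, b, prune = 1e-12) {
  k <- outer(a$k, b$k, `+`)
  p <- outer(a$p, b$p)
  m <- outer(a$m, b$m, `+`)
  keep <- p > 0
  k <- k[keep]; p <- p[keep]; m <- m[keep]
  # aggregate by neutron count; mean mass weighted by probability
  ks <- sort(unique(k))
  pi <- vapply(ks, function(kk) sum(p[k == kk]), numeric(1))
  mi <- vapply(ks, function(kk) {
    sum(p[k == kk] * m[k == kk]) / sum(p[k == kk])
  }, numeric(1))
  keep <- pi > prune
  list(k = ks[keep], p = pi[keep], m = mi[keep])
}

#' Aggregated isotopologue distribution of a composition
#'
#' Exact convolution over elements, aggregated by total extra neutron count.
#' The zero-neutron peak mass equals the monoisotopic mass exactly; higher
#' peaks carry abundance-weighted mean masses.
#'
#' @param comp composition vector over C, H, N, O, S.
#' @param prune drop aggregated isotopologues below this probability during
#'   convolution. Default 1e-12.
#' @return data.frame with columns `k` (extra neutrons), `mass` (neutral Da)
#'   and `p` (probability); probabilities sum to ~1.
#' @export
isotopologue_distribution <- function(comp, prune = 1e-12) {
  acc <- list(k = 0, p = 1, m = 0)
  for (el in names(comp)) {
    if (comp[[el]] > 0) {
      acc <- convolve_dist(acc, element_distribution(el, comp[[el]], prune),
                           prune)
    }
  }
  ord <- order(acc$k)
  data.frame(k = acc$k[ord], mass = acc$m[ord], p = acc$p[ord])
}

#' Isotope envelope of a charged precursor
#'
#' Computes the aggregated isotopologue distribution, converts to m/z,
#' aggregates probabilities into the run's m/z bins, and discards peaks with
#' abundance at or below `min_abundance` of the total distribution. The
#' retained abundances are NOT renormalised, so activation coefficients stay
#' comparable across candidates.
#'
#' @param modified_sequence modified peptide string.
#' @param charge positive integer charge.
#' @param min_abundance abundance threshold (fraction of total). Default 0.01.
#' @param mz_bin_width bin width in Th for aggregation. Default 0.01.
#' @param fixed_cam treat C residues as carbamidomethylated.
#' @return object of class `isotope_envelope`: list with `peaks`
#'   (data.frame mz, bin, abundance, sorted by mz), `mono_mz`, `mono_mass`,
#'   `charge`.
#' @export
compute_isotope_envelope <- function(modified_sequence, charge,
                                     min_abundance = 0.01,
                                     mz_bin_width = 0.01,
                                     fixed_cam = FALSE) {
  stopifnot(charge >= 1)
  comp <- peptide_composition(modified_sequence, fixed_cam = fixed_cam)
  dist <- isotopologue_distribution(comp)
  mz <- (dist$mass + charge * PROTON_MASS) / charge
  bin <- floor(mz / mz_bin_width)
  # aggregate per bin (abundance-weighted mean m/z within the bin)
  agg_p <- tapply(dist$p, bin, sum)
  agg_mz <- tapply(dist$p * mz, bin, sum) / agg_p
  keep <- agg_p > min_abundance
  peaks <- data.frame(mz = as.numeric(agg_mz[keep]),
                      bin = as.integer(names(agg_p))[keep],
                      abundance = as.numeric(agg_p[keep]))
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  mono_mass <- monoisotopic_mass(comp)
  structure(list(peaks = peaks,
                 mono_mz = (mono_mass + charge * PROTON_MASS) / charge,
                 mono_mass = mono_mass,
                 charge = charge),
            class = "isotope_envelope")
}

#' @export
print.isotope_envelope <- function(x, ...) {
  cat(sprintf("<isotope_envelope> z=%d mono m/z=%.4f, %d peaks\n",
              x$charge, x$mono_mz, nrow(x$peaks)))
  print(x$peaks)
  invisible(x)
}
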