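# Library merging, RT alignment, calibration percentiles, search windows
# and mutation decoys.

test_that("duplicate keys keep the highest intensity with deterministic ties", {
  a <- make_evidence(c("AAAK", "CCCK"), intensity = c(1e5, 3e5))
  b <- make_evidence(c("AAAK", "DDDK"), intensity = c(2e5, 4e5),
                     source = "reference")
  merged <- merge_libraries(a, b)
  expect_equal(nrow(merged), 3)
  row <- merged[merged$modified_sequence == "AAAK", ]
  expect_equal(row$intensity, 2e5)
  expect_equal(row$source, "both")
  expect_equal(merged$source[merged$modified_sequence == "DDDK"], "reference")

  # tie on intensity: the experiment record wins
  tie_a <- make_evidence("AAAK", intensity = 5e5)
  tie_a$rt_obs <- 10; tie_a$rt_start <- 9.9; tie_a$rt_end <- 10.1
  tie_b <- make_evidence("AAAK", intensity = 5e5, source = "reference")
  tie_b$rt_obs <- 20; tie_b$rt_start <- 19.9; tie_b$rt_end <- 20.1
  tie <- merge_libraries(tie_a, tie_b)
  expect_equal(tie$rt_obs, 10)
  expect_equal(tie$source, "both")
})

test_that("merging disjoint libraries concatenates and is idempotent", {
  a <- make_evidence(c("AAAK", "CCCK", "EEEK"))
  b <- make_evidence(c("GGGK", "HHHK"), source = "reference")
  merged <- merge_libraries(a, b)
  expect_equal(nrow(merged), 5)
  again <- merge_libraries(merged, merged)
  expect_equal(again, merged)
})

test_that("LOWESS alignment recovers identity and constant shifts", {
  x <- seq(1, 100, length.out = 200)
  ident <- lowess_rt_alignment(x, x)
  expect_lt(max(abs(ident(x) - x)), 1e-6)

  set.seed(5)
  xs <- runif(500, 0, 100)
  ys <- xs + 2.0 + rnorm(500, 0, 0.05)
  shift <- lowess_rt_alignment(xs, ys)
  grid <- seq(quantile(xs, 0.10), quantile(xs, 0.90), length.out = 50)
  expect_lt(max(abs(shift(grid) - (grid + 2.0))), 0.05)

  # nonmonotone noise still yields a single-valued non-decreasing mapping
  yn <- xs + rnorm(500, 0, 5)
  noisy <- lowess_rt_alignment(xs, yn)
  g <- noisy(seq(0, 100, length.out = 300))
  expect_true(all(diff(g) >= -1e-12))

  expect_error(lowess_rt_alignment(1:5, 1:5), "20")
})

test_that("calibration percentiles follow the linear-interpolation rule", {
  s0 <- compute_calibration_stats(rt_pred = rep(1, 10), rt_obs = rep(1, 10),
                                  im_lengths = rep(0.07, 10))
  expect_equal(s0$delta_rt95, 0)

  s1 <- compute_calibration_stats(rt_pred = rep(0.1, 10) + 5,
                                  rt_obs = rep(5, 10),
                                  im_lengths = rep(0.07, 10))
  expect_equal(s1$delta_rt95, 0.1)

  # explicit sort + interpolate oracle on 0.01..1.00
  res <- seq(0.01, 1.00, by = 0.01)
  set.seed(1)
  s2 <- compute_calibration_stats(rt_pred = 5 + sample(res),
                                  rt_obs = rep(5, 100),
                                  im_lengths = res)
  h <- (100 - 1) * 0.95 + 1
  oracle95 <- res[floor(h)] + (h - floor(h)) * (res[ceiling(h)] - res[floor(h)])
  expect_equal(s2$delta_rt95, oracle95)
  h999 <- (100 - 1) * 0.999 + 1
  oracle999 <- res[floor(h999)] +
    (h999 - floor(h999)) * (res[ceiling(h999)] - res[floor(h999)])
  expect_equal(s2$im_length_q999, oracle999)
})

make_stats <- function(delta_rt95, delta_im, im_len) {
  compute_calibration_stats(rt_pred = 5 + rep(delta_rt95, 10),
                            rt_obs = rep(5, 10),
                            im_lengths = rep(im_len, 10),
                            delta_im_cross = delta_im)
}

test_that("search windows implement center +/- delta (+ length padding)", {
  stats <- make_stats(0.8, 0.047, 0.072)
  cand <- data.frame(rt_pred = 20.0, im_center = 1.00)
  out <- assign_search_windows(cand, stats, "experimental")
  expect_equal(c(out$rt_lo, out$rt_hi), c(19.2, 20.8))
  expect_equal(out$rt_hi - out$rt_lo, 1.6)
  expect_equal(c(out$im_lo, out$im_hi), c(0.917, 1.083))

  degenerate <- assign_search_windows(cand, make_stats(0, 0.047, 0.072),
                                      "experimental")
  expect_equal(degenerate$rt_lo, degenerate$rt_hi)
  expect_equal(degenerate$rt_lo, 20.0)
})

test_that("windows contain their centers and widen monotonically", {
  set.seed(3)
  cand <- data.frame(rt_pred = runif(50, 5, 25),
                     im_center = runif(50, 0.8, 1.2))
  for (d in c(0.2, 0.5, 1.1)) {
    out <- assign_search_windows(cand, make_stats(d, 0.02, 0.07),
                                 "experimental")
    expect_true(all(out$rt_lo <= cand$rt_pred & cand$rt_pred <= out$rt_hi))
    expect_true(all(out$im_lo <= cand$im_center & cand$im_center <= out$im_hi))
  }
  narrow <- assign_search_windows(cand, make_stats(0.2, 0.01, 0.05),
                                  "experimental")
  wide <- assign_search_windows(cand, make_stats(0.5, 0.03, 0.09),
                                "experimental")
  expect_true(all(wide$rt_lo <= narrow$rt_lo & wide$rt_hi >= narrow$rt_hi))
  expect_true(all(wide$im_lo <= narrow$im_lo & wide$im_hi >= narrow$im_hi))
})

test_that("two-round mutation follows the composition-closeness gate", {
  targets <- data.frame(id = 1L, modified_sequence = "PEPTIDE", charge = 2L,
                        stringsAsFactors = FALSE)
  decoys <- quiet(generate_decoys(targets, toy_mutation_map(),
                                  closeness_tol = 0.01))
  # round 1 swaps E<->D at positions 2 and n-1, conserving composition,
  # so round 2 mutates the third-to-last residue (I -> V)
  expect_equal(decoys$modified_sequence, "PDPTVEE")
  expect_equal(decoys$decoy_rounds, 2L)
  expect_equal(monoisotopic_mass("PDPTVEE") - monoisotopic_mass("PEPTIDE"),
               -14.01565, tolerance = 1e-4)

  # a round-1 decoy with a large mass shift skips round 2
  far <- data.frame(id = 1L, modified_sequence = "AGAGAGK", charge = 2L,
                    stringsAsFactors = FALSE)
  d_far <- quiet(generate_decoys(far, toy_mutation_map(),
                                 closeness_tol = 0.01))
  expect_equal(d_far$decoy_rounds, 1L)
  expect_equal(d_far$modified_sequence, "AAAGAAK")
})

test_that("decoys colliding with targets are removed and shorts skipped", {
  targets <- data.frame(id = 1:3,
                        modified_sequence = c("PEPTIDE", "PDPTVEE", "AGK"),
                        charge = 2L, stringsAsFactors = FALSE)
  decoys <- quiet(generate_decoys(targets, toy_mutation_map()))
  # decoy of PEPTIDE equals target PDPTVEE (and PDPTVEE's two-round decoy
  # mutates back to PEPTIDE) -> both removed; AGK too short for a decoy
  expect_false("PDPTVEE" %in% decoys$modified_sequence)
  expect_equal(attr(decoys, "n_short"), 1L)
  expect_equal(attr(decoys, "n_collision"), 2L)
  expect_equal(nrow(decoys), 0L)
})

test_that("decoys preserve length and charge; pair ids are a bijection", {
  seqs <- random_sequences(60, seed = 9)
  targets <- data.frame(id = seq_along(seqs), modified_sequence = seqs,
                        charge = sample(2:4, 60, TRUE),
                        stringsAsFactors = FALSE)
  decoys <- quiet(generate_decoys(targets, toy_mutation_map()))
  m <- match(decoys$pair_id, targets$id)
  expect_false(anyNA(m))
  expect_equal(nchar(decoys$modified_sequence),
               nchar(targets$modified_sequence[m]))
  expect_equal(decoys$charge, targets$charge[m])
  expect_false(any(duplicated(decoys$pair_id)))
})

test_that("modifications travel with mutated positions", {
  targets <- data.frame(id = 1L, modified_sequence = "PM[ox]PTIDE",
                        charge = 2L, stringsAsFactors = FALSE)
  decoys <- quiet(generate_decoys(targets, toy_mutation_map(),
                                  closeness_tol = 0.01))
  # position 2 M -> C keeps the [ox] tag attached to the position
  expect_match(decoys$modified_sequence, "^PC\\[ox\\]")
})

test_that("dictionary construction wires windows, envelopes and decoys", {
  lib <- simulate_library(30, gradient_length = 2, seed = 4)
  cfg <- ms1prop_config(random_seed = 2)
  dict <- quiet(build_dictionary(lib$evidence, config = cfg,
                                 rt_method = "observed",
                                 window_mode = "evidence"))
  cand <- dict$candidates
  expect_equal(sum(!cand$is_decoy), 30)
  expect_gt(sum(cand$is_decoy), 25)
  expect_false(any(duplicated(
    cand[, c("modified_sequence", "charge", "is_decoy")])))
  expect_equal(length(dict$envelopes), nrow(cand))
  # windows contain the predicted coordinates
  ok <- cand$window_ok
  expect_true(all(cand$rt_lo[ok] <= cand$rt_obs[ok] + 1e-9 |
                    cand$is_decoy[ok]))
  expect_equal(cand$mono_bin,
               as.integer(floor(cand$mono_mz / cfg$mz_bin_width)))
})
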