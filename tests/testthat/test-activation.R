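# Frame rasterization, scan dictionaries, NNLS deconvolution,
# divide-and-conquer equivalence and image assembly.

test_that("rasterization applies the floor rule and sums cell collisions", {
  grid <- seq(0.8, 1.2, by = 0.01)
  f <- ms1_frame(1, 0.5, data.frame(mz = c(500.005, 500.009, 600.5),
                                    im = c(0.90, 0.90, 1.00),
                                    intensity = c(40, 60, 5)))
  sfm <- rasterize_frame(f, 0.01, grid)
  expect_equal(sort(sfm$bin), c(50000, 60050))
  expect_equal(sfm$intensity[sfm$bin == 50000], 100)

  empty <- rasterize_frame(ms1_frame(2, 0.6, data.frame(mz = numeric(0),
                                                        im = numeric(0),
                                                        intensity = numeric(0))),
                           0.01, grid)
  expect_length(empty$bin, 0)

  # off-grid points snap within half a step, otherwise drop
  f2 <- ms1_frame(3, 0.7, data.frame(mz = c(500, 500), im = c(0.902, 0.7),
                                     intensity = c(10, 10)))
  sfm2 <- quiet(rasterize_frame(f2, 0.01, grid))
  expect_equal(length(sfm2$bin), 1)
  expect_equal(sfm2$im_idx, which(abs(grid - 0.90) < 1e-9))
  expect_equal(sfm2$n_dropped, 1L)
})

test_that("scan dictionaries admit exactly the in-window candidates", {
  lib <- simulate_library(100, gradient_length = 4, seed = 12)
  dict <- quiet(build_dictionary(lib$evidence, rt_method = "observed",
                                 window_mode = "evidence"))
  cand <- dict$candidates
  for (T_i in c(1.0, 2.0, 3.3)) {
    sd <- build_scan_dictionary(dict, T_i)
    brute <- cand$id[cand$window_ok & cand$rt_lo <= T_i & T_i <= cand$rt_hi]
    expect_setequal(sd$cand_ids, brute)
  }
  # boundary scan times are inclusive on both ends
  row <- cand[which(cand$window_ok)[1], ]
  for (Tb in c(row$rt_lo, row$rt_hi)) {
    sd <- build_scan_dictionary(dict, Tb)
    expect_true(row$id %in% sd$cand_ids)
  }
})

test_that("NNLS recovers exact coefficients on identity and disjoint cases", {
  e <- c(0.6, 0.3, 0.1)
  sol <- nnls_solve(matrix(e, ncol = 1), 3 * e)
  expect_equal(sol$x, 3.0, tolerance = 1e-8)
  expect_lt(sol$residual, 1e-10)

  # disjoint supports solve independently
  A <- cbind(c(0.7, 0.3, 0, 0), c(0, 0, 0.5, 0.5))
  b <- 2 * A[, 1] + 7 * A[, 2]
  sol2 <- nnls_solve(A, b)
  expect_equal(sol2$x, c(2, 7), tolerance = 1e-8)
  expect_equal(sol2$x[1], nnls_solve(A[, 1, drop = FALSE], b)$x,
               tolerance = 1e-8)
})

test_that("overlapping isobars match the brute-force grid-search oracle", {
  set.seed(21)
  for (rep in 1:5) {
    e1 <- runif(4); e1 <- e1 / sum(e1)
    e2 <- c(e1[-1], runif(1)); e2 <- e2 / sum(e2)  # shifted, overlapping
    A <- cbind(c(e1, 0), c(0, e2))
    truth <- c(2, 5)
    b <- A %*% truth
    sol <- nnls_solve(A, drop(b))
    expect_equal(sol$x, truth, tolerance = 1e-6)
    # dense grid-search oracle around the optimum
    grid <- seq(0, 8, by = 0.01)
    rss <- outer(grid, grid, Vectorize(function(a1, a2) {
      sum((drop(b) - A %*% c(a1, a2))^2)
    }))
    best <- which(rss == min(rss), arr.ind = TRUE)[1, ]
    expect_lt(max(abs(c(grid[best[1]], grid[best[2]]) - sol$x)), 1e-2 + 1e-9)
  }
})

test_that("activations are nonnegative and perturbations never help", {
  set.seed(33)
  for (rep in 1:20) {
    m <- sample(4:10, 1); k <- sample(2:5, 1)
    A <- matrix(abs(rnorm(m * k)), m, k)
    b <- rnorm(m, 1)
    sol <- nnls_solve(A, b)
    expect_true(all(sol$x >= 0))
    base <- sum((b - A %*% sol$x)^2)
    for (j in seq_len(k)) {
      for (eps in c(-1e-6, 1e-6)) {
        x2 <- sol$x
        x2[j] <- max(0, x2[j] + eps)
        expect_gte(sum((b - A %*% x2)^2), base - 1e-12)
      }
    }
  }
})

test_that("block partition finds connected components", {
  sd <- structure(list(cand_ids = 1:3,
                       bin = c(1L, 2L, 5L, 6L, 9L),
                       col = c(1L, 1L, 2L, 2L, 3L),
                       abundance = rep(0.5, 5)),
                  class = "scan_dictionary")
  blocks <- partition_dictionary_blocks(sd)
  expect_length(blocks, 3)

  # chain A-B and B-C overlap -> one block of three
  sd$bin <- c(1L, 2L, 2L, 3L, 3L)
  blocks2 <- partition_dictionary_blocks(sd)
  expect_length(blocks2, 1)
  expect_setequal(blocks2[[1]]$cols, 1:3)
})

test_that("blockwise solving equals the monolithic solve on 200 candidates", {
  sdict <- make_random_scan_dict(200, n_bins = 400, seed = 8)
  set.seed(9)
  truth <- ifelse(runif(200) < 0.4, 0, 10^runif(200, 1, 3))
  n_bins <- 400
  signal <- numeric(n_bins)
  for (t in seq_len(length(sdict$col))) {
    j <- sdict$col[t]
    signal[sdict$bin[t]] <- signal[sdict$bin[t]] +
      truth[j] * sdict$abundance[t]
  }
  present <- which(signal > 0)
  sfm <- structure(list(bin = present, im_idx = rep(1L, length(present)),
                        intensity = signal[present], im_grid = 1.0,
                        n_dropped = 0L, scan_time = 1),
                   class = "sparse_frame_matrix")
  act <- solve_scan_activation(sfm, sdict)
  # monolithic dense solve over all bins and candidates
  A <- matrix(0, n_bins, 200)
  A[cbind(sdict$bin, sdict$col)] <- sdict$abundance
  mono <- nnls_solve(A, signal)
  expect_lt(max(abs(act[, 1] - mono$x)), 1e-9)
})

test_that("scan order never changes the assembled cube", {
  lib <- simulate_library(8, gradient_length = 1, seed = 3)
  sim <- simulate_ms1_frames(lib$ledger, 1, frame_interval = 0.05)
  dict <- quiet(build_dictionary(lib$evidence, rt_method = "observed",
                                 window_mode = "evidence"))
  cfg <- ms1prop_config()
  cube1 <- deconvolute_run(sim$frames, dict, cfg)
  cube2 <- deconvolute_run(rev(sim$frames), dict, cfg,
                           im_grid = cube1$im_grid)
  # reversed processing, re-ordered back
  expect_equal(cube1$activations,
               rev(cube2$activations))
})

test_that("sliced images conserve the deposited signal on a noiseless run", {
  lib <- simulate_library(12, gradient_length = 1.2, seed = 6)
  sim <- simulate_ms1_frames(lib$ledger, 1.2, frame_interval = 0.02)
  dict <- quiet(build_dictionary(lib$evidence, rt_method = "observed",
                                 window_mode = "evidence"))
  cand <- dict$candidates
  cfg <- ms1prop_config()
  cube <- deconvolute_run(sim$frames, dict, cfg,
                          subset = which(!cand$is_decoy))
  images <- assemble_and_slice(cube, dict,
                               ids = cand$id[!cand$is_decoy])
  # image dims equal the admitted scans x in-window grid columns
  for (key in names(images)) {
    row <- cand[match(as.integer(key), cand$id), ]
    n_scans <- sum(cube$scan_times >= row$rt_lo & cube$scan_times <= row$rt_hi)
    n_cols <- sum(cube$im_grid >= row$im_lo & cube$im_grid <= row$im_hi)
    expect_equal(dim(images[[key]]$values), c(n_scans, n_cols))
  }
  # naive intensities track the in-rectangle deposits
  naive <- vapply(images, naive_intensity, numeric(1))
  m <- match(paste(cand$modified_sequence[match(as.integer(names(images)),
                                                cand$id)],
                   cand$charge[match(as.integer(names(images)), cand$id)]),
             paste(sim$truth$modified_sequence, sim$truth$charge))
  rel <- abs(naive - sim$truth$deposited_in_rect[m]) /
    sim$truth$deposited_in_rect[m]
  expect_lt(median(rel), 1e-3)
  expect_gt(cor(naive, sim$truth$deposited_in_rect[m]), 0.999)
})

test_that("naive intensity is the plain pixel sum", {
  img <- precursor_image(matrix(2, 3, 3), 1:3, 1:3)
  expect_equal(naive_intensity(img), 18)
  expect_equal(naive_intensity(precursor_image(matrix(0, 2, 2), 1:2, 1:2)), 0)
  set.seed(2)
  M <- matrix(abs(rnorm(30)), 5, 6)
  expect_equal(naive_intensity(precursor_image(M, 1:5, 1:6)),
               sum(as.vector(M)))
})

test_that("the chunked image store round-trips", {
  imgs <- list(
    "1" = precursor_image(matrix(1:6 / 2, 2, 3), c(1, 2), c(0.9, 0.95, 1.0),
                          candidate_id = 1),
    "2" = precursor_image(matrix(0, 1, 1), 5, 1.1, candidate_id = 2)
  )
  dir <- withr::local_tempdir()
  write_activation_images(imgs, dir, chunk_size = 1)
  back <- read_activation_images(dir)
  expect_equal(back[["1"]]$values, imgs[["1"]]$values)
  expect_equal(back[["1"]]$im_coords, imgs[["1"]]$im_coords)
  expect_equal(back[["2"]]$values, imgs[["2"]]$values)
})
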