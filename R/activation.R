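# Scan-wise deconvolution: frame rasterization, scan-specific dictionaries,
# non-negative least squares activation, divide-and-conquer block solving,
# and assembly of per-precursor activation images.

#' Construct an MS1 frame object
#'
#' @param frame_id integer frame identifier.
#' @param scan_time scan time in minutes.
#' @param points data.frame with columns `mz`, `im`, `intensity`.
#' @return object of class `ms1_frame`.
#' @export
ms1_frame <- function(frame_id, scan_time, points) {
  stopifnot(all(points$mz > 0), all(points$intensity >= 0))
  structure(list(frame_id = as.integer(frame_id),
                 scan_time = as.numeric(scan_time),
                 points = points),
            class = "ms1_frame")
}

#' Run-level ion-mobility grid
#'
#' Sorted union of distinct 1/K0 values observed across frames, so images
#' from different scans share columns.
#'
#' @param frames list of `ms1_frame`.
#' @return sorted numeric vector.
#' @export
im_grid_from_frames <- function(frames) {
  sort(unique(unlist(lapply(frames, function(f) f$points$im))))
}

#' Rasterize a frame into a sparse (m/z bin x 1/K0) matrix
#'
#' m/z values map to bins by `floor(mz / mz_bin_width)`; intensities of
#' points sharing a cell are summed. Points whose 1/K0 is off-grid snap to
#' the nearest grid value when within half a local grid step, otherwise
#' they are dropped and counted.
#'
#' @param frame `ms1_frame`.
#' @param mz_bin_width bin width in Th.
#' @param im_grid sorted 1/K0 grid (see [im_grid_from_frames()]).
#' @return object of class `sparse_frame_matrix`: list with integer `bin`,
#'   integer `im_idx` (into `im_grid`), numeric `intensity`, the `im_grid`,
#'   and `n_dropped`.
#' @export
rasterize_frame <- function(frame, mz_bin_width, im_grid) {
  pts <- frame$points
  if (nrow(pts) == 0) {
    return(structure(list(bin = integer(0), im_idx = integer(0),
                          intensity = numeric(0), im_grid = im_grid,
                          n_dropped = 0L, scan_time = frame$scan_time),
                     class = "sparse_frame_matrix"))
  }
  idx <- findInterval(pts$im, im_grid)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(im_grid))
  snap <- ifelse(abs(pts$im - im_grid[lo]) <= abs(im_grid[hi] - pts$im), lo, hi)
  step <- local_grid_step(im_grid, snap)
  ok <- abs(pts$im - im_grid[snap]) <= step / 2 + 1e-12
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    stage_log("rasterize_frame", nrow(pts), sum(ok),
              sprintf("frame %d: %d off-grid points dropped",
                      frame$frame_id, n_dropped), quiet = TRUE)
  }
  pts <- pts[ok, , drop = FALSE]
  snap <- snap[ok]
  bin <- as.integer(floor(pts$mz / mz_bin_width))
  cell <- paste(bin, snap, sep = ":")
  agg <- tapply(pts$intensity, cell, sum)
  parts <- strsplit(names(agg), ":", fixed = TRUE)
  structure(list(bin = vapply(parts, function(p) as.integer(p[1]), integer(1)),
                 im_idx = vapply(parts, function(p) as.integer(p[2]), integer(1)),
                 intensity = as.numeric(agg),
                 im_grid = im_grid, n_dropped = n_dropped,
                 scan_time = frame$scan_time),
            class = "sparse_frame_matrix")
}

local_grid_step <- function(grid, idx) {
  if (length(grid) < 2) return(rep(Inf, length(idx)))
  steps <- diff(grid)
  pmax(steps[pmax(idx - 1, 1)], steps[pmin(idx, length(steps))])
}

#' Scan-specific dictionary
#'
#' Admits exactly the candidates whose RT window contains the scan time
#' (inclusive on both ends). Targets and decoys are searched separately, so
#' pass a pre-filtered candidate table.
#'
#' @param dictionary `precursor_dictionary`.
#' @param scan_time scan time `T_i` in minutes.
#' @param subset optional logical/integer index into the candidate table
#'   (e.g. targets only).
#' @return object of class `scan_dictionary`: list with `cand_ids`, and
#'   triplet vectors `bin`, `col` (index into `cand_ids`), `abundance`.
#' @export
build_scan_dictionary <- function(dictionary, scan_time, subset = NULL) {
  cand <- dictionary$candidates
  if (!is.null(subset)) cand <- cand[subset, , drop = FALSE]
  keep <- cand$window_ok & cand$rt_lo <= scan_time & scan_time <= cand$rt_hi
  cand <- cand[keep, , drop = FALSE]
  ids <- cand$id
  bins <- integer(0); cols <- integer(0); ab <- numeric(0)
  for (j in seq_along(ids)) {
    env <- dictionary$envelopes[[as.character(ids[j])]]
    # envelope bins can collide after binning: sum within a bin
    pb <- tapply(env$peaks$abundance, env$peaks$bin, sum)
    bins <- c(bins, as.integer(names(pb)))
    cols <- c(cols, rep.int(j, length(pb)))
    ab <- c(ab, as.numeric(pb))
  }
  structure(list(cand_ids = ids, bin = bins, col = cols, abundance = ab),
            class = "scan_dictionary")
}

#' Lawson-Hanson non-negative least squares
#'
#' Active-set solver for `min ||A x - b||_2` subject to `x >= 0`.
#'
#' @param A design matrix (m x k).
#' @param b response (length m).
#' @param tol dual-feasibility tolerance. Default 1e-10.
#' @param max_iter maximum outer iterations; default `3 * ncol(A)`.
#' @return list with `x` (length k, nonnegative) and `residual` (2-norm).
#' @export
nnls_solve <- function(A, b, tol = 1e-10, max_iter = 3L * ncol(A)) {
  k <- ncol(A)
  x <- numeric(k)
  passive <- logical(k)
  w <- drop(crossprod(A, b))
  iter <- 0
  scale <- max(abs(w), 1)
  while (any(!passive & w > tol * scale) && iter < max_iter) {
    iter <- iter + 1
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      Ap <- A[, P, drop = FALSE]
      z <- tryCatch(qr.solve(Ap, b), error = function(e) NULL)
      if (is.null(z)) {  # rank-deficient passive set: drop the newcomer
        passive[j] <- FALSE
        break
      }
      if (all(z > 0)) {
        x[] <- 0
        x[P] <- z
        break
      }
      neg <- which(z <= 0)
      alpha <- min(x[P][neg] / (x[P][neg] - z[neg]))
      x[P] <- x[P] + alpha * (z - x[P])
      drop_idx <- P[x[P] <= tol * max(1, max(abs(x)))]
      passive[drop_idx] <- FALSE
      x[drop_idx] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  list(x = x, residual = sqrt(sum((b - A %*% x)^2)))
}

#' Partition a scan dictionary into independent blocks
#'
#' Connected components of the bipartite bin-candidate graph. The NNLS
#' objective separates exactly over these blocks, so solving them
#' independently reproduces the monolithic solution.
#'
#' @param sdict `scan_dictionary`.
#' @return list of blocks, each a list with `cols` (candidate indices into
#'   `sdict$cand_ids`) and `bins` (their union of m/z bins).
#' @export
partition_dictionary_blocks <- function(sdict) {
  k <- length(sdict$cand_ids)
  if (k == 0) return(list())
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # union candidates sharing a bin
  by_bin <- split(sdict$col, sdict$bin)
  for (cols in by_bin) {
    if (length(cols) > 1) {
      r <- find(cols[1])
      for (c in cols[-1]) parent[find(c)] <- r
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  lapply(split(seq_len(k), roots), function(cols) {
    list(cols = cols,
         bins = sort(unique(sdict$bin[sdict$col %in% cols])))
  })
}

#' Deconvolute one frame against a scan dictionary
#'
#' Solves, for every ion-mobility column of the frame independently, the
#' non-negative least squares problem matching the binned spectrum to a
#' nonnegative combination of candidate isotope envelopes. Candidates with
#' no m/z overlap with a column's signal get zero activation; frame signal
#' in bins covered by no candidate contributes only to the residual.
#'
#' @param frame_matrix `sparse_frame_matrix`.
#' @param sdict `scan_dictionary` for the frame's scan time.
#' @param tol NNLS tolerance.
#' @param blocks optional precomputed [partition_dictionary_blocks()] result.
#' @return matrix (candidates x IM columns) with rownames = candidate ids
#'   and attribute `residuals` (per-column residual 2-norms).
#' @export
solve_scan_activation <- function(frame_matrix, sdict, tol = 1e-10,
                                  blocks = NULL) {
  n_im <- length(frame_matrix$im_grid)
  k <- length(sdict$cand_ids)
  act <- matrix(0, nrow = k, ncol = n_im,
                dimnames = list(as.character(sdict$cand_ids), NULL))
  residuals <- numeric(n_im)
  if (is.null(blocks)) blocks <- partition_dictionary_blocks(sdict)
  cols_with_signal <- unique(frame_matrix$im_idx)
  for (ci in cols_with_signal) {
    sel <- frame_matrix$im_idx == ci
    s_bins <- frame_matrix$bin[sel]
    s_vals <- frame_matrix$intensity[sel]
    covered <- logical(length(s_bins))
    for (blk in blocks) {
      if (!any(s_bins %in% blk$bins)) next
      covered <- covered | s_bins %in% blk$bins
      rows <- blk$bins
      b <- numeric(length(rows))
      m <- match(s_bins, rows)
      hit <- !is.na(m)
      b[m[hit]] <- s_vals[hit]
      A <- matrix(0, nrow = length(rows), ncol = length(blk$cols))
      in_blk <- sdict$col %in% blk$cols
      A[cbind(match(sdict$bin[in_blk], rows),
              match(sdict$col[in_blk], blk$cols))] <- sdict$abundance[in_blk]
      if (k > 0) {
        sol <- nnls_solve(A, b, tol = tol)
        act[blk$cols, ci] <- sol$x
        residuals[ci] <- residuals[ci] + sol$residual^2
      }
    }
    residuals[ci] <- residuals[ci] + sum(s_vals[!covered]^2)
    residuals[ci] <- sqrt(residuals[ci])
  }
  attr(act, "residuals") <- residuals
  act
}

#' Deconvolute a whole run
#'
#' Rasterizes every frame and solves each scan independently (scans are
#' embarrassingly parallel; results are order-independent).
#'
#' @param frames list of `ms1_frame` ordered by scan time.
#' @param dictionary `precursor_dictionary`.
#' @param config `ms1prop_config`.
#' @param subset optional candidate subset (e.g. targets-only search).
#' @param im_grid optional fixed 1/K0 grid; default the run-level union.
#' @return object of class `activation_cube`: list with `activations`
#'   (per-scan candidate x IM matrices), `scan_times`, `im_grid`,
#'   `residuals`.
#' @export
deconvolute_run <- function(frames, dictionary, config = ms1prop_config(),
                            subset = NULL, im_grid = NULL) {
  if (is.null(im_grid)) im_grid <- im_grid_from_frames(frames)
  scan_times <- vapply(frames, function(f) f$scan_time, numeric(1))
  acts <- vector("list", length(frames))
  residuals <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    sfm <- rasterize_frame(frames[[i]], config$mz_bin_width, im_grid)
    sdict <- build_scan_dictionary(dictionary, scan_times[i], subset = subset)
    a <- solve_scan_activation(sfm, sdict, tol = config$nnls_tol)
    acts[[i]] <- a
    residuals[[i]] <- attr(a, "residuals")
  }
  structure(list(activations = acts, scan_times = scan_times,
                 im_grid = im_grid, residuals = residuals),
            class = "activation_cube")
}

#' Slice the activation cube into per-precursor images
#'
#' For each candidate, rows are the scans whose time lies in the RT window
#' and columns the IM grid values inside the 1/K0 window. Pixels carry the
#' explained signal intensity (the NNLS coefficient times the candidate's
#' envelope abundance sum), so summing an image estimates the precursor's
#' deposited ion current. A candidate whose windows intersect no scan or
#' no grid column yields a flagged 1x1 zero image.
#'
#' @param cube `activation_cube` from [deconvolute_run()].
#' @param dictionary `precursor_dictionary`.
#' @param ids candidate ids to slice; default all with valid windows.
#' @return named list of `precursor_image` objects: each a list with
#'   `values` (matrix scans x IM), `rt_coords`, `im_coords`,
#'   `candidate_id`, `degenerate` flag.
#' @export
assemble_and_slice <- function(cube, dictionary, ids = NULL) {
  cand <- dictionary$candidates
  if (is.null(ids)) ids <- cand$id[cand$window_ok]
  out <- vector("list", length(ids))
  names(out) <- as.character(ids)
  for (n in seq_along(ids)) {
    row <- cand[match(ids[n], cand$id), ]
    scans <- which(cube$scan_times >= row$rt_lo & cube$scan_times <= row$rt_hi)
    cols <- which(cube$im_grid >= row$im_lo & cube$im_grid <= row$im_hi)
    if (length(scans) == 0 || length(cols) == 0) {
      out[[n]] <- precursor_image(matrix(0, 1, 1), rt_coords = row$rt_pred,
                                  im_coords = row$im_center,
                                  candidate_id = ids[n], degenerate = TRUE)
      next
    }
    vals <- matrix(0, nrow = length(scans), ncol = length(cols))
    key <- as.character(ids[n])
    env_sum <- sum(dictionary$envelopes[[key]]$peaks$abundance)
    for (si in seq_along(scans)) {
      a <- cube$activations[[scans[si]]]
      if (key %in% rownames(a)) vals[si, ] <- a[key, cols] * env_sum
    }
    out[[n]] <- precursor_image(vals, rt_coords = cube$scan_times[scans],
                                im_coords = cube$im_grid[cols],
                                candidate_id = ids[n], degenerate = FALSE)
  }
  out
}

#' Precursor activation image
#'
#' @param values nonnegative matrix (RT scans x IM columns).
#' @param rt_coords scan times (minutes) of the rows.
#' @param im_coords 1/K0 values of the columns.
#' @param candidate_id candidate id.
#' @param degenerate TRUE when the windows intersected no data.
#' @return object of class `precursor_image`.
#' @export
precursor_image <- function(values, rt_coords, im_coords, candidate_id = NA,
                            degenerate = FALSE) {
  stopifnot(nrow(values) == length(rt_coords),
            ncol(values) == length(im_coords), all(values >= 0))
  structure(list(values = values, rt_coords = rt_coords,
                 im_coords = im_coords, candidate_id = candidate_id,
                 degenerate = degenerate),
            class = "precursor_image")
}

#' Naive inferred intensity: the sum of all image pixels
#'
#' @param image `precursor_image` (or bare matrix).
#' @return scalar sum.
#' @export
naive_intensity <- function(image) {
  if (inherits(image, "precursor_image")) image <- image$values
  sum(image)
}

# --- chunked on-disk image store ---------------------------------------

#' Persist activation images as a chunked text store
#'
#' Long-format TSV chunks keyed by candidate id (columns candidate_id,
#' rt, im, value) plus an index file, so precursors can be re-read in
#' chunks for post-processing.
#'
#' @param images named list of `precursor_image`.
#' @param dir output directory (created).
#' @param chunk_size precursors per chunk file. Default 200.
#' @return the index data.frame, invisibly.
#' @export
write_activation_images <- function(images, dir, chunk_size = 200) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(images)
  chunks <- split(ids, ceiling(seq_along(ids) / chunk_size))
  index <- data.frame(candidate_id = ids,
                      chunk = rep(sprintf("chunk_%04d.tsv", seq_along(chunks)),
                                  vapply(chunks, length, integer(1))),
                      stringsAsFactors = FALSE)
  for (ci in seq_along(chunks)) {
    rows <- do.call(rbind, lapply(chunks[[ci]], function(id) {
      img <- images[[id]]
      data.frame(candidate_id = id,
                 rt = rep(img$rt_coords, times = ncol(img$values)),
                 im = rep(img$im_coords, each = nrow(img$values)),
                 value = as.vector(img$values))
    }))
    utils::write.table(rows, file.path(dir, sprintf("chunk_%04d.tsv", ci)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(index, file.path(dir, "index.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(index)
}

#' Read activation images back from a chunked store
#'
#' @param dir store directory written by [write_activation_images()].
#' @param ids candidate ids to load; default all.
#' @return named list of `precursor_image`.
#' @export
read_activation_images <- function(dir, ids = NULL) {
  index <- utils::read.delim(file.path(dir, "index.tsv"),
                             colClasses = c("character", "character"))
  if (is.null(ids)) ids <- index$candidate_id else ids <- as.character(ids)
  out <- list()
  for (ch in unique(index$chunk[index$candidate_id %in% ids])) {
    tab <- utils::read.delim(file.path(dir, ch),
                             colClasses = c("character", "numeric",
                                            "numeric", "numeric"))
    for (id in intersect(unique(tab$candidate_id), ids)) {
      sub <- tab[tab$candidate_id == id, ]
      rts <- sort(unique(sub$rt))
      ims <- sort(unique(sub$im))
      vals <- matrix(0, length(rts), length(ims))
      vals[cbind(match(sub$rt, rts), match(sub$im, ims))] <- sub$value
      out[[id]] <- precursor_image(vals, rts, ims, candidate_id = id)
    }
  }
  out[ids]
}
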