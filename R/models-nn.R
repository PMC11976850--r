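# Numerical building blocks for the peak-selection and scoring models:
# bilinear resize as explicit interpolation matrices, box blurs, a small
# fully-connected network with hand-written backprop, Adam, a one-cycle
# learning-rate schedule, and the combo segmentation loss (BCE + dice +
# focal) with analytic gradients.

# S x n bilinear interpolation matrix: native pixel centers (j-0.5)/n,
# resized pixel centers (i-0.5)/S, both on [0,1]
interp_matrix <- function(n_native, size) {
  if (n_native == 1) return(matrix(1, nrow = size, ncol = 1))
  centers_out <- (seq_len(size) - 0.5) / size
  centers_in <- (seq_len(n_native) - 0.5) / n_native
  M <- matrix(0, nrow = size, ncol = n_native)
  for (i in seq_len(size)) {
    x <- centers_out[i]
    j <- findInterval(x, centers_in)
    if (j == 0) {
      M[i, 1] <- 1
    } else if (j >= n_native) {
      M[i, n_native] <- 1
    } else {
      w <- (x - centers_in[j]) / (centers_in[j + 1] - centers_in[j])
      M[i, j] <- 1 - w
      M[i, j + 1] <- w
    }
  }
  M
}

# n x S area-overlap matrix (rows sum to 1): overlap of native cell
# [(j-1)/n, j/n] with resized cell [(i-1)/S, i/S]
overlap_matrix <- function(n_native, size) {
  M <- matrix(0, nrow = n_native, ncol = size)
  for (j in seq_len(n_native)) {
    a <- (j - 1) / n_native
    b <- j / n_native
    lo <- pmax(a, (seq_len(size) - 1) / size)
    hi <- pmin(b, seq_len(size) / size)
    ov <- pmax(0, hi - lo)
    M[j, ] <- ov / sum(ov)
  }
  M
}

resize_bilinear <- function(mat, size) {
  interp_matrix(nrow(mat), size) %*% mat %*% t(interp_matrix(ncol(mat), size))
}

minmax_scale <- function(mat) {
  rng <- range(mat)
  if (rng[2] - rng[1] <= 0) return(matrix(0, nrow(mat), ncol(mat)))
  (mat - rng[1]) / (rng[2] - rng[1])
}

# mean filter over a (2r+1)^2 window clipped at borders, via cumsums
box_blur <- function(mat, r) {
  if (r < 1) return(mat)
  n <- nrow(mat); m <- ncol(mat)
  cs <- apply(apply(mat, 2, cumsum), 1, cumsum)  # transposed 2D cumsum
  cs <- t(cs)
  padded <- matrix(0, n + 1, m + 1)
  padded[-1, -1] <- cs
  r1 <- pmax(seq_len(n) - r, 1); r2 <- pmin(seq_len(n) + r, n)
  c1 <- pmax(seq_len(m) - r, 1); c2 <- pmin(seq_len(m) + r, m)
  sums <- padded[r2 + 1, c2 + 1, drop = FALSE] -
    padded[r1, c2 + 1, drop = FALSE] -
    padded[r2 + 1, c1, drop = FALSE] + padded[r1, c1, drop = FALSE]
  counts <- outer(r2 - r1 + 1, c2 - c1 + 1)
  sums / counts
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# --- small dense network -----------------------------------------------

mlp_init <- function(sizes, seed) {
  set.seed(seed)
  layers <- list()
  for (l in seq_len(length(sizes) - 1)) {
    fan_in <- sizes[l]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * sizes[l + 1], sd = sqrt(2 / fan_in)),
                 fan_in, sizes[l + 1]),
      b = numeric(sizes[l + 1])
    )
  }
  layers
}

# forward pass; returns logits and the per-layer activations for backprop
mlp_forward <- function(X, layers) {
  acts <- list(X)
  L <- length(layers)
  for (l in seq_len(L)) {
    Z <- acts[[l]] %*% layers[[l]]$W
    Z <- sweep(Z, 2, layers[[l]]$b, `+`)
    acts[[l + 1]] <- if (l < L) pmax(Z, 0) else Z
  }
  list(logits = acts[[L + 1]], acts = acts)
}

# backprop given dL/dlogits; returns per-layer gradients
mlp_backward <- function(fw, layers, dlogits) {
  L <- length(layers)
  grads <- vector("list", L)
  delta <- dlogits
  for (l in rev(seq_len(L))) {
    A <- fw$acts[[l]]
    grads[[l]] <- list(W = crossprod(A, delta), b = colSums(delta))
    if (l > 1) {
      delta <- (delta %*% t(layers[[l]]$W)) * (fw$acts[[l]] > 0)
    }
  }
  grads
}

adam_init <- function(layers) {
  lapply(layers, function(ly) list(mW = ly$W * 0, vW = ly$W * 0,
                                   mb = ly$b * 0, vb = ly$b * 0))
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(layers)) {
    state[[l]]$mW <- beta1 * state[[l]]$mW + (1 - beta1) * grads[[l]]$W
    state[[l]]$vW <- beta2 * state[[l]]$vW + (1 - beta2) * grads[[l]]$W^2
    state[[l]]$mb <- beta1 * state[[l]]$mb + (1 - beta1) * grads[[l]]$b
    state[[l]]$vb <- beta2 * state[[l]]$vb + (1 - beta2) * grads[[l]]$b^2
    mW <- state[[l]]$mW / (1 - beta1^t)
    vW <- state[[l]]$vW / (1 - beta2^t)
    mb <- state[[l]]$mb / (1 - beta1^t)
    vb <- state[[l]]$vb / (1 - beta2^t)
    layers[[l]]$W <- layers[[l]]$W - lr * mW / (sqrt(vW) + eps)
    layers[[l]]$b <- layers[[l]]$b - lr * mb / (sqrt(vb) + eps)
  }
  list(layers = layers, state = state)
}

# one-cycle schedule: linear warm-up to max_lr over the first 30% of steps,
# then linear anneal down to max_lr/100
one_cycle_lr <- function(step, total_steps, max_lr, warmup = 0.3) {
  w <- max(1, round(warmup * total_steps))
  if (step <= w) {
    max_lr * step / w
  } else {
    frac <- (step - w) / max(1, total_steps - w)
    max_lr * (1 - frac) + (max_lr / 100) * frac
  }
}

# --- losses ------------------------------------------------------------

# binary cross-entropy with logits; returns loss and dL/dlogit (mean red.)
bce_with_logits <- function(logits, y) {
  p <- sigmoid(logits)
  eps <- 1e-12
  loss <- mean(-y * log(p + eps) - (1 - y) * log(1 - p + eps))
  list(loss = loss, dlogits = (p - y) / length(y))
}

# combo loss = w_bce * BCE + w_dice * dice + w_focal * focal, with
# analytic gradient w.r.t. logits. Dice uses a global soft formulation
# with smoothing 1; focal uses gamma = 2, alpha = 0.5.
combo_loss <- function(logits, y, weights = c(bce = 1, dice = 4, focal = 1),
                       gamma = 2, alpha = 0.5, smooth = 1) {
  n <- length(y)
  p <- sigmoid(logits)
  eps <- 1e-12
  dp_dz <- p * (1 - p)

  bce <- mean(-y * log(p + eps) - (1 - y) * log(1 - p + eps))
  d_bce <- (p - y) / n

  inter <- sum(p * y)
  denom <- sum(p) + sum(y) + smooth
  dice <- 1 - (2 * inter + smooth) / denom
  d_dice <- (-(2 * y * denom - (2 * inter + smooth)) / denom^2) * dp_dz

  fl_pos <- -alpha * (1 - p)^gamma * log(p + eps)
  fl_neg <- -(1 - alpha) * p^gamma * log(1 - p + eps)
  focal <- mean(y * fl_pos + (1 - y) * fl_neg)
  d_fl_pos <- alpha * (gamma * (1 - p)^(gamma - 1) * log(p + eps) -
                         (1 - p)^gamma / (p + eps))
  d_fl_neg <- (1 - alpha) * (-gamma * p^(gamma - 1) * log(1 - p + eps) +
                               p^gamma / (1 - p + eps))
  d_focal <- ((y * d_fl_pos + (1 - y) * d_fl_neg) / n) * dp_dz

  loss <- weights[["bce"]] * bce + weights[["dice"]] * dice +
    weights[["focal"]] * focal
  dlogits <- weights[["bce"]] * d_bce + weights[["dice"]] * d_dice +
    weights[["focal"]] * d_focal
  list(loss = loss, dlogits = dlogits,
       parts = c(bce = bce, dice = dice, focal = focal))
}

# seeded 8:1:1 (or configured) split of indices into train/validation/test
split_pool <- function(n, split = c(0.8, 0.1, 0.1), seed = 1L) {
  set.seed(seed)
  idx <- sample.int(n)
  n_train <- round(split[1] * n)
  n_val <- round(split[2] * n)
  if (n_train + n_val >= n) {
    n_train <- max(1L, n - 2L)
    n_val <- 1L
  }
  list(train = idx[seq_len(n_train)],
       validation = idx[n_train + seq_len(n_val)],
       test = idx[(n_train + n_val + 1):n])
}
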