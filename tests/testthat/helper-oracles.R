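# Independent brute-force oracles used across the suite. All are written as
# explicit loops / set arithmetic, deliberately sharing no code with the
# package internals they check.

# Per-position channel mean by double loop.
oracle_channel_mean <- function(u) {
  d <- dim(u)
  out <- matrix(0, d[2], d[3])
  for (h in seq_len(d[2])) {
    for (w in seq_len(d[3])) {
      out[h, w] <- mean(u[, h, w])
    }
  }
  out
}

# Per-channel spatial mean by loop.
oracle_spatial_mean <- function(u) {
  d <- dim(u)
  out <- numeric(d[1])
  for (c in seq_len(d[1])) out[c] <- mean(u[c, , ])
  out
}

# Direct sliding-window 3x3 convolution (padding 1) on a (C,H,W) map using
# the package's documented weight layout: column (k-1)*C + c of the weight
# matrix is channel c at offset k = dw*3 + dh + 1, taps read (h+dh-1, w+dw-1)
# in 1-based padded coordinates.
oracle_conv3x3 <- function(x, W_mat, b) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  n_out <- nrow(W_mat)
  out <- array(0, c(n_out, H, W))
  for (o in seq_len(n_out)) {
    for (h in seq_len(H)) {
      for (w in seq_len(W)) {
        acc <- b[o]
        for (dw in 0:2) {
          for (dh in 0:2) {
            sh <- h + dh - 1L; sw <- w + dw - 1L
            if (sh < 1 || sh > H || sw < 1 || sw > W) next
            k <- dw * 3L + dh + 1L
            for (c in seq_len(C)) {
              acc <- acc + W_mat[o, (k - 1L) * C + c] * x[c, sh, sw]
            }
          }
        }
        out[o, h, w] <- acc
      }
    }
  }
  out
}

# Set-arithmetic metrics on binary masks via explicit pixel loops.
oracle_mask_metrics <- function(a, b) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    if (a[i] == 1 && b[i] == 1) inter <- inter + 1
    if (a[i] == 1) na <- na + 1
    if (b[i] == 1) nb <- nb + 1
  }
  uni <- na + nb - inter
  list(dice = if (na + nb == 0) 1 else 2 * inter / (na + nb),
       jaccard = if (uni == 0) 1 else inter / uni,
       rvd = if (na == 0) NA_real_ else (nb - na) / na)
}

# Per-pixel argmax loop.
oracle_argmax <- function(logits) {
  d <- dim(logits)
  out <- matrix(0L, d[2], d[3])
  for (h in seq_len(d[2])) {
    for (w in seq_len(d[3])) {
      out[h, w] <- which.max(logits[, h, w]) - 1L
    }
  }
  out
}

# Even-odd crossing-number point-in-polygon test.
oracle_point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py)) {
      xint <- vx[i] + (py - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Small shared fixtures -------------------------------------------------------

tiny_phantom_data <- function(n = 4, size = 64, seed = 11) {
  cfg <- phantom_config(size = size, n_glands = c(2, 4),
                        radius_range = c(0.12, 0.25), noise_sd = 8,
                        seed = seed)
  generate_phantom_tibble(cfg, n)
}

tiny_model <- function(..., seed = 3) {
  build_scau_net(scau_config(base_channels = 8, depth = 3,
                             use_spatial_attention = TRUE,
                             use_channel_attention = TRUE, seed = seed, ...))
}

random_mask <- function(h, w, p = 0.4) {
  matrix(rbinom(h * w, 1, p), h, w)
}
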