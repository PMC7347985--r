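# Spatial-attention (SA) and channel-attention (CA) plug-and-play modules.
#
# Both are shape-preserving recalibrations of a feature map U (C x H x W):
#
#   SA:  p[h,w] = mean_c U[c,h,w]                    (channel-wise pooling)
#        t = sigmoid(conv3x3_{m->1}(relu(conv3x3_{1->m}(p))))   t in (0,1)^{HxW}
#        U'[c,h,w] = U[c,h,w] * t[h,w]
#
#   CA:  q[c] = mean_{h,w} U[c,h,w]                  (spatial pooling)
#        v = sigmoid(W2 relu(W1 q + b1) + b2)        v in (0,1)^C
#        U'[c,h,w] = U[c,h,w] * v[c]
#
# The hidden sizes are absolute constants (m = 16 channels for SA, K = 32
# neurons for CA), not reduction ratios of C.

#' Spatial-attention parameters
#'
#' Creates the learnable parameters of the spatial-attention module: two 3x3
#' convolutions (1 -> `hidden` -> 1 channels, padding 1 so spatial shape is
#' preserved) with biases. Weights are Kaiming-uniform, biases zero.
#'
#' @param hidden Hidden channel count m (default 16).
#' @param seed Integer seed fixing the draw.
#' @return An object of class `sa_params`: list with conv weight matrices
#'   `W1` (m x 9), `b1` (m), `W2` (1 x 9m), `b2` (1).
#' @export
sa_params <- function(hidden = 16L, seed = 1L) {
  stopifnot(hidden >= 1)
  with_seed(seed, {
    p <- list(W1 = kaiming_uniform(hidden, 9L),
              b1 = numeric(hidden),
              W2 = kaiming_uniform(1L, 9L * hidden),
              b2 = numeric(1L),
              hidden = as.integer(hidden))
    class(p) <- "sa_params"
    p
  })
}

#' Channel-attention parameters
#'
#' Two fully connected layers C -> `hidden` -> C with biases; `channels` must
#' match the feature map the module is applied to.
#'
#' @param channels Number of feature channels C.
#' @param hidden Hidden neuron count K (default 32).
#' @param seed Integer seed fixing the draw.
#' @return An object of class `ca_params`: `W1` (K x C), `b1` (K),
#'   `W2` (C x K), `b2` (C).
#' @export
ca_params <- function(channels, hidden = 32L, seed = 1L) {
  stopifnot(channels >= 1, hidden >= 1)
  with_seed(seed, {
    p <- list(W1 = kaiming_uniform(hidden, channels),
              b1 = numeric(hidden),
              W2 = kaiming_uniform(channels, hidden),
              b2 = numeric(channels),
              channels = as.integer(channels),
              hidden = as.integer(hidden))
    class(p) <- "ca_params"
    p
  })
}

#' Number of learnable parameters of an attention module
#' @param params An `sa_params` or `ca_params` object.
#' @return Integer parameter count, biases included.
#' @export
n_attention_params <- function(params) {
  sum(vapply(params[c("W1", "b1", "W2", "b2")], length, integer(1)))
}

#' Channel-pooled spatial descriptor
#'
#' Global average pooling over the channel axis: the descriptor at (h, w) is
#' the mean of the C channel values at that position.
#'
#' @param u Feature map, 3-d array (C, H, W).
#' @return H x W matrix.
#' @export
aggregate_channels <- function(u) {
  check_feature_map(u)
  d <- dim(u)
  m <- u; dim(m) <- c(d[1], d[2] * d[3])
  out <- colMeans(m)
  dim(out) <- d[2:3]
  out
}

#' Spatially pooled channel descriptor
#'
#' Global average pooling over the spatial axes: entry c is the mean of the
#' H x W values of channel c.
#'
#' @param u Feature map, 3-d array (C, H, W).
#' @return Numeric vector of length C.
#' @export
aggregate_spatial <- function(u) {
  check_feature_map(u)
  d <- dim(u)
  m <- u; dim(m) <- c(d[1], d[2] * d[3])
  rowMeans(m)
}

#' Spatial weight learner
#'
#' Maps a spatial descriptor to per-position weights in (0,1):
#' `sigmoid(conv2(relu(conv1(p))))` with 3x3 shape-preserving convolutions.
#'
#' @param p Spatial descriptor, H x W matrix.
#' @param params `sa_params`.
#' @return H x W matrix of weights, all strictly in (0,1).
#' @export
spatial_weight_learner <- function(p, params) {
  if (!is.matrix(p) || any(dim(p) < 1L)) {
    stop("`p` must be a matrix with positive dimensions", call. = FALSE)
  }
  x <- array(p, c(1L, nrow(p), ncol(p), 1L))
  t_map <- sa_weights_forward(x, params, keep_cache = FALSE)$t
  dim(t_map) <- dim(p)
  t_map
}

#' Channel weight learner
#'
#' Maps a channel descriptor to per-channel weights in (0,1):
#' `sigmoid(W2 relu(W1 q + b1) + b2)`.
#'
#' @param q Channel descriptor, numeric vector of length C.
#' @param params `ca_params` with matching `channels`.
#' @return Numeric vector of length C with entries strictly in (0,1).
#' @export
channel_weight_learner <- function(q, params) {
  if (length(q) != params$channels) {
    stop(sprintf("descriptor length %d does not match module channels %d",
                 length(q), params$channels), call. = FALSE)
  }
  z1 <- drop(params$W1 %*% q) + params$b1
  a <- pmax(z1, 0)
  drop(sigmoid(drop(params$W2 %*% a) + params$b2))
}

#' Apply spatial attention to a feature map
#'
#' Every channel at position (h, w) is multiplied by the learned spatial
#' weight t[h, w].
#'
#' @param u Feature map (C, H, W).
#' @param params `sa_params`.
#' @return Recalibrated feature map, same shape as `u`.
#' @export
apply_spatial_attention <- function(u, params) {
  check_feature_map(u)
  x <- as_batch(u)
  out <- sa_forward(x, params, keep_cache = FALSE)$out
  dim(out) <- dim(u)
  out
}

#' Apply channel attention to a feature map
#'
#' Every position of channel c is multiplied by the learned channel weight
#' v[c].
#'
#' @param u Feature map (C, H, W).
#' @param params `ca_params` with `channels == dim(u)[1]`.
#' @return Recalibrated feature map, same shape as `u`.
#' @export
apply_channel_attention <- function(u, params) {
  check_feature_map(u)
  x <- as_batch(u)
  out <- ca_forward(x, params, keep_cache = FALSE)$out
  dim(out) <- dim(u)
  out
}

# ---- batched internals with backward passes ---------------------------------

# p: (1,H,W,N) descriptor -> t: (1,H,W,N) weights
sa_weights_forward <- function(p, params, keep_cache = TRUE) {
  c1 <- conv3x3_forward(p, params$W1, params$b1, keep_cache)
  r1 <- relu_forward(c1$out, keep_cache)
  c2 <- conv3x3_forward(r1$out, params$W2, params$b2, keep_cache)
  t_map <- sigmoid(c2$out)
  list(t = t_map,
       cache = if (keep_cache) list(c1 = c1$cache, r1 = r1$cache,
                                    c2 = c2$cache, t = t_map) else NULL)
}

sa_forward <- function(x, params, keep_cache = TRUE) {
  d <- dim(x); C <- d[1]
  xm <- x; dim(xm) <- c(C, prod(d[-1]))
  p <- colMeans(xm)
  dim(p) <- c(1L, d[2], d[3], d[4])
  wf <- sa_weights_forward(p, params, keep_cache)
  tb <- array(rep(as.vector(wf$t), each = C), d)
  out <- x * tb
  list(out = out,
       t = wf$t,
       cache = if (keep_cache) list(x = x, tb = tb, wf = wf$cache, dims = d) else NULL)
}

sa_backward <- function(dout, params, cache) {
  d <- cache$dims; C <- d[1]
  dx1 <- dout * cache$tb
  dtm <- dout * cache$x; dim(dtm) <- c(C, prod(d[-1]))
  dt <- colSums(dtm)
  dim(dt) <- c(1L, d[2], d[3], d[4])
  wf <- cache$wf
  dz2 <- dt * wf$t * (1 - wf$t)
  b2 <- conv3x3_backward(dz2, params$W2, wf$c2)
  dr <- relu_backward(b2$dx, wf$r1)
  b1 <- conv3x3_backward(dr, params$W1, wf$c1)
  dp <- b1$dx                      # (1,H,W,N)
  dx2 <- array(rep(as.vector(dp), each = C), d) / C
  list(dx = dx1 + dx2,
       grads = list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db))
}

ca_forward <- function(x, params, keep_cache = TRUE) {
  d <- dim(x); C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  xr <- x; dim(xr) <- c(C * HW, N)
  q <- matrix(0, C, N)
  for (n in seq_len(N)) q[, n] <- rowMeans(matrix(xr[, n], C))
  z1 <- params$W1 %*% q + params$b1
  a <- pmax(z1, 0)
  v <- sigmoid(params$W2 %*% a + params$b2)   # C x N
  vb <- array(0, d)
  for (n in seq_len(N)) vb[, , , n] <- v[, n]
  out <- x * vb
  list(out = out, v = v,
       cache = if (keep_cache) list(x = x, vb = vb, q = q, z1 = z1, a = a,
                                    v = v, dims = d) else NULL)
}

ca_backward <- function(dout, params, cache) {
  d <- cache$dims; C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  dx1 <- dout * cache$vb
  prod_ <- dout * cache$x
  dim(prod_) <- c(C * HW, N)
  dv <- matrix(0, C, N)
  for (n in seq_len(N)) dv[, n] <- rowSums(matrix(prod_[, n], C))
  dz2 <- dv * cache$v * (1 - cache$v)
  dW2 <- dz2 %*% t(cache$a)
  db2 <- rowSums(dz2)
  da <- crossprod(params$W2, dz2)
  dz1 <- da * (cache$z1 > 0)
  dW1 <- dz1 %*% t(cache$q)
  db1 <- rowSums(dz1)
  dq <- crossprod(params$W1, dz1)   # C x N
  dx2 <- array(0, d)
  for (n in seq_len(N)) dx2[, , , n] <- dq[, n] / HW
  list(dx = dx1 + dx2,
       grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}
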