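# The SCAU-Net encoder-decoder.
#
# Encoder: `depth` levels of Block(base * 2^(l-1)) followed by 2x2 max
# pooling; Block(x) = [conv3x3 -> batchnorm -> ReLU] twice with x output
# channels. Bottleneck Block(base * 2^depth). Decoder mirrors the encoder:
# bilinear x2 upsampling, concatenation with the same-level encoder output
# (the skip "copy"), then a Block reducing back to the level's channel
# count. A 1x1 convolution maps to the class scores (2 classes: gland
# foreground vs background).
#
# Attention insertion (both optional, per config):
#   - spatial attention on the encoder output of each level in `sa_levels`
#     (default: level 1 only, the low-level contour/edge features), applied
#     before the skip copy so both the skip and the pooled path see the
#     recalibrated features;
#   - channel attention on the bottleneck output (the high-level,
#     many-channel features).

#' Model configuration
#'
#' @param in_channels Input image channels (3 for RGB).
#' @param num_classes Output classes (2: background / gland).
#' @param base_channels Channels of the first encoder block; doubled at each
#'   of the `depth` poolings.
#' @param depth Number of pooling steps; input height and width must be
#'   divisible by `2^depth`.
#' @param use_spatial_attention,use_channel_attention Attention ablation
#'   flags. Both `FALSE` gives a plain U-Net.
#' @param sa_levels Encoder levels (1-based) that receive spatial attention.
#' @param sa_hidden Hidden channels m of the spatial-attention learner.
#' @param ca_hidden Hidden neurons K of the channel-attention learner.
#' @param seed Seed for parameter initialisation.
#' @return A `scau_config` list.
#' @export
scau_config <- function(in_channels = 3L, num_classes = 2L, base_channels = 64L,
                        depth = 4L, use_spatial_attention = FALSE,
                        use_channel_attention = FALSE, sa_levels = 1L,
                        sa_hidden = 16L, ca_hidden = 32L, seed = 1L) {
  stopifnot(depth >= 1, base_channels >= 1, in_channels >= 1, num_classes >= 2)
  sa_levels <- as.integer(sort(unique(sa_levels)))
  if (use_spatial_attention &&
      (length(sa_levels) == 0 || any(sa_levels < 1 | sa_levels > depth))) {
    stop("`sa_levels` must be a non-empty subset of 1..depth", call. = FALSE)
  }
  structure(list(in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth),
                 use_spatial_attention = isTRUE(use_spatial_attention),
                 use_channel_attention = isTRUE(use_channel_attention),
                 sa_levels = sa_levels,
                 sa_hidden = as.integer(sa_hidden),
                 ca_hidden = as.integer(ca_hidden),
                 seed = as.integer(seed)),
            class = "scau_config")
}

# Encoder output channels at level l.
enc_channels <- function(cfg, l) cfg$base_channels * 2L^(l - 1L)

#' Parameter count of one convolution block
#'
#' Block(x) is conv3x3 -> batchnorm -> ReLU, twice; the count covers both
#' conv kernels and biases plus the per-channel batch-norm scale and shift.
#'
#' @param in_ch,out_ch Input and output channel counts.
#' @return Integer parameter count.
#' @export
n_block_params <- function(in_ch, out_ch) {
  (9L * in_ch * out_ch + out_ch) + 2L * out_ch +
    (9L * out_ch * out_ch + out_ch) + 2L * out_ch
}

block_param_names <- function(prefix) {
  paste0(prefix, "_", c("conv1_W", "conv1_b", "bn1_gamma", "bn1_beta",
                        "conv2_W", "conv2_b", "bn2_gamma", "bn2_beta"))
}

init_block <- function(params, bn, prefix, in_ch, out_ch) {
  params[[paste0(prefix, "_conv1_W")]] <- kaiming_uniform(out_ch, 9L * in_ch)
  params[[paste0(prefix, "_conv1_b")]] <- numeric(out_ch)
  params[[paste0(prefix, "_bn1_gamma")]] <- rep(1, out_ch)
  params[[paste0(prefix, "_bn1_beta")]] <- numeric(out_ch)
  params[[paste0(prefix, "_conv2_W")]] <- kaiming_uniform(out_ch, 9L * out_ch)
  params[[paste0(prefix, "_conv2_b")]] <- numeric(out_ch)
  params[[paste0(prefix, "_bn2_gamma")]] <- rep(1, out_ch)
  params[[paste0(prefix, "_bn2_beta")]] <- numeric(out_ch)
  bn[[paste0(prefix, "_bn1")]] <- list(mean = numeric(out_ch), var = rep(1, out_ch))
  bn[[paste0(prefix, "_bn2")]] <- list(mean = numeric(out_ch), var = rep(1, out_ch))
  list(params = params, bn = bn)
}

#' Build a SCAU-Net model
#'
#' Initialises all parameters (Kaiming-uniform weights, zero biases, unit
#' batch-norm scale) under the config's seed.
#'
#' @param cfg A [scau_config()].
#' @return An object of class `scau_net`: `config`, flat named parameter
#'   list `params`, and batch-norm running statistics `bn`.
#' @export
build_scau_net <- function(cfg = scau_config()) {
  stopifnot(inherits(cfg, "scau_config"))
  with_seed(cfg$seed, {
    params <- list(); bn <- list()
    in_ch <- cfg$in_channels
    for (l in seq_len(cfg$depth)) {
      out_ch <- enc_channels(cfg, l)
      st <- init_block(params, bn, paste0("enc", l), in_ch, out_ch)
      params <- st$params; bn <- st$bn
      if (cfg$use_spatial_attention && l %in% cfg$sa_levels) {
        m <- cfg$sa_hidden
        params[[paste0("sa", l, "_W1")]] <- kaiming_uniform(m, 9L)
        params[[paste0("sa", l, "_b1")]] <- numeric(m)
        params[[paste0("sa", l, "_W2")]] <- kaiming_uniform(1L, 9L * m)
        params[[paste0("sa", l, "_b2")]] <- numeric(1L)
      }
      in_ch <- out_ch
    }
    bott_ch <- cfg$base_channels * 2L^cfg$depth
    st <- init_block(params, bn, "bott", in_ch, bott_ch)
    params <- st$params; bn <- st$bn
    if (cfg$use_channel_attention) {
      K <- cfg$ca_hidden
      params[["ca_W1"]] <- kaiming_uniform(K, bott_ch)
      params[["ca_b1"]] <- numeric(K)
      params[["ca_W2"]] <- kaiming_uniform(bott_ch, K)
      params[["ca_b2"]] <- numeric(bott_ch)
    }
    for (l in rev(seq_len(cfg$depth))) {
      up_ch <- cfg$base_channels * 2L^l        # channels arriving from below
      skip_ch <- enc_channels(cfg, l)
      st <- init_block(params, bn, paste0("dec", l), up_ch + skip_ch, skip_ch)
      params <- st$params; bn <- st$bn
    }
    params[["head_W"]] <- kaiming_uniform(cfg$num_classes, cfg$base_channels)
    params[["head_b"]] <- numeric(cfg$num_classes)
    structure(list(config = cfg, params = params, bn = bn), class = "scau_net")
  })
}

#' Total learnable parameter count
#' @param model A `scau_net`.
#' @return Integer count over all weights, biases, and batch-norm affine
#'   parameters.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.scau_net <- function(x, ...) {
  cfg <- x$config
  att <- c(if (cfg$use_spatial_attention)
             paste0("SA@", paste(cfg$sa_levels, collapse = ",")),
           if (cfg$use_channel_attention) "CA")
  cat(sprintf("<scau_net> depth %d, base %d, in %d -> %d classes, %s, %s parameters\n",
              cfg$depth, cfg$base_channels, cfg$in_channels, cfg$num_classes,
              if (length(att)) paste(att, collapse = "+") else "no attention",
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

sa_param_subset <- function(params, l) {
  list(W1 = params[[paste0("sa", l, "_W1")]], b1 = params[[paste0("sa", l, "_b1")]],
       W2 = params[[paste0("sa", l, "_W2")]], b2 = params[[paste0("sa", l, "_b2")]])
}

block_forward <- function(x, params, bn, prefix, train, keep_cache) {
  c1 <- conv3x3_forward(x, params[[paste0(prefix, "_conv1_W")]],
                        params[[paste0(prefix, "_conv1_b")]], keep_cache)
  n1 <- batchnorm_forward(c1$out, params[[paste0(prefix, "_bn1_gamma")]],
                          params[[paste0(prefix, "_bn1_beta")]],
                          bn[[paste0(prefix, "_bn1")]], train,
                          keep_cache = keep_cache)
  bn[[paste0(prefix, "_bn1")]] <- n1$running
  r1 <- relu_forward(n1$out, keep_cache)
  c2 <- conv3x3_forward(r1$out, params[[paste0(prefix, "_conv2_W")]],
                        params[[paste0(prefix, "_conv2_b")]], keep_cache)
  n2 <- batchnorm_forward(c2$out, params[[paste0(prefix, "_bn2_gamma")]],
                          params[[paste0(prefix, "_bn2_beta")]],
                          bn[[paste0(prefix, "_bn2")]], train,
                          keep_cache = keep_cache)
  bn[[paste0(prefix, "_bn2")]] <- n2$running
  r2 <- relu_forward(n2$out, keep_cache)
  list(out = r2$out, bn = bn,
       cache = if (keep_cache) list(c1 = c1$cache, n1 = n1$cache, r1 = r1$cache,
                                    c2 = c2$cache, n2 = n2$cache, r2 = r2$cache) else NULL)
}

block_backward <- function(dout, params, prefix, cache) {
  g <- list()
  d <- relu_backward(dout, cache$r2)
  bnb <- batchnorm_backward(d, params[[paste0(prefix, "_bn2_gamma")]], cache$n2)
  g[[paste0(prefix, "_bn2_gamma")]] <- bnb$dgamma
  g[[paste0(prefix, "_bn2_beta")]] <- bnb$dbeta
  cb <- conv3x3_backward(bnb$dx, params[[paste0(prefix, "_conv2_W")]], cache$c2)
  g[[paste0(prefix, "_conv2_W")]] <- cb$dW
  g[[paste0(prefix, "_conv2_b")]] <- cb$db
  d <- relu_backward(cb$dx, cache$r1)
  bnb <- batchnorm_backward(d, params[[paste0(prefix, "_bn1_gamma")]], cache$n1)
  g[[paste0(prefix, "_bn1_gamma")]] <- bnb$dgamma
  g[[paste0(prefix, "_bn1_beta")]] <- bnb$dbeta
  cb <- conv3x3_backward(bnb$dx, params[[paste0(prefix, "_conv1_W")]], cache$c1)
  g[[paste0(prefix, "_conv1_W")]] <- cb$dW
  g[[paste0(prefix, "_conv1_b")]] <- cb$db
  list(dx = cb$dx, grads = g)
}

check_forward_input <- function(cfg, x) {
  d <- dim(x)
  if (d[1] != cfg$in_channels) {
    stop(sprintf("input has %d channels; model expects %d", d[1], cfg$in_channels),
         call. = FALSE)
  }
  div <- 2L^cfg$depth
  if (d[2] %% div != 0L || d[3] %% div != 0L) {
    stop(sprintf("input %dx%d not divisible by 2^depth = %d", d[2], d[3], div),
         call. = FALSE)
  }
  invisible(NULL)
}

# Full forward pass. `train` toggles batch-norm mode; `keep_cache` retains
# every intermediate needed by net_backward().
net_forward <- function(model, x, train = FALSE, keep_cache = train) {
  cfg <- model$config
  x <- as_batch(x)
  check_forward_input(cfg, x)
  params <- model$params
  bn <- model$bn
  skips <- list(); caches <- list(enc = list(), pool = list(), sa = list(),
                                  up = list(), dec = list())
  h <- x
  for (l in seq_len(cfg$depth)) {
    bf <- block_forward(h, params, bn, paste0("enc", l), train, keep_cache)
    bn <- bf$bn
    caches$enc[[l]] <- bf$cache
    h <- bf$out
    if (cfg$use_spatial_attention && l %in% cfg$sa_levels) {
      sf <- sa_forward(h, sa_param_subset(params, l), keep_cache)
      caches$sa[[l]] <- sf$cache
      h <- sf$out
    }
    skips[[l]] <- h
    pf <- maxpool2_forward(h, keep_cache)
    caches$pool[[l]] <- pf$cache
    h <- pf$out
  }
  bf <- block_forward(h, params, bn, "bott", train, keep_cache)
  bn <- bf$bn
  caches$bott <- bf$cache
  h <- bf$out
  if (cfg$use_channel_attention) {
    cf <- ca_forward(h, list(W1 = params$ca_W1, b1 = params$ca_b1,
                             W2 = params$ca_W2, b2 = params$ca_b2), keep_cache)
    caches$ca <- cf$cache
    h <- cf$out
  }
  bott_out <- if (keep_cache) h else NULL
  for (l in rev(seq_len(cfg$depth))) {
    uf <- upsample2_forward(h)
    caches$up[[l]] <- uf$cache
    h <- concat_channels(uf$out, skips[[l]])
    bf <- block_forward(h, params, bn, paste0("dec", l), train, keep_cache)
    bn <- bf$bn
    caches$dec[[l]] <- bf$cache
    h <- bf$out
  }
  hf <- conv1x1_forward(h, params$head_W, params$head_b, keep_cache)
  list(logits = hf$out, bn = bn, skips = if (keep_cache) skips else NULL,
       bott_out = bott_out,
       cache = if (keep_cache) c(caches, list(head = hf$cache)) else NULL)
}

# Backward pass: gradients of a scalar loss with respect to every parameter,
# given d(loss)/d(logits) from a cached training forward pass. Returns a flat
# named list aligned with model$params.
net_backward <- function(model, fw, dlogits) {
  cfg <- model$config
  params <- model$params
  grads <- list()
  hb <- conv1x1_backward(dlogits, params$head_W, fw$cache$head)
  grads$head_W <- hb$dW
  grads$head_b <- hb$db
  d <- hb$dx
  # Decoder ran l = depth..1 in forward, so backward ascends l = 1..depth;
  # after each level, d is the gradient at the output of the stage below
  # (the next decoder block, or the bottleneck at l = depth).
  dskip <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    bb <- block_backward(d, params, paste0("dec", l), fw$cache$dec[[l]])
    grads <- c(grads, bb$grads)
    dcat <- bb$dx
    up_ch <- cfg$base_channels * 2L^l
    dup <- dcat[seq_len(up_ch), , , , drop = FALSE]
    dskip[[l]] <- dcat[up_ch + seq_len(enc_channels(cfg, l)), , , , drop = FALSE]
    d <- upsample2_backward(dup, fw$cache$up[[l]])
  }
  if (cfg$use_channel_attention) {
    cb <- ca_backward(d, list(W1 = params$ca_W1, b1 = params$ca_b1,
                              W2 = params$ca_W2, b2 = params$ca_b2), fw$cache$ca)
    grads$ca_W1 <- cb$grads$W1; grads$ca_b1 <- cb$grads$b1
    grads$ca_W2 <- cb$grads$W2; grads$ca_b2 <- cb$grads$b2
    d <- cb$dx
  }
  bb <- block_backward(d, params, "bott", fw$cache$bott)
  grads <- c(grads, bb$grads)
  d <- bb$dx
  for (l in rev(seq_len(cfg$depth))) {
    d <- maxpool2_backward(d, fw$cache$pool[[l]])
    d <- d + dskip[[l]]          # gradient into the (possibly recalibrated)
                                 # encoder output: pooled path + skip copy
    if (cfg$use_spatial_attention && l %in% cfg$sa_levels) {
      sp <- sa_param_subset(params, l)
      sb <- sa_backward(d, sp, fw$cache$sa[[l]])
      grads[[paste0("sa", l, "_W1")]] <- sb$grads$W1
      grads[[paste0("sa", l, "_b1")]] <- sb$grads$b1
      grads[[paste0("sa", l, "_W2")]] <- sb$grads$W2
      grads[[paste0("sa", l, "_b2")]] <- sb$grads$b2
      d <- sb$dx
    }
    bb <- block_backward(d, params, paste0("enc", l), fw$cache$enc[[l]])
    grads <- c(grads, bb$grads)
    d <- bb$dx
  }
  grads
}

#' Segmentation logits for one image
#'
#' Runs the network in evaluation mode (batch-norm running statistics).
#'
#' @param model A `scau_net`.
#' @param image Array (in_channels, H, W) with H, W divisible by 2^depth.
#' @return Logits array (num_classes, H, W).
#' @export
forward_logits <- function(model, image) {
  check_feature_map(image, "image")
  fw <- net_forward(model, image, train = FALSE, keep_cache = FALSE)
  out <- fw$logits
  dim(out) <- dim(out)[1:3]
  out
}

#' Predict a binary mask
#'
#' Decodes the two-class logits by per-pixel argmax. Ties resolve to the
#' lowest class index (background).
#'
#' @param model A `scau_net`.
#' @param image Array (in_channels, H, W).
#' @return Integer H x W matrix with values in {0, 1}.
#' @export
predict_mask <- function(model, image) {
  logits <- forward_logits(model, image)
  argmax_mask(logits)
}

# Per-pixel argmax over the class axis of (C,H,W) logits; ties -> class 0.
argmax_mask <- function(logits) {
  d <- dim(logits)
  out <- matrix(0L, d[2], d[3])
  best <- logits[1, , ]
  for (k in 2:d[1]) {
    plane <- logits[k, , ]
    sel <- plane > best
    out[sel] <- k - 1L
    best[sel] <- plane[sel]
  }
  out
}
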