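# Primitive network layers on plain R arrays.
#
# A feature batch is a 4-D double array with dim (C, H, W, N): channel first
# (fastest-varying in memory), then rows, columns, and the batch axis last.
# Single feature maps (C, H, W) are promoted to N = 1 where needed.
# All layers return list(out = ..., cache = ...); the cache carries exactly
# what the matching *_backward() needs.

BN_EPS <- 1e-5

#' @keywords internal
as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stop("expected a (C,H,W) feature map or a (C,H,W,N) batch", call. = FALSE)
  }
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

check_feature_map <- function(u, arg = "u") {
  d <- dim(u)
  if (is.null(d) || length(d) != 3L) {
    stop(sprintf("`%s` must be a 3-d array (channels, height, width)", arg),
         call. = FALSE)
  }
  if (any(d < 1L)) stop(sprintf("`%s` has non-positive dimensions", arg), call. = FALSE)
  if (!all(is.finite(u))) stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  invisible(u)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- parameter initialisation -----------------------------------------------

#' Kaiming-uniform weight draw
#'
#' Weights are drawn from U(-b, b) with b = sqrt(6 / fan_in), the ReLU-gain
#' uniform scheme; biases start at zero.
#' @keywords internal
kaiming_uniform <- function(n_out, n_in) {
  b <- sqrt(6 / n_in)
  matrix(stats::runif(n_out * n_in, -b, b), n_out, n_in)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# ---- 3x3 convolution (stride 1, padding 1) ----------------------------------
#
# Weights are stored as a (C_out x 9*C_in) matrix. Column (k-1)*C_in + c holds
# the kernel tap for input channel c at offset k in 1..9, where k enumerates
# (dh, dw) in {0,1,2}^2 with dh fastest: k = dw*3 + dh + 1. A tap (dh, dw)
# reads the padded input at (h + dh, w + dw) for output position (h, w), i.e.
# kernel row index dh+1, kernel column index dw+1.

im2col3 <- function(x) {
  d <- dim(x)
  im2col3_cpp(x, d[1], d[2], d[3], d[4])
}

col2im3 <- function(dP, C, H, W, N) {
  dx <- col2im3_cpp(dP, C, H, W, N)
  dim(dx) <- c(C, H, W, N)
  dx
}

# Patch-matrix budget for cache-free forwards; beyond it the image is
# processed in column strips (the 3x3 support only needs one neighbouring
# column on each side, so strips overlap by one and edge strips keep the
# genuine zero padding). Overridable via options(scaunet.patch_bytes = ...).
PATCH_BYTES_LIMIT <- 256e6

conv3x3_forward <- function(x, W_mat, b, keep_cache = TRUE) {
  d <- dim(x)
  limit <- getOption("scaunet.patch_bytes", PATCH_BYTES_LIMIT)
  patch_bytes <- 9 * d[1] * prod(d[-1]) * 8
  if (keep_cache || patch_bytes <= limit) {
    P <- im2col3(x)
    out <- W_mat %*% P + b
    dim(out) <- c(nrow(W_mat), d[2], d[3], d[4])
    return(list(out = out,
                cache = if (keep_cache) list(P = P, dims = d) else NULL))
  }
  C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  cw <- max(1L, floor(limit / (9 * C * H * N * 8)))
  out <- array(0, c(nrow(W_mat), H, W, N))
  a <- 1L
  while (a <= W) {
    bnd <- min(a + cw - 1L, W)
    lo <- max(a - 1L, 1L); hi <- min(bnd + 1L, W)
    sub <- x[, , lo:hi, , drop = FALSE]
    P <- im2col3(sub)
    os <- W_mat %*% P + b
    dim(os) <- c(nrow(W_mat), H, hi - lo + 1L, N)
    out[, , a:bnd, ] <- os[, , (a - lo + 1L):(bnd - lo + 1L), , drop = FALSE]
    a <- bnd + 1L
  }
  list(out = out, cache = NULL)
}

conv3x3_backward <- function(dout, W_mat, cache) {
  d <- cache$dims
  dm <- dout; dim(dm) <- c(nrow(W_mat), d[2] * d[3] * d[4])
  dW <- tcrossprod(dm, cache$P)
  db <- rowSums(dm)
  dP <- crossprod(W_mat, dm)
  dx <- col2im3(dP, d[1], d[2], d[3], d[4])
  list(dx = dx, dW = dW, db = db)
}

# ---- 1x1 convolution ---------------------------------------------------------

conv1x1_forward <- function(x, W_mat, b, keep_cache = TRUE) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1], d[2] * d[3] * d[4])
  out <- W_mat %*% xm + b
  dim(out) <- c(nrow(W_mat), d[2], d[3], d[4])
  list(out = out, cache = if (keep_cache) list(xm = xm, dims = d) else NULL)
}

conv1x1_backward <- function(dout, W_mat, cache) {
  d <- cache$dims
  dm <- dout; dim(dm) <- c(nrow(W_mat), d[2] * d[3] * d[4])
  dW <- tcrossprod(dm, cache$xm)
  db <- rowSums(dm)
  dx <- crossprod(W_mat, dm)
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

# ---- batch normalisation -----------------------------------------------------
#
# Per-channel normalisation over the batch and spatial axes. Train mode uses
# batch statistics (biased variance) and updates running averages with
# momentum 0.1; eval mode uses the running averages.

batchnorm_forward <- function(x, gamma, beta, running, train, momentum = 0.1,
                              keep_cache = TRUE) {
  d <- dim(x); C <- d[1]
  xm <- x; dim(xm) <- c(C, prod(d[-1]))
  if (train) {
    mu <- rowMeans(xm)
    va <- rowMeans(xm * xm) - mu * mu
    va <- pmax(va, 0)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var  <- (1 - momentum) * running$var + momentum * va
  } else {
    mu <- running$mean
    va <- running$var
  }
  inv_sd <- 1 / sqrt(va + BN_EPS)
  xhat <- (xm - mu) * inv_sd
  out <- gamma * xhat + beta
  dim(out) <- d
  list(out = out, running = running,
       cache = if (keep_cache) list(xhat = xhat, inv_sd = inv_sd, dims = d) else NULL)
}

batchnorm_backward <- function(dout, gamma, cache) {
  d <- cache$dims
  dm <- dout; dim(dm) <- c(d[1], prod(d[-1]))
  xhat <- cache$xhat
  dgamma <- rowSums(dm * xhat)
  dbeta <- rowSums(dm)
  dxhat <- dm * gamma
  dx <- cache$inv_sd *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- ReLU --------------------------------------------------------------------

relu_forward <- function(x, keep_cache = TRUE) {
  mask <- x > 0
  x[!mask] <- 0
  list(out = x, cache = if (keep_cache) mask else NULL)
}

relu_backward <- function(dout, mask) {
  dout[!mask] <- 0
  dout
}

# ---- 2x2 max pooling, stride 2 -----------------------------------------------

maxpool2_forward <- function(x, keep_cache = TRUE) {
  d <- dim(x)
  if (d[2] %% 2L != 0L || d[3] %% 2L != 0L) {
    stop("spatial dimensions must be even for 2x2 max pooling", call. = FALSE)
  }
  ro <- seq(1L, d[2], 2L); re <- ro + 1L
  co <- seq(1L, d[3], 2L); ce <- co + 1L
  s1 <- x[, ro, co, , drop = FALSE]
  s2 <- x[, re, co, , drop = FALSE]
  s3 <- x[, ro, ce, , drop = FALSE]
  s4 <- x[, re, ce, , drop = FALSE]
  out <- s1; idx <- array(1L, dim(out))
  m <- s2 > out; out[m] <- s2[m]; idx[m] <- 2L
  m <- s3 > out; out[m] <- s3[m]; idx[m] <- 3L
  m <- s4 > out; out[m] <- s4[m]; idx[m] <- 4L
  list(out = out, cache = if (keep_cache) list(idx = idx, dims = d) else NULL)
}

maxpool2_backward <- function(dout, cache) {
  d <- cache$dims
  idx <- cache$idx
  dx <- array(0, d)
  ro <- seq(1L, d[2], 2L); re <- ro + 1L
  co <- seq(1L, d[3], 2L); ce <- co + 1L
  rows <- list(ro, re, ro, re)
  cols <- list(co, co, ce, ce)
  for (k in 1:4) {
    sel <- idx == k
    if (!any(sel)) next
    blk <- array(0, dim(dout))
    blk[sel] <- dout[sel]
    dx[, rows[[k]], cols[[k]], ] <- dx[, rows[[k]], cols[[k]], , drop = FALSE] + blk
  }
  dx
}

# ---- bilinear interpolation --------------------------------------------------
#
# interp_matrix(n_out, n_in) is the dense 1-d bilinear resampling operator
# under the half-pixel (align_corners = FALSE) convention: output sample i
# reads source coordinate (i - 0.5) * n_in / n_out - 0.5 (0-based), clamped
# to the valid range. 2-d resampling applies it separably to rows and
# columns; the backward pass is the transposed operator.

interp_matrix <- function(n_out, n_in) {
  M <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale - 0.5       # 0-based source coordinate
    l <- floor(src)
    frac <- src - l
    l0 <- min(max(l, 0), n_in - 1)
    l1 <- min(max(l + 1, 0), n_in - 1)
    M[i, l0 + 1] <- M[i, l0 + 1] + (1 - frac)
    M[i, l1 + 1] <- M[i, l1 + 1] + frac
  }
  M
}

# Apply row operator R (H2 x H) and column operator Cm (W2 x W) to a batch.
resample_bilinear <- function(x, Rm, Cm) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  H2 <- nrow(Rm); W2 <- nrow(Cm)
  y <- aperm(x, c(2, 1, 3, 4)); dim(y) <- c(H, C * W * N)
  y <- Rm %*% y; dim(y) <- c(H2, C, W, N)
  y <- aperm(y, c(3, 2, 1, 4)); dim(y) <- c(W, C * H2 * N)
  y <- Cm %*% y; dim(y) <- c(W2, C, H2, N)
  aperm(y, c(2, 3, 1, 4))
}

upsample2_forward <- function(x) {
  d <- dim(x)
  Rm <- interp_matrix(2L * d[2], d[2])
  Cm <- interp_matrix(2L * d[3], d[3])
  list(out = resample_bilinear(x, Rm, Cm), cache = list(Rm = Rm, Cm = Cm))
}

upsample2_backward <- function(dout, cache) {
  resample_bilinear(dout, t(cache$Rm), t(cache$Cm))
}

# ---- channel concatenation ---------------------------------------------------

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[-1] == db[-1]))
  out <- array(0, c(da[1] + db[1], da[2], da[3], da[4]))
  out[seq_len(da[1]), , , ] <- a
  out[da[1] + seq_len(db[1]), , , ] <- b
  out
}
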