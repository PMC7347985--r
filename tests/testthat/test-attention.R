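# Spatial and channel attention modules against brute-force oracles.

test_that("channel aggregation matches the per-position mean oracle", {
  # constant / identity corner cases
  u <- array(0, c(2, 2, 2)); u[1, , ] <- 1; u[2, , ] <- 3
  expect_equal(aggregate_channels(u), matrix(2, 2, 2))
  u1 <- array(rnorm(1 * 5 * 4), c(1, 5, 4))
  expect_equal(aggregate_channels(u1), u1[1, , ])

  set.seed(101)
  u <- array(rnorm(64 * 32 * 32), c(64, 32, 32))
  expect_equal(aggregate_channels(u), oracle_channel_mean(u), tolerance = 1e-6)
})

test_that("spatial aggregation matches the per-channel mean oracle", {
  u <- array(rep(0:4, each = 6 * 6), c(6, 6, 5))
  u <- aperm(u, c(3, 1, 2))             # channel c filled with value c-1
  expect_equal(aggregate_spatial(u), as.numeric(0:4))
  u1 <- array(c(2, 7, -1), c(3, 1, 1))
  expect_equal(aggregate_spatial(u1), c(2, 7, -1))

  set.seed(102)
  u <- array(rnorm(128 * 16 * 16), c(128, 16, 16))
  expect_equal(aggregate_spatial(u), oracle_spatial_mean(u), tolerance = 1e-6)
})

test_that("spatial weight learner equals the sliding-window oracle and stays in (0,1)", {
  set.seed(103)
  params <- sa_params(hidden = 16, seed = 42)
  p <- matrix(rnorm(12 * 10), 12, 10)
  t_map <- spatial_weight_learner(p, params)
  expect_equal(dim(t_map), dim(p))
  expect_true(all(t_map > 0 & t_map < 1))

  # dense reimplementation: conv(1->m), relu, conv(m->1), sigmoid
  x <- array(p, c(1, nrow(p), ncol(p)))
  h <- oracle_conv3x3(x, params$W1, params$b1)
  h[h < 0] <- 0
  z <- oracle_conv3x3(h, params$W2, params$b2)
  expect_equal(t_map, 1 / (1 + exp(-z[1, , ])), tolerance = 1e-5)

  # zero parameters give sigmoid(0) = 0.5 everywhere
  zp <- params
  zp$W1[] <- 0; zp$b1[] <- 0; zp$W2[] <- 0; zp$b2[] <- 0
  expect_equal(spatial_weight_learner(p, zp), matrix(0.5, 12, 10))

  expect_error(spatial_weight_learner(1:3, params), "matrix")
})

test_that("channel weight learner equals dense matvec arithmetic and counts parameters", {
  set.seed(104)
  params <- ca_params(channels = 20, hidden = 32, seed = 7)
  q <- rnorm(20)
  v <- channel_weight_learner(q, params)
  expect_length(v, 20)
  expect_true(all(v > 0 & v < 1))
  a <- pmax(as.vector(params$W1 %*% q + params$b1), 0)
  z <- as.vector(params$W2 %*% a + params$b2)
  expect_equal(v, 1 / (1 + exp(-z)), tolerance = 1e-6)

  zp <- params
  zp$W1[] <- 0; zp$b1[] <- 0; zp$W2[] <- 0; zp$b2[] <- 0
  expect_equal(channel_weight_learner(q, zp), rep(0.5, 20))

  expect_error(channel_weight_learner(rnorm(5), params), "does not match")

  # closed-form parameter counts, biases included
  expect_identical(n_attention_params(ca_params(1024, 32, seed = 1)), 66592L)
  expect_identical(n_attention_params(sa_params(16, seed = 1)),
                   (1L * 16L * 9L + 16L) + (16L * 9L + 1L))
})

test_that("recalibration is elementwise multiplication by the broadcast weights", {
  set.seed(105)
  u <- array(rnorm(6 * 8 * 8), c(6, 8, 8))
  sp <- sa_params(seed = 9)
  cp <- ca_params(6, seed = 9)

  t_map <- spatial_weight_learner(aggregate_channels(u), sp)
  out_sa <- apply_spatial_attention(u, sp)
  v <- channel_weight_learner(aggregate_spatial(u), cp)
  out_ca <- apply_channel_attention(u, cp)
  for (c in 1:6) {
    for (h in 1:8) {
      for (w in 1:8) {
        expect_equal(out_sa[c, h, w], u[c, h, w] * t_map[h, w])
        expect_equal(out_ca[c, h, w], u[c, h, w] * v[c])
      }
    }
  }

  # zero-parameter modules scale features by exactly 0.5
  zs <- sp; zs$W1[] <- 0; zs$b1[] <- 0; zs$W2[] <- 0; zs$b2[] <- 0
  zc <- cp; zc$W1[] <- 0; zc$b1[] <- 0; zc$W2[] <- 0; zc$b2[] <- 0
  expect_equal(apply_spatial_attention(u, zs), 0.5 * u)
  expect_equal(apply_channel_attention(u, zc), 0.5 * u)

  # zero input stays zero regardless of parameters
  z <- array(0, c(6, 8, 8))
  expect_equal(apply_spatial_attention(z, sp), z)
  expect_equal(apply_channel_attention(z, cp), z)
})

test_that("both modules preserve shape and strictly attenuate nonzero entries", {
  set.seed(106)
  for (dims in list(c(3, 4, 4), c(64, 32, 32), c(5, 7, 9))) {
    u <- array(rnorm(prod(dims)), dims)
    sp <- sa_params(seed = 1)
    cp <- ca_params(dims[1], seed = 1)
    out_sa <- apply_spatial_attention(u, sp)
    out_ca <- apply_channel_attention(u, cp)
    expect_identical(dim(out_sa), dim(u))
    expect_identical(dim(out_ca), dim(u))
    nz <- u != 0
    expect_true(all(abs(out_sa[nz]) < abs(u[nz])))
    expect_true(all(abs(out_ca[nz]) < abs(u[nz])))
  }
  # large-shape contract at the paper's bottleneck scale, kept cheap
  u <- array(rnorm(1024 * 4 * 4), c(1024, 4, 4))
  expect_identical(dim(apply_channel_attention(u, ca_params(1024, seed = 2))),
                   c(1024L, 4L, 4L))
})

test_that("module outputs carry nonzero gradients to inputs and all parameters", {
  ns <- asNamespace("scaunet")
  set.seed(107)
  x <- array(rnorm(5 * 6 * 6 * 1), c(5, 6, 6, 1))
  dout <- array(1, dim(x))

  sp <- sa_params(seed = 3)
  fw <- ns$sa_forward(x, sp, keep_cache = TRUE)
  bk <- ns$sa_backward(dout, sp, fw$cache)
  expect_gt(sum(abs(bk$dx)), 0)
  for (g in bk$grads) expect_gt(sum(abs(g)), 0)

  cp <- ca_params(5, seed = 3)
  fw <- ns$ca_forward(x, cp, keep_cache = TRUE)
  bk <- ns$ca_backward(dout, cp, fw$cache)
  expect_gt(sum(abs(bk$dx)), 0)
  for (g in bk$grads) expect_gt(sum(abs(g)), 0)
})

test_that("attention module gradients agree with central finite differences", {
  ns <- asNamespace("scaunet")
  set.seed(108)
  x <- array(rnorm(3 * 5 * 5 * 2), c(3, 5, 5, 2))
  tgt <- array(rnorm(prod(dim(x))), dim(x))
  eps <- 1e-6

  check_module <- function(params, fwd, bwd) {
    loss_of <- function(p) sum(fwd(x, p)$out * tgt)
    fw <- fwd(x, params)
    bk <- bwd(tgt, params, fw$cache)
    for (nm in c("W1", "b1", "W2", "b2")) {
      idx <- sample(length(params[[nm]]), min(4, length(params[[nm]])))
      for (i in idx) {
        p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps; up <- loss_of(p2)
        p2[[nm]][i] <- p2[[nm]][i] - 2 * eps; dn <- loss_of(p2)
        num <- (up - dn) / (2 * eps)
        expect_equal(bk$grads[[nm]][i], num, tolerance = 1e-4)
      }
    }
    i <- sample(length(x), 5)
    for (j in i) {
      x2 <- x; x2[j] <- x2[j] + eps
      up <- sum(fwd(x2, params)$out * tgt)
      x2[j] <- x2[j] - 2 * eps
      dn <- sum(fwd(x2, params)$out * tgt)
      expect_equal(bk$dx[j], (up - dn) / (2 * eps), tolerance = 1e-4)
    }
  }

  check_module(sa_params(hidden = 4, seed = 5),
               function(x, p) ns$sa_forward(x, p, keep_cache = TRUE),
               ns$sa_backward)
  check_module(ca_params(3, hidden = 4, seed = 5),
               function(x, p) ns$ca_forward(x, p, keep_cache = TRUE),
               ns$ca_backward)
})
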