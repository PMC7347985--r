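# Architecture contracts of the encoder-decoder.

test_that("encoder channels double per level and blocks count parameters in closed form", {
  cfg <- scau_config(base_channels = 64, depth = 4, seed = 1)
  model <- build_scau_net(cfg)
  # conv2 of each encoder block maps out_ch -> out_ch: its weight matrix has
  # out_ch rows, pinning the channel plan 64,128,256,512 and bottleneck 1024
  for (l in 1:4) {
    expect_identical(nrow(model$params[[paste0("enc", l, "_conv1_W")]]),
                     as.integer(64 * 2^(l - 1)))
  }
  expect_identical(nrow(model$params$bott_conv1_W), 1024L)

  # Block(x) = (conv 9*in*out + out) + 2*out + (conv 9*out*out + out) + 2*out
  expect_identical(n_block_params(3L, 64L),
                   (9L * 3L * 64L + 64L) + 2L * 64L +
                     (9L * 64L * 64L + 64L) + 2L * 64L)
  small <- build_scau_net(scau_config(base_channels = 4, depth = 1, seed = 1))
  expect_identical(
    length(small$params$enc1_conv1_W) + length(small$params$enc1_conv1_b) +
      length(small$params$enc1_bn1_gamma) + length(small$params$enc1_bn1_beta) +
      length(small$params$enc1_conv2_W) + length(small$params$enc1_conv2_b) +
      length(small$params$enc1_bn2_gamma) + length(small$params$enc1_bn2_beta),
    n_block_params(3L, 4L))
})

test_that("blocks preserve spatial shape for odd and even sizes", {
  ns <- asNamespace("scaunet")
  model <- build_scau_net(scau_config(base_channels = 4, depth = 1, seed = 2))
  for (hw in list(c(5L, 9L), c(8L, 8L), c(1L, 3L))) {
    x <- array(rnorm(3 * hw[1] * hw[2]), c(3L, hw, 1L))
    bf <- ns$block_forward(x, model$params, model$bn, "enc1",
                           train = FALSE, keep_cache = FALSE)
    expect_identical(dim(bf$out), c(4L, hw, 1L))
  }
})

test_that("disabling attention reproduces a plain U-Net parameter set exactly", {
  base <- scau_config(base_channels = 8, depth = 3, seed = 5)
  plain <- build_scau_net(base)
  expect_false(any(grepl("^(sa|ca)", names(plain$params))))

  # closed-form plain U-Net count: encoder + bottleneck + decoder + 1x1 head
  expected <- n_block_params(3L, 8L) + n_block_params(8L, 16L) +
    n_block_params(16L, 32L) +                       # encoder
    n_block_params(32L, 64L) +                        # bottleneck
    n_block_params(64L + 32L, 32L) + n_block_params(32L + 16L, 16L) +
    n_block_params(16L + 8L, 8L) +                    # decoder
    (8L * 2L + 2L)                                    # head
  expect_identical(n_parameters(plain), expected)

  # attention arms add exactly their module counts
  sa_only <- build_scau_net(modifyList(base, list(use_spatial_attention = TRUE)))
  ca_only <- build_scau_net(modifyList(base, list(use_channel_attention = TRUE)))
  expect_identical(n_parameters(sa_only) - n_parameters(plain),
                   as.integer(n_attention_params(sa_params(16, seed = 1))))
  expect_identical(n_parameters(ca_only) - n_parameters(plain),
                   as.integer(n_attention_params(ca_params(64, 32, seed = 1))))
})

test_that("forward pass maps (3,H,W) to (2,H,W) and rejects indivisible sizes", {
  model <- tiny_model(seed = 6)
  set.seed(301)
  x <- array(runif(3 * 64 * 64), c(3, 64, 64))
  lg <- forward_logits(model, x)
  expect_identical(dim(lg), c(2L, 64L, 64L))
  # two eval-mode passes are identical
  expect_identical(lg, forward_logits(model, x))
  expect_error(forward_logits(model, array(0, c(3, 60, 64))), "divisible")
  expect_error(forward_logits(model, array(0, c(1, 64, 64))), "channels")
})

test_that("zeroed spatial-attention parameters halve the recalibrated features", {
  ns <- asNamespace("scaunet")
  set.seed(302)
  sa_on <- build_scau_net(scau_config(base_channels = 4, depth = 2,
                                      use_spatial_attention = TRUE, seed = 9))
  for (nm in grep("^sa1_", names(sa_on$params), value = TRUE)) {
    sa_on$params[[nm]][] <- 0
  }
  sa_off <- build_scau_net(scau_config(base_channels = 4, depth = 2, seed = 9))
  # transplant the shared block parameters so the only difference is the
  # (zeroed) attention module
  shared <- names(sa_off$params)
  sa_off$params[shared] <- sa_on$params[shared]

  x <- array(rnorm(3 * 16 * 16), c(3, 16, 16, 1))
  fw_on <- ns$net_forward(sa_on, x, train = FALSE, keep_cache = TRUE)
  fw_off <- ns$net_forward(sa_off, x, train = FALSE, keep_cache = TRUE)
  # encoder level-1 output of the attention model is exactly half the plain one
  expect_equal(fw_on$skips[[1]], 0.5 * fw_off$skips[[1]], tolerance = 1e-12)
})

test_that("mask prediction is the per-pixel argmax with ties to background", {
  logits <- array(0, c(2, 3, 3))
  logits[2, , ] <- 1
  model_free_mask <- asNamespace("scaunet")$argmax_mask
  expect_equal(model_free_mask(logits), matrix(1L, 3, 3))
  logits[2, , ] <- 0                    # tie -> class 0
  expect_equal(model_free_mask(logits), matrix(0L, 3, 3))
  set.seed(303)
  logits <- array(rnorm(2 * 6 * 5), c(2, 6, 5))
  expect_equal(model_free_mask(logits), oracle_argmax(logits))
})

test_that("checkpoints round-trip bit-exactly through disk", {
  model <- tiny_model(seed = 12)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_checkpoint(path)
  expect_identical(back$params, model$params)
  expect_identical(back$bn, model$bn)
  expect_identical(unclass(back$config), unclass(model$config))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(side$base_channels, 8L)
  expect_error(load_checkpoint(tempfile()), "not found")
})
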