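# Attention and feature inspection: snapshots of intermediate encoder /
# bottleneck activations and, where spatial attention is active, the learned
# (0,1) weight map, exported as grayscale PNGs.

valid_level_tags <- function(cfg) {
  c(paste0("encoder-block-", seq_len(cfg$depth)), "bottleneck")
}

#' Capture intermediate activations
#'
#' Runs one evaluation-mode forward pass and returns, for each requested
#' level, the feature map that flows onward from that level (for encoder
#' levels this is the block output after any spatial-attention
#' recalibration, i.e. the value copied over the skip connection) and, when
#' spatial attention is active there, the spatial weight map.
#'
#' @param model A `scau_net`.
#' @param image Array (in_channels, H, W).
#' @param levels Character level tags: `"encoder-block-<l>"` or
#'   `"bottleneck"`.
#' @return A list of snapshots, each a list with `level`, `features`
#'   (C x H x W array) and `weights` (H x W matrix in (0,1), or NULL when no
#'   spatial attention is applied at that level).
#' @export
capture_activations <- function(model, image,
                                levels = "encoder-block-1") {
  check_feature_map(image, "image")
  cfg <- model$config
  valid <- valid_level_tags(cfg)
  bad <- setdiff(levels, valid)
  if (length(bad) > 0) {
    stop("unknown level tag(s) ", paste(bad, collapse = ", "),
         "; valid tags: ", paste(valid, collapse = ", "), call. = FALSE)
  }
  fw <- net_forward(model, image, train = FALSE, keep_cache = TRUE)
  lapply(levels, function(tag) {
    if (tag == "bottleneck") {
      feat <- fw$bott_out
      w <- NULL
    } else {
      l <- as.integer(sub("encoder-block-", "", tag))
      feat <- fw$skips[[l]]
      w <- NULL
      if (cfg$use_spatial_attention && l %in% cfg$sa_levels) {
        t_map <- fw$cache$sa[[l]]$wf$t
        w <- matrix(t_map, dim(t_map)[2], dim(t_map)[3])
      }
    }
    dim(feat) <- dim(feat)[1:3]
    list(level = tag, features = feat, weights = w)
  })
}

# Half-up rounding to 8-bit levels (R's round() is round-half-even).
quantize8 <- function(x) floor(x * 255 + 0.5)

#' Render a spatial-attention weight map and its activation image
#'
#' The weight map (already valued in (0,1)) is written unnormalised as an
#' 8-bit grayscale PNG using half-up rounding, so a constant 0.5 map renders
#' as gray level 128. The companion activation image is the channel mean of
#' the features, min-max normalised to [0,1]; a constant (zero-range)
#' feature map renders as all zeros.
#'
#' @param snapshot One element of [capture_activations()] output; its
#'   `weights` entry must be present.
#' @param out Output path for the weight-map PNG; the activation image goes
#'   to `<out stem>_activation.png`.
#' @return Invisibly, the paths written.
#' @export
render_weight_map <- function(snapshot, out) {
  if (is.null(snapshot$weights)) {
    stop("snapshot has no spatial weight map (no spatial attention at level ",
         snapshot$level, ")", call. = FALSE)
  }
  w8 <- quantize8(snapshot$weights)
  png::writePNG(w8 / 255, out)
  act <- aggregate_channels(snapshot$features)
  rng <- range(act)
  act_n <- if (rng[2] > rng[1]) (act - rng[1]) / (rng[2] - rng[1]) else act * 0
  act_path <- paste0(sub("\\.png$", "", out), "_activation.png")
  png::writePNG(quantize8(act_n) / 255, act_path)
  invisible(c(weights = out, activation = act_path))
}
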