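# Training loss and evaluation metrics.
#
# Training minimises a convex combination of pixel-wise binary cross-entropy
# and a soft Dice loss on the foreground probability plane:
#
#   CE    = -(1/n) sum_i [ y_i log y'_i + (1 - y_i) log(1 - y'_i) ]
#   DiceL = 1 - (2 sum(y' y) + eps) / (sum y' + sum y + eps)
#   Loss  = lambda * CE + (1 - lambda) * DiceL,     lambda = 0.5 by default
#
# The soft Dice *coefficient* is maximised at perfect overlap, so the loss is
# one minus it (the V-Net convention); eps guards empty masks and y' is
# clipped away from {0,1} before the logarithms.
#
# Evaluation metrics operate on binary masks: Dice, Jaccard, and the signed
# relative volume difference (|B| - |A|) / |A|.

CE_CLIP <- 1e-7

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)) &&
      !(is.null(dim(a)) && is.null(dim(b)) && length(a) == length(b))) {
    stop("prediction and ground truth shapes differ", call. = FALSE)
  }
  invisible(NULL)
}

check_binary <- function(m, arg) {
  if (!all(m %in% c(0, 1))) {
    stop(sprintf("`%s` must be binary (0/1)", arg), call. = FALSE)
  }
  invisible(NULL)
}

#' Loss configuration
#'
#' @param lambda Mixing weight of the cross-entropy term, in `[0, 1]`;
#'   `1 - lambda` weights the Dice loss. Default 0.5.
#' @param dice_smooth Additive smoothing of the soft Dice ratio.
#' @return A `loss_config` list.
#' @export
loss_config <- function(lambda = 0.5, dice_smooth = 1e-6) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0 || lambda > 1) {
    stop("`lambda` must be a single value in [0, 1]", call. = FALSE)
  }
  stopifnot(dice_smooth > 0)
  structure(list(lambda = lambda, dice_smooth = dice_smooth),
            class = "loss_config")
}

#' Binary cross-entropy loss
#'
#' Mean over all pixels of the negative log-likelihood of the ground truth
#' under the predicted foreground probability; probabilities are clipped to
#' `[1e-7, 1 - 1e-7]` before the logarithms.
#'
#' @param prob Foreground probabilities, values in `[0, 1]`.
#' @param truth Binary ground-truth mask of the same shape.
#' @return Non-negative scalar.
#' @export
cross_entropy_loss <- function(prob, truth) {
  check_same_shape(prob, truth)
  check_binary(truth, "truth")
  p <- pmin(pmax(prob, CE_CLIP), 1 - CE_CLIP)
  -mean(truth * log(p) + (1 - truth) * log(1 - p))
}

#' Soft Dice loss
#'
#' One minus the smoothed soft Dice coefficient
#' `(2 sum(prob * truth) + eps) / (sum(prob) + sum(truth) + eps)`.
#' Both-empty inputs give loss 0 through the smoothing.
#'
#' @inheritParams cross_entropy_loss
#' @param dice_smooth Smoothing constant eps.
#' @return Scalar in `[0, 1]`.
#' @export
dice_loss <- function(prob, truth, dice_smooth = 1e-6) {
  check_same_shape(prob, truth)
  check_binary(truth, "truth")
  1 - (2 * sum(prob * truth) + dice_smooth) /
    (sum(prob) + sum(truth) + dice_smooth)
}

#' Combined cross-entropy + Dice loss
#'
#' `lambda * CE + (1 - lambda) * DiceLoss`; `lambda = 1` reduces to pure
#' cross-entropy, `lambda = 0` to pure Dice loss.
#'
#' @inheritParams cross_entropy_loss
#' @param cfg A [loss_config()].
#' @return Scalar loss.
#' @export
combined_loss <- function(prob, truth, cfg = loss_config()) {
  stopifnot(inherits(cfg, "loss_config"))
  cfg$lambda * cross_entropy_loss(prob, truth) +
    (1 - cfg$lambda) * dice_loss(prob, truth, cfg$dice_smooth)
}

# Loss and gradient w.r.t. the two-class logits for a batch.
# logits: (2, H, W, N); truth: (H, W, N). The Dice term is computed per
# image, then batch-averaged; CE is the mean over every pixel of the batch.
combined_loss_grad <- function(logits, truth, cfg = loss_config()) {
  d <- dim(logits)
  N <- d[4]
  z0 <- logits[1, , , , drop = FALSE]
  z1 <- logits[2, , , , drop = FALSE]
  p1 <- sigmoid(z1 - z0)           # softmax foreground plane, stable form
  dim(p1) <- d[c(2, 3, 4)]
  tr <- truth; dim(tr) <- d[c(2, 3, 4)]
  n_pix <- length(p1)
  pc <- pmin(pmax(p1, CE_CLIP), 1 - CE_CLIP)
  ce <- -mean(tr * log(pc) + (1 - tr) * log(1 - pc))
  dce_dp <- (-tr / pc + (1 - tr) / (1 - pc)) / n_pix
  eps <- cfg$dice_smooth
  dice_terms <- numeric(N)
  ddice_dp <- array(0, dim(p1))
  for (n in seq_len(N)) {
    pn <- p1[, , n]; tn <- tr[, , n]
    num <- 2 * sum(pn * tn) + eps
    den <- sum(pn) + sum(tn) + eps
    dice_terms[n] <- 1 - num / den
    ddice_dp[, , n] <- -(2 * tn * den - num) / den^2 / N
  }
  dl <- mean(dice_terms)
  loss <- cfg$lambda * ce + (1 - cfg$lambda) * dl
  dp <- cfg$lambda * dce_dp + (1 - cfg$lambda) * ddice_dp
  dz1 <- dp * p1 * (1 - p1)
  dlogits <- array(0, d)
  dlogits[2, , , ] <- dz1
  dlogits[1, , , ] <- -dz1
  list(loss = loss, ce = ce, dice_loss = dl, dlogits = dlogits, prob = p1)
}

#' Dice similarity coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b Binary masks of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice_score <- function(a, b) {
  check_same_shape(a, b)
  check_binary(a, "a"); check_binary(b, "b")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

#' Jaccard coefficient of two binary masks
#'
#' `|A n B| / |A u B|`; defined as 1 when both masks are empty.
#'
#' @inheritParams dice_score
#' @return Scalar in `[0, 1]`.
#' @export
jaccard_score <- function(a, b) {
  check_same_shape(a, b)
  check_binary(a, "a"); check_binary(b, "b")
  inter <- sum(a * b)
  uni <- sum(a) + sum(b) - inter
  if (uni == 0) return(1)
  inter / uni
}

#' Relative volume difference
#'
#' `(|B| - |A|) / |A|`, signed: positive means over-segmentation relative to
#' the ground truth `a`, negative under-segmentation. Undefined (NA) when the
#' ground truth is empty.
#'
#' @param a Ground-truth binary mask.
#' @param b Predicted binary mask of the same shape.
#' @return Scalar, or `NA_real_` when `sum(a) == 0`.
#' @export
rvd_score <- function(a, b) {
  check_same_shape(a, b)
  check_binary(a, "a"); check_binary(b, "b")
  sa <- sum(a)
  if (sa == 0) return(NA_real_)
  (sum(b) - sa) / sa
}

#' Per-image segmentation metrics
#'
#' @param truths,preds Lists of binary masks (same length, matching shapes).
#' @param ids Optional character ids, one per image.
#' @return A tibble of class `scau_metrics` with columns `id`, `dice`,
#'   `jaccard`, `rvd` (NA where the ground truth is empty). Use [glance()]
#'   for the mean aggregate.
#' @export
metrics_report <- function(truths, preds, ids = NULL) {
  stopifnot(length(truths) == length(preds))
  if (is.null(ids)) ids <- sprintf("image_%03d", seq_along(truths))
  out <- tibble::tibble(
    id = as.character(ids),
    dice = purrr::map2_dbl(truths, preds, dice_score),
    jaccard = purrr::map2_dbl(truths, preds, jaccard_score),
    rvd = purrr::map2_dbl(truths, preds, rvd_score)
  )
  class(out) <- c("scau_metrics", class(out))
  out
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' Mean aggregate of a metrics report
#'
#' @param x A `scau_metrics` tibble.
#' @param ... Unused.
#' @return One-row tibble with `n_images`, `mean_dice`, `mean_jaccard`,
#'   `mean_rvd` (mean over images with a defined RVD) and `n_rvd_missing`.
#' @export
glance.scau_metrics <- function(x, ...) {
  tibble::tibble(
    n_images = nrow(x),
    mean_dice = mean(x$dice),
    mean_jaccard = mean(x$jaccard),
    mean_rvd = if (all(is.na(x$rvd))) NA_real_ else mean(x$rvd, na.rm = TRUE),
    n_rvd_missing = sum(is.na(x$rvd))
  )
}

#' Write a metrics report to disk
#'
#' Writes `metrics.csv` (one row per image) and `metrics_summary.json`
#' (the [glance()] means) into `dir`.
#'
#' @param report A `scau_metrics` tibble.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_metrics_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "metrics.csv")
  utils::write.csv(as.data.frame(report), csv, row.names = FALSE)
  js <- file.path(dir, "metrics_summary.json")
  jsonlite::write_json(as.list(glance(report)), js, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(c(csv = csv, json = js))
}
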