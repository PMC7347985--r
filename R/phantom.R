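# Synthetic H&E gland phantoms.
#
# Each phantom is a stained-tissue-like RGB image with a paired binary mask:
# gland objects are star-convex blobs with a purple epithelial rim around a
# near-white lumen, drawn on a pink stromal background with additive Gaussian
# pixel noise. The blob boundary is a radial harmonic perturbation of a
# circle,
#
#   radius(theta) = r0 * (1 + sum_{k=1..4} a_k cos(k theta + phi_k)),
#
# which is closed and hole-free (gland-like) and has an analytic enclosed
# area, so rasterisation can be checked against an exact oracle. The bright
# lumen interior reproduces the classic failure mode where the inside of a
# gland is mistaken for background, and near-touching glands reproduce
# boundary "sticking".

#' Phantom generator configuration
#'
#' Colours are 8-bit RGB triples in 0..255; `noise_sd` is in the same 8-bit
#' intensity units.
#'
#' @param size Image side length in pixels (square images).
#' @param n_glands Integer range (length 2) of gland counts per image.
#' @param radius_range Gland base radius r0 as a fraction of `size`.
#' @param boundary_irregularity Overall amplitude of the radial harmonics;
#'   0 gives circles.
#' @param lumen_fraction Lumen radius as a fraction of the local gland
#'   radius, in (0, 1).
#' @param rim_color,lumen_color,background_color RGB triples.
#' @param noise_sd Additive Gaussian noise standard deviation (8-bit units).
#' @param allow_touching If `FALSE`, gland centres are re-drawn so blobs do
#'   not overlap (bounded retries); if `TRUE`, glands may touch or merge.
#' @param seed Integer seed.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(size = 256L, n_glands = c(3L, 8L),
                           radius_range = c(0.06, 0.18),
                           boundary_irregularity = 0.25,
                           lumen_fraction = 0.5,
                           rim_color = c(120, 60, 140),
                           lumen_color = c(235, 225, 235),
                           background_color = c(230, 180, 200),
                           noise_sd = 8, allow_touching = TRUE, seed = 1L) {
  stopifnot(size >= 8, length(n_glands) == 2, n_glands[1] <= n_glands[2],
            n_glands[1] >= 0, length(radius_range) == 2,
            all(radius_range > 0), radius_range[1] <= radius_range[2],
            boundary_irregularity >= 0,
            lumen_fraction > 0, lumen_fraction < 1,
            noise_sd >= 0,
            all(c(rim_color, lumen_color, background_color) >= 0),
            all(c(rim_color, lumen_color, background_color) <= 255))
  structure(list(size = as.integer(size), n_glands = as.integer(n_glands),
                 radius_range = radius_range,
                 boundary_irregularity = boundary_irregularity,
                 lumen_fraction = lumen_fraction,
                 rim_color = rim_color, lumen_color = lumen_color,
                 background_color = background_color, noise_sd = noise_sd,
                 allow_touching = isTRUE(allow_touching),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Draw one blob's shape parameters. Harmonic amplitudes are scaled so their
# worst-case sum stays below ~0.45, keeping radius(theta) positive.
draw_blob <- function(cfg) {
  r0 <- stats::runif(1, cfg$radius_range[1], cfg$radius_range[2]) * cfg$size
  amp <- cfg$boundary_irregularity * stats::runif(4, 0, 0.45) / (1:4)
  phase <- stats::runif(4, 0, 2 * pi)
  list(r0 = r0, amp = amp, phase = phase)
}

blob_radius <- function(blob, theta) {
  r <- rep(blob$r0, length(theta))
  for (k in 1:4) r <- r + blob$r0 * blob$amp[k] * cos(k * theta + blob$phase[k])
  r
}

# Exact enclosed area of the harmonic boundary:
# (1/2) Int r(theta)^2 dtheta = pi r0^2 (1 + sum a_k^2 / 2).
blob_area <- function(blob) {
  pi * blob$r0^2 * (1 + sum(blob$amp^2) / 2)
}

# Inside test for pixel centres (vectorised over a coordinate grid).
blob_inside <- function(blob, cx, cy, X, Y, scale = 1) {
  dx <- X - cx; dy <- Y - cy
  r <- sqrt(dx * dx + dy * dy)
  theta <- atan2(dy, dx)
  r <= scale * blob_radius(blob, theta)
}

#' Generate one gland phantom
#'
#' @param cfg A [phantom_config()]. The config's `seed` is used unless the
#'   caller has already fixed the RNG state and passes `use_seed = FALSE`
#'   (as [generate_phantom_dataset()] does per image).
#' @param use_seed Whether to seed the RNG from `cfg$seed`.
#' @return A one-row tibble (a labelled sample) with columns `id`,
#'   `image` (list of H x W x 3 double arrays in `[0, 1]`), `mask` (list of
#'   integer H x W matrices in {0, 1}), and `n_glands`.
#' @export
generate_phantom <- function(cfg = phantom_config(), use_seed = TRUE) {
  stopifnot(inherits(cfg, "phantom_config"))
  gen <- function() generate_phantom_impl(cfg)
  if (use_seed) with_seed(cfg$seed, gen()) else gen()
}

generate_phantom_impl <- function(cfg) {
  s <- cfg$size
  grid <- seq_len(s) - 0.5          # pixel centres
  X <- matrix(rep(grid, each = s), s, s)   # column coordinate  (x varies by col)
  Y <- matrix(rep(grid, times = s), s, s)  # row coordinate
  n <- if (cfg$n_glands[1] == cfg$n_glands[2]) cfg$n_glands[1] else
    sample(cfg$n_glands[1]:cfg$n_glands[2], 1)
  mask <- matrix(FALSE, s, s)
  lumen <- matrix(FALSE, s, s)
  placed <- list()
  k <- 0L
  attempts <- 0L
  while (k < n && attempts < 50L * max(n, 1L)) {
    attempts <- attempts + 1L
    blob <- draw_blob(cfg)
    margin <- blob$r0 * (1 + sum(blob$amp))
    if (2 * margin >= s) next      # degenerate for this image size; redraw
    cx <- stats::runif(1, margin, s - margin)
    cy <- stats::runif(1, margin, s - margin)
    if (!cfg$allow_touching && length(placed) > 0) {
      clash <- vapply(placed, function(p) {
        sqrt((p$cx - cx)^2 + (p$cy - cy)^2) <
          (p$margin + margin) * 1.05
      }, logical(1))
      if (any(clash)) next
    }
    inside <- blob_inside(blob, cx, cy, X, Y)
    mask <- mask | inside
    lumen <- lumen | blob_inside(blob, cx, cy, X, Y, scale = cfg$lumen_fraction)
    k <- k + 1L
    placed <- c(placed, list(list(cx = cx, cy = cy, margin = margin,
                                  blob = blob)))
  }
  if (k < n) {
    warning(sprintf("placed %d of %d glands after bounded retries", k, n))
  }
  img <- array(0, c(s, s, 3))
  for (ch in 1:3) {
    plane <- matrix(cfg$background_color[ch], s, s)
    plane[mask] <- cfg$rim_color[ch]
    plane[lumen] <- cfg$lumen_color[ch]
    img[, , ch] <- plane
  }
  if (cfg$noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, cfg$noise_sd)
  }
  img <- pmin(pmax(img, 0), 255) / 255
  tibble::tibble(id = "phantom_000",
                 image = list(img),
                 mask = list(matrix(as.integer(mask), s, s)),
                 n_glands = k)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_images` image/mask PNG pairs in the `images/` + `masks/` layout
#' consumed by [load_dataset()], plus a JSON manifest recording the seed and
#' each image's gland count and foreground area.
#'
#' @param cfg A [phantom_config()]; `cfg$seed` seeds the whole dataset.
#' @param n_images Number of image/mask pairs.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
generate_phantom_dataset <- function(cfg, n_images, out_dir) {
  stopifnot(inherits(cfg, "phantom_config"), n_images >= 1)
  img_dir <- file.path(out_dir, "images")
  msk_dir <- file.path(out_dir, "masks")
  ok <- dir.create(img_dir, showWarnings = FALSE, recursive = TRUE) | dir.exists(img_dir)
  ok2 <- dir.create(msk_dir, showWarnings = FALSE, recursive = TRUE) | dir.exists(msk_dir)
  if (!ok || !ok2) stop("cannot create output directories under ", out_dir, call. = FALSE)
  entries <- with_seed(cfg$seed, {
    lapply(seq_len(n_images), function(i) {
      smp <- generate_phantom(cfg, use_seed = FALSE)
      id <- sprintf("phantom_%03d", i)
      png::writePNG(smp$image[[1]], file.path(img_dir, paste0(id, ".png")))
      png::writePNG(smp$mask[[1]] + 0, file.path(msk_dir, paste0(id, ".png")))
      list(id = id, n_glands = smp$n_glands,
           foreground_area = sum(smp$mask[[1]]))
    })
  })
  manifest <- list(seed = cfg$seed, size = cfg$size, n_images = n_images,
                   images = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Generate an in-memory phantom dataset
#'
#' Like [generate_phantom_dataset()] but returns the samples as a tibble
#' without touching disk.
#'
#' @inheritParams generate_phantom_dataset
#' @return A tibble with columns `id`, `image`, `mask`, `n_glands`.
#' @export
generate_phantom_tibble <- function(cfg, n_images) {
  stopifnot(inherits(cfg, "phantom_config"), n_images >= 1)
  with_seed(cfg$seed, {
    rows <- lapply(seq_len(n_images), function(i) {
      smp <- generate_phantom(cfg, use_seed = FALSE)
      smp$id <- sprintf("phantom_%03d", i)
      smp
    })
    dplyr::bind_rows(rows)
  })
}
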