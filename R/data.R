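# Dataset I/O, resizing and augmentation.
#
# A dataset is a tibble with one row per labelled sample:
#   id    <chr>   basename of the image file
#   image <list>  H x W x 3 double array, values in [0, 1]
#   mask  <list>  integer H x W matrix, values in {0, 1}
#
# On disk the layout is `root/images/<id>.<ext>` + `root/masks/<id>.png`
# (PNG, TIFF or BMP images; single-channel PNG masks stored as {0,1} or
# {0,255}). Masks always travel through nearest-neighbour resampling so they
# stay binary; images through bilinear.

IMAGE_EXTS <- c("png", "tif", "tiff", "bmp")

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    bmp = read_bmp(path),
    stop("unsupported image format: ", path, call. = FALSE)
  )
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3), c(dim(img), 3L))
  } else if (dim(img)[3] == 4L) {
    img <- img[, , 1:3, drop = FALSE]   # drop alpha
  } else if (dim(img)[3] == 2L) {
    img <- array(rep(img[, , 1], 3), c(dim(img)[1:2], 3L))
  }
  img
}

read_mask_file <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(m > 0), nrow(m), ncol(m))
}

# Minimal uncompressed 24-bit BMP reader (bottom-up rows, BI_RGB).
read_bmp <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM") {
    stop("not a BMP file: ", path, call. = FALSE)
  }
  le32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
  le16 <- function(off) sum(as.integer(raw[off + 1:2]) * 256^(0:1))
  data_off <- le32(10)
  w <- le32(18); h <- le32(22)
  bpp <- le16(28)
  if (bpp != 24 || le32(30) != 0) {
    stop("only uncompressed 24-bit BMP is supported: ", path, call. = FALSE)
  }
  row_bytes <- ((w * 3 + 3) %/% 4) * 4
  img <- array(0, c(h, w, 3))
  for (r in seq_len(h)) {
    off <- data_off + (r - 1) * row_bytes
    row <- as.integer(raw[off + seq_len(w * 3)])
    # BGR order, bottom-up
    img[h - r + 1, , 1] <- row[seq(3, w * 3, 3)]
    img[h - r + 1, , 2] <- row[seq(2, w * 3, 3)]
    img[h - r + 1, , 3] <- row[seq(1, w * 3, 3)]
  }
  img / 255
}

#' Load an image/mask dataset from disk
#'
#' Expects `dir/images/` and `dir/masks/` with matching basenames; masks are
#' binarised (any value > 0 becomes 1). Samples are returned sorted by id.
#'
#' @param dir Dataset root directory.
#' @return A tibble with columns `id`, `image`, `mask` (see module header).
#'   An empty directory yields a zero-row tibble with a warning.
#' @export
load_dataset <- function(dir) {
  img_dir <- file.path(dir, "images")
  msk_dir <- file.path(dir, "masks")
  if (!dir.exists(img_dir) || !dir.exists(msk_dir)) {
    stop("expected `images/` and `masks/` under ", dir, call. = FALSE)
  }
  files <- sort(list.files(img_dir,
                           pattern = paste0("\\.(", paste(IMAGE_EXTS, collapse = "|"), ")$"),
                           ignore.case = TRUE))
  if (length(files) == 0) {
    warning("no images found under ", img_dir)
    return(tibble::tibble(id = character(), image = list(), mask = list()))
  }
  ids <- tools::file_path_sans_ext(files)
  mask_paths <- file.path(msk_dir, paste0(ids, ".png"))
  missing <- ids[!file.exists(mask_paths)]
  if (length(missing) > 0) {
    stop("missing masks for: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  images <- lapply(file.path(img_dir, files), read_image_file)
  masks <- lapply(mask_paths, read_mask_file)
  for (i in seq_along(ids)) {
    if (!identical(dim(images[[i]])[1:2], dim(masks[[i]]))) {
      stop("image/mask shape mismatch for ", ids[i], call. = FALSE)
    }
  }
  tibble::tibble(id = ids, image = images, mask = masks)
}

# 2-d resampling of a single plane with precomputed operators.
resample_plane <- function(m, Rm, Cm) Rm %*% m %*% t(Cm)

# Nearest-neighbour index map under the same half-pixel convention as
# interp_matrix(); an identity-size resize is exactly the identity.
nearest_index <- function(n_out, n_in) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  pmin(pmax(round(src), 0), n_in - 1) + 1
}

resize_image <- function(img, height, width) {
  d <- dim(img)
  Rm <- interp_matrix(height, d[1])
  Cm <- interp_matrix(width, d[2])
  out <- array(0, c(height, width, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- resample_plane(img[, , ch], Rm, Cm)
  out
}

resize_mask <- function(mask, height, width) {
  ri <- nearest_index(height, nrow(mask))
  ci <- nearest_index(width, ncol(mask))
  mask[ri, ci, drop = FALSE]
}

#' Resize samples to the network input size
#'
#' Images are resampled bilinearly, masks with nearest-neighbour so they stay
#' binary. The default 512 matches the fixed network input resolution.
#'
#' @param data Dataset tibble (`id`, `image`, `mask`).
#' @param size Target side length in pixels.
#' @return The tibble with resized `image` and `mask` columns.
#' @export
resize_to_input <- function(data, size = 512L) {
  stopifnot(size >= 1)
  data$image <- lapply(data$image, resize_image, height = size, width = size)
  data$mask <- lapply(data$mask, resize_mask, height = size, width = size)
  data
}

#' Augmentation configuration
#'
#' @param rotate Random right-angle rotation (0/90/180/270 degrees).
#' @param hflip,vflip Random horizontal/vertical flips.
#' @param max_scale_jitter Scale factor drawn from
#'   `[1 - j, 1 + j]`; the scaled sample is centre-cropped or zero-padded
#'   back to its original size. 0 disables.
#' @param free_rotate Free-angle rotation instead of right angles; mask
#'   warping is nearest-neighbour (off by default: right angles avoid
#'   boundary interpolation artefacts in masks).
#' @param seed Base seed; the effective draw is derived from
#'   (seed, sample index, epoch) so every augmentation is reproducible.
#' @return An `augment_config` list.
#' @export
augment_config <- function(rotate = TRUE, hflip = TRUE, vflip = TRUE,
                           max_scale_jitter = 0.2, free_rotate = FALSE,
                           seed = 1L) {
  stopifnot(max_scale_jitter >= 0, max_scale_jitter < 1)
  structure(list(rotate = isTRUE(rotate), hflip = isTRUE(hflip),
                 vflip = isTRUE(vflip), max_scale_jitter = max_scale_jitter,
                 free_rotate = isTRUE(free_rotate), seed = as.integer(seed)),
            class = "augment_config")
}

rot90_plane <- function(m) t(m)[ncol(m):1, , drop = FALSE]

rotate_free <- function(plane, angle, nearest) {
  h <- nrow(plane); w <- ncol(plane)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ct <- cos(-angle); st <- sin(-angle)
  out <- matrix(0, h, w)
  for (j in seq_len(w)) {
    x <- j - cx
    ys <- seq_len(h) - cy
    sx <- ct * x - st * ys + cx
    sy <- st * x + ct * ys + cy
    if (nearest) {
      si <- round(sy); sj <- round(sx)
      ok <- si >= 1 & si <= h & sj >= 1 & sj <= w
      out[ok, j] <- plane[cbind(si[ok], sj[ok])]
    } else {
      i0 <- floor(sy); j0 <- floor(sx)
      fy <- sy - i0; fx <- sx - j0
      for (corner in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
        ii <- i0 + corner[1]; jj <- j0 + corner[2]
        wgt <- (if (corner[1] == 0) 1 - fy else fy) *
               (if (corner[2] == 0) 1 - fx else fx)
        ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
        out[ok, j] <- out[ok, j] + wgt[ok] * plane[cbind(ii[ok], jj[ok])]
      }
    }
  }
  out
}

scale_and_restore <- function(plane, s, nearest) {
  h <- nrow(plane); w <- ncol(plane)
  nh <- max(1L, round(h * s)); nw <- max(1L, round(w * s))
  scaled <- if (nearest) {
    plane[nearest_index(nh, h), nearest_index(nw, w), drop = FALSE]
  } else {
    resample_plane(plane, interp_matrix(nh, h), interp_matrix(nw, w))
  }
  out <- matrix(0, h, w)
  if (nh >= h) {
    r0 <- (nh - h) %/% 2; c0 <- (nw - w) %/% 2
    out <- scaled[r0 + seq_len(h), c0 + seq_len(w), drop = FALSE]
  } else {
    r0 <- (h - nh) %/% 2; c0 <- (w - nw) %/% 2
    out[r0 + seq_len(nh), c0 + seq_len(nw)] <- scaled
  }
  out
}

# One jointly drawn geometric transform applied to image and mask.
augment_one <- function(image, mask, cfg) {
  if (cfg$rotate) {
    k <- sample(0:3, 1)
    if (cfg$free_rotate) {
      ang <- stats::runif(1, 0, 2 * pi)
      for (ch in 1:3) image[, , ch] <- rotate_free(image[, , ch], ang, nearest = FALSE)
      mask <- matrix(as.integer(rotate_free(mask, ang, nearest = TRUE) > 0),
                     nrow(mask), ncol(mask))
    } else if (k > 0) {
      for (i in seq_len(k)) {
        d <- dim(image)
        img2 <- array(0, c(d[2], d[1], 3L))
        for (ch in 1:3) img2[, , ch] <- rot90_plane(image[, , ch])
        image <- img2
        mask <- rot90_plane(mask)
      }
    }
  }
  if (cfg$hflip && stats::runif(1) < 0.5) {
    image <- image[, ncol(mask):1, , drop = FALSE]
    mask <- mask[, ncol(mask):1, drop = FALSE]
  }
  if (cfg$vflip && stats::runif(1) < 0.5) {
    image <- image[nrow(mask):1, , , drop = FALSE]
    mask <- mask[nrow(mask):1, , drop = FALSE]
  }
  if (cfg$max_scale_jitter > 0) {
    s <- stats::runif(1, 1 - cfg$max_scale_jitter, 1 + cfg$max_scale_jitter)
    for (ch in 1:3) image[, , ch] <- scale_and_restore(image[, , ch], s, nearest = FALSE)
    mask <- matrix(as.integer(scale_and_restore(mask + 0, s, nearest = TRUE)),
                   nrow(mask), ncol(mask))
  }
  list(image = image, mask = mask)
}

#' Augment a dataset for one epoch
#'
#' Applies an independent, reproducible geometric transform to every sample:
#' the RNG for sample i at epoch e is seeded from
#' `cfg$seed + 100003 * e + i`, so the whole augmentation stream is a pure
#' function of (seed, sample index, epoch). Image and mask always receive
#' the same transform; masks stay binary.
#'
#' @param data Dataset tibble.
#' @param cfg An [augment_config()].
#' @param epoch Integer epoch index (part of the derived seed).
#' @return The augmented tibble.
#' @export
augment_dataset <- function(data, cfg = augment_config(), epoch = 0L) {
  stopifnot(inherits(cfg, "augment_config"))
  for (i in seq_len(nrow(data))) {
    res <- with_seed(cfg$seed + 100003L * as.integer(epoch) + i, {
      augment_one(data$image[[i]], data$mask[[i]], cfg)
    })
    data$image[[i]] <- res$image
    data$mask[[i]] <- res$mask
  }
  data
}

#' Split a dataset into train and test partitions
#'
#' Seeded random shuffle; `round(frac * n)` samples go to training, the rest
#' to test. The partition is disjoint and exhaustive.
#'
#' @param data Dataset tibble with at least 2 rows.
#' @param frac Training fraction, strictly in (0, 1). Default 0.8.
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test`.
#' @export
split_train_test <- function(data, frac = 0.8, seed = 1L) {
  n <- nrow(data)
  if (n < 2) stop("need at least 2 samples to split", call. = FALSE)
  if (!is.numeric(frac) || frac <= 0 || frac >= 1) {
    stop("`frac` must be strictly between 0 and 1", call. = FALSE)
  }
  idx <- with_seed(seed, sample.int(n))
  n_train <- round(frac * n)
  n_train <- min(max(n_train, 1L), n - 1L)
  list(train = data[sort(idx[seq_len(n_train)]), ],
       test = data[sort(idx[(n_train + 1L):n]), ])
}
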