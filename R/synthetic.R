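# Synthetic phantom slices and the paired LR/HR dataset machinery:
# generation, degradation pairing, patch extraction, augmentation,
# splitting and image/volume I/O.

#' Generate a synthetic MR-like phantom slice
#'
#' Produces a deterministic gray-scale image emulating an axial MR
#' slice: a smooth low-intensity background gradient, a large head-like
#' ellipse, `n_shapes` overlapping anti-aliased internal ellipses of
#' varying intensity (smooth tissue-like regions bounded by sharp
#' edges), optional mild Gaussian smoothing, and optional additive
#' Gaussian noise. Intensities are clipped to `[0, 1]`; the same
#' specification always yields the identical image.
#'
#' @param height,width Output dimensions in pixels (at least 32).
#' @param n_shapes Number of internal ellipses (0 gives the degenerate
#'   constant/background-only image when `noise_sd = 0` and
#'   `background = "flat"`).
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   `[0, 1]` intensity scale.
#' @param seed Integer seed; all randomness derives from it.
#' @param background `"gradient"` (default) or `"flat"`.
#' @param smooth Half-width of a small binomial smoothing kernel
#'   applied before the noise (0 disables; default 1 gives mildly
#'   anti-aliased edges).
#' @return An `height x width` matrix in `[0, 1]`.
#' @export
generate_phantom <- function(height = 240L, width = 240L, n_shapes = 12L,
                             noise_sd = 0.02, seed = 1L,
                             background = c("gradient", "flat"),
                             smooth = 1L) {
  background <- match.arg(background)
  height <- as.integer(height); width <- as.integer(width)
  if (height < 32L || width < 32L) {
    stop("phantom dimensions must be at least 32 x 32")
  }
  with_seed(seed, {
    hh <- (seq_len(height) - 0.5) / height
    ww <- (seq_len(width) - 0.5) / width
    img <- if (background == "gradient") {
      outer(hh, ww, function(h, w) 0.06 + 0.04 * h + 0.03 * w)
    } else {
      matrix(0.1, height, width)
    }
    if (n_shapes > 0L) {
      # head-like outer ellipse containing the tissue shapes
      img <- draw_ellipse(img, 0.5, 0.5, 0.44, 0.38,
                          angle = 0, value = 0.35, soft = 1.5 / height)
      for (k in seq_len(n_shapes)) {
        cy <- stats::runif(1, 0.2, 0.8)
        cx <- stats::runif(1, 0.2, 0.8)
        ry <- stats::runif(1, 0.04, 0.22)
        rx <- stats::runif(1, 0.04, 0.22)
        ang <- stats::runif(1, 0, pi)
        val <- stats::runif(1, 0.15, 0.95)
        img <- draw_ellipse(img, cy, cx, ry, rx, ang, val,
                            soft = 1.5 / height)
      }
    }
    if (smooth > 0L) img <- binomial_smooth(img, smooth)
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(height * width, 0, noise_sd),
                          height, width)
    }
    clamp01(img)
  })
}

# Blend an anti-aliased ellipse into img. Coordinates are in [0,1]^2;
# the soft parameter controls the ~1-pixel edge transition width.
draw_ellipse <- function(img, cy, cx, ry, rx, angle, value, soft) {
  hh <- (seq_len(nrow(img)) - 0.5) / nrow(img) - cy
  ww <- (seq_len(ncol(img)) - 0.5) / ncol(img) - cx
  ca <- cos(angle); sa <- sin(angle)
  u <- outer(hh, ww, function(h, w) (h * ca + w * sa) / ry)
  v <- outer(hh, ww, function(h, w) (-h * sa + w * ca) / rx)
  q <- sqrt(u * u + v * v)
  # smoothstep from 1 (inside) to 0 (outside) across [1 - e, 1 + e]
  e <- soft / min(ry, rx)
  tt <- clamp01((1 + e - q) / (2 * e))
  cov <- tt * tt * (3 - 2 * tt)
  img * (1 - cov) + value * cov
}

# Separable [1 2 1]/4 smoothing applied `times` times (replicate edges).
binomial_smooth <- function(img, times = 1L) {
  for (i in seq_len(times)) {
    x <- as_batch(img)
    x <- (shift_h(x, -1L) + 2 * x + shift_h(x, 1L)) / 4
    x <- (shift_w(x, -1L) + 2 * x + shift_w(x, 1L)) / 4
    img <- as_image(x)
  }
  img
}

#' Build a paired low/high-resolution sample
#'
#' Degrades a high-resolution image with the requested simulator and
#' records the provenance. The dimension ratio between the members is
#' exactly `s` in both axes.
#'
#' @param hr `H x W` matrix in `[0, 1]`; `s` must divide `H` and `W`.
#' @param mode `"BD"` (bicubic) or `"TD"` (k-space truncation).
#' @param s Integer scale factor.
#' @return A `paired_sample`: list with `lr`, `hr`, `mode`, `scale`.
#' @export
make_pair <- function(hr, mode = c("BD", "TD"), s = 2L) {
  mode <- toupper(mode[1])
  mode <- match.arg(mode, c("BD", "TD"))
  lr <- degrade_image(hr, mode, s)
  structure(list(lr = lr, hr = hr, mode = mode, scale = as.integer(s)),
            class = "paired_sample")
}

#' Extract a corresponding LR/HR patch pair
#'
#' Samples a uniformly random top-left offset `(i, j)` on the LR grid
#' (0-based) and takes the `patch x patch` LR region together with the
#' exactly corresponding `patch*s x patch*s` HR region at offset
#' `(s*i, s*j)`. For BD pairs the LR patch is regenerated by bicubic
#' downsampling of the cropped HR region, which makes the pair exactly
#' self-consistent: re-degrading the HR patch reproduces the LR patch
#' bit for bit. (A plain crop of the full LR image cannot satisfy this
#' at patch borders, because the cubic kernel's support crosses the
#' crop boundary.) TD pairs crop both members, since k-space truncation
#' is a global operator.
#'
#' @param sample A `paired_sample` from [make_pair()].
#' @param patch LR patch side length (default 24).
#' @param seed Integer seed driving the offset draw.
#' @return A `paired_sample` holding the patch pair.
#' @export
extract_patch_pair <- function(sample, patch = 24L, seed = 1L) {
  stopifnot(inherits(sample, "paired_sample"))
  patch <- as.integer(patch)
  h <- nrow(sample$lr); w <- ncol(sample$lr)
  if (patch > h || patch > w) {
    stop(sprintf("patch size %d exceeds the %d x %d LR image", patch, h, w))
  }
  s <- sample$scale
  off <- with_seed(seed, c(sample.int(h - patch + 1L, 1L),
                           sample.int(w - patch + 1L, 1L))) - 1L
  hr_patch <- sample$hr[(s * off[1] + 1L):(s * (off[1] + patch)),
                        (s * off[2] + 1L):(s * (off[2] + patch))]
  lr_patch <- if (sample$mode == "BD") {
    bicubic_downsample(hr_patch, s)
  } else {
    sample$lr[(off[1] + 1L):(off[1] + patch),
              (off[2] + 1L):(off[2] + patch)]
  }
  structure(list(lr = lr_patch, hr = hr_patch, mode = sample$mode,
                 scale = s, offset = off),
            class = "paired_sample")
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

#' Augment a paired sample
#'
#' With seed-driven coin flips, applies a horizontal flip and/or a 90
#' degree rotation, identically to both members of the pair, so the
#' LR/HR correspondence (and, for BD pairs, the re-degradation
#' consistency) is preserved. The flip is an involution; the rotation
#' has order 4.
#'
#' @param sample A `paired_sample`.
#' @param seed Integer seed for the two coin flips.
#' @param flip,rotate Explicit overrides; if supplied, no randomness is
#'   used for that transform.
#' @return The transformed `paired_sample`.
#' @export
augment_pair <- function(sample, seed = 1L, flip = NULL, rotate = NULL) {
  stopifnot(inherits(sample, "paired_sample"))
  coins <- with_seed(seed, stats::runif(2) < 0.5)
  if (is.null(flip)) flip <- coins[1]
  if (is.null(rotate)) rotate <- coins[2]
  tf <- function(m) {
    if (flip) m <- m[, ncol(m):1, drop = FALSE]
    if (rotate) m <- rot90cw(m)
    m
  }
  sample$lr <- tf(sample$lr)
  sample$hr <- tf(sample$hr)
  sample
}

#' Split items into train / validation / test sets
#'
#' Seed-driven shuffle followed by a deterministic partition:
#' `floor(f_train * N)` training items, `floor(f_val * N)` validation
#' items, and the remainder as test. The three parts are disjoint and
#' cover the input.
#'
#' @param items A vector or list.
#' @param fractions Numeric triple summing to 1 (default
#'   `c(0.7, 0.1, 0.2)`).
#' @param seed Integer shuffle seed.
#' @return A list with elements `train`, `val`, `test`.
#' @export
split_dataset <- function(items, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be three non-negative numbers summing to 1")
  }
  n <- length(items)
  ord <- with_seed(seed, sample.int(n))
  n_train <- floor(fractions[1] * n)
  n_val <- floor(fractions[2] * n)
  idx_train <- ord[seq_len(n_train)]
  idx_val <- ord[n_train + seq_len(n_val)]
  idx_test <- ord[-seq_len(n_train + n_val)]
  pick <- function(idx) if (is.list(items)) items[idx] else items[idx]
  list(train = pick(idx_train), val = pick(idx_val), test = pick(idx_test))
}

# ---- image and volume I/O ------------------------------------------------

#' Read and write gray-scale images
#'
#' `read_image()` loads a PNG (8- or 16-bit gray; colour images are
#' averaged to gray) or TIFF as an `H x W` matrix in `[0, 1]`.
#' `write_image()` writes 8-bit PNG or, for `bit_depth = 16`, 16-bit
#' TIFF (the PNG writer available to the package is 8-bit only). The
#' write-then-read round trip differs from the source by at most one
#' quantisation step of the stored bit depth.
#'
#' @param path File path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @param img `H x W` matrix in `[0, 1]`.
#' @param bit_depth 8 (PNG or TIFF) or 16 (TIFF only).
#' @return `read_image()` the image matrix; `write_image()` the path,
#'   invisibly.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("image file not found: '%s'", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s' (use png/tif/tiff)", ext)))
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    img <- if (nc >= 3L) {
      (img[, , 1] + img[, , 2] + img[, , 3]) / 3   # colour -> gray
    } else {
      img[, , 1]                                    # gray (+alpha)
    }
  }
  matrix(as.numeric(img), nrow(img), ncol(img))
}

#' @rdname read_image
#' @export
write_image <- function(img, path, bit_depth = 8L) {
  check_image(img)
  img <- clamp01(img)
  ext <- tolower(tools::file_ext(path))
  if (bit_depth == 16L) {
    if (!ext %in% c("tif", "tiff")) {
      stop("16-bit output requires a .tif/.tiff path")
    }
    tiff::writeTIFF(img, path, bits.per.sample = 16L)
  } else if (bit_depth == 8L) {
    if (ext == "png") {
      png::writePNG(img, path)
    } else if (ext %in% c("tif", "tiff")) {
      tiff::writeTIFF(img, path, bits.per.sample = 8L)
    } else {
      stop(sprintf("unsupported image format '.%s'", ext))
    }
  } else {
    stop("bit_depth must be 8 or 16")
  }
  invisible(path)
}

#' Extract axial slices from a NIfTI volume
#'
#' Reads an `.nii`/`.nii.gz` volume of shape `H x W x D` and returns
#' its `D` axial slices as matrices, intensities rescaled to `[0, 1]`
#' by the volume-wide min/max (a constant volume maps to 0).
#'
#' @param path NIfTI file path.
#' @return A list of `D` matrices of shape `H x W`.
#' @export
read_volume_slices <- function(path) {
  if (!file.exists(path)) stop(sprintf("volume file not found: '%s'", path))
  vol <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf(
                    "could not read '%s' as NIfTI: %s", path,
                    conditionMessage(e))))
  arr <- as.array(vol)
  if (length(dim(arr)) != 3L) {
    stop(sprintf("expected a 3-D volume, got %d dimensions",
                 length(dim(arr))))
  }
  rng <- range(arr)
  arr <- if (rng[2] > rng[1]) (arr - rng[1]) / (rng[2] - rng[1]) else arr * 0
  lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
}

#' Read or write a dataset manifest
#'
#' The manifest is a CSV with one row per paired sample and columns
#' `id`, `split`, `path_lr`, `path_hr`, `mode`, `scale`.
#'
#' @param df Manifest data frame.
#' @param path CSV path.
#' @return `write_manifest()` the path invisibly; `read_manifest()` the
#'   data frame.
#' @export
write_manifest <- function(df, path) {
  need <- c("id", "split", "path_lr", "path_hr", "mode", "scale")
  if (!all(need %in% names(df))) {
    stop(sprintf("manifest must have columns: %s",
                 paste(need, collapse = ", ")))
  }
  utils::write.csv(df[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: '%s'", path))
  utils::read.csv(path, stringsAsFactors = FALSE)
}
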