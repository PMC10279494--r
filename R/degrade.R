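# HR -> LR degradation simulators: bicubic downsampling (BD) and k-space
# truncation (TD), plus the bicubic-upsampling no-training baseline.

# Keys cubic convolution kernel, a = -0.5 (the standard bicubic kernel).
cubic_kernel <- function(u, a = -0.5) {
  u <- abs(u)
  ifelse(u <= 1, (a + 2) * u^3 - (a + 3) * u^2 + 1,
         ifelse(u < 2, a * (u^3 - 5 * u^2 + 8 * u - 4), 0))
}

# Dense 1-D resampling matrix (n_out x n_in), half-pixel-centre aligned.
# When downscaling, the kernel is stretched by the scale factor
# (anti-aliasing); rows are renormalised to sum to 1 so constants are
# exact fixed points, and out-of-range taps are clamped to the edge
# (replicate boundary).
resample_matrix <- function(n_in, n_out, antialias = TRUE) {
  scale <- n_in / n_out
  kw <- if (antialias && scale > 1) scale else 1
  support <- 2 * kw
  M <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    u <- (i - 0.5) * scale - 0.5            # centre in 0-based input coords
    lo <- floor(u - support) + 1
    hi <- ceiling(u + support) - 1
    j <- lo:hi
    w <- cubic_kernel((u - j) / kw) / kw
    keep <- w != 0
    j <- pmin(pmax(j[keep], 0), n_in - 1)
    w <- w[keep]
    w <- w / sum(w)
    for (k in seq_along(j)) M[i, j[k] + 1] <- M[i, j[k] + 1] + w[k]
  }
  M
}

#' Bicubic image resampling
#'
#' Separable resampling with the Keys cubic kernel (`a = -0.5`),
#' half-pixel centre alignment and replicate boundary handling. When
#' shrinking, the kernel is widened by the scale factor so the result
#' is anti-aliased.
#'
#' @param img `H x W` numeric matrix.
#' @param height,width Output dimensions.
#' @param antialias Widen the kernel when shrinking (default `TRUE`).
#' @return A `height x width` matrix.
#' @export
resize_bicubic <- function(img, height, width, antialias = TRUE) {
  check_image(img)
  Mr <- resample_matrix(nrow(img), height, antialias)
  Mc <- resample_matrix(ncol(img), width, antialias)
  Mr %*% img %*% t(Mc)
}

check_divisible <- function(img, s) {
  s <- as.integer(s)
  if (s < 1L) stop("scale must be a positive integer")
  if (nrow(img) %% s != 0L || ncol(img) %% s != 0L) {
    stop(sprintf("scale %d must divide both image dimensions (%d x %d)",
                 s, nrow(img), ncol(img)))
  }
  s
}

#' Bicubic downsampling degradation (BD)
#'
#' Simulates a low-resolution acquisition by anti-aliased cubic-kernel
#' downsampling to `(H/s, W/s)`, clipping the result to `[0, 1]`.
#' Constant images are exact fixed points (on the smaller grid).
#'
#' @param hr `H x W` matrix in `[0, 1]`; `s` must divide `H` and `W`.
#' @param s Integer scale factor.
#' @return `(H/s) x (W/s)` matrix in `[0, 1]`.
#' @export
bicubic_downsample <- function(hr, s) {
  check_image(hr, "hr")
  s <- check_divisible(hr, s)
  clamp01(resize_bicubic(hr, nrow(hr) %/% s, ncol(hr) %/% s))
}

#' Bicubic upsampling baseline
#'
#' Upscales by cubic interpolation to `(H*s, W*s)` — the no-training
#' reference against which learned super-resolution is evaluated.
#'
#' @param lr `H x W` matrix in `[0, 1]`.
#' @param s Integer scale factor.
#' @return `(H*s) x (W*s)` matrix in `[0, 1]`.
#' @export
bicubic_upsample <- function(lr, s) {
  check_image(lr, "lr")
  s <- as.integer(s)
  stopifnot(s >= 1L)
  clamp01(resize_bicubic(lr, nrow(lr) * s, ncol(lr) * s))
}

fftshift_idx <- function(n) ((seq_len(n) - 1L - floor(n / 2)) %% n) + 1L
ifftshift_idx <- function(n) ((seq_len(n) - 1L + floor(n / 2)) %% n) + 1L

#' k-space truncation degradation (TD)
#'
#' Simulates the MR acquisition route to low resolution: the image is
#' taken to k-space by a centred 2-D DFT, only the central
#' `(H/s) x (W/s)` block of spatial frequencies is retained (truncation
#' along both axes), and the small grid is inverse-transformed. The
#' real part is kept, the spectrum is rescaled by `1/s^2` so a constant
#' image maps to the same constant, and the result is clipped to
#' `[0, 1]` unless `clip = FALSE`. Before clipping the operator is
#' linear in the input, and images already band-limited to the retained
#' block pass through unchanged (up to the grid change).
#'
#' @param hr `H x W` matrix; `s` must divide both dimensions and the
#'   output must be at least 2 x 2.
#' @param s Integer scale factor.
#' @param clip Clip the output to `[0, 1]` (default `TRUE`).
#' @return `(H/s) x (W/s)` matrix.
#' @export
kspace_truncate <- function(hr, s, clip = TRUE) {
  check_image(hr, "hr")
  s <- check_divisible(hr, s)
  H <- nrow(hr); W <- ncol(hr)
  Hs <- H %/% s; Ws <- W %/% s
  if (Hs < 2L || Ws < 2L) stop("truncated grid must be at least 2 x 2")
  F <- stats::fft(hr)
  Fs <- F[fftshift_idx(H), fftshift_idx(W)]
  r0 <- floor(H / 2) - floor(Hs / 2)
  c0 <- floor(W / 2) - floor(Ws / 2)
  blk <- Fs[(r0 + 1L):(r0 + Hs), (c0 + 1L):(c0 + Ws)]
  blk <- blk[ifftshift_idx(Hs), ifftshift_idx(Ws)]
  # unnormalised inverse DFT / (Hs*Ws) then spectrum rescale 1/s^2;
  # together 1/(H*W)
  out <- Re(stats::fft(blk, inverse = TRUE)) / (H * W)
  if (clip) out <- clamp01(out)
  out
}

#' Degrade a high-resolution image
#'
#' Dispatch over the two degradation modes: `"BD"` bicubic
#' downsampling, `"TD"` k-space truncation.
#'
#' @param hr `H x W` matrix in `[0, 1]`.
#' @param mode `"BD"` or `"TD"` (case-insensitive).
#' @param s Integer scale factor dividing both dimensions.
#' @return `(H/s) x (W/s)` matrix in `[0, 1]`.
#' @export
degrade_image <- function(hr, mode = c("BD", "TD"), s = 2L) {
  mode <- toupper(mode[1])
  mode <- match.arg(mode, c("BD", "TD"))
  if (mode == "BD") bicubic_downsample(hr, s) else kspace_truncate(hr, s)
}
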