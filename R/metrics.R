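# Full-reference image quality metrics: RMSE, PSNR, SSIM, and their
# aggregation over an evaluation set.

check_pair_shapes <- function(hr, sr) {
  check_image(hr, "hr"); check_image(sr, "sr")
  if (!identical(dim(hr), dim(sr))) {
    stop(sprintf("shape mismatch: %s vs %s",
                 paste(dim(hr), collapse = "x"),
                 paste(dim(sr), collapse = "x")))
  }
}

#' Root mean square error
#'
#' `sqrt(mean((HR - SR)^2))` over all pixels, computed on the `[0, 1]`
#' intensity scale.
#'
#' @param hr,sr Equal-shape image matrices in `[0, 1]`.
#' @return Non-negative number.
#' @export
img_rmse <- function(hr, sr) {
  check_pair_shapes(hr, sr)
  sqrt(mean((hr - sr)^2))
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10((2^bits - 1)^2 / MSE)` with both images mapped to the
#' integer intensity scale of the stated bit depth (default 8, i.e.
#' peak 255). For images stored in `[0, 1]` this equals
#' `-10 * log10(MSE_[0,1])` for any bit depth. Identical images yield
#' `Inf` (the documented sentinel for a zero-error comparison).
#'
#' @param hr,sr Equal-shape image matrices in `[0, 1]`.
#' @param bits Bits per pixel value of the reference scale.
#' @return PSNR in dB, or `Inf` for identical images.
#' @export
img_psnr <- function(hr, sr, bits = 8L) {
  check_pair_shapes(hr, sr)
  peak <- 2^bits - 1
  mse <- mean(((hr - sr) * peak)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

gaussian_window <- function(size = 11L, sigma = 1.5) {
  half <- (size - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  g / sum(g)
}

# Separable 'valid' filtering with a 1-D window along both axes.
filter_valid <- function(x, g) {
  k <- length(g)
  n_out_r <- nrow(x) - k + 1L
  n_out_c <- ncol(x) - k + 1L
  Mr <- matrix(0, n_out_r, nrow(x))
  for (i in seq_len(n_out_r)) Mr[i, i:(i + k - 1L)] <- g
  Mc <- matrix(0, n_out_c, ncol(x))
  for (i in seq_len(n_out_c)) Mc[i, i:(i + k - 1L)] <- g
  Mr %*% x %*% t(Mc)
}

#' Structural similarity index
#'
#' `SSIM = (2 mu1 mu2 + c1)(2 sigma12 + c2) /
#'         ((mu1^2 + mu2^2 + c1)(sigma1^2 + sigma2^2 + c2))`
#' with `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2` and dynamic range `L = 1`
#' for images in `[0, 1]`.
#'
#' Two modes: `"window"` (default) evaluates the formula on local
#' statistics under a sliding 11x11 Gaussian window (sigma 1.5) and
#' returns the mean map value — the standard reported SSIM;
#' `"global"` evaluates it once on whole-image statistics, which admits
#' closed-form checks (e.g. two constant images with values `a`, `b`
#' give `(2ab + c1) / (a^2 + b^2 + c1)`). Both modes give exactly 1 for
#' identical images and are symmetric in their arguments.
#'
#' @param hr,sr Equal-shape image matrices in `[0, 1]`.
#' @param mode `"window"` or `"global"`.
#' @param window_size,sigma Gaussian window parameters (window mode).
#' @param L Dynamic range of the intensity scale.
#' @return A number in `[-1, 1]`.
#' @export
img_ssim <- function(hr, sr, mode = c("window", "global"),
                     window_size = 11L, sigma = 1.5, L = 1) {
  mode <- match.arg(mode)
  check_pair_shapes(hr, sr)
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  if (mode == "global") {
    mu1 <- mean(hr); mu2 <- mean(sr)
    v1 <- mean(hr^2) - mu1^2
    v2 <- mean(sr^2) - mu2^2
    cov12 <- mean(hr * sr) - mu1 * mu2
    return(((2 * mu1 * mu2 + c1) * (2 * cov12 + c2)) /
             ((mu1^2 + mu2^2 + c1) * (v1 + v2 + c2)))
  }
  if (min(dim(hr)) < window_size) {
    stop(sprintf("image (%d x %d) is smaller than the %d-pixel SSIM window",
                 nrow(hr), ncol(hr), window_size))
  }
  g <- gaussian_window(window_size, sigma)
  mu1 <- filter_valid(hr, g); mu2 <- filter_valid(sr, g)
  v1 <- filter_valid(hr * hr, g) - mu1^2
  v2 <- filter_valid(sr * sr, g) - mu2^2
  cov12 <- filter_valid(hr * sr, g) - mu1 * mu2
  smap <- ((2 * mu1 * mu2 + c1) * (2 * cov12 + c2)) /
    ((mu1^2 + mu2^2 + c1) * (v1 + v2 + c2))
  mean(smap)
}

#' Evaluate a set of image pairs
#'
#' Computes PSNR, SSIM and RMSE for every `(hr, sr)` pair and returns
#' their arithmetic means (the order of pairs is irrelevant).
#'
#' @param pairs Non-empty list; each element a list with elements `hr`
#'   and `sr` (equal-shape matrices in `[0, 1]`).
#' @param ssim_mode Passed to [img_ssim()].
#' @return A `metrics_record`: list with `psnr`, `ssim`, `rmse`,
#'   `n_images`, and a `per_image` data frame.
#' @export
evaluate_set <- function(pairs, ssim_mode = "window") {
  if (!is.list(pairs) || length(pairs) == 0L) {
    stop("pairs must be a non-empty list of (hr, sr) pairs")
  }
  per <- data.frame(
    id = seq_along(pairs),
    psnr = vapply(pairs, function(p) img_psnr(p$hr, p$sr), numeric(1)),
    ssim = vapply(pairs, function(p) img_ssim(p$hr, p$sr, mode = ssim_mode),
                  numeric(1)),
    rmse = vapply(pairs, function(p) img_rmse(p$hr, p$sr), numeric(1))
  )
  structure(list(psnr = mean(per$psnr), ssim = mean(per$ssim),
                 rmse = mean(per$rmse), n_images = nrow(per),
                 per_image = per),
            class = "metrics_record")
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf("Evaluation over %d image(s): PSNR %.4f dB | SSIM %.4f | RMSE %.5f\n",
              x$n_images, x$psnr, x$ssim, x$rmse))
  invisible(x)
}

#' Write an evaluation report as CSV
#'
#' One row per image (`id`, `psnr`, `ssim`, `rmse`) followed by a
#' `summary` row holding the means.
#'
#' @param record A `metrics_record` from [evaluate_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(record, path) {
  stopifnot(inherits(record, "metrics_record"))
  df <- record$per_image
  df$id <- as.character(df$id)
  df <- rbind(df, data.frame(id = "summary", psnr = record$psnr,
                             ssim = record$ssim, rmse = record$rmse))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
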