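#' SimAM inverse energy (attention logits)
#'
#' Computes, per sample and per channel, the inverse of the SimAM
#' minimal energy at every spatial position. With `u` the spatial mean
#' of a channel map, `d_t = (t - u)^2` and `s2` the spatial variance of
#' the map, the minimal energy for neuron `t` is
#' `e_t = 4 (s2 + lambda) / (d_t + 2 s2 + 2 lambda)`, so its inverse is
#' the linear form
#'
#'   `1/e_t = d_t / (4 (s2 + lambda)) + 1/2`.
#'
#' The inverse is computed directly in this form (never by forming `e_t`
#' and dividing), which is numerically safe when `d_t` is tiny and makes
#' the constant-map case exact: a constant channel has `d_t = 0`
#' everywhere and the logit is exactly `1/2`, even when `lambda = 0`.
#'
#' @param x A feature map, `(B, C, H, W)` array (see [feature_map()]).
#' @param lambda Non-negative regulariser added to the spatial variance.
#'   Default `1e-4`.
#' @param var_denom Divisor convention for the spatial variance: the
#'   default `"n-1"` uses `H*W - 1`; `"n"` uses `H*W`.
#' @return An array shaped like `x` holding `1/e_t` at each position;
#'   every entry is `>= 0.5`.
#' @seealso [simam()], [pcfb()]
#' @examples
#' x <- feature_map(array(c(0, 2), dim = c(1, 1, 1, 2)))
#' inverse_energy(x, lambda = 1e-4)  # both entries ~0.62499
#' @export
inverse_energy <- function(x, lambda = 1e-4, var_denom = c("n-1", "n")) {
  var_denom <- match.arg(var_denom)
  x <- feature_map(x)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda < 0) {
    stop("lambda must be a single non-negative finite number")
  }
  d <- dim(x)
  m <- simam_matrix(x)                        # (H*W) x (B*C)
  st <- simam_stats(m, lambda, var_denom)
  w <- sweep(st$d, 2L, st$A, "*") + 0.5
  simam_unmatrix(w, d)
}

# Reshape (B,C,H,W) -> (H*W) x (B*C) with spatial positions down columns.
simam_matrix <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(3L, 4L, 1L, 2L))
  dim(m) <- c(d[3] * d[4], d[1] * d[2])
  m
}

simam_unmatrix <- function(m, d) {
  dim(m) <- c(d[3], d[4], d[1], d[2])
  aperm(m, c(3L, 4L, 1L, 2L))
}

# Shared per-column statistics: centred values, squared deviations,
# and the coefficient A = 1/(4 (s2 + lambda)), guarded so an all-constant
# column with lambda = 0 yields A = 0 (and hence logits exactly 1/2).
simam_stats <- function(m, lambda, var_denom) {
  n <- nrow(m)
  mu <- colMeans(m)
  xc <- sweep(m, 2L, mu, "-")
  dsq <- xc * xc
  denom_n <- if (var_denom == "n-1") max(n - 1L, 1L) else n
  s2 <- colSums(dsq) / denom_n
  den <- 4 * (s2 + lambda)
  A <- ifelse(den > 0, 1 / den, 0)
  list(mu = mu, xc = xc, d = dsq, s2 = s2, A = A, n = n)
}

#' SimAM parameter-free attention
#'
#' Weights every entry of a feature map by the sigmoid of its inverse
#' energy: `simam(x) = sigmoid(inverse_energy(x, lambda)) * x`,
#' element-wise. The operator has no learnable parameters and preserves
#' the input shape; since the sigmoid output lies in (0, 1), the result
#' is an element-wise attenuation of `x`.
#'
#' @inheritParams inverse_energy
#' @return A feature map shaped like `x`.
#' @examples
#' x <- feature_map(array(1, dim = c(1, 2, 3, 3)))
#' simam(x)[1, 1, 1, 1]  # constant map: sigmoid(0.5) ~ 0.62246
#' @export
simam <- function(x, lambda = 1e-4, var_denom = c("n-1", "n")) {
  sigmoid(inverse_energy(x, lambda, var_denom)) * x
}

# Forward pass retaining everything the backward pass needs.
simam_forward <- function(x, lambda, var_denom = "n-1") {
  d <- dim(x)
  m <- simam_matrix(x)
  st <- simam_stats(m, lambda, var_denom)
  w <- sweep(st$d, 2L, st$A, "*") + 0.5
  a <- sigmoid(w)
  y <- a * m
  list(y = simam_unmatrix(y, d), cache = list(m = m, st = st, a = a, d = d,
                                              var_denom = var_denom))
}

# Reverse-mode gradient of simam_forward w.r.t. its input.
simam_backward <- function(g, cache) {
  st <- cache$st; a <- cache$a; m <- cache$m
  G <- simam_matrix(g)
  n <- st$n
  denom_n <- if (cache$var_denom == "n-1") max(n - 1L, 1L) else n
  q <- G * m * a * (1 - a)                       # dL/d(logit)
  # dL/d d_s = A q_s - (4 A^2 / denom) * sum_t q_t d_t
  corr <- (4 * st$A^2 / denom_n) * colSums(q * st$d)
  dd <- sweep(q, 2L, st$A, "*") -
    sweep(matrix(1, n, ncol(m)), 2L, corr, "*")
  # d d_s / d x_r through the centring: 2 xc_s (delta_sr - 1/n)
  dx <- 2 * st$xc * dd -
    sweep(matrix(1, n, ncol(m)), 2L, (2 / n) * colSums(dd * st$xc), "*")
  dx <- dx + G * a
  simam_unmatrix(dx, cache$d)
}

#' Split a feature map into channel chunks
#'
#' Splits the channel axis into `n` contiguous, equally sized ranges, in
#' order. The split is deterministic and exactly invertible by
#' [merge_chunks()].
#'
#' @param x A feature map `(B, C, H, W)`.
#' @param n Number of chunks; must divide the channel count.
#' @return A list of `n` feature maps, each `(B, C/n, H, W)`.
#' @export
chunk_channels <- function(x, n) {
  x <- feature_map(x)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("n must be a positive integer")
  }
  n <- as.integer(n)
  C <- dim(x)[2]
  if (C %% n != 0L) {
    stop(sprintf("channel count %d is not divisible into %d chunks", C, n))
  }
  k <- C %/% n
  lapply(seq_len(n), function(i) {
    x[, ((i - 1L) * k + 1L):(i * k), , , drop = FALSE]
  })
}

#' Concatenate channel chunks back into one feature map
#'
#' Channel-wise concatenation in list order; `merge_chunks(chunk_channels(x, n))`
#' reproduces `x` exactly. Chunks may have unequal channel counts but must
#' agree in batch and spatial dimensions.
#'
#' @param chunks Non-empty list of feature maps.
#' @return A feature map whose channel count is the sum over chunks.
#' @export
merge_chunks <- function(chunks) {
  if (!is.list(chunks) || length(chunks) == 0L) {
    stop("chunks must be a non-empty list of feature maps")
  }
  chunks <- lapply(chunks, feature_map)
  d0 <- dim(chunks[[1]])
  for (ch in chunks) {
    d <- dim(ch)
    if (!all(d[c(1, 3, 4)] == d0[c(1, 3, 4)])) {
      stop("chunks must share batch, height and width dimensions")
    }
  }
  Cs <- vapply(chunks, function(ch) dim(ch)[2], integer(1))
  out <- array(0, dim = c(d0[1], sum(Cs), d0[3], d0[4]))
  at <- 0L
  for (i in seq_along(chunks)) {
    out[, (at + 1L):(at + Cs[i]), , ] <- chunks[[i]]
    at <- at + Cs[i]
  }
  out
}

#' Parameter-free chunking fusion block (PCFB)
#'
#' Splits the channels into `n` contiguous chunks, applies SimAM
#' attention to each chunk independently, and concatenates the attended
#' chunks back in order. Because SimAM is parameter-free, the whole
#' block contributes zero learnable parameters; with `n = 1` it reduces
#' to [simam()] on the full map.
#'
#' @inheritParams inverse_energy
#' @param n Number of channel chunks (must divide the channel count).
#' @return A feature map shaped like `x`.
#' @export
pcfb <- function(x, n = 2L, lambda = 1e-4, var_denom = c("n-1", "n")) {
  var_denom <- match.arg(var_denom)
  merge_chunks(lapply(chunk_channels(x, n), simam, lambda = lambda,
                      var_denom = var_denom))
}

pcfb_forward <- function(x, n, lambda, var_denom = "n-1") {
  chunks <- chunk_channels(x, n)
  fw <- lapply(chunks, simam_forward, lambda = lambda, var_denom = var_denom)
  list(y = merge_chunks(lapply(fw, `[[`, "y")),
       cache = list(caches = lapply(fw, `[[`, "cache"), n = n))
}

pcfb_backward <- function(g, cache) {
  gs <- chunk_channels(g, cache$n)
  merge_chunks(Map(simam_backward, gs, cache$caches))
}
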