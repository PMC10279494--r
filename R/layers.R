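# Network building blocks: 2-D convolution (im2col + BLAS), PReLU,
# LayerNorm, PixelShuffle and the Laplacian edge operator, each with an
# explicit reverse-mode backward pass. All tensors are (B, C, H, W).

.im2col_cache <- new.env(parent = emptyenv())

# Gather index turning a zero-padded (B,C,Hp,Wp) array into the
# (K*K*Cin) x (B*Ho*Wo) column matrix of a stride-1 'same' convolution.
# Cached per shape: training re-uses a handful of shapes thousands of times.
im2col_index <- function(B, C, Hp, Wp, K) {
  key <- paste(B, C, Hp, Wp, K, sep = "x")
  idx <- .im2col_cache[[key]]
  if (!is.null(idx)) return(idx)
  Ho <- Hp - K + 1L; Wo <- Wp - K + 1L
  kh <- rep(seq_len(K), times = K * C)
  kw <- rep(rep(seq_len(K), each = K), times = C)
  ci <- rep(seq_len(C), each = K * K)
  row_off <- (ci - 1L) * B + (kh - 1L) * B * C + (kw - 1L) * B * C * Hp
  b <- rep(seq_len(B), times = Ho * Wo)
  ho <- rep(rep(seq_len(Ho), each = B), times = Wo)
  wo <- rep(seq_len(Wo), each = B * Ho)
  col_off <- b + (ho - 1L) * B * C + (wo - 1L) * B * C * Hp
  idx <- outer(row_off, col_off, "+")
  dim(idx) <- NULL
  attr(idx, "nr") <- K * K * C
  attr(idx, "nc") <- B * Ho * Wo
  .im2col_cache[[key]] <- idx
  idx
}

zero_pad <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2], d[3] + 2L * p, d[4] + 2L * p))
  out[, , (p + 1L):(p + d[3]), (p + 1L):(p + d[4])] <- x
  out
}

#' 2-D convolution (stride 1, zero 'same' padding)
#'
#' Cross-correlation of a feature map with a kernel bank, the primitive
#' behind every network layer. Weights are stored as a
#' `(K, K, C_in, C_out)` array; odd `K` only, output spatial size equals
#' input size.
#'
#' @param x Feature map `(B, C_in, H, W)`.
#' @param w Kernel array `(K, K, C_in, C_out)`.
#' @param b Bias vector of length `C_out` (or `NULL` for no bias).
#' @return Feature map `(B, C_out, H, W)`.
#' @export
conv2d <- function(x, w, b = NULL) {
  conv2d_forward(x, w, b)$y
}

conv2d_forward <- function(x, w, b = NULL) {
  d <- dim(x); dw <- dim(w)
  K <- dw[1]
  stopifnot(dw[2] == K, K %% 2L == 1L)
  if (dw[3] != d[2]) {
    stop(sprintf("conv2d: input has %d channels but kernel expects %d",
                 d[2], dw[3]))
  }
  p <- (K - 1L) %/% 2L
  xp <- zero_pad(x, p)
  dp <- dim(xp)
  idx <- im2col_index(dp[1], dp[2], dp[3], dp[4], K)
  Xcol <- xp[idx]
  dim(Xcol) <- c(attr(idx, "nr"), attr(idx, "nc"))
  Wmat <- w
  dim(Wmat) <- c(K * K * dw[3], dw[4])          # (K*K*C_in) x C_out
  Y <- crossprod(Wmat, Xcol)                    # C_out x (B*H*W)
  if (!is.null(b)) Y <- Y + b
  dim(Y) <- c(dw[4], d[1], d[3], d[4])
  list(y = aperm(Y, c(2L, 1L, 3L, 4L)),
       cache = list(Xcol = Xcol, w = w, xdim = d))
}

conv2d_backward <- function(g, cache) {
  w <- cache$w; dw <- dim(w); d <- cache$xdim
  Gmat <- aperm(g, c(2L, 1L, 3L, 4L))
  dim(Gmat) <- c(dw[4], d[1] * d[3] * d[4])
  dW <- t(tcrossprod(Gmat, cache$Xcol))         # (K*K*C_in) x C_out
  dim(dW) <- dw
  db <- rowSums(Gmat)
  # grad w.r.t. input = 'same' conv of g with the spatially flipped
  # kernel, in/out channels swapped
  K <- dw[1]
  wt <- aperm(w[K:1, K:1, , , drop = FALSE], c(1L, 2L, 4L, 3L))
  dx <- conv2d_forward(g, wt, NULL)$y
  list(dx = dx, dw = dW, db = db)
}

# Broadcast a per-channel vector over a (B,C,H,W) array; relies on
# column-major recycling of the length-(B*C) expansion.
channel_bc <- function(a, d) rep(a, each = d[1])

#' Parametric ReLU
#'
#' `prelu(x) = x` where `x > 0` and `a * x` where `x <= 0`, with one
#' learnable slope per channel (a scalar `a` is broadcast).
#'
#' @param x Feature map `(B, C, H, W)`.
#' @param a Negative-branch slope(s), scalar or length-`C` vector,
#'   conventionally in `[0, 1]`.
#' @return Feature map shaped like `x`.
#' @export
prelu <- function(x, a) {
  prelu_forward(x, a)$y
}

prelu_forward <- function(x, a) {
  d <- dim(x)
  if (length(a) == 1L) a <- rep(a, d[2])
  stopifnot(length(a) == d[2])
  ab <- channel_bc(a, d)
  pos <- x > 0
  slope <- pos + ab * (1 - pos)     # 1 where x > 0, a elsewhere
  y <- slope * x
  dim(y) <- d
  list(y = y, cache = list(x = x, a = a, pos = pos, slope = slope))
}

prelu_backward <- function(g, cache) {
  d <- dim(cache$x)
  dx <- g * cache$slope
  dim(dx) <- d
  s <- g * cache$x * (1 - cache$pos)
  s <- aperm(s, c(2L, 1L, 3L, 4L))
  dim(s) <- c(d[2], d[1] * d[3] * d[4])
  list(dx = dx, da = rowSums(s))
}

#' Layer normalisation
#'
#' Normalises each sample of the batch by the mean and (population)
#' variance taken jointly over its channel and spatial axes —
#' independent of batch size — then applies a learnable per-channel
#' scale `gamma` and shift `beta`:
#' `y = (x - E[x]) / sqrt(Var[x] + eps) * gamma + beta`.
#'
#' @param x Feature map `(B, C, H, W)`.
#' @param gamma,beta Per-channel scale and shift (scalars broadcast).
#' @param eps Small positive stabiliser added to the variance.
#' @param axes `"all"` (default) normalises over `(C, H, W)` jointly;
#'   `"spatial"` normalises each channel over `(H, W)` only.
#' @return Feature map shaped like `x`.
#' @export
layer_norm <- function(x, gamma = 1, beta = 0, eps = 1e-5,
                       axes = c("all", "spatial")) {
  layer_norm_forward(x, gamma, beta, eps, match.arg(axes))$y
}

# Reshape so normalisation groups are columns: "all" -> (C*H*W) x B,
# "spatial" -> (H*W) x (B*C).
ln_matrix <- function(x, axes) {
  d <- dim(x)
  if (axes == "all") {
    m <- aperm(x, c(2L, 3L, 4L, 1L))
    dim(m) <- c(d[2] * d[3] * d[4], d[1])
  } else {
    m <- simam_matrix(x)
  }
  m
}

ln_unmatrix <- function(m, d, axes) {
  if (axes == "all") {
    dim(m) <- c(d[2], d[3], d[4], d[1])
    aperm(m, c(4L, 1L, 2L, 3L))
  } else {
    simam_unmatrix(m, d)
  }
}

layer_norm_forward <- function(x, gamma, beta, eps, axes = "all") {
  stopifnot(eps > 0)
  d <- dim(x)
  if (length(gamma) == 1L) gamma <- rep(gamma, d[2])
  if (length(beta) == 1L) beta <- rep(beta, d[2])
  m <- ln_matrix(x, axes)
  mu <- colMeans(m)
  xc <- sweep(m, 2L, mu, "-")
  v <- colMeans(xc * xc)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, inv_sd, "*")
  xhat_arr <- ln_unmatrix(xhat, d, axes)
  gb <- channel_bc(gamma, d)
  bb <- channel_bc(beta, d)
  y <- xhat_arr * gb + bb
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma,
                           d = d, axes = axes))
}

layer_norm_backward <- function(g, cache) {
  d <- cache$d; axes <- cache$axes
  gb <- channel_bc(cache$gamma, d)
  xhat_arr <- ln_unmatrix(cache$xhat, d, axes)
  # parameter grads (per channel)
  s1 <- g * xhat_arr
  perm <- function(z) {
    z <- aperm(z, c(2L, 1L, 3L, 4L)); dim(z) <- c(d[2], d[1] * d[3] * d[4]); z
  }
  dgamma <- rowSums(perm(s1))
  dbeta <- rowSums(perm(g))
  # input grad through the normalisation
  gh <- g * gb; dim(gh) <- d
  Gh <- ln_matrix(gh, axes)
  xhat <- cache$xhat
  n <- nrow(Gh)
  t1 <- sweep(Gh, 2L, colMeans(Gh), "-")
  t2 <- sweep(xhat, 2L, colMeans(Gh * xhat), "*")
  dxm <- sweep(t1 - t2, 2L, cache$inv_sd, "*")
  list(dx = ln_unmatrix(dxm, d, axes), dgamma = dgamma, dbeta = dbeta)
}

#' Sub-pixel rearrangement (PixelShuffle)
#'
#' Rearranges an `(B, C*r^2, H, W)` map into `(B, C, H*r, W*r)`:
#' with zero-based indices,
#' `out[b, c, h*r + i, w*r + j] = in[b, c*r^2 + i*r + j, h, w]`.
#' A pure permutation — the multiset of values is preserved; `r = 1` is
#' the identity.
#'
#' @param x Feature map whose channel count is divisible by `r^2`.
#' @param r Integer upscaling factor, `>= 1`.
#' @return Feature map `(B, C/r^2, H*r, W*r)`.
#' @export
pixel_shuffle <- function(x, r) {
  x <- feature_map(x)
  r <- as.integer(r)
  stopifnot(r >= 1L)
  d <- dim(x)
  if (d[2] %% (r * r) != 0L) {
    stop(sprintf("pixel_shuffle: %d channels not divisible by r^2 = %d",
                 d[2], r * r))
  }
  if (r == 1L) return(x)
  Cout <- d[2] %/% (r * r)
  out <- array(0, dim = c(d[1], Cout, d[3] * r, d[4] * r))
  for (i in 0:(r - 1L)) {
    for (j in 0:(r - 1L)) {
      ch <- (seq_len(Cout) - 1L) * r * r + i * r + j + 1L
      out[, , seq(i + 1L, by = r, length.out = d[3]),
          seq(j + 1L, by = r, length.out = d[4])] <-
        x[, ch, , , drop = FALSE]
    }
  }
  out
}

# Exact inverse of pixel_shuffle; also its adjoint (a permutation).
pixel_unshuffle <- function(y, r) {
  r <- as.integer(r)
  if (r == 1L) return(y)
  d <- dim(y)
  stopifnot(d[3] %% r == 0L, d[4] %% r == 0L)
  H <- d[3] %/% r; W <- d[4] %/% r
  out <- array(0, dim = c(d[1], d[2] * r * r, H, W))
  for (i in 0:(r - 1L)) {
    for (j in 0:(r - 1L)) {
      ch <- (seq_len(d[2]) - 1L) * r * r + i * r + j + 1L
      out[, ch, , ] <- y[, , seq(i + 1L, by = r, length.out = H),
                         seq(j + 1L, by = r, length.out = W), drop = FALSE]
    }
  }
  out
}

# ---- Laplacian edge operator (replicate padding) -------------------------

# Clamped spatial shifts on (B,C,H,W) arrays and their adjoints.
shift_h <- function(x, by) {       # by = -1: row h takes row h-1 (clamped)
  H <- dim(x)[3]
  idx <- pmin(pmax(seq_len(H) + by, 1L), H)
  x[, , idx, , drop = FALSE]
}
shift_w <- function(x, by) {
  W <- dim(x)[4]
  idx <- pmin(pmax(seq_len(W) + by, 1L), W)
  x[, , , idx, drop = FALSE]
}
shift_h_adj <- function(g, by) {   # adjoint of shift_h(., by)
  H <- dim(g)[3]
  out <- array(0, dim = dim(g))
  src <- pmin(pmax(seq_len(H) + by, 1L), H)
  for (h in seq_len(H)) {
    out[, , src[h], ] <- out[, , src[h], ] + g[, , h, ]
  }
  out
}
shift_w_adj <- function(g, by) {
  W <- dim(g)[4]
  out <- array(0, dim = dim(g))
  src <- pmin(pmax(seq_len(W) + by, 1L), W)
  for (w in seq_len(W)) {
    out[, , , src[w]] <- out[, , , src[w]] + g[, , , w]
  }
  out
}

#' Laplacian edge response
#'
#' Applies the discrete Laplacian with replicate (edge-clamped) padding.
#' The default 4-neighbour kernel is `[[0,1,0],[1,-4,1],[0,1,0]]`; the
#' 8-neighbour variant adds the diagonals with centre -8. Under
#' replicate padding a constant image maps to exactly zero, so the
#' response is invariant to constant intensity offsets.
#'
#' @param img An `H x W` matrix or a `(B, C, H, W)` feature map.
#' @param neighbours 4 (default) or 8.
#' @return Same shape as the input.
#' @export
laplacian <- function(img, neighbours = 4L) {
  was_mat <- is.matrix(img)
  x <- as_batch(img)
  y <- laplacian_op(x, neighbours)
  if (was_mat) as_image(y) else y
}

laplacian_op <- function(x, neighbours = 4L) {
  s <- shift_h(x, -1L) + shift_h(x, 1L) + shift_w(x, -1L) + shift_w(x, 1L)
  if (neighbours == 4L) return(s - 4 * x)
  diagc <- shift_w(shift_h(x, -1L), -1L) + shift_w(shift_h(x, -1L), 1L) +
    shift_w(shift_h(x, 1L), -1L) + shift_w(shift_h(x, 1L), 1L)
  s + diagc - 8 * x
}

# Adjoint of laplacian_op (needed by the edge-loss gradient).
laplacian_adj <- function(g, neighbours = 4L) {
  s <- shift_h_adj(g, -1L) + shift_h_adj(g, 1L) +
    shift_w_adj(g, -1L) + shift_w_adj(g, 1L)
  if (neighbours == 4L) return(s - 4 * g)
  diagc <- shift_h_adj(shift_w_adj(g, -1L), -1L) +
    shift_h_adj(shift_w_adj(g, 1L), -1L) +
    shift_h_adj(shift_w_adj(g, -1L), 1L) +
    shift_h_adj(shift_w_adj(g, 1L), 1L)
  s + diagc - 8 * g
}
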