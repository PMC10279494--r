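# Independent brute-force oracles used across the test files. These are
# deliberately written as plain per-pixel loops, sharing no code with the
# package's vectorised implementations.

# Energy-based attention logits, looped pixel by pixel: form the minimal
# energy e_t itself and invert it (the package computes 1/e_t directly).
oracle_inverse_energy <- function(x, lambda, denom = c("n-1", "n")) {
  denom <- match.arg(denom)
  d <- dim(x)
  out <- array(NA_real_, dim = d)
  for (b in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      map <- x[b, ch, , ]
      n <- length(map)
      u <- mean(map)
      s2 <- sum((map - u)^2) / (if (denom == "n-1") n - 1 else n)
      for (h in seq_len(d[3])) {
        for (w in seq_len(d[4])) {
          t <- x[b, ch, h, w]
          e <- (4 * (s2 + lambda)) / ((t - u)^2 + 2 * s2 + 2 * lambda)
          out[b, ch, h, w] <- 1 / e
        }
      }
    }
  }
  out
}

# Plain quadruple-loop 'same' cross-correlation with zero padding,
# weights (K, K, Cin, Cout).
oracle_conv2d <- function(x, w, bias = NULL) {
  d <- dim(x); dw <- dim(w)
  K <- dw[1]; p <- (K - 1) / 2
  out <- array(0, dim = c(d[1], dw[4], d[3], d[4]))
  for (b in seq_len(d[1])) {
    for (co in seq_len(dw[4])) {
      for (h in seq_len(d[3])) {
        for (wd in seq_len(d[4])) {
          acc <- 0
          for (ci in seq_len(d[2])) {
            for (kh in seq_len(K)) {
              for (kw in seq_len(K)) {
                hh <- h + kh - 1 - p
                ww <- wd + kw - 1 - p
                if (hh >= 1 && hh <= d[3] && ww >= 1 && ww <= d[4]) {
                  acc <- acc + x[b, ci, hh, ww] * w[kh, kw, ci, co]
                }
              }
            }
          }
          out[b, co, h, wd] <- acc + if (is.null(bias)) 0 else bias[co]
        }
      }
    }
  }
  out
}

# Looped Laplacian with replicate padding on an H x W matrix.
oracle_laplacian <- function(img, neighbours = 4) {
  H <- nrow(img); W <- ncol(img)
  cl <- function(i, n) min(max(i, 1), n)
  out <- matrix(0, H, W)
  for (h in seq_len(H)) {
    for (w in seq_len(W)) {
      s <- img[cl(h - 1, H), w] + img[cl(h + 1, H), w] +
        img[h, cl(w - 1, W)] + img[h, cl(w + 1, W)]
      if (neighbours == 4) {
        out[h, w] <- s - 4 * img[h, w]
      } else {
        s <- s + img[cl(h - 1, H), cl(w - 1, W)] +
          img[cl(h - 1, H), cl(w + 1, W)] +
          img[cl(h + 1, H), cl(w - 1, W)] +
          img[cl(h + 1, H), cl(w + 1, W)]
        out[h, w] <- s - 8 * img[h, w]
      }
    }
  }
  out
}

# Direct kernel-sum evaluation of separable cubic resampling at output
# sample centres (half-pixel convention, replicate edges, row renorm).
oracle_cubic_1d <- function(v, n_out, antialias = TRUE) {
  keys <- function(u) {
    u <- abs(u)
    if (u <= 1) 1.5 * u^3 - 2.5 * u^2 + 1
    else if (u < 2) -0.5 * u^3 + 2.5 * u^2 - 4 * u + 2
    else 0
  }
  n_in <- length(v)
  scale <- n_in / n_out
  kw <- if (antialias && scale > 1) scale else 1
  out <- numeric(n_out)
  for (i in seq_len(n_out)) {
    u <- (i - 0.5) * scale - 0.5
    js <- (floor(u - 2 * kw) + 1):(ceiling(u + 2 * kw) - 1)
    wts <- vapply(js, function(j) keys((u - j) / kw) / kw, numeric(1))
    js <- pmin(pmax(js, 0), n_in - 1)
    out[i] <- sum(wts * v[js + 1]) / sum(wts)
  }
  out
}

oracle_resize_bicubic <- function(img, h_out, w_out) {
  tmp <- t(apply(img, 1, oracle_cubic_1d, n_out = w_out))
  apply(tmp, 2, oracle_cubic_1d, n_out = h_out)
}

oracle_rmse <- function(a, b) {
  acc <- 0
  for (h in seq_len(nrow(a))) {
    for (w in seq_len(ncol(a))) acc <- acc + (a[h, w] - b[h, w])^2
  }
  sqrt(acc / (nrow(a) * ncol(a)))
}

# Random feature map of the given shape (values roughly in [-1, 1]).
rand_map <- function(B, C, H, W) {
  array(stats::runif(B * C * H * W, -1, 1), dim = c(B, C, H, W))
}
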