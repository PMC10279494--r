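# Composite training loss: pixel (L1/L2), perceptual (feature-space L1
# through an injected extractor) and Laplacian edge terms, each with its
# gradient w.r.t. the super-resolved image.

coerce_pair <- function(sr, hr) {
  sr <- as_batch(sr); hr <- as_batch(hr)
  if (!identical(dim(sr), dim(hr))) {
    stop(sprintf("shape mismatch: SR is %s, HR is %s",
                 paste(dim(sr), collapse = "x"),
                 paste(dim(hr), collapse = "x")))
  }
  list(sr = sr, hr = hr)
}

#' Pixel loss
#'
#' Pixel-wise difference between the super-resolved and reference
#' images: `L1` is the mean absolute difference, `L2` the mean squared
#' difference, in both cases averaged over every pixel of every image
#' in the batch (so the value is scale-free in the batch and image
#' size).
#'
#' @param sr,hr Image matrices or `(B, 1, H, W)` batches of equal shape.
#' @param kind `"L1"` (default) or `"L2"`.
#' @return A single non-negative number.
#' @export
pixel_loss <- function(sr, hr, kind = c("L1", "L2")) {
  kind <- match.arg(kind)
  p <- coerce_pair(sr, hr)
  d <- p$sr - p$hr
  if (kind == "L1") mean(abs(d)) else mean(d * d)
}

pixel_loss_grad <- function(sr, hr, kind = "L1") {
  d <- sr - hr
  n <- length(d)
  if (kind == "L1") sign(d) / n else 2 * d / n
}

#' Feature extractors for the perceptual loss
#'
#' The perceptual term compares deep features of the two images through
#' a fixed, deterministic extractor handle. `identity_extractor()`
#' returns the image itself (making the perceptual loss coincide with
#' the pixel L1 loss). `conv_extractor()` builds a deterministic
#' random-feature convolutional bank: `n_layers` fixed 3x3 convolutions
#' (Glorot-initialised from `seed`, never trained) with leaky
#' rectification between layers — a self-contained stand-alone feature
#' space in the spirit of random-feature perceptual distances.
#'
#' An extractor is a list with elements `forward(x)` (image batch to
#' feature batch) and `vjp(g)` (vector-Jacobian product at the last
#' `forward` input, mapping a feature-space gradient back to image
#' space).
#'
#' @param seed Integer seed fixing the random kernels.
#' @param n_features Feature channels per layer.
#' @param n_layers Number of convolution layers.
#' @param slope Fixed leaky-rectifier negative slope.
#' @return An extractor handle.
#' @export
identity_extractor <- function() {
  list(name = "identity",
       forward = function(x) x,
       vjp = function(g) g)
}

#' @rdname identity_extractor
#' @export
conv_extractor <- function(seed = 7L, n_features = 8L, n_layers = 2L,
                           slope = 0.2) {
  weights <- with_seed(seed, {
    cin <- 1L
    lapply(seq_len(n_layers), function(i) {
      w <- xavier_conv(3L, cin, n_features)
      cin <<- n_features
      w
    })
  })
  state <- new.env(parent = emptyenv())
  forward <- function(x) {
    caches <- vector("list", n_layers)
    t <- x
    for (i in seq_len(n_layers)) {
      cv <- conv2d_forward(t, weights[[i]], NULL)
      caches[[i]] <- cv$cache
      t <- cv$y
      if (i < n_layers) {
        pos <- t > 0
        caches[[i]]$slope_mask <- pos + slope * (1 - pos)
        t <- caches[[i]]$slope_mask * t
      }
    }
    state$caches <- caches
    t
  }
  vjp <- function(g) {
    caches <- state$caches
    for (i in rev(seq_len(n_layers))) {
      if (i < n_layers) g <- g * caches[[i]]$slope_mask
      g <- conv2d_backward(g, caches[[i]])$dx
    }
    g
  }
  list(name = sprintf("conv_random(seed=%d,C=%d,L=%d)", seed, n_features,
                      n_layers),
       forward = forward, vjp = vjp)
}

#' Perceptual loss
#'
#' Mean absolute difference between extractor features of the
#' super-resolved and reference images. With the identity extractor it
#' equals `pixel_loss(sr, hr, "L1")` exactly.
#'
#' @inheritParams pixel_loss
#' @param extractor An extractor handle (see [conv_extractor()]).
#' @return A single non-negative number.
#' @export
perceptual_loss <- function(sr, hr, extractor = conv_extractor()) {
  p <- coerce_pair(sr, hr)
  fs <- extractor$forward(p$sr)
  fh <- extractor$forward(p$hr)
  mean(abs(fs - fh))
}

# Value + gradient w.r.t. sr in one pass (extractor caches refer to the
# most recent forward, so order matters: hr first, then sr).
perceptual_loss_vg <- function(sr, hr, extractor) {
  fh <- extractor$forward(hr)
  fs <- extractor$forward(sr)
  d <- fs - fh
  g <- extractor$vjp(array(sign(d) / length(d), dim = dim(d)))
  list(value = mean(abs(d)), grad = g)
}

#' Edge-aware loss
#'
#' Mean absolute difference between the Laplacian edge responses of the
#' two images (replicate padding, 4-neighbour kernel by default; see
#' [laplacian()]). Because the Laplacian annihilates constants, the
#' loss is invariant to adding the same constant offset to both images,
#' and any two constant images compare to zero.
#'
#' @inheritParams pixel_loss
#' @param neighbours Laplacian stencil, 4 (default) or 8.
#' @return A single non-negative number.
#' @export
edge_loss <- function(sr, hr, neighbours = 4L) {
  p <- coerce_pair(sr, hr)
  mean(abs(laplacian_op(p$sr, neighbours) - laplacian_op(p$hr, neighbours)))
}

edge_loss_vg <- function(sr, hr, neighbours = 4L) {
  d <- laplacian_op(sr, neighbours) - laplacian_op(hr, neighbours)
  g <- laplacian_adj(array(sign(d) / length(d), dim = dim(d)), neighbours)
  list(value = mean(abs(d)), grad = g)
}

#' Loss weights
#'
#' Bundles the composite-loss hyper-parameters: the perceptual weight
#' `alpha`, the edge weight `beta`, the pixel norm, and the feature
#' extractor handle. Defaults are the published protocol values
#' `alpha = 0.3`, `beta = 0.1` with an L1 pixel term.
#'
#' @param alpha Non-negative perceptual weight.
#' @param beta Non-negative edge weight.
#' @param pixel_kind `"L1"` or `"L2"`.
#' @param extractor Extractor handle for the perceptual term.
#' @param neighbours Laplacian stencil for the edge term.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(alpha = 0.3, beta = 0.1, pixel_kind = c("L1", "L2"),
                         extractor = conv_extractor(), neighbours = 4L) {
  if (!is.finite(alpha) || alpha < 0 || !is.finite(beta) || beta < 0) {
    stop("alpha and beta must be finite and non-negative")
  }
  structure(list(alpha = alpha, beta = beta,
                 pixel_kind = match.arg(pixel_kind),
                 extractor = extractor, neighbours = neighbours),
            class = "loss_weights")
}

#' Composite super-resolution loss
#'
#' `L = L_pixel + alpha * L_perceptual + beta * L_edge`. Returns the
#' total together with the three unweighted components, so the
#' decomposition can always be audited:
#' `total == pixel + alpha * perceptual + beta * edge`.
#'
#' @inheritParams pixel_loss
#' @param weights A [loss_weights()] bundle.
#' @return A list with elements `total`, `pixel`, `perceptual`, `edge`.
#' @export
composite_loss <- function(sr, hr, weights = loss_weights()) {
  p <- coerce_pair(sr, hr)
  lp <- pixel_loss(p$sr, p$hr, weights$pixel_kind)
  lper <- perceptual_loss(p$sr, p$hr, weights$extractor)
  ledge <- edge_loss(p$sr, p$hr, weights$neighbours)
  list(total = lp + weights$alpha * lper + weights$beta * ledge,
       pixel = lp, perceptual = lper, edge = ledge)
}

# Value + gradient of the composite loss w.r.t. sr (training path).
composite_loss_vg <- function(sr, hr, weights) {
  lp <- pixel_loss(sr, hr, weights$pixel_kind)
  gp <- pixel_loss_grad(sr, hr, weights$pixel_kind)
  per <- perceptual_loss_vg(sr, hr, weights$extractor)
  edg <- edge_loss_vg(sr, hr, weights$neighbours)
  list(total = lp + weights$alpha * per$value + weights$beta * edg$value,
       pixel = lp, perceptual = per$value, edge = edg$value,
       grad = gp + weights$alpha * per$grad + weights$beta * edg$grad)
}
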