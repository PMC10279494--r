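# The super-resolution network: a small residual trunk with PReLU and
# LayerNorm, an optional parameter-free chunking fusion (PCFB) stage, and
# a sub-pixel reconstruction head. Forward and reverse passes are written
# explicitly so the whole model trains without any autodiff framework.

#' Network configuration
#'
#' Collects the architecture hyper-parameters. Defaults follow the
#' SRResNet-style trunk (16 residual blocks of 64 features) the method
#' builds on; the chunk count defaults to the published protocol value
#' `n = 2`.
#'
#' @param scale_factor Integer upscaling factor `r` in 1..4. `r = 4` is
#'   realised as two successive x2 sub-pixel stages; other factors use a
#'   single stage.
#' @param n_chunks Channel chunks `n` used by the PCFB (must divide
#'   `n_features`).
#' @param n_res_blocks Number of residual blocks in the trunk.
#' @param n_features Trunk width `C` (feature channels).
#' @param simam_lambda SimAM energy regulariser.
#' @param prelu_init Initial PReLU negative-branch slope in `[0, 1]`.
#' @param layer_norm_eps LayerNorm variance stabiliser.
#' @param use_pcfb Insert the PCFB between the trunk output and the
#'   reconstruction head (the block holds zero learnable parameters, so
#'   toggling it never changes the parameter count).
#' @param pcfb_per_block Additionally apply the PCFB after every
#'   residual block.
#' @param global_skip Add the head-conv output to the trunk output
#'   (long skip connection).
#' @param ln_axes LayerNorm normalisation axes, `"all"` = per sample
#'   over (channel, height, width) jointly, `"spatial"` = per channel.
#' @param var_denom SimAM spatial-variance divisor convention
#'   (`"n-1"` or `"n"`).
#' @return An object of class `sr_config` (a validated list).
#' @export
sr_config <- function(scale_factor = 2L, n_chunks = 2L, n_res_blocks = 16L,
                      n_features = 64L, simam_lambda = 1e-4,
                      prelu_init = 0.25, layer_norm_eps = 1e-5,
                      use_pcfb = TRUE, pcfb_per_block = FALSE,
                      global_skip = TRUE, ln_axes = c("all", "spatial"),
                      var_denom = c("n-1", "n")) {
  cfg <- list(scale_factor = as.integer(scale_factor),
              n_chunks = as.integer(n_chunks),
              n_res_blocks = as.integer(n_res_blocks),
              n_features = as.integer(n_features),
              simam_lambda = simam_lambda,
              prelu_init = prelu_init,
              layer_norm_eps = layer_norm_eps,
              use_pcfb = isTRUE(use_pcfb),
              pcfb_per_block = isTRUE(pcfb_per_block),
              global_skip = isTRUE(global_skip),
              ln_axes = match.arg(ln_axes),
              var_denom = match.arg(var_denom))
  validate_sr_config(cfg)
  class(cfg) <- "sr_config"
  cfg
}

validate_sr_config <- function(cfg) {
  if (!cfg$scale_factor %in% 1:4) {
    stop("invalid config: scale_factor must be one of 1, 2, 3, 4")
  }
  if (cfg$n_chunks < 1L) stop("invalid config: n_chunks must be >= 1")
  if (cfg$n_res_blocks < 1L) stop("invalid config: n_res_blocks must be >= 1")
  if (cfg$n_features < 1L) stop("invalid config: n_features must be >= 1")
  if (cfg$n_features %% cfg$n_chunks != 0L) {
    stop(sprintf(
      "invalid config: n_features (%d) must be divisible by n_chunks (%d)",
      cfg$n_features, cfg$n_chunks))
  }
  if (cfg$simam_lambda < 0) stop("invalid config: simam_lambda must be >= 0")
  if (cfg$prelu_init < 0 || cfg$prelu_init > 1) {
    stop("invalid config: prelu_init must lie in [0, 1]")
  }
  if (cfg$layer_norm_eps <= 0) {
    stop("invalid config: layer_norm_eps must be > 0")
  }
  invisible(cfg)
}

upscale_stages <- function(r) {
  if (r == 4L) c(2L, 2L) else r
}

# Xavier/Glorot uniform draw for a (K,K,Cin,Cout) kernel.
xavier_conv <- function(K, cin, cout) {
  fan_in <- K * K * cin
  fan_out <- K * K * cout
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(K * K * cin * cout, -lim, lim), dim = c(K, K, cin, cout))
}

# Draw a full parameter set for a config; assumes the RNG is already seeded.
draw_params <- function(cfg) {
  C <- cfg$n_features
  p <- list()
  p[["head.w"]] <- xavier_conv(3L, 1L, C)
  p[["head.b"]] <- numeric(C)
  p[["head.a"]] <- rep(cfg$prelu_init, C)
  for (i in seq_len(cfg$n_res_blocks)) {
    nm <- sprintf("block%d", i)
    p[[paste0(nm, ".conv1.w")]] <- xavier_conv(3L, C, C)
    p[[paste0(nm, ".conv1.b")]] <- numeric(C)
    p[[paste0(nm, ".ln.gamma")]] <- rep(1, C)
    p[[paste0(nm, ".ln.beta")]] <- numeric(C)
    p[[paste0(nm, ".act.a")]] <- rep(cfg$prelu_init, C)
    p[[paste0(nm, ".conv2.w")]] <- xavier_conv(3L, C, C)
    p[[paste0(nm, ".conv2.b")]] <- numeric(C)
  }
  p[["trunk.w"]] <- xavier_conv(3L, C, C)
  p[["trunk.b"]] <- numeric(C)
  stages <- upscale_stages(cfg$scale_factor)
  for (s in seq_along(stages)) {
    ru <- stages[s]
    p[[sprintf("recon%d.w", s)]] <- xavier_conv(3L, C, C * ru * ru)
    p[[sprintf("recon%d.b", s)]] <- numeric(C * ru * ru)
  }
  p[["recon.act.a"]] <- rep(cfg$prelu_init, C)
  p[["out.w"]] <- xavier_conv(1L, C, 1L)
  p[["out.b"]] <- numeric(1L)
  p
}

#' Build the super-resolution network
#'
#' Constructs the model deterministically from a configuration and a
#' seed: head 3x3 convolution (1 -> C) with PReLU, `n_res_blocks`
#' residual blocks (conv - LayerNorm - PReLU - conv with identity
#' skip), a trunk convolution with a long skip from the head output,
#' the PCFB attention stage, and a reconstruction head (3x3 convolution
#' to `C * r^2` channels, PixelShuffle, PReLU, 1x1 convolution to one
#' channel). Weights use Xavier (Glorot) uniform initialisation, biases
#' are zero, PReLU slopes start at `prelu_init`, and LayerNorm at
#' `gamma = 1`, `beta = 0`. Two builds from the same `(config, seed)`
#' are bit-identical.
#'
#' @param config An [sr_config()].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `sr_network`, with `print`, `summary`,
#'   `coef` and `predict` methods.
#' @examples
#' net <- sr_network(sr_config(n_res_blocks = 1, n_features = 4), seed = 1)
#' count_parameters(net)
#' @export
sr_network <- function(config = sr_config(), seed = 1L) {
  validate_sr_config(config)
  params <- with_seed(seed, draw_params(config))
  structure(list(config = config, seed = as.integer(seed), params = params),
            class = "sr_network")
}

#' Re-initialise a network with Xavier weights
#'
#' Redraws all convolution kernels from the Glorot uniform distribution
#' `U(-sqrt(6/(fan_in+fan_out)), +sqrt(6/(fan_in+fan_out)))`, zeroes the
#' biases, and resets PReLU slopes and LayerNorm affine parameters to
#' their initial values. Deterministic per seed.
#'
#' @param model An `sr_network`.
#' @param seed Integer seed.
#' @return The re-initialised `sr_network`.
#' @export
xavier_init <- function(model, seed) {
  stopifnot(inherits(model, "sr_network"))
  model$params <- with_seed(seed, draw_params(model$config))
  model$seed <- as.integer(seed)
  model
}

#' Count the learnable parameters of a network
#'
#' Sums every learnable scalar: convolution kernels and biases, PReLU
#' slopes, and LayerNorm scales/shifts. The count is a deterministic
#' function of the configuration (never of the seed), and is unchanged
#' by enabling or disabling the parameter-free PCFB stage.
#'
#' @param model An `sr_network`.
#' @return Non-negative integer.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "sr_network"))
  sum(vapply(model$params, length, integer(1)))
}

#' Apply one residual block
#'
#' The trunk's unit of computation: `x + F(x)` with branch
#' `F = conv(3x3) -> LayerNorm -> PReLU -> conv(3x3)`, both convolutions
#' stride 1 with shape-preserving padding. With an all-zero branch
#' (zero kernels and biases, LayerNorm shift `beta = 0`) the block is
#' exactly the identity, which is also how every block behaves at the
#' start of training in the skip direction.
#'
#' @param x Feature map `(B, C, H, W)`.
#' @param params List with elements `conv1_w`, `conv1_b` (`(3,3,C,C)`
#'   kernel and length-`C` bias), `ln_gamma`, `ln_beta`, `act_a`
#'   (per-channel), `conv2_w`, `conv2_b`.
#' @param eps LayerNorm stabiliser.
#' @param axes LayerNorm axes (see [layer_norm()]).
#' @return Feature map shaped like `x`.
#' @export
residual_block <- function(x, params, eps = 1e-5, axes = "all") {
  x <- feature_map(x)
  if (dim(params$conv1_w)[3] != dim(x)[2]) {
    stop(sprintf("residual_block: input has %d channels, block expects %d",
                 dim(x)[2], dim(params$conv1_w)[3]))
  }
  t <- conv2d(x, params$conv1_w, params$conv1_b)
  t <- layer_norm(t, params$ln_gamma, params$ln_beta, eps, axes)
  t <- prelu(t, params$act_a)
  x + conv2d(t, params$conv2_w, params$conv2_b)
}

# Pull block i's parameters out of a network as a residual_block() list.
block_params <- function(model, i) {
  p <- model$params
  nm <- sprintf("block%d", i)
  list(conv1_w = p[[paste0(nm, ".conv1.w")]],
       conv1_b = p[[paste0(nm, ".conv1.b")]],
       ln_gamma = p[[paste0(nm, ".ln.gamma")]],
       ln_beta = p[[paste0(nm, ".ln.beta")]],
       act_a = p[[paste0(nm, ".act.a")]],
       conv2_w = p[[paste0(nm, ".conv2.w")]],
       conv2_b = p[[paste0(nm, ".conv2.b")]])
}

# ---- forward / backward --------------------------------------------------

# Full forward pass. keep = TRUE retains every intermediate needed by
# sr_backward (training); keep = FALSE is the cheap inference path.
sr_forward <- function(model, x, keep = FALSE) {
  cfg <- model$config
  p <- model$params
  if (!all(is.finite(x))) stop("forward: input contains non-finite values")
  x <- feature_map(x)
  cache <- if (keep) list() else NULL
  cv <- conv2d_forward(x, p[["head.w"]], p[["head.b"]])
  pr <- prelu_forward(cv$y, p[["head.a"]])
  f0 <- pr$y
  if (keep) cache$head <- list(conv = cv$cache, act = pr$cache)
  t <- f0
  blocks <- vector("list", cfg$n_res_blocks)
  for (i in seq_len(cfg$n_res_blocks)) {
    nm <- sprintf("block%d", i)
    c1 <- conv2d_forward(t, p[[paste0(nm, ".conv1.w")]],
                         p[[paste0(nm, ".conv1.b")]])
    ln <- layer_norm_forward(c1$y, p[[paste0(nm, ".ln.gamma")]],
                             p[[paste0(nm, ".ln.beta")]],
                             cfg$layer_norm_eps, cfg$ln_axes)
    ac <- prelu_forward(ln$y, p[[paste0(nm, ".act.a")]])
    c2 <- conv2d_forward(ac$y, p[[paste0(nm, ".conv2.w")]],
                         p[[paste0(nm, ".conv2.b")]])
    t <- t + c2$y
    blk <- list(conv1 = c1$cache, ln = ln$cache, act = ac$cache,
                conv2 = c2$cache)
    if (cfg$pcfb_per_block) {
      pf <- pcfb_forward(t, cfg$n_chunks, cfg$simam_lambda, cfg$var_denom)
      t <- pf$y
      blk$pcfb <- pf$cache
    }
    if (keep) blocks[[i]] <- blk
  }
  if (keep) cache$blocks <- blocks
  tc <- conv2d_forward(t, p[["trunk.w"]], p[["trunk.b"]])
  if (keep) cache$trunk <- tc$cache
  t <- tc$y
  if (cfg$global_skip) t <- t + f0
  if (cfg$use_pcfb) {
    pf <- pcfb_forward(t, cfg$n_chunks, cfg$simam_lambda, cfg$var_denom)
    t <- pf$y
    if (keep) cache$pcfb <- pf$cache
  }
  stages <- upscale_stages(cfg$scale_factor)
  rec <- vector("list", length(stages))
  for (s in seq_along(stages)) {
    rc <- conv2d_forward(t, p[[sprintf("recon%d.w", s)]],
                         p[[sprintf("recon%d.b", s)]])
    t <- pixel_shuffle(rc$y, stages[s])
    if (keep) rec[[s]] <- rc$cache
  }
  if (keep) cache$recon <- rec
  pa <- prelu_forward(t, p[["recon.act.a"]])
  if (keep) cache$recon_act <- pa$cache
  ov <- conv2d_forward(pa$y, p[["out.w"]], p[["out.b"]])
  if (keep) cache$out <- ov$cache
  list(y = ov$y, cache = cache)
}

# Reverse pass: gy is dLoss/dOutput, returns a grads list named like params.
sr_backward <- function(model, cache, gy) {
  cfg <- model$config
  gr <- list()
  stages <- upscale_stages(cfg$scale_factor)
  bo <- conv2d_backward(gy, cache$out)
  gr[["out.w"]] <- bo$dw; gr[["out.b"]] <- bo$db
  bp <- prelu_backward(bo$dx, cache$recon_act)
  gr[["recon.act.a"]] <- bp$da
  g <- bp$dx
  for (s in rev(seq_along(stages))) {
    g <- pixel_unshuffle(g, stages[s])
    br <- conv2d_backward(g, cache$recon[[s]])
    gr[[sprintf("recon%d.w", s)]] <- br$dw
    gr[[sprintf("recon%d.b", s)]] <- br$db
    g <- br$dx
  }
  if (cfg$use_pcfb) g <- pcfb_backward(g, cache$pcfb)
  g_skip <- if (cfg$global_skip) g else NULL
  bt <- conv2d_backward(g, cache$trunk)
  gr[["trunk.w"]] <- bt$dw; gr[["trunk.b"]] <- bt$db
  g <- bt$dx
  for (i in rev(seq_len(cfg$n_res_blocks))) {
    nm <- sprintf("block%d", i)
    blk <- cache$blocks[[i]]
    if (cfg$pcfb_per_block) g <- pcfb_backward(g, blk$pcfb)
    b2 <- conv2d_backward(g, blk$conv2)
    gr[[paste0(nm, ".conv2.w")]] <- b2$dw
    gr[[paste0(nm, ".conv2.b")]] <- b2$db
    ba <- prelu_backward(b2$dx, blk$act)
    gr[[paste0(nm, ".act.a")]] <- ba$da
    bl <- layer_norm_backward(ba$dx, blk$ln)
    gr[[paste0(nm, ".ln.gamma")]] <- bl$dgamma
    gr[[paste0(nm, ".ln.beta")]] <- bl$dbeta
    b1 <- conv2d_backward(bl$dx, blk$conv1)
    gr[[paste0(nm, ".conv1.w")]] <- b1$dw
    gr[[paste0(nm, ".conv1.b")]] <- b1$db
    g <- g + b1$dx                     # identity skip inside the block
  }
  if (!is.null(g_skip)) g <- g + g_skip
  bh <- prelu_backward(g, cache$head$act)
  gr[["head.a"]] <- bh$da
  bc <- conv2d_backward(bh$dx, cache$head$conv)
  gr[["head.w"]] <- bc$dw; gr[["head.b"]] <- bc$db
  gr[names(model$params)]
}

#' Super-resolve images with a network
#'
#' Runs the forward pass `I_SR = G(I_LR; theta)`. The spatial output
#' size is exactly `scale_factor` times the input size in both axes,
#' for any valid input size; repeated calls on the same input give
#' identical output.
#'
#' @param object An `sr_network` (or an `sr_fit` from [sr_train()]).
#' @param newdata An `H x W` numeric matrix in `[0, 1]`, a list of such
#'   matrices, or a `(B, 1, H, W)` batch array.
#' @param clip Clip the output to `[0, 1]` (default `TRUE`; inference
#'   convenience — raw network output is unbounded).
#' @param ... Unused.
#' @return The same container kind as `newdata`, upscaled.
#' @export
predict.sr_network <- function(object, newdata, clip = TRUE, ...) {
  if (is.list(newdata) && !is.array(newdata)) {
    return(lapply(newdata, function(im) predict(object, im, clip = clip)))
  }
  was_mat <- is.matrix(newdata)
  x <- as_batch(newdata)
  y <- sr_forward(object, x, keep = FALSE)$y
  if (clip) y <- clamp01(y)
  if (was_mat) as_image(y) else y
}

#' @export
print.sr_network <- function(x, ...) {
  cfg <- x$config
  cat("Super-resolution network (residual trunk + PCFB + sub-pixel head)\n")
  cat(sprintf("  scale factor    : x%d\n", cfg$scale_factor))
  cat(sprintf("  trunk           : %d residual block(s), %d features\n",
              cfg$n_res_blocks, cfg$n_features))
  cat(sprintf("  PCFB            : %s (n = %d chunks, lambda = %g)\n",
              if (cfg$use_pcfb) "enabled" else "disabled",
              cfg$n_chunks, cfg$simam_lambda))
  cat(sprintf("  parameters      : %s learnable scalars\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' @export
summary.sr_network <- function(object, ...) {
  sizes <- vapply(object$params, length, integer(1))
  out <- list(config = object$config, seed = object$seed,
              n_parameters = sum(sizes), parameter_sizes = sizes)
  class(out) <- "summary.sr_network"
  out
}

#' @export
print.summary.sr_network <- function(x, ...) {
  cat(sprintf("sr_network: %s parameters (seed %d)\n",
              format(x$n_parameters, big.mark = ","), x$seed))
  df <- data.frame(parameter = names(x$parameter_sizes),
                   size = unname(x$parameter_sizes))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.sr_network <- function(object, ...) {
  object$params
}

# ---- checkpoints ---------------------------------------------------------

#' Save / load a network checkpoint
#'
#' A checkpoint is a flat archive of the named parameter arrays together
#' with the serialised configuration and seed. The round trip is
#' bit-exact for every parameter.
#'
#' @param model An `sr_network`.
#' @param path File path (conventionally `.rds`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `sr_network`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "sr_network"))
  obj <- list(format = "pcfbsr-checkpoint-1",
              config = unclass(model$config),
              seed = model$seed,
              params = model$params)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "pcfbsr-checkpoint-1")) {
    stop(sprintf("'%s' is not a recognised checkpoint file", path))
  }
  cfg <- obj$config
  class(cfg) <- "sr_config"
  validate_sr_config(cfg)
  structure(list(config = cfg, seed = obj$seed, params = obj$params),
            class = "sr_network")
}
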