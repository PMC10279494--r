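test_that("conv2d matches the quadruple-loop oracle", {
  set.seed(5)
  x <- rand_map(2, 3, 5, 4)
  w <- array(rnorm(3 * 3 * 3 * 2), dim = c(3, 3, 3, 2))
  b <- rnorm(2)
  expect_equal(conv2d(x, w, b), oracle_conv2d(x, w, b), tolerance = 1e-12)
  # 1x1 convolution is a channel mix
  w1 <- array(rnorm(3 * 2), dim = c(1, 1, 3, 2))
  expect_equal(conv2d(x, w1, NULL), oracle_conv2d(x, w1), tolerance = 1e-12)
  expect_error(conv2d(x, array(0, c(3, 3, 4, 2))), "channels")
})

test_that("prelu follows its two-branch definition", {
  x <- array(c(2, -2), dim = c(1, 1, 1, 2))
  expect_equal(as.vector(prelu(x, 0.25)), c(2, -0.5))
  set.seed(1)
  z <- rand_map(2, 3, 4, 4)
  expect_equal(prelu(z, 1), z)               # a = 1 is the identity
  a <- c(0.1, 0.5, 0.9)
  y <- prelu(z, a)
  for (ch in 1:3) {
    m <- z[, ch, , ]
    expect_equal(y[, ch, , ], ifelse(m > 0, m, a[ch] * m))
  }
})

test_that("layer norm standardises per sample and applies affine", {
  # two-value sample [1, 3]: mean 2, population variance 1
  x <- array(c(1, 3), dim = c(1, 1, 1, 2))
  expect_equal(as.vector(layer_norm(x, 1, 0, eps = 1e-12)), c(-1, 1),
               tolerance = 1e-5)
  # already standardised input is (nearly) a fixed point
  set.seed(2)
  z <- rand_map(2, 3, 6, 6)
  m <- pcfbsr:::ln_matrix(z, "all")
  m <- sweep(m, 2, colMeans(m), "-")
  m <- sweep(m, 2, sqrt(colMeans(m^2)), "/")
  zs <- pcfbsr:::ln_unmatrix(m, dim(z), "all")
  expect_equal(layer_norm(zs, 1, 0, eps = 1e-10), zs, tolerance = 1e-4)
  # gamma = 0 collapses to the shift
  expect_equal(as.vector(layer_norm(z, 0, 0.7)), rep(0.7, length(z)))
  # pre-affine output has mean ~0 and variance ~1 per sample
  y <- layer_norm(z, 1, 0, eps = 1e-10)
  ym <- pcfbsr:::ln_matrix(y, "all")
  expect_lt(max(abs(colMeans(ym))), 1e-12)
  expect_equal(unname(colMeans(ym^2)), rep(1, 2), tolerance = 1e-6)
})

test_that("residual block is x + F(x) and identity for a zero branch", {
  set.seed(8)
  C <- 6
  x <- rand_map(2, C, 5, 5)
  zero <- list(conv1_w = array(0, c(3, 3, C, C)), conv1_b = numeric(C),
               ln_gamma = rep(1, C), ln_beta = numeric(C),
               act_a = rep(0.25, C),
               conv2_w = array(0, c(3, 3, C, C)), conv2_b = numeric(C))
  expect_equal(residual_block(x, zero), x)
  rnd <- list(conv1_w = array(rnorm(9 * C * C, 0, 0.1), c(3, 3, C, C)),
              conv1_b = rnorm(C), ln_gamma = runif(C), ln_beta = rnorm(C),
              act_a = runif(C),
              conv2_w = array(rnorm(9 * C * C, 0, 0.1), c(3, 3, C, C)),
              conv2_b = rnorm(C))
  y <- residual_block(x, rnd)
  expect_identical(dim(y), dim(x))
  expect_true(all(is.finite(y)))
  expect_error(residual_block(rand_map(1, 4, 5, 5), rnd), "channels")
})

test_that("pixel shuffle follows the stated index convention", {
  x <- rand_map(2, 4, 3, 3)
  expect_identical(pixel_shuffle(x, 1), x)
  # channel values 1..4 land as [[1,2],[3,4]]
  v <- array(1:4, dim = c(1, 4, 1, 1))
  expect_equal(pixel_shuffle(v, 2)[1, 1, , ], matrix(1:4, 2, 2, byrow = TRUE))
  # index-loop oracle under out[b,c,h*r+i,w*r+j] = in[b,c*r^2+i*r+j,h,w]
  set.seed(4)
  r <- 2L
  z <- rand_map(2, 8, 3, 2)
  y <- pixel_shuffle(z, r)
  for (b in 1:2) for (co in 1:2) for (h in 0:2) for (w in 0:1) {
    for (i in 0:(r - 1)) for (j in 0:(r - 1)) {
      expect_identical(y[b, co, h * r + i + 1, w * r + j + 1],
                       z[b, (co - 1) * r^2 + i * r + j + 1, h + 1, w + 1])
    }
  }
  # permutation: the multiset of values is preserved
  expect_equal(sort(as.vector(y)), sort(as.vector(z)))
  expect_identical(pcfbsr:::pixel_unshuffle(y, r), z)
  expect_error(pixel_shuffle(rand_map(1, 6, 2, 2), 2), "divisible")
})

test_that("network builds deterministically and validates its config", {
  cfg <- sr_config(n_res_blocks = 2, n_features = 8, n_chunks = 2)
  n1 <- sr_network(cfg, seed = 42)
  n2 <- sr_network(cfg, seed = 42)
  expect_identical(n1$params, n2$params)
  n3 <- sr_network(cfg, seed = 43)
  expect_false(identical(n1$params, n3$params))
  expect_no_error(sr_network(sr_config(n_features = 64, n_chunks = 2),
                             seed = 1))
  expect_error(sr_config(n_features = 64, n_chunks = 3), "divisible")
  expect_error(sr_config(scale_factor = 5), "scale_factor")
  expect_error(sr_config(simam_lambda = -1), "simam_lambda")
})

test_that("forward emits (H*r, W*r) and is deterministic", {
  set.seed(9)
  for (r in c(1L, 2L, 3L, 4L)) {
    net <- sr_network(sr_config(scale_factor = r, n_res_blocks = 1,
                                n_features = 4, n_chunks = 2), seed = 7)
    lr <- matrix(runif(24 * 24), 24, 24)
    sr <- predict(net, lr)
    expect_identical(dim(sr), c(24L * r, 24L * r))
    expect_identical(sr, predict(net, lr))
  }
  # odd input size still scales exactly
  net <- sr_network(sr_config(n_res_blocks = 1, n_features = 4), seed = 1)
  expect_identical(dim(predict(net, matrix(runif(15 * 17), 15, 17))),
                   c(30L, 34L))
  bad <- matrix(c(NA, runif(24 * 24 - 1)), 24, 24)
  expect_error(predict(net, bad), "finite")
})

test_that("parameter count is config-determined and PCFB-neutral", {
  set.seed(30)
  for (rep in 1:5) {
    C <- sample(c(4L, 8L, 16L), 1)
    cfg_on <- sr_config(scale_factor = sample(1:4, 1),
                        n_res_blocks = sample(1:3, 1), n_features = C,
                        n_chunks = sample(c(1L, 2L), 1), use_pcfb = TRUE)
    cfg_off <- cfg_on; cfg_off$use_pcfb <- FALSE
    n_on <- sr_network(cfg_on, seed = rep)
    n_off <- sr_network(cfg_off, seed = rep)
    expect_identical(count_parameters(n_on), count_parameters(n_off))
    # count is invariant to the seed
    expect_identical(count_parameters(n_on),
                     count_parameters(sr_network(cfg_on, seed = rep + 99)))
  }
  # single 3x3 conv from 1 channel to 1 channel with bias holds 10 scalars
  net1 <- sr_network(sr_config(n_res_blocks = 1, n_features = 1,
                               n_chunks = 1), seed = 1)
  expect_identical(length(coef(net1)$head.w) + length(coef(net1)$head.b), 10L)
})

test_that("zero-branch identity holds for every block of a built model", {
  net <- sr_network(sr_config(n_res_blocks = 3, n_features = 4), seed = 2)
  x <- rand_map(1, 4, 6, 6)
  for (i in 1:3) {
    bp <- pcfbsr:::block_params(net, i)
    bp$conv1_w[] <- 0; bp$conv1_b[] <- 0
    bp$conv2_w[] <- 0; bp$conv2_b[] <- 0
    bp$ln_beta[] <- 0
    expect_equal(residual_block(x, bp), x)
  }
})

test_that("autodiff gradient of the composite loss matches finite differences", {
  set.seed(42)
  net <- sr_network(sr_config(scale_factor = 2, n_chunks = 2,
                              n_res_blocks = 1, n_features = 4), seed = 5)
  xb <- array(runif(2 * 36), dim = c(2, 1, 6, 6))
  hr <- array(runif(2 * 144), dim = c(2, 1, 12, 12))
  w <- loss_weights(0.3, 0.1,
                    extractor = conv_extractor(seed = 9, n_features = 4,
                                               n_layers = 2))
  fwd <- pcfbsr:::sr_forward(net, xb, keep = TRUE)
  vg <- pcfbsr:::composite_loss_vg(fwd$y, hr, w)
  gr <- pcfbsr:::sr_backward(net, fwd$cache, vg$grad)
  lossfun <- function(n) {
    pcfbsr:::composite_loss_vg(pcfbsr:::sr_forward(n, xb)$y, hr, w)$total
  }
  h <- 1e-5
  for (nm in names(net$params)) {
    p <- net$params[[nm]]
    for (i in sample(length(p), min(2, length(p)))) {
      n1 <- net; n1$params[[nm]][i] <- p[i] + h
      n2 <- net; n2$params[[nm]][i] <- p[i] - h
      fd <- (lossfun(n1) - lossfun(n2)) / (2 * h)
      an <- gr[[nm]][i]
      expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-8), 1e-3)
    }
  }
})

test_that("checkpoints round-trip bit-exactly", {
  net <- sr_network(sr_config(n_res_blocks = 1, n_features = 4), seed = 77)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(net, f)
  back <- load_checkpoint(f)
  expect_identical(back$params, net$params)
  expect_identical(unclass(back$config), unclass(net$config))
  expect_identical(back$seed, net$seed)
  x <- matrix(runif(16 * 16), 16, 16)
  expect_identical(predict(back, x), predict(net, x))
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(load_checkpoint(bad), "not a recognised")
})
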