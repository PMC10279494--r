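# Optimisation loop: Adam on the composite loss over randomly extracted,
# augmented LR/HR patch pairs, with periodic validation and best-PSNR
# checkpoint selection.

#' Training configuration
#'
#' Defaults follow the published protocol: batch size 16, 24x24 LR
#' patches, Adam with initial learning rate 0.001, perceptual weight
#' `alpha = 0.3` and edge weight `beta = 0.1`. Adam moment parameters
#' are the optimiser's canonical defaults (0.9, 0.999, 1e-8) and are
#' recorded in the config. The learning rate is constant unless a step
#' decay is configured.
#'
#' @param batch_size Patch pairs per iteration.
#' @param patch LR patch side length.
#' @param learning_rate Initial Adam learning rate.
#' @param alpha,beta Composite-loss weights (perceptual, edge).
#' @param max_iters Total Adam iterations (0 = return the model
#'   unchanged).
#' @param val_every Validate every this many iterations (0 disables).
#' @param seed Master seed for batch sampling, patch offsets and
#'   augmentation.
#' @param mode Degradation mode the pairs were built with (`"BD"` or
#'   `"TD"`), recorded for provenance.
#' @param scale Upscaling factor, recorded for provenance.
#' @param extractor Feature extractor for the perceptual term (default
#'   a fixed random convolutional bank, [conv_extractor()]).
#' @param adam_beta1,adam_beta2,adam_eps Adam moment/stabiliser
#'   constants.
#' @param decay_every,decay_factor Optional step decay: multiply the
#'   rate by `decay_factor` every `decay_every` iterations
#'   (`decay_every = 0` keeps the rate constant).
#' @param augment Apply random flip/rotation to training patches.
#' @return An `sr_train_config` list.
#' @export
sr_train_config <- function(batch_size = 16L, patch = 24L,
                            learning_rate = 0.001, alpha = 0.3, beta = 0.1,
                            max_iters = 200L, val_every = 50L, seed = 1L,
                            mode = "BD", scale = 2L,
                            extractor = conv_extractor(),
                            adam_beta1 = 0.9, adam_beta2 = 0.999,
                            adam_eps = 1e-8,
                            decay_every = 0L, decay_factor = 0.5,
                            augment = TRUE) {
  cfg <- list(batch_size = as.integer(batch_size), patch = as.integer(patch),
              learning_rate = learning_rate, alpha = alpha, beta = beta,
              max_iters = as.integer(max_iters),
              val_every = as.integer(val_every), seed = as.integer(seed),
              mode = toupper(mode), scale = as.integer(scale),
              extractor = extractor,
              adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
              adam_eps = adam_eps, decay_every = as.integer(decay_every),
              decay_factor = decay_factor, augment = isTRUE(augment))
  stopifnot(cfg$batch_size >= 1L, cfg$patch >= 1L, cfg$learning_rate > 0,
            cfg$alpha >= 0, cfg$beta >= 0, cfg$max_iters >= 0L)
  class(cfg) <- "sr_train_config"
  cfg
}

#' Train a super-resolution network
#'
#' Runs the optimisation loop: each iteration samples `batch_size`
#' paired patches (with replacement) from the training split, extracts
#' and augments them, runs the forward pass, evaluates the composite
#' loss, backpropagates, and takes one Adam step on every learnable
#' parameter. Every `val_every` iterations the current model is scored
#' (PSNR/SSIM/RMSE) on the validation split; the returned model is the
#' checkpoint with the best validation PSNR (or the final state when no
#' validation is available). The run is bit-reproducible from
#' `(model, data, config)`.
#'
#' @param model An [sr_network()].
#' @param data A list with element `train` (non-empty list of
#'   [make_pair()] samples) and optionally `val` (validation pairs); a
#'   plain list of pairs is treated as the training split.
#' @param config An [sr_train_config()].
#' @return An object of class `sr_fit`: the trained network plus the
#'   full per-iteration loss history and validation records, with
#'   `print`, `summary`, `plot`, `predict` and `coef` methods.
#' @export
sr_train <- function(model, data, config = sr_train_config()) {
  stopifnot(inherits(model, "sr_network"))
  if (inherits(data, "paired_sample")) data <- list(data)
  if (!is.null(data$train)) {
    train_pairs <- data$train
    val_pairs <- data$val
  } else {
    train_pairs <- data
    val_pairs <- NULL
  }
  if (length(train_pairs) == 0L) stop("training split is empty")
  cfg <- config
  weights <- loss_weights(cfg$alpha, cfg$beta, extractor = cfg$extractor)

  history <- data.frame(iter = integer(0), lr = numeric(0),
                        total = numeric(0), pixel = numeric(0),
                        perceptual = numeric(0), edge = numeric(0))
  val_history <- data.frame(iter = integer(0), psnr = numeric(0),
                            ssim = numeric(0), rmse = numeric(0))
  best <- list(psnr = -Inf, params = NULL, iter = NA_integer_)

  if (cfg$max_iters > 0L) {
    with_seed(cfg$seed, {
      adam_m <- lapply(model$params, function(p) p * 0)
      adam_v <- adam_m
      for (it in seq_len(cfg$max_iters)) {
        idx <- sample.int(length(train_pairs), cfg$batch_size, replace = TRUE)
        seeds <- sample.int(.Machine$integer.max, 2L * cfg$batch_size)
        lr_list <- vector("list", cfg$batch_size)
        hr_list <- vector("list", cfg$batch_size)
        for (b in seq_len(cfg$batch_size)) {
          sm <- extract_patch_pair(train_pairs[[idx[b]]], cfg$patch,
                                   seed = seeds[2L * b - 1L])
          if (cfg$augment) sm <- augment_pair(sm, seed = seeds[2L * b])
          lr_list[[b]] <- sm$lr
          hr_list[[b]] <- sm$hr
        }
        xb <- stack_images(lr_list)
        yb <- stack_images(hr_list)
        fw <- sr_forward(model, xb, keep = TRUE)
        vg <- composite_loss_vg(fw$y, yb, weights)
        if (!is.finite(vg$total)) {
          dump <- tempfile("sr_train_diag_", fileext = ".rds")
          saveRDS(list(iteration = it, loss = vg[c("total", "pixel",
                                                   "perceptual", "edge")],
                       params = model$params), dump)
          stop(sprintf(
            "non-finite composite loss at iteration %d; state dumped to %s",
            it, dump))
        }
        grads <- sr_backward(model, fw$cache, vg$grad)
        rate <- cfg$learning_rate
        if (cfg$decay_every > 0L) {
          rate <- rate * cfg$decay_factor^(it %/% cfg$decay_every)
        }
        bc1 <- 1 - cfg$adam_beta1^it
        bc2 <- 1 - cfg$adam_beta2^it
        for (nm in names(model$params)) {
          g <- grads[[nm]]
          adam_m[[nm]] <- cfg$adam_beta1 * adam_m[[nm]] +
            (1 - cfg$adam_beta1) * g
          adam_v[[nm]] <- cfg$adam_beta2 * adam_v[[nm]] +
            (1 - cfg$adam_beta2) * g * g
          model$params[[nm]] <- model$params[[nm]] -
            rate * (adam_m[[nm]] / bc1) /
              (sqrt(adam_v[[nm]] / bc2) + cfg$adam_eps)
        }
        history[nrow(history) + 1L, ] <- list(it, rate, vg$total, vg$pixel,
                                              vg$perceptual, vg$edge)
        if (cfg$val_every > 0L && length(val_pairs) > 0L &&
            it %% cfg$val_every == 0L) {
          rec <- evaluate_model(model, val_pairs)
          val_history[nrow(val_history) + 1L, ] <-
            list(it, rec$psnr, rec$ssim, rec$rmse)
          if (rec$psnr > best$psnr) {
            best$psnr <- rec$psnr
            best$params <- model$params
            best$iter <- it
          }
        }
      }
    })
  }
  if (!is.null(best$params)) model$params <- best$params
  structure(list(model = model, history = history,
                 val_history = val_history, config = cfg,
                 best_iter = best$iter, best_psnr = best$psnr),
            class = "sr_fit")
}

#' Evaluate a model on a set of paired samples
#'
#' Super-resolves every LR member (output clipped to `[0, 1]`) and
#' scores it against the HR member with [evaluate_set()].
#'
#' @param model An `sr_network` or `sr_fit`.
#' @param test_pairs Non-empty list of `paired_sample` objects.
#' @param ssim_mode Passed to [img_ssim()].
#' @return A `metrics_record`.
#' @export
evaluate_model <- function(model, test_pairs, ssim_mode = "window") {
  if (inherits(model, "sr_fit")) model <- model$model
  if (length(test_pairs) == 0L) stop("test set is empty")
  pairs <- lapply(test_pairs, function(p) {
    list(hr = p$hr, sr = predict(model, p$lr, clip = TRUE))
  })
  evaluate_set(pairs, ssim_mode = ssim_mode)
}

#' @export
print.sr_fit <- function(x, ...) {
  cat("Fitted super-resolution network\n")
  print(x$model)
  n <- nrow(x$history)
  if (n > 0L) {
    k <- min(20L, n)
    cat(sprintf("  iterations      : %d (loss %.4f -> %.4f, first/last %d-iteration medians)\n",
                n, stats::median(x$history$total[seq_len(k)]),
                stats::median(x$history$total[(n - k + 1L):n]), k))
  }
  if (nrow(x$val_history) > 0L) {
    cat(sprintf("  best validation : PSNR %.3f dB at iteration %d\n",
                x$best_psnr, x$best_iter))
  }
  invisible(x)
}

#' @export
summary.sr_fit <- function(object, ...) {
  list(model = summary(object$model), history = object$history,
       val_history = object$val_history, best_iter = object$best_iter,
       best_psnr = object$best_psnr)
}

#' @export
predict.sr_fit <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' @export
coef.sr_fit <- function(object, ...) {
  coef(object$model)
}

#' Plot the training history
#'
#' Composite-loss trajectory (log scale) and, when validation records
#' exist, the validation PSNR curve.
#'
#' @param x An `sr_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sr_fit <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0L) {
    stop("no training history to plot (max_iters was 0)")
  }
  has_val <- nrow(x$val_history) > 0L
  if (has_val) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  graphics::plot(h$iter, h$total, type = "l", log = "y",
                 xlab = "iteration", ylab = "composite loss", ...)
  if (has_val) {
    graphics::plot(x$val_history$iter, x$val_history$psnr, type = "b",
                   xlab = "iteration", ylab = "validation PSNR (dB)")
  }
  invisible(x)
}
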