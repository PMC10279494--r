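#' @keywords internal
"_PACKAGE"

sigmoid <- function(x) 1 / (1 + exp(-x))

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so no function in the package leaks hidden global
#' state.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Construct a feature map
#'
#' Feature maps are dense rank-4 arrays indexed `(batch, channel, height,
#' width)`, the layout used throughout the network, attention and loss
#' code. `feature_map()` validates and tags a plain array; 2-D matrices
#' are promoted to a single-sample, single-channel map.
#'
#' @param x A numeric array with `dim` of length 4 (`B, C, H, W`), or a
#'   numeric matrix (`H, W`) promoted to shape `(1, 1, H, W)`.
#' @return The validated array (invisibly classed as a plain array; no
#'   attribute beyond `dim` is attached so arithmetic stays vanilla).
#' @examples
#' x <- feature_map(matrix(runif(16), 4, 4))
#' dim(x)  # 1 1 4 4
#' @export
feature_map <- function(x) {
  if (is.matrix(x)) {
    x <- array(x, dim = c(1L, 1L, nrow(x), ncol(x)))
  }
  if (!is.array(x) || length(dim(x)) != 4L) {
    stop("a feature map must be a rank-4 (batch, channel, height, width) array")
  }
  if (!all(is.finite(x))) stop("feature map entries must be finite")
  if (any(dim(x) < 1L)) stop("all feature map dimensions must be >= 1")
  storage.mode(x) <- "double"
  x
}

# Promote a 2-D image (H x W matrix in [0,1]) to a (1,1,H,W) batch.
as_batch <- function(img) {
  if (is.matrix(img)) array(img, dim = c(1L, 1L, nrow(img), ncol(img))) else img
}

# Collapse a (1,1,H,W) batch back to an H x W matrix.
as_image <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L, d[1] == 1L, d[2] == 1L)
  matrix(x, d[3], d[4])
}

# Stack a list of H x W matrices (equal shapes) into a (B,1,H,W) batch.
stack_images <- function(imgs) {
  H <- nrow(imgs[[1]]); W <- ncol(imgs[[1]])
  out <- array(0, dim = c(length(imgs), 1L, H, W))
  for (i in seq_along(imgs)) out[i, 1, , ] <- imgs[[i]]
  out
}

check_image <- function(img, arg = "image") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("%s must be a numeric H x W matrix", arg))
  }
  invisible(img)
}
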