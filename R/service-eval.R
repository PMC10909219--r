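# Standalone numerics of the registration-review pipeline: multi-scale
# valid 1-D convolution over the time axis, maximum-value wave-function
# eigenvalue correction, and a numerically stable softmax head. Forward
# passes only; no training is provided.

activation_fun <- function(activation = c("identity", "relu", "tanh")) {
  activation <- match.arg(activation)
  switch(activation,
    identity = function(z) z,
    relu = function(z) pmax(z, 0),
    tanh = tanh
  )
}

#' Multi-scale 1-D convolution over the time axis
#'
#' Applies `k` convolution kernels of different window sizes to an input of
#' shape `(n, t, d)` (samples, time steps, features). Each kernel performs a
#' valid (no-padding) convolution; with `h = max(h_i)` the per-kernel
#' outputs are truncated to the common length `t - h + 1` and concatenated
#' on the channel axis.
#'
#' @param x Numeric array `(n, t, d)`, or a `t x d` matrix (taken as one
#'   sample).
#' @param kernels List of kernels, each a list with `weights` (array
#'   `h x d x c`) and `bias` (length-`c` numeric).
#' @param activation Elementwise activation: `"identity"` (default),
#'   `"relu"` or `"tanh"`.
#' @return Array `(n, t - max(h) + 1, sum(c))`.
#' @export
multiscale_conv <- function(x, kernels, activation = "identity") {
  if (is.matrix(x)) x <- array(x, c(1L, nrow(x), ncol(x)))
  if (length(dim(x)) != 3L) abort_data("`x` must be an (n, t, d) array")
  n <- dim(x)[1]; t_len <- dim(x)[2]; d <- dim(x)[3]
  f <- activation_fun(activation)

  hs <- integer(length(kernels))
  cs <- integer(length(kernels))
  for (i in seq_along(kernels)) {
    W <- kernels[[i]]$weights
    if (is.matrix(W)) W <- array(W, c(dim(W), 1L))
    if (length(dim(W)) != 3L || dim(W)[2] != d) {
      abort_data(paste0("kernel ", i, ": weights must be an (h, d, c) array matching d = ", d))
    }
    if (any(!is.finite(W))) abort_data(paste0("kernel ", i, ": non-finite weights"))
    kernels[[i]]$weights <- W
    hs[i] <- dim(W)[1]
    cs[i] <- dim(W)[3]
    b <- kernels[[i]]$bias
    if (length(b) != cs[i]) {
      abort_data(paste0("kernel ", i, ": bias length must equal the channel count"))
    }
    if (hs[i] > t_len) {
      abort_data(paste0("kernel ", i, ": window ", hs[i],
                        " exceeds the time length ", t_len))
    }
  }
  L <- t_len - max(hs) + 1L
  out <- array(0, c(n, L, sum(cs)))
  ch0 <- 0L
  for (i in seq_along(kernels)) {
    W <- kernels[[i]]$weights
    b <- kernels[[i]]$bias
    h <- hs[i]
    for (cc in seq_len(cs[i])) {
      for (s in seq_len(L)) {
        # weighted sum over the window and all feature dimensions
        seg <- x[, s:(s + h - 1L), , drop = FALSE]
        wmat <- W[, , cc]
        out[, s, ch0 + cc] <- apply(seg, 1L, function(m) sum(m * wmat)) + b[cc]
      }
    }
    ch0 <- ch0 + cs[i]
  }
  f(out)
}

#' Maximum-value wave-function eigenvalue correction
#'
#' Corrects a feature vector elementwise by
#' `v' = v * exp(-sin(2 * pi * v / v_max))` with `v_max = max(v)`. Components
#' at `0`, `v_max / 2` and `v_max` are fixed points (the sine vanishes), and
#' the map is scale-equivariant: `wave_correct(c * v) = c * wave_correct(v)`
#' for `c > 0`, since only the ratio `v / v_max` enters the phase.
#'
#' @param v Numeric vector with `max(v) > 0`.
#' @return Corrected vector of the same length.
#' @export
#' @examples
#' wave_correct(c(0, 0.25, 0.5, 1))
wave_correct <- function(v) {
  if (length(v) == 0L || any(!is.finite(v))) {
    abort_data("`v` must be a non-empty finite numeric vector")
  }
  v_max <- max(v)
  if (v_max <= 0) {
    abort_numeric("wave correction requires max(v) > 0")
  }
  v * exp(-sin(2 * pi * v / v_max))
}

#' Softmax classification head
#'
#' Computes per-class probabilities `O_i = exp(W_i x + b_i) / sum_j
#' exp(W_j x + b_j)`, stabilized by subtracting the maximum logit before
#' exponentiation (a shift that leaves the probabilities unchanged). The
#' predicted class is the argmax, with ties resolved to the lowest class
#' index.
#'
#' @param x Feature vector (length `p`).
#' @param weights `k x p` class-weight matrix (`k >= 2`).
#' @param bias Length-`k` bias vector.
#' @return Probability vector of length `k` summing to 1, with attribute
#'   `class_index` holding the predicted class index.
#' @export
#' @examples
#' softmax_classify(1, matrix(c(log(3), 0), 2, 1), c(0, 0))
softmax_classify <- function(x, weights, bias) {
  if (is.null(dim(weights))) weights <- matrix(weights, ncol = length(x))
  k <- nrow(weights)
  if (k < 2L) abort_data("at least 2 classes are required")
  if (ncol(weights) != length(x) || length(bias) != k) {
    abort_data("dimensions of `x`, `weights` and `bias` are inconsistent")
  }
  logits <- as.vector(weights %*% x + bias)
  if (any(!is.finite(logits))) abort_numeric("non-finite logits")
  z <- exp(logits - max(logits))
  p <- z / sum(z)
  structure(p, class_index = which.max(p))
}
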