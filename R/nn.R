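# R-side surface of the convolutional engine: architecture descriptions,
# parameter initialisation, and thin wrappers over the compiled training and
# forward passes. Parameter order must match src/nn.cpp exactly:
# per encoder block: Wa ba gA betaA Wb bb gB betaB Wc bc gC betaC (12),
# then for encoders the dense head (Wfc, bfc); for U-Nets, per decoder stage
# Wt bt + one block (14), then the final 1x1 convolution (W, b).

encoder_arch <- function(tile, in_ch, widths, out_dim, head) {
  list(type = "encoder", tile = as.integer(tile), in_ch = as.integer(in_ch),
       widths = as.integer(widths), out_dim = as.integer(out_dim), head = head)
}

unet_arch <- function(tile, in_ch, widths) {
  list(type = "unet", tile = as.integer(tile), in_ch = as.integer(in_ch),
       widths = as.integer(widths), out_dim = 1L, head = "sigmoid_map")
}

# He-style initialisation; biases zero, BN gamma 1 / beta 0.
init_params <- function(arch, seed = 1L) {
  withr::with_seed(seed, init_params_impl(arch))
}

he_mat <- function(nout, nin) {
  matrix(rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin)
}

block_params <- function(cin, w) {
  list(he_mat(w, 9 * cin), matrix(0, w, 1), matrix(1, w, 1), matrix(0, w, 1),
       he_mat(w, 9 * w), matrix(0, w, 1), matrix(1, w, 1), matrix(0, w, 1),
       he_mat(w, 9 * w), matrix(0, w, 1), matrix(1, w, 1), matrix(0, w, 1))
}

init_params_impl <- function(arch) {
  widths <- arch$widths
  nb <- length(widths)
  params <- list()
  bn_dims <- integer()
  cin <- arch$in_ch
  for (b in seq_len(nb)) {
    params <- c(params, block_params(cin, widths[b]))
    bn_dims <- c(bn_dims, rep(widths[b], 3))
    cin <- widths[b]
  }
  if (arch$type == "encoder") {
    hw <- (arch$tile / 2^(nb - 1))^2
    params <- c(params, list(he_mat(arch$out_dim, widths[nb] * hw),
                             matrix(0, arch$out_dim, 1)))
  } else {
    for (s in seq(nb - 1, 1)) {
      w <- widths[s]
      cin_dec <- if (s == nb - 1) widths[nb] else widths[s + 1]
      params <- c(params, list(he_mat(4 * w, cin_dec), matrix(0, w, 1)))
      params <- c(params, block_params(2 * w, w))
      bn_dims <- c(bn_dims, rep(w, 3))
    }
    params <- c(params, list(he_mat(1, widths[1]), matrix(0, 1, 1)))
  }
  running <- list(mean = lapply(bn_dims, function(d) rep(0, d)),
                  var = lapply(bn_dims, function(d) rep(1, d)))
  list(params = params, running = running)
}

# generic trained-model container
new_conv_model <- function(arch, fit, config, split, class) {
  structure(list(arch = arch, params = fit$params, running = fit$running,
                 history = tibble::as_tibble(fit$history),
                 best_epoch = fit$best_epoch, best_val = fit$best_val,
                 config = config, split = split),
            class = c(class, "leaftrace_conv_model"))
}

#' @export
print.leaftrace_conv_model <- function(x, ...) {
  cat(sprintf("<%s: tile %d, widths %s, best val loss %.5g (epoch %d/%d)>\n",
              class(x)[1], x$arch$tile,
              paste(x$arch$widths, collapse = "-"),
              x$best_val, x$best_epoch, nrow(x$history)))
  invisible(x)
}

# eval-mode forward pass on a tile array (S, S, C, n)
model_forward <- function(model, tiles, batch = 64L) {
  if (length(dim(tiles)) == 3) dim(tiles) <- c(dim(tiles), 1L)
  cpp_forward(model$arch, model$params, model$running, tiles, as.integer(batch))
}

run_training <- function(arch, X, Y, Xval, Yval, loss_cfg, config,
                         validTr = NULL, validVa = NULL) {
  init <- init_params(arch, seed = config$seed)
  opts <- list(epochs = as.integer(config$epochs),
               batch = as.integer(config$batch),
               patience = as.integer(config$patience),
               lr = config$lr, seed = as.integer(config$seed),
               verbose = isTRUE(config$verbose))
  if (!is.null(config$decay_at)) {
    opts$decay_at <- as.integer(config$decay_at)
    opts$decay_factor <- config$decay_factor %||% 0.3
  }
  if (!is.null(config$train_augment)) {
    ta <- config$train_augment
    opts$aug <- list(flip = isTRUE(ta$flip),
                     jitter = as.integer(ta$jitter %||% 0),
                     color = ta$color %||% 0)
  }
  cpp_train(arch, init$params, init$running, X, Y, Xval, Yval,
            validTr, validVa, loss_cfg, opts)
}

#' Trace-loss weight profile
#'
#' Weights for the boundary tracer's weighted mean-squared-error objective:
#' `w_i = 1 + (1 - tanh(alpha * i + beta)) / 2` for `i = 1..N`. With the
#' defaults (`alpha = 8/N`, `beta = -4`) the weight decreases smoothly from
#' about 2 at the tile centre to about 1 at the tile edge, so displacement
#' errors near the centre of the tile count roughly twice.
#'
#' @param N number of predicted displacements (default 128).
#' @param alpha,beta shape parameters of the tanh ramp.
#' @return Numeric vector of length `N`, strictly decreasing, in `(1, 2)`.
#' @export
trace_weights <- function(N = 128, alpha = 8 / N, beta = -4) {
  if (N < 1) abort("N must be >= 1")
  i <- seq_len(N)
  1 + (1 - tanh(alpha * i + beta)) / 2
}

#' Weighted mean squared displacement error
#'
#' `(1/N) * sum_i w_i * ||y_i - yhat_i||^2` where each `y_i` is a
#' (row, col) displacement pair.
#'
#' @param pred,target `2 x N` matrices (row 1 = row displacement, row 2 =
#'   column displacement).
#' @param weights length-`N` weight vector, e.g. [trace_weights()].
#' @return Scalar loss.
#' @export
weighted_mse <- function(pred, target, weights) {
  if (!all(dim(pred) == dim(target))) abort("shape mismatch")
  N <- ncol(pred)
  if (length(weights) != N) abort("shape mismatch")
  d2 <- colSums((pred - target)^2)
  sum(weights * d2) / N
}

#' Focal loss for binary pixel classification
#'
#' `-alpha * (1-p)^gamma * log(p)` when `y = 1` and
#' `-(1-alpha) * p^gamma * log(1-p)` otherwise; probabilities are clamped to
#' `[1e-7, 1 - 1e-7]` before the logarithm. `mode = "bce"` gives plain binary
#' cross-entropy, which equals the focal form with `gamma = 0`, `alpha = 0.5`
#' rescaled by 2.
#'
#' @param p predicted foreground probabilities.
#' @param y ground-truth labels in `{0, 1}`.
#' @param alpha class-balance weight (default 0.25).
#' @param gamma focusing exponent (default 2).
#' @param mode `"focal"` or `"bce"`.
#' @return Per-element losses (same shape as `p`).
#' @export
focal_loss <- function(p, y, alpha = 0.25, gamma = 2, mode = c("focal", "bce")) {
  mode <- match.arg(mode)
  p <- pmin(1 - 1e-7, pmax(1e-7, p))
  if (mode == "bce") {
    return(-(y * log(p) + (1 - y) * log(1 - p)))
  }
  ifelse(y > 0.5,
         -alpha * (1 - p)^gamma * log(p),
         -(1 - alpha) * p^gamma * log(1 - p))
}
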