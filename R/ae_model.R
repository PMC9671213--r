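#' Architecture specification for the convolutional autoencoder
#'
#' The default architecture is an encoder / bottleneck / decoder stack of
#' six 1D convolutions (stride 1, same padding) with filter counts
#' (32, 64, 128, 64, 32, C): conv32 -> maxpool2 -> dropout0.2 -> conv64 ->
#' maxpool2 -> dropout0.2 -> conv128 (bottleneck) -> conv64 -> upsample2 ->
#' dropout0.2 -> conv32 -> upsample2 -> dropout0.2 -> convC with softmax
#' over channels. All kernels have width 5 and an L1 weight penalty of
#' 1e-4; hidden activations are ReLU. The SNP dimension must be divisible
#' by the pooling product (default 4) so pooling cancels upsampling and the
#' output length equals the input length.
#'
#' @param n_snps input length (number of SNPs).
#' @param n_channels 4 (diploid one-hot) or 3 (yeast/haploid one-hot).
#' @param filters filter counts of the five hidden convolutions (encoder,
#'   bottleneck, decoder); the sixth, output convolution always has
#'   `n_channels` filters.
#' @param kernel convolution kernel width (odd).
#' @param l1 L1 regularization factor applied to every convolution kernel.
#' @param pool_size max-pool and upsample factor.
#' @param dropout dropout rate.
#' @return A `model_spec` with an ordered `layers` list.
#' @export
model_spec <- function(n_snps, n_channels = 4L,
                       filters = c(32L, 64L, 128L, 64L, 32L),
                       kernel = 5L, l1 = 1e-4, pool_size = 2L,
                       dropout = 0.2) {
  if (!n_channels %in% c(3L, 4L)) abort("`n_channels` must be 3 or 4.")
  if (length(filters) != 5L || any(filters < 1L)) {
    abort("`filters` must be five positive counts.")
  }
  if (kernel < 1L || kernel %% 2L == 0L) abort("`kernel` must be odd and >= 1.")
  if (pool_size < 2L) abort("`pool_size` must be >= 2.")
  if (dropout < 0 || dropout >= 1) abort("`dropout` must lie in [0, 1).")
  conv <- function(f, act = "relu") {
    list(kind = "conv", filters = as.integer(f), kernel = as.integer(kernel),
         l1 = l1, activation = act)
  }
  pool <- list(kind = "maxpool", rate = as.integer(pool_size))
  up <- list(kind = "upsample", rate = as.integer(pool_size))
  drop <- list(kind = "dropout", rate = dropout)
  layers <- list(
    conv(filters[1]), pool, drop,
    conv(filters[2]), pool, drop,
    conv(filters[3]),            # bottleneck
    conv(filters[4]), up, drop,
    conv(filters[5]), up, drop,
    conv(n_channels, act = "softmax")
  )
  pool_product <- prod(vapply(layers, function(l)
    if (l$kind == "maxpool") l$rate else 1L, numeric(1)))
  if (n_snps %% pool_product != 0L) {
    abort(sprintf(paste0(
      "`n_snps` (%d) must be divisible by the pooling product (%d); ",
      "use `truncate_to_multiple()` first."), n_snps, pool_product))
  }
  structure(
    list(n_snps = as.integer(n_snps), n_channels = as.integer(n_channels),
         layers = layers, pool_product = as.integer(pool_product)),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> input %d SNPs x %d channels\n",
              x$n_snps, x$n_channels))
  for (l in x$layers) {
    cat("  ", switch(l$kind,
      conv = sprintf("conv(filters=%d, kernel=%d, l1=%g, %s)",
                     l$filters, l$kernel, l$l1, l$activation),
      maxpool = sprintf("maxpool(%d)", l$rate),
      upsample = sprintf("upsample(%d)", l$rate),
      dropout = sprintf("dropout(%.2f)", l$rate)
    ), "\n", sep = "")
  }
  invisible(x)
}

#' Build (initialize) an autoencoder model
#'
#' Allocates convolution weights with seeded Glorot-uniform initialization
#' (limit sqrt(6 / (fan_in + fan_out))) and zero biases.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed for weight initialization.
#' @return An `ae_model` holding the spec and a per-layer parameter list.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  set.seed(seed)
  c_in <- spec$n_channels
  params <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    if (l$kind == "conv") {
      fan_in <- l$kernel * c_in
      fan_out <- l$kernel * l$filters
      lim <- sqrt(6 / (fan_in + fan_out))
      W <- array(runif(l$kernel * c_in * l$filters, -lim, lim),
                 c(l$kernel, c_in, l$filters))
      params[[i]] <- list(W = W, b = numeric(l$filters))
      c_in <- l$filters
    }
  }
  structure(list(spec = spec, params = params, init_seed = as.integer(seed)),
            class = "ae_model")
}

#' @export
print.ae_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, function(p)
    if (is.null(p)) 0L else length(p$W) + length(p$b), integer(1)))
  cat(sprintf("<ae_model> %d parameters, input %d SNPs x %d channels\n",
              n_par, x$spec$n_snps, x$spec$n_channels))
  invisible(x)
}

# full forward pass; caches intermediates when `collect_cache` for backprop.
# dropout consumes the current RNG stream only when `training` is TRUE.
model_forward <- function(model, x, training = FALSE, collect_cache = FALSE) {
  spec <- model$spec
  caches <- if (collect_cache) vector("list", length(spec$layers)) else NULL
  h <- x
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    if (l$kind == "conv") {
      cf <- conv1d_forward(h, model$params[[i]]$W, model$params[[i]]$b)
      z <- cf$out
      if (l$activation == "relu") {
        a <- relu_forward(z)
        if (collect_cache) {
          caches[[i]] <- list(Xcol = cf$Xcol, in_dim = dim(h), relu_keep = z > 0)
        }
        h <- a
      } else {                    # softmax output layer
        p <- softmax_channels(z)
        if (collect_cache) caches[[i]] <- list(Xcol = cf$Xcol, in_dim = dim(h))
        h <- p
      }
    } else if (l$kind == "maxpool") {
      mf <- maxpool_forward(h, l$rate)
      if (collect_cache) caches[[i]] <- mf[c("which_off", "in_dim")]
      h <- mf$out
    } else if (l$kind == "upsample") {
      h <- upsample_forward(h, l$rate)
    } else if (l$kind == "dropout") {
      if (training) {
        df <- dropout_forward(h, l$rate)
        if (collect_cache) caches[[i]] <- list(keep = df$keep)
        h <- df$out
      }
    }
  }
  list(out = h, caches = caches)
}

# backward pass from the gradient wrt the final conv's PRE-softmax logits
# (the softmax Jacobian is folded into the cross-entropy gradient by the
# caller). Returns per-layer gradients aligned with model$params; L1 is NOT
# included here.
model_backward <- function(model, caches, d_logits, training = TRUE) {
  spec <- model$spec
  grads <- vector("list", length(spec$layers))
  d <- d_logits
  for (i in rev(seq_along(spec$layers))) {
    l <- spec$layers[[i]]
    if (l$kind == "conv") {
      if (l$activation == "relu") d <- d * caches[[i]]$relu_keep
      bk <- conv1d_backward(d, caches[[i]]$Xcol, model$params[[i]]$W,
                            caches[[i]]$in_dim)
      grads[[i]] <- list(dW = bk$dW, db = bk$db)
      d <- bk$dx
    } else if (l$kind == "maxpool") {
      d <- maxpool_backward(d, caches[[i]], l$rate)
    } else if (l$kind == "upsample") {
      d <- upsample_backward(d, l$rate)
    } else if (l$kind == "dropout") {
      if (training) d <- dropout_backward(d, caches[[i]]$keep, l$rate)
    }
  }
  grads
}

#' Forward pass of the autoencoder
#'
#' Runs the encoder-decoder on a one-hot batch and returns per-position
#' channel posteriors (softmax output, so each (sample, SNP) vector sums to
#' one). Dropout is active only in training mode; inference is
#' deterministic given the weights.
#'
#' @param model an [build_model()] result.
#' @param batch an `encoded_tensor` (samples x SNPs x channels).
#' @param training logical; activates dropout (consumes the RNG stream).
#' @return A `posterior_tensor`.
#' @export
forward <- function(model, batch, training = FALSE) {
  stopifnot(inherits(model, "ae_model"))
  d <- dim(batch)
  if (length(d) != 3L || d[3] != model$spec$n_channels) {
    abort(sprintf("Batch channel count (%d) does not match the model (%d).",
                  if (length(d) == 3L) d[3] else -1L, model$spec$n_channels))
  }
  if (d[2] != model$spec$n_snps) {
    abort(sprintf("Batch SNP dimension (%d) does not match the model (%d).",
                  d[2], model$spec$n_snps))
  }
  ploidy <- attr(batch, "ploidy") %||%
    if (model$spec$n_channels == 4L) "diploid" else "haploid"
  out <- model_forward(model, unclass(batch), training = training)$out
  new_posterior_tensor(out, ploidy)
}

#' Categorical cross-entropy reconstruction loss
#'
#' Mean over the N = samples x SNPs positions of the cross-entropy between
#' the one-hot target and the predicted channel posterior, with the
#' prediction clamped below at `eps` before the log. A perfect point-mass
#' prediction scores (numerically) zero.
#'
#' @param x one-hot target tensor (samples x SNPs x channels).
#' @param xhat predicted posterior tensor of the same shape.
#' @param eps log clamp, default 1e-7.
#' @return Non-negative scalar loss.
#' @export
cce_loss <- function(x, xhat, eps = 1e-7) {
  if (!identical(dim(x), dim(xhat))) abort("`x` and `xhat` shapes differ.")
  if (anyNA(x) || anyNA(xhat)) abort("NaN/NA in loss inputs.")
  n_pos <- dim(x)[1] * dim(x)[2]
  -sum(x * log(pmax(xhat, eps))) / n_pos
}

# analytic gradient of cce_loss wrt xhat (zero inside the clamp region)
cce_loss_grad <- function(x, xhat, eps = 1e-7) {
  n_pos <- dim(x)[1] * dim(x)[2]
  g <- -(x / pmax(xhat, eps)) / n_pos
  g[xhat < eps] <- 0
  g
}

#' Weighted training loss
#'
#' `alpha * cce_loss(x, xhat)`, plus the model's L1 kernel penalty when a
#' model is supplied (as it is during training).
#'
#' @param x one-hot target tensor.
#' @param xhat predicted posterior tensor.
#' @param alpha positive loss weight (default 1).
#' @param model optional `ae_model` whose L1 penalty is added.
#' @return Scalar loss.
#' @export
weighted_loss <- function(x, xhat, alpha = 1, model = NULL) {
  if (alpha <= 0) abort("`alpha` must be positive.")
  alpha * cce_loss(x, xhat) + if (is.null(model)) 0 else l1_penalty(model)
}

#' L1 kernel penalty of a model
#'
#' Sum over convolution layers of `l1 * sum(abs(W))`; biases are excluded.
#'
#' @param model an `ae_model`.
#' @return Non-negative scalar.
#' @export
l1_penalty <- function(model) {
  total <- 0
  for (i in seq_along(model$spec$layers)) {
    l <- model$spec$layers[[i]]
    if (l$kind == "conv") total <- total + l$l1 * sum(abs(model$params[[i]]$W))
  }
  total
}
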