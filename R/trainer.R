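#' Training configuration
#'
#' Defaults follow the model's standard hyperparameters: 100 epochs, batch
#' size 32, Adam with initial learning rate 0.001, loss weight `alpha = 1`.
#' `loss_mode = "per_batch"` takes one optimizer step on every mini-batch's
#' own loss (the customized training loop); `"averaged_k"` accumulates the
#' mean-loss gradient over `k` consecutive batches before stepping (the
#' baseline it is contrasted with, default `k = 2`).
#'
#' @param epochs number of passes over the training data.
#' @param batch_size mini-batch size.
#' @param learning_rate Adam initial learning rate.
#' @param alpha positive weight of the cross-entropy term.
#' @param loss_mode `"per_batch"` or `"averaged_k"`.
#' @param k batch-accumulation count for `"averaged_k"`.
#' @param seed integer seed driving shuffling and dropout.
#' @return A `training_config` list.
#' @export
training_config <- function(epochs = 100L, batch_size = 32L,
                            learning_rate = 0.001, alpha = 1,
                            loss_mode = c("per_batch", "averaged_k"),
                            k = 2L, seed = 1L) {
  loss_mode <- match.arg(loss_mode)
  if (epochs < 1L || batch_size < 1L || k < 1L) {
    abort("`epochs`, `batch_size` and `k` must be positive counts.")
  }
  if (learning_rate <= 0) abort("`learning_rate` must be positive.")
  if (alpha <= 0) abort("`alpha` must be positive.")
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, alpha = alpha, loss_mode = loss_mode,
         k = as.integer(k), seed = as.integer(seed)),
    class = "training_config"
  )
}

adam_init <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) NULL
    else list(mW = array(0, dim(p$W)), vW = array(0, dim(p$W)),
              mb = numeric(length(p$b)), vb = numeric(length(p$b)))
  })
}

adam_step <- function(params, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (i in seq_along(params)) {
    if (is.null(params[[i]])) next
    g <- grads[[i]]
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    params[[i]]$W <- params[[i]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    params[[i]]$b <- params[[i]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[i]] <- s
  }
  list(params = params, state = state)
}

# L1 subgradient of the kernel penalty, added to accumulated data gradients
add_l1_grads <- function(grads, model) {
  for (i in seq_along(model$spec$layers)) {
    l <- model$spec$layers[[i]]
    if (l$kind == "conv") {
      grads[[i]]$dW <- grads[[i]]$dW + l$l1 * sign(model$params[[i]]$W)
    }
  }
  grads
}

#' Train the denoising autoencoder
#'
#' Inputs are the masked one-hot encodings, targets the unmasked encodings
#' of the same samples (denoising convention). In `per_batch` mode the
#' optimizer steps immediately on each mini-batch's weighted loss plus L1
#' penalty; in `averaged_k` mode gradients of the mean loss over `k`
#' consecutive batches are accumulated before each step, so `k = 1`
#' reproduces `per_batch` exactly. Each epoch records the mean training
#' batch objective, full-pass training accuracy, validation loss and
#' accuracy (inference mode, dropout off), and wall time. All stochasticity
#' (shuffling, dropout) is driven by `config$seed`.
#'
#' @param model an initialized [build_model()] model.
#' @param train_input,train_target `encoded_tensor`s of the training split.
#' @param val_input,val_target optional validation tensors.
#' @param config a [training_config()].
#' @return An `ae_fit`: list with the trained `model` and `history` tibble.
#' @export
train <- function(model, train_input, train_target,
                  val_input = NULL, val_target = NULL,
                  config = training_config()) {
  stopifnot(inherits(model, "ae_model"))
  if (!identical(dim(train_input), dim(train_target))) {
    abort("Training input and target shapes differ.")
  }
  n <- dim(train_input)[1]
  k_eff <- if (config$loss_mode == "per_batch") 1L else config$k
  x_in <- unclass(train_input)
  x_tg <- unclass(train_target)
  n_pos_batch <- function(nb) nb * model$spec$n_snps
  state <- adam_init(model$params)
  t_step <- 0L
  history <- vector("list", config$epochs)
  set.seed(config$seed)
  for (epoch in seq_len(config$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    batch_losses <- numeric(length(starts))
    acc_grads <- NULL
    acc_count <- 0L
    for (bi in seq_along(starts)) {
      idx <- perm[starts[bi]:min(starts[bi] + config$batch_size - 1L, n)]
      xb <- x_in[idx, , , drop = FALSE]
      tb <- x_tg[idx, , , drop = FALSE]
      fw <- model_forward(model, xb, training = TRUE, collect_cache = TRUE)
      p <- fw$out
      data_loss <- config$alpha * cce_loss(tb, p)
      obj <- data_loss + l1_penalty(model)
      if (!is.finite(obj)) {
        abort(sprintf("Non-finite loss %g at epoch %d, batch %d.",
                      obj, epoch, bi))
      }
      batch_losses[bi] <- obj
      # softmax + CCE gradient wrt logits, scaled by alpha
      d_logits <- config$alpha * (p - tb) / n_pos_batch(length(idx))
      g <- model_backward(model, fw$caches, d_logits)
      if (is.null(acc_grads)) {
        acc_grads <- g
      } else {
        for (i in seq_along(g)) {
          if (is.null(g[[i]])) next
          acc_grads[[i]]$dW <- acc_grads[[i]]$dW + g[[i]]$dW
          acc_grads[[i]]$db <- acc_grads[[i]]$db + g[[i]]$db
        }
      }
      acc_count <- acc_count + 1L
      if (acc_count == k_eff || bi == length(starts)) {
        if (acc_count > 1L) {
          for (i in seq_along(acc_grads)) {
            if (is.null(acc_grads[[i]])) next
            acc_grads[[i]]$dW <- acc_grads[[i]]$dW / acc_count
            acc_grads[[i]]$db <- acc_grads[[i]]$db / acc_count
          }
        }
        acc_grads <- add_l1_grads(acc_grads, model)
        t_step <- t_step + 1L
        upd <- adam_step(model$params, acc_grads, state, t_step,
                         config$learning_rate)
        model$params <- upd$params
        state <- upd$state
        acc_grads <- NULL
        acc_count <- 0L
      }
    }
    train_eval <- evaluate_loss_accuracy(model, train_input, train_target,
                                         config$alpha)
    val_eval <- if (!is.null(val_input)) {
      evaluate_loss_accuracy(model, val_input, val_target, config$alpha)
    } else {
      list(loss = NA_real_, accuracy = NA_real_)
    }
    history[[epoch]] <- tibble(
      epoch = epoch,
      train_loss = mean(batch_losses),
      train_accuracy = train_eval$accuracy,
      val_loss = val_eval$loss,
      val_accuracy = val_eval$accuracy,
      seconds = proc.time()[["elapsed"]] - t0
    )
  }
  structure(list(model = model, history = dplyr::bind_rows(history),
                 config = config),
            class = "ae_fit")
}

#' @export
print.ae_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<ae_fit> %d epochs (%s): final train loss %.4f, train acc %.4f%s\n",
    nrow(x$history), x$config$loss_mode, last$train_loss, last$train_accuracy,
    if (is.finite(last$val_accuracy)) {
      sprintf(", val acc %.4f", last$val_accuracy)
    } else ""
  ))
  invisible(x)
}

#' @export
tidy.ae_fit <- function(x, ...) x$history

#' @export
glance.ae_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble(
    epochs = nrow(x$history), loss_mode = x$config$loss_mode,
    final_train_loss = last$train_loss,
    final_train_accuracy = last$train_accuracy,
    final_val_loss = last$val_loss, final_val_accuracy = last$val_accuracy
  )
}

# chunked inference pass returning loss (incl. L1) and hard-call accuracy
evaluate_loss_accuracy <- function(model, input, target, alpha = 1,
                                   chunk = 512L) {
  n <- dim(input)[1]
  total_ce <- 0
  n_match <- 0
  n_eval <- 0
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    xb <- unclass(input)[idx, , , drop = FALSE]
    tb <- unclass(target)[idx, , , drop = FALSE]
    p <- model_forward(model, xb, training = FALSE)$out
    total_ce <- total_ce + cce_loss(tb, p) * length(idx)
    cls_true <- apply_argmax(tb)
    cls_pred <- apply_argmax_excluding_missing(p)
    ok <- cls_true != 1L              # positions with a real target class
    n_match <- n_match + sum(cls_pred[ok] == cls_true[ok])
    n_eval <- n_eval + sum(ok)
  }
  list(loss = alpha * total_ce / n + l1_penalty(model),
       accuracy = if (n_eval > 0) n_match / n_eval else NA_real_)
}

apply_argmax <- function(x) {
  d <- dim(x)
  max.col(matrix(x, d[1] * d[2], d[3]), ties.method = "first")
}

apply_argmax_excluding_missing <- function(x) {
  d <- dim(x)
  M <- matrix(x, d[1] * d[2], d[3])[, -1L, drop = FALSE]
  max.col(M, ties.method = "first") + 1L
}

#' Hard-call reconstruction accuracy of a model
#'
#' Fraction of sample x SNP positions where the decoded call from a
#' deterministic forward pass matches the target's class. Positions whose
#' target is the missing channel (no ground truth) are excluded.
#'
#' @param model an `ae_model` (or `ae_fit`).
#' @param input an `encoded_tensor` of (possibly masked) inputs.
#' @param target the unmasked one-hot `encoded_tensor`.
#' @return Accuracy in \[0, 1\].
#' @export
evaluate_accuracy <- function(model, input, target) {
  if (inherits(model, "ae_fit")) model <- model$model
  evaluate_loss_accuracy(model, input, target)$accuracy
}

#' Impute missing genotypes with a trained model
#'
#' Encodes the matrix, runs a deterministic forward pass, and returns hard
#' calls, the full posterior and (diploid mode) the dosage matrix. With
#' `preserve_observed = TRUE` (default) observed genotypes are copied
#' through unchanged and only missing entries are filled from the model.
#'
#' @param model an `ae_model` or `ae_fit`.
#' @param matrix a [genotype_matrix()] whose SNP count matches the model.
#' @param preserve_observed copy observed genotypes through (default TRUE).
#' @return List with `calls` ([genotype_matrix()]), `posterior`
#'   (`posterior_tensor`) and `dosage` (matrix, diploid only).
#' @export
impute <- function(model, matrix, preserve_observed = TRUE) {
  if (inherits(model, "ae_fit")) model <- model$model
  stopifnot(inherits(model, "ae_model"), inherits(matrix, "genotype_matrix"))
  if (ncol(matrix) != model$spec$n_snps) {
    abort(sprintf(paste0(
      "Matrix has %d SNPs but the model expects %d; ",
      "use `truncate_to_multiple()` to match."),
      ncol(matrix), model$spec$n_snps))
  }
  enc <- encode_onehot(matrix)
  n <- dim(enc)[1]
  chunks <- split(seq_len(n), ceiling(seq_len(n) / 512L))
  outs <- lapply(chunks, function(idx) {
    model_forward(model, unclass(enc)[idx, , , drop = FALSE],
                  training = FALSE)$out
  })
  probs <- array(0, c(n, model$spec$n_snps, model$spec$n_channels))
  for (ci in seq_along(chunks)) probs[chunks[[ci]], , ] <- outs[[ci]]
  posterior <- new_posterior_tensor(probs, gt_ploidy(matrix))
  calls <- decode_calls(posterior, variant_meta = variant_meta(matrix),
                        sample_ids = sample_ids(matrix))
  if (preserve_observed) {
    v <- unclass(calls)
    obs <- !is.na(unclass(matrix))
    v[obs] <- unclass(matrix)[obs]
    calls <- gt_replace(calls, v)
  }
  dose <- if (gt_ploidy(matrix) == "diploid") dosage(posterior) else NULL
  list(calls = calls, posterior = posterior, dosage = dose)
}
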