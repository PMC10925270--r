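#' Train a GSNN by minibatch Adam on mean squared error
#'
#' Trains the model on encoded inputs/targets, tracking validation
#' mean-Pearson when validation data are supplied; the parameters achieving
#' the best validation score are restored at the end (early stopping with
#' `patience` epochs). Test data are never consulted here.
#'
#' @param g a `structural_graph`
#' @param x,y training input and target matrices (observations x input nodes
#'   / output nodes), e.g. from [encode_observations()]
#' @param cfg a [gsnn_config()]
#' @param x_val,y_val optional validation matrices
#' @param epochs maximum training epochs
#' @param batch_size minibatch size (the memory profile of the edge-state
#'   representation favors small batches)
#' @param lr Adam learning rate
#' @param patience early-stopping patience in epochs (ignored without
#'   validation data)
#' @param seed seed for shuffling and dropout
#' @param verbose print per-epoch losses
#' @return a `gsnn_fit` (also a `gsnn_model`) with elements `history`
#'   (tibble: epoch, train_mse, val_pearson) and `best_val_pearson`
#' @export
gsnn_fit <- function(g, x, y, cfg = gsnn_config(), x_val = NULL, y_val = NULL,
                     epochs = 50, batch_size = 32, lr = 1e-2, patience = 10,
                     seed = cfg$seed, verbose = FALSE) {
  model <- gsnn_model(g, cfg)
  assert_that_(nrow(x) == nrow(y), "x and y must have the same rows")
  opt <- adam_state(model$params)
  n <- nrow(x)
  history <- vector("list", epochs)
  best <- list(score = -Inf, params = model$params, epoch = 0L)
  wait <- 0L
  with_seed_(derive_seed(seed, "train"), {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      batches <- split(perm, ceiling(seq_along(perm) / batch_size))
      ep_loss <- 0
      for (bi in batches) {
        fwd <- gsnn_forward(model, x[bi, , drop = FALSE], training = TRUE,
                            keep_cache = TRUE)
        err <- fwd$pred - y[bi, , drop = FALSE]
        loss <- mean(err^2)
        if (!is.finite(loss)) abort("non-finite training loss")
        ep_loss <- ep_loss + loss * length(bi)
        dpred <- 2 * err / length(err)
        bk <- gsnn_backward(model, fwd, dpred)
        upd <- adam_step(model$params, bk$param_grads, opt, lr = lr)
        model$params <- upd$params
        opt <- upd$state
      }
      ep_loss <- ep_loss / n
      val_p <- NA_real_
      if (!is.null(x_val)) {
        val_pred <- gsnn_forward(model, x_val)$pred
        val_p <- mean_pearson(val_pred, y_val)$mean_pearson
        if (is.finite(val_p) && val_p > best$score) {
          best <- list(score = val_p, params = model$params, epoch = ep)
          wait <- 0L
        } else {
          wait <- wait + 1L
        }
      }
      history[[ep]] <- tibble(epoch = ep, train_mse = ep_loss,
                              val_pearson = val_p)
      if (verbose) {
        inform(sprintf("epoch %3d  train mse %.5f  val pearson %s",
                       ep, ep_loss,
                       ifelse(is.na(val_p), "-", sprintf("%.3f", val_p))))
      }
      if (!is.null(x_val) && wait >= patience) break
    }
  })
  if (!is.null(x_val) && is.finite(best$score)) {
    model$params <- best$params
  }
  model$history <- bind_rows(history)
  model$best_val_pearson <- if (is.null(x_val)) NA_real_ else best$score
  class(model) <- c("gsnn_fit", class(model))
  model
}

#' @export
print.gsnn_fit <- function(x, ...) {
  NextMethod()
  h <- x$history
  cat(sprintf("  trained %d epochs, final train mse %.5f, best val pearson %s\n",
              nrow(h), h$train_mse[nrow(h)],
              ifelse(is.na(x$best_val_pearson), "-",
                     sprintf("%.3f", x$best_val_pearson))))
  invisible(x)
}

#' @method tidy gsnn_fit
#' @export
tidy.gsnn_fit <- function(x, ...) {
  x$history
}

#' @method glance gsnn_fit
#' @export
glance.gsnn_fit <- function(x, ...) {
  h <- x$history
  tibble(
    epochs = nrow(h),
    train_mse = h$train_mse[nrow(h)],
    best_val_pearson = x$best_val_pearson,
    n_parameters = realized_parameter_count(x$params)
  )
}

#' Plot GSNN training history
#'
#' @param object a `gsnn_fit`
#' @param ... ignored
#' @return a ggplot of train MSE and validation mean-Pearson per epoch
#' @method autoplot gsnn_fit
#' @export
autoplot.gsnn_fit <- function(object, ...) {
  h <- object$history |>
    tidyr::pivot_longer(c("train_mse", "val_pearson"),
                        names_to = "metric", values_to = "value") |>
    filter(is.finite(.data$value))
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "epoch", y = NULL)
}
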