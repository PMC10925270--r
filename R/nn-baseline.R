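#' Fully connected baseline regressor
#'
#' A two-layer neural network (linear -> batch norm -> ELU -> linear) trained
#' by minibatch Adam on mean squared error, serving as the unconstrained
#' baseline for the graph-structured model. The *cell-agnostic* variant is
#' obtained by encoding the data with `cell_agnostic = TRUE` (all non-drug
#' input positions zeroed), which reduces the model to predicting each drug's
#' average response across cell lines.
#'
#' @param x,y training matrices (observations x inputs / outputs)
#' @param hidden hidden width
#' @param x_val,y_val optional validation matrices for early stopping by
#'   mean-Pearson
#' @param epochs,batch_size,lr,patience optimizer settings
#' @param seed seed for initialization, shuffling
#' @param verbose print per-epoch losses
#' @return a `baseline_nn` fit with `history` and `best_val_pearson`
#' @export
train_baseline_nn <- function(x, y, hidden = 64, x_val = NULL, y_val = NULL,
                              epochs = 100, batch_size = 32, lr = 1e-2,
                              patience = 10, seed = 1, verbose = FALSE) {
  n_in <- ncol(x)
  n_out <- ncol(y)
  bn_eps <- 1e-5
  with_seed_(derive_seed(seed, "nn-init"), {
    params <- list(
      W1 = matrix(rnorm(hidden * n_in, 0, sqrt(2 / n_in)), hidden, n_in),
      b1 = numeric(hidden),
      g = rep(1, hidden), s = numeric(hidden),
      W2 = matrix(rnorm(n_out * hidden, 0, sqrt(2 / hidden)), n_out, hidden),
      b2 = numeric(n_out)
    )
  })
  run_mu <- numeric(hidden)
  run_var <- rep(1, hidden)
  momentum <- 0.9

  fwd <- function(p, xb, training) {
    z <- p$W1 %*% t(xb) + p$b1                 # hidden x B
    if (training) {
      mu <- rowMeans(z)
      zc <- z - mu
      v <- rowMeans(zc^2)
      run_mu <<- momentum * run_mu + (1 - momentum) * mu
      run_var <<- momentum * run_var + (1 - momentum) * v
    } else {
      mu <- run_mu
      zc <- z - mu
      v <- run_var
    }
    sdinv <- 1 / sqrt(v + bn_eps)
    zhat <- zc * sdinv
    zn <- zhat * p$g + p$s
    a <- elu(zn)
    pred <- t(p$W2 %*% a + p$b2)
    list(pred = pred, z = z, zhat = zhat, zn = zn, a = a, sdinv = sdinv)
  }
  bwd <- function(p, xb, f, dpred) {
    doutT <- t(dpred)                          # n_out x B
    gW2 <- doutT %*% t(f$a)
    gb2 <- rowSums(doutT)
    da <- crossprod(p$W2, doutT)
    dzn <- da * elu_grad(f$zn)
    gg <- rowSums(dzn * f$zhat)
    gs <- rowSums(dzn)
    dzhat <- dzn * p$g
    # batch-norm backward (per hidden unit, statistics over the batch)
    m1 <- rowMeans(dzhat)
    m2 <- rowMeans(dzhat * f$zhat)
    dz <- f$sdinv * (dzhat - m1 - f$zhat * m2)
    gW1 <- dz %*% xb
    gb1 <- rowSums(dz)
    list(W1 = gW1, b1 = gb1, g = gg, s = gs, W2 = gW2, b2 = gb2)
  }

  opt <- adam_state(params)
  n <- nrow(x)
  history <- vector("list", epochs)
  best <- list(score = -Inf, params = params, run_mu = run_mu,
               run_var = run_var)
  wait <- 0L
  with_seed_(derive_seed(seed, "nn-train"), {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      batches <- split(perm, ceiling(seq_along(perm) / batch_size))
      ep_loss <- 0
      for (bi in batches) {
        if (length(bi) < 2) next  # batch norm needs batch statistics
        xb <- x[bi, , drop = FALSE]
        f <- fwd(params, xb, training = TRUE)
        err <- f$pred - y[bi, , drop = FALSE]
        loss <- mean(err^2)
        if (!is.finite(loss)) abort("non-finite baseline-NN loss")
        ep_loss <- ep_loss + loss * length(bi)
        grads <- bwd(params, xb, f, 2 * err / length(err))
        upd <- adam_step(params, grads, opt, lr = lr)
        params <- upd$params
        opt <- upd$state
      }
      ep_loss <- ep_loss / n
      val_p <- NA_real_
      if (!is.null(x_val)) {
        val_p <- mean_pearson(fwd(params, x_val, FALSE)$pred, y_val)$mean_pearson
        if (is.finite(val_p) && val_p > best$score) {
          best <- list(score = val_p, params = params, run_mu = run_mu,
                       run_var = run_var)
          wait <- 0L
        } else wait <- wait + 1L
      }
      history[[ep]] <- tibble(epoch = ep, train_mse = ep_loss,
                              val_pearson = val_p)
      if (verbose) inform(sprintf("nn epoch %3d mse %.5f", ep, ep_loss))
      if (!is.null(x_val) && wait >= patience) break
    }
  })
  if (!is.null(x_val) && is.finite(best$score)) {
    params <- best$params
    run_mu <- best$run_mu
    run_var <- best$run_var
  }
  structure(list(params = params, run_mu = run_mu, run_var = run_var,
                 bn_eps = bn_eps, hidden = hidden,
                 history = bind_rows(history),
                 best_val_pearson = if (is.null(x_val)) NA_real_ else best$score),
            class = "baseline_nn")
}

#' @export
predict.baseline_nn <- function(object, x, ...) {
  p <- object$params
  z <- p$W1 %*% t(x) + p$b1
  zhat <- (z - object$run_mu) / sqrt(object$run_var + object$bn_eps)
  a <- elu(zhat * p$g + p$s)
  t(p$W2 %*% a + p$b2)
}

#' @export
print.baseline_nn <- function(x, ...) {
  cat(sprintf("<baseline_nn> hidden %d, trained %d epochs\n",
              x$hidden, nrow(x$history)))
  invisible(x)
}

#' @method glance baseline_nn
#' @export
glance.baseline_nn <- function(x, ...) {
  h <- x$history
  tibble(epochs = nrow(h), train_mse = h$train_mse[nrow(h)],
         best_val_pearson = x$best_val_pearson)
}
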