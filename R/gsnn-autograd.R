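# Reverse-mode gradients for the GSNN forward pass.
#
# The forward caches per-node intermediates (gather, pre-norm, normalized,
# activated, dropped); backward walks layers in reverse, undoing the residual
# add, the optional mask/baseline mixing, and each node's
# scatter <- W2 <- dropout <- activation <- layer-norm <- W1 <- gather chain.
# Because every edge has exactly one target node, gathers are disjoint across
# nodes and gradients never collide except through the residual path.

zero_like <- function(x) {
  if (is.list(x)) map(x, zero_like) else x * 0
}

# dpred: B x n_outputs gradient of the loss wrt predictions.
# Returns list(param_grads, input_grads (B x n_inputs), mask_grads (E x B)).
gsnn_backward <- function(model, fwd, dpred,
                          want_params = TRUE, want_input = FALSE,
                          want_mask = FALSE, masks = NULL,
                          baseline_states = NULL) {
  cfg <- model$config
  act <- activation_fun(cfg$activation)
  E <- nrow(model$graph$edges)
  B <- nrow(dpred)
  dstate <- matrix(0, E, B)
  dstate[model$out_edge_idx, ] <- t(dpred)
  pgrads <- if (want_params) zero_like(model$params) else NULL
  mgrads <- if (want_mask) matrix(0, E, B) else NULL

  for (l in rev(seq_len(cfg$layers))) {
    if (!is.null(masks)) {
      if (want_mask) {
        mgrads <- mgrads + (fwd$premix[[l]] - baseline_states[[l]]) * dstate
      }
      dstate <- masks * dstate
    }
    W <- layer_weights(model, l)
    wl <- if (cfg$share_layer_params) 1L else l
    nrm <- if (cfg$norm == "layer") model$params$norms[[l]] else NULL
    dprev <- dstate
    for (k in seq_along(model$blocks)) {
      b <- model$blocks[[k]]
      if (b$d_out == 0) next
      cch <- fwd$caches[[l]][[k]]
      dout <- dstate[b$idx_out, , drop = FALSE]
      if (all(dout == 0)) next
      if (want_params) {
        pgrads$weights[[wl]][[k]]$W2 <-
          pgrads$weights[[wl]][[k]]$W2 + dout %*% t(cch$ad)
        pgrads$weights[[wl]][[k]]$b2 <-
          pgrads$weights[[wl]][[k]]$b2 + rowSums(dout)
      }
      dad <- crossprod(W[[k]]$W2, dout)
      da <- if (!is.null(cch$dmask)) dad * cch$dmask else dad
      dzn <- da * act$grad(cch$zn)
      if (!is.null(nrm)) {
        if (want_params) {
          pgrads$norms[[l]][[k]]$g <-
            pgrads$norms[[l]][[k]]$g + rowSums(dzn * cch$zhat)
          pgrads$norms[[l]][[k]]$s <-
            pgrads$norms[[l]][[k]]$s + rowSums(dzn)
        }
        dzhat <- dzn * nrm[[k]]$g
        m1 <- colMeans(dzhat)
        m2 <- colMeans(dzhat * cch$zhat)
        dz <- sweep(sweep(dzhat, 2, m1) - sweep(cch$zhat, 2, m2, `*`),
                    2, cch$sdinv, `*`)
      } else {
        dz <- dzn
      }
      if (want_params) {
        pgrads$weights[[wl]][[k]]$b1 <-
          pgrads$weights[[wl]][[k]]$b1 + rowSums(dz)
      }
      if (b$d_in > 0) {
        if (want_params) {
          pgrads$weights[[wl]][[k]]$W1 <-
            pgrads$weights[[wl]][[k]]$W1 + dz %*% t(cch$inp)
        }
        dprev[b$idx_in, ] <- dprev[b$idx_in, , drop = FALSE] +
          crossprod(W[[k]]$W1, dz)
      }
    }
    dstate <- dprev
  }

  input_grads <- NULL
  if (want_input) {
    din_edges <- dstate[model$input_edge_pos, , drop = FALSE]
    input_grads <- matrix(0, B, length(model$input_nodes),
                          dimnames = list(NULL, model$input_nodes))
    acc <- rowsum(din_edges, group = model$input_edge_src)
    input_grads[, as.integer(rownames(acc))] <- t(acc)
  }
  list(param_grads = pgrads, input_grads = input_grads, mask_grads = mgrads)
}

#' Jacobian of the outputs with respect to the input nodes
#'
#' Exact reverse-mode derivative of every output-node prediction with respect
#' to every input-node value at the point `x`. Because the computation graph
#' is constrained by the structural graph, the entry for (output o, input i)
#' is exactly zero whenever i is not an ancestor of o.
#'
#' @param model a `gsnn_model`
#' @param x a single encoded observation (vector or 1-row matrix over input
#'   nodes)
#' @return matrix (output nodes x input nodes) of partial derivatives
#' @export
gsnn_input_jacobian <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  assert_that_(nrow(x) == 1, "x must be a single observation")
  n_out <- length(model$output_nodes)
  xs <- x[rep(1, n_out), , drop = FALSE]
  fwd <- gsnn_forward(model, xs, keep_cache = TRUE)
  dpred <- diag(n_out)
  bk <- gsnn_backward(model, fwd, dpred, want_params = FALSE,
                      want_input = TRUE)
  jac <- bk$input_grads
  dimnames(jac) <- list(model$output_nodes, model$input_nodes)
  jac
}

# ---- Adam over nested parameter lists -------------------------------------

adam_state <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

tree_map2 <- function(x, y, f) {
  if (is.list(x)) map2(x, y, tree_map2, f = f) else f(x, y)
}
tree_map3 <- function(x, y, z, f) {
  if (is.list(x)) {
    out <- lapply(seq_along(x), function(i) tree_map3(x[[i]], y[[i]], z[[i]], f))
    names(out) <- names(x)
    out
  } else f(x, y, z)
}

adam_step <- function(params, grads, st, lr = 1e-2, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- tree_map2(st$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  st$v <- tree_map2(st$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  params <- tree_map3(params, st$m, st$v, function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  })
  list(params = params, state = st)
}
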