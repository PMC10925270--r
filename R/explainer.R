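#' Explainer configuration
#'
#' Settings for the edge-mask explanation optimizer. Masks are drawn from a
#' binary-concrete (Gumbel-softmax) relaxation with one logit per edge; the
#' temperature anneals geometrically from `tau_start` to `tau_end` across
#' iterations.
#'
#' @param iterations optimization iterations (N)
#' @param beta mask-size penalty coefficient; penalizes
#'   `max(0, sum(mask) - free_edges)`
#' @param gamma weight-decay coefficient on the mask logits
#' @param free_edges number of edges exempt from the size penalty
#' @param lr learning rate for the logit updates
#' @param init_prior initial inclusion probability P of every edge (the
#'   optimization starts from almost the full graph)
#' @param mask_samples relaxed mask draws per iteration (B), averaged in the
#'   loss
#' @param tau_start,tau_end geometric temperature schedule endpoints
#' @param seed integer seed
#' @return list of class `explainer_config`
#' @export
explainer_config <- function(iterations = 150, beta = 0.01, gamma = 0,
                             free_edges = 0, lr = 0.25, init_prior = 0.9,
                             mask_samples = 8, tau_start = 5, tau_end = 0.5,
                             seed = 1) {
  assert_that_(init_prior > 0 && init_prior < 1, "init_prior must be in (0,1)")
  assert_that_(tau_start > tau_end && tau_end > 0,
               "need tau_start > tau_end > 0")
  structure(list(iterations = as.integer(iterations), beta = beta,
                 gamma = gamma, free_edges = free_edges, lr = lr,
                 init_prior = init_prior,
                 mask_samples = as.integer(mask_samples),
                 tau_start = tau_start, tau_end = tau_end,
                 seed = as.integer(seed)),
            class = "explainer_config")
}

#' Layerwise baseline activations
#'
#' Runs the model on the baseline observation in evaluation mode and records
#' the edge state after every layer. Excluded edges are pinned to these
#' values during masked forwards.
#'
#' @param model a `gsnn_model`
#' @param x_b encoded baseline observation (vector or 1-row matrix)
#' @return list of `layers` numeric vectors of length E
#' @export
baseline_activations <- function(model, x_b) {
  if (is.null(dim(x_b))) x_b <- matrix(x_b, 1)
  fwd <- gsnn_forward(model, x_b)
  map(fwd$states[-1], ~ .x[, 1])
}

#' Masked forward pass against a baseline
#'
#' Runs the model on `x` with, after every layer, edges carrying `mask = 0`
#' overwritten by the corresponding baseline activation; edges with
#' `mask = 1` are untouched. An all-ones mask reproduces the model's
#' prediction for `x` exactly; an all-zeros mask reproduces the prediction
#' for the baseline exactly.
#'
#' @param model a `gsnn_model`
#' @param x encoded observation (vector or 1-row matrix)
#' @param mask numeric vector over edges in `[0, 1]`
#' @param a_b baseline activations from [baseline_activations()]
#' @return prediction vector over output nodes
#' @export
masked_forward <- function(model, x, mask, a_b) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  assert_that_(length(mask) == nrow(model$graph$edges),
               "mask length must equal the number of edges")
  fwd <- gsnn_forward(model, x, masks = matrix(mask, ncol = 1),
                      baseline_states = a_b)
  fwd$pred[1, ]
}

#' Explain a prediction by learning an edge mask
#'
#' Learns, by gradient descent on per-edge logits, a discrete edge subset
#' whose masked prediction preserves the model's *differential* prediction
#' `f(x) - f(x_b)`. Each iteration draws `mask_samples` relaxed binary masks
#' from the concrete distribution at the current temperature, computes
#' masked-forward outputs (excluded edges pinned to the baseline's layerwise
#' activations), and averages
#' `MSE(target, output) + beta * max(0, sum(mask) - free_edges) +
#'  gamma * ||logits||^2` before a gradient step. Scores are the final
#' inclusion probabilities `sigmoid(logits)`.
#'
#' @param model a trained `gsnn_model` / `gsnn_fit`
#' @param x encoded observation to explain
#' @param x_b encoded baseline observation (e.g. the same cell line at dose 0)
#' @param cfg an [explainer_config()]
#' @return object of class `edge_importance`: tibble `$scores`
#'   (source, target, edge_class, score), `$variance_retained` (fraction of
#'   the differential-prediction variance preserved by the hard mask
#'   `score > 0.5`), plus the config and loss trace
#' @export
explain <- function(model, x, x_b, cfg = explainer_config()) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (is.null(dim(x_b))) x_b <- matrix(x_b, 1)
  E <- nrow(model$graph$edges)
  B <- cfg$mask_samples
  a_b <- baseline_activations(model, x_b)
  pred_b <- gsnn_forward(model, x_b)$pred[1, ]
  target <- gsnn_forward(model, x)$pred[1, ] - pred_b
  theta <- rep(log(cfg$init_prior / (1 - cfg$init_prior)), E)
  taus <- cfg$tau_start * (cfg$tau_end / cfg$tau_start)^
    (seq(0, 1, length.out = cfg$iterations))
  xs <- x[rep(1, B), , drop = FALSE]
  target_mat <- matrix(target, B, length(target), byrow = TRUE)
  opt <- adam_state(list(theta = theta))
  losses <- numeric(cfg$iterations)
  with_seed_(derive_seed(cfg$seed, "explain"), {
    for (it in seq_len(cfg$iterations)) {
      tau <- taus[it]
      u <- matrix(runif(E * B), E, B)
      logits <- (theta + log(u) - log1p(-u)) / tau
      masks <- sigmoid(logits)
      fwd <- gsnn_forward(model, xs, masks = masks, baseline_states = a_b,
                          keep_cache = TRUE)
      out <- sweep(fwd$pred, 2, pred_b)          # B x n_out differential
      err <- out - target_mat
      mse <- rowMeans(err^2)
      excess <- pmax(0, colSums(masks) - cfg$free_edges)
      loss <- mean(mse) + cfg$beta * mean(excess) +
        cfg$gamma * sum(theta^2)
      if (!is.finite(loss)) {
        abort(paste0("non-finite explainer loss at iteration ", it))
      }
      losses[it] <- loss
      dpred <- 2 * err / (length(target) * B)
      bk <- gsnn_backward(model, fwd, dpred, want_params = FALSE,
                          want_mask = TRUE, masks = masks,
                          baseline_states = a_b)
      dmask <- bk$mask_grads
      # size penalty: d/dmask of beta * mean_j max(0, sum_e m - free)
      hinge_on <- excess > 0
      if (any(hinge_on)) {
        dmask[, hinge_on] <- dmask[, hinge_on] + cfg$beta / B
      }
      # chain through the concrete relaxation: dm/dtheta = m(1-m)/tau
      dtheta <- rowSums(dmask * masks * (1 - masks)) / tau +
        2 * cfg$gamma * theta
      upd <- adam_step(list(theta = theta), list(theta = dtheta), opt,
                       lr = cfg$lr)
      theta <- upd$params$theta
      opt <- upd$state
    }
  })
  scores <- sigmoid(theta)
  hard <- as.numeric(scores > 0.5)
  hard_out <- masked_forward(model, x, hard, a_b) - pred_b
  vt <- var(target)
  variance_retained <- if (vt > 0) 1 - mean((target - hard_out)^2) / vt else NA_real_
  structure(list(
    scores = model$graph$edges |>
      select("source", "target", "edge_class") |>
      mutate(score = scores),
    variance_retained = variance_retained,
    config = cfg, losses = losses
  ), class = "edge_importance")
}

#' @export
print.edge_importance <- function(x, ...) {
  cat(sprintf("<edge_importance> %d edges, %d with score > 0.5, variance retained %s\n",
              nrow(x$scores), sum(x$scores$score > 0.5),
              ifelse(is.na(x$variance_retained), "-",
                     sprintf("%.2f", x$variance_retained))))
  invisible(x)
}

#' @method tidy edge_importance
#' @export
tidy.edge_importance <- function(x, ...) {
  x$scores |> arrange(dplyr::desc(.data$score))
}

#' @method glance edge_importance
#' @export
glance.edge_importance <- function(x, ...) {
  tibble(n_edges = nrow(x$scores),
         n_selected = sum(x$scores$score > 0.5),
         variance_retained = x$variance_retained,
         final_loss = x$losses[length(x$losses)])
}

#' Plot edge importance scores
#'
#' @param object an `edge_importance`
#' @param ... ignored
#' @return a ggplot of ranked scores colored by edge class
#' @method autoplot edge_importance
#' @export
autoplot.edge_importance <- function(object, ...) {
  s <- tidy(object) |> mutate(rank = row_number())
  ggplot2::ggplot(s, ggplot2::aes(x = .data$rank, y = .data$score,
                                  color = .data$edge_class)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "edge rank", y = "inclusion score", color = NULL)
}

#' Average edge-importance replicates
#'
#' Elementwise mean of the scores of several explainer replicates run on the
#' same model and observation; averaging reduces the sampling variance of the
#' concrete relaxation.
#'
#' @param replicates list of `edge_importance` objects over the same edge set
#' @return an `edge_importance` with averaged scores
#' @export
average_replicates <- function(replicates) {
  assert_that_(length(replicates) >= 1, "need at least one replicate")
  ref <- replicates[[1]]
  for (r in replicates[-1]) {
    if (!identical(r$scores$source, ref$scores$source) ||
        !identical(r$scores$target, ref$scores$target)) {
      abort("replicates have mismatched edge spaces")
    }
  }
  sc <- rowMeans(do.call(cbind, map(replicates, ~ .x$scores$score)))
  out <- ref
  out$scores$score <- sc
  out$variance_retained <- mean(map_dbl(replicates, "variance_retained"))
  out$losses <- NULL
  out
}

#' Extract an explanation subgraph by thresholding scores
#'
#' Restricts the graph to edges with score at or above the threshold plus
#' their incident nodes. Explanation subgraphs may strand nodes, so role
#' invariants are not enforced; the result carries a `fragment = TRUE`
#' attribute.
#'
#' @param imp an `edge_importance`
#' @param g the `structural_graph` the scores refer to
#' @param threshold inclusion threshold in (0, 1]; edges with
#'   `score >= threshold` are kept
#' @return a fragment list with `nodes` and `edges` tibbles (class
#'   `graph_fragment`); empty (with a warning) if no edge passes
#' @export
subgraph_from_scores <- function(imp, g, threshold = 0.5) {
  keep <- imp$scores |> filter(.data$score >= threshold)
  if (nrow(keep) == 0) {
    warn("no edges at or above threshold; empty explanation subgraph")
  }
  nm <- unique(c(keep$source, keep$target))
  structure(list(
    nodes = g$nodes |> filter(.data$name %in% nm) |>
      select("name", "entity_class", "role"),
    edges = keep,
    fragment = TRUE
  ), class = "graph_fragment")
}

#' @export
print.graph_fragment <- function(x, ...) {
  cat(sprintf("<graph_fragment> %d nodes, %d edges (role invariants relaxed)\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}
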