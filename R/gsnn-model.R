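#' GSNN hyperparameter configuration
#'
#' @param channels hidden channels per function node (C)
#' @param layers number of GSNN layers (L); signal propagates at most L hops
#' @param dropout dropout rate on hidden channels, in `[0, 1)`
#' @param share_layer_params share function-node weights across layers
#'   (normalization scale/shift stay per-layer; their statistics are
#'   depth-dependent)
#' @param add_self_edges add a self-edge to every function node before
#'   building the model
#' @param scale_channels_by_degree use
#'   `C_n = max(1, min(C, max(D_in, D_out)))` hidden channels for node n
#' @param init_scheme `"kaiming"` (variance `2 / D_in`) or `"xavier"`
#'   (variance `2 / (D_in + D_out)`); fans are the node's degrees in the graph
#' @param activation elementwise nonlinearity (`"elu"`, `"tanh"`, `"relu"`)
#' @param norm `"layer"` for per-node layer normalization of the hidden
#'   vector, `"none"` to disable
#' @param seed integer seed for parameter initialization
#' @return a `gsnn_config` list
#' @export
gsnn_config <- function(channels = 8, layers = 5, dropout = 0,
                        share_layer_params = FALSE, add_self_edges = FALSE,
                        scale_channels_by_degree = FALSE,
                        init_scheme = c("kaiming", "xavier"),
                        activation = "elu", norm = c("layer", "none"),
                        seed = 1) {
  assert_that_(channels >= 1 && layers >= 1, "channels and layers must be >= 1")
  assert_that_(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  structure(list(
    channels = as.integer(channels), layers = as.integer(layers),
    dropout = dropout, share_layer_params = isTRUE(share_layer_params),
    add_self_edges = isTRUE(add_self_edges),
    scale_channels_by_degree = isTRUE(scale_channels_by_degree),
    init_scheme = match.arg(init_scheme), activation = activation,
    norm = match.arg(norm), seed = as.integer(seed)
  ), class = "gsnn_config")
}

# Per-function-node structural info reused by forward/backward.
node_blocks <- function(g, cfg) {
  fn_idx <- which(g$nodes$role == "function")
  map(fn_idx, function(i) {
    idx_in <- which(g$edges$tgt_index == i)
    idx_out <- which(g$edges$src_index == i)
    d_in <- length(idx_in)
    d_out <- length(idx_out)
    c_n <- if (cfg$scale_channels_by_degree) {
      max(1L, min(cfg$channels, max(d_in, d_out)))
    } else cfg$channels
    list(name = g$nodes$name[i], idx_in = idx_in, idx_out = idx_out,
         d_in = d_in, d_out = d_out, c_n = as.integer(c_n))
  })
}

#' Initialize GSNN parameters
#'
#' Weights of function node n are drawn i.i.d. from `Normal(0, 2/D_in)`
#' (kaiming) or `Normal(0, 2/(D_in + D_out))` (xavier) — the second argument
#' is the *variance* — where the fans are the node's degrees in the structural
#' graph (self-edges included; degenerate degrees are clamped to 1). Biases
#' start at zero, normalization scales at one and shifts at zero.
#'
#' @param g a `structural_graph` (after optional self-edge addition)
#' @param cfg a [gsnn_config()]
#' @return list of `cfg$layers` layers (or one shared block replicated by
#'   reference semantics at use), each a list over function nodes with
#'   elements `W1` (C_n x D_in), `b1`, `W2` (D_out x C_n), `b2`, `g` (norm
#'   scale), `s` (norm shift)
#' @export
init_parameters <- function(g, cfg) {
  blocks <- node_blocks(g, cfg)
  n_weight_layers <- if (cfg$share_layer_params) 1L else cfg$layers
  with_seed_(cfg$seed, {
    weights <- map(seq_len(n_weight_layers), function(l) {
      map(blocks, function(b) {
        v <- switch(cfg$init_scheme,
          kaiming = 2 / max(1L, b$d_in),
          xavier = 2 / max(1L, b$d_in + b$d_out))
        list(
          W1 = matrix(rnorm(b$c_n * b$d_in, 0, sqrt(v)), b$c_n, b$d_in),
          b1 = numeric(b$c_n),
          W2 = matrix(rnorm(b$d_out * b$c_n, 0, sqrt(v)), b$d_out, b$c_n),
          b2 = numeric(b$d_out)
        )
      })
    })
    norms <- if (cfg$norm == "layer") {
      map(seq_len(cfg$layers), function(l) {
        map(blocks, function(b) list(g = rep(1, b$c_n), s = numeric(b$c_n)))
      })
    } else NULL
    list(weights = weights, norms = norms)
  })
}

#' Closed-form GSNN parameter count
#'
#' `sum_l sum_n [D_in * C_n + C_n + C_n * D_out + D_out]` plus, when layer
#' normalization is enabled, `layers * sum_n 2 * C_n` (normalization
#' parameters are always per-layer, even under weight sharing). With
#' `share_layer_params`, the weight term is counted once.
#'
#' @inheritParams init_parameters
#' @return integer parameter count
#' @export
count_parameters <- function(g, cfg) {
  if (cfg$add_self_edges) g <- add_self_edges(g)
  blocks <- node_blocks(g, cfg)
  per_node_w <- map_dbl(blocks, function(b) {
    b$d_in * b$c_n + b$c_n + b$c_n * b$d_out + b$d_out
  })
  per_node_norm <- map_dbl(blocks, function(b) 2 * b$c_n)
  w_layers <- if (cfg$share_layer_params) 1 else cfg$layers
  total <- w_layers * sum(per_node_w)
  if (cfg$norm == "layer") total <- total + cfg$layers * sum(per_node_norm)
  as.integer(total)
}

# Count parameters actually realized in a parameter store.
realized_parameter_count <- function(params) {
  cnt <- function(x) {
    if (is.list(x)) sum(map_dbl(x, cnt)) else length(x)
  }
  as.integer(cnt(params))
}

#' Build an (untrained) GSNN model
#'
#' Bundles the graph (with self-edges added when configured), config,
#' per-node block layout and initialized parameters.
#'
#' @inheritParams init_parameters
#' @return object of class `gsnn_model`
#' @export
gsnn_model <- function(g, cfg = gsnn_config()) {
  if (cfg$add_self_edges) g <- add_self_edges(g)
  blocks <- node_blocks(g, cfg)
  m <- structure(list(
    graph = g, config = cfg, blocks = blocks,
    params = init_parameters(g, cfg),
    input_nodes = input_nodes(g), output_nodes = output_nodes(g),
    out_edge_idx = output_edge_index(g)
  ), class = "gsnn_model")
  # edge index of each input node's outgoing edges, for clamping x
  in_idx <- match(m$input_nodes, g$nodes$name)
  m$input_edge_src <- match(g$edges$src_index[g$edges$edge_class == "input_edge"],
                            in_idx)
  m$input_edge_pos <- which(g$edges$edge_class == "input_edge")
  m
}

#' @export
print.gsnn_model <- function(x, ...) {
  cat(sprintf("<gsnn_model> %d edges, %d function nodes, L=%d, C=%d, %d parameters\n",
              nrow(x$graph$edges), length(x$blocks), x$config$layers,
              x$config$channels, realized_parameter_count(x$params)))
  invisible(x)
}

layer_weights <- function(model, l) {
  if (model$config$share_layer_params) model$params$weights[[1]]
  else model$params$weights[[l]]
}

LN_EPS <- 1e-5

# Forward for one layer over all function nodes.
# state: E x B matrix. Returns list(state=new E x B, cache=per-node list).
gsnn_layer_forward <- function(model, state, l, training = FALSE,
                               keep_cache = FALSE, dropout_masks = NULL) {
  cfg <- model$config
  act <- activation_fun(cfg$activation)
  W <- layer_weights(model, l)
  nrm <- if (cfg$norm == "layer") model$params$norms[[l]] else NULL
  B <- ncol(state)
  contrib <- matrix(0, nrow(state), B)
  cache <- if (keep_cache) vector("list", length(model$blocks)) else NULL
  for (k in seq_along(model$blocks)) {
    b <- model$blocks[[k]]
    if (b$d_out == 0) next
    w <- W[[k]]
    inp <- if (b$d_in > 0) state[b$idx_in, , drop = FALSE] else
      matrix(0, 0, B)
    z <- if (b$d_in > 0) w$W1 %*% inp + w$b1 else
      matrix(w$b1, b$c_n, B)
    if (!is.null(nrm)) {
      mu <- colMeans(z)
      zc <- sweep(z, 2, mu)
      sdinv <- 1 / sqrt(colMeans(zc^2) + LN_EPS)
      zhat <- sweep(zc, 2, sdinv, `*`)
      zn <- zhat * nrm[[k]]$g + nrm[[k]]$s
    } else {
      mu <- NULL; sdinv <- NULL; zhat <- NULL; zn <- z
    }
    a <- act$f(zn)
    if (training && cfg$dropout > 0) {
      dmask <- if (!is.null(dropout_masks)) dropout_masks[[k]] else
        matrix(rbinom(b$c_n * B, 1, 1 - cfg$dropout), b$c_n, B) /
          (1 - cfg$dropout)
      ad <- a * dmask
    } else {
      dmask <- NULL
      ad <- a
    }
    out <- w$W2 %*% ad + w$b2
    contrib[b$idx_out, ] <- out
    if (keep_cache) {
      cache[[k]] <- list(inp = inp, z = z, mu = mu, sdinv = sdinv, zhat = zhat,
                         zn = zn, a = a, dmask = dmask, ad = ad)
    }
  }
  new_state <- contrib + state
  if (any(!is.finite(new_state))) {
    abort(paste0("non-finite edge state at layer ", l))
  }
  list(state = new_state, cache = cache)
}

# Initial edge state from the encoded input matrix x (B x n_inputs).
initial_state <- function(model, x) {
  B <- nrow(x)
  state <- matrix(0, nrow(model$graph$edges), B)
  state[model$input_edge_pos, ] <- t(x)[model$input_edge_src, , drop = FALSE]
  state
}

#' GSNN forward pass
#'
#' Initializes the edge state to zero, writes each input node's encoded value
#' onto its outgoing edges, then applies `layers` residual GSNN layer updates
#' (`state <- F(state) + state`); function-node contributions never write
#' input edges, so the residual path keeps the stimulus clamped at every
#' depth. Optionally, a per-sample edge mask mixes each post-layer state with
#' recorded baseline activations (`masked` explanation forward: masked-out
#' edges are pinned to the baseline's layerwise value).
#'
#' @param model a `gsnn_model`
#' @param x encoded input matrix (observations x input nodes), e.g. from
#'   [encode_observations()]
#' @param training enable dropout
#' @param masks optional E x B matrix of edge masks in `[0, 1]` (1 = keep)
#' @param baseline_states optional list of per-layer baseline edge states
#'   (vectors of length E) as returned by [baseline_activations()]
#' @param keep_cache keep intermediate activations (needed for backward)
#' @return list with `pred` (observations x output nodes), `states` (list of
#'   edge-state matrices, index 1 = initial), and `caches` when requested
#' @export
gsnn_forward <- function(model, x, training = FALSE, masks = NULL,
                         baseline_states = NULL, keep_cache = FALSE) {
  cfg <- model$config
  if (is.null(dim(x))) x <- matrix(x, 1, dimnames = list(NULL, names(x)))
  assert_that_(ncol(x) == length(model$input_nodes),
               "x must have one column per input node")
  if (!is.null(masks)) {
    assert_that_(nrow(masks) == nrow(model$graph$edges),
                 "mask length must equal the number of edges")
    assert_that_(!is.null(baseline_states),
                 "masked forward requires baseline_states")
  }
  state <- initial_state(model, x)
  states <- vector("list", cfg$layers + 1L)
  states[[1]] <- state
  caches <- if (keep_cache) vector("list", cfg$layers) else NULL
  premix <- if (keep_cache) vector("list", cfg$layers) else NULL
  for (l in seq_len(cfg$layers)) {
    step <- gsnn_layer_forward(model, state, l, training = training,
                               keep_cache = keep_cache)
    state <- step$state
    if (!is.null(masks)) {
      if (keep_cache) premix[[l]] <- state
      state <- masks * state + (1 - masks) * baseline_states[[l]]
    }
    states[[l + 1L]] <- state
    if (keep_cache) caches[[l]] <- step$cache
  }
  pred <- t(state[model$out_edge_idx, , drop = FALSE])
  dimnames(pred) <- list(rownames(x), model$output_nodes)
  if (any(!is.finite(pred))) abort("non-finite model output")
  res <- list(pred = pred, states = states)
  if (keep_cache) {
    res$caches <- caches
    res$premix <- premix
  }
  res
}

#' Predict perturbation responses
#'
#' @param object a `gsnn_model` (or `gsnn_fit`)
#' @param x encoded input matrix
#' @param ... ignored
#' @return matrix of predictions (observations x output nodes)
#' @export
predict.gsnn_model <- function(object, x, ...) {
  gsnn_forward(object, x)$pred
}
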