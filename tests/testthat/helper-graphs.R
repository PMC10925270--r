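# Shared fixtures: tiny hand-built graphs and independent oracles.

chain_graph <- function() {
  structural_graph(
    tibble::tibble(name = c("drugA", "protP", "lincsG"),
                   entity_class = c("DRUG", "PROTEIN", "LINCS")),
    tibble::tibble(source = c("drugA", "protP"),
                   target = c("protP", "lincsG")))
}

# drug -> p1 -> p2 -> r1 -> LINCS; p1 -> r1 shortcut; EXPR input on p2
small_graph <- function() {
  structural_graph(
    tibble::tibble(
      name = c("d1", "PROTEIN_p1", "PROTEIN_p2", "RNA_r1", "LINCS_r1",
               "EXPR_p2"),
      entity_class = c("DRUG", "PROTEIN", "PROTEIN", "RNA", "LINCS", "EXPR")),
    tibble::tibble(
      source = c("d1", "PROTEIN_p1", "PROTEIN_p1", "PROTEIN_p2", "RNA_r1",
                 "EXPR_p2"),
      target = c("PROTEIN_p1", "PROTEIN_p2", "RNA_r1", "RNA_r1", "LINCS_r1",
                 "PROTEIN_p2")))
}

# a function-node chain of given length: d -> f1 -> ... -> fk -> out
depth_chain_graph <- function(k) {
  fns <- paste0("PROTEIN_f", seq_len(k))
  structural_graph(
    tibble::tibble(name = c("d1", fns, "LINCS_o"),
                   entity_class = c("DRUG", rep("PROTEIN", k), "LINCS")),
    tibble::tibble(source = c("d1", fns), target = c(fns, "LINCS_o")))
}

# random DAG over n function nodes plus one drug input and a few outputs,
# for reachability and oracle tests
random_dag_graph <- function(n_fn = 20, n_out = 4, p = 0.15, seed = 1) {
  withr::with_seed(seed, {
    fns <- sprintf("PROTEIN_f%02d", seq_len(n_fn))
    # upper-triangular adjacency => acyclic
    e <- expand.grid(i = seq_len(n_fn), j = seq_len(n_fn))
    e <- e[e$i < e$j & stats::runif(nrow(e)) < p, ]
    edges <- tibble::tibble(source = fns[e$i], target = fns[e$j])
    # backbone chain keeps every node non-degenerate
    edges <- dplyr::distinct(dplyr::bind_rows(
      edges, tibble::tibble(source = fns[-n_fn], target = fns[-1])))
    outs <- paste0("LINCS_o", seq_len(n_out))
    out_src <- fns[n_fn - seq_len(n_out) + 1]
    structural_graph(
      tibble::tibble(name = c("d1", fns, outs),
                     entity_class = c("DRUG", rep("PROTEIN", n_fn),
                                      rep("LINCS", n_out))),
      dplyr::bind_rows(tibble::tibble(source = "d1", target = fns[1]),
                       edges,
                       tibble::tibble(source = out_src, target = outs)))
  })
}

# Brute-force transitive closure by repeated boolean matrix multiplication.
closure_oracle <- function(g) {
  n <- nrow(g$nodes)
  A <- matrix(FALSE, n, n)
  A[cbind(g$edges$src_index, g$edges$tgt_index)] <- TRUE
  R <- A
  for (i in seq_len(n)) {
    R2 <- R | ((R %*% A) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  dimnames(R) <- list(g$nodes$name, g$nodes$name)
  R
}

# Dense masked-matrix oracle for one GSNN layer: materializes the full
# (sum C_n x E) gather and (E x sum C_n) scatter matrices and multiplies
# them explicitly, with per-node-block layer norm and activation.
dense_layer_oracle <- function(model, state, l) {
  cfg <- model$config
  W <- if (cfg$share_layer_params) model$params$weights[[1]] else
    model$params$weights[[l]]
  blocks <- model$blocks
  E <- nrow(model$graph$edges)
  total_c <- sum(vapply(blocks, function(b) b$c_n, integer(1)))
  big_w1 <- matrix(0, total_c, E)
  big_b1 <- numeric(total_c)
  big_w2 <- matrix(0, E, total_c)
  big_b2 <- numeric(E)
  offset <- 0L
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    rows <- offset + seq_len(b$c_n)
    if (b$d_in > 0) big_w1[rows, b$idx_in] <- W[[k]]$W1
    big_b1[rows] <- W[[k]]$b1
    big_w2[b$idx_out, rows] <- W[[k]]$W2
    big_b2[b$idx_out] <- W[[k]]$b2
    offset <- offset + b$c_n
  }
  h <- big_w1 %*% state + big_b1
  offset <- 0L
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    rows <- offset + seq_len(b$c_n)
    hb <- h[rows, , drop = FALSE]
    if (cfg$norm == "layer") {
      nrm <- model$params$norms[[l]][[k]]
      mu <- colMeans(hb)
      zc <- sweep(hb, 2, mu)
      sdinv <- 1 / sqrt(colMeans(zc^2) + 1e-5)
      hb <- sweep(zc, 2, sdinv, `*`) * nrm$g + nrm$s
    }
    h[rows, ] <- ifelse(hb > 0, hb, exp(pmin(hb, 0)) - 1)  # ELU
    offset <- offset + b$c_n
  }
  out <- big_w2 %*% h + big_b2
  emitted <- unique(unlist(lapply(blocks, function(b) b$idx_out)))
  silent <- setdiff(seq_len(E), emitted)
  out[silent, ] <- 0
  out + state
}

# Full-depth dense-oracle forward returning predictions.
dense_forward_oracle <- function(model, x) {
  state <- matrix(0, nrow(model$graph$edges), nrow(x))
  in_pos <- which(model$graph$edges$edge_class == "input_edge")
  in_nodes_idx <- match(model$input_nodes, model$graph$nodes$name)
  src <- match(model$graph$edges$src_index[in_pos], in_nodes_idx)
  state[in_pos, ] <- t(x)[src, , drop = FALSE]
  for (l in seq_len(model$config$layers)) {
    state <- dense_layer_oracle(model, state, l)
    state[in_pos, ] <- t(x)[src, , drop = FALSE]
  }
  t(state[model$out_edge_idx, , drop = FALSE])
}

expect_partition <- function(parts, n) {
  all_idx <- sort(unname(unlist(parts)))
  expect_identical(all_idx, seq_len(n))
}
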