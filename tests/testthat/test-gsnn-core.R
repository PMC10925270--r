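test_that("initialization variances follow the degree-aware schemes", {
  # kaiming: Normal(0, 2/D_in); node with D_in = 2 => variance 1
  g <- structural_graph(
    tibble::tibble(name = c("d1", "d2", "PROTEIN_p", "LINCS_g"),
                   entity_class = c("DRUG", "DRUG", "PROTEIN", "LINCS")),
    tibble::tibble(source = c("d1", "d2", "PROTEIN_p"),
                   target = c("PROTEIN_p", "PROTEIN_p", "LINCS_g")))
  cfg <- gsnn_config(channels = 500, layers = 100, init_scheme = "kaiming",
                     seed = 9)
  params <- init_parameters(g, cfg)
  draws <- unlist(purrr::map(params$weights, ~ .x[[1]]$W1))
  expect_gte(length(draws), 1e5)
  expect_equal(var(draws), 1.0, tolerance = 0.05)
  expect_equal(mean(draws), 0, tolerance = 0.02)

  # xavier: Normal(0, 2/(D_in + D_out)); D_in = 3, D_out = 1 => variance 0.5
  g2 <- structural_graph(
    tibble::tibble(name = c("d1", "d2", "d3", "PROTEIN_p", "LINCS_g"),
                   entity_class = c("DRUG", "DRUG", "DRUG", "PROTEIN",
                                    "LINCS")),
    tibble::tibble(source = c("d1", "d2", "d3", "PROTEIN_p"),
                   target = c(rep("PROTEIN_p", 3), "LINCS_g")))
  cfg2 <- gsnn_config(channels = 500, layers = 60, init_scheme = "xavier",
                      seed = 9)
  draws2 <- unlist(purrr::map(init_parameters(g2, cfg2)$weights,
                              ~ .x[[1]]$W1))
  expect_equal(var(draws2), 0.5, tolerance = 0.025)

  # fixed seed reproduces parameters bit-identically
  expect_identical(init_parameters(g, cfg), init_parameters(g, cfg))
  # biases zero, norm scale one / shift zero
  expect_identical(params$weights[[1]][[1]]$b1, numeric(500))
  expect_identical(params$norms[[1]][[1]]$g, rep(1, 500))
  expect_identical(params$norms[[1]][[1]]$s, numeric(500))
})

test_that("parameter count matches the closed form and the realized store", {
  # single function node, D_in=2, D_out=1, C=2, L=1, norm on:
  # 2*2 + 2 + 2*1 + 1 + 2*2 = 13
  g <- structural_graph(
    tibble::tibble(name = c("d1", "d2", "PROTEIN_p", "LINCS_g"),
                   entity_class = c("DRUG", "DRUG", "PROTEIN", "LINCS")),
    tibble::tibble(source = c("d1", "d2", "PROTEIN_p"),
                   target = c("PROTEIN_p", "PROTEIN_p", "LINCS_g")))
  cfg <- gsnn_config(channels = 2, layers = 1)
  expect_identical(count_parameters(g, cfg), 13L)

  # sharing weights leaves only per-layer norm parameters depth-dependent
  cfg_sh <- gsnn_config(channels = 2, layers = 10, share_layer_params = TRUE)
  cfg_sh1 <- gsnn_config(channels = 2, layers = 1, share_layer_params = TRUE)
  norm_per_layer <- 4L
  expect_identical(count_parameters(g, cfg_sh) -
                     count_parameters(g, cfg_sh1), 9L * norm_per_layer)
  cfg_sh_nonorm <- gsnn_config(channels = 2, layers = 10,
                               share_layer_params = TRUE, norm = "none")
  cfg_sh1_nonorm <- gsnn_config(channels = 2, layers = 1,
                                share_layer_params = TRUE, norm = "none")
  expect_identical(count_parameters(g, cfg_sh_nonorm),
                   count_parameters(g, cfg_sh1_nonorm))

  # formula equals the realized store on fixture graphs, with and without
  # degree-scaled channels and self-edges
  gf <- fixture_graph(fixture_spec(seed = 4))
  for (cfg in list(gsnn_config(channels = 3, layers = 2),
                   gsnn_config(channels = 3, layers = 2,
                               scale_channels_by_degree = TRUE),
                   gsnn_config(channels = 4, layers = 3,
                               add_self_edges = TRUE, norm = "none"))) {
    m <- gsnn_model(gf, cfg)
    expect_identical(realized_parameter_count(m$params),
                     count_parameters(gf, cfg))
  }
})

test_that("zero weights give the pure residual identity", {
  g <- small_graph()
  cfg <- gsnn_config(channels = 3, layers = 4, norm = "none")
  m <- gsnn_model(g, cfg)
  m$params <- zero_like(m$params)
  x <- c(d1 = 0.7, EXPR_p2 = -1.2)
  fwd <- gsnn_forward(m, matrix(x, 1))
  for (st in fwd$states[-1]) {
    expect_identical(st, fwd$states[[1]])
  }
  expect_identical(unname(fwd$pred[1, ]), 0)
})

test_that("sparse forward equals the dense masked-matrix oracle", {
  graphs <- list(small_graph(),
                 random_dag_graph(n_fn = 30, n_out = 5, seed = 2),
                 fixture_graph(fixture_spec(seed = 5)))
  for (g in graphs) {
    for (cfg in list(gsnn_config(channels = 4, layers = 3, seed = 2),
                     gsnn_config(channels = 3, layers = 5, norm = "none",
                                 seed = 3),
                     gsnn_config(channels = 5, layers = 2,
                                 scale_channels_by_degree = TRUE,
                                 add_self_edges = TRUE, seed = 4))) {
      m <- gsnn_model(g, cfg)
      withr::with_seed(7, {
        x <- matrix(rnorm(3 * length(m$input_nodes)), 3)
      })
      expect_lt(max(abs(gsnn_forward(m, x)$pred - dense_forward_oracle(m, x))),
                1e-5)
    }
  }
})

test_that("gradients are exactly zero from non-ancestor inputs (structural faithfulness)", {
  g <- fixture_graph(fixture_spec(seed = 6))
  m <- gsnn_model(g, gsnn_config(channels = 4, layers = 4, seed = 1))
  withr::with_seed(1, x <- rnorm(length(m$input_nodes)) / 2)
  jac <- gsnn_input_jacobian(m, x)
  R <- closure_oracle(g)
  for (o in m$output_nodes) {
    for (i in m$input_nodes) {
      if (!R[i, o]) expect_identical(jac[o, i], 0)
    }
  }
  # and ancestors do reach: at least one nonzero gradient per output
  expect_true(all(rowSums(abs(jac)) > 0))
})

test_that("reverse-mode parameter gradients match finite differences", {
  g <- small_graph()
  cfg <- gsnn_config(channels = 2, layers = 3, seed = 5)
  m <- gsnn_model(g, cfg)
  withr::with_seed(2, {
    x <- matrix(rnorm(4 * length(m$input_nodes)), 4)
    y <- matrix(rnorm(4 * length(m$output_nodes)), 4)
  })
  loss_of <- function(model) {
    mean((gsnn_forward(model, x)$pred - y)^2)
  }
  fwd <- gsnn_forward(m, x, keep_cache = TRUE)
  dpred <- 2 * (fwd$pred - y) / length(y)
  bk <- gsnn_backward(m, fwd, dpred)
  eps <- 1e-6
  probe <- function(path_set, path_get) {
    m2 <- m
    m2$params <- path_set(m2$params, eps)
    (loss_of(m2) - loss_of(m)) / eps
  }
  # a W1 entry, a W2 entry, a norm scale, and a bias on layer 2, node 1
  checks <- list(
    list(num = probe(function(p, e) {p$weights[[2]][[1]]$W1[1, 1] <- p$weights[[2]][[1]]$W1[1, 1] + e; p}),
         ana = bk$param_grads$weights[[2]][[1]]$W1[1, 1]),
    list(num = probe(function(p, e) {p$weights[[2]][[1]]$W2[1, 2] <- p$weights[[2]][[1]]$W2[1, 2] + e; p}),
         ana = bk$param_grads$weights[[2]][[1]]$W2[1, 2]),
    list(num = probe(function(p, e) {p$norms[[2]][[1]]$g[2] <- p$norms[[2]][[1]]$g[2] + e; p}),
         ana = bk$param_grads$norms[[2]][[1]]$g[2]),
    list(num = probe(function(p, e) {p$weights[[1]][[2]]$b1[1] <- p$weights[[1]][[2]]$b1[1] + e; p}),
         ana = bk$param_grads$weights[[1]][[2]]$b1[1])
  )
  for (chk in checks) {
    expect_equal(chk$ana, chk$num, tolerance = 1e-3)
  }
})

test_that("signal needs exactly as many layers as the path is long", {
  g <- depth_chain_graph(3)  # d -> f1 -> f2 -> f3 -> out: 3 function hops
  x0 <- c(d1 = 0)
  x1 <- c(d1 = 1)
  for (L in 2:4) {
    m <- gsnn_model(g, gsnn_config(channels = 3, layers = L, seed = 8))
    delta <- unname(abs(gsnn_forward(m, matrix(x1, 1))$pred[1, 1] -
                          gsnn_forward(m, matrix(x0, 1))$pred[1, 1]))
    if (L < 3) expect_identical(delta, 0) else expect_gt(delta, 1e-8)
  }
})

test_that("perturbing an input propagates only one function-hop per layer", {
  g <- depth_chain_graph(4)
  m <- gsnn_model(g, gsnn_config(channels = 2, layers = 4, seed = 3))
  x0 <- matrix(c(d1 = 0), 1)
  x1 <- matrix(c(d1 = 1), 1)
  s0 <- gsnn_forward(m, x0)$states
  s1 <- gsnn_forward(m, x1)$states
  # after layer l, only edges within l hops of the input may differ
  hop_of_edge <- seq_len(nrow(g$edges)) - 1  # chain graph: edge i is hop i-1
  for (l in 1:4) {
    diff_edges <- which(abs(s1[[l + 1]] - s0[[l + 1]])[, 1] > 0)
    expect_true(all(hop_of_edge[diff_edges] <= l))
  }
})

test_that("training reduces the MSE substantially on fixture data", {
  spec <- fixture_spec(seed = 10)
  g <- fixture_graph(spec)
  sim <- simulate_responses(g, spec)
  enc <- encode_observations(sim$observations, g, sim$omics, sim$targets)
  cfg <- gsnn_config(channels = 4, layers = 4, seed = 1)
  m0 <- gsnn_model(g, cfg)
  mse0 <- mean((gsnn_forward(m0, enc$x)$pred - enc$y)^2)
  fit <- gsnn_fit(g, enc$x, enc$y, cfg, epochs = 8, batch_size = 24,
                  lr = 5e-3)
  mse1 <- mean((gsnn_forward(fit, enc$x)$pred - enc$y)^2)
  expect_lt(mse1, 0.5 * mse0)
  expect_s3_class(glance(fit), "tbl_df")
  expect_identical(nrow(tidy(fit)), 8L)
})

test_that("forward is deterministic in eval mode and dropout only acts in training", {
  g <- small_graph()
  m <- gsnn_model(g, gsnn_config(channels = 4, layers = 3, dropout = 0.5,
                                 seed = 2))
  x <- matrix(c(1, 0.3), 1)
  p1 <- gsnn_forward(m, x)$pred
  p2 <- gsnn_forward(m, x)$pred
  expect_identical(p1, p2)
  withr::with_seed(1, t1 <- gsnn_forward(m, x, training = TRUE)$pred)
  withr::with_seed(2, t2 <- gsnn_forward(m, x, training = TRUE)$pred)
  expect_false(identical(t1, t2))
})
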