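# direct covariance-formula implementation, independent of stats::cor
pearson_oracle <- function(a, b) {
  ca <- a - mean(a)
  cb <- b - mean(b)
  sum(ca * cb) / sqrt(sum(ca^2) * sum(cb^2))
}

test_that("mean pearson matches identities and the covariance-formula oracle", {
  withr::with_seed(1, y <- matrix(rnorm(40), 8, 5))
  expect_equal(mean_pearson(y, y)$mean_pearson, 1)
  expect_equal(mean_pearson(-y, y)$mean_pearson, -1)
  withr::with_seed(2, {
    yhat <- matrix(rnorm(100), 20, 5)
    yy <- matrix(rnorm(100), 20, 5)
  })
  rep <- mean_pearson(yhat, yy)
  manual <- vapply(1:5, function(j) pearson_oracle(yhat[, j], yy[, j]),
                   numeric(1))
  expect_equal(unname(rep$per_output_pearson), manual, tolerance = 1e-12)
  expect_equal(rep$mean_pearson, mean(manual), tolerance = 1e-12)
})

test_that("zero-variance columns are skipped with a count; all-flat errors", {
  withr::with_seed(3, y <- matrix(rnorm(30), 10, 3))
  yhat <- y
  yhat[, 2] <- 1  # constant prediction column
  rep <- mean_pearson(yhat, y)
  expect_identical(rep$n_skipped, 1L)
  expect_true(is.na(rep$per_output_pearson[2]))
  expect_equal(rep$mean_pearson, 1)
  expect_error(mean_pearson(matrix(1, 5, 2), matrix(1, 5, 2)),
               "zero variance")
})

test_that("paired t-test matches the hand formula and the Bonferroni relation", {
  a <- c(1, 2, 3)
  b <- c(1.1, 2.2, 2.9)
  res <- paired_test(a, b, n_tests = 1)
  d <- a - b
  t_manual <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(res$t, t_manual, tolerance = 1e-10)
  expect_equal(res$p_value,
               2 * pt(abs(t_manual), df = 2, lower.tail = FALSE),
               tolerance = 1e-10)
  # cross-check against the reference implementation
  expect_equal(res$p_value, t.test(a, b, paired = TRUE)$p.value,
               tolerance = 1e-12)

  # per-fold scores rounded to two digits give exactly constant differences,
  # which the zero-variance guard must flag rather than fabricate a p-value
  res2 <- paired_test(c(0.56, 0.51, 0.56), c(0.53, 0.48, 0.53), n_tests = 3)
  expect_true(res2$zero_variance)
  expect_true(is.na(res2$p_value))
  # with realistic unrounded scores the Bonferroni relation holds
  res2b <- paired_test(c(0.561, 0.512, 0.558), c(0.53, 0.481, 0.529),
                       n_tests = 3)
  expect_false(res2b$zero_variance)
  expect_equal(res2b$p_adjusted, min(1, res2b$p_value * 3))
  expect_lt(res2b$p_value, res2b$p_adjusted)
  # a vs a + delta has zero-variance differences: flagged, p undefined
  res3 <- paired_test(c(1, 2, 3), c(1, 2, 3) + 0.5)
  expect_true(res3$zero_variance)
  expect_true(is.na(res3$p_value))
  # adjusted p capped at 1
  res4 <- paired_test(c(0.5, 0.52, 0.49), c(0.51, 0.5, 0.51), n_tests = 50)
  expect_lte(res4$p_adjusted, 1)
})

test_that("BH/BY adjustment matches the step-up oracle and ordering relation", {
  # step-up oracle computed by hand: (0.01, 0.02, 0.03, 0.9) under BH
  p <- c(0.01, 0.02, 0.03, 0.9)
  expect_equal(p.adjust(p, "BH"), c(0.04, 0.04, 0.04, 0.9))

  # brute-force sort-based step-up oracle vs p.adjust on random vectors
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(o)]
  }
  withr::with_seed(5, {
    for (i in 1:20) {
      p <- runif(sample(3:30, 1))^2
      expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
      expect_true(all(p.adjust(p, "BY") >= p.adjust(p, "BH") - 1e-15))
    }
  })
})

grouped_scores_fixture <- function(delta = 0.03, n_groups = 6, n_folds = 3,
                                   seed = 8) {
  withr::with_seed(seed, {
    base <- tidyr::crossing(group = paste0("g", seq_len(n_groups)),
                            fold = seq_len(n_folds)) |>
      dplyr::mutate(
        base = runif(dplyr::n(), 0.3, 0.6),
        noise = rnorm(dplyr::n(), 0, 0.005))
    sizes <- tibble::tibble(
      group = paste0("g", seq_len(n_groups)),
      n_obs = sample(c(4, 10), n_groups, replace = TRUE, prob = c(0.3, 0.7)))
    dplyr::bind_rows(
      base |> dplyr::mutate(method = "gsnn", score = base + delta + noise),
      base |> dplyr::mutate(method = "nn", score = base)) |>
      dplyr::left_join(sizes, by = "group") |>
      dplyr::select("group", "fold", "method", "score", "n_obs")
  })
}

test_that("grouped performance drops small groups, tests pairs, controls FDR", {
  sc <- grouped_scores_fixture()
  res <- grouped_performance(sc, min_group_size = 5, fdr_method = "BH",
                             fdr_threshold = 0.1)
  small <- sc |> dplyr::group_by(group) |>
    dplyr::summarise(mn = min(n_obs)) |> dplyr::filter(mn < 5) |>
    dplyr::pull(group)
  expect_false(any(res$group %in% small))
  expect_true(all(c("mean_gsnn", "mean_nn", "p_value", "q_value") %in%
                    names(res)))
  # single surviving group: q = p under BH
  sc1 <- sc |> dplyr::filter(group == "g1")
  res1 <- grouped_performance(sc1, min_group_size = 0)
  expect_equal(res1$q_value, res1$p_value)
  # BY is uniformly more conservative
  res_by <- grouped_performance(sc, min_group_size = 5, fdr_method = "BY")
  expect_true(all(res_by$q_value >= res$q_value - 1e-15))
  # nothing survives: empty result with a warning
  expect_warning(out <- grouped_performance(sc, min_group_size = 100),
                 "no groups")
  expect_identical(nrow(out), 0L)
})

test_that("baseline NN learns a linear map to high fidelity", {
  withr::with_seed(11, {
    A <- matrix(rnorm(8 * 5), 5, 8)
    x <- matrix(rnorm(400 * 8), 400, 8)
    y <- x %*% t(A)
  })
  fit <- train_baseline_nn(x[1:300, ], y[1:300, ], hidden = 32,
                           x_val = x[301:350, ], y_val = y[301:350, ],
                           epochs = 60, seed = 2)
  rep <- mean_pearson(predict(fit, x[351:400, ]), y[351:400, ])
  expect_gte(rep$mean_pearson, 0.95)
  # fixed seed reproduces the final loss
  fit2 <- train_baseline_nn(x[1:300, ], y[1:300, ], hidden = 32,
                            x_val = x[301:350, ], y_val = y[301:350, ],
                            epochs = 60, seed = 2)
  expect_identical(fit$history$train_mse, fit2$history$train_mse)
})

test_that("removing cell context hurts when responses vary by cell line", {
  # response = drug effect + strong cell-line effect carried by omics
  spec <- fixture_spec(seed = 12, n_cell_lines = 4)
  g <- fixture_graph(spec)
  sim <- simulate_responses(g, spec)
  enc <- encode_observations(sim$observations, g, sim$omics, sim$targets)
  enc0 <- encode_observations(sim$observations, g, sim$omics, sim$targets,
                              cell_agnostic = TRUE)
  sp <- mccv_split(sim$observations, seed = 1)
  idx <- function(part) sim$observations$obs_id %in%
    filter_split(sim$observations, part)$obs_id
  tr <- idx(sp$train); va <- idx(sp$val); te <- idx(sp$test)
  wins <- 0
  for (s in 1:5) {
    aware <- train_baseline_nn(enc$x[tr, ], enc$y[tr, ], hidden = 32,
                               x_val = enc$x[va, ], y_val = enc$y[va, ],
                               epochs = 40, seed = s)
    agnostic <- train_baseline_nn(enc0$x[tr, ], enc0$y[tr, ], hidden = 32,
                                  x_val = enc0$x[va, ], y_val = enc0$y[va, ],
                                  epochs = 40, seed = s)
    r_aware <- mean_pearson(predict(aware, enc$x[te, ]), enc$y[te, ])
    r_agn <- mean_pearson(predict(agnostic, enc0$x[te, ]), enc$y[te, ])
    wins <- wins + (r_aware$mean_pearson > r_agn$mean_pearson)
  }
  expect_gte(wins, 4)
})

test_that("grid search selects by validation score and never sees test data", {
  grid <- tibble::tibble(channels = c(2, 4))
  calls <- new.env()
  calls$log <- list()
  train_fn <- function(cfg_row, fold) {
    calls$log <- c(calls$log, list(list(cfg = cfg_row, fold = fold)))
    list(val_pearson = ifelse(cfg_row$channels == 4, 0.6, 0.4),
         config = cfg_row)
  }
  res <- grid_search(grid, train_fn, folds = 1:3)
  expect_identical(nrow(res), 3L)
  expect_true(all(res$channels == 4))
  expect_identical(length(calls$log), 6L)  # every config trained per fold
  # single-point grid returns that config
  res1 <- grid_search(grid[1, ], train_fn, folds = 1)
  expect_identical(res1$channels, 2)
})
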