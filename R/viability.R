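# Beta negative log-likelihood head on frozen expression predictions.
#
# Each ensemble member is a single linear layer from the predicted expression
# vector to two outputs mapped through softplus(.) + 1e-6 to the Beta
# concentration parameters (a, b); members differ by initialization and data
# shuffling. Targets are clipped into (delta, 1 - delta) for NLL stability.

BETA_POS_EPS <- 1e-6
BETA_CLIP <- 1e-4

beta_nll <- function(a, b, y) {
  -((a - 1) * log(y) + (b - 1) * log1p(-y) - lbeta(a, b))
}

#' Train a Beta-likelihood viability ensemble
#'
#' Fits `ensemble_size` probabilistic heads predicting cell viability from
#' the *frozen* expression model's predictions: viability is modeled as
#' `Beta(a, b)` with `(a, b)` produced by a single linear layer plus a
#' positivity transform, trained by the Beta negative log-likelihood with
#' Adam. The expression model's parameters are never updated (it is only
#' ever called through its forward pass).
#'
#' @param expr_model a trained `gsnn_model` / `gsnn_fit` (or `baseline_nn`)
#' @param viability tibble with columns `drug`, `cell_line`, `conc_uM`,
#'   `viability` in `[0, 1]` (values outside are clipped); optional `drug2`,
#'   `conc2_uM` for combinations
#' @param g the structural graph the expression model was built on
#' @param omics wide 'omics tibble for encoding cell-line context
#' @param ensemble_size number of ensemble members
#' @param epochs,batch_size,lr optimizer settings
#' @param seed integer seed; member m uses the derived stream `(seed, m)`
#' @return object of class `viability_ensemble`
#' @export
train_viability_head <- function(expr_model, viability, g, omics,
                                 ensemble_size = 10, epochs = 200,
                                 batch_size = 64, lr = 0.05, seed = 1) {
  viability <- as_tibble(viability)
  obs <- viability |>
    mutate(obs_id = paste0("v", row_number()))
  enc <- encode_observations(obs, g, omics)
  feats <- predict(expr_model, enc$x)          # n x n_outputs, frozen use
  y <- pmin(pmax(viability$viability, 0), 1)   # clip into [0, 1]
  y <- pmin(pmax(y, BETA_CLIP), 1 - BETA_CLIP)
  n <- nrow(feats)
  p <- ncol(feats)

  fit_member <- function(m) {
    mseed <- derive_seed(seed, paste0("viab-member-", m))
    with_seed_(mseed, {
      params <- list(W = matrix(rnorm(2 * p, 0, sqrt(1 / p)), 2, p),
                     b = c(1, 1))
      opt <- adam_state(params)
      for (ep in seq_len(epochs)) {
        perm <- sample.int(n)
        for (bi in split(perm, ceiling(seq_along(perm) / batch_size))) {
          xb <- feats[bi, , drop = FALSE]
          yb <- y[bi]
          pre <- params$W %*% t(xb) + params$b      # 2 x B
          ab <- softplus(pre) + BETA_POS_EPS
          a <- ab[1, ]; b2 <- ab[2, ]
          nll <- beta_nll(a, b2, yb)
          if (any(!is.finite(nll))) abort("non-finite Beta NLL")
          # d nll / d a = -(log y - (digamma(a) - digamma(a+b)))
          dga <- -(log(yb) - (digamma(a) - digamma(a + b2))) / length(bi)
          dgb <- -(log1p(-yb) - (digamma(b2) - digamma(a + b2))) / length(bi)
          dpre <- rbind(dga, dgb) * sigmoid(pre)    # softplus' = sigmoid
          grads <- list(W = dpre %*% xb, b = rowSums(dpre))
          upd <- adam_step(params, grads, opt, lr = lr)
          params <- upd$params
          opt <- upd$state
        }
      }
      params
    })
  }
  members <- map(seq_len(ensemble_size), fit_member)
  structure(list(members = members, n_features = p,
                 feature_names = colnames(feats), seed = seed),
            class = "viability_ensemble")
}

#' @export
print.viability_ensemble <- function(x, ...) {
  cat(sprintf("<viability_ensemble> %d members on %d expression features\n",
              length(x$members), x$n_features))
  invisible(x)
}

member_ab <- function(ensemble, feats) {
  map(ensemble$members, function(p) {
    ab <- softplus(p$W %*% t(feats) + p$b) + BETA_POS_EPS
    list(a = ab[1, ], b = ab[2, ])
  })
}

#' Predict viability Beta mixtures
#'
#' Runs the frozen expression model on the encoded observations and maps each
#' ensemble member to its `(a, b)` Beta concentration pair; the predictive
#' distribution is the uniform mixture over members.
#'
#' @param ensemble a `viability_ensemble`
#' @param expr_model the frozen expression model
#' @param obs observation tibble (`obs_id`, `drug`, `conc_uM`, `cell_line`,
#'   optional `drug2`, `conc2_uM`)
#' @param g structural graph
#' @param omics wide 'omics tibble
#' @return object of class `beta_prediction`: tibble `$params` with columns
#'   `obs_id`, `member`, `a`, `b`, `mean`; `$mixture_mean` (named vector of
#'   per-observation mixture means)
#' @export
predict_viability <- function(ensemble, expr_model, obs, g, omics) {
  obs <- as_tibble(obs)
  enc <- encode_observations(obs, g, omics)
  feats <- predict(expr_model, enc$x)
  abs_ <- member_ab(ensemble, feats)
  params <- imap(abs_, function(ab, m) {
    tibble(obs_id = obs$obs_id, member = m, a = ab$a, b = ab$b,
           mean = ab$a / (ab$a + ab$b))
  }) |> bind_rows()
  mm <- params |>
    group_by(.data$obs_id) |>
    summarise(mean = mean(.data$mean), .groups = "drop")
  structure(list(params = params,
                 mixture_mean = setNames(mm$mean, mm$obs_id)),
            class = "beta_prediction")
}

#' @export
print.beta_prediction <- function(x, ...) {
  cat(sprintf("<beta_prediction> %d observations x %d members\n",
              length(x$mixture_mean), max(x$params$member)))
  invisible(x)
}

#' @method tidy beta_prediction
#' @export
tidy.beta_prediction <- function(x, ...) x$params

#' Prioritization specification
#'
#' @param target_lines cell lines in which a desirable (cytotoxic) response
#'   is sought
#' @param background_lines cell lines that should respond less; disjoint
#'   from the target set
#' @param n_mc Monte Carlo rounds
#' @param seed integer seed
#' @return list of class `prioritization_spec`
#' @export
prioritization_spec <- function(target_lines, background_lines, n_mc = 1000,
                                seed = 1) {
  assert_that_(length(target_lines) > 0 && length(background_lines) > 0,
               "target and background line sets must be nonempty")
  assert_that_(length(intersect(target_lines, background_lines)) == 0,
               "target and background line sets must be disjoint")
  structure(list(target_lines = as.character(target_lines),
                 background_lines = as.character(background_lines),
                 n_mc = as.integer(n_mc), seed = as.integer(seed)),
            class = "prioritization_spec")
}

#' Selective-response probability of a drug
#'
#' Monte Carlo estimate of `P(mean viability over target lines < mean
#' viability over background lines)` under the ensemble's Beta mixture: each
#' round draws, for every line, one ensemble member uniformly and then one
#' viability sample from that member's Beta distribution, and compares the
#' target and background means.
#'
#' @param ensemble a `viability_ensemble`
#' @param expr_model the frozen expression model
#' @param drug drug node name (use `NA` for a no-drug reference)
#' @param dose concentration in micromolar
#' @param spec a [prioritization_spec()]
#' @param g structural graph
#' @param omics wide 'omics tibble
#' @return the estimated probability in `[0, 1]`
#' @export
psens <- function(ensemble, expr_model, drug, dose, spec, g, omics) {
  lines <- c(spec$target_lines, spec$background_lines)
  obs <- tibble(obs_id = paste0("line_", seq_along(lines)),
                drug = drug, conc_uM = dose, cell_line = lines)
  enc <- encode_observations(obs, g, omics)
  feats <- predict(expr_model, enc$x)
  abs_ <- member_ab(ensemble, feats)
  a_mat <- do.call(cbind, map(abs_, "a"))       # lines x members
  b_mat <- do.call(cbind, map(abs_, "b"))
  n_l <- length(lines)
  n_t <- length(spec$target_lines)
  M <- length(ensemble$members)
  with_seed_(derive_seed(spec$seed, paste0("psens-", drug, "-", dose)), {
    pick <- matrix(sample.int(M, spec$n_mc * n_l, replace = TRUE),
                   n_l, spec$n_mc)
    idx <- cbind(rep(seq_len(n_l), spec$n_mc), as.vector(pick))
    draws <- matrix(rbeta(spec$n_mc * n_l, a_mat[idx], b_mat[idx]),
                    n_l, spec$n_mc)
    ybar_t <- colMeans(draws[seq_len(n_t), , drop = FALSE])
    ybar_b <- colMeans(draws[-seq_len(n_t), , drop = FALSE])
    mean(ybar_t < ybar_b)
  })
}

#' Rank drugs by selective-response probability
#'
#' Computes [psens()] for every drug at the given dose and sorts descending
#' (ties broken by drug id for determinism).
#'
#' @inheritParams psens
#' @param drugs character vector of drug node names
#' @return tibble of class `drug_ranking`: `drug`, `p_sens`, `rank`
#' @export
rank_drugs <- function(ensemble, expr_model, drugs, dose, spec, g, omics) {
  assert_that_(length(drugs) > 0, "drug set must be nonempty")
  drugs <- unique(drugs)
  ps <- map_dbl(sort(drugs), function(d) {
    psens(ensemble, expr_model, d, dose, spec, g, omics)
  })
  out <- tibble(drug = sort(drugs), p_sens = ps) |>
    arrange(dplyr::desc(.data$p_sens), .data$drug) |>
    mutate(rank = row_number())
  class(out) <- c("drug_ranking", class(out))
  out
}

#' Plot a drug ranking
#'
#' @param object a `drug_ranking`
#' @param ... ignored
#' @return a ggplot lollipop chart of p_sens by drug
#' @method autoplot drug_ranking
#' @export
autoplot.drug_ranking <- function(object, ...) {
  d <- as_tibble(object) |> mutate(drug = stats::reorder(.data$drug, .data$p_sens))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$p_sens, y = .data$drug)) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$drug),
                          color = "grey70") +
    ggplot2::geom_point() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = expression(p[sens]), y = NULL)
}

#' Evaluate a drug ranking against indication labels
#'
#' AUROC of the `p_sens` scores against binary indication labels (1 = target
#' disease indication), with a permutation null: the p-value is the
#' proportion of `n_null` random score permutations whose AUROC is at least
#' the observed one. Unlabeled drugs are excluded; rankings that are all
#' positive or all negative are an error.
#'
#' @param ranking a `drug_ranking`
#' @param labels named vector (or tibble with `drug`, `label`) mapping drugs
#'   to 0/1
#' @param n_null random permutations for the null distribution
#' @param seed integer seed
#' @return tibble with `auroc`, `p_value`, `n_pos`, `n_neg`
#' @export
evaluate_ranking_auroc <- function(ranking, labels, n_null = 1000, seed = 1) {
  if (is.data.frame(labels)) {
    labels <- setNames(labels$label, labels$drug)
  }
  r <- as_tibble(ranking) |> filter(.data$drug %in% names(labels))
  lab <- as.numeric(labels[r$drug])
  assert_that_(all(lab %in% c(0, 1)), "labels must be 0/1")
  n_pos <- sum(lab == 1)
  n_neg <- sum(lab == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("need at least one positive and one negative label")
  }
  score_auroc <- function(score) {
    # Mann-Whitney formulation; ties share credit
    rk <- rank(score)
    (sum(rk[lab == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  obs <- score_auroc(r$p_sens)
  null <- with_seed_(derive_seed(seed, "auroc-null"), {
    vapply(seq_len(n_null), function(i) score_auroc(sample(r$p_sens)),
           numeric(1))
  })
  tibble(auroc = obs, p_value = mean(null >= obs),
         n_pos = n_pos, n_neg = n_neg)
}
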