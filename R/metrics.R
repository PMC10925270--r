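#' Mean Pearson correlation over output genes
#'
#' Computes the Pearson correlation per output column across observations and
#' averages over columns. Columns with zero variance in either matrix are
#' skipped (their count is reported); if no column has variance, an error is
#' raised.
#'
#' @param yhat,y matrices (observations x outputs) of predictions and targets
#' @return list of class `metrics_report`: `mean_pearson`,
#'   `per_output_pearson` (named vector), `n_skipped`
#' @export
mean_pearson <- function(yhat, y) {
  assert_that_(all(dim(yhat) == dim(y)), "yhat and y must have equal shape")
  assert_that_(nrow(y) >= 2, "need at least 2 observations")
  sds_a <- apply(yhat, 2, sd)
  sds_b <- apply(y, 2, sd)
  ok <- sds_a > 0 & sds_b > 0
  if (!any(ok)) abort("all output columns have zero variance")
  r <- rep(NA_real_, ncol(y))
  r[ok] <- vapply(which(ok), function(j) cor(yhat[, j], y[, j]), numeric(1))
  if (!is.null(colnames(y))) names(r) <- colnames(y)
  structure(list(mean_pearson = mean(r[ok]),
                 per_output_pearson = r,
                 n_skipped = sum(!ok)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> mean pearson %.4f over %d outputs (%d skipped)\n",
              x$mean_pearson, sum(!is.na(x$per_output_pearson)), x$n_skipped))
  invisible(x)
}

#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) {
  tibble(output = names(x$per_output_pearson) %||%
           as.character(seq_along(x$per_output_pearson)),
         pearson = unname(x$per_output_pearson))
}

#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble(mean_pearson = x$mean_pearson, n_skipped = x$n_skipped)
}

#' Paired t-test across folds with Bonferroni adjustment
#'
#' Two-sided paired t-test on per-fold scores of two methods; the adjusted
#' p-value is `min(1, p * n_tests)`.
#'
#' @param scores_a,scores_b equal-length numeric vectors of per-fold scores
#' @param n_tests number of comparisons performed in the run
#' @return tibble with `t`, `df`, `p_value`, `p_adjusted`,
#'   `zero_variance` flag (p is NA when the paired differences have zero
#'   variance)
#' @export
paired_test <- function(scores_a, scores_b, n_tests = 1) {
  assert_that_(length(scores_a) == length(scores_b) && length(scores_a) >= 2,
               "score vectors must have equal length >= 2")
  d <- scores_a - scores_b
  n <- length(d)
  if (sd(d) == 0) {
    return(tibble(t = NA_real_, df = n - 1, p_value = NA_real_,
                  p_adjusted = NA_real_, zero_variance = TRUE))
  }
  tt <- mean(d) / (sd(d) / sqrt(n))
  p <- 2 * pt(abs(tt), df = n - 1, lower.tail = FALSE)
  tibble(t = tt, df = n - 1, p_value = p,
         p_adjusted = min(1, p * n_tests), zero_variance = FALSE)
}

#' Grouped local-performance comparison with FDR control
#'
#' Compares two methods' per-group scores across MCCV folds: for each group
#' label, the mean score per method is computed and a paired two-sided t-test
#' across folds is performed; p-values are adjusted across groups with the
#' Benjamini-Hochberg or Benjamini-Yekutieli procedure. Groups with fewer
#' than `min_group_size` observations in any fold are dropped.
#'
#' @param scores tibble with columns `fold`, `group`, `method`, `score`,
#'   `n_obs` (observations behind each score)
#' @param min_group_size minimum per-fold group size
#' @param fdr_method `"BH"` or `"BY"`
#' @param fdr_threshold FDR level used to set the `significant` flag
#' @return tibble: one row per group with per-method mean scores, `t`,
#'   `p_value`, `q_value`, `significant`
#' @export
grouped_performance <- function(scores, min_group_size = 5,
                                fdr_method = c("BH", "BY"),
                                fdr_threshold = 0.1) {
  fdr_method <- match.arg(fdr_method)
  scores <- as_tibble(scores)
  methods <- unique(scores$method)
  assert_that_(length(methods) == 2, "exactly two methods are compared")
  assert_that_(length(unique(scores$fold)) >= 2, "need at least 2 folds")

  keep <- scores |>
    group_by(.data$group) |>
    summarise(min_n = min(.data$n_obs), .groups = "drop") |>
    filter(.data$min_n >= min_group_size) |>
    pull("group")
  scores <- scores |> filter(.data$group %in% keep)
  if (nrow(scores) == 0) {
    warn("no groups survive the minimum-size filter")
    return(tibble(group = character(), p_value = numeric(),
                  q_value = numeric()))
  }
  wide <- scores |>
    tidyr::pivot_wider(id_cols = c("group", "fold"), names_from = "method",
                       values_from = "score")
  res <- wide |>
    group_by(.data$group) |>
    summarise(
      mean_a = mean(.data[[methods[1]]]),
      mean_b = mean(.data[[methods[2]]]),
      test = list(paired_test(.data[[methods[1]]], .data[[methods[2]]])),
      .groups = "drop") |>
    tidyr::unnest("test") |>
    select(-"p_adjusted", -"zero_variance")
  names(res)[names(res) == "mean_a"] <- paste0("mean_", methods[1])
  names(res)[names(res) == "mean_b"] <- paste0("mean_", methods[2])
  res$q_value <- p.adjust(res$p_value, method = fdr_method)
  res$significant <- !is.na(res$q_value) & res$q_value < fdr_threshold
  res
}

#' Grid search with per-fold selection on validation score
#'
#' Trains one model per configuration in the grid and selects, within each
#' fold, the configuration with the best validation mean-Pearson. Test data
#' are never seen by this function.
#'
#' @param grid a tibble (or data frame) whose columns are hyperparameter
#'   names and rows are candidate configurations
#' @param train_fn function(config_row, fold_id) returning a list with at
#'   least `val_pearson` (and anything else, e.g. the fitted model)
#' @param folds vector of fold identifiers
#' @return tibble with one row per fold: `fold`, the selected configuration
#'   columns, `val_pearson`, and a `result` list-column with `train_fn`'s
#'   full return value
#' @export
grid_search <- function(grid, train_fn, folds) {
  grid <- as_tibble(grid)
  assert_that_(nrow(grid) >= 1, "grid must be nonempty")
  out <- map(folds, function(f) {
    fits <- map(seq_len(nrow(grid)), function(i) train_fn(grid[i, ], f))
    val <- map_dbl(fits, "val_pearson")
    best <- which.max(val)
    bind_cols(tibble(fold = f), grid[best, ],
              tibble(val_pearson = val[best], result = list(fits[[best]])))
  })
  bind_rows(out)
}
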