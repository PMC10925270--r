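#' @importFrom rlang abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange left_join anti_join semi_join
#'   bind_rows bind_cols distinct group_by summarise ungroup pull n rename
#'   row_number case_when
#'   across all_of
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_int map_lgl map2 imap pmap keep walk
#' @importFrom stats rnorm runif rbinom rbeta sd var cor pt qt p.adjust
#'   setNames complete.cases
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Scoped RNG: every stochastic entry point takes an explicit seed and runs
# under an isolated RNG state so callers' streams are never disturbed.
with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a named sub-stream seed from a global seed (kept < 2^31).
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

assert_that_ <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

#' Elementwise exponential linear unit
#' @param x numeric vector or matrix
#' @param alpha saturation scale for negative inputs
#' @return object shaped like `x`
#' @keywords internal
elu <- function(x, alpha = 1) {
  ifelse(x > 0, x, alpha * (exp(pmin(x, 0)) - 1))
}

elu_grad <- function(x, alpha = 1) {
  ifelse(x > 0, 1, alpha * exp(pmin(x, 0)))
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

activation_fun <- function(name) {
  switch(name,
    elu = list(f = elu, grad = elu_grad),
    tanh = list(f = tanh, grad = function(x) 1 - tanh(x)^2),
    relu = list(f = function(x) pmax(x, 0), grad = function(x) (x > 0) * 1),
    abort(paste0("unknown activation: ", name))
  )
}
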