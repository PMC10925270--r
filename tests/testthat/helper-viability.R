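# Stub expression models and hand-built ensembles for head/prioritization
# tests (S3 methods are picked up from the test environment).

# expression model that ignores everything: three all-zero features
predict.zero_expr <- function(object, x, ...) {
  matrix(0, nrow(x), 3, dimnames = list(NULL, paste0("f", 1:3)))
}
zero_expr_model <- function() structure(list(), class = "zero_expr")
registerS3method("predict", "zero_expr", predict.zero_expr,
                 envir = asNamespace("stats"))

# expression model that exposes the EXPR_p2 'omic value as its one feature
predict.omic_expr <- function(object, x, ...) {
  matrix(x[, "EXPR_p2"], ncol = 1, dimnames = list(NULL, "f1"))
}
omic_expr_model <- function() structure(list(), class = "omic_expr")
registerS3method("predict", "omic_expr", predict.omic_expr,
                 envir = asNamespace("stats"))

softplus_inv <- function(y) log(expm1(y))

# ensemble member with constant Beta parameters (softplus(b) ~= target)
const_member <- function(a, b, p = 3) {
  list(W = matrix(0, 2, p), b = c(softplus_inv(a), softplus_inv(b)))
}

make_ensemble <- function(members, p = 3) {
  structure(list(members = members, n_features = p,
                 feature_names = paste0("f", seq_len(p)), seed = 1),
            class = "viability_ensemble")
}

# member mapping feature f = +1 to Beta(a_hi, b_hi) and f = -1 to the
# reverse, by solving the linear pre-activations through softplus
switch_member <- function(a_pos, b_pos, a_neg, b_neg) {
  wa <- (softplus_inv(a_pos) - softplus_inv(a_neg)) / 2
  ba <- (softplus_inv(a_pos) + softplus_inv(a_neg)) / 2
  wb <- (softplus_inv(b_pos) - softplus_inv(b_neg)) / 2
  bb <- (softplus_inv(b_pos) + softplus_inv(b_neg)) / 2
  list(W = matrix(c(wa, wb), 2, 1), b = c(ba, bb))
}

viability_graph <- function() small_graph()

viability_omics <- function(lines_pos = c("T1", "T2"),
                            lines_neg = c("B1", "B2", "B3")) {
  tibble::tibble(cell_line = c(lines_pos, lines_neg),
                 EXPR_p2 = c(rep(1, length(lines_pos)),
                             rep(-1, length(lines_neg))))
}
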