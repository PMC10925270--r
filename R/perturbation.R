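#' Log-linear drug dose transformation
#'
#' Maps a concentration in micromolar to the unit scale used on drug input
#' nodes: `x = -(log10(c + eps) - log10(eps)) / log10(eps)`. With the default
#' `eps = 1e-6`, 0 uM maps to exactly 0 and 1 uM maps to 1, and the transform
#' is approximately linear in log10 concentration over the therapeutically
#' relevant range. Strictly increasing in concentration.
#'
#' @param conc_uM non-negative concentration(s) in micromolar
#' @param eps positive shift controlling where the log-linear range sits
#' @return transformed dose value(s)
#' @export
transform_dose <- function(conc_uM, eps = 1e-6) {
  assert_that_(all(eps > 0), "eps must be positive")
  if (any(conc_uM < 0)) abort("negative concentration")
  -(log10(conc_uM + eps) - log10(eps)) / log10(eps)
}

#' Encode observations as model input matrices
#'
#' Builds the input matrix (observations x input nodes) and, when a target
#' table is given, the output matrix (observations x output nodes). Drug
#' concentrations pass through [transform_dose()]; 'omic values are placed
#' untransformed. Positions not mentioned by an observation are zero. Two-drug
#' combinations (columns `drug2`, `conc2_uM`) set two drug positions
#' simultaneously.
#'
#' @param obs tibble with columns `obs_id`, `drug`, `conc_uM`, `cell_line`
#'   (optional `drug2`, `conc2_uM`; `drug` may be NA for no-drug controls)
#' @param g a `structural_graph`
#' @param omics wide tibble: `cell_line` column plus one column per 'omic
#'   input node (may be `NULL` if the graph has no 'omic inputs)
#' @param targets optional wide tibble: `obs_id` column plus one column per
#'   output node
#' @param cell_agnostic if `TRUE`, all non-DRUG input positions are zeroed
#'   (removes cellular context; used by the cell-agnostic baseline)
#' @param eps dose transform epsilon
#' @return list with `x` (n_obs x n_inputs matrix, columns named by input
#'   node), `y` (n_obs x n_outputs matrix or NULL), and `meta` (the obs tibble)
#' @export
encode_observations <- function(obs, g, omics = NULL, targets = NULL,
                                cell_agnostic = FALSE, eps = 1e-6) {
  obs <- as_tibble(obs)
  in_nodes <- input_nodes(g)
  node_cls <- setNames(g$nodes$entity_class, g$nodes$name)
  x <- matrix(0, nrow(obs), length(in_nodes),
              dimnames = list(obs$obs_id, in_nodes))

  put_drug <- function(x, drugs, concs) {
    use <- !is.na(drugs) & drugs != ""
    if (!any(use)) return(x)
    unknown <- setdiff(unique(drugs[use]), in_nodes)
    if (length(unknown) > 0) {
      abort(paste0("drug not an input node of the graph: ",
                   paste(unknown, collapse = ", ")))
    }
    not_drug <- unique(drugs[use][node_cls[drugs[use]] != "DRUG"])
    if (length(not_drug) > 0) {
      abort(paste0("dose given for non-DRUG node: ",
                   paste(not_drug, collapse = ", ")))
    }
    x[cbind(which(use), match(drugs[use], in_nodes))] <-
      transform_dose(concs[use], eps)
    x
  }
  x <- put_drug(x, obs$drug, obs$conc_uM)
  if ("drug2" %in% names(obs)) {
    x <- put_drug(x, obs$drug2, obs$conc2_uM)
  }

  if (!cell_agnostic && !is.null(omics)) {
    om_nodes <- intersect(names(omics), in_nodes)
    if (length(om_nodes) > 0) {
      row <- match(obs$cell_line, omics$cell_line)
      if (anyNA(row)) {
        abort(paste0("cell line missing from omics table: ",
                     paste(unique(obs$cell_line[is.na(row)]), collapse = ", ")))
      }
      x[, om_nodes] <- as.matrix(omics[row, om_nodes, drop = FALSE])
    }
  }

  y <- NULL
  if (!is.null(targets)) {
    out_nodes <- output_nodes(g)
    missing_out <- setdiff(out_nodes, names(targets))
    if (length(missing_out) > 0) {
      abort(paste0("target table missing output node column(s): ",
                   paste(missing_out, collapse = ", ")))
    }
    row <- match(obs$obs_id, targets$obs_id)
    y <- as.matrix(targets[row, out_nodes, drop = FALSE])
    rownames(y) <- obs$obs_id
  }
  list(x = x, y = y, meta = obs)
}

#' Monte Carlo cross-validation split over (drug, cell line) pairs
#'
#' Shuffles the distinct pairs under `seed` and assigns `floor(frac * n)`
#' pairs to validation and test, with the remainder going to train, so all
#' observations sharing a (drug, cell line) pair land in the same partition.
#'
#' @param pairs tibble with columns `drug`, `cell_line` (other columns
#'   ignored; duplicated pairs collapsed)
#' @param fractions numeric length-3 (train, val, test), summing to 1
#' @param seed integer seed
#' @return list of tibbles `train`, `val`, `test` (columns drug, cell_line),
#'   disjoint with union equal to the distinct input pairs
#' @export
mccv_split <- function(pairs, fractions = c(0.6, 0.2, 0.2), seed = 1) {
  pairs <- as_tibble(pairs) |> distinct(.data$drug, .data$cell_line)
  n <- nrow(pairs)
  if (n == 0) abort("empty pair set")
  if (n < 5) abort("need at least 5 (drug, cell line) pairs")
  assert_that_(length(fractions) == 3 && abs(sum(fractions) - 1) < 1e-8,
               "fractions must be length 3 and sum to 1")
  perm <- with_seed_(seed, sample.int(n))
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  val_idx <- perm[seq_len(n_val)]
  test_idx <- perm[n_val + seq_len(n_test)]
  train_idx <- perm[-seq_len(n_val + n_test)]
  list(train = pairs[sort(train_idx), ],
       val = pairs[sort(val_idx), ],
       test = pairs[sort(test_idx), ])
}

#' Restrict observations to one MCCV partition
#'
#' @param obs observation tibble with `drug`, `cell_line` columns
#' @param part one element of the list returned by [mccv_split()]
#' @return the rows of `obs` whose (drug, cell line) pair is in `part`
#' @export
filter_split <- function(obs, part) {
  semi_join(as_tibble(obs), part, by = c("drug", "cell_line"))
}
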