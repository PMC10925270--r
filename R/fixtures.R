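#' Synthetic fixture specification
#'
#' Controls the deterministic generators that emulate every input the other
#' modules consume: toy interaction tables, simulated perturbation responses
#' propagated through a known graph, and viability/indication tables with a
#' planted selective drug. Every generator is a pure function of its seed.
#'
#' @param n_drugs,n_proteins,n_rnas,n_lincs,n_cell_lines fixture sizes
#' @param edge_density probability of optional interaction edges, in (0, 1]
#' @param noise_sd Gaussian noise added to simulated targets
#' @param n_doses_reps replicate observations per (drug, cell, dose)
#' @param seed integer master seed
#' @param planted list of flags: `selective_drug` plants a drug whose
#'   expression response (and hence cytotoxicity) is confined to the first
#'   two cell lines; `planted_path` is realized by
#'   [planted_path_instance()]
#' @return list of class `fixture_spec`
#' @export
fixture_spec <- function(n_drugs = 6, n_proteins = 12, n_rnas = 10,
                         n_lincs = 6, n_cell_lines = 5, edge_density = 0.15,
                         noise_sd = 0.05, n_doses_reps = 2, seed = 1,
                         planted = list(selective_drug = FALSE)) {
  assert_that_(all(c(n_drugs, n_proteins, n_rnas, n_lincs, n_cell_lines) >= 1),
               "fixture sizes must be >= 1")
  assert_that_(edge_density > 0 && edge_density <= 1,
               "edge_density must be in (0, 1]")
  assert_that_(noise_sd >= 0, "noise_sd must be non-negative")
  structure(list(n_drugs = n_drugs, n_proteins = n_proteins,
                 n_rnas = n_rnas, n_lincs = n_lincs,
                 n_cell_lines = n_cell_lines, edge_density = edge_density,
                 noise_sd = noise_sd, n_doses_reps = n_doses_reps,
                 seed = as.integer(seed), planted = planted),
            class = "fixture_spec")
}

fixture_ids <- function(prefix, n) sprintf("%s%02d", prefix, seq_len(n))

#' Generate toy interaction tables
#'
#' Random drug-target, protein-protein (cycles allowed), TF-regulation,
#' miRNA-regulation and translation tables with two pathway labels
#' (`P1` = all proteins, `P2` = the first half), a measurable-RNA list
#' covering the first `n_lincs` RNAs, and EXPR 'omic features for every
#' entity. A protein backbone chain plus the guarantee that the first drug
#' targets the chain head ensures at least one drug reaches at least a
#' quarter of the measurable outputs, so default pruning always retains a
#' drug.
#'
#' @param spec a [fixture_spec()]
#' @return an [interaction_tables()]
#' @export
generate_interaction_tables <- function(spec) {
  pro <- fixture_ids("pro", spec$n_proteins)
  rna <- fixture_ids("rna", spec$n_rnas)
  drg <- fixture_ids("drg", spec$n_drugs)
  dens <- spec$edge_density
  with_seed_(derive_seed(spec$seed, "tables"), {
    # drug targets: every (drug, protein) pair with prob = density, plus a
    # guaranteed target per drug; drug 1 hits the chain head
    dt <- tidyr::crossing(drug = drg, protein = pro) |>
      filter(runif(n()) < dens)
    guaranteed <- tibble(
      drug = drg,
      protein = c(pro[1], sample(pro, spec$n_drugs - 1, replace = TRUE)))
    dt <- bind_rows(dt, guaranteed) |> distinct() |> arrange(.data$drug, .data$protein)

    # PPI: backbone chain plus random extra directed pairs (cycles allowed)
    chain <- tibble(source = pro[-spec$n_proteins], target = pro[-1])
    extra <- tidyr::crossing(source = pro, target = pro) |>
      filter(.data$source != .data$target, runif(n()) < dens)
    ppi <- bind_rows(chain, extra) |> distinct() |> arrange(.data$source, .data$target)

    # TF regulation: each RNA gets at least one regulator
    tf <- tidyr::crossing(protein = pro, rna = rna) |>
      filter(runif(n()) < dens)
    tf <- bind_rows(tf, tibble(protein = sample(pro, spec$n_rnas,
                                                replace = TRUE), rna = rna)) |>
      distinct() |> arrange(.data$protein, .data$rna)

    mir <- tidyr::crossing(source = rna, target = rna) |>
      filter(.data$source != .data$target, runif(n()) < dens / 3) |>
      arrange(.data$source, .data$target)

    trl <- tibble(rna = rna[seq_len(max(1, spec$n_rnas %/% 4))]) |>
      mutate(protein = sample(pro, n(), replace = TRUE)) |>
      distinct() |> arrange(.data$rna, .data$protein)

    pw <- bind_rows(tibble(pathway = "P1", protein = pro),
                    tibble(pathway = "P2",
                           protein = pro[seq_len(ceiling(spec$n_proteins / 2))]))

    om <- tibble(omic_class = "EXPR", entity = c(pro, rna))

    interaction_tables(
      drug_target = dt, ppi = ppi, tf_regulation = tf,
      mirna_regulation = mir, translation = trl, pathway_membership = pw,
      available_lincs = rna[seq_len(spec$n_lincs)], available_omics = om)
  })
}

#' Build the default fixture graph
#'
#' Convenience wrapper: generates interaction tables and runs the builder
#' with both pathways at depth 2 and the default pruning fraction.
#'
#' @param spec a [fixture_spec()]
#' @return a `structural_graph`
#' @export
fixture_graph <- function(spec = fixture_spec()) {
  tabs <- generate_interaction_tables(spec)
  suppressMessages(
    build_subgraph(tabs, builder_params(pathways = c("P1", "P2"),
                                        rna_descendant_depth = 2)))
}

# Ground-truth dynamics assigned to a graph: per function node a random
# linear read-out squashed by tanh, with a per-cell gain driven by the
# node's EXPR 'omic feature. Edges arriving straight from drug nodes get
# weights of guaranteed magnitude so perturbations register above the
# omics-driven background. Independent of the model's forward pass.
fixture_dynamics <- function(g, seed, planted_drug = NULL) {
  fn_idx <- which(g$nodes$role == "function")
  drug_idx <- which(g$nodes$entity_class == "DRUG")
  planted_idx <- if (!is.null(planted_drug)) {
    which(g$nodes$name == planted_drug)
  } else integer()
  with_seed_(derive_seed(seed, "dynamics"), {
    map(fn_idx, function(i) {
      idx_in <- which(g$edges$tgt_index == i)
      idx_out <- which(g$edges$src_index == i)
      w <- rnorm(length(idx_in), 0, 1.4 / sqrt(max(1, length(idx_in))))
      from_drug <- g$edges$src_index[idx_in] %in% drug_idx
      if (any(from_drug)) {
        w[from_drug] <- sample(c(-1, 1), sum(from_drug), replace = TRUE) *
          runif(sum(from_drug), 1.5, 2.5)
      }
      # the planted selective drug hits its targets with a fixed strong
      # positive weight so its response never cancels
      from_planted <- g$edges$src_index[idx_in] %in% planted_idx
      w[from_planted] <- 2.5
      list(idx_in = idx_in, idx_out = idx_out,
           name = g$nodes$name[i], w = w,
           u = runif(length(idx_out), 0.6, 1.4) *
             sample(c(-1, 1), length(idx_out), replace = TRUE))
    })
  })
}

# Synchronous propagation of encoded inputs through the ground-truth
# dynamics; cycles are unrolled a fixed number of steps.
propagate_fixture <- function(g, dyn, x_row, gains, unroll = 10) {
  E <- nrow(g$edges)
  state <- numeric(E)
  in_pos <- which(g$edges$edge_class == "input_edge")
  in_nodes_idx <- match(input_nodes(g), g$nodes$name)
  src_in <- match(g$edges$src_index[in_pos], in_nodes_idx)
  state[in_pos] <- x_row[src_in]
  for (s in seq_len(unroll)) {
    nxt <- state
    for (k in seq_along(dyn)) {
      d <- dyn[[k]]
      v <- tanh(gains[[d$name]] * sum(d$w * state[d$idx_in]))
      nxt[d$idx_out] <- d$u * v
    }
    nxt[in_pos] <- state[in_pos]
    state <- nxt
  }
  state
}

#' Simulate perturbation responses through a known graph
#'
#' Assigns each function node a random smooth scalar function (linear map
#' squashed by tanh with a per-cell-line gain driven by the node's EXPR
#' feature), encodes each observation's inputs, propagates synchronously for
#' `unroll` steps, and adds Gaussian noise with sd `spec$noise_sd` to the
#' output-edge values. When `spec$planted$selective_drug` is set, the first
#' drug's input signal is suppressed outside the first two cell lines, so
#' its expression response is selective by construction.
#'
#' @param g a `structural_graph`
#' @param spec a [fixture_spec()]
#' @param doses concentrations (uM) crossed with every (drug, cell) pair;
#'   dose 0 rows serve as unperturbed controls
#' @param unroll propagation steps used to unroll cycles
#' @param dyn optional precomputed ground-truth dynamics (used by
#'   [planted_path_instance()] to pin the planted chain's weights); defaults
#'   to random dynamics derived from `spec$seed`
#' @return list: `observations` (obs_id, drug, conc_uM, cell_line),
#'   `targets` (wide, obs_id x output node), `omics` (wide, cell_line x
#'   'omic node, standardized per feature), `baseline` (cell_line x output
#'   matrix of zero-dose responses), `active_edges` (per drug, the edge
#'   indices reachable from it), `target_lines` / `planted_drug` when a
#'   selective drug is planted
#' @export
simulate_responses <- function(g, spec, doses = c(0, 0.1, 1, 10),
                               unroll = 10, dyn = NULL) {
  drugs_all <- g$nodes$name[g$nodes$entity_class == "DRUG"]
  if (is.null(dyn)) {
    dyn <- fixture_dynamics(
      g, spec$seed,
      planted_drug = if (isTRUE(spec$planted$selective_drug)) drugs_all[1])
  }
  cells <- fixture_ids("cell", spec$n_cell_lines)
  om_nodes <- g$nodes |>
    filter(.data$role == "input", .data$entity_class != "DRUG") |>
    pull("name")
  drugs <- g$nodes |>
    filter(.data$entity_class == "DRUG") |> pull("name")
  out_nodes <- output_nodes(g)

  omics <- with_seed_(derive_seed(spec$seed, "omics"), {
    m <- matrix(rnorm(length(cells) * length(om_nodes)), length(cells))
    if (length(cells) > 1) m <- scale(m)         # standardized per feature
    colnames(m) <- om_nodes
    bind_cols(tibble(cell_line = cells), as_tibble(m))
  })

  # per-cell gain of node n: 1 + 0.4 * its EXPR feature (1 where absent);
  # the gain couples each node's behavior to its own 'omic context, so
  # drug responses carry structured drug-by-cell interactions
  fn_names <- map(dyn, "name")
  gains_by_cell <- map(seq_along(cells), function(ci) {
    gg <- setNames(rep(1, length(dyn)), unlist(fn_names))
    for (nm in names(gg)) {
      feat <- paste0("EXPR_", sub("^(PROTEIN|RNA)_", "", nm))
      if (feat %in% om_nodes) gg[nm] <- 1 + 0.4 * omics[[feat]][ci]
    }
    gg
  })

  planted_drug <- NULL
  target_lines <- NULL
  if (isTRUE(spec$planted$selective_drug)) {
    planted_drug <- drugs[1]
    target_lines <- cells[seq_len(min(2, length(cells)))]
  }

  obs <- tidyr::crossing(drug = drugs, cell_line = cells, conc_uM = doses,
                         rep = seq_len(spec$n_doses_reps)) |>
    mutate(obs_id = sprintf("obs%04d", row_number())) |>
    select("obs_id", "drug", "conc_uM", "cell_line", "rep")

  enc <- encode_observations(obs, g, omics)
  x <- enc$x
  if (!is.null(planted_drug)) {
    off <- !(obs$cell_line %in% target_lines)
    x[off, planted_drug] <- 0
  }

  ci <- match(obs$cell_line, cells)
  oe_idx <- output_edge_index(g)
  y <- matrix(NA_real_, nrow(obs), length(out_nodes),
              dimnames = list(obs$obs_id, out_nodes))
  for (i in seq_len(nrow(obs))) {
    st <- propagate_fixture(g, dyn, x[i, ], gains_by_cell[[ci[i]]], unroll)
    y[i, ] <- st[oe_idx]
  }
  if (spec$noise_sd > 0) {
    y <- y + with_seed_(derive_seed(spec$seed, "noise"), {
      matrix(rnorm(length(y), 0, spec$noise_sd), nrow(y))
    })
  }

  baseline <- matrix(NA_real_, length(cells), length(out_nodes),
                     dimnames = list(cells, out_nodes))
  x0 <- enc$x * 0
  om_cols <- intersect(colnames(x0), om_nodes)
  for (ci0 in seq_along(cells)) {
    row <- x0[1, ]
    row[om_cols] <- as.numeric(omics[ci0, om_cols])
    baseline[ci0, ] <-
      propagate_fixture(g, dyn, row, gains_by_cell[[ci0]], unroll)[oe_idx]
  }

  active_edges <- map(setNames(drugs, drugs), function(d) {
    desc <- descendants(g, d)
    which(g$edges$source %in% c(d, desc))
  })

  list(observations = obs |> select(-"rep"),
       targets = bind_cols(tibble(obs_id = obs$obs_id), as_tibble(y)),
       omics = omics, baseline = baseline, active_edges = active_edges,
       planted_drug = planted_drug, target_lines = target_lines)
}

#' Planted-path explanation instance
#'
#' Constructs a graph in which exactly one directed drug -> ... -> output
#' path carries the drug's effect: the planted chain of `path_length`
#' function nodes links the single drug to one output, while a disjoint
#' decoy chain (driven only by 'omic inputs) feeds a second output. Every
#' function node also has an EXPR input, so all edges carry omics-driven
#' activity, but drug signal exists only on the planted path by
#' construction. Simulated responses and the planted edge indices are
#' returned ready for explainer recovery experiments.
#'
#' @param seed integer seed
#' @param path_length number of function nodes on the planted path (2-6)
#' @param n_cell_lines,noise_sd,n_doses_reps passed to the simulation
#' @return list: `graph`, `sim` (as [simulate_responses()]), `planted_edges`
#'   (integer indices into `graph$edges`), `drug`
#' @export
planted_path_instance <- function(seed = 1, path_length = 3,
                                  n_cell_lines = 4, noise_sd = 0.02,
                                  n_doses_reps = 2) {
  assert_that_(path_length >= 2 && path_length <= 6,
               "path_length must be in 2..6")
  chain <- c(paste0("PROTEIN_main", seq_len(path_length - 1)), "RNA_main")
  decoy <- c(paste0("PROTEIN_dec", seq_len(2)), "RNA_dec")
  nodes <- bind_rows(
    tibble(name = "drgX", entity_class = "DRUG"),
    tibble(name = c(chain, decoy),
           entity_class = ifelse(startsWith(c(chain, decoy), "RNA"),
                                 "RNA", "PROTEIN")),
    tibble(name = c("LINCS_main", "LINCS_dec"), entity_class = "LINCS"),
    tibble(name = paste0("EXPR_", sub("^(PROTEIN|RNA)_", "", c(chain, decoy))),
           entity_class = "EXPR")
  )
  path_edges <- tibble(source = c("drgX", chain),
                       target = c(chain, "LINCS_main"))
  decoy_edges <- tibble(source = decoy, target = c(decoy[-1], "LINCS_dec"))
  omic_edges <- tibble(
    source = paste0("EXPR_", sub("^(PROTEIN|RNA)_", "", c(chain, decoy))),
    target = c(chain, decoy))
  g <- structural_graph(nodes,
                        bind_rows(path_edges, decoy_edges, omic_edges))
  spec <- fixture_spec(n_drugs = 1, n_cell_lines = n_cell_lines,
                       noise_sd = noise_sd, n_doses_reps = n_doses_reps,
                       seed = seed)
  # pin the planted chain's dynamics to a high positive gain so the drug
  # response on the planted output is strong and unambiguous
  dyn <- fixture_dynamics(g, seed)
  for (k in seq_along(dyn)) {
    if (dyn[[k]]$name %in% chain) {
      src_cls <- g$nodes$entity_class[g$edges$src_index[dyn[[k]]$idx_in]]
      dyn[[k]]$w <- ifelse(src_cls %in% c("DRUG", "PROTEIN", "RNA"), 1.5, 0.3)
      dyn[[k]]$u <- rep(1, length(dyn[[k]]$idx_out))
    }
  }
  sim <- simulate_responses(g, spec, dyn = dyn)
  planted <- which(paste(g$edges$source, g$edges$target) %in%
                     paste(path_edges$source, path_edges$target))
  list(graph = g, sim = sim, planted_edges = planted, drug = "drgX")
}

#' Generate viability and indication tables with a planted selective drug
#'
#' Viability is drawn from Beta distributions whose mean is a logistic
#' function of the simulated expression shift (mean absolute deviation of
#' the observation's targets from the cell line's zero-dose baseline,
#' normalized by the dataset's upper-quantile shift). With a planted
#' selective drug in `sim`, that drug shifts expression only in the target
#' lines, so its viability drops there by a construction margin of at least
#' 0.3 at saturating dose while background lines are spared. The indication
#' table labels the planted drug with the target disease and every other
#' drug with the background disease.
#'
#' @param spec a [fixture_spec()]
#' @param g the `structural_graph` used for `sim`
#' @param sim result of [simulate_responses()] with
#'   `planted$selective_drug = TRUE`
#' @param concentration_k Beta concentration (a + b); larger is less noisy
#' @return list: `viability` (drug, cell_line, conc_uM, viability),
#'   `indications` (drug, disease), `target_disease`
#' @export
generate_viability <- function(spec, g, sim, concentration_k = 60) {
  assert_that_(!is.null(sim$planted_drug),
               "sim must be generated with planted$selective_drug = TRUE")
  obs <- sim$observations
  y <- as.matrix(sim$targets[, -1, drop = FALSE])
  base <- sim$baseline[obs$cell_line, , drop = FALSE]
  shift <- rowMeans(abs(y - base))
  # non-planted drugs are non-selective by construction: their shift is
  # pooled within (drug, dose) across cell lines, so only the planted drug
  # carries a cell-line-dependent cytotoxicity signal
  pooled <- stats::ave(shift, obs$drug, obs$conc_uM)
  shift <- ifelse(obs$drug == sim$planted_drug, shift, pooled)
  ref <- stats::quantile(shift[shift > 0], 0.9)
  shift_n <- pmin(shift / max(ref, 1e-8), 1.5)
  mean_v <- stats::plogis(1.6 - 3.8 * shift_n)
  viab <- with_seed_(derive_seed(spec$seed, "viability"), {
    rbeta(length(mean_v), mean_v * concentration_k,
          (1 - mean_v) * concentration_k)
  })
  viability <- obs |>
    mutate(viability = pmin(pmax(viab, 0), 1)) |>
    select("drug", "cell_line", "conc_uM", "viability")
  drugs <- unique(obs$drug)
  indications <- tibble(
    drug = drugs,
    disease = ifelse(drugs == sim$planted_drug, "disease_target",
                     "disease_background"))
  list(viability = viability, indications = indications,
       target_disease = "disease_target")
}
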