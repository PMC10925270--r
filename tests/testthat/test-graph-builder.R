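# The printed toy from the construction procedure: pathway P1 = {p1, p2};
# p1 -> p2 PPI; p2 -> r1 TF; drug d1 -> p1; drug d2 -> p3 (outside P1);
# r1 measurable. Hand-traced expectation: d1, p1, p2, r1 and the output
# survive; d2 and p3 are excluded; 4 edges.
toy_tables <- function() {
  interaction_tables(
    drug_target = tibble::tibble(drug = c("d1", "d2"),
                                 protein = c("p1", "p3")),
    ppi = tibble::tibble(source = "p1", target = "p2"),
    tf_regulation = tibble::tibble(protein = "p2", rna = "r1"),
    pathway_membership = tibble::tibble(pathway = c("P1", "P1"),
                                        protein = c("p1", "p2")),
    available_lincs = "r1")
}

test_that("subgraph construction follows the hand-traced toy", {
  g <- build_subgraph(toy_tables(), builder_params("P1"))
  expect_setequal(g$nodes$name,
                  c("d1", "PROTEIN_p1", "PROTEIN_p2", "RNA_r1", "LINCS_r1"))
  expect_false(any(grepl("d2|p3", g$nodes$name)))
  expect_identical(nrow(g$edges), 4L)
  expect_setequal(paste(g$edges$source, g$edges$target),
                  c("d1 PROTEIN_p1", "PROTEIN_p1 PROTEIN_p2",
                    "PROTEIN_p2 RNA_r1", "RNA_r1 LINCS_r1"))
  expect_error(build_subgraph(toy_tables(), builder_params("P9")),
               "no proteins match")
})

test_that("a drug failing the output-coverage fraction is pruned (to an error if last)", {
  # second measurable RNA unreachable from d1; prune_fraction = 1 kills d1
  tabs <- interaction_tables(
    drug_target = tibble::tibble(drug = "d1", protein = "p1"),
    ppi = tibble::tibble(source = "p1", target = "p2"),
    tf_regulation = tibble::tibble(protein = c("p2", "p3"),
                                   rna = c("r1", "r2")),
    pathway_membership = tibble::tibble(pathway = "P1",
                                        protein = c("p1", "p2", "p3")),
    available_lincs = c("r1", "r2"))
  # p3 gets an upstream via translation from r2 (a cycle not reachable from
  # d1), keeping the pre-pruning graph valid
  tabs$translation <- tibble::tibble(rna = "r2", protein = "p3")
  g <- build_subgraph(tabs, builder_params("P1", drug_prune_fraction = 0.25))
  expect_true("d1" %in% g$nodes$name)
  expect_error(
    build_subgraph(tabs, builder_params("P1", drug_prune_fraction = 1)),
    "zero drugs")
})

test_that("regulator-chain depth controls multi-step RNA inclusion", {
  # TF -> miR -> mRNA: the mRNA enters only at depth >= 2
  tabs <- interaction_tables(
    drug_target = tibble::tibble(drug = "d1", protein = "tf"),
    tf_regulation = tibble::tibble(protein = "tf", rna = "miR"),
    mirna_regulation = tibble::tibble(source = "miR", target = "mRNA"),
    pathway_membership = tibble::tibble(pathway = "P1", protein = "tf"),
    available_lincs = c("miR", "mRNA"))
  g1 <- build_subgraph(tabs, builder_params("P1", rna_descendant_depth = 1))
  expect_false("RNA_mRNA" %in% g1$nodes$name)
  g2 <- build_subgraph(tabs, builder_params("P1", rna_descendant_depth = 2))
  expect_true("RNA_mRNA" %in% g2$nodes$name)
  expect_true("LINCS_mRNA" %in% g2$nodes$name)
})

test_that("omic attachment adds input nodes with the dual-edge expression rule", {
  # entity e exists as both protein and RNA: EXPR_e gains two edges
  tabs <- interaction_tables(
    drug_target = tibble::tibble(drug = "d1", protein = "e"),
    tf_regulation = tibble::tibble(protein = "e", rna = "e"),
    pathway_membership = tibble::tibble(pathway = "P1", protein = "e"),
    available_lincs = "e",
    available_omics = tibble::tibble(omic_class = c("EXPR", "MUT"),
                                     entity = c("e", "p9")))
  expect_message(g <- build_subgraph(tabs, builder_params("P1")),
                 "absent entities")
  expr_edges <- g$edges |> dplyr::filter(source == "EXPR_e")
  expect_setequal(expr_edges$target, c("PROTEIN_e", "RNA_e"))
  # pruned/absent entity p9 contributes no node
  expect_false("MUT_p9" %in% g$nodes$name)
  # added omics satisfy input-node invariants (validation ran inside)
  om <- g$nodes |> dplyr::filter(entity_class == "EXPR")
  expect_true(all(om$role == "input" & om$d_in == 0 & om$d_out >= 1))
})

test_that("builder invariants hold on generated fixtures", {
  spec <- fixture_spec(seed = 21)
  tabs <- generate_interaction_tables(spec)
  params <- builder_params(c("P1", "P2"), rna_descendant_depth = 2)
  g <- suppressMessages(build_subgraph(tabs, params))
  expect_s3_class(g, "structural_graph")
  outs <- g$nodes$name[g$nodes$role == "output"]
  # every retained drug covers >= the pruning fraction of outputs
  for (d in g$nodes$name[g$nodes$entity_class == "DRUG"]) {
    cov <- length(intersect(descendants(g, d), outs))
    expect_gte(cov, params$drug_prune_fraction * length(outs))
  }
  # every retained protein/RNA reaches at least one output
  for (f in g$nodes$name[g$nodes$role == "function"]) {
    expect_gt(length(intersect(descendants(g, f), outs)), 0)
  }
  # deterministic for fixed inputs
  g2 <- suppressMessages(build_subgraph(tabs, params))
  expect_identical(g$nodes, g2$nodes)
  expect_identical(g$edges, g2$edges)
})

test_that("interaction table validation catches duplicates and bad classes", {
  expect_error(
    interaction_tables(ppi = tibble::tibble(source = c("a", "a"),
                                            target = c("b", "b"))),
    "duplicate rows in ppi")
  expect_error(
    interaction_tables(available_omics = tibble::tibble(omic_class = "RNAseq",
                                                        entity = "x")),
    "unknown omic_class")
  expect_error(
    interaction_tables(ppi = tibble::tibble(source = "", target = "b")),
    "empty identifier")
})

test_that("randomization conserves per-class edge counts, node set, and endpoints rules", {
  g <- fixture_graph(fixture_spec(seed = 31))
  rg <- randomize_graph(g, seed = 5)
  count_by <- function(gr) table(factor(gr$edges$edge_class,
                                        levels = c("input_edge",
                                                   "function_edge",
                                                   "output_edge")))
  expect_identical(count_by(rg), count_by(g))
  expect_identical(rg$nodes$name, g$nodes$name)
  expect_identical(nrow(rg$edges), nrow(g$edges))
  expect_false(anyDuplicated(paste(rg$edges$source, rg$edges$target)) > 0)
  # input edges keep sources; output edges keep destinations
  fn <- g$nodes$name[g$nodes$role == "function"]
  ein <- rg$edges |> dplyr::filter(edge_class == "input_edge")
  expect_identical(sort(ein$source),
                   sort(g$edges$source[g$edges$edge_class == "input_edge"]))
  expect_true(all(ein$target %in% fn))
  eout <- rg$edges |> dplyr::filter(edge_class == "output_edge")
  expect_identical(sort(eout$target),
                   sort(g$edges$target[g$edges$edge_class == "output_edge"]))
  expect_true(all(eout$source %in% fn))
  efun <- rg$edges |> dplyr::filter(edge_class == "function_edge")
  expect_true(all(efun$source %in% fn) && all(efun$target %in% fn))
  # output nodes keep in-degree exactly one
  expect_true(all(rg$nodes$d_in[rg$nodes$role == "output"] == 1))
  # deterministic under a fixed seed
  rg2 <- randomize_graph(g, seed = 5)
  expect_identical(rg$edges, rg2$edges)
  expect_false(identical(randomize_graph(g, seed = 6)$edges, rg$edges))
})

test_that("randomized function-edge sets barely overlap the original", {
  g <- fixture_graph(fixture_spec(seed = 32, n_proteins = 30, n_rnas = 20,
                                  n_lincs = 10, edge_density = 0.1))
  orig <- paste(g$edges$source, g$edges$target)[
    g$edges$edge_class == "function_edge"]
  jac <- vapply(1:20, function(s) {
    rg <- randomize_graph(g, seed = s)
    new <- paste(rg$edges$source, rg$edges$target)[
      rg$edges$edge_class == "function_edge"]
    length(intersect(orig, new)) / length(union(orig, new))
  }, numeric(1))
  expect_lt(mean(jac), 0.05)
})
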