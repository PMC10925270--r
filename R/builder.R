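#' Bundle raw interaction tables
#'
#' Collects the literature-style relation tables a biological network is
#' built from. Each relation table has two identifier columns; duplicates
#' within a table and empty identifiers are rejected.
#'
#' @param drug_target tibble (drug, protein)
#' @param ppi tibble (protein, protein): columns `source`, `target`
#' @param tf_regulation tibble (protein, rna): transcription-factor targets
#' @param mirna_regulation tibble (rna, rna): miRNA regulation
#' @param translation tibble (rna, protein)
#' @param pathway_membership tibble (pathway, protein)
#' @param available_lincs character vector of measurable RNA names
#' @param available_omics tibble (omic_class in EXPR/CNV/MUT/METHYL, entity)
#' @return validated list of class `interaction_tables`
#' @export
interaction_tables <- function(drug_target = NULL, ppi = NULL,
                               tf_regulation = NULL, mirna_regulation = NULL,
                               translation = NULL, pathway_membership = NULL,
                               available_lincs = character(),
                               available_omics = NULL) {
  empty2 <- function(a, b) setNames(tibble(x = character(), y = character()),
                                    c(a, b))
  tabs <- list(
    drug_target = drug_target %||% empty2("drug", "protein"),
    ppi = ppi %||% empty2("source", "target"),
    tf_regulation = tf_regulation %||% empty2("protein", "rna"),
    mirna_regulation = mirna_regulation %||% empty2("source", "target"),
    translation = translation %||% empty2("rna", "protein"),
    pathway_membership = pathway_membership %||% empty2("pathway", "protein"),
    available_omics = available_omics %||% empty2("omic_class", "entity")
  )
  tabs <- map(tabs, function(t) {
    t <- as_tibble(t) |> mutate(across(dplyr::everything(), as.character))
    if (nrow(t) > 0 && any(t == "" | is.na(t))) {
      abort("empty identifier in interaction table")
    }
    t
  })
  for (nm in c("drug_target", "ppi", "tf_regulation", "mirna_regulation",
               "translation")) {
    if (anyDuplicated(tabs[[nm]])) abort(paste0("duplicate rows in ", nm, " table"))
  }
  bad <- setdiff(unique(tabs$available_omics$omic_class),
                 c("EXPR", "CNV", "MUT", "METHYL"))
  if (length(bad) > 0) {
    abort(paste0("unknown omic_class: ", paste(bad, collapse = ", ")))
  }
  tabs$available_lincs <- as.character(available_lincs)
  structure(tabs, class = "interaction_tables")
}

#' Subgraph construction parameters
#'
#' @param pathways set of pathway names to seed the protein space
#' @param rna_descendant_depth regulator-chain depth for the RNA space; depth
#'   1 (the default) keeps only RNAs directly targeted by a protein-space
#'   member, depth d follows up to d regulation hops (e.g. TF -> miRNA ->
#'   mRNA needs depth 2)
#' @param drug_prune_fraction minimum fraction of measurable output nodes a
#'   drug must reach to be retained (default 0.25)
#' @param resources subset of relation-table names to include when collecting
#'   edges
#' @return list of class `builder_params`
#' @export
builder_params <- function(pathways,
                           rna_descendant_depth = 1,
                           drug_prune_fraction = 0.25,
                           resources = c("drug_target", "ppi",
                                         "tf_regulation", "mirna_regulation",
                                         "translation")) {
  assert_that_(length(pathways) > 0, "pathways must be nonempty")
  assert_that_(drug_prune_fraction >= 0 && drug_prune_fraction <= 1,
               "drug_prune_fraction must be in [0, 1]")
  structure(list(pathways = as.character(pathways),
                 rna_descendant_depth = as.integer(rna_descendant_depth),
                 drug_prune_fraction = drug_prune_fraction,
                 resources = resources),
            class = "builder_params")
}

# Node-name namespacing: the same biological entity can appear as both a
# protein and an RNA node, so function nodes are named PROTEIN_<id> and
# RNA_<id>; drugs keep their raw ids, outputs are LINCS_<id>, 'omic inputs
# are <CLASS>_<id>.
prot_node <- function(x) paste0("PROTEIN_", x)
rna_node <- function(x) paste0("RNA_", x)
lincs_node <- function(x) paste0("LINCS_", x)

#' Build a pathway-focused structural graph from interaction tables
#'
#' Executes, in order: (1) the *protein space* is the union of proteins
#' belonging to any requested pathway; (2) the *RNA space* is every RNA
#' reachable from the protein space through regulator chains
#' (TF->RNA, RNA->RNA, and RNA->translated-protein->RNA steps constrained to
#' retained nodes) within `rna_descendant_depth` hops; (3) the *drug space*
#' is every drug with a reported target in the protein space; (4) the
#' measurable output space is the RNA space intersected with
#' `available_lincs`; (5) all enabled-resource edges with both endpoints
#' retained are collected; (6) one output node `LINCS_<rna>` is attached to
#' each measurable RNA; (7) drugs whose descendants cover fewer than
#' `drug_prune_fraction` of the output nodes are pruned; (8) protein/RNA
#' nodes without a downstream output are pruned; (9) 'omic input nodes are
#' attached ([attach_omics()]). Degenerate function nodes left by pruning are
#' cascaded away so the result always validates. Function nodes are named
#' `PROTEIN_<id>` / `RNA_<id>` so an entity can carry both a protein and an
#' RNA node.
#'
#' @param tables an [interaction_tables()]
#' @param params a [builder_params()]
#' @return a `structural_graph`
#' @export
build_subgraph <- function(tables, params) {
  # (1) protein space
  pw <- tables$pathway_membership |> filter(.data$pathway %in% params$pathways)
  protein_space <- unique(pw$protein)
  if (length(protein_space) == 0) abort("no proteins match pathways")

  # (2) rna space: BFS over regulation edges, restricted to retained spaces
  reg_edges <- bind_rows(
    if ("tf_regulation" %in% params$resources)
      tables$tf_regulation |>
        filter(.data$protein %in% protein_space) |>
        mutate(from = prot_node(.data$protein), to = rna_node(.data$rna)) |>
        select("from", "to"),
    if ("mirna_regulation" %in% params$resources)
      tables$mirna_regulation |>
        mutate(from = rna_node(.data$source), to = rna_node(.data$target)) |>
        select("from", "to"),
    if ("translation" %in% params$resources)
      tables$translation |>
        filter(.data$protein %in% protein_space) |>
        mutate(from = rna_node(.data$rna), to = prot_node(.data$protein)) |>
        select("from", "to")
  )
  rna_space <- character()
  frontier <- prot_node(protein_space)
  visited <- frontier
  depth <- 0L
  while (depth < params$rna_descendant_depth && length(frontier) > 0) {
    nxt <- reg_edges |> filter(.data$from %in% frontier) |> pull("to")
    nxt <- setdiff(unique(nxt), visited)
    rna_space <- union(rna_space, sub("^RNA_", "", nxt[startsWith(nxt, "RNA_")]))
    visited <- union(visited, nxt)
    frontier <- nxt
    depth <- depth + 1L
  }

  # (3) drug space
  drug_space <- tables$drug_target |>
    filter(.data$protein %in% protein_space) |>
    pull("drug") |> unique()

  # (4) measurable output space
  lincs_space <- intersect(rna_space, tables$available_lincs)
  if (length(lincs_space) == 0) abort("zero surviving LINCS outputs")

  # (5) collect edges with both endpoints retained
  res <- params$resources
  edges <- bind_rows(
    if ("drug_target" %in% res)
      tables$drug_target |>
        filter(.data$drug %in% drug_space, .data$protein %in% protein_space) |>
        mutate(source = .data$drug, target = prot_node(.data$protein)) |>
        select("source", "target"),
    if ("ppi" %in% res)
      tables$ppi |>
        filter(.data$source %in% protein_space,
               .data$target %in% protein_space) |>
        mutate(source = prot_node(.data$source),
               target = prot_node(.data$target)) |>
        select("source", "target"),
    if ("tf_regulation" %in% res)
      tables$tf_regulation |>
        filter(.data$protein %in% protein_space, .data$rna %in% rna_space) |>
        mutate(source = prot_node(.data$protein),
               target = rna_node(.data$rna)) |>
        select("source", "target"),
    if ("mirna_regulation" %in% res)
      tables$mirna_regulation |>
        filter(.data$source %in% rna_space, .data$target %in% rna_space) |>
        mutate(source = rna_node(.data$source),
               target = rna_node(.data$target)) |>
        select("source", "target"),
    if ("translation" %in% res)
      tables$translation |>
        filter(.data$rna %in% rna_space, .data$protein %in% protein_space) |>
        mutate(source = rna_node(.data$rna),
               target = prot_node(.data$protein)) |>
        select("source", "target")
  ) |> distinct()

  # (6) output nodes
  out_nodes <- lincs_node(lincs_space)
  edges <- bind_rows(edges,
                     tibble(source = rna_node(lincs_space), target = out_nodes))

  nodes <- bind_rows(
    tibble(name = drug_space, entity_class = "DRUG"),
    tibble(name = prot_node(protein_space), entity_class = "PROTEIN"),
    tibble(name = rna_node(rna_space), entity_class = "RNA"),
    tibble(name = out_nodes, entity_class = "LINCS")
  )
  used <- unique(c(edges$source, edges$target))
  nodes <- nodes |> filter(.data$name %in% used)
  edges <- edges |>
    filter(.data$source %in% nodes$name, .data$target %in% nodes$name)

  # (7) drug pruning by output coverage, then (8) protein/RNA pruning,
  # both computed on the pre-omics graph
  reach <- reachable_sets(nodes, edges)
  need <- params$drug_prune_fraction * length(out_nodes)
  drugs_present <- intersect(drug_space, nodes$name)
  keep_drug <- vapply(drugs_present, function(d) {
    length(intersect(reach[[d]], out_nodes)) >= need
  }, logical(1))
  if (!any(keep_drug)) abort("zero drugs survive pruning")
  dropped_drugs <- drugs_present[!keep_drug]

  fnames <- nodes$name[nodes$entity_class %in% c("PROTEIN", "RNA")]
  keep_fn <- vapply(fnames, function(nm) {
    length(intersect(reach[[nm]], out_nodes)) > 0
  }, logical(1))
  dropped_fn <- fnames[!keep_fn]

  nodes <- nodes |> filter(!.data$name %in% c(dropped_drugs, dropped_fn))
  edges <- edges |>
    filter(.data$source %in% nodes$name, .data$target %in% nodes$name)

  # cascade away degenerate nodes so the graph validates
  repeat {
    d_out <- table(factor(edges$source, levels = nodes$name))
    d_in <- table(factor(edges$target, levels = nodes$name))
    bad <- nodes |>
      filter((.data$entity_class %in% c("PROTEIN", "RNA") &
                (d_in[.data$name] == 0 | d_out[.data$name] == 0)) |
             (.data$entity_class == "DRUG" & d_out[.data$name] == 0) |
             (.data$entity_class == "LINCS" & d_in[.data$name] == 0)) |>
      pull("name")
    if (length(bad) == 0) break
    nodes <- nodes |> filter(!.data$name %in% bad)
    edges <- edges |>
      filter(.data$source %in% nodes$name, .data$target %in% nodes$name)
  }
  if (!any(nodes$entity_class == "LINCS")) abort("zero surviving LINCS outputs")
  if (!any(nodes$entity_class == "DRUG")) abort("zero drugs survive pruning")

  g <- structural_graph(nodes, edges)
  # (9) attach cellular-context inputs
  attach_omics(g, tables)
}

# descendant name sets for every node, from raw node/edge name tables
reachable_sets <- function(nodes, edges) {
  g <- igraph::graph_from_data_frame(edges, vertices = nodes$name,
                                     directed = TRUE)
  sets <- igraph::ego(g, order = nrow(nodes), mode = "out", mindist = 1)
  setNames(map(sets, ~ names(.x)), nodes$name)
}

#' Attach 'omic input nodes to a built graph
#'
#' For each available (omic class, entity) whose entity is present as a
#' `PROTEIN_<entity>` or `RNA_<entity>` function node, adds the input node
#' `<class>_<entity>` with one edge to every matching entity node — so an
#' expression feature for an entity carrying both a protein and an RNA node
#' gains two edges. Features for entities pruned from the graph are skipped
#' (with a message) so 'omics never resurrect pruned entities.
#'
#' @param g a `structural_graph` built through the pruning steps
#' @param tables an [interaction_tables()] supplying `available_omics`
#' @return a new `structural_graph` including the 'omic input nodes
#' @export
attach_omics <- function(g, tables) {
  om <- tables$available_omics |> distinct(.data$omic_class, .data$entity)
  if (nrow(om) == 0) return(g)
  candidates <- om |>
    mutate(node = paste0(.data$omic_class, "_", .data$entity)) |>
    tidyr::crossing(prefix = c("PROTEIN_", "RNA_")) |>
    mutate(target = paste0(.data$prefix, .data$entity)) |>
    filter(.data$target %in% g$nodes$name)
  matched <- unique(paste0(candidates$omic_class, "_", candidates$entity))
  all_feats <- paste0(om$omic_class, "_", om$entity)
  skipped <- setdiff(all_feats, matched)
  if (length(skipped) > 0) {
    inform(paste0("skipping ", length(skipped),
                  " 'omic feature(s) for absent entities: ",
                  paste(utils::head(skipped, 5), collapse = ", "),
                  if (length(skipped) > 5) ", ..." else ""))
  }
  if (nrow(candidates) == 0) return(g)
  new_nodes <- candidates |>
    distinct(name = .data$node, entity_class = .data$omic_class)
  new_edges <- candidates |> select(source = "node", "target") |> distinct()
  structural_graph(
    bind_rows(g$nodes |> select("name", "entity_class"), new_nodes),
    bind_rows(g$edges |> select("source", "target"), new_edges))
}
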