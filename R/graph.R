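#' Structural graphs for perturbation modeling
#'
#' A structural graph is the fixed directed network that constrains every
#' computation in this package. Nodes play one of three roles: *input* nodes
#' (drugs and cellular-context 'omic features; in-degree 0), *function* nodes
#' (proteins and RNAs, each realized in the model as a small node-specific
#' neural map; nonzero in- and out-degree) and *output* nodes (measured
#' transcripts; out-degree 0 and in-degree exactly 1). Edges are classed by
#' the same logic: edges leaving input nodes are `input_edge`s, edges entering
#' output nodes are `output_edge`s (this classification takes precedence), and
#' all remaining edges are `function_edge`s. Cycles among function nodes are
#' allowed.
#'
#' Node and edge orderings are deterministic — nodes sort lexicographically by
#' (entity_class, name) and edges by (source index, target index) — so every
#' derived matrix layout is reproducible.
#'
#' @param nodes data frame with columns `name`, `entity_class` (one of DRUG,
#'   EXPR, CNV, MUT, METHYL, PROTEIN, RNA, LINCS, OTHER)
#' @param edges data frame with columns `source`, `target`
#' @param allow_degenerate if `TRUE`, function nodes may have zero in- or
#'   out-degree (needed for randomized control graphs, which do not preserve
#'   node degrees)
#' @return an object of class `structural_graph` with tibbles `$nodes`
#'   (name, entity_class, role, d_in, d_out) and `$edges`
#'   (source, target, edge_class, src_index, tgt_index)
#' @export
structural_graph <- function(nodes, edges, allow_degenerate = FALSE) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  assert_that_(all(c("name", "entity_class") %in% names(nodes)),
               "node table must have columns name, entity_class")
  assert_that_(all(c("source", "target") %in% names(edges)),
               "edge table must have columns source, target")
  nodes <- nodes |>
    mutate(name = as.character(.data$name),
           entity_class = as.character(.data$entity_class)) |>
    select("name", "entity_class")
  edges <- edges |>
    mutate(source = as.character(.data$source),
           target = as.character(.data$target)) |>
    select("source", "target")

  bad_class <- setdiff(unique(nodes$entity_class), entity_classes())
  if (length(bad_class) > 0) {
    abort(paste0("unknown entity_class: ", paste(bad_class, collapse = ", ")))
  }
  if (anyDuplicated(nodes$name)) {
    abort(paste0("duplicate node names: ",
                 paste(unique(nodes$name[duplicated(nodes$name)]), collapse = ", ")))
  }
  dup <- duplicated(paste(edges$source, edges$target, sep = "\r"))
  if (any(dup)) {
    offenders <- paste0(edges$source[dup], "->", edges$target[dup])
    abort(paste0("duplicate edges: ", paste(unique(offenders), collapse = ", ")))
  }
  unknown <- setdiff(c(edges$source, edges$target), nodes$name)
  if (length(unknown) > 0) {
    bad <- edges |>
      filter(.data$source %in% unknown | .data$target %in% unknown) |>
      mutate(lab = paste0(.data$source, "->", .data$target)) |>
      pull("lab")
    abort(paste0("edge references unknown node: ", paste(bad, collapse = ", ")))
  }

  # deterministic ordering: nodes by (entity_class, name), C collation
  ord <- withr::with_collate("C", order(nodes$entity_class, nodes$name))
  nodes <- nodes[ord, ]
  idx <- setNames(seq_len(nrow(nodes)), nodes$name)
  edges <- edges |>
    mutate(src_index = unname(idx[.data$source]),
           tgt_index = unname(idx[.data$target])) |>
    arrange(.data$src_index, .data$tgt_index)

  d_out <- tabulate(edges$src_index, nbins = nrow(nodes))
  d_in <- tabulate(edges$tgt_index, nbins = nrow(nodes))
  nodes$d_in <- d_in
  nodes$d_out <- d_out
  nodes$role <- node_role(nodes$entity_class)
  infer <- nodes$role == "infer"
  nodes$role[infer] <- ifelse(d_in[infer] == 0, "input",
                       ifelse(d_out[infer] == 0, "output", "function"))

  edges$edge_class <- edge_class_of(nodes, edges)

  g <- structure(list(nodes = nodes, edges = edges), class = "structural_graph")
  validate_structural_graph(g, allow_degenerate = allow_degenerate)
  g
}

entity_classes <- function() {
  c("DRUG", "EXPR", "CNV", "MUT", "METHYL", "PROTEIN", "RNA", "LINCS", "OTHER")
}

node_role <- function(entity_class) {
  dplyr::case_when(
    entity_class %in% c("DRUG", "EXPR", "CNV", "MUT", "METHYL") ~ "input",
    entity_class %in% c("PROTEIN", "RNA") ~ "function",
    entity_class == "LINCS" ~ "output",
    TRUE ~ "infer"
  )
}

edge_class_of <- function(nodes, edges) {
  src_role <- nodes$role[edges$src_index]
  tgt_role <- nodes$role[edges$tgt_index]
  # output classification takes precedence over function classification
  ifelse(tgt_role == "output", "output_edge",
  ifelse(src_role == "input", "input_edge", "function_edge"))
}

#' Validate a structural graph
#'
#' Checks the role/degree invariants: input nodes have in-degree 0 and
#' out-degree at least 1; output nodes have out-degree 0 and in-degree exactly
#' 1; function nodes have nonzero in- and out-degree (unless
#' `allow_degenerate`).
#'
#' @inheritParams structural_graph
#' @param g a `structural_graph`
#' @return `g`, invisibly; aborts with an informative message on violation
#' @export
validate_structural_graph <- function(g, allow_degenerate = FALSE) {
  n <- g$nodes
  bad <- n |> filter(.data$role == "input" & (.data$d_in != 0 | .data$d_out < 1))
  if (nrow(bad) > 0) {
    abort(paste0("input node invariant violated (need d_in=0, d_out>=1): ",
                 paste(bad$name, collapse = ", ")))
  }
  bad <- n |> filter(.data$role == "output" & (.data$d_out != 0 | .data$d_in != 1))
  if (nrow(bad) > 0) {
    abort(paste0("output node invariant violated (need d_out=0, d_in=1): ",
                 paste(bad$name, collapse = ", ")))
  }
  if (!allow_degenerate) {
    bad <- n |> filter(.data$role == "function" & (.data$d_in < 1 | .data$d_out < 1))
    if (nrow(bad) > 0) {
      abort(paste0("function node with zero in- or out-degree: ",
                   paste(bad$name, collapse = ", ")))
    }
  }
  invisible(g)
}

#' @export
print.structural_graph <- function(x, ...) {
  counts <- table(factor(x$nodes$role, levels = c("input", "function", "output")))
  ecounts <- table(factor(x$edges$edge_class,
                          levels = c("input_edge", "function_edge", "output_edge")))
  cat(sprintf("<structural_graph> %d nodes (%d input, %d function, %d output), %d edges (%d/%d/%d input/function/output)\n",
              nrow(x$nodes), counts[1], counts[2], counts[3],
              nrow(x$edges), ecounts[1], ecounts[2], ecounts[3]))
  invisible(x)
}

#' @method tidy structural_graph
#' @export
tidy.structural_graph <- function(x, ...) {
  x$edges |> select("source", "target", "edge_class")
}

#' @method glance structural_graph
#' @export
glance.structural_graph <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_input = sum(x$nodes$role == "input"),
    n_function = sum(x$nodes$role == "function"),
    n_output = sum(x$nodes$role == "output"),
    n_edges = nrow(x$edges),
    n_input_edges = sum(x$edges$edge_class == "input_edge"),
    n_function_edges = sum(x$edges$edge_class == "function_edge"),
    n_output_edges = sum(x$edges$edge_class == "output_edge")
  )
}

#' Plot a structural graph
#'
#' Fruchterman-Reingold layout (via igraph) with nodes colored by role and
#' edges drawn as segments.
#'
#' @param object a `structural_graph`
#' @param ... ignored
#' @return a ggplot object
#' @method autoplot structural_graph
#' @export
autoplot.structural_graph <- function(object, ...) {
  ig <- igraph::graph_from_data_frame(
    object$edges[, c("source", "target")],
    vertices = object$nodes$name, directed = TRUE)
  xy <- igraph::layout_with_fr(ig)
  lay <- tibble(name = igraph::V(ig)$name, x = xy[, 1], y = xy[, 2]) |>
    left_join(object$nodes |> select("name", "role"), by = "name")
  seg <- object$edges |>
    left_join(lay |> rename(x0 = "x", y0 = "y"), by = c(source = "name")) |>
    left_join(lay |> select(name2 = "name", x1 = "x", y1 = "y"),
              by = c(target = "name2"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
                   linetype = .data$edge_class),
      color = "grey50",
      arrow = ggplot2::arrow(length = ggplot2::unit(1.6, "mm"))) +
    ggplot2::geom_point(data = lay,
                        ggplot2::aes(x = .data$x, y = .data$y, color = .data$role),
                        size = 3) +
    ggplot2::theme_void() +
    ggplot2::labs(color = "node role", linetype = "edge class")
}

#' Load a structural graph from node and edge TSV files
#'
#' The node TSV has header columns `name` and `entity_class`; the edge TSV has
#' `source` and `target`. Roles are inferred from entity classes and degrees.
#'
#' @param edge_table_path path to edge TSV
#' @param node_table_path path to node TSV
#' @inheritParams structural_graph
#' @return a `structural_graph`
#' @export
load_graph <- function(edge_table_path, node_table_path, allow_degenerate = FALSE) {
  nodes <- readr::read_tsv(node_table_path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  edges <- readr::read_tsv(edge_table_path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  structural_graph(nodes, edges, allow_degenerate = allow_degenerate)
}

#' Save a structural graph as two TSV files
#'
#' Writes `nodes.tsv` (name, entity_class) and `edges.tsv` (source, target)
#' into `dir`. Round-trips byte-identically through [load_graph()].
#'
#' @param g a `structural_graph`
#' @param dir output directory, created if needed
#' @return `dir`, invisibly
#' @export
save_graph <- function(g, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(g$nodes |> select("name", "entity_class"),
                   file.path(dir, "nodes.tsv"), progress = FALSE)
  readr::write_tsv(g$edges |> select("source", "target"),
                   file.path(dir, "edges.tsv"), progress = FALSE)
  invisible(dir)
}

#' Partition edge indices by class
#'
#' @param g a `structural_graph`
#' @return named list of integer vectors `input_edges`, `function_edges`,
#'   `output_edges`, a partition of `1:E`
#' @export
classify_edges <- function(g) {
  cls <- g$edges$edge_class
  list(
    input_edges = which(cls == "input_edge"),
    function_edges = which(cls == "function_edge"),
    output_edges = which(cls == "output_edge")
  )
}

#' Descendants of a set of nodes
#'
#' All nodes reachable by a directed path of length at least one from any of
#' the sources. Safe on cyclic graphs.
#'
#' @param g a `structural_graph`
#' @param sources character vector of node names
#' @return character vector of node names (sorted in graph node order)
#' @export
descendants <- function(g, sources) {
  unknown <- setdiff(sources, g$nodes$name)
  if (length(unknown) > 0) {
    abort(paste0("unknown source node(s): ", paste(unknown, collapse = ", ")))
  }
  nn <- nrow(g$nodes)
  adj <- split(g$edges$tgt_index, factor(g$edges$src_index, levels = seq_len(nn)))
  start <- match(sources, g$nodes$name)
  seen <- rep(FALSE, nn)
  frontier <- unique(unlist(adj[start], use.names = FALSE))
  while (length(frontier) > 0) {
    frontier <- frontier[!seen[frontier]]
    seen[frontier] <- TRUE
    frontier <- unique(unlist(adj[frontier], use.names = FALSE))
  }
  g$nodes$name[seen]
}

#' Add a self-edge to every function node
#'
#' Self-edges let a function node read its own previous-layer state; they are
#' classed as function edges, participate in degree counts (and hence in the
#' initialization fan values), and are not re-added if already present.
#'
#' @param g a `structural_graph`
#' @return a new `structural_graph` with `E + F` edges (F = function nodes
#'   lacking a self-edge)
#' @export
add_self_edges <- function(g) {
  fn <- g$nodes$name[g$nodes$role == "function"]
  have <- g$edges |> filter(.data$source == .data$target) |> pull("source")
  new <- setdiff(fn, have)
  edges <- bind_rows(g$edges |> select("source", "target"),
                     tibble(source = new, target = new))
  structural_graph(g$nodes |> select("name", "entity_class"), edges)
}

# -- internal index helpers -------------------------------------------------

input_nodes <- function(g) g$nodes$name[g$nodes$role == "input"]
output_nodes <- function(g) g$nodes$name[g$nodes$role == "output"]
function_nodes <- function(g) g$nodes$name[g$nodes$role == "function"]

# For each output node (in node order) the index of its single incoming edge.
output_edge_index <- function(g) {
  outs <- which(g$nodes$role == "output")
  vapply(outs, function(i) which(g$edges$tgt_index == i), integer(1))
}
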