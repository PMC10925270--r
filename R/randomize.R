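#' Randomized control graph
#'
#' Produces a degree-shuffled control for the prior-knowledge graph by
#' resampling edge endpoints independently within each edge class, exactly
#' preserving the number of edges per class and the node set: input edges
#' keep their source (an input node) and draw a new destination uniformly
#' from the function nodes; output edges keep their destination (an output
#' node) and draw a new source uniformly from the function nodes; function
#' edges draw both endpoints uniformly from the function nodes. Self-loops
#' are resampled away unless the original graph contained self-edges.
#' Individual function-node degrees are *not* preserved, so the result may
#' contain function nodes with zero in- or out-degree; validation of the
#' control graph therefore relaxes that one invariant.
#'
#' @param g a `structural_graph`
#' @param seed integer seed (fixed seed gives an identical control graph)
#' @param max_rounds resampling rounds allowed to resolve duplicate edges
#' @return a `structural_graph` with the same node set and per-class edge
#'   counts as `g`
#' @export
randomize_graph <- function(g, seed = 1, max_rounds = 1000) {
  fn <- function_nodes(g)
  assert_that_(length(fn) >= 2, "need at least 2 function nodes to randomize")
  allow_self <- any(g$edges$source == g$edges$target)
  ec <- g$edges$edge_class
  n_in <- sum(ec == "input_edge")
  n_fun <- sum(ec == "function_edge")
  n_out <- sum(ec == "output_edge")

  with_seed_(derive_seed(seed, "randomize"), {
    src <- g$edges$source
    tgt <- g$edges$target
    tgt[ec == "input_edge"] <- sample(fn, n_in, replace = TRUE)
    src[ec == "function_edge"] <- sample(fn, n_fun, replace = TRUE)
    tgt[ec == "function_edge"] <- sample(fn, n_fun, replace = TRUE)
    src[ec == "output_edge"] <- sample(fn, n_out, replace = TRUE)

    redraw <- function(i) {
      if (ec[i] == "input_edge") {
        tgt[i] <<- sample(fn, 1)
      } else if (ec[i] == "output_edge") {
        src[i] <<- sample(fn, 1)
      } else {
        src[i] <<- sample(fn, 1)
        tgt[i] <<- sample(fn, 1)
      }
    }
    for (round in seq_len(max_rounds)) {
      key <- paste(src, tgt, sep = "\r")
      bad <- which(duplicated(key) | (!allow_self & src == tgt))
      if (length(bad) == 0) break
      for (i in bad) redraw(i)
      if (round == max_rounds) {
        abort("graph too small to resolve duplicate edges while randomizing")
      }
    }
  })

  rg <- structural_graph(g$nodes |> select("name", "entity_class"),
                         tibble(source = src, target = tgt),
                         allow_degenerate = TRUE)
  stopifnot(identical(
    unname(table(factor(rg$edges$edge_class, levels = unique(ec)))[unique(ec)]),
    unname(table(factor(ec, levels = unique(ec)))[unique(ec)])))
  rg
}
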