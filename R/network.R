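#' Construct a gene interaction network
#'
#' Builds an undirected, simple (no self-loops, no duplicate edges) network
#' over opaque gene identifiers. Self-loops and duplicate edges present in the
#' input are silently dropped, with a message reporting how many.
#'
#' @param edges two-column character matrix or data frame of edge endpoints,
#'   or an existing `igraph` object to validate and simplify.
#' @param nodes optional character vector of additional (possibly isolated)
#'   node identifiers to include.
#' @return an undirected simple `igraph` object with named vertices.
#' @examples
#' net <- gene_network(cbind(c("a", "b"), c("b", "c")))
#' igraph::vcount(net)
#' @export
gene_network <- function(edges, nodes = NULL) {
  if (igraph::is_igraph(edges)) {
    g <- edges
    if (is.null(igraph::V(g)$name)) {
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    }
    if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  } else {
    edges <- as.matrix(edges)
    if (length(edges) && ncol(edges) != 2) {
      stop("`edges` must have exactly two columns", call. = FALSE)
    }
    storage.mode(edges) <- "character"
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  }
  if (!is.null(nodes)) {
    extra <- setdiff(as.character(nodes), igraph::V(g)$name)
    if (length(extra)) g <- igraph::add_vertices(g, length(extra), name = extra)
  }
  n_loops <- sum(igraph::which_loop(g))
  n_multi <- sum(igraph::which_multiple(g))
  if (n_loops || n_multi) {
    message("dropped ", n_loops, " self-loop(s) and ", n_multi,
            " duplicate edge(s)")
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  }
  g
}

#' Restrict a network to scored genes
#'
#' Returns the subgraph induced by the genes that carry an input P-value.
#' This defines the analysis universe: only scored genes can be neighborhood
#' members or candidate centers.
#'
#' @param network an undirected `igraph` network (see [gene_network()]).
#' @param scores a [score_table()] (or named numeric vector of P-values).
#' @return the induced `igraph` subgraph.
#' @export
restrict_network <- function(network, scores) {
  keep <- intersect(igraph::V(network)$name, names(scores))
  if (!length(keep)) {
    stop("no overlap between network nodes and scored genes; ",
         "check that the two inputs use the same identifier format",
         call. = FALSE)
  }
  igraph::induced_subgraph(network, keep)
}

#' Extract the local subnetwork around a center gene
#'
#' The local subnetwork of a gene is the gene itself together with all of its
#' direct interaction partners (its radius-1 neighborhood).
#'
#' @param network an undirected `igraph` network.
#' @param g a gene identifier present in the network.
#' @return a list with elements `center`, `members` (character vector
#'   including the center) and `m` (member count, `degree(g) + 1`).
#' @export
local_subnetwork <- function(network, g) {
  idx <- match(g, igraph::V(network)$name)
  if (is.na(idx)) stop("gene '", g, "' is not in the network", call. = FALSE)
  nb <- igraph::neighbors(network, idx)
  members <- union(g, nb$name)
  list(center = g, members = members, m = length(members))
}

#' Graph radius of an induced subgraph
#'
#' The eccentricity of a node is its maximal shortest-path distance to any
#' other node of the induced subgraph; the radius is the minimal eccentricity
#' over its nodes. Local subnetworks are exactly the subnetworks of radius 1
#' (plus the degenerate single-node case, radius 0).
#'
#' @param network an undirected `igraph` network.
#' @param members character vector of node identifiers; must induce a
#'   connected subgraph.
#' @return a non-negative integer radius.
#' @export
graph_radius <- function(network, members) {
  missing <- setdiff(members, igraph::V(network)$name)
  if (length(missing)) {
    stop("members not in network: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sg <- igraph::induced_subgraph(network, members)
  if (!igraph::is_connected(sg)) {
    stop("members do not induce a connected subgraph; radius is undefined",
         call. = FALSE)
  }
  d <- igraph::distances(sg)
  as.integer(min(apply(d, 1L, max)))
}
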