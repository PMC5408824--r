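# Evaluate expr with a temporarily seeded RNG, restoring the previous state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Simulation configuration
#'
#' Parameters of the pathway-deregulation simulation: a number of connected
#' subnetworks ("pathways") is planted in a network, and each pathway gene,
#' with probability `p_enr`, has its P-value redrawn from (0, `p_scale`]
#' instead of the Uniform(0, 1] background. `p_scale` governs how much more
#' significant a deregulated gene looks; `p_enr` is the expected fraction of
#' pathway genes carrying signal.
#'
#' @param n_pathways number of planted subnetworks.
#' @param pathway_size genes per planted subnetwork.
#' @param p_enr per-gene redraw probability in \[0, 1\].
#' @param p_scale upper bound of the redraw interval, in (0, 1\].
#' @param target_radius optional induced graph radius the planted subnetworks
#'   must have exactly (rejection-sampled); `NULL` leaves the radius free.
#' @param seed integer seed; the simulated dataset is a pure function of
#'   (network, config).
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_pathways = 3L, pathway_size = 30L,
                              p_enr = 0.5, p_scale = 0.1,
                              target_radius = NULL, seed = 1L) {
  stopifnot(n_pathways >= 1, pathway_size >= 1,
            p_enr >= 0, p_enr <= 1, p_scale > 0, p_scale <= 1)
  if (!is.null(target_radius)) stopifnot(target_radius >= 1)
  structure(list(n_pathways = as.integer(n_pathways),
                 pathway_size = as.integer(pathway_size),
                 p_enr = p_enr, p_scale = p_scale,
                 target_radius = target_radius, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a scale-free fixture network
#'
#' Builds a connected scale-free-like network by preferential attachment with
#' triadic closure: each new node attaches its first edge to an existing node
#' with probability proportional to degree, and each further edge, with
#' probability `triad_prob`, to a random neighbor of the previously chosen
#' target (closing a triangle), falling back to preferential attachment when
#' no such neighbor is free. The closure step reproduces the strong local
#' clustering of curated functional interaction networks (where annotated
#' pathways are densely interconnected), which a pure preferential-attachment
#' graph lacks entirely; the degree distribution stays heavy-tailed. This is
#' a stand-in for a network such as STRING so that simulations and tests need
#' no external download.
#'
#' @param n_nodes number of genes.
#' @param attachment edges added per new node.
#' @param seed integer seed (optional; uses the session RNG when `NULL`).
#' @param triad_prob probability that each edge after the first closes a
#'   triangle; the default 1 gives the most clustered member of this family,
#'   the closest match to a functional interaction network at small
#'   `attachment`. 0 gives plain preferential attachment.
#' @return an undirected simple `igraph` with vertex names `g0001`, ...
#' @export
generate_fixture_network <- function(n_nodes, attachment = 3L, seed = NULL,
                                     triad_prob = 1) {
  if (n_nodes <= attachment) {
    stop("`n_nodes` must exceed `attachment`", call. = FALSE)
  }
  stopifnot(attachment >= 1, triad_prob >= 0, triad_prob <= 1)
  m <- as.integer(attachment)
  n <- as.integer(n_nodes)
  .with_seed(seed, {
    # seed clique on m + 1 nodes; replist holds every edge endpoint, so a
    # uniform draw from it is degree-proportional (preferential attachment)
    seed_pairs <- utils::combn(seq_len(m + 1L), 2L)
    edges <- as.integer(seed_pairs)
    replist <- edges
    adj <- vector("list", n)
    for (i in seq_len(ncol(seed_pairs))) {
      a <- seed_pairs[1L, i]; b <- seed_pairs[2L, i]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
    if (n > m + 1L) for (v in (m + 2L):n) {
      targets <- integer(0)
      last <- NA_integer_
      for (e in seq_len(m)) {
        cand <- NA_integer_
        if (e > 1L && stats::runif(1) < triad_prob) {
          nb <- setdiff(adj[[last]], c(targets, v))
          if (length(nb)) cand <- nb[sample.int(length(nb), 1L)]
        }
        if (is.na(cand)) repeat {
          cand <- replist[sample.int(length(replist), 1L)]
          if (!(cand %in% targets)) break
        }
        targets <- c(targets, cand)
        last <- cand
      }
      edges <- c(edges, rbind(rep(v, m), targets))
      replist <- c(replist, rbind(rep(v, m), targets))
      adj[[v]] <- targets
      for (t in targets) adj[[t]] <- c(adj[[t]], v)
    }
    g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2L, byrow = TRUE),
                                     directed = FALSE)
    g <- igraph::simplify(g)
    igraph::V(g)$name <- sprintf("g%0*d", nchar(as.character(n)), seq_len(n))
    g
  })
}

#' Sample a connected subnetwork by frontier growth
#'
#' Grows a node set from a uniformly chosen start node by repeatedly adding a
#' uniformly chosen neighbor of the current set, yielding a connected induced
#' subgraph of the requested size. This random expansion produces subnetworks
#' whose induced radius is typically well above 1 (not biased toward stars).
#'
#' @param network an undirected `igraph` network.
#' @param size number of nodes to sample.
#' @param max_tries restarts allowed when growth stalls in a small component.
#' @return character vector of `size` node identifiers.
#' @export
sample_connected_subnetwork <- function(network, size, max_tries = 100L) {
  n <- igraph::vcount(network)
  if (size > n) stop("`size` exceeds the number of nodes", call. = FALSE)
  adj <- igraph::as_adj_list(network)
  for (try in seq_len(max_tries)) {
    members <- sample.int(n, 1L)
    frontier <- setdiff(as.integer(adj[[members]]), members)
    while (length(members) < size && length(frontier)) {
      nxt <- frontier[sample.int(length(frontier), 1L)]
      members <- c(members, nxt)
      frontier <- setdiff(union(frontier, as.integer(adj[[nxt]])), members)
    }
    if (length(members) == size) return(igraph::V(network)$name[members])
  }
  stop("could not grow a connected subnetwork of size ", size,
       " in ", max_tries, " attempts (component too small?)", call. = FALSE)
}

#' Sample a connected subnetwork with a prescribed graph radius
#'
#' Rejection wrapper around [sample_connected_subnetwork()]: draws connected
#' node sets until the induced subgraph has exactly the requested
#' [graph_radius()].
#'
#' @inheritParams sample_connected_subnetwork
#' @param radius required induced graph radius.
#' @param max_tries rejection attempts before giving up.
#' @return character vector of node identifiers, with attribute `"tries"`.
#' @export
sample_subnetwork_with_radius <- function(network, size, radius,
                                          max_tries = 5000L) {
  if (radius > size - 1L) {
    stop("radius ", radius, " is impossible for size ", size,
         " (a path of n nodes has radius floor(n/2) <= n - 1)", call. = FALSE)
  }
  seen <- c(Inf, -Inf)
  for (try in seq_len(max_tries)) {
    members <- sample_connected_subnetwork(network, size)
    r <- graph_radius(network, members)
    if (r == radius) {
      attr(members, "tries") <- try
      return(members)
    }
    seen <- c(min(seen[1], r), max(seen[2], r))
  }
  stop("no subnetwork of radius ", radius, " found in ", max_tries,
       " attempts (observed radii in [", seen[1], ", ", seen[2], "])",
       call. = FALSE)
}

#' Plant deregulated pathways in a network
#'
#' Simulates a transcriptomic deregulation experiment: every gene receives an
#' i.i.d. Uniform(0, 1] background P-value, then `n_pathways` disjoint
#' connected subnetworks are planted and each of their genes, independently
#' with probability `p_enr`, has its P-value replaced by a Uniform(0,
#' `p_scale`] draw. Draws use half-open intervals so P-values stay strictly
#' positive.
#'
#' @param network an undirected connected `igraph` network.
#' @param config a [simulation_config()]; its `seed` makes the dataset a pure
#'   function of (network, config).
#' @param max_tries attempts to find disjoint pathways before erroring.
#' @return a list of class `lean_sim`: `scores` (a [score_table()]),
#'   `pathway_genes` (union of planted members, the ROC positives),
#'   `pathways` (list of `list(members, radius)`), `redrawn` (genes whose
#'   P-value was actually replaced) and `config`.
#' @export
plant_deregulation <- function(network, config, max_tries = 100L) {
  stopifnot(inherits(config, "simulation_config"))
  n <- igraph::vcount(network)
  if (config$n_pathways * config$pathway_size > n) {
    stop("requested pathways exceed the node budget of the network",
         call. = FALSE)
  }
  .with_seed(config$seed, {
    pathways <- list()
    taken <- character(0)
    for (i in seq_len(config$n_pathways)) {
      for (try in seq_len(max_tries)) {
        members <- if (is.null(config$target_radius)) {
          sample_connected_subnetwork(network, config$pathway_size)
        } else {
          sample_subnetwork_with_radius(network, config$pathway_size,
                                        config$target_radius)
        }
        if (!length(intersect(members, taken))) break
        members <- NULL
      }
      if (is.null(members)) {
        stop("could not place ", config$n_pathways,
             " disjoint pathways in ", max_tries, " attempts", call. = FALSE)
      }
      pathways[[i]] <- list(members = as.character(members),
                            radius = graph_radius(network, members))
      taken <- c(taken, members)
    }
    genes <- igraph::V(network)$name
    p <- 1 - stats::runif(n)                     # Uniform(0, 1]
    names(p) <- genes
    pathway_genes <- unique(unlist(lapply(pathways, `[[`, "members")))
    hit <- pathway_genes[stats::runif(length(pathway_genes)) < config$p_enr]
    p[hit] <- config$p_scale * (1 - stats::runif(length(hit)))
    structure(list(scores = score_table(p), pathway_genes = pathway_genes,
                   pathways = pathways, redrawn = hit, config = config),
              class = "lean_sim")
  })
}

#' @export
print.lean_sim <- function(x, ...) {
  cat("Simulated deregulation dataset:", length(x$scores), "genes,",
      length(x$pathways), "planted pathway(s) of size",
      x$config$pathway_size, "\n")
  cat("  radii:", paste(vapply(x$pathways, `[[`, numeric(1), "radius"),
                        collapse = ", "),
      "| redrawn genes:", length(x$redrawn),
      sprintf("(p_enr = %.2f, p_scale = %.2g)\n",
              x$config$p_enr, x$config$p_scale))
  invisible(x)
}

#' Randomly rewire a fraction of network edges
#'
#' Removes `ceiling(fraction * |E|)` randomly chosen edges and replaces each
#' with a new edge between a uniformly chosen, currently unconnected node
#' pair (no self-loops), preserving the edge count but not the degree
#' sequence. Set `keep_degree = TRUE` for degree-preserving double-edge
#' swaps instead.
#'
#' @param network an undirected `igraph` network.
#' @param fraction fraction of edges to rewire, in \[0, 1\].
#' @param seed optional integer seed.
#' @param keep_degree use degree-preserving edge swaps.
#' @return a rewired copy of the network; the input is unmodified.
#' @export
rewire_network <- function(network, fraction, seed = NULL,
                           keep_degree = FALSE) {
  stopifnot(fraction >= 0, fraction <= 1)
  n_rw <- ceiling(fraction * igraph::ecount(network))
  if (n_rw == 0L) return(network)
  .with_seed(seed, {
    if (keep_degree) {
      return(igraph::rewire(network,
                            igraph::keeping_degseq(niter = n_rw)))
    }
    g <- network
    n <- igraph::vcount(g)
    drop <- sample.int(igraph::ecount(g), n_rw)
    g <- igraph::delete_edges(g, drop)
    max_attempts <- 100L * n_rw + 1000L
    added <- 0L
    while (added < n_rw && max_attempts > 0L) {
      pair <- sample.int(n, 2L)
      max_attempts <- max_attempts - 1L
      if (!igraph::are_adjacent(g, pair[1], pair[2])) {
        g <- igraph::add_edges(g, pair)
        added <- added + 1L
      }
    }
    if (added < n_rw) {
      stop("network too dense to place ", n_rw, " replacement edges",
           call. = FALSE)
    }
    g
  })
}
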