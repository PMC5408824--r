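# Independent brute-force oracles, kept free of the code paths they check.

# Binomial upper tail by direct term-by-term enumeration.
naive_binomial_tail <- function(k, m, p) {
  sum(choose(m, k:m) * p^(k:m) * (1 - p)^(m - (k:m)))
}

# Enrichment score by enumeration over all prefix lengths.
naive_enrichment <- function(p) {
  sp <- sort(p)
  m <- length(sp)
  tails <- vapply(seq_len(m), function(k) naive_binomial_tail(k, m, sp[k]),
                  numeric(1))
  k_star <- which.min(tails)
  list(es = -log10(tails[k_star]), k_star = k_star,
       p_tilde_min = tails[k_star], p_k_star = sp[k_star])
}

# Textbook Benjamini-Hochberg step-up recursion.
bh_recursion <- function(p) {
  n <- length(p)
  o <- order(p)
  s <- p[o]
  adj <- numeric(n)
  adj[n] <- s[n]
  if (n > 1) for (i in (n - 1):1) adj[i] <- min(adj[i + 1], n / i * s[i])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# AUC as the normalized Mann-Whitney statistic over all positive/negative
# pairs (smaller score = more significant).
mw_auc <- function(score, label) {
  pos <- score[as.logical(label)]
  neg <- score[!as.logical(label)]
  cmp <- outer(pos, neg, function(a, b) (a < b) + 0.5 * (a == b))
  mean(cmp)
}

# Graph radius by brute-force all-pairs BFS on an explicit edge list.
naive_radius <- function(edges, nodes) {
  adj <- lapply(nodes, function(v) {
    unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))
  })
  names(adj) <- nodes
  ecc <- vapply(nodes, function(v) {
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    dist[v] <- 0
    queue <- v
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      for (w in adj[[u]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[u] + 1
          queue <- c(queue, w)
        }
      }
    }
    max(dist)
  }, numeric(1))
  min(ecc)
}

# Small named fixtures.
make_star <- function(n_leaves, center = "hub") {
  leaves <- paste0("leaf", seq_len(n_leaves))
  gene_network(cbind(center, leaves))
}

make_path <- function(nodes) {
  gene_network(cbind(nodes[-length(nodes)], nodes[-1]))
}
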