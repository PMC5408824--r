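#' Local GSEA comparator score
#'
#' Applies the classical weighted Kolmogorov-Smirnov running-sum enrichment
#' statistic to a gene's local subnetwork, treating the neighborhood as the
#' gene set and ranking all scored genes of the restricted network by
#' decreasing -log10(P). Returns the maximum positive deviation of the
#' running sum. This is a ranking comparator only: no permutation
#' normalization is applied (rank-equivalent for benchmarking).
#'
#' @param network an undirected `igraph` network.
#' @param scores a [score_table()] or named numeric vector of P-values.
#' @param g center gene identifier.
#' @param weight_exponent exponent on the ranking statistic for hit weights
#'   (0 gives the unweighted KS statistic; default 1).
#' @return a scalar score; larger means more enriched.
#' @export
local_gsea_score <- function(network, scores, g, weight_exponent = 1) {
  scores <- if (inherits(scores, "score_table")) scores else score_table(scores)
  net <- restrict_network(network, scores)
  if (!g %in% igraph::V(net)$name) {
    stop("gene '", g, "' is not in the restricted network", call. = FALSE)
  }
  genes <- igraph::V(net)$name
  stat <- -log10(as.numeric(scores[genes]))
  set <- local_subnetwork(net, g)$members
  ord <- order(stat, decreasing = TRUE)
  hit <- genes[ord] %in% set
  n_miss <- sum(!hit)
  if (n_miss == 0L) return(0)
  w <- abs(stat[ord])^weight_exponent
  w[!hit] <- 0
  denom <- sum(w)
  p_hit <- if (denom > 0) cumsum(w) / denom else cumsum(hit) / sum(hit)
  p_miss <- cumsum(!hit) / n_miss
  max(p_hit - p_miss)
}

#' Hypergeometric enrichment test of a gene list
#'
#' Upper-tail hypergeometric P-value for the overlap between a list of
#' detected genes and a target gene set within a common universe (the
#' classical one-sided over-representation test).
#'
#' @param significant character vector of detected genes (subset of
#'   `universe`).
#' @param target character vector of target genes (subset of `universe`).
#' @param universe character vector of all genes considered.
#' @return a P-value in (0, 1].
#' @export
hypergeometric_list_test <- function(significant, target, universe) {
  significant <- unique(as.character(significant))
  target <- unique(as.character(target))
  universe <- unique(as.character(universe))
  if (length(setdiff(significant, universe))) {
    stop("`significant` must be a subset of `universe`", call. = FALSE)
  }
  if (length(setdiff(target, universe))) {
    stop("`target` must be a subset of `universe`", call. = FALSE)
  }
  q <- length(intersect(significant, target))
  if (q == 0L) return(1)
  stats::phyper(q - 1L, m = length(target),
                n = length(universe) - length(target),
                k = length(significant), lower.tail = FALSE)
}
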