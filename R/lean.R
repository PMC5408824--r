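#' Local enrichment analysis of a scored interaction network
#'
#' For every gene of the network (restricted to scored genes), tests whether
#' the gene's direct neighborhood is enriched for low P-values. The
#' neighborhood P-values are scored with a binomial order-statistic
#' enrichment score ([enrichment_score()]), calibrated against an empirical
#' background of random gene sets of the same size drawn from the pooled
#' input P-values ([sample_background()]), and the resulting empirical
#' P-values are Benjamini-Hochberg corrected across all candidate centers.
#'
#' Background distributions are computed once per distinct neighborhood size
#' and shared across all centers of that size; the random seed is advanced
#' deterministically per size in ascending order, so results do not depend on
#' node iteration order.
#'
#' @param network an undirected `igraph` network (see [gene_network()]).
#' @param scores a [score_table()] or named numeric vector of P-values in
#'   (0, 1].
#' @param n_samples background samples per neighborhood size (default 10000).
#' @param seed integer seed controlling all background sampling; when `NULL`
#'   a seed is drawn from the session RNG and recorded in the result.
#' @param background_pool `"scored-and-in-network"` (default) draws background
#'   gene sets from the P-values of the restricted analysis universe;
#'   `"all-scored"` draws from every scored gene, including those absent from
#'   the network.
#' @param replace sample background gene sets with replacement?
#' @return an object of class `lean`: a list with `results` (data frame with
#'   columns `center`, `m`, `k_star`, `p_k_star`, `es`, `p_star`, `lean_p`,
#'   sorted by `lean_p` with ties broken by center identifier), `n_samples`,
#'   `seed`, `background_pool`, `replace`, `n_genes`, `n_edges` and `call`.
#' @examples
#' net <- generate_fixture_network(60, attachment = 2, seed = 1)
#' sc <- score_table(stats::setNames(1 - stats::runif(60),
#'                                   igraph::V(net)$name))
#' fit <- lean(net, sc, n_samples = 200, seed = 1)
#' head(as.data.frame(fit))
#' @export
lean <- function(network, scores, n_samples = 10000L, seed = NULL,
                 background_pool = c("scored-and-in-network", "all-scored"),
                 replace = FALSE) {
  background_pool <- match.arg(background_pool)
  scores <- if (inherits(scores, "score_table")) scores else score_table(scores)
  net <- restrict_network(network, scores)
  genes <- igraph::V(net)$name
  if (is.null(seed)) seed <- sample.int(2^31 - 10^6, 1L)
  seed <- as.integer(seed)

  pool <- if (background_pool == "all-scored") {
    as.numeric(scores)
  } else {
    as.numeric(scores[genes])
  }

  adj <- igraph::adjacent_vertices(net, genes)
  member_p <- lapply(seq_along(genes), function(i) {
    as.numeric(scores[c(genes[i], adj[[i]]$name)])
  })
  sizes <- lengths(member_p)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  distinct_m <- sort(unique(sizes))
  bg <- vector("list", max(distinct_m))
  for (i in seq_along(distinct_m)) {
    m <- distinct_m[i]
    set.seed((seed + i) %% (2^31 - 1))
    bg[[m]] <- sample_background(pool, m, n_samples = n_samples,
                                 replace = replace)
  }

  es_fit <- lapply(member_p, enrichment_score)
  es <- vapply(es_fit, `[[`, numeric(1), "es")
  p_star <- vapply(seq_along(genes), function(i) {
    empirical_pvalue(es[i], bg[[sizes[i]]])
  }, numeric(1))

  results <- data.frame(
    center = genes,
    m = as.integer(sizes),
    k_star = vapply(es_fit, `[[`, integer(1), "k_star"),
    p_k_star = vapply(es_fit, `[[`, numeric(1), "p_k_star"),
    es = es,
    p_star = p_star,
    lean_p = bh_adjust(p_star),
    stringsAsFactors = FALSE
  )
  results <- results[order(results$lean_p, results$center), , drop = FALSE]
  rownames(results) <- NULL

  structure(
    list(results = results, n_samples = as.integer(n_samples), seed = seed,
         background_pool = background_pool, replace = replace,
         n_genes = length(genes), n_edges = igraph::ecount(net),
         call = match.call()),
    class = "lean"
  )
}

#' @export
print.lean <- function(x, ...) {
  cat("Local enrichment analysis\n")
  cat("  analysis universe:", x$n_genes, "genes,", x$n_edges, "edges\n")
  cat("  background:", x$n_samples, "samples per size, pool =",
      x$background_pool, ", seed =", x$seed, "\n")
  n_sig <- sum(x$results$lean_p <= 0.05)
  cat("  centers with BH-corrected P <= 0.05:", n_sig, "\n")
  invisible(x)
}

#' @param object,x a `lean` fit.
#' @param alpha significance cutoff on the BH-corrected P-value.
#' @param ... unused.
#' @rdname lean
#' @export
summary.lean <- function(object, alpha = 0.05, ...) {
  res <- object$results
  sig <- res[res$lean_p <= alpha, , drop = FALSE]
  out <- list(n_genes = object$n_genes, n_edges = object$n_edges,
              n_samples = object$n_samples, alpha = alpha,
              n_significant = nrow(sig),
              top = utils::head(res, 10L), significant = sig)
  class(out) <- "summary.lean"
  out
}

#' @export
print.summary.lean <- function(x, ...) {
  cat("Local enrichment analysis of ", x$n_genes, " genes (", x$n_edges,
      " edges), ", x$n_samples, " background samples per size\n", sep = "")
  cat(x$n_significant, "significant local subnetwork center(s) at alpha =",
      x$alpha, "\n\nTop candidates:\n")
  print(x$top, digits = 4)
  invisible(x)
}

#' @rdname lean
#' @export
as.data.frame.lean <- function(x, ...) x$results

#' @export
plot.lean <- function(x, alpha = 0.05, ...) {
  res <- x$results
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::hist(res$p_star, breaks = 20, main = "Enrichment P-values",
                 xlab = "p*", col = "grey85")
  graphics::abline(h = nrow(res) / 20, lty = 2)
  sig <- res$lean_p <= alpha
  graphics::plot(res$m, res$es, log = "x", pch = 19, cex = 0.5,
                 col = ifelse(sig, "firebrick", "grey50"),
                 xlab = "neighborhood size m", ylab = "enrichment score")
  invisible(x)
}

#' Significant local subnetwork centers
#'
#' @param results a `lean` fit or its results data frame.
#' @param alpha cutoff in (0, 1] applied to the BH-corrected P-value.
#' @return character vector of center gene identifiers.
#' @export
significant_centers <- function(results, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1) {
    stop("`alpha` must be a single value in (0, 1]", call. = FALSE)
  }
  res <- if (inherits(results, "lean")) results$results else results
  res$center[res$lean_p <= alpha]
}
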