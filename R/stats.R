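#' Binomial tail probability
#'
#' Probability that at least `k` of `m` i.i.d. Uniform(0,1) P-values fall at
#' or below `p`, i.e. the upper tail of a Binomial(m, p) distribution at k.
#' Computed with the numerically stable survival function, not naive
#' summation.
#'
#' @param k integer, 1 <= k <= m.
#' @param m integer, the neighborhood size.
#' @param p success probability in \[0, 1\].
#' @return the tail probability in \[0, 1\]. Vectorized over `k`, `m`, `p`.
#' @export
binomial_tail <- function(k, m, p) {
  if (any(k < 1L) || any(k > m)) {
    stop("`k` must satisfy 1 <= k <= m", call. = FALSE)
  }
  if (any(p < 0) || any(p > 1)) stop("`p` must lie in [0, 1]", call. = FALSE)
  stats::pbinom(k - 1L, size = m, prob = p, lower.tail = FALSE)
}

#' Local enrichment score of a set of P-values
#'
#' Sorts the neighborhood P-values ascending and, for every prefix length k,
#' evaluates the binomial tail probability that at least k of m uniform
#' P-values are <= the k-th sorted value. The enrichment score is -log10 of
#' the minimal tail over all prefixes; ties are broken toward the smallest k
#' (the strongest leading edge).
#'
#' @param p numeric vector of P-values in (0, 1] (the neighborhood values,
#'   in any order).
#' @return a list of class `enrichment_score` with elements `es`
#'   (non-negative), `k_star` (smallest argmin prefix length), `p_tilde_min`
#'   (the minimal binomial tail), `p_k_star` (the k*-th sorted input P-value)
#'   and `m`.
#' @examples
#' enrichment_score(c(0.01, 0.2, 0.9))
#' @export
enrichment_score <- function(p) {
  if (!length(p)) stop("empty P-value sequence", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("P-values must lie in (0, 1]", call. = FALSE)
  }
  m <- length(p)
  sp <- sort(p)
  p_tilde <- stats::pbinom(0:(m - 1L), size = m, prob = sp, lower.tail = FALSE)
  k_star <- which.min(p_tilde)
  structure(
    list(es = -log10(p_tilde[k_star]), k_star = as.integer(k_star),
         p_tilde_min = p_tilde[k_star], p_k_star = sp[k_star], m = m),
    class = "enrichment_score"
  )
}

#' @export
print.enrichment_score <- function(x, ...) {
  cat(sprintf("ES = %.4f (m = %d, k* = %d, p_k* = %.4g, min tail = %.4g)\n",
              x$es, x$m, x$k_star, x$p_k_star, x$p_tilde_min))
  invisible(x)
}

#' Empirical background distribution of enrichment scores
#'
#' Draws `n_samples` random gene sets of size `m` from the pooled input
#' P-values and scores each with [enrichment_score()], giving the null
#' distribution used to calibrate observed scores of neighborhoods of the
#' same size. Sampling is without replacement by default (a random gene set
#' is a set); with-replacement sampling is available for pools barely larger
#' than `m`.
#'
#' Uses the session RNG; seed it (or let [lean()] do so) for reproducibility.
#'
#' @param pool numeric vector of pooled P-values (e.g. a [score_table()]).
#' @param m gene-set size.
#' @param n_samples number of background samples.
#' @param replace sample with replacement?
#' @return a list of class `lean_background` with elements `size`, `samples`
#'   (the ES values), `n_samples`.
#' @export
sample_background <- function(pool, m, n_samples = 10000L, replace = FALSE) {
  pool <- as.numeric(pool)
  n_pool <- length(pool)
  if (!replace && m > n_pool) {
    stop("gene-set size m = ", m, " exceeds pool size ", n_pool, call. = FALSE)
  }
  if (m < 1L || n_samples < 1L) stop("m and n_samples must be >= 1", call. = FALSE)
  idx <- vapply(seq_len(n_samples),
                function(i) sample.int(n_pool, m, replace = replace),
                integer(m))
  X <- matrix(pool[idx], nrow = n_samples, ncol = m, byrow = TRUE)
  es <- .es_rows(X)
  structure(list(size = as.integer(m), samples = es,
                 n_samples = as.integer(n_samples)),
            class = "lean_background")
}

# Vectorized enrichment score over the rows of a P-value matrix.
# Row-sorts via a single order() call, evaluates all binomial tails in one
# pbinom() call, and reduces with pmin; equals enrichment_score() row-wise.
.es_rows <- function(X) {
  n <- nrow(X)
  m <- ncol(X)
  Xs <- matrix(X[order(row(X), X)], nrow = n, byrow = TRUE)
  K <- matrix(0:(m - 1L), nrow = n, ncol = m, byrow = TRUE)
  Pt <- stats::pbinom(K, size = m, prob = Xs, lower.tail = FALSE)
  -log10(do.call(pmin, as.data.frame(Pt)))
}

#' Empirical enrichment P-value
#'
#' The probability, under the size-matched null, of a background enrichment
#' score at least as large as the observed one, estimated with the
#' add-one (r + 1)/(n + 1) convention so the result is a valid P-value and
#' never exactly 0. Ties count toward the exceedance.
#'
#' @param es observed enrichment score (non-negative).
#' @param background a `lean_background` from [sample_background()], or a
#'   numeric vector of background ES values.
#' @return a P-value in (0, 1\].
#' @export
empirical_pvalue <- function(es, background) {
  samples <- if (inherits(background, "lean_background")) {
    background$samples
  } else {
    as.numeric(background)
  }
  if (!length(samples)) stop("empty background distribution", call. = FALSE)
  (sum(samples >= es) + 1) / (length(samples) + 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment; output order matches
#' input order and values are capped at 1.
#'
#' @param p numeric vector of P-values in (0, 1\].
#' @return adjusted P-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) stop("empty P-value vector", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("P-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
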