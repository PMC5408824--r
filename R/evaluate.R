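#' ROC curve points for a gene ranking
#'
#' Computes the ROC staircase for a scored gene list against binary truth
#' labels. Scores follow the P-value convention: smaller means more
#' significant. Tied scores are grouped into a single step, so within-tie
#' ordering cannot inflate the curve.
#'
#' @param score numeric vector; smaller = more confidently positive.
#' @param label logical (or 0/1) vector of the same length; `TRUE` =
#'   positive.
#' @return a data frame with columns `fpr` and `tpr`, a monotone staircase
#'   from (0, 0) to (1, 1).
#' @export
roc_points <- function(score, label) {
  label <- as.logical(label)
  if (length(score) != length(label) || anyNA(score) || anyNA(label)) {
    stop("`score` and `label` must be complete vectors of equal length",
         call. = FALSE)
  }
  n_pos <- sum(label)
  n_neg <- sum(!label)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs at least one positive and one negative", call. = FALSE)
  }
  ord <- order(score)
  s <- score[ord]
  l <- label[ord]
  grp_end <- c(which(diff(s) > 0), length(s))
  tp <- cumsum(l)[grp_end]
  fp <- cumsum(!l)[grp_end]
  data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
}

#' Area under a ROC curve
#'
#' Trapezoidal area under a staircase produced by [roc_points()].
#'
#' @param points data frame with `fpr`, `tpr` columns.
#' @return area in \[0, 1\].
#' @export
roc_auc <- function(points) {
  x <- points$fpr
  y <- points$tpr
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Partial area under a ROC curve
#'
#' Integrates the ROC staircase over the low false-positive-rate range
#' `[0, fpr_max]`, interpolating linearly at the cut. Reported both raw (area
#' in units of the full square) and normalized by `fpr_max` (1 = perfect).
#'
#' @param points data frame from [roc_points()].
#' @param fpr_max upper FPR bound, in (0, 1].
#' @return list with elements `raw` and `normalized`.
#' @export
roc_pauc <- function(points, fpr_max = 0.05) {
  if (!is.numeric(fpr_max) || fpr_max <= 0 || fpr_max > 1) {
    stop("`fpr_max` must lie in (0, 1]", call. = FALSE)
  }
  x <- points$fpr
  y <- points$tpr
  if (fpr_max < max(x)) {
    i <- findInterval(fpr_max, x)
    y_cut <- if (x[i + 1L] == x[i]) y[i] else {
      y[i] + (y[i + 1L] - y[i]) * (fpr_max - x[i]) / (x[i + 1L] - x[i])
    }
    keep <- x <= fpr_max
    x <- c(x[keep], fpr_max)
    y <- c(y[keep], y_cut)
  }
  raw <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  list(raw = raw, normalized = raw / fpr_max)
}

#' Jaccard index of two gene sets
#'
#' @param a,b character vectors (treated as sets).
#' @return `|a n b| / |a u b|`; 0 when both sets are empty.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Gene-level ranking scores from a LEAN fit
#'
#' Maps a fitted [lean()] object onto an arbitrary gene universe for ROC
#' evaluation: each gene gets its BH-corrected LEAN P-value; genes without a
#' result (e.g. absent from the network) get 1, the least significant score,
#' so that rankings from different methods share the same universe.
#'
#' @param fit a `lean` object.
#' @param genes character vector, the evaluation universe.
#' @return named numeric vector of scores over `genes` (smaller = better).
#' @export
lean_ranking <- function(fit, genes) {
  res <- if (inherits(fit, "lean")) fit$results else fit
  out <- stats::setNames(rep(1, length(genes)), genes)
  hit <- match(res$center, genes)
  ok <- !is.na(hit)
  out[hit[ok]] <- res$lean_p[ok]
  out
}
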