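#' Construct a gene score table
#'
#' A score table maps gene identifiers to input P-values in (0, 1], typically
#' from a gene-level differential-expression test. Values of exactly 0 are
#' rejected: a zero would make the log of its binomial tail infinite, so users
#' should floor such values (e.g. at machine epsilon) before import.
#'
#' @param p numeric vector of P-values, or a two-column data frame
#'   (gene, pvalue).
#' @param genes character vector of gene identifiers (ignored when `p` is a
#'   data frame; required otherwise unless `p` is already named).
#' @return a named numeric vector of class `score_table`.
#' @examples
#' score_table(c(g1 = 0.01, g2 = 0.5))
#' @export
score_table <- function(p, genes = NULL) {
  if (is.data.frame(p)) {
    genes <- as.character(p[[1]])
    p <- p[[2]]
  }
  if (!is.null(genes)) names(p) <- as.character(genes)
  if (is.null(names(p))) stop("gene identifiers are required", call. = FALSE)
  if (!is.numeric(p)) stop("P-values must be numeric", call. = FALSE)
  bad <- !is.finite(p) | p <= 0 | p > 1
  if (any(bad)) {
    stop("invalid P-value(s) for gene(s) ",
         paste(utils::head(names(p)[bad], 5), collapse = ", "),
         ": values must lie in (0, 1]; floor exact zeros before import",
         call. = FALSE)
  }
  if (anyDuplicated(names(p))) {
    stop("duplicate gene identifier(s): ",
         paste(unique(names(p)[duplicated(names(p))]), collapse = ", "),
         call. = FALSE)
  }
  structure(as.numeric(stats::setNames(p, names(p))), names = names(p),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat("Gene score table:", length(x), "genes, P-values in [",
      format(min(x), digits = 3), ",", format(max(x), digits = 3), "]\n")
  invisible(x)
}

#' @export
`[.score_table` <- function(x, i) {
  out <- unclass(x)[i]
  class(out) <- "score_table"
  out
}
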