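# Full-precision scientific formatting used for all numeric output, so that
# written files round-trip exactly and identical runs are byte-identical.
.fmt_num <- function(x) formatC(x, format = "e", digits = 16)

#' Read an interaction network from an edge-list file
#'
#' Supported formats: `tsv` (two or three whitespace-separated columns:
#' gene1, gene2 and an optional numeric score), `sif` (Simple Interaction
#' Format: source, relation type, one or more targets; single-token lines are
#' isolated nodes) and `string-links` (STRING protein-links dialect: header
#' line, then protein1, protein2 and an integer `combined_score` in
#' \[0, 1000\]).
#'
#' When `min_score` is given, edges scoring below it are dropped. For
#' `string-links`, a `min_score` in (0, 1] is interpreted on STRING's 0-1
#' confidence scale and compared against `combined_score / 1000` (so 0.9
#' keeps scores >= 900); larger values are compared to the integer score
#' directly. Self-loops and duplicate edges are dropped with a message.
#'
#' @param path file path.
#' @param format one of `"tsv"`, `"sif"`, `"string-links"`.
#' @param min_score optional numeric score threshold (inclusive).
#' @return an undirected simple `igraph` (see [gene_network()]).
#' @export
read_edge_list <- function(path, format = c("tsv", "sif", "string-links"),
                           min_score = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")

  bad_line <- function(i, why) {
    stop("malformed line ", lineno[i], " in '", path, "': ", why,
         call. = FALSE)
  }

  if (format == "string-links") {
    if (!length(fields)) stop("empty file: ", path, call. = FALSE)
    header <- fields[[1]]
    if (length(header) < 3 || !any(grepl("score", header))) {
      stop("'", path, "' does not look like STRING protein-links ",
           "(expected a header with a score column)", call. = FALSE)
    }
    fields <- fields[-1L]
    lineno <- lineno[-1L]
    edges <- matrix(character(0), 0, 2)
    sc <- numeric(0)
    for (i in seq_along(fields)) {
      f <- fields[[i]]
      if (length(f) < 3) bad_line(i, "expected protein1 protein2 score")
      s <- suppressWarnings(as.numeric(f[3]))
      if (is.na(s)) bad_line(i, "non-numeric combined_score")
      edges <- rbind(edges, f[1:2])
      sc <- c(sc, s)
    }
    if (!is.null(min_score)) {
      thr <- if (min_score > 0 && min_score <= 1) round(min_score * 1000) else min_score
      edges <- edges[sc >= thr, , drop = FALSE]
    }
    return(gene_network(edges))
  }

  if (format == "sif") {
    edges <- matrix(character(0), 0, 2)
    isolated <- character(0)
    for (i in seq_along(fields)) {
      f <- fields[[i]]
      if (length(f) == 1L) {
        isolated <- c(isolated, f)
      } else if (length(f) >= 3L) {
        edges <- rbind(edges, cbind(f[1], f[3:length(f)]))
      } else {
        bad_line(i, "SIF lines need 1 token (isolated node) or >= 3")
      }
    }
    return(gene_network(edges, nodes = isolated))
  }

  # tsv
  edges <- matrix(character(0), 0, 2)
  sc <- numeric(0)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (!length(f) %in% 2:3) bad_line(i, "expected 2 or 3 columns")
    s <- if (length(f) == 3L) suppressWarnings(as.numeric(f[3])) else NA_real_
    if (length(f) == 3L && is.na(s)) bad_line(i, "non-numeric edge score")
    edges <- rbind(edges, f[1:2])
    sc <- c(sc, s)
  }
  if (!is.null(min_score)) {
    drop <- !is.na(sc) & sc < min_score
    edges <- edges[!drop, , drop = FALSE]
  }
  gene_network(edges)
}

#' Read a gene score table from a TSV file
#'
#' Expects two tab- or whitespace-separated columns (gene identifier,
#' P-value), with or without a header line. Non-numeric or out-of-range
#' P-values and duplicate gene identifiers are rejected with the offending
#' line numbers.
#'
#' @param path file path.
#' @return a [score_table()].
#' @export
read_scores <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  n_col <- lengths(fields)
  if (any(n_col != 2L)) {
    stop("malformed line ", lineno[which(n_col != 2L)[1]], " in '", path,
         "': expected 2 columns (gene, pvalue)", call. = FALSE)
  }
  genes <- vapply(fields, `[[`, character(1), 1L)
  pv <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  if (length(pv) && is.na(pv[1]) && length(pv) > 1) {
    # header line
    genes <- genes[-1L]
    pv <- pv[-1L]
    lineno <- lineno[-1L]
  }
  bad <- is.na(pv) | pv <= 0 | pv > 1
  if (any(bad)) {
    stop("invalid P-value(s) at line(s) ",
         paste(utils::head(lineno[bad], 5), collapse = ", "), " in '", path,
         "': values must be numeric and in (0, 1]", call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    dup <- genes[duplicated(genes)][1]
    stop("duplicate gene '", dup, "' at line ",
         lineno[which(genes == dup)[2]], " in '", path, "'", call. = FALSE)
  }
  score_table(pv, genes)
}

#' Write LEAN results to a TSV file
#'
#' Columns are exactly `center`, `m`, `k_star`, `p_k_star`, `es`, `p_star`,
#' `lean_p`, sorted ascending by `lean_p` with ties broken by center
#' identifier; all reals are written in full-precision scientific notation so
#' a round-trip reproduces the numbers exactly.
#'
#' @param results a `lean` fit or its results data frame.
#' @param path output file path.
#' @export
write_results <- function(results, path) {
  res <- if (inherits(results, "lean")) results$results else results
  res <- res[order(res$lean_p, res$center), , drop = FALSE]
  out <- data.frame(center = res$center, m = res$m, k_star = res$k_star,
                    p_k_star = .fmt_num(res$p_k_star), es = .fmt_num(res$es),
                    p_star = .fmt_num(res$p_star),
                    lean_p = .fmt_num(res$lean_p), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a results file written by [write_results()]
#'
#' @param path file path.
#' @return a results data frame.
#' @export
read_results <- function(path) {
  res <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "integer",
                                          "numeric", "numeric", "numeric",
                                          "numeric"))
  names(res) <- c("center", "m", "k_star", "p_k_star", "es", "p_star",
                  "lean_p")
  res
}

#' Build a reproducibility manifest for a LEAN run
#'
#' Records input paths with MD5 content hashes, the background sample count,
#' seed, significance cutoff, package version and a timestamp — enough to
#' reproduce a run bit for bit (the timestamp is informational).
#'
#' @param network_path,scores_path input file paths.
#' @param n_samples,seed,alpha run parameters.
#' @return a list of class `run_manifest`.
#' @export
run_manifest <- function(network_path, scores_path, n_samples, seed,
                         alpha = 0.05) {
  inputs <- list(
    network = list(path = network_path,
                   md5 = unname(tools::md5sum(network_path))),
    scores = list(path = scores_path,
                  md5 = unname(tools::md5sum(scores_path)))
  )
  structure(list(inputs = inputs, n_samples = n_samples, seed = seed,
                 alpha = alpha,
                 version = as.character(utils::packageVersion("leanet")),
                 timestamp = format(Sys.time(), tz = "UTC")),
            class = "run_manifest")
}

#' Write a manifest as JSON
#'
#' @param manifest a [run_manifest()].
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
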