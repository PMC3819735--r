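#' Directed binary network
#'
#' Container for a directed network of binary neurons.  The adjacency is
#' stored as a sparse binary matrix \code{w} with the convention that
#' \code{w[i, j] == 1} means there is an edge \emph{from node j to node i}
#' (j presynaptic, i postsynaptic).  Consequently the in-degree of node
#' \code{i} is the i-th row sum and the out-degree of node \code{j} is the
#' j-th column sum.
#'
#' @param w adjacency matrix (anything coercible to a sparse
#'   \code{\link[Matrix]{dgCMatrix-class}}); entries must be 0/1 and the
#'   diagonal must be zero.
#' @param kind optional character tag recording how the network was
#'   generated (e.g. \code{"anti"}, \code{"er"}).
#' @param meta optional named list of generator metadata (artifact rates,
#'   prescribed degrees, ...).
#'
#' @return An object of class \code{directed_network} with elements
#'   \code{w} (sparse adjacency), \code{n_nodes}, \code{edge_count},
#'   \code{kind} and \code{meta}.
#' @export
directed_network <- function(w, kind = NA_character_, meta = list()) {
  if (!inherits(w, "Matrix")) w <- Matrix::Matrix(w, sparse = TRUE)
  w <- methods::as(methods::as(methods::as(w, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  w <- Matrix::drop0(w)
  if (nrow(w) != ncol(w))
    stop("adjacency must be square")
  if (any(w@x != 1))
    stop("adjacency entries must be binary 0/1")
  if (any(Matrix::diag(w) != 0))
    stop("adjacency diagonal must be zero (no self-loops)")
  structure(
    list(w = w,
         n_nodes = nrow(w),
         edge_count = length(w@x),
         kind = kind,
         meta = meta),
    class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("<directed_network> %d nodes, %d edges%s\n",
              x$n_nodes, x$edge_count,
              if (is.na(x$kind)) "" else sprintf(" [%s]", x$kind)))
  din <- in_degree(x); dout <- out_degree(x)
  cat(sprintf("  mean degree %.2f; in-degree sd %.2f; out-degree sd %.2f\n",
              mean(din), stats::sd(din), stats::sd(dout)))
  if (x$n_nodes >= 3 && stats::sd(din) > 0 && stats::sd(dout) > 0)
    cat(sprintf("  in/out degree correlation rho = %.3f\n",
                degree_correlation(x)))
  invisible(x)
}

#' Node degrees
#'
#' In-degree (number of afferent edges) and out-degree (number of efferent
#' edges) per node.
#'
#' @param net a \code{\link{directed_network}}.
#' @return Integer vector of length \code{n_nodes}.
#' @export
in_degree <- function(net) as.integer(round(Matrix::rowSums(net$w)))

#' @rdname in_degree
#' @export
out_degree <- function(net) as.integer(round(Matrix::colSums(net$w)))

#' Correlation between a node's in- and out-degree
#'
#' Signed Pearson correlation of \code{(in_degree, out_degree)} across
#' nodes.  This is the single-node degree correlation (not assortativity,
#' which correlates degrees of connected node pairs).
#'
#' @param net a \code{\link{directed_network}} with at least 3 nodes.
#' @return Scalar correlation in \code{[-1, 1]}.
#' @export
degree_correlation <- function(net) {
  if (net$n_nodes < 3) stop("need at least 3 nodes")
  din <- in_degree(net); dout <- out_degree(net)
  if (stats::sd(din) == 0 || stats::sd(dout) == 0)
    stop("degree correlation undefined: zero variance in a marginal")
  stats::cor(din, dout)
}

#' Read and write directed networks
#'
#' Two plain-text formats are supported.  Edge-list TSV has a header line
#' \code{source<TAB>target} and 0-based node ids, one edge per line
#' (source = presynaptic j, target = postsynaptic i).  Matrix Market
#' coordinate pattern format stores the adjacency with the convention
#' row = target (postsynaptic), column = source (presynaptic), 1-based
#' indices as required by the format; the convention is recorded in a
#' comment line.
#'
#' @param net a \code{\link{directed_network}}.
#' @param path file path; format chosen by extension (\code{.mtx} for
#'   Matrix Market, anything else is edge-list TSV) unless \code{format}
#'   is given.
#' @param format \code{"tsv"} or \code{"mtx"}.
#' @param n_nodes for TSV input, the number of nodes (needed because
#'   isolated nodes do not appear in an edge list); defaults to
#'   \code{max(id) + 1}.
#' @return \code{write_network} returns \code{path} invisibly;
#'   \code{read_network} returns a \code{\link{directed_network}}.
#' @export
write_network <- function(net, path,
                          format = if (grepl("\\.mtx$", path)) "mtx" else "tsv") {
  w <- net$w
  src <- rep.int(seq_len(ncol(w)), diff(w@p))  # column = source
  tgt <- w@i + 1L                              # row    = target
  if (format == "mtx") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("%%MatrixMarket matrix coordinate pattern general",
                 "% directed network adjacency: row = target (postsynaptic i), column = source (presynaptic j)",
                 sprintf("%d %d %d", nrow(w), ncol(w), length(tgt))), con)
    if (length(tgt))
      writeLines(sprintf("%d %d", tgt, src), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("source\ttarget", con)
    if (length(tgt))
      writeLines(sprintf("%d\t%d", src - 1L, tgt - 1L), con)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path,
                         format = if (grepl("\\.mtx$", path)) "mtx" else "tsv",
                         n_nodes = NULL) {
  if (format == "mtx") {
    m <- Matrix::readMM(path)
    return(directed_network(m))
  }
  lines <- readLines(path)
  if (!length(lines) || !identical(strsplit(lines[1], "\t")[[1]],
                                   c("source", "target")))
    stop("malformed edge list (line 1): expected header 'source\\ttarget'")
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad))
    stop(sprintf("malformed edge list line %d: '%s'", bad[1] + 1L, body[bad[1]]))
  src <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  tgt <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  if (anyNA(src) || anyNA(tgt)) {
    bad <- which(is.na(src) | is.na(tgt))[1]
    stop(sprintf("malformed edge list line %d: non-integer id", bad + 1L))
  }
  if (is.null(n_nodes))
    n_nodes <- if (length(src)) max(src, tgt) + 1L else 0L
  w <- Matrix::sparseMatrix(i = tgt + 1L, j = src + 1L, x = 1,
                            dims = c(n_nodes, n_nodes))
  directed_network(w)
}
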