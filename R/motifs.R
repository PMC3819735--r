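# Triad classification -------------------------------------------------
#
# A 3-node motif is encoded as the 9-bit integer
#   sum_ij a[i, j] * 2^(9 - (3 (i - 1) + j))
# (a11 most significant, row-major, a33 least), where a[i, j] = 1 means
# an edge i -> j.  The canonical id of an isomorphism class is the
# minimum encoding over the 6 simultaneous row/column permutations.
# Under this labeling the directed 3-cycle ("ring") is id 98 and the
# fully connected triad is id 238.

.triad_perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                     c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

.encode_triad <- function(m) {
  bits <- as.integer(t(m))           # row-major a11..a33
  sum(bits * 2^(9 - seq_len(9)))
}

#' Canonical id of a 3-node motif
#'
#' Encodes a 3x3 binary adjacency (entry \code{[i, j]} = 1 for an edge
#' i -> j, zero diagonal) as a 9-bit integer (row-major, a11 most
#' significant) and returns the minimum encoding over the six node
#' permutations, which is invariant under relabeling.  The directed
#' 3-cycle has id 98 and the complete triad id 238.
#'
#' @param m 3x3 binary matrix with zero diagonal.
#' @return Integer canonical id.
#' @export
triad_canonical_id <- function(m) {
  m <- as.matrix(m)
  stopifnot(identical(dim(m), c(3L, 3L)), all(m %in% c(0, 1)))
  if (any(diag(m) != 0)) stop("nonzero diagonal: self-loops not allowed")
  min(vapply(.triad_perms, function(p) .encode_triad(m[p, p]), numeric(1)))
}

# Build a 3x3 motif matrix from a 6-bit dyad code (bit 0: u->v,
# 1: v->u, 2: u->w, 3: w->u, 4: v->w, 5: w->v) with nodes (u, v, w)
# = (1, 2, 3)
.code_to_matrix <- function(code) {
  m <- matrix(0L, 3, 3)
  if (bitwAnd(code, 1L)) m[1, 2] <- 1L
  if (bitwAnd(code, 2L)) m[2, 1] <- 1L
  if (bitwAnd(code, 4L)) m[1, 3] <- 1L
  if (bitwAnd(code, 8L)) m[3, 1] <- 1L
  if (bitwAnd(code, 16L)) m[2, 3] <- 1L
  if (bitwAnd(code, 32L)) m[3, 2] <- 1L
  m
}

.triad_tables_env <- new.env(parent = emptyenv())

# Lookup tables shared by the census: canonical id, edge count and
# weak-connectivity flag per 6-bit code, plus the 13 connected classes
# with their edge counts and automorphism-group sizes.
.triad_tables <- function() {
  if (!is.null(.triad_tables_env$tab)) return(.triad_tables_env$tab)
  codes <- 0:63
  canon <- integer(64); edges <- integer(64); conn <- logical(64)
  aut_by_id <- list()
  for (cd in codes) {
    m <- .code_to_matrix(cd)
    canon[cd + 1] <- triad_canonical_id(m)
    edges[cd + 1] <- sum(m)
    und <- (m + t(m)) > 0
    # weakly connected iff every node touches an edge and the three
    # nodes form one component (for 3 nodes: connected iff at least 2
    # of the 3 dyads are linked, or ... just check reachability)
    reach <- und | diag(3) > 0
    reach <- (reach %*% reach) > 0
    conn[cd + 1] <- all(reach)
    aut_by_id[[as.character(canon[cd + 1])]] <-
      sum(vapply(.triad_perms, function(p) identical(m[p, p], m), logical(1)))
  }
  conn_ids <- sort(unique(canon[conn]))
  classes <- data.frame(
    motif_id = conn_ids,
    n_edges = vapply(conn_ids, function(id)
      edges[match(id, canon)], integer(1)),
    aut = vapply(as.character(conn_ids), function(id)
      aut_by_id[[id]], numeric(1)))
  classes$lambda <- 1 / classes$aut
  tab <- list(canon = canon, edges = edges, conn = conn,
              classes = classes)
  .triad_tables_env$tab <- tab
  tab
}

#' The 13 connected triad classes
#'
#' Canonical ids, edge counts, automorphism-group sizes and the
#' normalization symmetry factor \code{lambda = 1 / |Aut|} of the 13
#' weakly connected 3-node motif classes.
#'
#' @return data.frame with columns \code{motif_id}, \code{n_edges},
#'   \code{aut}, \code{lambda}.
#' @export
triad_classes <- function() .triad_tables()$classes

#' Census of connected 3-node motifs
#'
#' Counts the induced 3-node subgraphs of every weakly connected node
#' triple and classifies them into the 13 connected triad classes
#' (neighbour-based enumeration in compiled code, O(sum of squared
#' degrees)).  Counts of the three disconnected classes (empty triple,
#' single edge + isolate, mutual dyad + isolate) are attached so that
#' all 16 classes sum to choose(N, 3).
#'
#' @param net a \code{\link{directed_network}} with at least 3 nodes.
#' @return Object of class \code{motif_count_table}: data.frame with
#'   columns \code{motif_id}, \code{n_edges}, \code{count}; attributes
#'   \code{disconnected} (named counts) and \code{n_nodes}.
#' @export
count_triads <- function(net) {
  if (net$n_nodes < 3) stop("need at least 3 nodes")
  tab <- .triad_tables()
  res <- triad_census_cpp(net$w@p, net$w@i, net$n_nodes)
  counts <- stats::setNames(numeric(nrow(tab$classes)),
                            tab$classes$motif_id)
  nz <- which(res$conn > 0)
  for (k in nz) {
    id <- as.character(tab$canon[k])
    counts[id] <- counts[id] + res$conn[k]
  }
  n <- net$n_nodes
  total <- choose(n, 3)
  n_null <- total - sum(res$conn) - res$n_single - res$n_mutual
  out <- data.frame(motif_id = tab$classes$motif_id,
                    n_edges = tab$classes$n_edges,
                    count = as.numeric(counts))
  structure(out,
            class = c("motif_count_table", "data.frame"),
            disconnected = c(null = n_null, single = res$n_single,
                             mutual = res$n_mutual),
            n_nodes = n)
}

#' Normalize motif counts by their sparse-random expectation scale
#'
#' Divides each class count by \code{lambda * N^3 * (k / N)^e}, where
#' \code{e} is the class edge count, \code{k} the mean degree (edges
#' per node) and \code{lambda = 1 / |Aut|} the symmetry factor, so that
#' a sparse Erdos-Renyi network yields normalized counts near 1 and
#' counts become comparable across motifs and network sizes.
#'
#' @param table a \code{motif_count_table} from
#'   \code{\link{count_triads}}.
#' @param n_nodes network (or sub-network) size N; defaults to the
#'   table's attribute.
#' @param k mean degree; defaults to the realized edges-per-node of the
#'   counted network if recorded, otherwise required.
#' @return The table with an added \code{normalized} column.
#' @export
normalize_counts <- function(table, n_nodes = attr(table, "n_nodes"), k) {
  cls <- triad_classes()
  stopifnot(identical(table$motif_id, cls$motif_id))
  denom <- cls$lambda * n_nodes^3 * (k / n_nodes)^cls$n_edges
  table$normalized <- ifelse(table$count == 0, 0, table$count / denom)
  table
}

#' Uniformly sampled induced sub-network
#'
#' Induced subgraph on a uniformly random subset of \code{n_sub} nodes
#' (sampled without replacement), emulating the experimentally
#' accessible part of a larger circuit.
#'
#' @param net a \code{\link{directed_network}}.
#' @param n_sub sub-network size.
#' @return A \code{\link{directed_network}} of \code{n_sub} nodes.
#' @export
sample_subnetwork <- function(net, n_sub) {
  stopifnot(n_sub >= 1, n_sub <= net$n_nodes)
  idx <- sort(sample.int(net$n_nodes, n_sub))
  directed_network(net$w[idx, idx, drop = FALSE], kind = net$kind)
}

#' Normalized motif counts across an ensemble of network realizations
#'
#' Generates \code{n_real} network realizations of the given kind, for
#' each samples one induced sub-network per requested size, runs the
#' triad census and normalizes the counts (using the realized mean
#' degree of each counted sub-network).
#'
#' @param spec a \code{\link{degree_spec}} (the N = 200, mu = 10
#'   setting is the usual choice for motif work).
#' @param n_real number of realizations (default 1000).
#' @param n_sub vector of sub-network sizes; use \code{spec$n_nodes}
#'   for the full network.
#' @return Object of class \code{ensemble_counts}: long data.frame with
#'   columns \code{kind}, \code{realization}, \code{n_sub},
#'   \code{motif_id}, \code{count}, \code{normalized}.
#' @export
ensemble_counts <- function(spec, n_real = 1000, n_sub = spec$n_nodes) {
  rows <- vector("list", n_real)
  for (r in seq_len(n_real)) {
    net <- generate_network(spec)
    per_size <- lapply(n_sub, function(ns) {
      sub <- if (ns == spec$n_nodes) net else sample_subnetwork(net, ns)
      k <- sub$edge_count / ns
      tab <- normalize_counts(count_triads(sub), n_nodes = ns, k = k)
      data.frame(kind = spec$kind, realization = r, n_sub = ns,
                 motif_id = tab$motif_id, count = tab$count,
                 normalized = tab$normalized)
    })
    rows[[r]] <- do.call(rbind, per_size)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ensemble_counts", "data.frame")
  out
}

#' Pool motif counts across realizations
#'
#' Averages normalized counts over groups of \code{n_av} realizations
#' to shrink the width of the count distribution.  \code{mode "split"}
#' partitions the realizations into \code{floor(n/n_av)} disjoint
#' groups; \code{mode "resample"} draws as many groups as there were
#' realizations, each of \code{n_av} sampled with replacement.
#'
#' @param x numeric vector of per-realization counts, or an
#'   \code{ensemble_counts} data.frame (pooled within kind, n_sub and
#'   motif).
#' @param n_av pooling group size (1 = identity).
#' @param mode \code{"split"} or \code{"resample"}.
#' @return Same shape as the input with pooled values (vector in,
#'   vector out; data.frame in, data.frame out with a \code{group}
#'   column replacing \code{realization}).
#' @export
pool_counts <- function(x, n_av, mode = c("split", "resample")) {
  mode <- match.arg(mode)
  pool_vec <- function(v) {
    if (n_av == 1) return(v)
    n <- length(v)
    if (mode == "split") {
      ng <- n %/% n_av
      if (ng < 1) stop("n_av exceeds the number of realizations")
      idx <- sample.int(n)  # random group assignment
      vapply(seq_len(ng), function(g)
        mean(v[idx[((g - 1) * n_av + 1):(g * n_av)]]), numeric(1))
    } else {
      vapply(seq_len(n), function(g)
        mean(v[sample.int(n, n_av, replace = TRUE)]), numeric(1))
    }
  }
  if (is.numeric(x)) return(pool_vec(x))
  stopifnot(inherits(x, "data.frame"))
  keys <- interaction(x$kind, x$n_sub, x$motif_id, drop = TRUE)
  parts <- lapply(split(x, keys), function(d) {
    pooled <- pool_vec(d$normalized)
    data.frame(kind = d$kind[1], group = seq_along(pooled),
               n_sub = d$n_sub[1], motif_id = d$motif_id[1],
               normalized = pooled)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' AUC for discriminating two ensembles by one motif's counts
#'
#' Mann-Whitney AUC between the two ensembles' (optionally pooled)
#' normalized counts of a single motif, with error bars from repeated
#' resampling: \code{n_sets} sets of \code{set_size} realizations are
#' drawn with replacement from each ensemble and the AUC computed per
#' set.  The orientation is fixed so that AUC >= 0.5.
#'
#' @param counts_a,counts_b numeric vectors of per-realization counts
#'   for the two ensembles (same motif and sub-network size).
#' @param n_sets number of resampled sets (default 20).
#' @param set_size realizations per set (default 500).
#' @return List with \code{auc} (mean over sets), \code{auc_sd}, and
#'   \code{auc_sets}.
#' @export
motif_auc <- function(counts_a, counts_b, n_sets = 20, set_size = 500) {
  aucs <- vapply(seq_len(n_sets), function(s) {
    a <- sample(counts_a, set_size, replace = TRUE)
    b <- sample(counts_b, set_size, replace = TRUE)
    max(.auc_mw(a, b), .auc_mw(b, a))
  }, numeric(1))
  list(auc = mean(aucs), auc_sd = stats::sd(aucs), auc_sets = aucs)
}

#' AUC for discriminating two ensembles by a pair of motifs via FCM
#'
#' Treats each realization as a 2-D point (the normalized counts of the
#' two motifs), clusters the union of both ensembles with fuzzy c-means
#' (k = 2, fuzzifier 2) and runs the ROC analysis on the cluster-1
#' membership with the ensemble as label.  Orientation fixed so
#' AUC >= 0.5.  Pass \code{n_av} to pool counts before clustering.
#'
#' @param a,b \code{ensemble_counts} data.frames (or two-column
#'   matrices of the pair's counts, one row per realization).
#' @param motif_pair integer vector of two canonical ids (may be equal,
#'   which degenerates to the single-motif analysis).
#' @param n_sub sub-network size to select from the data.frames.
#' @param n_av optional pooling group size (split mode).
#' @return Scalar AUC.
#' @export
pair_fcm_auc <- function(a, b, motif_pair, n_sub = NULL, n_av = 1) {
  get_mat <- function(d) {
    if (is.matrix(d)) return(d)
    if (!is.null(n_sub)) d <- d[d$n_sub == n_sub, ]
    v1 <- d$normalized[d$motif_id == motif_pair[1]]
    v2 <- d$normalized[d$motif_id == motif_pair[2]]
    m <- cbind(v1, v2)
    if (n_av > 1) {
      # pool jointly: the same realization group feeds both coordinates
      ng <- nrow(m) %/% n_av
      if (ng < 1) stop("n_av exceeds the number of realizations")
      idx <- sample.int(nrow(m))
      m <- t(vapply(seq_len(ng), function(g)
        colMeans(m[idx[((g - 1) * n_av + 1):(g * n_av)], , drop = FALSE]),
        numeric(2)))
    }
    m
  }
  ma <- get_mat(a); mb <- get_mat(b)
  pts <- rbind(ma, mb)
  cl <- fcm(pts, k = 2, fuzzifier = 2)
  u1 <- cl$membership[, 1]
  pos <- u1[seq_len(nrow(ma))]
  neg <- u1[-seq_len(nrow(ma))]
  max(.auc_mw(pos, neg), .auc_mw(neg, pos))
}
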