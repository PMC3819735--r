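# Independent oracles used by the tests.  These deliberately avoid the
# package's own code paths.

# Exhaustive O(N^3) triad census: classify the induced subgraph of every
# node triple by its canonical id (recomputed here from scratch, via the
# same published encoding but an independent implementation route).
oracle_triad_census <- function(net) {
  a <- as.matrix(net$w)          # a[i, j] = 1 iff edge j -> i
  m_src <- t(a)                  # m[i, j] = 1 iff edge i -> j
  n <- nrow(m_src)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  enc <- function(m) sum(as.integer(t(m)) * 2^(8:0))
  counts <- new.env(parent = emptyenv())
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    m <- m_src[c(i, j, k), c(i, j, k)]
    und <- (m + t(m)) > 0
    # weak connectivity of 3 nodes: at least 2 linked dyads
    if (sum(und[upper.tri(und)] > 0) < 2) next
    id <- as.character(min(vapply(perms, function(p) enc(m[p, p]),
                                  numeric(1))))
    counts[[id]] <- (if (is.null(counts[[id]])) 0 else counts[[id]]) + 1
  }
  out <- unlist(as.list(counts))
  out[order(as.integer(names(out)))]
}

# Mann-Whitney AUC via wilcox.test's U statistic (ties handled by
# midranks internally, matching the tie-half convention)
oracle_auc <- function(pos, neg) {
  w <- suppressWarnings(stats::wilcox.test(pos, neg))
  unname(w$statistic) / (length(pos) * length(neg))
}

# Closed-form expected induced triad-class counts in a directed ER
# graph: choose(N,3) * (6/|Aut|) * p^e * (1-p)^(6-e)
oracle_er_expectation <- function(n, p) {
  cls <- triad_classes()
  data.frame(motif_id = cls$motif_id,
             expected = choose(n, 3) * (6 / cls$aut) *
               p^cls$n_edges * (1 - p)^(6 - cls$n_edges))
}

# Homogeneous directed circulant network: every node receives edges
# from its k predecessors, so every in- and out-degree equals k and the
# deterministic dynamics collapse onto the scalar mean-field map.
homogeneous_network <- function(n, k) {
  src <- rep(seq_len(n), each = k)
  tgt <- ((src - 1 + rep(seq_len(k), n)) %% n) + 1
  w <- Matrix::sparseMatrix(i = tgt, j = src, x = 1, dims = c(n, n))
  directed_network(w)
}

# Small standard spec used across tests (kept small for speed)
small_spec <- function(kind, n = 200) degree_spec(n, 0.05, kind = kind)
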