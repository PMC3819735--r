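test_that("canonical triad ids match the published labeling", {
  cyc <- matrix(0, 3, 3)
  cyc[1, 2] <- cyc[2, 3] <- cyc[3, 1] <- 1   # ring 1->2->3->1
  expect_identical(triad_canonical_id(cyc), 98)
  full <- matrix(1, 3, 3) - diag(3)
  expect_identical(triad_canonical_id(full), 238)
  expect_error(triad_canonical_id(diag(3)), "diagonal")
  # permutation invariance on random motifs
  set.seed(51)
  perms <- list(c(1, 2, 3), c(2, 1, 3), c(3, 1, 2), c(3, 2, 1))
  for (i in 1:25) {
    m <- matrix(rbinom(9, 1, 0.5), 3, 3); diag(m) <- 0
    ids <- vapply(perms, function(p) triad_canonical_id(m[p, p]),
                  numeric(1))
    expect_length(unique(ids), 1L)
  }
})

test_that("the 13 connected classes are distinct and include the named ids", {
  cls <- triad_classes()
  expect_identical(nrow(cls), 13L)
  expect_false(anyDuplicated(cls$motif_id) > 0)
  expect_true(all(c(98, 110, 238) %in% cls$motif_id))
  expect_identical(sort(unique(cls$n_edges)), 2:6)
  expect_equal(cls$lambda[cls$motif_id == 98], 1 / 3)
  expect_equal(cls$lambda[cls$motif_id == 238], 1 / 6)
})

test_that("fast triad census equals exhaustive enumeration on small graphs", {
  set.seed(52)
  graphs <- c(
    lapply(1:4, function(i) erdos_renyi(25, 0.1)),
    lapply(1:3, function(i) erdos_renyi(40, 0.05)),
    lapply(c("anti", "positive", "uncorrelated"), function(k)
      generate_network(degree_spec(30, 0.2, kind = k)))
  )
  for (net in graphs) {
    tab <- count_triads(net)
    oracle <- oracle_triad_census(net)
    got <- setNames(tab$count, tab$motif_id)
    expect_equal(got[got > 0], oracle[names(got[got > 0])])
    expect_true(all(got[setdiff(names(got), names(oracle))] == 0))
    # census completeness over all 16 classes
    expect_equal(sum(tab$count) + sum(attr(tab, "disconnected")),
                 choose(net$n_nodes, 3))
  }
  # a single directed 3-cycle
  cyc <- matrix(0, 3, 3); cyc[2, 1] <- cyc[3, 2] <- cyc[1, 3] <- 1
  tab <- count_triads(directed_network(cyc))
  expect_identical(tab$count[tab$motif_id == 98], 1)
  expect_identical(sum(tab$count), 1)
  # empty graph
  tab0 <- count_triads(erdos_renyi(10, 0))
  expect_true(all(tab0$count == 0))
})

test_that("triad census agrees with igraph's on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(53)
  # map each connected class to igraph's census slot via its
  # representative 3-node graph
  cls <- triad_classes()
  slot_of <- vapply(cls$motif_id, function(id) {
    bits <- as.integer(intToBits(id))[9:1]
    m <- matrix(bits, 3, 3, byrow = TRUE)
    g <- igraph::graph_from_adjacency_matrix(m, mode = "directed")
    which(igraph::triad_census(g) == 1)
  }, integer(1))
  for (i in 1:5) {
    net <- erdos_renyi(60, 0.08)
    g <- igraph::graph_from_adjacency_matrix(t(as.matrix(net$w)),
                                             mode = "directed")
    ig <- igraph::triad_census(g)
    tab <- count_triads(net)
    expect_equal(unname(ig[slot_of]), tab$count)
  }
})

test_that("ER triad-class means match the closed-form expectation", {
  set.seed(54)
  n <- 60; p <- 0.1; n_rep <- 200
  acc <- matrix(0, n_rep, 13)
  for (r in seq_len(n_rep)) {
    acc[r, ] <- count_triads(erdos_renyi(n, p))$count
  }
  exp_tab <- oracle_er_expectation(n, p)
  for (j in 1:13) {
    se <- sd(acc[, j]) / sqrt(n_rep)
    expect_lt(abs(mean(acc[, j]) - exp_tab$expected[j]),
              max(3 * se, 1e-8) + 1e-8)
  }
})

test_that("normalization brings sparse-ER counts to order one, independent of N", {
  set.seed(55)
  means <- vapply(c(100, 200), function(n) {
    vals <- replicate(30, {
      net <- erdos_renyi(n, 0.05)
      tab <- normalize_counts(count_triads(net), n,
                              k = net$edge_count / n)
      tab$normalized[tab$motif_id == 98]
    })
    mean(vals)
  }, numeric(1))
  expect_true(all(abs(means - 1) < 0.25))
  expect_lt(abs(means[1] - means[2]), 0.15)
  # zero raw count stays zero
  tab0 <- normalize_counts(count_triads(erdos_renyi(10, 0)), 10, k = 0)
  expect_true(all(tab0$normalized == 0))
})

test_that("sub-network sampling is uniform induced subgraph extraction", {
  set.seed(56)
  net <- generate_network(small_spec("anti"))
  sub_full <- sample_subnetwork(net, net$n_nodes)
  expect_equal(as.matrix(sub_full$w), as.matrix(net$w))
  n_sub <- 40
  edge_counts <- replicate(60, sample_subnetwork(net, n_sub)$edge_count)
  expected <- net$edge_count * n_sub * (n_sub - 1) /
    (net$n_nodes * (net$n_nodes - 1))
  se <- sd(edge_counts) / sqrt(60)
  expect_lt(abs(mean(edge_counts) - expected), 4 * se)
})

test_that("pooling shrinks the count spread by sqrt(n_av)", {
  set.seed(57)
  v <- rgamma(1000, shape = 4)
  expect_identical(pool_counts(v, 1), v)
  pooled <- pool_counts(v, 25)
  expect_length(pooled, 40)
  expect_lt(abs(sd(pooled) / (sd(v) / 5) - 1), 0.5)
  res <- pool_counts(v, 25, mode = "resample")
  expect_length(res, 1000)
  expect_lt(abs(sd(res) / (sd(v) / 5) - 1), 0.5)
})

test_that("motif AUC is 0.5 for identical ensembles and separates shifted ones", {
  set.seed(58)
  a <- rnorm(600, 1, 0.2)
  au_same <- motif_auc(a, a, n_sets = 10, set_size = 200)
  expect_lt(abs(au_same$auc - 0.5), 3 * au_same$auc_sd + 0.02)
  b <- rnorm(600, 1.6, 0.2)
  au_diff <- motif_auc(a, b, n_sets = 10, set_size = 200)
  expect_gt(au_diff$auc, 0.95)
  # orientation is fixed: order of arguments cannot push AUC below 0.5
  expect_gte(motif_auc(b, a, n_sets = 5, set_size = 100)$auc, 0.5)
})

test_that("paired-motif FCM with a duplicated motif reduces to the single-motif AUC", {
  set.seed(59)
  a <- cbind(rnorm(300, 0), rnorm(300, 0))
  b <- cbind(rnorm(300, 1.5), rnorm(300, 1.5))
  auc_pair <- pair_fcm_auc(a, b, motif_pair = c(98, 98))
  direct <- motif_auc(a[, 1], b[, 1], n_sets = 5, set_size = 300)$auc
  expect_lt(abs(auc_pair - direct), 0.1)
  expect_gte(auc_pair, 0.5)
})

test_that("degree correlations order the ring-motif abundance", {
  set.seed(60)
  kinds <- c("anti", "uncorrelated", "positive")
  means <- vapply(kinds, function(k) {
    spec <- degree_spec(200, 0.05, kind = k)
    e <- ensemble_counts(spec, n_real = 60, n_sub = 200)
    mean(e$normalized[e$motif_id == 98])
  }, numeric(1))
  expect_lt(means["anti"], means["uncorrelated"])
  expect_lt(means["uncorrelated"], means["positive"])
})
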