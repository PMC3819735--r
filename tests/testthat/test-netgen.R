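test_that("rotated bivariate sampling produces the prescribed degree correlations", {
  set.seed(11)
  spec <- degree_spec(2000, 0.05, kind = "anti")
  pairs <- sample_degree_pairs(spec)
  expect_length(pairs$d_in, 2000)
  expect_true(all(pairs$d_in >= 1 & pairs$d_in <= 200))
  expect_true(all(pairs$d_out >= 1 & pairs$d_out <= 200))
  rho_anti <- cor(pairs$d_in, pairs$d_out)
  expect_lt(rho_anti, -0.75)
  expect_gt(rho_anti, -0.90)

  pos <- sample_degree_pairs(degree_spec(2000, 0.05, kind = "positive"))
  expect_gt(cor(pos$d_in, pos$d_out), 0.75)

  unc <- sample_degree_pairs(degree_spec(2000, 0.05, kind = "uncorrelated"))
  expect_lt(abs(cor(unc$d_in, unc$d_out)), 0.06)
})

test_that("vanishing dispersion degenerates to exact anti-correlation", {
  set.seed(12)
  spec <- degree_spec(2000, 0.05, dispersion = 1e-9, kind = "anti")
  pairs <- sample_degree_pairs(spec)
  # long axis exactly on the anti-diagonal: d_in + d_out = 2 mu
  expect_true(all(pairs$d_in + pairs$d_out == 200L))
  expect_equal(cor(pairs$d_in, pairs$d_out), -1)
})

test_that("marginal degree distributions agree across correlation kinds", {
  set.seed(13)
  pooled <- lapply(c("anti", "positive", "uncorrelated"), function(k) {
    spec <- degree_spec(2000, 0.05, kind = k)
    do.call(rbind, lapply(1:5, function(i) {
      p <- sample_degree_pairs(spec)
      data.frame(d_in = p$d_in, d_out = p$d_out)
    }))
  })
  for (i in 1:2) for (j in (i + 1):3) {
    ks <- suppressWarnings(
      ks.test(pooled[[i]]$d_in, pooled[[j]]$d_in))
    expect_gt(ks$p.value, 0.01)
    ks2 <- suppressWarnings(
      ks.test(pooled[[i]]$d_out, pooled[[j]]$d_out))
    expect_gt(ks2$p.value, 0.01)
  }
})

test_that("balance_totals equalizes stub totals with minimal disturbance", {
  set.seed(14)
  spec <- degree_spec(500, 0.05, kind = "anti")
  pairs <- sample_degree_pairs(spec)
  bal <- balance_totals(pairs)
  expect_identical(sum(bal$d_in), sum(bal$d_out))
  expect_true(all(bal$d_in >= 1 & bal$d_in <= 50))
  # already-balanced input is returned unchanged
  bal2 <- balance_totals(bal)
  expect_identical(bal2$d_in, bal$d_in)
  expect_identical(bal2$d_out, bal$d_out)
  # a known imbalance of +3 is removed by exactly 3 unit adjustments
  p3 <- pairs
  p3$d_in <- bal$d_in; p3$d_out <- bal$d_out
  p3$d_in[1:3] <- p3$d_in[1:3] + 1L
  b3 <- balance_totals(p3)
  expect_identical(sum(b3$d_in), sum(b3$d_out))
  moved <- sum(abs(b3$d_in - p3$d_in)) + sum(abs(b3$d_out - p3$d_out))
  expect_identical(as.integer(moved), 3L)
  # every repair spends exactly one unit adjustment per unit of initial
  # imbalance, so the marginal means move by at most |Delta| / N
  set.seed(15)
  rel_shift <- replicate(50, {
    p <- sample_degree_pairs(spec)
    delta <- abs(sum(p$d_in) - sum(p$d_out))
    b <- balance_totals(p)
    total_moved <- sum(abs(c(b$d_in - p$d_in, b$d_out - p$d_out)))
    expect_identical(as.integer(total_moved), as.integer(delta))
    shift <- abs(mean(b$d_in) - mean(p$d_in)) +
      abs(mean(b$d_out) - mean(p$d_out))
    expect_lte(shift, delta / length(p$d_in) + 1e-12)
    shift / p$spec$mu
  })
  expect_lt(mean(rel_shift), 0.05)
})

test_that("configuration model realizes prescribed degrees minus removed artifacts", {
  set.seed(16)
  # unique tiny matching
  spec <- degree_spec(2, 0.9, dispersion = 1, kind = "anti")
  pairs <- structure(list(d_in = c(0L, 1L), d_out = c(1L, 0L), spec = spec),
                     class = "degree_pairs")
  net <- configuration_model(pairs)
  expect_equal(as.matrix(net$w), matrix(c(0, 0, 1, 0), 2, 2,
                                        byrow = TRUE))
  expect_error(configuration_model(
    structure(list(d_in = c(1L, 1L), d_out = c(1L, 0L), spec = spec),
              class = "degree_pairs")), "unbalanced")

  # realized degrees match prescribed up to the removed-edge fraction
  spec <- degree_spec(2000, 0.05, kind = "uncorrelated")
  net <- generate_network(spec)
  din <- in_degree(net)
  expect_lt(mean(abs(din - net$meta$prescribed_in)) / mean(din), 0.03)
  expect_identical(net$edge_count + net$meta$n_removed,
                   net$meta$n_pairings)
})

test_that("stub-matching artifact rates match sparse-network expectations", {
  set.seed(17)
  spec <- degree_spec(2000, 0.05, kind = "uncorrelated")
  rates <- t(replicate(5, {
    net <- generate_network(spec)
    c(self = net$meta$self_fraction, multi = net$meta$multi_fraction)
  }))
  # ~1/N self-pairings and ~2.7% duplicates at mean degree 100
  expect_gt(mean(rates[, "self"]), 0.0003)
  expect_lt(mean(rates[, "self"]), 0.0008)
  expect_gt(mean(rates[, "multi"]), 0.022)
  expect_lt(mean(rates[, "multi"]), 0.032)
})

test_that("stub matching is a uniform random matching (tiny enumeration check)", {
  set.seed(18)
  spec <- degree_spec(3, 0.5, dispersion = 1, kind = "anti")
  pairs <- structure(list(d_in = c(0L, 1L, 1L), d_out = c(1L, 1L, 0L),
                          spec = spec),
                     class = "degree_pairs")
  # out stubs (1,2) match the permuted in stubs (2,3): two equally
  # likely matchings; one contains the self-pairing 2->2 and leaves a
  # single edge 1->3 after removal
  n_rep <- 400
  with_self <- 0
  for (i in seq_len(n_rep)) {
    net <- configuration_model(pairs)
    if (net$edge_count == 1) with_self <- with_self + 1
  }
  p_hat <- with_self / n_rep
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / n_rep))
})

test_that("Erdos-Renyi sampling has binomial degree statistics", {
  set.seed(19)
  expect_identical(erdos_renyi(10, 0)$edge_count, 0L)
  full <- erdos_renyi(10, 1)
  expect_true(all(in_degree(full) == 9))
  net <- erdos_renyi(2000, 0.05)
  din <- in_degree(net)
  ratio <- sd(din) / mean(din)
  # sd/mean of Binomial(N-1, p): sqrt((1-p)/((N-1) p))
  expect_lt(abs(ratio - sqrt(0.95 / (1999 * 0.05))), 0.01)
  expect_lt(abs(degree_correlation(net)), 0.06)
})

test_that("degree_correlation is signed and relabeling-invariant", {
  set.seed(20)
  net <- generate_network(degree_spec(300, 0.05, kind = "anti"))
  rho <- degree_correlation(net)
  expect_lt(rho, 0)
  perm <- sample.int(net$n_nodes)
  net_p <- directed_network(net$w[perm, perm])
  expect_equal(degree_correlation(net_p), rho)
  # reciprocal pair: every node has d_in == d_out
  w <- matrix(0, 4, 4); w[1, 2] <- w[2, 1] <- w[3, 4] <- w[4, 3] <- 1
  w[1, 3] <- w[3, 1] <- 1
  expect_equal(degree_correlation(directed_network(w)), 1)
  # zero marginal variance is signalled
  ring <- homogeneous_network(5, 1)
  expect_error(degree_correlation(ring), "zero variance")
})
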