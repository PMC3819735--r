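test_that("threshold-sweep AUC equals the Mann-Whitney oracle, with ties", {
  set.seed(31)
  for (rep in 1:20) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    pos <- sample(0:10, n1, replace = TRUE) + rnorm(n1, sd = 0.01)
    neg <- sample(0:10, n2, replace = TRUE) + rnorm(n2, sd = 0.01)
    r <- roc_auc(pos, neg, n_boot = 0)
    expect_equal(r$auc, oracle_auc(pos, neg), tolerance = 1e-12)
  }
  # heavy ties
  expect_equal(roc_auc(c(1, 1, 1), c(1, 1, 1), n_boot = 0)$auc, 0.5)
  expect_equal(roc_auc(c(4, 5, 6), c(1, 2, 3), n_boot = 0)$auc, 1.0)
  expect_error(roc_auc(numeric(0), 1:3), "empty")
})

test_that("ROC curve is monotone from (0,0) to (1,1)", {
  set.seed(32)
  r <- roc_auc(rnorm(50, 1), rnorm(60), n_boot = 0)
  expect_equal(r$curve$fpr[1], 0); expect_equal(r$curve$tpr[1], 0)
  expect_equal(tail(r$curve$fpr, 1), 1)
  expect_equal(tail(r$curve$tpr, 1), 1)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
})

test_that("bootstrap AUC error shrinks roughly as 1/sqrt(n)", {
  set.seed(33)
  sds <- vapply(c(40, 160, 640), function(n) {
    roc_auc(rnorm(n, 0.8), rnorm(n), n_boot = 400)$auc_boot_sd
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
  expect_lt(sds[3] / sds[1], 0.45)  # ~1/4 expected, allow slack
})

test_that("uncoupled networks make stimulated and spontaneous conditions identical", {
  set.seed(34)
  spec <- small_spec("uncorrelated")
  ds <- run_detection_ensemble(spec, J = 0, n_realizations = 4,
                               trials_per = 25)
  # pre-stimulus and during-stimulus bins both carry no information
  tc <- auc_timecourse(ds, n_boot = 0)
  expect_true(all(abs(tc$auc - 0.5) < 0.12))
  expect_error(run_detection_ensemble(spec, J = 0, n_p = 300),
               "exceeds")
})

test_that("stimulation raises downstream rates and the during-stimulus AUC", {
  set.seed(35)
  spec <- degree_spec(1000, 0.05, kind = "uncorrelated")
  ds <- run_detection_ensemble(spec, J = 18, n_p = 8,
                               n_realizations = 8, trials_per = 25)
  win <- (ds$start + 1):(ds$start + ds$duration) + 1L
  expect_gt(mean(ds$rate_stim[, win]), mean(ds$rate_spont[, win]))
  tc <- auc_timecourse(ds, n_boot = 0)
  pre <- tc$auc[tc$bin > 0 & tc$bin < ds$start]
  during <- tc$auc[tc$in_window & tc$bin > ds$start]
  expect_gt(mean(during), mean(pre) + 0.05)
})

test_that("out-degree of the stimulated group drives detectability", {
  set.seed(36)
  spec <- degree_spec(1000, 0.05, kind = "uncorrelated")
  a1 <- outdegree_group_auc(spec, group = 1, J = 18,
                            n_realizations = 8, trials_per = 25)
  a10 <- outdegree_group_auc(spec, group = 10, J = 18,
                             n_realizations = 8, trials_per = 25)
  expect_gt(a1$auc, a10$auc)
})

test_that("return-map density integrates to one and peaks at the data", {
  set.seed(37)
  r <- c(0.01, 0.012, 0.011, 0.013, 0.009, 0.012, 0.014, 0.01,
         0.011, 0.013)
  d <- return_map_density(r, n_grid = 80)
  cell <- diff(d$x[1:2]) * diff(d$y[1:2])
  expect_equal(sum(d$z) * cell, 1, tolerance = 1e-6)
  # constant series collapses onto the diagonal point
  dc <- return_map_density(rep(0.5, 20), n_grid = 40)
  expect_equal(unname(dc$peak), c(0.5, 0.5), tolerance = 1e-3)
})

test_that("fuzzy c-means produces normalized memberships and decreasing objective", {
  set.seed(38)
  pts <- rbind(matrix(rnorm(100, 0, 0.5), ncol = 2),
               matrix(rnorm(100, 20, 0.5), ncol = 2))
  cl <- fcm(pts, k = 2)
  expect_equal(rowSums(cl$membership), rep(1, 100), tolerance = 1e-12)
  expect_true(all(apply(cl$membership, 1, max) > 0.99))
  expect_true(all(diff(cl$objective) <= 1e-8))
  expect_error(fcm(pts[1:1, , drop = FALSE], k = 2), "clusters")
  expect_error(fcm(matrix(1, 10, 2), k = 2), "degenerate")
})

test_that("fcm-based detection AUC behaves symmetrically", {
  set.seed(39)
  a <- matrix(rnorm(120, 0, 1), ncol = 2)
  b <- matrix(rnorm(120, 0, 1), ncol = 2)
  r_same <- fcm_detection_auc(a, b, n_boot = 0)
  expect_lt(abs(r_same$auc - 0.5), 0.12)
  shifted <- sweep(b, 2, c(3, 3), "+")
  r_shift <- fcm_detection_auc(a, shifted, n_boot = 0)
  expect_gt(r_shift$auc, 0.95)
})

test_that("perceptron training converges on separable data and flags failure", {
  set.seed(40)
  x <- rbind(matrix(rnorm(40, 3), ncol = 2), matrix(rnorm(40, -3), ncol = 2))
  y <- rep(c(1, -1), each = 20)
  fit <- perceptron_train(x, y, epochs = 100)
  expect_true(fit$converged)
  expect_identical(tail(fit$errors, 1), 0L)
  pred <- sign(x %*% fit$weights)
  expect_equal(as.numeric(pred), y)
  # label flip mirrors the separator (same RNG stream -> same shuffles)
  set.seed(41); f1 <- perceptron_train(x, y, epochs = 100)
  set.seed(41); f2 <- perceptron_train(x, -y, epochs = 100)
  expect_equal(f2$weights, -f1$weights)
  # identical inputs with mixed labels cannot converge
  bad <- matrix(1, 10, 3)
  fit_bad <- perceptron_train(bad, rep(c(1, -1), 5), epochs = 25)
  expect_false(fit_bad$converged)
  expect_identical(fit_bad$epochs_run, 25L)
  expect_error(perceptron_train(x, rep(1, 40)), "two classes")
})

test_that("weight-feature correlations expose direct stimulated inputs", {
  set.seed(42)
  net <- generate_network(degree_spec(400, 0.05, kind = "uncorrelated"))
  stim <- sample.int(400, 8)
  keep <- setdiff(1:400, stim)
  # construct weights equal to the direct-input count plus noise: the
  # direct correlation must dominate
  ind <- numeric(400); ind[stim] <- 1
  direct <- as.numeric(net$w %*% ind)[keep]
  w <- direct + rnorm(length(keep), sd = 0.1)
  co <- weight_feature_correlations(w, net, stim)
  expect_gt(co["direct_inputs"], 0.9)
  expect_true(all(abs(co[c("in_degree", "out_degree")]) <
                    co["direct_inputs"]))
  # empty stimulated set leaves features 3 and 4 undefined
  w0 <- rnorm(400)
  ws <- capture_warnings(
    co0 <- weight_feature_correlations(w0, net, integer(0)))
  expect_true(any(grepl("zero variance", ws)))
  expect_true(is.na(co0["direct_inputs"]))
})
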