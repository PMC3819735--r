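#' ROC curve and AUC by threshold sweep
#'
#' Sweeps every observed value as a threshold, tracing the true-positive
#' fraction against the false-positive fraction.  The area under the
#' curve equals the Mann-Whitney statistic
#' \code{P(pos > neg) + 0.5 P(pos == neg)}; ties count one half.
#' Bootstrap resampling of both samples supplies an error estimate.
#'
#' @param pos samples from the positive (e.g. stimulated) condition.
#' @param neg samples from the negative (spontaneous) condition.
#' @param n_boot bootstrap resamples for the AUC error (default 2000;
#'   0 disables).
#' @return Object of class \code{roc_result}: data.frame \code{curve}
#'   (fpr, tpr; monotone from (0,0) to (1,1)), \code{auc},
#'   \code{auc_boot_mean}, \code{auc_boot_sd}.
#' @export
roc_auc <- function(pos, neg, n_boot = 2000) {
  if (!length(pos) || !length(neg)) stop("empty sample")
  thr <- sort(unique(c(pos, neg)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  curve <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  auc <- .auc_mw(pos, neg)
  boot_mean <- boot_sd <- NA_real_
  if (n_boot > 0) {
    b <- vapply(seq_len(n_boot), function(i) {
      .auc_mw(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    }, numeric(1))
    boot_mean <- mean(b); boot_sd <- stats::sd(b)
  }
  structure(list(curve = curve, auc = auc,
                 auc_boot_mean = boot_mean, auc_boot_sd = boot_sd),
            class = "roc_result")
}

# Mann-Whitney AUC with the tie-half convention, via midranks
.auc_mw <- function(pos, neg) {
  n1 <- length(pos); n2 <- length(neg)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f", x$auc))
  if (!is.na(x$auc_boot_sd))
    cat(sprintf(" (bootstrap %.4f +- %.4f)", x$auc_boot_mean, x$auc_boot_sd))
  cat("\n")
  invisible(x)
}

#' Paired stimulated / spontaneous detection dataset
#'
#' For each network realization, runs paired stochastic simulations with
#' and without the stimulation protocol and records the per-bin
#' population rate computed over the non-stimulated neurons only (the
#' read-out available to a downstream decision process; it is also
#' invariant to the clamped values themselves).
#'
#' @param spec a \code{\link{degree_spec}}, or a fixed
#'   \code{\link{directed_network}}.
#' @param J coupling strength.
#' @param r0 baseline rate in Hz.
#' @param n_p number of stimulated neurons (default 8).
#' @param start,duration stimulation window (defaults: bins 10..15).
#' @param n_realizations network realizations (default 50).
#' @param trials_per paired trials per realization (default 1).
#' @param steps bins per trial (default start + duration + 4).
#' @param stim_group optional out-degree decile (1 = highest) from
#'   which stimulated cells are drawn; \code{NULL} = uniform.
#' @param delta_t bin width in seconds.
#' @return Object of class \code{detection_dataset}: matrices
#'   \code{rate_stim}, \code{rate_spont} (trials x bins, population
#'   activity of non-stimulated cells), window metadata.
#' @export
run_detection_ensemble <- function(spec, J, r0 = 1, n_p = 8,
                                   start = 10, duration = 6,
                                   n_realizations = 50, trials_per = 1,
                                   steps = start + duration + 4,
                                   stim_group = NULL, delta_t = 0.01) {
  fresh <- inherits(spec, "degree_spec")
  norm <- if (fresh) spec$n_nodes * spec$p_c else mean(in_degree(spec))
  n <- if (fresh) spec$n_nodes else spec$n_nodes
  if (n_p > n) stop("n_p exceeds the network size")
  params <- dynamics_params(J = J, norm = norm, r0 = r0, delta_t = delta_t)
  n_trials <- n_realizations * trials_per
  rate_stim <- matrix(NA_real_, n_trials, steps + 1)
  rate_spont <- matrix(NA_real_, n_trials, steps + 1)
  row <- 0L
  for (r in seq_len(n_realizations)) {
    net <- if (fresh) generate_network(spec) else spec
    stim_nodes <- .pick_stim(net, n_p, stim_group)
    keep <- setdiff(seq_len(n), stim_nodes)
    prot <- stim_protocol(stim_nodes, start = start, duration = duration)
    for (k in seq_len(trials_per)) {
      row <- row + 1L
      x0 <- initial_state_lfs(net, params)
      s1 <- simulate_network(net, params, steps, initial = x0,
                             protocol = prot, record_raster = TRUE)
      x0 <- initial_state_lfs(net, params)
      s0 <- simulate_network(net, params, steps, initial = x0,
                             record_raster = TRUE)
      rate_stim[row, ] <- rowMeans(s1$raster[, keep, drop = FALSE])
      rate_spont[row, ] <- rowMeans(s0$raster[, keep, drop = FALSE])
    }
  }
  structure(list(rate_stim = rate_stim, rate_spont = rate_spont,
                 start = start, duration = duration, n_p = n_p,
                 delta_t = delta_t),
            class = "detection_dataset")
}

# stimulated cells: uniform, or uniform within an out-degree decile
# (group 1 = highest out-degree)
.pick_stim <- function(net, n_p, stim_group = NULL) {
  if (is.null(stim_group))
    return(sample.int(net$n_nodes, n_p))
  stopifnot(stim_group >= 1, stim_group <= 10)
  ord <- order(out_degree(net), decreasing = TRUE)
  gsize <- floor(net$n_nodes / 10)
  members <- ord[((stim_group - 1) * gsize + 1):(stim_group * gsize)]
  sample(members, n_p)
}

#' Per-bin AUC time course
#'
#' Mann-Whitney AUC between the stimulated and spontaneous rate
#' distributions for every time bin of a detection dataset.  Bins before
#' the stimulus give AUC near 0.5; during the stimulus the AUC rises.
#'
#' @param dataset a \code{detection_dataset}.
#' @param n_boot bootstrap resamples per bin (default 200; 0 disables).
#' @return data.frame with columns \code{bin} (0-based, 0 = initial
#'   state), \code{auc}, \code{auc_sd}, \code{in_window}.
#' @export
auc_timecourse <- function(dataset, n_boot = 200) {
  nb <- ncol(dataset$rate_stim)
  res <- lapply(seq_len(nb), function(b) {
    r <- roc_auc(dataset$rate_stim[, b], dataset$rate_spont[, b],
                 n_boot = n_boot)
    c(auc = r$auc, auc_sd = r$auc_boot_sd)
  })
  res <- do.call(rbind, res)
  bin <- seq_len(nb) - 1L
  data.frame(bin = bin, auc = res[, "auc"], auc_sd = res[, "auc_sd"],
             in_window = bin >= dataset$start &
               bin < dataset$start + dataset$duration)
}

#' During-stimulus AUC for an out-degree group
#'
#' Stimulated cells are drawn from one of ten equal-size groups ordered
#' by out-degree (group 1 = highest).  Returns the single-bin AUC in the
#' middle of the stimulation window; sensitivity tracks the mean
#' out-degree of the stimulated cells.
#'
#' @inheritParams run_detection_ensemble
#' @param group decile index 1..10.
#' @param bin 0-based bin used for detection (default: last stimulated
#'   bin).
#' @return List with \code{auc}, \code{auc_sd} and the \code{group}.
#' @export
outdegree_group_auc <- function(spec, group, J, r0 = 1, n_p = 8,
                                start = 10, duration = 6,
                                n_realizations = 50, trials_per = 1,
                                bin = start + duration - 1,
                                delta_t = 0.01) {
  ds <- run_detection_ensemble(spec, J, r0 = r0, n_p = n_p, start = start,
                               duration = duration,
                               n_realizations = n_realizations,
                               trials_per = trials_per,
                               stim_group = group, delta_t = delta_t)
  r <- roc_auc(ds$rate_stim[, bin + 1L], ds$rate_spont[, bin + 1L],
               n_boot = 500)
  list(auc = r$auc, auc_sd = r$auc_boot_sd, group = group)
}

#' Return-map density of consecutive population rates
#'
#' Gaussian kernel density estimate of the pairs (r_t, r_{t+1}) of
#' consecutive population rates.  The per-axis bandwidth follows
#' Silverman's rule of thumb for two dimensions,
#' \code{h = sd(x) * n^(-1/6)}.  The grid covers the data plus a margin
#' of several bandwidths so that the discrete integral of the density
#' is 1.
#'
#' @param rate numeric vector of per-bin population rates (or a
#'   \code{raster}).
#' @param n_grid grid points per axis (default 64).
#' @param margin grid margin in bandwidths (default 6).
#' @return List with grid vectors \code{x}, \code{y}, density matrix
#'   \code{z}, bandwidths \code{h}, and the \code{peak} (x, y) of the
#'   density.
#' @export
return_map_density <- function(rate, n_grid = 64, margin = 6) {
  if (inherits(rate, "activity_raster")) rate <- rate$rate
  n <- length(rate) - 1
  if (n < 2) stop("need at least 3 rate bins")
  px <- rate[seq_len(n)]
  py <- rate[seq_len(n) + 1]
  hx <- stats::sd(px) * n^(-1 / 6)
  hy <- stats::sd(py) * n^(-1 / 6)
  eps <- 1e-9  # constant series: degenerate to a narrow peak
  hx <- max(hx, eps); hy <- max(hy, eps)
  x <- seq(min(px) - margin * hx, max(px) + margin * hx,
           length.out = n_grid)
  y <- seq(min(py) - margin * hy, max(py) + margin * hy,
           length.out = n_grid)
  gx <- outer(x, px, function(a, b) stats::dnorm(a, b, hx))
  gy <- outer(y, py, function(a, b) stats::dnorm(a, b, hy))
  z <- gx %*% t(gy) / n
  pk <- which(z == max(z), arr.ind = TRUE)[1, ]
  list(x = x, y = y, z = z, h = c(hx, hy),
       peak = c(x = x[pk[1]], y = y[pk[2]]))
}

#' Fuzzy c-means clustering
#'
#' Standard fuzzy c-means: alternating updates of cluster centres
#' (membership-weighted means) and memberships
#' \code{u_ij = 1 / sum_l (d_ij / d_il)^(2/(m-1))}, with fuzzifier
#' \code{m}.  Membership rows sum to one; the objective
#' \code{sum u^m d^2} is non-increasing across iterations.
#'
#' @param points numeric matrix (observations x features) or vector.
#' @param k number of clusters (default 2).
#' @param fuzzifier fuzzifier exponent m > 1 (default 2).
#' @param tol convergence threshold on the maximum membership change.
#' @param max_iter iteration cap.
#' @return List with \code{membership} (n x k), \code{centers},
#'   \code{objective} (trace), \code{iterations}.
#' @export
fcm <- function(points, k = 2, fuzzifier = 2, tol = 1e-6,
                max_iter = 200) {
  x <- as.matrix(points)
  n <- nrow(x)
  if (k > n) stop("more clusters than points")
  if (all(apply(x, 2, stats::sd) == 0))
    stop("degenerate input: all points identical")
  u <- matrix(stats::runif(n * k), n, k)
  u <- u / rowSums(u)
  m <- fuzzifier
  obj <- numeric(0)
  for (it in seq_len(max_iter)) {
    um <- u^m
    centers <- t(um) %*% x / colSums(um)
    d2 <- outer(rowSums(x^2), rep(1, k)) -
      2 * x %*% t(centers) + outer(rep(1, n), rowSums(centers^2))
    d2 <- pmax(d2, 1e-300)
    obj <- c(obj, sum(um * d2))
    inv <- d2^(-1 / (m - 1))
    u_new <- inv / rowSums(inv)
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) break
  }
  list(membership = u, centers = centers, objective = obj,
       iterations = it)
}

#' Detection AUC from fuzzy clustering of return-map points
#'
#' Pools two-dimensional points (e.g. consecutive-rate pairs) from the
#' stimulated and spontaneous conditions, clusters them with fuzzy
#' c-means (k = 2, fuzzifier 2), and runs the ROC analysis on the
#' cluster-1 membership with the condition as label.  The AUC is
#' oriented to be >= 0.5 (cluster numbering is arbitrary).
#'
#' @param points_stim,points_spont numeric matrices of 2-D points.
#' @param n_boot bootstrap resamples (default 500).
#' @return An \code{roc_result} (AUC oriented >= 0.5).
#' @export
fcm_detection_auc <- function(points_stim, points_spont, n_boot = 500) {
  all_pts <- rbind(as.matrix(points_stim), as.matrix(points_spont))
  cl <- fcm(all_pts, k = 2, fuzzifier = 2)
  u1 <- cl$membership[, 1]
  n1 <- nrow(as.matrix(points_stim))
  pos <- u1[seq_len(n1)]
  neg <- u1[-seq_len(n1)]
  if (.auc_mw(pos, neg) < 0.5) { tmp <- pos; pos <- neg; neg <- tmp }
  roc_auc(pos, neg, n_boot = n_boot)
}

#' Train a perceptron read-out on network states
#'
#' Classical perceptron (learning rate 1, zero-initialized weights,
#' samples shuffled each epoch) separating stimulated-condition state
#' vectors from spontaneous ones.  Callers should remove the stimulated
#' cells' entries from the state vectors first.  Non-separable data runs
#' to the epoch cap and is flagged unconverged.
#'
#' @param x numeric matrix, one state vector per row.
#' @param labels vector with exactly two levels; the first level sorted
#'   is coded -1, the second +1 (or pass numeric -1/+1 directly).
#' @param epochs epoch cap (default 500).
#' @return List with \code{weights}, \code{converged},
#'   \code{epochs_run}, \code{errors} (per-epoch misclassifications).
#' @export
perceptron_train <- function(x, labels, epochs = 500) {
  x <- as.matrix(x)
  if (is.numeric(labels) && all(labels %in% c(-1, 1))) {
    y <- as.integer(labels)
    if (length(unique(y)) != 2) stop("labels must have exactly two classes")
  } else {
    lv <- sort(unique(as.character(labels)))
    if (length(lv) != 2) stop("labels must have exactly two classes")
    y <- ifelse(as.character(labels) == lv[2], 1L, -1L)
  }
  if (length(y) != nrow(x)) stop("labels must match rows of x")
  perceptron_cpp(t(x), y, as.integer(epochs))
}

#' Correlate perceptron weights with connectivity features
#'
#' For each non-stimulated neuron computes four structural features:
#' in-degree, out-degree, the number of direct synaptic inputs it
#' receives from the stimulated set, and the number of inputs it
#' receives from cells that themselves receive direct stimulated input.
#' Returns the Pearson correlation of the perceptron weight with each.
#'
#' @param weights weight vector over the non-stimulated neurons (order
#'   = increasing node index with stimulated nodes removed).
#' @param net a \code{\link{directed_network}}.
#' @param stim_nodes indices of the stimulated neurons.
#' @return Named numeric vector: \code{in_degree}, \code{out_degree},
#'   \code{direct_inputs}, \code{indirect_inputs}.  A feature with zero
#'   variance yields \code{NA} with a warning.
#' @export
weight_feature_correlations <- function(weights, net, stim_nodes) {
  n <- net$n_nodes
  keep <- setdiff(seq_len(n), stim_nodes)
  if (length(weights) != length(keep))
    stop("weights must have one entry per non-stimulated neuron")
  din <- in_degree(net); dout <- out_degree(net)
  ind <- numeric(n); ind[stim_nodes] <- 1
  direct <- as.numeric(net$w %*% ind)
  relay <- numeric(n)
  relay_set <- setdiff(which(direct > 0), stim_nodes)
  if (length(relay_set)) {
    ind2 <- numeric(n); ind2[relay_set] <- 1
    relay <- as.numeric(net$w %*% ind2)
  }
  feats <- cbind(in_degree = din[keep], out_degree = dout[keep],
                 direct_inputs = direct[keep],
                 indirect_inputs = relay[keep])
  out <- vapply(colnames(feats), function(f) {
    v <- feats[, f]
    if (stats::sd(v) == 0) {
      warning("feature '", f, "' has zero variance; correlation undefined")
      return(NA_real_)
    }
    stats::cor(weights, v)
  }, numeric(1))
  out
}

#' Detection AUC from a paired dataset
#'
#' Mann-Whitney AUC between the stimulated and spontaneous conditions
#' using one summary statistic per trial: either the population rate in
#' a single bin (\code{statistic = "bin"}) or the trial's firing-rate
#' response, the rate averaged over the post-onset stimulation bins
#' (\code{statistic = "window"}, bins start+1 .. start+duration-1; the
#' onset bin itself carries no downstream signal yet).
#'
#' @param dataset a \code{detection_dataset}.
#' @param statistic \code{"window"} or \code{"bin"}.
#' @param bin 0-based bin for \code{statistic = "bin"} (default: last
#'   stimulated bin).
#' @param n_boot bootstrap resamples (default 1000).
#' @return An \code{roc_result}.
#' @export
detection_auc <- function(dataset, statistic = c("window", "bin"),
                          bin = dataset$start + dataset$duration - 1,
                          n_boot = 1000) {
  statistic <- match.arg(statistic)
  if (statistic == "bin") {
    pos <- dataset$rate_stim[, bin + 1L]
    neg <- dataset$rate_spont[, bin + 1L]
  } else {
    cols <- (dataset$start + 1):(dataset$start + dataset$duration - 1) + 1L
    pos <- rowMeans(dataset$rate_stim[, cols, drop = FALSE])
    neg <- rowMeans(dataset$rate_spont[, cols, drop = FALSE])
  }
  roc_auc(pos, neg, n_boot = n_boot)
}
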