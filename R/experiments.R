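#' Named experiment configurations
#'
#' Fully resolved parameter sets for the package's standard experiments,
#' keyed by the analysis they drive: \code{"degrees"} (degree-pair
#' ensembles and artifact rates), \code{"stability"} (HFS-transition
#' curves), \code{"boa"} (basin-of-attraction profile),
#' \code{"sensitivity"} (stimulation ROC/AUC), \code{"perceptron"}
#' (read-out weight analysis) and \code{"motifs"} (sub-network motif
#' discrimination).  Defaults follow the standard model setting: large
#' networks N = 2000 with p_c = 0.05 (mean degree 100), sigma_y = mu/3,
#' dispersion 0.3, baseline rate 1 Hz in 10 ms bins, stimulation of
#' n_p = 8 cells for 6 bins starting at bin 10; motif work uses the
#' small N = 200 setting (mu = 10).
#'
#' @param name experiment name.
#' @param ... overrides of individual parameters.
#' @param seed integer seed recorded in, and applied by,
#'   \code{\link{run_experiment}}.
#' @return A list of class \code{experiment_config}.
#' @export
experiment_config <- function(name = c("degrees", "stability", "boa",
                                       "sensitivity", "perceptron",
                                       "motifs"),
                              ..., seed = 1L) {
  name <- match.arg(name)
  base <- list(n_nodes = 2000L, p_c = 0.05, dispersion = 0.3, r0 = 1,
               delta_t = 0.01, seed = as.integer(seed))
  extra <- switch(name,
    degrees = list(kinds = c("anti", "positive", "uncorrelated"),
                   n_real = 20L),
    stability = list(kind = "uncorrelated", n_trials = 100L,
                     steps = 500L, burn = 100L),
    boa = list(kind = "anti", J = 25, n_active_range = 0:200,
               n_init = 1000L, n_realizations = 4L),
    sensitivity = list(kind = "uncorrelated", J = 18, n_p = 8L,
                       start = 10L, duration = 6L,
                       n_realizations = 50L, trials_per = 40L),
    perceptron = list(kind = "uncorrelated", J = 18, n_p = 8L,
                      start = 10L, duration = 6L, n_rep = 10L,
                      trials = 50L, epochs = 500L),
    motifs = list(n_nodes = 200L, kinds = c("anti", "positive"),
                  n_real = 1000L, n_sub = 50L, n_av = 50L))
  cfg <- utils::modifyList(c(base, extra), list(...))
  cfg$name <- name
  structure(cfg, class = "experiment_config")
}

#' Run a named experiment
#'
#' Seeds the RNG, dispatches to the module drivers, and (optionally)
#' writes the results plus the fully resolved configuration to an
#' output directory as CSV/JSON.  Re-running with the same seed and
#' configuration reproduces the numbers exactly.
#'
#' @param config an \code{\link{experiment_config}}.
#' @param out_dir optional output directory; created if missing.
#' @return A list with \code{config} and experiment-specific
#'   \code{results}.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  res <- switch(config$name,
    degrees = .exp_degrees(config),
    stability = .exp_stability(config),
    boa = .exp_boa(config),
    sensitivity = .exp_sensitivity(config),
    perceptron = .exp_perceptron(config),
    motifs = .exp_motifs(config))
  out <- list(config = config, results = res)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(res)) {
      v <- res[[nm]]
      if (is.data.frame(v))
        utils::write.csv(v, file.path(out_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
    }
    scalars <- res[!vapply(res, is.data.frame, logical(1))]
    manifest <- c(unclass(config), scalars)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
    } else {
      dput(manifest, file.path(out_dir, "manifest.R"))
    }
  }
  out
}

.exp_spec <- function(config, kind) {
  degree_spec(config$n_nodes, config$p_c, dispersion = config$dispersion,
              kind = kind)
}

.exp_degrees <- function(config) {
  rows <- lapply(config$kinds, function(kind) {
    spec <- .exp_spec(config, kind)
    per <- t(vapply(seq_len(config$n_real), function(r) {
      net <- generate_network(spec)
      c(rho = degree_correlation(net),
        self_pct = 100 * net$meta$self_fraction,
        multi_pct = 100 * net$meta$multi_fraction)
    }, numeric(3)))
    data.frame(kind = kind, rho = mean(per[, "rho"]),
               abs_rho = mean(abs(per[, "rho"])),
               rho_sd = stats::sd(per[, "rho"]),
               self_pct = mean(per[, "self_pct"]),
               multi_pct = mean(per[, "multi_pct"]))
  })
  list(degree_summary = do.call(rbind, rows))
}

.exp_stability <- function(config) {
  spec <- .exp_spec(config, config$kind)
  h0 <- h0_from_rate(config$r0, config$delta_t)
  sc <- stability_curve(spec, h0, n_trials = config$n_trials,
                        steps = config$steps, burn = config$burn,
                        delta_t = config$delta_t)
  list(curve = sc$curve, J_h = sc$J_h, sigma_J = sc$sigma_J,
       r_squared = sc$r_squared,
       J_c_meanfield = meanfield_Jc(h0))
}

.exp_boa <- function(config) {
  spec <- .exp_spec(config, config$kind)
  h0 <- h0_from_rate(config$r0, config$delta_t)
  bp <- boa_profile(spec, config$J, h0,
                    n_active_range = config$n_active_range,
                    n_init = config$n_init,
                    n_realizations = config$n_realizations,
                    delta_t = config$delta_t)
  list(bins = bp$bins, N_eff_90 = bp$N_eff_90)
}

.exp_sensitivity <- function(config) {
  spec <- .exp_spec(config, config$kind)
  ds <- run_detection_ensemble(spec, config$J, r0 = config$r0,
                               n_p = config$n_p, start = config$start,
                               duration = config$duration,
                               n_realizations = config$n_realizations,
                               trials_per = config$trials_per,
                               delta_t = config$delta_t)
  tc <- auc_timecourse(ds)
  list(auc_timecourse = tc,
       auc_pre = mean(tc$auc[!tc$in_window & tc$bin < config$start]),
       auc_during = mean(tc$auc[tc$in_window]))
}

.exp_perceptron <- function(config) {
  spec <- .exp_spec(config, config$kind)
  reps <- t(vapply(seq_len(config$n_rep), function(r) {
    perceptron_weight_analysis(spec, J = config$J, r0 = config$r0,
                               n_p = config$n_p, start = config$start,
                               duration = config$duration,
                               trials = config$trials,
                               epochs = config$epochs,
                               delta_t = config$delta_t)$correlations
  }, numeric(4)))
  list(correlations = data.frame(feature = colnames(reps),
                                 mean = colMeans(reps),
                                 sd = apply(reps, 2, stats::sd)))
}

.exp_motifs <- function(config) {
  ens <- lapply(config$kinds, function(kind) {
    spec <- degree_spec(config$n_nodes, config$p_c,
                        dispersion = config$dispersion, kind = kind)
    ensemble_counts(spec, n_real = config$n_real, n_sub = config$n_sub)
  })
  names(ens) <- config$kinds
  a <- ens[[1]]; b <- ens[[2]]
  get98 <- function(d) d$normalized[d$motif_id == 98]
  pooled_a <- pool_counts(get98(a), config$n_av)
  pooled_b <- pool_counts(get98(b), config$n_av)
  au <- motif_auc(pooled_a, pooled_b,
                  set_size = min(500, length(pooled_a)))
  list(counts = do.call(rbind, ens),
       motif98_auc_pooled = au$auc, motif98_auc_sd = au$auc_sd)
}

#' End-to-end perceptron weight analysis
#'
#' Builds one network, collects equal numbers of during-stimulus and
#' spontaneous binary state vectors (stimulated cells' entries
#' removed), trains the perceptron read-out and correlates its weights
#' with the four connectivity features of
#' \code{\link{weight_feature_correlations}}.
#'
#' @param spec a \code{\link{degree_spec}} or a fixed
#'   \code{\link{directed_network}}.
#' @param J,r0,n_p,start,duration,delta_t model and stimulation
#'   parameters (defaults J = 18, r0 = 1 Hz, 8 cells, bins 10..15).
#' @param trials paired trials collected; each contributes
#'   \code{duration} state vectors per condition.
#' @param epochs perceptron epoch cap.
#' @return List with \code{correlations} (named vector),
#'   \code{weights}, \code{stim_nodes}, \code{converged}.
#' @export
perceptron_weight_analysis <- function(spec, J = 18, r0 = 1, n_p = 8,
                                       start = 10, duration = 6,
                                       trials = 50, epochs = 500,
                                       delta_t = 0.01) {
  fresh <- inherits(spec, "degree_spec")
  net <- if (fresh) generate_network(spec) else spec
  norm <- if (fresh) spec$n_nodes * spec$p_c else mean(in_degree(net))
  params <- dynamics_params(J = J, norm = norm, r0 = r0, delta_t = delta_t)
  n <- net$n_nodes
  stim_nodes <- sample.int(n, n_p)
  keep <- setdiff(seq_len(n), stim_nodes)
  prot <- stim_protocol(stim_nodes, start = start, duration = duration)
  steps <- start + duration - 1
  win <- (start:(start + duration - 1)) + 1L  # raster rows of the window
  xs <- vector("list", 2 * trials)
  for (k in seq_len(trials)) {
    s1 <- simulate_network(net, params, steps,
                           initial = initial_state_lfs(net, params),
                           protocol = prot)
    s0 <- simulate_network(net, params, steps,
                           initial = initial_state_lfs(net, params))
    xs[[2 * k - 1]] <- s1$raster[win, keep, drop = FALSE]
    xs[[2 * k]] <- s0$raster[win, keep, drop = FALSE]
  }
  X <- do.call(rbind, xs)
  y <- rep(rep(c(1L, -1L), trials), each = duration)
  fit <- perceptron_train(X, y, epochs = epochs)
  corr <- weight_feature_correlations(fit$weights, net, stim_nodes)
  list(correlations = corr, weights = fit$weights,
       stim_nodes = stim_nodes, converged = fit$converged)
}
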