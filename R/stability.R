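#' Classify the attractor reached by a run
#'
#' The bistable network settles either in the low-firing state (LFS,
#' population activity around r0 * delta_t, e.g. 0.01) or the
#' high-firing state (HFS, activity near 1).  A run is classified HFS
#' when the mean population activity over the last \code{n_tail} bins
#' exceeds \code{threshold}; with attractors at ~0.01 and ~1 any
#' mid-range threshold gives the same answer.
#'
#' @param x a \code{raster} from \code{\link{simulate_network}}, or a
#'   numeric vector of per-bin population activities.
#' @param threshold activity threshold (default 0.5).
#' @param n_tail number of final bins averaged (default 10).
#' @return \code{"HFS"} or \code{"LFS"}.
#' @export
classify_attractor <- function(x, threshold = 0.5, n_tail = 10) {
  if (inherits(x, "activity_raster")) {
    if (isTRUE(x$hfs_early)) return("HFS")
    x <- x$rate
  }
  if (length(x) < n_tail) stop("need at least ", n_tail, " bins")
  tail_mean <- mean(x[(length(x) - n_tail + 1):length(x)])
  if (tail_mean > threshold) "HFS" else "LFS"
}

#' Mean-field critical coupling
#'
#' The largest coupling at which the low-firing fixed point of the
#' scalar mean-field map still exists, found by bisection on J (the
#' existence predicate evaluates \code{\link{mean_field_fixed_points}}
#' and asks for a stable root below 0.5).
#'
#' @param h0 background field.
#' @param tol bisection tolerance in J (default 1e-4).
#' @param J_max upper bracket; the default comfortably exceeds the
#'   tangency point \code{exp(h0 - 1)} of the sparse-rate regime.
#' @return Critical coupling \code{J_c}.
#' @export
meanfield_Jc <- function(h0, tol = 1e-4, J_max = 2 * exp(h0 - 1) + 10) {
  has_lfs <- function(J) {
    fp <- mean_field_fixed_points(J, h0)
    any(fp$stable & fp$v < 0.5)
  }
  lo <- 0
  hi <- J_max
  if (!has_lfs(lo)) stop("no low-firing state even at J = 0")
  if (has_lfs(hi)) stop("J_max bracket too small")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (has_lfs(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Critical coupling of the deterministic finite-size dynamics
#'
#' Bisection on J: at each candidate the deterministic rate map is
#' iterated from the uniform LFS-matched rate vector for at most
#' \code{max_steps} steps and the attractor is classified.  Finite-size
#' degree heterogeneity makes this J_c smaller than the mean-field one.
#'
#' @param net a \code{\link{directed_network}}.
#' @param h0 background field.
#' @param norm coupling normalization (default \code{N * p_c} is not
#'   known to the network, so pass it; defaults to the realized mean
#'   in-degree).
#' @param tol bisection tolerance in J (default 0.05).
#' @param max_steps iteration cap per candidate J.
#' @param J_bracket initial bracket; default (0, mean-field J_c).
#' @param delta_t bin width (only threaded through to the params).
#' @return Critical coupling \code{J_c}.
#' @export
deterministic_Jc <- function(net, h0, norm = mean(in_degree(net)),
                             tol = 0.05, max_steps = 400,
                             J_bracket = NULL, delta_t = 0.01) {
  goes_hfs <- function(J) {
    params <- dynamics_params(J = J, norm = norm, delta_t = delta_t, h0 = h0)
    sim <- simulate_network(net, params, max_steps,
                            mode = "deterministic", record_raster = FALSE)
    classify_attractor(sim) == "HFS"
  }
  if (is.null(J_bracket)) J_bracket <- c(0, meanfield_Jc(h0) + 1)
  lo <- J_bracket[1]; hi <- J_bracket[2]
  if (goes_hfs(lo)) stop("lower bracket already reaches the HFS")
  if (!goes_hfs(hi)) stop("upper bracket still reaches the LFS")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (goes_hfs(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Fraction of stochastic trials reaching the high-firing state
#'
#' Runs repeated stochastic simulations from mean-field-matched random
#' initial states and reports the fraction classified HFS.  By default
#' a fresh network realization is generated per trial (pass a
#' \code{\link{degree_spec}}); passing a \code{\link{directed_network}}
#' keeps the realization fixed.
#'
#' @param net_or_spec a \code{degree_spec} (fresh realization per
#'   trial) or a \code{directed_network} (fixed realization).
#' @param J coupling strength.
#' @param h0 background field.
#' @param n_trials number of trials (default 100).
#' @param steps trial length in bins (default 500).
#' @param burn initial bins regarded as transient (default 100; a trial
#'   counts as HFS when it is classified as such on the post-burn
#'   window).
#' @param norm coupling normalization; defaults to \code{N * p_c} of
#'   the spec, or the realized mean in-degree of a fixed network.
#' @param delta_t bin width in seconds.
#' @return Fraction in [0, 1].
#' @export
hfs_fraction <- function(net_or_spec, J, h0, n_trials = 100, steps = 500,
                         burn = 100, norm = NULL, delta_t = 0.01) {
  fresh <- inherits(net_or_spec, "degree_spec")
  if (is.null(norm)) {
    norm <- if (fresh) net_or_spec$n_nodes * net_or_spec$p_c
            else mean(in_degree(net_or_spec))
  }
  params <- dynamics_params(J = J, norm = norm, delta_t = delta_t, h0 = h0)
  net <- if (fresh) NULL else net_or_spec
  n_hfs <- 0L
  for (k in seq_len(n_trials)) {
    if (fresh) net <- generate_network(net_or_spec)
    x0 <- initial_state_lfs(net, params)
    res <- .run_trial(net, params, steps, x0, burn = burn)
    hfs <- isTRUE(res$hfs_early) ||
      mean(utils::tail(res$rate, 10)) > 0.5
    if (hfs) n_hfs <- n_hfs + 1L
  }
  n_hfs / n_trials
}

#' Fit the sigmoidal HFS-transition curve
#'
#' Nonlinear least squares of
#' \code{p(J) = 1 / (1 + exp(-(J - J_h) / sigma_J))} to the fraction of
#' trials reaching the HFS as a function of coupling.  \code{J_h} is the
#' transition midpoint (the stochastic critical coupling) and
#' \code{sigma_J} the transition width.
#'
#' @param J numeric grid of couplings (>= 4 points).
#' @param fraction HFS fractions in [0, 1] at each J.
#' @return List with \code{J_h}, \code{sigma_J}, \code{r_squared} and
#'   the \code{fitted} values.
#' @export
fit_sigmoid <- function(J, fraction) {
  stopifnot(length(J) == length(fraction), length(J) >= 4)
  if (all(fraction == 0) || all(fraction == 1))
    stop("cannot fit a transition to an all-0 or all-1 curve")
  start_Jh <- J[which.min(abs(fraction - 0.5))]
  fit <- minpack.lm::nlsLM(
    fraction ~ 1 / (1 + exp(-(J - Jh) / sJ)),
    start = list(Jh = start_Jh, sJ = max(diff(range(J)) / 10, 1e-3)),
    lower = c(-Inf, 1e-8),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  co <- stats::coef(fit)
  fitted <- stats::fitted(fit)
  ss_res <- sum((fraction - fitted)^2)
  ss_tot <- sum((fraction - mean(fraction))^2)
  list(J_h = unname(co["Jh"]), sigma_J = unname(co["sJ"]),
       r_squared = 1 - ss_res / ss_tot, fitted = as.numeric(fitted))
}

#' HFS-fraction transition curve with sigmoid fit
#'
#' Locates the stochastic transition by a coarse scan, then measures the
#' HFS fraction on a fine J grid spanning the transition (default
#' midpoint +- 2 at step 0.2) and fits the sigmoid of
#' \code{\link{fit_sigmoid}}.
#'
#' @inheritParams hfs_fraction
#' @param J_grid optional explicit grid; when \code{NULL} a coarse
#'   pre-scan (\code{scan_trials} trials per point) brackets the
#'   midpoint first.
#' @param scan_trials trials per point for the pre-scan (default 20).
#' @param span,step fine-grid half-width and step (defaults 2 and 0.2).
#' @return Object of class \code{stability_curve}: data.frame
#'   \code{curve} (J, fraction) plus fit parameters \code{J_h},
#'   \code{sigma_J}, \code{r_squared}.
#' @export
stability_curve <- function(net_or_spec, h0, J_grid = NULL,
                            n_trials = 100, steps = 500, burn = 100,
                            norm = NULL, delta_t = 0.01,
                            scan_trials = 20, span = 2, step = 0.2) {
  if (is.null(J_grid)) {
    # coarse bracket of the 50% crossing, then golden-ish refinement
    J_hi <- meanfield_Jc(h0, tol = 0.01)
    lo <- 0; hi <- J_hi
    repeat {
      mid <- (lo + hi) / 2
      f <- hfs_fraction(net_or_spec, mid, h0, n_trials = scan_trials,
                        steps = steps, burn = burn, norm = norm,
                        delta_t = delta_t)
      if (f < 0.5) lo <- mid else hi <- mid
      if (hi - lo < 1) break
    }
    centre <- (lo + hi) / 2
    J_grid <- seq(centre - span, centre + span, by = step)
  }
  fraction <- vapply(J_grid, function(J)
    hfs_fraction(net_or_spec, J, h0, n_trials = n_trials, steps = steps,
                 burn = burn, norm = norm, delta_t = delta_t), numeric(1))
  fit <- fit_sigmoid(J_grid, fraction)
  structure(list(curve = data.frame(J = J_grid, fraction = fraction),
                 J_h = fit$J_h, sigma_J = fit$sigma_J,
                 r_squared = fit$r_squared),
            class = "stability_curve")
}

#' @export
print.stability_curve <- function(x, ...) {
  cat(sprintf("<stability_curve> J_h = %.3f, sigma_J = %.4f, R^2 = %.4f (%d J values)\n",
              x$J_h, x$sigma_J, x$r_squared, nrow(x$curve)))
  invisible(x)
}

#' Stability gap between mean-field and stochastic finite-size networks
#'
#' \code{J_gap} is the mean-field critical coupling minus the
#' stochastic transition midpoint \code{J_h}; a smaller gap means the
#' finite noisy network loses less stability relative to the mean-field
#' ideal.
#'
#' @inheritParams stability_curve
#' @param curve optionally a precomputed \code{stability_curve}.
#' @return List with \code{J_gap}, \code{J_c_meanfield}, \code{J_h}.
#' @export
j_gap <- function(net_or_spec, h0, curve = NULL, ...) {
  if (is.null(curve))
    curve <- stability_curve(net_or_spec, h0, ...)
  Jc_mf <- meanfield_Jc(h0)
  list(J_gap = Jc_mf - curve$J_h, J_c_meanfield = Jc_mf, J_h = curve$J_h)
}

#' Effective number of active neurons
#'
#' Initial states with the same number of active neurons differ in how
#' strongly they drive the network, depending on the out-degrees of the
#' active cells.  The effective count weights each active neuron by its
#' out-degree:
#' \deqn{N_{eff} = N \sum_{i \in active} d^{out}_i / \sum_i d^{out}_i.}
#'
#' @param active integer vector of active node indices (1-based), or a
#'   binary 0/1 vector of length \code{n_nodes}.
#' @param net a \code{\link{directed_network}}.
#' @return Scalar in [0, N].
#' @export
effective_active <- function(active, net) {
  dout <- out_degree(net)
  if (length(active) == net$n_nodes && all(active %in% c(0, 1)))
    active <- which(active == 1)
  net$n_nodes * sum(dout[active]) / sum(dout)
}

#' Basin-of-attraction profile over N_eff
#'
#' Random initial states with varying numbers of active neurons are
#' simulated and classified; binning trials by their effective active
#' count N_eff maps out the basin boundary between the LFS and the HFS.
#' \code{N_eff_90} is the lowest unit-width bin in which at least 90\%
#' of trials (among bins with at least \code{min_trials}) reached the
#' HFS.
#'
#' @param net_or_spec a \code{degree_spec} (fresh realizations) or a
#'   fixed \code{directed_network}.
#' @param J,h0 coupling and background field.
#' @param n_active_range range of initial active-neuron counts sampled
#'   uniformly (default 0:200).
#' @param n_init initial conditions per realization (default 1000).
#' @param n_realizations network realizations averaged (default 4; 1 if
#'   a fixed network is supplied).
#' @param steps simulation cap per trial (default 400).
#' @param min_trials minimum trials for a bin to be defined.
#' @param norm,delta_t as in \code{\link{hfs_fraction}}.
#' @return Object of class \code{boa_profile}: data.frame \code{bins}
#'   (n_eff bin, lfs count, hfs count) and \code{N_eff_90}.
#' @export
boa_profile <- function(net_or_spec, J, h0, n_active_range = 0:200,
                        n_init = 1000, n_realizations = 4, steps = 400,
                        min_trials = 20, norm = NULL, delta_t = 0.01) {
  fresh <- inherits(net_or_spec, "degree_spec")
  if (!fresh) n_realizations <- 1L
  if (is.null(norm)) {
    norm <- if (fresh) net_or_spec$n_nodes * net_or_spec$p_c
            else mean(in_degree(net_or_spec))
  }
  params <- dynamics_params(J = J, norm = norm, delta_t = delta_t, h0 = h0)
  neff <- numeric(0); hfs <- logical(0)
  for (r in seq_len(n_realizations)) {
    net <- if (fresh) generate_network(net_or_spec) else net_or_spec
    n <- net$n_nodes
    for (k in seq_len(n_init)) {
      na <- sample(n_active_range, 1L)
      x0 <- integer(n)
      if (na > 0) x0[sample.int(n, min(na, n))] <- 1L
      res <- .run_trial(net, params, steps, x0)
      neff <- c(neff, effective_active(x0, net))
      hfs <- c(hfs, isTRUE(res$hfs_early) ||
                 mean(utils::tail(res$rate, 10)) > 0.5)
    }
  }
  bin <- floor(neff)
  agg <- stats::aggregate(cbind(hfs = hfs, n = 1L),
                          by = list(n_eff = bin), FUN = sum)
  bins <- data.frame(n_eff = agg$n_eff,
                     n_lfs = agg$n - agg$hfs,
                     n_hfs = agg$hfs,
                     n_trials = agg$n)
  bins$hfs_fraction <- ifelse(bins$n_trials >= min_trials,
                              bins$n_hfs / bins$n_trials, NA_real_)
  defined <- !is.na(bins$hfs_fraction)
  hit <- which(defined & bins$hfs_fraction >= 0.9)
  n_eff_90 <- if (length(hit)) bins$n_eff[min(hit)] else NA_real_
  structure(list(bins = bins, N_eff_90 = n_eff_90, J = J),
            class = "boa_profile")
}

#' @export
print.boa_profile <- function(x, ...) {
  cat(sprintf("<boa_profile> J = %.3f, %d trials, N_eff,90 = %s\n",
              x$J, sum(x$bins$n_trials),
              ifelse(is.na(x$N_eff_90), "undefined", format(x$N_eff_90))))
  invisible(x)
}

#' Squared correlation between per-neuron firing rate and in-degree
#'
#' A neuron's stationary low-firing-state rate grows with its in-degree.
#' Under the deterministic rate map the relation is almost perfect
#' (R^2 close to 1); under the stochastic dynamics it is jittered by
#' spike-counting noise.  The stochastic measurement averages each
#' neuron's activity over the post-burn bins; resolving rates of a few
#' Hz against the across-neuron rate spread (a few tenths of a Hz)
#' requires averaging windows of order 2000 bins, hence the default
#' \code{steps}.  Runs that escape to the high-firing state are
#' discarded and redrawn (the scatter is a property of the low-firing
#' state).
#'
#' @param net_or_spec a \code{\link{degree_spec}} (fresh realization per
#'   repeat) or a fixed \code{\link{directed_network}}.
#' @param J coupling strength (e.g. 30.96, just below the anti-network
#'   transition).
#' @param h0 background field.
#' @param mode \code{"stochastic"} or \code{"deterministic"}.
#' @param steps,burn simulation length and discarded transient
#'   (defaults 2000/100 stochastic, 500/100 deterministic).
#' @param n_realizations repeats averaged (default 10).
#' @param norm,delta_t as in \code{\link{hfs_fraction}}.
#' @param max_redraw cap on redraws after HFS escapes.
#' @return List with \code{r_squared} (mean), \code{r_squared_sd},
#'   \code{values}.
#' @export
rate_indegree_r2 <- function(net_or_spec, J, h0,
                             mode = c("stochastic", "deterministic"),
                             steps = if (mode == "stochastic") 2000 else 500,
                             burn = 100, n_realizations = 10,
                             norm = NULL, delta_t = 0.01,
                             max_redraw = 20) {
  mode <- match.arg(mode)
  fresh <- inherits(net_or_spec, "degree_spec")
  if (is.null(norm)) {
    norm <- if (fresh) net_or_spec$n_nodes * net_or_spec$p_c
            else mean(in_degree(net_or_spec))
  }
  params <- dynamics_params(J = J, norm = norm, delta_t = delta_t, h0 = h0)
  vals <- numeric(n_realizations)
  for (r in seq_len(n_realizations)) {
    for (try in seq_len(max_redraw)) {
      net <- if (fresh) generate_network(net_or_spec) else net_or_spec
      s <- simulate_network(net, params, steps, mode = mode,
                            record_raster = FALSE, burn = burn)
      if (classify_attractor(s) == "LFS") break
      if (!fresh && try == 1 && mode == "deterministic")
        stop("deterministic run reaches the HFS at this coupling")
    }
    if (classify_attractor(s) == "HFS")
      stop("all runs escaped to the HFS; coupling too large")
    vals[r] <- stats::cor(s$neuron_mean, in_degree(net))^2
  }
  list(r_squared = mean(vals), r_squared_sd = stats::sd(vals),
       values = vals)
}
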