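#' Dynamics parameters
#'
#' Parameters of the binary-neuron update.  Each time bin (width
#' \code{delta_t}, nominally 10 ms) neuron i fires with probability
#' \deqn{\nu_i = 1 / (1 + \exp(h_0 - (J / N p_c) \sum_j w_{ij} x_j)),}
#' where \code{h0} is the background field setting the baseline firing
#' rate and the coupling J is normalized by the expected in-degree
#' \code{norm = N * p_c} so that J measures the overall coupling
#' strength independently of network size.
#'
#' @param J coupling strength (dimensionless, >= 0).
#' @param norm coupling normalization, the expected in-degree
#'   \code{N * p_c}.
#' @param r0 baseline firing rate in Hz (rate at J = 0); used to set
#'   \code{h0} when \code{h0} is not given.
#' @param delta_t time-bin width in seconds (default 0.01 = 10 ms).
#' @param h0 background field; defaults to
#'   \code{h0_from_rate(r0, delta_t)}.
#' @return Object of class \code{dynamics_params}.
#' @export
dynamics_params <- function(J, norm, r0 = 1, delta_t = 0.01,
                            h0 = h0_from_rate(r0, delta_t)) {
  stopifnot(J >= 0, norm > 0, delta_t > 0)
  structure(list(J = J, norm = norm, h0 = h0, delta_t = delta_t),
            class = "dynamics_params")
}

#' Background field from baseline firing rate
#'
#' The baseline rate is the firing rate at zero coupling,
#' \code{r0 = (1 / delta_t) / (1 + exp(h0))}; this helper inverts that
#' relation: \code{h0 = log(1 / (r0 * delta_t) - 1)}.
#'
#' @param r0 baseline firing rate in Hz.
#' @param delta_t bin width in seconds.
#' @return The background field \code{h0}.
#' @export
h0_from_rate <- function(r0, delta_t = 0.01) {
  p <- r0 * delta_t
  if (p <= 0 || p >= 1)
    stop("r0 * delta_t must lie strictly between 0 and 1")
  log(1 / p - 1)
}

# logistic of (h0 - drive), exponent clipped to +-700
.sigmoid <- function(z) 1 / (1 + exp(pmin(pmax(z, -700), 700)))

#' Per-neuron firing probabilities
#'
#' Evaluates \code{1 / (1 + exp(h0 - (J/norm) * inputs))} where
#' \code{inputs} is the number of active presynaptic neurons (or, for a
#' real-valued rate state, the summed presynaptic rate).
#'
#' @param x binary state or rate vector of length \code{n_nodes}.
#' @param net a \code{\link{directed_network}}.
#' @param params a \code{\link{dynamics_params}}.
#' @return Probability vector in (0, 1).
#' @export
firing_probabilities <- function(x, net, params) {
  drive <- as.numeric(net$w %*% x)
  .sigmoid(params$h0 - (params$J / params$norm) * drive)
}

#' One step of the stochastic binary update
#'
#' Each neuron independently becomes active when a fresh uniform variate
#' is at most its firing probability.
#'
#' @inheritParams firing_probabilities
#' @return Binary 0/1 vector.
#' @export
step_stochastic <- function(x, net, params) {
  nu <- firing_probabilities(x, net, params)
  as.integer(stats::runif(length(nu)) <= nu)
}

#' One step of the deterministic rate map
#'
#' The same sigmoidal map applied to real-valued per-neuron rates,
#' without sampling: the zero-noise counterpart of the stochastic
#' update, isolating the effect of degree heterogeneity.
#'
#' @param v rate vector in [0, 1].
#' @inheritParams firing_probabilities
#' @return Next rate vector.
#' @export
step_deterministic <- function(v, net, params) {
  firing_probabilities(v, net, params)
}

#' Mean-field fixed points
#'
#' In the infinite homogeneous limit the per-neuron rates collapse to a
#' scalar map \code{v -> 1/(1 + exp(h0 - J v))}.  Its fixed points are
#' the roots of \code{f(x) = x - 1/(1 + exp(h0 - J x))} on [0, 1],
#' located by a sign-change scan on a dense grid followed by bracketed
#' root polishing.  A root is stable when the map's derivative
#' \code{J g (1 - g)} has magnitude below 1.
#'
#' @param J coupling strength.
#' @param h0 background field.
#' @param n_grid grid resolution for the sign-change scan.
#' @param tol residual tolerance for polished roots.
#' @return data.frame with columns \code{v} (ascending) and
#'   \code{stable}.
#' @export
mean_field_fixed_points <- function(J, h0, n_grid = 1e4, tol = 1e-12) {
  f <- function(x) x - .sigmoid(h0 - J * x)
  g <- seq(0, 1, length.out = n_grid)
  fg <- f(g)
  roots <- g[fg == 0]
  sgn <- sign(fg)
  idx <- which(sgn[-1] * sgn[-n_grid] < 0)
  for (k in idx) {
    r <- stats::uniroot(f, c(g[k], g[k + 1]), tol = .Machine$double.eps^0.75)
    roots <- c(roots, r$root)
  }
  roots <- sort(unique(roots))
  if (length(roots) && any(abs(f(roots)) > tol))
    roots <- roots[abs(f(roots)) <= tol]
  gr <- .sigmoid(h0 - J * roots)
  deriv <- J * gr * (1 - gr)
  data.frame(v = roots, stable = abs(deriv) < 1)
}

#' Stimulation protocol
#'
#' A nanostimulation-like perturbation: a set of \code{n_p} neurons is
#' clamped active for \code{duration} consecutive bins starting at bin
#' \code{start} (bin 0 is the initial state).  Clamping is applied after
#' the stochastic update, so stimulated cells fire on every bin of the
#' window regardless of their inputs.
#'
#' @param nodes integer vector of stimulated node indices (1-based,
#'   distinct).
#' @param start first stimulated bin (default 10).
#' @param duration number of stimulated bins (default 6, i.e. bins
#'   10..15 with the defaults).
#' @return Object of class \code{stim_protocol}.
#' @export
stim_protocol <- function(nodes, start = 10, duration = 6) {
  nodes <- as.integer(nodes)
  stopifnot(length(nodes) >= 1, !anyDuplicated(nodes), start >= 1,
            duration >= 1)
  structure(list(nodes = nodes, start = as.integer(start),
                 duration = as.integer(duration)),
            class = "stim_protocol")
}

#' Initial state matched to the mean-field low-firing rate
#'
#' A uniformly random set of \code{round(N * v)} neurons is made active,
#' where \code{v} is the mean-field low-firing-state rate at the given
#' coupling (falling back to the baseline rate \code{1/(1+exp(h0))} when
#' no low root exists).  On average the state has the same number of
#' active neurons as the mean-field limit predicts.
#'
#' @param net a \code{\link{directed_network}}.
#' @param params a \code{\link{dynamics_params}}.
#' @return Binary 0/1 vector of length \code{n_nodes}.
#' @export
initial_state_lfs <- function(net, params) {
  fp <- mean_field_fixed_points(params$J, params$h0)
  low <- fp$v[fp$stable & fp$v < 0.5]
  v <- if (length(low)) min(low) else .sigmoid(params$h0)
  n_active <- round(net$n_nodes * v)
  x <- integer(net$n_nodes)
  if (n_active > 0)
    x[sample.int(net$n_nodes, n_active)] <- 1L
  x
}

#' Simulate the network dynamics
#'
#' Iterates the stochastic binary update (or its deterministic rate
#' counterpart) for \code{steps} time bins, optionally applying a
#' stimulation protocol.  In stochastic mode the loop runs in compiled
#' code with per-neuron uniform thresholding; reproducibility is
#' governed by \code{set.seed()}.
#'
#' @param net a \code{\link{directed_network}}.
#' @param params a \code{\link{dynamics_params}}.
#' @param steps number of update steps T; the returned raster has
#'   \code{steps + 1} rows (row 1 = initial state).
#' @param initial initial binary state (stochastic) or rate vector
#'   (deterministic); default \code{\link{initial_state_lfs}} /
#'   its rate analogue.
#' @param protocol optional \code{\link{stim_protocol}} (stochastic mode
#'   only).
#' @param mode \code{"stochastic"} or \code{"deterministic"}.
#' @param record_raster keep the full binary raster (rows = bins,
#'   columns = neurons)?  Population rates are always recorded.
#' @param burn bins discarded before computing per-neuron mean
#'   activities.
#' @return Object of class \code{raster}: list with \code{rate}
#'   (per-bin population activity, fraction of active neurons),
#'   \code{rate_hz} (the same divided by \code{delta_t}),
#'   \code{neuron_mean} (per-neuron mean activity over post-burn bins),
#'   \code{raster} (if recorded), \code{hfs_early}, \code{steps_run},
#'   \code{delta_t}.
#' @export
simulate_network <- function(net, params, steps,
                             initial = NULL, protocol = NULL,
                             mode = c("stochastic", "deterministic"),
                             record_raster = TRUE, burn = 0) {
  mode <- match.arg(mode)
  n <- net$n_nodes
  if (!is.null(protocol)) {
    if (any(protocol$nodes < 1 | protocol$nodes > n))
      stop("stimulated nodes out of range")
    if (protocol$start + protocol$duration - 1 > steps && steps > 0)
      stop("stimulation window extends past the simulation length")
  }
  if (mode == "deterministic") {
    if (is.null(initial)) {
      fp <- mean_field_fixed_points(params$J, params$h0)
      low <- fp$v[fp$stable & fp$v < 0.5]
      v0 <- if (length(low)) min(low) else .sigmoid(params$h0)
      initial <- rep(v0, n)
    }
    if (!is.null(protocol))
      stop("stimulation clamping is defined for the stochastic mode")
    ras <- matrix(NA_real_, steps + 1, n)
    ras[1, ] <- initial
    v <- initial
    for (t in seq_len(steps)) {
      v <- step_deterministic(v, net, params)
      ras[t + 1, ] <- v
    }
    rate <- rowMeans(ras)
    post <- if (steps > burn) (burn + 2):(steps + 1) else integer(0)
    nm <- if (length(post)) colMeans(ras[post, , drop = FALSE]) else rep(NA_real_, n)
    out <- list(rate = rate, rate_hz = rate / params$delta_t,
                neuron_mean = nm,
                raster = if (record_raster) ras else NULL,
                hfs_early = FALSE, steps_run = steps,
                delta_t = params$delta_t, mode = mode)
    return(structure(out, class = "activity_raster"))
  }
  if (is.null(initial)) initial <- initial_state_lfs(net, params)
  stopifnot(length(initial) == n, all(initial %in% c(0L, 1L)))
  stim <- if (is.null(protocol)) integer(0) else protocol$nodes - 1L
  res <- sim_stochastic_cpp(net$w@p, net$w@i, n,
                            params$J / params$norm, params$h0, steps,
                            as.integer(initial), stim,
                            if (is.null(protocol)) 0L else protocol$start,
                            if (is.null(protocol)) 0L else protocol$duration,
                            record_raster, as.integer(burn),
                            FALSE, 1.0, 1L)
  out <- list(rate = res$rate, rate_hz = res$rate / params$delta_t,
              neuron_mean = res$neuron_mean,
              raster = if (record_raster) res$raster else NULL,
              hfs_early = res$hfs_early, steps_run = res$steps_run,
              delta_t = params$delta_t, mode = mode)
  structure(out, class = "activity_raster")
}

#' @export
print.activity_raster <- function(x, ...) {
  cat(sprintf("<activity_raster> %s run, %d bins, mean activity %.4f (%.2f Hz)\n",
              x$mode, length(x$rate), mean(x$rate),
              mean(x$rate) / x$delta_t))
  invisible(x)
}

# internal fast trial runner used by the stability module: no raster,
# early termination once the HFS is reached
.run_trial <- function(net, params, steps, initial, burn = 0,
                       early_thresh = 0.9, early_bins = 10) {
  sim_stochastic_cpp(net$w@p, net$w@i, net$n_nodes,
                     params$J / params$norm, params$h0, steps,
                     as.integer(initial), integer(0), 0L, 0L,
                     FALSE, as.integer(burn),
                     TRUE, early_thresh, as.integer(early_bins))
}
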