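#' Joint degree distribution specification
#'
#' Parameters of the truncated, rotated bivariate-Gaussian joint
#' distribution of a node's (in-degree, out-degree).  The base density is
#' an axis-aligned Gaussian centred at \code{(mu, mu)} with a short axis
#' \code{sigma_x} and a long axis \code{sigma_y}; rotating it by 45
#' degrees anticlockwise puts the long axis along the anti-diagonal
#' (anti-correlated degrees) and clockwise along the diagonal (positively
#' correlated degrees).  The uncorrelated control uses a diagonal
#' covariance with per-axis standard deviation
#' \code{sqrt((sigma_x^2 + sigma_y^2) / 2)} so its marginals match the
#' rotated cases.  Degrees are truncated to \code{[1, 2 mu]}: zero-degree
#' nodes are excluded and the interval is symmetric about the mean.
#'
#' @param n_nodes number of nodes N.
#' @param p_c connection probability in (0, 1); the mean degree is
#'   \code{mu = n_nodes * p_c}.
#' @param sigma_y long-axis standard deviation, in degree units
#'   (default \code{mu / 3}).
#' @param dispersion ratio \code{sigma_x / sigma_y} in (0, 1]; smaller
#'   values give stronger degree correlation (default 0.3).
#' @param kind one of \code{"anti"}, \code{"positive"},
#'   \code{"uncorrelated"}, \code{"er"}.
#'
#' @return An object of class \code{degree_spec}.
#' @export
degree_spec <- function(n_nodes, p_c, sigma_y = n_nodes * p_c / 3,
                        dispersion = 0.3,
                        kind = c("anti", "positive", "uncorrelated", "er")) {
  kind <- match.arg(kind)
  mu <- n_nodes * p_c
  stopifnot(n_nodes >= 2, p_c > 0, p_c < 1, mu >= 1,
            sigma_y > 0, dispersion > 0, dispersion <= 1)
  structure(
    list(n_nodes = as.integer(n_nodes), p_c = p_c, mu = mu,
         sigma_y = sigma_y, sigma_x = dispersion * sigma_y,
         dispersion = dispersion, kind = kind,
         trunc = c(1, 2 * mu)),
    class = "degree_spec")
}

#' @export
print.degree_spec <- function(x, ...) {
  cat(sprintf(paste0("<degree_spec> kind=%s N=%d p_c=%g (mu=%g), ",
                     "sigma_y=%.3g, dispersion=%.3g, degrees in [%g, %g]\n"),
              x$kind, x$n_nodes, x$p_c, x$mu, x$sigma_y, x$dispersion,
              x$trunc[1], x$trunc[2]))
  invisible(x)
}

#' Sample per-node (in-degree, out-degree) pairs
#'
#' Draws \code{n_nodes} pairs from the truncated, rotated bivariate
#' Gaussian described by the spec.  For \code{kind = "anti"} /
#' \code{"positive"} the axis-aligned draw \code{(x, y)} (standard
#' deviations \code{sigma_x}, \code{sigma_y}) is rotated about
#' \code{(mu, mu)} by +45 degrees (anticlockwise) or -45 degrees
#' (clockwise) respectively; for \code{"uncorrelated"} both axes use the
#' marginal-matching standard deviation.  Truncation to \code{[1, 2 mu]}
#' is enforced by rejection on the continuous values, which are then
#' rounded to the nearest integer.
#'
#' @param spec a \code{\link{degree_spec}} (kind must not be \code{"er"};
#'   Erdos-Renyi degrees are implied by edge sampling).
#' @param max_reject stop with an error if the per-round rejection rate
#'   stays above this fraction (an infeasible truncation interval).
#' @return A list of class \code{degree_pairs} with integer vectors
#'   \code{d_in}, \code{d_out}.
#' @export
sample_degree_pairs <- function(spec, max_reject = 0.999) {
  if (spec$kind == "er")
    stop("Erdos-Renyi networks imply their degrees; use erdos_renyi()")
  n <- spec$n_nodes
  mu <- spec$mu
  lo <- spec$trunc[1]; hi <- spec$trunc[2]
  if (lo > hi) stop("empty truncation interval")
  s <- 1 / sqrt(2)
  d_in <- numeric(0); d_out <- numeric(0)
  need <- n
  while (need > 0) {
    m <- max(2L * need, 64L)
    if (spec$kind == "uncorrelated") {
      sd_eq <- sqrt((spec$sigma_x^2 + spec$sigma_y^2) / 2)
      u <- mu + stats::rnorm(m, 0, sd_eq)
      v <- mu + stats::rnorm(m, 0, sd_eq)
    } else {
      x <- stats::rnorm(m, 0, spec$sigma_x)   # short axis
      y <- stats::rnorm(m, 0, spec$sigma_y)   # long axis
      if (spec$kind == "anti") {
        # anticlockwise 45 deg: long axis -> anti-diagonal
        u <- mu + s * (x - y)
        v <- mu + s * (x + y)
      } else {
        # clockwise 45 deg: long axis -> diagonal
        u <- mu + s * (x + y)
        v <- mu + s * (y - x)
      }
    }
    ok <- u >= lo & u <= hi & v >= lo & v <= hi
    if (mean(ok) < 1 - max_reject)
      stop("rejection rate above limit: truncated degree spec infeasible")
    keep <- min(sum(ok), need)
    idx <- which(ok)[seq_len(keep)]
    d_in <- c(d_in, u[idx]); d_out <- c(d_out, v[idx])
    need <- need - keep
  }
  structure(list(d_in = as.integer(round(d_in)),
                 d_out = as.integer(round(d_out)),
                 spec = spec),
            class = "degree_pairs")
}

#' Balance total in- and out-degree
#'
#' The configuration model needs \code{sum(d_in) == sum(d_out)}.  The
#' totals of a sampled sequence differ by an O(sqrt(N mu)) amount; this
#' helper removes the imbalance by repeatedly picking a uniformly random
#' node and nudging the deficient side by one unit, while keeping every
#' degree inside the truncation interval.  Marginal means move by at most
#' \code{|imbalance| / N}.
#'
#' @param pairs a \code{degree_pairs} object from
#'   \code{\link{sample_degree_pairs}}.
#' @return A balanced \code{degree_pairs} object.
#' @export
balance_totals <- function(pairs) {
  d_in <- pairs$d_in; d_out <- pairs$d_out
  lo <- pairs$spec$trunc[1]; hi <- pairs$spec$trunc[2]
  delta <- sum(d_in) - sum(d_out)
  while (delta != 0) {
    i <- sample.int(length(d_in), 1L)
    if (delta > 0) {
      # in-total too large: either decrement an in-degree or increment
      # an out-degree, chosen at random, bounds permitting
      if (stats::runif(1) < 0.5 && d_in[i] > lo) {
        d_in[i] <- d_in[i] - 1L; delta <- delta - 1L
      } else if (d_out[i] < hi) {
        d_out[i] <- d_out[i] + 1L; delta <- delta - 1L
      }
    } else {
      if (stats::runif(1) < 0.5 && d_out[i] > lo) {
        d_out[i] <- d_out[i] - 1L; delta <- delta + 1L
      } else if (d_in[i] < hi) {
        d_in[i] <- d_in[i] + 1L; delta <- delta + 1L
      }
    }
  }
  structure(list(d_in = d_in, d_out = d_out, spec = pairs$spec),
            class = "degree_pairs")
}

#' Realize a degree sequence with the configuration model
#'
#' Builds the list of out-stubs and the list of in-stubs implied by the
#' degree pairs, randomly permutes the in-stub list, and matches the k-th
#' out-stub to the k-th in-stub.  Stub matching can produce two
#' artifacts: self-pairings (both stubs on the same node) and duplicate
#' pairings (an ordered node pair drawn more than once).  The
#' corresponding links are removed, so realized degrees equal the
#' prescribed degrees minus removals.  Both artifact rates (as fractions
#' of all stub pairings) are recorded in \code{meta}.
#'
#' @param pairs balanced \code{degree_pairs}
#'   (see \code{\link{balance_totals}}).
#' @return A \code{\link{directed_network}} whose \code{meta} holds
#'   \code{self_fraction}, \code{multi_fraction}, \code{n_pairings} and
#'   the prescribed degrees.
#' @export
configuration_model <- function(pairs) {
  if (sum(pairs$d_in) != sum(pairs$d_out))
    stop("degree totals are unbalanced; call balance_totals() first")
  n <- length(pairs$d_in)
  out_stubs <- rep.int(seq_len(n), pairs$d_out)
  in_stubs <- rep.int(seq_len(n), pairs$d_in)
  in_stubs <- in_stubs[sample.int(length(in_stubs))]
  m <- length(out_stubs)
  self <- out_stubs == in_stubs
  key <- (as.numeric(out_stubs) - 1) * n + as.numeric(in_stubs)
  dup <- duplicated(key)
  keep <- !self & !dup
  w <- Matrix::sparseMatrix(i = in_stubs[keep], j = out_stubs[keep], x = 1,
                            dims = c(n, n))
  directed_network(w, kind = pairs$spec$kind,
                   meta = list(self_fraction = mean(self),
                               multi_fraction = mean(dup),
                               n_self = sum(self), n_multi = sum(dup),
                               n_removed = sum(self | dup),
                               n_pairings = m,
                               prescribed_in = pairs$d_in,
                               prescribed_out = pairs$d_out))
}

#' Erdos-Renyi directed network
#'
#' Each ordered pair (j -> i), i != j, is included independently with
#' probability \code{p}.  Both degree marginals are Binomial(N - 1, p),
#' so the relative spread sd/mean is approximately
#' \code{sqrt((1 - p) / (N p))}: tight for large networks, which is why
#' the bivariate-Gaussian ensembles are used when a broad degree
#' distribution is wanted.
#'
#' @param n_nodes number of nodes.
#' @param p connection probability in [0, 1].
#' @return A \code{\link{directed_network}} with \code{kind = "er"}.
#' @export
erdos_renyi <- function(n_nodes, p) {
  stopifnot(p >= 0, p <= 1)
  n <- as.integer(n_nodes)
  if (p == 0) {
    w <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n))
    return(directed_network(w, kind = "er"))
  }
  hit <- which(stats::runif(as.numeric(n) * n) < p)
  i <- ((hit - 1L) %% n) + 1L
  j <- ((hit - 1L) %/% n) + 1L
  keep <- i != j
  w <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1, dims = c(n, n))
  directed_network(w, kind = "er")
}

#' Generate a network of a given degree-correlation kind
#'
#' Convenience wrapper: samples degree pairs, balances the totals, and
#' runs the configuration model (or draws an Erdos-Renyi network for
#' \code{kind = "er"}).
#'
#' @param spec a \code{\link{degree_spec}}.
#' @return A \code{\link{directed_network}}.
#' @export
generate_network <- function(spec) {
  if (spec$kind == "er")
    return(erdos_renyi(spec$n_nodes, spec$p_c))
  configuration_model(balance_totals(sample_degree_pairs(spec)))
}
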