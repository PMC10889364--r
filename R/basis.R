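#' Gaussian radial-basis representation of the response interval
#'
#' Constructs the basis geometry used throughout the package: `n_elements`
#' Gaussian radial basis functions (RBFs) with centers spaced evenly across the
#' response interval `[0, interval_length]`. Each element has a temporal
#' receptive field of variance `basis_width_sq`; the temporal-generalization
#' (eligibility) function has variance `gen_width_sq`, equal to the basis width
#' by default. The interval is discretized into `bin_width`-second response
#' bins for the multinomial choice rule.
#'
#' When `basis_width_sq` is `NULL` (the default), the width is chosen by 1-D
#' root-finding so that two adjacent density-normalized elements share
#' `overlap_target` of their area (the shared area is the integral of the
#' pointwise minimum of the two densities). The default target of 0.5 yields
#' approximately 50% overlap between neighbours, which balances the locality
#' of credit assignment against generalization across nearby response times.
#'
#' Eligibility integrals are evaluated by fixed-grid trapezoidal quadrature on
#' `n_quad` points spanning the interval extended by four basis standard
#' deviations on either side. The extension keeps boundary elements
#' effectively untruncated, so that a response centered exactly on any element
#' attains eligibility 1 (a truncated integral over `[0, T]` would break this
#' identity for edge elements).
#'
#' @param n_elements Number of basis elements B (default 24).
#' @param interval_length Length T of the response interval in seconds
#'   (default 4).
#' @param bin_width Width of a discrete response bin in seconds (default 0.1,
#'   giving 40 bins on the default interval).
#' @param overlap_target Shared area between adjacent normalized elements used
#'   to select the basis width (default 0.5).
#' @param basis_width_sq Optional basis variance in seconds^2; overrides the
#'   overlap-based width selection.
#' @param gen_width_sq Optional variance of the temporal-generalization
#'   function; defaults to the basis variance.
#' @param n_quad Number of quadrature nodes for eligibility and overlap
#'   integrals (default 20001; accurate to well below 1e-6 for the default
#'   geometry).
#'
#' @return An object of class `basis_config`: a list with the geometry
#'   (`centers`, `basis_width_sq`, `gen_width_sq`, `n_bins`, `bin_centers`,
#'   ...) plus cached quadrature and bin-level basis matrices used internally.
#' @examples
#' cfg <- basis_config()
#' cfg$n_bins
#' range(eligibility(cfg, 2))
#' @export
basis_config <- function(n_elements = 24L,
                         interval_length = 4,
                         bin_width = 0.1,
                         overlap_target = 0.5,
                         basis_width_sq = NULL,
                         gen_width_sq = NULL,
                         n_quad = 20001L) {
  stopifnot(n_elements >= 2, interval_length > 0, bin_width > 0,
            overlap_target > 0, overlap_target < 1, n_quad >= 2000)
  centers <- seq(0, interval_length, length.out = n_elements)
  delta <- centers[2L] - centers[1L]

  if (is.null(basis_width_sq)) {
    s <- .solve_basis_width(delta, overlap_target)
    basis_width_sq <- s^2
  } else {
    if (basis_width_sq <= 0) stop("`basis_width_sq` must be positive")
    s <- sqrt(basis_width_sq)
  }
  if (is.null(gen_width_sq)) gen_width_sq <- basis_width_sq
  if (gen_width_sq <= 0) stop("`gen_width_sq` must be positive")

  n_bins <- as.integer(round(interval_length / bin_width))
  bin_centers <- (seq_len(n_bins) - 0.5) * bin_width

  # quadrature grid: interval extended 4 basis SDs on each side
  lo <- -4 * s
  hi <- interval_length + 4 * s
  tau <- seq(lo, hi, length.out = as.integer(n_quad))
  h <- tau[2L] - tau[1L]
  quad_w <- rep(h, length(tau))
  quad_w[c(1L, length(tau))] <- h / 2

  # density-normalized elements on the quadrature grid (n_quad x B)
  phi_quad <- vapply(centers, function(mu) stats::dnorm(tau, mu, s),
                     numeric(length(tau)))
  # unit-height elements at the response-bin centers (n_bins x B)
  phi_bins <- vapply(centers, function(mu) exp(-(bin_centers - mu)^2 /
                                                 (2 * basis_width_sq)),
                     numeric(n_bins))

  cfg <- structure(
    list(n_elements = as.integer(n_elements),
         interval_length = interval_length,
         centers = centers,
         basis_width_sq = basis_width_sq,
         gen_width_sq = gen_width_sq,
         bin_width = bin_width,
         n_bins = n_bins,
         bin_centers = bin_centers,
         overlap_target = overlap_target,
         n_quad = as.integer(n_quad),
         tau = tau,
         quad_w = quad_w,
         phi_quad = phi_quad,
         phi_bins = phi_bins),
    class = "basis_config")
  # eligibility evaluated once at every response-bin center (n_bins x B);
  # used by the simulation and likelihood loops
  cfg$elig_bins <- t(vapply(bin_centers, function(t0) eligibility(cfg, t0),
                            numeric(n_elements)))
  cfg
}

# default configs are reused heavily by the simulators; cache by interval
.cfg_cache <- new.env(parent = emptyenv())
.default_config <- function(interval_length = 4) {
  key <- sprintf("T=%.6g", interval_length)
  if (is.null(.cfg_cache[[key]])) {
    .cfg_cache[[key]] <- basis_config(interval_length = interval_length)
  }
  .cfg_cache[[key]]
}

# width such that the min-overlap of adjacent normalized elements hits the
# target; overlap is monotone increasing in s so uniroot is safe
.solve_basis_width <- function(delta, target) {
  f <- function(s) .gaussian_min_overlap(delta, s) - target
  stats::uniroot(f, lower = delta / 50, upper = 10 * delta,
                 tol = .Machine$double.eps^0.75)$root
}

# shared area between two equal-width normal densities delta apart, by dense
# trapezoidal quadrature over +/- 8 SD
.gaussian_min_overlap <- function(delta, s, n = 20001L) {
  tau <- seq(-8 * s, delta + 8 * s, length.out = n)
  f <- pmin(stats::dnorm(tau, 0, s), stats::dnorm(tau, delta, s))
  h <- tau[2L] - tau[1L]
  (sum(f) - (f[1L] + f[n]) / 2) * h
}

#' @export
print.basis_config <- function(x, ...) {
  cat("<basis_config>\n")
  cat(sprintf("  %d Gaussian elements on [0, %g] s (width^2 = %.5g s^2)\n",
              x$n_elements, x$interval_length, x$basis_width_sq))
  cat(sprintf("  %d response bins of %g s; generalization width^2 = %.5g\n",
              x$n_bins, x$bin_width, x$gen_width_sq))
  invisible(x)
}

#' Evaluate a single basis element
#'
#' Evaluates element `b` of the basis at time `x`, either in unit-height form
#' (`exp(-(x - mu_b)^2 / (2 s_b^2))`, maximum 1 at the center) or as a
#' probability density integrating to 1 over the real line.
#'
#' @param cfg A [basis_config()].
#' @param b Element index in `1:n_elements`.
#' @param x Time(s) in seconds within `[0, interval_length]`.
#' @param normalized If `TRUE`, return the density form; otherwise the
#'   unit-height form used for value evaluation.
#' @return Numeric vector of element values at `x`.
#' @export
basis_function <- function(cfg, b, x, normalized = FALSE) {
  stopifnot(inherits(cfg, "basis_config"))
  if (length(b) != 1L || b < 1L || b > cfg$n_elements) {
    stop("element index `b` out of range")
  }
  if (any(x < 0 | x > cfg$interval_length)) {
    stop("`x` must lie within [0, interval_length]")
  }
  if (normalized) {
    stats::dnorm(x, cfg$centers[b], sqrt(cfg$basis_width_sq))
  } else {
    exp(-(x - cfg$centers[b])^2 / (2 * cfg$basis_width_sq))
  }
}

#' Evaluate the learned value function on the response-bin grid
#'
#' The value of response bin j is the weighted sum of the unit-height basis
#' elements at the bin center: `V_j = sum_b w_b phi_b(x_j)`.
#'
#' @param cfg A [basis_config()].
#' @param weights Numeric weight vector of length `n_elements`.
#' @return Numeric vector of length `n_bins`.
#' @export
value_function <- function(cfg, weights) {
  stopifnot(inherits(cfg, "basis_config"))
  weights <- .check_weights(cfg, weights, allow_negative = TRUE)
  drop(cfg$phi_bins %*% weights)
}

#' Eligibility of each basis element for a response at time t
#'
#' The eligibility of element b is the shared area between the
#' temporal-generalization function (a Gaussian of variance `gen_width_sq`
#' centered on the response time) and the element's receptive field, both
#' taken as probability densities: `e_b = integral of min(g, phi_b)`. Each
#' eligibility lies in `[0, 1]`; with matching widths it reaches exactly 1
#' when the response falls on the element's center and decays toward 0 with
#' distance. The integral is evaluated by the fixed-grid quadrature cached in
#' `cfg`.
#'
#' @param cfg A [basis_config()].
#' @param t Response time in seconds, within `[0, interval_length]`.
#' @return Numeric vector of length `n_elements`, each entry in `[0, 1]`.
#' @export
eligibility <- function(cfg, t) {
  stopifnot(inherits(cfg, "basis_config"), length(t) == 1L)
  if (t < 0 || t > cfg$interval_length) {
    stop("`t` must lie within [0, interval_length]")
  }
  g <- stats::dnorm(cfg$tau, t, sqrt(cfg$gen_width_sq))
  e <- drop(crossprod(cfg$quad_w, pmin(cfg$phi_quad, g)))
  pmin(pmax(e, 0), 1)
}

#' Shannon entropy (log10) of a nonnegative weight vector
#'
#' Weights are normalized to sum to 1 for this computation only; terms with
#' zero weight contribute 0. An all-zero vector carries no evidence and is
#' assigned the maximum entropy `log10(B)`, the entropy of a uniform
#' distribution over the B elements. Entropy is invariant to positive
#' rescaling of the weights.
#'
#' @param weights Nonnegative numeric vector (negative entries are an error).
#' @return Entropy in log10 units, in `[0, log10(length(weights))]`.
#' @examples
#' value_entropy(rep(1, 24))  # log10(24)
#' value_entropy(c(1, rep(0, 23)))  # 0
#' @export
value_entropy <- function(weights) {
  if (!is.numeric(weights) || length(weights) < 1L) {
    stop("`weights` must be a numeric vector")
  }
  if (any(!is.finite(weights))) stop("`weights` must be finite")
  if (any(weights < 0)) stop("`weights` must be nonnegative")
  s <- sum(weights)
  if (s == 0) return(log10(length(weights)))
  p <- weights / s
  p <- p[p > 0]
  -sum(p * log10(p))
}

#' Response time of the learned value maximum (RT_Vmax)
#'
#' Returns the bin-center time at which the value function attains its global
#' maximum. Ties are broken toward the earliest bin.
#'
#' @inheritParams value_function
#' @return Time in seconds.
#' @export
rt_vmax <- function(cfg, weights) {
  v <- value_function(cfg, weights)
  cfg$bin_centers[which.max(v)]
}

.check_weights <- function(cfg, weights, allow_negative = FALSE) {
  if (length(weights) != cfg$n_elements) {
    stop(sprintf("`weights` must have length %d", cfg$n_elements))
  }
  if (any(!is.finite(weights))) stop("`weights` must be finite")
  if (!allow_negative && any(weights < 0)) stop("`weights` must be nonnegative")
  as.numeric(weights)
}
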