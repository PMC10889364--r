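#' Working-memory comparator with a selection-history buffer
#'
#' `wm_state()` creates the state of the working-memory (WM) comparator
#' model: a buffer of the last `k` response times (the selection history) and
#' a parallel buffer of the last `k` reward/omission flags (the outcome
#' history). The model shares the radial-basis representation: the buffered
#' response times are turned into a selection-history function `s(x)`, the
#' sum of unit-height Gaussians of variance `gen_width_sq` centered on each
#' buffered RT, and the WM basis weights are the integrals
#' `w_b = integral of s(tau) * phi_b(tau)` with `phi_b` density-normalized.
#' Each buffered response therefore contributes at most 1 to any weight, so
#' the weights are bounded by `k`. The model has no free parameters.
#'
#' @param cfg A [basis_config()].
#' @param k Buffer capacity (default 4, the empirically supported depth of
#'   the outcome buffer).
#' @return An object of class `wm_state` with fields `rt_buffer`,
#'   `outcome_buffer` and `wm_weights`.
#' @export
wm_state <- function(cfg, k = 4L) {
  stopifnot(inherits(cfg, "basis_config"), k >= 1)
  structure(list(cfg = cfg, k = as.integer(k),
                 rt_buffer = numeric(0), outcome_buffer = integer(0),
                 wm_weights = rep(0, cfg$n_elements)),
            class = "wm_state")
}

#' @export
print.wm_state <- function(x, ...) {
  cat(sprintf("<wm_state> k = %d, %d buffered trials\n",
              x$k, length(x$rt_buffer)))
  invisible(x)
}

#' Push a trial into the working-memory buffers
#'
#' Appends the response time and outcome flag to the buffers (evicting the
#' oldest entry at capacity `k`) and rebuilds the selection-history function
#' and WM weights.
#'
#' @param wm A [wm_state()].
#' @param rt Response time in seconds.
#' @param rewarded 1 for reward, 0 for omission.
#' @return The updated `wm_state`.
#' @export
wm_update <- function(wm, rt, rewarded) {
  stopifnot(inherits(wm, "wm_state"))
  cfg <- wm$cfg
  if (rt < 0 || rt > cfg$interval_length) {
    stop("`rt` must lie within [0, interval_length]")
  }
  wm$rt_buffer <- utils::tail(c(wm$rt_buffer, rt), wm$k)
  wm$outcome_buffer <- utils::tail(c(wm$outcome_buffer, as.integer(rewarded)),
                                   wm$k)
  wm$wm_weights <- .wm_weights(cfg, wm$rt_buffer)
  wm
}

# WM weights = integral of the selection-history function (sum of unit-height
# Gaussians at the buffered RTs) times each density-normalized element
.wm_weights <- function(cfg, rts) {
  if (length(rts) == 0L) return(rep(0, cfg$n_elements))
  sg <- sqrt(cfg$gen_width_sq)
  s_tau <- rowSums(vapply(rts,
                          function(t0) exp(-(cfg$tau - t0)^2 /
                                             (2 * cfg$gen_width_sq)),
                          numeric(length(cfg$tau))))
  drop(crossprod(cfg$quad_w * s_tau, cfg$phi_quad))
}

#' Total working-memory entropy
#'
#' The information content of the WM comparator is the joint entropy of its
#' two normalized buffers: `H_total = H(normalized WM weights) + H(normalized
#' outcome vector)`, each computed as in [value_entropy()] except that an
#' all-zero or empty buffer contributes 0 (an empty buffer holds no
#' competing items, unlike an uninformed value map).
#'
#' @param wm A [wm_state()].
#' @return Total entropy in log10 units.
#' @examples
#' cfg <- basis_config()
#' wm <- wm_state(cfg)
#' wm <- wm_update(wm, 1.5, 1)
#' wm_entropy(wm)
#' @export
wm_entropy <- function(wm) {
  stopifnot(inherits(wm, "wm_state"))
  h_w <- .buffer_entropy(wm$wm_weights)
  h_o <- .buffer_entropy(as.numeric(wm$outcome_buffer))
  h_w + h_o
}

# entropy of a normalized buffer; empty/all-zero buffers carry no items and
# contribute 0 (contrast with value_entropy, where zero evidence means a
# uniform prior)
.buffer_entropy <- function(x) {
  if (length(x) == 0L || sum(x) == 0) return(0)
  if (any(x < 0)) stop("buffer entries must be nonnegative")
  p <- x / sum(x)
  p <- p[p > 0]
  -sum(p * log10(p))
}
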