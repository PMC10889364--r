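#' Agent parameters
#'
#' Bundles the free parameters of the learning models: learning rate `alpha`
#' in (0, 1), softmax temperature `beta` > 0 (choices become more stochastic
#' at higher `beta`), selective-maintenance rate `gamma` in \[0, 1\] scaling
#' the decay of ineligible elements toward the prior point `h` (0 by default,
#' i.e. full forgetting of unchosen options' values).
#'
#' @param alpha Learning rate, in (0, 1).
#' @param beta Softmax temperature, > 0.
#' @param gamma Selective-maintenance (decay) parameter in \[0, 1\]. `gamma = 0`
#'   reduces the selective rule to traditional full-maintenance RL.
#' @param h Decay target in points (default 0).
#' @return An object of class `agent_params`.
#' @examples
#' agent_params(alpha = 0.1, beta = 20, gamma = 0.3)
#' @export
agent_params <- function(alpha, beta, gamma = 0, h = 0) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)")
  }
  if (!is.numeric(beta) || beta <= 0) stop("`beta` must be positive")
  if (!is.numeric(gamma) || gamma < 0 || gamma > 1) {
    stop("`gamma` must lie in [0, 1]")
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma, h = h),
            class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf("<agent_params> alpha = %.4g, beta = %.4g, gamma = %.4g, h = %g\n",
              x$alpha, x$beta, x$gamma, x$h))
  invisible(x)
}

#' Learning-rule weight updates
#'
#' `update_traditional()` applies the full-maintenance delta rule: each
#' element's weight moves toward the obtained reward in proportion to its
#' eligibility and the learning rate,
#' `w_b <- w_b + e_b * alpha * (reward - w_b)`. Elements with zero
#' eligibility are untouched, so values of unchosen response times persist
#' indefinitely.
#'
#' `update_selective()` adds information-compressing selective maintenance:
#' on top of the delta rule, every weight decays toward the prior point `h`
#' in inverse proportion to its eligibility,
#' `w_b <- w_b + e_b * alpha * (reward - w_b) - gamma * (1 - e_b) * (w_b - h)`.
#' Weights of spatiotemporally distant (ineligible) elements revert toward
#' `h`, compressing the value map around preferred response times. With
#' `gamma = 0` the two rules coincide exactly.
#'
#' @param cfg A [basis_config()].
#' @param weights Current weight vector (length `n_elements`).
#' @param params An [agent_params()].
#' @param rt Response time in seconds.
#' @param reward Obtained reward in points (0 on omission).
#' @param elig Optional precomputed eligibility vector for `rt`; computed via
#'   [eligibility()] when missing.
#' @return The updated weight vector.
#' @export
update_traditional <- function(cfg, weights, params, rt, reward, elig = NULL) {
  weights <- .check_weights(cfg, weights, allow_negative = TRUE)
  if (is.null(elig)) elig <- eligibility(cfg, rt)
  weights + elig * params$alpha * (reward - weights)
}

#' @rdname update_traditional
#' @export
update_selective <- function(cfg, weights, params, rt, reward, elig = NULL) {
  weights <- .check_weights(cfg, weights, allow_negative = TRUE)
  if (is.null(elig)) elig <- eligibility(cfg, rt)
  weights + elig * params$alpha * (reward - weights) -
    params$gamma * (1 - elig) * (weights - params$h)
}

#' Softmax choice probabilities over response bins
#'
#' Converts the value function into a multinomial choice distribution over
#' the response bins: `p_j` is proportional to `exp(V_j / beta)`. The maximum
#' is subtracted before exponentiation for numerical stability, which leaves
#' the probabilities unchanged (the rule is invariant to adding a constant to
#' V).
#'
#' @inheritParams update_traditional
#' @return Probability vector of length `n_bins`, summing to 1.
#' @export
choice_probabilities <- function(cfg, weights, params) {
  v <- value_function(cfg, weights)
  softmax(v, params$beta)
}

#' @rdname choice_probabilities
#' @param v Numeric vector of values.
#' @param beta Temperature, > 0.
#' @export
softmax <- function(v, beta) {
  if (any(!is.finite(v))) stop("values must be finite")
  if (beta <= 0) stop("`beta` must be positive")
  z <- v / beta
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Simulate an agent on the clock task
#'
#' Runs the closed simulation loop for `n_trials` trials: on each trial the
#' agent computes its value function from the current weights, samples a
#' response bin from the softmax policy, receives a probabilistic outcome
#' from the contingency (reward with probability `p(rt)`, magnitude `m(rt)`,
#' zero on omission), and updates its weights under the requested learning
#' rule. Pre-update entropy `H` is aligned with the decision phase; the
#' entropy change `dH = H_after - H_before` produced by the feedback-driven
#' update is aligned with feedback.
#'
#' @param cfg A [basis_config()].
#' @param params An [agent_params()].
#' @param env A `contingency` (see [make_contingency()]) or a list of
#'   contingencies of length `n_trials` (one per trial, supporting mid-run
#'   reversals).
#' @param n_trials Number of trials to simulate.
#' @param rule `"selective"` (information-compressing) or `"traditional"`
#'   (full maintenance).
#' @param seed Optional integer seed for reproducibility.
#' @param init Initial weights: `"uniform"` draws each weight uniformly on
#'   `[0, w0]` (random uniform prior); `"zero"` starts all weights at 0.
#' @param w0 Upper bound of the uniform initial weights (default 1 point).
#' @param weights Optional explicit initial weight vector overriding `init`.
#' @return A tibble of class `sceptic_sim` with one row per trial: `trial`,
#'   `contingency`, `rt`, `rt_bin` (0-based), `rewarded`, `reward`,
#'   `entropy`, `entropy_change`, `rt_vmax`, `v_max`, `v_chosen`, `pe`. The
#'   trial-by-element weight trajectory (weights before each trial's update,
#'   plus the final row) is attached as attribute `"weights"`, and the final
#'   weight vector as `"final_weights"`.
#' @export
run_agent <- function(cfg, params, env, n_trials,
                      rule = c("selective", "traditional"),
                      seed = NULL,
                      init = c("uniform", "zero"),
                      w0 = 1,
                      weights = NULL) {
  rule <- match.arg(rule)
  init <- match.arg(init)
  stopifnot(inherits(cfg, "basis_config"), inherits(params, "agent_params"),
            n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  env <- .as_trial_envs(env, n_trials)

  if (is.null(weights)) {
    weights <- switch(init,
                      uniform = stats::runif(cfg$n_elements, 0, w0),
                      zero = rep(0, cfg$n_elements))
  } else {
    weights <- .check_weights(cfg, weights)
  }

  gamma <- if (rule == "selective") params$gamma else 0
  n_bins <- cfg$n_bins
  out <- tibble::tibble(
    trial = seq_len(n_trials),
    contingency = vapply(env, function(cc) cc$label, character(1)),
    rt = NA_real_, rt_bin = NA_integer_, rewarded = NA_integer_,
    reward = NA_real_, entropy = NA_real_, entropy_change = NA_real_,
    rt_vmax = NA_real_, v_max = NA_real_, v_chosen = NA_real_, pe = NA_real_)
  w_trace <- matrix(NA_real_, n_trials + 1L, cfg$n_elements)

  for (i in seq_len(n_trials)) {
    w_trace[i, ] <- weights
    v <- drop(cfg$phi_bins %*% weights)
    p <- softmax(v, params$beta)
    h_before <- value_entropy(weights)
    j <- sample.int(n_bins, 1L, prob = p)          # 1-based bin
    rt <- cfg$bin_centers[j]
    cc <- env[[i]]
    rewarded <- stats::rbinom(1L, 1L, cc$p(rt))
    reward <- if (rewarded == 1L) cc$m(rt) else 0
    elig <- cfg$elig_bins[j, ]
    pe <- reward - v[j]
    weights <- weights + elig * params$alpha * (reward - weights) -
      gamma * (1 - elig) * (weights - params$h)
    h_after <- value_entropy(weights)
    jmax <- which.max(v)
    out$rt[i] <- rt
    out$rt_bin[i] <- j - 1L
    out$rewarded[i] <- rewarded
    out$reward[i] <- reward
    out$entropy[i] <- h_before
    out$entropy_change[i] <- h_after - h_before
    out$rt_vmax[i] <- cfg$bin_centers[jmax]
    out$v_max[i] <- v[jmax]
    out$v_chosen[i] <- v[j]
    out$pe[i] <- pe
  }
  w_trace[n_trials + 1L, ] <- weights
  attr(out, "weights") <- w_trace
  attr(out, "final_weights") <- weights
  class(out) <- c("sceptic_sim", class(out))
  out
}

#' Replay a fixed choice/outcome sequence through a learning rule
#'
#' Deterministically recomputes the latent trajectory (weights, value
#' function, entropy, entropy change, RT_Vmax, prediction error) implied by a
#' given sequence of response times and rewards, without any sampling. This
#' is the reference R implementation of the update loop; the fitting code
#' uses a compiled equivalent.
#'
#' @inheritParams run_agent
#' @param rt Numeric vector of response times in seconds.
#' @param reward Numeric vector of obtained rewards (same length as `rt`).
#' @param weights Initial weight vector (default all zero).
#' @return A tibble with per-trial latents (as in [run_agent()]); the
#'   trial-by-bin value-function matrix (pre-choice) is attached as attribute
#'   `"values"` and the weight trajectory as `"weights"`.
#' @export
replay_agent <- function(cfg, params, rt, reward,
                         rule = c("selective", "traditional"),
                         weights = NULL) {
  rule <- match.arg(rule)
  stopifnot(length(rt) == length(reward), all(rt >= 0),
            all(rt <= cfg$interval_length))
  n <- length(rt)
  if (is.null(weights)) weights <- rep(0, cfg$n_elements)
  weights <- .check_weights(cfg, weights, allow_negative = TRUE)
  gamma <- if (rule == "selective") params$gamma else 0
  bins <- rt_to_bin(cfg, rt)                        # 0-based

  vals <- matrix(NA_real_, n, cfg$n_bins)
  w_trace <- matrix(NA_real_, n + 1L, cfg$n_elements)
  out <- tibble::tibble(
    trial = seq_len(n), rt = rt, rt_bin = bins, reward = reward,
    entropy = NA_real_, entropy_change = NA_real_, rt_vmax = NA_real_,
    v_max = NA_real_, v_chosen = NA_real_, pe = NA_real_)

  for (i in seq_len(n)) {
    w_trace[i, ] <- weights
    v <- drop(cfg$phi_bins %*% weights)
    vals[i, ] <- v
    j <- bins[i] + 1L
    h_before <- value_entropy(weights)
    elig <- cfg$elig_bins[j, ]
    pe <- reward[i] - v[j]
    weights <- weights + elig * params$alpha * (reward[i] - weights) -
      gamma * (1 - elig) * (weights - params$h)
    h_after <- value_entropy(weights)
    jmax <- which.max(v)
    out$entropy[i] <- h_before
    out$entropy_change[i] <- h_after - h_before
    out$rt_vmax[i] <- cfg$bin_centers[jmax]
    out$v_max[i] <- v[jmax]
    out$v_chosen[i] <- v[j]
    out$pe[i] <- pe
  }
  w_trace[n + 1L, ] <- weights
  attr(out, "values") <- vals
  attr(out, "weights") <- w_trace
  out
}

#' Map continuous response times to 0-based response bins
#'
#' `floor(rt / bin_width)`, clamped to `[0, n_bins - 1]` so that a response
#' exactly at the end of the interval falls in the last bin.
#'
#' @inheritParams value_function
#' @param rt Response times in seconds.
#' @return Integer vector of 0-based bin indices.
#' @export
rt_to_bin <- function(cfg, rt) {
  b <- as.integer(floor(rt / cfg$bin_width + 1e-9))
  pmin(pmax(b, 0L), cfg$n_bins - 1L)
}

# normalize env argument to a list of per-trial contingencies
.as_trial_envs <- function(env, n_trials) {
  if (inherits(env, "contingency")) {
    rep(list(env), n_trials)
  } else if (is.list(env) && all(vapply(env, inherits, logical(1),
                                        "contingency"))) {
    if (length(env) != n_trials) {
      stop("`env` list must have one contingency per trial")
    }
    env
  } else {
    stop("`env` must be a contingency or a list of contingencies")
  }
}
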