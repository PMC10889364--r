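#' Default effect map for synthetic neural responses
#'
#' A convenience effect map with a single entropy-change effect: a Gaussian
#' bump of height `amplitude` peaking `peak` seconds after feedback, with SD
#' `width` seconds. Effect maps are tibbles with columns `signal` (a column
#' name in the trial log), `time` (seconds relative to feedback onset) and
#' `beta` (response units per signal unit), evaluated on the epoch grid.
#'
#' @param times Time grid (seconds relative to feedback onset).
#' @param signal Trial-log column the effect is tied to.
#' @param amplitude Peak effect size.
#' @param peak Peak time in seconds.
#' @param width SD of the effect curve in seconds.
#' @return An effect-map tibble.
#' @export
effect_map_bump <- function(times = seq(-4, 4, by = 1),
                            signal = "entropy_change",
                            amplitude = 1, peak = 1, width = 1.5) {
  tibble::tibble(signal = signal, time = times,
                 beta = amplitude * exp(-(times - peak)^2 / (2 * width^2)))
}

#' Synthesize trial-aligned neural response series
#'
#' Emulates deconvolved, feedback-aligned neural activity for every trial in
#' a cohort log: for each trial and each epoch time point,
#' `response = sum_signals beta(signal, time) * signal(trial) +
#' subject intercept + noise`. Signals are taken from columns of the log
#' (e.g. `entropy_change`, `entropy`, `reward`, `v_max`, `pe`); each
#' signal is z-scored across trials before weighting so that effect
#' amplitudes are comparable across signals. Subject random intercepts are
#' drawn once per subject (`SD = intercept_sd`) and Gaussian noise of SD
#' `noise_sd` is added per cell.
#'
#' @param log Trial log with a `subject`, `trial` and the signal columns
#'   named by `effect_map`.
#' @param effect_map Tibble with columns `signal`, `time`, `beta` (see
#'   [effect_map_bump()]); may contain several signals. May be `NULL` for
#'   pure-noise responses.
#' @param noise_sd Gaussian noise SD (response units).
#' @param seed Optional integer seed.
#' @param times Epoch grid in seconds relative to feedback onset.
#' @param intercept_sd SD of the subject random intercepts (default 0.5).
#' @param scale_signals If `TRUE` (default), z-score each signal across the
#'   log before applying the effect curve.
#' @return A long tibble (`subject`, `trial`, `time`, `response`) with the
#'   generating effect map attached as attribute `"effect_map"` and the
#'   subject intercepts as `"intercepts"`.
#' @export
synth_neural <- function(log, effect_map = effect_map_bump(),
                         noise_sd = 0.5, seed = NULL,
                         times = seq(-4, 4, by = 1),
                         intercept_sd = 0.5,
                         scale_signals = TRUE) {
  stopifnot(is.data.frame(log), all(c("subject", "trial") %in% names(log)))
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(effect_map)) {
    missing_sig <- setdiff(unique(effect_map$signal), names(log))
    if (length(missing_sig)) {
      stop("log lacks signal column(s): ", paste(missing_sig, collapse = ", "))
    }
  }

  n_trials <- nrow(log)
  subjects <- unique(log$subject)
  intercepts <- stats::rnorm(length(subjects), 0, intercept_sd)
  names(intercepts) <- subjects

  grid <- tidyr::expand_grid(
    log[c("subject", "trial")],
    time = times)
  mu <- rep(0, nrow(grid))
  if (!is.null(effect_map)) {
    for (sig in unique(effect_map$signal)) {
      x <- log[[sig]]
      if (scale_signals) {
        sdx <- stats::sd(x)
        x <- if (is.na(sdx) || sdx == 0) x - mean(x) else (x - mean(x)) / sdx
      }
      curve <- effect_map[effect_map$signal == sig, ]
      beta_at <- stats::approx(curve$time, curve$beta, xout = times,
                               rule = 2)$y
      mu <- mu + rep(x, each = length(times)) *
        beta_at[match(grid$time, times)]
    }
  }
  grid$response <- mu + intercepts[grid$subject] +
    stats::rnorm(nrow(grid), 0, noise_sd)
  attr(grid, "effect_map") <- effect_map
  attr(grid, "intercepts") <- intercepts
  grid
}
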