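#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities, peak-normalized to 1: a positive lobe
#' peaking at `peak_delay` seconds and an undershoot peaking at
#' `undershoot_delay` seconds with relative amplitude `undershoot_ratio`.
#' The shape parameters are conventional implementation defaults.
#'
#' @param t Time(s) in seconds since event onset (>= 0).
#' @param peak_delay Mode of the positive lobe in seconds (default 6).
#' @param undershoot_delay Mode of the undershoot in seconds (default 16).
#' @param undershoot_ratio Undershoot amplitude relative to the peak lobe
#'   (default 1/6).
#' @return HRF amplitude(s); maximum 1 on a dense grid.
#' @export
hrf <- function(t, peak_delay = 6, undershoot_delay = 16,
                undershoot_ratio = 1 / 6) {
  if (any(t < 0)) stop("`t` must be nonnegative")
  raw <- function(x) {
    stats::dgamma(x, shape = peak_delay + 1, rate = 1) -
      undershoot_ratio * stats::dgamma(x, shape = undershoot_delay + 1,
                                       rate = 1)
  }
  tt <- seq(0, 50, by = 0.01)
  raw(t) / max(raw(tt))
}

# sample the HRF kernel on a dt grid (32-s support)
.hrf_kernel <- function(dt, ...) hrf(seq(0, 32, by = dt), ...)

.check_events <- function(events) {
  stopifnot(is.data.frame(events),
            all(c("onset", "duration") %in% names(events)))
  ord <- order(events$onset)
  events <- events[ord, ]
  if (nrow(events) > 1L) {
    gap <- events$onset[-1L] - (events$onset[-nrow(events)] +
                                  events$duration[-nrow(events)])
    if (any(gap < -1e-9)) stop("overlapping events are not allowed")
  }
  events
}

#' Build an event regressor on a sampling grid
#'
#' Places a unit-height boxcar over each event's duration, scales it by the
#' event's (optionally mean-centered) parametric value, optionally convolves
#' the resulting stick series with the canonical HRF, and samples the result
#' on `grid` (e.g. the TR grid of a scan). Events must not overlap.
#'
#' @param events Tibble with columns `onset`, `duration` (seconds) and
#'   optionally `value` (parametric modulation; defaults to 1).
#' @param grid Output sampling times in seconds.
#' @param convolve Convolve with the HRF (default `TRUE`).
#' @param center Mean-center the parametric values before scaling (default
#'   `TRUE` when a `value` column is present).
#' @param dt Internal sampling resolution in seconds (default 0.05).
#' @param ... Passed to [hrf()].
#' @return Numeric vector of regressor values on `grid`.
#' @export
event_regressor <- function(events, grid, convolve = TRUE, center = TRUE,
                            dt = 0.05, ...) {
  events <- .check_events(events)
  values <- events$value %||% rep(1, nrow(events))
  if (center && !is.null(events$value)) values <- values - mean(values)

  tmax <- max(grid, events$onset + events$duration) + 33
  tt <- seq(0, tmax, by = dt)
  x <- rep(0, length(tt))
  for (i in seq_len(nrow(events))) {
    on <- tt >= events$onset[i] & tt < events$onset[i] + events$duration[i]
    x[on] <- x[on] + values[i]
  }
  if (convolve) {
    k <- .hrf_kernel(dt, ...)
    x <- stats::convolve(x, rev(k), type = "open")[seq_along(tt)] * dt
  }
  stats::approx(tt, x, xout = grid, rule = 2)$y
}

#' Peak-renormalized parametric regressor
#'
#' For decision-phase regressors whose events vary in duration, the height
#' of a convolved duration-modulated boxcar confounds event duration with
#' the parametric signal. This constructor decouples them: for each trial, a
#' unit-height boxcar over the trial's duration is convolved with the HRF
#' and its peak renormalized to 1; the renormalized curve is multiplied by
#' that trial's signal value, and the per-trial curves are summed into a
#' single regressor. Trials with very different durations but equal signal
#' values thus contribute equal peak heights.
#'
#' @param events Tibble with `onset`, `duration` and `value` (one signal
#'   value per event; mean-center beforehand if desired).
#' @inheritParams event_regressor
#' @return Numeric vector of regressor values on `grid`.
#' @export
peak_renormalized_regressor <- function(events, grid, dt = 0.05, ...) {
  events <- .check_events(events)
  if (is.null(events$value)) stop("`events` must carry a `value` column")
  tmax <- max(grid, events$onset + events$duration) + 33
  tt <- seq(0, tmax, by = dt)
  k <- .hrf_kernel(dt, ...)
  out <- rep(0, length(tt))
  for (i in seq_len(nrow(events))) {
    x <- as.numeric(tt >= events$onset[i] &
                      tt < events$onset[i] + events$duration[i])
    ci <- stats::convolve(x, rev(k), type = "open")[seq_along(tt)] * dt
    pk <- max(ci)
    if (pk <= 0) stop("degenerate event with zero convolved peak")
    out <- out + ci / pk * events$value[i]
  }
  stats::approx(tt, out, xout = grid, rule = 2)$y
}

#' Temporal high-pass filter
#'
#' Removes slow drifts below `cutoff_hz`. The default method is a
#' Gaussian-weighted running-line detrend: at each time point a local linear
#' trend, estimated with Gaussian weights of SD `1 / (2 * cutoff_hz)`
#' seconds, is subtracted, so a constant (or slowly drifting) series maps to
#' approximately zero while high-frequency content passes essentially
#' unattenuated. The same operator must be applied to data and design
#' regressors. A Butterworth alternative (via the `signal` package) is
#' available behind `method = "butterworth"`.
#'
#' @param x Numeric series, uniformly sampled.
#' @param tr Sampling interval in seconds.
#' @param cutoff_hz High-pass cutoff in Hz (default 0.008).
#' @param method `"gaussian"` (running-line) or `"butterworth"`.
#' @return Filtered series of the same length.
#' @export
highpass <- function(x, tr, cutoff_hz = 0.008,
                     method = c("gaussian", "butterworth")) {
  method <- match.arg(method)
  stopifnot(is.numeric(x), tr > 0, cutoff_hz > 0)
  n <- length(x)
  sigma_sec <- 1 / (2 * cutoff_hz)
  if (n * tr < sigma_sec) {
    stop("series shorter than the filter window (",
         round(sigma_sec), " s)")
  }
  if (method == "butterworth") {
    if (!requireNamespace("signal", quietly = TRUE)) {
      stop("`method = \"butterworth\"` requires the signal package")
    }
    bf <- signal::butter(2, 2 * cutoff_hz * tr, type = "high")
    return(as.numeric(signal::filtfilt(bf, x - mean(x))))
  }
  tt <- seq_len(n) * tr
  sigma <- sigma_sec
  fitted <- vapply(seq_len(n), function(i) {
    w <- stats::dnorm(tt - tt[i], 0, sigma)
    sw <- sum(w)
    xm <- sum(w * tt) / sw
    ym <- sum(w * x) / sw
    sxx <- sum(w * (tt - xm)^2)
    b <- if (sxx > 0) sum(w * (tt - xm) * (x - ym)) / sxx else 0
    ym + b * (tt[i] - xm)
  }, numeric(1))
  x - fitted
}

#' Epoch a continuous series around feedback onsets
#'
#' Extracts, for each trial, the signal surrounding feedback onset on an
#' evenly spaced grid (`window` at TR spacing) anchored at the onset, using
#' linear interpolation (no resampling in the time domain beyond grid
#' alignment: values at existing sample times are returned exactly). Grid
#' cells whose absolute time falls outside the trial's own span — i.e.
#' overlapping the previous or next trial — are marked invalid, as are cells
#' outside the series.
#'
#' @param series Tibble with columns `time` and `value` (one run's signal),
#'   or a numeric vector sampled at `tr` starting at time 0.
#' @param onsets Feedback onset times in seconds (one per trial).
#' @param tr Grid spacing in seconds.
#' @param window Epoch window around onset, `c(min, max)` seconds (default
#'   `c(-4, 4)`).
#' @param trial_start,trial_end Span of each trial in seconds (same length
#'   as `onsets`); cells outside `[trial_start, trial_end)` are masked.
#'   Defaults to unbounded spans (series-range masking only).
#' @return A tibble of class `epoched_signal`: `trial`, `rel_time`, `time`,
#'   `value`, `valid`.
#' @export
epoch_feedback <- function(series, onsets, tr, window = c(-4, 4),
                           trial_start = NULL, trial_end = NULL) {
  if (is.numeric(series) && is.null(dim(series))) {
    series <- tibble::tibble(time = (seq_along(series) - 1) * tr,
                             value = series)
  }
  stopifnot(is.data.frame(series),
            all(c("time", "value") %in% names(series)))
  n <- length(onsets)
  if (any(onsets < min(series$time) | onsets > max(series$time))) {
    stop("feedback onset outside the series")
  }
  trial_start <- trial_start %||% rep(-Inf, n)
  trial_end <- trial_end %||% rep(Inf, n)
  stopifnot(length(trial_start) == n, length(trial_end) == n)

  rel <- seq(window[1L], window[2L], by = tr)
  out <- tidyr::expand_grid(trial = seq_len(n), rel_time = rel)
  out$time <- onsets[out$trial] + out$rel_time
  in_series <- out$time >= min(series$time) & out$time <= max(series$time)
  out$value <- NA_real_
  out$value[in_series] <- stats::approx(series$time, series$value,
                                        xout = out$time[in_series])$y
  out$valid <- in_series &
    out$time >= trial_start[out$trial] &
    out$time < trial_end[out$trial]
  class(out) <- c("epoched_signal", class(out))
  out
}

#' Stack epoched neural data with model-derived covariates
#'
#' Builds the engine-agnostic analysis tables for neural model comparison:
#' for each candidate model, the trial-aligned neural responses are joined
#' (by subject and trial) with that model's latent signals (`entropy`,
#' `entropy_change`) and the shared behavioral covariates, and the per-model
#' tables are stacked with a `model` column. Only the model-derived columns
#' differ between the stacked blocks. Mixed-model estimation itself is
#' delegated to external engines; [neural_model_aic()] provides a simple
#' per-time AIC bookkeeping hook, and [by_adjust()] the Benjamini-Yekutieli
#' correction for the resulting dependent p-value sets.
#'
#' @param epochs Long tibble of neural responses with columns `subject`,
#'   `trial`, `time`, `response` (e.g. from [synth_neural()], or an
#'   [epoch_feedback()] table joined across subjects); an optional `region`
#'   column is carried through.
#' @param model_logs Named list of trial logs, one per candidate model, each
#'   with `subject`, `trial`, `entropy` and `entropy_change` columns (e.g.
#'   from [refit_at_group_means()] under each rule).
#' @param covariates Character vector of shared covariate columns to carry
#'   from the first log (defaults to those present among `rt`, `v_max`,
#'   `pe`, `rewarded`, `reward`).
#' @return A tibble with one row per (model, response cell).
#' @export
model_comparison_dataset <- function(epochs, model_logs,
                                     covariates = NULL) {
  stopifnot(is.data.frame(epochs),
            all(c("subject", "trial", "time", "response") %in%
                  names(epochs)),
            is.list(model_logs), length(model_logs) >= 1L,
            !is.null(names(model_logs)))
  first <- model_logs[[1L]]
  covariates <- covariates %||%
    intersect(c("rt", "v_max", "pe", "rewarded", "reward"), names(first))
  for (nm in names(model_logs)) {
    lg <- model_logs[[nm]]
    if (!all(c("subject", "trial", "entropy", "entropy_change") %in%
             names(lg))) {
      stop("model log '", nm,
           "' must contain subject, trial, entropy, entropy_change")
    }
    if (!all(paste(epochs$subject, epochs$trial) %in%
             paste(lg$subject, lg$trial))) {
      stop("epochs contain trials missing from model log '", nm, "'")
    }
  }
  shared <- dplyr::select(first, "subject", "trial",
                          dplyr::all_of(covariates))
  purrr::imap(model_logs, function(lg, nm) {
    mdl <- dplyr::select(lg, "subject", "trial", "entropy",
                         "entropy_change")
    epochs |>
      dplyr::inner_join(shared, by = c("subject", "trial")) |>
      dplyr::inner_join(mdl, by = c("subject", "trial")) |>
      dplyr::mutate(model = nm)
  }) |>
    dplyr::bind_rows() |>
    dplyr::relocate("model")
}

#' Per-time AIC bookkeeping for neural model comparison
#'
#' For each candidate model (and each time point and region, when present),
#' fits a fixed-effects linear model of the neural response on the model's
#' signal columns plus covariates and a subject intercept, and tabulates the
#' AIC. Summing AIC across time points gives the global model-selection
#' score: the model with the lowest summed AIC best accounts for the
#' event-aligned activity.
#'
#' @param data A [model_comparison_dataset()] table.
#' @param predictors Model-derived predictor columns (default
#'   `"entropy_change"`).
#' @param covariates Additional covariate columns (default: none beyond the
#'   subject intercept).
#' @return A list with `per_time` (tibble: model, time, region if any, aic)
#'   and `summary` (tibble: model, aic, delta_aic; lower is better,
#'   `delta_aic = 0` marks the selected model).
#' @export
neural_model_aic <- function(data, predictors = "entropy_change",
                             covariates = character(0)) {
  stopifnot(is.data.frame(data),
            all(c("model", "response", "time", "subject") %in% names(data)),
            all(predictors %in% names(data)),
            all(covariates %in% names(data)))
  grp <- c("model", "time", intersect("region", names(data)))
  rhs <- paste(c(predictors, covariates, "factor(subject)"),
               collapse = " + ")
  fml <- stats::as.formula(paste("response ~", rhs))
  per_time <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(aic = stats::AIC(stats::lm(fml, data =
                                                  dplyr::pick(dplyr::everything()))),
                     .groups = "drop")
  summary <- per_time |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(aic = sum(.data$aic), .groups = "drop") |>
    dplyr::mutate(delta_aic = .data$aic - min(.data$aic)) |>
    dplyr::arrange(.data$aic)
  list(per_time = per_time, summary = summary)
}

#' Benjamini-Yekutieli adjustment
#'
#' False-discovery-rate control valid under arbitrary dependence of the
#' tests, as appropriate for the spatially and temporally correlated model
#' sets produced by [neural_model_aic()]. Thin wrapper over
#' [stats::p.adjust()] with `method = "BY"`.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values.
#' @examples
#' by_adjust(c(0.01, 0.02, 0.03))
#' @export
by_adjust <- function(p) stats::p.adjust(p, method = "BY")
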