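#' Trial-to-trial response-time swings
#'
#' Adds the model-free exploration index `rt_swing = |RT_t - RT_{t-1}|`
#' (seconds) to a trial log. The first trial of each subject-by-run cell has
#' no predecessor and gets `NA`.
#'
#' @param log Trial log with an `rt` column, ordered by trial; `subject` and
#'   `run` columns are respected when present.
#' @return The log with an `rt_swing` column appended.
#' @export
rt_swings <- function(log) {
  stopifnot(is.data.frame(log), "rt" %in% names(log))
  grp <- intersect(c("subject", "run"), names(log))
  log |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(rt_swing = abs(.data$rt - dplyr::lag(.data$rt))) |>
    dplyr::ungroup()
}

# window presets: lags (in trials back from t) defining the source and
# reference RT windows of the divergence
.kld_presets <- list(
  behavioral = list(source = c(4L, 3L, 2L), reference = c(3L, 2L, 1L)),
  fmri       = list(source = 1L,            reference = c(4L, 3L, 2L)),
  meg        = list(source = c(3L, 2L),     reference = 1L))

#' Kullback-Leibler divergence of recent response-time history
#'
#' Quantifies recent shifts in the local distribution of choices: for each
#' trial t, the RTs in a *source* window of preceding trials and those in a
#' *reference* window are each converted to a density over the response-bin
#' grid (a normalized mixture of unit-height Gaussians of variance
#' `bandwidth_sq` centered on the window's RTs, floored at `epsilon` and
#' renormalized), and the discrete KL divergence of the source density from
#' the reference density is summed over bins. Higher values reflect a
#' history of larger RT swings. Three window presets correspond to the three
#' recipes used across analysis streams:
#'
#' * `"behavioral"`: trials t-4, t-3, t-2 versus the preceding three trials
#'   (t-3, t-2, t-1);
#' * `"fmri"`: the last RT (t-1) versus the three preceding (t-4 ... t-2);
#' * `"meg"`: RTs at t-3, t-2 versus the last RT (t-1).
#'
#' Trials without enough history get `NA`. The statistic is a pure function
#' of the RT sequence and the basis geometry. The natural-log KLD is floored
#' at `epsilon` before the log transform, so identical windows map to the
#' floor.
#'
#' @param log Trial log with `rt`, ordered by trial; grouped by `subject`
#'   and `run` when present.
#' @param cfg Optional [basis_config()] providing the bin grid and default
#'   bandwidth; inferred as for [sceptic_nll()] when omitted.
#' @param window_spec A preset name (`"behavioral"`, `"fmri"`, `"meg"`) or a
#'   list with integer vectors `source` and `reference` of lags.
#' @param bandwidth_sq Gaussian bandwidth (variance, s^2) of the RT
#'   densities; defaults to the basis generalization width.
#' @param epsilon Density floor and KLD floor (default 1e-6).
#' @return The log with columns `kld` and `log_kld` appended.
#' @export
kld_rt_history <- function(log, cfg = NULL, window_spec = "behavioral",
                           bandwidth_sq = NULL, epsilon = 1e-6) {
  stopifnot(is.data.frame(log), "rt" %in% names(log))
  cfg <- .infer_config(log, cfg)
  if (is.character(window_spec)) {
    window_spec <- .kld_presets[[match.arg(window_spec,
                                           names(.kld_presets))]]
  }
  stopifnot(is.list(window_spec),
            all(c("source", "reference") %in% names(window_spec)))
  src <- as.integer(window_spec$source)
  ref <- as.integer(window_spec$reference)
  if (!length(src) || !length(ref) || any(src < 1L) || any(ref < 1L)) {
    stop("window lags must be positive integers")
  }
  bw <- bandwidth_sq %||% cfg$gen_width_sq
  max_lag <- max(src, ref)

  kld_one <- function(rts) {
    n <- length(rts)
    kld <- rep(NA_real_, n)
    for (t in seq_len(n)) {
      if (t <= max_lag) next
      a <- rts[t - src]
      b <- rts[t - ref]
      if (anyNA(a) || anyNA(b)) next
      kld[t] <- .grid_kld(a, b, cfg$bin_centers, bw, epsilon)
    }
    kld
  }

  grp <- intersect(c("subject", "run"), names(log))
  out <- log |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(kld = kld_one(.data$rt)) |>
    dplyr::ungroup()
  out$log_kld <- log(pmax(out$kld, epsilon))
  out
}

# discrete KLD of the source-window density from the reference-window density
.grid_kld <- function(rts_a, rts_b, grid, bw, eps) {
  dens <- function(rts) {
    d <- rowSums(vapply(rts, function(r) exp(-(grid - r)^2 / (2 * bw)),
                        numeric(length(grid))))
    d <- d / sum(d)
    d <- pmax(d, eps)
    d / sum(d)
  }
  p <- dens(rts_a)
  q <- dens(rts_b)
  sum(p * log(p / q))
}

#' Working-memory buffer regression dataset
#'
#' Builds the analysis table for testing how far a buffer of recent choices
#' and outcomes explains the current choice, and whether the learned value
#' maximum adds explanatory power beyond it: for each trial, the current RT,
#' the k preceding RTs (`rt_lag1 ... rt_lagk`), the k preceding
#' reward/omission flags (`reward_lag1 ...`), their products
#' (`rt_x_reward_lag1 ...`), the inverse-transformed trial number
#' (`inv_trial = 1 / trial_in_run`), and optionally the current `rt_vmax`.
#' Rows with incomplete lag history are dropped. For reversal designs the
#' first `drop_first` trials of each block can be excluded as an
#' analysis-stage novelty filter.
#'
#' @param log Trial log with `rt`, `rewarded` (and `rt_vmax` when
#'   requested), ordered by trial; grouped by `subject`/`run` when present.
#' @param k Buffer depth (default 5).
#' @param include_rt_vmax Include the model-derived `rt_vmax` column
#'   (default `TRUE` when present in the log).
#' @param drop_first Number of trials to drop at the start of each
#'   reversal block (default 0; use 10 for the replication-style novelty
#'   filter).
#' @param reversal_every Block length for `drop_first`; taken from the log's
#'   design attribute when omitted.
#' @return A tibble with one row per usable trial.
#' @export
buffer_regression_dataset <- function(log, k = 5L,
                                      include_rt_vmax = TRUE,
                                      drop_first = 0L,
                                      reversal_every = NULL) {
  stopifnot(is.data.frame(log), k >= 1,
            all(c("rt", "rewarded") %in% names(log)))
  if (include_rt_vmax && !"rt_vmax" %in% names(log)) include_rt_vmax <- FALSE

  if (drop_first > 0L) {
    if (is.null(reversal_every)) {
      design <- attr(log, "design")
      reversal_every <- if (inherits(design, "session_design"))
        design$reversal_every else NA_integer_
    }
    if (is.na(reversal_every) || is.null(reversal_every)) {
      stop("`drop_first` requires a reversal block length")
    }
  }

  grp <- intersect(c("subject", "run"), names(log))
  out <- log |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(.row_in_cell = dplyr::row_number())
  for (j in seq_len(k)) {
    out <- dplyr::mutate(out,
      !!paste0("rt_lag", j) := dplyr::lag(.data$rt, j),
      !!paste0("reward_lag", j) := dplyr::lag(as.numeric(.data$rewarded), j))
  }
  out <- dplyr::ungroup(out)
  for (j in seq_len(k)) {
    out[[paste0("rt_x_reward_lag", j)]] <-
      out[[paste0("rt_lag", j)]] * out[[paste0("reward_lag", j)]]
  }
  trial_col <- if ("trial_in_run" %in% names(out)) out$trial_in_run
               else out$.row_in_cell
  out$inv_trial <- 1 / trial_col
  out <- out[stats::complete.cases(out[paste0("rt_lag", seq_len(k))]), ]
  if (drop_first > 0L) {
    tcol <- if ("trial" %in% names(out)) out$trial else out$.row_in_cell
    pos_in_block <- (tcol - 1L) %% reversal_every + 1L
    out <- out[pos_in_block > drop_first, ]
  }
  keep <- c(grp, intersect(c("trial", "trial_in_run"), names(out)), "rt",
            paste0("rt_lag", seq_len(k)), paste0("reward_lag", seq_len(k)),
            paste0("rt_x_reward_lag", seq_len(k)), "inv_trial",
            if (include_rt_vmax) "rt_vmax")
  tibble::as_tibble(out[keep])
}

#' Within-trial survival dataset with time-varying value
#'
#' Expands each trial into a discrete-hazard (counting-process) dataset over
#' the within-trial response window: one record per `step`-ms bin from the
#' window start until the response or the window end, with the
#' model-estimated value at that bin as a time-varying covariate. The
#' modeled window excludes the first `front_censor` ms of the interval
#' (deliberation and motor planning) and the last `back_censor` ms (avoided
#' to not miss responding); the default window is 1000-3500 ms on the 4-s
#' interval. A response inside the window scores `event = 1` in its bin;
#' responses before the window contribute no records; responses after the
#' window leave all records censored. Bins are half-open `[start, stop)` in
#' ms, and the value covariate is read from the trial's pre-choice value
#' function at the bin's start.
#'
#' The resulting table is ready for external mixed-effects survival engines
#' (e.g. `survival::coxph(Surv(start, stop, event) ~ value + ...)`).
#'
#' @param log Trial log (one row per trial, with `rt` in seconds; `subject`,
#'   `run`, `trial` carried through when present), e.g. the output of
#'   [refit_at_group_means()].
#' @param values Per-trial value functions: a trials x bins matrix, or a
#'   named list of per-subject matrices; defaults to the `"values"`
#'   attribute of `log`.
#' @param cfg Optional [basis_config()]; inferred from the log when omitted.
#' @param front_censor,back_censor Censored spans at the start/end of the
#'   trial interval, in ms (defaults 1000 and 500).
#' @param window Optional explicit window `c(start, end)` in ms, overriding
#'   the censor arguments.
#' @param step Bin width in ms (default 100; must be a multiple of the
#'   basis bin width).
#' @return A tibble with columns `subject`, `run`, `trial`, `start`, `stop`
#'   (ms), `event` (0/1) and `value`.
#' @export
survival_dataset <- function(log, values = NULL, cfg = NULL,
                             front_censor = 1000, back_censor = 500,
                             window = NULL, step = 100) {
  stopifnot(is.data.frame(log), "rt" %in% names(log))
  cfg <- .infer_config(log, cfg)
  values <- values %||% attr(log, "values")
  if (is.null(values)) stop("`values` (per-trial value functions) required")
  if (is.list(values) && !is.matrix(values)) {
    ord <- if ("subject" %in% names(log)) unique(log$subject) else names(values)
    values <- do.call(rbind, values[ord])
  }
  if (nrow(values) != nrow(log)) {
    stop("`values` must have one row per trial of `log`")
  }
  window <- window %||% c(front_censor,
                          cfg$interval_length * 1000 - back_censor)
  stopifnot(length(window) == 2L, window[2L] > window[1L])
  if (abs(step / 1000 / cfg$bin_width - round(step / 1000 / cfg$bin_width)) >
      1e-9) {
    stop("`step` must align with the basis bin grid")
  }
  n_bins_win <- as.integer(round((window[2L] - window[1L]) / step))
  starts <- window[1L] + (seq_len(n_bins_win) - 1L) * step

  rt_ms <- round(log$rt * 1000)
  # number of at-risk records: bins up to and including the one whose
  # (start, stop] span contains the response; capped at the window length
  n_rec <- pmin(pmax(ceiling((rt_ms - window[1L]) / step), 0L), n_bins_win)
  keep <- n_rec > 0L

  id_cols <- intersect(c("subject", "run", "trial"), names(log))
  if (!any(keep)) {
    return(tibble::as_tibble(c(log[integer(0), id_cols, drop = FALSE],
                               list(start = numeric(0), stop = numeric(0),
                                    event = integer(0),
                                    value = numeric(0)))))
  }
  idx <- rep(which(keep), n_rec[keep])
  rec <- seq_len(sum(n_rec[keep]))
  within <- rec - rep(cumsum(c(0, n_rec[keep][-sum(keep)])), n_rec[keep])
  out <- tibble::as_tibble(log[idx, id_cols, drop = FALSE])
  out$start <- starts[within]
  out$stop <- out$start + step
  out$event <- as.integer(within == n_rec[idx] &
                            rt_ms[idx] <= window[2L])
  bin_idx <- as.integer(out$start / (cfg$bin_width * 1000)) + 1L
  out$value <- values[cbind(idx, bin_idx)]
  out
}
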