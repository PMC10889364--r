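#' Read and write trial logs
#'
#' Trial logs are tab-separated long-format tables with one row per trial.
#' The canonical header is: `subject`, `run`, `trial`, `trial_in_run`,
#' `contingency`, `rt` (seconds), `rt_bin` (0-based), `rewarded` (0/1),
#' `reward` (points, 0 on omission), plus any latent columns (`entropy`,
#' `entropy_change`, `rt_vmax`, `v_max`, `v_chosen`, `pe`) and timing
#' columns (`iti`, `trial_onset`, `feedback_onset`). Extra columns pass
#' through unchanged.
#'
#' @param log A trial-log tibble.
#' @param path File path.
#' @return `write_trial_log()` returns `log` invisibly; `read_trial_log()`
#'   returns a tibble.
#' @export
write_trial_log <- function(log, path) {
  stopifnot(is.data.frame(log))
  readr::write_tsv(as.data.frame(log), path)
  invisible(log)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read and write basis configuration files
#'
#' Flat key/value text (YAML) holding the user-settable fields of a
#' [basis_config()]: `n_elements`, `interval_length`, `bin_width`,
#' `overlap_target`, and optionally explicit `basis_width_sq` /
#' `gen_width_sq` (the generalization width otherwise follows the basis
#' width).
#'
#' @param cfg A [basis_config()].
#' @param path File path.
#' @return `read_basis_config()` returns a rebuilt [basis_config()].
#' @export
write_basis_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "basis_config"))
  yaml::write_yaml(list(n_elements = cfg$n_elements,
                        interval_length = cfg$interval_length,
                        bin_width = cfg$bin_width,
                        overlap_target = cfg$overlap_target,
                        basis_width_sq = cfg$basis_width_sq,
                        gen_width_sq = cfg$gen_width_sq),
                   path, precision = 15L)
  invisible(cfg)
}

#' @rdname write_basis_config
#' @export
read_basis_config <- function(path) {
  f <- yaml::read_yaml(path)
  basis_config(n_elements = f$n_elements,
               interval_length = f$interval_length,
               bin_width = f$bin_width,
               overlap_target = f$overlap_target,
               basis_width_sq = f$basis_width_sq,
               gen_width_sq = f$gen_width_sq)
}

#' Write weight or value trajectories in long format
#'
#' Flattens a trial-by-element (or trial-by-bin) matrix into a long
#' delimited table with columns `subject`, `run`, `trial`, `element` (or
#' `bin`), `value`.
#'
#' @param mat Numeric matrix, one row per trial.
#' @param path File path.
#' @param subject,run Identifiers recycled across rows.
#' @param what Column name for the second index (default `"element"`).
#' @return The long tibble, invisibly.
#' @export
write_trajectory <- function(mat, path, subject = "s01", run = 1L,
                             what = "element") {
  stopifnot(is.matrix(mat))
  long <- tibble::tibble(
    subject = subject, run = run,
    trial = rep(seq_len(nrow(mat)), ncol(mat)),
    index = rep(seq_len(ncol(mat)), each = nrow(mat)),
    value = as.vector(mat))
  names(long)[names(long) == "index"] <- what
  readr::write_tsv(long, path)
  invisible(long)
}

#' Write a three-column event file
#'
#' Standard `onset, duration, value` event table (tab-separated, seconds),
#' the exchange format for regressor construction.
#'
#' @param events Tibble with `onset`, `duration` and optionally `value`
#'   (defaults to 1).
#' @param path File path.
#' @return The events, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(is.data.frame(events),
            all(c("onset", "duration") %in% names(events)))
  ev <- tibble::tibble(onset = events$onset, duration = events$duration,
                       value = if ("value" %in% names(events)) events$value
                               else rep(1, nrow(events)))
  readr::write_tsv(ev, path)
  invisible(ev)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
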