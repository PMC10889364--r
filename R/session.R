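#' Session designs for the clock task
#'
#' Named presets reproduce the three study structures:
#'
#' * `"fmri_original"`: 8 runs of 50 trials, 4-s interval, one fixed
#'   contingency per run (the four contingency types, each twice).
#' * `"meg_original"`: as above with 63-trial runs.
#' * `"replication"`: 240 trials in 2 runs of 120, 5-s interval, IEV/DEV
#'   alternating in 40-trial blocks, with the contingency reversing every 40
#'   trials without any signal to the agent.
#'
#' Inter-trial intervals are drawn from a truncated exponential distribution;
#' each trial's feedback is displayed for `feedback_duration` seconds. The
#' ITIs and event onsets are recorded for the neural-design module but never
#' seen by the agent.
#'
#' @param preset One of `"fmri_original"`, `"meg_original"`, `"replication"`.
#' @param ... Named fields overriding the preset (e.g. `n_runs`,
#'   `trials_per_run`, `run_contingencies`, `reversal_every`, `iti_mean`).
#' @return An object of class `session_design`.
#' @export
session_design <- function(preset = c("fmri_original", "meg_original",
                                      "replication"),
                           ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    fmri_original = list(
      n_runs = 8L, trials_per_run = 50L, trial_length = 4,
      run_contingencies = rep(c("IEV", "DEV", "CEV", "CEVR"), 2L),
      reversal_every = NA_integer_, reset_per_run = TRUE),
    meg_original = list(
      n_runs = 8L, trials_per_run = 63L, trial_length = 4,
      run_contingencies = rep(c("IEV", "DEV", "CEV", "CEVR"), 2L),
      reversal_every = NA_integer_, reset_per_run = TRUE),
    replication = list(
      n_runs = 2L, trials_per_run = 120L, trial_length = 5,
      run_contingencies = c("IEV", "IEV"),   # placeholder; blocks alternate
      reversal_every = 40L, reset_per_run = FALSE))
  base$preset <- preset
  base$feedback_duration <- 0.9
  base$iti_mean <- 2
  base$iti_max <- 10
  # scan repetition time profile for the neural-design module
  base$tr <- switch(preset, fmri_original = 1.0, replication = 0.6,
                    meg_original = NA_real_)
  design <- utils::modifyList(base, list(...))
  design$n_trials <- design$n_runs * design$trials_per_run
  structure(design, class = "session_design")
}

#' @export
print.session_design <- function(x, ...) {
  cat(sprintf("<session_design %s> %d runs x %d trials, %g-s interval",
              x$preset, x$n_runs, x$trials_per_run, x$trial_length))
  if (!is.na(x$reversal_every)) {
    cat(sprintf(", reversal every %d trials", x$reversal_every))
  }
  cat("\n")
  invisible(x)
}

#' Global trial indices at which the contingency reverses
#'
#' For reversal designs, the contingency switches at the start of each
#' 40-trial block after the first, i.e. at global trials 41, 81, ..., with no
#' signal to the agent. Designs without reversals return an empty vector.
#'
#' @param design A [session_design()].
#' @return Integer vector of the first trial of each post-reversal block.
#' @export
reversal_trials <- function(design) {
  stopifnot(inherits(design, "session_design"))
  if (is.na(design$reversal_every)) return(integer(0))
  s <- seq.int(design$reversal_every + 1L, design$n_trials,
               by = design$reversal_every)
  as.integer(s)
}

# per-trial contingency labels for a design (global trial order)
.design_labels <- function(design) {
  if (!is.na(design$reversal_every)) {
    blocks <- ceiling(seq_len(design$n_trials) / design$reversal_every)
    c("IEV", "DEV")[(blocks - 1L) %% 2L + 1L]
  } else {
    rep(design$run_contingencies, each = design$trials_per_run)
  }
}

#' Simulate a full session of the clock task
#'
#' Generates a complete trial log for one agent under a [session_design()]:
#' the agent is simulated run by run via [run_agent()], contingency reversals
#' are applied at the scheduled block boundaries without resetting the
#' agent's weights (the manipulation is unsignaled), and event timing (trial
#' onset, feedback onset, ITI) is laid down for the neural-design module.
#' In the original designs the agent's weights are re-initialized at each run
#' boundary (runs are separate contingency blocks); the replication preset
#' carries weights across its runs as one continuous session.
#'
#' @inheritParams run_agent
#' @param design A [session_design()].
#' @param subject_id Subject identifier stored in the log (default `"s01"`).
#' @return A tibble of class `sceptic_sim`: the [run_agent()] columns plus
#'   `subject`, `run`, `trial_in_run`, global `trial`, `iti`, `trial_onset`,
#'   `feedback_onset` (seconds from session start). Attribute `"design"`
#'   holds the design.
#' @export
generate_session <- function(design, params,
                             rule = c("selective", "traditional"),
                             seed = NULL, subject_id = "s01",
                             init = c("uniform", "zero"), w0 = 1) {
  rule <- match.arg(rule)
  init <- match.arg(init)
  stopifnot(inherits(design, "session_design"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- .default_config(design$trial_length)
  labels <- .design_labels(design)
  conts <- lapply(unique(labels), make_contingency,
                  interval_length = design$trial_length)
  names(conts) <- unique(labels)

  logs <- vector("list", design$n_runs)
  carry <- NULL
  for (r in seq_len(design$n_runs)) {
    idx <- (r - 1L) * design$trials_per_run + seq_len(design$trials_per_run)
    env <- conts[labels[idx]]
    w_init <- if (design$reset_per_run || is.null(carry)) NULL else carry
    sim <- run_agent(cfg, params, unname(env), design$trials_per_run,
                     rule = rule, init = init, w0 = w0, weights = w_init)
    carry <- attr(sim, "final_weights")
    sim$run <- r
    sim$trial_in_run <- sim$trial
    sim$trial <- idx
    logs[[r]] <- sim
  }
  log <- dplyr::bind_rows(logs)
  log$subject <- subject_id
  log$iti <- pmin(stats::rexp(nrow(log), 1 / design$iti_mean), design$iti_max)
  # event timing: clock onset -> response at rt -> feedback (0.9 s) -> ITI
  trial_dur <- log$rt + design$feedback_duration + log$iti
  log$trial_onset <- cumsum(c(0, utils::head(trial_dur, -1L)))
  log$feedback_onset <- log$trial_onset + log$rt
  log <- dplyr::relocate(log, "subject", "run", "trial", "trial_in_run")
  attr(log, "design") <- design
  class(log) <- c("sceptic_sim", setdiff(class(log), "sceptic_sim"))
  log
}

#' Specify a synthetic cohort of agents
#'
#' Population distributions for the agent parameters, expressed on the
#' unconstrained fitting scales (logit for `alpha` and `gamma`, log for
#' `beta`); per-subject parameters are drawn as independent normals and
#' mapped back through the inverse transforms, which guarantees the bounds.
#' The defaults describe a moderately heterogeneous cohort centered on a
#' learning rate of 0.1, a temperature of 5 points, and a selective
#' maintenance rate of 0.15 -- a regime in which agents show the
#' task-typical mixture of early exploration and late exploitation.
#'
#' @param n_subjects Number of agents.
#' @param mean Named numeric vector of transformed-scale means
#'   (`alpha`, `beta`, `gamma`).
#' @param sd Named numeric vector of transformed-scale SDs (all > 0).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 40L,
                        mean = c(alpha = stats::qlogis(0.1),
                                 beta = log(5),
                                 gamma = stats::qlogis(0.15)),
                        sd = c(alpha = 0.5, beta = 0.4, gamma = 0.7)) {
  stopifnot(n_subjects >= 2)
  pn <- c("alpha", "beta", "gamma")
  if (!all(pn %in% names(mean)) || !all(pn %in% names(sd))) {
    stop("`mean` and `sd` must name alpha, beta and gamma")
  }
  if (any(sd[pn] <= 0)) stop("population SDs must be positive")
  structure(list(n_subjects = as.integer(n_subjects),
                 mean = mean[pn], sd = sd[pn]),
            class = "cohort_spec")
}

#' Simulate a cohort of heterogeneous agents
#'
#' Draws per-subject parameters from the population specification, simulates
#' each subject with [generate_session()], and returns the concatenated logs
#' together with the ground-truth parameter table for recovery studies.
#'
#' @param spec A [cohort_spec()].
#' @param design A [session_design()].
#' @inheritParams run_agent
#' @return A list of class `sceptic_cohort` with elements `logs` (tibble,
#'   all subjects) and `truth` (tibble: `subject`, `alpha`, `beta`, `gamma`
#'   on the native scales).
#' @export
generate_cohort <- function(spec, design,
                            rule = c("selective", "traditional"),
                            seed = NULL, init = c("uniform", "zero"),
                            w0 = 1) {
  rule <- match.arg(rule)
  init <- match.arg(init)
  stopifnot(inherits(spec, "cohort_spec"), inherits(design, "session_design"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_subjects
  ids <- sprintf("s%03d", seq_len(n))
  draw_t <- vapply(c("alpha", "beta", "gamma"), function(p) {
    stats::rnorm(n, spec$mean[[p]], spec$sd[[p]])
  }, numeric(n))
  truth <- tibble::tibble(
    subject = ids,
    alpha = stats::plogis(draw_t[, "alpha"]),
    beta = exp(draw_t[, "beta"]),
    gamma = stats::plogis(draw_t[, "gamma"]))
  subject_seeds <- sample.int(.Machine$integer.max, n)
  logs <- purrr::pmap(truth, function(subject, alpha, beta, gamma) {
    i <- match(subject, ids)
    generate_session(design,
                     agent_params(alpha = alpha, beta = beta, gamma = gamma),
                     rule = rule, seed = subject_seeds[i],
                     subject_id = subject, init = init, w0 = w0)
  })
  structure(list(logs = dplyr::bind_rows(logs), truth = truth,
                 design = design, rule = rule),
            class = "sceptic_cohort")
}

#' @export
print.sceptic_cohort <- function(x, ...) {
  cat(sprintf("<sceptic_cohort> %d subjects x %d trials (%s rule, %s design)\n",
              nrow(x$truth), x$design$n_trials, x$rule, x$design$preset))
  invisible(x)
}
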