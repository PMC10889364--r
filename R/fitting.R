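#' Parameter transforms between native and unconstrained scales
#'
#' Fitting is performed on unconstrained scales: logit for `alpha` and
#' `gamma` (bounded in (0, 1)), log for `beta` (positive). The transforms
#' are bijective and exact to numerical round-off.
#'
#' @param x Named numeric vector with entries among `alpha`, `beta`, `gamma`.
#' @return Named numeric vector on the other scale.
#' @export
to_unconstrained <- function(x) {
  out <- x
  for (p in names(x)) {
    out[[p]] <- switch(p,
                       alpha = stats::qlogis(x[[p]]),
                       gamma = stats::qlogis(x[[p]]),
                       beta = log(x[[p]]),
                       stop("unknown parameter: ", p))
  }
  out
}

#' @rdname to_unconstrained
#' @export
to_native <- function(x) {
  out <- x
  for (p in names(x)) {
    out[[p]] <- switch(p,
                       alpha = stats::plogis(x[[p]]),
                       gamma = stats::plogis(x[[p]]),
                       beta = exp(x[[p]]),
                       stop("unknown parameter: ", p))
  }
  out
}

.rule_params <- function(rule) {
  switch(rule, traditional = c("alpha", "beta"),
         selective = c("alpha", "beta", "gamma"))
}

# resolve the basis configuration for a trial log: explicit > design attr >
# default 4-s interval
.infer_config <- function(log, cfg = NULL) {
  if (!is.null(cfg)) {
    stopifnot(inherits(cfg, "basis_config"))
    return(cfg)
  }
  design <- attr(log, "design")
  if (inherits(design, "session_design")) {
    return(.default_config(design$trial_length))
  }
  .default_config(4)
}

# extract replay arrays from a single-subject log
.replay_data <- function(log, cfg) {
  stopifnot(all(c("reward") %in% names(log)))
  rt_bin <- if ("rt_bin" %in% names(log)) as.integer(log$rt_bin)
            else rt_to_bin(cfg, log$rt)
  if (any(rt_bin < 0L | rt_bin >= cfg$n_bins)) {
    stop("response bins outside the configured interval")
  }
  run <- if ("run" %in% names(log)) as.integer(log$run) else rep(1L, nrow(log))
  list(rt_bin = rt_bin, reward = as.numeric(log$reward), run = run)
}

#' Negative log-likelihood of a trial log under a learning rule
#'
#' Replays the observed choice/outcome sequence deterministically through the
#' learning rule, recomputing the latent value function before each choice,
#' and accumulates the negative log-probability of the observed response bins
#' under the softmax policy. Weights start at zero and, by default, re-
#' initialize at each run boundary (runs are separate contingency blocks in
#' the original designs). Trials with missing response times are dropped.
#'
#' @param log Single-subject trial log with columns `reward`, `run`, and
#'   `rt_bin` or `rt`.
#' @param params An [agent_params()] (or named list with `alpha`, `beta` and,
#'   for the selective rule, `gamma`).
#' @param rule `"selective"` or `"traditional"`.
#' @param cfg Optional [basis_config()]; inferred from the log's design
#'   attribute (or the 4-s default) when omitted.
#' @param reset_per_run Re-initialize weights at run boundaries (default
#'   `TRUE`; the replication design uses `FALSE`).
#' @return The negative log-likelihood (scalar).
#' @export
sceptic_nll <- function(log, params, rule = c("selective", "traditional"),
                        cfg = NULL, reset_per_run = TRUE) {
  rule <- match.arg(rule)
  cfg <- .infer_config(log, cfg)
  rt_col <- log[["rt_bin"]] %||% log[["rt"]]
  if (is.null(rt_col)) stop("log must contain `rt_bin` or `rt`")
  log <- log[!is.na(log$reward) & !is.na(rt_col), ]
  d <- .replay_data(log, cfg)
  gamma <- if (rule == "selective") params$gamma %||% 0 else 0
  res <- .replay_cpp(cfg$phi_bins, cfg$elig_bins, d$rt_bin, d$reward, d$run,
                     params$alpha, params$beta, gamma, params$h %||% 0,
                     reset_per_run, rep(0, cfg$n_elements), FALSE)
  res$nll
}

#' Fit one subject by MAP with a Laplace approximation
#'
#' Maximizes the log-posterior (log-likelihood plus an independent Gaussian
#' prior on the transformed scales) by multistart BFGS, and obtains posterior
#' SDs from the diagonal of the inverse Hessian at the mode. With
#' `prior = NULL` the prior is flat and the fit is maximum likelihood.
#'
#' @inheritParams sceptic_nll
#' @param prior `NULL`, or a list with named vectors `mean` and `sd` on the
#'   transformed scales (the population prior of the empirical-Bayes loop).
#' @param n_starts Number of optimizer starts (default 5); the first start
#'   is at the prior mean (or a neutral default), the rest are seeded random
#'   draws around it.
#' @param seed Optional integer seed for the random starts.
#' @param warm_start Optional named vector on the transformed scale used as
#'   the single start (overrides `n_starts`); used internally to warm-start
#'   empirical-Bayes iterations.
#' @return A list with `par` (native scale), `par_t` and `sd_t` (transformed
#'   scale), `nll` at the mode, `logpost`, `hessian`, `converged` and
#'   `n_trials`.
#' @export
fit_subject <- function(log, rule = c("selective", "traditional"),
                        prior = NULL, cfg = NULL, reset_per_run = TRUE,
                        n_starts = 5L, seed = NULL, warm_start = NULL) {
  rule <- match.arg(rule)
  cfg <- .infer_config(log, cfg)
  pn <- .rule_params(rule)
  log <- log[!is.na(log$reward), ]
  d <- .replay_data(log, cfg)
  w0 <- rep(0, cfg$n_elements)

  nll_fun <- function(theta_t) {
    th <- to_native(stats::setNames(theta_t, pn))
    gamma <- if (rule == "selective") th[["gamma"]] else 0
    res <- try(.replay_cpp(cfg$phi_bins, cfg$elig_bins, d$rt_bin, d$reward,
                           d$run, th[["alpha"]], th[["beta"]], gamma, 0,
                           reset_per_run, w0, FALSE), silent = TRUE)
    if (inherits(res, "try-error")) return(1e10)
    res$nll
  }
  objective <- function(theta_t) {
    val <- nll_fun(theta_t)
    if (!is.null(prior)) {
      val <- val + sum(((theta_t - prior$mean[pn]) / prior$sd[pn])^2) / 2
    }
    if (!is.finite(val)) 1e10 else val
  }

  center <- if (!is.null(prior)) prior$mean[pn] else
    to_unconstrained(c(alpha = 0.2, beta = 10, gamma = 0.2))[pn]
  spread <- if (!is.null(prior)) pmin(prior$sd[pn], 2) else rep(1.5, length(pn))

  if (!is.null(warm_start)) {
    starts <- list(warm_start[pn])
  } else {
    if (!is.null(seed)) set.seed(seed)
    starts <- c(list(center),
                lapply(seq_len(max(n_starts - 1L, 0L)), function(i) {
                  center + stats::rnorm(length(pn), 0, spread)
                }))
  }

  fits <- lapply(starts, function(s0) {
    try(stats::optim(s0, objective, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-10)),
        silent = TRUE)
  })
  ok <- !vapply(fits, inherits, logical(1), "try-error")
  if (!any(ok)) {
    return(list(par = NULL, par_t = NULL, sd_t = NULL, nll = NA_real_,
                logpost = NA_real_, hessian = NULL, converged = FALSE,
                n_trials = nrow(log)))
  }
  fits <- fits[ok]
  best <- fits[[which.min(vapply(fits, function(f) f$value, numeric(1)))]]
  theta_t <- stats::setNames(best$par, pn)

  hess <- try(stats::optimHess(theta_t, objective), silent = TRUE)
  sd_t <- rep(NA_real_, length(pn))
  if (!inherits(hess, "try-error")) {
    vcv <- try(solve(hess), silent = TRUE)
    if (!inherits(vcv, "try-error")) {
      dg <- diag(vcv)
      sd_t <- ifelse(dg > 0, sqrt(dg), NA_real_)
    }
  }
  list(par = to_native(theta_t),
       par_t = theta_t,
       sd_t = stats::setNames(sd_t, pn),
       nll = nll_fun(theta_t),
       logpost = -best$value,
       hessian = if (inherits(hess, "try-error")) NULL else hess,
       converged = best$convergence == 0,
       n_trials = nrow(log))
}

#' Empirical-Bayes population fit
#'
#' Alternates between subject-level MAP fits (under the current population
#' prior, on the transformed scales) and population-moment updates: the
#' population mean is the mean of the posterior modes, and the population
#' variance is the mean of the posterior variances plus the variance of the
#' modes. Over iterations, subject estimates are shrunk toward the inferred
#' population distribution. Iteration stops when the population means move
#' less than `tol` (relative) or after `max_iter` iterations (flagged as
#' non-converged). After the first iteration, subject fits are warm-started
#' from their previous modes.
#'
#' @param cohort A `sceptic_cohort` (from [generate_cohort()]) or a tibble of
#'   logs with a `subject` column.
#' @inheritParams fit_subject
#' @param init Optional initial prior (list with `mean`, `sd` on transformed
#'   scales); a weak default is used when omitted.
#' @param tol Relative convergence tolerance on the population means
#'   (default 1e-6).
#' @param max_iter Maximum empirical-Bayes iterations (default 50).
#' @return An object of class `sceptic_fit`: list with `subjects` (tibble of
#'   per-subject modes, SDs and likelihoods), `population` (tibble of
#'   population moments), `trace` (iteration history), `rule`, `n_params`,
#'   `nll_total`, `aic_total` (AIC = 2 k - 2 logL summed over subjects) and
#'   `converged`.
#' @export
fit_population <- function(cohort, rule = c("selective", "traditional"),
                           cfg = NULL, reset_per_run = TRUE,
                           init = NULL, tol = 1e-6, max_iter = 50L,
                           n_starts = 5L, seed = 1L) {
  rule <- match.arg(rule)
  logs <- if (inherits(cohort, "sceptic_cohort")) cohort$logs else cohort
  stopifnot(is.data.frame(logs), "subject" %in% names(logs))
  pn <- .rule_params(rule)
  subjects <- unique(logs$subject)
  if (length(subjects) < 2L) stop("need at least 2 subjects")
  cfg <- .infer_config(logs, cfg)
  sub_logs <- split(logs, factor(logs$subject, levels = subjects))

  prior <- init %||% list(
    mean = stats::setNames(to_unconstrained(
      c(alpha = 0.2, beta = 10, gamma = 0.2))[pn], pn),
    sd = stats::setNames(rep(2, length(pn)), pn))

  trace <- list()
  modes <- NULL
  fits <- NULL
  converged <- FALSE
  set.seed(seed)
  sub_seeds <- sample.int(2^30, length(subjects))

  for (iter in seq_len(max_iter)) {
    fits <- purrr::imap(sub_logs, function(lg, id) {
      i <- match(id, subjects)
      ws <- if (!is.null(modes)) modes[i, ] else NULL
      fit_subject(lg, rule = rule, prior = prior, cfg = cfg,
                  reset_per_run = reset_per_run, n_starts = n_starts,
                  seed = sub_seeds[i], warm_start = ws)
    })
    bad <- vapply(fits, function(f) is.null(f$par_t), logical(1))
    if (any(bad)) stop("subject fit failed for: ",
                       paste(subjects[bad], collapse = ", "))
    modes <- do.call(rbind, lapply(fits, function(f) f$par_t[pn]))
    vars <- do.call(rbind, lapply(fits, function(f) {
      v <- f$sd_t[pn]^2
      ifelse(is.na(v), 0, v)
    }))
    new_mean <- colMeans(modes)
    new_var <- colMeans(vars) + apply(modes, 2L, stats::var)
    new_sd <- sqrt(pmax(new_var, 1e-8))

    delta <- max(abs(new_mean - prior$mean[pn]) / (1 + abs(prior$mean[pn])))
    trace[[iter]] <- tibble::tibble(
      iteration = iter, param = pn,
      mean_t = unname(new_mean), sd_t = unname(new_sd),
      delta = delta)
    prior <- list(mean = stats::setNames(new_mean, pn),
                  sd = stats::setNames(new_sd, pn))
    if (delta < tol) { converged <- TRUE; break }
  }

  subj_tbl <- tibble::tibble(subject = subjects)
  vnum <- function(g) unname(vapply(fits, g, numeric(1)))
  for (p in pn) {
    subj_tbl[[p]] <- vnum(function(f) f$par[[p]])
    subj_tbl[[paste0(p, "_t")]] <- vnum(function(f) f$par_t[[p]])
    subj_tbl[[paste0("sd_", p, "_t")]] <- vnum(function(f) f$sd_t[[p]])
  }
  subj_tbl$nll <- vnum(function(f) f$nll)
  subj_tbl$n_trials <- vnum(function(f) f$n_trials)
  subj_tbl$converged <- unname(vapply(fits, function(f) f$converged,
                                      logical(1)))

  k <- length(pn)
  structure(list(
    subjects = subj_tbl,
    population = tibble::tibble(
      param = pn,
      mean_t = unname(prior$mean[pn]),
      sd_t = unname(prior$sd[pn]),
      mean_native = unname(to_native(prior$mean[pn]))),
    trace = dplyr::bind_rows(trace),
    rule = rule, n_params = k,
    nll_total = sum(subj_tbl$nll),
    aic_total = sum(2 * k + 2 * subj_tbl$nll),
    converged = converged,
    fingerprint = list(subjects = subjects,
                       n_trials = unname(subj_tbl$n_trials))),
    class = "sceptic_fit")
}

#' @export
print.sceptic_fit <- function(x, ...) {
  cat(sprintf("<sceptic_fit> %s rule, %d subjects, %d iterations%s\n",
              x$rule, nrow(x$subjects), max(x$trace$iteration),
              if (x$converged) "" else " (not converged)"))
  cat(sprintf("  total NLL = %.2f, total AIC = %.2f\n",
              x$nll_total, x$aic_total))
  print(x$population)
  invisible(x)
}

#' Recompute latent trajectories at fixed (group-mean) parameters
#'
#' Fixes the model parameters at the supplied values for every subject and
#' replays each subject's own choices and outcomes to recompute the latent
#' states (entropy, entropy change, RT_Vmax, value maxima, prediction
#' errors) without any optimization. Refitting at the group means puts the
#' latent signals of all subjects on a common parameter scale, so that
#' between-subject differences in downstream regressions reflect behavior
#' rather than parameter scaling.
#'
#' @param cohort A `sceptic_cohort` or a tibble of logs with a `subject`
#'   column.
#' @param means Named vector of parameters on the native scale (e.g.
#'   `mean_native` from a [fit_population()] object), or a `sceptic_fit`
#'   whose population means are used.
#' @inheritParams fit_subject
#' @return A tibble: the input logs augmented with `entropy`,
#'   `entropy_change`, `rt_vmax`, `v_max`, `v_chosen`, `pe` recomputed at the
#'   fixed parameters. Per-subject pre-choice value matrices (trial x bin)
#'   are attached as attribute `"values"`.
#' @export
refit_at_group_means <- function(cohort, means,
                                 rule = c("selective", "traditional"),
                                 cfg = NULL, reset_per_run = TRUE) {
  rule <- match.arg(rule)
  logs <- if (inherits(cohort, "sceptic_cohort")) cohort$logs else cohort
  stopifnot(is.data.frame(logs), "subject" %in% names(logs))
  if (inherits(means, "sceptic_fit")) {
    means <- stats::setNames(means$population$mean_native,
                             means$population$param)
  }
  pn <- .rule_params(rule)
  if (!all(pn %in% names(means))) {
    stop("`means` must name: ", paste(pn, collapse = ", "))
  }
  cfg <- .infer_config(logs, cfg)
  gamma <- if (rule == "selective") means[["gamma"]] else 0

  subjects <- unique(logs$subject)
  values <- vector("list", length(subjects))
  names(values) <- subjects
  out <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    lg <- logs[logs$subject == subjects[i], ]
    d <- .replay_data(lg, cfg)
    res <- .replay_cpp(cfg$phi_bins, cfg$elig_bins, d$rt_bin, d$reward,
                       d$run, means[["alpha"]], means[["beta"]], gamma, 0,
                       reset_per_run, rep(0, cfg$n_elements), TRUE)
    lg$entropy <- res$entropy
    lg$entropy_change <- res$entropy_change
    lg$rt_vmax <- cfg$bin_centers[res$rt_vmax_bin + 1]
    lg$v_max <- res$v_max
    lg$v_chosen <- res$v_chosen
    lg$pe <- res$pe
    values[[i]] <- res$values
    out[[i]] <- lg
  }
  out <- dplyr::bind_rows(out)
  attr(out, "values") <- values
  attr(out, "config") <- cfg
  out
}

#' Compare fitted models by summed AIC
#'
#' Tabulates, for each fitted model, the total negative log-likelihood and
#' summed AIC (`AIC = 2 k - 2 logL` per subject, summed over subjects), plus
#' the AIC difference from the best model. Lower AIC indicates better fit;
#' `delta_aic` is reported relative to the minimum (best) model, so the best
#' model has `delta_aic = 0`. Models must have been fitted to the same data
#' (same subjects and trial counts).
#'
#' @param ... Named [fit_population()] objects (or a single named list of
#'   them).
#' @return A tibble with columns `model`, `rule`, `n_params`, `nll`, `aic`,
#'   `delta_aic`, sorted by AIC.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1L]], "sceptic_fit")) {
    fits <- fits[[1L]]
  }
  stopifnot(length(fits) >= 2L,
            all(vapply(fits, inherits, logical(1), "sceptic_fit")))
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$rule, character(1))
  }
  fp <- lapply(fits, function(f) f$fingerprint)
  for (i in seq_along(fp)[-1L]) {
    if (!identical(fp[[i]], fp[[1L]])) {
      stop("models were fitted to different data")
    }
  }
  out <- tibble::tibble(
    model = names(fits),
    rule = unname(vapply(fits, function(f) f$rule, character(1))),
    n_params = unname(vapply(fits, function(f) f$n_params, numeric(1))),
    nll = unname(vapply(fits, function(f) f$nll_total, numeric(1))),
    aic = unname(vapply(fits, function(f) f$aic_total, numeric(1))))
  out$delta_aic <- out$aic - min(out$aic)
  dplyr::arrange(out, .data$aic)
}

#' Parameter-recovery study
#'
#' Runs the full generate-fit-compare loop: simulates a cohort from known
#' population parameters, fits it with the empirical-Bayes procedure, and
#' reports truth-versus-estimate correlation, bias and RMSE for each
#' parameter on the native scale.
#'
#' @param spec A [cohort_spec()].
#' @param design A [session_design()].
#' @inheritParams fit_population
#' @param seed Integer seed controlling both generation and fitting.
#' @param out Optional directory; when given, the estimates and summary are
#'   written there as TSV files (`recovery_estimates.tsv`,
#'   `recovery_summary.tsv`).
#' @param ... Passed to [fit_population()].
#' @return An object of class `sceptic_recovery`: list with `estimates`
#'   (truth and estimate per subject and parameter), `summary` (per-parameter
#'   `cor`, `bias`, `rmse`), and the underlying `fit`.
#' @export
recover_parameters <- function(spec, design,
                               rule = c("selective", "traditional"),
                               seed = 1L, out = NULL, ...) {
  rule <- match.arg(rule)
  cohort <- generate_cohort(spec, design, rule = rule, seed = seed)
  fit <- fit_population(cohort, rule = rule, seed = seed + 1L, ...)
  pn <- .rule_params(rule)
  est <- fit$subjects[c("subject", pn)]
  truth <- cohort$truth[c("subject", pn)]
  long <- dplyr::bind_rows(
    dplyr::mutate(tidyr::pivot_longer(truth, -"subject",
                                      names_to = "param",
                                      values_to = "value"),
                  kind = "truth"),
    dplyr::mutate(tidyr::pivot_longer(est, -"subject",
                                      names_to = "param",
                                      values_to = "value"),
                  kind = "estimate"))
  wide <- tidyr::pivot_wider(long, names_from = "kind",
                             values_from = "value")
  summary <- dplyr::summarise(
    dplyr::group_by(wide, .data$param),
    cor = stats::cor(.data$truth, .data$estimate),
    bias = mean(.data$estimate - .data$truth),
    rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
    .groups = "drop")
  res <- structure(list(estimates = wide, summary = summary, fit = fit,
                        spec = spec, design = design, rule = rule,
                        seed = seed),
                   class = "sceptic_recovery")
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(wide, file.path(out, "recovery_estimates.tsv"))
    readr::write_tsv(summary, file.path(out, "recovery_summary.tsv"))
  }
  res
}

#' @export
print.sceptic_recovery <- function(x, ...) {
  cat(sprintf("<sceptic_recovery> %s rule, %d subjects, seed %d\n",
              x$rule, x$spec$n_subjects, x$seed))
  print(x$summary)
  invisible(x)
}
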