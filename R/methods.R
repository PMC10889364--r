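#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a population fit
#'
#' One row per subject and parameter, with the posterior mode on both scales
#' and the Laplace SD on the transformed scale.
#'
#' @param x A `sceptic_fit`.
#' @param ... Unused.
#' @return A tibble with columns `subject`, `param`, `estimate`,
#'   `estimate_t`, `std_error_t`.
#' @method tidy sceptic_fit
#' @export
tidy.sceptic_fit <- function(x, ...) {
  pn <- .rule_params(x$rule)
  purrr::map_dfr(pn, function(p) {
    tibble::tibble(subject = x$subjects$subject,
                   param = p,
                   estimate = x$subjects[[p]],
                   estimate_t = x$subjects[[paste0(p, "_t")]],
                   std_error_t = x$subjects[[paste0("sd_", p, "_t")]])
  })
}

#' Glance at a population fit
#'
#' @param x A `sceptic_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `rule`, `n_subjects`, `n_params`, `nll`,
#'   `aic`, `iterations`, `converged`.
#' @method glance sceptic_fit
#' @export
glance.sceptic_fit <- function(x, ...) {
  tibble::tibble(rule = x$rule,
                 n_subjects = nrow(x$subjects),
                 n_params = x$n_params,
                 nll = x$nll_total,
                 aic = x$aic_total,
                 iterations = max(x$trace$iteration),
                 converged = x$converged)
}

#' @method tidy sceptic_recovery
#' @export
tidy.sceptic_recovery <- function(x, ...) x$estimates

#' @method glance sceptic_recovery
#' @export
glance.sceptic_recovery <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "param",
                     values_from = c("cor", "bias", "rmse"))
}

#' Plot a simulated session
#'
#' Trajectories of the response time, the learned value maximum, and the
#' decision-phase value entropy across trials, faceted by run when present.
#'
#' @param object A `sceptic_sim` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sceptic_sim
#' @export
autoplot.sceptic_sim <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("trial", "rt", "rt_vmax", "entropy")],
    -"trial", names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$trial, .data$value,
                                   color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, ncol = 1L, scales = "free_y") +
    ggplot2::guides(color = "none") +
    ggplot2::labs(x = "trial", y = NULL)
}

#' Plot parameter recovery
#'
#' Truth versus estimate per parameter with the identity line.
#'
#' @param object A `sceptic_recovery`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sceptic_recovery
#' @export
autoplot.sceptic_recovery <- function(object, ...) {
  ggplot2::ggplot(object$estimates,
                  ggplot2::aes(.data$truth, .data$estimate)) +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~param, scales = "free") +
    ggplot2::labs(x = "generating value", y = "recovered value")
}

#' Plot a value function over the response interval
#'
#' @param cfg A [basis_config()].
#' @param weights Weight vector.
#' @return A ggplot object.
#' @export
plot_value_function <- function(cfg, weights) {
  v <- value_function(cfg, weights)
  df <- tibble::tibble(time = cfg$bin_centers, value = v)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = rt_vmax(cfg, weights), linetype = 2) +
    ggplot2::labs(x = "response time (s)", y = "expected value")
}
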