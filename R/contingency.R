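#' Reward contingencies of the clock task
#'
#' Builds one of the four monotone reward contingencies that define the task
#' environments: on a trial with response time `t`, reward is delivered with
#' probability `p(t)` and, if delivered, has magnitude `m(t)` points, so the
#' expected value is `ev(t) = p(t) * m(t)`.
#'
#' * **IEV** (increasing expected value) and **DEV** (decreasing expected
#'   value) are learnable: `ev` is strictly increasing/decreasing, so a
#'   value-maximizing agent should shift late/early.
#' * **CEV** (constant expected value) and **CEVR** (CEV reversed) are
#'   unlearnable: `ev` is constant. In CEV the magnitude rises while the
#'   probability falls with time; CEVR reverses that trade-off (probability
#'   rises, magnitude falls).
#'
#' The default functional family is deliberately simple and fully
#' overridable via `ev_params`: magnitudes are affine in `t`, expected value
#' is affine (IEV/DEV) or constant (CEV/CEVR), and `p(t) = ev(t) / m(t)`
#' clipped to `[0.05, 0.95]`. Parameters that would push `p` outside `[0, 1]`
#' before clipping are an error. The defaults put expected value in the
#' 25-65 point range.
#'
#' @param label One of `"IEV"`, `"DEV"`, `"CEV"`, `"CEVR"`.
#' @param interval_length Trial length T in seconds (default 4).
#' @param ev_params Optional named list overriding the default schedule
#'   parameters: for CEV/CEVR `ev` (constant expected value), `m0`, `m_slope`
#'   (magnitude intercept/slope); for IEV/DEV additionally `ev0`, `ev_slope`.
#' @return An object of class `contingency`: a list with `label` and
#'   vectorized functions `p`, `m`, `ev` of time in seconds.
#' @examples
#' cev <- make_contingency("CEV")
#' cev$ev(0.5) / cev$ev(3.5)  # constant expected value
#' @export
make_contingency <- function(label = c("IEV", "DEV", "CEV", "CEVR"),
                             interval_length = 4,
                             ev_params = NULL) {
  label <- match.arg(label)
  defaults <- switch(label,
    IEV  = list(ev0 = 25, ev_slope = 10,  m0 = 50,  m_slope = 25),
    DEV  = list(ev0 = 65, ev_slope = -10, m0 = 150, m_slope = -25),
    CEV  = list(ev = 40, m0 = 50,  m_slope = 25),
    CEVR = list(ev = 40, m0 = 150, m_slope = -25))
  pars <- utils::modifyList(defaults, as.list(ev_params %||% list()))

  m_fun <- local({
    m0 <- pars$m0; m_slope <- pars$m_slope
    function(t) m0 + m_slope * t
  })
  ev_fun <- if (label %in% c("CEV", "CEVR")) {
    local({ ev <- pars$ev; function(t) rep_len(ev, length(t)) })
  } else {
    local({
      ev0 <- pars$ev0; ev_slope <- pars$ev_slope
      function(t) ev0 + ev_slope * t
    })
  }

  # validate on a dense grid: magnitudes positive, raw p inside [0, 1]
  tt <- seq(1e-6, interval_length, length.out = 512L)
  m_grid <- m_fun(tt)
  if (any(m_grid <= 0)) stop("magnitude schedule must be positive on (0, T]")
  p_raw <- ev_fun(tt) / m_grid
  if (any(p_raw < 0 | p_raw > 1)) {
    stop("schedule parameters yield reward probabilities outside [0, 1]")
  }

  p_fun <- function(t) pmin(pmax(ev_fun(t) / m_fun(t), 0.05), 0.95)
  structure(list(label = label,
                 interval_length = interval_length,
                 params = pars,
                 p = p_fun, m = m_fun,
                 ev = function(t) p_fun(t) * m_fun(t)),
            class = "contingency")
}

#' @export
print.contingency <- function(x, ...) {
  tt <- c(0.5, x$interval_length - 0.5)
  cat(sprintf("<contingency %s> on [0, %g] s\n", x$label, x$interval_length))
  cat(sprintf("  p(%g) = %.3f, p(%g) = %.3f; m: %.0f -> %.0f; ev: %.1f -> %.1f\n",
              tt[1], x$p(tt[1]), tt[2], x$p(tt[2]),
              x$m(tt[1]), x$m(tt[2]), x$ev(tt[1]), x$ev(tt[2])))
  invisible(x)
}

#' Plot a contingency's probability, magnitude and expected-value schedules
#'
#' @param object A `contingency`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot contingency
#' @export
autoplot.contingency <- function(object, ...) {
  tt <- seq(0.05, object$interval_length, length.out = 200L)
  df <- tibble::tibble(
    time = rep(tt, 3L),
    schedule = rep(c("p(t)", "m(t)", "ev(t)"), each = length(tt)),
    value = c(object$p(tt), object$m(tt), object$ev(tt)))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~schedule, scales = "free_y") +
    ggplot2::labs(title = paste("Contingency", object$label),
                  x = "response time (s)", y = NULL)
}
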