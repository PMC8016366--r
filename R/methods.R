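# print / tidy / glance / autoplot methods for the result types.

#' @export
print.capture_result <- function(x, ...) {
  cat(sprintf("<capture_result: %s @ %g mV>\n", x$scenario_name,
              1e3 * x$voltage))
  cat(sprintf("  f_a = %.4g Hz  f_e = %.4g Hz  f = %.4g Hz\n",
              x$f_a, x$f_e, x$f))
  cat(sprintf("  tau = %.4g s (approach %.4g s, entrance %.4g s)\n",
              x$tau, x$tau_a, x$tau_e))
  cat(sprintf("  phi(r_e) = %.4g   regime: %s\n", x$phi_e, x$regime))
  invisible(x)
}

#' Tidy a capture result
#'
#' @param x A `"capture_result"`.
#' @param ... Unused.
#' @return `tidy()`: a tibble with columns `quantity`, `value`, `unit`;
#'   `glance()`: a one-row tibble with the main frequencies, times,
#'   potential, regime and competition numbers.
#' @method tidy capture_result
#' @export
tidy.capture_result <- function(x, ...) {
  tibble::tribble(
    ~quantity, ~value, ~unit,
    "f_a", x$f_a, "1/s",
    "f_e", x$f_e, "1/s",
    "f", x$f, "1/s",
    "tau_a", x$tau_a, "s",
    "tau_e", x$tau_e, "s",
    "tau", x$tau, "s",
    "phi_e", x$phi_e, "",
    "k", x$k, "m/s",
    "a2", x$a2, "m^3/s",
    "a2_ep", x$a2_ep, "m^3/s",
    "a2_eo", x$a2_eo, "m^3/s",
    "a3", x$a3, "m^4/s",
    "I", x$I, "A",
    "Q_f", x$Q_f, "m^3/s",
    "b_eo_ep", x$b_eo_ep, "",
    "b_eo_di", x$b_eo_di, ""
  )
}

#' @rdname tidy.capture_result
#' @method glance capture_result
#' @export
glance.capture_result <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario_name, voltage = x$voltage,
    f_a = x$f_a, f_e = x$f_e, f = x$f,
    tau_a = x$tau_a, tau_e = x$tau_e, tau = x$tau,
    phi_e = x$phi_e, regime = x$regime,
    b_eo_ep = x$b_eo_ep, b_eo_di = x$b_eo_di
  )
}

#' Glance at a Brownian-dynamics result
#'
#' @param x A `"bd_result"`.
#' @param ... Unused.
#' @return A one-row tibble with the estimate, its standard error, the
#'   analytic reference value and the walker counts.
#' @method glance bd_result
#' @export
glance.bd_result <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, n = x$n, captured = x$captured,
    estimate = x$estimate, se = x$se,
    analytic = if (is.null(x$analytic)) NA_real_ else x$analytic,
    dt = x$dt
  )
}

#' Plot a voltage sweep
#'
#' Capture, approach and entrance frequencies against voltage on a log
#' frequency axis.
#'
#' @param object A `"capture_sweep"` from [voltage_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot capture_sweep
#' @export
autoplot.capture_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "voltage", "f_a", "f_e", "f"),
    cols = c("f_a", "f_e", "f"),
    names_to = "component", values_to = "frequency"
  )
  long <- dplyr::filter(long, is.finite(.data$frequency),
                        .data$frequency > 0)
  ggplot2::ggplot(long, ggplot2::aes(x = 1e3 * .data$voltage,
                                     y = .data$frequency,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "voltage (mV)", y = "frequency (1/s)",
                  colour = NULL,
                  title = attr(object, "scenario_name")) +
    ggplot2::theme_minimal()
}

#' Plot a current trace with detected events
#'
#' @param object A `"current_trace"`.
#' @param events Optional `"blockade_events"` tibble; blocked intervals are
#'   shaded.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot current_trace
#' @export
autoplot.current_trace <- function(object, events = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$time_s,
                                    y = .data$current_pA)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "current (pA)") +
    ggplot2::theme_minimal()
  if (!is.null(events)) {
    blk <- dplyr::filter(tibble::as_tibble(events), .data$state == "blocked")
    if (nrow(blk)) {
      p <- p + ggplot2::geom_rect(
        data = blk,
        ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                     ymin = -Inf, ymax = Inf),
        inherit.aes = FALSE, alpha = 0.2, fill = "red"
      )
    }
  }
  p
}

#' Plot a stationary concentration profile
#'
#' @param object A `"concentration_profile"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot concentration_profile
#' @export
autoplot.concentration_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$r * 1e9, y = .data$C)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (nm)", y = expression(C(r) ~ (m^-3))) +
    ggplot2::theme_minimal()
}
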