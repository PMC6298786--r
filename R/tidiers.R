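#' Tidy a decay fit
#'
#' @param x A `vsp_decay_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`,
#'   `std.error`). Capped fits report the capped rate with no standard error.
#' @export
tidy.vsp_decay_fit <- function(x, ...) {
  if (x$capped || is.null(x$fit)) {
    return(tibble(
      term = c("k_per_s", "tau_s", "plateau"),
      estimate = c(x$k_per_s, x$tau_s, x$plateau),
      std.error = NA_real_
    ))
  }
  cf <- x$fit$par
  se <- x$se %||% rep(NA_real_, length(cf))
  out <- tibble(term = names(cf), estimate = unname(cf),
    std.error = unname(se))
  k <- out$estimate[out$term == "k"]
  k_se <- out$std.error[out$term == "k"]
  out$term[out$term == "k"] <- "k_per_s"
  out$term[out$term == "C"] <- "plateau"
  dplyr::bind_rows(out, tibble(
    term = "tau_s", estimate = 1 / k, std.error = k_se / k^2 # delta method
  ))
}

#' Glance at a decay fit
#'
#' @param x A `vsp_decay_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `k_per_s`, `tau_s`, `plateau`, `capped`,
#'   `resid_norm`, `n`, `plateau_mode`.
#' @export
glance.vsp_decay_fit <- function(x, ...) {
  tibble(
    k_per_s = x$k_per_s, tau_s = x$tau_s, plateau = x$plateau,
    capped = x$capped, resid_norm = x$resid_norm, n = x$n,
    plateau_mode = x$plateau_mode
  )
}

#' Tidy a Boltzmann fit
#'
#' @param x A `vsp_boltzmann_fit`.
#' @param ... Unused.
#' @return A tibble with one row per component and columns `component`, `A`,
#'   `v_half_mV`, `slope_mV`, `ratio_pct` plus standard errors.
#' @export
tidy.vsp_boltzmann_fit <- function(x, ...) x$params

#' Glance at a Boltzmann fit
#'
#' @param x A `vsp_boltzmann_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n_components`, `n`, `rss`, `resid_norm`, `aicc`.
#' @export
glance.vsp_boltzmann_fit <- function(x, ...) {
  tibble(
    n_components = x$n_components, n = x$n, rss = x$rss,
    resid_norm = x$resid_norm, aicc = x$aicc
  )
}

#' Tidy a kinetics fit
#'
#' @param x A `vsp_kinetics_fit`.
#' @param ... Unused.
#' @return The components tibble (`component`, `A`, `tau_ms`).
#' @export
tidy.vsp_kinetics_fit <- function(x, ...) x$components

#' Glance at a kinetics fit
#'
#' @param x A `vsp_kinetics_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n_components`, `t_half_ms`,
#'   `slow_fraction_pct`, `resid_norm`.
#' @export
glance.vsp_kinetics_fit <- function(x, ...) {
  tibble(
    n_components = x$n_components, t_half_ms = x$t_half_ms,
    slow_fraction_pct = x$slow_fraction_pct, resid_norm = x$resid_norm
  )
}

#' Plot a binding trace
#'
#' Depth and orientation time courses of a binding trace: center-of-mass
#' depths of the phosphatase domain, C2 domain and hydrophobic spine relative
#' to the phosphorus layer (top panel via faceting), and the
#' productive-orientation angle with the productive band.
#'
#' @param object A `vsp_binding_trace` from [analyze_trajectory()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vsp_binding_trace <- function(object, ...) {
  cfg <- attr(object, "config") %||% classifier_config()
  depths <- object |>
    dplyr::select("time_ps", "pd_com_A", "c2_com_A", "spine_com_A") |>
    tidyr::pivot_longer(-"time_ps", names_to = "selection",
      values_to = "depth_A") |>
    dplyr::mutate(panel = "center-of-mass depth (A)",
      value = .data$depth_A)
  angles <- object |>
    dplyr::transmute(.data$time_ps, selection = "angle",
      panel = "orientation angle (deg)", value = .data$angle_deg)
  dat <- dplyr::bind_rows(depths[, c("time_ps", "selection", "panel", "value")],
    angles)
  ggplot2::ggplot(dat, ggplot2::aes(.data$time_ps / 1000, .data$value,
    colour = .data$selection)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(
      data = data.frame(panel = "orientation angle (deg)",
        y = cfg$productive_angle_deg[2]),
      ggplot2::aes(yintercept = .data$y), linetype = 2, colour = "grey40") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (ns)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a decay series and its fit
#'
#' Normalized Kir test-pulse amplitudes against accumulated depolarization
#' time, with the fitted exponential when a fit is supplied.
#'
#' @param object A `vsp_decay_fit` or `vsp_decay_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vsp_decay_fit <- function(object, ...) {
  s <- object$series
  p <- ggplot2::ggplot(s, ggplot2::aes(.data$t_acc_s, .data$i_norm)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "accumulated depolarization time (s)",
      y = "normalized Kir current") +
    ggplot2::theme_minimal()
  tt <- seq(0, max(s$t_acc_s), length.out = 200)
  yy <- (1 - object$plateau) * exp(-object$k_per_s * tt) + object$plateau
  p + ggplot2::geom_line(data = data.frame(t_acc_s = tt, i_norm = yy),
    colour = "firebrick")
}

#' @rdname autoplot.vsp_decay_fit
#' @export
autoplot.vsp_decay_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t_acc_s, .data$i_norm)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "accumulated depolarization time (s)",
      y = "normalized Kir current") +
    ggplot2::theme_minimal()
}

#' Plot an F-V curve and its Boltzmann decomposition
#'
#' Data points with the fitted curve; for two-component fits the individual
#' components are drawn separately.
#'
#' @param object A `vsp_boltzmann_fit` (or a plain `vsp_fv` tibble).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vsp_boltzmann_fit <- function(object, ...) {
  vv <- seq(min(object$data$v_mV), max(object$data$v_mV), length.out = 300)
  total <- data.frame(v_mV = vv, f = boltzmann_eval(vv, object$params),
    component = "fit")
  p <- ggplot2::ggplot(object$data, ggplot2::aes(.data$v_mV, .data$f)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = total, colour = "black") +
    ggplot2::labs(x = "membrane potential (mV)", y = "F") +
    ggplot2::theme_minimal()
  if (object$n_components == 2) {
    comps <- purrr::map_dfr(1:2, function(i) {
      data.frame(v_mV = vv, f = boltzmann_eval(vv, object$params[i, ]),
        component = paste("component", i))
    })
    p <- p + ggplot2::geom_line(
      data = comps,
      ggplot2::aes(colour = .data$component)) +
      ggplot2::labs(colour = NULL)
  }
  p
}

#' @rdname autoplot.vsp_boltzmann_fit
#' @export
autoplot.vsp_fv <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$v_mV, .data$f)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "membrane potential (mV)", y = "F") +
    ggplot2::theme_minimal()
}

#' Plot an activity-property association
#'
#' Per-residue phosphatase activity against the side-chain property, with the
#' least-squares line.
#'
#' @param object A `vsp_association` from [correlate_activity_property()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vsp_association <- function(object, ...) {
  ggplot2::ggplot(object$data,
    ggplot2::aes(.data[[object$property]], .data$k_per_s)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
      colour = "firebrick") +
    ggplot2::labs(x = object$property, y = "phosphatase activity (1/s)") +
    ggplot2::theme_minimal()
}
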