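#' Extract a fluorescence-voltage (F-V) relationship
#'
#' Reduces a set of voltage-clamp fluorometry sweeps (one Delta-F/F time
#' series per test voltage) to one point per voltage, using one of the
#' extraction strategies in routine use:
#'
#' * `"last_1ms_mean"` — mean of the final 1 ms of the test pulse (robust
#'   steady-state readout for slow probes such as G214C-TMRM);
#' * `"endpoint"` — the last sample inside the pulse (used for Anap traces
#'   that have not plateaued);
#' * `"at_reference_peak_time"` — the value of every trace at the time the
#'   reference-voltage trace peaks (used for Q208C-TMRM, whose transient
#'   signal peaks before the pulse ends), with linear interpolation between
#'   samples.
#'
#' Optionally all points are normalized to the value at `reference_mV`
#' (normalization is applied even when the curve has not saturated there; the
#' flag is recorded in the result's attributes).
#'
#' @param sweeps Tidy tibble: `voltage_mV`, `time_ms`, `df_over_f`.
#' @param strategy Extraction strategy (above).
#' @param pulse_ms Two-element start/end of the test pulse, ms.
#' @param reference_mV Reference voltage for normalization and for the peak
#'   time lookup.
#' @param normalize Divide all points by the value at `reference_mV`.
#' @return A tibble of class `vsp_fv` with columns `v_mV`, `f`, sorted by
#'   voltage; attributes `strategy`, `normalized`, `reference_mV`.
#' @export
extract_fv <- function(sweeps,
                       strategy = c("last_1ms_mean", "endpoint",
                         "at_reference_peak_time"),
                       pulse_ms = c(50, 550),
                       reference_mV = 200,
                       normalize = FALSE) {
  strategy <- match.arg(strategy)
  if (pulse_ms[1] < min(sweeps$time_ms) - 1e-9 ||
      pulse_ms[2] > max(sweeps$time_ms) + 1e-9) {
    abort("pulse window lies outside the sweeps", class = "vsp_protocol_error")
  }
  traces <- split(sweeps, sweeps$voltage_mV)
  volts <- as.numeric(names(traces))

  ref_time <- NULL
  if (strategy == "at_reference_peak_time") {
    ref <- traces[[as.character(reference_mV)]]
    if (is.null(ref)) {
      abort(sprintf("reference trace at %g mV is missing", reference_mV),
        class = "vsp_parameter_error")
    }
    inwin <- ref$time_ms >= pulse_ms[1] & ref$time_ms <= pulse_ms[2]
    base <- ref$df_over_f[which.min(abs(ref$time_ms - pulse_ms[1]))]
    dev <- abs(ref$df_over_f - base)
    dev[!inwin] <- -Inf
    ref_time <- ref$time_ms[which.max(dev)]
  }

  f <- vapply(traces, function(tr) {
    switch(strategy,
      last_1ms_mean = {
        sel <- tr$time_ms >= pulse_ms[2] - 1 - 1e-9 & tr$time_ms <= pulse_ms[2] + 1e-9
        mean(tr$df_over_f[sel])
      },
      endpoint = {
        sel <- tr$time_ms <= pulse_ms[2] + 1e-9
        tr$df_over_f[max(which(sel))]
      },
      at_reference_peak_time =
        approx(tr$time_ms, tr$df_over_f, xout = ref_time)$y
    )
  }, numeric(1))

  if (normalize) {
    i_ref <- match(reference_mV, volts)
    if (is.na(i_ref)) {
      abort(sprintf("no trace at the reference voltage %g mV", reference_mV),
        class = "vsp_parameter_error")
    }
    if (f[i_ref] == 0) {
      abort("value at the reference voltage is zero; cannot normalize",
        class = "vsp_normalization_error")
    }
    f <- f / f[i_ref]
  }
  ord <- order(volts)
  out <- tibble(v_mV = volts[ord], f = unname(f)[ord])
  structure(out, class = c("vsp_fv", class(out)),
    strategy = strategy, normalized = normalize, reference_mV = reference_mV)
}

#' Evaluate a sum of Boltzmann components
#'
#' `F(V) = sum_i A_i / (1 + exp((V - Vhalf_i) / slope_i))`. With positive
#' slope each component falls from `A_i` at hyperpolarized potentials to 0 at
#' depolarized potentials; the direction of the fluorescence change is carried
#' by the sign of `A_i`.
#'
#' @param v Voltages, mV.
#' @param components Tibble/data frame with columns `A`, `v_half_mV`,
#'   `slope_mV`.
#' @return Numeric vector of F values.
#' @export
boltzmann_eval <- function(v, components) {
  out <- numeric(length(v))
  for (i in seq_len(nrow(components))) {
    out <- out + components$A[i] /
      (1 + exp((v - components$v_half_mV[i]) / components$slope_mV[i]))
  }
  out
}

# deterministic multi-start grid around a base start (16 variants)
.boltzmann_starts <- function(base, n_components, v_range) {
  if (n_components == 1) {
    jit <- expand.grid(dv = c(0, -20, 20, -40), fs = c(1, 0.5, 2, 4))
    lapply(seq_len(nrow(jit)), function(i) {
      s <- base
      s$v1 <- s$v1 + jit$dv[i]
      s$ls1 <- s$ls1 + log(jit$fs[i])
      s
    })
  } else {
    jit <- expand.grid(dv = c(0, -15, 15, 30), r1 = c(0.25, 0.5, 0.75, 0.1))
    lapply(seq_len(nrow(jit)), function(i) {
      s <- base
      tot <- s$A1 + s$A2
      s$A1 <- tot * jit$r1[i]
      s$A2 <- tot * (1 - jit$r1[i])
      s$v1 <- s$v1 - jit$dv[i]
      s$v2 <- s$v2 + jit$dv[i]
      s
    })
  }
}

.fv_half_crossing <- function(v, f, level) {
  s <- (f - level)
  idx <- which(s[-1] * s[-length(s)] <= 0)
  if (!length(idx)) return(stats::median(v))
  i <- idx[1]
  if (s[i + 1] == s[i]) return(v[i])
  v[i] + (v[i + 1] - v[i]) * (level - f[i]) / (f[i + 1] - f[i])
}

#' Fit one or two Boltzmann components to an F-V curve
#'
#' Nonlinear least-squares fit of `F(V) = sum_i A_i / (1 + exp((V -
#' Vhalf_i)/slope_i))` with 1 or 2 components. Slopes are constrained positive
#' (log-parametrized); amplitudes are free in sign. Initial half-maximum
#' potentials are seeded from half-amplitude crossings of the data, and a
#' deterministic grid of 16 start variants guards against local minima; the
#' best converged start by residual sum of squares wins.
#'
#' For two components the result is ordered `v_half_1 < v_half_2` and, when
#' the amplitudes share a sign, each component's contribution ratio
#' `A_i / (A_1 + A_2) * 100` (%) is reported.
#'
#' @param fv An F-V tibble (`v_mV`, `f`), e.g. from [extract_fv()].
#' @param n_components 1 or 2.
#' @param max_starts Cap on the number of start variants tried.
#' @return An object of class `vsp_boltzmann_fit`: `$params` (tibble with
#'   `component`, `A`, `v_half_mV`, `slope_mV`, `ratio_pct` and standard
#'   errors), `$rss`, `$resid_norm`, `$aicc`, `$n`, `$vcov`, the `nls` object
#'   and the data. Supports [tidy()], [glance()], [autoplot()].
#' @examples
#' comps <- tibble::tibble(A = c(0.243, 0.757), v_half_mV = c(27.1, 82.7),
#'                         slope_mV = c(10, 15))
#' fv <- tibble::tibble(v_mV = seq(-60, 200, 20),
#'                      f = boltzmann_eval(seq(-60, 200, 20), comps))
#' fit_boltzmann(fv, 2)$params
#' @export
fit_boltzmann <- function(fv, n_components = 1, max_starts = 16) {
  stopifnot(n_components %in% c(1, 2))
  v <- fv$v_mV
  f <- fv$f
  n <- length(v)
  if (n < 2 * 2 * n_components) {
    abort(sprintf("need at least %d points for a %d-component fit",
      4 * n_components, n_components), class = "vsp_fit_error")
  }
  if (diff(range(f)) < 1e-12 * max(1, max(abs(f)))) {
    abort("flat F-V data: fit is degenerate", class = "vsp_degenerate_fit")
  }
  a_tot <- f[which.min(v)] - f[which.max(v)] + f[which.max(v)] # ~ total A
  if (abs(a_tot) < 1e-12) a_tot <- diff(range(f))
  slope0 <- diff(range(v)) / 10

  if (n_components == 1) {
    base <- list(A1 = a_tot, v1 = .fv_half_crossing(v, f, a_tot / 2),
      ls1 = log(slope0))
    form <- f ~ A1 / (1 + exp((v - v1) / exp(ls1)))
  } else {
    base <- list(
      A1 = 0.3 * a_tot, A2 = 0.7 * a_tot,
      v1 = .fv_half_crossing(v, f, 0.75 * a_tot),
      v2 = .fv_half_crossing(v, f, 0.25 * a_tot),
      ls1 = log(slope0 * 0.6), ls2 = log(slope0)
    )
    form <- f ~ A1 / (1 + exp((v - v1) / exp(ls1))) +
      A2 / (1 + exp((v - v2) / exp(ls2)))
  }
  starts <- utils::head(.boltzmann_starts(base, n_components, range(v)), max_starts)
  dat <- data.frame(v = v, f = f)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = s,
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    abort("Boltzmann fit failed to converge from any start",
      class = "vsp_fit_error")
  }
  fit <- best$fit
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, length(cf)))
  names(se) <- names(cf)
  comp <- if (n_components == 1) {
    tibble(component = 1L, A = cf[["A1"]], v_half_mV = cf[["v1"]],
      slope_mV = exp(cf[["ls1"]]),
      A_se = se[["A1"]], v_half_se = se[["v1"]],
      slope_se = exp(cf[["ls1"]]) * se[["ls1"]],
      ratio_pct = 100)
  } else {
    out <- tibble(
      component = 1:2,
      A = c(cf[["A1"]], cf[["A2"]]),
      v_half_mV = c(cf[["v1"]], cf[["v2"]]),
      slope_mV = exp(c(cf[["ls1"]], cf[["ls2"]])),
      A_se = c(se[["A1"]], se[["A2"]]),
      v_half_se = c(se[["v1"]], se[["v2"]]),
      slope_se = exp(c(cf[["ls1"]], cf[["ls2"]])) * c(se[["ls1"]], se[["ls2"]])
    )
    out <- out[order(out$v_half_mV), ]
    out$component <- 1:2
    out$ratio_pct <- if (prod(sign(out$A)) > 0) {
      100 * out$A / sum(out$A)
    } else {
      rep(NA_real_, 2)
    }
    out
  }
  p <- length(cf) + 1
  rss <- best$rss
  aicc <- n * log(rss / n) + 2 * p +
    if (n - p - 1 > 0) 2 * p * (p + 1) / (n - p - 1) else Inf
  structure(list(
    n_components = n_components, params = comp,
    rss = rss, resid_norm = sqrt(rss), n = n, n_par = length(cf),
    aicc = aicc, vcov = tryCatch(vcov(fit), error = function(e) NULL),
    fit = fit, data = tibble(v_mV = v, f = f)
  ), class = "vsp_boltzmann_fit")
}

#' @export
print.vsp_boltzmann_fit <- function(x, ...) {
  cat(sprintf("<vsp_boltzmann_fit> %d component(s), n = %d, resid norm = %.3g, AICc = %.3g\n",
    x$n_components, x$n, x$resid_norm, x$aicc))
  print(x$params)
  invisible(x)
}

#' Predict from a Boltzmann fit
#' @param object A `vsp_boltzmann_fit`.
#' @param newdata Optional tibble with `v_mV`.
#' @param ... Unused.
#' @return Fitted F values.
#' @export
predict.vsp_boltzmann_fit <- function(object, newdata = NULL, ...) {
  v <- if (is.null(newdata)) object$data$v_mV else newdata$v_mV
  boltzmann_eval(v, object$params)
}

#' Choose between one- and two-component Boltzmann fits
#'
#' Fits both models and selects by small-sample-corrected AIC (default) or by
#' the extra-sum-of-squares F-test at level `alpha`. Both criteria are
#' reported; if the two-component fit fails to converge the single component
#' is selected.
#'
#' @param fv An F-V tibble (`v_mV`, `f`).
#' @param criterion `"aicc"` or `"ftest"`.
#' @param alpha F-test level.
#' @return A list of class `vsp_model_selection`: `n_components`, `criterion`,
#'   `aicc_1`, `aicc_2`, `f_statistic`, `f_p_value`, and both fits (`fit1`,
#'   `fit2`).
#' @export
select_model <- function(fv, criterion = c("aicc", "ftest"), alpha = 0.05) {
  criterion <- match.arg(criterion)
  fit1 <- fit_boltzmann(fv, 1)
  fit2 <- tryCatch(fit_boltzmann(fv, 2), error = function(e) NULL)
  f_stat <- f_p <- NA_real_
  if (!is.null(fit2)) {
    df1 <- fit1$n - fit1$n_par
    df2 <- fit2$n - fit2$n_par
    if (df2 > 0 && fit2$rss > 0) {
      f_stat <- ((fit1$rss - fit2$rss) / (df1 - df2)) / (fit2$rss / df2)
      f_p <- stats::pf(f_stat, df1 - df2, df2, lower.tail = FALSE)
    }
  }
  choice <- if (is.null(fit2)) {
    1L
  } else if (criterion == "aicc") {
    if (fit2$aicc < fit1$aicc) 2L else 1L
  } else {
    if (is.finite(f_p) && f_p < alpha) 2L else 1L
  }
  structure(list(
    n_components = choice, criterion = criterion,
    aicc_1 = fit1$aicc, aicc_2 = if (is.null(fit2)) NA_real_ else fit2$aicc,
    f_statistic = f_stat, f_p_value = f_p,
    fit1 = fit1, fit2 = fit2
  ), class = "vsp_model_selection")
}

#' @export
print.vsp_model_selection <- function(x, ...) {
  cat(sprintf(
    "<vsp_model_selection> chose %d component(s) by %s (AICc 1: %.3g, 2: %.3g; F p = %.3g)\n",
    x$n_components, x$criterion, x$aicc_1, x$aicc_2, x$f_p_value
  ))
  invisible(x)
}

#' Time to half-maximum change
#'
#' First time, measured from the start of the analysis window, at which a
#' trace crosses halfway between its baseline (the value at the window start,
#' or a supplied baseline) and its extremum within the window, with linear
#' interpolation between samples.
#'
#' @param trace Tibble with `time_ms` and `value` columns.
#' @param window Two-element analysis window, ms.
#' @param baseline Optional baseline value; defaults to the trace value at the
#'   window start.
#' @param value_col Name of the value column.
#' @return t-half in ms (relative to the window start).
#' @export
compute_t_half <- function(trace, window = range(trace$time_ms),
                           baseline = NULL, value_col = "value") {
  t <- trace$time_ms
  y <- trace[[value_col]]
  sel <- t >= window[1] - 1e-9 & t <= window[2] + 1e-9
  t <- t[sel]
  y <- y[sel]
  if (length(t) < 2) abort("analysis window contains fewer than 2 samples",
    class = "vsp_protocol_error")
  if (is.null(baseline)) baseline <- y[1]
  ext <- y[which.max(abs(y - baseline))]
  if (abs(ext - baseline) < .Machine$double.eps) {
    abort("trace never departs from baseline; no half-maximum crossing",
      class = "vsp_fit_error")
  }
  target <- baseline + 0.5 * (ext - baseline)
  s <- y - target
  dir <- sign(ext - baseline)
  cross <- which(dir * s[-1] >= 0 & dir * s[-length(s)] < 0)
  if (dir * s[1] >= 0) return(0)
  if (!length(cross)) {
    abort("trace never crosses the half-maximum level", class = "vsp_fit_error")
  }
  i <- cross[1]
  t_cross <- t[i] + (t[i + 1] - t[i]) * (target - y[i]) / (y[i + 1] - y[i])
  t_cross - window[1]
}

#' Fit fluorescence relaxation kinetics
#'
#' Fits a sum of saturating exponentials `F(t) = sum_i A_i * (1 -
#' exp(-t/tau_i))` (t measured from pulse onset) to a fluorescence trace, with
#' 1 or 2 components. Time constants are log-parametrized (positive); for two
#' components the result is ordered `tau_fast < tau_slow` and the slow
#' fraction `|A_slow| / (|A_fast| + |A_slow|) * 100` (%) is reported, along
#' with the time to half-maximum of the trace.
#'
#' @param trace Tibble with `time_ms` and `value` columns.
#' @param n_components 1 or 2.
#' @param onset_ms Pulse onset; samples before it are ignored.
#' @param value_col Name of the value column.
#' @return An object of class `vsp_kinetics_fit`: `$components` (tibble with
#'   `component`, `A`, `tau_ms`), `$slow_fraction_pct`, `$t_half_ms`,
#'   `$resid_norm`, the `nls` object and the data.
#' @export
fit_fluorescence_kinetics <- function(trace, n_components = 1, onset_ms = 0,
                                      value_col = "value") {
  stopifnot(n_components %in% c(1, 2))
  sel <- trace$time_ms >= onset_ms - 1e-9
  t <- trace$time_ms[sel] - onset_ms
  y <- trace[[value_col]][sel]
  if (length(t) < 4 * n_components) {
    abort(sprintf("need at least %d samples after onset", 4 * n_components),
      class = "vsp_fit_error")
  }
  a_end <- y[length(y)]
  if (abs(a_end) < .Machine$double.eps) a_end <- max(abs(y)) * sign(y[which.max(abs(y))])
  th <- tryCatch(
    compute_t_half(tibble(time_ms = t, value = y), c(0, max(t))),
    error = function(e) max(t) / 10
  )
  tau0 <- max(th / log(2), diff(range(t)) / 100)
  dat <- data.frame(t = t, y = y)
  fit <- if (n_components == 1) {
    minpack.lm::nlsLM(y ~ A1 * (1 - exp(-t / exp(lt1))),
      data = dat, start = list(A1 = a_end, lt1 = log(tau0)),
      control = minpack.lm::nls.lm.control(maxiter = 300))
  } else {
    minpack.lm::nlsLM(
      y ~ A1 * (1 - exp(-t / exp(lt1))) + A2 * (1 - exp(-t / exp(lt2))),
      data = dat,
      start = list(A1 = 0.9 * a_end, A2 = 0.1 * a_end,
        lt1 = log(tau0), lt2 = log(tau0 * 10)),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  cf <- coef(fit)
  comps <- if (n_components == 1) {
    tibble(component = 1L, A = cf[["A1"]], tau_ms = exp(cf[["lt1"]]))
  } else {
    out <- tibble(component = 1:2, A = c(cf[["A1"]], cf[["A2"]]),
      tau_ms = exp(c(cf[["lt1"]], cf[["lt2"]])))
    out <- out[order(out$tau_ms), ]
    out$component <- 1:2
    out
  }
  slow_frac <- if (n_components == 2) {
    100 * abs(comps$A[2]) / sum(abs(comps$A))
  } else {
    NA_real_
  }
  structure(list(
    n_components = n_components, components = comps,
    slow_fraction_pct = slow_frac,
    t_half_ms = th,
    resid_norm = sqrt(sum(resid(fit)^2)),
    fit = fit, data = tibble(time_ms = t, value = y)
  ), class = "vsp_kinetics_fit")
}

#' @export
print.vsp_kinetics_fit <- function(x, ...) {
  cat(sprintf("<vsp_kinetics_fit> %d component(s), t_half = %.3g ms%s\n",
    x$n_components, x$t_half_ms,
    if (!is.na(x$slow_fraction_pct)) {
      sprintf(", slow fraction = %.1f%%", x$slow_fraction_pct)
    } else ""))
  print(x$components)
  invisible(x)
}
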