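#' Kir test-pulse protocol description
#'
#' Describes the segment layout of an episodic two-electrode voltage-clamp
#' sweep used to read out voltage-dependent phosphatase activity: a ramp pulse
#' to confirm the inward Kir current, a test pulse at -120 mV whose end-point
#' amplitude reports the PI(4,5)P2 level, and a depolarization pulse at
#' +50 mV that activates the phosphatase. The protocol is repeated over
#' episodes; the accumulated depolarization time is the x-axis of the decay
#' analysis.
#'
#' @param depol_duration_ms Depolarization pulse length (300 ms in the
#'   standard protocol, 50 ms in the short protocol for fast constructs).
#' @param ramp_ms,test_ms,depol_ms Two-element start/end times of each
#'   segment, ms from sweep start. Defaults place the ramp at 0-50 ms, the
#'   test pulse at 50-100 ms and the depolarization immediately after.
#' @param test_mV,depol_mV,holding_mV Segment voltages, mV.
#' @param dt_ms Sampling interval, ms.
#' @return A list of class `vsp_protocol`.
#' @export
kir_protocol <- function(depol_duration_ms = 300,
                         ramp_ms = c(0, 50),
                         test_ms = c(50, 100),
                         depol_ms = c(100, 100 + depol_duration_ms),
                         test_mV = -120, depol_mV = 50, holding_mV = -60,
                         dt_ms = 0.2) {
  stopifnot(depol_duration_ms > 0,
    ramp_ms[2] <= test_ms[1], test_ms[2] <= depol_ms[1])
  structure(list(
    ramp_ms = ramp_ms, test_ms = test_ms, depol_ms = depol_ms,
    depol_duration_ms = depol_duration_ms,
    test_mV = test_mV, depol_mV = depol_mV, holding_mV = holding_mV,
    dt_ms = dt_ms
  ), class = "vsp_protocol")
}

#' Test-pulse amplitude of one episode
#'
#' Steady-state current amplitude of an episode, read as the mean current over
#' the final `averaging_ms` of the test-pulse window (end-point averaging is
#' more noise robust than the literal last sample).
#'
#' @param episode A tibble with `time_ms` and `current_uA` for one sweep.
#' @param protocol A [kir_protocol()].
#' @param averaging_ms Averaging window at the end of the test pulse, ms. Use
#'   one sample period to take the end-point sample itself.
#' @return Amplitude in microamps (signed; inward currents are negative).
#' @export
extract_test_amplitude <- function(episode, protocol, averaging_ms = 2) {
  tw <- protocol$test_ms
  if (tw[1] < min(episode$time_ms) - 1e-9 ||
      tw[2] > max(episode$time_ms) + 1e-9) {
    abort("test-pulse window lies outside the sweep", class = "vsp_protocol_error")
  }
  sel <- episode$time_ms >= tw[2] - averaging_ms - 1e-9 &
    episode$time_ms <= tw[2] + 1e-9
  if (!any(sel)) abort("no samples inside the averaging window",
    class = "vsp_protocol_error")
  mean(episode$current_uA[sel])
}

#' Normalized decay series over accumulated depolarization time
#'
#' Extracts per-episode test-pulse amplitudes, normalizes them to the first
#' episode, and lays them out against accumulated depolarization time
#' (episode 1 at 0 s, episode i at `(i - 1) * depol_duration`). The decay of
#' this series is the phosphatase-activity readout.
#'
#' @param recording A tidy recording tibble with columns `episode`, `time_ms`,
#'   `current_uA` (at least 2 episodes).
#' @param protocol A [kir_protocol()]; taken from the recording's `protocol`
#'   attribute when `NULL`.
#' @param averaging_ms Passed to [extract_test_amplitude()].
#' @param expected_sign Optional `-1` or `1`; error if the first amplitude has
#'   the opposite sign (inward Kir currents are negative).
#' @return A tibble of class `vsp_decay_series` with columns `episode`,
#'   `t_acc_s`, `amp_uA`, `i_norm`.
#' @export
build_decay_series <- function(recording, protocol = NULL, averaging_ms = 2,
                               expected_sign = NULL) {
  protocol <- protocol %||% attr(recording, "protocol")
  if (is.null(protocol)) abort("no protocol supplied", class = "vsp_protocol_error")
  eps <- split(recording, recording$episode)
  if (length(eps) < 2) abort("need at least 2 episodes", class = "vsp_protocol_error")
  amps <- vapply(eps, extract_test_amplitude, numeric(1),
    protocol = protocol, averaging_ms = averaging_ms)
  if (amps[1] == 0) {
    abort("first test-pulse amplitude is zero; cannot normalize",
      class = "vsp_normalization_error")
  }
  if (!is.null(expected_sign) && sign(amps[1]) != sign(expected_sign)) {
    abort("first test-pulse amplitude has unexpected sign",
      class = "vsp_normalization_error")
  }
  idx <- seq_along(amps)
  out <- tibble(
    episode = as.integer(names(eps)),
    t_acc_s = (idx - 1) * protocol$depol_duration_ms / 1000,
    amp_uA = unname(amps),
    i_norm = unname(amps / amps[1])
  )
  structure(out, class = c("vsp_decay_series", class(out)), protocol = protocol)
}

#' Fit the phosphatase-activity decay rate
#'
#' Fits `I(t) = (1 - C) * exp(-k * t) + C` to a normalized decay series by
#' nonlinear least squares (plateau `C` free in `[0, 1)` by default, or fixed
#' to zero). The rate constant `k` is the voltage-dependent phosphatase
#' activity proxy; `tau = 1/k`.
#'
#' Capping rule: when the second episode's normalized amplitude is below
#' `cap_threshold` (1% of the first episode) the decay is too fast to resolve
#' with the protocol, so fitting is skipped and the result is capped at the
#' conventional values `tau = 0.065 s`, `k = 15.4 s^-1` (the reported pair;
#' 15.4 is 1/0.065 at the reported precision).
#'
#' @param series A `vsp_decay_series` (or tibble with `t_acc_s`, `i_norm`).
#' @param plateau `"free"` (default) or `"zero"` (pure exponential).
#' @param cap_threshold Second-episode fraction below which the cap applies.
#' @param cap_tau_s Capped time constant, s.
#' @param cap_k_per_s Capped rate constant, 1/s.
#' @return An object of class `vsp_decay_fit`: fields `k_per_s`, `tau_s`,
#'   `plateau`, `capped`, `resid_norm`, `n`, plus the underlying `nls` fit
#'   (`NULL` when capped). Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' s <- tibble::tibble(t_acc_s = seq(0, 5.7, by = 0.3),
#'                     i_norm = exp(-5 * seq(0, 5.7, by = 0.3)))
#' fit_decay(s)$k_per_s
#' @export
fit_decay <- function(series, plateau = c("free", "zero"),
                      cap_threshold = 0.01, cap_tau_s = 0.065,
                      cap_k_per_s = 15.4) {
  plateau <- match.arg(plateau)
  stopifnot(nrow(series) >= 4, abs(series$i_norm[1] - 1) < 1e-8)
  t <- series$t_acc_s
  y <- series$i_norm
  if (y[2] < cap_threshold) {
    return(structure(list(
      k_per_s = cap_k_per_s, tau_s = cap_tau_s, plateau = 0,
      capped = TRUE, resid_norm = NA_real_, n = length(y),
      plateau_mode = plateau, fit = NULL, series = series
    ), class = "vsp_decay_fit"))
  }
  if (y[length(y)] >= y[1]) {
    warn("decay series does not decay; rate constant will be near zero")
  }
  c0 <- max(0, min(0.9, min(y) - 0.01))
  yy <- pmax((y - c0) / (1 - c0), 1e-6)
  k0 <- max(1e-3, -unname(coef(lm(log(yy) ~ t))[2]))
  # raw Levenberg-Marquardt: for slow decays over a short span the (k, C)
  # Jacobian columns are nearly collinear and nls-style fitters reject the
  # start; LM damping handles that regime.
  model_f <- if (plateau == "free") {
    function(p) (1 - p[2]) * exp(-p[1] * t) + p[2]
  } else {
    function(p) exp(-p[1] * t)
  }
  par0 <- if (plateau == "free") c(k = k0, C = c0) else c(k = k0)
  lower <- if (plateau == "free") c(1e-8, 0) else 1e-8
  upper <- if (plateau == "free") c(Inf, 1 - 1e-8) else Inf
  fit <- minpack.lm::nls.lm(
    par = par0, fn = function(p) y - model_f(p),
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  cf <- fit$par
  se <- tryCatch({
    s2 <- sum(fit$fvec^2) / max(1, length(y) - length(cf))
    sqrt(diag(s2 * solve(fit$hessian)))
  }, error = function(e) rep(NA_real_, length(cf)))
  structure(list(
    k_per_s = unname(cf[["k"]]),
    tau_s = 1 / unname(cf[["k"]]),
    plateau = if (plateau == "free") unname(cf[["C"]]) else 0,
    capped = FALSE,
    se = setNames(se, names(cf)),
    resid_norm = sqrt(sum(fit$fvec^2)),
    n = length(y), plateau_mode = plateau,
    fit = fit, series = series
  ), class = "vsp_decay_fit")
}

#' @export
print.vsp_decay_fit <- function(x, ...) {
  cat(sprintf(
    "<vsp_decay_fit> k = %.4g 1/s (tau = %.4g s), plateau = %.3g, %s, n = %d\n",
    x$k_per_s, x$tau_s, x$plateau,
    if (x$capped) "CAPPED (2nd episode < 1%)" else
      sprintf("resid norm = %.3g", x$resid_norm),
    x$n
  ))
  invisible(x)
}

#' Off-sensing charge by P/N subtraction and integration
#'
#' Estimates the gating (sensing) charge moved during a repolarization step.
#' Leak and symmetric capacitive currents are removed by a P/N protocol: the
#' `n_sub` subsweeps, each driven at 1/`pn_order` of the step amplitude, are
#' summed and scaled by `pn_order / n_sub`, then subtracted from the main
#' sweep. The residual is baseline-corrected by the mean over the
#' `baseline_ms` preceding the step and integrated over the transient
#' (1 uA * ms = 1 nC).
#'
#' The integration window runs from the step onset to the first sample (after
#' the transient peak) at which the residual has decayed below 1% of its peak,
#' or to `window_end_ms`, whichever comes first; set `adaptive = FALSE` to
#' always use the full fixed window.
#'
#' @param sweep Main sweep tibble: `time_ms`, `current_uA`.
#' @param pn_sweeps Subsweep tibble: `sub`, `time_ms`, `current_uA`; all
#'   subsweeps and the main sweep must share the same timebase.
#' @param step_onset_ms Time of the repolarization step.
#' @param pn_order The N of P/N (between 4 and 8).
#' @param window_end_ms End of the admissible integration window, ms.
#' @param baseline_ms Length of the pre-step baseline window, ms.
#' @param adaptive Stop integrating once the transient has decayed to <1% of
#'   its peak.
#' @return A one-row tibble: `q_off_nC` (magnitude), `q_signed_nC`,
#'   `pn_order`, `t_start_ms`, `t_end_ms`, `baseline_uA`, `peak_uA`.
#' @export
integrate_off_sensing_charge <- function(sweep, pn_sweeps, step_onset_ms,
                                         pn_order = 4,
                                         window_end_ms = max(sweep$time_ms),
                                         baseline_ms = 5,
                                         adaptive = TRUE) {
  if (pn_order < 4 || pn_order > 8) {
    abort("pn_order must be between 4 and 8", class = "vsp_protocol_error")
  }
  subs <- split(pn_sweeps, pn_sweeps$sub)
  n_sub <- length(subs)
  for (s in subs) {
    if (length(s$time_ms) != length(sweep$time_ms) ||
        max(abs(s$time_ms - sweep$time_ms)) > 1e-9) {
      abort("subsweep timebase does not match the main sweep",
        class = "vsp_protocol_error")
    }
  }
  leak <- Reduce(`+`, lapply(subs, function(s) s$current_uA)) * pn_order / n_sub
  corrected <- sweep$current_uA - leak
  t <- sweep$time_ms
  base_sel <- t >= step_onset_ms - baseline_ms & t < step_onset_ms
  if (!any(base_sel)) abort("no samples in the baseline window",
    class = "vsp_protocol_error")
  baseline <- mean(corrected[base_sel])
  if (sd(corrected[base_sel]) > 0.05 * max(abs(corrected - baseline))) {
    warn("unstable pre-step baseline; charge estimate may drift")
  }
  corrected <- corrected - baseline
  win <- t >= step_onset_ms & t <= window_end_ms
  tw <- t[win]
  iw <- corrected[win]
  t_end <- window_end_ms
  if (adaptive && length(iw) > 2) {
    ipk <- which.max(abs(iw))
    below <- which(abs(iw) < 0.01 * abs(iw[ipk]))
    below <- below[below > ipk]
    if (length(below)) {
      t_end <- tw[below[1]]
      keep <- tw <= t_end
      tw <- tw[keep]
      iw <- iw[keep]
    }
  }
  q <- sum(diff(tw) * (head(iw, -1) + tail(iw, -1)) / 2) # trapezoid, uA*ms = nC
  tibble(
    q_off_nC = abs(q), q_signed_nC = q, pn_order = pn_order,
    t_start_ms = step_onset_ms, t_end_ms = t_end,
    baseline_uA = baseline, peak_uA = iw[which.max(abs(iw))]
  )
}

#' Association between phosphatase activity and a side-chain property
#'
#' Pairs per-residue activities (decay rate constants) with a side-chain
#' property (e.g., Hessa-scale transfer free energy in kcal/mol, or side-chain
#' volume in cubic Angstrom) and reports Pearson and Spearman coefficients
#' together with the paired series for plotting.
#'
#' @param activities Tibble with columns `residue` and `k_per_s`.
#' @param properties Tibble with column `residue` and the property column.
#' @param property Name of the property column in `properties`.
#' @return A list of class `vsp_association`: `$data` (joined tibble) and
#'   `$stats` (one-row tibble with `n`, `pearson_r`, `pearson_p`,
#'   `spearman_rho`, `spearman_p`; coefficients are `NA` with a note when a
#'   series is constant).
#' @export
correlate_activity_property <- function(activities, properties,
                                        property = "hydrophobicity") {
  if (!property %in% names(properties)) {
    abort(sprintf("column '%s' not found in `properties`", property),
      class = "vsp_parameter_error")
  }
  data <- dplyr::inner_join(
    dplyr::select(activities, "residue", "k_per_s"),
    dplyr::select(properties, "residue", dplyr::all_of(property)),
    by = "residue"
  )
  if (nrow(data) < 3) {
    abort("need at least 3 overlapping residues", class = "vsp_parameter_error")
  }
  x <- data[[property]]
  y <- data$k_per_s
  degenerate <- sd(x) == 0 || sd(y) == 0
  stats <- if (degenerate) {
    tibble(n = nrow(data), pearson_r = NA_real_, pearson_p = NA_real_,
      spearman_rho = NA_real_, spearman_p = NA_real_,
      note = "constant series; correlation undefined")
  } else {
    pe <- cor.test(x, y, method = "pearson")
    sp <- suppressWarnings(cor.test(x, y, method = "spearman"))
    tibble(n = nrow(data), pearson_r = unname(pe$estimate),
      pearson_p = pe$p.value, spearman_rho = unname(sp$estimate),
      spearman_p = sp$p.value, note = NA_character_)
  }
  structure(list(data = data, property = property, stats = stats),
    class = "vsp_association")
}

#' @export
print.vsp_association <- function(x, ...) {
  cat(sprintf("<vsp_association> activity vs %s, n = %d\n", x$property,
    x$stats$n))
  print(x$stats)
  invisible(x)
}

#' Relative in vitro phosphatase activity
#'
#' Normalizes replicate phosphate-release measurements (malachite-green
#' readout) of each construct to the mean of a reference construct (wild
#' type), returning per-construct mean and SD of the relative activity.
#'
#' @param plate Tibble with columns `construct` and `phosphate` (one row per
#'   replicate).
#' @param reference Name of the reference construct (default `"WT"`).
#' @return A tibble: `construct`, `n`, `relative_activity`, `sd`.
#' @export
relative_invitro_activity <- function(plate, reference = "WT") {
  if (!reference %in% plate$construct) {
    abort(sprintf("reference construct '%s' not in plate", reference),
      class = "vsp_parameter_error")
  }
  ref_mean <- mean(plate$phosphate[plate$construct == reference])
  if (!is.finite(ref_mean) || ref_mean <= 0) {
    abort("reference mean must be positive", class = "vsp_normalization_error")
  }
  plate |>
    dplyr::group_by(.data$construct) |>
    dplyr::summarise(
      n = dplyr::n(),
      relative_activity = mean(.data$phosphate / ref_mean),
      sd = sd(.data$phosphate / ref_mean),
      .groups = "drop"
    )
}

#' Two-sample comparison of group means
#'
#' Classical two-tailed Student's t-test (equal variances pooled) between two
#' groups of measurements; a Welch variant is available.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @param welch Use the Welch (unequal-variance) variant.
#' @return The two-tailed p-value.
#' @export
compare_groups <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs at least 2 observations", class = "vsp_parameter_error")
  }
  t.test(a, b, var.equal = !welch)$p.value
}
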