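#' Generate a synthetic F-V dataset
#'
#' Evaluates a one- or two-component Boltzmann curve on a voltage grid and
#' adds Gaussian noise. Component magnitudes default to the wild-type-like
#' two-component decomposition (ratio 24.3/75.7, half-maximum potentials
#' 27.1 and 82.7 mV, slopes 10 and 15 mV).
#'
#' @param components Tibble with columns `A`, `v_half_mV`, `slope_mV`.
#' @param voltages Voltage grid, mV.
#' @param noise_sd Additive noise SD in F units (e.g., 3% of the total
#'   amplitude: `0.03 * sum(abs(components$A))`).
#' @param seed RNG seed.
#' @return An F-V tibble (`v_mV`, `f`) with a [ground_truth()] attribute.
#' @export
sim_fv_dataset <- function(components = wt_boltzmann_components(),
                           voltages = seq(-60, 200, by = 20),
                           noise_sd = 0, seed = 1) {
  stopifnot(noise_sd >= 0)
  f <- boltzmann_eval(voltages, components)
  if (noise_sd > 0) {
    with_seed(seed, {
      f <- f + rnorm(length(f), 0, noise_sd)
    })
  }
  out <- tibble(v_mV = voltages, f = f)
  structure(out, class = c("vsp_fv", class(out)),
    strategy = "synthetic", normalized = FALSE, reference_mV = NA_real_,
    ground_truth = list(
      generator = "fv_dataset", seed = seed,
      params = list(components = components, voltages = voltages,
        noise_sd = noise_sd)
    ))
}

#' Wild-type-like two-component Boltzmann decomposition
#'
#' The default generative truth for two-component F-V data: amplitude ratio
#' 24.3/75.7 (%), half-maximum potentials 27.1 and 82.7 mV, slopes 10 and
#' 15 mV, total amplitude 1.
#'
#' @return A two-row components tibble (`A`, `v_half_mV`, `slope_mV`).
#' @export
wt_boltzmann_components <- function() {
  tibble(A = c(0.243, 0.757), v_half_mV = c(27.1, 82.7), slope_mV = c(10, 15))
}

#' Generate synthetic voltage-clamp fluorometry sweeps
#'
#' Builds one Delta-F/F trace per test voltage: baseline zero before the pulse
#' onset, then a one- or two-exponential relaxation whose end-of-pulse value
#' equals the generating Boltzmann F(V) exactly (the relaxation is rescaled so
#' the final sample hits the endpoint, making endpoint extraction an exact
#' inverse at zero noise).
#'
#' @param components Boltzmann components (see [sim_fv_dataset()]).
#' @param voltages Test voltages, mV.
#' @param tau_fast_ms,tau_slow_ms Relaxation time constants, ms.
#' @param slow_fraction Fraction of the amplitude in the slow component
#'   (0 gives a single exponential).
#' @param pulse_ms Pulse window `c(onset, end)`, ms.
#' @param dt_ms Sampling interval, ms.
#' @param noise_sd Additive per-sample noise SD.
#' @param seed RNG seed.
#' @return A sweep tibble (`voltage_mV`, `time_ms`, `df_over_f`) with a
#'   [ground_truth()] attribute (including the endpoint F(V) per voltage).
#' @export
sim_fluorescence_sweeps <- function(components = wt_boltzmann_components(),
                                    voltages = seq(-60, 200, by = 20),
                                    tau_fast_ms = 5, tau_slow_ms = 50,
                                    slow_fraction = 0.4,
                                    pulse_ms = c(50, 550), dt_ms = 1,
                                    noise_sd = 0, seed = 1) {
  stopifnot(tau_fast_ms > 0, tau_slow_ms > 0,
    slow_fraction >= 0, slow_fraction <= 1, noise_sd >= 0)
  f_end <- boltzmann_eval(voltages, components)
  t <- seq(0, pulse_ms[2], by = dt_ms)
  tp <- pmax(0, t - pulse_ms[1])
  shape <- (1 - slow_fraction) * (1 - exp(-tp / tau_fast_ms)) +
    slow_fraction * (1 - exp(-tp / tau_slow_ms))
  shape <- shape / shape[length(shape)] # endpoint hits F(V) exactly
  sweeps <- purrr::map_dfr(seq_along(voltages), function(i) {
    tibble(voltage_mV = voltages[i], time_ms = t,
      df_over_f = f_end[i] * shape)
  })
  if (noise_sd > 0) {
    with_seed(seed, {
      sweeps$df_over_f <- sweeps$df_over_f + rnorm(nrow(sweeps), 0, noise_sd)
    })
  }
  structure(sweeps, ground_truth = list(
    generator = "fluorescence_sweeps", seed = seed,
    params = list(components = components, voltages = voltages,
      tau_fast_ms = tau_fast_ms, tau_slow_ms = tau_slow_ms,
      slow_fraction = slow_fraction, pulse_ms = pulse_ms, dt_ms = dt_ms,
      noise_sd = noise_sd),
    f_end = setNames(f_end, voltages)
  ))
}
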