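#' Generate an episodic Kir recording
#'
#' Synthesizes a two-electrode voltage-clamp recording of the Kir readout
#' protocol: per episode a ramp segment, a test pulse whose amplitude decays
#' exponentially in accumulated depolarization time, and a depolarization
#' segment. The test-pulse amplitude of episode i is
#' `amp0 * ((1 - C) * exp(-k * (i - 1) * depol_ms / 1000) + C)` plus Gaussian
#' noise of SD `noise_sd * |amp0|`.
#'
#' @param k Decay rate constant, 1/s (> 0).
#' @param C Plateau fraction in `[0, 1)`.
#' @param noise_sd Amplitude noise SD as a fraction of `|amp0|`.
#' @param n_episodes Number of episodes (>= 2; the standard protocol uses 20).
#' @param depol_ms Depolarization duration per episode, ms (300 or 50).
#' @param amp0 First-episode test-pulse amplitude, microamps (negative for
#'   inward Kir current).
#' @param seed RNG seed.
#' @param protocol A [kir_protocol()]; built from `depol_ms` when `NULL`.
#' @return A tidy recording tibble (`episode`, `time_ms`, `current_uA`) with
#'   attributes `protocol` and [ground_truth()].
#' @export
sim_kir_recording <- function(k, C = 0, noise_sd = 0, n_episodes = 20,
                              depol_ms = 300, amp0 = -10, seed = 1,
                              protocol = NULL) {
  stopifnot(k > 0, C >= 0, C < 1, n_episodes >= 2, noise_sd >= 0)
  protocol <- protocol %||% kir_protocol(depol_duration_ms = depol_ms)
  i <- seq_len(n_episodes)
  amp_true <- amp0 * ((1 - C) * exp(-k * (i - 1) * depol_ms / 1000) + C)
  amps <- amp_true
  if (noise_sd > 0) {
    with_seed(seed, {
      amps <- amp_true + rnorm(n_episodes, 0, noise_sd * abs(amp0))
    })
  }
  t_end <- protocol$depol_ms[2] + 20
  tgrid <- seq(0, t_end, by = protocol$dt_ms)
  ramp_frac <- pmin(1, pmax(0,
    (tgrid - protocol$ramp_ms[1]) / diff(protocol$ramp_ms)))
  in_test <- tgrid >= protocol$test_ms[1] & tgrid <= protocol$test_ms[2]
  in_ramp <- tgrid >= protocol$ramp_ms[1] & tgrid < protocol$ramp_ms[1] +
    diff(protocol$ramp_ms)
  in_depol <- tgrid > protocol$depol_ms[1] & tgrid <= protocol$depol_ms[2]
  rec <- purrr::map_dfr(i, function(ep) {
    cur <- numeric(length(tgrid))
    cur[in_ramp] <- amps[ep] * ramp_frac[in_ramp]
    cur[in_test] <- amps[ep]
    cur[in_depol] <- 2 # outward current during the depolarizing step
    tibble(episode = ep, time_ms = tgrid, current_uA = cur)
  })
  structure(rec, protocol = protocol, ground_truth = list(
    generator = "kir_recording", seed = seed,
    params = list(k = k, C = C, noise_sd = noise_sd, n_episodes = n_episodes,
      depol_ms = depol_ms, amp0 = amp0),
    amp_true = amp_true, amp_realized = amps
  ))
}

#' Generate sensing-current sweeps with P/N subsweeps
#'
#' Synthesizes a repolarization-step sweep (150 mV to the holding potential)
#' carrying an exponential off-sensing transient of total charge `q_off_nC`
#' with time constant `tau_off_ms`, on top of a linear (ohmic) leak, plus the
#' matching P/N subsweeps in which only the leak appears at 1/N amplitude.
#'
#' @param q_off_nC Total transient charge, nC.
#' @param tau_off_ms Transient time constant, ms.
#' @param leak_G_uS Leak conductance, microsiemens.
#' @param pn_order The N of the P/N protocol (4-8).
#' @param seed RNG seed (reserved; the generator is currently deterministic).
#' @param step_from_mV,holding_mV Step voltages.
#' @param step_onset_ms Step time, ms.
#' @param sweep_ms Sweep length, ms.
#' @param dt_ms Sampling interval, ms.
#' @return A list with `sweep` (tibble `time_ms`, `current_uA`), `pn_sweeps`
#'   (tibble `sub`, `time_ms`, `current_uA`), `step_onset_ms`, `pn_order`, and
#'   a [ground_truth()] attribute.
#' @export
sim_sensing_sweeps <- function(q_off_nC = 25, tau_off_ms = 5, leak_G_uS = 0.1,
                               pn_order = 4, seed = 1,
                               step_from_mV = 150, holding_mV = -60,
                               step_onset_ms = 20, sweep_ms = 80,
                               dt_ms = 0.1) {
  stopifnot(q_off_nC >= 0, tau_off_ms > 0, pn_order >= 4, pn_order <= 8)
  t <- seq(0, sweep_ms, by = dt_ms)
  v <- ifelse(t < step_onset_ms, step_from_mV, holding_mV)
  leak <- leak_G_uS * v / 1000 # uS * mV / 1000 = uA
  trans <- ifelse(t >= step_onset_ms,
    -(q_off_nC / tau_off_ms) * exp(-(t - step_onset_ms) / tau_off_ms), 0)
  sweep <- tibble(time_ms = t, current_uA = leak + trans)
  pn <- purrr::map_dfr(seq_len(pn_order), function(s) {
    tibble(sub = s, time_ms = t, current_uA = leak / pn_order)
  })
  structure(list(
    sweep = sweep, pn_sweeps = pn,
    step_onset_ms = step_onset_ms, pn_order = pn_order
  ), ground_truth = list(
    generator = "sensing_sweeps", seed = seed,
    params = list(q_off_nC = q_off_nC, tau_off_ms = tau_off_ms,
      leak_G_uS = leak_G_uS, pn_order = pn_order,
      step_from_mV = step_from_mV, holding_mV = holding_mV,
      step_onset_ms = step_onset_ms, sweep_ms = sweep_ms, dt_ms = dt_ms)
  ))
}

#' Generate an in vitro phosphatase activity plate
#'
#' Replicate phosphate-release measurements (malachite-green style) for a set
#' of constructs with known true activities relative to the reference,
#' multiplicative Gaussian noise of coefficient of variation `cv`.
#'
#' @param true_relative Named numeric vector of true relative activities; must
#'   include the reference construct (value 1 by convention).
#' @param cv Coefficient of variation of the replicate noise.
#' @param replicates Replicates per construct.
#' @param base_phosphate Phosphate released by one unit of relative activity
#'   (arbitrary units).
#' @param seed RNG seed.
#' @return A plate tibble (`construct`, `replicate`, `phosphate`) with a
#'   [ground_truth()] attribute.
#' @export
sim_invitro_plate <- function(true_relative = c(WT = 1, L284F = 0.9,
                                L284Q = 0.35, F285Q = 0.3),
                              cv = 0.1, replicates = 9,
                              base_phosphate = 10, seed = 1) {
  stopifnot(cv >= 0, replicates >= 1)
  with_seed(seed, {
    plate <- purrr::imap_dfr(as.list(true_relative), function(act, con) {
      mu <- base_phosphate * act
      tibble(
        construct = con, replicate = seq_len(replicates),
        phosphate = pmax(0, mu * (1 + rnorm(replicates, 0, cv)))
      )
    })
  })
  structure(plate, ground_truth = list(
    generator = "invitro_plate", seed = seed,
    params = list(true_relative = true_relative, cv = cv,
      replicates = replicates, base_phosphate = base_phosphate)
  ))
}
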