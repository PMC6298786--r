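test_that("test-pulse amplitude is the mean over the window tail", {
  proto <- kir_protocol()
  t <- seq(0, 420, by = 0.2)
  flat <- tibble::tibble(time_ms = t,
    current_uA = ifelse(t >= 50 & t <= 100, -5, 0))
  expect_equal(extract_test_amplitude(flat, proto), -5)

  # linear ramp across the test window: oracle = mean of the tail samples
  ramped <- tibble::tibble(time_ms = t,
    current_uA = ifelse(t >= 50 & t <= 100, -(t - 50) / 10, 0))
  sel <- t >= 98 & t <= 100
  expect_equal(extract_test_amplitude(ramped, proto),
    sum(-(t[sel] - 50) / 10) / sum(sel))

  # averaging over one sample period returns the endpoint region only
  expect_equal(extract_test_amplitude(flat, proto, averaging_ms = 0.2), -5)

  short <- tibble::tibble(time_ms = seq(0, 60, 0.2), current_uA = 0)
  expect_error(extract_test_amplitude(short, proto),
    class = "vsp_protocol_error")
})

test_that("decay series normalizes to the first episode over accumulated time", {
  proto <- kir_protocol(depol_duration_ms = 300)
  t <- seq(0, 420, by = 0.2)
  mk <- function(amp, ep) tibble::tibble(episode = ep, time_ms = t,
    current_uA = ifelse(t >= 50 & t <= 100, amp, 0))
  rec <- dplyr::bind_rows(mk(-10, 1), mk(-5, 2), mk(-2.5, 3))
  s <- build_decay_series(rec, proto)
  expect_equal(s$i_norm, c(1, 0.5, 0.25))
  expect_equal(s$t_acc_s, c(0, 0.3, 0.6))

  # 20 episodes x 50 ms -> accumulated endpoint 0.95 s
  rec20 <- sim_kir_recording(k = 2, n_episodes = 20, depol_ms = 50)
  s20 <- build_decay_series(rec20)
  expect_equal(max(s20$t_acc_s), 0.95)
  expect_equal(s20$i_norm[1], 1)

  # identical amplitudes -> all ones
  rec_c <- dplyr::bind_rows(mk(-4, 1), mk(-4, 2), mk(-4, 3))
  expect_equal(build_decay_series(rec_c, proto)$i_norm, rep(1, 3))

  rec_z <- dplyr::bind_rows(mk(0, 1), mk(-1, 2))
  expect_error(build_decay_series(rec_z, proto),
    class = "vsp_normalization_error")
  expect_error(build_decay_series(dplyr::bind_rows(mk(-3, 1), mk(-2, 2)),
    proto, expected_sign = 1), class = "vsp_normalization_error")

  # scale invariance: k is unchanged when all raw amplitudes are rescaled
  s_a <- build_decay_series(sim_kir_recording(k = 3, C = 0.1, amp0 = -10))
  s_b <- build_decay_series(sim_kir_recording(k = 3, C = 0.1, amp0 = -2.5))
  expect_equal(fit_decay(s_a)$k_per_s, fit_decay(s_b)$k_per_s,
    tolerance = 1e-9)
})

test_that("decay fit recovers noiseless parameters to numerical tolerance", {
  for (k_true in c(0.05, 0.5, 2, 5, 15)) {
    s <- build_decay_series(sim_kir_recording(k = k_true, C = 0,
      n_episodes = 20, depol_ms = 300))
    f <- fit_decay(s)
    expect_false(f$capped)
    expect_equal(f$k_per_s, k_true, tolerance = 1e-6)
    expect_equal(f$tau_s, 1 / k_true, tolerance = 1e-6)
    expect_lt(f$plateau, 1e-6)
  }
  # with a true plateau
  s_c <- build_decay_series(sim_kir_recording(k = 4, C = 0.2))
  f_c <- fit_decay(s_c)
  expect_equal(f_c$k_per_s, 4, tolerance = 1e-6)
  expect_equal(f_c$plateau, 0.2, tolerance = 1e-6)

  # fixed-zero plateau option
  f_z <- fit_decay(build_decay_series(sim_kir_recording(k = 4, C = 0)),
    plateau = "zero")
  expect_equal(f_z$k_per_s, 4, tolerance = 1e-6)
  expect_equal(f_z$plateau, 0)
})

test_that("cap rule fires iff the second episode drops below 1%", {
  mk_series <- function(i2) {
    tibble::tibble(
      t_acc_s = seq(0, 5.7, by = 0.3),
      i_norm = c(1, i2, rep(i2 / 2, 18))
    )
  }
  capped <- fit_decay(mk_series(0.005))
  expect_true(capped$capped)
  expect_identical(capped$k_per_s, 15.4)
  expect_identical(capped$tau_s, 0.065)

  expect_false(fit_decay(mk_series(0.02))$capped)
  # boundary: exactly 1% is not capped ("less than 1%")
  expect_false(fit_decay(mk_series(0.01))$capped)
  # independence of later episodes
  s_late <- mk_series(0.005)
  s_late$i_norm[10] <- 0.9
  expect_true(fit_decay(s_late)$capped)

  # a fast generator run routes into the cap downstream
  rec_fast <- sim_kir_recording(k = 50, n_episodes = 20, depol_ms = 300)
  expect_lt(build_decay_series(rec_fast)$i_norm[2], 0.01)
  expect_true(fit_decay(build_decay_series(rec_fast))$capped)
})

test_that("non-decaying series warns and returns a near-zero rate", {
  s <- tibble::tibble(t_acc_s = seq(0, 2, by = 0.25),
    i_norm = c(1, 1.01, 1.02, 1.01, 1.03, 1.02, 1.04, 1.03, 1.05))
  expect_warning(f <- fit_decay(s), "does not decay")
  expect_lt(f$k_per_s, 0.1)
})

test_that("Monte-Carlo decay recovery stays within stated error bounds", {
  # study conditions: k = 2/s, plateau 0.1, sd 0.02, 20 episodes x 300 ms
  k_hat <- vapply(1:40, function(s) {
    rec <- sim_kir_recording(k = 2, C = 0.1, noise_sd = 0.02,
      n_episodes = 20, depol_ms = 300, seed = s)
    fit_decay(build_decay_series(rec))$k_per_s
  }, numeric(1))
  rel_err <- abs(k_hat - 2) / 2
  expect_lt(median(rel_err), 0.05)
  expect_lt(abs(mean(k_hat) - 2) / 2, 0.02)
})

test_that("off-sensing charge integrates the leak-subtracted transient", {
  # rectangular transient of 1 uA x 10 ms with zero leak -> 10 nC
  t <- seq(0, 80, by = 0.1)
  sweep <- tibble::tibble(time_ms = t,
    current_uA = ifelse(t >= 20 & t < 30, 1, 0))
  pn <- purrr::map_dfr(1:4, function(s) tibble::tibble(
    sub = s, time_ms = t, current_uA = 0))
  q <- integrate_off_sensing_charge(sweep, pn, step_onset_ms = 20,
    pn_order = 4, adaptive = FALSE, window_end_ms = 40)
  expect_equal(q$q_off_nC, 10, tolerance = 0.02)

  # pure linear leak cancels exactly under ideal P/4 subsweeps
  leak <- 0.3 + 0.002 * t
  sweep_l <- tibble::tibble(time_ms = t, current_uA = leak)
  pn_l <- purrr::map_dfr(1:4, function(s) tibble::tibble(
    sub = s, time_ms = t, current_uA = leak / 4))
  q_l <- integrate_off_sensing_charge(sweep_l, pn_l, 20, 4,
    adaptive = FALSE, window_end_ms = 60)
  expect_equal(q_l$q_off_nC, 0, tolerance = 1e-9)

  # generator ground truth recovered within 2%, invariant to doubled leak
  g1 <- sim_sensing_sweeps(q_off_nC = 25, tau_off_ms = 5, leak_G_uS = 0.1)
  r1 <- integrate_off_sensing_charge(g1$sweep, g1$pn_sweeps,
    g1$step_onset_ms, g1$pn_order)
  expect_lt(abs(r1$q_off_nC - 25) / 25, 0.02)

  g2 <- sim_sensing_sweeps(q_off_nC = 25, tau_off_ms = 5, leak_G_uS = 0.2)
  r2 <- integrate_off_sensing_charge(g2$sweep, g2$pn_sweeps,
    g2$step_onset_ms, g2$pn_order)
  expect_equal(r2$q_off_nC, r1$q_off_nC, tolerance = 1e-6)

  # additive offset is removed by baseline correction
  g3 <- sim_sensing_sweeps(q_off_nC = 25, tau_off_ms = 5, leak_G_uS = 0.1)
  g3$sweep$current_uA <- g3$sweep$current_uA + 0.5
  r3 <- integrate_off_sensing_charge(g3$sweep, g3$pn_sweeps,
    g3$step_onset_ms, g3$pn_order)
  expect_equal(r3$q_off_nC, r1$q_off_nC, tolerance = 1e-6)

  # mismatched timebase
  bad <- g1$pn_sweeps
  bad$time_ms <- bad$time_ms + 0.01
  expect_error(integrate_off_sensing_charge(g1$sweep, bad,
    g1$step_onset_ms, 4), class = "vsp_protocol_error")
})

test_that("activity-property association reports both coefficients", {
  acts <- tibble::tibble(residue = c("G", "A", "V", "L", "F"),
    k_per_s = c(1, 2, 3, 4, 5))
  props <- tibble::tibble(residue = c("G", "A", "V", "L", "F"),
    hydrophobicity = c(1, 2, 3, 4, 5) * 0.5 - 1) # exactly linear in k
  a <- correlate_activity_property(acts, props)
  expect_equal(a$stats$pearson_r, 1)
  expect_equal(a$stats$spearman_rho, 1)

  # constant activities -> undefined, reported as such
  acts_c <- acts
  acts_c$k_per_s <- 2
  a_c <- correlate_activity_property(acts_c, props)
  expect_true(is.na(a_c$stats$pearson_r))
  expect_match(a_c$stats$note, "undefined")

  # random pairs match the textbook-formula oracle
  set.seed(31)
  acts_r <- tibble::tibble(residue = letters[1:8], k_per_s = runif(8, 0, 10))
  props_r <- tibble::tibble(residue = letters[1:8],
    hydrophobicity = rnorm(8))
  a_r <- correlate_activity_property(acts_r, props_r)
  expect_equal(a_r$stats$pearson_r,
    oracle_pearson(props_r$hydrophobicity, acts_r$k_per_s),
    tolerance = 1e-12)

  expect_error(correlate_activity_property(acts[1:2, ], props),
    class = "vsp_parameter_error")
})

test_that("in vitro activities are normalized to the reference mean", {
  plate <- tibble::tibble(
    construct = rep(c("WT", "mut"), each = 3),
    replicate = rep(1:3, 2),
    phosphate = c(9, 10, 11, 4.5, 5, 5.5)
  )
  rel <- relative_invitro_activity(plate)
  expect_equal(rel$relative_activity[rel$construct == "WT"], 1)
  expect_equal(rel$relative_activity[rel$construct == "mut"], 0.5)

  # summation oracle on a random table
  set.seed(32)
  plate_r <- tibble::tibble(
    construct = rep(c("WT", "m1", "m2"), each = 5),
    replicate = rep(1:5, 3),
    phosphate = runif(15, 1, 20)
  )
  rel_r <- relative_invitro_activity(plate_r)
  ref_mean <- mean(plate_r$phosphate[plate_r$construct == "WT"])
  for (con in c("WT", "m1", "m2")) {
    v <- plate_r$phosphate[plate_r$construct == con] / ref_mean
    expect_equal(rel_r$relative_activity[rel_r$construct == con], mean(v))
    expect_equal(rel_r$sd[rel_r$construct == con], sd(v))
  }
  expect_error(relative_invitro_activity(plate, reference = "hPTEN"),
    class = "vsp_parameter_error")

  # generator with zero CV returns the truth exactly
  p0 <- sim_invitro_plate(c(WT = 1, mut = 0.5), cv = 0, replicates = 9)
  r0 <- relative_invitro_activity(p0)
  expect_equal(r0$relative_activity[r0$construct == "mut"], 0.5)
})

test_that("group comparison is the classical two-tailed t-test", {
  a <- c(1, 2, 3, 4)
  expect_equal(compare_groups(a, a), 1)
  expect_lt(compare_groups(a, a + 100 * sd(a)), 1e-8)
  set.seed(33)
  x <- rnorm(6)
  y <- rnorm(5, 0.5)
  expect_equal(compare_groups(x, y), oracle_t_p(x, y), tolerance = 1e-12)
  expect_error(compare_groups(1, c(1, 2)), class = "vsp_parameter_error")
})

test_that("decay fit tidiers expose parameters and fit summary", {
  f <- fit_decay(build_decay_series(sim_kir_recording(k = 3, C = 0.1)))
  td <- tidy(f)
  expect_true(all(c("k_per_s", "plateau", "tau_s") %in% td$term))
  expect_equal(td$estimate[td$term == "tau_s"],
    1 / td$estimate[td$term == "k_per_s"])
  g <- glance(f)
  expect_equal(g$k_per_s, f$k_per_s)
  expect_false(g$capped)
  p <- autoplot(f)
  expect_s3_class(p, "ggplot")
})
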